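# Canonical k-mer and minimizer extraction; per-sample k-mer counting.
#
# Seeds are always canonical (lexicographic minimum of a window and its
# reverse complement, byte order A<C<G<T) so that reads from opposite strands
# of the same locus still share them. Each m-mer is canonicalized BEFORE the
# window minimum is taken, which makes minimizer sets strand-invariant too.
# Any window containing a non-ACGT character (e.g. N) is skipped entirely.
# The heavy lifting lives in src/seeds.cpp.

#' Seed extraction parameters
#'
#' @param k k-mer length (also the minimizer window length). Default 41.
#' @param m minimizer length, `1 <= m <= k`. Default 22.
#' @param mode `"kmer"` or `"minimizer"`. Minimizers compress runs of adjacent
#'   shared k-mers into single seeds, shrinking the overlap graph without a
#'   practical loss of sensitivity on short reads.
#' @return An object of class `seed_params`.
#' @export
seed_params <- function(k = 41L, m = 22L, mode = c("minimizer", "kmer")) {
  mode <- match.arg(mode)
  k <- as.integer(k); m <- as.integer(m)
  if (k < 2L) stop("k must be >= 2")
  if (m < 1L || m > k) stop("m must satisfy 1 <= m <= k")
  structure(list(k = k, m = m, mode = mode), class = "seed_params")
}

#' @export
print.seed_params <- function(x, ...) {
  cat(sprintf("seed_params: mode=%s k=%d m=%d\n", x$mode, x$k, x$m))
  invisible(x)
}

#' Canonical form of DNA sequences
#'
#' The lexicographic minimum of each sequence and its reverse complement.
#' Idempotent. Errors on characters outside `{A,C,G,T}` — callers are
#' expected to pre-filter N-containing windows.
#'
#' @param seqs Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
canonical <- function(seqs) {
  cpp_canonical(seqs)
}

#' Canonical k-mers of a sequence
#'
#' One k-mer per position `1..nchar(seq)-k+1`, in order; windows containing
#' N are skipped; each emitted k-mer is canonical. Empty if the sequence is
#' shorter than `k`.
#'
#' @param seq A single DNA string.
#' @param k k-mer length.
#' @return Character vector of canonical k-mers (possibly with duplicates).
#' @export
kmers <- function(seq, k) {
  cpp_kmers(seq, as.integer(k))
}

#' Window minimizers of a sequence
#'
#' For every k-length window, the lexicographically smallest canonical m-mer
#' among its `k - m + 1` constituents; the distinct set of these window
#' minima is returned (adjacent windows usually share their minimizer, which
#' is the compression). Windows containing N are skipped.
#'
#' @param seq A single DNA string.
#' @param params A [seed_params()] object (uses its `k` and `m`).
#' @return Character vector (a set) of canonical m-mers.
#' @export
minimizers <- function(seq, params) {
  cpp_minimizers(seq, params$k, params$m)
}

# Distinct seed set per read (list of character vectors), per the configured
# mode. Internal: this is what the overlap graph is built from.
seed_sets <- function(sequences, params) {
  cpp_seed_sets(sequences, params$k, params$m, params$mode == "minimizer")
}

#' Count canonical k-mers per sample
#'
#' Occurrence counts of every canonical k-mer, kept separate per sample.
#' Absent (kmer, sample) pairs mean count zero.
#'
#' @param reads A reads table from [load_reads()] (columns `sample_id`,
#'   `sequence`).
#' @param k k-mer length.
#' @param kmers Optional character vector restricting counting to a fixed
#'   k-mer set (canonical); used to pull representative-k-mer counts out of
#'   whole samples without materializing the full spectrum.
#' @return A `data.table` with columns `kmer`, `sample_id`, `count`.
#' @export
count_kmers_by_sample <- function(reads, k, kmers = NULL) {
  k <- as.integer(k)
  samples <- sort_c(unique(reads$sample_id))
  pieces <- lapply(samples, function(s) {
    cnt <- cpp_count_kmers(reads$sequence[reads$sample_id == s], k, kmers)
    if (!length(cnt)) return(NULL)
    data.table::data.table(kmer = names(cnt), sample_id = s,
                           count = as.integer(cnt))
  })
  out <- data.table::rbindlist(pieces)
  if (!nrow(out))
    out <- data.table::data.table(kmer = character(), sample_id = character(),
                                  count = integer())
  out[]
}
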