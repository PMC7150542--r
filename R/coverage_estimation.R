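# Per-sample sequencing coverage of read clusters via representative k-mers.
#
# The pooled (all samples combined) k-mer frequency spectrum of a cluster
# peaks at the sequencing depth of its underlying genome region (in k-mer
# count units, i.e. roughly base coverage scaled by (L-k+1)/L for read
# length L). k-mers drawn near that peak are "representative": their
# per-sample counts, summarized by the median, estimate the cluster's
# coverage in each sample. Counts below an error floor are ignored when
# locating the peak, because sequencing-error k-mers pile up at count 1.

#' Coverage-estimation parameters
#'
#' @param rp Number of representative k-mers per cluster. Default 100.
#' @param error_count_floor Pooled counts below this are ignored for peak
#'   finding (error k-mers dominate count 1). Default 2.
#' @param peak_window Representative k-mers are drawn with pooled count in
#'   `[peak - peak_window, peak + peak_window]`. Default 2.
#' @return An object of class `global_params`.
#' @export
global_params <- function(rp = 100L, error_count_floor = 2L,
                          peak_window = 2L) {
  p <- list(rp = as.integer(rp),
            error_count_floor = as.integer(error_count_floor),
            peak_window = as.integer(peak_window))
  if (p$rp < 1L) stop("rp must be >= 1")
  if (p$error_count_floor < 1L) stop("error_count_floor must be >= 1")
  if (p$peak_window < 0L) stop("peak_window must be >= 0")
  structure(p, class = "global_params")
}

# Pooled canonical k-mer counts over the reads of one cluster (named integer
# vector). Internal building block shared by spectrum and selection.
cluster_kmer_counts <- function(read_ids, reads, k) {
  seqs <- reads$sequence[match(read_ids, reads$read_id)]
  if (anyNA(seqs)) stop("cluster contains read ids absent from the read set")
  cpp_count_kmers(seqs, as.integer(k))
}

#' k-mer frequency spectrum of a read cluster
#'
#' Histogram of pooled (all-samples-combined) occurrence counts over the
#' distinct canonical k-mers of the cluster's reads.
#'
#' @param read_ids Read ids of the cluster.
#' @param reads Reads table.
#' @param k k-mer length.
#' @return A `data.table` with columns `count` and `n_kmers` (number of
#'   distinct k-mers having that pooled count), sorted by `count`.
#' @export
cluster_spectrum <- function(read_ids, reads, k) {
  if (!length(read_ids)) stop("cluster is empty")
  counts <- cluster_kmer_counts(read_ids, reads, k)
  dt <- data.table::data.table(count = as.integer(counts))
  spec <- dt[, .(n_kmers = .N), by = count]
  data.table::setorder(spec, count)
  spec[]
}

#' Locate the coverage peak of a k-mer spectrum
#'
#' Counts below `error_count_floor` are discarded, then the peak is the
#' count maximizing the k-mer mass `count * n_kmers` smoothed over a
#' centered window of `2 * smooth_window + 1` count values (missing counts
#' contribute zero); ties are broken toward the larger count. Mass rather
#' than raw k-mer number is maximized because coincident sequencing-error
#' k-mers pile up just above the floor in sparse per-cluster spectra and
#' would otherwise out-vote the (spread-out) true coverage mode; the mass
#' criterion agrees with the raw mode whenever the spectrum has a single
#' clean peak. If nothing survives the floor the spectrum carries no
#' coverage signal and a classed error (`readclust_unreliable_spectrum`) is
#' raised; callers drop such clusters from global clustering.
#'
#' @param spectrum A spectrum from [cluster_spectrum()].
#' @param error_count_floor Minimum count considered.
#' @param smooth_window Half-width of the smoothing window (in count units).
#' @return Integer peak count.
#' @export
find_peak <- function(spectrum, error_count_floor = 2L, smooth_window = 2L) {
  sub <- spectrum[count >= error_count_floor]
  if (!nrow(sub))
    stop(structure(class = c("readclust_unreliable_spectrum", "error",
                             "condition"),
                   list(message = "spectrum empty after error-count floor; unreliable",
                        call = sys.call())))
  mass <- numeric(max(sub$count) + smooth_window)
  mass[sub$count] <- as.numeric(sub$count) * sub$n_kmers
  smoothed_at <- vapply(sub$count, function(c) {
    lo <- max(c - smooth_window, 1L)
    sum(mass[lo:(c + smooth_window)])
  }, numeric(1))
  best <- order(-smoothed_at, -mass[sub$count], -sub$count)[1]
  sub$count[best]
}

#' Select representative k-mers for a cluster
#'
#' Distinct k-mers whose pooled count lies within `peak_window` of the peak;
#' if more than `rp` candidates exist, the `rp` selected deterministically by
#' (distance from peak, lexicographic k-mer) ordering; if fewer, all.
#'
#' @param kmer_counts Named integer vector of pooled per-k-mer counts
#'   (e.g. from the cluster's reads).
#' @param peak Peak count from [find_peak()].
#' @param params A [global_params()] object.
#' @return Character vector of canonical k-mers, length `<= params$rp`.
#' @export
select_representative_kmers <- function(kmer_counts, peak, params) {
  cnt <- as.integer(kmer_counts)
  km <- names(kmer_counts)
  in_win <- abs(cnt - peak) <= params$peak_window
  km <- km[in_win]; cnt <- cnt[in_win]
  ord <- order_c(abs(cnt - peak), km)
  head(km[ord], params$rp)
}

#' Per-sample coverage vector of a cluster
#'
#' For each sample, the median count of the cluster's representative k-mers
#' in that sample; k-mers absent from a sample count as 0. Even-cardinality
#' medians are the mean of the two central values. The median damps both
#' repeat-inflated and error-deflated counts.
#'
#' @param rep_kmers Representative k-mers of the cluster.
#' @param sample_counts Per-sample k-mer counts
#'   ([count_kmers_by_sample()]), covering at least `rep_kmers`.
#' @param samples Ordered character vector of sample ids.
#' @return Numeric vector named by `samples`.
#' @export
coverage_vector <- function(rep_kmers, sample_counts, samples) {
  if (!length(rep_kmers)) stop("no representative k-mers")
  sub <- sample_counts[kmer %in% rep_kmers]
  vapply(samples, function(s) {
    cnt <- sub[sample_id == s]
    v <- cnt$count[match(rep_kmers, cnt$kmer)]
    v[is.na(v)] <- 0L
    stats::median(as.numeric(v))
  }, numeric(1))
}

#' Build the samples-by-clusters coverage matrix
#'
#' One column per cluster with a reliable spectrum; clusters whose spectrum
#' is empty after the error floor are excluded and reported in the
#' `"excluded"` attribute (they are carried through the merge stage
#' unmerged).
#'
#' @param assignment Cluster assignment (`read_id`, `cluster_id`).
#' @param reads Reads table covering every assigned read.
#' @param k k-mer length.
#' @param params A [global_params()] object.
#' @return Numeric matrix (samples x clusters) with `dimnames`; attribute
#'   `excluded` holds ids of clusters without a reliable spectrum, attribute
#'   `representatives` the list of representative k-mers per column.
#' @export
build_coverage_matrix <- function(assignment, reads, k = 41L,
                                  params = global_params()) {
  samples <- sort_c(unique(reads$sample_id))
  clusters <- sort_c(unique(assignment$cluster_id))
  reps <- vector("list", length(clusters))
  names(reps) <- clusters
  excluded <- character()
  for (cl in clusters) {
    ids <- assignment$read_id[assignment$cluster_id == cl]
    counts <- cluster_kmer_counts(ids, reads, k)
    spec <- data.table::data.table(count = as.integer(counts))[
      , .(n_kmers = .N), by = count]
    peak <- tryCatch(find_peak(spec, params$error_count_floor),
                     error = function(e) {
                       if (inherits(e, "readclust_unreliable_spectrum"))
                         return(NA_integer_)
                       stop(e)
                     })
    if (is.na(peak)) {
      excluded <- c(excluded, cl)
      next
    }
    reps[[cl]] <- select_representative_kmers(counts, peak, params)
  }
  kept <- setdiff(clusters, excluded)
  mat <- matrix(0, nrow = length(samples), ncol = length(kept),
                dimnames = list(samples, kept))
  if (length(kept)) {
    all_rep <- unique(unlist(reps[kept], use.names = FALSE))
    sc <- count_kmers_by_sample(reads, k, kmers = all_rep)
    for (cl in kept)
      mat[, cl] <- coverage_vector(reps[[cl]], sc, samples)
  }
  attr(mat, "excluded") <- excluded
  attr(mat, "representatives") <- reps[kept]
  mat
}

#' Write / read a coverage matrix
#'
#' TSV with first column `sample_id` and one column per cluster id.
#'
#' @param mat Coverage matrix from [build_coverage_matrix()].
#' @param path TSV path.
#' @export
write_coverage_matrix <- function(mat, path) {
  dt <- data.table::data.table(sample_id = rownames(mat))
  for (cl in colnames(mat)) dt[[cl]] <- mat[, cl]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_coverage_matrix
#' @export
read_coverage_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- dt$sample_id
  m
}
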