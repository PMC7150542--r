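# Truth-labeled multi-sample community simulator.
#
# Emulates the statistical structure the global stage exploits: every genome
# has a sample-specific abundance profile shared by all its reads, so read
# clusters from one genome covary across samples. Genomes are i.i.d. uniform
# ACGT (random 50 kb sequences share essentially no 41-mers, giving
# controlled separability); reads are drawn uniformly from a circularized
# genome (no edge-coverage artifacts), strands fairly, with i.i.d.
# substitution errors. Optional near-identical strain pairs exercise
# species-level purity.

#' Community specification
#'
#' @param n_genomes Number of genomes.
#' @param n_samples Number of samples.
#' @param genome_length Genome length in bp. Default 50000.
#' @param read_length Read length in bp. Default 150.
#' @param mean_base_coverage Expected base coverage per genome per sample at
#'   mean abundance; a scalar, or a length-`n_samples` vector giving each
#'   sample its own depth. Default 3 (with 10 samples this pools to ~30x per
#'   genome, the regime the default overlap-graph parameters are tuned for).
#' @param abundance Either `list(type = "lognormal", meanlog, sdlog)`
#'   (default `meanlog = 0`, `sdlog = 1`) or an explicit nonnegative
#'   `n_genomes x n_samples` matrix; columns are renormalized to sum to 1.
#' @param substitution_error_rate Per-base substitution probability.
#'   Default 0.005.
#' @param strain_divergence If set, genomes are paired into species and the
#'   second strain of each pair is a copy of the first with
#'   `Bernoulli(strain_divergence)` substitutions.
#' @param rng_seed Master seed; every operation derives its own stream from
#'   it by fixed offsets.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(n_genomes, n_samples, genome_length = 50000L,
                           read_length = 150L, mean_base_coverage = 3,
                           abundance = list(type = "lognormal",
                                            meanlog = 0, sdlog = 1),
                           substitution_error_rate = 0.005,
                           strain_divergence = NULL, rng_seed = 1L) {
  n_genomes <- as.integer(n_genomes); n_samples <- as.integer(n_samples)
  if (n_genomes < 1L || n_samples < 1L) stop("counts must be >= 1")
  if (as.integer(read_length) > as.integer(genome_length))
    stop("read_length must not exceed genome_length")
  if (substitution_error_rate < 0 || substitution_error_rate >= 1)
    stop("substitution_error_rate must lie in [0, 1)")
  if (!is.null(strain_divergence) &&
      (strain_divergence < 0 || strain_divergence >= 1))
    stop("strain_divergence must lie in [0, 1)")
  if (!length(mean_base_coverage) %in% c(1L, n_samples))
    stop("mean_base_coverage must be a scalar or one value per sample")
  if (any(mean_base_coverage <= 0)) stop("mean_base_coverage must be > 0")
  if (is.matrix(abundance)) {
    if (any(abundance < 0)) stop("explicit abundance matrix has negative entries")
    if (!all(dim(abundance) == c(n_genomes, n_samples)))
      stop("explicit abundance matrix must be n_genomes x n_samples")
  }
  structure(list(n_genomes = n_genomes, n_samples = n_samples,
                 genome_length = as.integer(genome_length),
                 read_length = as.integer(read_length),
                 mean_base_coverage = as.numeric(mean_base_coverage),
                 abundance = abundance,
                 substitution_error_rate = substitution_error_rate,
                 strain_divergence = strain_divergence,
                 rng_seed = as.integer(rng_seed)),
            class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat(sprintf(
    "community_spec: %d genomes x %d samples, %d bp genomes, %d bp reads, seed %d\n",
    x$n_genomes, x$n_samples, x$genome_length, x$read_length, x$rng_seed))
  invisible(x)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate community genomes
#'
#' i.i.d. uniform ACGT sequences. With `strain_divergence` set, genomes are
#' paired `(1,2), (3,4), ...` into species and the even member of each pair
#' is a diverged copy of the odd one; otherwise each genome is its own
#' species. Deterministic given the spec's seed.
#'
#' @param spec A [community_spec()].
#' @return `data.table` with columns `genome_id`, `species_id`, `sequence`.
#' @export
generate_genomes <- function(spec) {
  withr::with_seed(spec$rng_seed + 101L, {
    g <- spec$n_genomes
    genome_id <- sprintf("G%d", seq_len(g))
    if (is.null(spec$strain_divergence)) {
      species_id <- sprintf("S%d", seq_len(g))
      sequence <- vapply(seq_len(g), function(i) random_dna(spec$genome_length),
                         character(1))
    } else {
      species_id <- sprintf("S%d", (seq_len(g) + 1L) %/% 2L)
      sequence <- character(g)
      for (i in seq_len(g)) {
        sequence[i] <- if (i %% 2L == 1L) random_dna(spec$genome_length)
                       else mutate_dna(sequence[i - 1L], spec$strain_divergence)
      }
    }
    data.table::data.table(genome_id = genome_id, species_id = species_id,
                           sequence = sequence)
  })
}

#' Draw the genomes-by-samples relative abundance matrix
#'
#' Lognormal draws per (genome, sample) with columns renormalized to sum to
#' 1; an explicit matrix in the spec is validated and column-renormalized.
#'
#' @param spec A [community_spec()].
#' @return Numeric `n_genomes x n_samples` matrix; columns sum to 1.
#' @export
sample_abundance_matrix <- function(spec) {
  ab <- if (is.matrix(spec$abundance)) {
    spec$abundance
  } else {
    withr::with_seed(spec$rng_seed + 202L, {
      matrix(rlnorm(spec$n_genomes * spec$n_samples,
                    spec$abundance$meanlog, spec$abundance$sdlog),
             spec$n_genomes, spec$n_samples)
    })
  }
  cs <- colSums(ab)
  if (any(cs == 0)) stop("abundance matrix has an all-zero sample column")
  out <- sweep(ab, 2, cs, "/")
  dimnames(out) <- list(sprintf("G%d", seq_len(spec$n_genomes)),
                        sprintf("S%d", seq_len(spec$n_samples)))
  out
}

# Draw reads for one (genome, sample) pair; positions uniform on the forward
# strand of the circularized genome, strand fair, substitution errors i.i.d.
draw_reads <- function(genome_seq, n_reads, read_length, error_rate) {
  G <- nchar(genome_seq)
  doubled <- paste0(genome_seq, substr(genome_seq, 1L, read_length - 1L))
  start <- sample.int(G, n_reads, replace = TRUE)   # 1-based start
  seqs <- substring(doubled, start, start + read_length - 1L)
  rc <- runif(n_reads) < 0.5
  if (any(rc)) {
    seqs[rc] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[rc])))
  }
  n_err <- rbinom(n_reads, read_length, error_rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(n_err > 0L)) {
    pos <- sample.int(read_length, n_err[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  list(sequence = seqs, start = start, strand = ifelse(rc, "-", "+"))
}

#' Simulate multi-sample reads from a community
#'
#' For each (genome, sample), the read count is
#' `round(coverage_s * n_genomes * abundance * genome_length / read_length)`
#' where `coverage_s` is that sample's `mean_base_coverage`, so that the
#' expected base coverage of the genome in that sample equals
#' `coverage_s * n_genomes * abundance`. Reads are written as one FASTQ per
#' sample with truth tokens (`genome=`, `species=`) in the read names, next
#' to a manifest TSV and a truth TSV.
#'
#' @param genomes Genome table from [generate_genomes()].
#' @param abundances Abundance matrix from [sample_abundance_matrix()].
#' @param spec A [community_spec()].
#' @param outdir Output directory (created if needed).
#' @return List with `manifest` (loaded manifest table), `truth` (truth
#'   `data.table` including read `start` and `strand`), `reads` (in-memory
#'   reads table), and paths `manifest_path`, `truth_path`.
#' @export
simulate_reads <- function(genomes, abundances, spec, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cov <- rep(spec$mean_base_coverage, length.out = spec$n_samples)
  L <- spec$read_length
  withr::with_seed(spec$rng_seed + 303L, {
    man <- list(); truths <- list()
    for (s in seq_len(spec$n_samples)) {
      sid <- sprintf("S%d", s)
      recs <- list()
      offset <- 0L
      for (g in seq_len(spec$n_genomes)) {
        n_reads <- round(cov[s] * spec$n_genomes * abundances[g, s] *
                         spec$genome_length / L)
        if (n_reads < 1L) next
        dr <- draw_reads(genomes$sequence[g], n_reads, L,
                         spec$substitution_error_rate)
        recs[[length(recs) + 1L]] <- data.table::data.table(
          read_id = sprintf("%s_r%06d", sid, offset + seq_len(n_reads)),
          sample_id = sid,
          sequence = dr$sequence,
          genome_id = genomes$genome_id[g],
          species_id = genomes$species_id[g],
          start = dr$start, strand = dr$strand)
        offset <- offset + n_reads
      }
      smp <- data.table::rbindlist(recs)
      fq <- file.path(outdir, paste0(sid, ".fastq"))
      write_fastq(smp$sequence,
                  paste0(smp$read_id, " genome=", smp$genome_id,
                         " species=", smp$species_id),
                  fq)
      man[[s]] <- data.table::data.table(sample_id = sid,
                                         path = basename(fq),
                                         format = "fastq")
      truths[[s]] <- smp
    }
    manifest_path <- file.path(outdir, "manifest.tsv")
    data.table::fwrite(data.table::rbindlist(man), manifest_path, sep = "\t")
    truth <- data.table::rbindlist(truths)
    truth_path <- file.path(outdir, "truth.tsv")
    write_truth(truth, truth_path)
    list(manifest = load_manifest(manifest_path),
         truth = truth[],
         reads = truth[, .(read_id, sample_id, sequence,
                           truth_genome = genome_id,
                           truth_species = species_id)],
         manifest_path = manifest_path, truth_path = truth_path)
  })
}

# Plain 4-line FASTQ writer with constant qualities (no algorithm reads
# qualities; Biostrings' FASTQ writer requires a quality object, so the flat
# writer keeps the simulator dependency-light and byte-stable).
write_fastq <- function(sequences, names, path) {
  qual <- vapply(nchar(sequences),
                 function(n) strrep("I", n), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", names, "\n", sequences, "\n+\n", qual), con,
             sep = "\n")
  invisible(path)
}

#' Simulate a full community in one call
#'
#' [generate_genomes()] + [sample_abundance_matrix()] + [simulate_reads()].
#'
#' @param spec A [community_spec()].
#' @param outdir Output directory.
#' @return As [simulate_reads()], plus `genomes` and `abundances`.
#' @export
simulate_community <- function(spec, outdir) {
  genomes <- generate_genomes(spec)
  ab <- sample_abundance_matrix(spec)
  out <- simulate_reads(genomes, ab, spec, outdir)
  out$genomes <- genomes
  out$abundances <- ab
  out
}
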