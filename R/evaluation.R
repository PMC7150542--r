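# Purity / completeness scoring of clusterings against ground truth.
#
# Purity of a cluster: fraction of its reads from the predominant genome
# (or species). Completeness: fraction of ALL reads of that genome in the
# dataset — clustered or not — captured by the cluster. A genome counts as
# recovered when a single cluster simultaneously has purity > min_purity and
# completeness > min_completeness (both strict).

#' Recovery criteria
#'
#' @param min_purity Strict lower bound on genome-level purity. Default 0.95.
#' @param min_completeness Strict lower bound on completeness. Default 0.80.
#' @return An object of class `recovery_criteria`.
#' @export
recovery_criteria <- function(min_purity = 0.95, min_completeness = 0.80) {
  if (min_purity <= 0 || min_purity > 1 ||
      min_completeness <= 0 || min_completeness > 1)
    stop("criteria must lie in (0, 1]")
  structure(list(min_purity = min_purity,
                 min_completeness = min_completeness),
            class = "recovery_criteria")
}

#' Score every cluster of an assignment against truth labels
#'
#' @param assignment Cluster assignment (`read_id`, `cluster_id`).
#' @param truth Truth table (`read_id`, `genome_id`, `species_id`) covering
#'   every read of the dataset, assigned or not (the completeness
#'   denominator is the genome's read count in the WHOLE dataset).
#' @return `data.table` with one row per cluster: `cluster_id`, `size`,
#'   `predominant_genome`, `purity_genome`, `purity_species`,
#'   `completeness`.
#' @export
score_clusters <- function(assignment, truth) {
  a <- data.table::as.data.table(assignment)
  t <- data.table::as.data.table(truth)
  if (!nrow(a))
    return(data.table::data.table(
      cluster_id = character(), size = integer(),
      predominant_genome = character(), purity_genome = numeric(),
      purity_species = numeric(), completeness = numeric()))
  j <- merge(a, t[, .(read_id, genome_id, species_id)], by = "read_id",
             all.x = TRUE)
  if (anyNA(j$genome_id))
    stop("read without truth genome label: ",
         j$read_id[which(is.na(j$genome_id))[1]])
  genome_totals <- t[, .(total = .N), by = genome_id]
  score_one <- function(genomes, species) {
    n <- length(genomes)
    gt <- sort(table(genomes), decreasing = TRUE)
    top <- max(gt)
    pred <- min_c(names(gt)[gt == top])      # tie -> lexicographically smallest
    st <- table(species)
    list(size = n,
         predominant_genome = pred,
         purity_genome = top / n,
         purity_species = max(st) / n)
  }
  sc <- j[, score_one(genome_id, species_id), by = cluster_id]
  sc <- merge(sc, genome_totals, by.x = "predominant_genome",
              by.y = "genome_id")
  pred_in_cluster <- j[, .(captured = .N), by = .(cluster_id, genome_id)]
  sc <- merge(sc, pred_in_cluster,
              by.x = c("cluster_id", "predominant_genome"),
              by.y = c("cluster_id", "genome_id"))
  sc[, completeness := captured / total]
  out <- sc[, .(cluster_id, size, predominant_genome, purity_genome,
                purity_species, completeness)]
  data.table::setorder(out, cluster_id)
  out[]
}

#' Genomes recovered by a clustering
#'
#' A genome is recovered when some cluster has it as predominant genome with
#' purity strictly above `min_purity` and completeness strictly above
#' `min_completeness`.
#'
#' @param scores Cluster scores from [score_clusters()].
#' @param criteria A [recovery_criteria()] object.
#' @return Sorted character vector of recovered genome ids.
#' @export
recovered_genomes <- function(scores, criteria = recovery_criteria()) {
  hit <- scores[purity_genome > criteria$min_purity &
                completeness > criteria$min_completeness]
  sort_c(unique(hit$predominant_genome))
}

#' Read-weighted cluster size distribution
#'
#' Clusters binned by decade of size (`[10^b, 10^(b+1))`); each bin reports
#' the fraction of all clustered reads it holds. Fractions sum to 1.
#'
#' @param assignment Cluster assignment.
#' @return `data.table` with columns `bin_low`, `bin_high`, `fraction`.
#' @export
size_distribution <- function(assignment) {
  a <- data.table::as.data.table(assignment)
  if (!nrow(a))
    return(data.table::data.table(bin_low = numeric(), bin_high = numeric(),
                                  fraction = numeric()))
  sizes <- a[, .(size = .N), by = cluster_id]
  sizes[, b := floor(log10(size))]
  total <- sum(sizes$size)
  out <- sizes[, .(fraction = sum(size) / total), by = b]
  data.table::setorder(out, b)
  out[, .(bin_low = 10^b, bin_high = 10^(b + 1), fraction)]
}

#' Evaluate a clustering end to end
#'
#' Scores every cluster, summarizes medians, recovered genomes and the size
#' distribution, and (optionally) writes a per-cluster TSV report plus a
#' JSON summary.
#'
#' @param assignment Cluster assignment.
#' @param truth Truth table for the whole dataset.
#' @param criteria A [recovery_criteria()] object.
#' @param report_tsv,summary_json Optional output paths.
#' @return List with `scores` (per-cluster table) and `summary` (list of
#'   medians, counts, recovered genomes, size distribution).
#' @export
evaluate_clustering <- function(assignment, truth,
                                criteria = recovery_criteria(),
                                report_tsv = NULL, summary_json = NULL) {
  scores <- score_clusters(assignment, truth)
  rec <- recovered_genomes(scores, criteria)
  summary <- list(
    n_clusters = nrow(scores),
    n_reads_clustered = sum(scores$size),
    n_reads_total = nrow(truth),
    median_purity_genome = stats::median(scores$purity_genome),
    median_purity_species = stats::median(scores$purity_species),
    median_completeness = stats::median(scores$completeness),
    recovered_genomes = rec,
    n_recovered_genomes = length(rec),
    size_distribution = size_distribution(assignment)
  )
  if (!is.null(report_tsv)) data.table::fwrite(scores, report_tsv, sep = "\t")
  if (!is.null(summary_json))
    jsonlite::write_json(summary, summary_json, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  list(scores = scores, summary = summary)
}
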