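# Global clustering: cosine similarity between cluster coverage profiles,
# thresholded into a weighted cluster graph, partitioned by weighted label
# propagation; member read clusters are then merged.
#
# Cosine similarity is scale-free, which is exactly what is needed: two
# clusters from the same genome have proportional coverage profiles whose
# absolute level differs with cluster size, and only the profile shape
# carries the genome identity.

#' Cluster-graph parameters
#'
#' @param cs Cosine similarity threshold in `[0, 1]`; edges below it are
#'   dropped (kept inclusively at equality). Default 0.925. Lower values
#'   merge more aggressively (over-clustering risk), higher values merge
#'   less (under-clustering remains).
#' @param lpa_max_iters Maximum label propagation sweeps. Default 20.
#' @param rng_seed Seed for the label propagation visit order.
#' @return An object of class `global_graph_params`.
#' @export
global_graph_params <- function(cs = 0.925, lpa_max_iters = 20L,
                                rng_seed = 1L) {
  if (cs < 0 || cs > 1) stop("cs must lie in [0, 1]")
  structure(list(cs = as.numeric(cs),
                 lpa_max_iters = as.integer(lpa_max_iters),
                 rng_seed = as.integer(rng_seed)),
            class = "global_graph_params")
}

#' Cosine similarity of two coverage vectors
#'
#' `dot(u, v) / (||u|| ||v||)`; lies in `[0, 1]` for nonnegative inputs.
#' A zero vector carries no coverage signal: a classed error
#' (`readclust_zero_vector`) is raised and callers exclude the cluster from
#' the graph.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Cosine similarity.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop(structure(list(message = "zero coverage vector: no-signal cluster",
                        call = sys.call()),
                   class = c("readclust_zero_vector", "error", "condition")))
  sum(u * v) / (nu * nv)
}

#' Build the cluster similarity graph
#'
#' All-pairs cosine similarities between coverage matrix columns, thresholded
#' at `params$cs`. Zero-coverage columns are excluded from the graph entirely
#' (recorded in attribute `zero_clusters` of the result).
#'
#' @param mat Coverage matrix (samples x clusters).
#' @param params A [global_graph_params()] object.
#' @return An object of class `cluster_graph`: list with `nodes` (cluster ids
#'   with nonzero coverage) and `edges` (`data.table` of `cluster_a`,
#'   `cluster_b`, `similarity`, with `cluster_a < cluster_b`).
#' @export
build_cluster_graph <- function(mat, params = global_graph_params()) {
  norms <- sqrt(colSums(mat^2))
  zero <- colnames(mat)[norms == 0]
  keep <- colnames(mat)[norms > 0]
  edges <- data.table::data.table(cluster_a = character(),
                                  cluster_b = character(),
                                  similarity = numeric())
  if (length(keep) >= 2) {
    sub <- mat[, keep, drop = FALSE]
    cn <- sweep(sub, 2, norms[keep], "/")
    sim <- crossprod(cn)
    hit <- which(upper.tri(sim) & sim >= params$cs, arr.ind = TRUE)
    if (nrow(hit)) {
      edges <- data.table::data.table(
        cluster_a = keep[hit[, 1]],
        cluster_b = keep[hit[, 2]],
        similarity = sim[hit])
      data.table::setorder(edges, cluster_a, cluster_b)
    }
  }
  structure(list(nodes = sort_c(keep), edges = edges, zero_clusters = zero),
            class = "cluster_graph")
}

#' @export
print.cluster_graph <- function(x, ...) {
  cat(sprintf("cluster_graph: %d nodes, %d edges (>= threshold)\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Merge local clusters by coverage covariation
#'
#' Partitions the cluster graph with weighted label propagation and merges
#' the member read clusters of each part. Local clusters absent from the
#' graph (excluded spectra, zero coverage) map to themselves, so the multiset
#' of clustered reads is conserved exactly. Merged groups with two or more
#' members get ids `G00001, G00002, ...` ordered by decreasing read count
#' (ties by smallest member cluster id); singleton groups keep their local
#' cluster id.
#'
#' @param assignment Local cluster assignment (`read_id`, `cluster_id`).
#' @param mat Coverage matrix whose columns are a subset of the assignment's
#'   cluster ids.
#' @param params A [global_graph_params()] object.
#' @return List with `merge_map` (`data.table` of `local_cluster`,
#'   `global_cluster`), `assignment` (merged read assignment), and `graph`
#'   (the `cluster_graph`).
#' @export
global_merge <- function(assignment, mat, params = global_graph_params()) {
  local_ids <- sort_c(unique(assignment$cluster_id))
  if (!all(colnames(mat) %in% local_ids))
    stop("coverage matrix columns must be a subset of assignment cluster ids")
  graph <- build_cluster_graph(mat, params)
  labels <- label_propagation(graph, params$lpa_max_iters, params$rng_seed,
                              weighted = TRUE)
  map <- data.table::data.table(local_cluster = local_ids)
  map[, label := local_cluster]                      # default: map to self
  map[local_cluster %in% names(labels),
      label := labels[local_cluster]]
  sizes <- data.table::as.data.table(assignment)[, .N, by = cluster_id]
  map <- merge(map, sizes, by.x = "local_cluster", by.y = "cluster_id",
               all.x = TRUE)
  groups <- map[, .(n_members = .N, n_reads = sum(N),
                    rep = min_c(local_cluster)), by = label]
  merged <- groups[n_members >= 2L]
  data.table::setorder(merged, -n_reads, rep)
  merged[, global_cluster := sprintf("G%05d", seq_len(.N))]
  map <- merge(map, merged[, .(label, global_cluster)], by = "label",
               all.x = TRUE)
  map[is.na(global_cluster), global_cluster := local_cluster]
  merge_map <- map[, .(local_cluster, global_cluster)]
  data.table::setorder(merge_map, local_cluster)
  out <- merge(data.table::as.data.table(assignment), merge_map,
               by.x = "cluster_id", by.y = "local_cluster")
  out <- out[, .(read_id, cluster_id = global_cluster)]
  data.table::setorder(out, read_id)
  list(merge_map = merge_map[], assignment = out[], graph = graph)
}
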