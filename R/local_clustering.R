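# Local clustering: read overlap graph from shared seeds, partitioned by
# deterministic label propagation, then filtered by cluster size.
#
# The construction never compares reads pairwise: reads are grouped by seed
# and each seed contributes one co-occurrence to every read pair under it.
# Seeds occurring in more than `max_seed_occurrence` reads are discarded
# outright (repeat mask / quadratic-blowup guard). Edge weight is the number
# of DISTINCT shared seeds; edges below `min_shared_kmers` are dropped, and
# each read then keeps at most `max_degree` edges (an edge survives if
# either endpoint ranks it), so deeply covered loci do not produce
# quadratic, uninformative neighbourhoods.

#' Local clustering parameters
#'
#' @param seed_params A [seed_params()] object.
#' @param min_shared_kmers Minimum number of distinct shared seeds for an
#'   edge to be kept (`minsk`). Default 2.
#' @param max_degree Per-read edge budget: each read keeps at most this many
#'   edges (ranked deterministically by partner token); an edge survives if
#'   either endpoint keeps it. Default 25.
#' @param max_seed_occurrence Seeds occurring in more than this many reads
#'   are discarded before pair generation (repeat masking). Default 1000.
#' @param min_reads_per_cluster Clusters smaller than this are discarded:
#'   small clusters do not produce reliable k-mer spectra for the coverage
#'   stage. Default 50 (inclusive, i.e. clusters of exactly 50 reads
#'   survive; set 51 to reproduce a strict "more than 50").
#' @param lpa_max_iters Maximum label propagation sweeps. Default 20.
#' @param rng_seed Retained for interface stability and per-stage seed
#'   bookkeeping; the synchronous propagation schedule is deterministic and
#'   does not consume randomness.
#' @return An object of class `local_params`.
#' @export
local_params <- function(seed_params = readclust::seed_params(),
                         min_shared_kmers = 2L, max_degree = 25L,
                         max_seed_occurrence = 1000L,
                         min_reads_per_cluster = 50L, lpa_max_iters = 20L,
                         rng_seed = 1L) {
  p <- list(seed_params = seed_params,
            min_shared_kmers = as.integer(min_shared_kmers),
            max_degree = as.integer(max_degree),
            max_seed_occurrence = as.integer(max_seed_occurrence),
            min_reads_per_cluster = as.integer(min_reads_per_cluster),
            lpa_max_iters = as.integer(lpa_max_iters),
            rng_seed = as.integer(rng_seed))
  for (f in c("min_shared_kmers", "max_degree", "max_seed_occurrence",
              "min_reads_per_cluster", "lpa_max_iters"))
    if (p[[f]] < 1L) stop(f, " must be >= 1")
  structure(p, class = "local_params")
}

# Keep, per node, at most `max_degree` edges; an edge survives if either
# endpoint keeps it. Ranking is by partner token (deterministic and, with
# arbitrary read ids, positionally unbiased): ranking by weight instead would
# keep only near-duplicate overlaps and localize the graph so much that
# label propagation fragments deeply covered loci.
cap_node_degree <- function(edges, max_degree) {
  if (!nrow(edges)) return(edges)
  long <- data.table::rbindlist(list(
    edges[, .(node = read_a, partner = read_b, eid = .I)],
    edges[, .(node = read_b, partner = read_a, eid = .I)]))
  data.table::setorder(long, node, partner)
  long[, rank := seq_len(.N), by = node]
  keep <- unique(long[rank <= max_degree, eid])
  edges[sort(keep)]
}

#' Build the read overlap graph
#'
#' @param reads Reads table ([load_reads()]).
#' @param params A [local_params()] object.
#' @return An object of class `read_graph`: list with `nodes` (sorted read
#'   ids) and `edges` (`data.table` of `read_a`, `read_b`, `weight`, with
#'   `read_a < read_b`).
#' @export
build_read_graph <- function(reads, params) {
  ord <- order_c(reads$read_id)
  nodes <- reads$read_id[ord]
  sets <- seed_sets(reads$sequence[ord], params$seed_params)
  pairs <- cpp_count_shared_seeds(sets, params$max_seed_occurrence,
                                  params$min_shared_kmers)
  edges <- data.table::data.table(read_a = nodes[pairs$i],
                                  read_b = nodes[pairs$j],
                                  weight = as.integer(pairs$weight))
  data.table::setorder(edges, read_a, read_b)
  edges <- cap_node_degree(edges, params$max_degree)
  structure(list(nodes = nodes, edges = edges[]), class = "read_graph")
}

#' @export
print.read_graph <- function(x, ...) {
  cat(sprintf("read_graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Shared deterministic LPA driver over token-named nodes.
lpa_partition <- function(nodes, from, to, weight, max_iters, weighted) {
  nodes <- sort_c(nodes)
  n <- length(nodes)
  if (n == 0L) return(character())
  fi <- match(from, nodes)
  ti <- match(to, nodes)
  lab <- cpp_lpa(n, as.integer(fi), as.integer(ti), as.numeric(weight),
                 as.integer(max_iters), weighted)
  stats::setNames(nodes[lab], nodes)
}

#' Label propagation partitioning
#'
#' Deterministic synchronous label propagation: every node starts with its
#' own label; each sweep, all nodes simultaneously adopt the label with the
#' maximum total weight (or neighbour count if `weighted = FALSE`) among
#' their neighbours' previous labels, ties broken by the lexicographically
#' smallest label token; a node only switches when the candidate strictly
#' beats its current label's score (or equals it with a smaller token), which
#' damps oscillation. Terminates when a sweep changes nothing or after
#' `max_iters` sweeps. Labels never cross connected components; isolated
#' nodes keep their own label.
#'
#' @param graph A `read_graph` or `cluster_graph` object.
#' @param max_iters Maximum sweeps.
#' @param rng_seed Unused by the synchronous schedule (kept so callers can
#'   thread one seed through every stage); the result is deterministic.
#' @param weighted Use edge weights in the update rule?
#' @return Named character vector: node token -> label token (labels are
#'   node tokens).
#' @export
label_propagation <- function(graph, max_iters = 20L, rng_seed = 1L,
                              weighted = TRUE) {
  e <- graph$edges
  if (inherits(graph, "cluster_graph")) {
    lpa_partition(graph$nodes, e$cluster_a, e$cluster_b, e$similarity,
                  max_iters, weighted)
  } else {
    lpa_partition(graph$nodes, e$read_a, e$read_b, e$weight,
                  max_iters, weighted)
  }
}

#' Local clustering of reads
#'
#' Builds the read overlap graph, partitions it with (unweighted) label
#' propagation, and discards clusters smaller than `min_reads_per_cluster`.
#' Unweighted updates are used at this stage because overlap weights
#' over-favour near-identical reads and fragment clusters to single loci.
#' Surviving clusters get stable ids `L00001, L00002, ...` ordered by
#' decreasing size (ties by smallest member read id).
#'
#' @param reads Reads table ([load_reads()]).
#' @param params A [local_params()] object.
#' @return A cluster assignment `data.table` (`read_id`, `cluster_id`);
#'   reads in discarded clusters are absent.
#' @export
local_cluster <- function(reads, params) {
  graph <- build_read_graph(reads, params)
  labels <- label_propagation(graph, params$lpa_max_iters, params$rng_seed,
                              weighted = FALSE)
  assignment_from_labels(labels, params$min_reads_per_cluster)
}

# Turn an LPA labelling into a size-filtered assignment with stable ids.
assignment_from_labels <- function(labels, min_reads_per_cluster) {
  a <- data.table::data.table(read_id = names(labels), label = labels)
  sizes <- a[, .(size = .N, rep = min_c(read_id)), by = label]
  keep <- sizes[size >= min_reads_per_cluster]
  data.table::setorder(keep, -size, rep)
  if (!nrow(keep))
    return(data.table::data.table(read_id = character(),
                                  cluster_id = character()))
  keep[, cluster_id := sprintf("L%05d", seq_len(.N))]
  out <- merge(a, keep[, .(label, cluster_id)], by = "label")
  out <- out[, .(read_id, cluster_id)]
  data.table::setorder(out, read_id)
  out[]
}
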