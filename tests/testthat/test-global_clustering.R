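test_that("cosine similarity matches the closed form", {
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(cosine_similarity(c(1, 2, 3), c(3, 2, 1)), 10 / 14)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)),
               class = "readclust_zero_vector")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("the cluster graph thresholds pairwise similarities", {
  # three profiles engineered around the threshold
  m <- cbind(c1 = c(1, 10, 1), c2 = c(1.2, 10, 1.4), c3 = c(10, 1, 1))
  rownames(m) <- paste0("S", 1:3)
  s12 <- cosine_similarity(m[, 1], m[, 2])
  s13 <- cosine_similarity(m[, 1], m[, 3])
  s23 <- cosine_similarity(m[, 2], m[, 3])
  stopifnot(s12 > 0.925, s13 < 0.925, s23 < 0.925)
  g <- build_cluster_graph(m, global_graph_params(cs = 0.925))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$cluster_a, "c1")
  expect_equal(g$edges$cluster_b, "c2")
  expect_equal(g$edges$similarity, s12)

  # cs = 1 with no exactly proportional pair -> empty edge set
  g1 <- build_cluster_graph(m, global_graph_params(cs = 1))
  expect_equal(nrow(g1$edges), 0L)

  # zero-coverage clusters are excluded from the graph
  mz <- cbind(m, c4 = c(0, 0, 0))
  gz <- build_cluster_graph(mz, global_graph_params(cs = 0.925))
  expect_false("c4" %in% gz$nodes)
  expect_equal(gz$zero_clusters, "c4")
})

test_that("graph edges match brute-force all-pairs thresholding", {
  set.seed(51)
  m <- matrix(rlnorm(8 * 40), nrow = 8,
              dimnames = list(paste0("S", 1:8), sprintf("c%02d", 1:40)))
  cs <- 0.925
  g <- build_cluster_graph(m, global_graph_params(cs = cs))
  want <- list()
  cl <- colnames(m)
  for (a in 1:39) for (b in (a + 1):40) {
    s <- oracle_cosine(m[, a], m[, b])
    if (s >= cs) want[[length(want) + 1]] <-
        data.frame(cluster_a = cl[a], cluster_b = cl[b], similarity = s)
  }
  want <- do.call(rbind, want)
  got <- as.data.frame(g$edges)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$cluster_a, want$cluster_a)
  expect_equal(got$cluster_b, want$cluster_b)
  expect_equal(got$similarity, want$similarity, tolerance = 1e-12)
})

test_that("raising the threshold only removes edges and splits components", {
  skip_if_not_installed("igraph")
  set.seed(52)
  m <- matrix(rlnorm(6 * 30), nrow = 6,
              dimnames = list(paste0("S", 1:6), sprintf("c%02d", 1:30)))
  grid <- c(0.5, 0.7, 0.85, 0.9, 0.925, 0.95, 0.99)
  prev_edges <- NULL
  prev_comp <- NULL
  for (cs in grid) {
    g <- build_cluster_graph(m, global_graph_params(cs = cs))
    key <- paste(g$edges$cluster_a, g$edges$cluster_b)
    if (!is.null(prev_edges)) expect_true(all(key %in% prev_edges))
    ig <- igraph::graph_from_data_frame(
      g$edges[, c("cluster_a", "cluster_b")], directed = FALSE,
      vertices = g$nodes)
    nc <- igraph::components(ig)$no
    if (!is.null(prev_comp)) expect_gte(nc, prev_comp)
    prev_edges <- key
    prev_comp <- nc
  }
})

test_that("similarities ignore the scale of coverage columns", {
  set.seed(53)
  m <- matrix(rlnorm(5 * 12), nrow = 5,
              dimnames = list(paste0("S", 1:5), sprintf("c%02d", 1:12)))
  m2 <- m
  m2[, 3] <- m2[, 3] * 1000     # a much larger read cluster, same profile
  m2[, 7] <- m2[, 7] * 1e-3
  g1 <- build_cluster_graph(m, global_graph_params(cs = 0.8))
  g2 <- build_cluster_graph(m2, global_graph_params(cs = 0.8))
  expect_equal(g1$edges, g2$edges, tolerance = 1e-12)
})

test_that("merging unions member clusters and conserves reads", {
  assignment <- data.table::data.table(
    read_id = sprintf("r%02d", 1:9),
    cluster_id = rep(c("c1", "c2", "c3"), each = 3))

  # no edges -> identity merge
  m0 <- cbind(c1 = c(10, 1), c2 = c(1, 10), c3 = c(5, 5))
  rownames(m0) <- c("S1", "S2")
  res0 <- global_merge(assignment, m0, global_graph_params(cs = 0.999))
  expect_equal(res0$merge_map$global_cluster, res0$merge_map$local_cluster)
  expect_equal(as.data.frame(res0$assignment[order(read_id)]),
               as.data.frame(assignment[order(read_id)]))

  # one strong edge -> the two clusters fuse, the third stays
  m1 <- cbind(c1 = c(10, 1), c2 = c(10.5, 1.2), c3 = c(1, 10))
  rownames(m1) <- c("S1", "S2")
  res1 <- global_merge(assignment, m1, global_graph_params(cs = 0.925))
  map <- stats::setNames(res1$merge_map$global_cluster,
                         res1$merge_map$local_cluster)
  expect_equal(map[["c1"]], map[["c2"]])
  expect_equal(map[["c3"]], "c3")
  merged_reads <- res1$assignment[cluster_id == map[["c1"]], read_id]
  expect_setequal(merged_reads, sprintf("r%02d", 1:6))
  # read conservation
  expect_setequal(res1$assignment$read_id, assignment$read_id)
  expect_equal(nrow(res1$assignment), nrow(assignment))
})

test_that("simulated per-genome profiles merge into exact genome groups", {
  set.seed(54)
  n_samples <- 10
  genomes <- sprintf("G%d", 1:3)
  profiles <- matrix(rlnorm(3 * n_samples, 0, 1), nrow = n_samples)
  cols <- list(); genome_of <- character()
  for (g in 1:3) for (j in 1:4) {
    noise <- 1 + runif(n_samples, -0.05, 0.05)   # +/-5% multiplicative
    cols[[length(cols) + 1]] <- profiles[, g] * noise * runif(1, 0.5, 2)
    genome_of[sprintf("c%02d", length(cols))] <- genomes[g]
  }
  m <- do.call(cbind, cols)
  dimnames(m) <- list(paste0("S", 1:n_samples), sprintf("c%02d", 1:12))
  assignment <- data.table::data.table(
    read_id = sprintf("r%03d", 1:120),
    cluster_id = rep(colnames(m), each = 10))
  res <- global_merge(assignment, m, global_graph_params(cs = 0.925))
  map <- stats::setNames(res$merge_map$global_cluster,
                         res$merge_map$local_cluster)
  # merged groups coincide exactly with the genome grouping
  expect_equal(length(unique(map)), 3L)
  for (g in genomes)
    expect_length(unique(map[names(genome_of)[genome_of == g]]), 1L)
})
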