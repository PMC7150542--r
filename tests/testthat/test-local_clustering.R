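test_that("two identical reads share one edge counting their distinct k-mers", {
  set.seed(21)
  s <- random_seq(100)
  # precondition of the construction: all 60 canonical 41-mers distinct
  stopifnot(length(unique(oracle_kmers(s, 41))) == 60L)
  reads <- reads_table(c(s, s))
  p <- local_params(seed_params = seed_params(k = 41, mode = "kmer"))
  g <- build_read_graph(reads, p)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 60L)

  disjoint <- reads_table(c(strrep("A", 60), strrep("C", 60)))
  expect_equal(nrow(build_read_graph(disjoint, p)$edges), 0L)
})

test_that("a seed shared by more reads than the mask allows yields no edges", {
  set.seed(22)
  core <- random_seq(41)
  # 26 single-window reads: every pair shares exactly the one seed
  reads <- reads_table(rep(core, 26))
  # default min_shared_kmers = 2: the single shared k-mer is not enough
  p <- local_params(seed_params = seed_params(k = 41, mode = "kmer"))
  expect_equal(nrow(build_read_graph(reads, p)$edges), 0L)
  # seed-occurrence mask: 26 occurrences > 25 kills the seed even at minsk 1
  p2 <- local_params(seed_params = seed_params(k = 41, mode = "kmer"),
                     min_shared_kmers = 1, max_seed_occurrence = 25)
  expect_equal(nrow(build_read_graph(reads, p2)$edges), 0L)
  # with the mask relaxed the 26-clique of weight-1 edges appears
  p3 <- local_params(seed_params = seed_params(k = 41, mode = "kmer"),
                     min_shared_kmers = 1, max_seed_occurrence = 100,
                     max_degree = 100)
  expect_equal(nrow(build_read_graph(reads, p3)$edges), 26L * 25L / 2L)
})

test_that("graph construction matches the brute-force all-pairs oracle", {
  set.seed(23)
  t1 <- random_seq(300); t2 <- random_seq(300)
  reads <- data.table::rbindlist(list(tile_reads(t1, 60, 10, "a"),
                                      tile_reads(t2, 60, 12, "b")))
  stopifnot(nrow(reads) <= 50)
  for (mode in c("kmer", "minimizer")) {
    p <- local_params(seed_params = seed_params(k = 15, m = 7, mode = mode),
                      min_shared_kmers = 1, max_degree = 6,
                      max_seed_occurrence = 12)
    got <- as.data.frame(build_read_graph(reads, p)$edges)
    want <- oracle_read_graph(reads, p)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = mode)
  }
})

test_that("label propagation respects components and collapses stars", {
  tri2 <- data.table::data.table(
    read_a = c("a1", "a1", "a2", "b1", "b1", "b2"),
    read_b = c("a2", "a3", "a3", "b2", "b3", "b3"), weight = 1L)
  g <- structure(list(nodes = c("a1", "a2", "a3", "b1", "b2", "b3", "lone"),
                      edges = tri2), class = "read_graph")
  lab <- label_propagation(g, weighted = FALSE)
  expect_length(unique(lab[c("a1", "a2", "a3")]), 1L)
  expect_length(unique(lab[c("b1", "b2", "b3")]), 1L)
  expect_false(lab[["a1"]] == lab[["b1"]])
  expect_equal(lab[["lone"]], "lone")     # isolated node keeps its own label

  star <- structure(list(nodes = paste0("n", 1:6),
                         edges = data.table::data.table(
                           read_a = "n1", read_b = paste0("n", 2:6),
                           weight = 1L)), class = "read_graph")
  expect_length(unique(label_propagation(star, weighted = FALSE)), 1L)
})

test_that("labels never span two connected components", {
  skip_if_not_installed("igraph")
  set.seed(24)
  for (i in 1:10) {
    n <- 40
    e <- data.table::data.table(
      read_a = sprintf("n%02d", sample(n, 60, replace = TRUE)),
      read_b = sprintf("n%02d", sample(n, 60, replace = TRUE)),
      weight = sample(1:5, 60, replace = TRUE))
    e <- e[read_a < read_b]
    e <- unique(e, by = c("read_a", "read_b"))
    g <- structure(list(nodes = sprintf("n%02d", 1:n), edges = e),
                   class = "read_graph")
    lab <- label_propagation(g, weighted = (i %% 2 == 0))
    ig <- igraph::graph_from_data_frame(
      e[, .(read_a, read_b)], directed = FALSE,
      vertices = sprintf("n%02d", 1:n))
    comp <- igraph::components(ig)$membership
    # each label lives inside exactly one component
    for (l in unique(lab)) {
      members <- names(lab)[lab == l]
      expect_length(unique(comp[members]), 1L)
    }
  }
})

test_that("local clustering keeps only clusters at the size threshold", {
  set.seed(25)
  tA <- random_seq(220)    # 60 mutually overlapping reads
  tB <- random_seq(220)    # 10 reads, below the filter
  stA <- sample(1:70, 60, TRUE)
  readsA <- reads_table(substring(tA, stA, stA + 149), prefix = "a")
  stB <- sample(1:70, 10, TRUE)
  readsB <- reads_table(substring(tB, stB, stB + 149), prefix = "b")
  reads <- data.table::rbindlist(list(readsA, readsB))
  p <- local_params()
  a <- local_cluster(reads, p)
  expect_equal(length(unique(a$cluster_id)), 1L)
  expect_equal(nrow(a), 60L)
  expect_true(all(grepl("^a", a$read_id)))

  # pairwise non-overlapping reads -> all singletons -> nothing survives
  lone <- reads_table(vapply(1:8, function(i) random_seq(150), character(1)))
  expect_equal(nrow(local_cluster(lone, p)), 0L)
})

test_that("the cluster size filter is inclusive at the threshold", {
  set.seed(26)
  t49 <- random_seq(200)
  mk <- function(template, n, prefix) {
    st <- sample(1:50, n, TRUE)
    reads_table(substring(template, st, st + 149), prefix = prefix)
  }
  p <- local_params()
  expect_equal(nrow(local_cluster(mk(t49, 49, "x"), p)), 0L)   # 49 < 50
  a50 <- local_cluster(mk(t49, 50, "x"), p)
  expect_equal(nrow(a50), 50L)                                  # 50 kept
})

test_that("clustering is deterministic and forms a partition", {
  set.seed(27)
  templates <- replicate(3, random_seq(400))
  reads <- data.table::rbindlist(lapply(1:3, function(i) {
    st <- sample(1:250, 70, TRUE)
    reads_table(substring(templates[i], st, st + 149),
                prefix = sprintf("g%d_", i))
  }))
  p <- local_params()
  a1 <- local_cluster(reads, p)
  a2 <- local_cluster(reads, p)
  expect_identical(a1, a2)
  expect_equal(anyDuplicated(a1$read_id), 0L)
  expect_true(all(a1$read_id %in% reads$read_id))
})

test_that("clusters from k-mer-disjoint genomes are pure", {
  set.seed(28)
  templates <- replicate(2, random_seq(500))
  reads <- data.table::rbindlist(lapply(1:2, function(i) {
    st <- sample(1:350, 80, TRUE)
    r <- reads_table(substring(templates[i], st, st + 149),
                     prefix = sprintf("g%d_", i))
    r$truth_genome <- sprintf("G%d", i)
    r$truth_species <- sprintf("S%d", i)
    r
  }))
  a <- local_cluster(reads, local_params())
  truth <- data.table::data.table(read_id = reads$read_id,
                                  genome_id = reads$truth_genome,
                                  species_id = reads$truth_species)
  sc <- score_clusters(a, truth)
  expect_true(all(sc$purity_genome == 1))
})
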