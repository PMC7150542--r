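# Independent pure-R oracles (no calls into the package's compiled kernels)
# plus small fixture builders shared across test files.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

oracle_canonical <- function(s) {
  rc <- oracle_revcomp(s)
  if (rc < s) rc else s
}

# all canonical k-mers, in order, skipping windows containing N
oracle_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character())
  out <- character()
  for (i in 1:(L - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (grepl("[^ACGT]", w)) next
    out <- c(out, oracle_canonical(w))
  }
  out
}

# per-window minimum over canonical m-mers, distinct set
oracle_minimizers <- function(seq, k, m) {
  L <- nchar(seq)
  if (L < k) return(character())
  res <- character()
  for (j in 1:(L - k + 1)) {
    w <- substr(seq, j, j + k - 1)
    if (grepl("[^ACGT]", w)) next
    mm <- vapply(1:(k - m + 1),
                 function(i) oracle_canonical(substr(w, i, i + m - 1)),
                 character(1))
    res <- c(res, min(mm))
  }
  sort(unique(res))
}

oracle_seed_set <- function(seq, params) {
  if (params$mode == "minimizer") {
    oracle_minimizers(seq, params$k, params$m)
  } else {
    sort(unique(oracle_kmers(seq, params$k)))
  }
}

# brute-force all-pairs shared-seed graph with the same repeat mask and
# node-degree cap rule as the implementation, written independently
oracle_read_graph <- function(reads, params) {
  sets <- lapply(reads$sequence, oracle_seed_set, params = params$seed_params)
  names(sets) <- reads$read_id
  occ <- table(unlist(sets))
  banned <- names(occ)[occ > params$max_seed_occurrence]
  sets <- lapply(sets, setdiff, y = banned)
  ids <- sort(reads$read_id)
  rows <- list()
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (a >= b) next
    w <- length(intersect(sets[[ids[a]]], sets[[ids[b]]]))
    if (w >= params$min_shared_kmers)
      rows[[length(rows) + 1]] <- data.frame(read_a = ids[a], read_b = ids[b],
                                             weight = w)
  }
  edges <- do.call(rbind, rows)
  if (is.null(edges))
    return(data.frame(read_a = character(), read_b = character(),
                      weight = integer()))
  # independent restatement of the per-node edge budget (rank by partner id)
  kept <- rep(FALSE, nrow(edges))
  for (id in ids) {
    inc <- which(edges$read_a == id | edges$read_b == id)
    partner <- ifelse(edges$read_a[inc] == id, edges$read_b[inc],
                      edges$read_a[inc])
    keep_n <- seq_len(min(params$max_degree, length(inc)))
    kept[inc[order(partner, method = "radix")][keep_n]] <- TRUE
  }
  edges <- edges[kept, ]
  edges[order(edges$read_a, edges$read_b), ]
}

oracle_cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# reads tiled over a template so that neighbours overlap by `len - by`
tile_reads <- function(template, len, by, prefix) {
  starts <- seq(1, nchar(template) - len + 1, by = by)
  data.table::data.table(
    read_id = sprintf("%s%03d", prefix, seq_along(starts)),
    sample_id = "S1",
    sequence = substring(template, starts, starts + len - 1),
    truth_genome = NA_character_, truth_species = NA_character_)
}

# minimal reads table from bare sequences
reads_table <- function(seqs, sample_id = "S1", prefix = "r") {
  data.table::data.table(
    read_id = sprintf("%s%03d", prefix, seq_along(seqs)),
    sample_id = sample_id, sequence = seqs,
    truth_genome = NA_character_, truth_species = NA_character_)
}

write_tsv_manifest <- function(dir, entries) {
  path <- file.path(dir, "manifest.tsv")
  writeLines(c("sample_id\tpath\tformat",
               vapply(entries, paste, character(1), collapse = "\t")), path)
  path
}

write_fastq_file <- function(path, ids, seqs, quals = NULL) {
  if (is.null(quals)) quals <- vapply(nchar(seqs), strrep, character(1),
                                      x = "I")
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}
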