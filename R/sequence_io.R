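# Sample manifests, read loading, and tabular artifact serialization.
#
# All intermediate artifacts in the pipeline are plain TSV so that runs are
# diffable and byte-reproducible. Sequence parsing is delegated to Biostrings.

#' Load and validate a sample manifest
#'
#' A manifest is a TSV with header `sample_id<TAB>path<TAB>format` declaring
#' one or more FASTQ/FASTA files per sample. Relative paths are resolved
#' against the manifest's own directory.
#'
#' @param path Path to the manifest TSV.
#' @return A `data.table` with columns `sample_id`, `path` (absolute),
#'   `format` (`"fastq"` or `"fasta"`).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character")
  required <- c("sample_id", "path", "format")
  if (!all(required %in% names(man)))
    stop("manifest must have columns sample_id, path, format")
  if (nrow(man) < 1L) stop("manifest is empty: ", path)
  bad_fmt <- which(!man$format %in% c("fastq", "fasta"))
  if (length(bad_fmt))
    stop("unknown format '", man$format[bad_fmt[1]], "' in manifest line ",
         bad_fmt[1] + 1L)
  dup <- which(duplicated(man[, c("sample_id", "path")]))
  if (length(dup))
    stop("duplicate (sample_id, path) entry in manifest line ", dup[1] + 1L)
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                file.path(base, man$path))
  missing <- which(!file.exists(abs))
  if (length(missing))
    stop("manifest references missing file: ", man$path[missing[1]],
         " (line ", missing[1] + 1L, ")")
  out <- data.table::data.table(sample_id = man$sample_id, path = abs,
                                format = man$format)
  out[]
}

# Parse optional "genome=<id>" / "species=<id>" tokens out of a read name.
parse_truth_tokens <- function(names) {
  g <- regmatches(names, regexpr("genome=[^[:space:]]+", names))
  s <- regmatches(names, regexpr("species=[^[:space:]]+", names))
  genome <- rep(NA_character_, length(names))
  species <- rep(NA_character_, length(names))
  has_g <- grepl("genome=", names, fixed = TRUE)
  has_s <- grepl("species=", names, fixed = TRUE)
  genome[has_g] <- sub("^genome=", "", g)
  species[has_s] <- sub("^species=", "", s)
  list(genome = genome, species = species)
}

# Report the index of the first structurally broken record of a 4-line FASTQ
# (sequence/quality length mismatches are silently tolerated by lenient
# parsers, so they are checked here explicitly).
first_bad_fastq_record <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  n <- length(lines) %/% 4L
  if (length(lines) %% 4L != 0L) return(n + 1L)
  for (i in seq_len(n)) {
    seq <- lines[4L * i - 2L]
    qual <- lines[4L * i]
    if (!startsWith(lines[4L * i - 3L], "@") || lines[4L * i - 1L] != "+" &&
        !startsWith(lines[4L * i - 1L], "+")) return(i)
    if (nchar(seq) != nchar(qual)) return(i)
  }
  NA_integer_
}

#' Load all reads declared in a manifest
#'
#' Every record of every manifest file is returned, tagged with its
#' `sample_id`. Truth labels are parsed from `genome=` / `species=` tokens in
#' the read name when present. If the same read name occurs in more than one
#' sample, colliding ids are disambiguated by prefixing `sample_id:`.
#' Quality strings are ignored: no downstream operation consumes them.
#'
#' @param manifest A manifest as returned by [load_manifest()].
#' @return A `data.table` with columns `read_id`, `sample_id`, `sequence`,
#'   `truth_genome`, `truth_species`.
#' @export
load_reads <- function(manifest) {
  pieces <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    fmt <- manifest$format[i]
    fp <- manifest$path[i]
    if (fmt == "fastq") {
      idx <- first_bad_fastq_record(fp)
      if (!is.na(idx))
        stop("malformed FASTQ record ", idx, " in ", fp,
             " (sequence/quality length mismatch or truncated record)",
             call. = FALSE)
    }
    seqs <- tryCatch(
      Biostrings::readDNAStringSet(fp, format = fmt),
      error = function(e)
        stop("failed to parse ", fp, ": ", conditionMessage(e), call. = FALSE))
    nm <- names(seqs)
    truth <- parse_truth_tokens(nm)
    pieces[[i]] <- data.table::data.table(
      read_id = sub("[[:space:]].*$", "", nm),
      sample_id = manifest$sample_id[i],
      sequence = toupper(as.character(seqs)),
      truth_genome = truth$genome,
      truth_species = truth$species
    )
  }
  reads <- data.table::rbindlist(pieces)
  # disambiguate read ids that collide across samples
  dup_ids <- unique(reads$read_id[duplicated(reads$read_id)])
  if (length(dup_ids)) {
    hit <- reads$read_id %in% dup_ids
    reads$read_id[hit] <- paste0(reads$sample_id[hit], ":", reads$read_id[hit])
  }
  if (anyDuplicated(reads$read_id))
    stop("read ids not unique within a sample: ",
         reads$read_id[duplicated(reads$read_id)][1])
  reads[]
}

#' Write / read a cluster assignment
#'
#' An assignment maps each clustered read to exactly one cluster; unassigned
#' reads are simply absent. Serialized as TSV `read_id<TAB>cluster_id`.
#' `read_assignment(write_assignment(a, f))` is the identity.
#'
#' @param assignment A `data.table`/data.frame with columns `read_id`,
#'   `cluster_id`.
#' @param path Output (or input) TSV path.
#' @return `write_assignment` returns `path` invisibly; `read_assignment`
#'   returns the assignment `data.table`.
#' @export
write_assignment <- function(assignment, path) {
  stopifnot(all(c("read_id", "cluster_id") %in% names(assignment)))
  out <- data.table::as.data.table(assignment)[, .(read_id, cluster_id)]
  data.table::setorder(out, read_id)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_assignment
#' @export
read_assignment <- function(path) {
  a <- data.table::fread(path, sep = "\t", header = TRUE,
                         colClasses = "character")
  if (!all(c("read_id", "cluster_id") %in% names(a)))
    stop("assignment file must have columns read_id, cluster_id: ", path)
  if (anyDuplicated(a$read_id))
    stop("read listed under two clusters: ",
         a$read_id[duplicated(a$read_id)][1])
  a[]
}

#' Write / read a truth table
#'
#' Sidecar ground-truth labels: TSV with columns `read_id`, `genome_id`,
#' `species_id`, `sample_id`.
#'
#' @param truth A table with those columns.
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  out <- data.table::as.data.table(truth)[
    , .(read_id, genome_id, species_id, sample_id)]
  data.table::setorder(out, read_id)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  t <- data.table::fread(path, sep = "\t", header = TRUE,
                         colClasses = "character")
  need <- c("read_id", "genome_id", "species_id")
  if (!all(need %in% names(t)))
    stop("truth file must have columns read_id, genome_id, species_id: ", path)
  t[]
}

#' Write / read a weighted edge list
#'
#' Generic TSV edge list used for both read graphs and cluster graphs.
#'
#' @param edges A table whose first two columns are node tokens and whose
#'   third is a numeric weight.
#' @param path TSV path.
#' @param cols Column names to use in the header.
#' @export
write_edges <- function(edges, path,
                        cols = c("read_a", "read_b", "weight")) {
  out <- data.table::as.data.table(edges)
  data.table::setnames(out, seq_along(cols), cols)
  data.table::setorderv(out, cols[1:2])
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE)
}
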