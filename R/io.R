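# Readers and writers: FASTA (via Biostrings), picked-signal TSV, GFF3
# cluster annotation (via rtracklayer), assignment TSV, ground-truth
# sidecars and the strict run configuration. All text output is UTF-8 with
# Unix newlines; tables are tab-separated so sequence strings never need
# quoting.

#' Read a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header;
#' sequences are uppercased and may be line-wrapped in the file.
#'
#' @param path Path to a FASTA file (nucleotide or protein).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate FASTA ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  bad <- regexpr("[^A-Z*]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal character '%s' in record '%s'",
                 substr(seqs[i], bad[i], bad[i]), ids[i]), call. = FALSE)
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width. Default 60.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "wb")  # binary keeps Unix newlines on every platform
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a picked-signal TSV
#'
#' The file must be tab-separated with the exact header
#' `peptide_id  mz  z`. Malformed rows (wrong field count, non-numeric or
#' out-of-range values) are skipped with a warning naming their line
#' numbers; a file with no valid rows is an error.
#'
#' @param path Path to the signal TSV.
#' @return Data frame with columns `peptide_id` (character), `mz` (numeric)
#'   and `z` (integer).
#' @export
read_signals <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop(sprintf("empty signal file: %s", path),
                                call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("peptide_id", "mz", "z"))) {
    stop("signal TSV must have header: peptide_id<TAB>mz<TAB>z",
         call. = FALSE)
  }
  body <- lines[-1L]
  fields <- strsplit(body, "\t", fixed = TRUE)
  parse_row <- function(f) {
    if (length(f) != 3L) return(NULL)
    mz <- suppressWarnings(as.numeric(f[2L]))
    z <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(mz) || is.na(z) || mz <= 0 || z < 1 || z != round(z)) {
      return(NULL)
    }
    data.frame(peptide_id = f[1L], mz = mz, z = as.integer(z),
               stringsAsFactors = FALSE)
  }
  parsed <- lapply(fields, parse_row)
  bad <- which(vapply(parsed, is.null, logical(1L)))
  if (length(bad) > 0L) {
    warning(sprintf("skipping malformed signal row(s) at line(s): %s",
                    paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  ok <- parsed[!vapply(parsed, is.null, logical(1L))]
  if (length(ok) == 0L) {
    stop(sprintf("no valid signal rows in %s", path), call. = FALSE)
  }
  res <- do.call(rbind, ok)
  rownames(res) <- NULL
  res
}

#' Write a picked-signal TSV
#'
#' @param signals Data frame with columns `peptide_id`, `mz`, `z`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signals <- function(signals, path) {
  stopifnot(all(c("peptide_id", "mz", "z") %in% names(signals)))
  out <- data.frame(
    peptide_id = signals$peptide_id,
    mz = sprintf("%.4f", signals$mz),
    z = signals$z
  )
  .write_tsv(out, path)
}

.write_tsv <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0L) {
    rows <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Write gene clusters as GFF3
#'
#' One `gene` feature per cluster member, 1-based inclusive coordinates per
#' the GFF3 standard, with the assigned biosynthetic role and cluster id in
#' the attribute column. An empty cluster list yields a valid GFF3 file
#' containing only the version pragma.
#'
#' @param clusters A `gene_cluster` or list of them ([assemble_cluster()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(clusters, path) {
  if (inherits(clusters, "gene_cluster")) clusters <- list(clusters)
  if (length(clusters) == 0L) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    return(invisible(path))
  }
  rows <- lapply(seq_along(clusters), function(ci) {
    m <- clusters[[ci]]$orfs
    data.frame(
      contig = m$contig_id, start = m$start, end = m$end,
      strand = m$strand, role = m$role,
      cluster_id = sprintf("cluster%d", ci),
      orf_id = sprintf("cluster%d_orf%d", ci, seq_len(nrow(m))),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$contig,
    ranges = IRanges::IRanges(start = tab$start + 1L, end = tab$end),
    strand = tab$strand
  )
  S4Vectors::mcols(gr)$source <- "lantimine"
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- tab$orf_id
  S4Vectors::mcols(gr)$role <- tab$role
  S4Vectors::mcols(gr)$cluster_id <- tab$cluster_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a cluster summary TSV
#'
#' One row per cluster member: cluster id, contig, coordinates, strand,
#' length and role, plus a `overlap_bp` column giving the member's total
#' overlap with other members (0 if none).
#'
#' @inheritParams write_gff
#' @return `path`, invisibly.
#' @export
write_cluster_summary <- function(clusters, path) {
  if (inherits(clusters, "gene_cluster")) clusters <- list(clusters)
  rows <- lapply(seq_along(clusters), function(ci) {
    m <- clusters[[ci]]$orfs
    ov <- clusters[[ci]]$overlaps
    member_ov <- vapply(seq_len(nrow(m)), function(i) {
      sum(ov$bp[ov$orf_i == i | ov$orf_j == i])
    }, numeric(1L))
    data.frame(
      cluster_id = sprintf("cluster%d", ci), contig = m$contig_id,
      start = m$start, end = m$end, strand = m$strand,
      length_aa = m$length_aa, role = m$role,
      overlap_bp = as.integer(member_ov), stringsAsFactors = FALSE
    )
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = character(), contig = character(),
               start = integer(), end = integer(), strand = character(),
               length_aa = integer(), role = character(),
               overlap_bp = integer())
  .write_tsv(tab, path)
}

.ASSIGNMENT_COLS <- c("product_id", "cleavage_after", "core_seq", "n_dehydr",
                      "theoretical_mass", "observed_mass", "delta",
                      "route_independent", "route_sequential")

#' Write variant assignments as TSV
#'
#' Masses are emitted with 4 decimal places. The processing-route flags
#' (family-level properties from [processing_routes()]) are repeated on
#' every row.
#'
#' @param assignments Data frame from [match_masses()].
#' @param path Output path.
#' @param routes Optional result of [processing_routes()].
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path, routes = NULL) {
  a <- assignments
  out <- data.frame(
    product_id = a$product_id,
    cleavage_after = a$cleavage_after,
    core_seq = a$core_seq,
    n_dehydr = a$n_dehydr,
    theoretical_mass = sprintf("%.4f", a$theoretical_mass),
    observed_mass = sprintf("%.4f", a$observed_mass),
    delta = sprintf("%.4f", a$delta),
    route_independent = if (is.null(routes)) NA else routes$independent,
    route_sequential = if (is.null(routes)) NA else routes$sequential,
    stringsAsFactors = FALSE
  )
  .write_tsv(out, path)
}

#' Read an assignment TSV written by [write_assignments()]
#'
#' @param path Path to the TSV.
#' @return Data frame with typed columns.
#' @export
read_assignments <- function(path) {
  res <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(.ASSIGNMENT_COLS %in% names(res))) {
    stop("not an assignment TSV (missing columns)", call. = FALSE)
  }
  res
}

#' Write a ground-truth sidecar
#'
#' Flat key-value text format (`key<TAB>value`, one per line) recording the
#' planted truth of a synthetic bundle; vectors are comma-joined.
#'
#' @param truth Named list of scalar or vector values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  keys <- names(truth)
  vals <- vapply(truth, function(v) paste(as.character(v), collapse = ","),
                 character(1L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(keys, vals, sep = "\t"), con)
  invisible(path)
}

#' Read a ground-truth sidecar
#'
#' @param path Path written by [write_truth()].
#' @return Named list of character values (comma-joined vectors split back).
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  vals <- lapply(parts, function(p) strsplit(p[2L], ",", fixed = TRUE)[[1L]])
  stats::setNames(vals, vapply(parts, `[`, character(1L), 1L))
}

.CONFIG_DEFAULTS <- list(
  scale = "average",
  tol_da = 1.0,
  max_dehydr = "auto",
  min_aa = 25L,
  start_codons = c("ATG", "GTG", "TTG"),
  max_gap_bp = 2000L,
  seed = 1L,
  log_level = "info"
)

#' Default run configuration
#'
#' @return A `run_config` list with the package defaults: average mass
#'   scale, 1 Da matching tolerance, automatic dehydration cap, 25-residue
#'   minimum ORF length, `ATG`/`GTG`/`TTG` start codons, 2000-bp cluster
#'   gap, seed 1, info-level logging.
#' @export
default_config <- function() {
  structure(.CONFIG_DEFAULTS, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Parsing is strict: unknown keys are fatal so that a misspelt option can
#' never be silently ignored. Missing keys take package defaults.
#'
#' @param path Path to a YAML config file.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(.CONFIG_DEFAULTS))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, raw)
  .validate_config(cfg)
  structure(cfg, class = "run_config")
}

.validate_config <- function(cfg) {
  if (!cfg$scale %in% c("average", "monoisotopic")) {
    stop("config: scale must be 'average' or 'monoisotopic'", call. = FALSE)
  }
  for (k in c("tol_da", "min_aa", "max_gap_bp")) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] <= 0) {
      stop(sprintf("config: %s must be a positive number", k), call. = FALSE)
    }
  }
  if (!identical(cfg$max_dehydr, "auto") &&
      (!is.numeric(cfg$max_dehydr) || cfg$max_dehydr < 0)) {
    stop("config: max_dehydr must be 'auto' or a non-negative number",
         call. = FALSE)
  }
  if (!all(grepl("^[ACGT]{3}$", cfg$start_codons))) {
    stop("config: start_codons must be nucleotide triplets", call. = FALSE)
  }
  if (!cfg$log_level %in% c("debug", "info", "warn")) {
    stop("config: log_level must be debug, info or warn", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (k in names(x)) {
    cat(sprintf("  %s = %s\n", k, paste(as.character(x[[k]]), collapse = ",")))
  }
  invisible(x)
}

.LOG_LEVELS <- c(debug = 1L, info = 2L, warn = 3L)

.log <- function(level, fmt, ..., threshold = "info") {
  if (.LOG_LEVELS[[level]] >= .LOG_LEVELS[[threshold]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

# Echo the resolved configuration to the log (reproducibility contract:
# every run records the parameters that produced it).
.log_config <- function(cfg) {
  for (k in names(cfg)) {
    .log("info", "config %s = %s", k,
         paste(as.character(cfg[[k]]), collapse = ","),
         threshold = cfg$log_level)
  }
}
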