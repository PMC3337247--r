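# High-level stage functions chaining the mining, deconvolution and
# matching modules. These are what the command-line surface calls; they are
# equally usable interactively.

#' Mine nucleotide sequences for lanthipeptide gene clusters
#'
#' Runs [find_orfs()], [classify_roles()] and [assemble_cluster()] over each
#' contig of a named sequence set.
#'
#' @param seqs Named character vector of nucleotide sequences (one per
#'   contig), e.g. from [read_fasta()].
#' @param min_aa Minimum ORF length in residues. Default 25.
#' @param starts Permitted start codons.
#' @param max_gap_bp Maximum intra-cluster gap in bp. Default 2000.
#' @param precursor_max Maximum precursor length in residues. Default 100.
#' @return List with `orfs` (data frame over all contigs with a `role`
#'   column) and `clusters` (flat list of `gene_cluster` objects).
#' @export
mine_sequences <- function(seqs, min_aa = 25, starts = c("ATG", "GTG", "TTG"),
                           max_gap_bp = 2000, precursor_max = 100) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  all_orfs <- list()
  clusters <- list()
  for (id in names(seqs)) {
    orfs <- find_orfs(seqs[[id]], min_aa = min_aa, starts = starts,
                      contig_id = id)
    roles <- classify_roles(orfs, precursor_max = precursor_max)
    orfs$role <- roles
    all_orfs[[id]] <- orfs
    clusters <- c(clusters, assemble_cluster(orfs[names(orfs) != "role"],
                                             roles, max_gap_bp = max_gap_bp))
  }
  list(orfs = do.call(rbind, all_orfs), clusters = clusters)
}

#' Deconvolve picked signals to one neutral mass per peptide
#'
#' Groups signal rows by `peptide_id` and forms a [consensus_mass()] for
#' each group. Groups whose charge states disagree beyond the consistency
#' window are reported with a warning and omitted — no consensus is emitted
#' for a conflicting set.
#'
#' @param signals Data frame with columns `peptide_id`, `mz`, `z`.
#' @param window Consistency window in Da. Default 3.
#' @return Named list of `neutral_mass` objects, in order of first
#'   appearance of each peptide id.
#' @export
deconvolve_signals <- function(signals, window = 3) {
  stopifnot(all(c("peptide_id", "mz", "z") %in% names(signals)))
  ids <- unique(signals$peptide_id)
  out <- list()
  for (id in ids) {
    grp <- signals[signals$peptide_id == id, c("mz", "z"), drop = FALSE]
    res <- tryCatch(consensus_mass(grp, window = window),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("peptide '%s': %s", id, conditionMessage(res)),
              call. = FALSE)
    } else {
      out[[id]] <- res
    }
  }
  out
}

#' Match observed signals against a precursor
#'
#' The full matcher stage: deconvolves the signals per peptide, enumerates
#' cleavage variants of the precursor over `window`, matches dehydrated
#' variant masses, optionally applies an Edman N-terminal constraint, and
#' reports processing-route consistency of the top assignment per product.
#'
#' @param pre A [prepeptide()] (or full precursor sequence string).
#' @param signals Signal data frame (`peptide_id`, `mz`, `z`) or a named
#'   numeric vector of already-deconvolved neutral masses.
#' @param tol Matching tolerance in Da. Default 1.
#' @param max_dehydr Dehydration cap; `NULL` = Ser+Thr count of each core.
#' @param nterm Optional N-terminal residue string constraint.
#' @param window Optional cleavage window passed to [enumerate_variants()].
#' @inheritParams peptide_mass
#' @return List with `observed` (named masses used), `assignments` (full
#'   table), `top` (best assignment per product) and `routes`.
#' @export
match_precursor <- function(pre, signals, tol = 1.0, max_dehydr = NULL,
                            nterm = NULL, window = NULL,
                            scale = c("average", "monoisotopic")) {
  scale <- .match_scale(scale)
  if (is.character(pre)) pre <- prepeptide(pre)
  if (is.data.frame(signals)) {
    observed <- deconvolve_signals(signals)
  } else {
    observed <- signals
  }
  variants <- enumerate_variants(pre, window = window)
  assignments <- match_masses(variants, observed, max_dehydr = max_dehydr,
                              tol = tol, scale = scale)
  if (!is.null(nterm)) {
    assignments <- apply_nterm_constraint(assignments, nterm)
  }
  top <- top_assignments(assignments)
  routes <- processing_routes(top, pre)
  list(observed = .observed_values(observed), assignments = assignments,
       top = top, routes = routes)
}

#' Best assignment per product
#'
#' [match_masses()] returns assignments sorted by quality; this keeps the
#' first (best) row for each product id.
#'
#' @param assignments Data frame from [match_masses()].
#' @return One-row-per-product data frame.
#' @export
top_assignments <- function(assignments) {
  res <- assignments[!duplicated(assignments$product_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Generate a complete synthetic fixture bundle
#'
#' Chains the generators: a five-gene cluster with its precursor, the
#' four-product truncation ladder at the planted cleavage sites, and
#' multi-charge signals for the product masses. When `out_dir` is given the
#' bundle is also written to disk (cluster FASTA, precursor FASTA, signal
#' TSV, ground-truth sidecar).
#'
#' @param seed Integer seed; the whole bundle is reproducible from it.
#' @param noise_sd Gaussian m/z noise in Thomson. Default 0.
#' @param charges Charge states simulated per product. Default `c(3, 4)`.
#' @param out_dir Optional output directory (created if needed).
#' @return List with `cluster` ([gen_cluster_dna()] result), `ladder`
#'   ([gen_product_ladder()] result), `signals` (data frame) and `paths`
#'   (named file paths, if written).
#' @export
simulate_bundle <- function(seed, noise_sd = 0, charges = c(3, 4),
                            out_dir = NULL) {
  cluster <- gen_cluster_dna(seed)
  pre <- cluster$precursor$pre
  truth <- cluster$precursor$truth
  ladder <- gen_product_ladder(pre, truth$cleavage_sites, truth$n_dehydr)
  signals <- gen_signals(stats::setNames(ladder$mass, ladder$product_id),
                         charges = charges, noise_sd = noise_sd,
                         seed = seed + 1L)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      cluster_fasta = file.path(out_dir, "cluster.fasta"),
      precursor_fasta = file.path(out_dir, "precursor.fasta"),
      signals_tsv = file.path(out_dir, "signals.tsv"),
      truth_txt = file.path(out_dir, "truth.txt")
    )
    write_fasta(stats::setNames(cluster$dna, cluster$contig_id),
                paths[["cluster_fasta"]])
    write_fasta(stats::setNames(pre$full_seq, "precursor"),
                paths[["precursor_fasta"]])
    write_signals(signals, paths[["signals_tsv"]])
    write_truth(list(
      seed = seed,
      noise_sd = noise_sd,
      precursor = pre$full_seq,
      leader_len = truth$leader_len,
      motif_start = truth$motif_start,
      cleavage_sites = truth$cleavage_sites,
      n_dehydr = truth$n_dehydr,
      gene = cluster$layout$gene,
      role = cluster$layout$role,
      strand = cluster$layout$strand,
      gene_start = cluster$layout$start,
      gene_end = cluster$layout$end,
      overlap_bp = cluster$overlap_bp
    ), paths[["truth_txt"]])
  }
  list(cluster = cluster, ladder = ladder, signals = signals, paths = paths)
}
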