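# Assignment of observed neutral masses to cleavage/trim variants of a
# precursor peptide: variant enumeration over a cleavage window, dehydrated
# mass matching, truncation-ladder inference and Edman N-terminal filtering.

#' Construct a precursor peptide (prepeptide) object
#'
#' Bundles a full precursor sequence with the leader-motif evidence that
#' localises the leader/core boundary. If `leader_motif` is not supplied the
#' sequence is scanned and the first FDL\[DN\] hit, if any, is recorded.
#'
#' @param full_seq Full precursor amino-acid sequence (1-based numbering).
#' @param leader_motif Optional one-row data frame as returned by
#'   [scan_motifs()] for pattern `leader_FDLX`, or `NULL`.
#' @return Object of class `prepeptide`: list with `full_seq` and
#'   `leader_motif` (possibly `NULL`).
#' @examples
#' prepeptide("MKNELFDLDVAADLGDYSSTTCC")
#' @export
prepeptide <- function(full_seq, leader_motif = NULL) {
  .check_seq(full_seq, "full_seq")
  if (is.null(leader_motif)) {
    hits <- scan_motifs(full_seq, "leader_FDLX")
    if (nrow(hits) > 0L) leader_motif <- hits[1L, , drop = FALSE]
  } else {
    stopifnot(is.data.frame(leader_motif), nrow(leader_motif) == 1L)
    if (leader_motif$end_1based > nchar(full_seq) ||
        leader_motif$start_1based < 1L) {
      stop("leader motif coordinates outside the precursor", call. = FALSE)
    }
  }
  structure(list(full_seq = full_seq, leader_motif = leader_motif),
            class = "prepeptide")
}

#' @export
print.prepeptide <- function(x, ...) {
  cat(sprintf("Prepeptide (%d aa): %s\n", nchar(x$full_seq), x$full_seq))
  if (!is.null(x$leader_motif)) {
    cat(sprintf("  leader motif %s at %d-%d\n", x$leader_motif$matched,
                x$leader_motif$start_1based, x$leader_motif$end_1based))
  }
  invisible(x)
}

.default_window <- function(pre) {
  n <- nchar(pre$full_seq)
  if (!is.null(pre$leader_motif)) {
    # 10 inter-residue positions centred on the end of the leader motif:
    # proteolytic maturation sites cluster just downstream of it
    e <- pre$leader_motif$end_1based
    lo <- max(1L, e - 4L)
    hi <- min(n - 1L, e + 5L)
  } else {
    lo <- 1L
    hi <- n - 1L
  }
  c(lo, hi)
}

#' Enumerate cleavage variants of a precursor
#'
#' One variant per inter-residue position in the window: cleavage after
#' position p yields the core suffix starting at p + 1.
#'
#' @param pre A [prepeptide()].
#' @param window Inclusive 1-based range of cleavage positions, either
#'   `c(lo, hi)` or a contiguous integer vector. `NULL` (default) uses 10
#'   positions centred on the end of the leader motif when one is recorded,
#'   otherwise the whole sequence.
#' @return Data frame with columns `cleavage_after` and `core_seq`.
#' @examples
#' pre <- prepeptide("MKNELFDLDVAADLGDYSSTTCC")
#' enumerate_variants(pre, c(10, 13))
#' @export
enumerate_variants <- function(pre, window = NULL) {
  stopifnot(inherits(pre, "prepeptide"))
  n <- nchar(pre$full_seq)
  if (is.null(window)) {
    window <- .default_window(pre)
  }
  if (length(window) == 0L) {
    return(data.frame(cleavage_after = integer(), core_seq = character(),
                      stringsAsFactors = FALSE))
  }
  window <- as.integer(range(window))
  if (window[1L] < 1L || window[2L] > n - 1L) {
    stop(sprintf("cleavage window [%d, %d] outside sequence bounds [1, %d]",
                 window[1L], window[2L], n - 1L), call. = FALSE)
  }
  pos <- seq.int(window[1L], window[2L])
  data.frame(
    cleavage_after = pos,
    core_seq = substring(pre$full_seq, pos + 1L, n),
    stringsAsFactors = FALSE
  )
}

.observed_values <- function(observed) {
  if (inherits(observed, "neutral_mass")) observed <- list(observed)
  if (is.list(observed) && !is.data.frame(observed)) {
    vals <- vapply(observed, function(o) {
      if (inherits(o, "neutral_mass")) o$value else as.numeric(o)
    }, numeric(1L))
    names(vals) <- names(observed)
    observed <- vals
  }
  stopifnot(is.numeric(observed), length(observed) >= 1L)
  if (is.null(names(observed)) || any(!nzchar(names(observed)))) {
    names(observed) <- paste0("obs", seq_along(observed))
  }
  observed
}

#' Match observed masses to dehydrated cleavage variants
#'
#' For every variant and every dehydration count up to
#' `min(max_dehydr, Ser+Thr count of the core)`, the theoretical dehydrated
#' mass is compared with each observed mass; pairs within `tol` become
#' candidate assignments. All candidates are reported; an observed mass
#' matched by more than one (variant, count) hypothesis is flagged
#' `ambiguous` rather than silently resolved, because mass alone cannot
#' discriminate near-ties — orthogonal evidence such as an Edman N-terminal
#' read ([apply_nterm_constraint()]) is the proper tie-breaker.
#'
#' @param variants Data frame from [enumerate_variants()].
#' @param observed Observed neutral masses: numeric vector (optionally named
#'   by product id), a `neutral_mass`, or a list of `neutral_mass` objects.
#' @param max_dehydr Maximum dehydration count per variant; `NULL` (default)
#'   means the Ser+Thr count of each candidate core.
#' @param tol Matching tolerance in Da. Default 1.0 (average scale at
#'   two-decimal ion-trap precision).
#' @inheritParams peptide_mass
#' @return Data frame sorted by `|delta|`, then fewer dehydrations, then
#'   more C-terminal cleavage, with columns `product_id`, `cleavage_after`,
#'   `core_seq`, `n_dehydr`, `theoretical_mass`, `observed_mass`, `delta`
#'   (observed - theoretical) and `ambiguous`. Observed masses with no match
#'   are returned in the `"unmatched"` attribute.
#' @export
match_masses <- function(variants, observed, max_dehydr = NULL, tol = 1.0,
                         scale = c("average", "monoisotopic")) {
  scale <- .match_scale(scale)
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0) {
    stop("`tol` must be positive", call. = FALSE)
  }
  observed <- .observed_values(observed)
  empty <- data.frame(
    product_id = character(), cleavage_after = integer(),
    core_seq = character(), n_dehydr = integer(),
    theoretical_mass = numeric(), observed_mass = numeric(),
    delta = numeric(), ambiguous = logical(), stringsAsFactors = FALSE
  )
  if (nrow(variants) == 0L) {
    attr(empty, "unmatched") <- observed
    return(empty)
  }
  w <- .water_mass(scale)
  rows <- vector("list", 0L)
  for (v in seq_len(nrow(variants))) {
    core <- variants$core_seq[v]
    m0 <- peptide_mass(core, scale)
    n_max <- count_ser_thr(core)
    if (!is.null(max_dehydr)) n_max <- min(n_max, max_dehydr)
    theo <- m0 - (0:n_max) * w
    for (oi in seq_along(observed)) {
      hit <- which(abs(observed[oi] - theo) <= tol)
      for (h in hit) {
        rows[[length(rows) + 1L]] <- data.frame(
          product_id = names(observed)[oi],
          cleavage_after = variants$cleavage_after[v],
          core_seq = core,
          n_dehydr = h - 1L,
          theoretical_mass = theo[h],
          observed_mass = unname(observed[oi]),
          delta = unname(observed[oi] - theo[h]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    attr(empty, "unmatched") <- observed
    return(empty)
  }
  res <- do.call(rbind, rows)
  res <- res[order(abs(res$delta), res$n_dehydr, -res$cleavage_after), ,
             drop = FALSE]
  rownames(res) <- NULL
  counts <- table(res$product_id)
  res$ambiguous <- as.vector(counts[res$product_id] > 1L)
  attr(res, "unmatched") <- observed[!(names(observed) %in% res$product_id)]
  res
}

#' Filter assignments by an Edman N-terminal read
#'
#' Keeps only assignments whose core sequence begins with the observed
#' N-terminal residues. Note that Edman cycles read the *unmodified*
#' residues; a dehydrated position blocks the ladder, so `nterm` should hold
#' the residues read before the first blocked cycle.
#'
#' @param assignments Data frame from [match_masses()].
#' @param nterm Non-empty amino-acid string of N-terminal residues.
#' @return The filtered assignment data frame (possibly zero rows).
#' @export
apply_nterm_constraint <- function(assignments, nterm) {
  .check_seq(nterm, "nterm")
  keep <- startsWith(assignments$core_seq, nterm)
  res <- assignments[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Infer a truncation ladder from a set of neutral masses
#'
#' Sorts the masses and, for each adjacent pair, asks whether the mass
#' difference is explained by a single amino-acid residue
#' ([residue_from_delta()]). Only adjacent differences are linked;
#' multi-residue gaps are reported as unexplained rather than
#' combinatorially decomposed.
#'
#' @param masses Numeric vector of at least two neutral masses (Da).
#' @param tol Residue-matching tolerance in Da. Default 0.5.
#' @inheritParams peptide_mass
#' @return Data frame of k-1 steps for k masses: `lighter_mass`,
#'   `heavier_mass`, `delta`, `residues` (slash-separated one-letter codes,
#'   `""` if none), `candidates` (list column of code vectors) and
#'   `explained`.
#' @examples
#' ladder_infer(c(4536, 4593, 4706, 4820))
#' @export
ladder_infer <- function(masses, tol = 0.5,
                         scale = c("average", "monoisotopic")) {
  scale <- .match_scale(scale)
  if (!is.numeric(masses) || length(masses) < 2L || any(is.na(masses))) {
    stop("`masses` must hold at least two neutral masses", call. = FALSE)
  }
  m <- sort(masses)
  lighter <- m[-length(m)]
  heavier <- m[-1L]
  delta <- heavier - lighter
  cand <- lapply(delta, residue_from_delta, tol = tol, scale = scale)
  res <- data.frame(
    lighter_mass = lighter,
    heavier_mass = heavier,
    delta = delta,
    residues = vapply(cand, paste, character(1L), collapse = "/"),
    stringsAsFactors = FALSE
  )
  res$candidates <- cand
  res$explained <- lengths(cand) > 0L
  res
}

#' Consistency of a product family with candidate processing routes
#'
#' Given one assignment per product of a single precursor, reports whether
#' the family is consistent with (a) independent proteolytic cleavage at
#' each site, and/or (b) one distal cleavage followed by successive removal
#' of single N-terminal residues (an exoproteolytic trimming ladder, which
#' requires consecutive cleavage sites). Both can be true; mass and sequence
#' data alone cannot distinguish them.
#'
#' @param assignments Data frame with columns `cleavage_after` and
#'   `core_seq`, one row per product.
#' @param pre The [prepeptide()] the products derive from.
#' @return List with `status` (`"ok"` or `"indeterminate"` for fewer than
#'   two products), `independent` and `sequential` (logical, `NA` when
#'   indeterminate).
#' @export
processing_routes <- function(assignments, pre) {
  stopifnot(inherits(pre, "prepeptide"))
  if (nrow(assignments) < 2L) {
    return(list(status = "indeterminate", independent = NA, sequential = NA))
  }
  n <- nchar(pre$full_seq)
  suffix_ok <- vapply(seq_len(nrow(assignments)), function(i) {
    p <- assignments$cleavage_after[i]
    identical(substring(pre$full_seq, p + 1L, n), assignments$core_seq[i])
  }, logical(1L))
  sites <- sort(assignments$cleavage_after)
  list(
    status = "ok",
    independent = all(suffix_ok),
    sequential = all(suffix_ok) && all(diff(sites) == 1L)
  )
}
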