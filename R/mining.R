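# Locus mining for lanthipeptide biosynthetic gene clusters: six-frame ORF
# calling, conserved-motif scanning, sequence-feature role assignment and
# cluster assembly.
#
# ORF coordinates are 0-based half-open on the forward strand (genomics
# convention); motif hits are reported 1-based inclusive (protein-position
# convention). An ORF interval includes its stop codon, so
# length_aa = (end - start)/3 - 1.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

.check_dna <- function(dna) {
  if (!is.character(dna) || length(dna) != 1L || is.na(dna)) {
    stop("`dna` must be a single nucleotide string", call. = FALSE)
  }
  dna <- toupper(dna)
  bad <- regexpr("[^ACGTN]", dna)
  if (bad > 0L) {
    stop(sprintf("non-IUPAC character '%s' at position %d of `dna`",
                 substr(dna, bad, bad), bad), call. = FALSE)
  }
  dna
}

.translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

#' Find open reading frames in all six frames
#'
#' Scans both strands and all three frames of `dna` for maximal
#' start-to-stop ORFs under the standard genetic code: within each
#' stop-delimited frame segment the ORF runs from the first start codon to
#' the closing stop. ORFs in different frames or on different strands may
#' overlap freely, including on the same strand.
#'
#' @param dna Nucleotide string over A/C/G/T/N.
#' @param min_aa Minimum number of encoded residues (start codon included,
#'   stop excluded). Default 25.
#' @param starts Character vector of permitted start codons. Default
#'   `c("ATG", "GTG", "TTG")`.
#' @param contig_id Identifier recorded for every ORF. Default `"contig"`.
#' @return Data frame with columns `contig_id`, `start`, `end` (0-based
#'   half-open, stop codon included), `strand` (`"+"`/`"-"`), `aa_seq`
#'   (translation, start codon as its literal amino acid, no stop character)
#'   and `length_aa`, sorted by `start` then `strand`.
#' @examples
#' find_orfs("ATGAAAGGGTAA", min_aa = 2)
#' @export
find_orfs <- function(dna, min_aa = 25, starts = c("ATG", "GTG", "TTG"),
                      contig_id = "contig") {
  dna <- .check_dna(dna)
  if (!is.numeric(min_aa) || length(min_aa) != 1L || min_aa < 1) {
    stop("`min_aa` must be >= 1", call. = FALSE)
  }
  L <- nchar(dna)
  out <- vector("list", 64L)
  n_out <- 0L
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else .revcomp(dna)
    for (f in 0:2) {
      n_cod <- (nchar(s) - f) %/% 3L
      if (n_cod < 2L) next
      cod_pos <- f + 3L * (seq_len(n_cod) - 1L) + 1L  # 1-based codon starts
      codons <- substring(s, cod_pos, cod_pos + 2L)
      stop_idx <- which(codons %in% .STOP_CODONS)
      start_idx <- which(codons %in% starts)
      if (length(stop_idx) == 0L || length(start_idx) == 0L) next
      prev <- 0L
      for (k in stop_idx) {
        j <- findInterval(prev, start_idx) + 1L  # first start after prev stop
        if (j <= length(start_idx) && start_idx[j] < k) {
          i <- start_idx[j]
          n_aa <- k - i
          if (n_aa >= min_aa) {
            s0 <- cod_pos[i] - 1L       # 0-based on scanned strand
            e0 <- cod_pos[k] + 2L       # half-open, includes stop codon
            if (strand == "+") {
              fwd_start <- s0
              fwd_end <- e0
            } else {
              fwd_start <- L - e0
              fwd_end <- L - s0
            }
            n_out <- n_out + 1L
            out[[n_out]] <- data.frame(
              contig_id = contig_id,
              start = fwd_start,
              end = fwd_end,
              strand = strand,
              aa_seq = .translate_codons(codons[i:(k - 1L)]),
              length_aa = n_aa,
              stringsAsFactors = FALSE
            )
          }
        }
        prev <- k
      }
    }
  }
  if (n_out == 0L) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      aa_seq = character(), length_aa = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out[seq_len(n_out)])
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Conserved patterns. The LanC cyclase consensus is relaxed at its variable
# positions so that only the strictly conserved His/Cys residues are pinned;
# the class I leader motif accepts Asp or Asn at its last position.
.MOTIF_PATTERNS <- c(
  leader_FDLX = "FDL[DN]",
  cyclase_GxxHG = "G..HG",
  cyclase_WCxG = "WC.G",
  cyclase_CHG = "CHG"
)

#' Scan a protein for conserved lanthipeptide motifs
#'
#' Finds every (possibly overlapping) occurrence of the class I leader motif
#' FDL\[DN\] and the three LanC cyclase motifs Gx..HG-type (GxxHG), WCxG and
#' CHG, in which the His and Cys residues are invariant.
#'
#' @param protein Amino-acid string over the standard one-letter codes.
#' @param patterns Subset of pattern ids to scan for; defaults to all of
#'   `"leader_FDLX"`, `"cyclase_GxxHG"`, `"cyclase_WCxG"`, `"cyclase_CHG"`.
#' @return Data frame with columns `pattern_id`, `start_1based`,
#'   `end_1based` (inclusive) and `matched`, ordered by position.
#' @examples
#' scan_motifs("MFDLDAGVSHG")
#' @export
scan_motifs <- function(protein, patterns = names(.MOTIF_PATTERNS)) {
  .check_seq(protein, "protein")
  patterns <- match.arg(patterns, names(.MOTIF_PATTERNS), several.ok = TRUE)
  rows <- lapply(patterns, function(pid) {
    # lookahead makes overlapping occurrences visible
    rx <- sprintf("(?=(%s))", .MOTIF_PATTERNS[[pid]])
    m <- gregexpr(rx, protein, perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(NULL)
    starts <- as.integer(m)
    lens <- attr(m, "capture.length")[, 1L]
    data.frame(
      pattern_id = pid,
      start_1based = starts,
      end_1based = starts + lens - 1L,
      matched = substring(protein, starts, starts + lens - 1L),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(pattern_id = character(), start_1based = integer(),
                      end_1based = integer(), matched = character(),
                      stringsAsFactors = FALSE))
  }
  res <- res[order(res$start_1based, res$pattern_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.has_ordered_cyclase_triple <- function(hits) {
  g <- hits$start_1based[hits$pattern_id == "cyclase_GxxHG"]
  w <- hits$start_1based[hits$pattern_id == "cyclase_WCxG"]
  c3 <- hits$start_1based[hits$pattern_id == "cyclase_CHG"]
  if (!length(g) || !length(w) || !length(c3)) return(FALSE)
  g1 <- min(g)
  w_after <- w[w > g1]
  if (!length(w_after)) return(FALSE)
  any(c3 > min(w_after))
}

# Walker-A P-loop of ABC transporter ATPase domains.
.WALKER_A <- "G..G.GK[ST]"

#' Assign a biosynthetic role to an ORF
#'
#' Sequence-feature heuristics for the members of a class I lanthipeptide
#' locus, applied in order of decreasing specificity:
#' \describe{
#'   \item{cyclase_like}{all three LanC motifs (GxxHG, WCxG, CHG) present in
#'     N-to-C order.}
#'   \item{precursor}{at most `precursor_max` residues with the leader motif
#'     FDL\[DN\] in the N-terminal half.}
#'   \item{dehydratase_like}{at least 800 residues (LanB dehydratases are
#'     large) and not cyclase_like.}
#'   \item{transporter_like}{Walker-A P-loop (GxxGxGK\[ST\]) present and
#'     400-800 residues. This is a heuristic stand-in for homology-based
#'     transporter identification and is flagged as such.}
#' }
#' Anything else is `unknown`.
#'
#' @param orf A one-row data frame or list with fields `aa_seq` and
#'   `length_aa`, as produced by [find_orfs()].
#' @param precursor_max Maximum precursor length in residues. Default 100.
#' @return One of `"cyclase_like"`, `"precursor"`, `"dehydratase_like"`,
#'   `"transporter_like"`, `"unknown"`.
#' @export
classify_role <- function(orf, precursor_max = 100) {
  aa <- if (is.data.frame(orf)) orf$aa_seq[[1L]] else orf$aa_seq
  len <- if (is.data.frame(orf)) orf$length_aa[[1L]] else orf$length_aa
  if (grepl("X", aa, fixed = TRUE)) return("unknown")  # ambiguous translation
  hits <- scan_motifs(aa)
  if (.has_ordered_cyclase_triple(hits)) return("cyclase_like")
  if (len <= precursor_max) {
    leader <- hits[hits$pattern_id == "leader_FDLX", , drop = FALSE]
    if (nrow(leader) > 0L && any(leader$start_1based <= ceiling(len / 2))) {
      return("precursor")
    }
  }
  if (len >= 800) return("dehydratase_like")
  if (len >= 400 && len <= 800 && grepl(.WALKER_A, aa)) {
    return("transporter_like")
  }
  "unknown"
}

#' @rdname classify_role
#' @param orfs Data frame of ORFs as produced by [find_orfs()].
#' @return `classify_roles()`: character vector of roles, one per row of
#'   `orfs`.
#' @export
classify_roles <- function(orfs, precursor_max = 100) {
  if (nrow(orfs) == 0L) return(character())
  vapply(seq_len(nrow(orfs)), function(i) {
    classify_role(orfs[i, , drop = FALSE], precursor_max = precursor_max)
  }, character(1L))
}

#' Assemble role-annotated ORFs into candidate gene clusters
#'
#' Groups ORFs with assigned roles (role other than `"unknown"`) whose
#' pairwise genomic gaps do not exceed `max_gap_bp` into clusters, anchored
#' on a cyclase-like ORF. A group is reported as a cluster only if it
#' contains at least one cyclase_like and at least one precursor member —
#' the minimal evidence for a functional class I locus. Every genuine
#' interval overlap between members is recorded in bp.
#'
#' @param orfs Data frame of ORFs from [find_orfs()] (one contig).
#' @param roles Character vector of roles, one per ORF row; see
#'   [classify_roles()].
#' @param max_gap_bp Maximum gap in bp between consecutive members.
#'   Default 2000.
#' @return List of `gene_cluster` objects; empty list if no group satisfies
#'   the anchor requirements. Each `gene_cluster` is a list with `orfs`
#'   (member data frame with a `role` column, sorted by `start`) and
#'   `overlaps` (data frame `orf_i`, `orf_j`, `bp` of member indices).
#' @export
assemble_cluster <- function(orfs, roles, max_gap_bp = 2000) {
  stopifnot(nrow(orfs) == length(roles))
  if (nrow(orfs) > 0L && length(unique(orfs$contig_id)) > 1L) {
    stop("all ORFs must be on one contig", call. = FALSE)
  }
  keep <- roles != "unknown"
  orfs <- orfs[keep, , drop = FALSE]
  roles <- roles[keep]
  if (nrow(orfs) == 0L) return(list())
  ord <- order(orfs$start, orfs$end)
  orfs <- orfs[ord, , drop = FALSE]
  roles <- roles[ord]
  orfs$role <- roles
  # chain members while the gap to the running cluster extent stays small
  group <- integer(nrow(orfs))
  g <- 1L
  cur_end <- orfs$end[1L]
  group[1L] <- g
  for (i in seq_len(nrow(orfs))[-1L]) {
    if (orfs$start[i] - cur_end > max_gap_bp) {
      g <- g + 1L
      cur_end <- orfs$end[i]
    } else {
      cur_end <- max(cur_end, orfs$end[i])
    }
    group[i] <- g
  }
  clusters <- list()
  for (gi in unique(group)) {
    members <- orfs[group == gi, , drop = FALSE]
    rownames(members) <- NULL
    if (!any(members$role == "cyclase_like") ||
        !any(members$role == "precursor")) next
    ov <- list()
    n <- nrow(members)
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        bp <- min(members$end[i], members$end[j]) -
          max(members$start[i], members$start[j])
        if (bp > 0L) {
          ov[[length(ov) + 1L]] <- data.frame(orf_i = i, orf_j = j, bp = bp)
        }
      }
    }
    overlaps <- if (length(ov)) do.call(rbind, ov) else
      data.frame(orf_i = integer(), orf_j = integer(), bp = integer())
    clusters[[length(clusters) + 1L]] <- structure(
      list(orfs = members, overlaps = overlaps),
      class = "gene_cluster"
    )
  }
  clusters
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat(sprintf("Gene cluster: %d ORFs on %s, span %d-%d\n",
              nrow(x$orfs), x$orfs$contig_id[1L],
              min(x$orfs$start), max(x$orfs$end)))
  df <- x$orfs[, c("start", "end", "strand", "length_aa", "role")]
  print(df, ...)
  if (nrow(x$overlaps) > 0L) {
    cat("Overlaps (member indices):\n")
    print(x$overlaps, ...)
  }
  invisible(x)
}
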