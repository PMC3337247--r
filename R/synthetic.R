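# Seeded generators of synthetic lanthipeptide loci with known ground truth:
# precursors with planted leader motifs, five-gene clusters with a 4-bp
# same-strand overlap and one opposite-strand gene, product truncation
# ladders and noisy multi-charge ESI signals. Every generated object carries
# its ground truth so pipeline stages can be tested end to end.

.AA20 <- names(.RESIDUE_AVG)[!duplicated(names(.RESIDUE_AVG))]

# residue -> synonymous codons (stops excluded), from the standard code
.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))[setdiff(unique(gc), "*")]
}

# Evaluate `expr` under a fixed seed, then restore the caller's RNG state.
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

.random_aa <- function(n) {
  paste(sample(.AA20, n, replace = TRUE), collapse = "")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.plant <- function(seq, motif, at) {
  paste0(substr(seq, 1L, at - 1L), motif,
         substr(seq, at + nchar(motif), nchar(seq)))
}

# Back-translate a protein with uniformly sampled synonymous codons.
# `forced` is a named list position -> codon overriding the sampled choice.
.backtranslate <- function(protein, stop_codon = "TAA", forced = list()) {
  tab <- .codon_table()
  chars <- strsplit(protein, "", fixed = TRUE)[[1L]]
  codons <- vapply(chars, function(a) {
    opts <- tab[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1L), USE.NAMES = FALSE)
  codons[1L] <- "ATG"
  for (p in names(forced)) codons[as.integer(p)] <- forced[[p]]
  paste0(paste(codons, collapse = ""), stop_codon)
}

#' Generate a synthetic lanthipeptide precursor with ground truth
#'
#' Produces a random precursor of `leader_len + core_len` residues (default
#' 64, a realistic class I precursor size) with the FDL\[DN\] leader motif
#' planted a few residues before the leader/core boundary, and a core
#' carrying at least 8 Ser/Thr (dehydration substrates) and 2 Cys (ring
#' partners). The background is uniform over the 20 residues; sequences with
#' accidental extra leader-motif copies are resampled so the recorded motif
#' is unambiguous.
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @param leader_len Leader length in residues, >= 6. Default 21.
#' @param core_len Core length in residues, >= 10. Default 43.
#' @return List with `pre` (a [prepeptide()]) and `truth`: `seed`,
#'   `leader_len`, `core_len`, `motif_start`, `cleavage_sites` (the four
#'   consecutive maturation sites straddling the leader end) and `n_dehydr`
#'   (planted dehydration count, 8).
#' @examples
#' gen_precursor(1)$pre
#' @export
gen_precursor <- function(seed, leader_len = 21, core_len = 43) {
  if (leader_len < 6) stop("`leader_len` must be >= 6 to host the leader motif",
                           call. = FALSE)
  if (core_len < 10) stop("`core_len` must be >= 10 to host 8 Ser/Thr and 2 Cys",
                          call. = FALSE)
  leader_len <- as.integer(leader_len)
  core_len <- as.integer(core_len)
  .with_seed(seed, {
    n <- leader_len + core_len
    motif_start <- max(2L, leader_len - 6L)
    plant_from <- leader_len + 1L + min(3L, core_len - 10L)
    for (attempt in 1:100) {
      leader <- paste0("M", .random_aa(leader_len - 1L))
      leader <- .plant(leader, paste0("FDL", sample(c("D", "N"), 1L)),
                       motif_start)
      core <- .random_aa(core_len)
      full <- paste0(leader, core)
      slots <- sample(seq.int(plant_from, n), 10L)
      st <- sample(c("S", "T"), 8L, replace = TRUE)
      for (i in 1:8) full <- .plant(full, st[i], slots[i])
      for (i in 9:10) full <- .plant(full, "C", slots[i])
      hits <- scan_motifs(full, "leader_FDLX")
      if (nrow(hits) == 1L && hits$start_1based == motif_start) break
    }
    if (nrow(hits) != 1L) {
      stop("failed to generate an unambiguous precursor", call. = FALSE)
    }
    list(
      pre = prepeptide(full, hits),
      truth = list(
        seed = seed, leader_len = leader_len, core_len = core_len,
        motif_start = motif_start,
        cleavage_sites = leader_len + (-1L):2L,
        n_dehydr = 8L
      )
    )
  })
}

# Fixed locus layout emulated by gen_cluster_dna: five genes, the first on
# the opposite strand, genes 3 and 4 overlapping by exactly 4 bp.
.CLUSTER_LAYOUT <- data.frame(
  gene = c("transporter1", "cyclase", "transporter2", "dehydratase",
           "precursor"),
  role = c("transporter_like", "cyclase_like", "transporter_like",
           "dehydratase_like", "precursor"),
  length_aa = c(596L, 454L, 625L, 1037L, 64L),
  strand = c("-", "+", "+", "+", "+"),
  stringsAsFactors = FALSE
)

.gen_cluster_attempt <- function(precursor_seq) {
  tab <- .CLUSTER_LAYOUT
  # transporters: Walker-A P-loop planted at residues 30-37
  p1 <- .plant(paste0("M", .random_aa(595L)), "GPSGSGKS", 30L)
  # cyclase: the three LanC motifs at their canonical positions
  p2 <- paste0("M", .random_aa(453L))
  p2 <- .plant(p2, "GVSHG", 244L)
  p2 <- .plant(p2, "WCYG", 316L)
  p2 <- .plant(p2, "CHG", 366L)
  # transporter2 ends "SK" so its tail back-translates to ...TCT AAA TGA,
  # which reads TAA|ATG in the +2 frame: an in-frame stop immediately
  # followed by the start of the overlapping dehydratase gene
  p3 <- .plant(paste0("M", .random_aa(622L), "SK"), "GPSGSGKS", 30L)
  # dehydratase residue 2 is Thr: every Thr codon starts with A, so the
  # gene's 4th base matches the trailing A of transporter2's TGA stop
  p4 <- paste0("MT", .random_aa(1035L))
  proteins <- list(p1, p2, p3, p4, precursor_seq)

  g1 <- .backtranslate(p1)
  g2 <- .backtranslate(p2)
  g3 <- .backtranslate(p3, stop_codon = "TGA",
                       forced = list(`624` = "TCT", `625` = "AAA"))
  g4 <- .backtranslate(p4)
  g5 <- .backtranslate(precursor_seq)

  spacers <- vapply(sample(80:200, 3L, replace = TRUE), .random_dna,
                    character(1L))
  pieces <- character()
  starts <- ends <- integer(5L)
  cursor <- 0L
  add <- function(x) {
    pieces[[length(pieces) + 1L]] <<- x
    cursor <<- cursor + nchar(x)
  }
  add(.random_dna(100L))                       # left flank
  starts[1L] <- cursor
  add(.revcomp(g1)); ends[1L] <- cursor
  add("TTA")                                   # minus-strand upstream stop
  add(spacers[1L]); add("TAA")                 # in-frame guard stop
  starts[2L] <- cursor
  add(g2); ends[2L] <- cursor
  add(spacers[2L]); add("TAA")
  starts[3L] <- cursor
  add(g3); ends[3L] <- cursor
  starts[4L] <- ends[3L] - 4L                  # 4-bp same-strand overlap
  add(substring(g4, 5L)); ends[4L] <- cursor
  add(spacers[3L]); add("TAA")
  starts[5L] <- cursor
  add(g5); ends[5L] <- cursor
  add(.random_dna(100L))                       # right flank

  tab$start <- starts
  tab$end <- ends
  tab$aa_seq <- vapply(proteins, identity, character(1L))
  list(dna = paste(pieces, collapse = ""), layout = tab)
}

#' Generate a synthetic five-gene lanthipeptide cluster with ground truth
#'
#' Emulates the canonical class I locus layout: two ABC-transporter genes, a
#' cyclase, a dehydratase and a short precursor gene on one contig. The
#' first gene is on the opposite strand; the dehydratase gene overlaps the
#' second transporter gene by exactly 4 bp on the same strand. Cyclase
#' motifs are planted at their canonical positions in the 454-residue
#' cyclase, Walker-A P-loops in the transporters, and the FDL\[DN\] motif in
#' the 64-residue precursor. Back-translation samples synonymous codons
#' uniformly. Each candidate locus is verified by running the package's own
#' miner ([find_orfs()], [classify_roles()], [assemble_cluster()]) and
#' resampled until the planted layout is recovered exactly, so the returned
#' truth is guaranteed mineable.
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `dna` (contig nucleotide string), `contig_id`,
#'   `layout` (data frame: `gene`, `role`, `length_aa`, `strand`, `start`,
#'   `end` in 0-based half-open forward coordinates, `aa_seq`),
#'   `precursor` (the [gen_precursor()] result) and `overlap_bp` (4).
#' @export
gen_cluster_dna <- function(seed) {
  .with_seed(seed, {
    sub <- sample.int(2^31 - 2, 30L)
    prec <- gen_precursor(sub[1L])
    for (attempt in 2:30) {
      cand <- .with_seed(sub[attempt], .gen_cluster_attempt(prec$pre$full_seq))
      orfs <- find_orfs(cand$dna, min_aa = 25, contig_id = "synthetic_contig")
      roles <- classify_roles(orfs)
      clusters <- assemble_cluster(orfs, roles)
      if (length(clusters) != 1L) next
      m <- clusters[[1L]]$orfs
      if (nrow(m) != 5L) next
      ok <- identical(m$start, cand$layout$start) &&
        identical(m$end, cand$layout$end) &&
        identical(m$strand, cand$layout$strand) &&
        identical(m$role, cand$layout$role) &&
        nrow(clusters[[1L]]$overlaps) == 1L &&
        clusters[[1L]]$overlaps$bp == 4L
      if (ok) {
        return(list(
          dna = cand$dna, contig_id = "synthetic_contig",
          layout = cand$layout, precursor = prec, overlap_bp = 4L,
          seed = seed
        ))
      }
    }
    stop("failed to generate a recoverable synthetic cluster", call. = FALSE)
  })
}

#' Generate a truncation ladder of modified products from a precursor
#'
#' One product per cleavage site: the core suffix after the site, dehydrated
#' `n_dehydr` times. Sites must be consecutive so adjacent products differ
#' by exactly one leading residue (a genuine ladder).
#'
#' @param pre A [prepeptide()].
#' @param sites Increasing, consecutive 1-based cleavage positions.
#' @param n_dehydr Dehydration count applied to every product. Default 8.
#' @inheritParams peptide_mass
#' @return Data frame with `product_id`, `cleavage_after`, `core_seq` and
#'   `mass` (neutral, Da).
#' @export
gen_product_ladder <- function(pre, sites, n_dehydr = 8,
                               scale = c("average", "monoisotopic")) {
  scale <- .match_scale(scale)
  stopifnot(inherits(pre, "prepeptide"))
  n <- nchar(pre$full_seq)
  if (any(sites < 1L) || any(sites > n - 1L)) {
    stop("cleavage sites outside sequence bounds", call. = FALSE)
  }
  if (length(sites) > 1L && any(diff(sites) != 1L)) {
    stop("cleavage sites must be consecutive to form a ladder", call. = FALSE)
  }
  cores <- substring(pre$full_seq, sites + 1L, n)
  data.frame(
    product_id = paste0("P", seq_along(sites)),
    cleavage_after = as.integer(sites),
    core_seq = cores,
    mass = vapply(cores, dehydrated_mass, numeric(1L), n_dehydr = n_dehydr,
                  scale = scale, USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Simulate multi-charge ESI signals for a set of neutral masses
#'
#' Emits one (m/z, z) signal per mass and charge state, with Gaussian noise
#' applied in m/z space (where the instrument errs), not mass space.
#'
#' @param masses Numeric vector of neutral masses (Da), optionally named by
#'   product id (default `P1`, `P2`, ...).
#' @param charges Integer charge states observed for each mass. Default
#'   `c(3, 4)`, the typical envelope of a 4-5 kDa peptide on an ion trap.
#' @param noise_sd Gaussian m/z noise standard deviation in Thomson.
#'   Default 0.
#' @param seed Integer seed.
#' @return Data frame with columns `peptide_id`, `mz`, `z`, one row per
#'   signal, in the schema read back by [read_signals()].
#' @export
gen_signals <- function(masses, charges = c(3, 4), noise_sd = 0, seed = 1) {
  stopifnot(is.numeric(masses), length(masses) >= 1L, noise_sd >= 0)
  ids <- names(masses)
  if (is.null(ids)) ids <- paste0("P", seq_along(masses))
  .with_seed(seed, {
    rows <- expand.grid(i = seq_along(masses), z = sort(charges),
                        KEEP.OUT.ATTRS = FALSE)
    mz <- mz_from_mass(masses[rows$i], rows$z)
    if (noise_sd > 0) mz <- mz + stats::rnorm(length(mz), 0, noise_sd)
    res <- data.frame(
      peptide_id = ids[rows$i],
      mz = mz,
      z = as.integer(rows$z),
      stringsAsFactors = FALSE
    )
    res <- res[order(match(res$peptide_id, ids), res$z), , drop = FALSE]
    rownames(res) <- NULL
    res
  })
}
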