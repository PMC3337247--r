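test_that("find_orfs calls a simple forward ORF and its reverse complement", {
  fwd <- find_orfs("ATGAAAGGGTAA", min_aa = 2)
  expect_identical(nrow(fwd), 1L)
  expect_identical(fwd$strand, "+")
  expect_identical(fwd$aa_seq, "MKG")
  expect_identical(fwd$start, 0L)
  expect_identical(fwd$end, 12L)
  expect_identical(fwd$length_aa, 3L)

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGAAAGGGTAA")))
  rev <- find_orfs(rc, min_aa = 2)
  expect_identical(nrow(rev), 1L)
  expect_identical(rev$strand, "-")
  expect_identical(rev$aa_seq, "MKG")
  expect_identical(rev$start, 0L)
  expect_identical(rev$end, 12L)
})

test_that("non-IUPAC characters are rejected with their position", {
  expect_error(find_orfs("ACGTXACGT"), "position 5")
  expect_no_error(find_orfs("ACGTNACGT", min_aa = 1))
})

test_that("find_orfs agrees with an independent brute-force oracle", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(c(90:600, 2000:3000), 1)
    dna <- random_dna(n)
    min_aa <- sample(c(5, 15, 25), 1)
    got <- find_orfs(dna, min_aa = min_aa)
    want <- oracle_orfs(dna, min_aa = min_aa)
    expect_identical(got[, c("start", "end", "strand", "aa_seq", "length_aa")],
                     want)
  }
})

test_that("ORFs on the reverse complement are the strand-flipped originals", {
  set.seed(12)
  for (i in 1:10) {
    dna <- random_dna(1500)
    L <- nchar(dna)
    fwd <- find_orfs(dna, min_aa = 10)
    rev <- find_orfs(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(dna))), min_aa = 10)
    flipped <- data.frame(
      start = L - rev$end, end = L - rev$start,
      strand = ifelse(rev$strand == "+", "-", "+"),
      aa_seq = rev$aa_seq, length_aa = rev$length_aa,
      stringsAsFactors = FALSE
    )
    flipped <- flipped[order(flipped$start, flipped$end, flipped$strand), ]
    rownames(flipped) <- NULL
    expect_identical(fwd[, names(flipped)], flipped)
  }
})

test_that("scan_motifs finds the cyclase motifs at their canonical positions", {
  set.seed(3)
  p <- random_protein(454)
  # strip accidental motif instances before planting
  p <- gsub("FDL[DN]", "FALA", p)
  substr(p, 244, 248) <- "GVSHG"
  substr(p, 316, 319) <- "WCYG"
  substr(p, 366, 368) <- "CHG"
  hits <- scan_motifs(p)
  g <- hits[hits$pattern_id == "cyclase_GxxHG", ]
  expect_true(any(g$start_1based == 244 & g$end_1based == 248 &
                    g$matched == "GVSHG"))
  w <- hits[hits$pattern_id == "cyclase_WCxG", ]
  expect_true(any(w$start_1based == 316 & w$end_1based == 319 &
                    w$matched == "WCYG"))
  c3 <- hits[hits$pattern_id == "cyclase_CHG", ]
  expect_true(any(c3$start_1based == 366 & c3$end_1based == 368))
})

test_that("the leader motif matches FDLD and FDLN at position 1", {
  for (m in c("FDLD", "FDLN")) {
    hits <- scan_motifs(paste0(m, "AGKR"), "leader_FDLX")
    expect_identical(hits$start_1based, 1L)
    expect_identical(hits$end_1based, 4L)
    expect_identical(hits$matched, m)
  }
  expect_identical(nrow(scan_motifs("FDLAAGKR", "leader_FDLX")), 0L)
})

test_that("every motif hit re-slices to its matched string", {
  set.seed(4)
  for (i in 1:30) {
    p <- random_protein(sample(50:400, 1))
    hits <- scan_motifs(p)
    if (nrow(hits) == 0) next
    for (k in seq_len(nrow(hits))) {
      expect_identical(substring(p, hits$start_1based[k], hits$end_1based[k]),
                       hits$matched[k])
    }
  }
  # overlapping instances are all reported
  hits <- scan_motifs("CHGCHG", "cyclase_CHG")
  expect_identical(hits$start_1based, c(1L, 4L))
  hits2 <- scan_motifs("GGGHGHG", "cyclase_GxxHG")
  expect_identical(nrow(hits2), 2L)
})

test_that("classify_role applies the lanthipeptide locus heuristics", {
  set.seed(5)
  cyc <- random_protein(454)
  substr(cyc, 244, 248) <- "GVSHG"
  substr(cyc, 316, 319) <- "WCYG"
  substr(cyc, 366, 368) <- "CHG"
  expect_identical(classify_role(list(aa_seq = cyc, length_aa = 454L)),
                   "cyclase_like")

  prec <- standin_precursor()
  expect_identical(classify_role(list(aa_seq = prec, length_aa = 64L)),
                   "precursor")
  no_motif <- gsub("FDL[DN]", "AALA", prec)
  expect_identical(classify_role(list(aa_seq = no_motif, length_aa = 64L)),
                   "unknown")

  big <- gsub("FDL[DN]", "AALA", random_protein(1037))
  big <- gsub("G..HG", "AAAAA", big)  # no accidental cyclase call
  expect_identical(classify_role(list(aa_seq = big, length_aa = 1037L)),
                   "dehydratase_like")

  tp <- random_protein(596)
  tp <- gsub("G..HG", "AAAAA", tp)
  substr(tp, 30, 37) <- "GPSGSGKS"
  expect_identical(classify_role(list(aa_seq = tp, length_aa = 596L)),
                   "transporter_like")
})

test_that("assemble_cluster requires a cyclase anchor plus a precursor", {
  cl <- gen_cluster_dna(3)
  orfs <- find_orfs(cl$dna, contig_id = cl$contig_id)
  roles <- classify_roles(orfs)
  clusters <- assemble_cluster(orfs, roles)
  expect_length(clusters, 1)
  m <- clusters[[1]]$orfs
  expect_identical(nrow(m), 5L)
  expect_identical(m$strand, c("-", "+", "+", "+", "+"))
  expect_identical(clusters[[1]]$overlaps$bp, 4L)

  # cyclase only: no cluster
  cyc_only <- orfs[roles == "cyclase_like", , drop = FALSE]
  expect_length(assemble_cluster(cyc_only, rep("cyclase_like", nrow(cyc_only))),
                0)

  # two anchor groups far apart become two clusters
  shifted <- m
  shifted$start <- m$start + max(m$end) + 5000L
  shifted$end <- m$end + max(m$end) + 5000L
  both <- rbind(m, shifted)
  expect_length(assemble_cluster(both[, setdiff(names(both), "role")],
                                 rep(m$role, 2)), 2)
})

test_that("cluster assembly is invariant to input ORF order", {
  cl <- gen_cluster_dna(9)
  orfs <- find_orfs(cl$dna, contig_id = cl$contig_id)
  roles <- classify_roles(orfs)
  ref <- assemble_cluster(orfs, roles)
  set.seed(6)
  for (i in 1:5) {
    perm <- sample(nrow(orfs))
    got <- assemble_cluster(orfs[perm, , drop = FALSE], roles[perm])
    expect_identical(lapply(got, function(x) {
      rownames(x$orfs) <- NULL
      x
    }), ref)
  }
})
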