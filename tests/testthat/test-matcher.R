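test_that("enumerate_variants yields one exact suffix per window position", {
  pre <- prepeptide(standin_precursor())
  v <- enumerate_variants(pre, c(20, 23))
  expect_identical(v$cleavage_after, 20:23)
  expect_identical(substr(v$core_seq, 1, 1), c("D", "L", "G", "D"))
  expect_identical(v$core_seq,
                   substring(pre$full_seq, 21:24, nchar(pre$full_seq)))

  one <- enumerate_variants(pre, c(22, 22))
  expect_identical(nrow(one), 1L)

  full <- enumerate_variants(pre, c(1, nchar(pre$full_seq) - 1))
  expect_identical(nrow(full), nchar(pre$full_seq) - 1L)

  expect_identical(nrow(enumerate_variants(pre, integer(0))), 0L)
  expect_error(enumerate_variants(pre, c(1, 64)), "bounds")
})

test_that("the default cleavage window tracks the leader motif", {
  pre <- prepeptide(standin_precursor())
  v <- enumerate_variants(pre)
  # motif ends at 18: ten positions centred there
  expect_identical(v$cleavage_after, 14:23)
  no_motif <- prepeptide(gsub("FDL[DN]", "AALA", standin_precursor()))
  expect_identical(nrow(enumerate_variants(no_motif)), 63L)
})

test_that("match_masses recovers a planted cleavage and dehydration count", {
  gp <- gen_precursor(21)
  lad <- gen_product_ladder(gp$pre, gp$truth$cleavage_sites, 8)
  v <- enumerate_variants(gp$pre)
  a <- match_masses(v, setNames(lad$mass, lad$product_id))
  top <- top_assignments(a)
  top <- top[order(top$product_id), ]
  expect_identical(top$cleavage_after, lad$cleavage_after)
  expect_identical(top$n_dehydr, rep(8L, 4))
  expect_equal(top$delta, rep(0, 4), tolerance = 1e-9)
})

test_that("an unmodified core matches with zero dehydrations", {
  pre <- prepeptide(standin_precursor())
  v <- enumerate_variants(pre, c(21, 21))
  a <- match_masses(v, peptide_mass(v$core_seq[1]), max_dehydr = 0)
  expect_identical(nrow(a), 1L)
  expect_identical(a$n_dehydr, 0L)
  expect_false(a$ambiguous)
})

test_that("near-degenerate hypotheses are both reported and flagged", {
  # Ala (71.08 Da) vs four waters (72.06 Da): cores X and AX collide within
  # 1 Da when the dehydration counts differ by four
  pre <- prepeptide("MFDLDASTSTSTSC")
  v <- enumerate_variants(pre, c(5, 6))
  obs <- peptide_mass("STSTSTSC")
  a <- match_masses(v, obs, tol = 1.0)
  expect_identical(nrow(a), 2L)
  expect_true(all(a$ambiguous))
  expect_identical(a$cleavage_after[1], 6L)  # exact match ranks first
  expect_identical(a$n_dehydr, c(0L, 4L))
})

test_that("match results are invariant to variant and observed order", {
  gp <- gen_precursor(22)
  lad <- gen_product_ladder(gp$pre, gp$truth$cleavage_sites, 8)
  v <- enumerate_variants(gp$pre)
  obs <- setNames(lad$mass, lad$product_id)
  ref <- match_masses(v, obs)
  set.seed(8)
  for (i in 1:5) {
    vp <- v[sample(nrow(v)), , drop = FALSE]
    op <- obs[sample(length(obs))]
    got <- match_masses(vp, op)
    rownames(got) <- rownames(ref) <- NULL
    expect_identical(got, ref)
  }
})

test_that("every assignment satisfies its tolerance by direct recomputation", {
  for (seed in c(31, 32)) {
    gp <- gen_precursor(seed)
    lad <- gen_product_ladder(gp$pre, gp$truth$cleavage_sites, 8)
    sg <- gen_signals(setNames(lad$mass, lad$product_id), noise_sd = 0.05,
                      seed = seed)
    res <- match_precursor(gp$pre, sg, tol = 1.0)
    a <- res$assignments
    for (k in seq_len(nrow(a))) {
      expect_lte(abs(a$observed_mass[k] -
                       dehydrated_mass(a$core_seq[k], a$n_dehydr[k])), 1.0)
    }
  }
})

test_that("unmatched observed masses are listed separately", {
  pre <- prepeptide(standin_precursor())
  v <- enumerate_variants(pre, c(21, 21))
  obs <- c(hit = peptide_mass(v$core_seq[1]), miss = 999)
  a <- match_masses(v, obs, max_dehydr = 0)
  expect_identical(names(attr(a, "unmatched")), "miss")
})

test_that("the Edman N-terminal constraint pins the cleavage site", {
  pre <- prepeptide(standin_precursor())
  v <- enumerate_variants(pre, c(20, 23))
  obs <- setNames(peptide_mass(v$core_seq), paste0("prod", 1:4))
  a <- match_masses(v, obs, max_dehydr = 0)
  lgdy <- apply_nterm_constraint(a, "LGDY")
  expect_identical(unique(lgdy$cleavage_after), 21L)
  dy <- apply_nterm_constraint(a, "DY")
  expect_identical(unique(dy$cleavage_after), 23L)
  expect_identical(nrow(apply_nterm_constraint(a, "WWWW")), 0L)
})

test_that("ladder_infer names the residues separating adjacent masses", {
  steps <- ladder_infer(c(4536, 4593, 4706, 4820))
  expect_identical(steps$delta, c(57, 113, 114))
  expect_identical(unname(steps$candidates[[1]]), "G")
  expect_setequal(unname(steps$candidates[[2]]), c("L", "I"))
  expect_identical(unname(steps$candidates[[3]]), "N")
  expect_true(all(steps$explained))

  one <- ladder_infer(c(3000, 3057.05))
  expect_identical(nrow(one), 1L)
  expect_identical(unname(one$candidates[[1]]), "G")

  gap <- ladder_infer(c(3000, 3200))
  expect_false(gap$explained)
  expect_identical(gap$residues, "")
})

test_that("ladder steps telescope: k-1 steps summing to the mass range", {
  set.seed(9)
  for (i in 1:10) {
    m <- sort(runif(sample(2:8, 1), 1000, 5000))
    steps <- ladder_infer(m)
    expect_identical(nrow(steps), length(m) - 1L)
    expect_equal(sum(steps$delta), max(m) - min(m), tolerance = 1e-9)
  }
})

test_that("processing_routes distinguishes trimming ladders from independent cuts", {
  pre <- prepeptide(standin_precursor())
  v <- enumerate_variants(pre, c(20, 23))
  r <- processing_routes(v, pre)
  expect_true(r$independent)
  expect_true(r$sequential)

  gapped <- v[c(1, 3), ]  # sites 20 and 22, no intermediate
  r2 <- processing_routes(gapped, pre)
  expect_true(r2$independent)
  expect_false(r2$sequential)

  r3 <- processing_routes(v[1, ], pre)
  expect_identical(r3$status, "indeterminate")
})
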