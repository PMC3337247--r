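# lantimine

Lanthipeptide gene-cluster mining and mass-ladder dereplication in R.

## The problem

Class I lanthipeptides (lantibiotics) are ribosomally synthesised
antibacterial peptides. A precursor (LanA) carries an N-terminal leader —
recognisable by the conserved FDL[DN] motif — and a Ser/Thr/Cys-rich core.
A dehydratase (LanB) converts Ser/Thr to Dha/Dhb, each dehydration removing
one water (−18.015 Da average); a cyclase (LanC, with conserved GxxHG, WCxG
and CHG motifs) closes the thioether rings; proteolysis removes the leader.
Producers often secrete a *family* of products from one precursor,
differing by successive single N-terminal residues — a truncation ladder.

Connecting a sequenced genome to the masses observed by ESI-MS therefore
takes a chain of small inferences, which this package implements as tested,
reusable pieces:

1. **Mining** — six-frame ORF calling, motif scanning and role assignment
   locate the biosynthetic locus and its precursor
   (`find_orfs()`, `scan_motifs()`, `classify_role()`,
   `assemble_cluster()`).
2. **Deconvolution** — picked (m/z, z) signals are collapsed to neutral
   masses under the [M+zH]ᶻ⁺ convention, M = z·(m/z − 1.007276), with a
   cross-charge consistency check and low-resolution integer reporting
   (`mass_from_mz()`, `consensus_mass()`).
3. **Matching** — cleavage/trim variants of the precursor, dehydrated k
   times, are matched to the observed masses; inter-mass differences are
   read as single residues; an Edman N-terminal read pins the cleavage
   site (`enumerate_variants()`, `match_masses()`, `ladder_infer()`,
   `apply_nterm_constraint()`, `processing_routes()`).
4. **Synthetic data** — seeded generators produce clusters, precursors,
   ladders and noisy signals with known ground truth, so the whole chain
   is testable offline (`gen_cluster_dna()`, `gen_precursor()`,
   `gen_product_ladder()`, `gen_signals()`, `simulate_bundle()`).

All mass arithmetic defaults to **average** masses: the target analytes are
4–5 kDa peptides on ion-trap instruments reporting m/z to two decimals,
where isotope envelopes are unresolved.

## Worked example

A published four-product ladder, measured as 3+/4+ ion pairs, ships with
the package. Deconvolving each product's signals:

```r
library(lantimine)
sig <- read_signals(system.file("extdata", "published_ladder_signals.tsv",
                                package = "lantimine"))
dec <- deconvolve_signals(sig)
for (d in dec) print(d)
#> Neutral mass: 4535.9495 Da (reported 4536 Da) from 2 signal(s), z = 3/4
#> Neutral mass: 4593.9645 Da (reported 4593 Da) from 2 signal(s), z = 3/4
#> Neutral mass: 4706.7495 Da (reported 4706 Da) from 2 signal(s), z = 3/4
#> Neutral mass: 4821.2045 Da (reported 4820 Da) from 2 signal(s), z = 3/4
```

The full-precision value is the mean across charge states; the reported
integer mass truncates the highest-charge (here 4+) deconvolution, the
convention that matches low-resolution multiply-charged reporting. The
inter-product differences then read as single residues:

```r
m <- vapply(dec, `[[`, integer(1), "integer_report")
ladder_infer(as.numeric(m))
#>   lighter_mass heavier_mass delta residues candidates explained
#> 1         4536         4593    57        G          G      TRUE
#> 2         4593         4706   113      L/I       L, I      TRUE
#> 3         4706         4820   114        N          N      TRUE
```

So the four products differ by Gly, Leu/Ile (isobaric, always co-reported)
and Asn — a truncation ladder from one precursor. The heaviest product's
mass deficit against its unmodified propeptide, 144 Da, is eight waters:

```r
infer_dehydration_count(144)
#> $n
#> [1] 8
#> $residual
#> [1] 0.1224
#> $low_confidence
#> [1] FALSE
```

End to end on synthetic data with known truth:

```r
b <- simulate_bundle(7)                                  # seeded fixture
mined <- mine_sequences(setNames(b$cluster$dna, b$cluster$contig_id))
mined$clusters[[1]]                                      # 5 ORFs, roles, 4-bp overlap
res <- match_precursor(mined$clusters[[1]]$orfs$aa_seq[5], b$signals)
res$top                                                  # planted sites + 8 dehydrations
```

A shell front end is installed as `exec/lantimine` with subcommands
`mine`, `match`, `simulate` and `run` (see `lanti_cli()`).

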