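---
title: "Methods: from genome to mass ladder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from genome to mass ladder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lantimine)
```

This vignette records the models, conventions and design choices behind
`lantimine`, in the order the pipeline applies them.

## Mass model

Peptide masses are residue-additive: the neutral mass of a sequence is the
sum of its residue masses plus one water (the termini). Two scales are
supported. **Average** masses (elemental-abundance weighted) are the
default, because the package targets 4–5 kDa peptides measured on ion-trap
instruments that report m/z to two decimals: at that size and resolution
the isotope envelope is unresolved and the measured centroid is an
average-scale quantity. Monoisotopic masses are available via
`scale = "monoisotopic"` everywhere but would only be appropriate for
resolved envelopes. Constants: water 18.0153 Da (average) / 18.010565 Da
(monoisotopic), proton 1.007276 Da.

Lanthipeptide maturation dehydrates Ser/Thr residues; each event removes
one water. `dehydrated_mass(seq, k)` therefore subtracts `k` waters and
refuses `k` beyond the Ser+Thr count — the hard chemical budget. Only the
*count* of dehydrations is ever inferred, never which residues carry them:
mass alone cannot localise the modification.

## Charge-state deconvolution

Positive electrospray ions follow the [M+zH]^z+ convention,
M = z·(m/z − m_p). `consensus_mass()` deconvolves every signal of one
analyte and applies two rules:

* **Consistency window** (default 3 Da): the per-signal masses must agree
  within the window or the set is rejected as conflicting, with no
  consensus emitted. The default reflects the empirical spread of 3+/4+
  pairs on two-decimal ion-trap data, where a ±0.005 Th centroid error is
  amplified z-fold in mass (up to ~2 Da across charge states).
* **Integer reporting by truncation of the highest charge state.** The
  full-precision consensus (mean over signals) is always retained, but the
  integer report floors the mass deconvolved from the highest z. Among the
  candidate conventions (round vs floor, 3+ vs 4+ vs mean) this is the one
  that reproduces the published integer masses of the reference
  four-product ladder from their printed 4+ signals, while 3+-derived
  masses land up to ~1.7 Da higher; the choice is a reporting convention,
  not physics, and the exact value is never used for matching — matching
  always uses full precision.

## Residue reading of mass differences

`residue_from_delta(delta, tol)` returns every standard residue whose
residue mass lies within `tol` (default 0.5 Da) of a mass difference. Two
honesty rules apply at this precision:

* Leu/Ile are exactly isobaric and are always co-reported; distinguishing
  them requires sequence context (e.g. a precursor that lacks Ile), which
  is the caller's knowledge, not the mass spectrum's.
* Near-isobars fall out of the window arithmetic: Gln/Lys differ by
  0.04 Da and are co-reported at any practical tolerance; Asn/Asp differ
  by 0.98 Da and separate cleanly at the 0.5 Da default. An empty
  candidate set is a valid result ("no single-residue explanation"), which
  `ladder_infer()` propagates as an unexplained step rather than
  decomposing multi-residue gaps combinatorially — a two-residue gap has
  too many decompositions at 0.5 Da to be evidence of anything.

## Mining

`find_orfs()` scans all six frames for maximal start-to-stop ORFs: within
each stop-delimited frame segment the ORF runs from the first permitted
start codon (default ATG/GTG/TTG) to the closing stop, which is included
in the interval. Coordinates are 0-based half-open on the forward strand
internally; motif hits are reported 1-based inclusive, matching how
protein positions are quoted in the literature. The default `min_aa = 25`
keeps the 64-residue precursor class comfortably above threshold while
suppressing micro-ORFs; neither value is canonical and both are
configurable.

`classify_role()` uses sequence features only, in decreasing order of
specificity: the three cyclase motifs in N-to-C order (GxxHG relaxed at
its variable positions — reference cyclases themselves violate the stricter
published consensus at position 3, so only the strictly conserved His/Cys
are pinned); precursor = ≤100 residues with FDL[DN] in the N-terminal
half; dehydratase = ≥800 residues (LanB proteins are consistently large);
transporter = Walker-A P-loop in a 400–800 residue protein. The Walker-A
rule is an explicit heuristic stand-in for homology-based transporter
calls, which are outside this package's scope (no BLAST, no databases).
Translations containing ambiguous codons (X) are never classified.

`assemble_cluster()` chains role-bearing ORFs with gaps ≤ 2000 bp and
reports a cluster only when it contains a cyclase anchor *and* a
precursor — the minimal evidence of a functional locus. ORFs classified
`unknown` are excluded from membership: random coding DNA always contains
spurious ORFs in alternate frames, and including them would make cluster
membership an artefact of the ORF caller's sensitivity rather than of
biosynthetic evidence. Genuine interval overlaps between members are
recorded in bp, since compact operon-like packing (including small
same-strand overlaps) is typical of these loci.

## Matching

`enumerate_variants()` generates one cleavage variant per inter-residue
position in a window. The default window is 10 positions centred on the
end of the leader motif when one is present: maturation sites cluster just
downstream of the leader, and a bounded window keeps the hypothesis space
honest (a full-sequence scan is available by passing the window
explicitly). `match_masses()` scores every (variant, dehydration count)
pair against every observed mass at `tol` (default 1.0 Da — twice the
worst-case deconvolution error of a two-decimal 4+ signal) and ranks by
|Δ|, then fewer dehydrations (parsimony), then more C-terminal cleavage
(shorter leader remnants are chemically likelier). Ties and multiple
candidates are *reported and flagged*, never dropped: the designed
tie-breaker is orthogonal evidence, an Edman N-terminal read applied via
`apply_nterm_constraint()`. A genuinely near-degenerate pair exists in
this space — Ala (71.08 Da) versus four waters (72.06 Da) differ by just
under 1 Da — which is why the flag matters.

`processing_routes()` checks a product family against two maturation
models: independent cleavage at each site, and a single distal cleavage
followed by successive single-residue N-terminal trimming (requires
consecutive sites). Both can hold simultaneously; mass and sequence data
cannot distinguish them, so both flags are reported.

## Synthetic data: what it emulates and what it does not

The generators emulate the study conditions of a canonical class I locus:
five genes (two ABC transporters of 596 and 625 residues, a 454-residue
cyclase with motifs planted at their canonical positions 244/316/366, a
1037-residue dehydratase, a 64-residue precursor split 21 + 43), the first
gene on the opposite strand, the dehydratase overlapping the second
transporter by exactly 4 bp, a four-product ladder at consecutive cleavage
sites straddling the leader end, eight dehydrations per product, and 3+/4+
signals with Gaussian noise applied in m/z space (where the instrument
errs), default sd 0 or 0.05 Th for the noisy condition — a realistic
centroid jitter for two-decimal ion-trap peak picking.

Construction guarantees exact mineability: an in-frame stop codon is
planted immediately upstream of every gene start, so the maximal-ORF rule
recovers precisely the planted coordinates, and the 4-bp overlap is
engineered through the upstream gene's C-terminal `...TCT AAA TGA` tail,
which reads `TAA|ATG` in the overlapped frame. Each candidate locus is
verified by running the package's own miner against the truth and
resampled on mismatch, so rare accidental motif plants cannot leak into
fixtures. Back-translation samples synonymous codons uniformly; no
codon-usage model is applied, as none of the tested logic depends on it.

What the generator does **not** emulate: isotope envelopes and peak
shapes (inputs are already-picked signals), chimeric or frame-shifted
genes, sequencing errors, codon bias, realistic intergenic grammar
(promoters, terminators), or products with heterogeneous dehydration
counts. Passing the recovery suite therefore demonstrates the inference
chain is correct *given* picked signals and clean assemblies; it does not
validate peak picking or assembly quality on real data.

## Problem sizes and determinism

The test and acceptance workloads use 200 random sequences for the ORF
oracle comparison (mostly 60–1200 bp with a 3–5 kb tail), 200 synthetic
precursors for matcher recovery (noiseless and 0.05 Th noise), and 50
seeded loci for full-pipeline recovery — sizes at which the binomial
uncertainty on the recovery rates is a few percent, comfortably inside the
95% floor the noisy condition is held to. Every stochastic step takes an
explicit integer seed; generators restore the caller's RNG state, and
identical seeds reproduce outputs byte for byte.

## Known limitations

* Ring topology (which Cys pairs with which Dha/Dhb) and dehydration
  positions are out of scope; only counts are inferred.
* The transporter call is a Walker-A heuristic, not a homology result.
* The integer-reporting convention is reverse-engineered from one
  published ladder; other instruments/sites may round differently, which
  is why the full-precision value is always carried alongside.
* Inputs are picked (m/z, z) pairs; raw spectra, mzML and isotope-envelope
  fitting are deliberately not handled.
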