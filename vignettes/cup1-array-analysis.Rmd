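---
title: "Characterizing CUP1 tandem arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing CUP1 tandem arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuparray)
```

## The biological problem

Most *Saccharomyces cerevisiae* isolates carry the copper-metallothionein
gene *CUP1* as a head-to-tail tandem array on chromosome VIII, between
*CIC1* and *RSC30*.  Copy number varies widely between strains (one to
about eighteen units) and correlates with copper resistance.  Arrays come
in at least five repeat classes that differ in unit size (about 2.0, 1.8,
1.2, 1.9, and 1.6 kb) because the founding duplication of each lineage
used different breakpoints around the *CUP1* gene.  Two mechanistically
distinct processes shape these arrays:

1. **Genesis**: a single-copy locus becomes a two-copy array.  The
   junction sequences of natural repeats show at most ~3 bp of homology
   between the joined ends — the signature of unequal *nonhomologous
   end-joining* (NHEJ) between two broken replication forks, not of
   homologous recombination.
2. **Resizing**: once two copies exist, *unequal crossover* between
   misaligned sister chromatids (and intrachromatid pop-out or
   single-strand-annealing deletions) changes unit counts rapidly, in
   integral steps.

This package implements the computational side of that analysis —
junction mapping, copy-number estimation, assay prediction, event
simulation, and fluctuation-rate estimation — together with a synthetic
data generator that stands in for the strains themselves.

## Junction mapping

`map_junction()` aligns a junction sequence against the centromere-distal
and centromere-proximal flanking references.  The prefix of the junction
is extended maximally against a substring of the distal reference, the
suffix against the proximal reference.  If the two matched spans overlap,
the overlap is *microhomology* — bases attributable to both flanks; if
they fail to meet, the uncovered middle is an *insertion* attributable to
neither.  Every mappable call satisfies

```
prefix_len + suffix_len − microhomology + insertion_len == junction_len
```

and a nonempty insertion forces zero microhomology (the two cannot
coexist at a single junction under this decomposition).

Numerical choices, all deterministic:

* **Mismatch policy.** Natural flanks differ from the repeats by rare
  SNPs, so matched extensions tolerate *isolated* single-base mismatches
  flanked by at least 5 exact matches on both sides; two mismatches
  within 5 bp terminate the extension.  Setting
  `allow_mismatches = FALSE` makes extensions strictly exact.
* **Anchoring.** A side must contain a run of at least `seed_len = 12`
  exact matches, otherwise the junction is reported *unmappable* (a
  result, not an error).
* **Tie-breaking.** Among equally long prefix matches the one ending
  closest to the distal reference's end wins; symmetrically, suffix
  matches prefer the start closest to the proximal reference's start.
* **Classification.** `classify_junction()` calls a junction
  `"nonhomologous"` when microhomology is at most 3 bp, the threshold
  below which NHEJ is the parsimonious mechanism; longer shared homology
  yields `"homology-mediated"`.

The test suite checks `map_junction()` against an exhaustive brute-force
oracle (enumeration over all reference start positions and candidate
match lengths, with an independently written policy predicate) on
hundreds of generated cases.

## Repeat-unit inference and typing

`infer_unit_length()` scores every candidate period `p` by the fraction
of positions `i` with `seq[i] == seq[i + p]`, returning the smallest
best-scoring period that reaches `match_threshold = 0.95`.  The
threshold sits comfortably above the ~1% per-position mismatch expected
when two copies each carry 0.5% substitution divergence, and far above
the 25% baseline of unrelated sequence.  Candidate periods are limited
to those leaving at least `min_p` bases of self-overlap, so a two-copy
array (whose repeat span is just under twice the unit) is still
callable.  The caller is expected to pass the repeat span, not a whole
chromosome: kilobases of single-copy flank dilute the match fraction
below threshold by design, which is what the no-tandem-structure result
means.

`classify_repeat_type()` assigns a unit length to the nearest of the
five configured exact lengths (1998, 1800, 1200, 1900, 1600 bp) within
`tolerance_bp = 60`; lengths near two bins (possible for the 1998/1900
pair) are explicitly `"ambiguous"` rather than silently resolved.

## Copy number from restriction fragments

*Eco*RI does not cut within any repeat class, so the fragment that
hybridizes to a *CUP1* probe grows by exactly one unit per extra copy:

```
L_frag = L_single + (n − 1) · unit        (predict_fragment)
n = round((L_frag − L_single)/unit) + 1   (copy_number_from_fragment)
```

with `L_single = 5.2` kb for the single-copy locus.

* **Tie rule.** One tabulated strain (an 18.7 kb fragment of 1.8 kb
  repeats) sits exactly on a half-unit boundary: (18.7 − 5.2)/1.8 = 7.5.
  Its tabulated copy number (8) is consistent only with rounding ties
  *down* (`ceiling(q − 1/2)`); round-half-to-even would give 9, and
  flooring would break other rows.  Tie-down is therefore the package's
  declared convention.
* **Per-type single-copy constant.** With the uniform 5.2 kb constant,
  11 of the 13 multi-copy rows of the bundled table are reproduced; the
  two misses are both 1.2 kb-repeat (Type 3) strains, whose computed
  values fall one unit short.  All three Type 3 rows become consistent
  with an effective constant of about 4.4 kb, suggesting that class's
  flanking *Eco*RI geometry differs.  The constant is therefore exposed
  per call (`run_array_analyses(single_copy_kb = c(5.2, 5.2, 4.4, 5.2,
  5.2))`), and the uniform default leaves the two rows as documented
  mismatches rather than guessing unpublished coordinates.
* **Sizing tolerance.** Fragments are accepted down to
  `L_single − 0.5` kb; half a kilobase is the implied precision of gel
  sizing, visible in the spread between replicate strains of the same
  array class.

`copy_number_from_depth()` is the orthogonal estimate: mean depth over
the repeat span divided by median depth over single-copy baselines, as
used by whole-genome sequencing.  The synthetic depth model is
independent per-base Poisson coverage multiplied by the copy number over
the repeat span; rounding the ratio is flagged unreliable below 5x.

## In-silico PCR

`insilico_pcr()` reports every convergent pair of exact primer sites
with a product of at most `max_len` bases (default 3000, a practical
extension limit that also restricts across-junction products to adjacent
copies).  Binding is exact-match because the assays modeled are
presence/absence, not thermodynamic; diverged primer sites therefore do
not bind, which mirrors primer failure rather than hybridization.  Two
assays matter:

* **Outward (array) assay**: primers inside *CUP1* pointing away from
  each other give *no* product on a single-copy locus and an
  `unit − 40` bp product on any array with two or more copies — one
  product class from `n − 1` adjacent-junction site pairs.
* **Flanking assay**: primers in *CIC1* and *RSC30* give a single
  ~2.7 kb product on the single-copy locus, the diagnostic of strains
  with one *CUP1* copy.

## The event simulator

`nhej_duplicate()` realizes array genesis at sequence level: breaks at
`proximal_break` and `distal_break` on sister forks, joined reciprocally
to yield a duplication (with optional junction insertion) and a deletion
product; lengths obey conservation exactly, and annotations are lifted
(clipped at break boundaries, with per-copy truncated *RSC30* copies
named *YHR054C* as in the reference annotation).

`unequal_crossover()` works on unit-count abstractions
(`array_state`) so population-scale simulation stays cheap; any single
event can still be realized at sequence level through the generator.
With offset `k` and boundary `i`, products carry `a$n + k` and
`b$n − k` units; markers are reassigned by unit index and a product can
carry 0, 1, or 2 of them.  `contract_array()` implements pop-out
(excised circle reported) and single-strand annealing.  The test suite
validates the crossover against a token-level oracle by exhaustive
enumeration of small arrays, and conservation of units and markers over
10^4 random events.

`simulate_marker_loss()` emulates a 5-FOA marker-loss screen: events
arise binomially over divisions and act independently on a fresh copy of
the starting array.  The event-size distribution is *uniform over
feasible k* by default — no empirical distribution of unit gains/losses
per event is available, so uniform is the declared, configurable choice
(`k_sampler`), and the observed single-copy fraction of a real screen is
calibration data, never hard-coded.  Note that conditioning on marker
loss makes the size distribution among *observed* events non-uniform
(larger events are more likely to capture the marker), so the expected
single-copy fraction is computed by enumerating the configured model,
which is exactly what the property test does.

## Fluctuation analysis

`simulate_ld_cultures()` grows cultures from `N0 = 10^3` cells (a
typical inoculum) to `N_final = 2 x 10^7` (saturation density scale) by
discrete divisions: every wild-type division mutates with probability
`mu`, mutant lineages double alongside, and the final generation is
partial so total divisions equal `N_final − N0` exactly.  Plating
efficiency and phenotypic lag are taken as perfect — no correction is
applied because none is available.

`lc_median_estimate()` implements the Lea-Coulson method of the median:
the expected mutations per culture `m` solves `r/m − ln m = 1.24` with
`r` the median mutant count, found by root bisection on `log m` over
`m in [10^-6, 10^9]` to relative tolerance 10^-9; the per-division rate
is `m/N_final`.  A zero median is reported as *below detection*, not as
a rate.  The estimator's parameter-recovery behaviour is checked by
simulation: across 200 replicate experiments of 60 cultures at a rate of
1.7 x 10^-5, the median estimate stays within a factor of two of truth.

`composite_rate()` scales a base rate by a screened fraction — e.g. the
rate of reduction to a single *CUP1* copy is the marker-loss rate times
the fraction of screened derivatives with the single-copy PCR signature:
(6/135) x 1.7 x 10^-5 ≈ 7.6 x 10^-7 per division — and propagates a
Clopper-Pearson binomial interval on the fraction.

## Regressions on strain tables

`strain_correlations()` runs the three planned OLS fits on a strain
table: deep-sequencing vs Southern copy number (strains with both),
inhibitory copper concentration vs copy number for diploids, and the
same including haploids.  For the haploid-inclusive fit the one censored
copper value ("<0.1 mM") enters at its bound, 0.1 mM — an explicit,
flagged assumption; the table's censoring flag makes any other treatment
a one-liner for the user.  Ordinary regression (not rank correlation) is
used because R² is the quantity of record.

## The synthetic-data generator

`build_single_locus()` emulates the single-copy *CUP1* locus rather than
reproducing it: a random sequence carrying annotated *CIC1*, a 150 bp
spacer, *RUF5* with an oppositely oriented 61-codon *CUP1* ORF, an ARS
overlapping the *RUF5* 3' end, a 70 bp spacer, and *RSC30*, with
flanking `GAATTC` sites exactly 5.2 kb apart and no internal site.  Gene
lengths are not all published, so they are configuration, chosen to make
all five repeat types' breakpoints realizable and the flanking PCR
product 2.7 kb.

Design choices worth stating:

* **Breakpoint zones.** Proximal breaks sit in the *CIC1*–*RUF5*
  intergenic region (Types 1, 2, 3, 5) or inside *CIC1* (Type 4).
  Distal breaks sit inside *RSC30* for Types 1, 2, 4, 5 and in the
  *RUF5*–*RSC30* intergenic region for Type 3.  With the published
  spacer widths (~150 bp and ~70 bp) and a realistic *RUF5* length, the
  1.8 and 1.6 kb units *cannot* terminate in the 70 bp intergenic
  window, so their distal breaks were placed in the 5'-proximal part of
  *RSC30*; only the 1.2 kb unit fits the intergenic zone.  Exact offsets
  are declared configuration, not a claim about the natural coordinates.
* **Junction conditioning.** Natural junctions show ≤3 bp homology; at a
  random junction the expected homology is below 1 bp but can
  occasionally exceed 3.  The builder deterministically caps the natural
  boundary homology of each type's future junction (and forces the
  Type 1 inserted base to match neither flank), so generated junction
  truth always satisfies the nonhomologous classification it is supposed
  to exemplify.
* **Divergence model.** Substitutions only, at 0.7% over the 600 bp
  proximal flank, 0.4% over the distal flank, and 0.5% within each
  repeat copy independently — the conservation levels observed between
  natural repeat lineages.  No indels are simulated (divergence is
  quantified as percent mismatch); junction tract-length changes are
  instead represented explicitly as homopolymer-expansion insertions in
  `generate_junction_cases()`.  Substitutions that would create a new
  `GAATTC` between the flanking sites are scrubbed so the two-cut digest
  geometry is preserved.
* **Determinism.** Every generator output is byte-identical per
  (seed, configuration); all truth (breaks, homology, inserts, expected
  fragment lengths, event log, mutation counts) is logged.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: real S288c sequence composition (base and
codon bias, repeats in the flanks), indel divergence, mixed-type arrays
(9 of 66 natural multi-copy strains carry more than one repeat type per
array), read-level sequencing error, and hybridization thermodynamics.
Conclusions about the *method's* correctness transfer; conclusions about
its error rates on real reads do not.

## Problem sizes used by the shipped tests

The suite exercises: 500 junction cases against the brute-force oracle;
a 25-strain grid (all five types crossed with n in {2, 3, 7, 14, 18})
plus five single-copy strains through the full pipeline at default
divergence; exhaustive crossover enumeration up to 4-unit arrays and
10^4 random conservation events; 200 replicate fluctuation experiments
of 60 cultures; and 10^5-event marker-loss tallies.  These sizes keep
the whole suite around a minute while leaving every statistical
assertion comfortably inside its sampling error.

## Known limitations

* Exact unit lengths and breakpoint coordinates for Types 2–5 are
  configured approximations (1800/1200/1900/1600 bp); only the 1998 bp
  Type 1 length is exact.
* The Type 3 effective single-copy fragment constant (~4.4 kb) is
  inferred from joint consistency of three table rows, not from
  sequence.
* Primer binding and probe matching are exact-match by default;
  `virtual_digest(probe_mismatch =)` provides hybridization-like
  tolerance, but no melting-temperature model is attempted.
* The marker-loss event-size distribution is a declared default, not an
  empirical law; comparisons of simulated single-copy fractions with
  screen outcomes are exploratory.
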