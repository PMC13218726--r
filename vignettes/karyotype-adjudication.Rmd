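---
title: "Adjudicating discordant chromosome counts between assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjudicating discordant chromosome counts between assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two chromosome-scale assemblies of the same species should report the same
haploid chromosome number. When they do not — say one places its bases in
47 chromosome-scale scaffolds and the other in 49 — either the populations
genuinely differ in karyotype, or at least one assembly has split a real
chromosome into two scaffolds. Splits of this kind are expected precisely
where assembly is hardest: repeat-dense boundaries depress both long-read
mappability and Hi-C alignment, so the scaffolder sees too little linkage
to join two arms that in reality are one chromosome.

`karyocourt` turns the adjudication of such disagreements into an explicit,
testable pipeline. A *breakpoint* is a position where one assembly
represents as two scaffolds what the other represents as one. For each
breakpoint the package asks three questions:

1. **Do the two split scaffolds still touch?** In Hi-C data, fragments of
   one chromosome keep contacting each other even if the assembly separates
   them. The trans contact count \(T_{ij}\) between split scaffolds *i* and
   *j* is normalized by scaffold lengths to a rate
   \(r_{ij} = T_{ij} / (L_i L_j)\) in pairs per Mb², and compared with the
   rates of *all* scaffold pairs of that assembly: the empirical p-value is
   the fraction of genome-wide rates at or above the observed rate. A
   length-matched uninvolved scaffold pair provides a control rate, and the
   within-scaffold rates \(I_i/L_i^2\) (intra pairs above 1 kb separation)
   put the observation in context — a disrupted intra-chromosomal contact
   is expected to stand far above the trans background yet below typical
   within-scaffold rates. Multiple breakpoints in one assembly are also
   tested jointly with a one-tailed Wilcoxon rank-sum test against the
   background.
2. **Does the junction look technically hard?** Read depth in 1 kb bins
   (MAPQ ≥ 10) over the terminal 200 kb of each split scaffold is
   summarized as a fold-change between distal flank and junction core;
   spanning reads (split alignments crossing the junction) are counted;
   and the masked fraction of the junction windows, per collapsed repeat
   class, is compared with the termini of control scaffolds.
3. **What does an outgroup say?** If a related species' assembly carries
   both split scaffolds on a single chromosome, phylogenetic parsimony
   favors the merge.

Verdicts are rule-based and auditable: a significant empirical p merges; a
non-significant p accompanied by a low-mappability coverage drop *and*
repeat enrichment merges (the signal was destroyed by the very feature
that caused the missplit); outgroup collinearity upgrades an otherwise
uncertain case; otherwise the split is kept. Each assembly's
chromosome-scale scaffold count, reduced by its merge verdicts, yields an
adjusted count, and agreement across assemblies yields the consensus
haploid number.

## The synthetic study generator

The deposited sequencing data behind a real adjudication are far too large
to recompute statistics from at desk scale, so the package ships a seeded
generator that emulates the *statistical structure* of such a study and
gives every pipeline stage a ground truth:

* a true genome of K chromosomes with a per-1 kb masked-fraction track
  (Beta-distributed around a baseline, raised inside ±100 kb junction
  neighborhoods);
* derived assemblies produced by cutting chromosomes at planted split
  positions, with an exact invertible liftover;
* Hi-C pairs with a power-law cis decay \(P(s) \propto s^{-\alpha}\)
  truncated to \([s_\text{min}, L]\), a uniform trans background fraction
  β, and per-end mappability loss with probability γ·density;
* Poisson depth tracks with mean \(\lambda (1 - \gamma d)\) per bin,
  halved on the Z chromosome of a Z0 female;
* qPCR Cq replicates with a ±1-cycle noiseless ΔCq.

### Default study conditions

| parameter | default | meaning |
|---|---|---|
| `n_chrom`, `chrom_lengths` | 8; 3–10 Mb | desk-scale genome (~52 Mb); a K = 46, ~5.7 Gb preset exists for smoke runs |
| `alpha` | 1.0 | cis contact-decay exponent; the canonical contact-probability scaling. The data behind the method constrain only its consequences, not the decay law itself, so the textbook value is used |
| `beta` | 0.1 | trans background fraction of pairs |
| `s_min` | 1 kb | minimum cis separation; also the strict intra-pair threshold |
| `n_pairs` | 5 × 10⁵ | emitted pairs per assembly |
| `depth_lambda` | 60 | mean depth per 1 kb bin at full mappability, the scale of a high-coverage HiFi dataset; large enough that median-based fold-changes are not dominated by Poisson integer granularity |
| `gamma` | 0.8 | mappability loss coefficient: a fully masked bin loses 80% of read ends, giving the ~5-fold depth drop a near-saturated junction shows |
| `repeat_base_mean` / `repeat_junction_mean` | 0.67 / 0.72 | masked fractions mirroring the ~68% vs ~72% contrast between ordinary termini and problem junctions; one junction in the default study is planted at 0.999, the nearly-fully-masked regime |
| `sex`, `z_chrom` | ZZ; last chromosome for Z0 | ZZ/Z0 system: a Z0 female shows half depth on Z |

The default two-assembly study mirrors the motivating situation: assembly
A splits one chromosome (K+1 scaffolds), assembly B splits three (K+3),
with the last of B's junctions planted at 0.999 masked density. That
extreme junction is deliberately adversarial: its Hi-C and depth signal
are both degraded, so the pipeline must rescue it through the
coverage + repeat rule or the outgroup, never through the empirical p.

### What the generator does *not* emulate

Real Hi-C libraries have restriction-site structure, distance-dependent
ligation artifacts and matrix-level biases (GC, fragment length) that the
generator omits; depth tracks have waviness beyond Poisson noise; repeat
landscapes are spatially autocorrelated rather than bin-independent; and
real assemblies can disagree through inversions and translocations, not
only splits. Passing tests therefore demonstrate that the statistics are
correctly computed and well calibrated under the stated model — not that
the model captures every failure mode of real assemblies. The alignment
between derived assemblies is exact by construction, so breakpoint
*detection* is exercised for its bookkeeping (partner coverage, junction
placement), not for alignment noise robustness.

## Numerical and design choices

* **Coordinates.** Everything internal is 0-based half-open; conversions
  happen only at format boundaries (RepeatMasker `.out` and SAM are
  1-based). Pair records are kept in the upper-triangle convention
  (earlier scaffold first).
* **Background convention.** The genome-wide background includes the
  breakpoint pairs themselves, so an empirical p is never 0 and is
  conservative; `empirical_pvalue()` simply takes whatever background
  vector the caller assembles, so the self-excluded variant is one
  subset away. Zero-count scaffold pairs are part of the background —
  the background is defined over *all* pairs, and dropping zeros would
  shrink the denominator and deflate p. Each assembly is tested against
  its own scaffold set's background.
* **Rank-sum paths.** Exact null distributions are used whenever
  `n·m ≤ 10⁴` and no ties are present; otherwise midranks with tie
  correction and a continuity-corrected normal approximation. The exact
  path is validated against full enumeration for all n + m ≤ 10.
* **Coverage-fold geometry.** The core is the 50 kb straddling the
  junction; the flank is the *distal* part of the terminal windows,
  beyond 100 kb from the junction. The gap matters: the ±100 kb junction
  neighborhood is repeat-enriched by construction (and plausibly in real
  data), so flanking bins taken immediately next to the core would share
  its depressed depth and hide the drop. Medians make the ratio robust
  to residual repeat bins in the flank.
* **Rescue rule.** The merge-despite-non-significance path requires
  *both* a coverage fold ≥ 2 and repeat enrichment; either alone is too
  common at ordinary termini.
* **Chromosome-scale counting.** Scaffolds jointly holding ≥ 95% of
  assembly bases count as chromosome-scale, extended to every scaffold at
  least as long as the shortest member of that set (so co-equal
  chromosomes are never dropped); unplaced debris is ignored.
* **Control selection.** Nearest length among scaffolds uninvolved in any
  breakpoint, ties toward earlier assembly order. Control repeat windows
  are the termini of both control scaffolds — "correct" scaffold ends.
* **qPCR sign convention.** The published diagnostic rule (ΔCq = A − S,
  positive ⇒ male ZZ) is implemented as stated even though a naive
  copy-number argument for a two-Z male suggests the opposite sign; the
  ΔCq value is always surfaced so users can audit borderline calls, and a
  configurable dead zone ε (default 0) guards against replicate noise
  around zero.
* **Split placement in the generator.** Junction neighborhoods are
  ±100 kb, so two splits of one chromosome must be ≥ 200 kb apart; split
  positions snap to the 1 kb bin grid, which lets depth and density
  tracks lift exactly between coordinate systems.

## Validation strategy and problem sizes

The test suite validates the pipeline in four tiers, all at the default
desk-scale conditions above: (i) counting operations against brute-force
per-record/per-base oracles on random fixtures; (ii) rank-sum p-values
against full enumeration; (iii) calibration — on split-free genomes the
empirical p of random scaffold pairs carries the correct tail mass
(20 simulations × 28 scaffold pairs), and ZZ genomes stay call-free in
100 depth replicates; (iv) power — planted single splits reach p ≤ 0.05
in ≥ 90% of 50 replicates, planted Z0 genomes call exactly Z at half
depth in ≥ 95% of 50, and the full two-assembly pipeline returns the true
K in ≥ 95% of 50 replicates, plus one K = 46 (47 vs 49 scaffolds) smoke
run. These sizes keep the whole suite within a coffee break on one core
while leaving the binomial error on every rate comfortably inside the
asserted margins.

## Known limitations

Breakpoints supported by three or more alignment partners are reported as
complex and excluded from testing. Only split/fusion discordances are
modeled — no inversions, translocations or copy-number changes. The
spanning-read counter needs alignments with supplementary records and
shared query names; the simulated studies carry no read-level alignments,
so their junction evidence reports zero spanning reads, which is also the
expected value at a junction that was never assembled. BAM/CRAM inputs
are out of scope: convert to SAM text or the 7-column tabular form first.
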