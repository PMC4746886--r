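---
title: "The separate-libraries method for Y-linked scaffold detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The separate-libraries method for Y-linked scaffold detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ylinkr)
```

## The problem and the model

Y chromosomes are largely heterochromatic and assemble poorly, so
Y-linked sequence is hard to identify in draft genomes. When a genome
project sequences male and female DNA in *separate libraries*, each read's
library name — and therefore its sex of origin — is carried in its read id.
`ylinkr` exploits this: for every scaffold it tallies the male and female
reads the assembler incorporated, and calls scaffolds assembled exclusively
from male reads candidates for Y linkage.

The statistical content is a single binomial argument. Let `p` be the
genome-wide male-read proportion. Because autosomes dominate the genome, `p`
also estimates the per-chromosome-copy male:female sampling-rate ratio
`r = p/(1-p)`. A scaffold of chromosomal class `c` with per-individual copy
numbers `(m_c, f_c)` — `(2, 2)` autosomal, `(1, 2)` X, `(1, 0)` Y —
accumulates male reads with expected fraction

\[
q_c = \frac{m_c\,r}{m_c\,r + f_c},
\]

i.e. `r/(r+1)` (autosome), `r/(r+2)` (X), and 1 (Y). Under the null that a
scaffold has no male-specific sequence, each of its `n` reads is male
independently with probability `p`, so the chance it is *all-male by
accident* is `p^n`. The method therefore only trusts all-male calls on
scaffolds with at least

\[
n_{\min} = \lceil \log\alpha / \log p \rceil
\]

reads, the smallest `n` with `p^n \le \alpha`.

```{r}
p <- global_read_stats(4227964, 2993635)$p_male # a realized male share of 58.5%
fp_probability(9, p)          # a 9-read scaffold: ~0.008 > 1/200
min_read_threshold(p, 1/200)  # 10 reads push the chance below 1/200
```

### Assumptions

* **Read independence.** Reads are sampled independently given the
  scaffold's class; no clustering by library batch, GC content or read
  length is modelled.
* **Autosome-dominated totals.** `p` is estimated from all retained reads;
  the Y and X contributions perturb it negligibly in a real genome.
  `global_male_fraction(counts, restrict_band = c(lo, hi))` restricts the
  estimate to scaffolds with a central male fraction when that assumption
  needs testing.
* **Per-scaffold error control.** `p^n` is a per-scaffold probability; no
  multiple-testing correction is applied across scaffolds, matching how a
  1-in-200 tolerance is naturally read. The summary instead reports the
  *expected number* of false positives, `sum(p^n)` over retained scaffolds,
  which is the quantity a genome-wide reading would control.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `alpha` | 1/200 | probability | tolerated per-scaffold chance that an autosome-like scaffold is all-male by accident |
| `min_reads` | 11 | reads | scaffolds with `n_total < 11` (i.e. 10 reads or less) are excluded |
| `x_band_halfwidth` | 0.05 | male fraction | half-width of the X flag band around `r/(r+2)` |
| `contaminant identity cutoff` | 95 (strict >) | % identity | bacterial/TE screen for candidate scaffolds; a genome-level screen at exactly 100% is available via `inclusive = TRUE` |
| `min_databases` | 3 | databases | gene-evidence databases required before a candidate gene is worth bench testing |

**The threshold off-by-one.** At `p = 0.585`, ten reads already satisfy
`p^10 ≈ 0.0047 ≤ 1/200`, yet the published filter this package reproduces
excluded scaffolds with ten reads *or less*. `classify_scaffolds()` keeps
`min_reads = 11` as its default for fidelity to that filter, records the
model-derived value (10) in the result's configuration, and emits a message
whenever the two disagree, so the discrepancy is visible rather than
silently resolved either way.

**The X band is a flag, not a call.** Autosomal sampling noise overlaps the
X expectation heavily — with hundreds of reads an autosomal scaffold easily
lands within a few percent of `r/(r+2)` — so `X_band` marks scaffolds worth
cytogenetic follow-up and nothing stronger. The default half-width of 0.05
keeps the flag tight around the analytic expectation.

## Classification and numerical choices

Each scaffold receives exactly one call, in priority order: contaminant,
no reads, low reads, `Y_candidate` (all reads male; `p^n` attached),
`X_band`, `autosome_like`.

* `male_fraction` is undefined (`NA`) for zero-read scaffolds — never 0/0.
* Serialized percentages are formatted to one decimal (`61.0`, `NA`).
* Histogram bins floor the male percentage to an integer, and the 100 bin
  is **reserved** for exactly-all-male scaffolds, so a 99.6%-male scaffold
  can never round into the Y bin.
* "Above 95% identity" in the contaminant screen is a strict `>`; the
  boundary case 95.0 does not flag. The genome-level bacterial screen looks
  for exact 100% matches, where "above" cannot apply, hence the
  `inclusive` switch.
* Unknown read prefixes are a hard error by default: silently misbinned
  reads would corrupt every male fraction downstream. `on_unknown = "skip"`
  drops them but counts what it dropped.
* A read placed on several scaffolds counts once on each (the assembler's
  view of read tracking); duplicate placements within one scaffold are
  collapsed. Whether a read spanning a contig boundary should count once or
  twice per scaffold is not decidable from read tracking alone; counting
  once per scaffold is the convention here.
* Evidence ordering ties are broken lexicographically by scaffold id so
  outputs are deterministic.

## Evidence triage

Candidate scaffolds are screened against homology hit tables (standard
12-column tabular output) from seven databases. Bacterial and
transposable-element databases act purely as contaminant screens. The five
gene-evidence databases feed a tier ranking in which transcript support is
tracked separately as the strongest sign of a real gene: (1) conserved known
gene from RefSeq/NR, (2) conserved hypothetical gene, (3) annotated gene of
the species, (4) unconserved hypothetical gene, (5) discarded annotation.
Candidates hit in at least three gene-evidence databases are flagged
`selected_for_testing`, ordered transcript-first, then by tier.

Two genuinely open design points were settled as follows. Conservation
status (`known` / `conserved_hypothetical` / `unconserved_hypothetical`) is
an **input annotation** of subject sequences: what counts as "conserved" is
a curation judgement, and inferring it from hit descriptions would encode
guesses as behavior. And where RefSeq and NR could disagree on a subject's
status, both databases are treated symmetrically at tiers 1, 2 and 4; the
scaffold takes the best tier among its hits, so a disagreement can only
promote, never demote.

## What the simulator emulates — and what it does not

`synthetic_genome_spec()` / `simulate_counts()` generate the statistical
structure the method assumes: per-scaffold read totals
`Poisson(length × reads_per_bp × w_c)` with class copy-weight
`w_c = (m_c r + f_c)/(2r + 2)` (normalised so `reads_per_bp` is autosomal
depth), male counts `Binomial(n, q_c)`, and optional cross-sex
contamination as independent sex-label flips with rate ε — under which the
chance a true Y scaffold with `n` reads survives as all-male is `(1-ε)^n`,
a closed form the recovery suite tests against.

Defaults were fixed once to mirror a low-coverage Sanger/454 draft genome:
male effort share 0.585 (the realized value in the genome project this
method comes from), `reads_per_bp = 0.01` (about 7 million reads on a
700 Mb assembly), log-uniform scaffold lengths between 1 kb and 100 kb to
mimic the heavy small-scaffold skew of such drafts, and a desk-scale 1000/
60/40 split of A/X/Y scaffolds.

Not modelled: sequences themselves, chimeric assembly (a scaffold mixing Y
and autosomal contigs), GC or length bias in sampling, correlated library
batch effects, or homology hits against real databases (evidence fixtures
are hand-written tables). Passing recovery tests therefore demonstrates the
*statistical* correctness of counting, modelling and classification — not
robustness to assembly artefacts, which in real data are handled by the
contaminant screen and by downstream PCR-style validation outside this
package's scope.

## Problem sizes

The test suite runs in seconds: unit fixtures use tens to hundreds of
scaffolds; the calibration check uses 100,000 simulated autosomal scaffolds
at a fixed nine reads (the regime where the false-positive model bites);
recovery uses 20,000 Y scaffolds per contamination rate; the end-to-end
round trip uses 1,000 scaffolds (~200,000 read-map rows). These sizes give
three-standard-error binomial bands tight enough to detect a miscalibrated
model while keeping the whole suite fast enough to run on every change.

## Known limitations

* The method needs assemblies that retain read tracking; k-mer-based short
  read assemblers discard it. For those, coverage-ratio methods
  (chromosome-quotient style, mapping sexed reads back to the assembly)
  are the appropriate substitute and are out of scope here.
* Sensitivity is bounded by coverage: scaffolds below the read threshold
  are unclassifiable, and in a low-coverage draft that can be most
  scaffolds by count.
* X detection is intrinsically weak (the band overlaps autosomal noise);
  `X_band` is deliberately a flag.
* Identity thresholds are applied per hit; partial masking of a scaffold is
  honored only upstream (the pipeline consumes pre-masked search results).
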