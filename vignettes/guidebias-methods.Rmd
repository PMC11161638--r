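---
title: "Models and methods behind guidebias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind guidebias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the artifact model,
the statistical procedures, what the synthetic-data generator does and does
not emulate, and the choices made where the design was genuinely open. It
states no empirical result that the test suite and `scripts/acceptance.R`
do not themselves compute.

## 1. The artifact model

A pooled CRISPR knockout screen measures, per guide `g` and cell line `c`, a
log fold-change of guide abundance; gene-level dependency scores aggregate
guides. Editing requires homology between the 20-nt protospacer and the
genome plus an NGG PAM immediately 3' of it. A germline SNV inside this
23-bp targeting sequence attenuates cutting in carriers, with a strong
positional structure: PAM-proximal ("seed") mismatches are least tolerated.

The generative model used throughout the package is

```
LFC(g, c) = effect(gene(g), c) * activity(g, c) + N(0, noise_sd^2)
activity(g, c) = prod over mismatching variants v of (1 - w_pos(v) * d(v, c))
```

where `w_pos` in [0, 1] is the positional attenuation weight (1 =
PAM-proximal), and `d` is 1 for homozygous-alternate carriers and
`het_attenuation_factor` for heterozygous carriers. The factor defaults to 1
— presence of the variant is treated as binary, matching the
presence/absence treatment used in the downstream tests — but is exposed for
sensitivity analyses. `effect(gene, c)` is the gene's baseline dependency
(negative = depleted on knockout), plus a per-gene lineage offset, plus any
genuine ancestry-specific effect. Because only carriers lose activity, and
carriers cluster by ancestry whenever the variant's allele frequency is
ancestry-differential, an essential gene with one affected guide out of four
shifts its gene-level mean by `effect * w / 4` in carriers: an apparent
ancestry-associated dependency with *positive* sign (less depletion).

## 2. Synthetic cohorts and what they do not emulate

`simulate_cohort()` draws, from one seed:

* **Reference panel** — per-variant, per-population alternate-allele
  frequencies under the Balding–Nichols model: ancestral
  `p ~ U(0.05, 0.95)`, population frequency
  `Beta(p(1-F)/F, (1-p)(1-F)/F)`, clipped to `[0.001, 0.999]`. A single
  parameter `F` per population controls differentiation; `F = 0` is handled
  exactly (frequencies equal the ancestral ones).
* **Admixed genomes** — each haplotype is a mosaic of ancestry blocks with
  Poisson breakpoints on the centimorgan scale (default rate 0.1/cM, mean
  block 10 cM); block populations are drawn from per-sample admixture
  proportions (default: samples split evenly across populations, 90% own /
  10% other ancestry — a cohort of largely single-ancestry cell lines with
  mild admixture). The painting is discretised to the 0.2 cM analysis
  windows, and alleles are drawn Bernoulli from the painted population's
  panel frequency. Dosage = sum of the two haplotypes.
* **Guide library** — genes at evenly spaced TSSs, 4 guides per gene tiled
  on mixed strands within a 2 kb locus, 20-nt protospacers, NGG PAMs, 23-bp
  targeting intervals clear of chromosome ends.
* **Screen** — the LFC model above; the gene-level matrix is the unweighted
  per-gene mean of guide LFCs.

Artifacts are injected *before* genotypes are drawn: the panel variant
nearest the chosen guide position is relocated into the targeting sequence
at a stated position-from-PAM and given strongly differential frequencies
(default 0.85 in population 1 vs 0.02 elsewhere), so that carrier status is
ancestry-correlated by construction. True ancestry effects are added in
proportion to the number of matching haplotypes at the gene's TSS (half
effect for heterozygous windows).

What the generator deliberately does **not** emulate: linkage
disequilibrium beyond block structure (within a block, sites are
independent given ancestry), recombination hotspots, sequencing error,
indels, copy-number alterations, and the Chronos model of screen dynamics
(gene scores here are guide means). Passing tests therefore demonstrate that
the *pipeline logic* recovers known truth under the stated mechanism — not
that every rate matches real cohorts, whose LD, lineage imbalance and
genotyping error are richer.

## 3. Local ancestry

Windows tile each chromosome greedily left-to-right at a minimum genetic
span of 0.2 cM; the last window per chromosome absorbs the remainder, and
membership is defined on the cM scale. Per window and sample, the classifier
scores every unordered population pair `(a, b)` by the naive-Bayes
log-likelihood of unphased dosages (one Bernoulli allele from each
population; sites independent given ancestry) and takes the argmax. This
replaces a conditional-random-field / random-forest local-ancestry engine on
purpose: the downstream analyses need only window labels, the classifier is
exactly testable against the simulated painting, and it requires no phasing.
Its known weaknesses — no information sharing across windows, sensitivity to
sparse windows — are mitigated by the window-size floor and by copying the
nearest assigned window (left neighbour preferred) into windows with no
informative variants.

Numerical conventions: ties are broken towards homozygous pairs, then
lexicographic label order (deterministic); the per-window margin (best minus
second-best log-likelihood) is reported. Global fractions average per-
chromosome haplotype-window fractions with equal chromosome weights; the
predominance rule is strict (`> 0.8`, so exactly 80% is Admixed). At a
heterozygous window, the single-population label of a locus is resolved
towards the pair member with the higher global fraction in that sample, then
lexicographically — the "maximal ancestry fraction" rule is ambiguous at
heterozygous blocks, and this resolution is isolated in
`ancestry_at_locus()` so it can be swapped without touching anything else.

## 4. Association, power, and multiple testing

Each ancestry group is tested one-vs-rest per gene: OLS of dependency on the
group indicator with lineage fixed-effect dummies (the smallest lineage is
the dropped pivot), two-sided coefficient t-test, Benjamini–Hochberg FDR
across genes *within the group*. Whether the FDR family should be per-group
or pooled is not dictated by anything in the data; per-group was chosen
because the per-group discovery counts are the quantity of interest, and the
choice is confined to `test_ancestry_dependency()`. Genes whose design is
singular (group confounded with lineage) are reported with missing p and
excluded from the family.

The power simulation draws group scores `N(delta, noise_sd^2)` against a
complement at `N(0, noise_sd^2)`, with lineage labels drawn once per group
from the supplied frequencies, and fits the same lineage-adjusted
regression. Noise is drawn once per replicate and shared across the effect
grid (common random numbers), which makes estimated power monotone in the
effect up to Monte-Carlo error and lets sample sizes be compared on the same
draws. The score SD defaults to 1 — the scale of the dependency scores is
not otherwise pinned down, and this default is flagged for sensitivity
analysis rather than asserted as realistic.

The d-QTL scan regresses dependency on additive dosage (plus lineage) for
every variant passing a strict `MAF > 1%` filter, and corrects per gene with
Benjamini–Yekutieli — the conservative choice appropriate for the strong
dependence among genome-wide variants; the BH q-value is also reported so
the `BY ≥ BH ≥ p` ordering can be asserted on every run. The marker is the
significant variant with lowest BY q (ties: lower raw p, then genomic
order). The eQTL test deliberately switches to presence/absence coding
(dosage ≥ 1), mirroring how expression effects of a disruptive allele are
screened; LD is composite `r²` of dosages (no phasing). The threshold for
"in LD with an in-guide variant" is `r² ≥ 0.8`, configurable, as no
canonical value exists.

Implementation note: the scan uses Frisch–Waugh–Lovell residualisation
against the lineage design, which is algebraically identical to the full
per-variant OLS fit (asserted against `lm()` in the tests) and vectorises
over variants. Variants with missing dosages fall back to casewise fits.

## 5. Mismatch mapping conventions

The targeting interval is the PAM plus the 20 nt 5' of it on the guide
strand: on '+', protospacer `[s, s+20)` and PAM `[s+20, s+23)`; on '−', the
PAM reads CCN on the reference at `[s, s+3)` (N at `s+2`) and the
protospacer is `[s+3, s+23)`. Position-from-PAM is 1 for the PAM-adjacent
protospacer base through 20 at the PAM-distal end; PAM bases are 0 (N), −1
and −2 (the two Gs). Records at the degenerate N position are *kept* in the
mismatch table but excluded from "affected" counts by default, since an
N-site SNV cannot disrupt NGG recognition; `include_pam_n = TRUE` restores
the literal 23-bp definition. Zygosity is recorded but presence is
zygosity-agnostic in all counting.

Positional effects pool (guide, sample) pairs with a mismatch at a given
position against pairs on the same guides with no mismatch at all, and
report the mean LFC difference with both Welch-t and Wilcoxon p-values; the
headline test is configurable because the two are legitimate alternatives
for this comparison (the pooling is at pair level, which keeps the control
distribution guide-matched). The Fisher enrichment test classifies guides as
"differentially depleted" between two ancestry groups at a configurable
`|ΔLFC| > 0.25` — a round value on the LFC scale chosen once; no canonical
cutoff exists.

## 6. Correction and design

Correction excludes a mismatched guide only for carrier cell lines and
re-aggregates (mean by default, median available); cells without mismatches
reproduce the uncorrected score bitwise, and a cell with all guides excluded
becomes missing rather than imputed. The pre/post comparison is a paired
two-sided t-test per gene on per-sample differences with BH across genes —
the simplest test consistent with the matched structure; it is a package
choice, not an external prescription.

Library design ranks candidates by supplied on-target score and drops those
carrying any targeting-interval variant with overall frequency above 1%, or
whose Hardy–Weinberg carrier rate (`1 − Π(1−f_v)²`, independence across a
guide's variants — individual genotypes are unavailable at design time) in
AFR exceeds 2.5× the non-AFR rate; the ratio rule is waived below an AFR
carrier rate of 1e-4 to avoid flagging vanishing rates. When fewer than four
candidates survive, the best excluded ones fill the set and the gene is
flagged `fallback_used` — a fixed library size was preferred to emitting
short gene sets. The same 1% knob serves both design filtering and
benchmarking; both uses are documented on `design_library()`.

## 7. Validation scenarios and problem sizes

The acceptance-level tests run on sizes chosen to give the mechanisms clear
expression while keeping the suite quick; they are stated here as the
package's validation design:

* mapping oracle: 1,000 guides × 10,000 SNVs on a 60 kb two-chromosome
  reference, checked record-for-record against sequence reconstruction;
* local ancestry: 3 populations at Fst 0.1, 50 samples, 10 windows of
  ~250 variants (recovery ≥ 90%);
* power: the screened cohort's group sizes (26/6/203/373/4), 1000
  replicates, effects 0–0.5;
* d-QTL recovery: 50 cohorts of 150 lines, one strongly essential gene
  (effect −3) with a fully attenuating seed-region SNV among ~1,000
  MAF-filtered variants;
* artifact correction: 10 cohorts of 200 lines, 50 genes, 10 artifact genes
  (effect −2, full attenuation, differential frequencies 0.85/0.02), no
  true effects — plus a cohort with genuine AFR-specific effects that must
  survive correction;
* positional gradient: 120 lines, 60 artifact genes spanning positions
  1–20 at three guides per position, weights decaying linearly 1 → 0.05,
  guide noise 0.5;
* design: 500 genes × 8 scored candidates with seeded variant frequencies.

Guide-level noise defaults to SD 1; the targeted-recovery scenarios use
0.4–0.5, reflecting that guide-level replicate noise is tighter than the
cross-line spread of gene-level scores. Baseline gene effects default to
`N(−1, 0.5²)`; artifact genes in the recovery scenarios are set to −2 or −3
(strongly essential genes are exactly the ones whose false negatives
matter).

## 8. Known limitations

* The ancestry classifier ignores between-window correlation; on real,
  finely admixed genomes a CRF-based engine will be more accurate,
  especially at low marker density.
* Gene aggregation is a guide mean, not a screen-dynamics model; corrected
  scores on real data should be recomputed with the screen's own
  gene-scoring pipeline after guide exclusion.
* Composite LD without phasing underestimates haplotype `r²` when
  genotypes are far from Hardy–Weinberg equilibrium.
* The generator's independence of sites within a block means in-guide
  variants have no LD "shadow"; real d-QTL scans will see more proxy
  associations near the causal variant than the synthetic ones do.
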