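---
title: "Pathway association in nuclear families: model, permutation null, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway association in nuclear families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fampath)
```

## The problem

Single-SNP association tests in genome-wide studies lose power against the
multiple-testing threshold when a disease is driven by many small effects
scattered over a pathway. Competitive gene-set (pathway) tests recover some
of that power by asking whether the genes of a pathway carry systematically
larger association signals than the rest of the genome. Most such tools
assume unrelated cases and controls, or at best parent–child trios. Many
real designs — autism sibships, late-onset disease with dead or
ungenotyped parents — are nuclear families with several affected and
unaffected siblings and frequently missing parents. `fampath` implements a
pathway test built for exactly those data.

## The statistic

**Per SNP.** For each nuclear family the pedigree disequilibrium test (PDT)
summand is

$$D_i = \sum_{\text{triads}} \big(2c - f - m\big) \;+\;
        \sum_{\text{DSPs}} \big(x_{\text{aff}} - x_{\text{unaff}}\big),$$

where dosages count copies of the reference-labelled allele
(`allele_b`, the lexicographically larger one), a *triad* is two genotyped
parents plus a genotyped affected offspring (transmitted minus
untransmitted allele copies), and a *discordant sib pair* (DSP) is one
genotyped affected and one genotyped unaffected sibling; all affected ×
unaffected pairs are scored. The per-SNP statistic is the sum-PDT form

$$Z = \frac{\sum_i D_i}{\sqrt{\sum_i D_i^2}},$$

which is asymptotically standard normal under the null of no association
(verified empirically by the test suite). Families without genotyped parent
pairs simply contribute no triads; their DSPs remain, which is what makes
the method usable when parents are missing.

**Per gene.** SNPs are assigned to a gene when they fall within the gene
body ± `window_kb` kilobases (default 5 kb; 20 kb is the common alternative
for regulatory margins). Each gene's score is the largest $z^2$ over its
informative SNPs — the best-SNP reduction corresponding to the minimum
single-SNP p-value. $z^2$ rather than $|z|$ keeps the score on the familiar
1-df chi-square scale of trio-based transmission tests; both are available
(`score = "abs"`), give identical rankings, and differ only in the
enrichment-score values.

**Per pathway.** With $N$ ranked genes (scores $r_j$, descending), a
pathway $P$ containing $N_H$ of them, and $N_R = \sum_{G_j \in P} r_j^w$,
the enrichment score is the running maximum of the weighted
Kolmogorov–Smirnov-like sum

$$ES(P) = \max_{1 \le i \le N} \left[
   \sum_{G_j \in P,\, j \le i} \frac{r_j^w}{N_R}
 - \sum_{G_j \notin P,\, j \le i} \frac{1}{N - N_H} \right],$$

with default weight $w = 1$. Note that this is the maximum of the *signed*
running sum, not of its absolute value: the running sum telescopes to zero
at $i = N$, so $ES \ge 0$ always, and a pathway *depleted* of signal
receives an ES near zero and a large p-value. Detecting depletion is a
documented non-goal of this statistic.

## The permutation null

Exchanging the transmitted and untransmitted parental alleles within a
family negates that family's $D_i$ — a fact the test suite verifies by
explicitly reconstructing untransmitted genotypes on trios and comparing.
So the null distribution is generated without touching genotypes: draw one
sign $s_{f,c} \in \{-1,+1\}$ per family $f$ per chromosome $c$ (all SNPs of
a chromosome flip together, preserving LD among them), flip the retained
family × SNP matrix of $D$ values, and recompute $Z$, the gene scores, the
ranking and every pathway's ES. The denominator $\sqrt{\sum_i D_i^2}$ is
sign-invariant and precomputed. Gene–SNP assignments, the ranked gene set,
and pathway memberships are frozen across permutations, so large genes or
pathways cannot bias the null.

With $K$ permutations the p-value is
$p = \big(1 + \#\{k : ES_k \ge ES_{\text{obs}}\}\big)/(K+1)$: ties count
against significance and $p > 0$ always. The strict exceedance proportion
$\#\{ES_k > ES_{\text{obs}}\}/K$ is available as `tie_rule = "gt"`.
Family-wise adjusted p-values use the Westfall–Young max-statistic over
per-pathway *normalised* ES values, $(ES - \bar{ES}_k)/\mathrm{sd}_k$,
which makes pathways of different sizes comparable before taking the
maximum; FDR q-values are Benjamini–Hochberg on the raw permutation
p-values. The permutation statistics give no exact finite-sample FDR, so
both adjustments are this package's constructions and are labelled as such.

Each permutation owns a seed derived from the run seed by permutation
index, and the sign stream is a splitmix64 generator seeded per
permutation. Results are therefore bit-identical for any `threads` value
and for any row order of the input files (families are assigned signs in
sorted-family-ID order). The inner loop — sign draw, $Z$ recomputation,
gene-score maxima, ranking, running sums — is compiled C++.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window_kb` | 5 | SNP-to-gene assignment margin, kb each side |
| `K` | 2000 | permutations; p-value resolution is $1/(K+1)$ |
| `w` | 1 | gene-score weight exponent in the running sum |
| `score` | `"squared"` | gene score $z^2$ (or `"abs"` for $|z|$) |
| `tie_rule` | `"ge"` | conservative add-one p-value (or `"gt"`) |
| `sign_by` | `"chromosome"` | sign granularity; `"genome"` flips whole families |
| `min_genes`, `max_genes` | 2, $\infty$ | admissible mapped pathway size; always clipped to $N-1$ |

`sign_by = "genome"` only matters for correlation *across* chromosomes
within a pathway — genes are intrachromosomal, so single-gene scores are
unaffected — and is provided for sensitivity analysis.

## The synthetic-family generator

`sim_config()` / `simulate_families()` emulate the simulation design
standard for this class of methods: parental haplotypes from a first-order
Markov model (per-SNP minor-allele frequency drawn from `maf_range`,
adjacent-indicator correlation `rho = 0.6`), children receiving one
unrecombined haplotype per parent, sibling affection from an additive
logistic model $\text{logit}\,P(\text{aff}) = \text{logit}(\pi_0) + \sum_c
x_c \ln OR_c$, ascertainment on at least one affected sibling, and optional
masking of both parents' genotypes in a fraction of families. Defaults are
500 families of two parents and three siblings, a 24-gene target pathway,
causal variants (when requested) at MAF 0.2 with odds ratios of 1.2–1.3 —
at a reduced marker scale of 10 chromosomes × 100 SNPs, 50 genes and 5
pathways so that replicated studies run in minutes. Baseline prevalence
$\pi_0$ defaults to 0.1, a typical complex-disease figure that keeps
ascertainment rejection rates moderate; it is a free knob.

What the generator deliberately does **not** emulate: real LD block
structure (the Markov chain has geometric-decay correlation, no hotspots),
within-chromosome recombination in gametes (chromosome segments are short),
population structure, genotyping error, and realistic gene length
variation. Calibration results on these data therefore demonstrate the
permutation machinery — correct type I error under an LD-structured null
with ascertained families and missing parents — not robustness to every
artefact of real genotype data.

## Numerical and degenerate-input choices

* Monomorphic or otherwise uninformative SNPs ($\sum D_i^2 = 0$) get
  $z = 0$, are flagged, and are excluded from gene-score maxima; genes with
  no informative SNP are dropped from the ranking before $N$ is fixed.
* Mendelian-inconsistent triad dosage patterns contribute 0 and are
  tallied, not fatal — real ped files contain genotyping errors. Triads
  require *both* parents genotyped; single-parent transmissions are never
  scored, avoiding untestable reconstruction of the missing parent.
* Ranking ties are broken by gene symbol (ascending), so results are
  deterministic; best-SNP ties within a gene go to the smallest SNP index.
* Pathways are skipped — with a logged reason, never silently — when their
  mapped size leaves the admissible range or when $N_R = 0$ in the observed
  ranking. If a permutation drives $N_R$ to zero the hit increments vanish
  and that permutation's ES is the all-miss running maximum.
* A pathway's adjusted p-value falls back to 1 if its permuted ES has zero
  variance (degenerate normalisation).
* Half-missing ped genotype records (`A 0`) are treated as missing with a
  logged count.

## Problem sizes used in the bundled studies

The packaged calibration studies run 300 null replicates (and 100
replicates per power point) of 200 families × 500 SNPs with $K = 500$,
sizes chosen so a full calibration completes in a few minutes on one core
while keeping the binomial uncertainty of an 0.05-level rejection rate
around ±0.03. The same machinery scales to GWAS-chip panels; $K = 2000$ is
the recommended analysis default and larger $K$ is needed only when
p-values far below $10^{-3}$ must be resolved.

## Worked example

```{r example}
sim <- simulate_families(sim_config(
  n_families = 100, n_sibs = 3, n_chrom = 5, snps_per_chrom = 40,
  n_genes = 20, target_genes = 8, n_pathways = 3,
  n_causal = 4, causal_or = 1.5, missing_parent_fraction = 0.5, seed = 42))

fit <- pathway_pdt(sim$ped, sim$genes, sim$pathways,
                   K = 999, seed = 1, quiet = TRUE)
tidy(fit)
glance(fit)
```

```{r plots, fig.width = 6, fig.height = 3}
autoplot(fit)
plot_running_sum(fit, "target")
```

## Known limitations

Extended multi-generational pedigrees are rejected rather than decomposed;
X-chromosome SNPs are processed with the autosomal formula (with a
warning); depleted pathways are not detectable by construction of the
signed running maximum; and the permutation FDR is the BH procedure on
permutation p-values, not a permutation-estimated FDR.
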