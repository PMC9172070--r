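---
title: "Local network entropy: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local network entropy: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnescore)
```

## The model and its assumptions

Disease progression is treated as a dynamical system approaching a
bifurcation. Near the tipping point a small subnetwork (the dynamic network
biomarker, DNB) loses stability: fluctuations of its genes grow, its genes
co-fluctuate more strongly with one another, and their coupling to the rest
of the network weakens. Local network entropy (LNE) turns this into a
single-sample statistic:

* A template network (typically a STRING PPI at confidence ≥ 0.8) fixes,
  for every gene $g^k$, a local neighborhood $N^k$ of its $M_k$ first-order
  neighbors.
* Over an expression matrix, neighbor $i$ gets weight
  $p_i = |r_i| / \sum_j |r_j|$ where $r_i$ is the Pearson correlation
  between neighbor and center across samples, and the local entropy is
  $E(k) = -\frac{1}{M_k}\sum_i p_i \ln p_i$.
* For one case sample, $E^{n}(k)$ is computed from the $n$ reference
  samples and $E^{n+1}(k)$ after appending the case column. The per-gene
  score is $\Delta E^k \cdot \Delta SD_k$, the product of the absolute
  entropy change and the absolute change of the center gene's standard
  deviation, and the sample's global score is the mean over all $Q$ network
  genes.

Assumptions worth keeping in mind: correlations are linear (Pearson); the
reference cohort is homogeneous enough that its correlation structure is a
meaningful baseline; one sample perturbs correlations only $O(1/n)$, so the
*scale* of all scores depends on $n$ — scores are comparable within one
cohort scored against one reference set, not across cohorts.

## Tunable parameters

| Parameter | Default | Meaning / why |
|---|---|---|
| `threshold` (network) | 0.8 | STRING confidence cut; 0.800 on the unit scale equals 800 on STRING's 0–1000 integer scale (`score_scale = "string-1000"`). |
| `fraction` (LNE genes) | 0.05 | Top 5% of genes per sample by $\Delta E^k \Delta SD_k$; $\lceil 0.05\,Q\rceil$ genes, ties broken lexicographically. |
| `dnb_min_fraction` | 0.5 | Fraction of critical-stage samples whose sets must contain a gene for DNB membership (see "Common genes" below). |
| `method` (transition) | `"peak"` | Stage of maximal mean score; `"max_increase"` takes the largest step instead. Ties go to the earlier stage — the earliest warning. |
| `alpha` | 0.05 | Log-rank significance for O-/P-LNE calls. |
| `de_alpha`, `lne_alpha` | 0.05 | Dark gene thresholds: BH-adjusted rank-sum p ≥ `de_alpha` for expression (no differential expression) and < `lne_alpha` for the LNE score shift. |
| `log_transform` | off | Optional `log2(x+1)` before any correlation; useful for raw RNA-seq quantifications. Whether to pre-transform is a data question the method itself does not settle. |

## Numerical choices

* **Logarithm base.** Natural log. Any other base rescales every entropy,
  hence every score, by one constant: rankings, stage curves and the called
  transition are unchanged.
* **Zero-variance genes.** Pearson correlation is undefined for a constant
  vector; it is defined here as 0 (no evidence of association). If *every*
  neighbor weight of a gene is 0, the weight vector falls back to uniform,
  making the entropy maximal rather than undefined — "no correlation
  structure" is treated as maximal disorder. An all-constant study therefore
  yields a global score of exactly 0 (identical entropies before and after
  mixing, zero $\Delta SD$).
* **Standard deviation flavor.** Sample SD ($n-1$ denominator) for both
  $SD^n$ and $SD^{n+1}$, consistent with Pearson's internal convention.
* **Missing values.** Rejected with an explicit gene list, not imputed.
* **Determinism.** Neighbors are sorted lexicographically; gene ties at the
  top-5% cutoff break lexicographically; every simulator function seeds its
  own RNG from the config, so identical configs give byte-identical outputs.
* **$Q$** is the number of genes in the expression-restricted, pruned
  network — exactly the genes with a defined local entropy.
* **Stage labels** are ordered clinically (I < II < IIIA < IIIB < IV), so
  the order is supplied by the caller, never inferred lexicographically.
* The per-sample engine standardizes gene rows once and evaluates all edge
  correlations as cross-products, grouped per center gene; tests verify
  agreement with a straight-line loop implementation to 1e−12.

## The synthetic world

`sim_config()` states the world the package is tested in: 100 genes, a
10-gene planted module, four stages with the critical one third, 50
reference samples, 20 case samples per stage. At the critical stage the
module's pairwise correlation rises 0.2 → 0.7, its SD rises 1 → 2, and its
correlation with a 10-gene boundary set falls 0.3 → 0.05; by default the
post-critical stage returns to baseline (the characteristic rise-then-fall
curve), or plateaus if configured.

Samples are multivariate normal via a single-factor construction: module
genes load $\sqrt{\rho_{in}}$ on a shared factor, boundary genes load
$\rho_{out}/\sqrt{\rho_{in}}$. This is exchangeable within the module and
positive semi-definite by construction; it requires
$\rho_{out}^2 \le \rho_{in}$, which the constructor enforces. (Realizing
$\rho_{out}$ as a dense module-to-everything correlation block is *not*
PSD at these effect sizes — that is why only a boundary set carries the
outside correlation.)

The background graph is wired at mean degree ~12, typical of STRING
subnetworks at 0.8 confidence. This matters: local entropies of very
low-degree genes are noisy, and an unrealistically sparse background (mean
degree ~3–6) buries the planted signal under background-gene noise.

Two background genes are planted prognostic biomarkers. Per case sample,
independent Bernoulli(0.5) indicators decide whether the sample expresses
the optimistic/pessimistic gene aberrantly (a 3-SD shift — a strong but
realistic outlier expression that reliably pushes the gene into that
sample's top-5% set). Survival is exponential with baseline median 24
(arbitrary units); the hazard is multiplied by the configured ratio
(default 4) for samples at/after the critical stage and for samples
positive for the pessimistic gene, and divided by it for the optimistic
gene. Positivity is the latent carrier indicator by default, or realized
set membership when the computed LNE gene sets are passed in — the latter
is what the biomarker-recovery tests use, because it makes the planted
truth exactly the stratification the classifier is supposed to detect.

**What a green test does and does not establish.** The generator realizes
the three DNB hallmarks with Gaussian marginals, a single exchangeable
module, and clean stage labels. It does not emulate RNA-seq count noise,
library-size effects, reference-cohort heterogeneity, batch structure, or
multiple interacting modules. Green tests establish that the statistics and
the pipeline do what they claim on data that contains the stated signal;
they do not establish clinical performance.

## Design decisions made where the design was open

* **Transition calling.** The published analyses identify the transition
  visually as an abrupt rise/peak of the stage curve. Both readings are
  implemented; `"peak"` is the default since in every described cohort the
  score maximum coincides with the called critical stage. The transition
  stage itself goes into the "before" survival group (stage I–III vs IV for
  a stage-III transition).
* **Common genes (DNB) at desk scale.** With genome-scale panels
  (Q ≈ 15,000, 5% sets of ~750 genes) a strict intersection across
  critical-stage samples is workable. At the package's testable scale
  (Q = 100, sets of 5, 20 samples) it is structurally empty: each module
  gene's per-sample score depends on that sample's own draw, so even a
  strongly perturbed gene has ≥ 20% probability of a quiet draw in any one
  sample, and $0.8^{20} \approx 0.01$ of surviving all twenty. The
  `common_lne_genes()` default remains the strict intersection
  (`min_fraction = 1`); the pipeline default is the majority rule
  (`dnb_min_fraction = 0.5`), which recovers module genes well above a
  size-matched permutation baseline in the bundled world.
* **Biomarker calls.** Membership of a gene in a sample's LNE set splits
  samples into with/without; the log-rank test decides significance and the
  restricted-mean survival of the two Kaplan–Meier curves decides the
  direction. Groups smaller than 3 are never called: the asymptotic
  chi-square is meaningless there.
* **Differential expression proxy.** Dark-gene screening uses a two-sided
  Wilcoxon rank-sum test with Benjamini–Hochberg correction rather than a
  count-model DE method; the DE backend is intentionally replaceable. Note
  the rank-sum test is a *location* test: genes whose variance (not mean)
  changes still count as non-differential, which is precisely what makes
  the planted module's genes detectable as dark genes.
* **Survival machinery.** Kaplan–Meier and the two-group log-rank test are
  implemented in the package (events precede censorings at ties; p-values
  from the asymptotic chi-square with 1 df); the `survival` package is used
  only as an independent oracle in the test suite.
* **Identifier mapping** (protein ↔ gene symbol) is out of scope; inputs
  must arrive pre-mapped to a common symbol space.

## Known limitations

* Scores scale with the reference cohort size $n$ (single-sample
  perturbations are $O(1/n)$); compare scores only within one analysis.
* The transition call has no uncertainty attached — no bootstrap bands on
  the stage curve, by design.
* Asymptotic log-rank p-values are slightly anti-conservative at small
  group sizes (measured type-I error ≈ 0.06 at n = 40 per group).
* Strict-intersection DNB extraction needs genome-scale panels; use the
  majority rule otherwise (see above).
* The entropy is computed on first-order neighborhoods only; genes whose
  perturbation is visible only at second order are invisible to the score.
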