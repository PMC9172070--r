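# lnescore

Single-sample detection of critical transition (pre-disease) states on a
protein–protein interaction network, via **local network entropy (LNE)**.

## The problem

Many diseases — tumor progression in particular — do not deteriorate
smoothly: there is a *tipping point* at which the system shifts abruptly
from a relatively normal state into an almost irreversible disease state.
The stage just before that shift (the critical or pre-disease state) is
where intervention still helps, but it is hard to see in expression levels
alone: means barely move while the *correlation structure* of a small group
of genes (a dynamic network biomarker, DNB) destabilizes — intra-group
correlation and variance surge, correlation with the rest of the network
drops. Classical DNB statistics need many samples per time point; clinical
reality often offers one sample per patient. LNE scores a **single case
sample** against a cohort of reference samples, so each patient gets their
own early-warning score.

## The statistic

Given an undirected gene network, for every gene *k* with first-order
neighbors *g<sub>1</sub> … g<sub>M</sub>* the local network entropy over an
expression matrix is

> E(k) = −(1/M) Σ<sub>i</sub> p<sub>i</sub> ln p<sub>i</sub>,  with
> p<sub>i</sub> = |PCC(g<sub>i</sub>, g<sub>k</sub>)| / Σ<sub>j</sub> |PCC(g<sub>j</sub>, g<sub>k</sub>)|

where PCC is the Pearson correlation across samples. For one case sample
the package computes E<sup>n</sup>(k) from the n reference samples and
E<sup>n+1</sup>(k) from the reference cohort with the case sample mixed in,
and combines

> ΔE<sup>k</sup> = |E<sup>n+1</sup>(k) − E<sup>n</sup>(k)|,
> ΔSD(k) = |SD<sup>n</sup>(k) − SD<sup>n+1</sup>(k)|,
> **global LNE score** ΔE = (1/Q) Σ<sub>k</sub> ΔE<sup>k</sup> · ΔSD(k)

over all Q network genes. Per clinical stage, the mean score of its samples
forms a stage curve; the stage where the curve peaks (or rises most) is the
called transition. The top 5% of genes per sample by ΔE<sup>k</sup>·ΔSD are
its *LNE genes*; genes shared by the critical-stage samples form the DNB;
LNE genes whose presence in a sample's set stratifies Kaplan–Meier survival
are *optimistic* (O-LNE, longer survival) or *pessimistic* (P-LNE, shorter
survival) prognostic biomarkers. *Dark genes* show no differential
expression but differential LNE — network-level signal invisible to
expression tests.

## Worked example (bundled simulator)

The package ships a generator that plants a 10-gene DNB module whose
intra-module correlation (0.2 → 0.7) and SD (1 → 2) rise, and whose outside
correlation falls (0.3 → 0.05), at stage III of four stages:

```r
library(lnescore)
cfg    <- sim_config(seed = 1)
sim    <- simulate_study(cfg)        # 100 genes, 50 refs, 20 cases/stage
net    <- simulate_network(cfg)      # gene_network: 100 nodes, 495 edges
scores <- score_cohort(sim$study, net)
(curve <- stage_curve(scores, cfg$stages))
#   stage  n   mean_score
# 1     I 20 4.843106e-05
# 2    II 20 4.668981e-05
# 3   III 20 7.217556e-05
# 4    IV 20 5.102605e-05
call_transition(curve)               # "III"  <- the planted critical stage
```

The mean score is flat at baseline, jumps ~50% at the planted critical
stage, and relaxes afterwards — the characteristic rise-then-fall of an
early-warning signal. Downstream:

```r
sets <- lapply(scores, lne_genes)                       # top-5% per sample
common_lne_genes(sets, samples_at = "III",
                 min_fraction = 0.5)                    # "MOD04" (a planted module gene)
clin <- simulate_survival(sim$truth, case_samples(sim$study), cfg, sets = sets)
bm   <- classify_biomarkers(sets, clin)
bm[bm$gene %in% c("OPT1", "PES1"), c("gene", "class", "logrank_p", "direction")]
#  gene class logrank_p direction
#  OPT1 O-LNE   8.3e-08    longer
#  PES1 P-LNE   1.7e-02   shorter
```

Both planted prognostic biomarkers are recovered with the right direction.
The whole pipeline also runs from files:

```sh
Rscript exec/lne simulate --outdir demo --seed 1
# write a config (flat key: value) pointing at demo/, then:
Rscript exec/lne full --config demo.cfg
```

which writes `scores.tsv`, `stage_curve.tsv`, `transition.tsv`,
`dnb_genes.txt`, `dnb.sif`/`dnb.graphml` (Cytoscape-ready), `biomarkers.tsv`,
`dark_genes.txt` and a JSON run manifest.

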