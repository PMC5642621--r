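# pancnet

Network-based candidate gene discovery for pancreatic cancer — an R
package plus a scripted analysis that integrates gene co-expression with
protein-protein interactions (PPI), extracts a seed-gene-connecting
subnetwork by bounded random walks, ranks the recruited *linker* genes,
and validates the resulting multi-gene signature against survival.

It is aimed at computational biologists who have (a) an expression
matrix for a tumor cohort, (b) a STRING-style PPI edge list, (c) a
curated list of known disease genes ("seeds"), and optionally (d) a
clinical table with overall survival — and who want a reproducible,
tested implementation of the seed → subnetwork → candidate workflow.

## The method

1. **Common network.** Co-expression adjacency $a_{gh} = |r_{gh}|^\beta$
   (Pearson, pairwise-complete; default $\beta = 1$, edge kept when
   $a \ge 0.5$) is intersected with the PPI edge set; common edges carry
   the co-expression weight.
2. **Limited k-walks.** For each seed $s$, a Markov random walk with
   $P(i\to j) = w_{ij}/\sum_k w_{ik}$ starts at $s$ and is absorbed at
   any other seed within $L$ steps (default 50). Edge relevance is the
   expected number of traversals conditioned on absorption, computed by
   forward/backward recursions and averaged over start seeds:
   $E_s(i,j) = Z_s^{-1}\sum_{l=0}^{L-1} \alpha_l(i) P(i\to j)
   \beta_{L-l-1}(j) + \alpha_l(j) P(j\to i) \beta_{L-l-1}(i)$ with
   $Z_s = \beta_L(s)$. Edges enter the subnetwork in decreasing
   relevance order until the seeds are connected. Non-seed nodes
   recruited this way are the *linker genes*.
3. **Ranking score.** For a linker $g$,
   $RS(g) = \sum_{(g,h)} m_h\, w_{gh}$ with $m_h = 2$ when $h$ is a
   seed, else 1. Candidates are linkers with $RS > 1$ (strict).
4. **Validation.** Seed-candidate Pearson correlations (t-reference
   p-values, BH-adjusted), Welch t-tests against clinical covariates,
   and a median split of the per-sample candidate expression sum tested
   by the log-rank test (score test of a Cox proportional-hazards fit).

The package ships the published reference tables of the study it
re-implements (52 seed genes; 82 linker genes with their printed ranking
scores) as fixtures, and a synthetic cohort generator
(`generate_cohort()`) that plants a co-expressed module, covering PPI
edges, and survival hazard tied to the module's latent factor — with
ground truth for recovery testing.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
synthetic cohort (310 genes, 100 samples, 5 seeds, 5 planted linkers)
and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_networks.R
Rscript analysis/03_subnetwork.R
Rscript analysis/04_ranking.R
Rscript analysis/05_validation.R
```

Output of the run (abridged):

```
       network nodes edges
           PPI   286   479
 Co-expression    10    45
        Common    10    25
Extracted subnetwork: 9 nodes, 8 edges
  seeds: 5  linkers: 4
Candidates (RS > 1): LNK05, LNK02, LNK03, LNK04
Published table: 82 linkers; RS > 1 selects 6 genes: BARD1, KRT19,
  MST1R, LGALS1, S100A14, RNF168
Seed-candidate pairs tested: 8 | significant (raw p < 0.05): 8
Covariate tests with p < 0.05: 0 of 12
Survival: 91 samples retained (9 excluded for missing clinical data)
  median-split log-rank chi-square = 12.78, p = 0.00035
```

Reading this: only the planted module survives the co-expression
threshold, so the common network is the module's seed-linker core; the
walk recruits 4 of the 5 planted linkers (connecting 5 seeds does not
require all of them), every recruited linker is a true planted one and
all pass RS > 1; their expression does not track gender/alcohol/smoking
(as simulated); and the signature's median split separates survival
strongly, as expected at a planted hazard ratio of 3. Applying the same
selection rule to the packaged published ranking table reproduces that
study's six candidates exactly. The same workflow
runs on real data by pointing `pipeline_config()` (one-call orchestration
via `run_pipeline()`) at your own files.

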