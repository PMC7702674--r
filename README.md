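# skullconv

Phylogenetic comparative analysis of skull-roof microanatomy in burrowing
(fossorial) lepidosaurs — and of any analogous system where a discrete
lifestyle is suspected to drive convergent evolution of continuous traits
measured from binary μCT cross-sections.

Head-first burrowing loads the skull roof, and fossorial lizards,
amphisbaenians and snakes are expected to respond convergently with a
compact (osteosclerotic), relatively thick skull roof, strongly overlapping
roofing bones, an elongate cranium and parietal, and a small skull
diameter. `skullconv` implements the full analysis chain needed to test
that hypothesis:

1. **Morphometry** — from binary cross-section masks of the premaxilla,
   nasal, frontal and parietal (two sections per bone, at 1/3 and 2/3 of
   bone length):
   - compactness `c` = bone pixels / pixels inside the filled outer
     boundary;
   - mean local thickness (2-D Hildebrand–Rüegsegger inscribed-disc
     diameter, cavities filled first), integrated as relative thickness
     over the anterior half of the cranial profile,
     `d = ∫₀^0.5 d_rel(s) ds`;
   - anteroposterior bone overlap
     `ovl = 100 (2/3 − 2Δ/(L_A + L_B))`, with Δ the signed distance
     between the neighbouring bones' facing cross-sections (100% =
     centred alignment, 0% = abutting);
   - `dia = √(w_cran · h_cran)`, `elo = l_cran/dia`,
     `rfp = L_frontal/L_parietal`, and the log-compactness transform
     `c_log = −log₁₀((105 − c)/105)`.
2. **Lifestyle signal** — phylogenetically informed ANOVA: Pagel's λ
   estimated by ML GLS (clamped to [0, 1]), GLS whitening by the
   λ-transformed Brownian-motion covariance, residual-randomization
   permutations (RRPP), pairwise least-squares-mean contrasts with Holm
   adjustment.
3. **Ancestral lifestyle** — ML Mk model (ER/ARD) via Felsenstein pruning,
   stochastic character mapping (joint node sampling + uniformized branch
   histories), branch-wise posterior profiles, and derivation of the
   independently acquiring fully-fossorial clades; Retention Index and a
   phylogeny-vs-lifestyle two-block PLS quantify clustering.
4. **Convergence** — univariate Stayton C1
   (`1 − D_tip/D_max`, averaged over between-clade tip pairs) and C5
   (number of lineages entering the focal morphospace region; interval in
   1-D, minimum-area enclosing ellipse in 2-D), with p-values from
   Brownian-motion simulation nulls.
5. **Synthetic studies** — a generator (pure-birth tree, Mk lifestyle with
   recorded history, regime-switching Ornstein–Uhlenbeck traits,
   procedural masks of exact compactness) provides full ground truth, so
   the entire chain is testable without any external data.

## Worked example

```r
library(skullconv)

cfg    <- sim_config(seed = 7)            # 99 tips, planted fossorial optima
study  <- gen_dataset(cfg, dir = NULL)    # tree, masks, tables, ground truth
config <- pipeline_config(n_perm = 999, n_maps = 200, n_sim = 999, seed = 7)
report <- run_full_pipeline(study, config)
print(report)
```

```
skullconv pipeline report
seed=7 n_perm=999 n_maps=200 n_sim=999 [reduced counts]
focal clades: 4 | RI = 0.857 | r-PLS = 0.805 (p = 0.001)
  trait lambda      F p_anova    C1  p_C1 C5  p_C5
1     c  1.000 439.50   0.001 0.882 0.001  4 0.353
2     d  0.878 145.78   0.001 0.715 0.002  4 0.349
3   ovl  0.976 592.36   0.001 0.813 0.001  4 0.366
4   rfp  0.907 343.34   0.001 0.834 0.001  4 0.377
5   elo  0.899 207.68   0.001 0.796 0.001  4 0.376
6   dia  0.919  62.85   0.001 0.780 0.001  4 0.362
7  ctrl  1.000   2.08   0.138 0.461 0.146  4 0.373
PCA on (c, d, ovl, rfp, elo, dia): PC1 = 89.8% of variance
```

Reading the output: the pipeline measured all 792 masks, found 4
independently acquiring fully-fossorial clades from 200 stochastic maps,
and reports for every trait its phylogenetic signal (λ), the RRPP ANOVA F
and permutation p for a lifestyle effect, the C1/C5 convergence indices
with simulation p-values, and the PCA share of the first component. The
six planted traits show strong lifestyle signal and significant C1
convergence; the neutral control trait (`ctrl`) shows neither — exactly
the planted structure. `write_report(report, "out/")` exports all tables
as CSV/JSON.

Measured traits can also be supplied directly (skipping masks) by putting
a data frame with columns `taxon`, trait columns and `lifestyle` into the
bundle; `load_dataset()` reads a study from disk (`tree.nwk`,
`specimens.csv`, `lifestyle.csv`, `masks/`).

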