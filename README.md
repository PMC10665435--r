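# erkktr

Single-cell Erk1/2 activity reconstruction from two-channel time-lapse
movies of cells expressing a kinase translocation reporter (KTR).

## The problem

A KTR is a fluorescent kinase substrate that is exported from the nucleus
when phosphorylated, so the kinase's activity in a single living cell can
be read out as the ratio of cytoplasmic to nuclear reporter fluorescence
(the **C/N ratio**). After serum stimulation, Erk1/2 activation drives the
C/N ratio of an Erk-KTR up from its baseline of 1; in senescing cell
populations the response differs in speed, amplitude, and persistence
between proliferative ("young"), intermediate ("mid-old"), and senescent
("old") fibroblasts. Quantifying those differences requires reconstructing
per-cell C/N trajectories from raw movies and reducing each trajectory to
interpretable kinetic parameters.

`erkktr` implements that reconstruction as a tested, reusable pipeline:

1. **Segmentation** — nuclei are segmented from a nuclear-dye (Hoechst)
   channel by Otsu thresholding, connected-component labeling, hole
   filling, and an area filter; each cell's cytoplasm is a 5-pixel
   (~1.1 µm) annular ring dilated outward from its nucleus, with contested
   pixels assigned to the nearest nucleus.
2. **Tracking** — cells are linked across frames by minimum-cost
   (Munkres/Hungarian) assignment on gated centroid distances.
3. **Quantification** — per cell and frame, C/N = mean reporter intensity
   over the ring / mean over the nucleus, normalized to the frame just
   prior to stimulation.
4. **Kinetics** — each normalized trace r(t) is fitted by bounded
   multi-start nonlinear least squares to a piecewise exponential model

   r(t) = 1                                        for t ≤ t_on
   r(t) = R_eq + (1 − R_eq)·exp(−k_on·(t − t_on))  for t > t_on

   with trans-localization rate `k_on` (1/s), onset delay `t_on` (s), and
   equilibrium ratio `R_eq`; traces whose pattern recovers toward baseline
   are fitted with the extended model that switches at `t_off` to

   r(t) = 1 + (r(t_off) − 1)·exp(−k_off·(t − t_off))

5. **Group statistics** — kinetic parameters are compared between
   cell-status groups (young / mid-old / old, classified from doubling
   time and SA-β-Gal positivity) with an exact one-tailed Mann-Whitney U
   test, reported as mean ± SD.

Because raw movies of this kind are rarely deposited, the package includes
a ground-truthed synthetic movie generator (`simulate_movie()`) that
emulates the acquisition schedule — one frame every 15 s for 30 min after
stimulation, plus a short baseline — and renders nuclei and reporter
intensities so that the true C/N of every cell at every frame is known
exactly. Every stage of the pipeline is validated against it.

## Worked example

```r
library(erkktr)

pop <- population_spec(20, c(young = 0.4, mid_old = 0.3, old = 0.3),
                       seed = 7)
img <- imaging_spec(image_size = c(288, 288), seed = 7)
sim <- simulate_movie(pop, img)          # movie + ground truth
res <- run_ktr_pipeline(sim$movie)       # segment -> track -> C/N -> fit
res
#> <ktr_result> 20 tracks, 20 fitted cells (0 excluded)

head(res$fit_table[res$fit_table$converged,
                   c("track_id", "variant", "k_on", "t_on", "R_eq")])
#>   track_id  variant       k_on      t_on     R_eq
#> 1        1 monotone 0.04664762  49.17209 2.123854
#> 2        2 monotone 0.02853909  39.76745 2.280842
#> 3        3 monotone 0.04671075  89.32435 2.098469
#> 4        4 monotone 0.01072915 128.37311 1.936776
#> 5        5 monotone 0.04434624  57.41423 3.199214
#> 6        6 monotone 0.01770537 104.82685 2.290586
```

Each row is one tracked cell: `variant` records whether the transient
(recovery) model was selected, `k_on` is the rate at which the reporter
redistributes after stimulation (1/s), `t_on` the onset delay after
stimulation (s), and `R_eq` the equilibrium C/N ratio the cell approaches
(dimensionless; 1 = no response). On this noiseless synthetic movie the
fitted parameters match the generator's ground truth to machine precision:
`evaluate_against_truth(res, sim$truth)` reports a maximum relative error
of 5.9e-16 across all parameters and cells.

Group comparison on fitted parameters (here using the generator's known
archetypes as the cell status; with real data the status comes from
doubling time and SA-β-Gal staining via `classify_cell_status()`):

```r
ev <- evaluate_against_truth(res, sim$truth)
fits <- merge(res$fit_table, ev[, c("track_id", "archetype")])
fits$status <- fits$archetype
compare_groups(fits, parameters = "k_on",
               alternative = c("old.vs.young" = "less"))
#>   parameter  group1 group2 n1 n2      mean1         sd1      mean2         sd2
#> 1      k_on mid_old    old  5  3 0.01444448 0.003616685 0.01600543 0.002470326
#> 2      k_on mid_old  young  5 12 0.01444448 0.003616685 0.03568767 0.008395624
#> 3      k_on     old  young  3 12 0.01600543 0.002470326 0.03568767 0.008395624
#>   U            p alternative method skipped
#> 1 7 0.5000000000        less  exact
#> 2 0 0.0009367898        less normal
#> 3 0 0.0057699942        less normal
```

Old cells translocate the reporter more slowly than young cells (mean
k_on 0.016 vs 0.036 1/s; one-tailed Mann-Whitney p = 0.0058), while the
mid-old vs old difference is not resolved at these group sizes.

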