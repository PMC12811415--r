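# smlmsweep

Quantitative cluster analysis for two-channel single-molecule
localization microscopy (PALM/STORM) of bacterial surface protein
complexes.

## The problem

Cellulolytic bacteria such as *Clostridium thermocellum* display
supramolecular multienzyme complexes — cellulosomes — on their cell
wall.  Super-resolution imaging localizes individual fluorophores on
two channels (Alexa Fluor 647 against the CBM3a module of the primary
scaffoldin; a photoactivatable GFP–dockerin fusion marking unoccupied
type I cohesins) and produces, per channel, a table of x–y coordinates
with localization uncertainties.  The scientific questions — how are
cellulosomes packed on the cell surface, how does the packing change
between growth phases, and how much of the signal relocates to the
cellulose substrate — reduce to quantitative statements about the
*density structure* of these point patterns.

`smlmsweep` implements that analysis as a reusable pipeline for
microscopists and image analysts:

1. **Localization I/O** — ThunderSTORM-style CSV tables
   (`x [nm]`, `y [nm]`, `frame`, `uncertainty [nm]`), precision
   filtering, pixel/physical-unit conversion.
2. **DBSCAN from scratch** — density-based spatial clustering with
   explicit core/border/noise semantics.  A localization is *core*
   when its closed epsilon-neighbourhood (Euclidean distance
   ≤ Eps, self included) holds at least MNM molecules (the *minimum
   number of molecules*); clusters propagate from core molecules.
   Defaults: Eps = 75 nm (channel A), 125 nm (channel B).
3. **MNM sweep profiles** — the central statistic: the number of
   detected clusters as a function of MNM ∈ [10, 1200] at fixed Eps,
   normalized to a peak of 1 per cell/ROI, then averaged over many
   cells.  The *modal MNM* (the grid value where the mean normalized
   profile peaks) summarizes how densely molecules pack in clusters.
4. **ROI stratification** — polygonal regions (single cell, multiple
   cells, particle, particle-with-cells) clip the tables before
   clustering.
5. **Colocalization** — coordinate-based red/green colocalization at
   localization level (fraction of channel-A localizations within
   *d* of any channel-B localization, default *d* = 75 nm) and at
   cluster level (nearest-centroid distances).
6. **Synthetic scenes** — a generator that plants ground-truth
   clusters on cell capsules, particle surfaces and
   enzyme–microbe–substrate (EMS) contact zones under four condition
   presets (`log_bound`, `stationary_bound`, `log_detached`,
   `stationary_detached`), with cellulosome stoichiometry (9 type I
   cohesins per CipA, heptavalent anchors → up to 63 enzymes per
   complex), blinking, Gaussian localization error and Poisson
   background — so every stage can be validated against planted
   truth.

## Worked example

```r
library(smlmsweep)

scene <- simulate_scene("log_bound", seed = 42)
scene
#> <smlm_scene> preset log_bound, seed 42: 7 planted clusters, 2661 + 2226 localizations

cell <- roi(rbind(c(900, 2400), c(4500, 2400), c(4500, 3600), c(900, 3600)),
            category = "single_cell", id = "cell1")
tabA <- clip_to_roi(scene$tables$A_af647, cell)

prof <- sweep_mnm(tabA, eps = 75, roi_id = "cell1", condition = "log_bound")
prof
#> <sweep_profile> roi 'cell1' (log_bound), eps = 75 nm, 32 grid values, peak 14 clusters at mnm = 20
head(profile_table(prof), 5)
#>   roi_id condition eps mnm count normalized
#> 1  cell1 log_bound  75  10    10  0.7142857
#> 2  cell1 log_bound  75  20    14  1.0000000
#> 3  cell1 log_bound  75  30    12  0.8571429
#> 4  cell1 log_bound  75  40     6  0.4285714
#> 5  cell1 log_bound  75  50     5  0.3571429

dbscan_cluster(tabA, eps = 75, mnm = 200)
#> <cluster_labeling> 2007 points, 2 clusters (eps = 75 nm, mnm = 200); 1251 noise

coloc_fraction(tabA, clip_to_roi(scene$tables$B_pagfp, cell), d = 75)
#> <coloc_result> d = 75 nm: 99.2% of 2007 A near B; 99.5% of 1833 B near A
```

Reading the numbers: at MNM = 10 the dense diffuse labeling of the
log-phase cell wall still bridges neighbouring protuberances, so only
10 clusters resolve; the count peaks (14) at MNM = 20 once the diffuse
background falls below the core threshold, and decays as MNM exceeds
the molecule content of individual clusters — the same
interconnected-then-resolving behaviour that distinguishes growth
phases in real data.  The normalized column rescales the peak to 1 so
profiles from cells with different absolute counts can be averaged.
The geometry helpers put the counts on a physical scale: a 75 nm disc
covers `eps_disc_area(75)` = 0.0177 ≈ 0.018 µm², so 40 molecules per
disc correspond to `local_density(40, 75)` ≈ 2264 molecules/µm².

End-to-end runs are driven by a JSON config:

```r
cmd_simulate(list(preset = "log_bound", seed = 42), "out/scene")
cmd_analyze(list(preset = "log_bound", seed = 42,
                 rois = list(list(id = "cell1", category = "single_cell",
                                  vertices = list(c(900, 2400), c(4500, 2400),
                                                  c(4500, 3600), c(900, 3600))))),
            "out/analysis")
```

or from a shell via the bundled CLI
(`system.file("cli/smlmsweep.R", package = "smlmsweep")`), with
subcommands `simulate` and `analyze`.

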