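# VoxelFlow

Voxel-by-voxel 4D-flow MRI hemodynamic mapping of the thoracic aorta.

4D-flow MRI delivers a time-resolved three-directional velocity field over
a 3-D volume. In bicuspid aortic valve (BAV) disease the question is
whether flow-derived markers — beyond plain diameter — track aortic
dilation and the need for surgery. VoxelFlow implements the voxel-wise
analysis such studies run: for every segmented lumen voxel it computes

* **forward flow** FF and **reverse flow** RF (mL/cycle): the volume moved
  downstream/upstream along the local centreline direction, summed over the
  cardiac cycle,
* **stasis** (%): the share of cardiac frames with speed below 0.1 m/s,
* **kinetic energy** (µJ): KE = Σ½ · ρ · dV · v(t)², ρ = 1060 kg/m³,
  dV = 1 mm³, cycle-summed,
* **systolic peak velocity** (m/s),

and summarises them over the five standard aortic regions (LVOT, AAo,
Arch, PDAo, DDAo) together with maximum effective diameters, BSA-indexed
diameters (Mosteller), dilation grading (<35 / 35–45 / >45 mm) and the
Reynolds number at the vena contracta. Around that core sit preprocessing
(noise masking, temporal velocity anti-aliasing against venc wrapping,
eddy-current background-phase correction, PC-MRA derivation), cubic-spline
resampling to a 1 mm isotropic grid, centreline extraction with
nearest-plane voxel matching, and a cohort statistics stage (normality
gated t / Mann-Whitney / ANOVA + Tukey comparisons, percent-change
reporting, correlations under the joint rule p ≤ 0.05 and |R| > 0.25, and
a standardized multivariable diameter model).

Because raw patient data of such studies are not public, the package ships
a ground-truthed synthetic generator: pulsatile Poiseuille flow in straight
and candy-cane (aorta-like) tubes with configurable retrograde and helical
components, venc wrapping, noise and eddy-like offsets, plus a cohort
simulator driven by published regional group means. Every stage is tested
against the analytic truth these phantoms carry.

## Worked example

Generate an aorta-like phantom, run the full per-subject pipeline, and
compare a synthetic cohort:

```r
library(VoxelFlow)

res <- runSubject(list(
    subject = "demo",
    phantom = list(geometry = "candy-cane", radius = 8, length = 50,
                   archRadius = 42, spacing = 2.4, nFrames = 20, seed = 7),
    bsa = 1.9))
print(res$summary, digits = 3)
#>   region nVoxels    ff      rf stasis   ke peakVelocity diameter indexedDiameter
#> 1   LVOT    5350 0.166 0.00739   70.1 1.46         1.75     17.5            9.23
#> 2    AAo   16685 0.170 0.00769   69.6 1.51         1.60     16.9            8.91
#> 3   Arch    7307 0.171 0.00780   69.4 1.52         1.60     17.2            9.04
#> 4   PDAo    9591 0.170 0.00773   69.7 1.51         1.60     16.9            8.88
#> 5   DDAo   10058 0.168 0.00747   69.9 1.48         1.75     17.4            9.14
```

The phantom's lumen radius is 8 mm, so every regional diameter sits within
a voxel of the true 16 mm; FF ≈ 0.17 mL/cycle per voxel and RF two orders
smaller reflect the almost purely forward default waveform, and ~70 %
stasis says a voxel spends ~14 of 20 frames below 0.1 m/s (the waveform is
zero through diastole). Peak velocity 1.75 m/s is the Poiseuille centre
peak (2 × the 0.8 m/s mean systolic velocity) minus profile decay at the
regional peak-voxel position.

```r
tab <- synthCohort(c(control = 23, bav = 73), seed = 7)
compareGroups(tab, "AAo_stasis", reference = "control")
#>    parameter group1  group2 mean1  sd1 mean2  sd2 percentChange   test        p
#> 1 AAo_stasis    bav control  23.1 12.4  48.9 10.4           -53 t-test 1.06e-12
```

The simulated BAV group shows the expected halving of ascending-aorta
stasis relative to controls (about −54 % at the published group means).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/voxelflow.R` (`phantom`, `map`, `stats`, `run-all`
subcommands).

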