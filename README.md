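# sulcalsim

Spatial smoothing is a near-universal preprocessing step in fMRI analysis,
and it has a geometric blind spot: two cortical locations can be a few
millimetres apart through the volume yet centimetres apart along the folded
cortical sheet. A 3D Gaussian kernel mixes their signals; a kernel applied
*along the surface* does not. The canonical example is the central sulcus,
where the primary motor cortex (precentral bank) and the primary
somatosensory cortex (postcentral bank) face each other across a ~4 mm gap
while being ~40 mm apart geodesically. Volumetric smoothing can therefore
manufacture false-positive "motor" activation from purely somatosensory
signal, and inflate motor–somatosensory functional connectivity.

`sulcalsim` makes this contamination measurable without any scanner data.
It provides:

* **A parametric folded-cortex phantom** — a C1 "U" fold (two banks joined
  by a semicylindrical fundus, extruded along the sulcus axis) with matched
  triangle-mesh and 3 mm voxel-grid representations, tissue compartments
  (cortex / white / CSF / background), outward normals, vertex–voxel maps,
  and two seed vertices realising the 4 mm / 40 mm geometry.
* **BOLD simulation** — canonical double-gamma haemodynamic responses
  h(t) = g(t; 6, 1) − g(t; 16, 1)/6 (peak-normalised), periodic,
  pseudo-randomised and alternating event designs sampled at TR = 2.52 s,
  amplitude ramps (1 at the centre to 0 at 6 mm geodesic distance),
  AR(1)-plus-drift resting-state-like backgrounds with mild spatial
  correlation, and the connectivity triplet: a 0.05 Hz carrier signal s1
  with a 20 % white-noise portion, a correlated partner s2c and an
  uncorrelated partner s2u, inserted into opposing banks with an
  amplitude-scaling loop until corr(combined, pure) ≥ 0.95.
* **Smoothing operators** — separable volumetric Gaussian smoothing
  (fwhm = 2·sqrt(2·ln 2)·sigma), geodesic surface smoothing by iterated
  one-ring Laplacian averaging with per-step variance calibration, and the
  two volume-to-surface samplers (sign-preserving absolute maximum;
  Gaussian weighted mean falling from 100 % at the segment centre to 50 %
  at its ends).
* **Inference** — mass-univariate OLS GLMs, one-sample group t maps,
  threshold-free cluster enhancement TFCE(v) = Σ_h e(h,v)^E · h^H · dh
  (E = 0.5, H = 2), and sign-flip permutation control of the familywise
  error rate via the maximum-statistic null.
* **Pipelines and experiments** — the three analysis orders (smooth→GLM in
  the volume, GLM→smooth in the volume, GLM→map-to-surface→smooth), the
  volume- and surface-based connectivity pipelines (band-pass 0.01–0.1 Hz,
  CSF regression, ROI extraction, Pearson r, Fisher z = atanh(r)), and
  experiment runners with region-wise suprathreshold counting, overlap
  metrics and the FWHM-trend regression.

## Worked example

```r
library(sulcalsim)

ph <- build_phantom(phantom_config())
ph
#> cortical_phantom: 2170 vertices, 4140 triangles
#>   grid 14 x 14 x 10 at 3 mm; tissue: background=1102 cortex=264 csf=265 white=329
#>   seeds: Euclidean 4.00 mm, geodesic 38.23 mm

rep <- run_connectivity_experiment(ph, fwhm_mm = 9, seed = 1)
rep
#> experiment_report: connectivity
#> VBA  mean r_cc 0.857  mean r_cu 0.695
#> SBA  mean r_cc 0.717  mean r_cu 0.332
rep$compare_cu[c("t", "dof", "p")]
#> $t   15.12434
#> $dof 36
#> $p   3.574857e-17
```

The two seed vertices are 4.00 mm apart through the volume but 38.2 mm
apart along the mesh. The 19-subject connectivity cohort is generated so
that each subject's final combined postcentral signal correlates 0.80–0.84
with the correlated precentral signal and at most |0.06| with the
uncorrelated one (designed values 0.82 and 0.04). After 9 mm smoothing the
*measured* ROI correlations drift from those designs: the volume pipeline
inflates the designed-uncorrelated pair from 0.04 to ≈ 0.70 while the
surface pipeline inflates it to ≈ 0.33, and the deviation difference is
highly significant in a two-sample t test on the Fisher scale. The same
machinery drives `run_hrf_experiment()` (false-positive precentral
activation counts that grow with the volumetric kernel while the surface
pipeline stays at zero) and `run_finger_experiment()` (two sources ~6 mm
apart on the postcentral bank, resolved more accurately by the surface
pipeline under inter-subject jitter).

See the methods vignette (`vignettes/sulcal-contamination.Rmd`) for the
model, every tunable parameter, and the reasoning behind the defaults.

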