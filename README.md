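# bordercell

Quantification of collective border-cell migration from fluorescence
time-lapses.

Border cells are a small cluster of 6–8 epithelial cells (plus two polar
cells) that migrates collectively through the *Drosophila* egg chamber.
Live imaging with an F-actin reporter (e.g. LifeAct) shows three
subcellular actin compartments with distinct mechanics: finger-like
**protrusions** extended by leader cells, a **supracellular actomyosin
cable** running along the outer rim of the whole group, and F-actin at the
inner **cell–cell contacts**. The balance between protrusive and
contractile actin decides how efficiently the group migrates, and it can
be read from two morphometric axes:

* the **protrusion area fraction** `A_p / (A_p + A_body)`, and
* the **cable discontinuity** `L_broken / (L_broken + L_intact)`, the
  length fraction of the rim whose cable is interrupted.

Groups are classified on these axes as **tight** (fraction < 10 % and
discontinuity ≤ 8 %), **loose** (fraction > 25 % and discontinuity ≥ 25 %)
or **balanced** (fraction in [10 %, 25 %] and 8 % < discontinuity < 25 %);
contradictory combinations are reported as unclassified rather than
forced into a category.

Actin dynamics are measured by particle image velocimetry (PIV): a source
window of 1.4 µm² is matched against a 2.4 µm² search window in the next
frame by zero-normalised cross-correlation; displacements whose peak
coefficient is ≤ c₀ = 0.5 are discarded; the kept vectors are interpolated
to all cell pixels with a 6 µm Gaussian kernel (σ = 1.2 µm) and smoothed in
time with a 20 s kernel (σ = 10 s). The velocity divergence ∇·V (central
differences) marks **network sinks** where converging actin loads
myosin II; the cosine between flow and the instantaneous motion direction
separates **retrograde** (negative) from **anterograde** (positive) flow.

The package implements the full pipeline:

* `synthetic_spec()`, `build_geometry()`, `render_timelapse()`,
  `make_fixture_suite()` — a synthetic fluorescence time-lapse generator
  with exact ground truth (advected speckle texture, photobleaching,
  noise), so every stage is testable without microscopy data;
* `segment_group()`, `decompose_protrusions()`, `trace_cables()`,
  `label_contacts()`, `extract_regions()` — the semi-automatic region
  decomposition driven by clicked landmarks;
* `morphology_summary()`, `cable_discontinuity()`,
  `region_mean_intensity()`, `migration_speed()`, `bleach_correct()`,
  `classify_group()` — morphometrics and classification;
* `piv_frame_pair()`, `interpolate_dense()`, `temporal_smooth()`,
  `flow_divergence()`, `classify_direction()`, `flow_occurrence()`,
  `angle_histogram()`, `sink_signal_correlation()` — the actin-flow
  pipeline;
* `bordercell_cli()` / `exec/bordercell` — a command line over the same
  functions (`synth`, `segment`, `quantify`, `piv`, `flowsum`, `run`).

## Worked example

```r
library(bordercell)

## simulate a "balanced" border-cell group drifting at 0.5 um/min
spec <- fixture_spec("balanced")
sim  <- simulate_cluster(spec)
frame <- get_frame(sim$stack, 1)

## decompose it into protrusions, cable and contacts
regions <- extract_regions(frame, sim$truth$landmarks,
                           pixel_size_um = spec$pixel_size_um)
morph <- morphology_summary(regions)
disc  <- cable_discontinuity(regions)
classify_group(morph$protrusion_area_fraction, disc)

## actin flows on a sink-flow movie (v = -k r, k = 0.5/min)
sink <- simulate_cluster(fixture_spec("sink_pair"))
cfg  <- piv_config(pixel_size_um = 0.2, frame_interval_s = 10,
                   source_side_px = 5L, search_side_px = 13L)
est  <- piv_frame_pair(get_frame(sink$stack, 1), get_frame(sink$stack, 2),
                       sink$truth$group_mask, cfg)
fld  <- interpolate_dense(est, sink$truth$group_mask, cfg)
dv   <- flow_divergence(fld, 0.2)
```

Output:

```
region_set: 3868 body px, 2 protrusion(s), 8 intact + 2 broken cable segment(s), 6 contact(s), 6 cells
protrusion area fraction: 0.147
cable discontinuity:      0.145
category:                 balanced
migration speed:          0.500 um/min
kept PIV vectors:         152
mean interior divergence: -0.90 /min (analytic: -1.00)
```

The generator's truth for this movie is a fraction of 0.150 and a
discontinuity of 0.154, so both axes are recovered within 0.01 and the
category matches; the drift of 0.5 µm/min is recovered by the
first-to-third-frame speed rule; and the PIV→interpolation→divergence
chain reproduces the analytic divergence −2k = −1.0 min⁻¹ of the sink
field to within its discretisation tolerance.

The same from the shell:

```sh
exec/bordercell synth --out fixtures/
exec/bordercell quantify --input fixtures/balanced_actin.tif \
    --landmarks fixtures/balanced_landmarks.json \
    --pixel-size 0.2 --frame-interval 24 --out out/
```

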