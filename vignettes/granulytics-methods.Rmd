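---
title: "Quantifying compartmentalized mRNA degradation in RNP granules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying compartmentalized mRNA degradation in RNP granules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granulytics)
```

## The measurement problem

In the early *Drosophila* embryo, *oskar* mRNA is packaged with Staufen
into founder granules in the posterior germ plasm, while *nanos* and
other transcripts occupy germ granules. Founder-granule *oskar* is
selectively degraded before and during pole cell formation: decapping
machinery (DCP1, the decapping-complex protein Me31B, and the 5'→3'
exonuclease Pacman) is recruited to intact founder granules, the total
localized *oskar* signal then falls, granules shrink, and Staufen
particles finally destabilize — all while unlocalized *oskar* in the
bulk cytoplasm persists until the general maternal-to-zygotic clearance.

granulytics implements the quantitative imaging analyses behind that
chronology — single-molecule-calibrated transcript counting, pairwise and
conditional colocalization, granule motility, per-volume compartment time
courses, and 5':3' transcript-integrity ratios — together with a
synthetic microscopy generator that renders every scenario with known
ground truth. The generator is the package's substitute for embryo
images, which are not publicly deposited: every analysis stage can be
validated against programmed truth, and the default scenario encodes the
published wild-type chronology so the whole pipeline can be exercised
end to end.

## Synthetic scenes

`scene_config()` describes a posterior-pole confocal field:

* Geometry and optics: 72 × 72 nm pixels, 340 nm z-step, anisotropic
  Gaussian PSF (σ~lateral~ = 110 nm, σ~axial~ = 350 nm). Voxel indices
  are 0-based; physical coordinates are voxel centers in µm.
* A cortical germ-plasm band (default 3 µm deep at the maximal-y edge)
  holds founder-granule sites and germ-granule sites; unlocalized
  single/low-copy particles fill the whole field (uniform in y, so the
  band and bulk compartments share one unlocalized density).
* Transcript-count distributions are log-uniform: founder granules over
  3–200 *oskar* transcripts, germ granules over 2–40; unlocalized
  *oskar* and *nanos* particles carry 2 and 1 transcripts — the internal
  calibration standards.
* Spots are rendered as per-voxel-integrated 3D Gaussians (pnorm
  differences per axis), so a spot fully inside the field sums exactly
  to its amplitude; photon-counting noise is Poisson on signal plus
  background with optional Gaussian read noise.

Each stage row of the stage table programs the biology: the true
localized total (`total_mult`), granule size scale (`size_mult`), the
fraction of founder sites surviving (`site_frac`), site occupancy by
*oskar* and Staufen, DCP1 partnering (`dcp1_coloc`), 5'-intact fraction,
and the unlocalized trajectory (`bulk_mult`). Protein partnering is
*assigned exactly* (a `round(f·n)`-sized random subset, not per-site
Bernoulli draws) so programmed colocalization fractions are recovered
exactly in the ground truth; Me31B and Pacman attach conditionally on
DCP1 (defaults 0.77 and 0.49 at DCP1-positive sites), which makes the
Pacman marginal trajectory a delayed, scaled copy of the DCP1 one — the
recruitment order seen in fixed embryos.

Granule counts are drawn i.i.d. and then rescaled so each embryo's true
localized total equals the programmed stage value times a lognormal
per-embryo staining effect (sd 0.08). The rescaling makes stage
trajectories realizable at desk-scale granule numbers (tens per field,
where raw log-uniform sums have ~15% spread); the biological variance is
injected explicitly through the embryo effect instead. A consequence is
that true transcript counts are continuous rather than integer — the
intensity-equivalent load, which is also what degradation leaves behind.
Two deliberate placement margins keep measurement well-behaved: granule
centers stay ≥ 1.2 µm from the axial field faces so the 3σ axial
measurement aperture never clips, and unlocalized particles have no y
margin so their density cancels between compartment ROIs.

What the generator does **not** emulate: nuclei and autofluorescent
yolk, depth-dependent attenuation and spherical aberration,
photobleaching, granule sub-structure, and spatial clustering of
granules around nuclei in fixed stacks. Passing tests therefore
demonstrate correctness of the measurement chain under idealized optics,
not robustness to every artifact of real embryo imaging.

Scenario parameterizations (`scenario_config()`) encode the study
conditions: `wild-type` (nc2–nc12; 98% loss of localized *oskar* from
the pre- to the post-pole-cell window, DCP1 recruitment from nc5, size
decline from nc9, Staufen decline from nc11, bulk decline reaching
significance at nc12), `wild-type-windows` and `tagged-reporter`
(collection windows; the founder-granule-targeted `og` reporter loses
90%, the germ-granule-targeted `odgn` reporter is stable),
`triple-dcp1` and `staufen-nc8` (conditional-colocalization fields),
`whole-embryo-early` (18% of total *oskar* localized), and `decay-null`
(degradation-deficient genotype mimic: trajectories pinned at 1, DCP1
partnering at chance). Genotype scenarios are parameterizations only; no
mechanism is modeled.

## Particle detection and intensity measurement

`detect_particles()` uses a Laplacian-of-Gaussian band-pass at the PSF
scale (separable Gaussian smoothing, per-axis scale-normalized discrete
Laplacian), 26-neighborhood local maxima with a deterministic
lexicographic tie-break, a response threshold in robust (MAD) standard
deviations (default 5), and a merge radius of 2σ~lateral~. Two further
choices matter at photon-counting backgrounds:

* **Background** is the *mean* of the channel outside the dilated spot
  apertures. A median would be the obvious robust choice, but at < 1
  count/voxel the integer-valued Poisson median is severely biased
  (median of Poisson(0.5) is 0) and the error multiplies by the ~270
  aperture voxels; the outside-mask mean is unbiased because spot tails
  beyond the 3σ apertures are negligible.
* **Integrated intensity** is the background-subtracted sum over a 3σ
  anisotropic ellipsoid. The aperture captures ≈ 97% of a Gaussian
  spot's mass; the deficit cancels exactly in the internal calibration
  because standards are measured identically. A particle must also
  integrate to > 5 sd of the expected Poisson background fluctuation
  over the aperture, which suppresses sub-photon response maxima that
  would otherwise corrupt the calibration mean.
* **Centroids** are intensity-weighted centers of mass over a tighter
  1.5σ aperture, re-centered once (two passes). The tight aperture is
  much less sensitive to the skirts of axially close neighbors — the
  dominant localization hazard in a thin z-series — and the second pass
  removes the half-voxel bias of dim particles whose response argmax
  jitters on the coarse z grid.

`measure_projection_intensity()` reproduces sum-slice projection
quantification: sum along z, threshold (triangle method by default,
which keeps the dim tail of the localized signal inside the mask; Otsu
and fixed available), and integrate above the per-pixel background.
`measure_roi_density()` divides box-ROI integrated density by physical
volume for germ plasm vs bulk comparisons, and
`measure_localized_share()` combines band and bulk densities into a
background-free estimate of the localized signal share (it requires the
zero-dark-count acquisition of the whole-embryo scenario).

## Internal single-molecule calibration

`calibrate()` divides the mean intensity of unlocalized particles from
the bulk cytoplasm of the *same stack* by their assumed average load
(*nanos* 1, *oskar* 2) to get photons-per-transcript; calibration is
strictly per-image and never pooled, which makes transcript counts
invariant to any global intensity rescaling of a stack and lets embryos
from different sessions be compared directly. A minimum of 20 standards
is enforced. `assign_transcript_counts()`, `size_distribution()` (default
bin edges 1, 2, 5, 10, 50, ∞; configurable), `abundance_timecourse()`
(baseline-normalized per-embryo totals, two-sided pooled-variance
Student's t-tests per stage, no multiple-testing correction, Welch
optional) and `percent_decrease()` build the stage-resolved outputs. The
statistical unit for time courses is the embryo; particles pool across
embryos only for size distributions.

`ratio_5to3()` measures transcript integrity: particles are detected in
the 3' probe channel and the 5' intensity is measured at the same
centroid (`measure_at()`), because independent 5' detection would drop
degraded particles and bias ratios upward. Ratios are rescaled so the
early-reference group mean is 1 and compared across stages within size
classes (default cut: 10 transcripts).

## Colocalization

`colocalize()` declares a reference particle colocalized when its
mutual-nearest query particle lies within a 3D centroid distance
threshold; matching is one-to-one by construction and ties break by
distance then id. Both directional fractions are reported, along with a
randomized-control chance estimate (query positions redrawn uniformly)
so chance colocalization can be subtracted; `chance_coloc_poisson()`
gives the closed form 1 − exp(−ρ·4/3·π·r³) for an ideal Poisson field.
`conditional_coloc()` restricts the reference set to particles carrying
the conditioning partner, and `coloc_by_size()` stratifies by calibrated
transcript-count bin.

Two thresholds are in play, deliberately. The generic default is 250 nm
(≈ 2σ~lateral~), appropriate for same-channel comparisons. Scenario
analyses of protein–mRNA partnering use 400 nm (`run_scenario()`
default): each protein particle sits an isotropic 80 nm/axis
registration offset from its granule (and Me31B–DCP1 comparisons
compound two such offsets), and axial centroid errors add ~60–80 nm per
channel, so a 250 nm gate would discard a fifth of true partners while
400 nm accepts ≳ 97% at the scenarios' densities. Every reported
fraction carries its threshold.

## Tracking and motility

`link_tracks()` replaces the proprietary autoregressive linker used on
the original movies with frame-to-frame minimal-cost bipartite
assignment: link costs are squared displacements gated at `max_disp`
(default 1 µm/frame at 5 frames/s), birth/death dummies cost
`max_disp`², and each gated component is solved exactly with a
shortest-augmenting-path (Hungarian) solver — so the matching maximizes
gated links and, among those, minimizes total squared displacement. No
gap closing. `track_metrics()` computes average velocity (path length /
duration), net displacement, linearity (net / path, in [0, 1]) and
duration; tracks shorter than 5 points are excluded from population
statistics by default. `region_occupancy()` partitions a rectangular
field into equal-area bands by distance from the cortex edge (region 4
nearest the cortex; boundary points assigned toward the cortex).

The movie generator mixes a directed population (constant speed toward
the nearest nucleus; the default nucleus row sits just beyond the
cortex-side edge so granules stream across the field for the whole
movie, and particles that leave the field vanish from the observed
frames) with a confined population (tethered jitter). Defaults: 5
frames/s, 600 frames, 0.30 µm/s directed speed, 0.03 µm confined jitter,
0.02 µm localization noise.

## Degradation kinetics

`onset_analysis()` reports, per statistic, the earliest stage whose
two-sided Student's t-test against the baseline is significant at α and
whose direction matches the overall trend (the sign of the change at the
final stage); this direction filter is the package's resolution of the
ambiguity between single-stage and sustained significance — an isolated
opposite-direction blip is not an onset, while the first same-direction
significant stage is, even if a later stage dips back. `compare_compartments()`
applies the same rule to germ plasm vs bulk densities and reports the
onset gap. `run_scenario()` chains generate → detect → calibrate →
colocalize → kinetics over all stages and pseudo-embryos and returns a
bit-reproducible report bundle (`report_hash()`).

One measurement subtlety: detected "oskar particles" in the band include
unlocalized mRNAs that happen to lie there, and their share grows as
granules disappear. The mean-particle-size statistic therefore counts
only particles with ≥ 3 calibrated transcripts (`granule_min_count`),
matching the definition of founder granules as multi-transcript RNPs;
without the filter the dilution masquerades as an early size decline.

## Numerical and statistical choices

* t-tests are pooled-variance ("Student's") by default, two-sided, with
  per-comparison α (0.05/0.01/0.001 conventions) and no multiple-testing
  correction; Welch is available everywhere (`welch = TRUE`). Degenerate
  constant samples compare as p = 1 when identical, p = 0 otherwise.
* All distances are 3D Euclidean in µm (2D for movies, as acquired).
* Determinism: a single master seed derives per-stage/per-embryo
  substreams (`substream_seed()`); identical (config, seed) give
  bit-identical arrays, tables and report hashes. Detection tie-breaks
  are lexicographic in voxel order; linking tie behavior is fixed by
  sorting particles by id within each frame.
* Degenerate inputs: empty channels give empty particle frames; an
  all-background projection gives a zero-area mask and zero intensity
  (not an error); empty query sets give fraction 0 with a warning; an
  empty conditioned set is flagged undefined rather than 0; zero-volume
  ROIs and zero-duration tracks are errors.

## Problem sizes and what the tests show

Test and acceptance runs use desk-scale fields (10–22 µm lateral, 5–7 µm
axial, tens of granules, 5–8 pseudo-embryos per stage or window; n ≥ 500
reference particles for conditional colocalization), sizes at which the
expected nearest-neighbor spacing stays well above the resolvability
warning threshold the generator enforces. Per-particle transcript
recovery (relative RMSE < 15% for ≥ 5 transcripts) holds for particles
whose neighbors lie outside the measurement aperture; axially
overlapping granules in a thin z-series blend in any aperture-photometry
pipeline, and the generator's density warning flags configurations where
that becomes common. Granule densities per µm² of germ plasm are not
published for this system; the defaults are chosen for resolvability and
are not validated against tissue.

## Known limitations

Aperture photometry, not PSF fitting: blended neighbors bias individual
intensities (population statistics are robust to the few-percent rate at
default densities). The triangle/Otsu projection mask can admit bright
unlocalized spots into "localized" totals; the scenario time courses
account for this by restricting the projection to the germ-plasm band.
The OME-style metadata travels in an XML sidecar rather than inside the
TIFF (the installed TIFF writer exposes no description tag). Movies are
2D; z-motion is not modeled.
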