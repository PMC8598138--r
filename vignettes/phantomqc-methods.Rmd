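---
title: "phantomqc: measurement models, simulator, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phantomqc: measurement models, simulator, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`phantomqc` turns an unprocessed ("for processing") image of a simple
Cu/Al test phantom into a vector of objective image-quality metrics —
SDNR, SNR, presampled MTF, detrended NNPS, the NPWE detectability index
d′, and a variance map — and trends those metrics per device with control
charts. This vignette documents the measurement models, the synthetic
world used to validate them, and every numerical decision that was
genuinely open, so a maintainer can tell a design choice from an
accident.

## Measurement models

### SDNR and SNR

`SDNR = (S_background − S_target) / σ_background`, with the mean and the
sample SD (n−1 denominator, unbiased at small ROI sizes) taken over
automatically placed 5 × 5 mm ROIs: one on the aluminium square, one on
the adjacent background. The SDNR's sign is preserved; a negative value
indicates a polarity or localization fault and is worth investigating
rather than hiding.

SNR is tracked as an output but is not pinned to a formula by the
methodology this reimplements. We define `SNR = S_background /
σ_background` (conventional large-area SNR, consistent with the SDNR
denominator). Whether the original tool uses the background or the Al ROI
is unknown; the choice is isolated in `compute_snr()`.

### Slanted-edge presampled MTF

The Cu square is slanted 2–5° relative to the pixel matrix, so pixel
centers in a band around each edge sample the edge profile at many
subpixel phases. The pipeline:

1. **Edge angle** — per image line, the 50% threshold crossing is found
   with linear interpolation after light 3-point smoothing; a
   least-squares line through the crossings gives the slant. Angles are
   the square's rotation, clockwise positive with the origin top-left;
   mirroring an image negates them. `|angle|` outside [1°, 7°] attaches a
   reliability warning; a crossing-fit RMSE above 0.5 px flags a ragged
   edge.
2. **Oversampled ESF** — every pixel within a band (default half-width
   32 px; wider for heavy blur) is projected onto the edge normal and
   binned at 0.1 native-pixel pitch. Empty bins are filled by linear
   interpolation; the profile is oriented low → high signal.
3. **LSF and window** — centered finite differences; then a Tukey taper
   centered on the LSF peak: flat over the central half of the profile,
   cosine roll-off outside. A full Hann window (the more common default)
   measurably attenuates the LSF *core* when the blur spread is a large
   fraction of the band — at σ = 1.0 mm and 0.1 mm pitch it biased f50
   high by 7%; the Tukey variant reduces that to < 0.1% while still
   suppressing tail noise.
4. **DFT and binning** — the windowed LSF is zero-padded (so the fine
   frequency sampling is at least ~3× denser than the common grid), its
   DFT magnitude is normalized to 1 at zero frequency, truncated at
   Nyquist = 1/(2·pitch), and bin-averaged onto the common frequency grid
   (spacing `1/(256·pitch)`, the NNPS grid). Values are renormalized so
   `MTF(0) = 1` exactly.

Characteristic frequencies f50/f20/f10 are the first downward crossings
of 0.5/0.2/0.1, linearly interpolated, `NA` when a level is not crossed
below Nyquist. Validation: across σ ∈ {0.2, 0.5, 1.0} mm at 0.1 mm pitch
the measured MTF matches the analytic Gaussian × pixel-aperture product
within 3% RMS (absolute difference, up to 0.8 × Nyquist) and f50 within
2% — in practice ≤ 0.4%.

### Detrended NNPS

From a 512 × 512 px homogeneous region: the region is flattened by
fitting and subtracting one least-squares linear ramp along columns, then
one along rows (the mean is restored — detrending removes gradient, not
level); 3 × 3 half-overlapping 256 × 256 ROIs are each mean-subtracted
and `NPS(u,v) = (p²/N²)·⟨|DFT|²⟩` is averaged over the nine;
`NNPS = NPS / mean²` (units mm²). 1-D cuts:

- **directional** — average of the 3 lines on each side of (but
  excluding) the zero-frequency axes, folded onto [0, Nyquist]. Axis
  exclusion avoids fixed-pattern/gradient leakage, which lives exactly on
  the axes for separable trends.
- **radial** — average over annuli of all 2-D bins up to Nyquist,
  excluding only the DC bin.

The common frequency grid shared by MTF and NNPS is the NNPS grid
(129 points, spacing `1/(256·p)`); `common_grid()` interpolates the MTF
onto it, and directional MTFs are averaged before d′.

One subtlety worth recording: for a *planar* gradient, the raw (un-
detrended) spectrum is contaminated at **all** frequencies by the ramp's
sinc² leakage — at realistic gradient strengths the raw radial NNPS sits
an order of magnitude above the white level even at mid frequencies. The
meaningful locality statement, which the tests enforce, is that the
*detrended* spectrum matches the gradient-free spectrum everywhere above
0.1 × Nyquist, while detrending strongly reduces the lowest-frequency
bins. Optional low-frequency filtering beyond linear detrending is
deliberately **not** applied by default.

Small-detector fallback: when a 512 px square cannot be placed clear of
the targets with a 5 mm margin, the region shrinks to 256 px with a
warning (mammography detectors can be shorter than 560 px after margins);
below that, NNPS analysis refuses to run.

### NPWE detectability index

`d′ = 2πC · ∫S²(u)·MTF²(u)·VTF²(u)·u du / sqrt(∫S²(u)·MTF²(u)·VTF⁴(u)·NNPS(u)·u du)`

evaluated by the trapezoid rule on the common grid over [0, Nyquist].

- `S(u) = (πD²/4)·2J₁(πDu)/(πDu)` is the disk shape function
  (`S(0)` = disk area); D defaults to 0.3/4.0 mm (radiography) and
  0.1/0.25 mm (mammography).
- The eye filter is `VTF(f) = f^1.5·exp(−1.5f/4)` in cycles/degree
  (`f = u·distance·π/180`, distance default 400 mm), normalized to peak 1
  at 4 cycles/degree. The upstream methodology cites the filter without
  printing its formula; this Burgess-style form is isolated in
  `visual_transfer_function()` so an alternative is a one-line change. No
  internal-noise term is applied.
- Contrast C defaults to the measured Al contrast
  `|S_bg − S_target|/S_bg`; a nominal tabulated value can be configured.
- The printed rendering of the formula is ambiguous about whether the 2π
  sits inside or outside the square root; we implement it exactly as
  printed (default `"as_printed"`), with the fully radial alternative
  (`sqrt(2π)·C·I₁/sqrt(I₂)`) selectable via `constant_placement` — the
  two differ by the constant factor `sqrt(2π)`, which cancels in
  trend analysis.

Validated against independent adaptive quadrature of the same integrals
(≤ 0.5% discrepancy; in practice ~10⁻⁶%), with exact homogeneity laws
(`d′ ∝ C`, `d′ ∝ NNPS^−1/2`).

### Variance map

The image is tiled into non-overlapping blocks of `round(2 mm / pitch)`
px (min 2); each block's sample variance is divided by the variance of
the detrended NNPS region. Tiling (rather than a sliding window) keeps
blocks independent and the map cheap; the upstream description says
"kernel" without specifying a stride. Blocks overlapping the located
targets are masked. Defects are 4-connected components above a threshold
(default 5.0 — effectively impossible under the χ² null at the block
sizes used), ranked by peak value, and matched across sessions by
centroid distance ≤ 1 block. Rendering uses a green→red ramp, values
clipped to a user display range, deterministic byte-for-byte.

### Trending

Per-device history is an append-only CSV of fixed schema (comma
separator, "." decimal, ISO-8601 UTC datetimes; absent = empty cell,
never zero). Baselines are the mean/SD of the first `n_baseline` sessions
(default 10 — the upstream programme collects daily data "at the
beginning" without fixing a count; 10 is two working weeks) and are never
recomputed as data accrue. Limit policies: ±10%, ±15% of baseline mean,
or ±2 baseline SD (rejected when the baseline SD is 0). A point exactly
on a limit is in control (strict inequality — the conventional reading).
Trend rules are deliberately simple and separately reported: a strictly
monotone run of ≥ 6 points, and a 5-point moving average drifting > 1
baseline SD from the baseline mean. Both are configurable; the upstream
text asks for trend observation without defining a rule.

## The simulator's stated world

`simulate_phantom_image()` renders: uniform background `M` (default 10⁴
detector units); a Cu square (transmission 0.5 radiography / 0.25
mammography — 2 mm vs 1 mm Cu) slanted 3° by default; a 1 × 1 cm Al
square (transmission 0.9 / 0.85); Gaussian system blur (σ = 0.2 mm
default, a typical DR system); an optional additive planar gradient
(detector units per mm, centered so the mean is conserved); Poisson noise
`gain·Pois(x/gain)` (gain = 1, quantum-limited) plus Gaussian read noise
(SD 20); then artifact overwrite (dead pixels/rows/columns, blobs) and
rounding to 16-bit integers — values outside [0, 65535] are an error,
never silently clipped. Edges are rendered by area-weighted subpixel
coverage (8 × 8 supersampling within 1.5 px of the boundary), so the
slanted edge is alias-free. All randomness is seeded; identical config +
seed is bit-identical, and analysis code contains no randomness at all —
which is what makes the repeat-analysis determinism test meaningful.

Ground truth carried with each image: the analytic presampled MTF
(Gaussian × pixel-aperture sinc), the expected SDNR
`M(1 − t_Al)/sqrt(gM + σ_e²)`, the flat NNPS level `(gM + σ_e²)p²/M²`,
and the exact ROI geometry.

What the simulator does **not** emulate — and hence what a green test
does not establish: kVp-dependent attenuation and beam hardening,
scatter, grid artifacts, heel-effect shapes beyond a planar ramp,
focal-spot blur anisotropy, detector gain maps, or vendor processing.
Passing tests demonstrate that the *estimators* recover known inputs
under a plausible noise model, not that any particular physical device
meets tolerances. The upstream field study's reproducibility tables and
multi-year trend figures come from real hardware and are deliberately not
reproduced; the movement-sensitivity test reproduces only their
qualitative structure (d′ varies less across repositioning than MTF10).

## Other numerical and design decisions

- Coordinates are 1-based R matrix indices, origin top-left, row-major;
  all physical lengths in mm via the pixel spacing. (The underlying
  convention question is off-by-one ROI drift; one stated convention
  avoids it.)
- Cu localization: Otsu threshold on the plate-interior histogram (the
  2% border is excluded), connected components via row-run union-find,
  candidate areas within [0.5, 2] × the expected square area, ties broken
  by distance to the expected fractional position. The slant angle is
  then *re-estimated* by subpixel edge regression, because a
  minimum-area-rectangle fit on a binary mask is quantization-limited for
  near-axis-aligned squares. Fragmented masks (pure noise) abort early
  with a typed localization error so a caller can fall back to manual
  placement.
- Al localization: minimum of the window-mean image (integral-image
  matched filter at the expected Al size), excluding the dilated Cu box
  and a 2% border; candidates weaker than 5 standard errors of the local
  noise are rejected as absent.
- The background ROI sits 10 mm from the Al square's edge along the row
  axis (+columns first, then −columns if blocked); the upstream text does
  not state the offset.
- DICOM: explicit VR little endian is written; explicit and implicit VR
  little endian are read. Exposure is stored both as rounded mAs
  (0018,1152) and µAs (0018,1153, preferred on read). MONOCHROME1 images
  are flipped to "higher value = more signal" on read and the flip is
  recorded as provenance. Vendor variability in exposure-index/dose tags
  is handled by a per-device JSON tag map; an unmapped tag reads as NA —
  the reader never invents numbers.
- Device/simulation configs are JSON (`jsonlite`); YAML support was
  dropped because no YAML parser is a guaranteed dependency in the
  deployment environment.
- CLI exit codes: 0 in control, 1 usage/analysis error, 2 limit
  violation, 3 trend flag — plumbing for remote automation.
- Chart and variance-map PNGs are rendered through the cairo device,
  which is byte-deterministic for fixed input in this environment (and
  tested as such).

## Known limitations

- The NNPS directional cuts average 3 lines per side of the axes; the
  upstream tool's count is unknown.
- d′ is computed from the measured Al contrast by default; if the Al
  square's thickness varies between phantom copies, absolute d′ values
  are not comparable across devices (trends per device remain valid).
- The DICOM codec supports uncompressed 16-bit monochrome only — QC
  images per the acquisition protocol — not compressed transfer syntaxes
  or sequences.
- `validate_acquisition()` compares kVp with a ±0.5 kV tolerance and
  string-equal detector IDs; site-specific rules beyond that belong in
  the device config layer.
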