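# phantomqc

Automated, remote-capable quality control (QC) for digital radiography and
mammography from images of a simple copper/aluminium test phantom.

## The problem

Radiography is the most widely used imaging modality, yet routine
(daily/weekly) technologist QC is often missing — especially where no
clinically qualified medical physicist (CQMP) is on site. A practical
answer is a cheap phantom (a PMMA plate carrying a 5 × 5 cm copper square,
slanted 2–5° to the pixel matrix, and a 1 × 1 cm aluminium square) imaged
with fixed technique, plus software that turns each image into objective
numbers a remote physicist can trend over time. `phantomqc` is a complete
R implementation of that analysis chain, for medical physicists and QC
engineers:

- **Automatic ROI localization** — Otsu segmentation + connected
  components find the Cu square (with subpixel edge regression for its
  slant angle), a matched filter finds the low-contrast Al square, and a
  homogeneous 512 × 512 px noise region is placed at maximal clearance
  from the targets. Manual override supported (`override_rois()`).
- **SDNR and SNR** — `SDNR = (S_bg − S_target)/σ_bg` from automatically
  placed 5 × 5 mm ROIs; `SNR = S_bg/σ_bg`.
- **Presampled MTF** — classic slanted-edge analysis: subpixel 50%
  crossings → edge angle; band projection onto the edge normal → 0.1-px
  oversampled ESF; finite-difference LSF, Tukey window, DFT; horizontal
  and vertical curves plus characteristic frequencies f50/f20/f10.
- **Detrended NNPS** — 3 × 3 half-overlapping 256 × 256 ROIs in the
  homogeneous region, linear detrending along both axes,
  `NNPS = (p²/N²)·⟨|DFT|²⟩ / mean²` (units mm²), with directional and
  radial 1-D cuts on a common frequency grid shared with the MTF.
- **NPWE detectability index** —
  `d′ = 2πC·∫S²M²V²u du / sqrt(∫S²M²V⁴·NNPS·u du)` for disks of 0.3/4.0 mm
  (radiography) or 0.1/0.25 mm (mammography), with a band-pass eye filter
  peaking at 4 cycles/degree at 400 mm viewing distance.
- **Variance map** — local variance in 2 × 2 mm tiles normalized by the
  NNPS-region variance; dead pixels/lines and blobs are flagged as
  connected components and matched across sessions (persistence).
- **Trending** — per-device CSV history, baselines from the first N
  sessions, 10%/15%/2-SD control limits, monotone-run and moving-average
  trend rules, deterministic PNG control charts.
- **Synthetic phantom simulator** — blur/noise/gradient/artifact model
  with analytic ground truth (MTF, SDNR, NNPS level, ROI geometry), so
  every stage is testable without an X-ray device.
- **I/O** — self-contained DICOM (explicit VR little endian) and 16-bit
  TIFF readers/writers, JSON device configs with per-vendor DICOM tag
  maps, and a fixed-schema QC record CSV for exchange with a remote
  center.

## Worked example

```r
library(phantomqc)

cfg <- simulation_config(seed = 42)          # 1024x1024 px, 0.2 mm pitch
sim <- simulate_phantom_image(cfg)
write_dicom(sim$image, "phantom.dcm")

report <- analyze_image("phantom.dcm")
print(report)
#> <analysis_report>
#>   SNR 100.99 | SDNR 10.06 | d'(small) 10.34 | d'(large) 255.81
#>   MTF50/20/10 (h): 0.908 / 1.367 / 1.612 cycles/mm
#>   MTF50/20/10 (v): 0.909 / 1.380 / 1.618 cycles/mm
#>   defects flagged: 0 | violations: 0 | warnings: 0
```

What the numbers mean: the simulated detector has quantum-limited noise at
a background of 10⁴ detector units (`SNR ≈ 100 ≈ sqrt(10⁴)`), the Al
square transmits 90% of the signal (`SDNR ≈ 10`, analytic oracle 9.81 for
this configuration — single-ROI sampling explains the difference), and the
0.2 mm Gaussian system blur puts the 50% MTF point near 0.9 cycles/mm in
both directions. The measured mid-band NNPS (4.16 × 10⁻⁶ mm²) matches the
analytic white-noise level for this configuration exactly to three
figures. `d'` for the small (0.3 mm) disk combines all of these with the
eye filter.

Session workflow and trending:

```r
res <- run_session("phantom.dcm", "device-1-history.csv", policy = "pct10")
res$status   # 0 = in control, 2 = limit violation, 3 = trend flag
render_charts(read_qc_csv("device-1-history.csv"), "charts/")
```

Command line (installed at `system.file("cli", "phantomqc")`):

```sh
phantomqc simulate --seed 42 --out phantom.dcm --truth truth.txt
phantomqc inspect phantom.dcm
phantomqc analyze phantom.dcm --config device.json --out report/
phantomqc trend --history device-1-history.csv --policy pct10 --out charts/
```

## Documentation

`vignettes/phantomqc-methods.Rmd` describes the measurement models, the
simulator's stated world and its limits, all numerical choices
(tolerances, windows, tie-breaks, degenerate inputs), and known
limitations.
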