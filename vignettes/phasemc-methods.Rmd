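---
title: "Phase-encoded Monte Carlo radiation transfer: model and methods"
author: "phasemc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-encoded Monte Carlo radiation transfer: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phasemc)
```

## The problem

Monte Carlo radiation transfer (MCRT) is the standard way to simulate light
transport in turbid media such as tissue: photon power packets take
exponentially distributed steps against the interaction coefficient
$\mu_t = \mu_s + \mu_a$ and change direction according to a phase function.
Plain MCRT, however, carries no optical phase, so it cannot represent the
interference that *shapes* modern microscopy illumination — the focus of a
Gaussian beam, the concentric rings of a Bessel beam behind an axicon, or a
diffraction pattern behind a slit. `phasemc` implements a phase-encoded
variant: each packet also carries its accumulated optical path length (OPL),
$\ell_{\mathrm{opt}} = \sum_i n_i \ell_i$, and detection is coherent.

Three modifications turn a standard MCRT engine into this one:

1. **Phase tracking.** A packet's complex field is
   $E = E_0 e^{2\pi i \ell_{\mathrm{opt}} / \lambda}$ with $\lambda$ the
   vacuum wavelength. (In the source description of the launch phase the
   refractive index appears as a prefactor of the trigonometric terms
   rather than inside the phase; taken literally that would leave the phase
   independent of the medium index and break the free-space validations
   whenever $n \ne 1$. We read it as ordinary optical-path phase,
   $2\pi \sum_i n_i \ell_i / \lambda$, with a unit prefactor.)
2. **Power normalization.** Every packet is launched with the same field
   amplitude $E_0 = \sqrt{P/A}\,/N$ for beam power $P$, illuminated area
   $A$ and packet count $N$, so that $N$ in-phase packets in one bin of
   area $A$ reproduce the intensity $P/A$.
3. **Huygens–Fresnel launch sampling.** Every point of an emitting surface
   (slit area, lens or axicon exit surface) is a source of forward-going
   secondary wavelets. A packet's position is sampled on the surface and
   its direction is defined by a uniformly sampled point on a target
   rectangle (the detector plane or the medium entry face), which
   importance-samples the detector and never generates backward waves.

Interference is evaluated **per bin**, never at points: a detector plane or
voxel grid holds one complex accumulator per bin,
$I(\xi) = \bigl|\sum_{\xi} E_0 e^{2\pi i \ell_{\mathrm{opt}}/\lambda}\bigr|^2$,
and the squared modulus is taken only at read-out. The bin size (default
1 µm) is therefore a resolution/coherence trade-off surfaced in the
configuration: bins must stay below the transverse phase period
$\lambda / \sin\theta$ of the most oblique wave of interest (about 12 µm
for a 2.3° conical wave at 488 nm).

## Sampling density follows the field amplitude

The coherent bin estimator is linear in the launch sampling density: the
expected bin field is $\propto \int p(q) e^{ikL(q,\xi)}\,dq$, so whatever
density $p$ is used *is* the effective aperture amplitude. For Gaussian
illumination with $1/e^2$ intensity radius $w$ we therefore sample launch
positions from the **amplitude** profile $\exp(-r^2/w^2)$ (a bivariate
normal with per-axis standard deviation $w/\sqrt 2$), with $E_0$ constant
across packets. Sampling from the intensity profile $\exp(-2r^2/w^2)$
instead would simulate a beam narrower by $\sqrt 2$ and focus it to a waist
$\sqrt 2$ *larger* than the textbook $w_0 = 2\lambda f/(\pi D)$ — a 41%
error that the Gaussian-beam validation would flag immediately. This was
verified against a direct quadrature of the Huygens integral during
development.

No obliquity (cosine) factor is applied to the wavelets, matching the
algorithm as described rather than the textbook Huygens–Fresnel–Kirchhoff
kernel; at the paraxial angles of every study here (≤ 4°) the difference
is below $10^{-3}$.

## Optical elements

Elements are traced with exact vector Snell refraction; small-angle
formulas live only in the `theory` oracles.

* **Slit pair / square aperture**: packets start uniformly on the open
  area with zero OPL (plane-wave illumination has equal phase there).
* **Plano-convex lens** (flat face toward the source): packets cross the
  flat face, accrue $n_{\mathrm{lens}} \times$ the glass path to the
  spherical exit surface, and are then Huygens-sampled. The sphere only
  exists to $r = \mathrm{roc}$, so the usable aperture is
  $\min(\text{mount radius}, \mathrm{roc})$. The default lens (UV fused
  silica, roc 4.6 mm, thickness 2.2 mm, $n = 1.4631$ at 488 nm) has
  $f = \mathrm{roc}/(n-1) = 9.93$ mm; a paraxial ray-trace oracle confirms
  the exit rays cross the axis there to within 1%.
* **Axicon** (flat face toward the source, cone apex downstream): the exit
  point on the cone $z(r) = -r\tan\alpha$ carries OPL
  $n_{\mathrm{lens}}(t_c - r\tan\alpha)$, producing the conical phase ramp
  whose gradient deflects the wave by
  $\sin\beta = (n-1)\tan\alpha$; exact Snell at the cone
  ($\beta = \arcsin(n\sin\alpha) - \alpha$) agrees with the small-angle
  $(n-1)\alpha$ to 1% at $\alpha = 5°$. A ray exactly on the apex axis is
  left undeviated — a probability-zero case fixed for determinism. An
  optional helical delay adds $m\phi$ of phase at azimuth $\phi$ for
  $m$-th order (vortex) Bessel beams; the first-order beam shows the
  expected on-axis null.

## Transport in the medium

Inside a slab the usual MCRT loop runs with phase tracking: step lengths
$s = -\ln U/\mu_t$, Henyey–Greenstein deflections with anisotropy $g$
(the de facto tissue-optics phase function; the source material uses a
scalar $g$ without naming one), absorption decided with probability
$\mu_a/\mu_t$ per interaction (absorbed packets terminate — partial
weights have no phase semantics), and OPL growing as
$n_{\mathrm{med}} \times$ distance. Steps that would cross a face are
clipped exactly to the boundary. Packets leaving through the far
(detector-facing) face are recorded coherently at their crossing point;
side and back exits are discarded, as in the cuvette experiments.

Boundaries are **index matched**: no Fresnel reflection and no refraction.
Two consequences are worth stating because they are model artifacts, not
physics:

* the transverse interference pattern inside a medium of index $n$ is
  compressed by $n$ (real interfaces preserve the transverse wavevector by
  Snell refraction; straight-ray propagation with $n$-scaled phases does
  not), and
* a beam crossing an air/medium split acquires an obliquity-dependent
  phase $\approx (n-1) k L_{\mathrm{med}} \theta^2/2$ across its aperture,
  which slightly broadens and dims tight foci formed through thick media.

The cuvette validation therefore compares the simulated exit-face pattern
against a quadrature oracle *of the same split-path model*, not against
the in-air Bessel profile.

## Estimators

* Images are normalized to their brightest pixel when compared across
  runs, as in the reference image comparisons.
* The accumulator also tallies the incoherent sum $\sum E_0^2$ per bin.
  The **coherent excess** $|\sum E|^2 - \sum E_0^2$ has expectation zero
  for fully randomized phases, so it estimates deterministic interference
  structure on top of the Monte Carlo/speckle floor. It is used wherever
  weak coherent structure must be measured at desk-scale packet counts
  (the far-field annulus, the cuvette series, the beam-comparison
  calibration). Its per-bin noise is of the order of the floor itself and
  is *independent of N once floor-dominated*; only bin aggregation
  (radial averaging, shape fits) reduces it.
* Azimuthally symmetric patterns are radially averaged; ring-system
  contrast across a dilution series is summarized by the image-wide
  coherent fraction $\sum(\text{excess})/\sum(\text{floor})$.

## The Gaussian/Bessel comparison

The two illumination strategies are made commensurable by matching the
Bessel core to the Gaussian waist. With $\kappa$ solving
$J_0^2(\kappa) = e^{-2}$ ($\kappa = 1.7520$, i.e. 1.75 to three
significant figures; the first-zero metric is $\kappa = 2.40483$), the
core radius is $r_0 = \kappa/(k\sin\beta)$ and the matching relation
$1.75\lambda/(2\pi\sin\beta) = 2\lambda f/(\pi D)$ fixes the axicon angle
$\alpha = \arcsin(1.75 D/4f)/(n-1)$. Both arms use the same beam
($D = 0.5$ mm at 488 nm — the beam of the lens validation, which the
beam-comparison study states it reuses) and the same lens-derived
$f = 9.93$ mm; with these the matched angle is 2.72° and the common core
radius 6.17 µm. The cores agree to 0.1% by construction and the pairing
refuses to run beyond 2% mismatch.

**Matched-peak calibration.** The power given to the Bessel beam is chosen
so its central-core maximum equals the Gaussian focal maximum without
scattering. Because intensity is linear in power ($E_0 \propto \sqrt P$),
one free-space run of each beam at equal power suffices; the ratio of the
two maxima is the power scaling. Each axial plane is simulated as its own
Huygens-targeted 9 × 9 µm window at 1 µm bins; per-plane images are
proportional to the squared aperture integral, and dividing by the squared
range restores the spherical wavelet's $1/r$ decay so planes at different
depths are on one physical scale. Core peaks are least-squares fits of the
theory shapes ($e^{-2r^2/w(z)^2}$, $J_0^2(k_r r)$) to the floor-subtracted
window, with parabolic interpolation over the plane grid. The Gaussian
maximum is searched within one Rayleigh range of the ray-optics focus; the
Bessel core maximum is searched over the 2 mm axial extent of the
comparison medium centred on that focus — the elements share an exit plane
(one swaps the element in an otherwise fixed rig), so the sample occupies
the same depths for both beams, and the Bessel core is credited with the
brightest plane *the sample actually sees* rather than its global optimum
several millimetres upstream. The calibration agrees with a direct
quadrature of both Huygens integrals to ~1% and returns a power ratio of
≈ 15.7–15.9 at $10^7$ packets per beam.

**Equal-power slab runs.** Both beams are Huygens-sampled onto the entry
face of a water cuvette whose axial midpoint sits at the Gaussian focus,
with scattering coefficients taken from the Intralipid dilution series
(linear scaling of $\mu_s$ with concentration; the published dilution
table is reproduced exactly in its own linear-in-stock-volume convention,
while the physically correct volume-fraction scaling is the package
default elsewhere; the stock scattering-particle fraction implied by the
table, ≈ 22.8%, is a documented constant, not an assertion). Detected
energy falls monotonically with $\mu_s$ (no absorption, so losses are side
exits only), and the Gaussian on-axis focal intensity exceeds the
Bessel's at equal power, as expected when one beam holds all its power in
a single spot. The slab defaults to the printed
$0.1 \times 0.1 \times 0.2$ mm volume; the figure captions of the same
study say 2 mm thickness, so thickness is an explicit parameter (the
matched-peak axial window uses the 2 mm reading).

## Study conditions and desk-scale packet counts

The bundled configurations encode the published geometries: double slit
(slit width $10\lambda$, separation $80\lambda$, screen at $10^4\lambda$,
1 mm screen in 2048 bins — the printed "20512" bins would give 49 nm bins,
inconsistent with the stated ≈488 nm bin size, so 2048 is used); square
aperture (351 nm; the printed 100 *nm* side cannot reach the near-field
regime at any plotted distance, so the side is 100 µm and the screen
distance is set from the requested Fresnel number); the plano-convex lens
focus; the 5° axicon with a detector 10 mm from the tip
(40 × 40 µm, 1 µm bins); and the 2 mm Intralipid cuvette. Unprinted
geometry is chosen once and documented: slits 10 µm long with a ±10 µm
detector y-range (keeps the y-phase spread ≪ 1 rad so the 1-D slice
follows the separable theory); the cuvette sits 10 mm from the axicon tip
rather than the quoted 10 cm, because with the printed beam widths the
conical rays cross the axis within ~25 mm and no core would exist at
10 cm; the "far field" plane is 35 mm (about three times the axial focal
zone), where the annulus is fully formed and still bright enough to
detect.

Default packet counts are $10^6$–$4 \times 10^7$ per run (versus
$10^9$–$8\times10^{10}$ in the reference results) — enough that every
validation criterion is met with margin: correlations ≥ 0.99 (double
slit), ≥ 0.98 (square aperture, both regimes; Bessel rings), waist errors
≤ 5%, and a matched-peak ratio reproducible to ±2% across seeds. At these
counts the coherent part of a heavily scattered beam
($\mu_s L \gtrsim 4$, coherent signal $\propto e^{-2\mu_s L}$) falls
below the speckle floor, so the dilution-series test asserts strict
degradation over the rows it can resolve and floor-consistency beyond —
passing it shows the model's coherence loss, not a quantitative match to
camera images.

## Reproducibility

A run is fully determined by (configuration, seed, packet count). The
packet index space is processed in fixed blocks of $10^6$; block $b$ of a
run with seed $s$ uses the derived substream seed
$(48271 s + 22695477 b + 12345) \bmod (2^{31}-1)$, so results are
independent of how blocks are scheduled and reruns are bit-identical.
Rejection steps (aperture truncation of Gaussian positions) consume a
deterministic draw sequence within their block.

## What the engine does not model

Polarization and fluorescence; curved or multi-layer media (one
homogeneous axis-aligned slab); Fresnel reflection/refraction at
boundaries; heterogeneous voxel-wise optical properties (the voxel grid
exists for field accumulation only); the experimental imaging train
(objective and camera) — comparisons are between max-normalized exit-face
images; wavelength-dependent Intralipid properties beyond linear
concentration scaling; and freeform phase masks beyond the helical delay.
Full per-track 3-D voxel painting is provided for small grids but the
slab comparisons record transverse planes instead, since painting every
crossed voxel at $10^7$ packets is out of desk-scale budget.
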