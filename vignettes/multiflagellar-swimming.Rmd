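---
title: "Modelling and measuring multi-flagellated bacterial swimming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring multi-flagellated bacterial swimming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimRFT)
```

## The physical model

A peritrichously flagellated bacterium such as *E. coli* swims by rotating
its flagellar filaments, which wrap into a single tight bundle behind the
cell. At the micrometre scale inertia is irrelevant (Reynolds number
~10^-5), so the swimmer is force-free and torque-free at every instant:
whatever thrust and torque the bundle generates is exactly balanced by the
viscous drag on the cell body.

`swimRFT` models the bundle as one rigid helix in the framework of
resistive force theory (RFT). A slender filament element feels anisotropic
drag per unit length, $\xi_\parallel$ along and $\xi_\perp$ across its
axis. Integrating these over a helix with radius $R$, pitch $P$ (pitch
angle $\psi = \arctan 2\pi R/P$) and contour length $\Lambda$ gives the
propulsion matrix linking the axial force $F$ and torque $T$ on the helix
to its swimming speed $v$ and rotation rate $\omega$:

$$\begin{pmatrix} F \\ T \end{pmatrix} =
  \begin{pmatrix} A & -B \\ -B & C \end{pmatrix}
  \begin{pmatrix} v \\ \omega \end{pmatrix}, \qquad
  A = \Lambda(\xi_\parallel\cos^2\psi + \xi_\perp\sin^2\psi), \quad
  B = \Lambda R \sin\psi\cos\psi\,(\xi_\perp - \xi_\parallel), \quad
  C = \Lambda R^2(\xi_\perp\cos^2\psi + \xi_\parallel\sin^2\psi).$$

The coupling $B$ is what turns rotation into thrust; it vanishes for a
straight filament ($\psi = 0$) and its sign follows the handedness
convention (left-handed helix, counter-clockwise rotation seen from
behind, $B > 0$, $v > 0$). The identity
$AC - B^2 = \Lambda^2 R^2 \xi_\parallel \xi_\perp > 0$ holds for every
valid input and is asserted in the tests.

The cell body is a prolate spheroid (default 3.0 µm × 0.9 µm) with
closed-form Perrin translational and rotational friction coefficients. A
swimming cell wobbles: its long axis makes an angle $\theta$ with the
swimming direction, which raises the effective drags through the
projections $A_{0,\mathrm{eff}} = A_{0,\parallel}\cos^2\theta +
A_{0,\perp}\sin^2\theta$ and $C_{0,\mathrm{eff}} =
C_{0,\mathrm{axial}}\cos^2\theta +
C_{0,\mathrm{transverse}}\sin^2\theta$. $\theta$ is supplied per cell (and
sampled in the population layer) rather than predicted from hook
mechanics; hook elasticity is outside the model, and the velocity-versus-N
prediction is insensitive to the precise $\theta$.

With the body counter-rotating at $\Omega$, `solve_swim()` solves the
linear system

$$(A + A_{0,\mathrm{eff}})\,v = B\,\omega, \qquad
  C\,\omega - B\,v = C_{0,\mathrm{eff}}\,\Omega, \qquad
  \omega + \Omega = \omega_m,$$

where the last line is the central constraint: the flagellar motor turns
the filament relative to the body at a constant rate $\omega_m$
(default 220 Hz), independent of load and of the number of flagella. This
is the regime of a motor running near its maximum speed at low torque. Two
consequences follow immediately and are enforced as invariants: the two
lab-frame rotation rates always sum to the motor frequency, and — because
every drag coefficient is linear in the viscosity $\mu$ — the kinematic
outputs $(v, \omega, \Omega)$ are independent of $\mu$ while all forces
and torques scale with it.

### Multiple flagella

$N$ filaments are represented as one effective rigid helix: thicker, with
effective filament radius $a_b = a\sqrt{N}$ (conserving the total
cross-sectional area of $N$ close-packed filaments; the exponent is
configurable), and longer, because cells that build more flagella also
build longer ones. The filament length enters through the empirical
couplings (below). Thickness only enters the friction coefficients through
a logarithm, so the model is robust to the precise thickening rule.

The velocity-versus-N curve this produces rises steeply at small $N$ and
saturates around five flagella. The mechanism is explicit in the algebra:
$v = B\omega/(A + A_{0,\mathrm{eff}})$, and once the flagellar drag $A$
dwarfs the body drag $A_{0,\mathrm{eff}}$, thrust ($B$) and drag ($A$)
gain identically from additional filaments, so $v/\omega \to B/A$, which
no longer depends on $N$ except logarithmically. The test suite checks
this directly by setting the body drag to zero. The bundle torque is
shared by the $N$ motors, so the load per motor falls monotonically with
$N$ — consistent with motors staying in their constant-speed, low-torque
regime throughout.

### Friction-coefficient variants

Two canonical RFT coefficient sets are implemented:

* `gray_hancock`: $\xi_\parallel = 2\pi\mu/(\ln(2P/a_b) - 1/2)$,
  $\xi_\perp = 4\pi\mu/(\ln(2P/a_b) + 1/2)$;
* `lighthill`: $\xi_\parallel = 2\pi\mu/\ln(0.18P/(a_b\cos\psi))$,
  $\xi_\perp = 4\pi\mu/(\ln(0.18P/(a_b\cos\psi)) + 1/2)$.

Both satisfy $0 < \xi_\parallel < \xi_\perp \le 2\xi_\parallel$; inputs
thick enough to break this ordering raise an explicit out-of-slender-body
error. The variants differ in absolute velocity, but the $N=1$-normalised
curves agree within about 10% over $N \le 10$ (asserted at 15% in the
acceptance suite) — the fractional change of velocity with flagellar
number is a robust prediction, the absolute scale is not. That is why the
comparison with data uses one calibration parameter (below).

### Default parameters

| parameter | default | meaning |
|---|---|---|
| helix radius $R$ | 0.2 µm | normal flagellar helix |
| pitch $P$ | 2.26 µm | pitch angle $\psi \approx 29°$ |
| filament radius $a$ | 0.01 µm | single filament cross-section |
| body | 3.0 × 0.9 µm | prolate spheroid |
| wobble $\theta$ | 20° (single cell); U(0°, 40°) (ensemble) | drag projection |
| motor frequency | 220 Hz | constant, load-independent |
| viscosity $\mu$ | 1e-3 Pa s | water-like motility buffer |

All rotation rates are stored and reported in Hz; the balance itself is
evaluated with angular velocities $2\pi f$ in SI units. The raw 3×3 system
spans ~14 decades, so the solver equilibrates it (velocity column
expressed in helix radii per second, rows normalised) before the dense
solve; this changes nothing but the condition number. Residuals of all
three equations are checked to 1e-10 relative on every solve, and the
solver is cross-checked against an independently coded dense solve on 100
random parameter draws.

## Population layer

`predict_population_curve()` averages the model over an ensemble of
modeled cells (default 5000): body length lognormal(mean 3.0 µm, CV 0.15),
width lognormal(mean 0.9 µm, CV 0.10), wobble uniform on [0°, 40°]. These
distributions are configurable and recorded in output metadata; the means
match the default single cell, the CVs are typical mid-exponential
*E. coli* size spreads, and the wobble bound reflects that realistic
wobble angles are substantially larger than a rigid-hook model would
predict. Draws violating the body invariants are rejected (with an error
after 10^4 consecutive rejections); the ensemble is a pure function of its
seed. The per-cell solves use the closed form of the balance, vectorised
over cells, and the tests verify it is identical to the matrix solver.

Two empirical couplings connect gene expression $E$ to flagellation:
number is linear, $N(E) = kE + N_0$, and filament length saturates,
$L(E) = L_{\max}E/(K + E)$ (defaults $k = 1$, $N_0 = 0$, $L_{\max} = 8$
µm, $K = 2$), so inverting the first gives the length-versus-number rule
the sweeps use: $L(N) = L_{\max}N/(K + N)$ for the defaults, i.e. 2.7 µm
at $N = 1$ rising to 6.7 µm at $N = 10$. `fit_couplings()` estimates both
from per-cell tables (ordinary least squares for number, bounded
Levenberg–Marquardt for length) and falls back to a flagged linear length
model when the saturating fit is unidentifiable (e.g. constant length, or
the half-saturation constant running far beyond the data range). When
converting expression to per-cell flagella the number is rounded to a
non-negative integer; curve fitting and plotting use the real-valued
mean-field form.

Absolute velocities are matched to observations by a single multiplicative
scale $s$ — the least structural one-parameter calibration, chosen because
the normalised curve is the robust model output. It has the closed form
$s = \sum v_{\mathrm{obs}}v_{\mathrm{pred}} / \sum v_{\mathrm{pred}}^2$,
which the tests verify against a brute-force grid search.

## Measuring motility from video

### Differential dynamic microscopy

DDM works in Fourier space on frame differences of a time-lapse movie: the
image structure function

$$D(q, \tau) = \langle |\hat I(\mathbf q, t+\tau) - \hat I(\mathbf q, t)|^2
  \rangle_t = A(q)\,[1 - f(q, \tau)] + B(q)$$

is radially averaged into annular bins one FFT pixel wide (zero frequency
excluded), and $f(q,\tau)$ is the intermediate scattering function of the
imaged population. For a mixture of a fraction $\alpha$ of swimmers among
diffusers, with all cells sharing diffusivity $D$,

$$f(q,\tau) = e^{-q^2 D \tau}\left[(1 - \alpha) +
  \alpha\,f_s(q,\tau)\right],$$

and for ballistic swimmers with isotropic 3-D directions and
Schulz-distributed speeds (mean $\bar v$, shape $Z$) the swimmer factor has
the closed form

$$f_s(q,\tau) = \frac{\sin(Z\arctan\lambda)}{Z\lambda\,
  (1+\lambda^2)^{Z/2}}, \qquad \lambda = \frac{q\bar v\tau}{Z+1},$$

equal to the Schulz average of $\mathrm{sinc}(qv\tau)$; the tests verify
it against Gauss–Legendre quadrature of the defining integral to 1e-6 in
the experimentally probed range. (At extreme parameters — $Z$ of tens
with $\lambda \gg 1$ — the ISF underflows to ~1e-13, where no quadrature
can resolve a relative comparison; those values are far below any
measurable signal.) The multiplicative diffusive factor on the swimmer
term treats swimmer Brownian jitter and diffuser motion with one shared
$D$; this matches the generator exactly and is the common single-$D$
variant of the mixed-population model.

Fitting is per-q bounded nonlinear least squares over lag time with fully
deterministic initialisation: $B$ from the smallest lag, $A$ from the
large-lag plateau, $D$ from a diffusion-only prefit, $\bar v$ from the
first-minimum heuristic ($q\bar v\tau \approx 4.49$ at the first interior
maximum of $D(\tau)$), $Z = 2$. Because the mixed model has degenerate
local minima (with $\alpha$ pinned at 0 or 1 the swimmer parameters lose
identifiability), each bin is fitted from a small fixed grid of starting
$(\alpha, \bar v)$ values and the lowest-residual converged solution is
kept — still deterministic, hence bitwise-reproducible estimates. $Z$ is
bounded to [0.5, 50] and boundary hits are flagged. Aggregate estimates
are medians of the per-q values over the q window, default 0.4–2.0 µm^-1:
below ~0.4 µm^-1 the diffusive decay is too slow for the lag range at
$D \sim 0.3$ µm²/s, above ~2 µm^-1 (at 0.7 µm/pixel) the swimmer
oscillations approach the frame-rate limit. Lags are log-spaced, about 30
per decade, up to half the stack length. The population-averaged velocity
is $\alpha\bar v$ — non-motile cells contribute zero.

### Flicker rotation spectra

Rotating anisotropic scatterers modulate their scattered intensity at
their rotation frequency. `power_spectrum()` computes a Welch-averaged
periodogram (default 1024-sample Hann-windowed segments, 50% overlap,
linear detrend per segment; 0.78 Hz bins at 800 Hz sampling), and
`detect_rotation()` picks the highest peak in the body band (default
5–40 Hz) and the flagellar band (50–350 Hz), accepting a peak only when it
exceeds five times the median in-band power. A band with no prominent peak
reports "no peak" rather than a guess, and the motor frequency — the sum
of the two lab-frame rates — is only reported when both are present. This
periodogram estimator is deliberately simpler than a full
scattering-anisotropy imaging model; it preserves the observable contract
(two rotation peaks, motor = sum) that the swimming model consumes.

## Synthetic data and what passing tests mean

Every pipeline input can be generated with ground truth attached, as a
pure function of parameters and seed:

* `generate_motility_movie()` — defaults 256 × 256 px at 0.7 µm/pixel,
  1000 frames at 100 fps, 2000 particles. Swim directions are drawn on the
  3-D unit sphere and observed in 2-D projection: that is the imaging
  geometry of a thick sample, and it is what makes the swimmer ISF the
  sinc average the fit model assumes (in-plane-only directions would give
  a Bessel-function ISF instead and bias the fitted speed upward by tens
  of percent). Spots are bilinearly placed with sub-pixel accuracy,
  convolved with a Gaussian PSF (σ = 1.5 px), on periodic boundaries, with
  additive Gaussian noise. Swimmers travel in straight lines within a
  movie (a tumble rate is available, default 0). The movie length is a
  desk-scale stand-in for a 10,000-frame acquisition; 1000 frames keep the
  structure-function statistics sufficient for the tolerances tested.
* `generate_flicker_trace()` — two random-phase sinusoids plus noise at
  800 Hz, 10 s.
* `generate_flagellation_table()` — per-cell counts and lengths around
  the coupling means; with zero noise the table lies exactly on the curves
  (real-valued counts, so noiseless round trips are exact), with noise the
  counts are non-negative integers.

What the recovery tests demonstrate: on these synthetic conditions the
full chain — generator, structure function, per-q fitting, aggregation —
returns the swimming fraction within ±0.05, the mean swimmer speed within
±10%, and the diffusivity of a pure-diffusion control within ±5%, and the
flicker analysis recovers injected rotation rates within one spectral bin
down to SNR ~3. What they do not demonstrate: performance on real imagery.
The generator renders isotropic Gaussian spots, not phase-contrast rings
or dark-field speckle; cells are monodisperse in brightness; there is no
drift, bleaching, defocus or depth-of-field variation; and swimmer
decorrelation from run–tumble dynamics is absent. These are fidelity
limits of the emulation, not of the estimators.

## Numerical choices and degenerate inputs

* Double precision throughout; balance residuals checked to 1e-10
  relative on every solve.
* A spherical cell body (length = width) is handled by the exact Stokes
  limit of the Perrin factors (eccentricity cutoff 1e-6), not an error.
* Achiral helices ($\psi \to 0$ or $90°$) give $v = 0$ through $B = 0$;
  the torque balance still partitions the motor rate between bundle and
  body.
* A static movie gives an identically zero structure function; pure
  camera noise gives a lag-independent floor $B(q)$ — both are tested.
* Ties in peak detection cannot occur on a continuous spectrum;
  `which.max` takes the first bin in the (measure-zero) event of an exact
  tie.
* Generators save and restore the caller's RNG state, so seeded pipelines
  compose without interference.

## Problem sizes

The default test-and-analysis sizes were chosen as the smallest that make
the statistical tolerances above comfortable: acquisition-scale movies
(256 × 256 × 1000 frames) for the headline DDM recovery, 128-px movies for
unit-level round trips, ensembles of 400–5000 cells, 10-second flicker
traces. The analysis scripts under `analysis/` print the recovered-versus-
true comparisons and write them under `results/`.

## Known limitations

* RFT ignores hydrodynamic interactions between filament turns, between
  bundle and body, and filament flexibility; the single-flagellum case is
  the least reliable (a lone filament is not rigid).
* No bundling/unbundling dynamics, no inter-filament solid friction, no
  motor torque–speed regulation: the motor is a fixed-speed constraint by
  assumption, which is the regime the rotation-frequency data support.
* The wobble angle is an input distribution, not a prediction.
* The DDM model assumes ballistic swimmers and one shared diffusivity;
  whether the swimmer term should carry its own diffusivity is not
  resolvable from the synthetic conditions and is left as the single-$D$
  form.
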