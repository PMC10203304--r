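---
title: "Shell inversion and rate estimation in spherical phototrophic granules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shell inversion and rate estimation in spherical phototrophic granules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granulr)
```

## The problem

Phototrophic granules are self-aggregated spheres, typically 2–4 mm across,
in which cyanobacteria, algae, nitrifiers, denitrifiers and other
heterotrophs coexist along steep radial gradients of light, oxygen and
nitrate. A microsensor driven along a radius returns a depth profile of
concentration; at steady state, the curvature of that profile encodes where
the community produces and consumes the analyte. In a flat biofilm a linear
profile means pure diffusion; in a sphere it does not, because the area
through which diffusion acts scales with $r^2$. Rates must therefore be
recovered with the spherical geometry built in. `granulr` implements that
recovery — the *shell inversion* — together with the incubation-based
estimators that complement it (dark-shift photosynthesis, $^{15}$N tracer
slopes, light attenuation, radiograph normalization) and a forward
simulator used to verify all of them.

## Coordinates, units, and sign conventions

Profiles are recorded as depth $z$ (µm) from the aggregate surface along a
radius, increasing into the granule; internally $r = R - z$ with $R$ the
granule radius. Depth 0 is the surface; negative depths are
diffusive-boundary-layer points, retained for plotting and excluded from
inversion (the inversion applies inside the aggregate). Canonical internal
units are µm, s and nmol: 1 µmol L$^{-1}$ = $10^{-12}$ nmol µm$^{-3}$.
Rates are reported in nmol h$^{-1}$ per shell or per granule and
nmol mm$^{-3}$ h$^{-1}$ volumetrically.

Interface fluxes follow Fick's first law with the outward direction
positive, $J = -D\,\partial C/\partial r \cdot 4\pi r^2$. Net shell rates
are flux divergences, $P_i = J_{\text{out},i} - J_{\text{in},i}$, so
production is positive and consumption negative, and the shell rates sum
telescopically to the surface flux — the only convention under which the
whole-granule budget is conserved at steady state.

## The shell grid and why the inversion is exact on quadratics

Shells are centred on the measurement radii with interfaces at the
midpoints between adjacent radii (a staggered grid). The two-point
difference $(C_k - C_{k+1})/(r_k - r_{k+1})$ equals the true derivative at
the midpoint whenever the profile is locally quadratic in $r$ — which is
exactly the form steady-state zero-order kinetics produce. Two closure
choices complete the grid:

* **Centre.** The innermost shell always extends to $r = 0$, where
  spherical symmetry forces zero flux. When the profile stops short of the
  centre the unmeasured extent is reported (`unmeasured_core_um`) rather
  than extrapolated; the unmeasured region contributes zero net rate. This
  is the conservative choice — nothing defensible can be said about an
  unmeasured core from a diffusion profile alone.
* **Surface.** The outermost interface sits at $r = R$, where no measured
  pair straddles the interface. Its gradient is obtained by linear-in-$r$
  extrapolation of the two outermost midpoint gradients. For a quadratic
  profile $dC/dr$ is linear in $r$, so the extrapolation is exact; with
  only two measured points the single available gradient is used
  unchanged.

Together these make the inversion *exact* (relative error $< 10^{-9}$,
in practice $\sim 10^{-14}$) on the uniform-consumption reference solution
$C(r) = C_R - q(R^2 - r^2)/(6D)$ at any measurement spacing, uniform or
not — the property the test suite checks first, and a useful field
calibration: any implementation that fails it is quietly mislocating
gradients.

Diffusion coefficients default to 2000 µm$^2$ s$^{-1}$ for oxygen and
1700 µm$^2$ s$^{-1}$ for nitrate (free-solution values commonly used in
microsensor work); both can be overridden per call, e.g. to correct for
temperature or EPS-reduced effective diffusivity.

## Noise, smoothing, and degenerate inputs

Differencing amplifies noise: with sensor noise $\sigma$ the flux noise
scales as $\sigma / \Delta z$ and shell rates difference the fluxes again.
No smoothing is applied by default — the inversion reports what the data
say. An optional Savitzky–Golay pre-smoother (`smooth = TRUE`, polynomial
order and window recorded in the output) is available for noisy profiles;
it requires uniform spacing and preserves quadratics when the order is
$\ge 2$, so it does not bias the exactness property. Duplicate depths,
non-finite concentrations, negative concentrations and profiles with fewer
than three in-granule points are rejected with messages naming the
offending values; depths beyond the radius are rejected by name unless
explicitly truncated (never silently).

## Dark-shift photosynthesis

Immediately after darkening, gross photosynthesis stops while consumption
and transport continue unchanged, so the initial rate of oxygen decline at
a depth equals the local gross photosynthesis. `gross_photosynthesis()`
fits an OLS line (with intercept — blanks need not be zero) over a window
defaulting to the first 5 s, capped at 10 s, and sign-flips the slope.
Rising oxygen is returned as a negative rate with a warning flag, not an
error, because it is diagnostic (e.g. probe outside the photic zone).

The method has a validity region set by diffusion. After light-off the
field relaxes from the boundaries inward over a penetration depth
$\sim\sqrt{D t}$ ($\approx$ 100 µm for oxygen at 5 s); the window-averaged
slope at distance $d$ from a fixed-concentration surface is attenuated by
roughly the window average of $\mathrm{erfc}(d / 2\sqrt{D t})$. In a
500-µm photic layer the simulator shows the 5-s, 1-Hz estimate is biased
low by $\approx$ 6 % at 200 µm depth but $\approx$ 3 % through the
mid-layer band (250–300 µm). Probes should sit several diffusion lengths
from both the surface and the layer edge; the verification suite places
them at 250, 275 and 300 µm, where recovery is within 5 %. Whole-granule
photosynthesis follows by `integrate_point_rates()` over the shell grid
(with `umol_l_s_to_nmol_mm3_h()` bridging the units).

## $^{15}$N tracer slopes

Closed vials amended with $^{15}$N-labelled ammonium or nitrate are killed
at successive times; headspace $^{29}$N$_2$ and $^{30}$N$_2$ excesses and
the NO$_x$ pool are measured. Total excess $^{15}$N is
$^{29}$N$_2 + 2\cdot{}^{30}$N$_2$. Denitrification is the OLS slope of
total excess $^{15}$N against time; nitrification is the slope of (total
excess $^{15}$N + NO$_x$) — extracellular nitrate/nitrite production plus
the labelled N$_2$ already denitrified from it, which makes the estimate
insensitive to how fast the produced NO$_x$ is passed on. All fits keep
their intercept (the timepoint-0 blank may be nonzero) and report the
standard error of the slope. NO$_x$ measured as a concentration is
converted to a vial amount with `nox_amount()` — vial volume minus
headspace is a required input, not a hard-coded vial size.

With the usual four kill times the slope has only two residual degrees of
freedom, so "$\pm 2$ standard errors" is *not* a 95 % interval ($t_2$
covers $\approx 82$ % at $\pm 2$ SE); confidence intervals must use the
$t$ quantile. The verification suite checks exactly this: over 200 seeded
synthetic series (nitrification 30, denitrification 10 nmol h$^{-1}$,
noise 10 % of final amounts) the 95 % $t$-interval covers truth 96–98 % of
the time, within the accepted [90 %, 99 %] band, and noiseless series are
recovered with zero standard error.

## Light attenuation

`light_attenuation()` renormalizes each wavelength to its surface value,
averages the requested band per depth, and fits
$I(z) = e^{-kz}$ by log-linear OLS; $z_p = -\ln p / k$ gives the depth at
which a fraction $p$ (default 0.1) of surface light remains. Wavelengths
whose relative irradiance rises *above* the surface value at depth —
photopigment fluorescence or scattering with weak absorption, typically at
700–800 nm — would bias $k$ low and are excluded from the fit
automatically and reported separately. A non-attenuating field yields
$k = 0$ with `z_p` undefined and a flag rather than an error.

## The forward simulator as oracle

`granule_scenario()` defines ground truth: concentric layers with
zero-order (concentration-independent) volumetric rates, optionally split
into a base (dark) rate and a gross-photosynthesis rate active in the
light; a bulk concentration fixed at the surface (the default, since
profiles are measured from stirred bulk) or a boundary-layer mass-transfer
condition; exponential optics; a noise level; one shared seed for all
stochastic draws. Zero-order kinetics were chosen deliberately: the shell
inversion is kinetics-free, zero-order admits closed-form checks, and
saturating (Monod) kinetics would only blur the comparison; they remain an
extension hook.

`solve_steady_state()` discretizes
$\frac{D}{r^2}\frac{d}{dr}(r^2 \frac{dC}{dr}) = -Q(r)$ with a conservative
finite-volume scheme on a uniform radial grid (default 5 µm), cell sources
taken as exact $r^3$-weighted layer averages. The scheme is exact for
uniform $Q$ and second-order otherwise; halving the grid changes the field
by $< 0.1$ %, and the one-sided surface flux balances the volume-integrated
realized source to $< 0.5$ %. Where zero-order consumption would drive
$C < 0$ the solver switches it off: the resulting complementarity problem
is solved by bisection on the oxic–anoxic front index, using the fact that
the centre concentration increases monotonically as consumption is
deactivated outward from the centre. The front lands within one grid cell
of the closed-form zero-order front, the core is flat at
$C \approx 0$, and the realized (front-gated) source field — not the
nominal one — is what `sample_profile()` attaches as ground truth. A
scenario whose anoxia is not a single centred core is rejected with an
error naming the offending radii rather than mis-solved.

`solve_dark_shift()` integrates the transient by the method of lines
(`deSolve::lsoda`, banded Jacobian, `rtol = atol = 10^{-8}`) from the
illuminated steady state with photosynthesis switched off; mass is
conserved to well under 1 % drift over 60 s. `sample_profile()`
interpolates the fine grid at measurement depths, adds seeded Gaussian
noise, clips at zero, and attaches per-shell ground truth volume-averaged
over the same shell grid the inversion will build — closing the
forward–inverse loop: the three-layer verification scenario (production
0.4 µmol L$^{-1}$ s$^{-1}$ in the outer 500 µm, inert middle, weak core
respiration, solved at 5 µm, sampled at 50 µm) is recovered within 2 % in
every non-inert shell.

The isotope generator accumulates labelled N$_2$ linearly and splits it
$2F(1-F) : F^2$ between $^{29}$N$_2$ and $^{30}$N$_2$ by random isotope
pairing — an explicit modelling assumption; real pairing depends on the
ambient $^{14}$N pool. Amounts are floored at zero, which slightly raises
the time-zero blank under noise (a visible but small intercept effect; the
slope estimators are insensitive to it by design).

### What the generator does and does not emulate

It emulates: spherical diffusion with literature coefficients, layered
zero-order stratification, anoxic cores, boundary layers, exponential
light attenuation with near-infrared excess, additive Gaussian sensor
noise, linear-in-time tracer accumulation. It does not emulate: coupled
multi-species stoichiometry (no O$_2$–NO$_x$–acetate feedback), saturating
or light-dependent kinetics, sensor drift, stirring artefacts, granule
asphericity, or tortuosity/EPS effects on diffusivity. Passing the
round-trip tests therefore demonstrates the *estimators* are correct under
their stated assumptions, not that real granules satisfy those
assumptions; on real data the leading uncontrolled terms are effective
diffusivity and deviation from steady state.

## Default parameter summary

| parameter | default | unit | rationale |
|---|---|---|---|
| D (oxygen) | 2000 | µm² s⁻¹ | standard free-solution value at ~ room temperature |
| D (nitrate) | 1700 | µm² s⁻¹ | standard free-solution value |
| granule radius (verification scenarios) | 1800 | µm | a typical 3.6-mm photogranule |
| bulk concentration | 250 | µmol L⁻¹ | near air saturation, slightly supersaturated |
| dark-shift window | 0–5 (cap 10) | s | before diffusion re-equilibrates |
| attenuation coefficient (optics) | ln(10)/600 | µm⁻¹ | 90 % of light absorbed within 600 µm |
| steady-state grid | 5 | µm | exactness/convergence demonstrated at this spacing |
| kill times (isotope) | 0, 2, 4.5, 5.5 | h | a realistic four-vial closed-vial design |

## Problem sizes

The verification suite and `scripts/acceptance.R` run the steady solver on
361-node grids (721 for the convergence check), 100 random profiles for
conservation, 200 seeded isotope series per calibration, a 6-s transient at
1 Hz output, and $10^4$ noise draws for the sampling-bias bound — small
enough to re-run in seconds while exercising every code path.

## Known limitations

* The inversion assumes steady state, radial symmetry, and constant $D$;
  none is checked from data, because none can be.
* An unmeasured core is assigned zero net rate; a profile that stops short
  of the centre cannot distinguish a dead core from one in equilibrium.
* Shell rates amplify sensor noise as spacing shrinks; smoothing trades
  variance for resolution and is therefore opt-in and recorded.
* Dark-shift estimates are biased low near layer boundaries and the
  surface (see above); depth placement matters more than window length.
* Radiograph rates are only relative until a count-to-mol conversion is
  supplied; region segmentation is the caller's responsibility.
* `reactor_scale_rate()` assumes every granule converts at the supplied
  per-granule rate — a deliberate, transparent simplification for
  scenario arithmetic, not a reactor model.
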