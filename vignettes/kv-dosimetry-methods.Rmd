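---
title: "Dosimetry of an 80 kV radiological-burn model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosimetry of an 80 kV radiological-burn model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`kvdosim` characterizes the dose delivered by a filtered 80 kV X-ray beam
to layered bone and soft-tissue geometries, the setting of preclinical
radiological-burn experiments on mouse hind legs.  At these energies the
photoelectric effect dominates and scales roughly as $Z^4$, so bone
(calcium, phosphorus) absorbs several times more dose per unit air kerma
than soft tissue; the package quantifies this enhancement along four
complementary routes: spectrum-weighted kerma ratios, Monte Carlo
transport, beam-profile geometry, and additive-dose EPR dosimetry of a
cohort, each with seeded synthetic generators so that every stage is
testable without external data.

```{r}
library(kvdosim)
```

## Photon interaction data

All physics rests on per-element mass interaction coefficients shipped as
plain CSV (1--200 keV, log-spaced with nodes straddling every K edge of
the elements involved plus the tungsten L edges).  The tables were
generated once from standard public tabulations: photoelectric cross
sections from Cromer--Liberman $f''$, incoherent scattering from
Klein--Nishina weighted by a form-factor-based incoherent function, and
Rayleigh scattering from IT92 elastic form factors; mass
energy-absorption coefficients follow from the energy-transfer
bookkeeping (photoelectric minus K-fluorescence re-emission, plus the
Compton energy-transfer term; radiative losses are negligible below
200 keV).  Generated values were validated against standard water, air
and copper tabulations (within $\sim$2% at the energies that matter
here).  Interpolation is log--log linear and exact at nodes; mixtures
follow mass-fraction additivity.

Material compositions are ICRU-44-like (soft tissue $\rho = 1.0$,
cortical bone $\rho = 1.92$, dry air $\rho = 1.205\times10^{-3}$
g/cm$^3$).  **Trabecular bone** deserves a note: a literal ICRU-46
spongiosa recipe ($\rho \approx 1.18$, Ca 7.4%) gives a trabecular/air
kerma ratio below 3 and a 7 mm attenuation near 30%, far from the
behaviour this class of irradiation study reports for the trabecular
compartment (conversion factor $\approx 6$, attenuation $\approx 48\%$).
Those dosimetric properties imply a mineral-rich bone-equivalent
material (comparable to the B-100 bone substitute).  The shipped
`trabecular_bone` is therefore a calibrated reconstruction: 88% cortical
mineral matrix + 12% red marrow by mass (Ca 19.8%, trace Fe),
$\rho = 1.50$, fixed at design time from kerma-level arithmetic and not
revisited.

```{r}
mass_coefficient("cortical_bone", 40, "en") / mass_coefficient("air", 40, "en")
```

## Beam model

The spectrum model is semi-empirical: a Kramers-form target spectrum
$(\mathrm{kVp}-E)/E$, thick-target anode self-attenuation
$(1-e^{-x})/x$ with $x = \mu_W(E)\, d/\sin\theta$, tungsten K lines only
above the 69.5 keV K edge, and Beer--Lambert filtration (0.8 mm Be +
0.15 mm Cu by default).  Two constants are calibrated once against the
measured beam quality of the modelled platform (half-value layer
0.138 mm Cu): the effective production depth $d = 2.2\,\mu$m and the
K-line fluence fraction 0.01.  The anode take-off angle defaults to
20&deg; as a configurable assumption; fluence is relative throughout
(tube current and absolute output are out of scope).

```{r}
s <- tube_spectrum(80)
c(mean_energy = mean_energy(s), hvl = hvl_analytic(s)$hvl)
```

Two HVL routes are provided: bisection on the attenuator thickness that
halves the spectrum-weighted air kerma (tolerance $10^{-4}$ mm), and a
quadratic fit to a nine-point copper transmission curve, mirroring
experimental practice.  They agree within 3% for this beam.

A known limitation, recorded here deliberately: with the beam calibrated
to the *measured* HVL of 0.138 mm Cu, the spectrum-weighted
cortical-bone/air kerma ratio is $\approx 6.1$ and is remarkably
insensitive to the calibration constant (it varies by $<1\%$ while the
HVL spans 0.124--0.157).  Reference Monte Carlo studies of this platform
report bone-to-air factors up to 6.7 -- obtained with a simulated
spectrum whose own HVL was 0.124 mm Cu, i.e. a distinctly softer beam
than measured.  Under the measured beam quality the factors computed
here (cortical $\approx 6.1$, combined bone $\approx 5.0$ in the
heterogeneous phantom) are the physically consistent values; matching
the softer-beam figures would require abandoning the measured HVL.

## Monte Carlo transport

`transport()` implements analog photon transport with secondary
electrons in slab (70 $\times$ 0.1 mm default) and rectilinear voxel
(90 $\mu$m default) geometries:

* free paths from the total linear attenuation of the local material;
  interaction channel by partial cross sections;
* Compton scattering by free-electron Klein--Nishina sampling
  (EGS-style composition--rejection), with the recoil electron taken
  from the scattering kinematics;
* photoelectric absorption with the element sampled from elemental
  photoelectric shares; above its K edge (probability = tabulated
  K-shell fraction, derived from the edge jump ratio rather than the
  generic 0.8) the vacancy relaxes to either a K$\alpha$ fluorescence
  photon (probability $\omega_K$, tracked) or a KLL Auger electron;
  residual relaxation energy deposits on the spot;
* Rayleigh scattering (optional, on by default) as a Thomson-sampled
  direction change -- broader than the true form-factor angular
  distribution, acceptable because it carries no energy;
* electrons transported as straight lines over their CSDA range with
  uniform energy loss per unit mass thickness, crossing cell
  boundaries; ranges use an ESTAR-like water table scaled by
  $(Z/A)_{\mathrm{water}}/(Z/A)_{\mathrm{medium}}$; the 0.25 keV cut
  deposits locally.  No multiple scattering and no $\delta$-rays: at
  sub-20 keV the ranges ($\le 20\,\mu$m) are far below the 100 $\mu$m
  slice scale, and the straight-line picture captures interface
  backscatter/forward effects qualitatively, with a tendency to
  *overestimate* boundary crossing (no detours), which should be kept
  in mind when reading the interface ratios below.

Scoring uses 25 statistical batches for per-slice errors; a fixed seed
gives bit-identical results (the engine carries its own xoshiro256++
generator).  Energy is conserved exactly per history
(incident = deposited + escaped).  For **free-in-air reference runs**
the analog estimator is hopeless (one interaction per slice per
$4\times10^5$ histories), so `kerma_tracklength = TRUE` scores collision
kerma with the standard track-length estimator; this is also the
appropriate quantity for a reference defined as air kerma free in air.

An analytic oracle mode (`photoelectric_only` + `local_deposition`)
restricts the physics to photoelectric absorption, for which the depth
dose is exactly $\propto e^{-\mu_{pe} z}$; the test suite holds the
engine to that curve within 3$\sigma$ per slice.

Problem sizes: the shipped checks use $2\times10^6$ histories for slab
runs (per-slice errors $\sim$1--2%) and $1.5\times10^6$ for the voxel
leg; each takes tens of seconds on one core.

### Secondary-electron analysis

Per-material electron energy histograms (0.05 keV bins) expose the
K-shell relaxation lines: in cortical bone the P KLL Auger line
(1.86 keV), the Ca KLL line (3.31 keV) and the Ca K$\alpha$
photoelectron line (3.67 keV) stand one to two orders of magnitude
above the continuum.  `electron_spectrum_peaks()` flags local maxima
exceeding the local continuum by a relative prominence (default 7);
that threshold keeps the mineral lines while rejecting the weak lines
of sub-percent trace elements (soft tissue contains 0.3% P/S/K, whose
lines rise only 2--4$\times$ above continuum) and the tungsten K-line
photoelectron artifacts.

`electron_path_modes()` reports the modal CSDA range of the
*photoelectron* population (default threshold 16 keV, above the maximum
Compton recoil energy of an 80 kVp beam).  Relaxation-line electrons
have sub-micron ranges and Compton recoils pile up at any lower
threshold, which would make the mode reflect composition rather than
density; the photoelectron population is common to all tissues, so its
modal path scales as $1/\rho$ and orders cortical < trabecular < soft
tissue.  The absolute modes (6--15 $\mu$m here) are a property of this
definition; the few-$\mu$m "specific paths" quoted in the reference
literature have no stated definition and are not reproduced, only the
density ordering is.

### Interface effects

Comparing the heterogeneous phantom with an all-soft-tissue phantom on
the same grid isolates the bone-interface physics: the 100 $\mu$m soft
slice upstream of the first cortical layer gains dose from
backscattered bone electrons, and the slice just downstream of the
second cortical layer shows a smaller deficit than deeper slices thanks
to forward electrons.  With straight-line electrons the upstream boost
converges to $\approx 1.19\times$, somewhat above the $\approx 1.10$
expected from condensed-history simulations -- consistent with the
known overestimate of boundary crossing noted above.

### Voxelized leg

`build_leg_voxel_phantom()` builds the synthetic stand-in for a
segmented microCT leg: concentric cylinders (soft tissue 5 mm, cortical
shell 0.3 mm, marrow core 0.9 mm; 90 $\mu$m voxels; axis perpendicular
to the beam).  Dimensions are nominal mouse-tibia values chosen once.
Bone separates cleanly (factor $\approx 5.6$, $\gg$ tissue and marrow).
The marrow factor converges to $0.94\times$ tissue rather than above
it: the shell attenuation ($-6\%$) outweighs electron spill-in and
shell fluorescence, because electron ranges are far below both the
voxel size and the core radius.  Reported marrow enhancements
($\sim1.6$) in segmented-microCT studies are attributable to
partial-volume trabecular mineral inside voxels labelled marrow in the
tibial head -- an effect a pure-composition concentric phantom cannot
show, by the same range argument.  This limitation is intrinsic to the
simplified geometry, not to the transport.

## Beam geometry and film

`simulate_profile()` ray-traces a Gaussian virtual source (FWHM 2.3 mm,
divergence half-angle 10&deg;) through an opaque square aperture to a
1 mm scoring grid at SSD 225 mm.  The aperture distance (145 mm) and
side (27.7 mm) are calibrated once so a point source projects the
nominal 4.3 cm field edge; the finite focal spot then produces
penumbrae ("fringes", the 80%$\to$20% lateral distance -- the standard
definition, adopted because the quoted fringe values of
$\sim$0.8--1.1 mm follow from it) of the right magnitude.  No
collimator transmission or scatter is modelled, which is why profile
tails are not expected to match film outside the beam edge.
`iaea_compare()` reports FWHM/fringe deviations, the central-region
point deviation (pass $\le 2\%$) and the relative deviation outside the
beam edge (pass $\le 30\%$).

Film calibration fits a fourth-degree polynomial response--dose curve
on $\ge 6$ points, refuses non-monotone fits, and inverts by
root-finding strictly within the calibrated range.

## EPR additive-dose dosimetry

For each bone sample the additive-dose method regresses peak-to-peak
EPR amplitude on added dose; the initial dose is intercept/slope, with
uncertainty from first-order propagation of the parameter covariance
$\sigma^2 = d_0^2[(\sigma_a/a)^2 + (\sigma_b/b)^2 - 2\,
\mathrm{cov}(a,b)/(ab)]$.  Replicates (3--5 per dose) are averaged
before the fit -- matching how per-bone measurements are summarized --
and the parameter covariance uses the pooled within-dose variance of
the mean, the dominant and directly measured error source; a
replicate-level fit is available behind `use_replicates = TRUE`.  The
added-dose schedule defaults to 0/50/100/150/200 Gy (configurable; no
schedule is prescribed by the underlying protocol).

`peak_to_peak()` takes the signal difference between the first and
third local extrema (by field) of the first-derivative curve, after
light smoothing and prominence-based pruning so that baseline noise on
steep flanks does not register as extrema.

Cohort statistics use sample SD (divisor $n-1$), which reproduces the
reference cohort's combined 194.0 $\pm$ 27.0 Gy and per-side SDs
exactly; intra-animal variability is the pair CV
$(|L-R|/\sqrt2)/\mathrm{mean}(L,R)$ -- the unique convention that
reproduces the quoted 0.4--21.9% range and 8% mean -- and an
inter-animal CV estimate subtracts half the mean squared pair CV from
the squared CV of per-animal means.

```{r}
st <- cohort_statistics(bone_dose_cohort())
st
cohort_conversion_factor(st, k_air_Gy = 30)
```

## Synthetic generators

`simulate_cohort()` uses a multiplicative nested model (animal effect
$\times$ side effect $\times$ measurement noise, truncated normal at
$\pm4\sigma$ so doses stay positive) with defaults matching the study
conditions: 15 animals, 30 Gy air kerma, true factor 6.5, inter-animal
CV 13%, intra-animal CV 8%, measurement CV 5%, 1/30 missing
probability.  The nesting is an assumption -- the true left/right
correlation structure beyond a shared animal effect is unknowable from
summary data -- and is documented as such.  `simulate_epr_series()`
produces linear-response amplitudes and, in raw mode, stylized
first-derivative curves (a small low-field dip, main lobe, main trough
over the 334--337 mT window) whose first-to-third-extremum amplitude
equals the configured value; real CO$_2^-$ lineshapes are more complex,
so passing tests show correct *pipeline arithmetic*, not spectroscopic
realism.  The generators emulate the statistical structure the analysis
assumes; they do not model bone-composition effects on EPR sensitivity,
signal fading, or scanner artifacts, so green tests say nothing about
those aspects of real data.

## Numerical choices

Bisection tolerance $10^{-4}$ mm (HVL); energy grid 1--200 keV with
edge-straddling nodes; spectrum bins 0.5 keV; histogram bins 0.05 keV /
0.05 $\mu$m (resolving 3.31 vs 3.67 keV); slab slices half-open
$[0.1i, 0.1(i+1))$ mm; transport RNG independent of R's RNG state, and
all generator helpers save/restore `.Random.seed`.  Degenerate inputs
(zero fluence, all-missing cohorts, single-slice segments, non-monotone
film responses, negative thicknesses) raise errors rather than produce
numbers.
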