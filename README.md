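# pgrange

**3D reconstruction of the prompt-gamma emission maximum for proton-therapy
range verification.**

`pgrange` localises the end of range of a clinical proton pencil beam from
the prompt gamma (PG) rays emitted by excited ¹⁶O nuclei along the track.
It targets the 2.741 & 6.128 MeV *couple* from the ¹⁶O cascade
2⁻ → 3⁻ → g.s.: the two de-excitation gammas are emitted effectively
simultaneously (~25 ps apart) from the same point, so a coincident detection
in two modules of an uncollimated 16-crystal LaBr₃(Ce) time-of-flight
spectrometer constrains their common emission point geometrically. The
package is aimed at medical-physics researchers prototyping in-vivo range
verification and at anyone who needs a tested implementation of the
sphere–torus coincidence reconstruction.

## The algorithm

For each registered gamma *i* the spectrometer provides the detector id, the
deposited energy `E_i`, the emission-to-arrival time `t_i`, and the last-hit
coordinates `(x_i, y_i, z_i)`. The reconstruction proceeds in three stages:

1. **Couple selection.** Coincident pairs in different detectors with one
   energy in 2.659–2.823 MeV and the other in 5.946–6.321 MeV (windows
   reflecting the 3 % FWHM energy resolution of LaBr₃(Ce)) are kept;
   everything else is rejected.
2. **Couple analysis.** Each event defines a sphere centred on its hit with
   radius `r_i = t_i · c`. The two spheres of a couple intersect in a
   circle — the locus of possible common emission points. The circle is
   fattened into a torus with a 3 mm tube radius that absorbs the
   hit-position uncertainty.
3. **Emission-position reconstruction.** Every torus surface is
   triangulated, clipped to the spectrometer central volume, and intersected
   with every other torus using a Möller triangle/triangle interval test.
   The centre of each non-empty intersection region is stored as a *virtual
   emission position*. Histogramming the virtual positions in 1 mm³ voxels
   and fitting a Gaussian `A·exp(−(z−μ)²/2σ²)` to the depth marginal yields
   the emission maximum μ and its spread σ.

Because PG emission peaks ~2 mm proximal to the Bragg peak (the production
cross sections peak near a residual proton energy of 13.5 MeV ≈ 2.2 mm
residual range), μ is a direct surrogate for the beam range. The package
also ships an analytic Bragg–Kleeman beam model (`R = αE^p`, water constants
α = 2.2·10⁻³ cm·MeV⁻ᵖ, p = 1.77) and a seeded Monte-Carlo event generator
(beam sampling, ray/crystal transport, detector response) that stands in for
a full transport simulation, so the whole pipeline runs self-contained.

## Worked example

A scaled-down 180 MeV run in the 8 cm spectrometer (≈ 340 selected couples):

```r
library(pgrange)
cfg <- pg_config(n_couples = 180000L, E0 = 180, R_spec = 8, seed = 11L)
res <- run_pipeline(cfg)
print(res)
#> prompt-gamma range reconstruction (R_spec = 8 cm, E0 = 180 MeV)
#>   emission maximum depth: mu = 21.37 +/- 0.01 cm, sigma = 4.63 mm
#>   expected (beam model):  21.35 cm;  shift = +0.2 mm
#>   positions: 33529 from 318 tori (18875 null pairs)
```

The reconstructed emission maximum sits at a depth of 21.37 cm in the
phantom — 2 mm proximal to the 21.60 cm Bragg peak of a 180 MeV beam — with
a spread of ≈ 4.6 mm; `shift` compares the fit against the beam model's
expected emission maximum. Lowering `E0` to 175 MeV (a 10 mm range
undershoot) moves μ to ≈ 20.3 cm:

```r
res175 <- run_pipeline(pg_config(n_couples = 180000L, E0 = 175, seed = 11L))
coef(res175)
#> mu_depth_cm    sigma_cm
#>  20.2697604   0.4820189
```

`plot(res)` draws the depth histogram with the fitted Gaussian overlaid.
A command-line front end with `simulate`, `reconstruct`, `report`, `run` and
`table1` subcommands is installed under `inst/exec/pgrange`.

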