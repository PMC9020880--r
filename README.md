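# vescav

Cavitation microbubble dynamics and wall stresses in elastic microvessels.

`vescav` is a desk-scale simulator for an ultrasound-driven air microbubble
confined inside a blood-filled elastic microvessel — the setting of
therapeutic cavitation at the micron scale, where the stresses an
oscillating bubble exerts on the vessel wall (circumferential "hoop"
stress, implicated in vessel rupture, and viscous wall shear, implicated in
membrane-level bio-effects) decide between therapy and injury.

Two tiers:

* **Radial tier.** The compressibility-corrected radial dynamics
  (Keller–Miksis) equation for a free spherical bubble,

  $$(1-\dot R/c)\,R\ddot R + \tfrac32(1-\dot R/3c)\,\dot R^2
    = \frac{R}{\rho c}\frac{dP_b}{dt}
    + \frac{1+\dot R/c}{\rho}\,(P_b - P_\infty - p(t)),
    \qquad
    P_b = p_{g0}\Big(\frac{R_0}{R}\Big)^{3k} - \frac{2\sigma}{R}
          - \frac{4\mu\dot R}{R},$$

  integrated adaptively (`solve_km()`), with the linearized resonance
  frequency, trace utilities and CSV/JSON export.
* **Coupled tier.** A half-symmetry tetrahedral finite-element model
  (`run_simulation()`): incompressible Navier–Stokes blood on a moving
  (ALE) mesh, a lumped polytropic gas bubble with Laplace–Beltrami surface
  tension, nearly incompressible linear-elastic vessel and tissue, a
  sponge absorbing outer layer, monolithic implicit coupling, and
  characteristic-impedance truncation of the vessel ends.  Post-processing
  extracts wall hoop/shear stress at nine azimuthal stations
  (`sample_wall_traces()`), bubble volume, centroid displacement,
  asymmetric ratio and microstreaming fields, with batch drivers for a
  bubble-offset sweep and a vessel-size sweep (`run_offset_sweep()`,
  `run_vessel_size_sweep()`).

The methods vignette (`vignettes/vescav-methods.Rmd`) documents the model,
the discretization and every numerical choice.

## Worked example

```r
library(vescav)

# free 2 um bubble under a 1 MHz, 130 kPa drive
tr <- solve_km(t_end = 2.5e-6)
tr
#> <radius_trace> 2001 samples over [0, 2.5] us
#>   R in [0.9377, 3.138] um
linear_resonance_frequency() / 1e6
#> [1] 1.66      # MHz

# coupled run: the same bubble centered in a 10 um vessel
mesh <- generate_mesh(geometry_spec(), "coarse")
mesh$quality
#> <mesh_quality_report>
#> 6704 tets (0 inverted), min dihedral 1.46 deg
#> bubble surface: 176 facets, volume deficit 5.017%

res <- run_simulation(mesh, config = solver_config(t_end = 1.5e-6))
summarize_stresses(sample_wall_traces(res))
```

The radius trace shows the familiar non-inertial cavitation cycle: growth
to ~3.1 µm during rarefaction, collapse to ~0.94 µm, at a resonance
frequency (1.66 MHz) above the 1 MHz drive.  The stress summary reports
the per-azimuth maxima of hoop and shear stress with the times at which
they occur; shear peaks at the wall point nearest the bubble and is the
quantity most sensitive to the bubble–wall gap.

A thin command-line driver ships in `inst/exec/vescav.R`:

```sh
Rscript inst/exec/vescav.R km --radius-um 2 --freq-mhz 1 \
    --pressure-kpa 130 --t-end-us 5 --out trace.csv
Rscript inst/exec/vescav.R sweep-offset --resolution reduced --out out/
```

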