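# pocketflim

Tools for relating the binding-pocket environment of an
environment-sensitive fluorophore to its fluorescence lifetime, and for
separating lifetime species in FLIM images by the phasor method.

Coumarin-pyridinium (COUPY) dyes change lifetime strongly with their
surroundings — roughly 1.4 ns free in aqueous solution and cells, up to
5.9 ns buried in the pocket of an engineered HaloTag variant. That makes
one dye usable as several imaging channels, *if* two analyses work:

1. **Pocket descriptors vs lifetime.** From predicted protein–ligand
   complex structures, the pocket is every amino acid with a heavy atom
   within 5 Å of the dye. Five descriptors are computed per predicted
   model — convex-hull volume and surface area, mean Kyte–Doolittle
   hydropathy, Shrake–Rupley solvent-accessible surface area, and the
   magnitude of the pocket dipole moment |Σ qᵢ(rᵢ − r̄)| — and each is
   correlated with measured lifetimes by Spearman's ρ (summarised as
   mean ± sd over the per-model correlations) with a protein-level
   bootstrap 95% CI for significance.
2. **Phasor-method FLIM unmixing.** Each pixel's TCSPC decay maps to
   phasor coordinates g = Σc·cos(ωt)/Σc, s = Σc·sin(ωt)/Σc at
   ω = 2π/T. Monoexponentials lie on the universal semicircle at
   g = 1/(1+ω²τ²), s = ωτ/(1+ω²τ²); mixtures combine linearly, so two or
   three reference species are unmixed per pixel by solving the
   barycentric system, with phase lifetime τ_φ = s/(ωg), modulation
   lifetime τ_m = √(1/(g²+s²)−1)/ω, and a Poisson maximum-likelihood
   monoexponential fit for cuvette decays.

A first-class synthetic-data module generates seeded TCSPC decays
(wrapped-exponential physics, optional Gaussian IRF), three-organelle FLIM
scenes (nucleus / Golgi ring / mitochondrial puncta at 5.5 / 5.9 / 1.4 ns),
and pseudo-protein structure sets with exactly known pocket dipoles and an
anticorrelated lifetime law — so every pipeline stage is testable with
known ground truth and no downloads.

Intended users: chemical biologists and microscopists developing
chemigenetic lifetime probes, and anyone needing a scriptable, provenanced
phasor-unmixing or pocket-descriptor pipeline in R.

## Worked example

Phase-lifetime recovery from a simulated 10⁶-photon TCSPC decay of the
protein-bound dye (5.9 ns, 25 ns laser period, 256 bins):

```r
library(pocketflim)
d <- simulate_decay(5.9, n_photons = 1e6, n_bins = 256, period = 25, seed = 1)
p <- phasor_transform(d)
p
#> pf_phasor: g = 0.31233, s = 0.46279 (omega = 0.25133 rad/ns, harmonic 1)
phasor_lifetime(p)
#> $tau_phase  5.9
#> $tau_mod    5.91
```

The phasor sits on the universal semicircle and both lifetime readings
agree with the generating value — the signature of a pure monoexponential.

Pocket arm, end to end on a synthetic 8-protein × 3-model structure set
generated with a dipole-anticorrelated lifetime law:

```r
ss <- simulate_structure_set(structure_set_spec(n_proteins = 8, n_models = 3,
                                                seed = 1), dir = "structs")
write.csv(ss$lifetimes, "structs/lifetimes.csv", row.names = FALSE)
res <- run_pocket_pipeline(list(structures = "structs",
                                lifetimes = "structs/lifetimes.csv",
                                out_dir = "out", seed = 1, n_boot = 2000))
res$report[, 1:6]
#>   descriptor rho_mean rho_sd  ci_lo  ci_hi significant
#> 1  volume_A3   -0.841 0.0137 -0.976 -0.282        TRUE
#> 2    area_A2   -0.833 0.0412 -0.976 -0.225        TRUE
#> 3 hydropathy   -0.595 0.0000 -1.000  0.308       FALSE
#> 4    sasa_A2   -0.889 0.0137 -0.982 -0.273        TRUE
#> 5  dipole_eA   -0.992 0.0137 -1.000 -0.795        TRUE
```

The dipole descriptor — the quantity the generator actually couples to the
lifetime — is recovered as strongly anticorrelated with a CI excluding
zero. (In this small synthetic geometry the hull and SASA descriptors are
partly collinear with the dipole, since a larger charge separation also
widens the pocket; hydropathy, which is independent by construction, is
flagged n.s.) The output directory receives `descriptors.csv`,
`correlation.csv`, `dipole_by_protein.csv`, a `run.log`, and
`config_used.yaml` recording every parameter, seed and package version, so
any run can be regenerated exactly.

FLIM arm: `flim_scene()` + `simulate_flim_image()` build a
three-organelle scene; `run_flim_pipeline()` writes per-component and
fraction TIFFs, a per-pixel phasor CSV and a JSON summary, with the
component images summing exactly to the masked total intensity.

A thin command-line front end over the same functions ships in
`inst/cli/pocketflim.R` (subcommands `pocket`, `flim`,
`simulate-structures`, `simulate-image`).

To run the pocket arm on real data instead: point `structures` at a
directory of predicted complex PDB/mmCIF files (one multi-model file per
protein, dye as a HETATM residue), supply a `protein_id,tau_ns` lifetime
CSV, and choose the charge scheme; descriptors are then comparable within
that named scheme.

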