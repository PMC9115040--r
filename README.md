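# elfxs

Energy-loss functions and inelastic electron cross sections from
linear-response dielectric theory, in R.

Monte Carlo track-structure codes (Geant4-DNA and its relatives) transport
electrons through liquid water event by event; everything they know about
inelastic collisions comes from the **energy loss function**

> ELF(E, q) = Im[ −1 / ε_M(E, q) ],

the imaginary part of the inverse macroscopic dielectric function over the
(energy loss E, momentum transfer q) plane — the Bethe surface.  `elfxs`
implements the complete chain from a random-phase-approximation (RPA)
linear-response description of a periodic system to the quantities those
codes consume, for people who build or benchmark such cross-section sets:

1. **Response stage.**  The independent-particle response
   χ⁰\_{GG′}(E, q) = (1/(N_k V_uc)) Σ\_{nmk} (f\_{nk} − f\_{mk+q})
   U^G U̅^{G′} / (E − (E\_{mk+q} − E\_{nk}) + iη)
   is assembled from band energies, occupations and plane-wave matrix
   elements U^G\_{nm,k}(q); the RPA Dyson equation
   χ = χ⁰[1 − vχ⁰]⁻¹ with the Coulomb kernel v\_{GG′} = 4πδ\_{GG′}/|q+G|²
   is solved by a dense linear solve, and the ELF is
   −(4π/q²) Im χ₀₀ — with crystal local-field effects (the off-diagonal
   G ≠ G′ couplings), or without them (head-only screening).
2. **Partition stage.**  Solving [1 − vχ⁰] V^eff = δ\_{G0} and applying χ⁰
   to the screened potential V^eff splits the ELF *exactly* into
   electron–hole pair terms, which can be regrouped by the occupied
   state's binding energy (the DELF), by species / angular momentum /
   species pairs through Mulliken weights of LCAO coefficients, or by
   molecular-orbital energy windows — for water the 2a1, 1b2, 3a1, 1b1
   channels.
3. **Cross-section stage.**  Plane-wave Born formulas turn any tabulated
   ELF surface into the double- and single-differential cross sections
   d²Σ/dEdq = ELF/(π a₀ T q),
   dΣ/dE = (1/π a₀ T) ∫ ELF(E,q)/q dq between the kinematic limits
   q\_min/max = √2(√T ∓ √(T−E)), the total inelastic cross section
   Σ(T) (inverse of the inelastic mean free path, IMFP) and the electronic
   stopping power S\_e(T), including per-channel versions.

Real ab initio water samples are out of scope; instead the package ships
fully testable stand-ins: a **jellium** generator whose response is checked
against the analytic complex **Lindhard function** (shipped as an oracle),
a gapped four-band **toy water** crystal whose occupied bands sit at the
measured liquid-water binding energies (30.90, 17.34, 13.50, 11.16 eV),
and parametric **Drude** ELF surfaces that satisfy the f-sum rule
∫ E·ELF dE = (π/2) ω_p² exactly.

## Worked example

```r
library(elfxs)

## a gapped four-band water-like crystal on a 2x2x2 k-mesh
water <- make_toy_water()
#> <ks_model: lcao>
#>   cell: cubic a = 6.000 bohr (V = 216.00 bohr^3)
#>   k-mesh 2x2x2 (8 points), 5 bands, 19 G-vectors
#>   E_F = -0.2319 Ha (-6.31 eV), gap = 0.3197 Ha, electrons/cell = 8.000

## macroscopic ELF at the optical limit of the mesh, with local fields
q0  <- 2 * pi / (2 * water$alat)          # 0.524 a.u.
E   <- seq(1, 45, by = 0.25)
elf <- elf_with_lfe(water, q0, E, eta = 1.0)
sprintf("ELF peak: %.2f at %.2f eV", max(elf), E[which.max(elf)])
#> "ELF peak: 1.43 at 18.00 eV"
```

A single dominant peak of height ≈ 1.4 near 20 eV is what inelastic X-ray
scattering measures for liquid water.  The ELF splits exactly into
species contributions (hydrogen and oxygen here add up to the 1.43 total):

```r
pairs <- pair_contributions(water, q0, 18, eta = 1.0)
round(project_labels(water, pairs, "species")$components, 4)
#>      H      O
#> 0.8012 0.6293
```

Per-molecular-orbital single-differential cross sections at T = 100 eV
(values in 1/(nm·eV); the channels sum to the total column exactly, and
each orbital owns one region of energy loss — 1b1 at the absorption onset,
1b2 at the main peak, 2a1 at high loss):

```r
ch <- mo_channel_elf(water, q_grid = q0 * c(1, 3),
                     energy_grid = seq(0.45, 45, by = 0.15), eta = 0.3)
cs <- channel_cross_sections(ch, T = 100)
round(cs[c(64, 111, 197), ], 5)
#>     energy   total      2a1      1b2     3a1     1b1
#> 64    9.90 0.01107 -0.00068 -0.00221 0.00009 0.01386
#> 111  16.95 0.08607 -0.00978  0.08800 0.00664 0.00121
#> 197  29.85 0.04451  0.03846  0.00513 0.00077 0.00015
```

IMFP and stopping power from a water-like Drude Bethe surface
(ω_p² = 462 eV², quadratic peak dispersion); the IMFP shows the
characteristic U-shape with its minimum of ≈ 0.5 nm near 100 eV:

```r
peaks <- drude_peaks(21.4, 10, 462, dispersion = "quadratic")
bethe <- make_drude_elf(peaks, energy_grid = seq(0.5, 5000, by = 0.5),
                        q_grid = exp(seq(log(0.1), log(60), length.out = 140)))
xs <- total_cross_section(bethe, T_grid = c(50, 100, 500, 1000, 5000))
as.data.frame(xs)[, 1:4]
#>     T sigma_total   imfp stopping
#>    50      1.0958 0.9126  17.5720
#>   100      1.9877 0.5031  50.7275
#>   500      0.8076 1.2382  27.0149
#>  1000      0.4716 2.1203  16.6874
#>  5000      0.1238 8.0777   4.7710
```

(Σ in 1/nm, IMFP in nm, S_e in eV/nm.)

ELF surfaces and cross-section tables read and write `#`-headed TSV files
(`read_elf_table()`, `write_elf_table()`, `write_xs_tables()`), and a thin
command-line pipeline is available through `elfxs_cli()` /
`inst/cli/elfxs.R` with subcommands `make-model`, `make-drude`, `elf`,
`partition` and `xs`.

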