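---
title: "Models, conventions and numerics behind elfxs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, conventions and numerics behind elfxs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elfxs)
```

# The model chain

`elfxs` computes the energy loss function ELF(E, q) = Im[−1/ε_M(E, q)] of a
periodic electronic system in the random-phase approximation and converts
it into the inelastic observables used by electron track-structure codes.
The chain is: a Kohn–Sham-like band model → the independent-particle
response χ⁰ → the RPA Dyson equation → the macroscopic ELF → Born-theory
cross sections.  This vignette records the conventions, default parameters
and numerical policies, and what the shipped toy systems do and do not
emulate.

## Units

Internally everything is in Hartree atomic units.  Public interfaces take
and return energies in eV and momentum transfers in atomic units of inverse
length; cross-section outputs use nm-based units (Σ in 1/nm, IMFP in nm,
S_e in eV/nm).  The conversion constants live in one place,
`elfxs_units` (1 hartree = 27.211386 eV, 1 bohr = 0.052917721 nm).

## The independent-particle response and its normalization

The response is assembled as

χ⁰_{GG′}(E, q) = (1/(N_k·V_uc)) Σ_{n,m,k} (f_{n,k} − f_{m,k+q})
U^G_{nm,k}(q) U̅^{G′}_{nm,k}(q) / (E − (E_{m,k+q} − E_{n,k}) + iη),

with U^G_{nm,k}(q) = ⟨Ψ_{n,k}| e^{−i(G+q)·r} |Ψ_{m,k+q}⟩ the
*dimensionless* overlap over one unit cell of cell-normalised states (a
Kronecker delta for plane-wave models).  The per-crystal-volume prefactor
1/(N_k·V_uc) is the convention under which ε = 1 − vχ⁰ is dimensionless
and a homogeneous-gas model reproduces the analytic Lindhard function;
other normalizations in circulation differ by factors of V_uc and are
absorbed here once.  Occupations carry the spin factor (f ∈ [0, 2]), so no
extra factor of two appears in the sum.  Terms with f_{n,k} = f_{m,k+q}
are skipped exactly; only occupied↔empty pairs contribute.

The Lindhard oracle is the closed form

χ⁰(q, z) = [J(z − q²/2) − J(z + q²/2)] / (2π²q³),
J(a) = aT + ((T² − a²)/2)·ln((a+T)/(a−T)),  T = k_F·q,  z = E + iη,

derived by elementary integration over the Fermi sphere and validated
against direct numerical integration; its static small-q limit is
−N(0) = −k_F/π².  It is used only in tests and the acceptance script,
never inside the response code.

## Broadening, grids and commensurability

* **η (Lorentzian broadening).**  Default 0.3 eV.  A useful spectrum needs
  η ≥ 2·ΔE of the energy grid; smaller values trigger a warning (not an
  error), and η = 0 is rejected.  On coarse k-meshes the discrete
  transition energies are spaced by roughly q·2π/(n_k·a) hartree; η should
  also exceed that spacing or the spectra show mesh ripple.  The jellium
  acceptance checks therefore use η = 1–1.5 eV on 16³ meshes.
* **ΔE.**  Default energy resolution 0.15 eV; ELF surfaces require a
  uniform energy grid.
* **q commensurability.**  A momentum transfer must connect k-mesh points:
  q·a·n_k/(2π) integer along the chosen direction.  Incommensurate q is an
  error naming the nearest commensurate magnitude.  The smallest
  representable q plays the role of the optical limit.  A q equal to a
  reciprocal lattice vector makes |q + G| = 0 for some G and the Coulomb
  kernel diverge; this is an informative error, and toy q-grids use odd
  half-multiples of 2π/a to stay clear of it.
* **Direction.**  q is a vector internally; public functions take a
  magnitude and a direction (default x).  For isotropic targets a
  `direction_average` option averages the three axis directions; on cubic
  jellium this is an exact no-op, which is tested.

## The Dyson solve and the effective potential

χ = χ⁰[1 − vχ⁰]⁻¹ is computed by a dense linear solve (never an explicit
inverse).  Singularity is detected through the reciprocal condition number
of [1 − vχ⁰] with the denominator floored at 1 — the identity sets the
natural scale, so an almost-zero 1×1 system (a plasmon pole at real energy
with η too small) is correctly flagged even though its relative singular
value spread is trivial; the tolerance is 1e−12.  The partition stage
solves [1 − vχ⁰]V^eff = δ_{G0} and verifies the residual below 1e−10.
Because the pair decomposition applies χ⁰ to V^eff term by term, the
sum over pairs reproduces the Dyson ELF to linear-solver accuracy
(observed ≤ 1e−15); this route equivalence is asserted at 1e−10.

## Partition conventions

* **Occupied-state attribution.**  Every pair term has one occupied and
  one empty state (the sign of f_n − f_m tells which).  The DELF histogram
  and all label projections attribute each term to its *occupied* state:
  the binding-energy delta functions are realised as histogram bins
  (default width 0.15 eV in spirit; the tests use bins aligned with the
  band windows), which makes the closure exact by construction.
* **Mulliken weights.**  Orbital weights of the occupied state are
  w_a = |C_a|² normalised per state (the toys use orthonormal orbital
  bases, so the overlap matrix is the identity).  Species-pair weights are
  the symmetrised products 2·w_{s₁}w_{s₂} (s₁ ≠ s₂) and w_s², which sum
  to 1.
* **Signs.**  Individual components — a pair term, an oxygen-s channel, a
  deep molecular-orbital channel off resonance — may legitimately be
  negative; only the total ELF is sign-constrained.  Channel ELF surfaces
  are therefore stored without a non-negativity check, and the surface
  container accepts `nonneg = FALSE` for exactly this case.
* **Energy reference for the channel windows.**  Band energies (and hence
  the molecular-orbital windows) sit on a binding-energy scale below the
  vacuum reference; the default windows place boundaries at midpoints
  between adjacent occupied band edges, so each window holds exactly one
  band and moving a boundary through an empty gap changes nothing (also
  tested).  How such windows map onto an absolute Kohn–Sham eigenvalue
  scale of a real calculation is a choice the user makes when supplying
  custom windows.

## Cross-section numerics

* **Interpolation policy.**  Bilinear in (E, q) inside the tabulated
  surface.  Below the smallest tabulated q the optical column is held
  constant (the optical limit is itself approximated by the smallest
  computed q).  Above the largest tabulated q the ELF is extended linearly
  in log ELF versus log q from the last two columns with the slope capped
  at ≤ 0 — a rising last column means the Bethe ridge is still inside the
  grid, where a power-law extension would diverge — and floored at zero.
  Below the first energy row the ELF ramps linearly from ELF(0) = 0; above
  the last row it is zero.  The fraction of each q-integral obtained from
  the extrapolated region is reported (`extrap_frac`).
* **Per-channel extension.**  Beyond the tabulated q range the *total*
  surface is extended and shared among channels in proportion to their
  weight at the last tabulated q.  This keeps the SDCS exactly linear in
  the channel decomposition, so per-channel curves sum to the total curve
  to round-off.
* **Quadrature.**  The q-integral uses the composite trapezoid rule on a
  logarithmic grid (default 200 nodes) between the kinematic limits; the
  energy integrals for Σ and S_e use the surface's native grid restricted
  to [E_min, E_max] with interpolated endpoints, or a caller-supplied node
  set (`energy_nodes`) when a log-spaced set is more economical at high T.
  Halving either step changes Σ and S_e by well under 0.2% on the Drude
  reference surface (tested).
* **Limits.**  E_max = min[(T + E_gap)/2, T − E_F]; E_min = 0 by default
  (`emin_mode = "zero"` — excitations below the gap threshold are
  allowed), with `emin_mode = "gap"` available for comparison.  q_min is
  computed through the product identity q_min·q_max = 2mE, which is
  algebraically identical to √2(√T − √(T−E)) but immune to the
  cancellation that destroys the subtractive form when E ≪ T.

# What the toy systems emulate — and what they do not

**Jellium** (`make_jellium`) is the exact plane-wave gas: band b at k is
the plane wave k + G_b with energy |k + G_b|²/2, occupied up to the Fermi
level of the requested density (default expressed via r_s).  The retained
band set keeps every |G| ≤ k_F + `band_headroom` (default 1.5 a.u.), which
guarantees no occupied→retained transition is lost for momentum transfers
up to the headroom; larger q needs a larger headroom.  Jellium exists to
be checked against the Lindhard oracle and to make local-field effects
vanish identically (its χ⁰ is diagonal in G).

**Toy water** (`make_toy_water`) is a four-occupied-band insulator whose
band centres sit at the measured liquid-water binding energies (30.90,
17.34, 13.50, 11.16 eV below vacuum), with a cosine dispersion of
half-width 0.5 eV — wide enough that the bands are genuine bands, narrow
enough that the four molecular-orbital windows stay separable, which the
channel analysis requires.  The default gap of 8.7 eV is the commonly
quoted electronic gap of liquid water; with it the Fermi level lands at
−6.31 eV.  The states are small anti-Hermitian rotations of distinct plane
waves, raw = I + inh·A(k): the k-dependence of A is essential (strictly
k-independent orthonormal coefficients would make every interband optical
matrix element vanish by orthogonality wherever the k+q fold needs no zone
wrap), and the per-band coupling amplitudes to the unoccupied band
(defaults 1.0, 1.4, 0.45, 0.35) concentrate oscillator strength on the
1b2-like transition so the optical ELF shows liquid water's single
dominant peak (height ≈ 1.4 near 18 eV) rather than a ladder of
single-particle lines.  Each band also carries an H/O and s/p orbital
composition for the label projections.  The toy is *not* an electronic
structure of water: its Bethe surface dies beyond q ≈ 2 a.u. (the states
have compact plane-wave support), its oscillator strengths are designed
rather than computed, and nothing in it knows about hydrogen bonding,
disorder or exchange–correlation.  Passing tests on it demonstrate the
correctness of the response, partition and cross-section machinery — not
agreement with real water spectra.

**Drude surfaces** (`make_drude_elf`) are sums of damped-oscillator peaks
A·γ·E/((E² − E_i(q)²)² + γ²E²).  The E-integral of E times this form is
(π/2)·A for every position and width, so the weight A is the squared
plasma frequency carried by the peak and the f-sum rule holds analytically
— surfaces are generated normalised, and the tests verify the quadrature
reproduces it (the energy grid must extend far beyond the damping width:
the neglected tail is ≈ 2γ/(πE_max) of the sum, so 0.5% accuracy with
γ = 3–4 eV needs E_max ≈ 900 eV).  A water-like single peak uses
E₁ = 21.4 eV, γ = 10 eV, A = 462 eV² (the valence f-sum of water at
0.997 g/cm³).  With `dispersion = "quadratic"` the peak rides the
free-electron ridge E₁ + q²/2.

On the choice of surface for the high-energy stopping check: with
quadratic dispersion the Bethe ridge at fixed E is a spike of q-width
γ/(27.2·q) a.u. which no fixed logarithmic q-table can resolve at large q
— the tabulated representation, not the quadrature, is the limit.  The
dispersionless plasmon pole has no ridge, its q-integral is exact under
the constant-extension policy, and S_e·T is analytically affine in ln T;
that is the surface the asymptote is checked on (observed fit
R² = 0.9999999 over 10–100 keV), while the dispersive surface is used for
the IMFP-shape check, which is insensitive to ridge resolution.

# Problem sizes

The test suite and acceptance script run the jellium oracle on 16³ k-meshes
(≈ 110k states, head-only response, seconds), the toy-water pipeline on a
2³ mesh with 19 G-vectors, Drude surfaces up to 50k × 140 grids, and
cross-section tables over 10 eV–100 keV; the full suite completes in about
half a minute on one CPU.  These sizes were chosen so every check runs at
interactive speed while the k-mesh refinement tests still demonstrate
convergence toward the analytic limits.

# Known limitations

* RPA only: no exchange–correlation kernel (f_xc ≡ 0), so the package
  cannot probe AGGA-type corrections; the Born approximation carries no
  exchange, Coulomb-field or relativistic corrections, which matter below
  ≈ 100 eV and above ≈ 100 keV respectively.
* Dense linear algebra throughout — appropriate for the ≤ tens of
  G-vectors of the toys, not for production ab initio basis sizes.
* The positivity of the ELF is exact only in the η → 0 limit; with finite
  broadening and a finite basis the matrix RPA can overshoot marginally
  below zero near the edge of a model's momentum support (observed at the
  1e−5 level where the ELF itself is 1e−4).  Totals are clipped at zero
  when assembling non-negative surfaces; anything beyond 1% of the surface
  maximum is treated as an error.
* Cubic cells and Γ-centred meshes only; q must be mesh-commensurate.
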