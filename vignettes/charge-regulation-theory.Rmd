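---
title: "A sequence-specific mean-field theory of charge regulation in disordered proteins"
author: "chargereg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A sequence-specific mean-field theory of charge regulation in disordered proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chargereg)
```

## The physical problem

Intrinsically disordered proteins (IDPs) are flexible heteropolymers rich in
weakly acidic (E, D) and weakly basic (K, R, H) residues. The ionization
state of each such residue is not fixed: it responds to pH **and** to the
electrostatic potential created by every other residue, which in turn depends
on the chain conformation, which itself depends on the charges. `chargereg`
solves this closed loop — *charge regulation coupled to conformation* — at
the mean-field level, for an arbitrary sequence, in seconds.

The model is an Edwards chain of $N$ residues with Kuhn length $l$ and
contour length $Nl$, carrying

* harmonic (Gaussian) connectivity,
* dimensionless pairwise excluded-volume parameters $\omega_{mn}$,
* Debye–Hückel screened Coulomb interactions
  $\lambda_B\, q_m q_n\, e^{-\kappa r}/r$, with Bjerrum length $\lambda_B$
  and screening parameter $\kappa = \sqrt{8\pi\lambda_B c_\mathrm{salt}}$,
* and a constant-pH ensemble for the charge states: each titratable residue
  fluctuates between neutral and charged with statistical weight
  $10^{\theta\,(pH - pK_A)}$, i.e. an external field
  $\ln(10)(pH - pK_A(i))$ coupled linearly to $q_i$.

Acidic residues take $q \in \{0, -1\}$, basic residues $q \in \{0, +1\}$.
Because the electrostatics are linearized (Debye–Hückel), nonlinear effects
such as counterion condensation and release are outside the model by
construction.

## The variational ansatz and the working equations

Exact averages over conformations and charge states are intractable, so the
package uses a *uniform-expansion* trial ensemble with two kinds of
variational parameters:

* a renormalized Kuhn length $l_r = x\,l$ — one scalar $x$ absorbing all
  interaction effects on conformation, so pair separations stay Gaussian
  with variance $\langle r_{mn}^2\rangle = |m-n|\, l\, l_r$;
* residue-specific mean-fields $\phi_i$ acting on the charges, under which
  the sites decouple and obey a logistic two-state law
  (`meanCharge()`):
  $$\langle q_i \rangle = -\frac{1}{1+e^{-\phi_i}} \;\text{(acid)},\qquad
    \langle q_i \rangle = +\frac{1}{1+e^{\phi_i}} \;\text{(base)}.$$

Imposing the Edwards–Singh conditions — the covariance of $R_e^2$, and of
each $q_i$, with the difference between the true and trial Hamiltonians must
vanish in the trial ensemble — yields a closed set of coupled equations.
The conformation equation (`residualX()`, `solveX()`) reads

$$N\Big(\frac1x - 1\Big)
 + \Big(\frac{3}{2\pi}\Big)^{3/2} \frac{1}{x^{5/2}}
   \sum_{m>n} \frac{\omega_{mn}}{\sqrt{m-n}}
 + \frac{2\lambda_B}{9\pi l}\, \frac{1}{x^{3/2}}
   \sum_{m>n} \langle q_m\rangle \langle q_n\rangle\, (m-n)^2
   A_{mn}(x, \kappa l) = 0,$$

and the $N$ mean-field equations (`fieldRHS()`) are

$$\phi_i = \ln(10)\,(pH - pK_{A,i})
 + \frac{2\lambda_B}{\pi l} \sum_{m \neq i} \langle q_m\rangle\,
   J_{mi}(x, \kappa l).$$

The second term of the field equation is the electrostatic $pK_A$ shift: for
a polyacid it is negative (like charges suppress ionization, the
*polyelectrolyte effect*), for an acid next to charged bases it is positive
(opposite charges enhance ionization).

### The coupling matrices

Both matrices are Gaussian-ensemble averages of the screened interaction and
depend on $(m, n)$ only through the separation $s = |m-n|$, which the
implementation exploits with one-dimensional separation caches. With
$z = \kappa l \sqrt{s x / 6}$ and $\mathrm{erfcx}(z) = e^{z^2}\mathrm{erfc}(z)$:

$$J(s; x, \kappa l) = \frac{\sqrt{6\pi}}{2\sqrt{s x}}
  \left[1 - \sqrt{\pi}\, z\, \mathrm{erfcx}(z)\right],$$

$$A(s; x, \kappa l) = \frac{\sqrt{6}}{s^{3/2}}
  \left[\tfrac32\sqrt{\pi} - 3\sqrt{\pi} z^2
        + 3\pi z^3\, \mathrm{erfcx}(z)\right].$$

$J$ comes from $\langle e^{-\kappa r}/r\rangle$ over the Gaussian pair
distance; $A$ from the covariance of $r^2$ with the same interaction, in the
normalization of the conformation equation above. Both forms are validated
in the test suite against an independent radial-quadrature oracle
(`gaussianScreenedAverage()`): $J$ directly to $10^{-6}$ relative error, $A$
against a finite-difference reconstruction of the defining covariance. A
Monte Carlo sampler of the trial ensemble (`sampleTrialEnsemble()`)
cross-checks the same averages stochastically.

Two numerical points are worth recording. First, the naive
$e^{z^2}\mathrm{erfc}(z)$ product overflows beyond $z \approx 27$, so the
package carries its own stable `erfcx()` (a `pnorm` form below $z = 4$, the
Laplace continued fraction above). Second, both bracketed factors are
differences that lose all significant digits at large $z$; beyond
$z = 10^2$–$10^3$ they switch to their asymptotic series. The kernels decay
*algebraically*, as $(\kappa l)^{-2}$ — a Gaussian average of a Yukawa
potential is never screened at short distance — so "strong screening" limits
are approached polynomially, not exponentially: at $\kappa l = 10^3$ the
entries are a few parts in $10^6$ of their unscreened values, and only at
$\kappa l \gtrsim 10^5$ do they drop below $10^{-8}$ absolutely.

### Limiting cases (all asserted as tests)

1. $\kappa l \to \infty$ or $\lambda_B/l \to 0$: both matrices vanish,
   titration becomes Henderson–Hasselbalch (`idealIonization()`), and the
   conformation is set by excluded volume alone.
2. Extreme pH: all sites saturate, the theory reduces to the quenched
   fixed-charge conformation equation (`quenchedSolve()`).
3. Frozen conformation (`fixedConformationSolve()`): only the field
   equations are iterated at a given $x$; at the converged $x$ of the full
   theory this reproduces the full solution exactly.

## The numerical scheme

`selfConsistentSolve()` implements a plain fixed-point loop: initialize the
fields at their ideal values, then repeat (i) solve the conformation
equation for $x$ at the current charges, (ii) update the fields by simple
mixing $\phi \leftarrow (1-\zeta)\phi + \zeta\,\mathrm{rhs}$ with
$\zeta = 0.5$, (iii) recompute the charges, until both
$\max_i |\Delta\langle q_i\rangle|$ and $|\Delta x|$ fall below the
tolerance ($10^{-10}$ by default). Converged states satisfy both equations
a posteriori, and the solution is independent of initialization for every
system exercised here (a property the suite checks with randomized
restarts).

Choices that were genuinely open, and how they were settled:

* **Root selection.** The conformation residual always tends to $-\infty$ as
  $x \to 0$ whenever the net electrostatic sum is attractive (the
  $x^{-3/2}$ attraction outruns the $N/x$ entropy), so a spurious small-$x$
  crossing generally accompanies the physical solution. `solveX()` scans a
  log-spaced grid over $[10^{-3}, 10^3]$ and refines the **largest** sign
  change — the continuation of the ideal $x = 1$ branch as the coupling is
  turned on — warning when several crossings exist. Inside the
  self-consistent loop the scan is first narrowed around the previous
  iteration's root.
* **Adaptive mixing.** $\zeta = 0.5$ converges for weakly and moderately
  coupled chains but settles into a period-2 oscillation for strongly
  coupled blocky polyampholytes (the field update overshoots). Whenever the
  residual fails to improve for 100 consecutive iterations the solver halves
  $\zeta$ (at most 7 times) and continues; the fixed point reached is
  unchanged, only the path to it.
* **Collapse boundary.** With $\omega = 0$ a sufficiently attractive
  polyampholyte has *no* root: two-body attraction cannot be balanced by
  chain entropy alone, which physically signals collapse beyond the validity
  of a two-body theory (stabilization would require three-body terms).
  `solveX()` reports this as a bracketing error with the scanned residual
  range rather than returning a spurious root.
* **Excluded volume for E/K chains.** Because of the collapse boundary,
  blocky E/K polyampholytes near their isoelectric point *require*
  $\omega > 0$. The package's convention is `omegaVolumes()`:
  $\omega_{mn} = (V_m + V_n)/(2 l^3)$ from tabulated van der Waals residue
  volumes (E: 138.4 Å$^3$, K: 168.6 Å$^3$), i.e. pair repulsion measured in
  Kuhn volumes, giving $\omega \approx 0.7$–$0.9$ at $l = 5.8$ Å. For the
  weak-polyacid studies $\omega = 0$, to isolate electrostatics.

### Default parameters

| parameter | default | units | meaning |
|---|---|---|---|
| $\lambda_B$ | 7.1 | Å | Bjerrum length (water, 298.15 K, $\varepsilon_r = 78.4$) |
| $l$ | 5.8 | Å | Kuhn length of the polypeptide backbone |
| $pK_A$ | D 4.0, E 4.4, H 6.3, K 10.4, R 12.0 | — | intrinsic side-chain values (Nozaki–Tanford) |
| $\omega$ | 0 | — | excluded volume; `"volumes"` for the vdW convention |
| $\zeta$ | 0.5 | — | mixing parameter |
| tol | $10^{-10}$ | — | convergence tolerance on $\langle q_i\rangle$ and $x$ |

Temperature and dielectric constant enter only through $\lambda_B$;
`bjerrumLength()` is provided as a convenience, but $\lambda_B$ itself is
the canonical input.

## Worked example: a weak polyacid

The classic testbed is a 30-residue homopolyacid with $pK_A = 4.0$,
$l = 5.8$ Å, $\omega = 0$:

```{r polyacid}
sp <- homopolymer("E", 30, pKa = c(E = 4.0))
pp <- physicalParams(pH = 4, salt = 1e-2)
st <- selfConsistentSolve(sp, pp)
st
th <- ionizationProfile(st, sp)
round(th[c(1, 8, 15, 23, 30)], 4)          # U-shaped along the chain
idealIonization(4, 4, "acid")              # ideal value at pH = pKa
```

Every residue ionizes *less* than Henderson–Hasselbalch predicts (the
polyelectrolyte effect), the deficit shrinks with added salt, and the chain
ends — having fewer interaction partners — stay more ionized than the
middle, a strictly palindromic U-shaped profile.

## The E/K variant library and what the generator does (and does not) emulate

Sequence effects are explored with 50-residue chains of fixed composition
25 E + 25 K, ordered by charge *blockiness* as measured by the sequence
charge decoration metric (`scd()`),
$\mathrm{SCD} = N^{-1}\sum_{m>n}\sigma_m\sigma_n\sqrt{m-n}$ with formal
charges $\sigma$. `ekVariantLibrary()` provides 30 such sequences. The two
endpoints are exact and canonical: variant 1 is the strict alternation
`EKEK…` (least blocky possible) and variant 30 the diblock
`E…EK…K` (blockiest possible). The 28 intermediates are **synthetic**:
deterministic seeded annealing of random 25/25 strings to SCD targets
spaced geometrically between the endpoint values, shipped as
`extdata/ek25_variants_synthetic.fasta` and regenerable bit-for-bit with
`makeEkVariantLibrary()`.

This library reproduces the *structural* facts that matter for the physics:
exact composition, strictly monotone blockiness, alternating and diblock
endpoints. It does not reproduce any particular published set of
intermediate strings, so conclusions tied to one specific historical variant
number (other than 1 and 30) should not be read off it; all properties
checked by the test suite — plateau versus steep ionization response,
compaction ordering at the isoelectric point, block-boundary ionization
enhancement — depend only on the ordering and the exact endpoints.
`randomBlockySequence()` generates further E/K chains with a target mean
block length when an ensemble is wanted.

For an equal-composition E/K chain the $pK_A$ pair (4.4, 10.4) makes the
ideal titration exactly antisymmetric about $(4.4 + 10.4)/2 = 7.4$, and the
interacting theory preserves this symmetry for sequences whose reversal
exchanges E and K (variants 1 and 30) up to the small
$\omega_{EE} \neq \omega_{KK}$ asymmetry — so the computed isoelectric
point of the alternating chain sits at 7.40, flanked by a broad net-neutral
plateau.

```{r pi, eval = FALSE}
spec <- sequenceSpec(ekVariant(1), omega = "volumes")
isoelectricPoint(spec, physicalParams(pH = 7, salt = 0.015))
```

## Problem sizes, tolerances, reproducibility

The suite exercises chains of $N = 2$–50 residues: kernel-oracle grids at
$N \le 10$, the polyacid at $N = 30$ over pH $\in [2, 8]$ and salt
$\in \{10^{-3}, 10^{-2}, 10^{-1}\}$ M, the E/K variants at $N = 50$ and
0.015 M — sizes at which a full titration sweep takes seconds. Monte Carlo
cross-checks use $10^5$ samples at fixed seeds (comparisons at three
standard errors, with the exact binomial error substituted where an
empirical one degenerates to zero near saturation). All stochastic pieces
(variant annealing, blocky-sequence generation, trial-ensemble sampling)
run under local seeds and restore the caller's RNG state.

## Known limitations

* Debye–Hückel electrostatics: no counterion condensation/release, no
  transient-dipole physics, no field nonlinearity.
* Two-body interactions only: strongly attractive (blocky, weakly screened,
  $\omega \approx 0$) chains hit the collapse boundary where the
  conformation equation loses its root; the solver diagnoses rather than
  papers over this.
* The uniform-expansion ansatz describes swelling/compaction by a single
  scale factor; monomer-resolved conformational detail (local compaction of
  one block) is outside the ansatz even though monomer-resolved *ionization*
  is captured.
* Terminal amine/carboxyl groups are not titrated; only side chains carry
  charge.
* Mean-field charge treatment: correlations between charge fluctuations on
  different residues are neglected, which is why ionization is the quantity
  to trust most and absolute sizes less so.
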