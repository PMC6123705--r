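---
title: "Exact NOE extraction and ensemble validation with exactnoe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact NOE extraction and ensemble validation with exactnoe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exactnoe)
```

## The problem

Conventional NOESY analysis converts cross-peak intensities into loose
upper distance bounds, discarding most of the quantitative information
the cross-relaxation rate carries.  Exact NOEs (eNOEs) instead fit the
full buildup of cross-peak intensity over a series of mixing times,
correct it for spin diffusion with a full relaxation-matrix simulation
of the molecule, and convert the fitted cross-relaxation rate
$\sigma$ into a distance through $\sigma \propto r^{-6}$.  Done
carefully, this yields interproton distances up to about 5 Å with
errors of order 0.1 Å — tight enough that bi-directional eNOEs are used
with *no* tolerance as both upper and lower limits, and tight enough to
resolve conformational averaging: because the NOE reports
$\langle r^{-6} \rangle^{-1/6}$, a restraint set of this accuracy can
prefer a multi-state ensemble over any single structure.

This package implements that extraction protocol and the validation
metrics used to judge ensembles against eNOE restraint sets, for
protonated RNA (the four ribonucleotides) and for synthetic benchmark
systems.  It does not perform structure calculation itself (no
torsion-angle dynamics or simulated annealing); it produces and
evaluates the restraints that such engines consume, in CYANA-style
`.upl`/`.lol` files.

## The relaxation model

All rates derive from the rigid, isotropically tumbling dipolar model.
With the spectral density

$$J(\omega) = \frac{\tau_c}{1 + (\omega\tau_c)^2}$$

an isolated proton pair at distance $r$ has

$$\sigma = K r^{-6}\,[\,6J(2\omega_0) - J(0)\,], \qquad
\rho_{pair} = K r^{-6}\,[\,J(0) + 3J(\omega_0) + 6J(2\omega_0)\,],$$

with $K = \tfrac{1}{10}\left(\frac{\mu_0}{4\pi}\hbar\gamma_H^2\right)^2$
and $\gamma_H = 2.6752218744\times10^{8}\,\mathrm{rad\,s^{-1}T^{-1}}$.
At high field and nanosecond tumbling ($\omega_0\tau_c \gg 1.12$),
$\sigma < 0$.  The constant convention is internal: distance extraction
inverts the same expressions, so any self-consistent convention yields
identical distances (enforced by a round-trip identity test at
$10^{-10}$ relative error).

The full relaxation matrix $R$ over all protons of a conformer has
$\sigma_{ij}$ off the diagonal and
$\rho_i = \sum_{j\neq i}\rho_{pair}(r_{ij}) + \rho_{ext,i}$ on it.
NOESY mixing propagates magnetization as $A(\tau_m) = e^{-R\tau_m}$,
computed with a dense general-purpose matrix exponential; the closed
two-spin Solomon solution serves as an independent oracle in the tests,
never as the production path.  $\rho_{ext}$ defaults to zero and can be
set per proton class to emulate, e.g., solvent exchange of labile
protons; no claim is made about the magnitude of such leakage in any
particular sample.

Anisotropic tumbling is deliberately out of scope: for modestly
anisotropic molecules (axis ratio ≈ 1.5) the isotropic assumption
costs at most ~2% in distance, which the ±10% tolerance classes absorb.

## Spin-diffusion correction

A measured cross peak contains, besides the direct $i\!\leftrightarrow\!j$
transfer, magnetization relayed through all other protons.  The
correction simulates both views from a reference structure: the
full-matrix intensity $A_{ij}(\tau_m)$ and the isolated two-spin
intensity computed from the same $\rho_i$, $\rho_j$, $\sigma_{ij}$.
The per-pair, per-mixing-time factor

$$F_{ij}(\tau_m) = \frac{\langle I^{2spin}_{ij}(\tau_m)\rangle}
                        {\langle I^{full}_{ij}(\tau_m)\rangle}$$

(conformer averages of intensities, taken before the ratio, because
intensities — not ratios — are the physical observables) multiplies the
measured intensity and restores an effective isolated-pair buildup.
For a system containing only the pair itself $F \equiv 1$ exactly, and
$F \to 1$ as $\tau_m \to 0$ for any system.  Initial magnetization in
both simulations is uniform, which cancels from the ratio.  A
`corrected` flag guards against double application, since the factors
are multiplicative rather than idempotent.  Corrections are applied in
a single pass; an iterate-against-the-refined-structure loop can be
built from the same primitives but is not part of the default protocol.

### Diagonal-decay bias and its correction

Diagonal decays of a dense spin system are multi-exponential; the
protocol nevertheless fits them with a monoexponential
$I(\tau) = \Delta M(0)e^{-\rho\tau}$, so the fitted $\rho$ and
$\Delta M(0)$ *underestimate* the matrix values — most strongly for
geminal-coupled methylene (and amino) protons, whose effective
$\sigma$ is dominated by the 1.78 Å partner, and increasingly so for
longer fit windows.  Because the cross-peak fit freezes these diagonal
parameters, the bias propagates into $\sigma$ and the distances.

`exactnoe` removes it with the same reference structure used for the
spin-diffusion factors: `diagonal_decay_reference()` simulates the
full-matrix diagonal decays, fits them with the identical
monoexponential protocol, and `correct_decay_fits()` rescales the
experimental parameters by true/apparent.  On noiseless synthetic data
this makes the full pipeline exact to numerical precision; without it,
the residual bias is a few hundredths of an Ångström for distances
near 5 Å.  The cross-peak correction factors themselves are unchanged
by this step, and measured diagonal *intensities* are never modified.

## Fitting protocol

* **Diagonals** are fitted by positive-parameterized least squares
  (log-scale $\Delta M(0)$, $\rho$), by default over 40–160 ms.  A fit
  with fewer than 3 points, a failed optimizer, or $r^2 < 0.9$ falls
  back to $\rho = 2.9\,\mathrm{s^{-1}}$ (a typical average
  auto-relaxation rate for a small RNA at these conditions) with
  $\Delta M(0)$ back-extrapolated from the earliest point.
* **Cross peaks** are fitted to the two-spin solution with
  $\rho_i,\rho_j,\Delta M(0)$ frozen and $\sigma$ the single free
  variable (sign-aware grid start, then local refinement).  Both
  directions of a pair are fitted independently; pairs with both
  fits are *bidirectional*, single-direction pairs *unidirectional*.
* **Normalization** prefers the spin of origin; if that diagonal is
  unusable and the destination diagonal is clean, normalization
  switches to the destination spin; if neither passes, the buildup is
  rejected.
* **Quality control** replaces visual curve inspection with explicit,
  configurable thresholds (diagonal $r^2 \ge 0.9$, $\sigma$ relative
  standard error ≤ 20%, ≥ 3 points).  Fits are flagged with the failed
  criterion, never silently deleted; tightening a threshold can only
  add flags.  Fitted $\sigma$ landing on the wrong side of zero for the
  tumbling regime carries no distance information and is flagged out.
* **gn-eNOEs**: cross peaks whose diagonal is overlapped are normalized
  with the *maxima* of $\Delta M(0)$ and $\rho$ over the successfully
  fitted members of the proton's atom group (amino / methylene /
  other; hydroxyls are kept as their own class for bookkeeping but
  grouped with "other" here).  Overstating $\Delta M(0)$ biases
  $|\sigma|$ low and the distance high, so the result is an upper
  limit.  The accompanying $\rho$ maximum works in the opposite,
  second-order direction; in noiseless synthetic tests it erodes the
  bound by < 0.01 Å, far inside the 10% tolerance the gn class carries.

### Fit range and the maximal mixing time

Short windows keep both the monoexponential diagonal model and the
perturbative spin-diffusion regime honest; long windows improve
precision.  The packaged rule is
$\tau_{max} = 4\times10^{-10}\,\mathrm{s^2}/\tau_c$ (for proteins, with
their denser proton network, the tighter
$2.5\times10^{-10}\,\mathrm{s^2}/\tau_c$ applies), floored to the
acquired grid: at $\tau_c = 2.23$ ns this gives 179 ms, i.e. fits to
160 ms of a 40–320 ms series.  The default fit range is therefore
40–160 ms, with the full series retained as an option.  On
model-consistent (monoexponential) data the two ranges agree; on
geminal-coupled decays the long range underestimates $\Delta M(0)$
progressively more — the direction of that effect is locked in a
regression test.

## Restraint classes

| class          | source                         | bounds            |
|----------------|--------------------------------|-------------------|
| bidirectional  | both cross peaks fitted; mean of the two $\sigma$ | upper = lower = $r$ |
| unidirectional | one usable direction           | $0.9r$ … $1.1r$   |
| gn             | group-normalized upper limit   | upper $=1.1r$ only |

The arithmetic mean of $\sigma_{ij},\sigma_{ji}$ is used for
bidirectional pairs (symmetric, unbiased for equal-noise directions).
Restraints are written as CYANA-style `.upl`/`.lol` lines (residue
number, residue name, atom name for both partners, bound in Å),
deterministically ordered.

## Validating ensembles

* `ensemble_distance()` gives $\langle r^{-6}\rangle^{-1/6}$ (what the
  NOE reports) or $\langle r\rangle$; Jensen's inequality guarantees
  r6 ≤ linear, with the gap a direct readout of motional averaging.
* `violation_tf()` scores a bundle by the unweighted target function
  $TF = \sum_k v_k^2$ (Å$^2$), with $v = \max(0, d-u) + \max(0, l-d)$,
  either per conformer or with the distance r6-averaged over states —
  the multi-state logic in which the ensemble, not each member, must
  satisfy the data.  Violations ≥ 0.2 Å are listed separately.  The
  absolute scale of engine-internal (weighted) target functions is not
  reproduced; the statistic is used comparatively.
* `jackknife()` partitions the restraints into k = 10 seeded folds
  (each restraint held out exactly once), evaluates the partial TF of
  every held-out fold against a supplied ensemble and sums them into a
  cross-validation TF.  Structure recalculation per fold is the job of
  the structure engine and is out of scope here.
* `prune_peaks()` emulates the overlap of larger RNA by deleting 2f of
  the diagonals and f of the cross peaks at random (diagonal overlap
  grows roughly twice as fast, since one coinciding resonance
  suffices), then demotes restraint classes down the chain
  bidirectional → unidirectional → gn; a pair that loses all cross
  peaks vanishes.  Deletion is uniform at random with a fixed seed
  (whether stratified deletion better mimics real overlap is an open
  question; uniform is the neutral default).
* `order_parameter()` computes
  $S^2 = \tfrac12\!\left(3\sum_{\alpha\beta}\langle\mu_\alpha\mu_\beta\rangle^2 - 1\right)$
  with equal conformer weights: 1 for any single-conformer bundle,
  0.25 for two equal states 90° apart, → 0 for isotropic sampling.
* `heavy_atom_rmsd()` reports the mean RMSD to the iteratively refined
  mean structure after optimal superposition on the selected subset.
  Published bundle RMSDs do not always state their convention
  (pairwise vs to-mean, superposition subset), so comparisons carry
  that caveat; ours is documented precisely so deviations can be
  diagnosed.
* `torsion_angles()` evaluates α…ζ, χ, η2 (C1'–C2'–O2'–HO2'), ν1, ν2
  with IUPAC atom quadruplets and circular statistics across
  conformers; η2 is skipped when the hydroxyl proton is absent, and
  δ, ν1, ν2 are rigidly linked through the ring geometry.

## The synthetic benchmark

`make_helix_spin_system()` places five protons per residue (a base
proton, ribose-like H1'/H2', and a geminal H5'/H5'' pair at 1.78 Å) on
an idealized helix (2.8 Å rise, 32.7° twist).  The geometry is
parametric and deterministic — realism in sequence or pucker is
unnecessary for testing rate extraction, while determinism is
essential.  Its construction guarantees: minimum interproton
separation 1.78 Å, pair distances covering the 1.8–6 Å working range,
and a geminal dipolar interaction that dominates each methylene
proton's auto-relaxation.  Optional per-conformer Gaussian jitter
(seeded) emulates ensembles, with the recorded ground truth being the
r⁻⁶-averaged distances; per-spin $\Delta M(0)$ heterogeneity exercises
the gn logic.  Noise is additive Gaussian scaled to the largest
first-mixing-time diagonal, matching how signal-to-noise is quoted in
NOESY practice.

What passing synthetic tests shows — and what it does not: they verify
the mathematics of simulation, correction, fitting and conversion to
numerical precision, and the direction and rough size of the
protocol's systematic errors.  They do not probe peak overlap,
lineshape and baseline distortions, chemical exchange, internal
dynamics faster than tumbling, or assignment errors, all of which real
spectra add on top.

## Worked example

```{r pipeline}
cond <- noe_conditions(tau_c = 2.23e-9, field_mhz = 900)
helix <- make_helix_spin_system(n_residues = 4, seed = 1)
buildups <- simulate_noesy(helix$spin_system, cond,
                           mixing_times = c(0.04, 0.08, 0.12, 0.16))
res <- extract_enoe_distances(buildups, helix$spin_system, cond)
id <- function(a, b) paste(pmin(a, b), pmax(a, b))
m <- match(id(res$distances$key_i, res$distances$key_j),
           id(helix$truth$key_i, helix$truth$key_j))
sel <- helix$truth$r_true[m] <= 5
max(abs(res$distances$r - helix$truth$r_true[m])[sel])
```

```{r restraints}
head(write_restraints(res$restraints, "upper"))
rep <- violation_tf(res$restraints, helix$spin_system)
rep$tf
```

## Numerical choices and problem sizes

Matrix exponentials use `Matrix::expm` on the full proton set (an
optional 8 Å cutoff exists for systems beyond a few hundred protons).
Nonlinear fits run on log-parameterized models via
Levenberg–Marquardt, with a Nelder–Mead polish when zero-residual
starts make the LM gradient singular; the one-dimensional $\sigma$
fits use a sign-aware coarse grid followed by golden-section
refinement, tie-breaking by residual norm.  Degenerate inputs fail
loudly: overlapping atoms (< 0.5 Å), hydrogen-free ensembles,
wrong-sign $\sigma$, unmappable hydrogen names.

Tests and the acceptance script run the 20-proton, 4-mixing-time
benchmark (about 2 s), Monte-Carlo loops of 100 seeds on 2–5-spin
systems, and an isotropic-S² check with $10^5$ orientations — sizes
chosen so the whole suite completes in well under a minute while every
statistical assertion still has comfortable margin.

## Known limitations

* Four standard ribonucleotides only; the naming table is extensible
  but non-standard residues are not guaranteed.
* Full-matrix treatment only — the three-spin approximation for
  partially deuterated samples is not implemented.
* Isotropic tumbling; no cross-correlated relaxation or chemical
  exchange inside the matrix.
* Validation against published reference ensembles requires the
  corresponding PDB depositions, which are not redistributed with the
  package (see the README for where to place them).
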