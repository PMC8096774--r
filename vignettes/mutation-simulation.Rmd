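---
title: "Simulating loss- and gain-of-function mutations in mass-action networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating loss- and gain-of-function mutations in mass-action networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnmut)
```

## The model

A signalling network is described as a chemical reaction network (CRN): `n`
well-mixed species with concentrations `x` (nM) and `r` irreversible
reactions with rate constants `k`.  Under mass-action kinetics each reaction
`j` carries the flux

    v_j = k_j * prod_i x_i^(a_ij)

with `a_ij` the stoichiometry of species `i` as a reactant of `j`, and the
state evolves as the polynomial ODE system

    dx/dt = S v(x, k)

where `S` is the `n x r` stoichiometric matrix (products minus reactants per
column).  Mass action, rather than Michaelis–Menten or Hill kinetics, is
appropriate here because in signal transduction the substrates are proteins
whose concentrations are comparable to those of the catalysing enzymes, so no
enzyme-saturation limit applies.  Reversible reactions are always stored
expanded into two irreversible columns sharing a `parent_id`: this makes the
column count equal to the number of directed reactions and lets a
gain-of-function projection delete a single direction.  Inflow species
("constant" species, e.g. external growth factors) are kept as state
variables whose rows of `S` are identically zero, so each contributes one
trivial conservation law instead of being eliminated.

## Conservation laws and elemental species

A semi-positive conservation vector is a non-zero, non-negative integer
vector `gamma` with `S^T gamma = 0`; then `gamma^T x` is constant along every
trajectory and counts the total number of molecules of one conserved moiety.
The set of all such vectors is a pointed polyhedral cone, and
`semipositive_generators()` enumerates its extreme rays with a tableau
(double-description) scheme run entirely in integer arithmetic: rows are
combined with positive integer weights and rescaled to coprime entries, so
`N S = 0` holds *exactly*, not merely to floating-point tolerance.  Ranks are
likewise computed exactly, by fraction-free (Bareiss) elimination, so the
basis condition `p = n - rank(S)` is a sharp test rather than a threshold
judgement.  All quantities stay far below 2^53, where double-precision
integer arithmetic is exact.

When the matrix `N` stacking the generators contains an identity minor, the
network is *weakly elemented* and the species indexing the minor are the
*elemental* (basic) species — free-form proteins, each belonging to exactly
one conservation law, from which all other conserved species (compounds) are
built.  The elemental set is generally not unique; `conservation_laws()`
resolves the ambiguity deterministically by scanning species in table order
and greedily assigning the first unit column matching each law.  The
remaining species split as `x = (x1, x2)` with `x1 = c - N2 x2`, where
`c = N x` collects the conserved totals.  If the generator count exceeds
`n - rank(S)` the generators are retained but every operation relying on the
basis property (ideal states, class sampling, projections) refuses to run
and says why: the block decomposition `N = [I_p, N2]` is simply not available
then.

```{r}
net <- fixture_phospho_cycle()
cs <- conservation_laws(net)
cs
tidy(cs)
```

## Compatibility classes and the in-class sampler

A stoichiometric compatibility class (SCC) is the set
`{y >= 0 : N y = N x}`; trajectories never leave their class.  The *ideal
state* of a class puts the entire total of each law on its elemental species.
`sample_class_point()` draws scattered states of a fixed class by a
three-stage sequential construction: unconserved species are drawn
log10-uniformly on `[1e-5, 1e5]` nM; the non-elemental conserved species are
visited in a random permutation and each takes a uniform fraction of the
*residual* headroom `min_j c_j / gamma_ji` over the laws that contain it,
with the residuals updated in place; the elemental species then absorb what
is left of their laws.  The scheme is a specific sequential construction, not
a uniform sampler of the class polytope, and it is reproduced as such on
purpose — its role is to generate widely dispersed, exactly class-consistent
initial states.  Constant species are excluded from all draws and keep their
declared values; their trivial laws are forced consistent with those values.

## Mutations as projection operators

**Loss of function.**  A null LoF mutation of elemental species `j` is the
state projection that zeroes the `j`-th conserved total: every compound
containing the `j`-th moiety is set to zero, `c_j` is set to zero, and the
elemental part is recomputed as `x1 = c~ - N2 x2~`.  Two consequences are
worth noting.  First, other elemental species may *increase*: molecules they
had bound in shared compounds return to free form instantaneously.  This
redistribution is implemented literally as the definition requires; whether
an instantaneous return to free form is biophysically realistic at the
moment of projection is irrelevant to the asymptotics, which only depend on
the class.  Second, the projection maps classes to classes, so any two
states of one class project into one class — which is what makes the mutated
steady state independent of whether one projects the initial state or the
physiological steady state, provided each class holds a single globally
stable state.  LoF of a non-elemental species is rejected rather than
approximated, and partial ("leaky") loss of function is out of scope.

**Gain of function.**  Constitutive activation of a protein is modelled by
deleting the deactivation reactions of its active form.  `gof_project()`
zeroes the corresponding columns of `S` while keeping the species set, the
state space and the rate-constant vector intact; zeroing columns rather than
rate constants keeps `k` available for exact reversal, and the two choices
define identical dynamics.  When the projected matrix keeps the rank of `S`,
the left kernel — hence the conservation structure and the classes — is
unchanged, which `check_rank_preserved()` certifies exactly, generator by
generator.  If the rank drops, the mutated network defines different
classes; the operation still runs but the result is stamped `scc_changing`
and the order-independence guarantees are explicitly void.
`deactivation_reactions()` suggests a candidate reaction set following the
kinase/phosphatase motif (`X* + Pase -> X*_Pase -> X + Pase`, both forward
steps); it is a heuristic and is never applied without being passed back
explicitly.

**Composition.**  A set of mutations is applied either directly — compose
all GoF projections on `S`, compose all LoF projections on the steady state,
integrate once — or iteratively, re-converging after each mutation to
quantify individual contributions.  Both routes, and every ordering, end in
the same class; under per-class global stability they therefore end in the
same steady state, which the test suite verifies numerically on fixtures.

## Integration to steady state

The ODE systems are stiff, so `integrate_to_steady()` uses deSolve's
variable-order implicit multistep solvers (`lsoda` by default, which
switches itself to BDF on stiffness; `bdf` can be forced).  Defaults:
`rtol = 1e-6`, `atol = 1e-12` nM, horizon `t_end = 2.5e7`.  The steady state
is *defined* as the solution at `t_end` — convergence is diagnosed (via the
terminal `||dx/dt||_inf` against `steady_tol = 1e-8`, relative to
`1 + max(x)`), never silently enforced, and no early exit fires by default so
the fixed-horizon protocol is exactly reproducible.  Numerical safeguards:

* **Conservation drift** is the central correctness oracle linking the
  integrator to the exact algebra: when a conservation set is supplied, the
  maximum relative drift of any `gamma^T x` along the trajectory is checked
  against `drift_tol = 1e-6` and an excess raises an error rather than a
  warning, because it can only mean the integration is untrustworthy.  In
  practice `lsoda` holds these linear invariants near 1e-12.
* **Negative concentrations** are never clipped silently.  Values below
  `-max(100 atol, 1e-10)` abort with an integrity error; the tiny band above
  that, which an implicit solver can legitimately produce for species pinned
  at zero, is reported as 0.
* **Relative differences** between mutated and physiological steady states,
  `d_i = (x_mut_i - x_phys_i) / x_phys_i`, encode full suppression as -1 and
  leave `d_i` missing (`NA`, never infinite) when the physiological value is
  zero.

## The global-stability protocol

Whether *every* class contains exactly one globally attracting steady state
is, for realistic networks, out of reach of current theory (deficiency-type
and Jacobian-based criteria do not apply to large open signalling networks),
so it is probed numerically.  `verify_global_stability()` draws `n_classes`
random classes (totals log10-uniform on `[1e-2, 1e3]` nM; trivial laws
pinned to the declared constants), samples `n_points` scattered states per
class, integrates each to `t_end`, and compares per-species coefficients of
variation of the initial values (`eps0`) and of the terminal states
(`eps_e`) across runs, averaged over non-constant species.  The qualitative
signature of per-class global stability — terminal dispersion collapsing
while initial dispersion is large — is operationalized as
`mean(eps_e) <= mean(eps0) / 10` per class; the factor 10 is configurable.
Species whose terminal mean is zero have an undefined coefficient of
variation and are excluded from the summaries (with counts reported), and
the report lists the ten worst-`eps_e` species, since slow species that have
not fully converged within the fixed horizon show up there rather than as
failures.

```{r}
rep <- verify_global_stability(net, cs, n_classes = 2, n_points = 10,
                               t_end = 1e6, seed = 1)
glance(rep)
```

## Fixtures: what they emulate and what they do not

All tests run on generated networks with known structure:

* `fixture_isomerization()` — `A <-> B`; one law, closed-form steady state
  `A_e = c k_r/(k_f + k_r)`, provably globally stable.  The quantitative
  oracle for the integrator.
* `fixture_phospho_cycle()` — the kinase/phosphatase futile cycle
  `A + K <-> AK -> A* + K`, `A* + P <-> A*P -> A + P`; three laws, elemental
  `{A, K, P}`.  The smallest network exhibiting the full machinery: shared
  compounds, a meaningful deactivation motif for GoF, non-trivial LoF
  redistribution.
* `random_conservative_crn()` — networks grown from reversible
  binding (`X + Y <-> C`) and conversion (`X <-> X'`) motifs.  Every species
  carries a moiety by construction and the per-moiety counting vectors are
  provably the extreme rays of the conservation cone, so each instance
  ships its own certificate.  Random *matrices* are useless here: their left
  kernels almost never meet the non-negative orthant.

Default rate constants are small integers (fixtures) or log-uniform draws on
`[0.1, 10]` (random networks), and default totals are order 1–10 nM — the
scale regime of signalling proteins.  What passing on these fixtures shows is
that the algebra is exact, the projections implement their definitions, and
the dynamics honour the conservation structure; what it cannot show is
global stability of any *particular* large real network (hundreds of
species, rate constants spanning many decades, 8 constant inflows) — for
such a network the protocol must be re-run on its own description, and
slower convergence per class is to be expected.

## Problem sizes and determinism

The shipped test-suite and acceptance runs use: 50 random networks of up to
12 species for oracle comparisons (the brute-force extreme-ray oracle is
exponential in the species count, which caps the exhaustive check); 20
random trajectories for drift; 100 parameter draws for the closed-form
equilibrium; and the 5 classes x 30 points protocol on the phospho cycle.
All randomness flows from one seed per entry point; sampling helpers accept
an explicit `seed` and restore the caller's RNG state, so reports are
bit-for-bit reproducible at fixed solver settings.

## Known limitations

* The tableau enumeration is exponential in the worst case; it is meant for
  networks up to a few hundred species with sparse moiety structure, not as
  a general-purpose double-description code.
* Only mass-action kinetic laws are supported; SBML models with other rate
  laws are out of scope, and the TSV dialect is the supported interchange
  format.
* The stability protocol supports, but can never prove, per-class global
  stability; a failing class may equally mean slow convergence within the
  fixed horizon.  Multistationarity detection and bifurcation analysis are
  non-goals.
* Leaky LoF mutations, enzyme-activity-reduction mutations (zeroing a rate
  constant while keeping the column) and constitutive-production
  pseudo-reactions are natural extension points, deliberately not
  implemented.
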