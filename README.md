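# crnmut

Simulating loss- and gain-of-function cancer mutations in mass-action
chemical reaction networks.

## What this is for

Signalling networks — the reaction systems through which a cell processes
growth-factor signals down to its transcription factors — can be written as
mass-action CRNs: `n` species with concentrations `x` (nM), `r` reactions
with rate constants `k`, and dynamics

    dx/dt = S v(x, k),        v_j = k_j * prod_i x_i^(a_ij)

with `S` the stoichiometric matrix.  Cancer-associated mutations perturb
such networks in two canonical ways, and both can be expressed as
*projection operators* on the healthy system:

* a **loss-of-function (LoF)** mutation of a free-form ("elemental")
  protein removes its entire conserved moiety: a projection of the *state*
  that zeroes the protein, all its compounds, and the corresponding
  conserved total `c_j` in `c = N x`, where the rows of `N` are the
  semi-positive conservation vectors (`S^T gamma = 0`, `gamma >= 0`);
* a **gain-of-function (GoF)** mutation makes a protein constitutively
  active by deleting the deactivation reactions of its active form: a
  projection of the *stoichiometric matrix* that zeroes the corresponding
  columns of `S`.

Because trajectories are confined to stoichiometric compatibility classes
`{y >= 0 : N y = N x}`, and the projections map classes to classes (LoF) or
preserve them outright (rank-preserving GoF), the mutated steady state is
independent of which representative state was projected and of the order in
which mutations are applied — provided each class carries a single globally
attracting steady state.  The package implements the whole chain needed to
use and to check this picture:

* exact (integer/rational) enumeration of the conservation-law generators,
  elemental-species selection, and the block decomposition `N = [I_p, N2]`;
* compatibility-class arithmetic: invariants, ideal states, and the
  sequential random sampler of states within a fixed class;
* LoF/GoF projections, exact rank-preservation certificates, and direct or
  one-mutation-at-a-time composition;
* stiff ODE integration (deSolve, `lsoda`/BDF) to the asymptotic steady
  state with exact conservation-drift checking;
* a Monte-Carlo protocol that probes per-class global stability by
  comparing the dispersion of many random initial states with the
  dispersion of the steady states they reach.

Audience: systems biologists and applied mathematicians who want to run
in-silico knockout/activation experiments on mass-action models, or to
check the conservation structure and stability behaviour of their networks.

## Worked example

The phosphorylation/dephosphorylation futile cycle — substrate `A`,
kinase `K`, phosphatase `P`, reactions `A + K <-> AK -> A* + K` and
`A* + P <-> A*P -> A + P` — combined mutation: knock out the kinase (LoF of
`K`) and make `A*` constitutively active (GoF: delete the two forward
deactivation reactions).

```r
library(crnmut)
net <- fixture_phospho_cycle()          # totals A=10, K=5, P=5 nM
cs  <- conservation_laws(net)
cs
#> <crn_conservation> 3 semi-positive conservation law(s); rank(S) = 3
#>   basis assumption p = n - rank(S): holds
#>   elemented; elemental species: A, K, P

x_e <- integrate_to_steady(net, conservation = cs)$x_e   # physiological state
round(x_e, 4)
#>      A      K      P     A*     AK    A*P
#> 2.3166 2.3166 2.3166 2.3166 2.6834 2.6834

H <- deactivation_reactions(net, "A*")   # suggested GoF reaction set
H
#> [1] "debind_f" "decat"

mut <- apply_mutation_spec(net, cs, mutation_spec(lof = "K", gof = list(H)), x_e)
ss  <- integrate_to_steady(mut$network, mut$x0, conservation = cs)
relative_difference(ss$x_e, x_e)
#> # A tibble: 6 × 4
#>   species  phys      mut     d
#>   <chr>   <dbl>    <dbl> <dbl>
#> 1 A        2.32 5.00e+ 0  1.16
#> 2 K        2.32 0        -1
#> 3 P        2.32 5.00e+ 0  1.16
#> 4 A*       2.32 5.00e+ 0  1.16
#> 5 AK       2.68 0        -1
#> 6 A*P      2.68 3.66e-71 -1
```

Reading the `d` column (`d_i = (x_mut_i - x_phys_i) / x_phys_i`): the kinase
moiety is fully suppressed (`d = -1` for `K` and `AK`), the phosphatase is
fully liberated from its complex (`A*P` drains through its remaining reverse
reaction, so `P` rises to its total of 5 nM), and the substrate moiety ends
split between free `A` and the now-undegradable active form `A*`.

Result objects follow broom/ggplot2 conventions: `tidy()` and `glance()`
return tibbles, `autoplot()` draws the standard diagnostic figures
(derivative-norm decay for steady-state runs, per-class dispersion bars for
stability reports).  Networks are read and written as plain TSV
(`species.tsv`/`reactions.tsv`, see `?read_crn`), and a thin command-line
front end with `analyze`, `sample`, `steady`, `mutate` and
`verify-stability` subcommands lives at `inst/scripts/crnmut`.

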