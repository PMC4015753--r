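# paramcorr

Parameter correlation analysis and experimental design for nonlinear ODE
models of biochemical networks.

## The problem

Kinetic models routinely contain groups of parameters that compensate each
other: coordinated changes leave every model trajectory unchanged, so a
perfect fit to one experiment says nothing about the individual values. For
a model

$$\dot{x} = f(x, u, p), \qquad y = h(x, u, q)$$

with constant experimental controls $u$, the state sensitivities
$S = \partial x/\partial p$ obey $\dot S = (\partial f/\partial x)S +
\partial f/\partial p$, $S(t_0) = 0$, which makes $S$ a linear integral
transform of $\partial f/\partial p$ along the trajectory. Linear
dependences among the columns of $\partial f/\partial p$ are therefore
inherited by every sensitivity and every output: the parameters involved
are non-identifiable from that experiment.

paramcorr samples $\partial f/\partial p$ (derived symbolically from the
model text) along trajectories, finds the dependent column groups from the
numerical null space, classifies each group — *pairwise* (all columns
parallel), *linked sets* (parallel sets tied by one relation) or a *joint
single relation* — and as *practical* (the dependence involves $u$ and
breaks under new inputs) or *structural* (no input helps). The
minimum number of data sets with distinct control inputs needed for unique
estimation is the largest group requirement: $k$ for a pairwise or joint
group of $k$ parameters, $\max(l_1, \dots, l_d, d)$ for linked sets. The
package also simulates experiment data, fits all data sets simultaneously
by multistart Levenberg–Marquardt with analytic sensitivities, and traces
zero-residual surfaces in correlated-parameter subspaces.

## Worked example

The built-in benchmark is the classic three-step metabolic pathway — three
genes, their enzymes and two metabolites (8 states, 36 parameters) with the
pathway substrate `S` and product `P` as constant controls:

```r
library(paramcorr)

bench <- three_step_pathway()
designs <- generate_designs(bench$model, 5, bench$nominal$controls,
                            bench$nominal$x0, seed = 1)
analyze_correlations(bench$model, bench$nominal$p, designs, seed = 1)
```

```
Parameter correlation analysis
  correlated groups: 5
   - <correlation_group> {p1, p2, p3, p4, p5}: pairwise_all, requires 5 data sets (practical)
   - <correlation_group> {p7, p8, p9, p10}: sets_linked [{p7} {p8,p9} {p10}, d = 3], requires 3 data sets (practical)
   - <correlation_group> {p13, p14, p15, p16}: sets_linked [{p13} {p14,p15} {p16}, d = 3], requires 3 data sets (practical)
   - <correlation_group> {p28, p29, p30}: joint_single_relation, requires 3 data sets (practical)
   - <correlation_group> {p35, p36}: pairwise_all, requires 2 data sets (practical)
  pairwise-parallel clusters (base design): 4
  rank by stacked designs: 26 -> 31 -> 34 -> 35 -> 36 (NP = 36)
  minimum data sets for unique estimation: 5
```

Reading the output: a single experiment leaves five correlated groups (10
rank deficiencies, rank 26 of 36). Every group is practical, so new control
settings help; the largest group has five members, so five data sets with
distinct `(P, S)` settings are needed — and indeed the stacked Jacobian
reaches full rank 36 at five designs. A zero-height dendrogram cluster
appears for each *pairwise* correlation (four of them); the two higher-order
groups are invisible to the dendrogram, which is why the null-space
analysis is the decision tool.

Downstream, with five simulated noise-free data sets the simultaneous fit
recovers all 36 parameters to the printed values (relative error below
1e-3), while a two-data-set fit pins only the small groups (e.g. the
Michaelis pair p35/p36 lands on 1.0) and leaves the five-member group on
its residual manifold. See the vignette
(`vignettes/parameter-correlations.Rmd`) for the model, the algorithms and
the numerical choices.

A thin command-line wrapper ships in `inst/scripts/paramcorr.R`
(`simulate | analyze | fit | surface | case-study`), and
`run_case_study()` executes the whole pipeline and writes a versioned JSON
report.

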