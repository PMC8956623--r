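---
title: "Group analysis of weighted structural connectomes with connstat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group analysis of weighted structural connectomes with connstat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Diffusion tractography yields, per subject, a symmetric matrix of
inter-regional connection strengths — here mean fractional anisotropy (FA)
along the streamlines joining two parcellated gray-matter regions. Comparing
such weighted networks between a control group and two or more disease
groups raises four intertwined statistical problems that `connstat`
addresses as one pipeline:

1. **Spurious and missed connections.** Tractography produces both
   false-positive and false-negative edges, so raw matrices must be screened
   before any topology is computed.
2. **Non-Gaussian, bounded measures with nuisance covariates.** Group
   differences in graph measures must be tested while controlling for age
   and sex, without leaning on normality.
3. **Mass-univariate edge testing.** Edge-level inference over thousands of
   connections needs family-wise error control that respects the network
   structure (NBS).
4. **Clinical linkage.** Network measures must be related to clinical scores
   (EDSS disability, disease duration) within disease groups, again with
   covariate control and with scores that are simply undefined for
   controls.

Because patient DTI data of this kind are rarely shareable, the package
carries a synthetic cohort generator with complete ground truth; every
statistical claim the package makes about itself is demonstrated on data
whose correct answer is known by construction.

# Network measures

All measures operate on a `weighted_network`: a symmetric, non-negative
matrix with zero diagonal; an edge exists wherever the weight is strictly
positive. With $w_{ij}$ the weight, $a_{ij} = [w_{ij} > 0]$, and $N$ nodes:

* degree $K_i = \sum_j a_{ij}$, nodal strength $S_i = \sum_j w_{ij}$, total
  strength $\sum_i S_i$ (the row-sum convention: each undirected edge
  contributes twice — this is the definitionally literal reading of "sum of
  nodal strengths" and is stated in the output documentation so magnitudes
  are interpretable);
* triangle intensity $t_i = \tfrac12 \sum_{j,k} (w_{ij} w_{jk} w_{ki})^{1/3}$
  and clustering $C_i = 2 t_i / (K_i (K_i - 1))$, zero when $K_i < 2$; the
  global coefficient averages $C_i$ over **all** nodes, zeros included;
* path lengths use the reciprocal-weight transform $\ell_{ij} = 1/w_{ij}$
  (strong connections are short) with Dijkstra shortest paths;
  characteristic path length averages the finite off-diagonal $d_{ij}$ only
  — disconnected pairs are ignored rather than imputed, and a network with
  no finite pair is an error rather than a silent zero;
* global efficiency $E_{glob} = \frac{1}{N}\sum_i \frac{\sum_{j \ne i}
  d_{ij}^{-1}}{N-1}$ and regional efficiency $E_{reg}(i) =
  \frac{1}{N-1}\sum_{j\ne i} d_{ij}^{-1}$, with $d^{-1} = 0$ for
  disconnected pairs;
* local efficiency of node $i$ sums
  $(w_{ij} w_{ik} [d_{jk}(N_i)]^{-1})^{1/3}$ over ordered neighbour pairs
  and divides by $K_i(K_i-1)$, where $d_{jk}(N_i)$ is computed **inside the
  neighbour subgraph with the centre excluded**. Two conventions here were
  genuinely open and are worth stating: (a) published nodal formulas for
  weighted local efficiency sometimes carry a leading $\tfrac12\sum_i$
  inherited from collapsing the global average into the nodal definition;
  we treat the nodal quantity as the ordered-pair sum divided by
  $K_i(K_i-1)$, the convention of the efficiency literature, and average
  over all nodes for the global value. (b) Whether $d_{jk}$ uses full-graph
  or subgraph paths is often left implicit; the subgraph reading follows
  directly from defining the local subgraph as the neighbour set excluding
  the centre. The test suite pins both choices against a literal
  brute-force oracle (neighbour enumeration plus subgraph Dijkstra).

Weights are used as-is (FA lies in (0,1)); no normalisation precedes the
cube roots. Shortest paths for the full graph go through `igraph`'s
Dijkstra; neighbour subgraphs use an internal Floyd–Warshall, and both are
validated against independent scalar oracles to $10^{-10}$ on random
networks.

# Edge screening

The prevalence of an edge is the fraction of **control** subjects in which
it exists. Given a candidate group threshold $\tau$, edges with prevalence
$\ge \tau$ form the "existing" set; counting over control subjects, an
existing edge absent in a subject is a false negative and a non-existing
edge present in a subject is a false positive. Under these definitions FN
is non-increasing and FP non-decreasing in $\tau$ (raising $\tau$ shrinks
the existing set), so the two counts cross; `optimal_threshold()` picks the
grid value minimising $\max(\mathrm{FP}, \mathrm{FN})$ — the minimax point
of two monotone step functions is exactly the balance point — breaking ties
toward the smaller $\tau$, which retains more edges. Note that narrative
descriptions of this procedure sometimes state the monotonicities the other
way around; the implementation follows the definitions, and the test suite
asserts the monotone directions on random cohorts.

Two deliberate choices: existence is $w > 0$ exactly (FA means are positive
wherever any streamline connected the pair), and both prevalence and the
FP/FN counts use control subjects only — letting patients shape the mask
would let disease effects leak into edge selection. The grid runs
0, 0.01, …, 1 (thresholds of this kind are conventionally reported to two
decimals). The control-derived mask is then applied to every subject of
every group.

# Permutation ANCOVA and FDR

Group effects on any measure are tested by the partial F of the group
factor given age and sex:
$$F = \frac{(\mathrm{RSS}_{reduced} - \mathrm{RSS}_{full})/(g-1)}
           {\mathrm{RSS}_{full}/(n-g-q)}$$
with the reduced model containing intercept and covariates only. The
permutation null uses the Freedman–Lane scheme: residuals of the reduced
fit are permuted and added back to the reduced fitted values, and the
statistic is recomputed — the standard asymptotically exact approach for
"ANCOVA with permutations" when nuisance covariates must be respected. With
no covariates it collapses to plain label permutation (asserted numerically
in the tests). P-values use the add-one convention
$p = (1 + \#\{F^* \ge F\})/(1 + B)$, so the smallest attainable value is
$1/(B+1)$ and no p-value is ever zero.

Degenerate responses are handled explicitly: a response fitted exactly by
the covariates alone gives $F = 0$; a response fitted exactly only by the
full model gives $F = \infty$ (which orders correctly in permutation
counts). The tolerance separating "exact fit" from rounding noise is
relative to the response's sum of squares.

Nodal comparisons run the omnibus test at every node with a shared
permutation stream (each node's p-value remains marginally valid), correct
across nodes by Benjamini–Hochberg FDR, and give surviving nodes the three
pairwise post-hoc comparisons, FDR-corrected across the three pairs.
Pairwise post-hoc tests refit on the two groups' subjects rather than using
contrasts inside the three-group fit — the natural reading of "pairwise
ANCOVA" — and direction labels (`MS < HC`) come from covariate-adjusted
group means at the overall covariate mean. FDR is Benjamini–Hochberg
step-up via `p.adjust`; Bonferroni is available for debugging only.

# Network-based statistics

Edge-wise partial F statistics over the screened edges are thresholded at
the cluster-forming value (default $F \ge 3.0$, inclusive — the boundary
convention has to be fixed somewhere and is documented in the result
object), connected components of the suprathreshold graph are extracted,
and component **extent** (edge count, not node count — published disrupted
subnetworks are described by their edges) is referred to a permutation null
of the **maximum** extent: one Freedman–Lane permutation produces one full
edge-stat matrix and one max-extent draw, the standard NBS scheme. This
controls the family-wise error of declaring any component significant.
Component extraction uses an internal union–find (cheap enough to run once
per permutation); the test suite checks it against `igraph`'s component
labelling on random matrices.

The cluster-forming threshold is a config value, not a fitted quantity:
selecting it by cluster stability across runs is an analyst procedure. Two
regimes matter in practice. For *detection* of diffuse differences the
conventional $F = 3.0$ (edge-level $p \approx 0.06$ at these group sizes)
is the default. For *recovery* of a compact planted subnetwork in
simulation, a stricter forming threshold ($F = 8$) is used by the demo and
the power checks: with a very large planted effect the planted edges
survive any reasonable threshold, while the stricter value keeps
suprathreshold noise edges (about 6% of edges at $F = 3$, any of which
merges into a component it touches) from inflating the recovered cluster.
The value follows from a Poisson argument about incident null edges: an
8-edge planted component at density 0.6 on 40 nodes typically spans ~9
nodes and touches ~170 other edges, so the expected number of chance
suprathreshold attachments is ~10 at $F=3$ (edge-set overlap with the
planted set diluted to ~0.5), ~0.9 at $F=6$ (overlap $\ge 0.8$ in only
~94% of draws, before attachment cascades), and ~0.2 at $F=8$, where two
or fewer attachments — overlap still $\ge 0.8$ — occur in over 99.8% of
draws.

Post-hoc tables report, per component edge, the three pairwise
permutation-ANCOVA p-values FDR-corrected across the pairs, with direction
labels; `count_significant()` counts a table column below a level, which is
also how the bundled published reference table (two subnetworks of 29 and 5
edges) is consumed as a worked example.

# Clinical associations

The association model is fitted literally as stated in the source
literature for this analysis family:
$$\mathrm{clinical} = \beta_0 + \beta_1\,\mathrm{measure} +
\beta_2\,\mathrm{age} + \beta_3\,\mathrm{sex} + \varepsilon,$$
with the clinical score as the response, by OLS within one disease group at
a time; subjects missing the score are dropped pairwise (controls typically
have no EDSS or duration at all and are skipped with a notice). The
reported `beta1` is unstandardized, on the raw measurement scale. Its
p-value is the analytic partial F by default — nothing in the model
requires permutation here — with a Freedman–Lane permutation option on the
measure term. EDSS is treated as continuous despite its ordinal origin,
matching how such models are conventionally fitted; an ordinal model is out
of scope. A minimum of five complete cases is required per fit.

# The synthetic cohort generator

`simulate_cohort()` draws subject networks as
$$w^{(s)} = \mathrm{clip}_0\!\big(\mathrm{template} \times
\mathrm{scale}_{g(s)} + \delta_{g(s)}\,[\text{planted edge}] +
\beta_{age}(age_s - \overline{age}) + \beta_{sex}\,sex_s +
\varepsilon\big)$$
on template edges; non-edges stay exactly zero. The defaults are the
package's standing description of the emulated study conditions and are not
adjusted per analysis:

* **Template**: Erdős–Rényi at 60% density on 90 nodes (AAL-90 labels
  bundled), resampled until connected. This is the simplest null topology;
  it reproduces the density regime of screened FA networks but *not* the
  small-world/modular structure of real connectomes — conclusions about
  topology-dependent behaviour of the metrics on real data do not follow
  from these simulations, only the correctness and calibration of the
  procedures do.
* **Weights**: truncated normal, mean 0.45, SD 0.1, bounded to
  [0.2, 0.7] — the FA range implied by the usual FA > 0.2 tracking
  threshold.
* **Subject noise**: additive Gaussian per edge, SD 0.04 by default
  (about 10% of the mean weight), clipped at zero. Real FA noise is
  heteroscedastic and spatially correlated; additive i.i.d. noise is the
  deliberate minimal model.
* **Groups**: one control and two disease groups of 15 (three-group
  designs of this size are typical for single-centre demyelinating-disease
  cohorts); disease groups get a multiplicative global attenuation (0.9 by
  default, matching the direction — lower strength and efficiency, longer
  path length — expected in demyelinating disease) and/or an additive
  planted delta on a connected edge set grown inside the template.
* **Covariates**: ages Normal(35, 9) for control and MS-like groups,
  Normal(44, 12) for the NMOSD-like group (truncated at 18), sex Bernoulli
  with P(female) = 0.7 — the demographic profile typical of these
  diseases. Null cohorts for calibration use the control age distribution
  for *every* group so that labels are exchangeable by construction.
* **Clinical scores**: linear in a subject's *realized* global measure
  plus age and sex, with Gaussian noise, defined only for disease groups.
  Scores are left unclipped so that coefficient-recovery and interval
  coverage checks are exact; occasional out-of-range values are accepted
  as the price of exactness.

# Numerical and procedural choices

* Symmetry repair on input averages the two triangles only below a $10^{-8}$
  tolerance; larger asymmetry is an error, never silently fixed.
* Prevalence/threshold comparisons carry a $10^{-9}$ slack so that ratios
  like 13/20 compare correctly against grid values like 0.65.
* Permutation streams are seeded through a single config seed fanned out by
  fixed child-seed derivation per stage; identical config and seed give
  byte-identical numeric tables (asserted in the tests).
* Ties in Dijkstra are irrelevant (only lengths are used); no path
  reconstruction is performed.
* All simulation sizes in the test and acceptance suites (e.g. 1000 null
  cohorts at 500 permutations for type-I calibration; 500 null and 100
  planted replicates at 40 nodes for NBS error and power; 500 replicates
  for interval coverage) were fixed when the suites were designed, as the
  smallest sizes at which the binomial Monte-Carlo error is comfortably
  inside the asserted bands.

# Worked example

```{r, eval = FALSE}
library(connstat)
report <- run_demo(seed = 1)
print(report)
summary(report$nbs)
report$recovery_jaccard
```

The demo generates a 40-node cohort with an 8-edge planted subnetwork,
writes it as a manifest plus matrix directory, reads it back through the
standard I/O path, and runs every stage. With the default seed the planted
component is recovered as the top significant NBS component with an
edge-set Jaccard overlap of at least 0.8, and the null-mode demo
(`run_demo(mode = "null")`) declares nothing significant.

# Known limitations

* Imaging front ends (tractography, parcellation, lesion handling) are out
  of scope; the package begins at connectivity matrices.
* The Erdős–Rényi template limits what the simulations can say about
  metric behaviour on realistically structured connectomes (see above).
* The permutation machinery assumes exchangeable subjects under the null
  within the Freedman–Lane approximation; family structure or site effects
  would need block permutation, which is not implemented.
* Binary-network variants, small-worldness indices, rich-club coefficients
  and betweenness are deliberately absent.
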