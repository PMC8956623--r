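# connstat

Group analysis of weighted structural brain connectomes in R.

`connstat` is for researchers comparing diffusion-MRI-derived connectivity
matrices between patient groups and controls — the typical setting is a
three-group cohort (e.g. multiple sclerosis, neuromyelitis optica spectrum
disorder, healthy controls) with one FA-weighted 90×90 matrix per subject,
ages, sex, and clinical scores such as EDSS and disease duration. The
package covers the full analysis chain:

1. **Edge screening** — per-edge prevalence in the control group, false-
   positive/false-negative counts across a threshold grid, and the minimax
   balance point as the group threshold; the control-derived mask is applied
   to all subjects.
2. **Weighted graph metrics** — degree `K_i = Σ_j a_ij`, strength
   `S_i = Σ_j w_ij` and total strength, Onnela-style weighted clustering
   `C_i = 2t_i / (K_i(K_i−1))` with `t_i = ½ Σ_{j,k} (w_ij w_jk w_ki)^{1/3}`,
   characteristic path length over finite reciprocal-weight Dijkstra
   distances, and global / local / regional efficiency.
3. **Permutation ANCOVA** — partial F for the group factor controlling age
   and sex, Freedman–Lane residual permutation, Benjamini–Hochberg FDR, and
   pairwise post-hoc comparisons with direction labels, at the global and
   nodal level.
4. **Network-based statistics (NBS)** — edge-wise F statistics, cluster
   forming at a threshold (default `F ≥ 3.0`), component extent (edge
   count) against a permutation null of the maximum extent for family-wise
   error control, and per-edge post-hoc tables.
5. **Clinical associations** — `clinical = β0 + β1·measure + β2·age +
   β3·sex` by OLS within each disease group, missing scores excluded
   pairwise.
6. **Synthetic cohorts** — a generator for FA-like connectome cohorts with
   known ground truth (global attenuation, planted connected subnetworks,
   covariate effects, clinical linkage), used by the whole test suite.

## Worked example

```r
library(connstat)
report <- run_demo(seed = 1)   # generates, writes, re-reads, analyses
print(report)
#> <connstat_report>
#>   screening: threshold 0.01, 468 edges retained
#>   global comparison: 5 of 5 measures with omnibus p <= 0.05
#> <nbs_result> cluster-forming threshold F >= 8, 500 permutations
#>   component 1: extent 9 edges, 8 nodes, p_fwer = 0.001996 *
#>   component 2: extent 1 edges, 2 nodes, p_fwer = 0.4212
report$recovery_jaccard
#> [1] 0.8888889
```

The demo plants an 8-edge connected subnetwork (weights reduced by 0.3 in
the MS-like group and 0.15 in the NMOSD-like group) in a 40-node cohort of
15 subjects per group. The printed report shows the screening threshold and
retained edge count, then the NBS components: the planted cluster comes
back as the top significant component (`p_fwer = 1/501`, the most extreme
value achievable with the add-one convention at 500 permutations) with an
edge-set Jaccard overlap of 0.89 against the planted truth; the second,
single-edge component is noise and is correctly non-significant. Running
`run_demo(seed = 1, mode = "null")` on an effect-free cohort declares
nothing significant.

On real data the entry point is a manifest CSV (`subject_id, group, age,
sex, matrix_file`, plus optional clinical columns) next to one matrix CSV
per subject:

```r
cohort <- read_cohort("cohort/manifest.csv")
report <- run_pipeline(cohort, analysis_config(seed = 1), out_dir = "report")
```

A thin command-line wrapper with the same functionality ships at
`inst/scripts/connstat-pipeline.R`.

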