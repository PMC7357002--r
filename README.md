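# geofuncnet

Co-occurrence network analysis for functional gene arrays (GeoChip-like
data) from environmental microbial communities.

A functional gene array probes thousands of genes involved in
biogeochemical cycling (carbon, nitrogen, phosphorus, sulfur), stress
response, resistance and contaminant degradation, plus phylogenetic
marker probes (e.g. *gyrB*) tied to taxa. Given the gene-by-site signal
matrix from such an array, `geofuncnet`:

- **builds a weighted co-occurrence network** from presence/absence
  profiles — Pearson profile correlation, unsigned soft-threshold
  adjacency `|r|^β`, and the topological overlap matrix
  `TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)` —
  then detects **modules** by average-linkage clustering of `1 − TOM`
  with a static tree cut, small-branch pooling and an optional
  consensus-profile refinement;
- **classifies module topology** (ER-like homogeneous wiring vs
  scale-free-like hub-dominated wiring) from the degree distribution's
  power-law fit index and variance/mean ratio;
- **clusters genes geographically** with KMeans++ seeding on squared
  Hamming distances and Lloyd iterations, including the tie
  multi-assignment variant (a gene equidistant from several centroids
  belongs to all of them) and a restart-based stability score;
- **mines association rules** among functional categories across sites
  with a level-wise Apriori, keeping sub-threshold rules in a side
  channel (the absence of strong function-level rules is itself
  informative);
- **tests compositional hypotheses**: per-category scaling regressions
  of gene count on group size (proportional representation gives slope
  = 1/#categories), exact Wilcoxon homogeneity tests, Holm-corrected
  pairwise Welch tests, and correlations between phylogenetic and
  functional module distributions;
- **simulates calibrated communities** with planted modules, exact
  largest-remainder category shares, Bernoulli flip noise and
  independent phylogenetic blocks, for validation when no array data
  are available.

## Worked example

End-to-end run on a simulated 600-gene, 10-site community with five
planted modules:

```r
library(geofuncnet)

cfg <- sim_config(n_genes = 600, n_modules = 5, n_marker_genes = 40,
                  n_taxa = 12, seed = 7)
params <- pipeline_params(k = 5, n_restarts = 5, min_module_size = 8)
report <- run_pipeline(cfg, params, seed = 7)
print(report)
```

Output:

```
Functional-gene-array pipeline report (schema 1.0 )
input: 600 genes x 10 sites, coverage 0.638
prevalence filter (>= 6 sites): 512 genes retained
network: 5 modules (+0 genes unassigned), 31654 links
clusters: k = 5, stability 0.913
scaling: pooled slope 0.1000 (clusters), R^2 0.95-1.00
recovery vs planted truth: module ARI 0.970, cluster ARI 0.969
```

All five planted modules are recovered (adjusted Rand index 0.97
against the planted truth), and the scaling regression recovers the
planted common category share of 0.1 with near-perfect per-category
linearity. Passing `out_dir =` additionally writes the gene table,
presence matrix, module/cluster assignments, edge list, itemsets, rules
and a JSON report; identical inputs and seed reproduce the report
bit-for-bit.

Individual stages are ordinary functions — for example:

```r
sim <- generate_community(cfg)
fp  <- binarize(sim$signal)[!sim$gene_table$is_phylo, ]
tom <- topological_overlap(soft_adjacency(profile_correlation(fp), 10))
mods <- detect_modules(tom, min_module_size = 8, refine_with = fp)
topology_report(tom, mods, tau = 0.1)
```

A command-line interface with `simulate` and `run` subcommands is
installed at `inst/scripts/funcnet.R`.

## Reproduction

Run the full test suite (unit tests with independent oracles, plus a
property-based acceptance suite covering oracle equivalence,
planted-structure recovery at 5,000-gene scale, topology
discrimination, statistical calibration and structural invariants)
against the installed package:

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "geofuncnet",
                               load_package = "installed")'
```

Recompute the headline quantities (coverage, module/cluster recovery
ARI, stability, pooled scaling slope, topology classification rates,
null calibration) from a single seed:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Every random draw in the script and the pipeline derives
deterministically from the given seed.

## Documentation

Methods, model assumptions, parameter defaults, generator scope and
numerical choices are documented in
`vignettes/geofuncnet-methods.Rmd`; function-level documentation lives
in roxygen comments alongside the source in `R/`.

## License

MIT (see `LICENSE`).
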