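# gptide

Gaussian-process time-course differential expression for the
maternal-to-zygotic transition, with trajectory clustering, 3′-UTR
microRNA-seed enrichment, promoter motif enrichment and repetitive-locus
read quantification.

## Who this is for

Developmental and RNA biologists comparing a perturbed embryo series
against controls across a densely sampled time course (e.g. uninjected
controls, UIC, versus morphants, MO, sampled every 30 min through the MZT)
who want to ask, per gene: *do the two conditions follow different
temporal trajectories, and what do the diverging genes have in common?*

## The statistic at the core

Each gene's TPM series is variance-stabilized,

```
f(x) = log2((x + α) / (m_i + β)),   α = 1, β = 1000,
```

with `m_i` the gene's maximum over all samples, then modelled by exact GP
regression with a Matern 5/2 kernel (hyperparameters `σ_f`, `τ`, `σ_n`
optimized as MAP in log space under normal priors; BFGS then Nelder–Mead).
Evidence for condition-specific trajectories is the marginal
likelihood ratio

```
LR = L_U + L_M − L_UM,
```

comparing separate fits for the two conditions with a single fit through
the pooled points, called at a null-calibrated threshold. Called genes are
k-means-clustered (seed 1618033) on max-normalized GP medians with
silhouette selection of k over 2–10; clusters are then interrogated for
microRNA seed matches (canonical 7-mer, offset 6-mer, extended 8-mer, in
transcriptome space), RNA elements (EDEN, ARE, YTHDF2), promoter PWM
scores (log2 likelihood ratio against genomic base frequencies, threshold
chosen above 5 to maximize cluster association), and 1/N-weighted coverage
of a repetitive microRNA locus, all with right-tail Fisher exact tests.
A synthetic-data generator with planted ground truth produces every input,
so the whole analysis is testable end to end.

## Worked example

```r
library(gptide)

# simulate the study design: 20 half-hourly timepoints, UIC vs MO,
# six planted trajectory classes of 20 genes each plus 30 null genes
cfg <- sim_config(n_genes = 150, noise_cv = 0.05, seed = 1618033,
                  library_types = "polyA",
                  cluster_spec = default_cluster_spec(n_per_cluster = 20))
sim <- simulate_timecourse(cfg)

keep <- filter_expressed(sim$datasets)       # run of 6 samples > 0.4 TPM
de   <- gp_de(sim$datasets$polyA, keep, lr_threshold = 5)
dplyr::count(de[de$called, ], direction)
#> # A tibble: 2 × 2
#>   direction     n
#>   <chr>     <int>
#> 1 decreased    47
#> 2 increased    52
head(de, 3)
#> # A tibble: 3 × 7
#>   gene_id     L_U    L_M  L_UM    LR direction called
#>   <chr>     <dbl>  <dbl> <dbl> <dbl> <chr>     <lgl>
#> 1 gene00001 6.12  -5.93  -63.9  64.1 increased TRUE
#> 2 gene00002 1.91   0.283 -63.4  65.6 increased TRUE
#> 3 gene00003 0.519 -4.23  -64.1  60.4 increased TRUE
```

The planted U-class genes (maternal transcripts whose clearance the
morphant blocks) are called `increased` with LR far above the null; `LR`
is exactly `L_U + L_M − L_UM`. The genes that escape calling are mostly
the late-onset decreased class, whose divergence window is shortest.
Continuing,

```r
traj <- gp_trajectories(sim$datasets$polyA, de$gene_id[de$called])
cl   <- cluster_trajectories(traj, de[de$called, ], k = 3)
table(cl$cluster)
#> D1 D2 D3 U1 U2 U3
#> 20 20  7 20 20 12
```

recovers the planted early/mid/late structure (93% label agreement with
the planted truth on the called genes), with `U1` the
earliest-diverging increased cluster. Seed enrichment on UTRs planted with
six copies of the extended miR427 seed `AGCACTTT` in U1 genes peaks at
that cluster and copy number (see `enrichment_matrix()`), mirroring how a
clearance-microRNA's targets concentrate in the earliest cluster.

A full simulated run with every stage and a manifest:

```r
run_dir <- run_pipeline(pipeline_config(lr_threshold = 5))
report_summary(run_dir)
```

or from a shell: `Rscript inst/scripts/run_pipeline.R --outdir myrun`.

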