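---
title: "Gaussian-process time-course differential expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian-process time-course differential expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gptide)
```

## The scientific problem

During the maternal-to-zygotic transition (MZT), maternally deposited
transcripts are cleared while zygotic transcription switches on. An
intervention that perturbs this handoff — here, depletion of a nucleoporin in
morpholino-injected (MO) embryos compared with uninjected controls (UIC) —
shows up as genes whose *temporal trajectory* differs between conditions:
maternal transcripts whose clearance stalls, or zygotic genes whose
activation is damped. `gptide` implements the full desk analysis for a
two-condition developmental RNA-seq time course sampled densely (by default
20 timepoints at 0.5 h spacing, emulating half-hourly sampling across
roughly ten hours of development), in polyA-selected and rRNA-depleted
(ribozero) library types.

## Variance-stabilizing transform

RNA-seq abundances are overdispersed and span orders of magnitude. Before
any regression, each gene's TPM values are mapped through

$$f(x) = \log_2\!\frac{x + \alpha}{m_i + \beta}, \qquad \alpha = 1,\ \beta = 1000,$$

where $m_i$ is the gene's maximum abundance over all samples of both
conditions. The offset $\alpha$ keeps zeros finite; the large denominator
offset $\beta$ compresses the dynamic range of lowly expressed genes so
that one common set of hyperpriors is reasonable transcriptome-wide.
Posterior summaries are reported back on the TPM scale through the exact
inverse $x = 2^y (m_i + \beta) - \alpha$; because the map is monotone, the
posterior median and the 95% band edges transform directly. Back-transformed
band edges can dip slightly below zero (never below $-\alpha$); they are
reported as-is rather than clipped.

## Gaussian-process regression and the likelihood-ratio test

Each transformed series is modelled as a zero-mean Gaussian process with a
Matern 5/2 kernel

$$k(r) = \sigma_f^2\left(1 + \frac{\sqrt5\,r}{\tau} + \frac{5r^2}{3\tau^2}\right)e^{-\sqrt5\,r/\tau},$$

plus independent Gaussian observation noise $\sigma_n^2$. The three
hyperparameters are optimized in log space by maximizing the penalized
marginal likelihood (BFGS with analytic gradients, then a Nelder–Mead
polishing step, multi-started from five prior draws under a fixed seed).
The hyperpriors are normal on the logs and configurable; the defaults are

* $\log\tau \sim \mathcal N(\log 2.5\,\mathrm h,\ 0.5^2)$ — timescales
  comparable to the spacing of developmental stages; much shorter would fit
  noise, much longer cannot track clearance;
* $\log\sigma_f \sim \mathcal N(0, 1)$ — signal of order one on the
  transformed scale;
* $\log\sigma_n \sim \mathcal N(-1.5, 1)$ — noise below signal.

The stored `loglik` of a fit is the *marginal* log-likelihood at the MAP,
excluding prior terms, so that the test statistic compares marginal
likelihoods; a penalized variant is available by configuration.

Temporal differential expression is scored by the marginal likelihood
ratio: with $L_U$ and $L_M$ the per-condition marginal log-likelihoods and
$L_{UM}$ that of a single regression through the pooled points of both
conditions,

$$LR = L_U + L_M - L_{UM}.$$

The pooled fit observes every timepoint twice; this is well defined because
the noise variance is strictly positive, and the likelihood evaluator
admits duplicate times only when explicitly asked (the strict default
guards accidental duplicate grids). A gene is *increased* when the MO
posterior median exceeds the UIC median on average over the grid, and
*decreased* otherwise, with ties going to *decreased*.

No published LR cutoff exists for this analysis, so the default calling
threshold is calibrated: `null_lr_threshold()` simulates genes with no
condition effect under the study's noise model and returns the empirical
99.5th percentile of the null LR (seed 1618033). The choice of the 0.5%
rate is a package default, not a reproduced value, and is configurable.

### Numerical choices

* Cholesky factorization with a diagonal jitter of $10^{-8}\sigma_f^2$
  applied only on failure and recorded in the fit.
* Gradient step tolerance $10^{-6}$; simplex polishing at relative
  tolerance $10^{-8}$; five restarts (first start at the prior mode).
* Posterior bands are the latent-function mean $\pm 1.96$ posterior sd on
  the transformed scale; the prediction grid defaults to the observation
  grid and is refinable.
* A constant series fits cleanly (the MAP drives $\sigma_f$ small); an
  all-zero gene is rejected at the `lr_test()` boundary because its $m_i$
  is zero.

## Trajectory clustering

Called genes are clustered *within* direction. For each gene the UIC and MO
posterior medians are divided by the maximum value attained by either
condition and concatenated, so every feature vector lies in $[0,1]$ and
clustering sees shape, not level. K-means (Lloyd's algorithm with
k-means++ seeding from seed 1618033, squared-Euclidean objective) is run
for $k = 2\ldots10$ and the mean Euclidean silhouette selects $k$; across
related runs (two library types $\times$ two directions) the pipeline
reports the mode of the per-run selections. The within-cluster
sum-of-squares is asserted non-increasing across Lloyd iterations, and an
emptied cluster is re-seeded at the point farthest from its centroid.

Cluster names are assigned by ordering cluster means by divergence onset —
the first grid position at which the mean |MO − UIC| feature difference
exceeds 10% of the normalized scale — so `U1` is always the
earliest-diverging increased cluster. The numbering rule is a package
convention chosen for reproducible naming.

## 3' UTR seed and element enrichment

MicroRNA seeds are reported as the sequence present in transcriptome space:
the reverse complement of the mature microRNA window with U exchanged for
T. Three classes are built per microRNA: canonical 7-mer (nt 2–8), offset
6-mer (nt 3–8) and extended 8-mer (nt 2–9); for the mature miR427 sequence
`GAAAGTGCTTTCTGTTTTGGGCG` the extended seed is `AGCACTTT`. Every seed also
carries its minimum Hamming distance, over all offsets, to the extended
11-nt reverse-complement region `AAAGCACTTTC`, which groups seeds into
mismatch/offset classes relative to miR427.

Matches are counted at every start position (overlapping; a greedy
non-overlapping mode exists), with IUPAC codes honored in patterns
(`RRACH`) and `N` in a UTR never matching. Isoform counts aggregate to
genes by maximum (default; robust to isoform-count inflation) or sum —
both readings of "per gene" are implemented because the field uses both.
Enrichment of "at least $N$ copies" in a cluster against all other
filtered genes uses the right-tail Fisher exact test
(`phyper` upper tail), reported as $-\log_{10}P$ for $N = 1\ldots6$;
element motifs (EDEN, ARE `ATTA`, YTHDF2 `RRACH`) are tested at $N = 1$.
The 39-nt EDEN literal is matched exactly and is expected to be near-zero
in natural sequence; a degenerate user-supplied pattern can replace it.

## Promoter PWM enrichment

Motif count matrices (JASPAR-style text) become PWMs with a
background-distributed pseudocount (default 0.8). A site scores
$\sum_j \log_2 p_j(\mathrm{base})/p_{bg}(\mathrm{base})$; a gene's score is
the maximum over all windows of all its 500-bp promoters, on both strands
by default (transcription-factor sites are orientation-agnostic; forward-only
is available). Log base 2 is the package default and configurable, since
printed thresholds elsewhere do not fix the base. For each motif the score
threshold is chosen from every distinct observed score above 5 to minimize
the right-tail Fisher p of (above threshold) × (in any cluster), ties
going to the lower threshold; per-cluster enrichment is then computed at
that threshold. The genomic background is an input 4-vector; no genome is
required.

## Repetitive-locus quantification and short-fragment inference

Reads over a highly repetitive locus (the default interval spans ~135 kb)
are retained when *all* of their alignments fall inside the locus — the
strict reading; counting reads that also map elsewhere would inflate the
signal, and the permissive "any alignment inside" policy is provided for
comparison. Coverage uses fractional weights: a read with $N$ alignments
adds $1/N$ at every covered position, so each read contributes exactly one
unit of its span, an invariant asserted on every simulated set.

Short inserts (mature-microRNA length) are recovered from adapter
read-through: for each pair the smallest candidate length $f$ is accepted
at which read 1's first $f$ bases equal the reverse complement of read 2's
first $f$ bases and the remainder of read 1 matches the adapter prefix
over the available overlap, both at zero mismatches by default. Fragments
shorter than the mature query count as instances when they are substrings
of the query; longer ones when they contain it. The adapter defaults to
the standard Illumina TruSeq read-1 sequence and is configurable.

## The synthetic-data generator

Every input the pipeline consumes can be generated with planted ground
truth: expression matrices with deterministic trajectory families
(maternal decay, zygotic sigmoid, constant) diverging between conditions
from a configurable onset; UTRs with an exact, rejection-sampled number of
seed copies; promoters with consensus sites at recorded offsets;
multi-mapping alignments with known multiplicities; and read pairs built
from known fragments. Expression noise is multiplicative lognormal with a
stated coefficient of variation — a simple, strictly positive model that is
monotone under the log-family transform; the real count-noise process is
not specified by any reference, so the model is deliberately configurable.
Null genes share the trajectory law exactly between conditions and differ
only by independent noise draws.

What the generator does *not* emulate: alignment and base-call error,
library-size and composition biases (the per-gene multiplicative
correction hook is the identity by default), ERCC spike physics, isoform
switching, and correlated noise across timepoints. Passing tests therefore
demonstrate correctness of the statistics under the stated model, not
robustness to every artifact of real libraries.

## Problem sizes and determinism

The shipped checks run the analysis at the study design scale —
20 timepoints, lognormal noise at CV 0.05–0.1 — with gene counts chosen for
a laptop-class machine: 1,000 null genes for threshold calibration, 400
fresh nulls for type-I verification, 50 planted genes for power, 240 genes
per clustering run (three planted shape classes of 80). Every simulator
takes an explicit seed and restores the caller's RNG state, so all results
are bit-reproducible; the expressed-gene filter (a strict run of six
consecutive samples above 0.4 TPM in each library type, in at least one
condition — the per-condition reading is the default, with a pooled
interleaved mode available) is deterministic by construction.

## Known limitations

* MAP hyperparameters only; no full posterior over $\sigma_f, \tau,
  \sigma_n$.
* The dinucleotide/composition abundance correction is an interface
  (per-gene multiplicative factors), not a method; it defaults to the
  identity.
* The LR null distribution is simulated, not asymptotic; thresholds are
  therefore tied to the noise model used to calibrate them.
* Seed enrichment is purely count-based: no site accessibility, context
  scores or 3'-supplementary pairing.
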