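---
title: "Estimating transcriptional error rates from per-site base counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating transcriptional error rates from per-site base counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txerr)
```

## The problem

Circular-consensus RNA sequencing (Cir-Seq and similar protocols) reads each
mRNA fragment several times in tandem, so a consensus call removes ordinary
sequencing errors while retaining true transcription errors. The data that
survive preprocessing are per-site base counts: for each nucleotide locus of
the genome, in each experimental condition, how many consensus reads covered
it and how often each of the four bases was seen. A minority base among many
reads of one site is the signature of mistranscription.

`txerr` turns such tables into error-rate estimates. The unit of analysis is
the **possible error**: one (locus, condition, substitution type) triple.
Every retained site contributes exactly three possible errors, one per
alternative base, each with an error count $E_i$ (reads supporting that
alternative) and the site's read total $R_i$ as denominator. The three
records at a site share $R_i$; the coupling between them (an error of one
type slightly reduces the denominator of the other two) is ignored, which is
negligible at error rates of $10^{-5}$–$10^{-3}$.

Substitution types are expressed on the **transcript strand** in the RNA
alphabet: a genomic G→A minority base inside a minus-strand gene is a C→U
transcription error. C→U is special throughout: cytosine deamination during
sample preparation mimics C→U errors, and an artifact of preparation should
not depend on how highly a gene is expressed. C→U records are therefore
excluded from the main model by default and analysed separately.

## The rate model

For possible error $i$ in gene $j$, the per-read error rate is modelled as
an additive function of substitution type, condition, and the log protein
abundance of the gene,

$$\frac{E_i}{R_i} = \rho_{\mathrm{type}(i),\,\mathrm{cond}(i)}
  + \beta \, \log_{10}(\mathrm{abundance}_j),$$

and $E_i$ is treated as Poisson with mean $R_i$ times that rate — an
identity-link Poisson regression with reads as exposure. The identity link
is the point: the scientific quantity is the rate itself, and a slope reads
directly as "errors per read per ten-fold increase in abundance". Abundance
enters as $\log_{10}$; a natural-log parameterisation would simply rescale
$\beta$ by $\ln 10$.

`fit_error_model()` uses reference-level coding (the first type and first
condition are absorbed into a baseline intercept) and supports five slope
structures: none, shared, per-condition, per-type, and `ga_specific`. The
last adds a G→A-specific slope *on top of* the shared slope, so the shared
model is nested inside it and the two can be compared by a likelihood-ratio
$\chi^2$ test (`lrt()`, or the two-model `anova()` method). Gene-level
covariates (chaperone-client status, gene length, absolute and relative
position) can enter either as rate offsets or as abundance-interaction
terms and are evaluated the same way. The degrees of freedom of a
comparison can be overridden manually when the automatic difference is not
the effective number of added parameters.

### Fitting under the identity link

The identity link makes the linear predictor itself a probability, so the
optimisation is constrained: every fitted rate must be nonnegative.
`stats::glm` can fail unpredictably here, so the package maximises the
Poisson log-likelihood directly by damped Fisher scoring:

* start at the pooled rate $\sum E / \sum R$ (always feasible);
* at each step solve the Fisher system and halve the step until the
  candidate keeps all rates nonnegative and does not decrease the
  likelihood;
* stop when the relative log-likelihood change is below $10^{-10}$
  (deterministic — no randomness enters the optimizer).

If the optimum pins any fitted rate against zero the fit is returned with
`boundary_hit = TRUE` rather than silently accepted; Wald variances come
from the inverse Fisher information at the optimum. On data where `glm`
does converge the two routes agree (this is tested), and for a
single-intercept model the maximiser is analytically $\sum E / \sum R$,
which the optimizer reproduces to more than ten significant digits.

Degenerate inputs are handled explicitly: an all-zero count vector yields a
zero-rate boundary fit; collinear term sets stop with an error rather than
returning an arbitrary solution; records whose type or condition is unknown
to a fit are an error in `predict()`.

## Hotspot exclusion

Recent mutations, mismapped reads, and programmed RNA editing produce loci
with far more "errors" of one type than transcription noise can explain.
These are removed by an iterative cumulative-binomial filter
(`filter_hotspots()`):

1. Fit a first-pass model with one pooled constant rate for all non-C→U
   records and a separate constant for C→U.
2. For every possible error compute the upper-tail probability
   $P(X \ge E_i)$, $X \sim \mathrm{Binomial}(R_i, p_i)$, under its expected
   rate $p_i$.
3. If any record at a locus falls below the cutoff (default $10^{-9}$),
   exclude the **entire locus** — all three substitutions in all
   conditions.
4. Refit on the cleaned data — now with the full type + condition +
   shared-slope model for coding non-C→U records, a condition-level model
   for C→U (the artifact mode is abundance-independent), and pooled
   constants for noncoding records, which carry no abundance — and repeat
   until no new locus is flagged or `max_iter` (default 20) is reached.

The cutoff is a fixed genome-wide threshold, not an FDR procedure: at
$10^{-9}$ and $\sim 10^7$ tests the expected number of falsely excluded
possible errors is of order $10^{-2}$, i.e. essentially zero, which the
false-exclusion tests confirm at the one-million-test scale. The excluded
set can only grow across iterations, so the procedure terminates. The tail
is one-sided (upper) because hotspots are excesses; with the degenerate
threshold 1.0 every locus with any observed error is flagged, a documented
boundary behaviour rather than a useful setting. Noncoding genes pass
through the filter like coding ones but are excluded from the GLM, which is
restricted to protein-coding genes.

## Exclusions and accounting

Ahead of the model the pipeline applies, in order: loci inside two or more
gene intervals are dropped (no single abundance can be assigned), as are
intergenic loci; sites with zero reads; coding-gene sites whose gene has no
(or zero) reported protein abundance; and sites whose reference base is
inconsistent across conditions. Every step is tallied in an accounting
report and the identities (`before − removed = after`, possible errors =
3 × retained sites) are asserted in the test suite. A locus excluded by the
hotspot filter removes *up to* 3 × (number of conditions) possible errors —
fewer when the locus lacked reads in some conditions — and the report
records exactly how many.

Synonymous status is classified per possible error by reconstructing each
coding gene's CDS from the reference bases of the count tables themselves
(no FASTA is required), complementing for minus-strand genes, and comparing
codons under the standard genetic code. Stop codons are treated as an
amino-acid class, so stop→stop substitutions count as synonymous, and stop
codons are not excluded from the possible-error set.

## Abundance-binned summaries

For visualisation (never for fitting), `make_bins()` spaces bin boundaries
evenly in $\log_{10}$ abundance between the 5% and 95% abundance quantiles,
with records beyond the quantiles folded into the edge bins; quantiles are
computed over records, with a read-weighted alternative behind a flag.
`summarize_bins()` pools counts per bin: $\hat p = \sum E / \sum R$,
binomial standard error $\sqrt{\hat p (1 - \hat p)/\sum R}$, and a 95% CI
of $\hat p \pm 1.96\,\mathrm{se}$, positioned at the geometric mean
abundance of the bin. Leading bins can be pooled either by count
(`pool_first`) or until a minimum read total is reached (`min_reads`),
because low-abundance genes carry few reads; edge bins are expected to
depart from the linear trend and should not be over-read.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` writes count tables, GFF3 and abundance files in
exactly the dialects the ingest functions read; `sim_possible_errors()`
draws the same records directly in memory for fast statistical
simulations. Both draw error counts as $\mathrm{Binomial}(R, \mathrm{rate})$
— exact at any rate, with the Poisson model as the fitting approximation —
with reads Poisson around a depth model, genes on both strands of one
contig, optional overlapping genes, hotspot loci with one inflated
substitution type, and an abundance-independent C→U mode.

The `"realistic"` preset encodes the study regime this package addresses:
four conditions (rich/minimal medium × midlog/stationary phase), mean depth
100 reads/site coupled to abundance with exponent 0.5 (read depth tracks
expression, protein ppm only partially tracks mRNA), non-C→U intercepts
$1.4\times10^{-5}$ errors/read with G→A at $3.0\times10^{-5}$, a shared
slope of $-8.4\times10^{-7}$ per decade with G→A at $-2.9\times10^{-6}$,
C→U at $1.0\times10^{-4}$ with slope 0, log-normal abundance
($\mu = 1.5$, $\sigma = 1$ in $\log_{10}$ ppm), 5% noncoding genes and 10%
of coding genes with unreported abundance. The `"scaled"` preset
(intercepts $10^{-3}$, slope $-10^{-4}$/decade, depth $10^3$, three
conditions, 2,000 short genes) raises rates and depth so that recovery and
calibration runs have power at desk scale; with it, the shared-slope 95%
CI covers the generating slope at close to nominal frequency across 200
replicates, and the slope likelihood-ratio test holds its 5% level across
800 null replicates (both asserted in the test suite, along with perfect
recall of 50× hotspots at depth $10^4$ and zero false exclusions across
twenty million-test runs).

What the generator does **not** emulate: read-level artifacts (no FASTQ or
rolling-circle consensus modelling), introns and splice isoforms,
polymorphic multi-copy loci such as rRNA operons (the reason noncoding
genes are filterable but not modelled), start/stop codon structure of the
CDS (sequences are random), sequence-context effects such as homopolymer
runs, and overdispersion beyond binomial sampling. Passing tests therefore
demonstrate that the estimator recovers the parameters of its own assumed
data-generating process, not that real libraries are free of structure the
model ignores.

## Worked example

```{r example, eval = FALSE}
out <- run_pipeline(list(
  synthetic = list(preset = "realistic"),
  seed = 1
), outdir = "txerr-demo")

# pooled rates on cleaned coding records
coding <- out$pe[out$pe$coding & !is.na(out$pe$abundance), ]
aggregate_rate(coding, types = sub_types("non-CU"))

# is the error rate expression-dependent?
out$comparisons

summary(out$fits$shared)
plot(out$fits$shared, coding)
```

An end-to-end run of this configuration (about 450,000 possible errors
from 150 genes in four conditions) takes well under a minute; the
simulation-heavy checks in the test suite use the scaled regime and run in
a few minutes in total. `scripts/acceptance.R` repeats the pipeline run
above from a command-line seed and writes the headline quantities as JSON.

## Design choices made where the design was open

* **Coordinates.** Internal gene intervals are 0-based half-open; GFF3
  (1-based inclusive) is converted only at the I/O boundary. Locus
  positions stay 1-based genomic coordinates, as in the count tables.
* **Alphabet.** Counts may arrive as T or U; everything internal is RNA
  (U), since error types are mRNA substitutions.
* **Batches and conditions.** Each count file carries one condition label;
  the pipeline ingests exactly the files listed in its manifest, so batch
  selection is configuration, not code.
* **Duplicate abundance entries** resolve to the last value, with a
  warning; zero or missing abundance marks the gene absent, which excludes
  its coding sites.
* **`ga_specific` nesting.** The G→A-specific slope is additional to the
  shared slope rather than replacing it, so the shared-slope model is
  strictly nested and the $\chi^2$ comparison is valid.
* **C→U guard.** `run_pipeline()` refuses to include C→U among the main
  model's types unless `include_cu` is set explicitly.
* **Hotspot convergence** means an iteration that flags no new locus; the
  excluded set is monotone, so this is also the fixed point.
* **Pooling rule for bins.** The number of leading bins to pool is stated
  by the analyst (`pool_first`) or driven by a read threshold
  (`min_reads`); the package does not guess.

## Limitations

The model is pure Poisson: there is no overdispersion term, no random
effects, and no hierarchical shrinkage across genes. Rates near the
feasibility boundary make Wald intervals unreliable (boundary hits are
flagged for exactly this reason). The synonymous classifier requires the
count tables to cover the full CDS of a gene; genes with coverage gaps get
`NA` and drop out of synonymous-fraction summaries. Finally, protein
abundance is a proxy for the expression level at which transcription
errors matter; mRNA-level covariates would slot into the same interface
but are not provided.
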