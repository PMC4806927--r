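---
title: "Bayesian assignment of ambiguous bisulfite reads: model and simulation design"
author: "bsassign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian assignment of ambiguous bisulfite reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsassign)
```

## The problem

Bisulfite sequencing converts unmethylated cytosines to thymines, so
aligners map the reads in a collapsed three-letter alphabet. The loss of
sequence complexity makes a large fraction of reads ("multireads") align
equally well to several genomic locations; standard pipelines discard
them, biasing methylation estimates and wasting data. `bsassign`
rescues multireads: for each candidate location it computes a posterior
probability from the read's agreement with the reference, a prior over
mutation and methylation events, and the bases that overlapping
*uniquely* mapped reads show at the same positions, then assigns the
read to the best location when the evidence is decisive.

## The model

For a multiread $X$ of length $K$ aligned at candidate location $t$, let
$M_k$ be the read base at position $k$, $R_k$ the reference base, and
$D_k = \{d_{1k},\dots,d_{rk}\}$ the bases observed there by the $r$
overlapping, strand-matched, high-MAPQ unique reads. Each position
contributes

$$P(M_k \mid D_k, R_k) =
  \frac{\pi(M_k \mid R_k)\, P(D_k \mid M_k)}
       {\pi(M_k \mid R_k)\, P(D_k \mid M_k) +
        \pi(\bar M_k \mid R_k)\, P(D_k \mid \bar M_k)},$$

and the candidate's score is the product over positions,
$P(X \mid D, R) = \prod_k P(M_k \mid D_k, R_k)$, accumulated in log
space. The assignment score is the log odds between the best and the
next-best candidate, $S = \log P_{best}/P_{next}$ (natural log); the
read is assigned when $S \ge S_0$ and reported unassignable otherwise.

**Likelihood.** A single unique-read base supports $M_k$ with
probability $1-\varepsilon_{jk}-\varepsilon_k+\varepsilon_{jk}\varepsilon_k$
when the bases agree (neither call is wrong) and
$\varepsilon_{jk}+\varepsilon_k-\varepsilon_{jk}\varepsilon_k$ otherwise,
where the $\varepsilon$ are the Phred-decoded miscall probabilities of
the unique-read and multiread base. The column likelihood
$P(D_k \mid M_k)$ is the arithmetic *mean* over the $r$ observations
rather than their product, so deeply covered columns are not penalised
merely for having more observations. Base matching is literal: a
unique-read T over a multiread C is a mismatch; bisulfite ambiguity is
handled entirely by the prior.

**Prior.** $\pi(M_k \mid R_k)$ encodes what can turn a reference base
into an observed read base on a directional library. A SNP rate
(default 0.001) is split 2:1:1 between the transition and the two
transversions, giving mutation masses 0.0005 and 0.00025/0.00025 and a
no-mutation mass of 0.999. A reference C observed as C must be
unmutated *and* methylated (protected from conversion); observed as T
it is either a C-to-T transition or an unmethylated, converted C. The
methylation probability depends on sequence context: 0.80 at CpG, 0.05
at CH (defaults; both configurable). On the reverse strand the same
rules apply with G playing the role of C and observed A the role of T,
with CpG context read from the *preceding* forward base. All 64
(reference, observed, context, strand) entries are tabulated by
`build_prior_table()`, exportable as TSV, and every
(reference, context, strand) row sums to 1.

**Complement hypothesis.** The composite hypothesis $\bar M_k$ ("the
true base is not $M_k$") needs an explicit construction, so the
package marginalises it properly: $P(D_k\mid \bar M_k)$ is the mixture of the
three alternative bases weighted by their renormalised priors,
$w_b = \pi(b \mid R_k)/\sum_{b'\neq M_k}\pi(b'\mid R_k)$. Under a
uniform prior this reduces to the plain average over the three
alternatives. Algebraically the resulting two-hypothesis posterior
equals the four-way Bayes posterior
$\pi(M_k\mid R_k)L_{M_k}/\sum_b \pi(b\mid R_k)L_b$, which is what the
vectorised engine computes; the test suite verifies that both routes
and an independent brute-force implementation agree to $10^{-9}$.

## Decision rules and numerical choices

* `S0` defaults to 0.05, suitable for simulated-style data; 0.2 is the
  recommended cutoff for real libraries with uneven coverage. Scores in
  the range 0.005–6 behave reasonably.
* Uncovered positions ($r=0$) contribute the prior $\pi(M_k \mid R_k)$
  — Bayes' rule under a flat likelihood — so candidates without
  evidence are still comparable. When $S < S_0$ and one candidate's
  total evidence coverage exceeds every other's by at least
  `coverage_factor` (default 2), the read is assigned there: loci with
  little or no shared unique coverage are resolved by "more unique
  reads". Reads whose candidates are all uncovered stay unassignable.
* Exact ties in log posterior are broken by higher coverage, then lower
  coordinate, and flagged (`tie_broken`).
* Per-position posteriors are floored at `1e-300` before the log;
  floored positions are counted and reported.
* `N` in the read or the reference makes a position uninformative: it
  is skipped, contributing factor 1.
* Candidates with gapped CIGARs are scored over aligned match columns
  only; inserted/deleted columns are skipped, and deletions in unique
  reads simply do not increment a column's coverage.
* Phred qualities decode as $\varepsilon = 10^{-Q/10}$ (offset 33 or
  64), clamped to $[10^{-10}, 0.75]$ so likelihoods stay in $(0,1)$.
* Contexts come from the *reference* (downstream base on the read's
  strand), not from the read: the reference context is
  strand-unambiguous and available for every candidate. First/last
  contig positions default to CH, the conservative low-methylation
  class.
* The "without prior" mode (`prior_mode = "uniform"`, $\pi = 1/4$
  everywhere) exists as a first-class switch so the contribution of the
  informed prior can be measured on paired data.

## The simulator and what it emulates

`simulate_bs_experiment()` reproduces the generative process the model
assumes, each stage deterministic under a seed derived from
`simulation_config(seed=)`:

1. **Genome**: uniform-random ACGT sequence with planted repeat
   families (`make_synthetic_genome()`). Identical repeat copies are the
   canonical worst case for mapping — every read from their interior is
   a perfect multiread — while the stochastic methylation states of the
   copies provide exactly the evidence signal the model exploits.
2. **Mutation** (`mutate_genome()`): every base mutates independently
   at rate 0.001; a mutating base becomes its transition partner with
   probability 1/2 and each transversion with 1/4. The mutated genome is
   the *sample*; the aligner and the prior still see the original
   reference, so planted SNPs exercise the mutation part of the prior.
3. **Methylation and conversion** (`methylate_and_convert()`): every
   cytosine on both strands, classified CpG/CH on the mutated genome, is
   methylated with probability 0.80 (CpG) or 0.005 (CH); unmethylated
   cytosines convert (C→T on the top strand, G→A in forward coordinates
   on the bottom). The CH default follows the simulation convention
   (99.5% of CH sites convert); note the *prior* default for CH
   methylation is 0.05 — the two constants describe different things (a
   genome-wide simulation truth versus prior belief) and are kept
   independent.
4. **Reads** (`sample_reads()`): directional — drawn only from the
   converted top strand — with uniform starts, constant or per-cycle
   miscall probabilities (default 0.005, a typical Illumina average),
   and quality strings encoding those probabilities. A truth record per
   read enables evaluation.
5. **Evidence coverage** (`generate_unique_coverage()`): candidate
   intervals are merged and strand-matched unique reads are staggered
   uniformly so each candidate position is covered by about
   `coverage_depth` reads (the depth grid 3/5/10/25/30 mirrors common
   study designs). How evidence reads should be staggered is a design
   choice; uniform stagger with a minimum overlap of
   `min(20, read_length/2)` bases was chosen as the least structured
   option.

The bundled `align_bs_reads()` closes the loop without any external
mapper: reads and the reference are collapsed C→T, two exact seeds per
read are matched genome-wide, extensions are kept within a mismatch
budget (default 3) and candidates within 1 mismatch of the read's best
hit are retained ("similar fidelity"). Reads with one candidate become
unique, with two or more become multireads.

**What the simulator does not emulate**: four-strand undirectional
libraries, PCR duplicates, indels, per-molecule methylation
heterogeneity (each cytosine has one state per genome, so all reads
from a position agree), quality-profile error structure beyond an
optional per-cycle vector, and the repeat taxonomy of real mammalian
genomes. Passing benchmarks on this generator therefore demonstrates
correctness of the method's mechanics and its qualitative behaviour,
not the headline rates attainable on real genomes, which depend on
hg19/mm10-scale repeat structure.

## Benchmark problem sizes

The packaged acceptance benchmarks use a 250 kb genome with 50
identical-copy repeat pairs of 500 bp and 30,000 directional 76 bp
reads, which yields roughly 5,000 multireads — large enough that
assignable/accuracy rates are stable to a fraction of a percent, small
enough to run on a laptop. Simulator calibration checks run on 10 Mb
(mutation) and 1 Mb (conversion) genomes with 3-sigma binomial
acceptance bands. On this benchmark the informed prior assigns fewer
reads than the uniform baseline but makes several-fold fewer errors per
read, accuracy rises with read length and evidence depth, and falls as
sequencing error grows — the qualitative behaviour expected of the
model. All of these are recomputed by `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`; the vignette itself asserts nothing the
tests do not compute.

## Limitations

* The averaged column likelihood is not monotone in every intuitive
  sense: appending a *mismatching* observation to a weakly supported
  candidate can slightly raise that candidate's posterior, because the
  mismatch lowers the averaged likelihood of the candidate's dominant
  alternative base proportionally more than that of the read base. A
  *matching* observation, by contrast, provably never decreases the
  supported candidate's posterior, and the property tests assert exactly
  that one-sided guarantee.
* Each multiread is scored independently; no joint or iterative
  reassignment across reads.
* Paired-end mates are scored as separate reads.
* The "error per read" denominator (total reads in the evaluated
  dataset) is a documented convention; other tools may normalise
  differently.
* Real aligners emit soft-clips that shift start coordinates; the
  evaluator's `slop` option exists for that, but the packaged
  benchmarks use exact coordinates.

## A minimal session

```{r example, eval = FALSE}
cfg <- simulation_config(genome_length = 50000, n_reads = 5000,
                         repeat_spec = list(n_families = 10L, copies = 2L,
                                            length = 400L, divergence = 0),
                         seed = 1)
st <- run_assignment_study(cfg)
st$evaluation
summary(st$assignment)
```
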