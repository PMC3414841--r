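---
title: "Dissecting mutational processes from somatic mutation catalogs"
author: "mutforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting mutational processes from somatic mutation catalogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

A catalog of somatic mutations is the superposition of the outputs of
several mutational processes, each active with different intensity in
different tumors. `mutforge` represents a cohort as a 96 × M count
matrix **A**: 96 mutated-trinucleotide channels (6 pyrimidine-reference
substitution classes × 16 flanking-base contexts; purine-reference
records are reverse-complemented before lookup, so both strand
presentations of one event share a channel) by M samples. The channel
order is fixed — classes C>A, C>G, C>T, T>A, T>C, T>G, contexts
lexicographic in (5′ base, 3′ base) — and serialized everywhere.

Signature extraction solves the nonnegative factorization

$$\min_{W \ge 0,\, H \ge 0} \tfrac12 \lVert A - W H \rVert_F^2,$$

with **W** (96 × k) the signature profiles and **H** (k × M) the
per-sample activities, by Lee–Seung multiplicative updates. Raw counts —
not trinucleotide-corrected values — are factorized; genome-frequency
correction (`correctSignatures()`) is a display transformation.
Exposures are reported three ways: the rescaled activities consistent
with the factorization, mutation counts (columns summing to each
sample's classifiable count), and proportions.

# Choosing the number of signatures

For each candidate rank, `selectRank()` performs `nRuns` seeded restarts
and records (i) the cophenetic correlation coefficient of the consensus
matrix built from co-assignment of samples to their maximal-activity
signature, and (ii) the best and mean Frobenius reconstruction errors.
The chosen rank is the largest rank that is still *stable*
(cophenetic ≥ 0.95; the stability collapse that rules out over-fitted
ranks is terminal, so the candidate range extends to the last stable
rank — intermediate ranks may be transiently unstable simply because
they are wrong models) and whose step still buys a *material* error
reduction.

"Material" is operationalized as a relative criterion: rank k qualifies
when the best error at k is at least 15% below the best error at k − 1.
On synthetic cohorts the two regimes are far apart — adding a true
signature cuts the error by 30–60%, adding a noise component by 6–11% —
so the 0.15 default sits in a wide margin. We use the per-rank *best*
error rather than the restart mean because the mean is inflated by runs
stuck in poor local minima, which blurs the elbow. Ambiguity is always
resolved toward the smaller rank.

Two numerical choices matter elsewhere in the factorization: factors are
initialized i.i.d. uniform(0, 1] scaled by `mean(A)` under a per-run
seed, and update denominators carry an epsilon of 1e−12 so all-zero
channels are tolerated. Multiplicative updates converge sublinearly near
the optimum; the package therefore uses many moderate-length restarts
for model selection (500 iterations; the consensus only needs the
argmax structure) and longer runs (5,000 iterations at tolerance 1e−10)
for final extraction. Known sequencing-artifact channels can be removed
from **A** by the caller before factorization (a channel blocklist);
no automatic artifact detection is attempted, since distinguishing an
artifact signature from a real one requires orthogonal re-sequencing
evidence.

# Kataegis

The package turns the visual phenomenon — dramatic local dips in a
rainfall plot — into an operational rule: a microcluster is a maximal
run of at least `minSize = 6` consecutive same-chromosome substitutions
with successive intermutation distances at most `imdThreshold = 1000`
bp, echoing the "few hundred base pairs" scale of observed
microclusters; clusters separated by at most 1 Mb aggregate into
macroclusters. All three knobs are exposed and echoed into outputs,
because the literature offers no numeric definition; the defaults are
one defensible operationalization. Cluster summaries report the TpC
fraction and flanking-base composition of C>X members (strand-collapsed)
and class fractions; processivity is summarized as maximal runs of
identical forward-strand changes (C>T kept distinct from G>A).
Mutation phase is consumed as an annotation from the generator, never
inferred — read-level phasing requires alignments, which are out of
scope. Rearrangement colocalization reports nearest-breakpoint distances
per cluster and, per macrocluster, a one-sided binomial enrichment
p-value with the region's length share as exposure.

# Double substitutions

Maximal runs of consecutive substituted positions partition every
substitution into singleton, doublet (run of 2) or complex (run ≥ 3);
complex runs are excluded from doublet counts, and members of runs ≥ 2
are likewise excluded from the 96-channel spectrum so each multi-base
event is counted once. Doublets collapse to 78 canonical classes under
reverse complementation. The Monte Carlo test places, per chromosome and
substitution class, the observed number of mutations uniformly at
random without positional collision (collisions are forbidden; at
genomic densities this choice is numerically negligible), and reports
the add-one empirical p-value (1 + #{sims ≥ observed})/(nSims + 1),
which is never exactly zero, plus the fold enrichment over the
simulated mean.

# Transcription effects

Strand assignment follows the pyrimidine convention: with the mutated
pyrimidine on the forward strand, a + strand gene puts it on the
untranscribed (coding) strand. Positions overlapping genes on both
strands are ambiguous and excluded; gene footprints are transcript
spans (whole-genome catalogs are dominated by intronic mutations, so
exon-level resolution would add noise, not signal). The strand-bias
test is an exact binomial test against the at-risk pyrimidine content
of each strand — correcting for base composition rather than assuming
0.5. The expression trend is a Poisson rate regression of per-gene
counts on mean log2 expression with log gene length as offset; the
equal-gene expression bins are descriptive output. TSS profiles count
the fraction of genes with ≥ 1 mutation (any strand — the
pyrimidine-collapsed alternative changes denominators, not shape) per
distance bin, excluding genes shorter than a bin's far edge from its
denominator.

# Indel architecture

Classification precedence is total and deterministic: *repeat* first
(the indel is whole copies of a ≤ 6 bp unit with at least one further
adjacent copy in the reference — a deletion inside a tandem repeat
trivially carries junction identity, hence the precedence), then
*microhomology* for deletions whose junction identity — the longer of
the prefix match 3′ of the deletion and the suffix match 5′ — reaches
`mhMin = 2` bp (single-base matches occur at nearly half of junctions
by chance), else *none*. Junction identity is recorded for every
deletion regardless of class, so the observed distribution can be
compared to the chance model: with per-position match probability
p = Σ<sub>b</sub> p<sub>b</sub>², each side's run is geometric capped
at the deletion length and the junction value is the max of the two
sides. Expected counts integrate to the number of deletions; the
chi-square summary pools cells with expectation below 5.

# The synthetic generator

The generator defines the study conditions under which every analysis
is validated. Defaults: a 10 Mb genome over 4 chromosomes (large enough
for context availability at 10,000 mutations per sample, small enough
for desk-scale runs), GC 0.41, CpG-depleted background (CpG→GpC swaps
retaining ~15% per pass, emulating germline deamination) with 40
CpG-enriched 1 kb islands, 300 non-overlapping genes with log-normal
lengths and normal log2 expression (mean 9, sd 1.5, spanning the 6–12
range typical of expression arrays). Cohorts are 21 samples from 5
signatures: an XpCpG C>T deamination-like signature, a TpCpX
C>T/C>G/C>A signature, a flat signature, a TpCpX C>G-dominated
signature, and a near-flat signature enriched for XpCpG C>G/C>A/C>T.
The last is given a stronger enrichment than the near-flat signatures
it is described alongside in the literature, because a synthetic truth
must be identifiable to be recoverable — two near-collinear signatures
define an ill-posed recovery target. Exposures anchor every signature
as dominant in two samples (as each process dominates some tumors) with
sparse Dirichlet mixtures elsewhere; per-sample totals are uniform on
2,000–10,000.

Mutations are placed by drawing channel counts multinomially from
**W**·exposure and sampling genome sites whose strand-collapsed context
matches the channel, without replacement, on both strands — so purine
and pyrimidine presentations occur in genomic proportions. Injectors
add kataegis clusters (TpC-focused C>T/C>G with linked rearrangement
breakpoints and a shared phase label), adjacent doublets, indels whose
class is guaranteed by construction from the reference sequence, and
strand-bias/expression thinning effects.

What the generator does *not* emulate: chromatin and replication-timing
covariates of mutation rate, sequence-dependent artifact processes,
subclonal structure, and read-level evidence. Passing tests therefore
demonstrate that the algorithms recover what they are defined to
recover under clean conditions — not that real catalogs are free of the
confounders these analyses are known to face.

# Problem sizes and determinism

The shipped tests run the full battery at reduced scale: rank selection
with 100 restarts per rank on one 21-sample cohort (the framework
supports 1,000), Monte Carlo tests at 150–1,000 simulations, calibration
and power sweeps over 20–200 seeds, and recovery checks over 10–50
seeds. Every stochastic routine takes an explicit seed, derives child
seeds below 2³¹ where it needs several streams, and restores the
caller's RNG state; identical inputs and seeds reproduce every output
byte for byte, as the pipeline tests assert.

# Known limitations

- Multiplicative updates converge sublinearly; near-exact factorizations
  need long runs (the separable-recovery test uses 2.5 × 10⁶
  iterations). KL-divergence objectives and accelerated solvers are out
  of scope.
- The kataegis thresholds are an operationalization; calls near the
  threshold boundary are sensitive to them, which is why they are
  echoed into all outputs.
- The CpG-island odds ratio uses a Woolf interval and no continuity
  correction: a zero cell leaves the interval undefined and flagged
  rather than silently corrected.
- Exact tests (binomial, Fisher) are conservative on discrete counts;
  calibration tests assert validity (rejection ≤ nominal), not exact
  uniformity, for them.
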