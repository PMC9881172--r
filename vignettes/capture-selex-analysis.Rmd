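---
title: "Analyzing and simulating Capture-SELEX sequencing experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing and simulating Capture-SELEX sequencing experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selexr)
library(tibble)
```

## The problem

Capture-SELEX selects small-molecule-binding RNA aptamers from combinatorial
pools. The pool is hybridized to a 3′-biotinylated DNA *capture
oligonucleotide*, immobilized on a streptavidin column, washed, and eluted
with a mix of candidate ligands; molecules that bind a ligand and thereby
release from the capture strand are amplified into the next generation.
When the starting pool is built on a riboswitch-derived *scaffold* —
a fixed structural framework with randomized joining regions — survivors
tend to retain the scaffold architecture, which eases the subsequent
grafting of a selected aptamer back onto a natural riboswitch expression
platform.

Analyzing such an experiment from sequencing data involves a fixed sequence
of computational steps: merge paired-end reads by overlap, tally merged
reads into a ranked abundance table per generation, group reads into
sequence classes by similarity (masking the constant primer-binding
regions), follow class abundances across generations, check candidate
classes for the "selfish" survival signature (unintended complementarity to
the capture oligonucleotide), summarize column elution profiles, and
estimate dissociation constants from titration band intensities. selexr
implements each step as a data-frame-in, tibble-out function, plus a
stochastic round simulator so that the entire pipeline can be exercised and
validated without any experimental data.

## Scaffolds and pool accounting

A `scaffold()` is an IUPAC template with annotated constant spans and a
capture-site span (all coordinates 0-based, half-open). The number of
distinct molecules a scaffold can realize is the product over positions of
the number of bases each code admits:

```{r}
sc <- scaffold_s1()
sc
pool_diversity(sc)
```

The built-in `scaffold_s1()` carries 23 fully randomized positions split
8+9+6 among three joining regions, so its diversity is $4^{23} \approx 7
\times 10^{13}$. The randomized-segment split is configurable because only
the total (23) and the swap that defines the third scaffold (N8 and N6
exchanged in `scaffold_s3()`) are fixed design facts; 8+9+6 is the
package's default reading. The built-in scaffold *sequences* (constant
regions, stems, capture oligo) are synthetic stand-ins with the right
architecture — published pool sequences live in supplementary material that
is not redistributed here — so they are suitable for simulation and
testing, not for re-analyzing a particular experiment.

`mutagenize()` models doped resynthesis for reselection pools: each
unprotected position mutates with probability $d$ (default use case $d =
0.06$, primer-binding regions protected), the substitute drawn uniformly
from the three alternatives. This per-position independent model is the
standard description of doped chemical synthesis; the doping chemistry's
true per-coupling biases are not modeled.

`graft()` is deliberately plain string assembly with a Watson-Crick check
on the enclosing P1 stem: grafting an aptamer onto an expression platform
is, at the sequence level, concatenation, and the check catches the one
error class (a non-complementary stem) that silently breaks the construct.

## Merging and tallying

`merge_pair()` scans every overlap length of R1 against the reverse
complement of R2, keeps the overlap with the fewest mismatches (ties going
to the longest), accepts it if the mismatch fraction is at most
`max_mismatch_rate`, and resolves mismatched positions toward the higher
Phred score (ties toward R1). Defaults are `min_overlap = 10` and
`max_mismatch_rate = 0.1` — permissive, in the spirit of the common overlap
mergers. Unmergeable pairs are dropped and counted, not propagated. With
150-nt reads and the ~100-nt templates typical of scaffold pools, mates
overlap nearly end-to-end and merging is essentially lossless.

`tally_pool()` collapses merged reads by exact match (case-insensitive, U
mapped to T) and ranks by count. Exact matching is deliberate: sequencing
errors are *not* corrected at this stage, mirroring the tally-then-cluster
order of the original workflow in which the clustering step absorbs the
error cloud around each true sequence. Ties are broken by first occurrence
in the stream, then lexicographically; percent columns are written with six
decimal places. Neither tie-break nor precision is a published fact — they
are fixed here so the TSV dialect round-trips deterministically. Reads
containing ambiguity codes are kept by default (`drop_ambiguous = TRUE`
excludes them): the default is lossless, and downstream similarity handles
them like any other mismatch.

## Clustering and class tracking

`cluster_pool()` reproduces rank-seeded greedy clustering: query ranks are
processed in order, each unabsorbed query seeds a cluster, and the pool is
scanned in rank order admitting sequences with masked similarity at least
0.90 until 1000 members are admitted or the pool ends. The similarity
metric is

$$ s(a, b) = 1 - \frac{\mathrm{Lev}(a_{\mathrm{var}}, b_{\mathrm{var}})}
{\max(|a_{\mathrm{var}}|, |b_{\mathrm{var}}|)} $$

where the variable regions are obtained by deleting the constant-region
strings (first exact occurrence of each). Normalizing Levenshtein distance
by the longer sequence is the convention of the widely used FASTAptamer
toolkit; whether the original analysis normalized by the longer, shorter,
or alignment length is not knowable from its description, so the choice is
stated here explicitly — it moves membership only at the threshold margin.
A sequence whose constant regions cannot be located exactly (e.g. a primer
region hit by a sequencing error) is compared full-length and flagged with
a warning rather than discarded.

Two exclusivity rules matter for interpretation. Queries already absorbed
by an earlier cluster are reported as skipped (with the owning cluster),
and — one step further — *members* are exclusive too: a sequence admitted
to an earlier cluster is never admitted again. This makes per-cluster
percent abundances additive, which is what a stacked class-vs-generation
plot assumes.

`track_classes()` applies the same metric, threshold, and first-match
exclusivity to a list of generation pools given one seed sequence per
class, returning the long table behind enrichment trajectories
(`autoplot()` draws them). Using the clustering metric for tracking keeps
the two views of the data consistent.

`consensus_profile()` provides per-column base frequencies and, for
annotated column pairs, a covariation count: the number of distinct
complementary (Watson-Crick or G:U) identities observed minus one, floored
at zero. This is intentionally lightweight — covariance-model motif
discovery and structure drawing are jobs for dedicated external tools.

## Selfish sequences and elution profiles

Classes can survive selection without binding any ligand by hybridizing
transiently to the capture oligonucleotide through a short unintended
complementarity and leaking off the column. The observed signature is
seven contiguous complementary nucleotides outside the intended capture
site. `scan_capture_complementarity()` reports every maximal exact
reverse-complement match of length ≥ `min_len` (default 7) between a
sequence and the oligo, flagging hits that overlap the annotated capture
site; unflagged hits are selfish candidates. The scan is exhaustive over
alignment diagonals and is tested against an all-substrings oracle; for a
random 100-nt sequence against a 30-nt oligo the expected number of
length-7 hits is about 0.14, so any recurrent unflagged hit across a class
is a strong signal.

`summarize_elution()` turns per-fraction signals into percent-of-total and
calls a compound elution *specific* when its signal is at least `k` times
the mean of designated background fractions (default `k = 3`, typically the
two preceding washes). Published elution profiles are interpreted
qualitatively; the factor-of-3 rule is this package's explicit, adjustable
operationalization.

## Dissociation constants

Ligand titrations read out at several structurally modulating sites are
normalized per site to fraction-modulated (decreasing sites inverted) and
pooled into one fit of the one-site Hill isotherm

$$ f(c) = f_0 + A\,\frac{c^n}{K_D^n + c^n}, \qquad n = 1 \text{ by default.} $$

Pooling matches the practice of estimating one $K_D$ from several sites of
the same gel; per-site fits (`pool_sites = FALSE`) are available for
diagnostics. With $n$ fixed, the model is *separable*: at any $K_D$ the
baseline and amplitude solve a linear least-squares problem, so `fit_kd()`
profiles the residual sum of squares over $\log K_D$ (variable projection)
and optimizes the one-dimensional profile — a coarse 240-point grid over
$\pm 6$ decades around the tested concentrations followed by golden-section
refinement to $10^{-11}$ in $\log K_D$. This is deterministic, needs no
starting values, and is scale-equivariant: concentrations are rescaled
internally by their geometric mean, and multiplying all concentrations by
$s$ multiplies the fitted $K_D$ by $s$ to well below $10^{-8}$ relative.
The standard error is the square root of the $K_D$ diagonal of the
Jacobian-based covariance at the optimum — the "goodness of fit" error of a
sigmoidal titration — reported on the linear molar scale. Freeing the Hill
exponent switches to Levenberg–Marquardt with bounded restarts.

Guard rails: at least four distinct non-zero concentrations are required;
zero-concentration points are allowed and pin $f_0$; constant sites are
dropped with a warning (and an all-constant series is refused rather than
fitted); a fitted $K_D$ more than 100× outside the tested range is flagged
`poorly_constrained`. Whether a titration is fitted against linear or
logarithmic concentration is immaterial here: the isotherm is a function of
$c$, and the estimate does not depend on the plotting axis.

## The simulator

`simulate_selex()` is the package's generative model of the experiment and
the source of all synthetic test data. Per round, each molecule survives
independently with probability

$$ p = 1 - (1 - p_{\mathrm{elute}})(1 - p_{\mathrm{leak}}), \qquad
p_{\mathrm{elute}} = \max_{\text{compound} \in \text{mix}}
p_{\mathrm{elute}}[\text{compound}], $$

then survivors are resampled multinomially to the amplification target.
The max (not sum) over compounds reflects that a molecule needs only one
ligand to release; combining elution and leak as independent chances
enables mixed-strategy classes (a ligand-dependent eluter that also leaks).
A compound absent from a round's mix contributes zero elution — removing a
ligand mid-selection reproduces the characteristic collapse of the
dependent class. The default elution schedule mirrors the published
experiment's shape: an eight-compound mix (several over-the-counter drugs
plus guanine and glucose) through round 13, then a six-compound subset
excluding guanine and quinine.

Classes are seeded with mutational clouds (`cloud_degeneracy` around the
seed, constant spans protected), and a background of random scaffold draws
survives at a small constant rate. `emit_reads()` draws read pairs
multinomially, covers each template from both ends at the configured read
length (default 150), applies i.i.d. per-base substitution errors, and
assigns flat Phred qualities consistent with the error rate. Everything is
reproducible from one integer seed, down to byte-identical FASTQ.

Two closed forms anchor the model's correctness and are enforced in the
test suite: with two classes at survival probabilities $p_A, p_B$, the
expected abundance ratio after $r$ rounds is $(p_A/p_B)^r$; and equal
survival probabilities leave expected abundances flat across rounds.

What the simulator does *not* emulate: wash kinetics and column geometry,
transcription/RT sequence bias, PCR cycle-level dynamics and chimeras,
read-quality degradation along the read, indel sequencing errors, and any
nucleotide-level binding or folding model. Passing tests therefore
demonstrate that the analysis code correctly inverts this idealized
generative process — multinomial sampling plus substitution noise — not
that it is robust to every artifact of real library preparation.

Real per-round enrichment rates are unknowable from endpoint data, so the
simulator's elution and leak probabilities are free parameters; defaults
(elution 0.3–0.5 for true binders, leak ~0.02–0.05 for selfish classes)
were chosen once to give visible enrichment within a few rounds at
realistic pool sizes.

## Problem sizes and numerical conventions

The test suite and the reproduction script run at deliberately moderate
scale, chosen as sizes at which every stochastic check has comfortable
statistical power: pools of $10^4$–$10^5$ molecules with a $10^5$-copy
amplification target, sequencing depth $10^5$ for the end-to-end abundance
check, 20 simulation seeds for closed-form comparisons, $10^4$ random
instances for the string-algorithm oracles, and 100 replicate titrations
for the noisy-$K_D$ check. Tolerances follow the statistics, not the other
way around: closed-form comparisons use three standard errors of the
estimate, abundance recovery uses three multinomial standard deviations at
the sequencing depth, and exact computations (diversity, merging,
tallying, noiseless fits) are checked to machine-level precision.

Other conventions: all intervals are 0-based half-open; the internal
alphabet is uppercase DNA with U accepted on input (`as_rna()` converts
back); random draws always come from an explicit per-call seed, never
global state; empty inputs raise typed errors (`selexr_empty_error`)
rather than returning empty results silently, while absence of a query
from a pool is a result, not an error.

## Limitations

* The built-in scaffolds and capture oligo are synthetic stand-ins;
  analyses of real experiments must supply their own scaffold definitions
  (`read_scaffold()`) and oligo sequence.
* Similarity is Levenshtein-based on masked sequences; for pools with
  large indel variation between classes, alignment-based metrics could
  rank borderline members differently.
* `consensus_profile()` requires equal-length variable regions among the
  members it uses and excludes the rest, which is adequate for
  substitution clouds but not for classes with internal indels.
* The $K_D$ standard error is the local (Wald) error of the fit; it does
  not propagate gel-quantitation or normalization uncertainty.
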