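---
title: "Filtering false-positive splice junctions from spliced RNA-Seq alignments"
author: "juncfilter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering false-positive splice junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(juncfilter)
library(data.table)
```

## The problem

Transcriptome-first spliced aligners (TopHat2 is the canonical case) place
many reads and quantify exon–exon junctions accurately, but pay for that
sensitivity with a tail of spurious junctions arising from artefactual gapped
alignments — typically reads forced across a splice site by low-quality ends,
paralogy or annotation errors. `juncfilter` post-processes the alignment
output: it keeps the aligner's mapping and quantification strengths and
removes unreliable junction calls afterwards, rather than constraining the
alignment itself.

## The model

For a uniquely mapping read spanning a junction $j$, the **overhang** is the
length of the shorter of its two aligned arms,
$o_i = \min(a_i^{\mathrm{left}}, a_i^{\mathrm{right}})$. Under random cDNA
fragmentation every admissible overhang is equally likely, so the $o_i$ of a
genuine junction follow a discrete uniform distribution on
$\{o_{\min}, \dots, o_{\max}\}$ with $o_{\max} = \lfloor L/2 \rfloor$ for
read length $L$. Artefactual junctions violate this expectation in a
characteristic way: systematically short overhangs, often with a recurrent
mismatch at a fixed distance from the splice site.

The pipeline proceeds in five stages.

1. **Evidence.** Each junction is represented by the multiset of its unique
   split-read overhangs; mismatch positions within the overhang arm are
   recovered from the MD tag. Overhangs are **trimmed** at the first
   mismatching base counted from the splice site — a mismatch at position
   $m$ leaves a matching overhang of $m - 1$.

2. **Labelling.** A junction is labelled a *potential false positive* (PFP)
   when its reads mismatch at exactly one distinct position $p^*$ within the
   overhang arm, no raw overhang is greater than $p^*$, and
   $$P = 1 - F(p^*)^{n} > 0.99, \qquad
     F(p) = \frac{p - o_{\min} + 1}{o_{\max} - o_{\min} + 1},$$
   i.e. at the observed read count $n$, at least one longer overhang would
   almost surely have been seen under uniformity. Junctions with *no*
   matching overhang (every read mismatching at the first base) are labelled
   PFP as well. Everything else is *presumed OK* — a class that tolerates
   label noise because proper mappings are the vast majority.

3. **Features.** For each junction, and each position
   $p = o_{\min}, \dots, o_{\max}-1$, the observed exceedance count
   $C_p = |\{o_i' > p\}|$ (over trimmed overhangs) is compared with its
   uniform expectation $E_p = n\,(o_{\max} - p)/(o_{\max} - o_{\min} + 1)$:
   $$x_p = \log_2 \frac{C_p + c}{E_p + c}$$
   with pseudocount $c = 0.5$. Genuine junctions give $x \approx 0$;
   artefacts are strongly negative at most positions.

4. **Classification.** An L1-regularized logistic regression of the PFP
   label on $x$ is fitted over the whole junction set (semi-supervised
   anomaly detection). The L1 penalty selects the informative positions
   agnostically — counts far from the splice site are noisier and mostly
   shrunk to zero. Each junction (including the labelled ones) receives a
   posterior probability of belonging to the false-positive class and is
   discarded when it strictly exceeds 0.5.

5. **Rescue.** A multimapped read whose candidate locations have all but one
   been eliminated is allocated to the surviving location and added to that
   junction's count.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `o_min`, `o_max` | 1, $\lfloor L/2\rfloor$ | support of the uniform overhang model; raise `o_min` if the aligner enforces a minimum anchor |
| `alpha` | 0.99 | labelling probability threshold; stricter values label fewer, more extreme anomalies |
| `pseudocount` | 0.5 | keeps $x_p$ finite; symmetric so $C_p = E_p \Rightarrow x_p = 0$ |
| `l1_c` | 1.0 | inverse penalty strength (sklearn-style $C$); internally $\lambda = 1/(C\,n)$ on the glmnet scale |
| `threshold` | 0.5 | posterior cut; strict inequality, so a posterior of exactly 0.5 is kept |
| `min_mapq` | 50 | uniqueness fallback when NH is absent (TopHat2 reports unique hits at MAPQ 50) |

## Numerical and design choices

* **Solver.** The penalized fit uses coordinate descent (glmnet) along a
  decreasing $\lambda$ path with warm starts, ending at the target
  $\lambda = 1/(C n)$; a lone small $\lambda$ does not converge reliably.
  Tolerance is 1e-6 with at most 1e4 iterations; if the target is not
  reached the nearest converged solution on the path is used, with a
  warning. glmnet's tolerance is defined on the objective change per
  coordinate sweep, not on a gradient norm, so "1e-6" is a convention, not
  an exact equivalence with other solvers.
* **Boundary conventions.** Intron coordinates are 0-based half-open.
  Feature positions exclude $p = o_{\max}$, where $E_p = 0$ and the log
  ratio is undefined. When the two arms are equal the left arm is taken as
  the overhang arm for mismatch bookkeeping; the overhang value itself is
  unaffected.
* **Single-mismatch rule.** "A single mismatch" is read per junction, not
  per read: mismatches must occur at exactly one *distinct* position across
  the junction's spanning reads, since the labelling probability concerns
  "the first mismatching position", a per-junction quantity.
* **Mixed read lengths.** The feature grid uses the modal read length
  (feature vectors must share a length); the labelling probability for a
  junction spanned only by shorter reads uses that junction's own
  $\lfloor L/2 \rfloor$ cap.
* **Indels.** Arm lengths are read-consuming lengths; a deletion does not
  extend an overhang. Reads with an indel within 3 bp of a splice site are
  excluded from evidence (configurable) — the overhang model only speaks to
  matches and mismatches.
* **Degenerate inputs.** No PFP label: no model is fitted and everything is
  accepted with posterior 0, loudly. No presumed-OK junction: the run
  aborts, since a one-class fit is meaningless. Reads with NM>0 but no MD
  tag contribute their overhang without mismatch information, flagged.
* **Rescue bookkeeping.** An alignment location survives iff it spans at
  least one junction and all of them were accepted; a gapless candidate
  location keeps the read ambiguous and blocks rescue. Each rescued read is
  allocated exactly once. The pipeline is single-pass: rescued counts do not
  feed back into relabelling or refitting.

## What the simulator emulates — and what it does not

`simulate_spliced_dataset()` generates SAM alignments with exactly the
statistical structure the model assumes: true junctions with uniform
overhangs on $\{1..\lfloor L/2\rfloor\}$ and i.i.d. background mismatches
(default rate 0.001/base, a typical Illumina substitution rate); artefactual
junctions with overhangs capped at `fp_max_overhang` (default 4) and a
recurrent mismatch at that position; per-junction read counts
$1 + \mathrm{Poisson}(\mu - 1)$ (default $\mu = 20$) so every junction is
detectable; and a configurable fraction (default 10%) of true-junction reads
emitted as NH=2 multireads with an artefactual decoy location. References
are fictitious and no sequence is emitted — MD tags are synthesized
directly, which is sound because the algorithm never reads the genome.

It is **not** a transcriptome simulator: no expression model, no fragment
coverage correlation along transcripts, no quality-dependent error profile,
no paired-end structure, no reads spanning two junctions at once. A green
end-to-end test therefore establishes that the implementation separates the
stated anomaly structure from the stated null — not that it would achieve
the same figures on any particular real library.

One property of the features deserves note: because of the pseudocount, the
expected value of $x_p$ under the uniform model is slightly negative at
positions where $E_p$ is small (the log of a skewed ratio). The bias shrinks
with read depth, not with the number of junctions; the test suite asserts
the empirically calibrated envelope rather than a false asymptotic.

## Worked example

```{r example}
cfg <- simulation_config(n_true_junctions = 200, n_fp_junctions = 40,
                         mean_reads_per_junction = 12, seed = 7)
sam <- tempfile(fileext = ".sam")
sim <- simulate_spliced_dataset(cfg, sam)
res <- filter_junctions(sam, seed = 7)
res

detection_metrics(res$evidence, sim$truth)   # before filtering
detection_metrics(res, sim$truth)            # after filtering
quantification_error(res, sim$truth)$total_absolute_error
```

## Known limitations

* The labelling rule considers substitution mismatches only; systematic
  indel artefacts near splice sites are excluded from evidence rather than
  modelled.
* Paired-end mates spanning the same junction are counted as independent
  observations; the overhang model has no notion of fragments.
* The posterior is a discriminative score against a noisy labelled subset,
  not a calibrated probability of artefact status.
* Strand comes from the XS tag; junctions identical in coordinates but
  differing in strand are distinct keys, so a missing XS on part of the
  reads can split evidence.
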