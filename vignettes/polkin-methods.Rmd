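---
title: "Models and methods in polkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in polkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polkin)
```

This vignette is the package's account of its models: what is assumed,
which tunable parameters matter, what the synthetic-data generator does
and does not emulate, and the numerical choices made where the design
was genuinely open. Every number shown here is computed by the code in
this document or by the package's test suite; nothing is quoted from
elsewhere.

## The transport model of elongation

A gene is discretized into `L` windows of width `w` kb. Three parameters
define the kinetic regime:

* `p` — mean time between successful initiation events (minutes).
  Default examples use 2 min, a busy but unexceptional promoter.
* `e` — elongation rate (kb/min). Mammalian RNAPII typically runs at
  1–4 kb/min; 3 kb/min is the canonical unperturbed value.
* `d` — processivity defect: the fraction of polymerases that stop
  transcribing per kb (dimensionless, e.g. `0.02`). Stored as a
  fraction; shown as %/kb only in reports, because the regression
  machinery uses it multiplicatively as `e + d·e`.

Unlabeled (`o_i`) and 4sU-labeled (`b_i`) occupancies evolve by a linear
transport system (see `?pol_integrate`). The model assumes constant
rates along the gene, no pausing or pause release, and no re-initiation
downstream — it is a mean-field description of occupancy, not a
single-molecule simulation.

Because the system is linear, its solutions are known in closed form,
and the package uses them both as test oracles and inside the data
generator:

* steady state: `o_i = (p e)^{-1} (1 + d)^{-i}` — geometric decline;
* labeling from equilibrium: `b_i(t) = o_i^{ss} (1 − e^{−kt})` with
  `k = e(1+d)` — total occupancy `o+b` is conserved across the mode
  switch;
* labeling from an empty gene (DRB release):
  `b_i(t) = o_i^{ss} P(Γ_i ≤ kt)`, an Erlang cascade.

```{r steady-state}
par <- sim_params(p = 2, e = 3, d = 0.02, L = 40)
st <- pol_integrate(par, polymerase_field(numeric(40)), "no4sU", 1000)
max(abs(st$o - steady_state_occupancy(par)) / steady_state_occupancy(par))
```

### Numerical diffusion and the labeling front

The Erlang form makes a discretization artifact explicit: a front that
should advect sharply at `e·t` kb is smeared with standard deviation
`sqrt(e t w)` kb. At the default `w = 1` kb and a 20 min chase this is
7–8 kb wide, which matters for wavefront estimation: fitting the
piecewise-linear chase model to a 1 kb-resolution profile places the
wavefront well beyond `e·t` (the likelihood chases the smooth
shoulder). `drb_foursu_kb()` therefore evaluates the closed form at
nucleotide resolution and aggregates to 1 kb analysis windows, keeping
the front sharp at the analysis scale. The half-maximum crossing of the
coarse profile — the Erlang median — still sits at `e·t`, which is what
`profile_front(profile, 0.5)` reports; the far tail of the exact
solution extends several kb beyond, so very low relative thresholds do
not localize the front.

## Gene-body LFC regression

For paired treated/control window counts the local log2 fold change is
modeled as `l(i) = o + s·min(i, b)`: linear decline at slope `s` up to a
turning point `b`, constant beyond (with a 15 min label and ~3 kb/min,
windows beyond roughly 45–90 kb carry fold-change information only
through the constant part, which the model represents without
truncation). The likelihood is the beta log2-odds density with
arguments `(a_i + p_a)·dds + 1` and `(c_i + p_c)·dds + 1`. Two readings
of this expression exist because the source formula is typeset flat;
only the one used here lets `dds` act as a downsampling factor, i.e. as
an overdispersion model, which is its declared purpose. `dds` is
bounded to `[1e-3, 1]`; in fits to overdispersed counts it settles near
(NB size)/(count level), so the effective information per window is the
NB size, not the raw count.

Two consequences are worth knowing:

* the `+1` pseudocount shrinks extreme fold changes when `dds` is
  small; at strong defects over long genes this attenuates the fitted
  slope by up to ~10%. This is a property of the estimator, shared by
  any fit of this likelihood, and is visible in the cohort recovery
  tests;
* on null genes the unrestricted MLE occasionally places a spurious
  early turning point with a steep two-window slope. The accurate-fit
  gate (95% CI of the per-kb defect narrower than 1 %/kb) screens these
  out, and all downstream consumers use gated fits.

Optimization profiles the likelihood over a grid of turning points
(the surface is only piecewise-smooth in `b`), with multiple slope and
`dds` starts, then releases all four parameters; ties break toward the
smaller `|s|`. CIs come from the central-difference Hessian; when the
`b` direction is flat (no turning point inside the gene) the Hessian is
re-profiled at fixed `b` so the slope keeps its CI. Counts are rounded
half-to-even and negative input-corrected values censored at zero
before likelihood evaluation, because the densities' count arguments
are integer-like.

The slope is reported both ways: `100·(2^{−s}−1)` %/kb (survival form,
default) and the signed `−100·(1−2^s)`.

## Termination regression

Post-PAS counts on a 250 nt grid follow `s(i) = o e^{−r i}` with NB
noise. Masking rules: exon-overlapping windows; all windows upstream of
a TU shorter than the 5 kb upstream span; all windows past a same-strand
neighbor's TSS within the 25 kb downstream span; and everything beyond
the first run of four consecutive windows below 1% of the PAS level
(spurious downstream peaks otherwise masquerade as readthrough). The
PAS level prior is Gaussian with moments from the upstream windows
(falling back to the first five downstream windows), weighted by the
number of usable windows so prior and likelihood carry equal weight; a
degenerate prior sd is widened to `max(sd, 0.1 m + 1)` to keep the
posterior proper. The source text's likelihood line names the other
regression's trend function; the decay model is the only reading
consistent with its own definitions, and is what is implemented.

Decline units: per window, nats/kb (`4r`), and the survival form
`100(1 − e^{−4r})` %/kb. The survival form is the default report
because "percent per kb" most naturally means polymerases lost per kb.

## Wavefront regression

The chase profile `w(i)` interpolates from the TSS level `o` to the
background `bg` at the wavefront `b`, damped by `2^{r·min(i,b)}`; `r`
is fixed at 0 for control samples and at the gene's gene-body LFC slope
for treated samples (genes failing the accurate-fit gate are dropped
rather than given a cohort-median slope). The first 5 kb are masked
(TSS peak). Window positions enter at their physical centers, so `b` is
in kb and `rate = b / chase_min` without offset corrections; no
pause-duration offset is subtracted. The background prior is Gaussian
on `log bg` with the 5% and 95% quantile-regression predictions mapped
to moments via mean = midpoint, sd = span/3.29 (the 5–95% span of a
normal is 3.29 sd). Quantile regression minimizes the pinball loss
directly (IRLS plus a Nelder–Mead polish); its contract is that ~5% and
~95% of residuals fall below the two lines. A fitted wavefront within
two windows of the gene end is flagged `at_boundary` — the wave may
have left the gene — and cohort summaries exclude such fits; without
this rule short genes truncate control-arm fronts and bias rate ratios
upward.

## SLAM kinetics

`da/dt = σ − δa` with closed-form new/old curves; observations are
normalized counts split by NTR. The control arm is assumed at steady
state; the depletion arm starts from `a0`, fixed to the mean old-RNA
level of the `t = 0` replicates. New-RNA observations at 2 h and 4 h
are excluded (prolonged labeling suppresses apparent new RNA; the
duplicated exclusion sentence in the source is read, per its own
context, as covering both late timepoints — configurable via
`exclude_new_h`). The default fit is a joint bounded least squares on
`(log σ, log δ)` via `minpack.lm::nls.lm` with equal weights. Note that
equal-weight least squares on levels does not exploit the precision of
the NTR ratio itself: with strongly overdispersed counts the σ
estimate inherits most of the count noise, which bounds per-gene
accuracy regardless of sequencing depth. TU-based median-of-ratios size
factors are used for normalization (these are scale-free: rescaling
the whole matrix leaves them unchanged).

## Scores and the moderated test

Completion = log2 of (last 15%) / (first 15%) sums of length-normalized
150 bp bins; readthrough = log2 of post-PAS (PAS+5..15 kb) over pre-PAS
(PAS−5..0 kb for 4sU, PAS−3..0 kb for occupancy) densities — densities,
not sums, because the windows differ in width. Both use a pseudocount
of one normalized count per window. Z-scores standardize the anti-logs
`2^score` with the sample (n−1) standard deviation; note that
anti-logging makes the spacing nonlinear relative to log-scale
z-scores, while a uniform log2 shift only rescales the anti-logs and
therefore leaves the z-scores unchanged. The differential test is an
empirical-Bayes moderated t: per-gene variances shrink toward the
pooled mean with a method-of-moments prior df; prior df 0 recovers the
ordinary two-sample t test.

## TU annotation

TSS: candidates explaining less than half of the gene's intronic reads
are removed (strictly more than 50% upstream ⇒ removed); among
survivors the maximal coverage increment `d_i − u_i` wins, ties to the
5′-most. PAS: the 3′-end read-start profile is smoothed with a
truncated-renormalized Gaussian kernel, sd 20 nt ("bandwidth" is read
as the kernel sd); `p` is the 3′-most position above 1% of the maximum.
Because smoothing carries `p` roughly 3 sd past a sharp read cluster,
the adoption window for an annotated PAS is symmetric (|annotated − p|
< 150 nt, 3′-most adopted); otherwise the PAS is `p + 100`.

## The synthetic cohort

`synth_config()` pins the emulated study: 300 genes, lengths
log-uniform 5–200 kb, triplicates in two arms, DRB chases at 10/20/30
min, SLAM at 0/1/2/4 h. Per-window expression is lognormal (median 100
counts per kb window — pooled-replicate depth typical of a
well-covered nascent-RNA library); NB size 5 for sequencing assays and
10 for SLAM counts; control elongation rates lognormal around 3 kb/min
(15% CV) with the treated arm at 0.75× and a 2%/kb defect; termination
declines of 0.0558 and 0.0266 per 250 nt window (20% and ~10%/kb);
SLAM degradation rates lognormal with median 0.35/h (half-life ≈ 2 h,
well inside the 0–4 h labeling design), synthesis σ = δ × level, and an
8-fold σ reduction in the treated arm; NTR noise is Beta with
precision 200. Gene-body counts take their means from the analytic
steady state (occupancy-proportional window densities), DRB counts
from the nucleotide-resolution front profile (10 nt in the generator),
PAS grids from the exponential decay. Determinism: one RNG stream per
(gene, assay, arm, replicate), derived from the seed; all of a gene's
SLAM draws come from a single vectorized stream — per-observation
reseeding is deliberately avoided, as first draws from structured seeds
are correlated.

What the generator does **not** emulate: mappability and GC artifacts,
exon-boundary read bleed, UMI duplication structure, spike-in pipetting
error beyond a scalar factor, transcriptional bursting (counts are NB
around deterministic means), pausing at the TSS (the generator has no
TSS peak even though the wavefront fit masks 5 kb for one), antisense
transcription, and multi-TSS genes. Passing recovery tests therefore
demonstrate estimator correctness under the declared noise model, not
robustness to every artifact of real libraries.

## Problem sizes and runtime choices

The recovery suites use the 300-gene default cohort; the dlfc
push-forward check uses 1e5 Monte-Carlo samples; grid-search oracle
comparisons run on 10–20-window toys where exhaustive grids are sharp.
These sizes keep the full test suite in the low minutes on one core
while leaving medians stable (recovery medians move by well under their
tolerance across seeds at n = 300).

## Known limitations

* The LFC slope inherits a small attenuation from the likelihood's
  pseudocount at strong defects (see above); the per-kb defect of a
  2%/kb cohort is recovered with a median within 10% but biased low.
* Per-gene SLAM σ accuracy is bounded by count overdispersion (~16%
  median relative error at NB size 10); cohort-level fold changes are
  accurate.
* The wavefront estimator needs the front inside the gene body; fits
  flagged `at_boundary` must be excluded from rate summaries.
* The simulator is mean-field and deterministic: no bursting, no
  pausing kinetics, no single-molecule variance.
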