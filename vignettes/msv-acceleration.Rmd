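---
title: "Methods: the MSV acceleration pipeline in msvscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the MSV acceleration pipeline in msvscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msvscan)
```

# The model

`msvscan` scores protein sequences against a profile hidden Markov model in
multihit local alignment mode. A core model of `M` consensus positions
carries match emission distributions `e_k(a)`, insert states emitting at
background frequency, and match/insert/delete transitions. Around the core,
flanking states N, C and J emit nonhomologous residues at background
frequency; the J state joins multiple homologous segments in one target.
All scores are log-odds in bits against an i.i.d. null model with a
geometric length distribution (`r = L/(L+1)`, so the expected null length
equals the target length `L`).

The length model ties the flanking transitions to the target: the N/C/J
self-loop probability is `L/(L+3)` and the move probability `3/(L+3)`;
`t(E->J) = t(E->C) = 0.5` makes the expected number of segments per target
2 under the model prior.

**Local entry and exit.** Local alignment is parameterized through a
collapsed representation of an implicit fragment model: every match state
has a local exit transition of probability 1, and the begin state enters
every position with probability `2/(M(M+1))`. Each entry/exit pair `(i, j)`
then carries probability exactly `2/(M(M+1))`, giving a uniform
distribution over the `M(M+1)/2` fragments that sums to 1; the marginal
probability of entering at position `k` is `2(M-k+1)/(M(M+1))`. The same
entry/exit scheme is used for the MSV, Viterbi and Forward scores, which
keeps the three stages mutually consistent and keeps Forward a proper
probability model: on random sequences the posterior expected segment
count stays between 1 (every path has a segment) and the prior of 2,
rather than exploding with the number of overcounted exits. Occupancy
weighting of entry probabilities, as some implementations use, is a
refinement we deliberately omit.

**MSV.** The multiple segment Viterbi score drops all core transitions
(match-match treated as probability 1, inserts and deletes removed) and
scores the optimal *set* of ordered, non-overlapping ungapped segments.
`msv_score()` is the full-precision serial recursion in O(M) memory;
`brute_force_msv()` is an exhaustive segment enumeration used as its test
oracle on tiny instances.

# Reduced precision

The filters run in quantized integer arithmetic, justified by two bounds:
a worst-case positive-scoring local alignment (one match, all other
residues flanking) cannot score below about -60 bits within the design
limits `M, L <= 100000`, and any score above 17 bits is certain to pass a
filter threshold of `P >= 1e-5` because `P(S >= t) <= 2^-t` for log-odds
scores (`overflow_bound()`). Saturation at the top of a range therefore
simply means "passes the filter".

* **MSV filter** (`msv_filter()`): unsigned bytes in units of 1/3 bit,
  base offset 190, per-residue bias making all emission costs unsigned.
  Cells live in a striped layout (`stripe()`): cell `k` goes to vector
  `(k-1) mod Q`, slot `(k-1) div Q`, so the diagonal dependency of the
  recursion lines up vector-to-vector with a single shift per row. The
  N/C/J self-loops are scored as zero cost in the recursion; their total
  contribution `L*log2(L/(L+3))` approaches the constant -4.33 bits, which
  is added back at termination (`flank_loop_total()` shows the
  convergence). The striped computation is kept bit-identical to a scalar
  saturated-byte reference (`msv_filter_scalar()`), which the test suite
  verifies per instance.
* **Viterbi filter** (`viterbi_filter()`): signed 16-bit words in units of
  1/500 bit with an integer offset of 12000, so representable scores span
  -89.5 to 41.5 bits. Emission words are stored striped; the along-row
  delete chain, which striping would otherwise serialize through lazy
  correction passes, is resolved by a serialized per-row pass in cell
  order — the always-exact degenerate form of the iterate-until-fixed-point
  correction, chosen because this implementation emulates rather than
  vectorizes the arithmetic. To keep the filter within ~0.1 bits of the
  full-precision Viterbi score despite the coarse per-loop rounding, the
  filter scores N/C/J loops as zero, pre-charges every emitted residue the
  quantized loop score, and restores the exact `L*log2(L/(L+3))` total in
  floating point at termination. The MSV filter deliberately keeps the
  cruder constant treatment: its observed roundoff (standard deviation
  0.4-0.6 bits at L = 400) is part of what calibration absorbs.

# Forward/Backward and sparse rescaling

The generic reference implementation works in the log domain with an exact
log-sum; `logsum_table()` provides the classic 16,000-entry lookup variant
with worst-case error below 0.001 bits. The production path
(`forward_score(..., mode = "parser")`) works in the odds-ratio domain in
O(M) memory plus full special-state columns. Underflow from long delete
chains is handled by *sparse rescaling*: when the E-cell odds ratio of a
row exceeds a threshold (default 1e10, chosen far below float overflow yet
rare enough to cost nothing; the trigger value is a tunable, not a claim),
the whole row is divided by the E value and the log2 scale factor is
accumulated. This is sound for multihit local models because any path
through a long deletion is dominated by an alternative that re-initiates
through E->J->B. The backward parser mirrors this, triggering on its B
cell. Forward and Backward totals agree to well under 1e-3 bits, and
`endpoint_posteriors()` decodes per-position probabilities that a segment
begins or ends at each residue; both posterior vectors sum to the expected
segment count.

# E-value statistics

MSV and Viterbi null scores follow Gumbel distributions whose slope is the
conjectured `log 2`, inflated for finite-length edge effects in
low-information models; `edge_corrected_lambda()` applies the ad hoc
correction `lambda = log 2 + 1.44/(M*H)` with `H` the relative entropy per
position in bits. `calibrate()` scores 200 i.i.d. random sequences of
length 400 (both defaults tunable) with the actual filter implementations
and fits the Gumbel locations by the closed-form fixed-slope maximum
likelihood estimator; the location's sampling error is about
`1.05/(lambda*sqrt(n))`, under 0.11 bits at the defaults. The Forward tail
is modeled as an exponential of the same slope above the top `tailmass`
fraction of calibration scores (default 0.04 — small enough to be in-tail,
large enough that 8 of 200 points anchor it), with the location
moment-matched at fixed slope (`tau = mean(tail) - 1/lambda`).

# The pipeline

`run_pipeline()` accepts or rejects each model/target comparison whole, in
stage order MSV (`P < F1 = 0.02`), bias-corrected MSV retest (same F1),
Viterbi filter (`P < F2 = 0.001`), Forward (`P < F3 = 1e-5`); `F3` sits
between `F2` and typical reporting thresholds and is configurable.
Overflowed filter scores always pass. The profile's length model is re-set
to each target's length before scoring. The bias filter rescores the MSV
null with a two-state HMM (average protein composition vs. the profile's
average composition, transitions stay-background 0.99 / go-bias 0.01 /
stay-bias 0.95 / go-background 0.05, starting in the background state —
hand-tuned values, as such filters conventionally are) and re-tests the
corrected P-value; it never changes the reported Forward score. E-values
are Forward P-values times the number of targets searched.

# Synthetic data and the benchmark constructor

`sample_profile()` defines the study conditions for the calibration and
roundoff experiments: per-position emissions drawn from a sharp Dirichlet
around the background and blended toward the background until the mean
relative entropy hits the target (default 0.6 bits/position, the
information content of typical entropy-weighted models and of BLOSUM62);
the headline experiments use `M = 170`, a typical mid-size model length,
`L = 400` targets, calibration `n = 200`, and 50,000 evaluation sequences.
Transitions are fixed to typical values since MSV ignores them and the
gapped stages are insensitive at these scales.

`profmark_build()` reimplements the benchmark constructor: degeneracies to
X; fragments (under 70% of mean unaligned length) removed; single-linkage
clustering at 25% identity (identities divided by the shorter unaligned
length) with single-cluster alignments excluded; the largest cluster
becomes the query; the remainder re-clustered at 50% with one random
domain per cluster; positives embed 1 or 2 domains in nonhomologous
context with total length drawn from the database length distribution
conditional on fitting the domains (rejection sampling with a capped
number of tries, falling back to the minimal length plus a geometric
flank); decoys copy the segment-length vectors of randomly chosen
positives. Nonhomologous segments come from mono-shuffled database
segments by default, with i.i.d., di-residue-preserving (randomized
Hierholzer Euler-path walk) and reversal modes as alternatives. Embedding
positions are drawn by uniform cut points over the spare length, which
preserves domain order; `profmark_verify()` re-checks every identity and
structure guarantee on the finished benchmark, and the test suite runs it
on every benchmark it builds. When no sequence database is supplied,
lengths come from a log-normal surrogate (median 350, sigma_log 0.6,
roughly the shape of protein database length distributions).

# What the synthetic tests do and do not show

The generators produce i.i.d. or shuffled sequences with realistic
composition but no repeats, no coiled-coil or transmembrane bias beyond
what the bias-filter tests construct explicitly, and profile emissions
without Dirichlet-mixture structure. Passing the calibration test (the
observed filter fraction within two-fold of the nominal 0.02 on 50,000
random length-400 sequences) therefore demonstrates the statistics under
the model's own null, which is the regime in which the two-fold
expectation is known to hold; heavily biased real sequences are exactly the case the
bias filter exists for, and short targets (L around 25) are known to make
filter P-values conservative by up to several fold. The 10,000-decoy
pipeline experiment bounds filter losses at desk scale (a few dozen strong
positives), not at database scale.

# Numerical choices and degenerate inputs

Degenerate residue codes map to X, which scores 0 bits everywhere —
neutral under log-odds. Emission pseudocounts are background-proportional
(`weight * 20 * f_a`), guaranteeing positivity for the log-odds transform;
the entropy-weighting multiplier is found by bisection to 0.01 bits.
Builder inputs with no consensus columns or no sequences are errors, as
are empty databases and ragged alignments. Sequences and model positions
are 1-based in all reports; intervals are closed. Byte sentinels (unused
striped slots) hold cost 255 and word sentinels -32768, so they can never
beat a live cell. Ties in the DP are irrelevant since only scores, never
tracebacks, are produced. Saturated word arithmetic treats -32768 both as
the representable floor and as "minus infinity"; paths resurrected from
the floor sit below -89 bits and cannot affect scores within the design
limits. Problem sizes in the test suite (tiny-instance oracle sweeps,
1,000-sequence roundoff runs, 50,000-sequence calibration, one
10,000-decoy search) were chosen as the smallest sizes at which the
corresponding statistical claims are sharp.
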