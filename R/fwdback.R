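#' Exact or table-driven log-sum operation
#'
#' Computes `log2(2^a + 2^b)`. In the generic log-domain Forward/Backward
#' recursions, probability-domain addition is replaced by this operation;
#' the table mode emulates the precalculated lookup used by fast
#' implementations, indexing the additive correction `log2(1 + 2^-d)` by the
#' rounded difference `d = |a - b|`.
#'
#' @param a,b Scores in bits (may be `-Inf`).
#' @param table Optional lookup table from [logsum_table()]; `NULL` uses
#'   exact arithmetic.
#' @return `log2(2^a + 2^b)` in bits.
#' @export
logsum <- function(a, b, table = NULL) {
  if (a == -Inf) return(b)
  if (b == -Inf) return(a)
  mx <- max(a, b); d <- abs(a - b)
  if (is.null(table)) return(mx + log1p(2^(-d)) / log(2))
  if (d >= table$cutoff) return(mx)
  mx + table$entries[round(d / table$step) + 1L]
}

#' Precomputed log-sum correction table
#'
#' `entries[i]` holds `log2(1 + 2^-d)` for `d = (i-1) * step`; beyond
#' `cutoff` the correction is treated as zero. The default step and cutoff
#' give a 16,000-entry table whose worst-case error against exact log-sum is
#' below 0.001 bits.
#'
#' @param step Table resolution in bits per entry.
#' @param cutoff Difference beyond which the correction is dropped.
#' @return List with `step`, `cutoff`, `entries`.
#' @export
logsum_table <- function(step = 0.001, cutoff = 16) {
  d <- seq(0, cutoff, by = step)
  list(step = step, cutoff = cutoff, entries = log1p(2^(-d)) / log(2))
}

#' Forward score: log-odds of the complete local alignment ensemble
#'
#' Sums probability over every multihit local alignment of the gapped
#' profile, reported as log2 odds versus the null model. Two
#' implementations are provided: `"generic"`, a log-domain reference using
#' exact log-sum-exp, and `"parser"`, the O(M)-memory odds-ratio-domain
#' implementation with sparse rescaling (a row is rescaled by its E-state
#' value whenever that value exceeds `rescale_threshold`, which keeps all
#' values in floating range even for long targets; multihit local models
#' guarantee that any underflowing long-deletion path is dominated by the
#' corresponding two-segment reinitiation path).
#'
#' Both modes return the special-state columns needed for endpoint posterior
#' decoding with [endpoint_posteriors()].
#'
#' @param sp A `search_profile`.
#' @param seq Residue string or encoded integers.
#' @param mode `"parser"` (default) or `"generic"`.
#' @param rescale_threshold Odds-ratio trigger for a row rescale (parser).
#' @return Object of class `fwdbwd_state`: list with `score` (bits),
#'   `total` (model log-odds before null subtraction), `logB`, `logE`
#'   (length L+1 special columns, log2), `direction`, and for the parser
#'   `scalelog` (per-row log2 scale factors) and `nrescale`.
#' @export
forward_score <- function(sp, seq, mode = c("parser", "generic"),
                          rescale_threshold = 1e10) {
  mode <- match.arg(mode)
  x <- aa_encode(seq)
  if (length(x) < 1L) stop("sequence must have length >= 1")
  if (mode == "generic") {
    lt <- profile_log_transitions(sp)
    r <- cpp_forward_generic(sp$s, x, lt$mm, lt$mi, lt$md, lt$im, lt$ii,
                             lt$dm, lt$dd, log2(sp$entry),
                             log2(sp$loop), log2(sp$move), sp$nulltr)
  } else {
    t7 <- sp$core$t
    r <- cpp_forward_parser(2^sp$s, x,
                            t7[, "mm"], t7[, "mi"], t7[, "md"],
                            t7[, "im"], t7[, "ii"], t7[, "dm"], t7[, "dd"],
                            sp$entry, sp$loop, sp$move, sp$nulltr,
                            rescale_threshold)
  }
  structure(c(r, list(mode = mode, direction = "forward", L = length(x))),
            class = "fwdbwd_state")
}

#' Backward score and state
#'
#' Mirror-image of [forward_score()]; the total score equals the Forward
#' total (a standard consistency identity used as a correctness check).
#'
#' @inheritParams forward_score
#' @return `fwdbwd_state` as for [forward_score()].
#' @export
backward_score <- function(sp, seq, mode = c("parser", "generic"),
                           rescale_threshold = 1e10) {
  mode <- match.arg(mode)
  x <- aa_encode(seq)
  if (length(x) < 1L) stop("sequence must have length >= 1")
  if (mode == "generic") {
    lt <- profile_log_transitions(sp)
    r <- cpp_backward_generic(sp$s, x, lt$mm, lt$mi, lt$md, lt$im, lt$ii,
                              lt$dm, lt$dd, log2(sp$entry),
                              log2(sp$loop), log2(sp$move), sp$nulltr)
  } else {
    t7 <- sp$core$t
    r <- cpp_backward_parser(2^sp$s, x,
                             t7[, "mm"], t7[, "mi"], t7[, "md"],
                             t7[, "im"], t7[, "ii"], t7[, "dm"], t7[, "dd"],
                             sp$entry, sp$loop, sp$move, sp$nulltr,
                             rescale_threshold)
  }
  structure(c(r, list(mode = mode, direction = "backward", L = length(x))),
            class = "fwdbwd_state")
}

#' Posterior probabilities of local alignment endpoints
#'
#' Combines matching Forward and Backward runs to decode, for every target
#' position, the posterior probability that an alignment segment begins
#' (B state used) or ends (E state used) there. The two posterior vectors
#' each sum to the expected number of alignment segments.
#'
#' @param fwd `fwdbwd_state` from [forward_score()].
#' @param bwd `fwdbwd_state` from [backward_score()] on the same profile and
#'   sequence.
#' @return List with `begin` (length L; `begin[i]` is the posterior that a
#'   segment starts at residue i), `end` (length L; segment ends at residue
#'   i), and `expected_segments`.
#' @export
endpoint_posteriors <- function(fwd, bwd) {
  if (fwd$direction != "forward" || bwd$direction != "backward")
    stop("need one forward and one backward state")
  if (fwd$L != bwd$L) stop("mismatched forward/backward runs")
  if (abs(fwd$total - bwd$total) > 0.01)
    stop("forward/backward totals disagree; mismatched runs?")
  L <- fwd$L
  tot <- fwd$total
  # B used after i residues means a segment starts at residue i+1
  begin <- 2^(fwd$logB[1:L] + bwd$logB[1:L] - tot)
  end <- 2^(fwd$logE[2:(L + 1)] + bwd$logE[2:(L + 1)] - tot)
  list(begin = begin, end = end, expected_segments = sum(begin))
}
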