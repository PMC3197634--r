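#' MSV score: optimal multihit ungapped alignment, full precision
#'
#' The multiple segment Viterbi (MSV) score is the log-odds (bits) of the
#' optimal set of one or more ordered, non-overlapping ungapped alignment
#' segments, versus the i.i.d. null model. Core transitions are ignored
#' (match-match treated as probability 1), entry into the model is uniform
#' `2/(M(M+1))`, every match state exits with probability 1, and the
#' flanking N/C/J states emit at background frequencies (zero emission
#' score). Null-model transition terms are included at termination.
#'
#' @param sp A `search_profile` configured for the target length.
#' @param seq Residue string or encoded integer vector.
#' @return Bit score (scalar).
#' @export
msv_score <- function(sp, seq) {
  x <- aa_encode(seq)
  if (length(x) < 1L) stop("sequence must have length >= 1")
  cpp_msv_score(sp$s, x, log2(sp$entry_msv),
                log2(sp$loop), log2(sp$move), sp$nulltr)
}

# Integer byte costs of the length-model transitions at the profile's
# current L. Costs are -scale * log2(prob), rounded, saturated at 255.
msv_byte_costs <- function(rp, sp) {
  costb <- function(logprob) as.integer(min(255, max(0, round(-rp$msv_scale * logprob))))
  list(tjb = costb(log2(sp$move)),        # N->B, J->B and C->T all use 3/(L+3)
       tbm = costb(log2(sp$entry_msv)),
       tec = costb(log2(0.5)))
}

#' MSV filter: striped, saturated unsigned-byte implementation
#'
#' Reduced-precision heuristic form of [msv_score()]: all cell arithmetic is
#' saturated unsigned 8-bit in units of 1/3 bit over striped vectors. The
#' NN/CC/JJ flanking loop transitions are scored as zero cost during the
#' recursion and their asymptotic total (about -4.3 bits) is added back at
#' termination. Saturation at the top of the byte range sets
#' `overflowed = TRUE` and the score is reported as `Inf` (an overflowed
#' target is certain to pass any reasonable filter threshold).
#'
#' @param rp A `reduced_profile` derived from `sp`.
#' @param sp The matching `search_profile` (supplies the length model).
#' @param seq Residue string or encoded integer vector.
#' @return List with `score` (bits), `overflowed`, `raw` (byte maximum).
#' @export
msv_filter <- function(rp, sp, seq) {
  if (rp$M != sp$M) stop("reduced profile does not match search profile")
  x <- aa_encode(seq)
  cb <- msv_byte_costs(rp, sp)
  res <- cpp_msv_filter(rp$msv_bytes, rp$Q_byte, rp$V_byte, x,
                        rp$msv_base, rp$msv_bias, cb$tjb, cb$tbm, cb$tec)
  if (res$overflow)
    return(list(score = Inf, overflowed = TRUE, raw = 255L))
  # Unwind the byte bookkeeping: raw = xJ tracks base + sum over segments of
  # (-tjb - tbm + matches - tec) in 1/scale-bit units; one further tjb pays
  # the C->T move. Restore the flanking-loop constant and null terms in
  # floating point.
  bits_model <- (res$raw - cb$tjb - rp$msv_base) / rp$msv_scale + MSV_LOOP_CONST
  list(score = bits_model - sp$nulltr, overflowed = FALSE, raw = res$raw)
}

#' Scalar saturated-byte MSV reference (non-striped)
#'
#' Same saturated unsigned-byte arithmetic as [msv_filter()] but computed in
#' plain cell order over the padded cell range (sentinel cells cost 255).
#' Used to verify that the striped data layout is a pure re-indexing:
#' results are bit-identical to the striped implementation.
#'
#' @inheritParams msv_filter
#' @return Same structure as [msv_filter()].
#' @export
msv_filter_scalar <- function(rp, sp, seq) {
  x <- aa_encode(seq)
  cb <- msv_byte_costs(rp, sp)
  sadd <- function(a, b) pmin(255L, a + b)
  ssub <- function(a, b) pmax(0L, a - b)
  ncell <- rp$Q_byte * rp$V_byte
  idx <- stripe_index0(rp$M, rp$V_byte)
  # emission costs in plain cell order; padding cells keep the 255 sentinel
  cost <- matrix(255L, ncell, 21L)
  cost[seq_along(idx), ] <- rp$msv_bytes[idx, , drop = FALSE]
  tjbm <- sadd(cb$tjb, cb$tbm)
  dp <- integer(ncell)
  xJ <- 0L
  xB <- ssub(rp$msv_base, tjbm)
  overflow <- FALSE
  for (i in seq_along(x)) {
    prev <- c(0L, dp[-ncell])
    sv <- ssub(sadd(pmax(prev, xB), rp$msv_bias), cost[, x[i] + 1L])
    dp <- sv
    xE <- max(sv)
    if (xE >= 255L - rp$msv_bias) { overflow <- TRUE; break }
    xJ <- max(xJ, ssub(xE, cb$tec))
    xB <- ssub(max(rp$msv_base, xJ), tjbm)
  }
  if (overflow) return(list(score = Inf, overflowed = TRUE, raw = 255L))
  bits_model <- (xJ - cb$tjb - rp$msv_base) / rp$msv_scale + MSV_LOOP_CONST
  list(score = bits_model - sp$nulltr, overflowed = FALSE, raw = xJ)
}

#' Brute-force MSV score by exhaustive segment enumeration
#'
#' Independent oracle for [msv_score()]: enumerates every ordered set of
#' non-overlapping ungapped segments (each segment a diagonal run of match
#' states against consecutive residues), scoring entries, E->J/E->C exits,
#' N/C/J loops, B moves and null terms exactly as the generative model
#' defines them, and returns the maximum. Exponential in instance size;
#' guarded to tiny problems.
#'
#' @param sp A `search_profile`.
#' @param seq Residue string or encoded integers.
#' @param max_cells Guard: refuse instances with more than this many
#'   model-by-sequence cells (default 100).
#' @return Bit score.
#' @export
brute_force_msv <- function(sp, seq, max_cells = 100) {
  x <- aa_encode(seq)
  M <- sp$M; L <- length(x)
  if (M * L > max_cells) stop("instance too large for brute-force enumeration")
  loop2 <- log2(sp$loop); move2 <- log2(sp$move)
  ent <- log2(sp$entry_msv)
  s <- sp$s
  # contribution of one segment: move into B, entry, matches (each charged
  # s - loop since the residue forgoes a flanking loop), E exit of -1 bit
  seg_contrib <- function(i, k, n) {
    sc <- move2 + ent - 1
    for (j in seq_len(n) - 1L)
      sc <- sc + s[k + j, x[i + j] + 1L] - loop2
    sc
  }
  best_from <- function(pos) {  # best additional score, segments start >= pos
    best <- 0
    for (i in pos:L) {
      nmax <- min(M, L - i + 1L)
      for (n in seq_len(nmax)) {
        for (k in seq_len(M - n + 1L)) {
          v <- seg_contrib(i, k, n) +
            if (i + n <= L) best_from_memo(i + n) else 0
          if (v > best) best <- v
        }
      }
    }
    best
  }
  memo <- rep(NA_real_, L + 1L)
  best_from_memo <- function(pos) {
    if (pos > L) return(0)
    if (is.na(memo[pos])) memo[pos] <<- best_from(pos)
    memo[pos]
  }
  # at least one segment is required
  best1 <- -Inf
  for (i in seq_len(L)) {
    nmax <- min(M, L - i + 1L)
    for (n in seq_len(nmax)) {
      for (k in seq_len(M - n + 1L)) {
        v <- seg_contrib(i, k, n) +
          if (i + n <= L) best_from_memo(i + n) else 0
        if (v > best1) best1 <- v
      }
    }
  }
  unname(best1 + move2 + L * loop2 - sp$nulltr)
}
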