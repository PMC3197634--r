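#' Gumbel survival function (P-value) for optimal-alignment bit scores
#'
#' `P(S > x) = 1 - exp(-exp(-lambda * (x - mu)))`. Optimal local alignment
#' bit scores of probabilistic local models (Viterbi and MSV) are expected
#' to follow a Gumbel distribution with slope `lambda = log 2`, inflated for
#' finite-length edge effects (see [edge_corrected_lambda()]); the location
#' `mu` is fitted from a small simulation.
#'
#' @param x Bit score(s).
#' @param p List with `mu` (bits) and `lambda` (1/bits, > 0).
#' @return P-value(s) in (0, 1).
#' @export
gumbel_pvalue <- function(x, p) {
  if (p$lambda <= 0) stop("lambda must be positive")
  -expm1(-exp(-p$lambda * (x - p$mu)))
}

#' Maximum-likelihood Gumbel location with known slope
#'
#' Closed form: `mu = -(1/lambda) * log(mean(exp(-lambda * x)))`.
#'
#' @param scores Numeric vector of bit scores (n >= 2).
#' @param lambda Fixed slope (1/bits, > 0).
#' @return Location `mu` in bits.
#' @export
fit_gumbel_location <- function(scores, lambda) {
  if (length(scores) < 2L) stop("need at least 2 scores")
  if (lambda <= 0) stop("lambda must be positive")
  # subtract the max for numerical stability of the exp mean
  m <- max(scores)
  m - log(mean(exp(-lambda * (scores - m)))) / lambda
}

#' Joint maximum-likelihood Gumbel fit
#'
#' Solves the profile-likelihood equation for the slope by root finding,
#' then recovers the location in closed form.
#'
#' @param scores Numeric vector (n >= 10, non-degenerate).
#' @return List with `mu`, `lambda`.
#' @export
fit_gumbel_ml <- function(scores) {
  if (length(scores) < 10L) stop("need at least 10 scores")
  if (stats::sd(scores) < 1e-12) stop("degenerate (constant) scores")
  xbar <- mean(scores)
  g <- function(lam) {
    w <- exp(-lam * (scores - max(scores)))
    1 / lam - xbar + sum(scores * w) / sum(w)
  }
  # moment-based bracket: lambda ~ pi / (sd * sqrt(6))
  lam0 <- pi / (stats::sd(scores) * sqrt(6))
  lo <- lam0 / 20; hi <- lam0 * 20
  lam <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  list(mu = fit_gumbel_location(scores, lam), lambda = lam)
}

#' Edge-corrected Gumbel slope
#'
#' The conjectured slope for local alignment bit scores is `log 2`; models
#' with low relative entropy per position need long alignments for high
#' scores and show a finite-length "edge effect" that inflates the observed
#' slope. The ad hoc correction `lambda = log 2 + 1.44 / (M * H)` (M model
#' positions, H bits/position) reproduces this inflation and tends to
#' `log 2` for information-rich or long models.
#'
#' @param M Model length in match states (>= 1).
#' @param H Relative entropy per position, bits (> 0).
#' @return Corrected slope, 1/bits.
#' @export
edge_corrected_lambda <- function(M, H) {
  if (M < 1) stop("M must be >= 1")
  if (H <= 0) stop("H must be positive")
  log(2) + 1.44 / (M * H)
}

#' Exponential-tail survival function for Forward bit scores
#'
#' The high-scoring tail of Forward scores follows an exponential of the
#' same slope as the Gumbel for Viterbi-type scores:
#' `P(S > x) = tailmass * exp(-lambda * (x - tau))`, clamped at 1.
#'
#' @param x Bit score(s).
#' @param p List with `tau` (bits), `lambda` (1/bits), `tailmass`.
#' @return P-value(s) in (0, 1].
#' @export
exp_tail_pvalue <- function(x, p) {
  if (p$lambda <= 0) stop("lambda must be positive")
  pmin(1, p$tailmass * exp(-p$lambda * (x - p$tau)))
}

#' Conservative P-value bound for a bit score threshold
#'
#' For any log-odds scoring system, `P(S >= t) <= 2^-t`. This bound is what
#' makes saturation at the top of a reduced-precision range safe: an
#' overflowed score is certain to pass any reasonable filter threshold.
#'
#' @param t Bit score threshold.
#' @return `2^-t`.
#' @export
overflow_bound <- function(t) 2^(-t)

#' Calibrate E-value statistics for a profile by simulation
#'
#' Scores `n` i.i.d. random sequences of length `Lcal` with the MSV filter,
#' the Viterbi filter and the Forward parser, then fits: Gumbel locations
#' for MSV and Viterbi by fixed-slope maximum likelihood with the
#' edge-corrected slope; and the Forward exponential tail location on the
#' top `tailmass` fraction of scores (moment-matched at fixed slope).
#' Deterministic given `seed`.
#'
#' @param sp A `search_profile`.
#' @param rp Optional matching `reduced_profile` (built if missing).
#' @param n Number of calibration sequences (default 200).
#' @param Lcal Calibration sequence length (default 400).
#' @param seed Integer seed.
#' @param tailmass Forward tail fraction (default 0.04).
#' @return Object of class `profile_calibration`: list with `msv`, `vit`
#'   (each `mu`, `lambda`) and `fwd` (`tau`, `lambda`, `tailmass`), plus
#'   `n`, `Lcal`, `seed`.
#' @export
calibrate <- function(sp, rp = NULL, n = 200, Lcal = 400, seed = 1L,
                      tailmass = 0.04) {
  if (n < 10) stop("need n >= 10 calibration sequences")
  if (is.null(rp)) rp <- reduce_profile(sp)
  spc <- profile_set_length(sp, Lcal)
  lam <- edge_corrected_lambda(sp$M, relative_entropy(sp$core, spc$null))
  scores <- with_seed(seed, {
    msv <- numeric(n); vit <- numeric(n); fwd <- numeric(n)
    for (i in seq_len(n)) {
      x <- sample.int(20L, Lcal, replace = TRUE, prob = spc$null$f) - 1L
      m <- msv_filter(rp, spc, x)
      v <- viterbi_filter(rp, spc, x)
      msv[i] <- if (m$overflowed) (255 - rp$msv_base) / rp$msv_scale else m$score
      vit[i] <- if (v$overflowed) viterbi_filter_max_bits(rp) else v$score
      fwd[i] <- forward_score(spc, x, mode = "parser")$score
    }
    list(msv = msv, vit = vit, fwd = fwd)
  })
  ntail <- max(2L, ceiling(tailmass * n))
  tail_scores <- sort(scores$fwd, decreasing = TRUE)[seq_len(ntail)]
  structure(list(
    msv = list(mu = fit_gumbel_location(scores$msv, lam), lambda = lam),
    vit = list(mu = fit_gumbel_location(scores$vit, lam), lambda = lam),
    fwd = list(tau = mean(tail_scores) - 1 / lam, lambda = lam,
               tailmass = tailmass),
    n = n, Lcal = Lcal, seed = seed
  ), class = "profile_calibration")
}

#' @export
print.profile_calibration <- function(x, ...) {
  cat(sprintf(
    "profile_calibration (n=%d, L=%d): MSV mu=%.2f, Viterbi mu=%.2f, Forward tau=%.2f, lambda=%.4f\n",
    x$n, x$Lcal, x$msv$mu, x$vit$mu, x$fwd$tau, x$msv$lambda))
  invisible(x)
}
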