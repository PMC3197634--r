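#' Stripe a per-position vector into SIMD-style vectors
#'
#' Cells are assigned non-consecutively so that the previous-row diagonal
#' dependency of a striped dynamic programming recursion lines up without
#' per-cell shuffles: cell `k` (1-based) goes to vector `(k-1) mod Q`,
#' slot `(k-1) div Q`, with `Q = ceiling(M/V)`. Unused slots hold the
#' sentinel value `NA`.
#'
#' @param values Numeric vector of length M (one value per model position).
#' @param V Cells per vector: 4, 8 or 16.
#' @return `Q x V` matrix; row `q` is vector `q-1` (class `striped`).
#' @export
stripe <- function(values, V) {
  if (!V %in% c(4L, 8L, 16L)) stop("V must be one of 4, 8, 16")
  M <- length(values)
  stopifnot(M >= 1)
  Q <- ceiling(M / V)
  out <- matrix(NA, nrow = Q, ncol = V)
  k <- seq_len(M)
  out[cbind((k - 1L) %% Q + 1L, (k - 1L) %/% Q + 1L)] <- values
  structure(out, M = M, class = c("striped", class(out)))
}

#' Invert [stripe()]
#'
#' @param sx Striped matrix from [stripe()].
#' @param M Number of model positions (defaults to the stored attribute).
#' @return Vector of length M in position order.
#' @export
unstripe <- function(sx, M = attr(sx, "M")) {
  Q <- nrow(sx); V <- ncol(sx)
  if (is.null(M)) M <- Q * V
  k <- seq_len(M)
  sx[cbind((k - 1L) %% Q + 1L, (k - 1L) %/% Q + 1L)]
}

# 0-based stripe index map: cell k (0-based) -> row q*V + v of the flat
# (Q*V) x 21 striped emission matrices handed to the C++ kernels.
stripe_index0 <- function(M, V) {
  Q <- ceiling(M / V)
  k <- seq_len(M) - 1L
  (k %% Q) * V + k %/% Q + 1L  # 1-based row index into the flat matrix
}

#' Reduced-precision integer representations of a search profile
#'
#' Builds the two quantized score sets used by the acceleration filters:
#'
#' * MSV: emission scores as unsigned byte *costs* in units of 1/3 bit.
#'   With `base = 190` the byte range 0..255 represents roughly -63..+21.7
#'   bits. `bias` is the maximum scaled residue score, so that
#'   `cost = bias - round(scale * s)` is non-negative for every residue,
#'   saturated at 255.
#' * Viterbi: emission and transition scores as signed 16-bit words in units
#'   of 1/500 bit with an integer offset of 12000, representable range
#'   -89.5 to 41.5 bits.
#'
#' Both emission sets are stored in striped order (see [stripe()]); byte
#' sentinel cells cost 255, word sentinels hold -32768.
#'
#' @param sp A `search_profile`.
#' @param V_byte Byte-lane count for MSV (default 16, i.e. 16-fold
#'   parallelism of a 128-bit vector).
#' @param V_word Word-lane count for the Viterbi filter (default 8).
#' @return Object of class `reduced_profile`.
#' @export
reduce_profile <- function(sp, V_byte = 16L, V_word = 8L) {
  if (!V_byte %in% c(4L, 8L, 16L) || !V_word %in% c(4L, 8L, 16L))
    stop("V must be one of 4, 8, 16")
  M <- sp$M
  s20 <- sp$s  # M x 21 bits

  # ---- MSV bytes -----------------------------------------------------------
  msv_scale <- 3; msv_base <- 190L
  scaled <- round(msv_scale * s20)
  msv_bias <- as.integer(max(0, max(scaled)))
  cost <- pmin(255, msv_bias - scaled)   # >= 0 by construction of bias
  Qb <- ceiling(M / V_byte)
  emb <- matrix(255L, nrow = Qb * V_byte, ncol = 21L)
  idx <- stripe_index0(M, V_byte)
  emb[idx, ] <- as.integer(cost)

  # ---- Viterbi words -------------------------------------------------------
  vit_scale <- 500; vit_base <- 12000L
  w <- function(x) as.integer(pmax(-32768, pmin(32767, round(vit_scale * x))))
  Qw <- ceiling(M / V_word)
  emw <- matrix(-32768L, nrow = Qw * V_word, ncol = 21L)
  idxw <- stripe_index0(M, V_word)
  emw[idxw, ] <- w(s20)

  lt <- profile_log_transitions(sp)
  tw <- lapply(lt, w)
  entry_w <- w(log2(sp$entry))

  structure(list(
    M = M,
    msv_bytes = emb, msv_base = msv_base, msv_scale = msv_scale,
    msv_bias = msv_bias, V_byte = as.integer(V_byte), Q_byte = as.integer(Qb),
    vit_words = emw, vit_base = vit_base, vit_scale = vit_scale,
    V_word = as.integer(V_word), Q_word = as.integer(Qw),
    t_words = tw, entry_words = entry_w,
    profile_name = sp$core$name
  ), class = "reduced_profile")
}

#' Maximum bit score representable by the Viterbi filter words
#'
#' @param rp A `reduced_profile` (defaults used if missing).
#' @return Upper bound in bits: `(32767 - base) / scale`.
#' @export
viterbi_filter_max_bits <- function(rp = NULL) {
  base <- if (is.null(rp)) 12000L else rp$vit_base
  scale <- if (is.null(rp)) 500 else rp$vit_scale
  (32767 - base) / scale
}

#' Dequantized MSV emission scores recovered from the byte representation
#'
#' @param rp A `reduced_profile`.
#' @return M x 21 matrix of bit scores (within 1/scale of the originals,
#'   except where saturated).
#' @export
dequantize_msv <- function(rp) {
  idx <- stripe_index0(rp$M, rp$V_byte)
  (rp$msv_bias - rp$msv_bytes[idx, , drop = FALSE]) / rp$msv_scale
}

#' @export
print.reduced_profile <- function(x, ...) {
  cat(sprintf(
    "reduced_profile '%s': M=%d; MSV bytes Q=%d V=%d (base %d, bias %d, 1/%g bit); Viterbi words Q=%d V=%d (offset %d, 1/%g bit)\n",
    x$profile_name, x$M, x$Q_byte, x$V_byte, x$msv_base, x$msv_bias,
    x$msv_scale, x$Q_word, x$V_word, x$vit_base, x$vit_scale))
  invisible(x)
}
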