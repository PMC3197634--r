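#' Viterbi score: optimal gapped multihit local alignment, full precision
#'
#' Log-odds score (bits) of the single best alignment of the full gapped
#' profile (match/insert/delete transitions, uniform-fragment local entry
#' `2(M-k+1)/(M(M+1))`, local exit probability 1 from every match state,
#' multihit J state, N/C/J flanking emission at background) against the
#' i.i.d. null model. O(M) memory.
#'
#' @param sp A `search_profile` configured for the target length.
#' @param seq Residue string or encoded integer vector.
#' @return Bit score (scalar).
#' @export
viterbi_score <- function(sp, seq) {
  x <- aa_encode(seq)
  if (length(x) < 1L) stop("sequence must have length >= 1")
  lt <- profile_log_transitions(sp)
  cpp_viterbi_score(sp$s, x, lt$mm, lt$mi, lt$md, lt$im, lt$ii, lt$dm, lt$dd,
                    log2(sp$entry), log2(sp$loop), log2(sp$move), sp$nulltr)
}

#' Viterbi filter: saturated signed 16-bit implementation
#'
#' Reduced-precision form of [viterbi_score()] in units of 1/500 bit with an
#' integer offset of 12000, so representable scores span -89.5 to 41.5 bits.
#' Emission words are read from the striped layout of the reduced profile;
#' the along-row delete chain is resolved by a serialized pass per row (the
#' striped-gapped-DP correction). The N/C/J self-loops are scored as zero
#' cost in integer arithmetic, with each emitted residue pre-charged the
#' loop score at quantized precision and the exact flanking total restored
#' in floating point at termination, so filter scores track the
#' full-precision score to within the quantization noise. Saturation at the
#' top of the range sets `overflowed = TRUE`: such a target is certain to
#' pass any reasonable filter threshold.
#'
#' @param rp A `reduced_profile` derived from `sp`.
#' @param sp The matching `search_profile`.
#' @param seq Residue string or encoded integers.
#' @return List with `score` (bits), `overflowed`, `raw`.
#' @export
viterbi_filter <- function(rp, sp, seq) {
  if (rp$M != sp$M) stop("reduced profile does not match search profile")
  x <- aa_encode(seq)
  L <- length(x)
  loop2 <- log2(sp$loop)
  w <- function(v) as.integer(max(-32768, min(32767, round(rp$vit_scale * v))))
  move_w <- w(log2(sp$move))
  ee_w <- w(log2(0.5))
  adj_w <- w(-loop2)   # per-emission charge replacing the zero-cost loops
  tw <- rp$t_words
  res <- cpp_viterbi_filter(rp$vit_words, rp$Q_word, rp$V_word, x,
                            tw$mm, tw$mi, tw$md, tw$im, tw$ii, tw$dm, tw$dd,
                            rp$entry_words, move_w, ee_w, adj_w, rp$vit_base)
  if (res$overflow)
    return(list(score = Inf, overflowed = TRUE, raw = 32767L))
  bits <- (res$raw - rp$vit_base) / rp$vit_scale + L * loop2 - sp$nulltr
  list(score = bits, overflowed = FALSE, raw = res$raw)
}
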