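#' Protein alphabet used throughout the package
#'
#' Twenty canonical amino acids in the fixed internal order
#' `ACDEFGHIKLMNPQRSTVWY`. All degenerate or non-standard residue codes
#' (B, Z, J, U, O, X and anything unrecognized) map to `X`, which scores
#' zero bits (odds ratio 1) at every profile position.
#'
#' @return Character vector of the 20 residue symbols.
#' @export
aa_alphabet <- function() AA_SYMBOLS

AA_SYMBOLS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_X <- 20L  # 0-based internal code for X

# Average protein residue composition (Swiss-Prot derived), normalized to 1.
AA_BACKGROUND_RAW <- c(
  A = 0.0825, C = 0.0137, D = 0.0545, E = 0.0675, F = 0.0386,
  G = 0.0707, H = 0.0227, I = 0.0596, K = 0.0584, L = 0.0966,
  M = 0.0242, N = 0.0406, P = 0.0470, Q = 0.0393, R = 0.0553,
  S = 0.0656, T = 0.0534, V = 0.0687, W = 0.0108, Y = 0.0292)

#' Background (null model) residue frequencies
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aa_background <- function() {
  f <- AA_BACKGROUND_RAW / sum(AA_BACKGROUND_RAW)
  names(f) <- AA_SYMBOLS
  f
}

#' Encode a residue string as internal integer codes
#'
#' Residues are upper-cased, canonical amino acids map to codes `0..19`
#' (order of [aa_alphabet()]), and every degenerate or unknown code maps to
#' `X` (code 20). The number of degeneracy substitutions is returned in the
#' `"n_degenerate"` attribute.
#'
#' @param x Single residue string, or an already-encoded integer vector
#'   (returned unchanged).
#' @return Integer vector of 0-based codes.
#' @export
aa_encode <- function(x) {
  if (is.integer(x)) return(x)
  if (is.numeric(x)) return(as.integer(x))
  stopifnot(is.character(x), length(x) == 1L)
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  code <- match(ch, AA_SYMBOLS) - 1L
  ndeg <- sum(is.na(code))
  code[is.na(code)] <- AA_X
  attr(code, "n_degenerate") <- ndeg
  code
}

#' Decode internal integer codes back to a residue string
#'
#' @param codes Integer vector of 0-based codes (20 = X).
#' @return Single residue string.
#' @export
aa_decode <- function(codes) {
  paste0(c(AA_SYMBOLS, "X")[codes + 1L], collapse = "")
}

#' Map degenerate residue characters in a string to X
#'
#' @param x Residue string.
#' @return Residue string over the canonical alphabet plus `X`.
#' @export
aa_canonicalize <- function(x) aa_decode(aa_encode(x))

#' i.i.d. null model with geometric length distribution
#'
#' The null hypothesis emits residues independently with background
#' frequencies `f` and has a geometric length distribution with loop
#' probability `L/(L+1)`, so that the expected emitted length equals
#' the target length `L`.
#'
#' @param L Target sequence length (>= 1).
#' @param f Background frequencies (default [aa_background()]).
#' @return Object of class `null_model`: list with `f`, `r`, `L`.
#' @export
null_model <- function(L, f = aa_background()) {
  stopifnot(L >= 1)
  if (abs(sum(f) - 1) > 1e-12) stop("background frequencies must sum to 1")
  if (any(f <= 0)) stop("background frequencies must be strictly positive")
  structure(list(f = f, r = L / (L + 1), L = as.numeric(L)),
            class = "null_model")
}

# Total null-model state-transition contribution, bits:
# L residues each taking the r loop, plus the final (1-r) stop.
null_transition_bits <- function(L) {
  r <- L / (L + 1)
  L * log2(r) + log2(1 - r)
}

#' Total flanking-loop score over a length-L target, in bits
#'
#' A typical local alignment assigns nearly all target residues to the N, C
#' and J flanking states, whose self-loop probability is `L/(L+3)`. The total
#' loop contribution `L * log2(L/(L+3))` converges to a constant of about
#' -4.3 bits for large `L`; the reduced-precision MSV filter scores these
#' loops as zero cost during the recursion and restores the asymptotic
#' constant at termination.
#'
#' @param L Target sequence length.
#' @return Total NN/CC/JJ loop contribution in bits.
#' @export
flank_loop_total <- function(L) L * log2(L / (L + 3))

# Asymptotic limit of flank_loop_total: -3 / ln 2 = -4.328 bits.
MSV_LOOP_CONST <- -3 / log(2)

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
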