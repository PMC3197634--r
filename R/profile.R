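#' Build a core profile from a multiple sequence alignment
#'
#' Columns with a gap fraction below 0.5 are classified as consensus (match)
#' columns; a Stockholm `#=GC RF` annotation, when present on the input,
#' overrides this rule (non-gap RF columns are consensus). Match emissions
#' are estimated from observed counts plus background-proportional
#' pseudocounts; transition probabilities are estimated from observed
#' match/insert/delete transitions with a weak prior.
#'
#' With `entropy_target` set, observed emission counts are down-weighted by a
#' scalar effective-sequence-number multiplier (found by bisection) until the
#' mean relative entropy per match position is within 0.01 bits of the
#' target. If the raw counts already give a relative entropy at or below the
#' target, no down-weighting is applied.
#'
#' @param msa An `msa` object from [read_msa()], a character vector of
#'   aligned sequences, or a character matrix (rows = sequences).
#' @param pseudocount_weight Positive scalar; each match column receives
#'   `pseudocount_weight * 20 * f_a` pseudocounts (a +1-style count spread
#'   proportionally over the background).
#' @param entropy_target Desired mean relative entropy in bits/position, or
#'   `NULL` for no entropy weighting.
#' @param name Model name.
#' @param f Background frequencies.
#' @return Object of class `core_profile` with fields `M`, `e` (M x 21
#'   emission matrix, X column zero-width), `t` (M x 7 transition matrix with
#'   columns mm, mi, md, im, ii, dm, dd), `consensus`, `name`, `nseq`.
#' @export
build_from_msa <- function(msa, pseudocount_weight = 1, entropy_target = NULL,
                           name = "query", f = aa_background()) {
  rows <- msa_rows(msa)
  if (length(rows) == 0L) stop("empty alignment")
  mat <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
  mat[mat %in% c(".", "~")] <- "-"
  ncol_aln <- ncol(mat)

  rf <- if (inherits(msa, "msa")) msa$rf else attr(msa, "rf")
  if (!is.null(rf) && nzchar(rf)) {
    rfch <- strsplit(rf, "", fixed = TRUE)[[1]]
    if (length(rfch) != ncol_aln) stop("RF annotation length mismatch")
    is_cons <- !(rfch %in% c(".", "-", "~"))
  } else {
    gapfrac <- colMeans(mat == "-")
    is_cons <- gapfrac < 0.5
  }
  M <- sum(is_cons)
  if (M == 0L) stop("alignment has zero consensus columns")

  # emission counts over consensus columns
  codes <- matrix(0L, nrow(mat), ncol_aln)
  for (j in seq_len(ncol_aln)) {
    cj <- match(mat[, j], AA_SYMBOLS) - 1L
    cj[mat[, j] == "-"] <- NA_integer_
    cj[is.na(cj) & mat[, j] != "-"] <- AA_X
    codes[, j] <- cj
  }
  cons_cols <- which(is_cons)
  counts <- matrix(0, M, 20L)
  for (m in seq_len(M)) {
    cj <- codes[, cons_cols[m]]
    cj <- cj[!is.na(cj) & cj < AA_X]  # X residues carry no emission evidence
    if (length(cj)) {
      tab <- tabulate(cj + 1L, nbins = 20L)
      counts[m, ] <- tab
    }
  }
  alpha <- pseudocount_weight * 20 * f  # background-proportional pseudocounts

  emis_from_nu <- function(nu) {
    e <- sweep(nu * counts, 2, alpha, "+")
    e / rowSums(e)
  }
  mean_re <- function(e20) {
    mean(rowSums(e20 * log2(sweep(e20, 2, f, "/"))))
  }

  nu <- 1
  if (!is.null(entropy_target)) {
    if (mean_re(emis_from_nu(1)) > entropy_target) {
      lo <- 0; hi <- 1
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (mean_re(emis_from_nu(mid)) > entropy_target) hi <- mid else lo <- mid
        if (abs(mean_re(emis_from_nu((lo + hi) / 2)) - entropy_target) < 0.001)
          break
      }
      nu <- (lo + hi) / 2
    }
  }
  e20 <- emis_from_nu(nu)

  # transition counts: classify each residue position of each sequence as
  # match (consensus, residue), delete (consensus, gap) or insert.
  tprior <- c(mm = 18, mi = 1, md = 1, im = 4, ii = 1, dm = 3, dd = 1)
  tc <- matrix(0, M, 7, dimnames = list(NULL, names(tprior)))
  for (si in seq_len(nrow(mat))) {
    state <- "B"; pos <- 0L
    for (j in seq_len(ncol_aln)) {
      gap <- mat[si, j] == "-"
      if (is_cons[j]) {
        new_state <- if (gap) "D" else "M"
        new_pos <- pos + 1L
      } else {
        if (gap) next
        new_state <- "I"; new_pos <- pos
      }
      if (pos >= 1L && pos <= M) {
        key <- paste0(tolower(state), tolower(new_state))
        if (key %in% colnames(tc)) tc[pos, key] <- tc[pos, key] + 1
      }
      state <- new_state; pos <- new_pos
    }
  }
  t7 <- matrix(0, M, 7, dimnames = list(NULL, names(tprior)))
  for (m in seq_len(M)) {
    cnt <- tc[m, ] + tprior / 10
    mrow <- cnt[c("mm", "mi", "md")]; t7[m, c("mm", "mi", "md")] <- mrow / sum(mrow)
    irow <- cnt[c("im", "ii")];       t7[m, c("im", "ii")] <- irow / sum(irow)
    drow <- cnt[c("dm", "dd")];       t7[m, c("dm", "dd")] <- drow / sum(drow)
  }
  t7[M, c("mm", "mi", "md")] <- c(1, 0, 0)
  t7[M, c("im", "ii")] <- c(1, 0)
  t7[M, c("dm", "dd")] <- c(1, 0)

  new_core_profile(e20, t7, name = name,
                   nseq = nrow(mat), entropy_target = entropy_target)
}

# Internal constructor; e20 is M x 20, rows summing to 1.
new_core_profile <- function(e20, t7, name = "model", nseq = NA_integer_,
                             entropy_target = NULL) {
  M <- nrow(e20)
  e <- cbind(e20, X = 0)  # X column is zero-width (scores 0 bits by fiat)
  colnames(e) <- c(AA_SYMBOLS, "X")
  consensus <- paste0(AA_SYMBOLS[max.col(e20)], collapse = "")
  obj <- structure(list(M = M, e = e, t = t7, consensus = consensus,
                        name = name, nseq = nseq,
                        entropy_target = entropy_target),
                   class = "core_profile")
  validate_core_profile(obj)
  obj
}

validate_core_profile <- function(core) {
  stopifnot(core$M >= 1)
  if (any(abs(rowSums(core$e[, 1:20, drop = FALSE]) - 1) > 1e-9))
    stop("emission rows must sum to 1")
  t7 <- core$t
  ok <- abs(rowSums(t7[, c("mm", "mi", "md"), drop = FALSE]) - 1) < 1e-9 &
        abs(rowSums(t7[, c("im", "ii"), drop = FALSE]) - 1) < 1e-9 &
        abs(rowSums(t7[, c("dm", "dd"), drop = FALSE]) - 1) < 1e-9
  if (!all(ok)) stop("transition rows must sum to 1")
  invisible(core)
}

#' @export
print.core_profile <- function(x, ...) {
  cat(sprintf("core_profile '%s': M=%d positions, %s sequences\n",
              x$name, x$M, ifelse(is.na(x$nseq), "?", x$nseq)))
  invisible(x)
}

#' Match state log-odds scores in bits
#'
#' `s_k(a) = log2(e_k(a) / f_a)`; the X column scores 0 at every position.
#'
#' @param core A `core_profile`.
#' @param null A `null_model` (only the background frequencies are used).
#' @return M x 21 numeric matrix in bits.
#' @export
match_scores <- function(core, null = null_model(400)) {
  f <- null$f
  if (any(f <= 0)) stop("zero background frequency")
  s <- log2(sweep(core$e[, 1:20, drop = FALSE], 2, f, "/"))
  cbind(s, X = 0)
}

#' Mean relative entropy of match emissions, bits per position
#'
#' Average over positions of the Kullback-Leibler divergence of the match
#' emission distribution from the background, in bits. This is the
#' "information content per position" that entropy weighting tunes.
#'
#' @inheritParams match_scores
#' @return Non-negative scalar, bits/position.
#' @export
relative_entropy <- function(core, null = null_model(400)) {
  e <- core$e[, 1:20, drop = FALSE]
  lr <- log2(sweep(e, 2, null$f, "/"))
  lr[e == 0] <- 0
  mean(rowSums(e * lr))
}

#' Configure a core profile for searching a target of length L
#'
#' Sets the multihit local alignment parameterization: N/C/J flanking-state
#' loop probability `L/(L+3)` and move probability `3/(L+3)`;
#' `t(E->J) = t(E->C) = 0.5`; and the collapsed uniform-fragment local
#' entry/exit: `t(B->M_k) = 2/(M(M+1))` for every k together with a local
#' exit of probability 1 from every match state. In this collapsed
#' representation of the implicit fragment model, each ungapped entry/exit
#' pair `(i, j)` carries probability `2/(M(M+1))`, so the fragment
#' distribution is uniform and sums to exactly 1 (the marginal probability
#' of entering at position k is `2(M-k+1)/(M(M+1))`). The null model loop
#' is `L/(L+1)`.
#'
#' @param core A `core_profile`.
#' @param L Target sequence length (>= 1).
#' @param f Background frequencies.
#' @return Object of class `search_profile`.
#' @export
configure_length <- function(core, L, f = aa_background()) {
  if (L <= 0) stop("L must be >= 1")
  null <- null_model(L, f)
  M <- core$M
  sp <- structure(list(
    core = core,
    M = M,
    L = as.numeric(L),
    s = match_scores(core, null),
    entry = rep(2 / (M * (M + 1)), M),   # uniform collapsed entry, exit 1
    entry_msv = 2 / (M * (M + 1)),
    loop = L / (L + 3),
    move = 3 / (L + 3),
    tEJ = 0.5, tEC = 0.5,
    null = null,
    nulltr = null_transition_bits(L),
    calibration = NULL
  ), class = "search_profile")
  sp
}

#' Re-set the target length model of a search profile
#'
#' Cheap per-target reconfiguration: only the length-dependent transitions
#' (N/C/J loop/move and the null model) change; match scores and entry
#' distributions are untouched.
#'
#' @param sp A `search_profile`.
#' @param L New target length.
#' @return The reconfigured `search_profile`.
#' @export
profile_set_length <- function(sp, L) {
  if (L <= 0) stop("L must be >= 1")
  sp$L <- as.numeric(L)
  sp$loop <- L / (L + 3)
  sp$move <- 3 / (L + 3)
  sp$null <- null_model(L, sp$null$f)
  sp$nulltr <- null_transition_bits(L)
  sp
}

#' @export
print.search_profile <- function(x, ...) {
  cat(sprintf("search_profile '%s': M=%d, configured L=%g%s\n",
              x$core$name, x$M, x$L,
              if (is.null(x$calibration)) "" else " [calibrated]"))
  invisible(x)
}

# log2 transition vectors for the DP kernels (length M, last entries unused)
profile_log_transitions <- function(sp) {
  t7 <- sp$core$t
  lapply(c(mm = "mm", mi = "mi", md = "md", im = "im", ii = "ii",
           dm = "dm", dd = "dd"),
         function(cn) log2(t7[, cn]))
}

# Extract aligned rows from the accepted msa input forms.
msa_rows <- function(msa) {
  if (inherits(msa, "msa")) return(msa$seqs)
  if (is.matrix(msa)) return(apply(msa, 1, paste0, collapse = ""))
  if (is.character(msa)) {
    if (length(unique(nchar(msa))) > 1L) stop("ragged alignment")
    return(msa)
  }
  stop("unsupported msa input")
}
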