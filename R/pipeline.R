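#' Acceleration pipeline configuration
#'
#' Per-stage P-value thresholds of the staged filter pipeline:
#' MSV filter (`F1`, default 0.02), bias-corrected MSV retest (same `F1`),
#' Viterbi filter (`F2`, default 0.001), Forward (`F3`, default 1e-5).
#' `max_mode` disables all filters and scores every target with Forward.
#'
#' @param F1 MSV filter P-value threshold.
#' @param F2 Viterbi filter P-value threshold.
#' @param F3 Forward P-value threshold.
#' @param bias_filter Apply the composition bias filter after MSV?
#' @param max_mode Disable all filters (full Forward on every target).
#' @param report_evalue_max Report hits with E-value at or below this.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(F1 = 0.02, F2 = 0.001, F3 = 1e-5,
                            bias_filter = TRUE, max_mode = FALSE,
                            report_evalue_max = 10) {
  if (!max_mode && !(F3 <= F2 && F2 <= F1 && F1 <= 1 && F3 > 0))
    stop("thresholds must satisfy 0 < F3 <= F2 <= F1 <= 1")
  structure(list(F1 = F1, F2 = F2, F3 = F3, bias_filter = bias_filter,
                 max_mode = max_mode, report_evalue_max = report_evalue_max),
            class = "pipeline_config")
}

#' Composition bias filter score
#'
#' Recomputes the null score of the target with a two-state HMM: one state
#' emits the average protein background composition, the other the average
#' composition of the query profile's match states, fully connected by four
#' hand-tuned transition probabilities (stay-background 0.99, go-bias 0.01,
#' stay-bias 0.95, go-background 0.05; the chain starts in the background
#' state). The MSV bit score is re-based against this richer null:
#' `corrected = msv_bits - max(0, log2 P(seq | two-state) - log2 P(seq | null))`.
#' The correction can only lower the score (it removes apparent signal that
#' a composition-biased null explains), and it has no effect on the final
#' reported Forward score -- it only makes the MSV stage stricter.
#'
#' @param seq Residue string or encoded integers.
#' @param sp A `search_profile`.
#' @param msv_bits Uncorrected MSV bit score.
#' @return Corrected bit score.
#' @export
bias_filter_score <- function(seq, sp, msv_bits) {
  x <- aa_encode(seq)
  f <- sp$null$f
  q <- colMeans(sp$core$e[, 1:20, drop = FALSE])
  # odds-ratio forward over the two states; background-state emissions
  # cancel against the null, geometric length model shared and cancelled
  odds <- rbind(rep(1, 21), c(q / f, 1))   # row 1 bg, row 2 bias; X -> 1
  Tm <- matrix(c(0.99, 0.01,
                 0.05, 0.95), 2, 2, byrow = TRUE)
  v <- c(1, 0)
  logacc <- 0
  for (i in seq_along(x)) {
    v <- as.vector(v %*% Tm) * odds[, x[i] + 1L]
    if ((i %% 64L) == 0L) {  # keep in floating range
      s <- sum(v); v <- v / s; logacc <- logacc + log2(s)
    }
  }
  correction <- max(0, logacc + log2(sum(v)))
  msv_bits - correction
}

#' Run the acceleration pipeline on one target sequence
#'
#' Stage order: MSV filter (P < F1), bias-corrected MSV retest (P < F1),
#' Viterbi filter (P < F2), Forward (P < F3). The comparison is accepted or
#' rejected in its entirety at each stage based on the P-value of the
#' stage's log-odds score; overflowed filter scores count as passing. The
#' profile's length model is re-set to the target's length before scoring.
#' In `max_mode` every target is scored with full Forward and no filter is
#' applied.
#'
#' @param sp Calibrated `search_profile` (see [calibrate()]).
#' @param rp Matching `reduced_profile`.
#' @param cal `profile_calibration`.
#' @param seq Target residue string or encoded integers.
#' @param cfg `pipeline_config`.
#' @param n_targets Number of targets in the search (for the E-value).
#' @param target Target identifier for the report.
#' @return One-row data frame (a `Hit`): target, L, msv_bits, bias_bits,
#'   vit_bits, fwd_bits, P-values per stage, evalue, stage_reached.
#' @export
run_pipeline <- function(sp, rp, cal, seq, cfg = pipeline_config(),
                         n_targets = 1L, target = "target") {
  h <- pipeline_one(sp, rp, cal, seq, cfg, n_targets, target)
  as.data.frame(h, stringsAsFactors = FALSE)
}

# Internal fast form of run_pipeline returning a plain list.
pipeline_one <- function(sp, rp, cal, seq, cfg, n_targets, target) {
  if (is.null(cal)) stop("profile must be calibrated before pipeline use")
  x <- aa_encode(seq)
  L <- length(x)
  spt <- profile_set_length(sp, L)
  hit <- list(target = target, L = L,
              msv_bits = NA_real_, bias_bits = NA_real_,
              vit_bits = NA_real_, fwd_bits = NA_real_,
              msv_p = NA_real_, bias_p = NA_real_, vit_p = NA_real_,
              fwd_p = NA_real_, evalue = NA_real_,
              stage_reached = "")

  if (!cfg$max_mode) {
    m <- msv_filter(rp, spt, x)
    hit$msv_bits <- m$score
    hit$msv_p <- if (m$overflowed) 0 else gumbel_pvalue(m$score, cal$msv)
    if (!m$overflowed && hit$msv_p >= cfg$F1) {
      hit$stage_reached <- "msv_rejected"
      return(hit)
    }
    if (cfg$bias_filter && !m$overflowed) {
      hit$bias_bits <- bias_filter_score(x, spt, m$score)
      hit$bias_p <- gumbel_pvalue(hit$bias_bits, cal$msv)
      if (hit$bias_p >= cfg$F1) {
        hit$stage_reached <- "bias_rejected"
        return(hit)
      }
    }
    v <- viterbi_filter(rp, spt, x)
    hit$vit_bits <- v$score
    hit$vit_p <- if (v$overflowed) 0 else gumbel_pvalue(v$score, cal$vit)
    if (!v$overflowed && hit$vit_p >= cfg$F2) {
      hit$stage_reached <- "vit_rejected"
      return(hit)
    }
  }
  fw <- forward_score(spt, x, mode = "parser")
  hit$fwd_bits <- fw$score
  hit$fwd_p <- exp_tail_pvalue(fw$score, cal$fwd)
  hit$evalue <- hit$fwd_p * n_targets
  if (!cfg$max_mode && hit$fwd_p >= cfg$F3) {
    hit$stage_reached <- "fwd_rejected"
    return(hit)
  }
  hit$stage_reached <- if (hit$evalue <= cfg$report_evalue_max) "reported"
                       else "fwd_rejected"
  hit
}

#' Search a sequence database with a calibrated profile
#'
#' Runs [run_pipeline()] on every target, collects per-stage counts, and
#' returns reported hits ranked by E-value (`E = Forward P-value x number
#' of targets searched`).
#'
#' @param sp Calibrated `search_profile` (or path to a profile file).
#' @param db Named character vector of sequences, or path to a FASTA file.
#' @param cfg `pipeline_config`.
#' @param rp Optional `reduced_profile` (built if missing).
#' @param cal Optional `profile_calibration` (taken from the profile file /
#'   `sp$calibration` if missing).
#' @return List of class `search_result`: `hits` (reported hits, E-value
#'   ascending), `all` (every comparison), `stats` (stage counts), `n_targets`.
#' @export
search_db <- function(sp, db, cfg = pipeline_config(), rp = NULL, cal = NULL) {
  if (is.character(sp) && length(sp) == 1L) sp <- read_profile(sp)
  if (is.character(db) && length(db) == 1L && file.exists(db))
    db <- read_fasta(db)
  if (length(db) == 0L) stop("empty database")
  if (is.null(names(db))) names(db) <- paste0("seq", seq_along(db))
  if (is.null(cal)) cal <- sp$calibration
  if (is.null(cal)) stop("profile is not calibrated")
  if (is.null(rp)) rp <- reduce_profile(sp)
  n <- length(db)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- pipeline_one(sp, rp, cal, db[[i]], cfg,
                              n_targets = n, target = names(db)[i])
  }
  all <- data.frame(
    target = vapply(rows, function(r) r$target, character(1)),
    L = vapply(rows, function(r) as.integer(r$L), integer(1)),
    msv_bits = vapply(rows, function(r) r$msv_bits, numeric(1)),
    bias_bits = vapply(rows, function(r) r$bias_bits, numeric(1)),
    vit_bits = vapply(rows, function(r) r$vit_bits, numeric(1)),
    fwd_bits = vapply(rows, function(r) r$fwd_bits, numeric(1)),
    msv_p = vapply(rows, function(r) r$msv_p, numeric(1)),
    bias_p = vapply(rows, function(r) r$bias_p, numeric(1)),
    vit_p = vapply(rows, function(r) r$vit_p, numeric(1)),
    fwd_p = vapply(rows, function(r) r$fwd_p, numeric(1)),
    evalue = vapply(rows, function(r) r$evalue, numeric(1)),
    stage_reached = vapply(rows, function(r) r$stage_reached, character(1)),
    stringsAsFactors = FALSE)
  stages <- c("msv_rejected", "bias_rejected", "vit_rejected",
              "fwd_rejected", "reported")
  reached <- factor(all$stage_reached, levels = stages)
  counts <- table(reached)
  stats <- data.frame(
    stage = c("msv", "bias", "viterbi", "forward", "reported"),
    entered = c(n,
                n - counts[["msv_rejected"]],
                n - counts[["msv_rejected"]] - counts[["bias_rejected"]],
                n - counts[["msv_rejected"]] - counts[["bias_rejected"]] -
                  counts[["vit_rejected"]],
                counts[["reported"]]))
  hits <- all[all$stage_reached == "reported", , drop = FALSE]
  hits <- hits[order(hits$evalue), , drop = FALSE]
  structure(list(hits = hits, all = all, stats = stats, n_targets = n),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("search_result: %d targets, %d reported hits\n",
              x$n_targets, nrow(x$hits)))
  print(x$stats, row.names = FALSE)
  invisible(x)
}
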