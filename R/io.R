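#' Read a FASTA sequence file
#'
#' Residues are canonicalized: degenerate codes (B, Z, J, U, O, X, ...) map
#' to X, and the number of substitutions is reported with a message.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (names = first header token,
#'   full headers in the `"descriptions"` attribute).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (!length(recs)) stop("empty FASTA file: ", path)
  seqs <- vapply(recs, function(r) as.character(r)[1], character(1))
  ndeg <- 0L
  out <- vapply(seqs, function(s) {
    code <- aa_encode(s)
    ndeg <<- ndeg + attr(code, "n_degenerate")
    aa_decode(code)
  }, character(1))
  names(out) <- names(recs)
  attr(out, "descriptions") <- vapply(recs, function(r) {
    a <- attr(r, "Annot"); if (is.null(a)) "" else sub("^>", "", a)
  }, character(1))
  if (ndeg > 0L)
    message(sprintf("read_fasta: mapped %d degenerate residues to X", ndeg))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = 60)
  invisible(path)
}

#' Read a multiple sequence alignment
#'
#' Supports Stockholm (single- or multi-block) and aligned FASTA. Gap
#' characters `-`, `.`, `~` are normalized to `-`; residue case is
#' preserved. A Stockholm `#=GC RF` line, when present, is retained and
#' overrides the gap-fraction consensus rule in [build_from_msa()].
#'
#' @param path Alignment file.
#' @param format `"auto"` (sniffed), `"stockholm"` or `"afa"`.
#' @return Object of class `msa`: list with `seqs` (named, equal-length
#'   aligned rows) and `rf` (reference annotation or `NULL`).
#' @export
read_msa <- function(path, format = c("auto", "stockholm", "afa")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "afa"
  }
  if (format == "afa") {
    recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                               forceDNAtolower = FALSE)
    seqs <- vapply(recs, function(r) as.character(r)[1], character(1))
    names(seqs) <- names(recs)
    rf <- NULL
  } else {
    lines <- readLines(path)
    if (!length(lines) || !grepl("^# STOCKHOLM", lines[1]))
      stop("not a Stockholm file (missing header): ", path)
    seqs <- character(0); rf <- ""
    for (ln in lines[-1]) {
      if (grepl("^\\s*$", ln) || ln == "//") next
      if (startsWith(ln, "#")) {
        if (grepl("^#=GC\\s+RF\\s+", ln))
          rf <- paste0(rf, sub("^#=GC\\s+RF\\s+", "", ln))
        next
      }
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) != 2L) stop("malformed Stockholm sequence line: ", ln)
      nm <- parts[1]
      seqs[nm] <- paste0(if (nm %in% names(seqs)) seqs[[nm]] else "", parts[2])
    }
    if (!length(seqs)) stop("Stockholm file contains no sequences: ", path)
    if (!nzchar(rf)) rf <- NULL
  }
  seqs <- vapply(seqs, function(s) chartr(".~", "--", s), character(1))
  if (length(unique(nchar(seqs))) != 1L) stop("ragged alignment in ", path)
  if (!is.null(rf) && nchar(rf) != nchar(seqs[1]))
    stop("RF annotation length mismatch in ", path)
  structure(list(seqs = seqs, rf = rf), class = "msa")
}

#' Write an alignment in Stockholm format
#'
#' @param msa An `msa` object or named character vector of aligned rows.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(msa, path) {
  if (inherits(msa, "msa")) { seqs <- msa$seqs; rf <- msa$rf }
  else { seqs <- msa; rf <- attr(msa, "rf") }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  w <- max(nchar(names(seqs)), nchar("#=GC RF"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  for (i in seq_along(seqs))
    writeLines(sprintf("%-*s %s", w, names(seqs)[i], seqs[[i]]), con)
  if (!is.null(rf))
    writeLines(sprintf("%-*s %s", w, "#=GC RF", rf), con)
  writeLines("//", con)
  invisible(path)
}

PROFILE_FORMAT_VERSION <- "msvscan-profile 1.0"

# Simple numeric checksum over the stored probabilities.
profile_checksum <- function(core) {
  v <- c(core$e[, 1:20], core$t)
  sprintf("%.6f", sum(v * seq_along(v)) %% 1e6)
}

#' Write a profile to the package's text format
#'
#' A documented key-value / table format carrying the model name, length,
#' alphabet, background, per-position emission and transition
#' probabilities, consensus, and (when present) calibration parameters.
#' Probabilities are written in full precision so that a round trip is
#' exact to 1e-15; scores are re-derived on load, never re-quantized.
#'
#' @param sp A `search_profile` (calibration taken from `sp$calibration`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(sp, path) {
  core <- sp$core
  con <- file(path, "w"); on.exit(close(con))
  num <- function(x) sprintf("%.17g", x)
  writeLines(PROFILE_FORMAT_VERSION, con)
  writeLines(paste("NAME", core$name), con)
  writeLines(paste("M", core$M), con)
  writeLines(paste("ALPH", paste0(AA_SYMBOLS, collapse = "")), con)
  writeLines(paste("CHECKSUM", profile_checksum(core)), con)
  writeLines(paste("BG", paste(num(sp$null$f), collapse = " ")), con)
  if (!is.null(sp$calibration)) {
    cal <- sp$calibration
    writeLines(paste("CAL_MSV", num(cal$msv$mu), num(cal$msv$lambda)), con)
    writeLines(paste("CAL_VIT", num(cal$vit$mu), num(cal$vit$lambda)), con)
    writeLines(paste("CAL_FWD", num(cal$fwd$tau), num(cal$fwd$lambda),
                     num(cal$fwd$tailmass)), con)
  }
  writeLines("EMISSIONS", con)
  for (k in seq_len(core$M))
    writeLines(paste(num(core$e[k, 1:20]), collapse = " "), con)
  writeLines("TRANSITIONS mm mi md im ii dm dd", con)
  for (k in seq_len(core$M))
    writeLines(paste(num(core$t[k, ]), collapse = " "), con)
  writeLines(paste("CONSENSUS", core$consensus), con)
  writeLines("END", con)
  invisible(path)
}

#' Read a profile written by [write_profile()]
#'
#' @param path Profile file.
#' @param L Target length to configure (default 400; reconfigure per target
#'   with [profile_set_length()]).
#' @return A `search_profile` with any stored calibration attached.
#' @export
read_profile <- function(path, L = 400) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines) || lines[1] != PROFILE_FORMAT_VERSION)
    stop("not a ", PROFILE_FORMAT_VERSION, " file: ", path)
  need <- function(section) {
    stop("truncated profile file: missing ", section, " section in ", path)
  }
  kv <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^", key, " "), "", ln[1])
  }
  name <- kv("NAME"); if (is.null(name)) need("NAME")
  M <- as.integer(kv("M")); if (is.null(M) || is.na(M)) need("M")
  bg <- kv("BG"); if (is.null(bg)) need("BG")
  f <- as.numeric(strsplit(bg, " ")[[1]])
  ei <- match("EMISSIONS", lines); if (is.na(ei)) need("EMISSIONS")
  ti <- grep("^TRANSITIONS", lines); if (!length(ti)) need("TRANSITIONS")
  if (is.na(match("END", lines))) need("END")
  if (ei + M > length(lines) || ti[1] + M > length(lines))
    need("complete emission/transition table")
  e20 <- do.call(rbind, lapply(lines[(ei + 1):(ei + M)], function(l)
    as.numeric(strsplit(l, " ")[[1]])))
  t7 <- do.call(rbind, lapply(lines[(ti[1] + 1):(ti[1] + M)], function(l)
    as.numeric(strsplit(l, " ")[[1]])))
  colnames(t7) <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
  core <- new_core_profile(e20, t7, name = name)
  stored_sum <- kv("CHECKSUM")
  if (!is.null(stored_sum) && stored_sum != profile_checksum(core))
    stop("profile checksum mismatch in ", path)
  names(f) <- AA_SYMBOLS
  sp <- configure_length(core, L, f = f)
  cm <- kv("CAL_MSV"); cv <- kv("CAL_VIT"); cf <- kv("CAL_FWD")
  if (!is.null(cm) && !is.null(cv) && !is.null(cf)) {
    pm <- as.numeric(strsplit(cm, " ")[[1]])
    pv <- as.numeric(strsplit(cv, " ")[[1]])
    pf <- as.numeric(strsplit(cf, " ")[[1]])
    sp$calibration <- structure(list(
      msv = list(mu = pm[1], lambda = pm[2]),
      vit = list(mu = pv[1], lambda = pv[2]),
      fwd = list(tau = pf[1], lambda = pf[2], tailmass = pf[3]),
      n = NA_integer_, Lcal = NA_integer_, seed = NA_integer_),
      class = "profile_calibration")
  }
  sp
}

#' Write search hits as a tab-separated report
#'
#' One row per reported hit (bit scores to 0.1, P/E-values in scientific
#' notation with two significant digits) under a commented header, followed
#' by a stats footer with the per-stage counts and run metadata.
#'
#' @param res A `search_result` from [search_db()].
#' @param path Output file.
#' @param seed Seed used for the run (recorded in the footer).
#' @return `path`, invisibly.
#' @export
write_hits <- function(res, path, seed = NA) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# msvscan search results", con)
  writeLines("# target\tL\tmsv_bits\tvit_bits\tfwd_bits\tmsv_p\tvit_p\tfwd_p\tevalue\tstage", con)
  h <- res$hits
  for (i in seq_len(nrow(h))) {
    writeLines(sprintf("%s\t%d\t%.1f\t%.1f\t%.1f\t%.1e\t%.1e\t%.1e\t%.1e\t%s",
                       h$target[i], h$L[i],
                       h$msv_bits[i], h$vit_bits[i], h$fwd_bits[i],
                       h$msv_p[i], h$vit_p[i], h$fwd_p[i], h$evalue[i],
                       h$stage_reached[i]), con)
  }
  writeLines(sprintf("# targets searched: %d", res$n_targets), con)
  for (i in seq_len(nrow(res$stats)))
    writeLines(sprintf("# stage %s: entered %d", res$stats$stage[i],
                       res$stats$entered[i]), con)
  writeLines(sprintf("# seed: %s", seed), con)
  invisible(path)
}
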