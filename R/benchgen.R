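#' Sample an i.i.d. random protein sequence
#'
#' Residues are drawn independently from the given background composition
#' (default: average protein residue frequencies).
#'
#' @param L Sequence length (>= 1).
#' @param freqs Residue frequencies (length 20, positive, summing to 1).
#' @param seed Optional integer seed (deterministic output).
#' @param as_string Return a string (default) or encoded integers.
#' @return Residue string, or 0-based integer codes.
#' @export
sample_iid <- function(L, freqs = aa_background(), seed = NULL,
                       as_string = TRUE) {
  stopifnot(L >= 1)
  if (length(freqs) != 20L || any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-9)
    stop("invalid frequencies")
  x <- with_seed(seed, sample.int(20L, L, replace = TRUE, prob = freqs) - 1L)
  if (as_string) aa_decode(x) else x
}

#' Shuffle a sequence preserving composition
#'
#' Modes: `"mono"` permutes residues (preserves 0th-order composition
#' exactly); `"di"` preserves the di-residue count matrix exactly using a
#' randomized Euler-path walk over the di-residue multigraph; `"reverse"`
#' reverses the sequence.
#'
#' @param seq Residue string.
#' @param mode One of `"mono"`, `"di"`, `"reverse"`.
#' @param seed Optional integer seed.
#' @return Shuffled residue string.
#' @export
shuffle_seq <- function(seq, mode = c("mono", "di", "reverse"), seed = NULL) {
  mode <- match.arg(mode)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(ch) == 0L) stop("empty sequence")
  if (mode == "reverse") return(paste0(rev(ch), collapse = ""))
  if (mode == "mono")
    return(with_seed(seed, paste0(sample(ch), collapse = "")))
  # di-residue shuffle
  if (length(ch) < 2L) stop("di-residue shuffle needs length >= 2")
  with_seed(seed, {
    verts <- unique(ch)
    nv <- length(verts)
    vi <- match(ch, verts)
    # adjacency lists of outgoing edges (multigraph), randomly ordered
    out <- vector("list", nv)
    for (v in seq_len(nv)) out[[v]] <- integer(0)
    for (i in seq_len(length(vi) - 1L))
      out[[vi[i]]] <- c(out[[vi[i]]], vi[i + 1L])
    out <- lapply(out, function(e) if (length(e) > 1L) sample(e) else e)
    ptr <- rep(1L, nv)
    # Hierholzer from the start vertex; always finds the Euler path
    stack <- vi[1L]; trail <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]
      if (ptr[v] <= length(out[[v]])) {
        w <- out[[v]][ptr[v]]
        ptr[v] <- ptr[v] + 1L
        stack <- c(stack, w)
      } else {
        trail <- c(trail, v)
        stack <- stack[-length(stack)]
      }
    }
    paste0(verts[rev(trail)], collapse = "")
  })
}

#' Percent identity of an aligned sequence pair
#'
#' Number of identical aligned residues divided by the length of the
#' shorter (unaligned) sequence.
#'
#' @param a,b Aligned rows of equal length (gaps `-`, `.` or `~`).
#' @return Fraction in [0, 1].
#' @export
percent_identity <- function(a, b) {
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) stop("aligned rows differ in length")
  gap <- c("-", ".", "~")
  na <- sum(!(ca %in% gap)); nb <- sum(!(cb %in% gap))
  if (na == 0L || nb == 0L) stop("zero-length sequence")
  idn <- sum(ca == cb & !(ca %in% gap))
  idn / min(na, nb)
}

#' Single-linkage clustering at an identity threshold
#'
#' Links every pair at or above the threshold and returns connected
#' components: between any two clusters there is no pair at or above the
#' threshold.
#'
#' @param n Number of items, or a symmetric identity matrix.
#' @param pid Function `(i, j) -> identity`, or missing when `n` is a matrix.
#' @param threshold Linking threshold.
#' @return Integer vector of cluster labels (1-based, by discovery order).
#' @export
single_linkage <- function(n, pid, threshold) {
  if (is.matrix(n)) {
    m <- n; n <- nrow(m)
    pid <- function(i, j) m[i, j]
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(0, n - 1L))) for (j in (i + 1L):n) {
    if (pid(i, j) >= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Generate one nonhomologous segment of length n.
make_neg_segment <- function(n, negmode, seqdb, freqs) {
  if (n == 0L) return("")
  if (negmode == "iid" || is.null(seqdb))
    return(sample_iid(n, freqs))
  # pick a database segment of the right length, then shuffle/reverse it
  long_enough <- which(nchar(seqdb) >= n)
  if (!length(long_enough)) return(sample_iid(n, freqs))
  src <- seqdb[[sample(long_enough, 1L)]]
  start <- sample.int(nchar(src) - n + 1L, 1L)
  seg <- substr(src, start, start + n - 1L)
  if (n == 1L && negmode == "di") return(seg)
  switch(negmode,
         mono = shuffle_seq(seg, "mono"),
         di = shuffle_seq(seg, "di"),
         reverse = shuffle_seq(seg, "reverse"),
         stop("unknown negmode"))
}

# Sample a total length from the database length distribution (or a
# log-normal surrogate), conditional on being >= minlen. Rejection sampling
# with a capped number of tries.
sample_total_length <- function(minlen, seqdb, surrogate_median = 350,
                                surrogate_sdlog = 0.6, max_tries = 1000L) {
  draw <- if (!is.null(seqdb) && length(seqdb)) {
    lens <- nchar(seqdb)
    function() lens[sample.int(length(lens), 1L)]
  } else {
    function() max(1L, round(stats::rlnorm(1, log(surrogate_median),
                                           surrogate_sdlog)))
  }
  for (t in seq_len(max_tries)) {
    l <- draw()
    if (l >= minlen) return(as.integer(l))
  }
  as.integer(minlen + stats::rgeom(1, 1 / 50))
}

#' Construct a sensitivity/specificity benchmark (profmark procedure)
#'
#' From trusted alignments and a source sequence database, builds query
#' alignments, remote true-test sequences and matched decoys:
#'
#' 1. degenerate residues are converted to X;
#' 2. sequence fragments (unaligned length below `frag_frac` of the
#'    alignment's mean) are removed;
#' 3. sequences are single-linkage clustered at `qthresh` identity; if only
#'    one cluster results the alignment is excluded;
#' 4. the largest cluster becomes the query alignment;
#' 5. the remainder is clustered at `tthresh`; with fewer than two clusters
#'    the alignment is excluded; one random sequence per cluster becomes a
#'    true test domain (so no test domain is over `qthresh` identical to
#'    any query sequence, nor over `tthresh` identical to another);
#' 6. true test sequences embed `ndomains` (1 or 2) test domains at random
#'    positions in nonhomologous context; total length is sampled from the
#'    database length distribution conditional on fitting the domains, so a
#'    positive consists of 3 or 5 segments;
#' 7. each decoy copies the segment-length vector of a random positive and
#'    fills every segment with nonhomologous sequence.
#'
#' @param msas Named list of alignments ([read_msa()] objects, character
#'   vectors, or matrices).
#' @param seqdb Named character vector of sequences used for length sampling
#'   and as shuffle source; `NULL` uses a log-normal length surrogate with
#'   i.i.d. segments.
#' @param frag_frac Fragment threshold (default 0.7).
#' @param qthresh Query/test identity threshold (default 0.25).
#' @param tthresh Test/test identity threshold (default 0.5).
#' @param ndomains Embedded domains per positive, 1 or 2.
#' @param negmode Nonhomologous segment generator: `"mono"`, `"iid"`,
#'   `"di"`, `"reverse"`.
#' @param n_neg Number of decoys.
#' @param seed Integer seed.
#' @return Object of class `benchmark_set`: `queries` (list of query
#'   alignments), `positives`, `decoys` (named character vectors), `truth`
#'   (data frame: target, query, label), `domains` (coordinates of embedded
#'   domains), `params`, plus the retained alignment rows needed for post
#'   hoc identity verification.
#' @export
profmark_build <- function(msas, seqdb = NULL, frag_frac = 0.7,
                           qthresh = 0.25, tthresh = 0.5, ndomains = 1L,
                           negmode = c("mono", "iid", "di", "reverse"),
                           n_neg = 200L, seed = 1L) {
  negmode <- match.arg(negmode)
  if (!ndomains %in% c(1L, 2L)) stop("ndomains must be 1 or 2")
  if (is.null(names(msas))) names(msas) <- paste0("msa", seq_along(msas))
  freqs <- aa_background()
  with_seed(seed, {
    queries <- list(); verify <- list()
    positives <- character(0); domains <- list()
    pos_seglens <- list()
    for (qname in names(msas)) {
      rows <- msa_rows(msas[[qname]])
      rows <- vapply(rows, function(r) {
        ch <- strsplit(r, "", fixed = TRUE)[[1]]
        isgap <- ch %in% c("-", ".", "~")
        ch[isgap] <- "-"
        ch[!isgap] <- strsplit(aa_canonicalize(paste0(ch[!isgap], collapse = "")),
                               "", fixed = TRUE)[[1]]
        paste0(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
      if (is.null(names(rows)) || !length(names(rows)))
        names(rows) <- paste0(qname, "_s", seq_along(rows))

      # step 2: remove fragments
      unal <- nchar(gsub("-", "", rows, fixed = TRUE))
      rows <- rows[unal >= frag_frac * mean(unal)]
      if (length(rows) < 3L) next

      # step 3: cluster at qthresh
      cl <- single_linkage(length(rows),
                           function(i, j) percent_identity(rows[i], rows[j]),
                           qthresh)
      if (max(cl) < 2L) next
      qcl <- which.max(tabulate(cl))
      qrows <- rows[cl == qcl]
      rest <- rows[cl != qcl]
      if (length(rest) < 2L) next

      # step 5: cluster remainder at tthresh, one domain per cluster
      cl2 <- single_linkage(length(rest),
                            function(i, j) percent_identity(rest[i], rest[j]),
                            tthresh)
      if (max(cl2) < 2L) next
      dom_rows <- vapply(seq_len(max(cl2)), function(g) {
        cand <- which(cl2 == g)
        rest[cand[sample.int(length(cand), 1L)]]
      }, character(1))
      doms <- gsub("-", "", dom_rows, fixed = TRUE)

      queries[[qname]] <- qrows
      verify[[qname]] <- list(query_rows = qrows, dom_rows = dom_rows)

      # step 6: embed domains
      groups <- if (ndomains == 1L) as.list(seq_along(doms))
                else split(seq_along(doms),
                           ceiling(seq_along(doms) / 2))
      for (g in groups) {
        if (ndomains == 2L && length(g) < 2L) next
        dlen <- nchar(doms[g])
        total <- sample_total_length(sum(dlen), seqdb)
        extra <- total - sum(dlen)
        ncuts <- length(g) + 1L
        cuts <- sort(sample.int(extra + 1L, ncuts - 1L, replace = TRUE) - 1L)
        seglens <- diff(c(0L, cuts, extra))
        parts <- character(0); coords <- NULL; pos <- 0L
        seg_vec <- integer(0)
        for (d in seq_along(g)) {
          nh <- make_neg_segment(seglens[d], negmode, seqdb, freqs)
          parts <- c(parts, nh, doms[g[d]])
          seg_vec <- c(seg_vec, seglens[d], dlen[d])
          pos <- pos + seglens[d]
          coords <- rbind(coords,
                          data.frame(start = pos + 1L, end = pos + dlen[d]))
          pos <- pos + dlen[d]
        }
        nh <- make_neg_segment(seglens[length(seglens)], negmode, seqdb, freqs)
        parts <- c(parts, nh)
        seg_vec <- c(seg_vec, seglens[length(seglens)])
        tid <- sprintf("%s_pos%d", qname, length(domains) + 1L)
        positives[tid] <- paste0(parts, collapse = "")
        coords$target <- tid; coords$query <- qname
        domains[[tid]] <- coords
        pos_seglens[[tid]] <- seg_vec
      }
    }
    if (!length(queries)) stop("no usable alignments")

    decoys <- character(0)
    for (i in seq_len(n_neg)) {
      seg_vec <- pos_seglens[[sample.int(length(pos_seglens), 1L)]]
      segs <- vapply(seg_vec, make_neg_segment, character(1),
                     negmode = negmode, seqdb = seqdb, freqs = freqs)
      decoys[sprintf("decoy%d", i)] <- paste0(segs, collapse = "")
    }
    truth <- rbind(
      data.frame(target = names(positives),
                 query = vapply(domains, function(d) d$query[1], character(1)),
                 label = "positive", stringsAsFactors = FALSE),
      data.frame(target = names(decoys), query = NA_character_,
                 label = "decoy", stringsAsFactors = FALSE))
    structure(list(queries = queries, positives = positives, decoys = decoys,
                   truth = truth, domains = do.call(rbind, domains),
                   verify = verify,
                   params = list(frag_frac = frag_frac, qthresh = qthresh,
                                 tthresh = tthresh, ndomains = ndomains,
                                 negmode = negmode, n_neg = n_neg,
                                 seed = seed)),
              class = "benchmark_set")
  })
}

#' Re-verify the identity guarantees of a built benchmark
#'
#' Post hoc check of the construction invariants: no test domain is over
#' `qthresh` identical to any query-alignment sequence; no two test domains
#' from the same alignment are over `tthresh` identical; every positive has
#' 3 or 5 segments with the recorded domain coordinates matching the
#' embedded domains.
#'
#' @param bs A `benchmark_set`.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
profmark_verify <- function(bs) {
  p <- bs$params
  for (qname in names(bs$verify)) {
    v <- bs$verify[[qname]]
    for (dr in v$dom_rows) {
      for (qr in v$query_rows)
        if (percent_identity(dr, qr) >= p$qthresh)
          stop("test domain exceeds query identity threshold in ", qname)
    }
    if (length(v$dom_rows) > 1L) {
      for (i in seq_len(length(v$dom_rows) - 1L))
        for (j in (i + 1L):length(v$dom_rows))
          if (percent_identity(v$dom_rows[i], v$dom_rows[j]) >= p$tthresh)
            stop("test domains exceed mutual identity threshold in ", qname)
    }
  }
  for (tid in names(bs$positives)) {
    d <- bs$domains[bs$domains$target == tid, , drop = FALSE]
    if (nrow(d) != p$ndomains) stop("wrong domain count in ", tid)
    for (r in seq_len(nrow(d))) {
      emb <- substr(bs$positives[[tid]], d$start[r], d$end[r])
      dr <- gsub("-", "", bs$verify[[d$query[r]]]$dom_rows, fixed = TRUE)
      if (!emb %in% dr) stop("embedded domain does not match in ", tid)
    }
  }
  invisible(TRUE)
}

#' Sample a synthetic core profile with a target relative entropy
#'
#' Emission distributions are drawn per position from a sharp Dirichlet
#' around the background and then blended toward the background
#' (`e' = w e + (1-w) f`, with `w` found by bisection) until the mean
#' relative entropy hits `H` within 0.005 bits. Transitions are fixed to
#' typical values (match continuation 0.96, insert extension 0.2, delete
#' extension 0.3). Used as the study condition for calibration and
#' roundoff experiments.
#'
#' @param M Model length.
#' @param H Target relative entropy, bits/position; `NULL` keeps the raw
#'   Dirichlet draw (no blending).
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration (smaller = sharper).
#' @param name Model name.
#' @return A `core_profile`.
#' @export
sample_profile <- function(M, H = 0.6, seed = 1L, concentration = 0.3,
                           name = sprintf("synthM%d", M)) {
  f <- aa_background()
  e <- with_seed(seed, {
    g <- matrix(stats::rgamma(M * 20L, shape = concentration * 20 * f,
                              rate = 1), M, 20L, byrow = TRUE)
    g / rowSums(g)
  })
  blend_re <- function(w) {
    eb <- w * e + (1 - w) * matrix(f, M, 20L, byrow = TRUE)
    mean(rowSums(eb * log2(sweep(eb, 2, f, "/"))))
  }
  if (is.null(H)) {
    t7 <- matrix(rep(c(0.96, 0.02, 0.02, 0.8, 0.2, 0.7, 0.3), each = M), M, 7)
    colnames(t7) <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
    t7[M, ] <- c(1, 0, 0, 1, 0, 1, 0)
    return(new_core_profile(e, t7, name = name))
  }
  if (blend_re(1) < H)
    stop("sampled emissions too close to background for requested H; ",
         "lower the concentration")
  lo <- 0; hi <- 1
  for (it in 1:50) {
    mid <- (lo + hi) / 2
    if (blend_re(mid) > H) hi <- mid else lo <- mid
    if (abs(blend_re((lo + hi) / 2) - H) < 0.005) break
  }
  w <- (lo + hi) / 2
  e <- w * e + (1 - w) * matrix(f, M, 20L, byrow = TRUE)
  t7 <- matrix(rep(c(0.96, 0.02, 0.02, 0.8, 0.2, 0.7, 0.3), each = M), M, 7)
  colnames(t7) <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
  t7[M, ] <- c(1, 0, 0, 1, 0, 1, 0)
  new_core_profile(e, t7, name = name)
}

#' Sample an ungapped alignment from a core profile
#'
#' Draws `nseq` sequences from the match emissions of a core profile (one
#' residue per consensus column, no indels), giving a synthetic trusted
#' alignment for builder and benchmark tests.
#'
#' @param core A `core_profile`.
#' @param nseq Number of sequences.
#' @param seed Integer seed.
#' @return Named character vector of aligned rows.
#' @export
sample_msa <- function(core, nseq, seed = 1L) {
  with_seed(seed, {
    rows <- vapply(seq_len(nseq), function(i) {
      paste0(vapply(seq_len(core$M), function(k) {
        AA_SYMBOLS[sample.int(20L, 1L, prob = core$e[k, 1:20])]
      }, character(1)), collapse = "")
    }, character(1))
    names(rows) <- paste0(core$name, "_s", seq_len(nseq))
    rows
  })
}

#' Observed filter pass fraction on random sequences
#'
#' Scores `n` i.i.d. random length-`L` sequences with the MSV filter and
#' reports the fraction whose calibrated P-value falls below `Pthr`. If
#' P-values are accurate the fraction matches `Pthr`, and it should do so
#' within about two-fold for almost all models.
#'
#' @param sp Calibrated `search_profile`.
#' @param rp Matching `reduced_profile`.
#' @param cal `profile_calibration`.
#' @param Pthr P-value threshold (default 0.02).
#' @param n Number of random sequences (>= 100).
#' @param L Sequence length.
#' @param seed Integer seed.
#' @return Observed pass fraction.
#' @export
filter_fraction_experiment <- function(sp, rp, cal, Pthr = 0.02, n = 50000L,
                                       L = 400L, seed = 1L) {
  if (n < 100) stop("need n >= 100")
  spt <- profile_set_length(sp, L)
  f <- spt$null$f
  with_seed(seed, {
    npass <- 0L
    for (i in seq_len(n)) {
      x <- sample.int(20L, L, replace = TRUE, prob = f) - 1L
      m <- msv_filter(rp, spt, x)
      p <- if (m$overflowed) 0 else gumbel_pvalue(m$score, cal$msv)
      if (p < Pthr) npass <- npass + 1L
    }
    npass / n
  })
}

#' Reduced-precision roundoff experiment
#'
#' Scores `n` random length-`L` sequences with both the byte MSV filter and
#' the full-precision MSV and summarizes the per-sequence difference
#' (filter minus full precision) in bits.
#'
#' @param sp A `search_profile`.
#' @param rp Matching `reduced_profile`.
#' @param n Number of sequences (>= 100).
#' @param L Sequence length.
#' @param seed Integer seed.
#' @return List with `mean`, `sd`, `max_abs`, and the vector of differences.
#' @export
roundoff_experiment <- function(sp, rp, n = 1000L, L = 400L, seed = 1L) {
  if (n < 100) stop("need n >= 100")
  spt <- profile_set_length(sp, L)
  f <- spt$null$f
  with_seed(seed, {
    diffs <- numeric(n)
    for (i in seq_len(n)) {
      x <- sample.int(20L, L, replace = TRUE, prob = f) - 1L
      m <- msv_filter(rp, spt, x)
      if (m$overflowed) { diffs[i] <- NA; next }
      diffs[i] <- m$score - msv_score(spt, x)
    }
    diffs <- diffs[!is.na(diffs)]
    list(mean = mean(diffs), sd = stats::sd(diffs),
         max_abs = max(abs(diffs)), diffs = diffs)
  })
}

#' ROC points for a benchmark search
#'
#' Merges ranked hits against the benchmark truth table and reports, at each
#' threshold in the E-value ranking, the fraction of true positives found
#' versus the number of false positives per query.
#'
#' @param truth Truth table from a `benchmark_set` (`target`, `label`).
#' @param hits Data frame with `target` and `evalue` columns (all queries
#'   merged).
#' @param n_queries Number of queries searched.
#' @return Data frame with `evalue`, `tp_fraction`, `fp_per_query`.
#' @export
bench_roc <- function(truth, hits, n_queries = 1L) {
  hits <- hits[order(hits$evalue), , drop = FALSE]
  lab <- truth$label[match(hits$target, truth$target)]
  npos <- sum(truth$label == "positive")
  tp <- cumsum(lab == "positive")
  fp <- cumsum(lab != "positive")
  data.frame(evalue = hits$evalue, tp_fraction = tp / npos,
             fp_per_query = fp / n_queries)
}
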