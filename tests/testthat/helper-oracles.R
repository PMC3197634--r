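# Independent oracles used by the test suite. These deliberately avoid the
# package's row-DP structure: the path enumerator is a top-down recursion
# over explicit state sequences; the clustering oracle is a transitive
# closure over the full identity matrix.

# Enumerate all complete paths of the multihit local profile over a
# sequence, combining path log2-scores with `max` (Viterbi) or log-sum
# (Forward). Exponential; use only on tiny instances.
enumerate_paths_score <- function(sp, seq, op = c("max", "sum")) {
  op <- match.arg(op)
  x <- aa_encode(seq)
  L <- length(x); M <- sp$M
  s <- sp$s
  t7 <- sp$core$t
  lt <- list(mm = log2(t7[, "mm"]), mi = log2(t7[, "mi"]),
             md = log2(t7[, "md"]), im = log2(t7[, "im"]),
             ii = log2(t7[, "ii"]), dm = log2(t7[, "dm"]),
             dd = log2(t7[, "dd"]))
  loop2 <- log2(sp$loop); move2 <- log2(sp$move)
  ent2 <- log2(sp$entry); lee <- log2(0.5)
  comb <- if (op == "max") function(v) if (length(v)) max(v) else -Inf
          else function(v) {
            v <- v[v > -Inf]
            if (!length(v)) return(-Inf)
            m <- max(v); m + log2(sum(2^(v - m)))
          }
  rec <- function(state, i, k = 0L) {
    if (state == "N") {
      opts <- move2 + rec("B", i)
      if (i < L) opts <- c(opts, loop2 + rec("N", i + 1L))
      return(comb(opts))
    }
    if (state == "B") {
      if (i >= L) return(-Inf)
      opts <- vapply(seq_len(M), function(kk)
        ent2[kk] + s[kk, x[i + 1L] + 1L] + rec("M", i + 1L, kk), numeric(1))
      return(comb(opts))
    }
    if (state == "M") {
      opts <- rec("E", i)  # local exit, probability 1
      if (k < M) {
        if (i < L)
          opts <- c(opts,
                    lt$mm[k] + s[k + 1L, x[i + 1L] + 1L] + rec("M", i + 1L, k + 1L),
                    lt$mi[k] + rec("I", i + 1L, k))
        opts <- c(opts, lt$md[k] + rec("D", i, k + 1L))
      }
      return(comb(opts))
    }
    if (state == "I") {
      if (i > L) return(-Inf)
      opts <- numeric(0)
      if (i < L && k < M)
        opts <- c(opts, lt$im[k] + s[k + 1L, x[i + 1L] + 1L] + rec("M", i + 1L, k + 1L))
      if (i < L) opts <- c(opts, lt$ii[k] + rec("I", i + 1L, k))
      return(comb(opts))
    }
    if (state == "D") {
      opts <- numeric(0)
      if (k < M) {
        if (i < L)
          opts <- c(opts, lt$dm[k] + s[k + 1L, x[i + 1L] + 1L] + rec("M", i + 1L, k + 1L))
        opts <- c(opts, lt$dd[k] + rec("D", i, k + 1L))
      }
      return(comb(opts))
    }
    if (state == "E") return(comb(c(lee + rec("J", i), lee + rec("C", i))))
    if (state == "J") {
      opts <- move2 + rec("B", i)
      if (i < L) opts <- c(opts, loop2 + rec("J", i + 1L))
      return(comb(opts))
    }
    if (state == "C") {
      if (i == L) return(move2)  # C -> T
      return(loop2 + rec("C", i + 1L))
    }
    stop("unknown state")
  }
  unname(rec("N", 0L) - sp$nulltr)
}

# Insert states in rec("I", ...) are entered after emitting; the i argument
# is the residues-emitted count, so entering I consumed residue i already.
# (The M -> I branch above passes i+1 for that reason.)

# Naive single-linkage oracle: boolean closure over the identity matrix.
naive_single_linkage <- function(idmat, threshold) {
  n <- nrow(idmat)
  adj <- idmat >= threshold
  diag(adj) <- TRUE
  reach <- adj
  for (rep in seq_len(n)) reach <- (reach %*% reach) > 0
  comp <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      nxt <- nxt + 1L
      comp[which(reach[i, ])] <- nxt
    }
  }
  comp
}

# Per-position KL divergence by a plain loop (relative entropy oracle).
naive_relative_entropy <- function(core, f) {
  tot <- 0
  for (k in seq_len(core$M)) {
    for (a in 1:20) {
      e <- core$e[k, a]
      if (e > 0) tot <- tot + e * log2(e / f[a])
    }
  }
  tot / core$M
}

# Random tiny profile for oracle tests (raw Dirichlet emissions, no
# entropy target so tiny M never fails a blending constraint).
tiny_profile <- function(M, seed, concentration = 0.15) {
  sample_profile(M = M, H = NULL, seed = seed, concentration = concentration)
}

# Deterministic small random instance: profile + configured search profile
# + sequence.
tiny_instance <- function(seed, M = NULL, L = NULL) {
  set.seed(seed)
  if (is.null(M)) M <- sample(1:3, 1)
  if (is.null(L)) L <- sample(2:6, 1)
  core <- tiny_profile(M, seed)
  sp <- configure_length(core, L)
  list(sp = sp, x = sample_iid(L, seed = seed + 5000L), M = M, L = L)
}
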