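test_that("log-sum identities hold and the lookup table meets its error bound", {
  expect_equal(logsum(3.7, 3.7), 4.7, tolerance = 1e-12)
  expect_equal(logsum(2.5, -Inf), 2.5)
  expect_equal(logsum(-Inf, -4), -4)
  expect_equal(logsum(0, -3), log2(1 + 2^-3), tolerance = 1e-12)
  tab <- logsum_table()
  expect_gte(length(tab$entries), 16000)
  d <- seq(0, 20, by = 0.0003)
  exact <- vapply(d, function(di) logsum(di, 0), numeric(1))
  approx <- vapply(d, function(di) logsum(di, 0, tab), numeric(1))
  expect_lt(max(abs(exact - approx)), 0.001)
})

test_that("Forward equals exhaustive path-sum enumeration on tiny instances", {
  for (t in 1:40) {
    ti <- tiny_instance(t, M = 2, L = 3)
    expect_equal(forward_score(ti$sp, ti$x, "generic")$score,
                 enumerate_paths_score(ti$sp, ti$x, "sum"), tolerance = 1e-9)
    expect_equal(forward_score(ti$sp, ti$x, "parser")$score,
                 enumerate_paths_score(ti$sp, ti$x, "sum"), tolerance = 1e-7)
  }
  # M = 1: effectively a hand computation (few dozen paths)
  for (t in 1:10) {
    ti <- tiny_instance(300 + t, M = 1, L = 2)
    expect_equal(forward_score(ti$sp, ti$x, "generic")$score,
                 enumerate_paths_score(ti$sp, ti$x, "sum"), tolerance = 1e-9)
    expect_equal(backward_score(ti$sp, ti$x, "generic")$score,
                 enumerate_paths_score(ti$sp, ti$x, "sum"), tolerance = 1e-9)
  }
})

test_that("sparse-rescaling parser matches the generic log-sum Forward", {
  for (t in 1:40) {
    set.seed(1600 + t)
    M <- sample(2:60, 1); L <- sample(10:150, 1)
    core <- sample_profile(M = M, H = NULL, seed = 1600 + t)
    sp <- configure_length(core, L)
    x <- sample_iid(L, seed = 1700 + t)
    expect_lt(abs(forward_score(sp, x, "parser")$score -
                  forward_score(sp, x, "generic")$score), 1e-3)
  }
  # biased-composition target
  core <- sample_profile(M = 40, H = NULL, seed = 1801)
  sp <- configure_length(core, 120)
  fb <- aa_background()
  fb[c("A", "V", "I", "L")] <- fb[c("A", "V", "I", "L")] * 6
  fb <- fb / sum(fb)
  xb <- sample_iid(120, freqs = fb, seed = 1802)
  expect_lt(abs(forward_score(sp, xb, "parser")$score -
                forward_score(sp, xb, "generic")$score), 1e-3)
})

test_that("parser survives long-deletion stress via reinitiation paths", {
  # near-1 delete extension invites 200+ residue deletions; the multihit
  # local model guarantees a dominating two-segment alternative
  core <- sample_profile(M = 300, H = NULL, seed = 1901)
  core$t[, "md"] <- 0.3; core$t[, "mm"] <- 0.68; core$t[, "mi"] <- 0.02
  core$t[, "dd"] <- 0.98; core$t[, "dm"] <- 0.02
  core$t[300, ] <- c(1, 0, 0, 1, 0, 1, 0)
  sp <- configure_length(core, 250)
  for (s in 1:3) {
    x <- sample_iid(250, seed = 1910 + s)
    expect_lt(abs(forward_score(sp, x, "parser")$score -
                  forward_score(sp, x, "generic")$score), 1e-3)
  }
})

test_that("rescaling triggers on strong hits and preserves the score", {
  core <- sample_profile(M = 50, H = NULL, seed = 2001, concentration = 0.05)
  target <- paste0(sample_iid(200, seed = 2002), strrep(core$consensus, 4),
                   sample_iid(200, seed = 2003))
  sp <- profile_set_length(configure_length(core, 100), nchar(target))
  fp <- forward_score(sp, target, "parser")
  expect_gte(fp$nrescale, 1L)
  expect_lt(abs(fp$score - forward_score(sp, target, "generic")$score), 1e-3)
  # scale bookkeeping: per-row factors are 0 except at rescale rows, and
  # their sum re-enters the reported total
  expect_equal(sum(fp$scalelog != 0), fp$nrescale)
})

test_that("Backward reproduces the Forward total", {
  for (t in 1:20) {
    set.seed(2100 + t)
    M <- sample(2:50, 1); L <- sample(10:120, 1)
    core <- sample_profile(M = M, H = NULL, seed = 2100 + t)
    sp <- configure_length(core, L)
    x <- sample_iid(L, seed = 2200 + t)
    f <- forward_score(sp, x, "parser")$score
    expect_lt(abs(backward_score(sp, x, "parser")$score - f), 1e-3)
    expect_lt(abs(backward_score(sp, x, "generic")$score - f), 1e-3)
  }
})

test_that("endpoint posteriors conserve mass and locate a planted segment", {
  # point-mass emissions on rare residues: ~6 bits/position, so alignments
  # that trim an end pay enough that begin/end mass stays at the true edges
  e20 <- matrix((1 - 0.9) / 19, 20, 20)
  wc <- ifelse(seq_len(20) %% 2 == 1, match("W", aa_alphabet()),
               match("C", aa_alphabet()))
  e20[cbind(seq_len(20), wc)] <- 0.9
  t7 <- matrix(rep(c(0.96, 0.02, 0.02, 0.8, 0.2, 0.7, 0.3), each = 20), 20, 7)
  colnames(t7) <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
  t7[20, ] <- c(1, 0, 0, 1, 0, 1, 0)
  core <- msvscan:::new_core_profile(e20, t7, name = "planted")
  flank1 <- sample_iid(30, seed = 2302)
  flank2 <- sample_iid(30, seed = 2303)
  target <- paste0(flank1, core$consensus, flank2)
  sp <- profile_set_length(configure_length(core, 100), nchar(target))
  po <- endpoint_posteriors(forward_score(sp, target),
                            backward_score(sp, target))
  expect_equal(sum(po$begin), sum(po$end), tolerance = 1e-6)
  # a segment almost surely starts and ends at the planted coordinates
  st <- nchar(flank1) + 1L
  expect_gt(sum(po$begin[(st - 1):(st + 1)]), 0.9)
  en <- nchar(flank1) + core$M
  expect_gt(sum(po$end[(en - 1):(en + 1)]), 0.9)
})

test_that("a null-only target keeps the expected segment count near prior", {
  core <- sample_profile(M = 30, H = 0.8, seed = 2401)
  sp <- configure_length(core, 150)
  x <- sample_iid(150, seed = 2402)
  po <- endpoint_posteriors(forward_score(sp, x), backward_score(sp, x))
  # every path uses B at least once; the multihit prior (tEJ = 0.5) puts
  # the expected count at 2, so the null posterior sits in [1, 2.5]
  expect_gte(po$expected_segments, 1)
  expect_lte(po$expected_segments, 2.5)
})

test_that("worst-case odds ratios stay inside float range at design limits", {
  # worst positive-scoring alignment: one match, everything else flanking;
  # its odds ratio is a simple function of M and L and must not underflow
  M <- 1e5; L <- 1e5
  worst_bits <- log2(2 / (M * (M + 1))) - 1 + 2 * log2(3 / (L + 3)) +
    (L - 1) * log2(L / (L + 3)) - null_transition_bits(L)
  expect_gt(2^worst_bits, .Machine$double.xmin)
  expect_gt(worst_bits, -89.5)  # inside the Viterbi word range too
})
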