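test_that("single-sequence build with heavy pseudocounts shrinks to background", {
  core <- build_from_msa("ACDE", pseudocount_weight = 50)
  expect_equal(core$M, 4L)
  expect_true(all(abs(rowSums(core$e[, 1:20]) - 1) < 1e-9))
  f <- aa_background()
  expect_lt(max(abs(sweep(core$e[, 1:20], 2, f, "-"))), 0.02)
})

test_that("entropy weighting drives relative entropy to its target", {
  core0 <- sample_profile(M = 40, H = NULL, seed = 7, concentration = 0.05)
  msa <- sample_msa(core0, 30, seed = 8)
  raw <- build_from_msa(msa, pseudocount_weight = 0.3)
  expect_gt(relative_entropy(raw), 0.6)  # sharp family: raw exceeds target
  ew <- build_from_msa(msa, pseudocount_weight = 0.3, entropy_target = 0.6)
  expect_lt(abs(relative_entropy(ew) - 0.6), 0.01)
  # already-below-target alignments are left alone
  low <- build_from_msa("ACDE", pseudocount_weight = 50, entropy_target = 0.6)
  ref <- build_from_msa("ACDE", pseudocount_weight = 50)
  expect_equal(low$e, ref$e)
})

test_that("emission parameters are recovered from a 50-sequence alignment", {
  core0 <- sample_profile(M = 30, H = NULL, seed = 21, concentration = 0.5)
  msa <- sample_msa(core0, 50, seed = 22)
  est <- build_from_msa(msa, pseudocount_weight = 0.1)
  dev <- abs(est$e[, 1:20] - core0$e[, 1:20])
  expect_lt(mean(dev), 0.05)
  expect_lt(max(dev), 0.2)       # worst single cell, sampling noise
})

test_that("length-model transitions follow the multihit local parameterization", {
  core <- sample_profile(M = 25, H = NULL, seed = 3)
  sp <- configure_length(core, 400)
  expect_equal(sp$loop, 400 / 403)
  expect_equal(sp$move, 3 / 403)
  expect_equal(sp$tEJ, 0.5)
  expect_equal(sp$null$r, 400 / 401)
  # geometric null: expected emitted length r/(1-r) equals L
  expect_equal(sp$null$r / (1 - sp$null$r), 400)
  expect_error(configure_length(core, 0), "L")
  # collapsed uniform-fragment model: entry x (number of exits) sums to 1
  for (M in c(1, 2, 7, 100, 1000)) {
    cm <- sample_profile(M = min(M, 50), H = NULL, seed = M)
    k <- seq_len(cm$M)
    spm <- configure_length(cm, 100)
    expect_equal(sum(spm$entry * (cm$M - k + 1)), 1, tolerance = 1e-12)
    # entry-position marginal equals 2(M-k+1)/(M(M+1))
    expect_equal(spm$entry * (cm$M - k + 1),
                 2 * (cm$M - k + 1) / (cm$M * (cm$M + 1)), tolerance = 1e-12)
  }
})

test_that("match scores are exact log-odds and invert to emissions", {
  f <- aa_background()
  # e = f gives 0 bits; e = 2f gives exactly +1 bit
  e20 <- matrix(f, 3, 20, byrow = TRUE)
  e20[2, ] <- f * 2; e20[2, ] <- e20[2, ] / sum(e20[2, ])  # renormalized
  t7 <- matrix(rep(c(0.9, 0.05, 0.05, 0.8, 0.2, 0.7, 0.3), each = 3), 3, 7)
  colnames(t7) <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
  core <- msvscan:::new_core_profile(e20, t7)
  s <- match_scores(core, null_model(100, f))
  expect_equal(s[1, 1:20], setNames(rep(0, 20), names(f)), tolerance = 1e-12)
  # unnormalized doubling: check on a clean two-residue toy instead
  e2 <- rbind(c(0.5, 0.5, rep(0, 18)))
  e2 <- e2 + 1e-12; e2 <- e2 / sum(e2)
  fu <- rep(0.05, 20); names(fu) <- aa_alphabet()
  t1 <- t7[1, , drop = FALSE]
  core2 <- msvscan:::new_core_profile(e2, t1)
  s2 <- match_scores(core2, null_model(100, fu))
  expect_equal(unname(s2[1, "A"]), log2(0.5 / 0.05), tolerance = 1e-6)
  # inversion identity f * 2^s = e on a random profile
  corer <- sample_profile(M = 12, H = NULL, seed = 5)
  sr <- match_scores(corer, null_model(50, f))
  expect_lt(max(abs(sweep(2^sr[, 1:20], 2, f, "*") - corer$e[, 1:20])), 1e-9)
  # X scores zero everywhere
  expect_true(all(sr[, 21] == 0))
})

test_that("relative entropy matches closed forms and a naive loop", {
  f <- aa_background()
  e20 <- matrix(f, 5, 20, byrow = TRUE)
  t7 <- matrix(rep(c(0.9, 0.05, 0.05, 0.8, 0.2, 0.7, 0.3), each = 5), 5, 7)
  colnames(t7) <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
  core <- msvscan:::new_core_profile(e20, t7)
  expect_equal(relative_entropy(core, null_model(100, f)), 0, tolerance = 1e-12)
  # single-residue point mass against uniform background: log2(20)
  ep <- matrix(0, 1, 20); ep[1, 7] <- 1
  fu <- rep(0.05, 20); names(fu) <- aa_alphabet()
  corep <- msvscan:::new_core_profile(ep, t7[1, , drop = FALSE])
  expect_equal(relative_entropy(corep, null_model(100, fu)), log2(20),
               tolerance = 1e-12)
  corer <- sample_profile(M = 17, H = NULL, seed = 9)
  expect_equal(relative_entropy(corer, null_model(100, f)),
               unname(naive_relative_entropy(corer, f)), tolerance = 1e-12)
})

test_that("striped indexing follows the interleaved layout", {
  sx <- stripe(1:14, 4L)
  expect_equal(nrow(sx), 4L)          # Q = ceiling(14/4)
  expect_equal(sx[1, ], c(1, 5, 9, 13))  # vector 0 holds cells 1,5,9,13
  expect_equal(sum(is.na(sx)), 2L)    # two unused sentinel slots
  expect_error(stripe(1:10, 5L), "V")
})

test_that("stripe/unstripe is a bijection across (M, V)", {
  set.seed(404)
  for (M in c(1, 2, 15, 16, 17, 100, 1537, 5000)) {
    for (V in c(4L, 8L, 16L)) {
      v <- rnorm(M)
      expect_identical(unstripe(stripe(v, V)), v)
    }
  }
})

test_that("reduced precision dequantizes within one unit and saturates", {
  core <- sample_profile(M = 37, H = NULL, seed = 11)
  sp <- configure_length(core, 200)
  rp <- reduce_profile(sp)
  dq <- dequantize_msv(rp)
  unsat <- rp$msv_bytes[msvscan:::stripe_index0(rp$M, rp$V_byte), ] < 255L
  expect_lt(max(abs(dq - sp$s)[unsat]), 1 / rp$msv_scale)
  # Viterbi words: 1/500-bit quantization
  idxw <- msvscan:::stripe_index0(rp$M, rp$V_word)
  wv <- rp$vit_words[idxw, ] / rp$vit_scale
  in_range <- abs(sp$s) * rp$vit_scale < 32767  # representable words only
  expect_lt(max(abs(wv - sp$s)[in_range]), 1 / rp$vit_scale)
  # an emission this improbable must saturate to byte cost 255
  etiny <- matrix(1 / 20, 2, 20)
  etiny[1, 1] <- 1e-40
  etiny <- etiny / rowSums(etiny)
  t7 <- matrix(rep(c(0.9, 0.05, 0.05, 0.8, 0.2, 0.7, 0.3), each = 2), 2, 7)
  colnames(t7) <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
  spt <- configure_length(msvscan:::new_core_profile(etiny, t7), 100)
  rpt <- reduce_profile(spt)
  expect_equal(rpt$msv_bytes[msvscan:::stripe_index0(2, 16)[1], 1], 255L)
})

test_that("constructed profiles satisfy the probability invariants", {
  for (seed in 1:10) {
    core <- sample_profile(M = sample(2:60, 1), H = NULL, seed = seed)
    expect_silent(msvscan:::validate_core_profile(core))
    msa <- sample_msa(core, 10, seed = seed)
    built <- build_from_msa(msa)
    expect_silent(msvscan:::validate_core_profile(built))
  }
})

test_that("degenerate residues map to X and X scores zero", {
  x <- aa_encode("ACBZJUOX")
  expect_equal(attr(x, "n_degenerate"), 6L)
  expect_equal(aa_decode(x), "ACXXXXXX")
  core <- sample_profile(M = 4, H = NULL, seed = 2)
  sp <- configure_length(core, 8)
  expect_true(all(sp$s[, 21] == 0))
})
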