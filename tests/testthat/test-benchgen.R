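# helper: mutate a residue string at a given per-site substitution rate
mutate_seq <- function(s, rate) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- runif(length(ch)) < rate
  ch[hit] <- sample(aa_alphabet(), sum(hit), replace = TRUE)
  paste0(ch, collapse = "")
}

# helper: an alignment with one large tight cluster and nclust remote ones
make_family_msa <- function(seed, M = 80, nclust = 3) {
  set.seed(seed)
  cons <- replicate(nclust, paste0(sample(aa_alphabet(), M, replace = TRUE),
                                   collapse = ""))
  rows <- c(vapply(1:5, function(i) mutate_seq(cons[1], 0.1), character(1)),
            unlist(lapply(2:nclust, function(cl)
              vapply(1:2, function(i) mutate_seq(cons[cl], 0.1), character(1)))))
  names(rows) <- paste0("m", seed, "_", seq_along(rows))
  rows
}

test_that("i.i.d. sampling matches the requested composition", {
  x <- sample_iid(1e6, seed = 1, as_string = FALSE)
  emp <- tabulate(x + 1L, 21)[1:20] / 1e6
  expect_lt(max(abs(emp - aa_background())), 0.005)
  expect_identical(sample_iid(50, seed = 7), sample_iid(50, seed = 7))
  expect_equal(nchar(sample_iid(1, seed = 2)), 1L)
  expect_error(sample_iid(5, freqs = rep(0.1, 20)), "frequencies")
})

test_that("shuffles preserve exactly what they claim to preserve", {
  s <- sample_iid(300, seed = 11)
  m <- shuffle_seq(s, "mono", seed = 12)
  expect_identical(sort(strsplit(m, "")[[1]]), sort(strsplit(s, "")[[1]]))
  expect_false(identical(m, s))
  d <- shuffle_seq(s, "di", seed = 13)
  dicount <- function(z) {
    ch <- strsplit(z, "")[[1]]
    table(paste0(head(ch, -1), tail(ch, -1)))
  }
  expect_identical(dicount(d), dicount(s))
  r <- shuffle_seq(s, "reverse")
  expect_identical(shuffle_seq(r, "reverse"), s)
  expect_error(shuffle_seq("A", "di"), "length")
  expect_identical(shuffle_seq(s, "di", seed = 13), d)  # seeded determinism
})

test_that("percent identity follows the shorter-sequence definition", {
  expect_equal(percent_identity("ACDEF", "ACDEF"), 1.0)
  # 5 identities, unaligned lengths 10 and 8 -> 5/8
  a <- "ACDEFGHIKL"
  b <- "ACDEF--GWW"  # identities at first 5 columns; b has 8 residues
  expect_equal(percent_identity(a, b), 5 / 8)
  expect_equal(percent_identity("AAAA", "CCCC"), 0.0)
  expect_error(percent_identity("A--", "---"), "zero-length")
})

test_that("single linkage matches its semantics and a naive closure oracle", {
  id0 <- matrix(0.1, 4, 4); diag(id0) <- 1
  expect_equal(max(single_linkage(id0, threshold = 0.25)), 4L)  # singletons
  # chain a~b, b~c, a!~c -> one cluster
  idc <- matrix(0, 3, 3); diag(idc) <- 1
  idc[1, 2] <- idc[2, 1] <- 0.5
  idc[2, 3] <- idc[3, 2] <- 0.5
  expect_equal(max(single_linkage(idc, threshold = 0.3)), 1L)
  set.seed(31)
  for (t in 1:20) {
    n <- 12
    m <- matrix(runif(n * n), n, n); m <- (m + t(m)) / 2; diag(m) <- 1
    got <- single_linkage(m, threshold = 0.8)
    want <- naive_single_linkage(m, 0.8)
    # same partition up to label names
    expect_equal(outer(got, got, "=="), outer(want, want, "=="))
  }
})

test_that("profmark construction follows the clustering/embedding procedure", {
  msas <- lapply(1:3, make_family_msa)
  names(msas) <- paste0("fam", 1:3)
  # a single-cluster alignment must be excluded
  set.seed(99)
  onecons <- paste0(sample(aa_alphabet(), 60, replace = TRUE), collapse = "")
  msas$onecluster <- vapply(1:6, function(i) mutate_seq(onecons, 0.08),
                            character(1))
  names(msas$onecluster) <- paste0("oc", 1:6)
  # plant a fragment: must be removed before clustering
  frag <- paste0(substr(msas$fam1[[1]], 1, 30),
                 strrep("-", nchar(msas$fam1[[1]]) - 30))
  msas$fam1 <- c(msas$fam1, frag = frag)

  set.seed(77)
  dblens <- pmax(120L, round(rlnorm(60, log(300), 0.4)))
  seqdb <- vapply(dblens, function(l) sample_iid(l), character(1))
  names(seqdb) <- paste0("db", seq_along(seqdb))

  bs <- profmark_build(msas, seqdb, ndomains = 1L, negmode = "mono",
                       n_neg = 50L, seed = 123)
  expect_false("onecluster" %in% names(bs$queries))
  expect_false(any(grepl("^frag", unlist(lapply(bs$queries, names)))))
  expect_gte(length(bs$positives), 2L)
  expect_equal(length(bs$decoys), 50L)
  # positives are domain + two nonhomologous segments (3 segments)
  for (tid in names(bs$positives)) {
    d <- bs$domains[bs$domains$target == tid, ]
    expect_equal(nrow(d), 1L)
    expect_gte(d$start, 1L)
    expect_lte(d$end, nchar(bs$positives[[tid]]))
  }
  # decoy lengths copy the positives' segment-length vectors
  expect_true(all(nchar(bs$decoys) %in% nchar(bs$positives)))
  # truth table covers every target exactly once
  expect_setequal(bs$truth$target, c(names(bs$positives), names(bs$decoys)))
  # identity guarantees re-verified post hoc
  expect_true(profmark_verify(bs))
  # determinism
  bs2 <- profmark_build(msas, seqdb, ndomains = 1L, negmode = "mono",
                        n_neg = 50L, seed = 123)
  expect_identical(bs$positives, bs2$positives)
})

test_that("two-domain positives carry five segments in order", {
  msas <- lapply(4:6, make_family_msa)
  names(msas) <- paste0("fam", 4:6)
  set.seed(88)
  seqdb <- vapply(1:40, function(i) sample_iid(400 + sample(0:200, 1)),
                  character(1))
  names(seqdb) <- paste0("db", 1:40)
  bs <- profmark_build(msas, seqdb, ndomains = 2L, negmode = "iid",
                       n_neg = 20L, seed = 5)
  expect_gte(length(bs$positives), 1L)
  for (tid in names(bs$positives)) {
    d <- bs$domains[bs$domains$target == tid, ]
    expect_equal(nrow(d), 2L)
    expect_lt(d$end[1], d$start[2])  # order preserved
  }
  expect_true(profmark_verify(bs))
})

test_that("filter-fraction experiment has its trivial limits and determinism", {
  core <- sample_profile(M = 25, H = 0.8, seed = 41)
  sp <- configure_length(core, 100)
  rp <- reduce_profile(sp)
  cal <- calibrate(sp, rp, n = 50, Lcal = 100, seed = 42)
  expect_equal(filter_fraction_experiment(sp, rp, cal, Pthr = 1.0, n = 150,
                                          L = 100, seed = 43), 1.0)
  f1 <- filter_fraction_experiment(sp, rp, cal, Pthr = 0.05, n = 300,
                                   L = 100, seed = 44)
  f2 <- filter_fraction_experiment(sp, rp, cal, Pthr = 0.05, n = 300,
                                   L = 100, seed = 44)
  expect_identical(f1, f2)
  expect_error(filter_fraction_experiment(sp, rp, cal, n = 50, L = 100,
                                          seed = 1), "n >= 100")
})

test_that("roundoff experiment is deterministic under a fixed seed", {
  core <- sample_profile(M = 30, H = 0.8, seed = 51)
  sp <- configure_length(core, 150)
  rp <- reduce_profile(sp)
  r1 <- roundoff_experiment(sp, rp, n = 120, L = 150, seed = 52)
  r2 <- roundoff_experiment(sp, rp, n = 120, L = 150, seed = 52)
  expect_identical(r1, r2)
  expect_true(is.finite(r1$sd))
})

test_that("ROC utility ranks merged hits against the truth table", {
  truth <- data.frame(target = c("p1", "p2", "d1", "d2"),
                      label = c("positive", "positive", "decoy", "decoy"))
  hits <- data.frame(target = c("p1", "d1", "p2"), evalue = c(1e-8, 0.5, 2))
  roc <- bench_roc(truth, hits, n_queries = 2)
  expect_equal(roc$tp_fraction, c(0.5, 0.5, 1.0))
  expect_equal(roc$fp_per_query, c(0, 0.5, 0.5))
})
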