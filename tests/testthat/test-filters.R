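test_that("Rost threshold matches direct evaluation of the curve", {
  # independent high-precision arithmetic, frozen
  expect_equal(rost_threshold(100, 0, decay = 100),
               480 * 100^(-0.32 * (1 + exp(-1))))
  expect_equal(rost_threshold(100, 0, decay = 100), 63.9437897, tolerance = 1e-7)
  expect_equal(rost_threshold(250, 0, decay = 1000),
               480 * 250^(-0.32 * (1 + exp(-0.25))))
  expect_equal(rost_threshold(250, 0, decay = 1000), 20.7154712,
               tolerance = 1e-7)
  expect_error(rost_threshold(0.5), "L must be >= 1")
})

test_that("the offset n is purely additive and never loosens the filter", {
  set.seed(51)
  L <- sample(1:2000, 100, replace = TRUE)
  n <- runif(100, 0, 60)
  expect_equal(rost_threshold(L, n), rost_threshold(L, 0) + n)
  expect_true(all(rost_threshold(L, n) >= rost_threshold(L, 0)))
})

test_that("identity filter keeps hits on or above the curve", {
  # 100% identity at L = 10 is still below the curve (threshold > 100%)
  p100 <- filter_params(rost_n = 0, decay_constant = 100)
  short_hit <- make_hits("a", 100, 10)
  res <- identity_filter(short_hit, p100)
  expect_equal(nrow(res$kept), 0L)
  expect_equal(res$decisions$reason, "below-rost-curve")
  # at L = 300 the threshold is < 100%
  long_hit <- make_hits("b", 100, 300)
  res <- identity_filter(long_hit, p100)
  expect_equal(res$kept$subject_id, "b")
  # empty input
  empty <- identity_filter(make_hits(character(), numeric(), integer()), p100)
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$decisions), 0L)
})

test_that("raising n monotonically shrinks the kept set", {
  set.seed(52)
  hits <- make_hits(paste0("h", 1:50), runif(50, 10, 100),
                    sample(20:500, 50, replace = TRUE))
  prev <- identity_filter(hits, filter_params(rost_n = 0))$kept$subject_id
  for (n in c(10, 20, 33, 50)) {
    cur <- identity_filter(hits, filter_params(rost_n = n))$kept$subject_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("length filter removes candidates at the printed boundary", {
  p <- filter_params(min_domain_len = 28)
  hits <- make_hits(c("rm", "keep"), c(90, 90), c(200, 200))
  lens <- c(rm = 272, keep = 273)
  res <- length_filter(hits, lens, accepted_lengths = c(300, 350), p)
  expect_equal(res$kept$subject_id, "keep")
  expect_equal(res$decisions$reason, c("too-short", "kept"))
})

test_that("length filter trims terminal overhangs, longest first", {
  p <- filter_params(min_domain_len = 28)
  # inside the band: untrimmed
  h <- make_hits("ok", 90, 300, s_start = 1, s_end = 300)
  res <- length_filter(h, c(ok = 400), c(300, 400), p)
  expect_equal(res$decisions$reason, "kept")
  expect_true(is.na(res$kept$trim_start))
  # length 500 aligned over 10..420: right overhang (80) is removed first,
  # bringing the length to 420 <= G + m = 428, left overhang survives
  h <- make_hits("long", 90, 411, s_start = 10, s_end = 420)
  res <- length_filter(h, c(long = 500), c(300, 400), p)
  expect_equal(res$decisions$reason, "kept-trimmed")
  expect_equal(res$decisions$trimmed_range, "1-420")
  expect_equal(res$kept$eff_length, 420L)
  # both overhangs removed when the longest alone is not enough
  h <- make_hits("vlong", 90, 401, s_start = 101, s_end = 501)
  res <- length_filter(h, c(vlong = 600), c(300, 400), p)
  expect_equal(res$decisions$trimmed_range, "101-501")
  expect_equal(res$kept$eff_length, 401L)
  expect_error(length_filter(h, c(vlong = 600), numeric(), p), "non-empty")
})

test_that("both filters are idempotent and partition their input", {
  set.seed(53)
  p <- filter_params()
  hits <- make_hits(paste0("h", 1:40), runif(40, 20, 100),
                    sample(30:400, 40, replace = TRUE))
  lens <- setNames(hits$aln_length + sample(0:300, 40, replace = TRUE),
                   hits$subject_id)
  accepted <- c(250, 320)

  i1 <- identity_filter(hits, p)
  i2 <- identity_filter(i1$kept, p)
  expect_equal(i2$kept, i1$kept)
  expect_setequal(i1$decisions$candidate_id, hits$subject_id)
  expect_equal(nrow(i1$decisions), nrow(hits))

  l1 <- length_filter(hits, lens, accepted, p)
  # trimming is recorded, never applied to the database, so a second pass
  # over the kept hits reproduces the first exactly
  l2 <- length_filter(l1$kept[, names(hits)], lens, accepted, p)
  expect_equal(l2$kept$subject_id, l1$kept$subject_id)
  expect_equal(l2$kept$eff_length, l1$kept$eff_length)
  expect_equal(l2$kept$trim_start, l1$kept$trim_start)
  # partition: every candidate decided exactly once, kept + removed = all
  expect_equal(nrow(l1$decisions), nrow(hits))
  expect_setequal(c(l1$kept$subject_id,
                    l1$decisions$candidate_id[!l1$decisions$kept]),
                  hits$subject_id)
  # trimming never increases a length
  expect_true(all(l1$kept$eff_length <= lens[l1$kept$subject_id]))
})
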