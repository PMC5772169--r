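# RPKM, peak-set overlap, moderated classification, paired shift test.

test_that("rpkm normalises by kilobase and million mapped reads", {
  expect_equal(as.numeric(rpkm(100, 1000, 1e6)), 100)
  expect_equal(as.numeric(rpkm(0, 1000, 1e6)), 0)
  expect_equal(as.numeric(rpkm(50, 500, 2e6)), 50)
  expect_error(rpkm(1, 1000, 0), "library")
  expect_error(rpkm(1, 0, 1e6), "length")
})

test_that("rpkm is linear in counts and inversely linear in library size", {
  set.seed(9)
  counts <- matrix(rpois(40, 60), 10)
  len <- runif(10, 200, 2000)
  lib <- runif(4, 1e6, 5e6)
  base <- rpkm(counts, len, lib)
  expect_equal(rpkm(3 * counts, len, lib), 3 * base)
  expect_equal(rpkm(counts, len, 2 * lib), base / 2)
})

test_that("positive overlap counts peaks touching the union", {
  a <- data.frame(chrom = "chr1", start = c(0, 100, 200, 300),
                  end = c(50, 150, 250, 350))
  expect_equal(positive_overlap(a, a)$fraction, 1.0)
  b <- data.frame(chrom = "chr1", start = 1000, end = 1100)
  expect_equal(positive_overlap(a, b)$fraction, 0.0)
  # 3 of 4 overlap (the union absorbs b's internal structure)
  b2 <- data.frame(chrom = "chr1", start = c(40, 140, 240),
                   end = c(60, 160, 260))
  ov <- positive_overlap(a, b2)
  expect_equal(ov$fraction, 0.75)
  expect_equal(nrow(ov$overlapping), 3L)
  # bookended intervals (half-open) do not overlap
  b3 <- data.frame(chrom = "chr1", start = 50, end = 100)
  expect_equal(positive_overlap(a[1, ], b3)$fraction, 0.0)
})

test_that("classification recovers planted effects and stays quiet on nulls", {
  set.seed(501)
  n_eff <- 150; n_null <- 300
  mu <- runif(n_eff * 2 + n_null, 100, 400)
  effect <- c(rep(-1, n_eff), rep(1, n_eff), rep(0, n_null))
  counts <- sapply(1:6, function(j) {
    m <- if (j > 3) mu * 2^effect else mu
    rnbinom(length(mu), mu = m, size = 1 / 0.05)
  })
  rc <- replicate_counts(counts, rep(c("control", "treated"), each = 3),
                         rep(500, length(mu)), rep(1e7, 6))
  cls <- classify_peaks(rc)
  expect_gt(mean(cls$class[1:n_eff] == "repressor"), 0.8)
  expect_gt(mean(cls$class[n_eff + 1:n_eff] == "activator"), 0.8)
  expect_lt(mean(cls$class[2 * n_eff + 1:n_null] != "neutral"), 0.1)
  # detected effects carry the planted sign
  det <- cls$class[1:(2 * n_eff)] != "neutral"
  expect_true(all(sign(cls$log2_fold_change[1:(2 * n_eff)])[det] ==
                    effect[1:(2 * n_eff)][det]))
})

test_that("identical condition means give a neutral call", {
  counts <- matrix(rep(c(50L, 80L, 110L), each = 6), nrow = 3, byrow = TRUE)
  rc <- replicate_counts(counts, rep(c("a", "b"), each = 3),
                         rep(1000, 3), rep(1e6, 6))
  cls <- classify_peaks(rc)
  expect_true(all(cls$class == "neutral"))
  expect_true(all(cls$p_value == 1))
  expect_true(all(cls$log2_fold_change == 0))
})

test_that("classification requires two replicates per condition", {
  counts <- matrix(rpois(9, 50), 3)
  expect_error(replicate_counts(counts, c("a", "a", "b"), rep(100, 3),
                                rep(1e6, 3)) |> classify_peaks(),
               "two replicates")
})

test_that("moderated statistics track a limma trend fit", {
  skip_if_not_installed("limma")
  set.seed(77)
  n <- 400
  mu <- runif(n, 20, 500)
  counts <- sapply(1:6, function(j) rnbinom(n, mu = mu, size = 10))
  rc <- replicate_counts(counts, rep(c("c", "t"), each = 3),
                         rep(500, n), rep(1e7, 6))
  cls <- classify_peaks(rc)
  y <- log2(rc$rpkm + 1)
  design <- cbind(1, rep(c(0, 1), each = 3))
  fit <- limma::eBayes(limma::lmFit(y, design), trend = TRUE)
  expect_gt(cor(cls$p_value, fit$p.value[, 2], method = "spearman"), 0.99)
  expect_gt(cor(-log10(cls$p_value), -log10(fit$p.value[, 2])), 0.95)
})

test_that("shift test matches the closed-form paired t exactly", {
  set.seed(808)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    ctl <- runif(n, 0, 20)
    trt <- ctl * runif(n, 0.5, 2) + rnorm(n, 0, 0.5)
    got <- region_set_shift_test(ctl, trt)
    want <- t.test(trt, ctl, paired = TRUE)$p.value
    expect_equal(got$p_value, want, tolerance = 1e-10)
  }
})

test_that("the fold-change gate blocks significance regardless of p", {
  set.seed(11)
  ctl <- runif(2000, 0.05, 20)  # low 1st percentile keeps epsilon small
  trt <- ctl * 1.05 + rnorm(2000, 0, 1e-4)  # tiny p, fold ~1.05
  res <- region_set_shift_test(ctl, trt)
  expect_lt(res$p_value, 1e-5)
  expect_lt(res$mean_fold, 1.15)
  expect_false(res$significant)
  # a 1.5-fold shift with the same precision is significant
  res2 <- region_set_shift_test(ctl, ctl * 1.5 + rnorm(2000, 0, 1e-4))
  expect_true(res2$significant)
  expect_equal(res2$mean_fold, 1.5, tolerance = 0.05)
  # downward folds pass through the reciprocal gate
  res3 <- region_set_shift_test(ctl, ctl / 1.5 + rnorm(2000, 0, 1e-4))
  expect_true(res3$significant)
})

test_that("shift test handles degenerate inputs as documented", {
  x <- c(1, 2, 3)
  same <- region_set_shift_test(x, x)
  expect_equal(same$p_value, 1)
  expect_equal(same$mean_fold, 1)
  expect_false(same$significant)
  shifted <- region_set_shift_test(x, x + 2)
  expect_equal(shifted$p_value, 0)  # constant nonzero differences
  expect_error(region_set_shift_test(1, 2), "two paired")
  expect_error(region_set_shift_test(c(1, 2), 2), "paired")
})
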