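# Coverage filtering, convergent pairing, overlap resolution, tiling.

test_that("coverage filter thresholds are fractions of the summed density", {
  ins <- make_insulators(c(1e4, 2e4, 3e4), rep("forward", 3),
                         ctcf = c(10, 10, 10), cohesin = c(5, 5, 5))
  kept <- suppressMessages(filter_insulators_by_coverage(ins))
  expect_equal(nrow(kept), 3L)  # thresholds 3e-4 and 1.5e-4

  ins2 <- make_insulators(c(1e4, 2e4), c("forward", "forward"),
                          ctcf = c(0, 10), cohesin = c(5, 5))
  kept2 <- suppressMessages(filter_insulators_by_coverage(ins2))
  expect_equal(kept2$pos, 2e4)

  # exceeding one protein's threshold only is not enough
  ins3 <- make_insulators(c(1e4, 2e4), c("forward", "forward"),
                          ctcf = c(10, 10), cohesin = c(0, 5))
  kept3 <- suppressMessages(filter_insulators_by_coverage(ins3))
  expect_equal(kept3$pos, 2e4)

  # the literal reading is available as a switch
  lit <- suppressMessages(filter_insulators_by_coverage(ins2, filter_mode = "literal"))
  expect_equal(lit$pos, 1e4)

  allz <- make_insulators(1e4, "forward", 0, 0)
  expect_warning(out <- filter_insulators_by_coverage(allz), "zero")
  expect_equal(nrow(out), 0L)
})

test_that("convergent pairing respects distance and fold bounds", {
  ins <- make_insulators(c(100000, 400000), c("forward", "reverse"),
                         ctcf = c(10, 15), cohesin = c(12, 20))
  d <- call_convergent_domains(ins)
  expect_equal(nrow(d), 1L)
  expect_equal(c(d$start, d$end), c(100000, 400000))
  expect_equal(d$pair_coverage, 10 + 12 + 15 + 20)

  # too close (500 bp)
  near <- make_insulators(c(100000, 100500), c("forward", "reverse"),
                          ctcf = c(10, 10), cohesin = c(10, 10))
  expect_equal(nrow(call_convergent_domains(near)), 0L)

  # 2.5-fold coverage difference fails
  unb <- make_insulators(c(100000, 400000), c("forward", "reverse"),
                         ctcf = c(10, 25), cohesin = c(10, 10))
  expect_equal(nrow(call_convergent_domains(unb)), 0L)

  # beyond 1 Mb fails; exactly 1 Mb passes ("within 1Mb")
  far <- make_insulators(c(1e5, 1e5 + 1.2e6), c("forward", "reverse"),
                         ctcf = c(10, 10), cohesin = c(10, 10))
  expect_equal(nrow(call_convergent_domains(far)), 0L)
  at <- make_insulators(c(1e5, 1e5 + 1e6), c("forward", "reverse"),
                        ctcf = c(10, 10), cohesin = c(10, 10))
  expect_equal(nrow(call_convergent_domains(at)), 1L)

  # zero coverage on one boundary can never pass the ratio test
  z <- make_insulators(c(1e5, 2e5), c("forward", "reverse"),
                       ctcf = c(0, 0), cohesin = c(10, 10))
  expect_equal(nrow(call_convergent_domains(z)), 0L)

  # unknown orientation never pairs; divergent layouts never pair
  u <- make_insulators(c(1e5, 2e5), c("unknown", "reverse"),
                       ctcf = c(10, 10), cohesin = c(10, 10))
  expect_equal(nrow(call_convergent_domains(u)), 0L)
  dv <- make_insulators(c(1e5, 2e5), c("reverse", "forward"),
                        ctcf = c(10, 10), cohesin = c(10, 10))
  expect_equal(nrow(call_convergent_domains(dv)), 0L)
})

test_that("no fallback to the next-nearest partner when coverage fails", {
  ins <- make_insulators(c(1e5, 2e5, 3e5),
                         c("forward", "reverse", "reverse"),
                         ctcf = c(10, 50, 10), cohesin = c(10, 10, 10))
  # nearest reverse (2e5) fails the ctcf fold test; 3e5 would pass but is
  # not considered
  expect_equal(nrow(call_convergent_domains(ins)), 0L)
})

test_that("overlap resolution keeps the highest-coverage domain greedily", {
  a <- data.frame(chrom = "chr1", start = 0, end = 10000, kind = "convergent",
                  pair_coverage = 40, left_ctcf_rpkm = 1,
                  left_cohesin_rpkm = 1, right_ctcf_rpkm = 1,
                  right_cohesin_rpkm = 1)
  b <- transform(a, start = 5000, end = 20000, pair_coverage = 30)
  expect_equal(resolve_domain_overlaps(rbind(a, b))$pair_coverage, 40)
  # disjoint domains are both kept; touching is not overlap
  c2 <- transform(a, start = 10000, end = 20000, pair_coverage = 30)
  expect_equal(nrow(resolve_domain_overlaps(rbind(a, c2))), 2L)
  # containment counts as overlap
  inner <- transform(a, start = 2000, end = 4000, pair_coverage = 10)
  expect_equal(resolve_domain_overlaps(rbind(inner, a))$pair_coverage, 40)
})

test_that("overlap resolution equals the exhaustive subset oracle", {
  set.seed(77)
  for (i in 1:60) {
    d <- random_domain_set(sample(2:8, 1), two_chroms = (i %% 4 == 0))
    got <- resolve_domain_overlaps(d)
    want <- bf_resolve(d)
    expect_equal(got$start, want$start)
    expect_equal(got$pair_coverage, want$pair_coverage)
  }
})

test_that("negative domains tile exactly the inter-domain gaps", {
  conv <- data.frame(chrom = "chr1", start = c(10000, 30000),
                     end = c(20000, 50000), kind = "convergent",
                     pair_coverage = c(1, 1))
  neg <- negative_domains(conv)
  expect_equal(neg$start, 20000)
  expect_equal(neg$end, 30000)

  expect_equal(nrow(negative_domains(conv[1, ])), 0L)

  adj <- data.frame(chrom = "chr1", start = c(10000, 20000),
                    end = c(20000, 30000), kind = "convergent",
                    pair_coverage = c(1, 1))
  expect_equal(nrow(negative_domains(adj)), 0L)

  # gaps never span chromosomes
  two <- data.frame(chrom = c("chr1", "chr2"), start = c(1e4, 5e4),
                    end = c(2e4, 6e4), kind = "convergent",
                    pair_coverage = c(1, 1))
  expect_equal(nrow(negative_domains(two)), 0L)
})

test_that("predicted domains satisfy their output invariants", {
  set.seed(88)
  n <- 40
  pos <- sort(sample.int(5e6, n))
  ins <- make_insulators(pos, sample(c("forward", "reverse"), n, TRUE),
                         ctcf = runif(n, 5, 20), cohesin = runif(n, 5, 20))
  dom <- suppressMessages(predict_domains(ins))
  conv <- dom[dom$kind == "convergent", ]
  if (nrow(conv)) {
    len <- conv$end - conv$start
    expect_true(all(len > 1000 & len <= 1e6))
    expect_true(all(pmax(conv$left_ctcf_rpkm, conv$right_ctcf_rpkm) /
                      pmin(conv$left_ctcf_rpkm, conv$right_ctcf_rpkm) < 2))
  }
  # convergent and negative domains never overlap anything
  o <- order(dom$chrom, dom$start)
  d <- dom[o, ]
  same <- d$chrom[-1] == d$chrom[-nrow(d)]
  expect_false(any(same & d$start[-1] < d$end[-nrow(d)]))
})
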