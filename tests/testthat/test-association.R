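# Domain assignment and the class x cluster association matrix.

dom2 <- data.frame(chrom = c("chr1", "chr1"), start = c(1000, 5000),
                   end = c(2000, 8000), kind = "convergent")

test_that("point assignment uses half-open containment", {
  pk <- data.frame(chrom = "chr1", summit = c(1500, 3000, 1000, 2000, 7999))
  out <- assign_to_domains(pk, dom2, "summit")
  expect_equal(out$domain_id,
               c("chr1:1000-2000", NA, "chr1:1000-2000", NA,
                 "chr1:5000-8000"))
  # TSS: start for +, end - 1 for -
  gn <- data.frame(chrom = "chr1", start = c(1000, 900), end = c(3000, 1100),
                   strand = c("+", "-"))
  out2 <- assign_to_domains(gn, dom2, "tss")
  expect_equal(out2$domain_id, c("chr1:1000-2000", "chr1:1000-2000"))
  expect_error(assign_to_domains(pk, data.frame(chrom = "chr1",
                                                start = c(0, 500),
                                                end = c(1000, 1500)),
                                 "summit"),
               "non-overlapping")
})

test_that("a single co-domain pair produces one raw count", {
  pk <- assign_to_domains(data.frame(chrom = "chr1", summit = 1500,
                                     class = "repressor"), dom2, "summit")
  gn <- assign_to_domains(data.frame(chrom = "chr1", start = 1200,
                                     end = 1400, strand = "+",
                                     cluster = "E"), dom2, "tss")
  am <- suppressWarnings(association_scores(
    pk, gn, classes = c("repressor", "neutral", "activator"),
    clusters = c("A", "E")))
  expect_equal(am$raw["repressor", "E"], 1)
  expect_equal(sum(am$raw), 1)
})

test_that("raw totals equal the brute-force domain-wise double loop", {
  set.seed(21)
  for (i in 1:10) {
    n_d <- 6
    doms <- data.frame(chrom = "chr1", start = seq(0, by = 10000,
                                                   length.out = n_d),
                       end = seq(5000, by = 10000, length.out = n_d))
    pk <- data.frame(chrom = "chr1",
                     summit = sample.int(60000L, 40),
                     class = sample(c("repressor", "neutral", "activator"),
                                    40, TRUE))
    gn <- data.frame(chrom = "chr1", start = sample.int(60000L, 30),
                     strand = "+",
                     cluster = sample(LETTERS[1:5], 30, TRUE))
    gn$end <- gn$start + 100
    pa <- assign_to_domains(pk, doms, "summit")
    ga <- assign_to_domains(gn, doms, "tss")
    am <- suppressWarnings(association_scores(pa, ga))
    want <- 0
    for (d in seq_len(n_d)) {
      id <- paste0("chr1:", doms$start[d], "-", doms$end[d])
      want <- want + sum(pa$domain_id == id, na.rm = TRUE) *
        sum(ga$domain_id == id, na.rm = TRUE)
    }
    expect_equal(sum(am$raw), want)
  }
})

test_that("column scaling gives mean 0 and unit sd where variance exists", {
  set.seed(22)
  doms <- data.frame(chrom = "chr1", start = c(0, 10000, 20000),
                     end = c(5000, 15000, 25000))
  pk <- assign_to_domains(
    data.frame(chrom = "chr1", summit = sample.int(25000L, 60),
               class = sample(c("repressor", "neutral", "activator"),
                              60, TRUE)), doms, "summit")
  gn <- data.frame(chrom = "chr1", start = sample.int(25000L, 40),
                   strand = "+", cluster = sample(c("A", "E"), 40, TRUE))
  gn$end <- gn$start + 10
  am <- suppressWarnings(association_scores(pk, assign_to_domains(gn, doms, "tss")))
  for (j in seq_len(ncol(am$scaled))) {
    if (sd(am$raw[, j]) > 0) {
      expect_equal(mean(am$scaled[, j]), 0, tolerance = 1e-9)
      expect_equal(sd(am$scaled[, j]), 1, tolerance = 1e-9)
    } else {
      expect_true(all(am$scaled[, j] == 0))
    }
  }
})

test_that("planted composition puts scaled maxima on matching cells", {
  # repressor peaks share domains with E genes, activators with A genes
  doms <- data.frame(chrom = "chr1", start = c(0, 10000), end = c(5000, 15000))
  pk <- data.frame(chrom = "chr1",
                   summit = c(rep(1000, 6), rep(11000, 6), 2000, 12000),
                   class = c(rep("repressor", 6), rep("activator", 6),
                             "neutral", "neutral"))
  gn <- data.frame(chrom = "chr1",
                   start = c(rep(1500, 5), rep(11500, 5)),
                   strand = "+",
                   cluster = c(rep("E", 5), rep("A", 5)))
  gn$end <- gn$start + 10
  pa <- assign_to_domains(pk, doms, "summit")
  ga <- assign_to_domains(gn, doms, "tss")
  am <- association_scores(pa, ga)
  expect_equal(rownames(am$scaled)[which.max(am$scaled[, "E"])], "repressor")
  expect_equal(rownames(am$scaled)[which.max(am$scaled[, "A"])], "activator")
  # permuting gene-cluster labels destroys the enrichment
  set.seed(23)
  ga_perm <- ga
  ga_perm$cluster <- c(rep(c("A", "E"), 5))
  am_p <- association_scores(pa, ga_perm)
  expect_false(
    identical(rownames(am_p$scaled)[which.max(am_p$scaled[, "E"])],
              "repressor") &&
      identical(rownames(am_p$scaled)[which.max(am_p$scaled[, "A"])],
                "activator"))
})

test_that("the matrix is invariant to input order and counts unique peaks on request", {
  set.seed(24)
  doms <- data.frame(chrom = "chr1", start = c(0, 10000), end = c(5000, 15000))
  pk <- data.frame(chrom = "chr1", summit = sample.int(15000L, 30),
                   class = sample(c("repressor", "activator"), 30, TRUE))
  gn <- data.frame(chrom = "chr1", start = sample.int(15000L, 20),
                   strand = "+", cluster = sample(c("A", "E"), 20, TRUE))
  gn$end <- gn$start + 10
  pa <- assign_to_domains(pk, doms, "summit")
  ga <- assign_to_domains(gn, doms, "tss")
  a1 <- suppressWarnings(association_scores(pa, ga))
  o1 <- sample.int(nrow(pa)); o2 <- sample.int(nrow(ga))
  a2 <- suppressWarnings(association_scores(pa[o1, ], ga[o2, ]))
  expect_equal(a1$raw, a2$raw)
  un <- suppressWarnings(association_scores(pa, ga, mode = "unique_peaks"))
  expect_true(all(un$raw <= a1$raw))
  # unique-peak counts are bounded by the number of peaks
  expect_true(all(un$raw <= nrow(pk)))
})
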