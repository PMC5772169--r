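# Regulated-gene calls, trajectory clusters, LPS-sensitivity clusters.

make_et <- function(log2means, noise_sd = 0.05, reps = 3, seed = 1,
                    genotypes = "WT", ko_mult = 0,
                    times = c(0, 1, 3, 6, 24)) {
  # log2means: genes x times matrix of planted WT log2 expression
  set.seed(seed)
  cols <- list(); vals <- list()
  for (gt in genotypes) {
    mult <- if (gt == "WT") 1 else ko_mult
    for (ti in seq_along(times)) {
      for (r in seq_len(reps)) {
        mu <- log2means[, 1] + mult * (log2means[, ti] - log2means[, 1])
        cols[[length(cols) + 1]] <- sprintf("%s_IL4_%s_%d", gt, times[ti], r)
        vals[[length(vals) + 1]] <- 2^(mu + rnorm(nrow(log2means), 0, noise_sd))
      }
    }
  }
  m <- do.call(cbind, vals)
  dimnames(m) <- list(rownames(log2means), unlist(cols))
  expression_table(m)
}

test_that("expressed-gene filter applies the 1 FPKM in any sample rule", {
  m <- rbind(allzero = rep(0, 4),
             onehit = c(0, 1.0, 0, 0),
             below = rep(0.99, 4))
  colnames(m) <- c("WT_IL4_0_1", "WT_IL4_0_2", "WT_IL4_6_1", "WT_IL4_6_2")
  kept <- expressed_genes(expression_table(m))
  expect_equal(rownames(kept$fpkm), "onehit")
})

test_that("regulated calls need both significance and fold change", {
  base <- matrix(3, nrow = 3, ncol = 5,
                 dimnames = list(c("induced", "flat", "noisy"), NULL))
  base["induced", 2] <- 5  # 4-fold at 1 h
  et <- make_et(base, noise_sd = 0.1, seed = 2)
  # inflate the noisy gene's variance manually
  noisy_cols <- seq_len(ncol(et$fpkm))
  et$fpkm["noisy", ] <- 2^(3 + rnorm(length(noisy_cols), 0, 2.5))
  calls <- call_regulated(et)
  expect_true(calls$regulated[calls$gene_id == "induced"])
  expect_equal(calls$direction[calls$gene_id == "induced"], "up")
  expect_false(calls$regulated[calls$gene_id == "flat"])
  expect_false(calls$regulated[calls$gene_id == "noisy"])
})

test_that("a repressed gene is called down", {
  base <- matrix(5, nrow = 1, ncol = 5, dimnames = list("rep", NULL))
  base[1, 3:5] <- 3
  calls <- call_regulated(make_et(base, seed = 3))
  expect_true(calls$regulated)
  expect_equal(calls$direction, "down")
})

test_that("a non-responding knockout genotype yields no knockout calls", {
  set.seed(4)
  base <- matrix(3, nrow = 40, ncol = 5,
                 dimnames = list(sprintf("g%02d", 1:40), NULL))
  base[1:20, 2:3] <- 5.5
  et <- make_et(base, noise_sd = 0.25, seed = 4, genotypes = c("WT", "KO"))
  calls <- call_regulated(et)
  expect_gt(sum(calls$regulated[1:20]), 15)
  expect_equal(sum(calls$regulated_KO), 0)
  expect_true(all(calls$genotype_dependent == calls$regulated))
})

test_that("unbalanced designs are rejected with the missing cells named", {
  m <- matrix(2, 2, 4, dimnames = list(c("a", "b"),
                                       c("WT_IL4_0_1", "WT_IL4_0_2",
                                         "WT_IL4_6_1", "KO_IL4_6_1")))
  expect_error(call_regulated(expression_table(m)), "KO:t0")
  m2 <- m
  colnames(m2) <- c("WT_IL4_0_1", "WT_IL4_0_2", "WT_IL4_6_1", "WT_IL4_6_2")
  expect_error(call_regulated(expression_table(m2), control_time = 12),
               "control time")
})

test_that("trajectory clustering recovers planted archetypes", {
  set.seed(6)
  profs <- rbind(c(2.4, 1.2, 0.4, 0.1),
                 c(2.0, 2.3, 1.9, 1.6),
                 c(0.8, 1.8, 2.3, 1.1),
                 c(0.2, 0.8, 1.6, 2.4))
  n_per <- 30
  fc <- profs[rep(1:4, each = n_per), ] + matrix(rnorm(4 * n_per * 4, 0, 0.25),
                                                 ncol = 4)
  fc <- rbind(fc, matrix(rep(c(-0.6, -1.6, -1.9, -1.7), each = n_per),
                         ncol = 4) + matrix(rnorm(n_per * 4, 0, 0.25),
                                            ncol = 4))
  rownames(fc) <- sprintf("g%03d", seq_len(nrow(fc)))
  colnames(fc) <- paste0("t", c(1, 3, 6, 24))
  cl <- trajectory_clusters(fc, k_induced = 4, seed = 1)
  truth <- data.frame(gene_id = rownames(fc),
                      cluster = rep(c("A", "B", "C", "D", "E"), each = n_per))
  expect_gte(evaluate_gene_clusters(cl, truth), 0.8)
  # the repressed archetype always lands in the repressed cluster
  expect_true(all(cl$cluster[121:150] == "E"))
  expect_false(any(cl$induced[121:150]))
})

test_that("trajectory clustering is deterministic and labels duplicates alike", {
  set.seed(8)
  fc <- matrix(runif(60, 0.2, 3), ncol = 3)
  fc[16:20, ] <- fc[rep(15, 5), ]  # duplicated rows
  rownames(fc) <- sprintf("g%02d", 1:20)
  colnames(fc) <- paste0("t", 1:3)
  a <- trajectory_clusters(fc, k_induced = 3, seed = 9)
  b <- trajectory_clusters(fc, k_induced = 3, seed = 9)
  expect_identical(a, b)
  expect_equal(length(unique(a$cluster[15:20])), 1L)
  expect_error(trajectory_clusters(fc, k_induced = 25, seed = 1),
               "exceeds")
})

test_that("all-repressed input forms a single repressed cluster", {
  fc <- matrix(-runif(30, 0.5, 2), ncol = 3,
               dimnames = list(sprintf("g%02d", 1:10), paste0("t", 1:3)))
  cl <- trajectory_clusters(fc, k_induced = 4, seed = 1)
  expect_equal(unique(cl$cluster), "E")
})

test_that("LPS sensitivity clusters split by pretreatment response", {
  set.seed(10)
  n <- 30
  base <- runif(4 * n, 2, 5)
  eff <- c(rep(2.5, 3 * n), rep(0, n))
  pre_mult <- c(rep(0.5, n), rep(1, n), rep(1.5, n), rep(1, n))
  cols <- c(); vals <- list()
  for (tr in c("control", "LPS", "IL4LPS")) {
    e <- switch(tr, control = 0, LPS = eff, IL4LPS = eff * pre_mult)
    for (r in 1:3) {
      cols <- c(cols, sprintf("WT_%s_3_%d", tr, r))
      vals[[length(vals) + 1]] <- 2^(base + e + rnorm(4 * n, 0, 0.2))
    }
  }
  m <- do.call(cbind, vals)
  dimnames(m) <- list(sprintf("g%03d", seq_len(4 * n)), cols)
  cl <- lps_response_clusters(expression_table(m))
  expect_gt(mean(cl$cluster[1:n] == 1, na.rm = TRUE), 0.85)
  expect_gt(mean(cl$cluster[n + 1:n] == 2, na.rm = TRUE), 0.85)
  expect_gt(mean(cl$cluster[2 * n + 1:n] == 3, na.rm = TRUE), 0.85)
  # non-induced genes are rarely called induced (type-I control)
  expect_lt(mean(cl$lps_induced[3 * n + 1:n]), 0.2)

  m2 <- m[, !grepl("IL4LPS", colnames(m))]
  expect_error(lps_response_clusters(expression_table(m2)), "IL4LPS")
})
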