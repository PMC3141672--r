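mat_from <- function(values) {
  # values: named list gene -> numeric vector (equal lengths)
  k <- length(values[[1]])
  out <- tibble::tibble(gene_symbol = names(values))
  for (j in seq_len(k)) {
    out[[sprintf("P:r%d", j)]] <- vapply(values, `[`, numeric(1), j)
  }
  out
}

test_that("SAM d statistic matches its closed form", {
  m <- mat_from(list(g1 = c(-1, 1), g2 = c(1, 2)))
  res <- sam_test(m, analysis_config(s0 = 0.1))
  expect_equal(res$d[res$gene_symbol == "g1"], 0)
  m2 <- mat_from(list(g1 = c(1, 2, 3), g2 = c(0.5, -0.5, 0.1)))
  res2 <- sam_test(m2, analysis_config(s0 = 0))
  # d = mean/(se) = 2 / (1/sqrt(3)) = 3.4641
  expect_equal(res2$d[res2$gene_symbol == "g1"], 2 / (1 / sqrt(3)),
               tolerance = 1e-6)
})

test_that("SAM sign-flip p equals exhaustive enumeration per gene", {
  withr::with_seed(67, {
    m <- mat_from(list(g1 = rnorm(3, 1), g2 = rnorm(3), g3 = rnorm(3, -2)))
  })
  cfg <- analysis_config(s0 = 0.2)
  res <- sam_test(m, cfg)
  y <- as.matrix(m[, -1])
  se <- apply(y, 1, function(v) sd(v) / sqrt(3))
  for (g in 1:3) {
    d_obs <- mean(y[g, ]) / (se[g] + 0.2)
    flips <- expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))
    d_null <- apply(flips, 1, function(e) {
      v <- as.numeric(e) * y[g, ]
      mean(v) / (sd(v) / sqrt(3) + 0.2)
    })
    expect_equal(res$p[g], mean(abs(d_null) >= abs(d_obs) - 1e-12))
  }
})

test_that("rank product attains 1 for a gene top-ranked everywhere", {
  m <- mat_from(list(g1 = c(3, 3), g2 = c(1, 2), g3 = c(-1, 0)))
  rp <- rank_product(m, "up")
  expect_equal(rp$rank_product[rp$gene_symbol == "g1"], 1)
})

test_that("single-column rank product is the column rank", {
  m <- tibble::tibble(gene_symbol = c("a", "b", "c"),
                      `P:r1` = c(0.5, 2, -1))
  expect_equal(rank_product(m, "up")$rank_product, c(2, 1, 3))
  expect_equal(rank_product(m, "down")$rank_product, c(2, 3, 1))
})

test_that("hand-rankable 3x2 example gives RP (1, 2, 3)", {
  m <- mat_from(list(g1 = c(1.0, 0.9), g2 = c(0.5, 0.2),
                     g3 = c(-0.3, -0.1)))
  expect_equal(rank_product(m, "up")$rank_product, c(1, 2, 3))
})

test_that("rank product is invariant under strictly monotone per-column transforms", {
  withr::with_seed(71, {
    m <- mat_from(list(a = rnorm(4), b = rnorm(4), c = rnorm(4),
                       d = rnorm(4), e = rnorm(4)))
  })
  base <- rank_product(m, "up")
  warped <- m
  warped$`P:r1` <- exp(warped$`P:r1`)
  warped$`P:r2` <- warped$`P:r2`^3
  warped$`P:r3` <- atan(warped$`P:r3`)
  warped$`P:r4` <- 5 * warped$`P:r4` + 2
  expect_equal(rank_product(warped, "up"), base)
})

test_that("exhaustive pfp matches the printed 3-gene worked example", {
  m <- mat_from(list(g1 = c(1.0, 0.9), g2 = c(0.5, 0.2),
                     g3 = c(-0.3, -0.1)))
  res <- rankprod_significance(m, "up")
  # P(null RP <= 1) = 1/9, E = 3 * 1/9 = 1/3, pfp(g1) = (1/3)/1
  expect_equal(res$E[res$gene_symbol == "g1"], 1 / 3)
  expect_equal(res$pfp[res$gene_symbol == "g1"], 1 / 3)
  expect_equal(res$nominal_p[res$gene_symbol == "g1"], 1 / 9)
})

test_that("exhaustive mode equals full (G!)^k enumeration on random instances", {
  for (seed in c(3, 4)) {
    withr::with_seed(seed, {
      G <- sample(3:5, 1)
      vals <- lapply(seq_len(G), function(i) rnorm(2))
      names(vals) <- sprintf("g%d", seq_len(G))
      m <- mat_from(vals)
    })
    for (dir in c("up", "down")) {
      res <- rankprod_significance(m, dir)
      y <- as.matrix(m[, -1])
      ranks <- vapply(1:2, function(j) {
        if (dir == "up") rank(-y[, j]) else rank(y[, j])
      }, numeric(G))
      E_oracle <- oracle_rankprod_E(ranks, res$rank_product)
      expect_equal(res$E, E_oracle, tolerance = 1e-12)
    }
  }
})

test_that("Monte-Carlo pfp agrees with exhaustive within 3 MC standard errors", {
  withr::with_seed(73, {
    m <- mat_from(list(a = rnorm(2), b = rnorm(2), c = rnorm(2),
                       d = rnorm(2), e = rnorm(2)))
  })
  B <- 2000L
  exact <- rankprod_significance(m, "up", mode = "exhaustive")
  mc <- rankprod_significance(m, "up",
                              analysis_config(n_permutations = B, seed = 5),
                              mode = "montecarlo")
  for (g in 1:5) {
    p_ex <- exact$E[g] / 5
    se <- sqrt(p_ex * (1 - p_ex) / (B * 5)) + 1e-9
    expect_lt(abs(mc$E[g] / 5 - p_ex), 3 * se)
  }
})

test_that("single-column pfp ordering follows the value ordering", {
  m <- tibble::tibble(gene_symbol = sprintf("g%d", 1:6),
                      `P:r1` = c(3, -1, 2, 0.5, -2, 1))
  res <- rankprod_significance(m, "up",
                               analysis_config(n_permutations = 200))
  # with one column every permutation contains each rank once, so pfp is
  # constant; the nominal p must follow the value ordering exactly
  expect_equal(order(res$nominal_p), order(res$rank_product))
  expect_equal(order(res$rank_product), order(-m$`P:r1`))
  expect_true(all(diff(res$pfp[order(res$rank_product)]) >= 0))
})

test_that("BH and Holm reproduce textbook step-up/step-down arithmetic", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(c(0.001, 0.02)), c(0.002, 0.02))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("zero-noise meta-analysis recovers the truth set exactly", {
  tx <- generate_transcriptome(60, seed = 79)
  truth <- make_truth(tx, n_de = 6, coverage = 1, include_dge = FALSE,
                      platforms = c("AGI", "OPE"), seed = 79)
  nm <- noise_model(probe_sd = 0, replicate_sd = 0)
  mats <- lapply(setNames(c("AGI", "OPE"), c("AGI", "OPE")), function(p) {
    pd <- generate_platform_data(truth, tx, p, noise = nm,
                                 bad_probe_fraction = 0, seed = 79)
    summarize_gene(pd$ratios, assign_genes(map_probes(pd$probes, tx)))
  })
  merged <- build_merged_matrix(mats)
  mr <- meta_rankprod(merged, analysis_config(n_permutations = 300,
                                              seed = 79))
  expect_setequal(called_genes(mr, "up"), truth$de_up)
  expect_setequal(called_genes(mr, "down"), truth$de_down)
})

test_that("the fold-change gate excludes small effects regardless of p", {
  # median log2ratio 0.2 -> FC 2^0.2 = 1.1487 < 1.2: never called
  withr::with_seed(83, {
    g <- sprintf("g%02d", 1:40)
    vals <- matrix(rnorm(40 * 6, 0, 0.05), 40)
    vals[1, ] <- 0.2
  })
  m <- tibble::tibble(gene_symbol = g)
  for (j in 1:6) m[[sprintf("P:r%d", j)]] <- vals[, j]
  merged <- build_merged_matrix(list(P = m))
  mr <- meta_rankprod(merged, analysis_config(n_permutations = 300,
                                              seed = 83))
  r <- mr$results[mr$results$gene_symbol == "g01" &
                    mr$results$direction == "up", ]
  expect_lt(r$adjusted_p, 0.05)      # clearly top-ranked
  expect_lt(r$median_fc, 1.2)        # but fails the FC gate
  expect_false(r$called)
  expect_equal(r$median_fc, 2^0.2)
})

test_that("meta results carry stratum structure and tidy/glance interfaces", {
  withr::with_seed(89, {
    mats <- list(
      P1 = tibble::tibble(gene_symbol = sprintf("g%02d", 1:20),
                          `P1:r1` = rnorm(20), `P1:r2` = rnorm(20)),
      P2 = tibble::tibble(gene_symbol = sprintf("g%02d", 5:24),
                          `P2:r1` = rnorm(20), `P2:r2` = rnorm(20)))
  })
  merged <- build_merged_matrix(mats)
  mr <- meta_rankprod(merged, analysis_config(n_permutations = 150))
  td <- tidy(mr)
  expect_true(all(c("gene_symbol", "direction", "pfp", "adjusted_p",
                    "stratum") %in% names(td)))
  # each gene tested in exactly one stratum, both directions
  expect_equal(nrow(td), 2 * length(unique(td$gene_symbol)))
  gl <- glance(mr)
  expect_equal(gl$n_genes, 24)
  expect_equal(gl$n_strata, 3)
})
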