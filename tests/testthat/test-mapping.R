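test_that("single-locus scan agrees with an explicit linear-model oracle", {
  # 6 lines, 2 environments: compare against anova() on lm fits
  set.seed(61)
  g <- coin_genotypes(6, c("m1", "m2"), seed = 61)
  m <- matrix(c(4.1, 5.2, 3.9, 6.0, 5.5, 4.4,
                7.2, 8.1, 6.8, 9.0, 8.4, 7.1), 6, 2,
              dimnames = list(g$line_ids, c("E1", "E2")))
  b <- validate_dataset(g, pheno_from_matrix(m))
  sc <- scan_single_locus(b, "y")
  for (mk in c("m1", "m2")) {
    df <- data.frame(y = as.vector(m), env = rep(c("E1", "E2"), each = 6),
                     x = rep(g$codes[, mk], 2))
    f0 <- lm(y ~ env, df)
    f1 <- lm(y ~ env + env:x, df)
    oracle <- anova(f0, f1)$F[2]
    expect_equal(sc$F_statistic[sc$term == mk], oracle, tolerance = 1e-10)
  }
})

test_that("noiseless data saturate the scan and recover the planted
           effect exactly", {
  g <- coin_genotypes(60, paste0("m", 1:2), seed = 62)
  tr <- qts_truth(mu = 8, additive = data.frame(marker_id = "m1", a = -1.3),
                  env_effects = c(E1 = 1, E2 = -1), residual_sd = 0)
  p <- simulate_phenotypes(g, tr, seed = 1)
  b <- validate_dataset(g, p)
  sc <- scan_single_locus(b, "trait")
  expect_equal(sc$F_statistic[sc$term == "m1"], 1e15)
  expect_equal(sc$a_hat[sc$term == "m1"], -1.3, tolerance = 1e-10)

  # swapping parent coding negates the effect but not the F statistic
  g2 <- g; g2$codes <- -g$codes
  sc2 <- scan_single_locus(validate_dataset(g2, p), "trait")
  expect_equal(sc2$a_hat[sc2$term == "m1"], 1.3, tolerance = 1e-10)
  expect_equal(sc2$F_statistic, sc$F_statistic)
})

test_that("scan results are invariant to line and marker ordering", {
  g <- coin_genotypes(40, paste0("m", 1:5), seed = 63)
  tr <- qts_truth(mu = 0, additive = data.frame(marker_id = "m3", a = 1),
                  residual_sd = 1)
  p <- simulate_phenotypes(g, tr, seed = 2)
  b <- validate_dataset(g, p)
  sc <- scan_single_locus(b, "trait")
  # permute lines
  set.seed(1)
  ord <- sample(40)
  g2 <- g
  g2$codes <- g$codes[ord, ]
  g2$line_ids <- g$line_ids[ord]
  sc2 <- scan_single_locus(validate_dataset(g2, p), "trait")
  expect_equal(sc2$F_statistic, sc$F_statistic)
  # scan a marker subset in different order
  sc3 <- scan_single_locus(b, "trait", candidates = c("m4", "m3"))
  expect_equal(sc3$F_statistic[sc3$term == "m3"],
               sc$F_statistic[sc$term == "m3"])
})

test_that("epistasis scan recovers planted interactions and skips
           degenerate pairs", {
  g <- coin_genotypes(80, paste0("m", 1:3), seed = 64)
  g$codes <- cbind(g$codes, m4 = g$codes[, "m1"])   # duplicated marker
  g$map <- marker_map(paste0("m", 1:4), "1", c(1000L, 2000L, 3000L, 4000L))
  tr <- qts_truth(mu = 0, epistatic = data.frame(marker_i = "m1",
                                                 marker_j = "m2", aa = 0.9),
                  residual_sd = 0)
  p <- simulate_phenotypes(g, tr, seed = 3)
  b <- validate_dataset(g, p)
  sc <- scan_epistasis(b, "trait", pairs = rbind(c("m1", "m2"),
                                                 c("m1", "m4")))
  expect_equal(sc$aa_hat[1], 0.9, tolerance = 1e-10)
  expect_equal(sc$F_statistic[1], 1e15)
  expect_true(is.na(sc$F_statistic[2]))             # collinear pair
})

test_that("epistasis p-values are uniform under an additive-only null", {
  # the product term tests clean of the marginal effects it adjusts for
  pv <- numeric(200)
  for (r in seq_len(200)) {
    g <- coin_genotypes(60, paste0("m", 1:2), seed = 700 + r)
    tr <- qts_truth(mu = 0,
                    additive = data.frame(marker_id = c("m1", "m2"),
                                          a = c(1, -0.7)),
                    residual_sd = 1)
    p <- simulate_phenotypes(g, tr, environments = c("E1", "E2"),
                             seed = 900 + r)
    sc <- scan_epistasis(validate_dataset(g, p), "trait",
                         pairs = rbind(c("m1", "m2")))
    pv[r] <- 10^(-sc$neg_log10_p[1])
  }
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("permutation threshold is reproducible and honours its
           boundary contract", {
  g <- coin_genotypes(50, paste0("m", 1:10), seed = 65)
  tr <- qts_truth(mu = 0, residual_sd = 1)
  p <- simulate_phenotypes(g, tr, seed = 4)
  b <- validate_dataset(g, p)
  t1 <- permutation_threshold(b, "trait", n_permutations = 150, seed = 9)
  t2 <- permutation_threshold(b, "trait", n_permutations = 150, seed = 9)
  expect_identical(t1$threshold, t2$threshold)
  expect_identical(t1$max_stats, t2$max_stats)
  # alpha = 1: threshold is the smallest max-F draw
  t3 <- permutation_threshold(b, "trait", alpha = 1, n_permutations = 150,
                              seed = 9)
  expect_equal(t3$threshold, min(t1$max_stats))
  expect_gt(t1$threshold, t3$threshold)
})

test_that("stepwise selection respects the threshold and deduplicates", {
  # pure-noise data with a high threshold: nothing enters
  g <- coin_genotypes(60, paste0("m", 1:4), seed = 66)
  tr <- qts_truth(mu = 0, residual_sd = 1)
  p <- simulate_phenotypes(g, tr, seed = 5)
  b <- validate_dataset(g, p)
  s1 <- scan_single_locus(b, "trait")
  empty <- stepwise_select(b, "trait", 1e6, s1)
  expect_equal(nrow(empty), 0)

  # a strong locus duplicated as a second column enters exactly once
  g2 <- coin_genotypes(120, paste0("m", 1:2), seed = 67)
  g2$codes[, "m2"] <- g2$codes[, "m1"]
  tr2 <- qts_truth(mu = 0, additive = data.frame(marker_id = "m1", a = 2),
                   residual_sd = 1)
  p2 <- simulate_phenotypes(g2, tr2, seed = 6)
  b2 <- validate_dataset(g2, p2)
  s2 <- scan_single_locus(b2, "trait")
  sel <- stepwise_select(b2, "trait", 10, s2)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$marker_i, "m1")
})

test_that("stepwise finds two planted unlinked loci most of the time", {
  # h2 ~ 15% and 10% at 138 lines
  vp <- 10
  a1 <- sqrt(0.15 * vp); a2 <- sqrt(0.10 * vp)
  resid <- sqrt(vp - a1^2 - a2^2)
  cfg <- sim_map_config(n_chromosomes = 2, markers_per_chromosome = 10,
                        n_lines = 138)
  both <- logical(50)
  for (r in seq_len(50)) {
    cfg$seed <- 40 + r
    g <- simulate_ril_genotypes(cfg, mode = "mosaic")
    tr <- qts_truth(mu = 0,
                    additive = data.frame(marker_id = c("c1m5", "c2m5"),
                                          a = c(a1, a2)),
                    residual_sd = resid)
    p <- simulate_phenotypes(g, tr, environments = c("E1", "E2"),
                             seed = 140 + r)
    b <- validate_dataset(g, p)
    thr <- permutation_threshold(b, "trait", n_permutations = 300,
                                 seed = 240 + r)
    s1 <- scan_single_locus(b, "trait")
    sel <- stepwise_select(b, "trait", thr, s1)
    both[r] <- all(c("c1m5", "c2m5") %in% sel$marker_i)
  }
  expect_gte(mean(both), 0.8)
})
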