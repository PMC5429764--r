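test_that("summary statistics reproduce CV and D from sample moments", {
  y1 <- exact_moments(138, 22.86, 6.10, seed = 1)
  y2 <- exact_moments(138, 17.69, 3.47, seed = 2)
  m <- cbind(E1 = y1, E2 = y2)
  rownames(m) <- sprintf("L%03d", 1:138)
  sm <- summarize_traits(pheno_from_matrix(m, trait = "GYD"))
  expect_equal(round(sm$per_environment$cv[1], 2), 26.68)
  expect_equal(round(sm$per_environment$cv[2], 2), 19.62)
  expect_equal(round(sm$difference$D, 2), 5.17)
  expect_equal(sm$difference$significance, "**")

  # identical environments: D = 0 and not significant
  m2 <- cbind(E1 = y1, E2 = y1)
  rownames(m2) <- rownames(m)
  sm2 <- summarize_traits(pheno_from_matrix(m2))
  expect_equal(sm2$difference$D, 0)
  expect_equal(sm2$difference$significance, "")
})

test_that("phenotypic correlations behave at the boundaries and under a
           known bivariate normal", {
  set.seed(7)
  n <- 138
  x <- rnorm(n)
  m <- matrix(rnorm(2 * n), n, 2, dimnames = list(sprintf("L%03d", 1:n),
                                                  c("E1", "E2")))
  recs <- rbind(
    as.data.frame(pheno_from_matrix(m, trait = "t1")),
    as.data.frame(pheno_from_matrix(-m, trait = "t2")))
  p <- phenotype_table(recs, environments = c("E1", "E2"))
  cr <- phenotypic_correlations(p)
  expect_equal(unname(diag(cr$E1$r)), c(1, 1))
  expect_equal(cr$E1$r["t1", "t2"], -1)
  expect_true(isSymmetric(cr$E2$r))

  # true rho = 0.6 at n = 138: estimate within the Fisher-z window and
  # strongly significant
  set.seed(8)
  a <- rnorm(n); b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(n)
  m2 <- cbind(E1 = a)
  rownames(m2) <- sprintf("L%03d", 1:n)
  recs2 <- rbind(as.data.frame(pheno_from_matrix(m2, trait = "t1",
                                                 envs = "E1")),
                 within(as.data.frame(pheno_from_matrix(m2, trait = "t2",
                                                        envs = "E1")),
                        value <- b))
  p2 <- phenotype_table(recs2, environments = "E1")
  cr2 <- phenotypic_correlations(p2)
  expect_lt(abs(cr2$E1$r["t1", "t2"] - 0.6), 0.15)
  expect_lt(cr2$E1$p["t1", "t2"], 0.005)
  expect_equal(cr2$E1$stars["t1", "t2"], "***")
})

test_that("genotypic-value shrinkage follows the closed form", {
  # zero residual variance: genotypic values are line means
  set.seed(10)
  gk <- rnorm(80, 0, 2)
  m <- cbind(E1 = 5 + gk, E2 = 1 + gk)
  rownames(m) <- sprintf("L%03d", 1:80)
  gv <- predict_genotypic_values(pheno_from_matrix(m, trait = "y"))
  expect_equal(gv$y, unname(rowMeans(m)), tolerance = 1e-10)
  expect_equal(mean(gv$y), mean(m))

  # zero genetic variance: values shrink to the grand mean
  m0 <- cbind(E1 = rnorm(200), E2 = rnorm(200))
  rownames(m0) <- sprintf("L%03d", 1:200)
  gv0 <- predict_genotypic_values(pheno_from_matrix(m0, trait = "y"))
  lam0 <- attr(gv0, "variance_components")$y[["lambda"]]
  expect_lt(lam0, 0.5)
  expect_lt(sd(gv0$y), 0.5 * sd(rowMeans(m0)))

  # known variance components: lambda ~ s2g / (s2g + s2e/2)
  set.seed(11)
  n <- 600
  gk <- rnorm(n, 0, 2)                      # s2g = 4
  eps <- matrix(rnorm(2 * n, 0, 2), n, 2)   # s2e = 4
  m2 <- cbind(E1 = 3 + gk + eps[, 1], E2 = -3 + gk + eps[, 2])
  rownames(m2) <- sprintf("L%04d", 1:n)
  gv2 <- predict_genotypic_values(pheno_from_matrix(m2, trait = "y"))
  vc <- attr(gv2, "variance_components")$y
  expect_lt(abs(vc[["lambda"]] - 4 / (4 + 4 / 2)), 0.08)
  expect_lt(abs(vc[["sigma2_g"]] - 4), 0.8)
  expect_lt(abs(vc[["sigma2_eps"]] - 4), 0.6)

  # single environment is refused with advice
  expect_error(predict_genotypic_values(
    pheno_from_matrix(m2[, 1, drop = FALSE])), "raw line means")
})

test_that("genotypic correlations separate shared from disjoint
           architectures", {
  g <- coin_genotypes(600, paste0("m", 1:4), seed = 12)
  shared <- data.frame(marker_id = c("m1", "m2"), a = c(1.5, -1))
  t_a <- qts_truth(mu = 0, additive = shared, residual_sd = 0.3)
  t_b <- qts_truth(mu = 2, additive = shared, residual_sd = 0.3)
  t_c <- qts_truth(mu = 0, additive = data.frame(marker_id = c("m3", "m4"),
                                                 a = c(1.2, 0.9)),
                   residual_sd = 0.3)
  recs <- rbind(
    as.data.frame(simulate_phenotypes(g, t_a, seed = 1, trait = "A")),
    as.data.frame(simulate_phenotypes(g, t_b, seed = 2, trait = "B")),
    as.data.frame(simulate_phenotypes(g, t_c, seed = 3, trait = "C")))
  p <- phenotype_table(recs, environments = c("E1", "E2"))
  gv <- predict_genotypic_values(p)
  gc_ <- genotypic_correlations(gv)
  expect_gt(gc_$r["A", "B"], 0.95)            # same QTS set
  expect_lt(abs(gc_$r["A", "C"]), 0.15)       # disjoint, unlinked
  expect_equal(unname(diag(gc_$r)), rep(1, 3))
})

test_that("conditioning removes the given trait and nothing else", {
  set.seed(13)
  n <- 5000
  delta <- rnorm(n, 0, 2)
  given <- rnorm(n, 10, 3)
  target <- given + delta
  m_t <- cbind(E1 = target, E2 = target + 1)
  m_g <- cbind(E1 = given, E2 = given)
  rownames(m_t) <- rownames(m_g) <- sprintf("L%04d", 1:n)
  p <- phenotype_table(rbind(
    as.data.frame(pheno_from_matrix(m_t, trait = "T1")),
    as.data.frame(pheno_from_matrix(m_g, trait = "T2"))),
    environments = c("E1", "E2"))
  cond <- conditional_phenotypes(p, "T1", "T2")
  expect_equal(trait_names(cond), "T1|T2")
  # zero within-environment covariance with the given trait
  for (h in c("E1", "E2")) {
    yc <- cond$value[cond$environment == h]
    yg <- m_g[match(cond$line_id[cond$environment == h],
                    rownames(m_g)), h]
    expect_lt(abs(cov(yc, yg)), 1e-8)
  }
  # the independent residual component is preserved
  yc1 <- cond$value[cond$environment == "E1"]
  d1 <- delta[match(cond$line_id[cond$environment == "E1"],
                    rownames(m_t))]
  expect_gt(cor(yc1, d1), 0.99)
  # conditioning is idempotent
  p2 <- append_phenotypes(p, cond)
  cond2 <- conditional_phenotypes(p2, "T1|T2", "T2")
  expect_equal(cond2$value, cond$value, tolerance = 1e-10)

  # conditioning on itself collapses each environment to a constant
  condself <- conditional_phenotypes(p, "T1", "T1")
  expect_lt(var(condself$value[condself$environment == "E1"]), 1e-16)

  # conditioning on an independent trait changes almost nothing
  m_i <- cbind(E1 = rnorm(n), E2 = rnorm(n))
  rownames(m_i) <- rownames(m_t)
  p3 <- phenotype_table(rbind(
    as.data.frame(pheno_from_matrix(m_t, trait = "T1")),
    as.data.frame(pheno_from_matrix(m_i, trait = "T3"))),
    environments = c("E1", "E2"))
  cond3 <- conditional_phenotypes(p3, "T1", "T3")
  y0 <- m_t[match(cond3$line_id[cond3$environment == "E1"],
                  rownames(m_t)), "E1"]
  expect_gt(cor(cond3$value[cond3$environment == "E1"], y0), 0.99)

  # zero-variance given trait is an error
  m_z <- m_i; m_z[] <- 1
  pz <- phenotype_table(rbind(
    as.data.frame(pheno_from_matrix(m_t, trait = "T1")),
    as.data.frame(pheno_from_matrix(m_z, trait = "Z"))),
    environments = c("E1", "E2"))
  expect_error(conditional_phenotypes(pz, "T1", "Z"), "zero variance")
})
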