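test_that("status classification is pure set logic", {
  u <- list(A = c("a", "ae"), B = "a")
  # identical sets: retained
  expect_equal(compare_term_sets(u, u)$status, rep("retained", 2))
  # component lost: retained_component_changed
  cmp <- compare_term_sets(u, list(A = "a", B = "a"))
  expect_equal(cmp$status[cmp$term == "A"], "retained_component_changed")
  # term lost / gained
  cmp2 <- compare_term_sets(list(A = "a", B = "a"),
                            list(A = "a", C = "a"))
  expect_equal(cmp2$status[cmp2$term == "B"], "absent_under_conditioning")
  expect_equal(cmp2$status[cmp2$term == "C"], "novel_conditional")

  # property: status depends only on membership and set equality
  set.seed(81)
  comps <- c("a", "ae", "aa")
  for (r in 1:50) {
    terms_u <- sample(LETTERS[1:6], sample(0:4, 1))
    terms_c <- sample(LETTERS[1:6], sample(0:4, 1))
    u2 <- setNames(lapply(terms_u, function(t)
      sample(comps, sample(1:3, 1))), terms_u)
    c2 <- setNames(lapply(terms_c, function(t)
      sample(comps, sample(1:3, 1))), terms_c)
    cmp <- compare_term_sets(u2, c2)
    expect_setequal(cmp$term, union(terms_u, terms_c))
    for (i in seq_len(nrow(cmp))) {
      t <- cmp$term[i]
      expected <- if (t %in% terms_u && t %in% terms_c) {
        if (setequal(u2[[t]], c2[[t]])) "retained"
        else "retained_component_changed"
      } else if (t %in% terms_u) "absent_under_conditioning"
      else "novel_conditional"
      expect_equal(cmp$status[i], expected)
    }
  }
})

test_that("rendered QTS tables are deterministic and round-trip", {
  # header-only table for an empty model
  tmp <- withr::local_tempfile(fileext = ".tsv")
  render_qts_table(NULL, tmp)
  empty <- read.delim(tmp)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("trait", "qts", "component", "effect", "h2") %in%
                    names(empty)))

  # fitted model: one row per component, ae rows labelled by environment
  g <- coin_genotypes(300, paste0("m", 1:2), seed = 82)
  tr <- qts_truth(mu = 10,
                  additive = data.frame(marker_id = "m1", a = -1.5),
                  env_effects = c(E1 = 2, E2 = -2),
                  ae = data.frame(marker_id = "m1",
                                  environment = c("E1", "E2"),
                                  ae = c(-0.65, 0.65)),
                  residual_sd = 2)
  p <- simulate_phenotypes(g, tr, seed = 10, trait = "GYD")
  b <- validate_dataset(g, p)
  terms <- data.frame(type = "marker", marker_i = "m1",
                      marker_j = NA_character_, stringsAsFactors = FALSE)
  fit <- estimate_effects_mcmc(b, "GYD", terms, n_iter = 2000,
                               burn_in = 500, thin = 5, seed = 4)
  tab <- render_qts_table(fit, tmp)
  expect_equal(tab$component, c("a", "ae1", "ae2"))
  back <- read.delim(tmp, colClasses = "character")
  expect_equal(back$effect, tab$effect)
  expect_equal(back$h2[1], tab$h2[1])
  # effect sizes rounded to two decimals
  expect_true(all(grepl("^-?[0-9]+\\.[0-9]{2}$", tab$effect)))
})

test_that("network export lists epistatic edges and environment-specific
           nodes", {
  # no epistasis: zero edges
  g <- coin_genotypes(500, paste0("m", 1:3), seed = 83)
  tr <- qts_truth(mu = 0,
                  additive = data.frame(marker_id = "m1", a = 1.5),
                  env_effects = c(E1 = 1, E2 = -1),
                  ae = data.frame(marker_id = "m1",
                                  environment = c("E1", "E2"),
                                  ae = c(-0.8, 0.8)),
                  residual_sd = 1)
  p <- simulate_phenotypes(g, tr, seed = 11, trait = "GYD")
  b <- validate_dataset(g, p)
  fit_a <- estimate_effects_mcmc(
    b, "GYD", data.frame(type = "marker", marker_i = c("m1", "m2"),
                         marker_j = NA_character_),
    n_iter = 2000, burn_in = 500, thin = 5, seed = 5)
  net_a <- export_network(list(fit_a))
  expect_equal(nrow(net_a$edges), 0)
  # the locus with a real interaction is flagged environment-specific,
  # the null locus is not
  expect_true(net_a$nodes$environment_specific[net_a$nodes$term == "m1"])
  expect_false(net_a$nodes$environment_specific[net_a$nodes$term == "m2"])

  # one epistatic pair: exactly one edge
  tr2 <- qts_truth(mu = 0, epistatic = data.frame(marker_i = "m2",
                                                  marker_j = "m3",
                                                  aa = 1),
                   residual_sd = 1)
  p2 <- simulate_phenotypes(g, tr2, seed = 12, trait = "NP")
  b2 <- validate_dataset(g, p2)
  fit_b <- estimate_effects_mcmc(
    b2, "NP", data.frame(type = "pair", marker_i = "m2", marker_j = "m3"),
    n_iter = 2000, burn_in = 500, thin = 5, seed = 6)
  net <- export_network(list(fit_a, fit_b))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$marker_i, "m2")
  expect_equal(net$edges$marker_j, "m3")
})

test_that("the pipeline runs end to end, writes a manifest and is
           deterministic", {
  cfgl <- list(
    simulate = list(traits = c("GYD", "NP"), n_lines = 100,
                    markers_per_chromosome = 3, n_chromosomes = 12),
    conditionings = list(GYD = list("NP")),
    n_permutations = 120, per_chromosome_k = 4, epistasis = FALSE,
    n_iter = 800, burn_in = 200, thin = 4, seed = 5)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  res <- run_pipeline(cfgl, out_dir = out1)
  expect_setequal(res$manifest$unconditional_models, c("GYD", "NP"))
  expect_equal(res$manifest$conditional_models, "GYD|NP")
  expect_true(all(c("summary.tsv", "qts_GYD.tsv", "qts_NP.tsv",
                    "qts_GYD.NP.tsv", "comparison_GYD.tsv",
                    "network_nodes.tsv", "network_edges.tsv",
                    "genotypes.tsv", "phenotypes.csv") %in%
                    res$manifest$files))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  # every comparison status is one of the four scenarios
  if (!is.null(res$comparison) && nrow(res$comparison))
    expect_true(all(res$comparison$status %in%
                      c("retained", "retained_component_changed",
                        "absent_under_conditioning", "novel_conditional")))
  # re-running the same config reproduces every table byte for byte
  run_pipeline(cfgl, out_dir = out2)
  for (f in res$manifest$files)
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)),
                     label = paste("file", f))
  # a YAML config behaves like the in-memory list
  cfg_yaml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfgl, cfg_yaml)
  out3 <- withr::local_tempdir()
  res3 <- run_pipeline(cfg_yaml, out_dir = out3)
  expect_identical(readLines(file.path(out1, "qts_GYD.tsv")),
                   readLines(file.path(out3, "qts_GYD.tsv")))
})
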