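# per-component least-squares tests in the final model: conditional F and
# -log10 p for the main (a / aa) and environment-interaction (ae / aae)
# parts of every term
.component_tests <- function(d, terms) {
  H <- length(d$envs)
  n <- nrow(d$codes)
  N <- n * H
  ystack <- as.vector(d$y)
  X0 <- matrix(0, N, H)
  for (h in seq_len(H)) X0[(h - 1L) * n + seq_len(n), h] <- 1
  xs_of <- function(i) {
    x <- if (terms$type[i] == "pair")
      d$codes[, terms$marker_i[i]] * d$codes[, terms$marker_j[i]]
    else d$codes[, terms$marker_i[i]]
    rep(x, H)
  }
  envidx <- rep(seq_len(H), each = n)
  Cdev <- stats::contr.sum(H)                     # H x (H-1) deviations
  main_cols <- lapply(seq_len(nrow(terms)), xs_of)
  dev_cols <- lapply(main_cols, function(xs)
    xs * Cdev[envidx, , drop = FALSE])
  Xfull <- do.call(cbind, c(list(X0), rbind(main_cols, dev_cols)))
  fit_full <- lm.fit(Xfull, ystack)
  rss_full <- sum(fit_full$residuals^2)
  rk_full <- fit_full$rank
  drop_test <- function(drop) {
    keep <- setdiff(seq_len(ncol(Xfull)), drop)
    fit0 <- lm.fit(Xfull[, keep, drop = FALSE], ystack)
    q <- rk_full - fit0$rank
    df2 <- N - rk_full
    if (q <= 0L || df2 <= 0L) return(c(NA_real_, NA_real_))
    f <- (sum(fit0$residuals^2) - rss_full) / q / (rss_full / df2)
    if (!is.finite(f) || rss_full <= 1e-10 * sum(ystack^2) / N) f <- 1e15
    f <- max(f, 0)
    c(f, .nlp(f, q, df2))
  }
  # column bookkeeping: X0 (H) then alternating main/dev blocks per term
  res <- list()
  off <- H
  for (i in seq_len(nrow(terms))) {
    main_at <- off + 1L
    dev_at <- off + 1L + seq_len(H - 1L)
    res[[i]] <- list(main = drop_test(main_at), dev = drop_test(dev_at))
    off <- off + H
  }
  res
}

#' Gibbs-sampler estimation of QTS effects
#'
#' Fits the saturated genetic model to the selected terms by Markov chain
#' Monte Carlo. Fixed effects (population mean, additive `a`, epistatic
#' `aa`) carry flat priors and are drawn jointly from their conditional
#' normal; random effects (environment `e_h`, additive-by-environment
#' `ae_hi`, epistasis-by-environment `aae_hij`) are drawn singly with
#' normal shrinkage under their variance components; the residual variance
#' uses the Jeffreys prior and the random-effect variances weakly
#' informative scaled-inverse-chi-squared priors. Reported interaction
#' effects are posterior means of environment deviations (summing to zero
#' over environments per term, the cross-environment mean being absorbed
#' into the main effect), and the environment-mean is absorbed into the
#' population mean. A split-chain diagnostic flags non-convergence when
#' the potential scale reduction factor exceeds 1.1 on any fixed effect.
#'
#' @param bundle a [validate_dataset()] bundle.
#' @param trait trait name.
#' @param terms a [stepwise_select()] result (or data.frame with `type`,
#'   `marker_i`, `marker_j`).
#' @param n_iter total Gibbs iterations (default 20000).
#' @param burn_in discarded initial iterations (default 2000).
#' @param thin keep every `thin`-th draw (default 10).
#' @param seed chain seed.
#' @param env_interactions include `ae`/`aae` random effects
#'   (default TRUE).
#' @param prior_df,prior_scale_frac scaled-inverse-chi-squared prior for
#'   the random-effect variances: degrees of freedom and prior scale as a
#'   fraction of the phenotypic variance (defaults 2 and 0.05; the
#'   environment variance prior scale uses `5 * prior_scale_frac`).
#' @return object of class `qts_model`; see [compute_heritability()] for
#'   the heritability fields.
#' @export
estimate_effects_mcmc <- function(bundle, trait, terms, n_iter = 20000L,
                                  burn_in = 2000L, thin = 10L, seed = 1L,
                                  env_interactions = TRUE,
                                  prior_df = 2, prior_scale_frac = 0.05) {
  d <- .stacked_data(bundle, trait)
  if (nrow(terms) == 0L) stop("no terms to estimate")
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  if (is.null(terms$label))
    terms$label <- vapply(seq_len(nrow(terms)), function(i)
      .term_label(terms[i, ]), "")
  if (is.null(terms$chromosome))
    terms$chromosome <- vapply(seq_len(nrow(terms)), function(i) {
      ci <- d$map$chromosome[match(terms$marker_i[i], d$map$marker_id)]
      if (terms$type[i] == "pair")
        paste(ci, d$map$chromosome[match(terms$marker_j[i],
                                         d$map$marker_id)], sep = " & ")
      else ci
    }, "")
  H <- length(d$envs)
  n <- nrow(d$codes)
  N <- n * H
  ystack <- as.vector(d$y)
  envidx <- rep(seq_len(H), each = n)
  vy <- .pooled_vp(d$y)

  xs <- lapply(seq_len(nrow(terms)), function(i) {
    x <- if (terms$type[i] == "pair")
      d$codes[, terms$marker_i[i]] * d$codes[, terms$marker_j[i]]
    else d$codes[, terms$marker_i[i]]
    rep(x, H)
  })
  X <- do.call(cbind, c(list(rep(1, N)), xs))
  p <- ncol(X)
  XtX <- crossprod(X)
  Rch <- chol(XtX + diag(1e-10, p))
  is_pair <- terms$type == "pair"
  t_idx <- seq_len(nrow(terms))

  # state
  set.seed(seed)
  beta <- qr.coef(qr(X), ystack)
  beta[is.na(beta)] <- 0
  e <- rep(0, H)
  ae <- matrix(0, nrow(terms), H)           # rows: terms (ae or aae)
  s2eps <- vy / 2
  s2e <- vy * prior_scale_frac * 5
  s2ae <- vy * prior_scale_frac
  s2aae <- vy * prior_scale_frac
  nu0 <- prior_df
  s0e <- vy * prior_scale_frac * 5
  s0ae <- vy * prior_scale_frac

  rand_contrib <- function() {
    out <- e[envidx]
    if (env_interactions)
      for (i in t_idx) out <- out + xs[[i]] * ae[i, envidx]
    out
  }
  keep_at <- seq(burn_in + thin, n_iter, by = thin)
  kept <- length(keep_at)
  B <- matrix(NA_real_, p, kept)
  E <- matrix(NA_real_, H, kept)
  AE <- array(NA_real_, c(nrow(terms), H, kept))
  V <- matrix(NA_real_, 4L, kept,
              dimnames = list(c("s2eps", "s2e", "s2ae", "s2aae"), NULL))
  ki <- 0L
  for (it in seq_len(n_iter)) {
    # fixed block
    r <- ystack - rand_contrib()
    bhat <- backsolve(Rch, forwardsolve(t(Rch), crossprod(X, r)))
    beta <- as.vector(bhat + sqrt(s2eps) * backsolve(Rch, rnorm(p)))
    res <- r - X %*% beta
    # environment main effects
    for (h in seq_len(H)) {
      sel <- envidx == h
      rp <- res[sel] + e[h]
      prec <- n / s2eps + 1 / s2e
      e_new <- rnorm(1L, sum(rp) / s2eps / prec, sqrt(1 / prec))
      res[sel] <- rp - e_new
      e[h] <- e_new
    }
    # interaction deviations
    if (env_interactions) {
      for (i in t_idx) {
        s2 <- if (is_pair[i]) s2aae else s2ae
        for (h in seq_len(H)) {
          sel <- envidx == h
          v <- xs[[i]][sel]
          rp <- res[sel] + v * ae[i, h]
          prec <- sum(v^2) / s2eps + 1 / s2
          m <- sum(v * rp) / s2eps / prec
          a_new <- rnorm(1L, m, sqrt(1 / prec))
          res[sel] <- rp - v * a_new
          ae[i, h] <- a_new
        }
      }
    }
    # variances
    s2eps <- max(sum(res^2), 1e-300) / rchisq(1L, N)
    s2e <- (nu0 * s0e + sum(e^2)) / rchisq(1L, nu0 + H)
    if (env_interactions) {
      if (any(!is_pair))
        s2ae <- (nu0 * s0ae + sum(ae[!is_pair, ]^2)) /
          rchisq(1L, nu0 + H * sum(!is_pair))
      if (any(is_pair))
        s2aae <- (nu0 * s0ae + sum(ae[is_pair, ]^2)) /
          rchisq(1L, nu0 + H * sum(is_pair))
    }
    if (it %in% keep_at) {
      ki <- ki + 1L
      B[, ki] <- beta; E[, ki] <- e; AE[, , ki] <- ae
      V[, ki] <- c(s2eps, s2e, s2ae, s2aae)
    }
  }

  # identification transform per draw: absorb cross-environment means of
  # the random effects into the fixed effects, keep deviations
  Em <- colMeans(E)
  mu_draws <- B[1L, ] + Em
  Edev <- sweep(E, 2L, Em)
  AEm <- apply(AE, c(1L, 3L), mean)               # terms x kept
  eff_draws <- B[-1L, , drop = FALSE] + AEm
  AEdev <- sweep(AE, c(1L, 3L), AEm)

  rhat <- function(x) {
    half <- floor(length(x) / 2)
    x1 <- x[seq_len(half)]; x2 <- x[half + seq_len(half)]
    W <- mean(c(var(x1), var(x2)))
    if (W <= 0) return(1)
    Bv <- var(c(mean(x1), mean(x2))) * half
    sqrt(((half - 1) / half * W + Bv / half) / W)
  }
  rhats <- apply(rbind(mu_draws, eff_draws), 1L, rhat)
  converged <- all(rhats < 1.1, na.rm = TRUE)
  if (!converged)
    warning("split-chain diagnostic > 1.1 on a fixed effect; ",
            "treat estimates with caution")

  comp_tests <- .component_tests(d, terms)
  varx <- vapply(xs, function(x) var(x[seq_len(n)]), numeric(1))

  effects <- list()
  for (i in t_idx) {
    lab <- .term_label(terms[i, ])
    comp <- if (is_pair[i]) "aa" else "a"
    effects[[length(effects) + 1L]] <- data.frame(
      term = lab, component = comp, environment = NA_character_,
      estimate = mean(eff_draws[i, ]), se = sd(eff_draws[i, ]),
      neg_log10_p = comp_tests[[i]]$main[2L], var_x = varx[i],
      stringsAsFactors = FALSE)
    if (env_interactions)
      effects[[length(effects) + 1L]] <- data.frame(
        term = lab, component = if (is_pair[i]) "aae" else "ae",
        environment = d$envs,
        estimate = apply(AEdev[i, , , drop = FALSE], 2L, mean),
        se = apply(AEdev[i, , , drop = FALSE], 2L, sd),
        neg_log10_p = comp_tests[[i]]$dev[2L], var_x = varx[i],
        stringsAsFactors = FALSE)
  }
  effects <- do.call(rbind, effects)
  effects$h2 <- NA_real_

  model <- structure(list(
    trait = trait, mu_hat = mean(mu_draws), mu_se = sd(mu_draws),
    effects = effects,
    e_hat = setNames(rowMeans(Edev), d$envs),
    residual_variance = mean(V["s2eps", ]),
    env_variance = mean(V["s2e", ]),
    V_P = vy, n_lines = n, environments = d$envs,
    terms = terms,
    mcmc = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                seed = seed, kept = kept, rhat = rhats,
                converged = converged),
    h2_total = NA_real_), class = "qts_model")
  compute_heritability(model)
}

#' Partition heritability over model components
#'
#' Fills the per-component heritabilities of a fitted model:
#' `h2(a_i) = 100 a_i^2 Var(x_i) / V_P`,
#' `h2(aa_ij) = 100 aa_ij^2 Var(x_i x_j) / V_P`,
#' `h2(ae_i) = 100 mean_h(ae_hi^2) Var(x_i) / V_P` (analogously for
#' `aae`), with `V_P` the pooled within-environment phenotypic variance
#' and sample marker variances (~1 in a balanced RIL). The total
#' heritability is the sum over all components; interaction components
#' carry their (shared) value on the first environment row.
#'
#' @param model a `qts_model` from [estimate_effects_mcmc()].
#' @return the model with `effects$h2` and `h2_total` filled.
#' @export
compute_heritability <- function(model) {
  stopifnot(inherits(model, "qts_model"))
  if (is.na(model$V_P) || model$V_P <= 0) stop("V_P must be positive")
  eff <- model$effects
  eff$h2 <- NA_real_
  for (term in unique(eff$term)) {
    for (comp in unique(eff$component[eff$term == term])) {
      rows <- which(eff$term == term & eff$component == comp)
      msq <- mean(eff$estimate[rows]^2)    # mean over environments
      h2 <- 100 * msq * eff$var_x[rows[1L]] / model$V_P
      eff$h2[rows] <- NA_real_
      eff$h2[rows[1L]] <- h2
    }
  }
  model$effects <- eff
  model$h2_total <- sum(eff$h2, na.rm = TRUE)
  model
}

#' @export
print.qts_model <- function(x, digits = 2, ...) {
  cat("qts_model for", x$trait, "-", nrow(x$terms), "term(s), h2_T =",
      round(x$h2_total, digits), "%\n")
  eff <- x$effects
  eff$estimate <- round(eff$estimate, digits)
  eff$se <- round(eff$se, digits)
  eff$neg_log10_p <- round(eff$neg_log10_p, digits)
  eff$h2 <- round(eff$h2, digits)
  print.data.frame(eff[, c("term", "component", "environment", "estimate",
                           "se", "neg_log10_p", "h2")], row.names = FALSE)
  invisible(x)
}

#' One-call mapping of a trait
#'
#' Convenience driver chaining the full inferential path for one trait:
#' candidate screening ([gmdr_screen_1d()], [select_top_candidates()]),
#' optional pair screening, the permutation threshold over the whole scan,
#' single-locus and pair scans, stepwise selection, Gibbs effect
#' estimation, and heritability partitioning.
#'
#' @param bundle a [validate_dataset()] bundle.
#' @param trait trait name.
#' @param per_chromosome_k candidates kept per chromosome in screening.
#' @param k_folds screening CV folds.
#' @param alpha experiment-wise error rate.
#' @param n_permutations permutations for the threshold.
#' @param epistasis also screen and scan marker pairs (pairs among the
#'   top `pair_top` screened candidates).
#' @param pair_top number of top single-locus candidates paired when
#'   `epistasis = TRUE`.
#' @param n_iter,burn_in,thin Gibbs sampler controls.
#' @param seed master seed (screening folds, permutations and the chain
#'   derive from it).
#' @return list of class `qts_fit`: `scan_1d`, `scan_2d`, `threshold`,
#'   `terms`, `model` (NULL when nothing is selected), `candidates`.
#' @export
map_trait <- function(bundle, trait, per_chromosome_k = 400L, k_folds = 5L,
                      alpha = 0.05, n_permutations = 2000L,
                      epistasis = TRUE, pair_top = 20L, n_iter = 20000L,
                      burn_in = 2000L, thin = 10L, seed = 1L) {
  g <- bundle$genotypes
  p <- bundle$phenotypes
  sc <- gmdr_screen_1d(g, p, trait, k_folds = k_folds, seed = seed)
  cand <- select_top_candidates(sc, per_chromosome_k = per_chromosome_k)
  pairs <- NULL
  if (epistasis) {
    top <- sc[sc$term %in% cand, , drop = FALSE]
    top <- top[order(-top$testing_accuracy, top$position_bp,
                     top$term), , drop = FALSE]
    ptop <- head(top$term, pair_top)
    if (length(ptop) >= 2L) pairs <- t(utils::combn(ptop, 2L))
  }
  thr <- permutation_threshold(bundle, trait, candidates = cand,
                               alpha = alpha,
                               n_permutations = n_permutations,
                               seed = seed + 1L, pairs = pairs)
  s1 <- scan_single_locus(bundle, trait, candidates = cand, threshold = thr)
  s2 <- if (!is.null(pairs))
    scan_epistasis(bundle, trait, pairs = pairs, threshold = thr) else NULL
  terms <- stepwise_select(bundle, trait, thr, s1, s2)
  model <- if (nrow(terms) > 0L)
    estimate_effects_mcmc(bundle, trait, terms, n_iter = n_iter,
                          burn_in = burn_in, thin = thin, seed = seed + 2L)
  else NULL
  structure(list(scan_1d = s1, scan_2d = s2, threshold = thr, terms = terms,
                 model = model, candidates = cand),
            class = "qts_fit")
}
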