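#' Per-environment trait summaries
#'
#' Mean, sample SD (n-1 denominator), range, and CV = 100*SD/mean per trait
#' and environment, plus the between-environment mean difference
#' D = mean(E1) - mean(E2) with a Welch two-sample test coded
#' `**` (p <= 0.01), `*` (p <= 0.05), `""` otherwise. With more than two
#' environments D is the difference between the first two.
#'
#' @param p a [phenotype_table()].
#' @return list of class `trait_summary`: `per_environment` (data.frame:
#'   trait, environment, n, mean, sd, min, max, cv) and `difference`
#'   (data.frame: trait, D, p_value, significance).
#' @export
summarize_traits <- function(p) {
  stopifnot(inherits(p, "phenotype_table"))
  envs <- environments(p)
  traits <- trait_names(p)
  pe <- list(); dd <- list()
  for (tr in traits) {
    m <- pheno_matrix(p, tr)
    ns <- colSums(!is.na(m))
    if (any(ns < 2L)) {
      warning("trait ", tr, " has < 2 lines in some environment; skipped")
      next
    }
    pe[[tr]] <- data.frame(
      trait = tr, environment = envs, n = ns,
      mean = colMeans(m, na.rm = TRUE),
      sd = apply(m, 2L, sd, na.rm = TRUE),
      min = apply(m, 2L, min, na.rm = TRUE),
      max = apply(m, 2L, max, na.rm = TRUE),
      stringsAsFactors = FALSE)
    pe[[tr]]$cv <- 100 * pe[[tr]]$sd / pe[[tr]]$mean
    if (length(envs) >= 2L) {
      x1 <- m[, 1L]; x2 <- m[, 2L]
      D <- mean(x1, na.rm = TRUE) - mean(x2, na.rm = TRUE)
      pv <- if (sd(x1, na.rm = TRUE) + sd(x2, na.rm = TRUE) == 0) 1 else
        t.test(x1, x2)$p.value
      dd[[tr]] <- data.frame(
        trait = tr, D = D, p_value = pv,
        significance = if (pv <= 0.01) "**" else if (pv <= 0.05) "*" else "",
        stringsAsFactors = FALSE)
    }
  }
  out <- list(per_environment = do.call(rbind, unname(pe)),
              difference = if (length(dd)) do.call(rbind, unname(dd)) else NULL)
  rownames(out$per_environment) <- NULL
  class(out) <- "trait_summary"
  out
}

#' @export
print.trait_summary <- function(x, digits = 2, ...) {
  pe <- x$per_environment
  pe$mean <- round(pe$mean, digits); pe$sd <- round(pe$sd, digits)
  pe$cv <- round(pe$cv, digits)
  print.data.frame(pe, row.names = FALSE)
  if (!is.null(x$difference)) {
    d <- x$difference
    cat("\nBetween-environment differences (E1 - E2):\n")
    print.data.frame(data.frame(trait = d$trait, D = round(d$D, digits),
                                significance = d$significance),
                     row.names = FALSE)
  }
  invisible(x)
}

# correlation matrix + p values from a lines x traits matrix
.cor_with_p <- function(m) {
  k <- ncol(m)
  r <- diag(1, k); pv <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(pv) <- list(colnames(m), colnames(m))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j) {
    ok <- complete.cases(m[, c(i, j)])
    if (sum(ok) < 3L || sd(m[ok, i]) == 0 || sd(m[ok, j]) == 0) {
      r[i, j] <- r[j, i] <- NA_real_
      next
    }
    ct <- cor.test(m[ok, i], m[ok, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    pv[i, j] <- pv[j, i] <- ct$p.value
  }
  list(r = r, p = pv)
}

.star <- function(p) ifelse(is.na(p), "",
                            ifelse(p <= 0.005, "***",
                                   ifelse(p <= 0.01, "**",
                                          ifelse(p <= 0.05, "*", ""))))

#' Phenotypic correlations between traits, per environment
#'
#' Pairwise Pearson correlations of trait values within each environment,
#' with two-sided p-values and significance stars at 0.05 / 0.01 / 0.005.
#' Constant traits yield missing correlations.
#'
#' @param p a [phenotype_table()].
#' @return list of class `correlation_report`: per environment, a list with
#'   `r`, `p`, `stars` matrices.
#' @export
phenotypic_correlations <- function(p) {
  stopifnot(inherits(p, "phenotype_table"))
  traits <- trait_names(p)
  out <- lapply(environments(p), function(h) {
    lines_ <- sort(unique(p$line_id))
    m <- sapply(traits, function(tr) pheno_matrix(p, tr, lines_)[, h])
    cp <- .cor_with_p(as.matrix(m))
    list(r = cp$r, p = cp$p, stars = .star(cp$p))
  })
  names(out) <- environments(p)
  class(out) <- "correlation_report"
  out
}

#' Predicted genotypic values by shrinkage
#'
#' Fits, per trait, the two-way model `y_hk = mean + env_h + g_k + eps`
#' with random line effects. On the balanced H-environment design the
#' moment (REML-equivalent) estimators are `sigma2_eps = MS_resid` and
#' `sigma2_g = (MS_line - MS_resid) / H` from the environment-adjusted
#' two-way ANOVA; the line effect is shrunk by
#' `lambda = sigma2_g / (sigma2_g + sigma2_eps / H_k)` where `H_k` is the
#' number of environments in which line k was observed. The genotypic value
#' is `grand mean + lambda * g_k`.
#'
#' @param p a [phenotype_table()].
#' @return data.frame of class `genotypic_values`: `line_id`, one column
#'   per trait, with attribute `variance_components` (per trait:
#'   `sigma2_g`, `sigma2_eps`, `lambda` for fully observed lines).
#' @export
predict_genotypic_values <- function(p) {
  stopifnot(inherits(p, "phenotype_table"))
  envs <- environments(p)
  if (length(envs) < 2L)
    stop("single environment without replication: residual variance is ",
         "inestimable; use raw line means instead")
  traits <- trait_names(p)
  lines_ <- sort(unique(p$line_id))
  out <- data.frame(line_id = lines_, stringsAsFactors = FALSE)
  vc <- list()
  for (tr in traits) {
    m <- pheno_matrix(p, tr, lines_)
    H <- ncol(m)
    grand <- mean(m, na.rm = TRUE)
    envm <- colMeans(m, na.rm = TRUE)
    adj <- sweep(m, 2L, envm)            # environment effects removed
    gk <- rowMeans(adj, na.rm = TRUE)    # raw line effects
    Hk <- rowSums(!is.na(m))
    # two-way ANOVA mean squares on complete rows
    cc <- Hk == H
    n <- sum(cc)
    if (n < 3L) stop("too few complete lines for trait ", tr)
    ms_line <- H * var(gk[cc])
    resid <- adj[cc, , drop = FALSE] - gk[cc]
    ms_resid <- sum(resid^2) / ((n - 1) * (H - 1))
    s2_eps <- ms_resid
    s2_g <- max(0, (ms_line - ms_resid) / H)
    lambda <- if (s2_g == 0) rep(0, length(gk)) else
      s2_g / (s2_g + s2_eps / pmax(Hk, 1L))
    out[[tr]] <- grand + lambda * gk
    vc[[tr]] <- c(sigma2_g = s2_g, sigma2_eps = s2_eps,
                  lambda = if (s2_g == 0) 0 else s2_g / (s2_g + s2_eps / H))
  }
  attr(out, "variance_components") <- vc
  class(out) <- c("genotypic_values", "data.frame")
  out
}

#' Genotypic correlations between traits
#'
#' Pearson correlations of predicted genotypic values across lines, with
#' p-values and stars as in [phenotypic_correlations()].
#'
#' @param gv a [predict_genotypic_values()] result.
#' @return list with `r`, `p`, `stars` matrices.
#' @export
genotypic_correlations <- function(gv) {
  stopifnot(inherits(gv, "genotypic_values"))
  m <- as.matrix(gv[, setdiff(names(gv), "line_id"), drop = FALSE])
  cp <- .cor_with_p(m)
  list(r = cp$r, p = cp$p, stars = .star(cp$p))
}

#' Conditional phenotypes: a target trait given a component trait
#'
#' Removes from the target trait the variation linearly predictable from a
#' given component trait, separately within each environment:
#' `b_h = Cov_h(target, given) / Var_h(given)` and
#' `y(T1|T2)_hk = y1_hk - b_h (y2_hk - mean_h(y2))`. The conditional values
#' have zero within-environment covariance with the given trait, which is
#' the defining contract of the construction. With `mode = "genotypic"` the
#' adjustment regresses on the predicted genotypic value of the given trait
#' instead of its observed phenotype (a Zhu-style variant conditioning on
#' the heritable part only).
#'
#' @param p a [phenotype_table()] containing both traits.
#' @param target trait to condition (T1).
#' @param given conditioning component trait (T2).
#' @param mode `"observed"` (default) or `"genotypic"`.
#' @return a [phenotype_table()] with the single trait `"T1|T2"` on the
#'   shared (line, environment) records.
#' @export
conditional_phenotypes <- function(p, target, given,
                                   mode = c("observed", "genotypic")) {
  stopifnot(inherits(p, "phenotype_table"))
  mode <- match.arg(mode)
  if (!all(c(target, given) %in% trait_names(p)))
    stop("target and given traits must both be present")
  envs <- environments(p)
  lines_ <- sort(unique(p$line_id))
  m1 <- pheno_matrix(p, target, lines_)
  m2 <- pheno_matrix(p, given, lines_)
  if (mode == "genotypic") {
    gv <- predict_genotypic_values(p)
    g2 <- gv[[given]][match(lines_, gv$line_id)]
    m2 <- matrix(g2, nrow = length(lines_), ncol = length(envs),
                 dimnames = dimnames(m2))
    m2[is.na(pheno_matrix(p, given, lines_))] <- NA  # keep record support
  }
  name <- paste0(target, "|", given)
  recs <- list()
  for (h in envs) {
    ok <- !is.na(m1[, h]) & !is.na(m2[, h])
    if (sum(ok) < 3L) next
    v2 <- var(m2[ok, h])
    if (v2 == 0) stop("given trait has zero variance in environment ", h)
    b <- cov(m1[ok, h], m2[ok, h]) / v2
    ycond <- m1[ok, h] - b * (m2[ok, h] - mean(m2[ok, h]))
    recs[[h]] <- data.frame(line_id = lines_[ok], environment = h,
                            trait = name, value = ycond,
                            stringsAsFactors = FALSE)
  }
  if (length(recs) == 0L) stop("no environment has enough shared records")
  phenotype_table(do.call(rbind, recs), environments = envs)
}

#' Append conditional trait records to an existing table
#'
#' @param p a [phenotype_table()].
#' @param cond a [conditional_phenotypes()] result on the same lines and
#'   environments.
#' @return a combined [phenotype_table()].
#' @export
append_phenotypes <- function(p, cond) {
  phenotype_table(rbind(as.data.frame(p), as.data.frame(cond)),
                  environments = environments(p))
}
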