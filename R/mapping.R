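# ---- stacked two-environment data -----------------------------------------

# complete-case lines x environments response for one trait, aligned to the
# genotype matrix
.stacked_data <- function(bundle, trait) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  g <- bundle$genotypes
  p <- bundle$phenotypes
  if (!trait %in% trait_names(p)) stop("trait not present: ", trait)
  m <- pheno_matrix(p, trait, lines = g$line_ids)
  keep <- complete.cases(m)
  if (sum(keep) < 3L) stop("fewer than 3 complete lines for trait ", trait)
  codes <- g$codes[keep, , drop = FALSE]
  if (anyNA(codes)) stop("genotypes contain missing codes; impute first")
  list(y = m[keep, , drop = FALSE], codes = codes,
       lines = g$line_ids[keep], envs = environments(p), map = g$map,
       n_dropped = sum(!keep))
}

# pooled within-environment phenotypic variance (environment means removed)
.pooled_vp <- function(y) {
  n <- nrow(y); H <- ncol(y)
  sum(sweep(y, 2L, colMeans(y))^2) / (n * H - H)
}

# ---- vectorised F statistics ----------------------------------------------

# Single-locus F of {additive + additive-x-environment} vs environment-only,
# via per-(environment, genotype-class) cell means. codes: n x m in {+1,-1};
# Ylist: one n x P response matrix per environment (P > 1 for permutation
# columns). Returns m x P matrix of F values (NA for monomorphic markers).
.scan1d_F <- function(codes, Ylist) {
  n <- nrow(codes); m <- ncol(codes); P <- ncol(Ylist[[1L]])
  M <- codes > 0
  N1 <- colSums(M)
  mono <- N1 == 0L | N1 == n
  RSS1 <- matrix(0, m, P)
  RSS0 <- numeric(P)
  SS <- 0
  for (Y in Ylist) {
    S1 <- crossprod(M, Y)                              # class +1 sums, m x P
    Stot <- colSums(Y)
    ss <- colSums(Y^2)
    SS <- SS + sum(ss)
    RSS0 <- RSS0 + ss - Stot^2 / n
    c1 <- S1^2 / pmax(N1, 1L)
    S0 <- sweep(-S1, 2L, Stot, "+")
    c0 <- S0^2 / pmax(n - N1, 1L)
    RSS1 <- RSS1 + rep(ss, each = m) - c1 - c0
  }
  H <- length(Ylist)
  df1 <- H
  df2 <- n * H - 2L * H
  Fm <- sweep(-RSS1, 2L, RSS0, "+") / df1 / (RSS1 / df2)
  Fm[RSS1 <= 1e-10 * SS / (n * H)] <- 1e15             # saturated fit
  Fm[!is.finite(Fm) | Fm > 1e15] <- 1e15
  Fm[Fm < 0] <- 0
  Fm[mono, ] <- NA_real_
  list(F = Fm, df1 = df1, df2 = df2, mono = mono)
}

# Pair F of {epistatic product + product-x-environment} added to marginal
# terms (per environment: 4 cell means vs regression on 1, x_i, x_j).
# pairs: 2-column character matrix of marker ids. Returns n_pairs x P.
.scan2d_F <- function(codes, Ylist, pairs) {
  n <- nrow(codes); P <- ncol(Ylist[[1L]]); H <- length(Ylist)
  np <- nrow(pairs)
  Fm <- matrix(NA_real_, np, P)
  df1 <- rep(NA_integer_, np); df2 <- rep(NA_integer_, np)
  ss_all <- sum(vapply(Ylist, function(Y) sum(Y^2), numeric(1)))
  for (k in seq_len(np)) {
    xi <- codes[, pairs[k, 1L]]; xj <- codes[, pairs[k, 2L]]
    cell <- 2L * (xi > 0) + (xj > 0) + 1L
    counts <- tabulate(cell, 4L)
    X <- cbind(1, xi, xj)
    qrX <- qr(X)
    ncell <- sum(counts > 0L)
    q_env <- ncell - qrX$rank
    if (q_env <= 0L) next                               # collinear pair
    Mcell <- vapply(which(counts > 0L), function(cc) cell == cc,
                    logical(n))                         # n x ncell
    Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    RSS1 <- numeric(P); RSS0 <- numeric(P)
    for (Y in Ylist) {
      ss <- colSums(Y^2)
      RSS0 <- RSS0 + ss - colSums(crossprod(Q, Y)^2)
      Sc <- crossprod(Mcell, Y)                         # ncell x P
      RSS1 <- RSS1 + ss - colSums(Sc^2 / counts[counts > 0L])
    }
    d1 <- H * q_env
    d2 <- n * H - ncell * H
    f <- (RSS0 - RSS1) / d1 / (RSS1 / d2)
    f[RSS1 <= 1e-10 * ss_all / (n * H)] <- 1e15
    f[!is.finite(f) | f > 1e15] <- 1e15
    f[f < 0] <- 0
    Fm[k, ] <- f
    df1[k] <- d1; df2[k] <- d2
  }
  list(F = Fm, df1 = df1, df2 = df2)
}

.nlp <- function(F, df1, df2) {
  out <- -pf(F, df1, df2, lower.tail = FALSE, log.p = TRUE) / log(10)
  out[is.na(F)] <- NA_real_
  out
}

# ---- scans -----------------------------------------------------------------

#' Single-locus association scan
#'
#' For each candidate marker, F-test of the additive plus
#' additive-by-environment terms against the environment-only null, by
#' least squares on the stacked multi-environment data (equivalently, the
#' nested comparison of per-(environment, genotype-class) cell means
#' against environment means). Monomorphic markers are skipped with a
#' warning. A saturated (zero-residual) fit caps F at 1e15.
#'
#' @param bundle a [validate_dataset()] bundle with imputed genotypes.
#' @param trait trait name.
#' @param candidates marker ids to test (default: all).
#' @param threshold optional [permutation_threshold()] (or a number) used
#'   to set the `significant` flag.
#' @return data.frame of class `scan_result`: `term`, `chromosome`,
#'   `position_bp`, `a_hat` (pooled additive estimate), `F_statistic`,
#'   `neg_log10_p`, `significant`.
#' @export
scan_single_locus <- function(bundle, trait, candidates = NULL,
                              threshold = NULL) {
  d <- .stacked_data(bundle, trait)
  if (is.null(candidates)) candidates <- d$map$marker_id
  candidates <- as.character(candidates)
  if (!all(candidates %in% d$map$marker_id)) stop("unknown candidate marker(s)")
  codes <- d$codes[, candidates, drop = FALSE]
  Ylist <- lapply(seq_along(d$envs), function(h) d$y[, h, drop = FALSE])
  sc <- .scan1d_F(codes, Ylist)
  if (any(sc$mono))
    warning(sum(sc$mono), " monomorphic marker(s) skipped")
  # pooled additive estimate: mean over environments of half the class
  # mean difference
  M <- codes > 0
  N1 <- colSums(M)
  a_hat <- rep(0, length(candidates))
  for (h in seq_along(d$envs)) {
    S1 <- crossprod(M, d$y[, h])
    Stot <- sum(d$y[, h])
    a_hat <- a_hat + (S1 / pmax(N1, 1) -
                        (Stot - S1) / pmax(nrow(codes) - N1, 1)) / 2
  }
  a_hat <- as.vector(a_hat) / length(d$envs)
  a_hat[sc$mono] <- NA_real_
  thr <- if (inherits(threshold, "permutation_threshold"))
    threshold$threshold else threshold
  mi <- match(candidates, d$map$marker_id)
  out <- data.frame(term = candidates, chromosome = d$map$chromosome[mi],
                    position_bp = d$map$position_bp[mi], a_hat = a_hat,
                    F_statistic = sc$F[, 1L],
                    neg_log10_p = .nlp(sc$F[, 1L], sc$df1, sc$df2),
                    significant = if (is.null(thr)) NA else sc$F[, 1L] > thr,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Two-locus epistasis scan
#'
#' For each marker pair, F-test of the product term `x_i x_j` plus its
#' environment interaction, added to a model already containing both
#' marginal (additive and additive-by-environment) terms. Collinear pairs
#' (`|cor| = 1`) are skipped.
#'
#' @param bundle a [validate_dataset()] bundle.
#' @param trait trait name.
#' @param pairs 2-column matrix/data.frame of marker ids, or NULL to
#'   enumerate all pairs of `candidates`.
#' @param candidates marker ids to pair when `pairs` is NULL.
#' @param threshold optional [permutation_threshold()] or number.
#' @param max_pairs guard on the number of tested pairs.
#' @return data.frame of class `scan_result_2d`: `marker_i`, `marker_j`,
#'   `aa_hat`, `F_statistic`, `neg_log10_p`, `significant`.
#' @export
scan_epistasis <- function(bundle, trait, pairs = NULL, candidates = NULL,
                           threshold = NULL, max_pairs = 50000L) {
  d <- .stacked_data(bundle, trait)
  if (is.null(pairs)) {
    if (is.null(candidates)) stop("supply pairs or candidates")
    candidates <- as.character(candidates)
    if (choose(length(candidates), 2L) > max_pairs)
      stop("pair count exceeds limit; tighten the candidate screen")
    pairs <- t(utils::combn(candidates, 2L))
  }
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "character"
  if (nrow(pairs) > max_pairs)
    stop("pair count exceeds limit; tighten the candidate screen")
  if (!all(pairs %in% d$map$marker_id)) stop("unknown marker id in pairs")
  Ylist <- lapply(seq_along(d$envs), function(h) d$y[, h, drop = FALSE])
  sc <- .scan2d_F(d$codes, Ylist, pairs)
  # pooled epistatic estimate: mean over environments of the product-term
  # contrast of the four cell means
  aa_hat <- vapply(seq_len(nrow(pairs)), function(k) {
    xi <- d$codes[, pairs[k, 1L]]; xj <- d$codes[, pairs[k, 2L]]
    prod_ <- xi * xj
    if (length(unique(prod_)) < 2L) return(NA_real_)
    est <- 0
    for (h in seq_along(d$envs)) {
      fit <- lm.fit(cbind(1, xi, xj, prod_), d$y[, h])
      est <- est + fit$coefficients[4L]
    }
    est / length(d$envs)
  }, numeric(1))
  thr <- if (inherits(threshold, "permutation_threshold"))
    threshold$threshold else threshold
  out <- data.frame(marker_i = pairs[, 1L], marker_j = pairs[, 2L],
                    aa_hat = aa_hat, F_statistic = sc$F[, 1L],
                    neg_log10_p = .nlp(sc$F[, 1L], sc$df1, sc$df2),
                    significant = if (is.null(thr)) NA else sc$F[, 1L] > thr,
                    stringsAsFactors = FALSE)
  class(out) <- c("scan_result_2d", "data.frame")
  out
}

#' Permutation threshold for experiment-wise error control
#'
#' Builds the null distribution of the scan maximum: each permutation
#' shuffles line identities jointly across environments (a line's
#' phenotype records move together, preserving environment structure while
#' breaking the genotype-phenotype link), re-runs the single-locus scan
#' over the candidates (and, if supplied, the pair scan), and records the
#' maximum F. The threshold is the empirical `1 - alpha` quantile (type 1)
#' of the max-F draws, so that exceeding it anywhere in the scan has
#' probability ~`alpha` under the null.
#'
#' @param bundle a [validate_dataset()] bundle.
#' @param trait trait name.
#' @param candidates marker ids scanned.
#' @param alpha experiment-wise type-I error rate (default 0.05).
#' @param n_permutations number of permutations (>= 100; default 2000).
#' @param seed permutation seed.
#' @param pairs optional 2-column marker-id matrix included in the max.
#' @return object of class `permutation_threshold`: list with `alpha`,
#'   `n_permutations`, `threshold`, `max_stats`, `seed`.
#' @export
permutation_threshold <- function(bundle, trait, candidates = NULL,
                                  alpha = 0.05, n_permutations = 2000L,
                                  seed = 1L, pairs = NULL) {
  stopifnot(n_permutations >= 100L, alpha > 0, alpha <= 1)
  d <- .stacked_data(bundle, trait)
  if (is.null(candidates)) candidates <- d$map$marker_id
  codes <- d$codes[, as.character(candidates), drop = FALSE]
  n <- nrow(codes)
  set.seed(seed)
  perm <- vapply(seq_len(n_permutations), function(i) sample.int(n),
                 integer(n))
  Ylist <- lapply(seq_along(d$envs), function(h)
    matrix(d$y[, h][perm], n, n_permutations))
  Fm <- .scan1d_F(codes, Ylist)$F
  maxs <- suppressWarnings(apply(Fm, 2L, max, na.rm = TRUE))
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    storage.mode(pairs) <- "character"
    F2 <- .scan2d_F(d$codes, Ylist, pairs)$F
    maxs2 <- suppressWarnings(apply(F2, 2L, max, na.rm = TRUE))
    maxs <- pmax(maxs, maxs2, na.rm = TRUE)
  }
  maxs[!is.finite(maxs)] <- NA_real_
  structure(list(alpha = alpha, n_permutations = n_permutations,
                 threshold = unname(quantile(maxs, 1 - alpha, type = 1,
                                             na.rm = TRUE)),
                 max_stats = maxs, seed = seed),
            class = "permutation_threshold")
}

#' @export
print.permutation_threshold <- function(x, ...) {
  cat("permutation_threshold: F* =", format(x$threshold, digits = 4),
      "at alpha =", x$alpha, "from", x$n_permutations, "permutations\n")
  invisible(x)
}

# ---- stepwise model construction ------------------------------------------

# stacked design columns of one term: one column per environment
# (x * 1[env == h]); spans additive + additive-x-environment (or the
# epistatic analogue) of that term
.term_design <- function(codes, H, term) {
  n <- nrow(codes)
  x <- if (term$type == "pair")
    codes[, term$marker_i] * codes[, term$marker_j]
  else codes[, term$marker_i]
  Z <- matrix(0, n * H, H)
  for (h in seq_len(H)) Z[(h - 1L) * n + seq_len(n), h] <- x
  Z
}

.term_label <- function(term) {
  if (term$type == "pair")
    paste(term$marker_i, term$marker_j, sep = " & ")
  else term$marker_i
}

#' Stepwise construction of the final QTS model
#'
#' Forward-backward selection against the permutation threshold: each
#' forward round refits every remaining candidate term (additive marker
#' terms and epistatic pair terms, each spanning its main effect and its
#' environment interaction) conditional on the current model and adds the
#' largest conditional F exceeding the threshold; each backward round
#' drops any included term whose conditional F falls below the threshold;
#' rounds repeat to a fixed point (cycle guard at 50 iterations).
#' Candidate order, and hence tie-breaking, is genomic position order.
#'
#' @param bundle a [validate_dataset()] bundle.
#' @param trait trait name.
#' @param threshold a [permutation_threshold()] or plain F cutoff.
#' @param scan_1d a [scan_single_locus()] result giving the single-locus
#'   candidate terms.
#' @param scan_2d optional [scan_epistasis()] result giving pair terms.
#' @return data.frame of class `qts_terms`: `type` ("marker"/"pair"),
#'   `marker_i`, `marker_j`, `label`, `F_conditional`, `neg_log10_p`
#'   (conditional, in the final model).
#' @export
stepwise_select <- function(bundle, trait, threshold, scan_1d,
                            scan_2d = NULL) {
  d <- .stacked_data(bundle, trait)
  thr <- if (inherits(threshold, "permutation_threshold"))
    threshold$threshold else threshold
  H <- length(d$envs)
  n <- nrow(d$codes)
  ystack <- as.vector(d$y)
  X0 <- matrix(0, n * H, H)
  for (h in seq_len(H)) X0[(h - 1L) * n + seq_len(n), h] <- 1
  mk_terms <- list()
  s1 <- scan_1d[!is.na(scan_1d$F_statistic), , drop = FALSE]
  s1 <- s1[order(match(s1$term, d$map$marker_id)), , drop = FALSE]
  for (i in seq_len(nrow(s1)))
    mk_terms[[length(mk_terms) + 1L]] <-
      list(type = "marker", marker_i = s1$term[i], marker_j = NA_character_)
  if (!is.null(scan_2d)) {
    s2 <- scan_2d[!is.na(scan_2d$F_statistic), , drop = FALSE]
    for (i in seq_len(nrow(s2)))
      mk_terms[[length(mk_terms) + 1L]] <-
        list(type = "pair", marker_i = s2$marker_i[i],
             marker_j = s2$marker_j[i])
  }
  if (length(mk_terms) == 0L) stop("no candidate terms")
  Zs <- lapply(mk_terms, function(tm) .term_design(d$codes, H, tm))
  labels <- vapply(mk_terms, .term_label, "")
  dup <- duplicated(vapply(Zs, function(z) paste(signif(z[, 1], 12),
                                                 collapse = ","), ""))
  rss_of <- function(X) {
    fit <- lm.fit(X, ystack)
    list(rss = sum(fit$residuals^2), rank = fit$rank)
  }
  cond_F <- function(in_idx, add_idx, r0 = NULL) {
    # conditional F of adding term add_idx to the model holding in_idx
    X_red <- do.call(cbind, c(list(X0), Zs[in_idx]))
    X_full <- cbind(X_red, Zs[[add_idx]])
    if (is.null(r0)) r0 <- rss_of(X_red)
    r1 <- rss_of(X_full)
    q <- r1$rank - r0$rank
    df2 <- length(ystack) - r1$rank
    if (q <= 0L || df2 <= 0L) return(c(NA_real_, NA, NA))
    f <- (r0$rss - r1$rss) / q / (r1$rss / df2)
    if (!is.finite(f) || r1$rss <= 1e-10 * sum(ystack^2) / length(ystack))
      f <- 1e15
    c(max(f, 0), q, df2)
  }
  selected <- integer(0)
  for (iter in seq_len(50L)) {
    changed <- FALSE
    # forward
    avail <- setdiff(which(!dup), selected)
    r0_cur <- rss_of(do.call(cbind, c(list(X0), Zs[selected])))
    bestF <- -Inf; best <- NA_integer_
    for (j in avail) {
      f <- cond_F(selected, j, r0 = r0_cur)[1L]
      if (!is.na(f) && f > bestF + 1e-9) { bestF <- f; best <- j }
    }
    if (!is.na(best) && bestF > thr) {
      selected <- c(selected, best)
      changed <- TRUE
    }
    # backward
    repeat {
      if (length(selected) <= 0L) break
      fs <- vapply(seq_along(selected), function(k)
        cond_F(setdiff(selected, selected[k]), selected[k])[1L], numeric(1))
      worst <- which.min(fs)
      if (length(worst) && !is.na(fs[worst]) && fs[worst] <= thr) {
        selected <- selected[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
    if (iter == 50L) stop("stepwise selection did not stabilise in 50 rounds")
  }
  chrom_of <- function(tm) {
    ci <- d$map$chromosome[match(tm$marker_i, d$map$marker_id)]
    if (tm$type == "pair")
      paste(ci, d$map$chromosome[match(tm$marker_j, d$map$marker_id)],
            sep = " & ")
    else ci
  }
  if (length(selected) == 0L) {
    out <- data.frame(type = character(0), marker_i = character(0),
                      marker_j = character(0), label = character(0),
                      chromosome = character(0),
                      F_conditional = numeric(0), neg_log10_p = numeric(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("qts_terms", "data.frame")
    return(out)
  }
  stats <- t(vapply(seq_along(selected), function(k) {
    v <- cond_F(setdiff(selected, selected[k]), selected[k])
    c(v[1L], .nlp(v[1L], v[2L], v[3L]))
  }, numeric(2)))
  out <- data.frame(
    type = vapply(mk_terms[selected], `[[`, "", "type"),
    marker_i = vapply(mk_terms[selected], `[[`, "", "marker_i"),
    marker_j = vapply(mk_terms[selected], function(t) t$marker_j, ""),
    label = labels[selected],
    chromosome = vapply(mk_terms[selected], chrom_of, ""),
    F_conditional = stats[, 1L],
    neg_log10_p = stats[, 2L], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("qts_terms", "data.frame")
  out
}
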