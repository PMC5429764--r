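# environment-centred residuals for one trait, stacked over environments;
# returns list(res = numeric, line = line index into g$line_ids)
.screen_residuals <- function(g, p, trait) {
  envs <- environments(p)
  m <- pheno_matrix(p, trait, lines = g$line_ids)
  res <- sweep(m, 2L, colMeans(m, na.rm = TRUE))
  idx <- which(!is.na(res), arr.ind = TRUE)
  list(res = res[idx], line = idx[, 1L])
}

# k-fold assignment of lines, deterministic under seed
.fold_lines <- function(n_lines, k_folds, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(k_folds), n_lines))
}

# core MDR-style CV accuracy: `cls` is the observation-level class id
# matrix (n_obs x n_terms, small integer codes), res the residuals,
# fold the per-observation fold id. Ties and empty training cells
# score 0.5.
.cv_accuracy <- function(cls, res, fold, k_folds) {
  n_terms <- ncol(cls)
  acc <- matrix(NA_real_, k_folds, n_terms)
  sgn <- sign(res)
  for (f in seq_len(k_folds)) {
    tr <- fold != f; te <- !tr
    if (!any(te)) { acc[f, ] <- NA; next }
    for (j in seq_len(n_terms)) {
      cj <- cls[, j]
      lab <- tapply(res[tr], cj[tr], function(v) sign(mean(v)))
      telab <- lab[as.character(cj[te])]          # NA for unseen cells
      s <- ifelse(is.na(telab) | telab == 0 | sgn[te] == 0, 0.5,
                  (telab == sgn[te]) * 1)
      acc[f, j] <- mean(s)
    }
  }
  colMeans(acc, na.rm = TRUE)
}

#' Single-locus candidate screening by cross-validated classification
#'
#' Screens every marker with the canonical MDR/GMDR cell-labelling rule:
#' trait values are centred per environment; within each training fold
#' each genotype class (+1 / -1) is labelled high or low by the sign of
#' its mean training residual; testing accuracy is the proportion of
#' held-out observations whose residual sign matches their class label
#' (ties and unseen cells credit 0.5), averaged over folds.
#'
#' @param g a [genotype_matrix()] (imputed).
#' @param p a [phenotype_table()].
#' @param trait trait to screen.
#' @param k_folds number of CV folds (default 5).
#' @param seed fold-assignment seed.
#' @return data.frame of class `screen_scores`: `term`, `chromosome`,
#'   `position_bp`, `testing_accuracy`, `rank_within_chromosome`.
#' @export
gmdr_screen_1d <- function(g, p, trait, k_folds = 5L, seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"), k_folds >= 2L)
  if (anyNA(g$codes)) stop("genotypes contain missing codes; impute first")
  rr <- .screen_residuals(g, p, trait)
  fold <- .fold_lines(length(g$line_ids), k_folds, seed)[rr$line]
  cls <- (g$codes[rr$line, , drop = FALSE] > 0) + 1L
  acc <- .cv_accuracy(cls, rr$res, fold, k_folds)
  out <- data.frame(term = g$map$marker_id, chromosome = g$map$chromosome,
                    position_bp = g$map$position_bp,
                    testing_accuracy = acc, stringsAsFactors = FALSE)
  out$rank_within_chromosome <- unsplit(
    lapply(split(out, out$chromosome), function(d)
      rank(order(order(-d$testing_accuracy, d$position_bp, d$term)))),
    out$chromosome)
  class(out) <- c("screen_scores", "data.frame")
  out
}

#' Two-locus interaction screening
#'
#' As [gmdr_screen_1d()] but the classification cells are the four
#' genotype combinations of a marker pair, so purely epistatic signals
#' (whose marginal effects cancel) become detectable. All pairs among
#' `candidates` are enumerated, guarded by `max_pairs`.
#'
#' @param g a [genotype_matrix()].
#' @param p a [phenotype_table()].
#' @param trait trait to screen.
#' @param candidates marker ids to pair (e.g. from
#'   [select_top_candidates()]).
#' @param k_folds number of CV folds.
#' @param seed fold-assignment seed.
#' @param max_pairs guard on the number of enumerated pairs.
#' @return data.frame of class `screen_scores_2d`: `marker_i`, `marker_j`,
#'   `testing_accuracy`.
#' @export
gmdr_screen_2d <- function(g, p, trait, candidates, k_folds = 5L, seed = 1L,
                           max_pairs = 50000L) {
  stopifnot(inherits(g, "genotype_matrix"), k_folds >= 2L)
  candidates <- unique(as.character(candidates))
  if (!all(candidates %in% g$map$marker_id))
    stop("unknown candidate marker(s)")
  np <- choose(length(candidates), 2L)
  if (np > max_pairs)
    stop(np, " pairs exceed the limit (", max_pairs,
         "); tighten the single-locus screen first")
  if (np == 0L) stop("need at least two candidate markers")
  rr <- .screen_residuals(g, p, trait)
  fold <- .fold_lines(length(g$line_ids), k_folds, seed)[rr$line]
  pairs <- t(utils::combn(candidates, 2L))
  ci <- (g$codes[rr$line, pairs[, 1L], drop = FALSE] > 0) + 0L
  cj <- (g$codes[rr$line, pairs[, 2L], drop = FALSE] > 0) + 0L
  cls <- 2L * ci + cj + 1L                      # 4 cells per pair
  acc <- .cv_accuracy(cls, rr$res, fold, k_folds)
  out <- data.frame(marker_i = pairs[, 1L], marker_j = pairs[, 2L],
                    testing_accuracy = acc, stringsAsFactors = FALSE)
  class(out) <- c("screen_scores_2d", "data.frame")
  out
}

#' Keep the top candidate markers per chromosome
#'
#' Retains, per chromosome, the `per_chromosome_k` markers with highest
#' single-locus testing accuracy (ties broken by smaller bp position, then
#' marker id), plus every marker appearing in a top-`per_chromosome_k`
#' pair of the optional two-locus scores.
#'
#' @param scores a [gmdr_screen_1d()] result.
#' @param per_chromosome_k candidates kept per chromosome (default 400,
#'   capped at the number of markers on the chromosome).
#' @param scores_2d optional [gmdr_screen_2d()] result.
#' @return character vector of marker ids (map order).
#' @export
select_top_candidates <- function(scores, per_chromosome_k = 400L,
                                  scores_2d = NULL) {
  stopifnot(inherits(scores, "screen_scores"))
  keep <- unlist(lapply(split(scores, scores$chromosome), function(d) {
    d <- d[order(-d$testing_accuracy, d$position_bp, d$term), , drop = FALSE]
    head(d$term, per_chromosome_k)
  }), use.names = FALSE)
  if (!is.null(scores_2d) && nrow(scores_2d)) {
    d2 <- scores_2d[order(-scores_2d$testing_accuracy), , drop = FALSE]
    top <- head(d2, per_chromosome_k)
    keep <- c(keep, top$marker_i, top$marker_j)
  }
  scores$term[scores$term %in% keep]
}
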