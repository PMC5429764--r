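#' Simulator configuration for a biparental RIL population
#'
#' @param n_chromosomes number of chromosomes.
#' @param markers_per_chromosome markers per chromosome, evenly spaced in
#'   genetic distance.
#' @param chromosome_length_cM genetic length of each chromosome.
#' @param n_lines number of RILs (default 138).
#' @param n_selfing_generations selfing generations after the F1
#'   (default 12, i.e. F13 lines).
#' @param seed RNG seed used by [simulate_ril_genotypes()].
#' @return list of class `sim_map_config`.
#' @export
sim_map_config <- function(n_chromosomes = 12, markers_per_chromosome = 20,
                           chromosome_length_cM = 150, n_lines = 138,
                           n_selfing_generations = 12, seed = 1L) {
  stopifnot(n_chromosomes >= 1, markers_per_chromosome >= 1, n_lines >= 1,
            n_selfing_generations >= 1, chromosome_length_cM > 0)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 markers_per_chromosome = as.integer(markers_per_chromosome),
                 chromosome_length_cM = as.numeric(chromosome_length_cM),
                 n_lines = as.integer(n_lines),
                 n_selfing_generations = as.integer(n_selfing_generations),
                 seed = as.integer(seed)),
            class = "sim_map_config")
}

#' Marker map implied by a simulator configuration
#'
#' Markers are evenly spaced in cM along each chromosome (a single marker
#' sits mid-chromosome); physical positions use a nominal 250 kb/cM.
#'
#' @param cfg a [sim_map_config()].
#' @return a [marker_map()] with `position_cM`.
#' @export
build_sim_map <- function(cfg) {
  stopifnot(inherits(cfg, "sim_map_config"))
  m <- cfg$markers_per_chromosome
  L <- cfg$chromosome_length_cM
  cm <- if (m == 1L) L / 2 else seq(0, L, length.out = m)
  chrs <- as.character(seq_len(cfg$n_chromosomes))
  marker_map(
    marker_id = paste0("c", rep(chrs, each = m), "m", rep(seq_len(m), cfg$n_chromosomes)),
    chromosome = rep(chrs, each = m),
    position_bp = rep(1L + as.integer(round(cm * 250000)), cfg$n_chromosomes),
    position_cM = rep(cm, cfg$n_chromosomes))
}

# Haldane map function: cM distance -> recombination fraction per meiosis
haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

# RIL-adjusted recombination fraction for selfed inbred lines
ril_recomb <- function(r) 2 * r / (1 + 2 * r)

# one round of gamete formation for all lines on one chromosome:
# A, B are n x m 0/1 origin matrices; r is the m-1 vector of adjacent
# recombination fractions. Returns one gamete per line.
.make_gametes <- function(A, B, r) {
  n <- nrow(A); m <- ncol(A)
  take <- matrix(0L, n, m)
  take[, 1L] <- rbinom(n, 1L, 0.5)
  if (m > 1L)
    for (j in 2:m)
      take[, j] <- (take[, j - 1L] + rbinom(n, 1L, r[j - 1L])) %% 2L
  gam <- A
  sel <- take == 1L
  gam[sel] <- B[sel]
  gam
}

#' Simulate RIL genotypes by single-seed descent
#'
#' Two modes are provided. `"meiosis"` runs the full generation-by-
#' generation engine: every line starts as an F1 (one intact paternal and
#' one maternal chromosome set), and each selfing generation draws two
#' gametes per line with crossovers between adjacent markers at Haldane
#' recombination fractions (no interference). Residual heterozygous loci at
#' the final generation are resolved by a fair coin and counted. `"mosaic"`
#' samples the limiting F-infinity distribution directly: each chromosome
#' is a Markov chain of +/-1 codes whose adjacent switch probability is the
#' RIL-adjusted recombination fraction 2r/(1+2r); it is much faster and has
#' the meiosis engine as its oracle.
#'
#' @param cfg a [sim_map_config()].
#' @param mode `"meiosis"` (default) or `"mosaic"`.
#' @return a [genotype_matrix()] with attributes `het_before_resolution`
#'   (count of heterozygous line-marker pairs at the final selfing
#'   generation; 0 in mosaic mode) and `het_rate`.
#' @export
simulate_ril_genotypes <- function(cfg, mode = c("meiosis", "mosaic")) {
  stopifnot(inherits(cfg, "sim_map_config"))
  mode <- match.arg(mode)
  map <- build_sim_map(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_lines
  codes <- matrix(NA_real_, n, nrow(map),
                  dimnames = list(sprintf("RIL%03d", seq_len(n)),
                                  map$marker_id))
  n_het <- 0L
  for (chr in unique(map$chromosome)) {
    j <- which(map$chromosome == chr)
    m <- length(j)
    r <- if (m > 1L) haldane_r(diff(map$position_cM[j])) else numeric(0)
    if (mode == "meiosis") {
      A <- matrix(0L, n, m)
      B <- matrix(1L, n, m)
      for (g in seq_len(cfg$n_selfing_generations)) {
        g1 <- .make_gametes(A, B, r)
        g2 <- .make_gametes(A, B, r)
        A <- g1; B <- g2
      }
      het <- A != B
      n_het <- n_het + sum(het)
      origin <- A
      if (any(het)) {
        coin <- matrix(rbinom(n * m, 1L, 0.5), n, m)
        origin[het] <- ifelse(coin[het] == 1L, B[het], A[het])
      }
      codes[, j] <- 1 - 2 * origin
    } else {
      R <- ril_recomb(r)
      x <- matrix(0L, n, m)
      x[, 1L] <- rbinom(n, 1L, 0.5)
      if (m > 1L)
        for (k in 2:m)
          x[, k] <- (x[, k - 1L] + rbinom(n, 1L, R[k - 1L])) %% 2L
      codes[, j] <- 1 - 2 * x
    }
  }
  g <- genotype_matrix(codes, map)
  attr(g, "het_before_resolution") <- n_het
  attr(g, "het_rate") <- n_het / length(codes)
  g
}

#' Planted genetic architecture for phenotype simulation
#'
#' Holds the generative parameters of the saturated genetic model: the
#' population mean, additive effects, additive-by-additive epistatic
#' effects, environment main effects, environment-interaction deviations
#' (which must sum to ~0 over environments for each term), and the residual
#' SD.
#'
#' @param mu population mean.
#' @param additive data.frame (`marker_id`, `a`) or NULL.
#' @param epistatic data.frame (`marker_i`, `marker_j`, `aa`) or NULL.
#' @param env_effects named numeric vector of environment main effects
#'   `e_h` (names = environment labels) or NULL.
#' @param ae data.frame (`marker_id`, `environment`, `ae`) or NULL.
#' @param aae data.frame (`marker_i`, `marker_j`, `environment`, `aae`) or
#'   NULL.
#' @param residual_sd SD of the residual, >= 0.
#' @param zero_sum_tol tolerance on per-term interaction deviations summing
#'   to zero (absolute, relative to `max(1, max |effect|)`); published
#'   deviations are rounded to 2 decimals, hence the slack.
#' @return list of class `qts_truth`.
#' @export
qts_truth <- function(mu = 0, additive = NULL, epistatic = NULL,
                      env_effects = NULL, ae = NULL, aae = NULL,
                      residual_sd = 1, zero_sum_tol = 0.02) {
  stopifnot(residual_sd >= 0)
  chk0 <- function(d, eff, by) {
    if (is.null(d) || nrow(d) == 0L) return(invisible())
    s <- vapply(split(d[[eff]], d[, by, drop = FALSE]), sum, numeric(1))
    tol <- zero_sum_tol * max(1, max(abs(d[[eff]])))
    if (any(abs(s) > tol))
      stop(eff, " deviations must sum to ~0 over environments per term")
  }
  chk0(ae, "ae", "marker_id")
  if (!is.null(aae) && nrow(aae))
    chk0(cbind(aae, pair = paste(aae$marker_i, aae$marker_j)), "aae", "pair")
  structure(list(mu = mu, additive = additive, epistatic = epistatic,
                 env_effects = env_effects, ae = ae, aae = aae,
                 residual_sd = residual_sd),
            class = "qts_truth")
}

# all marker ids referenced by a truth object
truth_markers <- function(truth) {
  unique(c(truth$additive$marker_id,
           truth$epistatic$marker_i, truth$epistatic$marker_j,
           truth$ae$marker_id, truth$aae$marker_i, truth$aae$marker_j))
}

#' Simulate multi-environment phenotypes from planted effects
#'
#' Generates `y_hk = mu + sum_i a_i x_ik + sum_{i<j} aa_ij x_ik x_jk + e_h
#' + sum_i ae_hi x_ik + sum_{i<j} aae_hij x_ik x_jk + eps_hk` with
#' `eps ~ N(0, residual_sd^2)`, one observation per line per environment.
#'
#' @param g a [genotype_matrix()] (no missing codes).
#' @param truth a [qts_truth()]; all referenced markers must exist in
#'   `g$map`.
#' @param environments ordered environment labels; defaults to the names of
#'   `truth$env_effects`, else `c("E1", "E2")`.
#' @param seed RNG seed for the residuals.
#' @param trait name given to the simulated trait (default `"trait"`).
#' @return a [phenotype_table()].
#' @export
simulate_phenotypes <- function(g, truth, environments = NULL, seed = 1L,
                                trait = "trait") {
  stopifnot(inherits(g, "genotype_matrix"), inherits(truth, "qts_truth"))
  if (anyNA(g$codes)) stop("genotypes contain missing codes; impute first")
  unknown <- setdiff(truth_markers(truth), g$map$marker_id)
  if (length(unknown))
    stop("truth references unknown marker(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(environments))
    environments <- if (!is.null(truth$env_effects))
      names(truth$env_effects) else c("E1", "E2")
  n <- length(g$line_ids)
  G <- rep(truth$mu, n)
  if (!is.null(truth$additive) && nrow(truth$additive))
    G <- G + as.vector(g$codes[, truth$additive$marker_id, drop = FALSE] %*%
                         truth$additive$a)
  if (!is.null(truth$epistatic) && nrow(truth$epistatic)) {
    prod <- g$codes[, truth$epistatic$marker_i, drop = FALSE] *
      g$codes[, truth$epistatic$marker_j, drop = FALSE]
    G <- G + as.vector(prod %*% truth$epistatic$aa)
  }
  set.seed(seed)
  recs <- lapply(environments, function(h) {
    y <- G
    if (!is.null(truth$env_effects) && h %in% names(truth$env_effects))
      y <- y + truth$env_effects[[h]]
    if (!is.null(truth$ae) && nrow(truth$ae)) {
      sub <- truth$ae[truth$ae$environment == h, , drop = FALSE]
      if (nrow(sub))
        y <- y + as.vector(g$codes[, sub$marker_id, drop = FALSE] %*% sub$ae)
    }
    if (!is.null(truth$aae) && nrow(truth$aae)) {
      sub <- truth$aae[truth$aae$environment == h, , drop = FALSE]
      if (nrow(sub))
        y <- y + as.vector((g$codes[, sub$marker_i, drop = FALSE] *
                              g$codes[, sub$marker_j, drop = FALSE]) %*% sub$aae)
    }
    y <- y + rnorm(n, 0, truth$residual_sd)
    data.frame(line_id = g$line_ids, environment = h, trait = trait,
               value = y, stringsAsFactors = FALSE)
  })
  phenotype_table(do.call(rbind, recs), environments = environments)
}

#' Effect preset emulating one of the reference yield traits
#'
#' Builds a [qts_truth()] whose effects are the catalogued values for the
#' requested trait ([yield_qts_catalogue()]), placed on a simulated genome:
#' loci go to the marker nearest the evenly spaced quantiles of their
#' catalogued chromosome (a single locus sits mid-chromosome). The target
#' phenotypic variance `V_P` is back-solved from the catalogued total
#' heritability, `V_P = (sum a^2 + sum aa^2 + mean_h sum ae_h^2) / h2_T`
#' (marker variance 1), and the residual SD is then solved so that the
#' *expected* sample `V_P` -- including the covariance `2 a_i a_j (1-2R)`
#' between loci sharing a chromosome, with `R` the RIL-adjusted
#' recombination fraction -- hits that target. Environment main effects
#' split the reference between-location mean difference D symmetrically
#' around the reference grand mean.
#'
#' @param trait one of `"GYD"`, `"NP"`, `"NFGP"`, `"GW"`.
#' @param cfg a [sim_map_config()] defining the simulated genome (default:
#'   12 chromosomes x 20 markers, 150 cM, 138 lines).
#' @return list of class `truth_preset` with elements `trait`, `truth`
#'   (a [qts_truth()]), `cfg`, `V_P`, `placement` (data.frame: qts,
#'   chromosome, marker_id, position_cM), and `expected_h2` (data.frame per
#'   component: qts, component, effect, h2).
#' @export
make_truth_preset <- function(trait = c("GYD", "NP", "NFGP", "GW"),
                              cfg = sim_map_config()) {
  trait <- match.arg(trait)
  stopifnot(inherits(cfg, "sim_map_config"))
  cat_ <- yield_qts_catalogue()
  sub <- cat_[cat_$trait == trait, , drop = FALSE]
  map <- build_sim_map(cfg)
  ref <- yield_trait_reference()

  # place single-locus terms: evenly spaced quantiles per chromosome
  loci <- unique(sub[sub$component %in% c("a", "ae"), c("qts", "chromosome")])
  place <- do.call(rbind, lapply(split(loci, loci$chromosome), function(d) {
    chr <- d$chromosome[1]
    if (!chr %in% map$chromosome)
      stop("preset chromosome ", chr, " absent from simulated map; ",
           "increase n_chromosomes")
    cand <- map[map$chromosome == chr, , drop = FALSE]
    L <- cfg$chromosome_length_cM
    targets <- L * seq_len(nrow(d)) / (nrow(d) + 1)
    idx <- integer(0)
    for (tcm in targets) {
      k <- order(abs(cand$position_cM - tcm))
      k <- k[!(k %in% idx)][1]
      if (is.na(k)) stop("not enough markers on chromosome ", chr)
      idx <- c(idx, k)
    }
    data.frame(qts = d$qts, chromosome = chr,
               marker_id = cand$marker_id[idx],
               position_cM = cand$position_cM[idx], stringsAsFactors = FALSE)
  }))
  rownames(place) <- NULL
  id_of <- setNames(place$marker_id, place$qts)

  add <- sub[sub$component == "a", , drop = FALSE]
  additive <- data.frame(marker_id = unname(id_of[add$qts]), a = add$effect,
                         stringsAsFactors = FALSE)
  aerow <- sub[sub$component == "ae", , drop = FALSE]
  ae <- if (nrow(aerow))
    data.frame(marker_id = unname(id_of[aerow$qts]),
               environment = aerow$environment, ae = aerow$effect,
               stringsAsFactors = FALSE) else NULL
  aarow <- sub[sub$component == "aa", , drop = FALSE]
  epistatic <- if (nrow(aarow)) {
    ij <- strsplit(aarow$qts, " & ", fixed = TRUE)
    data.frame(marker_i = unname(id_of[vapply(ij, `[`, "", 1)]),
               marker_j = unname(id_of[vapply(ij, `[`, "", 2)]),
               aa = aarow$effect, stringsAsFactors = FALSE)
  } else NULL

  # variance bookkeeping (marker variance 1, codes +/-1)
  envs <- c("E1", "E2")
  ss_a <- sum(additive$a^2)
  ss_aa <- if (is.null(epistatic)) 0 else sum(epistatic$aa^2)
  ms_ae <- if (is.null(ae)) 0 else
    sum(vapply(split(ae$ae, ae$marker_id), function(v) mean(v^2), numeric(1)))
  h2T <- sum(sub$h2, na.rm = TRUE) / 100
  V_P <- (ss_a + ss_aa + ms_ae) / h2T
  # linkage covariance between additive terms sharing a chromosome
  cov_link <- 0
  pl <- merge(additive, place, by = "marker_id")
  for (chr in unique(pl$chromosome)) {
    d <- pl[pl$chromosome == chr, , drop = FALSE]
    if (nrow(d) > 1L)
      for (i in seq_len(nrow(d) - 1L))
        for (j in (i + 1L):nrow(d)) {
          rho <- 1 - 2 * ril_recomb(haldane_r(abs(d$position_cM[i] -
                                                    d$position_cM[j])))
          cov_link <- cov_link + 2 * d$a[i] * d$a[j] * rho
        }
  }
  resid_var <- V_P - (ss_a + ss_aa + ms_ae + cov_link)
  if (resid_var <= 0) stop("non-positive residual variance in preset")

  # environment main effects: split reference D symmetrically; mu = grand mean
  dref <- ref$difference[ref$difference$trait == trait, ]
  mu <- mean(ref$per_environment$mean[ref$per_environment$trait == trait])
  env_effects <- setNames(c(dref$D / 2, -dref$D / 2), envs)

  truth <- qts_truth(mu = mu, additive = additive, epistatic = epistatic,
                     env_effects = env_effects, ae = ae,
                     residual_sd = sqrt(resid_var))
  exp_h2 <- rbind(
    data.frame(qts = add$qts, component = "a",
               effect = add$effect, h2 = 100 * add$effect^2 / V_P),
    if (nrow(aerow)) data.frame(
      qts = aerow$qts[1], component = "ae", effect = NA_real_,
      h2 = 100 * mean(aerow$effect^2) / V_P) else NULL,
    if (nrow(aarow)) data.frame(
      qts = aarow$qts, component = "aa", effect = aarow$effect,
      h2 = 100 * aarow$effect^2 / V_P) else NULL)
  structure(list(trait = trait, truth = truth, cfg = cfg, V_P = V_P,
                 placement = place, expected_h2 = exp_h2),
            class = "truth_preset")
}

#' Simulate a full dataset from a preset
#'
#' Convenience wrapper: simulates genotypes under the preset's map
#' configuration and phenotypes under its planted effects, returning an
#' aligned [validate_dataset()] bundle.
#'
#' @param preset a [make_truth_preset()] result.
#' @param seed seed controlling both genotypes and residuals.
#' @param mode genotype simulation mode, see [simulate_ril_genotypes()].
#' @return a `dataset_bundle` with attribute `preset`.
#' @export
simulate_preset_dataset <- function(preset, seed = 1L,
                                    mode = c("meiosis", "mosaic")) {
  stopifnot(inherits(preset, "truth_preset"))
  mode <- match.arg(mode)
  cfg <- preset$cfg
  cfg$seed <- as.integer(seed)
  g <- simulate_ril_genotypes(cfg, mode = mode)
  p <- simulate_phenotypes(g, preset$truth, seed = seed + 1L,
                           trait = preset$trait)
  b <- validate_dataset(g, p)
  attr(b, "preset") <- preset
  b
}

#' Serialise a truth object to YAML (and read it back)
#'
#' Used to keep the planted architecture alongside simulated datasets for
#' recovery tests.
#'
#' @param truth a [qts_truth()].
#' @param path output YAML file.
#' @return `path` invisibly for the writer, a [qts_truth()] for the reader.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "qts_truth"))
  obj <- lapply(unclass(truth), function(x)
    if (is.data.frame(x)) as.list(x) else x)
  obj$env_effects <- as.list(truth$env_effects)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- yaml::read_yaml(path)
  df <- function(x) if (is.null(x) || length(x) == 0L) NULL else
    as.data.frame(x, stringsAsFactors = FALSE)
  qts_truth(mu = obj$mu, additive = df(obj$additive),
            epistatic = df(obj$epistatic),
            env_effects = if (length(obj$env_effects))
              unlist(obj$env_effects) else NULL,
            ae = df(obj$ae), aae = df(obj$aae),
            residual_sd = obj$residual_sd)
}
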