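#' Reference QTS effect catalogue for rice yield traits
#'
#' Detected quantitative trait SNPs for grain yield (GYD), panicle number
#' per plant (NP), filled grains per panicle (NFGP), and 1000-grain weight
#' (GW) in a 138-line F13 rice RIL population (XieqingzaoB x Zhonghui9308)
#' grown in two locations (Hangzhou = E1, Lingshui = E2). One row per
#' genetic component: additive (`a`), additive-by-environment (`ae`, one row
#' per environment, heritability shared by the pair and stored on the E1
#' row), and additive-by-additive epistasis (`aa`, `qts` holds both marker
#' ids separated by `" & "`). Effects are expressed for the paternal-allele
#' homozygote (QQ, Zhonghui9308), coded +1.
#'
#' These values parameterise the simulator presets
#' ([make_truth_preset()]) and the internal-consistency checks
#' ([total_heritability()], [check_h2_proportionality()]).
#'
#' @return data.frame with columns `trait`, `qts`, `chromosome`, `allele`,
#'   `component`, `environment`, `effect`, `neg_log10_p`, `h2`.
#' @export
yield_qts_catalogue <- function() {
  rw <- function(trait, qts, chr, allele, component, env, effect, nlp, h2)
    data.frame(trait = trait, qts = qts, chromosome = chr, allele = allele,
               component = component, environment = env, effect = effect,
               neg_log10_p = nlp, h2 = h2, stringsAsFactors = FALSE)
  rbind(
    rw("GYD", "rs8203251",  "4",  "C/T", "a",  NA,   -1.54, 12.43, 10.91),
    rw("GYD", "rs8203251",  "4",  "C/T", "ae", "E1", -0.65,  1.62,  1.91),
    rw("GYD", "rs8203251",  "4",  "C/T", "ae", "E2",  0.64,  1.61,  NA),
    rw("GYD", "rs26662491", "5",  "A/C", "a",  NA,   -1.04,  6.09,  5.02),
    rw("GYD", "rs5137246",  "6",  "T/G", "a",  NA,    1.19,  7.76,  6.56),
    rw("GYD", "rs26302731", "6",  "G/A", "a",  NA,   -1.42, 10.75,  9.34),
    rw("GYD", "rs12354751", "9",  "A/G", "a",  NA,   -0.93,  4.98,  4.01),
    rw("GYD", "rs17926420", "12", "C/A", "a",  NA,   -1.07,  6.40,  5.31),
    rw("NP",  "rs28989077", "3",  "C/T", "a",  NA,   -0.83, 20.65, 18.54),
    rw("NP",  "rs20829501", "7",  "C/T", "a",  NA,   -0.65, 13.01, 11.39),
    rw("NP",  "rs20270326", "9",  "T/C", "a",  NA,   -0.44,  6.23,  5.12),
    rw("NP",  "rs9429313",  "10", "A/C", "a",  NA,   -0.47,  7.16,  5.98),
    rw("NP",  "rs20829501 & rs9429313", "7 & 10", "C/T & A/C",
                                        "aa", NA,    0.29,  3.12,  2.32),
    rw("NFGP", "rs41315645", "1",  "G/A", "a", NA,    6.31,  9.70,  8.16),
    rw("NFGP", "rs27878540", "3",  "C/T", "a", NA,    4.31,  4.87,  3.82),
    rw("NFGP", "rs29922937", "3",  "A/T", "a", NA,    6.45, 10.10,  8.53),
    rw("NFGP", "rs31992782", "4",  "A/T", "a", NA,   -4.60,  5.45,  4.33),
    rw("NFGP", "rs645267",   "5",  "A/G", "a", NA,   -5.57,  7.70,  6.35),
    rw("NFGP", "rs24646393", "6",  "G/A", "a", NA,    4.23,  4.70,  3.67),
    rw("NFGP", "rs23681930", "11", "C/T", "a", NA,    5.83,  8.38,  6.96),
    rw("NFGP", "rs645267 & rs23681930", "5 & 11", "A/G & C/T",
                                        "aa", NA,    3.55,  3.47,  2.58),
    rw("GW",  "rs7115540",  "1",  "C/T", "a",  NA,   -0.49,  7.09,  5.43),
    rw("GW",  "rs12778614", "2",  "A/T", "a",  NA,   -0.44,  5.93,  4.45),
    rw("GW",  "rs18572583", "3",  "T/C", "a",  NA,   -0.82, 18.52, 15.19),
    rw("GW",  "rs13250114", "5",  "A/C", "a",  NA,   -0.50,  7.40,  5.69),
    rw("GW",  "rs23416877", "6",  "G/A", "a",  NA,   -0.54,  8.64,  6.74),
    rw("GW",  "rs2377773",  "11", "C/T", "a",  NA,   -0.46,  6.43,  4.87),
    rw("GW",  "rs25458920", "12", "T/C", "a",  NA,    0.51,  7.76,  5.99)
  )
}

#' Reference trait summaries for the RIL yield study
#'
#' Per-environment means, SDs, ranges and CVs of the four yield traits in
#' the reference RIL population, plus the between-location mean difference
#' D = mean(E1) - mean(E2). Used to calibrate simulator environment effects
#' and population means.
#'
#' @return list with `per_environment` (data.frame: trait, environment,
#'   mean, sd, min, max, cv) and `difference` (data.frame: trait, D,
#'   significance).
#' @export
yield_trait_reference <- function() {
  pe <- data.frame(
    trait = rep(c("GYD", "NP", "NFGP", "GW"), each = 2),
    environment = rep(c("E1", "E2"), 4),
    mean = c(22.86, 17.69, 10.60, 8.21, 88.22, 95.69, 25.68, 25.14),
    sd   = c(6.10, 3.47, 2.03, 1.86, 24.27, 24.26, 2.54, 2.57),
    min  = c(8.50, 7.70, 5.60, 4.80, 27.80, 38.10, 20.70, 19.60),
    max  = c(39.50, 27.00, 18.00, 16.70, 152.50, 153.60, 37.60, 37.80),
    cv   = c(26.68, 19.61, 19.20, 22.63, 27.51, 25.36, 9.88, 10.23),
    stringsAsFactors = FALSE)
  diff <- data.frame(trait = c("GYD", "NP", "NFGP", "GW"),
                     D = c(5.17, 2.38, -7.47, 0.54),
                     significance = c("**", "*", "**", ""),
                     stringsAsFactors = FALSE)
  list(per_environment = pe, difference = diff)
}

#' Total heritability per trait from a QTS component table
#'
#' Sums per-component heritabilities (each `ae`/`aae` pair contributes one
#' component value) to the accumulated explanatory heritability of each
#' trait.
#'
#' @param catalogue a component table shaped like [yield_qts_catalogue()].
#' @param components which component types to include (default all).
#' @return named numeric vector of summed h2 (%), one element per trait, in
#'   order of appearance.
#' @export
total_heritability <- function(catalogue = yield_qts_catalogue(),
                               components = c("a", "ae", "aa", "aae")) {
  cat_ <- catalogue[catalogue$component %in% components, , drop = FALSE]
  sums <- vapply(split(cat_$h2, factor(cat_$trait, unique(cat_$trait))),
                 function(x) sum(x, na.rm = TRUE), numeric(1))
  round(sums, 10)
}

#' Internal-consistency check of the heritability formula
#'
#' Under `h2 = 100 * effect^2 * Var(x) / V_P` with a single phenotypic
#' variance `V_P` per trait and `Var(x)` constant (= 1 in a balanced RIL),
#' the catalogued h2 values must be proportional to squared effect sizes
#' within each trait. For `ae` components the squared effect is the mean of
#' the squared per-environment deviations. The implied
#' `V_P = 100 * effect^2 / h2` is back-solved per component; its spread
#' within a trait measures how well the proportionality holds.
#'
#' @param catalogue a component table shaped like [yield_qts_catalogue()].
#' @return data.frame with one row per (trait, term, component):
#'   `effect_sq`, `h2`, `implied_VP`, and `rel_dev`, the relative deviation
#'   of `implied_VP` from the trait median.
#' @export
check_h2_proportionality <- function(catalogue = yield_qts_catalogue()) {
  rows <- list()
  for (tr in unique(catalogue$trait)) {
    sub <- catalogue[catalogue$trait == tr, , drop = FALSE]
    for (term in unique(sub$qts)) {
      tsub <- sub[sub$qts == term, , drop = FALSE]
      for (comp in unique(tsub$component)) {
        csub <- tsub[tsub$component == comp, , drop = FALSE]
        eff2 <- mean(csub$effect^2)   # mean over environments for ae/aae
        h2 <- sum(csub$h2, na.rm = TRUE)
        rows[[length(rows) + 1L]] <-
          data.frame(trait = tr, qts = term, component = comp,
                     effect_sq = eff2, h2 = h2,
                     implied_VP = 100 * eff2 / h2, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  med <- vapply(split(out$implied_VP, factor(out$trait, unique(out$trait))),
                median, numeric(1))
  out$rel_dev <- out$implied_VP / med[out$trait] - 1
  out
}
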