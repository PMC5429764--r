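# component set of a fitted model: per term, the components whose
# component-level test is significant at `component_alpha` (the main
# a/aa component is always present -- the term was selected)
model_component_sets <- function(model, component_alpha = 0.05) {
  if (is.null(model) || nrow(model$terms) == 0L) return(list())
  eff <- model$effects
  out <- list()
  for (term in unique(eff$term)) {
    sub <- eff[eff$term == term, , drop = FALSE]
    comps <- unique(sub$component[sub$component %in% c("a", "aa")])
    for (ic in c("ae", "aae")) {
      rows <- sub[sub$component == ic, , drop = FALSE]
      if (nrow(rows) && any(!is.na(rows$neg_log10_p) &
                            rows$neg_log10_p > -log10(component_alpha)))
        comps <- c(comps, ic)
    }
    out[[term]] <- comps
  }
  out
}

#' Classify terms across unconditional and conditional mappings
#'
#' Pure set logic on "term -> component set" maps: a term significant in
#' both mappings with an unchanged component set is `retained`; with a
#' component gained or lost it is `retained_component_changed`; a term
#' significant only unconditionally is `absent_under_conditioning`; one
#' significant only conditionally is `novel_conditional`.
#'
#' @param unconditional named list: term -> character vector of components
#'   (e.g. `list(rs1 = c("a", "ae"))`).
#' @param conditional same shape, for one conditioning.
#' @return data.frame `term`, `status`.
#' @export
compare_term_sets <- function(unconditional, conditional) {
  terms <- union(names(unconditional), names(conditional))
  status <- vapply(terms, function(t) {
    in_u <- t %in% names(unconditional)
    in_c <- t %in% names(conditional)
    if (in_u && in_c) {
      if (setequal(unconditional[[t]], conditional[[t]])) "retained"
      else "retained_component_changed"
    } else if (in_u) "absent_under_conditioning"
    else "novel_conditional"
  }, "")
  data.frame(term = terms, status = unname(status), stringsAsFactors = FALSE)
}

#' Compare an unconditional model with conditional models
#'
#' Applies [compare_term_sets()] to a fitted unconditional model and one
#' or more conditional models (the target trait conditioned on different
#' component traits), classifying every QTS under every conditioning.
#'
#' @param unconditional a `qts_model` (or NULL for an empty model).
#' @param conditionals named list of `qts_model`s (names = conditioning
#'   trait).
#' @param component_alpha nominal level deciding whether an interaction
#'   component is present (default 0.05).
#' @return data.frame of class `conditional_comparison`: `term`,
#'   `conditioning`, `status`.
#' @export
compare_conditional <- function(unconditional, conditionals,
                                component_alpha = 0.05) {
  u <- model_component_sets(unconditional, component_alpha)
  out <- do.call(rbind, lapply(names(conditionals), function(nm) {
    cmp <- compare_term_sets(
      u, model_component_sets(conditionals[[nm]], component_alpha))
    if (nrow(cmp)) cmp$conditioning <- nm
    cmp
  }))
  if (is.null(out))
    out <- data.frame(term = character(0), status = character(0),
                      conditioning = character(0), stringsAsFactors = FALSE)
  class(out) <- c("conditional_comparison", "data.frame")
  out
}

#' Render a fitted model as a publication-style QTS table
#'
#' One row per genetic component per term: trait, QTS, chromosome,
#' component (`a`, `ae1`, `ae2`, ..., `aa`, `aae1`, ...), effect size,
#' -log10(P), h2(%), h2_T(%) -- effects and heritabilities rounded to two
#' decimals, deterministic row order (terms in model order, `a`/`aa`
#' before interaction rows).
#'
#' @param model a `qts_model`, or NULL for a header-only table.
#' @param path optional TSV output path.
#' @return the table data.frame (invisibly when `path` is given).
#' @export
render_qts_table <- function(model, path = NULL) {
  cols <- c("trait", "qts", "chromosome", "component", "effect",
            "neg_log10_p", "h2", "h2_total")
  if (is.null(model) || nrow(model$terms) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                  cols), stringsAsFactors = FALSE)
  } else {
    eff <- model$effects
    envs <- model$environments
    chr <- setNames(model$terms$chromosome, model$terms$label)
    comp_label <- ifelse(eff$component %in% c("a", "aa"), eff$component,
                         paste0(eff$component,
                                match(eff$environment, envs)))
    out <- data.frame(trait = model$trait, qts = eff$term,
                      chromosome = unname(chr[eff$term]),
                      component = comp_label,
                      effect = sprintf("%.2f", eff$estimate),
                      neg_log10_p = sprintf("%.2f", eff$neg_log10_p),
                      h2 = ifelse(is.na(eff$h2), "",
                                  sprintf("%.2f", eff$h2)),
                      h2_total = "", stringsAsFactors = FALSE)
    out$h2_total[1L] <- sprintf("%.2f", model$h2_total)
  }
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Export the QTS network as node and edge lists
#'
#' Nodes are the QTSs of all supplied models with their trait, component
#' set, and an environment-specific flag (TRUE when an `ae`/`aae`
#' component is present at `component_alpha`); edges are the epistatic
#' pairs.
#'
#' @param models list of `qts_model`s (NULL entries allowed).
#' @param component_alpha nominal level for the environment-specific flag.
#' @return list with `nodes` (data.frame: trait, term, components,
#'   environment_specific) and `edges` (data.frame: trait, marker_i,
#'   marker_j, aa_hat).
#' @export
export_network <- function(models, component_alpha = 0.05) {
  nodes <- list(); edges <- list()
  for (model in models) {
    if (is.null(model) || nrow(model$terms) == 0L) next
    sets <- model_component_sets(model, component_alpha)
    for (i in seq_len(nrow(model$terms))) {
      tm <- model$terms[i, ]
      if (tm$type == "pair") {
        aa <- model$effects$estimate[model$effects$term == tm$label &
                                       model$effects$component == "aa"]
        edges[[length(edges) + 1L]] <- data.frame(
          trait = model$trait, marker_i = tm$marker_i,
          marker_j = tm$marker_j, aa_hat = aa, stringsAsFactors = FALSE)
      }
      members <- if (tm$type == "pair") c(tm$marker_i, tm$marker_j)
        else tm$marker_i
      for (mk in members)
        nodes[[length(nodes) + 1L]] <- data.frame(
          trait = model$trait, term = mk,
          components = paste(sets[[tm$label]], collapse = "+"),
          environment_specific = any(c("ae", "aae") %in% sets[[tm$label]]),
          stringsAsFactors = FALSE)
    }
  }
  nodes <- if (length(nodes)) do.call(rbind, nodes) else
    data.frame(trait = character(0), term = character(0),
               components = character(0),
               environment_specific = logical(0), stringsAsFactors = FALSE)
  # a marker can enter via several terms: keep one row, OR-ing the flag
  if (nrow(nodes)) {
    key <- paste(nodes$trait, nodes$term)
    nodes <- do.call(rbind, lapply(split(nodes, key), function(d)
      data.frame(trait = d$trait[1L], term = d$term[1L],
                 components = paste(unique(unlist(
                   strsplit(d$components, "+", fixed = TRUE))),
                   collapse = "+"),
                 environment_specific = any(d$environment_specific),
                 stringsAsFactors = FALSE)))
    nodes <- nodes[order(nodes$trait, nodes$term), , drop = FALSE]
    rownames(nodes) <- NULL
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(trait = character(0), marker_i = character(0),
               marker_j = character(0), aa_hat = numeric(0),
               stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}

#' Run the full mapping pipeline from a configuration
#'
#' Executes simulate/load, summarise, screen, map (unconditional, then
#' conditional for each requested target-given pair), and report, writing
#' all tables, the QTS network, a run log and a machine-readable manifest
#' to the output directory. Fully reproducible from (config, seed).
#'
#' Configuration (YAML file or list): either `simulate:` (fields `traits`,
#' optional `n_lines`, `markers_per_chromosome`, `chromosome_length_cM`)
#' or `inputs:` (fields `genotypes`, `format`, `phenotypes`, optional
#' `map`, `paternal`, `maternal`); optional `conditionings:` (map
#' target -> list of given traits), `alpha`, `n_permutations`,
#' `per_chromosome_k`, `epistasis`, `pair_top`, `n_iter`, `burn_in`,
#' `thin`, `seed`, `out_dir`.
#'
#' @param config YAML path or list.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return (invisibly) list with `bundle`, `fits`, `conditional_fits`,
#'   `comparison`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(list(alpha = 0.05, n_permutations = 500L,
                         per_chromosome_k = 400L, epistasis = TRUE,
                         pair_top = 12L, n_iter = 6000L, burn_in = 1000L,
                         thin = 5L, seed = 1L, conditionings = list()),
                    config)
  out_dir <- out_dir %||% cfg$out_dir %||% stop("out_dir required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  cat("", file = logf)
  files <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[3L]
    res <- tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
    cat(sprintf("%-12s %.2fs\n", name, proc.time()[3L] - t0),
        file = logf, append = TRUE)
    res
  }
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, name)
    path
  }

  bundle <- stage("load", {
    if (!is.null(cfg$simulate)) {
      sim <- cfg$simulate
      traits <- sim$traits %||% c("GYD", "NP", "NFGP", "GW")
      mapcfg <- sim_map_config(
        n_chromosomes = sim$n_chromosomes %||% 12L,
        markers_per_chromosome = sim$markers_per_chromosome %||% 20L,
        chromosome_length_cM = sim$chromosome_length_cM %||% 150,
        n_lines = sim$n_lines %||% 138L,
        seed = cfg$seed)
      g <- simulate_ril_genotypes(mapcfg)
      recs <- lapply(seq_along(traits), function(i) {
        preset <- make_truth_preset(traits[i], cfg = mapcfg)
        as.data.frame(simulate_phenotypes(g, preset$truth,
                                          seed = cfg$seed + i,
                                          trait = traits[i]))
      })
      p <- phenotype_table(do.call(rbind, recs),
                           environments = c("E1", "E2"))
      emit("genotypes.tsv", function(f) write_genotypes(g, f))
      emit("phenotypes.csv", function(f) write_phenotypes(p, f))
      validate_dataset(g, p)
    } else {
      inp <- cfg$inputs %||% stop("config needs simulate: or inputs:")
      g <- read_genotypes(inp$genotypes, format = inp$format %||% "tsv",
                          map = if (!is.null(inp$map))
                            utils::read.delim(inp$map) else NULL,
                          paternal = inp$paternal, maternal = inp$maternal)
      g <- impute_missing(g)
      validate_dataset(g, read_phenotypes(inp$phenotypes))
    }
  })
  traits <- bundle$trait_names

  stage("summarize", {
    sm <- summarize_traits(bundle$phenotypes)
    emit("summary.tsv", function(f)
      write.table(format(sm$per_environment, digits = 6), f, sep = "\t",
                  quote = FALSE, row.names = FALSE))
    emit("differences.tsv", function(f)
      write.table(format(sm$difference, digits = 6), f, sep = "\t",
                  quote = FALSE, row.names = FALSE))
    if (length(traits) > 1L) {
      gv <- predict_genotypic_values(bundle$phenotypes)
      gc_ <- genotypic_correlations(gv)
      emit("genotypic_correlations.tsv", function(f)
        write.table(round(gc_$r, 4), f, sep = "\t", quote = FALSE))
    }
  })

  fit_one <- function(b, trait, tag) {
    fit <- map_trait(b, trait, per_chromosome_k = cfg$per_chromosome_k,
                     alpha = cfg$alpha,
                     n_permutations = cfg$n_permutations,
                     epistasis = cfg$epistasis, pair_top = cfg$pair_top,
                     n_iter = cfg$n_iter, burn_in = cfg$burn_in,
                     thin = cfg$thin, seed = cfg$seed)
    emit(paste0("qts_", tag, ".tsv"), function(f)
      render_qts_table(fit$model, f))
    fit
  }
  fits <- list()
  for (tr in traits)
    fits[[tr]] <- stage(paste0("map:", tr), fit_one(bundle, tr, tr))

  cond_fits <- list()
  comparison <- NULL
  if (length(cfg$conditionings)) {
    for (target in names(cfg$conditionings)) {
      for (given in cfg$conditionings[[target]]) {
        tag <- paste0(target, ".", given)
        cond_fits[[paste0(target, "|", given)]] <-
          stage(paste0("condition:", tag), {
            cp <- conditional_phenotypes(bundle$phenotypes, target, given)
            cb <- validate_dataset(bundle$genotypes, cp)
            fit_one(cb, paste0(target, "|", given), tag)
          })
      }
      cmp <- stage(paste0("compare:", target), {
        cond_models <- lapply(
          cond_fits[grep(paste0("^", target, "\\|"), names(cond_fits))],
          `[[`, "model")
        names(cond_models) <- sub(paste0("^", target, "\\|"), "",
                                  names(cond_models))
        cc <- compare_conditional(fits[[target]]$model, cond_models)
        emit(paste0("comparison_", target, ".tsv"), function(f)
          write.table(cc, f, sep = "\t", quote = FALSE, row.names = FALSE))
        cc
      })
      comparison <- rbind(comparison, cmp)
    }
  }

  stage("report", {
    net <- export_network(c(lapply(fits, `[[`, "model"),
                            lapply(cond_fits, `[[`, "model")))
    emit("network_nodes.tsv", function(f)
      write.table(net$nodes, f, sep = "\t", quote = FALSE,
                  row.names = FALSE))
    emit("network_edges.tsv", function(f)
      write.table(net$edges, f, sep = "\t", quote = FALSE,
                  row.names = FALSE))
  })

  manifest <- list(
    seed = cfg$seed,
    traits = traits,
    unconditional_models = traits,
    conditional_models = names(cond_fits),
    files = sort(files),
    config = cfg[setdiff(names(cfg), "out_dir")])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(bundle = bundle, fits = fits,
                 conditional_fits = cond_fits, comparison = comparison,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
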