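#' Marker map
#'
#' Builds a validated marker map: one row per SNP marker with its chromosome
#' label and physical (bp) position, optionally a genetic (cM) position,
#' sorted by chromosome and position.
#'
#' @param marker_id character vector of unique marker identifiers.
#' @param chromosome chromosome labels (coerced to character). Any label set
#'   is accepted; rice conventionally uses "1".."12".
#' @param position_bp integer physical positions, 1-based.
#' @param position_cM optional numeric genetic positions, non-negative and
#'   non-decreasing within chromosome. Required by the RIL simulator.
#' @return A `data.frame` of class `marker_map` with columns `marker_id`,
#'   `chromosome`, `position_bp` and (if given) `position_cM`, sorted by
#'   (chromosome, position_bp).
#' @export
marker_map <- function(marker_id, chromosome, position_bp, position_cM = NULL) {
  marker_id <- as.character(marker_id)
  chromosome <- as.character(chromosome)
  position_bp <- as.integer(position_bp)
  n <- length(marker_id)
  if (length(chromosome) == 1L) chromosome <- rep(chromosome, n)
  stopifnot(length(chromosome) == n, length(position_bp) == n)
  if (anyDuplicated(marker_id))
    stop("duplicate marker ids: ",
         paste(unique(marker_id[duplicated(marker_id)]), collapse = ", "))
  if (any(position_bp < 1L)) stop("position_bp must be >= 1")
  map <- data.frame(marker_id = marker_id, chromosome = chromosome,
                    position_bp = position_bp, stringsAsFactors = FALSE)
  if (!is.null(position_cM)) {
    stopifnot(length(position_cM) == n)
    if (any(position_cM < 0)) stop("position_cM must be non-negative")
    map$position_cM <- as.numeric(position_cM)
  }
  ord <- order(map$chromosome, map$position_bp)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  if (!is.null(map$position_cM)) {
    bad <- vapply(split(map$position_cM, map$chromosome),
                  function(cm) any(diff(cm) < 0), logical(1))
    if (any(bad))
      stop("position_cM not non-decreasing on chromosome(s): ",
           paste(names(bad)[bad], collapse = ", "))
  }
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Genotype matrix for a biparental RIL population
#'
#' Lines-by-markers matrix of parental-origin codes: `+1` for the paternal
#' homozygote (QQ), `-1` for the maternal homozygote (qq), `NA` for missing
#' (including residual heterozygous calls, which carry no information under
#' a purely additive RIL model).
#'
#' @param codes numeric matrix, rows = lines, columns = markers, entries in
#'   `{+1, -1, NA}`.
#' @param map a [marker_map()] whose markers match `colnames(codes)`.
#' @param line_ids character vector of line identifiers; defaults to
#'   `rownames(codes)`.
#' @param max_missing maximum tolerated per-marker missing fraction
#'   (default 0.2); markers above it are rejected.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `line_ids`, `map`, `codes`.
#' @export
genotype_matrix <- function(codes, map, line_ids = rownames(codes),
                            max_missing = 0.2) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  if (is.null(line_ids)) stop("line_ids required (or set rownames on codes)")
  line_ids <- as.character(line_ids)
  if (length(line_ids) != nrow(codes))
    stop("line_ids length does not match rows of codes")
  if (anyDuplicated(line_ids))
    stop("duplicate line ids: ",
         paste(unique(line_ids[duplicated(line_ids)]), collapse = ", "))
  if (!inherits(map, "marker_map")) stop("map must be a marker_map")
  if (is.null(colnames(codes))) colnames(codes) <- map$marker_id
  if (!identical(sort(colnames(codes)), sort(map$marker_id)))
    stop("codes columns do not match map marker ids")
  codes <- codes[, map$marker_id, drop = FALSE]  # map order is canonical
  ok <- codes %in% c(1, -1) | is.na(codes)
  if (!all(ok)) stop("genotype codes must be +1, -1 or NA")
  mfrac <- colMeans(is.na(codes))
  if (any(mfrac > max_missing))
    stop("marker(s) exceed missing-fraction ceiling (", max_missing, "): ",
         paste(colnames(codes)[mfrac > max_missing], collapse = ", "))
  rownames(codes) <- line_ids
  structure(list(line_ids = line_ids, map = map, codes = codes),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nmis <- sum(is.na(x$codes))
  cat("genotype_matrix:", length(x$line_ids), "lines x",
      nrow(x$map), "markers on",
      length(unique(x$map$chromosome)), "chromosome(s);",
      nmis, "missing\n")
  invisible(x)
}

#' Multi-environment phenotype table
#'
#' Long-format table of trait observations: one row per
#' (line, environment, trait) with at most one value per cell.
#'
#' @param records data.frame with columns `line_id`, `environment`, `trait`,
#'   `value`.
#' @param environments ordered environment labels; the first label is E1
#'   (environment order matters for reporting interaction deviations).
#'   Defaults to order of first appearance.
#' @return A `data.frame` of class `phenotype_table` with an `environments`
#'   attribute.
#' @export
phenotype_table <- function(records, environments = NULL) {
  req <- c("line_id", "environment", "trait", "value")
  if (!all(req %in% names(records)))
    stop("records must have columns ", paste(req, collapse = ", "))
  rec <- data.frame(line_id = as.character(records$line_id),
                    environment = as.character(records$environment),
                    trait = as.character(records$trait),
                    value = as.numeric(records$value),
                    stringsAsFactors = FALSE)
  key <- paste(rec$line_id, rec$environment, rec$trait, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (line, environment, trait) records: ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = "; "))
  if (is.null(environments)) environments <- unique(rec$environment)
  environments <- as.character(environments)
  if (!all(rec$environment %in% environments))
    stop("records contain environments outside the declared set")
  rec <- rec[order(rec$trait, match(rec$environment, environments),
                   rec$line_id), , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "environments") <- environments
  class(rec) <- c("phenotype_table", "data.frame")
  rec
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat("phenotype_table:", length(unique(x$line_id)), "lines,",
      length(attr(x, "environments")), "environment(s),",
      length(unique(x$trait)), "trait(s),",
      nrow(x), "records (", sum(is.na(x$value)), "missing )\n")
  invisible(x)
}

#' Environment labels of a phenotype table
#' @param p a [phenotype_table()].
#' @return character vector of ordered environment labels.
#' @export
environments <- function(p) attr(p, "environments")

#' Trait names present in a phenotype table
#' @param p a [phenotype_table()].
#' @return character vector.
#' @export
trait_names <- function(p) unique(p$trait)

# lines x environments value matrix for one trait (internal workhorse)
pheno_matrix <- function(p, trait, lines = NULL) {
  envs <- environments(p)
  sub <- p[p$trait == trait, , drop = FALSE]
  if (nrow(sub) == 0L) stop("trait not present: ", trait)
  if (is.null(lines)) lines <- sort(unique(sub$line_id))
  m <- matrix(NA_real_, length(lines), length(envs),
              dimnames = list(lines, envs))
  m[cbind(match(sub$line_id, lines), match(sub$environment, envs))] <- sub$value
  m
}

#' Align a genotype matrix and phenotype table into an analysis bundle
#'
#' Keeps the lines present in both inputs (lexicographically ordered),
#' reports those dropped from either side, and carries the trait list.
#'
#' @param g a [genotype_matrix()].
#' @param p a [phenotype_table()].
#' @return An object of class `dataset_bundle`: list with `genotypes`,
#'   `phenotypes`, `trait_names`, and `dropped` (list with elements
#'   `genotypes_only`, `phenotypes_only`).
#' @export
validate_dataset <- function(g, p) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(p, "phenotype_table"))
  gl <- g$line_ids
  pl <- unique(p$line_id)
  common <- sort(intersect(gl, pl))
  if (length(common) == 0L)
    stop("no lines shared between genotypes and phenotypes")
  dropped <- list(genotypes_only = sort(setdiff(gl, pl)),
                  phenotypes_only = sort(setdiff(pl, gl)))
  g2 <- g
  g2$codes <- g$codes[match(common, gl), , drop = FALSE]
  g2$line_ids <- common
  p2 <- p[p$line_id %in% common, , drop = FALSE]
  attr(p2, "environments") <- environments(p)
  class(p2) <- class(p)
  structure(list(genotypes = g2, phenotypes = p2,
                 trait_names = trait_names(p2), dropped = dropped),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat("dataset_bundle:", length(x$genotypes$line_ids), "lines,",
      nrow(x$genotypes$map), "markers, traits:",
      paste(x$trait_names, collapse = ", "), "\n")
  nd <- lengths(x$dropped)
  if (any(nd > 0))
    cat("  dropped:", nd[["genotypes_only"]], "genotype-only,",
        nd[["phenotypes_only"]], "phenotype-only line(s)\n")
  invisible(x)
}
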