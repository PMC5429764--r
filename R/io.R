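#' Read a RIL genotype matrix from TSV or VCF
#'
#' Two on-disk representations are supported. The TSV form is a plain matrix
#' (rows = lines, columns = marker ids, cells `1` / `-1` / `NA`) with the
#' marker map supplied separately (or synthesised as a single chromosome at
#' 1 bp spacing). The VCF form is a biallelic SNP VCF that includes the two
#' parent lines as samples; each RIL genotype is recoded relative to the
#' parents: `+1` when it matches the paternal homozygote, `-1` for the
#' maternal homozygote, and missing for heterozygous, missing, or
#' parent-inconsistent calls.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param map optional [marker_map()] (TSV format only).
#' @param paternal,maternal parent sample names (VCF format only).
#' @param max_missing per-marker missing ceiling passed to
#'   [genotype_matrix()].
#' @return A [genotype_matrix()]. Records at which the parents are not two
#'   distinct homozygotes are dropped with a warning (they carry no
#'   parental-origin information).
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), map = NULL,
                           paternal = NULL, maternal = NULL,
                           max_missing = 0.2) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- tryCatch(
      read.table(path, header = TRUE, sep = "\t", row.names = 1,
                 check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) stop("genotype TSV parse error in ", path, ": ",
                               conditionMessage(e)))
    codes <- as.matrix(tab)
    storage.mode(codes) <- "double"
    bad <- which(!(codes %in% c(1, -1)) & !is.na(codes))
    if (length(bad))
      stop("genotype TSV ", path, ": invalid code at data row ",
           ((bad[1] - 1) %% nrow(codes)) + 1)
    if (is.null(map))
      map <- marker_map(colnames(codes), "1", seq_len(ncol(codes)))
    genotype_matrix(codes, map, max_missing = max_missing)
  } else {
    if (is.null(paternal) || is.null(maternal))
      stop("VCF input requires the paternal and maternal sample names")
    vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                    error = function(e) stop("VCF parse error in ", path,
                                             ": ", conditionMessage(e)))
    fix <- vcfR::getFIX(vcf)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    samples <- colnames(gt)
    missing_parents <- setdiff(c(paternal, maternal), samples)
    if (length(missing_parents))
      stop("parent sample(s) absent from VCF: ",
           paste(missing_parents, collapse = ", "))
    biallelic <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "." &
      nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
    # collapse a GT string to a single allele index, NA unless homozygous
    hom <- function(x) {
      al <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
      vapply(al, function(a) {
        a <- a[a != "."]
        if (length(a) == 0L || length(unique(a)) != 1L) return(NA_integer_)
        as.integer(a[1])
      }, integer(1))
    }
    pat <- hom(gt[, paternal])
    mat <- hom(gt[, maternal])
    informative <- biallelic & !is.na(pat) & !is.na(mat) & pat != mat
    if (!all(informative))
      warning(sum(!informative),
              " record(s) dropped: not biallelic SNPs with two distinct ",
              "homozygous parents")
    if (!any(informative)) stop("no informative records in ", path)
    keep <- which(informative)
    lines_ <- setdiff(samples, c(paternal, maternal))
    codes <- matrix(NA_real_, length(lines_), length(keep),
                    dimnames = list(lines_, fix[keep, "ID"]))
    for (s in lines_) {
      a <- hom(gt[keep, s])
      codes[s, ] <- ifelse(is.na(a), NA_real_,
                           ifelse(a == pat[keep], 1,
                                  ifelse(a == mat[keep], -1, NA_real_)))
    }
    ids <- fix[keep, "ID"]
    noid <- is.na(ids) | ids == "."
    ids[noid] <- paste0(fix[keep, "CHROM"], "_", fix[keep, "POS"])[noid]
    colnames(codes) <- ids
    map <- marker_map(ids, fix[keep, "CHROM"], as.integer(fix[keep, "POS"]))
    genotype_matrix(codes, map, max_missing = max_missing)
  }
}

#' Write a genotype matrix to TSV or VCF
#'
#' The TSV form round-trips codes exactly. The VCF form represents the
#' paternal allele as REF and the maternal allele as ALT and writes the two
#' parent samples (`0/0` and `1/1`) ahead of the RIL samples, so that
#' [read_genotypes()] recovers the same codes.
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @param format `"tsv"` or `"vcf"`.
#' @param paternal,maternal parent sample names used for VCF output.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("tsv", "vcf"),
                            paternal = "P1", maternal = "P2") {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- as.data.frame(g$codes, check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, na = "NA",
                row.names = TRUE, col.names = NA)
  } else {
    gtcode <- function(x) ifelse(is.na(x), "./.", ifelse(x > 0, "0/0", "1/1"))
    body <- apply(g$codes, 1L, gtcode)           # markers x lines
    if (is.null(dim(body))) body <- matrix(body, nrow = nrow(g$map))
    rows <- cbind(g$map$chromosome, g$map$position_bp, g$map$marker_id,
                  "A", "T", ".", "PASS", ".", "GT", "0/0", "1/1", body)
    header <- c("##fileformat=VCFv4.2",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", paternal, maternal, g$line_ids),
                      collapse = "\t"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(apply(rows, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Impute missing genotype codes from flanking markers
#'
#' Each missing code is replaced by the nearest non-missing marker code of
#' the same line on the same chromosome (distance in bp; ties go to the
#' left flank). Non-missing entries are never changed.
#'
#' @param g a [genotype_matrix()].
#' @param max_missing per-marker missing ceiling; markers above it are
#'   rejected rather than imputed.
#' @return A [genotype_matrix()] with no missing codes.
#' @export
impute_missing <- function(g, max_missing = 0.2) {
  stopifnot(inherits(g, "genotype_matrix"))
  codes <- g$codes
  mfrac <- colMeans(is.na(codes))
  if (any(mfrac > max_missing))
    stop("marker(s) exceed missing-fraction ceiling: ",
         paste(colnames(codes)[mfrac > max_missing], collapse = ", "))
  for (chr in unique(g$map$chromosome)) {
    j <- which(g$map$chromosome == chr)
    pos <- g$map$position_bp[j]
    sub <- codes[, j, drop = FALSE]
    for (i in which(rowSums(is.na(sub)) > 0L)) {
      x <- sub[i, ]
      obs <- which(!is.na(x))
      if (length(obs) == 0L)
        stop("line ", g$line_ids[i], " is entirely missing on chromosome ",
             chr, "; cannot impute")
      for (k in which(is.na(x)))
        # obs is ascending, so which.min resolves equal distances leftward
        x[k] <- x[obs[which.min(abs(pos[obs] - pos[k]))]]
      sub[i, ] <- x
    }
    codes[, j] <- sub
  }
  g$codes <- codes
  g
}

#' Read a multi-environment phenotype CSV
#'
#' Expects a wide CSV with header `line_id, environment, <trait>, <trait>,
#' ...` and one row per (line, environment). Non-numeric trait cells become
#' missing and are counted in a message.
#'
#' @param path input CSV.
#' @param environments optional ordered environment labels; defaults to
#'   order of first appearance in the file.
#' @return A [phenotype_table()] (missing cells are dropped from the long
#'   form).
#' @export
read_phenotypes <- function(path, environments = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = ",", check.names = FALSE,
               stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("phenotype CSV parse error in ", path, ": ",
                             conditionMessage(e)))
  if (!all(c("line_id", "environment") %in% names(tab)))
    stop("phenotype CSV must have line_id and environment columns")
  key <- paste(tab$line_id, tab$environment, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (line, environment) rows: ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = "; "))
  traits <- setdiff(names(tab), c("line_id", "environment"))
  if (length(traits) == 0L) stop("no trait columns found")
  n_dropped <- 0L
  recs <- do.call(rbind, lapply(traits, function(tr) {
    v <- suppressWarnings(as.numeric(tab[[tr]]))
    bad <- is.na(v) & !(is.na(tab[[tr]]) | tab[[tr]] %in% c("", "NA"))
    n_dropped <<- n_dropped + sum(bad) + sum(tab[[tr]] %in% c("", "NA") |
                                               is.na(tab[[tr]]))
    data.frame(line_id = tab$line_id, environment = tab$environment,
               trait = tr, value = v, stringsAsFactors = FALSE)
  }))
  recs <- recs[!is.na(recs$value), , drop = FALSE]
  if (n_dropped > 0L)
    message(n_dropped, " missing/non-numeric phenotype cell(s) dropped")
  if (is.null(environments)) environments <- unique(tab$environment)
  phenotype_table(recs, environments = environments)
}

#' Write a phenotype table to wide CSV
#'
#' Inverse of [read_phenotypes()]: one row per (line, environment), one
#' column per trait, values written at full double precision so the
#' round-trip is exact.
#'
#' @param p a [phenotype_table()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(p, path) {
  stopifnot(inherits(p, "phenotype_table"))
  envs <- environments(p)
  traits <- trait_names(p)
  lines_ <- sort(unique(p$line_id))
  grid <- expand.grid(environment = envs, line_id = lines_,
                      stringsAsFactors = FALSE)[, c(2, 1)]
  out <- grid
  for (tr in traits) {
    m <- pheno_matrix(p, tr, lines = lines_)
    v <- m[cbind(match(grid$line_id, lines_), match(grid$environment, envs))]
    out[[tr]] <- ifelse(is.na(v), "", formatC(v, digits = 17, format = "g"))
  }
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
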