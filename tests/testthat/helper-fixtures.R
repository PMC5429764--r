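# shared in-code fixtures for the test suite

# tiny deterministic genotype matrix: n lines x markers from a fair coin
coin_genotypes <- function(n_lines, marker_ids, chromosome = "1",
                           spacing_bp = 1000L, seed = 1) {
  set.seed(seed)
  codes <- matrix(sample(c(1, -1), n_lines * length(marker_ids),
                         replace = TRUE),
                  n_lines, length(marker_ids),
                  dimnames = list(sprintf("L%03d", seq_len(n_lines)),
                                  marker_ids))
  map <- marker_map(marker_ids, chromosome,
                    seq_along(marker_ids) * spacing_bp)
  genotype_matrix(codes, map)
}

# phenotype table from a lines x environments matrix
pheno_from_matrix <- function(m, trait = "y", envs = colnames(m)) {
  recs <- do.call(rbind, lapply(seq_along(envs), function(h)
    data.frame(line_id = rownames(m), environment = envs[h], trait = trait,
               value = m[, h], stringsAsFactors = FALSE)))
  phenotype_table(recs, environments = envs)
}

# a vector with exact sample mean and sd (n-1 denominator)
exact_moments <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  z <- (z - mean(z)) / stats::sd(z)
  mean + sd * z
}

# minimal two-parent VCF text for read_genotypes tests
write_test_vcf <- function(path, lines_gt, pat = "P1", mat = "P2",
                           chrom = "1", pos = NULL, ids = NULL) {
  m <- nrow(lines_gt)                 # markers x lines character matrix
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(ids)) ids <- paste0("snp", seq_len(m))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", pat, mat, colnames(lines_gt)),
                    collapse = "\t"))
  rows <- vapply(seq_len(m), function(i)
    paste(c(chrom, pos[i], ids[i], "A", "T", ".", "PASS", ".", "GT",
            "0/0", "1/1", lines_gt[i, ]), collapse = "\t"), "")
  writeLines(c(header, rows), path)
  path
}
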