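pkg_version <- function() as.character(utils::packageVersion("tumoreqtl"))

header_comment <- function(what, seed = NULL, config_hash = NULL) {
  parts <- c(sprintf("# tumoreqtl %s | %s", pkg_version(), what),
             if (!is.null(seed)) sprintf("seed=%s", seed),
             if (!is.null(config_hash)) sprintf("config=%s", config_hash))
  paste(parts, collapse = " | ")
}

config_hash <- function(config) {
  json <- jsonlite::serializeJSON(unclass(config))
  # cheap stable digest: sum of char codes mixed with position
  codes <- utf8ToInt(json)
  sprintf("%08x", sum(codes * (seq_along(codes) %% 97 + 1)) %% .Machine$integer.max)
}

write_with_header <- function(df, path, what, seed = NULL, hash = NULL) {
  writeLines(header_comment(what, seed, hash), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_checked_tsv <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0)
    abort(sprintf("%s is malformed or truncated (%d parsing problem(s), first at row %d).",
                  path, nrow(probs), probs$row[1]))
  df
}

#' Write a samples x features matrix as a feature-by-sample TSV
#'
#' Features (genes or variants) are rows on disk, samples are columns, with
#' a `feature_id` first column and a `#`-prefixed header line recording the
#' package version and seed.
#'
#' @param x Samples x features numeric matrix.
#' @param path Output file.
#' @param what Short description stored in the header comment.
#' @param seed Optional seed recorded in the header.
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(x, path, what = "matrix", seed = NULL) {
  x <- as.matrix(x)
  df <- tibble::as_tibble(t(x))
  names(df) <- rownames(x) %||% paste0("sample_", seq_len(nrow(x)))
  df <- dplyr::bind_cols(
    tibble::tibble(feature_id = colnames(x) %||%
                     paste0("feature_", seq_len(ncol(x)))), df)
  write_with_header(df, path, what, seed)
}

#' Read a feature-by-sample TSV into a samples x features matrix
#'
#' Inverse of [write_matrix_tsv()]. `#` comment lines are skipped; ragged or
#' truncated files are rejected.
#'
#' @param path Input TSV.
#' @return Samples x features numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_checked_tsv(path)
  ids <- df[[1]]
  m <- t(as.matrix(df[-1]))
  colnames(m) <- ids
  m
}

#' Read a genotype dosage matrix from TSV or minimal VCF
#'
#' TSV input follows the [write_matrix_tsv()] layout (variants in rows). VCF
#' input is restricted to biallelic sites with a GT field: dosage counts
#' alternate-allele copies, missing genotypes become `NA`, and multiallelic
#' records are skipped with a counted warning. Variant coordinates, when
#' available, are attached as the `"variants"` attribute (tibble with
#' `variant_id`, `chrom`, `pos`).
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"`.
#' @return Samples x variants dosage matrix.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") return(read_matrix_tsv(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix)) # drop vcfR class quirks
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    warn(sprintf("skipped %d multi-allelic record(s).", sum(multi)))
  keep <- which(!multi)
  if (!length(keep)) abort("no biallelic variants in VCF.")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  dosage <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  })
  ids <- fix[keep, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"])[is.na(ids) | ids == "."]
  rownames(dosage) <- ids
  out <- t(dosage)
  attr(out, "variants") <- tibble::tibble(
    variant_id = ids,
    chrom = fix[keep, "CHROM"],
    pos = as.numeric(fix[keep, "POS"]))
  out
}

#' Write and read per-sample tumor purity
#'
#' Two-column TSV (`sample_id`, `cancer_fraction`) with a header comment.
#'
#' @param purity Purity tibble.
#' @param path File path.
#' @param seed Optional seed recorded in the header.
#' @return `write_purity()` the path invisibly; `read_purity()` a purity
#'   tibble with the derived `normal_fraction` column.
#' @export
write_purity <- function(purity, path, seed = NULL) {
  write_with_header(purity[c("sample_id", "cancer_fraction")], path,
                    "tumor purity (cancer-cell fraction)", seed)
}

#' @rdname write_purity
#' @export
read_purity <- function(path) {
  df <- read_checked_tsv(path)
  new_purity(df$cancer_fraction, sample_id = df$sample_id)
}

eqtl_result_cols <- c("variant_id", "gene_id", "model", "beta1", "se1",
                      "t", "p", "q", "beta4", "beta5", "n", "status")

#' Write and read eQTL scan results
#'
#' TSV with the stable column order `variant_id, gene_id, model, beta1, se1,
#' t, p, q, beta4, beta5, n, status`.
#'
#' @param results Tibble of eQTL records.
#' @param path File path.
#' @param seed Optional seed recorded in the header.
#' @export
write_eqtl_results <- function(results, path, seed = NULL) {
  write_with_header(results[eqtl_result_cols], path, "eQTL scan results", seed)
}

#' @rdname write_eqtl_results
#' @export
read_eqtl_results <- function(path) {
  df <- read_checked_tsv(path)
  missing <- setdiff(eqtl_result_cols, names(df))
  if (length(missing))
    abort(paste0("result file lacks column(s): ",
                 paste(missing, collapse = ", ")))
  out <- tibble::as_tibble(df[eqtl_result_cols])
  class(out) <- c("eqtl_scan_tbl", class(out))
  out
}

#' Write a simulated cohort to a directory of TSV files
#'
#' Writes bulk/cancer/normal expression (genes x samples), genotype dosages
#' (variants x samples), the truth table and the purity table, each with a
#' header comment carrying the package version, the cohort seed and a hash
#' of the simulation configuration.
#'
#' @param cohort An `eqtl_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seed <- cohort$seed
  hash <- config_hash(cohort$config)
  p <- function(f) file.path(dir, f)
  write_matrix_tsv(cohort$expression, p("expression_bulk.tsv"),
                   "bulk expression", seed)
  write_matrix_tsv(cohort$cancer, p("expression_cancer.tsv"),
                   "latent cancer expression", seed)
  write_matrix_tsv(cohort$normal, p("expression_normal.tsv"),
                   "latent normal expression", seed)
  write_matrix_tsv(cohort$genotypes, p("genotypes.tsv"),
                   "genotype dosages", seed)
  write_with_header(cohort$truth, p("truth.tsv"),
                    "simulated eQTL architecture", seed, hash)
  write_purity(cohort$purity, p("purity.tsv"), seed)
  invisible(dir)
}
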