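#' Quantile-normalize samples and inverse-normal transform each gene
#'
#' Two-step normalization following common eQTL practice: expression
#' distributions are first quantile-normalized across samples (via
#' [limma::normalizeQuantiles()]), then each gene is mapped to a standard
#' normal distribution by a rank-based inverse-normal transform with the
#' Blom-style offset `qnorm((rank - 0.5) / n)` (average ranks for ties).
#' Genes with all-identical values cannot be ranked meaningfully and are
#' dropped with a warning.
#'
#' @param expr Samples x genes numeric matrix of raw expression.
#' @return Samples x genes matrix; each gene has mean ~0, sd ~1 and the same
#'   within-gene sample ranking as the input.
#' @export
normalize_expression <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 3) abort("need at least 3 samples to normalize.")
  constant <- apply(expr, 2, function(v) max(v) == min(v))
  if (any(constant)) {
    warn(sprintf("dropping %d gene(s) with constant expression.",
                 sum(constant)))
    expr <- expr[, !constant, drop = FALSE]
    if (ncol(expr) == 0) abort("no genes left after dropping constant genes.")
  }
  qn <- t(limma::normalizeQuantiles(t(expr)))
  out <- apply(qn, 2, inverse_normal_transform)
  dimnames(out) <- dimnames(qn)
  out
}

#' Rank-based inverse-normal transform
#'
#' Maps a vector onto standard-normal quantiles by rank:
#' `qnorm((rank - 0.5) / n)`, with average ranks for ties. The result has
#' mean 0 (exactly, for untied data), sd ~1 and the input's ranking.
#'
#' @param v Numeric vector.
#' @return Transformed numeric vector.
#' @export
inverse_normal_transform <- function(v) {
  qnorm((rank(v, ties.method = "average") - 0.5) / length(v))
}

#' Filter genes by expressed-sample fraction
#'
#' Retains genes whose raw value exceeds `threshold` in at least
#' `min_fraction` of samples (boundary inclusive).
#'
#' @param expr Samples x genes raw expression matrix.
#' @param min_fraction Minimum expressed fraction (default 0.75).
#' @param threshold A sample counts as "expressed" when its value is
#'   strictly greater than this (default 0).
#' @return The filtered samples x genes matrix.
#' @export
filter_genes_expressed <- function(expr, min_fraction = 0.75, threshold = 0) {
  expr <- as.matrix(expr)
  keep <- colMeans(expr > threshold) >= min_fraction
  if (!any(keep)) abort("no genes pass the expressed-fraction filter.")
  expr[, keep, drop = FALSE]
}

#' Filter variants by minor allele frequency
#'
#' MAF is computed from the dosages as `min(f, 1 - f)` with
#' `f = sum(dosage) / (2n)`; variants with MAF below `maf_min` are removed.
#'
#' @param geno Samples x variants dosage matrix (0/1/2).
#' @param maf_min Minimum MAF (default 0.05).
#' @return The filtered samples x variants matrix.
#' @export
filter_variants_maf <- function(geno, maf_min = 0.05) {
  geno <- as.matrix(geno)
  f <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  geno[, maf >= maf_min, drop = FALSE]
}

#' Pair variants with genes in cis
#'
#' A variant is paired with every gene on the same chromosome whose anchor
#' lies within `window` base pairs (boundary inclusive). The gene anchor is
#' the transcription start site: `start` for `+` (or missing) strand, `end`
#' for `-` strand. Coordinates are 1-based inclusive.
#'
#' @param variants Tibble with columns `variant_id`, `chrom`, `pos`.
#' @param genes Tibble with columns `gene_id`, `chrom`, `start`, `end` and
#'   optionally `strand`.
#' @param window Cis window in base pairs (default 500000).
#' @return Tibble with columns `variant_id`, `gene_id`, `distance` (signed,
#'   variant position minus gene anchor), ordered by variant then gene.
#' @export
map_cis_pairs <- function(variants, genes, window = 500000) {
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(variants)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  strand <- if ("strand" %in% names(genes)) genes$strand else "+"
  genes <- dplyr::mutate(genes,
                         anchor = ifelse(strand == "-", .data$end, .data$start))
  orphan <- setdiff(unique(variants$chrom), unique(genes$chrom))
  if (length(orphan))
    warn(paste0("skipping variants on chromosome(s) with no genes: ",
                paste(orphan, collapse = ", ")))
  dplyr::inner_join(
    dplyr::select(variants, "variant_id", "chrom", "pos"),
    dplyr::select(genes, "gene_id", "chrom", "anchor"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    dplyr::mutate(distance = .data$pos - .data$anchor) |>
    dplyr::filter(abs(.data$distance) <= window) |>
    dplyr::arrange(.data$variant_id, .data$gene_id) |>
    dplyr::select("variant_id", "gene_id", "distance")
}

#' Genotype principal components for population structure
#'
#' Variants are standardized (centered, unit variance; zero-variance
#' variants are dropped with a warning) and the first `k` principal-
#' component sample scores are returned, the usual population-structure
#' covariates of an eQTL model.
#'
#' @param geno Samples x variants dosage matrix.
#' @param k Number of components (default 3).
#' @return Samples x `k` matrix with columns `geno_PC1..k`.
#' @export
compute_genotype_pcs <- function(geno, k = 3) {
  geno <- as.matrix(geno)
  if (nrow(geno) < k + 1) abort("need at least k + 1 samples.")
  v <- apply(geno, 2, sd)
  if (any(v == 0)) {
    if (all(v == 0))
      abort("all variants are constant; genotype PCs are undefined.")
    warn(sprintf("dropping %d constant variant(s) before PCA.", sum(v == 0)))
    geno <- geno[, v > 0, drop = FALSE]
  }
  pc <- prcomp(scale(geno), center = FALSE, scale. = FALSE)
  if (ncol(pc$x) < k)
    abort(sprintf("requested %d PCs but the genotype matrix has rank %d.",
                  k, ncol(pc$x)))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("geno_PC", seq_len(k))
  rownames(scores) <- rownames(geno)
  scores
}

residualize <- function(mat, covariates) {
  if (is.null(covariates)) return(scale(mat, scale = FALSE))
  X <- cbind(1, as.matrix(covariates))
  qr.resid(qr(X), mat)
}

#' Expression-heterogeneity factors by principal component analysis
#'
#' Surrogate for latent-confounder factors: the known covariates are
#' regressed out of every gene, and the first `k` principal-component sample
#' scores of the residual matrix are returned. `k = 0` yields an empty
#' covariate block, appropriate for simulated cohorts with no hidden
#' structure.
#'
#' @param expr Samples x genes (normalized) expression matrix.
#' @param known_covariates Optional samples x m matrix regressed out of each
#'   gene before the decomposition (e.g., genotype PCs, purity).
#' @param k Number of factors.
#' @return Samples x `k` matrix with columns `expr_factor1..k`.
#' @export
compute_expression_factors <- function(expr, known_covariates = NULL, k) {
  expr <- as.matrix(expr)
  if (k == 0) {
    out <- matrix(numeric(0), nrow = nrow(expr), ncol = 0)
    rownames(out) <- rownames(expr)
    return(out)
  }
  if (nrow(expr) < k + 1) abort("need at least k + 1 samples.")
  res <- residualize(expr, known_covariates)
  pc <- prcomp(res, center = TRUE, scale. = FALSE)
  if (ncol(pc$x) < k)
    abort(sprintf("requested %d factors but the residual matrix has rank %d.",
                  k, ncol(pc$x)))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("expr_factor", seq_len(k))
  rownames(scores) <- rownames(expr)
  scores
}

#' Transfer tumor-purity estimates to a cohort lacking them
#'
#' Fits a cross-validated Lasso of reference-cohort purity on reference
#' expression over the genes shared by both cohorts, predicts purity for the
#' target cohort, and quantile-maps the predictions onto the reference
#' purity distribution (sorted predictions are replaced by the corresponding
#' reference quantiles, so the output distribution matches the reference).
#'
#' @param expr_target Samples x genes expression matrix of the cohort
#'   without purity estimates.
#' @param expr_reference Samples x genes expression matrix of the reference
#'   cohort.
#' @param purity_reference Purity tibble (or cancer-fraction vector) for the
#'   reference cohort.
#' @param seed Optional integer seed (cross-validation folds).
#' @param nfolds Folds for [glmnet::cv.glmnet()] (default 10).
#' @return Purity tibble for the target samples.
#' @export
purity_transfer <- function(expr_target, expr_reference, purity_reference,
                            seed = NULL, nfolds = 10) {
  shared <- intersect(colnames(expr_target), colnames(expr_reference))
  if (length(shared) < 10)
    abort(sprintf("only %d genes are shared between cohorts; need at least 10.",
                  length(shared)))
  cf <- purity_fractions(purity_reference)
  pred <- with_seed_if(seed, {
    cv <- glmnet::cv.glmnet(expr_reference[, shared, drop = FALSE], cf,
                            alpha = 1, nfolds = nfolds)
    as.numeric(predict(cv, expr_target[, shared, drop = FALSE],
                       s = "lambda.min"))
  })
  nt <- length(pred)
  mapped <- numeric(nt)
  ref_q <- if (nt == length(cf)) sort(cf)
           else as.numeric(quantile(cf, probs = (seq_len(nt) - 0.5) / nt))
  mapped[order(pred)] <- ref_q
  new_purity(mapped, sample_id = rownames(expr_target))
}

#' @importFrom stats predict quantile
NULL
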