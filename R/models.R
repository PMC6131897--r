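#' @section Model overview:
#' Two per-pair regressions are fit by ordinary least squares. The
#' conventional model regresses bulk expression on genotype dosage plus
#' covariates:
#'
#'   y = b0 + b1 x + B2.a + B3.b + e
#'
#' The interaction model adds the normal-cell fraction p (1 - tumor purity)
#' and its product with genotype:
#'
#'   y = b0 + b1 x + B2.a + B3.b + b4 p + b5 (p * x) + e
#'
#' Because p is 0 for a sample of pure cancer cells, b1 is the eQTL effect
#' extrapolated to 100% cancer cells; b5 measures how the effect differs
#' between the two cell types. Significance is a two-sided t test on b1 with
#' residual degrees of freedom.
#' @name eqtl-models
NULL

# Complete-case QR least squares with classical standard errors.
# Returns NULL-like (status) rather than erroring so that scans can emit
# NaN records for degenerate designs.
ols_fit <- function(X, y) {
  ok <- complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  n <- length(y)
  k <- ncol(X)
  if (n <= k)
    return(list(status = "insufficient_samples", n = n))
  dec <- qr(X)
  if (dec$rank < k) {
    bad <- colnames(X)[dec$pivot[(dec$rank + 1L):k]]
    return(list(status = "rank_deficient", n = n, collinear = bad))
  }
  cf <- qr.coef(dec, y)
  res <- qr.resid(dec, y)
  df <- n - k
  s2 <- sum(res^2) / df
  unpivot <- order(dec$pivot)
  xtx_inv <- chol2inv(qr.R(dec))[unpivot, unpivot, drop = FALSE]
  se <- setNames(sqrt(s2 * diag(xtx_inv)), names(cf))
  tval <- cf / se
  list(status = "ok", coefficients = cf, se = se, t = tval,
       p = 2 * pt(-abs(tval), df), df = df, n = n, sigma2 = s2,
       residuals = res)
}

as_covar_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  cv <- as.matrix(covariates)
  if (nrow(cv) != n)
    abort(sprintf("`covariates` has %d rows but %d samples expected.",
                  nrow(cv), n))
  if (is.null(colnames(cv)))
    colnames(cv) <- paste0("covar", seq_len(ncol(cv)))
  cv
}

build_design <- function(x, covariates, normal_fraction = NULL) {
  X <- cbind(`(Intercept)` = 1, genotype = x)
  cv <- as_covar_matrix(covariates, length(x))
  if (!is.null(cv)) X <- cbind(X, cv)
  if (!is.null(normal_fraction))
    X <- cbind(X, normal_fraction = normal_fraction,
               `genotype:normal_fraction` = normal_fraction * x)
  X
}

record_row <- function(fit, model, variant_id = NA_character_,
                       gene_id = NA_character_) {
  if (fit$status != "ok") {
    return(tibble::tibble(
      variant_id = variant_id, gene_id = gene_id, model = model,
      beta1 = NaN, se1 = NaN, t = NaN, p = NaN, q = NA_real_,
      beta4 = NaN, beta5 = NaN, n = fit$n, status = fit$status))
  }
  b4 <- unname(fit$coefficients["normal_fraction"])
  b5 <- unname(fit$coefficients["genotype:normal_fraction"])
  tibble::tibble(
    variant_id = variant_id, gene_id = gene_id, model = model,
    beta1 = unname(fit$coefficients["genotype"]),
    se1 = unname(fit$se["genotype"]),
    t = unname(fit$t["genotype"]),
    p = unname(fit$p["genotype"]),
    q = NA_real_,
    beta4 = if (model == "interaction") b4 else NA_real_,
    beta5 = if (model == "interaction") b5 else NA_real_,
    n = fit$n, status = "ok")
}

check_fittable <- function(x, fit) {
  if (sd(x, na.rm = TRUE) == 0)
    abort("genotype vector is constant; the eQTL effect is not estimable.")
  if (fit$status == "rank_deficient")
    abort(paste0("design is rank deficient; collinear term(s): ",
                 paste(fit$collinear, collapse = ", ")))
  if (fit$status == "insufficient_samples")
    abort("fewer samples than model parameters.")
  invisible(fit)
}

#' Fit the conventional bulk-tissue eQTL model for one SNP-gene pair
#'
#' Ordinary least squares of expression on genotype dosage plus optional
#' covariates; the eQTL statistics (`beta1`, `se1`, `t`, `p`) come from the
#' genotype term, with a two-sided t test on residual degrees of freedom.
#'
#' @param y Numeric expression vector.
#' @param x Numeric genotype dosage vector (0/1/2 copies of the minor
#'   allele).
#' @param covariates Optional numeric matrix/data frame of per-sample
#'   covariates (e.g., genotype principal components, expression factors).
#' @return A one-row tibble (an eQTL record) with columns `variant_id`,
#'   `gene_id`, `model`, `beta1`, `se1`, `t`, `p`, `q` (NA for single fits),
#'   `beta4`, `beta5`, `n`, `status`.
#' @export
fit_conventional <- function(y, x, covariates = NULL) {
  fit <- ols_fit(build_design(x, covariates), y)
  check_fittable(x, fit)
  record_row(fit, "conventional")
}

#' Fit the purity-interaction eQTL model for one SNP-gene pair
#'
#' Adds the normal-cell fraction and its product with genotype to the
#' conventional design. `purity` is supplied as the *cancer*-cell fraction
#' (tumor purity); it is converted internally to the normal fraction
#' `p = 1 - purity`, so that the genotype main effect `beta1` is the eQTL
#' effect extrapolated to 100% cancer cells. `beta5` (the interaction term)
#' measures the difference in effect between the two cell types.
#'
#' @inheritParams fit_conventional
#' @param purity Purity tibble (or numeric cancer-fraction vector), strictly
#'   inside (0, 1) with nonzero variance.
#' @return A one-row eQTL record tibble (see [fit_conventional()]) with
#'   `beta4` (purity main effect) and `beta5` (interaction) populated.
#' @export
fit_interaction <- function(y, x, purity, covariates = NULL) {
  pn <- 1 - purity_fractions(purity)
  if (sd(pn, na.rm = TRUE) == 0)
    abort("normal_fraction is constant; the purity terms are collinear with the intercept.")
  fit <- ols_fit(build_design(x, covariates, normal_fraction = pn), y)
  check_fittable(x, fit)
  record_row(fit, "interaction")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment via [stats::p.adjust()]. Missing
#' p-values are excluded from the adjustment and returned as `NA`.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Numeric vector of BH-adjusted q-values, same length as `p`.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    abort("p-values must lie in [0, 1].")
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Scan SNP-gene pairs with a chosen eQTL model
#'
#' Fits the conventional or interaction model for every pair and BH-adjusts
#' the genotype-term p-values across all tested pairs. Degenerate designs
#' (constant genotype, collinearity) yield records with `NaN` statistics and
#' a reason in `status` rather than being dropped.
#'
#' @param x An `eqtl_cohort` (from [simulate_cohort()]) or a samples x genes
#'   expression matrix.
#' @param ... Passed to methods.
#' @return A tibble of eQTL records, one per pair, with `q` computed over
#'   all pairs with a valid p-value; rows keep the input pair order.
#' @export
eqtl_scan <- function(x, ...) UseMethod("eqtl_scan")

#' @rdname eqtl_scan
#' @param geno Samples x variants dosage matrix.
#' @param pairs Tibble with columns `variant_id`, `gene_id` (e.g., from
#'   [map_cis_pairs()]). Defaults to pairing variant i with gene i when the
#'   two matrices have equal width.
#' @param purity Purity tibble or cancer-fraction vector (interaction model
#'   only; converted internally to the normal fraction).
#' @param covariates Optional samples x k covariate matrix.
#' @param model `"conventional"` or `"interaction"`.
#' @export
eqtl_scan.default <- function(x, geno, pairs = NULL, purity = NULL,
                              covariates = NULL,
                              model = c("conventional", "interaction"),
                              ...) {
  model <- match.arg(model)
  expr <- as.matrix(x)
  if (nrow(expr) != nrow(geno))
    abort(sprintf("expression has %d samples but genotypes have %d.",
                  nrow(expr), nrow(geno)))
  if (!is.null(rownames(expr)) && !is.null(rownames(geno)) &&
      !identical(rownames(expr), rownames(geno)))
    abort(paste0("sample ids of expression and genotypes differ, e.g.: ",
                 paste(head(setdiff(rownames(expr), rownames(geno)), 3),
                       collapse = ", ")))
  if (is.null(pairs)) {
    if (ncol(expr) != ncol(geno))
      abort("`pairs` must be given unless expression and genotype matrices pair column i with column i.")
    pairs <- tibble::tibble(variant_id = colnames(geno) %||%
                              paste0("var_", seq_len(ncol(geno))),
                            gene_id = colnames(expr) %||%
                              paste0("gene_", seq_len(ncol(expr))))
    vidx <- seq_len(ncol(geno)); gidx <- seq_len(ncol(expr))
  } else {
    vidx <- match(pairs$variant_id, colnames(geno))
    gidx <- match(pairs$gene_id, colnames(expr))
    if (anyNA(vidx) || anyNA(gidx))
      abort("`pairs` refers to variants or genes absent from the matrices.")
  }

  pn <- NULL
  if (model == "interaction") {
    if (is.null(purity))
      abort("the interaction model requires `purity`.")
    cf <- purity_fractions(purity)
    if (length(cf) != nrow(expr))
      abort("`purity` length does not match the number of samples.")
    inform("interaction model: purity interpreted as cancer-cell fraction; fitting on normal fraction p = 1 - purity.",
           .frequency = "once",
           .frequency_id = "tumoreqtl_purity_convention")
    pn <- 1 - cf
  }
  cv <- as_covar_matrix(covariates, nrow(expr))

  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    xg <- geno[, vidx[i]]
    design <- build_design(xg, cv, normal_fraction = pn)
    fit <- ols_fit(design, expr[, gidx[i]])
    if (fit$status == "ok" && sd(xg, na.rm = TRUE) == 0)
      fit <- list(status = "constant_genotype", n = fit$n)
    rows[[i]] <- record_row(fit, model, pairs$variant_id[i], pairs$gene_id[i])
  }
  out <- dplyr::bind_rows(rows)
  out$q <- bh_fdr(out$p)
  class(out) <- c("eqtl_scan_tbl", class(out))
  out
}

#' @rdname eqtl_scan
#' @export
eqtl_scan.eqtl_cohort <- function(x, model = c("conventional", "interaction"),
                                  purity = NULL, covariates = NULL, ...) {
  model <- match.arg(model)
  eqtl_scan.default(x$expression, x$genotypes,
                    pairs = tibble::tibble(variant_id = x$truth$variant_id,
                                           gene_id = x$truth$gene_id),
                    purity = purity %||% x$purity,
                    covariates = covariates, model = model)
}

#' Z-test for an effect-size difference between two datasets
#'
#' For a SNP-gene pair measured in two cohorts,
#' `z = (beta_a - beta_b) / sqrt(se_a^2 + se_b^2)`; the two-sided p-value
#' comes from the standard normal distribution. All arguments are vectorized.
#'
#' @param beta_a,se_a Effect size and standard error in dataset A.
#' @param beta_b,se_b Effect size and standard error in dataset B.
#' @return Tibble with columns `beta_a`, `se_a`, `beta_b`, `se_b`, `z`, `p`.
#' @export
zdiff_test <- function(beta_a, se_a, beta_b, se_b) {
  if (any(se_a <= 0, na.rm = TRUE) || any(se_b <= 0, na.rm = TRUE))
    abort("standard errors must be positive.")
  z <- (beta_a - beta_b) / sqrt(se_a^2 + se_b^2)
  tibble::tibble(beta_a = beta_a, se_a = se_a, beta_b = beta_b, se_b = se_b,
                 z = z, p = 2 * pnorm(-abs(z)))
}

#' Deconstruct an eQTL effect across tumor-purity bins
#'
#' Splits samples into `n_bins` equal-sized bins by purity rank, fits the
#' conventional model within each bin, and returns per-bin effect sizes with
#' t-based 95% confidence intervals. The whole-cohort conventional and
#' interaction fits are attached as attributes for plotting: a normal-driven
#' eQTL shows effects shrinking toward 0 as cancer-cell content rises, while
#' the extrapolated interaction estimate sits near the high-purity bins.
#'
#' @inheritParams fit_interaction
#' @param n_bins Number of purity bins (default 5).
#' @param conf_level Confidence level for the per-bin intervals.
#' @return Tibble (class `eqtl_binned`) with columns `bin_index`,
#'   `purity_low`, `purity_high`, `beta`, `ci_low`, `ci_high`, `n_in_bin`,
#'   plus attributes `conventional` and `interaction` (one-row records).
#' @export
binned_effects <- function(y, x, purity, n_bins = 5, covariates = NULL,
                           conf_level = 0.95) {
  cf <- purity_fractions(purity)
  n <- length(cf)
  k_par <- 2 + if (is.null(covariates)) 0 else ncol(as.matrix(covariates))
  if (n < n_bins * (k_par + 2))
    abort(sprintf("%d samples are too few for %d bins of a %d-parameter model.",
                  n, n_bins, k_par))
  ord <- order(cf, seq_len(n))           # deterministic tie-break by index
  bin <- integer(n)
  bin[ord] <- ceiling(seq_len(n) / (n / n_bins))
  cv <- as_covar_matrix(covariates, n)
  rows <- purrr::map(seq_len(n_bins), function(b) {
    idx <- which(bin == b)
    fit <- ols_fit(build_design(x[idx], cv[idx, , drop = FALSE]), y[idx])
    if (fit$status != "ok")
      abort(sprintf("bin %d design is degenerate (%s).", b, fit$status))
    hw <- qt(1 - (1 - conf_level) / 2, fit$df) * fit$se["genotype"]
    tibble::tibble(bin_index = b,
                   purity_low = min(cf[idx]), purity_high = max(cf[idx]),
                   beta = unname(fit$coefficients["genotype"]),
                   ci_low = unname(fit$coefficients["genotype"] - hw),
                   ci_high = unname(fit$coefficients["genotype"] + hw),
                   n_in_bin = length(idx))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "conventional") <- fit_conventional(y, x, covariates)
  attr(out, "interaction") <- fit_interaction(y, x, cf, covariates)
  attr(out, "conf_level") <- conf_level
  class(out) <- c("eqtl_binned", class(out))
  out
}
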