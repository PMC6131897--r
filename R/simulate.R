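#' Simulation configuration for mixed cancer/normal expression cohorts
#'
#' Describes a synthetic bulk-tumor cohort: latent "cancer" and "normal"
#' expression compartments with a known per-gene eQTL architecture, mixed
#' per sample by a cancer-cell fraction (tumor purity).
#'
#' The default architecture comprises six groups of `genes_per_group` genes:
#' \describe{
#'   \item{group 1}{independent eQTL effects in cancer and normal cells}
#'   \item{group 2}{eQTL in cancer cells only}
#'   \item{group 3}{eQTL in normal cells only}
#'   \item{group 4}{no eQTL in either compartment}
#'   \item{group 5}{identical eQTL effect in both compartments}
#'   \item{group 6}{identical effects, plus Normal(0, `group6_noise_sd`)
#'     noise added to every normal-compartment expression value}
#' }
#' plus `extra_normal_only` additional normal-only eQTL genes (group label
#' `"normal_only_extra"`), used to probe false-discovery behaviour when
#' normal-driven regulation dominates.
#'
#' Effect sizes live on a symmetric grid from `effect_min` to `effect_max` in
#' steps of `effect_step` with 0 excluded; each eQTL-bearing group receives
#' the nonzero grid values exactly once (recycled if the group size differs
#' from the grid length), in seeded random order.
#'
#' @param n_samples Number of samples (default 1000).
#' @param genes_per_group Genes per architecture group (default 100).
#' @param extra_normal_only Extra normal-only eQTL genes appended after the
#'   six groups (default 0; the augmented benchmark uses 500).
#' @param effect_min,effect_max,effect_step Effect-size grid, in expression
#'   units per minor-allele copy.
#' @param baseline_mean,baseline_sd Per-sample baseline expression draw,
#'   Normal(`baseline_mean`, `baseline_sd`).
#' @param group6_noise_sd Standard deviation of the extra noise added to the
#'   normal compartment of group-6 genes.
#' @param purity_shape1,purity_shape2 Beta parameters for the simulated
#'   cancer-cell fraction (defaults give mean ~0.72, sd ~0.14, emulating
#'   consensus purity estimates in breast tumors).
#' @param purity_values Optional empirical purity vector to resample from
#'   instead of the Beta distribution.
#' @param purity_noise_sd Default measurement-noise standard deviation used
#'   when purity noise is requested (see [add_purity_noise()]).
#'
#' @return A `sim_config` list.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_samples = 1000,
                       genes_per_group = 100,
                       extra_normal_only = 0,
                       effect_min = -0.5,
                       effect_max = 0.5,
                       effect_step = 0.01,
                       baseline_mean = 1,
                       baseline_sd = 1,
                       group6_noise_sd = 0.25,
                       purity_shape1 = 6.686,
                       purity_shape2 = 2.600,
                       purity_values = NULL,
                       purity_noise_sd = 0.1) {
  stopifnot(n_samples > 0, genes_per_group > 0, extra_normal_only >= 0,
            effect_step > 0, baseline_sd > 0, group6_noise_sd >= 0,
            purity_noise_sd >= 0)
  if (!isTRUE(all.equal(effect_min, -effect_max)))
    abort("`effect_min`/`effect_max` must be symmetric about 0.")
  if (!is.null(purity_values) &&
      (any(purity_values <= 0) || any(purity_values >= 1)))
    abort("`purity_values` must lie strictly inside (0, 1).")
  cfg <- list(
    n_samples = as.integer(n_samples),
    genes_per_group = as.integer(genes_per_group),
    extra_normal_only = as.integer(extra_normal_only),
    effect_min = effect_min, effect_max = effect_max,
    effect_step = effect_step,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    group6_noise_sd = group6_noise_sd,
    purity_shape1 = purity_shape1, purity_shape2 = purity_shape2,
    purity_values = purity_values,
    purity_noise_sd = purity_noise_sd
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  n_genes <- 6L * x$genes_per_group + x$extra_normal_only
  cat("<sim_config>\n")
  cat("  samples:", x$n_samples, " genes:", n_genes,
      sprintf("(6 x %d + %d normal-only)\n",
              x$genes_per_group, x$extra_normal_only))
  cat(sprintf("  effect grid: %g..%g step %g (0 excluded)\n",
              x$effect_min, x$effect_max, x$effect_step))
  cat(sprintf("  baseline: Normal(%g, %g); group-6 noise sd %g\n",
              x$baseline_mean, x$baseline_sd, x$group6_noise_sd))
  src <- if (is.null(x$purity_values))
    sprintf("Beta(%g, %g)", x$purity_shape1, x$purity_shape2)
  else sprintf("empirical (n = %d)", length(x$purity_values))
  cat("  purity source:", src,
      sprintf(" measurement-noise sd %g\n", x$purity_noise_sd))
  invisible(x)
}

#' Nonzero effect-size grid of a simulation configuration
#'
#' @param config A [sim_config()].
#' @return Numeric vector of nonzero effect sizes.
#' @export
effect_grid <- function(config) {
  g <- round(seq(config$effect_min, config$effect_max,
                 by = config$effect_step), 8)
  g[g != 0]
}

#' Simulate a genotype dosage matrix at allele frequency 0.5
#'
#' Each variant is biallelic with both alleles at frequency 0.5 and exact
#' Hardy-Weinberg genotype counts: `n/4` samples with dosage 0, `n/2` with
#' dosage 1 and `n/4` with dosage 2, randomly permuted across samples. The
#' minor allele is designated arbitrarily. When `n_samples` is not divisible
#' by 4 the remainder is assigned to the heterozygote class first and a
#' warning is issued.
#'
#' @param n_samples,n_variants Matrix dimensions.
#' @param seed Optional integer seed; fixes the permutation.
#' @return Numeric matrix (samples x variants) of dosages in \{0, 1, 2\},
#'   with `sample_*` row names and `var_*` column names.
#' @export
simulate_genotypes <- function(n_samples, n_variants, seed = NULL) {
  stopifnot(n_samples >= 4, n_variants >= 1)
  n_samples <- as.integer(n_samples)
  c0 <- n_samples %/% 4L
  c2 <- n_samples %/% 4L
  c1 <- n_samples - c0 - c2
  if (n_samples %% 4L != 0L)
    warn(sprintf(
      "n_samples = %d is not divisible by 4; using genotype counts %d/%d/%d.",
      n_samples, c0, c1, c2))
  template <- rep(c(0, 1, 2), times = c(c0, c1, c2))
  geno <- with_seed_if(seed,
    vapply(seq_len(n_variants),
           function(i) sample(template),
           numeric(n_samples)))
  dimnames(geno) <- list(paste0("sample_", seq_len(n_samples)),
                         paste0("var_", seq_len(n_variants)))
  geno
}

sim_group_labels <- function(config) {
  c(rep(as.character(1:6), each = config$genes_per_group),
    rep("normal_only_extra", config$extra_normal_only))
}

# every nonzero grid value once per group (recycled), seeded order
fill_effects <- function(grid, m) sample(rep_len(grid, m))

#' Simulate latent cancer and normal expression compartments
#'
#' Draws per-sample baselines from Normal(`baseline_mean`, `baseline_sd`) and
#' adds `beta * dosage` per gene, with compartment-specific effect sizes
#' determined by the gene's architecture group (see [sim_config()]). Group-6
#' genes copy the cancer-compartment effect and then receive additional
#' Normal(0, `group6_noise_sd`) noise on every normal-compartment value.
#'
#' @param config A [sim_config()].
#' @param genotypes Dosage matrix from [simulate_genotypes()] with one
#'   variant per gene.
#' @param seed Optional integer seed.
#' @return List with elements `cancer` and `normal` (samples x genes
#'   matrices) and `truth`, a tibble with columns `gene_id`, `variant_id`,
#'   `group`, `beta_cancer`, `beta_normal`.
#' @export
simulate_expression_pair <- function(config, genotypes, seed = NULL) {
  group <- sim_group_labels(config)
  n_genes <- length(group)
  if (ncol(genotypes) != n_genes)
    abort(sprintf(
      "`genotypes` has %d variants but the configuration implies %d genes (one variant per gene).",
      ncol(genotypes), n_genes))
  n <- nrow(genotypes)
  grid <- effect_grid(config)
  gpg <- config$genes_per_group

  with_seed_if(seed, {
    beta_cancer <- beta_normal <- numeric(n_genes)
    idx <- function(g) which(group == g)
    beta_cancer[idx("1")] <- fill_effects(grid, gpg)
    beta_normal[idx("1")] <- fill_effects(grid, gpg)
    beta_cancer[idx("2")] <- fill_effects(grid, gpg)
    beta_normal[idx("3")] <- fill_effects(grid, gpg)
    beta_cancer[idx("5")] <- fill_effects(grid, gpg)
    beta_normal[idx("5")] <- beta_cancer[idx("5")]
    beta_cancer[idx("6")] <- fill_effects(grid, gpg)
    beta_normal[idx("6")] <- beta_cancer[idx("6")]
    if (config$extra_normal_only > 0)
      beta_normal[idx("normal_only_extra")] <-
        fill_effects(grid, config$extra_normal_only)

    base <- function() rnorm(n, config$baseline_mean, config$baseline_sd)
    cancer <- vapply(seq_len(n_genes),
                     function(g) base() + beta_cancer[g] * genotypes[, g],
                     numeric(n))
    normal <- vapply(seq_len(n_genes),
                     function(g) base() + beta_normal[g] * genotypes[, g],
                     numeric(n))
    g6 <- idx("6")
    if (length(g6))
      normal[, g6] <- normal[, g6] +
        matrix(rnorm(n * length(g6), 0, config$group6_noise_sd), n)

    gene_id <- sprintf("gene_%04d", seq_len(n_genes))
    dimnames(cancer) <- dimnames(normal) <- list(rownames(genotypes), gene_id)
    list(
      cancer = cancer,
      normal = normal,
      truth = tibble::tibble(
        gene_id = gene_id,
        variant_id = colnames(genotypes),
        group = group,
        beta_cancer = beta_cancer,
        beta_normal = beta_normal
      )
    )
  })
}

new_purity <- function(cancer_fraction, sample_id = NULL) {
  eps <- 1e-6
  if (any(cancer_fraction <= 0) || any(cancer_fraction >= 1)) {
    warn("purity values outside (0, 1); clamping.")
    cancer_fraction <- pmin(pmax(cancer_fraction, eps), 1 - eps)
  }
  tibble::tibble(
    sample_id = sample_id %||% paste0("sample_", seq_along(cancer_fraction)),
    cancer_fraction = cancer_fraction,
    normal_fraction = 1 - cancer_fraction
  )
}

# accept a purity tibble or a bare numeric vector
purity_fractions <- function(purity) {
  if (is.data.frame(purity)) {
    if (!"cancer_fraction" %in% names(purity))
      abort("`purity` must have a `cancer_fraction` column.")
    purity$cancer_fraction
  } else {
    as.numeric(purity)
  }
}

#' Simulate per-sample tumor purity (cancer-cell fraction)
#'
#' Draws cancer-cell fractions either from a Beta distribution (default
#' shapes give a right-skewed distribution with mean ~0.72 and sd ~0.14) or,
#' when `config$purity_values` is supplied, as a seeded resample of that
#' empirical vector.
#'
#' @param n_samples Number of samples.
#' @param config A [sim_config()] (supplies the Beta shapes or the
#'   empirical vector).
#' @param seed Optional integer seed.
#' @return A purity tibble with columns `sample_id`, `cancer_fraction`,
#'   `normal_fraction` (fractions strictly inside (0, 1)).
#' @export
simulate_purity <- function(n_samples, config = sim_config(), seed = NULL) {
  cf <- with_seed_if(seed, {
    if (!is.null(config$purity_values))
      sample(config$purity_values, n_samples, replace = TRUE)
    else
      rbeta(n_samples, config$purity_shape1, config$purity_shape2)
  })
  new_purity(cf)
}

#' Mix latent compartments into bulk expression
#'
#' `bulk[s, g] = cancer_fraction[s] * cancer[s, g] +
#'  normal_fraction[s] * normal[s, g]` — a per-sample weighted mean, the
#' linear-mixing assumption for bulk tumor expression.
#'
#' @param cancer,normal Samples x genes matrices with identical dimensions
#'   and ordering.
#' @param purity Purity tibble (or numeric cancer-fraction vector) with one
#'   entry per sample.
#' @return Samples x genes bulk expression matrix.
#' @export
mix_bulk <- function(cancer, normal, purity) {
  if (!all(dim(cancer) == dim(normal)))
    abort(sprintf(
      "`cancer` (%d x %d) and `normal` (%d x %d) dimensions differ.",
      nrow(cancer), ncol(cancer), nrow(normal), ncol(normal)))
  w <- purity_fractions(purity)
  if (length(w) != nrow(cancer))
    abort(sprintf(
      "`purity` has %d samples but the expression matrices have %d rows.",
      length(w), nrow(cancer)))
  w * cancer + (1 - w) * normal
}

#' Add quantile-preserving measurement noise to purity estimates
#'
#' Adds Normal(0, `noise_sd`) noise to each cancer-cell fraction and then
#' quantile-normalizes the noisy values back onto the original purity
#' distribution: the sorted output values equal the sorted input values
#' exactly, while the ranking follows input + noise. This emulates imprecise
#' purity measurement without distorting the purity distribution.
#'
#' @param purity Purity tibble (or numeric cancer-fraction vector).
#' @param noise_sd Noise standard deviation (default 0.1).
#' @param seed Optional integer seed.
#' @return Purity tibble with the same sample ids and a reshuffled-by-noise
#'   assignment of the original fraction values.
#' @export
add_purity_noise <- function(purity, noise_sd = 0.1, seed = NULL) {
  stopifnot(noise_sd >= 0)
  cf <- purity_fractions(purity)
  noisy <- with_seed_if(seed, cf + rnorm(length(cf), 0, noise_sd))
  out <- numeric(length(cf))
  out[order(noisy)] <- sort(cf)
  new_purity(out, sample_id = if (is.data.frame(purity)) purity$sample_id)
}

#' Randomly permute purity assignments across samples
#'
#' Used as a negative control: the purity value multiset is preserved but
#' the sample assignment is randomized, destroying any real relationship
#' between measured purity and cell composition.
#'
#' @inheritParams add_purity_noise
#' @return Purity tibble with permuted cancer fractions.
#' @export
permute_purity <- function(purity, seed = NULL) {
  cf <- purity_fractions(purity)
  out <- with_seed_if(seed, cf[sample(length(cf))])
  new_purity(out, sample_id = if (is.data.frame(purity)) purity$sample_id)
}

#' Simulate a complete bulk-tumor eQTL cohort
#'
#' Convenience wrapper that simulates genotypes, latent cancer/normal
#' expression with known eQTL architecture, tumor purity, and the purity-
#' mixed bulk expression matrix. All randomness derives from `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed fixing the whole cohort.
#' @return An `eqtl_cohort` list with elements `expression` (bulk,
#'   samples x genes), `cancer`, `normal`, `genotypes`, `purity` (tibble),
#'   `truth` (tibble), `config` and `seed`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 100, genes_per_group = 5),
#'                           seed = 1)
#' cohort$truth
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  with_seed_if(seed, {
    n_genes <- 6L * config$genes_per_group + config$extra_normal_only
    geno <- simulate_genotypes(config$n_samples, n_genes)
    pair <- simulate_expression_pair(config, geno)
    purity <- simulate_purity(config$n_samples, config)
    purity$sample_id <- rownames(geno)
    bulk <- mix_bulk(pair$cancer, pair$normal, purity)
    structure(
      list(expression = bulk, cancer = pair$cancer, normal = pair$normal,
           genotypes = geno, purity = purity, truth = pair$truth,
           config = config, seed = seed),
      class = "eqtl_cohort")
  })
}

#' @export
print.eqtl_cohort <- function(x, ...) {
  cat("<eqtl_cohort>\n")
  cat(sprintf("  %d samples x %d genes (one cis variant per gene)\n",
              nrow(x$expression), ncol(x$expression)))
  cat("  groups:",
      paste(sprintf("%s=%d", names(table(x$truth$group)),
                    table(x$truth$group)), collapse = " "), "\n")
  cat(sprintf("  purity: mean %.3f sd %.3f\n",
              mean(x$purity$cancer_fraction), sd(x$purity$cancer_fraction)))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}
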