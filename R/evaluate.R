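#' Score a scan against simulated ground truth
#'
#' A gene is a true cancer eQTL when its simulated cancer-compartment effect
#' is nonzero (architecture groups 1, 2, 5 and 6); genes with a zero cancer
#' effect (groups 3, 4 and the extra normal-only genes) are negatives. Calls
#' are records with `q < fdr_threshold`. The realized ("true") FDR is the
#' fraction of calls that are false, as opposed to the nominal BH level.
#'
#' @param results Tibble of eQTL records from [eqtl_scan()].
#' @param truth Truth tibble from [simulate_cohort()] (columns `gene_id`,
#'   `group`, `beta_cancer`, `beta_normal`).
#' @param fdr_threshold Significance threshold on `q` (default 0.05).
#' @return An `eqtl_performance` object; [glance()] gives the one-row metric
#'   summary, [tidy()] the per-group call/false-positive breakdown.
#' @export
classify_performance <- function(results, truth, fdr_threshold = 0.05) {
  missing <- setdiff(results$gene_id, truth$gene_id)
  if (length(missing))
    abort(paste0("no truth rows for gene(s): ",
                 paste(head(missing, 3), collapse = ", ")))
  joined <- dplyr::inner_join(results, truth, by = "gene_id",
                              suffix = c("", ".truth"))
  joined <- dplyr::mutate(
    joined,
    positive = .data$beta_cancer != 0,
    called = !is.na(.data$q) & .data$q < fdr_threshold)
  tp <- sum(joined$called & joined$positive)
  fp <- sum(joined$called & !joined$positive)
  tn <- sum(!joined$called & !joined$positive)
  fn <- sum(!joined$called & joined$positive)
  by_group <- joined |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_called = sum(.data$called),
      false_positives = sum(.data$called & !.data$positive),
      normal_driven_fp = sum(.data$called & !.data$positive &
                               .data$beta_normal != 0),
      .groups = "drop")
  metrics <- tibble::tibble(
    model = results$model[1],
    fdr_threshold = fdr_threshold,
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    true_fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
    fp_normal_driven = sum(by_group$normal_driven_fp))
  structure(list(metrics = metrics, by_group = by_group,
                 fdr_threshold = fdr_threshold),
            class = "eqtl_performance")
}

#' @export
print.eqtl_performance <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<eqtl_performance: %s model, q < %g>\n", m$model,
              x$fdr_threshold))
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%  true FDR %.1f%%\n",
              100 * m$sensitivity, 100 * m$specificity, 100 * m$true_fdr))
  cat(sprintf("  TP %d  FP %d (%d normal-driven)  TN %d  FN %d\n",
              m$tp, m$fp, m$fp_normal_driven, m$tn, m$fn))
  invisible(x)
}

#' @export
#' @method glance eqtl_performance
glance.eqtl_performance <- function(x, ...) x$metrics

#' @export
#' @method tidy eqtl_performance
tidy.eqtl_performance <- function(x, ...) x$by_group

#' Sweep purity-measurement noise and track model performance
#'
#' Holds one simulated cohort fixed and varies only the *measured* purity:
#' for each noise level, Normal(0, sd) noise is added to the true purity and
#' quantile-normalized back onto its distribution ([add_purity_noise()]),
#' the interaction model is re-scanned with the noisy purity, and
#' performance is scored against truth. The Pearson correlation between
#' noisy and true purity summarizes the effective measurement accuracy.
#'
#' @param cohort An `eqtl_cohort` from [simulate_cohort()].
#' @param sd_grid Noise standard deviations (default 0.01 to 1.5 in steps of
#'   0.025).
#' @param fdr_threshold Significance threshold (default 0.05).
#' @param seed Optional integer seed (one noise draw per grid point).
#' @return Tibble (class `eqtl_sweep`) with columns `noise_sd`, `pearson_r`,
#'   `sensitivity`, `specificity`, `true_fdr`, `n_significant`.
#' @export
noise_sweep <- function(cohort, sd_grid = seq(0.01, 1.5, by = 0.025),
                        fdr_threshold = 0.05, seed = NULL) {
  truth <- cohort$truth
  cf <- cohort$purity$cancer_fraction
  with_seed_if(seed, {
    rows <- purrr::map(sd_grid, function(s) {
      measured <- add_purity_noise(cohort$purity, noise_sd = s)
      res <- eqtl_scan(cohort, model = "interaction", purity = measured)
      perf <- glance(classify_performance(res, truth, fdr_threshold))
      tibble::tibble(noise_sd = s,
                     pearson_r = cor(measured$cancer_fraction, cf),
                     sensitivity = perf$sensitivity,
                     specificity = perf$specificity,
                     true_fdr = perf$true_fdr,
                     n_significant = perf$tp + perf$fp)
    })
    out <- dplyr::bind_rows(rows)
    class(out) <- c("eqtl_sweep", class(out))
    out
  })
}

#' Compare a high-purity-subset scan with the interaction model
#'
#' Restricting an eQTL scan to the samples with the highest cancer-cell
#' content is the naive alternative to purity modeling. This helper runs the
#' conventional model on the top `top_fraction` of samples by purity
#' (deterministic rank selection), and correlates the subset effect sizes
#' with (a) the interaction-model and (b) the full-cohort conventional
#' effect estimates. When normal-driven eQTLs are present, (a) exceeds (b).
#'
#' @param cohort An `eqtl_cohort`.
#' @param top_fraction Fraction of samples to keep (default 0.10).
#' @param purity Optional measured purity for the interaction scan (defaults
#'   to the cohort's true purity).
#' @return List with `r_interaction`, `r_conventional`, `n_subset`, and a
#'   `betas` tibble (gene_id, subset, conventional, interaction effects).
#' @export
high_purity_comparison <- function(cohort, top_fraction = 0.10,
                                   purity = NULL) {
  cf <- cohort$purity$cancer_fraction
  n <- length(cf)
  n_sub <- max(1L, floor(top_fraction * n))
  if (n_sub < 4)
    abort("the high-purity subset is smaller than the model parameter count.")
  keep <- order(-cf, seq_len(n))[seq_len(n_sub)]   # rank, ties by index
  sub_res <- eqtl_scan(cohort$expression[keep, , drop = FALSE],
                       cohort$genotypes[keep, , drop = FALSE],
                       pairs = tibble::tibble(
                         variant_id = cohort$truth$variant_id,
                         gene_id = cohort$truth$gene_id),
                       model = "conventional")
  full_res <- eqtl_scan(cohort, model = "conventional")
  int_res <- eqtl_scan(cohort, model = "interaction",
                       purity = purity %||% cohort$purity)
  betas <- tibble::tibble(gene_id = cohort$truth$gene_id,
                          subset = sub_res$beta1,
                          conventional = full_res$beta1,
                          interaction = int_res$beta1)
  ok <- complete.cases(betas[-1]) & is.finite(betas$subset) &
    is.finite(betas$conventional) & is.finite(betas$interaction)
  list(r_interaction = cor(betas$subset[ok], betas$interaction[ok]),
       r_conventional = cor(betas$subset[ok], betas$conventional[ok]),
       n_subset = n_sub,
       betas = betas)
}
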