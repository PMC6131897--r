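test_that("inverse-normal transform matches the normal-quantile oracle", {
  expect_equal(inverse_normal_transform(c(1, 2, 3)),
               qnorm(c(1, 3, 5) / 6))
  expect_equal(qnorm(c(1, 3, 5) / 6), c(-0.9674216, 0, 0.9674216),
               tolerance = 1e-6)
  v <- rnorm(57)
  expect_equal(rank(inverse_normal_transform(v)), rank(v))
  expect_equal(mean(inverse_normal_transform(v)), 0, tolerance = 1e-12)
  # ties get average ranks, hence equal transformed values
  expect_equal(inverse_normal_transform(c(1, 1, 2))[1:2],
               rep(qnorm(mean(c(1, 2) - 0.5) / 3), 2))
})

test_that("normalized expression is gene-wise standard normal", {
  set.seed(21)
  expr <- matrix(rlnorm(150 * 20), 150, 20,
                 dimnames = list(paste0("s", 1:150), paste0("g", 1:20)))
  out <- normalize_expression(expr)
  expect_equal(dim(out), dim(expr))
  # quantile normalization introduces ties, so gene means are near but not
  # exactly zero
  expect_true(all(abs(colMeans(out)) < 0.02))
  expect_true(all(abs(apply(out, 2, sd) - 1) < 0.1))
  # the rank-based transform alone is KS-indistinguishable from N(0, 1)
  ks <- stats::ks.test(inverse_normal_transform(rnorm(150)), "pnorm")
  expect_gt(ks$p.value, 0.05)
  # constant genes are flagged and dropped
  expr2 <- cbind(expr, flat = rep(2, 150))
  expect_warning(out2 <- normalize_expression(expr2), "constant")
  expect_equal(ncol(out2), 20)
})

test_that("expression filter keeps genes expressed in >= 75% of samples", {
  n <- 100
  expr <- cbind(all = rep(1, n),
                at74 = c(rep(1, 74), rep(0, 26)),
                at75 = c(rep(1, 75), rep(0, 25)))
  kept <- filter_genes_expressed(expr)
  expect_setequal(colnames(kept), c("all", "at75"))
  # boundary: 3 of 4 samples = 0.75 is retained
  toy <- cbind(g1 = c(1, 2, 3, 0), g2 = c(0, 0, 1, 1))
  expect_equal(colnames(filter_genes_expressed(toy)), "g1")
  expect_identical(filter_genes_expressed(filter_genes_expressed(expr)),
                   filter_genes_expressed(expr))
  expect_error(filter_genes_expressed(matrix(0, 10, 2)), "no genes")
})

test_that("MAF filter computes min(f, 1-f) from dosages", {
  geno <- cbind(mono = rep(0, 20),
                rare = c(1, rep(0, 19)),          # MAF 1/40 = 0.025
                common = rep(c(0, 1, 1, 2), 5))   # MAF 0.5
  kept <- filter_variants_maf(geno)
  expect_equal(colnames(kept), "common")
  # the simulated 250/500/250 architecture always survives
  g <- simulate_genotypes(1000, 5, seed = 3)
  expect_equal(ncol(filter_variants_maf(g)), 5)
  expect_identical(filter_variants_maf(filter_variants_maf(geno)),
                   filter_variants_maf(geno))
})

test_that("cis pairing honors the window boundary and gene strand", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB", "gC", "gD"),
    chrom = "1",
    start = c(1400000, 1400000, 2000000, 1500000),
    end = c(1499999, 1500001, 2100000, 1600000),
    strand = c("-", "-", "+", "+"))
  variants <- tibble::tibble(variant_id = "v1", chrom = "1", pos = 1000000)
  pairs <- map_cis_pairs(variants, genes)
  # gA: minus-strand anchor 1,499,999 -> within window; gB anchor 1,500,001
  # -> outside; gD: plus-strand anchor exactly 500 kb away -> boundary kept
  expect_setequal(pairs$gene_id, c("gA", "gD"))
  expect_equal(pairs$distance[pairs$gene_id == "gA"], 1000000 - 1499999)
  expect_equal(pairs$distance[pairs$gene_id == "gD"], -500000)
})

test_that("cis pairing equals a brute-force distance scan", {
  for (seed in 1:5) {
    set.seed(seed)
    nv <- 30; ng <- 15; win <- 1000
    variants <- tibble::tibble(variant_id = paste0("v", 1:nv),
                               chrom = sample(c("1", "2"), nv, TRUE),
                               pos = sample.int(10000, nv))
    genes <- tibble::tibble(gene_id = paste0("g", 1:ng),
                            chrom = sample(c("1", "2"), ng, TRUE),
                            start = sample.int(10000, ng),
                            end = 0, strand = "+")
    genes$end <- genes$start + sample.int(500, ng)
    got <- map_cis_pairs(variants, genes, window = win)
    want <- list()
    for (i in seq_len(nv)) for (j in seq_len(ng)) {
      if (variants$chrom[i] == genes$chrom[j] &&
          abs(variants$pos[i] - genes$start[j]) <= win)
        want[[length(want) + 1]] <- tibble::tibble(
          variant_id = variants$variant_id[i], gene_id = genes$gene_id[j],
          distance = variants$pos[i] - genes$start[j])
    }
    want <- dplyr::arrange(dplyr::bind_rows(want), variant_id, gene_id)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
  expect_warning(
    map_cis_pairs(tibble::tibble(variant_id = "v", chrom = "chrUn", pos = 1),
                  tibble::tibble(gene_id = "g", chrom = "1", start = 1,
                                 end = 2)),
    "chrUn")
})

test_that("genotype PCs match the SVD oracle up to sign", {
  set.seed(31)
  geno <- matrix(sample(0:2, 40 * 8, TRUE), 40, 8)
  pcs <- compute_genotype_pcs(geno, k = 3)
  sv <- svd(scale(geno))
  oracle <- sv$u[, 1:3] %*% diag(sv$d[1:3])
  for (j in 1:3)
    expect_equal(abs(cor(pcs[, j], oracle[, j])), 1, tolerance = 1e-8)
  expect_lt(max(abs(crossprod(pcs)[upper.tri(diag(3))])), 1e-8)
  expect_error(compute_genotype_pcs(matrix(1, 10, 3), k = 2), "constant")
  expect_warning(compute_genotype_pcs(cbind(geno, rep(1, 40)), k = 2),
                 "constant")
})

test_that("expression factors are orthogonal to regressed-out covariates", {
  set.seed(32)
  n <- 60
  covar <- cbind(a = rnorm(n), b = runif(n))
  expr <- matrix(rnorm(n * 25), n, 25) + covar[, 1] %o% rnorm(25)
  fac <- compute_expression_factors(expr, known_covariates = covar, k = 4)
  expect_equal(dim(fac), c(n, 4))
  expect_lt(max(abs(crossprod(fac, scale(covar, scale = FALSE)))), 1e-8)
  expect_equal(ncol(compute_expression_factors(expr, k = 0)), 0)
  # residualizing a covariate out of itself leaves nothing
  expect_lt(max(abs(tumoreqtl:::residualize(covar, covar))), 1e-10)
})

test_that("purity transfer recovers purity-driven structure and maps quantiles", {
  set.seed(33)
  n_ref <- 120; n_tgt <- 80; n_genes <- 60
  purity_ref <- runif(n_ref, 0.3, 0.95)
  purity_tgt <- runif(n_tgt, 0.3, 0.95)
  loadings <- c(rnorm(50, sd = 1), rep(0, n_genes - 50))
  make_expr <- function(p, n) {
    m <- p %o% loadings + matrix(rnorm(n * n_genes, sd = 0.3), n, n_genes)
    dimnames(m) <- list(paste0("s", seq_len(n)), paste0("g", seq_len(n_genes)))
    m
  }
  ref <- make_expr(purity_ref, n_ref)
  tgt <- make_expr(purity_tgt, n_tgt)
  est <- purity_transfer(tgt, ref, purity_ref, seed = 5)
  expect_gt(cor(est$cancer_fraction, purity_tgt), 0.8)
  expect_gte(min(est$cancer_fraction), min(purity_ref))
  expect_lte(max(est$cancer_fraction), max(purity_ref))
  # same-cohort transfer returns the reference purity multiset
  self <- purity_transfer(ref, ref, purity_ref, seed = 5)
  expect_equal(sort(self$cancer_fraction), sort(purity_ref))
  expect_error(purity_transfer(tgt[, 1:5], ref[, 1:5], purity_ref), "shared")
})
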