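make_ann <- function(gene = "g", tissue = "t", snp_ids, models) {
  snps <- data.frame(snp_id = snp_ids, position = seq_along(snp_ids),
                     effect_allele = "A", other_allele = "B",
                     pip = pip_from_models_test(models, snp_ids))
  gene_annotation(gene, tissue, snps, models)
}

pip_from_models_test <- function(models, snp_ids) {
  vapply(snp_ids, function(s) sum(vapply(models, function(m)
    if (s %in% m$snp_ids) m$posterior_prob else 0, numeric(1))),
    numeric(1))
}

test_that("model-averaged weights reduce to OLS slopes in hand cases", {
  G <- toy_genotypes(250, 4, rho = 0, seed = 11)
  x <- toy_expression(G, 1, 0.8, seed = 12)
  # one certain model: weight equals the marginal OLS slope
  ann <- make_ann(snp_ids = colnames(G),
                  models = list(list(snp_ids = "snp1",
                                     posterior_prob = 1.0)))
  civ <- build_composite_iv(ann, G, x)
  g1 <- G[, 1] - mean(G[, 1])
  slope <- sum(g1 * (x - mean(x))) / sum(g1^2)
  expect_equal(civ$weights[civ$snp_ids == "snp1"], slope,
               tolerance = 1e-12)
  expect_true(all(civ$weights[civ$snp_ids != "snp1"] == 0))

  # two equally weighted singleton models average their slopes
  ann2 <- make_ann(snp_ids = colnames(G), models = list(
    list(snp_ids = "snp1", posterior_prob = 0.5),
    list(snp_ids = "snp2", posterior_prob = 0.5)))
  civ2 <- build_composite_iv(ann2, G, x)
  g2 <- G[, 2] - mean(G[, 2])
  slope2 <- sum(g2 * (x - mean(x))) / sum(g2^2)
  expect_equal(civ2$weights[civ2$snp_ids == "snp1"], 0.5 * slope,
               tolerance = 1e-12)
  expect_equal(civ2$weights[civ2$snp_ids == "snp2"], 0.5 * slope2,
               tolerance = 1e-12)
})

test_that("composite score equals the posterior-weighted ensemble of
           per-model predictions", {
  # the weighted-sum form and the model-ensemble form are algebraically
  # identical; verify to near machine precision on a fine-mapped locus
  G <- toy_genotypes(300, 20, rho = 0.7, seed = 13)
  x <- toy_expression(G, c(4, 15), c(1, -0.7), seed = 14)
  ann <- finemap(G, x)
  civ <- build_composite_iv(ann, G, x)
  Gc <- scale(G[, civ$snp_ids, drop = FALSE], center = TRUE, scale = FALSE)
  xhat_w <- drop(Gc %*% civ$weights)
  # oracle: per-model least-squares predictions combined by posterior
  xc <- x - mean(x)
  xhat_m <- numeric(nrow(G))
  for (m in ann$models) {
    if (!length(m$snp_ids)) next
    W <- scale(G[, m$snp_ids, drop = FALSE], center = TRUE, scale = FALSE)
    b <- solve(crossprod(W), crossprod(W, xc))
    xhat_m <- xhat_m + m$posterior_prob * drop(W %*% b)
  }
  expect_lt(max(abs(xhat_w - xhat_m)), 1e-10)
})

test_that("individual-level scan handles perfect and degenerate cases", {
  G <- toy_genotypes(200, 5, rho = 0, seed = 15)
  x <- toy_expression(G, 2, 1, seed = 16)
  ann <- make_ann(snp_ids = colnames(G),
                  models = list(list(snp_ids = "snp2",
                                     posterior_prob = 1.0)))
  civ <- build_composite_iv(ann, G, x)
  # trait exactly equal to the composite score: p collapses to the floor
  xhat <- drop(scale(G[, "snp2"], scale = FALSE)) *
    civ$weights[civ$snp_ids == "snp2"]
  res <- scan_individual(civ, G, xhat)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1e-100)
  expect_true(is.finite(res$z) || is.infinite(res$z))
  # zero-variance composite score is an undefined test
  civ0 <- civ
  G0 <- G
  G0[, "snp2"] <- G0[1, "snp2"]
  expect_error(scan_individual(civ0, G0, x), "zero variance")
})

test_that("null scan p-values are uniform over replicates", {
  set.seed(17)
  G <- toy_genotypes(306, 20, rho = 0.5, seed = 17)
  x <- toy_expression(G, 7, 1, seed = 18)
  ann <- finemap(G, x)
  civ <- build_composite_iv(ann, G, x)
  pvals <- replicate(500, scan_individual(civ, G, rnorm(306))$p_value)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("summary-statistic scan degenerates and composes correctly", {
  civ <- structure(list(gene_id = "g", tissue = "t", snp_ids = "s1",
                        weights = 1, genotype_sd = 1),
                   class = "composite_iv")
  res <- scan_summary(civ, gwas_z = 2.5, ld = diag(1), lambda = 0)
  expect_equal(res$z, 2.5, tolerance = 1e-12)
  civ2 <- structure(list(gene_id = "g", tissue = "t",
                         snp_ids = c("s1", "s2"), weights = c(1, 1),
                         genotype_sd = c(1, 1)),
                    class = "composite_iv")
  res2 <- scan_summary(civ2, c(2, 2), diag(2), lambda = 0)
  expect_equal(res2$z, 2 * sqrt(2), tolerance = 1e-12)
  # inconsistent LD with negative quadratic form raises a usable error
  bad_ld <- matrix(c(1, -2, -2, 1), 2, 2)
  expect_error(scan_summary(civ2, c(2, 2), bad_ld, lambda = 0),
               "regulariz")
})

test_that("summary and individual-level scans agree on a matched panel", {
  run_pair <- function(effects, eta, seed) {
    G <- toy_genotypes(400, 20, rho = 0.6, seed = seed)
    x <- toy_expression(G, c(6, 14), effects, seed = seed + 1)
    Gg <- toy_genotypes(306, 20, rho = 0.6, seed = seed + 2)
    xg <- toy_expression(Gg, c(6, 14), effects, seed = seed + 3)
    set.seed(seed + 4)
    y <- simulate_trait(xg, eta)
    ann <- finemap(G, x)
    civ <- build_composite_iv(ann, G, x)
    ind <- scan_individual(civ, Gg, y)
    # GWAS summary statistics and LD from the same GWAS cohort
    n <- nrow(Gg)
    Gc <- scale(Gg, center = TRUE, scale = FALSE)
    yc <- y - mean(y)
    sxx <- colSums(Gc^2)
    beta <- drop(crossprod(Gc, yc)) / sxx
    se <- sqrt(pmax(sum(yc^2) - beta^2 * sxx, 0) / ((n - 2) * sxx))
    civ_g <- civ
    civ_g$genotype_sd <- apply(Gg[, civ$snp_ids, drop = FALSE], 2, sd)
    summ <- scan_summary(civ_g, (beta / se)[civ$snp_ids],
                         cor(Gg)[civ$snp_ids, civ$snp_ids], lambda = 0)
    c(ind = ind$z, summ = summ$z)
  }
  # moderate association: absolute agreement
  z <- run_pair(c(0.6, 0.5), 0.5, seed = 19)
  expect_lt(abs(z["summ"] - z["ind"]), 0.2)
  # strong association: marginal z-scores embed the per-SNP residual
  # variance, so agreement is relative rather than absolute
  z2 <- run_pair(c(1.2, 0.9), 1, seed = 25)
  expect_lt(abs(z2["summ"] - z2["ind"]) / abs(z2["ind"]), 0.1)
  expect_equal(unname(sign(z2["summ"])), unname(sign(z2["ind"])))
})

test_that("Gini coefficient matches hand values and the Lorenz oracle", {
  expect_equal(gini(c(1, 0, 0, 0)), 0.75, tolerance = 1e-12)
  expect_equal(gini(rep(0.3, 4)), 0, tolerance = 1e-12)
  expect_error(gini(c(0, 0)), "all-zero")
  set.seed(23)
  w <- rexp(100) * sample(c(-1, 1), 100, replace = TRUE)
  # oracle: Lorenz-curve integration, G = 1 - 2 * AUC(Lorenz)
  a <- sort(abs(w))
  lorenz <- c(0, cumsum(a) / sum(a))
  auc <- sum((lorenz[-1] + lorenz[-length(lorenz)]) / 2) / 100
  expect_equal(gini(w), 1 - 2 * auc, tolerance = 1e-3)
})
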