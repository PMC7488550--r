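test_that("Wald ratio and delta-method variance match hand arithmetic", {
  w <- snp_wald(0.5, 0.1, 1.0, 0.1)
  expect_equal(w$beta_xy, 0.5)
  expect_equal(w$var_xy, 0.01 + 0.0025)
  w0 <- snp_wald(0, 0.1, 1.0, 0.1)
  expect_equal(w0$beta_xy, 0)
  expect_equal(w0$var_xy, 0.01)
  expect_error(snp_wald(0.5, 0.1, 1e-9, 1), "weak instrument")
})

test_that("delta-method variance matches the Monte-Carlo ratio variance
           for a strong instrument", {
  set.seed(31)
  beta_e <- 1; se_e <- 0.1               # z_eqtl = 10
  beta_g <- 0.8; se_g <- 0.2
  draws <- rnorm(1e6, beta_g, se_g) / rnorm(1e6, beta_e, se_e)
  w <- snp_wald(beta_g, se_g, beta_e, se_e)
  expect_equal(w$var_xy, var(draws), tolerance = 0.1)
})

test_that("cluster estimates follow the laws of total expectation and
           variance", {
  cl <- list(cluster_id = 1L, member_snp_ids = c("a", "b"), spip = 1.0)
  pips <- c(a = 0.5, b = 0.5)
  mk <- function(b, v, id) structure(list(snp_id = id, beta_xy = b,
                                          var_xy = v),
                                     class = "snp_wald")
  # homogeneous members: variance reduces to the shared member variance
  est <- cluster_estimate(cl, list(a = mk(1, 0.01, "a"),
                                   b = mk(1, 0.01, "b")), pips)
  expect_equal(est$beta, 1)
  expect_equal(est$var, 0.01, tolerance = 1e-12)
  expect_equal(sum(est$tilde_p), 1, tolerance = 1e-12)
  # discordant members: between-SNP spread enters the variance
  est2 <- cluster_estimate(cl, list(a = mk(1, 0.01, "a"),
                                    b = mk(-1, 0.01, "b")), pips)
  expect_equal(est2$beta, 0)
  expect_equal(est2$var, 1.01, tolerance = 1e-12)
  # singleton cluster reduces to the SNP-level Wald estimate
  cl1 <- list(cluster_id = 2L, member_snp_ids = "a", spip = 1.0)
  est3 <- cluster_estimate(cl1, list(a = mk(0.7, 0.04, "a")),
                           c(a = 1.0))
  expect_equal(est3$beta, 0.7)
  expect_equal(est3$var, 0.04)
  expect_error(cluster_estimate(cl, list(a = mk(1, 0.01, "a")), pips),
               "missing Wald")
})

test_that("cluster variance is never negative (law of total variance)", {
  set.seed(32)
  for (r in 1:200) {
    m <- sample(2:6, 1)
    ids <- paste0("s", seq_len(m))
    pips <- setNames(runif(m, 0.01, 1), ids)
    walds <- lapply(ids, function(s) structure(
      list(snp_id = s, beta_xy = rnorm(1, 0, 2),
           var_xy = runif(1, 1e-4, 1)), class = "snp_wald"))
    names(walds) <- ids
    cl <- list(cluster_id = 1L, member_snp_ids = ids, spip = sum(pips))
    est <- cluster_estimate(cl, walds, pips)
    expect_gte(est$var, 0)
    expect_gte(est$var + 1e-12,
               sum(est$tilde_p * vapply(walds, function(w) w$var_xy,
                                        numeric(1))))
  }
})

test_that("IVW combination matches closed forms and filters weak clusters", {
  mk_cl <- function(beta, var, spip, id) structure(
    list(cluster_id = id, spip = spip, beta = beta, var = var,
         member_estimates = list(), tilde_p = 1),
    class = "cluster_estimate")
  # two identical estimates halve the variance
  eff <- ivw_combine(list(mk_cl(1, 0.01, 0.9, 1), mk_cl(1, 0.01, 0.9, 2)))
  expect_equal(eff$beta, 1)
  expect_equal(eff$se, sqrt(0.005), tolerance = 1e-12)
  expect_equal(eff$q_stat, 0)
  expect_equal(eff$i2, 0)
  # singleton passes through with the convention I2 = 0
  eff1 <- ivw_combine(list(mk_cl(0.7, 0.04, 0.8, 1)))
  expect_equal(eff1$beta, 0.7)
  expect_equal(eff1$se, 0.2)
  expect_equal(eff1$n_instruments, 1L)
  expect_equal(eff1$i2, 0)
  # three heterogeneous estimates: longhand fixed-effect meta-analysis
  b <- c(0.4, 1.1, 0.8); v <- c(0.02, 0.05, 0.01)
  eff3 <- ivw_combine(list(mk_cl(b[1], v[1], 0.95, 1),
                           mk_cl(b[2], v[2], 0.8, 2),
                           mk_cl(b[3], v[3], 0.6, 3)))
  expect_equal(eff3$beta, sum(b / v) / sum(1 / v), tolerance = 1e-12)
  expect_equal(eff3$se, 1 / sqrt(sum(1 / v)), tolerance = 1e-12)
  expect_equal(eff3$q_stat,
               sum((b - sum(b / v) / sum(1 / v))^2 / v),
               tolerance = 1e-12)
  # weak clusters are excluded; none eligible means not estimable
  expect_equal(ivw_combine(list(mk_cl(5, 0.01, 0.3, 1),
                                mk_cl(1, 0.01, 0.9, 2)))$beta, 1)
  expect_null(ivw_combine(list(mk_cl(1, 0.01, 0.2, 1))))
})

test_that("a PIP-1 singleton cluster reproduces the SMR Wald ratio", {
  w <- snp_wald(0.42, 0.11, 0.9, 0.07, snp_id = "s")
  cl <- list(cluster_id = 1L, member_snp_ids = "s", spip = 1.0)
  est <- cluster_estimate(cl, list(s = w), c(s = 1.0))
  eff <- ivw_combine(list(est))
  expect_equal(eff$beta, w$beta_xy, tolerance = 1e-14)
  expect_equal(eff$se^2, w$var_xy, tolerance = 1e-14)
})

test_that("effect z-test follows the two-sided normal reference", {
  mk_eff <- function(beta, se) structure(
    list(gene_id = "g", tissue = "t", beta = beta, se = se,
         n_instruments = 1L, q_stat = 0, i2 = 0), class = "gene_effect")
  expect_equal(effect_z_test(mk_eff(0, 0.3)), 1.0)
  expect_equal(effect_z_test(mk_eff(1.959964 * 0.5, 0.5)), 0.05,
               tolerance = 1e-6)
})
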