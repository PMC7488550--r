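#' Simulation scenario for the two-sample TWAS experiments
#'
#' Parameterizes the generative model used throughout the simulation
#' studies: for each gene, `n_snps` cis-SNP dosages with AR(1)-decaying
#' LD; sparse causal eQTLs sampled per SNP from `Bernoulli(causal_freq)`
#' with effects `N(0, sparse_effect_var)`; a polygenic background scaled
#' so expression heritability is about `target_h2`; unit-variance
#' residual noise; and a trait generated by the structural equation
#' `y = u + eta * x + e`, `e ~ N(0, 1)`. Samples are split into
#' non-overlapping eQTL (`n_eqtl`) and GWAS (`n_gwas`) cohorts.
#'
#' Defaults reproduce the study conditions: 706 samples split 400/306,
#' 1500 cis-SNPs per gene, causal frequency 0.002 (three causal eQTLs
#' per gene on average), sparse effect variance 0.5, heritability target
#' 0.5, `eta = 1` fixed for estimation runs, and
#' `eta ~ N(0, phi^2)` with `phi^2` drawn from
#' `{0, 0.2, 0.5, 0.8, 1, 1.2}` for power runs.
#'
#' @param n_genes Number of simulated genes.
#' @param n_total,n_eqtl,n_gwas Total sample size and two-sample split.
#' @param n_snps cis-SNPs per gene.
#' @param causal_freq Per-SNP probability of being a causal eQTL.
#' @param sparse_effect_var Variance of sparse causal effect sizes.
#' @param target_h2 Target expression heritability.
#' @param eta_var_grid Grid of gene-to-trait effect variances for power
#'   runs.
#' @param eta_fixed Fixed gene-to-trait effect for estimation runs.
#' @param ld_decay AR(1) correlation of the latent haplotype process.
#' @param maf_range Range of minor allele frequencies.
#' @param pleiotropy_sd Magnitude (per allele) of the direct pleiotropic
#'   SNP-to-trait effect injected in heterogeneity runs; the sign is
#'   randomized per gene.
#' @param seed Integer seed; every run is deterministic given the seed.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(n_genes = 1000L, n_total = 706L, n_eqtl = 400L,
                         n_gwas = 306L, n_snps = 1500L,
                         causal_freq = 0.002, sparse_effect_var = 0.5,
                         target_h2 = 0.5,
                         eta_var_grid = c(0, 0.2, 0.5, 0.8, 1, 1.2),
                         eta_fixed = 1, ld_decay = 0.85,
                         maf_range = c(0.05, 0.5), pleiotropy_sd = 1,
                         seed = 1L) {
  stopifnot(n_eqtl + n_gwas <= n_total, ld_decay >= 0, ld_decay < 1,
            causal_freq >= 0, causal_freq <= 1, sparse_effect_var >= 0,
            target_h2 >= 0, target_h2 < 1)
  structure(list(n_genes = as.integer(n_genes),
                 n_total = as.integer(n_total),
                 n_eqtl = as.integer(n_eqtl), n_gwas = as.integer(n_gwas),
                 n_snps = as.integer(n_snps), causal_freq = causal_freq,
                 sparse_effect_var = sparse_effect_var,
                 target_h2 = target_h2, eta_var_grid = eta_var_grid,
                 eta_fixed = eta_fixed, ld_decay = ld_decay,
                 maf_range = maf_range, pleiotropy_sd = pleiotropy_sd,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate genotype dosages with AR(1) linkage disequilibrium
#'
#' Each of the `2n` haplotypes follows a latent Gaussian AR(1) process
#' across SNPs with correlation `ld_decay`; the latent value is
#' thresholded at the allele-frequency quantile to give a binary allele,
#' and the two haplotypes are summed into a dosage in `{0, 1, 2}`.
#' Adjacent-SNP r-squared decays geometrically with distance on the
#' latent scale; on the dosage scale the correlation is attenuated by
#' thresholding, more strongly for mismatched allele frequencies.
#'
#' @param n Number of individuals.
#' @param scenario A [sim_scenario()] (fields `n_snps`, `ld_decay`,
#'   `maf_range` are used).
#' @return `n x n_snps` integer dosage matrix with columns `snp1 ...`,
#'   MAFs attached as attribute `"maf"`.
#' @export
simulate_genotypes <- function(n, scenario = sim_scenario()) {
  p <- scenario$n_snps
  rho <- scenario$ld_decay
  maf <- stats::runif(p, scenario$maf_range[1], scenario$maf_range[2])
  L <- matrix(stats::rnorm(2 * n * p), 2 * n, p)
  if (rho > 0) {
    s <- sqrt(1 - rho^2)
    for (j in 2:p) L[, j] <- rho * L[, j - 1] + s * L[, j]
  }
  thr <- stats::qnorm(maf)
  H <- L < matrix(thr, nrow(L), p, byrow = TRUE)
  G <- H[seq_len(n), , drop = FALSE] + H[n + seq_len(n), , drop = FALSE]
  storage.mode(G) <- "integer"
  colnames(G) <- sprintf("snp%d", seq_len(p))
  attr(G, "maf") <- maf
  G
}

#' Simulate expression with sparse causal eQTLs and polygenic background
#'
#' Implements the expression generative model
#' `x_i = mu + sum_j (beta_j gamma_j + alpha_j) g_ij + eps_i`,
#' `eps ~ N(0, 1)`: causal indicators `gamma_j ~ Bernoulli(causal_freq)`,
#' sparse effects `beta_j ~ N(0, sparse_effect_var)`, and a polygenic
#' background `alpha_j` scaled per gene so that total genetic variance
#' over total variance is about `target_h2` given the realized sparse
#' effects (when the sparse effects alone exceed the target, no
#' polygenic background is added and heritability exceeds the target;
#' this variation mirrors the dependence on realized allele
#' frequencies).
#'
#' @param genotypes Dosage matrix from [simulate_genotypes()].
#' @param scenario A [sim_scenario()].
#' @return List: `expression` (n-vector) and `truth` with `causal_idx`,
#'   `beta` (sparse effects of causal SNPs), `alpha_sd`, `h2` (realized
#'   heritability).
#' @export
simulate_expression <- function(genotypes, scenario = sim_scenario()) {
  G <- genotypes
  n <- nrow(G)
  p <- ncol(G)
  gamma <- stats::rbinom(p, 1, scenario$causal_freq)
  beta <- stats::rnorm(p, 0, sqrt(scenario$sparse_effect_var)) * gamma
  causal_idx <- which(gamma == 1)
  g_sparse <- if (length(causal_idx))
    drop(G[, causal_idx, drop = FALSE] %*% beta[causal_idx]) else
      numeric(n)
  v_sparse <- stats::var(g_sparse)
  # residual variance is 1; genetic variance hitting target_h2 solves
  # v_target = target_h2 / (1 - target_h2)
  v_target <- scenario$target_h2 / (1 - scenario$target_h2)
  alpha_sd <- 0
  g_poly <- numeric(n)
  if (v_sparse < v_target && scenario$target_h2 > 0) {
    alpha_raw <- stats::rnorm(p)
    poly_raw <- drop(G %*% alpha_raw)
    v_raw <- stats::var(poly_raw)
    if (v_raw > 0) {
      alpha_sd <- sqrt((v_target - v_sparse) / v_raw)
      g_poly <- alpha_sd * poly_raw
    }
  }
  g_total <- g_sparse + g_poly
  expression <- g_total + stats::rnorm(n)
  h2 <- stats::var(g_total) / (stats::var(g_total) + 1)
  list(expression = expression,
       truth = list(causal_idx = causal_idx, beta = beta[causal_idx],
                    alpha_sd = alpha_sd, h2 = h2))
}

#' Simulate a complex trait from expression
#'
#' Structural equation `y = u + eta * x + e`, `e ~ N(0, 1)`.
#'
#' @param expression Expression n-vector.
#' @param eta Gene-to-trait causal effect.
#' @param intercept Trait intercept `u`.
#' @return Trait n-vector.
#' @export
simulate_trait <- function(expression, eta, intercept = 0) {
  intercept + eta * expression + stats::rnorm(length(expression))
}

# vectorized single-SNP OLS summary statistics (marginal beta, se, z)
marginal_stats <- function(G, y) {
  G <- as.matrix(G)
  n <- nrow(G)
  Gc <- scale(G, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(Gc^2)
  sxy <- drop(crossprod(Gc, yc))
  syy <- sum(yc^2)
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  ssr <- pmax(syy - beta^2 * sxx, 0)
  se <- sqrt(ssr / ((n - 2) * sxx))
  data.frame(snp_id = colnames(G), beta = beta, se = se, z = beta / se,
             stringsAsFactors = FALSE)
}

#' Full single-gene analysis on a two-sample design
#'
#' Runs the complete per-gene pipeline: fine-mapping of the eQTL cohort,
#' composite-IV construction and scan against the GWAS cohort, Wald
#' ratios for signal-cluster members from marginal summary statistics,
#' cluster-level estimates, IVW combination, exclusion-restriction
#' diagnosis, and the single-top-eQTL (SMR-style) comparator.
#'
#' @param G_eqtl,expression eQTL-cohort dosages and expression.
#' @param G_gwas,trait GWAS-cohort dosages and trait (non-overlapping
#'   samples).
#' @param spip_min Minimum SPIP for clusters used in estimation and
#'   diagnosis.
#' @param fm_config A [finemap_config()].
#' @return List with `annotation`, `civ`, `scan`, `cluster_estimates`,
#'   `effect` (IVW; `NULL` if not estimable), `het`
#'   (`NULL` if < 2 eligible clusters), `best` (highest-SPIP eligible
#'   cluster estimate or `NULL`), and `smr`
#'   (list `snp_id`, `beta`, `var`, `z`, `p`).
#' @export
ptwas_gene <- function(G_eqtl, expression, G_gwas, trait, spip_min = 0.50,
                       fm_config = finemap_config()) {
  ann <- finemap(G_eqtl, expression, fm_config)
  civ <- build_composite_iv(ann, G_eqtl, expression)
  scan <- scan_individual(civ, G_gwas, trait)

  eq_all <- marginal_stats(G_eqtl, expression)
  gw_all <- marginal_stats(G_gwas, trait)
  rownames(eq_all) <- eq_all$snp_id
  rownames(gw_all) <- gw_all$snp_id

  pips <- stats::setNames(ann$snps$pip, ann$snps$snp_id)
  cl_est <- list()
  for (cl in ann$clusters) {
    ids <- cl$member_snp_ids
    ok <- ids[abs(eq_all[ids, "z"]) >= 1e-6 & is.finite(eq_all[ids, "z"])]
    if (!length(ok)) next
    walds <- lapply(ok, function(s)
      snp_wald(gw_all[s, "beta"], gw_all[s, "se"],
               eq_all[s, "beta"], eq_all[s, "se"], snp_id = s))
    names(walds) <- ok
    cl2 <- list(cluster_id = cl$cluster_id, member_snp_ids = ok,
                spip = cl$spip)
    cl_est[[length(cl_est) + 1L]] <- cluster_estimate(cl2, walds, pips)
  }
  effect <- ivw_combine(cl_est, spip_min, gene_id = ann$gene_id,
                        tissue = ann$tissue)
  het <- er_diagnose(cl_est, spip_min)
  elig <- Filter(function(e) e$spip >= spip_min && e$var > 0, cl_est)
  best <- if (length(elig))
    elig[[which.max(vapply(elig, function(e) e$spip, numeric(1)))]] else
      NULL

  top <- which.max(abs(eq_all$z))
  sid <- eq_all$snp_id[top]
  smr_w <- snp_wald(gw_all[sid, "beta"], gw_all[sid, "se"],
                    eq_all[sid, "beta"], eq_all[sid, "se"], snp_id = sid)
  smr_z <- smr_w$beta_xy / sqrt(smr_w$var_xy)
  smr <- list(snp_id = sid, beta = smr_w$beta_xy, var = smr_w$var_xy,
              z = smr_z, p = 2 * stats::pnorm(-abs(smr_z)))

  list(annotation = ann, civ = civ, scan = scan,
       cluster_estimates = cl_est, effect = effect, het = het,
       best = best, smr = smr)
}

#' Run a simulation experiment end-to-end
#'
#' Generates `n_genes` independent gene loci under the scenario and runs
#' the full per-gene analysis on each, under a strict two-sample split
#' (samples `1..n_eqtl` for eQTL mapping, the remaining `n_gwas` for the
#' trait).
#'
#' Modes:
#' * `"power"`: gene-to-trait effects `eta ~ N(0, phi^2)` with `phi^2`
#'   assigned in equal numbers from `eta_var_grid` (including 0, the
#'   null). The summary reports, for the composite-IV scan, the
#'   estimation-based z-test and the SMR-style top-SNP test: power at
#'   the Storey FDR 5% threshold among truly non-null genes, type-I
#'   error at nominal p <= 0.05 among null genes, and ROC points.
#' * `"estimation"`: `eta = eta_fixed` for every gene; genes passing the
#'   scan at p <= 0.05 are estimated. The summary reports RMSE of the
#'   IVW (all eligible clusters), best-single-cluster, and SMR
#'   estimators, the mean estimate, and mean I-squared, at SPIP
#'   thresholds 0.5 / 0.7 / 0.9 / 0.95.
#' * `"heterogeneity"`: `eta = eta_fixed`; for half the genes one causal
#'   eQTL SNP is given a direct (pleiotropic) effect on the trait of
#'   magnitude `pleiotropy_sd` per allele with random sign -- a severe
#'   exclusion-restriction violation. The summary contrasts the
#'   I-squared distribution with and without the injected pleiotropy.
#'
#' @param scenario A [sim_scenario()].
#' @param mode `"power"`, `"estimation"` or `"heterogeneity"`.
#' @param spip_min SPIP threshold for estimation/diagnosis.
#' @param fm_config A [finemap_config()].
#' @param fdr_level FDR level for the power summary.
#' @param verbose Print a progress line every 50 genes.
#' @return List with `genes` (per-gene `data.frame`), `summary`
#'   (`data.frame`), and `mode`.
#' @export
run_experiment <- function(scenario = sim_scenario(),
                           mode = c("power", "estimation", "heterogeneity"),
                           spip_min = 0.50, fm_config = finemap_config(),
                           fdr_level = 0.05, verbose = FALSE) {
  mode <- match.arg(mode)
  set.seed(scenario$seed)
  ng <- scenario$n_genes
  idx_eqtl <- seq_len(scenario$n_eqtl)
  idx_gwas <- scenario$n_eqtl + seq_len(scenario$n_gwas)
  stopifnot(length(intersect(idx_eqtl, idx_gwas)) == 0)

  phi2 <- NULL
  if (mode == "power") {
    phi2 <- rep(scenario$eta_var_grid, length.out = ng)
    phi2 <- sample(phi2)
  }
  pleio <- if (mode == "heterogeneity")
    rep(c(FALSE, TRUE), length.out = ng) else rep(FALSE, ng)

  rows <- vector("list", ng)
  cl_store <- vector("list", ng)
  for (g in seq_len(ng)) {
    G <- simulate_genotypes(scenario$n_total, scenario)
    ex <- simulate_expression(G, scenario)
    eta <- if (mode == "power") stats::rnorm(1, 0, sqrt(phi2[g])) else
      scenario$eta_fixed
    y_all <- simulate_trait(ex$expression, eta)
    if (pleio[g] && length(ex$truth$causal_idx)) {
      # severe exclusion-restriction violation: one causal eQTL also acts
      # on the trait directly, with a per-allele effect of fixed magnitude
      # and random sign
      j <- ex$truth$causal_idx[1]
      delta <- sample(c(-1, 1), 1) * scenario$pleiotropy_sd
      y_all <- y_all + delta * G[, j]
    }
    res <- tryCatch(
      ptwas_gene(G[idx_eqtl, , drop = FALSE], ex$expression[idx_eqtl],
                 G[idx_gwas, , drop = FALSE], y_all[idx_gwas],
                 spip_min = spip_min, fm_config = fm_config),
      error = function(e) {
        warning("gene ", g, ": analysis failed (", conditionMessage(e),
                "); recorded as missing")
        NULL
      })
    if (is.null(res)) {
      rows[[g]] <- data.frame(
        gene = g, eta = eta,
        phi2 = if (is.null(phi2)) NA_real_ else phi2[g],
        pleiotropy = pleio[g], n_causal = length(ex$truth$causal_idx),
        h2 = ex$truth$h2, scan_z = NA_real_, scan_p = NA_real_,
        beta_ivw = NA_real_, se_ivw = NA_real_, n_instruments = 0L,
        q_stat = NA_real_, i2 = NA_real_, beta_best = NA_real_,
        var_best = NA_real_, beta_smr = NA_real_, var_smr = NA_real_,
        p_smr = NA_real_, p_estz = NA_real_, max_spip = 0,
        stringsAsFactors = FALSE)
      cl_store[[g]] <- list()
      next
    }
    eff <- res$effect
    rows[[g]] <- data.frame(
      gene = g, eta = eta,
      phi2 = if (is.null(phi2)) NA_real_ else phi2[g],
      pleiotropy = pleio[g], n_causal = length(ex$truth$causal_idx),
      h2 = ex$truth$h2, scan_z = res$scan$z, scan_p = res$scan$p_value,
      beta_ivw = if (is.null(eff)) NA_real_ else eff$beta,
      se_ivw = if (is.null(eff)) NA_real_ else eff$se,
      n_instruments = if (is.null(eff)) 0L else eff$n_instruments,
      q_stat = if (is.null(res$het)) NA_real_ else res$het$q,
      i2 = if (is.null(res$het)) NA_real_ else res$het$i2,
      beta_best = if (is.null(res$best)) NA_real_ else res$best$beta,
      var_best = if (is.null(res$best)) NA_real_ else res$best$var,
      beta_smr = res$smr$beta, var_smr = res$smr$var,
      p_smr = res$smr$p,
      p_estz = if (is.null(eff)) NA_real_ else effect_z_test(eff),
      max_spip = if (length(res$cluster_estimates))
        max(vapply(res$cluster_estimates, function(e) e$spip,
                   numeric(1))) else 0,
      stringsAsFactors = FALSE)
    cl_store[[g]] <- res$cluster_estimates
    if (verbose && g %% 50 == 0)
      message("  gene ", g, "/", ng)
  }
  genes <- do.call(rbind, rows)
  summary <- switch(mode,
    power = summarize_power(genes, fdr_level),
    estimation = summarize_estimation(genes, cl_store, scenario),
    heterogeneity = summarize_heterogeneity(genes))
  list(mode = mode, genes = genes, summary = summary,
       cluster_estimates = cl_store)
}

summarize_power <- function(genes, fdr_level = 0.05) {
  nonnull <- genes$eta != 0
  # missing p-values (not-estimable or failed genes) count as
  # non-rejections
  methods <- list(ptwas_scan = ifelse(is.na(genes$scan_p), 1,
                                      genes$scan_p),
                  estimation_z = ifelse(is.na(genes$p_estz), 1,
                                        genes$p_estz),
                  smr = ifelse(is.na(genes$p_smr), 1, genes$p_smr))
  do.call(rbind, lapply(names(methods), function(m) {
    p <- methods[[m]]
    q <- storey_qvalues(p)
    data.frame(method = m,
               power_fdr05 = mean(q[nonnull] <= fdr_level),
               rejections_fdr05 = sum(q <= fdr_level),
               type1_p05 = mean(p[!nonnull] <= 0.05),
               n_nonnull = sum(nonnull), n_null = sum(!nonnull),
               stringsAsFactors = FALSE)
  }))
}

summarize_estimation <- function(genes, cl_store, scenario,
                                 spip_grid = c(0.5, 0.7, 0.9, 0.95)) {
  pass <- which(genes$scan_p <= 0.05)
  eta <- scenario$eta_fixed
  out <- lapply(spip_grid, function(thr) {
    ivw_b <- best_b <- i2s <- rep(NA_real_, length(pass))
    multi <- logical(length(pass))
    for (k in seq_along(pass)) {
      ce <- cl_store[[pass[k]]]
      eff <- ivw_combine(ce, spip_min = thr)
      if (is.null(eff)) next
      ivw_b[k] <- eff$beta
      multi[k] <- eff$n_instruments >= 2
      elig <- Filter(function(e) e$spip >= thr && e$var > 0, ce)
      best <- elig[[which.max(vapply(elig, function(e) e$spip,
                                     numeric(1)))]]
      best_b[k] <- best$beta
      if (eff$n_instruments >= 2) i2s[k] <- eff$i2
    }
    ok <- !is.na(ivw_b)
    data.frame(
      spip_min = thr, n_genes = sum(ok), n_multi = sum(multi),
      rmse_ivw = sqrt(mean((ivw_b[ok] - eta)^2)),
      rmse_best_cluster = sqrt(mean((best_b[ok] - eta)^2)),
      rmse_ivw_multi = if (any(multi))
        sqrt(mean((ivw_b[multi] - eta)^2)) else NA_real_,
      mean_ivw = mean(ivw_b[ok]),
      mean_i2 = mean(i2s, na.rm = TRUE),
      rmse_smr = sqrt(mean((genes$beta_smr[pass][ok] - eta)^2)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "n_pass") <- length(pass)
  attr(out, "pass_rate") <- length(pass) / nrow(genes)
  out
}

summarize_heterogeneity <- function(genes) {
  do.call(rbind, lapply(c(FALSE, TRUE), function(pl) {
    d <- genes[genes$pleiotropy == pl & !is.na(genes$i2), ]
    data.frame(pleiotropy = pl, n_genes = nrow(d),
               mean_i2 = mean(d$i2), median_i2 = stats::median(d$i2),
               frac_flagged = mean(d$i2 > 0.5), stringsAsFactors = FALSE)
  }))
}
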