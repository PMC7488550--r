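#' SNP-level Wald (2SLS) ratio estimate of the gene-to-trait effect
#'
#' For a single instrument SNP, the causal effect of expression on the
#' trait is the ratio of the marginal GWAS effect to the marginal eQTL
#' effect, `beta_xy = beta_gwas / beta_eqtl`, with variance from the
#' two-term delta method:
#' `var_xy = se_gwas^2 / beta_eqtl^2 +
#'           beta_gwas^2 * se_eqtl^2 / beta_eqtl^4`.
#'
#' @param beta_gwas,se_gwas Marginal GWAS effect and standard error.
#' @param beta_eqtl,se_eqtl Marginal (single-SNP) eQTL effect and
#'   standard error.
#' @param snp_id Optional SNP identifier.
#' @return A `snp_wald` list: `snp_id`, `beta_xy`, `var_xy`.
#' @export
snp_wald <- function(beta_gwas, se_gwas, beta_eqtl, se_eqtl,
                     snp_id = NA_character_) {
  stopifnot(se_gwas > 0, se_eqtl > 0)
  if (abs(beta_eqtl / se_eqtl) < 1e-6)
    stop("weak instrument: |beta_eqtl / se_eqtl| < 1e-6 for ", snp_id)
  beta_xy <- beta_gwas / beta_eqtl
  var_xy <- se_gwas^2 / beta_eqtl^2 +
    beta_gwas^2 * se_eqtl^2 / beta_eqtl^4
  structure(list(snp_id = snp_id, beta_xy = beta_xy, var_xy = var_xy),
            class = "snp_wald")
}

#' Signal-cluster-level causal effect estimate by Bayesian model averaging
#'
#' Within one eQTL signal cluster with SPIP `q`, each member SNP's PIP is
#' renormalized to the conditional causal probability
#' `tilde_p_i = p_i / q`. The cluster-level estimate combines the member
#' Wald ratios by the law of total expectation,
#' `beta = sum_i tilde_p_i beta_i`, and its variance by the law of total
#' variance,
#' `var = sum_i tilde_p_i (var_i + beta_i^2) - beta^2`,
#' which accounts for the residual uncertainty about which member SNP is
#' the causal eQTL.
#'
#' @param cluster A signal cluster (see [build_clusters()]): list with
#'   `cluster_id`, `member_snp_ids`, `spip`; member PIPs are taken from
#'   `pips` aligned to `member_snp_ids`.
#' @param walds Named list of [snp_wald()] objects covering every member
#'   SNP.
#' @param pips Named numeric vector of SNP-level PIPs (names = SNP ids).
#' @return A `cluster_estimate` list: `cluster_id`, `spip`, `beta`,
#'   `var`, `member_estimates`, `tilde_p`.
#' @export
cluster_estimate <- function(cluster, walds, pips) {
  ids <- cluster$member_snp_ids
  if (!all(ids %in% names(walds)))
    stop("missing Wald estimate for SNP(s): ",
         paste(setdiff(ids, names(walds)), collapse = ","))
  if (!all(ids %in% names(pips)))
    stop("missing PIP for SNP(s): ",
         paste(setdiff(ids, names(pips)), collapse = ","))
  if (cluster$spip <= 0) stop("cluster SPIP must be positive")
  p <- pips[ids]
  tilde_p <- as.numeric(p / sum(p))
  b <- vapply(walds[ids], function(w) w$beta_xy, numeric(1))
  v <- vapply(walds[ids], function(w) w$var_xy, numeric(1))
  beta <- sum(tilde_p * b)
  var <- sum(tilde_p * (v + b^2)) - beta^2
  var <- max(var, 0)                     # guard tiny negative round-off
  structure(list(cluster_id = cluster$cluster_id, spip = cluster$spip,
                 beta = beta, var = var,
                 member_estimates = walds[ids], tilde_p = tilde_p),
            class = "cluster_estimate")
}

#' Gene-level causal effect by inverse-variance-weighted meta-analysis
#'
#' Combines cluster-level estimates from independent eQTL signals using a
#' fixed-effect meta-analysis: `beta = sum(b_k / v_k) / sum(1 / v_k)`,
#' `se = 1 / sqrt(sum(1 / v_k))`. Only clusters whose SPIP reaches
#' `spip_min` (strong instruments) participate. Cochran's Q and the
#' I-squared heterogeneity statistic across the participating clusters
#' are attached when two or more instruments are available; with a single
#' instrument `Q = 0` and `I2 = 0` by convention.
#'
#' @param estimates List of [cluster_estimate()] objects.
#' @param spip_min Minimum SPIP for a cluster to be admitted.
#' @param gene_id,tissue Labels for the returned record.
#' @return A `gene_effect` list (`beta`, `se`, `n_instruments`, `q_stat`,
#'   `i2`, ...), or `NULL` when no cluster is eligible (not estimable;
#'   distinct from an error).
#' @export
ivw_combine <- function(estimates, spip_min = 0.50, gene_id = "gene",
                        tissue = "tissue") {
  el <- Filter(function(e) e$spip >= spip_min && e$var > 0, estimates)
  if (!length(el)) return(NULL)
  b <- vapply(el, function(e) e$beta, numeric(1))
  v <- vapply(el, function(e) e$var, numeric(1))
  wt <- 1 / v
  beta <- sum(wt * b) / sum(wt)
  se <- 1 / sqrt(sum(wt))
  if (length(el) >= 2) {
    qr <- cochran_q(b, sqrt(v))
    q <- qr$q
    i2 <- i_squared(q, length(el))
  } else {
    q <- 0
    i2 <- 0
  }
  structure(list(gene_id = gene_id, tissue = tissue, beta = beta, se = se,
                 n_instruments = length(el), q_stat = q, i2 = i2),
            class = "gene_effect")
}

#' @export
print.gene_effect <- function(x, ...) {
  cat(sprintf(
    "gene_effect: %s [%s]  beta = %.4f (se %.4f), %d instrument(s), I2 = %.3f\n",
    x$gene_id, x$tissue, x$beta, x$se, x$n_instruments, x$i2))
  invisible(x)
}

#' Two-sided z-test p-value for an estimated gene-to-trait effect
#'
#' Tests `beta = 0` using the normal reference for `z = beta / se`. This
#' estimation-based test is less powerful than the composite-IV scan (the
#' delta-method standard errors are conservative at realistic sample
#' sizes) and is provided as a comparator, not a replacement for the
#' scan.
#'
#' @param effect A [ivw_combine()] result (or any list with `beta`,
#'   `se`).
#' @return Two-sided p-value.
#' @export
effect_z_test <- function(effect) {
  stopifnot(effect$se > 0)
  min(2 * stats::pnorm(-abs(effect$beta / effect$se)), 1)
}
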