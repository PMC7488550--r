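#' Cochran's Q across independent effect estimates
#'
#' `Q = sum_k (b_k - b_fixed)^2 / se_k^2`, where `b_fixed` is the
#' inverse-variance-weighted fixed-effect mean.
#'
#' @param betas Effect estimates (length >= 2).
#' @param ses Standard errors (> 0), same length.
#' @return List with `q` and `fixed_beta`.
#' @export
cochran_q <- function(betas, ses) {
  if (length(betas) < 2) stop("Cochran's Q requires at least two estimates")
  stopifnot(length(ses) == length(betas), all(ses > 0))
  wt <- 1 / ses^2
  fixed_beta <- sum(wt * betas) / sum(wt)
  list(q = sum((betas - fixed_beta)^2 * wt), fixed_beta = fixed_beta)
}

#' I-squared heterogeneity statistic
#'
#' `I2 = max(0, (Q - T + 1) / Q)` for `T` independent estimates; 0 when
#' `Q = 0`. Values near 0 indicate consistent estimates (as expected when
#' the exclusion restriction holds); values near 1 indicate severe
#' inconsistency, e.g. horizontal pleiotropy. No hypothesis test is
#' attached: I-squared is reported as a quantitative metric only.
#'
#' @param q Cochran's Q (>= 0).
#' @param t Number of independent estimates (>= 2).
#' @return I-squared in `[0, 1]`.
#' @export
i_squared <- function(q, t) {
  stopifnot(t >= 2, q >= 0)
  if (q == 0) return(0)
  max(0, (q - t + 1) / q)
}

#' Exclusion-restriction diagnosis across eQTL signal clusters
#'
#' Each strong, independent eQTL signal cluster yields its own estimate
#' of the gene-to-trait effect; under the exclusion restriction these
#' estimates agree up to sampling noise. This computes Cochran's Q and
#' I-squared across the cluster-level estimates whose SPIP reaches
#' `spip_min`.
#'
#' @param estimates List of [cluster_estimate()] objects for one gene.
#' @param spip_min Minimum SPIP for a cluster to participate.
#' @return A `heterogeneity_result` (list with `q`, `t`, `i2`,
#'   `fixed_beta`), or `NULL` when fewer than two clusters are eligible
#'   (diagnosis not applicable).
#' @export
er_diagnose <- function(estimates, spip_min = 0.50) {
  el <- Filter(function(e) e$spip >= spip_min && e$var > 0, estimates)
  if (length(el) < 2) return(NULL)
  b <- vapply(el, function(e) e$beta, numeric(1))
  s <- sqrt(vapply(el, function(e) e$var, numeric(1)))
  qr <- cochran_q(b, s)
  structure(list(q = qr$q, t = length(el),
                 i2 = i_squared(qr$q, length(el)),
                 fixed_beta = qr$fixed_beta),
            class = "heterogeneity_result")
}

#' Cross-tissue heterogeneity of gene-to-trait effects
#'
#' Applies Cochran's Q / I-squared to per-tissue gene-level effect
#' estimates; large values suggest tissue-specific (environment
#' -modified) gene-to-trait effects.
#'
#' @param effects List of [ivw_combine()] results for one gene across
#'   tissues.
#' @return A `heterogeneity_result`, or `NULL` with fewer than two
#'   tissues with finite standard errors.
#' @export
cross_tissue_i2 <- function(effects) {
  el <- Filter(function(e) !is.null(e) && is.finite(e$se) && e$se > 0,
               effects)
  if (length(el) < 2) return(NULL)
  b <- vapply(el, function(e) e$beta, numeric(1))
  s <- vapply(el, function(e) e$se, numeric(1))
  qr <- cochran_q(b, s)
  structure(list(q = qr$q, t = length(el),
                 i2 = i_squared(qr$q, length(el)),
                 fixed_beta = qr$fixed_beta),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("heterogeneity: T = %d, Q = %.3f, I2 = %.3f\n",
              x$t, x$q, x$i2))
  invisible(x)
}
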