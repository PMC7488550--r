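#' Cauchy-combination (ACAT) p-value aggregation
#'
#' Combines p-values with the aggregated Cauchy association test:
#' `T = sum_i w_i tan((0.5 - p_i) pi) / sum_i w_i`, with combined p-value
#' `P(Cauchy > T) = 0.5 - arctan(T) / pi`. The combination is valid under
#' arbitrary dependence of the inputs. P-values below 1e-15 contribute
#' via the Cauchy tail approximation `tan((0.5 - p) pi) ~= 1 / (p pi)` to
#' avoid overflow.
#'
#' @param pvals P-values in `(0, 1)`. Values of exactly 1 are pulled back
#'   to `1 - 1e-16`.
#' @param weights Optional non-negative weights (default uniform).
#' @return Combined p-value.
#' @export
acat <- function(pvals, weights = NULL) {
  if (!length(pvals)) stop("acat requires at least one p-value")
  stopifnot(all(pvals > 0), all(pvals <= 1))
  if (is.null(weights)) weights <- rep(1, length(pvals))
  stopifnot(length(weights) == length(pvals), all(weights >= 0),
            any(weights > 0))
  w <- weights / sum(weights)
  p <- pmin(pvals, 1 - 1e-16)
  tiny <- p < 1e-15
  stat <- numeric(length(p))
  stat[!tiny] <- tanpi(0.5 - p[!tiny])
  stat[tiny] <- 1 / (p[tiny] * pi)
  t_acat <- sum(w * stat)
  stats::pcauchy(t_acat, lower.tail = FALSE)
}

#' Storey q-values for FDR control
#'
#' Estimates the null proportion `pi0` by smoothing
#' `pi0(lambda) = mean(p > lambda) / (1 - lambda)` over the grid
#' `lambda = 0.05, 0.10, ..., 0.95` with a cubic smoothing spline
#' evaluated at the largest lambda, then computes
#' `q_i = min over {j: p_j >= p_i} of pi0 * m * p_j / rank(p_j)`.
#' Q-values are monotone non-decreasing in the p-values. With fewer than
#' 100 p-values `pi0` is set to 1 (the Benjamini-Hochberg limit) with a
#' warning.
#'
#' @param pvals P-values in `[0, 1]`.
#' @return Vector of q-values, same order as `pvals`.
#' @export
storey_qvalues <- function(pvals) {
  stopifnot(all(pvals >= 0), all(pvals <= 1))
  m <- length(pvals)
  if (m < 100) {
    warning("fewer than 100 p-values; using pi0 = 1 (Benjamini-Hochberg)")
    pi0 <- 1
  } else {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(pvals > l) / (1 - l),
                    numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * pvals[o] / rank(pvals, ties.method = "max")[o]))
  q[ro]
}

#' Multi-tissue global-null scan
#'
#' For each gene, combines the per-tissue scan p-values with [acat()]
#' (uniform weights) to test the global null hypothesis that the gene's
#' causal effect is zero in every tissue, then applies
#' [storey_qvalues()] across genes for FDR control.
#'
#' @param scan_results `data.frame` with columns `gene_id`, `tissue`,
#'   `p_value` (one row per gene-tissue scan), or a list of
#'   `scan_result` objects.
#' @return `data.frame` with one row per gene: `gene_id`, `acat_p`,
#'   `q_value`, `n_tissues`, `min_tissue`, `min_p`.
#' @export
global_scan <- function(scan_results) {
  if (!is.data.frame(scan_results)) {
    scan_results <- do.call(rbind, lapply(scan_results, function(s)
      data.frame(gene_id = s$gene_id, tissue = s$tissue,
                 p_value = s$p_value, stringsAsFactors = FALSE)))
  }
  stopifnot(all(c("gene_id", "tissue", "p_value") %in% names(scan_results)))
  by_gene <- split(scan_results, scan_results$gene_id)
  out <- do.call(rbind, lapply(by_gene, function(d) {
    i <- which.min(d$p_value)
    data.frame(gene_id = d$gene_id[1], acat_p = acat(d$p_value),
               n_tissues = nrow(d), min_tissue = d$tissue[i],
               min_p = d$p_value[i], stringsAsFactors = FALSE)
  }))
  out$q_value <- storey_qvalues(out$acat_p)
  rownames(out) <- NULL
  out[, c("gene_id", "acat_p", "q_value", "n_tissues", "min_tissue",
          "min_p")]
}
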