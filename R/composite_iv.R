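#' Build a composite instrumental variable by Bayesian model averaging
#'
#' For each candidate association model in the annotation, the per-SNP
#' genetic effects on expression are estimated jointly by ordinary least
#' squares on the eQTL cohort (effects of SNPs outside the model are
#' zero). The composite-IV weight for SNP j averages these estimates over
#' models, weighted by posterior model probability:
#' `w_j = sum_i P(M_i) beta_hat(M_i, j)`. The resulting score
#' `xhat = sum_j w_j G_j` equals the posterior-weighted ensemble of the
#' per-model least-squares predictions and serves as a single valid
#' instrument that accounts for allelic heterogeneity and LD.
#'
#' Weights are computed on centered, unstandardized allele dosages, so
#' they are in expression units per allele. Reference genotype standard
#' deviations from the eQTL panel are stored for use with GWAS summary
#' statistics.
#'
#' @param annotation A [gene_annotation()].
#' @param genotypes eQTL-cohort dosage matrix (`n x p`, column names
#'   matching annotation SNP ids; otherwise columns are taken in
#'   annotation order).
#' @param expression Expression `n`-vector.
#' @return An object of class `composite_iv`: list with `gene_id`,
#'   `tissue`, `snp_ids`, `weights`, `genotype_sd` (restricted to the
#'   union of model SNPs).
#' @export
build_composite_iv <- function(annotation, genotypes, expression) {
  X <- as.matrix(genotypes)
  y <- as.numeric(expression)
  ids <- colnames(X)
  if (is.null(ids)) {
    ids <- annotation$snps$snp_id
    if (ncol(X) != length(ids))
      stop("genotypes lack column names and do not match annotation size")
    colnames(X) <- ids
  }
  support <- unique(unlist(lapply(annotation$models, function(m) m$snp_ids)))
  if (!length(support)) stop("annotation contains no non-null model")
  if (!all(support %in% ids))
    stop("genotypes missing model SNP(s): ",
         paste(setdiff(support, ids), collapse = ","))
  support <- ids[ids %in% support]       # genotype order
  Xc <- scale(X[, support, drop = FALSE], center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  w <- numeric(length(support))
  # single-SNP models share the same marginal OLS slope: accumulate their
  # posterior mass and apply the vectorized slopes once
  sxx <- colSums(Xc^2)
  sxy <- drop(crossprod(Xc, yc))
  mass1 <- numeric(length(support))
  lens <- lengths(lapply(annotation$models, `[[`, "snp_ids"))
  idx_all <- match(unlist(lapply(annotation$models, `[[`, "snp_ids")),
                   support)
  midx <- split(idx_all, factor(rep.int(seq_along(lens), lens),
                                levels = seq_along(lens)))
  for (i in seq_along(annotation$models)) {
    m <- annotation$models[[i]]
    idx <- midx[[i]]
    if (!length(idx) || m$posterior_prob <= 0) next
    if (length(idx) == 1) {
      mass1[idx] <- mass1[idx] + m$posterior_prob
      next
    }
    W <- Xc[, idx, drop = FALSE]
    G <- crossprod(W)
    b <- tryCatch(solve(G, crossprod(W, yc)), error = function(e) {
      warning("singular design for model {",
              paste(m$snp_ids, collapse = ","), "}; using ridge fallback")
      solve(G + diag(1e-6 * mean(diag(G)), ncol(G)), crossprod(W, yc))
    })
    w[idx] <- w[idx] + m$posterior_prob * drop(b)
  }
  ok1 <- mass1 > 0 & sxx > 0
  w[ok1] <- w[ok1] + mass1[ok1] * sxy[ok1] / sxx[ok1]
  if (all(w == 0)) stop("composite IV has no nonzero weight")
  Xsup <- X[, support, drop = FALSE]
  n <- nrow(Xsup)
  gsd <- sqrt(pmax(colSums(Xsup^2) - n * colMeans(Xsup)^2, 0) / (n - 1))
  structure(list(gene_id = annotation$gene_id, tissue = annotation$tissue,
                 snp_ids = support, weights = w,
                 genotype_sd = stats::setNames(gsd, support)),
            class = "composite_iv")
}

#' @export
print.composite_iv <- function(x, ...) {
  cat("composite_iv:", x$gene_id, "[", x$tissue, "],",
      length(x$snp_ids), "SNPs,",
      sum(x$weights != 0), "nonzero weights\n")
  invisible(x)
}

# internal: composite IV score on centered dosages
civ_score <- function(civ, genotypes) {
  X <- as.matrix(genotypes)
  if (is.null(colnames(X)))
    stop("genotypes must carry column names matching composite IV SNP ids")
  if (!all(civ$snp_ids %in% colnames(X)))
    stop("genotypes missing composite IV SNP(s)")
  Xs <- X[, civ$snp_ids, drop = FALSE]
  Xs <- scale(Xs, center = TRUE, scale = FALSE)
  drop(Xs %*% civ$weights)
}

#' Gene-trait scan test on individual-level data
#'
#' Evaluates the composite IV on the GWAS cohort's genotypes and tests
#' its association with the trait by simple linear regression
#' (z = slope / SE, two-sided normal p-value).
#'
#' @param civ A [build_composite_iv()] result.
#' @param genotypes GWAS-cohort dosage matrix with named columns covering
#'   the composite IV SNPs.
#' @param trait Trait `n`-vector, same sample order as `genotypes`.
#' @return A `scan_result`: list with `gene_id`, `tissue`, `z`, `p_value`.
#' @export
scan_individual <- function(civ, genotypes, trait) {
  xhat <- civ_score(civ, genotypes)
  y <- as.numeric(trait)
  n <- length(y)
  vx <- stats::var(xhat)
  if (vx <= 0) stop("composite IV score has zero variance; test undefined")
  r <- stats::cor(xhat, y)
  # z from the regression slope: slope/SE = r * sqrt((n-2)/(1-r^2))
  z <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  scan_result(civ$gene_id, civ$tissue, z)
}

#' Gene-trait scan test from GWAS summary statistics
#'
#' Burden-style combination of single-SNP GWAS z-scores using the
#' composite IV weights and a reference LD matrix:
#' `z = (sum_j w_j s_j z_j) / sqrt(sum_jk w_j w_k s_j s_k R_jk)`,
#' where `s_j` are reference genotype standard deviations from the eQTL
#' panel. The LD matrix is shrunk towards the identity,
#' `(1 - lambda) R + lambda I`, to guard against reference-panel mismatch.
#'
#' @param civ A [build_composite_iv()] result.
#' @param gwas_z Vector of GWAS z-scores aligned to `civ$snp_ids` (allele
#'   -harmonized; see [harmonize_alleles()]).
#' @param ld SNP correlation matrix aligned to `civ$snp_ids`.
#' @param lambda LD regularization weight in `[0,1]`.
#' @return A `scan_result`.
#' @export
scan_summary <- function(civ, gwas_z, ld, lambda = 0.05) {
  p <- length(civ$snp_ids)
  if (length(gwas_z) != p) stop("gwas_z not aligned to composite IV SNPs")
  if (!is.matrix(ld) || any(dim(ld) != p))
    stop("ld not aligned to composite IV SNPs")
  R <- (1 - lambda) * ld + lambda * diag(p)
  ws <- civ$weights * civ$genotype_sd
  denom <- drop(crossprod(ws, R %*% ws))
  if (denom <= 0)
    stop("non-positive test variance; LD reference inconsistent with ",
         "weights -- increase the LD regularization lambda")
  z <- sum(ws * gwas_z) / sqrt(denom)
  scan_result(civ$gene_id, civ$tissue, z)
}

scan_result <- function(gene_id, tissue, z) {
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(gene_id = gene_id, tissue = tissue, z = z,
                 p_value = max(p, .Machine$double.xmin)),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result: %s [%s]  z = %.3f  p = %.3g\n",
              x$gene_id, x$tissue, x$z, x$p_value))
  invisible(x)
}

#' Gini coefficient of composite IV weight sparsity
#'
#' Summarizes how concentrated the absolute weights are over SNPs using
#' the mean-absolute-difference form of the Gini coefficient. Values near
#' 1 indicate a sparse instrument (a few SNPs dominate); values near 0
#' indicate evenly spread weights.
#'
#' @param weights Numeric weight vector with at least one nonzero entry.
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini <- function(weights) {
  a <- abs(weights)
  if (all(a == 0)) stop("Gini coefficient undefined for all-zero weights")
  n <- length(a)
  a <- sort(a)
  # identity: G = (2 * sum_i i*a_(i) / (n * sum a)) - (n + 1)/n
  2 * sum(seq_len(n) * a) / (n * sum(a)) - (n + 1) / n
}
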