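#' Configuration for the Bayesian multi-SNP fine-mapper
#'
#' @param max_model_size Largest number of SNPs allowed in a candidate
#'   association model.
#' @param prior_inclusion Per-SNP prior inclusion probability; `NULL`
#'   (default) uses `1/p`, i.e. one causal eQTL expected a priori.
#' @param effect_prior_variance Prior variance of a standardized per-SNP
#'   effect (relative to residual variance).
#' @param max_models_retained Cap on the number of candidate models kept
#'   for posterior normalization.
#' @param search `"greedy"` (forward selection with swap refinement) or
#'   `"exhaustive"` (full enumeration up to `max_model_size`; small loci
#'   only).
#' @return A `finemap_config` list.
#' @export
finemap_config <- function(max_model_size = 5L, prior_inclusion = NULL,
                           effect_prior_variance = 0.25,
                           max_models_retained = 4096L,
                           search = c("greedy", "exhaustive")) {
  search <- match.arg(search)
  stopifnot(max_model_size >= 1,
            is.null(prior_inclusion) ||
              (prior_inclusion > 0 && prior_inclusion < 1),
            effect_prior_variance > 0, max_models_retained >= 1)
  structure(list(max_model_size = as.integer(max_model_size),
                 prior_inclusion = prior_inclusion,
                 effect_prior_variance = effect_prior_variance,
                 max_models_retained = as.integer(max_models_retained),
                 search = search),
            class = "finemap_config")
}

#' Log marginal likelihood of a multi-SNP association model
#'
#' Conjugate Bayesian linear regression with independent Gaussian effect
#' priors: `y = W b + e`, `e ~ N(0, s2 I)`, `b ~ N(0, v s2 I)`, and the
#' reference prior `p(s2) ~ 1/s2`. With `y` centered and the columns of
#' `W` standardized, the marginal likelihood has the closed form
#' `log m = lgamma(n/2) - (n/2) log(pi) - 0.5 log|I + v W'W|
#'  - (n/2) log(y'y - y'W (W'W + I/v)^{-1} W'y)`.
#' The `k = 0` (null) model reduces to the intercept-only Gaussian model,
#' `log m = lgamma(n/2) - (n/2) log(pi) - (n/2) log(y'y)`.
#'
#' @param genotypes `n x k` matrix of standardized genotype columns (may
#'   have zero columns for the null model).
#' @param expression Centered expression `n`-vector.
#' @param config A [finemap_config()]; only `effect_prior_variance` is
#'   used.
#' @return Log marginal likelihood (finite scalar). Zero-variance or
#'   linearly redundant columns are dropped with a warning.
#' @export
model_log_marginal <- function(genotypes, expression, config = finemap_config()) {
  W <- as.matrix(genotypes)
  y <- as.numeric(expression)
  n <- length(y)
  v <- config$effect_prior_variance
  cst <- lgamma(n / 2) - (n / 2) * log(pi)
  if (ncol(W) == 0) return(cst - (n / 2) * log(sum(y^2)))
  sds <- apply(W, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance genotype column(s): ",
            paste(which(sds == 0), collapse = ","))
    W <- W[, sds > 0, drop = FALSE]
    if (ncol(W) == 0) return(cst - (n / 2) * log(sum(y^2)))
  }
  G <- crossprod(W)
  # drop linearly redundant columns (pivoted Cholesky rank check)
  ch <- suppressWarnings(chol(G, pivot = TRUE))
  rank <- attr(ch, "rank")
  if (rank < ncol(W)) {
    drop_idx <- attr(ch, "pivot")[(rank + 1):ncol(W)]
    warning("dropping linearly redundant genotype column(s): ",
            paste(drop_idx, collapse = ","))
    W <- W[, -drop_idx, drop = FALSE]
    G <- crossprod(W)
  }
  k <- ncol(W)
  A <- G + diag(1 / v, k)
  Wty <- crossprod(W, y)
  qf <- drop(crossprod(Wty, solve(A, Wty)))
  logdet <- as.numeric(determinant(diag(k) + v * G, logarithm = TRUE)$modulus)
  cst - 0.5 * logdet - (n / 2) * log(sum(y^2) - qf)
}

# log prior of a model of size k under independent Bernoulli(pi1) inclusion
model_log_prior <- function(k, p, pi1) {
  k * log(pi1) + (p - k) * log1p(-pi1)
}

#' Bayesian multi-SNP fine-mapping of a gene's cis-region
#'
#' Produces the probabilistic eQTL annotation used throughout the
#' analysis: a set of candidate association models with posterior
#' probabilities (normalized over the retained set plus the null model),
#' SNP-level PIPs (posterior mass of models containing each SNP), and LD
#' -based signal clusters with signal-level PIPs.
#'
#' The greedy search performs deterministic forward selection; at each
#' step every single-SNP extension of the current best model is scored
#' (and retained, which spreads posterior mass across LD partners of the
#' selected SNP), and selection stops when no extension improves the
#' unnormalized log posterior. A one-step swap refinement then rescores
#' every replacement of each selected SNP. Exhaustive search enumerates
#' all models up to `max_model_size` and is intended as a small-locus
#' oracle (p <= ~15).
#'
#' Expression and genotypes are centered and scaled internally, which
#' makes `effect_prior_variance` a standardized quantity. Ties in the log
#' marginal are broken by SNP index.
#'
#' @param genotypes `n x p` dosage matrix (column names used as SNP ids).
#' @param expression Expression `n`-vector.
#' @param config A [finemap_config()].
#' @param gene_id,tissue Labels stored in the annotation.
#' @param snp_info Optional `data.frame(snp_id, position, effect_allele,
#'   other_allele)` carried into the annotation.
#' @param r2_min,pip_floor Clustering thresholds, see [build_clusters()].
#' @return A [gene_annotation()]. If the posterior mass of the null model
#'   exceeds 0.99 the cluster list is empty.
#' @export
finemap <- function(genotypes, expression, config = finemap_config(),
                    gene_id = "gene", tissue = "tissue", snp_info = NULL,
                    r2_min = 0.25, pip_floor = 0.01) {
  X <- as.matrix(genotypes)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= config$max_model_size + 2)
    stop("need n > max_model_size + 2 samples")
  ids <- colnames(X)
  if (is.null(ids)) ids <- sprintf("snp%d", seq_len(p))
  y <- as.numeric(scale(expression))
  sds <- sqrt(pmax(colSums(X^2) - n * colMeans(X)^2, 0) / (n - 1))
  ok <- which(sds > 0)
  Xs <- scale(X[, ok, drop = FALSE])
  v <- config$effect_prior_variance
  pi1 <- if (is.null(config$prior_inclusion)) 1 / p else config$prior_inclusion

  if (config$search == "exhaustive") {
    fit <- finemap_exhaustive(Xs, y, v, pi1, p, config)
  } else {
    fit <- finemap_greedy(Xs, y, v, pi1, p, config)
  }
  # fit: list(models = list of integer index vectors into ok, logpost)
  lp <- fit$logpost - max(fit$logpost)
  post <- exp(lp) / sum(exp(lp))
  # truncate: cap the retained count and drop models carrying no
  # appreciable posterior mass (the null model is always kept)
  is_null <- vapply(fit$models, length, integer(1)) == 0
  keep <- order(post, decreasing = TRUE)
  keep <- keep[seq_len(min(length(keep), config$max_models_retained))]
  keep <- union(keep[post[keep] >= 1e-7], which(is_null))
  keep <- sort(keep)
  post <- post[keep] / sum(post[keep])
  models <- lapply(seq_along(keep), function(i) {
    idx <- fit$models[[keep[i]]]
    list(snp_ids = ids[ok][idx], posterior_prob = post[i])
  })
  pip_ok <- numeric(length(ok))
  for (i in seq_along(keep)) {
    idx <- fit$models[[keep[i]]]
    if (length(idx)) pip_ok[idx] <- pip_ok[idx] + post[i]
  }
  pip <- numeric(p)
  pip[ok] <- pip_ok
  names(pip) <- ids

  null_i <- which(vapply(models, function(m) length(m$snp_ids) == 0,
                         logical(1)))
  null_mass <- if (length(null_i)) models[[null_i]]$posterior_prob else 0
  if (null_mass > 0.99) {
    clusters <- list()
  } else {
    cand <- which(pip >= pip_floor)
    if (length(cand)) {
      ldc <- stats::cor(X[, cand, drop = FALSE])
      pv <- pip[cand]
      clusters <- build_clusters(pv, ldc, r2_min = r2_min,
                                 pip_floor = pip_floor)
    } else clusters <- list()
  }
  if (is.null(snp_info)) {
    snps <- data.frame(snp_id = ids, position = seq_len(p),
                       effect_allele = "A", other_allele = "B",
                       pip = unname(pip), stringsAsFactors = FALSE)
  } else {
    snps <- snp_info[match(ids, snp_info$snp_id), , drop = FALSE]
    snps$pip <- unname(pip)
  }
  gene_annotation(gene_id, tissue, snps, models, clusters)
}

# Greedy forward search (small beam) with frontier retention and one-step
# swap refinement. Works on standardized X (q columns), returns candidate
# models (index vectors into columns of Xs) with unnormalized log
# posteriors. All score updates use rank-one Schur-complement identities,
# so each step costs O(q k) per beam after one crossprod.
finemap_greedy <- function(Xs, y, v, pi1, p, config, beam_width = 4L) {
  n <- length(y)
  q <- ncol(Xs)
  yty <- sum(y^2)
  Xty <- drop(crossprod(Xs, y))
  colsq <- rep(n - 1, q)                 # standardized columns
  cst <- lgamma(n / 2) - (n / 2) * log(pi)

  # frontier chunks: each is list(base, add, lp) standing for the models
  # {base + j : j in add}; materialized once at the end
  chunks <- list(list(base = integer(0), add = NA_integer_,
                      lp = cst - (n / 2) * log(yty) +
                        model_log_prior(0, p, pi1)))

  score_additions <- function(B, A_inv, C, logdet_B, qf_B) {
    # scores log-marginal + prior for B + {j}, all j; -Inf for j in B or
    # collinear additions
    k <- length(B)
    if (k == 0) {
      d <- colsq + 1 / v
      qf <- Xty^2 / d
      logdet <- log1p(v * colsq)
    } else {
      AC <- A_inv %*% C
      cAc <- colSums(C * AC)
      d <- colsq + 1 / v - cAc
      u <- drop(A_inv %*% Xty[B])
      h <- Xty - drop(crossprod(C, u))   # Xty_j - c_j' A^{-1} Wty
      qf <- qf_B + h^2 / pmax(d, 1e-12)
      logdet <- logdet_B + log(v) + log(pmax(d, 1e-12))
    }
    s <- yty - qf
    lm <- cst - 0.5 * logdet - (n / 2) * log(pmax(s, 1e-12))
    lp <- lm + model_log_prior(k + 1, p, pi1)
    lp[B] <- -Inf
    bad <- if (k == 0) colsq <= 1e-8 else d <= 1e-8
    lp[bad] <- -Inf
    lp
  }
  add_state <- function(j, B, A_inv, C, logdet_B, qf_B) {
    k <- length(B)
    xj <- Xs[, j]
    cj <- if (k) drop(C[, j]) else numeric(0)
    gj <- colsq[j] + 1 / v
    if (k == 0) {
      A_inv2 <- matrix(1 / gj, 1, 1)
      logdet2 <- log1p(v * colsq[j])
      qf2 <- Xty[j]^2 / gj
      C2 <- matrix(drop(crossprod(xj, Xs)), 1, q)
    } else {
      Acj <- drop(A_inv %*% cj)
      d <- gj - sum(cj * Acj)
      A_inv2 <- rbind(cbind(A_inv + tcrossprod(Acj) / d, -Acj / d),
                      c(-Acj / d, 1 / d))
      logdet2 <- logdet_B + log(v) + log(d)
      u <- drop(A_inv %*% Xty[B])
      h <- Xty[j] - sum(cj * u)
      qf2 <- qf_B + h^2 / d
      C2 <- rbind(C, drop(crossprod(xj, Xs)))
    }
    list(B = c(B, j), A_inv = A_inv2, C = C2, logdet = logdet2, qf = qf2)
  }

  # each retained frontier chunk is capped: the top extensions by score
  # carry all appreciable posterior mass (LD partners of a real signal
  # rank at the top); an uncapped frontier would let thousands of
  # negligible models distort the truncated normalization
  chunk_cap <- 64L
  retain_chunk <- function(base, lp, fin) {
    if (length(fin) > chunk_cap)
      fin <- fin[order(lp[fin], decreasing = TRUE)[seq_len(chunk_cap)]]
    chunks[[length(chunks) + 1L]] <<- list(base = base, add = fin,
                                           lp = lp[fin])
  }
  empty_state <- list(B = integer(0), A_inv = matrix(0, 0, 0),
                      C = matrix(0, 0, q), logdet = 0, qf = 0,
                      lp = chunks[[1]]$lp)
  beams <- list(empty_state)
  best_overall <- empty_state
  for (step in seq_len(config$max_model_size)) {
    cand <- list()                       # (beam index, snp, lp)
    seen <- character(0)
    for (b in seq_along(beams)) {
      st <- beams[[b]]
      lp <- score_additions(st$B, st$A_inv, st$C, st$logdet, st$qf)
      fin <- which(is.finite(lp))
      if (!length(fin)) next
      retain_chunk(st$B, lp, fin)
      cand[[b]] <- data.frame(beam = b, snp = fin, lp = lp[fin])
    }
    if (!length(cand)) break
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$lp, cand$snp), ]
    # next beams: top distinct models (ties in lp broken by SNP index)
    nxt <- list()
    for (i in seq_len(nrow(cand))) {
      if (length(nxt) >= beam_width) break
      st <- beams[[cand$beam[i]]]
      key <- paste(sort(c(st$B, cand$snp[i])), collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      st2 <- add_state(cand$snp[i], st$B, st$A_inv, st$C, st$logdet, st$qf)
      st2$lp <- cand$lp[i]
      nxt[[length(nxt) + 1L]] <- st2
    }
    if (!length(nxt)) break
    if (nxt[[1]]$lp > best_overall$lp) best_overall <- nxt[[1]]
    # keep expanding while the best model of this size retains appreciable
    # posterior mass relative to the best overall; larger models beyond
    # that carry no weight in the truncated normalization
    if (nxt[[1]]$lp <= best_overall$lp - log(1e6)) break
    beams <- nxt
  }

  # swap refinement on the best model: rebuild it without each selected
  # SNP and score all single-SNP completions (spreads posterior mass over
  # LD partners of every selected SNP)
  B <- best_overall$B
  if (length(B) >= 2) {
    for (drop_i in seq_along(B)) {
      Bm <- B[-drop_i]
      st <- list(B = integer(0), A_inv = matrix(0, 0, 0),
                 C = matrix(0, 0, q), logdet = 0, qf = 0)
      for (j in Bm) st <- add_state(j, st$B, st$A_inv, st$C, st$logdet, st$qf)
      lp <- score_additions(st$B, st$A_inv, st$C, st$logdet, st$qf)
      fin <- which(is.finite(lp))
      if (length(fin)) retain_chunk(Bm, lp, fin)
    }
  }
  # materialize and deduplicate; models more than ~27 log-units below the
  # best carry no normalized posterior mass and are skipped
  thr <- max(vapply(chunks, function(ch) max(ch$lp), numeric(1))) - log(1e12)
  models <- vector("list", sum(vapply(chunks, function(ch)
    length(ch$lp), integer(1))))
  logpost <- numeric(length(models))
  pos <- 0L
  for (ch in chunks) {
    if (length(ch$add) == 1 && is.na(ch$add[1])) {
      pos <- pos + 1L
      models[[pos]] <- integer(0)
      logpost[pos] <- ch$lp
    } else {
      base <- sort(ch$base)              # one sort per chunk
      for (i in which(ch$lp >= thr)) {
        pos <- pos + 1L
        j <- ch$add[i]
        at <- findInterval(j, base)
        models[[pos]] <- c(base[seq_len(at)], j,
                           base[seq_len(length(base) - at) + at])
        logpost[pos] <- ch$lp[i]
      }
    }
  }
  length(models) <- pos
  logpost <- logpost[seq_len(pos)]
  keys <- vapply(models, paste, character(1), collapse = ",")
  first <- !duplicated(keys)
  list(models = models[first], logpost = logpost[first])
}

finemap_exhaustive <- function(Xs, y, v, pi1, p, config) {
  q <- ncol(Xs)
  kmax <- min(config$max_model_size, q)
  total <- sum(vapply(0:kmax, function(k) choose(q, k), numeric(1)))
  if (total > 2^20)
    stop("exhaustive enumeration too large (", total, " models); ",
         "use greedy search")
  n <- length(y)
  yty <- sum(y^2)
  cst <- lgamma(n / 2) - (n / 2) * log(pi)
  G <- crossprod(Xs)
  Xty <- drop(crossprod(Xs, y))
  models <- list(integer(0))
  logpost <- cst - (n / 2) * log(yty) + model_log_prior(0, p, pi1)
  for (k in seq_len(kmax)) {
    combs <- utils::combn(q, k)
    for (i in seq_len(ncol(combs))) {
      idx <- combs[, i]
      A <- G[idx, idx, drop = FALSE] + diag(1 / v, k)
      qf <- drop(crossprod(Xty[idx], solve(A, Xty[idx])))
      logdet <- as.numeric(determinant(
        diag(k) + v * G[idx, idx, drop = FALSE], logarithm = TRUE)$modulus)
      lm <- cst - 0.5 * logdet - (n / 2) * log(max(yty - qf, 1e-12))
      models[[length(models) + 1L]] <- idx
      logpost <- c(logpost, lm + model_log_prior(k, p, pi1))
    }
  }
  list(models = models, logpost = logpost)
}
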