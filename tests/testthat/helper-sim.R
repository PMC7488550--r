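# shared test helpers: small simulated loci and independent oracles

# dosage matrix for a small locus
toy_genotypes <- function(n, p, rho = 0.6, seed = 1) {
  sc <- sim_scenario(n_snps = p, ld_decay = rho, seed = seed)
  set.seed(seed)
  simulate_genotypes(n, sc)
}

# expression with known causal SNPs (no polygenic background)
toy_expression <- function(G, causal, effects, seed = 2) {
  set.seed(seed)
  drop(G[, causal, drop = FALSE] %*% effects) + rnorm(nrow(G))
}

# oracle: connected components of the r2 >= r2_min graph restricted to
# SNPs with pip >= pip_floor (independent of the greedy implementation)
cluster_components <- function(pips, ld, r2_min, pip_floor) {
  keep <- which(pips >= pip_floor)
  adj <- ld[keep, keep, drop = FALSE]^2 >= r2_min
  n <- length(keep)
  comp <- integer(n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0) next
    cur <- cur + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (comp[u] > 0) next
      comp[u] <- cur
      queue <- c(queue, which(adj[u, ] & comp == 0L))
    }
  }
  split(keep, comp)
}

# oracle: Pearson correlation of two thresholded AR(1)-correlated latent
# Gaussians (1-D quadrature; no bivariate-normal package needed)
thresholded_gauss_cor <- function(rho, f1, f2) {
  q1 <- qnorm(f1); q2 <- qnorm(f2)
  p11 <- integrate(function(z)
    dnorm(z) * pnorm((q2 - rho * z) / sqrt(1 - rho^2)),
    -Inf, q1, rel.tol = 1e-10)$value
  (p11 - f1 * f2) / sqrt(f1 * (1 - f1) * f2 * (1 - f2))
}
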