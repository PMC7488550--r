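write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("reader recovers PIPs and clusters from simple model files", {
  # single certain model
  f <- write_lines_tmp(c("gene g1 blood", "M 1.0 s1"))
  ann <- read_annotation(f)
  expect_equal(ann$snps$pip[ann$snps$snp_id == "s1"], 1.0)
  expect_length(ann$clusters, 1)
  expect_equal(ann$clusters[[1]]$spip, 1.0)

  # two mutually exclusive models partition one signal
  f <- write_lines_tmp(c("gene g1 blood", "M 0.6 s1", "M 0.4 s2"))
  ann <- read_annotation(f)
  pip <- setNames(ann$snps$pip, ann$snps$snp_id)
  expect_equal(unname(pip[c("s1", "s2")]), c(0.6, 0.4))
  expect_length(ann$clusters, 1)
  expect_equal(ann$clusters[[1]]$spip, 1.0, tolerance = 1e-12)
})

test_that("reader PIPs equal explicit membership sums on a 5-SNP toy", {
  models <- list(list(c("a"), 0.30), list(c("b"), 0.20),
                 list(c("a", "c"), 0.25), list(c("b", "c"), 0.10),
                 list(c("d"), 0.05), list(character(0), 0.10))
  lines <- c("gene g5 liver", vapply(models, function(m)
    paste("M", m[[2]], if (length(m[[1]])) paste(m[[1]], collapse = ",")
          else "."), character(1)))
  ann <- read_annotation(write_lines_tmp(lines))
  # oracle: direct membership sum over the listed models
  snps <- c("a", "b", "c", "d")
  oracle <- vapply(snps, function(s)
    sum(vapply(models, function(m)
      if (s %in% m[[1]]) m[[2]] else 0, numeric(1))), numeric(1))
  got <- setNames(ann$snps$pip, ann$snps$snp_id)[snps]
  expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
  # sum of SPIPs bounded by the expected number of signals
  exp_signals <- sum(vapply(models, function(m)
    m[[2]] * length(m[[1]]), numeric(1)))
  expect_lte(sum(vapply(ann$clusters, function(cl) cl$spip, numeric(1))),
             exp_signals + 1e-6)
})

test_that("malformed and duplicate annotation input is rejected", {
  f <- write_lines_tmp(c("gene g1 blood", "M 0.5 s1", "bogus line here x"))
  expect_error(read_annotation(f), "line 3")
  f <- write_lines_tmp(c("gene g1 blood", "M notanumber s1"))
  expect_error(read_annotation(f), "line 2")
  f <- write_lines_tmp(c("gene g1 blood", "M 0.5 s1",
                         "S s1 10 A G 0.5", "S s1 11 A G 0.5"))
  expect_error(read_annotation(f), "duplicate")
})

test_that("write/read round trip preserves retained fields", {
  G <- toy_genotypes(200, 25, rho = 0.7, seed = 5)
  x <- toy_expression(G, c(5, 18), c(1.2, -0.9), seed = 6)
  ann <- finemap(G, x, gene_id = "gX", tissue = "muscle")
  f <- withr::local_tempfile(fileext = ".txt")
  write_annotation(ann, f)
  ann2 <- read_annotation(f)
  expect_equal(ann2$gene_id, ann$gene_id)
  expect_equal(ann2$tissue, ann$tissue)
  expect_equal(ann2$snps$snp_id, ann$snps$snp_id)
  expect_equal(ann2$snps$pip, ann$snps$pip, tolerance = 1e-9)
  expect_equal(length(ann2$models), length(ann$models))
  expect_equal(vapply(ann2$models, function(m) m$posterior_prob,
                      numeric(1)),
               vapply(ann$models, function(m) m$posterior_prob,
                      numeric(1)), tolerance = 1e-9)
  expect_equal(lapply(ann2$clusters, function(cl) cl$member_snp_ids),
               lapply(ann$clusters, function(cl) cl$member_snp_ids))
})

test_that("clustering matches hand cases and the graph-component oracle", {
  # perfect proxies collapse into one cluster
  ld <- matrix(c(1, 1, 1, 1), 2, 2)
  cl <- build_clusters(c(0.5, 0.5), ld)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$spip, 1.0)
  # independent SNPs stay apart
  cl <- build_clusters(c(0.9, 0.9), diag(2))
  expect_length(cl, 2)
  expect_equal(vapply(cl, function(c) c$spip, numeric(1)), c(0.9, 0.9))

  # block-diagonal LD: clusters equal the r2-graph components
  set.seed(42)
  blk <- function(k, r) {
    m <- matrix(r, k, k); diag(m) <- 1; m
  }
  ld <- matrix(0, 10, 10)
  ld[1:5, 1:5] <- blk(5, 0.8)
  ld[6:10, 6:10] <- blk(5, 0.7)
  pips <- c(runif(5, 0.1, 0.2), runif(5, 0.05, 0.15))
  cl <- build_clusters(pips, ld, r2_min = 0.25, pip_floor = 0.01)
  oracle <- cluster_components(pips, ld, 0.25, 0.01)
  expect_length(cl, length(oracle))
  got <- lapply(cl, function(c) sort(match(c$member_snp_ids,
                                           paste0("snp", 1:10))))
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(lapply(oracle, sort), paste, collapse = ","))
})

test_that("clustering is invariant to SNP input order and drops low PIPs", {
  set.seed(9)
  G <- toy_genotypes(300, 12, rho = 0.8, seed = 9)
  ld <- cor(G)
  pips <- setNames(runif(12, 0.02, 0.9), colnames(G))
  cl1 <- build_clusters(pips, ld)
  perm <- sample(12)
  cl2 <- build_clusters(pips[perm], ld[perm, perm])
  key <- function(cl) sort(vapply(cl, function(c)
    paste(sort(c$member_snp_ids), collapse = ","), character(1)))
  expect_equal(key(cl1), key(cl2))

  pips["snp3"] <- 0.001
  cl3 <- build_clusters(pips, ld, pip_floor = 0.01)
  expect_false("snp3" %in% unlist(lapply(cl3, function(c)
    c$member_snp_ids)))
  expect_error(build_clusters(pips, ld[1:5, 1:5]), "correlation matrix")
})
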