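#' Probabilistic eQTL annotations
#'
#' A `gene_annotation` bundles the three levels of probabilistic eQTL
#' annotation produced by Bayesian multi-SNP fine-mapping of a gene's
#' cis-region:
#'
#' * candidate association models (SNP subsets) with posterior model
#'   probabilities,
#' * SNP-level posterior inclusion probabilities (PIPs), and
#' * signal clusters -- sets of SNPs in LD representing the same
#'   independent eQTL signal -- with signal-level PIPs (SPIPs, the sum of
#'   member PIPs).
#'
#' @param gene_id Gene identifier.
#' @param tissue Tissue label.
#' @param snps `data.frame` with columns `snp_id`, `position`,
#'   `effect_allele`, `other_allele`, `pip`.
#' @param models List of models; each a list with `snp_ids` (character,
#'   possibly empty for the null model) and `posterior_prob`.
#' @param clusters List of signal clusters from [build_clusters()] (may be
#'   empty).
#'
#' @return An object of class `gene_annotation`.
#' @seealso [read_annotation()], [write_annotation()], [build_clusters()],
#'   [finemap()]
#' @export
gene_annotation <- function(gene_id, tissue, snps, models, clusters = list()) {
  obj <- structure(
    list(gene_id = as.character(gene_id), tissue = as.character(tissue),
         snps = snps, models = models, clusters = clusters),
    class = "gene_annotation")
  validate_annotation(obj)
  obj
}

#' Validate a gene_annotation against its invariants
#'
#' Checks PIP ranges, uniqueness of SNP ids, total posterior model mass,
#' cluster disjointness and the SPIP = sum-of-member-PIPs identity.
#'
#' @param ann A `gene_annotation`.
#' @param tol Numerical tolerance for probability identities.
#' @return `ann`, invisibly; errors describe the violated invariant.
#' @export
validate_annotation <- function(ann, tol = 1e-8) {
  snps <- ann$snps
  stopifnot(is.data.frame(snps))
  need <- c("snp_id", "position", "effect_allele", "other_allele", "pip")
  if (!all(need %in% names(snps)))
    stop("snps table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(snps$snp_id))
    stop("duplicate SNP id in annotation: ",
         snps$snp_id[duplicated(snps$snp_id)][1])
  if (any(snps$pip < -tol | snps$pip > 1 + tol))
    stop("PIP outside [0,1]")
  pm <- vapply(ann$models, function(m) m$posterior_prob, numeric(1))
  if (length(pm) && (any(pm < -tol | pm > 1 + tol) || sum(pm) > 1 + 1e-6))
    stop("posterior model probabilities must lie in [0,1] and sum to <= 1")
  keys <- vapply(ann$models, function(m) {
    ids <- m$snp_ids
    paste(if (length(ids) > 1) sort(ids) else ids, collapse = ",")
  }, character(1))
  if (anyDuplicated(keys)) stop("duplicate association models")
  model_snps <- unique(unlist(lapply(ann$models, function(m) m$snp_ids)))
  if (!all(model_snps %in% snps$snp_id))
    stop("model references unknown SNP(s): ",
         paste(setdiff(model_snps, snps$snp_id), collapse = ","))
  memb <- unlist(lapply(ann$clusters, function(cl) cl$member_snp_ids))
  if (anyDuplicated(memb)) stop("signal clusters are not disjoint")
  if (!all(memb %in% snps$snp_id)) stop("cluster references unknown SNP(s)")
  pip <- stats::setNames(snps$pip, snps$snp_id)
  for (cl in ann$clusters)
    if (abs(cl$spip - sum(pip[cl$member_snp_ids])) > 1e-6)
      stop("cluster ", cl$cluster_id, ": SPIP != sum of member PIPs")
  invisible(ann)
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", x$gene_id, "[", x$tissue, "]\n")
  cat("  ", nrow(x$snps), "SNPs,", length(x$models), "models,",
      length(x$clusters), "signal clusters\n")
  if (length(x$clusters)) {
    spips <- vapply(x$clusters, function(cl) cl$spip, numeric(1))
    cat("  SPIPs:", paste(sprintf("%.3f", spips), collapse = " "), "\n")
  }
  invisible(x)
}

# PIP of each snp_id as the posterior mass of models containing it
pip_from_models <- function(models, snp_ids) {
  pip <- stats::setNames(numeric(length(snp_ids)), snp_ids)
  for (m in models)
    if (length(m$snp_ids))
      pip[m$snp_ids] <- pip[m$snp_ids] + m$posterior_prob
  pip
}

#' Group SNPs into independent eQTL signal clusters
#'
#' SNPs in strong LD that share posterior support represent the same
#' underlying causal eQTL and are grouped into a signal cluster whose
#' signal-level PIP (SPIP) is the sum of member PIPs. Clustering is greedy:
#' SNPs are visited in order of decreasing PIP; a SNP joins an existing
#' cluster when its r-squared with the cluster's seed SNP reaches `r2_min`,
#' otherwise it seeds a new cluster. SNPs with PIP below `pip_floor` are
#' left unclustered.
#'
#' @param pips Numeric vector of SNP PIPs (names used as SNP ids when
#'   present).
#' @param ld SNP-by-SNP correlation matrix (r, not r-squared), aligned to
#'   `pips`.
#' @param r2_min Minimum r-squared with a cluster seed for membership.
#' @param pip_floor SNPs below this PIP are excluded from clusters.
#' @return List of clusters, each a list with `cluster_id`,
#'   `member_snp_ids` (decreasing PIP) and `spip`.
#' @export
build_clusters <- function(pips, ld, r2_min = 0.25, pip_floor = 0.01) {
  p <- length(pips)
  if (!is.matrix(ld) || nrow(ld) != p || ncol(ld) != p)
    stop("ld must be a ", p, "x", p, " correlation matrix aligned to pips")
  ids <- names(pips)
  if (is.null(ids)) ids <- paste0("snp", seq_len(p))
  keep <- which(pips >= pip_floor)
  # order by decreasing PIP, ties broken by SNP id so that the result does
  # not depend on input ordering
  keep <- keep[order(-pips[keep], ids[keep])]
  seeds <- integer(0)
  assign <- list()
  for (j in keep) {
    placed <- FALSE
    for (s in seq_along(seeds)) {
      if (ld[j, seeds[s]]^2 >= r2_min) {
        assign[[s]] <- c(assign[[s]], j)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      seeds <- c(seeds, j)
      assign[[length(seeds)]] <- j
    }
  }
  lapply(seq_along(seeds), function(s) {
    members <- assign[[s]]
    list(cluster_id = s, member_snp_ids = ids[members],
         spip = sum(pips[members]))
  })
}

#' Read a probabilistic eQTL annotation file
#'
#' Parses the plain-text per-gene annotation dialect: a header line
#' `gene <id> <tissue>`; model lines `M <prob> <snp1,snp2,...>` (`.` for
#' the empty SNP list, i.e. the null model); optional SNP lines
#' `S <snp_id> <pos> <effect_allele> <other_allele> <pip>`; optional
#' cluster lines `C <cluster_id> <spip> <snp1,...>`.
#'
#' SNPs named in models but lacking an `S` line get their PIP computed as
#' the summed posterior probability of the models containing them
#' (position/alleles set to `NA`/`"N"`). When no `C` lines are present,
#' clusters are reconstructed from model co-occurrence: SNPs that never
#' appear together in a retained model are interchangeable explanations of
#' the same signal and are grouped; SNPs that co-occur represent distinct
#' signals.
#'
#' @param file Path to an annotation file.
#' @param pip_floor PIP threshold for cluster reconstruction (ignored when
#'   `C` lines are present).
#' @return A [gene_annotation()].
#' @export
read_annotation <- function(file, pip_floor = 0.01) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  gene_id <- tissue <- NULL
  models <- list()
  srec <- list()
  clusters <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    bad <- function() stop("malformed annotation line ", i, ": ", lines[i])
    if (f[1] == "gene") {
      if (length(f) != 3) bad()
      gene_id <- f[2]; tissue <- f[3]
    } else if (f[1] == "M") {
      if (length(f) != 3) bad()
      prob <- suppressWarnings(as.numeric(f[2]))
      if (is.na(prob)) bad()
      ids <- if (f[3] == ".") character(0) else strsplit(f[3], ",")[[1]]
      models[[length(models) + 1L]] <-
        list(snp_ids = ids, posterior_prob = prob)
    } else if (f[1] == "S") {
      if (length(f) != 6) bad()
      pip <- suppressWarnings(as.numeric(f[6]))
      pos <- suppressWarnings(as.integer(f[3]))
      if (is.na(pip)) bad()
      srec[[length(srec) + 1L]] <- data.frame(
        snp_id = f[2], position = pos, effect_allele = f[4],
        other_allele = f[5], pip = pip, stringsAsFactors = FALSE)
    } else if (f[1] == "C") {
      if (length(f) != 4) bad()
      cid <- suppressWarnings(as.integer(f[2]))
      spip <- suppressWarnings(as.numeric(f[3]))
      if (is.na(cid) || is.na(spip)) bad()
      clusters[[length(clusters) + 1L]] <- list(
        cluster_id = cid, member_snp_ids = strsplit(f[4], ",")[[1]],
        spip = spip)
    } else bad()
  }
  if (is.null(gene_id)) stop("annotation file lacks a 'gene' header line")
  snps <- if (length(srec)) do.call(rbind, srec) else
    data.frame(snp_id = character(0), position = integer(0),
               effect_allele = character(0), other_allele = character(0),
               pip = numeric(0), stringsAsFactors = FALSE)
  if (anyDuplicated(snps$snp_id))
    stop("duplicate SNP id in annotation: ",
         snps$snp_id[duplicated(snps$snp_id)][1])
  model_snps <- unique(unlist(lapply(models, function(m) m$snp_ids)))
  missing <- setdiff(model_snps, snps$snp_id)
  if (length(missing)) {
    pip <- pip_from_models(models, missing)
    snps <- rbind(snps, data.frame(
      snp_id = missing, position = NA_integer_, effect_allele = "N",
      other_allele = "N", pip = unname(pip), stringsAsFactors = FALSE))
  }
  if (!length(clusters) && length(model_snps))
    clusters <- clusters_from_models(models, snps, pip_floor)
  gene_annotation(gene_id, tissue, snps, models, clusters)
}

# Reconstruct signal clusters without LD: SNPs that never co-occur in a
# retained model are alternative explanations of one signal; co-occurring
# SNPs are distinct signals. Connected components of the "never co-occur"
# graph over SNPs with pip >= floor.
clusters_from_models <- function(models, snps, pip_floor = 0.01) {
  pip <- stats::setNames(snps$pip, snps$snp_id)
  cand <- snps$snp_id[snps$pip >= pip_floor]
  cand <- intersect(cand,
                    unique(unlist(lapply(models, function(m) m$snp_ids))))
  if (!length(cand)) return(list())
  n <- length(cand)
  co <- matrix(FALSE, n, n, dimnames = list(cand, cand))
  for (m in models) {
    ids <- intersect(m$snp_ids, cand)
    if (length(ids) > 1) co[ids, ids] <- TRUE
  }
  adj <- !co
  diag(adj) <- FALSE
  comp <- integer(n)
  cur <- 0L
  for (v in order(-pip[cand], cand)) {
    if (comp[v] > 0L) next
    cur <- cur + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (comp[u] > 0L) next
      comp[u] <- cur
      queue <- c(queue, which(adj[u, ] & comp == 0L))
    }
  }
  lapply(seq_len(cur), function(k) {
    members <- cand[comp == k]
    members <- members[order(-pip[members], members)]
    list(cluster_id = k, member_snp_ids = members,
         spip = sum(pip[members]))
  })
}

#' Write a probabilistic eQTL annotation file
#'
#' Emits the header, model (`M`), SNP (`S`) and cluster (`C`) sections of
#' the annotation dialect read by [read_annotation()].
#'
#' @param ann A [gene_annotation()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_annotation <- function(ann, file) {
  out <- c(paste("gene", ann$gene_id, ann$tissue),
           vapply(ann$models, function(m)
             paste("M", format(m$posterior_prob, digits = 12),
                   if (length(m$snp_ids)) paste(m$snp_ids, collapse = ",")
                   else "."),
             character(1)),
           vapply(seq_len(nrow(ann$snps)), function(i)
             paste("S", ann$snps$snp_id[i], ann$snps$position[i],
                   ann$snps$effect_allele[i], ann$snps$other_allele[i],
                   format(ann$snps$pip[i], digits = 12)),
             character(1)),
           vapply(ann$clusters, function(cl)
             paste("C", cl$cluster_id, format(cl$spip, digits = 12),
                   paste(cl$member_snp_ids, collapse = ",")),
             character(1)))
  writeLines(out, file)
  invisible(file)
}
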