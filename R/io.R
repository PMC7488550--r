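FORMAT_VERSION <- "ptwas/0.1"

#' Analysis run configuration
#'
#' @param spip_min Minimum signal-level PIP for a cluster to be used as
#'   an instrument (estimation and diagnosis).
#' @param i2_exclude Genes with I-squared above this are flagged and
#'   excluded from the estimate table.
#' @param fdr_level FDR level for scan rejection.
#' @param ld_regularization Shrinkage weight applied to reference LD in
#'   summary-statistic scans.
#' @param seed Seed recorded with the run.
#' @return A `run_config` list.
#' @export
run_config <- function(spip_min = 0.50, i2_exclude = 0.5,
                       fdr_level = 0.05, ld_regularization = 0.05,
                       seed = 1L) {
  stopifnot(spip_min >= 0, spip_min <= 1, i2_exclude >= 0,
            i2_exclude <= 1, fdr_level > 0, fdr_level < 1,
            ld_regularization >= 0, ld_regularization <= 1)
  structure(list(spip_min = spip_min, i2_exclude = i2_exclude,
                 fdr_level = fdr_level,
                 ld_regularization = ld_regularization,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read GWAS summary statistics
#'
#' TSV with header; required columns `snp_id`, `effect_allele`,
#' `other_allele`, and either `z` or both `beta` and `se` (then
#' `z = beta / se`). Optional column `n` (sample size).
#'
#' @param file Path to TSV.
#' @return `data.frame` with at least `snp_id`, `effect_allele`,
#'   `other_allele`, `z`.
#' @export
read_gwas_sumstats <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("snp_id", "effect_allele", "other_allele")
  if (!all(need %in% names(d)))
    stop("sumstats must have columns: ", paste(need, collapse = ", "))
  if (!"z" %in% names(d)) {
    if (!all(c("beta", "se") %in% names(d)))
      stop("sumstats need either a z column or beta and se columns")
    d$z <- d$beta / d$se
  }
  if (any(!is.finite(d$z))) stop("non-finite z in sumstats")
  if (any(!nzchar(d$effect_allele)) || any(!nzchar(d$other_allele)))
    stop("empty allele strings in sumstats")
  d
}

#' Read a dosage matrix
#'
#' TSV, SNPs in rows and samples in columns; first column `snp_id`,
#' remaining columns one per sample.
#'
#' @param file Path to TSV.
#' @return Numeric samples-by-SNPs matrix (transposed for analysis) with
#'   SNP column names.
#' @export
read_dosage <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "snp_id") stop("first dosage column must be snp_id")
  m <- t(as.matrix(d[, -1, drop = FALSE]))
  colnames(m) <- d$snp_id
  m
}

#' Write composite IV weights
#'
#' TSV with columns `gene`, `tissue`, `snp_id`, `effect_allele`,
#' `weight`, `genotype_sd`; only nonzero-weight SNPs are emitted.
#'
#' @param civ A [build_composite_iv()] result (effect alleles taken from
#'   `alleles` when given).
#' @param file Output path.
#' @param alleles Optional named character vector of effect alleles by
#'   SNP id.
#' @return `file`, invisibly.
#' @export
write_weights <- function(civ, file, alleles = NULL) {
  keep <- civ$weights != 0
  ea <- if (is.null(alleles)) rep("A", sum(keep)) else
    unname(alleles[civ$snp_ids[keep]])
  d <- data.frame(gene = civ$gene_id, tissue = civ$tissue,
                  snp_id = civ$snp_ids[keep], effect_allele = ea,
                  weight = civ$weights[keep],
                  genotype_sd = civ$genotype_sd[keep])
  writeLines(paste0("# ", FORMAT_VERSION, " weights"), file)
  suppressWarnings(utils::write.table(
    d, file, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(file)
}

#' Read a composite IV weight file
#'
#' @param file Path written by [write_weights()].
#' @return A `composite_iv` object.
#' @export
read_weights <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE, comment.char = "#")
  structure(list(gene_id = d$gene[1], tissue = d$tissue[1],
                 snp_ids = d$snp_id, weights = d$weight,
                 genotype_sd = d$genotype_sd),
            class = "composite_iv")
}

#' Harmonize GWAS summary statistics to annotation alleles
#'
#' Aligns GWAS z-scores to the effect alleles of the eQTL annotation:
#' matching alleles keep their sign, swapped alleles flip the sign,
#' strand-ambiguous SNPs (A/T, C/G) and SNPs with mismatching allele
#' pairs or missing from the summary statistics are dropped.
#'
#' @param sumstats `data.frame` from [read_gwas_sumstats()].
#' @param snps Annotation SNP table (`snp_id`, `effect_allele`,
#'   `other_allele`).
#' @return List: `z` (named vector aligned to the retained annotation
#'   SNPs) and `log` (counts: matched, flipped, ambiguous, mismatched,
#'   missing).
#' @export
harmonize_alleles <- function(sumstats, snps) {
  norm <- function(x) toupper(trimws(x))
  amb <- function(a, b) paste0(norm(a), norm(b)) %in% c("AT", "TA", "CG",
                                                        "GC")
  idx <- match(snps$snp_id, sumstats$snp_id)
  z <- rep(NA_real_, nrow(snps))
  status <- rep("missing", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    j <- idx[i]
    if (is.na(j)) next
    ea_a <- norm(snps$effect_allele[i]); oa_a <- norm(snps$other_allele[i])
    ea_g <- norm(sumstats$effect_allele[j])
    oa_g <- norm(sumstats$other_allele[j])
    if (amb(ea_a, oa_a)) { status[i] <- "ambiguous"; next }
    if (ea_g == ea_a && oa_g == oa_a) {
      z[i] <- sumstats$z[j]; status[i] <- "matched"
    } else if (ea_g == oa_a && oa_g == ea_a) {
      z[i] <- -sumstats$z[j]; status[i] <- "flipped"
    } else status[i] <- "mismatched"
  }
  keep <- !is.na(z)
  if (!any(keep)) stop("no SNPs could be harmonized between sumstats and ",
                       "annotation")
  n_amb <- sum(status == "ambiguous")
  n_mis <- sum(status == "mismatched")
  if (n_amb) warning(n_amb, " strand-ambiguous SNP(s) dropped")
  if (n_mis) warning(n_mis, " allele-mismatched SNP(s) dropped")
  list(z = stats::setNames(z[keep], snps$snp_id[keep]),
       log = c(matched = sum(status == "matched"),
               flipped = sum(status == "flipped"), ambiguous = n_amb,
               mismatched = n_mis, missing = sum(status == "missing")))
}

#' Run the summary-statistic analysis pipeline over genes
#'
#' Executes, per gene: allele harmonization, the composite-IV scan from
#' GWAS z-scores and reference LD, exclusion-restriction diagnosis, and
#' causal-effect estimation, in the staged order of the workflow: genes
#' failing the scan (p > `fdr_level` after Storey FDR across genes) are
#' not estimated; genes with I-squared above `i2_exclude` are flagged
#' and excluded from the estimate table (genes with a single eligible
#' instrument are estimated with I2 = 0 by convention).
#'
#' @param config A [run_config()].
#' @param genes List of per-gene inputs; each a list with `annotation`
#'   (a [gene_annotation()]), `civ` (a `composite_iv`), `sumstats`
#'   (GWAS summary `data.frame`), `ld` (reference correlation matrix
#'   with SNP dimnames covering the composite IV and cluster SNPs), and
#'   `eqtl_sumstats` (`data.frame` `snp_id`, `beta`, `se` of marginal
#'   eQTL effects; needed for estimation).
#' @return List of `data.frame`s: `scan`, `diagnosis`, `estimates`, plus
#'   `counts`, a named vector accounting for every gene
#'   (scanned / not_rejected / not_estimable / flagged / estimated).
#' @export
run_pipeline <- function(config, genes) {
  scan_rows <- vector("list", length(genes))
  details <- vector("list", length(genes))
  for (k in seq_along(genes)) {
    gi <- genes[[k]]
    res <- tryCatch({
      h <- harmonize_alleles(gi$sumstats, gi$annotation$snps)
      ids <- intersect(gi$civ$snp_ids, names(h$z))
      if (!length(ids)) stop("no harmonized SNP overlaps the composite IV")
      civ <- gi$civ
      keep <- match(ids, civ$snp_ids)
      civ$snp_ids <- civ$snp_ids[keep]
      civ$weights <- civ$weights[keep]
      civ$genotype_sd <- civ$genotype_sd[keep]
      ld <- gi$ld[ids, ids, drop = FALSE]
      scan <- scan_summary(civ, unname(h$z[ids]), ld,
                           lambda = config$ld_regularization)
      list(scan = scan, harmonized = h)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("gene ", gi$annotation$gene_id, ": scan failed: ",
              conditionMessage(res))
      details[[k]] <- list(failed = TRUE)
      scan_rows[[k]] <- data.frame(
        gene = gi$annotation$gene_id, tissue = gi$annotation$tissue,
        z = NA_real_, p_value = NA_real_, stringsAsFactors = FALSE)
    } else {
      details[[k]] <- res
      scan_rows[[k]] <- data.frame(
        gene = gi$annotation$gene_id, tissue = gi$annotation$tissue,
        z = res$scan$z, p_value = res$scan$p_value,
        stringsAsFactors = FALSE)
    }
  }
  scan_df <- do.call(rbind, scan_rows)
  pv <- ifelse(is.na(scan_df$p_value), 1, scan_df$p_value)
  scan_df$q_value <- storey_qvalues(pv)
  rejected <- !is.na(scan_df$p_value) & scan_df$q_value <= config$fdr_level

  diag_rows <- list()
  est_rows <- list()
  counts <- c(genes_in = length(genes), scanned = sum(!is.na(scan_df$z)),
              rejected = sum(rejected), not_estimable = 0L,
              flagged = 0L, estimated = 0L)
  for (k in seq_along(genes)) {
    if (!rejected[k]) next
    gi <- genes[[k]]
    ann <- gi$annotation
    ce <- tryCatch(
      cluster_estimates_from_sumstats(ann, gi$eqtl_sumstats,
                                      gi$sumstats, details[[k]]$harmonized),
      error = function(e) list())
    eff <- ivw_combine(ce, config$spip_min, gene_id = ann$gene_id,
                       tissue = ann$tissue)
    if (is.null(eff)) {
      counts["not_estimable"] <- counts["not_estimable"] + 1L
      next
    }
    het <- er_diagnose(ce, config$spip_min)
    flagged <- !is.null(het) && het$i2 > config$i2_exclude
    diag_rows[[length(diag_rows) + 1L]] <- data.frame(
      gene = ann$gene_id, tissue = ann$tissue,
      T = if (is.null(het)) 1L else het$t,
      Q = if (is.null(het)) 0 else het$q,
      I2 = if (is.null(het)) 0 else het$i2,
      flagged = flagged, stringsAsFactors = FALSE)
    if (flagged) {
      counts["flagged"] <- counts["flagged"] + 1L
      next
    }
    counts["estimated"] <- counts["estimated"] + 1L
    est_rows[[length(est_rows) + 1L]] <- data.frame(
      gene = ann$gene_id, tissue = ann$tissue, beta = eff$beta,
      se = eff$se, n_instruments = eff$n_instruments, Q = eff$q_stat,
      I2 = eff$i2,
      eligible_clusters = eff$n_instruments, stringsAsFactors = FALSE)
  }
  counts["not_rejected"] <- counts[["genes_in"]] - sum(rejected)
  list(scan = scan_df,
       diagnosis = if (length(diag_rows)) do.call(rbind, diag_rows) else
         NULL,
       estimates = if (length(est_rows)) do.call(rbind, est_rows) else
         NULL,
       counts = counts)
}

# Cluster-level estimates from summary statistics: Wald ratios for each
# cluster member using marginal eQTL beta/se and harmonized GWAS z
# converted back to beta/se on the eQTL-panel allele scale.
cluster_estimates_from_sumstats <- function(ann, eqtl_sumstats, sumstats,
                                            harmonized) {
  pips <- stats::setNames(ann$snps$pip, ann$snps$snp_id)
  es <- eqtl_sumstats
  rownames(es) <- es$snp_id
  gs <- sumstats
  rownames(gs) <- gs$snp_id
  hz <- harmonized$z
  out <- list()
  for (cl in ann$clusters) {
    ids <- cl$member_snp_ids
    ids <- ids[ids %in% rownames(es) & ids %in% names(hz)]
    ids <- ids[abs(es[ids, "beta"] / es[ids, "se"]) >= 1e-6]
    if (!length(ids)) next
    walds <- lapply(ids, function(s) {
      g <- gs[match(s, gs$snp_id), ]
      se_g <- if (!is.null(g$se) && is.finite(g$se)) g$se else
        1 / sqrt(max(g$n, 2))            # unit-variance trait scale
      snp_wald(hz[[s]] * se_g, se_g, es[s, "beta"], es[s, "se"],
               snp_id = s)
    })
    names(walds) <- ids
    cl2 <- list(cluster_id = cl$cluster_id, member_snp_ids = ids,
                spip = cl$spip)
    out[[length(out) + 1L]] <- cluster_estimate(cl2, walds, pips)
  }
  out
}

#' Write a tabular result with a format-version header
#'
#' @param d `data.frame`.
#' @param file Output path.
#' @param what Short table label recorded in the header line.
#' @return `file`, invisibly.
#' @export
write_table_versioned <- function(d, file, what = "table") {
  writeLines(paste0("# ", FORMAT_VERSION, " ", what), file)
  suppressWarnings(utils::write.table(
    d, file, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(file)
}
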