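#' Residualize relative expression on copy number and methylation
#'
#' Step one of the two-step association scan. For every gene i an OLS fit
#' `RT_i ~ intercept + SCNA_i + M_i` is computed; the stored residuals are
#' what the SNV scan operates on. Sequential (type-I) ANOVA sums of squares
#' give each determinant's variance fraction, and per-determinant F-test
#' p-values are Benjamini-Hochberg adjusted across genes.
#'
#' Genes whose SCNA or methylation vector is constant are fitted without
#' that term (flagged in the output); complete cases are used per gene.
#'
#' @param cohort a regression `multi_omics_cohort` (expression,
#'   methylation and scna aligned).
#' @param fdr FDR level used to flag determinant-regulated genes
#'   (default 0.05).
#' @return an object of class `residual_matrix`: list with `residuals`
#'   (gene x sample), `determinants` (per-gene data.frame: variance
#'   fractions, raw and BH-adjusted p per determinant, significance
#'   flags, degenerate-fit flag).
#' @export
residualize <- function(cohort, fdr = 0.05) {
  rt <- cohort$expression
  sc <- cohort$scna
  me <- cohort$methylation
  if (is.null(sc) || is.null(me))
    stop("residualize() needs the regression cohort (methylation + scna)")
  genes <- intersect(rownames(rt), intersect(rownames(sc), rownames(me)))
  n <- ncol(rt)
  if (n < 3) stop("fewer samples than regression parameters")

  res <- matrix(NA_real_, length(genes), n,
                dimnames = list(genes, colnames(rt)))
  det <- data.frame(
    gene = genes, frac_scna = 0, frac_meth = 0,
    p_scna = NA_real_, p_meth = NA_real_,
    degenerate = FALSE, stringsAsFactors = FALSE
  )
  for (g in seq_along(genes)) {
    y <- rt[genes[g], ]
    x1 <- sc[genes[g], ]
    x2 <- me[genes[g], ]
    ok <- is.finite(y) & is.finite(x1) & is.finite(x2)
    yv <- y[ok]; x1v <- x1[ok]; x2v <- x2[ok]
    use1 <- stats::sd(x1v) > 0
    use2 <- stats::sd(x2v) > 0
    if (length(yv) < 2 + use1 + use2)
      stop("fewer samples than parameters for gene ", genes[g])
    det$degenerate[g] <- !(use1 && use2)
    sst <- sum((yv - mean(yv))^2)
    ## sequential SS: SCNA first, then methylation
    r1 <- if (use1) stats::lm.fit(cbind(1, x1v), yv)$residuals
          else yv - mean(yv)
    ss_scna <- sst - sum(r1^2)
    r2 <- if (use2) stats::lm.fit(cbind(1, x1v * use1, x2v), yv)$residuals
          else r1
    ss_meth <- sum(r1^2) - sum(r2^2)
    res[g, ok] <- r2
    if (sst > 0) {
      det$frac_scna[g] <- ss_scna / sst
      det$frac_meth[g] <- ss_meth / sst
    }
    df_res <- length(yv) - 1L - use1 - use2
    ms_res <- sum(r2^2) / df_res
    if (use1 && ms_res > 0)
      det$p_scna[g] <- stats::pf(ss_scna / ms_res, 1, df_res,
                                 lower.tail = FALSE)
    if (use2 && ms_res > 0)
      det$p_meth[g] <- stats::pf(ss_meth / ms_res, 1, df_res,
                                 lower.tail = FALSE)
  }
  det$fdr_scna <- stats::p.adjust(det$p_scna, "BH")
  det$fdr_meth <- stats::p.adjust(det$p_meth, "BH")
  det$sig_scna <- !is.na(det$fdr_scna) & det$fdr_scna < fdr
  det$sig_meth <- !is.na(det$fdr_meth) & det$fdr_meth < fdr
  structure(list(residuals = res, determinants = det, fdr = fdr),
            class = "residual_matrix")
}

#' Scan all SNV-gene pairs on residual expression
#'
#' Step two: for every SNV j and gene i, a simple OLS of the gene's
#' residual expression on the binary mutation status, giving the effect
#' size beta, its Wald 95% confidence interval, the two-sided t-test
#' p-value and the variance explained (R^2). Significance is flagged by
#' Bonferroni at family size = number of pairs actually tested. SNVs with
#' fewer than `min_carriers` mutated or fewer than 2 wild-type samples are
#' skipped (recorded in the summary attribute).
#'
#' @param residual_matrix a `residual_matrix` from [residualize()], or a
#'   plain gene x sample numeric matrix of residuals.
#' @param mutation_matrix SNV x sample binary matrix (same samples).
#' @param alpha family-wise error level for the Bonferroni flag.
#' @param min_carriers minimum number of mutated samples per SNV.
#' @param family one of "global" (one Bonferroni family over all tested
#'   pairs, the default) or "per_gene".
#' @param conf_level confidence level of the Wald interval.
#' @return data.frame of class `esnv_scan` with columns snv_id, gene_id,
#'   beta, ci_low, ci_high, p, var_explained, p_bonf_sig; attributes
#'   `n_tested`, `n_skipped_snvs`.
#' @export
esnv_scan <- function(residual_matrix, mutation_matrix, alpha = 0.05,
                      min_carriers = 2, family = c("global", "per_gene"),
                      conf_level = 0.95) {
  family <- match.arg(family)
  eps <- if (inherits(residual_matrix, "residual_matrix"))
    residual_matrix$residuals else residual_matrix
  mm <- mutation_matrix
  if (!all(mm %in% c(0L, 1L))) stop("mutation matrix must be binary 0/1")
  common <- intersect(colnames(eps), colnames(mm))
  if (length(common) < 4) stop("too few shared samples for the scan")
  eps <- eps[, common, drop = FALSE]
  mm <- mm[, common, drop = FALSE]
  n <- length(common)

  carriers <- rowSums(mm)
  usable <- carriers >= min_carriers & (n - carriers) >= 2
  skipped <- rownames(mm)[!usable]
  mm <- mm[usable, , drop = FALSE]
  if (nrow(mm) == 0) stop("no SNV passes the carrier filter")

  ## vectorized per-SNV simple OLS across all genes
  yc <- eps - rowMeans(eps)           # center genes
  syy <- rowSums(yc^2)
  g_names <- rownames(eps)
  out <- vector("list", nrow(mm))
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
  for (j in seq_len(nrow(mm))) {
    x <- mm[j, ]
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    sxy <- as.vector(yc %*% xc)
    beta <- sxy / sxx
    rss <- pmax(syy - beta * sxy, 0)
    se <- sqrt(rss / (n - 2) / sxx)
    tstat <- ifelse(se > 0, beta / se, Inf * sign(beta))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    r2 <- ifelse(syy > 0, beta * sxy / syy, 0)
    out[[j]] <- data.frame(
      snv_id = rownames(mm)[j], gene_id = g_names,
      beta = beta, ci_low = beta - tcrit * se, ci_high = beta + tcrit * se,
      p = p, var_explained = r2, stringsAsFactors = FALSE
    )
  }
  assoc <- do.call(rbind, out)
  rownames(assoc) <- NULL
  n_tested <- nrow(assoc)
  if (family == "global") {
    assoc$p_bonf_sig <- assoc$p < alpha / n_tested
  } else {
    fam <- stats::ave(assoc$p, assoc$gene_id, FUN = length)
    assoc$p_bonf_sig <- assoc$p < alpha / fam
  }
  attr(assoc, "n_tested") <- n_tested
  attr(assoc, "n_skipped_snvs") <- length(skipped)
  attr(assoc, "skipped_snvs") <- skipped
  class(assoc) <- c("esnv_scan", "data.frame")
  assoc
}

#' Genomic-control inflation factor
#'
#' Converts two-sided p-values to 1-df chi-square quantiles and returns
#' the ratio of their median to the null median of the chi-square(1)
#' distribution (0.4549...). Values near 1 indicate calibrated tests; an
#' inflated lambda suggests confounding or relatedness.
#'
#' @param pvals vector of p-values in (0, 1].
#' @return lambda_GC, a positive scalar.
#' @export
genomic_inflation <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0) stop("empty p-value vector")
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Classify associations as cis- or trans-acting
#'
#' An association is cis when the SNV's position lies within the interval
#' (1-based inclusive, both boundaries) of the gene whose expression it is
#' associated with, on the same chromosome; otherwise trans. Genes with no
#' interval are classified trans with a warning.
#'
#' @param assoc an `esnv_scan` data.frame.
#' @param mutations per-SNV catalog with snv_id, chrom, pos.
#' @param gene_intervals data.frame (gene, chrom, start, end; 1-based).
#' @return `assoc` with an added logical `cis` column.
#' @export
classify_cis_trans <- function(assoc, mutations, gene_intervals) {
  mi <- match(assoc$snv_id, mutations$snv_id)
  gi <- match(assoc$gene_id, gene_intervals$gene)
  if (anyNA(gi))
    warning(sum(is.na(gi) & !duplicated(assoc$gene_id[is.na(gi)])),
            " gene(s) without interval classified trans")
  cis <- !is.na(gi) & !is.na(mi) &
    mutations$chrom[mi] == gene_intervals$chrom[gi] &
    mutations$pos[mi] >= gene_intervals$start[gi] &
    mutations$pos[mi] <= gene_intervals$end[gi]
  assoc$cis <- cis
  assoc
}

#' Summarize an association scan
#'
#' Counts tested and significant pairs, unique eSNVs and affected genes,
#' reports lambda_GC over all raw p-values, and the mean variance
#' explained separately over significant cis- and trans-acting
#' associations.
#'
#' @param assoc an `esnv_scan` data.frame with `cis` and `p_bonf_sig`.
#' @return list of class `scan_summary`.
#' @export
summarize_scan <- function(assoc) {
  sig <- assoc[assoc$p_bonf_sig, , drop = FALSE]
  n_tested <- attr(assoc, "n_tested")
  if (is.null(n_tested)) n_tested <- nrow(assoc)
  structure(list(
    n_pairs_tested = n_tested,
    n_significant = nrow(sig),
    pct_significant = if (n_tested > 0) 100 * nrow(sig) / n_tested else 0,
    lambda_gc = genomic_inflation(assoc$p),
    n_esnvs = length(unique(sig$snv_id)),
    n_genes_affected = length(unique(sig$gene_id)),
    mean_var_cis = if (any(sig$cis)) mean(sig$var_explained[sig$cis]) else 0,
    mean_var_trans = if (any(!sig$cis)) mean(sig$var_explained[!sig$cis]) else 0
  ), class = "scan_summary")
}

#' @export
print.scan_summary <- function(x, ...) {
  cat("eSNV association scan\n")
  cat(sprintf("  pairs tested:       %d\n", x$n_pairs_tested))
  cat(sprintf("  significant pairs:  %d (%.3f%%)\n", x$n_significant,
              x$pct_significant))
  cat(sprintf("  lambda_GC:          %.3f\n", x$lambda_gc))
  cat(sprintf("  eSNVs / genes:      %d / %d\n", x$n_esnvs,
              x$n_genes_affected))
  cat(sprintf("  mean R2 cis/trans:  %.3f / %.3f\n", x$mean_var_cis,
              x$mean_var_trans))
  invisible(x)
}

#' QQ-plot data for an association scan
#' @param pvals raw p-values.
#' @return data.frame with expected and observed -log10 p, sorted.
#' @export
qq_data <- function(pvals) {
  pvals <- sort(pvals[!is.na(pvals)])
  n <- length(pvals)
  data.frame(expected = -log10(stats::ppoints(n)),
             observed = -log10(pvals))
}

#' Write scan associations as TSV
#' @param assoc an `esnv_scan` data.frame.
#' @param path output file.
#' @export
write_associations <- function(assoc, path) {
  utils::write.table(format(as.data.frame(assoc), digits = 15, trim = TRUE,
                            scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
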