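#' Prognostic eSNV signatures by per-variant Cox regression
#'
#' For each eSNV, progression-free survival is regressed on carrier
#' status, both unadjusted and adjusted for clinical covariates; the
#' variant is selected when either fit gives p < `alpha`. Variants whose
#' fit is inestimable (no carrier, separation) are skipped and logged.
#'
#' @param mutation_matrix eSNV x sample binary matrix.
#' @param clinical clinical data.frame (sample, pfs_time, pfs_event plus
#'   adjustment columns).
#' @param adjust_covariates clinical columns to adjust for (default stage
#'   and histology).
#' @param alpha selection level (default 0.05).
#' @return list with `selected` (character vector of eSNV ids), `table`
#'   (per-eSNV p-values and HRs), `skipped`.
#' @export
prognostic_signatures <- function(mutation_matrix, clinical,
                                  adjust_covariates = c("stage", "histology"),
                                  alpha = 0.05) {
  cl <- clinical[match(colnames(mutation_matrix), clinical$sample), ,
                 drop = FALSE]
  skipped <- character(0)
  rows <- lapply(rownames(mutation_matrix), function(s) {
    carrier <- mutation_matrix[s, ]
    if (sum(carrier) < 1 || sum(carrier) == length(carrier)) {
      skipped <<- c(skipped, s)
      return(NULL)
    }
    ## per-variant fits on few carriers routinely fail to converge;
    ## those are skipped, so their warnings carry no information
    un <- tryCatch(
      suppressWarnings(cox_fit(cl$pfs_time, cl$pfs_event,
                               data.frame(carrier = carrier))),
      error = function(e) NULL)
    adj_df <- data.frame(carrier = carrier, cl[, adjust_covariates,
                                               drop = FALSE])
    ad <- tryCatch(suppressWarnings(cox_fit(cl$pfs_time, cl$pfs_event,
                                            adj_df)),
                   error = function(e) NULL)
    if (is.null(un) && is.null(ad)) {
      skipped <<- c(skipped, s)
      return(NULL)
    }
    data.frame(
      snv_id = s,
      hr = if (!is.null(un)) un$hr[1] else NA_real_,
      p_unadjusted = if (!is.null(un)) un$p[1] else NA_real_,
      p_adjusted = if (!is.null(ad)) ad$p[ad$term == "carrier"] else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  sel <- tab$snv_id[(!is.na(tab$p_unadjusted) & tab$p_unadjusted < alpha) |
                      (!is.na(tab$p_adjusted) & tab$p_adjusted < alpha)]
  list(selected = sel, table = tab, skipped = skipped)
}

#' Dichotomize patients by a signature set and compare survival
#'
#' Patients carrying at least one mutation among the signature eSNVs are
#' compared to carriers of none, via Cox regression and Kaplan-Meier
#' curves.
#'
#' @param mutation_matrix eSNV x sample binary matrix.
#' @param signature character vector of eSNV ids (nonempty).
#' @param clinical clinical data.frame (sample, pfs_time, pfs_event).
#' @return list with `groups` (named 0/1: 1 = carrier), `cox` (a
#'   `cox_fit`), `km` (from [km_curve()]).
#' @export
signature_dichotomize <- function(mutation_matrix, signature, clinical) {
  if (length(signature) == 0) stop("empty signature set")
  sig <- intersect(signature, rownames(mutation_matrix))
  grp <- as.integer(colSums(mutation_matrix[sig, , drop = FALSE]) > 0)
  names(grp) <- colnames(mutation_matrix)
  if (all(grp == 1) || all(grp == 0))
    stop("degenerate grouping: every patient falls in one group")
  cl <- clinical[match(names(grp), clinical$sample), , drop = FALSE]
  cox <- cox_fit(cl$pfs_time, cl$pfs_event, data.frame(mutated = grp))
  km <- km_curve(cl$pfs_time, cl$pfs_event,
                 ifelse(grp == 1, "mutated", "wild-type"))
  list(groups = grp, cox = cox, km = km)
}

#' Cluster-related eSNV signatures by Fisher's exact test
#'
#' Per eSNV, tests the carrier x cluster contingency table; variants with
#' p < `alpha` are selected. All-carrier and no-carrier variants are
#' skipped.
#'
#' @param mutation_matrix eSNV x sample binary matrix.
#' @param assignment a `cluster_assignment`.
#' @param alpha selection level (default 0.05).
#' @return list with `selected`, `table` (snv_id, p), `skipped`.
#' @export
cluster_signatures <- function(mutation_matrix, assignment, alpha = 0.05) {
  samples <- names(assignment$labels)
  mm <- mutation_matrix[, samples, drop = FALSE]
  labs <- assignment$labels
  skipped <- character(0)
  rows <- lapply(rownames(mm), function(s) {
    carrier <- mm[s, ]
    if (all(carrier == 0) || all(carrier == 1)) {
      skipped <<- c(skipped, s)
      return(NULL)
    }
    tab <- table(factor(carrier, levels = 0:1), labs)
    p <- stats::fisher.test(tab)$p.value
    data.frame(snv_id = s, p = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(selected = tab$snv_id[tab$p < alpha], table = tab, skipped = skipped)
}

#' Consensus clustering of eSNVs on their association coefficients
#'
#' Repeatedly subsamples the eSNVs, k-means-clusters their beta-coefficient
#' vectors (Euclidean distance), and accumulates a consensus matrix of
#' co-assignment frequencies among co-sampled pairs. Final consensus
#' clusters come from average-linkage hierarchical clustering of
#' `1 - consensus` cut at k.
#'
#' @param beta_matrix eSNV x gene matrix of scan beta coefficients
#'   (non-significant pairs as 0).
#' @param k number of consensus clusters (default 4).
#' @param subsample subsampling fraction (default 0.8).
#' @param iterations number of subsampled k-means runs (default 1000).
#' @param seed RNG seed.
#' @return list with `clusters` (named integer vector per eSNV) and
#'   `consensus` (symmetric matrix of co-assignment frequencies).
#' @export
consensus_cluster_esnvs <- function(beta_matrix, k = 4, subsample = 0.8,
                                    iterations = 1000, seed = 1) {
  x <- as.matrix(beta_matrix)
  n <- nrow(x)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of eSNVs")
  co <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  m <- max(k, floor(subsample * n))
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      idx <- sample.int(n, m)
      sub <- x[idx, , drop = FALSE]
      ## jitter-free k-means needs distinct centers; duplicates allowed in data
      km <- tryCatch(stats::kmeans(sub, centers = k, nstart = 1,
                                   iter.max = 30),
                     error = function(e) NULL)
      if (is.null(km)) next
      cnt[idx, idx] <- cnt[idx, idx] + 1
      for (c in seq_len(k)) {
        mem <- idx[km$cluster == c]
        co[mem, mem] <- co[mem, mem] + 1
      }
    }
  })
  cons <- ifelse(cnt > 0, co / cnt, 0)
  diag(cons) <- 1
  hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
  clusters <- stats::cutree(hc, k = k)
  names(clusters) <- rownames(x)
  dimnames(cons) <- list(rownames(x), rownames(x))
  list(clusters = clusters, consensus = cons)
}

#' Pairwise eSNV co-occurrence over associated-gene sets
#'
#' For each eSNV pair, a 2x2 table over the tested gene universe (gene
#' associated with a? with b?) is tested with Fisher's exact test;
#' p-values are Bonferroni-adjusted over all pairs. A pair is retained as
#' a co-occurrence when the adjusted p < `alpha`, the association is
#' positive (odds ratio > 1), the overlap is at least `min_overlap`
#' genes, and (when consensus clusters are supplied) both eSNVs share a
#' consensus cluster.
#'
#' @param gene_sets named list: eSNV id -> character vector of associated
#'   genes.
#' @param universe character vector, the gene universe of the scan.
#' @param consensus_clusters optional named integer vector per eSNV.
#' @param alpha significance level on Bonferroni-adjusted p (default 0.05).
#' @param min_overlap minimum shared associated genes (default 10).
#' @return data.frame of class `cooccurrence`: snv_a, snv_b, overlap,
#'   p, p_bonf, odds_ratio, same_consensus_cluster, retained.
#' @export
cooccurrence_scan <- function(gene_sets, universe,
                              consensus_clusters = NULL, alpha = 0.05,
                              min_overlap = 10) {
  ids <- names(gene_sets)
  if (length(ids) < 2) stop("need >= 2 eSNVs")
  if (length(universe) == 0) stop("empty gene universe")
  nu <- length(universe)
  sets <- lapply(gene_sets, function(g) intersect(g, universe))
  pairs <- utils::combn(length(ids), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(c) {
    i <- pairs[1, c]; j <- pairs[2, c]
    a <- sets[[i]]; b <- sets[[j]]
    both <- length(intersect(a, b))
    only_a <- length(a) - both
    only_b <- length(b) - both
    neither <- nu - both - only_a - only_b
    tab <- matrix(c(both, only_a, only_b, neither), 2)
    ft <- stats::fisher.test(tab)
    data.frame(snv_a = ids[i], snv_b = ids[j], overlap = both,
               p = ft$p.value, odds_ratio = unname(ft$estimate),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- pmin(out$p * nrow(out), 1)
  out$same_consensus_cluster <- if (is.null(consensus_clusters)) TRUE else
    consensus_clusters[out$snv_a] == consensus_clusters[out$snv_b]
  out$retained <- out$p_bonf < alpha & out$odds_ratio > 1 &
    out$overlap >= min_overlap & out$same_consensus_cluster
  class(out) <- c("cooccurrence", "data.frame")
  out
}

#' Screen genes for bimodal expression
#'
#' Expression values are floored at `floor_value` and log2-transformed;
#' per gene, one- and two-component Gaussian mixtures are fitted by EM and
#' the gene is called bimodal when the 2-component model wins by more than
#' `delta_bic` BIC units, both mixture weights are at least `min_weight`,
#' and the standardized mode separation is at least `min_separation`.
#' Samples are assigned to modes by posterior probability.
#'
#' @param expression gene x sample matrix of nonnegative raw abundances.
#' @param floor_value floor applied before log2 (default 0.1).
#' @param delta_bic required BIC margin for the 2-component model
#'   (default 10).
#' @param min_weight minimum component weight (default 0.1).
#' @param min_separation minimum `|mu1 - mu2| / sigma_pooled` (default 2).
#' @param seed RNG seed for EM initialization.
#' @return list with `bimodal_genes` and `modes` (gene -> named vector of
#'   mode labels, 1 = low mode, 2 = high mode).
#' @export
bimodality_screen <- function(expression, floor_value = 0.1, delta_bic = 10,
                              min_weight = 0.1, min_separation = 2,
                              seed = 1) {
  if (any(expression < 0)) stop("expression must be nonnegative")
  lg <- log2(pmax(expression, floor_value))
  bimodal <- character(0)
  modes <- list()
  with_seed(seed, {
    for (g in rownames(lg)) {
      y <- lg[g, ]
      if (stats::sd(y) == 0) next
      fit1 <- tryCatch(
        mclust::Mclust(y, G = 1, modelNames = "V", verbose = FALSE),
        error = function(e) NULL)
      fit2 <- tryCatch(
        mclust::Mclust(y, G = 2, modelNames = "V", verbose = FALSE),
        error = function(e) NULL)
      if (is.null(fit1) || is.null(fit2)) next
      ## mclust BIC: larger is better
      if (fit2$bic <= fit1$bic + delta_bic) next
      w <- fit2$parameters$pro
      mu <- fit2$parameters$mean
      sg <- sqrt(fit2$parameters$variance$sigmasq)
      if (length(sg) == 1) sg <- rep(sg, 2)
      pooled <- sqrt(sum(w * sg^2))
      if (min(w) < min_weight) next
      if (abs(diff(mu)) / pooled < min_separation) next
      lab <- fit2$classification
      ## label 1 = low mode, 2 = high mode
      if (mu[1] > mu[2]) lab <- 3L - lab
      names(lab) <- colnames(lg)
      bimodal <- c(bimodal, g)
      modes[[g]] <- lab
    }
  })
  list(bimodal_genes = bimodal, modes = modes)
}

#' BEEM test: mutation exclusivity with a bimodal expression mode
#'
#' Fisher's exact test of the carrier x mode 2x2 table for one bimodal
#' gene and one eSNV; a synthetic-lethality candidate pair is emitted when
#' p < `alpha`.
#'
#' @param mode_labels named vector of mode labels (1/2) for one bimodal
#'   gene, as from [bimodality_screen()].
#' @param carrier named binary vector of eSNV carrier status over the same
#'   samples.
#' @param alpha significance level (default 0.05).
#' @return one-row data.frame (p, n_carrier_low, n_carrier_high) when
#'   significant, else `NULL`.
#' @export
beem_test <- function(mode_labels, carrier, alpha = 0.05) {
  if (length(unique(mode_labels)) < 2)
    stop("single-mode assignment; gene should not have passed the screen")
  common <- intersect(names(mode_labels), names(carrier))
  ml <- mode_labels[common]
  cr <- carrier[common]
  tab <- table(factor(cr, levels = 0:1), factor(ml, levels = 1:2))
  p <- stats::fisher.test(tab)$p.value
  if (p >= alpha) return(NULL)
  data.frame(p = p, n_carrier_low = sum(cr == 1 & ml == 1),
             n_carrier_high = sum(cr == 1 & ml == 2))
}

#' Nominate synthetic-lethality pairs across all bimodal genes and eSNVs
#'
#' @param screen result of [bimodality_screen()].
#' @param mutation_matrix eSNV x sample binary matrix.
#' @param alpha per-pair significance level (default 0.05).
#' @return data.frame (snv_id, gene_id, p, n_carrier_low, n_carrier_high).
#' @export
sl_nominate <- function(screen, mutation_matrix, alpha = 0.05) {
  rows <- list()
  for (g in screen$bimodal_genes) {
    ml <- screen$modes[[g]]
    for (s in rownames(mutation_matrix)) {
      carrier <- mutation_matrix[s, ]
      if (sum(carrier) < 2) next
      r <- beem_test(ml, carrier, alpha)
      if (!is.null(r)) {
        r$snv_id <- s; r$gene_id <- g
        rows[[length(rows) + 1]] <- r
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(snv_id = character(0), gene_id = character(0),
                      p = numeric(0), n_carrier_low = integer(0),
                      n_carrier_high = integer(0)))
  out <- do.call(rbind, rows)
  out[, c("snv_id", "gene_id", "p", "n_carrier_low", "n_carrier_high")]
}

#' Score eSNVs on seven evidence criteria
#'
#' The criteria, one boolean each: (1) missense variant; (2) nonsense
#' variant; (3) cis-acting; (4) prognostic signature; (5) cluster-related
#' signature; (6) member of at least one retained co-occurrence pair; (7)
#' synthetic-lethality nomination. The score is the criterion count and
#' the risk flag marks scores >= `risk_cutoff`. A phi-correlation matrix
#' of the criteria with pairwise significance (chi-square, p < 0.01) is
#' attached.
#'
#' @param esnv_ids character vector of the eSNVs to score.
#' @param mutations per-SNV catalog (snv_id, mutation_type).
#' @param cis_esnvs eSNVs classified cis-acting.
#' @param prognostic,cluster_related,sl_esnvs eSNV id vectors from the
#'   evidence layers (missing layers may be passed as `character(0)`).
#' @param cooccurrence a `cooccurrence` data.frame (or `NULL`).
#' @param risk_cutoff minimum score for the risk flag (default 2).
#' @return data.frame of class `esnv_evidence` (snv_id, c1..c7, score,
#'   risk) with attributes `phi` and `phi_significant`.
#' @export
score_esnvs <- function(esnv_ids, mutations, cis_esnvs = character(0),
                        prognostic = character(0),
                        cluster_related = character(0),
                        cooccurrence = NULL, sl_esnvs = character(0),
                        risk_cutoff = 2) {
  missing_ids <- setdiff(esnv_ids, mutations$snv_id)
  if (length(missing_ids) > 0)
    stop("eSNV absent from annotation: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  mtype <- mutations$mutation_type[match(esnv_ids, mutations$snv_id)]
  co_members <- if (!is.null(cooccurrence)) {
    unique(c(cooccurrence$snv_a[cooccurrence$retained],
             cooccurrence$snv_b[cooccurrence$retained]))
  } else character(0)
  ev <- data.frame(
    snv_id = esnv_ids,
    c1_missense = mtype == "missense",
    c2_nonsense = mtype == "nonsense",
    c3_cis = esnv_ids %in% cis_esnvs,
    c4_prognostic = esnv_ids %in% prognostic,
    c5_cluster = esnv_ids %in% cluster_related,
    c6_cooccurrence = esnv_ids %in% co_members,
    c7_sl = esnv_ids %in% sl_esnvs,
    stringsAsFactors = FALSE
  )
  crit <- as.matrix(ev[, -1]) * 1L
  ev$score <- rowSums(crit)
  ev$risk <- ev$score >= risk_cutoff
  ## phi correlation of the criteria columns
  phi <- suppressWarnings(stats::cor(crit))
  phi[is.na(phi)] <- 0
  diag(phi) <- 1
  n <- nrow(crit)
  phi_p <- stats::pchisq(n * phi^2, df = 1, lower.tail = FALSE)
  attr(ev, "phi") <- phi
  attr(ev, "phi_significant") <- phi_p < 0.01
  class(ev) <- c("esnv_evidence", "data.frame")
  ev
}

#' Phi correlation coefficient of two binary vectors
#' @param a,b binary vectors.
#' @return phi in `[-1, 1]`.
#' @export
phi_coefficient <- function(a, b) {
  v <- stats::cor(as.numeric(a), as.numeric(b))
  if (is.na(v)) 0 else v
}
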