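#' Build a gene network from an edge list
#'
#' @param edges data.frame with columns `source`, `target` (gene symbols);
#'   self-loops are dropped.
#' @return object of class `gene_network`: list with `nodes` and the
#'   column-normalized adjacency (transition) matrix.
#' @export
gene_network <- function(edges) {
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  nodes <- sort(unique(c(edges$source, edges$target)))
  if (length(nodes) == 0) stop("empty network")
  a <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  a[cbind(match(edges$source, nodes), match(edges$target, nodes))] <- 1
  ## impact flows upstream: a regulator collects score from the targets it
  ## perturbs, so each target's mass is split among its in-neighbors
  cs <- colSums(a)
  cs[cs == 0] <- 1
  tr <- sweep(a, 2, cs, "/")
  structure(list(nodes = nodes, transition = tr), class = "gene_network")
}

#' Deterministic toy gene network generator
#'
#' A small-world-ish directed network for tests: genes on a ring with
#' forward edges plus seeded random chords.
#'
#' @param genes character vector of node symbols.
#' @param n_chords number of extra random edges.
#' @param seed RNG seed.
#' @return a `gene_network`.
#' @export
toy_network <- function(genes, n_chords = 2L * length(genes), seed = 1) {
  n <- length(genes)
  ring <- data.frame(source = genes, target = genes[c(2:n, 1)],
                     stringsAsFactors = FALSE)
  chords <- with_seed(seed, data.frame(
    source = sample(genes, n_chords, replace = TRUE),
    target = sample(genes, n_chords, replace = TRUE),
    stringsAsFactors = FALSE))
  gene_network(unique(rbind(ring, chords)))
}

#' Rank a patient's mutated genes by network impact
#'
#' Personalized propagation: node scores iterate
#' `r <- (1 - d) * f + d * T r`, where `f` is the patient's differential
#' expression magnitude normalized to sum 1 and `T` the column-normalized
#' adjacency, until the max-norm change drops below `tol`. The patient's
#' mutated genes are then extracted and ranked by score. Genes carrying
#' high scores perturb many differentially expressed neighbors — the
#' propagation principle used to separate drivers from passengers.
#'
#' @param diff_expr named nonnegative vector of differential-expression
#'   magnitudes for this patient.
#' @param mutated_genes character vector of the patient's mutated genes.
#' @param network a `gene_network`.
#' @param damping damping factor in `[0, 1)` (default 0.85).
#' @param tol convergence tolerance (default 1e-9).
#' @param max_iter iteration cap.
#' @return object of class `patient_ranking`: data.frame (gene, score)
#'   sorted by nonincreasing score, plus attributes.
#' @export
rank_patient <- function(diff_expr, mutated_genes, network, damping = 0.85,
                         tol = 1e-9, max_iter = 1000L) {
  if (any(diff_expr < 0)) stop("diff_expr must be nonnegative")
  nodes <- network$nodes
  f <- diff_expr[nodes]
  f[is.na(f)] <- 0
  if (sum(f) > 0) f <- f / sum(f) else f <- rep(1 / length(nodes), length(nodes))
  r <- f
  for (it in seq_len(max_iter)) {
    r_new <- (1 - damping) * f + damping * as.vector(network$transition %*% r)
    delta <- max(abs(r_new - r))
    r <- r_new
    if (delta < tol) break
  }
  if (delta >= tol)
    stop("propagation did not converge; last delta = ", format(delta))
  names(r) <- nodes
  mg <- intersect(mutated_genes, nodes)
  if (length(mg) == 0) {
    warning("no mutated gene present in the network")
    ranking <- data.frame(gene = character(0), score = numeric(0))
  } else {
    ranking <- data.frame(gene = mg, score = unname(r[mg]),
                          stringsAsFactors = FALSE)
    ranking <- ranking[order(-ranking$score, ranking$gene), , drop = FALSE]
    rownames(ranking) <- NULL
  }
  structure(ranking, iterations = it, scores = r,
            class = c("patient_ranking", "data.frame"))
}

#' Split a patient's ranked genes into drivers and passengers
#'
#' Chooses the cutpoint maximizing the standardized two-sample rank
#' statistic between the genes above and below it, with candidate
#' cutpoints restricted to the central quantile window
#' `[1 - quantile_bound, quantile_bound]` of the score order statistics.
#' Genes above the selected cutpoint are flagged drivers.
#'
#' @param ranking a `patient_ranking` (>= 5 genes required).
#' @param quantile_bound upper quantile bound of the candidate window
#'   (default 0.95).
#' @return the ranking with added `driver` flag column and attributes
#'   `cutpoint` (score threshold) and `statistic`.
#' @export
maxstat_split <- function(ranking, quantile_bound = 0.95) {
  scores <- ranking$score
  n <- length(scores)
  if (n < 5) stop("too few ranked genes (need >= 5)")
  if (length(unique(scores)) == 1L) {
    warning("all scores equal; no split")
    ranking$driver <- FALSE
    attr(ranking, "cutpoint") <- NA_real_
    return(ranking)
  }
  rk <- rank(scores)
  ord <- order(scores)
  stats_at <- rep(NA_real_, n - 1)
  lo <- max(1L, floor(n * (1 - quantile_bound)))
  hi <- min(n - 1L, ceiling(n * quantile_bound))
  for (m in lo:hi) {  # m = size of the low group
    low_idx <- ord[seq_len(m)]
    if (scores[ord[m]] == scores[ord[m + 1]]) next  # not a valid cutpoint
    s <- sum(rk[low_idx])
    e <- m * (n + 1) / 2
    v <- m * (n - m) * (n + 1) / 12
    ## tie correction
    ties <- table(rk)
    if (any(ties > 1)) {
      v <- m * (n - m) / (12 * n * (n - 1)) *
        (n^3 - n - sum(ties^3 - ties))
    }
    if (v > 0) stats_at[m] <- abs(s - e) / sqrt(v)
  }
  if (all(is.na(stats_at))) {
    warning("no admissible cutpoint; no split")
    ranking$driver <- FALSE
    attr(ranking, "cutpoint") <- NA_real_
    return(ranking)
  }
  m_best <- which.max(stats_at)
  cut <- mean(c(scores[ord[m_best]], scores[ord[m_best + 1]]))
  ranking$driver <- ranking$score > cut
  attr(ranking, "cutpoint") <- cut
  attr(ranking, "statistic") <- stats_at[m_best]
  ranking
}

#' Union of per-patient driver genes with a known-driver list
#'
#' @param rankings list of `patient_ranking` objects carrying `driver`
#'   flags (as from [maxstat_split()]).
#' @param known_drivers character vector of predefined driver genes.
#' @return sorted character vector of driver genes.
#' @export
build_driver_gene_list <- function(rankings, known_drivers = character(0)) {
  from_rank <- unlist(lapply(rankings, function(r) r$gene[r$driver]))
  sort(unique(c(from_rank, known_drivers)))
}

#' Restrict significant associations to driver loci
#'
#' Keeps significant eSNVs whose locus gene belongs to the driver list and
#' reports the count quadruple (driver eSNVs, mapped loci, correlated
#' genes, significant pairs).
#'
#' @param assoc an `esnv_scan` data.frame with `p_bonf_sig` flags.
#' @param mutations per-SNV catalog with snv_id and gene_locus.
#' @param driver_genes character vector of driver genes.
#' @return list with `assoc` (the retained significant associations) and
#'   `counts` (n_esnvs, n_loci, n_genes, n_pairs).
#' @export
prioritize_esnvs <- function(assoc, mutations, driver_genes) {
  sig <- assoc[assoc$p_bonf_sig, , drop = FALSE]
  locus <- mutations$gene_locus[match(sig$snv_id, mutations$snv_id)]
  keep <- !is.na(locus) & locus %in% driver_genes
  out <- sig[keep, , drop = FALSE]
  loci <- locus[keep]
  list(
    assoc = out,
    counts = list(
      n_esnvs = length(unique(out$snv_id)),
      n_loci = length(unique(loci)),
      n_genes = length(unique(out$gene_id)),
      n_pairs = nrow(out)
    )
  )
}

#' Test driver burden against clinical categories
#'
#' Kruskal-Wallis rank-sum test of per-patient driver counts across the
#' categories of each clinical variable, followed by pairwise Wilcoxon
#' rank-sum tests with Bonferroni adjustment. Categories with fewer than 2
#' patients are excluded with a warning.
#'
#' @param driver_counts named integer vector (per patient).
#' @param clinical clinical data.frame with `sample` plus the variables.
#' @param variables clinical columns to test.
#' @return named list per variable: `kruskal_p`, `pairwise` (matrix of
#'   Bonferroni-adjusted Wilcoxon p-values).
#' @export
driver_burden_tests <- function(driver_counts, clinical,
                                variables = c("stage", "histology", "grade")) {
  out <- list()
  cl <- clinical[match(names(driver_counts), clinical$sample), , drop = FALSE]
  for (v in variables) {
    grp <- factor(cl[[v]])
    sizes <- table(grp)
    small <- names(sizes)[sizes < 2]
    if (length(small) > 0) {
      warning("excluding category with < 2 patients in ", v, ": ",
              paste(small, collapse = ", "))
      keep <- !(grp %in% small)
    } else keep <- rep(TRUE, length(grp))
    g <- droplevels(grp[keep])
    x <- driver_counts[keep]
    if (nlevels(g) < 2) next
    kw <- stats::kruskal.test(x, g)
    pw <- stats::pairwise.wilcox.test(x, g, p.adjust.method = "bonferroni",
                                      exact = FALSE)
    out[[v]] <- list(kruskal_p = kw$p.value, pairwise = pw$p.value)
  }
  out
}

#' Mutation-type composition by transcription-factor annotation
#'
#' Relative frequencies of mutation types in the full eSNV set and in the
#' TF-related / non-TF-related strata (by locus gene membership in
#' `tf_genes`), the multiple of change of each stratum versus the full
#' set, and a per-type hypergeometric comparison of the strata.
#'
#' @param mutations per-SNV catalog restricted to the eSNVs of interest
#'   (snv_id, gene_locus, mutation_type).
#' @param tf_genes character vector of transcription-function-related
#'   genes.
#' @return data.frame per (stratum, type): count, freq, mc, hyper_p; with
#'   attribute `empty_tf` if the TF stratum is empty.
#' @export
mutation_type_composition <- function(mutations, tf_genes) {
  unknown <- setdiff(unique(mutations$mutation_type), MUTATION_TYPES)
  if (length(unknown) > 0)
    stop("unknown mutation type(s): ", paste(unknown, collapse = ", "))
  is_tf <- mutations$gene_locus %in% tf_genes
  strata <- list(all = rep(TRUE, nrow(mutations)), tf = is_tf,
                 non_tf = !is_tf)
  n_all <- nrow(mutations)
  tab_all <- table(factor(mutations$mutation_type, levels = MUTATION_TYPES))
  rows <- lapply(names(strata), function(s) {
    sel <- strata[[s]]
    tab <- table(factor(mutations$mutation_type[sel],
                        levels = MUTATION_TYPES))
    freq <- if (sum(sel) > 0) as.numeric(tab) / sum(sel) else rep(0, length(tab))
    freq_all <- as.numeric(tab_all) / n_all
    mc <- ifelse(freq_all > 0, freq / freq_all, NA_real_)
    ## upper-tail hypergeometric: enrichment of type in stratum vs all
    hp <- vapply(seq_along(tab), function(i) {
      stats::phyper(as.numeric(tab[i]) - 1, as.numeric(tab_all[i]),
                    n_all - as.numeric(tab_all[i]), sum(sel),
                    lower.tail = FALSE)
    }, numeric(1))
    data.frame(stratum = s, mutation_type = MUTATION_TYPES,
               count = as.integer(tab), freq = freq, mc = mc, hyper_p = hp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "empty_tf") <- !any(is_tf)
  out
}
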