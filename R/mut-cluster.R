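#' Spherical k-means clustering of mutation profiles
#'
#' Clusters samples by the direction of their binary mutation vectors:
#' rows are L2-normalized, assignment maximizes cosine similarity to the
#' current centroids, and centroids are updated as the normalized mean of
#' their members, until assignments are stable. The best of `n_restarts`
#' random initializations (by total cosine objective) is returned. Samples
#' with no mutation across the panel have no direction and are held out,
#' reported in `unclustered`.
#'
#' @param mutation_matrix sample x eSNV binary matrix (samples in rows).
#' @param k number of clusters (default 3).
#' @param seed RNG seed controlling the restarts.
#' @param n_restarts number of random initializations (default 20).
#' @param max_iter iteration cap per restart.
#' @return object of class `cluster_assignment`: list with `labels`
#'   (named integer vector in 1..k), `centroids` (k x eSNV, unit rows),
#'   `objective`, `k`, `seed`, `unclustered`.
#' @export
spherical_kmeans <- function(mutation_matrix, k = 3, seed = 1,
                             n_restarts = 20, max_iter = 100) {
  x <- as.matrix(mutation_matrix)
  norms <- sqrt(rowSums(x^2))
  unclustered <- rownames(x)[norms == 0]
  x <- x[norms > 0, , drop = FALSE]
  xn <- x / sqrt(rowSums(x^2))
  n <- nrow(xn)
  n_distinct <- nrow(unique(xn))
  if (k > n_distinct)
    stop("k exceeds the number of distinct nonzero mutation profiles (",
         n_distinct, ")")

  run_once <- function() {
    cent <- xn[sample.int(n, k), , drop = FALSE]
    lab <- rep(0L, n)
    for (it in seq_len(max_iter)) {
      sim <- xn %*% t(cent)                       # cosine similarity
      new_lab <- max.col(sim, ties.method = "first")
      if (all(new_lab == lab)) break
      lab <- new_lab
      for (c in seq_len(k)) {
        mem <- lab == c
        if (!any(mem)) next                        # empty cluster kept as-is
        v <- colMeans(xn[mem, , drop = FALSE])
        nv <- sqrt(sum(v^2))
        if (nv > 0) cent[c, ] <- v / nv
      }
    }
    obj <- sum(sim[cbind(seq_len(n), lab)])
    list(labels = lab, centroids = cent, objective = obj)
  }
  best <- with_seed(seed, {
    b <- NULL
    for (r in seq_len(n_restarts)) {
      cur <- run_once()
      if (is.null(b) || cur$objective > b$objective) b <- cur
    }
    b
  })
  labels <- best$labels
  names(labels) <- rownames(xn)
  structure(list(labels = labels, centroids = best$centroids,
                 objective = best$objective, k = k, seed = seed,
                 unclustered = unclustered),
            class = "cluster_assignment")
}

#' Test cluster-clinical associations
#'
#' Fisher's exact test of the cluster x category contingency table for
#' each clinical variable. Small tables are tested exactly; larger ones by
#' Monte-Carlo simulation with a fixed seed (method recorded). Variables
#' with a single category, or tables with a zero margin, are skipped with
#' a warning.
#'
#' @param assignment a `cluster_assignment`.
#' @param clinical clinical data.frame with `sample` plus the variables.
#' @param variables columns of `clinical` to test.
#' @param mc_cells table-cell-count threshold above which the Monte-Carlo
#'   approximation is used.
#' @param mc_b number of Monte-Carlo draws (default 1e5).
#' @param seed seed for the Monte-Carlo method.
#' @return named list per variable: `table`, `p`, `method`.
#' @export
cluster_clinical_tests <- function(assignment, clinical,
                                   variables = c("stage", "histology", "grade"),
                                   mc_cells = 2e6, mc_b = 1e5, seed = 1) {
  cl <- clinical[match(names(assignment$labels), clinical$sample), ,
                 drop = FALSE]
  out <- list()
  for (v in variables) {
    grp <- factor(cl[[v]])
    if (nlevels(grp) < 2) {
      warning("variable ", v, " has a single category; skipped")
      next
    }
    tab <- table(cluster = assignment$labels, category = grp)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warning("zero margin in ", v, " table; test skipped")
      out[[v]] <- list(table = tab, p = NA_real_, method = "skipped")
      next
    }
    big <- prod(dim(tab)) > 6 * 4 || sum(tab) * prod(dim(tab)) > mc_cells
    ft <- if (big) {
      with_seed(seed, stats::fisher.test(tab, simulate.p.value = TRUE,
                                         B = mc_b))
    } else {
      tryCatch(stats::fisher.test(tab, workspace = 2e7),
               error = function(e) with_seed(seed,
                 stats::fisher.test(tab, simulate.p.value = TRUE, B = mc_b)))
    }
    method <- if (grepl("simulated", ft$method)) "monte-carlo" else "exact"
    out[[v]] <- list(table = tab, p = ft$p.value, method = method)
  }
  out
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant agreement between two clusterings (1 = identical
#' up to relabeling, ~0 = chance).
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
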