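test_that("prognostic signatures recover implanted hazards and calibrate", {
  g <- default_cohort()
  co <- g$cohort
  mm <- co$mutation_matrix
  out <- prognostic_signatures(mm, co$clinical)
  ## implanted HR=3 variants are selected
  expect_true(all(g$truth$prognostic_snvs$snv_id %in% out$selected))
  ## carrier-free variant skipped
  mm2 <- rbind(mm, "9:999999" = rep(0L, ncol(mm)))
  out2 <- prognostic_signatures(mm2["9:999999", , drop = FALSE], co$clinical)
  expect_identical(out2$skipped, "9:999999")
})

test_that("null variants are selected at about the nominal rate", {
  g <- null_cohort()
  out <- prognostic_signatures(g$cohort$mutation_matrix, g$cohort$clinical,
                               adjust_covariates = character(0))
  rate <- length(out$selected) / nrow(out$table)
  expect_lt(rate, 0.15)
})

test_that("signature dichotomization builds the two-group comparison", {
  g <- default_cohort()
  co <- g$cohort
  sig <- g$truth$prognostic_snvs$snv_id
  out <- signature_dichotomize(co$mutation_matrix, sig, co$clinical)
  expect_gt(out$cox$hr, 1)
  expect_lt(out$cox$p, 0.05)
  ## removing a never-mutated eSNV leaves the grouping unchanged
  mm2 <- rbind(co$mutation_matrix, "9:999999" = rep(0L, ncol(co$mutation_matrix)))
  out2 <- signature_dichotomize(mm2, c(sig, "9:999999"), co$clinical)
  expect_identical(out$groups, out2$groups)
  ## degenerate grouping errors
  allmut <- matrix(1L, 1, ncol(co$mutation_matrix),
                   dimnames = list("1:1", colnames(co$mutation_matrix)))
  expect_error(signature_dichotomize(allmut, "1:1", co$clinical),
               "degenerate")
  expect_error(signature_dichotomize(co$mutation_matrix, character(0),
                                     co$clinical), "empty")
})

test_that("cluster signatures flag cluster-exclusive variants only", {
  labels <- rep(1:3, each = 50)
  names(labels) <- sprintf("S%03d", 1:150)
  asg <- structure(list(labels = labels), class = "cluster_assignment")
  mm <- rbind(
    excl = c(rep(1L, 10), rep(0L, 140)),          # only in cluster 1
    unif = rep(c(1L, 0L, 0L, 0L, 0L), 30),        # uniform carriers
    none = rep(0L, 150))
  colnames(mm) <- names(labels)
  out <- cluster_signatures(mm, asg)
  expect_true("excl" %in% out$selected)
  expect_false("unif" %in% out$selected)
  expect_identical(out$skipped, "none")
  ## oracle check of the exclusive pattern (2x3 table collapses to 2x2 vs rest)
  p <- fisher.test(table(mm["excl", ], labels))$p.value
  expect_lt(p, 0.001)
})

test_that("co-occurrence requires significance, direction, overlap and cluster", {
  universe <- sprintf("g%03d", 1:100)
  shared <- universe[1:20]
  sets <- list(a = shared, b = shared,                  # identical, size 20
               c = universe[21:40],                     # disjoint from a/b
               d = c(shared[1:9], universe[41:52]))     # overlap 9 with a
  out <- cooccurrence_scan(sets, universe, min_overlap = 10)
  ab <- out[out$snv_a == "a" & out$snv_b == "b", ]
  expect_true(ab$retained)
  expect_equal(ab$overlap, 20L)
  expect_lt(ab$p_bonf, 1e-10)
  ac <- out[out$snv_a == "a" & out$snv_b == "c", ]
  expect_false(ac$retained)  # disjoint: no positive association
  ad <- out[out$snv_a == "a" & out$snv_b == "d", ]
  expect_false(ad$retained)  # overlap 9 < 10 rule
  expect_equal(ad$overlap, 9L)
  ## consensus-cluster filter
  cc <- c(a = 1L, b = 2L, c = 1L, d = 1L)
  out2 <- cooccurrence_scan(sets, universe, consensus_clusters = cc,
                            min_overlap = 10)
  expect_false(out2$retained[out2$snv_a == "a" & out2$snv_b == "b"])
  expect_error(cooccurrence_scan(sets["a"], universe), ">= 2")
  expect_error(cooccurrence_scan(sets, character(0)), "universe")
})

test_that("co-occurrence Fisher p matches the hypergeometric tail oracle", {
  set.seed(17)
  universe <- sprintf("g%03d", 1:80)
  for (i in 1:50) {
    na <- sample(5:40, 1); nb <- sample(5:40, 1)
    a <- sample(universe, na); b <- sample(universe, nb)
    out <- cooccurrence_scan(list(x = a, y = b), universe, min_overlap = 0)
    tab <- matrix(c(length(intersect(a, b)),
                    na - length(intersect(a, b)),
                    nb - length(intersect(a, b)),
                    80 - length(union(a, b))), 2)
    expect_equal(out$p, fisher_oracle_2x2(tab), tolerance = 1e-9)
  }
})

test_that("consensus clustering recovers block structure", {
  set.seed(3)
  b1 <- matrix(rnorm(10 * 6, 5), 10, 6)
  b2 <- matrix(rnorm(10 * 6, -5), 10, 6)
  x <- rbind(b1, b2)
  rownames(x) <- paste0("e", 1:20)
  out <- consensus_cluster_esnvs(x, k = 2, iterations = 100, seed = 2)
  expect_gte(adjusted_rand_index(out$clusters, rep(1:2, each = 10)), 0.99)
  ## blockwise consensus near 0/1
  expect_gt(mean(out$consensus[1:10, 1:10]), 0.95)
  expect_lt(mean(out$consensus[1:10, 11:20]), 0.05)
  ## duplicated rows end in the same consensus cluster
  x2 <- rbind(x, e21 = x[1, ])
  out2 <- consensus_cluster_esnvs(x2, k = 2, iterations = 100, seed = 2)
  expect_equal(out2$clusters[["e21"]], out2$clusters[["e1"]])
  expect_error(consensus_cluster_esnvs(x, k = 30), "exceeds")
})

test_that("four implanted coefficient groups are recovered at k = 4", {
  set.seed(5)
  centers <- matrix(rnorm(4 * 8, sd = 4), 4, 8)
  x <- centers[rep(1:4, each = 8), ] + matrix(rnorm(32 * 8, sd = 0.5), 32, 8)
  rownames(x) <- paste0("e", 1:32)
  out <- consensus_cluster_esnvs(x, k = 4, iterations = 200, seed = 9)
  expect_gte(adjusted_rand_index(out$clusters, rep(1:4, each = 8)), 0.9)
})

test_that("bimodality screen accepts clear mixtures and rejects unimodal genes", {
  set.seed(21)
  n <- 120
  uni <- 2^rnorm(n, 6, 1)
  bim <- 2^c(rnorm(n / 2, 0, 1), rnorm(n / 2, 6, 1))
  const <- rep(4, n)
  x <- rbind(uni = uni, bim = bim, const = const)
  colnames(x) <- paste0("S", 1:n)
  out <- bimodality_screen(x, seed = 2)
  expect_false("uni" %in% out$bimodal_genes)
  expect_false("const" %in% out$bimodal_genes)
  expect_true("bim" %in% out$bimodal_genes)
  ## mode assignment accuracy >= 0.99 for the 50/50 mixture
  truth <- rep(1:2, each = n / 2)
  acc <- mean(out$modes$bim == truth)
  expect_gte(max(acc, 1 - acc), 0.99)
  ## floor rule: 0.01 is treated as 0.1 before log2
  expect_equal(log2(pmax(0.01, 0.1)), -3.321928, tolerance = 1e-6)
  expect_error(bimodality_screen(x - 100), "nonnegative")
})

test_that("BEEM reduces to the exact 2x2 Fisher test", {
  modes <- c(rep(1, 20), rep(2, 30))
  names(modes) <- paste0("S", 1:50)
  carrier <- c(rep(1, 10), rep(0, 40))
  names(carrier) <- names(modes)
  out <- beem_test(modes, carrier)
  tab <- table(factor(carrier, levels = 0:1), factor(modes, levels = 1:2))
  expect_equal(out$p, fisher_oracle_2x2(tab), tolerance = 1e-9)
  expect_lt(out$p, 1e-3)
  expect_equal(out$n_carrier_low, 10)
  ## proportionally split carriers are not emitted
  carrier2 <- rep(c(1, 0, 0, 0, 0), 10)
  names(carrier2) <- names(modes)
  expect_null(beem_test(modes, carrier2))
  expect_error(beem_test(rep(1, 50), carrier), "single-mode")
})

test_that("implanted synthetic-lethality pairs are recovered", {
  g <- default_cohort()
  screen <- bimodality_screen(g$cohort$raw_expression, seed = 1)
  sl <- sl_nominate(screen, g$cohort$mutation_matrix)
  hits <- merge(sl, g$truth$sl_pairs)
  expect_gte(nrow(hits) / nrow(g$truth$sl_pairs), 0.8)
})

test_that("the seven-criterion score counts evidence and flags risk", {
  mu <- data.frame(snv_id = c("s1", "s2", "s3"),
                   mutation_type = c("missense", "silent", "nonsense"))
  ev <- score_esnvs(c("s1", "s2", "s3"), mu,
                    cis_esnvs = "s1", prognostic = "s3",
                    cluster_related = "s3", sl_esnvs = "s3")
  ## missense + cis, nothing else: score 2, risk
  expect_equal(ev$score[ev$snv_id == "s1"], 2)
  expect_true(ev$risk[ev$snv_id == "s1"])
  ## silent, trans, no evidence: score 0
  expect_equal(ev$score[ev$snv_id == "s2"], 0)
  expect_false(ev$risk[ev$snv_id == "s2"])
  expect_equal(ev$score[ev$snv_id == "s3"], 4)
  ## monotonicity: adding a criterion never lowers a score
  ev2 <- score_esnvs(c("s1", "s2", "s3"), mu,
                     cis_esnvs = "s1", prognostic = c("s1", "s3"),
                     cluster_related = "s3", sl_esnvs = "s3")
  expect_true(all(ev2$score >= ev$score))
  expect_error(score_esnvs("s9", mu), "absent")
})

test_that("phi correlation behaves like a correlation of binaries", {
  a <- c(1, 1, 0, 0, 1, 0)
  expect_equal(phi_coefficient(a, a), 1)
  expect_equal(phi_coefficient(a, 1 - a), -1)
  b <- c(1, 0, 1, 0, 1, 0)
  expect_gte(phi_coefficient(a, b), -1)
  expect_lte(phi_coefficient(a, b), 1)
  ## the attached phi matrix marks identical criteria as perfectly correlated
  mu <- data.frame(snv_id = c("s1", "s2"), mutation_type = c("missense", "silent"))
  ev <- score_esnvs(c("s1", "s2"), mu, prognostic = "s1", sl_esnvs = "s1")
  phi <- attr(ev, "phi")
  expect_equal(phi["c4_prognostic", "c7_sl"], 1)
})
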