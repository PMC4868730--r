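test_that("a mutated hub feeding expressed leaves ranks first", {
  leaves <- paste0("L", 1:6)
  edges <- data.frame(source = "HUB", target = leaves)
  net <- gene_network(rbind(edges,
                            data.frame(source = leaves, target = "SINK")))
  de <- setNames(c(rep(1, 6), 0, 0), c(leaves, "HUB", "SINK"))
  r <- rank_patient(de, c("HUB", "L1", "SINK"), net)
  expect_identical(r$gene[1], "HUB")  # collects impact from all DE leaves
  expect_gt(r$score[r$gene == "HUB"], r$score[r$gene == "SINK"])
})

test_that("zero damping returns the normalized differential expression", {
  net <- toy_network(paste0("g", 1:8), seed = 2)
  de <- setNames(abs(rnorm(8)), paste0("g", 1:8))
  r <- rank_patient(de, paste0("g", 1:8), net, damping = 0)
  expect_equal(sort(attr(r, "scores")), sort(de / sum(de)),
               tolerance = 1e-12)
})

test_that("mutations in one component leave the other component's scores alone", {
  cliqueA <- paste0("a", 1:4); cliqueB <- paste0("b", 1:4)
  full <- expand.grid(source = cliqueA, target = cliqueA,
                      stringsAsFactors = FALSE)
  fullB <- expand.grid(source = cliqueB, target = cliqueB,
                       stringsAsFactors = FALSE)
  net <- gene_network(rbind(full, fullB))
  de <- setNames(runif(8, 0.5, 1), c(cliqueA, cliqueB))
  r1 <- rank_patient(de, "a1", net)
  r2 <- rank_patient(de, c("a1", "a2"), net)
  s1 <- attr(r1, "scores"); s2 <- attr(r2, "scores")
  expect_equal(s1[cliqueB], s2[cliqueB], tolerance = 1e-12)
})

test_that("propagation scores are nonnegative and label-permutation equivariant", {
  genes <- paste0("g", 1:10)
  net_edges <- data.frame(
    source = sample(genes, 25, TRUE), target = sample(genes, 25, TRUE))
  net_edges <- net_edges[net_edges$source != net_edges$target, ]
  net <- gene_network(net_edges)
  de <- setNames(abs(rnorm(10)), genes)
  r <- rank_patient(de, genes[1:5], net)
  expect_true(all(attr(r, "scores") >= 0))
  ## relabel nodes: scores follow the relabeling
  perm <- setNames(paste0("h", 1:10), genes)
  edges2 <- data.frame(source = unname(perm[net_edges$source]),
                       target = unname(perm[net_edges$target]))
  de2 <- setNames(de, unname(perm[names(de)]))
  r2 <- rank_patient(de2, unname(perm[genes[1:5]]), gene_network(edges2))
  s1 <- attr(r, "scores"); s2 <- attr(r2, "scores")
  expect_equal(unname(s2[unname(perm[names(s1)])]), unname(s1),
               tolerance = 1e-12)
})

## brute force: evaluate the standardized rank statistic at every cutpoint
maxstat_oracle <- function(scores, qb = 0.95) {
  n <- length(scores)
  rk <- rank(scores)
  ord <- order(scores)
  best <- c(stat = -Inf, cut = NA)
  for (m in max(1, floor(n * (1 - qb))):min(n - 1, ceiling(n * qb))) {
    if (scores[ord[m]] == scores[ord[m + 1]]) next
    s <- sum(rk[ord[seq_len(m)]])
    e <- m * (n + 1) / 2
    ties <- table(rk)
    v <- m * (n - m) / (12 * n * (n - 1)) * (n^3 - n - sum(ties^3 - ties))
    st <- abs(s - e) / sqrt(v)
    if (st > best["stat"]) {
      best <- c(stat = st, cut = mean(scores[ord[m + 0:1]]))
    }
  }
  best
}

test_that("maxstat split separates well-separated groups and matches brute force", {
  mk <- function(scores) {
    r <- data.frame(gene = paste0("g", seq_along(scores)), score = scores)
    r <- r[order(-r$score), ]
    class(r) <- c("patient_ranking", "data.frame")
    r
  }
  ## perfect separation
  r <- maxstat_split(mk(c(10, 10, 10, 1, 1, 1)))
  expect_equal(sum(r$driver), 3L)
  expect_true(attr(r, "cutpoint") > 1 && attr(r, "cutpoint") < 10)
  ## uniform ladder: agreement with exhaustive search
  set.seed(8)
  for (rep in 1:10) {
    scores <- sample(seq(1, 50, length.out = sample(8:30, 1)))
    split <- maxstat_split(mk(scores))
    oracle <- maxstat_oracle(scores)
    expect_equal(attr(split, "cutpoint"), unname(oracle["cut"]),
                 tolerance = 1e-12)
    expect_equal(attr(split, "statistic"), unname(oracle["stat"]),
                 tolerance = 1e-12)
  }
  expect_error(maxstat_split(mk(c(1, 2, 3, 4))), "few")
  expect_warning(r0 <- maxstat_split(mk(rep(2, 6))), "equal")
  expect_false(any(r0$driver))
})

test_that("driver list union merges rankings with known genes", {
  expect_identical(build_driver_gene_list(list(), paste0("k", 1:12)),
                   paste0("k", sprintf("%d", 1:12))[order(paste0("k", 1:12))])
  r <- data.frame(gene = c("k1", "x9"), score = c(2, 1),
                  driver = c(TRUE, TRUE))
  out <- build_driver_gene_list(list(r), c("k1", "k2"))
  expect_setequal(out, c("k1", "k2", "x9"))  # known gene counted once
})

test_that("eSNV prioritization restricts to driver loci and reports counts", {
  assoc <- data.frame(
    snv_id = c("s1", "s1", "s2", "s3"),
    gene_id = c("gA", "gB", "gA", "gC"),
    p_bonf_sig = c(TRUE, TRUE, TRUE, FALSE))
  mu <- data.frame(snv_id = c("s1", "s2", "s3"),
                   gene_locus = c("D1", "P1", "D1"))
  out <- prioritize_esnvs(assoc, mu, c("D1", "D2"))
  expect_equal(out$counts$n_esnvs, 1L)
  expect_equal(out$counts$n_loci, 1L)
  expect_equal(out$counts$n_genes, 2L)
  expect_equal(out$counts$n_pairs, 2L)
  ## subset of input and idempotent
  expect_true(all(out$assoc$snv_id %in% assoc$snv_id))
  again <- prioritize_esnvs(out$assoc, mu, c("D1", "D2"))
  expect_identical(again$assoc, out$assoc)
  ## no driver overlap -> empty
  none <- prioritize_esnvs(assoc, mu, "ZZZ")
  expect_equal(none$counts$n_pairs, 0L)
})

test_that("driver burden tests match rank-test oracles", {
  counts <- setNames(c(1, 2, 3, 10, 11, 12), paste0("S", 1:6))
  clin <- data.frame(sample = paste0("S", 1:6),
                     stage = rep(c("I", "III"), each = 3),
                     histology = "endometrioid", grade = 1)
  out <- suppressWarnings(driver_burden_tests(counts, clin, "stage"))
  ## exact two-sided Wilcoxon p for complete 3v3 separation = 2/20
  wx <- wilcox.test(c(1, 2, 3), c(10, 11, 12), exact = TRUE)
  expect_equal(wx$p.value, 0.1, tolerance = 1e-12)
  expect_equal(out$stage$kruskal_p,
               kruskal.test(counts, factor(clin$stage))$p.value)
  ## three shifted groups: KW statistic equals the hand rank computation
  x <- c(1, 2, 3, 6, 7, 8, 11, 12, 13)
  gr <- rep(1:3, each = 3)
  rk <- rank(x)
  h <- 12 / (9 * 10) * sum(tapply(rk, gr, sum)^2 / 3) - 3 * 10
  expect_equal(unname(kruskal.test(x, gr)$statistic), h, tolerance = 1e-12)
})

test_that("identical burden distributions across groups are not rejected", {
  counts <- setNames(rep(c(3, 5, 7, 9), 3), paste0("S", 1:12))
  clin <- data.frame(sample = paste0("S", 1:12),
                     stage = rep(c("I", "II", "III"), each = 4),
                     histology = "endometrioid", grade = 1)
  out <- suppressWarnings(driver_burden_tests(counts, clin, "stage"))
  expect_gt(out$stage$kruskal_p, 0.9)
})

test_that("mutation-type composition reports frequencies and fold changes", {
  mu <- data.frame(
    snv_id = paste0("s", 1:10),
    gene_locus = c(rep("TF1", 4), rep("OT1", 6)),
    mutation_type = c("missense", "missense", "nonsense", "silent",
                      rep("missense", 3), rep("silent", 3)))
  out <- mutation_type_composition(mu, tf_genes = "TF1")
  all_mis <- out$freq[out$stratum == "all" & out$mutation_type == "missense"]
  tf_mis <- out$freq[out$stratum == "tf" & out$mutation_type == "missense"]
  expect_equal(all_mis, 0.5)
  expect_equal(tf_mis, 0.5)
  expect_equal(out$mc[out$stratum == "tf" & out$mutation_type == "missense"],
               1)  # stratum equal to all -> MC = 1
  expect_equal(out$mc[out$stratum == "tf" & out$mutation_type == "nonsense"],
               0.25 / 0.1)
  ## empty TF list flagged
  out2 <- mutation_type_composition(mu, tf_genes = character(0))
  expect_true(attr(out2, "empty_tf"))
  mu$mutation_type[1] <- "frameshift"
  expect_error(mutation_type_composition(mu, "TF1"), "frameshift")
})
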