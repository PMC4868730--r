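make_reg_cohort <- function(rt, scna, meth) {
  structure(list(expression = rt, scna = scna, methylation = meth),
            class = "multi_omics_cohort")
}

test_that("residualization reproduces hand-computed decompositions", {
  ## RT = 2*SCNA exactly, M constant: SCNA fraction 1, residuals 0
  s <- matrix(c(0, 1, 2, 1, 0), 1, 5, dimnames = list("g1", paste0("S", 1:5)))
  m <- matrix(0.5, 1, 5, dimnames = dimnames(s))
  rt <- 2 * s
  r <- residualize(make_reg_cohort(rt, s, m))
  expect_equal(r$determinants$frac_scna, 1, tolerance = 1e-12)
  expect_equal(max(abs(r$residuals)), 0, tolerance = 1e-10)
  expect_true(r$determinants$degenerate)  # constant methylation flagged

  ## hand OLS: RT = (1,2,3), SCNA = (0,0,1), M constant
  s2 <- matrix(c(0, 0, 1, 0), 1, 4, dimnames = list("g1", paste0("S", 1:4)))
  rt2 <- matrix(c(1, 2, 3, 1.5), 1, 4, dimnames = dimnames(s2))
  m2 <- matrix(0.3, 1, 4, dimnames = dimnames(s2))
  ## restrict to the 3-sample hand case via complete cases
  rt2[1, 4] <- NA
  r2 <- residualize(make_reg_cohort(rt2, s2, m2))
  fit <- lm(c(1, 2, 3) ~ c(0, 0, 1))
  expect_equal(unname(r2$residuals[1, 1:3]), unname(residuals(fit)),
               tolerance = 1e-12)
  expect_equal(r2$determinants$frac_scna, 0.75, tolerance = 1e-12)
})

test_that("residuals are orthogonal to both determinant columns", {
  g <- default_cohort()
  r <- residualize(g$cohort)
  genes <- sample(rownames(r$residuals), 25)
  for (gene in genes) {
    eps <- r$residuals[gene, ]
    sc <- g$cohort$scna[gene, ] - mean(g$cohort$scna[gene, ])
    me <- g$cohort$methylation[gene, ] - mean(g$cohort$methylation[gene, ])
    expect_lt(abs(sum(eps * sc)), 1e-8)
    expect_lt(abs(sum(eps * me)), 1e-8)
    expect_lt(abs(sum(eps)), 1e-8)
  }
  frac <- r$determinants$frac_scna + r$determinants$frac_meth
  expect_true(all(frac >= 0 & frac <= 1 + 1e-12))
})

test_that("independent determinants give null variance fractions", {
  set.seed(42)
  n <- 100
  rt <- matrix(rnorm(20 * n), 20, n,
               dimnames = list(sprintf("g%02d", 1:20), paste0("S", 1:n)))
  s <- matrix(sample(-2:2, 20 * n, TRUE), 20, n, dimnames = dimnames(rt))
  m <- matrix(rbeta(20 * n, 2, 2), 20, n, dimnames = dimnames(rt))
  r <- residualize(make_reg_cohort(rt, s, m))
  expect_lt(mean(r$determinants$frac_scna), 0.05)
  expect_gt(mean(r$determinants$fdr_scna, na.rm = TRUE), 0.5)
})

test_that("scan results equal the brute-force normal-equations oracle", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    eps <- matrix(rnorm(3 * n), 3, n,
                  dimnames = list(paste0("g", 1:3), paste0("S", 1:n)))
    x <- integer(n)
    x[sample(n, sample(2:(n - 2), 1))] <- 1L
    mm <- matrix(x, 1, n, dimnames = list("1:100", colnames(eps)))
    a <- esnv_scan(eps, mm)
    for (k in 1:3) {
      o <- ols_oracle(eps[k, ], x)
      row <- a[a$gene_id == paste0("g", k), ]
      expect_equal(row$beta, unname(o$beta), tolerance = 1e-10)
      expect_equal(row$ci_low, unname(o$ci[1]), tolerance = 1e-10)
      expect_equal(row$ci_high, unname(o$ci[2]), tolerance = 1e-10)
      expect_equal(row$p, unname(o$p), tolerance = 1e-10)
      expect_equal(row$var_explained, unname(o$r2), tolerance = 1e-10)
    }
  }
})

test_that("scan enforces carrier filters and binary input", {
  eps <- matrix(rnorm(40), 2, 20,
                dimnames = list(c("g1", "g2"), paste0("S", 1:20)))
  mm <- rbind("1:1" = c(1L, rep(0L, 19)),        # 1 carrier: skipped
              "1:2" = c(1L, 1L, rep(0L, 18)))    # kept
  colnames(mm) <- colnames(eps)
  a <- esnv_scan(eps, mm)
  expect_equal(attr(a, "n_skipped_snvs"), 1L)
  expect_setequal(unique(a$snv_id), "1:2")
  mm_bad <- mm; mm_bad[1, 1] <- 2L
  expect_error(esnv_scan(eps, mm_bad), "binary")
})

test_that("genomic inflation factor matches its definition", {
  expect_equal(genomic_inflation(rep(0.5, 10)), 1.0, tolerance = 1e-12)
  set.seed(5)
  p <- runif(4e5)
  expect_equal(genomic_inflation(p), 1.0, tolerance = 0.02)
  expect_gt(genomic_inflation(p / 2), 1)  # halving p inflates lambda
  expect_error(genomic_inflation(numeric(0)), "empty")
  expect_error(genomic_inflation(c(0.5, 0)), "0, 1")
})

test_that("cis/trans classification is inclusive, exhaustive and disjoint", {
  gi <- data.frame(gene = c("gA", "gB"), chrom = c(1L, 2L),
                   start = c(100L, 100L), end = c(200L, 200L))
  mu <- data.frame(snv_id = c("1:100", "1:200", "1:150", "2:150", "1:150"),
                   chrom = c(1L, 1L, 1L, 2L, 1L),
                   pos = c(100L, 200L, 150L, 150L, 150L))
  mu <- mu[!duplicated(mu$snv_id), ]
  assoc <- data.frame(
    snv_id = c("1:100", "1:200", "1:150", "2:150", "1:150"),
    gene_id = c("gA", "gA", "gA", "gA", "gB"),
    stringsAsFactors = FALSE)
  out <- classify_cis_trans(assoc, mu, gi)
  expect_identical(out$cis, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  ## unknown gene interval -> trans with a warning
  assoc2 <- data.frame(snv_id = "1:100", gene_id = "gZ")
  expect_warning(out2 <- classify_cis_trans(assoc2, mu, gi), "interval")
  expect_false(out2$cis)
})

test_that("scan summary counts and percentage arithmetic are exact", {
  ## synthetic association table with known composition
  assoc <- data.frame(
    snv_id = c("a", "a", "b", "c"), gene_id = c("g1", "g2", "g1", "g3"),
    beta = 1, ci_low = 0, ci_high = 2, p = c(1e-10, 1e-9, 0.5, 1e-8),
    var_explained = c(0.4, 0.2, 0.1, 0.3),
    p_bonf_sig = c(TRUE, TRUE, FALSE, TRUE),
    cis = c(TRUE, FALSE, FALSE, FALSE))
  attr(assoc, "n_tested") <- 4L
  s <- summarize_scan(assoc)
  expect_equal(s$n_significant, 3L)
  expect_equal(s$n_esnvs, 2L)
  expect_equal(s$n_genes_affected, 3L)
  expect_equal(s$mean_var_cis, 0.4)
  expect_equal(s$mean_var_trans, 0.25)
  ## the percentage arithmetic at published scale: 74,713 of 78,571,584
  expect_equal(round(100 * 74713 / 78571584, 3), 0.095)
})

test_that("per-gene Bonferroni families are available as an option", {
  g <- null_cohort()
  r <- residualize(g$cohort)
  a_glob <- esnv_scan(r, g$cohort$mutation_matrix, family = "global")
  a_gene <- esnv_scan(r, g$cohort$mutation_matrix, family = "per_gene")
  expect_gte(sum(a_gene$p_bonf_sig), sum(a_glob$p_bonf_sig))
})
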