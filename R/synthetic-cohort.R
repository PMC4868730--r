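#' Simulation configuration for a synthetic multi-omic cohort
#'
#' Collects every knob of the cohort generator. Defaults define the standard
#' study conditions used throughout the package's tests: a mid-sized tumor
#' cohort with discrete GISTIC copy-number calls, beta-valued methylation,
#' sparse binary somatic mutations carrying cluster structure, expression
#' linearly driven by the three determinants, exponential progression-free
#' survival with variant-dependent hazards, and a handful of bimodal genes
#' whose high expression mode excludes carriers of a paired variant.
#'
#' @param n_samples number of tumor samples.
#' @param n_normals number of matched normal samples (used for the
#'   normalization layer of the cohort files).
#' @param n_genes number of genes.
#' @param n_snvs number of somatic SNVs.
#' @param n_clusters number of implanted mutational clusters.
#' @param n_effects number of implanted SNV-gene expression effects.
#' @param cis_fraction fraction of effect SNVs placed inside their target
#'   gene's interval (cis-acting); the rest are trans.
#' @param beta_range range from which implanted effect sizes are drawn
#'   (standardized expression units per mutant allele). The default spans
#'   the effect sizes typical of prioritized cis-acting variants.
#' @param scna_effect_sd,meth_effect_sd standard deviation of the per-gene
#'   copy-number and methylation coefficients.
#' @param noise_sd residual standard deviation of expression.
#' @param effect_rate carrier probability of effect SNVs.
#' @param background_rate background mutation probability per SNV/sample.
#' @param marker_rate within-cluster mutation probability of cluster-marker
#'   SNVs.
#' @param markers_per_cluster number of marker SNVs per cluster.
#' @param scna_probs marginal probabilities of GISTIC calls -2..2.
#' @param prognostic_hr hazard ratio implanted for prognostic SNVs.
#' @param n_prognostic number of prognostic SNVs.
#' @param censoring_rate target proportion of censored samples (approximate;
#'   random exponential censoring plus an administrative 10-year horizon).
#' @param n_bimodal number of synthetic-lethality (bimodal gene, SNV) pairs.
#' @param seed master RNG seed; one sub-stream per data layer is derived
#'   from it so layers are individually reproducible.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 200, n_normals = 10, n_genes = 150,
                              n_snvs = 100, n_clusters = 3, n_effects = 20,
                              cis_fraction = 0.25, beta_range = c(0.3, 2.3),
                              scna_effect_sd = 0.5, meth_effect_sd = 0.5,
                              noise_sd = 1, effect_rate = 0.15,
                              background_rate = 0.04, marker_rate = 0.7,
                              markers_per_cluster = 5,
                              scna_probs = c(0.05, 0.15, 0.6, 0.15, 0.05),
                              prognostic_hr = 3, n_prognostic = 3,
                              censoring_rate = 0.3, n_bimodal = 5, seed = 1) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_normals = as.integer(n_normals),
    n_genes = as.integer(n_genes), n_snvs = as.integer(n_snvs),
    n_clusters = as.integer(n_clusters), n_effects = as.integer(n_effects),
    cis_fraction = cis_fraction, beta_range = as.numeric(beta_range),
    scna_effect_sd = scna_effect_sd, meth_effect_sd = meth_effect_sd,
    noise_sd = noise_sd, effect_rate = effect_rate,
    background_rate = background_rate, marker_rate = marker_rate,
    markers_per_cluster = as.integer(markers_per_cluster),
    scna_probs = scna_probs, prognostic_hr = prognostic_hr,
    n_prognostic = as.integer(n_prognostic),
    censoring_rate = censoring_rate, n_bimodal = as.integer(n_bimodal),
    seed = as.integer(seed)
  )
  validate_simulation_config(structure(cfg, class = "simulation_config"))
}

validate_simulation_config <- function(cfg) {
  counts <- c("n_samples", "n_normals", "n_genes", "n_snvs", "n_clusters")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("configuration error: ", f, " must be a count >= 1")
  }
  if (cfg$cis_fraction < 0 || cfg$cis_fraction > 1)
    stop("configuration error: cis_fraction must lie in [0, 1]")
  if (length(cfg$beta_range) != 2L || cfg$beta_range[1] > cfg$beta_range[2])
    stop("configuration error: beta_range must be an ordered interval")
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1)
    stop("configuration error: censoring_rate must lie in [0, 1)")
  if (cfg$n_snvs < cfg$n_clusters)
    stop("configuration error: n_snvs must be >= n_clusters")
  n_reserved <- cfg$n_effects + cfg$n_clusters * cfg$markers_per_cluster +
    cfg$n_bimodal
  if (n_reserved > cfg$n_snvs)
    stop("configuration error: n_effects + markers + n_bimodal exceed n_snvs")
  if (cfg$n_effects > 0 && cfg$n_effects > cfg$n_genes)
    stop("configuration error: n_effects exceeds n_genes")
  if (abs(sum(cfg$scna_probs) - 1) > 1e-8 || length(cfg$scna_probs) != 5L)
    stop("configuration error: scna_probs must be 5 probabilities summing to 1")
  cfg
}

# Derive one reproducible sub-seed per data layer from the master seed.
layer_seeds <- function(seed, n = 10L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  sample.int(2147483646L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

with_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  force(code)
}

MUTATION_TYPES <- c("missense", "silent", "nonsense", "3'UTR", "intron",
                    "RNA", "splice site", "5'UTR")
MUTATION_TYPE_PROBS <- c(0.52, 0.22, 0.12, 0.05, 0.04, 0.02, 0.02, 0.01)

#' Generate a synthetic multi-omic cohort with known ground truth
#'
#' Emits aligned expression / methylation / copy-number matrices, a sparse
#' binary mutation profile, clinical records with censored progression-free
#' survival, gene intervals, and a raw expression matrix containing bimodal
#' genes, together with the implanted truth (effect pairs, cluster labels,
#' prognostic variants, synthetic-lethal pairs, determinant coefficients).
#'
#' Per gene the relative expression is
#' `intercept + b_scna * SCNA + b_meth * M + sum(beta * SNV) + noise`,
#' the generative structure assumed by the two-step association scan.
#' Survival times are exponential with log-hazard proportional to the
#' carrier status of the implanted prognostic SNVs, administratively
#' censored at a 10-year horizon.
#'
#' @param config a [simulation_config()].
#' @return a list with elements `cohort` (class `multi_omics_cohort`) and
#'   `truth` (class `synthetic_truth`).
#' @export
generate_cohort <- function(config) {
  cfg <- validate_simulation_config(config)
  if (cfg$cis_fraction > 0 && cfg$n_genes < 1)
    stop("configuration error: cis placement requires gene intervals")
  seeds <- layer_seeds(cfg$seed, 10L)

  samples <- sprintf("S%03d", seq_len(cfg$n_samples))
  normals <- sprintf("N%03d", seq_len(cfg$n_normals))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  snv_n <- cfg$n_snvs

  ## gene intervals: genes laid out along chromosomes 1..22, 20 kb each,
  ## 100 kb apart (1-based inclusive internally)
  chrom <- rep(1:22, length.out = cfg$n_genes)
  idx_on_chrom <- stats::ave(seq_len(cfg$n_genes), chrom, FUN = seq_along)
  start <- 1e5 * (idx_on_chrom - 1L) + 1e4
  gene_intervals <- data.frame(
    gene = genes, chrom = chrom,
    start = as.integer(start), end = as.integer(start + 19999),
    stringsAsFactors = FALSE
  )

  ## role assignment of SNVs (deterministic partition of a shuffled order)
  roles <- with_seed(seeds[1], {
    ord <- sample.int(snv_n)
    n_mark <- cfg$n_clusters * cfg$markers_per_cluster
    list(
      effect = ord[seq_len(cfg$n_effects)],
      marker = ord[cfg$n_effects + seq_len(n_mark)],
      sl = ord[cfg$n_effects + n_mark + seq_len(cfg$n_bimodal)]
    )
  })

  ## effect pairs: targets are distinct genes; cis SNVs live inside the
  ## target gene, trans SNVs in a different gene
  truth_env <- with_seed(seeds[2], {
    n_eff <- cfg$n_effects
    target_gene <- if (n_eff > 0) sample(genes, n_eff) else character(0)
    n_cis <- round(cfg$cis_fraction * n_eff)
    cis <- rep(FALSE, n_eff)
    if (n_cis > 0) cis[seq_len(n_cis)] <- TRUE
    betas <- if (n_eff > 0) stats::runif(n_eff, cfg$beta_range[1], cfg$beta_range[2]) else numeric(0)
    ## locus gene of every SNV; effect SNVs overridden below
    locus <- sample(genes, snv_n, replace = TRUE)
    if (n_eff > 0) {
      locus[roles$effect[cis]] <- target_gene[cis]
      for (i in which(!cis)) {
        other <- setdiff(genes, target_gene[i])
        locus[roles$effect[i]] <- sample(other, 1)
      }
    }
    list(target_gene = target_gene, cis = cis, betas = betas, locus = locus)
  })
  locus <- truth_env$locus
  li <- match(locus, gene_intervals$gene)
  pos <- with_seed(seeds[3], as.integer(gene_intervals$start[li] +
    floor(stats::runif(snv_n) * 20000)))
  snv_chrom <- gene_intervals$chrom[li]
  snv_id <- sprintf("%d:%d", snv_chrom, pos)
  ## guarantee unique ids (collisions possible within a gene)
  dup <- duplicated(snv_id)
  while (any(dup)) {
    pos[dup] <- pos[dup] + 1L
    snv_id <- sprintf("%d:%d", snv_chrom, pos)
    dup <- duplicated(snv_id)
  }

  bases <- c("A", "C", "G", "T")
  alleles <- with_seed(seeds[4], {
    ref <- sample(bases, snv_n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    type <- sample(MUTATION_TYPES, snv_n, replace = TRUE,
                   prob = MUTATION_TYPE_PROBS)
    list(ref = ref, alt = unname(alt), type = type)
  })

  ## cluster labels and mutation matrix (SNV x sample, binary)
  cluster_labels <- rep(seq_len(cfg$n_clusters), length.out = cfg$n_samples)
  names(cluster_labels) <- samples
  marker_cluster <- rep(seq_len(cfg$n_clusters), each = cfg$markers_per_cluster)
  mut <- with_seed(seeds[5], {
    p <- matrix(cfg$background_rate, snv_n, cfg$n_samples)
    p[roles$effect, ] <- cfg$effect_rate
    p[roles$sl, ] <- max(cfg$effect_rate, 0.2)
    for (j in seq_along(roles$marker)) {
      in_cl <- cluster_labels == marker_cluster[j]
      p[roles$marker[j], in_cl] <- cfg$marker_rate
    }
    m <- matrix(stats::rbinom(length(p), 1L, p), snv_n, cfg$n_samples)
    ## effect/prognostic/SL variants need >= 2 carriers to be scannable
    need <- unique(c(roles$effect, roles$sl))
    for (i in need) {
      while (sum(m[i, ]) < 2L) m[i, sample.int(cfg$n_samples, 1)] <- 1L
    }
    m
  })
  dimnames(mut) <- list(snv_id, samples)

  ## determinant layers
  scna <- with_seed(seeds[6], matrix(
    sample(-2:2, cfg$n_genes * cfg$n_samples, replace = TRUE,
           prob = cfg$scna_probs),
    cfg$n_genes, cfg$n_samples, dimnames = list(genes, samples)))
  meth <- with_seed(seeds[7], matrix(
    stats::rbeta(cfg$n_genes * cfg$n_samples, 2, 2),
    cfg$n_genes, cfg$n_samples, dimnames = list(genes, samples)))

  ## expression: linear in the three determinant layers
  expr_parts <- with_seed(seeds[8], {
    b_scna <- stats::rnorm(cfg$n_genes, 0, cfg$scna_effect_sd)
    b_meth <- stats::rnorm(cfg$n_genes, 0, cfg$meth_effect_sd)
    noise <- matrix(stats::rnorm(cfg$n_genes * cfg$n_samples, 0, cfg$noise_sd),
                    cfg$n_genes, cfg$n_samples)
    list(b_scna = b_scna, b_meth = b_meth, noise = noise)
  })
  expr <- expr_parts$b_scna * scna + expr_parts$b_meth * meth +
    expr_parts$noise
  if (cfg$n_effects > 0) {
    gi <- match(truth_env$target_gene, genes)
    for (i in seq_len(cfg$n_effects)) {
      expr[gi[i], ] <- expr[gi[i], ] +
        truth_env$betas[i] * mut[roles$effect[i], ]
    }
  }
  dimnames(expr) <- list(genes, samples)

  ## raw abundance matrix (log2-normal background) with bimodal SL genes
  sl_snv <- snv_id[roles$sl]
  raw <- with_seed(seeds[9], {
    lg <- matrix(stats::rnorm(cfg$n_genes * cfg$n_samples, 5, 0.7),
                 cfg$n_genes, cfg$n_samples, dimnames = list(genes, samples))
    sl_gene <- character(cfg$n_bimodal)
    if (cfg$n_bimodal > 0) {
      pool <- setdiff(genes, truth_env$target_gene)
      sl_gene <- sample(pool, cfg$n_bimodal)
      for (b in seq_len(cfg$n_bimodal)) {
        carrier <- mut[roles$sl[b], ] == 1L
        ## high mode excludes carriers; non-carriers split between modes
        hi <- !carrier & stats::runif(cfg$n_samples) < 0.5
        v <- stats::rnorm(cfg$n_samples, 3, 0.5)
        v[hi] <- stats::rnorm(sum(hi), 9, 0.5)
        lg[sl_gene[b], ] <- v
      }
    }
    list(raw = 2^lg, sl_gene = sl_gene)
  })

  ## survival: exponential PFS, log-hazard from prognostic SNV carriage
  prog_idx <- roles$effect[seq_len(min(cfg$n_prognostic, cfg$n_effects))]
  surv <- with_seed(seeds[10], {
    lp <- rep(0, cfg$n_samples)
    for (i in prog_idx) lp <- lp + log(cfg$prognostic_hr) * mut[i, ]
    rate0 <- log(2) / 5  # median 5 years at baseline (years^-1)
    t_event <- stats::rexp(cfg$n_samples, rate0 * exp(lp))
    cens <- if (cfg$censoring_rate > 0) {
      stats::rexp(cfg$n_samples,
                  rate0 * cfg$censoring_rate / (1 - cfg$censoring_rate))
    } else rep(Inf, cfg$n_samples)
    cens <- pmin(cens, 10)
    time <- pmin(t_event, cens)
    event <- as.integer(t_event <= cens)
    stage <- character(cfg$n_samples)
    hist <- character(cfg$n_samples)
    for (k in seq_len(cfg$n_clusters)) {
      in_k <- cluster_labels == k
      ## one cluster enriched for late stage / serous-like histology
      aggressive <- (k == 2L || cfg$n_clusters == 1L)
      stage[in_k] <- sample(c("I", "II", "III", "IV"), sum(in_k), TRUE,
        prob = if (aggressive) c(0.35, 0.15, 0.3, 0.2) else c(0.6, 0.2, 0.15, 0.05))
      hist[in_k] <- sample(c("endometrioid", "serous-like", "mixed"),
        sum(in_k), TRUE,
        prob = if (aggressive) c(0.4, 0.5, 0.1) else c(0.78, 0.12, 0.1))
    }
    grade <- sample(1:3, cfg$n_samples, TRUE, prob = c(0.3, 0.4, 0.3))
    data.frame(sample = samples, stage = stage, histology = hist,
               grade = grade, pfs_time = round(time * 365.25, 2),
               pfs_event = event, stringsAsFactors = FALSE)
  })

  mutations <- data.frame(
    snv_id = snv_id, chrom = snv_chrom, pos = pos,
    ref = alleles$ref, alt = alleles$alt, gene_locus = locus,
    mutation_type = alleles$type, stringsAsFactors = FALSE
  )

  cohort <- structure(list(
    expression = expr, methylation = meth, scna = scna,
    mutation_matrix = mut, mutations = mutations,
    clinical = surv, gene_intervals = gene_intervals,
    raw_expression = raw$raw, samples = samples, normals = normals
  ), class = "multi_omics_cohort")

  truth <- structure(list(
    effect_pairs = data.frame(
      snv_id = snv_id[roles$effect],
      gene_id = truth_env$target_gene,
      beta = truth_env$betas, cis = truth_env$cis,
      stringsAsFactors = FALSE
    ),
    cluster_labels = cluster_labels,
    prognostic_snvs = data.frame(
      snv_id = snv_id[prog_idx],
      log_hr = rep(log(cfg$prognostic_hr), length(prog_idx)),
      stringsAsFactors = FALSE
    ),
    sl_pairs = data.frame(snv_id = sl_snv, gene_id = raw$sl_gene,
                          stringsAsFactors = FALSE),
    determinant_effects = data.frame(
      gene_id = genes, b_scna = expr_parts$b_scna,
      b_meth = expr_parts$b_meth, stringsAsFactors = FALSE
    )
  ), class = "synthetic_truth")

  ## truth consistency
  stopifnot(all(truth$effect_pairs$snv_id %in% rownames(mut)),
            all(truth$effect_pairs$gene_id %in% genes))
  list(cohort = cohort, truth = truth)
}

#' Generate a synthetic drug-target table
#'
#' A configurable fraction of drug targets is drawn from the implanted
#' effect genes (so enrichment is recoverable); the rest are uniform over
#' the gene universe. A subset of drugs carries hematologic-malignancy
#' indication strings, the remainder solid-tumor indications.
#'
#' @param config a [simulation_config()].
#' @param truth the `synthetic_truth` from [generate_cohort()].
#' @param cohort the matching `multi_omics_cohort`.
#' @param n_drugs number of drugs.
#' @param targets_per_drug targets per drug.
#' @param enrich_fraction fraction of targets drawn from effect genes.
#' @param hematologic_fraction fraction of drugs given hematologic
#'   indications.
#' @return a data.frame with columns drug, target_gene, indication, status.
#' @export
generate_drug_table <- function(config, truth, cohort, n_drugs = 30,
                                targets_per_drug = 5, enrich_fraction = 0.5,
                                hematologic_fraction = 0.3) {
  genes <- rownames(cohort$expression)
  if (targets_per_drug > length(genes))
    stop("configuration error: requested target count exceeds gene universe")
  effect_genes <- unique(truth$effect_pairs$gene_id)
  hema_kw <- c("leukemia", "lymphatic leukemia", "multiple myeloma",
               "lymphoma", "leukemias and lymphomas",
               "hematologic malignancies")
  solid_ind <- c("colorectal cancer", "breast cancer", "prostate cancer",
                 "non-small cell lung cancer", "ovarian cancer")
  with_seed(config$seed + 101L, {
    rows <- lapply(seq_len(n_drugs), function(d) {
      n_enr <- stats::rbinom(1, targets_per_drug, enrich_fraction)
      n_enr <- min(n_enr, length(effect_genes))
      tg <- c(if (n_enr > 0) sample(effect_genes, n_enr) else character(0),
              sample(genes, targets_per_drug - n_enr))
      hema <- stats::runif(1) < hematologic_fraction
      ind <- if (hema) sample(hema_kw, 1) else sample(solid_ind, 1)
      data.frame(drug = sprintf("drug%02d", d), target_gene = unique(tg),
                 indication = ind, status = "approved",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `expression.tsv`, `methylation.tsv`, `scna.tsv` (genes x samples),
#' `mutations.maf.tsv` (MAF-like, one row per variant per carrier),
#' `clinical.tsv`, `genes.bed` (0-based half-open) and `truth.json`.
#'
#' @param cohort a `multi_omics_cohort`.
#' @param truth optional `synthetic_truth`.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, truth = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_mat <- function(m, f) {
    df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_mat(cohort$expression, "expression.tsv")
  write_mat(cohort$methylation, "methylation.tsv")
  write_mat(cohort$scna, "scna.tsv")

  maf <- maf_from_cohort(cohort)
  utils::write.table(maf, file.path(dir, "mutations.maf.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- data.frame(chrom = cohort$gene_intervals$chrom,
                    start = cohort$gene_intervals$start - 1L,
                    end = cohort$gene_intervals$end,
                    name = cohort$gene_intervals$gene)
  utils::write.table(bed, file.path(dir, "genes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(file.path(dir, c("expression.tsv", "methylation.tsv", "scna.tsv",
                             "mutations.maf.tsv", "clinical.tsv", "genes.bed",
                             "truth.json")))
}

## MAF-like long table from the cohort's mutation matrix + catalog
maf_from_cohort <- function(cohort) {
  mm <- cohort$mutation_matrix
  idx <- which(mm == 1L, arr.ind = TRUE)
  rec <- cohort$mutations[match(rownames(mm)[idx[, 1]],
                                cohort$mutations$snv_id), ]
  class_map <- c("missense" = "Missense_Mutation", "silent" = "Silent",
                 "nonsense" = "Nonsense_Mutation", "3'UTR" = "3'UTR",
                 "intron" = "Intron", "RNA" = "RNA",
                 "splice site" = "Splice_Site", "5'UTR" = "5'UTR")
  data.frame(
    Hugo_Symbol = rec$gene_locus,
    Chromosome = rec$chrom,
    Start_Position = rec$pos,
    Reference_Allele = rec$ref,
    Tumor_Seq_Allele2 = rec$alt,
    Variant_Classification = unname(class_map[rec$mutation_type]),
    Variant_Type = "SNP",
    Mutation_Status = "Somatic",
    Tumor_Sample_Barcode = colnames(mm)[idx[, 2]],
    stringsAsFactors = FALSE
  )
}
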