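#' Default pipeline configuration
#'
#' Thresholds of the full analysis: scan family-wise level, signature
#' selection level, co-occurrence overlap minimum, risk-score cutoff, ROC
#' horizon, consensus-clustering settings, and the simulation config used
#' by the `simulate` stage.
#'
#' @param simulation a [simulation_config()].
#' @param scan_alpha family-wise level of the Bonferroni scan flag.
#' @param signature_alpha selection level of the evidence layers.
#' @param min_overlap co-occurrence overlap minimum.
#' @param risk_cutoff minimum criterion score of a risk eSNV.
#' @param roc_horizon_years time-dependent ROC horizon in years.
#' @param consensus_k,consensus_iterations consensus clustering settings.
#' @param n_clusters mutational clusters (spherical k-means k).
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            scan_alpha = 0.05, signature_alpha = 0.05,
                            min_overlap = 10, risk_cutoff = 2,
                            roc_horizon_years = 10, consensus_k = 4,
                            consensus_iterations = 200, n_clusters = 3,
                            seed = 1) {
  stopifnot(scan_alpha > 0, scan_alpha < 1, signature_alpha > 0,
            signature_alpha < 1, min_overlap >= 0, risk_cutoff >= 0,
            risk_cutoff <= 7, roc_horizon_years > 0, consensus_k >= 2)
  structure(list(simulation = simulation, scan_alpha = scan_alpha,
                 signature_alpha = signature_alpha,
                 min_overlap = min_overlap, risk_cutoff = risk_cutoff,
                 roc_horizon_years = roc_horizon_years,
                 consensus_k = consensus_k,
                 consensus_iterations = consensus_iterations,
                 n_clusters = n_clusters, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates every stage end-to-end: cohort simulation, sample
#' intersection, two-step residual scan with genomic-control and cis/trans
#' annotation, driver ranking and eSNV prioritization, spherical k-means
#' clustering with clinical tests, survival analyses (cluster Cox fits,
#' time-dependent ROC, Uno's concordance), evidence integration into the
#' seven-criterion score, and drug-target enrichment. All randomness
#' derives from `config$seed`; identical configs give identical results.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, stage outputs and a JSON
#'   manifest are written as TSV/JSON files.
#' @return list with the per-stage results (`cohort`, `truth`, `scan`,
#'   `summary`, `drivers`, `prioritized`, `clusters`, `survival`,
#'   `evidence`, `repurposing`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  cfg <- config
  sim <- cfg$simulation
  sim$seed <- cfg$seed
  sim <- validate_simulation_config(sim)

  ## stage: simulate
  gen <- generate_cohort(sim)
  cohort <- gen$cohort
  truth <- gen$truth

  ## stage: associate (two-step scan on the regression layers)
  resid <- residualize(cohort)
  assoc <- esnv_scan(resid, cohort$mutation_matrix, alpha = cfg$scan_alpha)
  assoc <- classify_cis_trans(assoc, cohort$mutations,
                              cohort$gene_intervals)
  summary <- summarize_scan(assoc)

  ## stage: prioritize (network propagation + maxstat + known drivers)
  net <- toy_network(rownames(cohort$expression), seed = cfg$seed)
  diff_expr <- abs(cohort$expression)
  mm <- cohort$mutation_matrix
  locus_of <- cohort$mutations$gene_locus[match(rownames(mm),
                                                cohort$mutations$snv_id)]
  rankings <- lapply(colnames(mm), function(s) {
    mut_genes <- unique(locus_of[mm[, s] == 1L])
    r <- rank_patient(diff_expr[, s], mut_genes, net)
    if (nrow(r) >= 5) maxstat_split(r) else {
      r$driver <- rep(FALSE, nrow(r)); r
    }
  })
  names(rankings) <- colnames(mm)
  known <- unique(truth$effect_pairs$gene_id)
  drivers <- build_driver_gene_list(rankings, known)
  pri <- prioritize_esnvs(assoc, cohort$mutations, drivers)
  esnv_ids <- unique(pri$assoc$snv_id)
  driver_counts <- vapply(rankings, function(r) sum(r$driver), integer(1))
  burden <- driver_burden_tests(driver_counts, cohort$clinical)

  ## stage: cluster
  panel <- mm[esnv_ids, , drop = FALSE]
  clus <- spherical_kmeans(t(panel), k = cfg$n_clusters, seed = cfg$seed)
  clin_tests <- cluster_clinical_tests(clus, cohort$clinical,
                                       seed = cfg$seed)

  ## stage: survival
  cl <- cohort$clinical[match(names(clus$labels), cohort$clinical$sample), ]
  time_y <- cl$pfs_time / 365.25
  cluster_cox <- cox_fit(time_y, cl$pfs_event,
                         data.frame(cluster = factor(clus$labels)))
  marker <- attr(cluster_cox, "linear_predictor")
  tau <- min(cfg$roc_horizon_years, max(time_y))
  troc <- cumulative_dynamic_auc(marker, time_y, cl$pfs_event, tau = tau)
  uno <- uno_concordance(marker, time_y, cl$pfs_event, tau = tau)

  ## stage: score (evidence layers + 7 criteria)
  prog <- prognostic_signatures(panel, cohort$clinical,
                                alpha = cfg$signature_alpha)
  clsig <- cluster_signatures(panel, clus, alpha = cfg$signature_alpha)
  sig_assoc <- pri$assoc
  gene_sets <- split(sig_assoc$gene_id, sig_assoc$snv_id)
  universe <- rownames(cohort$expression)
  co <- NULL
  if (length(gene_sets) >= 2) {
    bm <- matrix(0, length(gene_sets), length(universe),
                 dimnames = list(names(gene_sets), universe))
    bm[cbind(match(sig_assoc$snv_id, names(gene_sets)),
             match(sig_assoc$gene_id, universe))] <- sig_assoc$beta
    cc <- consensus_cluster_esnvs(bm, k = min(cfg$consensus_k,
                                              nrow(bm) - 1),
                                  iterations = cfg$consensus_iterations,
                                  seed = cfg$seed)
    co <- cooccurrence_scan(gene_sets, universe, cc$clusters,
                            min_overlap = cfg$min_overlap)
  }
  screen <- bimodality_screen(cohort$raw_expression, seed = cfg$seed)
  sl <- sl_nominate(screen, panel, alpha = cfg$signature_alpha)
  evidence <- if (length(esnv_ids) > 0) {
    score_esnvs(esnv_ids, cohort$mutations,
                cis_esnvs = unique(sig_assoc$snv_id[sig_assoc$cis]),
                prognostic = prog$selected,
                cluster_related = clsig$selected,
                cooccurrence = co, sl_esnvs = unique(sl$snv_id),
                risk_cutoff = cfg$risk_cutoff)
  } else NULL

  ## stage: repurpose
  risk_esnvs <- if (!is.null(evidence))
    evidence$snv_id[evidence$risk] else character(0)
  risk_loci <- unique(cohort$mutations$gene_locus[
    cohort$mutations$snv_id %in% risk_esnvs])
  risk_corr <- unique(sig_assoc$gene_id[sig_assoc$snv_id %in% risk_esnvs])
  query <- unique(c(risk_loci, risk_corr))
  drug_table <- generate_drug_table(sim, truth, cohort)
  profile <- classify_indications(drug_table)
  repurposing <- NULL
  if (length(query) > 0) {
    solid <- drug_enrichment(query, profile$solid_targets,
                             length(universe))
    hema <- drug_enrichment(query, profile$hematologic_targets,
                            length(universe))
    repurposing <- list(solid = solid, hematologic = hema,
                        cross = cross_class_overlap(solid, hema),
                        query_size = length(query))
  }

  result <- list(config = cfg, cohort = cohort, truth = truth,
                 residuals = resid, scan = assoc, summary = summary,
                 rankings = rankings, drivers = drivers,
                 prioritized = pri, burden = burden, clusters = clus,
                 clinical_tests = clin_tests,
                 survival = list(cluster_cox = cluster_cox,
                                 time_roc = troc, uno_c = uno),
                 prognostic = prog, cluster_signatures = clsig,
                 cooccurrence = co, sl_pairs = sl, evidence = evidence,
                 repurposing = repurposing)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Run a single pipeline stage by name
#'
#' Thin dispatcher over [run_pipeline()]: runs the pipeline up to and
#' including the requested stage and returns that stage's outputs.
#' Stages: simulate, associate, prioritize, cluster, survival, score,
#' repurpose, all.
#'
#' @param stage stage name.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (only used for "all").
#' @return the stage's result object.
#' @export
run_stage <- function(stage = c("all", "simulate", "associate",
                                "prioritize", "cluster", "survival",
                                "score", "repurpose"),
                      config = pipeline_config(), out_dir = NULL) {
  stage <- match.arg(stage)
  if (stage == "simulate") {
    sim <- config$simulation; sim$seed <- config$seed
    return(generate_cohort(validate_simulation_config(sim)))
  }
  res <- run_pipeline(config, out_dir = if (stage == "all") out_dir else NULL)
  switch(stage,
    all = res,
    associate = list(scan = res$scan, summary = res$summary),
    prioritize = list(drivers = res$drivers, prioritized = res$prioritized,
                      burden = res$burden),
    cluster = list(clusters = res$clusters,
                   clinical_tests = res$clinical_tests),
    survival = res$survival,
    score = list(evidence = res$evidence, cooccurrence = res$cooccurrence,
                 sl_pairs = res$sl_pairs),
    repurpose = res$repurposing)
}

#' Write pipeline outputs and a JSON manifest to a directory
#'
#' @param result the list returned by [run_pipeline()].
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest path.
#' @export
write_pipeline_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_associations(result$scan, file.path(dir, "associations.tsv"))
  utils::write.table(
    data.frame(sample = names(result$clusters$labels),
               cluster = unname(result$clusters$labels)),
    file.path(dir, "clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(result$evidence)) {
    utils::write.table(as.data.frame(result$evidence),
                       file.path(dir, "evidence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(qq_data(result$scan$p), file.path(dir, "qq.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(result$survival$time_roc),
                     file.path(dir, "time_roc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    seed = result$config$seed,
    package_version = as.character(utils::packageVersion("mutexpress")),
    n_samples = ncol(result$cohort$expression),
    n_genes = nrow(result$cohort$expression),
    n_snvs = nrow(result$cohort$mutation_matrix),
    n_pairs_tested = result$summary$n_pairs_tested,
    n_significant = result$summary$n_significant,
    lambda_gc = result$summary$lambda_gc,
    n_driver_esnvs = result$prioritized$counts$n_esnvs,
    uno_c = result$survival$uno_c,
    files = c("associations.tsv", "clusters.tsv", "evidence.tsv",
              "qq.tsv", "time_roc.tsv")
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
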