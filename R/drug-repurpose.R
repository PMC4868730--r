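HEMATOLOGIC_KEYWORDS <- c("leukemia", "lymphatic leukemia",
                          "multiple myeloma", "lymphoma",
                          "leukemias and lymphomas",
                          "hematologic malignancies")

#' Split a drug table into solid- and hematologic-tumor target profiles
#'
#' A drug is classed hematologic when any of its indication strings
#' contains one of the keywords (case-insensitive substring); all
#' remaining drugs, including those with missing indications (warned),
#' build the solid-tumor profile. Per class, the union of target genes is
#' collected.
#'
#' @param drug_table data.frame (drug, target_gene, indication, status);
#'   only rows with status "approved" are used.
#' @param keywords hematologic indication keywords.
#' @return object of class `drug_target_profile`: list with `drugs`
#'   (drug -> class), `solid_targets`, `hematologic_targets`.
#' @export
classify_indications <- function(drug_table,
                                 keywords = HEMATOLOGIC_KEYWORDS) {
  dt <- drug_table[drug_table$status == "approved", , drop = FALSE]
  drugs <- unique(dt$drug)
  pat <- paste(keywords, collapse = "|")
  cls <- vapply(drugs, function(d) {
    ind <- dt$indication[dt$drug == d]
    ind <- ind[!is.na(ind) & nzchar(ind)]
    if (length(ind) == 0) {
      warning("drug without indication classed solid: ", d)
      return("solid")
    }
    if (any(grepl(pat, tolower(ind), fixed = FALSE))) "hematologic"
    else "solid"
  }, character(1))
  names(cls) <- drugs
  tg <- function(class) sort(unique(
    dt$target_gene[dt$drug %in% drugs[cls == class]]))
  structure(list(drugs = cls, solid_targets = tg("solid"),
                 hematologic_targets = tg("hematologic")),
            class = "drug_target_profile")
}

#' Hypergeometric enrichment of a query gene set in a drug-target profile
#'
#' Upper-tail hypergeometric probability of observing at least the actual
#' overlap between the query genes and the class target genes, drawing
#' `|query|` genes from a universe of `universe_size`.
#'
#' @param query character vector of query genes.
#' @param targets character vector of class target genes.
#' @param universe_size size of the gene universe (must be at least the
#'   target count and the query size).
#' @return list of class `enrichment_result`: overlap genes and count,
#'   class target count, query size, universe size, hypergeometric p,
#'   overlap percentage (of the class target count).
#' @export
drug_enrichment <- function(query, targets, universe_size) {
  query <- unique(query)
  targets <- unique(targets)
  if (universe_size < length(query))
    stop("universe smaller than the query set")
  if (universe_size < length(targets))
    stop("universe smaller than the target set")
  overlap <- intersect(query, targets)
  k <- length(overlap)
  p <- stats::phyper(k - 1, length(targets),
                     universe_size - length(targets), length(query),
                     lower.tail = FALSE)
  structure(list(
    overlap_genes = sort(overlap), overlap = k,
    n_targets = length(targets), n_query = length(query),
    universe_size = universe_size, p = p,
    overlap_pct = if (length(targets) > 0) 100 * k / length(targets) else 0
  ), class = "enrichment_result")
}

#' Overlap between solid- and hematologic-profile enrichment hits
#'
#' Reports genes shared between the two overlap lists, the fraction of
#' the hematologic overlap that is shared, and a hypergeometric p for
#' that sharing against the two class gene sets.
#'
#' @param solid,hematologic `enrichment_result` objects.
#' @return list: shared genes, fraction of the hematologic overlap shared,
#'   hypergeometric p.
#' @export
cross_class_overlap <- function(solid, hematologic) {
  shared <- intersect(solid$overlap_genes, hematologic$overlap_genes)
  frac <- if (hematologic$overlap > 0)
    length(shared) / hematologic$overlap else 0
  p <- stats::phyper(length(shared) - 1, solid$n_targets,
                     solid$universe_size - solid$n_targets,
                     hematologic$n_targets, lower.tail = FALSE)
  list(shared_genes = sort(shared), fraction_of_hematologic = frac, p = p)
}
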