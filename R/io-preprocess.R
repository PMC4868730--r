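#' Read a genes-x-samples matrix from TSV
#'
#' Expects a header row of sample IDs and a first column of gene symbols.
#'
#' @param path file path.
#' @return a numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a MAF-like somatic mutation table
#'
#' Required columns: Hugo_Symbol, Chromosome, Start_Position,
#' Reference_Allele, Tumor_Seq_Allele2, Variant_Classification,
#' Tumor_Sample_Barcode. Optional: Variant_Type, Mutation_Status (used by
#' [sanitize_mutations()]).
#'
#' @param path file path.
#' @return a data.frame, one row per variant per carrier.
#' @export
read_maf <- function(path) {
  maf <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("Hugo_Symbol", "Chromosome", "Start_Position", "Reference_Allele",
            "Tumor_Seq_Allele2", "Variant_Classification",
            "Tumor_Sample_Barcode")
  miss <- setdiff(need, names(maf))
  if (length(miss) > 0)
    stop("MAF file is missing columns: ", paste(miss, collapse = ", "))
  maf
}

#' Read gene intervals from a BED file
#'
#' BED is 0-based half-open; intervals are converted to the 1-based
#' inclusive convention used internally.
#'
#' @param path file path (chrom, start, end, name; no header).
#' @return data.frame with columns gene, chrom, start, end (1-based).
#' @export
read_gene_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(gene = bed[[4]], chrom = parse_chrom(bed[[1]]),
             start = bed[[2]] + 1L, end = bed[[3]],
             stringsAsFactors = FALSE)
}

#' Read a clinical table
#' @param path TSV with columns sample, stage, histology, grade, pfs_time,
#'   pfs_event.
#' @return data.frame.
#' @export
read_clinical_tsv <- function(path) {
  cl <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (any(cl$pfs_time < 0)) stop("negative pfs_time in clinical table")
  cl
}

## "1".."22", "23", "X" -> 23; anything else -> NA
parse_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x))
  out <- suppressWarnings(as.integer(x))
  out[x %in% c("X", "x")] <- 23L
  out[!is.na(out) & (out < 1L | out > 23L)] <- NA_integer_
  out
}

#' Standardize tumor profiles against a pool of matched normals
#'
#' For each gene, returns `|tumor - mean(normal)| / sd(normal)`: the
#' absolute z-score of each tumor sample relative to the normal pool, the
#' "standardized absolute differential" representation consumed by the
#' association scan. Genes with zero normal-pool variance (or absent from
#' the normal matrix) are dropped and reported via attribute
#' `"dropped_genes"`.
#'
#' @param tumor,normal genes-x-samples matrices sharing gene symbols.
#' @return matrix over the retained genes; nonnegative everywhere.
#' @export
normalize_vs_normal <- function(tumor, normal) {
  if (is.null(normal) || ncol(normal) == 0)
    stop("no normal samples available for standardization")
  common <- intersect(rownames(tumor), rownames(normal))
  if (length(common) == 0) {
    stop("tumor and normal matrices share no genes; missing from normal: ",
         paste(utils::head(setdiff(rownames(tumor), rownames(normal)), 5),
               collapse = ", "))
  }
  if (ncol(normal) < 2)
    stop("need >= 2 normal samples to estimate a gene-wise sd")
  tm <- tumor[common, , drop = FALSE]
  nm <- normal[common, , drop = FALSE]
  mu <- rowMeans(nm)
  sdv <- apply(nm, 1, stats::sd)
  keep <- is.finite(sdv) & sdv > 0
  out <- abs(tm[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  attr(out, "dropped_genes") <- common[!keep]
  out
}

#' Aggregate probe-level methylation to gene level
#'
#' A probe mapping to several genes contributes to each of them; the
#' gene-level value is the mean beta over probes whose distance to the
#' transcription start site is at most `window` bp. Genes with no
#' qualifying probe are absent from the output.
#'
#' @param probe_betas probes-x-samples matrix of beta values.
#' @param probe_map data.frame with columns probe, gene, tss_distance
#'   (nonnegative bp); one row per probe-gene assignment.
#' @param window maximum TSS distance in bp (default 1500).
#' @return genes-x-samples matrix.
#' @export
gene_level_methylation <- function(probe_betas, probe_map, window = 1500) {
  if (is.null(probe_map) || nrow(probe_map) == 0)
    stop("empty probe map")
  if (any(probe_map$tss_distance < 0))
    stop("tss_distance must be nonnegative")
  pm <- probe_map[probe_map$tss_distance <= window &
                    probe_map$probe %in% rownames(probe_betas), ,
                  drop = FALSE]
  if (nrow(pm) == 0) return(matrix(numeric(0), 0, ncol(probe_betas)))
  genes <- sort(unique(pm$gene))
  out <- matrix(NA_real_, length(genes), ncol(probe_betas),
                dimnames = list(genes, colnames(probe_betas)))
  for (g in genes) {
    pr <- pm$probe[pm$gene == g]
    out[g, ] <- colMeans(probe_betas[pr, , drop = FALSE])
  }
  out
}

#' Default MHC exclusion interval (chromosome 6, hg19 convention)
#' @return list with chrom, start, end (1-based inclusive).
#' @export
mhc_interval <- function() list(chrom = 6L, start = 28477797L, end = 33448354L)

#' Sanitize a somatic mutation catalog
#'
#' Applies the standard filtering rules before association scanning:
#' removes indels (Variant_Type != SNP), non-somatic calls, variants
#' outside chromosomes 1-23, singleton ("sole") variants carried by fewer
#' than `min_carriers` samples, and variants falling inside the MHC
#' exclusion interval. Malformed rows are collected into a rejects report
#' rather than raising.
#'
#' @param maf MAF-like data.frame from [read_maf()].
#' @param mhc exclusion interval as from [mhc_interval()]; `NULL` disables.
#' @param min_carriers minimum carrier count (default 2; carriers below
#'   this are the "sole SNV" rule).
#' @return list with elements `records` (per-SNV catalog: snv_id, chrom,
#'   pos, ref, alt, gene_locus, mutation_type), `matrix` (SNV x sample
#'   binary), `removed` (named counts per rule), `rejects` (malformed rows).
#' @export
sanitize_mutations <- function(maf, mhc = mhc_interval(), min_carriers = 2) {
  chrom <- parse_chrom(maf$Chromosome)
  pos <- suppressWarnings(as.integer(maf$Start_Position))
  malformed <- is.na(pos) | pos < 1L
  rejects <- maf[malformed, , drop = FALSE]
  removed <- c(malformed = sum(malformed), indel = 0L, germline = 0L,
               chrom = 0L, sole = 0L, mhc = 0L)
  keep <- !malformed

  if ("Variant_Type" %in% names(maf)) {
    bad <- keep & maf$Variant_Type != "SNP"
    removed["indel"] <- sum(bad); keep <- keep & !bad
  }
  if ("Mutation_Status" %in% names(maf)) {
    bad <- keep & maf$Mutation_Status != "Somatic"
    removed["germline"] <- sum(bad); keep <- keep & !bad
  }
  bad <- keep & is.na(chrom)
  removed["chrom"] <- sum(bad); keep <- keep & !bad

  df <- maf[keep, , drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]
  snv_id <- sprintf("%d:%d", chrom, pos)

  ## sole-SNV rule on distinct carriers
  carriers <- tapply(df$Tumor_Sample_Barcode, snv_id,
                     function(s) length(unique(s)))
  sole <- names(carriers)[carriers < min_carriers]
  removed["sole"] <- length(sole)
  drop_row <- snv_id %in% sole
  df <- df[!drop_row, , drop = FALSE]
  chrom <- chrom[!drop_row]; pos <- pos[!drop_row]
  snv_id <- snv_id[!drop_row]

  if (!is.null(mhc)) {
    in_mhc <- chrom == mhc$chrom & pos >= mhc$start & pos <= mhc$end
    removed["mhc"] <- length(unique(snv_id[in_mhc]))
    df <- df[!in_mhc, , drop = FALSE]
    chrom <- chrom[!in_mhc]; pos <- pos[!in_mhc]
    snv_id <- snv_id[!in_mhc]
  }

  type_map <- c("Missense_Mutation" = "missense", "Silent" = "silent",
                "Nonsense_Mutation" = "nonsense", "3'UTR" = "3'UTR",
                "Intron" = "intron", "RNA" = "RNA",
                "Splice_Site" = "splice site", "5'UTR" = "5'UTR")
  mtype <- unname(type_map[df$Variant_Classification])
  mtype[is.na(mtype)] <- df$Variant_Classification[is.na(mtype)]

  first <- !duplicated(snv_id)
  records <- data.frame(
    snv_id = snv_id[first], chrom = chrom[first], pos = pos[first],
    ref = df$Reference_Allele[first], alt = df$Tumor_Seq_Allele2[first],
    gene_locus = df$Hugo_Symbol[first], mutation_type = mtype[first],
    stringsAsFactors = FALSE
  )
  records <- records[order(records$chrom, records$pos), , drop = FALSE]
  rownames(records) <- NULL

  samples <- sort(unique(df$Tumor_Sample_Barcode))
  m <- matrix(0L, nrow(records), length(samples),
              dimnames = list(records$snv_id, samples))
  if (nrow(df) > 0)
    m[cbind(match(snv_id, records$snv_id),
            match(df$Tumor_Sample_Barcode, samples))] <- 1L

  list(records = records, matrix = m, removed = removed, rejects = rejects)
}

#' Drop genes inside the MHC exclusion interval from a matrix
#' @param mat genes-x-samples matrix.
#' @param gene_intervals data.frame (gene, chrom, start, end, 1-based).
#' @param mhc interval as from [mhc_interval()].
#' @return the matrix without MHC genes.
#' @export
drop_mhc_genes <- function(mat, gene_intervals, mhc = mhc_interval()) {
  gi <- gene_intervals[match(rownames(mat), gene_intervals$gene), ]
  in_mhc <- !is.na(gi$chrom) & gi$chrom == mhc$chrom &
    gi$end >= mhc$start & gi$start <= mhc$end
  mat[!in_mhc, , drop = FALSE]
}

#' Intersect samples across omic layers
#'
#' Builds the two working cohorts of the pipeline: the *full* cohort of
#' samples with expression + mutation + clinical data (used for
#' clustering and survival) and the *regression* cohort additionally
#' covered by methylation and copy number (used for the two-step scan).
#' Sample order is lexicographic in both.
#'
#' @param expression genes-x-samples matrix (relative expression).
#' @param methylation,scna genes-x-samples matrices (may cover fewer
#'   samples).
#' @param mutation_matrix SNV-x-sample binary matrix.
#' @param mutations per-SNV catalog (as from [sanitize_mutations()]).
#' @param clinical clinical data.frame with a `sample` column.
#' @param gene_intervals gene interval data.frame.
#' @param raw_expression optional raw abundance matrix.
#' @return list with elements `full` and `regression`, both
#'   `multi_omics_cohort` objects (the full cohort has empty methylation
#'   and scna slots).
#' @export
intersect_layers <- function(expression, methylation, scna, mutation_matrix,
                             mutations, clinical, gene_intervals,
                             raw_expression = NULL) {
  full_samples <- sort(Reduce(intersect, list(
    colnames(expression), colnames(mutation_matrix), clinical$sample)))
  if (length(full_samples) == 0)
    stop("empty sample intersection between expression, mutations and clinical")
  reg_samples <- sort(Reduce(intersect, list(
    full_samples, colnames(methylation), colnames(scna))))
  if (length(reg_samples) == 0)
    stop("empty sample intersection for the regression cohort")

  common_genes <- sort(Reduce(intersect, list(
    rownames(expression), rownames(methylation), rownames(scna))))

  make <- function(samples, genes, with_det) {
    structure(list(
      expression = expression[genes, samples, drop = FALSE],
      methylation = if (with_det) methylation[genes, samples, drop = FALSE] else NULL,
      scna = if (with_det) scna[genes, samples, drop = FALSE] else NULL,
      mutation_matrix = mutation_matrix[, samples, drop = FALSE],
      mutations = mutations,
      clinical = clinical[match(samples, clinical$sample), , drop = FALSE],
      gene_intervals = gene_intervals,
      raw_expression = if (!is.null(raw_expression))
        raw_expression[, samples, drop = FALSE] else NULL,
      samples = samples
    ), class = "multi_omics_cohort")
  }
  list(full = make(full_samples, sort(rownames(expression)), FALSE),
       regression = make(reg_samples, common_genes, TRUE))
}

#' Read a cohort back from files written by [write_cohort()]
#' @param dir directory containing the cohort files.
#' @return list with `full` and `regression` cohorts, via
#'   [intersect_layers()].
#' @export
read_cohort <- function(dir) {
  expr <- read_matrix_tsv(file.path(dir, "expression.tsv"))
  meth <- read_matrix_tsv(file.path(dir, "methylation.tsv"))
  scna <- read_matrix_tsv(file.path(dir, "scna.tsv"))
  maf <- read_maf(file.path(dir, "mutations.maf.tsv"))
  clin <- read_clinical_tsv(file.path(dir, "clinical.tsv"))
  gi <- read_gene_bed(file.path(dir, "genes.bed"))
  san <- sanitize_mutations(maf)
  intersect_layers(expr, meth, scna, san$matrix, san$records, clin, gi)
}
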