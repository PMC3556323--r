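#' @importFrom stats t.test p.adjust
NULL

## ---------------------------------------------------------------------------
## Differential-expression contrasts over the 2x2 genotype x treatment design
## and the eight-way response-type classification.
##
## Contrasts (A vs B, per gene, on log2 values):
##   ligand_wt   wt+ligand    vs wt+vehicle
##   genotype    null+vehicle vs wt+vehicle
##   ligand_null null+ligand  vs null+vehicle
## ---------------------------------------------------------------------------

CONTRASTS <- list(
  ligand_wt   = list(A = c("wt", "ligand"),      B = c("wt", "vehicle")),
  genotype    = list(A = c("null", "vehicle"),   B = c("wt", "vehicle")),
  ligand_null = list(A = c("null", "ligand"),    B = c("null", "vehicle"))
)

#' Classifier thresholds
#'
#' The defaults are the fold-change and FDR cutoffs used to call a contrast
#' significant: fold change >= 1.3 and BH q-value <= 0.25.
#'
#' @param fc_min minimum fold change (linear, > 1).
#' @param fdr_max maximum BH q-value.
#' @export
response_thresholds <- function(fc_min = 1.3, fdr_max = 0.25) {
  if (fc_min <= 1) stop("fc_min must exceed 1", call. = FALSE)
  if (fdr_max <= 0 || fdr_max >= 1) stop("fdr_max must be in (0, 1)", call. = FALSE)
  structure(list(fc_min = fc_min, fdr_max = fdr_max), class = "response_thresholds")
}

#' Read an expression matrix and sample sheet
#'
#' The matrix TSV has gene ids in the first column and one column per
#' sample; the sample sheet TSV has columns `sample`, `genotype`
#' (`wt`/`null`), `treatment` (`vehicle`/`ligand`), `replicate`.
#'
#' @param matrix_path,design_path file paths.
#' @return list with `matrix` (numeric, genes x samples) and `design`.
#' @export
read_expression <- function(matrix_path, design_path) {
  dt <- data.table::fread(matrix_path, header = TRUE, sep = "\t")
  mat <- as.matrix(dt[, -1])
  rownames(mat) <- as.character(dt[[1]])
  design <- as.data.frame(data.table::fread(design_path, header = TRUE, sep = "\t"))
  if (!all(c("sample", "genotype", "treatment", "replicate") %in% names(design)))
    stop("sample sheet must have sample, genotype, treatment, replicate", call. = FALSE)
  if (!all(colnames(mat) %in% design$sample))
    stop("matrix columns missing from sample sheet", call. = FALSE)
  design <- design[match(colnames(mat), design$sample), ]
  if (anyNA(mat)) stop("expression matrix contains missing values", call. = FALSE)
  list(matrix = mat, design = design)
}

#' Write an expression matrix and sample sheet
#' @param mat genes x samples matrix.
#' @param design sample sheet data.frame.
#' @param matrix_path,design_path output paths.
#' @export
write_expression <- function(mat, design, matrix_path, design_path) {
  dt <- data.table::data.table(gene_id = rownames(mat))
  for (j in colnames(mat)) dt[[j]] <- mat[, j]
  data.table::fwrite(dt, matrix_path, sep = "\t")
  data.table::fwrite(design, design_path, sep = "\t")
  invisible(matrix_path)
}

design_columns <- function(design, genotype, treatment) {
  which(design$genotype == genotype & design$treatment == treatment)
}

#' Per-gene differential-expression statistics for one contrast
#'
#' Computes, per gene, the log2 difference of group means, the linear fold
#' change `2^|delta|` with its direction, a two-sided Welch t-test p-value
#' on the log2 values, and BH q-values across all genes in the contrast.
#' Genes with zero variance in both groups get `p = 1` when the difference
#' is zero and `p = 0` (with a warning) otherwise.
#'
#' @param mat log2 expression matrix (genes x samples).
#' @param design sample sheet (see [read_expression()]).
#' @param contrast one of `"ligand_wt"`, `"genotype"`, `"ligand_null"`, or a
#'   list `list(A = c(genotype, treatment), B = c(genotype, treatment))`.
#' @return data.frame: `gene_id`, `contrast`, `delta` (log2 A - B),
#'   `fold_change`, `direction` (`up`/`down`/`none`), `p`, `q`.
#' @export
contrast_stats <- function(mat, design, contrast) {
  if (is.character(contrast)) {
    label <- contrast
    contrast <- CONTRASTS[[contrast]]
    if (is.null(contrast)) stop("unknown contrast '", label, "'", call. = FALSE)
  } else label <- "custom"
  ia <- design_columns(design, contrast$A[1], contrast$A[2])
  ib <- design_columns(design, contrast$B[1], contrast$B[2])
  if (length(ia) < 2 || length(ib) < 2)
    stop("each contrast group needs >= 2 replicates", call. = FALSE)
  A <- mat[, ia, drop = FALSE]
  B <- mat[, ib, drop = FALSE]
  delta <- rowMeans(A) - rowMeans(B)
  va <- apply(A, 1, stats::var)
  vb <- apply(B, 1, stats::var)
  p <- numeric(nrow(mat))
  degenerate <- va == 0 & vb == 0
  if (any(degenerate & delta != 0))
    warning("zero within-group variance with a nonzero difference; p set to 0")
  p[degenerate] <- ifelse(delta[degenerate] == 0, 1, 0)
  idx <- which(!degenerate)
  p[idx] <- vapply(idx, function(i)
    t.test(A[i, ], B[i, ], var.equal = FALSE)$p.value, 0)
  data.frame(gene_id = rownames(mat),
             contrast = label,
             delta = delta,
             fold_change = 2^abs(delta),
             direction = ifelse(delta > 0, "up", ifelse(delta < 0, "down", "none")),
             p = p,
             q = bh_adjust(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, with input checks;
#' q-values are returned in input order and clipped at 1.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

significant_call <- function(cr, thresholds) {
  sig <- cr$fold_change >= thresholds$fc_min & cr$q <= thresholds$fdr_max
  ifelse(sig & cr$direction == "up", "up",
         ifelse(sig & cr$direction == "down", "down", "none"))
}

#' Classify genes into the eight response types
#'
#' The constitutive call comes from the genotype contrast (knockout vs
#' wild-type, vehicle): significant *up* in the knockout means the receptor
#' represses the gene ("repressed"); significant *down* means it activates
#' ("activated"). The ligand call comes from the wild-type ligand contrast
#' and requires the same contrast in knockout cells to be non-significant
#' (a receptor-dependent ligand response): up = "activated", down =
#' "repressed". Types: I repressed-only, II activated-only, III
#' ligand-activated-only, IV ligand-repressed-only, V repressed +
#' ligand-activated, VI activated + ligand-repressed, VII activated +
#' ligand-activated, VIII repressed + ligand-repressed; anything else is
#' `none`. Genes whose ligand response is also present in knockout cells are
#' flagged in `ligand_response_in_null`.
#'
#' @param ligand_wt,genotype,ligand_null [contrast_stats()] results for the
#'   same genes in the same order.
#' @param thresholds a [response_thresholds()].
#' @return data.frame: `gene_id`, `constitutive` (repressed/activated/none),
#'   `ligand` (activated/repressed/none), `type` (I..VIII or none),
#'   `ligand_response_in_null` (logical).
#' @export
classify_genes <- function(ligand_wt, genotype, ligand_null,
                           thresholds = response_thresholds()) {
  if (!(identical(ligand_wt$gene_id, genotype$gene_id) &&
        identical(genotype$gene_id, ligand_null$gene_id)))
    stop("contrasts must cover the same genes in the same order", call. = FALSE)
  geno <- significant_call(genotype, thresholds)
  lw <- significant_call(ligand_wt, thresholds)
  ln <- significant_call(ligand_null, thresholds)

  constitutive <- ifelse(geno == "up", "repressed",
                         ifelse(geno == "down", "activated", "none"))
  lig_dependent <- ln == "none"
  ligand <- ifelse(lw == "up" & lig_dependent, "activated",
                   ifelse(lw == "down" & lig_dependent, "repressed", "none"))

  key <- paste(constitutive, ligand, sep = "/")
  map <- c("repressed/none" = "I", "activated/none" = "II",
           "none/activated" = "III", "none/repressed" = "IV",
           "repressed/activated" = "V", "activated/repressed" = "VI",
           "activated/activated" = "VII", "repressed/repressed" = "VIII",
           "none/none" = "none")
  data.frame(gene_id = ligand_wt$gene_id,
             constitutive = constitutive,
             ligand = ligand,
             type = unname(map[key]),
             ligand_response_in_null = lw != "none" & !lig_dependent,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run all three contrasts and classify every gene
#'
#' @param mat log2 expression matrix (genes x samples).
#' @param design sample sheet.
#' @param thresholds a [response_thresholds()].
#' @return list of class `response_classification`: `assignments` (per-gene
#'   calls and all three contrasts' statistics), `counts` (named per-type
#'   gene counts, I..VIII then none), and `switch_ratio` (per mixed type V
#'   and VI, the mean over genes of the linear ratio of the wild-type ligand
#'   response to the knockout constitutive response).
#' @export
classify_all <- function(mat, design, thresholds = response_thresholds()) {
  crs <- lapply(names(CONTRASTS), function(nm) contrast_stats(mat, design, nm))
  names(crs) <- names(CONTRASTS)
  cls <- classify_genes(crs$ligand_wt, crs$genotype, crs$ligand_null, thresholds)
  for (nm in names(crs)) {
    for (col in c("fold_change", "p", "q")) {
      cls[[paste(nm, col, sep = "_")]] <- crs[[nm]][[col]]
    }
  }
  counts <- table(factor(cls$type, levels = c(RESPONSE_TYPES, "none")))
  counts <- setNames(as.integer(counts), names(counts))
  ratio <- vapply(c(V = "V", VI = "VI"), function(tp) {
    g <- cls$type == tp
    if (!any(g)) return(NA_real_)
    mean(2^(crs$ligand_wt$delta[g] - crs$genotype$delta[g]))
  }, 0)
  structure(list(assignments = cls, counts = counts, switch_ratio = ratio,
                 thresholds = thresholds),
            class = "response_classification")
}

#' @export
print.response_classification <- function(x, ...) {
  n_de <- sum(x$counts[RESPONSE_TYPES])
  cat("Response-type classification: ", n_de, " differentially expressed of ",
      sum(x$counts), " genes (fc >= ", x$thresholds$fc_min,
      ", q <= ", x$thresholds$fdr_max, ")\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Aggregate statistics over per-type gene counts
#'
#' From named per-type counts (`I`..`VIII`, optionally `none`), computes the
#' totals and percentages used to summarize an eight-type classification:
#' the count and share of the four major types (I-IV), the mixed types
#' (V-VIII), the ligand-dependent types (III-IV), and the constitutive
#' (I + II) and ligand (III + IV) totals.
#'
#' @param counts named integer vector of per-type counts.
#' @return list with `total`, `constitutive_n`, `ligand_n`, `mixed_n`,
#'   `major_pct`, `mixed_pct`, `ligand_pct`, and `pct_of_total(n)` helper
#'   values are plain numbers (percent scale).
#' @export
summarize_response_counts <- function(counts) {
  stopifnot(all(RESPONSE_TYPES %in% names(counts)))
  cc <- counts[RESPONSE_TYPES]
  total <- sum(cc)
  major <- sum(cc[c("I", "II", "III", "IV")])
  mixed <- sum(cc[c("V", "VI", "VII", "VIII")])
  list(total = total,
       constitutive_n = unname(cc[["I"]] + cc[["II"]]),
       ligand_n = unname(cc[["III"]] + cc[["IV"]]),
       mixed_n = unname(mixed),
       major_pct = 100 * major / total,
       mixed_pct = 100 * mixed / total,
       ligand_pct = 100 * (cc[["III"]] + cc[["IV"]]) / total)
}

#' Sequencing run summary arithmetic
#'
#' Recomputes, per sample, the totals and percentages of a two-run
#' sequencing summary table: total reads = run1 + run2, percent passing
#' quality control = 100 * QC-passed / total, and percent mapped =
#' 100 * mapped / QC-passed.
#'
#' @param runs data.frame with columns `sample`, `reads_run1`, `reads_run2`,
#'   `qc_passed_reads`, `mapped_reads`.
#' @return data.frame with `sample`, `total_reads`, `pct_qc_passed`,
#'   `pct_mapped`.
#' @export
sequencing_run_summary <- function(runs) {
  total <- runs$reads_run1 + runs$reads_run2
  data.frame(sample = runs$sample,
             total_reads = total,
             pct_qc_passed = 100 * runs$qc_passed_reads / total,
             pct_mapped = 100 * runs$mapped_reads / runs$qc_passed_reads,
             row.names = NULL, stringsAsFactors = FALSE)
}
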