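## ---------------------------------------------------------------------------
## Peak-to-gene integration: nearest-TSS assignment, the +/- 10 kb direct-
## target rule, occupancy set algebra, and TSS distance profiles.
## ---------------------------------------------------------------------------

#' Assign each peak to its nearest TSS
#'
#' Distance is measured from the peak midpoint to the strand-resolved TSS;
#' each peak goes to the gene minimizing `|midpoint - tss|` among genes on
#' its chromosome, ties broken by lexicographically smallest `gene_id`. The
#' signed distance is positive when the peak lies downstream of the TSS in
#' the gene's reading direction, negative upstream. Peaks on chromosomes
#' without genes get `gene_id = NA` and infinite distance.
#'
#' @param peaks peak `GRanges`.
#' @param genes gene models `GRanges`.
#' @return data.frame: `peak` (index into `peaks`), `chrom`, `midpoint`
#'   (0-based), `gene_id`, `distance` (signed bp), `abs_distance`.
#' @export
assign_peaks_to_tss <- function(peaks, genes) {
  tss <- gene_tss(genes)
  gchrom <- as.character(seqnames(genes))
  gstrand <- as.character(strand(genes))
  by_chrom <- split(seq_along(genes), gchrom)
  # 0-based midpoint of [start0, end0): floor((start0 + end0) / 2)
  mid <- floor((start(peaks) - 1 + end(peaks)) / 2)
  pchrom <- as.character(seqnames(peaks))
  out_gene <- rep(NA_character_, length(peaks))
  out_dist <- rep(Inf, length(peaks))
  for (ch in unique(pchrom)) {
    gi <- by_chrom[[ch]]
    if (is.null(gi)) next
    t <- tss[gi]
    ids <- genes$gene_id[gi]
    str <- gstrand[gi]
    o <- order(t, ids)
    t <- t[o]; ids <- ids[o]; str <- str[o]
    pk <- which(pchrom == ch)
    for (i in pk) {
      m <- mid[i]
      d <- abs(t - m)
      dmin <- min(d)
      cand <- which(d == dmin)
      j <- cand[order(ids[cand])[1]]
      out_gene[i] <- ids[j]
      out_dist[i] <- if (str[j] == "+") m - t[j] else t[j] - m
    }
  }
  data.frame(peak = seq_along(peaks),
             chrom = pchrom,
             midpoint = mid,
             gene_id = out_gene,
             distance = out_dist,
             abs_distance = abs(out_dist),
             row.names = NULL, stringsAsFactors = FALSE)
}

occupied_genes <- function(assignments, window_bp) {
  unique(assignments$gene_id[!is.na(assignments$gene_id) &
                               assignments$abs_distance <= window_bp])
}

#' Intersection size by inclusion-exclusion
#'
#' `|A intersect B| = |A| + |B| - |A union B|`.
#'
#' @param n_a,n_b,n_union set sizes.
#' @return intersection size.
#' @export
intersect_size_from_union <- function(n_a, n_b, n_union) {
  n_a + n_b - n_union
}

#' Direct-target sets with and without ligand
#'
#' A direct target is a differentially expressed gene (response type not
#' `none`) with at least one assigned peak within `window_bp` of its TSS.
#' Set A uses the without-ligand peak assignments, set B the with-ligand
#' ones. The summary reports |A|, |B|, |A union B| and the intersection both
#' counted directly and via inclusion-exclusion, plus a per-type breakdown
#' of occupancy (without-only / with-only / both).
#'
#' @param assignments_without,assignments_with [assign_peaks_to_tss()]
#'   results for the two peak sets.
#' @param responses per-gene classification (data.frame with `gene_id`,
#'   `type`), e.g. `classify_all(...)$assignments`.
#' @param window_bp occupancy window around the TSS (bp).
#' @return list of class `direct_targets`: `genes` (data.frame: gene_id,
#'   type, occ_without, occ_with), `summary` (n_without, n_with,
#'   n_intersect, n_union), `by_type` (per-type occupancy table).
#' @export
direct_target_sets <- function(assignments_without, assignments_with,
                               responses, window_bp = 10000) {
  de <- responses$gene_id[responses$type != "none"]
  A <- intersect(de, occupied_genes(assignments_without, window_bp))
  B <- intersect(de, occupied_genes(assignments_with, window_bp))
  both <- union(A, B)
  genes <- data.frame(gene_id = both,
                      type = responses$type[match(both, responses$gene_id)],
                      occ_without = both %in% A,
                      occ_with = both %in% B,
                      row.names = NULL, stringsAsFactors = FALSE)
  genes <- genes[order(genes$gene_id), ]
  summary <- list(n_without = length(A),
                  n_with = length(B),
                  n_union = length(both),
                  n_intersect = length(intersect(A, B)),
                  n_intersect_incl_excl = intersect_size_from_union(
                    length(A), length(B), length(both)))
  occ_class <- ifelse(genes$occ_without & genes$occ_with, "both",
                      ifelse(genes$occ_without, "without_only", "with_only"))
  by_type <- table(type = factor(genes$type, levels = RESPONSE_TYPES),
                   occupancy = factor(occ_class,
                                      levels = c("without_only", "with_only", "both")))
  structure(list(genes = genes, summary = summary, by_type = by_type,
                 window_bp = window_bp),
            class = "direct_targets")
}

#' @export
print.direct_targets <- function(x, ...) {
  s <- x$summary
  cat("Direct targets (occupancy within +/-", x$window_bp, "bp of TSS):\n")
  cat("  without ligand:", s$n_without, " with ligand:", s$n_with,
      " both:", s$n_intersect, " union:", s$n_union, "\n")
  invisible(x)
}

#' Binned TSS-distance profile of direct-target occupancy
#'
#' Histograms the signed peak-to-TSS distances of assignments to direct-
#' target genes, per response type, over `[-window_bp, window_bp]`.
#'
#' @param targets a [direct_target_sets()] result.
#' @param assignments the [assign_peaks_to_tss()] result for one condition.
#' @param responses per-gene classification data.frame.
#' @param window_bp profile half-width (bp).
#' @param bin_bp bin width (bp).
#' @return matrix of counts, bins x response types; bin labels are left
#'   edges (bp relative to TSS).
#' @export
tss_distance_profile <- function(targets, assignments, responses,
                                 window_bp = 10000, bin_bp = 500) {
  keep <- !is.na(assignments$gene_id) &
    assignments$gene_id %in% targets$genes$gene_id &
    assignments$abs_distance <= window_bp
  a <- assignments[keep, ]
  type <- responses$type[match(a$gene_id, responses$gene_id)]
  edges <- seq(-window_bp, window_bp, by = bin_bp)
  bin <- cut(a$distance, breaks = edges, include.lowest = TRUE, right = FALSE)
  tab <- table(bin, factor(type, levels = RESPONSE_TYPES))
  m <- unclass(tab)
  rownames(m) <- as.character(edges[-length(edges)])
  m
}
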