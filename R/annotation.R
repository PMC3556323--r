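#' @importFrom stats binom.test
NULL

## ---------------------------------------------------------------------------
## Genomic-feature annotation of peaks and enrichment against genome
## baseline fractions.
##
## Categories partition the genome under a fixed precedence: inside a
## transcript, 5'UTR > 3'UTR > coding exon > intron; outside, distance-
## ordered flank bins from the TSS (upstream) and transcript 3' end
## (downstream), nearer rings first so a peak between two genes takes the
## nearer feature at bin granularity; everything else is intergenic.
## ---------------------------------------------------------------------------

FEATURE_PRECEDENCE <- c("utr5", "utr3", "coding_exon", "intron",
                        "upstream_1k", "downstream_1k",
                        "upstream_2k", "downstream_2k",
                        "upstream_3k", "downstream_3k")

FEATURE_CATEGORIES <- c(FEATURE_PRECEDENCE, "intergenic")

# Raw (pre-precedence) ranges per category for one gene set.
feature_ranges <- function(genes, chrom_lengths, bin_edges = c(1000, 2000, 3000)) {
  chrom <- as.character(seqnames(genes))
  str <- as.character(strand(genes))
  plus <- str == "+"
  ex <- genes$blocks                # absolute exon coords (IRangesList)
  exons <- GRanges(rep(chrom, lengths(ex)), unlist(ex))
  tx <- granges_strip(genes)
  cds_start <- start(genes$thick); cds_end <- end(genes$thick)
  coding <- width(genes$thick) > 0

  # UTR sides depend on strand: for '+', the 5'UTR is exonic bp left of the
  # CDS; for '-', exonic bp right of it.
  plus_c <- plus[coding]
  pre_cds <- GRanges(chrom[coding],
                     IRanges::IRanges(start(genes)[coding], cds_start[coding] - 1L))
  post_cds <- GRanges(chrom[coding],
                      IRanges::IRanges(cds_end[coding] + 1L, end(genes)[coding]))
  utr5_side <- c(pre_cds[plus_c], post_cds[!plus_c])
  utr3_side <- c(post_cds[plus_c], pre_cds[!plus_c])
  utr5_side <- utr5_side[width(utr5_side) > 0]
  utr3_side <- utr3_side[width(utr3_side) > 0]
  exons_r <- GenomicRanges::reduce(exons)
  utr5 <- GenomicRanges::intersect(GenomicRanges::reduce(utr5_side), exons_r)
  utr3 <- GenomicRanges::intersect(GenomicRanges::reduce(utr3_side), exons_r)
  cds_gr <- GRanges(chrom[coding], genes$thick[coding])
  coding_exon <- GenomicRanges::intersect(GenomicRanges::reduce(cds_gr), exons_r)
  intron <- GenomicRanges::setdiff(GenomicRanges::reduce(tx), exons_r)

  # flank rings: upstream from the TSS, downstream from the transcript 3' end
  clip <- function(gr) {
    L <- chrom_lengths[as.character(seqnames(gr))]
    IRanges::restrict(gr, start = 1L, end = as.integer(L))
  }
  ring <- function(anchor, side, lo, hi) {
    # anchor: 1-based position; ring covers [anchor+lo, anchor+hi] to its
    # right (side +1) or [anchor-hi, anchor-lo] to its left (side -1)
    s <- ifelse(side > 0, anchor + lo, anchor - hi)
    e <- ifelse(side > 0, anchor + hi, anchor - lo)
    clip(GRanges(chrom, IRanges::IRanges(s, e)))
  }
  tss1 <- ifelse(plus, start(genes), end(genes))       # 1-based TSS
  tes1 <- ifelse(plus, end(genes), start(genes))       # 1-based 3' end
  up_side <- ifelse(plus, -1L, +1L)
  down_side <- ifelse(plus, +1L, -1L)
  edges <- c(0L, as.integer(bin_edges))
  rings <- list()
  for (k in seq_along(bin_edges)) {
    rings[[paste0("upstream_", k, "k")]] <-
      ring(tss1, up_side, edges[k] + 1L, edges[k + 1])
    rings[[paste0("downstream_", k, "k")]] <-
      ring(tes1, down_side, edges[k] + 1L, edges[k + 1])
  }

  c(list(utr5 = utr5, utr3 = utr3, coding_exon = coding_exon, intron = intron),
    rings)
}

#' Precedence-resolved genomic feature partition
#'
#' Builds disjoint category ranges covering the genome: each bp belongs to
#' the highest-precedence category claiming it, with `intergenic` as the
#' complement.
#'
#' @param genes gene models `GRanges`.
#' @param chrom_lengths named chromosome lengths (bp).
#' @param bin_edges outer edges of the flank bins (bp from TSS / 3' end).
#' @return named `GRangesList`-like list of disjoint `GRanges`, one per
#'   category in [FEATURE_CATEGORIES] order.
#' @export
genome_feature_partition <- function(genes, chrom_lengths,
                                     bin_edges = c(1000, 2000, 3000)) {
  genome <- GRanges(names(chrom_lengths),
                    IRanges::IRanges(1L, as.integer(chrom_lengths)))
  if (length(genes) == 0) {
    out <- setNames(rep(list(GRanges()), length(FEATURE_PRECEDENCE)),
                    FEATURE_PRECEDENCE)
    out$intergenic <- genome
    return(out)
  }
  raw <- feature_ranges(genes, chrom_lengths, bin_edges)
  taken <- GRanges()
  out <- list()
  for (cat in FEATURE_PRECEDENCE) {
    r <- GenomicRanges::reduce(raw[[cat]])
    r <- suppressWarnings(GenomicRanges::setdiff(r, taken))
    out[[cat]] <- r
    taken <- GenomicRanges::reduce(suppressWarnings(c(taken, r)))
  }
  out$intergenic <- suppressWarnings(GenomicRanges::setdiff(genome, taken))
  out
}

#' Annotate peaks by genomic feature category
#'
#' Each peak is assigned the category containing its midpoint.
#'
#' @param peaks peak `GRanges`.
#' @param partition a [genome_feature_partition()].
#' @return factor of categories, one per peak.
#' @export
annotate_peaks <- function(peaks, partition) {
  mid0 <- floor((start(peaks) - 1 + end(peaks)) / 2)   # 0-based midpoint
  mid <- GRanges(seqnames(peaks), IRanges::IRanges(mid0 + 1L, mid0 + 1L))
  out <- rep("intergenic", length(peaks))
  for (cat in FEATURE_PRECEDENCE) {
    hit <- IRanges::overlapsAny(mid, partition[[cat]])
    out[hit & out == "intergenic"] <- cat
  }
  factor(out, levels = FEATURE_CATEGORIES)
}

#' Genome baseline fractions per category and chromosome
#'
#' @param partition a [genome_feature_partition()].
#' @param chrom_lengths named chromosome lengths (bp).
#' @return list with `category` (named fractions summing to 1) and
#'   `chromosome` (chrom length / genome length).
#' @export
genome_category_fractions <- function(partition, chrom_lengths) {
  genome_bp <- sum(as.numeric(chrom_lengths))
  cat_bp <- vapply(partition, function(gr) sum(as.numeric(width(gr))), 0)
  list(category = cat_bp / genome_bp,
       chromosome = setNames(as.numeric(chrom_lengths) / genome_bp,
                             names(chrom_lengths)))
}

#' Enrichment of observed peak categories against genome baselines
#'
#' Per label, an exact two-sided binomial test of the observed peak count
#' against `n_peaks * baseline`, with the observed/baseline ratio and BH
#' q-values across labels. A zero baseline with observed peaks yields an
#' infinite ratio and a test against a half-count floor `0.5 / n_peaks`
#' (with a warning).
#'
#' @param observed factor or character vector of per-peak labels, or a named
#'   count vector.
#' @param baseline named baseline fractions (same label universe).
#' @return data.frame: `label`, `observed_count`, `observed_fraction`,
#'   `baseline_fraction`, `ratio`, `p`, `q`.
#' @export
category_enrichment <- function(observed, baseline) {
  counts <- if (!is.null(names(observed)) && is.numeric(observed)) observed
            else {
              tt <- table(factor(observed, levels = names(baseline)))
              setNames(as.integer(tt), names(tt))
            }
  n_peaks <- sum(counts)
  if (n_peaks <= 0) stop("no peaks to test", call. = FALSE)
  labs <- names(baseline)
  obs_frac <- counts[labs] / n_peaks
  ratio <- ifelse(baseline > 0, obs_frac / baseline,
                  ifelse(obs_frac > 0, Inf, NA_real_))
  if (any(baseline == 0 & obs_frac > 0))
    warning("zero baseline with observed peaks; testing against a half-count floor")
  p <- vapply(seq_along(labs), function(i) {
    p0 <- if (baseline[i] > 0) baseline[i] else 0.5 / n_peaks
    binom.test(counts[labs[i]], n_peaks, p = min(p0, 1))$p.value
  }, 0)
  data.frame(label = labs,
             observed_count = as.integer(counts[labs]),
             observed_fraction = as.numeric(obs_frac),
             baseline_fraction = as.numeric(baseline),
             ratio = as.numeric(ratio),
             p = p,
             q = bh_adjust(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-chromosome peak enrichment
#'
#' Convenience wrapper: compares the fraction of peaks per chromosome with
#' the fraction of genome bp per chromosome.
#'
#' @param peaks peak `GRanges`.
#' @param chrom_lengths named chromosome lengths.
#' @return [category_enrichment()] data.frame over chromosomes.
#' @export
chromosome_enrichment <- function(peaks, chrom_lengths) {
  baseline <- as.numeric(chrom_lengths) / sum(as.numeric(chrom_lengths))
  names(baseline) <- names(chrom_lengths)
  category_enrichment(factor(as.character(seqnames(peaks)),
                             levels = names(chrom_lengths)),
                      baseline)
}
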