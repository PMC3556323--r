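#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths seqlengths<-
#' @importFrom methods is
#' @importFrom stats setNames
NULL

## ---------------------------------------------------------------------------
## Gene models
##
## Gene models are held as a GRanges (1-based, closed; the Bioconductor
## convention) with metadata columns:
##   gene_id   character, unique
##   thick     IRanges, the CDS (zero-width when non-coding)
##   blocks    IRangesList, exons relative to the chromosome (absolute coords)
## BED12 files (0-based half-open) are converted on read/write by rtracklayer.
## ---------------------------------------------------------------------------

#' Read gene models from BED12 or GTF
#'
#' Parses transcript models into a `GRanges` with `gene_id`, CDS (`thick`)
#' and absolute exon coordinates (`blocks`, an `IRangesList`). The TSS of a
#' plus-strand transcript is its first base; for a minus-strand transcript it
#' is the last base.
#'
#' @param path path to a BED12 or GTF file.
#' @param format `"auto"` (by extension), `"bed"` or `"gtf"`.
#' @return `GRanges` of transcripts, sorted by (chrom, start).
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gtf", "gff", "gff2")) "gtf" else "bed"
  }
  gr <- if (format == "bed") read_gene_models_bed(path) else read_gene_models_gtf(path)
  validate_gene_models(gr)
  sort_genomic(gr)
}

read_gene_models_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("failed to parse BED gene models '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (any(strand(gr) == "*"))
    stop("gene model with unknown strand in '", path, "'", call. = FALSE)
  ids <- if (!is.null(gr$name)) gr$name else sprintf("gene%05d", seq_along(gr))
  blocks <- if (!is.null(gr$blocks)) {
    # rtracklayer blocks are transcript-relative; shift to absolute coords
    IRanges::shift(gr$blocks, start(gr) - 1L)
  } else {
    ir <- IRanges::IRanges(start(gr), end(gr))
    unname(S4Vectors::split(ir, seq_along(ir)))
  }
  thick <- if (!is.null(gr$thick)) gr$thick else IRanges::IRanges(start(gr), width = 0L)
  out <- GRanges(seqnames(gr), IRanges::IRanges(start(gr), end(gr)), strand = strand(gr))
  mcols(out)$gene_id <- ids
  mcols(out)$thick <- thick
  mcols(out)$blocks <- blocks
  out
}

read_gene_models_gtf <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "GTF"),
                 error = function(e) stop("failed to parse GTF gene models '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stop("no exon records in GTF '", path, "'", call. = FALSE)
  if (is.null(ex$transcript_id)) stop("GTF exons lack transcript_id in '", path, "'", call. = FALSE)
  if (any(strand(ex) == "*")) stop("gene model with unknown strand in '", path, "'", call. = FALSE)
  txs <- split(ex, ex$transcript_id)
  cds <- gr[gr$type == "CDS"]
  cds_by_tx <- if (length(cds)) split(cds, cds$transcript_id) else NULL
  rows <- lapply(names(txs), function(tx) {
    e <- sort(txs[[tx]])
    chrom <- as.character(seqnames(e))[1]
    str <- as.character(strand(e))[1]
    thick <- if (!is.null(cds_by_tx) && tx %in% names(cds_by_tx)) {
      cc <- cds_by_tx[[tx]]
      IRanges::IRanges(min(start(cc)), max(end(cc)))
    } else IRanges::IRanges(min(start(e)), width = 0L)
    list(chrom = chrom, start = min(start(e)), end = max(end(e)), strand = str,
         gene_id = tx, thick = thick,
         blocks = IRanges::IRanges(start(e), end(e)))
  })
  out <- GRanges(vapply(rows, `[[`, "", "chrom"),
                 IRanges::IRanges(vapply(rows, `[[`, 0, "start"),
                                  vapply(rows, `[[`, 0, "end")),
                 strand = vapply(rows, `[[`, "", "strand"))
  mcols(out)$gene_id <- vapply(rows, `[[`, "", "gene_id")
  mcols(out)$thick <- do.call(c, lapply(rows, `[[`, "thick"))
  mcols(out)$blocks <- do.call(IRanges::IRangesList, lapply(rows, `[[`, "blocks"))
  out
}

validate_gene_models <- function(gr) {
  if (anyDuplicated(gr$gene_id)) stop("duplicated gene_id in gene models", call. = FALSE)
  bl <- gr$blocks
  within_tx <- all(min(start(bl)) >= start(gr)) && all(max(end(bl)) <= end(gr))
  if (!within_tx) stop("exon blocks extend outside their transcript", call. = FALSE)
  invisible(gr)
}

#' Write gene models as BED12
#'
#' @param genes gene models from [read_gene_models()] or [simulate_genome()].
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  gr <- GRanges(seqnames(genes), IRanges::ranges(genes), strand = strand(genes))
  mcols(gr)$name <- genes$gene_id
  mcols(gr)$score <- 0L
  mcols(gr)$thick <- genes$thick
  mcols(gr)$blocks <- IRanges::shift(genes$blocks, 1L - start(genes))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Strand-resolved transcription start sites
#'
#' Returns the 0-based TSS position of each gene model: the first transcript
#' base for `+` genes, the last for `-` genes.
#'
#' @param genes gene models (`GRanges` with strand).
#' @return integer vector of 0-based TSS positions, named by `gene_id`.
#' @export
gene_tss <- function(genes) {
  pos <- ifelse(as.character(strand(genes)) == "+", start(genes) - 1L, end(genes) - 1L)
  setNames(as.integer(pos), genes$gene_id)
}

## ---------------------------------------------------------------------------
## Plain intervals
## ---------------------------------------------------------------------------

#' Overlap in base pairs between two half-open intervals
#'
#' Coordinates are 0-based half-open. Intervals on different chromosomes
#' never overlap; touching intervals overlap by 0 bp.
#'
#' @param a,b lists or data.frames with `chrom`, `start`, `end`.
#' @return integer bp of overlap.
#' @export
interval_overlap_bp <- function(a, b) {
  if (!identical(as.character(a$chrom), as.character(b$chrom))) return(0L)
  as.integer(max(0, min(a$end, b$end) - max(a$start, b$start)))
}

## ---------------------------------------------------------------------------
## Mappability
## ---------------------------------------------------------------------------

#' Read a mappability track (BED3 of uniquely mappable regions)
#'
#' @param path BED3 path.
#' @return `GRanges` of mappable regions, reduced and sorted.
#' @export
read_mappability <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::reduce(sort_genomic(gr))
}

#' Write a mappability track as BED3
#' @param track mappable regions (`GRanges`).
#' @param path output path.
#' @export
write_mappability <- function(track, path) {
  rtracklayer::export(granges_strip(track), path, format = "BED")
  invisible(path)
}

# Per-chromosome index of sorted disjoint mappable intervals in 0-based
# half-open coordinates, with cumulative widths, for O(log m) coverage queries.
mappability_index <- function(track) {
  track <- GenomicRanges::reduce(sort_genomic(track))
  sp <- split(IRanges::ranges(track), as.character(seqnames(track)))
  lapply(as.list(sp), function(ir) {
    s <- start(ir) - 1L   # 0-based
    e <- end(ir)          # half-open
    list(s = as.numeric(s), e = as.numeric(e), cs = cumsum(as.numeric(e - s)))
  })
}

# Cumulative mappable bp strictly below 0-based coordinate x (vectorized).
mappable_cum <- function(idx_chrom, x) {
  s <- idx_chrom$s; e <- idx_chrom$e; cs <- idx_chrom$cs
  i <- findInterval(x, s)
  out <- numeric(length(x))
  hit <- i > 0L
  ih <- i[hit]
  out[hit] <- cs[ih] - pmax(0, e[ih] - pmax(s[ih], pmin(x[hit], e[ih])))
  out
}

#' Uniquely mappable base pairs within an interval
#'
#' @param chrom chromosome name (scalar).
#' @param start,end 0-based half-open bounds (vectors allowed, paired).
#' @param track mappable regions (`GRanges`) or a prebuilt index.
#' @return numeric vector of mappable bp.
#' @export
mappable_bp <- function(chrom, start, end, track) {
  if (is(track, "GRanges") && length(track) > 0 &&
      !chrom %in% GenomeInfoDb::seqlevels(track)) {
    stop("unknown chromosome '", chrom, "' in mappability track", call. = FALSE)
  }
  idx <- if (is(track, "GRanges")) mappability_index(track) else track
  if (!chrom %in% names(idx)) return(numeric(length(start)))
  mappable_cum(idx[[chrom]], end) - mappable_cum(idx[[chrom]], start)
}

## ---------------------------------------------------------------------------
## Tag tracks
##
## A TagTrack is per-chromosome sorted unique 0-based tag 5' positions with
## integer counts, a total, and a multiplicative scale (input normalization).
## ---------------------------------------------------------------------------

#' Construct a tag track from tag 5' positions
#'
#' @param chrom,pos parallel vectors: chromosome and 0-based 5' position of
#'   each tag (repeat a position to represent multiple tags), or `pos` may be
#'   omitted and `chrom` a data.frame with columns `chrom`, `pos` and
#'   optionally `count`.
#' @param sample sample label.
#' @return object of class `TagTrack`.
#' @export
tag_track <- function(chrom, pos = NULL, sample = "sample") {
  if (is.data.frame(chrom)) {
    df <- chrom
    cnt <- if ("count" %in% names(df)) df$count else rep(1L, nrow(df))
    df <- data.frame(chrom = as.character(df$chrom), pos = as.numeric(df$pos), count = cnt)
  } else {
    df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos), count = 1L)
  }
  if (any(df$count < 0)) stop("negative tag counts", call. = FALSE)
  chroms <- list()
  for (ch in sort(unique(df$chrom))) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    agg <- rowsum(sub$count, group = sub$pos)
    p <- as.numeric(rownames(agg))
    o <- order(p)
    chroms[[ch]] <- list(pos = p[o], count = as.numeric(agg[o, 1]))
  }
  structure(list(chroms = chroms,
                 total_tags = sum(df$count),
                 scale = 1.0,
                 sample = sample),
            class = "TagTrack")
}

#' @export
print.TagTrack <- function(x, ...) {
  cat("TagTrack '", x$sample, "': ", format(x$total_tags, big.mark = ","),
      " tags on ", length(x$chroms), " chromosome(s); scale = ",
      format(x$scale), "\n", sep = "")
  invisible(x)
}

#' Total effective tags (scaled)
#' @param track a `TagTrack`.
#' @export
effective_total <- function(track) track$total_tags * track$scale

#' Read tags from BED6 (one record per tag)
#'
#' Each record is reduced to its 5' position: `start` (0-based) for `+`
#' records, `end - 1` for `-`. Records without strand are taken as `+`.
#'
#' @param path BED path.
#' @param sample sample label (default: file base name).
#' @return `TagTrack`.
#' @export
read_tags <- function(path, sample = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 3L) stop("tag BED '", path, "' needs >= 3 columns", call. = FALSE)
  str <- if (ncol(dt) >= 6L) as.character(dt[[6]]) else rep("+", nrow(dt))
  pos0 <- ifelse(str == "-", as.numeric(dt[[3]]) - 1, as.numeric(dt[[2]]))
  tag_track(data.frame(chrom = dt[[1]], pos = pos0),
            sample = if (is.null(sample)) basename(path) else sample)
}

#' Write tags as BED6 (one record per tag)
#' @param track `TagTrack`.
#' @param path output path.
#' @export
write_tags <- function(track, path) {
  parts <- lapply(names(track$chroms), function(ch) {
    tc <- track$chroms[[ch]]
    pos <- rep(tc$pos, times = tc$count)
    data.table::data.table(chrom = ch, start = as.integer(pos),
                           end = as.integer(pos) + 1L,
                           name = "tag", score = 0L, strand = "+")
  })
  data.table::fwrite(data.table::rbindlist(parts), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

# Tag count within [a, b) (0-based half-open) on one chromosome; vectorized
# over paired a, b. Applies the track scale.
tag_count <- function(track, chrom, a, b) {
  tc <- track$chroms[[chrom]]
  if (is.null(tc)) return(numeric(length(a)))
  cs <- c(0, cumsum(tc$count))
  lo <- findInterval(a - 0.5, tc$pos)
  hi <- findInterval(b - 0.5, tc$pos)
  (cs[hi + 1L] - cs[lo + 1L]) * track$scale
}

## ---------------------------------------------------------------------------
## Shared small helpers
## ---------------------------------------------------------------------------

sort_genomic <- function(gr) {
  gr[order(as.character(seqnames(gr)), start(gr), end(gr))]
}

granges_strip <- function(gr) {
  GRanges(seqnames(gr), IRanges::ranges(gr))
}
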