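## ---------------------------------------------------------------------------
## Hotspot-style peak caller: 150 bp target windows scored against a 200 kb
## local background with a binomial model whose success probability is the
## mappability ratio of the two windows; windows with z > 60 are retained
## and merged; peaks overlapping knockout-derived peaks by > 1 bp are
## excluded.
## ---------------------------------------------------------------------------

#' Peak-caller parameters
#'
#' @param window_bp target window width (bp).
#' @param background_bp background window width (bp), centered on the target
#'   window and clipped at chromosome ends.
#' @param z_threshold retain windows with z strictly greater than this.
#' @param min_window_tags minimum input-subtracted tag count per window.
#' @param merge_adjacent merge book-ended retained windows as well as
#'   overlapping ones.
#' @return list of class `peak_params`.
#' @export
peak_params <- function(window_bp = 150L, background_bp = 200000L,
                        z_threshold = 60, min_window_tags = 1,
                        merge_adjacent = TRUE) {
  if (window_bp >= background_bp)
    stop("window_bp must be smaller than background_bp", call. = FALSE)
  if (z_threshold <= 0) stop("z_threshold must be positive", call. = FALSE)
  structure(list(window_bp = as.integer(window_bp),
                 background_bp = as.integer(background_bp),
                 z_threshold = z_threshold,
                 min_window_tags = min_window_tags,
                 merge_adjacent = isTRUE(merge_adjacent)),
            class = "peak_params")
}

#' Normalize an input track to the ChIP library size
#'
#' Sets the track's multiplicative scale so that its effective tag total
#' equals the ChIP total; counts themselves are untouched.
#'
#' @param input_track input-sample `TagTrack`.
#' @param chip_total tag total of the matched ChIP sample.
#' @return the rescaled `TagTrack`.
#' @export
normalize_input <- function(input_track, chip_total) {
  if (input_track$total_tags <= 0)
    stop("input track has zero tags; cannot normalize", call. = FALSE)
  input_track$scale <- chip_total / input_track$total_tags
  input_track
}

#' Binomial z-score for a tag window
#'
#' `z = (n - N p) / sqrt(N p (1 - p))`: the normal approximation to the
#' binomial count of background tags expected to fall in the target window.
#' Vectorized; `N = 0` gives `z = 0`.
#'
#' @param n input-subtracted tag count in the target window (>= 0).
#' @param N tag count in the background window.
#' @param p mappability probability, in (0, 1).
#' @return numeric z-scores.
#' @export
window_zscore <- function(n, N, p) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)", call. = FALSE)
  mu <- N * p
  sigma <- sqrt(N * p * (1 - p))
  ifelse(N == 0, 0, (n - mu) / sigma)
}

#' Call hotspot peaks from ChIP and normalized input tag tracks
#'
#' Candidate windows of `window_bp` are anchored at tag-bearing positions
#' (`candidates = "tags"`, covering `[pos, pos + window)`), or tiled at every
#' position (`"exhaustive"`, for small chromosomes and oracle checks). Each
#' window is scored with [window_zscore()] using `n = max(0, chip - scaled
#' input)` within the window, `N` = ChIP tags in the background window
#' centered on the target and clipped at chromosome ends, and
#' `p` = mappable bp of the window over mappable bp of the (clipped)
#' background. Retained windows (`z > z_threshold`, `n >= min_window_tags`)
#' are merged; each merged peak carries its maximum-z window's statistics.
#' Windows with no mappable bp, or whose background is entirely within the
#' window, are skipped.
#'
#' @param chip ChIP `TagTrack`.
#' @param input_scaled input `TagTrack`, already passed through
#'   [normalize_input()] (or `NULL` for no input correction).
#' @param mappability mappable regions (`GRanges`).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param params a [peak_params()].
#' @param candidates `"tags"` or `"exhaustive"`.
#' @return `GRanges` of peaks sorted by (chrom, start), with metadata
#'   columns `z`, `n`, `N`, `p`, `sample`.
#' @export
call_hotspots <- function(chip, input_scaled, mappability, chrom_lengths,
                          params = peak_params(),
                          candidates = c("tags", "exhaustive")) {
  candidates <- match.arg(candidates)
  midx <- mappability_index(mappability)
  w <- params$window_bp
  B <- params$background_bp
  out <- list()
  for (ch in names(chip$chroms)) {
    L <- chrom_lengths[[ch]]
    if (is.null(L)) stop("no chromosome length for '", ch, "'", call. = FALSE)
    a <- if (candidates == "tags") chip$chroms[[ch]]$pos
         else as.numeric(0:(L - w))
    if (length(a) == 0) next
    win_end <- pmin(a + w, L)
    n_chip <- tag_count(chip, ch, a, win_end)
    n_inp <- if (is.null(input_scaled)) 0 else tag_count(input_scaled, ch, a, win_end)
    n <- pmax(0, n_chip - n_inp)
    center <- a + w / 2
    bg_lo <- pmax(0, center - B / 2)
    bg_hi <- pmin(L, center + B / 2)
    N <- tag_count_unscaled(chip, ch, bg_lo, bg_hi)
    mi <- midx[[ch]]
    if (is.null(mi)) next
    mw <- mappable_cum(mi, win_end) - mappable_cum(mi, a)
    mb <- mappable_cum(mi, bg_hi) - mappable_cum(mi, bg_lo)
    ok <- mw > 0 & mb > mw
    if (!any(ok)) next
    p <- mw[ok] / mb[ok]
    z <- window_zscore(n[ok], N[ok], p)
    keep <- z > params$z_threshold & n[ok] >= params$min_window_tags
    if (!any(keep)) next
    ka <- a[ok][keep]; kend <- win_end[ok][keep]
    kz <- z[keep]; kn <- n[ok][keep]; kN <- N[ok][keep]; kp <- p[keep]
    ir <- IRanges::IRanges(ka + 1, kend)   # 1-based closed
    merged <- IRanges::reduce(ir, min.gapwidth = if (params$merge_adjacent) 1L else 0L)
    hits <- IRanges::findOverlaps(ir, merged)
    best <- vapply(seq_along(merged), function(m) {
      members <- queryHits(hits)[subjectHits(hits) == m]
      members[which.max(kz[members])]
    }, 0L)
    gr <- GRanges(ch, merged)
    mcols(gr)$z <- kz[best]
    mcols(gr)$n <- kn[best]
    mcols(gr)$N <- kN[best]
    mcols(gr)$p <- kp[best]
    out[[ch]] <- gr
  }
  if (length(out) == 0) {
    gr <- GRanges()
    mcols(gr)$z <- numeric(0); mcols(gr)$n <- numeric(0)
    mcols(gr)$N <- numeric(0); mcols(gr)$p <- numeric(0)
    mcols(gr)$sample <- character(0)
    return(gr)
  }
  gr <- sort_genomic(suppressWarnings(do.call(c, unname(out))))
  mcols(gr)$sample <- chip$sample
  gr
}

# Background N is counted from raw ChIP tags, ignoring any scale.
tag_count_unscaled <- function(track, chrom, a, b) {
  sc <- track$scale
  track$scale <- 1.0
  on.exit(NULL)
  tag_count(track, chrom, a, b)
}

#' Exclude peaks overlapping knockout-derived peaks
#'
#' A peak is removed iff it overlaps any null peak by strictly more than
#' 1 bp (i.e. by 2 bp or more). Order is preserved; the result is always a
#' subset of the input and the operation is idempotent.
#'
#' @param peaks,null_peaks peak `GRanges` (as from [call_hotspots()]).
#' @return filtered `GRanges`.
#' @export
subtract_null_peaks <- function(peaks, null_peaks) {
  if (length(null_peaks) == 0 || length(peaks) == 0) return(peaks)
  drop <- IRanges::overlapsAny(granges_strip(peaks), granges_strip(null_peaks),
                               minoverlap = 2L)
  peaks[!drop]
}

#' Write peaks as BED6+ (chrom, start, end, name, z, strand, n, N, p)
#' @param peaks peak `GRanges`.
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  dt <- data.table::data.table(
    chrom = as.character(seqnames(peaks)),
    start = start(peaks) - 1L,
    end = end(peaks),
    name = sprintf("peak%05d", seq_along(peaks)),
    score = round(peaks$z, 4),
    strand = ".",
    n = peaks$n, N = peaks$N, p = signif(peaks$p, 8))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read peaks written by [write_peaks()]
#' @param path BED6+ path.
#' @param sample sample label.
#' @return peak `GRanges`.
#' @export
read_peaks <- function(path, sample = basename(path)) {
  if (file.size(path) == 0) {
    gr <- GRanges()
    mcols(gr)$z <- numeric(0)
    mcols(gr)$sample <- character(0)
    return(gr)
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  gr <- GRanges(as.character(dt[[1]]), IRanges::IRanges(dt[[2]] + 1L, dt[[3]]))
  mcols(gr)$z <- dt[[5]]
  if (ncol(dt) >= 9) {
    mcols(gr)$n <- dt[[7]]; mcols(gr)$N <- dt[[8]]; mcols(gr)$p <- dt[[9]]
  }
  mcols(gr)$sample <- sample
  gr
}
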