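#' @importFrom stats hclust as.dist prop.test
NULL

## ---------------------------------------------------------------------------
## PPRE/DR1 motif analysis: position frequency matrices with pseudocounts,
## IUPAC consensus, log-odds scanning of 400 bp peak regions on both
## strands, knockout-corrected co-occurrence, and a motif-similarity tree.
## ---------------------------------------------------------------------------

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                 ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' Motif-scanning parameters
#'
#' @param region_bp width of the region extracted around each peak for
#'   scanning.
#' @param score_fraction_threshold report hits scoring at least this
#'   fraction of the motif's maximum log-odds score.
#' @param consensus_major_threshold single-base consensus probability cutoff.
#' @param consensus_minor_threshold minimum probability for a base to enter
#'   a degenerate IUPAC code.
#' @export
motif_params <- function(region_bp = 400L, score_fraction_threshold = 0.8,
                         consensus_major_threshold = 0.6,
                         consensus_minor_threshold = 0.25) {
  stopifnot(region_bp > 0, score_fraction_threshold > 0,
            score_fraction_threshold <= 1)
  structure(list(region_bp = as.integer(region_bp),
                 score_fraction_threshold = score_fraction_threshold,
                 consensus_major_threshold = consensus_major_threshold,
                 consensus_minor_threshold = consensus_minor_threshold),
            class = "motif_params")
}

#' Build a position frequency/weight matrix from aligned site sequences
#'
#' Counts bases per column (an `N` contributes 1/4 to each base), adds a
#' pseudocount, normalizes to probabilities and derives log2-odds against
#' the background. `max_score` is the sum of the column maxima of the
#' log-odds matrix.
#'
#' @param sequences equal-length DNA strings (alphabet ACGTN).
#' @param pseudocount per-base pseudocount.
#' @param background base frequencies (A, C, G, T), default uniform.
#' @param name motif name.
#' @return object of class `PWM`: `name`, `counts`, `probs`, `log_odds`
#'   (all 4 x L), `max_score`, `pseudocount`, `background`, `nsites`.
#' @export
build_pfm <- function(sequences, pseudocount = 0.25,
                      background = rep(0.25, 4), name = "motif") {
  if (length(sequences) == 0) stop("no site sequences", call. = FALSE)
  sequences <- toupper(sequences)
  L <- unique(nchar(sequences))
  if (length(L) != 1) stop("site sequences must have equal length", call. = FALSE)
  if (L < 1) stop("empty site sequences", call. = FALSE)
  chars <- strsplit(sequences, "")
  bad <- setdiff(unique(unlist(chars)), c(DNA_BASES, "N"))
  if (length(bad)) stop("invalid characters in site sequences: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  counts <- matrix(0, 4, L, dimnames = list(DNA_BASES, NULL))
  for (s in chars) {
    for (j in seq_len(L)) {
      if (s[j] == "N") counts[, j] <- counts[, j] + 0.25
      else counts[s[j], j] <- counts[s[j], j] + 1
    }
  }
  pwm_from_counts(counts, pseudocount, background, name,
                  nsites = length(sequences))
}

pwm_from_counts <- function(counts, pseudocount = 0.25,
                            background = rep(0.25, 4), name = "motif",
                            nsites = NULL) {
  stopifnot(nrow(counts) == 4)
  rownames(counts) <- DNA_BASES
  n <- if (is.null(nsites)) max(colSums(counts)) else nsites
  probs <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
  log_odds <- log2(sweep(probs, 1, background, "/"))
  structure(list(name = name, counts = counts, probs = probs,
                 log_odds = log_odds,
                 max_score = sum(apply(log_odds, 2, max)),
                 pseudocount = pseudocount, background = background,
                 nsites = n),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat("PWM '", x$name, "' (", ncol(x$counts), " columns, ", x$nsites,
      " sites): ", consensus_iupac(x), "\n", sep = "")
  invisible(x)
}

#' Motif length (columns)
#' @param pwm a `PWM`.
#' @export
pwm_length <- function(pwm) ncol(pwm$counts)

#' IUPAC consensus string of a PWM
#'
#' Per column: the single base whose probability reaches the major
#' threshold, otherwise the IUPAC degeneracy code covering every base at or
#' above the minor threshold (`N` when all four qualify).
#'
#' @param pwm a `PWM`.
#' @param params a [motif_params()] (thresholds).
#' @return consensus string.
#' @export
consensus_iupac <- function(pwm, params = motif_params()) {
  maj <- params$consensus_major_threshold
  mino <- params$consensus_minor_threshold
  cols <- apply(pwm$probs, 2, function(pc) {
    if (max(pc) >= maj) return(DNA_BASES[which.max(pc)])
    keep <- DNA_BASES[pc >= mino]
    if (length(keep) == 0) keep <- DNA_BASES[which.max(pc)]
    IUPAC_CODES[[paste(sort(keep), collapse = "")]]
  })
  paste(cols, collapse = "")
}

#' Expand peaks to fixed-width scan regions
#'
#' Returns intervals of exactly `region_bp` centered on each peak midpoint,
#' shifted (never truncated) to fit within the chromosome.
#'
#' @param peaks peak `GRanges`.
#' @param chrom_lengths named chromosome lengths (bp).
#' @param region_bp region width.
#' @return `GRanges` of regions, same order as `peaks`.
#' @export
expand_region <- function(peaks, chrom_lengths, region_bp = 400L) {
  L <- as.numeric(chrom_lengths[as.character(seqnames(peaks))])
  if (any(is.na(L))) stop("peak chromosome missing from chrom_lengths", call. = FALSE)
  if (any(L < region_bp))
    stop("chromosome shorter than region_bp", call. = FALSE)
  mid0 <- floor((start(peaks) - 1 + end(peaks)) / 2)     # 0-based
  s0 <- mid0 - floor(region_bp / 2)
  s0 <- pmax(0, pmin(s0, L - region_bp))                 # shift, not truncate
  GRanges(seqnames(peaks), IRanges::IRanges(s0 + 1L, s0 + region_bp))
}

#' Extract region sequences from a genome
#' @param genome `DNAStringSet` (names = chromosomes).
#' @param regions `GRanges`.
#' @return character vector of sequences.
#' @export
region_sequences <- function(genome, regions) {
  vapply(seq_along(regions), function(i) {
    ch <- as.character(seqnames(regions))[i]
    as.character(Biostrings::subseq(genome[[ch]], start(regions)[i], end(regions)[i]))
  }, "")
}

seq_to_index <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(chars, DNA_BASES)           # N and friends -> NA
  if (any(is.na(idx) & chars != "N"))
    stop("non-ACGTN character in sequence", call. = FALSE)
  idx
}

scan_strand <- function(idx, lo) {
  L <- ncol(lo)
  n <- length(idx) - L + 1L
  if (n < 1) return(numeric(0))
  score <- numeric(n)
  for (j in seq_len(L)) {
    v <- lo[, j][idx[j:(j + n - 1L)]]
    v[is.na(v)] <- 0                       # N scores as background (0 log-odds)
    score <- score + v
  }
  score
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores the log2-odds of the motif at every offset on the forward
#' sequence and its reverse complement; offsets always refer to the
#' forward sequence (0-based). Hits reach at least
#' `score_fraction_threshold * max_score`.
#'
#' @param sequence DNA string (ACGTN).
#' @param pwm a `PWM`.
#' @param params a [motif_params()].
#' @return data.frame: `offset`, `strand`, `score`, `score_frac`.
#' @export
scan_region <- function(sequence, pwm, params = motif_params()) {
  idx <- seq_to_index(sequence)
  L <- pwm_length(pwm)
  if (length(idx) < L) stop("sequence shorter than the motif", call. = FALSE)
  fwd <- scan_strand(idx, pwm$log_odds)
  rc_idx <- rev(5L - idx)                  # A<->T, C<->G on the reversed seq
  rev_sc <- scan_strand(rc_idx, pwm$log_odds)
  n <- length(fwd)
  hits <- rbind(
    data.frame(offset = seq_len(n) - 1L, strand = "+", score = fwd),
    data.frame(offset = n - seq_len(n), strand = "-", score = rev_sc))
  hits$score_frac <- hits$score / pwm$max_score
  hits <- hits[hits$score >= params$score_fraction_threshold * pwm$max_score, ]
  hits <- hits[order(hits$offset, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

#' Fraction of regions containing at least one motif hit
#' @param sequences character vector of region sequences.
#' @param pwm a `PWM`.
#' @param params a [motif_params()].
#' @return list: `fraction`, `n_hit`, `n_regions`.
#' @export
region_hit_fraction <- function(sequences, pwm, params = motif_params()) {
  hit <- vapply(sequences, function(s) nrow(scan_region(s, pwm, params)) > 0,
                TRUE, USE.NAMES = FALSE)
  list(fraction = mean(hit), n_hit = sum(hit), n_regions = length(hit))
}

#' Null-corrected motif co-occurrence across region groups
#'
#' For each motif and group, the fraction of regions carrying at least one
#' hit. A motif is flagged `background` (and dropped from the retained list)
#' unless its hit fraction in the reference wild-type group significantly
#' exceeds its fraction in the knockout-derived null regions (one-sided
#' two-proportion test at `alpha`).
#'
#' @param regions_by_group named list of character vectors of region
#'   sequences (one element per group).
#' @param pwms list of `PWM`s.
#' @param null_regions sequences of regions called in the knockout sample.
#' @param params a [motif_params()].
#' @param wt_group name of the reference wild-type group (default: first).
#' @param alpha significance level for the enrichment-over-null test.
#' @return data.frame sorted by descending fraction within group: `motif`,
#'   `group`, `fraction`, `n_hit`, `n_regions`, `null_fraction`,
#'   `background` (flag), `retained`.
#' @export
region_cooccurrence <- function(regions_by_group, pwms, null_regions,
                                params = motif_params(),
                                wt_group = names(regions_by_group)[1],
                                alpha = 0.05) {
  stopifnot(length(regions_by_group) > 0, !is.null(names(regions_by_group)))
  if (is(pwms, "PWM")) pwms <- list(pwms)
  nm <- vapply(pwms, `[[`, "", "name")
  rows <- list()
  for (mi in seq_along(pwms)) {
    pwm <- pwms[[mi]]
    null_hf <- region_hit_fraction(null_regions, pwm, params)
    wt_hf <- region_hit_fraction(regions_by_group[[wt_group]], pwm, params)
    background <- TRUE
    if (wt_hf$fraction > null_hf$fraction) {
      pt <- suppressWarnings(prop.test(
        c(wt_hf$n_hit, null_hf$n_hit),
        c(wt_hf$n_regions, null_hf$n_regions),
        alternative = "greater"))
      background <- !(pt$p.value <= alpha)
    }
    for (g in names(regions_by_group)) {
      hf <- if (g == wt_group) wt_hf
            else region_hit_fraction(regions_by_group[[g]], pwm, params)
      rows[[length(rows) + 1L]] <- data.frame(
        motif = nm[mi], group = g,
        fraction = hf$fraction, n_hit = hf$n_hit, n_regions = hf$n_regions,
        null_fraction = null_hf$fraction,
        background = background, retained = !background,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$group, -out$fraction, out$motif), ]
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Motif similarity tree
## ---------------------------------------------------------------------------

reverse_complement_pwm <- function(pwm) {
  m <- pwm$probs[4:1, rev(seq_len(ncol(pwm$probs))), drop = FALSE]
  rownames(m) <- DNA_BASES
  m
}

# Best Pearson correlation of aligned probability columns over all ungapped
# offsets and both orientations; minimum overlap of 4 columns.
pwm_similarity <- function(a, b, min_overlap = 4L) {
  score_pair <- function(ma, mb) {
    La <- ncol(ma); Lb <- ncol(mb)
    best <- -1
    for (off in (-(Lb - min_overlap)):(La - min_overlap)) {
      lo <- max(1, 1 + off); hi <- min(La, Lb + off)
      if (hi - lo + 1 < min_overlap) next
      ia <- lo:hi
      ib <- ia - off
      r <- suppressWarnings(stats::cor(as.vector(ma[, ia]), as.vector(mb[, ib])))
      if (!is.na(r) && r > best) best <- r
    }
    best
  }
  max(score_pair(a$probs, b$probs),
      score_pair(a$probs, reverse_complement_pwm(b)))
}

#' Motif-similarity tree
#'
#' Pairwise motif distance is `1 - best Pearson correlation` of aligned
#' probability columns over all ungapped offsets and both orientations
#' (minimum overlap 4 columns); motifs are clustered by average linkage and
#' returned as a `phylo` tree with its newick serialization.
#'
#' @param pwms list of >= 2 `PWM`s with distinct names.
#' @param min_overlap minimum aligned columns.
#' @return list: `tree` (`phylo`), `newick` (string), `dist` (matrix).
#' @export
motif_tree <- function(pwms, min_overlap = 4L) {
  if (length(pwms) < 2) stop("need at least two PWMs", call. = FALSE)
  nm <- vapply(pwms, `[[`, "", "name")
  k <- length(pwms)
  d <- matrix(0, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d[i, j] <- d[j, i] <- 1 - pwm_similarity(pwms[[i]], pwms[[j]], min_overlap)
  }
  hc <- hclust(as.dist(d), method = "average")
  tree <- ape::as.phylo(hc)
  list(tree = tree, newick = ape::write.tree(tree), dist = d)
}

## ---------------------------------------------------------------------------
## TRANSFAC-format motif I/O
## ---------------------------------------------------------------------------

#' Read motifs from a TRANSFAC-format file
#'
#' Parses minimal TRANSFAC records: an `ID` (or `NA`) line naming the
#' motif, a `P0` (or `PO`) header, numbered count rows with four values in
#' A C G T order, and `//` record terminators.
#'
#' @param path file path.
#' @param pseudocount,background passed to the PWM constructor.
#' @return named list of `PWM`s.
#' @export
read_transfac <- function(path, pseudocount = 0.25, background = rep(0.25, 4)) {
  lines <- readLines(path)
  pwms <- list()
  name <- NULL
  rows <- list()
  flush <- function() {
    if (!is.null(name) && length(rows) > 0) {
      counts <- t(do.call(rbind, rows))
      pwms[[name]] <<- pwm_from_counts(counts, pseudocount, background, name)
    }
    name <<- NULL; rows <<- list()
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, "XX")) next
    if (startsWith(ln, "//")) { flush(); next }
    tok <- strsplit(ln, "\\s+")[[1]]
    tag <- tok[1]
    if (tag %in% c("ID", "NA", "DE")) { if (is.null(name)) name <- tok[2] }
    else if (tag %in% c("P0", "PO", "AC", "BF")) next
    else if (grepl("^[0-9]+$", tag)) {
      vals <- suppressWarnings(as.numeric(tok[2:5]))
      if (anyNA(vals)) stop("malformed TRANSFAC count row: '", ln, "'", call. = FALSE)
      rows[[length(rows) + 1L]] <- vals
    }
  }
  flush()
  if (length(pwms) == 0) stop("no motifs parsed from '", path, "'", call. = FALSE)
  pwms
}

#' Write motifs to a TRANSFAC-format file
#' @param pwms list of `PWM`s.
#' @param path output path.
#' @export
write_transfac <- function(pwms, path) {
  if (is(pwms, "PWM")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (pwm in pwms) {
    writeLines(c(paste("ID", pwm$name), "XX",
                 paste("P0", "A", "C", "G", "T", sep = "\t")), con)
    for (j in seq_len(pwm_length(pwm))) {
      writeLines(paste(sprintf("%02d", j),
                       paste(format(pwm$counts[, j], trim = TRUE), collapse = "\t"),
                       sep = "\t"), con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}
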