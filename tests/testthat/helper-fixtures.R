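# Shared fixtures, memoized so expensive simulations run once per session.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# A small, fast simulation used by most module tests.
small_sim_config <- function(seed = 11, ...) {
  sim_config(seed = seed, n_chroms = 1L, chrom_len_bp = 250000L,
             n_genes = 30L, n_planted_sites = 15L, n_null_artifact_sites = 4L,
             n_de_per_type = c(I = 5L, II = 6L, III = 3L, IV = 2L,
                               V = 1L, VI = 1L, VII = 1L, VIII = 1L),
             ...)
}

small_sim <- function() cached("small_sim", simulate_genome(small_sim_config()))

# The full default-scale study: one pipeline run reused by the acceptance and
# pipeline tests.
default_run <- function() {
  cached("default_run", {
    run_pipeline(pipeline_config(seed = 1L, out_dir = file.path(tempdir(), "ct_run")),
                 verbose = FALSE)
  })
}

# Construct a gene-model GRanges by hand.
make_genes <- function(chrom, start1, end1, strand, gene_id,
                       cds_start1 = start1, cds_end1 = end1, exons = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1),
                               strand = strand)
  S4Vectors::mcols(gr)$gene_id <- gene_id
  S4Vectors::mcols(gr)$thick <- IRanges::IRanges(cds_start1, cds_end1)
  if (is.null(exons)) {
    ir <- IRanges::IRanges(start1, end1)
    blocks <- unname(S4Vectors::split(ir, seq_along(ir)))
  } else {
    blocks <- do.call(IRanges::IRangesList, exons)
  }
  S4Vectors::mcols(gr)$blocks <- blocks
  gr
}

# Minimal fabricated contrast rows for classifier unit tests.
fake_contrast <- function(gene_id, delta = 0, p = 1, q = p, label = "custom") {
  data.frame(gene_id = gene_id, contrast = label, delta = delta,
             fold_change = 2^abs(delta),
             direction = ifelse(delta > 0, "up", ifelse(delta < 0, "down", "none")),
             p = p, q = q, stringsAsFactors = FALSE)
}

# Exact two-sided binomial p-value by direct enumeration (oracle).
binom_two_sided_oracle <- function(x, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= dbinom(x, n, p0) * (1 + 1e-7)])
}

# Tag positions of a track as a flat data.frame (test inspection helper).
track_positions <- function(track) {
  do.call(rbind, lapply(names(track$chroms), function(ch) {
    tc <- track$chroms[[ch]]
    data.frame(chrom = ch, pos = rep(tc$pos, tc$count))
  }))
}

# Independent oracle: score every 150 bp window on a fully mappable toy
# chromosome by naive per-window summation of the defining formula, then
# merge as the caller does. Mappability is trivial here: p = window/background.
naive_hotspots <- function(pos, L, w = 150, B = 200000, zthr = 60) {
  rows <- list()
  for (a in 0:(L - w)) {
    we <- min(a + w, L)
    n <- sum(pos >= a & pos < we)
    if (n < 1) next
    center <- a + w / 2
    lo <- max(0, center - B / 2); hi <- min(L, center + B / 2)
    N <- sum(pos >= lo & pos < hi)
    p <- (we - a) / (hi - lo)
    z <- (n - N * p) / sqrt(N * p * (1 - p))
    if (z > zthr) rows[[length(rows) + 1L]] <- c(a, we, z)
  }
  if (length(rows) == 0) return(NULL)
  m <- do.call(rbind, rows)
  ir <- IRanges::IRanges(m[, 1] + 1, m[, 2])
  merged <- IRanges::reduce(ir, min.gapwidth = 1L)
  hits <- IRanges::findOverlaps(ir, merged)
  zmax <- vapply(seq_along(merged), function(k)
    max(m[S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == k], 3]), 0)
  list(ranges = merged, z = zmax)
}
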