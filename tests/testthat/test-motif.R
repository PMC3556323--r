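ppre_seqs <- c("GGGACAAAGGTCA", "GGGCCAAAGGTCA", "GGGGCAAAGGTCA", "GGGTCAAAGGTCA")

test_that("position frequency matrices count and normalize correctly", {
  one <- build_pfm("ACGT", pseudocount = 0)
  expect_equal(unname(one$counts[, 1]), c(1, 0, 0, 0))
  expect_equal(unname(one$probs[cbind(1:4, 1:4)]), rep(1, 4))
  two <- build_pfm(c("AAAA", "TAAA"), pseudocount = 0)
  expect_equal(unname(two$probs[, 1]), c(0.5, 0, 0, 0.5))
  # probabilities always sum to one, with or without pseudocounts
  pfm <- build_pfm(ppre_seqs)
  expect_equal(unname(colSums(pfm$probs)), rep(1, 13), tolerance = 1e-9)
  # N splits its count over the four bases
  withN <- build_pfm(c("AN", "AN"), pseudocount = 0)
  expect_equal(unname(withN$counts[, 2]), rep(0.5, 4))
  expect_error(build_pfm(c("AA", "AAA")), "equal length")
  expect_error(build_pfm(character(0)), "no site")
  expect_error(build_pfm("AXA"), "invalid")
})

test_that("IUPAC consensus reflects the thresholds", {
  pfm <- build_pfm(ppre_seqs)
  expect_equal(consensus_iupac(pfm), "GGGNCAAAGGTCA")
  one_hot <- build_pfm("GATTACA", pseudocount = 0)
  expect_equal(consensus_iupac(one_hot), "GATTACA")
  uniform <- build_pfm(c("A", "C", "G", "T"))
  expect_equal(consensus_iupac(uniform), "N")
  # consensus of n identical sequences is that sequence, any n
  for (n in c(1, 3, 10))
    expect_equal(consensus_iupac(build_pfm(rep("TGACCT", n))), "TGACCT")
  # two-base columns collapse to degeneracy codes
  ry <- build_pfm(c("AC", "GT"), pseudocount = 0)
  expect_equal(consensus_iupac(ry), "RY")
})

test_that("regions expand to exactly region_bp, shifted at chromosome ends", {
  lens <- c(chr1 = 100000)
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1150))
  r <- expand_region(pk, lens)
  expect_equal(start(r) - 1, 875)          # midpoint 1075 (0-based) +/- 200
  expect_equal(end(r), 1275)
  edge <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 20))
  r2 <- expand_region(edge, lens)
  expect_equal(start(r2), 1)               # clamped, not truncated
  expect_equal(width(r2), 400)
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(99950, 99990))
  expect_equal(end(expand_region(far, lens)), 100000)
  expect_error(expand_region(pk, c(chr1 = 300)), "shorter")
})

test_that("scanning finds planted motifs on both strands", {
  pfm <- build_pfm(ppre_seqs)
  region <- paste0(strrep("A", 20), "GGGTCAAAGGTCA", strrep("C", 20))
  hits <- scan_region(region, pfm)
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$offset, 20)
  expect_equal(plus$score_frac, 1, tolerance = 1e-9)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(region)))
  hits_rc <- scan_region(rc, pfm)
  minus <- hits_rc[hits_rc$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  # mirrored offset: len - L - offset
  expect_equal(minus$offset, nchar(region) - 13 - 20)
  expect_equal(minus$score, plus$score)
  expect_error(scan_region("ACGTXACGT", pfm), "non-ACGTN")
})

test_that("scanning agrees with a per-base brute-force oracle", {
  set.seed(77)
  pfm <- build_pfm(c("TGACGT", "TGACGT", "TTACGT"))
  region <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  region <- paste0(region, "TGACGT")       # ensure at least one strong site
  params <- motif_params(score_fraction_threshold = 0.7)
  got <- scan_region(region, pfm, params)
  # oracle: enumerate every offset and strand, summing single-base log-odds
  chars <- strsplit(region, "")[[1]]
  rc_map <- c(A = "T", C = "G", G = "C", T = "A")
  L <- 6
  rows <- list()
  for (o in 0:(nchar(region) - L)) {
    for (strand in c("+", "-")) {
      sub <- chars[(o + 1):(o + L)]
      if (strand == "-") sub <- rev(unname(rc_map[sub]))
      sc <- sum(vapply(seq_len(L), function(j) pfm$log_odds[sub[j], j], 0))
      if (sc >= 0.7 * pfm$max_score)
        rows[[length(rows) + 1]] <- data.frame(offset = o, strand = strand,
                                               score = sc)
    }
  }
  oracle <- do.call(rbind, rows)
  oracle <- oracle[order(oracle$offset, oracle$strand), ]
  expect_equal(got$offset, oracle$offset)
  expect_equal(got$strand, oracle$strand)
  expect_equal(got$score, oracle$score, tolerance = 1e-9)
})

test_that("hit sets are invariant under reverse complement of the region", {
  set.seed(78)
  pfm <- build_pfm(ppre_seqs)
  region <- paste0(paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = ""),
                   "GGGTCAAAGGTCA",
                   paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""))
  fwd <- scan_region(region, pfm)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(region)))
  rev <- scan_region(rc, pfm)
  expect_equal(nrow(fwd), nrow(rev))
  remapped <- data.frame(offset = nchar(region) - 13 - rev$offset,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         score = rev$score)
  remapped <- remapped[order(remapped$offset, remapped$strand), ]
  expect_equal(remapped$offset, fwd$offset)
  expect_equal(remapped$strand, fwd$strand)
  expect_equal(remapped$score, fwd$score, tolerance = 1e-9)
})

test_that("co-occurrence fractions count regions with hits", {
  pfm <- build_pfm(ppre_seqs, name = "PPRE")
  with_site <- paste0(strrep("A", 30), "GGGTCAAAGGTCA", strrep("A", 30))
  without <- strrep("ACGTG", 15)
  groups <- list(wt = c(with_site, with_site, with_site, without),
                 other = c(with_site, without))
  nulls <- rep(without, 10)
  res <- region_cooccurrence(groups, list(pfm), nulls, wt_group = "wt")
  expect_equal(res$fraction[res$group == "wt"], 0.75)
  expect_equal(res$fraction[res$group == "other"], 0.5)
  # order invariance
  res2 <- region_cooccurrence(lapply(groups, rev), list(pfm), nulls,
                              wt_group = "wt")
  expect_equal(res2$fraction, res$fraction)
})

test_that("motifs present in knockout regions are flagged as background", {
  specific <- build_pfm(ppre_seqs, name = "specific")
  decoy <- build_pfm(rep("TGACGTCA", 4), name = "decoy")
  site <- function(m) paste0(strrep("A", 25), m, strrep("C", 25))
  wt_regions <- c(rep(site("GGGTCAAAGGTCA"), 18), rep(site("TGACGTCA"), 18))
  null_regions <- c(rep(site("TGACGTCA"), 18), rep(strrep("ACG", 20), 2))
  res <- region_cooccurrence(list(wt = wt_regions), list(specific, decoy),
                             null_regions, wt_group = "wt")
  expect_false(res$background[res$motif == "specific"][1])
  expect_true(res$background[res$motif == "decoy"][1])
  expect_true(res$retained[res$motif == "specific"][1])
})

test_that("motif trees group similar matrices", {
  A <- build_pfm(rep("GGGTCAAAGGTCA", 6), name = "A")
  B <- build_pfm(c(rep("GGGTCAAAGGTCA", 5), "GGGTCAAAGGTCT"), name = "B")
  C <- build_pfm(rep("TTTTACGTACAAT", 6), name = "C")
  tr <- motif_tree(list(A, B, C))
  expect_s3_class(tr$tree, "phylo")
  # distance matrix sanity
  expect_equal(diag(tr$dist), c(A = 0, B = 0, C = 0))
  expect_equal(tr$dist, t(tr$dist))
  expect_lt(tr$dist["A", "B"], tr$dist["A", "C"])
  # identical PWMs are sisters at distance zero
  tr2 <- motif_tree(list(A, build_pfm(rep("GGGTCAAAGGTCA", 6), name = "A2"), C))
  expect_equal(tr2$dist["A", "A2"], 0, tolerance = 1e-9)
  # topology: A and B cluster before C joins
  pair <- ape::extract.clade(tr$tree, ape::getMRCA(tr$tree, c("A", "B")))
  expect_setequal(pair$tip.label, c("A", "B"))
  expect_error(motif_tree(list(A)), "two")
})

test_that("TRANSFAC files round-trip motif counts", {
  pfms <- list(build_pfm(ppre_seqs, name = "PPRE"),
               build_pfm(c("TTGCAA", "TTGCAA", "TTGCTA"), name = "mini"))
  path <- tempfile(fileext = ".transfac")
  write_transfac(pfms, path)
  back <- read_transfac(path)
  expect_equal(names(back), c("PPRE", "mini"))
  for (nm in names(back)) {
    orig <- pfms[[which(vapply(pfms, `[[`, "", "name") == nm)]]
    expect_equal(unname(back[[nm]]$counts), unname(orig$counts))
  }
  empty <- tempfile(); writeLines("XX", empty)
  expect_error(read_transfac(empty), "no motifs")
})

test_that("the bundled synthetic PPRE site list reproduces the DR1 consensus", {
  path <- system.file("extdata", "ppre_sites_synthetic.txt", package = "cistrotype")
  sites <- readLines(path)
  sites <- sites[!startsWith(sites, "#") & nzchar(sites)]
  expect_equal(length(sites), 52L)
  expect_equal(consensus_iupac(build_pfm(sites)), "GGGNCAAAGGTCA")
})
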