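make_design <- function(n_reps = 3) {
  cond <- data.frame(genotype = c("wt", "wt", "null", "null"),
                     treatment = c("vehicle", "ligand", "vehicle", "ligand"),
                     stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(cond)), function(i)
    data.frame(sample = sprintf("%s_%s_r%d", cond$genotype[i],
                                cond$treatment[i], seq_len(n_reps)),
               genotype = cond$genotype[i], treatment = cond$treatment[i],
               replicate = seq_len(n_reps), stringsAsFactors = FALSE)))
}

# Deterministic matrix: per-condition means plus a fixed within-group jitter,
# so contrasts are exact and variances tiny but nonzero.
make_matrix <- function(means, design, jitter = c(-0.01, 0, 0.01)) {
  mat <- sapply(seq_len(nrow(design)), function(j) {
    key <- paste(design$genotype[j], design$treatment[j], sep = ".")
    means[, key] + jitter[design$replicate[j]]
  })
  dimnames(mat) <- list(rownames(means), design$sample)
  mat
}

test_that("contrast statistics match hand-computed Welch results", {
  design <- make_design()
  mat <- rbind(gA = c(1.0, 1.2, 0.8, 2.0, 2.2, 1.8, 5, 5, 5, 5, 5, 5),
               gB = rep(3, 12))
  colnames(mat) <- design$sample
  cs <- contrast_stats(mat, design,
                       list(A = c("wt", "vehicle"), B = c("wt", "ligand")))
  # A = (1.0, 1.2, 0.8), B = (2.0, 2.2, 1.8): delta -1, fold change 2, down
  expect_equal(cs$delta[1], -1)
  expect_equal(cs$fold_change[1], 2)
  expect_equal(cs$direction[1], "down")
  # Welch closed form: s2 = 0.04 each, se = sqrt(2 * 0.04/3), df = 4
  se <- sqrt(0.04 / 3 + 0.04 / 3)
  t_stat <- -1 / se
  expect_equal(cs$p[1], 2 * pt(t_stat, df = 4), tolerance = 1e-12)
  # identical groups: fold change 1, p = 1 (degenerate zero-variance case)
  expect_equal(cs$fold_change[2], 1)
  expect_equal(cs$p[2], 1)
})

test_that("contrasts are invariant to replicate order", {
  design <- make_design()
  set.seed(4)
  mat <- matrix(rnorm(10 * 12, 8), 10, 12,
                dimnames = list(sprintf("g%02d", 1:10), design$sample))
  a <- contrast_stats(mat, design, "ligand_wt")
  perm <- sample(ncol(mat))
  b <- contrast_stats(mat[, perm], design[perm, ], "ligand_wt")
  expect_equal(a$delta, b$delta)
  expect_equal(a$p, b$p)
})

test_that("zero variance with a real difference warns and gives p = 0", {
  design <- make_design()
  mat <- matrix(rep(c(1, 2, 1, 1), each = 3), 1, 12,
                dimnames = list("g1", design$sample))
  expect_warning(cs <- contrast_stats(mat, design, "ligand_wt"), "zero")
  expect_equal(cs$p, 0)
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_adjust(0.37), 0.37)                      # m = 1
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))                  # worked example
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))        # ties
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # monotone non-decreasing on sorted input
  set.seed(8)
  p <- sort(runif(50))
  expect_true(all(diff(bh_adjust(p)) >= -1e-12))
  # q in original order: manual step-up oracle
  p2 <- c(0.9, 0.004, 0.06, 0.02)
  o <- order(p2)
  m <- length(p2)
  q_sorted <- rev(cummin(rev(p2[o] * m / seq_len(m))))
  expect_equal(bh_adjust(p2)[o], pmin(q_sorted, 1))
})

test_that("classification maps the two calls onto types exactly", {
  g <- "g1"
  sig_up <- fake_contrast(g, delta = 1, p = 0.001, q = 0.01)
  sig_dn <- fake_contrast(g, delta = -1, p = 0.001, q = 0.01)
  ns <- fake_contrast(g, delta = 0.05, p = 0.6, q = 0.9)
  cases <- list(
    list(lw = ns,     gt = sig_up, ln = ns,     type = "I"),
    list(lw = ns,     gt = sig_dn, ln = ns,     type = "II"),
    list(lw = sig_up, gt = ns,     ln = ns,     type = "III"),
    list(lw = sig_dn, gt = ns,     ln = ns,     type = "IV"),
    list(lw = sig_up, gt = sig_up, ln = ns,     type = "V"),
    list(lw = sig_dn, gt = sig_dn, ln = ns,     type = "VI"),
    list(lw = sig_up, gt = sig_dn, ln = ns,     type = "VII"),
    list(lw = sig_dn, gt = sig_up, ln = ns,     type = "VIII"),
    list(lw = ns,     gt = ns,     ln = ns,     type = "none"),
    # a ligand response also present in knockout cells is not PPAR-dependent
    list(lw = sig_up, gt = ns,     ln = sig_up, type = "none"))
  for (cs in cases) {
    out <- classify_genes(cs$lw, cs$gt, cs$ln)
    expect_equal(out$type, cs$type)
  }
  out <- classify_genes(sig_up, ns, sig_up)
  expect_true(out$ligand_response_in_null)
  # sub-threshold fold change never significant even at q ~ 0
  weak <- fake_contrast(g, delta = log2(1.2), p = 1e-6, q = 1e-5)
  expect_equal(classify_genes(weak, ns, ns)$type, "none")
})

test_that("classification partitions genes and counts add up", {
  design <- make_design()
  means <- rbind(
    g1 = c(wt.vehicle = 8, wt.ligand = 8, null.vehicle = 9, null.ligand = 9),  # I
    g2 = c(8, 8, 7, 7),                                                        # II
    g3 = c(8, 9, 8, 8),                                                        # III
    g4 = c(8, 7, 8, 8),                                                        # IV
    g5 = c(8, 9, 9, 9),                                                        # V
    g6 = c(8, 8.05, 8.05, 8))                                                  # none
  colnames(means) <- c("wt.vehicle", "wt.ligand", "null.vehicle", "null.ligand")
  mat <- make_matrix(means, design)
  cl <- classify_all(mat, design)
  expect_equal(unname(cl$counts[c("I", "II", "III", "IV", "V", "none")]),
               c(1L, 1L, 1L, 1L, 1L, 1L))
  expect_equal(sum(cl$counts), nrow(mat))                   # partition
  expect_equal(cl$assignments$type[cl$assignments$gene_id == "g5"], "V")
  # type V switch ratio: ligand fold 2 over constitutive fold 2 -> 1
  expect_equal(unname(cl$switch_ratio["V"]), 1, tolerance = 0.05)
})

test_that("swapping genotype labels exchanges constitutive directions", {
  design <- make_design()
  means <- rbind(g1 = c(8, 8, 9, 9),    # repressed by the receptor (type I)
                 g2 = c(8, 8, 7, 7))    # activated by the receptor (type II)
  colnames(means) <- c("wt.vehicle", "wt.ligand", "null.vehicle", "null.ligand")
  mat <- make_matrix(means, design)
  cl1 <- classify_all(mat, design)
  swapped <- design
  swapped$genotype <- ifelse(design$genotype == "wt", "null", "wt")
  cl2 <- classify_all(mat, swapped)
  t1 <- cl1$assignments$type
  t2 <- cl2$assignments$type
  expect_equal(t1, c("I", "II"))
  expect_equal(t2, c("II", "I"))
})

test_that("planted response types are recovered from simulated expression", {
  sim <- small_sim()
  ex <- simulate_expression(sim)
  cl <- classify_all(ex$matrix, ex$design)
  truth <- sim$manifest$response_types
  called <- cl$assignments$type[match(names(truth), cl$assignments$gene_id)]
  planted <- truth != "none"
  expect_gt(mean(called[planted] == truth[planted]), 0.8)
  expect_equal(sum(cl$counts), length(truth))
})

test_that("expression matrices round-trip through TSV", {
  sim <- small_sim()
  ex <- simulate_expression(sim)
  mp <- tempfile(fileext = ".tsv"); dp <- tempfile(fileext = ".tsv")
  write_expression(ex$matrix, ex$design, mp, dp)
  back <- read_expression(mp, dp)
  expect_equal(back$matrix, ex$matrix, tolerance = 1e-12)
  expect_equal(back$design$genotype, ex$design$genotype)
})

test_that("response-count summaries compute the right aggregates", {
  counts <- c(I = 10L, II = 20L, III = 5L, IV = 5L,
              V = 2L, VI = 2L, VII = 1L, VIII = 0L)
  s <- summarize_response_counts(counts)
  expect_equal(s$total, 45L)
  expect_equal(s$constitutive_n, 30L)
  expect_equal(s$ligand_n, 10L)
  expect_equal(s$major_pct, 100 * 40 / 45)
  expect_equal(s$mixed_pct, 100 * 5 / 45)
})

test_that("sequencing run summaries recompute totals and percentages", {
  runs <- data.frame(sample = "s1", reads_run1 = 100, reads_run2 = 300,
                     qc_passed_reads = 380, mapped_reads = 190)
  s <- sequencing_run_summary(runs)
  expect_equal(s$total_reads, 400)
  expect_equal(s$pct_qc_passed, 95)
  expect_equal(s$pct_mapped, 50)
})
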