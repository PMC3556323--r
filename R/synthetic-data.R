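#' @importFrom stats rnorm rmultinom runif
NULL

## ---------------------------------------------------------------------------
## Synthetic study generator: toy genome + annotation + mappability mask +
## ChIP/input/knockout tag tracks with planted 150 bp enriched sites + a
## log2 expression matrix with planted response types, and a ground-truth
## manifest. Everything is deterministic under the configured seed.
## ---------------------------------------------------------------------------

#' Sample conditions known to the simulator
#' @export
SIM_CONDITIONS <- c("chip_wt_veh", "chip_wt_lig", "chip_null_veh",
                    "chip_null_lig", "input_wt", "input_null")

#' The eight response-type labels
#' @export
RESPONSE_TYPES <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")

#' Simulation configuration
#'
#' Defaults define the bundled study conditions: a ~1.6 Mb two-chromosome
#' genome, 150 non-overlapping genes, a 90% mappable mask, planted 150 bp
#' binding sites within +/- 10 kb of TSSs at 10x background enrichment over
#' a tag background of 0.5 tags per mappable bp (so a 200 kb background
#' window holds roughly 1e5 tags, giving the z > 60 decision boundary
#' adequate counting depth), knockout-only artifact sites, and a log2
#' expression design with genes planted in each of the eight response types
#' at fold change 2 with replicate sd 0.25 and 3 replicates per condition.
#'
#' @param seed master seed (integer).
#' @param n_chroms,chrom_len_bp toy genome shape.
#' @param n_genes number of non-overlapping gene models.
#' @param gene_len_range min/max transcript length (bp).
#' @param mappable_fraction fraction of each chromosome uniquely mappable.
#' @param background_rate expected background tags per mappable bp.
#' @param enrichment_factor fold tag enrichment within a planted 150 bp site.
#' @param site_bp planted site width.
#' @param n_planted_sites number of planted binding sites (one per gene).
#' @param site_offset_bp planted sites fall uniformly within +/- this many
#'   bp of the host gene's TSS.
#' @param occupancy_probs probabilities that a planted site is occupied
#'   without ligand only, in both conditions, or with ligand only.
#' @param n_null_artifact_sites artifact sites enriched in every ChIP sample
#'   including the knockout (the non-specific peaks the subtraction removes).
#' @param n_de_per_type named integer vector, planted genes per response type.
#' @param fold_change planted expression fold change (linear scale, > 1).
#' @param baseline_mean,baseline_sd log2 baseline distribution across genes.
#' @param replicate_sd log2 replicate noise sd.
#' @param n_reps replicates per condition.
#' @param motif_consensus DR1-style motif planted at site centers.
#' @param motif_fraction fraction of planted sites carrying the motif.
#' @param decoy_consensus background motif planted in artifact sites (present
#'   in wild-type and knockout regions alike, so co-occurrence background
#'   correction has work to do).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_len_bp = 800000L,
                       n_genes = 150L,
                       gene_len_range = c(2000L, 6000L),
                       mappable_fraction = 0.9,
                       background_rate = 0.5,
                       enrichment_factor = 10,
                       site_bp = 150L,
                       n_planted_sites = 100L,
                       site_offset_bp = 10000L,
                       occupancy_probs = c(veh_only = 0.2, both = 0.2, lig_only = 0.6),
                       n_null_artifact_sites = 15L,
                       n_de_per_type = c(I = 30L, II = 48L, III = 12L, IV = 5L,
                                         V = 3L, VI = 2L, VII = 1L, VIII = 2L),
                       fold_change = 2,
                       baseline_mean = 8,
                       baseline_sd = 1.5,
                       replicate_sd = 0.25,
                       n_reps = 3L,
                       motif_consensus = "GGGTCAAAGGTCA",
                       motif_fraction = 0.8,
                       decoy_consensus = "TGACGTCA") {
  cfg <- as.list(environment())
  # YAML-sourced configurations arrive as lists
  cfg$n_de_per_type <- unlist(cfg$n_de_per_type)
  cfg$occupancy_probs <- unlist(cfg$occupancy_probs)
  cfg$gene_len_range <- unlist(cfg$gene_len_range)
  stopifnot(cfg$n_chroms > 0, cfg$chrom_len_bp > 0, cfg$n_genes > 0,
            cfg$n_planted_sites > 0, cfg$n_reps >= 2, cfg$site_bp > 0)
  if (!(cfg$mappable_fraction > 0 && cfg$mappable_fraction <= 1))
    stop("mappable_fraction must be in (0, 1]", call. = FALSE)
  if (cfg$enrichment_factor < 1) stop("enrichment_factor must be >= 1", call. = FALSE)
  if (cfg$fold_change < 1) stop("fold_change must be >= 1", call. = FALSE)
  if (cfg$n_planted_sites > cfg$n_genes)
    stop("n_planted_sites cannot exceed n_genes", call. = FALSE)
  if (!all(names(cfg$n_de_per_type) %in% RESPONSE_TYPES))
    stop("n_de_per_type names must be response types I..VIII", call. = FALSE)
  if (sum(cfg$n_de_per_type) > cfg$n_genes)
    stop("more planted DE genes than genes", call. = FALSE)
  cfg$occupancy_probs <- cfg$occupancy_probs / sum(cfg$occupancy_probs)
  structure(cfg, class = "sim_config")
}

# Restore the caller's RNG state on exit so simulation calls do not perturb
# the session stream; sub-seeds keep the stages independently reproducible.
with_sim_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Place k non-overlapping intervals of widths w inside [0, L) by distributing
# the free space as uniform stick-breaking gaps. Returns 0-based starts.
place_nonoverlapping <- function(L, w, margin = 0L) {
  k <- length(w)
  free <- L - sum(w) - 2 * margin
  if (free < 0) stop("intervals cannot be placed without overlap; ",
                     "increase the genome size", call. = FALSE)
  cuts <- sort(runif(k))
  gaps <- diff(c(0, cuts)) * free
  starts <- margin + cumsum(gaps) + cumsum(c(0, w[-k]))
  as.integer(floor(starts))
}

#' Simulate a toy genome, annotation, mappability mask and truth manifest
#'
#' @param config a [sim_config()].
#' @return list of class `cistrome_sim` with elements `genome`
#'   (`DNAStringSet`), `genes` (gene-model `GRanges`), `mappability`
#'   (`GRanges`), and `manifest` (ground truth: planted sites per condition,
#'   artifact sites, planted response types, planted motif positions, and the
#'   generator parameters).
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(cfg) {
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  L <- cfg$chrom_len_bp

  ## genome sequence
  seqs <- lapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- chroms

  ## mappability: carve unmappable blocks out of each chromosome
  map_list <- lapply(chroms, function(ch) {
    miss <- round((1 - cfg$mappable_fraction) * L)
    if (miss == 0) return(GRanges(ch, IRanges::IRanges(1L, L)))
    nblock <- max(1L, round(miss / 1500))
    w <- as.integer(round(miss * as.vector(rmultinom(1, 1000, rep(1, nblock))) / 1000))
    w <- w[w > 0]
    s0 <- place_nonoverlapping(L, w)   # 0-based starts of unmappable blocks
    unmap <- IRanges::IRanges(s0 + 1L, s0 + w)
    GenomicRanges::setdiff(GRanges(ch, IRanges::IRanges(1L, L)), GRanges(ch, unmap))
  })
  mappability <- sort_genomic(suppressWarnings(do.call(c, map_list)))
  GenomeInfoDb::seqlevels(mappability) <- chroms
  suppressWarnings(GenomeInfoDb::seqlengths(mappability) <- rep(L, cfg$n_chroms))

  ## gene models (non-overlapping), split roughly evenly across chromosomes
  per_chrom <- diff(floor(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
  gene_rows <- list()
  gi <- 0L
  for (ci in seq_along(chroms)) {
    k <- per_chrom[ci]
    if (k == 0) next
    w <- as.integer(round(runif(k, cfg$gene_len_range[1], cfg$gene_len_range[2])))
    s0 <- place_nonoverlapping(L, w, margin = 12000L)  # leave room for flank bins
    for (j in seq_len(k)) {
      gi <- gi + 1L
      gene_rows[[gi]] <- build_gene(chroms[ci], s0[j], w[j],
                                    strand = sample(c("+", "-"), 1),
                                    gene_id = sprintf("gene%04d", gi))
    }
  }
  genes <- suppressWarnings(do.call(c, lapply(gene_rows, `[[`, "gr")))
  GenomeInfoDb::seqlevels(genes) <- chroms
  suppressWarnings(GenomeInfoDb::seqlengths(genes) <- rep(L, cfg$n_chroms))
  genes <- sort_genomic(genes)
  tss <- gene_tss(genes)

  ## planted binding sites near TSSs of randomly chosen host genes
  midx <- mappability_index(mappability)
  site_genes <- sort(sample(genes$gene_id, cfg$n_planted_sites))
  site_rows <- lapply(site_genes, function(g) {
    ch <- as.character(seqnames(genes))[match(g, genes$gene_id)]
    t0 <- tss[[g]]
    for (try in 1:80) {
      off <- floor(runif(1, -cfg$site_offset_bp, cfg$site_offset_bp - cfg$site_bp))
      s0 <- t0 + off
      if (s0 < 0 || s0 + cfg$site_bp > cfg$chrom_len_bp) next
      if (mappable_bp(ch, s0, s0 + cfg$site_bp, midx) == cfg$site_bp)
        return(data.frame(chrom = ch, start = s0, end = s0 + cfg$site_bp,
                          gene_id = g, stringsAsFactors = FALSE))
    }
    NULL
  })
  sites <- do.call(rbind, site_rows)
  sites$class <- sample(names(cfg$occupancy_probs), nrow(sites),
                        replace = TRUE, prob = cfg$occupancy_probs)
  sites$has_motif <- runif(nrow(sites)) < cfg$motif_fraction

  ## knockout artifact sites: mappable, away from planted sites
  art_rows <- list()
  occupied <- GRanges(sites$chrom, IRanges::IRanges(sites$start + 1L, sites$end))
  for (i in seq_len(cfg$n_null_artifact_sites)) {
    for (try in 1:200) {
      ch <- sample(chroms, 1)
      s0 <- floor(runif(1, 0, cfg$chrom_len_bp - cfg$site_bp))
      cand <- GRanges(ch, IRanges::IRanges(s0 + 1L, s0 + cfg$site_bp))
      if (mappable_bp(ch, s0, s0 + cfg$site_bp, midx) == cfg$site_bp &&
          !any(IRanges::overlapsAny(cand, occupied))) {
        art_rows[[i]] <- data.frame(chrom = ch, start = s0, end = s0 + cfg$site_bp,
                                    stringsAsFactors = FALSE)
        occupied <- suppressWarnings(c(occupied, cand))
        break
      }
    }
  }
  artifacts <- do.call(rbind, art_rows)

  ## plant motifs into the genome sequence
  motif_rows <- list()
  plant <- function(ch, s0, motif) {
    at <- s0 + (cfg$site_bp - nchar(motif)) %/% 2  # 0-based
    Biostrings::subseq(genome[[ch]], at + 1L, at + nchar(motif)) <<-
      Biostrings::DNAString(motif)
    data.frame(chrom = ch, start = at, end = at + nchar(motif),
               motif = motif, stringsAsFactors = FALSE)
  }
  k <- 0L
  for (i in seq_len(nrow(sites))) if (sites$has_motif[i]) {
    k <- k + 1L
    motif_rows[[k]] <- plant(sites$chrom[i], sites$start[i], cfg$motif_consensus)
  }
  for (i in seq_len(nrow(artifacts))) {
    k <- k + 1L
    motif_rows[[k]] <- plant(artifacts$chrom[i], artifacts$start[i], cfg$decoy_consensus)
  }
  motif_positions <- do.call(rbind, motif_rows)

  ## planted response types
  types <- rep(names(cfg$n_de_per_type), times = cfg$n_de_per_type)
  de_genes <- sample(genes$gene_id, length(types))
  truth_types <- setNames(rep("none", length(genes)), genes$gene_id)
  truth_types[de_genes] <- types

  ## per-condition enriched site sets; artifact sites are non-specific and so
  ## appear in every ChIP sample, wild-type and knockout alike
  art4 <- cbind(artifacts, gene_id = NA_character_)
  wt_veh <- sites[sites$class %in% c("veh_only", "both"),
                  c("chrom", "start", "end", "gene_id")]
  wt_lig <- sites[sites$class %in% c("lig_only", "both"),
                  c("chrom", "start", "end", "gene_id")]
  site_conditions <- list(
    chip_wt_veh = rbind(wt_veh, art4),
    chip_wt_lig = rbind(wt_lig, art4),
    chip_null_veh = art4,
    chip_null_lig = art4
  )

  manifest <- list(config = unclass(cfg),
                   chrom_lengths = setNames(rep(L, cfg$n_chroms), chroms),
                   planted_sites = sites,
                   artifact_sites = artifacts,
                   site_conditions = site_conditions,
                   response_types = truth_types,
                   motif_positions = motif_positions)
  class(manifest) <- "truth_manifest"

  structure(list(genome = genome, genes = genes, mappability = mappability,
                 manifest = manifest),
            class = "cistrome_sim")
}

# One random gene model: exon/intron structure plus a CDS leaving short UTRs.
build_gene <- function(chrom, s0, width, strand, gene_id) {
  n_ex <- sample(2:4, 1)
  # allocate exon and intron widths (alternating, exons first/last)
  parts <- 2L * n_ex - 1L
  raw <- runif(parts, 0.5, 1.5)
  w <- pmax(80L, as.integer(floor(raw / sum(raw) * width)))
  w[parts] <- width - sum(w[-parts])
  if (w[parts] < 80L) { w[1] <- w[1] + w[parts] - 80L; w[parts] <- 80L }
  bounds <- cumsum(c(0L, w))
  exon_idx <- seq(1, parts, by = 2)
  ex_start <- s0 + bounds[exon_idx]           # 0-based
  ex_end <- s0 + bounds[exon_idx + 1]
  utr5 <- min(60L, w[1] %/% 3)
  utr3 <- min(60L, w[parts] %/% 3)
  if (strand == "+") {
    cds0 <- ex_start[1] + utr5; cds1 <- ex_end[n_ex] - utr3
  } else {
    cds0 <- ex_start[1] + utr3; cds1 <- ex_end[n_ex] - utr5
  }
  gr <- GRanges(chrom, IRanges::IRanges(s0 + 1L, s0 + width), strand = strand)
  mcols(gr)$gene_id <- gene_id
  mcols(gr)$thick <- IRanges::IRanges(cds0 + 1L, cds1)
  mcols(gr)$blocks <- IRanges::IRangesList(IRanges::IRanges(ex_start + 1L, ex_end))
  list(gr = gr)
}

#' Simulate a tag track for one sample condition
#'
#' Background tags fall uniformly over mappable bp at `background_rate`;
#' each planted site for the condition receives `enrichment_factor` times
#' the background expectation within its bounds. Knockout conditions carry
#' only artifact sites plus background; input conditions are pure background.
#' The total is a multinomial draw, so tag totals are exact.
#'
#' @param sim a `cistrome_sim` from [simulate_genome()].
#' @param condition one of `chip_wt_veh`, `chip_wt_lig`, `chip_null_veh`,
#'   `chip_null_lig`, `input_wt`, `input_null`.
#' @return `TagTrack`.
#' @export
simulate_tags <- function(sim, condition) {
  stopifnot(inherits(sim, "cistrome_sim"))
  if (!condition %in% SIM_CONDITIONS)
    stop("unknown condition '", condition, "'; expected one of: ",
         paste(SIM_CONDITIONS, collapse = ", "), call. = FALSE)
  cfg <- sim$manifest$config
  sub_seed <- cfg$seed + 1000L * match(condition, SIM_CONDITIONS)
  with_sim_seed(sub_seed, simulate_tags_impl(sim, condition, cfg))
}

simulate_tags_impl <- function(sim, condition, cfg) {
  midx <- mappability_index(sim$mappability)
  chroms <- names(sim$manifest$chrom_lengths)
  map_total <- vapply(chroms, function(ch) {
    i <- midx[[ch]]; if (is.null(i)) 0 else i$cs[length(i$cs)]
  }, 0)

  sites <- if (startsWith(condition, "input")) NULL
           else sim$manifest$site_conditions[[condition]]
  n_sites <- if (is.null(sites)) 0L else nrow(sites)

  site_map <- if (n_sites > 0)
    vapply(seq_len(n_sites), function(i)
      mappable_bp(sites$chrom[i], sites$start[i], sites$end[i], midx), 0)
  else numeric(0)

  ## expected mass: background everywhere + (EF - 1) extra within sites
  mass_bg <- cfg$background_rate * sum(map_total)
  mass_sites <- (cfg$enrichment_factor - 1) * cfg$background_rate * site_map
  mass <- c(mass_bg, mass_sites)
  total <- round(sum(mass))
  counts <- as.vector(rmultinom(1, total, prob = mass))

  ## background tags: uniform over mappable bp genome-wide
  draw_uniform_mappable <- function(ch, n) {
    if (n == 0) return(numeric(0))
    i <- midx[[ch]]
    u <- floor(runif(n, 0, i$cs[length(i$cs)]))  # offset into mappable space
    j <- pmin(findInterval(u + 0.5, c(0, i$cs)), length(i$s))
    i$s[j] + (u - c(0, i$cs)[j])
  }
  bg_per_chrom <- as.vector(rmultinom(1, counts[1], prob = map_total))
  pos_list <- lapply(seq_along(chroms), function(ci) {
    data.frame(chrom = chroms[ci],
               pos = draw_uniform_mappable(chroms[ci], bg_per_chrom[ci]))
  })

  ## site tags: uniform over mappable bp within each site
  if (n_sites > 0) {
    for (i in seq_len(n_sites)) {
      n <- counts[i + 1L]
      if (n == 0) next
      ch <- sites$chrom[i]
      ic <- midx[[ch]]
      lo <- mappable_cum(ic, sites$start[i])
      u <- lo + floor(runif(n, 0, site_map[i]))
      j <- pmin(findInterval(u + 0.5, c(0, ic$cs)), length(ic$s))
      pos_list[[length(pos_list) + 1L]] <-
        data.frame(chrom = ch, pos = ic$s[j] + (u - c(0, ic$cs)[j]))
    }
  }
  df <- do.call(rbind, pos_list)
  tag_track(df, sample = condition)
}

## response-type condition shifts (relative to wild-type vehicle):
##   constitutive +1 means knockout samples shifted up (receptor represses),
##   ligand +1 means wild-type + ligand shifted up (ligand activates).
type_effects <- function(type) {
  const <- c(I = 1, II = -1, III = 0, IV = 0, V = 1, VI = -1, VII = -1, VIII = 1,
             none = 0)
  lig <- c(I = 0, II = 0, III = 1, IV = -1, V = 1, VI = -1, VII = 1, VIII = -1,
           none = 0)
  cbind(const = const[type], lig = lig[type])
}

#' Simulate the log2 expression matrix for the 2x2 design
#'
#' Gene baselines are normal on the log2 scale; the planted response type of
#' each gene shifts condition means by `log2(fold_change)` following the
#' eight-type semantics: a constitutive shift applies to both knockout
#' samples (the receptor's absence reveals repression or activation), and a
#' ligand shift applies to wild-type + ligand only (ligand responses require
#' the receptor, so knockout samples never respond to ligand).
#'
#' @param sim a `cistrome_sim`.
#' @return list of class `expr_sim`: `matrix` (genes x samples, log2),
#'   `design` (data.frame: sample, genotype, treatment, replicate).
#' @export
simulate_expression <- function(sim) {
  stopifnot(inherits(sim, "cistrome_sim"))
  cfg <- sim$manifest$config
  with_sim_seed(cfg$seed + 77L, {
    genes <- names(sim$manifest$response_types)
    types <- sim$manifest$response_types
    delta <- log2(cfg$fold_change)
    eff <- type_effects(types)
    baseline <- rnorm(length(genes), cfg$baseline_mean, cfg$baseline_sd)
    cond <- expand.grid(treatment = c("vehicle", "ligand"),
                        genotype = c("wt", "null"),
                        stringsAsFactors = FALSE)[, c(2, 1)]
    design <- do.call(rbind, lapply(seq_len(nrow(cond)), function(i) {
      data.frame(sample = sprintf("%s_%s_r%d", cond$genotype[i],
                                  substr(cond$treatment[i], 1, 3), seq_len(cfg$n_reps)),
                 genotype = cond$genotype[i], treatment = cond$treatment[i],
                 replicate = seq_len(cfg$n_reps), stringsAsFactors = FALSE)
    }))
    mu <- sapply(seq_len(nrow(design)), function(j) {
      g <- design$genotype[j]; tr <- design$treatment[j]
      shift <- numeric(length(genes))
      if (g == "null") shift <- shift + eff[, "const"] * delta
      if (g == "wt" && tr == "ligand") shift <- shift + eff[, "lig"] * delta
      baseline + shift
    })
    mat <- mu + matrix(rnorm(length(mu), 0, cfg$replicate_sd), nrow = nrow(mu))
    dimnames(mat) <- list(genes, design$sample)
    structure(list(matrix = mat, design = design), class = "expr_sim")
  })
}

#' Write all simulated inputs to a directory
#'
#' Writes genome FASTA, gene models BED12, mappability BED3, one tag BED6
#' per condition, the expression matrix and sample sheet TSVs, and the truth
#' manifest JSON. Every file is re-readable by the package's own readers.
#'
#' @param sim a `cistrome_sim`.
#' @param dir output directory (created if needed).
#' @param conditions which tag tracks to write.
#' @param expression optionally a precomputed [simulate_expression()] result.
#' @return invisibly, a named list of written paths.
#' @export
write_simulation <- function(sim, dir, conditions = SIM_CONDITIONS,
                             expression = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  paths$genome <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, paths$genome)
  paths$genes <- file.path(dir, "genes.bed")
  write_gene_models(sim$genes, paths$genes)
  paths$mappability <- file.path(dir, "mappability.bed")
  write_mappability(sim$mappability, paths$mappability)
  for (cond in conditions) {
    p <- file.path(dir, paste0("tags_", cond, ".bed"))
    write_tags(simulate_tags(sim, cond), p)
    paths[[paste0("tags_", cond)]] <- p
  }
  ex <- if (is.null(expression)) simulate_expression(sim) else expression
  paths$expression <- file.path(dir, "expression.tsv")
  write_expression(ex$matrix, ex$design,
                   paths$expression, file.path(dir, "samples.tsv"))
  paths$samples <- file.path(dir, "samples.tsv")
  paths$manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(sim$manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(paths)
}
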