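# Synthetic paired tumor/normal data with known truth: germline-het SNP
# tracks with a telomere-anchored CN-LOH segment, per-tumor variant tables,
# and multi-tumor patients with truncal sharing. Depths are overdispersed
# (negative binomial, variance = dispersion x mean) to stress boundary
# detection the way real exome capture does; allele counts are binomial.
# No read-level or sequencing-error simulation.

#' Build and validate a SNP-track simulation configuration
#'
#' Defaults describe a realistic chromosome-arm scenario: a 36 Mb arm (the
#' size of 16p) carrying the target locus at 2.1 Mb, ~800 informative
#' germline het SNPs, mean exome depth 80 with variance twice the mean,
#' tumor purity 0.5, and a telomere-anchored CN-LOH segment ending at 10 Mb
#' (published region sizes span ~3-30 Mb).
#'
#' @param seed RNG seed (\code{NULL} = do not reseed; used when a caller
#'   manages the RNG stream).
#' @param chrom chromosome name.
#' @param chrom_length arm length in bp.
#' @param n_snps number of germline heterozygous SNPs.
#' @param snp_spacing \code{"random"} (uniform positions) or
#'   \code{"uniform"} (equally spaced).
#' @param mean_depth mean read depth, both samples.
#' @param depth_dispersion variance/mean ratio of depth (>= 1; 1 = Poisson).
#' @param purity tumor purity in \[0, 1\].
#' @param cnloh_breakpoint CN-LOH breakpoint (LOH spans telomere to here);
#'   \code{NULL} for no LOH.
#' @param locus_pos position of the target tumor-suppressor locus.
#' @return validated config list of class \code{simulation_config}.
#' @export
simulation_config <- function(seed = 1, chrom = "chr16",
                              chrom_length = 36e6, n_snps = 800,
                              snp_spacing = c("random", "uniform"),
                              mean_depth = 80, depth_dispersion = 2,
                              purity = 0.5, cnloh_breakpoint = 10e6,
                              locus_pos = 2.1e6) {
  snp_spacing <- match.arg(snp_spacing)
  if (!is.null(seed) && (!is.numeric(seed) || is.na(seed)))
    stop("seed must be numeric or NULL")
  if (is.na(purity) || purity < 0 || purity > 1)
    stop("purity must be in [0, 1]")
  if (!is.null(cnloh_breakpoint) && cnloh_breakpoint >= chrom_length)
    stop("cnloh_breakpoint must be < chrom_length")
  if (n_snps < 1) stop("n_snps must be >= 1")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (depth_dispersion < 1) stop("depth_dispersion must be >= 1")
  structure(list(seed = seed, chrom = chrom, chrom_length = chrom_length,
                 n_snps = n_snps, snp_spacing = snp_spacing,
                 mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion, purity = purity,
                 cnloh_breakpoint = cnloh_breakpoint,
                 locus_pos = locus_pos),
            class = "simulation_config")
}

draw_depth <- function(n, mean_depth, dispersion) {
  if (dispersion <= 1) stats::rpois(n, mean_depth)
  else stats::rnbinom(n, mu = mean_depth,
                      size = mean_depth / (dispersion - 1))
}

#' Simulate a paired tumor/normal SNP allele-count track
#'
#' Places germline heterozygous SNPs along the arm; normal alt counts are
#' Binomial(depth, 1/2). Inside the CN-LOH segment one haplotype is lost
#' region-wide: each SNP's alt allele sits on the retained or the lost
#' haplotype according to a simulated phase (drawn once per SNP), so skew
#' direction alternates across SNPs while its magnitude is set by purity —
#' tumor alt counts are Binomial(depth, (1+p)/2) or Binomial(depth, (1-p)/2).
#' Outside the segment the expected tumor AF is 1/2.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list: \code{track} (SNP track data.frame) and \code{truth}
#'   (breakpoint, purity, per-SNP phase and expected AF).
#' @export
simulate_snp_track <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  if (!is.null(config$seed)) set.seed(config$seed)
  pos <- if (config$snp_spacing == "random")
    sort(sample.int(config$chrom_length, config$n_snps))
  else round(seq(1, config$chrom_length, length.out = config$n_snps))
  n <- length(pos)
  in_loh <- if (is.null(config$cnloh_breakpoint)) rep(FALSE, n)
  else pos <= config$cnloh_breakpoint
  phase_retained <- stats::runif(n) < 0.5  # is the ALT allele retained?
  af_true <- rep(0.5, n)
  af_true[in_loh & phase_retained] <-
    expected_af("germline_het_cnloh_retained", config$purity)
  af_true[in_loh & !phase_retained] <-
    expected_af("germline_het_cnloh_lost", config$purity)
  nd <- draw_depth(n, config$mean_depth, config$depth_dispersion)
  td <- draw_depth(n, config$mean_depth, config$depth_dispersion)
  nalt <- stats::rbinom(n, nd, 0.5)
  talt <- stats::rbinom(n, td, af_true)
  track <- data.frame(
    chrom = config$chrom, pos = pos,
    normal_ref = nd - nalt, normal_alt = nalt,
    tumor_ref = td - talt, tumor_alt = talt,
    paired = TRUE, stringsAsFactors = FALSE
  )
  list(track = track,
       truth = list(breakpoint = config$cnloh_breakpoint,
                    purity = config$purity, in_loh = in_loh,
                    phase_retained = phase_retained, af_true = af_true,
                    locus_pos = config$locus_pos))
}

#' Simulate a windowed coverage-ratio track
#'
#' Tumor/normal depth-ratio windows over an interval, given true integer
#' copy number per window and tumor purity: the expected ratio is
#' \code{(p * copies + (1-p) * 2) / 2}, with log-normal noise.
#'
#' @param starts,ends window coordinates.
#' @param copies true tumor copy number per window.
#' @param purity tumor purity.
#' @param noise_sd standard deviation of log-normal noise (default 0.05).
#' @return data.frame: start, end, ratio, true_copies.
#' @export
simulate_coverage_ratios <- function(starts, ends, copies, purity,
                                     noise_sd = 0.05) {
  mu <- (purity * copies + (1 - purity) * 2) / 2
  data.frame(start = starts, end = ends,
             ratio = mu * exp(stats::rnorm(length(starts), 0, noise_sd)),
             true_copies = copies)
}

.SYNTH_GENES <- sprintf("SGENE%03d", 1:500)

synth_variant_row <- function(patient_id, sample_id, gene, variant_type,
                              cdna, protein, af_true, mean_depth,
                              dispersion, origin) {
  depth <- max(draw_depth(1, mean_depth, dispersion), 1)
  alt <- stats::rbinom(1, depth, af_true)
  data.frame(patient_id = patient_id, sample_id = sample_id, gene = gene,
             variant_type = variant_type, cdna_change = cdna,
             protein_change = protein, mutant_reads = alt,
             ref_reads = depth - alt, origin = origin,
             bidirectional = TRUE, functional_class = NA_character_,
             uncovered = depth == 0,
             af = if (depth > 0) alt / depth else NA_real_,
             stringsAsFactors = FALSE)
}

random_missense <- function(gene) {
  pos <- sample.int(2000, 1)
  list(cdna = sprintf("c.%dG>A", 3 * pos - 1),
       protein = sprintf("p.G%dD", pos))
}

#' Multi-tumor patient simulation presets
#'
#' \describe{
#'   \item{p13_like}{16 tumors sharing one germline TSC2 frameshift: a
#'     3-tumor truncal group with 2 shared somatic mutations and a common
#'     CN-LOH breakpoint, 2 tumors with somatic point second hits, 9 tumors
#'     with CN-LOH at distinct breakpoints, and 2 tumors with no second hit
#'     (mechanism none).}
#'   \item{sporadic_two_hit}{one tumor, two distinct somatic TSC2 variants,
#'     no LOH.}
#'   \item{homozygous_del}{one tumor whose TSC2 locus sits in a 50 kb
#'     homozygous deletion nested inside a 150 kb single-copy-loss region.}
#' }
#'
#' @param preset preset name.
#' @param seed RNG seed.
#' @param purity tumor purity (scalar, recycled per tumor). Default 0.5
#'   (mid-cohort); the homozygous-deletion preset defaults to 0.8, the
#'   purity implied by the observed probe depressions to 0.29-0.45 copies.
#' @param mean_depth mean depth.
#' @param n_snps SNPs per tumor track.
#' @return patient-level config list for \code{\link{simulate_patient}}.
#' @export
patient_preset <- function(preset = c("p13_like", "sporadic_two_hit",
                                      "homozygous_del"),
                           seed = 1, purity = NULL, mean_depth = 86,
                           n_snps = 800) {
  preset <- match.arg(preset)
  if (is.null(purity)) purity <- if (preset == "homozygous_del") 0.8 else 0.5
  base <- list(seed = seed, purity = purity, mean_depth = mean_depth,
               n_snps = n_snps, chrom = "chr16", chrom_length = 36e6,
               locus_pos = 2.1e6, depth_dispersion = 2, preset = preset,
               n_private_lambda = 4)
  if (preset == "p13_like") {
    base$n_tumors <- 16L
    base$second_hit <- c(rep("cnloh", 3), rep("point_mutation", 2),
                         rep("cnloh", 9), rep("none", 2))
    # truncal trio shares breakpoint 8 Mb; the other CN-LOH tumors get
    # distinct breakpoints spread over the published 3-30 Mb size range
    base$breakpoints <- c(rep(8e6, 3), NA, NA,
                          seq(3e6, 30e6, length.out = 9), NA, NA)
    base$truncal_groups <- list(list(members = 1:3, n_shared = 2))
    base$germline <- TRUE
  } else if (preset == "sporadic_two_hit") {
    base$n_tumors <- 1L
    base$second_hit <- "two_somatic"
    base$breakpoints <- NA
    base$truncal_groups <- list()
    base$germline <- FALSE
  } else {
    base$n_tumors <- 1L
    base$second_hit <- "homozygous_del"
    base$breakpoints <- NA
    base$truncal_groups <- list()
    base$germline <- FALSE
    # S7-like geometry: 50 kb homozygous dip centred on the locus, nested in
    # a 150 kb single-copy-loss interval
    base$hom_del <- list(hom_start = 2.08e6, hom_end = 2.13e6,
                         loss_start = 2.03e6, loss_end = 2.18e6)
  }
  base
}

#' Simulate a multi-tumor patient with known truth
#'
#' Every tumor carries the patient's germline first hit (when configured),
#' its own second-hit mechanism, and private somatic mutations
#' (Poisson-distributed count, synthetic gene vocabulary). Tumors in a
#' truncal group share the configured number of truncal somatic mutations
#' and the same CN-LOH breakpoint. Identical seeds give bit-identical
#' output.
#'
#' @param config a patient config from \code{\link{patient_preset}} (or an
#'   equivalently shaped list).
#' @return list: \code{patient_id}, \code{tumors} (per tumor: sample_id,
#'   track, coverage (when simulated), variants), \code{variants} (combined
#'   table), \code{truth} (mechanisms, breakpoints, truncal partition).
#' @export
simulate_patient <- function(config) {
  n <- config$n_tumors
  if (is.null(n) || n < 1) stop("n_tumors must be >= 1")
  if (length(config$second_hit) != n)
    stop("second_hit must have one entry per tumor")
  for (g in config$truncal_groups)
    if (any(g$members > n))
      stop("truncal group members inconsistent with n_tumors")
  set.seed(config$seed)
  purity <- rep_len(config$purity, n)
  patient_id <- "SIMP1"
  sample_ids <- sprintf("T%02d", seq_len(n))
  # truncal mutations, one set per group
  used_genes <- character(0)
  truncal <- lapply(config$truncal_groups, function(g) {
    genes <- sample(setdiff(.SYNTH_GENES, used_genes), g$n_shared)
    used_genes <<- c(used_genes, genes)
    lapply(genes, function(gene) c(gene = gene, random_missense(gene)))
  })
  germline_cdna <- "c.1000delA"
  tumors <- vector("list", n)
  mechanisms <- character(n)
  for (i in seq_len(n)) {
    hit <- config$second_hit[i]
    bp <- config$breakpoints[i]
    has_loh <- hit == "cnloh"
    track_cfg <- simulation_config(
      seed = NULL, chrom = config$chrom, chrom_length = config$chrom_length,
      n_snps = config$n_snps, mean_depth = config$mean_depth,
      depth_dispersion = config$depth_dispersion, purity = purity[i],
      cnloh_breakpoint = if (has_loh) bp else NULL,
      locus_pos = config$locus_pos
    )
    sim <- simulate_snp_track(track_cfg)
    rows <- list()
    if (isTRUE(config$germline)) {
      g_af <- if (has_loh)
        expected_af("germline_het_cnloh_retained", purity[i]) else 0.5
      rows[[length(rows) + 1]] <- synth_variant_row(
        patient_id, sample_ids[i], "TSC2", "frameshift_del", germline_cdna,
        "p.K334fs", g_af, config$mean_depth, config$depth_dispersion,
        "germline")
    }
    coverage <- NULL
    if (hit == "point_mutation") {
      ins_pos <- 100 + i  # unique per tumor
      rows[[length(rows) + 1]] <- synth_variant_row(
        patient_id, sample_ids[i], "TSC2", "frameshift_ins",
        sprintf("c.%d_%dinsT", ins_pos, ins_pos + 1),
        sprintf("p.F%dfs", ceiling(ins_pos / 3)),
        expected_af("somatic_het_no_loh", purity[i]),
        config$mean_depth, config$depth_dispersion, "somatic")
      mechanisms[i] <- "two_mutation"
    } else if (hit == "two_somatic") {
      for (v in 1:2) {
        m <- random_missense("TSC2")
        rows[[length(rows) + 1]] <- synth_variant_row(
          patient_id, sample_ids[i], "TSC2", "nonsense",
          sprintf("c.%dC>T", 500 * v), sprintf("p.Q%d*", 167 * v),
          expected_af("somatic_het_no_loh", purity[i]),
          config$mean_depth, config$depth_dispersion, "somatic")
      }
      mechanisms[i] <- "two_mutation"
    } else if (hit == "homozygous_del") {
      hd <- config$hom_del
      win <- seq(hd$loss_start - 50e3, hd$loss_end + 50e3 - 1, by = 10e3)
      copies <- ifelse(win + 10e3 > hd$hom_start & win <= hd$hom_end, 0,
                       ifelse(win + 10e3 > hd$loss_start & win <= hd$loss_end,
                              1, 2))
      coverage <- simulate_coverage_ratios(win, win + 10e3, copies,
                                           purity[i])
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = patient_id, sample_id = sample_ids[i], gene = "TSC2",
        variant_type = "genomic_del", cdna_change = NA_character_,
        protein_change = NA_character_, mutant_reads = NA_real_,
        ref_reads = NA_real_, origin = "somatic", bidirectional = TRUE,
        functional_class = NA_character_, uncovered = TRUE, af = NA_real_,
        stringsAsFactors = FALSE)
      mechanisms[i] <- "homozygous_deletion"
    } else if (has_loh) {
      mechanisms[i] <- if (isTRUE(config$germline)) "mutation_plus_cnloh"
      else "cnloh_only"
    } else {
      mechanisms[i] <- if (isTRUE(config$germline)) "none" else "none"
    }
    # truncal somatic mutations for group members
    for (gi in seq_along(config$truncal_groups)) {
      g <- config$truncal_groups[[gi]]
      if (i %in% g$members)
        for (tm in truncal[[gi]])
          rows[[length(rows) + 1]] <- synth_variant_row(
            patient_id, sample_ids[i], tm$gene, "missense", tm$cdna,
            tm$protein, expected_af("somatic_het_no_loh", purity[i]),
            config$mean_depth, config$depth_dispersion, "somatic")
    }
    # private somatic mutations, genes unique across the patient
    n_priv <- stats::rpois(1, config$n_private_lambda)
    if (n_priv > 0) {
      genes <- sample(setdiff(.SYNTH_GENES, used_genes), n_priv)
      used_genes <- c(used_genes, genes)
      for (gene in genes) {
        m <- random_missense(gene)
        rows[[length(rows) + 1]] <- synth_variant_row(
          patient_id, sample_ids[i], gene, "missense", m$cdna, m$protein,
          expected_af("somatic_het_no_loh", purity[i]),
          config$mean_depth, config$depth_dispersion, "somatic")
      }
    }
    variants <- do.call(rbind, rows)
    tumors[[i]] <- list(sample_id = sample_ids[i], track = sim$track,
                        track_truth = sim$truth, coverage = coverage,
                        variants = variants)
  }
  partition <- lapply(config$truncal_groups, function(g)
    sample_ids[g$members])
  all_variants <- do.call(rbind, lapply(tumors, `[[`, "variants"))
  class(all_variants) <- c("variant_table", "data.frame")
  list(patient_id = patient_id, tumors = tumors, variants = all_variants,
       truth = list(
         mechanisms = stats::setNames(mechanisms, sample_ids),
         breakpoints = stats::setNames(config$breakpoints, sample_ids),
         truncal_partition = partition,
         purity = stats::setNames(purity, sample_ids),
         locus_pos = config$locus_pos))
}

#' Write a simulated patient to disk in the pipeline's formats
#'
#' Emits one SNP-track TSV per tumor, the combined variant TSV, and a truth
#' JSON, so simulated data can be fed back through the file-based interface.
#'
#' @param sim result of \code{\link{simulate_patient}}.
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
export_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (tm in sim$tumors) {
    p <- file.path(dir, paste0("track_", tm$sample_id, ".tsv"))
    write_snp_track(tm$track, p)
    paths[[paste0("track_", tm$sample_id)]] <- p
  }
  vp <- file.path(dir, "variants.tsv")
  write_variant_table(sim$variants, vp)
  paths$variants <- vp
  tp <- file.path(dir, "truth.json")
  truth <- sim$truth
  truth$truncal_partition <- lapply(truth$truncal_partition, as.list)
  # named vectors become JSON objects (not arrays) so names survive
  truth$mechanisms <- as.list(truth$mechanisms)
  truth$breakpoints <- as.list(truth$breakpoints)
  truth$purity <- as.list(truth$purity)
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  paths$truth <- tp
  invisible(paths)
}
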