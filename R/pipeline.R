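# End-to-end runner: fixtures or simulated data in; per-sample status,
# burden summary, LOH regions, contingency + Fisher p, clone trees and a
# reproduction section out. The R functions themselves are the interface;
# every number in a report is computed at run time from the inputs.

.PIPELINE_DEFAULTS <- list(
  min_alt_reads = 3, min_af = 0.05,
  het_min_depth = 20, het_af_low = 0.40, het_af_high = 0.60,
  skew_af_low = 0.40, skew_af_high = 0.60,
  min_skewed = 10, max_interior_discordant_frac = 0.1,
  log2_tolerance = 0.3, territory_mb = 33, min_shared = 2,
  seed = 1, output_dir = NULL, variant_table = NULL, snp_tracks = NULL
)

#' Validate and normalise a pipeline configuration
#'
#' Unknown keys are rejected; missing keys are filled with the documented
#' defaults; out-of-range thresholds raise an error naming the field.
#'
#' @param config named list of overrides (may be empty).
#' @return the normalised config list.
#' @export
validate_config <- function(config = list()) {
  unknown <- setdiff(names(config), names(.PIPELINE_DEFAULTS))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.PIPELINE_DEFAULTS, config,
                           keep.null = TRUE)
  chk_range <- function(field, lo, hi) {
    v <- cfg[[field]]
    if (!is.numeric(v) || is.na(v) || v < lo || v > hi)
      stop(field, " must be in [", lo, ", ", hi, "]")
  }
  chk_range("min_af", 0, 1)
  chk_range("het_af_low", 0, 1); chk_range("het_af_high", 0, 1)
  chk_range("skew_af_low", 0, 1); chk_range("skew_af_high", 0, 1)
  chk_range("max_interior_discordant_frac", 0, 1)
  if (cfg$het_af_low >= cfg$het_af_high)
    stop("het_af_low must be < het_af_high")
  if (cfg$skew_af_low >= cfg$skew_af_high)
    stop("skew_af_low must be < skew_af_high")
  if (cfg$min_alt_reads < 0) stop("min_alt_reads must be >= 0")
  if (cfg$min_skewed < 1) stop("min_skewed must be >= 1")
  if (cfg$log2_tolerance <= 0) stop("log2_tolerance must be > 0")
  if (cfg$territory_mb <= 0) stop("territory_mb must be > 0")
  if (cfg$min_shared < 1) stop("min_shared must be >= 1")
  cfg
}

fixture_loh_groups <- function(samples, patient) {
  sub <- samples[samples$patient_id == patient &
                   !is.na(samples$loh_region_id) &
                   samples$loh_region_id != "uncertain", , drop = FALSE]
  if (nrow(sub) == 0) return(list())
  unname(split(sub$sample_id, sub$loh_region_id))
}

#' Run the full analysis pipeline
#'
#' With no input paths in the config, runs on the packaged cohort fixtures
#' and appends a reproduction section with the cohort's headline numbers
#' (biallelic fraction, CN-LOH fraction, somatic TSC2 variant counts,
#' burden median/rate, mechanism contingency with Fisher p, and the
#' multifocal-patient clone trees). With \code{variant_table} (and
#' optionally \code{snp_tracks}) paths set, the same stages run on user
#' data. Deterministic given config + inputs.
#'
#' @param config named list of overrides, see \code{\link{validate_config}}.
#' @return object of class \code{secondhit_report}.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  if (is.null(cfg$variant_table)) {
    fx <- load_fixtures()
    table1 <- fx$table1; table2 <- fx$table2; samples <- fx$samples
  } else {
    table1 <- read_variant_table(cfg$variant_table)
    table2 <- table1[!(table1$gene %in% c("TSC1", "TSC2")), , drop = FALSE]
    table1 <- table1[table1$gene %in% c("TSC1", "TSC2"), , drop = FALSE]
    first <- !duplicated(table1$sample_id)
    ns <- sum(first)
    samples <- data.frame(
      sample_id = table1$sample_id[first],
      patient_id = table1$patient_id[first],
      source = rep(NA_character_, ns), tsc = rep(NA, ns),
      paired = rep(TRUE, ns),
      loh_annotation = if (!is.null(table1$loh_annotation))
        table1$loh_annotation[first] else rep(NA_character_, ns),
      loh_region_id = rep(NA_character_, ns), stringsAsFactors = FALSE)
  }
  if (nrow(samples) > 0) {
    statuses <- classify_cohort(table1, samples)
    statuses$tsc <- samples$tsc[match(statuses$sample_id,
                                      samples$sample_id)]
  } else {
    statuses <- data.frame(sample_id = character(0), locus = character(0),
                           mechanism = character(0), biallelic = logical(0),
                           n_hits = integer(0), loh = logical(0),
                           tsc = logical(0), stringsAsFactors = FALSE)
  }

  paired_ids <- samples$sample_id[samples$paired]
  counts <- count_nonsyn_per_sample(table2, paired_ids)
  uniq <- dedup_unique_mutations(table2)
  covered_calls <- sum(!table2$uncovered &
                         !(table2$gene %in% c("TSC1", "TSC2")))
  burden <- if (length(counts) > 0)
    burden_summary(counts, uniq, territory_mb = cfg$territory_mb,
                   call_count = covered_calls) else NULL
  subclonal <- rbind(subclonal_tally(table2, denominator = "per_call"),
                     subclonal_tally(table2, denominator = "per_unique"))

  contingency <- NULL; fisher_p <- NA_real_
  if (!any(is.na(statuses$tsc))) {
    contingency <- mechanism_contingency(
      statuses, stats::setNames(statuses$tsc, statuses$sample_id))
    fisher_p <- fisher_exact_two_sided(contingency)
  }

  tsc2_somatic <- count_somatic_tsc_variants(table1, "TSC2")

  multi <- names(which(table(samples$patient_id) > 1))
  trees <- list()
  for (p in multi) {
    sids <- samples$sample_id[samples$patient_id == p]
    p_t2 <- table2[table2$patient_id == p, , drop = FALSE]
    groups <- shared_mutation_groups(p_t2, min_shared = cfg$min_shared)
    p_t1 <- table1[table1$patient_id == p, , drop = FALSE]
    germ <- p_t1$cdna_change[p_t1$origin == "germline"][1]
    trees[[p]] <- build_clone_tree(
      p, statuses[statuses$sample_id %in% sids, , drop = FALSE], groups,
      loh_groups = fixture_loh_groups(samples, p),
      tsc_variants = p_t1,
      germline_annotation = if (is.na(germ)) NULL else germ)
  }

  reproduction <- list(
    n_samples = nrow(samples),
    n_patients = length(unique(samples$patient_id)),
    n_biallelic = sum(statuses$biallelic),
    biallelic_fraction = mean(statuses$biallelic),
    n_cnloh = sum(statuses$loh),
    cnloh_fraction = mean(statuses$loh),
    tsc2_somatic_variants = tsc2_somatic$total,
    tsc2_somatic_nonsense = unname(tsc2_somatic$by_type["nonsense"]),
    burden_median = if (is.null(burden)) 0 else burden$median,
    burden_range = if (is.null(burden)) c(0, 0) else burden$range,
    rate_per_mb = if (is.null(burden)) 0 else burden$rate_per_mb,
    fisher_p = fisher_p
  )

  report <- structure(list(
    config = cfg, statuses = statuses, counts = counts, burden = burden,
    subclonal = subclonal, contingency = contingency, fisher_p = fisher_p,
    tsc2_somatic = tsc2_somatic, trees = trees, reproduction = reproduction
  ), class = "secondhit_report")

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_sample_status(statuses, file.path(cfg$output_dir,
                                            "sample_status.tsv"))
    utils::write.table(
      data.frame(sample_id = names(counts), n_mutations = counts),
      file.path(cfg$output_dir, "per_sample_counts.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    # output_dir is excluded from the provenance echo so that two runs into
    # different directories produce byte-identical reports
    cfg_echo <- cfg[!vapply(cfg, is.null, logical(1))]
    cfg_echo$output_dir <- NULL
    jsonlite::write_json(
      list(config = cfg_echo,
           reproduction = reproduction,
           burden = if (is.null(burden)) NULL else
             list(median = burden$median, range = burden$range,
                  rate_per_mb = burden$rate_per_mb,
                  unique_mutations = burden$unique_mutations,
                  call_count = burden$call_count,
                  spectrum = burden$spectrum),
           subclonal = subclonal,
           contingency = contingency,
           fisher_p = fisher_p),
      file.path(cfg$output_dir, "report.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
    for (p in names(trees)) {
      ex <- export_tree(trees[[p]],
                        json_path = file.path(cfg$output_dir,
                                              paste0("clone_tree_", p,
                                                     ".json")))
      writeLines(ex$newick, file.path(cfg$output_dir,
                                      paste0("clone_tree_", p, ".nwk")))
    }
  }
  report
}

#' @export
print.secondhit_report <- function(x, ...) {
  r <- x$reproduction
  cat("second-hit analysis report\n")
  cat(sprintf("  %d samples / %d patients\n", r$n_samples, r$n_patients))
  cat(sprintf("  biallelic TSC1/TSC2 loss: %d/%d (%.0f%%)\n",
              r$n_biallelic, r$n_samples, 100 * r$biallelic_fraction))
  cat(sprintf("  copy-neutral LOH: %d/%d (%.0f%%)\n", r$n_cnloh,
              r$n_samples, 100 * r$cnloh_fraction))
  cat(sprintf("  somatic TSC2 variants: %d (%d nonsense)\n",
              r$tsc2_somatic_variants, r$tsc2_somatic_nonsense))
  cat(sprintf("  burden: median %g/tumor (range %g-%g), %.2f/Mb\n",
              r$burden_median, r$burden_range[1], r$burden_range[2],
              r$rate_per_mb))
  if (!is.na(r$fisher_p))
    cat(sprintf("  mechanism contingency Fisher p = %.4f\n", r$fisher_p))
  for (p in names(x$trees)) {
    tr <- x$trees[[p]]
    ng <- length(tr$groups)
    if (ng > 0)
      cat(sprintf("  %s: %d truncal group(s): %s\n", p, ng,
                  paste(vapply(tr$groups, function(g)
                    paste0("{", paste(g$samples, collapse = ","), "}"),
                    character(1)), collapse = " ")))
  }
  invisible(x)
}

#' Analyse one tumor's SNP track for locus LOH
#'
#' Runs het-SNP selection, skew calling and region delineation, and reports
#' whether a region's confident span covers the locus (or only an
#' uncertainty flank does).
#'
#' @param track paired SNP track.
#' @param locus_pos locus position.
#' @param cfg validated pipeline config.
#' @return list: \code{regions}, \code{loh_at_locus}, \code{flank_only},
#'   \code{locus_region} (row index into regions or NA).
#' @export
analyze_tumor_track <- function(track, locus_pos, cfg = validate_config()) {
  hets <- identify_het_snps(track, min_depth = cfg$het_min_depth,
                            af_low = cfg$het_af_low,
                            af_high = cfg$het_af_high)
  regions <- delineate_loh_regions(
    call_skew(hets, cfg$skew_af_low, cfg$skew_af_high),
    min_skewed = cfg$min_skewed,
    max_interior_discordant_frac = cfg$max_interior_discordant_frac)
  covers <- which(regions$confident_start <= locus_pos &
                    regions$confident_end >= locus_pos)
  flank <- which(regions$uncertain_start <= locus_pos &
                   regions$uncertain_end >= locus_pos)
  list(regions = regions,
       loh_at_locus = length(covers) > 0,
       flank_only = length(covers) == 0 && length(flank) > 0,
       locus_region = if (length(covers) > 0) covers[1]
       else if (length(flank) > 0) flank[1] else NA_integer_)
}

#' Analyse a simulated multi-tumor patient end to end
#'
#' The scoring path for simulation studies: per tumor, LOH mapping from the
#' SNP track (and deletion detection from the coverage track when present),
#' variant filtering, mechanism classification; then mutation-sharing
#' groups, LOH-boundary matching, and the clone tree.
#'
#' @param sim result of \code{\link{simulate_patient}}.
#' @param config pipeline config overrides.
#' @return list: \code{statuses}, \code{tree}, \code{regions} (per sample),
#'   \code{groups}, \code{loh_groups}.
#' @export
analyze_simulated_patient <- function(sim, config = list()) {
  cfg <- validate_config(config)
  locus <- sim$truth$locus_pos
  statuses <- list()
  locus_regions <- list()
  for (tm in sim$tumors) {
    ana <- analyze_tumor_track(tm$track, locus, cfg)
    variants <- tm$variants
    sv <- variants[variants$gene %in% c("TSC1", "TSC2") &
                     variants$variant_type != "genomic_del", , drop = FALSE]
    sv <- filter_variant_calls(sv, cfg$min_alt_reads, cfg$min_af)$kept
    # genomic deletions are established from the coverage track, not reads
    if (!is.null(tm$coverage)) {
      dels <- detect_homozygous_deletion(tm$coverage, cfg$log2_tolerance)
      hom <- dels[dels$copy_status == "homozygous_loss" &
                    dels$start <= locus & dels$end >= locus, , drop = FALSE]
      if (nrow(hom) > 0)
        sv <- rbind(sv, variants[variants$variant_type == "genomic_del", ,
                                 drop = FALSE])
    }
    st <- classify_sample_status(
      sv, loh_locus = if (ana$loh_at_locus) "TSC2" else "none",
      loh_flank_only = ana$flank_only, sample_id = tm$sample_id)
    statuses[[tm$sample_id]] <- st
    if (ana$loh_at_locus)
      locus_regions[[tm$sample_id]] <- ana$regions[ana$locus_region, ,
                                                   drop = FALSE]
  }
  statuses <- do.call(rbind, statuses)
  # partition samples by matching LOH boundaries
  ids <- names(locus_regions)
  loh_groups <- list()
  if (length(ids) > 0) {
    assigned <- rep(NA_integer_, length(ids))
    gid <- 0L
    for (i in seq_along(ids)) {
      if (!is.na(assigned[i])) next
      gid <- gid + 1L
      assigned[i] <- gid
      if (i < length(ids)) for (j in seq(i + 1, length(ids))) {
        if (!is.na(assigned[j])) next
        if (loh_boundary_match(locus_regions[[i]],
                               locus_regions[[j]]) == "same")
          assigned[j] <- gid
      }
    }
    loh_groups <- unname(lapply(split(ids, assigned), identity))
  }
  somatic_other <- sim$variants[sim$variants$origin == "somatic" &
                                  !(sim$variants$gene %in%
                                      c("TSC1", "TSC2")), , drop = FALSE]
  somatic_other <- filter_variant_calls(somatic_other, cfg$min_alt_reads,
                                        cfg$min_af)$kept
  groups <- shared_mutation_groups(somatic_other,
                                   min_shared = cfg$min_shared)
  tree <- build_clone_tree(
    sim$patient_id, statuses, groups, loh_groups = loh_groups,
    tsc_variants = sim$variants[sim$variants$gene %in%
                                  c("TSC1", "TSC2"), , drop = FALSE])
  list(statuses = statuses, tree = tree, regions = locus_regions,
       groups = groups, loh_groups = loh_groups)
}
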