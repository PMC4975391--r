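# LOH mapping from SNP allele fractions: select germline-heterozygous SNPs,
# call tumor AF skew, delineate LOH regions with confident spans and
# uncertainty flanks, and assess copy status from windowed depth ratios.
#
# All AF threshold comparisons use a 1e-9 epsilon on the count scale so that
# boundary sites (AF exactly 0.40/0.60 etc.) land on the documented side
# regardless of binary float representation.

snp_normal_af <- function(track) variant_af(track$normal_alt, track$normal_ref)
snp_tumor_af <- function(track) variant_af(track$tumor_alt, track$tumor_ref)

.COPY_STATUS <- c("neutral", "single_loss", "homozygous_loss", "gain",
                  "indeterminate")

#' Select germline heterozygous SNPs from a paired track
#'
#' Keeps SNPs whose normal-sample read depth is at least \code{min_depth}
#' (default 20, i.e. "depth > 19") and whose normal allele fraction lies in
#' \[\code{af_low}, \code{af_high}\] (inclusive). Only these sites are
#' informative for LOH in the tumor.
#'
#' @param track SNP track data.frame (see \code{\link{read_snp_track}}).
#' @param min_depth minimum normal depth (default 20).
#' @param af_low,af_high inclusive normal-AF bounds (defaults 0.40, 0.60).
#' @return the subset of rows passing both rules.
#' @export
identify_het_snps <- function(track, min_depth = 20, af_low = 0.40,
                              af_high = 0.60) {
  if (!isTRUE(all(track$paired)) || all(is.na(track$normal_ref)))
    stop("track is unpaired (no normal counts); ",
         "use identify_candidate_snps_unpaired()")
  depth <- track$normal_ref + track$normal_alt
  alt <- track$normal_alt
  ok <- !is.na(depth) & depth >= min_depth &
    alt + 1e-9 >= af_low * depth & alt - 1e-9 <= af_high * depth
  track[ok, , drop = FALSE]
}

#' Select candidate heterozygous SNPs from an unpaired tumor track
#'
#' Without a matched normal, likely germline heterozygous sites are taken as
#' those with tumor allele fraction in \[\code{af_low}, \code{af_high}\]
#' (defaults 0.05 and 0.95, inclusive), which removes homozygous sites.
#'
#' @param track SNP track data.frame.
#' @param af_low,af_high inclusive tumor-AF bounds.
#' @return the subset of rows passing the rule.
#' @export
identify_candidate_snps_unpaired <- function(track, af_low = 0.05,
                                             af_high = 0.95) {
  depth <- track$tumor_ref + track$tumor_alt
  alt <- track$tumor_alt
  ok <- !is.na(depth) & depth > 0 &
    alt + 1e-9 >= af_low * depth & alt - 1e-9 <= af_high * depth
  track[ok, , drop = FALSE]
}

#' Call tumor allele-fraction skew per SNP
#'
#' A SNP is \code{skewed} when its tumor AF is strictly below
#' \code{af_low} or strictly above \code{af_high}; AF exactly at a threshold
#' is \code{normal} (conservative: fewer false LOH calls). SNPs with zero
#' tumor depth are dropped with a warning.
#'
#' @param track SNP track data.frame.
#' @param af_low,af_high skew thresholds (defaults 0.40, 0.60).
#' @return the track with an added factor column \code{skew}
#'   (\code{skewed}/\code{normal}); zero-depth rows removed.
#' @export
call_skew <- function(track, af_low = 0.40, af_high = 0.60) {
  depth <- track$tumor_ref + track$tumor_alt
  zero <- is.na(depth) | depth == 0
  if (any(zero)) {
    warning(sum(zero), " SNP(s) with zero tumor depth dropped")
    track <- track[!zero, , drop = FALSE]
    depth <- depth[!zero]
  }
  alt <- track$tumor_alt
  skewed <- (alt < af_low * depth - 1e-9) | (alt > af_high * depth + 1e-9)
  track$skew <- factor(ifelse(skewed, "skewed", "normal"),
                       levels = c("skewed", "normal"))
  track
}

#' Delineate LOH regions from skew calls
#'
#' Scans a single-chromosome track (sorted by position) for maximal runs of
#' skewed SNPs. Isolated normal-AF SNPs inside a run do not split it as long
#' as the interior discordant fraction stays at or below
#' \code{max_interior_discordant_frac}; they are counted and reported. Runs
#' with fewer than \code{min_skewed} skewed SNPs are discarded (their sites
#' are returned in the \code{unassigned} attribute). The confident span runs
#' from the first to the last skewed SNP; the uncertainty flanks extend to
#' the nearest flanking normal-AF SNP, or to the end of the observed track
#' when none exists on that side. A region is \code{telomere_anchored} when
#' no normal-AF SNP lies between it and the first observed position.
#'
#' @param track SNP track for one chromosome, with or without a \code{skew}
#'   column (\code{\link{call_skew}} is applied if absent).
#' @param min_skewed minimum skewed SNPs per region (default 10).
#' @param max_interior_discordant_frac maximum tolerated fraction of
#'   normal-AF SNPs inside the confident span (default 0.1).
#' @param af_low,af_high skew thresholds passed to \code{call_skew}.
#' @return data.frame of class \code{loh_regions}: chrom, uncertain_start,
#'   confident_start, confident_end, uncertain_end, n_skewed,
#'   n_discordant_interior, telomere_anchored, copy_status (initialised
#'   \code{indeterminate}; see \code{\link{assess_copy_neutrality}}).
#' @export
delineate_loh_regions <- function(track, min_skewed = 10,
                                  max_interior_discordant_frac = 0.1,
                                  af_low = 0.40, af_high = 0.60) {
  if (length(unique(track$chrom)) > 1)
    stop("delineate_loh_regions() expects a single-chromosome track")
  if (is.null(track$skew)) track <- call_skew(track, af_low, af_high)
  if (is.unsorted(track$pos)) track <- track[order(track$pos), , drop = FALSE]
  empty <- data.frame(
    chrom = character(0), uncertain_start = numeric(0),
    confident_start = numeric(0), confident_end = numeric(0),
    uncertain_end = numeric(0), n_skewed = integer(0),
    n_discordant_interior = integer(0), telomere_anchored = logical(0),
    start_censored = logical(0), end_censored = logical(0),
    copy_status = character(0), stringsAsFactors = FALSE
  )
  n <- nrow(track)
  skew_idx <- which(track$skew == "skewed")
  if (length(skew_idx) == 0) {
    class(empty) <- c("loh_regions", "data.frame")
    attr(empty, "unassigned") <- numeric(0)
    return(empty)
  }
  # Greedy left-to-right merge of consecutive-skew runs across interior
  # normal-AF SNPs. A merge must pass two gates: locally, the bridge itself
  # (next run + normals crossed) must stay majority-skewed (discordance
  # <= 1/3), which stops a large region from chaining out to isolated
  # false-skew SNPs in diploid territory; globally, the region's interior
  # discordant fraction must stay <= max_interior_discordant_frac.
  is_skew <- track$skew == "skewed"
  rl <- rle(as.vector(is_skew))
  run_end <- cumsum(rl$lengths)
  run_start <- run_end - rl$lengths + 1L
  sk_runs <- which(rl$values)
  runs <- list()
  cur_start <- run_start[sk_runs[1]]; cur_end <- run_end[sk_runs[1]]
  n_skew <- rl$lengths[sk_runs[1]]; n_disc <- 0L
  for (r in sk_runs[-1]) {
    g <- run_start[r] - cur_end - 1L
    b <- rl$lengths[r]
    local_ok <- g / (g + b) <= 1 / 3
    global_ok <- (n_disc + g) / (n_skew + b + n_disc + g) <=
      max_interior_discordant_frac
    if (local_ok && global_ok) {
      cur_end <- run_end[r]; n_skew <- n_skew + b; n_disc <- n_disc + g
    } else {
      runs[[length(runs) + 1L]] <- c(cur_start, cur_end, n_skew, n_disc)
      cur_start <- run_start[r]; cur_end <- run_end[r]
      n_skew <- b; n_disc <- 0L
    }
  }
  runs[[length(runs) + 1L]] <- c(cur_start, cur_end, n_skew, n_disc)
  keep <- vapply(runs, function(r) r[3] >= min_skewed, logical(1))
  unassigned <- unlist(lapply(runs[!keep], function(r)
    track$pos[seq(r[1], r[2])][track$skew[seq(r[1], r[2])] == "skewed"]))
  runs <- runs[keep]
  if (length(runs) == 0) {
    class(empty) <- c("loh_regions", "data.frame")
    attr(empty, "unassigned") <- if (is.null(unassigned)) numeric(0) else unassigned
    return(empty)
  }
  normal_idx <- which(track$skew == "normal")
  out <- do.call(rbind, lapply(runs, function(r) {
    i0 <- r[1]; i1 <- r[2]
    left_norm <- normal_idx[normal_idx < i0]
    right_norm <- normal_idx[normal_idx > i1]
    telomere <- length(left_norm) == 0
    data.frame(
      chrom = track$chrom[1],
      uncertain_start = if (telomere) min(track$pos) else
        track$pos[max(left_norm)],
      confident_start = track$pos[i0],
      confident_end = track$pos[i1],
      uncertain_end = if (length(right_norm) == 0) max(track$pos) else
        track$pos[min(right_norm)],
      n_skewed = r[3],
      n_discordant_interior = r[4],
      telomere_anchored = telomere,
      start_censored = telomere,
      end_censored = length(right_norm) == 0,
      copy_status = "indeterminate",
      stringsAsFactors = FALSE
    )
  }))
  class(out) <- c("loh_regions", "data.frame")
  attr(out, "unassigned") <- if (is.null(unassigned)) numeric(0) else unassigned
  out
}

median_log2_ratio <- function(coverage, start, end) {
  ov <- coverage$end >= start & coverage$start <= end
  if (sum(ov) == 0) return(list(n = 0L, m = NA_real_))
  list(n = sum(ov), m = stats::median(log2(coverage$ratio[ov])))
}

classify_log2 <- function(m, log2_tolerance) {
  if (is.na(m)) "indeterminate"
  else if (m <= -1.5) "homozygous_loss"
  else if (m <= -log2_tolerance) "single_loss"
  else if (m < log2_tolerance) "neutral"
  else "gain"
}

#' Assess copy status of an LOH region from coverage ratios
#'
#' Classifies the region from the median log2 tumor/normal depth ratio of the
#' coverage windows overlapping its confident span: within
#' \code{(-log2_tolerance, +log2_tolerance)} is copy-neutral (the CN-LOH
#' signature), at or below -1.5 homozygous loss, between those single-copy
#' loss, at or above \code{+log2_tolerance} gain. Fewer than
#' \code{min_windows} overlapping windows yields \code{indeterminate}.
#'
#' @param region one row of a \code{loh_regions} data.frame.
#' @param coverage data.frame of windows: \code{start}, \code{end},
#'   \code{ratio} (tumor/normal mean depth ratio, 1 = diploid).
#' @param log2_tolerance half-width of the neutral band (default 0.3,
#'   tolerant of exome capture noise).
#' @param min_windows minimum overlapping windows (default 5).
#' @return one of \code{neutral}, \code{single_loss}, \code{homozygous_loss},
#'   \code{gain}, \code{indeterminate}.
#' @export
assess_copy_neutrality <- function(region, coverage, log2_tolerance = 0.3,
                                   min_windows = 5) {
  s <- median_log2_ratio(coverage, region$confident_start,
                         region$confident_end)
  if (s$n < min_windows) return("indeterminate")
  classify_log2(s$m, log2_tolerance)
}

#' Detect genomic deletions from windowed coverage ratios
#'
#' Finds maximal runs of coverage windows whose log2 tumor/normal ratio is at
#' or below \code{-log2_tolerance}, and within each run the sub-runs at or
#' below -1.5 (homozygous loss). A run that mixes the two levels is reported
#' as a single-copy-loss interval with its homozygous sub-intervals nested
#' inside it (the geometry of a focal homozygous deletion with hemizygous
#' flanks). Single-window runs are flagged low-confidence.
#'
#' @param coverage data.frame of windows sorted by \code{start}:
#'   \code{start}, \code{end}, \code{ratio}.
#' @param log2_tolerance neutral band half-width (default 0.3).
#' @return data.frame: start, end, copy_status, n_windows, low_confidence.
#' @export
detect_homozygous_deletion <- function(coverage, log2_tolerance = 0.3) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      copy_status = character(0), n_windows = integer(0),
                      low_confidence = logical(0), stringsAsFactors = FALSE)
  if (nrow(coverage) == 0) return(empty)
  if (is.unsorted(coverage$start))
    coverage <- coverage[order(coverage$start), , drop = FALSE]
  l2 <- log2(coverage$ratio)
  loss <- l2 <= -log2_tolerance
  r <- rle(loss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    hom <- l2[i0:i1] <= -1.5
    rh <- rle(hom)
    hends <- cumsum(rh$lengths) + i0 - 1L
    hstarts <- hends - rh$lengths + 1L
    all_hom <- all(hom)
    if (!all_hom) {
      out[[length(out) + 1L]] <- data.frame(
        start = coverage$start[i0], end = coverage$end[i1],
        copy_status = "single_loss", n_windows = i1 - i0 + 1L,
        low_confidence = (i1 == i0), stringsAsFactors = FALSE)
    }
    for (h in which(rh$values)) {
      out[[length(out) + 1L]] <- data.frame(
        start = coverage$start[hstarts[h]], end = coverage$end[hends[h]],
        copy_status = "homozygous_loss",
        n_windows = hends[h] - hstarts[h] + 1L,
        low_confidence = (hends[h] == hstarts[h]), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  out <- do.call(rbind, out)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Write LOH regions as a BED-like TSV
#' @param regions \code{loh_regions} data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_loh_regions <- function(regions, path) {
  utils::write.table(as.data.frame(regions), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
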