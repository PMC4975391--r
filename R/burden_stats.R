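# Somatic mutation burden, spectrum, subclonality tallies and the
# TSC-vs-sporadic mechanism contingency with an exact Fisher test.

#' Count somatic coding mutations per sample
#'
#' Counts covered somatic calls outside \code{exclude_genes} for every sample
#' in \code{sample_ids} (tumor-normal pairs), filling zeros for samples with
#' no rows. Uncovered calls and germline calls are excluded; literal
#' duplicate rows are counted as printed (deduplication is a separate,
#' reported step, see \code{\link{dedup_unique_mutations}}).
#'
#' @param calls variant table of non-TSC1/TSC2 somatic calls.
#' @param sample_ids samples to count over (typically the paired samples).
#' @param exclude_genes genes excluded from the burden (default TSC1/TSC2).
#' @return named integer vector, one count per requested sample.
#' @export
count_nonsyn_per_sample <- function(calls, sample_ids,
                                    exclude_genes = c("TSC1", "TSC2")) {
  calls <- as.data.frame(calls)
  keep <- calls$origin == "somatic" & !calls$uncovered &
    !(calls$gene %in% exclude_genes) & calls$sample_id %in% sample_ids
  tab <- table(factor(calls$sample_id[keep], levels = sample_ids))
  stats::setNames(as.integer(tab), sample_ids)
}

#' Deduplicate mutations to the patient-level unique set
#'
#' A mutation (gene + cDNA change) shared by several samples of one patient
#' counts once (truncal events are one mutation); identical mutations in
#' different patients count separately; literal duplicate rows within one
#' sample collapse. Uncovered rows are dropped.
#'
#' @param calls variant table with \code{patient_id}.
#' @return the unique subset of rows (first occurrence kept).
#' @export
dedup_unique_mutations <- function(calls) {
  calls <- as.data.frame(calls)
  calls <- calls[!calls$uncovered, , drop = FALSE]
  key <- paste(calls$patient_id, calls$gene, calls$cdna_change)
  calls[!duplicated(key), , drop = FALSE]
}

#' Summarise somatic mutation burden
#'
#' @param counts named per-sample counts from
#'   \code{\link{count_nonsyn_per_sample}}.
#' @param unique_calls patient-level unique mutation set from
#'   \code{\link{dedup_unique_mutations}} (drives the spectrum).
#' @param territory_mb size of the sequenced coding territory in Mb
#'   (default 33, the exome capture size); the rate is median/territory.
#' @param call_count total number of mutation calls behind \code{counts}
#'   (reported alongside the unique count; the two differ when truncal
#'   mutations recur across a patient's samples).
#' @return object of class \code{burden_summary}.
#' @export
burden_summary <- function(counts, unique_calls, territory_mb = 33,
                           call_count = sum(counts)) {
  if (length(counts) == 0) stop("no per-sample counts supplied")
  spectrum_counts <- table(unique_calls$variant_type)
  spectrum <- data.frame(
    variant_type = names(spectrum_counts),
    count = as.integer(spectrum_counts),
    fraction = as.numeric(spectrum_counts) / nrow(unique_calls),
    stringsAsFactors = FALSE
  )
  structure(list(
    per_sample_counts = counts,
    n_samples = length(counts),
    median = stats::median(counts),
    range = range(counts),
    territory_mb = territory_mb,
    rate_per_mb = stats::median(counts) / territory_mb,
    rate_range_per_mb = range(counts) / territory_mb,
    unique_mutations = nrow(unique_calls),
    call_count = call_count,
    spectrum = spectrum
  ), class = "burden_summary")
}

#' @export
print.burden_summary <- function(x, ...) {
  cat(sprintf(
    "somatic burden over %d tumor-normal pairs:\n  median %g mutations/tumor (range %g-%g)\n  rate %.2f/Mb (range %.2f-%.2f) over %g Mb\n  %d unique mutations (%d calls)\n",
    x$n_samples, x$median, x$range[1], x$range[2], x$rate_per_mb,
    x$rate_range_per_mb[1], x$rate_range_per_mb[2], x$territory_mb,
    x$unique_mutations, x$call_count))
  sp <- x$spectrum[order(-x$spectrum$count), ]
  for (i in seq_len(nrow(sp)))
    cat(sprintf("    %-15s %3d (%2.0f%%)\n", sp$variant_type[i], sp$count[i],
                100 * sp$fraction[i]))
  invisible(x)
}

#' Tally subclonal mutation fractions
#'
#' Fraction of mutations with allele fraction below each threshold. The
#' denominator definition (every covered call vs the patient-level unique
#' set) is configurable and echoed in the result, since published tallies
#' use both without stating which.
#'
#' @param calls variant table of somatic calls.
#' @param thresholds AF thresholds (default 0.15 and 0.10).
#' @param denominator \code{"per_call"} (default) or \code{"per_unique"}.
#' @return data.frame: threshold, n_below, n_total, fraction, denominator.
#' @export
subclonal_tally <- function(calls, thresholds = c(0.15, 0.10),
                            denominator = c("per_call", "per_unique")) {
  denominator <- match.arg(denominator)
  calls <- as.data.frame(calls)
  calls <- calls[!calls$uncovered, , drop = FALSE]
  if (denominator == "per_unique") calls <- dedup_unique_mutations(calls)
  af <- calls$af
  data.frame(
    threshold = thresholds,
    n_below = vapply(thresholds, function(t) sum(af < t), integer(1)),
    n_total = length(af),
    fraction = vapply(thresholds, function(t) mean(af < t), numeric(1)),
    denominator = denominator,
    stringsAsFactors = FALSE
  )
}

#' Mechanism-by-cohort contingency table
#'
#' Cross-tabulates specimens by whether their biallelic inactivation used a
#' two-event small-scale mechanism (two point mutations or a homozygous
#' deletion) against TSC vs sporadic disease status.
#'
#' @param statuses status data.frame from \code{\link{classify_cohort}}.
#' @param tsc_labels named logical vector (or vector aligned to
#'   \code{statuses$sample_id}): TRUE for specimens from TSC subjects.
#' @return 2x2 integer matrix, rows sporadic/TSC, columns two_event/other.
#' @export
mechanism_contingency <- function(statuses, tsc_labels) {
  if (!is.null(names(tsc_labels)))
    tsc_labels <- tsc_labels[statuses$sample_id]
  if (length(tsc_labels) != nrow(statuses) || any(is.na(tsc_labels)))
    stop("every sample needs a TSC/sporadic label")
  two_event <- statuses$mechanism %in% c("two_mutation",
                                         "homozygous_deletion")
  m <- matrix(c(
    sum(!tsc_labels & two_event), sum(!tsc_labels & !two_event),
    sum(tsc_labels & two_event), sum(tsc_labels & !two_event)
  ), nrow = 2, byrow = TRUE,
  dimnames = list(cohort = c("sporadic", "TSC"),
                  mechanism = c("two_event", "other")))
  m
}

log_hyper_pmf <- function(k, r1, c1, n) {
  # log P(X = k) for the hypergeometric with fixed margins: choose k of c1
  # "successes" into row 1 (size r1) out of n
  lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability definition: with margins fixed, the p-value is the sum
#' of the probabilities of all hypergeometric outcomes no more likely than
#' the observed table (a relative tolerance of 1e-7 guards ties against
#' rounding). Probabilities are computed in log space via \code{lchoose} so
#' large margins do not overflow. A doubling variant (twice the smaller
#' one-sided tail, capped at 1) is available for comparison.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param method \code{"point_prob"} (default, the conventional definition)
#'   or \code{"doubling"}.
#' @return the two-sided p-value.
#' @export
fisher_exact_two_sided <- function(tab, method = c("point_prob", "doubling")) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be non-negative integers")
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (n == 0) return(1)
  k_obs <- tab[1, 1]
  k <- max(0, c1 - (n - r1)):min(r1, c1)
  logp <- log_hyper_pmf(k, r1, c1, n)
  logp_obs <- log_hyper_pmf(k_obs, r1, c1, n)
  if (method == "point_prob") {
    p <- sum(exp(logp[logp <= logp_obs + log(1 + 1e-7)]))
  } else {
    lower <- sum(exp(logp[k <= k_obs]))
    upper <- sum(exp(logp[k >= k_obs]))
    p <- 2 * min(lower, upper)
  }
  min(p, 1)
}
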