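# Closed-form copy-neutral mixture arithmetic relating tumor purity to the
# expected variant allele fraction. Total tumor copy number is fixed at 2:
# mitotic recombination (the CN-LOH mechanism seen at these loci) replaces
# one haplotype with the other without changing copy number, and no other
# gains or losses are modelled.

.GENOTYPE_MODELS <- list(
  germline_het_no_loh        = c(mutant_copies_tumor = 1, mutant_copies_normal = 1),
  germline_het_cnloh_retained = c(mutant_copies_tumor = 2, mutant_copies_normal = 1),
  germline_het_cnloh_lost    = c(mutant_copies_tumor = 0, mutant_copies_normal = 1),
  somatic_het_no_loh         = c(mutant_copies_tumor = 1, mutant_copies_normal = 0),
  somatic_cnloh              = c(mutant_copies_tumor = 2, mutant_copies_normal = 0)
)

#' Copy-neutral genotype model
#'
#' Describes how many copies of an allele the tumor and admixed normal cells
#' carry, under a diploid (copy-neutral) tumor genome:
#' \describe{
#'   \item{germline_het_no_loh}{heterozygous in both compartments; AF = 1/2
#'     at any purity (uninformative).}
#'   \item{germline_het_cnloh_retained}{germline het, CN-LOH duplicated the
#'     mutant haplotype; AF = (1+p)/2.}
#'   \item{germline_het_cnloh_lost}{germline het, CN-LOH removed the mutant
#'     haplotype; AF = (1-p)/2.}
#'   \item{somatic_het_no_loh}{clonal somatic heterozygous mutation;
#'     AF = p/2.}
#'   \item{somatic_cnloh}{somatic mutation homozygous via CN-LOH; AF = p.}
#' }
#'
#' @param label one of the model names above.
#' @return an object of class \code{genotype_model}.
#' @export
genotype_model <- function(label = names(.GENOTYPE_MODELS)) {
  label <- match.arg(label)
  cfg <- .GENOTYPE_MODELS[[label]]
  structure(list(label = label,
                 mutant_copies_tumor = unname(cfg["mutant_copies_tumor"]),
                 total_copies_tumor = 2,
                 mutant_copies_normal = unname(cfg["mutant_copies_normal"])),
            class = "genotype_model")
}

#' @export
print.genotype_model <- function(x, ...) {
  cat("genotype model:", x$label, "\n",
      " mutant copies tumor/normal:", x$mutant_copies_tumor, "/",
      x$mutant_copies_normal, " (total tumor copies 2)\n")
  invisible(x)
}

as_genotype_model <- function(model) {
  if (inherits(model, "genotype_model")) return(model)
  genotype_model(model)
}

#' Expected allele fraction under a genotype model
#'
#' For tumor purity p the expected AF is
#' \deqn{(p \cdot m_T + (1-p) \cdot m_N) / 2}
#' where \eqn{m_T}, \eqn{m_N} are mutant copies in tumor and normal cells and
#' the denominator 2 is the (copy-neutral) total copy number in both
#' compartments.
#'
#' @param model a \code{\link{genotype_model}} or its label.
#' @param purity tumor purity in \[0, 1\] (vectorised).
#' @return expected allele fraction(s).
#' @export
expected_af <- function(model, purity) {
  model <- as_genotype_model(model)
  if (any(is.na(purity)) || any(purity < 0) || any(purity > 1))
    stop("purity must be in [0, 1]")
  (purity * model$mutant_copies_tumor +
     (1 - purity) * model$mutant_copies_normal) / 2
}

#' Estimate tumor purity from an observed allele fraction
#'
#' Inverts the linear purity/AF map of a genotype model and propagates an
#' exact binomial confidence interval on the observed AF through the inverse.
#' Estimates falling outside \[0, 1\] (expected for noisy AFs at low depth)
#' are clipped and flagged rather than rejected. The estimator assumes the
#' event is clonal (cancer cell fraction 1); subclonal events bias purity
#' downward.
#'
#' @param af observed allele fraction.
#' @param model a \code{\link{genotype_model}} or label; must be informative
#'   for purity (all models except \code{germline_het_no_loh}).
#' @param depth total read depth at the site (for the binomial interval).
#' @param conf_level confidence level of the interval (default 0.95).
#' @return an object of class \code{purity_estimate}: purity, model,
#'   observed AF, interval, clipping flag.
#' @export
estimate_purity <- function(af, model, depth, conf_level = 0.95) {
  model <- as_genotype_model(model)
  slope <- (model$mutant_copies_tumor - model$mutant_copies_normal) / 2
  if (slope == 0)
    stop("model '", model$label, "' is uninformative for purity ",
         "(expected AF constant in p)")
  if (is.na(af) || af < 0 || af > 1) stop("af must be in [0, 1]")
  if (is.na(depth) || depth <= 0) stop("depth must be positive")
  invert <- function(a) (a - model$mutant_copies_normal / 2) / slope
  p_raw <- invert(af)
  clipped <- p_raw < 0 || p_raw > 1
  alt <- round(af * depth)
  ci_af <- stats::binom.test(alt, depth, conf.level = conf_level)$conf.int
  ci_p <- sort(invert(ci_af))
  structure(list(
    purity = min(max(p_raw, 0), 1),
    purity_raw = p_raw,
    model = model,
    af_observed = af,
    depth = depth,
    ci_low = min(max(ci_p[1], 0), 1),
    ci_high = min(max(ci_p[2], 0), 1),
    conf_level = conf_level,
    clipped = clipped
  ), class = "purity_estimate")
}

#' @export
print.purity_estimate <- function(x, ...) {
  cat(sprintf("purity estimate: %.3f (%.0f%% CI %.3f-%.3f) under %s%s\n",
              x$purity, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$model$label, if (x$clipped) " [clipped to [0,1]]" else ""))
  invisible(x)
}
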