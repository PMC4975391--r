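# Per-specimen TSC1/TSC2 inactivation verdicts: variant typing from HGVS
# strings, and the Knudson two-hit mechanism classification combining small
# variants, genomic deletions and copy-neutral LOH.

.MECHANISMS <- c("two_mutation", "mutation_plus_cnloh", "homozygous_deletion",
                 "cnloh_only", "none")
.BIALLELIC_MECHANISMS <- c("two_mutation", "mutation_plus_cnloh",
                           "homozygous_deletion")
.INACTIVATING_TYPES <- c("nonsense", "splice", "frameshift_del",
                         "frameshift_ins", "inframe_del", "genomic_del")

hgvs_del_length <- function(cdna) {
  m <- regmatches(cdna, regexec("c\\.(\\d+)_(\\d+)del", cdna))[[1]]
  if (length(m) == 3) return(as.numeric(m[3]) - as.numeric(m[2]) + 1)
  seq <- regmatches(cdna, regexec("del([ACGT]+)$", cdna))[[1]]
  if (length(seq) == 2) return(nchar(seq[2]))
  if (grepl("del", cdna)) return(1)
  NA_real_
}

hgvs_ins_length <- function(cdna) {
  seq <- regmatches(cdna, regexec("ins([ACGT]+)$", cdna))[[1]]
  if (length(seq) == 2) return(nchar(seq[2]))
  NA_real_
}

classify_one_variant <- function(cdna, protein) {
  if (is.na(cdna) || !nzchar(cdna)) return("unknown")
  protein <- if (is.na(protein)) "" else protein
  if (grepl("_splice", protein) || grepl("_splice", cdna)) return("splice")
  if (grepl("\\*$", protein)) return("nonsense")
  if (grepl("ins", cdna)) {
    len <- hgvs_ins_length(cdna)
    if (is.na(len)) return("unknown")
    return(if (len %% 3 == 0) "unknown" else "frameshift_ins")
  }
  if (grepl("del", cdna)) {
    len <- hgvs_del_length(cdna)
    if (is.na(len)) return("unknown")
    return(if (len %% 3 == 0) "inframe_del" else "frameshift_del")
  }
  # intronic offset on a substitution: only the canonical +/-1, +/-2 sites
  # are inferred splice; deeper offsets need a _splice annotation or an
  # explicit declared type
  off <- regmatches(cdna, regexec("^c\\.\\d+[+-](\\d+)[ACGT]>[ACGT]$",
                                  cdna))[[1]]
  if (length(off) == 2)
    return(if (as.numeric(off[2]) <= 2) "splice" else "unknown")
  if (grepl("^c\\.\\d+[ACGT]>[ACGT]$", cdna)) {
    if (protein == "" || grepl("^p\\.[A-Z]\\d+[A-Z]$", protein))
      return("missense")
    return("unknown")
  }
  "unknown"
}

#' Classify a variant's type from its HGVS strings
#'
#' Infers the variant type: nonsense when the protein change ends in a stop
#' (\code{*}); splice when the protein annotation carries \code{_splice} or
#' the cDNA substitution has an intronic offset (\code{+n}/\code{-n});
#' deletions and insertions are frameshift vs in-frame by whether the
#' deleted/inserted length is a multiple of 3; single-residue substitutions
#' are missense. An explicit \code{declared} type overrides the inference
#' (the override is logged with \code{message()}): this is how annotations
#' such as an extended splice-region variant typed "splice" despite a -15
#' offset are honoured. Unparseable strings yield \code{unknown} with a
#' warning.
#'
#' @param cdna_change HGVS c. string(s).
#' @param protein_change HGVS p. string(s) or empty.
#' @param declared optional explicit type token(s) taking precedence.
#' @return character vector of variant types.
#' @export
classify_variant_type <- function(cdna_change, protein_change = "",
                                  declared = NULL) {
  n <- length(cdna_change)
  protein_change <- rep_len(protein_change, n)
  inferred <- mapply(classify_one_variant, cdna_change, protein_change,
                     USE.NAMES = FALSE)
  if (!is.null(declared)) {
    declared <- rep_len(declared, n)
    bad <- !is.na(declared) & !(declared %in% .VARIANT_TYPES)
    if (any(bad)) stop("unknown declared variant_type token: ",
                       paste(unique(declared[bad]), collapse = ", "))
    override <- !is.na(declared) & declared != inferred
    if (any(override))
      message("declared variant_type overrides inference for: ",
              paste(cdna_change[override], collapse = ", "))
    inferred[!is.na(declared)] <- declared[!is.na(declared)]
  }
  unresolved <- inferred == "unknown" & !is.na(cdna_change)
  if (any(unresolved))
    warning("could not infer type for: ",
            paste(cdna_change[unresolved], collapse = ", "))
  inferred
}

#' Classify a specimen's TSC1/TSC2 inactivation mechanism
#'
#' Applies the two-hit precedence rules to one specimen's filtered TSC1/TSC2
#' variant calls plus its locus LOH verdict:
#' \enumerate{
#'   \item \code{homozygous_deletion} when a genomic deletion covers the
#'     locus at homozygous-loss copy status;
#'   \item \code{two_mutation} when the sample carries at least two distinct
#'     inactivating variants at one locus (germline + somatic counts, as do
#'     two somatic);
#'   \item \code{mutation_plus_cnloh} when exactly one variant is accompanied
#'     by copy-neutral LOH spanning the locus;
#'   \item \code{cnloh_only} when LOH is present without any detected
#'     variant;
#'   \item \code{none} otherwise.
#' }
#' "Distinct" means distinct cDNA change strings at the locus; phasing is
#' unknowable from short-read data and a trans configuration is assumed.
#'
#' @param variants variant table rows for this sample restricted to TSC1 and
#'   TSC2 (germline and somatic).
#' @param loh_locus locus with copy-neutral LOH spanning it: \code{"TSC2"},
#'   \code{"TSC1"} or \code{"none"}.
#' @param loh_flank_only the locus lies only in the LOH uncertainty flank,
#'   not the confident span: a cnloh_only verdict is then demoted to
#'   \code{none} with a warning.
#' @param sample_id specimen identifier for the output row.
#' @return one-row data.frame: sample_id, locus, mechanism, biallelic,
#'   n_hits, loh.
#' @export
classify_sample_status <- function(variants, loh_locus = "none",
                                   loh_flank_only = FALSE,
                                   sample_id = NULL) {
  loh_locus <- match.arg(loh_locus, c("none", "TSC2", "TSC1"))
  variants <- as.data.frame(variants)
  if (nrow(variants) > 0) {
    variants <- variants[variants$gene %in% c("TSC1", "TSC2"), , drop = FALSE]
  }
  loci <- unique(variants$gene)
  if (length(loci) > 1)
    stop("variants at both TSC1 and TSC2 in one sample: manual resolution ",
         "required")
  if (is.null(sample_id))
    sample_id <- if (nrow(variants) > 0) variants$sample_id[1] else NA_character_
  locus <- if (length(loci) == 1) loci else loh_locus
  if (identical(locus, "none")) locus <- "none"
  inact <- variants[variants$variant_type %in% .INACTIVATING_TYPES, ,
                    drop = FALSE]
  n_distinct <- length(unique(inact$cdna_change[inact$variant_type !=
                                                  "genomic_del"]))
  has_genomic_del <- any(inact$variant_type == "genomic_del")
  loh_here <- !identical(loh_locus, "none") &&
    (locus == "none" || loh_locus == locus)
  mechanism <- if (has_genomic_del) "homozygous_deletion"
  else if (n_distinct >= 2) "two_mutation"
  else if (n_distinct == 1 && loh_here && !loh_flank_only)
    "mutation_plus_cnloh"
  else if (n_distinct == 0 && loh_here && !loh_flank_only) "cnloh_only"
  else "none"
  if (mechanism == "none" && loh_here && loh_flank_only)
    warning("sample ", sample_id, ": locus only in LOH uncertainty flank; ",
            "cnloh evidence demoted to none")
  data.frame(
    sample_id = sample_id,
    locus = if (mechanism == "none" && n_distinct == 0 && !loh_here) "none"
            else locus,
    mechanism = mechanism,
    biallelic = mechanism %in% .BIALLELIC_MECHANISMS,
    n_hits = n_distinct + 2L * has_genomic_del,
    loh = loh_here,
    stringsAsFactors = FALSE
  )
}

loh_locus_from_annotation <- function(ann) {
  if (is.na(ann)) return("none")
  switch(ann, "Yes" = "TSC2", "9q LOH" = "TSC1", "none")
}

#' Classify every specimen of a cohort
#'
#' Runs \code{\link{classify_sample_status}} over all samples of a fixture
#' bundle (or an equivalently shaped variant table + sample metadata),
#' taking each sample's LOH verdict from its annotation ("Yes" = 16p/TSC2
#' CN-LOH, "9q LOH" = TSC1 CN-LOH).
#'
#' @param table1 variant table of TSC1/TSC2 calls.
#' @param samples per-sample metadata with \code{sample_id} and
#'   \code{loh_annotation} (see \code{\link{load_fixtures}}).
#' @return data.frame with one status row per sample.
#' @export
classify_cohort <- function(table1, samples) {
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    sid <- samples$sample_id[i]
    classify_sample_status(
      table1[table1$sample_id == sid, , drop = FALSE],
      loh_locus = loh_locus_from_annotation(samples$loh_annotation[i]),
      sample_id = sid
    )
  })
  do.call(rbind, rows)
}

#' Count distinct somatic TSC2 variants in a cohort
#'
#' Occurrences are deduplicated within a patient (the same mutation seen in
#' two specimens of one patient counts once) but not across patients;
#' genomic deletions count as two large-scale deletion alleles (the
#' homozygous deletion removes both copies). Returns the total and the
#' per-type spectrum.
#'
#' @param table1 variant table of TSC1/TSC2 calls.
#' @param gene locus to count (default "TSC2").
#' @return list: \code{total}, \code{by_type} (named integer vector over the
#'   distinct counted events).
#' @export
count_somatic_tsc_variants <- function(table1, gene = "TSC2") {
  x <- as.data.frame(table1)
  x <- x[x$gene == gene & x$origin == "somatic", , drop = FALSE]
  small <- x[x$variant_type != "genomic_del", , drop = FALSE]
  small <- small[!duplicated(paste(small$patient_id, small$cdna_change)), ,
                 drop = FALSE]
  genomic <- x[x$variant_type == "genomic_del", , drop = FALSE]
  genomic <- genomic[!duplicated(genomic$sample_id), , drop = FALSE]
  by_type <- table(small$variant_type)
  by_type <- stats::setNames(as.integer(by_type), names(by_type))
  if (nrow(genomic) > 0) by_type["genomic_del"] <- 2L * nrow(genomic)
  list(total = nrow(small) + 2L * nrow(genomic), by_type = by_type)
}

#' Write per-sample statuses as TSV
#' @param statuses status data.frame from \code{\link{classify_cohort}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_sample_status <- function(statuses, path) {
  utils::write.table(statuses, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
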