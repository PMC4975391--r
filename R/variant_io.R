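#' @keywords internal
"_PACKAGE"

# Canonical column set of the tab-delimited variant format. Extra columns are
# carried through untouched; the reader only insists on these.
.VARIANT_REQUIRED_COLS <- c(
  "patient_id", "sample_id", "gene", "variant_type", "cdna_change",
  "protein_change", "mutant_reads", "ref_reads", "origin"
)

.VARIANT_TYPES <- c(
  "missense", "nonsense", "splice", "frameshift_del", "frameshift_ins",
  "inframe_del", "genomic_del", "unknown"
)

.ORIGINS <- c("germline", "somatic", "unknown")

#' Allele fraction from read counts
#'
#' Computes mutant_reads / (mutant_reads + ref_reads). Zero or missing depth
#' yields \code{NA}: a call without coverage has no allele fraction.
#'
#' @param mutant_reads,ref_reads non-negative integer vectors.
#' @return numeric vector of allele fractions in \[0, 1\], \code{NA} where the
#'   denominator is zero or the counts are missing.
#' @export
variant_af <- function(mutant_reads, ref_reads) {
  depth <- mutant_reads + ref_reads
  ifelse(is.na(depth) | depth == 0, NA_real_, mutant_reads / depth)
}

#' Read a variant-call table
#'
#' Reads the package's canonical tab-delimited variant format (one small
#' mutation or genomic deletion per row). The allele fraction is always
#' recomputed from the read counts; any printed AF column is carried as an
#' annotation but never trusted. Rows with missing read counts (e.g. "no
#' coverage" entries) are flagged \code{uncovered} rather than dropped.
#'
#' @param path path to a tab-delimited UTF-8 file with a header containing at
#'   least \code{patient_id, sample_id, gene, variant_type, cdna_change,
#'   protein_change, mutant_reads, ref_reads, origin}.
#' @return a \code{data.frame} of variant calls with recomputed \code{af},
#'   logical \code{uncovered} and \code{bidirectional} columns (the latter
#'   defaults to \code{TRUE} when the file carries no strand information).
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("variant table not found: ", path)
  # every column is read as character and only the read-count columns are
  # converted, so annotation columns (e.g. a printed-AF transcription)
  # survive a write round-trip byte-identically
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, na.strings = c("NA", ""),
                         quote = "", fileEncoding = "UTF-8",
                         colClasses = "character")
  missing_cols <- setdiff(.VARIANT_REQUIRED_COLS, names(x))
  if (length(missing_cols) > 0)
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  bad_type <- !is.na(x$variant_type) & !(x$variant_type %in% .VARIANT_TYPES)
  if (any(bad_type))
    stop("unknown variant_type token(s): ",
         paste(unique(x$variant_type[bad_type]), collapse = ", "),
         " (row ", which(bad_type)[1], ")")
  for (col in c("mutant_reads", "ref_reads")) {
    bad <- !is.na(x[[col]]) & !grepl("^-?[0-9.]+$", x[[col]])
    if (any(bad)) stop("non-numeric ", col, " in row ", which(bad)[1])
    x[[col]] <- as.numeric(x[[col]])
  }
  if (!is.null(x$bidirectional) && is.character(x$bidirectional))
    x$bidirectional <- as.logical(x$bidirectional)
  x$variant_type[is.na(x$variant_type)] <- "unknown"
  x$origin[is.na(x$origin)] <- "unknown"
  bad_origin <- !(x$origin %in% .ORIGINS)
  if (any(bad_origin))
    stop("unknown origin token(s): ",
         paste(unique(x$origin[bad_origin]), collapse = ", "))
  # HGVS sanity: cDNA strings must start with "c." when present (genomic
  # deletions carry none).
  has_cdna <- !is.na(x$cdna_change)
  bad_hgvs <- has_cdna & !grepl("^c\\.", x$cdna_change)
  if (any(bad_hgvs))
    stop("malformed HGVS cDNA string in row ", which(bad_hgvs)[1], ": ",
         x$cdna_change[which(bad_hgvs)[1]])
  if (any(!is.na(x$mutant_reads) & x$mutant_reads < 0) ||
      any(!is.na(x$ref_reads) & x$ref_reads < 0))
    stop("negative read counts")
  if (is.null(x$bidirectional)) x$bidirectional <- rep(TRUE, nrow(x))
  x$bidirectional[is.na(x$bidirectional)] <- TRUE
  if (is.null(x$functional_class))
    x$functional_class <- rep(NA_character_, nrow(x))
  depth <- x$mutant_reads + x$ref_reads
  x$uncovered <- is.na(depth) | depth == 0
  x$af <- variant_af(x$mutant_reads, x$ref_reads)
  class(x) <- c("variant_table", "data.frame")
  x
}

#' Write a variant-call table
#'
#' Inverse of \code{\link{read_variant_table}}; derived columns (\code{af},
#' \code{uncovered}) are not written so that read/write round-trips the
#' canonical file byte-identically.
#'
#' @param x variant table as returned by \code{read_variant_table}.
#' @param path output path.
#' @param keep_derived write the derived columns too (default \code{FALSE}).
#' @return \code{path}, invisibly.
#' @export
write_variant_table <- function(x, path, keep_derived = FALSE) {
  out <- as.data.frame(x)
  if (!keep_derived) {
    drop <- c("af", "uncovered")
    # drop columns the reader synthesises when absent, so that files
    # lacking them round-trip byte-identically
    if (all(out$bidirectional)) drop <- c(drop, "bidirectional")
    if (!is.null(out$functional_class) && all(is.na(out$functional_class)))
      drop <- c(drop, "functional_class")
    out <- out[, setdiff(names(out), drop), drop = FALSE]
  }
  out[] <- lapply(out, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- "NA"
    col
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Apply the variant-call review filters
#'
#' Reproduces the study-design review rules for raw caller output: calls are
#' rejected when the mutant read count is below \code{min_alt_reads}, when
#' supporting reads were seen in only one direction, when the allele fraction
#' is below \code{min_af}, or when the site had no coverage. Boundary values
#' are kept (3 mutant reads and AF exactly 5\% pass). AF comparison uses
#' integer arithmetic (\code{20 * mutant >= depth} at the 5\% default) so the
#' boundary is exact.
#'
#' @param calls variant table (see \code{\link{read_variant_table}}).
#' @param min_alt_reads minimum mutant read count (default 3).
#' @param min_af minimum allele fraction (default 0.05).
#' @return list with elements \code{kept} and \code{rejected}; the latter
#'   carries a \code{reject_reason} column (first failing rule).
#' @export
filter_variant_calls <- function(calls, min_alt_reads = 3, min_af = 0.05) {
  calls <- as.data.frame(calls)
  n <- nrow(calls)
  if (n == 0) {
    empty <- calls
    empty$reject_reason <- character(0)
    return(list(kept = calls, rejected = empty))
  }
  depth <- calls$mutant_reads + calls$ref_reads
  uncovered <- is.na(depth) | depth == 0
  low_alt <- !uncovered & calls$mutant_reads < min_alt_reads
  unidir <- !uncovered & !calls$bidirectional
  # mutant/depth < min_af  <=>  mutant < min_af * depth; the epsilon keeps the
  # boundary (AF exactly min_af) on the kept side despite float rounding
  low_af <- !uncovered & (calls$mutant_reads + 1e-9 < min_af * depth)
  reason <- rep(NA_character_, n)
  reason[low_af] <- sprintf("allele fraction < %g", min_af)
  reason[unidir] <- "reads in one direction only"
  reason[low_alt] <- sprintf("variant reads < %d", min_alt_reads)
  reason[uncovered] <- "no coverage"
  rejected <- calls[!is.na(reason), , drop = FALSE]
  rejected$reject_reason <- reason[!is.na(reason)]
  list(kept = calls[is.na(reason), , drop = FALSE], rejected = rejected)
}

# md5 checksums of the shipped fixture transcriptions; load_fixtures() refuses
# to serve a modified file.
.FIXTURE_MD5 <- c(
  table1_tsc_variants.tsv = "f046f3751f5e0758c7143e202b25356d",
  table2_other_somatic.tsv = "ddfa15d02b8256317c0510973187000d"
)

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "secondhit")
  if (identical(p, "")) stop("fixture not installed: ", file)
  p
}

#' Load the packaged cohort fixtures
#'
#' Returns transcriptions of the published cohort tables: \code{table1}, the
#' TSC1/TSC2 mutation and LOH findings for all 32 specimens from 15 patients
#' (with per-sample LOH annotations), and \code{table2}, the somatic coding
#' mutations outside TSC1/TSC2 found in the 23 tumor-normal pairs. A third
#' element \code{samples} gives per-specimen metadata (source, TSC status,
#' whether a matched normal exists, LOH annotation and, for the multifocal
#' P13 tumors, the annotated 16p LOH region identity). The duplicated THBS3
#' row printed for S7 is retained and flagged in column \code{duplicate_row}.
#'
#' @return list with elements \code{table1}, \code{table2} and \code{samples}.
#' @export
load_fixtures <- function() {
  for (f in names(.FIXTURE_MD5)) {
    sum <- unname(tools::md5sum(fixture_path(f)))
    if (!identical(sum, unname(.FIXTURE_MD5[f])))
      stop("fixture checksum mismatch for ", f,
           " (got ", sum, "): refusing to load a modified transcription")
  }
  t1 <- read_variant_table(fixture_path("table1_tsc_variants.tsv"))
  t2 <- read_variant_table(fixture_path("table2_other_somatic.tsv"))
  key <- paste(t2$sample_id, t2$gene, t2$cdna_change)
  t2$duplicate_row <- duplicated(key)
  first <- !duplicated(t1$sample_id)
  samples <- data.frame(
    sample_id = t1$sample_id[first],
    patient_id = t1$patient_id[first],
    source = t1$source[first],
    tsc = grepl("TSC", t1$notes[first]),
    paired = !grepl("no normal", t1$notes[first]),
    loh_annotation = t1$loh_annotation[first],
    loh_region_id = t1$loh_region_id[first],
    stringsAsFactors = FALSE
  )
  samples$tsc[is.na(samples$tsc)] <- FALSE
  samples$paired[is.na(samples$paired)] <- TRUE
  list(table1 = t1, table2 = t2, samples = samples)
}

#' Import variant calls from a VCF file
#'
#' Optional convenience importer mapping standard \code{AD} genotype depths
#' (ref, alt) onto the canonical mutant/ref read-count columns. Requires the
#' VariantAnnotation package.
#'
#' @param path path to a VCF 4.x file.
#' @param sample_id sample column to extract (default: first).
#' @param patient_id patient identifier to stamp on the calls.
#' @param origin origin label for all imported calls (default "unknown").
#' @return a variant table (see \code{\link{read_variant_table}}); the HGVS
#'   and gene columns are left empty unless the VCF carries them in INFO.
#' @export
read_variant_vcf <- function(path, sample_id = NULL, patient_id = NA_character_,
                             origin = "unknown") {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_variant_vcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop("VCF has no AD genotype field")
  if (is.null(sample_id)) sample_id <- colnames(ad)[1]
  adx <- ad[, sample_id]
  ref_reads <- vapply(adx, function(v) as.numeric(v[1]), numeric(1))
  alt_reads <- vapply(adx, function(v) if (length(v) > 1) as.numeric(v[2]) else 0, numeric(1))
  out <- data.frame(
    patient_id = patient_id,
    sample_id = sample_id,
    gene = NA_character_,
    variant_type = "unknown",
    cdna_change = NA_character_,
    protein_change = NA_character_,
    mutant_reads = alt_reads,
    ref_reads = ref_reads,
    origin = origin,
    stringsAsFactors = FALSE
  )
  out$bidirectional <- TRUE
  out$functional_class <- NA_character_
  depth <- out$mutant_reads + out$ref_reads
  out$uncovered <- is.na(depth) | depth == 0
  out$af <- variant_af(out$mutant_reads, out$ref_reads)
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Read a SNP allele-count track
#'
#' Reads the tab-delimited per-SNP allele-count format (chrom, pos,
#' normal_ref, normal_alt, tumor_ref, tumor_alt). Positions are 1-based and
#' must be strictly increasing within a chromosome.
#'
#' @param path path to the TSV.
#' @return data.frame with a logical \code{paired} column (FALSE when the
#'   normal count columns are absent or all missing).
#' @export
read_snp_track <- function(path) {
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("chrom", "pos", "tumor_ref", "tumor_alt")
  if (length(setdiff(req, names(x))) > 0)
    stop("SNP track is missing required column(s): ",
         paste(setdiff(req, names(x)), collapse = ", "))
  has_normal <- all(c("normal_ref", "normal_alt") %in% names(x)) &&
    !all(is.na(x$normal_ref))
  if (!has_normal) {
    x$normal_ref <- NA_real_
    x$normal_alt <- NA_real_
  }
  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  dup <- stats::ave(x$pos, x$chrom, FUN = function(p) c(0, diff(p))) == 0 &
    duplicated(paste(x$chrom, x$pos))
  if (any(dup)) stop("duplicate positions in SNP track")
  counts <- c(x$normal_ref, x$normal_alt, x$tumor_ref, x$tumor_alt)
  if (any(counts < 0, na.rm = TRUE)) stop("negative read counts in SNP track")
  x$paired <- has_normal
  rownames(x) <- NULL
  x
}

#' Write a SNP allele-count track
#' @param x SNP track data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_snp_track <- function(x, path) {
  out <- x[, intersect(c("chrom", "pos", "normal_ref", "normal_alt",
                         "tumor_ref", "tumor_alt"), names(x))]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
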