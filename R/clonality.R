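# Patient-level clonal phylogeny of multifocal tumors from shared somatic
# mutations, shared LOH boundaries, and second-hit identity. The tree is
# event-set logic, two levels deep: a germline root, truncal nodes for
# definitely-shared groups, and sample leaves.

#' Group a patient's samples by shared somatic mutations
#'
#' Finds maximal sample sets sharing at least \code{min_shared} identical
#' somatic non-TSC mutations (gene + cDNA change). Sample pairs sharing
#' exactly one mutation are reported as \code{possible_links} but never
#' grouped: a single recurrent artifact could explain a singleton match.
#' Grouping is independent of input row order.
#'
#' @param calls somatic non-TSC1/TSC2 variant calls of one patient, with
#'   \code{sample_id}, \code{gene}, \code{cdna_change}.
#' @param min_shared minimum identical mutations for a definite group
#'   (default 2).
#' @return list: \code{groups} (list of lists with \code{samples} and
#'   \code{shared_mutations}), \code{possible_links} (data.frame of sample
#'   pairs sharing exactly one mutation).
#' @export
shared_mutation_groups <- function(calls, min_shared = 2) {
  calls <- as.data.frame(calls)
  if (!is.null(calls$uncovered))
    calls <- calls[!calls$uncovered, , drop = FALSE]
  calls <- calls[!(calls$gene %in% c("TSC1", "TSC2")), , drop = FALSE]
  empty <- list(groups = list(),
                possible_links = data.frame(sample_a = character(0),
                                            sample_b = character(0),
                                            shared_mutation = character(0),
                                            stringsAsFactors = FALSE))
  if (nrow(calls) == 0) return(empty)
  key <- paste(calls$gene, calls$cdna_change)
  # samples carrying each mutation (unique)
  carriers <- lapply(split(calls$sample_id, key), unique)
  samples <- sort(unique(calls$sample_id))
  ns <- length(samples)
  shared <- matrix(0L, ns, ns, dimnames = list(samples, samples))
  for (cs in carriers) {
    cs <- sort(cs)
    if (length(cs) > 1)
      for (i in seq_len(length(cs) - 1))
        for (j in seq(i + 1, length(cs)))
          shared[cs[i], cs[j]] <- shared[cs[i], cs[j]] + 1L
  }
  # connected components of the >= min_shared pairwise graph
  adj <- (shared + t(shared)) >= min_shared
  comp <- rep(NA_integer_, ns)
  cid <- 0L
  for (i in seq_len(ns)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    frontier <- i
    comp[i] <- cid
    while (length(frontier) > 0) {
      nxt <- which(adj[frontier[1], ] & is.na(comp))
      comp[nxt] <- cid
      frontier <- c(frontier[-1], nxt)
    }
  }
  groups <- list()
  for (g in unique(comp)) {
    members <- samples[comp == g]
    if (length(members) < 2) next
    joint <- names(carriers)[vapply(carriers, function(cs)
      all(members %in% cs), logical(1))]
    groups[[length(groups) + 1L]] <- list(
      samples = members,
      shared_mutations = sort(joint),
      conflict = length(joint) < min_shared
    )
  }
  links <- which(shared + t(shared) == 1 & upper.tri(shared), arr.ind = TRUE)
  possible <- if (nrow(links) > 0) {
    data.frame(
      sample_a = samples[links[, 1]], sample_b = samples[links[, 2]],
      shared_mutation = apply(links, 1, function(ij) {
        names(carriers)[vapply(carriers, function(cs)
          all(samples[ij] %in% cs), logical(1))][1]
      }),
      stringsAsFactors = FALSE
    )
  } else empty$possible_links
  list(groups = groups, possible_links = possible)
}

#' Compare the boundaries of two LOH regions
#'
#' On each side, a region's true breakpoint lies between its confident
#' boundary (last skewed SNP) and its uncertainty boundary (nearest normal-AF
#' SNP). Two regions on the same chromosome are the \code{same} when these
#' breakpoint-uncertainty intervals overlap on both sides (the true
#' breakpoints are indistinguishable at SNP resolution); \code{different}
#' when on some side the intervals are disjoint (the spans disagree beyond
#' both uncertainty flanks); \code{indeterminate} when a side cannot be
#' judged because a flank is censored by the end of the observed track (two
#' telomere-anchored regions share their telomeric side by construction and
#' are compared on the centromeric side only).
#'
#' @param region_a,region_b single rows of \code{loh_regions} data.frames.
#' @return \code{"same"}, \code{"different"} or \code{"indeterminate"}.
#' @export
loh_boundary_match <- function(region_a, region_b) {
  if (!identical(region_a$chrom, region_b$chrom))
    stop("regions on different chromosomes cannot be compared")
  cens <- function(r, field) isTRUE(r[[field]])
  side <- function(conf_a, unc_a, conf_b, unc_b, cens_a, cens_b) {
    if (cens_a && cens_b) return("same")  # both censored: e.g. telomere side
    if (cens_a || cens_b) return("indeterminate")
    lo_a <- min(conf_a, unc_a); hi_a <- max(conf_a, unc_a)
    lo_b <- min(conf_b, unc_b); hi_b <- max(conf_b, unc_b)
    if (hi_a < lo_b || hi_b < lo_a) "different" else "same"
  }
  s1 <- side(region_a$confident_start, region_a$uncertain_start,
             region_b$confident_start, region_b$uncertain_start,
             cens(region_a, "start_censored"), cens(region_b, "start_censored"))
  s2 <- side(region_a$confident_end, region_a$uncertain_end,
             region_b$confident_end, region_b$uncertain_end,
             cens(region_a, "end_censored"), cens(region_b, "end_censored"))
  if (s1 == "different" || s2 == "different") "different"
  else if (s1 == "same" && s2 == "same") "same"
  else "indeterminate"
}

#' Build a patient's clone tree
#'
#' Combines the evidence tiers into per-sample clonal classes and a
#' two-level phylogeny:
#' \itemize{
#'   \item \code{definite_shared}: member of a mutation-sharing group
#'     (>= 2 identical somatic mutations); nested under a truncal node.
#'   \item \code{independent}: carries a unique TSC second-hit variant or a
#'     unique LOH region within the patient.
#'   \item \code{possible_shared}: linked to other samples only by an
#'     identical LOH boundary (the weaker evidence tier; never overrides a
#'     mutation group).
#'   \item \code{unresolved}: no usable second-hit or sharing evidence.
#' }
#' Contradictory evidence (a mutation-sharing group whose members have
#' non-matching LOH) keeps the group and sets its \code{conflict} flag.
#'
#' @param patient_id patient identifier.
#' @param statuses per-sample status rows for this patient
#'   (\code{\link{classify_cohort}}).
#' @param mutation_groups result of \code{\link{shared_mutation_groups}}.
#' @param loh_groups list of character vectors: sample sets whose LOH
#'   boundaries match (singletons = unique region); samples absent from all
#'   sets have no usable LOH boundary evidence.
#' @param tsc_variants TSC1/TSC2 variant rows of this patient (used to spot
#'   unique somatic second-hit variants).
#' @param germline_annotation optional germline variant label for the root.
#' @return object of class \code{clone_tree}.
#' @export
build_clone_tree <- function(patient_id, statuses, mutation_groups,
                             loh_groups = list(), tsc_variants = NULL,
                             germline_annotation = NULL) {
  samples <- statuses$sample_id
  if (length(samples) == 0) stop("no samples for patient ", patient_id)
  classes <- stats::setNames(rep("unresolved", length(samples)), samples)
  groups <- mutation_groups$groups
  in_group <- unlist(lapply(groups, `[[`, "samples"))
  # unique somatic second-hit variants
  unique_hit <- character(0)
  if (!is.null(tsc_variants) && nrow(tsc_variants) > 0) {
    som <- tsc_variants[tsc_variants$origin == "somatic" &
                          tsc_variants$variant_type != "genomic_del", ,
                        drop = FALSE]
    if (nrow(som) > 0) {
      tab <- table(som$cdna_change)
      uniq_vars <- names(tab)[tab == 1]
      unique_hit <- unique(som$sample_id[som$cdna_change %in% uniq_vars])
    }
  }
  loh_sizes <- stats::setNames(rep(NA_integer_, length(samples)), samples)
  for (g in loh_groups) loh_sizes[intersect(g, samples)] <- length(g)
  for (s in samples) {
    cls <- if (s %in% in_group) "definite_shared"
    else if (statuses$mechanism[statuses$sample_id == s] == "none")
      "unresolved"
    else if (s %in% unique_hit) "independent"
    else if (!is.na(loh_sizes[s]) && loh_sizes[s] >= 2) "possible_shared"
    else if (!is.na(loh_sizes[s]) && loh_sizes[s] == 1) "independent"
    else "unresolved"
    classes[s] <- cls
  }
  # LOH-vs-mutation conflict: a definite group split across LOH groups
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    memb_loh <- lapply(loh_groups, intersect, g$samples)
    covered <- unlist(memb_loh)
    split_groups <- sum(vapply(memb_loh, length, integer(1)) > 0)
    if (length(covered) > 0 && split_groups > 1) {
      groups[[i]]$conflict <- TRUE
      warning("patient ", patient_id, ": mutation-sharing group {",
              paste(g$samples, collapse = ","),
              "} spans non-matching LOH regions; group retained with ",
              "conflict flag")
    }
  }
  structure(list(
    patient_id = patient_id,
    germline = germline_annotation,
    groups = groups,
    classes = classes,
    samples = samples,
    loh_groups = loh_groups
  ), class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("clone tree for", x$patient_id, "-", length(x$samples), "samples\n")
  if (!is.null(x$germline)) cat("  germline:", x$germline, "\n")
  for (g in x$groups)
    cat("  truncal group {", paste(g$samples, collapse = ", "), "} sharing ",
        length(g$shared_mutations), " mutation(s)",
        if (isTRUE(g$conflict)) " [CONFLICT]" else "", "\n", sep = "")
  tab <- table(factor(x$classes, levels = c("definite_shared",
                                            "possible_shared", "independent",
                                            "unresolved")))
  for (cl in names(tab)) if (tab[cl] > 0)
    cat("  ", cl, ": ", tab[cl], "\n", sep = "")
  invisible(x)
}

#' Export a clone tree as newick and JSON
#'
#' The newick string nests each definite mutation-sharing group under an
#' internal node labelled with its truncal event count; all other samples
#' attach directly to the root (labelled with the patient id). The JSON
#' mirrors the full event lists. The newick round-trips through standard
#' phylogenetics readers (e.g. \code{ape::read.tree}).
#'
#' @param tree a \code{clone_tree}.
#' @param json_path optional path: when given, the JSON report is written
#'   there.
#' @return list: \code{newick} (string), \code{json} (string).
#' @export
export_tree <- function(tree, json_path = NULL) {
  if (!inherits(tree, "clone_tree")) stop("not a clone_tree")
  if (length(tree$samples) == 0) stop("empty patient: nothing to export")
  grouped <- unlist(lapply(tree$groups, `[[`, "samples"))
  parts <- character(0)
  for (g in tree$groups)
    parts <- c(parts, paste0("(", paste(sort(g$samples), collapse = ","),
                             ")shared", length(g$shared_mutations)))
  singles <- sort(setdiff(tree$samples, grouped))
  parts <- c(parts, singles)
  newick <- if (length(parts) == 1 && length(tree$groups) == 0)
    paste0("(", parts, ")", tree$patient_id, ";")
  else paste0("(", paste(parts, collapse = ","), ")", tree$patient_id, ";")
  payload <- list(
    patient_id = tree$patient_id,
    germline = tree$germline,
    groups = lapply(tree$groups, function(g)
      list(samples = g$samples, shared_mutations = g$shared_mutations,
           conflict = isTRUE(g$conflict))),
    classes = as.list(tree$classes),
    loh_groups = tree$loh_groups,
    newick = newick
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(json_path)) writeLines(json, json_path)
  list(newick = newick, json = as.character(json))
}
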