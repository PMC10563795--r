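CALLER_ORDER <- c("M2", "SC", "MU")
# field-merge precedence when callers disagree on depths/quality
MERGE_PRECEDENCE <- c("M2", "MU", "SC")

#' Multi-caller consensus of somatic calls
#'
#' With all three callers available, keeps variants supported by two or more
#' callers. When MuSE (`MU`) calls are unavailable (no matched normal), falls
#' back to the union of Mutect2 and SureCall. Variant identity is the exact
#' (chrom, pos, ref, alt) tuple. Depths, VAF and annotations are taken from
#' the highest-precedence supporting caller (M2 > MU > SC); the `callers`
#' column records the full supporting subset.
#'
#' @param per_caller_sets named list of variant tables (names among
#'   `"M2"`, `"SC"`, `"MU"`).
#' @param available_callers callers that were run (defaults to the names of
#'   `per_caller_sets`); an empty call set from an available caller still
#'   counts as a run caller.
#' @return variant table of consensus calls.
#' @export
consensus_calls <- function(per_caller_sets,
                            available_callers = names(per_caller_sets)) {
  available_callers <- intersect(CALLER_ORDER, available_callers)
  if (length(available_callers) < 2) stopf("insufficient callers")
  sets <- per_caller_sets[intersect(available_callers,
                                    names(per_caller_sets))]
  sets <- sets[vapply(sets, function(s) !is.null(s), logical(1))]
  all <- data.table::rbindlist(
    lapply(names(sets), function(cl) {
      s <- sets[[cl]]
      if (!nrow(s)) return(NULL)
      s$callers <- cl
      s
    }), use.names = TRUE, fill = TRUE)
  if (is.null(all) || !nrow(all)) return(empty_variants())
  all <- as.data.frame(all)
  key <- vkeys(all)
  support <- tapply(all$callers, key, function(x) sort(unique(x)))
  n_support <- lengths(support)
  keep_keys <- if ("MU" %in% available_callers) {
    names(support)[n_support >= 2L]
  } else {
    names(support)  # union of M2 and SC
  }
  if (!length(keep_keys)) return(empty_variants())
  # representative row per variant by merge precedence
  all$.prec <- match(all$callers, MERGE_PRECEDENCE)
  all <- all[order(key, all$.prec), ]
  key <- vkeys(all)
  rep_rows <- all[!duplicated(key) & key %in% keep_keys, ]
  rep_rows$callers <- vapply(
    support[vkeys(rep_rows)],
    function(s) paste(intersect(CALLER_ORDER, s), collapse = ","),
    character(1))
  rep_rows$.prec <- NULL
  rep_rows <- rep_rows[order(rep_rows$chrom, rep_rows$pos, rep_rows$ref,
                             rep_rows$alt), ]
  rownames(rep_rows) <- NULL
  class(rep_rows) <- c("ipmn_variants", "data.frame")
  rep_rows
}

#' Remove likely germline polymorphisms by population allele frequency
#'
#' Variants whose maximum gnomAD/ExAC-style population allele frequency
#' exceeds `max_af` are removed; variants with no population record
#' (`pop_af` NA) are retained. Idempotent.
#'
#' @param variants variant table.
#' @param max_af removal threshold, default 0.01 (1%).
#' @export
population_filter <- function(variants, max_af = 0.01) {
  stopifnot(max_af > 0, max_af <= 1)
  if (!nrow(variants)) return(variants)
  keep <- is.na(variants$pop_af) | variants$pop_af <= max_af
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Targeted rescue of single-caller calls
#'
#' Single-caller calls are normally discarded by the consensus rule; calls at
#' predetermined loci are rescued under a relaxed quality threshold. Rescue
#' sites are (i) driver hotspot loci in established PDAC genes and (ii) sites
#' where the stringent two-caller rule detected an SNV in another non-blood
#' sample of the same patient. Rescued calls are flagged `rescued = TRUE` and
#' are site-disjoint from the consensus set.
#'
#' @param single_caller_calls variant table of calls supported by exactly one
#'   caller.
#' @param panel list with `driver_loci` (data.frame chrom, pos),
#'   `shared_sites` (data.frame chrom, pos; may be empty) and
#'   `relaxed_threshold` (emission log-odds, default 1.5).
#' @param consensus optional consensus variant table; rescued calls at sites
#'   already in it are dropped to guarantee disjointness.
#' @export
rescue_targeted <- function(single_caller_calls, panel, consensus = NULL) {
  if (is.null(panel$driver_loci) || !nrow(panel$driver_loci))
    stopf("rescue panel has no driver loci")
  thr <- panel$relaxed_threshold %||% 1.5
  v <- single_caller_calls
  if (!nrow(v)) return(empty_variants())
  sites <- skeys(panel$driver_loci)
  if (!is.null(panel$shared_sites) && nrow(panel$shared_sites))
    sites <- union(sites, skeys(panel$shared_sites))
  keep <- skeys(v) %in% sites & !is.na(v$quality) & v$quality >= thr
  out <- v[keep, , drop = FALSE]
  if (!is.null(consensus) && nrow(consensus))
    out <- out[!skeys(out) %in% skeys(consensus), , drop = FALSE]
  if (nrow(out)) out$rescued <- TRUE
  rownames(out) <- NULL
  out
}

#' Classify variants as deleterious
#'
#' A variant is deleterious iff it is exonic or splicing AND (at least two of
#' the seven predictors call it deleterious OR ClinVar labels it pathogenic).
#'
#' @param variants variant table (vectorized over rows).
#' @return logical vector.
#' @export
classify_deleterious <- function(variants) {
  if (!nrow(variants)) return(logical())
  variants$func_class %in% c("exonic", "splicing") &
    (pred7_count(variants$pred7) >= 2L | variants$clinvar == "pathogenic")
}

#' Depth filter for small insertions and deletions
#'
#' Keeps indels with at least `min_tumor` supporting reads in the tumor and
#' at most `max_normal` supporting reads in the matched normal (both bounds
#' inclusive). Indels with no matched normal (`normal_alt` NA) are treated as
#' having zero normal support.
#'
#' @param indels variant table (rows with `type == "indel"` are filtered;
#'   other rows pass through untouched).
#' @param min_tumor minimum tumor alt reads, default 5.
#' @param max_normal maximum normal alt reads, default 0.
#' @export
filter_indels <- function(indels, min_tumor = 5L, max_normal = 0L) {
  stopifnot(min_tumor >= 0, max_normal >= 0)
  if (!nrow(indels)) return(indels)
  is_indel <- indels$type == "indel"
  nalt <- ifelse(is.na(indels$normal_alt), 0L, indels$normal_alt)
  keep <- !is_indel | (indels$tumor_alt >= min_tumor & nalt <= max_normal)
  out <- indels[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nonsynonymous mutation burden per megabase
#'
#' Counts exonic/splicing variants (the deleterious-eligible classes; the
#' eligible classes are configurable) and divides by the captured footprint.
#' Rescued calls are excluded by default so that burden reflects the
#' stringent genome-wide calling rule only.
#'
#' @param variants variant table.
#' @param captured_mb size of the captured sequence space in Mb.
#' @param classes functional classes that count, default exonic + splicing.
#' @param include_rescued count rescued calls too? default FALSE.
#' @return mutations per Mb.
#' @export
mutation_burden <- function(variants, captured_mb,
                            classes = c("exonic", "splicing"),
                            include_rescued = FALSE) {
  if (!is.numeric(captured_mb) || captured_mb <= 0)
    stopf("captured_mb must be positive")
  if (!nrow(variants)) return(0)
  n <- sum(variants$func_class %in% classes &
             (include_rescued | !variants$rescued))
  n / captured_mb
}
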