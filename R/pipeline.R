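#' Default analysis configuration for [run_pipeline()]
#' @param ... overrides.
#' @export
pipeline_config <- function(...) {
  modifyList(list(
    capture_mb = 50, max_pop_af = 0.01, indel_min_tumor = 5L,
    indel_max_normal = 0L, rescue = TRUE, relaxed_threshold = 1.5,
    logr_gain = 0.2, logr_loss = -0.2, presence_threshold = 0.01,
    merge_height = 0.2, containment_tol = 0.1, min_event_mb = 5,
    exclude_cna_overlap = TRUE, n_perm = 1000, fdr_threshold = 0.05,
    blocklist = NULL), list(...))
}

# consensus + filters + rescue for one region given its per-caller call sets
harmonize_region <- function(calls, driver_loci, shared_sites, config) {
  available <- names(calls)
  cons <- consensus_calls(calls, available)
  cons <- population_filter(cons, config$max_pop_af)
  cons <- filter_indels(cons, config$indel_min_tumor, config$indel_max_normal)
  if (!is.null(config$blocklist) && nrow(cons))
    cons <- cons[!skeys(cons) %in% skeys(config$blocklist), , drop = FALSE]
  rescued <- empty_variants()
  if (isTRUE(config$rescue)) {
    all <- do.call(rbind, lapply(names(calls), function(cl) {
      s <- calls[[cl]]
      if (nrow(s)) s$callers <- cl
      s
    }))
    if (!is.null(all) && nrow(all)) {
      key <- vkeys(all)
      single <- all[key %in% names(which(table(key) == 1)), , drop = FALSE]
      single <- population_filter(single, config$max_pop_af)
      single <- filter_indels(single, config$indel_min_tumor,
                              config$indel_max_normal)
      panel <- list(driver_loci = driver_loci, shared_sites = shared_sites,
                    relaxed_threshold = config$relaxed_threshold)
      rescued <- rescue_targeted(single, panel, consensus = cons)
    }
  }
  out <- rbind(cons, rescued)
  if (nrow(out)) out <- out[order(out$chrom, out$pos, out$ref, out$alt), ]
  rownames(out) <- NULL
  class(out) <- c("ipmn_variants", "data.frame")
  out
}

# sites detected by the stringent consensus rule in any OTHER region of the
# same patient (the shared-site arm of the rescue panel)
shared_site_panel <- function(consensus_by_region, region) {
  others <- setdiff(names(consensus_by_region), region)
  if (!length(others)) return(data.frame(chrom = character(),
                                         pos = integer()))
  s <- do.call(rbind, lapply(others, function(r)
    consensus_by_region[[r]][, c("chrom", "pos")]))
  unique(s)
}

#' Analyze one patient of a cohort
#'
#' Runs the full integration for a single patient: per-region consensus +
#' filters + targeted rescue, CNA overlay calling with aneuploidy score and
#' 1q flag, SNV clone tree with topology classification, CNA small-parsimony
#' tree, minor-clone expansion detection, and per-region subtype calls.
#'
#' @param patient one element of `ipmn_cohort$patients` (truth + data) or an
#'   equivalent structure with a `data` layer.
#' @param cohort the cohort (for arms, genes, templates).
#' @param config [pipeline_config()].
#' @param seed seed for the permutation tests.
#' @return list with `regions` (per-region summary), `variants`,
#'   `cna_events`, `snv_tree`, `snv_class`, `cna_class`, `minor_expansion`,
#'   `subtype_calls`.
#' @export
analyze_patient <- function(patient, cohort, config = pipeline_config(),
                            seed = 1L) {
  arms <- cohort$arms
  regions <- names(patient$data$calls)
  reginfo <- patient$truth$regions
  grades <- setNames(reginfo$grade, reginfo$region)
  purity <- setNames(reginfo$purity, reginfo$region)
  driver_loci <- driver_loci_panel()
  # pass 1: stringent consensus per region (also feeds shared-site rescue)
  cons0 <- lapply(setNames(nm = regions), function(r) {
    calls <- patient$data$calls[[r]]
    cons <- consensus_calls(calls, names(calls))
    cons <- population_filter(cons, config$max_pop_af)
    filter_indels(cons, config$indel_min_tumor, config$indel_max_normal)
  })
  # pass 2: add targeted rescue with the cross-region panel
  variants <- lapply(setNames(nm = regions), function(r) {
    harmonize_region(patient$data$calls[[r]], driver_loci,
                     shared_site_panel(cons0, r), config)
  })
  # CNA layer
  cna <- lapply(setNames(nm = regions), function(r) {
    seg <- patient$data$segments[[r]]
    overlay_cna(seg$ai, seg$logr, config$logr_gain, config$logr_loss)
  })
  region_summary <- do.call(rbind, lapply(regions, function(r) {
    ev <- cna[[r]]
    data.frame(
      patient = patient$truth$patient, region = r, grade = grades[r],
      purity = purity[r], n_variants = nrow(variants[[r]]),
      burden = mutation_burden(variants[[r]], config$capture_mb),
      n_deleterious = sum(classify_deleterious(variants[[r]])),
      as = aneuploidy_score(ev, arms),
      flag_1q = arm_amplification_flag(ev, arms, "1q"),
      n_focal = sum(classify_focal(ev) == "focal"),
      n_broad = sum(classify_focal(ev) == "broad"),
      stringsAsFactors = FALSE)
  }))
  rownames(region_summary) <- NULL
  # SNV clone tree over neoplastic regions
  neo <- regions[purity[regions] > 0]
  snv_tree <- NULL
  snv_class <- "unclassifiable"
  minor <- NULL
  if (length(neo) >= 2) {
    keys <- sort(unique(unlist(lapply(neo, function(r)
      vkeys(variants[[r]])))))
    if (isTRUE(config$exclude_cna_overlap) && length(keys)) {
      inside <- rep(FALSE, length(keys))
      parts <- do.call(rbind, strsplit(keys, ":"))
      kc <- parts[, 1]; kp <- as.numeric(parts[, 2])
      for (r in neo) {
        ev <- cna[[r]]
        if (!nrow(ev)) next
        for (i in seq_len(nrow(ev)))
          inside <- inside | (kc == ev$chrom[i] & kp >= ev$start[i] &
                                kp <= ev$end[i])
      }
      keys <- keys[!inside]
    }
    if (length(keys) >= 2) {
      vaf <- matrix(0, length(neo), length(keys),
                    dimnames = list(neo, keys))
      for (r in neo) {
        v <- variants[[r]]
        hit <- match(vkeys(v), keys)
        ok <- !is.na(hit)
        vaf[r, hit[ok]] <- v$vaf[ok]
      }
      clusters <- cluster_variants(vaf, purity[neo],
                                   config$presence_threshold,
                                   config$merge_height)
      snv_tree <- build_snv_tree(clusters, tol = config$containment_tol)
      snv_class <- classify_topology(snv_tree, grades)
      minor <- detect_minor_expansion(snv_tree, grades)
    }
  }
  # CNA parsimony tree
  cna_class <- "unclassifiable"
  if (length(neo) >= 2 && all(c("LG", "HG") %in% grades[neo])) {
    prof <- arm_state_profiles(cna[neo], arms, config$min_event_mb)
    lg <- neo[grades[neo] == "LG"][1]; hg <- neo[grades[neo] == "HG"][1]
    cna_class <- build_cna_tree(prof, lg = lg, hg = hg)$classification
  }
  # subtype layer
  sub_seeds <- derive_seeds(seed, length(regions))
  subtype_calls <- list()
  region_summary$subtype <- NA_character_
  for (i in seq_along(regions)) {
    r <- regions[i]
    counts <- patient$data$expression[[r]]
    norm <- suppressWarnings(normalize_counts(counts))
    calls <- classify_replicates(norm, cohort$templates,
                                 n_perm = config$n_perm,
                                 fdr_threshold = config$fdr_threshold,
                                 seed = sub_seeds[i])
    subtype_calls[[r]] <- calls
    region_summary$subtype[region_summary$region == r] <-
      aggregate_replicates(calls)
  }
  list(regions = region_summary, variants = variants, cna_events = cna,
       snv_tree = snv_tree, snv_class = snv_class, cna_class = cna_class,
       minor_expansion = minor, subtype_calls = subtype_calls)
}

#' Run the full pipeline over a cohort
#'
#' Executes variant harmonization, CNA calling, clonal-trajectory
#' classification and subtype assignment for every patient, then assembles
#' cohort-level results: the HG-vs-LG comparisons of aneuploidy score and
#' mutation burden (paired and unpaired), the subtype-by-1q 2x2 table with
#' its exact test, SNV/CNA trajectory agreement, and the class-switch
#' report. Deterministic given the cohort and `seed`.
#'
#' @param cohort an `ipmn_cohort` (in memory) or a cohort directory written
#'   by [write_cohort()].
#' @param config [pipeline_config()].
#' @param seed master seed for permutation tests.
#' @param out_dir optional directory for TSV/JSON reports and a log.
#' @return list of class `ipmn_report`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), seed = 1L,
                         out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  seeds <- derive_seeds(seed, length(cohort$patients))
  log <- character()
  results <- list()
  for (i in seq_along(cohort$patients)) {
    pid <- names(cohort$patients)[i]
    res <- tryCatch(
      analyze_patient(cohort$patients[[pid]], cohort, config, seeds[i]),
      error = function(e) {
        log <<- c(log, sprintf("patient %s failed: %s", pid,
                               conditionMessage(e)))
        NULL
      })
    if (!is.null(res)) results[[pid]] <- res
  }
  regions <- do.call(rbind, lapply(results, `[[`, "regions"))
  rownames(regions) <- NULL
  patients <- data.frame(
    patient = names(results),
    snv_class = vapply(results, `[[`, character(1), "snv_class"),
    cna_class = vapply(results, `[[`, character(1), "cna_class"),
    stringsAsFactors = FALSE)
  rownames(patients) <- NULL
  traj <- compare_trajectories(
    setNames(patients$snv_class, patients$patient),
    setNames(patients$cna_class, patients$patient))
  lesions <- regions[regions$grade %in% c("LG", "HG"), , drop = FALSE]
  pairs <- do.call(rbind, lapply(split(lesions, lesions$patient),
                                 function(x) {
    lg <- x$region[x$grade == "LG"]; hg <- x$region[x$grade == "HG"]
    if (!length(lg) || !length(hg)) return(NULL)
    data.frame(patient = x$patient[1],
               lg = paste0(x$patient[1], ":", lg[1]),
               hg = paste0(x$patient[1], ":", hg[1]),
               stringsAsFactors = FALSE)
  }))
  rid <- paste0(lesions$patient, ":", lesions$region)
  grades_v <- setNames(lesions$grade, rid)
  as_cmp <- burden_cmp <- NULL
  if (sum(lesions$grade == "HG") >= 2 && sum(lesions$grade == "LG") >= 2) {
    as_cmp <- suppressWarnings(compare_grades(
      setNames(lesions$as, rid), grades_v, pairs))
    burden_cmp <- suppressWarnings(compare_grades(
      setNames(lesions$burden, rid), grades_v, pairs))
  }
  hg <- regions[regions$grade == "HG", , drop = FALSE]
  tab <- subtype_cna_table(
    setNames(hg$subtype, paste0(hg$patient, ":", hg$region)),
    setNames(hg$flag_1q, paste0(hg$patient, ":", hg$region)))
  tab_test <- if (sum(tab) > 0) suppressWarnings(exact_2x2(tab)) else NULL
  switches <- class_switches(
    data.frame(patient = lesions$patient, region = lesions$region,
               grade = lesions$grade, label = lesions$subtype,
               stringsAsFactors = FALSE))
  report <- structure(list(
    regions = regions, patients = patients, trajectory = traj,
    as_comparison = as_cmp, burden_comparison = burden_cmp,
    subtype_1q_table = tab, subtype_1q_test = tab_test,
    class_switches = switches, results = results, log = log,
    config = config, seed = seed), class = "ipmn_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.ipmn_report <- function(x, ...) {
  cat(sprintf("<ipmn_report: %d patients, %d regions>\n",
              nrow(x$patients), nrow(x$regions)))
  print(x$patients)
  invisible(x)
}

#' Write a pipeline report to disk
#' @param report `ipmn_report`.
#' @param out_dir output directory.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(report$regions, file.path(out_dir, "regions.tsv"),
                     sep = "\t")
  data.table::fwrite(report$patients, file.path(out_dir, "patients.tsv"),
                     sep = "\t")
  summary <- list(
    trajectory_agreement = report$trajectory$agreement,
    subtype_1q_table = as.list(report$subtype_1q_table),
    subtype_1q_p_exact = report$subtype_1q_test$p_exact %||% NA,
    as_p_paired = report$as_comparison$p_paired %||% NA,
    as_p_unpaired = report$as_comparison$p_unpaired %||% NA,
    burden_p_paired = report$burden_comparison$p_paired %||% NA,
    seed = report$seed)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report$log %||% character(), file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}
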