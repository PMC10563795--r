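#' Default CNA event menu on the toy genome
#'
#' Broad arm-scale events (80% of an arm, one entry per arm) plus one 2 Mb
#' focal gain; the 1q gain is preferentially assigned to the high-grade
#' lineage by the simulator, mirroring 1q amplification as a progression
#' event.
#' @export
default_cna_menu <- function() {
  arms <- toy_arm_table()
  mk <- function(name, chrom, arm, direction, fraction = 0.8) {
    a <- arms[arms$chrom == chrom & arms$arm == arm, ]
    len <- a$end - a$start + 1
    data.frame(name = name, chrom = chrom,
               start = a$end - floor(fraction * len) + 1, end = a$end,
               direction = direction, stringsAsFactors = FALSE)
  }
  rbind(
    mk("1q_gain", "1", "q", "gain"),
    mk("2q_loss", "2", "q", "loss"),
    mk("3p_loss", "3", "p", "loss"),
    mk("3q_gain", "3", "q", "gain"),
    mk("4p_cnloh", "4", "p", "cnloh"),
    mk("4q_gain", "4", "q", "gain"),
    data.frame(name = "2p_focal_gain", chrom = "2", start = 10e6,
               end = 12e6 - 1, direction = "gain", stringsAsFactors = FALSE)
  )
}

#' Default per-caller sensitivity / false-positive profiles
#'
#' Sensitivities are stratified by expected VAF; the strata breaks are
#' `c(0, 0.02, 0.05, 0.1, 1)`. The three profiles emulate a
#' haplotype-aware caller (M2), a vendor pipeline (SC) and a
#' matched-normal-only caller (MU); values are stipulated defaults (no
#' published per-caller operating points exist for this assay).
#' @export
default_caller_profiles <- function() {
  list(
    M2 = list(sensitivity = c(0.60, 0.90, 0.97, 0.99), fp_rate = 0.02),
    SC = list(sensitivity = c(0.45, 0.80, 0.93, 0.98), fp_rate = 0.05),
    MU = list(sensitivity = c(0.50, 0.85, 0.95, 0.99), fp_rate = 0.03)
  )
}

#' Simulation configuration for a synthetic multi-region cohort
#'
#' Defaults state the simulated world: 400x mean depth, 2-5 microdissected
#' regions per patient (always one LG and one HG lesion; extra regions drawn
#' from ND/AC/PDAC), truncal KRAS G12D and GNAS R201C hotspots, 3-5 clones
#' with 5-12 private subclonal SNVs each, per-region neoplastic purity in
#' [0.2, 0.9], three callers with distinct sensitivity/false-positive
#' profiles, and 2-5 expression replicates per region drawn from subtype
#' templates with log-normal noise and dropout.
#'
#' @param n_patients number of patients.
#' @param regions_per_patient length-2 range of regions per patient.
#' @param mean_depth mean sequencing depth (reads).
#' @param topology_mix named proportions over c(linear, branched); must sum
#'   to 1.
#' @param n_clones length-2 range of clones per patient.
#' @param n_subclonal_snvs length-2 range of private SNVs per clone.
#' @param purity_range per-region neoplastic purity range for lesions.
#' @param cna_menu CNA event menu (name, chrom, start, end, direction).
#' @param caller_profiles per-caller list(sensitivity by VAF stratum,
#'   fp_rate per Mb); see [default_caller_profiles()].
#' @param vaf_strata VAF stratum breaks for the sensitivity vectors.
#' @param mu_missing_prob probability a patient lacks a matched normal and
#'   hence MuSE calls.
#' @param capture_mb captured sequence space (Mb) for burden and
#'   false-positive placement.
#' @param expression list(n_marker, hi, lo, bg, n_background, noise_sd,
#'   dropout, replicates (range), nonclassifiable_prob, switch_prob,
#'   sf_sd).
#' @param segment_noise_sd Gaussian noise on log-ratio segment means.
#' @param logr_gain_level,logr_loss_level true mean log2 shift of simulated
#'   gains/losses.
#' @param cna_detect_ccf clone CCF above which a clone's CNA manifests in a
#'   region's segmentation (clonal-dominance detectability).
#' @param noiseless TRUE collapses every stochastic layer: perfect
#'   sensitivity, zero false positives, deterministic depths/alt counts,
#'   zero segment and expression noise (the exact-recovery regime).
#' @param seed master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 4,
                       regions_per_patient = c(2, 5),
                       mean_depth = 400,
                       topology_mix = c(linear = 0.5, branched = 0.5),
                       n_clones = c(3, 5),
                       n_subclonal_snvs = c(5, 12),
                       purity_range = c(0.2, 0.9),
                       cna_menu = default_cna_menu(),
                       caller_profiles = default_caller_profiles(),
                       vaf_strata = c(0, 0.02, 0.05, 0.1, 1),
                       mu_missing_prob = 0.1,
                       capture_mb = 50,
                       expression = list(),
                       segment_noise_sd = 0.05,
                       logr_gain_level = 0.4,
                       logr_loss_level = -0.45,
                       cna_detect_ccf = 0.5,
                       noiseless = FALSE,
                       seed = 1L) {
  expr_default <- list(n_marker = 30, hi = 8, lo = 3, bg = 5,
                       n_background = 110, noise_sd = 1, dropout = 0.1,
                       replicates = c(2, 5), nonclassifiable_prob = 0.1,
                       switch_prob = 0.15, sf_sd = 0.3)
  expression <- modifyList(expr_default, expression)
  if (abs(sum(topology_mix) - 1) > 1e-8) stopf("topology_mix must sum to 1")
  if (mean_depth <= 0) stopf("depth must be positive")
  probs <- c(mu_missing_prob, expression$dropout,
             expression$nonclassifiable_prob, expression$switch_prob,
             unlist(lapply(caller_profiles, `[[`, "sensitivity")))
  if (any(probs < 0 | probs > 1)) stopf("all probabilities must lie in [0,1]")
  if (noiseless) {
    caller_profiles <- lapply(caller_profiles, function(p)
      list(sensitivity = rep(1, length(p$sensitivity)), fp_rate = 0))
    segment_noise_sd <- 0
    expression$noise_sd <- 0
    expression$dropout <- 0
    expression$sf_sd <- 0
    expression$nonclassifiable_prob <- 0
    mu_missing_prob <- 0
  }
  structure(list(
    n_patients = n_patients, regions_per_patient = regions_per_patient,
    mean_depth = mean_depth, topology_mix = topology_mix,
    n_clones = n_clones, n_subclonal_snvs = n_subclonal_snvs,
    purity_range = purity_range, cna_menu = cna_menu,
    caller_profiles = caller_profiles, vaf_strata = vaf_strata,
    mu_missing_prob = mu_missing_prob, capture_mb = capture_mb,
    expression = expression, segment_noise_sd = segment_noise_sd,
    logr_gain_level = logr_gain_level, logr_loss_level = logr_loss_level,
    cna_detect_ccf = cna_detect_ccf, noiseless = noiseless,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate a ground-truth clone tree with a requested topology
#'
#' Linear topology: a clone chain in which the dominant HG clone is the
#' direct child of the dominant LG clone and is present as a minor
#' subpopulation (CCF 0.02) in the LG lesion - the stepwise-acquisition
#' pattern. Branched topology: a truncal chain splitting into an LG-dominant
#' and an HG-dominant branch, with the HG branch absent from the LG lesion.
#' CCFs are constructed so the topology classifier recovers the requested
#' label (self-consistency by design).
#'
#' @param n_clones number of clones (>= 2; branched needs >= 3).
#' @param topology "linear" or "branched".
#' @param seed RNG seed (reserved; the construction is deterministic).
#' @param regions region ids for the LG and HG columns.
#' @return `clone_tree` with abstract per-clone mutation placeholders.
#' @export
simulate_clone_tree <- function(n_clones, topology = c("linear", "branched"),
                                seed = 1L, regions = c(LG = "LG", HG = "HG")) {
  topology <- match.arg(topology)
  if (n_clones < 2) stopf("degenerate tree: need >= 2 clones")
  if (topology == "branched" && n_clones < 3)
    stopf("degenerate tree: branched topology needs >= 3 clones")
  ids <- paste0("C", seq_len(n_clones))
  k <- n_clones
  ccf <- matrix(0, k, 2, dimnames = list(ids, unname(regions)))
  if (topology == "linear") {
    parent <- c(NA, ids[-k])
    lgdom <- k - 1; hgdom <- k
    ccf[seq_len(k - 1), 1] <- 1 - 0.12 * (seq_len(k - 1) - 1)
    ccf[k, 1] <- 0.02
    ccf[seq_len(k - 1), 2] <- 1 - 0.04 * (seq_len(k - 1) - 1)
    ccf[k, 2] <- 0.72
  } else {
    t <- k - 2
    parent <- c(NA, ids[seq_len(t - 1)], ids[t], ids[t])
    lgdom <- t + 1; hgdom <- t + 2
    ccf[seq_len(t), 1] <- 1 - 0.06 * (seq_len(t) - 1)
    ccf[lgdom, 1] <- min(0.78, ccf[t, 1] - 0.05)
    ccf[hgdom, 1] <- 0
    ccf[seq_len(t), 2] <- 1 - 0.04 * (seq_len(t) - 1)
    ccf[lgdom, 2] <- 0.15
    ccf[hgdom, 2] <- 0.70
  }
  mutations <- setNames(lapply(ids, function(cl)
    paste0(cl, "_m", 1:2)), ids)
  tr <- clone_tree(data.frame(clone = ids, parent = parent,
                              stringsAsFactors = FALSE),
                   ccf, mutations = mutations, topology = topology)
  tr$lgdom <- ids[lgdom]; tr$hgdom <- ids[hgdom]
  tr
}

vaf_stratum <- function(vaf, breaks) {
  pmin(length(breaks) - 1L, pmax(1L, findInterval(vaf, breaks,
                                                  rightmost.closed = TRUE)))
}

# expected VAF of a variant in a region, with a crude ploidy adjustment at
# sites inside region-manifest CNA events
expected_vaf <- function(variants, ccf_region, purity, region_events) {
  base <- purity * ccf_region[variants$clone] / 2
  if (!is.null(region_events) && nrow(region_events)) {
    for (i in seq_len(nrow(region_events))) {
      e <- region_events[i, ]
      hit <- variants$chrom == e$chrom & variants$pos >= e$start &
        variants$pos <= e$end
      if (!any(hit)) next
      base[hit] <- switch(e$direction,
                          gain = base[hit] * 2 / 3,
                          loss = pmin(0.95, base[hit] * 2),
                          cnloh = base[hit])
    }
  }
  unname(pmin(0.95, base))
}

#' Simulate per-caller somatic call sets for one region
#'
#' Each true variant with nonzero CCF in the region receives a depth
#' (Poisson around the configured mean) and an alt count (binomial at the
#' purity- and clone-fraction-implied expected VAF, diploid unless the site
#' overlaps a region-manifest CNA). Each caller then detects it
#' independently with its VAF-stratum sensitivity, and adds false positives
#' uniformly over the capture space at its per-Mb rate. Under
#' `noiseless = TRUE` depths and alt counts are deterministic and
#' sensitivity is perfect. Patient-level germline leak-through sites
#' (population AF above 1%) are emitted by every caller; the population
#' filter is expected to remove them downstream.
#'
#' @param truth patient truth object from [simulate_patient()].
#' @param region region id within the patient.
#' @param profiles caller profiles, default from the truth's config.
#' @param seed RNG seed.
#' @return named list of variant tables (M2/SC, plus MU when available).
#' @export
simulate_region_calls <- function(truth, region,
                                  profiles = truth$config$caller_profiles,
                                  seed = 1L) {
  cfg <- truth$config
  if (!region %in% truth$regions$region) stopf("unknown region '%s'", region)
  purity <- truth$regions$purity[truth$regions$region == region]
  callers <- names(profiles)
  if (!truth$mu_available) callers <- setdiff(callers, "MU")
  with_seed(seed, {
    v <- truth$variants
    ccf_region <- setNames(truth$tree$ccf[, region], rownames(truth$tree$ccf))
    present <- ccf_region[v$clone] > 0 & purity > 0
    v <- v[present, , drop = FALSE]
    ev <- truth$region_events[[region]]
    out <- list()
    if (nrow(v)) {
      vexp <- expected_vaf(v, ccf_region, purity, ev)
      depth <- if (cfg$noiseless) rep(cfg$mean_depth, nrow(v))
               else pmax(30L, rpois(nrow(v), cfg$mean_depth))
      alt <- if (cfg$noiseless) pmax(1L, round(depth * vexp))
             else rbinom(nrow(v), depth, vexp)
      strat <- vaf_stratum(vexp, cfg$vaf_strata)
      detected_any <- alt >= 1L
      base <- variant_table(
        chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
        type = v$type, tumor_depth = depth, tumor_alt = alt,
        normal_depth = cfg$mean_depth, normal_alt = 0L,
        quality = round(pmin(100, alt * 2.5), 1), pop_af = v$pop_af,
        pred7 = v$pred7, clinvar = v$clinvar, func_class = v$func_class,
        gene = v$gene)
      for (cl in callers) {
        sens <- profiles[[cl]]$sensitivity[strat]
        hit <- detected_any & (runif(nrow(v)) < sens)
        out[[cl]] <- base[hit, , drop = FALSE]
      }
    } else {
      for (cl in callers) out[[cl]] <- empty_variants()
    }
    # germline leak-through: called by every caller, high population AF
    gl <- truth$germline
    if (!is.null(gl) && nrow(gl)) {
      depth <- if (cfg$noiseless) rep(cfg$mean_depth, nrow(gl))
               else pmax(30L, rpois(nrow(gl), cfg$mean_depth))
      alt <- if (cfg$noiseless) round(depth * 0.5)
             else rbinom(nrow(gl), depth, 0.5)
      glv <- variant_table(
        chrom = gl$chrom, pos = gl$pos, ref = gl$ref, alt = gl$alt,
        type = "SNV", tumor_depth = depth, tumor_alt = alt,
        normal_depth = cfg$mean_depth, normal_alt = 0L,
        quality = round(pmin(100, alt * 2.5), 1), pop_af = gl$pop_af,
        pred7 = 0L, clinvar = "absent", func_class = "exonic",
        gene = ".")
      for (cl in callers)
        out[[cl]] <- rbind(out[[cl]], glv)
    }
    # caller-specific false positives over the capture space
    lens <- chrom_lengths(toy_arm_table())
    for (cl in callers) {
      nfp <- rpois(1, profiles[[cl]]$fp_rate * cfg$capture_mb)
      if (nfp > 0) {
        ch <- sample(names(lens), nfp, replace = TRUE, prob = lens)
        pos <- vapply(lens[ch], function(L) sample.int(L, 1), numeric(1))
        vaf <- runif(nfp, 0.01, 0.08)
        depth <- pmax(30L, rpois(nfp, cfg$mean_depth))
        alt <- pmax(1L, rbinom(nfp, depth, vaf))
        fp <- variant_table(
          chrom = ch, pos = pos,
          ref = sample(c("A", "C", "G", "T"), nfp, TRUE),
          alt = sample(c("A", "C", "G", "T"), nfp, TRUE),
          type = "SNV", tumor_depth = depth, tumor_alt = alt,
          normal_depth = cfg$mean_depth,
          normal_alt = rbinom(nfp, 3, 0.2),
          quality = round(runif(nfp, 0.5, 5), 1), pop_af = NA_real_,
          pred7 = 0L, clinvar = "absent",
          func_class = sample(c("exonic", "other"), nfp, TRUE), gene = ".")
        out[[cl]] <- rbind(out[[cl]], fp)
      }
      o <- out[[cl]]
      o <- o[order(o$chrom, o$pos, o$ref, o$alt), , drop = FALSE]
      o <- o[!duplicated(vkeys(o)), , drop = FALSE]
      rownames(o) <- NULL
      class(o) <- c("ipmn_variants", "data.frame")
      out[[cl]] <- o
    }
    out
  })
}

#' Simulate allelic-imbalance and log-ratio segment tables for one region
#'
#' Every region-manifest CNA event yields an AI segment (high posterior) and
#' a log-ratio segment whose mean matches the event direction (+0.4 gain,
#' -0.45 loss, ~0 for copy-neutral LOH) plus Gaussian noise; the neutral
#' background is tiled with near-zero log-ratio segments and carries no AI.
#' Values are rounded to 6 decimals so file round-trips are exact.
#'
#' @param truth patient truth object.
#' @param region region id.
#' @param seed RNG seed.
#' @return list(ai = segment table, logr = segment table).
#' @export
simulate_segments <- function(truth, region, seed = 1L) {
  cfg <- truth$config
  if (!region %in% truth$regions$region) stopf("unknown region '%s'", region)
  ev <- truth$region_events[[region]]
  lens <- chrom_lengths(toy_arm_table())
  with_seed(seed, {
    sdv <- cfg$segment_noise_sd
    ai <- if (!is.null(ev) && nrow(ev)) {
      data.frame(chrom = ev$chrom, start = ev$start, end = ev$end,
                 value = round(if (sdv == 0) rep(0.99, nrow(ev))
                               else runif(nrow(ev), 0.95, 0.999), 6),
                 stringsAsFactors = FALSE)
    } else data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric())
    logr <- list()
    for (ch in names(lens)) {
      e <- if (!is.null(ev) && nrow(ev)) ev[ev$chrom == ch, , drop = FALSE]
           else NULL
      cuts <- c(1, lens[[ch]] + 1)
      if (!is.null(e) && nrow(e)) cuts <- sort(unique(c(cuts, e$start,
                                                        e$end + 1)))
      st <- cuts[-length(cuts)]; en <- cuts[-1] - 1
      mu <- numeric(length(st))
      if (!is.null(e) && nrow(e)) {
        for (i in seq_len(nrow(e))) {
          inside <- st >= e$start[i] & en <= e$end[i]
          mu[inside] <- switch(e$direction[i], gain = cfg$logr_gain_level,
                               loss = cfg$logr_loss_level, cnloh = 0)
        }
      }
      val <- round(mu + if (sdv == 0) 0 else rnorm(length(st), 0, sdv), 6)
      logr[[ch]] <- data.frame(chrom = ch, start = st, end = en,
                               value = val, stringsAsFactors = FALSE)
    }
    logr <- do.call(rbind, logr)
    rownames(logr) <- NULL
    ai <- ai[order(ai$chrom, ai$start), , drop = FALSE]
    rownames(ai) <- NULL
    list(ai = ai, logr = logr)
  })
}

#' Default synthetic subtype templates
#'
#' One generating classifier with classes classical, basal and exocrine
#' (acinar/ADEX-like background), 30 marker genes each. The published
#' Moffitt/Collisson/Bailey marker lists are user-supplied inputs via
#' [read_template_set()]; these synthetic templates exist so the pipeline is
#' testable without vendored signatures.
#'
#' @param n_marker markers per class, default 30.
#' @export
default_templates <- function(n_marker = 30) {
  mk <- function(prefix, class) data.frame(
    gene = sprintf("%s_%02d", prefix, seq_len(n_marker)), class = class,
    stringsAsFactors = FALSE)
  template_set("synthetic", rbind(mk("CLA", "classical"),
                                  mk("BAS", "basal"),
                                  mk("EXO", "exocrine")))
}

expression_gene_universe <- function(cfg) {
  tpl <- default_templates(cfg$expression$n_marker)
  c(rownames(tpl$template),
    sprintf("BG_%03d", seq_len(cfg$expression$n_background)))
}

expression_centroid <- function(subtype, cfg) {
  ex <- cfg$expression
  genes <- expression_gene_universe(cfg)
  mu <- setNames(rep(ex$bg, length(genes)), genes)
  tpl <- default_templates(ex$n_marker)
  marker <- tpl$markers
  if (subtype %in% colnames(tpl$template)) {
    mu[marker$gene] <- ex$lo
    mu[marker$gene[marker$class == subtype]] <- ex$hi
  }                                  # nonclassifiable: flat profile
  mu
}

#' Simulate expression count replicates for one region
#'
#' Each replicate is the class centroid (log2 scale) plus Gaussian noise,
#' scaled by a log-normal replicate size factor, Poisson-sampled to counts,
#' with dropout zeros; "nonclassifiable" regions are drawn from a flat
#' non-template profile. With zero noise/dropout the replicate equals the
#' centroid counts exactly.
#'
#' @param region_subtype "classical", "basal", "exocrine" or
#'   "nonclassifiable".
#' @param templates `template_set` defining the valid classes.
#' @param cfg `sim_config`.
#' @param seed RNG seed.
#' @param n_replicates optional; default drawn from the configured range.
#' @return genes x replicates integer count matrix.
#' @export
simulate_expression <- function(region_subtype, templates = default_templates(),
                                cfg = sim_config(), seed = 1L,
                                n_replicates = NULL) {
  ex <- cfg$expression
  if (!region_subtype %in% c(colnames(templates$template), "nonclassifiable"))
    stopf("unknown template class '%s'", region_subtype)
  with_seed(seed, {
    n_rep <- n_replicates %||% sample(ex$replicates[1]:ex$replicates[2], 1)
    mu <- expression_centroid(region_subtype, cfg)
    counts <- vapply(seq_len(n_rep), function(j) {
      if (ex$noise_sd == 0 && ex$dropout == 0 && ex$sf_sd == 0)
        return(round(2^mu))
      lmu <- mu + rnorm(length(mu), 0, ex$noise_sd)
      sf <- 2^rnorm(1, 0, ex$sf_sd)
      cnt <- rpois(length(mu), sf * 2^lmu)
      cnt[runif(length(mu)) < ex$dropout] <- 0L
      cnt
    }, numeric(length(mu)))
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(names(mu), paste0("rep", seq_len(n_rep)))
    counts
  })
}

# ---- patient-level simulation -----------------------------------------

random_positions <- function(n, lens, existing = character()) {
  ch <- sample(names(lens), n, replace = TRUE, prob = lens)
  pos <- vapply(lens[ch], function(L) sample.int(L, 1), numeric(1))
  keep <- !paste(ch, pos) %in% existing
  data.frame(chrom = ch, pos = as.integer(pos),
             stringsAsFactors = FALSE)[keep, , drop = FALSE]
}

#' Simulate one patient: ground truth plus raw per-region data
#'
#' Builds the ground-truth clone tree (topology drawn from the configured
#' mix), assigns truncal hotspot mutations, per-clone private SNVs, one
#' optional truncal indel, CNA events from the menu (the high-grade lineage
#' receives more arm-scale events and preferentially the 1q gain), region
#' purities, subtype labels, and then generates caller call sets, segment
#' tables and expression replicates for every region.
#'
#' @param cfg `sim_config`.
#' @param patient_id patient label.
#' @param seed RNG seed.
#' @return list with `truth`-level fields (tree, variants, cna_events,
#'   regions, region_events, topology, cna_class, ...) and `data` (calls,
#'   segments, expression).
#' @export
simulate_patient <- function(cfg, patient_id = "P01", seed = 1L) {
  seeds <- derive_seeds(seed, 6)
  arms <- toy_arm_table()
  lens <- chrom_lengths(arms)
  truth <- with_seed(seeds[1], {
    topology <- sample(names(cfg$topology_mix), 1, prob = cfg$topology_mix)
    n_clones <- if (topology == "branched")
      sample(max(3, cfg$n_clones[1]):max(3, cfg$n_clones[2]), 1)
    else sample(cfg$n_clones[1]:cfg$n_clones[2], 1)
    tree <- simulate_clone_tree(n_clones, topology, seed = seeds[2])
    ids <- tree$nodes$clone
    # regions: always LG + HG, extras among ND/AC/PDAC
    n_regions <- sample(cfg$regions_per_patient[1]:cfg$regions_per_patient[2], 1)
    extras <- head(sample(c("ND", "AC", "PDAC")), max(0, n_regions - 2))
    regions <- c("LG", "HG", extras)
    grades <- setNames(ifelse(regions %in% c("ND", "AC"), regions,
                              regions), regions)
    # extend the CCF matrix to the extra regions
    ccf <- tree$ccf
    for (r in extras) {
      col <- setNames(rep(0, length(ids)), ids)
      if (r == "PDAC") {
        anc <- ct_path(tree, tree$hgdom)
        col[anc] <- 0.97 - 0.01 * (seq_along(anc) - 1)
        col[tree$hgdom] <- 0.85
      }
      ccf <- cbind(ccf, col)
      colnames(ccf)[ncol(ccf)] <- r
    }
    purity <- setNames(ifelse(regions %in% c("ND", "AC"), 0,
                              round(runif(length(regions),
                                          cfg$purity_range[1],
                                          cfg$purity_range[2]), 3)),
                       regions)
    # variants: truncal hotspots + per-clone private SNVs (+ truncal indel)
    panel <- driver_loci_panel()
    hot <- panel[panel$label != "hotspot", ]
    variants <- variant_table(
      chrom = hot$chrom, pos = hot$pos, ref = hot$ref, alt = hot$alt,
      type = "SNV", pred7 = pred7_mask(c("sift", "polyphen", "provean")),
      clinvar = "pathogenic", func_class = "exonic", gene = hot$gene)
    variants$clone <- ids[1]
    used <- paste(variants$chrom, variants$pos)
    for (cl in ids) {
      n <- sample(cfg$n_subclonal_snvs[1]:cfg$n_subclonal_snvs[2], 1)
      p <- random_positions(n, lens, used)
      used <- c(used, paste(p$chrom, p$pos))
      if (!nrow(p)) next
      refalt <- t(vapply(seq_len(nrow(p)), function(i)
        sample(c("A", "C", "G", "T"), 2), character(2)))
      nv <- variant_table(
        chrom = p$chrom, pos = p$pos, ref = refalt[, 1], alt = refalt[, 2],
        type = "SNV",
        pop_af = ifelse(runif(nrow(p)) < 0.1,
                        round(runif(nrow(p), 0, 0.005), 5), NA_real_),
        pred7 = vapply(seq_len(nrow(p)), function(i)
          pred7_mask(sample(PRED7, sample(0:4, 1))), integer(1)),
        clinvar = "absent",
        func_class = sample(c("exonic", "splicing", "other"), nrow(p),
                            TRUE, prob = c(0.8, 0.1, 0.1)),
        gene = ".")
      nv$clone <- cl
      variants <- rbind(variants, nv)
    }
    if (runif(1) < 0.4) {
      p <- random_positions(1, lens, used)
      if (nrow(p)) {
        iv <- variant_table(chrom = p$chrom, pos = p$pos, ref = "AT",
                            alt = "A", type = "indel",
                            pred7 = pred7_mask(c("sift", "LRT")),
                            func_class = "exonic", gene = ".")
        iv$clone <- ids[1]
        variants <- rbind(variants, iv)
        used <- c(used, paste(p$chrom, p$pos))
      }
    }
    class(variants) <- c("ipmn_variants", "data.frame")
    # germline leak-through sites (population AF > 1%)
    ngl <- rpois(1, 2)
    germline <- if (ngl > 0) {
      p <- random_positions(ngl, lens, used)
      if (nrow(p)) data.frame(
        chrom = p$chrom, pos = p$pos,
        ref = sample(c("A", "C", "G", "T"), nrow(p), TRUE),
        alt = sample(c("A", "C", "G", "T"), nrow(p), TRUE),
        pop_af = round(runif(nrow(p), 0.02, 0.2), 5),
        stringsAsFactors = FALSE)
      else NULL
    } else NULL
    # CNA assignment: HG lineage gets more arm events, preferentially 1q
    menu <- cfg$cna_menu
    broad <- menu[menu$end - menu$start + 1 >= 5e6, , drop = FALSE]
    focal <- menu[menu$end - menu$start + 1 < 5e6, , drop = FALSE]
    n_hg <- sample(1:3, 1)
    hg_events <- if (nrow(broad)) {
      w <- ifelse(broad$name == "1q_gain", 3, 1)
      broad[sample(nrow(broad), min(n_hg, nrow(broad)), prob = w), ,
            drop = FALSE]
    } else broad
    rest <- broad[!broad$name %in% hg_events$name, , drop = FALSE]
    cna <- data.frame()
    if (nrow(rest) && runif(1) < 0.5) {
      cna <- rbind(cna, cbind(rest[1, ], clone = ids[1]))
      rest <- rest[-1, , drop = FALSE]
    }
    if (nrow(rest) && runif(1) < 0.7)
      cna <- rbind(cna, cbind(rest[1, ], clone = tree$lgdom))
    if (nrow(hg_events))
      cna <- rbind(cna, cbind(hg_events, clone = tree$hgdom))
    if (nrow(focal) && runif(1) < 0.4)
      cna <- rbind(cna, cbind(focal[1, ], clone = ids[1]))
    if (!nrow(cna))
      cna <- data.frame(name = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        direction = character(), clone = character(),
                        stringsAsFactors = FALSE)
    rownames(cna) <- NULL
    # region-manifest events: clones detectable at the segment level
    region_events <- setNames(lapply(regions, function(r) {
      cls <- ids[ccf[, r] >= cfg$cna_detect_ccf]
      if (purity[r] == 0) cls <- character()
      ev <- cna[cna$clone %in% cls, , drop = FALSE]
      if (!nrow(ev)) return(empty_cna_events()[, c("chrom", "start", "end",
                                                   "direction")])
      ev <- ev[order(ev$chrom, ev$start), c("chrom", "start", "end",
                                            "direction")]
      rownames(ev) <- NULL
      ev
    }), regions)
    # subtype truth
    base <- sample(c("classical", "basal"), 1, prob = c(0.65, 0.35))
    hgsub <- if (runif(1) < cfg$expression$switch_prob)
      setdiff(c("classical", "basal"), base) else base
    subtype <- setNames(ifelse(regions %in% c("ND", "AC"), "exocrine",
                               ifelse(regions == "LG", base, hgsub)),
                        regions)
    for (r in regions) {
      if (!r %in% c("ND", "AC") &&
          runif(1) < cfg$expression$nonclassifiable_prob)
        subtype[r] <- "nonclassifiable"
    }
    mu_available <- runif(1) >= cfg$mu_missing_prob
    # per-region summary truth
    regdf <- data.frame(region = regions, grade = unname(grades),
                        purity = unname(purity),
                        subtype = unname(subtype),
                        stringsAsFactors = FALSE)
    list(patient = patient_id, topology = topology, tree = NULL,
         ccf = ccf, variants = variants, germline = germline,
         cna_events = cna, region_events = region_events,
         regions = regdf, mu_available = mu_available)
  })
  # rebuild the tree over all regions and attach real mutation keys
  ids <- rownames(truth$ccf)
  muts <- split(vkeys(truth$variants), truth$variants$clone)[ids]
  muts <- setNames(lapply(muts, function(m) m %||% character()), ids)
  tree0 <- simulate_clone_tree(
    if (truth$topology == "branched") max(3, length(ids)) else length(ids),
    truth$topology, seed = seed)
  tree <- clone_tree(tree0$nodes, truth$ccf, mutations = muts,
                     topology = truth$topology)
  tree$lgdom <- tree0$lgdom; tree$hgdom <- tree0$hgdom
  truth$tree <- tree
  # region truth summaries derived from the stated rules
  truth$regions$as <- vapply(truth$regions$region, function(r)
    aneuploidy_score(as_events(truth$region_events[[r]]), arms), integer(1))
  truth$regions$flag_1q <- vapply(truth$regions$region, function(r)
    arm_amplification_flag(as_events(truth$region_events[[r]]), arms, "1q"),
    logical(1))
  truth$regions$n_variants <- vapply(truth$regions$region, function(r) {
    if (truth$regions$purity[truth$regions$region == r] == 0) return(0L)
    sum(truth$ccf[truth$variants$clone, r] > 0)
  }, integer(1))
  truth$regions$burden <- vapply(truth$regions$region, function(r) {
    if (truth$regions$purity[truth$regions$region == r] == 0) return(0)
    present <- truth$ccf[truth$variants$clone, r] > 0
    sum(present & truth$variants$func_class %in% c("exonic", "splicing")) /
      cfg$capture_mb
  }, numeric(1))
  # truth CNA-tree classification from the stated arm-state reduction
  neo <- truth$regions$region[truth$regions$purity > 0]
  truth$cna_class <- if (length(neo) >= 2) {
    prof <- arm_state_profiles(
      lapply(setNames(nm = neo), function(r)
        as_events(truth$region_events[[r]])), arms)
    build_cna_tree(prof, lg = "LG", hg = "HG")$classification
  } else "unclassifiable"
  truth$config <- cfg
  # raw data layers
  region_seeds <- derive_seeds(seeds[3], nrow(truth$regions) * 3)
  calls <- segments <- expression <- list()
  for (i in seq_len(nrow(truth$regions))) {
    r <- truth$regions$region[i]
    calls[[r]] <- simulate_region_calls(truth, r,
                                        seed = region_seeds[3 * i - 2])
    segments[[r]] <- simulate_segments(truth, r,
                                       seed = region_seeds[3 * i - 1])
    expression[[r]] <- simulate_expression(truth$regions$subtype[i],
                                           default_templates(cfg$expression$n_marker),
                                           cfg, seed = region_seeds[3 * i])
  }
  list(truth = truth,
       data = list(mu_available = truth$mu_available, calls = calls,
                   segments = segments, expression = expression))
}

# coerce a bare (chrom,start,end,direction) truth event table to the CNA
# event layout used by the scoring functions
as_events <- function(ev) {
  if (is.null(ev) || !nrow(ev)) return(empty_cna_events())
  ev$length_mb <- (ev$end - ev$start + 1) / 1e6
  ev$focal <- ev$length_mb < 3
  ev$ai_posterior <- NA_real_
  ev$mean_log2 <- NA_real_
  ev[, c("chrom", "start", "end", "direction", "length_mb", "focal",
         "ai_posterior", "mean_log2")]
}

#' Simulate a full synthetic cohort
#'
#' @param cfg `sim_config`.
#' @return list of class `ipmn_cohort` with `config`, `patients` (each a
#'   truth + data pair), `templates`, `arms`, `genes`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  seeds <- derive_seeds(cfg$seed, cfg$n_patients)
  ids <- sprintf("P%02d", seq_len(cfg$n_patients))
  patients <- setNames(lapply(seq_len(cfg$n_patients), function(i)
    simulate_patient(cfg, ids[i], seed = seeds[i])), ids)
  structure(list(config = cfg, patients = patients,
                 templates = default_templates(cfg$expression$n_marker),
                 arms = toy_arm_table(), genes = toy_gene_table()),
            class = "ipmn_cohort")
}

#' @export
print.ipmn_cohort <- function(x, ...) {
  cat(sprintf("<ipmn_cohort: %d patients, toy genome>\n", length(x$patients)))
  invisible(x)
}
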