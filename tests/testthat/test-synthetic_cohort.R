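test_that("configuration invariants are enforced", {
  expect_error(sim_config(topology_mix = c(linear = 0.7, branched = 0.5)),
               "sum to 1")
  expect_error(sim_config(mean_depth = -1), "positive")
  expect_error(sim_config(mu_missing_prob = 1.5), "probabilities")
})

test_that("noiseless region calls equal the truth set for all callers", {
  cfg <- sim_config(n_patients = 1, noiseless = TRUE, seed = 2)
  p <- simulate_patient(cfg, "P01", seed = 2)
  r <- "HG"
  calls <- simulate_region_calls(p$truth, r, seed = 99)
  truth_keys <- with(p$truth, {
    present <- ccf[variants$clone, r] > 0
    paste(variants$chrom, variants$pos, variants$ref,
          variants$alt, sep = ":")[present]
  })
  gl_keys <- if (is.null(p$truth$germline)) character() else
    with(p$truth$germline, paste(chrom, pos, ref, alt, sep = ":"))
  for (cl in names(calls)) {
    got <- paste(calls[[cl]]$chrom, calls[[cl]]$pos, calls[[cl]]$ref,
                 calls[[cl]]$alt, sep = ":")
    expect_setequal(got, c(truth_keys, gl_keys))
  }
  expect_error(simulate_region_calls(p$truth, "nope"), "unknown region")
})

test_that("a zero-sensitivity caller emits only false positives", {
  cfg <- sim_config(n_patients = 1, seed = 4)
  cfg$caller_profiles$SC$sensitivity <- rep(0, 4)
  p <- simulate_patient(cfg, "P01", seed = 4)
  calls <- simulate_region_calls(p$truth, "HG", cfg$caller_profiles,
                                 seed = 10)
  truth_keys <- with(p$truth, paste(variants$chrom, variants$pos, sep = ":"))
  sc_keys <- paste(calls$SC$chrom, calls$SC$pos, sep = ":")
  expect_false(any(sc_keys %in% truth_keys))
})

test_that("truncal hotspot VAF sits in the binomial interval at 400x", {
  # clone fraction 1, purity 0.5, diploid: expected VAF 0.25
  cfg <- sim_config(n_patients = 1, seed = 6, purity_range = c(0.5, 0.5),
                    cna_menu = default_cna_menu()[0, ])
  p <- simulate_patient(cfg, "P01", seed = 6)
  calls <- simulate_region_calls(p$truth, "LG", seed = 123)
  kras <- calls$M2[calls$M2$gene == "KRAS", ]
  expect_equal(nrow(kras), 1)
  # binomial 99% interval at the realized depth
  lo <- qbinom(0.005, kras$tumor_depth, 0.25)
  hi <- qbinom(0.995, kras$tumor_depth, 0.25)
  expect_gte(kras$tumor_alt, lo)
  expect_lte(kras$tumor_alt, hi)
})

test_that("segment tables reflect truth events with matching signs", {
  cfg <- sim_config(n_patients = 1, noiseless = TRUE, seed = 8)
  p <- simulate_patient(cfg, "P01", seed = 8)
  for (r in p$truth$regions$region) {
    seg <- simulate_segments(p$truth, r, seed = 5)
    ev <- p$truth$region_events[[r]]
    validate_segments(seg$ai); validate_segments(seg$logr)
    expect_equal(nrow(seg$ai), nrow(ev))
    if (!nrow(ev)) {
      expect_true(all(seg$logr$value == 0))
      next
    }
    for (i in seq_len(nrow(ev))) {
      piece <- seg$logr[seg$logr$chrom == ev$chrom[i] &
                          seg$logr$start == ev$start[i], ]
      expected <- switch(ev$direction[i], gain = 0.4, loss = -0.45,
                         cnloh = 0)
      expect_equal(piece$value, expected)
    }
  }
})

test_that("cn-LOH events are recovered as cnloh by the overlay", {
  cfg <- sim_config(n_patients = 1, noiseless = TRUE, seed = 8)
  menu <- default_cna_menu()
  cfg$cna_menu <- menu[menu$direction == "cnloh", , drop = FALSE]
  found <- FALSE
  for (s in 1:10) {
    p <- simulate_patient(cfg, "P01", seed = s)
    for (r in p$truth$regions$region) {
      ev <- p$truth$region_events[[r]]
      if (!nrow(ev)) next
      seg <- simulate_segments(p$truth, r, seed = s)
      got <- overlay_cna(seg$ai, seg$logr)
      expect_equal(got$direction, ev$direction)
      expect_equal(got$start, ev$start)
      found <- TRUE
    }
  }
  expect_true(found)
})

test_that("identical config and seed give identical cohorts and files", {
  cfg <- sim_config(n_patients = 2, seed = 33)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(sim_config(n_patients = 2, seed = 33))
  expect_equal(c1$patients, c2$patients)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_cohort(c1, d1); write_cohort(c2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_equal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("write_cohort/read_cohort round-trips every simulated value", {
  cfg <- sim_config(n_patients = 2, seed = 12)
  co <- simulate_cohort(cfg)
  d <- file.path(tempdir(), "rt")
  write_cohort(co, d)
  co2 <- read_cohort(d)
  for (pid in names(co$patients)) {
    p1 <- co$patients[[pid]]; p2 <- co2$patients[[pid]]
    expect_equal(p1$data$calls, p2$data$calls)
    expect_equal(p1$data$segments, p2$data$segments)
    expect_identical(p1$data$expression, p2$data$expression)
    expect_equal(p1$truth$regions, p2$truth$regions)
    expect_equal(p1$truth$variants, p2$truth$variants)
    expect_equal(p1$truth$tree$ccf, p2$truth$tree$ccf)
    expect_equal(p1$truth$tree$nodes, p2$truth$tree$nodes)
    expect_equal(p1$truth$region_events, p2$truth$region_events)
    expect_equal(p1$truth$topology, p2$truth$topology)
    expect_equal(p1$truth$cna_class, p2$truth$cna_class)
  }
  # manifest declares one VCF per available caller per region
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  for (pid in names(man$patients)) {
    m <- man$patients[[pid]]
    n_expected <- if (isTRUE(m$mu_available)) 3L else 2L
    for (r in names(m$vcfs))
      expect_length(m$vcfs[[r]], n_expected)
  }
  unlink(d, recursive = TRUE)
})

test_that("an empty cohort writes a valid manifest", {
  co <- structure(list(config = sim_config(n_patients = 0),
                       patients = list(), templates = default_templates(),
                       arms = toy_arm_table(), genes = toy_gene_table()),
                  class = "ipmn_cohort")
  d <- file.path(tempdir(), "empty")
  write_cohort(co, d)
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(man$n_patients, 0)
  unlink(d, recursive = TRUE)
})

test_that("VCF round-trip preserves all variant fields", {
  v <- variant_table(
    chrom = c("1", "2"), pos = c(100L, 20000500L), ref = c("A", "G"),
    alt = c("T", "A"), type = c("SNV", "indel"),
    tumor_depth = c(400L, 380L), tumor_alt = c(120L, 12L),
    normal_depth = 400L, normal_alt = c(0L, 1L), quality = c(60, 2.5),
    pop_af = c(NA, 0.004), pred7 = c(0L, 21L),
    clinvar = c("absent", "pathogenic"), func_class = c("exonic", "other"),
    gene = c(".", "KRAS"))
  f <- tempfile(fileext = ".vcf")
  write_vcf(v, f)
  v2 <- read_vcf(f)
  expect_equal(as.data.frame(v2), as.data.frame(v))
  unlink(f)
})

test_that("higher caller sensitivity never lowers consensus recall", {
  recall <- function(boost, seed) {
    cfg <- sim_config(n_patients = 1, seed = seed)
    if (boost) cfg$caller_profiles <- lapply(cfg$caller_profiles, function(x)
      list(sensitivity = pmin(1, x$sensitivity + 0.3), fp_rate = x$fp_rate))
    p <- simulate_patient(cfg, "P01", seed = seed)
    calls <- p$data$calls$HG
    cons <- consensus_calls(calls, names(calls))
    truth_keys <- with(p$truth, {
      present <- ccf[variants$clone, "HG"] > 0
      paste(variants$chrom, variants$pos, sep = ":")[present]
    })
    mean(truth_keys %in% paste(cons$chrom, cons$pos, sep = ":"))
  }
  base <- vapply(1:20, function(s) recall(FALSE, s), numeric(1))
  high <- vapply(1:20, function(s) recall(TRUE, s), numeric(1))
  expect_gte(mean(high), mean(base))
  expect_gte(mean(high), 0.95)
})
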