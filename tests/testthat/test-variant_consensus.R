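test_that("consensus keeps two-or-more-caller calls with three callers", {
  A <- vset(100); B <- vset(200); C <- vset(300)
  sets <- list(M2 = rbind(A, B), SC = rbind(B, C), MU = B)
  out <- consensus_calls(sets, c("M2", "SC", "MU"))
  expect_equal(out$pos, 200L)
  expect_equal(out$callers, "M2,SC,MU")
})

test_that("consensus falls back to the M2/SC union when MuSE is absent", {
  A <- vset(100); B <- vset(200); C <- vset(300)
  out <- consensus_calls(list(M2 = rbind(A, B), SC = rbind(B, C)),
                         c("M2", "SC"))
  expect_setequal(out$pos, c(100L, 200L, 300L))
  expect_equal(out$callers[out$pos == 100], "M2")
  expect_equal(out$callers[out$pos == 200], "M2,SC")
})

test_that("consensus edge cases: empty sets, too few callers", {
  expect_equal(nrow(consensus_calls(list(M2 = vset(integer()),
                                         SC = vset(integer()),
                                         MU = vset(integer())))), 0)
  expect_error(consensus_calls(list(M2 = vset(100))), "insufficient callers")
})

test_that("consensus equals a brute-force voting oracle on enumerated sets", {
  # every assignment of 4 variants to caller subsets (2^3 options each)
  pos <- c(10L, 20L, 30L, 40L)
  subsets <- expand.grid(v1 = 0:7, v2 = 0:7)  # exhaustive for 2 variants,
  combos <- expand.grid(v1 = 0:7, v2 = 0:7, v3 = 0:7, v4 = 0:7)
  set.seed(1)
  combos <- combos[sample(nrow(combos), 400), ]  # plus sampled 4-variant maps
  check <- function(assign_mat) {
    for (k in seq_len(nrow(assign_mat))) {
      bits <- as.integer(assign_mat[k, ])
      sets <- lapply(1:3, function(ci)
        vset(pos[seq_along(bits)][bitwAnd(bitwShiftR(bits, ci - 1L), 1L) == 1L]))
      names(sets) <- c("M2", "SC", "MU")
      out <- consensus_calls(sets, c("M2", "SC", "MU"))
      votes <- colSums(rbind(bitwAnd(bits, 1L) > 0,
                             bitwAnd(bits, 2L) > 0,
                             bitwAnd(bits, 4L) > 0))
      expected <- sort(pos[seq_along(bits)][votes >= 2])
      expect_identical(sort(out$pos), as.integer(expected))
      # output is always a subset of the union of caller sets
      expect_true(all(out$pos %in% pos[seq_along(bits)][votes >= 1]))
    }
  }
  check(as.matrix(subsets))
  check(as.matrix(combos))
})

test_that("population filter removes >1% AF, keeps missing AF, idempotent", {
  v <- vset(c(1L, 2L, 3L), pop_af = c(0.02, 0.005, NA))
  out <- population_filter(v)
  expect_setequal(out$pos, c(2L, 3L))
  expect_equal(population_filter(out), out)
})

test_that("targeted rescue requires panel site and relaxed quality", {
  panel <- list(driver_loci = data.frame(chrom = "2", pos = 20000500L),
                shared_sites = data.frame(chrom = "1", pos = 555L),
                relaxed_threshold = 1.5)
  kras <- mkvar("2", 20000500L, "G", "A", quality = 2, tumor_depth = 400L,
                tumor_alt = 12L)
  shared <- mkvar("1", 555L, quality = 3, tumor_depth = 400L,
                  tumor_alt = 8L)
  nonpanel <- mkvar("3", 999L, quality = 50, tumor_depth = 400L,
                    tumor_alt = 90L)
  lowq <- mkvar("2", 20000500L, "G", "A", quality = 1.0,
                tumor_depth = 400L, tumor_alt = 4L)
  out <- rescue_targeted(rbind(kras, shared, nonpanel), panel)
  expect_setequal(out$pos, c(20000500L, 555L))
  expect_true(all(out$rescued))
  expect_equal(nrow(rescue_targeted(lowq, panel)), 0)
  # disjointness from consensus is enforced at the site level
  out2 <- rescue_targeted(rbind(kras, shared), panel, consensus = kras)
  expect_equal(out2$pos, 555L)
})

test_that("deleteriousness needs exonic/splicing and 2 predictors or ClinVar", {
  two <- mkvar(pred7 = pred7_mask(c("sift", "provean")))
  one_clinvar <- mkvar(pred7 = pred7_mask("sift"), clinvar = "pathogenic")
  gated <- mkvar(func_class = "other", pred7 = 127L)  # all 7 predictors
  one <- mkvar(pred7 = pred7_mask("fathmm"))
  expect_true(classify_deleterious(two))
  expect_true(classify_deleterious(one_clinvar))
  expect_false(classify_deleterious(gated))
  expect_false(classify_deleterious(one))
})

test_that("indel depth filter bounds are inclusive", {
  v <- rbind(
    mkvar(pos = 1L, type = "indel", tumor_depth = 400L, tumor_alt = 5L,
          normal_alt = 0L),
    mkvar(pos = 2L, type = "indel", tumor_depth = 400L, tumor_alt = 5L,
          normal_alt = 1L),
    mkvar(pos = 3L, type = "indel", tumor_depth = 400L, tumor_alt = 4L,
          normal_alt = 0L),
    mkvar(pos = 4L, type = "SNV", tumor_depth = 400L, tumor_alt = 1L,
          normal_alt = 2L))
  out <- filter_indels(v)
  expect_setequal(out$pos, c(1L, 4L))   # SNVs pass through untouched
})

test_that("mutation burden is nonsynonymous count over captured Mb", {
  v <- vset(seq_len(45))
  expect_equal(mutation_burden(v, 50), 0.9)
  expect_equal(mutation_burden(vset(integer()), 50), 0)
  expect_error(mutation_burden(v, 0), "positive")
  # rescued calls excluded by default
  v$rescued[1:5] <- TRUE
  expect_equal(mutation_burden(v, 50), 0.8)
  expect_equal(mutation_burden(v, 50, include_rescued = TRUE), 0.9)
})

test_that("filters commute on random variant sets", {
  set.seed(42)
  for (i in 1:20) {
    n <- 30
    v <- variant_table(
      chrom = sample(c("1", "2"), n, TRUE), pos = sample(1e6, n),
      ref = "A", alt = "T",
      type = sample(c("SNV", "indel"), n, TRUE),
      tumor_depth = 400L, tumor_alt = sample(0:30, n, TRUE),
      normal_alt = sample(0:2, n, TRUE),
      pop_af = ifelse(runif(n) < 0.4, runif(n, 0, 0.05), NA))
    a <- filter_indels(population_filter(v))
    b <- population_filter(filter_indels(v))
    expect_equal(a[order(a$pos), ], b[order(b$pos), ], ignore_attr = TRUE)
  }
})

test_that("noiseless consensus + rescue has perfect recall and precision", {
  cfg <- sim_config(n_patients = 1, noiseless = TRUE, seed = 3)
  p <- simulate_patient(cfg, "P01", seed = 3)
  for (r in p$truth$regions$region[p$truth$regions$purity > 0]) {
    calls <- p$data$calls[[r]]
    cons <- population_filter(consensus_calls(calls, names(calls)))
    truth_keys <- with(p$truth, {
      present <- ccf[variants$clone, r] > 0
      paste(variants$chrom, variants$pos, variants$ref,
            variants$alt, sep = ":")[present]
    })
    got <- paste(cons$chrom, cons$pos, cons$ref, cons$alt, sep = ":")
    expect_setequal(got, truth_keys)
  }
})
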