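toy_templates <- function() {
  template_set("toy", data.frame(
    gene = c(paste0("A", 1:12), paste0("B", 1:12)),
    class = rep(c("classical", "basal"), each = 12)))
}

test_that("normalization is scale-invariant and recovers size factors", {
  set.seed(3)
  base <- rpois(50, 100) + 1
  counts <- cbind(s1 = base, s2 = 2L * base)
  rownames(counts) <- paste0("g", 1:50)
  norm <- normalize_counts(counts)
  expect_equal(norm[, "s1"], norm[, "s2"])
  sf <- attr(norm, "size_factors")
  expect_equal(unname(sf["s2"] / sf["s1"]), 2)
  # known size factors {1, 2, 4} recovered within 5%
  mu <- rpois(200, 200) + 5
  m <- sapply(c(1, 2, 4), function(f) rpois(200, f * mu))
  rownames(m) <- paste0("g", 1:200); colnames(m) <- c("a", "b", "c")
  sf2 <- attr(normalize_counts(m), "size_factors")
  rel <- sf2 / sf2[1]
  expect_true(all(abs(rel - c(1, 2, 4)) / c(1, 2, 4) < 0.05))
  # all-zero gene stays zero; all-zero sample is dropped with a warning
  m2 <- cbind(a = c(0L, 5L, 7L), b = c(0L, 6L, 8L))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(normalize_counts(m2)["g1", ]), c(0, 0))
  m3 <- cbind(m2, z = c(0L, 0L, 0L))
  expect_warning(n3 <- normalize_counts(m3), "all-zero")
  expect_equal(colnames(n3), c("a", "b"))
})

test_that("size factors match the reference median-of-ratios implementation", {
  set.seed(8)
  m <- matrix(rpois(300, 80) + 1L, 100, 3,
              dimnames = list(paste0("g", 1:100), c("a", "b", "c")))
  m[, 2] <- m[, 2] * 3L
  ours <- attr(normalize_counts(m), "size_factors")
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("a centroid profile gets its class at the permutation floor", {
  tpl <- toy_templates()
  profile <- setNames(c(rep(10, 12), rep(2, 12)), rownames(tpl$template))
  out <- ntp_classify(profile, tpl, n_perm = 200, seed = 1, min_genes = 10)
  expect_equal(out$label, "classical")
  expect_equal(out$p, 1 / 201)
  # affine rescaling leaves the call unchanged (correlation distance)
  out2 <- ntp_classify(3 * profile + 7, tpl, n_perm = 200, seed = 1,
                       min_genes = 10)
  expect_equal(out2$label, out$label)
  expect_equal(out2$distance, out$distance)
})

test_that("low gene overlap yields nonclassifiable with a reason", {
  tpl <- toy_templates()
  profile <- setNames(rnorm(5), rownames(tpl$template)[1:5])
  out <- ntp_classify(profile, tpl, n_perm = 100, min_genes = 20)
  expect_equal(out$label, "nonclassifiable")
  expect_equal(out$reason, "low gene overlap")
})

test_that("permutation p matches the exhaustive oracle on a 6-gene toy", {
  tpl <- template_set("six", data.frame(gene = paste0("g", 1:6),
                                        class = rep(c("x", "y"), each = 3)))
  profile <- setNames(c(5, 4.5, 4.8, 1.2, 1.0, 1.4), paste0("g", 1:6))
  tm <- tpl$template[names(profile), ]
  d <- 1 - drop(cor(profile, tm))
  best <- which.min(d)
  perms <- gtools_permutations <- NULL
  # enumerate all 720 permutations by recursion
  allperm <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in allperm(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  ds <- vapply(allperm(unname(profile)), function(p)
    1 - max(cor(p, tm)), numeric(1))   # nearest-template null

  p_exhaustive <- mean(ds <= d[best])
  out <- ntp_classify(profile, tpl, n_perm = 2000, seed = 42, min_genes = 5)
  # Monte-Carlo standard error at n_perm = 2000
  se <- sqrt(p_exhaustive * (1 - p_exhaustive) / 2000)
  expect_lt(abs(out$p - p_exhaustive), 4 * se + 1 / 2000)
})

test_that("gene-shuffled profiles are mostly nonclassifiable under FDR", {
  tpl <- toy_templates()
  set.seed(10)
  hits <- vapply(1:100, function(i) {
    profile <- setNames(sample(c(rep(8, 12), rep(2, 12))),
                        rownames(tpl$template))
    out <- ntp_classify(profile, tpl, n_perm = 200, seed = i, min_genes = 10)
    out$p > 0.05          # single profile: fdr == p
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("noisy centroids classify accurately over repeated draws", {
  tpl <- toy_templates()
  set.seed(5)
  acc <- vapply(1:200, function(i) {
    truth <- sample(c("classical", "basal"), 1)
    mu <- ifelse(tpl$markers$class == truth, 6, 2)
    profile <- setNames(mu + rnorm(24, 0, 2), tpl$markers$gene)
    ntp_classify(profile, tpl, n_perm = 100, seed = i,
                 min_genes = 10)$best_class == truth
  }, logical(1))
  expect_gte(mean(acc), 0.8)
})

test_that("replicate aggregation: majority, ties, order invariance", {
  calls <- data.frame(label = c("classical", "classical", "basal"),
                      classifiable = TRUE)
  expect_equal(aggregate_replicates(calls), "classical")
  expect_equal(aggregate_replicates(calls[sample(3), ]), "classical")
  tie <- data.frame(label = c("classical", "basal"), classifiable = TRUE)
  expect_equal(aggregate_replicates(tie), "nonclassifiable")
  none <- data.frame(label = c("nonclassifiable", "nonclassifiable"),
                     classifiable = FALSE)
  expect_equal(aggregate_replicates(none), "nonclassifiable")
})

test_that("class switches are reported for classifiable LG/HG pairs", {
  labs <- data.frame(
    patient = c("P1", "P1", "P2", "P2", "P3", "P3"),
    region = c("LG", "HG", "LG", "HG", "LG", "HG"),
    grade = rep(c("LG", "HG"), 3),
    label = c("classical", "basal", "classical", "classical",
              "nonclassifiable", "basal"))
  sw <- class_switches(labs)
  expect_equal(sw$patient, "P1")
  expect_equal(sw$hg_label, "basal")
})

test_that("subtype-by-1q table matches the printed TCGA layout", {
  labels <- c(rep("classical", 34), rep("basal", 18), "exocrine")
  flags <- c(rep(TRUE, 18), rep(FALSE, 16), rep(TRUE, 3), rep(FALSE, 15),
             TRUE)
  names(labels) <- names(flags) <- paste0("s", seq_along(labels))
  tab <- subtype_cna_table(labels, flags)
  expect_equal(unname(tab[c("a", "b", "c", "d")]), c(18L, 16L, 3L, 15L))
  expect_equal(attr(tab, "excluded"), "s53")
  empty <- subtype_cna_table(setNames(character(), character()),
                             setNames(logical(), character()))
  expect_equal(unname(empty[1:4]), c(0L, 0L, 0L, 0L))
  one <- subtype_cna_table(c(r = "classical"), c(r = TRUE))
  expect_equal(unname(one[1:4]), c(1L, 0L, 0L, 0L))
})

test_that("simulated expression recovers the generating class", {
  cfg <- sim_config(seed = 1)
  tpl <- default_templates()
  # noiseless replicate equals the centroid counts exactly
  cfg0 <- sim_config(noiseless = TRUE)
  m0 <- simulate_expression("classical", tpl, cfg0, seed = 1,
                            n_replicates = 2)
  centroid <- round(2^ipmnevo:::expression_centroid("classical", cfg0))
  expect_equal(unname(m0[, 1]), unname(centroid))
  expect_equal(m0[, 1], m0[, 2])
  # default noise: classified correctly with FDR < 0.05 in >= 95% of seeds
  ok <- vapply(1:100, function(i) {
    m <- simulate_expression("classical", tpl, cfg, seed = i,
                             n_replicates = 1)
    norm <- normalize_counts(m)
    out <- ntp_classify(norm[, 1], tpl, n_perm = 200, seed = i)
    isTRUE(out$label == "classical" && out$fdr < 0.05)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  # flat non-template source: nonclassifiable in >= 90% of seeds
  nc <- vapply(1:100, function(i) {
    m <- simulate_expression("nonclassifiable", tpl, cfg, seed = i + 500,
                             n_replicates = 1)
    norm <- normalize_counts(m)
    ntp_classify(norm[, 1], tpl, n_perm = 200, seed = i)$label ==
      "nonclassifiable"
  }, logical(1))
  expect_gte(mean(nc), 0.9)
  expect_error(simulate_expression("squamous", tpl, cfg, 1),
               "unknown template class")
})
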