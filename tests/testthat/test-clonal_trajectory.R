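test_that("identical VAF profiles collapse to one cluster", {
  vaf <- rbind(LG = c(a = 0.40, b = 0.40, c = 0.05),
               HG = c(a = 0.42, b = 0.41, c = 0.30))
  cl <- cluster_variants(vaf, c(LG = 1, HG = 1))
  expect_equal(nrow(cl$ccf), 2)
  expect_setequal(cl$members$C1, c("a", "b"))
  expect_error(cluster_variants(vaf[1, , drop = FALSE], c(LG = 1)),
               "cannot cluster")
})

test_that("a 2% precursor clone counts as present in both regions", {
  vaf <- rbind(LG = c(a = 0.5, b = 0.01), HG = c(a = 0.5, b = 0.45))
  cl <- cluster_variants(vaf, c(LG = 1, HG = 1))
  b_cl <- names(which(vapply(cl$members, function(m) "b" %in% m,
                             logical(1))))
  expect_true(cl$presence[b_cl, "LG"])
  expect_true(cl$presence[b_cl, "HG"])
})

test_that("containment tree: nested CCFs give a chain, exclusivity branches", {
  chain <- list(ccf = rbind(C1 = c(LG = 1, HG = 1.0),
                            C2 = c(LG = 0.9, HG = 0.5),
                            C3 = c(LG = 0.05, HG = 0.2)),
                members = list(C1 = "m1", C2 = "m2", C3 = "m3"),
                presence_threshold = 0.01)
  chain$presence <- chain$ccf >= 0.01
  tr <- build_snv_tree(chain)
  expect_equal(tr$nodes$parent, c(NA, "C1", "C2"))
  expect_false(tr$unresolved)

  branchy <- list(ccf = rbind(C1 = c(LG = 1, HG = 1),
                              C2 = c(LG = 0.8, HG = 0.0),
                              C3 = c(LG = 0.0, HG = 0.7)),
                  members = list(C1 = "m1", C2 = "m2", C3 = "m3"),
                  presence_threshold = 0.01)
  branchy$presence <- branchy$ccf >= 0.01
  tr2 <- build_snv_tree(branchy)
  expect_equal(tr2$nodes$parent, c(NA, "C1", "C1"))
})

test_that("sum-rule: overshoot allowed only under a saturated parent", {
  # C2 and C3 are mutually exclusive in regions B/C (forced siblings) and
  # together overshoot the parent in region A
  sib_ccf <- function(parent_a) rbind(
    C1 = c(A = parent_a, B = 0.9, C = 0.9),
    C2 = c(A = 0.6, B = 0.5, C = 0.0),
    C3 = c(A = 0.6, B = 0.0, C = 0.5))
  mk <- function(ccf) {
    cl <- list(ccf = ccf, members = list(C1 = "m1", C2 = "m2", C3 = "m3"),
               presence_threshold = 0.01)
    cl$presence <- cl$ccf >= 0.01
    cl
  }
  # saturated parent (CCF 1.0): 0.6 + 0.6 overshoot tolerated
  tr_ok <- build_snv_tree(mk(sib_ccf(1.0)))
  expect_equal(sort(tr_ok$nodes$parent[tr_ok$nodes$clone %in% c("C2", "C3")]),
               c("C1", "C1"))
  expect_false(tr_ok$unresolved)
  # unsaturated parent (CCF 0.8): pigeonhole violation
  expect_true(build_snv_tree(mk(sib_ccf(0.8)))$unresolved)
})

test_that("no truncal cluster yields an unclassifiable tree", {
  cl <- list(ccf = rbind(C1 = c(LG = 0.9, HG = 0.0),
                         C2 = c(LG = 0.0, HG = 0.9)),
             members = list(C1 = "m1", C2 = "m2"),
             presence_threshold = 0.01)
  cl$presence <- cl$ccf >= 0.01
  tr <- build_snv_tree(cl)
  expect_equal(classify_topology(tr, c(LG = "LG", HG = "HG")),
               "unclassifiable")
})

test_that("topology classifier matches the stated definitions", {
  grades <- c(LG = "LG", HG = "HG")
  # chain root -> C1 (LG dom) -> C2 (HG dom)
  lin <- clone_tree(data.frame(clone = c("C1", "C2"),
                               parent = c(NA, "C1")),
                    rbind(C1 = c(LG = 1, HG = 1),
                          C2 = c(LG = 0.02, HG = 0.7)))
  expect_equal(classify_topology(lin, grades), "linear")
  # trunk with LG-dominant and HG-dominant sibling branches
  br <- clone_tree(data.frame(clone = c("C1", "C2", "C3"),
                              parent = c(NA, "C1", "C1")),
                   rbind(C1 = c(LG = 1, HG = 1),
                         C2 = c(LG = 0.8, HG = 0.0),
                         C3 = c(LG = 0.0, HG = 0.7)))
  expect_equal(classify_topology(br, grades), "branched")
  # missing HG region
  expect_equal(classify_topology(lin, c(LG = "LG", HG = "PDAC")),
               "unclassifiable")
})

test_that("generated truth trees classify as requested (noiseless law)", {
  for (n in 2:5) {
    tr <- simulate_clone_tree(n, "linear", seed = n)
    expect_equal(classify_topology(tr, c(LG = "LG", HG = "HG")), "linear")
  }
  for (n in 3:5) {
    tr <- simulate_clone_tree(n, "branched", seed = n)
    expect_equal(classify_topology(tr, c(LG = "LG", HG = "HG")), "branched")
  }
  expect_error(simulate_clone_tree(1, "linear"), "degenerate")
  # smallest cases have the documented shapes
  t2 <- simulate_clone_tree(2, "linear", seed = 1)
  expect_equal(t2$dominant[["LG"]], "C1")
  expect_equal(t2$dominant[["HG"]], "C2")
  t3 <- simulate_clone_tree(3, "branched", seed = 1)
  expect_equal(t3$nodes$parent, c(NA, "C1", "C1"))
})

test_that("mutation sets are nested along every root-to-leaf path", {
  tr <- simulate_clone_tree(5, "branched", seed = 2)
  for (cl in tr$nodes$clone) {
    par <- tr$nodes$parent[tr$nodes$clone == cl]
    if (is.na(par)) next
    par_set <- ipmnevo:::ct_mutation_set(tr, par)
    child_set <- ipmnevo:::ct_mutation_set(tr, cl)
    expect_true(all(par_set %in% child_set))
    expect_gt(length(child_set), length(par_set))
  }
})

test_that("minor-clone expansion is detected across grade order", {
  tr <- clone_tree(data.frame(clone = c("C1", "C2"), parent = c(NA, "C1")),
                   rbind(C1 = c(HG = 1, PDAC = 1),
                         C2 = c(HG = 0.03, PDAC = 0.85)))
  out <- detect_minor_expansion(tr, c(HG = "HG", PDAC = "PDAC"))
  expect_equal(out$clone, "C2")
  expect_equal(out$region_high, "PDAC")
  # 2% LG -> 60% HG
  tr2 <- clone_tree(data.frame(clone = c("C1", "C2"), parent = c(NA, "C1")),
                    rbind(C1 = c(LG = 1, HG = 1),
                          C2 = c(LG = 0.02, HG = 0.6)))
  expect_equal(nrow(detect_minor_expansion(tr2, c(LG = "LG", HG = "HG"))), 1)
  # a stable 40% clone is not reported
  tr3 <- clone_tree(data.frame(clone = c("C1", "C2"), parent = c(NA, "C1")),
                    rbind(C1 = c(LG = 1, HG = 1),
                          C2 = c(LG = 0.4, HG = 0.4)))
  expect_equal(nrow(detect_minor_expansion(tr3, c(LG = "LG", HG = "HG"))), 0)
})

test_that("Newick export reflects the tree topology", {
  br <- clone_tree(data.frame(clone = c("C1", "C2", "C3"),
                              parent = c(NA, "C1", "C1")),
                   rbind(C1 = c(LG = 1, HG = 1),
                         C2 = c(LG = 0.8, HG = 0.0),
                         C3 = c(LG = 0.0, HG = 0.7)))
  nw <- tree_newick(br)
  expect_equal(nw, "(C2,C3)C1;")
  # parseable by the standard phylogenetics reader
  ph <- ape::read.tree(text = nw)
  expect_equal(ape::Ntip(ph), 2)
})

test_that("trajectory agreement excludes unclassifiable pairs", {
  snv <- c(P1 = "linear", P2 = "branched", P3 = "unclassifiable")
  cna <- c(P1 = "linear", P2 = "linear", P3 = "branched")
  out <- compare_trajectories(snv, cna)
  expect_equal(out$agreement, 0.5)
  expect_equal(out$n_compared, 2)
  out2 <- compare_trajectories(c(P1 = "linear"), c(P1 = "linear"))
  expect_equal(out2$agreement, 1)
})

test_that("region input order never changes the classification", {
  cfg <- sim_config(n_patients = 1, seed = 5)
  p <- simulate_patient(cfg, "P01", seed = 5)
  co <- simulate_cohort(sim_config(n_patients = 1, seed = 5))
  base <- analyze_patient(co$patients$P01, co, pipeline_config(n_perm = 100),
                          1)
  perm <- co
  pt <- perm$patients$P01
  ord <- rev(names(pt$data$calls))
  pt$data$calls <- pt$data$calls[ord]
  pt$data$segments <- pt$data$segments[ord]
  pt$data$expression <- pt$data$expression[ord]
  pt$truth$regions <- pt$truth$regions[rev(seq_len(nrow(pt$truth$regions))), ]
  perm$patients$P01 <- pt
  out <- analyze_patient(perm$patients$P01, perm,
                         pipeline_config(n_perm = 100), 1)
  expect_equal(out$snv_class, base$snv_class)
  expect_equal(out$cna_class, base$cna_class)
})
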