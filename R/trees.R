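#' Construct a clone tree
#'
#' A rooted tree of clones with per-clone mutation sets and per-region
#' cancer-cell fractions (CCF). Clone fractions (the population private to a
#' clone) are derived as CCF minus the summed CCF of its children, clamped at
#' zero. Mutation sets must be nested along every root-to-leaf path: a
#' clone's full mutation set is the union of `mutations` over its ancestors
#' and itself.
#'
#' @param nodes data.frame with columns `clone`, `parent` (NA for the root).
#' @param ccf clones x regions CCF matrix (rownames = clone ids).
#' @param mutations named list clone -> character vector of private mutation
#'   keys.
#' @param topology optional topology label.
#' @param presence_threshold CCF at or above which a clone counts as present
#'   in a region, default 0.01.
#' @param unresolved logical, TRUE when containment/sum-rule violations were
#'   detected during construction.
#' @export
clone_tree <- function(nodes, ccf, mutations = NULL, topology = NA_character_,
                       presence_threshold = 0.01, unresolved = FALSE) {
  stopifnot(all(c("clone", "parent") %in% names(nodes)))
  if (sum(is.na(nodes$parent)) != 1) stopf("clone tree needs a single root")
  if (!all(rownames(ccf) == nodes$clone))
    stopf("ccf rownames must match nodes$clone")
  if (any(ccf < -1e-9 | ccf > 1 + 1e-9)) stopf("CCFs must lie in [0, 1]")
  mutations <- mutations %||% setNames(vector("list", nrow(nodes)),
                                       nodes$clone)
  tr <- structure(list(nodes = nodes, ccf = ccf, mutations = mutations,
                       topology = topology,
                       presence_threshold = presence_threshold,
                       unresolved = unresolved),
                  class = "clone_tree")
  tr$fractions <- clone_fractions(tr)
  tr$dominant <- dominant_clones(tr)
  tr
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("<clone_tree: %d clones, %d regions, topology=%s%s>\n",
              nrow(x$nodes), ncol(x$ccf), x$topology,
              if (x$unresolved) ", unresolved" else ""))
  invisible(x)
}

ct_root <- function(tree) tree$nodes$clone[is.na(tree$nodes$parent)]

ct_children <- function(tree, clone) {
  tree$nodes$clone[!is.na(tree$nodes$parent) & tree$nodes$parent == clone]
}

# path from the root to `clone`, inclusive
ct_path <- function(tree, clone) {
  path <- clone
  repeat {
    p <- tree$nodes$parent[tree$nodes$clone == path[1]]
    if (is.na(p)) break
    path <- c(p, path)
  }
  path
}

# full (accumulated) mutation set of a clone
ct_mutation_set <- function(tree, clone) {
  unique(unlist(tree$mutations[ct_path(tree, clone)], use.names = FALSE))
}

clone_fractions <- function(tree) {
  fr <- tree$ccf
  for (cl in tree$nodes$clone) {
    kids <- ct_children(tree, cl)
    if (length(kids))
      fr[cl, ] <- pmax(0, tree$ccf[cl, ] -
                         colSums(tree$ccf[kids, , drop = FALSE]))
  }
  fr
}

# dominant clone per region: largest fraction, then largest accumulated
# mutation set, then lowest clone id
dominant_clones <- function(tree) {
  fr <- tree$fractions
  musize <- vapply(tree$nodes$clone,
                   function(cl) length(ct_mutation_set(tree, cl)), numeric(1))
  out <- setNames(rep(NA_character_, ncol(fr)), colnames(fr))
  for (r in colnames(fr)) {
    f <- fr[, r]
    if (all(f <= 0)) next
    ord <- order(-f, -musize, tree$nodes$clone)
    out[r] <- tree$nodes$clone[ord[1]]
  }
  out
}

#' Newick export of a clone tree topology
#'
#' @param tree `clone_tree`.
#' @return Newick string (clone ids as labels).
#' @export
tree_newick <- function(tree) {
  rec <- function(cl) {
    kids <- ct_children(tree, cl)
    if (!length(kids)) return(cl)
    sprintf("(%s)%s", paste(vapply(kids, rec, character(1)),
                            collapse = ","), cl)
  }
  paste0(rec(ct_root(tree)), ";")
}

#' Cluster variants by cancer-cell-fraction profile
#'
#' Groups variants whose allelic-fraction profiles agree across regions and
#' reports each cluster's CCF profile under the diploid approximation
#' (CCF = min(1, 2 VAF / purity)). Clustering distances are computed on the
#' variance-stabilized arcsine-sqrt VAF scale, where binomial sampling noise
#' has near-constant standard deviation 1/(2 sqrt(depth)) irrespective of
#' VAF and purity - on the raw CCF scale the noise grows as 1/purity and
#' low-purity regions shatter true clones into spurious clusters.
#' Complete-linkage hierarchical clustering is cut at `merge_height`
#' (default 0.2, about eight noise standard deviations at 400x). Clusters
#' are ordered by mean CCF (C1 = highest). A cluster is present in a region
#' when its mean CCF there reaches `presence_threshold` (default 0.01, so
#' that 2-3% precursor clones count as present).
#'
#' @param vaf_matrix regions x variants VAF matrix (0 where not detected).
#' @param purity named per-region neoplastic purity.
#' @param presence_threshold CCF presence cutoff.
#' @param merge_height clustering cut height on the arcsine scale,
#'   default 0.2.
#' @return list with `ccf` (clusters x regions), `members` (named list of
#'   variant keys), `presence` (logical matrix), `presence_threshold`.
#' @export
cluster_variants <- function(vaf_matrix, purity, presence_threshold = 0.01,
                             merge_height = 0.2) {
  if (nrow(vaf_matrix) < 2) stopf("cannot cluster: need >= 2 regions")
  if (is.null(names(purity))) names(purity) <- rownames(vaf_matrix)
  pur <- purity[rownames(vaf_matrix)]
  ccf_v <- pmin(2 * sweep(vaf_matrix, 1, pur, "/"), 1)  # keep dim attrs
  ccf_v[!is.finite(ccf_v)] <- 0
  x <- t(ccf_v)                              # variants x regions
  z <- t(asin(sqrt(pmin(pmax(vaf_matrix, 0), 1))))
  grp <- if (nrow(x) == 1) 1L else
    cutree(hclust(dist(z), method = "complete"), h = merge_height)
  ids <- sort(unique(grp))
  ccf <- do.call(rbind, lapply(ids, function(g)
    colMeans(x[grp == g, , drop = FALSE])))
  members <- lapply(ids, function(g) rownames(x)[grp == g])
  ord <- order(-rowMeans(ccf))
  ccf <- ccf[ord, , drop = FALSE]
  members <- members[ord]
  rownames(ccf) <- names(members) <- paste0("C", seq_along(ord))
  list(ccf = ccf, members = members,
       presence = ccf >= presence_threshold,
       presence_threshold = presence_threshold)
}

#' Build a clone tree from variant clusters by CCF containment
#'
#' The truncal cluster (present in every region that harbours any cluster,
#' with the highest mean CCF) becomes the root. Each remaining cluster, in
#' decreasing mean-CCF order, is attached to the already-placed cluster with
#' the smallest mean CCF whose CCF dominates it in every region (within
#' `tol`). Clusters with no admissible parent are attached to the root and
#' the tree is marked unresolved, as are pigeonhole violations of the sum
#' rule (children CCFs summing above the parent's in some region).
#'
#' @param clusters output of [cluster_variants()].
#' @param tol CCF tolerance for containment and sum-rule checks, default 0.1.
#' @return `clone_tree` (topology "unclassifiable" when no truncal cluster
#'   exists).
#' @export
build_snv_tree <- function(clusters, tol = 0.1) {
  ccf <- clusters$ccf
  thr <- clusters$presence_threshold
  k <- nrow(ccf)
  involved <- colSums(ccf >= thr) > 0       # regions with any presence
  truncal <- which(apply(ccf[, involved, drop = FALSE] >= thr, 1, all))
  if (!length(truncal)) {
    tr <- clone_tree(data.frame(clone = rownames(ccf),
                                parent = c(NA, rep(rownames(ccf)[1], k - 1))),
                     ccf, mutations = clusters$members,
                     topology = "unclassifiable", presence_threshold = thr,
                     unresolved = TRUE)
    return(tr)
  }
  root <- rownames(ccf)[truncal[1]]
  ord <- order(-rowMeans(ccf))
  placed <- root
  parent <- setNames(rep(NA_character_, k), rownames(ccf))
  unresolved <- FALSE
  for (i in ord) {
    cl <- rownames(ccf)[i]
    if (cl == root) next
    cand <- placed[vapply(placed, function(p)
      all(ccf[p, ] >= ccf[cl, ] - tol), logical(1))]
    if (!length(cand)) {
      parent[cl] <- root
      unresolved <- TRUE
    } else {
      parent[cl] <- cand[order(rowMeans(ccf)[cand],
                               decreasing = FALSE)][1]
    }
    placed <- c(placed, cl)
  }
  nodes <- data.frame(clone = rownames(ccf), parent = parent[rownames(ccf)],
                      stringsAsFactors = FALSE)
  # sum rule: children CCFs must not exceed the parent's, per region
  for (p in rownames(ccf)) {
    kids <- nodes$clone[!is.na(nodes$parent) & nodes$parent == p]
    if (length(kids) < 2) next
    tot <- colSums(ccf[kids, , drop = FALSE])
    # a saturated parent (CCF ~ 1) may legitimately carry children summing
    # above it (spatial mixing + CCF clamping); below saturation it may not
    if (any(tot > ccf[p, ] + tol & ccf[p, ] < 1 - tol)) unresolved <- TRUE
  }
  clone_tree(nodes, ccf, mutations = clusters$members,
             presence_threshold = thr, unresolved = unresolved)
}

#' Classify the evolutionary topology of a clone tree
#'
#' Linear evolution: every clone on the path from the root to the dominant
#' HG clone is present in the LG region (CCF at or above the presence
#' threshold) or is the dominant HG clone itself, and the dominant LG clone
#' lies on that path (the HG dominant arises stepwise from the LG lineage).
#' Branched evolution: the dominant HG clone sits on a branch that, below
#' the divergence node (the deepest LG-present ancestor on the path), carries
#' no LG-present clone. Anything else - missing LG or HG region, no truncal
#' cluster, unresolved containment, identical lineages - is unclassifiable.
#'
#' @param tree `clone_tree`.
#' @param grades named character vector region -> grade (ND/AC/LG/HG/PDAC).
#' @param lg,hg which regions to use; default the first LG and first HG
#'   region found in `grades`.
#' @return "linear", "branched" or "unclassifiable".
#' @export
classify_topology <- function(tree, grades, lg = NULL, hg = NULL) {
  if (identical(tree$topology, "unclassifiable") || tree$unresolved)
    return("unclassifiable")
  regions <- colnames(tree$ccf)
  grades <- grades[regions]
  lg <- lg %||% regions[which(grades == "LG")[1]]
  hg <- hg %||% regions[which(grades == "HG")[1]]
  if (is.na(lg) || is.na(hg)) return("unclassifiable")
  dom_lg <- tree$dominant[lg]; dom_hg <- tree$dominant[hg]
  if (is.na(dom_lg) || is.na(dom_hg)) return("unclassifiable")
  thr <- tree$presence_threshold
  path <- ct_path(tree, dom_hg)
  lg_present <- tree$ccf[, lg] >= thr
  if (dom_lg %in% path &&
      all(lg_present[path] | path == dom_hg))
    return("linear")
  div_idx <- which(lg_present[path])
  div_idx <- if (length(div_idx)) max(div_idx) else 0L
  below <- if (div_idx < length(path)) path[(div_idx + 1):length(path)]
           else character()
  if (length(below) && !any(lg_present[below]))
    return("branched")
  "unclassifiable"
}

#' Detect minor-clone expansions across grades
#'
#' Reports clones whose population fraction is small but nonzero
#' (0 < fraction <= `low`) in one region and large (>= `high`) in a region
#' of strictly higher grade (grade order ND = AC < LG < HG < PDAC) - the
#' signature of a minor precursor subpopulation later sweeping to dominance.
#'
#' @param tree `clone_tree`.
#' @param grades named character vector region -> grade.
#' @param low,high fraction cutoffs, defaults 0.05 and 0.5.
#' @return data.frame clone, region_low, fraction_low, region_high,
#'   fraction_high.
#' @export
detect_minor_expansion <- function(tree, grades, low = 0.05, high = 0.5) {
  rank <- c(ND = 0, AC = 0, LG = 1, HG = 2, PDAC = 3)
  fr <- tree$fractions
  regions <- colnames(fr)
  g <- rank[grades[regions]]
  out <- data.frame(clone = character(), region_low = character(),
                    fraction_low = numeric(), region_high = character(),
                    fraction_high = numeric(), stringsAsFactors = FALSE)
  for (cl in rownames(fr)) for (r1 in regions) for (r2 in regions) {
    if (is.na(g[r1]) || is.na(g[r2]) || g[r2] <= g[r1]) next
    if (fr[cl, r1] > 0 && fr[cl, r1] <= low && fr[cl, r2] >= high)
      out <- rbind(out, data.frame(
        clone = cl, region_low = r1, fraction_low = fr[cl, r1],
        region_high = r2, fraction_high = fr[cl, r2],
        stringsAsFactors = FALSE))
  }
  out
}

#' Agreement between SNV- and CNA-derived trajectory classifications
#'
#' @param snv_class,cna_class named character vectors patient -> label.
#' @param exclude_unclassifiable drop pairs where either label is
#'   unclassifiable before computing the agreement fraction (default TRUE).
#' @return list with per-patient table and `agreement` fraction.
#' @export
compare_trajectories <- function(snv_class, cna_class,
                                 exclude_unclassifiable = TRUE) {
  patients <- intersect(names(snv_class), names(cna_class))
  tab <- data.frame(patient = patients,
                    snv = unname(snv_class[patients]),
                    cna = unname(cna_class[patients]),
                    stringsAsFactors = FALSE)
  tab$agree <- tab$snv == tab$cna
  use <- if (exclude_unclassifiable)
    tab$snv != "unclassifiable" & tab$cna != "unclassifiable"
  else rep(TRUE, nrow(tab))
  agreement <- if (any(use)) mean(tab$agree[use]) else NA_real_
  list(table = tab, agreement = agreement, n_compared = sum(use))
}
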