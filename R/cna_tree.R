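#' Integer arm-state profiles from CNA events
#'
#' Reduces a region's CNA events to one integer copy state per chromosome
#' arm, keeping only events of 5 Mb and larger (smaller events are excluded
#' from copy-number phylogeny). An arm is state 3 when gain-event bases on
#' the arm exceed loss-event bases (and at least `min_event_mb` of the arm is
#' altered), state 1 in the mirrored loss case, and state 2 (neutral)
#' otherwise. Copy-neutral LOH does not change the copy state and is ignored
#' here; deeper states (0, 4) are supported by the parsimony machinery but
#' are not emitted by this reduction.
#'
#' @param events_by_region named list region -> CNA event table.
#' @param arms arm coordinate table.
#' @param min_event_mb minimum single-event size, default 5.
#' @return regions x arms integer matrix.
#' @export
arm_state_profiles <- function(events_by_region, arms, min_event_mb = 5) {
  ids <- arm_id(arms)
  prof <- matrix(2L, length(events_by_region), length(ids),
                 dimnames = list(names(events_by_region), ids))
  for (r in names(events_by_region)) {
    ev <- events_by_region[[r]]
    if (is.null(ev) || !nrow(ev)) next
    ev <- ev[ev$length_mb >= min_event_mb, , drop = FALSE]
    if (!nrow(ev)) next
    gain <- arm_coverage(ev, arms, directions = "gain")
    loss <- arm_coverage(ev, arms, directions = "loss")
    arm_mb <- (arms$end - arms$start + 1) / 1e6
    gmb <- gain * arm_mb; lmb <- loss * arm_mb
    prof[r, gmb > lmb & gmb >= min_event_mb] <- 3L
    prof[r, lmb > gmb & lmb >= min_event_mb] <- 1L
  }
  prof
}

# ---- topology enumeration ---------------------------------------------

# all unrooted binary topologies over the given leaf labels, as edge
# matrices; internal nodes are labelled I1, I2, ...
enum_unrooted <- function(leaves) {
  n <- length(leaves)
  stopifnot(n >= 2)
  if (n == 2) return(list(matrix(leaves, 1, 2)))
  tops <- list(matrix(c(leaves[1], "I1", leaves[2], "I1", leaves[3], "I1"),
                      3, 2, byrow = TRUE))
  if (n == 3) return(tops)
  for (k in 4:n) {
    newI <- paste0("I", k - 2)
    leaf <- leaves[k]
    tops <- unlist(lapply(tops, function(ed) {
      lapply(seq_len(nrow(ed)), function(i) {
        rbind(ed[-i, , drop = FALSE],
              matrix(c(ed[i, 1], newI, ed[i, 2], newI, leaf, newI),
                     3, 2, byrow = TRUE))
      })
    }), recursive = FALSE)
  }
  tops
}

# root an edge matrix at the leaf `root`: returns named parent vector
root_topology <- function(edges, root = "ROOT") {
  nodes <- unique(as.vector(edges))
  parent <- setNames(rep(NA_character_, length(nodes)), nodes)
  adj <- lapply(setNames(nm = nodes), function(v)
    unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])))
  queue <- root; seen <- root
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in setdiff(adj[[v]], seen)) {
      parent[w] <- v
      seen <- c(seen, w); queue <- c(queue, w)
    }
  }
  parent
}

path_to_root <- function(parent, node) {
  p <- node
  while (!is.na(parent[p[1]])) p <- c(parent[p[1]], p)
  p
}

# ---- small parsimony ---------------------------------------------------

# Sankoff dynamic programme for one arm: minimum total |state change| over
# the rooted tree with leaf states fixed and the root leaf fixed at 2.
sankoff_arm_cost <- function(parent, leaf_states, states = 0:4) {
  children <- split(names(parent)[!is.na(parent)],
                    parent[!is.na(parent)])
  cost_of <- function(v) {
    if (v %in% names(leaf_states)) {
      cv <- rep(Inf, length(states))
      cv[states == leaf_states[v]] <- 0
      return(cv)
    }
    kids <- children[[v]]
    cv <- rep(0, length(states))
    for (k in kids) {
      ck <- cost_of(k)
      cv <- cv + vapply(states, function(s)
        min(ck + abs(s - states)), numeric(1))
    }
    cv
  }
  root <- names(parent)[is.na(parent)]
  kids <- children[[root]]
  tot <- 0
  for (k in kids) {
    ck <- cost_of(k)
    tot <- tot + min(ck + abs(leaf_states[root] - states))
  }
  tot
}

# exhaustive internal-state enumeration for one arm; returns min total cost
# and, among total-optimal assignments, the minimum cost restricted to the
# given edge subsets (as named list of edge matrices)
enumerate_arm_reconstructions <- function(parent, leaf_states,
                                          edge_subsets = list(),
                                          states = 0:4) {
  nodes <- names(parent)
  internal <- setdiff(nodes, names(leaf_states))
  edges <- cbind(parent = unname(parent[!is.na(parent)]),
                 child = nodes[!is.na(parent)])
  if (!length(internal)) {
    costs <- abs(leaf_states[edges[, 1]] - leaf_states[edges[, 2]])
    total <- sum(costs)
    sub <- vapply(edge_subsets, function(es) {
      if (!nrow(es)) return(0)
      sum(costs[paste(edges[, 1], edges[, 2]) %in%
                  paste(es[, 1], es[, 2])])
    }, numeric(1))
    return(list(total = total, subset_costs = sub))
  }
  grid <- as.matrix(expand.grid(rep(list(states), length(internal))))
  colnames(grid) <- internal
  state_of <- function(v) {
    if (v %in% names(leaf_states))
      rep(leaf_states[v], nrow(grid)) else grid[, v]
  }
  edge_cost <- matrix(0, nrow(grid), nrow(edges))
  for (i in seq_len(nrow(edges)))
    edge_cost[, i] <- abs(state_of(edges[i, 1]) - state_of(edges[i, 2]))
  total_all <- rowSums(edge_cost)
  best <- min(total_all)
  opt <- total_all == best
  sub <- vapply(edge_subsets, function(es) {
    if (!nrow(es)) return(0)
    idx <- paste(edges[, 1], edges[, 2]) %in% paste(es[, 1], es[, 2])
    if (!any(idx)) return(0)
    min(rowSums(edge_cost[opt, idx, drop = FALSE]))
  }, numeric(1))
  list(total = best, subset_costs = sub)
}

path_edges <- function(parent, from_ancestor, to_node) {
  path <- path_to_root(parent, to_node)
  i <- match(from_ancestor, path)
  if (is.na(i) || i == length(path)) return(matrix(character(), 0, 2))
  cbind(path[i:(length(path) - 1)], path[(i + 1):length(path)])
}

#' Copy-number phylogeny by exhaustive small parsimony
#'
#' Leaves are the region arm-state profiles plus an all-neutral root; every
#' unrooted binary topology over them is enumerated (at most six regions),
#' internal arm states are solved by unit-cost small parsimony (cost =
#' absolute copy-state change per arm, states 0-4), and the topologies with
#' minimum total event count are retained. Each co-optimal topology is
#' classified from the LG and HG leaves: with M the LG/HG divergence node,
#' the topology is linear when some minimum-cost reconstruction places no
#' event between M and the LG leaf (HG derives from the LG state), branched
#' when both the LG and HG sides of M carry events in every minimum-cost
#' reconstruction, and unclassifiable when the LG and HG profiles are
#' identical (no discriminating events). Disagreement among co-optimal
#' topologies is reported as unclassifiable.
#'
#' @param profiles regions x arms integer state matrix (states 0-4; events
#'   below 5 Mb are expected to have been excluded upstream by
#'   [arm_state_profiles()]).
#' @param lg,hg row names of the low-grade and high-grade regions; default
#'   the first two rows.
#' @return list of class `cna_tree`: `classification`, `cost`,
#'   `n_topologies` (co-optimal count), `labels` (per co-optimal topology),
#'   `profiles`.
#' @export
build_cna_tree <- function(profiles, lg = rownames(profiles)[1],
                           hg = rownames(profiles)[2]) {
  if (nrow(profiles) > 6) stopf("exceeds exhaustive bound (> 6 regions)")
  if (nrow(profiles) < 2) stopf("need >= 2 region profiles")
  if (any(profiles < 0 | profiles > 4)) stopf("states must lie in 0..4")
  regions <- rownames(profiles)
  leaves <- c("ROOT", regions)
  tops <- enum_unrooted(leaves)
  leaf_states_all <- rbind(ROOT = rep(2L, ncol(profiles)), profiles)
  costs <- vapply(tops, function(ed) {
    parent <- root_topology(ed, "ROOT")
    sum(vapply(seq_len(ncol(profiles)), function(j) {
      sankoff_arm_cost(parent, setNames(leaf_states_all[, j],
                                        rownames(leaf_states_all)))
    }, numeric(1)))
  }, numeric(1))
  best <- min(costs)
  co <- which(costs == best)
  identical_lg_hg <- all(profiles[lg, ] == profiles[hg, ])
  labels <- vapply(co, function(i) {
    if (identical_lg_hg) return("unclassifiable")
    parent <- root_topology(tops[[i]], "ROOT")
    m <- divergence_node(parent, lg, hg)
    lg_edges <- path_edges(parent, m, lg)
    hg_edges <- path_edges(parent, m, hg)
    sub <- vapply(seq_len(ncol(profiles)), function(j) {
      enumerate_arm_reconstructions(
        parent, setNames(leaf_states_all[, j], rownames(leaf_states_all)),
        edge_subsets = list(lg = lg_edges, hg = hg_edges))$subset_costs
    }, numeric(2))
    lg_cost <- sum(sub[1, ]); hg_cost <- sum(sub[2, ])
    if (lg_cost == 0 && hg_cost > 0) "linear"
    else if (lg_cost > 0 && hg_cost > 0) "branched"
    else "unclassifiable"
  }, character(1))
  classification <- if (length(unique(labels)) == 1) labels[1]
                    else "unclassifiable"
  structure(list(classification = classification, cost = best,
                 n_topologies = length(co), labels = labels,
                 profiles = profiles),
            class = "cna_tree")
}

divergence_node <- function(parent, lg, hg) {
  p1 <- path_to_root(parent, lg)
  p2 <- path_to_root(parent, hg)
  common <- intersect(p1, p2)
  common[length(common)]
}

#' @export
print.cna_tree <- function(x, ...) {
  cat(sprintf("<cna_tree: %s, cost %d, %d co-optimal topolog%s>\n",
              x$classification, x$cost, x$n_topologies,
              if (x$n_topologies == 1) "y" else "ies"))
  invisible(x)
}
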