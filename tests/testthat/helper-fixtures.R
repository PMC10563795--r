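# shared builders for desk-scale fixtures

mkvar <- function(chrom = "1", pos = 100L, ref = "A", alt = "T", ...) {
  variant_table(chrom = chrom, pos = pos, ref = ref, alt = alt, ...)
}

# variant set from a vector of integer positions on chromosome "1"
vset <- function(pos, ...) {
  if (!length(pos)) return(variant_table())
  variant_table(chrom = "1", pos = as.integer(pos), ref = "A", alt = "T",
                tumor_depth = 400L, tumor_alt = 100L, quality = 60, ...)
}

seg_tbl <- function(chrom, start, end, value) {
  data.frame(chrom = as.character(chrom), start = start, end = end,
             value = value, stringsAsFactors = FALSE)
}

event_tbl <- function(chrom, start, end, direction) {
  len <- (end - start + 1) / 1e6
  data.frame(chrom = as.character(chrom), start = start, end = end,
             direction = direction, length_mb = len, focal = len < 3,
             ai_posterior = 0.99, mean_log2 = ifelse(direction == "gain",
                                                     0.4, -0.45),
             stringsAsFactors = FALSE)
}

# independent per-base (10 kb grid) arm-coverage oracle used against
# aneuploidy_score; events must be aligned to the grid
coverage_oracle_as <- function(events, arms, min_fraction = 0.75,
                               bin = 1e4) {
  hit <- 0L
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    nbin <- (a$end - a$start + 1) / bin
    covered <- logical(nbin)
    ev <- events[events$chrom == a$chrom, , drop = FALSE]
    if (nrow(ev)) for (j in seq_len(nrow(ev))) {
      s <- max(ev$start[j], a$start); e <- min(ev$end[j], a$end)
      if (s > e) next
      b1 <- (s - a$start) / bin + 1
      b2 <- (e - a$start + 1) / bin
      covered[b1:b2] <- TRUE
    }
    if (mean(covered) >= min_fraction) hit <- hit + 1L
  }
  hit
}

# random grid-aligned event set on the toy genome
random_event_set <- function(n, seed) {
  arms <- toy_arm_table()
  withr::with_seed(seed, {
    i <- sample(nrow(arms), n, replace = TRUE)
    a <- arms[i, ]
    s <- a$start + floor(runif(n) * (a$end - a$start) / 1e4) * 1e4
    len <- pmax(1e4, floor(runif(n)^2 * (a$end - s) / 1e4) * 1e4)
    e <- pmin(a$end, s + len - 1)
    # snap ends to close the 10 kb grid
    e <- s + (floor((e - s + 1) / 1e4) * 1e4) - 1
    e <- pmax(e, s + 1e4 - 1)
    event_tbl(a$chrom, s, pmin(e, a$end),
              sample(c("gain", "loss", "cnloh"), n, replace = TRUE))
  })
}

# exhaustive small-parsimony oracle: minimum total |state change| over every
# assignment of internal states, every unrooted topology (via the package
# enumerator is avoided: topologies are re-enumerated by brute force over
# leaf-addition order is the same algorithm, so instead the oracle fixes the
# topology and enumerates states only)
parsimony_oracle <- function(parent, leaf_states, states = 0:4) {
  nodes <- names(parent)
  internal <- setdiff(nodes, names(leaf_states))
  edges <- cbind(unname(parent[!is.na(parent)]), nodes[!is.na(parent)])
  if (!length(internal))
    return(sum(abs(leaf_states[edges[, 1]] - leaf_states[edges[, 2]])))
  grid <- expand.grid(rep(list(states), length(internal)))
  colnames(grid) <- internal
  best <- Inf
  for (k in seq_len(nrow(grid))) {
    st <- c(leaf_states, unlist(grid[k, , drop = FALSE]))
    best <- min(best, sum(abs(st[edges[, 1]] - st[edges[, 2]])))
  }
  best
}
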