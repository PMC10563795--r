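#' Validate a segment table
#'
#' Segments are 1-based inclusive intervals with a `value` column holding an
#' allelic-imbalance posterior (AI segments) or a mean log2 copy ratio (LOGR
#' segments). Within one table, segments must be sorted and non-overlapping
#' per chromosome.
#'
#' @param seg data.frame with chrom, start, end, value.
#' @export
validate_segments <- function(seg) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(seg)))
  if (!nrow(seg)) return(invisible(seg))
  if (any(seg$start > seg$end)) stopf("segment with start > end")
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    if (is.unsorted(s$start)) stopf("segments unsorted on chromosome %s", ch)
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
      stopf("segments overlap on chromosome %s", ch)
  }
  invisible(seg)
}

empty_cna_events <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             direction = character(), length_mb = numeric(),
             focal = logical(), ai_posterior = numeric(),
             mean_log2 = numeric(), stringsAsFactors = FALSE)
}

#' Call CNAs by overlaying allelic-imbalance and log-ratio segmentations
#'
#' Copy-number events are emitted only inside allelic-imbalance (AI)
#' segments: each AI segment is intersected with the log-ratio segmentation,
#' and each intersected piece is classified as a gain (mean log2 at or above
#' `logr_gain`), a loss (at or below `logr_loss`), or copy-neutral LOH
#' otherwise. Adjacent same-direction pieces are merged; the merged event
#' carries the AI posterior and the length-weighted mean log2 of its pieces.
#' Log-ratio shifts with no AI support are not emitted (balanced
#' amplifications are therefore undetectable by design).
#'
#' @param ai AI segment table (value = posterior).
#' @param logr log-ratio segment table (value = mean log2 ratio).
#' @param logr_gain,logr_loss log2 thresholds, defaults +0.2 / -0.2.
#' @return CNA event table: chrom, start, end, direction
#'   (gain/loss/cnloh), length_mb, focal, ai_posterior, mean_log2.
#' @export
overlay_cna <- function(ai, logr, logr_gain = 0.2, logr_loss = -0.2) {
  validate_segments(ai); validate_segments(logr)
  if (!nrow(ai) || !nrow(logr)) return(empty_cna_events())
  pieces <- list()
  for (i in seq_len(nrow(ai))) {
    a <- ai[i, ]
    l <- logr[logr$chrom == a$chrom & logr$end >= a$start &
                logr$start <= a$end, , drop = FALSE]
    if (!nrow(l)) next
    st <- pmax(l$start, a$start); en <- pmin(l$end, a$end)
    dir <- ifelse(l$value >= logr_gain, "gain",
                  ifelse(l$value <= logr_loss, "loss", "cnloh"))
    p <- data.frame(chrom = a$chrom, start = st, end = en, direction = dir,
                    ai_posterior = a$value, mean_log2 = l$value,
                    stringsAsFactors = FALSE)
    # merge adjacent same-direction pieces within this AI segment
    j <- 1L
    while (j < nrow(p)) {
      if (p$direction[j + 1] == p$direction[j] &&
          p$start[j + 1] <= p$end[j] + 1) {
        w1 <- p$end[j] - p$start[j] + 1; w2 <- p$end[j + 1] - p$start[j + 1] + 1
        p$mean_log2[j] <- (p$mean_log2[j] * w1 + p$mean_log2[j + 1] * w2) /
          (w1 + w2)
        p$end[j] <- p$end[j + 1]
        p <- p[-(j + 1), , drop = FALSE]
      } else j <- j + 1L
    }
    pieces[[length(pieces) + 1L]] <- p
  }
  if (!length(pieces)) return(empty_cna_events())
  ev <- do.call(rbind, pieces)
  ev$length_mb <- (ev$end - ev$start + 1) / 1e6
  ev$focal <- ev$length_mb < 3
  ev <- ev[order(ev$chrom, ev$start),
           c("chrom", "start", "end", "direction", "length_mb", "focal",
             "ai_posterior", "mean_log2")]
  rownames(ev) <- NULL
  ev
}

#' Focal versus broad classification of CNA events
#'
#' Focal iff the event spans strictly less than 3 Mb; everything else is
#' broad (a total partition).
#'
#' @param events CNA event table.
#' @return character vector "focal"/"broad".
#' @export
classify_focal <- function(events) {
  if (!nrow(events)) return(character())
  ifelse(events$length_mb < 3, "focal", "broad")
}

# Fraction of each arm covered by the union of the given events.
arm_coverage <- function(events, arms,
                         directions = c("gain", "loss", "cnloh")) {
  validate_arm_table(arms)
  out <- setNames(numeric(nrow(arms)), arm_id(arms))
  ev <- events[events$direction %in% directions, , drop = FALSE]
  if (!nrow(ev)) return(out)
  if (!all(ev$chrom %in% arms$chrom))
    stopf("event on chromosome absent from arm table")
  lens <- chrom_lengths(arms)
  if (any(ev$end > lens[ev$chrom] | ev$start < 1))
    stopf("event outside arm table coordinates")
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    e <- ev[ev$chrom == a$chrom, , drop = FALSE]
    if (!nrow(e)) next
    ir <- IRanges::restrict(IRanges::IRanges(e$start, e$end),
                            start = a$start, end = a$end)
    covered <- sum(IRanges::width(IRanges::reduce(ir)))
    out[i] <- covered / (a$end - a$start + 1)
  }
  out
}

#' Arm-level aneuploidy score
#'
#' The aneuploidy score (AS) of a region is the number of chromosome arms
#' whose length is at least 75% covered by the union of CNA event bases.
#' Any event direction counts by default (including copy-neutral LOH); each
#' arm counts at most once.
#'
#' @param events CNA event table for one region.
#' @param arms arm coordinate table.
#' @param min_fraction coverage threshold, default 0.75.
#' @param directions event directions that count.
#' @return integer score.
#' @export
aneuploidy_score <- function(events, arms, min_fraction = 0.75,
                             directions = c("gain", "loss", "cnloh")) {
  cov <- arm_coverage(events, arms, directions)
  as.integer(sum(cov >= min_fraction))
}

#' Arm amplification flag
#'
#' TRUE iff gain-direction events cover at least 75% of the requested arm
#' (the aneuploidy-score rule restricted to gains); used for the 1q
#' amplification status of each region.
#'
#' @param events CNA event table.
#' @param arms arm coordinate table.
#' @param arm_id arm identifier such as "1q".
#' @param min_fraction coverage threshold, default 0.75.
#' @export
arm_amplification_flag <- function(events, arms, arm_id = "1q",
                                   min_fraction = 0.75) {
  ids <- paste0(arms$chrom, arms$arm)
  if (!arm_id %in% ids) stopf("unknown arm '%s'", arm_id)
  cov <- arm_coverage(events, arms, directions = "gain")
  unname(cov[arm_id] >= min_fraction)
}

#' Write CNA events as BED
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open. The name field carries direction and focal/broad class, the
#' score field the mean log2 ratio scaled by 1000.
#'
#' @param events CNA event table.
#' @param path output path.
#' @export
write_cna_bed <- function(events, path) {
  lines <- if (nrow(events)) {
    sprintf("%s\t%d\t%d\t%s_%s\t%d",
            events$chrom, as.integer(events$start - 1),
            as.integer(events$end), events$direction,
            classify_focal(events),
            as.integer(round(1000 * ifelse(is.na(events$mean_log2), 0,
                                           events$mean_log2))))
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' Annotate genes hit by CNA events
#'
#' A gene is hit when its interval intersects an event by at least one base.
#' Membership in the packaged chromosomal-instability gene set is reported.
#'
#' @param events CNA event table.
#' @param genes gene coordinate table (gene, chrom, start, end).
#' @param panel named character vector/list of gene sets; default the
#'   chromosomal-instability set.
#' @return data.frame gene, chrom, direction, focal, instability_set.
#' @export
annotate_genes <- function(events, genes,
                           panel = list(instability = instability_genes())) {
  out <- data.frame(gene = character(), chrom = character(),
                    direction = character(), focal = logical(),
                    instability_set = logical(), stringsAsFactors = FALSE)
  if (!nrow(events) || !nrow(genes)) return(out)
  hits <- list()
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    g <- genes[genes$chrom == e$chrom & genes$end >= e$start &
                 genes$start <= e$end, , drop = FALSE]
    if (!nrow(g)) next
    hits[[length(hits) + 1L]] <- data.frame(
      gene = g$gene, chrom = g$chrom, direction = e$direction,
      focal = e$focal, stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(out)
  h <- unique(do.call(rbind, hits))
  h$instability_set <- h$gene %in% (panel$instability %||% character())
  h <- h[order(h$gene), ]
  rownames(h) <- NULL
  h
}
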