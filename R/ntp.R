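#' Construct a template set for nearest-template prediction
#'
#' A template set is a named classifier (Moffitt-style, Collisson-style, ...)
#' with one marker-gene list per class. Internally it is a genes x classes
#' template matrix of weights (+1 marker membership by default, or centroid
#' values).
#'
#' @param name classifier label.
#' @param markers data.frame with columns `gene`, `class` and optionally
#'   `weight` (default 1).
#' @return object of class `template_set`.
#' @export
template_set <- function(name, markers) {
  stopifnot(all(c("gene", "class") %in% names(markers)))
  if (is.null(markers$weight)) markers$weight <- 1
  classes <- sort(unique(markers$class))
  if (length(classes) < 2) stopf("template set needs >= 2 classes")
  genes <- unique(markers$gene)
  tpl <- matrix(0, length(genes), length(classes),
                dimnames = list(genes, classes))
  for (i in seq_len(nrow(markers)))
    tpl[markers$gene[i], markers$class[i]] <- markers$weight[i]
  structure(list(name = name, template = tpl, markers = markers),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set '%s': %d classes, %d genes>\n", x$name,
              ncol(x$template), nrow(x$template)))
  invisible(x)
}

#' Read a template set from a marker TSV
#' @param path TSV with columns gene, class and optional weight.
#' @param name classifier name; defaults to the file stem.
#' @export
read_template_set <- function(path, name = NULL) {
  m <- as.data.frame(data.table::fread(path))
  template_set(name %||% tools::file_path_sans_ext(basename(path)), m)
}

#' Write a template set to a marker TSV
#' @param templates `template_set`.
#' @param path output TSV.
#' @export
write_template_set <- function(templates, path) {
  data.table::fwrite(templates$markers, path, sep = "\t")
  invisible(path)
}

#' Median-of-ratios normalization of a count matrix
#'
#' Scale-factor normalization in the DESeq style: each sample's size factor
#' is the median of its per-gene ratios to the gene-wise geometric mean
#' (computed over genes expressed in every sample), followed by a log2
#' transform with pseudocount 1. This deterministic scheme replaces
#' count-depth regression normalization; template correlation only needs
#' relative profiles, not variance stabilization.
#'
#' All-zero samples cannot be normalized and are dropped with a warning.
#'
#' @param counts nonnegative gene x sample matrix.
#' @return log2-normalized matrix with a `size_factors` attribute.
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be nonnegative")
  zero <- colSums(counts) == 0
  if (any(zero)) {
    warning(sprintf("excluding %d all-zero sample(s): %s", sum(zero),
                    paste(colnames(counts)[zero], collapse = ", ")))
    counts <- counts[, !zero, drop = FALSE]
  }
  loggeo <- rowMeans(log(counts))            # -Inf where any zero
  use <- is.finite(loggeo)
  sf <- if (any(use)) {
    apply(counts[use, , drop = FALSE], 2, function(cnt)
      exp(stats::median(log(cnt) - loggeo[use])))
  } else {
    ls <- colSums(counts)
    ls / exp(mean(log(ls)))
  }
  norm <- log2(sweep(counts, 2, sf, "/") + 1)
  attr(norm, "size_factors") <- sf
  norm
}

#' Nearest-template prediction for a single expression profile
#'
#' Computes the correlation distance d_c = 1 - Pearson(profile, template_c)
#' over the template genes present in the profile, assigns the class with the
#' smallest distance, and estimates significance by permuting gene labels of
#' the profile: p = (1 + #permutations whose nearest-template distance is <=
#' the observed one) / (n_perm + 1). The permuted distance is itself the
#' minimum over classes, so the null accounts for best-class selection and
#' stays calibrated (comparing permutations against only the winning
#' template inflates the false-call rate roughly by the number of classes).
#' FDR control across replicates is applied by
#' [classify_replicates()]; for a lone profile `fdr = p`.
#'
#' @param profile named numeric vector of normalized expression.
#' @param templates `template_set`.
#' @param n_perm number of gene-label permutations (>= 100), default 1000.
#' @param fdr_threshold calls with FDR above this are nonclassifiable,
#'   default 0.05.
#' @param seed RNG seed for the permutations.
#' @param min_genes minimum template genes that must be present, default 20.
#' @return one-row data.frame: label, best_class, distance, p, fdr,
#'   classifiable, reason.
#' @export
ntp_classify <- function(profile, templates, n_perm = 1000,
                         fdr_threshold = 0.05, seed = NULL,
                         min_genes = 20L) {
  stopifnot(n_perm >= 100)
  tpl <- templates$template
  genes <- intersect(rownames(tpl), names(profile))
  if (length(genes) < min_genes) {
    return(data.frame(label = "nonclassifiable", best_class = NA_character_,
                      distance = NA_real_, p = NA_real_, fdr = NA_real_,
                      classifiable = FALSE, reason = "low gene overlap",
                      stringsAsFactors = FALSE))
  }
  x <- profile[genes]
  tm <- tpl[genes, , drop = FALSE]
  if (stats::sd(x) == 0) {
    return(data.frame(label = "nonclassifiable", best_class = NA_character_,
                      distance = NA_real_, p = NA_real_, fdr = NA_real_,
                      classifiable = FALSE, reason = "flat profile",
                      stringsAsFactors = FALSE))
  }
  d <- 1 - drop(cor(x, tm))
  best <- which.min(d)
  d_obs <- d[best]
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample(x), numeric(length(x)))
  })
  d_perm <- 1 - apply(cor(perm, tm), 1, max)   # nearest-template distance
  p <- (1 + sum(d_perm <= d_obs)) / (n_perm + 1)
  ok <- p <= fdr_threshold         # lone profile: fdr == p
  data.frame(label = if (ok) colnames(tm)[best] else "nonclassifiable",
             best_class = colnames(tm)[best],
             distance = unname(d_obs), p = p, fdr = p, classifiable = ok,
             reason = if (ok) "" else "fdr above threshold",
             stringsAsFactors = FALSE)
}

#' Classify every replicate of a normalized expression matrix
#'
#' Runs [ntp_classify()] per column and applies Benjamini-Hochberg FDR
#' across replicates; calls with FDR above `fdr_threshold` are relabelled
#' nonclassifiable (their best class is retained in `best_class`).
#'
#' @param mat normalized genes x replicates matrix.
#' @param templates `template_set`.
#' @param seed master seed; each replicate gets a derived seed.
#' @inheritParams ntp_classify
#' @return data.frame, one row per replicate.
#' @export
classify_replicates <- function(mat, templates, n_perm = 1000,
                                fdr_threshold = 0.05, seed = 1L,
                                min_genes = 20L) {
  mat <- as.matrix(mat)
  seeds <- derive_seeds(seed, ncol(mat))
  calls <- do.call(rbind, lapply(seq_len(ncol(mat)), function(j) {
    ntp_classify(mat[, j], templates, n_perm = n_perm,
                 fdr_threshold = fdr_threshold, seed = seeds[j],
                 min_genes = min_genes)
  }))
  calls$replicate <- colnames(mat) %||% as.character(seq_len(ncol(mat)))
  ok <- !is.na(calls$p)
  calls$fdr[ok] <- p.adjust(calls$p[ok], method = "BH")
  pass <- ok & calls$fdr <= fdr_threshold
  calls$label[pass] <- calls$best_class[pass]
  calls$classifiable[pass] <- TRUE
  calls$reason[pass] <- ""
  flip <- ok & !pass
  calls$label[flip] <- "nonclassifiable"
  calls$classifiable[flip] <- FALSE
  calls$reason[flip] <- "fdr above threshold"
  calls[, c("replicate", "label", "best_class", "distance", "p", "fdr",
            "classifiable", "reason")]
}

#' Aggregate replicate subtype calls to a region label
#'
#' Majority vote over classifiable replicates; a tie or the absence of any
#' classifiable replicate yields "nonclassifiable".
#'
#' @param calls data.frame from [classify_replicates()].
#' @return region label (character scalar).
#' @export
aggregate_replicates <- function(calls) {
  ok <- calls[calls$classifiable, , drop = FALSE]
  if (!nrow(ok)) return("nonclassifiable")
  tab <- sort(table(ok$label), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) return("nonclassifiable")
  names(tab)[1]
}

#' Report subtype class switches between grades
#'
#' Lists patients whose LG and HG region labels are both classifiable and
#' differ (a class switch upon progression).
#'
#' @param region_labels data.frame with columns patient, region, grade,
#'   label.
#' @export
class_switches <- function(region_labels) {
  out <- data.frame(patient = character(), lg_label = character(),
                    hg_label = character(), stringsAsFactors = FALSE)
  for (p in unique(region_labels$patient)) {
    r <- region_labels[region_labels$patient == p, ]
    lg <- r$label[r$grade == "LG"]; hg <- r$label[r$grade == "HG"]
    if (!length(lg) || !length(hg)) next
    lg <- lg[1]; hg <- hg[1]
    if (lg != "nonclassifiable" && hg != "nonclassifiable" && lg != hg)
      out <- rbind(out, data.frame(patient = p, lg_label = lg,
                                   hg_label = hg, stringsAsFactors = FALSE))
  }
  out
}

#' Subtype-by-CNA 2x2 table
#'
#' Cross-tabulates classical/basal region labels against a per-region binary
#' CNA flag (1q amplification for the headline use). Regions with any other
#' label are excluded and listed in the `excluded` attribute.
#'
#' @param labels named character vector region -> label.
#' @param flags named logical vector region -> CNA flag.
#' @return integer vector c(a, b, c, d) = (classical & flag,
#'   classical & !flag, basal & flag, basal & !flag) with attribute
#'   `excluded`.
#' @export
subtype_cna_table <- function(labels, flags) {
  regions <- intersect(names(labels), names(flags))
  lab <- labels[regions]; fl <- flags[regions]
  use <- lab %in% c("classical", "basal")
  excl <- regions[!use]
  lab <- lab[use]; fl <- fl[use]
  out <- c(a = sum(lab == "classical" & fl),
           b = sum(lab == "classical" & !fl),
           c = sum(lab == "basal" & fl),
           d = sum(lab == "basal" & !fl))
  attr(out, "excluded") <- excl
  out
}
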