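PRED7 <- c("sift", "polyphen", "HVAR", "LRT", "mutationTaster", "fathmm",
           "provean")

#' Construct a harmonized somatic variant table
#'
#' The package-wide variant container is a plain data.frame with one row per
#' somatic call. Identity of a variant is the exact tuple
#' (chrom, pos, ref, alt); no position fuzzing is applied when comparing
#' callers. `pred7` holds the seven in-silico deleteriousness verdicts
#' (sift, polyphen, HVAR, LRT, mutationTaster, fathmm, provean) packed as a
#' 7-bit integer; see [pred7_mask()].
#'
#' @param chrom,pos,ref,alt variant identity (1-based position).
#' @param type `"SNV"` or `"indel"`.
#' @param tumor_depth,tumor_alt,normal_depth,normal_alt read counts; `vaf`
#'   defaults to `tumor_alt / tumor_depth`.
#' @param callers comma-separated caller tags among `M2`, `SC`, `MU`.
#' @param quality caller confidence (Mutect2 emission log-odds scale for
#'   rescue thresholding).
#' @param pop_af maximum population allele frequency (NA when the site is
#'   absent from population databases).
#' @param pred7 integer bitmask of predictor verdicts (0-127).
#' @param clinvar `"pathogenic"`, `"other"` or `"absent"`.
#' @param func_class `"exonic"`, `"splicing"` or `"other"`.
#' @param gene annotated gene symbol or `"."`.
#' @param rescued logical, TRUE for targeted-rescue calls.
#' @return data.frame of class `ipmn_variants`.
#' @export
variant_table <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          type = "SNV", tumor_depth = NA_integer_,
                          tumor_alt = NA_integer_, normal_depth = NA_integer_,
                          normal_alt = NA_integer_, vaf = NULL,
                          callers = "", quality = NA_real_,
                          pop_af = NA_real_, pred7 = 0L,
                          clinvar = "absent", func_class = "exonic",
                          gene = ".", rescued = FALSE) {
  n <- max(length(chrom), length(pos))
  v <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.integer(pos), n),
    ref = as.character(ref), alt = as.character(alt),
    type = rep_len(type, n),
    tumor_depth = rep_len(as.integer(tumor_depth), n),
    tumor_alt = rep_len(as.integer(tumor_alt), n),
    normal_depth = rep_len(as.integer(normal_depth), n),
    normal_alt = rep_len(as.integer(normal_alt), n),
    callers = rep_len(callers, n), quality = rep_len(quality, n),
    pop_af = rep_len(pop_af, n), pred7 = rep_len(as.integer(pred7), n),
    clinvar = rep_len(clinvar, n), func_class = rep_len(func_class, n),
    gene = rep_len(gene, n), rescued = rep_len(rescued, n),
    stringsAsFactors = FALSE
  )
  v$vaf <- if (is.null(vaf))
    as.numeric(ifelse(!is.na(v$tumor_depth) & v$tumor_depth > 0,
                      v$tumor_alt / v$tumor_depth, NA_real_))
  else rep_len(as.numeric(vaf), n)
  if (n) {
    bad <- !is.na(v$tumor_alt) & !is.na(v$tumor_depth) &
      v$tumor_alt > v$tumor_depth
    if (any(bad)) stopf("tumor_alt exceeds tumor_depth for %d variant(s)",
                        sum(bad))
  }
  class(v) <- c("ipmn_variants", "data.frame")
  v
}

empty_variants <- function() variant_table()

#' Pack predictor verdicts into a 7-bit mask
#'
#' @param which character vector of predictor names (subset of
#'   `c("sift","polyphen","HVAR","LRT","mutationTaster","fathmm","provean")`).
#' @export
pred7_mask <- function(which = character()) {
  i <- match(which, PRED7)
  if (anyNA(i)) stopf("unknown predictor(s): %s",
                      paste(which[is.na(i)], collapse = ", "))
  as.integer(sum(bitwShiftL(1L, i - 1L)))
}

#' Count deleterious verdicts in a pred7 mask
#' @param mask integer vector of 7-bit masks.
#' @export
pred7_count <- function(mask) {
  n <- integer(length(mask))
  m <- as.integer(mask)
  for (b in 0:6) n <- n + bitwAnd(bitwShiftR(m, b), 1L)
  n
}

vkeys <- function(v) variant_key(v$chrom, v$pos, v$ref, v$alt)
skeys <- function(v) paste(v$chrom, v$pos, sep = ":")
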