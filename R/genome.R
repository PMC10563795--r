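#' Toy genome arm table
#'
#' A four-chromosome, 400 Mb genome with p/q arms, used by the cohort
#' simulator and by desk-scale tests. Coordinates are 1-based inclusive.
#' An hg19-like arm table (approximate centromere splits for chr1-22) is
#' shipped under `inst/extdata/arms.hg19like.tsv` for users analysing real
#' segmentations; the toy genome is the default everywhere in this package.
#'
#' @return data.frame with columns `chrom`, `arm`, `start`, `end`.
#' @export
toy_arm_table <- function() {
  data.frame(
    chrom = rep(c("1", "2", "3", "4"), each = 2),
    arm   = rep(c("p", "q"), 4),
    start = c(1, 55e6 + 1, 1, 45e6 + 1, 1, 40e6 + 1, 1, 35e6 + 1),
    end   = c(55e6, 130e6, 45e6, 100e6, 40e6, 90e6, 35e6, 80e6),
    stringsAsFactors = FALSE
  )
}

#' Read an arm coordinate table
#'
#' @param path TSV with columns chrom, arm, start, end. `"toy"` and
#'   `"hg19like"` select the packaged tables.
#' @export
read_arm_table <- function(path = "toy") {
  if (identical(path, "toy")) return(toy_arm_table())
  if (identical(path, "hg19like"))
    path <- system.file("extdata", "arms.hg19like.tsv", package = "ipmnevo")
  arms <- as.data.frame(data.table::fread(path, colClasses = list(character = "chrom")))
  validate_arm_table(arms)
  arms
}

validate_arm_table <- function(arms) {
  stopifnot(all(c("chrom", "arm", "start", "end") %in% names(arms)))
  if (any(arms$start > arms$end)) stopf("arm table has start > end")
  for (ch in unique(arms$chrom)) {
    a <- arms[arms$chrom == ch, ]
    a <- a[order(a$start), ]
    if (nrow(a) > 1 && any(a$start[-1] <= a$end[-nrow(a)]))
      stopf("arms overlap on chromosome %s", ch)
  }
  invisible(arms)
}

arm_id <- function(arms) paste0(arms$chrom, arms$arm)

chrom_lengths <- function(arms) {
  vapply(split(arms$end, arms$chrom), max, numeric(1))
}

#' Toy gene coordinate table
#'
#' Gene symbols are real (established PDAC drivers, chromosomal-instability
#' and RTK/cell-cycle genes); the coordinates are synthetic placements on the
#' toy genome, chosen so that `PARP1` and `RIT1` sit on arm 1q where the
#' simulator places 1q gains.
#'
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
toy_gene_table <- function() {
  g <- function(gene, chrom, start) data.frame(
    gene = gene, chrom = chrom, start = start, end = start + 1e5 - 1,
    stringsAsFactors = FALSE)
  rbind(
    g("ARID1A", "1",  8e6),  g("MAP2K4", "1", 20e6),  g("STK11",  "1", 30e6),
    g("PARP1",  "1", 100e6), g("RIT1",   "1", 105e6), g("MDM2",   "1", 112e6),
    g("KRAS",   "2", 20e6),  g("BRAF",   "2", 30e6),  g("PIK3CA", "2", 38e6),
    g("CDKN2A", "2", 60e6),  g("CDK6",   "2", 70e6),  g("RAD51",  "2", 80e6),
    g("CHEK2",  "2", 90e6),  g("GNAS",   "3", 70e6),  g("RNF43",  "3", 10e6),
    g("CTNNB1", "3", 20e6),  g("SF3B1",  "3", 30e6),  g("ATR",    "3", 50e6),
    g("ATM",    "3", 80e6),  g("XRCC2",  "3", 85e6),  g("TP53",   "4", 10e6),
    g("SMAD4",  "4", 18e6),  g("TGFBR1", "4", 24e6),  g("TGFBR2", "4", 28e6),
    g("KDM6A",  "4", 32e6),  g("RBM10",  "4", 40e6),  g("IDH1",   "4", 46e6),
    g("PTEN",   "4", 52e6),  g("APC",    "4", 58e6),  g("BRCA1",  "4", 64e6),
    g("BRCA2",  "4", 70e6),  g("PALB2",  "4", 76e6),  g("ROS1",   "2", 10e6),
    g("MET",    "3", 40e6),  g("EGFR",   "1", 40e6)
  )
}

#' Chromosomal-instability gene set
#'
#' The nine genome-integrity genes screened for co-occurring SNV/CNA hits in
#' precursor lesions.
#' @export
instability_genes <- function() {
  c("PARP1", "TP53", "XRCC2", "ATR", "ATM", "MDM2", "RAD51", "CHEK2", "PALB2")
}

#' Established PDAC driver genes used for targeted rescue
#' @export
pdac_driver_genes <- function() {
  c("KRAS", "TP53", "SMAD4", "CDKN2A", "GNAS", "BRAF", "PIK3CA", "MAP2K4",
    "TGFBR1", "TGFBR2", "RNF43", "CTNNB1", "STK11", "ARID1A", "KDM6A",
    "SF3B1", "RBM10", "IDH1", "PTEN", "APC", "ATM", "BRCA1", "BRCA2")
}

#' Driver hotspot loci on the toy genome
#'
#' One recurrent hotspot position per established PDAC driver gene (synthetic
#' toy-genome coordinates; one locus per gene placed inside the gene body).
#' This is the packaged stand-in for a COSMIC-derived locus panel.
#'
#' @return data.frame gene, chrom, pos, ref, alt, label.
#' @export
driver_loci_panel <- function() {
  path <- system.file("extdata", "driver_loci.toy.tsv", package = "ipmnevo")
  as.data.frame(data.table::fread(path, colClasses = list(character = c("chrom", "ref", "alt"))))
}
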