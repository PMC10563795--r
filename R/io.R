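VCF_INFO_DEFS <- c(
  '##INFO=<ID=TDP,Number=1,Type=Integer,Description="Tumor depth">',
  '##INFO=<ID=TAC,Number=1,Type=Integer,Description="Tumor alt count">',
  '##INFO=<ID=NDP,Number=1,Type=Integer,Description="Normal depth">',
  '##INFO=<ID=NAC,Number=1,Type=Integer,Description="Normal alt count">',
  '##INFO=<ID=VTYPE,Number=1,Type=String,Description="SNV or indel">',
  '##INFO=<ID=POPAF,Number=1,Type=Float,Description="Max population AF">',
  '##INFO=<ID=PRED7,Number=1,Type=Integer,Description="7-bit predictor verdict mask">',
  '##INFO=<ID=CLNSIG,Number=1,Type=String,Description="ClinVar class">',
  '##INFO=<ID=FUNC,Number=1,Type=String,Description="Functional class">',
  '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">'
)

#' Write a variant table as VCF v4.2
#'
#' Depths, counts and annotations are stored under documented INFO keys
#' (TDP, TAC, NDP, NAC, VTYPE, POPAF, PRED7, CLNSIG, FUNC, GENE); the caller
#' confidence score goes in QUAL.
#'
#' @param variants variant table.
#' @param path output path.
#' @param contigs named vector of contig lengths (defaults to the toy
#'   genome).
#' @export
write_vcf <- function(variants, path,
                      contigs = chrom_lengths(toy_arm_table())) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=ipmnevo",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                   as.integer(contigs)),
           VCF_INFO_DEFS,
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE,
                                                      trim = TRUE))
  rows <- if (nrow(variants)) {
    v <- variants[order(variants$chrom, variants$pos, variants$ref,
                        variants$alt), ]
    info <- sprintf(
      "TDP=%s;TAC=%s;NDP=%s;NAC=%s;VTYPE=%s;POPAF=%s;PRED7=%s;CLNSIG=%s;FUNC=%s;GENE=%s",
      fmt_num(v$tumor_depth), fmt_num(v$tumor_alt), fmt_num(v$normal_depth),
      fmt_num(v$normal_alt), v$type, fmt_num(v$pop_af), fmt_num(v$pred7),
      v$clinvar, v$func_class, v$gene)
    sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t%s", v$chrom, v$pos, v$ref, v$alt,
            fmt_num(v$quality), info)
  } else character()
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a VCF written by [write_vcf()] into a variant table
#'
#' Parsing is delegated to `VariantAnnotation::readVcf`.
#'
#' @param path VCF path.
#' @export
read_vcf <- function(path) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "toy"))
  n <- length(vcf)
  if (n == 0) return(empty_variants())
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  variant_table(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt,
    type = as.character(info$VTYPE),
    tumor_depth = as.integer(info$TDP), tumor_alt = as.integer(info$TAC),
    normal_depth = as.integer(info$NDP), normal_alt = as.integer(info$NAC),
    quality = as.numeric(VariantAnnotation::qual(vcf)),
    pop_af = as.numeric(info$POPAF), pred7 = as.integer(info$PRED7),
    clinvar = as.character(info$CLNSIG),
    func_class = as.character(info$FUNC),
    gene = as.character(info$GENE))
}

write_segments <- function(seg, path) {
  data.table::fwrite(seg, path, sep = "\t")
  invisible(path)
}

read_segments <- function(path) {
  s <- as.data.frame(data.table::fread(
    path, colClasses = list(character = "chrom")))
  if (!nrow(s)) return(data.frame(chrom = character(), start = numeric(),
                                  end = numeric(), value = numeric()))
  s$start <- as.numeric(s$start); s$end <- as.numeric(s$end)
  s$value <- as.numeric(s$value)
  s
}

write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

read_counts <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene
  m
}

df_to_json <- function(df) as.list(df)

truth_to_list <- function(truth) {
  tr <- truth$tree
  list(
    patient = truth$patient,
    topology = truth$topology,
    cna_class = truth$cna_class,
    nodes = tr$nodes,
    ccf = data.frame(clone = rownames(tr$ccf), tr$ccf, check.names = FALSE),
    mutations = tr$mutations,
    lgdom = tr$lgdom, hgdom = tr$hgdom,
    variants = as.data.frame(truth$variants),
    germline = truth$germline,
    cna_events = truth$cna_events,
    region_events = truth$region_events,
    regions = truth$regions,
    mu_available = truth$mu_available
  )
}

fix_df <- function(df, int_cols = character(), chr_cols = character(),
                   num_cols = character()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (cc in intersect(int_cols, names(df))) df[[cc]] <- as.integer(df[[cc]])
  for (cc in intersect(chr_cols, names(df))) df[[cc]] <- as.character(df[[cc]])
  for (cc in intersect(num_cols, names(df))) df[[cc]] <- as.numeric(df[[cc]])
  df
}

empty_region_events <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             direction = character(), stringsAsFactors = FALSE)
}

list_to_truth <- function(x, cfg) {
  vcols <- c("pos", "tumor_depth", "tumor_alt", "normal_depth", "normal_alt",
             "pred7")
  variants <- fix_df(x$variants, int_cols = vcols, chr_cols = "chrom",
                     num_cols = c("quality", "vaf", "pop_af"))
  class(variants) <- c("ipmn_variants", "data.frame")
  ccf <- as.matrix(x$ccf[, -1, drop = FALSE])
  storage.mode(ccf) <- "double"
  rownames(ccf) <- x$ccf$clone
  nodes <- fix_df(x$nodes, chr_cols = c("clone", "parent"))
  muts <- setNames(lapply(x$mutations, as.character), names(x$mutations))
  tree <- clone_tree(nodes, ccf, mutations = muts[nodes$clone],
                     topology = x$topology)
  tree$lgdom <- x$lgdom; tree$hgdom <- x$hgdom
  region_events <- setNames(lapply(x$region_events, function(ev) {
    if (is.null(ev) || !length(ev) || (is.data.frame(ev) && !nrow(ev)))
      return(empty_region_events())
    fix_df(ev, chr_cols = c("chrom", "direction"),
           num_cols = c("start", "end"))
  }), names(x$region_events))
  truth <- list(
    patient = x$patient, topology = x$topology, tree = tree, ccf = ccf,
    variants = variants,
    germline = if (is.null(x$germline) || !length(x$germline)) NULL
               else fix_df(x$germline, int_cols = "pos", chr_cols = "chrom",
                           num_cols = "pop_af"),
    cna_events = if (is.null(x$cna_events) || !length(x$cna_events) ||
                     (is.data.frame(x$cna_events) && !nrow(x$cna_events)))
      data.frame(name = character(), chrom = character(), start = numeric(),
                 end = numeric(), direction = character(),
                 clone = character(), stringsAsFactors = FALSE)
    else fix_df(x$cna_events,
                chr_cols = c("name", "chrom", "direction", "clone"),
                num_cols = c("start", "end")),
    region_events = region_events,
    regions = fix_df(x$regions, int_cols = c("as", "n_variants"),
                     chr_cols = c("region", "grade", "subtype"),
                     num_cols = c("purity", "burden")),
    mu_available = x$mu_available, cna_class = x$cna_class,
    config = cfg)
  truth
}

#' Write a simulated cohort to a directory tree
#'
#' Layout: `manifest.json`, `config.json`, `arms.tsv`, `genes.tsv`,
#' `templates.tsv`, `truth.json`, and per patient
#' `patients/<id>/regions.tsv` plus per region one VCF per caller
#' (`<region>.M2.vcf`, ...), `<region>.ai.tsv`, `<region>.seg.tsv` and
#' `<region>.counts.tsv`. All files are plain text; re-reading with
#' [read_cohort()] reproduces the in-memory cohort exactly.
#'
#' @param cohort `ipmn_cohort` from [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create directory '%s'", out_dir)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(out_dir, f), auto_unbox = TRUE, digits = NA, null = "null",
    na = "null", pretty = TRUE)
  data.table::fwrite(cohort$arms, file.path(out_dir, "arms.tsv"), sep = "\t")
  data.table::fwrite(cohort$genes, file.path(out_dir, "genes.tsv"),
                     sep = "\t")
  write_template_set(cohort$templates, file.path(out_dir, "templates.tsv"))
  cfg <- cohort$config
  wj(unclass(cfg), "config.json")
  wj(lapply(cohort$patients, function(p) truth_to_list(p$truth)),
     "truth.json")
  manifest <- list(package = "ipmnevo", n_patients = length(cohort$patients),
                   patients = list())
  contigs <- chrom_lengths(cohort$arms)
  for (pid in names(cohort$patients)) {
    p <- cohort$patients[[pid]]
    pdir <- file.path(out_dir, "patients", pid)
    dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(p$truth$regions[, c("region", "grade", "purity")],
                       file.path(pdir, "regions.tsv"), sep = "\t")
    files <- list()
    for (r in names(p$data$calls)) {
      for (cl in names(p$data$calls[[r]])) {
        f <- sprintf("%s.%s.vcf", r, cl)
        write_vcf(p$data$calls[[r]][[cl]], file.path(pdir, f), contigs)
        files[[r]] <- c(files[[r]], f)
      }
      write_segments(p$data$segments[[r]]$ai,
                     file.path(pdir, sprintf("%s.ai.tsv", r)))
      write_segments(p$data$segments[[r]]$logr,
                     file.path(pdir, sprintf("%s.seg.tsv", r)))
      write_counts(p$data$expression[[r]],
                   file.path(pdir, sprintf("%s.counts.tsv", r)))
    }
    manifest$patients[[pid]] <- list(
      regions = p$truth$regions$region, mu_available = p$data$mu_available,
      vcfs = files)
  }
  wj(manifest, "manifest.json")
  invisible(out_dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return `ipmn_cohort`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"),
                                 simplifyVector = TRUE)
  cfg <- sim_config(
    n_patients = cfg_raw$n_patients,
    regions_per_patient = cfg_raw$regions_per_patient,
    mean_depth = cfg_raw$mean_depth,
    topology_mix = unlist(cfg_raw$topology_mix),
    n_clones = cfg_raw$n_clones,
    n_subclonal_snvs = cfg_raw$n_subclonal_snvs,
    purity_range = cfg_raw$purity_range,
    cna_menu = fix_df(cfg_raw$cna_menu,
                      chr_cols = c("name", "chrom", "direction")),
    caller_profiles = cfg_raw$caller_profiles,
    vaf_strata = cfg_raw$vaf_strata,
    mu_missing_prob = cfg_raw$mu_missing_prob,
    capture_mb = cfg_raw$capture_mb,
    expression = cfg_raw$expression,
    segment_noise_sd = cfg_raw$segment_noise_sd,
    logr_gain_level = cfg_raw$logr_gain_level,
    logr_loss_level = cfg_raw$logr_loss_level,
    cna_detect_ccf = cfg_raw$cna_detect_ccf,
    noiseless = cfg_raw$noiseless,
    seed = cfg_raw$seed)
  truth_raw <- jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE,
                                   simplifyMatrix = FALSE)
  patients <- list()
  for (pid in names(manifest$patients)) {
    m <- manifest$patients[[pid]]
    pdir <- file.path(dir, "patients", pid)
    truth <- list_to_truth(truth_raw[[pid]], cfg)
    calls <- segments <- expression <- list()
    for (r in unlist(m$regions)) {
      callers <- sub(sprintf("^%s\\.([A-Z0-9]+)\\.vcf$", r), "\\1",
                     unlist(m$vcfs[[r]]))
      calls[[r]] <- setNames(lapply(unlist(m$vcfs[[r]]), function(f)
        read_vcf(file.path(pdir, f))), callers)
      segments[[r]] <- list(
        ai = read_segments(file.path(pdir, sprintf("%s.ai.tsv", r))),
        logr = read_segments(file.path(pdir, sprintf("%s.seg.tsv", r))))
      expression[[r]] <- read_counts(file.path(pdir,
                                               sprintf("%s.counts.tsv", r)))
    }
    patients[[pid]] <- list(
      truth = truth,
      data = list(mu_available = isTRUE(m$mu_available), calls = calls,
                  segments = segments, expression = expression))
  }
  structure(list(
    config = cfg, patients = patients,
    templates = read_template_set(file.path(dir, "templates.tsv"),
                                  name = "synthetic"),
    arms = read_arm_table(file.path(dir, "arms.tsv")),
    genes = as.data.frame(data.table::fread(
      file.path(dir, "genes.tsv"), colClasses = list(character = "chrom")))),
    class = "ipmn_cohort")
}
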