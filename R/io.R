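#' Read a tumour/normal variant table
#'
#' Two dialects are supported. The flat TSV dialect has one column per
#' [validate_variants()] field (`chrom`, `pos`, `ref_allele`, `alt_allele`,
#' `tumour_alt_fwd`, `tumour_alt_rev`, `tumour_depth`, `control_alt_count`,
#' `control_depth`, `variant_class`, `region_class`, `effect_class`,
#' `known_snp_id`). The minimal VCF v4.2 dialect (read through
#' \pkg{VariantAnnotation}) carries two sample columns, `TUMOUR` and
#' `CONTROL`, with per-sample FORMAT fields `DP` (depth), `ADF` and `ADR`
#' (alt reads on the forward/reverse strand; the control's strand split is
#' not tracked, its alt count is `ADF + ADR`), the class annotations in the
#' INFO fields `VC`, `RC` and `EC`, and the known-SNP identifier in the ID
#' column.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return Validated variant data frame.
#' @export
read_variants <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  v <- if (format == "vcf") read_variants_vcf(path) else {
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c(known_snp_id = "character"))
  }
  v$known_snp_id[is.na(v$known_snp_id)] <- ""
  validate_variants(v)
  v
}

read_variants_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF requires the VariantAnnotation package", call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  geno <- VariantAnnotation::geno(vcf)
  info <- VariantAnnotation::info(vcf)
  ids <- names(rr)
  snp <- ifelse(grepl("^rs", ids), ids, "")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref_allele = as.character(rr$REF),
    alt_allele = vapply(rr$ALT, function(a) as.character(a)[1], character(1)),
    tumour_alt_fwd = as.integer(geno$ADF[, "TUMOUR"]),
    tumour_alt_rev = as.integer(geno$ADR[, "TUMOUR"]),
    tumour_depth = as.integer(geno$DP[, "TUMOUR"]),
    control_alt_count = as.integer(geno$ADF[, "CONTROL"]) +
      as.integer(geno$ADR[, "CONTROL"]),
    control_depth = as.integer(geno$DP[, "CONTROL"]),
    variant_class = as.character(info$VC),
    region_class = as.character(info$RC),
    effect_class = as.character(info$EC),
    known_snp_id = snp,
    stringsAsFactors = FALSE
  )
}

#' Write variant tables
#'
#' `write_variants_tsv()` writes the flat dialect; `write_variants_vcf()`
#' writes the minimal VCF v4.2 dialect described in [read_variants()].
#'
#' @param variants Validated variant data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  validate_variants(variants)
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_variants_tsv
#' @export
write_variants_vcf <- function(variants, path) {
  validate_variants(variants)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=gisttools",
    '##INFO=<ID=VC,Number=1,Type=String,Description="Variant class">',
    '##INFO=<ID=RC,Number=1,Type=String,Description="Region class">',
    '##INFO=<ID=EC,Number=1,Type=String,Description="Effect class">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste0('##FORMAT=<ID=ADF,Number=1,Type=Integer,Description=',
           '"Alt reads, forward strand (control: all alt reads)">'),
    paste0('##FORMAT=<ID=ADR,Number=1,Type=Integer,Description=',
           '"Alt reads, reverse strand">'),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TUMOUR", "CONTROL", sep = "\t")
  )
  id <- ifelse(variants$known_snp_id == "", ".", variants$known_snp_id)
  info <- sprintf("VC=%s;RC=%s;EC=%s", variants$variant_class,
                  variants$region_class, variants$effect_class)
  tum <- sprintf("%d:%d:%d", variants$tumour_depth,
                 variants$tumour_alt_fwd, variants$tumour_alt_rev)
  ctl <- sprintf("%d:%d:0", variants$control_depth,
                 variants$control_alt_count)
  rows <- paste(variants$chrom, variants$pos, id, variants$ref_allele,
                variants$alt_allele, ".", "PASS", info, "DP:ADF:ADR",
                tum, ctl, sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read and write screening-panel tables
#'
#' The panel TSV has columns `site_id`, `maf` (decimal minor allele
#' frequency, or `?` when unknown), `carriers` (number of panel samples
#' carrying the variant) and `panel_size`. Unknown MAFs become `NA`.
#'
#' @param path File path.
#' @return Data frame of screen sites.
#' @export
read_screen_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(maf = "character"))
  need <- c("site_id", "maf", "carriers", "panel_size")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("screen panel lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x$maf <- suppressWarnings(as.numeric(ifelse(x$maf %in% c("?", ""),
                                              NA, x$maf)))
  x
}

#' @rdname read_screen_panel
#' @param sites Screen-site data frame.
#' @export
write_screen_panel <- function(sites, path) {
  out <- sites
  out$maf <- ifelse(is.na(out$maf), "?", format(out$maf, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write methylation matrices
#'
#' Probes in rows (first column `probe_id`), samples in columns.
#'
#' @param path File path.
#' @return Numeric matrix, probes x samples, with probe/sample dimnames.
#' @export
read_methylation_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(x)[1] != "probe_id") {
    stop("first column of a methylation matrix must be `probe_id`",
         call. = FALSE)
  }
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$probe_id
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m))) stop("duplicate probe ids", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids", call. = FALSE)
  m
}

#' @rdname read_methylation_matrix
#' @param mat Probes x samples matrix.
#' @export
write_methylation_matrix <- function(mat, path) {
  out <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a chromosome-arm table
#'
#' BED-like TSV with columns `chrom`, `arm`, `start`, `end`; intervals are
#' 0-based, half-open.
#'
#' @param path File path.
#' @return Arm data frame.
#' @export
read_arms <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "arm", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("arm table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Packaged data: GIST founder-mutation candidates
#'
#' The thirteen protein-region candidate founding mutations identified in a
#' whole-genome-sequenced very low-risk gastric GIST (twelve SNVs, among
#' them the KIT V559A driver at 14 of 53 reads, plus one frameshift deletion
#' in RNF146), with the published per-site alt-read fractions.
#'
#' @return Data frame with columns `gene`, `consequence`, `variant_class`,
#'   `alt_count`, `coverage`, `dbsnp_id`.
#' @export
founder_candidates <- function() {
  utils::read.delim(gisttools_extdata("founder_candidates.tsv"),
                    stringsAsFactors = FALSE)
}

#' Packaged data: ZNF407 prevalence-screen panel
#'
#' Single-nucleotide variants found by sequencing exon 1 of ZNF407 across a
#' panel of 52 GIST samples: 117 point-mutation observations at 20 sites,
#' with 1000 Genomes minor allele frequencies where known (`?` for the five
#' sites without a population frequency).
#'
#' @return Screen-site data frame (see [read_screen_panel()]), plus
#'   annotation columns `aa_change` and `kind`.
#' @export
znf407_screen_panel <- function() {
  read_screen_panel(gisttools_extdata("znf407_screen_panel.tsv"))
}

#' Packaged data: ZNF407 zinc-finger motifs and substitutions
#'
#' The two published 22-residue C2H2 zinc-finger motifs of ZNF407 (fingers
#' reported at protein positions 705--728 and 1017--1040 of NP_060227;
#' the printed motif strings, treated as authoritative here, are 22-mers)
#' together with the three reported amino-acid substitutions and their
#' 1-based offsets within the motif strings.
#'
#' @return Data frame with columns `motif_id`, `aa_start`, `aa_end`,
#'   `motif_seq`, `variant`, `dbsnp_id`, `offset_in_motif`.
#' @export
znf407_zinc_fingers <- function() {
  utils::read.delim(gisttools_extdata("znf407_zinc_fingers.tsv"),
                    stringsAsFactors = FALSE)
}

gisttools_extdata <- function(file) {
  path <- system.file("extdata", file, package = "gisttools")
  if (path == "") stop("packaged file not found: ", file, call. = FALSE)
  path
}
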