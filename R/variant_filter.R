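#' Somatic-variant filter configuration
#'
#' @param min_depth Minimal sequencing depth required in both the tumour and
#'   the control sample (default 10; sites shallower than this give
#'   unreliable allele-frequency estimates).
#' @param max_control_alt Maximal number of alt reads tolerated in the
#'   control before a variant stops counting as somatic (default 0: "absent
#'   in the control").
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 10, max_control_alt = 0) {
  stopifnot(is.numeric(min_depth), length(min_depth) == 1L, min_depth >= 0,
            is.numeric(max_control_alt), length(max_control_alt) == 1L,
            max_control_alt >= 0)
  structure(list(min_depth = min_depth, max_control_alt = max_control_alt),
            class = "filter_config")
}

variant_columns <- c(
  "chrom", "pos", "ref_allele", "alt_allele",
  "tumour_alt_fwd", "tumour_alt_rev", "tumour_depth",
  "control_alt_count", "control_depth",
  "variant_class", "region_class", "effect_class", "known_snp_id"
)

variant_class_levels <- c("SNV", "insertion", "deletion")
region_class_levels <- c("exonic-coding", "exonic-noncoding",
                         "intronic", "intergenic")
effect_class_levels <- c("silent", "nonsynonymous", "frameshift",
                         "noncoding", "unknown")

#' Validate a tumour/normal variant table
#'
#' Checks presence of the per-strand allele-depth columns and the class
#' annotations, enforces count invariants (alt reads cannot exceed depth) and
#' rejects unknown enumeration values, naming the offending record and field.
#'
#' @param variants Data frame of variant records; see [read_variants()] for
#'   the column dialect.
#' @return The validated data frame, invisibly.
#' @export
validate_variants <- function(variants) {
  stopifnot(is.data.frame(variants))
  miss <- setdiff(variant_columns, names(variants))
  if (length(miss)) {
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(variants) == 0L) return(invisible(variants))
  loc <- paste0(variants$chrom, ":", variants$pos)
  check_enum <- function(col, levels) {
    bad <- which(!(variants[[col]] %in% levels))
    if (length(bad)) {
      stop("record ", loc[bad[1]], ": invalid ", col, " value ",
           deparse(as.character(variants[[col]][bad[1]])),
           " (expected one of ", paste(levels, collapse = ", "), ")",
           call. = FALSE)
    }
  }
  check_enum("variant_class", variant_class_levels)
  check_enum("region_class", region_class_levels)
  check_enum("effect_class", effect_class_levels)
  bad <- which(variants$tumour_alt_fwd + variants$tumour_alt_rev >
                 variants$tumour_depth)
  if (length(bad)) {
    stop("record ", loc[bad[1]],
         ": tumour alt reads exceed tumour depth", call. = FALSE)
  }
  bad <- which(variants$control_alt_count > variants$control_depth)
  if (length(bad)) {
    stop("record ", loc[bad[1]],
         ": control alt reads exceed control depth", call. = FALSE)
  }
  bad <- which(variants$pos < 1 | nchar(variants$ref_allele) == 0 |
                 nchar(variants$alt_allele) == 0)
  if (length(bad)) {
    stop("record ", loc[bad[1]], ": position must be >= 1 and alleles ",
         "non-empty", call. = FALSE)
  }
  invisible(variants)
}

#' Somatic, strand-support and depth predicates
#'
#' The three per-record predicates of the variant filter cascade. A variant
#' is *somatic* when the control sample shows at most `max_control_alt`
#' reads of the alternate allele ("present/absent in the control"); it has
#' *strand support* when the mutant allele was seen on both the forward and
#' the reverse strand (mutations supported by one strand only are sequencing
#' artefact candidates); it passes the *depth* filter when both samples
#' reach `min_depth` reads, so that the allele-frequency estimate is
#' reliable.
#'
#' @param variants Validated variant data frame.
#' @param max_control_alt Control alt-read tolerance (default 0).
#' @param min_depth Minimal depth in both samples (default 10).
#' @return Logical vector, one element per record.
#' @name variant_predicates
NULL

#' @rdname variant_predicates
#' @export
is_somatic <- function(variants, max_control_alt = 0) {
  variants$control_alt_count <= max_control_alt
}

#' @rdname variant_predicates
#' @export
strand_filter <- function(variants) {
  variants$tumour_alt_fwd >= 1 & variants$tumour_alt_rev >= 1
}

#' @rdname variant_predicates
#' @export
depth_filter <- function(variants, min_depth = 10) {
  variants$tumour_depth >= min_depth & variants$control_depth >= min_depth
}

cascade_stages <- c("input", "somatic", "strand_ok", "depth_ok",
                    "transcribed", "non_silent", "novel")

#' Run the somatic-variant filter cascade
#'
#' Applies, in fixed order: somatic (control alt reads within tolerance),
#' strand support on both strands, depth in both samples, transcribed region
#' (`region_class` exonic-coding or exonic-noncoding), non-silent effect,
#' and novelty (no known SNP identifier). Each record is removed at the
#' first stage it fails, which fixes the per-stage attrition counts; the
#' final survivor set does not depend on stage order since the stages are
#' independent predicates.
#'
#' @param variants Variant data frame (validated on entry).
#' @param config A [filter_config()].
#' @return A list of class `cascade_result` with elements `variants` (the
#'   surviving records) and `report`, a `filter_report`: named integer
#'   vector of survivor counts after each stage, starting at `input`.
#' @examples
#' sim <- simulate_variant_table(n_founder = 5, n_subclonal = 5,
#'                               n_germline_het = 5, seed = 1)
#' run_cascade(sim)$report
#' @export
run_cascade <- function(variants, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  validate_variants(variants)
  counts <- integer(length(cascade_stages))
  names(counts) <- cascade_stages
  counts["input"] <- nrow(variants)
  keep <- variants
  stage_keep <- list(
    somatic = function(v) is_somatic(v, config$max_control_alt),
    strand_ok = function(v) strand_filter(v),
    depth_ok = function(v) depth_filter(v, config$min_depth),
    transcribed = function(v)
      v$region_class %in% c("exonic-coding", "exonic-noncoding"),
    non_silent = function(v) v$effect_class != "silent",
    novel = function(v) is.na(v$known_snp_id) | v$known_snp_id == ""
  )
  for (stage in names(stage_keep)) {
    if (nrow(keep) > 0L) keep <- keep[stage_keep[[stage]](keep), , drop = FALSE]
    counts[stage] <- nrow(keep)
  }
  rownames(keep) <- NULL
  structure(
    list(variants = keep,
         report = structure(counts, class = "filter_report")),
    class = "cascade_result"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Variant filter cascade attrition:\n")
  for (s in names(x)) cat(sprintf("  %-11s %d\n", s, x[[s]]))
  invisible(x)
}

#' Write a filter report as JSON
#'
#' @param report A `filter_report` from [run_cascade()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(as.list(unclass(report)), path, auto_unbox = TRUE)
  invisible(path)
}
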