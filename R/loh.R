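#' Expected B-allele frequencies of a germline het site under monoallelic
#' loss
#'
#' In a sample of tumour purity `t` where the tumour cells have lost one
#' allele of a germline-heterozygous site, the retained allele contributes
#' reads from every cell while the lost allele is seen only in the admixed
#' normal cells. Out of an average `2 - t` allele copies per cell, `1` is
#' the retained allele and `1 - t` the lost one, so the observed B-allele
#' frequency concentrates at `(1 - t) / (2 - t)` or `1 / (2 - t)` depending
#' on which allele is the B allele. At `t = 0.65` these are approximately
#' 0.26 and 0.74 -- the symmetric bands away from 0.5 that reveal arm-level
#' LOH in an impure tumour.
#'
#' @param purity Tumour purity `t` in `[0, 1]`.
#' @return Numeric vector `c(lower, upper)`; the two components sum to 1.
#' @examples
#' expected_baf_under_loh(0.65)
#' @export
expected_baf_under_loh <- function(purity) {
  if (!is.numeric(purity) || length(purity) != 1L || is.na(purity) ||
      purity < 0 || purity > 1) {
    stop("`purity` must be a single number in [0, 1]", call. = FALSE)
  }
  c(lower = (1 - purity) / (2 - purity), upper = 1 / (2 - purity))
}

#' Estimate tumour purity from folded B-allele frequencies in an LOH region
#'
#' Inverts the mixture relation of [expected_baf_under_loh()]: with
#' `b` the median folded BAF (`min(f, 1 - f)`) of germline-het sites on an
#' arm under monoallelic loss, the purity estimate is
#' `t = (1 - 2 b) / (1 - b)`, clipped to `[0, 1]`.
#'
#' @param folded_baf Numeric vector of folded BAF values in `[0, 0.5]`.
#' @param min_sites Minimal number of sites required (default 20); fewer
#'   sites give an unreliable median and raise an error.
#' @return Purity estimate in `[0, 1]`.
#' @examples
#' estimate_purity_from_baf(rep(0.2593, 30))
#' @export
estimate_purity_from_baf <- function(folded_baf, min_sites = 20) {
  folded_baf <- folded_baf[!is.na(folded_baf)]
  if (length(folded_baf) < min_sites) {
    stop("purity estimation needs at least ", min_sites,
         " folded BAF values, got ", length(folded_baf), call. = FALSE)
  }
  if (any(folded_baf < 0 | folded_baf > 0.5 + 1e-12)) {
    stop("folded BAF values must lie in [0, 0.5]", call. = FALSE)
  }
  b <- stats::median(folded_baf)
  min(max((1 - 2 * b) / (1 - b), 0), 1)
}

#' Assign chromosome arms to SNP records
#'
#' @param snps SNP data frame with `chrom` and 1-based `pos`.
#' @param arms Arm table with `chrom`, `arm` and 0-based half-open
#'   `start`/`end` (see [read_arms()]).
#' @return `snps` with an `arm` column (`NA` where no arm covers the
#'   position).
#' @export
assign_arms <- function(snps, arms) {
  stopifnot(is.data.frame(snps), is.data.frame(arms))
  arm <- rep(NA_character_, nrow(snps))
  for (i in seq_len(nrow(arms))) {
    hit <- snps$chrom == arms$chrom[i] &
      snps$pos - 1 >= arms$start[i] & snps$pos - 1 < arms$end[i]
    arm[hit] <- arms$arm[i]
  }
  snps$arm <- arm
  snps
}

#' Per-arm B-allele-frequency and depth-ratio summaries with LOH calls
#'
#' Restricts the input to usable germline-heterozygous sites (control BAF
#' within `het_range` and depth of at least `min_depth` in both samples),
#' then summarises each chromosome arm: number of usable SNPs, median
#' folded tumour BAF, median tumour/control depth ratio after dividing each
#' sample's depths by its genome-wide median (removing library-size
#' effects), an LOH call, and -- for called arms with at least 20 usable
#' sites -- a purity estimate via [estimate_purity_from_baf()].
#'
#' The LOH call is `median_folded_baf < cutoff`. When `purity` is supplied,
#' the cutoff is the midpoint between 0.5 and the expected LOH BAF at that
#' purity; otherwise a fixed cutoff of 0.4 is used, which is robust to the
#' small-sample folding bias (the folded-BAF median of a truly diploid arm
#' sits below 0.5 by roughly `0.8 / sqrt(depth)`).
#'
#' @param snps Data frame with columns `chrom`, `arm` (or assign via
#'   [assign_arms()]), `pos`, `tumour_alt`, `tumour_depth`, `control_alt`,
#'   `control_depth`.
#' @param purity Optional known tumour purity in `[0, 1]`.
#' @param het_range Control-BAF window for selecting heterozygous sites
#'   (default `c(0.4, 0.6)`).
#' @param min_depth Minimal depth in both samples (default 10, matching the
#'   variant filter).
#' @param loh_cutoff Override the folded-BAF decision cutoff.
#' @return Data frame of class `arm_summary` with one row per arm: `chrom`,
#'   `arm`, `n_snps`, `median_folded_baf`, `depth_ratio`, `loh_call`,
#'   `purity_estimate`. Arms with no usable SNPs get `n_snps = 0` and `NA`
#'   statistics.
#' @examples
#' sim <- simulate_loh_genome(purity = 0.65, seed = 1)
#' summ <- arm_summaries(sim)
#' summ[summ$loh_call %in% TRUE, ]
#' @export
arm_summaries <- function(snps, purity = NULL, het_range = c(0.4, 0.6),
                          min_depth = 10, loh_cutoff = NULL) {
  need <- c("chrom", "arm", "pos", "tumour_alt", "tumour_depth",
            "control_alt", "control_depth")
  miss <- setdiff(need, names(snps))
  if (length(miss)) {
    stop("SNP table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(snps$tumour_alt > snps$tumour_depth) ||
      any(snps$control_alt > snps$control_depth)) {
    stop("alt counts exceed depth", call. = FALSE)
  }
  if (is.null(loh_cutoff)) {
    loh_cutoff <- if (is.null(purity)) 0.4 else
      (0.5 + expected_baf_under_loh(purity)[["lower"]]) / 2
  }
  # genome-wide per-sample depth normalisation (all input sites)
  med_t <- stats::median(snps$tumour_depth)
  med_c <- stats::median(snps$control_depth)
  control_baf <- snps$control_alt / snps$control_depth
  usable <- control_baf >= het_range[1] & control_baf <= het_range[2] &
    snps$tumour_depth >= min_depth & snps$control_depth >= min_depth
  arms <- unique(snps[, c("chrom", "arm")])
  arms <- arms[order(arms$chrom, arms$arm), , drop = FALSE]
  res <- lapply(seq_len(nrow(arms)), function(i) {
    on_arm <- snps$chrom == arms$chrom[i] & snps$arm == arms$arm[i]
    u <- snps[on_arm & usable, , drop = FALSE]
    n <- nrow(u)
    if (n == 0L) {
      return(data.frame(chrom = arms$chrom[i], arm = arms$arm[i],
                        n_snps = 0L, median_folded_baf = NA_real_,
                        depth_ratio = NA_real_, loh_call = NA,
                        purity_estimate = NA_real_,
                        stringsAsFactors = FALSE))
    }
    baf <- u$tumour_alt / u$tumour_depth
    folded <- pmin(baf, 1 - baf)
    mfb <- stats::median(folded)
    dr <- stats::median(u$tumour_depth / med_t) /
      stats::median(u$control_depth / med_c)
    call <- mfb < loh_cutoff
    pe <- if (call && n >= 20) estimate_purity_from_baf(folded) else NA_real_
    data.frame(chrom = arms$chrom[i], arm = arms$arm[i], n_snps = n,
               median_folded_baf = mfb, depth_ratio = dr, loh_call = call,
               purity_estimate = pe, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "loh_cutoff") <- loh_cutoff
  class(out) <- c("arm_summary", "data.frame")
  out
}
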