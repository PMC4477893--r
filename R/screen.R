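#' Expected mutant-allele count of a polymorphism in a diploid panel
#'
#' Under the population minor allele frequency `maf`, a panel of
#' `panel_size` diploid samples carries `2 * panel_size * maf` mutant
#' alleles in expectation.
#'
#' @param maf Minor allele frequency in `[0, 0.5]`; `NA` when unknown.
#' @param panel_size Number of samples in the panel.
#' @return Expected allele count (`NA` when `maf` is unknown). Vectorised.
#' @examples
#' expected_allele_count(0.0115, 52)
#' @export
expected_allele_count <- function(maf, panel_size) {
  stopifnot(is.numeric(panel_size), all(panel_size >= 1))
  if (any(!is.na(maf) & (maf < 0 | maf > 0.5))) {
    stop("known MAF values must lie in [0, 0.5]", call. = FALSE)
  }
  2 * panel_size * maf
}

#' Exact binomial enrichment test of screening-panel carrier counts
#'
#' Tests whether a polymorphism was observed in the panel more often than
#' its population minor allele frequency predicts. Each of the `carriers`
#' samples contributes `alleles_per_carrier` mutant alleles (default 1, a
#' conservative lower bound since zygosity is typically not recorded) and
#' the observed allele count is compared against
#' `Binomial(2 * panel_size, maf)` with a one-sided upper-tail exact
#' binomial test. Sites with unknown MAF are reported untested
#' (`NA` p-value and significance).
#'
#' @param sites Screen-site data frame with columns `site_id`, `maf`
#'   (`NA` = unknown), `carriers`, `panel_size`.
#' @param alpha Significance level (default 0.05); a site is significant
#'   when `p_value < alpha`.
#' @param alleles_per_carrier 1 (default) or 2 mutant alleles per carrier.
#' @return Data frame with one row per site: `site_id`, `maf`, `carriers`,
#'   `panel_size`, `expected_alleles`, `observed_alleles`, `p_value`,
#'   `significant`.
#' @examples
#' panel <- znf407_screen_panel()
#' head(enrichment_test(panel))
#' @export
enrichment_test <- function(sites, alpha = 0.05, alleles_per_carrier = 1) {
  stopifnot(is.data.frame(sites))
  need <- c("site_id", "maf", "carriers", "panel_size")
  miss <- setdiff(need, names(sites))
  if (length(miss)) {
    stop("screen table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!alleles_per_carrier %in% c(1, 2)) {
    stop("`alleles_per_carrier` must be 1 or 2", call. = FALSE)
  }
  bad <- which(sites$carriers < 0 | sites$carriers > sites$panel_size)
  if (length(bad)) {
    stop("carriers outside [0, panel_size] for site(s): ",
         paste(sites$site_id[bad], collapse = ", "), call. = FALSE)
  }
  n_alleles <- 2 * sites$panel_size
  observed <- sites$carriers * alleles_per_carrier
  p <- rep(NA_real_, nrow(sites))
  testable <- which(!is.na(sites$maf))
  for (i in testable) {
    p[i] <- stats::binom.test(observed[i], n_alleles[i], sites$maf[i],
                              alternative = "greater")$p.value
  }
  data.frame(
    site_id = sites$site_id,
    maf = sites$maf,
    carriers = sites$carriers,
    panel_size = sites$panel_size,
    expected_alleles = expected_allele_count(sites$maf, sites$panel_size),
    observed_alleles = observed,
    p_value = p,
    significant = ifelse(is.na(p), NA, p < alpha),
    stringsAsFactors = FALSE
  )
}

#' Test a whole screening panel and summarise it
#'
#' Runs [enrichment_test()] on every site of the panel and reports summary
#' bookkeeping: number of sites, the total number of observations (the sum
#' of per-site carrier counts), how many sites were testable (known MAF)
#' and how many were significantly enriched.
#'
#' @inheritParams enrichment_test
#' @param bonferroni If `TRUE`, divide `alpha` by the number of testable
#'   sites (off by default; the analysis this reproduces reported a single
#'   unadjusted significance claim).
#' @return List of class `screen_result` with elements `results` (per-site
#'   data frame) and `summary` (list: `n_sites`, `total_observations`,
#'   `n_testable`, `n_significant`, `alpha`).
#' @examples
#' sp <- screen_panel(znf407_screen_panel())
#' sp$summary
#' @export
screen_panel <- function(sites, alpha = 0.05, alleles_per_carrier = 1,
                         bonferroni = FALSE) {
  if (nrow(sites) > 0 && length(unique(sites$panel_size)) != 1L) {
    stop("inconsistent panel sizes across sites", call. = FALSE)
  }
  n_testable <- sum(!is.na(sites$maf))
  eff_alpha <- if (bonferroni && n_testable > 0) alpha / n_testable else alpha
  results <- enrichment_test(sites, alpha = eff_alpha,
                             alleles_per_carrier = alleles_per_carrier)
  structure(
    list(results = results,
         summary = list(
           n_sites = nrow(sites),
           total_observations = sum(sites$carriers),
           n_testable = n_testable,
           n_significant = sum(results$significant, na.rm = TRUE),
           alpha = eff_alpha)),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("Screening panel: %d sites, %d observations; ",
                     "%d testable, %d enriched at alpha = %g\n"),
              s$n_sites, s$total_observations, s$n_testable,
              s$n_significant, s$alpha))
  sig <- x$results[!is.na(x$results$significant) & x$results$significant, ]
  if (nrow(sig)) {
    cat("Enriched sites:\n")
    print(sig[, c("site_id", "maf", "observed_alleles", "expected_alleles",
                  "p_value")], row.names = FALSE)
  }
  invisible(x)
}
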