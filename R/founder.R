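#' Parameters of the binomial founder-mutation model
#'
#' Sequencing of a heterozygous somatic mutation from an impure tumour sample
#' is modelled as a Bernoulli process: each of the `n` reads covering the
#' site carries the mutant allele independently with success probability
#' `q = purity * het_factor`. With tumour purity `p` and a heterozygous
#' diploid site, `het_factor = 1/2` and `q = p/2`: only the tumour-cell
#' fraction contributes mutant DNA, and only one of its two alleles is
#' mutant. A mutation present in (essentially) all tumour cells -- a
#' *founding* mutation -- then shows an alt-read count
#' `X ~ Binomial(n, q)`.
#'
#' @param purity Fraction of cells in the sample that are tumour cells, in
#'   `(0, 1]`. Default 0.6, the lower end of a typical histological estimate
#'   of 60--70% and the value under which the default threshold table is
#'   calibrated.
#' @param het_factor Allele-dosage factor, in `(0, 1]`. `1/2` (default) for a
#'   heterozygous diploid site; use `1` for hemizygous sites, e.g. on an arm
#'   under monoallelic loss.
#' @param inclusion Designed sensitivity of the classifier, in `(0, 1)`:
#'   the expected fraction of true founding mutations that pass the
#'   threshold. Default 0.95.
#'
#' @return An object of class `founder_params`: a list with elements
#'   `purity`, `het_factor`, `inclusion` and the derived per-read success
#'   probability `q`.
#' @seealso [founder_threshold()], [classify_founder()]
#' @examples
#' founder_params()
#' founder_params(purity = 0.65)
#' @export
founder_params <- function(purity = 0.6, het_factor = 0.5, inclusion = 0.95) {
  if (!is.numeric(purity) || length(purity) != 1L || is.na(purity) ||
      purity <= 0 || purity > 1) {
    stop("`purity` must be a single number in (0, 1], got ",
         deparse(purity), call. = FALSE)
  }
  if (!is.numeric(het_factor) || length(het_factor) != 1L ||
      is.na(het_factor) || het_factor <= 0 || het_factor > 1) {
    stop("`het_factor` must be a single number in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(inclusion) || length(inclusion) != 1L || is.na(inclusion) ||
      inclusion <= 0 || inclusion >= 1) {
    stop("`inclusion` must be a single number in (0, 1), got ",
         deparse(inclusion), call. = FALSE)
  }
  structure(
    list(purity = purity, het_factor = het_factor, inclusion = inclusion,
         q = purity * het_factor),
    class = "founder_params"
  )
}

#' @export
print.founder_params <- function(x, ...) {
  cat("Binomial founder-mutation model parameters\n")
  cat(sprintf("  purity:     %.3f\n", x$purity))
  cat(sprintf("  het_factor: %.3f  (per-read success q = %.3f)\n",
              x$het_factor, x$q))
  cat(sprintf("  inclusion:  %.3f\n", x$inclusion))
  invisible(x)
}

as_founder_params <- function(params) {
  if (inherits(params, "founder_params")) return(params)
  if (is.list(params)) return(do.call(founder_params, params))
  stop("`params` must be a founder_params object; see founder_params()",
       call. = FALSE)
}

# Exact upper tail P(X >= k), X ~ Binomial(n, q), summing pmf terms from the
# smallest outward. Threshold boundaries near n ~ 30 are decided by tail-mass
# differences of ~3e-3, so the summation order is fixed rather than left to
# chance.
binom_upper_tail <- function(k, n, q) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  terms <- stats::dbinom(k:n, n, q)
  sum(sort(terms))
}

#' Minimal alt-read count for a founding mutation at a given coverage
#'
#' Returns the threshold `k(n)`: the largest `k >= 1` such that a true
#' founding mutation, with alt-read count `X ~ Binomial(n, q)`, satisfies
#' `P(X >= k) >= inclusion`. A mutation supported by at least `k(n)` of `n`
#' reads is deemed consistent with presence in the majority of tumour cells
#' while guaranteeing that at least the `inclusion` fraction (by default 95%)
#' of true founding mutations pass. When no `k >= 1` achieves the required
#' tail mass (very low coverage), the threshold is floored at 1 so that a
#' call always needs at least one supporting read.
#'
#' At the default parameters (purity 0.6, heterozygous factor 1/2,
#' inclusion 0.95) the threshold is 1 for `n <= 13`, first reaches 2 at
#' `n = 14`, 5 at `n = 28`, 6 at `n = 33` and 7 at `n = 37`.
#'
#' @param n Coverage (number of reads) at the site; positive integer,
#'   vectorised.
#' @param params A [founder_params()] object.
#' @return Integer vector of thresholds, same length as `n`.
#' @examples
#' founder_threshold(c(13, 14, 28, 33, 37), founder_params())
#' @export
founder_threshold <- function(n, params = founder_params()) {
  params <- as_founder_params(params)
  if (!is.numeric(n) || length(n) == 0L || anyNA(n) ||
      any(n < 1) || any(n != floor(n))) {
    stop("`n` must be positive integer coverage value(s)", call. = FALSE)
  }
  vapply(as.integer(n), function(ni) {
    # tail P(X >= k) is non-increasing in k; scan k upward until it drops
    # below the inclusion level
    k <- 1L
    while (k <= ni && binom_upper_tail(k, ni, params$q) >= params$inclusion) {
      k <- k + 1L
    }
    max(k - 1L, 1L)
  }, integer(1))
}

#' Tabulate founder thresholds over a coverage range
#'
#' @param n_min,n_max Inclusive coverage range, `1 <= n_min <= n_max`.
#' @param params A [founder_params()] object.
#' @return A data frame of class `threshold_table` with columns `n`
#'   (coverage) and `k` (minimal alt-read count); the parameters are attached
#'   as attribute `params`. `k` is non-decreasing in `n`.
#' @examples
#' build_threshold_table(10, 40)
#' @export
build_threshold_table <- function(n_min, n_max, params = founder_params()) {
  params <- as_founder_params(params)
  ok <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x == floor(x)
  if (!ok(n_min) || !ok(n_max) || n_min < 1 || n_min > n_max) {
    stop("need integer coverage range with 1 <= n_min <= n_max", call. = FALSE)
  }
  n <- seq.int(n_min, n_max)
  tab <- data.frame(n = as.integer(n),
                    k = founder_threshold(n, params))
  attr(tab, "params") <- params
  class(tab) <- c("threshold_table", "data.frame")
  tab
}

#' Classify mutations as founding from alt-read support
#'
#' A mutation is classified as a potential founding mutation when at least
#' `founder_threshold(coverage)` of its `coverage` reads carry the mutant
#' allele.
#'
#' @param alt_count Number of reads carrying the mutation; vectorised.
#' @param coverage Total reads at the site; vectorised, recycled with
#'   `alt_count`.
#' @param params A [founder_params()] object.
#' @return Logical vector.
#' @examples
#' classify_founder(14, 53)  # KIT V559A read support: founding
#' classify_founder(1, 100)  # far below the 95%-inclusion threshold
#' @export
classify_founder <- function(alt_count, coverage, params = founder_params()) {
  params <- as_founder_params(params)
  if (!is.numeric(alt_count) || !is.numeric(coverage) ||
      anyNA(alt_count) || anyNA(coverage)) {
    stop("`alt_count` and `coverage` must be numeric and non-missing",
         call. = FALSE)
  }
  n <- length(alt_count)
  m <- length(coverage)
  if (n != m) {
    len <- max(n, m)
    alt_count <- rep_len(alt_count, len)
    coverage <- rep_len(coverage, len)
  }
  if (any(coverage < 1)) stop("`coverage` must be >= 1", call. = FALSE)
  if (any(alt_count < 0)) stop("`alt_count` must be >= 0", call. = FALSE)
  bad <- which(alt_count > coverage)
  if (length(bad)) {
    stop("alt_count exceeds coverage at position(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  alt_count >= founder_threshold(coverage, params)
}

#' Count single-nucleotide variants passing the founder classifier
#'
#' Applies [classify_founder()] to a table of candidate mutations and counts
#' how many rows labelled as SNVs pass. Indels are classified too (their
#' pass/fail status is returned in the attribute `pass`) but only SNV rows
#' contribute to the count.
#'
#' @param variants Data frame with columns `alt_count`, `coverage` and
#'   `variant_class` (`"SNV"`, `"insertion"` or `"deletion"`); an optional
#'   identifier column (`gene`, `site_id` or `id`) is used in error messages.
#' @param params A [founder_params()] object.
#' @return Integer count of SNV rows passing, with the full logical pass
#'   vector attached as attribute `pass`.
#' @examples
#' cand <- founder_candidates()
#' count_founder_snvs(cand)
#' @export
count_founder_snvs <- function(variants, params = founder_params()) {
  params <- as_founder_params(params)
  stopifnot(is.data.frame(variants))
  if (nrow(variants) == 0L) {
    return(structure(0L, pass = logical(0)))
  }
  need <- c("alt_count", "coverage", "variant_class")
  miss <- setdiff(need, names(variants))
  if (length(miss)) {
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  idcol <- intersect(c("gene", "site_id", "id"), names(variants))
  ids <- if (length(idcol)) as.character(variants[[idcol[1]]]) else
    paste0("row ", seq_len(nrow(variants)))
  bad <- which(!is.finite(variants$alt_count) |
                 !is.finite(variants$coverage) |
                 variants$alt_count < 0 | variants$coverage < 1 |
                 variants$alt_count > variants$coverage)
  if (length(bad)) {
    stop("malformed alt_count/coverage for: ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  pass <- classify_founder(variants$alt_count, variants$coverage, params)
  n <- sum(pass & variants$variant_class == "SNV")
  structure(as.integer(n), pass = pass)
}
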