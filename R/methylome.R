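#' Normalise a probe read-out against reference anchor signals
#'
#' Array methylation probes differ in dynamic range, consistently across
#' samples. Given per-probe reference intensities at the fully unmethylated
#' (`ref_low`) and fully methylated (`ref_high`) state, a raw read-out is
#' rescaled linearly between the anchors and clipped into `[0, 1]`,
#' yielding a value comparable to the conventional beta value.
#'
#' @param raw_value Non-negative raw intensity; vectorised.
#' @param ref_low,ref_high Reference intensities, `ref_high > ref_low >= 0`;
#'   recycled against `raw_value`.
#' @return Normalised value(s) in `[0, 1]`.
#' @examples
#' normalize_probe(c(100, 550, 2000), ref_low = 100, ref_high = 1000)
#' @export
normalize_probe <- function(raw_value, ref_low, ref_high) {
  if (any(is.na(ref_low)) || any(is.na(ref_high)) ||
      any(ref_high <= ref_low) || any(ref_low < 0)) {
    stop("need ref_high > ref_low >= 0 for every probe", call. = FALSE)
  }
  if (any(raw_value < 0, na.rm = TRUE)) {
    stop("raw intensities must be non-negative", call. = FALSE)
  }
  pmin(pmax((raw_value - ref_low) / (ref_high - ref_low), 0), 1)
}

#' Normalise a raw intensity matrix with per-probe reference anchors
#'
#' @param mat Probes x samples matrix of raw intensities, probe ids as
#'   rownames.
#' @param reference Data frame with columns `probe_id`, `ref_low`,
#'   `ref_high`; every probe of `mat` must be present.
#' @return Matrix of normalised values in `[0, 1]`.
#' @export
normalize_matrix <- function(mat, reference) {
  stopifnot(is.matrix(mat), is.data.frame(reference))
  need <- c("probe_id", "ref_low", "ref_high")
  miss <- setdiff(need, names(reference))
  if (length(miss)) {
    stop("reference lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(rownames(mat), reference$probe_id)
  if (anyNA(idx)) {
    stop("no reference anchors for probe(s): ",
         paste(utils::head(rownames(mat)[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  lo <- reference$ref_low[idx]
  hi <- reference$ref_high[idx]
  out <- normalize_probe(mat, lo, hi)
  dimnames(out) <- dimnames(mat)
  out
}

#' Beta values from methylated/unmethylated channel intensities
#'
#' Conventional alternative to the reference-anchor rescale:
#' `M / (M + U + offset)`.
#'
#' @param meth,unmeth Non-negative intensity matrices or vectors of the
#'   methylated and unmethylated channel.
#' @param offset Stabilising offset (default 100).
#' @return Beta values in `[0, 1)`.
#' @export
beta_from_intensities <- function(meth, unmeth, offset = 100) {
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE)) {
    stop("channel intensities must be non-negative", call. = FALSE)
  }
  meth / (meth + unmeth + offset)
}

#' Select probes by across-sample variance
#'
#' Keeps probes whose sample variance (n - 1 denominator) across samples
#' strictly exceeds `threshold`. The conventional cutoff of 0.1 extracts
#' probes that differ substantially between sample groups while dropping
#' the constant background.
#'
#' @param mat Probes x samples matrix of normalised values.
#' @param threshold Variance cutoff (default 0.1).
#' @return Character vector of retained probe ids (or integer indices when
#'   `mat` has no rownames).
#' @examples
#' sim <- simulate_methylation(seed = 1)
#' length(variance_filter(sim$matrix, threshold = 0.05))
#' @export
variance_filter <- function(mat, threshold = 0.1) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2L) {
    stop("variance is undefined with fewer than 2 samples", call. = FALSE)
  }
  v <- apply(mat, 1L, stats::var)
  keep <- which(v > threshold)
  if (is.null(rownames(mat))) keep else rownames(mat)[keep]
}

#' Cluster samples by Pearson-correlation distance, complete linkage
#'
#' Computes pairwise sample distances `d(a, b) = 1 - r(a, b)` (Pearson
#' correlation across probes; anticorrelated profiles are maximally
#' distant at `d = 2`) and agglomerates with complete linkage. The
#' agglomeration is deterministic given the input sample order.
#'
#' @param mat Probes x samples matrix (typically restricted to
#'   variance-filtered probes).
#' @return List of class `methyl_clust` with elements `hclust` (a
#'   [stats::hclust] tree over samples), `dist` (the distance object) and
#'   `n_probes`.
#' @examples
#' sim <- simulate_methylation(seed = 1)
#' cl <- cluster_samples(sim$matrix)
#' cut_clusters(cl, 2)
#' @export
cluster_samples <- function(mat) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2L || nrow(mat) < 2L) {
    stop("clustering needs at least 2 samples and 2 probes", call. = FALSE)
  }
  sds <- apply(mat, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance sample(s): ",
         paste(colnames(mat)[sds == 0], collapse = ", "),
         " (correlation undefined)", call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(mat))
  hc <- stats::hclust(d, method = "complete")
  structure(list(hclust = hc, dist = d, n_probes = nrow(mat)),
            class = "methyl_clust")
}

#' @rdname cluster_samples
#' @param clust A `methyl_clust` object.
#' @param k Number of flat clusters to cut the dendrogram into.
#' @return `cut_clusters()`: named integer vector of cluster labels.
#' @export
cut_clusters <- function(clust, k) {
  stopifnot(inherits(clust, "methyl_clust"))
  stats::cutree(clust$hclust, k = k)
}

#' Export a sample dendrogram in Newick format
#'
#' @param clust A `methyl_clust` object from [cluster_samples()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clust, path) {
  stopifnot(inherits(clust, "methyl_clust"))
  phy <- ape::as.phylo(clust$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
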