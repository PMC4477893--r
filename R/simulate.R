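with_sim_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

sim_depth <- function(n, depth_mean, depth_model, dispersion) {
  d <- switch(depth_model,
    poisson = stats::rpois(n, depth_mean),
    `negative-binomial` = stats::rnbinom(n, mu = depth_mean,
                                         size = dispersion),
    stop("depth_model must be 'poisson' or 'negative-binomial'",
         call. = FALSE))
  pmax(d, 1L)
}

#' Simulate a tumour/normal variant table with known truth
#'
#' Generates variant records at the read-count level under the same model
#' the founder classifier assumes. Founder variants draw their tumour
#' alt count from `Binomial(n, purity/2)` (heterozygous, present in all
#' tumour cells); subclonal variants from `Binomial(n, purity * c / 2)`
#' with a per-variant clone fraction `c` drawn uniformly from
#' `clone_fraction_range`; germline heterozygous variants from
#' `Binomial(n, 1/2)` in both samples. Alt reads are split across strands
#' as `Binomial(alt, 1/2)`. Somatic records show control alt reads only at
#' `control_error_rate` (default 0, "absent in the control"). Germline
#' records are annotated with a known-SNP identifier; somatic records are
#' novel, exonic-coding and non-silent, so the filter cascade and founder
#' classifier can be scored against the attached truth labels.
#'
#' @param n_founder,n_subclonal,n_germline_het Number of records per class.
#' @param purity Tumour purity in `(0, 1]` (default 0.6).
#' @param depth_mean Mean sequencing depth (default 45, bracketing typical
#'   tumour/control genome coverages of about 42 and 50).
#' @param depth_model `"poisson"` (default) or `"negative-binomial"`.
#' @param dispersion Negative-binomial size parameter (default 5).
#' @param clone_fraction_range Uniform range of subclone cell fractions
#'   (default `c(0.05, 0.3)`).
#' @param control_error_rate Per-read probability of a spurious alt read in
#'   the control for somatic records (default 0).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return Variant data frame (see [validate_variants()]) with an extra
#'   `truth` column (`"founder"`, `"subclonal"`, `"germline"`).
#' @examples
#' head(simulate_variant_table(n_founder = 3, seed = 1))
#' @export
simulate_variant_table <- function(n_founder = 200, n_subclonal = 100,
                                   n_germline_het = 200, purity = 0.6,
                                   depth_mean = 45,
                                   depth_model = "poisson", dispersion = 5,
                                   clone_fraction_range = c(0.05, 0.3),
                                   control_error_rate = 0, seed = NULL) {
  stopifnot(n_founder >= 0, n_subclonal >= 0, n_germline_het >= 0,
            purity > 0, purity <= 1, depth_mean > 0)
  with_sim_seed(seed, {
    n <- n_founder + n_subclonal + n_germline_het
    truth <- rep(c("founder", "subclonal", "germline"),
                 c(n_founder, n_subclonal, n_germline_het))
    t_depth <- sim_depth(n, depth_mean, depth_model, dispersion)
    c_depth <- sim_depth(n, depth_mean, depth_model, dispersion)
    vaf <- c(
      rep(purity / 2, n_founder),
      purity * stats::runif(n_subclonal, clone_fraction_range[1],
                            clone_fraction_range[2]) / 2,
      rep(0.5, n_germline_het)
    )
    alt <- stats::rbinom(n, t_depth, vaf)
    alt_fwd <- stats::rbinom(n, alt, 0.5)
    somatic <- truth != "germline"
    control_alt <- integer(n)
    control_alt[somatic] <- stats::rbinom(sum(somatic), c_depth[somatic],
                                          control_error_rate)
    control_alt[!somatic] <- stats::rbinom(sum(!somatic),
                                           c_depth[!somatic], 0.5)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt_allele <- vapply(ref, function(r)
      sample(setdiff(bases, r), 1L), character(1))
    out <- data.frame(
      chrom = sample(paste0("chr", 1:22), n, replace = TRUE),
      pos = sample.int(2e8L, n, replace = TRUE),
      ref_allele = ref,
      alt_allele = alt_allele,
      tumour_alt_fwd = alt_fwd,
      tumour_alt_rev = alt - alt_fwd,
      tumour_depth = t_depth,
      control_alt_count = pmin(control_alt, c_depth),
      control_depth = c_depth,
      variant_class = "SNV",
      region_class = ifelse(somatic, "exonic-coding", "intronic"),
      effect_class = ifelse(somatic, "nonsynonymous", "unknown"),
      known_snp_id = ifelse(somatic, "",
                            paste0("rsSIM", seq_len(n))),
      truth = truth,
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
  })
}

#' Default chromosome-arm table for simulations
#'
#' Forty-four synthetic autosome arms (`1p` .. `22q`), each 100 Mb, with
#' 0-based half-open coordinates (p arm `[0, 1e8)`, q arm `[1e8, 2e8)`).
#'
#' @return Arm data frame (`chrom`, `arm`, `start`, `end`).
#' @export
default_arms <- function() {
  data.frame(
    chrom = rep(paste0("chr", 1:22), each = 2),
    arm = paste0(rep(1:22, each = 2), c("p", "q")),
    start = rep(c(0, 1e8), 22),
    end = rep(c(1e8, 2e8), 22)
  )
}

#' Simulate germline-het SNP allele counts with one arm under LOH
#'
#' Every arm carries `n_snps_per_arm` germline heterozygous SNPs; control
#' alt counts are `Binomial(depth, 1/2)`. On diploid arms the tumour
#' behaves identically. On `loh_arm` the tumour has lost one allele in all
#' tumour cells: the tumour depth is scaled by `(2 - t) / 2` (one of two
#' copies gone in the tumour fraction) and the alt count is drawn at BAF
#' `(1 - t) / (2 - t)` or `1 / (2 - t)` with random phase.
#'
#' @param purity Tumour purity `t` (default 0.65, a typical histological
#'   estimate).
#' @param n_snps_per_arm SNPs per arm (default 500).
#' @param depth_mean Mean depth (default 45).
#' @param loh_arm Arm label carrying the loss (default `"14q"`; `NULL` or
#'   purity 0 for a fully diploid genome).
#' @param arms Arm table (default [default_arms()]).
#' @param seed Integer seed.
#' @return SNP data frame (`chrom`, `arm`, `pos`, `tumour_alt`,
#'   `tumour_depth`, `control_alt`, `control_depth`) with attribute
#'   `truth`: list with `loh_arm` and `purity`.
#' @examples
#' sim <- simulate_loh_genome(purity = 0.65, n_snps_per_arm = 100, seed = 1)
#' attr(sim, "truth")
#' @export
simulate_loh_genome <- function(purity = 0.65, n_snps_per_arm = 500,
                                depth_mean = 45, loh_arm = "14q",
                                arms = default_arms(), seed = NULL) {
  stopifnot(purity >= 0, purity <= 1, n_snps_per_arm >= 1)
  if (!is.null(loh_arm) && !loh_arm %in% arms$arm) {
    stop("loh_arm ", deparse(loh_arm), " not in the arm table",
         call. = FALSE)
  }
  with_sim_seed(seed, {
    per_arm <- lapply(seq_len(nrow(arms)), function(i) {
      n <- n_snps_per_arm
      is_loh <- !is.null(loh_arm) && arms$arm[i] == loh_arm && purity > 0
      c_depth <- pmax(stats::rpois(n, depth_mean), 1L)
      t_mean <- if (is_loh) depth_mean * (2 - purity) / 2 else depth_mean
      t_depth <- pmax(stats::rpois(n, t_mean), 1L)
      if (is_loh) {
        baf <- expected_baf_under_loh(purity)
        p_t <- ifelse(stats::runif(n) < 0.5, baf[["lower"]],
                      baf[["upper"]])
      } else {
        p_t <- rep(0.5, n)
      }
      data.frame(
        chrom = arms$chrom[i],
        arm = arms$arm[i],
        pos = sort(sample(seq.int(arms$start[i] + 1L, arms$end[i]), n)),
        tumour_alt = stats::rbinom(n, t_depth, p_t),
        tumour_depth = t_depth,
        control_alt = stats::rbinom(n, c_depth, 0.5),
        control_depth = c_depth,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, per_arm)
    rownames(out) <- NULL
    attr(out, "truth") <- list(
      loh_arm = if (purity > 0) loh_arm else NULL, purity = purity)
    out
  })
}

#' Default screening-panel minor allele frequencies
#'
#' The fifteen known 1000 Genomes minor allele frequencies of the packaged
#' ZNF407 prevalence screen, padded with five typical values to a 20-site
#' panel.
#'
#' @return Numeric vector of length 20.
#' @export
default_screen_mafs <- function() {
  panel <- znf407_screen_panel()
  c(panel$maf[!is.na(panel$maf)], c(0.01, 0.02, 0.05, 0.1, 0.25))
}

#' Simulate screening-panel carrier counts
#'
#' Each of `panel_size` diploid samples carries a variant with probability
#' `1 - (1 - maf)^2` (at least one mutant allele under
#' `Binomial(2, maf)`); the carrier count per site is the number of such
#' samples. Sites flagged `enriched` draw from an inflated frequency
#' `min(maf * enrichment_multiplier, 0.5)`, emulating a
#' disease-association signal on top of the population frequency.
#'
#' @param mafs Per-site minor allele frequencies (default
#'   [default_screen_mafs()]).
#' @param enriched Logical vector (or site indices) marking enriched sites
#'   (default: none).
#' @param enrichment_multiplier Frequency inflation for enriched sites
#'   (default 8).
#' @param panel_size Number of samples (default 52).
#' @param seed Integer seed.
#' @return Screen-site data frame with `truth_enriched` column.
#' @examples
#' simulate_screen_panel(enriched = 1, seed = 1)[1:3, ]
#' @export
simulate_screen_panel <- function(mafs = default_screen_mafs(),
                                  enriched = logical(length(mafs)),
                                  enrichment_multiplier = 8,
                                  panel_size = 52, seed = NULL) {
  stopifnot(all(mafs >= 0), all(mafs <= 0.5), panel_size >= 1)
  if (is.numeric(enriched)) {
    idx <- enriched
    enriched <- logical(length(mafs))
    enriched[idx] <- TRUE
  }
  stopifnot(length(enriched) == length(mafs))
  with_sim_seed(seed, {
    eff <- ifelse(enriched, pmin(mafs * enrichment_multiplier, 0.5), mafs)
    p_carrier <- 1 - (1 - eff)^2
    data.frame(
      site_id = sprintf("site%02d", seq_along(mafs)),
      maf = mafs,
      carriers = stats::rbinom(length(mafs), panel_size, p_carrier),
      panel_size = panel_size,
      truth_enriched = enriched,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a two-group methylation matrix
#'
#' Emulates the contrast between a globally hypermethylated and a
#' normal-like methylome block: `n_informative` probes take group-specific
#' means (`group_means[g]` for samples of group `g`) with Gaussian noise
#' `noise_sd`; `n_background` probes share a per-probe mean drawn from a
#' bimodal `Beta(0.5, 0.5)` (the typical U-shape of methylation beta
#' values) with small noise `background_sd`, hence low across-sample
#' variance. All values are clipped to `[0, 1]`.
#'
#' @param group_sizes Samples per group (default `c(10, 10)`).
#' @param group_means Informative-probe means per group (default
#'   `c(0.8, 0.2)`).
#' @param fraction_reversed Fraction of informative probes whose group
#'   means are reversed (default 0: a one-directional hypermethylated
#'   block). Real group contrasts usually run in both directions; a
#'   two-directional block (e.g. 0.5) is also what Pearson-correlation
#'   clustering needs when the background probes are filtered out first,
#'   since a one-directional block alone leaves every sample vector flat
#'   up to noise.
#' @param n_informative Number of group-informative probes (default 200).
#' @param n_background Number of background probes (default 2000).
#' @param background_sd Across-sample noise of background probes (default
#'   0.01).
#' @param seed Integer seed.
#' @return List with `matrix` (probes x samples) and `truth` (list:
#'   `groups` named integer vector, `informative_probes` character vector).
#' @examples
#' sim <- simulate_methylation(seed = 1)
#' dim(sim$matrix)
#' @export
simulate_methylation <- function(group_sizes = c(10, 10),
                                 group_means = c(0.8, 0.2),
                                 fraction_reversed = 0,
                                 noise_sd = 0.05, n_informative = 200,
                                 n_background = 2000, background_sd = 0.01,
                                 seed = NULL) {
  stopifnot(length(group_sizes) == length(group_means),
            all(group_sizes >= 1), n_informative >= 0, n_background >= 0,
            fraction_reversed >= 0, fraction_reversed <= 1)
  with_sim_seed(seed, {
    n_samples <- sum(group_sizes)
    groups <- rep(seq_along(group_sizes), group_sizes)
    sample_ids <- sprintf("S%02d_g%d", seq_len(n_samples), groups)
    n_rev <- round(n_informative * fraction_reversed)
    means <- matrix(rep(group_means[groups], each = n_informative),
                    nrow = n_informative, ncol = n_samples)
    if (n_rev > 0) {
      means[seq_len(n_rev), ] <- matrix(rev(group_means)[groups],
                                        nrow = n_rev, ncol = n_samples,
                                        byrow = TRUE)
    }
    inf <- means +
      matrix(stats::rnorm(n_informative * n_samples, 0, noise_sd),
             n_informative, n_samples)
    bg_mean <- stats::rbeta(n_background, 0.5, 0.5)
    bg <- matrix(bg_mean, n_background, n_samples) +
      matrix(stats::rnorm(n_background * n_samples, 0, background_sd),
             n_background, n_samples)
    m <- rbind(inf, bg)
    m <- pmin(pmax(m, 0), 1)
    rownames(m) <- c(sprintf("cgINF%05d", seq_len(n_informative)),
                     sprintf("cgBG%05d", seq_len(n_background)))[
                       seq_len(nrow(m))]
    colnames(m) <- sample_ids
    list(matrix = m,
         truth = list(groups = stats::setNames(groups, sample_ids),
                      informative_probes =
                        rownames(m)[seq_len(n_informative)]))
  })
}

#' Simulate a protein with planted C2H2 zinc fingers
#'
#' Builds a random amino-acid background free of cysteine and histidine
#' (so no spurious fingers can arise), plants `n_fingers` zinc-finger
#' motifs at known, recorded coordinates separated by at least
#' `min_separation` residues, and places one variant inside each planted
#' finger at a recorded offset. By default the first two planted fingers
#' are the two published 22-residue ZNF407 motifs; additional fingers use
#' the canonical `C-x(2)-C-x(12)-H-x(3)-H` spacing with random spacer
#' residues.
#'
#' @param n_fingers Number of fingers to plant (default 2, max 22).
#' @param use_znf407_motifs Plant the packaged ZNF407 motif strings first
#'   (default `TRUE`).
#' @param min_separation Minimal background stretch between fingers
#'   (default 12).
#' @param seed Integer seed.
#' @return List: `sequence` (string), `fingers` (data frame `start`, `end`,
#'   `motif_seq`), `variants` (data frame `position`, `ref_aa`, `alt_aa`,
#'   `finger_index`, `offset_in_motif`).
#' @examples
#' prot <- simulate_zf_protein(seed = 1)
#' scan_c2h2(prot$sequence)
#' @export
simulate_zf_protein <- function(n_fingers = 2, use_znf407_motifs = TRUE,
                                min_separation = 12, seed = NULL) {
  stopifnot(n_fingers >= 1, n_fingers <= 22, min_separation >= 10)
  background <- setdiff(AA_ALPHABET, c("C", "H"))
  with_sim_seed(seed, {
    known <- unique(znf407_zinc_fingers()$motif_seq)
    motifs <- character(n_fingers)
    take <- if (use_znf407_motifs) min(n_fingers, length(known)) else 0L
    if (take > 0) motifs[seq_len(take)] <- known[seq_len(take)]
    for (i in seq_len(n_fingers)) {
      if (i <= take) next
      spacers <- vapply(c(2, 12, 3), function(len)
        paste(sample(background, len, replace = TRUE), collapse = ""),
        character(1))
      motifs[i] <- paste0("C", spacers[1], "C", spacers[2], "H",
                          spacers[3], "H")
    }
    seq_parts <- character(0)
    fingers <- data.frame(start = integer(n_fingers),
                          end = integer(n_fingers),
                          motif_seq = motifs, stringsAsFactors = FALSE)
    pos <- 0L
    for (i in seq_len(n_fingers)) {
      gap <- paste(sample(background, min_separation + sample.int(8, 1),
                          replace = TRUE), collapse = "")
      seq_parts <- c(seq_parts, gap, motifs[i])
      pos <- pos + nchar(gap)
      fingers$start[i] <- pos + 1L
      pos <- pos + nchar(motifs[i])
      fingers$end[i] <- pos
    }
    tail_gap <- paste(sample(background, min_separation, replace = TRUE),
                      collapse = "")
    sequence <- paste(c(seq_parts, tail_gap), collapse = "")
    chars <- strsplit(toupper(sequence), "")[[1]]
    # one variant per finger, two residues upstream of the terminal H
    variants <- do.call(rbind, lapply(seq_len(n_fingers), function(i) {
      offset <- nchar(motifs[i]) - 2L
      p <- fingers$start[i] + offset - 1L
      ref <- chars[p]
      alt <- sample(setdiff(background, ref), 1L)
      data.frame(position = p, ref_aa = ref, alt_aa = alt,
                 finger_index = i, offset_in_motif = offset,
                 stringsAsFactors = FALSE)
    }))
    list(sequence = sequence, fingers = fingers, variants = variants)
  })
}
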