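#' Pipeline configuration
#'
#' Collects the analysis parameters (the defaults are the values the
#' whole-genome characterisation was run with: purity 0.6, 95% founder
#' inclusion, depth >= 10, control alt tolerance 0, alpha 0.05, variance
#' cutoff 0.1) and the input file paths. A stage runs only when its input
#' path is set; any stage may be skipped by leaving its path `NULL`.
#'
#' @param purity Tumour purity for founder classification and, when
#'   `loh_purity_aware = TRUE`, for the LOH cutoff.
#' @param inclusion Founder-model inclusion level.
#' @param min_depth,max_control_alt Variant-filter settings.
#' @param alpha Screen-test significance level.
#' @param var_threshold Methylation variance cutoff.
#' @param cluster_k Flat cluster count cut from the dendrogram.
#' @param loh_purity_aware Use the purity-aware LOH cutoff (default
#'   `FALSE`: fixed folded-BAF cutoff 0.4).
#' @param variants,snps,arms,screen,fasta,protein_variants,methylation
#'   Input file paths (or `NULL` to skip the stage). `variants` is a
#'   TSV/VCF variant table, `snps` a SNP BAF TSV, `arms` an arm BED-like
#'   TSV (optional if `snps` carries an `arm` column), `screen` a panel
#'   TSV, `fasta` a protein FASTA, `protein_variants` a TSV with columns
#'   `position`, `ref_aa`, `alt_aa` (or a `variant` shorthand column),
#'   `methylation` a probes-x-samples TSV.
#' @param seed Integer seed echoed into the report (the analysis stages
#'   are deterministic).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(purity = 0.6, inclusion = 0.95, min_depth = 10,
                            max_control_alt = 0, alpha = 0.05,
                            var_threshold = 0.1, cluster_k = 2,
                            loh_purity_aware = FALSE,
                            variants = NULL, snps = NULL, arms = NULL,
                            screen = NULL, fasta = NULL,
                            protein_variants = NULL, methylation = NULL,
                            seed = 1L) {
  cfg <- list(purity = purity, inclusion = inclusion, min_depth = min_depth,
              max_control_alt = max_control_alt, alpha = alpha,
              var_threshold = var_threshold, cluster_k = cluster_k,
              loh_purity_aware = loh_purity_aware,
              variants = variants, snps = snps, arms = arms,
              screen = screen, fasta = fasta,
              protein_variants = protein_variants,
              methylation = methylation, seed = seed)
  founder_params(purity, inclusion = inclusion)  # validates the domains
  filter_config(min_depth, max_control_alt)
  stopifnot(alpha > 0, alpha < 1, var_threshold >= 0, cluster_k >= 1)
  for (f in c("variants", "snps", "arms", "screen", "fasta",
              "protein_variants", "methylation")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("input file for `", f, "` does not exist: ", cfg[[f]],
           call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the analysis pipeline end to end
#'
#' Executes, in order, each stage whose input is configured: variant filter
#' cascade plus founder classification; arm-level LOH and purity
#' estimation; screening-panel enrichment; zinc-finger scan and variant
#' mapping; methylation variance filter and clustering. Deterministic
#' given the inputs and configuration; a failing stage aborts with the
#' stage name and the offending record's context in the message.
#'
#' @param config A [pipeline_config()].
#' @return List of class `run_report`: configuration echo, package
#'   version, timestamp, and one summary entry per executed stage.
#' @examples
#' \donttest{
#' dir <- tempfile(); dir.create(dir)
#' v <- simulate_variant_table(n_founder = 20, n_subclonal = 10,
#'                             n_germline_het = 10, seed = 1)
#' write_variants_tsv(v[names(v) != "truth"], file.path(dir, "v.tsv"))
#' rep <- run_pipeline(pipeline_config(variants = file.path(dir, "v.tsv")))
#' rep$founder$n_founder_snvs
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("gisttools")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  fp <- founder_params(config$purity, inclusion = config$inclusion)

  if (!is.null(config$variants)) {
    report$filter <- run_stage("variant_filter", {
      v <- read_variants(config$variants)
      res <- run_cascade(v, filter_config(config$min_depth,
                                          config$max_control_alt))
      list(report = as.list(unclass(res$report)),
           survivors = nrow(res$variants))
    })
    report$founder <- run_stage("founder_model", {
      v <- read_variants(config$variants)
      res <- run_cascade(v, filter_config(config$min_depth,
                                          config$max_control_alt))
      surv <- res$variants
      surv$alt_count <- surv$tumour_alt_fwd + surv$tumour_alt_rev
      surv$coverage <- surv$tumour_depth
      n <- count_founder_snvs(surv, fp)
      list(n_candidates = nrow(surv), n_founder_snvs = as.integer(n))
    })
  }

  if (!is.null(config$snps)) {
    report$loh <- run_stage("loh_cnv", {
      snps <- utils::read.delim(config$snps, stringsAsFactors = FALSE)
      if (!"arm" %in% names(snps)) {
        if (is.null(config$arms)) {
          stop("SNP table has no `arm` column and no arm file configured")
        }
        snps <- assign_arms(snps, read_arms(config$arms))
      }
      summ <- arm_summaries(
        snps,
        purity = if (config$loh_purity_aware) config$purity else NULL,
        min_depth = config$min_depth)
      called <- summ$arm[summ$loh_call %in% TRUE]
      list(arms = as.data.frame(summ), loh_arms = called,
           purity_estimates =
             stats::setNames(summ$purity_estimate[summ$loh_call %in% TRUE],
                             called))
    })
  }

  if (!is.null(config$screen)) {
    report$screen <- run_stage("screen_enrichment", {
      panel <- read_screen_panel(config$screen)
      sp <- screen_panel(panel, alpha = config$alpha)
      sig <- sp$results$site_id[sp$results$significant %in% TRUE]
      c(sp$summary, list(significant_sites = sig))
    })
  }

  if (!is.null(config$fasta)) {
    report$zf <- run_stage("zf_motif", {
      seqs <- read_protein_fasta(config$fasta)
      fingers <- scan_c2h2(seqs[[1]])
      out <- list(n_fingers = nrow(fingers),
                  fingers = as.data.frame(fingers))
      if (!is.null(config$protein_variants)) {
        pv <- utils::read.delim(config$protein_variants,
                                stringsAsFactors = FALSE)
        if ("variant" %in% names(pv) && !"position" %in% names(pv)) {
          pv <- parse_protein_variant(pv$variant)
        }
        out$variants <- map_variants_to_fingers(seqs[[1]], pv)
      }
      out
    })
  }

  if (!is.null(config$methylation)) {
    report$methylome <- run_stage("methylome", {
      m <- read_methylation_matrix(config$methylation)
      keep <- variance_filter(m, config$var_threshold)
      if (length(keep) < 2) {
        stop("fewer than 2 probes pass the variance filter")
      }
      cl <- cluster_samples(m[keep, , drop = FALSE])
      labels <- cut_clusters(cl, config$cluster_k)
      list(n_probes_total = nrow(m), n_probes_variable = length(keep),
           cluster_labels = as.list(labels))
    })
  }

  structure(report, class = "run_report")
}

#' Write a pipeline report as JSON (and optionally plain text)
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param json_path Output JSON file.
#' @param text_path Optional human-readable summary file.
#' @return `json_path`, invisibly.
#' @export
write_run_report <- function(report, json_path, text_path = NULL) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "rows",
                       force = TRUE)
  if (!is.null(text_path)) {
    con <- file(text_path, "w")
    on.exit(close(con))
    writeLines(utils::capture.output(utils::str(unclass(report),
                                                max.level = 3)), con)
  }
  invisible(json_path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("gisttools pipeline report (", x$timestamp, ")\n", sep = "")
  stages <- intersect(c("filter", "founder", "loh", "screen", "zf",
                        "methylome"), names(x))
  if (!length(stages)) {
    cat("  no stages executed\n")
    return(invisible(x))
  }
  for (s in stages) {
    cat("  stage ", s, ":\n", sep = "")
    if (s == "filter") {
      cat("    survivors:", x$filter$survivors, "\n")
    } else if (s == "founder") {
      cat("    founder SNVs:", x$founder$n_founder_snvs, "of",
          x$founder$n_candidates, "candidates\n")
    } else if (s == "loh") {
      cat("    LOH arms:", paste(x$loh$loh_arms, collapse = ", "), "\n")
    } else if (s == "screen") {
      cat("    enriched sites:",
          paste(x$screen$significant_sites, collapse = ", "), "\n")
    } else if (s == "zf") {
      cat("    fingers found:", x$zf$n_fingers, "\n")
    } else if (s == "methylome") {
      cat("    variable probes:", x$methylome$n_probes_variable, "of",
          x$methylome$n_probes_total, "\n")
    }
  }
  invisible(x)
}
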