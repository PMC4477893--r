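# Shared fixtures and independent oracles, built in code.

# Brute-force oracle for the founder threshold: scans k upward using the
# closed-form binomial tail from stats::pbinom (independent of the package's
# own term-by-term summation).
oracle_threshold <- function(n, q, inclusion = 0.95) {
  ks <- which(stats::pbinom(0:(n - 1), n, q, lower.tail = FALSE) >= inclusion)
  if (length(ks)) max(ks) else 1L
}

# One valid baseline variant record.
base_variant <- function(n = 1) {
  if (n == 0) return(base_variant(1)[0, ])
  data.frame(
    chrom = "chr1", pos = seq_len(n),
    ref_allele = "A", alt_allele = "G",
    tumour_alt_fwd = 7L, tumour_alt_rev = 7L, tumour_depth = 30L,
    control_alt_count = 0L, control_depth = 30L,
    variant_class = "SNV", region_class = "exonic-coding",
    effect_class = "nonsynonymous", known_snp_id = "",
    stringsAsFactors = FALSE
  )
}

# 100-record cascade fixture with planted per-stage failures:
# 10 germline, 10 single-strand, 10 low-depth, 40 non-transcribed,
# 15 silent, 5 known SNPs, 10 clean. Every planted failure passes all
# earlier stages, forcing the attrition [100, 90, 80, 70, 30, 15, 10].
make_cascade_fixture <- function() {
  v <- base_variant(100)
  v$pos <- 1:100
  v$control_alt_count[1:10] <- 5L                     # fail somatic
  v$tumour_alt_fwd[11:20] <- 14L                      # fail strand
  v$tumour_alt_rev[11:20] <- 0L
  v$tumour_depth[21:30] <- 9L                         # fail depth
  v$tumour_alt_fwd[21:30] <- 4L
  v$tumour_alt_rev[21:30] <- 4L
  v$region_class[31:70] <- rep(c("intronic", "intergenic"), 20)
  v$effect_class[71:85] <- "silent"                   # fail non-silent
  v$known_snp_id[86:90] <- paste0("rs", 86:90)        # fail novelty
  v
}

expected_cascade_counts <- c(input = 100L, somatic = 90L, strand_ok = 80L,
                             depth_ok = 70L, transcribed = 30L,
                             non_silent = 15L, novel = 10L)
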