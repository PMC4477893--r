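AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Scan a protein sequence for C2H2 zinc-finger motifs
#'
#' A C2H2 (Krueppel-type) zinc finger coordinates a zinc ion through two
#' cysteines and two histidines. The scanner matches the spacing pattern
#' `C-x(1,5)-C-x(10,14)-H-x(3,5)-H` (generalising the canonical
#' `C-x(2)-C-x(12)-H-x(3)-H`), left to right and non-overlapping. When a
#' cysteine anchors several admissible anchor placements, the one closest
#' to the canonical spacing is chosen (ties broken towards the shortest
#' finger); this keeps non-coordinating histidines inside the spacer -- for
#' instance an internal histidine nine residues into a finger cannot be
#' mistaken for the first coordinating H, whose admissible window starts
#' ten residues after the second C.
#'
#' @param sequence Amino-acid string (single sequence, 20-letter alphabet,
#'   case-insensitive; matching is performed on the upper-cased sequence).
#' @param c_spacer,mid_spacer,h_spacer Integer pairs giving the admissible
#'   spacer lengths between C1--C2, C2--H1 and H1--H2.
#' @return Data frame of class `zf_scan`, one row per finger: `start`,
#'   `end` (1-based in the parent sequence), `c1`, `c2`, `h1`, `h2`
#'   (1-based offsets of the coordinating residues within the motif) and
#'   `motif_seq` (the matched substring, as given).
#' @examples
#' scan_c2h2("CKKCFYKTRSSTVLTRHIKLRH")
#' @export
scan_c2h2 <- function(sequence, c_spacer = c(1, 5), mid_spacer = c(10, 14),
                      h_spacer = c(3, 5)) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad)) {
    stop("non-amino-acid character ", deparse(chars[bad[1]]),
         " at position ", bad[1], call. = FALSE)
  }
  n <- length(chars)
  c_pos <- which(chars == "C")
  h_pos <- which(chars == "H")
  canonical <- c(2, 12, 3)
  fingers <- list()
  cursor <- 1L
  for (c1 in c_pos) {
    if (c1 < cursor) next
    c2s <- c_pos[c_pos - c1 - 1 >= c_spacer[1] & c_pos - c1 - 1 <= c_spacer[2]]
    best <- NULL
    for (c2 in c2s) {
      h1s <- h_pos[h_pos - c2 - 1 >= mid_spacer[1] &
                     h_pos - c2 - 1 <= mid_spacer[2]]
      for (h1 in h1s) {
        h2s <- h_pos[h_pos - h1 - 1 >= h_spacer[1] &
                       h_pos - h1 - 1 <= h_spacer[2]]
        for (h2 in h2s) {
          gaps <- c(c2 - c1 - 1, h1 - c2 - 1, h2 - h1 - 1)
          score <- sum(abs(gaps - canonical))
          cand <- list(c1 = c1, c2 = c2, h1 = h1, h2 = h2, score = score)
          if (is.null(best) || score < best$score ||
              (score == best$score && h2 < best$h2)) {
            best <- cand
          }
        }
      }
    }
    if (!is.null(best)) {
      fingers[[length(fingers) + 1L]] <- best
      cursor <- best$h2 + 1L  # greedy, non-overlapping
    }
  }
  if (!length(fingers)) {
    out <- data.frame(start = integer(0), end = integer(0), c1 = integer(0),
                      c2 = integer(0), h1 = integer(0), h2 = integer(0),
                      motif_seq = character(0), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, lapply(fingers, function(f) {
      data.frame(start = f$c1, end = f$h2,
                 c1 = 1L, c2 = f$c2 - f$c1 + 1L,
                 h1 = f$h1 - f$c1 + 1L, h2 = f$h2 - f$c1 + 1L,
                 motif_seq = substr(sequence, f$c1, f$h2),
                 stringsAsFactors = FALSE)
    }))
  }
  class(out) <- c("zf_scan", "data.frame")
  out
}

#' Locate an amino-acid substitution within a zinc finger
#'
#' Maps a 1-based offset within a scanned finger to its structural role:
#' `zinc-coordinating` for the two cysteines and two histidines,
#' `recognition-helix` for the residues strictly between the second C and
#' the first H (these determine the DNA sequence the finger recognises),
#' and `spacer` otherwise. Residues between the two histidines -- still
#' part of the recognition alpha-helix -- are flagged `helix_adjacent`.
#' The distance upstream of the terminal histidine (`h2 - offset`) is
#' reported; low-frequency residues close to the terminal H (e.g. a
#' tryptophan two residues upstream) destabilise the helix.
#'
#' @param finger One row of a [scan_c2h2()] result.
#' @param offset_in_motif 1-based position within the motif.
#' @return List of class `zf_substitution`: `offset_in_motif`, `role`,
#'   `helix_adjacent`, `dist_upstream_of_terminal_H`.
#' @examples
#' f <- scan_c2h2("ClhCefsahssaslelHvkrkH")
#' locate_substitution(f[1, ], 20)  # Arg1038Trp: 2 upstream of terminal H
#' @export
locate_substitution <- function(finger, offset_in_motif) {
  stopifnot(is.data.frame(finger), nrow(finger) == 1L)
  len <- finger$h2 - finger$c1 + 1L
  if (!is.numeric(offset_in_motif) || length(offset_in_motif) != 1L ||
      offset_in_motif < 1 || offset_in_motif > len) {
    stop("offset must lie within the finger (1..", len, "), got ",
         offset_in_motif, call. = FALSE)
  }
  off <- as.integer(offset_in_motif)
  anchors <- c(finger$c1, finger$c2, finger$h1, finger$h2)
  role <- if (off %in% anchors) {
    "zinc-coordinating"
  } else if (off > finger$c2 && off < finger$h1) {
    "recognition-helix"
  } else {
    "spacer"
  }
  structure(
    list(offset_in_motif = off, role = role,
         helix_adjacent = off > finger$h1 && off < finger$h2,
         dist_upstream_of_terminal_H = finger$h2 - off),
    class = "zf_substitution"
  )
}

#' Parse protein-variant shorthand
#'
#' Accepts `"Arg1038Trp"`-style (three-letter) and `"R1038W"`-style
#' (one-letter) HGVS-like protein substitution shorthand.
#'
#' @param x Character vector of shorthand strings.
#' @return Data frame with columns `position`, `ref_aa`, `alt_aa`
#'   (one-letter codes).
#' @examples
#' parse_protein_variant(c("Arg1038Trp", "K725T"))
#' @export
parse_protein_variant <- function(x) {
  three <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")
  one <- function(aa) {
    if (nchar(aa) == 1L) return(toupper(aa))
    key <- paste0(toupper(substr(aa, 1, 1)), tolower(substr(aa, 2, 3)))
    if (!key %in% names(three)) {
      stop("unknown amino-acid code: ", aa, call. = FALSE)
    }
    unname(three[key])
  }
  m <- regmatches(x, regexec("^([A-Za-z]{1,3})([0-9]+)([A-Za-z]{1,3})$", x))
  out <- lapply(seq_along(x), function(i) {
    parts <- m[[i]]
    if (length(parts) != 4L) {
      stop("cannot parse protein variant: ", x[i], call. = FALSE)
    }
    data.frame(position = as.integer(parts[3]), ref_aa = one(parts[2]),
               alt_aa = one(parts[4]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Map protein variants onto scanned zinc fingers
#'
#' Scans `sequence` with [scan_c2h2()] and annotates each variant with the
#' finger it falls into (if any) and its structural position there.
#'
#' @param sequence Amino-acid string.
#' @param variants Data frame with columns `position`, `ref_aa`, `alt_aa`,
#'   or a character vector of shorthand parsed by
#'   [parse_protein_variant()].
#' @param ... Passed on to [scan_c2h2()].
#' @return Data frame, one row per variant: `position`, `ref_aa`, `alt_aa`,
#'   `in_finger`, `finger_index`, `finger_start`, `offset_in_motif`,
#'   `role`, `helix_adjacent`, `dist_upstream_of_terminal_H`.
#' @examples
#' prot <- simulate_zf_protein(seed = 1)
#' map_variants_to_fingers(prot$sequence, prot$variants)
#' @export
map_variants_to_fingers <- function(sequence, variants, ...) {
  if (is.character(variants)) variants <- parse_protein_variant(variants)
  stopifnot(is.data.frame(variants))
  need <- c("position", "ref_aa", "alt_aa")
  miss <- setdiff(need, names(variants))
  if (length(miss)) {
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  fingers <- scan_c2h2(sequence, ...)
  chars <- strsplit(toupper(sequence), "")[[1]]
  out <- variants[, need, drop = FALSE]
  nv <- nrow(out)
  out$in_finger <- rep(FALSE, nv)
  out$finger_index <- rep(NA_integer_, nv)
  out$finger_start <- rep(NA_integer_, nv)
  out$offset_in_motif <- rep(NA_integer_, nv)
  out$role <- rep(NA_character_, nv)
  out$helix_adjacent <- rep(NA, nv)
  out$dist_upstream_of_terminal_H <- rep(NA_integer_, nv)
  for (i in seq_len(nrow(out))) {
    pos <- out$position[i]
    if (pos < 1 || pos > length(chars)) {
      stop("variant position ", pos, " outside the sequence (length ",
           length(chars), ")", call. = FALSE)
    }
    found <- chars[pos]
    if (found != toupper(out$ref_aa[i])) {
      stop("reference mismatch at position ", pos, ": expected ",
           out$ref_aa[i], ", found ", found, call. = FALSE)
    }
    hit <- which(fingers$start <= pos & fingers$end >= pos)
    if (length(hit)) {
      f <- fingers[hit[1], ]
      s <- locate_substitution(f, pos - f$start + 1L)
      out$in_finger[i] <- TRUE
      out$finger_index[i] <- hit[1]
      out$finger_start[i] <- f$start
      out$offset_in_motif[i] <- s$offset_in_motif
      out$role[i] <- s$role
      out$helix_adjacent[i] <- s$helix_adjacent
      out$dist_upstream_of_terminal_H[i] <- s$dist_upstream_of_terminal_H
    }
  }
  out
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet()` returning a named
#' character vector.
#'
#' @param path FASTA file.
#' @return Named character vector of amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package", call. = FALSE)
  }
  seqs <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}

#' @rdname read_protein_fasta
#' @param sequences Named character vector.
#' @export
write_protein_fasta <- function(sequences, path) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  lines <- unlist(lapply(names(sequences), function(nm) {
    body <- gsub(sprintf("(.{1,%d})", 60L), "\\1\n", sequences[[nm]])
    c(paste0(">", nm), strsplit(body, "\n")[[1]])
  }))
  writeLines(lines, path)
  invisible(path)
}
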