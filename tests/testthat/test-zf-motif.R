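test_that("the two published ZNF407 motifs scan to one finger each", {
  for (motif in unique(znf407_zinc_fingers()$motif_seq)) {
    f <- scan_c2h2(motif)
    expect_identical(nrow(f), 1L)
    expect_identical(c(f$c1, f$c2, f$h1, f$h2), c(1L, 4L, 17L, 22L))
    expect_identical(f$motif_seq, motif)
  }
  # the non-coordinating histidine at offset 9 of the second motif must
  # stay inside the spacer: its window (10..14 after C2) excludes it
  f2 <- scan_c2h2("ClhCefsahssaslelHvkrkH")
  expect_identical(f2$h1, 17L)
})

test_that("scanning is case-insensitive and validates the alphabet", {
  motif <- "CkkCfyktrsstvltrHiklrH"
  expect_equal(scan_c2h2(toupper(motif))[, 1:6],
               scan_c2h2(tolower(motif))[, 1:6], ignore_attr = TRUE)
  expect_identical(nrow(scan_c2h2("AAAAAA")), 0L)
  expect_error(scan_c2h2("CKKCX"), "position 5")
  expect_error(scan_c2h2("CkkC2yktrsstvltrHiklrH"), "position 5")
})

test_that("planted fingers are recovered at their coordinates", {
  for (k in c(3L, 8L, 22L)) {
    prot <- simulate_zf_protein(n_fingers = k, seed = 100 + k)
    found <- scan_c2h2(prot$sequence)
    expect_identical(nrow(found), k)
    expect_identical(found$start, prot$fingers$start)
    expect_identical(found$end, prot$fingers$end)
    # coordinate round-trip: (start, end) extracts the matched substring
    expect_identical(substring(prot$sequence, found$start, found$end),
                     found$motif_seq)
  }
})

test_that("substitutions map to structural roles and distances", {
  zf <- znf407_zinc_fingers()
  f1017 <- scan_c2h2(unique(zf$motif_seq)[2])
  arg1038 <- locate_substitution(f1017, 20)  # Arg1038Trp
  expect_identical(arg1038$dist_upstream_of_terminal_H, 2L)
  expect_identical(arg1038$role, "spacer")
  expect_true(arg1038$helix_adjacent)

  f705 <- scan_c2h2(unique(zf$motif_seq)[1])
  lys725 <- locate_substitution(f705, 19)    # Lys725Thr
  expect_identical(lys725$dist_upstream_of_terminal_H, 3L)

  leu1020 <- locate_substitution(f1017, 2)   # Leu1020Trp, C1-C2 spacer
  expect_identical(leu1020$role, "spacer")
  expect_false(leu1020$helix_adjacent)

  anchor <- locate_substitution(f1017, 1)
  expect_identical(anchor$role, "zinc-coordinating")
  expect_identical(anchor$dist_upstream_of_terminal_H, 21L)
  helix <- locate_substitution(f1017, 10)
  expect_identical(helix$role, "recognition-helix")
  expect_error(locate_substitution(f1017, 23), "within the finger")
})

test_that("variants map onto fingers with reference checking", {
  prot <- simulate_zf_protein(n_fingers = 2, seed = 42)
  outside <- data.frame(position = 5L,
                        ref_aa = substr(prot$sequence, 5, 5),
                        alt_aa = "A")
  ann <- map_variants_to_fingers(prot$sequence,
                                 rbind(prot$variants[, 1:3], outside))
  expect_identical(ann$in_finger, c(TRUE, TRUE, FALSE))
  expect_identical(ann$dist_upstream_of_terminal_H[1:2], c(2L, 2L))
  # variant at a coordinating cysteine
  c_anchor <- data.frame(position = prot$fingers$start[1],
                         ref_aa = "C", alt_aa = "Y")
  ann_c <- map_variants_to_fingers(prot$sequence, c_anchor)
  expect_identical(ann_c$role, "zinc-coordinating")
  # reference mismatch names position, expected and found
  bad <- data.frame(position = prot$fingers$start[1], ref_aa = "W",
                    alt_aa = "A")
  expect_error(map_variants_to_fingers(prot$sequence, bad),
               "expected W, found C")
  expect_identical(nrow(map_variants_to_fingers(prot$sequence,
                                                outside[0, ])), 0L)
})

test_that("protein-variant shorthand parses both notations", {
  pv <- parse_protein_variant(c("Arg1038Trp", "K725T"))
  expect_identical(pv$position, c(1038L, 725L))
  expect_identical(pv$ref_aa, c("R", "K"))
  expect_identical(pv$alt_aa, c("W", "T"))
  expect_error(parse_protein_variant("Xyz10Ala"), "unknown amino-acid")
  expect_error(parse_protein_variant("10A"), "cannot parse")
})
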