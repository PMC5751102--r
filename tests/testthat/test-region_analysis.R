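fake_classmap <- function(aa3_epi, aa3_surf) {
  n <- length(aa3_epi) + length(aa3_surf)
  out <- data.frame(
    key = residue_key("A", seq_len(n)),
    chain = "A", resno = seq_len(n), icode = "",
    aa3 = c(aa3_epi, aa3_surf),
    class = c(rep("EPITOPE", length(aa3_epi)),
              rep("SURFACE_NONIMMUNOGENIC", length(aa3_surf))),
    stringsAsFactors = FALSE)
  class(out) <- c("residue_class_map", "data.frame")
  out
}

test_that("region composition normalizes per class and differences subtract", {
  cm <- fake_classmap(c("SER", "SER", "ALA", "GLY"), c("ALA", "VAL"))
  rc <- region_composition(cm)
  expect_equal(sum(rc$epitope_freq), 1, tolerance = 1e-9)
  expect_equal(sum(rc$surface_freq), 1, tolerance = 1e-9)
  expect_equal(rc$epitope_freq[rc$aa1 == "S"], 0.5)
  expect_equal(rc$difference, rc$epitope_freq - rc$surface_freq)

  same <- fake_classmap(c("SER", "ALA"), c("SER", "ALA"))
  expect_true(all(region_composition(same)$difference == 0))

  # pooling over structures equals recomputation from pooled counts
  cm2 <- fake_classmap(c("TYR", "ARG"), c("PRO", "PRO", "VAL"))
  pooled <- region_composition(list(cm, cm2))
  manual <- region_composition(fake_classmap(
    c("SER", "SER", "ALA", "GLY", "TYR", "ARG"),
    c("ALA", "VAL", "PRO", "PRO", "VAL")))
  expect_equal(pooled, manual)

  empty <- cm[cm$class == "EPITOPE", ]
  class(empty) <- class(cm)
  expect_error(region_composition(empty), "no residues")
})

test_that("the Welch test matches the closed-form computation to 1e-10", {
  x <- c(4.1, 3.7, 5.2, 4.8, 4.4)
  y <- c(3.1, 2.8, 3.9, 3.3)
  got <- aaindex_region_test(x, y, "ARGP820101")
  # closed-form Welch t with Welch-Satterthwaite df, computed by hand here
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * pt(-abs(tstat), df)
  expect_equal(got$p_value, p, tolerance = 1e-10)
  expect_equal(got$statistic, tstat, tolerance = 1e-10)
  expect_equal(got$mean_iab, mean(x))
  expect_equal(got$mean_background, mean(y))

  # symmetry: swapping groups leaves p unchanged
  expect_equal(aaindex_region_test(y, x)$p_value, got$p_value,
               tolerance = 1e-12)
  # identical constant groups -> p = 1; separated constants -> p = 0
  expect_equal(aaindex_region_test(c(1, 1), c(1, 1))$p_value, 1)
  expect_equal(aaindex_region_test(c(0, 0), c(1, 1))$p_value, 0)
  # extreme separation with tiny jitter
  expect_lt(aaindex_region_test(c(0, 0, 0, 1e-9), c(1, 1, 1, 1 + 1e-9))$p_value,
            1e-6)
  expect_error(aaindex_region_test(1, c(1, 2)), "at least 2")
})

test_that("Kabat CDR ranges are implemented with insertion letters", {
  expect_true(kabat_is_cdr("H", 31))
  expect_true(kabat_is_cdr("H", 35, "B"))
  expect_false(kabat_is_cdr("H", 35, "C"))
  expect_false(kabat_is_cdr("H", 36))
  expect_true(kabat_is_cdr("H", 100, "A"))  # insertion inside 95-102
  expect_false(kabat_is_cdr("H", 27))
  expect_true(all(kabat_is_cdr("L", c(24, 34, 50, 56, 89, 97))))
  expect_false(any(kabat_is_cdr("L", c(23, 35, 49, 57, 88, 98))))
})

test_that("CDR-based epitope calls use a strict majority of region residues", {
  kab <- data.frame(key = residue_key("A", 1:20),
                    is_cdr = c(rep(TRUE, 8), rep(FALSE, 12)))
  region6 <- residue_key("A", c(1:6, 9:12))   # 6 of 10 in CDR
  region5 <- residue_key("A", c(1:5, 9:13))   # exactly half
  expect_true(classify_cdr_epitope(region6, kab))
  expect_false(classify_cdr_epitope(region5, kab))
  expect_error(classify_cdr_epitope(residue_key("A", 99), kab), "unannotated")
  # coverage reading: region holding 5 of 8 CDR residues
  expect_true(classify_cdr_epitope(residue_key("A", 1:5), kab,
                                   mode = "cdr_coverage"))
  expect_false(classify_cdr_epitope(residue_key("A", 1:4), kab,
                                    mode = "cdr_coverage"))
})

test_that("the census separates SAME, SUBSTITUTED and INSERTED columns", {
  aln <- c(iab = "SACDEFG",
           bg1 = "GACDE-G",
           bg2 = "GACDE-G",
           bg3 = "GAC-E-G")
  cen <- substitution_insertion_census(aln, "iab", 1:7)
  expect_equal(cen$status[1], "SUBSTITUTED")  # S vs modal G
  expect_equal(cen$modal_residue[1], "G")
  expect_equal(cen$status[2], "SAME")
  expect_equal(cen$status[6], "INSERTED")     # gap-majority column
  expect_equal(attr(cen, "summary"),
               c(SAME = 5L, SUBSTITUTED = 1L, INSERTED = 1L))
  # conservation: statuses partition the epitope columns
  expect_equal(sum(attr(cen, "summary")), 7L)

  # identical sequences -> all SAME
  aln2 <- c(iab = "ACDEF", b1 = "ACDEF", b2 = "ACDEF")
  expect_true(all(substitution_insertion_census(aln2, "iab", 1:5)$status == "SAME"))
  # modal ties break alphabetically
  aln3 <- c(iab = "A", b1 = "C", b2 = "A")
  expect_equal(substitution_insertion_census(aln3, "iab", 1)$modal_residue, "A")
  expect_error(substitution_insertion_census(aln, "nope", 1), "not found")
  expect_error(substitution_insertion_census(aln, "iab", 9), "outside")
})

test_that("a planted insertion block is recovered from a toy alignment", {
  # background antibodies lack a 7-column block that the iAb carries
  core <- "QVQLVESGGGLVQPGGSLRLS"
  ins <- "AKDYFYD"
  iab <- paste0(substr(core, 1, 10), ins, substr(core, 11, nchar(core)))
  bg <- paste0(substr(core, 1, 10), strrep("-", nchar(ins)),
               substr(core, 11, nchar(core)))
  aln <- c(iab = iab, bg1 = bg, bg2 = bg, bg3 = bg, bg4 = bg,
           bg5 = bg, bg6 = bg, bg7 = bg, bg8 = bg, bg9 = bg, bg10 = bg)
  cen <- substitution_insertion_census(aln, "iab", seq_len(nchar(iab)))
  expect_equal(which(cen$status == "INSERTED"), 11:17)
  expect_equal(unname(attr(cen, "summary")["INSERTED"]), 7L)
  expect_equal(unname(attr(cen, "summary")["SAME"]), nchar(core))
})

test_that("gapped FASTA round-trips through the reader", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">iab", "SACD-EFG", ">bg1", "GACD-E-G"), path)
  aln <- read_gapped_fasta(path)
  expect_equal(unname(aln["iab"]), "SACD-EFG")
  expect_length(aln, 2L)
  writeLines(c(">a", "ACGT", ">b", "ACG"), path)
  expect_error(read_gapped_fasta(path), "same length")
})

test_that("Kabat annotation TSVs are parsed and CDR flags derived", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chain\tresnum\ticode\tkabat_label",
               "H\t31\t\tH31",
               "H\t100\tA\tH100A",
               "H\t10\t\tH10",
               "L\t27\t\tL27"), path)
  k <- read_kabat_annotation(path)
  expect_equal(k$is_cdr, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(k$key[2], "H:100:A")
})
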