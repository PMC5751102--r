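# fixture shared by the descriptor tests: IAB-only model with ASA and
# anchors computed once
descr_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tm <- .toy1()
      iab <- iab_model(tm$model)
      asa <- compute_asa(iab, n_points = 240)
      bp <- select_benchmark_points(iab, detect_disulfides(iab))
      cache <<- list(iab = iab, asa = asa, bp = bp, tab = aaindex_table())
    }
    cache
  }
})

test_that("shell bins are half-open and the neighborhood bound is strict", {
  mk <- function(d2, d3) paste(c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, c(0, 0, 0), "C"),
    pdb_atom_line(2, "CA", "GLY", "A", 2, c(d2, 0, 0), "C"),
    pdb_atom_line(3, "CA", "GLY", "A", 3, c(d3, 0, 0), "C"),
    "END"), collapse = "\n")
  sh <- build_shells(parse_structure(mk(1.9, 2.0)), "A:1:")
  expect_equal(sh$layers[[1]], "A:2:")
  expect_equal(sh$layers[[2]], "A:3:")
  sh20 <- build_shells(parse_structure(mk(19.999, 20.0)), "A:1:")
  expect_equal(sh20$layers[[10]], "A:2:")  # 20.0 excluded entirely
  expect_equal(sum(lengths(sh20$layers)), 1L)
  expect_error(build_shells(parse_structure(mk(1, 2)), "Z:9:"), "unknown")
})

test_that("shell memberships equal the brute-force pairwise scan for every residue", {
  fx <- descr_fixture()
  p <- ab_params()
  for (k in fx$iab$residues$key) {
    got <- build_shells(fx$iab, k, p)
    orc <- oracle_layers(fx$iab, k, p)
    expect_equal(lapply(got$layers, sort), lapply(orc, sort))
    # partition property: members together cover the <20 A neighbourhood
    expect_equal(sum(lengths(got$layers)), length(got$distances))
  }
})

test_that("IAD is a pure amino-acid lookup", {
  fx <- descr_fixture()
  res <- fx$iab$residues
  k_gly <- res$key[res$aa3 == "GLY"][1]
  v <- iad(fx$iab, k_gly, fx$tab)
  expect_equal(unname(v), unname(fx$tab[c("ARGP820101", "FAUJ880109",
                                          "FAUJ880103"), "G"]))
  # identical amino acids give identical IAD regardless of coordinates
  aa_counts <- table(res$aa3)
  aa_dup <- names(aa_counts)[aa_counts >= 2][1]
  ks <- res$key[res$aa3 == aa_dup][1:2]
  expect_equal(iad(fx$iab, ks[1], fx$tab), iad(fx$iab, ks[2], fx$tab))
  # spot values frozen from the published scales
  expect_equal(unname(fx$tab["ARGP820101", "W"]), 2.65)
  expect_equal(unname(fx$tab["FAUJ880109", "R"]), 4)
  expect_equal(unname(fx$tab["FAUJ880103", "G"]), 0)
})

test_that("shell summaries equal brute-force max and sum, with zero for empty layers", {
  fx <- descr_fixture()
  p <- ab_params()
  aa1 <- stats::setNames(unname(abepitope:::AA3_TO_AA1[fx$iab$residues$aa3]),
                         fx$iab$residues$key)
  for (k in fx$iab$residues$key[c(1, 10, 25, 40, 60)]) {
    sh <- build_shells(fx$iab, k, p)
    sm <- sed_max(sh, fx$iab, fx$tab)
    ss <- sed_sum(sh, fx$iab, fx$tab)
    for (l in seq_len(10)) {
      members <- aa1[sh$layers[[l]]]
      for (i in seq_along(c("ARGP820101", "FAUJ880109", "FAUJ880103"))) {
        idx <- c("ARGP820101", "FAUJ880109", "FAUJ880103")[i]
        pos <- (l - 1) * 3 + i
        if (!length(members)) {
          expect_identical(unname(sm[pos]), 0)
          expect_identical(unname(ss[pos]), 0)
        } else {
          expect_equal(unname(sm[pos]), max(fx$tab[idx, members]))
          expect_equal(unname(ss[pos]), sum(fx$tab[idx, members]))
        }
      }
    }
  }
})

test_that("a singleton layer has max equal to sum for both scales and ASA", {
  pdb <- paste(c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, c(0, 0, 0), "C"),
    pdb_atom_line(2, "CA", "GLY", "A", 2, c(3, 0, 0), "C"),
    "END"), collapse = "\n")
  m <- parse_structure(pdb)
  sh <- build_shells(m, "A:1:")
  tab <- aaindex_table()
  sm <- sed_max(sh, m, tab); ss <- sed_sum(sh, m, tab)
  expect_equal(unname(sm[4:6]), unname(tab[c("ARGP820101", "FAUJ880109",
                                             "FAUJ880103"), "G"]))
  expect_equal(sm, ss, ignore_attr = TRUE)
  asa <- compute_asa(m, n_points = 240)
  al <- asa_layers(sh, asa)
  expect_equal(unname(al$ASAm[2]), unname(asa$residue_asa["A:2:"]))
  expect_equal(al$ASAm, al$ASAs, ignore_attr = TRUE)
  expect_true(all(al$ASAm[-2] == 0))
})

test_that("ASA layer blocks match brute-force recomputation", {
  fx <- descr_fixture()
  for (k in fx$iab$residues$key[c(5, 20, 45)]) {
    sh <- build_shells(fx$iab, k)
    al <- asa_layers(sh, fx$asa)
    for (l in seq_len(10)) {
      mem <- sh$layers[[l]]
      expect_equal(unname(al$ASAm[l]),
                   if (length(mem)) max(fx$asa$residue_asa[mem]) else 0)
      expect_equal(unname(al$ASAs[l]),
                   if (length(mem)) sum(fx$asa$residue_asa[mem]) else 0)
    }
  }
  bad <- fx$asa
  bad$residue_asa <- bad$residue_asa[-1]
  sh1 <- build_shells(fx$iab, fx$iab$residues$key[2])
  expect_error(asa_layers(sh1, bad), "missing")
})

test_that("cross terms are elementwise products with the stated shapes", {
  expect_error(cross_terms(1, rep(1, 3), rep(1, 30), rep(1, 30),
                           rep(1, 10), rep(1, 10)), "mismatch")
  ct0 <- cross_terms(c(2, 3), c(1, 2, 3), rep(1, 30), rep(1, 30),
                     rep(0, 10), rep(0, 10))
  expect_true(all(ct0$InterD2 == 0) && all(ct0$InterD3 == 0))
  ct1 <- cross_terms(c(1, 1), c(4, 5, 6), rep(1, 30), rep(1, 30),
                     rep(1, 10), rep(1, 10))
  expect_equal(unname(ct1$InterD1), c(4, 5, 6, 4, 5, 6))

  set.seed(2)
  dsd_v <- runif(2); iad_v <- runif(3); sedm <- runif(30); seds <- runif(30)
  asam <- runif(10); asas <- runif(10)
  ct <- cross_terms(dsd_v, iad_v, sedm, seds, asam, asas)
  for (l in 1:10) for (i in 1:3) {
    expect_equal(unname(ct$InterD2[(l - 1) * 3 + i]),
                 asam[l] * sedm[(l - 1) * 3 + i])
    expect_equal(unname(ct$InterD3[(l - 1) * 3 + i]),
                 asas[l] * seds[(l - 1) * 3 + i])
  }
  expect_equal(unname(ct$InterD1), as.vector(outer(iad_v, dsd_v)))
})

test_that("the assembled descriptor has 151 elements in the stated block layout", {
  fx <- descr_fixture()
  k <- fx$iab$residues$key[12]
  d <- assemble_descriptor(fx$iab, k, fx$bp, fx$asa, fx$tab)
  expect_length(d, 151L)
  expect_equal(unname(attr(d, "blocks")),
               c(2L, 3L, 30L, 30L, 10L, 10L, 6L, 30L, 30L))
  expect_equal(names(d), descriptor_names())
  expect_true(all(is.finite(d)))

  # every element equals its sub-operation recomputed independently
  sh <- build_shells(fx$iab, k)
  expect_equal(d[1:2], dsd(fx$iab, k, fx$bp))
  expect_equal(d[3:5], iad(fx$iab, k, fx$tab))
  expect_equal(d[6:35], sed_max(sh, fx$iab, fx$tab))
  expect_equal(d[36:65], sed_sum(sh, fx$iab, fx$tab))
  al <- asa_layers(sh, fx$asa)
  expect_equal(d[66:75], al$ASAm)
  expect_equal(d[76:85], al$ASAs)
  ct <- cross_terms(d[1:2], d[3:5], d[6:35], d[36:65], d[66:75], d[76:85])
  expect_equal(d[86:91], ct$InterD1)
  expect_equal(d[92:121], ct$InterD2)
  expect_equal(d[122:151], ct$InterD3)
})

test_that("an isolated residue yields zero shell blocks but live DSD and IAD", {
  pdb <- paste(c(
    pdb_atom_line(1, "CA", "TRP", "A", 1, c(0, 0, 0), "C"),
    pdb_atom_line(2, "CA", "GLY", "A", 2, c(50, 0, 0), "C"),
    "END"), collapse = "\n")
  m <- parse_structure(pdb)
  asa <- compute_asa(m, n_points = 240)
  anchors <- structure(list(p1 = c(10, 0, 0), p2 = c(0, 10, 0),
                            source_bonds = NULL), class = "benchmark_points")
  d <- assemble_descriptor(m, "A:1:", anchors, asa)
  expect_true(all(d[6:85] == 0))   # SEDm/SEDs/ASAm/ASAs
  expect_true(all(d[92:151] == 0)) # InterD2/InterD3
  expect_true(all(d[1:5] != 0))
  expect_true(all(d[86:91] != 0))
})

test_that("the full descriptor is rigid-motion invariant", {
  fx <- descr_fixture()
  motion <- random_rigid_motion(21)
  rot <- rotate_model(fx$iab, motion)
  asa_rot <- compute_asa(rot, n_points = 240)
  bp_rot <- select_benchmark_points(rot, detect_disulfides(rot))
  for (k in fx$iab$residues$key[c(2, 18, 33)]) {
    d0 <- assemble_descriptor(fx$iab, k, fx$bp, fx$asa, fx$tab)
    d1 <- assemble_descriptor(rot, k, bp_rot, asa_rot, fx$tab)
    expect_equal(d1, d0, tolerance = 1e-6)
  }
})

test_that("the feature table covers exactly the surface and epitope residues", {
  tm <- .toy1()
  out <- featurize_structure(tm$model, n_points = 240)
  cm <- out$classmap
  expect_equal(nrow(out$features),
               sum(cm$class %in% c("SURFACE_NONIMMUNOGENIC", "EPITOPE")))
  expect_equal(ncol(out$features), 7L + 151L)
  expect_setequal(out$features$key[out$features$class == "EPITOPE"],
                  tm$toy$manifest$interface$key)
})
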