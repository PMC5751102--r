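test_that("parsing handles minimal records, altlocs and role maps", {
  line <- pdb_atom_line(1, "CA", "ALA", "A", 1, c(1, 2, 3), "C")
  m <- parse_structure(paste(c(line, "END"), collapse = "\n"))
  expect_equal(length(m$roles), 1L)
  expect_equal(nrow(m$residues), 1L)
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(unname(m$roles["A"]), "IAB")
  expect_equal(as.numeric(m$residues[1, c("cx", "cy", "cz")]), c(1, 2, 3))

  # altloc collapse keeps the highest-occupancy conformer
  alt <- paste(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, c(0, 0, 0), "C", occupancy = 0.6,
                  altloc = "A"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, c(5, 0, 0), "C", occupancy = 0.4,
                  altloc = "B"),
    "END"), collapse = "\n")
  ma <- parse_structure(alt)
  expect_equal(nrow(ma$atoms), 1L)
  expect_equal(ma$atoms$x, 0)
  expect_equal(ma$atoms$altloc, "A")

  expect_error(parse_structure(""), "empty")
  expect_error(parse_structure(paste(c(line, "END"), collapse = "\n"),
                               roles = c(Z = "IAB")), "not present")
})

test_that("hydrogens and waters are dropped; MSE becomes MET", {
  pdb <- paste(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, c(0, 0, 0), "C"),
    pdb_atom_line(2, "H", "ALA", "A", 1, c(0.5, 0, 0), "H"),
    sub("^ATOM  ", "HETATM", pdb_atom_line(3, "CA", "MSE", "A", 2,
                                           c(3.8, 0, 0), "C")),
    sub("^ATOM  ", "HETATM", pdb_atom_line(4, "O", "HOH", "A", 100,
                                           c(9, 9, 9), "O")),
    "END"), collapse = "\n")
  m <- parse_structure(pdb)
  expect_equal(nrow(m$atoms), 2L)
  expect_false(any(m$atoms$element == "H"))
  expect_equal(m$residues$aa3, c("ALA", "MET"))
  expect_true(all(m$residues$standard))
})

test_that("fixture parse matches the generator manifest", {
  tm <- .toy1()
  expect_equal(nrow(tm$model$atoms), tm$toy$manifest$n_atoms)
  expect_equal(nrow(tm$model$residues), tm$toy$manifest$n_residues)
  for (ch in c("A", "B")) {
    got <- tm$model$residues[tm$model$residues$chain == ch, ]
    expect_equal(nrow(got), tm$toy$manifest$chains[[ch]]$n)
    expect_equal(stats::setNames(got$aa3, got$key),
                 tm$toy$manifest$chains[[ch]]$aa)
  }
})

test_that("epitope labeling is a strict 5 Angstrom nearest-atom rule", {
  expect_equal(label_epitope_residues(two_residue_complex(4.9)), "A:1:")
  expect_equal(label_epitope_residues(two_residue_complex(5.0)), character(0))
  expect_equal(label_epitope_residues(two_residue_complex(5.0),
                                      ab_params(epitope_cutoff = 5.1)),
               "A:1:")
  m <- two_residue_complex(4)
  m$roles["B"] <- "IGNORE"
  expect_error(label_epitope_residues(m), "no ADA chain")
})

test_that("epitope labels match the brute-force all-pairs scan and recover the plant", {
  for (seed in c(1, 4)) {
    tm <- toy_model(seed = seed, n_interface = 5)
    got <- label_epitope_residues(tm$model)
    expect_equal(got, oracle_epitope(tm$model, 5.0))
    expect_setequal(got, tm$toy$manifest$interface$key)
  }
})

test_that("epitope sets grow monotonically with the cutoff", {
  tm <- .toy1()
  sets <- lapply(c(4, 5, 6, 8), function(cut) {
    label_epitope_residues(tm$model, ab_params(epitope_cutoff = cut))
  })
  for (i in seq_len(length(sets) - 1L)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1L]]))
  }
})

test_that("residue classification is total and matches recomputation", {
  tm <- .toy1()
  iab <- iab_model(tm$model)
  asa <- compute_asa(iab, n_points = 240)
  ep <- label_epitope_residues(tm$model)
  cm <- classify_residues(tm$model, asa$residue_rasa, ep)
  expect_equal(nrow(cm), nrow(iab$residues))
  expect_false(any(duplicated(cm$key)))
  # epitope wins; the rest split on the rASA threshold
  expect_setequal(cm$key[cm$class == "EPITOPE"], ep)
  others <- cm[cm$class != "EPITOPE", ]
  expect_equal(others$class == "SURFACE_NONIMMUNOGENIC",
               unname(asa$residue_rasa[others$key] >= 0.05))
  # direct threshold cases
  rasa <- stats::setNames(rep(0.5, nrow(iab$residues)), iab$residues$key)
  rasa[iab$residues$key[1]] <- 0
  cm2 <- classify_residues(tm$model, rasa, character())
  expect_equal(cm2$class[1], "CORE")
  expect_true(all(cm2$class[-1] == "SURFACE_NONIMMUNOGENIC"))
  expect_error(classify_residues(tm$model, rasa[-1], character()), "missing")
})

test_that("epitope labels survive rigid motion", {
  tm <- .toy1()
  base <- label_epitope_residues(tm$model)
  rot <- rotate_model(tm$model, random_rigid_motion(7))
  expect_equal(label_epitope_residues(rot), base)
})

test_that("region grouping is single linkage on centroids", {
  tm <- .toy1()
  keys <- tm$model$residues$key[1:2]  # adjacent, ~5.5 A apart
  expect_length(group_epitope_regions(keys, tm$model, 10), 1L)
  far <- c(tm$model$residues$key[1], tm$model$residues$key[10])
  expect_length(group_epitope_regions(far, tm$model, 10), 2L)
  expect_equal(group_epitope_regions(character(), tm$model), list())

  tp <- toy_model(seed = 3, n_interface = 6, n_patches = 2)
  ep <- label_epitope_residues(tp$model)
  regions <- group_epitope_regions(ep, tp$model, 10)
  expect_length(regions, 2L)
  expect_setequal(
    lapply(regions, sort),
    lapply(tp$toy$manifest$patches, sort))
})
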