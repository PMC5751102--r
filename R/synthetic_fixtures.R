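# Deterministic synthetic structures and planted-signal datasets.
#
# The toy antibody is not a physical fold: it is a controlled geometry on a
# perturbed lattice in which every quantity the pipeline later computes —
# interface contacts, disulfide pairs, shell memberships — is planted with
# known ground truth and wide safety margins, so tests can compare pipeline
# output against the generator's manifest.

# run code under a seed without disturbing the caller's RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Format one PDB ATOM record
#'
#' Fixed-width ATOM line (columns per the PDB format spec, coordinates
#' 8.3); used by the fixture generators and handy for building minimal
#' test structures.
#'
#' @param serial Atom serial number.
#' @param name Atom name (1-3 characters, e.g. `"CA"`, `"SG"`).
#' @param aa3 Residue name.
#' @param chain Chain id (single character).
#' @param resno Residue number.
#' @param xyz Numeric 3-vector.
#' @param element Element symbol.
#' @param icode Insertion code, default none.
#' @param occupancy,bfactor Occupancy and B-factor fields.
#' @param altloc Alternate-location indicator, default none.
#' @return A single character string.
#' @export
pdb_atom_line <- function(serial, name, aa3, chain, resno, xyz,
                          element = substr(name, 1L, 1L), icode = "",
                          occupancy = 1.0, bfactor = 0.0, altloc = "") {
  nm <- if (nchar(name) < 4L) sprintf("%-4s", paste0(" ", name)) else name
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, substr(paste0(altloc, " "), 1L, 1L), aa3, chain, resno,
          substr(paste0(icode, " "), 1L, 1L),
          xyz[1L], xyz[2L], xyz[3L], occupancy, bfactor, element)
}

# standard amino acids excluding CYS (CYS placed only where planted)
#' @keywords internal
NON_CYS_AA3 <- setdiff(names(AA3_TO_AA1), "CYS")

#' Generate a deterministic toy antibody complex
#'
#' Emits PDB text for a three-chain complex: two IAB chains (`A` = light,
#' `B` = heavy) on jittered straight-line backbones (one CA and one
#' pseudo-side-chain atom per residue), each carrying a planted
#' intra-chain CYS-CYS pair at SG distance 2.03 Angstrom, plus an ADA
#' chain (`C`) whose contact residues are placed so that exactly
#' `n_interface` chain-A residues have nearest-atom distance inside
#' (3.8, 4.9) Angstrom while every other IAB residue stays at least 6
#' Angstrom from all ADA atoms. With `n_patches = 2` the interface is
#' split into two sequence-separated patches more than 25 Angstrom apart.
#' The same seed always yields byte-identical PDB text.
#'
#' @param seed Integer seed.
#' @param n_res_per_chain Residues per IAB chain (>= 20).
#' @param n_interface Number of planted epitope residues (>= 1).
#' @param params An [ab_params()] object (used for validation cutoffs).
#' @param n_patches 1 or 2 spatial epitope patches.
#' @param n_ss_per_chain 1 or 2 planted disulfide bonds per IAB chain.
#' @return List with `pdb` (single string), `roles` (named vector for
#'   [parse_structure()]) and `manifest` (seed, per-chain residue counts
#'   and amino acids, planted bonds with SG distances, planted interface
#'   keys with nearest-atom distances, patch memberships, atom count).
#' @examples
#' toy <- generate_toy_antibody(seed = 7, n_interface = 4)
#' toy$manifest$interface$key
#' @export
generate_toy_antibody <- function(seed = 1L, n_res_per_chain = 30L,
                                  n_interface = 6L, params = ab_params(),
                                  n_patches = 1L, n_ss_per_chain = 1L) {
  n <- as.integer(n_res_per_chain)
  if (n < 20L) stop("n_res_per_chain must be >= 20")
  if (n_interface < 1L) stop("n_interface must be >= 1")
  if (!n_patches %in% 1:2) stop("n_patches must be 1 or 2")
  if (!n_ss_per_chain %in% 1:2) stop("n_ss_per_chain must be 1 or 2")

  spacing <- 5.5
  ss_pos <- list(c(3L, 4L), c(13L, 14L))[seq_len(n_ss_per_chain)]
  ss_res <- unlist(ss_pos)

  # interface layout on chain A: contiguous runs clear of CYS positions and
  # chain ends
  first_free <- max(ss_res) + 2L
  if (n_patches == 1L) {
    starts <- first_free
    lens <- n_interface
  } else {
    lens <- c(ceiling(n_interface / 2), floor(n_interface / 2))
    starts <- c(first_free, n - 1L - lens[2L] + 1L - 1L)
  }
  patches <- lapply(seq_along(starts), function(i) {
    starts[i]:(starts[i] + lens[i] - 1L)
  })
  iface <- unlist(patches)
  if (any(iface > n - 2L) || (n_patches == 2L &&
                              patches[[2L]][1L] - patches[[1L]][lens[1L]] < 6L)) {
    stop("infeasible geometry: chain too short for requested interface layout")
  }

  with_seed(seed, {
    jit <- function(n, a) stats::runif(n, -a, a)

    build_chain <- function(chain, z0) {
      ca <- cbind(spacing * seq_len(n) + jit(n, 0.15), jit(n, 0.1),
                  z0 + jit(n, 0.15))
      cb <- ca + cbind(jit(n, 0.1), 2.0, jit(n, 0.1))
      aa <- sample(NON_CYS_AA3, n, replace = TRUE)
      aa[ss_res] <- "CYS"
      sg <- matrix(NA_real_, n, 3L)
      for (pr in ss_pos) {
        m <- (ca[pr[1L], ] + ca[pr[2L], ]) / 2 + c(0, -2.5, 0)
        sg[pr[1L], ] <- m - c(1.015, 0, 0)
        sg[pr[2L], ] <- m + c(1.015, 0, 0)
      }
      list(chain = chain, ca = ca, cb = cb, sg = sg, aa = aa)
    }

    A <- build_chain("A", 0)
    B <- build_chain("B", 14)

    # ADA chain: far-away bulk plus one contact residue per planted epitope
    n_bulk <- 8L
    bulk_ca <- cbind(spacing * seq_len(n_bulk), 60 + jit(n_bulk, 0.2),
                     jit(n_bulk, 0.2))
    d_plant <- stats::runif(length(iface), 3.8, 4.9)
    contact_ca <- A$cb[iface, , drop = FALSE] +
      cbind(0, d_plant, 0)
    contact_cb <- contact_ca
    contact_cb[, 2L] <- contact_cb[, 2L] + 1.5
    ada_aa <- sample(NON_CYS_AA3, n_bulk + length(iface), replace = TRUE)

    # ---- plant validation against the package's stated cutoffs ----
    iab_xyz <- rbind(A$ca, A$cb, A$sg[!is.na(A$sg[, 1L]), , drop = FALSE],
                     B$ca, B$cb, B$sg[!is.na(B$sg[, 1L]), , drop = FALSE])
    iab_res <- c(rep(seq_len(n), 2L), which(!is.na(A$sg[, 1L])),
                 rep(seq_len(n) + n, 2L), which(!is.na(B$sg[, 1L])) + n)
    ada_xyz <- rbind(bulk_ca, contact_ca, contact_cb)
    nearest <- vapply(seq_len(2L * n), function(r) {
      rows <- iab_res == r
      min(sqrt(outer(rowSums(iab_xyz[rows, , drop = FALSE]^2),
                     rowSums(ada_xyz^2), "+") -
                 2 * iab_xyz[rows, , drop = FALSE] %*% t(ada_xyz)))
    }, 0)
    planted <- rep(FALSE, 2L * n); planted[iface] <- TRUE
    if (any(nearest[planted] >= params$epitope_cutoff) ||
        any(nearest[planted] <= 3.5) ||
        any(nearest[!planted] < 6)) {
      stop("infeasible geometry: planted contact distances violated")
    }

    # ---- emit PDB ----
    lines <- character(0L)
    serial <- 0L
    emit <- function(name, aa3, chain, resno, xyz, element) {
      serial <<- serial + 1L
      lines[[length(lines) + 1L]] <<-
        pdb_atom_line(serial, name, aa3, chain, resno, xyz, element)
    }
    for (ch in list(A, B)) {
      for (i in seq_len(n)) {
        emit("CA", ch$aa[i], ch$chain, i, ch$ca[i, ], "C")
        emit("CB", ch$aa[i], ch$chain, i, ch$cb[i, ], "C")
        if (!is.na(ch$sg[i, 1L])) emit("SG", ch$aa[i], ch$chain, i,
                                       ch$sg[i, ], "S")
      }
      lines[[length(lines) + 1L]] <- "TER"
    }
    for (i in seq_len(n_bulk)) {
      emit("CA", ada_aa[i], "C", i, bulk_ca[i, ], "C")
    }
    for (j in seq_along(iface)) {
      i <- n_bulk + j
      emit("CA", ada_aa[i], "C", i, contact_ca[j, ], "C")
      emit("CB", ada_aa[i], "C", i, contact_cb[j, ], "C")
    }
    lines <- c(lines, "TER", "END")

    key_a <- residue_key("A", seq_len(n))
    key_b <- residue_key("B", seq_len(n))
    bonds <- do.call(rbind, lapply(list(c("A", key_a), c("B", key_b)),
      function(chk) {
        do.call(rbind, lapply(ss_pos, function(pr) {
          data.frame(cys1 = chk[1L + pr[1L]], cys2 = chk[1L + pr[2L]],
                     sg_distance = 2.03, stringsAsFactors = FALSE)
        }))
      }))

    manifest <- list(
      seed = as.integer(seed),
      chains = list(A = list(n = n, role = "IAB", aa = stats::setNames(A$aa, key_a)),
                    B = list(n = n, role = "IAB", aa = stats::setNames(B$aa, key_b)),
                    C = list(n = n_bulk + length(iface), role = "ADA")),
      cys_bonds = bonds,
      interface = data.frame(key = key_a[iface], distance = d_plant,
                             patch = rep(seq_along(patches), lens),
                             stringsAsFactors = FALSE),
      patches = lapply(patches, function(p) key_a[p]),
      n_atoms = serial,
      n_residues = 2L * n + n_bulk + length(iface)
    )

    list(pdb = paste(lines, collapse = "\n"),
         roles = c(A = "IAB", B = "IAB", C = "ADA"),
         manifest = manifest)
  })
}

#' Generate a planted-signal descriptor dataset
#'
#' Draws `n_rows` feature vectors of width 151 (named like real
#' descriptors) from a standard normal, and labels from a logistic model
#' whose coefficient vector is nonzero on the first ten feature positions
#' with alternating signs and Euclidean norm `effect_size`; the intercept
#' is `qlogis(imbalance)`, so `imbalance` is the marginal positive rate at
#' zero effect. `effect_size = 0` gives label noise (null data).
#'
#' @param seed Integer seed.
#' @param n_rows Number of rows (>= 100).
#' @param effect_size Euclidean norm of the true coefficient vector.
#' @param imbalance Baseline positive-class fraction, in (0, 1).
#' @param n_structures Rows are attributed round-robin to this many
#'   pseudo-structures (for per-structure evaluation). Default 8.
#' @return A `labeled_dataset` with an extra `manifest` element recording
#'   the true coefficients and intercept.
#' @export
generate_descriptor_dataset <- function(seed = 1L, n_rows = 5000L,
                                        effect_size = 2, imbalance = 0.2,
                                        n_structures = 8L) {
  n_rows <- as.integer(n_rows)
  if (n_rows < 100L) stop("n_rows must be >= 100")
  if (!(imbalance > 0 && imbalance < 1)) stop("imbalance must be in (0, 1)")
  p <- 151L
  with_seed(seed, {
    x <- matrix(stats::rnorm(n_rows * p), n_rows, p,
                dimnames = list(NULL, descriptor_names()))
    beta <- numeric(p)
    beta[1:10] <- rep(c(1, -1), 5L) * effect_size / sqrt(10)
    intercept <- stats::qlogis(imbalance)
    prob <- sigmoid(intercept + drop(x %*% beta))
    y <- stats::rbinom(n_rows, 1L, prob)
    if (length(unique(y)) < 2L) {
      stop("degenerate draw: a single class was generated; adjust imbalance")
    }
    structure(
      list(x = x, y = y,
           structure_id = sprintf("sim%02d",
                                  rep_len(seq_len(n_structures), n_rows)),
           key = residue_key("S", seq_len(n_rows)),
           manifest = list(seed = as.integer(seed), beta = beta,
                           intercept = intercept,
                           effect_size = effect_size,
                           imbalance = imbalance)),
      class = "labeled_dataset")
  })
}

#' Extended tripeptide fixture with full heavy-atom backbone
#'
#' Builds an idealised fully extended (all-trans) tripeptide with N, CA,
#' C, O and (except glycine) CB atoms from standard bond lengths and
#' angles, as PDB text. The central residue of such a peptide is the
#' classical reference geometry for maximum solvent exposure, so its
#' relative ASA should sit near 1.
#'
#' @param central Three-letter code of the central residue.
#' @param flank Three-letter code of both flanking residues.
#' @return PDB text (single string), chain A, residues 1-3.
#' @export
generate_extended_tripeptide <- function(central = "ALA", flank = "GLY") {
  aa <- c(flank, central, flank)
  if (!all(aa %in% names(AA3_TO_AA1))) stop("unknown residue code")
  # backbone zigzag in the xy-plane: consecutive atoms N, CA, C per residue
  blen <- c(NCA = 1.458, CAC = 1.525, CN = 1.329)
  ang <- c(N = 121.7, CA = 111.0, C = 116.2) * pi / 180
  pos <- matrix(0, 9L, 3L)
  atom <- rep(c("N", "CA", "C"), 3L)
  dir <- 0  # current bond direction angle in the plane
  sgn <- 1
  for (k in 2:9) {
    prev <- atom[k - 1L]
    len <- switch(prev, N = blen["NCA"], CA = blen["CAC"], C = blen["CN"])
    if (k > 2L) {
      dir <- dir + sgn * (pi - ang[[prev]])
      sgn <- -sgn
    }
    pos[k, ] <- pos[k - 1L, ] + len * c(cos(dir), sin(dir), 0)
  }
  lines <- character(0L)
  serial <- 0L
  for (r in 1:3) {
    iN <- 3L * (r - 1L) + 1L; iCA <- iN + 1L; iC <- iN + 2L
    nxt <- if (r < 3L) pos[iC + 1L, ] else
      pos[iC, ] + (pos[iC, ] - pos[iCA, ])  # virtual next N at C-terminus
    # carbonyl O in-plane, opposite the N(next)/CA bisector
    vo <- -((nxt - pos[iC, ]) / sqrt(sum((nxt - pos[iC, ])^2)) +
              (pos[iCA, ] - pos[iC, ]) / sqrt(sum((pos[iCA, ] - pos[iC, ])^2)))
    o <- pos[iC, ] + 1.231 * vo / sqrt(sum(vo^2))
    emit <- function(name, xyz, el) {
      serial <<- serial + 1L
      lines[[length(lines) + 1L]] <<-
        pdb_atom_line(serial, name, aa[r], "A", r, xyz, el)
    }
    emit("N", pos[iN, ], "N")
    emit("CA", pos[iCA, ], "C")
    emit("C", pos[iC, ], "C")
    emit("O", o, "O")
    if (aa[r] != "GLY") {
      vb <- -((pos[iN, ] - pos[iCA, ]) / blen["NCA"] +
                (pos[iC, ] - pos[iCA, ]) / blen["CAC"])
      vb <- vb / sqrt(sum(vb^2)) + c(0, 0, if (r %% 2L) 1 else -1)
      emit("CB", pos[iCA, ] + 1.53 * vb / sqrt(sum(vb^2)), "C")
    }
  }
  paste(c(lines, "TER", "END"), collapse = "\n")
}
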