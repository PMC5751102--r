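# PDB ingestion and residue classification.
#
# A parsed structure is held as an `ab_structure`: a heavy-atom table, a
# residue table with centroids, and a chain-role map distinguishing the
# immunogenic antibody (IAB) from the anti-drug antibody (ADA).

#' Canonical residue key
#'
#' Residues are addressed everywhere by the string `"chain:resno:icode"`,
#' e.g. `"A:100:"` or `"B:100:A"`. The insertion code is empty for the
#' common case; ordering of keys follows PDB convention
#' (chain, then residue number, then blank < "A" < "B" ...).
#'
#' @param chain Chain identifier(s), single characters.
#' @param resno Residue sequence number(s).
#' @param icode Insertion code(s); `""` or `NA` for none.
#' @return Character vector of keys.
#' @export
residue_key <- function(chain, resno, icode = "") {
  icode <- as.character(icode)
  icode[is.na(icode)] <- ""
  sprintf("%s:%d:%s", chain, as.integer(resno), icode)
}

#' @keywords internal
split_residue_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  data.frame(
    chain = vapply(parts, `[`, "", 1L),
    resno = as.integer(vapply(parts, `[`, "", 2L)),
    icode = vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "", ""),
    stringsAsFactors = FALSE
  )
}

VALID_ROLES <- c("IAB", "ADA", "IGNORE")

#' @keywords internal
guess_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  el <- substr(nm, 1L, 1L)
  el[nm %in% c("SE", "SG", "SD")] <- "S"   # sulfur/selenium side-chain atoms
  el[startsWith(nm, "CL")] <- "CL"
  el[el == ""] <- "C"
  el
}

#' Parse a PDB structure with chain-role annotation
#'
#' Reads ATOM (and polymeric HETATM) records into an `ab_structure`. Only
#' heavy atoms are retained; waters are dropped; alternate locations are
#' collapsed to the highest-occupancy conformer (ties broken by altloc
#' letter); selenomethionine (MSE) is treated as MET. Residues outside the
#' 20 standard amino acids are kept for geometry but flagged nonstandard,
#' which excludes them from descriptor generation.
#'
#' @param pdb Either a path to a PDB file or a character vector/string of
#'   PDB text containing at least one ATOM record.
#' @param roles Named character vector or list mapping chain id to one of
#'   `"IAB"` (immunogenic antibody), `"ADA"` (anti-drug antibody) or
#'   `"IGNORE"`. Chains absent from a supplied map default to `"IGNORE"`;
#'   with `roles = NULL` every chain is treated as IAB (prediction mode on
#'   an unbound antibody).
#' @param structure_id Identifier stored with the model (e.g. a PDB id).
#' @return An object of class `ab_structure` with elements `structure_id`,
#'   `atoms` (data frame: serial, name, element, altloc, occupancy, x, y, z,
#'   chain, resno, icode, aa3, key), `residues` (data frame: key, chain,
#'   resno, icode, aa3, n_atoms, standard, cx, cy, cz) and `roles`.
#' @examples
#' toy <- generate_toy_antibody(seed = 1)
#' mod <- parse_structure(toy$pdb, roles = toy$roles, structure_id = "toy1")
#' mod
#' @export
parse_structure <- function(pdb, roles = NULL, structure_id = "structure") {
  if (length(pdb) == 0L || !any(nzchar(pdb))) stop("empty PDB input")
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(paste(pdb, collapse = "\n"), "\n")), path)
  }
  p <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                        verbose = FALSE))
  at <- p$atom
  if (is.null(at) || nrow(at) == 0L) stop("no ATOM records found")

  keep <- at$type == "ATOM" | (at$type == "HETATM" & at$resid == "MSE")
  at <- at[keep & !(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records found")

  # selenomethionine -> methionine
  mse <- at$resid == "MSE"
  at$resid[mse] <- "MET"
  at$elety[mse & at$elety == "SE"] <- "SD"

  element <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                            guess_element(at$elety), at$elesy))
  at <- at[!(element %in% c("H", "D")), , drop = FALSE]
  element <- element[!(element %in% c("H", "D"))]
  if (nrow(at) == 0L) stop("structure contains no heavy atoms")

  icode <- ifelse(is.na(at$insert), "", at$insert)
  chain <- ifelse(is.na(at$chain), " ", at$chain)
  occ <- ifelse(is.na(at$o), 1.0, at$o)
  altloc <- ifelse(is.na(at$alt), "", at$alt)

  atoms <- data.frame(
    serial = at$eleno, name = at$elety, element = element,
    altloc = altloc, occupancy = occ,
    x = at$x, y = at$y, z = at$z,
    chain = chain, resno = at$resno, icode = icode, aa3 = at$resid,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }

  # altloc collapse: within (residue, atom name) keep highest occupancy,
  # ties by altloc letter order (blank sorts first).
  grp <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name, sep = "\r")
  ord <- order(grp, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(grp[ord]), , drop = FALSE]

  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$icode, atoms$serial), ,
                 drop = FALSE]
  atoms$key <- residue_key(atoms$chain, atoms$resno, atoms$icode)
  rownames(atoms) <- NULL

  first <- !duplicated(atoms$key)
  residues <- data.frame(
    key = atoms$key[first],
    chain = atoms$chain[first],
    resno = atoms$resno[first],
    icode = atoms$icode[first],
    aa3 = atoms$aa3[first],
    stringsAsFactors = FALSE
  )
  residues$n_atoms <- as.integer(table(atoms$key)[residues$key])
  residues$standard <- residues$aa3 %in% names(AA3_TO_AA1)
  residues$cx <- tapply(atoms$x, atoms$key, mean)[residues$key]
  residues$cy <- tapply(atoms$y, atoms$key, mean)[residues$key]
  residues$cz <- tapply(atoms$z, atoms$key, mean)[residues$key]
  rownames(residues) <- NULL

  chains <- unique(residues$chain)
  if (is.null(roles)) {
    roles <- stats::setNames(rep("IAB", length(chains)), chains)
  } else {
    roles <- stats::setNames(toupper(unlist(roles)), names(roles))
    unknown <- setdiff(names(roles), chains)
    if (length(unknown)) {
      stop("roles refer to chain(s) not present in the structure: ",
           paste(unknown, collapse = ", "))
    }
    if (!all(roles %in% VALID_ROLES)) {
      stop("chain roles must be one of ", paste(VALID_ROLES, collapse = ", "))
    }
    missing <- setdiff(chains, names(roles))
    roles <- c(roles, stats::setNames(rep("IGNORE", length(missing)), missing))
  }
  roles <- roles[chains]  # model chain order

  structure(
    list(structure_id = structure_id, atoms = atoms, residues = residues,
         roles = roles),
    class = "ab_structure"
  )
}

#' @export
print.ab_structure <- function(x, ...) {
  cat(sprintf("ab_structure '%s': %d chains, %d residues, %d heavy atoms\n",
              x$structure_id, length(x$roles), nrow(x$residues),
              nrow(x$atoms)))
  for (ch in names(x$roles)) {
    cat(sprintf("  chain %s [%s]: %d residues\n", ch, x$roles[[ch]],
                sum(x$residues$chain == ch)))
  }
  invisible(x)
}

#' @keywords internal
chains_with_role <- function(model, role) {
  names(model$roles)[model$roles == role]
}

#' Restrict a structure to a subset of chains
#'
#' @param model An `ab_structure`.
#' @param chains Chain ids to keep.
#' @return An `ab_structure` with only those chains.
#' @export
subset_chains <- function(model, chains) {
  stopifnot(inherits(model, "ab_structure"))
  missing <- setdiff(chains, names(model$roles))
  if (length(missing)) stop("unknown chain(s): ", paste(missing, collapse = ", "))
  model$atoms <- model$atoms[model$atoms$chain %in% chains, , drop = FALSE]
  model$residues <- model$residues[model$residues$chain %in% chains, , drop = FALSE]
  model$roles <- model$roles[names(model$roles) %in% chains]
  rownames(model$atoms) <- rownames(model$residues) <- NULL
  model
}

#' The immunogenic-antibody part of a complex
#'
#' @param model An `ab_structure`.
#' @return The model restricted to IAB chains.
#' @export
iab_model <- function(model) {
  ch <- chains_with_role(model, "IAB")
  if (!length(ch)) stop("model has no IAB chain")
  subset_chains(model, ch)
}

# rigid-motion helper used by invariance checks: y = R x + t
#' @keywords internal
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2L, translation, "+")
  model$atoms$x <- xyz[, 1L]; model$atoms$y <- xyz[, 2L]; model$atoms$z <- xyz[, 3L]
  cen <- as.matrix(model$residues[, c("cx", "cy", "cz")]) %*% t(rotation)
  cen <- sweep(cen, 2L, translation, "+")
  model$residues$cx <- cen[, 1L]; model$residues$cy <- cen[, 2L]
  model$residues$cz <- cen[, 3L]
  model
}

#' Label epitope residues of the immunogenic antibody
#'
#' A residue of the IAB is an epitope residue when at least one of its heavy
#' atoms lies strictly closer than `params$epitope_cutoff` (default 5
#' Angstrom) to any heavy atom of the ADA.
#'
#' @param model An `ab_structure` with at least one IAB and one ADA chain.
#' @param params An [ab_params()] object.
#' @return Character vector of epitope residue keys (possibly empty).
#' @export
label_epitope_residues <- function(model, params = ab_params()) {
  stopifnot(inherits(model, "ab_structure"))
  iab_ch <- chains_with_role(model, "IAB")
  ada_ch <- chains_with_role(model, "ADA")
  if (!length(iab_ch)) stop("model has no IAB chain")
  if (!length(ada_ch)) stop("model has no ADA chain")

  a <- model$atoms[model$atoms$chain %in% iab_ch, , drop = FALSE]
  b <- model$atoms[model$atoms$chain %in% ada_ch, , drop = FALSE]
  ax <- as.matrix(a[, c("x", "y", "z")])
  bx <- as.matrix(b[, c("x", "y", "z")])

  cut2 <- params$epitope_cutoff^2
  hit <- logical(nrow(a))
  # chunked squared-distance scan keeps memory bounded for large complexes
  chunk <- max(1L, floor(2e6 / max(1L, nrow(bx))))
  for (s in seq(1L, nrow(ax), by = chunk)) {
    idx <- s:min(nrow(ax), s + chunk - 1L)
    d2 <- outer(rowSums(ax[idx, , drop = FALSE]^2), rowSums(bx^2), "+") -
      2 * ax[idx, , drop = FALSE] %*% t(bx)
    hit[idx] <- apply(d2, 1L, min) < cut2
  }
  sort(unique(a$key[hit]))
}

#' Partition IAB residues into core / surface / epitope classes
#'
#' Epitope membership wins; otherwise a residue is surface when its relative
#' ASA reaches `params$surface_rasa_threshold`, else core. Epitope residues
#' are exempt from the rASA test: a contact residue is solvent-reachable by
#' construction.
#'
#' @param model An `ab_structure`.
#' @param rasa Named numeric vector of relative ASA fractions covering every
#'   IAB residue key (see [relative_asa()]).
#' @param epitope Character vector of epitope residue keys (possibly empty).
#' @param params An [ab_params()] object.
#' @return A data frame of class `residue_class_map` with columns key,
#'   chain, resno, icode, aa3 and class in
#'   `{CORE, SURFACE_NONIMMUNOGENIC, EPITOPE}`.
#' @export
classify_residues <- function(model, rasa, epitope = character(),
                              params = ab_params()) {
  stopifnot(inherits(model, "ab_structure"))
  res <- model$residues[model$residues$chain %in% chains_with_role(model, "IAB"), ,
                        drop = FALSE]
  if (!nrow(res)) stop("model has no IAB residues")
  need <- setdiff(res$key, names(rasa))
  if (length(need)) {
    stop("rasa is missing entries for residue(s): ",
         paste(utils::head(need, 5L), collapse = ", "))
  }
  cls <- ifelse(res$key %in% epitope, "EPITOPE",
                ifelse(rasa[res$key] >= params$surface_rasa_threshold,
                       "SURFACE_NONIMMUNOGENIC", "CORE"))
  out <- data.frame(key = res$key, chain = res$chain, resno = res$resno,
                    icode = res$icode, aa3 = res$aa3, class = unname(cls),
                    stringsAsFactors = FALSE)
  class(out) <- c("residue_class_map", "data.frame")
  out
}

#' Group epitope residues into spatial regions
#'
#' Single-linkage clustering of epitope residues by centroid distance: two
#' residues belong to the same region when they are connected by a chain of
#' residues each at most `link_distance` apart. One complex can carry
#' several spatially distinct epitope patches.
#'
#' @param epitope Character vector of epitope residue keys.
#' @param model The `ab_structure` the keys refer to.
#' @param link_distance Linkage distance in Angstrom (default 10).
#' @return List of character vectors (disjoint regions covering all epitope
#'   residues); empty list for empty input.
#' @export
group_epitope_regions <- function(epitope, model, link_distance = 10) {
  if (!length(epitope)) return(list())
  res <- model$residues[match(epitope, model$residues$key), , drop = FALSE]
  if (anyNA(res$key)) stop("epitope keys not present in model")
  if (nrow(res) == 1L) return(list(res$key))
  d <- stats::dist(as.matrix(res[, c("cx", "cy", "cz")]))
  hc <- stats::hclust(d, method = "single")
  grp <- stats::cutree(hc, h = link_distance)
  unname(split(res$key, grp))
}

#' Write a residue class map as TSV
#'
#' @param classmap A `residue_class_map`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_class_map <- function(classmap, path) {
  utils::write.table(
    classmap[, c("chain", "resno", "icode", "aa3", "class")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
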