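# The 151-element integrated per-residue descriptor.
#
# Block layout (names addressable, sizes in parentheses):
#   DSD (2)      distances to the two disulfide benchmark points
#   IAD (3)      the residue's own ARGP820101 / FAUJ880109 / FAUJ880103
#   SEDm (30)    per-layer maximum of the three scales over shell members
#   SEDs (30)    per-layer sum of the three scales
#   ASAm (10)    per-layer maximum residue ASA
#   ASAs (10)    per-layer sum of residue ASA
#   InterD1 (6)  all pairwise products DSD_i * IAD_j
#   InterD2 (30) per layer, ASAm * SEDm (elementwise over the 3 scales)
#   InterD3 (30) per layer, ASAs * SEDs
# Total 2+3+30+30+10+10+6+30+30 = 151.

#' @keywords internal
DESCRIPTOR_BLOCKS <- c(DSD = 2L, IAD = 3L, SEDm = 30L, SEDs = 30L,
                       ASAm = 10L, ASAs = 10L, InterD1 = 6L,
                       InterD2 = 30L, InterD3 = 30L)

#' @keywords internal
layer_index_names <- function(prefix, n_layers = 10L,
                              indices = DESCRIPTOR_INDICES) {
  as.vector(vapply(seq_len(n_layers), function(l) {
    sprintf("%s_L%02d_%s", prefix, l, indices)
  }, character(length(indices))))
}

#' Names of the 151 descriptor elements
#'
#' @param n_layers Number of radial shells (default 10).
#' @return Character vector of length 151 in block order.
#' @export
descriptor_names <- function(n_layers = 10L) {
  c("DSD_p1", "DSD_p2",
    paste0("IAD_", DESCRIPTOR_INDICES),
    layer_index_names("SEDm", n_layers),
    layer_index_names("SEDs", n_layers),
    sprintf("ASAm_L%02d", seq_len(n_layers)),
    sprintf("ASAs_L%02d", seq_len(n_layers)),
    as.vector(outer(DESCRIPTOR_INDICES, c("DSD_p1", "DSD_p2"),
                    function(i, d) paste0("InterD1_", d, "_", i))),
    layer_index_names("InterD2", n_layers),
    layer_index_names("InterD3", n_layers))
}

#' Radial shell profile of a residue's neighborhood
#'
#' All residues with centroid-to-centroid distance strictly below
#' `params$neighborhood_radius` (default 20 Angstrom) of the target are
#' partitioned into `n_layers` half-open shells
#' `[(k-1) * layer_width, k * layer_width)`; a residue at exactly a layer
#' boundary falls in the outer layer, and one at exactly the neighborhood
#' radius is excluded. The target itself is never a member.
#'
#' @param model An `ab_structure` (typically the IAB alone).
#' @param target Residue key of the target residue.
#' @param params An [ab_params()] object.
#' @return Object of class `shell_profile`: list with `target`, `layers`
#'   (list of `n_layers` character vectors of residue keys) and `distances`
#'   (named numeric vector over all members).
#' @export
build_shells <- function(model, target, params = ab_params()) {
  stopifnot(inherits(model, "ab_structure"))
  i <- match(target, model$residues$key)
  if (is.na(i)) stop("unknown target residue: ", target)
  cen <- as.matrix(model$residues[, c("cx", "cy", "cz")])
  d <- sqrt(colSums((t(cen) - cen[i, ])^2))
  names(d) <- model$residues$key
  member <- d < params$neighborhood_radius & names(d) != target
  d <- d[member]
  layer <- pmin(floor(d / params$layer_width) + 1L, params$n_layers)
  layers <- lapply(seq_len(params$n_layers),
                   function(k) names(d)[layer == k])
  structure(list(target = target, layers = layers, distances = d),
            class = "shell_profile")
}

#' @export
print.shell_profile <- function(x, ...) {
  cat(sprintf("shell_profile for %s: %d neighbours in %d layers (%s)\n",
              x$target, length(x$distances), length(x$layers),
              paste(lengths(x$layers), collapse = "/")))
  invisible(x)
}

#' Individual AAindex descriptor of a residue
#'
#' The residue's own values of the three scales entering the descriptor:
#' hydrophobicity (ARGP820101), hydrogen-bond donors (FAUJ880109) and
#' normalized van der Waals volume (FAUJ880103). Depends only on amino-acid
#' identity.
#'
#' @param model An `ab_structure`.
#' @param target Residue key.
#' @param table AAindex table from [aaindex_table()].
#' @return Named numeric 3-vector.
#' @export
iad <- function(model, target, table = aaindex_table()) {
  i <- match(target, model$residues$key)
  if (is.na(i)) stop("unknown residue key: ", target)
  aa1 <- AA3_TO_AA1[model$residues$aa3[i]]
  if (is.na(aa1)) {
    stop("nonstandard residue ", model$residues$aa3[i],
         " has no AAindex values (", target, ")")
  }
  stats::setNames(table[DESCRIPTOR_INDICES, aa1],
                  paste0("IAD_", DESCRIPTOR_INDICES))
}

# shared worker: per-layer summary of the three AAindex scales over the
# standard-residue members of each shell; empty layer -> 0
#' @keywords internal
sed_layers <- function(shells, model, table, fun, prefix) {
  aa1_all <- stats::setNames(AA3_TO_AA1[model$residues$aa3],
                             model$residues$key)
  vals <- vapply(shells$layers, function(keys) {
    aa1 <- aa1_all[keys]
    aa1 <- aa1[!is.na(aa1)]  # nonstandard members carry no scale values
    if (!length(aa1)) return(numeric(3L))
    apply(table[DESCRIPTOR_INDICES, aa1, drop = FALSE], 1L, fun)
  }, numeric(3L))
  stats::setNames(as.vector(vals), layer_index_names(prefix, length(shells$layers)))
}

#' Shell-environment descriptor, per-layer maxima
#'
#' For each of the 10 layers, the maximum value of each of the three
#' AAindex scales over the residues in that layer; empty layers contribute
#' zeros. 3 scales x 10 layers = 30 elements.
#'
#' @param shells A `shell_profile`.
#' @param model The matching `ab_structure`.
#' @param table AAindex table.
#' @return Named numeric 30-vector.
#' @export
sed_max <- function(shells, model, table = aaindex_table()) {
  sed_layers(shells, model, table, max, "SEDm")
}

#' Shell-environment descriptor, per-layer sums
#'
#' As [sed_max()] with the sum in place of the maximum.
#'
#' @inheritParams sed_max
#' @return Named numeric 30-vector.
#' @export
sed_sum <- function(shells, model, table = aaindex_table()) {
  sed_layers(shells, model, table, sum, "SEDs")
}

#' Per-layer ASA maxima and sums
#'
#' For each layer, the maximum and the sum of the absolute residue ASA of
#' its members; empty layers contribute zeros.
#'
#' @param shells A `shell_profile`.
#' @param asa An `asa_result` covering all shell members.
#' @return List with named 10-vectors `ASAm` and `ASAs`.
#' @export
asa_layers <- function(shells, asa) {
  member <- unlist(shells$layers, use.names = FALSE)
  missing <- setdiff(member, names(asa$residue_asa))
  if (length(missing)) {
    stop("ASA missing for shell member(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  n <- length(shells$layers)
  m <- vapply(shells$layers, function(keys) {
    if (!length(keys)) 0 else max(asa$residue_asa[keys])
  }, 0)
  s <- vapply(shells$layers, function(keys) {
    if (!length(keys)) 0 else sum(asa$residue_asa[keys])
  }, 0)
  list(ASAm = stats::setNames(m, sprintf("ASAm_L%02d", seq_len(n))),
       ASAs = stats::setNames(s, sprintf("ASAs_L%02d", seq_len(n))))
}

#' Multiplicative cross-term blocks
#'
#' InterD1 is the full outer product of the 2-element DSD with the
#' 3-element IAD (6 values, DSD-major order); InterD2 multiplies each
#' layer's ASA maximum into that layer's three SEDm values; InterD3 does
#' the same with sums.
#'
#' @param dsd Numeric 2-vector.
#' @param iad Numeric 3-vector.
#' @param sedm,seds Numeric 30-vectors.
#' @param asam,asas Numeric 10-vectors.
#' @return List with `InterD1` (6), `InterD2` (30), `InterD3` (30).
#' @export
cross_terms <- function(dsd, iad, sedm, seds, asam, asas) {
  if (length(dsd) != 2L || length(iad) != 3L || length(sedm) != 30L ||
      length(seds) != 30L || length(asam) != 10L || length(asas) != 10L) {
    stop("cross_terms: input block length mismatch")
  }
  inter1 <- as.vector(outer(iad, dsd))  # d1*a, d1*b, d1*c, d2*a, d2*b, d2*c
  names(inter1) <- as.vector(outer(DESCRIPTOR_INDICES, c("DSD_p1", "DSD_p2"),
                                   function(i, d) paste0("InterD1_", d, "_", i)))
  inter2 <- rep(asam, each = 3L) * sedm
  names(inter2) <- layer_index_names("InterD2", 10L)
  inter3 <- rep(asas, each = 3L) * seds
  names(inter3) <- layer_index_names("InterD3", 10L)
  list(InterD1 = inter1, InterD2 = inter2, InterD3 = inter3)
}

#' Assemble the 151-element descriptor of one residue
#'
#' Concatenates DSD, IAD, SEDm, SEDs, ASAm, ASAs, InterD1, InterD2 and
#' InterD3 in that order. Descriptors are defined for standard-amino-acid
#' residues; in the pipeline they are computed for surface and epitope
#' residues only (core residues are outside the classification universe).
#'
#' @param model An `ab_structure`, typically the IAB alone.
#' @param target Residue key.
#' @param anchors A `benchmark_points` object.
#' @param asa An `asa_result` on `model`.
#' @param table AAindex table.
#' @param params An [ab_params()] object.
#' @return Named numeric vector of length 151 with attribute `blocks`
#'   (the block sizes).
#' @examples
#' toy <- generate_toy_antibody(seed = 1)
#' mod <- iab_model(parse_structure(toy$pdb, roles = toy$roles))
#' asa <- compute_asa(mod, n_points = 240)
#' bp <- select_benchmark_points(mod, detect_disulfides(mod))
#' d <- assemble_descriptor(mod, mod$residues$key[10], bp, asa)
#' length(d)  # 151
#' @export
assemble_descriptor <- function(model, target, anchors, asa,
                                table = aaindex_table(),
                                params = ab_params()) {
  shells <- build_shells(model, target, params)
  v_dsd <- dsd(model, target, anchors)
  v_iad <- iad(model, target, table)
  v_sedm <- sed_max(shells, model, table)
  v_seds <- sed_sum(shells, model, table)
  v_asa <- asa_layers(shells, asa)
  v_x <- cross_terms(v_dsd, v_iad, v_sedm, v_seds, v_asa$ASAm, v_asa$ASAs)
  out <- c(v_dsd, v_iad, v_sedm, v_seds, v_asa$ASAm, v_asa$ASAs,
           v_x$InterD1, v_x$InterD2, v_x$InterD3)
  stopifnot(length(out) == sum(DESCRIPTOR_BLOCKS), all(is.finite(out)))
  attr(out, "blocks") <- DESCRIPTOR_BLOCKS
  out
}

#' Feature table for all classified residues of one structure
#'
#' Computes the 151-element descriptor for every surface and epitope
#' residue of the IAB. ASA and geometry are taken from the IAB alone so
#' the same features are produced for bound complexes and unbound
#' antibodies. Nonstandard residues are skipped with a message.
#'
#' @param model An `ab_structure` (complex or antibody alone).
#' @param classmap A `residue_class_map` from [classify_residues()].
#' @param anchors A `benchmark_points` object.
#' @param asa An `asa_result` on the IAB model.
#' @param table AAindex table.
#' @param params An [ab_params()] object.
#' @return Data frame: structure_id, key, chain, resno, icode, aa1, class,
#'   then the 151 named feature columns.
#' @export
feature_table <- function(model, classmap, anchors, asa,
                          table = aaindex_table(), params = ab_params()) {
  iab <- iab_model(model)
  sel <- classmap[classmap$class %in% c("SURFACE_NONIMMUNOGENIC", "EPITOPE"), ,
                  drop = FALSE]
  std <- iab$residues$standard[match(sel$key, iab$residues$key)]
  if (any(!std)) {
    message("skipping ", sum(!std), " nonstandard residue(s): ",
            paste(sel$key[!std], collapse = ", "))
    sel <- sel[std, , drop = FALSE]
  }
  if (!nrow(sel)) stop("no surface or epitope residues to featurize")
  feats <- t(vapply(sel$key, function(k) {
    as.numeric(assemble_descriptor(iab, k, anchors, asa, table, params))
  }, numeric(151L)))
  colnames(feats) <- descriptor_names(params$n_layers)
  cbind(
    data.frame(structure_id = model$structure_id, key = sel$key,
               chain = sel$chain, resno = sel$resno, icode = sel$icode,
               aa1 = unname(AA3_TO_AA1[sel$aa3]), class = sel$class,
               stringsAsFactors = FALSE),
    as.data.frame(feats)
  )
}
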