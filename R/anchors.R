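# Disulfide detection and the disulfide-anchored spatial location
# descriptor (DSD).
#
# Antibody Fab fragments carry two intra-chain disulfide bonds per chain
# (e.g. light chain A23-A88 and A133-A193); the geometric centers of the
# two variable-domain bonds serve as fixed benchmark points, and every
# residue's pair of Euclidean distances to them is its 2-D location
# descriptor.

#' Detect disulfide bonds geometrically
#'
#' All cysteine SG-SG pairs within `params$disulfide_cutoff` (default 2.5
#' Angstrom; a covalent S-S bond is about 2.05) are matched greedily by
#' ascending distance so that no cysteine joins two bonds. SSBOND records
#' are not trusted; bonds are recomputed from coordinates. Cysteines
#' without an SG atom are skipped.
#'
#' @param model An `ab_structure`.
#' @param params An [ab_params()] object.
#' @return Data frame of class `disulfide_bonds` with columns cys1, cys2
#'   (residue keys, cys1 < cys2 in residue order), sg_distance and the bond
#'   center coordinates cx, cy, cz (SG midpoint). Zero rows when no bond.
#' @export
detect_disulfides <- function(model, params = ab_params()) {
  stopifnot(inherits(model, "ab_structure"))
  sg <- model$atoms[model$atoms$aa3 == "CYS" & model$atoms$name == "SG", ,
                    drop = FALSE]
  empty <- data.frame(cys1 = character(), cys2 = character(),
                      sg_distance = numeric(), cx = numeric(),
                      cy = numeric(), cz = numeric(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("disulfide_bonds", "data.frame")
  if (nrow(sg) < 2L) return(empty)

  xyz <- as.matrix(sg[, c("x", "y", "z")])
  pairs <- utils::combn(nrow(sg), 2L)
  d <- sqrt(rowSums((xyz[pairs[1L, ], , drop = FALSE] -
                     xyz[pairs[2L, ], , drop = FALSE])^2))
  ok <- d <= params$disulfide_cutoff
  if (!any(ok)) return(empty)
  pairs <- pairs[, ok, drop = FALSE]
  d <- d[ok]

  ord <- order(d)
  used <- logical(nrow(sg))
  rows <- list()
  res_order <- model$residues$key
  for (k in ord) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    ki <- sg$key[i]; kj <- sg$key[j]
    if (match(ki, res_order) > match(kj, res_order)) { tmp <- ki; ki <- kj; kj <- tmp
      tmp <- i; i <- j; j <- tmp }
    rows[[length(rows) + 1L]] <- data.frame(
      cys1 = ki, cys2 = kj, sg_distance = d[k],
      cx = (xyz[i, 1L] + xyz[j, 1L]) / 2,
      cy = (xyz[i, 2L] + xyz[j, 2L]) / 2,
      cz = (xyz[i, 3L] + xyz[j, 3L]) / 2,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$cys1, res_order)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("disulfide_bonds", "data.frame")
  out
}

#' Select the two variable-region benchmark points
#'
#' Per antibody chain the variable-domain disulfide is identified as the
#' intra-chain bond whose first cysteine has the lowest residue number
#' (consistent with Kabat-style numbering, where the variable-domain bond
#' precedes the constant-domain ones). The benchmark points are the bond
#' centers of that bond on the light and heavy chain respectively.
#'
#' @param model An `ab_structure`.
#' @param bonds Output of [detect_disulfides()].
#' @param light_chain,heavy_chain Chain ids of the light and heavy chain.
#'   Default: the first and second IAB chain in model order.
#' @param override Optional list with elements `p1` and `p2` (3-vectors)
#'   bypassing selection entirely, for structures where the rule does not
#'   apply (single-chain or Fc-only inputs).
#' @return Object of class `benchmark_points`: list with 3-vectors `p1`
#'   (light) and `p2` (heavy) and the `source_bonds` rows used.
#' @export
select_benchmark_points <- function(model, bonds, light_chain = NULL,
                                    heavy_chain = NULL, override = NULL) {
  if (!is.null(override)) {
    stopifnot(length(override$p1) == 3L, length(override$p2) == 3L)
    return(structure(list(p1 = as.numeric(override$p1),
                          p2 = as.numeric(override$p2),
                          source_bonds = NULL),
                     class = "benchmark_points"))
  }
  iab <- chains_with_role(model, "IAB")
  if (is.null(light_chain)) light_chain <- iab[1L]
  if (is.null(heavy_chain)) heavy_chain <- if (length(iab) >= 2L) iab[2L] else NA
  if (is.na(heavy_chain) || is.null(light_chain)) {
    stop("cannot identify light and heavy chains; pass light_chain/heavy_chain ",
         "or an explicit override with p1/p2 coordinates")
  }

  pick <- function(chain) {
    if (!nrow(bonds)) return(NULL)
    k1 <- split_residue_key(bonds$cys1)
    k2 <- split_residue_key(bonds$cys2)
    intra <- which(k1$chain == chain & k2$chain == chain)
    if (!length(intra)) return(NULL)
    intra[which.min(k1$resno[intra])]
  }
  i1 <- pick(light_chain)
  i2 <- pick(heavy_chain)
  if (is.null(i1) || is.null(i2)) {
    stop("fewer than two eligible intra-chain disulfide bonds (light chain ",
         light_chain, ", heavy chain ", heavy_chain, "); pass explicit ",
         "override = list(p1 = ..., p2 = ...)")
  }
  structure(
    list(p1 = as.numeric(bonds[i1, c("cx", "cy", "cz")]),
         p2 = as.numeric(bonds[i2, c("cx", "cy", "cz")]),
         source_bonds = bonds[c(i1, i2), , drop = FALSE]),
    class = "benchmark_points"
  )
}

#' @export
print.benchmark_points <- function(x, ...) {
  cat(sprintf("benchmark_points: p1 (%.2f, %.2f, %.2f)  p2 (%.2f, %.2f, %.2f)\n",
              x$p1[1], x$p1[2], x$p1[3], x$p2[1], x$p2[2], x$p2[3]))
  if (!is.null(x$source_bonds)) {
    cat("  from bonds:", paste(x$source_bonds$cys1, x$source_bonds$cys2,
                               sep = "-", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Disulfide-anchored spatial location descriptor
#'
#' The pair of Euclidean distances from a residue's position to the two
#' benchmark points. The residue position is its heavy-atom centroid by
#' default; `mode = "ca"` uses the C-alpha atom instead.
#'
#' @param model An `ab_structure`.
#' @param target Residue key.
#' @param anchors A `benchmark_points` object.
#' @param mode `"centroid"` (default) or `"ca"`.
#' @return Numeric 2-vector `c(DSD_p1, DSD_p2)` in Angstrom.
#' @export
dsd <- function(model, target, anchors, mode = c("centroid", "ca")) {
  mode <- match.arg(mode)
  pos <- residue_position(model, target, mode)
  out <- c(DSD_p1 = sqrt(sum((pos - anchors$p1)^2)),
           DSD_p2 = sqrt(sum((pos - anchors$p2)^2)))
  out
}

#' @keywords internal
residue_position <- function(model, target, mode = "centroid") {
  i <- match(target, model$residues$key)
  if (is.na(i)) stop("unknown residue key: ", target)
  if (mode == "centroid") {
    return(as.numeric(model$residues[i, c("cx", "cy", "cz")]))
  }
  ca <- model$atoms[model$atoms$key == target & model$atoms$name == "CA", ,
                    drop = FALSE]
  if (!nrow(ca)) stop("residue ", target, " has no CA atom")
  as.numeric(ca[1L, c("x", "y", "z")])
}
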