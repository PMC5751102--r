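#' Analysis parameters
#'
#' Bundles every tunable constant of the pipeline with the defaults used by
#' the method: a residue of the immunogenic antibody (iAb) is an epitope
#' residue when its nearest heavy atom lies strictly closer than
#' `epitope_cutoff` to any heavy atom of the anti-drug antibody (ADA); the
#' micro-environment of a residue is the set of residues with centroid
#' distance below `neighborhood_radius`, partitioned into `n_layers` radial
#' shells of width `layer_width`; solvent accessibility uses a water-sized
#' probe of radius `probe_radius`, and a residue counts as surface when its
#' relative ASA is at least `surface_rasa_threshold`; disulfide bonds are
#' cysteine pairs with SG-SG distance at most `disulfide_cutoff`.
#'
#' @param epitope_cutoff Contact cutoff in Angstrom for epitope labeling
#'   (strict less-than). Default 5.
#' @param neighborhood_radius Outer radius in Angstrom of the shell
#'   neighborhood. Default 20.
#' @param layer_width Width in Angstrom of each radial shell. Default 2.
#' @param n_layers Number of radial shells. Default 10; must satisfy
#'   `n_layers * layer_width == neighborhood_radius`.
#' @param probe_radius Solvent probe radius in Angstrom. Default 1.4 (water).
#' @param surface_rasa_threshold Relative-ASA fraction at or above which a
#'   non-epitope residue is classified as surface. Default 0.05.
#' @param disulfide_cutoff Maximum SG-SG distance in Angstrom for a
#'   disulfide bond. Default 2.5.
#' @param cv_folds Number of cross-validation folds. Default 10.
#' @param rng_seed Integer seed used wherever the pipeline draws random
#'   numbers (fold assignment, simulations).
#' @return An object of class `ab_params` (a named list).
#' @examples
#' p <- ab_params()
#' p$epitope_cutoff
#' @export
ab_params <- function(epitope_cutoff = 5.0,
                      neighborhood_radius = 20.0,
                      layer_width = 2.0,
                      n_layers = 10L,
                      probe_radius = 1.4,
                      surface_rasa_threshold = 0.05,
                      disulfide_cutoff = 2.5,
                      cv_folds = 10L,
                      rng_seed = 1L) {
  p <- list(
    epitope_cutoff = as.numeric(epitope_cutoff),
    neighborhood_radius = as.numeric(neighborhood_radius),
    layer_width = as.numeric(layer_width),
    n_layers = as.integer(n_layers),
    probe_radius = as.numeric(probe_radius),
    surface_rasa_threshold = as.numeric(surface_rasa_threshold),
    disulfide_cutoff = as.numeric(disulfide_cutoff),
    cv_folds = as.integer(cv_folds),
    rng_seed = as.integer(rng_seed)
  )
  radii <- c(p$epitope_cutoff, p$neighborhood_radius, p$layer_width,
             p$probe_radius, p$disulfide_cutoff)
  if (any(!is.finite(radii)) || any(radii <= 0)) {
    stop("all radii and cutoffs must be positive and finite")
  }
  if (p$n_layers < 1L) stop("n_layers must be >= 1")
  if (abs(p$n_layers * p$layer_width - p$neighborhood_radius) > 1e-9) {
    stop("n_layers * layer_width must equal neighborhood_radius")
  }
  if (p$cv_folds < 2L) stop("cv_folds must be >= 2")
  class(p) <- "ab_params"
  p
}

#' @export
print.ab_params <- function(x, ...) {
  cat("Antibody epitope analysis parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
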