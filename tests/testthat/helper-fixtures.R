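# Shared fixtures and independent brute-force oracles. The oracles use
# plain double loops over atoms/residues so they share no code path with
# the package implementations they check.

toy_model <- function(seed = 1, ...) {
  toy <- generate_toy_antibody(seed = seed, ...)
  list(toy = toy,
       model = parse_structure(toy$pdb, roles = toy$roles,
                               structure_id = paste0("toy", seed)))
}

# proper rotation + translation drawn under a local seed
random_rigid_motion <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(rotation = Q, translation = rnorm(3, 0, 25))
}

rotate_model <- function(model, motion) {
  abepitope:::transform_model(model, motion$rotation, motion$translation)
}

# O(n^2) nearest-atom contact scan
oracle_epitope <- function(model, cutoff) {
  iab <- names(model$roles)[model$roles == "IAB"]
  ada <- names(model$roles)[model$roles == "ADA"]
  a <- model$atoms[model$atoms$chain %in% iab, ]
  b <- model$atoms[model$atoms$chain %in% ada, ]
  hits <- character(0)
  for (k in unique(a$key)) {
    ra <- a[a$key == k, ]
    found <- FALSE
    for (i in seq_len(nrow(ra))) {
      for (j in seq_len(nrow(b))) {
        d <- sqrt((ra$x[i] - b$x[j])^2 + (ra$y[i] - b$y[j])^2 +
                    (ra$z[i] - b$z[j])^2)
        if (d < cutoff) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) hits <- c(hits, k)
  }
  sort(hits)
}

# O(n^2) layer-membership scan over residue centroids
oracle_layers <- function(model, target, params) {
  res <- model$residues
  ti <- which(res$key == target)
  layers <- replicate(params$n_layers, character(0), simplify = FALSE)
  for (i in seq_len(nrow(res))) {
    if (i == ti) next
    d <- sqrt((res$cx[i] - res$cx[ti])^2 + (res$cy[i] - res$cy[ti])^2 +
                (res$cz[i] - res$cz[ti])^2)
    if (d >= params$neighborhood_radius) next
    k <- 1L
    while (d >= k * params$layer_width) k <- k + 1L
    layers[[k]] <- c(layers[[k]], res$key[i])
  }
  layers
}

# all-pairs SG scan with greedy matching by ascending distance
oracle_disulfides <- function(model, cutoff) {
  sg <- model$atoms[model$atoms$aa3 == "CYS" & model$atoms$name == "SG", ]
  if (nrow(sg) < 2) return(data.frame(cys1 = character(), cys2 = character()))
  cand <- NULL
  for (i in seq_len(nrow(sg) - 1)) {
    for (j in (i + 1):nrow(sg)) {
      d <- sqrt((sg$x[i] - sg$x[j])^2 + (sg$y[i] - sg$y[j])^2 +
                  (sg$z[i] - sg$z[j])^2)
      if (d <= cutoff) cand <- rbind(cand, data.frame(i = i, j = j, d = d))
    }
  }
  if (is.null(cand)) return(data.frame(cys1 = character(), cys2 = character()))
  cand <- cand[order(cand$d), ]
  used <- logical(nrow(sg)); out <- NULL
  for (r in seq_len(nrow(cand))) {
    if (used[cand$i[r]] || used[cand$j[r]]) next
    used[cand$i[r]] <- used[cand$j[r]] <- TRUE
    ks <- sort(c(sg$key[cand$i[r]], sg$key[cand$j[r]]))
    out <- rbind(out, data.frame(cys1 = ks[1], cys2 = ks[2]))
  }
  out
}

# minimal two-residue complex: one IAB atom at the origin, one ADA atom at
# distance d along x
two_residue_complex <- function(d) {
  pdb <- paste(c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, c(0, 0, 0), "C"),
    "TER",
    pdb_atom_line(2, "CA", "GLY", "B", 1, c(d, 0, 0), "C"),
    "TER", "END"), collapse = "\n")
  parse_structure(pdb, roles = c(A = "IAB", B = "ADA"))
}

# canonical small complex reused across files (cached per session)
.toy1 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- toy_model(seed = 1)
    cache
  }
})
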