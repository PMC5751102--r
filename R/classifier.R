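# Ridge-penalised logistic regression over the 151-element descriptors,
# evaluated by stratified ten-fold cross-validation (pooled across
# structures, or per structure as in the per-antibody evaluation).

#' Build a labeled dataset from a feature table
#'
#' @param features Feature table as produced by [feature_table()] (possibly
#'   row-bound over structures): metadata columns followed by feature
#'   columns.
#' @return Object of class `labeled_dataset`: list with matrix `x`, 0/1
#'   integer `y` (1 = EPITOPE), and vectors `structure_id` and `key`.
#' @export
as_labeled_dataset <- function(features) {
  meta <- c("structure_id", "key", "chain", "resno", "icode", "aa1", "class")
  feat_cols <- setdiff(colnames(features), meta)
  x <- as.matrix(features[, feat_cols, drop = FALSE])
  storage.mode(x) <- "double"
  y <- as.integer(features$class == "EPITOPE")
  structure(list(x = x, y = y,
                 structure_id = as.character(features$structure_id),
                 key = as.character(features$key)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d rows x %d features, %d positives (%.1f%%), %d structures\n",
              nrow(x$x), ncol(x$x), sum(x$y), 100 * mean(x$y),
              length(unique(x$structure_id))))
  invisible(x)
}

# sigmoid kept explicit so serialized models are reproducible anywhere
#' @keywords internal
sigmoid <- function(z) 1 / (1 + exp(-z))

#' Fit the epitope classifier
#'
#' Features are standardized (zero mean, unit scale; constant features get
#' scale 1) and a logistic regression with a weak L2 (ridge) penalty is
#' fitted by penalised maximum likelihood. The fit is deterministic given
#' the data and row order. Coefficients are reported on the standardized
#' scale together with the standardization, so the artifact is
#' self-contained and serializable.
#'
#' @param dataset A `labeled_dataset` with both classes present.
#' @param seed Integer seed recorded in the artifact (the fit itself is
#'   deterministic).
#' @param lambda Ridge penalty strength (glmnet scale). Default `1e-4`,
#'   a weak penalty that stabilises separable fits without biasing
#'   coefficients appreciably.
#' @return Object of class `epitope_model`: list with `coefficients`,
#'   `intercept`, `center`, `scale`, `lambda`, `seed`, `n`.
#' @export
fit_epitope_model <- function(dataset, seed = 1L, lambda = 1e-4) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  x <- dataset$x; y <- dataset$y
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")

  # glmnet needs >= 2 columns; pad one-feature problems with a zero dummy
  pad <- ncol(xs) == 1L
  if (pad) xs <- cbind(xs, 0)

  # decreasing lambda path ending at the requested penalty; warm starts make
  # the final solution stable and deterministic
  path <- sort(unique(c(10^(1:-3), lambda)), decreasing = TRUE)
  # glmnet warns on classes under 8 rows; routine here (per-structure folds
  # with few epitope residues), so silence that specific message
  fit <- withCallingHandlers(
    glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                   lambda = path, standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  beta <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
  if (pad) beta <- beta[-length(beta)]
  structure(
    list(coefficients = stats::setNames(beta[-1L], colnames(x)),
         intercept = beta[1L], center = center, scale = scale,
         lambda = lambda, seed = as.integer(seed), n = nrow(x)),
    class = "epitope_model"
  )
}

#' @export
print.epitope_model <- function(x, ...) {
  cat(sprintf("epitope_model: %d features, intercept %.4f, lambda %g, n = %d\n",
              length(x$coefficients), x$intercept, x$lambda, x$n))
  invisible(x)
}

#' Predicted epitope probabilities
#'
#' @param object An `epitope_model`.
#' @param newx Numeric matrix (or vector for one row) with the model's
#'   feature width.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.epitope_model <- function(object, newx, ...) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
  if (ncol(newx) != length(object$coefficients)) {
    stop("feature width mismatch: model has ", length(object$coefficients),
         ", input has ", ncol(newx))
  }
  xs <- sweep(sweep(newx, 2L, object$center), 2L, object$scale, "/")
  as.numeric(sigmoid(object$intercept + xs %*% object$coefficients))
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney U
#' statistic with midranks (exact tie handling); invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores Numeric predictions.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`; `NA` if a class is absent.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# seeded stratified fold assignment; every fold sees both classes whenever
# each class has at least k members
#' @keywords internal
make_folds <- function(y, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated evaluation of the epitope classifier
#'
#' Stratified, seeded k-fold cross-validation. In `"pooled"` mode all rows
#' from all structures are folded together ("all epitope residues and
#' non-immunogenic surface residues integrated"); per-structure AUC and
#' accuracy are additionally read off the pooled held-out probabilities. In
#' `"per_structure"` mode every structure is cross-validated independently
#' on its own residues. Accuracy uses the 0.5 probability threshold. AUC is
#' the rank statistic over held-out probabilities. A structure whose minor
#' class has fewer than 2 residues cannot be stratified and is skipped with
#' a warning; when the minor class is smaller than the number of folds the
#' fold count is reduced for that evaluation.
#'
#' @param dataset A `labeled_dataset`.
#' @param params An [ab_params()] object (`cv_folds`, `rng_seed`).
#' @param mode `"pooled"` (default) or `"per_structure"`.
#' @param lambda Ridge penalty passed to [fit_epitope_model()].
#' @return Object of class `evaluation_report`: list with `pooled`
#'   (named vector auc/accuracy, `NA` in per-structure mode),
#'   `per_structure` data frame (structure_id, n, n_pos, auc, accuracy),
#'   `mean_per_structure`, `folds`, `threshold`, `mode`, `seed`.
#' @export
cross_validate <- function(dataset, params = ab_params(),
                           mode = c("pooled", "per_structure"),
                           lambda = 1e-4) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "labeled_dataset"))
  k <- params$cv_folds
  seed <- params$rng_seed
  threshold <- 0.5

  run_cv <- function(x, y, sid, key, k, seed) {
    kk <- min(k, min(table(y)))
    if (kk < 2L) return(NULL)
    fold <- make_folds(y, kk, seed)
    prob <- numeric(length(y))
    for (f in seq_len(kk)) {
      tr <- fold != f
      ds <- structure(list(x = x[tr, , drop = FALSE], y = y[tr],
                           structure_id = sid[tr], key = key[tr]),
                      class = "labeled_dataset")
      m <- fit_epitope_model(ds, seed = seed, lambda = lambda)
      prob[!tr] <- predict(m, x[!tr, , drop = FALSE])
    }
    list(prob = prob, fold = fold, k = kk)
  }

  per_structure <- NULL
  pooled <- c(auc = NA_real_, accuracy = NA_real_)
  folds <- NULL

  if (mode == "pooled") {
    cv <- run_cv(dataset$x, dataset$y, dataset$structure_id, dataset$key,
                 k, seed)
    if (is.null(cv)) stop("dataset cannot be stratified: a class has < 2 rows")
    pooled <- c(auc = auc_rank(cv$prob, dataset$y),
                accuracy = mean((cv$prob >= threshold) == (dataset$y == 1L)))
    folds <- cv$fold
    per_structure <- do.call(rbind, lapply(
      unique(dataset$structure_id), function(s) {
        i <- dataset$structure_id == s
        data.frame(structure_id = s, n = sum(i), n_pos = sum(dataset$y[i]),
                   auc = auc_rank(cv$prob[i], dataset$y[i]),
                   accuracy = mean((cv$prob[i] >= threshold) ==
                                     (dataset$y[i] == 1L)),
                   stringsAsFactors = FALSE)
      }))
  } else {
    rows <- list()
    for (s in unique(dataset$structure_id)) {
      i <- which(dataset$structure_id == s)
      cv <- run_cv(dataset$x[i, , drop = FALSE], dataset$y[i],
                   dataset$structure_id[i], dataset$key[i], k, seed)
      if (is.null(cv)) {
        warning("structure ", s, " skipped: a class has < 2 residues")
        next
      }
      rows[[s]] <- data.frame(
        structure_id = s, n = length(i), n_pos = sum(dataset$y[i]),
        auc = auc_rank(cv$prob, dataset$y[i]),
        accuracy = mean((cv$prob >= threshold) == (dataset$y[i] == 1L)),
        stringsAsFactors = FALSE)
    }
    if (!length(rows)) stop("no structure could be cross-validated")
    per_structure <- do.call(rbind, rows)
    rownames(per_structure) <- NULL
  }

  structure(
    list(pooled = pooled, per_structure = per_structure,
         mean_per_structure = c(auc = mean(per_structure$auc, na.rm = TRUE),
                                accuracy = mean(per_structure$accuracy)),
         folds = folds, threshold = threshold, mode = mode,
         seed = as.integer(seed)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report (%s mode, seed %d):\n", x$mode, x$seed))
  if (!is.na(x$pooled["auc"])) {
    cat(sprintf("  pooled:        AUC %.3f  accuracy %.3f\n",
                x$pooled["auc"], x$pooled["accuracy"]))
  }
  cat(sprintf("  per-structure: mean AUC %.3f  mean accuracy %.3f (%d structures)\n",
              x$mean_per_structure["auc"], x$mean_per_structure["accuracy"],
              nrow(x$per_structure)))
  invisible(x)
}

#' Serialize / restore a fitted model as JSON
#'
#' The artifact stores coefficients, intercept and standardization, so a
#' model can be applied from any language.
#'
#' @param model An `epitope_model`.
#' @param path JSON file path.
#' @return `write_model_json`: the path, invisibly. `read_model_json`: the
#'   restored `epitope_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "epitope_model"))
  jsonlite::write_json(
    list(coefficients = as.list(model$coefficients),
         intercept = model$intercept,
         center = as.list(model$center), scale = as.list(model$scale),
         lambda = model$lambda, seed = model$seed, n = model$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(coefficients = unlist(j$coefficients), intercept = j$intercept,
         center = unlist(j$center), scale = unlist(j$scale),
         lambda = j$lambda, seed = as.integer(j$seed), n = as.integer(j$n)),
    class = "epitope_model"
  )
}
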