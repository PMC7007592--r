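#' Supported classification algorithms
#' @export
phenotype_algorithms <- c("linear_svm", "gaussian_nb", "decision_tree", "random_forest")

default_hyperparameters <- function(algorithm) {
  switch(algorithm,
    linear_svm = list(cost = 1),
    gaussian_nb = list(sd_floor = 1e-6),
    decision_tree = list(minsplit = 5, cp = 0.01),
    random_forest = list(ntree = 100, nodesize = 1),
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  )
}

#' Train a phenotype classifier on patient vectors
#'
#' Fits one of four standard classifier families to labeled patient-level
#' feature vectors. All four share one contract: they consume the same
#' vector table and emit per-class probability scores, so models are
#' interchangeable downstream.
#'
#' Default hyperparameters (overridable through `hyperparameters`):
#' * `linear_svm` — linear kernel, L2-regularized with `cost = 1`; features
#'   are standardized with center/scale fitted on the training data only;
#'   probabilities come from a logistic (Platt) fit on the training folds, so
#'   the signed margin satisfies the same probability contract as the others.
#' * `gaussian_nb` — Gaussian class-conditional densities; per-class standard
#'   deviations are floored at `sd_floor = 1e-6` so constant (often all-zero)
#'   count features keep finite densities.
#' * `decision_tree` — CART with `minsplit = 5`, `cp = 0.01`; class scores are
#'   leaf class frequencies.
#' * `random_forest` — `ntree = 100` trees, unlimited depth; class scores are
#'   the mean of per-tree class votes.
#'
#' Raw mean counts are used unscaled except for the SVM standardization noted
#' above. Multi-class problems are supported natively by all four families.
#' Training is deterministic given `seed`.
#'
#' @param data Labeled patient vectors, e.g. from [vectorize_patients()]:
#'   columns `patient_id`, `label`, feature columns (and optionally
#'   `n_notes`, ignored).
#' @param algorithm One of [phenotype_algorithms].
#' @param hyperparameters Named list overriding the defaults above.
#' @param seed Integer seed fixed before any stochastic fitting step.
#' @return A `phenotype_model` carrying the fit, `feature_names` (coordinate
#'   order), `class_names` (sorted; also the score column order and the
#'   tie-break order), and the resolved hyperparameters.
#' @export
train_model <- function(data, algorithm = "random_forest",
                        hyperparameters = list(), seed = 1L) {
  algorithm <- match.arg(algorithm, phenotype_algorithms)
  data <- tibble::as_tibble(data)
  if (!all(c("patient_id", "label") %in% names(data))) {
    stop("training data needs 'patient_id' and 'label' columns", call. = FALSE)
  }
  if (any(is.na(data$label))) stop("training data contains unlabeled patients", call. = FALSE)
  feat <- feature_columns(data)
  if (length(feat) == 0) stop("no feature columns found", call. = FALSE)
  x <- as.matrix(data[, feat])
  if (!is.numeric(x)) stop("feature columns must be numeric", call. = FALSE)
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  class_names <- sort(unique(data$label))
  if (length(class_names) < 2) {
    stop("training requires at least 2 classes; got only '", class_names, "'",
         call. = FALSE)
  }
  y <- factor(data$label, levels = class_names)
  hp <- utils::modifyList(default_hyperparameters(algorithm), hyperparameters)

  fit <- withr::with_seed(as.integer(seed), {
    switch(algorithm,
      linear_svm = fit_linear_svm(x, y, hp),
      gaussian_nb = fit_gaussian_nb(x, y, hp),
      decision_tree = fit_decision_tree(x, y, hp),
      random_forest = fit_random_forest(x, y, hp)
    )
  })

  structure(
    list(algorithm = algorithm, fit = fit, feature_names = feat,
         class_names = class_names, hyperparameters = hp, seed = as.integer(seed),
         n_train = nrow(x),
         class_priors = as.numeric(table(y)[class_names]) / length(y)),
    class = "phenotype_model"
  )
}

fit_linear_svm <- function(x, y, hp) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  xs <- scale(x, center = center, scale = scale)
  svm_fit <- e1071::svm(x = xs, y = y, kernel = "linear", cost = hp$cost,
                        scale = FALSE, probability = TRUE)
  list(svm = svm_fit, center = center, scale = scale)
}

fit_gaussian_nb <- function(x, y, hp) {
  nb <- e1071::naiveBayes(x = as.data.frame(x), y = y)
  # floor per-class sd so zero-variance count features keep finite densities
  nb$tables <- lapply(nb$tables, function(tab) {
    tab[, 2] <- pmax(tab[, 2], hp$sd_floor)
    tab
  })
  nb
}

fit_decision_tree <- function(x, y, hp) {
  df <- as.data.frame(x)
  names(df) <- make.names(colnames(x), unique = TRUE)
  fit <- rpart::rpart(
    y ~ ., data = cbind(df, y = y), method = "class",
    control = rpart::rpart.control(minsplit = hp$minsplit, cp = hp$cp, xval = 0)
  )
  list(tree = fit, safe_names = stats::setNames(names(df), colnames(x)))
}

fit_random_forest <- function(x, y, hp) {
  # a wholly constant feature matrix sends the forest's split search into an
  # endless loop; with zero feature signal the only defensible fit is the
  # class prior, so store that directly
  if (all(apply(x, 2, function(col) length(unique(col)) == 1))) {
    return(structure(list(priors = as.numeric(table(y)) / length(y),
                          classes = levels(y)),
                     class = "degenerate_prior_fit"))
  }
  randomForest::randomForest(x = x, y = y, ntree = hp$ntree, nodesize = hp$nodesize)
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat(sprintf("<phenotype_model> %s, %d features, classes: %s (n_train = %d)\n",
              x$algorithm, length(x$feature_names),
              paste(x$class_names, collapse = ", "), x$n_train))
  invisible(x)
}

# Per-class probability matrix, rows in input order, columns = class_names.
model_scores <- function(model, x) {
  raw <- switch(model$algorithm,
    linear_svm = {
      xs <- scale(x, center = model$fit$center, scale = model$fit$scale)
      pred <- stats::predict(model$fit$svm, xs, probability = TRUE)
      attr(pred, "probabilities")
    },
    gaussian_nb = {
      stats::predict(model$fit, as.data.frame(x), type = "raw")
    },
    decision_tree = {
      df <- as.data.frame(x)
      names(df) <- unname(model$fit$safe_names[colnames(x)])
      stats::predict(model$fit$tree, df, type = "prob")
    },
    random_forest = {
      if (inherits(model$fit, "degenerate_prior_fit")) {
        matrix(model$fit$priors, nrow(x), length(model$fit$classes),
               byrow = TRUE, dimnames = list(NULL, model$fit$classes))
      } else {
        stats::predict(model$fit, x, type = "prob")
      }
    }
  )
  raw <- as.matrix(raw)
  missing <- setdiff(model$class_names, colnames(raw))
  if (length(missing) > 0) {
    raw <- cbind(raw, matrix(0, nrow(raw), length(missing),
                             dimnames = list(NULL, missing)))
  }
  p <- raw[, model$class_names, drop = FALSE]
  # guard against degenerate rows (underflow); fall back to training priors
  p[!is.finite(p)] <- 0
  rs <- rowSums(p)
  bad <- rs <= 0
  if (any(bad)) p[bad, ] <- rep(model$class_priors, each = sum(bad))
  p / rowSums(p)
}

#' Classify patients with a trained model
#'
#' Produces one prediction per patient with per-class probability scores
#' summing to one. The predicted label is the highest-scoring class; exact
#' ties resolve to the class earliest in the model's `class_names` order, and
#' the confidence is the predicted class's score.
#'
#' @param object A `phenotype_model`.
#' @param new_data Patient vectors with the model's feature columns (extra
#'   columns such as `label` are passed through untouched).
#' @param ... Unused.
#' @return A tibble `patient_id`, `predicted_label`, `confidence`, then one
#'   score column per class (named by class).
#' @export
predict.phenotype_model <- function(object, new_data, ...) {
  new_data <- tibble::as_tibble(new_data)
  missing <- setdiff(object$feature_names, names(new_data))
  if (length(missing) > 0) {
    stop("input lacks model feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(new_data[, object$feature_names])
  p <- model_scores(object, x)
  idx <- apply(p, 1, which.max)  # ties -> first class in class_names order
  out <- tibble::tibble(
    patient_id = as.character(new_data$patient_id),
    predicted_label = object$class_names[idx],
    confidence = p[cbind(seq_len(nrow(p)), idx)]
  )
  dplyr::bind_cols(out, tibble::as_tibble(p))
}

#' Save a trained model
#'
#' Persists a versioned container (algorithm, hyperparameters, feature and
#' class names, fitted parameters). [load_model()] refuses files from a
#' different container version, and prediction refuses vectors whose feature
#' columns do not match the model's.
#'
#' @param model A `phenotype_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "phenotype_model"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(container_version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the `phenotype_model`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$container_version, 1L) ||
      !inherits(obj$model, "phenotype_model")) {
    stop("not a recognized model container: ", path, call. = FALSE)
  }
  obj$model
}

#' @export
#' @method tidy phenotype_model
tidy.phenotype_model <- function(x, ...) {
  switch(x$algorithm,
    random_forest = {
      if (inherits(x$fit, "degenerate_prior_fit")) {
        tibble::tibble(feature = x$feature_names,
                       importance = rep(0, length(x$feature_names)))
      } else {
        imp <- randomForest::importance(x$fit)
        tibble::tibble(feature = rownames(imp), importance = as.numeric(imp[, 1]))
      }
    },
    decision_tree = {
      vi <- x$fit$tree$variable.importance
      if (is.null(vi)) {
        tibble::tibble(feature = x$feature_names,
                       importance = rep(0, length(x$feature_names)))
      } else {
        inv <- stats::setNames(names(x$fit$safe_names), x$fit$safe_names)
        tibble::tibble(feature = unname(inv[names(vi)]), importance = as.numeric(vi))
      }
    },
    linear_svm = {
      w <- crossprod(x$fit$svm$coefs, x$fit$svm$SV)
      tibble::tibble(feature = colnames(w), importance = abs(as.numeric(w[1, ])))
    },
    gaussian_nb = {
      means <- vapply(x$fit$tables, function(tab) max(tab[, 1]) - min(tab[, 1]),
                      numeric(1))
      tibble::tibble(feature = names(means), importance = as.numeric(means))
    }
  ) |> dplyr::arrange(dplyr::desc(.data$importance))
}

#' @export
#' @method glance phenotype_model
glance.phenotype_model <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    n_train = x$n_train,
    n_features = length(x$feature_names),
    n_classes = length(x$class_names),
    seed = x$seed
  )
}
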