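#' Fit boundary types by k-means over all boundaries of an image set
#'
#' Standardizes the 40 per-boundary metrics (per-feature median/IQR robust
#' scaling; zero-IQR features are dropped from the distance) and runs seeded
#' k-means with multiple restarts, keeping the best-inertia model. Boundary
#' types are the cluster labels; per-image counts of types are the image
#' descriptor.
#'
#' @param features feature tibble from [extract_features_set()] (or any data
#'   frame containing the 40 [feature_names()] columns).
#' @param n_types number of boundary types N.
#' @param seed RNG seed.
#' @param use_features which feature columns to use (default all 40; pass
#'   `feature_names()[1:20]` for the in-graph-only ablation).
#' @param nstart k-means restarts.
#' @return A `boundary_type_model`: list with `centroids` (standardized),
#'   `center`/`scale` vectors, `features` (column names used), `n_types`,
#'   `seed`.
#' @export
fit_boundary_types <- function(features, n_types = 12, seed = 1,
                               use_features = feature_names(), nstart = 10) {
  x <- as.matrix(features[, use_features, drop = FALSE])
  if (nrow(x) < n_types) {
    abort(sprintf("%d boundaries cannot support %d types", nrow(x), n_types),
          class = "shapegraph_size_error")
  }
  ctr <- apply(x, 2, median)
  scl <- apply(x, 2, stats::IQR)
  keep <- scl > 1e-12
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  set.seed(seed)
  km <- kmeanspp(xs, n_types, nstart)
  structure(list(centroids = km$centers, center = ctr, scale = scl,
                 keep = keep, features = use_features,
                 n_types = n_types, seed = seed,
                 inertia = km$tot.withinss),
            class = "boundary_type_model")
}

# k-means with k-means++ seeding and multiple restarts (best inertia kept);
# RNG state is the caller's responsibility
kmeanspp <- function(x, k, nstart = 10) {
  n <- nrow(x)
  best <- NULL
  for (s in seq_len(nstart)) {
    centers <- matrix(NA_real_, k, ncol(x))
    centers[1, ] <- x[sample.int(n, 1), ]
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (j in seq_len(k - 1) + 1) {
      prob <- d2 / sum(d2)
      centers[j, ] <- x[sample.int(n, 1, prob = prob), ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
    km <- suppressWarnings(kmeans(x, centers = centers, iter.max = 100))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

#' @export
print.boundary_type_model <- function(x, ...) {
  cat(sprintf("<boundary_type_model> %d types over %d features (seed %d)\n",
              x$n_types, length(x$features), x$seed))
  invisible(x)
}

#' Assign boundary types
#'
#' Nearest centroid in the model's standardized space; ties broken by the
#' lowest type index.
#'
#' @param model a `boundary_type_model`.
#' @param features feature tibble/data frame.
#' @return Integer vector of type labels (1..N).
#' @export
assign_types <- function(model, features) {
  miss <- setdiff(model$features, colnames(features))
  if (length(miss)) {
    abort(sprintf("feature columns missing: %s", paste(miss, collapse = ", ")),
          class = "shapegraph_dimension_error")
  }
  x <- as.matrix(features[, model$features, drop = FALSE])
  xs <- sweep(sweep(x[, model$keep, drop = FALSE], 2,
                    model$center[model$keep]), 2,
              model$scale[model$keep], "/")
  d2 <- outer(rowSums(xs^2), rowSums(model$centroids^2), "+") -
    2 * xs %*% t(model$centroids)
  apply(d2, 1, which.min)
}

#' Per-image boundary-type histograms
#'
#' @param model a `boundary_type_model`.
#' @param features feature tibble with an `image_id` column.
#' @param normalize return frequencies (summing to 1) instead of counts.
#' @return A tibble: `image_id`, `type_1` ... `type_N`.
#' @export
image_histograms <- function(model, features, normalize = FALSE) {
  ty <- assign_types(model, features)
  ids <- unique(features$image_id)
  h <- vapply(ids, function(im) {
    tabulate(ty[features$image_id == im], nbins = model$n_types)
  }, numeric(model$n_types))
  h <- if (model$n_types == 1) matrix(h, ncol = 1) else t(h)
  if (normalize) h <- h / pmax(rowSums(h), 1)
  out <- as_tibble(h, .name_repair = "minimal")
  colnames(out) <- paste0("type_", seq_len(model$n_types))
  bind_cols(tibble(image_id = ids), out)
}

histogram_matrix <- function(histograms) {
  as.matrix(histograms[, grep("^type_", colnames(histograms)), drop = FALSE])
}

#' Difference of normalized histograms between two image groups
#'
#' The per-type difference in mean normalized counts, used to read off which
#' boundary types distinguish two conditions.
#'
#' @param histograms histogram tibble from [image_histograms()].
#' @param ids_a,ids_b image ids of the two groups.
#' @return Numeric vector (group A minus group B), one entry per type.
#' @export
histogram_difference <- function(histograms, ids_a, ids_b) {
  m <- histogram_matrix(histograms)
  m <- m / pmax(rowSums(m), 1)
  colMeans(m[histograms$image_id %in% ids_a, , drop = FALSE]) -
    colMeans(m[histograms$image_id %in% ids_b, , drop = FALSE])
}

#' PCA embedding of per-image histograms
#'
#' @param histograms histogram tibble from [image_histograms()].
#' @return List: `scores` tibble (image_id, PC1, PC2, ...), `sdev`,
#'   `explained` (variance fractions), and the `prcomp` object.
#' @export
pca_embed <- function(histograms) {
  m <- histogram_matrix(histograms)
  if (nrow(m) < 2) abort("PCA needs at least two images")
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  sc <- as_tibble(p$x, .name_repair = "minimal")
  list(scores = bind_cols(tibble(image_id = histograms$image_id), sc),
       sdev = p$sdev, explained = p$sdev^2 / sum(p$sdev^2), prcomp = p)
}

#' Leave-one-out k-nearest-neighbour classification of histograms
#'
#' Euclidean distance between per-image histograms (raw counts by default),
#' majority vote among the k nearest other images; vote ties are broken by
#' the single nearest neighbour.
#'
#' @param histograms histogram tibble.
#' @param labels class label per image (factor or character).
#' @param k number of neighbours (default 3).
#' @param normalize use normalized histograms.
#' @return List: `predictions`, `accuracy`, `confusion` (table).
#' @export
knn_classify <- function(histograms, labels, k = 3, normalize = FALSE) {
  m <- histogram_matrix(histograms)
  if (normalize) m <- m / pmax(rowSums(m), 1)
  n <- nrow(m)
  labels <- as.character(labels)
  if (k > n - 1) {
    abort(sprintf("k = %d but only %d other images", k, n - 1),
          class = "shapegraph_size_error")
  }
  d <- as.matrix(dist(m))
  diag(d) <- Inf
  pred <- character(n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(k)]
    votes <- table(labels[nb])
    top <- names(votes)[votes == max(votes)]
    pred[i] <- if (length(top) == 1) top else labels[nb[1]]
  }
  conf <- table(truth = labels, predicted = pred)
  list(predictions = pred, accuracy = mean(pred == labels),
       confusion = conf)
}

#' Linear regression of generative parameters on type histograms
#'
#' Ordinary least squares of each log-transformed parameter on the
#' boundary-type counts; evaluated by leave-one-out cross-validation with
#' mean absolute error and Pearson correlation per parameter. A small ridge
#' penalty can be supplied for rank-deficient designs.
#'
#' @param histograms histogram tibble.
#' @param targets data frame of positive numeric parameters, one row per
#'   image (same order as `histograms`); values are log-transformed before
#'   fitting.
#' @param log_transform log-transform the targets (default TRUE).
#' @param ridge ridge penalty lambda (0 = OLS; OLS errors on rank-deficient
#'   designs).
#' @return A `type_regression` list: per-parameter coefficients, leave-one-out
#'   `predictions` (log scale), `mae`, `pearson`, and metadata.
#' @export
fit_param_regression <- function(histograms, targets, log_transform = TRUE,
                                 ridge = 0) {
  m <- histogram_matrix(histograms)
  ty <- as.data.frame(targets)
  stopifnot(nrow(ty) == nrow(m))
  if (log_transform) {
    if (any(ty <= 0)) abort("targets must be positive for log transform")
    ty <- log(ty)
  }
  n <- nrow(m)
  X <- cbind(1, m)
  fit_one <- function(Xt, yt) {
    if (ridge > 0) {
      P <- diag(ncol(Xt)) * ridge
      P[1, 1] <- 0
      solve(crossprod(Xt) + P, crossprod(Xt, yt))
    } else {
      # aliased columns (a type absent from a fold) drop out with
      # coefficient 0, as in lm()
      b <- qr.coef(qr(Xt), yt)
      b[is.na(b)] <- 0
      b
    }
  }
  coefs <- lapply(ty, function(y) fit_one(X, y))
  preds <- matrix(NA_real_, n, ncol(ty))
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    for (j in seq_len(ncol(ty))) {
      b <- fit_one(Xi, ty[-i, j])
      preds[i, j] <- drop(X[i, , drop = FALSE] %*% b)
    }
  }
  mae <- colMeans(abs(preds - as.matrix(ty)))
  pearson <- vapply(seq_len(ncol(ty)), function(j) {
    stats::cor(preds[, j], ty[, j])
  }, numeric(1))
  structure(list(coefficients = coefs, predictions = preds,
                 targets = as.matrix(ty), mae = setNames(mae, names(ty)),
                 pearson = setNames(pearson, names(ty)),
                 log_transform = log_transform, ridge = ridge,
                 n = n),
            class = "type_regression")
}

#' @export
print.type_regression <- function(x, ...) {
  cat(sprintf("<type_regression> %d images, %d parameter(s)\n",
              x$n, length(x$mae)))
  for (p in names(x$mae)) {
    cat(sprintf("  %s: leave-one-out MAE %.4f, r %.4f\n",
                p, x$mae[[p]], x$pearson[[p]]))
  }
  invisible(x)
}

#' Predict parameters for new histograms
#'
#' @param object a `type_regression`.
#' @param histograms histogram tibble.
#' @param ... unused.
#' @return Matrix of predictions on the (log) fitting scale.
#' @export
predict.type_regression <- function(object, histograms, ...) {
  X <- cbind(1, histogram_matrix(histograms))
  sapply(object$coefficients, function(b) drop(X %*% b))
}

#' Select the number of boundary types
#'
#' Refits the type model for each candidate N and scores it by leave-one-out
#' 3-NN classification accuracy (`criterion = "knn_accuracy"`, needs
#' `labels`) or by leave-one-out regression error summed over parameters
#' (`criterion = "regression_cv"`, needs `targets`). Ties go to the smallest
#' N.
#'
#' @param features per-boundary feature tibble (with `image_id`).
#' @param candidate_ns integer candidates.
#' @param criterion `"knn_accuracy"` or `"regression_cv"`.
#' @param labels per-image class labels (image order = unique image_id).
#' @param targets per-image parameter data frame.
#' @param seed RNG seed.
#' @param k neighbours for the k-NN criterion.
#' @return The selected N (integer), with the per-candidate scores as
#'   attribute `"scores"`.
#' @export
select_num_types <- function(features, candidate_ns,
                             criterion = c("knn_accuracy", "regression_cv"),
                             labels = NULL, targets = NULL, seed = 1, k = 3) {
  criterion <- match.arg(criterion)
  candidate_ns <- sort(unique(as.integer(candidate_ns)))
  if (length(candidate_ns) == 1) return(candidate_ns)
  if (criterion == "knn_accuracy" && is.null(labels)) {
    abort("knn_accuracy criterion needs labels",
          class = "shapegraph_config_error")
  }
  if (criterion == "regression_cv" && is.null(targets)) {
    abort("regression_cv criterion needs targets",
          class = "shapegraph_config_error")
  }
  scores <- vapply(candidate_ns, function(nn) {
    model <- fit_boundary_types(features, n_types = nn, seed = seed)
    h <- image_histograms(model, features)
    if (criterion == "knn_accuracy") {
      knn_classify(h, labels, k = k)$accuracy
    } else {
      -sum(fit_param_regression(h, targets)$mae)
    }
  }, numeric(1))
  best <- candidate_ns[which.max(scores)]
  attr(best, "scores") <- setNames(scores, candidate_ns)
  best
}
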