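#' Aggregate per-cell features to a per-well vector
#'
#' The per-well descriptor is the mean and standard deviation, across the
#' cells in the well, of the 19 in-graph and 19 out-graph per-cell metrics
#' (the exterior/interior flag is dropped): 4 x 19 = 76 values, ordered
#' mean(in), mean(out), sd(in), sd(out), each block in metric order.
#' Standard deviations are population SDs (a single-cell well gives 0).
#'
#' @param cell_features feature tibble for the cells of one well (rows =
#'   cells; must contain the 40 [feature_names()] columns).
#' @return Named numeric vector of length 76.
#' @export
aggregate_well <- function(cell_features) {
  if (!nrow(cell_features)) {
    abort("empty well", class = "shapegraph_empty_error")
  }
  fn <- well_metric_names()
  x <- as.matrix(cell_features[, fn, drop = FALSE])
  mu <- colMeans(x)
  sdv <- sqrt(pmax(colMeans(x^2) - mu^2, 0))
  out <- c(mu, sdv)
  names(out) <- c(paste0("mean_", fn), paste0("sd_", fn))
  out
}

well_metric_names <- function() {
  fn <- feature_names()
  fn[!grepl("_exterior$", fn)]
}

#' Build the well-feature table for an experiment
#'
#' @param cell_features per-cell feature tibble with `plate_id` and
#'   `well_id` columns (plus the 40 feature columns).
#' @return Tibble: `plate_id`, `well_id`, then the 76 aggregated columns.
#' @export
aggregate_wells <- function(cell_features) {
  stopifnot(all(c("plate_id", "well_id") %in% colnames(cell_features)))
  cell_features %>%
    group_by(.data$plate_id, .data$well_id) %>%
    group_split() %>%
    map(function(g) {
      bind_cols(tibble(plate_id = g$plate_id[1], well_id = g$well_id[1]),
                as_tibble(as.list(aggregate_well(g))))
    }) %>%
    list_rbind()
}

#' Normalize well features to plate controls
#'
#' Subtracts, feature-wise, the median vector of each plate's control wells
#' from every well of that plate (removing plate-to-plate variance).
#'
#' @param wells well-feature tibble ([aggregate_wells()] output).
#' @param layout tibble with `plate_id`, `well_id`, `class`, `is_control`.
#' @return The normalized well tibble (same shape), with `class` joined.
#' @export
normalize_to_controls <- function(wells, layout) {
  stopifnot(all(c("plate_id", "well_id", "class", "is_control") %in%
                  colnames(layout)))
  wells <- left_join(wells, layout,
                     by = c("plate_id", "well_id"))
  fcols <- grep("^(mean|sd)_", colnames(wells), value = TRUE)
  for (p in unique(wells$plate_id)) {
    sel <- wells$plate_id == p
    ctrl <- sel & wells$is_control
    if (!any(ctrl)) {
      abort(sprintf("plate %s has no control wells", p),
            class = "shapegraph_config_error")
    }
    med <- apply(wells[ctrl, fcols, drop = FALSE], 2, median)
    wells[sel, fcols] <- sweep(as.matrix(wells[sel, fcols, drop = FALSE]),
                               2, med)
  }
  wells
}

#' Held-out-plate decision-tree classification
#'
#' Each plate is held out in turn; a decision tree (CART, Gini impurity,
#' fixed seed) trained on the remaining plates predicts its wells. Pooled
#' predictions give per-class precision, recall, F1 =
#' 2 * precision * recall / (precision + recall), and the unweighted (macro)
#' mean F1.
#'
#' @param wells normalized well tibble with a `class` column.
#' @param seed RNG seed for the tree.
#' @param exclude_controls drop control wells before classification
#'   (default FALSE: controls form their own class).
#' @param control an [rpart::rpart.control()]; the default grows the tree
#'   to purity (depth-unlimited, no complexity pruning).
#' @return List: `per_class` tibble (class, precision, recall, f1),
#'   `mean_f1`, `confusion` table, `predictions`.
#' @export
holdout_plate_classify <- function(wells, seed = 1, exclude_controls = FALSE,
                                   control = rpart::rpart.control(
                                     minsplit = 2, minbucket = 1, cp = 0,
                                     maxdepth = 30)) {
  stopifnot("class" %in% colnames(wells))
  if (exclude_controls && "is_control" %in% colnames(wells)) {
    wells <- wells[!wells$is_control, ]
  }
  plates <- unique(wells$plate_id)
  if (length(plates) < 2) abort("need at least two plates")
  if (length(unique(wells$class)) < 2) abort("need at least two classes")
  fcols <- grep("^(mean|sd)_", colnames(wells), value = TRUE)
  truth <- character(0); pred <- character(0)
  for (p in plates) {
    test <- wells$plate_id == p
    train <- wells[!test, ]
    absent <- setdiff(unique(wells$class[test]), unique(train$class))
    if (length(absent)) {
      warn(sprintf("class(es) %s absent from training folds for plate %s",
                   paste(absent, collapse = ", "), p))
    }
    df <- data.frame(class = factor(train$class),
                     train[, fcols, drop = FALSE], check.names = FALSE)
    set.seed(seed)
    tree <- rpart::rpart(class ~ ., data = df, method = "class",
                         parms = list(split = "gini"), control = control)
    nd <- data.frame(wells[test, fcols, drop = FALSE], check.names = FALSE)
    ph <- predict(tree, newdata = nd, type = "class")
    truth <- c(truth, as.character(wells$class[test]))
    pred <- c(pred, as.character(ph))
  }
  classes <- sort(unique(truth))
  per <- map(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    tibble(class = cl, precision = precision, recall = recall, f1 = f1)
  }) %>% list_rbind()
  list(per_class = per,
       mean_f1 = mean(per$f1),
       confusion = table(truth = truth, predicted = pred),
       predictions = tibble(truth = truth, predicted = pred))
}

#' F1 scores from a confusion table
#'
#' @param confusion a table/matrix with true classes in rows and predictions
#'   in columns.
#' @return Tibble with class, precision, recall, f1, and attribute
#'   `mean_f1`.
#' @export
f1_scores <- function(confusion) {
  m <- as.matrix(confusion)
  classes <- union(rownames(m), colnames(m))
  full <- matrix(0, length(classes), length(classes),
                 dimnames = list(classes, classes))
  full[rownames(m), colnames(m)] <- m
  per <- map(classes, function(cl) {
    tp <- full[cl, cl]
    fp <- sum(full[, cl]) - tp
    fn <- sum(full[cl, ]) - tp
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    tibble(class = cl, precision = precision, recall = recall, f1 = f1)
  }) %>% list_rbind()
  attr(per, "mean_f1") <- mean(per$f1)
  per
}
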