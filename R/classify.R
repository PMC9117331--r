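#' Train a supervised visual-barcode classifier
#'
#' Per-experiment training on cytological profiles from single-clone
#' control wells: a stratified 70/30 train/validation split and a
#' boosted ensemble of shallow trees with a fixed stage budget (the
#' additive-rules model class; 50 stages by default). Every class must
#' contribute at least 200 labeled cells. Features are matched by name,
#' so column order is irrelevant at prediction time.
#'
#' @param features `cell_features` data.frame (or any numeric
#'   data.frame); non-feature columns `field`, `clone`, `label` are
#'   ignored automatically.
#' @param labels Character/factor vector of true clone labels, one per
#'   row.
#' @param split Training fraction of the stratified split (default 0.7).
#' @param budget Number of boosting stages ("rules", default 50).
#' @param seed Integer seed (split and boosting are deterministic given
#'   it).
#' @param min_per_class Minimum labeled cells per class (default 200).
#' @return List: `model` (class `barcode_model`) and `confusion` (a
#'   `confusion_summary` on the held-out validation split).
#' @export
train_barcode_classifier <- function(features, labels, split = 0.7,
                                     budget = 50, seed = 1,
                                     min_per_class = 200) {
  labels <- as.character(labels)
  x <- feature_matrix(features)
  stopifnot(nrow(x) == length(labels))
  counts <- table(labels)
  short <- names(counts)[counts < min_per_class]
  if (length(short))
    stop("class(es) with fewer than ", min_per_class, " cells: ",
         paste(short, collapse = ", "))
  classes <- sort(names(counts))
  yi <- match(labels, classes) - 1L
  idx_tr <- with_seed(seed, {
    unlist(lapply(classes, function(cl) {
      i <- which(labels == cl)
      sample(i, floor(split * length(i)))
    }), use.names = FALSE)
  })
  idx_va <- setdiff(seq_len(nrow(x)), idx_tr)
  dtrain <- xgboost::xgb.DMatrix(x[idx_tr, , drop = FALSE],
                                 label = yi[idx_tr], nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softprob",
                  num_class = length(classes),
                  max_depth = 2, eta = 0.3, nthread = 1,
                  seed = seed),
    data = dtrain, nrounds = budget, verbose = 0)
  model <- structure(list(booster = booster, classes = classes,
                          feature_names = colnames(x),
                          metadata = list(
                            n_per_class = as.list(table(labels[idx_tr])),
                            split = split, budget = budget, seed = seed)),
                     class = "barcode_model")
  calls <- call_barcodes(model, features[idx_va, , drop = FALSE])
  confusion <- confusion_metrics(labels[idx_va], calls$barcode)
  list(model = model, confusion = confusion)
}

#' @export
print.barcode_model <- function(x, ...) {
  cat("Visual-barcode classifier:", length(x$classes), "classes,",
      x$metadata$budget, "boosting stages,",
      length(x$feature_names), "features\n")
  invisible(x)
}

# Numeric feature matrix with stable name-sorted columns.
feature_matrix <- function(features, required = NULL) {
  df <- as.data.frame(features)
  df <- df[setdiff(names(df), c("field", "clone", "label"))]
  df <- df[vapply(df, is.numeric, TRUE)]
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop("feature column(s) missing: ", paste(missing, collapse = ", "))
    df <- df[required]
  } else {
    df <- df[sort(names(df))]
  }
  as.matrix(df)
}

#' Call barcodes on new cells
#'
#' Applies a trained [train_barcode_classifier()] model to cytological
#' profiles, returning one barcode label and a confidence (the maximum
#' class probability) per cell. Feature columns are matched by name;
#' missing columns raise an error listing them.
#'
#' @param model A `barcode_model`.
#' @param features `cell_features` data.frame.
#' @return data.frame with columns `barcode` and `confidence`.
#' @export
call_barcodes <- function(model, features) {
  stopifnot(inherits(model, "barcode_model"))
  x <- feature_matrix(features, required = model$feature_names)
  pr <- predict(model$booster, xgboost::xgb.DMatrix(x, nthread = 1))
  pr <- matrix(pr, ncol = length(model$classes))
  i <- max.col(pr, ties.method = "first")
  data.frame(barcode = model$classes[i],
             confidence = pr[cbind(seq_len(nrow(pr)), i)],
             stringsAsFactors = FALSE)
}

#' Confusion metrics for barcode calling
#'
#' Per predicted class the false detection rate `FDR = FP / (FP + TP)`
#' (fraction of cells assigned the barcode that truly belong to another
#' clone) and per true class the miss rate `miss = FN / (FN + TP)`
#' (fraction of a clone's cells not assigned its barcode), with macro
#' averages. Classes never predicted have undefined FDR (`NA`).
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @return Object of class `confusion_summary`: `matrix` (true x
#'   predicted counts), `fdr`, `miss` (named per-class rates),
#'   `macro_fdr`, `macro_miss`.
#' @export
confusion_metrics <- function(true_labels, predicted_labels) {
  if (length(true_labels) == 0L) stop("empty input")
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  lev <- sort(unique(c(as.character(true_labels),
                       as.character(predicted_labels))))
  tl <- factor(as.character(true_labels), levels = lev)
  pl <- factor(as.character(predicted_labels), levels = lev)
  cm <- table(true = tl, predicted = pl)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  fdr <- ifelse(colSums(cm) > 0, fp / (fp + tp), NA_real_)
  miss <- ifelse(rowSums(cm) > 0, fn / (fn + tp), NA_real_)
  structure(list(matrix = cm,
                 fdr = setNames(as.numeric(fdr), lev),
                 miss = setNames(as.numeric(miss), lev),
                 macro_fdr = mean(fdr, na.rm = TRUE),
                 macro_miss = mean(miss, na.rm = TRUE)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("Barcode-calling confusion: macro FDR %.2f%%, macro miss %.2f%%\n",
              100 * x$macro_fdr, 100 * x$macro_miss))
  print(x$matrix)
  invisible(x)
}
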