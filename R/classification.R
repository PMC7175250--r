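# Semi-supervised polymorph classification: training labels come from
# single-feature threshold rules applied per image (in single images the
# crystal types separate on one feature, e.g. size or maximum intensity,
# even though no single feature works across images); a degree-3
# polynomial-kernel ("cubic") SVM trained on the pooled annotations then
# classifies all images. Class vocabulary: 0 = COM, 1 = COD,
# 2 = not defined (n.d.), 3 = background noise.

#' Crystal class vocabulary
#' @return Data frame mapping class codes 0..3 to names.
#' @export
crystal_classes <- function() {
  data.frame(code = 0:3,
             name = c("COM", "COD", "n.d.", "noise"))
}

#' Build an annotation rule set
#'
#' Each rule labels crystals of the images in its scope whose single feature
#' satisfies the comparison. Later rules override earlier ones (priority
#' defaults to the list position); two matching rules with equal explicit
#' priority but different classes are a conflict.
#'
#' @param rules Data frame with columns `image_scope` (image id or `"*"`),
#'   `feature` (one of [feature_names()]), `comparator` (one of `<`, `<=`,
#'   `>`, `>=`, `between`), `threshold_lo`, `threshold_hi` (only for
#'   `between`), `class` (0..3), and optionally `priority`.
#' @return A validated `annotation_rules` data frame.
#' @export
annotation_rules <- function(rules) {
  stopifnot(is.data.frame(rules))
  need <- c("image_scope", "feature", "comparator", "threshold_lo", "class")
  missing <- setdiff(need, names(rules))
  if (length(missing))
    stop("rule set is missing column(s): ", paste(missing, collapse = ", "))
  if (!"threshold_hi" %in% names(rules))
    rules$threshold_hi <- rep(NA_real_, nrow(rules))
  if (!"priority" %in% names(rules)) rules$priority <- seq_len(nrow(rules))
  bad <- setdiff(rules$feature, feature_names())
  if (length(bad)) stop("unknown feature(s) in rules: ", paste(bad, collapse = ", "))
  if (!all(rules$comparator %in% c("<", "<=", ">", ">=", "between")))
    stop("comparator must be one of <, <=, >, >=, between")
  if (!all(rules$class %in% 0:3)) stop("rule classes must be in {0,1,2,3}")
  btw <- rules$comparator == "between"
  if (any(btw & (is.na(rules$threshold_hi) |
                 rules$threshold_lo >= rules$threshold_hi)))
    stop("between-rules require threshold_lo < threshold_hi")
  class(rules) <- c("annotation_rules", "data.frame")
  rules
}

#' Read annotation rules from YAML or CSV
#'
#' @param path A `.yaml`/`.yml` file holding a list of rule mappings, or a
#'   CSV with the [annotation_rules()] columns.
#' @return An `annotation_rules` data frame.
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) stop("rules file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    lst <- yaml::read_yaml(path)
    do.call(rbind, lapply(lst, function(r)
      data.frame(image_scope = as.character(r$image_scope %||% "*"),
                 feature = r$feature, comparator = r$comparator,
                 threshold_lo = as.numeric(r$threshold_lo),
                 threshold_hi = as.numeric(r$threshold_hi %||% NA),
                 class = as.integer(r$class),
                 priority = as.numeric(r$priority %||% NA))))
  } else utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(raw$priority) && all(is.na(raw$priority))) raw$priority <- NULL
  annotation_rules(raw)
}

.rule_matches <- function(rule, x) {
  switch(rule$comparator,
         "<"  = x < rule$threshold_lo,
         "<=" = x <= rule$threshold_lo,
         ">"  = x > rule$threshold_lo,
         ">=" = x >= rule$threshold_lo,
         "between" = x >= rule$threshold_lo & x <= rule$threshold_hi)
}

#' Annotate crystals by single-feature threshold rules
#'
#' Applies image-scoped rules to a feature table. A crystal receives a label
#' iff, after precedence resolution, exactly one rule wins; crystals matched
#' by no rule are excluded from the returned training table.
#'
#' @param crystals Feature table with an `image_id` column (absent: all
#'   rules with scope `"*"` apply) and the [feature_names()] columns.
#' @param rules An [annotation_rules()] set.
#' @return The labeled subset of `crystals` with a `class` column.
#' @export
annotate <- function(crystals, rules) {
  rules <- annotation_rules(as.data.frame(rules))
  stopifnot(is.data.frame(crystals))
  if (nrow(rules) == 0L || nrow(crystals) == 0L) {
    out <- crystals[integer(0), , drop = FALSE]
    out$class <- integer(0)
    return(out)
  }
  img <- if ("image_id" %in% names(crystals)) as.character(crystals$image_id)
         else rep("*", nrow(crystals))
  scoped <- unique(rules$image_scope[rules$image_scope != "*"])
  unknown <- setdiff(scoped, unique(img))
  if (length(unknown))
    stop("rule scope refers to absent image(s): ", paste(unknown, collapse = ", "))
  lab <- rep(NA_integer_, nrow(crystals))
  pri <- rep(-Inf, nrow(crystals))
  conflict <- logical(nrow(crystals))
  for (k in seq_len(nrow(rules))) {
    r <- rules[k, ]
    in_scope <- r$image_scope == "*" | img == r$image_scope
    hit <- in_scope & .rule_matches(r, crystals[[r$feature]])
    hit[is.na(hit)] <- FALSE
    tie <- hit & pri == r$priority & !is.na(lab) & lab != r$class
    conflict <- conflict | tie
    win <- hit & r$priority >= pri
    lab[win] <- r$class
    pri[win] <- r$priority
  }
  if (any(conflict))
    stop("conflicting same-priority rules for crystal row(s): ",
         paste(utils::head(which(conflict), 20), collapse = ", "))
  out <- crystals[!is.na(lab), , drop = FALSE]
  out$class <- lab[!is.na(lab)]
  rownames(out) <- NULL
  out
}

#' Precision, recall and F1 per class from predicted vs true labels
#'
#' The confusion matrix has rows = true class, columns = predicted class.
#' Precision and recall default to 0 when their denominator is 0, and
#' F1 = 2PR/(P+R), 0 when P + R = 0.
#'
#' @param predicted,truth Integer label vectors (codes 0..3), equal length.
#' @param classes Class codes spanning the confusion matrix.
#' @return List: `confusion` (matrix), `overall_accuracy`, `precision`,
#'   `recall`, `f1` (named per class), `n_per_class`.
#' @export
evaluate_predictions <- function(predicted, truth, classes = 0:3) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  if (!all(c(predicted, truth) %in% classes))
    stop("labels outside the class vocabulary {",
         paste(classes, collapse = ","), "}")
  cm <- table(true = factor(truth, levels = classes),
              predicted = factor(predicted, levels = classes))
  cm <- unclass(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  names(prec) <- names(rec) <- names(f1) <- as.character(classes)
  list(confusion = cm,
       overall_accuracy = sum(tp) / sum(cm),
       precision = prec, recall = rec, f1 = f1,
       n_per_class = rowSums(cm))
}

.standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

.standardize_apply <- function(x, st)
  sweep(sweep(as.matrix(x), 2, st$center, "-"), 2, st$scale, "/")

# Order-invariant canonical row order: sort by feature values, then label.
.canonical_order <- function(tab) {
  keys <- c(unname(as.list(tab[feature_names()])), list(tab$class))
  do.call(order, keys)
}

#' Train the cubic-SVM crystal classifier with fivefold cross-validation
#'
#' Fits a degree-3 polynomial-kernel SVM (C = 1, coef0 = 1, one-vs-one
#' multiclass, no class weighting) on standardized features. Performance is
#' estimated by stratified fivefold cross-validation in which the
#' standardization parameters are fitted on the training folds only (no
#' test-fold leakage); the reported confusion matrix pools the five test
#' folds. The final model is refit on all data. Rows are put into a
#' canonical (content-derived) order first, so fold assignment and the
#' fitted model do not depend on the row order of the input.
#'
#' @param training Data frame with the 15 [feature_names()] columns and an
#'   integer `class` column (codes 0..3).
#' @param seed Integer seed for the stratified fold assignment; recorded in
#'   the report.
#' @param cost,degree,coef0 SVM hyperparameters (defaults: the conventional
#'   "cubic SVM": C = 1, degree 3, coef0 1).
#' @param gamma Kernel scale; default `1/n_features` on standardized data.
#' @param n_folds Number of CV folds (default 5).
#' @param rules Optional rule set stored in the model fingerprint.
#' @return List with `model` (a `crystal_classifier`) and `cv` (a
#'   `cv_report`: `n_folds`, `overall_accuracy`, 4x4 `confusion` with rows =
#'   true class, per-class `precision`/`recall`/`f1`, `n_per_class`,
#'   `seed`).
#' @export
train_classifier <- function(training, seed = 1L, cost = 1, degree = 3,
                             coef0 = 1, gamma = NULL, n_folds = 5L,
                             rules = NULL) {
  stopifnot(is.data.frame(training), "class" %in% names(training))
  miss <- setdiff(feature_names(), names(training))
  if (length(miss)) stop("training table missing feature(s): ",
                         paste(miss, collapse = ", "))
  if (!all(training$class %in% 0:3)) stop("class labels must be in {0,1,2,3}")
  counts <- table(factor(training$class, levels = 0:3))
  present <- names(counts)[counts > 0]
  if (length(present) < 2) stop("need at least 2 classes to train")
  short <- names(counts)[counts > 0 & counts < n_folds]
  if (length(short))
    stop("class(es) with fewer than ", n_folds, " examples: ",
         paste(short, collapse = ", "))
  training <- training[.canonical_order(training), , drop = FALSE]
  x <- as.matrix(training[feature_names()])
  y <- factor(training$class, levels = sort(as.integer(present)))
  p <- ncol(x)
  if (is.null(gamma)) gamma <- 1 / p
  folds <- integer(nrow(x))
  .with_seed(seed, {
    for (cl in levels(y)) {
      i <- which(y == cl)
      folds[i] <- sample(rep_len(seq_len(n_folds), length(i)))
    }
  })
  pred_all <- integer(nrow(x))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    st <- .standardize_fit(x[tr, , drop = FALSE])
    fit <- e1071::svm(.standardize_apply(x[tr, , drop = FALSE], st),
                      y[tr], kernel = "polynomial", degree = degree,
                      coef0 = coef0, cost = cost, gamma = gamma,
                      scale = FALSE)
    pr <- stats::predict(fit, .standardize_apply(x[!tr, , drop = FALSE], st))
    pred_all[!tr] <- as.integer(as.character(pr))
  }
  cv <- evaluate_predictions(pred_all, as.integer(as.character(y)))
  cv$n_folds <- n_folds
  cv$seed <- as.integer(seed)
  class(cv) <- "cv_report"
  st <- .standardize_fit(x)
  fit <- e1071::svm(.standardize_apply(x, st), y, kernel = "polynomial",
                    degree = degree, coef0 = coef0, cost = cost,
                    gamma = gamma, scale = FALSE)
  model <- structure(list(fit = fit, center = st$center, scale = st$scale,
                          features = feature_names(),
                          classes = as.integer(levels(y)),
                          hyperparameters = list(cost = cost, degree = degree,
                                                 coef0 = coef0, gamma = gamma),
                          fingerprint = list(seed = as.integer(seed),
                                             n = nrow(x),
                                             n_per_class = as.vector(counts),
                                             rules = rules),
                          version = "1"),
                     class = "crystal_classifier")
  list(model = model, cv = cv)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV: overall accuracy %.1f%% (n = %d)\n",
              x$n_folds, 100 * x$overall_accuracy, sum(x$confusion)))
  print(x$confusion)
  print(round(rbind(precision = x$precision, recall = x$recall, F1 = x$f1), 3))
  invisible(x)
}

#' Classify crystals with a trained model
#'
#' @param model A `crystal_classifier` from [train_classifier()].
#' @param crystals Feature table with the model's feature columns.
#' @return Integer class labels (0..3), one per row; empty input gives an
#'   empty vector. Deterministic.
#' @export
classify <- function(model, crystals) {
  stopifnot(inherits(model, "crystal_classifier"))
  miss <- setdiff(model$features, names(crystals))
  if (length(miss)) stop("feature schema mismatch; missing: ",
                         paste(miss, collapse = ", "))
  if (nrow(crystals) == 0L) return(integer(0))
  xs <- .standardize_apply(as.matrix(crystals[model$features]),
                           list(center = model$center, scale = model$scale))
  as.integer(as.character(stats::predict(model$fit, xs)))
}

#' Save / load a trained classifier
#'
#' The artifact stores the SVM weights, the feature standardization
#' parameters and the training fingerprint; reloading reproduces identical
#' predictions.
#'
#' @param model A `crystal_classifier`.
#' @param path File path for the model artifact (RDS).
#' @return `path` invisibly (save); the model (load).
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "crystal_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "crystal_classifier"))
    stop("file does not contain a crystal_classifier")
  model
}
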