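#' Calibrate a one-dimensional threshold rule
#'
#' Finds the split separating a target class from the remaining pool on
#' one feature. The direction (which side of the threshold accepts the
#' target) points toward the target's mean; the threshold is then the
#' midpoint between adjacent distinct sorted values that minimises
#' training misclassifications (target on the wrong side + rest on the
#' accepting side). Ties are broken toward the smallest threshold, so
#' the result is deterministic.
#'
#' @param target numeric feature values of the target class.
#' @param rest numeric feature values of all other classes in the pool.
#' @return list with `threshold`, `direction` (`"GE"` or `"LE"`),
#'   `errors` (training misclassification count).
#' @export
calibrate_threshold <- function(target, rest) {
  target <- target[!is.na(target)]
  rest <- rest[!is.na(rest)]
  if (!length(target) || !length(rest)) stop("empty sample vector")
  pooled <- sort(unique(c(target, rest)))
  if (length(pooled) < 2)
    stop("target and rest are identical constants; feature cannot separate")
  direction <- if (mean(target) >= mean(rest)) "GE" else "LE"
  cuts <- (pooled[-length(pooled)] + pooled[-1]) / 2
  err <- vapply(cuts, function(t) {
    if (direction == "GE") sum(target < t) + sum(rest >= t)
    else sum(target > t) + sum(rest <= t)
  }, numeric(1))
  best <- which.min(err)  # first minimum: smallest threshold wins ties
  list(threshold = cuts[best], direction = direction,
       errors = as.integer(err[best]))
}

#' Decision rules and knowledge decision trees
#'
#' A `decision_rule` assigns `class` to any still-unlabelled pixel whose
#' `feature` value satisfies `direction` against `threshold`. A
#' `knowledge_tree` is an ordered list of such rules applied
#' sequentially (each rule peels one class off the remaining pixels)
#' plus a fallback class for pixels surviving every rule.
#'
#' @param feature feature name (must exist in the feature set used at
#'   prediction time).
#' @param threshold numeric threshold in index-value units.
#' @param direction `"GE"` (accept when value >= threshold) or `"LE"`.
#' @param class class label assigned by the rule.
#' @return `decision_rule()`: an object of class `decision_rule`;
#'   `knowledge_tree()`: an object of class `knowledge_tree`.
#' @export
decision_rule <- function(feature, threshold, direction, class) {
  stopifnot(direction %in% c("GE", "LE"))
  structure(list(feature = feature, threshold = threshold,
                 direction = direction, class = class),
            class = "decision_rule")
}

#' @rdname decision_rule
#' @param rules list of `decision_rule` objects.
#' @param fallback class assigned to pixels that satisfy no rule.
#' @export
knowledge_tree <- function(rules, fallback) {
  ok <- vapply(rules, inherits, logical(1), "decision_rule")
  if (!all(ok)) stop("rules must be decision_rule objects")
  structure(list(rules = rules, fallback = fallback),
            class = "knowledge_tree")
}

#' @export
print.knowledge_tree <- function(x, ...) {
  cat("<knowledge_tree> ", length(x$rules), " rules, fallback '",
      x$fallback, "'\n", sep = "")
  for (r in x$rules)
    cat(sprintf("  %-10s <- %s %s %.6g\n", r$class, r$feature,
                if (r$direction == "GE") ">=" else "<=", r$threshold))
  invisible(x)
}

#' Default classification hierarchy
#'
#' The expert rule order: December NDVI peels off the evergreen Pinus
#' tabuliformis, April NDVI the still-bare crops, UTM-DMI the pine-oak
#' mixed forests, MTM-NDQI Quercus wutaishanica, MTM-DSI scrub grass,
#' and MTM-RSI splits shaw (high side) from the Larix
#' principis-rupprechtii fallback.
#'
#' @return data frame (feature, class) in application order; the last
#'   row's class is split against the fallback on the same feature.
#' @export
default_hierarchy <- function() {
  data.frame(
    feature = c("NDVI@DEC", "NDVI@APR", "UTM-DMI", "MTM-NDQI",
                "MTM-DSI", "MTM-RSI"),
    class = c("pinus_tabuliformis", "crops", "pine_oak_mixed",
              "quercus_wutaishanica", "scrub_grass", "shaw"),
    stringsAsFactors = FALSE)
}

#' Build a knowledge decision tree from training samples
#'
#' Calibrates each rule of the hierarchy in order with
#' [calibrate_threshold()], at each stage using only the classes not yet
#' assigned by earlier rules. After the last listed rule exactly one
#' class remains; it becomes the fallback. Expert thresholds can be
#' injected via `overrides`.
#'
#' @param training wide feature table (as from [feature_table()]) with a
#'   `class` column and one column per hierarchy feature.
#' @param hierarchy data frame (feature, class) as from
#'   [default_hierarchy()].
#' @param overrides optional named list feature -> list(threshold,
#'   direction) replacing the calibrated values for that rule.
#' @return a [knowledge_tree()].
#' @export
build_knowledge_tree <- function(training, hierarchy = default_hierarchy(),
                                 overrides = list()) {
  stopifnot(is.data.frame(training), "class" %in% names(training))
  needed <- unique(c(hierarchy$class))
  have <- unique(training$class)
  miss <- setdiff(needed, have)
  if (length(miss))
    stop("training data is missing class(es): ", paste(miss, collapse = ", "))
  if (length(setdiff(have, needed)) != 1L)
    stop("training data must contain the hierarchy classes plus exactly ",
         "one fallback class; found extra/missing labels")
  remaining <- have
  rules <- vector("list", nrow(hierarchy))
  for (i in seq_len(nrow(hierarchy))) {
    feat <- hierarchy$feature[i]
    cls <- hierarchy$class[i]
    if (!feat %in% names(training))
      stop("training table has no feature column '", feat, "'")
    tv <- training[[feat]][training$class == cls]
    rv <- training[[feat]][training$class %in% setdiff(remaining, cls)]
    ov <- overrides[[feat]]
    cal <- if (is.null(ov)) calibrate_threshold(tv, rv)
           else list(threshold = ov$threshold, direction = ov$direction)
    rules[[i]] <- decision_rule(feat, cal$threshold, cal$direction, cls)
    remaining <- setdiff(remaining, cls)
  }
  knowledge_tree(rules, fallback = remaining)
}

#' Classify with a knowledge decision tree
#'
#' Sequential masking: each pixel (or table row) receives the class of
#' the first rule it satisfies; survivors of all rules get the fallback.
#' A pixel whose feature value is masked (`NA`) at a rule it still needs
#' is labelled `NA` (nodata).
#'
#' @param tree a [knowledge_tree()].
#' @param features a [feature_set()] (returns a character label matrix)
#'   or a wide data frame with one column per rule feature (returns a
#'   character vector).
#' @param n_rules number of leading rules to apply (default all); later
#'   rules never affect pixels assigned by earlier ones.
#' @return character matrix or vector of class labels, `NA` = nodata.
#' @export
classify_tree <- function(tree, features, n_rules = length(tree$rules)) {
  stopifnot(inherits(tree, "knowledge_tree"))
  if (inherits(features, "feature_set")) {
    get_feat <- function(nm) {
      if (!nm %in% names(features$layers))
        stop("feature set has no layer '", nm, "'")
      features$layers[[nm]]$values
    }
    d <- dim(features$layers[[1]]$values)
    labels <- matrix(NA_character_, d[1], d[2])
  } else if (is.data.frame(features)) {
    get_feat <- function(nm) {
      if (!nm %in% names(features))
        stop("feature table has no column '", nm, "'")
      features[[nm]]
    }
    labels <- rep(NA_character_, nrow(features))
  } else stop("features must be a feature_set or a data frame")

  undecided <- rep(TRUE, length(labels))
  dead <- rep(FALSE, length(labels))  # hit a masked value: nodata
  rules <- tree$rules[seq_len(n_rules)]
  for (r in rules) {
    v <- as.vector(get_feat(r$feature))
    masked <- undecided & is.na(v)
    dead <- dead | masked
    undecided <- undecided & !masked
    hit <- undecided &
      (if (r$direction == "GE") v >= r$threshold else v <= r$threshold)
    hit[is.na(hit)] <- FALSE
    labels[hit] <- r$class
    undecided <- undecided & !hit
  }
  labels[undecided & !dead] <- tree$fallback
  labels
}

#' Serialize a knowledge tree to and from JSON
#'
#' @param tree a [knowledge_tree()].
#' @param path JSON file path.
#' @return `path` invisibly; `read_tree_json()` returns the tree.
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "knowledge_tree"))
  payload <- list(
    rules = lapply(tree$rules, function(r)
      list(feature = r$feature, threshold = r$threshold,
           direction = r$direction, class = r$class)),
    fallback = tree$fallback)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(p$rules, function(r)
    decision_rule(r$feature, r$threshold, r$direction, r$class))
  knowledge_tree(rules, fallback = p$fallback)
}

#' Random-forest comparator configuration
#'
#' The benchmark classifier is a standard bagged-tree ensemble with 250
#' trees and floor(sqrt(p)) candidate features per split -- the usual
#' remote-sensing parameterisation. It is a comparator for the
#' knowledge tree, not a contribution of this package; internally it
#' delegates to \pkg{randomForest}.
#'
#' @param n_trees number of trees (default 250).
#' @param mtry features tried per split; default `floor(sqrt(p))`
#'   computed at fit time.
#' @param seed integer RNG seed making the fit reproducible.
#' @return an object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_trees = 250, mtry = NULL, seed = 1) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  structure(list(n_trees = as.integer(n_trees),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Train the random-forest comparator
#'
#' @param x data frame or matrix of feature columns (p >= 1).
#' @param y class labels (coerced to factor; >= 2 classes required).
#' @param config an [ensemble_config()].
#' @return an object of class `ensemble_classifier` wrapping the fitted
#'   forest; `$mtry` records the features-per-split actually used.
#' @export
train_ensemble <- function(x, y, config = ensemble_config()) {
  stopifnot(inherits(config, "ensemble_config"))
  x <- as.data.frame(x)
  if (ncol(x) < 1) stop("need at least one feature column")
  y <- factor(y)
  if (nlevels(y) < 2) stop("training data contains a single class")
  mtry <- if (is.null(config$mtry))
    max(1L, as.integer(floor(sqrt(ncol(x))))) else config$mtry
  fit <- with_seed(config$seed,
    randomForest::randomForest(x = x, y = y, ntree = config$n_trees,
                               mtry = mtry))
  structure(list(fit = fit, mtry = mtry, features = colnames(x),
                 config = config),
            class = "ensemble_classifier")
}

#' Predict with the random-forest comparator
#'
#' @param classifier an [train_ensemble()] result.
#' @param newdata data frame with the training feature columns.
#' @return factor of predicted labels, one per row (majority vote over
#'   trees); empty input gives an empty factor.
#' @export
classify_ensemble <- function(classifier, newdata) {
  stopifnot(inherits(classifier, "ensemble_classifier"))
  newdata <- as.data.frame(newdata)
  miss <- setdiff(classifier$features, names(newdata))
  if (length(miss))
    stop("newdata is missing feature column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(newdata) == 0L)
    return(factor(character(0), levels = levels(classifier$fit$y)))
  stats::predict(classifier$fit,
                 newdata = newdata[, classifier$features, drop = FALSE])
}
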