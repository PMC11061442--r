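# Early- and late-onset preeclampsia classifiers.
#
# The early-onset classifier is a logistic regression on standardized
# features; the late-onset classifier is a 500-tree random forest. Both
# model kinds are available for both contexts. Training fixes a score
# threshold at the smallest cutoff whose training specificity is >= 0.90.

#' Train a PE classifier
#'
#' @param features Feature table from [build_features()], or a plain
#'   numeric matrix/data.frame of features with `y` supplied.
#' @param y Binary outcome (1 = case) when `features` is a plain matrix.
#' @param model_kind `"lr"` (logistic regression on z-scored features,
#'   fitted by maximum likelihood) or `"rf"` (random forest, 500 trees,
#'   sqrt-p variables per split, Gini impurity, no depth cap).
#' @param seed Integer seed (fixes the random forest; stored either way).
#' @param spec_target Training specificity target for the stored threshold.
#' @param ntree,mtry Random-forest hyperparameters (defaults 500 and
#'   floor(sqrt(p))).
#' @return A `pe_classifier`: model kind, fitted parameters (LR:
#'   intercept/coefficients plus standardization means and sds; RF: the
#'   forest), feature schema and hash, training threshold, seed.
#' @export
pe_train <- function(features, y = NULL, model_kind = c("lr", "rf"),
                     seed = 1L, spec_target = 0.90, ntree = 500,
                     mtry = NULL) {
  model_kind <- match.arg(model_kind)
  xs <- extract_xy(features, y)
  x <- xs$x; y <- xs$y
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  if (anyNA(x)) stop("undefined feature values in training data")
  fit <- NULL
  if (model_kind == "lr") {
    mu <- colMeans(x)
    sds <- apply(x, 2, stats::sd)
    sds[sds == 0] <- 1
    xz <- sweep(sweep(x, 2, mu), 2, sds, `/`)
    df <- data.frame(xz, check.names = FALSE)
    df$.y <- y
    glm_fit <- suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::binomial()))
    fit <- list(coef = stats::coef(glm_fit), center = mu, scale = sds)
  } else {
    fit <- with_seed(seed, {
      randomForest::randomForest(
        x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
        ntree = ntree,
        mtry = mtry %||% max(1, floor(sqrt(ncol(x)))))
    })
  }
  model <- structure(list(model_kind = model_kind, fit = fit,
                          schema = colnames(x),
                          schema_hash = schema_hash(colnames(x)),
                          class_context = attr(features, "class_context"),
                          seed = as.integer(seed),
                          spec_target = spec_target,
                          threshold = NA_real_),
                     class = "pe_classifier")
  scores <- pe_predict(model, features)
  model$threshold <- threshold_at_specificity(scores, y, spec_target)
  model
}

extract_xy <- function(features, y = NULL) {
  if (is.data.frame(features) && !is.null(attr(features, "schema"))) {
    feats <- attr(features, "schema")
    x <- as.matrix(features[, feats, drop = FALSE])
    y <- y %||% features$y
  } else {
    x <- as.matrix(features)
    if (is.null(y)) stop("y required when features carry no schema")
  }
  storage.mode(x) <- "double"
  list(x = x, y = y)
}

#' Predict case risk scores
#'
#' LR: logistic of the linear predictor on standardized features.
#' RF: fraction of trees voting for the case class. Scores lie in [0, 1].
#'
#' @param model A `pe_classifier`.
#' @param features Feature table or matrix matching the training schema.
#' @return Named numeric vector of scores.
#' @export
pe_predict <- function(model, features) {
  if (is.data.frame(features) && !is.null(attr(features, "schema"))) {
    if (!identical(attr(features, "schema_hash"), model$schema_hash)) {
      stop("feature schema mismatch: expected hash ", model$schema_hash)
    }
    x <- as.matrix(features[, model$schema, drop = FALSE])
    ids <- features$sample_id
  } else {
    x <- as.matrix(features)
    miss <- setdiff(model$schema, colnames(x))
    if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
    x <- x[, model$schema, drop = FALSE]
    ids <- rownames(x)
  }
  storage.mode(x) <- "double"
  if (model$model_kind == "lr") {
    xz <- sweep(sweep(x, 2, model$fit$center), 2, model$fit$scale, `/`)
    eta <- model$fit$coef[1] + as.vector(xz %*% model$fit$coef[-1])
    s <- stats::plogis(eta)
  } else {
    s <- stats::predict(model$fit, newdata = as.data.frame(x),
                        type = "prob")[, "1"]
  }
  stats::setNames(as.vector(s), ids)
}

#' Smallest score threshold achieving a specificity target
#'
#' A sample is called positive when `score >= threshold`; the returned
#' threshold is the smallest candidate cutoff (over the observed scores
#' and +Inf) whose specificity on the given labels is at least
#' `spec_target`.
#'
#' @param scores Numeric risk scores.
#' @param y Binary labels (1 = case).
#' @param spec_target Required specificity.
#' @return The threshold.
#' @export
threshold_at_specificity <- function(scores, y, spec_target = 0.90) {
  ctrl <- scores[y == 0]
  if (!length(ctrl)) stop("no controls to anchor the specificity target")
  cand <- sort(unique(c(scores, Inf)))
  for (t in cand) {
    if (mean(ctrl < t) >= spec_target) return(t)
  }
  Inf
}

#' Binary calls from scores
#'
#' @param model A `pe_classifier` (supplies the training threshold).
#' @param scores Scores from [pe_predict()].
#' @param threshold_override Optional threshold replacing the trained one.
#' @return Integer vector of calls (1 = predicted case).
#' @export
pe_classify <- function(model, scores, threshold_override = NULL) {
  t <- threshold_override %||% model$threshold
  as.integer(scores >= t)
}

#' @export
print.pe_classifier <- function(x, ...) {
  cat("<pe_classifier>", toupper(x$model_kind),
      "for", x$class_context %||% "unspecified", "context;",
      length(x$schema), "features (hash", paste0(x$schema_hash, ");"),
      "training threshold", signif(x$threshold, 4), "\n")
  invisible(x)
}

#' Serialize / restore a classifier as JSON
#'
#' LR models round-trip exactly; random forests serialize their full tree
#' ensemble via [randomForest::getTree()] records.
#'
#' @param model A `pe_classifier`.
#' @param path Output path.
#' @return `path` ([write_classifier_json()]) / a `pe_classifier`
#'   ([read_classifier_json()]).
#' @export
write_classifier_json <- function(model, path) {
  obj <- list(version = 1L, model_kind = model$model_kind,
              schema = model$schema, schema_hash = model$schema_hash,
              class_context = model$class_context, seed = model$seed,
              spec_target = model$spec_target, threshold = model$threshold)
  if (model$model_kind == "lr") {
    obj$fit <- list(coef = as.list(model$fit$coef),
                    center = as.list(model$fit$center),
                    scale = as.list(model$fit$scale))
  } else {
    ntree <- model$fit$ntree
    obj$fit <- list(ntree = ntree,
                    trees = lapply(seq_len(ntree), function(k) {
                      tr <- randomForest::getTree(model$fit, k,
                                                  labelVar = FALSE)
                      as.data.frame(tr)
                    }))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier_json
#' @export
read_classifier_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$model_kind != "lr") {
    stop("only LR models can be restored from JSON; retrain RF from data")
  }
  structure(list(model_kind = "lr",
                 fit = list(coef = unlist(obj$fit$coef),
                            center = unlist(obj$fit$center),
                            scale = unlist(obj$fit$scale)),
                 schema = obj$schema, schema_hash = obj$schema_hash,
                 class_context = obj$class_context, seed = obj$seed,
                 spec_target = obj$spec_target, threshold = obj$threshold),
            class = "pe_classifier")
}
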