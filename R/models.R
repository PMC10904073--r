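#' The eight-algorithm classifier panel
#'
#' @return character vector of the registered algorithm IDs.
#' @export
algorithm_ids <- function() {
  c("cart", "rf", "xgboost", "lgbm", "logistic",
    "svc_linear", "svc_rbf", "knn")
}

#' Default hyperparameters of a registered algorithm
#'
#' These are the backing libraries' defaults (plus, where the backing library
#' requires an explicit value, the conventional one), recorded verbatim into
#' run manifests rather than tuned: `rf` 100 trees, `xgboost` 100 rounds at
#' eta 0.3 / depth 6, `lgbm` leaf-wise histogram boosting with 31 leaves at
#' eta 0.1, `logistic` ridge-penalized with lambda 1/n, `knn` k = 5,
#' SVCs at cost 1.
#'
#' @param algorithm one of [algorithm_ids()].
#' @return named list of defaults.
#' @export
default_hyperparameters <- function(algorithm) {
  switch(algorithm,
    cart = list(cp = 0.01, minsplit = 20),
    rf = list(num_trees = 100),
    xgboost = list(nrounds = 100, eta = 0.3, max_depth = 6),
    lgbm = list(nrounds = 100, eta = 0.1, max_leaves = 31),
    logistic = list(alpha = 0, lambda = NULL),  # NULL -> 1/n at fit time
    svc_linear = list(cost = 1),
    svc_rbf = list(cost = 1, gamma = NULL),     # NULL -> 1/p at fit time
    knn = list(k = 5),
    abort(sprintf("unknown algorithm '%s'; valid ids: %s", algorithm,
                  paste(algorithm_ids(), collapse = ", "))))
}

#' Specify a classification model
#'
#' A model spec names one of the eight panel algorithms and a mode: either
#' `all_features` (train on the full feature matrix) or `omc` (nested-CV
#' optimal-model-complexity feature selection, see [fit_omc()]).
#'
#' @param algorithm one of [algorithm_ids()].
#' @param mode `"all_features"` or `"omc"`.
#' @param hyperparameters named list overriding [default_hyperparameters()].
#' @return a `model_spec`.
#' @export
model_spec <- function(algorithm, mode = c("all_features", "omc"),
                       hyperparameters = list()) {
  if (!algorithm %in% algorithm_ids()) {
    abort(sprintf("unknown algorithm '%s'; valid ids: %s", algorithm,
                  paste(algorithm_ids(), collapse = ", ")))
  }
  mode <- match.arg(mode)
  hp <- modifyList(default_hyperparameters(algorithm), hyperparameters)
  structure(list(algorithm = algorithm, mode = mode, hyperparameters = hp),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%s)\n", x$algorithm, x$mode))
  invisible(x)
}

# The registry keys fitting and scoring on sanitized column names so feature
# IDs with arbitrary characters (e.g. "fpkm:ENSG...") never hit formula
# interfaces.
sanitize_x <- function(x) {
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}

#' Fit one classifier on a training matrix
#'
#' Satisfies the CV engine's predictor contract: a fitted object that scores
#' new samples with a ranking score. Probability-type algorithms (cart, rf,
#' xgboost, lgbm, logistic, knn) return the estimated probability of the
#' responder class; margin-type algorithms (the two SVCs) return their signed
#' decision value. Stochastic learners consume `seed`, so the same spec, data
#' and seed always reproduce the same model.
#'
#' @param spec a [model_spec()].
#' @param x samples x features numeric matrix with feature IDs as colnames.
#' @param y response labels aligned with rows of `x`.
#' @param seed integer seed for stochastic learners.
#' @return a `fitted_classifier` with elements `score_type`
#'   (`"probability"` or `"margin"`) and `features` (the feature IDs used).
#' @export
fit_classifier <- function(spec, x, y, seed = 0L) {
  stopifnot(inherits(spec, "model_spec"), is.matrix(x))
  y <- as_response_factor(y)
  hp <- spec$hyperparameters
  xs <- sanitize_x(x)
  score_type <- if (spec$algorithm %in% c("svc_linear", "svc_rbf")) "margin" else "probability"
  model <- with_seed(seed, switch(spec$algorithm,
    cart = {
      df <- data.frame(xs, check.names = FALSE)
      df$.response <- y
      rpart::rpart(.response ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = hp$cp,
                                                  minsplit = hp$minsplit))
    },
    rf = ranger::ranger(x = data.frame(xs, check.names = FALSE), y = y,
                        num.trees = hp$num_trees, probability = TRUE,
                        seed = seed, num.threads = 1),
    xgboost = xgb_fit(xs, y, nrounds = hp$nrounds, seed = seed,
                      params = list(eta = hp$eta, max_depth = hp$max_depth)),
    lgbm = xgb_fit(xs, y, nrounds = hp$nrounds, seed = seed,
                   params = list(eta = hp$eta, tree_method = "hist",
                                 grow_policy = "lossguide",
                                 max_leaves = hp$max_leaves, max_depth = 0)),
    # suppressWarnings: glmnet warns about class counts < 8, which is the
    # normal regime for inner-CV training splits at n ~ 70
    logistic = suppressWarnings(
      glmnet::glmnet(pad_columns(xs), y, family = "binomial",
                     alpha = hp$alpha,
                     lambda = hp$lambda %||% 1 / nrow(xs))),
    svc_linear = e1071::svm(x = xs, y = y, kernel = "linear",
                            cost = hp$cost, scale = FALSE),
    svc_rbf = e1071::svm(x = xs, y = y, kernel = "radial", cost = hp$cost,
                         gamma = hp$gamma %||% 1 / ncol(xs), scale = FALSE),
    knn = list(train = xs, y = y, k = hp$k)
  ))
  structure(list(algorithm = spec$algorithm, model = model,
                 features = colnames(x), score_type = score_type,
                 seed = as.integer(seed)),
            class = "fitted_classifier")
}

# glmnet needs >= 2 columns; pad single-feature matrices with a zero column.
pad_columns <- function(xs) {
  if (ncol(xs) >= 2) return(xs)
  cbind(xs, .pad = 0)
}

xgb_fit <- function(xs, y, nrounds, seed, params) {
  dm <- xgboost::xgb.DMatrix(xs, label = as.integer(y == .positive_class),
                             nthread = 1)
  xgboost::xgb.train(
    params = c(list(objective = "binary:logistic", nthread = 1,
                    seed = seed), params),
    data = dm, nrounds = nrounds, verbose = 0)
}

#' Ranking scores of a fitted classifier on new samples
#'
#' @param fitted a `fitted_classifier` from [fit_classifier()].
#' @param x samples x features matrix; must contain the features the model was
#'   fitted on (extra columns are ignored, order is restored by name).
#' @return numeric vector: probability of the responder class, or the signed
#'   margin (positive = responder) for SVCs.
#' @export
predict_scores <- function(fitted, x) {
  stopifnot(inherits(fitted, "fitted_classifier"))
  if (!all(fitted$features %in% colnames(x))) {
    abort("prediction matrix is missing features the model was fitted on")
  }
  xs <- sanitize_x(x[, fitted$features, drop = FALSE])
  m <- fitted$model
  switch(fitted$algorithm,
    cart = {
      p <- predict(m, newdata = data.frame(xs, check.names = FALSE),
                   type = "prob")
      prob_of(p, .positive_class)
    },
    rf = {
      p <- predict(m, data = data.frame(xs, check.names = FALSE),
                   num.threads = 1)$predictions
      prob_of(p, .positive_class)
    },
    xgboost = predict(m, xgboost::xgb.DMatrix(xs, nthread = 1)),
    lgbm = predict(m, xgboost::xgb.DMatrix(xs, nthread = 1)),
    logistic = as.numeric(predict(m, newx = pad_columns(xs),
                                  type = "response")),
    svc_linear = svm_margin(m, xs),
    svc_rbf = svm_margin(m, xs),
    knn = with_seed(fitted$seed, {
      pred <- class::knn(train = m$train, test = xs, cl = m$y, k = m$k,
                         prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == .positive_class, p, 1 - p)
    })
  )
}

prob_of <- function(p, cls) {
  if (cls %in% colnames(p)) p[, cls] else rep(0, nrow(p))
}

svm_margin <- function(m, xs) {
  pred <- predict(m, newdata = xs, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  if (first == .positive_class) dv[, 1] else -dv[, 1]
}

#' Threshold ranking scores into hard classes
#'
#' Probability scores are cut at `threshold` (default 0.5, strictly above =
#' responder); margin scores are cut at 0.
#'
#' @param scores numeric scores from [predict_scores()].
#' @param score_type `"probability"` or `"margin"`.
#' @param threshold probability cutoff (default 0.5).
#' @return character vector of hard classes.
#' @export
classify_scores <- function(scores, score_type, threshold = 0.5) {
  cut <- if (score_type == "margin") 0 else threshold
  ifelse(scores > cut, .positive_class, "nonresponder")
}

#' Instantiate a predictor handle from a model spec
#'
#' Thin closure wrapper over [fit_classifier()] / [predict_scores()] /
#' [classify_scores()], the fit/score/classify contract consumed by the CV
#' engine.
#'
#' @param spec a [model_spec()].
#' @return list with functions `fit(x, y, seed)`, `score(fitted, x)` and
#'   `classify(scores, threshold)`, plus the `model_spec` itself.
#' @export
make_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  list(
    spec = spec,
    fit = function(x, y, seed = 0L) fit_classifier(spec, x, y, seed),
    score = function(fitted, x) predict_scores(fitted, x),
    classify = function(scores, threshold = 0.5) {
      score_type <- if (spec$algorithm %in% c("svc_linear", "svc_rbf"))
        "margin" else "probability"
      classify_scores(scores, score_type, threshold)
    })
}
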