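fs_methods_all <- c("elastic_net", "linear_correlation", "rank_correlation",
                    "info_gain", "gain_ratio", "rf_accuracy", "rf_impurity")

classifiers_all <- c("logistic", "elastic_net_regression", "svm", "boosting",
                     "random_forest", "knn")

as_binary <- function(labels, positive = "CRC") {
  if (is.numeric(labels)) {
    y <- as.integer(labels != 0)
  } else {
    y <- as.integer(as.character(labels) == positive)
  }
  if (length(unique(y)) < 2L) {
    abort("labels must contain both classes")
  }
  y
}

# Mann-Whitney AUC with midrank half-credit for ties.
auc_mw <- function(scores, y) {
  r <- rank(scores)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

discretize_ef <- function(x, bins = 10L) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE, type = 7))
  if (length(br) < 2L) return(factor(rep(1L, length(x))))
  cut(x, breaks = br, include.lowest = TRUE)
}

info_gain_score <- function(x, y, bins = 10L, ratio = FALSE) {
  d <- discretize_ef(x, bins)
  hy <- entropy2(table(y) / length(y))
  tab <- table(d, y)
  px <- rowSums(tab) / length(y)
  hyx <- sum(px * apply(tab, 1, function(r) {
    if (sum(r) == 0) 0 else entropy2(r / sum(r))
  }))
  ig <- hy - hyx
  if (!ratio) return(ig)
  hx <- entropy2(px)
  if (hx == 0) 0 else ig / hx
}

#' Rank features for classification
#'
#' Returns the top-`k` features of a predictor matrix by one of seven
#' criteria: elastic-net path entry order (first entry along a decreasing
#' regularization path at mixing parameter 0.5), absolute Pearson or
#' Spearman correlation with the outcome, information gain or gain ratio
#' (equal-frequency 10-bin discretization), or random-forest permutation
#' (accuracy) / impurity importance. Forest methods are seeded and
#' deterministic given the seed.
#'
#' @param matrix a [pretreat()] feature matrix, or a plain numeric matrix.
#' @param labels binary outcome (`"CRC"` is the positive class).
#' @param method one of `r paste0('"', fs_methods_all, '"', collapse = ", ")`.
#' @param k number of features to return (`<=` feature count).
#' @param seed RNG seed for forest methods.
#' @param num_trees forest size for the importance methods.
#' @return character vector of `k` feature names, best first.
#' @export
rank_features <- function(matrix, labels, method, k, seed = 1L,
                          num_trees = 500L) {
  method <- match.arg(method, fs_methods_all)
  x <- if (inherits(matrix, "feature_matrix")) {
    feature_matrix_as_matrix(matrix)
  } else {
    as.matrix(matrix)
  }
  y <- as_binary(labels)
  if (k > ncol(x)) abort("`k` exceeds the number of features")
  scores <- switch(
    method,
    elastic_net = {
      fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0.5,
                            nlambda = 100, lambda.min.ratio = 1e-4,
                            standardize = TRUE)
      beta <- as.matrix(fit$beta)
      entry <- apply(beta != 0, 1, function(r) {
        w <- which(r)
        if (length(w)) w[1] else ncol(beta) + 1L
      })
      # earlier entry = stronger; break ties on final |coefficient|
      -(entry * 1e6 - abs(beta[, ncol(beta)]))
    },
    linear_correlation = {
      s <- abs(suppressWarnings(cor(x, y)))[, 1]
      s[is.na(s)] <- 0
      s
    },
    rank_correlation = {
      s <- abs(suppressWarnings(cor(x, y, method = "spearman")))[, 1]
      s[is.na(s)] <- 0
      s
    },
    info_gain = apply(x, 2, info_gain_score, y = y),
    gain_ratio = apply(x, 2, info_gain_score, y = y, ratio = TRUE),
    rf_accuracy = ranger_importance(x, y, "permutation", num_trees, seed),
    rf_impurity = ranger_importance(x, y, "impurity", num_trees, seed)
  )
  names(scores) <- colnames(x)
  names(sort(scores, decreasing = TRUE))[seq_len(k)]
}

ranger_importance <- function(x, y, type, num_trees, seed) {
  d <- data.frame(x, check.names = FALSE)
  d$.outcome <- factor(y, levels = c(0, 1))
  fit <- ranger::ranger(
    dependent.variable.name = ".outcome", data = d,
    num.trees = num_trees, importance = type,
    seed = seed, num.threads = 1L
  )
  imp <- fit$variable.importance
  imp[colnames(x)]
}

default_params <- function(algorithm) {
  switch(algorithm,
    logistic = list(),
    elastic_net_regression = list(alpha = 0.5, lambda = 0.01),
    svm = list(kernel = "radial", cost = 1, balanced = TRUE),
    boosting = list(nrounds = 50, max_depth = 3, eta = 0.3),
    random_forest = list(num_trees = 300),
    knn = list(k = 25)
  )
}

#' Fit a binary classifier emitting a continuous CRC score
#'
#' One interface over the six classifier families. Logistic regression is
#' the reference family (IRLS via [stats::glm()]); complete separation is
#' detected and handled by an automatic small-ridge refit, flagged on the
#' returned model. All models emit a continuous score in which higher
#' means more CRC-like (the positive-class probability where available).
#'
#' @param matrix numeric predictor matrix (or `feature_matrix`); may have
#'   zero columns for an intercept-only logistic fit.
#' @param labels binary outcome (`"CRC"` positive).
#' @param algorithm one of
#'   `r paste0('"', classifiers_all, '"', collapse = ", ")`.
#' @param params named list of algorithm parameters (see
#'   `default_params`); unspecified entries take defaults.
#' @param seed RNG seed for stochastic learners.
#' @return object of class `panel_model`; score new data with
#'   [predict()][predict.panel_model].
#' @export
fit_classifier <- function(matrix, labels, algorithm, params = list(),
                           seed = 1L) {
  algorithm <- match.arg(algorithm, classifiers_all)
  x <- if (inherits(matrix, "feature_matrix")) {
    feature_matrix_as_matrix(matrix)
  } else {
    as.matrix(matrix)
  }
  y <- as_binary(labels)
  params <- utils::modifyList(default_params(algorithm), params)
  separation <- FALSE
  fit <- switch(
    algorithm,
    logistic = {
      d <- data.frame(x, check.names = FALSE)
      d$.outcome <- y
      fml <- if (ncol(x) == 0L) .outcome ~ 1 else .outcome ~ .
      sep_warn <- FALSE
      g <- withCallingHandlers(
        glm(fml, data = d, family = binomial()),
        warning = function(w) {
          msg <- conditionMessage(w)
          if (grepl("fitted probabilities numerically 0 or 1", msg) ||
              grepl("algorithm did not converge", msg)) {
            sep_warn <<- TRUE
            invokeRestart("muffleWarning")
          }
        }
      )
      sep_detect <- any(!is.finite(coef(g))) ||
        ((sep_warn || !g$converged) &&
           (any(abs(coef(g)[-1]) > 15) || !g$converged))
      if (!g$converged && !sep_detect) {
        abort(sprintf(
          "logistic regression did not converge in %d IRLS iterations", g$iter))
      }
      if (sep_detect) {
        separation <- TRUE
        if (ncol(x) >= 2L) {
          g <- suppressWarnings(
            glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                           lambda = 1e-3, standardize = FALSE))
        } else {
          # one-column ridge via penalized IRLS is overkill; rescale instead
          co <- coef(g)
          co[-1] <- pmax(pmin(co[-1], 15), -15)
          g$coefficients <- co
        }
      }
      g
    },
    elastic_net_regression = {
      if (ncol(x) < 2L) abort("elastic net needs at least 2 predictors")
      glmnet::glmnet(x, y, family = "binomial", alpha = params$alpha,
                     standardize = TRUE)
    },
    svm = {
      # inverse-prevalence class weights: unweighted hinge loss all but
      # ignores the ~10% case class
      cw <- if (isTRUE(params$balanced %||% TRUE)) {
        c("0" = 1, "1" = sum(y == 0) / sum(y == 1))
      }
      with_seed(seed, e1071::svm(
        x, factor(y, levels = c(0, 1)), kernel = params$kernel,
        cost = params$cost, scale = TRUE, class.weights = cw
      ))
    },
    boosting = {
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth, eta = params$eta,
                      nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
        nrounds = params$nrounds, verbose = 0
      )
    },
    random_forest = {
      d <- data.frame(x, check.names = FALSE)
      d$.outcome <- factor(y, levels = c(0, 1))
      ranger::ranger(dependent.variable.name = ".outcome", data = d,
                     probability = TRUE, num.trees = params$num_trees,
                     seed = seed, num.threads = 1L)
    },
    knn = list(train = x, y = y, k = params$k, seed = seed)
  )
  structure(
    list(algorithm = algorithm, fit = fit, features = colnames(x),
         params = params, separation = separation, seed = seed),
    class = "panel_model"
  )
}

#' Score new data with a fitted panel classifier
#'
#' @param object a [fit_classifier()] model.
#' @param newdata numeric matrix or `feature_matrix` containing the model's
#'   feature columns.
#' @param ... unused.
#' @return numeric vector of CRC scores (higher = more CRC-like).
#' @export
predict.panel_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) {
    feature_matrix_as_matrix(newdata, object$features)
  } else {
    as.matrix(newdata)[, object$features, drop = FALSE]
  }
  switch(
    object$algorithm,
    logistic = {
      if (inherits(object$fit, "glmnet")) {
        as.numeric(predict(object$fit, x, type = "response"))
      } else {
        co <- coef(object$fit)
        co[is.na(co)] <- 0
        eta <- if (length(co) > 1L) co[1] + drop(x %*% co[-1]) else {
          rep(co[1], nrow(x))
        }
        as.numeric(plogis(eta))
      }
    },
    elastic_net_regression = as.numeric(
      predict(object$fit, x, s = object$params$lambda, type = "response")),
    svm = {
      pr <- predict(object$fit, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # decision value is positive for the class named first in the column
      sgn <- if (startsWith(colnames(dv)[1], "1/")) 1 else -1
      sgn * as.numeric(dv[, 1])
    },
    boosting = as.numeric(
      predict(object$fit, xgboost::xgb.DMatrix(x, nthread = 1))),
    random_forest = {
      d <- data.frame(x, check.names = FALSE)
      predict(object$fit, data = d, num.threads = 1L)$predictions[, "1"]
    },
    knn = {
      with_seed(object$seed, {
        pr <- class::knn(object$fit$train, x,
                         factor(object$fit$y, levels = c(0, 1)),
                         k = object$fit$k, prob = TRUE)
        p <- attr(pr, "prob")
        ifelse(pr == "1", p, 1 - p)
      })
    }
  )
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("<panel_model> %s on %d feature(s)%s\n", x$algorithm,
              length(x$features),
              if (x$separation) " [separation: ridge fallback]" else ""))
  invisible(x)
}

stratified_folds <- function(y, folds, seed) {
  with_seed(seed, {
    f <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(sample(folds), length(idx)))
    }
    f
  })
}
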