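#' Base classifier roster
#'
#' The fusion experiment combines the probabilistic outputs of classical
#' models suited to small tabular cohorts: decision tree, k-nearest
#' neighbors, SVMs with linear / quadratic / cubic kernels, logistic
#' regression, random forest, and a multilayer perceptron. Each entry
#' provides `fit(x, y)` returning an object and `prob(model, newx)`
#' returning an n-by-2 matrix of class probabilities (columns in level
#' order). Features are standardized with training-set statistics inside
#' every wrapper, so scale-sensitive models (kNN, SVM, MLP) behave
#' sensibly.
#'
#' @param names Subset of roster names to return; default all eight.
#' @return Named list of classifier definitions.
#' @examples
#' names(classifier_roster())
#' @export
classifier_roster <- function(names = NULL) {
  roster <- list(
    decision_tree = list(
      fit = function(x, y) {
        rpart::rpart(y ~ ., data = data.frame(x, y = y), method = "class",
                     control = rpart::rpart.control(minsplit = 5, cp = 0.01))
      },
      prob = function(model, newx) {
        stats::predict(model, newdata = data.frame(newx), type = "prob")
      }
    ),
    knn = list(
      fit = function(x, y) {
        sc <- .feature_scaler(x)
        list(x = sc$transform(x), y = y, scaler = sc,
             k = min(5, max(1, floor(length(y) / 4))))
      },
      prob = function(model, newx) {
        pred <- class::knn(model$x, model$scaler$transform(newx), model$y,
                           k = model$k, prob = TRUE)
        pwin <- attr(pred, "prob")
        lv <- levels(model$y)
        p1 <- ifelse(pred == lv[1], pwin, 1 - pwin)
        matrix(c(p1, 1 - p1), ncol = 2, dimnames = list(NULL, lv))
      }
    ),
    svm_linear = .svm_entry("linear", degree = 3),
    svm_quadratic = .svm_entry("polynomial", degree = 2),
    svm_cubic = .svm_entry("polynomial", degree = 3),
    logistic = list(
      fit = function(x, y) {
        sc <- .feature_scaler(x)
        df <- data.frame(sc$transform(x), y = y)
        suppressWarnings(
          list(model = stats::glm(y ~ ., data = df, family = stats::binomial()),
               scaler = sc, levels = levels(y))
        )
      },
      prob = function(model, newx) {
        p2 <- suppressWarnings(
          stats::predict(model$model,
                         newdata = data.frame(model$scaler$transform(newx)),
                         type = "response"))
        matrix(c(1 - p2, p2), ncol = 2, dimnames = list(NULL, model$levels))
      }
    ),
    random_forest = list(
      fit = function(x, y) randomForest::randomForest(x, y, ntree = 300),
      prob = function(model, newx) {
        stats::predict(model, newdata = newx, type = "prob")
      }
    ),
    mlp = list(
      fit = function(x, y) {
        sc <- .feature_scaler(x)
        net <- nnet::nnet(sc$transform(x), stats::model.matrix(~ y - 1)[, 2],
                          size = 4, decay = 0.1, maxit = 300, trace = FALSE)
        list(model = net, scaler = sc, levels = levels(y))
      },
      prob = function(model, newx) {
        p2 <- as.numeric(stats::predict(model$model,
                                        model$scaler$transform(newx)))
        p2 <- pmin(pmax(p2, 0), 1)
        matrix(c(1 - p2, p2), ncol = 2, dimnames = list(NULL, model$levels))
      }
    )
  )
  if (!is.null(names)) {
    missing <- setdiff(names, base::names(roster))
    if (length(missing)) stop("unknown classifier(s): ",
                              paste(missing, collapse = ", "), call. = FALSE)
    roster <- roster[names]
  }
  roster
}

.svm_entry <- function(kernel, degree) {
  list(
    fit = function(x, y) {
      sc <- .feature_scaler(x)
      m <- e1071::svm(sc$transform(x), y, kernel = kernel, degree = degree,
                      probability = TRUE, cost = 1)
      list(model = m, scaler = sc, levels = levels(y))
    },
    prob = function(model, newx) {
      pred <- stats::predict(model$model, model$scaler$transform(newx),
                             probability = TRUE)
      pr <- attr(pred, "probabilities")
      pr[, model$levels, drop = FALSE]
    }
  )
}

# Train-set standardizer; constant features pass through unscaled.
.feature_scaler <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  list(transform = function(z) {
    z <- as.matrix(z)
    scale(z, center = mu, scale = sdv)
  })
}
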