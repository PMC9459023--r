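#' Default misclassification cost matrix
#'
#' Rows index the true class (negative, positive), columns the predicted
#' class. The default doubles the penalty of a false negative (a missed
#' tumor) relative to a false positive.
#'
#' @return 2x2 numeric matrix `[[0, 1], [2, 0]]`.
#' @export
default_cost_matrix <- function() {
  matrix(c(0, 2, 1, 0), nrow = 2,
         dimnames = list(true = c("neg", "pos"), pred = c("neg", "pos")))
}

validate_cost_matrix <- function(cost) {
  if (!is.matrix(cost) || !all(dim(cost) == c(2, 2))) {
    stop("cost matrix must be 2x2")
  }
  if (any(diag(cost) != 0)) stop("cost matrix must have a zero diagonal")
  if (any(cost < 0)) stop("cost matrix entries must be non-negative")
  if (cost[1, 2] == 0 || cost[2, 1] == 0) {
    stop("off-diagonal misclassification costs must be positive")
  }
  invisible(cost)
}

#' Train a cost-sensitive linear SVM
#'
#' Linear support-vector classifier minimizing
#' `1/2 ||w||^2 + C_reg * sum_i c_i * hinge(y_i (w.x_i + b))`, where `c_i`
#' is the misclassification cost of example i's true class — under the
#' default cost matrix, positives (tumor) weigh twice as much as negatives,
#' shifting the boundary toward sensitivity. Support vectors are the
#' training rows with margin at most 1 (non-zero hinge contribution).
#'
#' @param X Numeric matrix (standardized training rows).
#' @param y Labels in `{-1, +1}`; both classes must be present.
#' @param cost Cost matrix, see [default_cost_matrix()].
#' @param C_reg Regularization constant, default 1.
#' @return An object of class `cost_svm` with elements `w`, `b`, `support`
#'   (training row indices), `n_train`, `cost`.
#' @export
train_cost_svm <- function(X, y, cost = default_cost_matrix(), C_reg = 1) {
  X <- as.matrix(X)
  validate_cost_matrix(cost)
  if (length(unique(y)) < 2) stop("training set contains a single class")
  stopifnot(all(y %in% c(-1, 1)), nrow(X) == length(y))
  yf <- factor(y, levels = c(-1, 1))
  wts <- c(`-1` = cost[1, 2], `1` = cost[2, 1])
  m <- e1071::svm(X, yf, type = "C-classification", kernel = "linear",
                  cost = C_reg, class.weights = wts, scale = FALSE,
                  tolerance = 1e-6)
  w <- drop(t(m$coefs) %*% m$SV)
  b <- -m$rho
  # libsvm orients the decision value toward the first label it encountered;
  # re-orient so positive decision values mean the +1 class
  first <- as.character(yf[!duplicated(yf)][1])
  if (first == "-1") {
    w <- -w
    b <- -b
  }
  structure(list(w = w, b = b, support = sort(m$index), n_train = nrow(X),
                 cost = cost, C_reg = C_reg),
            class = "cost_svm")
}

#' Decision values of a linear SVM
#'
#' @param model A [train_cost_svm()] model.
#' @param X Numeric matrix on the model's feature columns.
#' @return Numeric vector `X w + b`; positive values favor the +1 class.
#' @export
decision_values <- function(model, X) {
  stopifnot(inherits(model, "cost_svm"))
  drop(as.matrix(X) %*% model$w + model$b)
}

#' Support-vector ratio
#'
#' Fraction of training observations that are support vectors; a proxy for
#' model complexity and overfitting risk.
#'
#' @param model A [train_cost_svm()] model.
#' @return Numeric in `[0, 1]`.
#' @export
sv_ratio <- function(model) {
  stopifnot(inherits(model, "cost_svm"))
  length(model$support) / model$n_train
}

#' Platt-scale a trained SVM into a posterior calibrator
#'
#' Fits the sigmoid `P(+1 | f) = 1 / (1 + exp(A f + B))` to the training
#' decision values by penalized maximum likelihood, using the conventional
#' regularized targets `(N+ + 1) / (N+ + 2)` and `1 / (N- + 2)` so that
#' perfectly separated folds do not diverge. `A` is negative when the
#' decision values are correctly ordered.
#'
#' @param model A [train_cost_svm()] model.
#' @param X,y The training rows and labels the model was fit on.
#' @return List with sigmoid coefficients `A` and `B`.
#' @export
calibrate_posterior <- function(model, X, y) {
  f <- decision_values(model, X)
  pos <- y == 1
  n_pos <- sum(pos); n_neg <- sum(!pos)
  t_i <- ifelse(pos, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  nll <- function(par) {
    z <- par[1] * f + par[2]
    # stable log(1 + exp(z)) and sigmoid cross-entropy
    lse <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
    sum(t_i * lse + (1 - t_i) * (lse - z))
  }
  grad <- function(par) {
    z <- par[1] * f + par[2]
    p <- 1 / (1 + exp(-z))  # = 1 - P(+1|f)
    d <- p - (1 - t_i)
    c(sum(d * f), sum(d))
  }
  init <- c(0, log((n_neg + 1) / (n_pos + 1)))
  opt <- stats::optim(init, nll, grad, method = "BFGS",
                      control = list(maxit = 200))
  list(A = opt$par[1], B = opt$par[2])
}

#' Posterior probability from a calibrated SVM
#'
#' @param calib Calibrator from [calibrate_posterior()].
#' @param f Decision values.
#' @return Posterior probabilities of the +1 class, in `[0, 1]`.
#' @export
posterior <- function(calib, f) {
  1 / (1 + exp(calib$A * f + calib$B))
}
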