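# Classical baseline harness: feature standardization + LDA or RBF-SVM.
# LDA is delegated to MASS; the SVM is a self-contained SMO solver with
# one-vs-one voting (no SVM package exists in the supported stack).

#' Fit a classical baseline classifier
#'
#' Features are standardized (column mean/SD from the training data;
#' zero-variance columns pass through unscaled) and fed to either linear
#' discriminant analysis or a radial-basis-function support vector machine
#' with the fixed defaults `C = 1`, `gamma = 1 / (n_features * var(x))`.
#'
#' @param x Numeric feature matrix (rows = samples) or list of
#'   `emg_features`.
#' @param labels Factor of class labels (ignored when `x` carries labels).
#' @param kind `"lda"` or `"svm"`.
#' @param cost SVM margin penalty C.
#' @param gamma RBF width; default `1 / (ncol(x) * var(as.vector(x)))`.
#' @param seed Seed for the SMO working-pair selection.
#' @return Object of class `emg_baseline` supporting [predict()].
#' @export
fit_baseline <- function(x, labels = NULL, kind = c("lda", "svm"),
                         cost = 1, gamma = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (is.list(x) && !is.matrix(x) && inherits(x[[1]], "emg_features")) {
    labels <- factor(vapply(x, `[[`, "", "gesture_label"))
    x <- do.call(rbind, lapply(x, `[[`, "values"))
  }
  if (!is.matrix(x)) abort_invalid("`x` must be a feature matrix")
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L)
    abort_invalid("need at least 2 classes, got %d", nlevels(labels))
  if (any(table(labels) < 2L))
    abort_invalid("every class needs at least 2 training samples")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  fit <- if (kind == "lda") {
    MASS::lda(xs, grouping = labels)
  } else {
    if (is.null(gamma)) {
      v <- stats::var(as.vector(xs))
      gamma <- 1 / (ncol(xs) * if (v > 0) v else 1)
    }
    svm_ovo_fit(xs, labels, cost = cost, gamma = gamma, seed = seed)
  }
  structure(list(kind = kind, fit = fit, classes = levels(labels),
                 center = mu, scale = sdv),
            class = "emg_baseline")
}

#' Predict with a baseline classifier
#'
#' @param object An `emg_baseline` model.
#' @param newdata Feature matrix or list of `emg_features`.
#' @param ... Unused.
#' @return Factor of predicted labels (levels = training classes).
#' @export
predict.emg_baseline <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.matrix(newdata) &&
      inherits(newdata[[1]], "emg_features"))
    newdata <- do.call(rbind, lapply(newdata, `[[`, "values"))
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  if (object$kind == "lda") {
    stats::predict(object$fit, xs)$class
  } else {
    factor(svm_ovo_predict(object$fit, xs), levels = object$classes)
  }
}

# --- RBF-kernel SVM via simplified SMO -------------------------------------

rbf_kernel <- function(x, y, gamma) {
  xn <- rowSums(x^2); yn <- rowSums(y^2)
  d2 <- outer(xn, yn, "+") - 2 * tcrossprod(x, y)
  exp(-gamma * pmax(d2, 0))
}

# Binary SMO (Platt's simplified variant) on labels in {-1, +1}.
svm_smo_binary <- function(K, y, cost, tol = 1e-3, max_passes = 10L,
                           max_iter = 5000L) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  passes <- 0L
  iter <- 0L
  fcache <- function(i) sum(alpha * y * K[, i]) + b
  while (passes < max_passes && iter < max_iter) {
    iter <- iter + 1L
    changed <- 0L
    for (i in seq_len(n)) {
      Ei <- fcache(i) - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < cost) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        j <- sample.int(n - 1L, 1L)
        if (j >= i) j <- j + 1L
        Ej <- fcache(j) - y[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old); H <- min(cost, cost + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - cost); H <- min(cost, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - y[j] * (Ei - Ej) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < 1e-5) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
          y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
          y[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < cost) b1
             else if (aj > 0 && aj < cost) b2
             else (b1 + b2) / 2
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  list(alpha = alpha, b = b)
}

svm_ovo_fit <- function(x, labels, cost, gamma, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  cls <- levels(labels)
  pairs <- utils::combn(length(cls), 2)
  machines <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    sel <- labels %in% cls[c(i, j)]
    xs <- x[sel, , drop = FALSE]
    yy <- ifelse(labels[sel] == cls[i], 1, -1)
    K <- rbf_kernel(xs, xs, gamma)
    fit <- svm_smo_binary(K, yy, cost)
    sv <- fit$alpha > 1e-8
    machines[[p]] <- list(pos = cls[i], neg = cls[j],
                          sv_x = xs[sv, , drop = FALSE],
                          sv_coef = (fit$alpha * yy)[sv], b = fit$b)
  }
  list(machines = machines, classes = cls, gamma = gamma)
}

svm_ovo_predict <- function(model, x) {
  votes <- matrix(0L, nrow(x), length(model$classes),
                  dimnames = list(NULL, model$classes))
  for (m in model$machines) {
    if (nrow(m$sv_x) == 0L) { votes[, m$neg] <- votes[, m$neg] + 1L; next }
    f <- rbf_kernel(x, m$sv_x, model$gamma) %*% m$sv_coef + m$b
    win <- ifelse(f >= 0, m$pos, m$neg)
    for (r in seq_len(nrow(x))) votes[r, win[r]] <- votes[r, win[r]] + 1L
  }
  model$classes[max.col(votes, ties.method = "first")]
}
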