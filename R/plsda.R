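#' Fit a PLS-DA model to one data block
#'
#' Partial least squares discriminant analysis: the class factor is coded as
#' a dummy indicator matrix and a PLS2 regression with `H` latent
#' components is fitted by NIPALS on the centered, unit-variance-scaled
#' predictors. The model stores the X loading weights `W` (p x H), the X
#' loadings `D` (p x H, regression coefficients of X on its latent
#' components) and `B` (H x g, regression coefficients of the dummy Y on
#' the latent components), from which predictions for new individuals are
#' `Yhat = Xnew W (D'W)^-1 B` and predicted scores
#' `Tpred = Xnew W (D'W)^-1`.
#'
#' @param X Numeric matrix, observations x variables.
#' @param Y Factor of class labels (>= 2 levels present).
#' @param H Number of latent components (capped at
#'   `min(ncol(X), nrow(X) - 1)`).
#' @param scale Scale columns to unit variance (default TRUE).
#' @return An object of class `plsda_fit`.
#' @export
plsda_fit <- function(X, Y, H = 2L, scale = TRUE) {
  Y <- droplevels(factor(Y))
  if (nlevels(Y) < 2) stop("Y must have at least two classes", call. = FALSE)
  X <- as.matrix(X)
  H <- min(H, ncol(X), nrow(X) - 1L)
  ctr <- colMeans(X)
  scl <- if (scale) {
    s <- apply(X, 2L, stats::sd)
    s[s == 0 | !is.finite(s)] <- 1
    s
  } else rep(1, ncol(X))
  E <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  Ydum <- stats::model.matrix(~ Y - 1)
  colnames(Ydum) <- levels(Y)
  ybar <- colMeans(Ydum)
  F_ <- sweep(Ydum, 2L, ybar)
  n <- nrow(E); p <- ncol(E); g <- ncol(F_)
  W <- matrix(0, p, H); D <- matrix(0, p, H); B <- matrix(0, H, g)
  Tmat <- matrix(0, n, H)
  for (h in seq_len(H)) {
    u <- F_[, which.max(colSums(F_^2))]
    w <- rep(0, p)
    for (it in 1:500) {
      w_new <- drop(crossprod(E, u))
      nw <- sqrt(sum(w_new^2))
      if (nw < 1e-12) break
      w_new <- w_new / nw
      t_ <- drop(E %*% w_new)
      q <- drop(crossprod(F_, t_)) / sum(t_^2)
      u_new <- drop(F_ %*% q) / sum(q^2)
      if (sqrt(sum((w_new - w)^2)) < 1e-10) { w <- w_new; break }
      w <- w_new; u <- u_new
    }
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-12) { W <- W[, seq_len(h - 1L), drop = FALSE]
      D <- D[, seq_len(h - 1L), drop = FALSE]
      B <- B[seq_len(h - 1L), , drop = FALSE]
      Tmat <- Tmat[, seq_len(h - 1L), drop = FALSE]; break }
    d <- drop(crossprod(E, t_)) / tt
    b <- drop(crossprod(F_, t_)) / tt
    W[, h] <- w; D[, h] <- d; B[h, ] <- b; Tmat[, h] <- t_
    E <- E - tcrossprod(t_, d)
    F_ <- F_ - tcrossprod(t_, b)
  }
  structure(list(W = W, D = D, B = B, center = ctr, scale = scl,
                 ybar = ybar, levels = levels(Y), scores = Tmat,
                 Y = Y, H = ncol(W)),
            class = "plsda_fit")
}

#' PLS prediction from the stored weight/loading/coefficient matrices
#'
#' The pure matrix form of the PLS-DA predictor: given the loading weights
#' `W` (p x H), the X loadings `D` (p x H) and the Y coefficients `B`
#' (H x g), the predicted responses for new rows `Xnew` are
#' `Xnew W (D'W)^-1 B` and the predicted scores are `Xnew W (D'W)^-1`.
#' `Xnew` must already be on the scale the matrices were derived on
#' (centered/scaled for a [plsda_fit()] model).
#'
#' @param Xnew Numeric matrix of new observations (rows).
#' @param W,D,B PLS matrices as above.
#' @return List with `Yhat` (n x g) and `Tpred` (n x H).
#' @export
pls_predict <- function(Xnew, W, D, B) {
  R <- W %*% solve(t(D) %*% W)
  Tpred <- Xnew %*% R
  list(Yhat = Tpred %*% B, Tpred = Tpred)
}

#' Predict classes from a PLS-DA model
#'
#' Applies the stored centering/scaling, computes predicted responses and
#' scores via [pls_predict()], and assigns each new observation to a class
#' by the requested rule: `"maximum"` takes the class with the largest
#' predicted dummy response; `"centroid"` assigns to the class whose
#' training-score centroid is nearest (Euclidean) to the predicted score;
#' `"mahalanobis"` does the same under the pooled within-class covariance
#' of the training scores.
#'
#' @param object A `plsda_fit`.
#' @param newdata Numeric matrix, observations x variables.
#' @param distance One of `"centroid"` (default), `"maximum"`,
#'   `"mahalanobis"`.
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.plsda_fit <- function(object, newdata,
                              distance = c("centroid", "maximum",
                                           "mahalanobis"), ...) {
  distance <- match.arg(distance)
  Xs <- sweep(sweep(as.matrix(newdata), 2L, object$center), 2L,
              object$scale, "/")
  pr <- pls_predict(Xs, object$W, object$D, object$B)
  assign_class(pr, object, distance)
}

assign_class <- function(pr, object, distance) {
  lev <- object$levels
  if (distance == "maximum") {
    Yhat <- sweep(pr$Yhat, 2L, object$ybar, "+")
    idx <- max.col(Yhat, ties.method = "first")
    return(factor(lev[idx], levels = lev))
  }
  Ttr <- object$scores
  cls <- object$Y
  centroids <- do.call(rbind, lapply(lev, function(l)
    colMeans(Ttr[cls == l, , drop = FALSE])))
  if (distance == "centroid") {
    d2 <- vapply(seq_along(lev), function(j)
      rowSums(sweep(pr$Tpred, 2L, centroids[j, ])^2), numeric(nrow(pr$Tpred)))
  } else {
    S <- pooled_within_cov(Ttr, cls)
    Sinv <- tryCatch(solve(S), error = function(e)
      solve(S + diag(1e-8, ncol(S))))
    d2 <- vapply(seq_along(lev), function(j) {
      Z <- sweep(pr$Tpred, 2L, centroids[j, ])
      rowSums((Z %*% Sinv) * Z)
    }, numeric(nrow(pr$Tpred)))
  }
  d2 <- matrix(d2, nrow = nrow(pr$Tpred))
  idx <- apply(d2, 1L, which.min)
  factor(lev[idx], levels = lev)
}

pooled_within_cov <- function(Tmat, cls) {
  lev <- levels(cls)
  p <- ncol(Tmat)
  S <- matrix(0, p, p)
  df <- 0
  for (l in lev) {
    Z <- Tmat[cls == l, , drop = FALSE]
    if (nrow(Z) > 1) {
      S <- S + stats::cov(Z) * (nrow(Z) - 1)
      df <- df + nrow(Z) - 1
    }
  }
  if (df == 0) diag(p) else S / df
}
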