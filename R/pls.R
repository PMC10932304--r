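#' Fit a PLS1 discriminant model by NIPALS
#'
#' Partial least squares regression of a single encoded class variable on a
#' complete, column-scaled feature matrix, computed with the NIPALS algorithm
#' and deflation of X. For a univariate response the weight vector of each
#' component is the (normalised) covariance direction `X'y`, so the fit is
#' fully deterministic — no random initialisation. The response is centred
#' but not scaled.
#'
#' After `A` components the regression vector is
#' `b = W (P'W)^{-1} q`, so that `yhat = (X - mean) b + mean(y)`; the
#' per-component score vectors are mutually orthogonal.
#'
#' @param x Complete numeric matrix (samples x features), typically
#'   autoscaled by [impute_and_scale()].
#' @param y Encoded class vector. Default encoding is `+1` for the target
#'   class and `-1` for the rest; a `0/1` encoding works identically (the
#'   model centres `y` either way).
#' @param n_lv Number of latent variables (components), at most `rank(x)`.
#' @return A `pls_model`: list with `n_lv`, `weights` (features x A),
#'   `loadings` (features x A), `scores` (n x A), `y_loadings` (A),
#'   `coefficients` (features, for the full `n_lv`), `coef_by_lv` (features x
#'   A, coefficients after 1..A components), `x_center` (all zero when x is
#'   pre-centred; kept for completeness), `y_mean`, `ssy` (explained sum of
#'   squares of y per component), `feature_ids`.
#' @export
fit_pls <- function(x, y, n_lv) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), n_lv >= 1)
  if (anyNA(x)) stop("x contains missing values; impute first")
  if (stats::var(y) == 0) stop("constant y: both classes required")
  n <- nrow(x); p <- ncol(x)
  feature_ids <- colnames(x) %||% paste0("F", seq_len(p))
  qx <- qr(x)
  if (n_lv > qx$rank)
    stop("n_lv (", n_lv, ") exceeds rank of x (", qx$rank, ")")
  y_mean <- mean(y)
  e <- x                       # deflated X
  f <- y - y_mean              # centred y (never deflated; PLS1)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv); Tm <- matrix(0, n, n_lv)
  qv <- numeric(n_lv); ssy <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- crossprod(e, f)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("degenerate component ", a, ": no residual covariance")
    w <- w / nw
    t_ <- e %*% w
    tt <- sum(t_^2)
    pvec <- crossprod(e, t_)[, 1] / tt
    qa <- sum(f * t_) / tt
    e <- e - t_ %*% t(pvec)
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t_
    qv[a] <- qa; ssy[a] <- qa^2 * tt
  }
  coef_by_lv <- matrix(0, p, n_lv)
  for (a in seq_len(n_lv)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    coef_by_lv[, a] <- Wa %*% solve(crossprod(Pa, Wa), qv[seq_len(a)])
  }
  dimnames(W) <- dimnames(P) <- dimnames(coef_by_lv) <-
    list(feature_ids, paste0("LV", seq_len(n_lv)))
  structure(list(n_lv = n_lv, weights = W, loadings = P, scores = Tm,
                 y_loadings = qv, coefficients = coef_by_lv[, n_lv],
                 coef_by_lv = coef_by_lv, y_mean = y_mean, ssy = ssy,
                 feature_ids = feature_ids),
            class = "pls_model")
}

#' Predict continuous class values from a PLS model
#'
#' Returns `yhat = x b + mean(y_train)` — the unbounded predicted value of
#' the encoded response. With the default `+1/-1` encoding the decision
#' threshold is 0; the membership-scale transform `(yhat + 1) / 2` used for
#' ternary mapping is provided by [predict.phenotype_ensemble()].
#'
#' @param object A `pls_model`.
#' @param newdata Matrix over the model's features (matched by column name
#'   when present), scaled exactly as the training matrix was.
#' @param n_lv Use the coefficients after this many components (default: the
#'   model's full count).
#' @param ... Unused.
#' @return Numeric vector of predicted values.
#' @export
predict.pls_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  newdata <- as.matrix(newdata)
  stopifnot(n_lv >= 1, n_lv <= object$n_lv)
  if (!is.null(colnames(newdata))) {
    miss <- setdiff(object$feature_ids, colnames(newdata))
    if (length(miss))
      stop("newdata lacks model feature(s): ",
           paste(utils::head(miss, 5), collapse = ", "),
           if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5) else "")
    newdata <- newdata[, object$feature_ids, drop = FALSE]
  } else if (ncol(newdata) != length(object$feature_ids)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$feature_ids))
  }
  as.numeric(newdata %*% object$coef_by_lv[, n_lv] + object$y_mean)
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", length(x$feature_ids), " features, ", x$n_lv,
      " latent variable(s)\n", sep = "")
  cat("  cumulative SSY explained: ",
      paste(sprintf("%.3f", cumsum(x$ssy) / sum(x$ssy)), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' VIP of feature `j` over the `A` components of a PLS model:
#' \deqn{VIP_j = \sqrt{p \, \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a}}
#' where `SSY_a` is the sum of squares of the response explained by
#' component `a` and `p` the number of features. The squared VIPs average to
#' 1 by construction, so VIP >= 1 marks features contributing more than
#' average; the conventional selection threshold is 1.
#'
#' @param model A `pls_model`.
#' @return Named numeric vector of VIP scores (one per feature).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (sum(model$ssy) <= 0) stop("model explains no response variance")
  W <- model$weights
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  p <- nrow(W)
  vip <- sqrt(p * as.numeric(wn2 %*% model$ssy) / sum(model$ssy))
  names(vip) <- model$feature_ids
  vip
}
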