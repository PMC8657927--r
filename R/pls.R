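# PLS1 regression (NIPALS), cross-validation (LOO / leave-many-out),
# Q2 / SDEP and latent-variable selection.

#' Fit a PLS1 regression model (NIPALS)
#'
#' Column-centred (optionally unit-variance scaled) NIPALS partial least
#' squares with a single response. Centring-only is the default: the
#' correlogram variables already share an energy-product scale.
#'
#' @param X numeric matrix, compounds x variables; no missing values.
#' @param y numeric response (pIC50).
#' @param n_latent number of latent variables; at most `min(n - 1, p)`.
#' @param scale_x unit-variance scale the columns (default FALSE).
#' @return object of class `pls_model`: weights `W`, loadings `P`, scores
#'   `T`, y-loadings `q`, regression coefficients on the original variable
#'   scale, `intercept`, `fitted`, training `r2` and the centring/scaling
#'   vectors.
#' @export
fit_pls <- function(X, y, n_latent = 2, scale_x = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X/y dimension mismatch")
  if (anyNA(X) || anyNA(y)) stop("missing values not supported")
  if (sd(y) == 0) stop("zero-variance response")
  if (n_latent > min(n - 1L, p))
    stop("n_latent must be <= min(n - 1, ncol(X))")
  x_center <- colMeans(X)
  x_scale <- if (scale_x) {
    s <- apply(X, 2L, sd); s[s == 0] <- 1; s
  } else rep(1, p)
  y_center <- mean(y)
  E <- sweep(sweep(X, 2L, x_center), 2L, x_scale, "/")
  f <- y - y_center

  W <- P <- matrix(0, p, 0)
  Tm <- matrix(0, n, 0)
  q <- numeric(0)
  for (lv in seq_len(n_latent)) {
    w <- crossprod(E, f)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- E %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    p_ <- crossprod(E, t_)[, 1] / tt
    q_ <- sum(t_ * f) / tt
    E <- E - t_ %*% t(p_)
    f <- f - t_ * q_
    W <- cbind(W, w); P <- cbind(P, p_); Tm <- cbind(Tm, t_)
    q <- c(q, q_)
  }
  k <- ncol(W)
  if (k == 0L) stop("no usable latent variable (X orthogonal to y?)")
  R <- W %*% solve(crossprod(P, W), diag(k))
  beta_scaled <- R %*% q
  coefficients <- as.numeric(beta_scaled) / x_scale
  intercept <- y_center - sum(coefficients * x_center)
  fitted <- as.numeric(X %*% coefficients + intercept)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  structure(
    list(n_latent = k, W = W, P = P, T = Tm, q = q,
         coefficients = coefficients, intercept = intercept,
         x_center = x_center, x_scale = x_scale, y_center = y_center,
         scale_x = scale_x, fitted = fitted, r2 = r2,
         variable_names = colnames(X)),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variables, %d variables, R2 = %.3f\n",
              x$n_latent, length(x$coefficients), x$r2))
  invisible(x)
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata numeric matrix with the training variable layout.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  as.numeric(newdata %*% object$coefficients + object$intercept)
}

#' Cross-validate a PLS model (LOO or leave-many-out)
#'
#' LOO refits one model per compound; `lmo` partitions the compounds into
#' `ceiling(n / k)` seeded random disjoint groups and refits per group.
#' `Q2 = 1 - PRESS / SS_tot` (centred response) and
#' `SDEP = sqrt(PRESS / n)`.
#'
#' @param X,y data as in [fit_pls()].
#' @param n_latent latent variables per refit.
#' @param scheme `"loo"` (default) or `"lmo"`.
#' @param k group size for `lmo` (default 5, i.e. leave-five-out).
#' @param seed integer seed for the `lmo` partition.
#' @param scale_x as in [fit_pls()].
#' @return list with `q2`, `sdep`, `press` and `predictions`
#'   (out-of-fold, one per compound).
#' @export
cross_validate <- function(X, y, n_latent = 2, scheme = c("loo", "lmo"),
                           k = 5, seed = 1, scale_x = FALSE) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 5L) stop("need at least 5 compounds for cross-validation")
  if (scheme == "lmo" && k >= n) stop("group size k must be < n")
  fold <- if (scheme == "loo") {
    seq_len(n)
  } else {
    n_groups <- ceiling(n / k)
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    f <- sample(rep(seq_len(n_groups), length.out = n))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    f
  }
  pred <- pls_cv_predictions_cpp(X, y, as.integer(n_latent),
                                 as.integer(fold), scale_x)
  press <- sum((y - pred)^2)
  list(q2 = 1 - press / sum((y - mean(y))^2),
       sdep = sqrt(press / n), press = press,
       predictions = as.numeric(pred), folds = fold)
}

#' Choose the number of latent variables by cross-validated Q2
#'
#' Fits models at 1..`max_lv` latent variables, picks the Q2 maximiser
#' (ties go to the smaller model) and returns the full (LV, Q2, R2, SDEP)
#' table. Warns when the retained model's R2 - Q2 gap exceeds 0.3, the
#' conventional overfitting alarm.
#'
#' @param X,y data as in [fit_pls()].
#' @param max_lv largest model considered (default 5).
#' @param scheme,k,seed,scale_x forwarded to [cross_validate()].
#' @return list with `n_latent` (chosen), `table` (data.frame LV/Q2/R2/
#'   SDEP) and `warning_overfit` flag.
#' @export
select_lv <- function(X, y, max_lv = 5, scheme = "loo", k = 5, seed = 1,
                      scale_x = FALSE) {
  X <- as.matrix(X)
  max_lv <- min(max_lv, nrow(X) - 2L, ncol(X))
  if (max_lv < 1L) stop("max_lv must be >= 1")
  rows <- lapply(seq_len(max_lv), function(lv) {
    cv <- cross_validate(X, y, n_latent = lv, scheme = scheme, k = k,
                         seed = seed, scale_x = scale_x)
    fit <- fit_pls(X, y, n_latent = lv, scale_x = scale_x)
    data.frame(lv = lv, q2 = cv$q2, r2 = fit$r2, sdep = cv$sdep)
  })
  tab <- do.call(rbind, rows)
  best <- which.max(tab$q2)  # ties -> smaller LV (which.max takes first)
  gap <- tab$r2[best] - tab$q2[best]
  if (best == max_lv && all(diff(tab$q2) > 0))
    warning("Q2 still increasing at max_lv; consider a larger search")
  if (gap > 0.3)
    warning(sprintf("R2 - Q2 = %.2f exceeds 0.3: possible overfit", gap))
  list(n_latent = tab$lv[best], table = tab, warning_overfit = gap > 0.3)
}
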