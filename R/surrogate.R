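#' Matérn-5/2 ARD kernel matrix
#'
#' `k(x, x') = s2 * (1 + sqrt(5) r + 5 r^2 / 3) * exp(-sqrt(5) r)` with
#' `r^2 = sum_i ((x_i - x'_i) / l_i)^2`. One length scale per variable
#' (automatic relevance determination).
#'
#' @param X1,X2 Matrices of unit-scaled points (rows).
#' @param length_scales Positive vector, one per column.
#' @param variance Kernel amplitude `s2`.
#' @return `nrow(X1) x nrow(X2)` covariance matrix.
#' @export
matern52_kernel <- function(X1, X2, length_scales, variance = 1) {
  X1s <- sweep(as.matrix(X1), 2, length_scales, "/")
  X2s <- sweep(as.matrix(X2), 2, length_scales, "/")
  d2 <- outer(rowSums(X1s^2), rowSums(X2s^2), "+") - 2 * tcrossprod(X1s, X2s)
  r <- sqrt(pmax(d2, 0))
  s5r <- sqrt(5) * r
  variance * (1 + s5r + 5 * r^2 / 3) * exp(-s5r)
}

# Cholesky with escalating jitter; PSD guard for near-duplicate designs.
chol_jitter <- function(K, max_jitter = 1e-6) {
  jit <- 0
  repeat {
    L <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jit))
    jit <- if (jit == 0) 1e-10 else jit * 10
    if (jit > max_jitter) stop("kernel matrix not positive definite even ",
                               "with jitter; data may be duplicated",
                               call. = FALSE)
  }
}

# Negative log marginal likelihood at log-parameters
# theta = (log ls_1..n, log s2, log noise_var), y standardized.
gp_nll <- function(theta, X, y) {
  n_dim <- ncol(X)
  ls <- exp(theta[seq_len(n_dim)])
  s2 <- exp(theta[n_dim + 1])
  nv <- exp(theta[n_dim + 2])
  K <- matern52_kernel(X, X, ls, s2) + diag(nv, nrow(X))
  ch <- tryCatch(chol_jitter(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  L <- ch$L
  alpha <- backsolve(L, forwardsolve(t(L), y))
  as.numeric(0.5 * crossprod(y, alpha) + sum(log(diag(L))) +
               0.5 * length(y) * log(2 * pi))
}

#' Fit a Gaussian-process surrogate
#'
#' Matérn-5/2 ARD kernel; the objective values are standardized to zero mean
#' and unit variance, and the kernel amplitude, per-variable length scales
#' and noise variance are chosen by maximizing the log marginal likelihood
#' with seeded multi-start L-BFGS-B (one default start plus `n_restarts`
#' log-uniform draws). Length scales are bounded to `[0.01, 100]` in
#' unit-scaled space and the noise variance is floored at `1e-8`, which keeps
#' small-campaign fits (7-30 points) regularized and reproducible.
#'
#' @param X Matrix of unit-scaled inputs in `[0, 1]^n`, one row per
#'   experiment.
#' @param y Objective values (fractions).
#' @param n_restarts Number of random restarts beyond the default start.
#' @param seed Integer seed for the restart draws.
#' @param ls_bounds Length-scale search bounds.
#' @param noise_floor Lower bound on the noise variance (standardized units).
#' @return An object of class `flowbo_gp` with the scaled training data,
#'   kernel amplitude, `length_scales`, `noise_variance`, and cached
#'   Cholesky factors.
#' @export
gp_fit <- function(X, y, n_restarts = 5L, seed = 1L,
                   ls_bounds = c(0.01, 100), noise_floor = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(is.finite(y)))
  if (nrow(X) < 2L) stop("need at least 2 training points", call. = FALSE)
  if (nrow(unique(X)) < 2L) {
    stop("training inputs are all duplicates; add distinct points or jitter",
         call. = FALSE)
  }
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
  ys <- (y - y_mean) / y_sd

  n_dim <- ncol(X)
  lower <- c(rep(log(ls_bounds[1]), n_dim), log(1e-6), log(noise_floor))
  upper <- c(rep(log(ls_bounds[2]), n_dim), log(1e3), log(1))
  starts <- with_seed(seed, {
    s0 <- c(rep(log(0.3), n_dim), log(1), log(1e-2))
    rand <- replicate(n_restarts,
                      stats::runif(n_dim + 2, lower, upper),
                      simplify = FALSE)
    c(list(s0), rand)
  })
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, gp_nll, X = X, y = ys, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("GP hyperparameter optimization failed", call. = FALSE)
  theta <- best$par
  ls <- exp(theta[seq_len(n_dim)])
  s2 <- exp(theta[n_dim + 1])
  nv <- exp(theta[n_dim + 2])
  K <- matern52_kernel(X, X, ls, s2) + diag(nv, nrow(X))
  ch <- chol_jitter(K)
  alpha <- backsolve(ch$L, forwardsolve(t(ch$L), ys))
  structure(list(
    X = X, y = y, y_mean = y_mean, y_sd = y_sd,
    kernel_variance = s2,
    length_scales = stats::setNames(ls, colnames(X)),
    noise_variance = nv, L = ch$L, alpha = alpha, jitter = ch$jitter,
    log_marginal_likelihood = -best$value
  ), class = "flowbo_gp")
}

#' GP posterior prediction
#'
#' Standard Gaussian-process posterior mean and standard deviation,
#' de-standardized to objective units. The reported standard deviation is
#' that of the latent function (no observation noise added).
#'
#' @param model A `flowbo_gp`.
#' @param Xnew Matrix (or single vector) of unit-scaled query points.
#' @return List with numeric vectors `mean` and `sd`.
#' @export
gp_predict <- function(model, Xnew) {
  if (!is.matrix(Xnew)) Xnew <- matrix(Xnew, nrow = 1)
  Ks <- matern52_kernel(Xnew, model$X, model$length_scales,
                        model$kernel_variance)
  mu_s <- Ks %*% model$alpha
  v <- forwardsolve(t(model$L), t(Ks))
  var_s <- pmax(model$kernel_variance - colSums(v^2), 0)
  list(mean = as.numeric(mu_s) * model$y_sd + model$y_mean,
       sd = sqrt(var_s) * model$y_sd)
}

#' Length-scale variable-importance ranking
#'
#' Ranks variables by ascending ARD length scale: the smaller the length
#' scale, the faster the objective varies along that variable, hence the
#' more important it is to the optimization. Length scales within
#' `tie_tol` (relative) are flagged as tied; ties keep variable order.
#'
#' A length scale sitting at the upper search bound means the training data
#' carried no information along that variable (e.g. a heavily exploited
#' campaign whose refinements all share one coordinate); interpret such
#' ranks as "unidentified" rather than "unimportant".
#'
#' @param model A fitted `flowbo_gp`.
#' @param space Optional `flowbo_space` supplying variable names.
#' @param tie_tol Relative difference under which two length scales count
#'   as tied.
#' @return Data frame with `variable`, `length_scale`, `rank` (1 = most
#'   important) and `tied` flag, ordered by rank.
#' @export
gp_importance <- function(model, space = NULL, tie_tol = 0.05) {
  ls <- model$length_scales
  nms <- if (!is.null(space)) names(space$variables) else
    names(ls) %||% paste0("x", seq_along(ls))
  ord <- order(ls)  # ties broken by variable order (stable sort)
  sorted <- ls[ord]
  tied <- rep(FALSE, length(ls))
  if (length(ls) > 1) {
    rel <- abs(diff(sorted)) / pmax(sorted[-length(sorted)], 1e-12)
    adj <- rel < tie_tol
    tied[c(adj, FALSE) | c(FALSE, adj)] <- TRUE
  }
  data.frame(variable = nms[ord], length_scale = unname(sorted),
             rank = seq_along(ls), tied = tied, row.names = NULL)
}

#' Serialize a GP surrogate to JSON
#'
#' Captures the training data and hyperparameters (not the cached
#' factorizations) for campaign logs.
#'
#' @param model A `flowbo_gp`.
#' @return A JSON string.
#' @export
gp_serialize <- function(model) {
  jsonlite::toJSON(list(
    X = model$X, y = model$y, y_mean = model$y_mean, y_sd = model$y_sd,
    kernel_variance = model$kernel_variance,
    length_scales = as.list(model$length_scales),
    noise_variance = model$noise_variance,
    log_marginal_likelihood = model$log_marginal_likelihood
  ), digits = NA, auto_unbox = TRUE)
}
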