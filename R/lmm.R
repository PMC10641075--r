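# Maximum-likelihood fit of the single-random-intercept linear mixed model
#
#   y_ij = x_ij' beta + b_i + e_ij,   b_i ~ N(0, sigma_b^2),  e_ij ~ N(0, sigma_e^2)
#
# used throughout for per-element activity (intercept only) and the allelic
# likelihood-ratio test (intercept + side indicator). The likelihood is
# profiled analytically over (beta, sigma_e^2) for a fixed variance ratio
# lambda = sigma_b^2 / sigma_e^2, leaving a 1-D optimization over lambda >= 0.
# With one grouping factor, V_i^-1 = (I - c_i 11') / sigma_e^2 with
# c_i = lambda / (1 + lambda n_i), so every profile evaluation costs O(G)
# given per-group sufficient statistics. ML (not REML) is used so that
# likelihood-ratio tests between nested fixed-effect models are valid.

# Profile log-likelihood machinery on sufficient statistics:
#   ni  group sizes (length G)
#   S   G x p matrix of per-group column sums of X
#   ti  per-group sums of y
#   yty, XtX, Xty  global cross-products
.lmm_profile <- function(lambda, ni, S, ti, yty, XtX, Xty, N) {
  ci <- lambda / (1 + lambda * ni)
  A <- XtX - crossprod(S, ci * S)
  b <- Xty - crossprod(S, ci * ti)[, 1L]
  beta <- tryCatch(solve(A, b), error = function(e) rep(NA_real_, length(b)))
  if (anyNA(beta)) {
    return(list(ll = -Inf, beta = beta, sigma2 = NA_real_))
  }
  Q <- max((yty - sum(ci * ti^2)) - sum(beta * b), 0)
  sigma2 <- max(Q / N, 1e-12)
  ll <- -N / 2 * (log(2 * pi * sigma2) + 1) - 0.5 * sum(log1p(lambda * ni))
  list(ll = ll, beta = beta, sigma2 = sigma2)
}

.lmm_fit_stats <- function(ni, S, ti, yty, XtX, Xty, N, tol = 1e-10) {
  obj <- function(s) {
    .lmm_profile(s / (1 - s), ni, S, ti, yty, XtX, Xty, N)$ll
  }
  at0 <- .lmm_profile(0, ni, S, ti, yty, XtX, Xty, N)
  opt <- optimize(obj, interval = c(1e-9, 1 - 1e-9), maximum = TRUE, tol = tol)
  if (opt$objective > at0$ll) {
    lambda <- opt$maximum / (1 - opt$maximum)
    fit <- .lmm_profile(lambda, ni, S, ti, yty, XtX, Xty, N)
  } else {
    lambda <- 0
    fit <- at0
  }
  list(
    beta = fit$beta,
    sigma_e = sqrt(fit$sigma2),
    sigma_b = sqrt(lambda * fit$sigma2),
    lambda = lambda,
    loglik = fit$ll,
    converged = is.finite(fit$ll)
  )
}

#' Fit the random-intercept mixed model by maximum likelihood
#'
#' Fits `y = X beta + b_group + e` with `b ~ N(0, sigma_b^2)` and
#' `e ~ N(0, sigma_e^2)` by full ML, profiling the likelihood over the
#' variance ratio with a non-negativity clamp (the fit degenerates
#' gracefully to ordinary least squares when the barcode variance estimate
#' hits zero, and to the sample mean for a single group).
#'
#' @param y Numeric response vector (log2 activities).
#' @param group Grouping factor (barcode ids).
#' @param X Fixed-effect design matrix (default: intercept only).
#' @returns A list of class `mpra_lmm` with elements `beta`, `sigma_b`,
#'   `sigma_e`, `loglik`, `n_obs`, `n_groups`, `converged`.
#' @export
fit_lmm <- function(y, group, X = NULL) {
  keep <- is.finite(y)
  y <- y[keep]
  N <- length(y)
  if (N == 0L) stop("no finite observations to fit", call. = FALSE)
  if (is.null(X)) {
    X <- matrix(1, nrow = N, ncol = 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- as.matrix(X)[keep, , drop = FALSE]
  }
  group <- factor(group[keep])
  gi <- as.integer(group)
  G <- nlevels(group)

  ni <- tabulate(gi, nbins = G)
  S <- rowsum(X, gi, reorder = TRUE)
  ti <- rowsum(y, gi, reorder = TRUE)[, 1L]
  fit <- .lmm_fit_stats(ni, S, ti, sum(y^2), crossprod(X), crossprod(X, y)[, 1L], N)

  structure(
    list(
      beta = setNames(as.numeric(fit$beta), colnames(X)),
      sigma_b = fit$sigma_b,
      sigma_e = fit$sigma_e,
      loglik = fit$loglik,
      n_obs = N,
      n_groups = G,
      converged = fit$converged
    ),
    class = "mpra_lmm"
  )
}

#' @export
print.mpra_lmm <- function(x, ...) {
  cat(sprintf(
    "<mpra_lmm> ML random-intercept fit: %d obs, %d groups\n", x$n_obs, x$n_groups
  ))
  cat("  fixed effects:",
      paste(sprintf("%s = %.4g", names(x$beta), x$beta), collapse = ", "), "\n")
  cat(sprintf("  sigma_b = %.4g, sigma_e = %.4g, logLik = %.4g\n",
              x$sigma_b, x$sigma_e, x$loglik))
  invisible(x)
}

#' @method tidy mpra_lmm
#' @export
tidy.mpra_lmm <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = as.numeric(x$beta))
}

#' @method glance mpra_lmm
#' @export
glance.mpra_lmm <- function(x, ...) {
  tibble::tibble(
    sigma_b = x$sigma_b, sigma_e = x$sigma_e, logLik = x$loglik,
    n_obs = x$n_obs, n_groups = x$n_groups, converged = x$converged
  )
}

#' @export
logLik.mpra_lmm <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) + 2L, class = "logLik")
}
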