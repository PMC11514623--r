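#' Construct a moment set
#'
#' A moment set bundles the saturated first and second moments (means and
#' covariances, denominator n -- the maximum-likelihood convention) of a set
#' of variables together with the effective sample size. All estimation in
#' the package runs off moment sets, so complete-data, listwise-deleted and
#' EM-under-missingness moments are interchangeable inputs.
#'
#' @param names Character vector of variable names (ordered).
#' @param mean Named numeric mean vector.
#' @param cov Covariance matrix (symmetric, positive semidefinite).
#' @param n_effective Effective sample size.
#' @param source One of `"complete"`, `"listwise"`, `"twostage_em"`,
#'   `"population"`.
#' @return An object of class `moment_set`.
#' @export
moment_set <- function(names, mean, cov, n_effective, source = "complete") {
  mean <- stats::setNames(as.numeric(mean), names)
  cov <- as.matrix(cov)
  dimnames(cov) <- list(names, names)
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov)))) {
    stop("covariance matrix is not symmetric", call. = FALSE)
  }
  cov <- (cov + t(cov)) / 2
  structure(list(names = names, mean = mean, cov = cov,
                 n_effective = n_effective, source = source),
            class = "moment_set")
}

#' @export
print.moment_set <- function(x, ...) {
  cat(sprintf("Moment set (%s): %d variables, n_effective = %s\n",
              x$source, length(x$names), format(x$n_effective)))
  invisible(x)
}

#' Compute saturated moments from data
#'
#' @param data A data frame of numeric columns (missing cells allowed).
#' @param method `"complete"` (sample moments, rows assumed complete),
#'   `"listwise"` (drop any row with a missing cell first), or
#'   `"twostage_em"` (maximum-likelihood saturated means/covariances under
#'   multivariate normality via the EM algorithm; `n_effective` is the total
#'   row count).
#' @param vars Optional character vector restricting/ordering the columns.
#' @param tol EM convergence tolerance on successive observed-data
#'   log-likelihood (default 1e-8).
#' @param max_iter Maximum EM iterations (default 500); non-convergence is
#'   an error reporting the iteration count.
#' @return A `moment_set`. Covariances use denominator n.
#' @examples
#' d <- data.frame(x = c(1, 2, 3, NA), y = c(2, 4, 5, 7))
#' compute_moments(d, method = "twostage_em")
#' @export
compute_moments <- function(data, method = c("complete", "listwise", "twostage_em"),
                            vars = NULL, tol = 1e-8, max_iter = 500L) {
  method <- match.arg(method)
  if (is.null(vars)) vars <- names(data)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(as.data.frame(data)[vars])
  if (!is.numeric(X)) {
    bad <- vars[!vapply(as.data.frame(data)[vars], is.numeric, logical(1))]
    stop("non-numeric column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- nrow(X)

  if (method == "listwise" || (method == "complete" && anyNA(X))) {
    keep <- stats::complete.cases(X)
    if (method == "complete" && any(!keep)) {
      stop("method 'complete' requires complete data; use 'listwise' or 'twostage_em'",
           call. = FALSE)
    }
    X <- X[keep, , drop = FALSE]
    if (!nrow(X)) stop("all rows dropped under listwise deletion", call. = FALSE)
    n <- nrow(X)
  }

  if (method %in% c("complete", "listwise")) {
    mu <- colMeans(X)
    S <- crossprod(sweep(X, 2, mu)) / n # denominator n (ML convention)
    return(moment_set(vars, mu, S, n, source = method))
  }

  em <- em_saturated(X, tol = tol, max_iter = max_iter)
  moment_set(vars, em$mean, em$cov, n, source = "twostage_em")
}

# EM for the saturated multivariate normal with data missing at random.
# E-step: per missingness pattern, conditional means and covariances of the
# missing block given the observed block; M-step: saturated mean/cov of the
# completed sufficient statistics. Converges in one step on complete data.
em_saturated <- function(X, tol = 1e-8, max_iter = 500L) {
  n <- nrow(X); p <- ncol(X)
  obs <- !is.na(X)
  if (any(rowSums(obs) == 0L)) X <- X[rowSums(obs) > 0L, , drop = FALSE]
  obs <- !is.na(X); n <- nrow(X)

  # start from available-case moments
  mu <- colMeans(X, na.rm = TRUE)
  Xc <- sweep(X, 2, mu)
  S <- matrix(0, p, p)
  for (j in seq_len(p)) for (k in j:p) {
    ok <- obs[, j] & obs[, k]
    v <- if (any(ok)) sum(Xc[ok, j] * Xc[ok, k]) / sum(ok) else 0
    S[j, k] <- v; S[k, j] <- v
  }
  diag(S) <- pmax(diag(S), 1e-12)

  pat <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pat)

  loglik <- -Inf
  for (iter in seq_len(max_iter)) {
    Tx <- numeric(p)
    Txx <- matrix(0, p, p)
    ll <- 0
    for (g in groups) {
      o <- obs[g[1L], ]
      m <- !o
      Xo <- X[g, o, drop = FALSE]
      ng <- length(g)
      Soo <- S[o, o, drop = FALSE]
      ch <- tryCatch(chol(Soo), error = function(e) NULL)
      if (is.null(ch)) stop("EM failed: singular observed-block covariance", call. = FALSE)
      dev <- sweep(Xo, 2, mu[o])
      # observed-data log-likelihood contribution
      z <- backsolve(ch, t(dev), transpose = TRUE)
      ll <- ll - ng * (sum(o) * log(2 * pi) / 2 + sum(log(diag(ch)))) -
        sum(z^2) / 2
      if (!any(m)) {
        Tx[o] <- Tx[o] + colSums(Xo)
        Txx[o, o] <- Txx[o, o] + crossprod(Xo)
        next
      }
      # B = Soo^-1 %*% Som, then transposed to missing x observed
      B <- backsolve(ch, backsolve(ch, S[o, m, drop = FALSE], transpose = TRUE))
      B <- t(B)
      Em <- matrix(mu[m], ng, sum(m), byrow = TRUE) + dev %*% t(B)
      Cmm <- S[m, m, drop = FALSE] - B %*% S[o, m, drop = FALSE]
      Xfull <- matrix(NA_real_, ng, p)
      Xfull[, o] <- Xo
      Xfull[, m] <- Em
      Tx <- Tx + colSums(Xfull)
      Txx <- Txx + crossprod(Xfull)
      Txx[m, m] <- Txx[m, m] + ng * Cmm
    }
    mu_new <- Tx / n
    S_new <- Txx / n - tcrossprod(mu_new)
    S_new <- (S_new + t(S_new)) / 2
    converged <- is.finite(loglik) && abs(ll - loglik) < tol
    mu <- mu_new; S <- S_new; loglik <- ll
    if (converged) {
      return(list(mean = mu, cov = S, iterations = iter, loglik = ll))
    }
  }
  stop(sprintf("EM did not converge in %d iterations (tolerance %g)", max_iter, tol),
       call. = FALSE)
}
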