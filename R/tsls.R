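#' Two-stage least squares for one transformed equation, from moments
#'
#' Estimates the slope vector as
#' \deqn{b = (S_{xz} S_{zz}^{-1} S_{zx})^{-1} S_{xz} S_{zz}^{-1} S_{zy}}
#' where the S are centred cross-moment matrices of the regressors x,
#' instruments z and outcome y, with the intercept recovered from the means.
#' This is algebraically identical to regressing y on the first-stage fitted
#' values, and reduces to ordinary least squares when the instruments equal
#' the regressors.
#'
#' @param system A `miiv_system`.
#' @param eq Equation id.
#' @param miivs A `miiv_set` for the equation (see [select_miivs()]).
#' @param moments A `moment_set` covering outcome, regressors, instruments.
#' @return A list of class `equation_estimate`: `equation`, `outcome`,
#'   `coefficients` (named: `(Intercept)` then regressors), `param_ids`,
#'   `residual_variance`, `first_stage_r2` (per endogenous regressor),
#'   `sargan` (list `stat`, `df`, `p`; `p` is NA when the equation is
#'   exactly identified), `instruments`, `n_effective`.
#' @export
fit_2sls_equation <- function(system, eq, miivs, moments) {
  equation <- system[[eq]]
  if (is.null(equation)) stop("unknown equation id '", eq, "'", call. = FALSE)
  y <- equation$outcome
  x <- equation$regressors$name
  z <- miivs$selected
  if (length(z) < length(x)) {
    stop("equation '", eq, "' is under-identified", call. = FALSE)
  }
  need <- unique(c(y, x, z))
  if (!all(need %in% moments$names)) {
    stop("moments do not cover: ",
         paste(setdiff(need, moments$names), collapse = ", "), call. = FALSE)
  }
  S <- moments$cov; m <- moments$mean
  Szz <- S[z, z, drop = FALSE]
  Szx <- S[z, x, drop = FALSE]
  Szy <- S[z, y]
  A <- tryCatch(solve(Szz, cbind(Szx, Szy)),
                error = function(e) stop("singular instrument moment matrix in equation '",
                                         eq, "'", call. = FALSE))
  XtPX <- crossprod(Szx, A[, seq_along(x), drop = FALSE])
  XtPy <- crossprod(Szx, A[, length(x) + 1L])
  b <- tryCatch(drop(solve(XtPX, XtPy)),
                error = function(e) stop("singular projected design in equation '",
                                         eq, "'", call. = FALSE))
  names(b) <- x
  a <- unname(m[y] - sum(b * m[x]))

  Sxx <- S[x, x, drop = FALSE]
  Sxy <- S[x, y]
  s_ee <- unname(S[y, y] - 2 * sum(b * Sxy) + drop(crossprod(b, Sxx %*% b)))
  s_ee <- max(s_ee, 0)

  endo <- equation$regressors$name[equation$regressors$endogenous]
  fs <- vapply(endo, function(v) {
    Szv <- S[z, v]
    drop(crossprod(Szv, solve(Szz, Szv))) / S[v, v]
  }, numeric(1))

  est <- list(
    equation = eq, outcome = y,
    coefficients = c("(Intercept)" = a, b),
    param_ids = c(equation$intercept_id, equation$regressors$param_id),
    residual_variance = s_ee,
    first_stage_r2 = fs,
    instruments = z,
    n_effective = moments$n_effective
  )
  est$sargan <- sargan_test(est, system, miivs, moments)
  class(est) <- "equation_estimate"
  est
}

#' Sargan overidentification test
#'
#' Tests whether an equation's instruments are uncorrelated with its error:
#' the statistic is `n` times the R-squared from the regression of the 2SLS
#' residual on all instruments (computed in centred moment algebra), with
#' degrees of freedom equal to instruments minus regressors and a chi-square
#' upper-tail p-value. For an exactly identified equation the p-value is
#' undefined (NA) and the statistic reported as 0 on 0 df.
#'
#' @param estimate An `equation_estimate` (coefficients already fitted).
#' @param system A `miiv_system`.
#' @param miivs The `miiv_set` used for the fit.
#' @param moments The `moment_set` used for the fit.
#' @return A list with `stat`, `df`, `p`.
#' @export
sargan_test <- function(estimate, system, miivs, moments) {
  equation <- system[[estimate$equation]]
  x <- equation$regressors$name
  z <- miivs$selected
  df <- length(z) - length(x)
  if (df <= 0L) {
    return(list(stat = 0, df = 0L, p = NA_real_))
  }
  S <- moments$cov
  b <- estimate$coefficients[x]
  # Cov(residual, z) and Var(residual) in centred moments
  c_ze <- S[z, estimate$outcome] - S[z, x, drop = FALSE] %*% b
  s_ee <- estimate$residual_variance
  if (s_ee <= 0) return(list(stat = 0, df = as.integer(df), p = 1))
  r2 <- drop(crossprod(c_ze, solve(S[z, z, drop = FALSE], c_ze))) / s_ee
  stat <- moments$n_effective * r2
  list(stat = stat, df = as.integer(df),
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Holm step-down adjustment
#'
#' Adjusts a family of p-values for multiple comparisons by Holm's
#' step-down method (a thin wrapper over [stats::p.adjust()]). Undefined
#' entries (NA, e.g. Sargan p-values of exactly identified equations) are
#' passed through and do not count towards the family size.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`, NAs allowed.
#' @return Adjusted p-values, same length and order; NAs preserved.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03)) # 0.03, 0.06, 0.06
#' @export
holm_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- p
  out[ok] <- stats::p.adjust(p[ok], method = "holm")
  out
}
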