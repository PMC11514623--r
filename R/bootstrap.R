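#' Bias-corrected and accelerated (BCa) interval
#'
#' Computes the nonparametric BCa confidence interval from a point
#' estimate, a vector of bootstrap replicates and the jackknife values of
#' the statistic. Bias correction `z0` is the normal quantile of the
#' fraction of replicates below the point estimate (ties counted half);
#' acceleration `a` comes from the jackknife skewness. Percentiles are read
#' from the replicate distribution with [stats::quantile()] type 6. A
#' degenerate replicate distribution collapses the interval to the point.
#'
#' @param point Point estimate.
#' @param boot Numeric vector of bootstrap replicates.
#' @param jack Numeric vector of jackknife (leave-one-out) estimates.
#' @param conf Coverage level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
bca_interval <- function(point, boot, jack, conf = 0.95) {
  B <- length(boot)
  stopifnot(B >= 2, conf > 0, conf < 1)
  if (max(boot) - min(boot) <= 0) return(c(point, point))
  frac <- (sum(boot < point) + 0.5 * sum(boot == point)) / B
  frac <- min(max(frac, 1 / (2 * B)), 1 - 1 / (2 * B))
  z0 <- stats::qnorm(frac)
  d <- mean(jack) - jack
  denom <- sum(d^2)^1.5
  a <- if (denom > 0) sum(d^3) / (6 * denom) else 0
  alpha <- (1 - conf) / 2
  zlo <- stats::qnorm(alpha)
  zhi <- stats::qnorm(1 - alpha)
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  unname(stats::quantile(boot, c(adj(zlo), adj(zhi)), type = 6, names = FALSE))
}

# Bootstrap engine shared by bootstrap_bca() and fit_miiv_sem().
# `prep` is a frozen fit context (system + instrument sets + plan); each
# replicate resamples rows of the analysis-scale data, recomputes moments
# (rerunning EM under the two-stage missing method) and refits every
# equation. Instrument sets are held at the original selection so all
# replicates estimate the same estimand. Failed replicates (singular fits,
# non-converged moments) are discarded and redrawn, up to 2B attempts.
boot_core <- function(Xa, prep, method, B, seed, conf = 0.95, point = NULL) {
  n <- nrow(Xa)
  if (!is.null(seed)) set.seed(seed)
  refit <- function(rows) {
    Xr <- Xa[rows, , drop = FALSE]
    if (method == "twostage_em" && anyNA(Xr)) {
      em <- em_saturated(Xr)
      S <- em$cov
      dimnames(S) <- list(colnames(Xa), colnames(Xa))
      coef_vector_from_moments(prep, S, stats::setNames(em$mean, colnames(Xa)))
    } else {
      if (anyNA(Xr)) Xr <- Xr[stats::complete.cases(Xr), , drop = FALSE]
      mu <- colMeans(Xr)
      S <- crossprod(sweep(Xr, 2, mu)) / nrow(Xr)
      coef_vector_from_moments(prep, S, mu)
    }
  }
  if (is.null(point)) point <- refit(seq_len(n))
  k <- length(point)

  reps <- matrix(NA_real_, B, k, dimnames = list(NULL, names(point)))
  failures <- character()
  got <- 0L; attempts <- 0L
  while (got < B && attempts < 2L * B) {
    attempts <- attempts + 1L
    rows <- sample.int(n, n, replace = TRUE)
    res <- tryCatch(refit(rows), error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, res)
    } else {
      got <- got + 1L
      reps[got, ] <- res
    }
  }
  if (got < B) {
    tab <- sort(table(failures), decreasing = TRUE)
    stop(sprintf("bootstrap: only %d of %d replications succeeded after %d attempts; failures: %s",
                 got, B, attempts,
                 paste(sprintf("%s (x%d)", names(tab), tab), collapse = "; ")),
         call. = FALSE)
  }

  # jackknife for the acceleration constant
  complete <- !anyNA(Xa)
  jack <- matrix(NA_real_, n, k)
  if (complete) {
    # leave-one-out moments by downdating the sufficient statistics
    cs <- colSums(Xa); cp <- crossprod(Xa)
    nm <- colnames(Xa)
    for (i in seq_len(n)) {
      xi <- Xa[i, ]
      mu_i <- stats::setNames((cs - xi) / (n - 1), nm)
      S_i <- (cp - tcrossprod(xi)) / (n - 1) - tcrossprod(mu_i)
      dimnames(S_i) <- list(nm, nm)
      jack[i, ] <- tryCatch(coef_vector_from_moments(prep, S_i, mu_i),
                            error = function(e) rep(NA_real_, k))
    }
  } else {
    for (i in seq_len(n)) {
      jack[i, ] <- tryCatch(refit(setdiff(seq_len(n), i)),
                            error = function(e) rep(NA_real_, k))
    }
  }

  warnings <- character()
  out <- tibble::tibble(
    term = names(point),
    estimate = unname(point),
    std.error = apply(reps, 2, stats::sd),
    conf.low = NA_real_, conf.high = NA_real_
  )
  for (j in seq_len(k)) {
    jj <- jack[, j]
    ci <- bca_interval(point[j], reps[, j], jj[!is.na(jj)], conf = conf)
    out$conf.low[j] <- ci[1]; out$conf.high[j] <- ci[2]
    if (ci[1] > point[j] || ci[2] < point[j]) {
      warnings <- c(warnings, sprintf(
        "BCa interval for '%s' does not bracket the point estimate (extreme acceleration)",
        names(point)[j]))
    }
  }
  list(table = out, B_successful = got, B_attempted = attempts,
       replicates = reps, warnings = warnings, conf = conf, seed = seed)
}

#' Nonparametric BCa bootstrap of a MIIV-2SLS fit
#'
#' Resamples rows of the data with replacement and refits the full
#' MIIV-2SLS pipeline per replicate, holding the instrument sets fixed at
#' the original selection. Standard errors are the standard deviation over
#' the successful replications; confidence intervals are BCa
#' (see [bca_interval()]). Under the two-stage missing method each replicate
#' reruns the EM moment step.
#'
#' @param data Data frame covering the model's observed variables (original
#'   scale).
#' @param model A `miiv_model`.
#' @param B Number of successful replications required (default 5000).
#' @param seed Integer seed for the resampling stream.
#' @param overid_degree,missing,conf,rescale As in [fit_miiv_sem()].
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high` (analysis scale), with attributes
#'   `B_successful`, `B_attempted`, `warnings`.
#' @export
bootstrap_bca <- function(data, model, B = 5000L, seed = NULL,
                          overid_degree = 2L,
                          missing = c("twostage", "listwise", "complete"),
                          conf = 0.95, rescale = NULL) {
  missing <- match.arg(missing)
  stopifnot(B >= 2)
  ctx <- prepare_fit(data, model, overid_degree = overid_degree,
                     missing = missing, rescale = rescale)
  res <- boot_core(ctx$Xa, ctx$prep, ctx$method, B = B, seed = seed, conf = conf,
                   point = ctx$point)
  out <- res$table
  attr(out, "B_successful") <- res$B_successful
  attr(out, "B_attempted") <- res$B_attempted
  attr(out, "warnings") <- res$warnings
  out
}
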