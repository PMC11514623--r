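#' Fit a latent-variable SEM by MIIV-2SLS
#'
#' Runs the full model-implied instrumental-variable pipeline on a data
#' table: rescale columns, compute saturated moments (optionally under
#' missingness), transform latents to observed-variable equations, find and
#' select instruments, estimate every equation by two-stage least squares,
#' run Sargan overidentification tests with Holm adjustment across
#' equations, and (optionally) compute BCa bootstrap standard errors and
#' intervals.
#'
#' @param data Data frame, one row per participant, columns covering the
#'   model's observed variables (original measurement scale; empty cells =
#'   missing).
#' @param model A `miiv_model` (default the packaged brain-body model).
#' @param overid_degree Instruments beyond exact identification per
#'   equation (default 2, so every overidentified equation carries a
#'   2-df Sargan test).
#' @param missing `"twostage"` (EM saturated moments, the default),
#'   `"listwise"`, or `"complete"`.
#' @param bootstrap_B Successful bootstrap replications for SEs/CIs
#'   (default 5000); 0 skips the bootstrap and marks SEs/CIs unavailable.
#' @param conf Confidence level for BCa intervals.
#' @param seed Master seed; the bootstrap stream is derived from it and
#'   recorded in the result.
#' @param rescale Named divisors overriding the model's rescale directive.
#' @return An object of class `miiv_fit`. Use [tidy()] for the coefficient
#'   table (analysis or original scale), [glance()] for a one-row summary,
#'   [sargan_tests()] for the per-equation diagnostics, and
#'   [ggplot2::autoplot()] for a coefficient plot.
#' @examples
#' d <- simulate_cohort(cohort_params(), seed = 7)
#' f <- fit_miiv_sem(d, bootstrap_B = 0)
#' tidy(f)
#' @export
fit_miiv_sem <- function(data, model = eth_model(), overid_degree = 2L,
                         missing = c("twostage", "listwise", "complete"),
                         bootstrap_B = 5000L, conf = 0.95, seed = NULL,
                         rescale = NULL) {
  missing <- match.arg(missing)
  ctx <- prepare_fit(data, model, overid_degree = overid_degree,
                     missing = missing, rescale = rescale)
  core <- fit_from_moments(ctx$prep, ctx$moments)

  boot <- NULL
  warnings <- unlist(lapply(ctx$prep$miiv_sets, function(m) m$warnings))
  if (bootstrap_B > 0) {
    boot_seed <- derive_seeds(seed, 1L)
    boot <- boot_core(ctx$Xa, ctx$prep, ctx$method, B = bootstrap_B,
                      seed = boot_seed, conf = conf, point = core$coef_vector)
    warnings <- c(warnings, boot$warnings)
  }

  structure(list(
    model = model, plan = ctx$prep$plan, system = ctx$prep$system,
    miiv_sets = ctx$prep$miiv_sets, moments = ctx$moments,
    equations = core$equations, coefficients = core$coefficients,
    sargan = core$sargan, bootstrap = boot,
    config = list(overid_degree = overid_degree, missing = missing,
                  bootstrap_B = bootstrap_B, ci = "bca", conf = conf,
                  sargan_adjust = "holm", seed = seed),
    n_obs = nrow(data), warnings = warnings
  ), class = "miiv_fit")
}

#' Fit from a moment set
#'
#' Runs the MIIV-2SLS estimator directly on saturated moments (for example
#' the closed-form population moments of [implied_moments()], on the
#' analysis scale). No bootstrap is possible without row-level data.
#'
#' @param model A `miiv_model`.
#' @param moments A `moment_set` on the analysis (rescaled) scale, covering
#'   the model's observed variables.
#' @param overid_degree As in [fit_miiv_sem()].
#' @param rescale Named divisors used only to report original-scale
#'   equivalents (default: the model's rescale directive).
#' @return A `miiv_fit` (without bootstrap).
#' @export
fit_miiv_moments <- function(model, moments, overid_degree = 2L, rescale = NULL) {
  if (is.null(rescale)) rescale <- attr(model, "rescale")
  plan <- rescale_plan(model, if (is.null(rescale)) numeric() else rescale)
  prep <- build_prep(model, moments, overid_degree, plan)
  core <- fit_from_moments(prep, moments)
  structure(list(
    model = model, plan = plan, system = prep$system,
    miiv_sets = prep$miiv_sets, moments = moments,
    equations = core$equations, coefficients = core$coefficients,
    sargan = core$sargan, bootstrap = NULL,
    config = list(overid_degree = overid_degree, missing = moments$source,
                  bootstrap_B = 0L, ci = "bca", conf = 0.95,
                  sargan_adjust = "holm", seed = NULL),
    n_obs = moments$n_effective,
    warnings = unlist(lapply(prep$miiv_sets, function(m) m$warnings))
  ), class = "miiv_fit")
}

# validate data, rescale, compute moments, freeze instrument selection
prepare_fit <- function(data, model, overid_degree, missing, rescale = NULL) {
  diags <- validate_spec(model)
  if (length(diags)) stop("invalid model: ", paste(diags, collapse = "; "), call. = FALSE)
  vars <- model$observed
  absent <- setdiff(vars, names(data))
  if (length(absent)) {
    stop("data lacks model variables: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  d <- as.data.frame(data)[vars]
  nonnum <- vars[!vapply(d, is.numeric, logical(1))]
  if (length(nonnum)) {
    stop("non-numeric column(s): ", paste(nonnum, collapse = ", "), call. = FALSE)
  }
  const <- vars[vapply(d, function(x) {
    x <- x[!is.na(x)]
    length(x) < 2L || max(x) == min(x)
  }, logical(1))]
  if (length(const)) {
    stop("constant column(s): ", paste(const, collapse = ", "), call. = FALSE)
  }

  if (is.null(rescale)) rescale <- attr(model, "rescale")
  plan <- rescale_plan(model, if (is.null(rescale)) numeric() else rescale)
  da <- apply_rescale(d, plan)
  method <- switch(missing, twostage = "twostage_em", listwise = "listwise",
                   complete = "complete")
  if (method == "complete" && anyNA(da)) {
    stop("missing cells present; choose missing = 'twostage' or 'listwise'",
         call. = FALSE)
  }
  if (method == "twostage_em" && !anyNA(da)) method <- "complete" # EM fixed point
  moments <- compute_moments(da, method = method, vars = vars)
  prep <- build_prep(model, moments, overid_degree, plan)
  Xa <- as.matrix(da)
  if (method == "listwise") Xa <- Xa[stats::complete.cases(Xa), , drop = FALSE]
  list(prep = prep, moments = moments, Xa = Xa, method = method,
       point = fit_from_moments(prep, moments)$coef_vector)
}

build_prep <- function(model, moments, overid_degree, plan) {
  system <- miiv_transform(model)
  miiv_sets <- lapply(names(system), function(id) {
    select_miivs(system, id, moments, overid_degree = overid_degree)
  })
  names(miiv_sets) <- names(system)
  eq_index <- lapply(names(system), function(id) {
    list(y = system[[id]]$outcome, x = system[[id]]$regressors$name,
         z = miiv_sets[[id]]$selected,
         ids = c(system[[id]]$intercept_id, system[[id]]$regressors$param_id))
  })
  list(model = model, system = system, miiv_sets = miiv_sets,
       overid_degree = overid_degree, plan = plan, eq_index = eq_index,
       coef_names = unlist(lapply(eq_index, `[[`, "ids")))
}

# lean coefficient-only refit used by the bootstrap and jackknife loops
coef_vector_from_moments <- function(prep, S, m) {
  out <- numeric(0)
  for (ix in prep$eq_index) {
    Szz <- S[ix$z, ix$z, drop = FALSE]
    Szx <- S[ix$z, ix$x, drop = FALSE]
    A <- solve(Szz, cbind(Szx, S[ix$z, ix$y]))
    k <- length(ix$x)
    b <- drop(solve(crossprod(Szx, A[, seq_len(k), drop = FALSE]),
                    crossprod(Szx, A[, k + 1L])))
    out <- c(out, m[ix$y] - sum(b * m[ix$x]), b)
  }
  stats::setNames(out, prep$coef_names)
}

# fit every transformed equation from a moment set; assemble coefficient
# table on analysis and original scales plus the Sargan family with Holm
fit_from_moments <- function(prep, moments) {
  system <- prep$system
  ests <- lapply(names(system), function(id) {
    fit_2sls_equation(system, id, prep$miiv_sets[[id]], moments)
  })
  names(ests) <- names(system)

  div <- plan_divisor(prep$plan, prep$model$observed)
  coefs <- purrr::map_dfr(ests, function(e) {
    eq <- system[[e$equation]]
    f_y <- div[[e$outcome]]
    f_x <- c(1, unname(div[eq$regressors$name])) # intercept then slopes
    tibble::tibble(
      term = e$param_ids,
      equation = e$equation,
      estimate = unname(e$coefficients),
      estimate_original = unname(e$coefficients) * f_y / f_x
    )
  })
  pt <- parameter_table(prep$model)
  coefs <- dplyr::left_join(coefs, pt[c("id", "kind")],
                            by = c(term = "id"))

  sargan <- purrr::map_dfr(ests, function(e) {
    tibble::tibble(equation = e$equation,
                   n_instruments = length(e$instruments),
                   stat = e$sargan$stat, df = e$sargan$df,
                   p.value = e$sargan$p)
  })
  sargan$p.holm <- holm_adjust(sargan$p.value)

  cv <- stats::setNames(coefs$estimate, coefs$term)
  list(equations = ests, coefficients = coefs, sargan = sargan,
       coef_vector = cv)
}

# derive k reproducible sub-seeds from a master seed (NULL stays NULL)
derive_seeds <- function(seed, k) {
  if (is.null(seed)) return(if (k == 1L) NULL else vector("list", k))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, k)
  if (k == 1L) s[[1L]] else as.list(s)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a MIIV-2SLS fit
#'
#' @param x A `miiv_fit`.
#' @param scale `"analysis"` (rescaled variables, the scale on which the
#'   model was estimated) or `"original"` (measurement units).
#' @param ... Unused.
#' @return A tibble: `term`, `equation`, `kind`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`. Uncertainty columns are NA when the fit was
#'   run without bootstrap.
#' @method tidy miiv_fit
#' @export
tidy.miiv_fit <- function(x, scale = c("analysis", "original"), ...) {
  scale <- match.arg(scale)
  out <- x$coefficients
  ratio <- out$estimate_original / out$estimate
  ratio[!is.finite(ratio)] <- 1
  if (!is.null(x$bootstrap)) {
    bt <- x$bootstrap$table
    out <- dplyr::left_join(out, bt[c("term", "std.error", "conf.low", "conf.high")],
                            by = "term")
  } else {
    out$std.error <- NA_real_
    out$conf.low <- NA_real_
    out$conf.high <- NA_real_
  }
  if (scale == "original") {
    out$estimate <- out$estimate_original
    out$std.error <- out$std.error * abs(ratio)
    lo <- out$conf.low * ratio; hi <- out$conf.high * ratio
    out$conf.low <- pmin(lo, hi); out$conf.high <- pmax(lo, hi)
  }
  out[c("term", "equation", "kind", "estimate", "std.error",
        "conf.low", "conf.high")]
}

#' Glance at a MIIV-2SLS fit
#'
#' @param x A `miiv_fit`.
#' @param ... Unused.
#' @return A one-row tibble: sample sizes, missing-data method, equation
#'   and parameter counts, the smallest raw and Holm-adjusted Sargan
#'   p-values, bootstrap size and seed.
#' @method glance miiv_fit
#' @export
glance.miiv_fit <- function(x, ...) {
  sg <- x$sargan
  tibble::tibble(
    n_obs = x$n_obs,
    n_effective = x$moments$n_effective,
    missing = x$config$missing,
    n_equations = nrow(sg),
    n_parameters = nrow(x$coefficients),
    sargan_min_p = suppressWarnings(min(sg$p.value, na.rm = TRUE)),
    sargan_min_p_holm = suppressWarnings(min(sg$p.holm, na.rm = TRUE)),
    bootstrap_B = if (is.null(x$bootstrap)) 0L else x$bootstrap$B_successful,
    seed = if (is.null(x$config$seed)) NA_integer_ else x$config$seed
  )
}

#' Per-equation Sargan diagnostics of a fit
#'
#' @param fit A `miiv_fit`.
#' @return A tibble: `equation`, `n_instruments`, `stat`, `df`, `p.value`
#'   (raw), `p.holm`. Exactly identified equations carry NA p-values and do
#'   not count towards the Holm family.
#' @export
sargan_tests <- function(fit) {
  stopifnot(inherits(fit, "miiv_fit"))
  fit$sargan
}

#' @export
print.miiv_fit <- function(x, digits = 3, ...) {
  cat("MIIV-2SLS fit:", length(x$equations), "equations,",
      nrow(x$coefficients), "free parameters\n")
  cat(sprintf("n = %s (effective %s), missing = %s\n",
              format(x$n_obs), format(x$moments$n_effective), x$config$missing))
  td <- tidy(x)
  td$estimate <- signif(td$estimate, digits)
  if (!is.null(x$bootstrap)) {
    td$std.error <- signif(td$std.error, digits)
    td$conf.low <- signif(td$conf.low, digits)
    td$conf.high <- signif(td$conf.high, digits)
    cat(sprintf("Bootstrap: %d successful replications (BCa %g%% intervals)\n",
                x$bootstrap$B_successful, 100 * x$bootstrap$conf))
  }
  print(as.data.frame(td), row.names = FALSE)
  cat("\nSargan tests (H0: instruments uncorrelated with equation error):\n")
  sg <- x$sargan
  sg$stat <- signif(sg$stat, digits)
  sg$p.value <- signif(sg$p.value, digits)
  sg$p.holm <- signif(sg$p.holm, digits)
  print(as.data.frame(sg), row.names = FALSE)
  if (length(x$warnings)) {
    cat("\nWarnings:\n")
    for (w in unique(x$warnings)) cat(" -", w, "\n")
  }
  invisible(x)
}

#' Serialise a fit to JSON
#'
#' Emits every number the printed report shows: coefficients on both
#' scales, bootstrap uncertainty, Sargan diagnostics, instrument report and
#' configuration (seed included).
#'
#' @param fit A `miiv_fit`.
#' @param pretty Pretty-print the JSON.
#' @return A JSON string.
#' @export
miiv_fit_json <- function(fit, pretty = TRUE) {
  stopifnot(inherits(fit, "miiv_fit"))
  payload <- list(
    schema = "latentiv/fit/v1",
    config = fit$config,
    n_obs = fit$n_obs,
    n_effective = fit$moments$n_effective,
    coefficients = dplyr::left_join(
      tidy(fit),
      fit$coefficients[c("term", "estimate_original")], by = "term"),
    sargan = fit$sargan,
    miivs = lapply(fit$miiv_sets, function(m) {
      list(eligible = m$eligible, selected = m$selected)
    }),
    bootstrap = if (is.null(fit$bootstrap)) NULL else list(
      B_successful = fit$bootstrap$B_successful,
      B_attempted = fit$bootstrap$B_attempted,
      conf = fit$bootstrap$conf,
      seed = fit$bootstrap$seed
    ),
    warnings = fit$warnings
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = pretty,
                   null = "null")
}
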