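#' The packaged brain-body trade-off model
#'
#' Returns the two-latent model used throughout the package: a brain latent
#' ("nutritional investment in brain tissues") measured by intracranial
#' volume (TIV, the scaling indicator), cerebrum and cerebellum; a lean-body
#' latent ("nutritional investment in lean body tissues") measured by summed
#' organ volumes (scaling indicator) and skeletal muscle (SM); height
#' predicting both latents and fat mass; and negative causal paths from the
#' brain latent to the body latent and to fat mass. The model file also
#' records the default rescaling divisors (10 or 100) used to reduce
#' disparities in variance.
#'
#' @return A `miiv_model`.
#' @export
eth_model <- function() {
  path <- system.file("extdata", "eth_brain_body.model", package = "latentiv")
  if (!nzchar(path)) stop("packaged model file not found; reinstall latentiv", call. = FALSE)
  parse_model(paste(readLines(path), collapse = "\n"))
}

#' Default generator parameters for the synthetic cohort
#'
#' Builds the parameter object of the synthetic brain/body-composition
#' cohort. Defaults encode the study conditions the analysis targets:
#' n = 70 women; causal paths (on the analysis scale) of -0.41 from the
#' brain latent to the lean-body latent and -0.56 from the brain latent to
#' fat mass; height with mean 161 cm and coefficient of variation 4.1%; and
#' 3 missing organ-volume cells, missing completely at random. Indicator
#' means, loadings and error scales are physiologically plausible defaults
#' (documented in the package vignette); parameter-recovery behaviour does
#' not depend on those choices.
#'
#' Path coefficients are expressed on the analysis (rescaled) scale; the
#' generator emits data on the original measurement scale by inverting the
#' rescale plan.
#'
#' @param n Cohort size.
#' @param beta_brain_body,beta_brain_fat Structural paths from the brain
#'   latent to the body latent and to fat mass (analysis scale).
#' @param b_height_brain,b_height_body,b_height_fat Height slopes
#'   (analysis scale).
#' @param height_mean,height_cv Height distribution: mean in cm and
#'   coefficient of variation in percent.
#' @param loadings Named free loadings (`brain=~cerebrum`,
#'   `brain=~cerebellum`, `body=~SM`), analysis scale.
#' @param intercepts Named free intercepts, analysis scale.
#' @param error_sd Named error standard deviations (`zeta_*`, `eps_*`),
#'   analysis scale.
#' @param missing_var,missing_n,missing_rate MCAR missingness: variable,
#'   cell count (default 3 on organs), or a rate overriding the count.
#' @param error_dist `"gaussian"` or `"skewed"` (centred, variance-matched
#'   gamma draws; changes marginal skewness but not the implied covariance).
#' @param cross_loading Optional misspecification fixture: a list
#'   `list(latent =, indicator =, standardized =)` adding a cross-loading of
#'   the given standardized size to the generating model (the analysis model
#'   omits it).
#' @return An object of class `cohort_params`.
#' @seealso [simulate_cohort()], [implied_moments()], [true_parameters()]
#' @export
cohort_params <- function(n = 70L,
                          beta_brain_body = -0.41,
                          beta_brain_fat = -0.56,
                          b_height_brain = 0.8,
                          b_height_body = 12,
                          b_height_fat = 2,
                          height_mean = 161,
                          height_cv = 4.1,
                          loadings = c("brain=~cerebrum" = 0.8,
                                       "brain=~cerebellum" = 0.7,
                                       "body=~SM" = 0.15),
                          intercepts = c("brain~1" = 1.12,
                                         "body~1" = 22.54,
                                         "fat~1" = -7.36,
                                         "cerebrum~1" = -1.2,
                                         "cerebellum~1" = 3.2,
                                         "SM~1" = -14.5),
                          error_sd = c(zeta_brain = 0.9,
                                       zeta_body = 10,
                                       zeta_fat = 5.2,
                                       eps_TIV = 0.3,
                                       eps_cerebrum = 0.35,
                                       eps_cerebellum = 0.8,
                                       eps_organs = 3,
                                       eps_SM = 1),
                          missing_var = "organs",
                          missing_n = 3L,
                          missing_rate = NULL,
                          error_dist = c("gaussian", "skewed"),
                          cross_loading = NULL) {
  error_dist <- match.arg(error_dist)
  stopifnot(n >= 1, height_cv > 0, all(error_sd >= 0))
  rescale <- attr(eth_model(), "rescale")
  h_mean_a <- height_mean / rescale[["height"]]
  h_sd_a <- height_mean * height_cv / 100 / rescale[["height"]]

  paths <- c("brain~height" = b_height_brain,
             "body~brain" = beta_brain_body,
             "body~height" = b_height_body,
             "fat~brain" = beta_brain_fat,
             "fat~height" = b_height_fat)

  miss_n <- if (!is.null(missing_rate)) as.integer(round(missing_rate * n)) else as.integer(missing_n)
  if (miss_n >= n) stop("missing count must be below n", call. = FALSE)

  p <- structure(list(
    n = as.integer(n),
    spec = eth_model(),
    loadings = loadings,
    paths = paths,
    intercepts = intercepts,
    error_sd = error_sd,
    exo = list(height = list(mean = h_mean_a, sd = h_sd_a)),
    missing = list(var = missing_var, n = miss_n),
    error_dist = error_dist,
    rescale = rescale,
    cross_loading = NULL
  ), class = "cohort_params")

  if (!is.null(cross_loading)) {
    p <- add_cross_loading(p, cross_loading)
  }
  p
}

# Augment the generating model with a cross-loading of a given standardized
# size, solving for the raw loading (the implied SD of the indicator changes
# with the loading, so the conversion is a one-dimensional root find).
add_cross_loading <- function(params, cl) {
  stopifnot(is.list(cl), all(c("latent", "indicator", "standardized") %in% names(cl)))
  aug_spec <- augment_spec_cross(params$spec, cl$latent, cl$indicator)
  id <- paste0(cl$latent, "=~", cl$indicator)
  std_of <- function(raw) {
    pl <- params
    pl$spec <- aug_spec
    pl$loadings <- c(params$loadings, stats::setNames(raw, id))
    pl$cross_loading <- NULL
    sys <- system_matrices(pl)
    mm <- moments_from_system(sys)
    lat_sd <- sqrt(mm$cov_all[cl$latent, cl$latent])
    ind_sd <- sqrt(mm$cov_all[cl$indicator, cl$indicator])
    raw * lat_sd / ind_sd
  }
  f <- function(raw) std_of(raw) - cl$standardized
  raw <- stats::uniroot(f, interval = c(0, 10), extendInt = "upX", tol = 1e-10)$root
  params$spec <- aug_spec
  params$loadings <- c(params$loadings, stats::setNames(raw, id))
  params$cross_loading <- c(cl, raw = raw)
  params
}

# divisor for one variable from a named rescale vector (1 when absent)
rescale_factor <- function(rescale, v) {
  if (is.null(rescale) || !(v %in% names(rescale))) return(1)
  f <- rescale[[v]]
  if (is.na(f)) 1 else f
}

# add indicator to a second latent in the spec (non-scaling cross-loading)
augment_spec_cross <- function(spec, latent, indicator) {
  stopifnot(latent %in% spec$latents, indicator %in% spec$observed)
  row <- tibble::tibble(latent = latent, indicator = indicator, scaling = FALSE,
                        loading_id = paste0(latent, "=~", indicator),
                        intercept_id = paste0(indicator, "~1"),
                        error = paste0("eps_", indicator))
  spec$measurement <- dplyr::bind_rows(spec$measurement, row)
  spec
}

# Build the recursive linear system x = a + A x + e over all variables
# (latents then observed). Error terms: zeta_<latent>/zeta_<outcome> for
# structural disturbances, eps_<indicator> for measurement errors,
# delta_<name> for exogenous observed sources.
system_matrices <- function(params) {
  spec <- params$spec
  vars <- c(spec$latents, spec$observed)
  p <- length(vars)
  A <- matrix(0, p, p, dimnames = list(vars, vars))
  a <- stats::setNames(numeric(p), vars)
  err_sd <- stats::setNames(numeric(p), vars)
  err_id <- stats::setNames(character(p), vars)

  lookup <- function(table, id) {
    if (!(id %in% names(table))) return(NULL)
    v <- table[[id]]
    if (is.na(v)) NULL else v
  }
  get_load <- function(id, scaling) {
    if (scaling) return(1)
    v <- lookup(params$loadings, id)
    if (is.null(v)) stop("missing loading value for ", id, call. = FALSE)
    v
  }
  get_int <- function(id, fixed0 = FALSE, optional = FALSE) {
    if (fixed0) return(0)
    v <- lookup(params$intercepts, id)
    if (is.null(v)) {
      if (optional) return(0)
      stop("missing intercept value for ", id, call. = FALSE)
    }
    v
  }
  get_sd <- function(id) {
    v <- lookup(params$error_sd, id)
    if (is.null(v)) stop("missing error SD for ", id, call. = FALSE)
    v
  }

  struct_out <- spec$structural_meta$outcome
  for (L in spec$latents) {
    if (L %in% struct_out) {
      preds <- spec$structural[spec$structural$outcome == L, ]
      for (j in seq_len(nrow(preds))) {
        A[L, preds$predictor[j]] <- params$paths[[preds$path_id[j]]]
      }
      a[L] <- get_int(paste0(L, "~1"))
    } else {
      # exogenous latent: mean defaults to 0 unless supplied
      a[L] <- get_int(paste0(L, "~1"), optional = TRUE)
    }
    err_sd[L] <- get_sd(paste0("zeta_", L))
    err_id[L] <- paste0("zeta_", L)
  }
  for (v in spec$observed) {
    rows <- spec$measurement[spec$measurement$indicator == v, ]
    if (nrow(rows)) {
      for (j in seq_len(nrow(rows))) {
        A[v, rows$latent[j]] <- get_load(rows$loading_id[j], rows$scaling[j])
      }
      a[v] <- get_int(paste0(v, "~1"), fixed0 = any(rows$scaling))
      err_sd[v] <- get_sd(paste0("eps_", v))
      err_id[v] <- paste0("eps_", v)
    } else if (v %in% struct_out) {
      preds <- spec$structural[spec$structural$outcome == v, ]
      for (j in seq_len(nrow(preds))) {
        A[v, preds$predictor[j]] <- params$paths[[preds$path_id[j]]]
      }
      a[v] <- get_int(paste0(v, "~1"))
      err_sd[v] <- get_sd(paste0("zeta_", v))
      err_id[v] <- paste0("zeta_", v)
    } else {
      ex <- params$exo[[v]]
      if (is.null(ex)) stop("no distribution given for exogenous variable ", v, call. = FALSE)
      a[v] <- ex$mean
      err_sd[v] <- ex$sd
      err_id[v] <- paste0("delta_", v)
    }
  }
  list(vars = vars, observed = spec$observed, A = A, a = a,
       err_sd = err_sd, err_id = err_id)
}

# closed-form implied means/covariances of the recursive linear system
moments_from_system <- function(sys) {
  p <- length(sys$vars)
  IA <- solve(diag(p) - sys$A)
  mu <- drop(IA %*% sys$a)
  Sg <- IA %*% diag(sys$err_sd^2, p) %*% t(IA)
  dimnames(Sg) <- list(sys$vars, sys$vars)
  names(mu) <- sys$vars
  list(mean_all = mu, cov_all = Sg)
}

# topological order of the system (children after parents)
topo_order <- function(A) {
  vars <- rownames(A)
  remaining <- vars
  out <- character()
  depends <- lapply(vars, function(v) vars[A[v, ] != 0])
  names(depends) <- vars
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(v) {
      !length(intersect(depends[[v]], remaining))
    }, logical(1))]
    if (!length(ready)) stop("cyclic system", call. = FALSE)
    out <- c(out, ready)
    remaining <- setdiff(remaining, ready)
  }
  out
}

# draw standardized errors: gaussian or centred variance-matched skewed gamma
draw_errors <- function(n, dist) {
  if (dist == "gaussian") return(stats::rnorm(n))
  shape <- 4 # skewness 2/sqrt(shape) = 1
  (stats::rgamma(n, shape = shape, rate = 1) - shape) / sqrt(shape)
}

# simulate the system on the analysis scale; optionally keep error draws
simulate_system <- function(sys, n, dist = "gaussian", keep_errors = FALSE) {
  ord <- topo_order(sys$A)
  X <- matrix(0, n, length(sys$vars), dimnames = list(NULL, sys$vars))
  E <- if (keep_errors) matrix(0, n, length(sys$vars),
                               dimnames = list(NULL, sys$err_id)) else NULL
  for (v in ord) {
    e <- draw_errors(n, dist) * sys$err_sd[v]
    parents <- sys$vars[sys$A[v, ] != 0]
    xb <- sys$a[v]
    if (length(parents)) {
      xb <- xb + X[, parents, drop = FALSE] %*% sys$A[v, parents]
    }
    X[, v] <- xb + e
    if (keep_errors) E[, sys$err_id[v]] <- e
  }
  list(X = X, E = E)
}

#' Simulate a synthetic cohort
#'
#' Draws a cohort from the recursive latent-variable model defined by the
#' generator parameters: height feeds the brain latent; the brain latent
#' feeds the body latent and fat mass; latents emit their indicators through
#' intercepts, loadings and independent errors. Data are generated on the
#' analysis scale and emitted on the original measurement scale (cm, cm^3,
#' kg) by inverting the rescale plan. MCAR missing cells are blanked after
#' generation. The same seed yields a bit-identical table.
#'
#' @param params A `cohort_params` object (see [cohort_params()]).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param keep_latent If TRUE, append the latent scores and error draws as
#'   extra columns (prefixed `.`) for diagnostic use.
#' @return A tibble with columns `height`, `TIV`, `cerebrum`, `cerebellum`,
#'   `organs`, `SM`, `fat` (one row per participant), with attribute
#'   `truth` holding [true_parameters()].
#' @examples
#' d <- simulate_cohort(cohort_params(n = 10), seed = 1)
#' dim(d)
#' @export
simulate_cohort <- function(params = cohort_params(), seed = NULL,
                            keep_latent = FALSE) {
  stopifnot(inherits(params, "cohort_params"))
  if (!is.null(seed)) set.seed(seed)
  sys <- system_matrices(params)
  sim <- simulate_system(sys, params$n, dist = params$error_dist,
                         keep_errors = keep_latent)
  X <- sim$X[, params$spec$observed, drop = FALSE]

  # back to original scale
  for (v in colnames(X)) {
    f <- rescale_factor(params$rescale, v)
    if (f != 1) X[, v] <- X[, v] * f
  }
  out <- tibble::as_tibble(as.data.frame(X))

  # MCAR cells, blanked after generation
  if (params$missing$n > 0L) {
    idx <- sample.int(params$n, params$missing$n)
    out[[params$missing$var]][idx] <- NA_real_
  }

  if (keep_latent) {
    lat <- sim$X[, params$spec$latents, drop = FALSE]
    colnames(lat) <- paste0(".eta_", colnames(lat))
    err <- sim$E
    colnames(err) <- paste0(".", colnames(err))
    out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(lat)),
                            tibble::as_tibble(as.data.frame(err)))
  }
  attr(out, "truth") <- true_parameters(params)
  out
}

#' Closed-form implied moments of the generator
#'
#' Computes the exact population means and covariances of the observed
#' variables implied by the generator parameters (path-tracing through the
#' recursive linear system), on the analysis scale by default. Feeding these
#' moments to the estimator must return every free parameter exactly:
#' population two-stage least squares is noise-free.
#'
#' @param params A `cohort_params`.
#' @param scale `"analysis"` (rescaled, the scale on which paths are
#'   expressed) or `"original"`.
#' @return A `moment_set` with `n_effective = params$n` and source
#'   `"population"`.
#' @export
implied_moments <- function(params = cohort_params(), scale = c("analysis", "original")) {
  scale <- match.arg(scale)
  stopifnot(inherits(params, "cohort_params"))
  sys <- system_matrices(params)
  mm <- moments_from_system(sys)
  obs <- params$spec$observed
  mu <- mm$mean_all[obs]
  S <- mm$cov_all[obs, obs]
  if (scale == "original") {
    f <- vapply(obs, function(v) rescale_factor(params$rescale, v), numeric(1))
    mu <- mu * f
    S <- S * tcrossprod(f)
  }
  moment_set(obs, mu, S, n_effective = params$n, source = "population")
}

#' True free-parameter values of the generator
#'
#' @param params A `cohort_params`.
#' @return A tibble `term`, `truth` on the analysis scale, with terms
#'   labelled as in [tidy()] output (`latent=~indicator` loadings,
#'   `outcome~predictor` paths, `outcome~1` intercepts). Only the free
#'   parameters of the analysis model are listed (an injected cross-loading
#'   is a generating-model misspecification fixture, not an analysis
#'   parameter).
#' @export
true_parameters <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  base <- eth_model()
  pt <- parameter_table(base)
  free <- pt$id[pt$status == "free"]
  val <- c(params$loadings, params$paths, params$intercepts)
  tibble::tibble(term = free,
                 truth = vapply(free, function(id) {
                   v <- val[[id]]
                   if (is.null(v)) NA_real_ else v
                 }, numeric(1)))
}

#' Write a simulated cohort to disk
#'
#' Writes the cohort as CSV (header row, one participant per row, empty
#' cell = missing) plus a sidecar JSON of the generating parameter values
#' (`<path>.params.json`) for parameter-recovery studies.
#'
#' @param cohort A tibble from [simulate_cohort()].
#' @param path Output CSV path.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  sidecar <- paste0(path, ".params.json")
  truth <- attr(cohort, "truth")
  payload <- if (is.null(truth)) list() else truth
  jsonlite::write_json(payload, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar))
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("Synthetic cohort parameters: n =", x$n, "\n")
  cat("  paths:", paste(names(x$paths), "=", signif(x$paths, 3), collapse = ", "), "\n")
  cat("  height: mean", x$exo$height$mean * x$rescale[["height"]], "cm, CV",
      round(100 * x$exo$height$sd / x$exo$height$mean, 2), "%\n")
  cat("  missing:", x$missing$n, "MCAR cells on", x$missing$var, "\n")
  cat("  errors:", x$error_dist, "\n")
  if (!is.null(x$cross_loading)) {
    cat("  cross-loading fixture:", x$cross_loading$latent, "=~",
        x$cross_loading$indicator, "(standardized",
        x$cross_loading$standardized, ")\n")
  }
  invisible(x)
}
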