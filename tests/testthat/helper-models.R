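# Shared fixtures and oracle utilities for the test suite.

brain_body_text <- "
brain =~ TIV + cerebrum + cerebellum
body  =~ organs + SM
brain ~ height
body  ~ brain + height
fat   ~ brain + height
"

brain_body_model <- function() parse_model(brain_body_text)

# Build a generator-parameter object for an arbitrary spec (same shape as
# cohort_params(), used by property tests over random models).
make_params <- function(spec, loadings = numeric(), paths = numeric(),
                        intercepts = numeric(), error_sd = numeric(),
                        exo = list(), n = 100L) {
  structure(list(
    n = as.integer(n), spec = spec, loadings = loadings, paths = paths,
    intercepts = intercepts, error_sd = error_sd, exo = exo,
    missing = list(var = NA_character_, n = 0L),
    error_dist = "gaussian", rescale = NULL, cross_loading = NULL
  ), class = "cohort_params")
}

# Random small recursive two-latent models with random parameter values,
# for the eligibility-oracle and population-identity property tests.
random_model_params <- function() {
  n1 <- sample(2:3, 1)
  n2 <- sample(2:3, 1)
  ind1 <- paste0("y", seq_len(n1))
  ind2 <- paste0("w", seq_len(n2))
  with_x <- runif(1) < 0.7       # exogenous observed covariate
  with_out <- runif(1) < 0.5     # observed structural outcome
  lines <- c(
    paste("F1 =~", paste(ind1, collapse = " + ")),
    paste("F2 =~", paste(ind2, collapse = " + ")),
    paste("F2 ~ F1", if (with_x) "+ x" else ""),
    if (with_x) "F1 ~ x",
    if (with_out) paste("v ~ F1", if (with_x) "+ x" else "")
  )
  spec <- parse_model(paste(lines, collapse = "\n"))

  rcoef <- function(k) round(sample(c(-1, 1), k, TRUE) * runif(k, 0.4, 1.2), 3)
  pt <- parameter_table(spec)
  free_load <- pt$id[pt$kind == "loading" & pt$status == "free"]
  loadings <- stats::setNames(rcoef(length(free_load)), free_load)
  path_ids <- spec$structural$path_id
  paths <- stats::setNames(rcoef(length(path_ids)), path_ids)
  int_ids <- pt$id[pt$kind == "intercept" & pt$status == "free"]
  intercepts <- stats::setNames(round(runif(length(int_ids), -1, 1), 3), int_ids)
  err_ids <- c(paste0("zeta_", spec$structural_meta$outcome),
               paste0("eps_", unique(spec$measurement$indicator)))
  latent_exo <- setdiff(spec$latents, spec$structural_meta$outcome)
  err_ids <- c(err_ids, paste0("zeta_", latent_exo))
  error_sd <- stats::setNames(round(runif(length(err_ids), 0.5, 1.5), 3), err_ids)
  exo <- if (with_x) list(x = list(mean = 0.5, sd = 1)) else list()
  make_params(spec, loadings, paths, intercepts, error_sd, exo)
}

# Evaluate a transformed equation's composite disturbance from simulated
# error draws: coefficient strings are "1" or "-<param id>".
eval_disturbance <- function(equation, E, params) {
  vals <- c(params$loadings, params$paths)
  u <- 0
  for (i in seq_len(nrow(equation$disturbance))) {
    term <- equation$disturbance$term[i]
    cf <- equation$disturbance$coef[i]
    coef <- if (cf == "1") 1 else -vals[[sub("^-", "", cf)]]
    u <- u + coef * E[[paste0(".", term)]]
  }
  u
}

# simulate an arbitrary params object on the analysis scale, keeping errors
simulate_params <- function(params, n, seed = NULL, keep = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  sys <- latentiv:::system_matrices(params)
  sim <- latentiv:::simulate_system(sys, n, dist = params$error_dist,
                                    keep_errors = keep)
  X <- sim$X[, params$spec$observed, drop = FALSE]
  out <- tibble::as_tibble(as.data.frame(X))
  if (keep) {
    err <- sim$E
    colnames(err) <- paste0(".", colnames(err))
    out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(err)))
  }
  out
}

# sample skewness
skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3

# Population moments of arbitrary params, as a moment_set (analysis scale)
implied_moments_params <- function(params, n_effective = 1000L) {
  sys <- latentiv:::system_matrices(params)
  mm <- latentiv:::moments_from_system(sys)
  obs <- params$spec$observed
  moment_set(obs, mm$mean_all[obs], mm$cov_all[obs, obs],
             n_effective = n_effective, source = "population")
}
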