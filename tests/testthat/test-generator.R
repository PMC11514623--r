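test_that("defaults encode the study conditions", {
  p <- cohort_params()
  expect_equal(p$n, 70L)
  expect_equal(unname(p$paths["body~brain"]), -0.41)
  expect_equal(unname(p$paths["fat~brain"]), -0.56)
  expect_equal(p$missing$var, "organs")
  expect_equal(p$missing$n, 3L)
  expect_equal(p$exo$height$mean * p$rescale[["height"]], 161)
  expect_equal(100 * p$exo$height$sd / p$exo$height$mean, 4.1, tolerance = 1e-12)
})

test_that("the same seed yields bit-identical cohorts", {
  a <- simulate_cohort(cohort_params(), seed = 123)
  b <- simulate_cohort(cohort_params(), seed = 123)
  expect_identical(a, b)
  c <- simulate_cohort(cohort_params(), seed = 124)
  expect_false(identical(a, c))
})

test_that("zero error SDs make every column an exact affine function of height", {
  p <- cohort_params(n = 50, missing_n = 0,
                     error_sd = c(zeta_brain = 0, zeta_body = 0, zeta_fat = 0,
                                  eps_TIV = 0, eps_cerebrum = 0,
                                  eps_cerebellum = 0, eps_organs = 0,
                                  eps_SM = 0))
  d <- simulate_cohort(p, seed = 6)
  R <- correlation_matrix(as.data.frame(d))
  expect_true(all(abs(abs(R) - 1) < 1e-10))
})

test_that("sample moments converge to the closed-form implied moments", {
  p <- cohort_params(n = 1e5, missing_n = 0)
  d <- simulate_cohort(p, seed = 2024)
  mom_emp <- compute_moments(
    latentiv:::apply_rescale(as.data.frame(d),
                             rescale_plan(p$spec, p$rescale)),
    "complete")
  mom_pop <- implied_moments(p)
  n <- p$n
  for (i in mom_pop$names) for (j in mom_pop$names) {
    # Monte-Carlo SE of a sample covariance under normality
    se <- sqrt((mom_pop$cov[i, i] * mom_pop$cov[j, j] + mom_pop$cov[i, j]^2) / n)
    expect_lt(abs(mom_emp$cov[i, j] - mom_pop$cov[i, j]), 4 * se)
  }
  expect_equal(mom_emp$mean, mom_pop$mean, tolerance = 0.02)

  # original-scale implied moments match the emitted data scale
  mom_orig <- implied_moments(p, scale = "original")
  expect_equal(unname(mom_orig$mean["TIV"]),
               unname(mom_pop$mean["TIV"] * 100))
  expect_equal(mean(d$TIV), unname(mom_orig$mean["TIV"]), tolerance = 0.01)
})

test_that("zero paths and unit error variances imply a diagonal covariance", {
  p <- cohort_params(
    beta_brain_body = 0, beta_brain_fat = 0, b_height_brain = 0,
    b_height_body = 0, b_height_fat = 0,
    loadings = c("brain=~cerebrum" = 0, "brain=~cerebellum" = 0, "body=~SM" = 0),
    error_sd = c(zeta_brain = 0, zeta_body = 0, zeta_fat = 1, eps_TIV = 1,
                 eps_cerebrum = 1, eps_cerebellum = 1, eps_organs = 1, eps_SM = 1))
  S <- implied_moments(p)$cov
  offdiag <- S[upper.tri(S)]
  expect_true(all(abs(offdiag) < 1e-12))
})

test_that("the implied fat variance decomposes by path tracing", {
  p <- cohort_params()
  S_all <- latentiv:::moments_from_system(latentiv:::system_matrices(p))$cov_all
  v_h <- p$exo$height$sd^2
  v_brain <- p$paths[["brain~height"]]^2 * v_h + p$error_sd[["zeta_brain"]]^2
  expect_equal(S_all["brain", "brain"], v_brain, tolerance = 1e-12)
  b2 <- p$paths[["fat~brain"]]; bh <- p$paths[["fat~height"]]
  cov_brain_h <- p$paths[["brain~height"]] * v_h
  v_fat <- b2^2 * v_brain + bh^2 * v_h + 2 * b2 * bh * cov_brain_h +
    p$error_sd[["zeta_fat"]]^2
  expect_equal(S_all["fat", "fat"], v_fat, tolerance = 1e-12)
})

test_that("population identity: the estimator inverts the generator exactly", {
  # the strongest correctness property: fitting the closed-form implied
  # moments recovers every free parameter to numerical precision
  set.seed(909)
  for (i in 1:25) {
    p <- cohort_params(
      beta_brain_body = runif(1, -1, 1),
      beta_brain_fat = runif(1, -1, 1),
      b_height_brain = runif(1, 0.3, 1.5),
      b_height_body = runif(1, 5, 15),
      b_height_fat = runif(1, 0.5, 3),
      loadings = c("brain=~cerebrum" = runif(1, 0.4, 1.2),
                   "brain=~cerebellum" = runif(1, 0.4, 1.2),
                   "body=~SM" = runif(1, 0.08, 0.3)),
      error_sd = c(zeta_brain = runif(1, 0.5, 1.2),
                   zeta_body = runif(1, 4, 12),
                   zeta_fat = runif(1, 2, 7),
                   eps_TIV = runif(1, 0.2, 0.5),
                   eps_cerebrum = runif(1, 0.2, 0.6),
                   eps_cerebellum = runif(1, 0.4, 1),
                   eps_organs = runif(1, 1, 4),
                   eps_SM = runif(1, 0.5, 1.5)))
    f <- fit_miiv_moments(eth_model(), implied_moments(p))
    cmp <- dplyr::inner_join(tidy(f), true_parameters(p), by = "term")
    expect_lt(max(abs(cmp$estimate - cmp$truth)), 1e-9)
  }
})

test_that("estimator bias shrinks as the cohort grows", {
  set.seed(515)
  med_err <- vapply(c(200, 2000, 20000), function(n) {
    p <- cohort_params(n = n, missing_n = 0)
    errs <- vapply(1:12, function(i) {
      d <- simulate_cohort(p)
      td <- tidy(fit_miiv_sem(d, bootstrap_B = 0))
      abs(td$estimate[td$term == "body~brain"] + 0.41)
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("MCAR cells are missing completely at random", {
  p <- cohort_params(n = 1e5, missing_rate = 0.05)
  d <- simulate_cohort(p, seed = 77)
  expect_equal(sum(is.na(d$organs)), 5000)
  miss <- as.integer(is.na(d$organs))
  preds <- c("height", "TIV", "cerebrum", "cerebellum", "SM", "fat")
  g <- stats::glm(stats::reformulate(preds, "miss"),
                  data = cbind(d[preds], miss = miss), family = stats::binomial())
  z <- summary(g)$coefficients[-1, "z value"]
  expect_true(all(abs(z) < 4))
})

test_that("skewed errors change marginal shape but not the implied covariance", {
  pg <- cohort_params(n = 1e5, missing_n = 0)
  ps <- cohort_params(n = 1e5, missing_n = 0, error_dist = "skewed")
  ds <- simulate_cohort(ps, seed = 41)
  mom_pop <- implied_moments(ps, scale = "original")
  emp <- compute_moments(as.data.frame(ds), "complete")
  # covariances agree within Monte-Carlo tolerance (skewed draws inflate
  # the MC error of second moments, hence the generous 6-SE band)
  for (i in mom_pop$names) for (j in mom_pop$names) {
    se <- sqrt((mom_pop$cov[i, i] * mom_pop$cov[j, j] + mom_pop$cov[i, j]^2) / ps$n)
    expect_lt(abs(emp$cov[i, j] - mom_pop$cov[i, j]), 6 * se)
  }
  # fat inherits the positive skew of its disturbance; gaussian fat does not
  dg <- simulate_cohort(pg, seed = 41)
  expect_gt(skewness(ds$fat), 0.25)
  expect_lt(abs(skewness(dg$fat)), 0.1)
})

test_that("cohorts round-trip through CSV with a truth sidecar", {
  d <- simulate_cohort(cohort_params(), seed = 88)
  path <- file.path(tempdir(), "cohort-test.csv")
  on.exit(unlink(c(path, paste0(path, ".params.json"))), add = TRUE)
  write_cohort(d, path)
  back <- utils::read.csv(path)
  plain <- as.data.frame(d)
  attr(plain, "truth") <- NULL
  expect_equal(as.data.frame(back), plain, tolerance = 1e-12)
  expect_equal(sum(is.na(back$organs)), 3)
  truth <- jsonlite::fromJSON(paste0(path, ".params.json"))
  expect_equal(truth$truth[truth$term == "body~brain"], -0.41)
})

test_that("the misspecification fixture injects the requested standardized cross-loading", {
  p <- cohort_params(cross_loading = list(latent = "body", indicator = "cerebellum",
                                          standardized = 0.5))
  expect_true("body=~cerebellum" %in% names(p$loadings))
  sys <- latentiv:::system_matrices(p)
  mm <- latentiv:::moments_from_system(sys)
  raw <- p$loadings[["body=~cerebellum"]]
  std <- raw * sqrt(mm$cov_all["body", "body"]) / sqrt(mm$cov_all["cerebellum", "cerebellum"])
  expect_equal(std, 0.5, tolerance = 1e-6)
})
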