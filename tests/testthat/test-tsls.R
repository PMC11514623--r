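# small helper: hand-built miiv_set with a forced instrument list
forced_set <- function(eq, selected) {
  structure(list(equation = eq, eligible = selected, selected = selected,
                 trace = NULL, warnings = character()), class = "miiv_set")
}

test_that("an exact linear relation is recovered with zero residual variance", {
  spec <- parse_model("y ~ x")
  sys <- miiv_transform(spec)
  d <- data.frame(x = 1:6, y = 2 * (1:6))
  mom <- compute_moments(d, "complete")
  est <- fit_2sls_equation(sys, "y", forced_set("y", "x"), mom)
  expect_equal(unname(est$coefficients), c(0, 2), tolerance = 1e-12)
  expect_equal(est$residual_variance, 0, tolerance = 1e-12)
})

test_that("instruments identical to regressors reproduce OLS exactly", {
  set.seed(5)
  n <- 120
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 1 + 0.7 * d$x1 - 1.2 * d$x2 + rnorm(n)
  spec <- parse_model("y ~ x1 + x2")
  sys <- miiv_transform(spec)
  mom <- compute_moments(d, "complete")
  est <- fit_2sls_equation(sys, "y", forced_set("y", c("x1", "x2")), mom)
  ols <- stats::coef(stats::lm(y ~ x1 + x2, d))
  expect_equal(unname(est$coefficients), unname(ols), tolerance = 1e-10)
})

test_that("moment-based 2SLS equals the literal stage-wise procedure on a fixed 8-row table", {
  # 1 endogenous regressor, 2 instruments, fixed fixture values
  d <- data.frame(
    z1 = c(0.8, -0.4, 1.3, 0.1, -1.1, 0.6, -0.2, 1.9),
    z2 = c(-0.5, 1.2, 0.3, -0.9, 0.7, -1.4, 0.2, 0.5),
    x  = c(1.1, 0.2, 1.8, -0.6, -1.0, 0.3, -0.1, 2.3),
    y  = c(2.5, 0.7, 3.9, -0.8, -2.2, 1.0, 0.1, 4.8)
  )
  # independent stage-wise oracle via lm()
  stage1 <- stats::lm(x ~ z1 + z2, d)
  stage2 <- stats::lm(d$y ~ stats::fitted(stage1))
  oracle <- unname(stats::coef(stage2))

  spec <- parse_model("L =~ x + z1 + z2\ny ~ L")
  sys <- miiv_transform(spec)
  mom <- compute_moments(d, "complete")
  est <- fit_2sls_equation(sys, "y", forced_set("y", c("z1", "z2")), mom)
  expect_equal(unname(est$coefficients), oracle, tolerance = 1e-8)
  expect_equal(est$sargan$df, 1L)
})

test_that("moment-based estimates equal an observation-level two-stage fit of the cohort model", {
  p <- cohort_params(missing_n = 0)
  d <- simulate_cohort(p, seed = 77)
  f <- fit_miiv_sem(d, bootstrap_B = 0)
  # observation-level oracle for the body equation, on the analysis scale
  da <- latentiv:::apply_rescale(as.data.frame(d), f$plan)
  z <- f$miiv_sets[["organs"]]$selected
  s1 <- stats::lm(stats::as.formula(paste("TIV ~", paste(z, collapse = "+"))), da)
  da$TIV_hat <- stats::fitted(s1)
  s2 <- stats::coef(stats::lm(organs ~ TIV_hat + height, da))
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "body~brain"], unname(s2["TIV_hat"]),
               tolerance = 1e-10)
  expect_equal(td$estimate[td$term == "body~height"], unname(s2["height"]),
               tolerance = 1e-10)
  expect_equal(td$estimate[td$term == "body~1"], unname(s2["(Intercept)"]),
               tolerance = 1e-10)
})

test_that("the Sargan statistic equals n times the residual-on-instruments R-squared", {
  p <- cohort_params(missing_n = 0)
  d <- simulate_cohort(p, seed = 31)
  f <- fit_miiv_sem(d, bootstrap_B = 0)
  da <- latentiv:::apply_rescale(as.data.frame(d), f$plan)
  td <- tidy(f)
  for (eqid in c("organs", "cerebrum")) {
    eq <- f$system[[eqid]]
    b <- td$estimate[match(f$equations[[eqid]]$param_ids, td$term)]
    resid <- da[[eq$outcome]] -
      as.matrix(cbind(1, da[eq$regressors$name])) %*% b
    z <- f$miiv_sets[[eqid]]$selected
    aux <- stats::lm(stats::as.formula(paste("resid ~", paste(z, collapse = "+"))),
                     data = cbind(da, resid = resid))
    r2 <- summary(aux)$r.squared
    sg <- sargan_tests(f)
    expect_equal(sg$stat[sg$equation == eqid], nrow(d) * r2, tolerance = 1e-8)
    expect_equal(sg$df[sg$equation == eqid], 2L)
  }
  # exactly identified equation: undefined p, flagged by df 0
  sg <- sargan_tests(f)
  expect_equal(sg$df[sg$equation == "TIV"], 0L)
  expect_true(is.na(sg$p.value[sg$equation == "TIV"]))
})

test_that("Holm adjustment matches the hand-computed fixture and its properties", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  # undefined entries pass through and shrink the family
  expect_equal(holm_adjust(c(0.01, NA, 0.04, 0.03)),
               c(0.03, NA, 0.06, 0.06))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    h <- holm_adjust(p)
    expect_true(all(h >= p))                        # never below raw p
    expect_true(all(diff(h[order(p)]) >= 0))        # monotone in raw p
    expect_true(all(h <= 1))                        # capped at 1
    expect_equal(h[order(p)], cummax(h[order(p)]))  # running maximum enforced
  }
})

test_that("coefficients transform exactly under data rescaling", {
  p <- cohort_params(n = 300, missing_n = 0)
  d <- simulate_cohort(p, seed = 55)
  base <- tidy(fit_miiv_sem(d, bootstrap_B = 0))
  get <- function(td, term) td$estimate[td$term == term]

  # multiplying a non-scaling indicator by c multiplies its loading and
  # intercept by c and changes nothing else
  c1 <- 3
  d2 <- d; d2$cerebrum <- d2$cerebrum * c1
  td2 <- tidy(fit_miiv_sem(d2, bootstrap_B = 0))
  expect_equal(get(td2, "brain=~cerebrum"), c1 * get(base, "brain=~cerebrum"),
               tolerance = 1e-8)
  expect_equal(get(td2, "cerebrum~1"), c1 * get(base, "cerebrum~1"),
               tolerance = 1e-8)
  for (t in setdiff(base$term, c("brain=~cerebrum", "cerebrum~1"))) {
    expect_equal(get(td2, t), get(base, t), tolerance = 1e-8)
  }

  # multiplying the scaling indicator by c rescales the latent's unit:
  # paths out of the latent divide by c, paths into it multiply by c
  c2 <- 2
  d3 <- d; d3$TIV <- d3$TIV * c2
  td3 <- tidy(fit_miiv_sem(d3, bootstrap_B = 0))
  expect_equal(get(td3, "body~brain"), get(base, "body~brain") / c2, tolerance = 1e-8)
  expect_equal(get(td3, "fat~brain"), get(base, "fat~brain") / c2, tolerance = 1e-8)
  expect_equal(get(td3, "brain~height"), get(base, "brain~height") * c2, tolerance = 1e-8)
  expect_equal(get(td3, "brain~1"), get(base, "brain~1") * c2, tolerance = 1e-8)
  expect_equal(get(td3, "brain=~cerebrum"), get(base, "brain=~cerebrum") / c2,
               tolerance = 1e-8)
  expect_equal(get(td3, "brain=~cerebellum"), get(base, "brain=~cerebellum") / c2,
               tolerance = 1e-8)
  # equations not involving the brain latent are untouched
  expect_equal(get(td3, "body~height"), get(base, "body~height"), tolerance = 1e-8)
  expect_equal(get(td3, "body=~SM"), get(base, "body=~SM"), tolerance = 1e-8)
})

test_that("degenerate inputs are rejected with named errors", {
  d <- simulate_cohort(cohort_params(missing_n = 0), seed = 3)
  d$height <- 161
  expect_error(fit_miiv_sem(d, bootstrap_B = 0), "constant column")
  d2 <- simulate_cohort(cohort_params(missing_n = 0), seed = 3)
  d2$fat <- NULL
  expect_error(fit_miiv_sem(d2, bootstrap_B = 0), "lacks model variables")
})
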