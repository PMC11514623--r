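test_that("latent substitution produces the documented composite disturbances", {
  sys <- miiv_transform(brain_body_model())
  expect_named(sys, c("cerebrum", "cerebellum", "SM", "TIV", "organs", "fat"),
               ignore.order = TRUE)

  # body equation: organs on TIV + height, u = zeta_body + eps_organs - beta*eps_TIV
  body <- sys[["organs"]]
  expect_equal(body$regressors$name, c("TIV", "height"))
  expect_equal(body$regressors$endogenous, c(TIV = TRUE, height = FALSE))
  expect_setequal(body$disturbance$term, c("zeta_body", "eps_organs", "eps_TIV"))
  expect_equal(body$disturbance$coef[body$disturbance$term == "eps_TIV"],
               "-body~brain")

  # measurement equation of cerebrum: substitution of the brain latent
  cer <- sys[["cerebrum"]]
  expect_equal(cer$regressors$name, "TIV")
  expect_true(cer$regressors$endogenous)
  expect_setequal(cer$disturbance$term, c("eps_cerebrum", "eps_TIV"))
  expect_equal(cer$disturbance$coef[cer$disturbance$term == "eps_TIV"],
               "-brain=~cerebrum")

  # no latents: substitution is the identity
  plain <- miiv_transform(parse_model("y ~ x"))
  expect_length(plain, 1)
  expect_equal(plain[["y"]]$disturbance$term, "zeta_y")
  expect_false(plain[["y"]]$regressors$endogenous)
})

test_that("transform conserves the free-parameter count", {
  for (spec in list(brain_body_model(), parse_model("F =~ a + b + c\nF ~ x"))) {
    sys <- miiv_transform(spec)
    n_free_transformed <- sum(vapply(sys, function(e) 1L + nrow(e$regressors),
                                     integer(1)))
    pt <- parameter_table(spec)
    expect_equal(n_free_transformed, sum(pt$status == "free"))
  }
})

test_that("eligible instruments match the structural-zero derivation for the packaged model", {
  sys <- miiv_transform(brain_body_model())
  expect_setequal(eligible_miivs(sys, "organs"),
                  c("height", "cerebrum", "cerebellum", "fat"))
  expect_setequal(eligible_miivs(sys, "cerebrum"),
                  c("height", "cerebellum", "organs", "SM", "fat"))
  expect_setequal(eligible_miivs(sys, "fat"),
                  c("height", "cerebrum", "cerebellum", "organs", "SM"))
  expect_setequal(eligible_miivs(sys, "SM"),
                  c("height", "TIV", "cerebrum", "cerebellum", "fat"))
  # the brain structural equation has only the exogenous covariate available
  expect_equal(eligible_miivs(sys, "TIV"), "height")

  # an exogenous observed regressor is always its own instrument
  plain <- miiv_transform(parse_model("y ~ x"))
  expect_true("x" %in% eligible_miivs(plain, "y"))
})

test_that("declaring an error covariance removes the linked candidate", {
  base <- brain_body_model()
  expect_true("cerebrum" %in% eligible_miivs(miiv_transform(base), "organs"))
  withcov <- parse_model(paste(brain_body_text, "\ncerebrum ~~ organs"))
  expect_false("cerebrum" %in% eligible_miivs(miiv_transform(withcov), "organs"))
  # unrelated candidates are untouched
  expect_true("cerebellum" %in% eligible_miivs(miiv_transform(withcov), "organs"))
})

test_that("eligibility agrees with a numeric brute-force oracle on random models", {
  set.seed(2718)
  n <- 2e5
  agree <- 0L
  trials <- 12L
  for (tr in seq_len(trials)) {
    p <- random_model_params()
    sys <- miiv_transform(p$spec)
    d <- simulate_params(p, n)
    ok <- TRUE
    for (id in names(sys)) {
      eq <- sys[[id]]
      u <- eval_disturbance(eq, d, p)
      elig <- eligible_miivs(sys, id)
      for (v in setdiff(p$spec$observed, eq$outcome)) {
        cv <- stats::cov(d[[v]], u)
        se <- stats::sd(d[[v]]) * stats::sd(u) / sqrt(n)
        numeric_zero <- abs(cv) < 4 * se
        if (numeric_zero != (v %in% elig)) ok <- FALSE
      }
    }
    agree <- agree + ok
  }
  expect_gte(agree, trials - 1L)
})

test_that("non-recursive structural models are rejected", {
  spec <- parse_model("a ~ b\nb ~ a")
  expect_error(miiv_transform(spec), "non-recursive|cyclic")
})

test_that("instrument selection is deterministic and honours the overidentification degree", {
  p <- cohort_params()
  mom <- implied_moments(p)
  sys <- miiv_transform(p$spec)

  s1 <- select_miivs(sys, "cerebrum", mom, overid_degree = 2)
  s2 <- select_miivs(sys, "cerebrum", mom, overid_degree = 2)
  expect_identical(s1$selected, s2$selected)
  expect_length(s1$selected, 3) # 1 regressor + 2
  st <- identification_status(sys, "cerebrum", s1)
  expect_equal(st$status, "overidentified")
  expect_equal(st$df, 2L)

  # eligible set exactly the target size: all selected, trivial trace
  s3 <- select_miivs(sys, "organs", mom, overid_degree = 2)
  expect_setequal(s3$selected, c("height", "cerebrum", "cerebellum", "fat"))
  expect_equal(identification_status(sys, "organs", s3)$df, 2L)

  # insufficient eligible instruments: all selected plus a warning
  s4 <- select_miivs(sys, "organs", mom, overid_degree = 5)
  expect_setequal(s4$selected, c("height", "cerebrum", "cerebellum", "fat"))
  expect_match(s4$warnings, "only 4 eligible")

  # exact and under-identified statuses
  fake_exact <- structure(list(equation = "organs", eligible = character(),
                               selected = c("height", "cerebrum"),
                               trace = NULL, warnings = character()),
                          class = "miiv_set")
  expect_equal(identification_status(sys, "organs", fake_exact)$status, "exact")
  fake_under <- fake_exact; fake_under$selected <- "height"
  expect_equal(identification_status(sys, "organs", fake_under)$status, "under")
})

test_that("greedy selection never prefers a zero-increment candidate (brute-force check)", {
  # variables: endogenous regressor x; candidates c (independent of x) and d
  nm <- c("y", "x", "c", "d")
  S <- diag(4); dimnames(S) <- list(nm, nm)
  S["x", "d"] <- S["d", "x"] <- 0.6
  S["x", "y"] <- S["y", "x"] <- 0.5
  mom <- moment_set(nm, rep(0, 4), S, 100)

  spec <- parse_model("L =~ x + c + d\ny ~ L")
  sys <- miiv_transform(spec)
  sel <- select_miivs(sys, "y", mom, overid_degree = 0,
                      eligible = c("c", "d"))
  # brute force: R2(x ~ d) = 0.36 > R2(x ~ c) = 0
  expect_equal(sel$selected, "d")
  expect_equal(sel$trace$min_r2[1], 0.36, tolerance = 1e-12)
})

test_that("the instrument report serialises per equation", {
  p <- cohort_params()
  mom <- implied_moments(p)
  sys <- miiv_transform(p$spec)
  sets <- lapply(names(sys), function(id) select_miivs(sys, id, mom))
  names(sets) <- names(sys)
  js <- jsonlite::fromJSON(miiv_report_json(sys, sets))
  expect_setequal(names(js), names(sys))
  expect_equal(js$organs$df, 2)
  expect_setequal(js$organs$eligible, c("height", "cerebrum", "cerebellum", "fat"))
})
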