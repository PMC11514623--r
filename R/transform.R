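#' Transform a latent-variable model to observed-variable equations
#'
#' Implements the latent-to-observed substitution at the heart of the
#' MIIV approach: every latent variable is replaced by its scaling indicator
#' minus that indicator's error term. Intercepts and factor loadings are
#' conserved. Each non-scaling measurement equation and each structural
#' equation becomes a regression among observed variables whose error is a
#' composite disturbance -- a signed combination of the equation's own
#' error/disturbance and the substituted scaling-indicator errors.
#'
#' @param spec A valid `miiv_model` (see [validate_spec()]).
#' @return An object of class `miiv_system`: a list of transformed
#'   equations. Each equation is a list with elements `id` (outcome name),
#'   `outcome`, `type` (`"measurement"` or `"structural"`), `regressors`
#'   (tibble: name, endogenous flag, parameter id), `intercept_id`, and
#'   `disturbance` (tibble: error term, coefficient expression as a string).
#' @examples
#' spec <- parse_model("brain =~ TIV + cerebrum\nbrain ~ height")
#' sys <- miiv_transform(spec)
#' sys[["cerebrum"]]$disturbance
#' @export
miiv_transform <- function(spec) {
  diags <- validate_spec(spec)
  if (length(diags)) stop("invalid model: ", paste(diags, collapse = "; "), call. = FALSE)

  scaling <- scaling_indicators(spec)
  red <- reduced_errors(spec)
  eqs <- list()

  # non-scaling measurement equations: y = alpha + sum_L lambda * s(L) + [eps_y - sum lambda*eps_s(L)]
  meas <- spec$measurement
  for (ind in unique(meas$indicator[!meas$scaling])) {
    rows <- meas[meas$indicator == ind, ]
    if (any(rows$scaling)) next # scaling for one latent: substituted away, no own equation
    dist <- tibble::tibble(term = paste0("eps_", ind), coef = "1")
    regs <- character(); pids <- character()
    for (j in seq_len(nrow(rows))) {
      L <- rows$latent[j]; s <- scaling[[L]]
      regs <- c(regs, s); pids <- c(pids, rows$loading_id[j])
      dist <- dplyr::bind_rows(dist, tibble::tibble(
        term = paste0("eps_", s), coef = paste0("-", rows$loading_id[j])))
    }
    eqs[[ind]] <- list(
      id = ind, outcome = ind, type = "measurement",
      regressors = tibble::tibble(name = regs, param_id = pids),
      intercept_id = paste0(ind, "~1"),
      disturbance = dist
    )
  }

  # structural equations: substitute latents on both sides
  for (o in spec$structural_meta$outcome) {
    meta <- spec$structural_meta[spec$structural_meta$outcome == o, ]
    preds <- spec$structural[spec$structural$outcome == o, ]
    if (o %in% spec$latents) {
      lhs <- scaling[[o]]
      dist <- tibble::tibble(
        term = c(meta$disturbance, paste0("eps_", lhs)), coef = c("1", "1"))
    } else {
      lhs <- o
      dist <- tibble::tibble(term = meta$disturbance, coef = "1")
    }
    regs <- character(); pids <- character()
    for (j in seq_len(nrow(preds))) {
      p <- preds$predictor[j]
      if (p %in% spec$latents) {
        s <- scaling[[p]]
        regs <- c(regs, s); pids <- c(pids, preds$path_id[j])
        dist <- dplyr::bind_rows(dist, tibble::tibble(
          term = paste0("eps_", s), coef = paste0("-", preds$path_id[j])))
      } else {
        regs <- c(regs, p); pids <- c(pids, preds$path_id[j])
      }
    }
    eqs[[lhs]] <- list(
      id = lhs, outcome = lhs,
      type = "structural",
      regressors = tibble::tibble(name = regs, param_id = pids),
      intercept_id = meta$intercept_id,
      disturbance = dist
    )
  }

  # endogeneity: a regressor is endogenous iff its reduced-form error set
  # intersects the equation's composite disturbance (error covariances count)
  for (id in names(eqs)) {
    eq <- eqs[[id]]
    dset <- expand_error_set(spec, eq$disturbance$term)
    eq$regressors$endogenous <- vapply(eq$regressors$name, function(v) {
      length(intersect(red[[v]], dset)) > 0L
    }, logical(1))
    eqs[[id]] <- eq
  }

  structure(eqs, class = "miiv_system", spec = spec)
}

# scaling indicator of each latent, as a named list
scaling_indicators <- function(spec) {
  m <- spec$measurement[spec$measurement$scaling, ]
  stats::setNames(as.list(m$indicator), m$latent)
}

# Reduced-form error sets: for every variable (latent and observed), the set
# of epsilon/zeta error-term ids appearing in its expansion into exogenous
# sources and errors, obtained by iterative substitution of structural and
# measurement equations. Exogenous observed variables expand to the empty
# set. Cyclic (non-recursive) structural dependencies are an error.
reduced_errors <- function(spec) {
  memo <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv()) # visiting flags for cycle detection
  st <- spec$structural
  meas <- spec$measurement
  struct_out <- unique(spec$structural_meta$outcome)

  expand <- function(v) {
    if (!is.null(memo[[v]])) return(memo[[v]])
    if (isTRUE(state[[v]])) {
      stop("non-recursive (cyclic) structural model is not supported", call. = FALSE)
    }
    state[[v]] <- TRUE
    if (v %in% spec$latents) {
      if (v %in% struct_out) {
        preds <- st$predictor[st$outcome == v]
        e <- unique(c(unlist(lapply(preds, expand)), paste0("zeta_", v)))
      } else {
        e <- paste0("zeta_", v) # exogenous latent: its disturbance is its source
      }
    } else if (v %in% meas$indicator) {
      Ls <- meas$latent[meas$indicator == v]
      e <- unique(c(unlist(lapply(Ls, expand)), paste0("eps_", v)))
    } else if (v %in% struct_out) {
      preds <- st$predictor[st$outcome == v]
      e <- unique(c(unlist(lapply(preds, expand)), paste0("zeta_", v)))
    } else {
      e <- character() # exogenous observed source
    }
    state[[v]] <- FALSE
    memo[[v]] <- e
    e
  }
  out <- lapply(c(spec$latents, spec$observed), expand)
  stats::setNames(out, c(spec$latents, spec$observed))
}

# map a declared variable-level error covariance a ~~ b to error-term ids
error_term_of <- function(spec, v) {
  if (v %in% spec$measurement$indicator) return(paste0("eps_", v))
  if (v %in% spec$structural_meta$outcome || v %in% spec$latents) {
    return(paste0("zeta_", v))
  }
  paste0("delta_", v) # exogenous observed; never appears in disturbances
}

# augment a set of error terms with declared covariance partners
expand_error_set <- function(spec, terms) {
  ec <- spec$error_covs
  if (!nrow(ec)) return(unique(terms))
  a <- vapply(ec$a, function(v) error_term_of(spec, v), "")
  b <- vapply(ec$b, function(v) error_term_of(spec, v), "")
  out <- unique(terms)
  repeat {
    add <- c(b[a %in% out], a[b %in% out])
    add <- setdiff(add, out)
    if (!length(add)) break
    out <- c(out, add)
  }
  out
}

#' Eligible model-implied instruments for an equation
#'
#' An observed variable is an eligible instrument for a transformed equation
#' when its model-implied covariance with the equation's composite
#' disturbance is structurally zero. Eligibility is decided symbolically:
#' each observed variable is expanded (by iterative substitution of the
#' model's structural and measurement equations) into a combination of
#' exogenous sources and error terms, and a candidate qualifies when its
#' expansion shares no error term -- directly or through a declared error
#' covariance -- with the composite disturbance. The equation's outcome is
#' never eligible.
#'
#' @param system A `miiv_system` from [miiv_transform()].
#' @param eq Equation id (the outcome name of a transformed equation).
#' @return Character vector of eligible observed variable names, in model
#'   registry order.
#' @export
eligible_miivs <- function(system, eq) {
  stopifnot(inherits(system, "miiv_system"))
  spec <- attr(system, "spec")
  equation <- system[[eq]]
  if (is.null(equation)) stop("unknown equation id '", eq, "'", call. = FALSE)
  red <- reduced_errors(spec)
  dset <- expand_error_set(spec, equation$disturbance$term)
  cands <- setdiff(spec$observed, equation$outcome)
  keep <- vapply(cands, function(v) {
    vset <- expand_error_set(spec, red[[v]])
    length(intersect(vset, dset)) == 0L
  }, logical(1))
  cands[keep]
}

#' Select instruments by first-stage R-squared
#'
#' Chooses the estimation set of instruments for one equation. Exogenous
#' regressors always instrument themselves. Remaining instruments are added
#' by greedy forward selection from the eligible set: at each step the
#' candidate that maximises the minimum first-stage R-squared increment
#' across the equation's endogenous regressors is added (ties broken by
#' model registry order), until the number of instruments equals the number
#' of regressors plus `overid_degree`. If too few eligible instruments
#' exist, all are selected and a warning is recorded.
#'
#' @param system A `miiv_system`.
#' @param eq Equation id.
#' @param moments A `moment_set` covering the observed variables (see
#'   [compute_moments()]).
#' @param overid_degree Non-negative integer: number of instruments beyond
#'   the number needed for exact identification (default 2).
#' @param eligible Optional character vector overriding [eligible_miivs()].
#' @return A list of class `miiv_set` with elements `equation`, `eligible`,
#'   `selected`, `trace` (tibble logging each greedy step) and `warnings`.
#' @export
select_miivs <- function(system, eq, moments, overid_degree = 2L, eligible = NULL) {
  stopifnot(inherits(system, "miiv_system"), overid_degree >= 0)
  equation <- system[[eq]]
  if (is.null(equation)) stop("unknown equation id '", eq, "'", call. = FALSE)
  if (is.null(eligible)) eligible <- eligible_miivs(system, eq)

  regs <- equation$regressors
  endo <- regs$name[regs$endogenous]
  exo <- regs$name[!regs$endogenous]
  target <- nrow(regs) + as.integer(overid_degree)

  selected <- exo # exogenous regressors are their own instruments
  warnings <- character()
  trace <- tibble::tibble(step = integer(), candidate = character(),
                          min_r2 = numeric())

  if (!length(endo)) {
    # no endogeneity: the equation is its own instrument set (OLS)
    return(structure(list(equation = eq, eligible = eligible, selected = exo,
                          trace = trace, warnings = warnings),
                     class = "miiv_set"))
  }

  candidates <- setdiff(eligible, selected)
  S <- moments$cov
  missing_vars <- setdiff(c(endo, exo, candidates), moments$names)
  if (length(missing_vars)) {
    stop("moments do not cover: ", paste(missing_vars, collapse = ", "), call. = FALSE)
  }

  r2 <- function(x, z) {
    if (!length(z)) return(0)
    Szz <- S[z, z, drop = FALSE]
    Szx <- S[z, x]
    drop(crossprod(Szx, solve(Szz, Szx))) / S[x, x]
  }

  step <- 0L
  while (length(selected) < target && length(candidates)) {
    step <- step + 1L
    # minimum R^2 across endogenous first stages, per candidate
    score <- vapply(candidates, function(cand) {
      min(vapply(endo, function(x) r2(x, c(selected, cand)), numeric(1)))
    }, numeric(1))
    best <- candidates[which.max(score)] # which.max: first max wins = registry order
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step, candidate = best, min_r2 = max(score)))
    selected <- c(selected, best)
    candidates <- setdiff(candidates, best)
  }

  if (length(selected) < target) {
    warnings <- c(warnings, sprintf(
      "equation '%s': only %d eligible instruments for target %d; all selected",
      eq, length(selected), target))
  }
  if (length(selected) < nrow(regs)) {
    stop("equation '", eq, "' is under-identified: ", length(selected),
         " instruments for ", nrow(regs), " regressors", call. = FALSE)
  }
  structure(list(equation = eq, eligible = eligible, selected = selected,
                 trace = trace, warnings = warnings),
            class = "miiv_set")
}

#' Identification status of an equation
#'
#' @param system A `miiv_system`.
#' @param eq Equation id.
#' @param miivs A `miiv_set` for that equation.
#' @return A list with `status` (`"under"`, `"exact"`, `"overidentified"`)
#'   and `df` (instruments minus regressors; NA when under-identified).
#' @export
identification_status <- function(system, eq, miivs) {
  equation <- system[[eq]]
  df <- length(miivs$selected) - nrow(equation$regressors)
  status <- if (df < 0L) "under" else if (df == 0L) "exact" else "overidentified"
  list(status = status, df = if (df < 0L) NA_integer_ else as.integer(df))
}

#' @export
print.miiv_system <- function(x, ...) {
  cat("MIIV transformed system:", length(x), "equations\n")
  for (eq in x) {
    dist <- paste0(ifelse(eq$disturbance$coef == "1", "",
                          paste0("(", eq$disturbance$coef, ")*")),
                   eq$disturbance$term, collapse = " + ")
    cat(sprintf("  %s ~ %s   [u = %s]\n", eq$outcome,
                paste(eq$regressors$name, collapse = " + "), dist))
  }
  invisible(x)
}

#' Serialise the instrument search to JSON
#'
#' @param system A `miiv_system`.
#' @param miiv_sets Named list of `miiv_set` objects (one per equation).
#' @return A JSON string: per equation the outcome, regressors, eligible and
#'   selected instruments, identification df and the selection trace.
#' @export
miiv_report_json <- function(system, miiv_sets) {
  out <- lapply(names(miiv_sets), function(id) {
    eq <- system[[id]]; ms <- miiv_sets[[id]]
    idst <- identification_status(system, id, ms)
    list(outcome = eq$outcome,
         regressors = eq$regressors$name,
         endogenous = eq$regressors$name[eq$regressors$endogenous],
         eligible = ms$eligible,
         selected = ms$selected,
         df = idst$df, status = idst$status,
         trace = ms$trace)
  })
  names(out) <- names(miiv_sets)
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
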