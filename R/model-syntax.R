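#' Parse a latent-variable model specification
#'
#' Reads a compact model syntax, one statement per line:
#'
#' * `L =~ a + b + c` declares latent variable `L` measured by indicators
#'   `a`, `b`, `c`. The first indicator listed is the scaling indicator: its
#'   loading is fixed to 1 and its intercept to 0, which gives the latent the
#'   unit (and mean) of that indicator.
#' * `y ~ x1 + x2` declares a structural equation for outcome `y` (a latent
#'   or an observed variable) with a free intercept, free path coefficients
#'   and a disturbance term.
#' * `a ~~ b` declares that the error terms of `a` and `b` are correlated
#'   (errors are otherwise assumed mutually uncorrelated).
#' * `#` begins a comment. A directive comment of the form
#'   `#| rescale: TIV = 100, organs = 10` records the divisors applied to
#'   columns before estimation; it is stored in the `rescale` attribute of
#'   the returned model.
#'
#' Names appearing on the left of `=~` are latent; all other names are
#' observed. A name that appears only as a predictor (for example a height
#' covariate) is an exogenous observed variable.
#'
#' @param text A single string (possibly multi-line) or character vector of
#'   lines in the model grammar.
#' @return An object of class `miiv_model`: a list with elements `latents`,
#'   `observed` (registry in order of first appearance), `measurement`
#'   (tibble: latent, indicator, scaling flag, parameter ids), `structural`
#'   (tibble: outcome, predictor, parameter id), `structural_meta` (tibble:
#'   outcome, intercept id, disturbance id), and `error_covs` (tibble of
#'   correlated error-term pairs).
#' @examples
#' m <- parse_model("
#'   brain =~ TIV + cerebrum + cerebellum
#'   body  =~ organs + SM
#'   brain ~ height
#'   body  ~ brain + height
#'   fat   ~ brain + height
#' ")
#' m
#' @seealso [validate_spec()], [miiv_transform()], [fit_miiv_sem()]
#' @export
parse_model <- function(text) {
  stopifnot(is.character(text))
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))

  rescale <- NULL
  directive <- grepl("^\\s*#\\|\\s*rescale\\s*:", lines)
  if (any(directive)) {
    body <- sub("^\\s*#\\|\\s*rescale\\s*:", "", lines[which(directive)[1L]])
    parts <- strsplit(body, ",", fixed = TRUE)[[1L]]
    kv <- lapply(parts, function(p) {
      m <- regmatches(p, regexec("^\\s*([A-Za-z][A-Za-z0-9_.]*)\\s*=\\s*([0-9.eE+-]+)\\s*$", p))[[1L]]
      if (length(m) != 3L) stop("malformed rescale directive: ", trimws(p), call. = FALSE)
      stats::setNames(as.numeric(m[3L]), m[2L])
    })
    rescale <- unlist(kv)
  }

  # strip comments, keep line numbers for error messages
  stripped <- sub("#.*$", "", lines)
  stripped <- trimws(stripped)
  keep <- nzchar(stripped)
  if (!any(keep)) stop("no statements in model text", call. = FALSE)
  stmts <- stripped[keep]
  lineno <- which(keep)

  name_rx <- "[A-Za-z][A-Za-z0-9_.]*"
  split_terms <- function(rhs, ln) {
    terms <- trimws(strsplit(rhs, "+", fixed = TRUE)[[1L]])
    if (!length(terms) || any(!nzchar(terms)) ||
        any(!grepl(paste0("^", name_rx, "$"), terms))) {
      stop("syntax error on line ", ln, ": malformed right-hand side", call. = FALSE)
    }
    terms
  }

  meas <- list()
  struct <- list()
  ecov <- list()
  registry <- character() # observed names in order of first appearance
  note <- function(v) {
    new <- setdiff(v, registry)
    if (length(new)) registry <<- c(registry, new)
  }

  for (i in seq_along(stmts)) {
    s <- stmts[i]; ln <- lineno[i]
    if (grepl("=~", s, fixed = TRUE)) {
      parts <- strsplit(s, "=~", fixed = TRUE)[[1L]]
      if (length(parts) != 2L) stop("syntax error on line ", ln, call. = FALSE)
      lhs <- trimws(parts[1L])
      if (!grepl(paste0("^", name_rx, "$"), lhs)) {
        stop("syntax error on line ", ln, ": bad latent name '", lhs, "'", call. = FALSE)
      }
      inds <- split_terms(parts[2L], ln)
      if (lhs %in% vapply(meas, `[[`, "", "latent")) {
        stop("latent '", lhs, "' defined twice (line ", ln, ")", call. = FALSE)
      }
      if (anyDuplicated(inds)) {
        stop("duplicate indicator in measurement equation on line ", ln, call. = FALSE)
      }
      meas[[length(meas) + 1L]] <- list(latent = lhs, indicators = inds)
      note(inds)
    } else if (grepl("~~", s, fixed = TRUE)) {
      parts <- trimws(strsplit(s, "~~", fixed = TRUE)[[1L]])
      if (length(parts) != 2L ||
          any(!grepl(paste0("^", name_rx, "$"), parts))) {
        stop("syntax error on line ", ln, call. = FALSE)
      }
      ecov[[length(ecov) + 1L]] <- list(a = parts[1L], b = parts[2L], line = ln)
    } else if (grepl("~", s, fixed = TRUE)) {
      parts <- strsplit(s, "~", fixed = TRUE)[[1L]]
      if (length(parts) != 2L) stop("syntax error on line ", ln, call. = FALSE)
      lhs <- trimws(parts[1L])
      if (!grepl(paste0("^", name_rx, "$"), lhs)) {
        stop("syntax error on line ", ln, ": bad outcome name '", lhs, "'", call. = FALSE)
      }
      preds <- split_terms(parts[2L], ln)
      if (lhs %in% vapply(struct, `[[`, "", "outcome")) {
        stop("outcome '", lhs, "' defined twice (line ", ln, ")", call. = FALSE)
      }
      if (anyDuplicated(preds)) {
        stop("duplicate predictor in equation for '", lhs, "' (line ", ln, ")", call. = FALSE)
      }
      struct[[length(struct) + 1L]] <- list(outcome = lhs, predictors = preds)
    } else {
      stop("syntax error on line ", ln, ": unrecognised statement '", s, "'", call. = FALSE)
    }
  }

  latents <- vapply(meas, `[[`, "", "latent")
  # names referenced in structural equations that are not latent are observed
  for (eq in struct) note(setdiff(c(eq$outcome, eq$predictors), latents))
  observed <- setdiff(registry, latents)

  measurement <- dplyr::bind_rows(
    tibble::tibble(latent = character(), indicator = character(),
                   scaling = logical()),
    purrr::map_dfr(meas, function(m) {
      tibble::tibble(
        latent = m$latent,
        indicator = m$indicators,
        scaling = seq_along(m$indicators) == 1L
      )
    })
  )
  measurement$loading_id <- paste0(measurement$latent, "=~", measurement$indicator)
  measurement$intercept_id <- paste0(measurement$indicator, "~1")
  measurement$error <- paste0("eps_", measurement$indicator)

  structural <- dplyr::bind_rows(
    tibble::tibble(outcome = character(), predictor = character(),
                   path_id = character()),
    purrr::map_dfr(struct, function(eq) {
      tibble::tibble(outcome = eq$outcome, predictor = eq$predictors,
                     path_id = paste0(eq$outcome, "~", eq$predictors))
    })
  )
  structural_meta <- dplyr::bind_rows(
    tibble::tibble(outcome = character(), intercept_id = character(),
                   disturbance = character()),
    purrr::map_dfr(struct, function(eq) {
      tibble::tibble(outcome = eq$outcome,
                     intercept_id = paste0(eq$outcome, "~1"),
                     disturbance = paste0("zeta_", eq$outcome))
    })
  )

  all_names <- c(latents, observed)
  for (ec in ecov) {
    bad <- setdiff(c(ec$a, ec$b), all_names)
    if (length(bad)) {
      stop("unknown name in '~~' on line ", ec$line, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  error_covs <- if (length(ecov)) {
    purrr::map_dfr(ecov, function(ec) tibble::tibble(a = ec$a, b = ec$b))
  } else {
    tibble::tibble(a = character(), b = character())
  }

  spec <- structure(
    list(latents = latents, observed = observed,
         measurement = measurement, structural = structural,
         structural_meta = structural_meta, error_covs = error_covs),
    class = "miiv_model", rescale = rescale
  )
  diags <- validate_spec(spec)
  if (length(diags)) {
    stop("invalid model: ", paste(diags, collapse = "; "), call. = FALSE)
  }
  spec
}

#' Validate a parsed model
#'
#' Checks the structural invariants of a `miiv_model` and returns
#' human-readable diagnostics instead of raising errors, so that manually
#' altered model objects can be inspected.
#'
#' @param spec A `miiv_model` object.
#' @return A character vector of diagnostics; empty when all invariants hold.
#' @export
validate_spec <- function(spec) {
  stopifnot(inherits(spec, "miiv_model"))
  out <- character()
  meas <- spec$measurement
  for (L in spec$latents) {
    rows <- meas[meas$latent == L, ]
    if (nrow(rows) == 0L) {
      out <- c(out, sprintf("latent '%s' has no indicators", L))
      next
    }
    ns <- sum(rows$scaling)
    if (ns == 0L) out <- c(out, sprintf("latent '%s' lacks scaling indicator", L))
    if (ns > 1L) out <- c(out, sprintf("latent '%s' has multiple scaling indicators", L))
  }
  if (anyDuplicated(meas[c("latent", "indicator")])) {
    out <- c(out, "duplicate measurement equations")
  }
  known <- c(spec$latents, spec$observed)
  st <- spec$structural
  unknown <- setdiff(unique(c(st$outcome, st$predictor)), known)
  if (length(unknown)) {
    out <- c(out, sprintf("unknown name in structural equation: %s",
                          paste(unknown, collapse = ", ")))
  }
  for (o in unique(st$outcome)) {
    preds <- st$predictor[st$outcome == o]
    if (o %in% preds) out <- c(out, sprintf("outcome '%s' predicts itself", o))
    if (anyDuplicated(preds)) out <- c(out, sprintf("duplicate predictors for '%s'", o))
  }
  if (anyDuplicated(spec$structural_meta$outcome)) {
    out <- c(out, "outcome defined in more than one structural equation")
  }
  if (nrow(spec$error_covs)) {
    bad <- setdiff(unique(c(spec$error_covs$a, spec$error_covs$b)), known)
    if (length(bad)) {
      out <- c(out, sprintf("unknown name in error covariance: %s",
                            paste(bad, collapse = ", ")))
    }
  }
  out
}

#' Parameter table of a model
#'
#' Enumerates every parameter of the model with its kind and status. Scaling
#' indicators carry a loading fixed to 1 and an intercept fixed to 0; all
#' other loadings, paths and intercepts are free.
#'
#' @param spec A `miiv_model`.
#' @return A tibble with columns `id`, `kind` (`"loading"`, `"path"`,
#'   `"intercept"`), `status` (`"fixed"`/`"free"`) and `value` (NA if free).
#' @export
parameter_table <- function(spec) {
  stopifnot(inherits(spec, "miiv_model"))
  meas <- spec$measurement
  loadings <- tibble::tibble(
    id = meas$loading_id, kind = "loading",
    status = ifelse(meas$scaling, "fixed", "free"),
    value = ifelse(meas$scaling, 1, NA_real_)
  )
  intercepts_meas <- tibble::tibble(
    id = meas$intercept_id, kind = "intercept",
    status = ifelse(meas$scaling, "fixed", "free"),
    value = ifelse(meas$scaling, 0, NA_real_)
  )
  paths <- tibble::tibble(
    id = spec$structural$path_id, kind = "path", status = "free", value = NA_real_
  )
  intercepts_struct <- tibble::tibble(
    id = spec$structural_meta$intercept_id, kind = "intercept",
    status = "free", value = NA_real_
  )
  out <- dplyr::bind_rows(loadings, intercepts_meas, paths, intercepts_struct)
  stopifnot(!anyDuplicated(out$id))
  out
}

#' Serialise a model back to its text grammar
#'
#' @param x A `miiv_model`.
#' @param ... Unused.
#' @return A single string in the model grammar; re-parsing it yields an
#'   identical model.
#' @export
format.miiv_model <- function(x, ...) {
  lines <- character()
  rs <- attr(x, "rescale")
  if (!is.null(rs)) {
    lines <- c(lines, paste0("#| rescale: ",
                             paste(names(rs), "=", rs, collapse = ", ")))
  }
  for (L in x$latents) {
    inds <- x$measurement$indicator[x$measurement$latent == L]
    lines <- c(lines, paste(L, "=~", paste(inds, collapse = " + ")))
  }
  for (o in x$structural_meta$outcome) {
    preds <- x$structural$predictor[x$structural$outcome == o]
    lines <- c(lines, paste(o, "~", paste(preds, collapse = " + ")))
  }
  if (nrow(x$error_covs)) {
    lines <- c(lines, paste(x$error_covs$a, "~~", x$error_covs$b))
  }
  paste(lines, collapse = "\n")
}

#' @export
print.miiv_model <- function(x, ...) {
  cat("Latent-variable model (", length(x$latents), " latent, ",
      length(x$observed), " observed)\n", sep = "")
  cat(format(x), "\n")
  invisible(x)
}

#' Build a rescaling plan
#'
#' Records per-variable divisors applied to data columns before estimation to
#' reduce disparities in variance among indicators (for example dividing
#' volumes in cm^3 by 10 or 100). The inverse transform is used to report
#' coefficients back on the original scale.
#'
#' @param spec A `miiv_model`.
#' @param factors Named numeric vector of positive divisors; names must be
#'   observed variables of the model. An empty vector yields the identity
#'   plan.
#' @return A tibble of class `rescale_plan` with columns `variable` and
#'   `divisor`, covering every observed variable (divisor 1 where
#'   unspecified).
#' @export
rescale_plan <- function(spec, factors = numeric()) {
  stopifnot(inherits(spec, "miiv_model"))
  factors <- unlist(factors)
  if (length(factors)) {
    if (is.null(names(factors)) || any(!nzchar(names(factors)))) {
      stop("rescale factors must be named", call. = FALSE)
    }
    unknown <- setdiff(names(factors), spec$observed)
    if (length(unknown)) {
      stop("unknown variable in rescale factors: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (any(!is.finite(factors)) || any(factors <= 0)) {
      stop("rescale factors must be positive and finite", call. = FALSE)
    }
  }
  div <- stats::setNames(rep(1, length(spec$observed)), spec$observed)
  div[names(factors)] <- factors
  structure(tibble::tibble(variable = names(div), divisor = unname(div)),
            class = c("rescale_plan", "tbl_df", "tbl", "data.frame"))
}

# divide data columns by plan divisors (analysis scale)
apply_rescale <- function(data, plan) {
  for (i in seq_len(nrow(plan))) {
    v <- plan$variable[i]
    if (plan$divisor[i] != 1 && v %in% names(data)) {
      data[[v]] <- data[[v]] / plan$divisor[i]
    }
  }
  data
}

# named divisor lookup with default 1
plan_divisor <- function(plan, vars) {
  d <- stats::setNames(plan$divisor, plan$variable)[vars]
  d[is.na(d)] <- 1
  stats::setNames(as.numeric(d), vars)
}
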