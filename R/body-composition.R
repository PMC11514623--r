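#' Four-component model coefficients
#'
#' Weights of the linear four-component (4C) fat-mass equation. The shipped
#' defaults are transcribed from Fuller et al. (1992, Clinical Science 82,
#' 687-693), the standard reference for the 4C model:
#' \deqn{FM = 2.747\,BV - 0.710\,TBW + 1.460\,BMC - 2.050\,Wt}
#' They are a configuration object, not a constant: studies using a
#' different calibration can supply their own weights.
#'
#' @param bv,tbw,bmc,wt Signed weights on body volume (l), total body water
#'   (l), bone mineral content (kg) and body weight (kg).
#' @return A named numeric vector of class `fourc_coefficients`.
#' @export
fourc_coefficients <- function(bv = 2.747, tbw = -0.710, bmc = 1.460, wt = -2.050) {
  out <- c(bv = bv, tbw = tbw, bmc = bmc, wt = wt)
  if (any(!is.finite(out))) stop("4C coefficients must be finite", call. = FALSE)
  class(out) <- c("fourc_coefficients", "numeric")
  out
}

#' Fat mass from the four-component model
#'
#' Combines body volume, total body water, bone mineral content and body
#' weight into fat mass by the 4C linear equation. Coefficients bind to the
#' named fields, not to argument positions. Vectorised over participants.
#'
#' @param bv Body volume (litres).
#' @param tbw Total body water (litres).
#' @param bmc Bone mineral content (kg).
#' @param wt Body weight (kg).
#' @param coefficients A [fourc_coefficients()] object.
#' @return Fat mass in kg. Negative values are allowed but flagged with a
#'   warning as physiologically implausible.
#' @examples
#' fat_mass_4c(bv = 55, tbw = 30, bmc = 2.5, wt = 57.8)
#' @export
fat_mass_4c <- function(bv, tbw, bmc, wt, coefficients = fourc_coefficients()) {
  args <- list(bv = bv, tbw = tbw, bmc = bmc, wt = wt)
  miss <- names(args)[vapply(args, function(a) is.null(a) || !length(a), logical(1))]
  if (length(miss)) stop("missing field(s): ", paste(miss, collapse = ", "), call. = FALSE)
  co <- unclass(coefficients)
  fm <- co[["bv"]] * bv + co[["tbw"]] * tbw + co[["bmc"]] * bmc + co[["wt"]] * wt
  if (any(fm < 0, na.rm = TRUE)) {
    warning("negative fat mass computed: physiologically implausible inputs")
  }
  fm
}

#' Body mass index
#'
#' @param weight Weight in kg.
#' @param height Height in metres (strictly positive).
#' @return BMI in kg/m^2. Vectorised.
#' @examples
#' bmi(57.8, 1.61) # 22.3
#' @export
bmi <- function(weight, height) {
  if (any(height <= 0, na.rm = TRUE)) stop("height must be positive", call. = FALSE)
  weight / height^2
}

#' Coefficient of variation
#'
#' @param values Numeric vector, at least 2 values, nonzero mean.
#' @param na.rm Drop missing values first.
#' @return 100 * SD / mean (SD with denominator n - 1), in percent.
#' @examples
#' coefficient_of_variation(c(9, 10, 11)) # 10
#' @export
coefficient_of_variation <- function(values, na.rm = FALSE) {
  if (na.rm) values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (!is.finite(m) || m == 0) stop("mean is zero; CV undefined", call. = FALSE)
  100 * stats::sd(values) / m
}
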