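#' BMI category schemes
#'
#' The analysis uses two fixed categorisations of body mass index (kg/m2):
#' eight "fine" bands used as the exposure in regression models
#' (18.5 to <20, 20 to <22.5, ..., >=40), and five "coarse" bands used for
#' population projection (<25, 25-29.9, 30-34.9, 35-39.9, >=40). All bands
#' are half-open `[lower, upper)`; the top band is closed below and
#' unbounded above. The reference fine band is 20 to <22.5.
#'
#' @return `fine_bmi_levels()` and `coarse_bmi_levels()` return the category
#'   labels in increasing BMI order.
#' @export
fine_bmi_levels <- function() {
  c("18.5 to <20", "20 to <22.5", "22.5 to <25", "25 to <27.5",
    "27.5 to <30", "30 to <35", "35 to <40", ">=40")
}

#' @rdname fine_bmi_levels
#' @export
coarse_bmi_levels <- function() {
  c("<25", "25-29.9", "30-34.9", "35-39.9", ">=40")
}

# lower bounds of the fine bands; upper bound of band k is lower bound of k+1
fine_bmi_breaks <- function() c(18.5, 20, 22.5, 25, 27.5, 30, 35, 40, Inf)

#' Fine BMI band reference category (20 to <22.5)
#' @export
reference_fine_level <- function() "20 to <22.5"

# fine bands whose weighted average defines the projection reference (20-24.9)
reference_coarse_members <- function() c("20 to <22.5", "22.5 to <25")

#' Assign fine BMI categories
#'
#' @param bmi numeric vector of BMI values (kg/m2); values below 18.5 are
#'   rejected since the analysis excludes underweight women.
#' @return factor with levels [fine_bmi_levels()].
#' @export
bmi_fine_category <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi < 18.5)) {
    stop("bmi must be finite and >= 18.5 kg/m2", call. = FALSE)
  }
  cut(bmi, breaks = fine_bmi_breaks(), labels = fine_bmi_levels(),
      right = FALSE, include.lowest = TRUE)
}

#' Map fine BMI bands to the coarse projection bands
#'
#' @return data.frame with columns `fine` and `coarse`.
#' @export
fine_to_coarse_map <- function() {
  data.frame(
    fine = fine_bmi_levels(),
    coarse = c("<25", "<25", "<25", "25-29.9", "25-29.9",
               "30-34.9", "35-39.9", ">=40"),
    stringsAsFactors = FALSE
  )
}

# knee of the generative piecewise log-linear BMI-rate relationship: flat
# below 20 kg/m2, log-linear above, matching the trend model's domain
bmi_slope_knee <- function() 20
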