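# Diabetes mediation by the adjusted-model difference method: how much of
# the excess-weight-attributable cost proportion disappears when diabetes
# status is added as a covariate.

#' Carry a diabetes onset forward through the panel
#'
#' A woman has the flag from the annual period in which evidence for
#' diabetes is first encountered and in all subsequent years. An onset
#' before the first follow-up year sets the flag throughout; no onset
#' leaves it false.
#'
#' @param panel person-year table with `person_id` and `year_index`
#' @param onset data.frame with `person_id` and `onset_year` (`NA` = no
#'   onset), or a vector of onset years named by person id
#' @return the panel with `diabetes_flag` (re)computed
#' @export
carry_forward_diabetes <- function(panel, onset) {
  if (is.data.frame(onset)) {
    o <- stats::setNames(onset$onset_year, onset$person_id)
  } else {
    o <- onset
  }
  onset_row <- o[as.character(panel$person_id)]
  panel$diabetes_flag <- !is.na(onset_row) & panel$year_index >= onset_row
  panel
}

#' Proportion of attributable costs explained by a mediator
#'
#' `E = (P_base - P_adj) / P_base` on the >=25 aggregate attributable
#' proportions, where the adjusted model adds the mediator (diabetes
#' status) as a covariate. A secondary decomposition on absolute
#' attributable costs is reported alongside.
#'
#' @param base `projection_result` from the primary model
#' @param adjusted `projection_result` from the model with diabetes status
#'   added
#' @param outcome optional label carried through to the result
#' @return object of class `mediation_result`: list with `p_base`,
#'   `p_adj`, `explained` and `explained_absolute`
#' @export
mediation_proportion <- function(base, adjusted, outcome = NA_character_) {
  get_agg <- function(x, col) x[[col]][x$category == ">=25"]
  p_base <- get_agg(base, "attributable_prop")
  p_adj <- get_agg(adjusted, "attributable_prop")
  if (!length(p_base) || !length(p_adj)) {
    stop("projection results lack the >=25 aggregate row", call. = FALSE)
  }
  if (p_base <= 0) {
    stop("mediation undefined: baseline attributable proportion is <= 0",
         call. = FALSE)
  }
  a_base <- get_agg(base, "attributable_m")
  a_adj <- get_agg(adjusted, "attributable_m")
  structure(list(outcome = outcome, p_base = p_base, p_adj = p_adj,
                 explained = (p_base - p_adj) / p_base,
                 explained_absolute = (a_base - a_adj) / a_base),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(paste0("mediation (%s): attributable proportion %.3f -> %.3f ",
                     "with mediator; explained %.1f%% (absolute-cost basis %.1f%%)\n"),
              x$outcome, x$p_base, x$p_adj, 100 * x$explained,
              100 * x$explained_absolute))
  invisible(x)
}
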