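#' Residual-survival parameters for pre-treatment red blood cells
#'
#' The model assumes that a red blood cell alive on the first day of
#' CDK4/6-inhibitor treatment has a LogNormal residual lifetime: the
#' probability that it is still circulating `t` days later is
#' \eqn{S(t) = 1 - \Phi((\log t - \mu)/\sigma)}, where \eqn{\Phi} is the
#' standard normal CDF. The population mean residual lifespan implied by
#' these parameters is \eqn{\exp(\mu + \sigma^2/2)} days.
#'
#' The defaults encode the 118-day lifespan measured in healthy adults:
#' `mu_survival = log(118) - 0.3^2/2` so that the implied mean is exactly
#' 118 days at the default log-scale spread of 0.3.
#'
#' @param mu_survival Location of the LogNormal residual-survival law, on the
#'   log-days scale.
#' @param sigma_survival Scale (standard deviation) on the log-days scale;
#'   must be strictly positive.
#'
#' @return An object of class `survival_params`: a named list with elements
#'   `mu_survival` and `sigma_survival`.
#' @examples
#' sp <- survival_params()
#' mean_lifespan(sp) # 118
#' @export
survival_params <- function(mu_survival = log(118) - 0.3^2 / 2,
                            sigma_survival = 0.3) {
  stopifnot(is.numeric(mu_survival), length(mu_survival) == 1L, is.finite(mu_survival),
            is.numeric(sigma_survival), length(sigma_survival) == 1L,
            is.finite(sigma_survival))
  if (sigma_survival <= 0) {
    rlang::abort("`sigma_survival` must be > 0.", class = "rbclifespan_domain_error")
  }
  structure(list(mu_survival = mu_survival, sigma_survival = sigma_survival),
            class = "survival_params")
}

#' @export
print.survival_params <- function(x, ...) {
  cat(sprintf(
    "<survival_params> mu = %.4f, sigma = %.4f (mean lifespan %.1f days)\n",
    x$mu_survival, x$sigma_survival, mean_lifespan(x)))
  invisible(x)
}

#' Residual survival fraction of pre-treatment red blood cells
#'
#' Fraction of the red blood cells present at treatment start (day 0) that
#' are still circulating `t` days later, under the LogNormal residual
#' survival law \eqn{S(t) = 1 - \Phi((\log t - \mu)/\sigma)}.
#'
#' Defined only for `t > 0`; use [old_fraction()] for a time axis that
#' extends to the pre-treatment period.
#'
#' @param t Days since the first dose; strictly positive (vectorised).
#' @param params A [survival_params()] object.
#' @return Survival fractions in (0, 1), same length as `t`.
#' @seealso [old_fraction()], [mean_lifespan()]
#' @export
residual_survival <- function(t, params) {
  stopifnot(inherits(params, "survival_params"), is.numeric(t))
  if (any(!is.finite(t)) || any(t <= 0)) {
    rlang::abort("`t` must be finite and > 0; route t <= 0 through `old_fraction()`.",
                 class = "rbclifespan_domain_error")
  }
  stats::pnorm((log(t) - params$mu_survival) / params$sigma_survival,
               lower.tail = FALSE)
}

#' Proportion of "old" (pre-treatment) red blood cells at time t
#'
#' Before the first dose every circulating cell predates treatment, so the
#' old-cell weight is exactly 1 for `t <= 0`; afterwards it decays along the
#' residual survival curve. This weight is the mixing proportion that links
#' the patient-level old/new red-cell indices to the measured blood counts.
#'
#' @inheritParams residual_survival
#' @param t Days relative to the first dose; any real value (vectorised).
#' @return Old-cell fractions in [0, 1], non-increasing in `t`.
#' @export
old_fraction <- function(t, params) {
  stopifnot(inherits(params, "survival_params"), is.numeric(t))
  out <- rep(1, length(t))
  pos <- is.finite(t) & t > 0
  if (any(pos)) out[pos] <- residual_survival(t[pos], params)
  out[!is.finite(t)] <- NA_real_
  out
}

#' Mean lifespan implied by the residual-survival law
#'
#' The mean of a LogNormal(\eqn{\mu}, \eqn{\sigma}) lifetime,
#' \eqn{\exp(\mu + \sigma^2/2)}, in days. This is the headline quantity of
#' the analysis: the mean total lifespan of red blood cells created before
#' treatment.
#'
#' @inheritParams residual_survival
#' @return Mean lifespan in days (scalar, > 0).
#' @export
mean_lifespan <- function(params) {
  stopifnot(inherits(params, "survival_params"))
  exp(params$mu_survival + params$sigma_survival^2 / 2)
}

#' Weighted mixture of old- and new-cell index values
#'
#' A measured red-cell index is the cell-population average of the value in
#' surviving pre-treatment ("old") cells and in on-treatment ("new") cells:
#' `w_old * value_old + (1 - w_old) * value_new`. The result always lies
#' between the two endpoint values.
#'
#' @param w_old Old-cell fraction(s) in [0, 1].
#' @param value_old,value_new Index value in the old and new cell
#'   populations (same units; vectorised with recycling).
#' @return The mixture mean, in the units of the inputs.
#' @export
mixture_mean <- function(w_old, value_old, value_new) {
  stopifnot(is.numeric(w_old), is.numeric(value_old), is.numeric(value_new))
  if (any(!is.finite(w_old)) || any(w_old < 0) || any(w_old > 1)) {
    rlang::abort("`w_old` must lie in [0, 1].", class = "rbclifespan_domain_error")
  }
  w_old * value_old + (1 - w_old) * value_new
}

#' Hemoglobin concentration derived from the red-cell indices
#'
#' Standard hematology identity: Hgb (g/dL) = RBC (10^12/L) x MCV (fL) x
#' MCHC (g/dL) / 1000. The model treats hemoglobin as a derived quantity —
#' only the RBC count, MCV and MCHC enter the likelihood — and computes
#' pre/post hemoglobin posteriors by applying this identity draw by draw to
#' the population means.
#'
#' @param n_rbc RBC count in 10^12 cells/L.
#' @param mcv Mean corpuscular volume in fL.
#' @param mchc Mean corpuscular hemoglobin concentration in g/dL.
#' @return Hemoglobin concentration in g/dL (vectorised).
#' @examples
#' derived_hemoglobin(5.0, 90.0, 33.0) # 14.85
#' @export
derived_hemoglobin <- function(n_rbc, mcv, mchc) {
  stopifnot(is.numeric(n_rbc), is.numeric(mcv), is.numeric(mchc))
  if (any(n_rbc < 0, na.rm = TRUE) || any(mcv < 0, na.rm = TRUE) ||
      any(mchc < 0, na.rm = TRUE)) {
    rlang::abort("red-cell indices must be non-negative.",
                 class = "rbclifespan_domain_error")
  }
  n_rbc * mcv * mchc / 1000
}
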