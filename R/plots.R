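#' Plot MCV trajectories of a synthetic cohort
#'
#' Spaghetti plot of per-patient measured MCV against time, with the
#' population mixture-mean curve implied by the generating parameters
#' overlaid.
#'
#' @param object An `rbc_cohort`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rbc_cohort <- function(object, ...) {
  cfg <- object$config
  tt <- seq(-cfg$baseline_window,
            max(object$observations$t_days), length.out = 200)
  curve <- tibble(
    t_days = tt,
    mcv_fL = mixture_mean(old_fraction(tt, cfg$survival),
                          cfg$population$mu_mcv_old,
                          cfg$population$mu_mcv_new))
  ggplot2::ggplot(object$observations,
                  ggplot2::aes(x = .data$t_days, y = .data$mcv_fL)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient_id),
                       alpha = 0.2, linewidth = 0.3) +
    ggplot2::geom_line(data = curve, colour = "firebrick",
                       linewidth = 1) +
    ggplot2::labs(x = "days since first dose", y = "MCV (fL)",
                  title = "Measured MCV and population mixture-mean curve") +
    ggplot2::theme_minimal()
}

#' Posterior densities by chain for the headline parameters
#'
#' Overlaid per-chain posterior density curves — the visual chain-overlap
#' check — for a selection of population-level parameters.
#'
#' @param object An `rbc_fit`.
#' @param parameters Parameter names to show (default: survival law,
#'   pre/post MCV means and lifespan).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rbc_fit <- function(object,
                             parameters = c("mu_mcv_old", "mu_mcv_new",
                                            "mu_s", "sigma_s", "lifespan"),
                             ...) {
  mats <- lapply(object$samples, as.matrix)
  parameters <- intersect(parameters, colnames(mats[[1]]))
  df <- purrr::imap(mats, function(m, ch) {
    purrr::map(parameters, function(p)
      tibble(chain = factor(ch), parameter = p, value = m[, p])) |>
      dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                   colour = .data$chain)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Plot a posterior predictive check
#'
#' Replicate density curves (thin blue lines), their mean (dashed orange)
#' and the observed-data density (black), in the style of standard
#' Bayesian-workflow PPC density overlays.
#'
#' @param object An `rbc_ppc` from [posterior_predictive()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rbc_ppc <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_line(data = object$curves,
                       ggplot2::aes(y = .data$density, group = .data$rep),
                       colour = "steelblue", alpha = 0.15,
                       linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rep_mean),
                       colour = "darkorange", linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), colour = "black",
                       linewidth = 0.7) +
    ggplot2::labs(x = object$observable, y = "density",
                  title = sprintf("Posterior predictive check: %s",
                                  object$observable)) +
    ggplot2::theme_minimal()
}

#' Plot per-chain rank histograms
#'
#' @param object An `rbc_rank` from [rank_statistics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rbc_rank <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$expected, linetype = "dashed") +
    ggplot2::facet_wrap(~chain, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "pooled-rank bin", y = "count") +
    ggplot2::theme_minimal()
}

#' k-hat diagnostic plot
#'
#' Pareto tail-shape estimates per leave-one-out point, with the 0.7
#' (influential) and 1.0 (severe outlier) reference lines.
#'
#' @param loo An `rbc_loo` from [loo_khat()].
#' @return A ggplot object.
#' @export
plot_khat <- function(loo) {
  stopifnot(inherits(loo, "rbc_loo"))
  ggplot2::ggplot(loo$pointwise,
                  ggplot2::aes(x = .data$point, y = .data$khat)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = c(0.7, 1.0), linetype = "dashed",
                        colour = "steelblue") +
    ggplot2::labs(x = "blood draw", y = expression(hat(k))) +
    ggplot2::theme_minimal()
}
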