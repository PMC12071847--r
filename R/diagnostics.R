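split_rhat_matrix <- function(mat) {
  n <- nrow(mat) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- cbind(mat[seq_len(n), , drop = FALSE],
                  mat[n + seq_len(n), , drop = FALSE])
  mns <- colMeans(halves)
  vrs <- apply(halves, 2, stats::var)
  W <- mean(vrs)
  B <- n * stats::var(mns)
  if (W == 0) return(ifelse(B == 0, 1, Inf))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Split-chain potential scale reduction factor
#'
#' Split-R-hat: each chain is cut in half and the usual between/within
#' variance ratio is computed over the resulting half-chains, which also
#' detects within-chain drift. Values close to 1 (conventionally < 1.01)
#' indicate convergence.
#'
#' @param x A `coda::mcmc.list`, an `rbc_fit`, or a numeric matrix with one
#'   column per chain.
#' @return Named vector of R-hat values (one per parameter), or a scalar
#'   for a matrix input.
#' @export
split_rhat <- function(x) {
  if (inherits(x, "rbc_fit")) x <- x$samples
  if (inherits(x, "mcmc.list")) {
    mats <- lapply(x, as.matrix)
    pars <- colnames(mats[[1]])
    vapply(pars, function(p)
      split_rhat_matrix(sapply(mats, function(m) m[, p])), numeric(1))
  } else {
    split_rhat_matrix(as.matrix(x))
  }
}

#' Per-chain rank histograms and uniformity scores
#'
#' Pools the draws of one parameter across chains, ranks them, and bins
#' each chain's ranks into `n_bins` equal-width bins. If the chains sample
#' the same distribution, every chain's rank histogram is near-uniform; a
#' shifted or stuck chain concentrates its ranks. A chi-square statistic
#' against the uniform expectation is returned per chain.
#'
#' @param x An `rbc_fit`, `coda::mcmc.list`, or numeric matrix with one
#'   column per chain.
#' @param parameter Parameter name (required for fit/mcmc.list input).
#' @param n_bins Number of rank bins (default 20).
#' @return An object of class `rbc_rank`: list with `histogram`
#'   (tibble `chain, bin, count`), `scores` (tibble `chain, statistic, df,
#'   p_value`) and `expected` (expected count per bin).
#' @export
rank_statistics <- function(x, parameter = NULL, n_bins = 20) {
  if (inherits(x, "rbc_fit")) x <- x$samples
  if (inherits(x, "mcmc.list")) {
    if (is.null(parameter)) {
      rlang::abort("`parameter` is required for mcmc.list/fit input.")
    }
    x <- sapply(lapply(x, as.matrix), function(m) m[, parameter])
  }
  x <- as.matrix(x)
  if (ncol(x) < 2L) {
    rlang::abort("rank statistics need at least two chains.",
                 class = "rbclifespan_domain_error")
  }
  n_iter <- nrow(x); n_chain <- ncol(x)
  r <- matrix(rank(as.vector(x), ties.method = "average"), n_iter, n_chain)
  breaks <- seq(0.5, n_iter * n_chain + 0.5, length.out = n_bins + 1)
  expected <- n_iter / n_bins
  hist_tbl <- purrr::map(seq_len(n_chain), function(ch) {
    counts <- as.vector(table(cut(r[, ch], breaks)))
    tibble(chain = ch, bin = seq_len(n_bins), count = counts)
  }) |> dplyr::bind_rows()
  scores <- hist_tbl |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(statistic = sum((.data$count - expected)^2 / expected),
                     .groups = "drop") |>
    dplyr::mutate(df = n_bins - 1,
                  p_value = stats::pchisq(.data$statistic, df = n_bins - 1,
                                          lower.tail = FALSE))
  structure(list(histogram = hist_tbl, scores = scores, expected = expected),
            class = "rbc_rank")
}

#' @export
print.rbc_rank <- function(x, ...) {
  cat("<rbc_rank> chi-square uniformity scores per chain:\n")
  print(as.data.frame(x$scores), row.names = FALSE)
  invisible(x)
}

#' Posterior predictive check for one observable
#'
#' Draws `n_rep` replicate datasets from the fitted generative model
#' (patient-level draws, survival-law weights, Student-t noise with
#' positivity rejection) and summarises each as a kernel density on a
#' common grid, using the rule-of-thumb bandwidth of the observed data for
#' every curve so that observed and replicated densities are comparable.
#'
#' @param fit An `rbc_fit`.
#' @param observable One of `"mcv"`, `"rbc"`, `"mchc"`.
#' @param n_rep Number of replicate datasets (default 100).
#' @param grid_size Density evaluation grid size.
#' @param seed Optional seed for the replicate draws.
#' @return An object of class `rbc_ppc`: list with `observable`, `curves`
#'   (tibble `rep, x, density`), and `summary` (tibble `x, observed,
#'   rep_mean, lower, upper` with a pointwise 95% replicate envelope; the
#'   envelope is `NA` when `n_rep == 1`).
#' @export
posterior_predictive <- function(fit, observable = c("mcv", "rbc", "mchc"),
                                 n_rep = 100, grid_size = 128, seed = NULL) {
  stopifnot(inherits(fit, "rbc_fit"))
  observable <- tryCatch(match.arg(observable), error = function(e)
    rlang::abort(sprintf("unknown observable; valid names: mcv, rbc, mchc"),
                 class = "rbclifespan_domain_error"))
  if (!is.null(seed)) set.seed(seed)
  m <- fit$model; pooled <- fit$pooled
  obs <- switch(observable, mcv = m$data$mcv, rbc = m$data$n,
                mchc = m$data$mchc)
  stubs <- switch(observable,
                  mcv = list(old = "mcv_old", new = "mcv_new",
                             sig = "sigma_mcv", nu = "nu_mcv"),
                  rbc = list(old = "n_old", new = "n_new",
                             sig = "sigma_n", nu = "nu_n"),
                  mchc = list(old = "mchc_old", new = "mchc_new",
                              sig = "sigma_mchc", nu = "nu_mchc"))
  J <- m$data$J; pid <- m$data$pid
  col <- function(stub) paste0(stub, "[", seq_len(m$data$P), "]")
  bw <- stats::bw.nrd0(obs)
  grid <- seq(min(obs) - 3 * bw, max(obs) + 3 * bw, length.out = grid_size)
  dens <- function(y) stats::density(y, bw = bw, from = grid[1],
                                     to = grid[grid_size], n = grid_size)$y
  draw_idx <- sample.int(nrow(pooled), n_rep, replace = n_rep > nrow(pooled))
  curves <- purrr::map(seq_len(n_rep), function(r) {
    s <- draw_idx[r]
    w <- ifelse(m$data$pre == 1, 1,
                stats::pnorm((m$data$logt - pooled[s, "mu_s"]) /
                               pooled[s, "sigma_s"], lower.tail = FALSE))
    loc <- w * pooled[s, col(stubs$old)][pid] +
      (1 - w) * pooled[s, col(stubs$new)][pid]
    y <- rt_ls_positive(J, pooled[s, stubs$nu], loc, pooled[s, stubs$sig])
    tibble(rep = r, x = grid, density = dens(y))
  }) |> dplyr::bind_rows()
  env <- curves |>
    dplyr::group_by(.data$x) |>
    dplyr::summarise(rep_mean = mean(.data$density),
                     lower = if (n_rep > 1)
                       quantile(.data$density, 0.025, names = FALSE)
                     else NA_real_,
                     upper = if (n_rep > 1)
                       quantile(.data$density, 0.975, names = FALSE)
                     else NA_real_,
                     .groups = "drop")
  env$observed <- dens(obs)
  structure(list(observable = observable,
                 curves = curves,
                 summary = env[, c("x", "observed", "rep_mean", "lower",
                                   "upper")]),
            class = "rbc_ppc")
}

#' @export
print.rbc_ppc <- function(x, ...) {
  inside <- mean(x$summary$observed >= x$summary$lower &
                   x$summary$observed <= x$summary$upper)
  cat(sprintf(
    "<rbc_ppc> %s: observed density inside 95%% replicate envelope at %.0f%% of grid points\n",
    x$observable, 100 * inside))
  invisible(x)
}

# --- Pareto-smoothed importance sampling ------------------------------------

# Generalized-Pareto fit to exceedances (Zhang & Stephens 2009 profile
# posterior-mean estimator, with the weakly informative shape adjustment of
# the PSIS reference implementation).
gpd_fit <- function(x, min_grid_pts = 30L) {
  x <- sort.int(x)
  n <- length(x)
  m <- min_grid_pts + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  b_grid <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_of <- vapply(b_grid, function(b) mean(log1p(-b * x)), numeric(1))
  l_prof <- n * (log(-b_grid / k_of) - k_of - 1)
  w <- 1 / vapply(jj, function(i) sum(exp(l_prof - l_prof[i])), numeric(1))
  b_hat <- sum(b_grid * w)
  k_hat <- mean(log1p(-b_hat * x))
  sigma_hat <- -k_hat / b_hat
  k_hat <- (n * k_hat + 10 * 0.5) / (n + 10)
  list(k = k_hat, sigma = sigma_hat)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Smooth one vector of log importance ratios; returns smoothed lw (shifted
# so max = 0 is NOT applied; normalization happens downstream) and khat.
psis_smooth <- function(lw, tail_len) {
  S <- length(lw)
  lw <- lw - max(lw)
  if (tail_len < 5L) return(list(lw = lw, khat = Inf))
  ord <- order(lw)
  tail_ids <- ord[(S - tail_len + 1L):S]
  cutoff <- lw[ord[S - tail_len]]
  x <- exp(lw[tail_ids]) - exp(cutoff)
  if (max(x) <= 0 || length(unique(x)) < 3L) {
    return(list(lw = lw, khat = -Inf))
  }
  fit <- gpd_fit(x)
  if (!is.finite(fit$k)) return(list(lw = lw, khat = Inf))
  p <- (seq_len(tail_len) - 0.5) / tail_len
  smoothed <- log(exp(cutoff) + qgpd(p, fit$k, fit$sigma))
  lw[tail_ids[order(lw[tail_ids])]] <- pmin(smoothed, 0)
  list(lw = lw, khat = fit$k)
}

# Relative MCMC efficiency of the importance ratios for one data point,
# from per-chain effective sample sizes of exp(lw).
relative_eff <- function(w_mat) {
  ess <- sum(apply(w_mat, 2, function(v) {
    if (stats::sd(v) == 0) return(length(v))
    as.numeric(coda::effectiveSize(v))
  }))
  min(1, ess / length(w_mat))
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Computes PSIS-LOO from the stored pointwise log-likelihoods. The
#' leave-one-out unit is one blood draw, with the log-likelihoods of the
#' three observables (RBC count, MCV, MCHC) summed per draw; set
#' `by = "observable"` to treat each observable measurement as its own
#' point. Raw importance ratios are stabilised by fitting a generalized
#' Pareto distribution to their upper tail; the tail-shape estimate k-hat
#' flags influential points (k-hat > 0.7) and severe outliers
#' (k-hat > 1.0).
#'
#' @param fit An `rbc_fit` fitted with `store_loglik = TRUE`.
#' @param by Pointwise unit: `"draw"` (per blood draw, default) or
#'   `"observable"` (per single measurement).
#' @param r_eff Adjust tail length for MCMC autocorrelation of the
#'   importance ratios? (default `TRUE`; slight extra cost).
#' @return An object of class `rbc_loo`: list with `pointwise` (tibble
#'   `point, khat, elpd_i`), `elpd` and `elpd_se`, `p_loo`, `lpd` (in-sample
#'   log pointwise predictive density), and `counts` (points with
#'   k-hat > 0.7 and > 1.0).
#' @export
loo_khat <- function(fit, by = c("draw", "observable"), r_eff = TRUE) {
  stopifnot(inherits(fit, "rbc_fit"))
  by <- match.arg(by)
  if (is.null(fit$pointwise_loglik)) {
    rlang::abort(
      "pointwise log-likelihood not stored; refit with `store_loglik = TRUE`.",
      class = "rbclifespan_domain_error")
  }
  ll <- if (by == "draw") fit$pointwise_loglik
        else do.call(cbind, pointwise_loglik_parts(fit))
  S <- nrow(ll); J <- ncol(ll)
  n_chain <- fit$config$n_chains
  iter <- S %/% n_chain
  khat <- numeric(J); elpd_i <- numeric(J); lpd_i <- numeric(J)
  for (j in seq_len(J)) {
    lw <- -ll[, j]
    reff_j <- if (r_eff)
      relative_eff(matrix(exp(lw - max(lw)), iter, n_chain)) else 1
    tail_len <- ceiling(min(0.2 * S, 3 * sqrt(S / max(reff_j, 1e-6))))
    sm <- psis_smooth(lw, as.integer(tail_len))
    khat[j] <- sm$khat
    elpd_i[j] <- log_sum_exp(sm$lw + ll[, j]) - log_sum_exp(sm$lw)
    lpd_i[j] <- log_sum_exp(ll[, j]) - log(S)
  }
  pointwise <- tibble(point = seq_len(J), khat = khat, elpd_i = elpd_i)
  structure(list(
    pointwise = pointwise,
    elpd = sum(elpd_i), elpd_se = sqrt(J * stats::var(elpd_i)),
    lpd = sum(lpd_i), p_loo = sum(lpd_i) - sum(elpd_i),
    counts = c(khat_gt_0_7 = sum(khat > 0.7), khat_gt_1_0 = sum(khat > 1.0)),
    by = by), class = "rbc_loo")
}

pointwise_loglik_parts <- function(fit) {
  m <- fit$model; pooled <- fit$pooled
  J <- m$data$J; pid <- m$data$pid
  col <- function(stub) paste0(stub, "[", seq_len(m$data$P), "]")
  S <- nrow(pooled)
  W <- stats::pnorm((matrix(m$data$logt, S, J, byrow = TRUE) -
                       pooled[, "mu_s"]) / pooled[, "sigma_s"],
                    lower.tail = FALSE)
  W[, m$data$pre == 1] <- 1
  parts <- list(
    mcv = list(old = "mcv_old", new = "mcv_new", y = m$data$mcv,
               sig = "sigma_mcv", nu = "nu_mcv"),
    mchc = list(old = "mchc_old", new = "mchc_new", y = m$data$mchc,
                sig = "sigma_mchc", nu = "nu_mchc"),
    rbc = list(old = "n_old", new = "n_new", y = m$data$n,
               sig = "sigma_n", nu = "nu_n"))
  lapply(parts, function(p) {
    loc <- W * pooled[, col(p$old)][, pid] +
      (1 - W) * pooled[, col(p$new)][, pid]
    dt_ls(matrix(p$y, S, J, byrow = TRUE), df = pooled[, p$nu],
          location = loc, scale = pooled[, p$sig])
  })
}

#' @export
print.rbc_loo <- function(x, ...) {
  cat(sprintf("<rbc_loo> elpd %.1f (SE %.1f), p_loo %.1f | khat > 0.7: %d, khat > 1.0: %d (of %d points)\n",
              x$elpd, x$elpd_se, x$p_loo, x$counts[["khat_gt_0_7"]],
              x$counts[["khat_gt_1_0"]], nrow(x$pointwise)))
  invisible(x)
}

#' Convergence-acceptance verdict
#'
#' Checks the fit against the convergence acceptance rules: zero divergent
#' transitions (trivially satisfied by the Gibbs backend), split-R-hat
#' below `rhat_max` and bulk effective sample size above `ess_min` for
#' every population-level parameter.
#'
#' @param fit An `rbc_fit`.
#' @param rhat_max Maximum admissible split-R-hat (default 1.01).
#' @param ess_min Minimum admissible effective sample size (default 400).
#' @return A tibble `check, value, threshold, pass`; attribute `"pass"`
#'   carries the overall verdict.
#' @export
check_convergence <- function(fit, rhat_max = 1.01, ess_min = 400) {
  stopifnot(inherits(fit, "rbc_fit"))
  d <- fit$diagnostics
  out <- tibble(
    check = c("n_divergences", "max_split_rhat", "min_ess"),
    value = c(d$n_divergences, d$max_rhat, d$min_ess),
    threshold = c(0, rhat_max, ess_min),
    pass = c(d$n_divergences == 0, d$max_rhat < rhat_max, d$min_ess > ess_min))
  attr(out, "pass") <- all(out$pass)
  out
}
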