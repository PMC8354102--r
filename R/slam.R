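#' Closed-form RNA level curves under first-order kinetics
#'
#' Total RNA follows `da/dt = sigma - delta a(t)`, so
#' `a(t) = (a0 - sigma/delta) exp(-t delta) + sigma/delta`. During a 4sU
#' labeling of duration `t`, new (labeled) RNA is
#' `f_new = sigma/delta (1 - exp(-t delta))` in both arms, while old RNA is
#' `f_old = sigma/delta exp(-t delta)` at steady state (control) and
#' `f_old = a0 exp(-t delta)` out of steady state (auxin, with `a0` the
#' total level when labeling starts).
#'
#' @param t Labeling time (hours, >= 0).
#' @param sigma Synthesis rate (RNA units per hour, >= 0).
#' @param delta Degradation rate (per hour, > 0).
#' @param a0 Total level at `t = 0` (auxin arm only).
#' @param arm `"ctrl"` or `"aux"`.
#' @return data.frame with columns `t`, `f_old`, `f_new`.
#' @export
slam_model_curves <- function(t, sigma, delta, a0 = NULL,
                              arm = c("ctrl", "aux")) {
  arm <- match.arg(arm)
  if (delta <= 0) stop("delta must be > 0")
  stopifnot(all(t >= 0), sigma >= 0)
  ss <- sigma / delta
  f_new <- ss * (1 - exp(-t * delta))
  f_old <- if (arm == "ctrl") ss * exp(-t * delta) else {
    if (is.null(a0)) stop("a0 required for the auxin arm")
    a0 * exp(-t * delta)
  }
  data.frame(t = t, f_old = f_old, f_new = f_new)
}

#' Median-of-ratios size factors
#'
#' For a genes x samples count matrix, each sample's factor is the median
#' across all-positive genes of its counts divided by the gene's geometric
#' mean. Normalized counts are raw counts divided by the factor.
#'
#' @param counts Numeric matrix (genes x samples).
#' @return Named numeric vector of per-sample divisors.
#' @export
size_factors_median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no gene with all-positive counts")
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(exp(lg - geo), 2, stats::median)
}

#' Assemble per-gene SLAM observations
#'
#' Derives new and old RNA levels from normalized counts and new-to-total
#' ratios: `g_new = count * ntr`, `g_old = count * (1 - ntr)`.
#'
#' @param df data.frame with columns `time_h`, `rep`, `count`, `ntr`
#'   (one arm of one gene).
#' @return The data.frame with added columns `g_new`, `g_old`.
#' @export
slam_levels <- function(df) {
  stopifnot(all(c("time_h", "count", "ntr") %in% names(df)),
            all(df$count >= 0), all(df$ntr >= 0 & df$ntr <= 1))
  df$g_new <- df$count * df$ntr
  df$g_old <- df$count * (1 - df$ntr)
  df
}

slam_residuals <- function(df, sigma, delta, arm, a0 = NULL) {
  cur <- slam_model_curves(df$time_h, sigma, delta, a0 = a0, arm = arm)
  c(df$g_old - cur$f_old, df$g_new - cur$f_new)[c(rep(TRUE, nrow(df)),
                                                  !df$exclude_new)]
}

slam_fit_engine <- function(df, arm, a0 = NULL, exclude_new_h = c(2, 4)) {
  df <- slam_levels(df)
  df$exclude_new <- df$time_h %in% exclude_new_h
  n_pts <- nrow(df) + sum(!df$exclude_new)
  if (n_pts < 4) stop("need at least 4 usable observations, got ", n_pts)
  if (stats::sd(df$time_h) == 0)
    stop("degradation rate unidentifiable from a single time point")
  # start from log-linear decay of old RNA and the implied steady level
  old_pos <- df$g_old > 0
  delta0 <- if (sum(old_pos) >= 2 && stats::sd(df$time_h[old_pos]) > 0) {
    max(-stats::coef(stats::lm(log(df$g_old[old_pos]) ~
                                 df$time_h[old_pos]))[2], 0.01)
  } else 0.2
  level0 <- max(mean(df$count), 1e-3)
  start <- c(log_sigma = log(level0 * delta0), log_delta = log(delta0))
  resid_fn <- function(par) {
    slam_residuals(df, exp(par[1]), exp(par[2]), arm, a0)
  }
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
  par <- unname(unlist(fit$par))
  sigma <- exp(par[1]); delta <- exp(par[2])
  res <- resid_fn(par)
  dof <- max(length(res) - 2, 1)
  s2 <- sum(res^2) / dof
  cov <- try(s2 * solve(fit$hessian), silent = TRUE)
  if (inherits(cov, "try-error") || any(!is.finite(diag(cov))) ||
      any(diag(cov) < 0)) {
    se <- c(sigma = NA_real_, delta = NA_real_)
    converged <- FALSE
  } else {
    se <- sqrt(diag(cov)) * c(sigma, delta)  # delta method from log scale
    names(se) <- c("sigma", "delta")
    converged <- fit$info %in% 1:4
  }
  at_bound <- delta < 1e-4
  structure(list(
    sigma = sigma, delta = delta, a0 = a0, arm = arm,
    half_life_h = log(2) / delta,
    steady_level = sigma / delta,
    se = se,
    ci_sigma = exp(par[1] + c(-1.96, 1.96) * se["sigma"] / sigma),
    ci_delta = exp(par[2] + c(-1.96, 1.96) * se["delta"] / delta),
    sse = sum(res^2), n_points = length(res),
    excluded = df[df$exclude_new, c("time_h", "rep")],
    converged = converged && !at_bound, at_bound = at_bound
  ), class = "kinetic_fit")
}

#' Fit steady-state (control) synthesis and degradation rates
#'
#' Nonlinear least squares of the steady-state curves to new and old RNA
#' levels with equal weights. New-RNA observations at late time points
#' (default 2 h and 4 h, where prolonged labeling suppresses apparent new
#' RNA) are excluded; degradation uses all time points.
#'
#' @param df One gene's control observations: columns `time_h`, `rep`,
#'   `count`, `ntr`.
#' @param exclude_new_h New-RNA time points to exclude (hours).
#' @return An object of class `kinetic_fit` with `sigma`, `delta`, CIs.
#' @export
fit_slam_control <- function(df, exclude_new_h = c(2, 4)) {
  slam_fit_engine(df, arm = "ctrl", exclude_new_h = exclude_new_h)
}

#' Fit non-steady-state (auxin) synthesis and degradation rates
#'
#' Like [fit_slam_control()] but out of steady state: the initial total
#' level `a0` is fixed to the mean old-RNA level of the `t = 0`
#' replicates, and old RNA follows `a0 exp(-t delta)`.
#'
#' @inheritParams fit_slam_control
#' @return An object of class `kinetic_fit`.
#' @export
fit_slam_auxin <- function(df, exclude_new_h = c(2, 4)) {
  df <- slam_levels(df)
  at0 <- df$g_old[df$time_h == 0]
  if (length(at0) == 0) stop("t = 0 observations required to anchor a0")
  slam_fit_engine(df, arm = "aux", a0 = mean(at0),
                  exclude_new_h = exclude_new_h)
}

#' Net synthesis-rate fold change between arms
#'
#' @param fit_aux,fit_ctrl `kinetic_fit` objects for the two arms.
#' @return List with `ratio` (`sigma_ctrl / sigma_aux`) and `log2_ratio`.
#' @export
net_rate_ratio <- function(fit_aux, fit_ctrl) {
  if (!fit_aux$converged || !fit_ctrl$converged)
    warning("one of the fits did not converge")
  ratio <- fit_ctrl$sigma / fit_aux$sigma
  if (!is.finite(ratio)) warning("non-finite rate ratio")
  list(ratio = ratio, log2_ratio = log2(ratio))
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<kinetic_fit> %s arm: sigma = %.3f /h, delta = %.3f /h ",
    "(t1/2 = %.2f h)\n  steady level = %.1f%s, SSE = %.1f over %d points, ",
    "converged = %s\n"),
    x$arm, x$sigma, x$delta, x$half_life_h, x$steady_level,
    if (!is.null(x$a0)) sprintf(", a0 = %.1f", x$a0) else "",
    x$sse, x$n_points, x$converged))
  invisible(x)
}
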