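#' Quantile regression by direct pinball-loss minimization
#'
#' Linear fit of `y ~ x` minimizing the check (pinball) loss for quantile
#' `tau`, via Schlossmacher-style iteratively reweighted least squares
#' followed by a Nelder-Mead polish of the exact loss. With a degenerate
#' design (constant `x`) the fit is intercept-only (the sample quantile).
#'
#' @param x,y Numeric vectors.
#' @param tau Quantile in (0, 1).
#' @return Named vector `c(intercept, slope)`.
#' @keywords internal
pinball_fit <- function(x, y, tau) {
  loss <- function(cf) {
    u <- y - cf[1] - cf[2] * x
    sum(u * (tau - (u < 0)))
  }
  if (stats::sd(x) < 1e-12) {
    return(c(intercept = unname(stats::quantile(y, tau, type = 1)),
             slope = 0))
  }
  cf <- stats::coef(stats::lm(y ~ x))
  for (iter in 1:100) {
    u <- y - cf[1] - cf[2] * x
    w <- ifelse(u >= 0, tau, 1 - tau) / pmax(abs(u), 1e-6)
    cf_new <- stats::coef(stats::lm(y ~ x, weights = w))
    if (max(abs(cf_new - cf)) < 1e-9) {
      cf <- cf_new
      break
    }
    cf <- cf_new
  }
  pol <- stats::optim(cf, loss, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (pol$value < loss(cf)) cf <- pol$par
  c(intercept = unname(cf[1]), slope = unname(cf[2]))
}

#' Expression-dependent background model for DRB-4sU-seq samples
#'
#' The background read density of a sample depends on expression. From
#' per-gene background densities (intronic reads in the last 5 kb of very
#' long genes, where the wave cannot have arrived) and per-gene expression
#' (reads per kb), quantile regressions of `log(density)` on
#' `log(expression)` at the 5% and 95% levels bound the plausible
#' background for any gene.
#'
#' @param density Per-gene background density (> 0; zeros dropped with a
#'   warning).
#' @param expression Per-gene expression, reads per kb (> 0).
#' @param min_genes Minimum genes required (default 50).
#' @return An object of class `background_model`.
#' @export
fit_background <- function(density, expression, min_genes = 50) {
  ok <- is.finite(density) & is.finite(expression) &
    density > 0 & expression > 0
  if (any(!ok)) warning(sum(!ok), " gene(s) with non-positive values dropped")
  density <- density[ok]
  expression <- expression[ok]
  if (length(density) < min_genes)
    stop("need at least ", min_genes, " genes, got ", length(density))
  lx <- log(expression)
  ly <- log(density)
  q05 <- pinball_fit(lx, ly, 0.05)
  q95 <- pinball_fit(lx, ly, 0.95)
  structure(list(q05 = q05, q95 = q95, n = length(density)),
            class = "background_model")
}

#' Predict background bounds for a gene
#'
#' @param object A `background_model`.
#' @param expression Expression values (reads per kb).
#' @param ... Unused.
#' @return data.frame with columns `q05`, `q95` (density units).
#' @export
predict.background_model <- function(object, expression, ...) {
  lx <- log(expression)
  lo <- object$q05[1] + object$q05[2] * lx
  hi <- object$q95[1] + object$q95[2] * lx
  data.frame(q05 = exp(pmin(lo, hi)), q95 = exp(pmax(lo, hi)))
}

#' Expected DRB-4sU-seq profile with a wavefront at b
#'
#' `w(i) = (o + (bg 2^(-r b) - o) / b * min(i, b)) * 2^(r min(i, b))`.
#' For `r = 0` this is the triangular shape: linear from `o` at the TSS
#' to the background `bg` at the wavefront `b`, constant beyond. For
#' `r < 0` the linear part is damped by the processivity decay `2^(r i)`,
#' still reaching exactly `bg` at `i = b`.
#'
#' @param i Window index (kb from TSS).
#' @param o Level at the TSS.
#' @param b Wavefront position (windows, > 0).
#' @param bg Background level.
#' @param r Decay slope in log2 per window (0 for control samples, the
#'   gene's LFC slope for treated samples).
#' @return Expected counts.
#' @export
wavefront_profile <- function(i, o, b, bg, r = 0) {
  stopifnot(b > 0)
  mi <- pmin(i, b)
  (o + (bg * 2^(-r * b) - o) / b * mi) * 2^(r * mi)
}

#' Fit the DRB-4sU-seq wavefront by NB regression
#'
#' Maximum-likelihood fit of [wavefront_profile()] to gene-body window
#' counts under NB noise, with a Gaussian prior on `log(bg)` whose 5% and
#' 95% percentiles match the background model's prediction (mean = the
#' log-scale midpoint, sd = span / 3.29). The first `tss_mask_kb`
#' windows are flagged missing (TSS peak). The decay slope `r` is fixed:
#' 0 for control samples, the gene's LFC slope for treated samples.
#' The elongation rate is the fitted wavefront divided by the chase time.
#'
#' @param wv A body-grid `window_vector` of DRB-4sU-seq counts.
#' @param chase_min Minutes between DRB washout and harvest.
#' @param r_fixed Fixed decay slope (log2 per window; default 0).
#' @param bg_q05,bg_q95 Background bounds in count units per window
#'   (either give these or `bgmodel` + `expression`).
#' @param bgmodel A [fit_background()] model.
#' @param expression The gene's expression (reads per kb) for the
#'   background prediction.
#' @param tss_mask_kb Kilobases masked at the TSS (default 5).
#' @param starts_e Elongation-rate starts in kb/min (default 1:4).
#' @param min_windows Minimum usable windows (default 10).
#' @return An object of class `wavefront_fit` with `b` (kb), elongation
#'   `rate` (kb/min), `o`, `bg`, `disp`, CIs, and flags.
#' @export
fit_wavefront <- function(wv, chase_min, r_fixed = 0,
                          bg_q05 = NULL, bg_q95 = NULL,
                          bgmodel = NULL, expression = NULL,
                          tss_mask_kb = 5, starts_e = 1:4,
                          min_windows = 10) {
  stopifnot(inherits(wv, "window_vector"))
  width_nt <- attr(wv, "width_nt")
  if (is.null(bg_q05) || is.null(bg_q95)) {
    if (is.null(bgmodel) || is.null(expression))
      stop("supply bg_q05/bg_q95 or bgmodel + expression")
    pr <- predict(bgmodel, expression)
    # model works in density (per nt); convert to counts per window
    bg_q05 <- pr$q05 * width_nt
    bg_q95 <- pr$q95 * width_nt
  }
  keep <- !wv$missing & wv$rel >= tss_mask_kb * 1000
  i <- (wv$rel[keep] + width_nt / 2) / width_nt  # window centers, in windows
  aa <- censor_counts(wv$count[keep])
  n <- length(aa)
  if (n < min_windows)
    stop("need at least ", min_windows, " usable windows, got ", n)
  L <- max(i)
  b_lo <- max(tss_mask_kb * 1000 / width_nt, 1) + 0.5
  if (L <= b_lo + 1) stop("gene too short for a wavefront fit")

  mu_bg <- (log(bg_q05) + log(bg_q95)) / 2
  sd_bg <- max((log(bg_q95) - log(bg_q05)) / 3.29, 0.05)

  nll <- function(th) {
    o <- exp(th[1])
    b <- b_lo + (L - b_lo) * stats::plogis(th[2])
    bg <- exp(th[3])
    disp <- exp(th[4])
    mu <- pmax(wavefront_profile(i, o, b, bg, r_fixed), 1e-9)
    -(sum(stats::dnbinom(aa, size = disp, mu = mu, log = TRUE)) +
        stats::dnorm(th[3], mu_bg, sd_bg, log = TRUE))
  }
  o0 <- max(mean(utils::head(aa, 3)), exp(mu_bg), 1)
  best <- NULL
  for (e0 in starts_e) {
    b0 <- min(max(e0 * chase_min, b_lo + 1), L - 0.5)
    th0 <- c(log(o0), stats::qlogis((b0 - b_lo) / (L - b_lo)), mu_bg, log(2))
    fit <- try(stats::optim(th0, nll, method = "BFGS",
                            control = list(maxit = 2000)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  th <- best$par
  o <- exp(th[1])
  b <- b_lo + (L - b_lo) * stats::plogis(th[2])
  bg <- exp(th[3])
  disp <- exp(th[4])
  # a wavefront within 2 windows of the gene end may have exited the gene
  at_boundary <- b > L - 2 || b < b_lo + 0.5
  hv <- hessian_ci(nll, th)
  db <- (L - b_lo) * stats::dlogis(th[2])
  se_b <- if (is.null(hv)) NA_real_ else hv$se[2] * db
  w_kb <- width_nt / 1000
  rate <- b * w_kb / chase_min
  structure(list(
    o = o, b = b, b_kb = b * w_kb, bg = bg, disp = disp,
    r_fixed = r_fixed, chase_min = chase_min,
    rate = rate, se_b = se_b,
    ci_rate = (b + c(-1.96, 1.96) * se_b) * w_kb / chase_min,
    bg_prior = c(q05 = bg_q05, q95 = bg_q95),
    n_used = n, loglik = -best$value,
    converged = !is.null(hv) && best$convergence == 0,
    at_boundary = at_boundary
  ), class = "wavefront_fit")
}

#' @export
print.wavefront_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<wavefront_fit> b = %.1f kb after %g min -> %.2f kb/min ",
    "(95%% CI %.2f..%.2f)\n",
    "  o = %.1f, bg = %.2f, disp = %.2f, r = %.4f; %d windows, ",
    "converged = %s%s\n"),
    x$b_kb, x$chase_min, x$rate, x$ci_rate[1], x$ci_rate[2],
    x$o, x$bg, x$disp, x$r_fixed, x$n_used, x$converged,
    if (x$at_boundary) " (b at boundary)" else ""))
  invisible(x)
}
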