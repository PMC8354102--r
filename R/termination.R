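#' Negative binomial probability mass with mean/overdispersion parameters
#'
#' `dnb(x; n, d) = choose(x + d - 1, x) (d/(d+n))^d (n/(d+n))^x`, the NB
#' pmf with mean `n` and size (overdispersion) parameter `d > 0`; the
#' variance is `n + n^2/d`. Thin wrapper over [stats::dnbinom()] for the
#' (mean, size) parameterization used throughout the regressions.
#'
#' @param x Non-negative counts.
#' @param n Mean (>= 0).
#' @param disp Size parameter (> 0).
#' @param log Return log probabilities.
#' @return Probabilities.
#' @export
dnb <- function(x, n, disp, log = FALSE) {
  if (any(disp <= 0)) stop("disp must be > 0")
  if (any(n < 0)) stop("mean must be >= 0")
  stats::dnbinom(x, size = disp, mu = n, log = log)
}

#' Level and spread of the pre-PAS signal
#'
#' Mean and standard deviation of the non-missing upstream windows of a
#' PAS-centered grid; if fewer than two are usable, the first five
#' non-missing downstream windows are used instead.
#'
#' @param wv A PAS-grid `window_vector` (column `rel` < 0 upstream).
#' @return List with `m`, `sd`, and `source` (`"upstream"` or
#'   `"downstream"`).
#' @export
upstream_stats <- function(wv) {
  stopifnot(inherits(wv, "window_vector"))
  up <- wv$count[wv$rel < 0 & !wv$missing]
  up <- up[is.finite(up)]
  src <- "upstream"
  if (length(up) < 2) {
    down <- wv$count[wv$rel >= 0 & !wv$missing]
    up <- utils::head(down[is.finite(down)], 5)
    src <- "downstream"
  }
  if (length(up) < 2) stop("fewer than 2 usable windows for the PAS level")
  list(m = mean(up), sd = stats::sd(up), source = src)
}

#' Truncate the termination zone at the noise floor
#'
#' Flags everything downstream of the first run of four consecutive
#' downstream windows whose counts fall below 1% of the PAS-level `m`
#' (missing windows interrupt a run).
#'
#' @param wv A PAS-grid `window_vector`.
#' @param m PAS signal level (from [upstream_stats()]).
#' @param frac Threshold fraction (default 0.01).
#' @param run_len Required run length (default 4).
#' @return The `window_vector` with an updated `missing` mask.
#' @export
apply_noise_cutoff <- function(wv, m, frac = 0.01, run_len = 4) {
  stopifnot(inherits(wv, "window_vector"))
  down <- which(wv$rel >= 0)
  below <- !wv$missing[down] & wv$count[down] < frac * m
  run <- 0L
  for (j in seq_along(down)) {
    run <- if (below[j]) run + 1L else 0L
    if (run >= run_len) {
      if (j < length(down)) wv$missing[down[(j + 1):length(down)]] <- TRUE
      break
    }
  }
  wv
}

#' Fit the post-PAS exponential decline by NB regression
#'
#' Models downstream counts as `s(i) = o exp(-r i)` (window index `i`
#' starting at 0 at the PAS) with NB observation noise, maximizing
#' `sum_i log dnb(a_i; s(i), disp) + n * log N(o; m, sd)` over non-missing
#' downstream windows, where the Gaussian prior on the PAS level `o` is
#' weighted by the number of used windows `n` to give prior and likelihood
#' equal weight. Optimized over `(log o, log r, log disp)` with
#' multi-start in `r`; CIs from the numeric Hessian.
#'
#' The decline is reported per window, in nats per kb, and as the per-kb
#' survival loss `100 (1 - exp(-r * windows_per_kb))` percent per kb (the
#' default reporting unit).
#'
#' @param wv A PAS-grid `window_vector` (noise cutoff applied internally).
#' @param m,sd Optional PAS-level prior parameters; computed by
#'   [upstream_stats()] when omitted. A degenerate `sd` is widened to
#'   `max(sd, 0.1 m + 1)`.
#' @param starts_r Multi-start decline rates per window.
#' @param min_windows Minimum usable downstream windows (default 6).
#' @return An object of class `term_fit`.
#' @export
fit_termination <- function(wv, m = NULL, sd = NULL,
                            starts_r = c(0.01, 0.05, 0.2),
                            min_windows = 6) {
  stopifnot(inherits(wv, "window_vector"))
  if (is.null(m) || is.null(sd)) {
    us <- upstream_stats(wv)
    if (is.null(m)) m <- us$m
    if (is.null(sd)) sd <- us$sd
  }
  sd_used <- max(sd, 0.1 * m + 1, na.rm = TRUE)
  wv <- apply_noise_cutoff(wv, m)
  keep <- wv$rel >= 0 & !wv$missing
  i <- wv$rel[keep] / attr(wv, "width_nt")  # 0-based window index
  aa <- censor_counts(wv$count[keep])
  n <- length(aa)
  if (n < min_windows)
    stop("need at least ", min_windows, " usable downstream windows, got ", n)
  win_per_kb <- 1000 / attr(wv, "width_nt")

  nll <- function(th) {
    o <- exp(th[1]); r <- exp(th[2]); disp <- exp(th[3])
    mu <- pmax(o * exp(-r * i), 1e-9)
    -(sum(stats::dnbinom(aa, size = disp, mu = mu, log = TRUE)) +
        n * stats::dnorm(o, m, sd_used, log = TRUE))
  }
  o0 <- max(m, mean(utils::head(aa, 5)), 1e-3)
  best <- NULL
  for (r0 in starts_r) {
    th0 <- c(log(o0), log(r0), log(2))
    fit <- try(stats::optim(th0, nll, method = "BFGS",
                            control = list(maxit = 1000)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  th <- best$par
  o <- exp(th[1]); r <- exp(th[2]); disp <- exp(th[3])
  hv <- hessian_ci(nll, th)
  se_lr <- NA_real_
  if (is.null(hv)) {
    # dispersion at its flat (Poisson) boundary: profile it out so the
    # decay parameters keep their quadratic CIs
    hv2 <- hessian_ci(function(th2) nll(c(th2, th[3])), th[1:2])
    if (is.null(hv2)) {
      se <- c(o = NA_real_, r = NA_real_, disp = NA_real_)
      converged <- FALSE
    } else {
      se <- c(o = hv2$se[1] * o, r = hv2$se[2] * r, disp = NA_real_)
      se_lr <- hv2$se[2]
      converged <- best$convergence == 0
    }
  } else {
    se <- c(o = hv$se[1] * o, r = hv$se[2] * r, disp = hv$se[3] * disp)
    se_lr <- hv$se[2]
    converged <- best$convergence == 0
  }
  ci_r <- exp(th[2] + c(-1.96, 1.96) * se_lr)
  structure(list(
    o = o, r = r, disp = disp,
    prior_m = m, prior_sd = sd_used,
    se = se, ci_r = ci_r,
    r_per_kb_nats = r * win_per_kb,
    decline_pct_per_kb = 100 * (1 - exp(-r * win_per_kb)),
    n_used = n, loglik = -best$value, converged = converged
  ), class = "term_fit")
}

#' @export
print.term_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<term_fit> o = %.2f, r = %.4f /window (%.1f %%/kb), disp = %.2f\n",
    "  prior N(%.2f, %.2f); %d windows, loglik = %.2f, converged = %s\n"),
    x$o, x$r, x$decline_pct_per_kb, x$disp, x$prior_m, x$prior_sd,
    x$n_used, x$loglik, x$converged))
  invisible(x)
}
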