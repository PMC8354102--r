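#' Expressed-gene filter
#'
#' A gene counts as expressed when (a) it is longer than 5 kb and (b) the
#' sum of read densities over 150 bp bins from PAS - 5 kb to PAS + 5 kb
#' is strictly greater than 4. For genes with several TSSs the longest
#' unit is considered first (handled upstream in TU selection).
#'
#' @param tu A [transcription_unit()].
#' @param pas_bin_densities Densities of the 150 bp bins around the PAS.
#' @param min_length_nt Length threshold (default 5000).
#' @param min_density_sum Density-sum threshold (default 4, strict).
#' @return `TRUE` if both criteria hold.
#' @export
expressed_filter <- function(tu, pas_bin_densities, min_length_nt = 5000,
                             min_density_sum = 4) {
  tu$length_nt > min_length_nt &&
    sum(pas_bin_densities, na.rm = TRUE) > min_density_sum
}

#' Transcription completion score
#'
#' Log2 ratio of summed signal in the last versus first 15% of the gene
#' body (distal vs proximal window), from length-normalized 150 bp bins.
#' A pseudocount of one normalized count guards zero sums; `NA` when both
#' windows are empty.
#'
#' @param body_bins Numeric vector of binned gene-body signal, 5' to 3'.
#' @param frac Fraction of the gene in each window (default 0.15).
#' @param pseudo Pseudocount (default 1).
#' @return Log2 completion score.
#' @export
completion_score <- function(body_bins, frac = 0.15, pseudo = 1) {
  n <- length(body_bins)
  k <- max(1, floor(frac * n))
  proximal <- sum(body_bins[seq_len(k)], na.rm = TRUE)
  distal <- sum(body_bins[seq.int(n - k + 1, n)], na.rm = TRUE)
  if (proximal == 0 && distal == 0) return(NA_real_)
  log2((distal + pseudo) / (proximal + pseudo))
}

#' Transcription readthrough score
#'
#' Log2 ratio of read density after versus before the PAS. The pre-PAS
#' window spans PAS - 5 kb to PAS for 4sU-seq and PAS - 3 kb to PAS for
#' occupancy (ChIP) data; the readthrough window spans PAS + 5 kb to
#' PAS + 15 kb for both. Densities (signal per nt) are compared because
#' the window widths differ.
#'
#' @param wv A PAS-grid `window_vector` (column `rel` relative to PAS).
#' @param assay `"foursu"` or `"chip"` (selects the pre-PAS span).
#' @param pseudo Pseudocount on the per-nt densities scaled to one
#'   normalized count per window (default 1).
#' @return Log2 readthrough score; `NA` if the post region is fully
#'   masked.
#' @export
readthrough_score <- function(wv, assay = c("foursu", "chip"), pseudo = 1) {
  assay <- match.arg(assay)
  stopifnot(inherits(wv, "window_vector"))
  width <- attr(wv, "width_nt")
  pre_span <- if (assay == "foursu") c(-5000, 0) else c(-3000, 0)
  post_span <- c(5000, 15000)
  pre <- wv$rel >= pre_span[1] & wv$rel < pre_span[2] & !wv$missing
  post <- wv$rel >= post_span[1] & wv$rel < post_span[2] & !wv$missing
  if (!any(post) || !any(pre)) return(NA_real_)
  dens_pre <- sum(wv$count[pre]) / (sum(pre) * width)
  dens_post <- sum(wv$count[post]) / (sum(post) * width)
  p <- pseudo / width  # one count per window, as density
  log2((dens_post + p) / (dens_pre + p))
}

#' Z-scores of anti-logged scores
#'
#' Converts log2 scores to the linear scale (`2^score`), then centers and
#' scales by the sample standard deviation.
#'
#' @param scores Numeric vector of log2 scores (>= 2 values).
#' @return Z-score vector.
#' @export
score_zscores <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 scores")
  x <- 2^scores
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero variance among scores")
  (x - mean(x)) / s
}

#' Moderated differential test between two arms of scores
#'
#' Empirical-Bayes two-sample test: per-gene variances are shrunk toward
#' a pooled prior variance with a method-of-moments prior df, a t
#' statistic is formed against the shrunk variance with `df + prior df`
#' degrees of freedom, and p values are BH-adjusted. With `prior_df = 0`
#' this reduces to the ordinary two-sample t test. With fewer than two
#' replicates per arm no test is performed and only the per-gene effect
#' is returned.
#'
#' @param arm1,arm2 Matrices (genes x replicates) of log2 scores.
#' @param prior_df Prior degrees of freedom; `NULL` (default) estimates
#'   them by method of moments from the spread of the per-gene variances.
#' @return data.frame with columns `delta` (arm2 - arm1), `t`, `df`, `p`,
#'   `q`.
#' @export
moderated_diff_test <- function(arm1, arm2, prior_df = NULL) {
  arm1 <- as.matrix(arm1)
  arm2 <- as.matrix(arm2)
  stopifnot(nrow(arm1) == nrow(arm2))
  n1 <- ncol(arm1); n2 <- ncol(arm2)
  delta <- rowMeans(arm2) - rowMeans(arm1)
  if (n1 < 2 || n2 < 2) {
    return(data.frame(delta = delta, t = NA_real_, df = NA_real_,
                      p = NA_real_, q = NA_real_))
  }
  df <- n1 + n2 - 2
  s2 <- (apply(arm1, 1, stats::var) * (n1 - 1) +
           apply(arm2, 1, stats::var) * (n2 - 1)) / df
  s2 <- pmax(s2, 1e-12)
  s0 <- mean(s2)
  if (is.null(prior_df)) {
    # Var(s2_g) ~ s0^2 (2/df + 2/d0) under a scaled chi-square hierarchy
    excess <- stats::var(s2) / s0^2 - 2 / df
    prior_df <- if (is.na(excess) || excess <= 1e-8) 1e6 else
      min(max(2 / excess, 0), 1e6)
  }
  s2_post <- (prior_df * s0 + df * s2) / (prior_df + df)
  tt <- delta / sqrt(s2_post * (1 / n1 + 1 / n2))
  df_tot <- df + prior_df
  p <- 2 * stats::pt(-abs(tt), df = df_tot)
  data.frame(delta = delta, t = tt, df = df_tot, p = p,
             q = stats::p.adjust(p, method = "BH"))
}
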