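#' Remove TSS candidates that leave most intronic signal upstream
#'
#' A candidate TSS is dropped when strictly more than half of the gene's
#' intronic reads lie upstream of it (the candidate would "explain" less
#' than 50% of the signal). If every candidate is dropped, the 5'-most
#' candidate is kept with a warning.
#'
#' @param candidates data.frame with a `pos` column (transcription-
#'   oriented coordinate, nt) and optionally `source`.
#' @param profile Numeric vector of per-nt intronic coverage over the
#'   gene span, 5' to 3'; `profile[k]` covers nt `k`.
#' @param max_upstream_frac Exclusion threshold (default 0.5, strict).
#' @return The surviving candidate rows, with an added `upstream_frac`
#'   column.
#' @export
filter_tss_candidates <- function(candidates, profile,
                                  max_upstream_frac = 0.5) {
  total <- sum(profile)
  if (total <= 0) stop("gene has no intronic reads")
  cum <- cumsum(profile)
  pos <- pmin(pmax(candidates$pos, 1), length(profile))
  upstream <- ifelse(pos <= 1, 0, cum[pmax(pos - 1, 1)] * (pos > 1))
  candidates$upstream_frac <- upstream / total
  keep <- candidates$upstream_frac <= max_upstream_frac
  if (!any(keep)) {
    warning("all TSS candidates removed; keeping the 5'-most")
    keep <- candidates$pos == min(candidates$pos)
  }
  candidates[keep, , drop = FALSE]
}

#' Select the TSS with the largest coverage increment
#'
#' For each candidate, the mean intronic coverage downstream (`d_i`) and
#' upstream (`u_i`) is computed from the per-nt profile; the candidate
#' maximizing `d_i - u_i` wins, ties going to the 5'-most.
#'
#' @inheritParams filter_tss_candidates
#' @return The chosen row of `candidates`, with `d_i`, `u_i` and
#'   `increment` columns added.
#' @export
select_tss <- function(candidates, profile) {
  if (nrow(candidates) == 0) stop("no TSS candidates")
  n <- length(profile)
  cum <- c(0, cumsum(profile))
  pos <- pmin(pmax(candidates$pos, 1), n)
  up <- ifelse(pos > 1, cum[pos] / (pos - 1), 0)
  down <- (cum[n + 1] - cum[pos]) / (n - pos + 1)
  candidates$u_i <- up
  candidates$d_i <- down
  candidates$increment <- down - up
  ord <- order(-candidates$increment, candidates$pos)
  candidates[ord[1], , drop = FALSE]
}

#' Gaussian smoothing with a truncated, renormalized kernel
#'
#' Mass-conserving smoothing of a non-negative profile; at the boundaries
#' the kernel is truncated and renormalized so that total mass is
#' preserved exactly.
#'
#' @param x Numeric vector.
#' @param bandwidth Kernel standard deviation in positions (default 20).
#' @return Smoothed vector, same length and total sum.
#' @export
smooth_gaussian <- function(x, bandwidth = 20) {
  n <- length(x)
  half <- ceiling(4 * bandwidth)
  k <- stats::dnorm(-half:half, sd = bandwidth)
  out <- numeric(n)
  nz <- which(x != 0)
  for (j in nz) {
    lo <- max(1, j - half)
    hi <- min(n, j + half)
    kk <- k[(lo - j + half + 1):(hi - j + half + 1)]
    out[lo:hi] <- out[lo:hi] + x[j] * kk / sum(kk)
  }
  out
}

#' Call the polyadenylation site from a 3'-end read-start profile
#'
#' The per-position read-start profile is smoothed with a Gaussian kernel
#' (sd `bandwidth`), and the 3'-most position `p` where the smoothed
#' profile exceeds 1% of its maximum is located. If an annotated PAS lies
#' less than 150 nt downstream of `p`, that annotated PAS is selected;
#' otherwise the PAS is `p + 100` (the typical offset of the read-start
#' cluster from the cleavage site).
#'
#' @param profile Numeric vector of read starts per position
#'   (transcription-oriented coordinates starting at 1).
#' @param annotated_pas Integer vector of annotated PAS positions in the
#'   same coordinates (may be empty).
#' @param bandwidth Smoothing kernel sd in nt (default 20).
#' @param rel_threshold Fraction of the maximum (default 0.01).
#' @param max_annotated_dist Maximum distance from `p` to an annotated
#'   PAS for adoption (default 150, strict).
#' @param offset Offset added when no annotated PAS is adopted
#'   (default 100).
#' @return An object of class `pas_call` with elements `pas`, `p`,
#'   `rule` (`"annotated"` or `"p_plus_100"`), and `smoothed`; `NA` call
#'   for an all-zero profile.
#' @export
select_pas <- function(profile, annotated_pas = integer(),
                       bandwidth = 20, rel_threshold = 0.01,
                       max_annotated_dist = 150, offset = 100) {
  if (length(profile) == 0 || all(profile == 0)) {
    return(structure(list(pas = NA_integer_, p = NA_integer_,
                          rule = NA_character_, smoothed = profile),
                     class = "pas_call"))
  }
  sm <- smooth_gaussian(profile, bandwidth)
  p <- max(which(sm > rel_threshold * max(sm)))
  # symmetric window: smoothing carries p up to ~3 sd past the read
  # cluster, so annotations slightly upstream of p still qualify
  ahead <- annotated_pas[abs(annotated_pas - p) < max_annotated_dist]
  if (length(ahead) > 0) {
    pas <- max(ahead)  # 3'-most qualifying annotation
    rule <- "annotated"
  } else {
    pas <- p + offset
    rule <- "p_plus_100"
  }
  structure(list(pas = pas, p = p, rule = rule, smoothed = sm),
            class = "pas_call")
}

#' @export
print.pas_call <- function(x, ...) {
  cat(sprintf("<pas_call> PAS at %s (p = %s, rule = %s)\n",
              x$pas, x$p, x$rule))
  invisible(x)
}
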