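#' Configuration for the synthetic cohort generator
#'
#' Defines the study design the generator emulates: two arms (control and
#' depletion) with triplicate pulse-labeled nascent-RNA sequencing,
#' occupancy profiles, DRB chases, PAS-centered termination grids, and
#' metabolic-labeling (SLAM) tables at 0/1/2/4 h. All draws are
#' deterministic under `seed`, with stream splitting per
#' (gene, assay, arm, replicate).
#'
#' Defaults: 300 genes with log-uniform lengths 5-200 kb; per-window
#' expression lognormal (median `expr_median` counts per kb window); NB
#' size 5 for sequencing assays and 10 for SLAM counts; control
#' elongation rate lognormal around 3 kb/min (15% CV) with the treated
#' arm scaled by 0.75 and carrying a 2%/kb processivity defect;
#' termination rates 0.0558 per 250 nt window (20%/kb survival loss) in
#' control and 0.0266 (10.1%/kb) in the treated arm; SLAM degradation
#' rates lognormal with median 0.35/h, synthesis rates `delta * level`
#' with lognormal levels, and an 8-fold synthesis reduction in the
#' treated arm.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes.
#' @param len_range_kb Gene length range, log-uniform (kb).
#' @param p Initiation interval (min).
#' @param e_ctrl_median,e_ctrl_sdlog Control elongation-rate distribution.
#' @param e_treat_scale Treated-arm elongation scaling.
#' @param d_ctrl,d_treat Processivity defect per arm (fraction per kb).
#' @param r_term_ctrl,r_term_treat Termination decline per 250 nt window.
#' @param expr_median,expr_sdlog Per-window expression distribution.
#' @param nb_size_seq,nb_size_slam NB size parameters.
#' @param label_min Pulse labeling time (min).
#' @param chase_min DRB chase times (min).
#' @param timepoints_h SLAM labeling durations (h).
#' @param reps Replicates per arm.
#' @param delta_median,delta_sdlog SLAM degradation-rate distribution (/h).
#' @param level_median,level_sdlog SLAM steady-state level distribution.
#' @param sigma_aux_scale Treated-arm synthesis scaling (default 1/8).
#' @param ntr_kappa Beta precision of NTR noise.
#' @param bg_frac DRB background density as a fraction of expression.
#' @param exons_per_gene Exons placed per gene (to exercise masks).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_genes = 300L,
                         len_range_kb = c(5, 200), p = 2,
                         e_ctrl_median = 3, e_ctrl_sdlog = 0.15,
                         e_treat_scale = 0.75,
                         d_ctrl = 0, d_treat = 0.02,
                         r_term_ctrl = 0.0558, r_term_treat = 0.0266,
                         expr_median = 100, expr_sdlog = 0.8,
                         nb_size_seq = 5, nb_size_slam = 10,
                         label_min = 15, chase_min = c(10, 20, 30),
                         timepoints_h = c(0, 1, 2, 4), reps = 3L,
                         delta_median = 0.35, delta_sdlog = 0.4,
                         level_median = 100, level_sdlog = 0.8,
                         sigma_aux_scale = 1 / 8, ntr_kappa = 200,
                         bg_frac = 0.01, exons_per_gene = 2L) {
  cfg <- as.list(environment())
  stopifnot(seed == as.integer(seed), n_genes >= 0,
            all(len_range_kb > 0), e_treat_scale > 0,
            sigma_aux_scale > 0, nb_size_seq > 0, nb_size_slam > 0)
  structure(cfg, class = "synth_config")
}

# deterministic sub-seed from labels, kept below 2^31
stream_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- sum(utf8ToInt(labels) * seq_along(utf8ToInt(labels)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Generate a synthetic transcription-unit cohort with ground truth
#'
#' Places `n_genes` TUs on synthetic chromosomes (alternating strands,
#' spaced so termination grids of different genes do not collide), each
#' with a few exons, and draws the per-gene kinetic truth: expression,
#' elongation rates per arm, processivity defects, termination rates,
#' and SLAM synthesis/degradation rates.
#'
#' @param config A [synth_config()].
#' @return List with `tus` (named list of [transcription_unit()]s) and
#'   `truth` (data.frame, one row per gene).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(stream_seed(config$seed, "cohort"))
  n <- config$n_genes
  if (n == 0) {
    return(list(tus = list(),
                truth = data.frame(gene = character())))
  }
  len_kb <- floor(exp(stats::runif(n, log(config$len_range_kb[1]),
                                   log(config$len_range_kb[2]))))
  expr <- stats::rlnorm(n, log(config$expr_median), config$expr_sdlog)
  e_ctrl <- stats::rlnorm(n, log(config$e_ctrl_median), config$e_ctrl_sdlog)
  delta <- stats::rlnorm(n, log(config$delta_median), config$delta_sdlog)
  level <- stats::rlnorm(n, log(config$level_median), config$level_sdlog)
  gene <- sprintf("G%04d", seq_len(n))
  strand <- rep(c("+", "-"), length.out = n)
  gap <- 60000  # keeps PAS grids clear of neighboring TSSs
  tus <- vector("list", n)
  pos <- 10000
  chrom_i <- 1
  for (g in seq_len(n)) {
    span <- len_kb[g] * 1000L
    if (pos + span + gap > 3e8) {
      chrom_i <- chrom_i + 1
      pos <- 10000
    }
    if (strand[g] == "+") {
      tss <- pos; pas <- pos + span
    } else {
      tss <- pos + span; pas <- pos
    }
    n_ex <- config$exons_per_gene
    exons <- if (n_ex > 0 && span > 8000) {
      st <- sort(sample.int(span - 3000, n_ex)) + pos
      data.frame(start = st, end = st + 1000L)
    } else data.frame(start = integer(), end = integer())
    tus[[g]] <- transcription_unit(gene[g], paste0("chrS", chrom_i),
                                   strand[g], tss, pas, exons)
    pos <- pos + span + gap
  }
  names(tus) <- gene
  truth <- data.frame(
    gene = gene, chrom = vapply(tus, function(t) t$chrom, ""),
    strand = strand, length_kb = len_kb, expr = expr,
    p = config$p,
    e_ctrl = e_ctrl, e_treat = e_ctrl * config$e_treat_scale,
    d_ctrl = config$d_ctrl, d_treat = config$d_treat,
    r_term_ctrl = config$r_term_ctrl, r_term_treat = config$r_term_treat,
    sigma_ctrl = delta * level, sigma_aux = delta * level *
      config$sigma_aux_scale,
    delta = delta
  )
  list(tus = tus, truth = truth)
}

#' Generate synthetic window counts for one assay, arm and replicate
#'
#' Expected window means come from the transport model (exact closed
#' forms: geometric steady state for gene-body occupancy and pulse
#' labeling, the Erlang-damped front for DRB chases) and from the
#' exponential termination model for PAS grids; observed counts are NB
#' draws around them. Exon-overlapping windows are masked.
#'
#' @param cohort Output of [generate_cohort()].
#' @param assay `"foursu"`, `"chip"`, `"drb"` or `"pas"`.
#' @param arm `"ctrl"` or `"aux"`.
#' @param rep Replicate number.
#' @param config The [synth_config()] used for the cohort.
#' @param chase_min Chase time for `assay = "drb"` (default 20).
#' @param noiseless Emit the expected means instead of NB draws.
#' @return Named list of `window_vector`s (one per gene).
#' @export
generate_counts <- function(cohort, assay = c("foursu", "chip", "drb",
                                              "pas"),
                            arm = c("ctrl", "aux"), rep = 1L, config,
                            chase_min = 20, noiseless = FALSE) {
  assay <- match.arg(assay)
  arm <- match.arg(arm)
  truth <- cohort$truth
  out <- vector("list", nrow(truth))
  names(out) <- truth$gene
  for (g in seq_len(nrow(truth))) {
    tu <- cohort$tus[[truth$gene[g]]]
    set.seed(stream_seed(config$seed, truth$gene[g], assay, arm, rep,
                         if (assay == "drb") chase_min else 0))
    d <- if (arm == "ctrl") truth$d_ctrl[g] else truth$d_treat[g]
    e <- if (arm == "ctrl") truth$e_ctrl[g] else truth$e_treat[g]
    if (assay %in% c("foursu", "chip")) {
      win <- make_windows(tu, "body")
      i <- win$index
      mu <- truth$expr[g] * (1 + d)^(-(i - 1))
    } else if (assay == "drb") {
      win <- make_windows(tu, "body")
      L <- nrow(win)
      if (L == 0) { out[[g]] <- NULL; next }
      sig <- drb_foursu_kb(truth$p[g], e, d, L, chase_min,
                           resolution_kb = 0.01)
      mu <- truth$expr[g] * sig / max(sig[1], 1e-12) +
        config$bg_frac * truth$expr[g]
    } else {
      win <- make_windows(tu, "pas")
      r <- if (arm == "ctrl") truth$r_term_ctrl[g] else truth$r_term_treat[g]
      dens <- truth$expr[g] / 4  # per 250 nt window
      i_down <- pmax(win$rel, 0) / 250
      mu <- ifelse(win$rel < 0, dens, dens * exp(-r * i_down))
    }
    counts <- if (noiseless) mu else
      stats::rnbinom(length(mu), size = config$nb_size_seq, mu = mu)
    missing <- rep(FALSE, nrow(win))
    if (nrow(tu$exons) > 0) {
      missing <- win$start < max(tu$exons$end) &
        win$end > min(tu$exons$start) &
        apply(outer(win$start, tu$exons$end, "<") &
                outer(win$end, tu$exons$start, ">"), 1, any)
    }
    kind <- if (assay == "pas") "pas" else "body"
    wv <- window_vector(tu$id, kind, win$end[1] - win$start[1],
                        counts, missing, win$rel)
    out[[g]] <- wv
  }
  out[!vapply(out, is.null, TRUE)]
}

#' Generate a synthetic SLAM-seq table
#'
#' Control-arm levels follow the steady-state curves; the treated arm
#' starts from the control steady state (`a0 = sigma_ctrl / delta`) with
#' the reduced synthesis rate. Counts are NB draws around the total
#' level; NTRs are Beta draws around the model ratio
#' `f_new / (f_new + f_old)` with precision `ntr_kappa`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param config The [synth_config()].
#' @param noiseless Emit exact model values.
#' @return data.frame with columns `gene`, `arm`, `time_h`, `rep`,
#'   `count`, `ntr`.
#' @export
generate_slam <- function(cohort, config, noiseless = FALSE) {
  truth <- cohort$truth
  grid <- expand.grid(gene = truth$gene, arm = c("ctrl", "aux"),
                      time_h = config$timepoints_h,
                      rep = seq_len(config$reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$gene, grid$arm, grid$time_h, grid$rep), ]
  rownames(grid) <- NULL
  tr <- truth[match(grid$gene, truth$gene), ]
  sigma <- ifelse(grid$arm == "ctrl", tr$sigma_ctrl, tr$sigma_aux)
  delta <- tr$delta
  a0 <- tr$sigma_ctrl / delta  # pre-depletion steady state
  ss_aux <- sigma / delta
  f_new <- ss_aux * (1 - exp(-grid$time_h * delta))
  f_old <- ifelse(grid$arm == "ctrl",
                  (tr$sigma_ctrl / delta) * exp(-grid$time_h * delta),
                  a0 * exp(-grid$time_h * delta))
  total <- f_new + f_old
  ntr_true <- ifelse(total > 0, f_new / total, 0)
  if (noiseless) {
    grid$count <- total
    grid$ntr <- ntr_true
    return(grid)
  }
  # one RNG stream per gene; all of a gene's draws are vectorized in the
  # (arm, time, rep) order fixed above
  count <- numeric(nrow(grid))
  ntr <- numeric(nrow(grid))
  for (g in unique(grid$gene)) {
    rows <- which(grid$gene == g)
    set.seed(stream_seed(config$seed, g, "slam"))
    count[rows] <- stats::rnbinom(length(rows),
                                  size = config$nb_size_slam,
                                  mu = total[rows])
    inner <- ntr_true[rows] > 0 & ntr_true[rows] < 1
    draws <- numeric(length(rows))
    draws[inner] <- stats::rbeta(sum(inner),
                                 config$ntr_kappa * ntr_true[rows][inner],
                                 config$ntr_kappa *
                                   (1 - ntr_true[rows][inner]))
    draws[!inner] <- pmin(pmax(ntr_true[rows][!inner], 0), 1)
    ntr[rows] <- draws
  }
  grid$count <- count
  grid$ntr <- ntr
  grid
}
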