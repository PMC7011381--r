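#' Per-OTU occurrence frequency
#'
#' Fraction of samples in which each OTU is detected at or above the
#' detection limit `d` (in reads).
#'
#' @param table a [count_table()].
#' @param d detection limit, reads (default 1).
#' @return Named numeric vector in [0, 1], one entry per OTU.
#' @export
occurrence_frequency <- function(table, d = 1L) {
  if (d < 1) stop("d must be >= 1")
  m <- unclass(table)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty count table")
  colMeans(m >= d)
}

#' Per-OTU mean relative abundance
#'
#' Mean over samples of each OTU's within-sample proportion; the
#' abscissa p of the neutral model. Sums to 1 over OTUs.
#'
#' @param table a [count_table()].
#' @return Named numeric vector summing to 1.
#' @export
mean_relative_abundance <- function(table) {
  colMeans(relative_abundance(table))
}

#' Sloan neutral-model occurrence prediction
#'
#' Under the neutral community model the local relative abundance of a
#' taxon with metacommunity abundance p follows a Beta(N m p, N m (1 - p))
#' distribution; the probability of detecting it at or above d reads in a
#' sample of N reads is therefore the upper tail of that Beta beyond
#' d / N:
#'   F(p; m, N, d) = 1 - I_{d/N}(N m p, N m (1 - p)),
#' with I the regularized incomplete beta function. Continuity gives
#' F(0) = 0 and F(1) = 1.
#'
#' @param p metacommunity relative abundance(s) in [0, 1] (vectorized).
#' @param m migration rate in (0, 1].
#' @param N community size (reads per sample); must exceed d.
#' @param d detection limit in reads.
#' @return Predicted occurrence frequency in [0, 1].
#' @export
predict_frequency <- function(p, m, N, d = 1L) {
  if (any(!is.finite(p)) || !is.finite(m) || !is.finite(N))
    stop("non-finite input")
  if (m <= 0 || m > 1) stop("m must be in (0, 1]")
  if (N <= d) stop("N must exceed the detection limit d")
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  out <- numeric(length(p))
  interior <- p > 0 & p < 1
  Nm <- N * m
  out[interior] <- 1 - stats::pbeta(d / N, Nm * p[interior],
                                    Nm * (1 - p[interior]))
  out[p >= 1] <- 1
  out
}

#' Wilson score interval for a binomial proportion
#'
#' @param f point estimate in [0, 1].
#' @param n number of trials.
#' @param level confidence level in (0, 1).
#' @return Numeric vector/matrix with columns `low`, `high`.
#' @export
wilson_interval <- function(f, n, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (n < 1) stop("n must be >= 1")
  if (any(f < 0 | f > 1)) stop("f must be in [0, 1]")
  z <- stats::qnorm(1 - (1 - level) / 2)
  z2 <- z^2
  denom <- 1 + z2 / n
  center <- (f + z2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(f * (1 - f) / n + z2 / (4 * n^2))
  cbind(low = pmax(0, center - half), high = pmin(1, center + half))
}

#' Fit the neutral occurrence curve to (p, f_obs) pairs
#'
#' Lower-level entry of [fit_ncm()]: estimates m by bounded nonlinear
#' least squares of observed occurrence frequencies on the neutral
#' prediction F(p; m, N, d) (multi-start bounded minimization polished
#' by golden-section search), then classifies each point against the
#' Wilson band of the given confidence level around its predicted
#' frequency.
#'
#' @param p metacommunity relative abundances.
#' @param f_obs observed occurrence frequencies in [0, 1].
#' @param N community size (reads per sample).
#' @param n_samples number of samples behind each f_obs (Wilson band n).
#' @param d detection limit, reads.
#' @param ci_level classification band confidence level.
#' @param ids optional point labels.
#' @return A list of class `ncm_fit` (see [fit_ncm()]).
#' @export
fit_ncm_curve <- function(p, f_obs, N, n_samples, d = 1L, ci_level = 0.95,
                          ids = NULL) {
  if (length(p) != length(f_obs)) stop("p and f_obs lengths differ")
  if (length(p) < 2) stop("need at least 2 points to fit")
  if (is.null(ids)) ids <- if (!is.null(names(p))) names(p)
                           else paste0("OTU", seq_along(p))
  sse <- function(mm) sum((f_obs - predict_frequency(p, mm, N, d))^2)
  fits <- lapply(c(0.01, 0.1, 0.5), function(s)
    stats::nlminb(s, sse, lower = 1e-6, upper = 1))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  opt <- stats::optimize(sse, interval = c(1e-6, 1), tol = 1e-9)
  m_hat <- if (opt$objective < best$objective) opt$minimum else best$par
  ss_res <- sse(m_hat)
  ss_tot <- sum((f_obs - mean(f_obs))^2)
  R2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  f_pred <- predict_frequency(p, m_hat, N, d)
  band <- wilson_interval(f_pred, n_samples, ci_level)
  cls <- ifelse(f_obs > band[, "high"], "above",
                ifelse(f_obs < band[, "low"], "below", "neutral"))
  otus <- data.frame(otu_id = ids, p = unname(p), f_obs = unname(f_obs),
                     f_pred = unname(f_pred),
                     ci_low = unname(band[, "low"]),
                     ci_high = unname(band[, "high"]),
                     class = unname(cls), stringsAsFactors = FALSE)
  structure(list(m = m_hat, N = N, d = d, R2 = R2, ci_level = ci_level,
                 n_samples = n_samples, otus = otus, m_ci = NULL,
                 n_excluded = 0L),
            class = "ncm_fit")
}

#' Fit the Sloan neutral community model
#'
#' Estimates the migration rate m by bounded nonlinear least squares of
#' observed occurrence frequencies against the neutral prediction
#' F(p; m, N, d), with N fixed at the mean (or median) sample read total.
#' Each OTU is then classified against the Wilson 95% band around its
#' predicted frequency: `neutral` inside the closed band, `above` over
#' it (more prevalent than neutrality allows, e.g. host-selected),
#' `below` under it. OTUs never detected are excluded from the fit
#' (they carry no information); OTUs detected everywhere are retained.
#'
#' @param table a [count_table()].
#' @param d detection limit, reads.
#' @param ci_level confidence level of the classification band.
#' @param bootstrap number of bootstrap resamples (of samples, with
#'   replacement) for an m interval; 0 disables.
#' @param N_stat `"mean"` (conventional) or `"median"` sample total.
#' @param seed seed for the bootstrap.
#' @return A list of class `ncm_fit`: `m`, `N`, `d`, `R2` (NA when all
#'   observed frequencies are identical), `n_samples`, `otus` (per-OTU
#'   data.frame with p, f_obs, f_pred, ci_low, ci_high, class),
#'   `m_ci` (bootstrap percentile interval or NULL).
#' @export
fit_ncm <- function(table, d = 1L, ci_level = 0.95, bootstrap = 0L,
                    N_stat = c("mean", "median"), seed = 1L) {
  N_stat <- match.arg(N_stat)
  m_counts <- unclass(table)
  n_samples <- nrow(m_counts)
  if (n_samples < 10)
    warning("fewer than 10 samples; the neutral fit will be coarse")
  totals <- rowSums(m_counts)
  N <- if (N_stat == "mean") mean(totals) else stats::median(totals)
  f_obs_all <- occurrence_frequency(table, d)
  p_all <- mean_relative_abundance(table)
  keep <- f_obs_all > 0
  if (sum(keep & f_obs_all < 1) < 2)
    stop("need at least 2 OTUs with intermediate occurrence to fit")
  p <- p_all[keep]
  f_obs <- f_obs_all[keep]
  fit <- fit_ncm_curve(p, f_obs, N, n_samples, d = d, ci_level = ci_level,
                       ids = names(p))
  m_ci <- NULL
  if (bootstrap > 0) {
    set.seed(seed_stream(seed, 900000))
    ms <- vapply(seq_len(bootstrap), function(b) {
      idx <- sample.int(n_samples, n_samples, replace = TRUE)
      sub <- count_table(m_counts[idx, , drop = FALSE],
                         sample_ids = paste0("B", seq_len(n_samples)))
      tryCatch(fit_ncm(sub, d = d, ci_level = ci_level, bootstrap = 0L,
                       N_stat = N_stat)$m,
               error = function(e) NA_real_)
    }, numeric(1))
    m_ci <- stats::quantile(ms, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
                            na.rm = TRUE, names = FALSE)
  }
  fit$m_ci <- m_ci
  fit$n_excluded <- sum(!keep)
  fit
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan neutral community model fit\n  m = %.4f  N = %.1f  R2 = %s  (%d samples, %d OTUs fitted, %d never detected)\n",
              x$m, x$N, ifelse(is.na(x$R2), "NA", sprintf("%.3f", x$R2)),
              x$n_samples, nrow(x$otus), x$n_excluded))
  tb <- table(factor(x$otus$class, c("neutral", "above", "below")))
  cat(sprintf("  classes: %d neutral / %d above / %d below\n",
              tb["neutral"], tb["above"], tb["below"]))
  invisible(x)
}

#' Neutral-fraction summary across strata
#'
#' One row per stratum (e.g. habitat x treatment x timepoint) with the
#' percentage of fitted OTUs classified neutral / above / below the
#' neutral band, plus the stratum's m and R2. Percentages sum to 100.
#'
#' @param fits named list of [fit_ncm()] results (NULL entries allowed
#'   for strata that could not be fitted; they are flagged, not dropped).
#' @return data.frame with columns stratum, n_otus, pct_neutral,
#'   pct_above, pct_below, m, R2, n_samples.
#' @export
neutral_fraction_summary <- function(fits) {
  if (is.null(names(fits))) names(fits) <- seq_along(fits)
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (is.null(f))
      return(data.frame(stratum = nm, n_otus = 0L, pct_neutral = NA_real_,
                        pct_above = NA_real_, pct_below = NA_real_,
                        m = NA_real_, R2 = NA_real_, n_samples = 0L,
                        stringsAsFactors = FALSE))
    cl <- factor(f$otus$class, c("neutral", "above", "below"))
    pct <- 100 * as.numeric(table(cl)) / length(cl)
    data.frame(stratum = nm, n_otus = length(cl), pct_neutral = pct[1],
               pct_above = pct[2], pct_below = pct[3], m = f$m, R2 = f$R2,
               n_samples = f$n_samples, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
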