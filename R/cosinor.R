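#' RPKM normalisation
#'
#' Converts raw read counts to reads per kilobase of transcript per
#' million mapped reads: `count / (length/1000) / (library_size/1e6)`.
#'
#' @param counts Integer matrix, transcripts x samples.
#' @param lengths Transcript lengths in bp (one per row), all > 0.
#' @param library_sizes Mapped reads per sample (one per column), all > 0.
#' @return Numeric matrix of RPKM values with the dimnames of `counts`.
#' @examples
#' compute_rpkm(matrix(10), lengths = 1000, library_sizes = 1e6) # 10
#' @export
compute_rpkm <- function(counts, lengths, library_sizes) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts))
    stop("'lengths' must have one entry per transcript row")
  if (length(library_sizes) != ncol(counts))
    stop("'library_sizes' must have one entry per sample column")
  bad <- which(lengths <= 0)
  if (length(bad))
    stop("nonpositive transcript length for: ",
         paste(if (is.null(rownames(counts))) bad else
               rownames(counts)[bad], collapse = ", "))
  bad <- which(library_sizes <= 0)
  if (length(bad))
    stop("nonpositive library size for sample(s): ",
         paste(bad, collapse = ", "))
  sweep(sweep(counts, 1, lengths / 1e3, "/"), 2, library_sizes / 1e6, "/")
}

# Design matrix of the first-harmonic cosinor model
# y = m + a*cos(wt) + b*sin(wt).
harmonic_design <- function(time, period) {
  w <- 2 * pi / period
  cbind(intercept = rep(1, length(time)),
        cosw = cos(w * time), sinw = sin(w * time))
}

n_distinct_times <- function(time, period) {
  length(unique(round(time %% period, 6)))
}

#' Fit a fixed-period cosine curve to a single expression series
#'
#' Least-squares cosinor regression
#' `y = m + a*cos(wt) + b*sin(wt)`, `w = 2*pi/period`, which is exactly
#' equivalent to fitting `m + A*cos(w*(t - phi))` over all phase shifts
#' `phi`: the amplitude is `A = sqrt(a^2 + b^2)` and the peak phase
#' `phi = atan2(b, a)/w`. Significance is the F-test of the two harmonic
#' terms against the intercept-only model (df 2 and n - 3). Replicates
#' and multi-day samples need no special handling: they enter through the
#' periodic regressors via `t mod period`.
#'
#' @param time Sampling times in hours.
#' @param values Expression values, same length as `time`.
#' @param period Oscillation period in hours (default 24).
#' @return An object of class `"cosine_fit"`: list with `mesor` (fitted
#'   baseline m), `amplitude` (A), `phase` (peak time in `[0, period)`;
#'   0 by convention when A = 0), `p_value` (floored at 1e-300),
#'   `relative_amplitude` (`log2((m+A)/(m-A))`, `NA` when `m <= A`),
#'   `coefficients`, `n`, `period`.
#' @details A constant series is not an error: it returns `amplitude = 0`
#'   and `p_value = 1`. Fewer than 4 distinct times modulo the period
#'   leave the 3-parameter fit underdetermined and raise an error.
#' @examples
#' t <- seq(0, 44, by = 4)
#' f <- fit_cosine(t, 5 + 2 * cos(2 * pi * (t - 6) / 24))
#' round(c(f$mesor, f$amplitude, f$phase), 3) # 5 2 6
#' @export
fit_cosine <- function(time, values, period = 24) {
  stopifnot(length(time) == length(values), period > 0)
  if (anyNA(values) || any(!is.finite(values)))
    stop("'values' must be finite")
  if (n_distinct_times(time, period) < 4L)
    stop("need >= 4 distinct sampling times modulo the period")
  res <- cosinor_fit_matrix(matrix(values, nrow = 1), time, period)
  structure(list(mesor = res$mesor, amplitude = res$amplitude,
                 phase = res$phase, p_value = res$p_value,
                 relative_amplitude = res$relative_amplitude,
                 coefficients = c(m = res$mesor, a = res$cos_coef,
                                  b = res$sin_coef),
                 n = length(values), period = period),
            class = "cosine_fit")
}

#' @export
print.cosine_fit <- function(x, ...) {
  cat(sprintf(
    "Cosinor fit (period %g h): mesor %.4g, amplitude %.4g, peak CT%.2f, p = %.3g\n",
    x$period, x$mesor, x$amplitude, x$phase, x$p_value))
  invisible(x)
}

#' Cosinor fits for every row of a time-series matrix
#'
#' Vectorised version of [fit_cosine()] sharing one design matrix across
#' transcripts.
#'
#' @param x A [time_series_matrix()] object, or a plain numeric matrix in
#'   which case `time` must be given.
#' @param time Sampling times in hours (ignored when `x` is a `tsm`).
#' @param period Period in hours.
#' @return Data frame with one row per transcript: `transcript`, `mesor`,
#'   `amplitude`, `phase`, `p_value`, `relative_amplitude`, `cos_coef`,
#'   `sin_coef`.
#' @export
fit_cosine_matrix <- function(x, time = NULL, period = 24) {
  if (inherits(x, "tsm")) {
    time <- x$time
    x <- x$values
  }
  x <- as.matrix(x)
  if (is.null(time) || length(time) != ncol(x))
    stop("'time' must have one entry per sample column")
  if (n_distinct_times(time, period) < 4L)
    stop("need >= 4 distinct sampling times modulo the period")
  out <- cosinor_fit_matrix(x, time, period)
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("transcript_", seq_len(nrow(x)))
  cbind(data.frame(transcript = ids, stringsAsFactors = FALSE), out)
}

# Shared workhorse: rows of 'values' fitted against one harmonic design.
cosinor_fit_matrix <- function(values, time, period) {
  X <- harmonic_design(time, period)
  qrX <- qr(X)
  if (qrX$rank < 3L)
    stop("harmonic design is rank deficient for these sampling times")
  B <- t(qr.coef(qrX, t(values)))          # transcripts x 3
  fitted <- B %*% t(X)
  rss1 <- rowSums((values - fitted)^2)
  mu <- rowMeans(values)
  rss0 <- rowSums((values - mu)^2)
  n <- ncol(values)
  df2 <- n - 3L
  Fstat <- ((rss0 - rss1) / 2) / (rss1 / df2)
  p <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
  amp <- sqrt(B[, 2]^2 + B[, 3]^2)
  w <- 2 * pi / period
  phase <- (atan2(B[, 3], B[, 2]) / w) %% period
  # Degenerate rows: constant series carry no rhythm evidence (p = 1);
  # perfect fits would give p = 0, floored to keep -log2(p) finite.
  const <- rss0 <= 1e-12 * pmax(1, mu^2)
  if (any(const)) {
    p[const] <- 1
    amp[const] <- 0
    phase[const] <- 0
  }
  p[!is.finite(p)] <- 1
  p <- pmax(p, P_FLOOR)
  mesor <- B[, 1]
  ra <- ifelse(mesor > amp, log2((mesor + amp) / (mesor - amp)), NA_real_)
  data.frame(mesor = mesor, amplitude = amp, phase = phase,
             p_value = p, relative_amplitude = ra,
             cos_coef = B[, 2], sin_coef = B[, 3], row.names = NULL)
}

#' Cross-dataset circadian consistency score
#'
#' Combines two independent cosinor fits of the same transcript into the
#' significance score `S = -log2(p1) - log2(p2)` (bits) and the circular
#' phase difference, and applies the rhythmicity rule: a transcript
#' passes when `S > score_min` (strict) and the phase difference is
#' strictly below `phasediff_max` hours.
#'
#' @param fit1,fit2 Objects of class `"cosine_fit"` (from [fit_cosine()]),
#'   or lists with elements `p_value` and `phase`.
#' @param score_min Score threshold in bits (default 9).
#' @param phasediff_max Maximal phase difference in hours (default 4).
#' @param period Period in hours (for the circular arithmetic).
#' @return List of class `"consistency_result"`: `score`, `phase_diff`,
#'   `combined_phase` (circular mean of the two phases weighted by
#'   `-log2(p)`), `pass`, `p_floored` (were p-values clipped at 1e-300?).
#' @examples
#' f1 <- list(p_value = 2^-12.56, phase = 23.5)
#' f2 <- list(p_value = 2^-12.56, phase = 0.5)
#' consistency_score(f1, f2)$score # 25.12
#' @export
consistency_score <- function(fit1, fit2, score_min = 9, phasediff_max = 4,
                              period = 24) {
  p1 <- fit1$p_value; p2 <- fit2$p_value
  stopifnot(is.finite(p1), is.finite(p2), p1 >= 0, p2 >= 0,
            p1 <= 1, p2 <= 1)
  floored <- (p1 < P_FLOOR) || (p2 < P_FLOOR)
  p1 <- max(p1, P_FLOOR); p2 <- max(p2, P_FLOOR)
  s <- -log2(p1) - log2(p2)
  dphi <- circular_diff(fit1$phase, fit2$phase, period)
  comb <- circular_mean(c(fit1$phase, fit2$phase),
                        weights = c(-log2(p1), -log2(p2)), period = period)
  structure(list(score = s, phase_diff = dphi, combined_phase = comb,
                 pass = (s > score_min) && (dphi < phasediff_max),
                 p_floored = floored),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("Consistency: S = %.2f bits, dphase = %.2f h, phase = %s, %s\n",
              x$score, x$phase_diff,
              ifelse(is.na(x$combined_phase), "NA",
                     sprintf("CT%.2f", x$combined_phase)),
              if (x$pass) "PASS" else "fail"))
  invisible(x)
}

#' Detect consistently circadian transcripts across two datasets
#'
#' Runs the full primary-transcript rhythmicity pipeline: cosinor fits in
#' each dataset, the consistency score, the phase-difference test, and
#' the pass flag, for every transcript present in both matrices.
#'
#' @param tsm1,tsm2 [time_series_matrix()] objects sharing transcript ids
#'   (analysis is restricted to the intersection, with a warning if the
#'   sets differ).
#' @param period Period in hours (default 24).
#' @param score_min,phasediff_max Pass thresholds (defaults 9 bits, 4 h).
#' @return Data frame with one row per transcript: per-dataset p-values,
#'   phases and amplitudes, `score`, `phase_diff`, `combined_phase`,
#'   `pass`.
#' @seealso [joint_phase_fit()] for the alternative shared-phase fit;
#'   [permute_and_score()] for the FDR of the pass rule.
#' @export
detect_rhythmic <- function(tsm1, tsm2, period = 24, score_min = 9,
                            phasediff_max = 4) {
  stopifnot(inherits(tsm1, "tsm"), inherits(tsm2, "tsm"))
  common <- intersect(rownames(tsm1$values), rownames(tsm2$values))
  if (length(common) == 0L) stop("matrices share no transcripts")
  if (length(common) < nrow(tsm1$values) ||
      length(common) < nrow(tsm2$values))
    warning("restricting to ", length(common), " shared transcripts")
  f1 <- fit_cosine_matrix(tsm1$values[common, , drop = FALSE], tsm1$time,
                          period)
  f2 <- fit_cosine_matrix(tsm2$values[common, , drop = FALSE], tsm2$time,
                          period)
  score <- -log2(f1$p_value) - log2(f2$p_value)
  dphi <- circular_diff(f1$phase, f2$phase, period)
  comb <- vapply(seq_along(common), function(i)
    circular_mean(c(f1$phase[i], f2$phase[i]),
                  weights = c(-log2(f1$p_value[i]), -log2(f2$p_value[i])),
                  period = period), numeric(1))
  data.frame(transcript = common,
             p_value1 = f1$p_value, p_value2 = f2$p_value,
             phase1 = f1$phase, phase2 = f2$phase,
             amplitude1 = f1$amplitude, amplitude2 = f2$amplitude,
             relative_amplitude1 = f1$relative_amplitude,
             relative_amplitude2 = f2$relative_amplitude,
             score = score, phase_diff = dphi, combined_phase = comb,
             pass = (score > score_min) & (dphi < phasediff_max),
             stringsAsFactors = FALSE)
}

#' Joint shared-phase cosinor fit across two datasets
#'
#' Alternative reading of a "common cosine with shifting phase" across
#' two datasets: one peak phase shared by both series, with
#' dataset-specific baseline and amplitude, profiled over a phase grid.
#' Exposed for comparison; [detect_rhythmic()] (separate fits plus a
#' consistency test) is the default pipeline.
#'
#' @param time1,values1,time2,values2 The two series.
#' @param period Period in hours.
#' @param grid_step Phase grid resolution in hours (default 0.01).
#' @return List with `phase` (shared), per-dataset `amplitude`, `mesor`
#'   and `p_value` (F-test of the fixed-phase cosine term, df 1), and
#'   `total_rss`.
#' @export
joint_phase_fit <- function(time1, values1, time2, values2, period = 24,
                            grid_step = 0.01) {
  w <- 2 * pi / period
  grid <- seq(0, period - grid_step, by = grid_step)
  rss_at <- function(time, values, phi) {
    X <- cbind(1, cos(w * (time - phi)))
    f <- stats::lm.fit(X, values)
    sum(f$residuals^2)
  }
  # Coarse-to-fine would be faster; an explicit scan keeps this honest as
  # a reference implementation.
  tot <- vapply(grid, function(phi)
    rss_at(time1, values1, phi) + rss_at(time2, values2, phi), numeric(1))
  phi <- grid[which.min(tot)]
  one <- function(time, values, phi) {
    X <- cbind(1, cos(w * (time - phi)))
    f <- stats::lm.fit(X, values)
    rss1 <- sum(f$residuals^2)
    rss0 <- sum((values - mean(values))^2)
    df2 <- length(values) - 2L
    Fst <- (rss0 - rss1) / (rss1 / df2)
    p <- stats::pf(Fst, 1, df2, lower.tail = FALSE)
    amp <- f$coefficients[2]
    list(mesor = unname(f$coefficients[1]), amplitude = unname(amp),
         p_value = max(ifelse(is.finite(p), p, 1), P_FLOOR))
  }
  d1 <- one(time1, values1, phi)
  d2 <- one(time2, values2, phi)
  # A negative fitted amplitude means the antiphase is the true peak.
  if (d1$amplitude + d2$amplitude < 0) {
    phi <- (phi + period / 2) %% period
    d1$amplitude <- -d1$amplitude
    d2$amplitude <- -d2$amplitude
  }
  list(phase = phi, mesor1 = d1$mesor, mesor2 = d2$mesor,
       amplitude1 = d1$amplitude, amplitude2 = d2$amplitude,
       p_value1 = d1$p_value, p_value2 = d2$p_value,
       total_rss = min(tot))
}

#' Relaxed rhythmicity test for mature miRNA series with replicates
#'
#' Mature miRNA oscillations are dampened, so they are tested with
#' relaxed criteria: a one-way ANOVA across time-point groups and a
#' cosinor fit on all points, both at p < 0.05.
#'
#' @param time Sampling times in hours (replicated times repeat).
#' @param values Expression values.
#' @param period Period in hours.
#' @param alpha Significance cutoff applied to both tests (default 0.05).
#' @return List with `anova_p`, `cosine_p`, `pass` and the underlying
#'   `fit` (class `"cosine_fit"`).
#' @details Requires at least two time groups and at least one group with
#'   two or more replicates; otherwise the ANOVA has no residual degrees
#'   of freedom and an error is raised.
#' @export
mature_rhythm_test <- function(time, values, period = 24, alpha = 0.05) {
  stopifnot(length(time) == length(values))
  g <- factor(time)
  if (nlevels(g) < 2L) stop("need >= 2 time groups")
  if (all(table(g) < 2L))
    stop("one-way ANOVA undefined: every time group is a singleton")
  if (stats::var(values) <= 1e-12 * max(1, mean(values)^2)) {
    anova_p <- 1
  } else {
    aovtab <- stats::anova(stats::lm(values ~ g))
    anova_p <- aovtab[["Pr(>F)"]][1]
    if (!is.finite(anova_p)) anova_p <- 1
  }
  fit <- fit_cosine(time, values, period)
  list(anova_p = anova_p, cosine_p = fit$p_value,
       pass = (anova_p < alpha) && (fit$p_value < alpha), fit = fit)
}
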