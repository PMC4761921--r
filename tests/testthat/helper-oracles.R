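# Independent reference implementations ("oracles") used to validate the
# package's vectorised code paths. They deliberately use brute force /
# enumeration / generic solvers rather than the package's own algebra.

# Exhaustive phase-grid cosinor fit: at every candidate phase the
# amplitude is estimated by ordinary least squares of
# y ~ 1 + cos(w*(t - phi)); the phase minimising the SSE wins, polished
# within one grid step by a 1-d minimiser of the same constrained SSE.
grid_cosine_oracle <- function(time, values, period = 24, step = 0.01) {
  w <- 2 * pi / period
  sse_at <- function(phi) {
    X <- cbind(1, cos(w * (time - phi)))
    sum(lm.fit(X, values)$residuals^2)
  }
  grid <- seq(0, period - step, by = step)
  sse <- vapply(grid, sse_at, numeric(1))
  i <- which.min(sse)
  phi <- stats::optimize(sse_at, c(grid[i] - step, grid[i] + step),
                         tol = 1e-10)$minimum %% period
  X <- cbind(1, cos(w * (time - phi)))
  cf <- lm.fit(X, values)$coefficients
  amp <- unname(cf[2])
  if (amp < 0) {                    # antiphase has the positive amplitude
    phi <- (phi + period / 2) %% period
    amp <- -amp
  }
  list(phase = phi, amplitude = amp, mesor = unname(cf[1]))
}

# Explicit sums-of-squares two-way ANOVA for a balanced 2x2xr design
# (main effects, no interaction): SS_factor / df over SS_resid / df.
ss_anova_oracle <- function(y, time, treatment) {
  n <- length(y)
  g <- mean(y)
  ss_of <- function(f) {
    mu <- tapply(y, f, mean)
    cnt <- table(f)
    sum(cnt * (mu[names(cnt)] - g)^2)
  }
  ss_time <- ss_of(time)
  ss_trt <- ss_of(treatment)
  ss_tot <- sum((y - g)^2)
  ss_res <- ss_tot - ss_time - ss_trt
  df_res <- n - 3
  list(f_time = (ss_time / 1) / (ss_res / df_res),
       f_treatment = (ss_trt / 1) / (ss_res / df_res))
}

# Two-sided Fisher exact p by explicit hypergeometric enumeration: sum
# the probabilities of all tables (along the observed margins) no more
# probable than the observed one.
fisher_enum_oracle <- function(a, b, cc, d) {
  m <- a + b
  n2 <- cc + d
  k <- a + cc
  supp <- max(0, k - n2):min(k, m)
  probs <- dhyper(supp, m, n2, k)
  pobs <- dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# O(n * m) brute-force regulator assignment in BED (0-based half-open)
# coordinates, independent of GenomicRanges.
quadratic_assign_oracle <- function(tr_df, peak_df, upstream = 5000,
                                    min_support = c(BMAL1 = 2),
                                    default_support = 1) {
  # tr_df: id, start0, end0, strand; peak_df: start0, end0, regulator,
  # support (all on one chromosome)
  edges <- list()
  for (i in seq_len(nrow(tr_df))) {
    if (tr_df$strand[i] == "+") {
      ws <- max(0, tr_df$start0[i] - upstream); we <- tr_df$end0[i]
    } else {
      ws <- tr_df$start0[i]; we <- tr_df$end0[i] + upstream
    }
    for (j in seq_len(nrow(peak_df))) {
      reg <- peak_df$regulator[j]
      req <- if (reg %in% names(min_support)) min_support[[reg]]
             else default_support
      if (peak_df$support[j] < req) next
      if (peak_df$start0[j] < we && peak_df$end0[j] > ws)   # >=1 bp shared
        edges[[length(edges) + 1L]] <-
          data.frame(regulator = reg, transcript = tr_df$id[i],
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(edges))
    return(data.frame(regulator = character(), transcript = character()))
  out <- unique(do.call(rbind, edges))
  out <- out[order(out$regulator, out$transcript), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Numerical steady-state attenuation of dP/dt = s0*(1 + a cos(w t)) - kP,
# via deSolve integration past the transient followed by a harmonic
# regression on the final period.
ode_attenuation_oracle <- function(half_life, period = 24, a = 0.5) {
  k <- log(2) / half_life
  w <- 2 * pi / period
  Tend <- max(16 / k, 10 * period)
  deriv <- function(t, y, parms) list(1 + a * cos(w * t) - k * y)
  times <- c(seq(0, Tend - period, length.out = 100),
             seq(Tend - period, Tend, by = period / 96))
  out <- deSolve::ode(y = c(P = 1 / k), times = times, func = deriv,
                      parms = NULL, rtol = 1e-10, atol = 1e-10)
  tail_idx <- out[, "time"] >= Tend - period
  tt <- out[tail_idx, "time"]
  pp <- out[tail_idx, "P"]
  cf <- lm(pp ~ cos(w * tt) + sin(w * tt))$coefficients
  amp <- sqrt(cf[2]^2 + cf[3]^2)
  unname((amp / cf[1]) / a)
}

# Deterministic GRanges builders for network tests.
make_transcripts <- function(start0, end0, strand, ids = NULL) {
  gr <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(start0 + 1, end0), strand = strand)
  if (is.null(ids)) ids <- paste0("t", seq_along(gr))
  S4Vectors::mcols(gr)$transcript_id <- ids
  gr
}

make_peaks <- function(start0, end0, regulator = "BMAL1", support = 2L) {
  gr <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(start0 + 1, end0), strand = "*")
  S4Vectors::mcols(gr)$regulator <- rep_len(regulator, length(gr))
  S4Vectors::mcols(gr)$n_supporting_datasets <-
    as.integer(rep_len(support, length(gr)))
  gr
}
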