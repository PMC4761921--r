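#' Parameters for the paired nascent-transcription simulator
#'
#' Defaults emulate the study conditions of the real datasets: dataset A
#' mirrors a GRO-seq style course sampled every 4 h over 48 h (12
#' points), dataset B a Nascent-seq style course on a different grid
#' (every 3 h over 24 h, 8 points) to exercise unequal designs; planted
#' rhythms have log2 peak-to-trough folds of 1–3 (at least 2-fold) with
#' phases uniform on [0, 24), and measurement noise is multiplicative
#' lognormal — nascent RPKM is positive and right-skewed, and the
#' lognormal keeps positivity without truncation.
#'
#' @param n_transcripts Number of transcripts.
#' @param frac_rhythmic Fraction planted rhythmic, in `[0, 1]`.
#' @param sampling_start,sampling_step,n_points Grid of dataset A in
#'   hours (defaults 0, 4, 12: "every four hours for 48 hours").
#' @param sampling_start_b,sampling_step_b,n_points_b Grid of dataset B
#'   (defaults 0, 3, 8).
#' @param baseline_log_mean,baseline_log_sd Natural-log scale of
#'   baseline expression.
#' @param rel_amplitude_range Range (length 2) of planted log2
#'   peak-to-trough folds for rhythmic transcripts.
#' @param noise_sd Sigma of the multiplicative lognormal noise.
#' @param phase_noise_sd SD in hours of independent per-dataset jitter
#'   added to the planted phase (default 0: the two datasets share
#'   phases exactly).
#' @param seed RNG seed.
#' @return Validated list of class `"rhythm_sim_params"`.
#' @export
rhythm_sim_params <- function(n_transcripts = 1000, frac_rhythmic = 0.2,
                              sampling_start = 0, sampling_step = 4,
                              n_points = 12, sampling_start_b = 0,
                              sampling_step_b = 3, n_points_b = 8,
                              baseline_log_mean = 3, baseline_log_sd = 1,
                              rel_amplitude_range = c(1, 3),
                              noise_sd = 0.2, phase_noise_sd = 0,
                              seed = 1L) {
  stopifnot(n_transcripts >= 1,
            frac_rhythmic >= 0, frac_rhythmic <= 1,
            sampling_step > 0, sampling_step_b > 0,
            baseline_log_sd >= 0, noise_sd >= 0, phase_noise_sd >= 0,
            length(rel_amplitude_range) == 2,
            all(rel_amplitude_range > 0),
            diff(rel_amplitude_range) >= 0)
  if (n_points < 4L || n_points_b < 4L)
    stop("need >= 4 time points per dataset: the cosinor fit is ",
         "underdetermined below that")
  structure(as.list(environment()), class = "rhythm_sim_params")
}

# log2 peak/trough fold r <-> fractional amplitude a of
# exp(b) * (1 + a cos): (1+a)/(1-a) = 2^r.
fold_to_amplitude <- function(r) (2^r - 1) / (2^r + 1)

#' Simulate a pair of nascent-transcription time courses
#'
#' Generates two datasets sharing transcripts and planted phases (up to
#' optional jitter) but with independent noise and, by default,
#' different sampling grids. Rhythmic transcripts follow
#' `value(t) = exp(b) * (1 + a*cos(2*pi*(t - phi)/24)) * lognormal noise`
#' with fractional amplitude `a` in (0, 1); non-rhythmic transcripts
#' have `a = 0`.
#'
#' @param params A [rhythm_sim_params()] object.
#' @param phases Optional vector overriding the planted phases (hours).
#' @param amplitudes Optional vector overriding the planted fractional
#'   amplitudes `a` (rhythmic transcripts only are affected by the
#'   `frac_rhythmic` mask); values must be < 1 (expression would
#'   otherwise go negative).
#' @param period Period in hours (default 24).
#' @return List with `dataset_a`, `dataset_b` (both
#'   [time_series_matrix()]) and `truth` (data frame: `transcript`,
#'   `rhythmic`, `phase`, `rel_amplitude` in log2 folds, `amplitude_a`,
#'   `baseline_log`).
#' @export
simulate_nascent_pair <- function(params, phases = NULL, amplitudes = NULL,
                                  period = 24) {
  stopifnot(inherits(params, "rhythm_sim_params"))
  set.seed(as.integer(params$seed))
  n <- params$n_transcripts
  n_r <- round(params$frac_rhythmic * n)
  rhythmic <- seq_len(n) <= n_r
  phi <- if (is.null(phases)) stats::runif(n, 0, period)
         else rep_len(phases, n) %% period
  r <- stats::runif(n, params$rel_amplitude_range[1],
                    params$rel_amplitude_range[2])
  a <- if (is.null(amplitudes)) fold_to_amplitude(r)
       else rep_len(amplitudes, n)
  if (any(a >= 1))
    stop("fractional amplitude >= 1 would give negative expression")
  a[!rhythmic] <- 0
  b <- stats::rnorm(n, params$baseline_log_mean, params$baseline_log_sd)
  ids <- sprintf("transcript_%04d", seq_len(n))
  w <- 2 * pi / period
  one_dataset <- function(t, label) {
    phi_d <- phi + if (params$phase_noise_sd > 0)
      stats::rnorm(n, 0, params$phase_noise_sd) else 0
    signal <- exp(b) * (1 + a * cos(w * outer(phi_d, t, function(p, tt)
      tt - p)))
    noise <- matrix(exp(stats::rnorm(n * length(t), 0, params$noise_sd)),
                    n, length(t))
    v <- signal * noise
    rownames(v) <- ids
    time_series_matrix(v, time = t, dataset = label)
  }
  t_a <- params$sampling_start +
    params$sampling_step * (seq_len(params$n_points) - 1)
  t_b <- params$sampling_start_b +
    params$sampling_step_b * (seq_len(params$n_points_b) - 1)
  da <- one_dataset(t_a, "dataset_A")
  db <- one_dataset(t_b, "dataset_B")
  truth <- data.frame(transcript = ids, rhythmic = rhythmic,
                      phase = ifelse(rhythmic, phi, NA_real_),
                      rel_amplitude = ifelse(rhythmic,
                                             log2((1 + a) / (1 - a)),
                                             0),
                      amplitude_a = a, baseline_log = b,
                      stringsAsFactors = FALSE)
  list(dataset_a = da, dataset_b = db, truth = truth)
}

#' Simulate mature-miRNA series from primary-transcript ground truth
#'
#' Mature miRNA levels are the steady-state response of first-order
#' decay driven by the (rhythmic) primary-transcript synthesis,
#' `dP/dt = s(t) - k*P`: each rhythmic primary with fractional amplitude
#' `a` yields a mature series with amplitude `a * k/sqrt(k^2 + omega^2)`
#' and a peak delayed by `atan(omega/k)/omega` hours, where
#' `k = ln(2)/half_life` (see [kinetic_attenuation()]). With the
#' literature mammalian average half-life of 119 h the oscillation is
#' attenuated ~45-fold, reproducing the near-flat mature profiles that
#' motivate detecting rhythms at the primary level.
#'
#' @param primary_truth Ground-truth data frame from
#'   [simulate_nascent_pair()].
#' @param half_life Mature miRNA half-life in hours (default 119).
#' @param period Period in hours (default 24).
#' @param sampling_start,sampling_step,n_points Sampling grid (defaults
#'   0, 4, 6: one day at 4-h steps).
#' @param reps Replicates per time point (default 3).
#' @param noise_sd Sigma of multiplicative lognormal measurement noise
#'   (default 0.1).
#' @param seed RNG seed.
#' @return A [time_series_matrix()] of mature levels (arbitrary units;
#'   baselines are rescaled so attenuation acts on the relative, not the
#'   absolute, level).
#' @export
simulate_mature <- function(primary_truth, half_life = 119, period = 24,
                            sampling_start = 0, sampling_step = 4,
                            n_points = 6, reps = 3, noise_sd = 0.1,
                            seed = 1L) {
  stopifnot(half_life > 0, period > 0, n_points >= 1, reps >= 1)
  att <- kinetic_attenuation(half_life, period)
  set.seed(as.integer(seed))
  a_m <- primary_truth$amplitude_a * att$attenuation
  phi_m <- (ifelse(is.na(primary_truth$phase), 0, primary_truth$phase) +
              att$phase_lag) %% period
  b <- primary_truth$baseline_log
  t0 <- sampling_start + sampling_step * (seq_len(n_points) - 1)
  t <- rep(t0, each = reps)
  repl <- rep(seq_len(reps), times = n_points)
  n <- nrow(primary_truth)
  w <- 2 * pi / period
  signal <- exp(b) * (1 + a_m * cos(w * outer(phi_m, t, function(p, tt)
    tt - p)))
  noise <- matrix(exp(stats::rnorm(n * length(t), 0, noise_sd)),
                  n, length(t))
  v <- signal * noise
  rownames(v) <- primary_truth$transcript
  time_series_matrix(v, time = t, replicate = repl, dataset = "mature")
}

#' Parameters for the over-expression experiment simulator
#'
#' Defaults emulate a 2 (CT10/CT22) x 2 (over-expression/control) liver
#' RNA-seq design with two replicate animals per cell; planted treatment
#' effects are predominantly repressive (8:1 under- vs over-expressed,
#' matching the strong inhibitory skew expected of a miRNA), and planted
#' repressed genes are annotated as miRNA targets at elevated odds.
#'
#' @param n_genes Number of genes.
#' @param frac_treatment_affected Fraction with a planted treatment
#'   effect.
#' @param frac_under_vs_over Among affected genes, fraction repressed
#'   (default 8/9).
#' @param frac_time_affected Fraction with a planted time (rhythm)
#'   effect; peak side is CT10 or CT22 with equal probability.
#' @param effect_log2fc Magnitude of planted effects in log2 units
#'   (default 1).
#' @param reps_per_cell Replicates per design cell (>= 2; the ANOVA
#'   needs residual degrees of freedom).
#' @param noise_sd Residual SD in log2 units (default 0.25).
#' @param target_enrichment Odds multiplier linking planted repression
#'   to target annotation (default 1.8; 1 = no association).
#' @param target_base_rate Baseline target-annotation probability.
#' @param frac_ra_shift Fraction of time-affected genes given an
#'   additional planted amplitude (interaction) shift (default 0).
#' @param ra_shift_log2fc Magnitude of the planted relative-amplitude
#'   shift; sign is oriented so the shift increases or decreases the
#'   oscillation magnitude with equal probability.
#' @param baseline_log2_mean,baseline_log2_sd Baseline log2 expression.
#' @param seed RNG seed.
#' @return Validated list of class `"oe_sim_params"`.
#' @export
oe_sim_params <- function(n_genes = 2000, frac_treatment_affected = 0.3,
                          frac_under_vs_over = 8 / 9,
                          frac_time_affected = 0.3, effect_log2fc = 1,
                          reps_per_cell = 2, noise_sd = 0.25,
                          target_enrichment = 1.8,
                          target_base_rate = 0.2, frac_ra_shift = 0,
                          ra_shift_log2fc = 1, baseline_log2_mean = 8,
                          baseline_log2_sd = 1.5, seed = 1L) {
  stopifnot(n_genes >= 1,
            frac_treatment_affected >= 0, frac_treatment_affected <= 1,
            frac_under_vs_over >= 0, frac_under_vs_over <= 1,
            frac_time_affected >= 0, frac_time_affected <= 1,
            frac_ra_shift >= 0, frac_ra_shift <= 1,
            noise_sd >= 0, target_enrichment > 0,
            target_base_rate >= 0, target_base_rate <= 1,
            baseline_log2_sd >= 0)
  if (reps_per_cell < 2L)
    stop("reps_per_cell must be >= 2 (ANOVA needs residual df)")
  structure(as.list(environment()), class = "oe_sim_params")
}

#' Simulate a miRNA over-expression 2x2 experiment
#'
#' Generates a [designed_expression()] table where log2 expression is
#' `baseline + time_effect*[CT10] + treatment_effect*[oe]
#'  (+ ra_shift*[CT10]*[oe]) + noise`, plus a target annotation list in
#' which planted repressed genes are enriched.
#'
#' @param params An [oe_sim_params()] object.
#' @return List with `expression` (a `designed_expression`), `truth`
#'   (data frame: per-gene planted flags, directions, `group` per the
#'   I–IV definitions, `ra_class` of the planted amplitude shift,
#'   `is_target`) and `targets` (character vector of annotated target
#'   genes).
#' @export
simulate_overexpression <- function(params) {
  stopifnot(inherits(params, "oe_sim_params"))
  set.seed(as.integer(params$seed))
  n <- params$n_genes
  ids <- sprintf("gene_%05d", seq_len(n))
  trt_aff <- stats::runif(n) < params$frac_treatment_affected
  under <- trt_aff & (stats::runif(n) < params$frac_under_vs_over)
  trt_eff <- ifelse(trt_aff, ifelse(under, -1, 1) * params$effect_log2fc, 0)
  time_aff <- stats::runif(n) < params$frac_time_affected
  peak10 <- stats::runif(n) < 0.5
  time_eff <- ifelse(time_aff, ifelse(peak10, 1, -1) * params$effect_log2fc,
                     0)
  ra_shifted <- time_aff & (stats::runif(n) < params$frac_ra_shift)
  ra_increase <- stats::runif(n) < 0.5
  # Interaction coefficient on the CT10:oe cell; oriented so that for a
  # CT22-peaking gene an "increase" makes its (negative) RA more negative.
  ra_coef <- ifelse(ra_shifted,
                    ifelse(peak10, 1, -1) * ifelse(ra_increase, 1, -1) *
                      params$ra_shift_log2fc,
                    0)
  r <- params$reps_per_cell
  cells <- expand.grid(replicate = seq_len(r),
                       treatment = c("null", "oe"),
                       time = c("CT10", "CT22"),
                       stringsAsFactors = FALSE)
  design <- data.frame(
    sample = sprintf("%s_%s_rep%d", cells$time, cells$treatment,
                     cells$replicate),
    time = cells$time, treatment = cells$treatment,
    replicate = cells$replicate, stringsAsFactors = FALSE)
  mu <- stats::rnorm(n, params$baseline_log2_mean, params$baseline_log2_sd)
  is10 <- design$time == "CT10"
  isoe <- design$treatment == "oe"
  m <- nrow(design)
  logv <- matrix(mu, n, m) +
    outer(time_eff, as.numeric(is10)) +
    outer(trt_eff, as.numeric(isoe)) +
    outer(ra_coef, as.numeric(is10 & isoe)) +
    matrix(stats::rnorm(n * m, 0, params$noise_sd), n, m)
  values <- 2^logv
  rownames(values) <- ids
  # Target annotation: planted repressed genes carry elevated odds.
  p0 <- params$target_base_rate
  p1 <- p0 * params$target_enrichment /
    (1 - p0 + p0 * params$target_enrichment)
  is_target <- stats::runif(n) < ifelse(under, p1, p0)
  group <- rep("none", n)
  both <- trt_aff & time_aff
  group[both & peak10 & under] <- "I"
  group[both & peak10 & !under] <- "II"
  group[both & !peak10 & under] <- "III"
  group[both & !peak10 & !under] <- "IV"
  oriented <- ifelse(peak10, 1, -1) * ra_coef
  ra_class <- ifelse(!ra_shifted, "unchanged",
                     ifelse(oriented > 0, "increased", "decreased"))
  truth <- data.frame(
    gene = ids, treatment_affected = trt_aff,
    treatment_direction = ifelse(trt_aff,
                                 ifelse(under, "under", "over"),
                                 NA_character_),
    time_affected = time_aff,
    time_direction = ifelse(time_aff,
                            ifelse(peak10, "CT10>CT22", "CT10<CT22"),
                            NA_character_),
    group = factor(group, levels = c("I", "II", "III", "IV", "none")),
    ra_shift = ra_coef, ra_class = ra_class, is_target = is_target,
    stringsAsFactors = FALSE)
  list(expression = designed_expression(values, design), truth = truth,
       targets = ids[is_target])
}

#' Simulate transcript models and TF binding calls
#'
#' Lays transcripts along a synthetic chromosome (alternating strands)
#' and places, for each regulator, ChIP peaks inside promoter windows
#' with a binding probability elevated by `enrichment_odds` for
#' circadian transcripts. BMAL1 calls carry a dataset-support count in
#' 1..6 (most >= 2, so the two-dataset support rule retains them);
#' other regulators carry small support counts.
#'
#' @param n_transcripts Number of transcripts.
#' @param circadian_flags Logical vector: which transcripts are
#'   circadian (default: first 30%).
#' @param regulators Character vector of regulator names.
#' @param enrichment_odds Odds multiplier (scalar or named per
#'   regulator, >= 1) for binding on circadian promoters.
#' @param base_rate Baseline binding probability per
#'   regulator-transcript pair.
#' @param upstream Promoter window extension used for peak placement.
#' @param peak_width Width of simulated peaks in bp.
#' @param seed RNG seed.
#' @return List with `transcripts` (stranded `GRanges` with
#'   `transcript_id` and `circadian` metadata) and `calls` (`GRanges`
#'   with `regulator`, `n_supporting_datasets`).
#' @export
simulate_binding <- function(n_transcripts = 300, circadian_flags = NULL,
                             regulators = c("BMAL1", "CLOCK", "REV-ERBA",
                                            "REV-ERBB"),
                             enrichment_odds = 5, base_rate = 0.15,
                             upstream = 5000, peak_width = 200,
                             seed = 1L) {
  stopifnot(n_transcripts >= 1, all(enrichment_odds >= 1),
            base_rate > 0, base_rate < 1)
  set.seed(as.integer(seed))
  if (is.null(circadian_flags))
    circadian_flags <- seq_len(n_transcripts) <= round(0.3 * n_transcripts)
  stopifnot(length(circadian_flags) == n_transcripts)
  ids <- sprintf("pri_mir_%04d", seq_len(n_transcripts))
  gene_w <- 10000L
  gap <- 50000L
  starts <- 10000L + (seq_len(n_transcripts) - 1L) * (gene_w + gap)
  tr <- GenomicRanges::GRanges(
    "chrSim", IRanges::IRanges(starts, width = gene_w),
    strand = rep(c("+", "-"), length.out = n_transcripts))
  S4Vectors::mcols(tr)$transcript_id <- ids
  S4Vectors::mcols(tr)$circadian <- circadian_flags
  win <- promoter_window(tr, upstream)
  odds_of <- function(reg) {
    if (!is.null(names(enrichment_odds)) &&
        reg %in% names(enrichment_odds))
      enrichment_odds[[reg]]
    else unname(enrichment_odds[1])
  }
  call_list <- list()
  for (reg in regulators) {
    odds <- odds_of(reg)
    p_circ <- base_rate * odds / (1 - base_rate + base_rate * odds)
    p <- ifelse(circadian_flags, p_circ, base_rate)
    bound <- stats::runif(n_transcripts) < p
    if (!any(bound)) next
    wstart <- GenomicRanges::start(win)[bound]
    wend <- GenomicRanges::end(win)[bound]
    pos <- wstart + floor(stats::runif(sum(bound)) *
                            pmax(1, wend - wstart - peak_width))
    support <- if (toupper(reg) == "BMAL1")
      1L + stats::rbinom(sum(bound), 5L, 0.5)
    else
      1L + stats::rbinom(sum(bound), 2L, 0.2)
    gr <- GenomicRanges::GRanges(
      "chrSim", IRanges::IRanges(pos, width = peak_width), strand = "*")
    S4Vectors::mcols(gr)$regulator <- reg
    S4Vectors::mcols(gr)$n_supporting_datasets <- support
    call_list[[reg]] <- gr
  }
  calls <- if (length(call_list))
    suppressWarnings(do.call(c, unname(call_list)))
  else
    GenomicRanges::GRanges()
  list(transcripts = tr, calls = calls)
}
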