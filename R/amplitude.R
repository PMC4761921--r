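#' Relative amplitude of a two-timepoint rhythm
#'
#' The relative amplitude (RA) of a circadian gene measured at only two
#' time points is the log2 fold-change between its CT10 and CT22 means:
#' `RA = log2(mean(CT10) / mean(CT22))`. For a gene peaking around CT10
#' the RA is positive; for one peaking around CT22 it is negative, and
#' `|RA|` is a two-point proxy for the peak-to-trough ratio.
#'
#' @param expr_ct10,expr_ct22 Nonempty numeric vectors of expression at
#'   the two time points (replicates).
#' @return The RA in log2 units.
#' @details A zero mean in either group is an error; add a pseudocount at
#'   the I/O layer if zeros are expected.
#' @examples
#' relative_amplitude(c(8, 8), c(2, 2)) # 2
#' @export
relative_amplitude <- function(expr_ct10, expr_ct22) {
  if (length(expr_ct10) == 0L || length(expr_ct22) == 0L)
    stop("both groups must be nonempty")
  m1 <- mean(expr_ct10); m2 <- mean(expr_ct22)
  if (m1 <= 0 || m2 <= 0)
    stop("group means must be positive (consider a pseudocount)")
  log2(m1 / m2)
}

# Relative amplitude per gene from a designed_expression object, within
# one treatment arm.
ra_by_condition <- function(de, treatment) {
  d <- de$design
  sel <- d$treatment == treatment
  tlev <- sort(unique(d$time))            # CT10 before CT22
  i10 <- sel & d$time == tlev[1]
  i22 <- sel & d$time == tlev[2]
  m10 <- rowMeans(de$values[, i10, drop = FALSE])
  m22 <- rowMeans(de$values[, i22, drop = FALSE])
  if (any(m10 <= 0) || any(m22 <= 0))
    stop("zero mean expression encountered; add a pseudocount upstream")
  log2(m10 / m22)
}

#' Classify relative-amplitude changes between two conditions
#'
#' Compares per-gene RAs between two conditions (e.g. control vs.
#' miRNA over-expression). The difference is oriented by each gene's
#' peak side so that a positive oriented difference always means a
#' larger-magnitude oscillation in condition 2: for CT10-peaking genes
#' (RA > 0) it is `RA2 - RA1`, for CT22-peaking genes (RA < 0) it is
#' `RA1 - RA2`.
#'
#' @param ra1,ra2 Named (or parallel) numeric vectors of RAs in
#'   conditions 1 and 2 over the same genes.
#' @param peak_side Character vector per gene: `"CT10"` or `"CT22"`. By
#'   default inferred from the sign of `ra1` (the reference condition).
#' @param threshold Change threshold in log2 units (default 0.5).
#'   `|delta| <= threshold` is "unchanged" (the boundary is inclusive:
#'   change requires a strictly larger difference).
#' @return Data frame: `gene`, `ra1`, `ra2`, `delta_ra` (raw `ra2 - ra1`),
#'   `oriented_delta`, `peak_side`, `class`
#'   (`increased`/`decreased`/`unchanged`), with a `counts` attribute
#'   (class x peak-side table).
#' @examples
#' compare_ra(c(g1 = 1, g2 = -1), c(g1 = 1.2, g2 = -1.8))$class
#' @export
compare_ra <- function(ra1, ra2, peak_side = NULL, threshold = 0.5) {
  if (length(ra1) != length(ra2))
    stop("conditions must cover the same gene universe")
  genes <- names(ra1)
  if (is.null(genes)) genes <- paste0("gene_", seq_along(ra1))
  if (!is.null(names(ra2))) {
    if (!setequal(genes, names(ra2)))
      stop("conditions must cover the same gene universe")
    ra2 <- ra2[genes]
  }
  if (is.null(peak_side))
    peak_side <- ifelse(ra1 >= 0, "CT10", "CT22")
  stopifnot(all(peak_side %in% c("CT10", "CT22")))
  delta <- ra2 - ra1
  oriented <- ifelse(peak_side == "CT10", delta, -delta)
  cls <- ifelse(abs(oriented) <= threshold, "unchanged",
                ifelse(oriented > 0, "increased", "decreased"))
  out <- data.frame(gene = genes, ra1 = unname(ra1), ra2 = unname(ra2),
                    delta_ra = unname(delta),
                    oriented_delta = unname(oriented),
                    peak_side = unname(peak_side), class = unname(cls),
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(class = out$class,
                               peak_side = out$peak_side)
  out
}

#' Nascent vs. mature relative amplitudes and gene-set enrichment
#'
#' For every gene present in both matrices, computes the RA (CT10 vs.
#' CT22) in the nascent and in the mature series — using, in each
#' matrix, the samples whose CT is circularly nearest to 10 and 22 h —
#' and tests by Fisher's exact test whether RA changes
#' (`|RA_nascent - RA_mature| > threshold`) are enriched in `gene_set`
#' relative to the rest of the shared genes.
#'
#' @param nascent,mature [time_series_matrix()] objects sharing gene ids.
#' @param gene_set Character vector of foreground gene ids.
#' @param threshold Change threshold in log2 units (default 0.5).
#' @return List with `per_gene` (data frame: gene, `ra_nascent`,
#'   `ra_mature`, `delta_ra`, `changed`, `in_set`), `enrichment` (an
#'   [fisher_enrichment()] result, or `NULL` if one margin is empty) and
#'   `n_excluded` (genes missing from either matrix).
#' @export
nascent_vs_mature_ra <- function(nascent, mature, gene_set,
                                 threshold = 0.5) {
  stopifnot(inherits(nascent, "tsm"), inherits(mature, "tsm"))
  common <- intersect(rownames(nascent$values), rownames(mature$values))
  n_excl <- length(union(rownames(nascent$values),
                         rownames(mature$values))) - length(common)
  if (n_excl > 0)
    warning(n_excl, " gene(s) missing from one matrix were excluded")
  if (length(common) == 0L) stop("matrices share no genes")
  ra_of <- function(ts) {
    d10 <- circular_diff(ts$time %% 24, 10)
    d22 <- circular_diff(ts$time %% 24, 22)
    i10 <- which(d10 == min(d10))
    i22 <- which(d22 == min(d22))
    m10 <- rowMeans(ts$values[common, i10, drop = FALSE])
    m22 <- rowMeans(ts$values[common, i22, drop = FALSE])
    if (any(m10 <= 0) || any(m22 <= 0))
      stop("zero mean expression encountered; add a pseudocount upstream")
    log2(m10 / m22)
  }
  ra_n <- ra_of(nascent)
  ra_m <- ra_of(mature)
  delta <- ra_n - ra_m
  changed <- abs(delta) > threshold
  in_set <- common %in% gene_set
  per_gene <- data.frame(gene = common, ra_nascent = unname(ra_n),
                         ra_mature = unname(ra_m),
                         delta_ra = unname(delta), changed = changed,
                         in_set = in_set, stringsAsFactors = FALSE)
  enr <- if (any(in_set) && any(!in_set))
    fisher_enrichment(sum(changed & in_set), sum(in_set),
                      sum(changed & !in_set), sum(!in_set))
  else NULL
  list(per_gene = per_gene, enrichment = enr, n_excluded = n_excl)
}

#' First-order kinetic attenuation of a driven oscillation
#'
#' Steady-state response of a product P with first-order decay driven by
#' a sinusoidal synthesis rate, `dP/dt = s(t) - k*P` with
#' `s(t) = s0 * (1 + a*cos(w*t))`: the product oscillates at the same
#' period with relative amplitude `a * k/sqrt(k^2 + w^2)` and its peak
#' lags the synthesis peak by `atan(w/k)/w` hours. With
#' `k = ln(2)/half_life` this quantifies how long-lived mature miRNAs
#' (average mammalian half-life around 119 h) flatten the circadian
#' rhythm inherited from their primary transcripts: at 119 h and a 24-h
#' period the attenuation factor is ~0.02, i.e. a strongly rhythmic
#' primary transcript yields a nearly flat mature miRNA.
#'
#' @param half_life Product half-life in hours (> 0).
#' @param period Driving period in hours (default 24).
#' @return List of class `"attenuation_model"`: `half_life`, `period`,
#'   `k` (1/h), `omega` (rad/h), `attenuation` (in `(0, 1]`),
#'   `phase_lag` (hours, in `[0, period/4)`).
#' @examples
#' kinetic_attenuation(119)$attenuation          # ~0.022
#' kinetic_attenuation(24 * log(2) / (2 * pi))   # k == omega: 1/sqrt(2), lag 3 h
#' @export
kinetic_attenuation <- function(half_life, period = 24) {
  stopifnot(half_life > 0, period > 0)
  k <- log(2) / half_life
  w <- 2 * pi / period
  structure(list(half_life = half_life, period = period, k = k,
                 omega = w,
                 attenuation = k / sqrt(k^2 + w^2),
                 phase_lag = atan(w / k) / w),
            class = "attenuation_model")
}

#' @export
print.attenuation_model <- function(x, ...) {
  cat(sprintf(
    "First-order attenuation: half-life %g h, period %g h -> amplitude x %.4g, peak lag %.2f h\n",
    x$half_life, x$period, x$attenuation, x$phase_lag))
  invisible(x)
}
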