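#' Per-gene two-way ANOVA on a 2x2 factorial design
#'
#' Fits, for every gene, the main-effects linear model
#' `log2(x + 1) ~ time + treatment` and tests each factor with an F-test
#' (reduced model dropping that factor vs. the full model, i.e. type-II
#' tests, which coincide with the classical sums of squares in the
#' balanced case).
#'
#' @param de A [designed_expression()] object.
#' @param transform `"log2p1"` (default, `log2(x + 1)`) or `"none"`.
#' @param interaction If `TRUE`, additionally reports `p_interaction`
#'   (time x treatment term tested against the main-effects model). The
#'   factor p-values are always from the main-effects comparison.
#' @return Data frame, one row per gene: `gene`, `p_time`,
#'   `p_treatment`, `f_time`, `f_treatment` (the F statistics),
#'   `time_diff` (mean log2 CT10 - CT22 in the control
#'   arm; positive = peaks around CT10), `treatment_diff` (mean log2
#'   over-expression - control across both times; negative = repressed),
#'   and `p_interaction` when requested. Genes with no variance at all
#'   get p = 1 for both factors.
#' @details The control-arm convention for `time_diff` follows from the
#'   design: with only two time points, "peaking around CT10" is read off
#'   the unperturbed (control) samples so that a treatment that reshapes
#'   the rhythm does not flip the gene's peak-side label. No multiplicity
#'   correction is applied; the raw p < 0.05 rule is the documented
#'   convention of this analysis.
#' @seealso [classify_groups()]
#' @export
two_way_anova <- function(de, transform = c("log2p1", "none"),
                          interaction = FALSE) {
  stopifnot(inherits(de, "designed_expression"))
  transform <- match.arg(transform)
  Y <- de$values
  if (transform == "log2p1") Y <- log2(Y + 1)
  d <- de$design
  tlev <- sort(unique(d$time))             # "CT10" < "CT22"
  time_f <- factor(d$time, levels = tlev)
  trt_f <- factor(d$treatment,
                  levels = if (all(c("oe", "null") %in% d$treatment))
                    c("null", "oe") else sort(unique(d$treatment)))
  n <- ncol(Y)
  X_full <- stats::model.matrix(~ time_f + trt_f)
  df_res <- n - qr(X_full)$rank
  if (df_res <= 0L)
    stop("no residual degrees of freedom: provide >= 2 replicates in ",
         "at least one design cell")
  rss_under <- function(X) {
    Q <- qr.Q(qr(X))
    E <- Y - (Y %*% Q) %*% t(Q)
    rowSums(E^2)
  }
  rss_full <- rss_under(X_full)
  rss_no_time <- rss_under(stats::model.matrix(~ trt_f))
  rss_no_trt <- rss_under(stats::model.matrix(~ time_f))
  f_of <- function(rss_red, df_diff = 1L) {
    ((rss_red - rss_full) / df_diff) / (rss_full / df_res)
  }
  p_of <- function(Fst, df_diff = 1L) {
    p <- stats::pf(Fst, df_diff, df_res, lower.tail = FALSE)
    p[!is.finite(p)] <- 1
    p
  }
  f_time <- f_of(rss_no_time)
  f_trt <- f_of(rss_no_trt)
  p_time <- p_of(f_time)
  p_trt <- p_of(f_trt)
  # Flat genes carry no evidence for either factor.
  tot <- rowSums((Y - rowMeans(Y))^2)
  flat <- tot <= 1e-12 * pmax(1, rowMeans(Y)^2)
  p_time[flat] <- 1
  p_trt[flat] <- 1
  f_time[flat] <- 0
  f_trt[flat] <- 0

  ctrl <- trt_f == levels(trt_f)[1]
  t10 <- d$time == tlev[1]
  time_diff <- rowMeans(Y[, ctrl & t10, drop = FALSE]) -
    rowMeans(Y[, ctrl & !t10, drop = FALSE])
  oe <- !ctrl
  treatment_diff <- rowMeans(Y[, oe, drop = FALSE]) -
    rowMeans(Y[, ctrl, drop = FALSE])
  out <- data.frame(gene = rownames(Y), p_time = p_time,
                    p_treatment = p_trt, f_time = f_time,
                    f_treatment = f_trt, time_diff = time_diff,
                    treatment_diff = treatment_diff,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (interaction) {
    X_int <- stats::model.matrix(~ time_f * trt_f)
    df_res_int <- n - qr(X_int)$rank
    if (df_res_int <= 0L)
      stop("interaction model leaves no residual degrees of freedom")
    Q <- qr.Q(qr(X_int))
    rss_int <- rowSums((Y - (Y %*% Q) %*% t(Q))^2)
    Fst <- (rss_full - rss_int) / (rss_int / df_res_int)
    p_int <- stats::pf(Fst, 1, df_res_int, lower.tail = FALSE)
    p_int[!is.finite(p_int)] <- 1
    p_int[flat] <- 1
    out$p_interaction <- p_int
  }
  out
}

#' Classify doubly significant genes into circadian groups I-IV
#'
#' Genes significant for both the time and the treatment factor are
#' partitioned by peak side and treatment direction:
#' * Group I — peaks around CT10, repressed by the over-expression;
#' * Group II — peaks around CT10, induced;
#' * Group III — peaks around CT22, repressed;
#' * Group IV — peaks around CT22, induced.
#'
#' Groups I and III (the repressed ones, consistent with direct miRNA
#' targeting) together form the "circadian target" set.
#'
#' @param anova_tab Data frame from [two_way_anova()].
#' @param alpha Significance cutoff for both factors (default 0.05,
#'   uncorrected by convention).
#' @return The input with added columns `time_direction`
#'   (`"CT10>CT22"`/`"CT10<CT22"`, `NA` when `p_time >= alpha`),
#'   `treatment_direction` (`"under"`/`"over"`, `NA` when
#'   `p_treatment >= alpha`) and `group` (factor with levels I, II, III,
#'   IV, none).
#' @export
classify_groups <- function(anova_tab, alpha = 0.05) {
  need <- c("p_time", "p_treatment", "time_diff", "treatment_diff")
  stopifnot(all(need %in% names(anova_tab)))
  sig_t <- anova_tab$p_time < alpha
  sig_tr <- anova_tab$p_treatment < alpha
  tdir <- ifelse(sig_t,
                 ifelse(anova_tab$time_diff > 0, "CT10>CT22",
                        ifelse(anova_tab$time_diff < 0, "CT10<CT22",
                               NA_character_)),
                 NA_character_)
  trdir <- ifelse(sig_tr,
                  ifelse(anova_tab$treatment_diff < 0, "under",
                         ifelse(anova_tab$treatment_diff > 0, "over",
                                NA_character_)),
                  NA_character_)
  grp <- rep("none", nrow(anova_tab))
  both <- !is.na(tdir) & !is.na(trdir)
  grp[both & tdir == "CT10>CT22" & trdir == "under"] <- "I"
  grp[both & tdir == "CT10>CT22" & trdir == "over"] <- "II"
  grp[both & tdir == "CT10<CT22" & trdir == "under"] <- "III"
  grp[both & tdir == "CT10<CT22" & trdir == "over"] <- "IV"
  anova_tab$time_direction <- tdir
  anova_tab$treatment_direction <- trdir
  anova_tab$group <- factor(grp, levels = c("I", "II", "III", "IV", "none"))
  anova_tab
}

#' Fisher exact enrichment of a hit set
#'
#' Two-sided Fisher exact test of the 2x2 table
#' `[[hits_in_set, set_size - hits_in_set],
#'   [hits_in_rest, rest_size - hits_in_rest]]`,
#' with the sample odds ratio `(a*d)/(b*c)` (Haldane 0.5 correction
#' applied, and flagged, only when a zero cell occurs).
#'
#' @param hits_in_set,set_size,hits_in_rest,rest_size Nonnegative counts;
#'   hits must not exceed their set sizes.
#' @return List of class `"enrichment_result"`: `table` (2x2 counts),
#'   `odds_ratio`, `p_value`, `test` (`"fisher_exact_two_sided"`),
#'   `haldane` flag.
#' @examples
#' fisher_enrichment(10, 30, 30, 270)$odds_ratio # 4
#' @export
fisher_enrichment <- function(hits_in_set, set_size, hits_in_rest,
                              rest_size) {
  a <- hits_in_set; b <- set_size - hits_in_set
  cc <- hits_in_rest; d <- rest_size - hits_in_rest
  if (any(c(a, b, cc, d) < 0)) stop("inconsistent counts")
  if (set_size + rest_size == 0) stop("empty universe")
  tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("set", "rest"), c("hit", "miss")))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  haldane <- any(tab == 0)
  orr <- if (haldane)
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  else
    (a * d) / (b * cc)
  structure(list(table = tab, odds_ratio = orr, p_value = min(p, 1),
                 test = "fisher_exact_two_sided", haldane = haldane),
            class = "enrichment_result")
}

#' Two-sample proportion enrichment test
#'
#' Two-sided z-test of `k1/n1` against `k2/n2` with pooled variance and
#' no continuity correction (the classical "proportion test").
#'
#' @param k1,n1 Hits and size of the first sample.
#' @param k2,n2 Hits and size of the second sample.
#' @return List of class `"enrichment_result"`: `table`, `proportions`,
#'   `z`, `p_value`, `test` (`"two_proportion_z"`). When the pooled
#'   proportion is degenerate (0 or 1 in both samples) `z = 0`, `p = 1`.
#' @examples
#' proportion_enrichment(142, 1000, 100, 1000)$p_value
#' @export
proportion_enrichment <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) stop("inconsistent counts")
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(table = matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2,
                                byrow = TRUE,
                                dimnames = list(c("sample1", "sample2"),
                                                c("hit", "miss"))),
                 proportions = c(p1 = p1, p2 = p2), z = z,
                 p_value = min(p, 1), test = "two_proportion_z"),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s: p = %.3g%s\n", x$test, x$p_value,
              if (!is.null(x$odds_ratio))
                sprintf(", OR = %.3g%s", x$odds_ratio,
                        if (isTRUE(x$haldane)) " (Haldane-corrected)" else "")
              else sprintf(", z = %.3g", x$z)))
  print(x$table)
  invisible(x)
}

#' Circular peak-time profiles of gene sets
#'
#' Summarises, for each gene set, the distribution of database peak
#' times around the clock: a 24-bin circular histogram, the circular
#' mean peak time and the mean resultant length (concentration).
#'
#' @param gene_sets Named list of character vectors of gene ids.
#' @param peak_time_db Named numeric vector: known circadian peak time
#'   (CT hours in `[0, 24)`) per gene.
#' @return Named list, one element per set: list with `n` (genes with a
#'   known peak time), `histogram` (counts for bins `[0,1), ... [23,24)`),
#'   `circular_mean`, `resultant_length`. Empty sets give `n = 0` and an
#'   all-zero histogram.
#' @export
peak_time_profile <- function(gene_sets, peak_time_db) {
  stopifnot(is.list(gene_sets), !is.null(names(peak_time_db)))
  if (any(peak_time_db < 0 | peak_time_db >= 24))
    stop("peak times must lie in [0, 24)")
  lapply(gene_sets, function(genes) {
    pt <- peak_time_db[intersect(genes, names(peak_time_db))]
    h <- integer(24)
    if (length(pt)) {
      tab <- table(factor(floor(pt), levels = 0:23))
      h <- as.integer(tab)
    }
    names(h) <- paste0("CT", 0:23)
    list(n = length(pt), histogram = h,
         circular_mean = circular_mean(pt),
         resultant_length = resultant_length(pt))
  })
}
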