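#' Permutation null distribution of the consistency-score classifier
#'
#' Re-runs the full two-dataset rhythmicity pipeline on permuted data and
#' records, for each permutation, how many transcripts pass the
#' `S > score_min & dphase < phasediff_max` rule.
#'
#' @param tsm1,tsm2 The two [time_series_matrix()] objects.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; per-permutation sub-seeds are derived from it
#'   so the run is reproducible (and would parallelise reproducibly).
#' @param method `"within_transcript"` (default) shuffles each
#'   transcript's values across samples, independently per transcript and
#'   per dataset — this destroys both the rhythm and the cross-dataset
#'   phase agreement while preserving every transcript's value
#'   distribution. `"gene_swap"` instead permutes transcript identities
#'   of the second dataset, destroying only the cross-dataset pairing.
#' @param period,score_min,phasediff_max As in [detect_rhythmic()].
#' @return Integer vector of length `n_perm`: passing transcripts per
#'   permutation.
#' @seealso [estimate_fdr()]
#' @export
permute_and_score <- function(tsm1, tsm2, n_perm, seed = 1L,
                              method = c("within_transcript", "gene_swap"),
                              period = 24, score_min = 9,
                              phasediff_max = 4) {
  stopifnot(inherits(tsm1, "tsm"), inherits(tsm2, "tsm"), n_perm >= 1)
  method <- match.arg(method)
  common <- intersect(rownames(tsm1$values), rownames(tsm2$values))
  if (length(common) == 0L) stop("matrices share no transcripts")
  v1 <- tsm1$values[common, , drop = FALSE]
  v2 <- tsm2$values[common, , drop = FALSE]
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, n_perm)
  pass_counts <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    set.seed(sub_seeds[i])
    if (method == "within_transcript") {
      p1 <- shuffle_within_rows(v1)
      p2 <- shuffle_within_rows(v2)
    } else {
      p1 <- v1
      p2 <- v2[sample.int(nrow(v2)), , drop = FALSE]
    }
    f1 <- cosinor_fit_matrix(p1, tsm1$time, period)
    f2 <- cosinor_fit_matrix(p2, tsm2$time, period)
    s <- -log2(f1$p_value) - log2(f2$p_value)
    dphi <- circular_diff(f1$phase, f2$phase, period)
    pass_counts[i] <- sum(s > score_min & dphi < phasediff_max)
  }
  pass_counts
}

#' Permutation estimate of the false discovery rate
#'
#' FDR of the rhythmicity classifier, defined as the mean number of
#' passing transcripts across permutations divided by the number passing
#' on the real data.
#'
#' @param real Either the data frame returned by [detect_rhythmic()] or
#'   the real pass count as a single integer.
#' @param permuted_counts Integer vector from [permute_and_score()].
#' @param score_min,phasediff_max The thresholds the counts were computed
#'   at (recorded in the result).
#' @param seed Optional seed to record alongside the estimate.
#' @return List of class `"fdr_estimate"`: `n_permutations`, `score_min`,
#'   `phasediff_max`, `n_pass_real`, `mean_pass_permuted`, `fdr` (capped
#'   at 1), `fdr_raw` (uncapped), `per_permutation_counts`, `seed`. With
#'   zero real passes the FDR is undefined and reported as `NA` rather
#'   than raising an error.
#' @examples
#' estimate_fdr(57, rep(16.5, 4))$fdr # ~0.29
#' @export
estimate_fdr <- function(real, permuted_counts, score_min = 9,
                         phasediff_max = 4, seed = NULL) {
  if (length(permuted_counts) < 1L) stop("need >= 1 permutation")
  n_real <- if (is.data.frame(real)) sum(real$pass) else as.numeric(real)
  mean_perm <- mean(permuted_counts)
  fdr_raw <- if (n_real > 0) mean_perm / n_real else NA_real_
  structure(list(n_permutations = length(permuted_counts),
                 score_min = score_min, phasediff_max = phasediff_max,
                 n_pass_real = n_real,
                 mean_pass_permuted = mean_perm,
                 fdr = if (is.na(fdr_raw)) NA_real_ else min(fdr_raw, 1),
                 fdr_raw = fdr_raw,
                 per_permutation_counts = as.integer(permuted_counts),
                 seed = seed),
            class = "fdr_estimate")
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat(sprintf(
    "Permutation FDR (%d perms, S > %g & dphase < %g): %d real passes, %.2f mean permuted, FDR = %s\n",
    x$n_permutations, x$score_min, x$phasediff_max, x$n_pass_real,
    x$mean_pass_permuted,
    if (is.na(x$fdr)) "undefined (no real passes)" else
      sprintf("%.1f%%", 100 * x$fdr)))
  invisible(x)
}
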