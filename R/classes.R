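#' Time-series expression matrix
#'
#' Container for a transcripts x samples matrix of nonnegative expression
#' values (RPKM or normalised counts) where every sample carries a
#' circadian-time annotation in hours and an optional replicate index.
#'
#' @param values Numeric matrix, transcripts in rows (rownames are
#'   transcript ids), samples in columns. All values must be nonnegative
#'   and finite.
#' @param time Numeric vector of CT sampling times in hours, one per
#'   column. Times beyond 24 h are allowed (multi-day designs); they enter
#'   periodic fits through `t mod period`.
#' @param replicate Optional integer replicate index per column (default
#'   all 1).
#' @param dataset Single string labelling the dataset (e.g. `"GROseq"`).
#' @return An object of class `"tsm"`: a list with elements `values`,
#'   `time`, `replicate`, `dataset`.
#' @examples
#' m <- matrix(rpois(24, 50), nrow = 2,
#'             dimnames = list(c("t1", "t2"), NULL))
#' ts <- time_series_matrix(m, time = seq(0, 44, by = 4), dataset = "demo")
#' ts
#' @export
time_series_matrix <- function(values, time, replicate = NULL,
                               dataset = "dataset") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be numeric")
  if (anyNA(values) || any(!is.finite(values)))
    stop("'values' must be finite")
  if (any(values < 0)) stop("expression values must be nonnegative")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("transcript_", seq_len(nrow(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate transcript ids")
  if (length(time) != ncol(values))
    stop("'time' must have one entry per sample column")
  if (is.null(replicate)) replicate <- rep(1L, ncol(values))
  if (length(replicate) != ncol(values))
    stop("'replicate' must have one entry per sample column")
  if (anyDuplicated(paste(time, replicate)))
    stop("duplicate (time, replicate) sample annotations")
  colnames(values) <- if (all(replicate == 1L) && !anyDuplicated(time))
    sprintf("CT%g", time)
  else
    sprintf("CT%g_rep%d", time, as.integer(replicate))
  structure(list(values = values, time = as.numeric(time),
                 replicate = as.integer(replicate),
                 dataset = as.character(dataset)[1]),
            class = "tsm")
}

#' @export
print.tsm <- function(x, ...) {
  cat(sprintf("Time-series matrix '%s': %d transcripts x %d samples\n",
              x$dataset, nrow(x$values), ncol(x$values)))
  cat("  CT times:", paste(format(x$time), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.tsm <- function(x) dim(x$values)

#' Two-by-two factorial expression table
#'
#' Container for a genes x samples matrix from a two-timepoint,
#' two-treatment design (e.g. CT10/CT22 x over-expression/control with
#' replicate animals per cell).
#'
#' @param values Numeric matrix of nonnegative normalised expression,
#'   genes in rows, samples in columns.
#' @param design Data frame with columns `sample`, `time` (factor-like,
#'   two levels, e.g. `"CT10"`/`"CT22"`), `treatment` (two levels, e.g.
#'   `"oe"`/`"null"`) and `replicate`, one row per column of `values`.
#' @return An object of class `"designed_expression"` with elements
#'   `values` and `design`.
#' @details Every (time, treatment) cell must contain at least one sample
#'   and at least one cell needs two or more replicates so the ANOVA has
#'   residual degrees of freedom.
#' @examples
#' sim <- simulate_overexpression(oe_sim_params(n_genes = 20, seed = 1))
#' sim$expression$design
#' @export
designed_expression <- function(values, design) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("expression values must be nonnegative")
  need <- c("sample", "time", "treatment", "replicate")
  if (!all(need %in% names(design)))
    stop("design needs columns: ", paste(need, collapse = ", "))
  if (nrow(design) != ncol(values))
    stop("design must have one row per sample column")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("gene_", seq_len(nrow(values)))
  design$time <- as.character(design$time)
  design$treatment <- as.character(design$treatment)
  if (length(unique(design$time)) != 2L ||
      length(unique(design$treatment)) != 2L)
    stop("design must have exactly two time points and two treatments")
  cell <- table(design$time, design$treatment)
  if (any(cell == 0L))
    stop("every (time, treatment) cell needs at least one sample")
  if (all(cell < 2L))
    stop("at least one design cell needs >= 2 replicates")
  colnames(values) <- design$sample
  structure(list(values = values, design = design),
            class = "designed_expression")
}

#' @export
print.designed_expression <- function(x, ...) {
  cat(sprintf("Designed expression: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  print(table(x$design$time, x$design$treatment))
  invisible(x)
}
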