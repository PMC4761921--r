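# Plain-text interchange formats: expression matrices are TSV with the
# transcript id in the first column and sample headers "CT<t>" or
# "CT<t>_rep<k>"; designs are 4-column TSV; intervals are BED (0-based
# half-open), read and written through rtracklayer.

#' Write a time-series matrix to TSV
#'
#' @param tsm A [time_series_matrix()] object.
#' @param path Output file.
#' @param digits Significant digits used for the values (fixed
#'   formatting keeps reruns byte-identical).
#' @return `path`, invisibly.
#' @export
write_tsm <- function(tsm, path, digits = 6) {
  stopifnot(inherits(tsm, "tsm"))
  df <- data.frame(transcript = rownames(tsm$values),
                   signif(tsm$values, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a time-series matrix from TSV
#'
#' Expects the format written by [write_tsm()]: first column transcript
#' id, remaining columns headed `CT<t>` or `CT<t>_rep<k>`.
#'
#' @param path Input file.
#' @param dataset Dataset label to attach (default: the file name).
#' @return A [time_series_matrix()] object.
#' @export
read_tsm <- function(path, dataset = basename(path)) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  hdr <- colnames(df)[-1]
  m <- regmatches(hdr, regexec("^CT([0-9.]+)(?:_rep([0-9]+))?$", hdr))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad))
    stop("malformed sample header(s): ", paste(hdr[bad], collapse = ", "))
  time <- vapply(m, function(x) as.numeric(x[2]), numeric(1))
  repl <- vapply(m, function(x)
    if (x[3] == "") 1L else as.integer(x[3]), integer(1))
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  time_series_matrix(v, time = time, replicate = repl, dataset = dataset)
}

#' Write a designed-expression object (expression + design TSVs)
#'
#' @param de A [designed_expression()] object.
#' @param expr_path,design_path Output files.
#' @param digits Significant digits for the values.
#' @return `expr_path`, invisibly.
#' @export
write_designed_expression <- function(de, expr_path, design_path,
                                      digits = 6) {
  stopifnot(inherits(de, "designed_expression"))
  df <- data.frame(gene = rownames(de$values), signif(de$values, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  utils::write.table(de$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(expr_path)
}

#' Read a designed-expression object from expression + design TSVs
#'
#' @param expr_path Expression TSV (first column gene id, one column per
#'   sample).
#' @param design_path Design TSV with columns `sample`, `time`,
#'   `treatment`, `replicate`.
#' @return A [designed_expression()] object.
#' @export
read_designed_expression <- function(expr_path, design_path) {
  expr <- utils::read.delim(expr_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  v <- as.matrix(expr[, -1, drop = FALSE])
  rownames(v) <- expr[[1]]
  if (!all(design$sample == colnames(v)))
    v <- v[, design$sample, drop = FALSE]
  designed_expression(v, design)
}

#' Read ChIP peak calls from a BED file
#'
#' BED6 input (0-based half-open) via rtracklayer; the name field is the
#' regulator and the score field the dataset-support count.
#'
#' @param path BED file.
#' @return `GRanges` with `regulator` and `n_supporting_datasets`
#'   metadata, ready for [assign_regulators()].
#' @export
read_binding_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to read BED files")
  gr <- rtracklayer::import(path, format = "BED")
  mc <- S4Vectors::mcols(gr)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    regulator = if ("name" %in% names(mc)) mc$name else "unknown",
    n_supporting_datasets = if ("score" %in% names(mc))
      pmax(1L, as.integer(mc$score)) else 1L)
  gr
}

#' Write intervals (peaks or transcripts) to a BED file
#'
#' @param gr `GRanges`; a `transcript_id` or `regulator` metadata column
#'   becomes the BED name, `n_supporting_datasets` the score.
#' @param path Output BED file (0-based half-open).
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to write BED files")
  mc <- S4Vectors::mcols(gr)
  name <- if ("transcript_id" %in% names(mc)) mc$transcript_id
          else if ("regulator" %in% names(mc)) mc$regulator
          else NULL
  score <- if ("n_supporting_datasets" %in% names(mc))
    as.numeric(mc$n_supporting_datasets) else NULL
  out <- gr
  S4Vectors::mcols(out) <- NULL
  if (!is.null(name)) names(out) <- name
  if (!is.null(score)) S4Vectors::mcols(out)$score <- score
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Write a ground-truth table with a JSON sidecar
#'
#' @param truth Ground-truth data frame from a simulator.
#' @param path Output TSV; a `.json` sidecar with the simulation summary
#'   is written next to it.
#' @param params Optional parameter object recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path, params = NULL) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    side <- sub("\\.tsv$", "", path)
    meta <- list(n = nrow(truth), columns = names(truth))
    if (!is.null(params)) meta$params <- unclass(params)
    jsonlite::write_json(meta, paste0(side, ".json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(path)
}
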