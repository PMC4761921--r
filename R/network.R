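#' Promoter-inclusive regulatory window of a transcript
#'
#' The region scanned for regulator binding: from 5,000 bp (by default)
#' upstream of the 5' end to the 3' end of the transcript, strand-aware
#' and clipped at the chromosome start.
#'
#' @param transcripts `GRanges` of transcript models (strand `+`/`-`).
#' @param upstream Upstream extension in bp (default 5000).
#' @return `GRanges` of the windows, same order and metadata columns.
#' @examples
#' library(GenomicRanges)
#' tr <- GRanges("chr1", IRanges(10001, 20000), strand = "+")
#' promoter_window(tr) # 5001-20000 (BED [5000, 20000))
#' @export
promoter_window <- function(transcripts, upstream = 5000) {
  stopifnot(methods::is(transcripts, "GRanges"), upstream >= 0)
  if (any(GenomicRanges::strand(transcripts) == "*"))
    stop("transcripts must be stranded")
  w <- suppressWarnings(GenomicRanges::resize(
    transcripts, GenomicRanges::width(transcripts) + upstream,
    fix = "end"))
  # Clip at the chromosome start; seqlengths are usually absent for the
  # synthetic genome, so do it explicitly rather than via trim().
  GenomicRanges::start(w) <- pmax(1L, GenomicRanges::start(w))
  GenomicRanges::trim(w)
}

# 1-based position of a peak's center; equals the BED floor((s0+e0)/2)
# convention (0-based) shifted to 1-based coordinates.
peak_center <- function(peaks) {
  floor((GenomicRanges::start(peaks) - 1 + GenomicRanges::end(peaks)) / 2) + 1
}

# 1-based position of the 5' end of each transcript.
five_prime_pos <- function(transcripts) {
  ifelse(as.character(GenomicRanges::strand(transcripts)) == "+",
         GenomicRanges::start(transcripts),
         GenomicRanges::end(transcripts))
}

#' Correct transcript 5' ends against promoter marks
#'
#' De novo assembled primary transcripts can miss the true TSS. This
#' checks each transcript's 5' end against H3K4me3 (promoter) and Pol II
#' marks within `tss_flank` bp: if an H3K4me3 and a Pol II peak are both
#' found the 5' end is confirmed (`h3k4me3_and_polii`); with only
#' H3K4me3, it is kept (`h3k4me3_only`); with neither, the 5' end is
#' moved to the center of the nearest H3K4me3 peak (falling back to Pol
#' II when no H3K4me3 peak lies within `max_distance`), ties broken
#' toward upstream (`corrected`); if no anchor is in reach the
#' transcript is flagged `uncorrectable` and left unchanged.
#'
#' @param transcripts Stranded `GRanges` of transcript models.
#' @param h3k4me3,polii `GRanges` of the two mark peak sets.
#' @param tss_flank Half-width in bp of the window around the current 5'
#'   end searched for confirming marks (default 1000).
#' @param max_distance Maximal center-to-5'-end distance in bp for a
#'   correction anchor (default 10000).
#' @param anchor `"h3k4me3_first"` (default: Pol II only as fallback) or
#'   `"either"` (nearest of the pooled peaks, H3K4me3 preferred on ties).
#' @return The transcripts with a `tss_status` metadata column; 5' ends
#'   moved only for status `"corrected"`. 3' ends and strands are never
#'   touched and the operation is idempotent.
#' @export
correct_tss <- function(transcripts, h3k4me3, polii, tss_flank = 1000,
                        max_distance = 10000,
                        anchor = c("h3k4me3_first", "either")) {
  stopifnot(methods::is(transcripts, "GRanges"),
            methods::is(h3k4me3, "GRanges"), methods::is(polii, "GRanges"))
  anchor <- match.arg(anchor)
  out <- transcripts
  plus <- as.character(GenomicRanges::strand(transcripts)) == "+"
  tss <- five_prime_pos(transcripts)
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(transcripts),
    IRanges::IRanges(pmax(1, tss - tss_flank), tss + tss_flank))
  has_h3 <- IRanges::overlapsAny(win, h3k4me3, ignore.strand = TRUE)
  has_pol <- IRanges::overlapsAny(win, polii, ignore.strand = TRUE)
  status <- ifelse(has_h3 & has_pol, "h3k4me3_and_polii",
                   ifelse(has_h3, "h3k4me3_only", "needs_correction"))

  nearest_anchor <- function(i) {
    chr <- as.character(GenomicRanges::seqnames(transcripts)[i])
    pick <- function(peaks) {
      same <- peaks[as.character(GenomicRanges::seqnames(peaks)) == chr]
      if (length(same) == 0L) return(NULL)
      centers <- peak_center(same)
      d <- abs(centers - tss[i])
      ok <- d <= max_distance
      if (!any(ok)) return(NULL)
      centers <- centers[ok]; d <- d[ok]
      best <- which(d == min(d))
      if (length(best) > 1L) {
        # Tie: choose the upstream candidate (lower coordinate on +,
        # higher on -).
        cand <- centers[best]
        best <- best[if (plus[i]) which.min(cand) else which.max(cand)]
      }
      c(center = centers[best], dist = d[best])
    }
    if (anchor == "h3k4me3_first") {
      hit <- pick(h3k4me3)
      if (is.null(hit)) hit <- pick(polii)
      hit
    } else {
      h1 <- pick(h3k4me3); h2 <- pick(polii)
      if (is.null(h1)) return(h2)
      if (is.null(h2)) return(h1)
      if (h2["dist"] < h1["dist"]) h2 else h1   # H3K4me3 wins ties
    }
  }

  for (i in which(status == "needs_correction")) {
    hit <- nearest_anchor(i)
    if (is.null(hit)) {
      status[i] <- "uncorrectable"
      next
    }
    ctr <- unname(hit["center"])
    # Guard: refuse a correction that would invert the transcript.
    if (plus[i]) {
      if (ctr >= GenomicRanges::end(out)[i]) { status[i] <- "uncorrectable"; next }
      GenomicRanges::start(out)[i] <- ctr
    } else {
      if (ctr <= GenomicRanges::start(out)[i]) { status[i] <- "uncorrectable"; next }
      GenomicRanges::end(out)[i] <- ctr
    }
    status[i] <- "corrected"
  }
  S4Vectors::mcols(out)$tss_status <- status
  out
}

#' Assign regulators to transcripts from ChIP peak calls
#'
#' A regulator is assigned to a transcript when one of its peaks overlaps
#' the transcript's promoter window ([promoter_window()]) by at least one
#' base AND the peak's dataset-support count meets the regulator's rule.
#' The default rule mirrors the asymmetric evidence available for
#' circadian TFs: BMAL1 binding (six published ChIP-seq datasets) needs
#' support in at least two datasets; every other regulator needs one.
#'
#' @param transcripts Stranded `GRanges` with a `transcript_id` metadata
#'   column (falls back to names, then to positional ids).
#' @param calls `GRanges` of peaks with metadata columns `regulator` and
#'   `n_supporting_datasets`.
#' @param min_support Named integer vector of per-regulator minimum
#'   support (default `c(BMAL1 = 2)`).
#' @param default_support Minimum support for regulators absent from
#'   `min_support` (default 1). Set to `NA` to require every regulator
#'   to be named explicitly — an unknown regulator is then an error.
#' @param upstream Promoter window upstream extension in bp.
#' @return Data frame of edges: `regulator`, `transcript`,
#'   `n_supporting_datasets` (maximum over that regulator's qualifying
#'   peaks in the window), deduplicated and sorted.
#' @export
assign_regulators <- function(transcripts, calls,
                              min_support = c(BMAL1 = 2L),
                              default_support = 1L, upstream = 5000) {
  stopifnot(methods::is(transcripts, "GRanges"), methods::is(calls, "GRanges"))
  mc <- S4Vectors::mcols(calls)
  if (!all(c("regulator", "n_supporting_datasets") %in% names(mc)))
    stop("calls need metadata columns 'regulator' and 'n_supporting_datasets'")
  if (any(mc$n_supporting_datasets < 1))
    stop("n_supporting_datasets must be >= 1")
  regs <- as.character(mc$regulator)
  known <- regs %in% names(min_support)
  if (any(!known) && is.na(default_support))
    stop("no support rule for regulator(s): ",
         paste(unique(regs[!known]), collapse = ", "))
  req <- ifelse(known, min_support[regs], default_support)
  ids <- S4Vectors::mcols(transcripts)$transcript_id
  if (is.null(ids)) ids <- names(transcripts)
  if (is.null(ids)) ids <- paste0("transcript_", seq_along(transcripts))
  win <- promoter_window(transcripts, upstream)
  keep <- mc$n_supporting_datasets >= req
  calls <- calls[keep]
  regs <- regs[keep]
  hits <- GenomicRanges::findOverlaps(win, calls, minoverlap = 1L,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(data.frame(regulator = character(), transcript = character(),
                      n_supporting_datasets = integer(),
                      stringsAsFactors = FALSE))
  df <- data.frame(
    regulator = regs[S4Vectors::subjectHits(hits)],
    transcript = ids[S4Vectors::queryHits(hits)],
    n_supporting_datasets =
      S4Vectors::mcols(calls)$n_supporting_datasets[
        S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  agg <- stats::aggregate(n_supporting_datasets ~ regulator + transcript,
                          data = df, FUN = max)
  agg <- agg[order(agg$regulator, agg$transcript), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Binding enrichment of a regulator on circadian promoters
#'
#' Proportion test of the bound fraction among circadian transcripts
#' against the bound fraction among all transcripts (the circadian set
#' is a subset of the universe, as in a foreground-vs-all comparison).
#'
#' @param circadian_transcripts,all_transcripts Character vectors of
#'   transcript ids; the circadian set must be contained in the full set.
#' @param edges Edge data frame from [assign_regulators()].
#' @param regulator Regulator name to test.
#' @return A [proportion_enrichment()] result.
#' @export
binding_enrichment <- function(circadian_transcripts, all_transcripts,
                               edges, regulator) {
  if (length(circadian_transcripts) == 0L || length(all_transcripts) == 0L)
    stop("empty transcript set")
  if (!all(circadian_transcripts %in% all_transcripts))
    stop("circadian transcripts must be a subset of all transcripts")
  bound <- unique(edges$transcript[edges$regulator == regulator])
  proportion_enrichment(sum(circadian_transcripts %in% bound),
                        length(circadian_transcripts),
                        sum(all_transcripts %in% bound),
                        length(all_transcripts))
}

# TF pairs anchoring the two motif types. ASCII aliases accepted for the
# REV-ERB paralogs.
MOTIF_TF_SETS <- list(
  "1" = c("BMAL1", "CLOCK"),
  "2" = c("REV-ERBA", "REV-ERBB", "REV-ERBALPHA", "REV-ERBBETA",
          "NR1D1", "NR1D2"))

#' Build miRNA / TF regulatory motifs
#'
#' Constructs the two feed-forward-style motifs linking a circadian
#' miRNA, a circadian TF pair and a jointly regulated target:
#' * type 1 — the target peaks around CT10 (Group I), is bound and
#'   functionally regulated by BMAL1/CLOCK, and is a miRNA target
#'   (the Gadd45a/Por pattern);
#' * type 2 — the target peaks around CT22 (Group III), is regulated by
#'   REV-ERBalpha/beta, and is a miRNA target (the Cdkn1a/Bcl2 pattern).
#'
#' TF regulation requires both a binding edge and a functional flag
#' (e.g. under-expression in the TF knockout, supplied as input).
#'
#' @param tf_edges Data frame with columns `tf`, `target` and logical
#'   `functional` (knockout evidence; rows with `functional = FALSE`
#'   contribute binding only and never form a motif).
#' @param mirna_target_edges Data frame with columns `mirna`, `target`.
#' @param groups Named character (or factor) vector: circadian group
#'   (`"I"`/`"II"`/`"III"`/`"IV"`/`"none"`) per gene, as produced by
#'   [classify_groups()].
#' @return Data frame sorted by motif type, target, miRNA: `motif_type`
#'   (1 or 2), `tf_set` (`"BMAL1/CLOCK"` or `"REV-ERBa/b"`), `tfs`
#'   (the supporting TFs, `+`-collapsed), `mirna`, `target`,
#'   `target_group`. Empty inputs give an empty frame.
#' @export
build_motifs <- function(tf_edges, mirna_target_edges, groups) {
  empty <- data.frame(motif_type = integer(), tf_set = character(),
                      tfs = character(), mirna = character(),
                      target = character(), target_group = character(),
                      stringsAsFactors = FALSE)
  if (NROW(tf_edges) == 0L || NROW(mirna_target_edges) == 0L ||
      length(groups) == 0L)
    return(empty)
  stopifnot(all(c("tf", "target", "functional") %in% names(tf_edges)),
            all(c("mirna", "target") %in% names(mirna_target_edges)),
            !is.null(names(groups)))
  groups <- stats::setNames(as.character(groups), names(groups))
  tf_edges <- tf_edges[tf_edges$functional, , drop = FALSE]
  rows <- list()
  for (type in c("1", "2")) {
    tfs_ok <- toupper(tf_edges$tf) %in% MOTIF_TF_SETS[[type]]
    want_grp <- if (type == "1") "I" else "III"
    set_lab <- if (type == "1") "BMAL1/CLOCK" else "REV-ERBa/b"
    for (j in seq_len(nrow(mirna_target_edges))) {
      tgt <- mirna_target_edges$target[j]
      if (is.na(groups[tgt]) || groups[tgt] != want_grp) next
      sup <- tf_edges$tf[tfs_ok & tf_edges$target == tgt]
      if (length(sup) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        motif_type = as.integer(type), tf_set = set_lab,
        tfs = paste(sort(unique(sup)), collapse = "+"),
        mirna = mirna_target_edges$mirna[j], target = tgt,
        target_group = want_grp, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$motif_type, out$target, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}
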