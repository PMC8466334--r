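#' Filter substances for an analysis set
#'
#' Applies the retention rule used before any statistics: a compound enters
#' the analysis only if it is present (area above `presence_threshold`) in
#' every sample of the analysis set, and it is not attributable to paper or
#' ambient background. The background screen uses the control sleeves/blanks:
#' a compound whose mean area in control samples is at least its mean area in
#' the analysis samples is considered background and dropped. Every drop is
#' reported with its reason.
#'
#' @param table A [peak_table()].
#' @param analysis_sources Character vector of sample sources defining the
#'   analysis set (e.g. `c("mark1", "mark2")`).
#' @param presence_threshold Area above which a compound counts as present
#'   (default 0: any strictly positive area).
#' @return A list of class `filter_report`: `retained` (compound names),
#'   `dropped_absent`, `dropped_background`, `analysis_sources`,
#'   `presence_threshold`, and a `log` data frame (compound, status, reason).
#' @export
filter_substances <- function(table, analysis_sources,
                              presence_threshold = 0) {
  stopifnot(inherits(table, "peak_table"))
  if (length(analysis_sources) == 0) stop("analysis_sources must be non-empty")
  if (!all(is_valid_source(analysis_sources)))
    stop("unknown analysis source: ",
         paste(analysis_sources[!is_valid_source(analysis_sources)],
               collapse = ", "))
  src <- table$sample_meta$source
  in_set <- src %in% analysis_sources
  if (!any(in_set)) stop("no samples with source in analysis_sources")
  ctrl <- src %in% c("control_sleeve", "blank")

  a_set <- table$areas[in_set, , drop = FALSE]
  present_all <- apply(a_set > presence_threshold, 2, all)

  if (any(ctrl)) {
    ctrl_mean <- colMeans(table$areas[ctrl, , drop = FALSE])
    set_mean <- colMeans(a_set)
    background <- ctrl_mean >= set_mean
  } else {
    background <- rep(FALSE, ncol(table$areas))
  }

  nm <- colnames(table$areas)
  dropped_absent <- nm[!present_all]
  dropped_background <- nm[present_all & background]
  retained <- nm[present_all & !background]
  if (length(retained) == 0)
    stop("all compounds dropped by the substance filter; dataset unusable")

  status <- ifelse(!present_all, "dropped_absent",
            ifelse(background, "dropped_background", "retained"))
  reason <- ifelse(!present_all,
                   "not present in all analysis samples",
            ifelse(background,
                   "control-sleeve mean >= analysis mean", ""))
  structure(list(retained = retained,
                 dropped_absent = dropped_absent,
                 dropped_background = dropped_background,
                 analysis_sources = analysis_sources,
                 presence_threshold = presence_threshold,
                 log = data.frame(compound = nm, status = status,
                                  reason = reason, stringsAsFactors = FALSE)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Substance filter (sources: ",
      paste(x$analysis_sources, collapse = ", "), "): ",
      length(x$retained), " retained, ",
      length(x$dropped_absent), " absent, ",
      length(x$dropped_background), " background\n", sep = "")
  invisible(x)
}

#' Screen for individual-specific private substances
#'
#' A compound is private to a bee if it is present (area above the filter
#' report's `presence_threshold`) in at least one of that bee's samples and
#' absent from every sample of every other bee. Control sleeves and blanks
#' are excluded from the scan. With a single bee in the table every present
#' compound is trivially private (degenerate case, reported as such).
#'
#' @param table A [peak_table()].
#' @param filter_report A [filter_substances()] result (supplies the presence
#'   threshold); optional, default threshold 0.
#' @return Named list bee -> character vector of private compounds; bees
#'   without private compounds are omitted (empty list if none anywhere).
#' @export
detect_private_substances <- function(table, filter_report = NULL) {
  stopifnot(inherits(table, "peak_table"))
  thr <- if (is.null(filter_report)) 0 else filter_report$presence_threshold
  keep <- !table$sample_meta$source %in% c("control_sleeve", "blank")
  areas <- table$areas[keep, , drop = FALSE]
  bees <- table$sample_meta$nest_id[keep]
  present <- areas > thr
  out <- list()
  for (b in unique(bees)) {
    own <- present[bees == b, , drop = FALSE]
    other <- present[bees != b, , drop = FALSE]
    in_own <- apply(own, 2, any)
    in_other <- if (nrow(other)) apply(other, 2, any)
                else rep(FALSE, ncol(present))
    priv <- colnames(areas)[in_own & !in_other]
    if (length(priv)) out[[b]] <- priv
  }
  out
}

#' Quantile normalization across samples
#'
#' Forces every sample (row) to share one common value distribution: values
#' are ranked within each sample and replaced by the mean of the
#' corresponding order statistics across all samples. Ties within a sample
#' receive the mean of the reference values at their tied ranks. This removes
#' non-linear per-sample intensity biases (e.g. extract amount or body size)
#' while preserving within-sample ranks.
#'
#' @param matrix Numeric matrix, samples in rows, compounds in columns; at
#'   least 2 rows.
#' @return Matrix of the same shape and dimnames.
#' @examples
#' quantile_normalize(rbind(c(2, 4, 6), c(3, 6, 9)))  # both rows (2.5, 5, 7.5)
#' @export
quantile_normalize <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("input must be a numeric matrix")
  if (any(!is.finite(matrix))) stop("input must be finite")
  if (nrow(matrix) < 2)
    stop("quantile normalization needs >= 2 samples (nothing to normalize against)")
  p <- ncol(matrix)
  # reference distribution: mean of order statistics across samples
  sorted <- apply(matrix, 1, sort)            # p x n, each column one sample
  ref <- rowMeans(sorted)
  out <- matrix
  for (i in seq_len(nrow(matrix))) {
    x <- matrix[i, ]
    ord <- order(x)
    vals <- ref
    # ties: average the reference values over each run of equal inputs
    runs <- rle(x[ord])
    pos <- 1L
    for (k in seq_along(runs$lengths)) {
      len <- runs$lengths[k]
      if (len > 1) vals[pos:(pos + len - 1)] <- mean(ref[pos:(pos + len - 1)])
      pos <- pos + len
    }
    out[i, ord] <- vals
  }
  out
}

#' Centered log-ratio transformation
#'
#' Per sample j, `clr(Y_ij) = ln(Y_ij / g(Y_j))` where `g(Y_j)` is the
#' geometric mean of all peak areas of sample j. Maps compositional rows to
#' an unconstrained space in which every row sums to zero, making the result
#' invariant to per-sample scaling. Zeros must have been removed upstream by
#' the substance filter; no pseudo-count is applied silently.
#'
#' @param matrix Numeric matrix, samples in rows; all values strictly
#'   positive.
#' @return Matrix of the same shape; rows sum to 0 (within 1e-9).
#' @export
clr_transform <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("input must be a numeric matrix")
  bad <- which(!(matrix > 0) | !is.finite(matrix), arr.ind = TRUE)
  if (nrow(bad)) {
    rn <- if (is.null(rownames(matrix))) bad[1, 1] else rownames(matrix)[bad[1, 1]]
    cn <- if (is.null(colnames(matrix))) bad[1, 2] else colnames(matrix)[bad[1, 2]]
    stop("clr requires strictly positive values; offending cell [", rn, ", ",
         cn, "]", if (nrow(bad) > 1) paste0(" (and ", nrow(bad) - 1, " more)"))
  }
  lx <- log(matrix)
  sweep(lx, 1, rowMeans(lx), "-")
}
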