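# Expression-matrix container, median normalization, low-expression
# filtering, and log transform.

#' Expression matrix container
#'
#' Transcript-by-sample values with a processing-stage flag. Stages advance
#' only raw -> normalized -> logged.
#'
#' @param values Numeric matrix, transcripts in rows, samples in columns.
#' @param transcript_ids,sample_ids Identifiers; default to dimnames.
#' @param cell_type,visit Labels carried through the pipeline.
#' @param stage One of `raw`, `normalized`, `logged`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, transcript_ids = rownames(values),
                        sample_ids = colnames(values),
                        cell_type = "unknown", visit = "visit1",
                        stage = c("raw", "normalized", "logged")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (is.null(transcript_ids)) transcript_ids <- sprintf("tr_%02d", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%05d", seq_len(ncol(values)))
  stopifnot(length(transcript_ids) == nrow(values),
            length(sample_ids) == ncol(values))
  if (stage == "raw" && any(values < 0, na.rm = TRUE)) {
    stop("raw counts must be nonnegative")
  }
  dimnames(values) <- list(transcript_ids, sample_ids)
  structure(list(values = values, transcript_ids = transcript_ids,
                 sample_ids = sample_ids, cell_type = cell_type,
                 visit = visit, stage = stage),
            class = "expr_matrix")
}

#' @export
#' @method print expr_matrix
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d transcripts x %d samples [%s, %s, stage=%s]\n",
              nrow(x$values), ncol(x$values), x$cell_type, x$visit, x$stage))
  invisible(x)
}

#' Median normalization of raw counts
#'
#' Each sample's counts are divided by its scale factor
#' `s_i = median_i / geometric mean of all sample medians`, so the scale
#' factors multiply to one and the operation is symmetric in samples.
#'
#' @param raw An `expr_matrix` at stage `raw`.
#' @return An `expr_matrix` at stage `normalized`, with the per-sample scale
#'   factors as attribute `scale_factors`.
#' @export
median_normalize <- function(raw) {
  stopifnot(inherits(raw, "expr_matrix"))
  if (raw$stage != "raw") stop("median_normalize expects stage 'raw'")
  v <- raw$values
  all_zero <- colSums(v != 0) == 0
  if (any(all_zero)) {
    stop("sample(s) with all-zero counts: ",
         paste(raw$sample_ids[all_zero], collapse = ", "))
  }
  med <- apply(v, 2, stats::median)
  if (any(med <= 0)) {
    stop("sample(s) with non-positive median count: ",
         paste(raw$sample_ids[med <= 0], collapse = ", "))
  }
  s <- med / exp(mean(log(med)))
  out <- sweep(v, 2, s, `/`)
  res <- expr_matrix(out, raw$transcript_ids, raw$sample_ids, raw$cell_type,
                     raw$visit, stage = "normalized")
  attr(res, "scale_factors") <- stats::setNames(s, raw$sample_ids)
  res
}

#' Low-expression transcript filter
#'
#' A transcript is retained iff all four rules hold: proportion of zeros
#' <= 0.5, median >= 1, expression range (max - min) >= 5, and maximum >= 10.
#' Removal corresponds to strictly violating a rule, so equality retains.
#'
#' @param norm An `expr_matrix` at stage `normalized`.
#' @return A list with `expression` (filtered `expr_matrix`) and `report`
#'   (class `filter_report`: one row per transcript with the rule values, the
#'   pass flag, and the first failing rule).
#' @export
filter_transcripts <- function(norm) {
  stopifnot(inherits(norm, "expr_matrix"))
  if (norm$stage != "normalized") stop("filter_transcripts expects stage 'normalized'")
  v <- norm$values
  if (nrow(v) == 0 || ncol(v) == 0) stop("empty expression matrix")
  proportion_zero <- rowMeans(v == 0)
  median_value <- apply(v, 1, stats::median)
  max_value <- apply(v, 1, max)
  range_value <- max_value - apply(v, 1, min)
  pass <- proportion_zero <= 0.5 & median_value >= 1 &
    range_value >= 5 & max_value >= 10
  first_fail <- rep(NA_character_, nrow(v))
  first_fail[max_value < 10] <- "max_value"
  first_fail[range_value < 5] <- "range_value"
  first_fail[median_value < 1] <- "median_value"
  first_fail[proportion_zero > 0.5] <- "proportion_zero"
  report <- data.frame(transcript_id = norm$transcript_ids,
                       proportion_zero = proportion_zero,
                       median_value = median_value,
                       range_value = range_value,
                       max_value = max_value,
                       pass = pass, first_failing_rule = first_fail,
                       stringsAsFactors = FALSE, row.names = NULL)
  class(report) <- c("filter_report", "data.frame")
  expression <- expr_matrix(v[pass, , drop = FALSE],
                            norm$transcript_ids[pass], norm$sample_ids,
                            norm$cell_type, norm$visit, stage = "normalized")
  attr(expression, "filtered") <- TRUE
  list(expression = expression, report = report)
}

#' Log2 transform with half-minimum zero replacement
#'
#' Per transcript, zero values are replaced with half the minimum positive
#' value of that transcript across the analysis sample, then all values are
#' log2-transformed. Rank order within each transcript is preserved.
#'
#' @param norm A filtered `expr_matrix` at stage `normalized`.
#' @return An `expr_matrix` at stage `logged`.
#' @export
log_transform <- function(norm) {
  stopifnot(inherits(norm, "expr_matrix"))
  if (norm$stage != "normalized") stop("log_transform expects stage 'normalized'")
  v <- norm$values
  for (i in seq_len(nrow(v))) {
    zero <- v[i, ] == 0
    if (any(zero)) {
      pos <- v[i, !zero]
      if (length(pos) == 0) {
        stop("transcript with all-zero values at log stage: ",
             norm$transcript_ids[i], " (should have been filtered)")
      }
      v[i, zero] <- min(pos) / 2
    }
  }
  expr_matrix(log2(v), norm$transcript_ids, norm$sample_ids, norm$cell_type,
              norm$visit, stage = "logged")
}
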