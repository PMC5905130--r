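# Image-level quality control and pooling.
#
# The model expects a 1:1 RedOnly:GreenOnly ratio; images where one
# single-color class outnumbers the other by a large fold (optics, uneven
# seed placement) would bias the pooled estimate and are discarded before
# pooling.

#' Quality-control parameters
#'
#' @param skew_fold Fold threshold on the RedOnly:GreenOnly ratio (either
#'   direction); default 4.  `Inf` disables the filter.
#' @param strict If `FALSE` (default) an image is discarded when the skew is
#'   `>= skew_fold` (inclusive rule); if `TRUE` only when strictly greater.
#' @return A `qc_params` object.
#' @export
qc_params <- function(skew_fold = 4, strict = FALSE) {
  if (!is.numeric(skew_fold) || length(skew_fold) != 1L || skew_fold <= 1)
    stop("'skew_fold' must be a single value > 1", call. = FALSE)
  structure(list(skew_fold = skew_fold, strict = isTRUE(strict)),
            class = "qc_params")
}

#' Filter images with a skewed RedOnly:GreenOnly ratio
#'
#' Computes for each image `skew = max(red_only, green_only) /
#' min(red_only, green_only)` and discards images whose skew reaches the
#' fold threshold.  If exactly one of the two counts is zero the skew is
#' infinite and the image is discarded; if both are zero the skew is defined
#' as 1 and the image is kept (it carries no recombinant signal to bias the
#' ratio).  The rule is symmetric in the two channels and ignores the BOTH
#' and NONE tallies.
#'
#' @param per_image_counts List of [seed_counts] (names used as image ids).
#' @param params A [qc_params] object.
#' @return List with `kept` and `discarded` (sublists of the input) and
#'   `report`, a data frame: `image_id`, `n_red_only`, `n_green_only`,
#'   `skew`, `kept`.
#' @export
skew_filter <- function(per_image_counts, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  per_image_counts <- lapply(per_image_counts, as_seed_counts)
  ids <- names(per_image_counts)
  if (is.null(ids)) ids <- as.character(seq_along(per_image_counts))
  skew <- vapply(per_image_counts, function(cc) {
    r <- cc[["red_only"]]; g <- cc[["green_only"]]
    if (r == 0 && g == 0) 1
    else if (min(r, g) == 0) Inf
    else max(r, g) / min(r, g)
  }, numeric(1))
  discard <- if (params$strict) skew > params$skew_fold else
    skew >= params$skew_fold
  report <- data.frame(
    image_id = ids,
    n_red_only = vapply(per_image_counts, `[[`, numeric(1), "red_only"),
    n_green_only = vapply(per_image_counts, `[[`, numeric(1), "green_only"),
    skew = unname(skew), kept = !discard, stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(kept = per_image_counts[!discard],
       discarded = per_image_counts[discard],
       report = report)
}

#' Pool per-image seed-class counts
#'
#' Elementwise sum of the kept images' tallies into one per-sample tally.
#'
#' @param kept Non-empty list of [seed_counts].
#' @return A [seed_counts] object.
#' @export
pool_counts <- function(kept) {
  if (!length(kept))
    stop("all images failed QC: no counts left to pool", call. = FALSE)
  kept <- lapply(kept, as_seed_counts)
  tot <- Reduce(`+`, lapply(kept, unclass))
  seed_counts(tot[["red_only"]], tot[["green_only"]], tot[["both"]],
              tot[["none"]])
}
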