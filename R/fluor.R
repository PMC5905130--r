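# Per-object fluorescence measurement and seed classification.
#
# Mean object intensity per channel is compared against adjustable
# thresholds on the [0, 1] scale (FilterObjects-style); a seed is positive
# in a channel iff its mean intensity reaches the channel threshold
# (inclusive), and the four phenotype classes follow from the two flags.

#' Fluorescence classification thresholds
#'
#' Defaults are the optimized settings for the reference microscope setup:
#' 0.12 for red and 0.077 for green fluorescence, on the bit-depth-normalized
#' [0, 1] intensity scale.  They are microscope-specific and should be
#' retuned for other setups.
#'
#' @param red_min,green_min Mean-intensity thresholds in (0, 1).
#' @return A `fluor_thresholds` object.
#' @export
fluor_thresholds <- function(red_min = 0.12, green_min = 0.077) {
  for (v in c(red_min, green_min))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0 || v >= 1)
      stop("fluorescence thresholds must be in (0, 1)", call. = FALSE)
  structure(list(red_min = red_min, green_min = green_min),
            class = "fluor_thresholds")
}

#' Measure per-object fluorescence
#'
#' Computes area, centroid and mean RFP/GFP intensity for every object in a
#' label mask.  Images must be co-registered with the mask and on a [0, 1]
#' scale.
#'
#' @param mask Integer label mask (0 = background).
#' @param rfp_image,gfp_image Channel intensity matrices, same shape as
#'   `mask`.
#' @return Data frame with one row per object: `object_id`, `area`,
#'   `centroid_row`, `centroid_col`, `mean_red`, `mean_green` (and no class
#'   yet; see [classify_seeds()]).  Empty mask gives an empty data frame.
#' @export
measure_seeds <- function(mask, rfp_image, gfp_image) {
  if (!identical(dim(mask), dim(rfp_image)) ||
      !identical(dim(mask), dim(gfp_image)))
    stop("mask and channel images differ in shape", call. = FALSE)
  k <- max(mask)
  empty <- data.frame(object_id = integer(0), area = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      mean_red = numeric(0), mean_green = numeric(0))
  if (k < 1L) return(empty)
  idx <- which(mask > 0L)
  lab <- factor(mask[idx], levels = seq_len(k))
  area <- as.integer(table(lab))
  present <- which(area > 0L)
  sum_by <- function(v) as.numeric(rowsum(v, lab)[, 1L])
  rows <- ((idx - 1L) %% nrow(mask)) + 1L
  cols <- ((idx - 1L) %/% nrow(mask)) + 1L
  df <- data.frame(object_id = present,
                   area = area[present],
                   centroid_row = sum_by(rows)[present] / area[present],
                   centroid_col = sum_by(cols)[present] / area[present],
                   mean_red = sum_by(rfp_image[idx])[present] / area[present],
                   mean_green = sum_by(gfp_image[idx])[present] / area[present])
  rownames(df) <- NULL
  df
}

#' Classify measured seeds by fluorescence thresholds
#'
#' A seed is red-positive iff `mean_red >= red_min` and green-positive iff
#' `mean_green >= green_min` (thresholds inclusive); the class is `BOTH`,
#' `RED_ONLY`, `GREEN_ONLY` or `NONE` accordingly.
#'
#' @param records Data frame from [measure_seeds()].
#' @param thresholds A [fluor_thresholds] object.
#' @return `records` with a `seed_class` column added; the per-image
#'   [seed_counts] tally is attached as attribute `counts` and also
#'   available via [count_classes()].
#' @export
classify_seeds <- function(records, thresholds = fluor_thresholds()) {
  stopifnot(inherits(thresholds, "fluor_thresholds"))
  if (!all(c("mean_red", "mean_green") %in% names(records)))
    stop("'records' must come from measure_seeds()", call. = FALSE)
  red <- records$mean_red >= thresholds$red_min
  green <- records$mean_green >= thresholds$green_min
  records$seed_class <- ifelse(red & green, "BOTH",
                        ifelse(red, "RED_ONLY",
                        ifelse(green, "GREEN_ONLY", "NONE")))
  attr(records, "counts") <- count_classes(records)
  records
}

#' @rdname classify_seeds
#' @export
count_classes <- function(records) {
  cls <- factor(records$seed_class, levels = SEED_CLASSES)
  tab <- table(cls)
  seed_counts(tab[["RED_ONLY"]], tab[["GREEN_ONLY"]], tab[["BOTH"]],
              tab[["NONE"]])
}
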