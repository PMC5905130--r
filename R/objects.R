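# From class-probability maps to individual seed objects.
#
# Core mask = pixels where Seed is both above `p_seed_min` and the argmax
# class; SeedEdge-dominant pixels are excluded from the core and thereby act
# as watershed barriers between tangent seeds.  Declumped cores are expanded
# back over the non-background zone (rims included) by intensity-guided
# propagation, the IdentifySecondaryObjects idiom.

#' Segmentation parameters
#'
#' @param p_seed_min Seed-probability threshold for the core mask.
#' @param declump Split touching seeds by watershed on the distance
#'   transform.
#' @param min_marker_distance Minimum distance (px) between watershed
#'   markers; default close to the expected seed minor axis.
#' @param area_min,area_max Object area limits in px^2 (fixture-calibrated
#'   defaults; retune for real microscopes).
#' @param discard_border_objects Drop objects touching the image border.
#' @param fill_holes Fill holes in the seed mask.
#' @return A `seg_params` object.
#' @export
seg_params <- function(p_seed_min = 0.5, declump = TRUE,
                       min_marker_distance = 7, area_min = 30,
                       area_max = 400, discard_border_objects = TRUE,
                       fill_holes = TRUE) {
  if (p_seed_min <= 0 || p_seed_min >= 1)
    stop("'p_seed_min' must be in (0, 1)", call. = FALSE)
  if (area_min >= area_max)
    stop("'area_min' must be smaller than 'area_max'", call. = FALSE)
  structure(list(p_seed_min = p_seed_min, declump = isTRUE(declump),
                 min_marker_distance = min_marker_distance,
                 area_min = area_min, area_max = area_max,
                 discard_border_objects = isTRUE(discard_border_objects),
                 fill_holes = isTRUE(fill_holes)),
            class = "seg_params")
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged with a small union-find pass.
label8 <- function(mask) {
  lab <- as_mat(EBImage::bwlabel(mask * 1))
  k <- max(lab)
  if (k < 2L) return(matrix(as.integer(lab), nrow(lab), ncol(lab)))
  pairs <- rbind(diag_pairs(lab, 1L, 1L), diag_pairs(lab, 1L, -1L))
  if (nrow(pairs)) {
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (p in seq_len(nrow(pairs))) {
      ra <- find(pairs[p, 1L]); rb <- find(pairs[p, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(k), find, integer(1))
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  relabel(lab)
}

diag_pairs <- function(lab, dr, dc) {
  s <- shift_mat(lab, dr, dc)
  sel <- lab > 0L & s > 0L & lab != s
  if (!any(sel)) return(matrix(integer(0), 0, 2))
  unique(cbind(lab[sel], s[sel]))
}

# Map labels to contiguous 1..K preserving first-appearance order.
relabel <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (length(u)) out[lab > 0L] <- match(lab[lab > 0L], u)
  out
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), dim(x)[1], dim(x)[2])
}

#' Segment individual seeds from a class-probability map
#'
#' @param prob `nrow x ncol x 3` probability array from [predict_pixels()]
#'   (planes Seed, SeedEdge, Background).
#' @param params A [seg_params] object.
#' @return Integer label mask (0 = background, k = object k, labels
#'   contiguous) with attribute `n_objects`.  An empty mask is a valid
#'   result with 0 objects.
#' @export
segment_seeds <- function(prob, params = seg_params()) {
  if (length(dim(prob)) != 3L || dim(prob)[3] != 3L)
    stop("'prob' must be a 3-plane class-probability array", call. = FALSE)
  stopifnot(inherits(params, "seg_params"))
  ps <- prob[, , 1L]; pe <- prob[, , 2L]; pb <- prob[, , 3L]
  core <- ps >= params$p_seed_min & ps >= pe & ps >= pb
  if (!any(core)) {
    out <- matrix(0L, nrow(ps), ncol(ps))
    attr(out, "n_objects") <- 0L
    return(out)
  }
  core_m <- core * 1
  if (params$fill_holes) core_m <- as_mat(EBImage::fillHull(core_m))
  if (params$declump) {
    d <- as_mat(EBImage::distmap(core_m))
    ext <- max(1L, as.integer(round(params$min_marker_distance / 2)))
    lab <- as_mat(EBImage::watershed(d, tolerance = 1, ext = ext))
  } else {
    lab <- label8(core_m)
  }
  # expand cores over the full non-background zone so rims belong to objects
  full <- (pmax(ps, pe) >= pb) | core_m > 0
  lab <- as_mat(EBImage::propagate(ps, lab, mask = full))
  if (params$fill_holes) {
    filled <- as_mat(EBImage::fillHull(lab))
    lab[lab == 0] <- filled[lab == 0]
  }
  lab <- matrix(as.integer(round(lab)), nrow(lab), ncol(lab))
  # area filter
  k <- max(lab)
  if (k > 0L) {
    areas <- tabulate(lab, nbins = k)
    drop <- which(areas < params$area_min | areas > params$area_max)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  if (params$discard_border_objects && max(lab) > 0L) {
    border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L],
                       lab[, ncol(lab)]))
    border <- border[border > 0L]
    if (length(border)) lab[lab %in% border] <- 0L
  }
  out <- relabel(lab)
  attr(out, "n_objects") <- max(out)
  out
}

#' Match segmented objects against ground truth
#'
#' Greedy one-to-one matching by intersection-over-union: candidate pairs
#' are visited in decreasing IoU order and accepted while both objects are
#' unmatched and IoU >= `iou_min`.
#'
#' @param mask Predicted label mask.
#' @param truth_mask Ground-truth label mask of identical shape.
#' @param iou_min Minimum IoU for a detection (default 0.5).
#' @return List with `precision`, `recall`, `f1`, `n_pred`, `n_truth`, and
#'   `matches` (data frame `pred`, `truth`, `iou`).
#' @export
match_to_truth <- function(mask, truth_mask, iou_min = 0.5) {
  if (!identical(dim(mask), dim(truth_mask)))
    stop("mask and ground truth differ in shape", call. = FALSE)
  mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  truth_mask <- matrix(as.integer(truth_mask), nrow(truth_mask),
                       ncol(truth_mask))
  a_pred <- tabulate(mask, nbins = max(max(mask), 1L))
  a_truth <- tabulate(truth_mask, nbins = max(max(truth_mask), 1L))
  # count objects actually present (labels need not be contiguous)
  n_pred <- sum(a_pred > 0L); n_truth <- sum(a_truth > 0L)
  sel <- mask > 0L & truth_mask > 0L
  matches <- data.frame(pred = integer(0), truth = integer(0),
                        iou = numeric(0))
  if (any(sel)) {
    ov <- table(pred = mask[sel], truth = truth_mask[sel])
    df <- as.data.frame(ov, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0L, ]
    df$pred <- as.integer(df$pred); df$truth <- as.integer(df$truth)
    df$iou <- df$Freq / (a_pred[df$pred] + a_truth[df$truth] - df$Freq)
    df <- df[order(-df$iou, df$pred, df$truth), ]
    used_p <- logical(length(a_pred)); used_t <- logical(length(a_truth))
    keep <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      if (df$iou[i] < iou_min) break
      if (!used_p[df$pred[i]] && !used_t[df$truth[i]]) {
        keep[i] <- TRUE
        used_p[df$pred[i]] <- TRUE
        used_t[df$truth[i]] <- TRUE
      }
    }
    matches <- df[keep, c("pred", "truth", "iou")]
  }
  tp <- nrow(matches)
  precision <- if (n_pred > 0L) tp / n_pred else NA_real_
  recall <- if (n_truth > 0L) tp / n_truth else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_pred = n_pred, n_truth = n_truth, matches = matches)
}
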