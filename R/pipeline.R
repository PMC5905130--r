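# Batch orchestration: discover White/RFP/GFP triplets, run
# classify -> segment -> measure -> QC -> estimate, write overlays and CSVs.

#' Discover White/RFP/GFP image triplets in a directory
#'
#' Groups files matching a naming pattern with placeholders `{sample}`,
#' `{index}` and `{channel}` (channel one of `white`, `rfp`, `gfp`,
#' case-insensitive) into complete triplets.  Incomplete triplets are
#' reported with a warning and skipped; zero complete triplets is an error.
#'
#' @param input_dir Directory to scan.
#' @param pattern Naming pattern; default `{sample}_{index}_{channel}.tif`
#'   (also matches `.tiff`).
#' @return Data frame with one row per triplet: `sample_id`, `image_index`,
#'   `white`, `rfp`, `gfp` (full paths), ordered by sample then index.
#' @export
discover_triplets <- function(input_dir,
                              pattern = "{sample}_{index}_{channel}.tif") {
  if (!dir.exists(input_dir))
    stop("input directory '", input_dir, "' does not exist", call. = FALSE)
  rx <- gsub("([][(){}.^$|*+?\\\\])", "\\\\\\1", pattern)
  rx <- sub("\\\\\\{sample\\\\\\}", "(.+?)", rx)
  rx <- sub("\\\\\\{index\\\\\\}", "([0-9]+)", rx)
  rx <- sub("\\\\\\{channel\\\\\\}", "(white|rfp|gfp)", rx)
  if (grepl("\\.tif$", rx)) rx <- paste0(rx, "f?")
  rx <- paste0("^", rx, "$")
  files <- list.files(input_dir)
  m <- regmatches(files, regexec(rx, files, ignore.case = TRUE))
  hit <- lengths(m) == 4L
  if (!any(hit))
    stop("no files in '", input_dir, "' match pattern '", pattern, "'",
         call. = FALSE)
  df <- data.frame(file = files[hit],
                   sample_id = vapply(m[hit], `[`, "", 2L),
                   image_index = vapply(m[hit], `[`, "", 3L),
                   channel = tolower(vapply(m[hit], `[`, "", 4L)),
                   stringsAsFactors = FALSE)
  key <- paste(df$sample_id, df$image_index, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    sub <- df[key == k, ]
    if (!all(c("white", "rfp", "gfp") %in% sub$channel)) {
      warning("incomplete triplet (", sub$sample_id[1L], ", image ",
              sub$image_index[1L], "): have only ",
              paste(sort(sub$channel), collapse = "/"), call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      sample_id = sub$sample_id[1L],
      image_index = sub$image_index[1L],
      white = file.path(input_dir, sub$file[sub$channel == "white"][1L]),
      rfp = file.path(input_dir, sub$file[sub$channel == "rfp"][1L]),
      gfp = file.path(input_dir, sub$file[sub$channel == "gfp"][1L]),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    stop("no complete White/RFP/GFP triplets found in '", input_dir, "'",
         call. = FALSE)
  res <- do.call(rbind, out)
  res[order(res$sample_id, suppressWarnings(as.integer(res$image_index)),
            res$image_index), , drop = FALSE]
}

# Read a TIFF as a [0,1] grayscale matrix (RGB inputs are averaged).
read_gray_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- rowMeans(x, dims = 2L)
  if (!is.matrix(x)) stop("'", path, "' is not a 2-D image", call. = FALSE)
  x
}

#' Read one co-registered image triplet
#'
#' @param triplet One row of [discover_triplets()] output (or a list with
#'   `white`, `rfp`, `gfp` paths).
#' @return List with `white`, `rfp`, `gfp` matrices on [0, 1]; an error if
#'   the three images differ in shape.
#' @export
read_triplet <- function(triplet) {
  imgs <- lapply(triplet[c("white", "rfp", "gfp")],
                 function(p) read_gray_tiff(as.character(p)))
  if (!identical(dim(imgs$white), dim(imgs$rfp)) ||
      !identical(dim(imgs$white), dim(imgs$gfp)))
    stop("triplet images differ in shape", call. = FALSE)
  imgs
}

# Object outlines colored by seed class over the bright-field image, with
# the object count annotated, written as PNG.
CLASS_COLORS <- c(RED_ONLY = "#FF2020", GREEN_ONLY = "#20DD20",
                  BOTH = "#FFD700", NONE = "#9A9A9A")

write_overlay <- function(white, mask, records, path) {
  nr <- nrow(white); nc <- ncol(white)
  img <- array(rep(pmin(pmax(white, 0), 1), 3L), dim = c(nr, nc, 3L))
  boundary <- mask > 0L &
    (shift_mat(mask, 1L, 0L) != mask | shift_mat(mask, -1L, 0L) != mask |
     shift_mat(mask, 0L, 1L) != mask | shift_mat(mask, 0L, -1L) != mask)
  cls_of <- character(max(mask, 1L))
  cls_of[records$object_id] <- records$seed_class
  bidx <- which(boundary)
  if (length(bidx)) {
    rgb_m <- grDevices::col2rgb(CLASS_COLORS[cls_of[mask[bidx]]]) / 255
    npix <- nr * nc
    img[bidx] <- rgb_m[1L, ]
    img[bidx + npix] <- rgb_m[2L, ]
    img[bidx + 2L * npix] <- rgb_m[3L, ]
  }
  grDevices::png(path, width = nc, height = nr)
  op <- graphics::par(mar = rep(0, 4), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, nc), ylim = c(0, nr))
  graphics::rasterImage(img, 0, 0, nc, nr)
  graphics::text(8, nr - 10, labels = sprintf("n = %d", nrow(records)),
                 adj = c(0, 1), col = "#2020FF", cex = max(1, nc / 650))
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}

#' Run the full seed-counting pipeline on a directory of image triplets
#'
#' For every discovered triplet: pixel classification of the bright-field
#' image, seed segmentation, per-object fluorescence measurement and
#' classification, and an overlay image; per-image class tallies then pass
#' the skew QC filter, kept images are pooled per sample and fitted with
#' [xo_fit()].  Per-image failures are logged and skipped; a sample fails
#' only if no image survives.
#'
#' @param input_dir Directory with TIFF triplets.
#' @param output_dir Output directory (created): `objects.csv`,
#'   `qc_report.csv`, `summary.csv`, `run.log`, `overlays/`, optionally
#'   `masks/`.
#' @param classifier A [train_pixel_classifier()] object, or path to an RDS
#'   file containing one.
#' @param thresholds,seg,qc Parameter objects ([fluor_thresholds()],
#'   [seg_params()], [qc_params()]).
#' @param map_function Mapping function highlighted in the log (all three
#'   distances are always reported in the summary).
#' @param pattern File-naming pattern, see [discover_triplets()].
#' @param save_masks Write label masks as 16-bit TIFFs.
#' @param overlays Write PNG overlays.
#' @param verbose Also log to stderr.
#' @return Invisibly, a list with `summary` (per-sample data frame, see
#'   [write_summary()]), `objects` (per-seed data frame), `qc` (QC report)
#'   and `fits` (named list of [xo_fit] objects).
#' @export
run_pipeline <- function(input_dir, output_dir, classifier,
                         thresholds = fluor_thresholds(),
                         seg = seg_params(), qc = qc_params(),
                         map_function = c("haldane", "kosambi", "identity"),
                         pattern = "{sample}_{index}_{channel}.tif",
                         save_masks = FALSE, overlays = TRUE,
                         verbose = TRUE) {
  map_function <- match.arg(map_function)
  if (is.character(classifier)) classifier <- readRDS(classifier)
  stopifnot(inherits(classifier, "pixel_classifier"),
            inherits(thresholds, "fluor_thresholds"),
            inherits(seg, "seg_params"), inherits(qc, "qc_params"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (overlays)
    dir.create(file.path(output_dir, "overlays"), showWarnings = FALSE)
  if (save_masks)
    dir.create(file.path(output_dir, "masks"), showWarnings = FALSE)
  logfile <- file.path(output_dir, "run.log")
  logcon <- file(logfile, open = "wt")
  on.exit(close(logcon))
  log <- function(...) {
    msg <- paste0(...)
    writeLines(msg, logcon)
    if (verbose) message(msg)
  }
  log("xoseed run: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  log("config: red_min=", thresholds$red_min,
      " green_min=", thresholds$green_min,
      " p_seed_min=", seg$p_seed_min,
      " area=[", seg$area_min, ",", seg$area_max, "]",
      " declump=", seg$declump,
      " skew_fold=", qc$skew_fold, " (strict=", qc$strict, ")",
      " map_function=", map_function)

  triplets <- discover_triplets(input_dir, pattern)
  log("found ", nrow(triplets), " complete triplet(s), ",
      length(unique(triplets$sample_id)), " sample(s)")

  all_objects <- list()
  image_counts <- list()
  for (i in seq_len(nrow(triplets))) {
    tr <- triplets[i, ]
    image_id <- sprintf("%s_%s", tr$sample_id, tr$image_index)
    res <- tryCatch({
      imgs <- read_triplet(tr)
      prob <- predict_pixels(classifier, imgs$white)
      mask <- segment_seeds(prob, seg)
      rec <- classify_seeds(measure_seeds(mask, imgs$rfp, imgs$gfp),
                            thresholds)
      if (overlays)
        write_overlay(imgs$white, mask, rec,
                      file.path(output_dir, "overlays",
                                paste0(image_id, ".png")))
      if (save_masks)
        tiff::writeTIFF(mask / 65535,
                        file.path(output_dir, "masks",
                                  paste0(image_id, "_mask.tif")),
                        bits.per.sample = 16L, compression = "none")
      list(records = rec, counts = attr(rec, "counts"))
    }, error = function(e) {
      log("ERROR in image ", image_id, ": ", conditionMessage(e),
          " (skipped)")
      NULL
    })
    if (is.null(res)) next
    rec <- res$records
    if (nrow(rec)) {
      rec <- cbind(image_id = image_id, sample_id = tr$sample_id, rec,
                   stringsAsFactors = FALSE)
      all_objects[[length(all_objects) + 1L]] <- rec
    }
    image_counts[[image_id]] <- list(sample_id = tr$sample_id,
                                     counts = res$counts)
    log(image_id, ": ", sum(res$counts), " seeds (",
        paste(names(res$counts), unclass(res$counts), sep = "=",
              collapse = ", "), ")")
  }
  if (!length(image_counts))
    stop("pipeline produced no usable images", call. = FALSE)

  objects_df <- if (length(all_objects)) do.call(rbind, all_objects) else
    data.frame()
  samples <- unique(vapply(image_counts, `[[`, "", "sample_id"))
  qc_rows <- list()
  summary_rows <- list()
  fits <- list()
  for (s in samples) {
    sel <- vapply(image_counts, function(x) x$sample_id == s, logical(1))
    counts <- lapply(image_counts[sel], `[[`, "counts")
    fl <- skew_filter(counts, qc)
    qc_rows[[s]] <- cbind(sample_id = s, fl$report,
                          stringsAsFactors = FALSE)
    row <- data.frame(sample_id = s, n_images_total = length(counts),
                      n_images_kept = length(fl$kept),
                      n_total = NA_real_, n_red_only = NA_real_,
                      n_green_only = NA_real_, n_both = NA_real_,
                      n_none = NA_real_, f_single = NA_real_,
                      r_hat = NA_real_, cm_identity = NA_real_,
                      cm_haldane = NA_real_, cm_kosambi = NA_real_,
                      flag = "", stringsAsFactors = FALSE)
    if (!length(fl$kept)) {
      log("sample ", s, ": all ", length(counts), " images failed QC")
      stop("sample '", s, "' has zero images left after QC", call. = FALSE)
    }
    pooled <- pool_counts(fl$kept)
    row[c("n_red_only", "n_green_only", "n_both", "n_none")] <-
      as.list(unclass(pooled))
    row$n_total <- sum(pooled)
    # one-channel-dead guard: a single dead color channel at nonzero signal
    # in the other points at a threshold problem, not biology
    dead <- xor(pooled[["red_only"]] == 0, pooled[["green_only"]] == 0) &&
      max(pooled[["red_only"]], pooled[["green_only"]]) >= 10
    fit <- tryCatch(xo_fit(pooled), error = function(e) {
      log("sample ", s, ": estimation failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(fit)) {
      fits[[s]] <- fit
      row$f_single <- fit$f_single
      row$r_hat <- fit$r_hat
      row$cm_identity <- fit$cm[["identity"]]
      row$cm_haldane <- fit$cm[["haldane"]]
      row$cm_kosambi <- fit$cm[["kosambi"]]
      log("sample ", s, ": n=", row$n_total, " f=",
          signif(fit$f_single, 5), " r_hat=", signif(fit$r_hat, 5), " (",
          signif(fit$cm[[map_function]], 5), " cM ", map_function, ")")
    } else {
      row$flag <- "estimation_failed"
    }
    if (dead) row$flag <- trimws(paste(row$flag, "threshold_suspect"))
    summary_rows[[s]] <- row
  }
  summary_df <- do.call(rbind, summary_rows)
  rownames(summary_df) <- NULL
  qc_df <- do.call(rbind, qc_rows)
  rownames(qc_df) <- NULL

  if (nrow(objects_df))
    write_csv(objects_df, file.path(output_dir, "objects.csv"))
  write_csv(qc_df, file.path(output_dir, "qc_report.csv"))
  write_summary(summary_df, file.path(output_dir, "summary.csv"))
  log("wrote summary for ", nrow(summary_df), " sample(s) to ",
      file.path(output_dir, "summary.csv"))
  invisible(list(summary = summary_df, objects = objects_df, qc = qc_df,
                 fits = fits))
}

#' Write the per-sample summary CSV
#'
#' Fixed column order: `sample_id`, `n_images_total`, `n_images_kept`,
#' `n_total`, `n_red_only`, `n_green_only`, `n_both`, `n_none`, `f_single`,
#' `r_hat`, `cm_identity`, `cm_haldane`, `cm_kosambi`, `flag`.
#'
#' @param summary_df Per-sample summary data frame (from [run_pipeline()]).
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_summary <- function(summary_df, path) {
  cols <- c("sample_id", "n_images_total", "n_images_kept", "n_total",
            "n_red_only", "n_green_only", "n_both", "n_none", "f_single",
            "r_hat", "cm_identity", "cm_haldane", "cm_kosambi", "flag")
  missing <- setdiff(cols, names(summary_df))
  if (length(missing))
    stop("summary is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  write_csv(summary_df[, cols, drop = FALSE], path)
  invisible(path)
}
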