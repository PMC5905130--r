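# Synthetic image triplets with ground truth.
#
# Emulates the acquisition protocol: seeds spread without overlap on a light
# background, photographed in bright field ("White") and in the RFP and GFP
# fluorescence channels.  Seeds are dark filled ellipses with a darker rim
# (the rim gives the pixel classifier an edge class to learn); fluorescence
# is a low autofluorescence baseline inside every seed plus a per-seed
# carrier signal in the channel(s) whose transgene the genotype carries.
# Genotypes are drawn from the coupling-phase F2 model at `r_true`.

#' Specification of a synthetic seed scene
#'
#' Parameters of one synthetic White/RFP/GFP image triplet.  Defaults emulate
#' the published acquisition: 2592 x 1944 px frames with ~400 seeds each (ten
#' frames per sample covering 3000-5000 seeds); seed size in pixels is a free
#' parameter of the microscope zoom and defaults to semi-axes 6-9 x 4-6 px.
#' Intensities are on a [0, 1] scale.
#'
#' @param width,height Image size in pixels.
#' @param n_seeds Number of seeds to place.
#' @param seed_axis_major,seed_axis_minor Ranges (min, max) of the ellipse
#'   semi-axes in pixels.
#' @param min_gap Minimum gap between seed boundaries in pixels; 0 allows
#'   tangent seeds.
#' @param n_debris Number of small sub-seed-sized distractor blobs.
#' @param background_level,seed_body_level Bright-field intensities of paper
#'   background and seed body.
#' @param rim_darkening Amount subtracted from the body level on the ~2 px
#'   seed rim.
#' @param rim_width Rim width in pixels.
#' @param carrier_signal_mean,carrier_signal_sd Per-seed fluorescence signal
#'   of transgene carriers (mean and between-seed SD).
#' @param autofluorescence_level Baseline fluorescence inside every seed,
#'   both channels.  The default is low; raise it to build a stress fixture
#'   for threshold tuning.
#' @param noise_sd Per-pixel Gaussian noise SD, all channels.
#' @param texture_sd SD of the smooth speckle texture on the bright-field
#'   background.
#' @param r_true Recombination fraction used to draw seed genotypes.
#' @param rng_seed Integer seed; scenes are fully reproducible.
#' @return A `scene_spec` object (validated list).
#' @examples
#' sp <- scene_spec(width = 324, height = 243, n_seeds = 60, rng_seed = 7)
#' @export
scene_spec <- function(width = 2592, height = 1944, n_seeds = 400,
                       seed_axis_major = c(6, 9), seed_axis_minor = c(4, 6),
                       min_gap = 2, n_debris = 20,
                       background_level = 0.85, seed_body_level = 0.40,
                       rim_darkening = 0.15, rim_width = 2,
                       carrier_signal_mean = 0.35, carrier_signal_sd = 0.04,
                       autofluorescence_level = 0.03,
                       noise_sd = 0.02, texture_sd = 0.02,
                       r_true = 0.16, rng_seed = 1) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_seeds = as.integer(n_seeds),
               seed_axis_major = seed_axis_major,
               seed_axis_minor = seed_axis_minor,
               min_gap = min_gap, n_debris = as.integer(n_debris),
               background_level = background_level,
               seed_body_level = seed_body_level,
               rim_darkening = rim_darkening, rim_width = rim_width,
               carrier_signal_mean = carrier_signal_mean,
               carrier_signal_sd = carrier_signal_sd,
               autofluorescence_level = autofluorescence_level,
               noise_sd = noise_sd, texture_sd = texture_sd,
               r_true = r_true, rng_seed = as.integer(rng_seed))
  lv <- c("background_level", "seed_body_level", "rim_darkening",
          "carrier_signal_mean", "carrier_signal_sd",
          "autofluorescence_level")
  for (nm in lv)
    if (spec[[nm]] < 0 || spec[[nm]] > 1)
      stop("'", nm, "' must be in [0, 1]", call. = FALSE)
  if (spec$noise_sd < 0 || spec$texture_sd < 0)
    stop("noise parameters must be non-negative", call. = FALSE)
  if (spec$carrier_signal_mean - 2 * spec$carrier_signal_sd <=
      spec$autofluorescence_level)
    stop("carrier_signal_mean - 2*carrier_signal_sd must exceed ",
         "autofluorescence_level (classes must be separable)", call. = FALSE)
  if (diff(spec$seed_axis_major) < 0 || diff(spec$seed_axis_minor) < 0 ||
      min(spec$seed_axis_minor) <= 0)
    stop("invalid seed axis ranges", call. = FALSE)
  check_rfrac(spec$r_true)
  if (spec$width < 16 || spec$height < 16 || spec$n_seeds < 1)
    stop("scene too small", call. = FALSE)
  structure(spec, class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("Synthetic scene: %d x %d px, %d seeds, r_true = %.3f, seed = %d\n",
              x$width, x$height, x$n_seeds, x$r_true, x$rng_seed))
  invisible(x)
}

# Non-overlap placement by rejection sampling on centre distances: two
# ellipses cannot intersect if their centres are further apart than the sum
# of their major semi-axes (conservative criterion).
place_seeds <- function(spec, a) {
  n <- spec$n_seeds
  cx <- cy <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 2000L * n
  margin <- a + spec$rim_width + 2
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", n, " non-overlapping seeds in a ",
           spec$height, " x ", spec$width,
           " px scene; lower n_seeds or the seed axis ranges",
           call. = FALSE)
    i <- placed + 1L
    x <- stats::runif(1, margin[i], spec$height - margin[i])
    y <- stats::runif(1, margin[i], spec$width - margin[i])
    if (placed > 0L) {
      j <- seq_len(placed)
      d2 <- (cx[j] - x)^2 + (cy[j] - y)^2
      if (any(d2 < (a[j] + a[i] + spec$min_gap)^2)) next
    }
    cx[i] <- x; cy[i] <- y
    placed <- i
  }
  cbind(row = cx, col = cy)
}

# Paint one ellipse into the label/rim masks (in-place via environment-free
# return of modified matrices would copy; caller loops, images are modest).
ellipse_masks <- function(nr, nc, cx, cy, a, b, theta, rim_width) {
  r0 <- max(1L, floor(cx - a - 1)); r1 <- min(nr, ceiling(cx + a + 1))
  c0 <- max(1L, floor(cy - a - 1)); c1 <- min(nc, ceiling(cy + a + 1))
  rr <- r0:r1; cc <- c0:c1
  dx <- outer(rr - cx, rep(1, length(cc)))
  dy <- outer(rep(1, length(rr)), cc - cy)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  full <- (u / a)^2 + (v / b)^2 <= 1
  ai <- max(a - rim_width, 1); bi <- max(b - rim_width, 1)
  inner <- (u / ai)^2 + (v / bi)^2 <= 1
  list(rows = rr, cols = cc, full = full, rim = full & !inner)
}

# Smooth speckle texture: white noise blurred at sigma = 3 px, rescaled.
speckle <- function(nr, nc, sd) {
  if (sd <= 0) return(matrix(0, nr, nc))
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  z <- conv_reflect(z, gauss_kernel(3))
  z / stats::sd(z) * sd
}

#' Generate one synthetic image triplet with ground truth
#'
#' Builds co-registered White/RFP/GFP intensity matrices on a [0, 1] scale
#' plus per-pixel and per-seed ground truth, fully reproducibly from
#' `spec$rng_seed`.  See [scene_spec()] for the scene model.
#'
#' @param spec A [scene_spec] object.
#' @return A list of class `seed_scene`:
#'   \describe{
#'     \item{images}{list of `white`, `rfp`, `gfp` matrices.}
#'     \item{truth}{list with `label_mask` (0 = background, k = seed k),
#'       `rim_mask`, `debris_mask`, and `seeds`, a data frame with one row
#'       per seed: `seed_id`, `gamete1`, `gamete2`, logical `red`/`green`
#'       carrier flags, `true_class`, `centroid_row`, `centroid_col`,
#'       `area`.}
#'     \item{spec}{the input spec.}
#'   }
#' @examples
#' sc <- generate_scene(scene_spec(width = 324, height = 243, n_seeds = 40))
#' table(sc$truth$seeds$true_class)
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$rng_seed, {
    nr <- spec$height; nc <- spec$width
    n <- spec$n_seeds
    a <- stats::runif(n, spec$seed_axis_major[1], spec$seed_axis_major[2])
    b <- stats::runif(n, spec$seed_axis_minor[1], spec$seed_axis_minor[2])
    theta <- stats::runif(n, 0, pi)
    centres <- place_seeds(spec, a)

    # genotypes: two independent gametes per seed
    g <- gamete_freqs(spec$r_true)
    g1 <- sample.int(4L, n, replace = TRUE, prob = g)
    g2 <- sample.int(4L, n, replace = TRUE, prob = g)
    red_by_gam <- c(TRUE, FALSE, FALSE, TRUE)   # GR, nn, Gn, nR
    green_by_gam <- c(TRUE, FALSE, TRUE, FALSE)
    red <- red_by_gam[g1] | red_by_gam[g2]
    green <- green_by_gam[g1] | green_by_gam[g2]
    true_class <- ifelse(red & green, "BOTH",
                  ifelse(red, "RED_ONLY",
                  ifelse(green, "GREEN_ONLY", "NONE")))

    label <- matrix(0L, nr, nc)
    rim <- matrix(FALSE, nr, nc)
    for (k in seq_len(n)) {
      em <- ellipse_masks(nr, nc, centres[k, 1], centres[k, 2],
                          a[k], b[k], theta[k], spec$rim_width)
      sub <- label[em$rows, em$cols]
      sub[em$full] <- k
      label[em$rows, em$cols] <- sub
      subr <- rim[em$rows, em$cols]
      subr[em$rim] <- TRUE
      rim[em$rows, em$cols] <- subr
    }
    inside <- label > 0L

    # bright field
    white <- matrix(spec$background_level, nr, nc) + speckle(nr, nc, spec$texture_sd)
    white[inside] <- spec$seed_body_level
    white[rim] <- spec$seed_body_level - spec$rim_darkening

    # debris: small irregular dark-grey blobs off the seeds, below seed size
    debris <- matrix(FALSE, nr, nc)
    if (spec$n_debris > 0L) {
      placed <- 0L; tries <- 0L
      while (placed < spec$n_debris && tries < 50L * spec$n_debris) {
        tries <- tries + 1L
        rad <- stats::runif(1, 1, 2.5)
        cx <- stats::runif(1, rad + 1, nr - rad - 1)
        cy <- stats::runif(1, rad + 1, nc - rad - 1)
        em <- ellipse_masks(nr, nc, cx, cy, rad, rad * stats::runif(1, 0.5, 1),
                            stats::runif(1, 0, pi), 0)
        if (any(label[em$rows, em$cols][em$full] > 0L)) next
        subd <- debris[em$rows, em$cols]
        subd[em$full] <- TRUE
        debris[em$rows, em$cols] <- subd
        placed <- placed + 1L
      }
      white[debris] <- 0.55
    }
    if (spec$noise_sd > 0)
      white <- white + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    white <- pmin(pmax(white, 0), 1)

    # fluorescence channels: camera floor + in-seed autofluorescence +
    # per-seed carrier signal
    sig_red <- stats::rnorm(n, spec$carrier_signal_mean, spec$carrier_signal_sd)
    sig_green <- stats::rnorm(n, spec$carrier_signal_mean, spec$carrier_signal_sd)
    chan <- function(carrier, sig) {
      img <- matrix(0.005, nr, nc)
      img[inside] <- spec$autofluorescence_level
      add <- which(carrier)
      for (k in add) {
        px <- label == k
        img[px] <- img[px] + sig[k]
      }
      if (spec$noise_sd > 0)
        img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
      pmin(pmax(img, 0), 1)
    }
    rfp <- chan(red, sig_red)
    gfp <- chan(green, sig_green)

    area <- tabulate(label, nbins = n)
    seeds <- data.frame(seed_id = seq_len(n),
                        gamete1 = GAMETE_CLASSES[g1],
                        gamete2 = GAMETE_CLASSES[g2],
                        red = red, green = green,
                        true_class = true_class,
                        centroid_row = centres[, 1],
                        centroid_col = centres[, 2],
                        area = area,
                        stringsAsFactors = FALSE)
    structure(list(images = list(white = white, rfp = rfp, gfp = gfp),
                   truth = list(label_mask = label, rim_mask = rim,
                                debris_mask = debris, seeds = seeds),
                   spec = spec),
              class = "seed_scene")
  })
}

#' Write a set of synthetic image triplets to disk
#'
#' Emits `n_images` TIFF triplets named by the pipeline's naming convention
#' (`{sample}_{index}_{channel}.tif`), one 16-bit label-mask TIFF per image,
#' and a single ground-truth CSV (`<sample>_ground_truth.csv`).  Image `i`
#' uses `rng_seed + i - 1`, so the set is deterministic for a fixed spec.
#'
#' @param spec A [scene_spec]; its `rng_seed` seeds the first image.
#' @param n_images Number of triplets (the protocol uses ten per sample).
#' @param out_dir Output directory (created if needed).
#' @param sample_id Sample identifier used in file names.
#' @param bits TIFF bit depth for the channel images (8 or 16).
#' @return Invisibly, a manifest data frame (`image_index`, `white`, `rfp`,
#'   `gfp`, `mask` paths) with the ground-truth CSV path as attribute
#'   `ground_truth`.
#' @export
write_fixture_set <- function(spec, n_images, out_dir, sample_id = "S1",
                              bits = 8L) {
  stopifnot(inherits(spec, "scene_spec"), bits %in% c(8L, 16L))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  manifest <- data.frame(image_index = seq_len(n_images),
                         white = character(n_images),
                         rfp = character(n_images),
                         gfp = character(n_images),
                         mask = character(n_images),
                         stringsAsFactors = FALSE)
  for (i in seq_len(n_images)) {
    sp <- spec
    sp$rng_seed <- spec$rng_seed + i - 1L
    sc <- generate_scene(sp)
    for (ch in c("white", "rfp", "gfp")) {
      path <- file.path(out_dir, sprintf("%s_%02d_%s.tif", sample_id, i, ch))
      write_image_tiff(sc$images[[ch]], path, bits = bits)
      manifest[[ch]][i] <- path
    }
    mpath <- file.path(out_dir, sprintf("%s_%02d_mask.tif", sample_id, i))
    tiff::writeTIFF(sc$truth$label_mask / 65535, mpath, bits.per.sample = 16L,
                    compression = "none")
    manifest$mask[i] <- mpath
    tr <- sc$truth$seeds
    rows[[i]] <- data.frame(image_id = sprintf("%s_%02d", sample_id, i),
                            seed_id = tr$seed_id, true_class = tr$true_class,
                            centroid_row = round(tr$centroid_row, 2),
                            centroid_col = round(tr$centroid_col, 2),
                            area = tr$area, stringsAsFactors = FALSE)
  }
  gt_path <- file.path(out_dir, sprintf("%s_ground_truth.csv", sample_id))
  write_csv(do.call(rbind, rows), gt_path)
  attr(manifest, "ground_truth") <- gt_path
  invisible(manifest)
}

# Quantize to the TIFF bit depth and write; readers recover values in [0,1].
write_image_tiff <- function(img, path, bits = 8L) {
  img <- pmin(pmax(img, 0), 1)
  ok <- try(tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits),
                            compression = "none"), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write TIFF '", path, "': ", attr(ok, "condition")$message,
         call. = FALSE)
  invisible(path)
}

# RFC-4180-ish CSV with a fixed eol so re-runs are byte identical.
write_csv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, eol = "\n")
  invisible(path)
}
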