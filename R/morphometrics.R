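#' Form factor of a shape
#'
#' The form factor (circularity) `FF = 4 * pi * area / perimeter^2`
#' compares a shape to the circle of equal perimeter: 1 for a circle
#' (isoperimetric equality) and values approaching 0 for polarized,
#' highly arborized outlines such as astrocytes with long processes. FF
#' is invariant to uniform rescaling of the shape.
#'
#' @param area enclosed area (e.g. um^2 or px^2); > 0.
#' @param perimeter boundary length in matching units; > 0.
#' @return the dimensionless form factor.
#' @export
form_factor <- function(area, perimeter) {
  if (!is.numeric(area) || !is.numeric(perimeter) ||
      any(!is.finite(area)) || any(!is.finite(perimeter)) ||
      any(area <= 0) || any(perimeter <= 0)) {
    stop("area and perimeter must be positive finite numbers")
  }
  4 * pi * area / perimeter^2
}

#' Read a binary mask image
#'
#' Reads an 8-bit PNG/TIFF (any pixel > 0 is foreground) into a 0/1
#' matrix.
#'
#' @param path image file readable by [EBImage::readImage()].
#' @return numeric matrix of 0/1.
#' @export
read_mask <- function(path) {
  img <- EBImage::readImage(path)
  m <- EBImage::imageData(img)
  if (length(dim(m)) > 2) m <- m[, , 1]   # first channel of RGB masks
  (m > 0) * 1
}

# Sub-pixel boundary length of a binary mask: marching-squares contour at
# level 0.5 (grDevices::contourLines on the padded mask), lightly smoothed
# with a circular 3-point moving average of the polygon vertices to remove
# the staircase-induced overestimate on curved boundaries. Hole contours
# are included in the total.
mask_perimeter <- function(mask, smooth_window = 3L) {
  z <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  z[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask > 0) * 1
  cl <- contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)), z = z,
                     levels = 0.5)
  smooth_closed <- function(v, w) {
    n <- length(v)
    if (w < 2L || n <= w) return(v)
    half <- w %/% 2L
    idx <- outer(seq_len(n), -half:half, function(i, k) ((i + k - 1L) %% n) + 1L)
    rowMeans(matrix(v[idx], n))
  }
  closed_length <- function(x, y) {
    x <- c(x, x[1]); y <- c(y, y[1])
    sum(sqrt(diff(x)^2 + diff(y)^2))
  }
  sum(vapply(cl, function(cc) {
    # contourLines may already close the loop; drop the duplicate vertex
    n <- length(cc$x)
    if (n > 1 && cc$x[1] == cc$x[n] && cc$y[1] == cc$y[n]) {
      cc$x <- cc$x[-n]; cc$y <- cc$y[-n]
    }
    closed_length(smooth_closed(cc$x, smooth_window),
                  smooth_closed(cc$y, smooth_window))
  }, 0))
}

#' Measure area, perimeter and form factor of a mask
#'
#' The mask must contain exactly one connected foreground component
#' (4-connectivity, as labelled by [EBImage::bwlabel()]). Area is the
#' foreground pixel count scaled by `pixel_size^2`; the perimeter is the
#' length of the sub-pixel marching-squares contour of the mask (lightly
#' smoothed to suppress pixelation bias on curved outlines) scaled by
#' `pixel_size`.
#'
#' @param mask 0/1 numeric or logical matrix, or a path readable by
#'   [read_mask()].
#' @param pixel_size physical side length of one pixel (e.g. um); default
#'   1 reports pixel units.
#' @return a `shape_measure` object: list with `area`, `perimeter`,
#'   `form_factor`.
#' @export
measure_mask <- function(mask, pixel_size = 1) {
  if (is.character(mask)) mask <- read_mask(mask)
  if (!is.matrix(mask)) stop("mask must be a matrix or an image path")
  fg <- (mask > 0) * 1
  n_fg <- sum(fg)
  if (n_fg == 0) stop("empty mask: no foreground pixels")
  n_comp <- max(EBImage::bwlabel(fg))
  if (n_comp != 1) {
    stop("mask must contain exactly one connected component, found ", n_comp)
  }
  area <- n_fg * pixel_size^2
  perimeter <- mask_perimeter(fg) * pixel_size
  structure(list(area = area, perimeter = perimeter,
                 form_factor = form_factor(area, perimeter)),
            class = "shape_measure")
}

#' @export
print.shape_measure <- function(x, ...) {
  cat("shape: area ", format(x$area, digits = 5), ", perimeter ",
      format(x$perimeter, digits = 5), ", form factor ",
      format(x$form_factor, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Distance-binned particle density profile along a process
#'
#' Bins particle distances from the process tip into half-open segments
#' `[i*w, (i+1)*w)` across the distal `segment_length` (e.g. fifteen 1-um
#' bins over the distal 15 um) and divides each bin's particle count by
#' the corresponding bin volume. Particles at or beyond `segment_length`
#' are excluded.
#'
#' @param particle_distances numeric vector of distances from the tip
#'   (um, >= 0).
#' @param bin_volumes per-bin process volumes (um^3), one per bin, all
#'   > 0.
#' @param segment_length profiled length from the tip (um); default 15.
#' @param bin_width bin width (um); default 1. `segment_length /
#'   bin_width` must be an integer equal to `length(bin_volumes)`.
#' @return a `process_profile` object: list with `counts`, `densities`
#'   (particles per um^3), `bin_start`, `bin_width`, `segment_length`,
#'   `bin_volumes`, `n_excluded`.
#' @export
particle_density_profile <- function(particle_distances, bin_volumes,
                                     segment_length = 15, bin_width = 1) {
  n_bins <- segment_length / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop("segment_length / bin_width must be an integer number of bins")
  }
  n_bins <- as.integer(round(n_bins))
  if (length(bin_volumes) != n_bins) {
    stop("expected ", n_bins, " bin volumes, got ", length(bin_volumes))
  }
  if (any(!is.finite(bin_volumes)) || any(bin_volumes <= 0)) {
    stop("bin volumes must be positive")
  }
  d <- particle_distances
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("particle distances must be finite and nonnegative")
  }
  breaks <- seq(0, segment_length, by = bin_width)
  idx <- findInterval(d, breaks)            # [breaks[i], breaks[i+1])
  in_seg <- idx >= 1L & idx <= n_bins & d < segment_length
  counts <- tabulate(idx[in_seg], nbins = n_bins)
  structure(list(counts = counts,
                 densities = counts / bin_volumes,
                 bin_start = breaks[-length(breaks)],
                 bin_width = bin_width,
                 segment_length = segment_length,
                 bin_volumes = bin_volumes,
                 n_excluded = sum(!in_seg)),
            class = "process_profile")
}

#' @export
print.process_profile <- function(x, ...) {
  cat("particle density profile: ", length(x$counts), " bins of ",
      x$bin_width, " um, ", sum(x$counts), " particles in segment (",
      x$n_excluded, " beyond)\n", sep = "")
  invisible(x)
}

#' Volume ratio (e.g. mitochondrial density of a process)
#'
#' @param object_volume volume of the labelled objects (um^3), >= 0.
#' @param region_volume volume of the enclosing region (um^3), > 0.
#' @return `object_volume / region_volume`.
#' @export
volume_ratio <- function(object_volume, region_volume) {
  if (!is.numeric(region_volume) || any(!is.finite(region_volume)) ||
      any(region_volume <= 0)) {
    stop("region_volume must be positive")
  }
  if (!is.numeric(object_volume) || any(!is.finite(object_volume)) ||
      any(object_volume < 0)) {
    stop("object_volume must be nonnegative")
  }
  object_volume / region_volume
}

#' Percent of one mask's area overlapped by another
#'
#' Computes `100 * |a & b| / |a|`: the percentage of `mask_a`'s
#' foreground covered by `mask_b` (e.g. the share of mitochondrial area
#' overlapping glutamate-transporter territory). Note the statistic is
#' asymmetric in its arguments.
#'
#' @param mask_a,mask_b matrices of identical dimensions; foreground is
#'   `> 0`. `mask_a` must be nonempty.
#' @return overlap percentage in \[0, 100\].
#' @export
area_overlap_percent <- function(mask_a, mask_b) {
  if (is.character(mask_a)) mask_a <- read_mask(mask_a)
  if (is.character(mask_b)) mask_b <- read_mask(mask_b)
  if (!identical(dim(mask_a), dim(mask_b))) {
    stop("masks must have identical dimensions")
  }
  a <- mask_a > 0; b <- mask_b > 0
  if (!sum(a)) stop("mask_a has no foreground pixels")
  100 * sum(a & b) / sum(a)
}

# wrap an angle (degrees) into [-90, 90)
wrap180 <- function(theta) ((theta + 90) %% 180) - 90

#' Orientation dispersion factor of a texture
#'
#' Estimates the local orientation of image structure (e.g. microtubule
#' bundles) at every pixel from the intensity gradient, accumulates a
#' gradient-energy-weighted orientation histogram over `[-90, 90)`
#' degrees, and fits a Gaussian (amplitude, mean, sigma, baseline) to the
#' histogram with wrap-around handling. The dispersion factor is the
#' fitted sigma in degrees: small for parallel, well-organized structure
#' and large for disorganized, near-isotropic texture.
#'
#' Orientation here is the direction *along* the structures (stripes),
#' i.e. perpendicular to the dominant intensity gradient; 0 degrees runs
#' along the first matrix dimension.
#'
#' @param image numeric matrix (grayscale).
#' @param roi optional logical/0-1 matrix of the same dimensions
#'   restricting the analysis; default uses the full frame.
#' @param bin_width histogram bin width in degrees (default 2).
#' @return an `orientation_dispersion` object: list with `histogram`
#'   (data.frame `angle`, `weight`), `fitted_mean` (degrees in
#'   `[-90, 90)`), `dispersion` (Gaussian sigma, degrees), `goodness`
#'   (R^2 of the fit, clipped to \[0, 1\]).
#' @export
dispersion_factor <- function(image, roi = NULL, bin_width = 2) {
  if (!is.matrix(image)) stop("image must be a numeric matrix")
  if (is.null(roi)) roi <- matrix(TRUE, nrow(image), ncol(image))
  if (!identical(dim(roi), dim(image))) {
    stop("image and roi must have identical dimensions")
  }
  if (!any(roi > 0)) stop("empty roi")
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3 || nc < 3) stop("image too small for gradient estimation")
  # central differences on the interior
  gx <- (image[3:nr, 2:(nc - 1)] - image[1:(nr - 2), 2:(nc - 1)]) / 2
  gy <- (image[2:(nr - 1), 3:nc] - image[2:(nr - 1), 1:(nc - 2)]) / 2
  inside <- roi[2:(nr - 1), 2:(nc - 1)] > 0
  energy <- (gx^2 + gy^2)[inside]
  if (sum(energy) <= 0) {
    stop("flat image: zero gradient energy inside the roi")
  }
  grad_angle <- atan2(gy, gx)[inside] * 180 / pi   # gradient direction
  orientation <- wrap180(grad_angle + 90)          # structure direction
  # energy-weighted histogram over [-90, 90)
  breaks <- seq(-90, 90, by = bin_width)
  bin <- findInterval(orientation, breaks, rightmost.closed = FALSE)
  bin[bin > length(breaks) - 1] <- length(breaks) - 1
  weight <- vapply(seq_len(length(breaks) - 1),
                   function(i) sum(energy[bin == i]), 0)
  centers <- breaks[-length(breaks)] + bin_width / 2
  hist_df <- data.frame(angle = centers, weight = weight)
  # recenter on the modal bin so the Gaussian never straddles the wrap
  center <- centers[which.max(weight)]
  theta_raw <- wrap180(orientation - center)
  mu_raw <- sum(theta_raw * energy) / sum(energy)
  sd_raw <- sqrt(sum((theta_raw - mu_raw)^2 * energy) / sum(energy))
  if (sd_raw < bin_width) {
    # near-delta orientation distribution (e.g. a noiseless grating): the
    # histogram is a single spike and a free Gaussian fit is singular, so
    # report the weighted circular statistics directly; the dispersion is
    # floored at the quantization sd of one bin
    return(structure(list(histogram = hist_df,
                          fitted_mean = wrap180(center + mu_raw),
                          dispersion = max(sd_raw, bin_width / sqrt(12)),
                          goodness = 1),
                     class = "orientation_dispersion"))
  }
  theta <- wrap180(centers - center)
  ord <- order(theta)
  df <- data.frame(theta = theta[ord], w = weight[ord])
  w_tot <- sum(df$w)
  mu0 <- sum(df$theta * df$w) / w_tot
  sigma0 <- sqrt(max(sum((df$theta - mu0)^2 * df$w) / w_tot, bin_width^2 / 12))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      w ~ a * exp(-(theta - mu)^2 / (2 * sigma^2)) + b,
      data = df,
      start = list(a = max(df$w) - min(df$w), mu = mu0,
                   sigma = sigma0, b = min(df$w)),
      lower = c(a = 0, mu = -90, sigma = bin_width / 4, b = 0),
      upper = c(a = Inf, mu = 90, sigma = 180, b = Inf),
      control = nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  tss <- sum((df$w - mean(df$w))^2)
  if (!is.null(fit)) {
    cf <- coef(fit)
    rss <- sum(residuals(fit)^2)
  } else {
    # Near-isotropic histograms leave the free Gaussian unidentifiable
    # (amplitude ~ 0, sigma unconstrained). Fall back to moments: mean and
    # sigma from the weighted histogram, amplitude and baseline by linear
    # least squares against the moment-matched Gaussian kernel.
    kernel <- exp(-(df$theta - mu0)^2 / (2 * sigma0^2))
    lin <- stats::lm(df$w ~ kernel)
    cf <- c(a = max(unname(coef(lin)[2]), 0), mu = mu0, sigma = sigma0,
            b = max(unname(coef(lin)[1]), 0))
    rss <- sum(residuals(lin)^2)
  }
  goodness <- if (tss > 0) min(max(1 - rss / tss, 0), 1) else 0
  structure(list(histogram = hist_df,
                 fitted_mean = wrap180(center + unname(cf["mu"])),
                 dispersion = unname(cf["sigma"]),
                 goodness = goodness),
            class = "orientation_dispersion")
}

#' @export
print.orientation_dispersion <- function(x, ...) {
  cat("orientation: mean ", format(x$fitted_mean, digits = 4),
      " deg, dispersion ", format(x$dispersion, digits = 4),
      " deg (fit R^2 ", format(x$goodness, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Mean frame-to-frame speed of a track
#'
#' The primary speed summary: the sum of stepwise Euclidean displacements
#' divided by the elapsed time (`n_steps * frame_interval`), in um/s. For
#' the alternative net-displacement definition see [track_net_speed()].
#'
#' @param track data.frame or matrix of ordered positions with columns
#'   `x`, `y` (um).
#' @param frame_interval time between consecutive points (s); > 0.
#' @return mean speed in um/s.
#' @export
track_mean_speed <- function(track, frame_interval = 1) {
  xy <- as.matrix(track[, c("x", "y")])
  if (nrow(xy) < 2) stop("a track needs at least two points")
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be positive")
  }
  steps <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  sum(steps) / (length(steps) * frame_interval)
}

#' Net-displacement speed of a track
#'
#' Straight-line distance from first to last point divided by the total
#' elapsed time; always <= [track_mean_speed()].
#'
#' @inheritParams track_mean_speed
#' @return net speed in um/s.
#' @export
track_net_speed <- function(track, frame_interval = 1) {
  xy <- as.matrix(track[, c("x", "y")])
  if (nrow(xy) < 2) stop("a track needs at least two points")
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be positive")
  }
  n <- nrow(xy)
  unname(sqrt((xy[n, 1] - xy[1, 1])^2 + (xy[n, 2] - xy[1, 2])^2) /
           ((n - 1) * frame_interval))
}

#' Per-track speed summary of a tracking table
#'
#' Summarizes a particle-tracker export (`track_id`, `frame`, `x`, `y`)
#' into per-track mean and net speeds.
#'
#' @param tracks data.frame with columns `track_id`, `frame`, `x`, `y`,
#'   or a path to such a CSV.
#' @param frame_interval seconds between frames.
#' @return data.frame with `track_id`, `n_points`, `mean_speed`,
#'   `net_speed` (um/s).
#' @export
track_speed_summary <- function(tracks, frame_interval = 1) {
  if (is.character(tracks)) {
    tracks <- utils::read.csv(tracks, stringsAsFactors = FALSE)
  }
  required <- c("track_id", "frame", "x", "y")
  if (!all(required %in% names(tracks))) {
    stop("track table must have columns track_id, frame, x, y")
  }
  ids <- unique(tracks$track_id)
  do.call(rbind, lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    data.frame(track_id = id, n_points = nrow(tr),
               mean_speed = track_mean_speed(tr, frame_interval),
               net_speed = track_net_speed(tr, frame_interval))
  }))
}
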