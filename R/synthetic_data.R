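#' Generate a planted-partition interactome with seeded disease blocks
#'
#' Samples a stochastic-block-model graph (`n_blocks` blocks of
#' `block_size` nodes, within-block edge probability `p_in`, between-block
#' `p_out`), names the nodes, and draws a seed set concentrated in the
#' chosen blocks with weights `|N(mu, sd)|` - mimicking the dynamic range
#' of `-log10` GWAS p-values without claiming distributional realism. The
#' generator requires the giant component to hold at least 90% of the
#' nodes; otherwise it regenerates (up to `max_attempts`, with a warning).
#'
#' All outputs are pure functions of the arguments and `rng_seed`.
#'
#' @param n_blocks,block_size,p_in,p_out block-model parameters;
#'   `0 <= p_out <= p_in <= 1` (equality gives the no-structure null
#'   model).
#' @param seed_blocks block indices that receive seed genes (default
#'   block 1).
#' @param n_seeds number of seed genes drawn uniformly without replacement
#'   from the seed blocks.
#' @param weight_mean,weight_sd parameters of the folded-normal seed
#'   weight law (defaults 3 and 1).
#' @param trait label for the generated seed set.
#' @param rng_seed integer seed; reruns are identical.
#' @param max_attempts regeneration attempts for the giant-component
#'   requirement.
#' @return list with `net` (igraph), `blocks` (named integer vector of
#'   planted labels) and `seeds` (a `seed_set`).
#' @export
make_planted_interactome <- function(n_blocks = 5, block_size = 100,
                                     p_in = 0.2, p_out = 0.01,
                                     seed_blocks = 1, n_seeds = 30,
                                     weight_mean = 3, weight_sd = 1,
                                     trait = "synthetic",
                                     rng_seed = 1, max_attempts = 10) {
  # p_out == p_in is allowed: it gives the no-structure null model
  stopifnot(p_out >= 0, p_out <= p_in, p_in <= 1, block_size > 10)
  n <- n_blocks * block_size
  pref <- matrix(p_out, n_blocks, n_blocks)
  diag(pref) <- p_in
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed)
  for (attempt in seq_len(max_attempts)) {
    g <- igraph::sample_sbm(n, pref.matrix = pref,
                            block.sizes = rep(block_size, n_blocks))
    igraph::V(g)$name <- sprintf("G%05d", seq_len(n))
    comp <- igraph::components(g)
    if (max(comp$csize) >= 0.9 * n) break
    if (attempt == max_attempts) {
      stop("giant component below 90% of nodes after ", max_attempts,
           " attempts; raise p_in/p_out")
    }
    warning("giant component below 90% of nodes; regenerating (attempt ",
            attempt, ")")
  }
  blocks <- setNames(rep(seq_len(n_blocks), each = block_size),
                     igraph::V(g)$name)
  pool <- names(blocks)[blocks %in% seed_blocks]
  seed_genes <- sample(pool, min(n_seeds, length(pool)))
  weights <- setNames(abs(rnorm(length(seed_genes), weight_mean, weight_sd)),
                      seed_genes)
  list(net = g, blocks = blocks, seeds = seed_set(trait, weights))
}

# save/restore the global RNG state so generators are reproducible without
# clobbering the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate paired transcript/protein tables with planted changes
#'
#' Planted genes receive a log2 ratio of `+-effect_log2` plus Gaussian
#' noise; a `concordant_fraction` of them carry the same sign in both
#' layers (the rest are sign-flipped in the protein layer). Null genes are
#' `N(0, noise_sd)` in both layers. Per-gene p-values are two-sided
#' z-tests of the observed ratio against the null noise level, which is
#' how downstream candidate selection expects its significance column.
#'
#' @param genes character vector: the gene universe of the tables.
#' @param planted_genes genes carrying a real effect; subset of `genes`.
#' @param effect_log2 absolute planted log2 fold change (default 2).
#' @param noise_sd Gaussian noise standard deviation (> 0; default 0.3).
#' @param concordant_fraction fraction of planted genes with
#'   sign-concordant transcript and protein changes (default 1).
#' @param rng_seed integer seed.
#' @return list with `transcript` and `protein` data.frames (`gene`,
#'   `layer`, `log2_ratio`, `pvalue`) and `planted` bookkeeping
#'   (data.frame `gene`, `sign`, `concordant`).
#' @export
make_omics_tables <- function(genes, planted_genes, effect_log2 = 2,
                              noise_sd = 0.3, concordant_fraction = 1,
                              rng_seed = 1) {
  stopifnot(noise_sd > 0, all(planted_genes %in% genes),
            concordant_fraction >= 0, concordant_fraction <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed)
  n <- length(genes)
  planted <- genes %in% planted_genes
  sgn <- ifelse(runif(n) < 0.5, -1, 1)
  concord <- runif(n) < concordant_fraction
  base_tx <- rnorm(n, 0, noise_sd)
  base_pr <- rnorm(n, 0, noise_sd)
  tx <- base_tx + ifelse(planted, sgn * effect_log2, 0)
  pr <- base_pr + ifelse(planted, ifelse(concord, sgn, -sgn) * effect_log2, 0)
  pval <- function(r) pmax(2 * pnorm(-abs(r) / noise_sd), .Machine$double.xmin)
  list(
    transcript = data.frame(gene = genes, layer = "transcript",
                            log2_ratio = tx, pvalue = pval(tx),
                            stringsAsFactors = FALSE),
    protein = data.frame(gene = genes, layer = "protein",
                         log2_ratio = pr, pvalue = pval(pr),
                         stringsAsFactors = FALSE),
    planted = data.frame(gene = genes[planted], sign = sgn[planted],
                         concordant = concord[planted],
                         stringsAsFactors = FALSE))
}

#' Generate a rasterized shape mask with analytic ground truth
#'
#' Produces a binary mask of a disk, square, rectangle or star on a square
#' canvas. The analytic area, perimeter and form factor of the underlying
#' continuous shape are attached as the `"truth"` attribute for direct use
#' in tests.
#'
#' @param kind one of `"disk"`, `"square"`, `"rectangle"`, `"star"`.
#' @param size_px canvas side length in pixels (>= 16).
#' @param rng_seed integer seed (used only by the star's spike phases).
#' @return 0/1 matrix with attribute `truth` (list `area`, `perimeter`,
#'   `form_factor`; the star's truth is approximated numerically from its
#'   polygon).
#' @export
make_shape_mask <- function(kind = c("disk", "square", "rectangle", "star"),
                            size_px = 128, rng_seed = 1) {
  kind <- match.arg(kind)
  stopifnot(size_px >= 16)
  cx <- (size_px + 1) / 2
  xg <- matrix(seq_len(size_px), size_px, size_px) - cx          # rows
  yg <- matrix(seq_len(size_px), size_px, size_px, byrow = TRUE) - cx
  if (kind == "disk") {
    r <- 0.4 * size_px
    m <- (xg^2 + yg^2 <= r^2) * 1
    truth <- list(area = pi * r^2, perimeter = 2 * pi * r)
  } else if (kind == "square") {
    h <- 0.3 * size_px
    m <- (abs(xg) <= h & abs(yg) <= h) * 1
    truth <- list(area = (2 * h)^2, perimeter = 8 * h)
  } else if (kind == "rectangle") {
    hx <- 0.45 * size_px; hy <- 0.1 * size_px
    m <- (abs(xg) <= hx & abs(yg) <= hy) * 1
    truth <- list(area = 4 * hx * hy, perimeter = 4 * (hx + hy))
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(rng_seed)
    n_spikes <- 8
    phase <- runif(1, 0, 2 * pi)
    r_out <- 0.45 * size_px; r_in <- 0.2 * size_px
    ang <- atan2(yg, xg)
    # radial star outline: linear interpolation between inner and outer
    # radius across each spike
    frac <- abs(((ang + phase) * n_spikes / (2 * pi)) %% 1 - 0.5) * 2
    rad <- r_in + (r_out - r_in) * frac
    m <- (sqrt(xg^2 + yg^2) <= rad) * 1
    # numeric truth from a dense polygon of the analytic outline
    tt <- seq(0, 2 * pi, length.out = 20001)[-1]
    fr <- abs(((tt + phase) * n_spikes / (2 * pi)) %% 1 - 0.5) * 2
    rr <- r_in + (r_out - r_in) * fr
    px <- rr * cos(tt); py <- rr * sin(tt)
    per <- sum(sqrt(diff(c(px, px[1]))^2 + diff(c(py, py[1]))^2))
    area <- abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
    truth <- list(area = area, perimeter = per)
  }
  truth$form_factor <- 4 * pi * truth$area / truth$perimeter^2
  attr(m, "truth") <- truth
  m
}

#' Generate a sinusoidal orientation texture
#'
#' A grating whose stripes run at `angle_deg` (degrees from the first
#' matrix axis, in `[-90, 90)`), with optional additive Gaussian noise.
#' The ground-truth orientation is attached as the `"truth"` attribute.
#'
#' @param angle_deg stripe orientation in degrees.
#' @param period_px stripe period in pixels (>= 4).
#' @param noise_sd additive Gaussian noise sd (signal amplitude is 1).
#' @param size_px canvas side (default 128).
#' @param rng_seed integer seed for the noise.
#' @return numeric matrix with attribute `truth` (list `angle_deg`).
#' @export
make_orientation_texture <- function(angle_deg, period_px = 8,
                                     noise_sd = 0, size_px = 128,
                                     rng_seed = 1) {
  stopifnot(period_px >= 4)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed)
  # phase varies perpendicular to the stripes
  phi <- (angle_deg + 90) * pi / 180
  xg <- matrix(seq_len(size_px), size_px, size_px)
  yg <- matrix(seq_len(size_px), size_px, size_px, byrow = TRUE)
  img <- sin(2 * pi * (xg * cos(phi) + yg * sin(phi)) / period_px)
  if (noise_sd > 0) {
    img <- img + matrix(rnorm(size_px^2, 0, noise_sd), size_px, size_px)
  }
  attr(img, "truth") <- list(angle_deg = wrap180(angle_deg))
  img
}

#' Generate particle and track tables with known ground truth
#'
#' Particles receive distances uniform on `[0, segment_length)`; tracks
#' are constant-speed straight lines in random directions, so their
#' frame-to-frame mean speed equals `speed` exactly.
#'
#' @param n_particles number of particles.
#' @param segment_length profiled process length (um; default 15).
#' @param speed track speed (um/s).
#' @param n_frames points per track (>= 2).
#' @param n_tracks number of tracks.
#' @param frame_interval seconds between frames.
#' @param rng_seed integer seed.
#' @return list with `particles` (data.frame `particle_id`,
#'   `distance_um`), `tracks` (data.frame `track_id`, `frame`, `x`, `y`)
#'   and `truth` (list `speed`, `frame_interval`).
#' @export
make_particles_and_tracks <- function(n_particles = 150, segment_length = 15,
                                      speed = 0.5, n_frames = 20,
                                      n_tracks = 5, frame_interval = 1,
                                      rng_seed = 1) {
  stopifnot(n_particles > 0, segment_length > 0, speed >= 0, n_frames >= 2,
            n_tracks > 0, frame_interval > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed)
  particles <- data.frame(
    particle_id = seq_len(n_particles),
    distance_um = runif(n_particles, 0, segment_length))
  # guard against the (measure-zero) right endpoint
  particles$distance_um[particles$distance_um >= segment_length] <- 0
  tracks <- do.call(rbind, lapply(seq_len(n_tracks), function(id) {
    theta <- runif(1, 0, 2 * pi)
    x0 <- runif(1, 0, 100); y0 <- runif(1, 0, 100)
    step <- speed * frame_interval
    fr <- seq_len(n_frames) - 1L
    data.frame(track_id = id, frame = fr,
               x = x0 + fr * step * cos(theta),
               y = y0 + fr * step * sin(theta))
  }))
  list(particles = particles, tracks = tracks,
       truth = list(speed = speed, frame_interval = frame_interval))
}
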