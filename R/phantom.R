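#' Parameters for the synthetic fundus phantom generator
#'
#' The phantom emulates the gross appearance of a colour fundus photograph: a
#' circular field of view (FOV) on a dark camera background, a smoothly shaded
#' red-dominant retina, and a branching tree of vessels that are darker than
#' their surroundings (mainly in the green channel, where real vessels show the
#' most contrast).  Vessel geometry is grown by recursive biased random walks,
#' giving varying widths, curvatures and lengths with exact pixel-level ground
#' truth.
#'
#' @param height,width Image size in pixels (at least 32).
#' @param n_trees Number of vessel root stems grown inside the FOV.
#' @param branch_prob Probability per segment of bifurcating.
#' @param width_root Vessel half-width in pixels at the stem.
#' @param width_min Minimal half-width; a branch stops once it tapers below it.
#' @param vessel_contrast Fraction in (0,1) by which vessels attenuate the
#'   local background intensity.
#' @param illum_gradient Peak-to-edge radial shading fraction of the
#'   background.
#' @param noise_sigma Additive Gaussian noise standard deviation on the
#'   0--255 scale.
#' @param fov_radius_frac FOV disc radius as a fraction of `min(height,
#'   width) / 2`.
#' @param seed Integer RNG seed; identical parameters (including the seed)
#'   yield bit-identical samples.
#'
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(height = 256L, width = 256L, n_trees = 3L,
                           branch_prob = 0.4, width_root = 4, width_min = 1,
                           vessel_contrast = 0.55, illum_gradient = 0.25,
                           noise_sigma = 4, fov_radius_frac = 0.92,
                           seed = 7L) {
  p <- list(height = as.integer(height), width = as.integer(width),
            n_trees = as.integer(n_trees), branch_prob = branch_prob,
            width_root = width_root, width_min = width_min,
            vessel_contrast = vessel_contrast,
            illum_gradient = illum_gradient, noise_sigma = noise_sigma,
            fov_radius_frac = fov_radius_frac, seed = as.integer(seed))
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  bad <- function(field, msg) {
    stop(sprintf("invalid phantom parameter `%s`: %s", field, msg),
         call. = FALSE)
  }
  if (p$height < 32L) bad("height", "must be >= 32")
  if (p$width < 32L) bad("width", "must be >= 32")
  if (p$n_trees < 0L) bad("n_trees", "must be >= 0")
  if (p$branch_prob < 0 || p$branch_prob > 1)
    bad("branch_prob", "must lie in [0, 1]")
  if (p$width_min < 1) bad("width_min", "must be >= 1")
  if (p$width_root < p$width_min) bad("width_root", "must be >= width_min")
  if (p$vessel_contrast <= 0 || p$vessel_contrast >= 1)
    bad("vessel_contrast", "must lie in (0, 1)")
  if (p$noise_sigma < 0) bad("noise_sigma", "must be >= 0")
  if (p$fov_radius_frac <= 0 || p$fov_radius_frac > 1)
    bad("fov_radius_frac", "must lie in (0, 1]")
  invisible(p)
}

# Stamp an anti-aliased disc of half-width w at (r, c) into canvas V (max
# accumulation); returns the updated canvas.
stamp_disc <- function(V, r, c, w) {
  H <- nrow(V); W <- ncol(V)
  rad <- ceiling(w + 0.5)
  r0 <- max(1L, floor(r - rad)); r1 <- min(H, ceiling(r + rad))
  c0 <- max(1L, floor(c - rad)); c1 <- min(W, ceiling(c + rad))
  if (r0 > r1 || c0 > c1) return(V)
  rr <- r0:r1; cc <- c0:c1
  dist <- sqrt(outer((rr - r)^2, (cc - c)^2, "+"))
  val <- pmin(pmax(w + 0.5 - dist, 0), 1)
  V[rr, cc] <- pmax(V[rr, cc], val)
  V
}

# Recursive biased random walk; appends step records to `env$steps`.
grow_branch <- function(env, pos, ang, w, p, depth = 0L) {
  if (w < p$width_min || depth > 8L) return(invisible(NULL))
  seg_steps <- 10L
  step_len <- 1.5
  repeat {
    for (i in seq_len(seg_steps)) {
      ang <- ang + stats::rnorm(1L, 0, 0.12)
      pos <- pos + step_len * c(cos(ang), sin(ang))
      d <- sqrt(sum((pos - env$center)^2))
      if (d > env$R - w - 1.5) return(invisible(NULL))
      env$n <- env$n + 1L
      env$steps[[env$n]] <- c(pos, w)
      w <- w * 0.995
      if (w < p$width_min) return(invisible(NULL))
    }
    if (stats::runif(1L) < p$branch_prob) {
      dth <- stats::runif(1L, 0.35, 0.8)
      wch <- w * 0.75
      grow_branch(env, pos, ang + dth, wch, p, depth + 1L)
      grow_branch(env, pos, ang - dth, wch, p, depth + 1L)
      return(invisible(NULL))
    }
  }
}

#' Generate one synthetic fundus sample
#'
#' Grows `n_trees` vessel trees by recursive random walks inside the FOV disc,
#' renders them as anti-aliased discs stamped along each walk (the binary
#' vessel mask is the rendering thresholded at 0.5), and composes a
#' red-dominant background with a radial illumination gradient and additive
#' Gaussian noise.  Deterministic in `params$seed`.
#'
#' @param params A [phantom_params()] object.
#' @return A `fundus_sample`: list with `image` (H x W x 3 array in
#'   \[0, 255\]), `vessel_mask` and `fov_mask` (H x W binary matrices, with
#'   every vessel pixel inside the FOV).
#' @export
#' @examples
#' s <- generate_phantom(phantom_params(height = 64, width = 64, seed = 1))
#' mean(s$vessel_mask[s$fov_mask == 1])
generate_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  validate_phantom_params(params)
  p <- params
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(p$seed)

  H <- p$height; W <- p$width
  center <- c((H + 1) / 2, (W + 1) / 2)
  R <- p$fov_radius_frac * min(H, W) / 2
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  d2 <- (rr - center[1])^2 + (cc - center[2])^2
  fov <- (d2 <= R^2) * 1

  env <- new.env(parent = emptyenv())
  env$steps <- vector("list", 4096L)
  env$n <- 0L
  env$center <- center
  env$R <- R
  if (p$n_trees > 0L) {
    for (k in seq_len(p$n_trees)) {
      th <- stats::runif(1L, 0, 2 * pi)
      r0 <- stats::runif(1L, 0.15, 0.35) * R
      pos <- center + r0 * c(cos(th), sin(th))
      ang <- th + stats::rnorm(1L, 0, 0.3)   # heading outward
      grow_branch(env, pos, ang, p$width_root, p)
    }
  }

  V <- matrix(0, H, W)
  if (env$n > 0L) {
    for (i in seq_len(env$n)) {
      s <- env$steps[[i]]
      V <- stamp_disc(V, s[1], s[2], s[3])
    }
  }
  vessel <- (V >= 0.5) * 1
  vessel <- vessel * fov

  illum <- 1 - p$illum_gradient * pmin(d2 / R^2, 1)
  base <- c(red = 185, green = 115, blue = 65)
  atten <- c(red = 0.35, green = 1, blue = 0.2) * p$vessel_contrast
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    plane <- base[ch] * illum * (1 - atten[ch] * V)
    plane[fov == 0] <- 5
    plane <- plane + stats::rnorm(H * W, 0, p$noise_sigma)
    img[, , ch] <- pmin(pmax(plane, 0), 255)
  }

  structure(list(image = img, vessel_mask = vessel, fov_mask = fov,
                 params = p),
            class = "fundus_sample")
}

#' Generate a deterministic list of phantom samples
#'
#' Per-sample seeds are derived from the master seed, so the same call yields
#' an identical list and (for `n >= 2`) pairwise-distinct vessel trees.
#'
#' @param n Number of samples (>= 1).
#' @param params Template [phantom_params()]; its `seed` field is replaced by
#'   the derived per-sample seeds.
#' @param seed Master seed.
#' @return List of `fundus_sample` objects.
#' @export
generate_dataset <- function(n, params = phantom_params(), seed = 1L) {
  if (n < 1L) stop("invalid parameter `n`: must be >= 1", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seeds, function(s) {
    pp <- params
    pp$seed <- s
    generate_phantom(pp)
  })
}

#' @export
print.fundus_sample <- function(x, ...) {
  cat(sprintf("<fundus_sample> %d x %d, vessel fraction of FOV: %.3f\n",
              nrow(x$vessel_mask), ncol(x$vessel_mask),
              sum(x$vessel_mask) / max(1, sum(x$fov_mask))))
  invisible(x)
}

#' Write a sample to disk as PNG triple plus a JSON manifest
#'
#' @param sample A `fundus_sample`.
#' @param dir Output directory (created if missing).
#' @param stem File-name stem.
#' @return Invisibly, the manifest path.
#' @export
write_fundus_sample <- function(sample, dir, stem = "sample") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(image = file.path(dir, paste0(stem, "_image.png")),
                vessel = file.path(dir, paste0(stem, "_vessel.png")),
                fov = file.path(dir, paste0(stem, "_fov.png")))
  png::writePNG(sample$image / 255, paths$image)
  png::writePNG(sample$vessel_mask, paths$vessel)
  png::writePNG(sample$fov_mask, paths$fov)
  manifest <- file.path(dir, paste0(stem, "_manifest.json"))
  jsonlite::write_json(list(files = paths,
                            params = unclass(sample$params)),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a sample previously written by [write_fundus_sample()]
#'
#' @param manifest Path to the JSON manifest.
#' @return A `fundus_sample`.
#' @export
read_fundus_sample <- function(manifest) {
  m <- jsonlite::read_json(manifest)
  base <- dirname(manifest)
  rel <- function(f) if (file.exists(f)) f else file.path(base, basename(f))
  img <- png::readPNG(rel(m$files$image)) * 255
  vessel <- round(png::readPNG(rel(m$files$vessel)))
  fov <- round(png::readPNG(rel(m$files$fov)))
  if (length(dim(vessel)) == 3L) vessel <- vessel[, , 1]
  if (length(dim(fov)) == 3L) fov <- fov[, , 1]
  structure(list(image = img, vessel_mask = vessel, fov_mask = fov,
                 params = m$params),
            class = "fundus_sample")
}
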