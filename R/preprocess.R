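#' Preprocessing configuration
#'
#' Defaults follow common fundus practice: the green channel carries the most
#' vessel contrast, CLAHE with a relative clip limit of 2 over an 8 x 8 tile
#' grid, and a mild gamma of 1.2.
#'
#' @param channel_mode `"green"` or `"luminance"` (Rec.601 weights).
#' @param clahe_clip Clip limit as a multiple of the uniform histogram bin
#'   height (> 0).
#' @param clahe_tiles Tile-grid count per axis (>= 1).
#' @param gamma Gamma exponent (> 0).
#' @param fov_threshold Intensity threshold in \[0, 255\] used when a FOV mask
#'   must be synthesised from the image.
#' @return A `preprocess_config` object.
#' @export
preprocess_config <- function(channel_mode = c("green", "luminance"),
                              clahe_clip = 2.0, clahe_tiles = 8L,
                              gamma = 1.2, fov_threshold = 30) {
  channel_mode <- match.arg(channel_mode)
  if (clahe_clip <= 0) stop("invalid `clahe_clip`: must be > 0", call. = FALSE)
  if (clahe_tiles < 1L) stop("invalid `clahe_tiles`: must be >= 1", call. = FALSE)
  if (gamma <= 0) stop("invalid `gamma`: must be > 0", call. = FALSE)
  structure(list(channel_mode = channel_mode, clahe_clip = clahe_clip,
                 clahe_tiles = as.integer(clahe_tiles), gamma = gamma,
                 fov_threshold = fov_threshold),
            class = "preprocess_config")
}

#' Convert a 3-channel image to a single intensity plane
#'
#' @param image H x W x 3 array in \[0, 255\].
#' @param mode `"green"` (channel selection) or `"luminance"`
#'   (0.299 R + 0.587 G + 0.114 B).
#' @return H x W matrix.
#' @export
to_intensity <- function(image, mode = c("green", "luminance")) {
  mode <- match.arg(mode)
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("`image` must be an H x W x 3 array", call. = FALSE)
  if (mode == "green") image[, , 2]
  else 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Standardise an intensity image and rescale onto \[0, 255\]
#'
#' Z-scores (mean 0, unit variance; statistics over FOV pixels when a mask is
#' given, else over all pixels) followed by an affine min--max map of the
#' z-scores onto \[0, 255\].  With a FOV mask the min--max range is taken over
#' the FOV and outside values are clipped into \[0, 255\].
#'
#' @param intensity H x W matrix.
#' @param fov_mask Optional binary matrix restricting the statistics.
#' @return H x W matrix spanning \[0, 255\] (over the FOV when masked).
#' @export
normalize_intensity <- function(intensity, fov_mask = NULL) {
  sel <- if (is.null(fov_mask)) rep(TRUE, length(intensity)) else fov_mask > 0
  v <- intensity[sel]
  mu <- mean(v)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("degenerate input: constant intensity image (zero variance)",
         call. = FALSE)
  z <- (intensity - mu) / s
  lo <- min(z[sel]); hi <- max(z[sel])
  out <- 255 * (z - lo) / (hi - lo)
  pmin(pmax(out, 0), 255)
}

#' Contrast-limited adaptive histogram equalisation
#'
#' Classic tile-based CLAHE: a 256-bin histogram per tile, clipped at
#' `clahe_clip` times the uniform bin height with the excess redistributed,
#' cumulative mappings per tile, and bilinear interpolation between the four
#' surrounding tile mappings at every pixel.  With a 1 x 1 tile grid this
#' reduces to global clipped histogram equalisation.
#'
#' @param intensity H x W matrix in \[0, 255\].
#' @param config A [preprocess_config()] (fields `clahe_clip`, `clahe_tiles`).
#' @return H x W matrix in \[0, 255\].
#' @export
apply_clahe <- function(intensity, config = preprocess_config()) {
  H <- nrow(intensity); W <- ncol(intensity)
  nt <- config$clahe_tiles
  if (H < nt || W < nt)
    stop("invalid parameter: image smaller than the CLAHE tile grid",
         call. = FALSE)
  nbins <- 256L
  bin <- pmin(pmax(floor(intensity), 0), 255) + 1L

  tile_r <- pmin(ceiling(seq_len(H) * nt / H), nt)
  tile_c <- pmin(ceiling(seq_len(W) * nt / W), nt)
  tid <- matrix(tile_r, H, W) + nt * (matrix(tile_c, H, W, byrow = TRUE) - 1L)
  ntiles <- nt * nt

  counts <- tabulate(tid + ntiles * (bin - 1L), nbins = ntiles * nbins)
  hist <- matrix(counts, ntiles, nbins)
  npix <- rowSums(hist)
  climit <- pmax(1, config$clahe_clip * npix / nbins)
  for (it in 1:5) {
    excess <- rowSums(pmax(hist - climit, 0))
    if (all(excess == 0)) break
    hist <- pmin(hist, climit) + excess / nbins
  }
  cdf <- t(apply(hist, 1L, cumsum))
  lut <- 255 * cdf / npix                       # ntiles x 256

  centers <- function(n, ntile) {
    bounds <- round(seq(0, n, length.out = ntile + 1))
    (bounds[-1] + bounds[-(ntile + 1)] + 1) / 2
  }
  cr <- centers(H, nt); cc <- centers(W, nt)
  interp1 <- function(pos, cen) {
    t0 <- findInterval(pos, cen)
    t0 <- pmin(pmax(t0, 1L), length(cen))
    t1 <- pmin(t0 + 1L, length(cen))
    w <- ifelse(t1 > t0, (pos - cen[t0]) / (cen[t1] - cen[t0]), 0)
    w <- pmin(pmax(w, 0), 1)
    list(t0 = t0, t1 = t1, w = w)
  }
  ir <- interp1(seq_len(H), cr)
  ic <- interp1(seq_len(W), cc)

  gather <- function(tr, tc) {
    tix <- matrix(tr, H, W) + nt * (matrix(tc, H, W, byrow = TRUE) - 1L)
    matrix(lut[cbind(as.vector(tix), as.vector(bin))], H, W)
  }
  wr <- matrix(ir$w, H, W)
  wc <- matrix(ic$w, H, W, byrow = TRUE)
  out <- (1 - wr) * (1 - wc) * gather(ir$t0, ic$t0) +
         (1 - wr) * wc       * gather(ir$t0, ic$t1) +
         wr       * (1 - wc) * gather(ir$t1, ic$t0) +
         wr       * wc       * gather(ir$t1, ic$t1)
  pmin(pmax(out, 0), 255)
}

#' Gamma correction
#'
#' `out = 255 * (in / 255)^gamma`, elementwise.
#'
#' @param intensity H x W matrix in \[0, 255\].
#' @param gamma Exponent (> 0).
#' @return H x W matrix.
#' @export
gamma_correct <- function(intensity, gamma) {
  if (gamma <= 0) stop("invalid parameter `gamma`: must be > 0", call. = FALSE)
  255 * (pmin(pmax(intensity, 0), 255) / 255)^gamma
}

#' Synthesise a field-of-view mask from an intensity image
#'
#' Thresholds the intensity, keeps the largest connected component, applies a
#' morphological closing and fills holes.  Used for datasets that ship no FOV
#' masks.
#'
#' @param intensity H x W matrix in \[0, 255\].
#' @param config A [preprocess_config()] (field `fov_threshold`).
#' @return H x W binary matrix.
#' @export
make_fov_mask <- function(intensity, config = preprocess_config()) {
  m <- intensity > config$fov_threshold
  if (!any(m))
    stop("degenerate input: no pixels above the FOV threshold", call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  tab <- tabulate(as.integer(lab[lab > 0]))
  keep <- which.max(tab)
  mask <- EBImage::Image((lab == keep) * 1)
  mask <- EBImage::closing(mask, EBImage::makeBrush(5, "disc"))
  mask <- EBImage::fillHull(mask)
  out <- (as.matrix(EBImage::imageData(mask)) > 0) * 1
  dim(out) <- dim(m)
  out
}

# -- spatial transforms shared by image and masks ------------------------------

rot90_ccw <- function(m) {
  m2 <- t(m)
  m2[rev(seq_len(nrow(m2))), , drop = FALSE]
}

shift_mat <- function(m, dr, dc) {
  out <- matrix(0, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) - dr
  cs <- seq_len(ncol(m)) - dc
  okr <- rs >= 1 & rs <= nrow(m)
  okc <- cs >= 1 & cs <= ncol(m)
  out[okr, okc] <- m[rs[okr], cs[okc]]
  out
}

zoom_mat <- function(m, factor) {
  H <- nrow(m); W <- ncol(m)
  h <- max(2L, round(factor * H)); w <- max(2L, round(factor * W))
  r0 <- floor((H - h) / 2); c0 <- floor((W - w) / 2)
  crop <- m[r0 + seq_len(h), c0 + seq_len(w), drop = FALSE]
  arr <- array(crop, c(h, w, 1, 1))
  out <- resize_bilinear_arr(arr, H, W)
  matrix(out, H, W)
}

#' Apply one of the five augmentation operations
#'
#' The identical spatial transform is applied to the image and both masks;
#' masks are re-binarised after interpolation, and vessel-inside-FOV
#' containment is re-imposed afterwards.  `rot90` rotates counter-clockwise;
#' `zoom` crops the central `zoom_factor` region and rescales back; `shift`
#' translates with zero fill.
#'
#' @param image H x W matrix or H x W x 3 array.
#' @param vessel_mask,fov_mask H x W binary matrices.
#' @param op One of `"hflip"`, `"vflip"`, `"rot90"`, `"zoom"`, `"shift"`.
#' @param zoom_factor Central-crop fraction for `"zoom"`.
#' @param shift_by Integer `(rows, cols)` offset for `"shift"`.
#' @return List with transformed `image`, `vessel_mask`, `fov_mask`.
#' @export
augment <- function(image, vessel_mask, fov_mask,
                    op = c("hflip", "vflip", "rot90", "zoom", "shift"),
                    zoom_factor = 0.8, shift_by = c(10L, 10L)) {
  if (!is.character(op) || !op[1] %in% c("hflip", "vflip", "rot90", "zoom",
                                         "shift"))
    stop(sprintf("invalid parameter `op`: unknown augmentation '%s'",
                 as.character(op[1])), call. = FALSE)
  op <- op[1]
  f <- switch(op,
    hflip = function(m) m[, rev(seq_len(ncol(m))), drop = FALSE],
    vflip = function(m) m[rev(seq_len(nrow(m))), , drop = FALSE],
    rot90 = rot90_ccw,
    zoom  = function(m) zoom_mat(m, zoom_factor),
    shift = function(m) shift_mat(m, shift_by[1], shift_by[2]))
  tx_img <- function(img) {
    if (length(dim(img)) == 3L) {
      planes <- lapply(seq_len(dim(img)[3]), function(ch) f(img[, , ch]))
      out <- array(0, c(dim(planes[[1]]), length(planes)))
      for (ch in seq_along(planes)) out[, , ch] <- planes[[ch]]
      out
    } else f(img)
  }
  vm <- (f(vessel_mask) >= 0.5) * 1
  fm <- (f(fov_mask) >= 0.5) * 1
  list(image = tx_img(image), vessel_mask = vm * fm, fov_mask = fm)
}

#' Extract overlapping patches on a regular grid
#'
#' Origins lie at all multiples of `stride` whose `patch_size` window fits in
#' the image; when the regular grid does not reach the border, the final
#' origin on that axis is clamped to `H - S` (resp. `W - S`) so the windows
#' cover the image completely.
#'
#' @param image H x W matrix.
#' @param patch_size Window side S (<= min(H, W)).
#' @param stride Grid step in pixels (>= 1).
#' @return A `patch_grid`: list of `patches`, integer `origins` matrix
#'   (0-based, top-left, one row per patch), `image_shape`, `patch_size`,
#'   `stride`.
#' @export
extract_patches <- function(image, patch_size, stride) {
  H <- nrow(image); W <- ncol(image)
  S <- as.integer(patch_size); t <- as.integer(stride)
  if (S > H || S > W)
    stop("invalid parameter `patch_size`: exceeds image size", call. = FALSE)
  if (t < 1L) stop("invalid parameter `stride`: must be >= 1", call. = FALSE)
  axis_origins <- function(n) {
    o <- seq(0L, n - S, by = t)
    if (o[length(o)] != n - S) o <- c(o, n - S)
    o
  }
  ro <- axis_origins(H); co <- axis_origins(W)
  origins <- cbind(rep(ro, times = length(co)), rep(co, each = length(ro)))
  patches <- lapply(seq_len(nrow(origins)), function(i) {
    r <- origins[i, 1]; c <- origins[i, 2]
    image[r + seq_len(S), c + seq_len(S), drop = FALSE] + 0
  })
  structure(list(patches = patches, origins = origins,
                 image_shape = c(H, W), patch_size = S, stride = t),
            class = "patch_grid")
}

#' Stitch a patch grid back into a full image by overlap averaging
#'
#' Each output pixel is the arithmetic mean of all patch values covering it.
#'
#' @param grid A `patch_grid` whose patches hold per-pixel values
#'   (e.g. probabilities).
#' @return H x W matrix.
#' @export
stitch_patches <- function(grid) {
  stopifnot(inherits(grid, "patch_grid"))
  H <- grid$image_shape[1]; W <- grid$image_shape[2]
  S <- grid$patch_size
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (i in seq_along(grid$patches)) {
    r <- grid$origins[i, 1]; c <- grid$origins[i, 2]
    rs <- r + seq_len(S); cs <- c + seq_len(S)
    acc[rs, cs] <- acc[rs, cs] + grid$patches[[i]]
    cnt[rs, cs] <- cnt[rs, cs] + 1
  }
  if (any(cnt == 0))
    stop("internal error: patch grid does not cover the image", call. = FALSE)
  acc / cnt
}

# Full preprocessing chain applied to one sample: intensity extraction,
# FOV-aware standardisation, CLAHE, gamma, then rescale to [0, 1] for the
# network.
preprocess_sample <- function(sample, config = preprocess_config()) {
  x <- to_intensity(sample$image, config$channel_mode)
  fov <- sample$fov_mask
  if (is.null(fov)) fov <- make_fov_mask(x, config)
  x <- normalize_intensity(x, fov)
  x <- apply_clahe(x, config)
  x <- gamma_correct(x, config$gamma)
  list(x = x / 255, vessel = sample$vessel_mask, fov = fov)
}
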