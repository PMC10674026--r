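test_that("intensity extraction selects the green channel or Rec.601 luminance", {
  img <- array(0, c(2, 2, 3))
  img[1, 1, ] <- c(10, 200, 30)
  expect_equal(to_intensity(img, "green")[1, 1], 200)
  gray <- array(77, c(3, 3, 3))
  expect_equal(to_intensity(gray, "green"), matrix(77, 3, 3))
  expect_equal(to_intensity(gray, "luminance"), matrix(77, 3, 3))
  img[1, 2, ] <- c(100, 100, 100)
  img[2, 1, ] <- c(0, 255, 0)
  lum <- to_intensity(img, "luminance")
  expect_equal(lum[1, 2], 100)
  expect_equal(lum[2, 1], 0.587 * 255)       # 149.685
  expect_error(to_intensity(matrix(1, 2, 2)), "3")
})

test_that("normalisation standardises then spans exactly [0, 255]", {
  x <- matrix(c(0, 10, 0, 10), 2, 2)
  expect_equal(normalize_intensity(x), matrix(c(0, 255, 0, 255), 2, 2))
  set.seed(1)
  r <- normalize_intensity(matrix(runif(64, 3, 9), 8, 8))
  expect_equal(min(r), 0)
  expect_equal(max(r), 255)
  expect_error(normalize_intensity(matrix(5, 4, 4)), "constant|variance")
  # FOV-restricted statistics ignore the outside
  m <- matrix(runif(64, 0, 255), 8, 8)
  fov <- matrix(0, 8, 8); fov[3:6, 3:6] <- 1
  rf <- normalize_intensity(m, fov)
  expect_equal(min(rf[fov == 1]), 0)
  expect_equal(max(rf[fov == 1]), 255)
})

test_that("CLAHE with one tile matches a global clipped-equalisation oracle", {
  # independent oracle: clip the global histogram, redistribute, map by cdf
  global_clipped_he <- function(x, clip) {
    bin <- pmin(pmax(floor(x), 0), 255) + 1
    h <- tabulate(bin, 256)
    lim <- max(1, clip * length(x) / 256)
    for (i in 1:5) {
      ex <- sum(pmax(h - lim, 0))
      if (ex == 0) break
      h <- pmin(h, lim) + ex / 256
    }
    cdf <- cumsum(h)
    lut <- 255 * cdf / length(x)
    matrix(lut[bin], nrow(x), ncol(x))
  }
  set.seed(4)
  x <- matrix(sample(0:255, 32 * 32, TRUE, prob = (256:1)^2), 32, 32)
  cfg <- preprocess_config(clahe_clip = 3, clahe_tiles = 1)
  expect_equal(apply_clahe(x, cfg), global_clipped_he(x, 3), tolerance = 1e-12)
})

test_that("CLAHE keeps constants constant, stays in range, raises contrast", {
  cfg <- preprocess_config(clahe_clip = 4, clahe_tiles = 1)
  const <- matrix(128, 16, 16)
  out <- apply_clahe(const, cfg)
  expect_equal(max(out) - min(out), 0)
  # two-level checkerboard stays two-level with a wide separation; a tight
  # clip keeps the map near identity so the contrast is essentially preserved
  cb <- matrix(50, 16, 16); cb[(row(cb) + col(cb)) %% 2 == 0] <- 200
  res <- apply_clahe(cb, cfg)
  expect_equal(length(unique(as.vector(res))), 2)
  expect_gte(diff(range(res)), 140)
  expect_true(all(res >= 0 & res <= 255))
  set.seed(2)
  r <- apply_clahe(matrix(runif(64 * 64, 0, 255), 64, 64),
                   preprocess_config())
  expect_true(all(r >= 0 & r <= 255))
  expect_error(apply_clahe(matrix(1, 4, 4), preprocess_config(clahe_tiles = 8)),
               "tile")
})

test_that("gamma correction follows the power law", {
  x <- matrix(c(0, 63.75, 128, 255), 2, 2)   # column-major fill
  expect_equal(gamma_correct(x, 1), x)
  expect_equal(gamma_correct(x, 0.5)[2, 1], 127.5)   # 0.25^0.5 = 0.5
  expect_equal(gamma_correct(x, 2.2)[1, 2], 255 * (128 / 255)^2.2)
  expect_equal(255 * (128 / 255)^2.2, 55.9775, tolerance = 1e-4)
  expect_error(gamma_correct(x, 0), "gamma")
})

test_that("FOV synthesis recovers the phantom disc almost exactly", {
  s <- small_phantom(seed = 6, hw = 96)
  g <- to_intensity(s$image, "green")
  m <- make_fov_mask(g, preprocess_config(fov_threshold = 40))
  inter <- sum(m * s$fov_mask)
  union <- sum((m + s$fov_mask) > 0)
  expect_gt(inter / union, 0.99)
  bright <- matrix(200, 16, 16)
  expect_equal(make_fov_mask(bright), matrix(1, 16, 16))
  expect_error(make_fov_mask(matrix(0, 16, 16)), "degenerate|threshold")
})

test_that("augmentations transform image and masks together", {
  s <- small_phantom(seed = 3, hw = 48)
  g <- to_intensity(s$image, "green")
  # involution
  h1 <- augment(g, s$vessel_mask, s$fov_mask, "hflip")
  h2 <- augment(h1$image, h1$vessel_mask, h1$fov_mask, "hflip")
  expect_equal(h2$image, g)
  expect_equal(h2$vessel_mask, s$vessel_mask)
  # rot90 on a 2x2: [[a,b],[c,d]] -> [[b,d],[a,c]] (counter-clockwise)
  m <- matrix(c("a", "c", "b", "d"), 2, 2)
  num <- matrix(1:4, 2, 2)     # a=1 c=2 b=3 d=4
  r <- augment(num, matrix(1, 2, 2), matrix(1, 2, 2), "rot90")
  expect_equal(r$image, matrix(c(3, 1, 4, 2), 2, 2))   # [[b,d],[a,c]]
  # containment survives every op
  for (op in c("hflip", "vflip", "rot90", "zoom", "shift")) {
    a <- augment(g, s$vessel_mask, s$fov_mask, op)
    expect_true(all(a$vessel_mask <= a$fov_mask), info = op)
    expect_true(all(a$vessel_mask %in% c(0, 1)), info = op)
  }
  expect_error(augment(g, s$vessel_mask, s$fov_mask, "sharpen"), "sharpen")
})

test_that("patch extraction enumerates the clamped grid", {
  # independent enumeration oracle for the origin set of one axis
  axis_oracle <- function(n, S, t) {
    o <- integer(0); pos <- 0
    while (pos + S <= n) { o <- c(o, pos); pos <- pos + t }
    if (o[length(o)] != n - S) o <- c(o, n - S)
    o
  }
  img <- matrix(seq_len(36), 6, 6)
  g <- extract_patches(img, 4, 2)
  expect_equal(length(g$patches), 4)
  expect_equal(sort(unique(g$origins[, 1])), c(0, 2))
  expect_equal(sort(unique(g$origins[, 2])), c(0, 2))

  one <- extract_patches(img, 6, 3)
  expect_equal(length(one$patches), 1)
  expect_equal(one$origins[1, ], c(0, 0))

  big <- matrix(0, 584, 565)
  gb <- extract_patches(big, 256, 20)
  ro <- axis_oracle(584, 256, 20); co <- axis_oracle(565, 256, 20)
  expect_equal(length(gb$patches), length(ro) * length(co))
  expect_equal(sort(unique(gb$origins[, 1])), ro)   # 0..320 by 20, then 328
  expect_equal(sort(unique(gb$origins[, 2])), co)   # 0..300 by 20, then 309
  expect_error(extract_patches(img, 10, 2), "patch_size")
})

test_that("extract then stitch is the identity and overlaps average", {
  set.seed(9)
  for (case in list(c(70, 70, 64, 16), c(64, 80, 64, 64), c(40, 52, 32, 8))) {
    img <- matrix(rnorm(case[1] * case[2]), case[1], case[2])
    g <- extract_patches(img, case[3], case[4])
    expect_equal(stitch_patches(g), img, tolerance = 1e-12)
  }
  # two overlapping constant patches: overlap column mean is 0.5
  g <- extract_patches(matrix(0, 4, 6), 4, 2)
  g$patches <- lapply(seq_along(g$patches), function(i)
    matrix(as.numeric(i == 1), 4, 4))
  # patch origins at cols 0 and 2: overlap columns 3..4
  st <- stitch_patches(g)
  expect_equal(st[, 1:2], matrix(1, 4, 2))
  expect_equal(st[, 3:4], matrix(0.5, 4, 2))
  expect_equal(st[, 5:6], matrix(0, 4, 2))
  # brute-force accumulator oracle on a random grid
  img <- matrix(rnorm(48 * 48), 48, 48)
  g <- extract_patches(img, 32, 8)
  acc <- matrix(0, 48, 48); cnt <- matrix(0, 48, 48)
  for (i in seq_along(g$patches)) {
    rs <- g$origins[i, 1] + 1:32; cs <- g$origins[i, 2] + 1:32
    acc[rs, cs] <- acc[rs, cs] + g$patches[[i]]
    cnt[rs, cs] <- cnt[rs, cs] + 1
  }
  expect_equal(stitch_patches(g), acc / cnt, tolerance = 1e-12)
})
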