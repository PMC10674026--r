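ns <- asNamespace("retseg")

test_that("dense blocks follow the growth arithmetic", {
  # F=48, j=12, D=4: block emits F+48 maps; layer d sees F+(d-1)*j channels
  cfg <- network_config(base_channels = 48, growth = 12, dense_layers = 4,
                        levels = 2, seed = 1)
  m <- build_model(cfg)
  for (d in 1:4) {
    w <- m$params[[paste0("enc1.dense.l", d, ".conv.w")]]
    expect_equal(dim(w)[3], 48 + (d - 1) * 12)   # input channels of layer d
    expect_equal(dim(w)[4], 12)                  # each layer adds j maps
  }
  expect_equal(m$channels$enc_out[1], 48 + 48)   # F + 48 finishing output

  # arbitrary C: output C + D*j, spatial shape preserved
  cfg2 <- micro_network()
  m2 <- build_model(cfg2)
  x <- array(runif(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  tp <- ns$tape_new(m2$params, m2$buffers, training = FALSE)
  id <- ns$dense_fwd(tp, ns$tp_input(tp, x), "enc1.dense", 2, 0)
  expect_equal(dim(ns$tp_val(tp, id)), c(8, 8, 4 + 2 * 2, 2))
})

test_that("channel arithmetic holds for every dense block of a built model", {
  cfg <- tiny_network()
  m <- build_model(cfg)
  D <- cfg$dense_layers; j <- cfg$growth
  for (prefix in c(paste0("enc", 1:3, ".dense"), paste0("dec", 1:2, ".dense"))) {
    cin <- dim(m$params[[paste0(prefix, ".l1.conv.w")]])[3]
    for (d in seq_len(D)) {
      w <- m$params[[paste0(prefix, ".l", d, ".conv.w")]]
      expect_equal(dim(w)[3], cin + (d - 1) * j)
      expect_equal(dim(w)[4], j)
    }
  }
})

test_that("atrous channel attention matches a hand 1-D convolution oracle", {
  # C=4, GAP vector [1,2,3,4], both kernels [0.5,0.5,0.5], dilation 2.
  # plain (zero pad):   [1.5, 3.0, 4.5, 3.5]
  # dilated taps c-2,c,c+2: [2.0, 3.0, 2.0, 3.0]
  # summed pre-activation:  [3.5, 6.0, 6.5, 6.5]
  x <- array(0, c(2, 2, 4, 1))
  for (c in 1:4) x[, , c, 1] <- c            # GAP = (1,2,3,4)
  p <- list(w1 = rep(0.5, 3), b1 = 0, w2 = rep(0.5, 3), b2 = 0)
  tp <- ns$tape_new(p, training = FALSE)
  id <- ns$tp_chatt(tp, ns$tp_input(tp, x), "w1", "b1", "w2", "b2", 2L)
  y <- ns$tp_val(tp, id)
  want_w <- 1 / (1 + exp(-c(3.5, 6.0, 6.5, 6.5)))
  for (c in 1:4)
    expect_equal(y[, , c, 1], x[, , c, 1] * want_w[c], tolerance = 1e-12)

  # symmetry: identical channels get identical weights
  xs <- array(2, c(3, 3, 7, 1))
  ps <- list(w1 = rnorm(3), b1 = 0.2, w2 = rnorm(3), b2 = -0.1)
  tp <- ns$tape_new(ps, training = FALSE)
  id <- ns$tp_chatt(tp, ns$tp_input(tp, xs), "w1", "b1", "w2", "b2", 2L)
  y <- ns$tp_val(tp, id)
  inner <- y[, , 3:5, 1]                      # edge channels see the padding
  expect_equal(max(inner) - min(inner), 0)

  # logistic bound: |output| <= |input| elementwise for nonnegative input
  xn <- array(runif(3 * 3 * 4 * 2), c(3, 3, 4, 2))
  tp <- ns$tape_new(ps, training = FALSE)
  id <- ns$tp_chatt(tp, ns$tp_input(tp, xn), "w1", "b1", "w2", "b2", 2L)
  expect_true(all(ns$tp_val(tp, id) <= xn))
})

test_that("UDKE with neutral subnets is the identity; forced gain/residual obey the update", {
  cfg <- micro_network()
  m <- build_model(cfg)
  C <- m$channels$dec_out[1]
  x <- array(runif(8 * 8 * C * 1), c(8, 8, C, 1))
  neutral <- m$params
  for (t in 1:cfg$udke_iters) {
    for (nm in grep(sprintf("dec1.udke.t%d", t), names(neutral), value = TRUE))
      neutral[[nm]] <- neutral[[nm]] * 0
    neutral[[paste0("dec1.udke.t", t, ".G.c2.b")]] <-
      rep(1, C)                              # G == 1
  }
  tp <- ns$tape_new(neutral, training = FALSE)
  id <- ns$udke_fwd(tp, ns$tp_input(tp, x), "dec1.udke", cfg$udke_iters)
  expect_equal(ns$tp_val(tp, id), x, tolerance = 1e-14)

  # G == 2, R == 0.5 on an all-ones input: one iteration gives 2.5
  forced <- neutral
  forced[["dec1.udke.t1.G.c2.b"]] <- rep(2, C)
  forced[["dec1.udke.t1.R.c2.b"]] <- rep(0.5, C)
  ones <- array(1, c(8, 8, C, 1))
  tp <- ns$tape_new(forced, training = FALSE)
  id <- ns$udke_fwd(tp, ns$tp_input(tp, ones), "dec1.udke", 1L)
  expect_equal(ns$tp_val(tp, id), ones * 2.5, tolerance = 1e-14)

  expect_error(network_config(udke_iters = 0), "udke_iters")
})

test_that("the attention gate degenerates to 0.5 with zeroed parameters", {
  cfg <- micro_network()
  m <- build_model(cfg)
  p <- m$params
  for (nm in grep("fam1.gate", names(p), value = TRUE)) p[[nm]] <- p[[nm]] * 0
  Cf <- m$channels$fused
  Cl <- m$channels$dec_out[1]
  fused <- array(runif(8 * 8 * Cf), c(8, 8, Cf, 1))
  level <- array(runif(8 * 8 * Cl), c(8, 8, Cl, 1))
  tp <- ns$tape_new(p, training = FALSE)
  fam <- ns$fam_fwd(tp, ns$tp_input(tp, fused), ns$tp_input(tp, level), "fam1")
  att <- ns$tp_val(tp, fam$att)
  expect_equal(att, array(0.5, dim(att)))
  refined <- ns$tp_val(tp, fam$refined)
  expect_equal(dim(refined), c(8, 8, 1, 1))
  expect_true(all(refined > 0 & refined < 1))
})

test_that("builds are deterministic and forward outputs are well-formed", {
  cfg <- micro_network(seed = 9)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)

  cfg3 <- network_config(base_channels = 4, growth = 2, dense_layers = 2,
                         levels = 3, udke_iters = 1, dropout_p = 0,
                         udke_hidden = 2, fam_channels = 2, seed = 2)
  m <- build_model(cfg3)
  out <- forward(m, matrix(runif(16 * 16), 16, 16))
  expect_length(out$coarse_maps, 2)          # L - 1 of each
  expect_length(out$refined_maps, 2)
  expect_length(out$attention_maps, 2)
  for (mp in c(out$coarse_maps, out$refined_maps, list(out$final_map))) {
    expect_equal(dim(mp), c(16, 16))
    expect_true(all(mp > 0 & mp < 1))
  }
  # final is exactly the mean of the refined maps
  expect_equal(out$final_map,
               (out$refined_maps[[1]] + out$refined_maps[[2]]) / 2,
               tolerance = 1e-14)
  expect_error(forward(m, matrix(0.5, 18, 18)), "divisible")
})

test_that("shapes are preserved across valid input sizes", {
  m <- build_model(micro_network())
  for (S in c(8, 12, 20)) {
    out <- forward(m, matrix(runif(S * S), S, S))
    expect_equal(dim(out$final_map), c(S, S))
  }
})

test_that("every parameter tensor receives gradient on a random batch", {
  cfg <- micro_network(seed = 5)
  m <- build_model(cfg)
  set.seed(1)
  x <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  y <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 1, 2))
  tp <- ns$tape_new(m$params, m$buffers, training = TRUE)
  g <- ns$net_graph(tp, m, x)
  seeds <- list()
  for (id in c(g$coarse, g$refined, list(g$final))) {
    r <- ns$bce_core(ns$tp_val(tp, id), y, want_grad = TRUE)
    seeds[[as.character(id)]] <- r$grad
  }
  ns$tape_backward(tp, seeds)
  for (nm in names(m$params)) {
    gr <- tp$pg[[nm]]
    expect_false(is.null(gr), info = nm)
    expect_gt(sum(abs(gr)), 0, label = paste("gradient of", nm))
  }
})

test_that("the default configuration builds", {
  m <- build_model(network_config())
  expect_equal(m$config$levels, 4)
  tab <- model_describe(m)
  expect_equal(nrow(tab), 7)
  expect_equal(tab$out_channels[1], 48 + 48)
  expect_silent(run_config())                 # 256 patches divide 2^(L-1)
})

test_that("the model description table tracks the configured channels", {
  m <- build_model(tiny_network())
  tab <- model_describe(m)
  expect_s3_class(tab, "tbl_df")
  expect_equal(tab$out_channels[1:3], c(32, 48, 64))   # F + D*j cascade
  expect_equal(nrow(tab), 5)                           # 3 encoder + 2 decoder
})
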