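#' Network configuration
#'
#' Hyperparameters of the segmentation network: a U-Net whose convolution
#' blocks are densely connected dropout blocks (each of `dense_layers` layers
#' adds `growth` feature maps, so a block maps C channels to C +
#' `dense_layers * growth`), atrous channel attention after every encoder
#' block, decoder levels of transpose-convolution upsampling, skip
#' concatenation, a dense block and an unfolded kernel-estimation (UDKE)
#' refinement block, and a multiheaded attention head producing one refined
#' map per decoder level.
#'
#' @param base_channels F, channels entering the first dense block.
#' @param growth j, channels added per dense layer.
#' @param dense_layers D, layers per dropout block.
#' @param levels L, resolution levels of the encoder/decoder.
#' @param udke_iters T, unfolding iterations per UDKE block.
#' @param att_kernel k, 1-D convolution kernel size in the channel attention.
#' @param att_dilation r, dilation rate of the second 1-D convolution.
#' @param dropout_p Dropout probability inside dense layers.
#' @param in_channels Input image channels (1 for preprocessed intensity).
#' @param udke_hidden Hidden channels of the UDKE gain/residual subnets.
#' @param fam_channels Hidden channels of the feature attention modules.
#' @param seed Initialisation seed; two builds with equal seeds have
#'   identical parameters.
#' @return A `network_config` object.
#' @export
network_config <- function(base_channels = 48L, growth = 12L,
                           dense_layers = 4L, levels = 4L, udke_iters = 3L,
                           att_kernel = 3L, att_dilation = 2L,
                           dropout_p = 0.2, in_channels = 1L,
                           udke_hidden = growth, fam_channels = 16L,
                           seed = 1L) {
  cfg <- list(base_channels = as.integer(base_channels),
              growth = as.integer(growth),
              dense_layers = as.integer(dense_layers),
              levels = as.integer(levels),
              udke_iters = as.integer(udke_iters),
              att_kernel = as.integer(att_kernel),
              att_dilation = as.integer(att_dilation),
              dropout_p = dropout_p, in_channels = as.integer(in_channels),
              udke_hidden = as.integer(udke_hidden),
              fam_channels = as.integer(fam_channels), seed = as.integer(seed))
  for (f in c("base_channels", "growth", "dense_layers", "levels",
              "udke_iters", "att_kernel", "udke_hidden", "fam_channels")) {
    if (cfg[[f]] < 1L)
      stop(sprintf("build error: `%s` must be >= 1", f), call. = FALSE)
  }
  if (cfg$att_dilation < 1L)
    stop("build error: `att_dilation` must be >= 1", call. = FALSE)
  if (cfg$dropout_p < 0 || cfg$dropout_p >= 1)
    stop("build error: `dropout_p` must lie in [0, 1)", call. = FALSE)
  if (cfg$levels < 2L)
    stop("build error: `levels` must be >= 2", call. = FALSE)
  class(cfg) <- "network_config"
  cfg
}

# He-normal weights, zero biases; all draws come from the model seed set in
# build_model so builds are reproducible.
winit_conv <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

#' Build a segmentation model
#'
#' Allocates and deterministically initialises every parameter tensor of the
#' architecture described in [network_config()], together with the channel
#' bookkeeping used by the forward pass.
#'
#' @param config A [network_config()].
#' @return A `retseg_model`: list with `params` (flat named list of arrays),
#'   `buffers` (environment of batch-norm running statistics), `config` and
#'   `channels`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "network_config"))
  cfg <- config
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)

  L <- cfg$levels; D <- cfg$dense_layers; j <- cfg$growth
  P <- list()

  add_dense <- function(P, prefix, cin) {
    cc <- cin
    for (d in seq_len(D)) {
      P[[paste0(prefix, ".l", d, ".bn.gamma")]] <- rep(1, cc)
      P[[paste0(prefix, ".l", d, ".bn.beta")]] <- rep(0, cc)
      P[[paste0(prefix, ".l", d, ".conv.w")]] <- winit_conv(3L, cc, j)
      P[[paste0(prefix, ".l", d, ".conv.b")]] <- rep(0, j)
      cc <- cc + j
    }
    P
  }

  # stem
  P[["stem.w"]] <- winit_conv(3L, cfg$in_channels, cfg$base_channels)
  P[["stem.b"]] <- rep(0, cfg$base_channels)

  enc_in <- integer(L); enc_out <- integer(L)
  cur <- cfg$base_channels
  for (l in seq_len(L)) {
    enc_in[l] <- cur
    P <- add_dense(P, paste0("enc", l, ".dense"), cur)
    cur <- cur + D * j
    enc_out[l] <- cur
    k <- cfg$att_kernel
    P[[paste0("enc", l, ".att.w1")]] <- stats::rnorm(k, 0, 0.1)
    P[[paste0("enc", l, ".att.b1")]] <- 0
    P[[paste0("enc", l, ".att.w2")]] <- stats::rnorm(k, 0, 0.1)
    P[[paste0("enc", l, ".att.b2")]] <- 0
  }

  dec_out <- integer(L - 1L)
  cur <- enc_out[L]
  for (l in seq(L - 1L, 1L)) {
    # transpose conv halves the channel count before the skip concatenation
    tout <- (enc_out[l] + 1L) %/% 2L
    P[[paste0("dec", l, ".tconv.w")]] <-
      array(stats::rnorm(4L * tout * cur, 0, sqrt(2 / (4 * cur))),
            c(2L, 2L, tout, cur))
    P[[paste0("dec", l, ".tconv.b")]] <- rep(0, tout)
    cin <- tout + enc_out[l]
    P <- add_dense(P, paste0("dec", l, ".dense"), cin)
    cur <- cin + D * j
    dec_out[l] <- cur
    h <- cfg$udke_hidden
    for (t in seq_len(cfg$udke_iters)) {
      for (sub in c("G", "R")) {
        # gain/residual subnets: 3x3 bottleneck then 1x1 expansion
        P[[paste0("dec", l, ".udke.t", t, ".", sub, ".c1.w")]] <-
          winit_conv(3L, cur, h)
        P[[paste0("dec", l, ".udke.t", t, ".", sub, ".c1.b")]] <- rep(0, h)
        P[[paste0("dec", l, ".udke.t", t, ".", sub, ".c2.w")]] <-
          winit_conv(1L, h, cur)
        P[[paste0("dec", l, ".udke.t", t, ".", sub, ".c2.b")]] <- rep(0, cur)
      }
    }
  }

  Cf <- sum(dec_out)
  fc <- cfg$fam_channels
  for (l in seq_len(L - 1L)) {
    P[[paste0("head", l, ".w")]] <- winit_conv(1L, dec_out[l], 1L)
    P[[paste0("head", l, ".b")]] <- 0
    P[[paste0("fam", l, ".gate.wf")]] <- winit_conv(1L, Cf, fc)
    P[[paste0("fam", l, ".gate.bf")]] <- rep(0, fc)
    P[[paste0("fam", l, ".gate.wl")]] <- winit_conv(1L, dec_out[l], fc)
    P[[paste0("fam", l, ".gate.bl")]] <- rep(0, fc)
    P[[paste0("fam", l, ".gate.wpsi")]] <- winit_conv(1L, fc, 1L)
    P[[paste0("fam", l, ".gate.bpsi")]] <- 0
    P[[paste0("fam", l, ".mix.c3.w")]] <- winit_conv(3L, 2L * dec_out[l], fc)
    P[[paste0("fam", l, ".mix.c3.b")]] <- rep(0, fc)
    P[[paste0("fam", l, ".mix.c1.w")]] <- winit_conv(1L, fc, 1L)
    P[[paste0("fam", l, ".mix.c1.b")]] <- 0
  }

  structure(list(params = P,
                 buffers = new.env(parent = emptyenv()),
                 config = cfg,
                 channels = list(enc_in = enc_in, enc_out = enc_out,
                                 dec_out = dec_out, fused = Cf)),
            class = "retseg_model")
}

#' @export
print.retseg_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    "<retseg_model> L=%d F=%d j=%d D=%d T=%d | %d parameter tensors, %s values\n",
    cfg$levels, cfg$base_channels, cfg$growth, cfg$dense_layers,
    cfg$udke_iters, length(x$params), format(np, big.mark = ",")))
  invisible(x)
}

#' Per-level channel table of a built model
#'
#' @param model A `retseg_model`.
#' @return A [tibble::tibble()] with one row per stage.
#' @export
model_describe <- function(model) {
  ch <- model$channels
  L <- model$config$levels
  tibble::tibble(
    stage = c(paste0("encoder", seq_len(L)), paste0("decoder", seq_len(L - 1))),
    in_channels = c(ch$enc_in,
                    (ch$enc_out[seq_len(L - 1)] + 1L) %/% 2L +
                      ch$enc_out[seq_len(L - 1)]),
    out_channels = c(ch$enc_out, ch$dec_out),
    scale = c(2^(seq_len(L) - 1), 2^(seq_len(L - 1) - 1)))
}

# -- forward graph -------------------------------------------------------------

dense_fwd <- function(tp, id, prefix, D, p) {
  cur <- id
  for (d in seq_len(D)) {
    h <- tp_bn(tp, cur, paste0(prefix, ".l", d, ".bn.gamma"),
               paste0(prefix, ".l", d, ".bn.beta"),
               paste0(prefix, ".l", d, ".bn"))
    h <- tp_conv(tp, h, paste0(prefix, ".l", d, ".conv.w"),
                 paste0(prefix, ".l", d, ".conv.b"))
    h <- tp_relu(tp, h)
    h <- tp_dropout(tp, h, p)
    cur <- tp_concat(tp, c(cur, h))
  }
  cur
}

udke_fwd <- function(tp, id, prefix, iters) {
  cur <- id
  for (t in seq_len(iters)) {
    subnet <- function(sub) {
      h <- tp_conv(tp, cur, paste0(prefix, ".t", t, ".", sub, ".c1.w"),
                   paste0(prefix, ".t", t, ".", sub, ".c1.b"))
      h <- tp_relu(tp, h)
      tp_conv(tp, h, paste0(prefix, ".t", t, ".", sub, ".c2.w"),
              paste0(prefix, ".t", t, ".", sub, ".c2.b"))
    }
    g <- subnet("G")
    r <- subnet("R")
    cur <- tp_add(tp, tp_mul(tp, cur, g), r)
  }
  cur
}

fam_fwd <- function(tp, fused, level, prefix) {
  g1 <- tp_conv(tp, fused, paste0(prefix, ".gate.wf"),
                paste0(prefix, ".gate.bf"))
  g2 <- tp_conv(tp, level, paste0(prefix, ".gate.wl"),
                paste0(prefix, ".gate.bl"))
  s <- tp_relu(tp, tp_add(tp, g1, g2))
  att <- tp_sigmoid(tp, tp_conv(tp, s, paste0(prefix, ".gate.wpsi"),
                                paste0(prefix, ".gate.bpsi")))
  gated <- tp_mul(tp, level, att)
  cat_ <- tp_concat(tp, c(gated, level))
  m <- tp_relu(tp, tp_conv(tp, cat_, paste0(prefix, ".mix.c3.w"),
                           paste0(prefix, ".mix.c3.b")))
  refined <- tp_sigmoid(tp, tp_conv(tp, m, paste0(prefix, ".mix.c1.w"),
                                    paste0(prefix, ".mix.c1.b")))
  list(refined = refined, att = att)
}

# Builds the whole forward graph on a tape; x is (H, W, Cin, N).
net_graph <- function(tp, model, x) {
  cfg <- model$config
  L <- cfg$levels
  d <- dim(x)
  S <- d[1]
  div <- 2^(L - 1L)
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop(sprintf(
      "shape error: input size %dx%d must be divisible by 2^(levels-1) = %d",
      d[1], d[2], div), call. = FALSE)

  cur <- tp_conv(tp, tp_input(tp, x), "stem.w", "stem.b")
  enc <- vector("list", L)
  for (l in seq_len(L)) {
    cur <- dense_fwd(tp, cur, paste0("enc", l, ".dense"), cfg$dense_layers,
                     cfg$dropout_p)
    cur <- tp_chatt(tp, cur, paste0("enc", l, ".att.w1"),
                    paste0("enc", l, ".att.b1"),
                    paste0("enc", l, ".att.w2"),
                    paste0("enc", l, ".att.b2"), cfg$att_dilation)
    enc[[l]] <- cur
    if (l < L) cur <- tp_maxpool2(tp, cur)
  }

  dec <- vector("list", L - 1L)
  for (l in seq(L - 1L, 1L)) {
    cur <- tp_tconv2(tp, cur, paste0("dec", l, ".tconv.w"),
                     paste0("dec", l, ".tconv.b"))
    cur <- tp_concat(tp, c(cur, enc[[l]]))
    cur <- dense_fwd(tp, cur, paste0("dec", l, ".dense"), cfg$dense_layers,
                     cfg$dropout_p)
    cur <- udke_fwd(tp, cur, paste0("dec", l, ".udke"), cfg$udke_iters)
    dec[[l]] <- cur
  }

  ups <- lapply(seq_len(L - 1L), function(l)
    tp_upsample(tp, dec[[l]], d[1], d[2]))
  coarse <- lapply(seq_len(L - 1L), function(l)
    tp_sigmoid(tp, tp_conv(tp, ups[[l]], paste0("head", l, ".w"),
                           paste0("head", l, ".b"))))
  fused <- if (L - 1L > 1L) tp_concat(tp, unlist(ups)) else ups[[1]]
  fams <- lapply(seq_len(L - 1L), function(l)
    fam_fwd(tp, fused, ups[[l]], paste0("fam", l)))
  refined <- lapply(fams, `[[`, "refined")
  atts <- lapply(fams, `[[`, "att")

  acc <- refined[[1]]
  if (L - 1L > 1L)
    for (l in seq(2L, L - 1L)) acc <- tp_add(tp, acc, refined[[l]])
  final <- tp_scale(tp, acc, 1 / (L - 1L))

  list(coarse = coarse, refined = refined, att = atts, final = final)
}

#' Run the network forward
#'
#' @param model A [build_model()] result.
#' @param patch Input: an H x W matrix, H x W x C array, or H x W x C x N
#'   batch, with H and W divisible by `2^(levels - 1)`.  Values are expected
#'   in \[0, 1\].
#' @param training Logical; enables dropout and batch statistics.
#' @return A `forward_outputs` list: `coarse_maps`, `refined_maps` and
#'   `attention_maps` (lists of L-1 maps each), and `final_map`, the
#'   elementwise mean of the refined maps.  For unbatched input all maps are
#'   H x W matrices.
#' @export
forward <- function(model, patch, training = FALSE) {
  stopifnot(inherits(model, "retseg_model"))
  x <- patch
  single <- FALSE
  if (is.matrix(x)) { dim(x) <- c(dim(x), 1L, 1L); single <- TRUE }
  else if (length(dim(x)) == 3L) { dim(x) <- c(dim(x), 1L); single <- TRUE }
  if (dim(x)[3] != model$config$in_channels)
    stop("shape error: wrong number of input channels", call. = FALSE)
  tp <- tape_new(model$params, model$buffers, training = training)
  g <- net_graph(tp, model, x)
  grab <- function(id) {
    v <- tp_val(tp, id)
    if (single) matrix(v, dim(v)[1], dim(v)[2]) else v
  }
  structure(list(coarse_maps = lapply(g$coarse, grab),
                 refined_maps = lapply(g$refined, grab),
                 attention_maps = lapply(g$att, grab),
                 final_map = grab(g$final)),
            class = "forward_outputs")
}
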