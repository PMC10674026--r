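#' Run configuration
#'
#' Bundles preprocessing, network, loss-weight and optimisation settings for
#' [train()], [predict_image()] and [evaluate()].
#'
#' @param preprocess A [preprocess_config()].
#' @param network A [network_config()].
#' @param weights A [loss_weights()] (defaults to one matching the network's
#'   level count).
#' @param batch_size Mini-batch size (default 4).
#' @param patch_size Training/inference patch side (default 256; must be
#'   divisible by `2^(levels - 1)`).
#' @param test_stride Patch-grid stride at inference (default 20); overlaps
#'   are averaged.
#' @param epochs Training epochs (one random patch per augmented variant per
#'   epoch).
#' @param max_steps Optional hard cap on optimisation steps.
#' @param lr Adam learning rate.
#' @param loss_in_fov Restrict the loss to FOV pixels (default TRUE).
#' @param seed Master seed fixing patch sampling, dropout and initialisation.
#' @param checkpoint_dir,report_dir Optional output directories.
#' @return A `run_config` object.
#' @export
run_config <- function(preprocess = preprocess_config(),
                       network = network_config(),
                       weights = NULL,
                       batch_size = 4L, patch_size = 256L, test_stride = 20L,
                       epochs = 50L, max_steps = NULL, lr = 1e-3,
                       loss_in_fov = TRUE, seed = 1L,
                       checkpoint_dir = NULL, report_dir = NULL) {
  if (is.null(weights)) weights <- loss_weights(network$levels)
  div <- 2^(network$levels - 1L)
  if (patch_size %% div != 0L)
    stop(sprintf(
      "config error: patch_size %d not divisible by 2^(levels-1) = %d",
      patch_size, div), call. = FALSE)
  if (batch_size < 1L) stop("config error: batch_size must be >= 1",
                            call. = FALSE)
  if (test_stride < 1L) stop("config error: test_stride must be >= 1",
                             call. = FALSE)
  structure(list(preprocess = preprocess, network = network,
                 weights = weights, batch_size = as.integer(batch_size),
                 patch_size = as.integer(patch_size),
                 test_stride = as.integer(test_stride),
                 epochs = as.integer(epochs),
                 max_steps = if (is.null(max_steps)) NULL else
                   as.integer(max_steps),
                 lr = lr, loss_in_fov = isTRUE(loss_in_fov),
                 seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir, report_dir = report_dir),
            class = "run_config")
}

# Reflect-pad a matrix up to at least (S, S); returns padded matrix plus the
# original size for cropping back.
reflect_pad_to <- function(m, S) {
  pad_axis <- function(n) {
    if (n >= S) return(seq_len(n))
    base <- c(seq_len(n), rev(seq_len(n))[-1])   # reflect without edge repeat
    rep_len(base, S)
  }
  m[pad_axis(nrow(m)), pad_axis(ncol(m)), drop = FALSE]
}

# Preprocess every sample and expand with the five augmentations.
build_variants <- function(dataset, pconf, augment_ops = TRUE) {
  out <- list()
  for (s in dataset) {
    pp <- preprocess_sample(s, pconf)
    out[[length(out) + 1L]] <- pp
    if (augment_ops) {
      for (op in c("hflip", "vflip", "rot90", "zoom", "shift")) {
        a <- augment(pp$x * 255, pp$vessel, pp$fov, op)
        out[[length(out) + 1L]] <-
          list(x = a$image / 255, vessel = a$vessel_mask, fov = a$fov_mask)
      }
    }
  }
  out
}

sample_patch <- function(v, S) {
  H <- nrow(v$x); W <- ncol(v$x)
  if (H < S || W < S) {
    v$x <- reflect_pad_to(v$x, S)
    v$vessel <- reflect_pad_to(v$vessel, S)
    v$fov <- reflect_pad_to(v$fov, S)
    H <- nrow(v$x); W <- ncol(v$x)
  }
  idx <- which(v$fov > 0)
  pick <- idx[sample.int(length(idx), 1L)]
  pr <- (pick - 1L) %% H + 1L
  pc <- (pick - 1L) %/% H + 1L
  r0 <- min(max(pr - S %/% 2L, 1L), H - S + 1L)
  c0 <- min(max(pc - S %/% 2L, 1L), W - S + 1L)
  rs <- r0 + seq_len(S) - 1L; cs <- c0 + seq_len(S) - 1L
  list(x = v$x[rs, cs], y = v$vessel[rs, cs], fov = v$fov[rs, cs])
}

#' Train the segmentation network on a dataset
#'
#' Applies the five augmentations to every sample, draws random FOV-centred
#' patches, and optimises the deep-supervision cross-entropy with Adam.
#' Fully deterministic under a fixed `config$seed`.
#'
#' @param config A [run_config()].
#' @param dataset Non-empty list of `fundus_sample` objects (or lists with
#'   `image`, `vessel_mask`, `fov_mask`).
#' @param verbose Print a progress line every 25 steps.
#' @return A `retseg_fit`: list with the trained `model`, the `config`, a
#'   per-step `log` tibble, and `checkpoint` (path or `NA`).  When
#'   `config$checkpoint_dir` is set, a checkpoint (with the config embedded)
#'   and a JSON-lines training log are written there.
#' @export
train <- function(config, dataset, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (length(dataset) == 0)
    stop("invalid parameter: empty dataset", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  variants <- build_variants(dataset, config$preprocess)
  model <- build_model(config$network)
  opt <- make_optimizer(model, lr = config$lr,
                        batch_size = config$batch_size)
  S <- config$patch_size
  B <- config$batch_size
  steps_per_epoch <- max(1L, ceiling(length(variants) / B))
  n_steps <- config$epochs * steps_per_epoch
  if (!is.null(config$max_steps)) n_steps <- min(n_steps, config$max_steps)

  log <- vector("list", n_steps)
  for (step in seq_len(n_steps)) {
    vix <- sample.int(length(variants), B, replace = TRUE)
    xb <- array(0, c(S, S, 1L, B))
    yb <- array(0, c(S, S, 1L, B))
    fb <- array(0, c(S, S, 1L, B))
    for (b in seq_len(B)) {
      pt <- sample_patch(variants[[vix[b]]], S)
      xb[, , 1L, b] <- pt$x
      yb[, , 1L, b] <- pt$y
      fb[, , 1L, b] <- pt$fov
    }
    fovm <- if (config$loss_in_fov) fb else NULL

    tp <- tape_new(model$params, model$buffers, training = TRUE)
    g <- net_graph(tp, model, xb)
    w <- config$weights
    seeds <- list()
    ct <- numeric(length(g$coarse)); rt <- numeric(length(g$refined))
    for (l in seq_along(g$coarse)) {
      r <- bce_core(tp_val(tp, g$coarse[[l]]), yb, fovm, want_grad = TRUE)
      ct[l] <- r$value
      if (w$alpha[l] > 0)
        seeds[[as.character(g$coarse[[l]])]] <- w$alpha[l] * r$grad
    }
    for (l in seq_along(g$refined)) {
      r <- bce_core(tp_val(tp, g$refined[[l]]), yb, fovm, want_grad = TRUE)
      rt[l] <- r$value
      if (w$beta[l] > 0)
        seeds[[as.character(g$refined[[l]])]] <- w$beta[l] * r$grad
    }
    rf <- bce_core(tp_val(tp, g$final), yb, fovm, want_grad = TRUE)
    if (w$gamma_f > 0) {
      key <- as.character(g$final)
      seeds[[key]] <- (seeds[[key]] %||% 0) + w$gamma_f * rf$grad
    }
    total <- sum(w$alpha * ct) + sum(w$beta * rt) + w$gamma_f * rf$value

    tape_backward(tp, seeds)
    model$params <- optimizer_step(opt, model$params, tp$pg)

    log[[step]] <- tibble::tibble(step = step,
                                  epoch = (step - 1L) %/% steps_per_epoch + 1L,
                                  total = total, final_term = rf$value)
    if (verbose && step %% 25L == 0L)
      message(sprintf("step %d/%d  loss %.4f", step, n_steps, total))
  }
  log <- do.call(rbind, log)

  fit <- structure(list(model = model, config = config, log = log,
                        checkpoint = NA_character_),
                   class = "retseg_fit")
  if (!is.null(config$checkpoint_dir)) {
    dir.create(config$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    fit$checkpoint <- file.path(config$checkpoint_dir, "model.rds")
    save_checkpoint(fit, fit$checkpoint)
    jl <- file.path(config$checkpoint_dir, "train_log.jsonl")
    writeLines(vapply(seq_len(nrow(log)), function(i)
      jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE), character(1)),
      jl)
  }
  fit
}

#' Save / load a fitted model (config embedded)
#'
#' @param fit A `retseg_fit`.
#' @param path Destination file.
#' @return `save_checkpoint` returns the path invisibly; `load_checkpoint`
#'   returns the `retseg_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  obj <- list(params = fit$model$params,
              buffers = as.list(fit$model$buffers),
              config = fit$config, log = fit$log)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path))
    stop(sprintf("I/O error: checkpoint '%s' not found", path), call. = FALSE)
  obj <- readRDS(path)
  model <- build_model(obj$config$network)
  model$params <- obj$params
  for (nm in names(obj$buffers)) model$buffers[[nm]] <- obj$buffers[[nm]]
  structure(list(model = model, config = obj$config, log = obj$log,
                 checkpoint = path),
            class = "retseg_fit")
}

#' @export
print.retseg_fit <- function(x, ...) {
  cat(sprintf("<retseg_fit> %d steps | final training loss %.4f\n",
              nrow(x$log), utils::tail(x$log$total, 1)))
  invisible(x)
}

#' Predict a whole-image vessel probability map
#'
#' Preprocesses the image, extracts overlapping patches at `test_stride`,
#' runs the network on each patch (in eval mode) and averages the final maps
#' over the overlaps; pixels outside the FOV are set to 0.  Images smaller
#' than the patch size are reflect-padded and cropped back.
#'
#' @param fit A `retseg_fit` or a checkpoint path.
#' @param sample A `fundus_sample` (or list with `image` and optionally
#'   `fov_mask`).
#' @param stride Optional override of `config$test_stride`.
#' @return H x W matrix of vessel probabilities.
#' @export
predict_image <- function(fit, sample, stride = NULL) {
  if (is.character(fit)) fit <- load_checkpoint(fit)
  config <- fit$config
  model <- fit$model
  S <- config$patch_size
  stride <- stride %||% config$test_stride

  pp <- preprocess_sample(sample, config$preprocess)
  H <- nrow(pp$x); W <- ncol(pp$x)
  x <- pp$x
  padded <- H < S || W < S
  if (padded) x <- reflect_pad_to(x, S)

  grid <- extract_patches(x, S, stride)
  B <- config$batch_size
  nb <- length(grid$patches)
  probs <- vector("list", nb)
  i <- 1L
  while (i <= nb) {
    take <- seq(i, min(i + B - 1L, nb))
    xb <- array(0, c(S, S, 1L, length(take)))
    for (b in seq_along(take)) xb[, , 1L, b] <- grid$patches[[take[b]]]
    out <- forward(model, xb, training = FALSE)
    fm <- out$final_map
    for (b in seq_along(take)) probs[[take[b]]] <- matrix(fm[, , 1L, b], S, S)
    i <- i + length(take)
  }
  grid$patches <- probs
  full <- stitch_patches(grid)
  full <- full[seq_len(H), seq_len(W), drop = FALSE]
  full * (pp$fov > 0)
}

#' Evaluate a fitted model on a dataset
#'
#' Runs [predict_image()] per sample, thresholds, and computes the full
#' metric suite inside the FOV.
#'
#' @param fit A `retseg_fit` or checkpoint path.
#' @param dataset List of samples with ground-truth vessel masks.
#' @param threshold Probability cut (default 0.5).
#' @return A `retseg_eval`: list with `per_image` (tibble, one row per
#'   sample) and `aggregate` (one-row tibble of means).  Written as CSV/JSON
#'   under `config$report_dir` when set.
#' @export
evaluate <- function(fit, dataset, threshold = 0.5) {
  if (is.character(fit)) fit <- load_checkpoint(fit)
  rows <- list()
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    if (is.null(s$vessel_mask)) {
      warning(sprintf("sample %d has no ground truth; skipped", i),
              call. = FALSE)
      next
    }
    pm <- predict_image(fit, s)
    rows[[length(rows) + 1L]] <-
      tibble::as_tibble(cbind(tibble::tibble(image = i),
                              metrics_report(pm, s$vessel_mask, s$fov_mask,
                                             threshold)))
  }
  per <- do.call(rbind, rows)
  agg <- tibble::as_tibble(as.list(colMeans(per[, -1])))
  res <- structure(list(per_image = per, aggregate = agg,
                        threshold = threshold),
                   class = "retseg_eval")
  rd <- fit$config$report_dir
  if (!is.null(rd)) {
    dir.create(rd, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per, file.path(rd, "per_image_metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(agg), file.path(rd, "aggregate.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.retseg_eval <- function(x, ...) {
  cat(sprintf("<retseg_eval> %d images | mean accuracy %.4f, F1 %.4f, AUC %.4f\n",
              nrow(x$per_image), x$aggregate$accuracy, x$aggregate$f1,
              x$aggregate$auc))
  invisible(x)
}
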