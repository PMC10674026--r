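#' Deep-supervision loss weights
#'
#' The total loss is `sum(alpha_l * coarse_l) + sum(beta_l * refined_l) +
#' gamma_f * final`, one coarse and one refined cross-entropy term per decoder
#' level plus the final-map term.  Defaults down-weight the auxiliary terms so
#' the final map dominates.
#'
#' @param levels L; the weight lists have length L - 1.
#' @param alpha Coarse-term weights (scalar recycled or length L - 1).
#' @param beta Refined-term weights (scalar recycled or length L - 1).
#' @param gamma_f Final-term weight.
#' @return A `loss_weights` object.
#' @export
loss_weights <- function(levels = 4L, alpha = 0.25, beta = 0.25,
                         gamma_f = 1.0) {
  nl <- levels - 1L
  alpha <- rep_len(alpha, nl)
  beta <- rep_len(beta, nl)
  if (any(c(alpha, beta, gamma_f) < 0))
    stop("invalid parameter: loss weights must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma_f = gamma_f),
            class = "loss_weights")
}

# Mean BCE over (FOV) pixels with epsilon clipping; optionally also the
# gradient with respect to the prediction (zero outside the FOV, zero where
# the clip is active).
bce_core <- function(pred, target, fov = NULL, eps = 1e-7, want_grad = FALSE) {
  if (!all(dim(pred)[1:2] == dim(target)[1:2]))
    stop("shape error: prediction and target differ in size", call. = FALSE)
  p <- pmin(pmax(pred, eps), 1 - eps)
  y <- target
  w <- if (is.null(fov)) array(1, dim(p)) else {
    f <- fov
    if (!all(dim(f)[1:2] == dim(p)[1:2]))
      stop("shape error: FOV mask differs in size", call. = FALSE)
    if (length(dim(p)) == 4L && length(dim(f)) < 4L)
      array(f, dim(p)) else f * 1
  }
  if (length(dim(p)) == 4L && length(dim(y)) < 4L) y <- array(y, dim(p))
  n <- sum(w)
  if (n == 0) stop("degenerate input: empty FOV", call. = FALSE)
  val <- -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / n
  if (!want_grad) return(list(value = val))
  g <- w * (-(y / p) + (1 - y) / (1 - p)) / n
  g[pred < eps | pred > 1 - eps] <- 0
  list(value = val, grad = g)
}

#' Binary cross-entropy of a probability map
#'
#' Mean over pixels (FOV pixels when a mask is given) of
#' `-(y * log(p) + (1 - y) * log(1 - p))`, with predictions clipped into
#' `(eps, 1 - eps)` for numerical stability.
#'
#' @param pred_map Probability matrix/array.
#' @param target_mask Binary matrix/array of the same spatial size.
#' @param fov_mask Optional binary mask; the mean runs over its support.
#' @param eps Clipping epsilon (default 1e-7).
#' @return Scalar loss.
#' @export
binary_cross_entropy <- function(pred_map, target_mask, fov_mask = NULL,
                                 eps = 1e-7) {
  bce_core(pred_map, target_mask, fov_mask, eps)$value
}

#' Composite deep-supervision loss
#'
#' Per-level cross-entropies on the coarse and refined maps plus the final
#' map, combined with [loss_weights()].
#'
#' @param outputs A [forward()] result.
#' @param target_mask Binary vessel mask.
#' @param weights A [loss_weights()] whose lists match the output level count.
#' @param fov_mask Optional FOV mask restricting every term.
#' @return A `loss_report`: list with `coarse_terms`, `refined_terms`,
#'   `final_term` and `total`.
#' @export
composite_loss <- function(outputs, target_mask, weights, fov_mask = NULL) {
  nl <- length(outputs$coarse_maps)
  if (length(weights$alpha) != nl || length(weights$beta) != nl)
    stop("invalid parameter: weight list length does not match output levels",
         call. = FALSE)
  ct <- vapply(outputs$coarse_maps, binary_cross_entropy, numeric(1),
               target_mask = target_mask, fov_mask = fov_mask)
  rt <- vapply(outputs$refined_maps, binary_cross_entropy, numeric(1),
               target_mask = target_mask, fov_mask = fov_mask)
  ft <- binary_cross_entropy(outputs$final_map, target_mask, fov_mask)
  structure(list(coarse_terms = ct, refined_terms = rt, final_term = ft,
                 total = sum(weights$alpha * ct) + sum(weights$beta * rt) +
                   weights$gamma_f * ft),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("<loss_report> total %.5f | final %.5f | coarse %s | refined %s\n",
              x$total, x$final_term,
              paste(sprintf("%.4f", x$coarse_terms), collapse = " "),
              paste(sprintf("%.4f", x$refined_terms), collapse = " ")))
  invisible(x)
}

#' Adam optimiser over all trainable parameters
#'
#' @param model A `retseg_model`.
#' @param lr Learning rate (> 0), default 1e-3.
#' @param batch_size Mini-batch size carried as metadata (default 4).
#' @param beta1,beta2,eps Adam moment decays and stabiliser.
#' @return An optimiser handle (environment with state).
#' @export
make_optimizer <- function(model, lr = 1e-3, batch_size = 4L, beta1 = 0.9,
                           beta2 = 0.999, eps = 1e-8) {
  if (lr <= 0) stop("invalid parameter `lr`: must be > 0", call. = FALSE)
  opt <- new.env(parent = emptyenv())
  opt$lr <- lr; opt$batch_size <- as.integer(batch_size)
  opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  opt$m <- lapply(model$params, function(p) p * 0)
  opt$v <- lapply(model$params, function(p) p * 0)
  opt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One Adam update
#'
#' @param opt A [make_optimizer()] handle (mutated in place).
#' @param params Named list of parameter arrays.
#' @param grads Named list/environment of gradients (missing entries are
#'   treated as zero).
#' @return The updated parameter list.
#' @export
optimizer_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- if (is.environment(grads)) grads[[nm]] else grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  params
}
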