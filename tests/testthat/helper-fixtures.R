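# Shared fixtures: every fixture is built in code, nothing is read from disk.

# Smallest network that exercises every block (fast unit tests).
micro_network <- function(seed = 3L) {
  network_config(base_channels = 4L, growth = 2L, dense_layers = 2L,
                 levels = 2L, udke_iters = 1L, att_kernel = 3L,
                 att_dilation = 2L, dropout_p = 0, udke_hidden = 2L,
                 fam_channels = 2L, seed = seed)
}

# The small-study configuration: L=3, F=16, j=4, T=2, 64-pixel patches.
tiny_network <- function(seed = 11L) {
  network_config(base_channels = 16L, growth = 4L, dense_layers = 4L,
                 levels = 3L, udke_iters = 2L, seed = seed)
}

small_phantom <- function(seed = 1L, hw = 96L) {
  generate_phantom(phantom_params(height = hw, width = hw, seed = seed))
}

# Random binary mask pair restricted to a disc FOV, for metric oracles.
random_mask_pair <- function(hw = 16L) {
  gt <- matrix(rbinom(hw * hw, 1, 0.3), hw, hw)
  pred <- matrix(rbinom(hw * hw, 1, 0.3), hw, hw)
  fov <- matrix(rbinom(hw * hw, 1, 0.8), hw, hw)
  list(gt = gt, pred = pred, fov = fov)
}

# Formula-free confusion oracle: enumerate pixels one by one.
count_confusion <- function(pred, gt, fov = NULL) {
  tn <- fp <- fn <- tp <- 0L
  for (i in seq_along(gt)) {
    if (!is.null(fov) && fov[i] == 0) next
    p <- pred[i] > 0; g <- gt[i] > 0
    if (p && g) tp <- tp + 1L
    else if (p && !g) fp <- fp + 1L
    else if (!p && g) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TN = tn, FP = fp, FN = fn, TP = tp)
}

# Mann-Whitney pair-counting AUC oracle (ties count half).
pair_count_auc <- function(p, g) {
  pos <- p[g > 0]; neg <- p[g == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# Exact rank-sum p-value by full enumeration of rank assignments.
enumerate_ranksum_p <- function(a, b) {
  n1 <- length(a); N <- n1 + length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  sums <- utils::combn(N, n1, function(ix) sum(r[ix]))
  mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
}
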