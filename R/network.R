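#' Configuration of the junction segmentation network
#'
#' Defaults mirror the published training setup for this assay: 256-px
#' inputs, batch size 32, learning rate 1e-5, 3x3 filters, stride 1, 128
#' channels, Adam with weight decay 0, 320 epochs (~12,000 updates on the
#' full annotation set). Every field can be overridden for desk-scale CPU
#' runs; reduced channel width and input crop size are the intended knobs.
#'
#' @param input_size_px Side of the square training crops.
#' @param batch_size Samples per update.
#' @param learning_rate Adam step size.
#' @param conv_filter_size Convolution kernel size (odd).
#' @param stride Convolution stride; only 1 is supported.
#' @param n_channels Channel width of every hidden layer.
#' @param n_epochs Passes over the training set.
#' @param weight_decay L2 penalty added to gradients.
#' @param optimiser Only `"adam"` is implemented.
#' @param rng_seed Seed for initialisation and batch sampling.
#' @param n_levels Resolution levels of the encoder/decoder (strides
#'   1, 2, 4, ... between levels).
#' @param eval_interval Updates between held-out evaluations/checkpoints.
#' @param n_updates Optional hard cap on total updates, overriding the
#'   epoch count.
#' @return An object of class `segmenter_config`.
#' @export
segmenter_config <- function(input_size_px = 256L, batch_size = 32L,
                             learning_rate = 1e-5, conv_filter_size = 3L,
                             stride = 1L, n_channels = 128L, n_epochs = 320L,
                             weight_decay = 0, optimiser = "adam",
                             rng_seed = 1L, n_levels = 4L,
                             eval_interval = 25L, n_updates = NULL) {
  stopifnot(input_size_px >= 16, batch_size >= 1, learning_rate > 0,
            conv_filter_size %% 2 == 1, stride == 1, n_channels >= 1,
            n_epochs >= 1, weight_decay >= 0, optimiser == "adam",
            n_levels >= 2)
  structure(list(input_size_px = as.integer(input_size_px),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 conv_filter_size = as.integer(conv_filter_size),
                 stride = 1L, n_channels = as.integer(n_channels),
                 n_epochs = as.integer(n_epochs),
                 weight_decay = weight_decay, optimiser = "adam",
                 rng_seed = as.integer(rng_seed),
                 n_levels = as.integer(n_levels),
                 eval_interval = as.integer(eval_interval),
                 n_updates = if (is.null(n_updates)) NULL
                             else as.integer(n_updates)),
            class = "segmenter_config")
}

# He-initialised conv parameters: w is (C_out, C_in*k*k), b zero.
.init_conv <- function(cin, cout, k) {
  fan <- cin * k * k
  list(w = matrix(rnorm(cout * fan, 0, sqrt(2 / fan)), cout, fan),
       b = numeric(cout))
}

.init_params <- function(config) {
  C <- config$n_channels; k <- config$conv_filter_size
  L <- config$n_levels
  set.seed(config$rng_seed)
  p <- list(stem = .init_conv(1, C, k), enc = vector("list", L),
            dec = vector("list", L - 1),
            head = .init_conv(C, 1, 1))
  for (l in seq_len(L))
    p$enc[[l]] <- list(a = .init_conv(C, C, k), b = .init_conv(C, C, k))
  for (l in seq_len(L - 1))
    p$dec[[l]] <- list(a = .init_conv(C, C, k), b = .init_conv(C, C, k))
  p
}

#' Create an untrained junction segmentation model
#'
#' A multi-resolution residual encoder-decoder: stacks of 3x3 convolutions
#' with ReLU and residual connections extract features at `n_levels`
#' resolutions (2x average pooling between levels); the decoder upsamples,
#' fuses each coarser map into the finer one by addition, and refines with
#' a further residual block; a 1x1 convolution and sigmoid give the
#' per-pixel junction probability.
#'
#' @param config A [segmenter_config()].
#' @return An object of class `tj_segmenter`.
#' @export
new_segmenter <- function(config = segmenter_config()) {
  structure(list(config = config, params = .init_params(config)),
            class = "tj_segmenter")
}

.relu <- function(x) { x[x < 0] <- 0; x }

.conv <- function(x, pp, k) cpp_conv_fwd(x, pp$w, pp$b, k)

# residual block: out = relu(a + convB(relu(convA(a)))); returns cache
.resblock_fwd <- function(a, pp, k) {
  h1p <- .conv(a, pp$a, k)
  h1 <- .relu(h1p)
  h2 <- .conv(h1, pp$b, k)
  pre <- a + h2
  list(out = .relu(pre), a = a, h1p = h1p, h1 = h1, pre = pre)
}

# backward through a residual block; returns d(input) and parameter grads
.resblock_bwd <- function(cache, pp, dout, k) {
  dpre <- dout * (cache$pre > 0)
  gb <- cpp_conv_bwd(cache$h1, pp$b$w, dpre, k)
  dh1p <- gb$dx * (cache$h1p > 0)
  ga <- cpp_conv_bwd(cache$a, pp$a$w, dh1p, k)
  list(din = dpre + ga$dx,
       grads = list(a = list(w = ga$dw, b = ga$db),
                    b = list(w = gb$dw, b = gb$db)))
}

# full forward pass on one (H, W) matrix; H, W divisible by 2^(L-1)
.net_fwd <- function(params, config, x) {
  k <- config$conv_filter_size; L <- config$n_levels
  xin <- array(x, c(nrow(x), ncol(x), 1))
  sp <- .conv(xin, params$stem, k)
  s <- .relu(sp)
  enc <- vector("list", L)
  a <- s
  for (l in seq_len(L)) {
    enc[[l]] <- .resblock_fwd(a, params$enc[[l]], k)
    if (l < L) a <- cpp_avgpool2(enc[[l]]$out)
  }
  dec <- vector("list", L - 1)
  u <- enc[[L]]$out
  for (l in rev(seq_len(L - 1))) {
    f <- cpp_upsample2(u) + enc[[l]]$out
    dec[[l]] <- .resblock_fwd(f, params$dec[[l]], k)
    u <- dec[[l]]$out
  }
  z <- cpp_conv_fwd(u, params$head$w, params$head$b, 1L)
  prob <- 1 / (1 + exp(-z[, , 1]))
  list(prob = prob, cache = list(xin = xin, sp = sp, s = s, enc = enc,
                                 dec = dec, u = u, z = z))
}

# backward from dL/dprob; returns gradient list shaped like params
.net_bwd <- function(params, config, cache, dprob) {
  k <- config$conv_filter_size; L <- config$n_levels
  p <- 1 / (1 + exp(-cache$z[, , 1]))
  dz <- array(dprob * p * (1 - p), dim(cache$z))
  gh <- cpp_conv_bwd(cache$u, params$head$w, dz, 1L)
  grads <- list(head = list(w = gh$dw, b = gh$db),
                enc = vector("list", L), dec = vector("list", L - 1))
  denc <- vector("list", L)    # gradient flowing into each enc output
  du <- gh$dx
  for (l in seq_len(L - 1)) {  # finest decoder block first
    rb <- .resblock_bwd(cache$dec[[l]], params$dec[[l]], du, k)
    grads$dec[[l]] <- rb$grads
    denc[[l]] <- rb$din                 # fuse: f = upsample(u_coarse) + e_l
    du <- cpp_upsample2_bwd(rb$din)
  }
  denc[[L]] <- du
  ds <- NULL
  for (l in rev(seq_len(L))) {
    d <- denc[[l]]
    rb <- .resblock_bwd(cache$enc[[l]], params$enc[[l]], d, k)
    grads$enc[[l]] <- rb$grads
    if (l > 1) {
      up <- cpp_avgpool2_bwd(rb$din)
      denc[[l - 1]] <- denc[[l - 1]] + up
    } else ds <- rb$din
  }
  dsp <- ds * (cache$sp > 0)
  gs <- cpp_conv_bwd(cache$xin, params$stem$w, dsp, k)
  grads$stem <- list(w = gs$dw, b = gs$db)
  grads
}

# soft-Dice loss (1 - dice) and its gradient wrt the probability map
.dice_loss_grad <- function(prob, target, smoothing = 1) {
  P <- sum(prob * target)
  Q <- sum(prob) + sum(target)
  dice <- (2 * P + smoothing) / (Q + smoothing)
  dprob <- -(2 * target * (Q + smoothing) - (2 * P + smoothing)) /
    (Q + smoothing)^2
  list(loss = 1 - dice, dprob = dprob)
}

# elementwise Adam over arbitrarily nested parameter lists
.adam_step <- function(params, grads, state, lr, wd, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.numeric(p)) {
      g <- g + wd * p
      if (is.null(s)) s <- list(m = p * 0, v = p * 0)
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      mh <- s$m / (1 - beta1^t)
      vh <- s$v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), s = s)
    } else {
      out <- vector("list", length(p)); names(out) <- names(p)
      snew <- vector("list", length(p)); names(snew) <- names(p)
      for (i in seq_along(p)) {
        key <- if (!is.null(names(p))) names(p)[i] else i
        r <- walk(p[[i]], g[[key]], if (is.null(s)) NULL else s[[key]])
        out[[i]] <- r$p; snew[[i]] <- r$s
      }
      list(p = out, s = snew)
    }
  }
  walk(params, grads, state)
}

# sum two gradient lists of identical shape
.grad_add <- function(a, b) {
  if (is.numeric(a)) return(a + b)
  out <- vector("list", length(a)); names(out) <- names(a)
  for (i in seq_along(a)) {
    key <- if (!is.null(names(a))) names(a)[i] else i
    out[[i]] <- .grad_add(a[[i]], b[[key]])
  }
  out
}

.grad_scale <- function(a, f) {
  if (is.numeric(a)) return(a * f)
  out <- vector("list", length(a)); names(out) <- names(a)
  for (i in seq_along(a)) out[[i]] <- .grad_scale(a[[i]], f)
  out
}
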