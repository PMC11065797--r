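#' Residual U-Net configuration
#'
#' Describes the dual-frame U-Net used for streak-artifact correction. The
#' contracting path has `depth` encoder blocks (two 3x3 conv + batch-norm +
#' ReLU each, followed by 2x2 max pooling), a two-conv bottleneck, and an
#' expanding path mirroring the encoder with 2x2 nearest-neighbour
#' upsampling and skip concatenations. With `dual_frame = TRUE`, the output
#' of each encoder block *after pooling* is additionally concatenated to the
#' input of the associated decoder block *before* upsampling (the
#' frame-condition bridges). A final 1x1 convolution maps to the
#' one-channel residual image.
#'
#' Convolutions are bias-free by default (batch normalization follows each
#' one); the final 1x1 convolution always carries a bias.
#'
#' @param input_size spatial size in pixels; must be divisible by
#'   `2^depth`.
#' @param in_channels input channels (1 for CT slices).
#' @param depth number of encoder blocks.
#' @param widths per-level channel widths, length `depth`.
#' @param bottleneck bottleneck channel width.
#' @param dual_frame add the pooled-feature bridges.
#' @param use_bias give the 3x3 convolutions biases.
#' @param batch_norm apply batch normalization after each 3x3 convolution.
#' @param bn_momentum running-statistics momentum; the framework default is
#'   0.99, but short desk-scale runs (of order 100 updates) need a faster
#'   0.8--0.9 so that inference-mode statistics catch up with training.
#' @param seed initialization seed.
#' @return an object of class `unet_config`.
#' @export
unet_config <- function(input_size = 512L, in_channels = 1L, depth = 4L,
                        widths = c(64L, 128L, 256L, 512L),
                        bottleneck = tail(widths, 1), dual_frame = TRUE,
                        use_bias = FALSE, batch_norm = TRUE,
                        bn_momentum = 0.99, seed = 42L) {
  stopifnot(depth >= 1, length(widths) == depth, all(widths >= 1),
            bottleneck >= 1)
  if (input_size %% 2^depth != 0)
    stop("input_size must be divisible by 2^depth")
  structure(list(input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 depth = as.integer(depth), widths = as.integer(widths),
                 bottleneck = as.integer(bottleneck),
                 dual_frame = isTRUE(dual_frame),
                 use_bias = isTRUE(use_bias),
                 batch_norm = isTRUE(batch_norm),
                 bn_momentum = bn_momentum, seed = as.integer(seed)),
            class = "unet_config")
}

#' Full-scale dual-frame U-Net configuration
#'
#' The canonical configuration: 512x512 input, four encoder blocks of widths
#' 64/128/256/512, bottleneck 512, dual-frame bridges at every level. See
#' the methods vignette for the parameter-count discussion.
#'
#' @param input_size override the input size (e.g. 128 for desk runs).
#' @export
unet_config_canonical <- function(input_size = 512L) {
  unet_config(input_size = input_size, depth = 4L,
              widths = c(64L, 128L, 256L, 512L), bottleneck = 512L,
              dual_frame = TRUE)
}

#' Toy configuration for desk-scale runs
#'
#' Depth-2, narrow-width variant that trains in minutes on one CPU.
#' @param input_size spatial size (divisible by 4).
#' @param base first-level width.
#' @param seed init seed.
#' @export
unet_config_toy <- function(input_size = 128L, base = 8L, seed = 42L) {
  unet_config(input_size = input_size, depth = 2L,
              widths = c(base, 2L * base), bottleneck = 4L * base,
              dual_frame = TRUE, bn_momentum = 0.9, seed = seed)
}

glorot_uniform <- function(k, cin, cout) {
  fan_in <- k * k * cin; fan_out <- k * k * cout
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(cout * k * k * cin, -lim, lim), cout, k * k * cin)
}

new_conv <- function(params, name, k, cin, cout, bias, bn) {
  params[[paste0(name, ".K")]] <- glorot_uniform(k, cin, cout)
  if (bias) params[[paste0(name, ".b")]] <- numeric(cout)
  if (bn) {
    params[[paste0(name, ".gamma")]] <- rep(1, cout)
    params[[paste0(name, ".beta")]] <- numeric(cout)
    params[[paste0(name, ".rmean")]] <- numeric(cout)
    params[[paste0(name, ".rvar")]] <- rep(1, cout)
  }
  params
}

#' Build a residual model from a configuration
#'
#' Allocates and initializes all weights (Glorot-uniform convolutions,
#' unit-gamma/zero-beta batch norm), seeded from the configuration.
#'
#' @param config a [unet_config()].
#' @return an object of class `residual_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  d <- config$depth; w <- config$widths; wb <- config$bottleneck
  bias <- config$use_bias; bn <- config$batch_norm
  with_seed(config$seed, {
    p <- list()
    cin <- config$in_channels
    for (i in seq_len(d)) {
      p <- new_conv(p, sprintf("enc%d_1", i), 3, cin, w[i], bias, bn)
      p <- new_conv(p, sprintf("enc%d_2", i), 3, w[i], w[i], bias, bn)
      cin <- w[i]
    }
    p <- new_conv(p, "bot_1", 3, w[d], wb, bias, bn)
    p <- new_conv(p, "bot_2", 3, wb, wb, bias, bn)
    s <- wb
    for (i in rev(seq_len(d))) {
      pre <- s + if (config$dual_frame) w[i] else 0L
      p <- new_conv(p, sprintf("dec%d_1", i), 3, pre + w[i], w[i], bias, bn)
      p <- new_conv(p, sprintf("dec%d_2", i), 3, w[i], w[i], bias, bn)
      s <- w[i]
    }
    # residual-head policy: the final 1x1 conv starts at zero so the
    # untrained model is the identity correction (predicts a zero artifact);
    # removes the large random-output transient that desk-scale budgets
    # cannot afford to train away
    p[["final.K"]] <- matrix(0, config$in_channels, w[1])
    p[["final.b"]] <- numeric(config$in_channels)
    structure(list(config = config, params = p, bn_eps = 1e-3,
                   bn_momentum = config$bn_momentum %||% 0.99),
              class = "residual_model")
  })
}

#' Count model parameters
#'
#' Total of convolution kernels and biases plus, when batch normalization is
#' enabled, its gamma/beta and moving mean/variance (the Keras
#' "total params" convention: trainable + non-trainable).
#'
#' @param model a `residual_model`.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "residual_model"))
  sum(vapply(model$params, length, numeric(1)))
}

# ---- forward / backward machinery ------------------------------------------

channel_sums <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3], d[4])
  rowSums(colSums(x))        # -> per-channel sums over (H, W, N)
}

# conv + optional BN + optional ReLU; returns output and cache for backward
unit_fw <- function(model, name, x, training, relu = TRUE) {
  p <- model$params
  K <- p[[paste0(name, ".K")]]
  k <- as.integer(sqrt(ncol(K) / (dim(x)[3])))
  b <- p[[paste0(name, ".b")]]
  y <- cpp_conv_fw(x, K, if (is.null(b)) numeric(0) else b, k)
  cache <- list(x = x, k = k, name = name)
  out <- y
  if (model$config$batch_norm && !is.null(p[[paste0(name, ".gamma")]])) {
    hw <- dim(y)[1] * dim(y)[2]
    if (training) {
      st <- cpp_bn_stats(y)
      mu <- st$mean; v <- st$var
    } else {
      mu <- p[[paste0(name, ".rmean")]]
      v <- p[[paste0(name, ".rvar")]]
    }
    inv <- 1 / sqrt(v + model$bn_eps)
    xhat <- (y - rep(mu, each = hw)) * rep(inv, each = hw)
    out <- xhat * rep(p[[paste0(name, ".gamma")]], each = hw) +
      rep(p[[paste0(name, ".beta")]], each = hw)
    dim(out) <- dim(y)
    cache$bn <- list(xhat = xhat, inv = inv, mu = mu, v = v,
                     training = training)
  }
  if (relu) {
    mask <- out > 0
    out <- out * mask
    cache$relu_mask <- mask
  }
  cache$out_dim <- dim(out)
  list(out = out, cache = cache)
}

# backward through conv(+BN)(+ReLU); returns dx and gradient list entries
unit_bw <- function(model, cache, dout, grads, need_dx = TRUE) {
  name <- cache$name
  p <- model$params
  if (!is.null(cache$relu_mask)) dout <- dout * cache$relu_mask
  if (!is.null(cache$bn)) {
    hw <- cache$out_dim[1] * cache$out_dim[2]
    m <- hw * cache$out_dim[4]
    xhat <- cache$bn$xhat
    gamma <- p[[paste0(name, ".gamma")]]
    dgamma <- channel_sums(dout * xhat)
    dbeta <- channel_sums(dout)
    grads[[paste0(name, ".gamma")]] <- dgamma
    grads[[paste0(name, ".beta")]] <- dbeta
    dxhat <- dout * rep(gamma, each = hw)
    sum_dxhat <- channel_sums(dxhat)
    sum_dxhat_xhat <- channel_sums(dxhat * xhat)
    dout <- (dxhat - rep(sum_dxhat / m, each = hw) -
               xhat * rep(sum_dxhat_xhat / m, each = hw)) *
      rep(cache$bn$inv, each = hw)
    dim(dout) <- cache$out_dim
  }
  K <- p[[paste0(name, ".K")]]
  bw <- cpp_conv_bw(cache$x, K, dout, cache$k, need_dx)
  grads[[paste0(name, ".K")]] <- bw$dk
  if (!is.null(p[[paste0(name, ".b")]]))
    grads[[paste0(name, ".b")]] <- as.numeric(bw$db)
  list(dx = if (need_dx) bw$dx else NULL, grads = grads)
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_ch <- function(x, c1) {
  d <- dim(x)
  list(a = array(x[, , seq_len(c1), ], c(d[1], d[2], c1, d[4])),
       b = array(x[, , (c1 + 1):d[3], ], c(d[1], d[2], d[3] - c1, d[4])))
}

# full U-Net forward; returns list(out, cache); cache retained only when
# backward is needed
unet_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  d <- cfg$depth
  cache <- list(enc = vector("list", d), dec = vector("list", d),
                pool_idx = vector("list", d), e_dim = vector("list", d),
                s_ch = integer(d))
  e_out <- vector("list", d)   # encoder block outputs (skip connections)
  pooled <- vector("list", d)  # pooled outputs (dual-frame bridges)
  s <- x
  for (i in seq_len(d)) {
    u1 <- unit_fw(model, sprintf("enc%d_1", i), s, training)
    u2 <- unit_fw(model, sprintf("enc%d_2", i), u1$out, training)
    e_out[[i]] <- u2$out
    mp <- cpp_maxpool_fw(u2$out)
    cache$enc[[i]] <- list(u1 = u1$cache, u2 = u2$cache)
    cache$pool_idx[[i]] <- mp$idx
    cache$e_dim[[i]] <- dim(u2$out)
    pooled[[i]] <- mp$y
    s <- mp$y
  }
  b1 <- unit_fw(model, "bot_1", s, training)
  b2 <- unit_fw(model, "bot_2", b1$out, training)
  cache$bot <- list(u1 = b1$cache, u2 = b2$cache)
  s <- b2$out
  for (i in rev(seq_len(d))) {
    cache$s_ch[i] <- dim(s)[3]
    pre <- if (cfg$dual_frame) concat_ch(s, pooled[[i]]) else s
    up <- cpp_upsample_fw(pre)
    cat_in <- concat_ch(up, e_out[[i]])
    v1 <- unit_fw(model, sprintf("dec%d_1", i), cat_in, training)
    v2 <- unit_fw(model, sprintf("dec%d_2", i), v1$out, training)
    cache$dec[[i]] <- list(u1 = v1$cache, u2 = v2$cache,
                           up_ch = dim(up)[3])
    s <- v2$out
  }
  fin <- unit_fw(model, "final", s, training, relu = FALSE)
  cache$fin <- fin$cache
  list(out = fin$out, cache = cache)
}

# full U-Net backward: dout -> gradient list (same names as params)
unet_backward <- function(model, cache, dout) {
  cfg <- model$config
  d <- cfg$depth
  grads <- list()
  bwf <- unit_bw(model, cache$fin, dout, grads)
  grads <- bwf$grads
  ds <- bwf$dx
  dbridge <- vector("list", d)   # grads flowing into pooled outputs
  de_skip <- vector("list", d)   # grads flowing into encoder outputs
  for (i in seq_len(d)) {        # decoder blocks, reverse creation order
    cc <- cache$dec[[i]]
    b2 <- unit_bw(model, cc$u2, ds, grads)
    b1 <- unit_bw(model, cc$u1, b2$dx, b2$grads)
    grads <- b1$grads
    sp <- split_ch(b1$dx, cc$up_ch)
    de_skip[[i]] <- sp$b
    dpre <- cpp_upsample_bw(sp$a)
    if (cfg$dual_frame) {
      sp2 <- split_ch(dpre, cache$s_ch[i])
      ds <- sp2$a
      dbridge[[i]] <- sp2$b
    } else {
      ds <- dpre
    }
  }
  b2 <- unit_bw(model, cache$bot$u2, ds, grads)
  b1 <- unit_bw(model, cache$bot$u1, b2$dx, b2$grads)
  grads <- b1$grads
  dp <- b1$dx                            # grad wrt pooled output of level d
  for (i in rev(seq_len(d))) {
    if (cfg$dual_frame) dp <- dp + dbridge[[i]]
    de <- cpp_maxpool_bw(dp, cache$pool_idx[[i]],
                         cache$e_dim[[i]][1], cache$e_dim[[i]][2]) +
      de_skip[[i]]
    e2 <- unit_bw(model, cache$enc[[i]]$u2, de, grads)
    e1 <- unit_bw(model, cache$enc[[i]]$u1, e2$dx, e2$grads, need_dx = i > 1)
    grads <- e1$grads
    if (i > 1) dp <- e1$dx
  }
  grads
}

# update BN running statistics from a training-mode forward cache
update_running_stats <- function(model, cache) {
  mom <- model$bn_momentum
  upd <- function(cc) {
    if (!is.null(cc$bn) && cc$bn$training) {
      nm <- cc$name
      model$params[[paste0(nm, ".rmean")]] <<-
        mom * model$params[[paste0(nm, ".rmean")]] + (1 - mom) * cc$bn$mu
      model$params[[paste0(nm, ".rvar")]] <<-
        mom * model$params[[paste0(nm, ".rvar")]] + (1 - mom) * cc$bn$v
    }
  }
  for (i in seq_along(cache$enc)) { upd(cache$enc[[i]]$u1); upd(cache$enc[[i]]$u2) }
  upd(cache$bot$u1); upd(cache$bot$u2)
  for (i in seq_along(cache$dec)) { upd(cache$dec[[i]]$u1); upd(cache$dec[[i]]$u2) }
  model
}

# coerce matrix / 3-d array / list of matrices to an [H,W,1,N] tensor
as_batch <- function(x) {
  if (is.list(x) && !is.array(x)) {
    n <- length(x)
    h <- nrow(x[[1]]); w <- ncol(x[[1]])
    out <- array(0, c(h, w, 1, n))
    for (i in seq_len(n)) out[, , 1, i] <- x[[i]]
    return(out)
  }
  if (is.matrix(x)) return(array(x, c(dim(x), 1, 1)))
  if (length(dim(x)) == 3) return(array(x, c(dim(x)[1:2], 1, dim(x)[3])))
  if (length(dim(x)) == 4) return(x)
  stop("cannot interpret input as an image batch")
}

#' Predict residual images
#'
#' Runs the model in inference mode (batch norm uses stored statistics), so
#' repeated calls on the same input are identical.
#'
#' @param model a `residual_model`.
#' @param sparse_batch a matrix (single image), a `[H,W,N]` or `[H,W,1,N]`
#'   array, or a list of matrices; spatial size must match the config.
#' @return predicted residual(s) in the same format as the input (matrix in,
#'   matrix out; otherwise a `[H,W,1,N]` array).
#' @export
predict_residual <- function(model, sparse_batch) {
  x <- as_batch(sparse_batch)
  if (dim(x)[1] != model$config$input_size ||
      dim(x)[2] != model$config$input_size)
    stop("input spatial size ", dim(x)[1], "x", dim(x)[2],
         " does not match the configured ", model$config$input_size)
  out <- unet_forward(model, x, training = FALSE)$out
  if (is.matrix(sparse_batch)) return(out[, , 1, 1])
  out
}

#' Per-layer model summary
#'
#' @param object a `residual_model`.
#' @param ... unused.
#' @export
summary.residual_model <- function(object, ...) {
  sizes <- vapply(object$params, length, numeric(1))
  df <- data.frame(tensor = names(sizes), n = as.integer(sizes),
                   row.names = NULL)
  cat(sprintf("dual_frame=%s depth=%d widths=%s bottleneck=%d\n",
              object$config$dual_frame, object$config$depth,
              paste(object$config$widths, collapse = "/"),
              object$config$bottleneck))
  print(df)
  cat("total parameters:", format(count_parameters(object), big.mark = ","),
      "\n")
  invisible(df)
}
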