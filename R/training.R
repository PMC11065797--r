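#' Training configuration
#'
#' MSE loss, Adam optimizer, exponential learning-rate decay
#' `lr_n = lr_{n-1} * exp(-decay_rate)` per epoch, early stopping on
#' validation loss, and best-validation checkpoint selection.
#'
#' @param max_epochs maximum number of epochs (study value: 30).
#' @param batch_size minibatch size (study value: 6).
#' @param lr0 initial learning rate (study value: 0.001).
#' @param decay_rate per-epoch exponential decay rate (study value: 0.1).
#' @param patience early-stopping patience in epochs without validation
#'   improvement (unstated in the emulated study; default 5).
#' @param min_delta minimum improvement counted as progress.
#' @param beta1,beta2,adam_eps Adam moment coefficients (framework
#'   defaults).
#' @param seed shuffling seed.
#' @return an object of class `train_config`.
#' @export
train_config <- function(max_epochs = 30L, batch_size = 6L, lr0 = 0.001,
                         decay_rate = 0.1, patience = 5L, min_delta = 0,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-7,
                         seed = 1L) {
  stopifnot(max_epochs >= 1, batch_size >= 1, lr0 > 0, patience >= 1)
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), lr0 = lr0,
                 decay_rate = decay_rate, patience = as.integer(patience),
                 min_delta = min_delta, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Closed form of the per-epoch exponential decay:
#' `lr = lr0 * exp(-decay_rate * epoch_index)`, with epoch 0 the first
#' epoch.
#'
#' @param epoch_index zero-based epoch index.
#' @param config a [train_config()].
#' @return learning rate.
#' @export
lr_at_epoch <- function(epoch_index, config = train_config()) {
  if (any(epoch_index < 0)) stop("epoch_index must be >= 0")
  config$lr0 * exp(-config$decay_rate * epoch_index)
}

pairs_to_tensors <- function(pairs) {
  x <- as_batch(lapply(pairs, `[[`, "sparse"))
  y <- as_batch(lapply(pairs, `[[`, "residual_label"))
  list(x = x, y = y)
}

# mean MSE loss over a set of pairs, evaluated in inference mode
eval_loss <- function(model, pairs, batch_size = 8L) {
  n <- length(pairs)
  tot <- 0
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    te <- pairs_to_tensors(pairs[b])
    out <- unet_forward(model, te$x, training = FALSE)$out
    tot <- tot + sum((out - te$y)^2) / prod(dim(te$y)[1:3])
  }
  tot / n
}

#' Train a residual model
#'
#' Minimizes MSE between predicted and true residual images with Adam,
#' shuffling per epoch, decaying the learning rate per epoch, stopping early
#' when validation loss has not improved for `patience` epochs, and
#' returning the weights of the minimum-validation-loss epoch (not the
#' last).
#'
#' @param model a freshly built (or warm) `residual_model`.
#' @param train_pairs,val_pairs lists of [make_residual_pair()] objects;
#'   subject sets should be disjoint (enforce via [split_cohort()]).
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (best-epoch weights), `history` (data frame of
#'   epoch, train_loss, val_loss, lr), `best_epoch` (1-based),
#'   `stopped_early`.
#' @export
train_model <- function(model, train_pairs, val_pairs,
                        config = train_config(), verbose = FALSE) {
  if (!length(train_pairs)) stop("empty training set")
  if (!length(val_pairs)) stop("empty validation set")
  tr_sub <- unique(vapply(train_pairs, `[[`, character(1), "subject_id"))
  va_sub <- unique(vapply(val_pairs, `[[`, character(1), "subject_id"))
  common <- intersect(tr_sub, va_sub)
  if (length(common) && !all(is.na(common)))
    stop("train and validation share subjects: ",
         paste(stats::na.omit(common), collapse = ", "))
  adam_m <- lapply(model$params, function(p) p * 0)
  adam_v <- adam_m
  step <- 0
  hist <- data.frame()
  best_val <- Inf; best_params <- model$params; best_epoch <- NA_integer_
  stopped_early <- FALSE; wait <- 0L
  n <- length(train_pairs)
  bn_names <- grep("\\.(rmean|rvar)$", names(model$params), value = TRUE)
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      lr <- lr_at_epoch(epoch - 1L, config)
      ord <- sample(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (b in batches) {
        te <- pairs_to_tensors(train_pairs[b])
        fw <- unet_forward(model, te$x, training = TRUE)
        diff <- fw$out - te$y
        loss <- sum(diff^2) / length(diff)
        if (!is.finite(loss))
          stop("NaN/Inf loss at epoch ", epoch, "; aborting (lr too high?)")
        ep_loss <- ep_loss + loss * length(b)
        model <- update_running_stats(model, fw$cache)
        grads <- unet_backward(model, fw$cache, 2 * diff / length(diff))
        step <- step + 1
        for (nm in names(grads)) {
          g <- grads[[nm]]
          adam_m[[nm]] <- config$beta1 * adam_m[[nm]] + (1 - config$beta1) * g
          adam_v[[nm]] <- config$beta2 * adam_v[[nm]] +
            (1 - config$beta2) * g^2
          mhat <- adam_m[[nm]] / (1 - config$beta1^step)
          vhat <- adam_v[[nm]] / (1 - config$beta2^step)
          model$params[[nm]] <- model$params[[nm]] -
            lr * mhat / (sqrt(vhat) + config$adam_eps)
        }
      }
      val_loss <- eval_loss(model, val_pairs)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = ep_loss / n,
                                     val_loss = val_loss, lr = lr))
      if (verbose)
        message(sprintf("epoch %d: train %.3e val %.3e lr %.3e", epoch,
                        ep_loss / n, val_loss, lr))
      if (val_loss < best_val - config$min_delta) {
        best_val <- val_loss; best_params <- model$params
        best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience && epoch < config$max_epochs) {
          stopped_early <- TRUE
          break
        }
      }
    }
  })
  model$params <- best_params
  list(model = model, history = hist, best_epoch = best_epoch,
       stopped_early = stopped_early)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train one model per view count
#'
#' Each view level gets an independently initialized model (no weight
#' sharing), trained on that level's residual pairs.
#'
#' @param train_by_view,val_by_view named lists (by view count) of residual
#'   pair lists.
#' @param model_config a [unet_config()]; the per-view model seeds are
#'   derived from its seed.
#' @param config a [train_config()].
#' @param verbose print progress.
#' @return named list (by view count) of [train_model()] results.
#' @export
train_all_views <- function(train_by_view, val_by_view,
                            model_config = unet_config_toy(),
                            config = train_config(), verbose = FALSE) {
  views <- names(train_by_view)
  if (!all(views %in% names(val_by_view)))
    stop("validation pairs missing for view level(s): ",
         paste(setdiff(views, names(val_by_view)), collapse = ", "))
  out <- lapply(views, function(v) {
    mc <- model_config
    mc$seed <- derive_seed(model_config$seed, paste0("view", v))
    tc <- config
    tc$seed <- derive_seed(config$seed, paste0("view", v))
    model <- build_model(mc)
    train_model(model, train_by_view[[v]], val_by_view[[v]], tc,
                verbose = verbose)
  })
  names(out) <- views
  out
}
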