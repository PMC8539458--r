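#' Training configuration for the segmentation network
#'
#' Bundles the optimisation protocol: dice loss with the Adam optimiser, an
#' initial learning rate that is halved after every `lr_patience` epochs
#' without improvement of the validation dice loss, and early stopping
#' after `stop_patience` epochs without improvement. The best-validation
#' weights are returned. Defaults follow the reference protocol
#' (learning rate `3e-5`, patiences 15 and 30); desk-scale experiments
#' typically raise the learning rate and cap `max_epochs` (see the package
#' vignette).
#'
#' @param lr initial learning rate.
#' @param lr_patience epochs without improvement before the learning rate
#'   is halved (the counter keeps running, so with continued stagnation the
#'   rate halves again after each further `lr_patience` epochs).
#' @param stop_patience epochs without improvement before training stops.
#' @param batch_size images per Adam step (gradients are averaged).
#' @param max_epochs hard cap on the number of epochs.
#' @param depth,base_filters network architecture, see [unet_init()].
#' @param augment an [augment_config()] describing the data augmentation
#'   regime.
#' @param seed optional integer seed for weight initialisation, shuffling
#'   and augmentation sampling.
#' @return a `train_config` object.
#' @export
train_config <- function(lr = 3e-5, lr_patience = 15L, stop_patience = 30L,
                         batch_size = 8L, max_epochs = 500L,
                         depth = 5L, base_filters = 16L,
                         augment = augment_config("none"), seed = NULL) {
  stopifnot(lr > 0, lr_patience > 0, stop_patience > 0, batch_size >= 1,
            max_epochs >= 1, inherits(augment, "augment_config"))
  structure(list(lr = lr, lr_patience = as.integer(lr_patience),
                 stop_patience = as.integer(stop_patience),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 augment = augment, seed = seed),
            class = "train_config")
}

#' Augmentation regimes
#'
#' Describes how each training image is modified, fresh, in every epoch:
#' * `"none"`: images enter training unchanged.
#' * `"size_only"`: random rescaling within `size_interval` only.
#' * `"waves"`: size augmentation plus procedurally generated fading waves
#'   (parameters drawn per image from `waves`).
#' * `"real_tiles"` / `"generated_tiles"`: size augmentation plus a
#'   full-frame artifact overlay mosaicked from tiles drawn from `tiles`
#'   (a [tile_source]); the two regimes differ only in where the source's
#'   tiles come from.
#'
#' Size augmentation is part of every overlay regime because it has proven
#' useful in combination with the more complex augmentations. Overlays are
#' applied with probability `prob` per image per epoch. Masks and trace
#' annotations are never altered by overlays; size augmentation rescales
#' them consistently.
#'
#' @param regime one of `"none"`, `"size_only"`, `"waves"`, `"real_tiles"`,
#'   `"generated_tiles"`.
#' @param size_interval `c(lower, upper)` scale factors or a
#'   [size_factor_interval()]; `NULL` disables size augmentation.
#' @param waves a [wave_intervals()] object (regime `"waves"`).
#' @param tiles a [tile_source] (tile regimes).
#' @param uncorrelated_sigma extra Gaussian noise added to tile overlays;
#'   defaults to 0 because real/generated tiles already carry pixel noise.
#' @param prob probability of applying the artifact overlay to an image.
#' @return an `augment_config` object.
#' @export
augment_config <- function(regime = c("none", "size_only", "waves",
                                      "real_tiles", "generated_tiles"),
                           size_interval = NULL, waves = NULL, tiles = NULL,
                           uncorrelated_sigma = 0, prob = 1) {
  regime <- match.arg(regime)
  if (regime == "waves" && !inherits(waves, "wave_intervals")) {
    stop("regime \"waves\" needs a wave_intervals() object")
  }
  if (regime %in% c("real_tiles", "generated_tiles") &&
      !inherits(tiles, "tile_source")) {
    stop("regime \"", regime, "\" needs a tile_source")
  }
  if (inherits(size_interval, "size_factor_interval")) {
    size_interval <- c(size_interval$lower, size_interval$upper)
  }
  structure(list(regime = regime, size_interval = size_interval,
                 waves = waves, tiles = tiles,
                 uncorrelated_sigma = uncorrelated_sigma, prob = prob),
            class = "augment_config")
}

# Apply the augmentation regime to one (image, mask) pair.
augment_image <- function(image, mask, aug) {
  if (aug$regime != "none" && !is.null(aug$size_interval)) {
    rs <- random_resize(image, mask, NULL, aug$size_interval)
    image <- rs$image; mask <- rs$mask
  }
  if (aug$prob < 1 && runif(1) > aug$prob) {
    return(list(image = image, mask = mask))
  }
  X <- ncol(image); Y <- nrow(image)
  if (aug$regime == "waves") {
    image <- clip01(compose_waves(image,
                                  sample_wave_params(aug$waves, c(X, Y))))
  } else if (aug$regime %in% c("real_tiles", "generated_tiles")) {
    overlay <- build_overlay(aug$tiles, X, Y, aug$uncorrelated_sigma)
    image <- apply_overlay(image, overlay)
  }
  list(image = image, mask = mask)
}

# -- learning-rate / early-stopping protocol --------------------------------

#' Optimisation protocol state machine
#'
#' Tracks the best validation dice loss seen so far. An epoch "improves"
#' when its validation loss is strictly below the best. The non-improvement
#' counter resets on any improvement; when it reaches a multiple of
#' `lr_patience` the learning rate is halved, and when it reaches
#' `stop_patience` the `stop` flag is raised. Factored out of the training
#' loop so the schedule can be driven and inspected directly.
#'
#' @param lr initial learning rate.
#' @param lr_patience,stop_patience see [train_config()].
#' @param best initial best loss (`Inf` unless a baseline is known).
#' @return `protocol_state()`: a state list; `protocol_update()`: the state
#'   after observing `val_loss`, with fields `lr`, `best`, `bad_epochs`,
#'   `improved` and `stop`.
#' @export
protocol_state <- function(lr, lr_patience = 15L, stop_patience = 30L,
                           best = Inf) {
  list(lr = lr, lr_patience = as.integer(lr_patience),
       stop_patience = as.integer(stop_patience), best = best,
       bad_epochs = 0L, improved = FALSE, stop = FALSE)
}

#' @rdname protocol_state
#' @param state a protocol state.
#' @param val_loss the epoch's validation dice loss.
#' @export
protocol_update <- function(state, val_loss) {
  if (val_loss < state$best) {
    state$best <- val_loss
    state$bad_epochs <- 0L
    state$improved <- TRUE
  } else {
    state$bad_epochs <- state$bad_epochs + 1L
    state$improved <- FALSE
    if (state$bad_epochs %% state$lr_patience == 0L) {
      state$lr <- state$lr / 2
    }
    if (state$bad_epochs >= state$stop_patience) {
      state$stop <- TRUE
    }
  }
  state
}

# -- training ---------------------------------------------------------------

#' Train the segmentation network
#'
#' Runs the epoch loop: every training image is augmented on the fly
#' according to the configured regime (a fresh overlay per image per
#' epoch), padded to the network stride, and contributes to batched Adam
#' steps on the dice loss. After each epoch the mean validation dice loss
#' drives the learning-rate/early-stopping protocol. The weights with the
#' best validation loss are returned.
#'
#' @param train_streams,val_streams lists of `sim_stream` objects (or lists
#'   with elements `frames` and `masks`).
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return a `trained_model`: list with `net`, `history` (data.frame of
#'   epoch, train and validation loss, learning rate), `best_val` and
#'   `config`.
#' @export
train <- function(train_streams, val_streams, config, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  train_items <- collect_items(train_streams)
  val_items <- collect_items(val_streams)
  if (length(train_items) == 0 || length(val_items) == 0) {
    stop("empty training or validation stream")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  net <- unet_init(config$depth, config$base_filters)
  opt <- adam_state(net$params)
  state <- protocol_state(config$lr, config$lr_patience, config$stop_patience)
  best_params <- net$params
  stride <- 2^(config$depth - 1L)
  history <- list()

  for (epoch in seq_len(config$max_epochs)) {
    order <- sample.int(length(train_items))
    grad_acc <- NULL
    n_acc <- 0L
    train_loss <- 0
    for (i in order) {
      item <- train_items[[i]]
      a <- augment_image(item$image, item$mask, config$augment)
      pim <- pad_to_stride(a$image, stride)
      pmk <- pad_to_stride(a$mask, stride)
      fw <- unet_forward(net, pim$x, keep_cache = TRUE)
      loss <- dice_loss(fw$soft, pmk$x)
      if (!is.finite(loss)) {
        stop("non-finite dice loss at epoch ", epoch,
             "; check input ranges and learning rate")
      }
      train_loss <- train_loss + loss
      g <- unet_backward(net, fw$cache, dice_loss_grad(fw$soft, pmk$x))
      grad_acc <- if (is.null(grad_acc)) g else params_add(grad_acc, g)
      n_acc <- n_acc + 1L
      if (n_acc == config$batch_size || i == order[length(order)]) {
        step <- adam_step(net$params, params_scale(grad_acc, 1 / n_acc),
                          opt, state$lr)
        net$params <- step$params
        opt <- step$state
        grad_acc <- NULL
        n_acc <- 0L
      }
    }
    val_loss <- mean(vapply(val_items, function(item) {
      pim <- pad_to_stride(item$image, stride)
      pmk <- pad_to_stride(item$mask, stride)
      dice_loss(unet_forward(net, pim$x)$soft, pmk$x)
    }, numeric(1)))
    state <- protocol_update(state, val_loss)
    if (state$improved) best_params <- net$params
    history[[epoch]] <- data.frame(
      epoch = epoch, train_loss = train_loss / length(train_items),
      val_loss = val_loss, lr = state$lr)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e",
                      epoch, train_loss / length(train_items), val_loss,
                      state$lr))
    }
    if (state$stop) break
  }

  net$params <- best_params
  structure(list(net = net, history = do.call(rbind, history),
                 best_val = state$best, config = config),
            class = "trained_model")
}

collect_items <- function(streams) {
  if (inherits(streams, "sim_stream")) streams <- list(streams)
  items <- list()
  for (s in streams) {
    stopifnot(!is.null(s$frames), !is.null(s$masks))
    for (t in seq_along(s$frames)) {
      items[[length(items) + 1L]] <- list(image = s$frames[[t]],
                                          mask = s$masks[[t]])
    }
  }
  items
}

# Symmetric zero padding to a multiple of `stride`; returns the padded
# matrix and the crop window of the original.
pad_to_stride <- function(x, stride) {
  Y <- nrow(x); X <- ncol(x)
  Yp <- ceiling(Y / stride) * stride
  Xp <- ceiling(X / stride) * stride
  if (Yp == Y && Xp == X) {
    return(list(x = x, rows = seq_len(Y), cols = seq_len(X)))
  }
  top <- (Yp - Y) %/% 2
  left <- (Xp - X) %/% 2
  out <- matrix(0, Yp, Xp)
  out[top + seq_len(Y), left + seq_len(X)] <- x
  list(x = out, rows = top + seq_len(Y), cols = left + seq_len(X))
}

#' Save or load a trained model
#'
#' The checkpoint holds the network weights and configuration; the training
#' history is additionally written next to it as JSON
#' (`<path>.history.json`) for easy inspection.
#'
#' @param model a `trained_model`.
#' @param path checkpoint file path.
#' @return `load_model()` returns the `trained_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(model, path)
  if (!is.null(model$history)) {
    jsonlite::write_json(model$history, paste0(path, ".history.json"),
                         dataframe = "rows", digits = NA)
  }
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "trained_model"))
  model
}

#' Predict a segmentation mask for one frame
#'
#' Runs the network forward (padding the frame symmetrically to the network
#' stride if needed, then cropping back) and thresholds the soft output.
#'
#' @param model a `trained_model` from [train()].
#' @param image numeric matrix in `[0, 1]`.
#' @param threshold binarisation threshold in `(0, 1)`.
#' @return binary matrix; with `soft = TRUE`, the soft mask instead.
#' @param soft return the soft (unthresholded) mask.
#' @export
predict_mask <- function(model, image, threshold = 0.5, soft = FALSE) {
  stopifnot(inherits(model, "trained_model"), threshold > 0, threshold < 1)
  stride <- 2^(model$net$depth - 1L)
  p <- pad_to_stride(image, stride)
  out <- unet_forward(model$net, p$x)$soft[p$rows, p$cols, drop = FALSE]
  if (soft) out else (out >= threshold) * 1L
}
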