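#' MLP architecture configuration for baseline recognition
#'
#' The default architecture maps a 60-point DO window through four fully
#' connected ReLU hidden layers of 1024, 512, 256 and 128 neurons to a
#' single linear output neuron holding the baseline estimate.
#'
#' @param input_size window length (input neurons), default 60.
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param activation hidden activation; only `"relu"` is supported.
#' @param output_size output neurons; fixed at 1.
#' @return an object of class `mlp_config`.
#' @export
mlp_config <- function(input_size = 60L,
                       hidden_sizes = c(1024L, 512L, 256L, 128L),
                       activation = "relu",
                       output_size = 1L) {
  input_size <- as.integer(input_size)
  hidden_sizes <- as.integer(hidden_sizes)
  output_size <- as.integer(output_size)
  if (input_size < 1L) stop("'input_size' must be >= 1", call. = FALSE)
  if (length(hidden_sizes) == 0L || any(hidden_sizes < 1L))
    stop("'hidden_sizes' must be a non-empty vector of positive counts",
         call. = FALSE)
  if (output_size != 1L)
    stop("'output_size' is fixed at 1 (scalar baseline)", call. = FALSE)
  activation <- match.arg(activation, "relu")
  structure(list(input_size = input_size, hidden_sizes = hidden_sizes,
                 activation = activation, output_size = output_size),
            class = "mlp_config")
}

#' Training configuration
#'
#' @param epochs maximum number of passes over the training set.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param optimizer only `"adam"` is supported.
#' @param seed integer seed for weight initialization and batch shuffling.
#' @param val_fraction fraction of the training set held out for early
#'   stopping.
#' @param patience epochs without validation-loss improvement before
#'   training stops (ignored when `val_fraction` is 0).
#' @param lr_schedule `"cosine"` (default) anneals the step size from
#'   `learning_rate` to `learning_rate / 100` over the epoch budget, which
#'   lets Adam settle into a sharp minimum; `"constant"` keeps it fixed.
#' @param weight_decay decoupled (AdamW-style) weight decay coefficient on
#'   the weight matrices (not biases); 0 disables it.
#' @param dropout probability of dropping a hidden activation during
#'   training (inverted dropout; inference is unaffected); 0 disables it.
#' @param input_jitter standard deviation (\%DO) of fresh Gaussian noise
#'   added to the window values of every minibatch. Emulates sensor noise
#'   as a training-time augmentation and regularizes the fit; 0 disables
#'   it. Validation and evaluation always see the unperturbed data.
#' @param level_shift maximum absolute vertical shift (\%DO) applied per
#'   minibatch sample to a window *and* its label (uniform draw). A
#'   baseline estimator is equivariant under vertical translation, so this
#'   augmentation is exact; 0 disables it.
#' @param ema_decay per-step decay of an exponential moving average of the
#'   weights; when > 0 the averaged model is validated and returned
#'   (Polyak averaging). 0 disables it.
#' @return an object of class `training_config`.
#' @export
training_config <- function(epochs = 450L, batch_size = 128L,
                            learning_rate = 1e-3, optimizer = "adam",
                            seed = 1L, val_fraction = 0.05, patience = 150L,
                            lr_schedule = c("cosine", "constant"),
                            weight_decay = 1e-4, dropout = 0,
                            input_jitter = 0.3, level_shift = 5,
                            ema_decay = 0) {
  optimizer <- match.arg(optimizer, "adam")
  lr_schedule <- match.arg(lr_schedule)
  epochs <- as.integer(epochs); batch_size <- as.integer(batch_size)
  patience <- as.integer(patience)
  if (epochs < 1L || batch_size < 1L || learning_rate <= 0 || patience < 1L)
    stop("epochs, batch_size, learning_rate and patience must be positive",
         call. = FALSE)
  if (val_fraction < 0 || val_fraction >= 1)
    stop("'val_fraction' must lie in [0, 1)", call. = FALSE)
  if (weight_decay < 0 || dropout < 0 || dropout >= 1 || input_jitter < 0)
    stop("'weight_decay' and 'input_jitter' must be >= 0 and 'dropout' in [0, 1)",
         call. = FALSE)
  if (level_shift < 0 || ema_decay < 0 || ema_decay >= 1)
    stop("'level_shift' must be >= 0 and 'ema_decay' in [0, 1)",
         call. = FALSE)
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed), val_fraction = val_fraction,
                 patience = patience, lr_schedule = lr_schedule,
                 weight_decay = weight_decay, dropout = dropout,
                 input_jitter = input_jitter, level_shift = level_shift,
                 ema_decay = ema_decay),
            class = "training_config")
}

#' Build an (untrained) baseline-recognition MLP
#'
#' Allocates weight matrices and bias vectors with seeded He-normal
#' initialization (weights ~ N(0, 2/fan_in), biases 0). Inputs and the label
#' are normalized by a fixed physical scale of 100 \%DO rather than by
#' per-dataset extremes, so deployment windows keep their absolute level.
#'
#' @param config an [mlp_config()].
#' @param seed integer initialization seed.
#' @return an object of class `baseline_mlp`.
#' @export
build_model <- function(config = mlp_config(), seed = 1L) {
  stopifnot(inherits(config, "mlp_config"))
  sizes <- c(config$input_size, config$hidden_sizes, config$output_size)
  set.seed(as.integer(seed))
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    fan_in <- sizes[l]
    W[[l]] <- matrix(stats::rnorm(fan_in * sizes[l + 1L], 0,
                                  sqrt(2 / fan_in)),
                     fan_in, sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  structure(list(W = W, b = b, config = config,
                 normalization = list(x_scale = 100, y_scale = 100),
                 training_meta = list(trained = FALSE, init_seed = seed)),
            class = "baseline_mlp")
}

#' @export
print.baseline_mlp <- function(x, ...) {
  sizes <- c(x$config$input_size, x$config$hidden_sizes, x$config$output_size)
  cat("<baseline_mlp> ", paste(sizes, collapse = " -> "),
      if (isTRUE(x$training_meta$trained)) " (trained)" else " (untrained)",
      "\n", sep = "")
  invisible(x)
}

# Forward pass on normalized inputs. Returns predictions and, if keep = TRUE,
# the pre-activations and activations needed for backpropagation.
mlp_forward <- function(model, xn, keep = FALSE) {
  L <- length(model$W)
  a <- xn
  acts <- if (keep) vector("list", L) else NULL
  zs <- if (keep) vector("list", L) else NULL
  for (l in seq_len(L)) {
    if (keep) acts[[l]] <- a
    z <- a %*% model$W[[l]]
    z <- z + rep(model$b[[l]], each = nrow(z))
    if (l < L) {
      a <- z * (z > 0)
      if (keep) zs[[l]] <- z
    } else {
      a <- z
    }
  }
  if (keep) list(pred = a, acts = acts, zs = zs) else a
}

#' Train the baseline-recognition MLP
#'
#' Minibatch gradient descent with the Adam optimizer on a mean-squared-error
#' loss, computed on the normalized (\%DO / 100) scale. A fraction of the
#' training windows is held out for early stopping: training stops when the
#' validation loss has not improved for `patience` epochs and the best
#' weights seen are restored.
#'
#' @param model a `baseline_mlp` from [build_model()].
#' @param data a `do_dataset` (or list with `x` matrix and `y` vector).
#' @param cfg a [training_config()].
#' @param verbose print per-epoch losses.
#' @param backend `"fast"` (default) runs the optimization loop in compiled
#'   single-precision code; `"reference"` is the plain-R double-precision
#'   implementation of the same algorithm, kept as an independent check.
#'   Both are deterministic in `cfg$seed`, but their shuffling streams (and
#'   hence exact weights) differ.
#' @return the trained `baseline_mlp`; `training_meta` records the seed,
#'   epochs run, loss history and final losses.
#' @export
train_baseline_model <- function(model, data, cfg = training_config(),
                                 verbose = FALSE,
                                 backend = c("fast", "reference")) {
  backend <- match.arg(backend)
  stopifnot(inherits(model, "baseline_mlp"), inherits(cfg, "training_config"))
  x <- data$x; y <- as.numeric(data$y)
  if (is.null(dim(x)) || nrow(x) == 0L)
    stop("training data must contain at least one window", call. = FALSE)
  if (ncol(x) != model$config$input_size)
    stop("window length ", ncol(x), " does not match model input size ",
         model$config$input_size, call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("training data must be finite", call. = FALSE)
  xn <- x / model$normalization$x_scale
  yn <- y / model$normalization$y_scale
  n <- nrow(xn)
  set.seed(cfg$seed)
  n_val <- floor(cfg$val_fraction * n)
  use_val <- n_val >= 1L
  if (use_val) {
    vidx <- sample.int(n, n_val)
    xv <- xn[vidx, , drop = FALSE]; yv <- yn[vidx]
    xn <- xn[-vidx, , drop = FALSE]; yn <- yn[-vidx]
    n <- nrow(xn)
  }
  if (backend == "fast") {
    res <- .cpp_train_mlp(model$W, model$b, xn, yn,
                          if (use_val) xv else matrix(0, 0, ncol(xn)),
                          if (use_val) yv else numeric(0),
                          cfg$epochs, cfg$batch_size, cfg$learning_rate,
                          cfg$lr_schedule == "cosine", 0.01,
                          cfg$patience, use_val, cfg$seed,
                          cfg$weight_decay, cfg$dropout,
                          cfg$input_jitter / model$normalization$x_scale,
                          cfg$level_shift / model$normalization$x_scale,
                          cfg$ema_decay)
    model$W <- res$W
    model$b <- lapply(res$b, as.numeric)
    history <- res$history
    val_history <- res$val_history
    if (verbose && length(history) > 0)
      message(sprintf("epochs %d  final train %.3e  best val %.3e",
                      res$epochs_run, history[length(history)],
                      if (use_val) res$best_val else NA))
    model$training_meta <- list(trained = TRUE,
                                init_seed = model$training_meta$init_seed,
                                seed = cfg$seed,
                                epochs_run = res$epochs_run,
                                final_train_loss = history[length(history)],
                                best_val_loss = if (use_val) res$best_val
                                                else NA,
                                loss_history = history,
                                val_history = val_history,
                                backend = backend,
                                config = unclass(cfg))
    return(model)
  }
  if (cfg$dropout > 0 || cfg$input_jitter > 0 || cfg$level_shift > 0 ||
      cfg$ema_decay > 0)
    stop("the reference backend implements only the core algorithm ",
         "(no dropout/jitter/shift/EMA); use backend = \"fast\"",
         call. = FALSE)
  L <- length(model$W)
  mW <- lapply(model$W, function(w) w * 0); vW <- mW
  mb <- lapply(model$b, function(bb) bb * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  best_val <- Inf; best_W <- model$W; best_b <- model$b; stale <- 0L
  history <- numeric(0); val_history <- numeric(0)
  epochs_run <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    lr <- if (cfg$lr_schedule == "cosine") {
      frac <- (epoch - 1) / max(cfg$epochs - 1, 1)
      lr_min <- cfg$learning_rate / 100
      lr_min + (cfg$learning_rate - lr_min) * (1 + cos(pi * frac)) / 2
    } else {
      cfg$learning_rate
    }
    perm <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
      xb <- xn[idx, , drop = FALSE]; yb <- yn[idx]
      B <- nrow(xb)
      fw <- mlp_forward(model, xb, keep = TRUE)
      resid <- fw$pred - yb
      loss <- sum(resid^2) / B
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; reduce the learning rate", call. = FALSE)
      ep_loss <- ep_loss + loss * B
      dz <- 2 * resid / B
      step <- step + 1L
      corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
      for (l in L:1) {
        gW <- crossprod(fw$acts[[l]], dz)
        gb <- colSums(dz)
        if (l > 1L) {
          da <- tcrossprod(dz, model$W[[l]])
          dz <- da * (fw$zs[[l - 1L]] > 0)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW * gW
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb * gb
        if (cfg$weight_decay > 0)
          model$W[[l]] <- model$W[[l]] * (1 - lr * cfg$weight_decay)
        model$W[[l]] <- model$W[[l]] -
          lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
        model$b[[l]] <- model$b[[l]] -
          lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
      }
    }
    epochs_run <- epoch
    history <- c(history, ep_loss / n)
    if (use_val) {
      pv <- mlp_forward(model, xv)
      vloss <- mean((pv - yv)^2)
      val_history <- c(val_history, vloss)
      if (verbose)
        message(sprintf("epoch %3d  train %.3e  val %.3e", epoch,
                        history[epoch], vloss))
      if (vloss < best_val - 1e-12) {
        best_val <- vloss; best_W <- model$W; best_b <- model$b; stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= cfg$patience) break
      }
    } else if (verbose) {
      message(sprintf("epoch %3d  train %.3e", epoch, history[epoch]))
    }
  }
  if (use_val) {
    model$W <- best_W; model$b <- best_b
  }
  model$training_meta <- list(trained = TRUE,
                              init_seed = model$training_meta$init_seed,
                              seed = cfg$seed, epochs_run = epochs_run,
                              final_train_loss = history[length(history)],
                              best_val_loss = if (use_val) best_val else NA,
                              loss_history = history,
                              val_history = val_history,
                              backend = backend,
                              config = unclass(cfg))
  model
}

#' Predict the DO baseline from a 60-point window
#'
#' Stateless inference: normalization is applied and inverted internally.
#'
#' @param model a `baseline_mlp`.
#' @param window a numeric vector of `input_size` finite DO readings, or a
#'   matrix with one window per row for batch prediction.
#' @return a numeric scalar (or vector for batch input) in \% air saturation.
#' @export
predict_baseline <- function(model, window) {
  stopifnot(inherits(model, "baseline_mlp"))
  if (is.null(dim(window))) {
    if (length(window) != model$config$input_size)
      stop("window must contain exactly ", model$config$input_size,
           " values", call. = FALSE)
    window <- matrix(as.numeric(window), 1L)
  } else {
    window <- as.matrix(window)
    if (ncol(window) != model$config$input_size)
      stop("windows must have ", model$config$input_size, " columns",
           call. = FALSE)
  }
  if (any(!is.finite(window)))
    stop("window values must be finite", call. = FALSE)
  pred <- mlp_forward(model, window / model$normalization$x_scale)
  as.numeric(pred) * model$normalization$y_scale
}

#' Regression metrics: MSE and coefficient of determination
#'
#' `mse = mean((y - pred)^2)`; `r2 = 1 - SS_res / SS_tot` with `SS_tot`
#' centered on the mean of `y`. With zero-variance `y` the `r2` is `NA` and
#' the result is flagged, rather than returning a silent `NaN`.
#'
#' @param y observed values.
#' @param pred predicted values, same length.
#' @return a list of class `eval_metrics`: `r2`, `mse`, `n`,
#'   `zero_variance_labels`.
#' @export
regression_metrics <- function(y, pred) {
  y <- as.numeric(y); pred <- as.numeric(pred)
  if (length(y) == 0L || length(y) != length(pred))
    stop("'y' and 'pred' must be non-empty and of equal length",
         call. = FALSE)
  mse <- mean((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  zero_var <- ss_tot == 0
  r2 <- if (zero_var) NA_real_ else 1 - sum((y - pred)^2) / ss_tot
  structure(list(r2 = r2, mse = mse, n = length(y),
                 zero_variance_labels = zero_var),
            class = "eval_metrics")
}

#' Evaluate a model on a labeled dataset
#'
#' Predicts every window and computes [regression_metrics()] on the raw
#' \%DO scale (the normalized-scale training loss times `y_scale^2`).
#'
#' @param model a trained `baseline_mlp`.
#' @param ds a `do_dataset` (or list with `x` and `y`).
#' @return a list of class `eval_metrics`: `r2`, `mse`, `n`,
#'   `zero_variance_labels`.
#' @export
evaluate_model <- function(model, ds) {
  if (is.null(dim(ds$x)) || nrow(ds$x) == 0L)
    stop("dataset must be non-empty", call. = FALSE)
  regression_metrics(as.numeric(ds$y), predict_baseline(model, ds$x))
}

#' Run the standard baseline-recognition protocol
#'
#' The end-to-end training protocol: generate `n` synthetic windows with the
#' default generator parameters, split 1:1, train the
#' 60-1024-512-256-128-1 ReLU network with Adam on an MSE loss, and
#' evaluate both halves. All randomness derives from `seed`.
#'
#' @param seed integer master seed (dataset, split, initialization,
#'   shuffling).
#' @param n number of synthetic windows (default 15000).
#' @param gen_params a [do_gen_params()].
#' @param model_config an [mlp_config()].
#' @param train_config a [training_config()]; its seed is overridden by
#'   `seed`.
#' @param ratio training fraction for the split (default 0.5).
#' @return list with `model`, `train_metrics`, `test_metrics`, `seed`.
#' @export
run_standard_protocol <- function(seed = 1L, n = 15000L,
                                  gen_params = do_gen_params(),
                                  model_config = mlp_config(),
                                  train_config = training_config(),
                                  ratio = 0.5) {
  seed <- as.integer(seed)
  ds <- generate_dataset(n, gen_params, seed = seed)
  sp <- split_dataset(ds, ratio = ratio, seed = seed)
  train_config$seed <- seed
  model <- build_model(model_config, seed = seed)
  model <- train_baseline_model(model, sp$train, train_config)
  list(model = model,
       train_metrics = evaluate_model(model, sp$train),
       test_metrics = evaluate_model(model, sp$test),
       seed = seed)
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("<eval_metrics> n = %d  R^2 = %s  MSE = %.4f (%%DO^2)\n",
              x$n, if (is.na(x$r2)) "NA (zero-variance labels)"
                   else sprintf("%.4f", x$r2), x$mse))
  invisible(x)
}

MODEL_FORMAT <- "neurostat_baseline_mlp"
MODEL_VERSION <- 1L

#' Save / load a trained model
#'
#' The checkpoint is a single-file archive embedding the architecture
#' configuration, all weights, and the normalization constants, so a loaded
#' model reproduces predictions bit for bit. Files that are not a checkpoint
#' of the expected format/version produce an explicit error.
#'
#' @param model a `baseline_mlp`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `baseline_mlp`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "baseline_mlp"))
  saveRDS(list(format = MODEL_FORMAT, version = MODEL_VERSION,
               model = unclass(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("not a readable model checkpoint: ",
                                           path, " (", conditionMessage(e),
                                           ")", call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT))
    stop("file is not a ", MODEL_FORMAT, " checkpoint: ", path, call. = FALSE)
  if (!identical(as.integer(obj$version), MODEL_VERSION))
    stop("checkpoint version ", obj$version, " not supported (expected ",
         MODEL_VERSION, ")", call. = FALSE)
  m <- obj$model
  if (is.null(m$W) || is.null(m$b) || is.null(m$normalization))
    stop("checkpoint is incomplete: ", path, call. = FALSE)
  class(m$config) <- "mlp_config"
  structure(m, class = "baseline_mlp")
}
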