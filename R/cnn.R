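#' Interpolator network configuration
#'
#' One convolutional regression network per spiral direction, mapping a
#' linearly interleaved (2m - 1) x n_samples pattern to the dense noise-free
#' pattern of the same size.  All layers are same-padded 2D convolutions;
#' hidden layers use ReLU with identity skip connections every `skip_period`
#' layers, and the linear output layer carries a global skip from the input,
#' so the untrained (zero output layer) network reproduces its input.
#'
#' Device-scale defaults: 7 x 77 kernels (sensor x time), 64 filters, shared
#' across the three directions; 8 conv layers.
#'
#' @param direction spiral direction this model serves (1, 2 or 3).
#' @param input_rows pattern rows (2m - 1): 27 / 45 / 75 for the device.
#' @param n_samples time samples (device: 1792).
#' @param kernel kernel size, c(rows, samples); both odd.
#' @param n_filters filters per hidden layer.
#' @param n_conv_layers total conv layers including the output layer.
#' @param skip_period hidden-layer skip spacing (0 disables hidden skips).
#' @return a `cnn_config`.
#' @export
cnn_config <- function(direction, input_rows, n_samples = 1792L,
                       kernel = c(7L, 77L), n_filters = 64L,
                       n_conv_layers = 8L, skip_period = 2L) {
  kernel <- as.integer(kernel)
  if (any(kernel %% 2L == 0L)) stop("kernel sizes must be odd")
  if (n_conv_layers < 2L) stop("need at least 2 conv layers")
  structure(list(direction = as.integer(direction),
                 input_rows = as.integer(input_rows),
                 n_samples = as.integer(n_samples),
                 kernel = kernel, n_filters = as.integer(n_filters),
                 n_conv_layers = as.integer(n_conv_layers),
                 skip_period = as.integer(skip_period)),
            class = "cnn_config")
}

cfg_args <- function(cfg) {
  list(H = cfg$input_rows, W = cfg$n_samples, kh = cfg$kernel[1],
       kw = cfg$kernel[2], F = cfg$n_filters, L = cfg$n_conv_layers,
       skip = cfg$skip_period)
}

#' Number of trainable parameters
#' @param cfg a [cnn_config()].
#' @return parameter count.
#' @export
cnn_n_params <- function(cfg) {
  a <- cfg_args(cfg)
  cnn_n_params_cpp(a$H, a$W, a$kh, a$kw, a$F, a$L, a$skip)
}

#' Build an interpolator network
#'
#' He-normal initialization of all hidden layers (seeded, deterministic); the
#' output layer is zero-initialized so that, through the global input skip,
#' the fresh model is exactly the identity on its input.
#'
#' @param cfg a [cnn_config()].
#' @param seed integer seed for the weight initialization.
#' @return a `cnn_model`: `cfg`, flat parameter vector `par`, `seed`,
#'   `normalization` (set at training time), `loss_history`.
#' @export
build_cnn <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "cnn_config"))
  a <- cfg_args(cfg)
  par <- with_seed(seed, {
    p <- numeric(cnn_n_params(cfg))
    off <- 0L
    for (l in seq_len(a$L)) {
      cin <- if (l == 1L) 1L else a$F
      cout <- if (l == a$L) 1L else a$F
      nw <- a$kh * a$kw * cin * cout
      if (l < a$L) {
        fan_in <- a$kh * a$kw * cin
        p[off + seq_len(nw)] <- rnorm(nw, sd = sqrt(2 / fan_in))
      }                                    # output layer stays zero
      off <- off + nw + cout               # biases stay zero
    }
    p
  })
  structure(list(cfg = cfg, par = par, seed = as.integer(seed),
                 normalization = 1.0, loss_history = numeric(0)),
            class = "cnn_model")
}

#' Forward pass of the interpolator
#'
#' @param model a `cnn_model`.
#' @param x numeric matrix (input_rows x n_samples) or 3D array
#'   (batch x rows x samples), already normalized.
#' @return object of the same shape as `x`.
#' @export
cnn_forward <- function(model, x) {
  a <- cfg_args(model$cfg)
  one <- is.matrix(x)
  if (one) x <- array(x, dim = c(1, dim(x)))
  if (!all(dim(x)[2:3] == c(a$H, a$W)))
    stop("input shape ", paste(dim(x)[2:3], collapse = "x"),
         " does not match model (", a$H, "x", a$W, ")")
  y <- cnn_forward_cpp(model$par, as.numeric(x), dim(x)[1],
                       a$H, a$W, a$kh, a$kw, a$F, a$L, a$skip)
  y <- array(y, dim = dim(x))
  if (one) y[1, , ] else y
}

#' Apply the interpolator to an interleaved pattern
#'
#' Normalizes by the model's training normalization constant, runs the
#' forward pass, and de-normalizes back to signal units.
#'
#' @param model a trained `cnn_model`.
#' @param interleaved an `interleaved_pattern`.
#' @return an `interleaved_pattern` of identical shape.
#' @export
cnn_predict <- function(model, interleaved) {
  stopifnot(inherits(interleaved, "interleaved_pattern"))
  v <- interleaved$values
  a <- cfg_args(model$cfg)
  if (!all(dim(v) == c(a$H, a$W)))
    stop("pattern shape ", paste(dim(v), collapse = "x"),
         " does not match model for direction ", model$cfg$direction,
         " (", a$H, "x", a$W, ")")
  out <- cnn_forward(model, v / model$normalization) * model$normalization
  if (any(!is.finite(out))) stop("non-finite interpolator output")
  structure(list(values = out, chain_ref = interleaved$chain_ref,
                 row_kind = "interleaved"),
            class = "interleaved_pattern")
}

#' Training configuration
#'
#' Resilient backpropagation (iRprop-) on mean squared error.  Device-scale
#' defaults: initial step = learning rate 1e-5, 50 epochs, mini-batch 50 /
#' 100 / 150 for directions 1 / 2 / 3.  Full-scale training (1000 phantoms,
#' about a month of GPU time in the original study) is representable but not
#' run here; `scale = "reduced"` marks desk-scale runs.
#'
#' @param learning_rate initial Rprop step size.
#' @param epochs training epochs.
#' @param batch_size mini-batch size (device defaults per direction:
#'   50/100/150).
#' @param seed shuffling seed.
#' @param scale `"full"` or `"reduced"`.
#' @param eta_plus,eta_minus,step_max,step_min Rprop step adaptation
#'   constants (standard values).
#' @return a `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, epochs = 50L,
                         batch_size = 50L, seed = 1L,
                         scale = c("full", "reduced"),
                         eta_plus = 1.2, eta_minus = 0.5,
                         step_max = 50, step_min = 1e-12) {
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 scale = match.arg(scale), eta_plus = eta_plus,
                 eta_minus = eta_minus, step_max = step_max,
                 step_min = step_min, loss = "mse", solver = "iRprop-"),
            class = "train_config")
}

#' Device mini-batch size for a direction
#' @param direction 1, 2 or 3.
#' @return integer batch size (50, 100 or 150).
#' @export
device_batch_size <- function(direction) c(50L, 100L, 150L)[direction]

#' Assemble a training set for one direction
#'
#' For each phantom: simulate ideal broadband signals at all real and virtual
#' sensors, band-limit them, add calibrated noise to the real-sensor rows,
#' and emit one sample per chain of the direction — input = linear interleave
#' of the noisy real pattern, target = noise-free band-limited pattern with
#' the true virtual rows in place.  Both are divided by the global
#' normalization constant (the reference amplitude), so a p0 = 100 absorber
#' maps to O(1) values.
#'
#' @param n_phantoms number of random phantoms.
#' @param direction spiral direction.
#' @param geometry a `pa_geometry`.
#' @param time a [time_axis()].
#' @param resp a [sensor_response()].
#' @param snr_db noise level for the inputs (default 30 dB).
#' @param c sound speed, m/s.
#' @param seed root seed; phantom i uses seed + i, noise uses a derived seed.
#' @param spec a [phantom_spec()] for the random phantoms.
#' @return a `training_set`: arrays `inputs`, `targets`
#'   (n x rows x samples), `normalization`, `phantom_of` (sample -> phantom
#'   index, for leakage-free splits).
#' @export
make_training_set <- function(n_phantoms, direction, geometry, time, resp,
                              snr_db = 30, c = 1500, seed = 1L,
                              spec = phantom_spec()) {
  stopifnot(n_phantoms >= 1)
  chains <- geometry$chains[[direction]]
  m <- length(chains[[1]]$member_indices)
  rows <- 2L * m - 1L
  norm <- reference_amplitude(resp, time, c, geometry$config$R)
  n_chain <- length(chains)
  n <- n_phantoms * n_chain
  inputs <- array(0, dim = c(n, rows, time$n_samples))
  targets <- array(0, dim = c(n, rows, time$n_samples))
  phantom_of <- integer(n)
  k <- 0L
  for (ph in seq_len(n_phantoms)) {
    phantom <- random_training_phantom(seed + ph, spec)
    ideal <- simulate_signals(phantom, geometry$coords, time, c,
                              sensor_ids = geometry$ids)
    ideal_bl <- apply_sensor_bandwidth(ideal, resp)
    real_ids <- paste0("r", geometry$array$indices)
    real_bl <- subset_signals(ideal_bl, real_ids)
    noisy <- add_noise(real_bl,
                       noise_spec(snr_db, rng_seed = seed * 1000L + ph),
                       resp, R = geometry$config$R, c = c)
    for (ch in chains) {
      k <- k + 1L
      ip_in <- interleave_linear(extract_pattern(ch, noisy))
      inputs[k, , ] <- ip_in$values / norm
      targets[k, , ] <- ideal_interleaved(ch, ideal_bl, geometry)$values / norm
      phantom_of[k] <- ph
    }
  }
  structure(list(inputs = inputs, targets = targets, normalization = norm,
                 direction = as.integer(direction), phantom_of = phantom_of),
            class = "training_set")
}

#' Ideal interleaved pattern of a chain
#'
#' Builds the ground-truth interleaved pattern from a dense (real + virtual)
#' signal set: odd rows are the chain's real-sensor traces, even rows the
#' simulated traces at the chain's virtual-sensor positions.
#'
#' @param chain a `spiral_chain`.
#' @param dense a `signal_set` over real and virtual sensors.
#' @param geometry the `pa_geometry`.
#' @return an `interleaved_pattern`.
#' @export
ideal_interleaved <- function(chain, dense, geometry) {
  m <- length(chain$member_indices)
  out <- matrix(0, 2 * m - 1, dense$time$n_samples)
  out[seq(1, 2 * m - 1, 2), ] <-
    subset_signals(dense, paste0("r", chain$member_indices))$values
  vids <- sprintf("v%d.%d.%d", chain$direction, chain$residue, seq_len(m - 1))
  out[seq(2, 2 * m - 2, 2), ] <- subset_signals(dense, vids)$values
  structure(list(values = out,
                 chain_ref = c(direction = chain$direction,
                               residue = chain$residue),
                 row_kind = "interleaved"),
            class = "interleaved_pattern")
}

#' Train an interpolator network
#'
#' Mini-batch iRprop- on mean squared error.  Deterministic given the
#' configuration seed.  Aborts with a diagnostic if the loss diverges.
#'
#' @param model a `cnn_model` from [build_cnn()].
#' @param ts a `training_set`.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch loss.
#' @return the trained `cnn_model` with `loss_history` (one mean loss per
#'   epoch) and `normalization` copied from the training set.
#' @export
train_cnn <- function(model, ts, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"), inherits(ts, "training_set"))
  a <- cfg_args(model$cfg)
  n <- dim(ts$inputs)[1]
  if (n < 1) stop("empty training set")
  if (!all(dim(ts$inputs)[2:3] == c(a$H, a$W)))
    stop("training set shape does not match model")
  par <- model$par
  step <- rep(cfg$learning_rate, length(par))
  prev_sign <- numeric(length(par))
  history <- numeric(cfg$epochs)
  x <- as.numeric(ts$inputs)
  y <- as.numeric(ts$targets)
  dim(x) <- dim(ts$inputs); dim(y) <- dim(ts$targets)
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(cfg$seed * 10000L + ep, sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (b in batches) {
      xb <- x[b, , , drop = FALSE]
      yb <- y[b, , , drop = FALSE]
      lg <- cnn_loss_grad_cpp(par, as.numeric(xb), as.numeric(yb),
                              length(b), a$H, a$W, a$kh, a$kw, a$F, a$L,
                              a$skip)
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      g <- lg$grad
      s <- sign(g)
      agree <- s * prev_sign
      step <- ifelse(agree > 0, pmin(step * cfg$eta_plus, cfg$step_max),
                     ifelse(agree < 0, pmax(step * cfg$eta_minus,
                                            cfg$step_min), step))
      s[agree < 0] <- 0            # iRprop-: skip update after a sign flip
      par <- par - s * step
      prev_sign <- s
      ep_loss <- ep_loss + lg$loss * length(b)
    }
    history[ep] <- ep_loss / n
    if (verbose)
      message(sprintf("epoch %3d  mse %.6g", ep, history[ep]))
  }
  model$par <- par
  model$loss_history <- c(model$loss_history, history)
  model$normalization <- ts$normalization
  model
}
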