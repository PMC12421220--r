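#' Encoder network configuration
#'
#' Architecture of the self-supervised encoder: an input layer of width
#' `n_inputs` (the number of acquired signals per voxel), `n_hidden_layers`
#' fully connected hidden layers of width `hidden_width` (defaulting to the
#' input width) with ELU activations, and a linear output layer of width
#' `n_outputs` (the number of model parameters, 4 for IVIM). Raw outputs are
#' mapped into the physiological parameter ranges by a scaled sigmoid (see
#' [build_network()]).
#'
#' @param n_inputs Number of measurements per voxel (Nz).
#' @param n_hidden_layers Number of hidden layers (default 3).
#' @param hidden_width Nodes per hidden layer (default `n_inputs`).
#' @param n_outputs Number of model parameters (default 4).
#' @return A `network_config` list.
#' @export
network_config <- function(n_inputs, n_hidden_layers = 3L,
                           hidden_width = n_inputs, n_outputs = 4L) {
  stopifnot(n_inputs >= 1, n_hidden_layers >= 1, hidden_width >= 1,
            n_outputs >= 1)
  structure(list(n_inputs = as.integer(n_inputs),
                 n_hidden_layers = as.integer(n_hidden_layers),
                 hidden_width = as.integer(hidden_width),
                 n_outputs = as.integer(n_outputs),
                 activation = "elu",
                 output_transform = "scaled_sigmoid"),
            class = "network_config")
}

#' Training configuration
#'
#' Optimisation settings for self-supervised training: Adam with the
#' standard defaults (learning rate 0.001, betas (0.9, 0.999), no weight
#' decay), batches of 256 voxels reshuffled every epoch from the seeded
#' stream (last partial batch kept), at most `max_epochs` epochs, stopping
#' early when the validation loss sets no new strict minimum for `patience`
#' consecutive epochs (final weights are kept). `sigma` is required for the
#' NLR loss; `sigma_scale` mis-scales it to study noise-level
#' mis-estimation.
#'
#' @param loss `"NLR"` or `"MSE"`.
#' @param sigma Noise standard deviation (scalar or [noise_spec()]);
#'   required when `loss = "NLR"`.
#' @param batch_size Voxels per gradient step (default 256).
#' @param max_epochs Maximum epochs (default 300).
#' @param patience Early-stopping patience in epochs (default 50).
#' @param learning_rate Adam step size (default 0.001).
#' @param betas Adam moment decays (default c(0.9, 0.999)).
#' @param weight_decay L2 penalty coefficient (default 0).
#' @param init_repetitions Training repetitions used by
#'   [common_initialisation()] (default 16).
#' @param sigma_scale Multiplier on sigma inside the NLR loss (default 1).
#' @param seed Integer seed controlling initialisation and batch order.
#' @return A `training_config` list.
#' @export
training_config <- function(loss = c("NLR", "MSE"), sigma = NULL,
                            batch_size = 256L, max_epochs = 300L,
                            patience = 50L, learning_rate = 0.001,
                            betas = c(0.9, 0.999), weight_decay = 0,
                            init_repetitions = 16L, sigma_scale = 1,
                            seed = 1L) {
  loss <- match.arg(loss)
  if (loss == "NLR") {
    if (is.null(sigma))
      stop("sigma must be supplied when loss = \"NLR\"")
    sigma <- resolve_sigma(sigma)
  }
  stopifnot(batch_size >= 1, max_epochs >= 1, patience <= max_epochs,
            learning_rate > 0, length(betas) == 2L, weight_decay >= 0)
  structure(list(loss = loss, sigma = sigma,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate, betas = betas,
                 weight_decay = weight_decay,
                 init_repetitions = as.integer(init_repetitions),
                 sigma_scale = sigma_scale, seed = as.integer(seed)),
            class = "training_config")
}

# Training-grid ranges widened by `frac` of the width on each side give the
# network room to express estimates at the grid edges; lower bounds that
# would cross zero for the strictly positive parameters are floored.
widen_ranges <- function(ranges, frac = 0.1) {
  positive <- c("Dt", "Dp", "S0")
  out <- lapply(names(ranges), function(nm) {
    r <- ranges[[nm]]
    w <- diff(r) * frac
    lo <- r[1] - w
    hi <- r[2] + w
    if (nm %in% positive) lo <- max(lo, 1e-6)
    if (nm == "f") {
      lo <- max(lo, 0)
      hi <- min(hi, 1)
    }
    c(lo, hi)
  })
  names(out) <- names(ranges)
  out
}

# Output-transform specification: a sigmoid scaled to each parameter's
# widened range, acting either on the parameter directly (default) or on
# its logarithm (`log_params`; a natural option for the scale-type
# diffusivities — it stretches the representable range at the top of the
# grid, at the price of a wider multiplicative spread at the bottom).
make_transform <- function(ranges, frac, log_params = character(0)) {
  out <- lapply(names(ranges), function(nm) {
    r <- ranges[[nm]]
    if (nm %in% log_params) {
      w <- diff(log(r)) * frac
      list(kind = "log", a = log(r[1]) - w, b = log(r[2]) + w,
           bounds = exp(c(log(r[1]) - w, log(r[2]) + w)))
    } else {
      w <- diff(r) * frac
      lo <- r[1] - w
      hi <- r[2] + w
      if (nm == "f") {
        lo <- max(lo, 0)
        hi <- min(hi, 1)
      } else if (nm %in% c("Dt", "Dp", "S0")) {
        lo <- max(lo, 1e-6)  # strictly positive quantities
      }
      list(kind = "linear", a = lo, b = hi, bounds = c(lo, hi))
    }
  })
  names(out) <- names(ranges)
  out
}

elu <- function(x) pmax(x, 0) + expm1(pmin(x, 0))
elu_grad_from_act <- function(a) 1 + pmin(a, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Build a self-supervised IVIM network
#'
#' Constructs the encoder (fully connected, ELU activations) whose decoder
#' is the fixed IVIM forward model: signals in, parameter estimates out,
#' predicted signals regenerated through [ivim_signal()] under the same
#' protocol. Raw outputs pass through a sigmoid scaled to each parameter's
#' bounds (the training ranges widened 50% per side by default — wide
#' enough that the spread of estimates at the grid edges is not truncated,
#' which would otherwise bias edge-level estimates toward the interior), so
#' estimates are always valid forward-model inputs. Weights and biases are
#' initialised uniformly on (-1/sqrt(fan_in), 1/sqrt(fan_in)) from the seed.
#'
#' @param config A [network_config()]; its `n_inputs` must match the
#'   protocol.
#' @param protocol An [acquisition_protocol()].
#' @param param_ranges Named list of training ranges (default
#'   [ivim_param_ranges()]); bounds used by the output transform are these
#'   widened by `widen_frac`.
#' @param seed Integer seed for weight initialisation.
#' @param widen_frac Range-widening fraction per side (default 0.5).
#' @param log_params Optional character vector of parameters whose sigmoid
#'   acts on the log scale (multiplicative range widening); e.g.
#'   `c("Dt", "Dp")` for the diffusivities. Default: none.
#' @return An `ivim_selfsup` network object.
#' @export
build_network <- function(config, protocol,
                          param_ranges = ivim_param_ranges(), seed = 1L,
                          widen_frac = 0.5, log_params = character(0)) {
  stopifnot(inherits(config, "network_config"),
            inherits(protocol, "acquisition_protocol"))
  if (config$n_inputs != protocol$n_measurements)
    stop("config$n_inputs must equal the protocol's number of b-values")
  if (config$n_outputs != length(param_ranges))
    stop("n_outputs must equal the number of model parameters")
  sizes <- c(config$n_inputs,
             rep(config$hidden_width, config$n_hidden_layers),
             config$n_outputs)
  set.seed(as.integer(seed))
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    k <- 1 / sqrt(sizes[l])
    W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1L], -k, k),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- runif(sizes[l + 1L], -k, k)
  }
  transform <- make_transform(param_ranges, widen_frac, log_params)
  structure(list(W = W, b = b, sizes = sizes, config = config,
                 protocol = protocol, transform = transform,
                 bounds = lapply(transform, `[[`, "bounds"),
                 init_seed = as.integer(seed), trained = FALSE),
            class = "ivim_selfsup")
}

#' @export
print.ivim_selfsup <- function(x, ...) {
  cat(sprintf("<ivim_selfsup> layers %s, %d weights%s\n",
              paste(x$sizes, collapse = "-"), n_weights(x),
              if (x$trained) sprintf(", trained (%s loss, %d epochs)",
                                     x$loss, x$n_epochs) else ", untrained"))
  invisible(x)
}

#' Number of trainable parameters of a network
#' @param net An `ivim_selfsup` network.
#' @return Integer count of weights plus biases.
#' @export
n_weights <- function(net) {
  sum(vapply(net$W, length, integer(1))) +
    sum(vapply(net$b, length, integer(1)))
}

# Forward pass. Returns activations (act[[1]] is the input), pre-sigmoid
# raw outputs, parameter estimates and the forward-model jacobian cache.
net_forward <- function(net, M) {
  L <- length(net$W)
  act <- vector("list", L + 1L)
  act[[1L]] <- M
  for (l in seq_len(L - 1L))
    act[[l + 1L]] <- elu(sweep(act[[l]] %*% net$W[[l]], 2, net$b[[l]], "+"))
  z <- sweep(act[[L]] %*% net$W[[L]], 2, net$b[[L]], "+")
  s <- sigmoid(z)
  theta <- s
  nm <- names(net$transform)
  for (k in seq_along(nm)) {
    tr <- net$transform[[nm[k]]]
    theta[, k] <- if (tr$kind == "log")
      exp(tr$a + (tr$b - tr$a) * s[, k])
    else tr$a + (tr$b - tr$a) * s[, k]
  }
  colnames(theta) <- nm
  p <- as.data.frame(theta)
  jac <- ivim_signal_jacobian(p, net$protocol)
  list(act = act, s = s, theta = p, jac = jac, A = jac$A)
}

# Backward pass: G is dLoss/dA (N x Nz). Returns gradient lists gW, gb.
net_backward <- function(net, fwd, G) {
  jac <- fwd$jac
  dtheta <- cbind(rowSums(G * jac$dDt), rowSums(G * jac$dDp),
                  rowSums(G * jac$df), rowSums(G * jac$dS0))
  # chain through the output transform: d theta / d s is (b - a) for the
  # linear sigmoid and (b - a) * theta for the log-scale sigmoid
  dtheta_ds <- dtheta
  nm <- names(net$transform)
  for (k in seq_along(nm)) {
    tr <- net$transform[[nm[k]]]
    span <- tr$b - tr$a
    dtheta_ds[, k] <- if (tr$kind == "log")
      dtheta[, k] * span * fwd$theta[[nm[k]]]
    else dtheta[, k] * span
  }
  dz <- dtheta_ds * fwd$s * (1 - fwd$s)
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- dz
  for (l in L:1) {
    gW[[l]] <- crossprod(fwd$act[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L)
      delta <- (delta %*% t(net$W[[l]])) * elu_grad_from_act(fwd$act[[l]])
  }
  list(gW = gW, gb = gb)
}

# Fused loss + gradient evaluation (shares the scaled-Bessel computation).
batch_loss_grad <- function(M, A, tcfg) {
  if (tcfg$loss == "NLR") {
    sigma <- tcfg$sigma * tcfg$sigma_scale
    s2 <- sigma^2
    Ac <- pmax(A, A_FLOOR)
    x <- M * Ac / s2
    i0e <- i0e_safe(x)
    lp <- log(M / s2) - (M^2 + Ac^2) / (2 * s2) + log(i0e) + x
    ratio <- i1e_safe(x) / i0e
    list(value = mean(-rowSums(lp)),
         grad = (Ac / s2 - (M / s2) * ratio) / nrow(M))
  } else {
    list(value = mse_loss(M, A)$value, grad = mse_loss_grad(M, A))
  }
}

score_batch <- function(net, batch, tcfg) {
  A <- net_forward(net, batch$M)$A
  if (tcfg$loss == "NLR")
    nlr_loss(batch$M, A, tcfg$sigma, tcfg$sigma_scale)$value
  else mse_loss(batch$M, A)$value
}

adam_init <- function(net) {
  zl <- function(x) lapply(x, function(p) array(0, dim = dim(p) %||% length(p)))
  list(mW = zl(net$W), vW = zl(net$W), mb = zl(net$b), vb = zl(net$b),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(net, grads, state, tcfg) {
  b1 <- tcfg$betas[1]; b2 <- tcfg$betas[2]; eps <- 1e-8
  state$t <- state$t + 1L
  lr_t <- tcfg$learning_rate * sqrt(1 - b2^state$t) / (1 - b1^state$t)
  for (l in seq_along(net$W)) {
    g <- grads$gW[[l]]
    if (tcfg$weight_decay > 0) g <- g + tcfg$weight_decay * net$W[[l]]
    state$mW[[l]] <- b1 * state$mW[[l]] + (1 - b1) * g
    state$vW[[l]] <- b2 * state$vW[[l]] + (1 - b2) * g^2
    net$W[[l]] <- net$W[[l]] - lr_t * state$mW[[l]] / (sqrt(state$vW[[l]]) + eps)
    g <- grads$gb[[l]]
    state$mb[[l]] <- b1 * state$mb[[l]] + (1 - b1) * g
    state$vb[[l]] <- b2 * state$vb[[l]] + (1 - b2) * g^2
    net$b[[l]] <- net$b[[l]] - lr_t * state$mb[[l]] / (sqrt(state$vb[[l]]) + eps)
  }
  list(net = net, state = state)
}

#' Train a self-supervised network
#'
#' Stochastic gradient training of the encoder with the chosen loss (NLR or
#' MSE) against the measured signals, via backpropagation through the fixed
#' IVIM decoder and Adam updates. Batches are reshuffled each epoch from
#' the seeded stream; training stops when the validation loss (evaluated
#' once per epoch on the full validation set) sets no new strict minimum
#' for `patience` consecutive epochs, or at `max_epochs`. Final weights are
#' kept. Loss accumulation is in double precision throughout. A non-finite
#' loss or gradient aborts with a diagnostic naming the epoch and batch.
#'
#' @param net An `ivim_selfsup` from [build_network()] (possibly already
#'   trained, e.g. a [common_initialisation()] state).
#' @param data Training `signal_batch`.
#' @param val Validation `signal_batch` (may be `NULL`: no early stopping).
#' @param tcfg A [training_config()].
#' @param verbose Print per-epoch losses.
#' @return The trained network, with `history` (per-epoch train/validation
#'   loss data.frame), `loss`, `n_epochs` and `all_finite` fields attached.
#' @export
train_network <- function(net, data, val, tcfg, verbose = FALSE) {
  stopifnot(inherits(net, "ivim_selfsup"),
            inherits(data, "signal_batch"),
            inherits(tcfg, "training_config"))
  if (ncol(data$M) != net$protocol$n_measurements)
    stop("training data does not match the network protocol")
  set.seed(tcfg$seed)
  N <- nrow(data$M)
  state <- adam_init(net)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  best_val <- Inf
  stall <- 0L
  all_finite <- TRUE
  for (epoch in seq_len(tcfg$max_epochs)) {
    idx <- sample.int(N)
    starts <- seq(1L, N, by = tcfg$batch_size)
    batch_losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      rows <- idx[starts[bi]:min(starts[bi] + tcfg$batch_size - 1L, N)]
      Mb <- data$M[rows, , drop = FALSE]
      fwd <- net_forward(net, Mb)
      lg <- batch_loss_grad(Mb, fwd$A, tcfg)
      if (!is.finite(lg$value) || any(!is.finite(lg$grad))) {
        all_finite <- FALSE
        stop(sprintf(
          "non-finite %s loss/gradient at epoch %d, batch %d (sigma = %s)",
          tcfg$loss, epoch, bi,
          if (is.null(tcfg$sigma)) "NA" else format(tcfg$sigma)))
      }
      grads <- net_backward(net, fwd, lg$grad)
      if (any(vapply(grads$gW, function(g) any(!is.finite(g)), logical(1)))) {
        all_finite <- FALSE
        stop(sprintf("non-finite weight gradient at epoch %d, batch %d",
                     epoch, bi))
      }
      upd <- adam_step(net, grads, state, tcfg)
      net <- upd$net
      state <- upd$state
      batch_losses[bi] <- lg$value
    }
    # epoch training loss = running mean over batches (weighted by size)
    sizes <- diff(c(starts, N + 1L))
    train_loss <- sum(batch_losses * sizes) / N
    val_loss <- if (!is.null(val)) score_batch(net, val, tcfg) else NA_real_
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = train_loss,
                                   val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.6f  val %.6f", epoch, train_loss,
                      val_loss))
    if (!is.null(val)) {
      if (val_loss < best_val) {
        best_val <- val_loss
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tcfg$patience) break
      }
    }
  }
  net$trained <- TRUE
  net$loss <- tcfg$loss
  net$n_epochs <- nrow(hist)
  net$history <- hist
  net$all_finite <- all_finite
  # exact full-data score of the final weights (the history column holds the
  # running mean over batches, which moves during the epoch)
  net$final_train_loss <- score_batch(net, data, tcfg)
  net$final_val_loss <- if (!is.null(val)) hist$val_loss[nrow(hist)] else NA
  net$tcfg <- tcfg
  net
}

#' Full-batch quasi-Newton refinement of a network
#'
#' Deterministic L-BFGS-B optimisation of all weights and biases against the
#' full-batch loss, with gradients from backpropagation. Stochastic Adam
#' training plateaus well above machine precision on small datasets; for
#' convergence studies (e.g. verifying that training recovers the
#' generating parameters on noise-free data) this refinement drives the
#' loss orders of magnitude further down. Not intended for large training
#' sets, where full-batch curvature estimation is slow and unnecessary.
#'
#' @param net A (typically Adam-pretrained) `ivim_selfsup` network.
#' @param data Training `signal_batch`.
#' @param tcfg A [training_config()] providing the loss (and sigma).
#' @param maxit Maximum L-BFGS-B iterations (default 5000).
#' @return The refined network with `final_train_loss` updated.
#' @export
refine_network <- function(net, data, tcfg, maxit = 5000L) {
  stopifnot(inherits(net, "ivim_selfsup"), inherits(data, "signal_batch"))
  flatten <- function(n) c(unlist(n$W), unlist(n$b))
  unflatten <- function(n, v) {
    i <- 0L
    for (l in seq_along(n$W)) {
      k <- length(n$W[[l]])
      n$W[[l]][] <- v[i + seq_len(k)]
      i <- i + k
    }
    for (l in seq_along(n$b)) {
      k <- length(n$b[[l]])
      n$b[[l]] <- v[i + seq_len(k)]
      i <- i + k
    }
    n
  }
  fg <- function(v) {
    nn <- unflatten(net, v)
    fwd <- net_forward(nn, data$M)
    lg <- batch_loss_grad(data$M, fwd$A, tcfg)
    grads <- net_backward(nn, fwd, lg$grad)
    list(value = lg$value, grad = c(unlist(grads$gW), unlist(grads$gb)))
  }
  res <- stats::optim(flatten(net), fn = function(v) fg(v)$value,
                      gr = function(v) fg(v)$grad, method = "L-BFGS-B",
                      control = list(maxit = as.integer(maxit), factr = 0))
  net <- unflatten(net, res$par)
  net$trained <- TRUE
  net$loss <- tcfg$loss
  net$final_train_loss <- res$value
  net
}

#' Best-of-k common initialisation
#'
#' To remove dependence on the random initialisation when comparing loss
#' functions, `init_repetitions` networks are trained with the NLR loss
#' from different child seeds and the state with the lowest validation loss
#' is kept. Both loss variants can then be trained onward from this single
#' state, sharing it bit-exactly.
#'
#' @param config A [network_config()].
#' @param protocol An [acquisition_protocol()].
#' @param data,val Training and validation `signal_batch`es.
#' @param tcfg A [training_config()] with `loss = "NLR"`; its
#'   `init_repetitions` and `seed` control the repetitions.
#' @param param_ranges Training ranges passed to [build_network()].
#' @param init_epochs Epochs per repetition (default `tcfg$max_epochs`).
#' @param widen_frac Output-transform widening passed to [build_network()].
#' @return The trained network with the lowest validation loss, plus a
#'   `init_manifest` field recording the seeds and per-repetition losses.
#' @export
common_initialisation <- function(config, protocol, data, val, tcfg,
                                  param_ranges = ivim_param_ranges(),
                                  init_epochs = NULL, widen_frac = 0.5) {
  stopifnot(tcfg$loss == "NLR")
  seeds <- derive_seeds(tcfg$seed, tcfg$init_repetitions)
  best <- NULL
  scores <- numeric(tcfg$init_repetitions)
  for (r in seq_len(tcfg$init_repetitions)) {
    tc_r <- tcfg
    tc_r$seed <- seeds[r]
    if (!is.null(init_epochs)) tc_r$max_epochs <- as.integer(init_epochs)
    net_r <- build_network(config, protocol, param_ranges, seed = seeds[r],
                           widen_frac = widen_frac)
    net_r <- train_network(net_r, data, val, tc_r)
    scores[r] <- net_r$final_val_loss
    if (is.null(best) || net_r$final_val_loss < best$final_val_loss)
      best <- net_r
  }
  best$init_manifest <- list(seeds = seeds, val_losses = scores)
  best
}

#' Predict IVIM parameters with a trained network
#'
#' Evaluation-mode forward pass: one parameter row per voxel, each estimate
#' inside the network's configured bounds, plus the corresponding predicted
#' noise-free signals.
#'
#' @param object A trained `ivim_selfsup` network.
#' @param batch A `signal_batch` (or bare N x Nz matrix) under the same
#'   protocol.
#' @param ... Unused.
#' @return List with `params` (an [ivim_params()] table) and `signals`
#'   (N x Nz matrix of model predictions).
#' @export
predict.ivim_selfsup <- function(object, batch, ...) {
  M <- if (inherits(batch, "signal_batch")) batch$M else as.matrix(batch)
  if (nrow(M) == 0L) {
    empty <- ivim_params(1, 1, 0, 1)[0, ]
    return(list(params = empty, signals = matrix(numeric(0), 0,
                                                 object$protocol$n_measurements)))
  }
  if (ncol(M) != object$protocol$n_measurements)
    stop("signal batch does not match the network protocol (Nz differs)")
  fwd <- net_forward(object, M)
  list(params = validate_ivim_params(fwd$theta), signals = fwd$A)
}

#' Serialize a network to a JSON file
#'
#' Writes the weights and a manifest (architecture, protocol, bounds,
#' seeds, loss type, epoch count, final losses) as a single JSON document;
#' [load_network()] restores it bit-exactly within double precision.
#'
#' @param net An `ivim_selfsup` network.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  payload <- list(
    sizes = net$sizes,
    W = lapply(net$W, function(w) list(dim = dim(w), data = as.vector(w))),
    b = net$b,
    bounds = net$bounds,
    transform = net$transform,
    b_values = net$protocol$b_values,
    config = unclass(net$config),
    init_seed = net$init_seed,
    trained = net$trained,
    loss = net$loss %||% NA,
    n_epochs = net$n_epochs %||% NA,
    final_val_loss = net$final_val_loss %||% NA)
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Restore a network written by [save_network()]
#' @param path JSON file path.
#' @return An `ivim_selfsup` network.
#' @export
load_network <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  p$W <- lapply(p$W, function(w) list(dim = unlist(w$dim),
                                      data = unlist(w$data)))
  p$b <- lapply(p$b, unlist)
  p$bounds <- lapply(p$bounds, unlist)
  p$config <- lapply(p$config, function(x)
    if (is.list(x)) unlist(x) else x)
  p$b_values <- unlist(p$b_values)
  cfg <- do.call(network_config, p$config[c("n_inputs", "n_hidden_layers",
                                            "hidden_width", "n_outputs")])
  net <- build_network(cfg, acquisition_protocol(p$b_values),
                       param_ranges = lapply(p$bounds, identity),
                       seed = p$init_seed, widen_frac = 0)
  net$bounds <- lapply(p$bounds, as.numeric)
  if (!is.null(p$transform))
    net$transform <- lapply(p$transform, function(tr)
      list(kind = tr$kind, a = as.numeric(tr$a), b = as.numeric(tr$b),
           bounds = as.numeric(unlist(tr$bounds))))
  net$W <- lapply(p$W, function(w) matrix(w$data, w$dim[1], w$dim[2]))
  net$b <- lapply(p$b, as.numeric)
  net$trained <- isTRUE(p$trained)
  if (!is.null(p$loss) && !is.na(p$loss)) net$loss <- p$loss
  if (!is.null(p$n_epochs) && !is.na(p$n_epochs)) net$n_epochs <- p$n_epochs
  net
}
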