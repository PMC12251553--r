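# Fully connected network with ReLU hidden layers and a linear output,
# written directly in matrix form so every quantity (pre-activations,
# gradients, moment estimates) is inspectable in tests. Samples are stored
# one per column internally: A0 is d0 x m.

#' Initialise network parameters
#'
#' He-scaled Gaussian weights (`sd = sqrt(2 / fan_in)`, appropriate for
#' ReLU hidden units) and zero biases, deterministic for a given seed.
#'
#' @param layer_dims integer vector `(d0, d1, ..., dL)`; `d0` is the input
#'   dimension, `dL` the output dimension.
#' @param seed integer seed for reproducible initialisation.
#' @return Object of class `fcnn_params`: lists `W` (each `d_l x d_{l-1}`)
#'   and `b` (each length `d_l`), plus `layer_dims`.
#' @export
init_network <- function(layer_dims, seed = 1L) {
  layer_dims <- as.integer(layer_dims)
  if (length(layer_dims) < 2L || any(layer_dims < 1L))
    stop("layer_dims must give at least input and output sizes, all >= 1")
  L <- length(layer_dims) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (l in seq_len(L)) {
    fan_in <- layer_dims[l]
    W[[l]] <- matrix(stats::rnorm(layer_dims[l + 1] * fan_in,
                                  sd = sqrt(2 / fan_in)),
                     layer_dims[l + 1], fan_in)
    b[[l]] <- numeric(layer_dims[l + 1])
  }
  structure(list(W = W, b = b, layer_dims = layer_dims),
            class = "fcnn_params")
}

#' Forward pass
#'
#' Propagates `Z_l = W_l A_{l-1} + b_l` with element-wise ReLU on hidden
#' layers and a linear output layer, returning the prediction and the
#' cached pre-activations/activations needed for backpropagation.
#'
#' @param params an `fcnn_params` object.
#' @param X input matrix, `d0 x m` (one sample per column).
#' @return List with `Yhat` (`dL x m`) and `cache` (lists `Z`, `A`).
#' @export
fcnn_forward <- function(params, X) {
  X <- as.matrix(X)
  if (nrow(X) != params$layer_dims[1])
    stop(sprintf("input has %d features, network expects %d",
                 nrow(X), params$layer_dims[1]))
  L <- length(params$W)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- params$W[[l]] %*% A[[l]] + params$b[[l]]
    A[[l + 1]] <- if (l < L) pmax(Z[[l]], 0) else Z[[l]]
  }
  list(Yhat = A[[L + 1]], cache = list(Z = Z, A = A))
}

#' Mean squared error loss
#'
#' `(1/m) * sum_i || yhat_i - y_i ||^2` over the `m` samples (columns).
#'
#' @param Yhat,Y matrices of equal shape, one sample per column.
#' @return Scalar loss.
#' @export
mse_loss <- function(Yhat, Y) {
  Yhat <- as.matrix(Yhat); Y <- as.matrix(Y)
  if (!all(dim(Yhat) == dim(Y))) stop("Yhat and Y must have the same shape")
  m <- ncol(Y)
  if (m < 1L) stop("loss needs at least one sample")
  sum((Yhat - Y)^2) / m
}

#' Backward pass (exact gradients of the MSE loss)
#'
#' Backpropagates through the linear output and ReLU hidden layers. The
#' ReLU subgradient at exactly zero is taken as zero.
#'
#' @param params an `fcnn_params` object.
#' @param cache forward cache from [fcnn_forward()] on the same parameters.
#' @param Y target matrix (`dL x m`).
#' @return List of class `fcnn_grads` with `dW`, `db` matching `params`.
#' @export
fcnn_backward <- function(params, cache, Y) {
  Y <- as.matrix(Y)
  L <- length(params$W)
  A <- cache$A; Z <- cache$Z
  if (is.null(A) || length(A) != L + 1L || !all(dim(A[[L + 1]]) == dim(Y)))
    stop("cache does not match the parameters/targets")
  m <- ncol(Y)
  dW <- vector("list", L)
  db <- vector("list", L)
  dZ <- 2 * (A[[L + 1]] - Y) / m          # d loss / d Z_L (linear output)
  for (l in L:1) {
    dW[[l]] <- dZ %*% t(A[[l]])
    db[[l]] <- rowSums(dZ)
    if (l > 1L) dZ <- (t(params$W[[l]]) %*% dZ) * (Z[[l - 1]] > 0)
  }
  structure(list(dW = dW, db = db), class = "fcnn_grads")
}

#' Plain gradient-descent update
#'
#' `theta <- theta - lambda * grad`, element-wise over all weights and
#' biases.
#'
#' @param params an `fcnn_params` object.
#' @param grads matching `fcnn_grads`.
#' @param lam learning rate.
#' @return Updated `fcnn_params`.
#' @export
sgd_update <- function(params, grads, lam) {
  for (l in seq_along(params$W)) {
    params$W[[l]] <- params$W[[l]] - lam * grads$dW[[l]]
    params$b[[l]] <- params$b[[l]] - lam * grads$db[[l]]
  }
  params
}

#' Initialise Adam optimizer state
#'
#' Zero first and second moment estimates for every parameter and step
#' counter `t = 0`.
#'
#' @param params an `fcnn_params` object.
#' @param lam learning rate.
#' @param beta1,beta2 exponential decay rates of the first and second
#'   moment estimates (must lie in `[0, 1)`).
#' @param eps positive stabiliser preventing division by zero.
#' @return Object of class `adam_state`.
#' @export
adam_init <- function(params, lam = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (eps <= 0) stop("eps must be positive")
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1)
    stop("beta1 and beta2 must lie in [0, 1)")
  zero_like <- function(p) lapply(p, function(z) z * 0)
  structure(list(mW = zero_like(params$W), vW = zero_like(params$W),
                 mb = zero_like(params$b), vb = zero_like(params$b),
                 t = 0L, lam = lam, beta1 = beta1, beta2 = beta2, eps = eps),
            class = "adam_state")
}

#' One Adam update step
#'
#' Adaptive moment estimation: exponentially decayed first and second
#' gradient moments with bias correction, then a per-parameter step
#' `theta <- theta - lam * mhat / (sqrt(vhat) + eps)`. The step counter is
#' incremented before the bias corrections.
#'
#' @param params an `fcnn_params` object.
#' @param grads matching `fcnn_grads`.
#' @param state an `adam_state` from [adam_init()].
#' @return List with updated `params` and `state`.
#' @export
adam_step <- function(params, grads, state) {
  state$t <- state$t + 1L
  c1 <- 1 - state$beta1^state$t
  c2 <- 1 - state$beta2^state$t
  upd <- function(theta, g, m, v) {
    m <- state$beta1 * m + (1 - state$beta1) * g
    v <- state$beta2 * v + (1 - state$beta2) * g^2
    theta <- theta - state$lam * (m / c1) / (sqrt(v / c2) + state$eps)
    list(theta = theta, m = m, v = v)
  }
  for (l in seq_along(params$W)) {
    r <- upd(params$W[[l]], grads$dW[[l]], state$mW[[l]], state$vW[[l]])
    params$W[[l]] <- r$theta; state$mW[[l]] <- r$m; state$vW[[l]] <- r$v
    r <- upd(params$b[[l]], grads$db[[l]], state$mb[[l]], state$vb[[l]])
    params$b[[l]] <- r$theta; state$mb[[l]] <- r$m; state$vb[[l]] <- r$v
  }
  list(params = params, state = state)
}

#' Train a network by full-batch iterative minimisation of the MSE loss
#'
#' Runs forward/backward passes over the whole training set each epoch and
#' updates the parameters with Adam (default) or plain gradient descent.
#' With a validation set, the parameters with the best validation loss are
#' returned and training stops early after `patience` epochs without
#' improvement. Deterministic for a given seed.
#'
#' @param X training inputs, `d0 x m`.
#' @param Y training targets, `dL x m`.
#' @param layer_dims network architecture `(d0, ..., dL)`.
#' @param epochs maximum number of epochs.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param lam learning rate.
#' @param beta1,beta2,eps Adam hyperparameters.
#' @param seed initialisation seed.
#' @param X_val,Y_val optional validation split.
#' @param patience early-stopping patience on validation loss (`Inf`
#'   disables early stopping).
#' @param params optional warm-start parameters (overrides `layer_dims`).
#' @return List of class `fcnn_fit`: `params`, `loss` (training loss per
#'   epoch), `val_loss` (or NULL), `epochs_run`.
#' @export
train_fcnn <- function(X, Y, layer_dims, epochs = 2000L,
                       optimizer = c("adam", "sgd"), lam = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8, seed = 1L,
                       X_val = NULL, Y_val = NULL, patience = Inf,
                       params = NULL) {
  optimizer <- match.arg(optimizer)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) < 1L) stop("training set is empty")
  if (is.null(params)) params <- init_network(layer_dims, seed = seed)
  state <- if (optimizer == "adam") adam_init(params, lam, beta1, beta2, eps)
  loss <- numeric(epochs)
  val_loss <- if (!is.null(X_val)) numeric(epochs)
  best <- list(params = params, val = Inf, epoch = 0L)
  wait <- 0L
  ep_run <- 0L
  for (ep in seq_len(epochs)) {
    fw <- fcnn_forward(params, X)
    loss[ep] <- mse_loss(fw$Yhat, Y)
    if (!is.finite(loss[ep]))
      stop(sprintf("training diverged (non-finite loss) at epoch %d, lam = %g",
                   ep, lam))
    gr <- fcnn_backward(params, fw$cache, Y)
    if (optimizer == "adam") {
      st <- adam_step(params, gr, state)
      params <- st$params; state <- st$state
    } else {
      params <- sgd_update(params, gr, lam)
    }
    ep_run <- ep
    if (!is.null(X_val)) {
      vl <- mse_loss(fcnn_forward(params, X_val)$Yhat, Y_val)
      val_loss[ep] <- vl
      if (vl < best$val) {
        best <- list(params = params, val = vl, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  }
  out_params <- if (!is.null(X_val) && is.finite(best$val)) best$params
                else params
  structure(list(params = out_params, loss = loss[seq_len(ep_run)],
                 val_loss = if (!is.null(X_val)) val_loss[seq_len(ep_run)],
                 epochs_run = ep_run),
            class = "fcnn_fit")
}
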