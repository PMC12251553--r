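test_that("initialisation is deterministic, shaped, and He-scaled", {
  p1 <- init_network(c(13, 32, 16, 1), seed = 9)
  p2 <- init_network(c(13, 32, 16, 1), seed = 9)
  expect_identical(p1, p2)
  expect_equal(dim(p1$W[[1]]), c(32L, 13L))
  expect_equal(dim(p1$W[[2]]), c(16L, 32L))
  expect_equal(dim(p1$W[[3]]), c(1L, 16L))
  expect_true(all(vapply(p1$b, function(b) all(b == 0), logical(1))))
  # law of large numbers: sample variance close to 2 / fan_in
  big <- init_network(c(100, 100), seed = 1)
  expect_equal(var(as.numeric(big$W[[1]])), 2 / 100, tolerance = 0.2)
  expect_error(init_network(c(5), seed = 1), "at least")
})

test_that("forward pass matches hand-computed arithmetic", {
  p <- init_network(c(2, 2, 1), seed = 1)
  p$W[[1]] <- matrix(c(1, -1, 2, 0.5), 2, 2)   # rows: units, cols: inputs
  p$b[[1]] <- c(0.1, -0.2)
  p$W[[2]] <- matrix(c(1, 2), 1, 2)
  p$b[[2]] <- 0.5
  x <- matrix(c(1, 1), 2, 1)
  # z1 = (1*1 + 2*1 + 0.1, -1*1 + 0.5*1 - 0.2) = (3.1, -0.7)
  # a1 = (3.1, 0); y = 1*3.1 + 2*0 + 0.5 = 3.6
  out <- fcnn_forward(p, x)
  expect_equal(as.numeric(out$Yhat), 3.6)

  # zero parameters give zero output; identity single layer passes input
  pz <- init_network(c(3, 2), seed = 1)
  pz$W[[1]][] <- 0
  expect_equal(as.numeric(fcnn_forward(pz, matrix(rnorm(9), 3))$Yhat),
               rep(0, 6))
  pid <- init_network(c(3, 3), seed = 1)
  pid$W[[1]] <- diag(3)
  X <- matrix(rnorm(12), 3)
  expect_equal(fcnn_forward(pid, X)$Yhat, X)
  expect_error(fcnn_forward(p, matrix(1, 3, 2)), "features")
})

test_that("MSE loss matches its definition", {
  expect_equal(mse_loss(matrix(1:6, 2), matrix(1:6, 2)), 0)
  expect_equal(mse_loss(matrix(c(2, 2), 1), matrix(c(1, 2), 1)), 0.5)
  set.seed(4)
  A <- matrix(rnorm(30), 3); B <- matrix(rnorm(30), 3)
  brute <- sum(vapply(1:10, function(i) sum((A[, i] - B[, i])^2),
                      numeric(1))) / 10
  expect_equal(mse_loss(A, B), brute, tolerance = 1e-12)
  expect_error(mse_loss(matrix(1, 2, 2), matrix(1, 2, 3)), "shape")
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(21)
  for (dims in list(c(13, 8, 1), c(5, 7, 4, 2))) {
    p <- init_network(dims, seed = 33)
    X <- matrix(rnorm(dims[1] * 12), dims[1])
    Y <- matrix(rnorm(dims[length(dims)] * 12), dims[length(dims)])
    fw <- fcnn_forward(p, X)
    gr <- fcnn_backward(p, fw$cache, Y)
    loss_at <- function(theta) {
      q <- p; k <- 1L
      for (l in seq_along(q$W)) {
        nW <- length(q$W[[l]])
        q$W[[l]][] <- theta[k:(k + nW - 1)]; k <- k + nW
      }
      for (l in seq_along(q$b)) {
        nb <- length(q$b[[l]])
        q$b[[l]][] <- theta[k:(k + nb - 1)]; k <- k + nb
      }
      mse_loss(fcnn_forward(q, X)$Yhat, Y)
    }
    th <- flatten_params(p)
    g_bp <- flatten_params(list(W = gr$dW, b = gr$db))
    g_fd <- vapply(seq_along(th), function(i) {
      h <- 1e-5 * max(1, abs(th[i]))
      tp <- th; tp[i] <- tp[i] + h
      tm <- th; tm[i] <- tm[i] - h
      (loss_at(tp) - loss_at(tm)) / (2 * h)
    }, numeric(1))
    expect_lt(sqrt(sum((g_bp - g_fd)^2)) /
                (sqrt(sum(g_bp^2)) + sqrt(sum(g_fd^2))), 1e-6)
  }
})

test_that("gradients vanish at a perfect fit and scale with the residual", {
  p <- init_network(c(4, 3, 2), seed = 5)
  X <- matrix(rnorm(20), 4)
  fw <- fcnn_forward(p, X)
  g0 <- fcnn_backward(p, fw$cache, fw$Yhat)     # residual zero
  expect_true(all(vapply(g0$dW, function(m) all(m == 0), logical(1))))
  # doubling the residual doubles the output-layer gradient
  Y <- fw$Yhat + matrix(rnorm(length(fw$Yhat)), nrow(fw$Yhat))
  g1 <- fcnn_backward(p, fw$cache, Y)
  g2 <- fcnn_backward(p, fw$cache, fw$Yhat + 2 * (Y - fw$Yhat))
  expect_equal(g2$dW[[2]], 2 * g1$dW[[2]], tolerance = 1e-12)
})

test_that("plain gradient descent takes the textbook step", {
  p <- init_network(c(2, 1), seed = 2)
  g <- list(dW = list(matrix(0, 1, 2)), db = list(0))
  expect_equal(sgd_update(p, g, 0.5), p)                  # zero gradient
  g$dW[[1]] <- matrix(c(1, 2), 1, 2)
  expect_equal(sgd_update(p, g, 0), p)                    # zero rate
  upd <- sgd_update(p, g, 0.1)
  expect_equal(upd$W[[1]], p$W[[1]] - 0.1 * matrix(c(1, 2), 1, 2))
})

test_that("Adam updates satisfy the first-step and constant-gradient identities", {
  p <- init_network(c(3, 1), seed = 8)
  gmat <- matrix(c(0.3, -2, 1e-4), 1, 3)
  g <- list(dW = list(gmat), db = list(0.7))
  # zero gradient from zero moments: parameters unchanged
  st <- adam_init(p, lam = 0.01)
  r0 <- adam_step(p, list(dW = list(gmat * 0), db = list(0)), st)
  expect_equal(r0$params$W, p$W)
  # first step with eps -> 0: every coordinate moves by exactly lam
  st <- adam_init(p, lam = 0.01, eps = 1e-12)
  r1 <- adam_step(p, g, st)
  expect_equal(abs(r1$params$W[[1]] - p$W[[1]]),
               matrix(0.01, 1, 3), tolerance = 1e-6)
  # second step with the same gradient: still ~ lam * sign(g)
  r2 <- adam_step(r1$params, g, r1$state)
  expect_equal(r2$params$W[[1]] - r1$params$W[[1]],
               -0.01 * sign(gmat), tolerance = 1e-6)
  # bounded step in the constant-gradient regime
  expect_lte(max(abs(r2$params$W[[1]] - r1$params$W[[1]])), 2 * 0.01)
  expect_error(adam_init(p, eps = 0), "positive")
})

test_that("Adam reduces to sign descent and to scaled gradient descent at its limits", {
  p <- init_network(c(2, 1), seed = 3)
  gmat <- matrix(c(0.4, -1.7), 1, 2)
  g <- list(dW = list(gmat), db = list(0))
  # beta1 = beta2 = 0, eps -> 0: sign-gradient descent of step lam
  st <- adam_init(p, lam = 0.05, beta1 = 0, beta2 = 0, eps = 1e-14)
  r <- adam_step(p, g, st)
  expect_equal(r$params$W[[1]], p$W[[1]] - 0.05 * sign(gmat),
               tolerance = 1e-10)
  # beta1 = beta2 = 0, huge eps: approximately SGD with rate lam / eps
  st2 <- adam_init(p, lam = 0.05, beta1 = 0, beta2 = 0, eps = 1e6)
  r2 <- adam_step(p, g, st2)
  expect_equal(r2$params$W[[1]], p$W[[1]] - (0.05 / 1e6) * gmat,
               tolerance = 1e-5)
})

test_that("training solves a noiseless linear regression and is reproducible", {
  set.seed(6)
  w <- c(1.5, -0.7, 0.3)
  X <- matrix(rnorm(3 * 50), 3)
  Y <- matrix(w %*% X, 1)
  fit <- train_fcnn(X, Y, c(3, 1), epochs = 200, optimizer = "adam",
                    lam = 0.05, seed = 4)
  expect_lt(tail(fit$loss, 1), 1e-4)
  fit2 <- train_fcnn(X, Y, c(3, 1), epochs = 200, optimizer = "adam",
                     lam = 0.05, seed = 4)
  expect_identical(fit$loss, fit2$loss)
  # constant targets are fitted to numerical zero by a linear net
  Yc <- matrix(2, 1, 50)
  fitc <- train_fcnn(X, Yc, c(3, 1), epochs = 400, optimizer = "adam",
                     lam = 0.05, seed = 4)
  expect_lt(tail(fitc$loss, 1), 1e-6)
})

test_that("Adam reaches the loss target in fewer epochs than fixed-rate descent", {
  # badly scaled features: per-coordinate adaptation is what Adam adds
  set.seed(16)
  w <- c(0.8, -1.2, 0.5, 2)
  X <- diag(c(20, 0.05, 1, 5)) %*% matrix(rnorm(4 * 60), 4)
  Y <- matrix(w %*% X, 1)
  first_below <- function(fit) {
    i <- which(fit$loss < 1e-4)
    if (length(i)) i[1] else Inf
  }
  fa <- train_fcnn(X, Y, c(4, 1), epochs = 10000, optimizer = "adam",
                   lam = 1e-3, seed = 2)
  fs <- train_fcnn(X, Y, c(4, 1), epochs = 10000, optimizer = "sgd",
                   lam = 1e-3, seed = 2)
  expect_lt(tail(fa$loss, 1), 1e-4)
  expect_lt(first_below(fa), first_below(fs))
})
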