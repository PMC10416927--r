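test_that("activations match their closed forms", {
  expect_equal(apply_activation("softplus", 0), log(2))
  expect_equal(apply_activation("relu", c(-3, 3)), c(0, 3))
  expect_equal(apply_activation("sigmoid", 0), 0.5)
  # overflow safety
  expect_equal(apply_activation("softplus", 1000), 1000)
  expect_equal(apply_activation("softplus", -1000), 0)
  expect_error(apply_activation("tanhh", 1), "unknown")
})

test_that("RINN weight matrices carry redundant-input rows with the right shapes", {
  hp <- rinn_hp(hidden_sizes = 2)
  w <- init_network("RINN", 3, 4, hp, seed = 1)
  expect_length(w$W, 9L)
  expect_identical(dim(w$W[[1]]), c(3L, 2L))
  for (i in 2:8) expect_identical(dim(w$W[[i]]), c(5L, 2L))
  expect_identical(dim(w$W[[9]]), c(2L, 4L))
  expect_true(all(vapply(w$b, function(b) all(b == 0), logical(1))))

  d <- init_network("DNN", 10, 7, rinn_hp(hidden_sizes = c(50, 50),
                                          architecture = "DNN"), seed = 1)
  expect_length(d$W, 3L)
  expect_identical(dim(d$W[[1]]), c(10L, 50L))
  expect_identical(dim(d$W[[3]]), c(50L, 7L))

  expect_identical(init_network("RINN", 3, 4, hp, seed = 5),
                   init_network("RINN", 3, 4, hp, seed = 5))
  expect_error(rinn_hp(hidden_sizes = c(2, 2), architecture = "RINN"),
               "8 hidden layers")
})

test_that("zero weights predict one half everywhere", {
  w <- init_network("RINN", 4, 3, rinn_hp(hidden_sizes = 2), seed = 1)
  w$W <- lapply(w$W, function(m) m * 0)
  P <- forward_rinn(w, matrix(rbinom(20, 1, 0.5), 5, 4))
  expect_true(all(P == 0.5))
})

test_that("zeroing redundant rows reduces the RINN forward pass to a DNN", {
  withr::with_seed(42, {
    for (case in 1:20) {
      m <- sample(2:6, 1); p <- sample(2:5, 1); h <- sample(2:4, 1)
      w <- init_network("RINN", m, p, rinn_hp(hidden_sizes = h), seed = case)
      wd <- w; wd$architecture <- "DNN"
      for (i in 2:8) {
        wd$W[[i]] <- w$W[[i]][seq_len(h), , drop = FALSE]
        w$W[[i]][(h + 1):(h + m), ] <- 0
      }
      X <- matrix(runif(7 * m), 7, m)
      expect_lt(max(abs(forward_rinn(w, X) - forward_dnn(wd, X))), 1e-10)
    }
  })
})

test_that("a hand-computed one-node-per-layer RINN matches the nested formula", {
  # 1 input, 8 hidden layers of 1 node, 1 output; all weights set by hand
  w <- init_network("RINN", 1, 1, rinn_hp(hidden_sizes = 1, activation = "relu"),
                    seed = 1)
  w$W[[1]] <- matrix(0.5)                      # x -> h1
  for (i in 2:8) w$W[[i]] <- matrix(c(1, 0.1)) # [h, x] -> h
  w$W[[9]] <- matrix(2)
  w$b <- lapply(w$b, function(b) b * 0)
  x <- 1
  h <- 0.5 * x
  for (i in 2:8) h <- max(0, 1 * h + 0.1 * x)
  expected <- 1 / (1 + exp(-2 * h))
  expect_equal(as.numeric(forward_rinn(w, matrix(x, 1, 1))), expected,
               tolerance = 1e-12)
})

test_that("the objective combines clamped cross-entropy and the L1 term", {
  w <- init_network("RINN", 2, 2, rinn_hp(hidden_sizes = 1), seed = 1)
  preds <- matrix(0.5, 3, 2); y <- matrix(1, 3, 2)
  o <- objective(preds, y, w, rr = 0)
  expect_equal(o$cel, log(2), tolerance = 1e-12)
  expect_equal(o$total, o$cel)
  # perfect predictions give (numerically) zero loss
  o2 <- objective(y, y, w, rr = 0)
  expect_lt(o2$cel, 1e-10)
  # arithmetic of the combined objective
  w$W <- list(matrix(c(1, -1)))  # sum|w| = 2
  o3 <- objective(preds, y, w, rr = 1)
  expect_equal(o3$total, log(2) + 2, tolerance = 1e-12)
  expect_error(objective(preds, y[1:2, ], w), "shape")
})

test_that("analytic gradients match central finite differences", {
  for (arch in c("RINN", "DNN")) {
    hp <- rinn_hp(hidden_sizes = if (arch == "RINN") 1 else c(2, 2),
                  activation = "softplus", architecture = arch)
    w <- init_network(arch, 2, 2, hp, seed = 3)
    X <- matrix(c(1, 0, 1, 1, 0, 1), 3, 2)
    Y <- matrix(c(1, 0, 0, 1, 1, 0), 3, 2)
    rr <- 0.01
    g <- network_gradients(w, X, Y, rr)
    eps <- 1e-6
    worst <- 0
    for (i in seq_along(w$W)) {
      for (idx in seq_along(w$W[[i]])) {
        wp <- w; wp$W[[i]][idx] <- wp$W[[i]][idx] + eps
        wm <- w; wm$W[[i]][idx] <- wm$W[[i]][idx] - eps
        num <- (objective(rinn:::network_forward(wp, X), Y, wp, rr)$total -
                objective(rinn:::network_forward(wm, X), Y, wm, rr)$total) / (2 * eps)
        ana <- g$W[[i]][idx]
        worst <- max(worst, abs(ana - num) / max(1e-4, abs(ana) + abs(num)))
      }
      for (idx in seq_along(w$b[[i]])) {
        wp <- w; wp$b[[i]][idx] <- wp$b[[i]][idx] + eps
        wm <- w; wm$b[[i]][idx] <- wm$b[[i]][idx] - eps
        num <- (objective(rinn:::network_forward(wp, X), Y, wp, rr)$total -
                objective(rinn:::network_forward(wm, X), Y, wm, rr)$total) / (2 * eps)
        worst <- max(worst, abs(g$b[[i]][idx] - num) /
                            max(1e-4, abs(g$b[[i]][idx]) + abs(num)))
      }
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("SGD training reduces the loss on a separable toy problem", {
  X <- matrix(rep(c(0L, 1L), each = 30), ncol = 1)
  dat <- list(sga = X, deg = X)  # DEG equals the single SGA
  hp <- rinn_hp(learning_rate = 0.3, l1 = 0, epochs = 50, batch_size = 10,
                hidden_sizes = 2)
  init <- init_network("RINN", 1, 1, hp, seed = 1)
  fit <- train_network(dat, "RINN", hp, seed = 1)
  o0 <- objective(forward_rinn(init, X), X, init, 0)$cel
  o1 <- objective(forward_rinn(fit$weights, X), X, fit$weights, 0)$cel
  expect_lt(o1, o0)
  expect_length(fit$history, 50L)
})

test_that("strong L1 regularization shrinks the total weight below initialization", {
  dat <- tiny_dataset(n = 60, m = 4, p = 6, seed = 2)
  hp <- rinn_hp(learning_rate = 0.1, l1 = 1, epochs = 20, batch_size = 20,
                hidden_sizes = 3)
  init <- init_network("RINN", 4, 6, hp, seed = rinn:::derive_seed(5, 0L, 0L))
  fit <- train_network(dat, "RINN", hp, seed = 5)
  sw <- function(w) sum(vapply(w$W, function(m) sum(abs(m)), numeric(1)))
  expect_lt(sw(fit$weights), sw(init))
})

test_that("training is bitwise reproducible for a fixed seed", {
  dat <- tiny_dataset(n = 40, m = 4, p = 6, seed = 3)
  hp <- rinn_hp(learning_rate = 0.2, l1 = 1e-4, epochs = 5, batch_size = 20,
                hidden_sizes = 3)
  a <- train_network(dat, "RINN", hp, seed = 11)
  b <- train_network(dat, "RINN", hp, seed = 11)
  expect_identical(a$history, b$history)
  expect_identical(a$weights, b$weights)
})

test_that("weight sums shrink as the regularization rate grows", {
  dat <- tiny_dataset(n = 80, m = 5, p = 8, seed = 4)
  sw_at <- function(rr) {
    med <- vapply(1:3, function(s) {
      hp <- rinn_hp(learning_rate = 0.2, l1 = rr, epochs = 30, batch_size = 20,
                    hidden_sizes = 4)
      fit <- train_network(dat, "RINN", hp, seed = s)
      sum(vapply(fit$weights$W, function(m) sum(abs(m)), numeric(1)))
    }, numeric(1))
    stats::median(med)
  }
  sums <- vapply(c(1e-6, 1e-4, 1e-2), sw_at, numeric(1))
  expect_true(all(diff(sums) <= 0))
})
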