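# Network construction, exact gradients, the Rprop+ update rule, data
# splitting and cross-validation.

test_that("parameter counts follow layer arithmetic", {
  # by-layer oracle: sum over layers of out*in + out
  count <- function(sizes) {
    sum(vapply(seq_len(length(sizes) - 1),
               function(l) sizes[l + 1] * sizes[l] + sizes[l + 1], 1))
  }
  gh <- mlp_init(6, mlp_architecture("gh"), seed = 1)
  te <- mlp_init(6, mlp_architecture("te"), seed = 1)
  expect_equal(mlp_n_params(gh), count(c(6, 12, 10, 10, 10, 6, 1)))
  expect_equal(mlp_n_params(gh), 507L)
  expect_equal(mlp_n_params(te), count(c(6, 10, 8, 8, 8, 6, 1)))
  expect_equal(mlp_n_params(te), 363L)
})

test_that("initialization is seeded, fan-in bounded, with zero biases", {
  a <- mlp_init(6, c(8, 4), seed = 7)
  b <- mlp_init(6, c(8, 4), seed = 7)
  expect_identical(a$W, b$W)
  expect_false(identical(a$W, mlp_init(6, c(8, 4), seed = 8)$W))
  for (l in seq_along(a$W)) {
    expect_lte(max(abs(a$W[[l]])), sqrt(6 / ncol(a$W[[l]])))
    expect_equal(a$b[[l]], numeric(length(a$b[[l]])))
  }
})

test_that("the forward pass matches hand-computed ReLU arithmetic", {
  m <- mlp_init(6, 1, seed = 1)
  # single hidden unit, hand-set weights
  m$W[[1]][] <- c(2, 1, 0, 0, 0, 0); m$b[[1]][] <- 0.5
  m$W[[2]][] <- 3; m$b[[2]][] <- -1
  # z = 2*1 + 1*(-1) + 0.5 = 1.5; out = 3*1.5 - 1
  expect_equal(mlp_forward(m, c(1, -1, 0, 0, 0, 0)), 3.5)
  # negative pre-activation is rectified away
  expect_equal(mlp_forward(m, c(-1, 0, 0, 0, 0, 0)), -1)

  z <- mlp_init(4, c(3, 2), seed = 2)
  for (l in seq_along(z$W)) z$W[[l]][] <- 0
  z$b[[length(z$b)]][] <- 4.25
  expect_equal(mlp_forward(z, matrix(rnorm(20), 5, 4)), rep(4.25, 5))
  expect_error(mlp_forward(z, matrix(0, 2, 3)), "expects")
})

test_that("backpropagated gradients match central finite differences", {
  for (s in 1:3) {
    set.seed(s)
    m <- mlp_init(3, c(4, 3), seed = s + 10)
    X <- matrix(rnorm(18), 6, 3)
    y <- rnorm(6)
    g <- mlp_gradients(m, X, y)
    ana <- unlist(c(g$W, g$b))
    th <- unlist(c(m$W, m$b))
    unpack <- function(v) serscal:::mlp_unpack(m, v)
    h <- 1e-6
    num <- vapply(seq_along(th), function(i) {
      up <- th; up[i] <- up[i] + h
      dn <- th; dn[i] <- dn[i] - h
      (mean((mlp_forward(unpack(up), X) - y)^2) -
       mean((mlp_forward(unpack(dn), X) - y)^2)) / (2 * h)
    }, 1)
    expect_lt(max(abs(ana - num) / pmax(abs(num), 1e-3)), 1e-5)
  }
})

test_that("Rprop+ grows step sizes geometrically under a stable gradient sign", {
  # constant unit gradient; first epoch takes the plain delta0 step, the
  # next two grow it by eta_plus: positions -0.1, -0.22, -0.364
  steps <- c(0.1, 0.1 * 1.2, 0.1 * 1.2^2)
  fit <- rprop_minimize(0, fn = function(w) -w, gr = function(w) 1,
                        config = train_config(max_epochs = 3, delta0 = 0.1,
                                              early_stop_tolerance = 0,
                                              patience = 10))
  expect_equal(fit$par, -sum(steps), tolerance = 1e-12)
})

test_that("Rprop+ minimizes a quadratic to its closed-form optimum", {
  fit <- rprop_minimize(0, fn = function(w) (w - 3)^2,
                        gr = function(w) 2 * (w - 3),
                        config = train_config(max_epochs = 200))
  expect_lt(abs(fit$par - 3), 1e-4)
  expect_true(all(is.finite(fit$history)))
})

test_that("a linear-only network recovers the least-squares solution", {
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3)
  beta <- c(1.5, -2, 0.5); y <- as.numeric(X %*% beta) + 0.75
  m <- mlp_init(3, integer(0), seed = 1)
  m <- mlp_train(m, X, y,
                 train_config(max_epochs = 5000, delta_min = 1e-9,
                              early_stop_tolerance = 0, patience = 5001))
  ols <- coef(lm(y ~ X))
  expect_equal(as.numeric(m$W[[1]]), unname(ols[2:4]), tolerance = 1e-6)
  expect_equal(m$b[[1]], unname(ols[1]), tolerance = 1e-6)
})

test_that("vectorized Rprop+ matches a literal per-parameter reference", {
  # tiny linear model y ~ w1 x1 + w2 x2 + b, trained 12 epochs; the
  # reference applies the published update rules scalar by scalar
  set.seed(9)
  X <- matrix(rnorm(10), 5, 2); y <- rnorm(5)
  cfg <- train_config(max_epochs = 12, early_stop_tolerance = 0,
                      patience = 20)
  grad_ref <- function(w) {
    pred <- as.numeric(X %*% w[1:2]) + w[3]
    c(2 * mean((pred - y) * X[, 1]), 2 * mean((pred - y) * X[, 2]),
      2 * mean(pred - y))
  }
  w <- c(0.3, -0.2, 0.1)
  step <- rep(cfg$delta0, 3); gprev <- numeric(3); uprev <- numeric(3)
  for (ep in 1:12) {
    g <- grad_ref(w)
    u <- numeric(3)
    for (i in 1:3) {
      s <- g[i] * gprev[i]
      if (s > 0) {
        step[i] <- min(step[i] * cfg$eta_plus, cfg$delta_max)
        u[i] <- -sign(g[i]) * step[i]; w[i] <- w[i] + u[i]; gprev[i] <- g[i]
      } else if (s < 0) {
        step[i] <- max(step[i] * cfg$eta_minus, cfg$delta_min)
        u[i] <- -uprev[i]; w[i] <- w[i] + u[i]; gprev[i] <- 0
      } else {
        u[i] <- -sign(g[i]) * step[i]; w[i] <- w[i] + u[i]; gprev[i] <- g[i]
      }
    }
    uprev <- u
  }
  m <- mlp_init(2, integer(0), seed = 1)
  m$W[[1]][] <- c(0.3, -0.2); m$b[[1]][] <- 0.1
  m <- mlp_train(m, X, y, cfg)
  expect_equal(as.numeric(m$W[[1]]), w[1:2], tolerance = 1e-12)
  expect_equal(m$b[[1]], w[3], tolerance = 1e-12)
})

test_that("hold-out splits are stratified, sized and reproducible", {
  targets <- rep(exp(seq(log(0.01), log(60), length.out = 30)), each = 30)
  sp <- holdout_split(targets, 0.75, seed = 3)
  expect_equal(length(sp$train), 675)
  expect_equal(length(sp$test), 225)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(targets))
  for (l in unique(targets)) {
    expect_gt(sum(targets[sp$train] == l), 0)
    expect_gt(sum(targets[sp$test] == l), 0)
  }
  expect_identical(holdout_split(targets, 0.75, seed = 3), sp)
  expect_false(identical(holdout_split(targets, 0.75, seed = 4), sp))

  y2 <- c(rep(1, 5), 9)   # singleton level goes to training, with warning
  expect_warning(s2 <- holdout_split(y2, 0.5, seed = 1), "single replicate")
  expect_true(which(y2 == 9) %in% s2$train)
  expect_error(holdout_split(targets, 1), "strictly between")
})

test_that("k-fold assignment balances folds within and across levels", {
  y <- rep(c(1, 5, 20), each = 8)
  f <- kfold_assign(y, 4, seed = 2)
  expect_equal(as.numeric(table(f)), rep(6, 4))
  for (l in unique(y)) {
    expect_equal(as.numeric(table(f[y == l])), rep(2, 4))
  }
  loo <- kfold_assign(rnorm(6), 6, seed = 1)
  expect_equal(sort(loo), 1:6)
  expect_error(kfold_assign(1:5, 6), "exceed")
  y900 <- rep(1:30, each = 30)
  expect_equal(as.numeric(table(kfold_assign(y900, 4, seed = 1))),
               rep(225, 4))
})

test_that("cross-validation reports per-fold metrics and their summary", {
  set.seed(11)
  sc <- matrix(rnorm(120), 40, 3)
  y <- 2 + sc[, 1] + rnorm(40, 0, 0.1)
  cv <- kfold_cv(sc, y, hidden_sizes = c(4), k = 4, seed = 1,
                 config = train_config(max_epochs = 150))
  expect_equal(nrow(cv$folds), 4)
  expect_equal(cv$rmse_mean, mean(cv$folds$rmse))
  expect_equal(cv$r2_mean, mean(cv$folds$r2))
  cvt <- kfold_cv(sc, y, hidden_sizes = c(4), k = 4, seed = 1,
                  config = train_config(max_epochs = 150), trace = TRUE)
  expect_true(cvt$best_epoch >= 1 && cvt$best_epoch <= 150)
  expect_equal(dim(cvt$trace)[2], 4)
})
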