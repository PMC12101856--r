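# Multilayer perceptron regression trained with resilient backpropagation
# with weight backtracking (Rprop+). Written from scratch: the optimizer's
# sign-based, per-parameter adaptive steps are the point, so no external
# neural-network code is used.

#' Hormone-specific network architectures
#'
#' Hidden-layer presets for the two calibration networks: GH uses five
#' hidden layers 12:10:10:10:6 and TE uses 10:8:8:8:6, both with ReLU hidden
#' activation and a linear output; the input is the six PC scores and the
#' output the predicted concentration.
#'
#' @param hormone `"gh"` or `"te"`.
#' @return Integer vector of hidden-layer sizes.
#' @export
mlp_architecture <- function(hormone = c("gh", "te")) {
  hormone <- match.arg(hormone)
  if (hormone == "gh") c(12L, 10L, 10L, 10L, 6L) else c(10L, 8L, 8L, 8L, 6L)
}

#' Initialize a multilayer perceptron
#'
#' Weights are drawn from a zero-mean uniform distribution scaled by fan-in
#' (He-style limits `sqrt(6 / fan_in)`, appropriate for ReLU); biases start
#' at zero. `hidden_sizes = integer(0)` gives a purely linear (affine)
#' network, which is useful for testing against closed-form least squares.
#'
#' @param input_size Number of inputs (PC scores).
#' @param hidden_sizes Integer vector of hidden-layer widths (possibly
#'   empty).
#' @param output_size Number of outputs (1 for concentration regression).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return An object of class `mlp`: list with `sizes`, weight matrices `W`
#'   (out x in) and bias vectors `b` per layer.
#' @export
#' @examples
#' m <- mlp_init(6, mlp_architecture("gh"), seed = 1)
#' mlp_n_params(m)  # 393
mlp_init <- function(input_size, hidden_sizes, output_size = 1, seed = NULL) {
  sizes <- as.integer(c(input_size, hidden_sizes, output_size))
  if (any(sizes < 1)) stop("all layer sizes must be >= 1")
  with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1)) {
      fan_in <- sizes[l]
      lim <- sqrt(6 / fan_in)
      W[[l]] <- matrix(stats::runif(sizes[l + 1] * fan_in, -lim, lim),
                       nrow = sizes[l + 1], ncol = fan_in)
      b[[l]] <- numeric(sizes[l + 1])
    }
    structure(list(sizes = sizes, W = W, b = b,
                   training_history = NULL), class = "mlp")
  })
}

#' @export
print.mlp <- function(x, ...) {
  cat("<mlp> ", paste(x$sizes, collapse = ":"), " (",
      mlp_n_params(x), " parameters, ReLU hidden / linear output)\n",
      sep = "")
  if (!is.null(x$training_history)) {
    n <- length(x$training_history)
    cat("  trained ", n, " epochs, final MSE ",
        signif(x$training_history[n], 6), "\n", sep = "")
  }
  invisible(x)
}

#' Total parameter count of a network
#' @param model An [mlp_init()] model.
#' @return Integer number of weights plus biases.
#' @export
mlp_n_params <- function(model) {
  sum(vapply(model$W, length, 1L)) + sum(vapply(model$b, length, 1L))
}

relu <- function(z) pmax(z, 0)

#' Score standardization preserving relative component magnitudes
#'
#' Centers each principal-component score on its training mean and divides
#' all components by one common factor, the standard deviation of the
#' first (largest) component. This brings the inputs to an order-one scale
#' for the optimizer while keeping low-variance (noise-dominated)
#' components small relative to the signal-carrying ones — per-component
#' z-scoring would amplify noise-only components to unit variance and
#' invite overfitting.
#'
#' @param scores Training score matrix (samples x components).
#' @return List with `center` (per-component means) and `scale` (the
#'   common factor, recycled per component); apply with
#'   [apply_score_scaler()].
#' @export
score_scaler <- function(scores) {
  scores <- as.matrix(scores)
  center <- colMeans(scores)
  s1 <- stats::sd(scores[, 1])
  if (!is.finite(s1) || s1 == 0) s1 <- 1
  list(center = center, scale = rep(s1, ncol(scores)))
}

#' @rdname score_scaler
#' @param scaler A `score_scaler()` result.
#' @export
apply_score_scaler <- function(scores, scaler) {
  scale(as.matrix(scores), center = scaler$center, scale = scaler$scale)
}

# Forward pass keeping the pre-activations needed for backprop.
mlp_forward_full <- function(model, X) {
  L <- length(model$W)
  A <- vector("list", L + 1)
  Z <- vector("list", L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- A[[l]] %*% t(model$W[[l]]) +
      matrix(model$b[[l]], nrow = nrow(X), ncol = length(model$b[[l]]),
             byrow = TRUE)
    A[[l + 1]] <- if (l < L) relu(Z[[l]]) else Z[[l]]
  }
  list(A = A, Z = Z, out = A[[L + 1]])
}

#' Forward pass of a multilayer perceptron
#'
#' Affine-ReLU hidden layers followed by a linear output, vectorized over
#' the rows of `X`.
#'
#' @param model An [mlp_init()] model.
#' @param X Numeric matrix (samples x inputs) or vector of length
#'   `input_size`.
#' @return Numeric vector of predictions, one per row of `X`.
#' @export
mlp_forward <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$sizes[1]) {
    stop("input has ", ncol(X), " columns but the network expects ",
         model$sizes[1])
  }
  as.numeric(mlp_forward_full(model, X)$out)
}

#' Backpropagated gradients of the mean-squared-error loss
#'
#' Returns the exact gradient of `mean((mlp_forward(model, X) - y)^2)` with
#' respect to every weight and bias, in the same list shapes as the model.
#'
#' @param model An [mlp_init()] model.
#' @param X Input matrix (samples x inputs).
#' @param y Numeric target vector.
#' @return List with elements `W`, `b` (gradients) and `loss`.
#' @export
mlp_gradients <- function(model, X, y) {
  fw <- mlp_forward_full(model, X)
  L <- length(model$W)
  n <- nrow(X)
  err <- fw$out - matrix(y, ncol = 1)
  loss <- mean(err^2)
  delta <- 2 * err / n
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- t(delta) %*% fw$A[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% model$W[[l]]) * (fw$Z[[l - 1]] > 0)
    }
  }
  list(W = gW, b = gb, loss = loss)
}

#' Rprop+ training configuration
#'
#' Standard resilient-backpropagation constants: step growth `eta_plus`
#' 1.2, shrink `eta_minus` 0.5, step bounds `delta_min` 1e-6 and
#' `delta_max` 50; the initial step `delta0` is 0.01, suited to z-scored
#' inputs. Training is full-batch and stops at `max_epochs` or when the
#' best loss has not improved by more than `early_stop_tolerance` for
#' `patience` consecutive epochs.
#'
#' @param max_epochs Maximum number of full-batch epochs.
#' @param eta_plus,eta_minus Step-size growth/shrink factors
#'   (0 < eta_minus < 1 < eta_plus).
#' @param delta0,delta_min,delta_max Initial / minimum / maximum step sizes.
#' @param early_stop_tolerance Minimum loss improvement that resets the
#'   patience counter.
#' @param patience Number of non-improving epochs tolerated before stopping.
#' @return A list of class `rprop_config`.
#' @export
train_config <- function(max_epochs = 2000, eta_plus = 1.2, eta_minus = 0.5,
                         delta0 = 0.01, delta_min = 1e-6, delta_max = 50,
                         early_stop_tolerance = 1e-8, patience = 50) {
  if (!(eta_minus > 0 && eta_minus < 1 && eta_plus > 1)) {
    stop("need 0 < eta_minus < 1 < eta_plus")
  }
  if (!(delta_min <= delta0 && delta0 <= delta_max)) {
    stop("need delta_min <= delta0 <= delta_max")
  }
  structure(list(max_epochs = max_epochs, eta_plus = eta_plus,
                 eta_minus = eta_minus, delta0 = delta0,
                 delta_min = delta_min, delta_max = delta_max,
                 early_stop_tolerance = early_stop_tolerance,
                 patience = patience),
            class = "rprop_config")
}

# One Rprop+ step on flat parameter/gradient vectors.
# state: list(step, prev_grad, prev_update). Returns updated theta + state.
rprop_step <- function(theta, grad, state, cfg) {
  s <- grad * state$prev_grad
  up <- s > 0; down <- s < 0; flat <- s == 0
  step <- state$step
  step[up] <- pmin(step[up] * cfg$eta_plus, cfg$delta_max)
  step[down] <- pmax(step[down] * cfg$eta_minus, cfg$delta_min)
  update <- numeric(length(theta))
  move <- up | flat
  update[move] <- -sign(grad[move]) * step[move]
  # backtracking: revert the previous update where the gradient sign flipped
  update[down] <- -state$prev_update[down]
  theta <- theta + update
  prev_grad <- grad
  prev_grad[down] <- 0   # forget the gradient so the next epoch takes a plain step
  list(theta = theta,
       state = list(step = step, prev_grad = prev_grad,
                    prev_update = update))
}

#' Minimize a differentiable function with Rprop+
#'
#' Generic driver for the resilient-backpropagation-with-backtracking
#' update used by [mlp_train()]: per parameter, the step size grows by
#' `eta_plus` while the gradient sign is stable and shrinks by `eta_minus`
#' when it flips, in which case the previous update is reverted and the
#' gradient memory cleared. Only gradient *signs* are used, never
#' magnitudes.
#'
#' @param par Numeric start vector.
#' @param fn Function returning the objective value (used for the history
#'   and early stopping).
#' @param gr Function returning the gradient vector.
#' @param config A [train_config()].
#' @param monitor Optional function of the parameter vector evaluated once
#'   per epoch; its values are returned as `monitor_history` (used for
#'   held-out-loss traces).
#' @return List with `par`, `value`, the per-epoch `history` and (when
#'   `monitor` is given) `monitor_history`.
#' @export
#' @examples
#' # minimize (w - 3)^2
#' rprop_minimize(0, function(w) (w - 3)^2, function(w) 2 * (w - 3))$par
rprop_minimize <- function(par, fn, gr, config = train_config(),
                           monitor = NULL) {
  theta <- as.numeric(par)
  state <- list(step = rep(config$delta0, length(theta)),
                prev_grad = numeric(length(theta)),
                prev_update = numeric(length(theta)))
  history <- numeric(config$max_epochs)
  mon <- if (is.null(monitor)) NULL else numeric(config$max_epochs)
  best <- Inf; stall <- 0L; used <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    g <- gr(theta)
    val <- fn(theta)
    if (!is.finite(val)) {
      stop("non-finite objective at epoch ", epoch, " (value = ", val, ")")
    }
    history[epoch] <- val
    if (!is.null(mon)) mon[epoch] <- monitor(theta)
    used <- epoch
    if (best - val > config$early_stop_tolerance) {
      best <- val; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
    st <- rprop_step(theta, g, state, config)
    theta <- st$theta; state <- st$state
  }
  out <- list(par = theta, value = fn(theta),
              history = history[seq_len(used)])
  if (!is.null(mon)) out$monitor_history <- mon[seq_len(used)]
  out
}

mlp_pack <- function(model) unlist(c(model$W, model$b), use.names = FALSE)

mlp_unpack <- function(model, theta) {
  pos <- 0L
  for (l in seq_along(model$W)) {
    k <- length(model$W[[l]])
    model$W[[l]][] <- theta[pos + seq_len(k)]
    pos <- pos + k
  }
  for (l in seq_along(model$b)) {
    k <- length(model$b[[l]])
    model$b[[l]][] <- theta[pos + seq_len(k)]
    pos <- pos + k
  }
  model
}

#' Train a multilayer perceptron with Rprop+
#'
#' Full-batch training of the mean-squared-error loss with the
#' resilient-backpropagation-with-backtracking update (see
#' [rprop_minimize()]). The per-epoch loss is recorded in
#' `training_history`.
#'
#' @param model An [mlp_init()] model.
#' @param X Input matrix (samples x inputs); at least 2 samples.
#' @param y Numeric target vector (finite), ng/ml.
#' @param config A [train_config()].
#' @param validation Optional list `list(X = , y = )` of held-out samples;
#'   their mean-squared error is recorded per epoch in
#'   `validation_history` (monitoring only — it never influences the
#'   weight updates or stopping).
#' @return The trained `mlp` with its `training_history` (and, if
#'   requested, `validation_history`) filled in.
#' @export
mlp_train <- function(model, X, y, config = train_config(),
                      validation = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("training needs at least 2 samples")
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)")
  if (any(!is.finite(y))) stop("targets must be finite")
  monitor <- NULL
  if (!is.null(validation)) {
    Xv <- as.matrix(validation$X); yv <- validation$y
    monitor <- function(th) {
      mean((mlp_forward(mlp_unpack(model, th), Xv) - yv)^2)
    }
  }
  fit <- rprop_minimize(
    mlp_pack(model),
    fn = function(th) {
      fw <- mlp_forward_full(mlp_unpack(model, th), X)
      mean((as.numeric(fw$out) - y)^2)
    },
    gr = function(th) {
      g <- mlp_gradients(mlp_unpack(model, th), X, y)
      unlist(c(g$W, g$b), use.names = FALSE)
    },
    config = config, monitor = monitor)
  out <- mlp_unpack(model, fit$par)
  out$training_history <- fit$history
  if (!is.null(fit$monitor_history)) {
    out$validation_history <- fit$monitor_history
  }
  out
}

#' Committee prediction of several trained networks
#'
#' Averages the forward-pass predictions of a list of networks trained
#' from independent initializations — a variance-reduction device for the
#' multi-start training used by [sers_calibrate()].
#'
#' @param models List of [mlp_init()] models (identical input size).
#' @param X Input matrix (samples x inputs).
#' @return Numeric vector of averaged predictions.
#' @export
ensemble_forward <- function(models, X) {
  preds <- vapply(models, function(m) mlp_forward(m, X),
                  numeric(if (is.null(dim(X))) 1L else nrow(X)))
  if (is.null(dim(preds))) mean(preds) else rowMeans(preds)
}

#' Concentration-stratified hold-out split
#'
#' Splits sample indices so that every concentration level is represented
#' in both partitions whenever its replicate count permits; a level with a
#' single replicate goes to the training set with a warning. With 900
#' samples and `train_fraction = 0.75` this yields 675/225.
#'
#' @param targets Numeric vector of known concentrations (the levels).
#' @param train_fraction Fraction assigned to training (0 < f < 1).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
holdout_split <- function(targets, train_fraction = 0.75, seed = 42) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1")
  }
  lev <- unique(targets)
  n <- length(targets)
  n_train_total <- round(train_fraction * n)
  counts <- vapply(lev, function(l) sum(targets == l), 1L)
  base <- floor(train_fraction * counts)
  frac <- train_fraction * counts - base
  # every multi-replicate level keeps at least one sample on each side
  base <- pmin(pmax(base, ifelse(counts >= 2, 1L, counts)), counts - 1L)
  base[counts == 1] <- 1L
  extra <- n_train_total - sum(base)
  if (extra > 0) {
    ord <- order(-frac, seq_along(lev))
    ord <- ord[base[ord] < counts[ord] - (counts[ord] >= 2)]
    take <- head(ord, extra)
    base[take] <- base[take] + 1L
  } else if (extra < 0) {
    ord <- order(frac, seq_along(lev))
    ord <- ord[base[ord] > 1]
    take <- head(ord, -extra)
    base[take] <- base[take] - 1L
  }
  if (any(counts == 1)) {
    warning("levels with a single replicate were placed in the training set")
  }
  with_seed(seed, {
    train <- integer(0)
    for (i in seq_along(lev)) {
      idx <- which(targets == lev[i])
      take <- if (length(idx) == 1) idx else sort(sample(idx, base[i]))
      train <- c(train, take)
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Concentration-stratified k-fold assignment
#'
#' Shuffles the replicates of each level and deals them into folds with a
#' rotating pointer carried across levels, so folds are stratified and the
#' overall fold sizes differ by at most one.
#'
#' @param targets Numeric concentration vector.
#' @param k Number of folds (2 <= k <= length(targets)).
#' @param seed Integer seed.
#' @return Integer fold label (1..k) per sample.
#' @export
kfold_assign <- function(targets, k, seed = 42) {
  n <- length(targets)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k must not exceed the number of samples")
  with_seed(seed, {
    folds <- integer(n)
    pointer <- 0L
    for (l in unique(targets)) {
      idx <- which(targets == l)
      idx <- idx[sample.int(length(idx))]
      for (i in idx) {
        folds[i] <- (pointer %% k) + 1L
        pointer <- pointer + 1L
      }
    }
    folds
  })
}

#' k-fold cross-validation of an Rprop+-trained network
#'
#' Trains one network per fold on the remaining folds (inputs standardized
#' with the training folds' [score_scaler()]) and evaluates RMSE and the
#' coefficient of determination on the held-out fold.
#'
#' @param scores Input matrix (samples x PC scores).
#' @param targets Concentration vector, ng/ml.
#' @param hidden_sizes Hidden-layer widths (e.g. [mlp_architecture()]).
#' @param config A [train_config()].
#' @param k Number of folds.
#' @param seed Integer seed (fold assignment and weight initialization).
#' @param trace If `TRUE`, the held-fold mean-squared error is recorded at
#'   every epoch; the result then also contains the epoch-by-fold `trace`
#'   matrix and `best_epoch`, the epoch minimizing the mean held-fold
#'   error — the cross-validated early-stopping point used by
#'   [sers_calibrate()]. Fold metrics are then reported at `best_epoch`.
#' @return List with the per-fold data frame `folds` and the summary
#'   statistics `rmse_mean`, `rmse_sd`, `r2_mean`, `r2_sd` (plus `trace`
#'   and `best_epoch` when `trace = TRUE`).
#' @export
kfold_cv <- function(scores, targets, hidden_sizes, config = train_config(),
                     k = 4, seed = 42, trace = FALSE) {
  scores <- as.matrix(scores)
  assign <- kfold_assign(targets, k, seed)
  traces <- vector("list", k)
  rows <- lapply(seq_len(k), function(f) {
    tr <- assign != f
    scl <- score_scaler(scores[tr, , drop = FALSE])
    sc <- apply_score_scaler(scores[tr, , drop = FALSE], scl)
    model <- mlp_init(ncol(scores), hidden_sizes, seed = seed + f)
    te <- apply_score_scaler(scores[!tr, , drop = FALSE], scl)
    model <- mlp_train(model, sc, targets[tr], config,
                       validation = if (trace) {
                         list(X = te, y = targets[!tr])
                       } else NULL)
    if (trace) traces[[f]] <<- model$validation_history
    pred <- mlp_forward(model, te)
    data.frame(fold = f,
               rmse = rmse(pred, targets[!tr]),
               r2 = r_squared(pred, targets[!tr]))
  })
  folds <- do.call(rbind, rows)
  out <- list(folds = folds)
  if (trace) {
    # pad each fold's trace forward to a common length, then average
    len <- max(lengths(traces))
    tmat <- vapply(traces, function(tt) {
      c(tt, rep(tt[length(tt)], len - length(tt)))
    }, numeric(len))
    best_epoch <- which.min(rowMeans(tmat))
    # fold metrics at the cross-validated stopping epoch
    fold_var <- vapply(seq_len(k), function(f) {
      yv <- targets[assign == f]
      mean((yv - mean(yv))^2)
    }, 1)
    mse_best <- vapply(seq_len(k), function(f) {
      tt <- traces[[f]]
      tt[min(best_epoch, length(tt))]
    }, 1)
    out$folds$rmse <- sqrt(mse_best)
    out$folds$r2 <- 1 - mse_best / fold_var
    out$trace <- tmat
    out$best_epoch <- best_epoch
  }
  out$rmse_mean <- mean(out$folds$rmse)
  out$rmse_sd <- stats::sd(out$folds$rmse)
  out$r2_mean <- mean(out$folds$r2)
  out$r2_sd <- stats::sd(out$folds$r2)
  out
}
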