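# Backpropagation regressor for texture prediction, with optional particle
# swarm (PSO) or real-coded genetic algorithm (GA) selection of the initial
# weights and biases.
#
# Architecture: 4 inputs (L*, a*, b*, contrast) -> sigmoid hidden layer ->
# linear output (one texture attribute at a time).  Training is full-batch
# gradient descent on mean squared error, stopping at `min_error` or
# `max_iters`.  Features and target are min-max scaled to [0, 1] using
# statistics of the training split only.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialize a backpropagation network
#'
#' Weights and biases are drawn uniformly from `[-1, 1]`, deterministically
#' for a given seed.
#'
#' @param n_hidden Number of hidden nodes, >= 1.
#' @param seed Integer seed, or `NULL` for the current RNG stream.
#' @param n_in,n_out Input/output widths (4 image features -> 1 attribute).
#' @return An object of class `bp_network` with weight matrices `W1`
#'   (`n_in x n_hidden`), `W2` (`n_hidden x n_out`) and bias vectors
#'   `b1`, `b2`.
#' @export
init_network <- function(n_hidden, seed = NULL, n_in = 4L, n_out = 1L) {
  check_number(n_hidden, "n_hidden", lower = 1)
  with_seed(seed, {
    structure(
      list(W1 = matrix(stats::runif(n_in * n_hidden, -1, 1), n_in, n_hidden),
           b1 = stats::runif(n_hidden, -1, 1),
           W2 = matrix(stats::runif(n_hidden * n_out, -1, 1), n_hidden, n_out),
           b2 = stats::runif(n_out, -1, 1),
           n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
           n_out = as.integer(n_out), activation = "sigmoid"),
      class = "bp_network")
  })
}

#' Hidden-layer sizing rule
#'
#' The common empirical rule `h = round(sqrt(n_in + n_out)) + a` with the
#' additive constant `a` chosen on a validation split (see
#' [select_hidden_nodes()]).
#'
#' @param a Additive constant, typically in 1..10.
#' @param n_in,n_out Layer widths.
#' @return Number of hidden nodes.
#' @export
hidden_nodes_rule <- function(a, n_in = 4L, n_out = 1L) {
  if (!is.numeric(a) || length(a) == 0L || any(!is.finite(a)) || any(a < 0)) {
    abort("`a` must be non-negative and finite", "extrurtd_domain_error")
  }
  as.integer(round(sqrt(n_in + n_out)) + a)
}

#' Forward pass through the network
#'
#' @param net A [init_network()] (possibly trained) network.
#' @param X Feature matrix `n x n_in` (a length-`n_in` vector is treated as
#'   one sample), scaled like the training data.
#' @return Numeric vector of predictions.
#' @export
forward <- function(net, X) {
  stopifnot(inherits(net, "bp_network"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != net$n_in) {
    abort(sprintf("expected %d input features, got %d", net$n_in, ncol(X)),
          "extrurtd_domain_error")
  }
  H <- sigmoid(sweep(X %*% net$W1, 2L, net$b1, "+"))
  drop(sweep(H %*% net$W2, 2L, net$b2, "+"))
}

#' Training configuration
#'
#' Defaults follow the usual settings for this kind of model: learning rate
#' 0.01, minimum error 1e-5, at most 1000 iterations, 90 training and 28
#' test samples.
#'
#' @param learning_rate Gradient descent step size.
#' @param min_error Stop when training MSE falls below this.
#' @param max_iters Iteration cap.
#' @param n_train,n_test Split sizes.
#' @param seed Integer seed for the split/initialization/optimizer stream.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, min_error = 1e-5,
                         max_iters = 1000L, n_train = 90L, n_test = 28L,
                         seed = NULL) {
  check_number(learning_rate, "learning_rate", lower = 0, strict_lower = TRUE)
  check_number(min_error, "min_error", lower = 0, strict_lower = TRUE)
  check_number(max_iters, "max_iters", lower = 1)
  check_number(n_train, "n_train", lower = 1)
  check_number(n_test, "n_test", lower = 1)
  structure(list(learning_rate = learning_rate, min_error = min_error,
                 max_iters = as.integer(max_iters),
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 seed = seed),
            class = "train_config")
}

# MSE loss and its analytic gradients for the 1-hidden-layer network.
bp_loss_grad <- function(net, X, y, want_grad = TRUE) {
  n <- nrow(X)
  H <- sigmoid(sweep(X %*% net$W1, 2L, net$b1, "+"))
  pred <- sweep(H %*% net$W2, 2L, net$b2, "+")
  r <- pred - y
  loss <- mean(r^2)
  if (!want_grad) return(list(loss = loss))
  g_out <- 2 * r / n                       # n x n_out
  gW2 <- crossprod(H, g_out)               # n_hidden x n_out
  gb2 <- colSums(g_out)
  dH <- g_out %*% t(net$W2) * H * (1 - H)  # n x n_hidden
  gW1 <- crossprod(X, dH)
  gb1 <- colSums(dH)
  list(loss = loss, gW1 = gW1, gb1 = gb1, gW2 = gW2, gb2 = gb2)
}

#' Train a network by batch gradient descent
#'
#' Full-batch gradient descent on the mean squared error, stopping when the
#' loss drops below `config$min_error` or after `config$max_iters`
#' iterations.
#'
#' @param net Initial [init_network()] parameters.
#' @param X Scaled feature matrix `n x n_in`.
#' @param y Scaled target vector, length `n`.
#' @param config A [train_config()].
#' @return List with the trained `net`, the `loss_trace`, the number of
#'   `iterations` run and a `converged` flag.
#' @export
train_bp <- function(net, X, y, config = train_config()) {
  stopifnot(inherits(net, "bp_network"), inherits(config, "train_config"))
  X <- as.matrix(X)
  y <- matrix(y, ncol = net$n_out)
  if (nrow(X) != nrow(y)) {
    abort("X and y disagree on the number of samples", "extrurtd_domain_error")
  }
  lr <- config$learning_rate
  trace <- numeric(config$max_iters)
  iters <- 0L
  converged <- FALSE
  for (i in seq_len(config$max_iters)) {
    g <- bp_loss_grad(net, X, y)
    if (!is.finite(g$loss)) {
      abort(sprintf(
        "training diverged (loss is not finite); lower the learning rate (currently %g)",
        lr), "extrurtd_divergence")
    }
    trace[i] <- g$loss
    iters <- i
    if (g$loss < config$min_error) {
      converged <- TRUE
      break
    }
    net$W1 <- net$W1 - lr * g$gW1
    net$b1 <- net$b1 - lr * g$gb1
    net$W2 <- net$W2 - lr * g$gW2
    net$b2 <- net$b2 - lr * g$gb2
  }
  list(net = net, loss_trace = trace[seq_len(iters)], iterations = iters,
       converged = converged)
}

# Flatten network parameters to a vector and back (for PSO/GA).
flatten_params <- function(net) {
  c(as.vector(net$W1), net$b1, as.vector(net$W2), net$b2)
}

unflatten_params <- function(net, v) {
  sizes <- c(net$n_in * net$n_hidden, net$n_hidden,
             net$n_hidden * net$n_out, net$n_out)
  stopifnot(length(v) == sum(sizes))
  ends <- cumsum(sizes)
  net$W1 <- matrix(v[seq_len(ends[1L])], net$n_in, net$n_hidden)
  net$b1 <- v[(ends[1L] + 1L):ends[2L]]
  net$W2 <- matrix(v[(ends[2L] + 1L):ends[3L]], net$n_hidden, net$n_out)
  net$b2 <- v[(ends[3L] + 1L):ends[4L]]
  net
}

#' Minimize a function by particle swarm optimization
#'
#' Canonical PSO: each particle's velocity mixes inertia (`w`), attraction
#' to its personal best (`c1`) and to the swarm's global best (`c2`).
#'
#' @param fn Objective, `fn(x) -> scalar`; minimized.
#' @param dim Dimension of the search space.
#' @param n_particles Swarm size, >= 1 (default 30).
#' @param iters Number of iterations (default 50).
#' @param w,c1,c2 Inertia, cognitive and social coefficients
#'   (defaults 0.8, 1.5, 1.5).
#' @param init_range Range for uniform position initialization.
#' @param vmax Per-component velocity clamp; defaults to a quarter of the
#'   initialization range, which keeps the swarm from overshooting once it
#'   has localized the optimum.
#' @param seed Integer seed, or `NULL`.
#' @return List with `par` (best position), `value` (best objective) and
#'   `trace` (best value per iteration).
#' @export
pso_minimize <- function(fn, dim, n_particles = 30L, iters = 50L,
                         w = 0.8, c1 = 1.5, c2 = 1.5,
                         init_range = c(-1, 1), vmax = NULL,
                         seed = NULL) {
  check_number(dim, "dim", lower = 1)
  check_number(n_particles, "n_particles", lower = 1)
  check_number(iters, "iters", lower = 1)
  if (is.null(vmax)) vmax <- 0.25 * diff(init_range)
  with_seed(seed, {
    pos <- matrix(stats::runif(n_particles * dim, init_range[1L],
                               init_range[2L]), n_particles, dim)
    vel <- matrix(0, n_particles, dim)
    fit <- apply(pos, 1L, fn)
    pbest <- pos
    pbest_fit <- fit
    g <- which.min(fit)
    gbest <- pos[g, ]
    gbest_fit <- fit[g]
    trace <- numeric(iters)
    for (it in seq_len(iters)) {
      r1 <- matrix(stats::runif(n_particles * dim), n_particles, dim)
      r2 <- matrix(stats::runif(n_particles * dim), n_particles, dim)
      vel <- w * vel + c1 * r1 * (pbest - pos) +
        c2 * r2 * sweep(-pos, 2L, gbest, "+")
      vel <- pmin(pmax(vel, -vmax), vmax)
      pos <- pos + vel
      fit <- apply(pos, 1L, fn)
      improved <- fit < pbest_fit
      pbest[improved, ] <- pos[improved, , drop = FALSE]
      pbest_fit[improved] <- fit[improved]
      g <- which.min(pbest_fit)
      if (pbest_fit[g] < gbest_fit) {
        gbest <- pbest[g, ]
        gbest_fit <- pbest_fit[g]
      }
      trace[it] <- gbest_fit
    }
    list(par = gbest, value = gbest_fit, trace = trace)
  })
}

#' Minimize a function by a real-coded genetic algorithm
#'
#' Tournament selection, arithmetic crossover, Gaussian mutation and
#' single-individual elitism over a real-valued chromosome.
#'
#' @param fn Objective, minimized.
#' @param dim Chromosome length.
#' @param pop_size Population size, >= 2 (default 30).
#' @param generations Number of generations (default 50).
#' @param p_crossover Per-pair crossover probability (default 0.8).
#' @param p_mutation Per-gene mutation probability (default 0.05).
#' @param mutation_sd Gaussian mutation standard deviation (default 0.1).
#' @param anneal Shrink the mutation scale linearly to zero over the
#'   generations (non-uniform mutation; default `TRUE`), trading late
#'   exploration for refinement.
#' @param init_range Range for uniform initialization.
#' @param seed Integer seed, or `NULL`.
#' @return List with `par`, `value` and `trace` (best value per
#'   generation, nonincreasing thanks to elitism).
#' @export
ga_minimize <- function(fn, dim, pop_size = 30L, generations = 50L,
                        p_crossover = 0.8, p_mutation = 0.05,
                        mutation_sd = 0.1, anneal = TRUE,
                        init_range = c(-1, 1), seed = NULL) {
  check_number(dim, "dim", lower = 1)
  check_number(pop_size, "pop_size", lower = 2)
  check_number(generations, "generations", lower = 1)
  with_seed(seed, {
    pop <- matrix(stats::runif(pop_size * dim, init_range[1L], init_range[2L]),
                  pop_size, dim)
    fit <- apply(pop, 1L, fn)
    trace <- numeric(generations)
    for (gen in seq_len(generations)) {
      elite_idx <- which.min(fit)
      elite <- pop[elite_idx, ]
      elite_fit <- fit[elite_idx]
      tournament <- function() {
        cand <- sample.int(pop_size, 2L)
        cand[which.min(fit[cand])]
      }
      children <- matrix(0, pop_size, dim)
      for (k in seq(1L, pop_size, by = 2L)) {
        p1 <- pop[tournament(), ]
        p2 <- pop[tournament(), ]
        if (stats::runif(1) < p_crossover) {
          a <- stats::runif(dim)
          c1 <- a * p1 + (1 - a) * p2
          c2 <- a * p2 + (1 - a) * p1
        } else {
          c1 <- p1
          c2 <- p2
        }
        children[k, ] <- c1
        if (k + 1L <= pop_size) children[k + 1L, ] <- c2
      }
      if (p_mutation > 0) {
        sd_gen <- if (anneal) {
          mutation_sd * (1 - (gen - 1) / generations)
        } else {
          mutation_sd
        }
        mut <- matrix(stats::runif(pop_size * dim) < p_mutation,
                      pop_size, dim)
        children[mut] <- children[mut] +
          stats::rnorm(sum(mut), 0, sd_gen)
      }
      children[1L, ] <- elite  # elitism
      pop <- children
      fit <- apply(pop, 1L, fn)
      if (fit[1L] > elite_fit) {
        # guard against an unlucky evaluation ordering; elite is exact
        fit[1L] <- elite_fit
        pop[1L, ] <- elite
      }
      trace[gen] <- min(fit)
    }
    best <- which.min(fit)
    list(par = pop[best, ], value = fit[best], trace = trace)
  })
}

# Fitness used by both optimizers: training-set MSE of the candidate
# parameter vector (forward pass only; no gradient steps).
make_fitness <- function(net, X, y) {
  y <- matrix(y, ncol = net$n_out)
  function(v) {
    cand <- unflatten_params(net, v)
    mean((forward(cand, X) - y)^2)
  }
}

#' Choose initial network weights by particle swarm optimization
#'
#' Runs [pso_minimize()] over the flattened weight/bias vector with
#' training-set MSE as the fitness, and returns the best candidate as the
#' network's initial parameters (to be refined by [train_bp()]).
#'
#' @param X,y Scaled training data.
#' @param net Template network (defines the architecture).
#' @param pso_params Named list overriding [pso_minimize()] defaults.
#' @param seed Integer seed, or `NULL`.
#' @return A `bp_network` carrying the optimized initial parameters.
#' @export
optimize_pso <- function(X, y, net, pso_params = list(), seed = NULL) {
  stopifnot(inherits(net, "bp_network"))
  fn <- make_fitness(net, as.matrix(X), y)
  args <- utils::modifyList(
    list(fn = fn, dim = length(flatten_params(net)), seed = seed),
    pso_params)
  res <- do.call(pso_minimize, args)
  unflatten_params(net, res$par)
}

#' Choose initial network weights by a genetic algorithm
#'
#' As [optimize_pso()], but with [ga_minimize()].
#'
#' @inheritParams optimize_pso
#' @param ga_params Named list overriding [ga_minimize()] defaults.
#' @return A `bp_network` carrying the optimized initial parameters.
#' @export
optimize_ga <- function(X, y, net, ga_params = list(), seed = NULL) {
  stopifnot(inherits(net, "bp_network"))
  fn <- make_fitness(net, as.matrix(X), y)
  args <- utils::modifyList(
    list(fn = fn, dim = length(flatten_params(net)), seed = seed),
    ga_params)
  res <- do.call(ga_minimize, args)
  unflatten_params(net, res$par)
}

#' Prediction error metrics
#'
#' MAE, RMSE, MAPE (in percent) and the Pearson correlation between
#' predictions and actual values.
#'
#' @param predictions,actuals Equal-length numeric vectors, length >= 2.
#' @param zero_action What to do when an actual value is exactly zero
#'   (MAPE undefined): `"error"` (default) or `"exclude"` those samples
#'   from MAPE only.
#' @return An object of class `metric_report` with fields `mae`, `rmse`,
#'   `mape`, `r` and `n`.
#' @export
evaluate <- function(predictions, actuals,
                     zero_action = c("error", "exclude")) {
  zero_action <- match.arg(zero_action)
  if (!is.numeric(predictions) || !is.numeric(actuals) ||
      length(predictions) != length(actuals) || length(actuals) < 2L ||
      any(!is.finite(predictions)) || any(!is.finite(actuals))) {
    abort("predictions and actuals must be finite vectors of equal length >= 2",
          "extrurtd_domain_error")
  }
  e <- predictions - actuals
  mae <- mean(abs(e))
  rmse <- sqrt(mean(e^2))
  nz <- actuals != 0
  if (!all(nz) && zero_action == "error") {
    abort("actuals contain zeros: MAPE is undefined (use zero_action = 'exclude')",
          "extrurtd_domain_error")
  }
  mape <- 100 * mean(abs(e[nz] / actuals[nz]))
  r <- if (stats::sd(predictions) == 0 || stats::sd(actuals) == 0) {
    NA_real_
  } else {
    stats::cor(predictions, actuals)
  }
  structure(list(mae = mae, rmse = rmse, mape = mape, r = r,
                 n = length(actuals)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> n = %d\n", x$n))
  cat(sprintf("  MAE  %.6g\n  RMSE %.6g\n  MAPE %.4g%%\n  r    %.5f\n",
              x$mae, x$rmse, x$mape, x$r))
  invisible(x)
}

# Min-max scaler fitted on training data only.
fit_scaler <- function(X) {
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  span <- hi - lo
  span[span == 0] <- 1
  list(min = lo, span = span)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(as.matrix(X), 2L, scaler$min, "-"), 2L, scaler$span, "/")
}

unscale_target <- function(scaler, z) z * scaler$span + scaler$min

#' Select the hidden-layer size on a validation split
#'
#' Grid search over the additive constant of [hidden_nodes_rule()]:
#' for each candidate `a`, a network is trained on the inner training
#' portion and scored (RMSE) on a held-out validation portion.
#'
#' @param X,y Scaled training data.
#' @param config A [train_config()] (its `max_iters`/`learning_rate` are
#'   used for the candidate fits).
#' @param a_grid Candidate additive constants (default 1..10).
#' @param val_frac Fraction of the data held out for validation.
#' @param seed Integer seed.
#' @return The selected number of hidden nodes.
#' @export
select_hidden_nodes <- function(X, y, config = train_config(),
                                a_grid = 1:10, val_frac = 0.2,
                                seed = NULL) {
  X <- as.matrix(X)
  with_seed(seed, {
    n <- nrow(X)
    n_val <- max(2L, floor(val_frac * n))
    idx <- sample.int(n)
    val <- idx[seq_len(n_val)]
    tr <- idx[-seq_len(n_val)]
    scores <- vapply(a_grid, function(a) {
      h <- hidden_nodes_rule(a, n_in = ncol(X))
      net <- init_network(h, n_in = ncol(X))
      fit <- train_bp(net, X[tr, , drop = FALSE], y[tr], config)
      sqrt(mean((forward(fit$net, X[val, , drop = FALSE]) - y[val])^2))
    }, numeric(1))
    hidden_nodes_rule(a_grid[which.min(scores)], n_in = ncol(X))
  })
}

#' Run one train/test texture-prediction experiment
#'
#' Splits the dataset, fits the min-max scaler on the training split only,
#' optionally chooses the initial weights by PSO or GA, trains the network
#' by backpropagation, and reports test-set metrics on the original scale.
#'
#' @param dataset Data frame with columns `L_star, a_star, b_star,
#'   contrast` and the target attribute.
#' @param attribute Name of the target column (e.g. `"hardness"`).
#' @param optimizer `"none"`, `"pso"` or `"ga"`.
#' @param config A [train_config()]; its `seed` drives the split,
#'   initialization and optimizer.
#' @param n_hidden Hidden-layer size; `NULL` selects it with
#'   [select_hidden_nodes()].
#' @param pso_params,ga_params Optional overrides for the optimizers.
#' @return An object of class `texture_fit`: `metrics`
#'   (a [evaluate()] report), `deviations` (predicted - actual on the test
#'   split), `predictions`, `actuals`, `net`, `scalers`, `split`,
#'   `n_hidden`, `attribute`, `optimizer`, `loss_trace`.
#' @export
run_experiment <- function(dataset, attribute,
                           optimizer = c("none", "pso", "ga"),
                           config = train_config(), n_hidden = 6L,
                           pso_params = list(), ga_params = list()) {
  optimizer <- match.arg(optimizer)
  stopifnot(inherits(config, "train_config"))
  feats <- c("L_star", "a_star", "b_star", "contrast")
  missing_cols <- setdiff(c(feats, attribute), names(dataset))
  if (length(missing_cols) > 0L) {
    abort(sprintf("dataset is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          "extrurtd_domain_error")
  }
  n <- nrow(dataset)
  if (n < config$n_train + config$n_test) {
    abort(sprintf("dataset has %d rows; need n_train + n_test = %d",
                  n, config$n_train + config$n_test),
          "extrurtd_domain_error")
  }
  X <- as.matrix(dataset[, feats])
  y <- dataset[[attribute]]
  with_seed(config$seed, {
    idx <- sample.int(n)
    train_idx <- idx[seq_len(config$n_train)]
    test_idx <- idx[config$n_train + seq_len(config$n_test)]
    x_scaler <- fit_scaler(X[train_idx, , drop = FALSE])
    y_scaler <- fit_scaler(matrix(y[train_idx], ncol = 1L))
    y_scaler <- list(min = y_scaler$min[1L], span = y_scaler$span[1L])
    Xtr <- apply_scaler(x_scaler, X[train_idx, , drop = FALSE])
    ytr <- (y[train_idx] - y_scaler$min) / y_scaler$span
    if (is.null(n_hidden)) {
      n_hidden <- select_hidden_nodes(Xtr, ytr, config)
    }
    net <- init_network(n_hidden)
    net <- switch(optimizer,
                  none = net,
                  pso = optimize_pso(Xtr, ytr, net, pso_params),
                  ga = optimize_ga(Xtr, ytr, net, ga_params))
    fit <- train_bp(net, Xtr, ytr, config)
    Xte <- apply_scaler(x_scaler, X[test_idx, , drop = FALSE])
    pred <- unscale_target(y_scaler, forward(fit$net, Xte))
    actual <- y[test_idx]
    structure(
      list(metrics = evaluate(pred, actual, zero_action = "exclude"),
           deviations = pred - actual,
           predictions = pred, actuals = actual,
           net = fit$net,
           scalers = list(x = x_scaler, y = y_scaler),
           split = list(train = train_idx, test = test_idx),
           n_hidden = n_hidden, attribute = attribute,
           optimizer = optimizer, loss_trace = fit$loss_trace),
      class = "texture_fit")
  })
}

#' @export
print.texture_fit <- function(x, ...) {
  cat(sprintf("<texture_fit> %s, optimizer = %s, %d hidden nodes\n",
              x$attribute, x$optimizer, x$n_hidden))
  print(x$metrics)
  invisible(x)
}

#' Save a fitted texture model as JSON
#'
#' Persists the network weights, the scalers and the metadata needed by
#' [predict_texture()].
#'
#' @param fit A [run_experiment()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "texture_fit"))
  obj <- list(
    attribute = fit$attribute,
    optimizer = fit$optimizer,
    n_hidden = fit$n_hidden,
    net = list(W1 = fit$net$W1, b1 = fit$net$b1,
               W2 = fit$net$W2, b2 = fit$net$b2,
               n_in = fit$net$n_in, n_hidden = fit$net$n_hidden,
               n_out = fit$net$n_out),
    scalers = fit$scalers)
  write_atomic(path, function(tmp) {
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
}

#' Load a texture model saved by [save_model()]
#'
#' @param path Path to the model JSON.
#' @return A list with the reconstructed `net`, `scalers` and metadata.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- structure(
    list(W1 = matrix(unlist(obj$net$W1), obj$net$n_in, obj$net$n_hidden),
         b1 = as.numeric(obj$net$b1),
         W2 = matrix(unlist(obj$net$W2), obj$net$n_hidden, obj$net$n_out),
         b2 = as.numeric(obj$net$b2),
         n_in = as.integer(obj$net$n_in),
         n_hidden = as.integer(obj$net$n_hidden),
         n_out = as.integer(obj$net$n_out),
         activation = "sigmoid"),
    class = "bp_network")
  scalers <- list(
    x = list(min = unlist(obj$scalers$x$min),
             span = unlist(obj$scalers$x$span)),
    y = list(min = as.numeric(obj$scalers$y$min),
             span = as.numeric(obj$scalers$y$span)))
  list(net = net, scalers = scalers, attribute = obj$attribute,
       optimizer = obj$optimizer, n_hidden = obj$n_hidden)
}

#' Predict a texture attribute for new image features
#'
#' @param model A [load_model()] result (or a `texture_fit`).
#' @param features Data frame with `L_star, a_star, b_star, contrast`.
#' @return Numeric vector of predictions on the original attribute scale.
#' @export
predict_texture <- function(model, features) {
  if (inherits(model, "texture_fit")) {
    model <- list(net = model$net, scalers = model$scalers)
  }
  feats <- c("L_star", "a_star", "b_star", "contrast")
  if (!all(feats %in% names(features))) {
    abort("features must contain L_star, a_star, b_star, contrast",
          "extrurtd_domain_error")
  }
  Xs <- apply_scaler(model$scalers$x, as.matrix(features[, feats]))
  unscale_target(model$scalers$y, forward(model$net, Xs))
}
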