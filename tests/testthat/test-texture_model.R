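# BP network, PSO/GA optimizers and the error metrics.

test_that("init_network is deterministic per seed with correct shapes", {
  n1 <- init_network(5, seed = 1)
  n2 <- init_network(5, seed = 1)
  expect_identical(n1, n2)
  expect_equal(dim(n1$W1), c(4L, 5L))
  expect_equal(length(n1$b1), 5L)
  expect_equal(dim(n1$W2), c(5L, 1L))
  expect_equal(length(n1$b2), 1L)
  expect_true(all(abs(unlist(n1[c("W1", "b1", "W2", "b2")])) <= 1))
})

test_that("hidden_nodes_rule follows sqrt(n_in + n_out) + a", {
  expect_equal(hidden_nodes_rule(1), 3L)   # round(sqrt(5)) + 1
  expect_equal(hidden_nodes_rule(10), 12L)
})

test_that("forward matches a pencil-and-paper two-node computation", {
  net <- init_network(2, seed = 3)
  net$W1 <- matrix(c(0.5, -0.25, 0.1, 0, 1, 0.2, -0.3, 0.4), 4, 2)
  net$b1 <- c(0.1, -0.2)
  net$W2 <- matrix(c(2, -1), 2, 1)
  net$b2 <- 0.5
  x <- c(0.2, 0.4, 0.6, 0.8)
  z <- as.numeric(t(net$W1) %*% x) + net$b1
  h <- 1 / (1 + exp(-z))
  expect_equal(forward(net, x), sum(h * c(2, -1)) + 0.5, tolerance = 1e-12)
  # zero weights: output equals the output bias
  net$W1[] <- 0
  net$b1[] <- 0
  net$W2[] <- 0
  expect_equal(forward(net, x), 0.5)
  expect_error(forward(net, c(1, 2)), class = "extrurtd_domain_error")
})

test_that("analytic gradients match central finite differences", {
  set.seed(31)
  for (rep in 1:3) {
    net <- init_network(sample(2:6, 1))
    X <- matrix(runif(10 * 4), 10, 4)
    y <- runif(10)
    g <- extrurtd:::bp_loss_grad(net, X, matrix(y, ncol = 1))
    analytic <- c(as.vector(g$gW1), g$gb1, as.vector(g$gW2), g$gb2)
    numeric_g <- fd_gradient(net, X, y)
    expect_lt(max(abs(analytic - numeric_g)), 1e-6)
  }
})

test_that("train_bp fits a noiseless linear target to small MAPE", {
  set.seed(12)
  n <- 118
  X <- matrix(runif(n * 4), n, 4)
  y <- X %*% c(0.3, 0.2, 0.25, 0.15) + 0.05
  net <- init_network(6, seed = 2)
  cfg <- train_config(learning_rate = 0.3, max_iters = 1000)
  fit <- train_bp(net, X[1:90, ], y[1:90], cfg)
  pred <- forward(fit$net, X[91:118, ])
  m <- evaluate(pred, as.numeric(y[91:118]))
  expect_lt(m$mape, 2)
})

test_that("train_bp converges to a constant on a repeated point", {
  X <- matrix(rep(c(0.2, 0.4, 0.6, 0.8), each = 20), 20, 4)
  y <- rep(0.7, 20)
  fit <- train_bp(init_network(3, seed = 4), X, y,
                  train_config(learning_rate = 0.3, max_iters = 2000))
  # min_error 1e-5 on the MSE bounds the prediction error by ~3e-3
  expect_equal(unique(forward(fit$net, X)), 0.7, tolerance = 5e-3)
  expect_true(fit$converged)
})

test_that("train_bp loss trace decreases and divergence is typed", {
  set.seed(9)
  X <- matrix(runif(40 * 4), 40, 4)
  y <- runif(40)
  fit <- train_bp(init_network(4, seed = 1), X, y,
                  train_config(learning_rate = 0.1, max_iters = 300))
  expect_lt(fit$loss_trace[length(fit$loss_trace)], fit$loss_trace[1])
  expect_error(
    train_bp(init_network(4, seed = 1), X, 1e6 * y,
             train_config(learning_rate = 1e6, max_iters = 50)),
    regexp = "learning rate")
})

test_that("PSO solves the 10-d sphere and degenerates gracefully", {
  sphere <- function(x) sum(x^2)
  res <- pso_minimize(sphere, dim = 10, n_particles = 30, iters = 100,
                      seed = 7)
  expect_lt(res$value, 1e-3)
  # a single particle with zero velocity stays at its initialization
  res1 <- pso_minimize(sphere, dim = 3, n_particles = 1, iters = 20,
                       seed = 11)
  init <- extrurtd:::with_seed(11, matrix(stats::runif(3, -1, 1), 1, 3))
  expect_equal(res1$par, as.numeric(init))
  # seeded runs are reproducible
  expect_identical(pso_minimize(sphere, 5, iters = 30, seed = 2)$par,
                   pso_minimize(sphere, 5, iters = 30, seed = 2)$par)
})

test_that("GA solves the 10-d sphere and elitism is monotone", {
  sphere <- function(x) sum(x^2)
  res <- ga_minimize(sphere, dim = 10, pop_size = 30, generations = 100,
                     seed = 7)
  expect_lt(res$value, 1e-3)
  # without crossover and mutation the best fitness never worsens
  res2 <- ga_minimize(sphere, dim = 5, pop_size = 10, generations = 30,
                      p_crossover = 0, p_mutation = 0, seed = 3)
  expect_true(all(diff(res2$trace) <= 0))
  expect_identical(ga_minimize(sphere, 5, generations = 20, seed = 2)$par,
                   ga_minimize(sphere, 5, generations = 20, seed = 2)$par)
})

test_that("evaluate reproduces the hand-computed metrics", {
  m <- evaluate(c(2, 4), c(1, 2))
  expect_equal(m$mae, 1.5)
  expect_equal(m$rmse, sqrt(2.5))
  # |2-1|/1 and |4-2|/2 both equal 1, so MAPE is 100%
  expect_equal(m$mape, 100)
  perfect <- evaluate(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mape, 0)
  expect_equal(perfect$r, 1)
  expect_equal(evaluate(c(3, 2, 1), c(1, 2, 3))$r, -1)
  expect_error(evaluate(c(1, 2), c(0, 2)), class = "extrurtd_domain_error")
  expect_equal(evaluate(c(1, 2), c(0, 2), zero_action = "exclude")$mape, 0)
})

test_that("RMSE >= MAE on random prediction pairs (property)", {
  set.seed(14)
  for (i in 1:20) {
    p <- rnorm(15)
    a <- rnorm(15, 1)
    m <- evaluate(p, a)
    expect_gte(m$rmse, m$mae)
  }
})

test_that("run_experiment splits disjointly and never leaks test data", {
  spec <- synth_dataset_spec(seed = 100)
  dat <- generate_dataset(spec)
  cfg <- train_config(learning_rate = 0.8, max_iters = 400, seed = 77)
  fit <- run_experiment(dat, "hardness", config = cfg)
  expect_length(intersect(fit$split$train, fit$split$test), 0)
  expect_length(fit$split$test, 28)
  # scaler depends only on the training rows
  dat2 <- dat
  dat2[fit$split$test, c("L_star", "a_star", "b_star", "contrast")] <-
    dat2[fit$split$test, c("L_star", "a_star", "b_star", "contrast")] * 3
  fit2 <- run_experiment(dat2, "hardness", config = cfg)
  expect_identical(fit$scalers, fit2$scalers)
  # seeded runs reproduce metrics exactly
  fit3 <- run_experiment(dat, "hardness", config = cfg)
  expect_identical(fit$metrics, fit3$metrics)
  expect_error(run_experiment(dat[1:50, ], "hardness", config = cfg),
               class = "extrurtd_domain_error")
  expect_error(run_experiment(dat, "nope", config = cfg),
               class = "extrurtd_domain_error")
})

test_that("optimized initial weights do not hurt median test RMSE", {
  # default config (learning rate 0.01, 1000 iterations): plain BP is
  # slow off a random start, which is exactly the regime the optimized
  # initializations are meant to fix
  dat <- generate_dataset(synth_dataset_spec(seed = 8))
  seeds <- 1:6
  rmse <- sapply(seeds, function(s) {
    cfg <- train_config(seed = s)
    c(none = run_experiment(dat, "hardness", "none", cfg)$metrics$rmse,
      pso = run_experiment(dat, "hardness", "pso", cfg)$metrics$rmse,
      ga = run_experiment(dat, "hardness", "ga", cfg)$metrics$rmse)
  })
  expect_lte(median(rmse["pso", ]), median(rmse["none", ]))
  expect_lte(median(rmse["ga", ]), median(rmse["none", ]))
})

test_that("models survive a JSON save/load round trip", {
  dat <- generate_dataset(synth_dataset_spec(seed = 10))
  cfg <- train_config(learning_rate = 0.8, max_iters = 300, seed = 5)
  fit <- run_experiment(dat, "chewiness", config = cfg)
  path <- tempfile(fileext = ".json")
  save_model(fit, path)
  model <- load_model(path)
  expect_equal(predict_texture(model, dat[1:10, ]),
               predict_texture(fit, dat[1:10, ]), tolerance = 1e-12)
  expect_equal(model$attribute, "chewiness")
})

test_that("select_hidden_nodes returns a rule-consistent size", {
  dat <- generate_dataset(synth_dataset_spec(n_samples = 60, seed = 3))
  X <- as.matrix(dat[, c("L_star", "a_star", "b_star", "contrast")])
  sc <- extrurtd:::fit_scaler(X)
  Xs <- extrurtd:::apply_scaler(sc, X)
  ys <- (dat$hardness - min(dat$hardness)) /
    (max(dat$hardness) - min(dat$hardness))
  h <- select_hidden_nodes(Xs, ys,
                           train_config(learning_rate = 0.5,
                                        max_iters = 60),
                           a_grid = c(1, 4, 8), seed = 1)
  expect_true(h %in% hidden_nodes_rule(c(1, 4, 8)))
})
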