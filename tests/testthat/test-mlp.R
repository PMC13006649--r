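test_that("the default architecture has the stated layer widths", {
  m <- build_model(mlp_config(), seed = 1)
  dims <- vapply(m$W, dim, integer(2))
  expect_equal(dims[1, ], c(60L, 1024L, 512L, 256L, 128L))
  expect_equal(dims[2, ], c(1024L, 512L, 256L, 128L, 1L))
  expect_equal(lengths(m$b), c(1024L, 512L, 256L, 128L, 1L))
})

test_that("config validation rejects inconsistent sizes", {
  expect_error(mlp_config(input_size = 0), "input_size")
  expect_error(mlp_config(hidden_sizes = integer(0)), "hidden_sizes")
  expect_error(mlp_config(output_size = 2), "fixed at 1")
})

test_that("zero parameters map any window to zero", {
  m <- build_model(mlp_config(hidden_sizes = c(8L, 4L)), seed = 1)
  m$W <- lapply(m$W, function(w) w * 0)
  expect_equal(predict_baseline(m, rep(0, 60)), 0)
  expect_equal(predict_baseline(m, rep(50, 60)), 0)
})

test_that("initialization is deterministic in the seed", {
  a <- build_model(mlp_config(hidden_sizes = c(16L, 8L)), seed = 5)
  b <- build_model(mlp_config(hidden_sizes = c(16L, 8L)), seed = 5)
  c_ <- build_model(mlp_config(hidden_sizes = c(16L, 8L)), seed = 6)
  expect_identical(a$W, b$W)
  expect_false(identical(a$W, c_$W))
})

test_that("prediction validates its input", {
  m <- build_model(mlp_config(hidden_sizes = c(8L)), seed = 1)
  expect_error(predict_baseline(m, rep(30, 59)), "exactly 60")
  expect_error(predict_baseline(m, c(rep(30, 59), NA)), "finite")
})

test_that("batch prediction equals element-wise single predictions", {
  m <- quick_model()
  ds <- generate_dataset(20, seed = 31)
  batch <- predict_baseline(m, ds$x)
  single <- vapply(seq_len(20),
                   function(i) predict_baseline(m, ds$x[i, ]), numeric(1))
  expect_equal(batch, single, tolerance = 1e-12)
  # stateless: repeated calls agree
  expect_identical(predict_baseline(m, ds$x[1, ]),
                   predict_baseline(m, ds$x[1, ]))
})

test_that("training memorizes a constant map to near-zero loss", {
  x <- matrix(30, nrow = 64, ncol = 60)
  y <- rep(30, 64)
  m <- build_model(mlp_config(hidden_sizes = c(16L, 8L)), seed = 2)
  m <- train_baseline_model(m, list(x = x, y = y),
                            training_config(epochs = 200, batch_size = 32,
                                            val_fraction = 0, seed = 2))
  expect_lt(m$training_meta$final_train_loss, 1e-4)
  expect_equal(predict_baseline(m, rep(30, 60)), 30, tolerance = 0.2)
})

test_that("training rejects empty or inconsistent data and flags divergence", {
  m <- build_model(mlp_config(hidden_sizes = c(8L)), seed = 1)
  expect_error(train_baseline_model(m, list(x = matrix(0, 0, 60),
                                            y = numeric(0))),
               "at least one window")
  expect_error(train_baseline_model(m, list(x = matrix(1, 4, 10),
                                            y = rep(1, 4))),
               "input size")
  x <- matrix(NA_real_, 4, 60)
  expect_error(train_baseline_model(m, list(x = x, y = rep(1, 4))),
               "finite")
})

test_that("metrics match hand-computed values and a brute-force oracle", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$mse, 1 / 3)
  expect_equal(m$r2, 0.5)  # 1 - (1/3)/(2/3)
  # perfect fit and mean predictor
  expect_equal(regression_metrics(1:10, 1:10)$r2, 1)
  expect_equal(regression_metrics(1:10, 1:10)$mse, 0)
  expect_equal(regression_metrics(1:10, rep(5.5, 10))$r2, 0)
  # 100 random pairs against an independent computation
  set.seed(77)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    y <- rnorm(n, 50, 10); p <- y + rnorm(n, 0, 3)
    got <- regression_metrics(y, p)
    expect_equal(got$mse, sum((y - p)^2) / n, tolerance = 1e-10)
    expect_equal(got$r2,
                 1 - sum((y - p)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-10)
  }
})

test_that("zero-variance labels yield a flagged NA r2, not a silent NaN", {
  m <- regression_metrics(rep(5, 4), c(5, 5, 5, 6))
  expect_true(is.na(m$r2))
  expect_true(m$zero_variance_labels)
  expect_false(is.nan(m$r2))
})

test_that("a converged model recovers flat baselines within 0.5 %DO", {
  m <- flat_model()
  # constant windows at several levels: label is the level by construction
  for (level in c(20, 30, 50)) {
    expect_equal(predict_baseline(m, rep(level, 60)), level,
                 tolerance = 0.5)
  }
})

test_that("a model cannot fit shuffled labels out of sample", {
  ds <- generate_dataset(2000, seed = 17)
  set.seed(17)
  ds$y <- sample(ds$y)  # destroy the signal
  sp <- split_dataset(ds, 0.5, seed = 17)
  m <- build_model(mlp_config(hidden_sizes = c(64L, 32L)), seed = 4)
  m <- train_baseline_model(m, sp$train,
                            training_config(epochs = 15, batch_size = 128,
                                            seed = 4))
  expect_lt(evaluate_model(m, sp$test)$r2, 0.2)
})

test_that("save/load round-trips predictions bit for bit", {
  m <- quick_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  ds <- generate_dataset(10, seed = 55)
  expect_identical(predict_baseline(m, ds$x), predict_baseline(m2, ds$x))
  expect_equal(m2$normalization, m$normalization)
})

test_that("corrupt or foreign checkpoints produce explicit errors", {
  path <- withr::local_tempfile(fileext = ".rds")
  writeLines("this is not a checkpoint", path)
  expect_error(load_model(path), "not a readable model checkpoint")
  saveRDS(list(something = "else"), path)
  expect_error(load_model(path), "checkpoint")
  expect_error(load_model(file.path(tempdir(), "absent.rds")), "no such file")
})

test_that("evaluation agrees between dataset call and direct metrics", {
  m <- quick_model()
  ds <- generate_dataset(200, seed = 41)
  ev <- evaluate_model(m, ds)
  pred <- predict_baseline(m, ds$x)
  expect_equal(ev$mse, mean((ds$y - pred)^2), tolerance = 1e-12)
  expect_equal(ev$n, 200)
})

test_that("fast and reference backends optimize the same objective", {
  ds <- generate_dataset(600, seed = 21)
  cfg <- training_config(epochs = 20, batch_size = 64, val_fraction = 0,
                         seed = 21, input_jitter = 0, level_shift = 0)
  m0 <- build_model(mlp_config(hidden_sizes = c(32L, 16L)), seed = 8)
  mf <- train_baseline_model(m0, ds, cfg, backend = "fast")
  mr <- train_baseline_model(m0, ds, cfg, backend = "reference")
  ef <- evaluate_model(mf, ds)
  er <- evaluate_model(mr, ds)
  # same algorithm, different shuffling streams and precision: the final
  # training losses must agree to within a small factor
  expect_lt(ef$mse, er$mse * 2 + 0.5)
  expect_lt(er$mse, ef$mse * 2 + 0.5)
  expect_gt(ef$r2, 0.9)
  expect_gt(er$r2, 0.9)
})

test_that("input noise degrades a noise-trained model only marginally", {
  m <- quick_model()
  ds <- generate_dataset(1500, seed = 88)
  base <- evaluate_model(m, ds)
  set.seed(88)
  noisy <- ds
  noisy$x <- pmin(pmax(ds$x + matrix(rnorm(length(ds$x)), nrow(ds$x)), 0),
                  100)
  pert <- evaluate_model(m, noisy)
  expect_lt(base$r2 - pert$r2, 0.01)
})
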