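test_that("hidden layer sizing follows the geometric-mean rule", {
  expect_identical(hidden_size(5, 9), 7L)
  expect_identical(hidden_size(1, 1), 1L)
  expect_identical(hidden_size(4, 9), 6L)
  expect_error(hidden_size(0, 9), class = "chclevels_validation_error")
})

test_that("sigmoid has the right value, asymptotes and slope", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(50), 1, tolerance = 1e-15)
  expect_equal(sigmoid(-50), 0, tolerance = 1e-15)
  # derivative at 0 is steepness / 4 (central finite difference)
  h <- 1e-6
  for (s in c(0.5, 1, 2)) {
    expect_equal((sigmoid(h, s) - sigmoid(-h, s)) / (2 * h), s / 4,
      tolerance = 1e-6)
  }
  expect_true(all(diff(sigmoid(seq(-5, 5, 0.1))) > 0))
})

test_that("forward propagation matches a hand evaluation and stays in (0,1)", {
  # all-zero 5-7-9 network: every output is sigmoid(0) = 0.5
  zero_net <- mlp_network(init_range = 0, seed = 1)
  expect_equal(unname(mlp_forward(zero_net, rep(0.3, 5))[1, ]), rep(0.5, 9))
  # 1-1-1 toy network, evaluated independently with plogis
  toy <- mlp_network(1, 1, 1, init_range = 0, seed = 1)
  toy$w1[] <- 0.5; toy$b1[] <- 0.1; toy$w2[] <- -0.3; toy$b2[] <- 0.2
  a1 <- stats::plogis(0.5 * 0.4 + 0.1)
  expect_equal(unname(mlp_forward(toy, 0.4)[1, 1]),
    stats::plogis(-0.3 * a1 + 0.2))
  # range property on random networks
  set.seed(2)
  net <- mlp_network(seed = 2)
  out <- mlp_forward(net, matrix(runif(50 * 5), 50))
  expect_true(all(out > 0 & out < 1))
  expect_error(mlp_forward(net, matrix(runif(8), 2, 4)),
    class = "chclevels_validation_error")
})

test_that("quadratic loss is Eq-style mean half squared error and order-invariant", {
  zero_net <- mlp_network(init_range = 0, seed = 1)
  # outputs all 0.5; targets all 0.4 -> each of 9 outputs off by 0.1
  data <- dplyr::bind_cols(
    profile_tbl(rep(0.2, 5)),
    tibble::as_tibble(setNames(as.list(rep(0.4, 9)), chc_domains()))
  )
  expect_equal(mlp_loss(zero_net, data), 9 * 0.01 / 2)
  # perfect prediction -> 0
  perfect <- dplyr::mutate(data,
    dplyr::across(dplyr::all_of(chc_domains()), ~0.5))
  expect_equal(mlp_loss(zero_net, perfect), 0)
  # order invariance
  set.seed(3)
  train <- mlp_training_set(40, seed = 3)
  shuffled <- train[sample.int(40), ]
  net <- mlp_network(seed = 3)
  expect_equal(mlp_loss(net, train), mlp_loss(net, shuffled))
  expect_error(mlp_loss(net, train[0, ]), class = "chclevels_validation_error")
})

test_that("analytic gradients match central finite differences", {
  set.seed(4)
  net <- mlp_network(seed = 4)
  train <- mlp_training_set(10, seed = 4)
  m <- chclevels:::training_matrices(train)
  grads <- chclevels:::mlp_gradients(net, m$x, m$y)
  h <- 1e-5
  numeric_grad <- function(field, idx) {
    up <- net; up[[field]][idx] <- up[[field]][idx] + h
    dn <- net; dn[[field]][idx] <- dn[[field]][idx] - h
    (mlp_loss(up, train) - mlp_loss(dn, train)) / (2 * h)
  }
  for (field in c("w1", "b1", "w2", "b2")) {
    for (idx in seq_along(net[[field]])) {
      expect_equal(grads[[field]][idx], numeric_grad(field, idx),
        tolerance = 1e-6)
    }
  }
})

test_that("training set generation is uniform, labelled by the oracle, reproducible", {
  ts1 <- mlp_training_set(1000, seed = 9)
  ts2 <- mlp_training_set(1000, seed = 9)
  expect_identical(ts1, ts2)
  expect_identical(nrow(ts1), 1000L)
  expect_true(all(as.matrix(ts1[chc_domains()]) >= 0 &
    as.matrix(ts1[chc_domains()]) <= 1))
  # targets equal the conversion oracle exactly
  expect_equal(
    as.matrix(ts1[chc_domains()]),
    as.matrix(chc_saturation(ts1[norm_cols()])[chc_domains()])
  )
})

test_that("training is deterministic under a fixed seed and reports a trajectory", {
  train <- mlp_training_set(60, seed = 5)
  cfg <- mlp_config(max_cycles = 4, threshold = 1e-9)
  f1 <- suppressWarnings(mlp_train(train, cfg, seed = 5))
  f2 <- suppressWarnings(mlp_train(train, cfg, seed = 5))
  expect_identical(f1$network, f2$network)
  expect_identical(f1$trajectory, f2$trajectory)
  expect_false(f1$report$converged)
  expect_warning(mlp_train(train, cfg, seed = 5), "max_cycles")
  expect_equal(nrow(f1$trajectory), 4)
})

test_that("constant targets are learned almost immediately", {
  set.seed(6)
  train <- profile_tbl(matrix(runif(200 * 5, min = 0, max = 1), 200))
  train[chc_domains()] <- 0.5
  fit <- mlp_train(train, seed = 6)
  expect_true(fit$report$converged)
  expect_lt(fit$report$cycles, 50)
  expect_lt(fit$report$final_loss, 0.005)
})

test_that("batch-mode loss is nonincreasing over cycles", {
  train <- mlp_training_set(80, seed = 7)
  fit <- suppressWarnings(
    mlp_train(train, mlp_config(threshold = 1e-9, max_cycles = 60),
      seed = 7, mode = "batch")
  )
  expect_true(all(diff(fit$trajectory$loss) <= 1e-12))
})

test_that("level prediction segments network outputs", {
  zero_net <- mlp_network(init_range = 0, seed = 1)
  fake_fit <- structure(
    list(network = zero_net,
      report = tibble::tibble(cycles = 0L, final_loss = NA_real_,
        final_error = NA_real_, converged = FALSE)),
    class = "chc_mlp"
  )
  # untrained all-zero network: outputs 0.5 -> level 4 everywhere
  lv <- predict(fake_fit, profile_tbl(runif(5)), type = "level")
  expect_equal(unlist(lv[chc_domains()], use.names = FALSE), rep(4L, 9))
})

test_that("the trained surrogate reproduces the expert conversion", {
  fit <- trained_mlp()
  expect_true(fit$report$converged)
  expect_lte(fit$report$final_error, 0.07)
  # all-one profile: top level nearly everywhere
  top <- predict(fit, diag_profiles(1), type = "level")
  expect_gte(sum(unlist(top[chc_domains()]) == 6L), 8)
  # fresh profiles: close saturations and high level agreement
  fresh <- mlp_training_set(2000, seed = 77)
  pred <- predict(fit, fresh[norm_cols()])
  oracle <- as.matrix(fresh[chc_domains()])
  expect_lte(mean(abs(as.matrix(pred[chc_domains()]) - oracle)), 0.05)
  lv_pred <- predict(fit, fresh[norm_cols()], type = "level")
  lv_true <- apply(oracle, 2, saturation_to_level)
  agree <- colMeans(as.matrix(lv_pred[chc_domains()]) == lv_true)
  expect_true(all(agree >= 0.88))
})

test_that("model serialisation round-trips predictions exactly", {
  fit <- trained_mlp()
  path <- withr::local_tempfile(fileext = ".json")
  write_mlp(fit, path)
  restored <- read_mlp(path)
  probe <- profile_tbl(matrix(runif(25), 5))
  expect_equal(predict(restored, probe), predict(fit, probe))
  expect_equal(restored$report$final_loss, fit$report$final_loss)
})
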