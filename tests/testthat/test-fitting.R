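make_fit_data <- function(seed = 1, o = 0) {
  withr::with_seed(seed, {
    net <- random_network(5, max_deg = 3)
    models <- sample_parameters(net)
    data <- noise_free_data(models, net$nodes, n_series = 4,
                            n_steps = 9)
    if (o > 0) data <- ts_set(lapply(data$series, observe, o = o),
                              dt = data$dt)
    list(net = net, models = models, data = data)
  })
}

test_that("regression system has the documented shape", {
  f <- make_fit_data(3)
  # h = 0: a single intercept column; responses are difference quotients
  sys <- build_regression_system(f$data, "A")
  expect_equal(ncol(sys$X), 1)
  expect_true(all(sys$X == 1))
  s1 <- f$data$series[[1]]
  expect_equal(sys$y[1], unname((s1[2, "A"] - s1[1, "A"]) / f$data$dt))
  expect_equal(length(sys$y), n_transitions(f$data))
  # h = 2: intercept, two linear, one product column
  sys2 <- build_regression_system(f$data, "A", c("B", "C"))
  expect_equal(colnames(sys2$X), c("(Intercept)", "B", "C", "B:C"))
  expect_equal(sys2$X[, "B:C"], sys2$X[, "B"] * sys2$X[, "C"])
  # 20 series x 10 points gives 180 transition rows
  cfg <- trial_config(o = 0.1, seed = 1)
  big <- run_trial(cfg)$data
  sys3 <- build_regression_system(big, "WNT5A")
  expect_equal(nrow(sys3$X), 180)
  expect_error(build_regression_system(f$data, "A", "A"), "target")
})

test_that("fit_node recovers planted coefficients on clean data", {
  for (seed in c(11, 12, 13)) {
    f <- make_fit_data(seed)
    for (v in f$net$nodes) {
      regs <- regulators(f$net, v)
      fit <- fit_node(f$data, v, regs)
      expect_lt(fit$sse, 1e-12)
      truth <- f$models[[v]]
      expect_equal(fit$model$a0, truth$a0, tolerance = 1e-6)
      if (length(regs)) {
        expect_equal(fit$model$a_lin, truth$a_lin, tolerance = 1e-6)
      }
      if (length(regs) >= 2) {
        expect_equal(fit$model$a_pair, truth$a_pair, tolerance = 1e-6)
      }
      expect_equal(fit$n_params,
                   1 + length(regs) + choose(length(regs), 2))
    }
  }
})

test_that("intercept-only optimum is the mean difference quotient", {
  f <- make_fit_data(21, o = 0.2)
  sys <- build_regression_system(f$data, "B")
  fit <- fit_node(f$data, "B")
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), mean(sys$y),
               tolerance = 1e-10)
})

test_that("reported sse matches a direct objective evaluation", {
  # re-evaluate the squared one-step prediction error by explicit loop
  f <- make_fit_data(31, o = 0.15)
  for (v in c("A", "D")) {
    regs <- regulators(f$net, v)
    fit <- fit_node(f$data, v, regs)
    direct <- 0
    for (s in f$data$series) {
      for (t in seq_len(nrow(s) - 1)) {
        pred <- oracle_step(s[t, ], fit$model, f$data$dt)
        direct <- direct + (s[t + 1, v] - pred)^2
      }
    }
    expect_equal(fit$sse, unname(direct), tolerance = 1e-8)
  }
})

test_that("sse is monotone under regulator-set nesting and invariant to order", {
  f <- make_fit_data(41, o = 0.2)
  sets <- list(character(), "B", c("B", "C"), c("B", "C", "D"),
               c("B", "C", "D", "E"))
  sses <- vapply(sets, function(s) fit_node(f$data, "A", s)$sse, 0)
  expect_true(all(diff(sses) <= 1e-9 * (1 + abs(sses[-length(sses)]))))
  # permuting the regulator list permutes coefficients consistently
  a <- fit_node(f$data, "A", c("B", "C", "D"))
  b <- fit_node(f$data, "A", c("D", "B", "C"))
  expect_equal(a$sse, b$sse, tolerance = 1e-9)
  expect_equal(a$model$a_lin[c("B", "C", "D")],
               b$model$a_lin[c("B", "C", "D")], tolerance = 1e-8)
})

test_that("degenerate fits warn but return the minimum-norm solution", {
  const <- matrix(0.5, 6, 3, dimnames = list(NULL, c("A", "B", "C")))
  data <- ts_set(const, dt = 0.2)
  expect_warning(fit <- fit_node(data, "A", c("B", "C")),
                 "rank-deficient")
  expect_equal(fit$sse, 0, tolerance = 1e-12)
  w <- capture_warnings(
    fit_node(ts_set(const[1:3, ], dt = 0.2), "A", c("B", "C")))
  expect_true(any(grepl("overparameterized", w)))
})

test_that("tidy and glance expose coefficients and fit summary", {
  f <- make_fit_data(51, o = 0.1)
  fit <- fit_node(f$data, "A", c("B", "C"))
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "B", "C", "B:C"))
  expect_equal(td$type, c("intercept", "linear", "linear", "pairwise"))
  gl <- glance(fit)
  expect_equal(gl$n_params, 4)
  expect_equal(gl$sse, fit$sse)
})
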