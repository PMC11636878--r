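# Architecture construction, exact parameter counting, forward equivalences
# and the exact-derivative contract of the three network kinds.

test_that("count_parameters equals brute-force enumeration of trainable arrays", {
  set.seed(10)
  ctx <- tiny_ctx()
  for (i in seq_len(50)) {
    kind <- sample(c("mixed", "hypernetwork", "modes"), 1)
    widths <- sample(2:9, sample(1:3, 1), replace = TRUE)
    spec <- switch(kind,
      mixed = network_spec("mixed", widths, use_tsc = sample(c(TRUE, FALSE), 1),
                           include_case = sample(c(TRUE, FALSE), 1),
                           input_bias = sample(c(TRUE, FALSE), 1)),
      hypernetwork = network_spec("hypernetwork", widths,
                                  hyper_widths = sample(2:6, 2, replace = TRUE),
                                  use_tsc = sample(c(TRUE, FALSE), 1),
                                  input_bias = sample(c(TRUE, FALSE), 1),
                                  hyper_feature = sample(2:5, 1)),
      modes = network_spec("modes", widths,
                           hyper_widths = sample(2:6, 2, replace = TRUE),
                           use_tsc = sample(c(TRUE, FALSE), 1),
                           n_modes = sample(1:6, 1),
                           input_bias = sample(c(TRUE, FALSE), 1),
                           hyper_feature = sample(2:5, 1)))
    model <- init_model(spec, ctx, seed = i)
    expect_identical(length(tubepinn:::model_flatten(model)),
                     as.integer(count_parameters(spec)))
  }
})

test_that("published parameter totals are reproduced exactly", {
  cnt <- function(...) count_parameters(network_spec(...))
  # single-case convention: first hidden layer without bias
  expect_equal(cnt("mixed", rep(384, 4), use_tsc = FALSE, include_case = FALSE,
                   input_bias = FALSE), 445443)
  expect_equal(cnt("mixed", rep(512, 4), use_tsc = FALSE, include_case = FALSE,
                   input_bias = FALSE), 790531)
  expect_equal(cnt("mixed", rep(1024, 4), use_tsc = FALSE, include_case = FALSE,
                   input_bias = FALSE), 3153923)
  expect_equal(cnt("mixed", rep(256, 4), use_tsc = TRUE, include_case = FALSE,
                   input_bias = FALSE), 200707)
  # multi-case convention: 12 inputs, first-layer bias present
  expect_equal(cnt("mixed", rep(856, 4), use_tsc = TRUE, include_case = TRUE,
                   input_bias = TRUE), 2214475)
  expect_equal(cnt("mixed", rep(516, 4), use_tsc = TRUE, include_case = TRUE,
                   input_bias = TRUE), 808575)
})

test_that("the three published architectures agree in size within 0.1%", {
  for (budget in c("large", "downsized")) {
    specs <- paper_architectures(budget)
    counts <- vapply(specs, count_parameters, 0)
    expect_lt(max(abs(counts - counts["mixed"])) / counts["mixed"], 0.001)
  }
  expect_equal(count_parameters(paper_architectures("large")$mixed), 2214475)
  expect_equal(count_parameters(paper_architectures("downsized")$mixed), 808575)
})

test_that("modes output is the inner product q . M and exactly linear in M", {
  ctx <- tiny_ctx()
  spec <- tiny_spec("modes")
  model <- init_model(spec, ctx, seed = 3)
  pts <- random_interior(20, seed = 11)
  case <- case_parameters(0.025, 0.13)
  # all-zero modes: zero the final hyper layer -> output identically zero
  m0 <- model
  L <- length(m0$params$hyper$W)
  m0$params$hyper$W[[L]][] <- 0; m0$params$hyper$b[[L]][] <- 0
  out0 <- predict_flow(m0, pts$x, pts$y, case)
  expect_true(all(out0 == 0))
  # doubling M (final hyper layer) exactly doubles the output
  m2 <- model
  m2$params$hyper$W[[L]] <- 2 * m2$params$hyper$W[[L]]
  m2$params$hyper$b[[L]] <- 2 * m2$params$hyper$b[[L]]
  out1 <- predict_flow(model, pts$x, pts$y, case)
  out2 <- predict_flow(m2, pts$x, pts$y, case)
  expect_identical(as.matrix(out2), 2 * as.matrix(out1))
})

test_that("a single mode selecting u reproduces the mode weight q1", {
  ctx <- tiny_ctx()
  spec <- network_spec("modes", c(6, 6), hyper_widths = c(5, 5),
                       use_tsc = TRUE, n_modes = 1, hyper_feature = 4)
  model <- init_model(spec, ctx, seed = 5)
  # force M = (1/V_u, 0, 0) so that u = q1 (in SI scaling), v = p = 0
  L <- length(model$params$hyper$W)
  model$params$hyper$W[[L]][] <- 0
  model$params$hyper$b[[L]] <- c(1, 0, 0)
  pts <- random_interior(15, seed = 2)
  out <- predict_flow(model, pts$x, pts$y, case_parameters(0.025, 0.13))
  ss0 <- tubepinn:::ss_value()
  fs <- tubepinn:::feature_states(pts$x, pts$y, rep(0.025, 15), rep(0.13, 15),
                                  ctx, spec, ss0)
  q <- tubepinn:::mlp_forward_states(model$params$main, fs$X, ss0)$out[[1L]]
  expect_equal(out$u, q[, 1L] * ctx$norms$V_u, tolerance = 1e-14)
  expect_true(all(out$v == 0) && all(out$p == 0))
})

test_that("hypernetwork at frozen lambda reproduces a plain FCNN exactly", {
  ctx <- tiny_ctx()
  model <- init_model(tiny_spec("hypernetwork"), ctx, seed = 8)
  case <- case_parameters(0.03, 0.15)
  plain <- frozen_lambda_fcnn(model, case)
  pts <- random_interior(1000, case, seed = 21)
  outh <- predict_flow(model, pts$x, pts$y, case)
  outp <- predict_flow(plain, pts$x, pts$y, case)
  expect_lt(max(abs(as.matrix(outh) - as.matrix(outp))), 1e-12)
})

test_that("second derivatives of all architectures match finite differences", {
  ctx <- tiny_ctx()
  case <- case_parameters(0.025, 0.13)
  ss <- tubepinn:::ss_phys()
  sid <- function(...) tubepinn:::ss_state_id(ss, c(...))
  for (kind in c("mixed", "hypernetwork", "modes")) {
    model <- init_model(tiny_spec(kind), ctx, seed = 13)
    pts <- random_interior(100, case, seed = 31)
    ev <- flow_eval(model, pts$x, pts$y, case, ss)
    f <- function(x, y) flow_eval(model, x, y, case,
                                  tubepinn:::ss_value())$states[[1L]]
    h <- 1e-4 * c(x = ctx$length, y = ctx$R0)  # step on normalized inputs
    for (v in c("x", "y")) {
      hv <- h[[v]]
      up <- f(pts$x + (v == "x") * hv, pts$y + (v == "y") * hv)
      dn <- f(pts$x - (v == "x") * hv, pts$y - (v == "y") * hv)
      mid <- f(pts$x, pts$y)
      fd2 <- (up - 2 * mid + dn) / hv^2
      got <- ev$states[[sid(v, v)]]
      expect_lt(max(abs(got - fd2) / (abs(fd2) + 1e-4 * max(abs(fd2)) + 1e-12)),
                1e-4)
    }
  }
})

test_that("checkpoints restore parameters bit-exactly and detect corruption", {
  ctx <- tiny_ctx()
  model <- init_model(tiny_spec("mixed"), ctx, seed = 17)
  trace <- data.frame(step = 1:3, total = c(3, 2, 1))
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(model, path, trace = trace)
  back <- load_checkpoint(path)
  expect_identical(tubepinn:::model_flatten(back$model),
                   tubepinn:::model_flatten(model))
  expect_identical(back$trace, trace)
  pts <- random_interior(100, seed = 1)
  expect_identical(predict_flow(back$model, pts$x, pts$y, case_parameters(0.025, 0.13)),
                   predict_flow(model, pts$x, pts$y, case_parameters(0.025, 0.13)))
  # corrupted payload must raise an integrity error, not silent garbage
  obj <- readRDS(path)
  obj$payload[100:120] <- as.raw(0)
  saveRDS(obj, path)
  expect_error(load_checkpoint(path), "integrity")
  writeLines("not a checkpoint", path)
  expect_error(load_checkpoint(path))
})
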