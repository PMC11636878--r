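# Training orchestration: batching, Adam optimization, reproducibility,
# the gPINN phase and checkpoint resume.

tiny_training_config <- function(iterations = 20L, seed = 5L, ...) {
  training_config(tiny_spec("mixed_single", widths = c(8L, 8L)),
                  tiny_ctx(), cases = data.frame(A = 0, sigma = 0.134),
                  counts = c(inlet = 8, outlet = 8, wall_top = 8,
                             wall_bottom = 8, interior = 32),
                  iterations = iterations, pool_factor = 50L,
                  trace_every = 5L, seed = seed, ...)
}

test_that("zero iterations returns the initialized model unchanged with empty trace", {
  tc <- tiny_training_config(iterations = 0L)
  fit <- train_pinn(tc)
  fresh <- init_model(tc$spec, tc$ctx, tc$seed)
  expect_identical(tubepinn:::model_flatten(fit$model),
                   tubepinn:::model_flatten(fresh))
  expect_equal(nrow(fit$trace), 0L)
})

test_that("a short run reduces the total loss", {
  tc <- tiny_training_config(iterations = 60L)
  fit <- train_pinn(tc)
  expect_lt(utils::tail(fit$trace$total, 1), fit$trace$total[1])
  expect_true(all(is.finite(fit$trace$total)))
  expect_true(all(diff(fit$trace$step) > 0))
})

test_that("identical configs and seeds give identical traces and parameters", {
  tc <- tiny_training_config(iterations = 15L)
  f1 <- train_pinn(tc)
  f2 <- train_pinn(tc)
  drop_time <- function(tr) tr[, setdiff(names(tr), "elapsed")]
  expect_identical(drop_time(f1$trace), drop_time(f2$trace))
  expect_identical(tubepinn:::model_flatten(f1$model),
                   tubepinn:::model_flatten(f2$model))
})

test_that("each iteration consumes exactly the configured region quotas", {
  cases <- data.frame(A = c(0.015, 0.025, 0.035), sigma = c(0.1, 0.13, 0.18))
  ctx <- tiny_ctx()
  geoms <- lapply(seq_len(3), function(i) {
    channel_geometry(case_parameters(cases$A[i], cases$sigma[i]))
  })
  counts <- c(inlet = 10, outlet = 10, wall_top = 10, wall_bottom = 10,
              interior = 32)
  pools <- lapply(geoms, collocation_pool, n = 200, seed = 1)
  rng <- tubepinn:::local_rng(2)
  consumed_by_case <- matrix(0, 3, 3)
  for (iter in 1:3) {
    b <- tubepinn:::sample_batch(cases, geoms, pools, counts, rng, iter)
    expect_equal(nrow(b), sum(counts))
    expect_equal(sum(b$region == "interior"), 32L)
    consumed_by_case[iter, ] <- tabulate(b$case_index, 3)
  }
  # remainders rotate round-robin: totals equalize over a full cycle of cases
  expect_equal(diff(range(colSums(consumed_by_case))), 0)
  # per-epoch accounting: pool_factor x interior quota points in each pool
  tc <- tiny_training_config()
  expect_equal(tc$pool_factor * tc$counts[["interior"]], 50 * 32)
})

test_that("the default schedule consumes 3.8 million points per epoch", {
  tc <- training_config(tiny_spec("mixed"), tiny_ctx(),
                        cases = build_case_grid()$training)
  per_iter <- sum(tc$counts)
  expect_equal(per_iter, 3840)
  expect_equal(signif(per_iter * tc$iterations_per_epoch, 2), 3.8e6)
})

test_that("a zero-weight gPINN phase reproduces continued plain training", {
  tc <- tiny_training_config(iterations = 10L)
  base <- train_pinn(tc)
  tc0 <- tiny_training_config(iterations = 10L,
                              weights = loss_weights(w_derivative = 0))
  cont_plain <- train_pinn(tc0, model = base$model)
  cont_gpinn <- train_gpinn_phase(base$model, tc0)
  expect_equal(tubepinn:::model_flatten(cont_gpinn$model),
               tubepinn:::model_flatten(cont_plain$model), tolerance = 1e-14)
  expect_equal(cont_gpinn$trace$total, cont_plain$trace$total, tolerance = 1e-12)
  expect_true(all(cont_gpinn$trace$phase == "gpinn"))
  expect_true(all(cont_plain$trace$phase == "plain"))
})

test_that("activating the derivative loss cannot lower the total at fixed parameters", {
  tc <- tiny_training_config(iterations = 40L)
  fit <- train_pinn(tc)
  g <- channel_geometry(case_parameters(0, 0.134))
  cs <- sample_collocation(g, c(20, 20, 20, 20, 60), seed = 77)
  plain <- pinn_losses(fit$model, cs, gpinn = FALSE)
  with_deriv <- pinn_losses(fit$model, cs, gpinn = TRUE)
  expect_gte(with_deriv$total, plain$total)
})

test_that("the gPINN phase is marked in the trace and optimizes its own total", {
  tc <- tiny_training_config(iterations = 15L)
  fit <- train_pinn(tc)
  gp <- train_gpinn_phase(fit$model, tiny_training_config(iterations = 15L))
  expect_true(all(gp$trace$phase == "gpinn"))
  expect_true(all(is.finite(gp$trace$derivative)))
  expect_equal(gp$model$meta$iterations, 30L)
})

test_that("a checkpointed run resumes from the recorded step", {
  tc <- tiny_training_config(iterations = 12L)
  fit <- train_pinn(tc)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(fit$model, path, trace = fit$trace)
  back <- load_checkpoint(path)
  expect_equal(back$model$meta$iterations, 12L)
  more <- train_pinn(tiny_training_config(iterations = 6L), model = back$model)
  expect_equal(more$model$meta$iterations, 18L)
  expect_equal(more$trace$step[1], 13L)
})
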