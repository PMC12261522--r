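# hand-built single linear layer: score = w . input + b
linear_critic <- function(w, b = 0) {
  list(list(W = matrix(w, nrow = 1), b = b))
}

test_that("generator and critic forward passes honour their shape contracts", {
  cfg <- gan_config(H = 4, latent_dim = 5, seed = 1)
  set.seed(1)
  gen <- scintigan:::mlp_init(c(cfg$latent_dim + 3, cfg$generator_widths, 6))
  critic <- scintigan:::mlp_init(c(9, cfg$critic_widths, 1))

  z <- matrix(rnorm(5 * 5), 5)
  cond <- matrix(rnorm(5 * 3), 5)
  out <- generator_forward(z, cond, gen)
  expect_identical(dim(out), c(5L, 6L))
  expect_identical(generator_forward(z, cond, gen), out) # deterministic

  zero_gen <- purrr::map(gen, ~ list(W = .x$W * 0, b = .x$b * 0))
  expect_true(all(generator_forward(z, cond, zero_gen) == 0))

  s <- critic_forward(out, cond, critic)
  expect_length(s, 5)
  one <- critic_forward(out[1, , drop = FALSE], cond[1, , drop = FALSE], critic)
  expect_length(one, 1)
  # row independence: a duplicated row gets a duplicated score
  dup <- critic_forward(out[c(1, 1), ], cond[c(1, 1), ], critic)
  expect_identical(dup[1], dup[2])
  zero_critic <- purrr::map(critic, ~ list(W = .x$W * 0, b = .x$b * 0))
  expect_true(all(critic_forward(out, cond, zero_critic) == 0))

  expect_error(generator_forward(matrix(0, 5, 2), cond, gen), "does not match")
  expect_error(critic_forward(out[, 1:3], cond, critic), "does not match")
})

test_that("MLP backward matches numerical gradients", {
  set.seed(2)
  params <- scintigan:::mlp_init(c(4, 8, 5, 1))
  x <- matrix(rnorm(12), 3, 4)
  fwd <- scintigan:::mlp_forward(params, x, cache = TRUE)
  back <- scintigan:::mlp_backward(params, fwd, matrix(1 / 3, 3, 1))
  loss <- function(p) mean(scintigan:::mlp_forward(p, x))
  h <- 1e-6
  for (i in seq_along(params)) {
    r <- 1 + (i %% nrow(params[[i]]$W))
    c <- 1 + (i %% ncol(params[[i]]$W))
    pp <- params; pp[[i]]$W[r, c] <- pp[[i]]$W[r, c] + h
    pm <- params; pm[[i]]$W[r, c] <- pm[[i]]$W[r, c] - h
    expect_equal(back$grads[[i]]$W[r, c], (loss(pp) - loss(pm)) / (2 * h),
                 tolerance = 1e-5)
  }
  # gradient w.r.t. the input
  xp <- x; xp[2, 3] <- xp[2, 3] + h
  xm <- x; xm[2, 3] <- xm[2, 3] - h
  num <- (mean(scintigan:::mlp_forward(params, xp)) -
            mean(scintigan:::mlp_forward(params, xm))) / (2 * h)
  expect_equal(back$grad_input[2, 3], num, tolerance = 1e-5)
})

test_that("gradient penalty matches hand-constructed critics", {
  real <- matrix(rnorm(48), 8, 6)
  fake <- matrix(rnorm(48), 8, 6)
  cond <- matrix(rnorm(24), 8, 3)

  # linear critic with unit feature-gradient norm: penalty exactly 0
  unit <- linear_critic(c(1, 0, 0, 0, 0, 0, 5, 5, 5))
  expect_equal(gradient_penalty(real, fake, cond, unit, seed = 1), 0)

  # constant critic: gradient norm 0, penalty (0 - 1)^2 = 1
  const <- linear_critic(rep(0, 9), b = 3)
  expect_equal(gradient_penalty(real, fake, cond, const, seed = 1), 1)

  # linear critic with feature-gradient norm 3: penalty (3 - 1)^2 = 4
  norm3 <- linear_critic(c(3, 0, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(gradient_penalty(real, fake, cond, norm3, seed = 1), 4)

  expect_error(gradient_penalty(real, fake[1:4, ], cond, unit), "shape")
})

test_that("gradient-penalty parameter gradients match numerical differentiation", {
  set.seed(3)
  critic <- scintigan:::mlp_init(c(9, 12, 7, 1))
  real <- matrix(rnorm(60), 10, 6)
  fake <- matrix(rnorm(60), 10, 6)
  cond <- matrix(rnorm(30), 10, 3)
  gp <- gradient_penalty(real, fake, cond, critic, seed = 4, with_grads = TRUE)
  expect_gte(gp$penalty, 0)
  h <- 1e-6
  for (i in seq_along(critic)) {
    for (probe in 1:3) {
      r <- sample(nrow(critic[[i]]$W), 1)
      c <- sample(ncol(critic[[i]]$W), 1)
      cp <- critic; cp[[i]]$W[r, c] <- cp[[i]]$W[r, c] + h
      cm <- critic; cm[[i]]$W[r, c] <- cm[[i]]$W[r, c] - h
      num <- (gradient_penalty(real, fake, cond, cp, seed = 4) -
                gradient_penalty(real, fake, cond, cm, seed = 4)) / (2 * h)
      expect_equal(gp$grads[[i]]$W[r, c], num, tolerance = 1e-4)
    }
  }
})

test_that("critic loss gradient equals the analytic Wasserstein-1 gradient", {
  # 1-D two-point distributions along the first feature, linear critic
  n <- 64
  real <- cbind(sample(c(0, 1), n, TRUE, prob = c(0.3, 0.7)),
                matrix(0, n, 5))
  fake <- cbind(sample(c(0, 2), n, TRUE), matrix(0, n, 5))
  cond <- matrix(0.5, n, 3)
  critic <- linear_critic(rnorm(9))

  fwd_r <- scintigan:::mlp_forward(critic, cbind(real, cond), cache = TRUE)
  fwd_f <- scintigan:::mlp_forward(critic, cbind(fake, cond), cache = TRUE)
  g_r <- scintigan:::mlp_backward(critic, fwd_r, matrix(-1 / n, n, 1))$grads
  g_f <- scintigan:::mlp_backward(critic, fwd_f, matrix(1 / n, n, 1))$grads
  grad_w <- scintigan:::add_grads(g_r, g_f)[[1]]$W
  # d/dw [mean w.fake - mean w.real] = colMeans(fake) - colMeans(real)
  analytic <- colMeans(cbind(fake, cond)) - colMeans(cbind(real, cond))
  expect_equal(as.numeric(grad_w), analytic, tolerance = 1e-12)
})

test_that("training bookkeeping: checkpoints per epoch and exact 3:1 ratio", {
  grid <- emission_grid(depths = c(2, 8))[c(1, 15), ]
  ds <- build_training_dataset(grid, 200, seed = 6)
  st <- compute_stats(ds)
  cfg <- gan_config(H = 8, latent_dim = 8, batch_size = 32, epochs = 2,
                    iterations_per_epoch = 10, seed = 6)
  fit <- train_gan(ds, st, cfg)
  expect_length(fit$checkpoints, 2)
  expect_identical(purrr::map_int(fit$checkpoints, "epoch"), 1:2)
  expect_identical(fit$n_critic_updates, 3L * fit$n_gen_updates)
  expect_identical(fit$n_gen_updates, 20L)
  expect_identical(nrow(tidy(fit)), 2L)
  expect_true(all(is.finite(fit$log$critic_loss)))
})

test_that("the generator collapses onto a per-condition point mass", {
  # all features equal a condition-dependent constant vector
  n <- 2000
  half <- n / 2
  mk <- function(cval, fval, m) {
    tibble::as_tibble(matrix(rep(c(rep(fval, 6), cval, cval, cval), m),
                             m, 9, byrow = TRUE,
                             dimnames = list(NULL, scintigan:::phase_space_columns)))
  }
  ds <- dplyr::bind_rows(mk(1, -1, half), mk(5, 2, half))
  st <- compute_stats(ds)
  cfg <- gan_config(H = 16, latent_dim = 8, learning_rate = 5e-4,
                    batch_size = 128, epochs = 10, iterations_per_epoch = 100,
                    eval_n = 1000, seed = 7)
  # training oscillates around the target; best-checkpoint selection against
  # per-condition references is part of the training protocol
  fit <- train_gan(ds, st, cfg,
                   reference = list(ds[ds$emX == 1, ], ds[ds$emX == 5, ]))
  gen <- select_best_checkpoint(fit)$generator
  norm <- normalize_table(ds, st)
  for (cval in c(1, 5)) {
    rows <- which(ds$emX == cval)
    cond <- as.matrix(norm[rows[1:500], 7:9])
    set.seed(8)
    out <- generator_forward(matrix(rnorm(500 * 8), 500), cond, gen)
    target <- as.numeric(norm[rows[1], 1:6])
    expect_lt(max(abs(colMeans(out) - target)), 0.05)
  }
})

test_that("best-checkpoint selection maximizes similarity, later epoch wins ties", {
  cp <- function(epoch, sim) {
    scintigan:::new_checkpoint(epoch, list(), list(), NULL, sim, NULL)
  }
  picked <- select_best_checkpoint(list(cp(1, 0.8), cp(2, 0.95), cp(3, 0.9)))
  expect_identical(picked$epoch, 2)
  expect_identical(select_best_checkpoint(list(cp(1, 0.7)))$epoch, 1)
  tied <- select_best_checkpoint(list(cp(1, 0.9), cp(2, 0.9)))
  expect_identical(tied$epoch, 2)
  expect_error(select_best_checkpoint(list()), "no checkpoints")
})

test_that("checkpoints round-trip through disk with identical outputs", {
  grid <- emission_grid(depths = c(2, 8))[c(1, 15), ]
  ds <- build_training_dataset(grid, 150, seed = 9)
  st <- compute_stats(ds)
  cfg <- gan_config(H = 8, latent_dim = 8, batch_size = 32, epochs = 1,
                    iterations_per_epoch = 5, seed = 9)
  fit <- train_gan(ds, st, cfg)
  cp <- fit$checkpoints[[1]]
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(cp, path)
  cp2 <- load_checkpoint(path)
  z <- matrix(rnorm(20 * 8), 20)
  cond <- matrix(rnorm(20 * 3), 20)
  expect_identical(generator_forward(z, cond, cp2$generator),
                   generator_forward(z, cond, cp$generator))
})
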