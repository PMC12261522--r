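#' Conditional WGAN-GP configuration
#'
#' Architecture and optimization settings for the conditional Wasserstein
#' GAN with gradient penalty. The generator maps a standard-normal latent
#' vector concatenated with the (normalized) emission coordinates through
#' ReLU hidden layers of widths `H, 2H, 2H, 4H` to the six phase-space
#' features (linear output layer). The critic maps the six features
#' concatenated with the condition through widths `4H, 2H, 2H, H` to a
#' single unbounded score. Both are trained with Adam
#' (`beta1 = 0.5, beta2 = 0.9`, learning rate `5e-5`) at a 3:1
#' critic:generator update ratio.
#'
#' @param H Base hidden width.
#' @param latent_dim Latent (noise) dimension.
#' @param learning_rate Adam learning rate, shared by both networks.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param n_critic Critic updates per generator update.
#' @param gp_lambda Gradient-penalty coefficient.
#' @param batch_size Minibatch size.
#' @param epochs Number of epochs; a checkpoint is scored and saved after
#'   each.
#' @param iterations_per_epoch Generator updates per epoch.
#' @param eval_n Rows generated per emission point when scoring a
#'   checkpoint against the held-out reference.
#' @param eval_bins Histogram bins for checkpoint scoring.
#' @param generator_widths,critic_widths Optional explicit hidden-layer
#'   widths, overriding the `H`-derived defaults.
#' @param seed Integer seed for initialization and training randomness.
#' @return An object of class `gan_config`.
#' @export
gan_config <- function(H = 128,
                       latent_dim = 64,
                       learning_rate = 5e-5,
                       adam_beta1 = 0.5,
                       adam_beta2 = 0.9,
                       n_critic = 3,
                       gp_lambda = 10,
                       batch_size = 1024,
                       epochs = 10,
                       iterations_per_epoch = 100,
                       eval_n = 10000,
                       eval_bins = 100,
                       generator_widths = NULL,
                       critic_widths = NULL,
                       seed = 1) {
  stopifnot(
    H >= 1, latent_dim >= 1, learning_rate > 0,
    n_critic >= 1, gp_lambda >= 0, batch_size >= 1,
    epochs >= 1, iterations_per_epoch >= 1
  )
  structure(
    list(
      H = as.integer(H),
      latent_dim = as.integer(latent_dim),
      feature_dim = 6L,
      condition_dim = 3L,
      learning_rate = learning_rate,
      adam_beta1 = adam_beta1,
      adam_beta2 = adam_beta2,
      n_critic = as.integer(n_critic),
      gp_lambda = gp_lambda,
      batch_size = as.integer(batch_size),
      epochs = as.integer(epochs),
      iterations_per_epoch = as.integer(iterations_per_epoch),
      eval_n = as.integer(eval_n),
      eval_bins = as.integer(eval_bins),
      generator_widths = as.integer(generator_widths %||% (H * c(1, 2, 2, 4))),
      critic_widths = as.integer(critic_widths %||% (H * c(4, 2, 2, 1))),
      seed = as.integer(seed)
    ),
    class = "gan_config"
  )
}

# ---- plain-matrix MLP with ReLU hidden layers and linear output ----------

# He-normal initialization; weights W[[i]] are (out x in), biases length out
mlp_init <- function(dims) {
  L <- length(dims) - 1
  params <- vector("list", L)
  for (i in seq_len(L)) {
    fan_in <- dims[i]
    params[[i]] <- list(
      W = matrix(stats::rnorm(dims[i + 1] * fan_in, sd = sqrt(2 / fan_in)),
                 dims[i + 1], fan_in),
      b = numeric(dims[i + 1])
    )
  }
  params
}

# Output-layer calibration at initialization (LSUV-style): rescale and
# shift the final linear layer so each output starts with zero mean and
# unit variance on a probe batch. With a small learning rate this avoids
# spending most of the update budget on global offset/scale corrections.
mlp_calibrate_output <- function(params, probe) {
  out <- mlp_forward(params, probe)
  mu <- colMeans(out)
  sdev <- pmax(apply(out, 2, stats::sd), 1e-6)
  L <- length(params)
  params[[L]]$W <- params[[L]]$W / sdev
  params[[L]]$b <- (params[[L]]$b - mu) / sdev
  params
}

# forward pass on a batch (rows = samples); returns output and a cache of
# activations/masks for backprop
mlp_forward <- function(params, x, cache = FALSE) {
  L <- length(params)
  acts <- if (cache) vector("list", L + 1) else NULL
  masks <- if (cache) vector("list", L) else NULL
  u <- x
  if (cache) acts[[1]] <- u
  for (i in seq_len(L)) {
    z <- tcrossprod(u, params[[i]]$W)
    z <- z + rep(params[[i]]$b, each = nrow(z))
    if (i < L) {
      m <- z > 0
      u <- z * m
      if (cache) masks[[i]] <- m
    } else {
      u <- z
    }
    if (cache) acts[[i + 1]] <- u
  }
  if (cache) list(out = u, acts = acts, masks = masks) else u
}

# backprop of dL/d(output) through the cached forward pass; returns
# parameter gradients and dL/d(input)
mlp_backward <- function(params, fwd, grad_out) {
  L <- length(params)
  grads <- vector("list", L)
  g <- grad_out
  for (i in rev(seq_len(L))) {
    grads[[i]] <- list(
      W = crossprod(g, fwd$acts[[i]]),
      b = colSums(g)
    )
    g <- g %*% params[[i]]$W
    if (i > 1) g <- g * fwd$masks[[i - 1]]
  }
  list(grads = grads, grad_input = g)
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)),
    v = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    for (nm in c("W", "b")) {
      g <- grads[[i]][[nm]]
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * g^2
      mhat <- state$m[[i]][[nm]] / c1
      vhat <- state$v[[i]][[nm]] / c2
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

add_grads <- function(a, b, scale = 1) {
  purrr::map2(a, b, function(ga, gb) {
    list(W = ga$W + scale * gb$W, b = ga$b + scale * gb$b)
  })
}

#' Generator forward pass
#'
#' Maps latent vectors and normalized emission-point conditions to the six
#' normalized phase-space features. Deterministic given its inputs.
#'
#' @param latent `n x latent_dim` matrix of latent draws.
#' @param condition `n x 3` matrix of normalized emission coordinates.
#' @param params Generator parameter list (from a fit or checkpoint).
#' @return An `n x 6` matrix in normalized feature space.
#' @export
generator_forward <- function(latent, condition, params) {
  latent <- as.matrix(latent)
  condition <- as.matrix(condition)
  if (nrow(latent) != nrow(condition)) stop("latent/condition row mismatch")
  x <- cbind(latent, condition)
  if (ncol(x) != ncol(params[[1]]$W)) {
    stop("input width ", ncol(x), " does not match generator input ",
         ncol(params[[1]]$W))
  }
  mlp_forward(params, x)
}

#' Critic forward pass
#'
#' Scores feature/condition rows with the Wasserstein critic: one unbounded
#' real score per row, no output nonlinearity.
#'
#' @param features `n x 6` matrix of normalized features.
#' @param condition `n x 3` matrix of normalized conditions.
#' @param params Critic parameter list.
#' @return Numeric vector of `n` scores.
#' @export
critic_forward <- function(features, condition, params) {
  features <- as.matrix(features)
  condition <- as.matrix(condition)
  if (nrow(features) != nrow(condition)) stop("features/condition row mismatch")
  x <- cbind(features, condition)
  if (ncol(x) != ncol(params[[1]]$W)) {
    stop("input width ", ncol(x), " does not match critic input ",
         ncol(params[[1]]$W))
  }
  drop(mlp_forward(params, x))
}

#' Gradient penalty of the critic
#'
#' The WGAN-GP one-Lipschitz penalty: features are interpolated uniformly
#' at random between paired real and fake rows, the critic's gradient with
#' respect to the interpolated features is computed, and the penalty is the
#' mean of `(||grad|| - 1)^2`.
#'
#' When `with_grads = TRUE` the gradient of the penalty with respect to the
#' critic parameters is also returned. For a ReLU network the activation
#' pattern is piecewise constant, so the parameter gradient of the penalty
#' has a closed form in the layer weights and the cached masks (the same
#' quantity reverse-mode autodiff computes).
#'
#' @param real `n x 6` matrix of real (normalized) features.
#' @param fake `n x 6` matrix of generated features.
#' @param condition `n x 3` matrix of conditions shared by the pairing.
#' @param params Critic parameter list.
#' @param seed Optional seed for the interpolation draws.
#' @param with_grads Also return parameter gradients.
#' @return The scalar penalty, or (with gradients) a list
#'   `list(penalty, grads)`.
#' @export
gradient_penalty <- function(real, fake, condition, params, seed = NULL,
                             with_grads = FALSE) {
  real <- as.matrix(real)
  fake <- as.matrix(fake)
  if (!all(dim(real) == dim(fake))) stop("real/fake shape mismatch")
  with_seed(seed)
  n <- nrow(real)
  d_feat <- ncol(real)
  epsln <- stats::runif(n)
  xhat <- epsln * real + (1 - epsln) * fake
  x <- cbind(xhat, as.matrix(condition))

  fwd <- mlp_forward(params, x, cache = TRUE)
  L <- length(params)

  # input-gradient backprop: B[[i]] holds the batched backward vectors
  B <- vector("list", L)
  g <- matrix(1, n, 1)
  B[[L]] <- g
  for (i in rev(seq_len(L))) {
    g <- g %*% params[[i]]$W
    if (i > 1) {
      g <- g * fwd$masks[[i - 1]]
      B[[i - 1]] <- g
    }
  }
  grad_x <- g[, seq_len(d_feat), drop = FALSE] # d critic / d xhat
  norms <- sqrt(rowSums(grad_x^2))
  penalty <- mean((norms - 1)^2)
  if (!with_grads) return(penalty)

  # closed-form parameter gradient (ReLU masks fixed a.e.):
  # d penalty / d W_i = B_i' Gamma_{i-1}, biases receive no gradient
  q <- matrix(0, n, ncol(x))
  q[, seq_len(d_feat)] <- grad_x * (2 * (norms - 1) / pmax(norms, 1e-12)) / n
  grads <- vector("list", L)
  gamma <- q
  for (i in seq_len(L)) {
    grads[[i]] <- list(W = crossprod(B[[i]], gamma), b = numeric(nrow(params[[i]]$W)))
    if (i < L) gamma <- tcrossprod(gamma, params[[i]]$W) * fwd$masks[[i]]
  }
  list(penalty = penalty, grads = grads)
}

# one critic update; returns updated critic, losses
critic_update <- function(gen, critic, copt, feat, cond, config) {
  n <- nrow(feat)
  z <- matrix(stats::rnorm(n * config$latent_dim), n)
  fake <- generator_forward(z, cond, gen)

  # one fused pass over the stacked real/fake batch
  fwd <- mlp_forward(critic, cbind(rbind(feat, fake), rbind(cond, cond)),
                     cache = TRUE)
  w_loss <- mean(fwd$out[(n + 1):(2 * n)]) - mean(fwd$out[1:n])
  grads <- mlp_backward(critic, fwd,
                        matrix(c(rep(-1 / n, n), rep(1 / n, n)), 2 * n, 1))$grads

  pen <- 0
  if (config$gp_lambda > 0) {
    gp <- gradient_penalty(feat, fake, cond, critic, with_grads = TRUE)
    pen <- gp$penalty
    grads <- add_grads(grads, gp$grads, scale = config$gp_lambda)
  }
  loss <- w_loss + config$gp_lambda * pen
  if (!is.finite(loss)) stop("non-finite critic loss")
  upd <- adam_step(critic, grads, copt, config$learning_rate,
                   config$adam_beta1, config$adam_beta2)
  list(critic = upd$params, copt = upd$state, loss = loss, penalty = pen)
}

# one generator update; returns updated generator and loss
generator_update <- function(gen, critic, gopt, cond, config) {
  n <- nrow(cond)
  z <- matrix(stats::rnorm(n * config$latent_dim), n)
  fwd_g <- mlp_forward(gen, cbind(z, cond), cache = TRUE)
  fwd_c <- mlp_forward(critic, cbind(fwd_g$out, cond), cache = TRUE)
  loss <- -mean(fwd_c$out)
  if (!is.finite(loss)) stop("non-finite generator loss")
  back_c <- mlp_backward(critic, fwd_c, matrix(-1 / n, n, 1))
  grad_fake <- back_c$grad_input[, seq_len(config$feature_dim), drop = FALSE]
  g_g <- mlp_backward(gen, fwd_g, grad_fake)$grads
  upd <- adam_step(gen, g_g, gopt, config$learning_rate,
                   config$adam_beta1, config$adam_beta2)
  list(gen = upd$params, gopt = upd$state, loss = loss)
}

#' Train the conditional WGAN-GP on a phase-space table
#'
#' Normalizes the dataset with `stats` (all nine columns z-scored), then
#' alternates `n_critic` critic updates per generator update. The critic
#' loss is `mean(critic(fake)) - mean(critic(real)) + gp_lambda * penalty`;
#' the generator loss is `-mean(critic(fake))`. A checkpoint is saved after
#' every epoch; when held-out `reference` tables are supplied each
#' checkpoint is scored by its mean 1-JSD similarity over the six features,
#' averaged over emission points.
#'
#' @param dataset Phase-space tibble in physical units (training set).
#' @param stats [compute_stats()] result for `dataset`.
#' @param config A [gan_config()].
#' @param reference Optional named-less list of held-out phase-space
#'   tibbles, one per emission point, used to score checkpoints.
#' @param verbose Print one line per epoch.
#' @return An object of class `gan_fit` with elements `checkpoints` (one
#'   per epoch), `log` (tibble: epoch, critic_loss, generator_loss,
#'   penalty, similarity), `stats` and `config`.
#' @export
train_gan <- function(dataset, stats, config = gan_config(),
                      reference = NULL, verbose = FALSE) {
  dataset <- check_phase_space(dataset)
  norm <- normalize_table(dataset, stats)
  feat_all <- as.matrix(norm[, 1:6])
  cond_all <- as.matrix(norm[, 7:9])
  n_rows <- nrow(feat_all)
  if (n_rows < config$batch_size) stop("dataset smaller than one batch")

  set.seed(config$seed)
  gen <- mlp_init(c(config$latent_dim + config$condition_dim,
                    config$generator_widths, config$feature_dim))
  # start the generator at zero mean / unit variance per (normalized) feature
  probe_rows <- sample.int(n_rows, min(4096L, n_rows))
  probe <- cbind(matrix(stats::rnorm(length(probe_rows) * config$latent_dim),
                        length(probe_rows)),
                 cond_all[probe_rows, , drop = FALSE])
  gen <- mlp_calibrate_output(gen, probe)
  critic <- mlp_init(c(config$feature_dim + config$condition_dim,
                       config$critic_widths, 1L))
  gopt <- adam_init(gen)
  copt <- adam_init(critic)

  checkpoints <- vector("list", config$epochs)
  log <- vector("list", config$epochs)
  n_critic_updates <- 0L
  n_gen_updates <- 0L

  for (epoch in seq_len(config$epochs)) {
    c_losses <- g_losses <- pens <- numeric(config$iterations_per_epoch)
    for (it in seq_len(config$iterations_per_epoch)) {
      for (k in seq_len(config$n_critic)) {
        rows <- sample.int(n_rows, config$batch_size, replace = TRUE)
        res <- tryCatch(
          critic_update(gen, critic, copt,
                        feat_all[rows, , drop = FALSE],
                        cond_all[rows, , drop = FALSE], config),
          error = function(e) {
            stop("critic update failed at epoch ", epoch, ", iteration ", it,
                 ": ", conditionMessage(e))
          }
        )
        critic <- res$critic
        copt <- res$copt
        n_critic_updates <- n_critic_updates + 1L
      }
      c_losses[it] <- res$loss
      pens[it] <- res$penalty
      rows <- sample.int(n_rows, config$batch_size, replace = TRUE)
      resg <- tryCatch(
        generator_update(gen, critic, gopt,
                         cond_all[rows, , drop = FALSE], config),
        error = function(e) {
          stop("generator update failed at epoch ", epoch, ", iteration ", it,
               ": ", conditionMessage(e))
        }
      )
      gen <- resg$gen
      gopt <- resg$gopt
      g_losses[it] <- resg$loss
      n_gen_updates <- n_gen_updates + 1L
    }

    sim <- NA_real_
    if (!is.null(reference)) {
      sim <- score_checkpoint(gen, stats, reference, config)
    }
    checkpoints[[epoch]] <- new_checkpoint(epoch, gen, critic, stats, sim, config)
    log[[epoch]] <- tibble::tibble(
      epoch = epoch,
      critic_loss = mean(c_losses),
      generator_loss = mean(g_losses),
      penalty = mean(pens),
      similarity = sim
    )
    if (verbose) {
      message(sprintf("epoch %d: critic %.4f generator %.4f penalty %.4f similarity %s",
                      epoch, mean(c_losses), mean(g_losses), mean(pens),
                      ifelse(is.na(sim), "-", sprintf("%.4f", sim))))
    }
  }

  structure(
    list(
      checkpoints = checkpoints,
      log = dplyr::bind_rows(log),
      stats = stats,
      config = config,
      n_critic_updates = n_critic_updates,
      n_gen_updates = n_gen_updates
    ),
    class = "gan_fit"
  )
}

# mean 1-JSD similarity of generated vs held-out reference, averaged over
# emission points
score_checkpoint <- function(gen, stats, reference, config) {
  sims <- purrr::map_dbl(reference, function(ref) {
    point <- c(ref$emX[1], ref$emY[1], ref$emZ[1])
    n_gen <- min(config$eval_n, nrow(ref))
    fake <- generate_features(gen, stats, point, n_gen, config$latent_dim)
    rep <- similarity_report(ref, fake, n_bins = config$eval_bins)
    mean(rep$similarity)
  })
  mean(sims)
}

# sample the generator at one emission point and denormalize to physical
# units; returns a phase-space tibble
generate_features <- function(gen, stats, point, n, latent_dim) {
  cond_phys <- tibble::tibble(emX = rep(point[1], n), emY = point[2], emZ = point[3])
  cond <- as.matrix(normalize_table(cond_phys, stats))
  z <- matrix(stats::rnorm(n * latent_dim), n)
  feat_norm <- generator_forward(z, cond, gen)
  colnames(feat_norm) <- phase_space_columns[1:6]
  feat <- denormalize_table(tibble::as_tibble(feat_norm), stats)
  dplyr::bind_cols(feat, cond_phys)
}

new_checkpoint <- function(epoch, gen, critic, stats, similarity, config) {
  structure(
    list(
      epoch = epoch,
      generator = gen,
      critic = critic,
      stats = stats,
      similarity = similarity,
      config = config
    ),
    class = "gan_checkpoint"
  )
}

#' Select the best checkpoint of a fit
#'
#' Returns the checkpoint with the highest similarity score; ties are
#' broken in favour of the later epoch (more training).
#'
#' @param fit A `gan_fit`, or a bare list of `gan_checkpoint`s.
#' @return A `gan_checkpoint`.
#' @export
select_best_checkpoint <- function(fit) {
  cps <- if (inherits(fit, "gan_fit")) fit$checkpoints else fit
  if (length(cps) == 0) stop("no checkpoints to select from")
  scores <- purrr::map_dbl(cps, function(cp) cp$similarity %||% NA_real_)
  if (all(is.na(scores))) stop("no checkpoint carries a similarity score")
  best <- max(scores, na.rm = TRUE)
  # ties broken by the later epoch
  cps[[max(which(scores == best))]]
}

#' Save or load a checkpoint
#'
#' Checkpoints are self-contained single files (RDS): generator and critic
#' parameters, the normalization statistics used at training time, the
#' similarity score and the configuration snapshot.
#'
#' @param checkpoint A `gan_checkpoint`.
#' @param path File path.
#' @return `save_checkpoint()` returns `path` invisibly;
#'   `load_checkpoint()` returns the checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "gan_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  cp <- readRDS(path)
  if (!inherits(cp, "gan_checkpoint")) stop("not a checkpoint file: ", path)
  cp
}

#' @export
print.gan_fit <- function(x, ...) {
  best <- tryCatch(select_best_checkpoint(x), error = function(e) NULL)
  cat(sprintf(
    "<gan_fit> %d epochs (%d generator / %d critic updates)%s\n",
    x$config$epochs, x$n_gen_updates, x$n_critic_updates,
    if (!is.null(best) && !is.na(best$similarity)) {
      sprintf(", best similarity %.4f at epoch %d", best$similarity, best$epoch)
    } else ""
  ))
  invisible(x)
}

#' Tidy a GAN fit into its per-epoch training log
#'
#' @param x A `gan_fit`.
#' @param ... Unused.
#' @return A tibble with columns `epoch, critic_loss, generator_loss,
#'   penalty, similarity`.
#' @method tidy gan_fit
#' @export
tidy.gan_fit <- function(x, ...) x$log

#' One-row summary of a GAN fit
#'
#' @param x A `gan_fit`.
#' @param ... Unused.
#' @return A tibble with the epoch count, update counts, final losses and
#'   the best checkpoint's epoch and similarity.
#' @method glance gan_fit
#' @export
glance.gan_fit <- function(x, ...) {
  best <- tryCatch(select_best_checkpoint(x), error = function(e) NULL)
  tibble::tibble(
    epochs = x$config$epochs,
    generator_updates = x$n_gen_updates,
    critic_updates = x$n_critic_updates,
    final_critic_loss = utils::tail(x$log$critic_loss, 1),
    final_generator_loss = utils::tail(x$log$generator_loss, 1),
    best_epoch = if (is.null(best)) NA_integer_ else best$epoch,
    best_similarity = if (is.null(best)) NA_real_ else best$similarity
  )
}
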