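#' Deep radiomics: convolutional autoencoder with optional prognostic loss
#'
#' A compact convolutional autoencoder for 2-D tumor slices, implemented as
#' vectorized matrix operations (im2col convolutions trained with Adam).
#' The encoder stacks stride-2 convolution blocks (kernel 4, padding 1, so
#' each block exactly halves the spatial size) followed by a dense latent
#' layer; the decoder mirrors it with transposed convolutions and a sigmoid
#' output. The loss is the reconstruction mean squared error, optionally
#' augmented by `lambda * L_prog` where `L_prog` is the negative Cox
#' partial log-likelihood of a linear risk head on the latent vector — the
#' "half-supervised" variant that steers the latent space toward prognosis.
#' Latent coordinates are the deep radiomics features.
#'
#' @name deep-radiomics
NULL

#' Configuration of the (half-supervised) convolutional autoencoder
#'
#' @param input_size Side of the square input in pixels (must be divisible
#'   by `2^length(channels)`); default 64.
#' @param channels Encoder channel widths, one per stride-2 block.
#' @param latent_dim Latent dimension; the reference configuration extracts
#'   1024 deep features per image.
#' @param lambda_prognostic Weight of the Cox prognostic loss (0 = plain
#'   autoencoder).
#' @param epochs,batch_size,learning_rate Adam training hyperparameters.
#' @param lr_schedule `"constant"`, or `"cosine"` for cosine annealing of
#'   the learning rate to a tenth of its initial value over the epochs
#'   (stabilizes the final reconstruction quality).
#' @param holdout_fraction Held-out fraction per cross-validation repeat
#'   (default 0.10, i.e. leave-10%-out).
#' @param cv_repeats Number of random-holdout repeats (the reference
#'   protocol uses 100; desk-scale default 1).
#' @param augment Apply random morphological augmentation during training.
#' @param final_refit Refit on all images after the holdout repeats.
#' @param seed Integer seed.
#' @return A `cae_config` list.
#' @export
cae_config <- function(input_size = 64, channels = c(8, 16, 32, 64),
                       latent_dim = 1024, lambda_prognostic = 0,
                       epochs = 30, batch_size = 32, learning_rate = 1e-3,
                       lr_schedule = c("constant", "cosine"),
                       holdout_fraction = 0.10, cv_repeats = 1,
                       augment = FALSE, final_refit = TRUE, seed = 1) {
  lr_schedule <- match.arg(lr_schedule)
  if (latent_dim < 1) stop_invalid("`latent_dim` must be >= 1.")
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop_invalid("`holdout_fraction` must lie in (0, 1).")
  }
  if (input_size %% (2^length(channels)) != 0) {
    stop_invalid("`input_size` must be divisible by 2^length(channels).")
  }
  check_positive(lambda_prognostic, "lambda_prognostic", strict = FALSE)
  structure(list(
    input_size = input_size, channels = channels, latent_dim = latent_dim,
    lambda_prognostic = lambda_prognostic, epochs = epochs,
    batch_size = batch_size, learning_rate = learning_rate,
    lr_schedule = lr_schedule,
    holdout_fraction = holdout_fraction, cv_repeats = cv_repeats,
    augment = augment, final_refit = final_refit, seed = seed
  ), class = "cae_config")
}

# ---- im2col machinery -------------------------------------------------
# geometry of one stride-2 conv: big (H, W) -> small (H/2, W/2), k = 4, p = 1

conv_geom <- function(H, cin, cout, k = 4, s = 2, p = 1) {
  OH <- (H + 2 * p - k) %/% s + 1
  list(H = H, W = H, OH = OH, OW = OH, cin = cin, cout = cout,
    k = k, s = s, p = p)
}

# patch-gather index array: (OH*OW) x (k*k) spatial offsets into the padded
# plane, expanded over channels by the caller
patch_index <- function(g) {
  Hp <- g$H + 2 * g$p
  oh <- rep(seq_len(g$OH), times = g$OW)
  ow <- rep(seq_len(g$OW), each = g$OH)
  ki <- rep(seq_len(g$k), times = g$k)
  kj <- rep(seq_len(g$k), each = g$k)
  ii <- outer((oh - 1) * g$s, ki, `+`) # (OHOW, k2) row coord in padded
  jj <- outer((ow - 1) * g$s, kj, `+`)
  (jj - 1) * Hp + ii
}

# full gather index for a batch: matrix (OH*OW*N, k2*cin) of positions in
# the flattened padded activation array (Hp, Hp, cin, N). Cached per
# (layer geometry, batch size) since building it is the expensive part.
full_index <- function(g, idx_sp, N) {
  Hp <- g$H + 2 * g$p
  S2 <- Hp * Hp
  ohow <- g$OH * g$OW
  k2 <- g$k^2
  # expand kernel columns over channels, then rows over images
  B <- idx_sp[, rep(seq_len(k2), g$cin), drop = FALSE] +
    matrix(rep((seq_len(g$cin) - 1) * S2, each = k2), ohow, k2 * g$cin,
      byrow = TRUE)
  B[rep(seq_len(ohow), N), , drop = FALSE] +
    rep((seq_len(N) - 1) * S2 * g$cin, each = ohow)
}

# inverse of full_index: for every padded-array position, the (at most
# (k/s)^2) patch-matrix elements that scatter-add into it, as a gather
# table padded with a sentinel pointing at a trailing zero slot
inverse_index <- function(fidx, len_out) {
  fv <- as.vector(fidx)
  o <- order(fv)
  tv <- fv[o]
  runs <- rle(tv)
  slot <- sequence(runs$lengths)
  M <- matrix(length(fv) + 1L, len_out, max(slot))
  M[cbind(tv, slot)] <- o
  M
}

# cache of gather/scatter indices, keyed by layer and batch size
index_cache <- function(geoms) {
  sp <- lapply(geoms, patch_index)
  env <- new.env(parent = emptyenv())
  list(
    get = function(l, N) {
      key <- paste0(l, "_", N)
      if (is.null(env[[key]])) {
        g <- geoms[[l]]
        f <- full_index(g, sp[[l]], N)
        Hp <- g$H + 2 * g$p
        env[[key]] <- list(f = f, inv = inverse_index(f, Hp * Hp * g$cin * N))
      }
      env[[key]]
    }
  )
}

pad_vec <- function(X, g) {
  N <- dim(X)[4]
  Hp <- g$H + 2 * g$p
  Xp <- array(0, c(Hp, Hp, g$cin, N))
  Xp[g$p + seq_len(g$H), g$p + seq_len(g$W), , ] <- X
  as.vector(Xp)
}

# X: array (H, W, cin, N) -> patches (OH*OW*N, k2*cin), rows n-major blocks
im2col <- function(X, g, idx) {
  matrix(pad_vec(X, g)[idx$f], nrow(idx$f), ncol(idx$f))
}

# scatter-add patches back: dP (OH*OW*N, k2*cin) -> array (H, W, cin, N);
# implemented as gathers through the precomputed inverse index
col2im <- function(dP, g, idx, N) {
  Hp <- g$H + 2 * g$p
  dPv <- c(as.vector(dP), 0)
  M <- idx$inv
  out <- dPv[M[, 1]]
  for (s in seq_len(ncol(M))[-1]) out <- out + dPv[M[, s]]
  Xp <- array(out, c(Hp, Hp, g$cin, N))
  Xp[g$p + seq_len(g$H), g$p + seq_len(g$W), , , drop = FALSE]
}

# reshape (OH*OW*N, cout) matrix (n-major row blocks) to (OH, OW, cout, N)
mat_to_array <- function(M, OH, OW, N) {
  aperm(array(M, c(OH, OW, N, ncol(M))), c(1, 2, 4, 3))
}

array_to_mat <- function(A) {
  d <- dim(A)
  matrix(aperm(A, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

he_init <- function(nr, nc) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
}

# build parameter list for the given config
init_params <- function(cfg) {
  ch <- c(1, cfg$channels)
  nb <- length(cfg$channels)
  H <- cfg$input_size
  geoms <- list()
  params <- list()
  for (l in seq_len(nb)) {
    g <- conv_geom(H, ch[l], ch[l + 1])
    geoms[[l]] <- g
    params[[paste0("We", l)]] <- he_init(g$k^2 * g$cin, g$cout)
    params[[paste0("be", l)]] <- numeric(g$cout)
    H <- g$OH
  }
  flat <- H * H * ch[nb + 1]
  params$Wfc <- he_init(flat, cfg$latent_dim)
  params$bfc <- numeric(cfg$latent_dim)
  params$Wdf <- he_init(cfg$latent_dim, flat)
  params$bdf <- numeric(flat)
  for (l in rev(seq_len(nb))) {
    g <- geoms[[l]]
    # transposed conv: small (cout) -> big (cin); weights (k2*cin, cout).
    # effective fan-in per output pixel is cout * (k/s)^2
    fan_in <- g$cout * (g$k / g$s)^2
    params[[paste0("Wd", l)]] <- matrix(
      rnorm(g$k^2 * g$cin * g$cout, 0, sqrt(2 / fan_in)),
      g$k^2 * g$cin, g$cout
    )
    params[[paste0("bd", l)]] <- numeric(g$cin)
  }
  params$Wrisk <- matrix(rnorm(cfg$latent_dim, 0, 0.01), cfg$latent_dim, 1)
  params$brisk <- 0
  list(params = params, geoms = geoms, flat = flat, side = H)
}

# full forward pass; returns activations needed for backprop
cae_forward <- function(X, net, cfg, cache) {
  nb <- length(net$geoms)
  acts <- list(A0 = X)
  A <- X
  for (l in seq_len(nb)) {
    g <- net$geoms[[l]]
    P <- im2col(A, g, cache$get(l, dim(A)[4]))
    Z <- sweep(P %*% net$params[[paste0("We", l)]], 2,
      net$params[[paste0("be", l)]], `+`)
    A <- mat_to_array(relu(Z), g$OH, g$OW, dim(A)[4])
    acts[[paste0("P", l)]] <- P
    acts[[paste0("A", l)]] <- A
  }
  N <- dim(A)[4]
  flat <- matrix(A, net$flat, N) # (flat, N), h-w-channel column-major
  latent <- t(flat) %*% net$params$Wfc
  latent <- sweep(latent, 2, net$params$bfc, `+`) # (N, latent)
  acts$flat <- flat
  acts$latent <- latent
  D <- relu(sweep(latent %*% net$params$Wdf, 2, net$params$bdf, `+`)) # (N, flat)
  acts$D <- D
  A <- array(t(D), c(net$side, net$side, net$geoms[[nb]]$cout, N))
  for (l in rev(seq_len(nb))) {
    g <- net$geoms[[l]]
    M <- array_to_mat(A) # (OH*OW*N, cout)
    big <- col2im(M %*% t(net$params[[paste0("Wd", l)]]), g,
      cache$get(l, N), N) # (H, W, cin, N)
    big <- sweep(big, 3, net$params[[paste0("bd", l)]], `+`)
    acts[[paste0("Dpre", l)]] <- big
    A <- if (l > 1) relu(big) else sigmoid(big)
    acts[[paste0("Dact", l)]] <- A
  }
  acts$xhat <- A
  acts
}

# negative Cox partial log-likelihood (Breslow) and gradient wrt risk
cox_loss_grad <- function(risk, time, event) {
  n <- length(risk)
  d <- sum(event)
  if (d == 0) return(list(loss = 0, grad = numeric(n)))
  er <- exp(risk - max(risk))
  ord <- order(time) # ascending; risk set of i = {j: t_j >= t_i}
  er_o <- er[ord]
  # cumulative risk-set sums from the back
  rs <- rev(cumsum(rev(er_o)))
  ev_o <- event[ord] == 1
  loss <- -sum((risk[ord][ev_o] - max(risk)) - log(rs[ev_o])) / d
  # grad_k = -(1/d) [e_k - er_k * sum_{i events with t_i <= t_k} 1/rs_i]
  inv_rs <- ifelse(ev_o, 1 / rs, 0)
  cum_inv <- cumsum(inv_rs)
  grad_o <- -(as.numeric(ev_o) - er_o * cum_inv) / d
  grad <- numeric(n)
  grad[ord] <- grad_o
  list(loss = loss, grad = grad)
}

# one training step on a batch; returns loss and parameter gradients
cae_backward <- function(X, net, cfg, cache, surv = NULL) {
  acts <- cae_forward(X, net, cfg, cache)
  N <- dim(X)[4]
  nb <- length(net$geoms)
  xhat <- acts$xhat
  resid <- xhat - X
  mse <- mean(resid^2)
  grads <- list()
  dA <- 2 * resid / length(resid)
  loss <- mse
  d_latent <- matrix(0, N, cfg$latent_dim)
  if (cfg$lambda_prognostic > 0) {
    if (is.null(surv)) stop_invalid("prognostic loss requires survival data.")
    risk <- drop(acts$latent %*% net$params$Wrisk) + net$params$brisk
    cl <- cox_loss_grad(risk, surv$time, surv$event)
    loss <- loss + cfg$lambda_prognostic * cl$loss
    dr <- cfg$lambda_prognostic * cl$grad # (N)
    grads$Wrisk <- t(acts$latent) %*% matrix(dr, ncol = 1)
    grads$brisk <- sum(dr)
    d_latent <- d_latent + outer(dr, drop(net$params$Wrisk))
  } else {
    grads$Wrisk <- matrix(0, cfg$latent_dim, 1)
    grads$brisk <- 0
  }
  # decoder backward
  for (l in seq_len(nb)) {
    g <- net$geoms[[l]]
    pre <- acts[[paste0("Dpre", l)]]
    dpre <- if (l == 1) {
      s <- acts$Dact1
      dA * s * (1 - s)
    } else {
      dA * (pre > 0)
    }
    grads[[paste0("bd", l)]] <- apply(dpre, 3, sum)
    Pd <- im2col(dpre, g, cache$get(l, N))
    # small input of this transposed layer, as an (OH*OW*N, cout) matrix
    Xs <- if (l == nb) {
      array_to_mat(array(t(acts$D), c(net$side, net$side, g$cout, N)))
    } else {
      array_to_mat(acts[[paste0("Dact", l + 1)]])
    }
    grads[[paste0("Wd", l)]] <- t(Pd) %*% Xs
    dSmall <- Pd %*% net$params[[paste0("Wd", l)]] # (OH*OW*N, cout)
    dA <- mat_to_array(dSmall, g$OH, g$OW, N)
  }
  # dA now (side, side, c_last, N) = gradient wrt reshaped dense output
  dD <- t(matrix(dA, net$flat, N)) * (acts$D > 0) # (N, flat)
  grads$Wdf <- t(acts$latent) %*% dD
  grads$bdf <- colSums(dD)
  d_latent <- d_latent + dD %*% t(net$params$Wdf)
  grads$Wfc <- acts$flat %*% d_latent
  grads$bfc <- colSums(d_latent)
  dflat <- net$params$Wfc %*% t(d_latent) # (flat, N)
  dA <- array(dflat, c(net$side, net$side, net$geoms[[nb]]$cout, N))
  # encoder backward
  for (l in rev(seq_len(nb))) {
    g <- net$geoms[[l]]
    dZ <- array_to_mat(dA) * (array_to_mat(acts[[paste0("A", l)]]) > 0)
    grads[[paste0("We", l)]] <- t(acts[[paste0("P", l)]]) %*% dZ
    grads[[paste0("be", l)]] <- colSums(dZ)
    if (l > 1) {
      dP <- dZ %*% t(net$params[[paste0("We", l)]])
      dA <- col2im(dP, g, cache$get(l, N), N)
    }
  }
  list(loss = loss, mse = mse, grads = grads)
}

adam_update <- function(net, grads, state, lr, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(net$params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gr
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gr^2
    mhat <- state$m[[nm]] / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    net$params[[nm]] <- net$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(net = net, state = state)
}

# normalize input into array (H, W, 1, N) in [0, 1]
prep_images <- function(images, input_size) {
  if (is.list(images)) {
    images <- simplify2array(images) # (H, W, N)
  }
  d <- dim(images)
  if (length(d) == 2) images <- array(images, c(d, 1))
  d <- dim(images)
  if (d[1] != d[2]) stop_invalid("images must be square.")
  if (d[1] != input_size) {
    images <- simplify2array(lapply(seq_len(d[3]), function(n) {
      resize_bilinear(images[, , n], input_size)
    }))
    d <- dim(images)
  }
  rng <- range(images)
  if (rng[1] < 0 || rng[2] > 1) {
    if (diff(rng) == 0) {
      images <- array(0, d)
    } else {
      images <- (images - rng[1]) / diff(rng)
    }
  }
  array(images, c(d[1], d[2], 1, d[3]))
}

# single full training run on a prepared array
train_network <- function(X, surv, cfg, seed) {
  net <- NULL
  history <- NULL
  with_seed(seed, {
    net <- init_params(cfg)
    cache <- index_cache(net$geoms)
    state <- list(
      m = lapply(net$params, function(p) p * 0),
      v = lapply(net$params, function(p) p * 0)
    )
    N <- dim(X)[4]
    t_step <- 0
    losses <- numeric(cfg$epochs)
    mses <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      lr_ep <- if (identical(cfg$lr_schedule, "cosine")) {
        frac <- (ep - 1) / max(cfg$epochs - 1, 1)
        cfg$learning_rate * (0.1 + 0.9 * (1 + cos(pi * frac)) / 2)
      } else {
        cfg$learning_rate
      }
      ord <- sample.int(N)
      ep_loss <- 0; ep_mse <- 0; nb_batches <- 0
      for (start in seq(1, N, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, N)]
        if (length(idx) < 2) next
        Xb <- X[, , , idx, drop = FALSE]
        if (cfg$augment) {
          for (q in seq_along(idx)) {
            Xb[, , 1, q] <- augment_image(Xb[, , 1, q],
              seed = sample.int(2^30, 1))
          }
        }
        sb <- if (!is.null(surv)) surv[idx, , drop = FALSE] else NULL
        bk <- cae_backward(Xb, net, cfg, cache, sb)
        if (!is.finite(bk$loss)) {
          abort("non-finite training loss", class = "sarcomix_training_failure",
            history = tibble(epoch = seq_len(ep - 1),
              loss = losses[seq_len(ep - 1)]))
        }
        t_step <- t_step + 1
        upd <- adam_update(net, bk$grads, state, lr_ep, t_step)
        net <- upd$net; state <- upd$state
        ep_loss <- ep_loss + bk$loss; ep_mse <- ep_mse + bk$mse
        nb_batches <- nb_batches + 1
      }
      losses[ep] <- ep_loss / max(nb_batches, 1)
      mses[ep] <- ep_mse / max(nb_batches, 1)
    }
    history <- tibble(epoch = seq_len(cfg$epochs), loss = losses, mse = mses)
  })
  list(net = net, history = history)
}

#' Train a (half-supervised) convolutional autoencoder
#'
#' Runs `cv_repeats` random holdout splits (each leaving out
#' `holdout_fraction` of the images), recording the held-out reconstruction
#' MSE per repeat, then optionally refits on all images. With
#' `lambda_prognostic > 0` the survival table is required and the Cox
#' prognostic loss is added batch-wise.
#'
#' @param images 3-D array (H, W, N), list of matrices, or (H, W, 1, N)
#'   array; intensities are min-max normalized to `[0, 1]` if needed and
#'   resized to `config$input_size`.
#' @param survival Optional data frame with `time` and `event` rows aligned
#'   to the images (required when `lambda_prognostic > 0`).
#' @param config A [cae_config()].
#' @return A `cae_model`: trained parameters, config, training history,
#'   and `holdout` tibble (`repeat`, `mse`).
#' @export
cae_train <- function(images, survival = NULL, config = cae_config()) {
  cfg <- config
  if (cfg$lambda_prognostic > 0 && is.null(survival)) {
    stop_invalid("`survival` is required when lambda_prognostic > 0.")
  }
  X <- prep_images(images, cfg$input_size)
  N <- dim(X)[4]
  if (!is.null(survival) && nrow(survival) != N) {
    stop_invalid("`survival` misaligned with images.")
  }
  holdout <- NULL
  last_fit <- NULL
  n_hold <- max(1, round(cfg$holdout_fraction * N))
  reps <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$cv_repeats), function(r) {
      list(hold = sample.int(N, n_hold), seed = sample.int(2^30, 1))
    })
  })
  hold_mse <- numeric(cfg$cv_repeats)
  for (r in seq_len(cfg$cv_repeats)) {
    hold <- reps[[r]]$hold
    tr <- setdiff(seq_len(N), hold)
    sv <- if (!is.null(survival)) survival[tr, , drop = FALSE] else NULL
    fit <- train_network(X[, , , tr, drop = FALSE], sv, cfg, reps[[r]]$seed)
    rec <- forward_reconstruct(fit$net, cfg, X[, , , hold, drop = FALSE])
    hold_mse[r] <- mean((rec - X[, , , hold, drop = FALSE])^2)
    last_fit <- fit
  }
  if (cfg$final_refit || is.null(last_fit)) {
    final <- train_network(X, survival, cfg, derive_seed(cfg$seed, "cae"))
  } else {
    final <- last_fit
  }
  structure(list(
    net = final$net, config = cfg, history = final$history,
    holdout = tibble(repeat_id = seq_len(cfg$cv_repeats), mse = hold_mse),
    trained = TRUE
  ), class = "cae_model")
}

#' @export
print.cae_model <- function(x, ...) {
  cat(sprintf(
    "<cae_model> input %dx%d, latent %d, lambda = %g, held-out MSE %s\n",
    x$config$input_size, x$config$input_size, x$config$latent_dim,
    x$config$lambda_prognostic,
    paste(signif(x$holdout$mse, 3), collapse = ", ")
  ))
  invisible(x)
}

#' Training-history plot
#' @param object A `cae_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cae_model <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Training loss")
}

forward_reconstruct <- function(net, cfg, X) {
  cae_forward(X, net, cfg, index_cache(net$geoms))$xhat
}

# encoder-only forward pass
forward_latent <- function(net, cfg, X) {
  cache <- index_cache(net$geoms)
  A <- X
  for (l in seq_along(net$geoms)) {
    g <- net$geoms[[l]]
    P <- im2col(A, g, cache$get(l, dim(A)[4]))
    Z <- sweep(P %*% net$params[[paste0("We", l)]], 2,
      net$params[[paste0("be", l)]], `+`)
    A <- mat_to_array(relu(Z), g$OH, g$OW, dim(A)[4])
  }
  flat <- matrix(A, net$flat, dim(X)[4])
  sweep(t(flat) %*% net$params$Wfc, 2, net$params$bfc, `+`)
}

#' Reconstruction error report
#'
#' Per-image mean squared error between input and reconstruction on the
#' `[0, 1]` intensity scale, plus the aggregate mean. The reference quality
#' contract is an aggregate below 0.01 (i.e. "below 1%").
#'
#' @param model A trained `cae_model`.
#' @param images Images as in [cae_train()].
#' @return A list: `mse` (aggregate), `per_subject` tibble.
#' @export
reconstruction_mse <- function(model, images) {
  X <- prep_images(images, model$config$input_size)
  rec <- forward_reconstruct(model$net, model$config, X)
  per <- vapply(seq_len(dim(X)[4]), function(n) {
    mean((rec[, , 1, n] - X[, , 1, n])^2)
  }, numeric(1))
  list(mse = mean(per),
    per_subject = tibble(subject = seq_along(per), mse = per))
}

#' Extract latent deep-radiomics features
#'
#' Encoder forward pass only; one row per image, `latent_dim` columns.
#'
#' @inheritParams reconstruction_mse
#' @return Numeric matrix, images x latent dimensions.
#' @export
extract_latent <- function(model, images) {
  if (!isTRUE(model$trained)) {
    abort("model is not trained.", class = "sarcomix_invalid_state")
  }
  X <- prep_images(images, model$config$input_size)
  L <- forward_latent(model$net, model$config, X)
  colnames(L) <- sprintf("drf%04d", seq_len(ncol(L)))
  L
}

#' Gradient-weighted class-activation map of the prognostic head
#'
#' For a half-supervised model, each activation of the last encoder
#' convolution is weighted by the gradient of the risk output with respect
#' to it — for the linear latent/risk head this product is exactly the
#' activation's additive contribution to the predicted risk. The rectified
#' channel sum is upsampled to the input size, highlighting the image
#' regions driving the risk prediction.
#'
#' @param model A `cae_model` trained with `lambda_prognostic > 0`.
#' @param image A single 2-D image.
#' @return Non-negative matrix of the input size.
#' @export
class_activation_map <- function(model, image) {
  if (model$config$lambda_prognostic <= 0) {
    abort("class activation maps require a prognostic head (lambda > 0).",
      class = "sarcomix_unsupported_operation")
  }
  X <- prep_images(list(image), model$config$input_size)
  net <- model$net
  cfg <- model$config
  acts <- cae_forward(X, net, cfg, index_cache(net$geoms))
  nb <- length(net$geoms)
  A4 <- acts[[paste0("A", nb)]][, , , 1] # (side, side, c_last)
  # closed-form gradient of risk wrt the flattened last activations; the
  # elementwise product with the activations is each unit's contribution
  # to the risk output
  dflat <- drop(net$params$Wfc %*% net$params$Wrisk) # (flat)
  gA <- array(dflat, dim(A4))
  contrib <- gA * A4
  cam <- apply(contrib, c(1, 2), sum)
  cam[cam < 0] <- 0
  resize_bilinear(cam, cfg$input_size)
}

# ---- 2-D resampling & augmentation -----------------------------------

# bilinear sample of img at fractional coordinates (matrices xi, yi);
# outside the grid -> 0
bilinear_sample <- function(img, xi, yi) {
  H <- nrow(img); W <- ncol(img)
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  get <- function(ix, iy) {
    v <- numeric(length(ix))
    ok <- ix >= 1 & ix <= H & iy >= 1 & iy <= W
    v[ok] <- img[cbind(ix[ok], iy[ok])]
    v
  }
  v <- get(x0, y0) * (1 - fx) * (1 - fy) +
    get(x0 + 1, y0) * fx * (1 - fy) +
    get(x0, y0 + 1) * (1 - fx) * fy +
    get(x0 + 1, y0 + 1) * fx * fy
  matrix(v, H, W)
}

resize_bilinear <- function(img, size) {
  H <- nrow(img); W <- ncol(img)
  xi <- matrix(seq(1, H, length.out = size), size, size)
  yi <- matrix(seq(1, W, length.out = size), size, size, byrow = TRUE)
  H2 <- size
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  cl <- function(v, n) pmin(pmax(v, 1), n)
  g <- function(ix, iy) img[cbind(as.vector(cl(ix, H)), as.vector(cl(iy, W)))]
  v <- g(x0, y0) * as.vector((1 - fx) * (1 - fy)) +
    g(x0 + 1, y0) * as.vector(fx * (1 - fy)) +
    g(x0, y0 + 1) * as.vector((1 - fx) * fy) +
    g(x0 + 1, y0 + 1) * as.vector(fx * fy)
  matrix(v, H2, H2)
}

#' Random morphological augmentation of a tumor slice
#'
#' Composition of random horizontal/vertical flips, rotation within +/- 20
#' degrees, zoom within +/- 10%, a mild elastic deformation, and
#' multiplicative intensity jitter within +/- 5%; the output is clipped to
#' `[0, 1]` and keeps the input shape. Deterministic given the seed; exact
#' parameters can be forced via `params` (flips alone are exact index
#' reversals, so two identical flips compose to the identity).
#'
#' @param image 2-D numeric matrix in `[0, 1]`.
#' @param seed Integer seed (ignored when `params` is given).
#' @param params Optional list overriding `flip_h`, `flip_v`, `angle`
#'   (degrees), `zoom`, `elastic` (displacement sd in pixels), `jitter`.
#' @return Augmented matrix of the same shape.
#' @export
augment_image <- function(image, seed = 1, params = NULL) {
  H <- nrow(image); W <- ncol(image)
  if (H != W) stop_invalid("image must be square.")
  if (is.null(params)) {
    params <- with_seed(seed, list(
      flip_h = runif(1) < 0.5, flip_v = runif(1) < 0.5,
      angle = runif(1, -20, 20), zoom = runif(1, 0.9, 1.1),
      elastic = runif(1, 0, 1.5), jitter = runif(1, 0.95, 1.05),
      noise_seed = sample.int(2^30, 1)
    ))
  }
  params <- utils::modifyList(list(
    flip_h = FALSE, flip_v = FALSE, angle = 0, zoom = 1, elastic = 0,
    jitter = 1, noise_seed = 1
  ), params)
  out <- image
  if (params$flip_h) out <- out[, rev(seq_len(W))]
  if (params$flip_v) out <- out[rev(seq_len(H)), ]
  if (params$angle != 0 || params$zoom != 1 || params$elastic > 0) {
    ctr <- (H + 1) / 2
    gx <- matrix(seq_len(H) - ctr, H, W)
    gy <- matrix(seq_len(W) - ctr, H, W, byrow = TRUE)
    th <- params$angle * pi / 180
    sc <- 1 / params$zoom
    xi <- ctr + sc * (cos(th) * gx - sin(th) * gy)
    yi <- ctr + sc * (sin(th) * gx + cos(th) * gy)
    if (params$elastic > 0) {
      disp <- with_seed(params$noise_seed, {
        dx <- matrix(rnorm(H * W), H, W)
        dy <- matrix(rnorm(H * W), H, W)
        sm <- function(m) {
          a <- array(m, c(H, W, 1))
          smooth_gaussian(a, c(3, 3, 0))[, , 1]
        }
        list(x = sm(dx), y = sm(dy))
      })
      xi <- xi + params$elastic * disp$x / max(abs(disp$x))
      yi <- yi + params$elastic * disp$y / max(abs(disp$y))
    }
    out <- bilinear_sample(out, xi, yi)
  }
  out <- out * params$jitter
  pmin(pmax(out, 0), 1)
}
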