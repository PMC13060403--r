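#' Configure the mixed-data beta-VAE
#'
#' Fully connected encoder/decoder with LeakyReLU activations, batch
#' normalization and dropout, mapping inputs to a Gaussian latent space via
#' the reparameterization trick. Categorical inputs are reconstructed through
#' per-feature softmax heads (cross-entropy loss), continuous inputs through
#' linear heads (squared-error loss); the Kullback-Leibler term against the
#' standard-normal prior is weighted by `beta_final` after warm-up.
#'
#' @param hidden_layers integer vector of hidden-layer widths (default 600).
#' @param latent_dim number of latent dimensions J (default 40).
#' @param dropout_rate dropout probability (default 0.2).
#' @param beta_final final KL weight beta (default 0.001).
#' @param leaky_slope negative-side slope of the LeakyReLU (default 0.01).
#' @param learning_rate Adam step size (default 1e-4).
#' @return an object of class `vae_config`.
#' @export
vae_config <- function(hidden_layers = 600L, latent_dim = 40L,
                       dropout_rate = 0.2, beta_final = 0.001,
                       leaky_slope = 0.01, learning_rate = 1e-4) {
  stopifnot(latent_dim >= 1, all(hidden_layers >= 1),
            dropout_rate >= 0, dropout_rate < 1, beta_final >= 0,
            leaky_slope >= 0, learning_rate > 0)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 latent_dim = as.integer(latent_dim),
                 dropout_rate = dropout_rate, beta_final = beta_final,
                 leaky_slope = leaky_slope, learning_rate = learning_rate),
            class = "vae_config")
}

#' Configure the training schedule
#'
#' Encodes the two dynamic schedules used during optimization: KLD warm-up
#' (beta held at 0, then raised linearly from `warmup_start` to its final
#' value at `warmup_end`) and batch dilation (the mini-batch size multiplied
#' by `dilation_factor` at each epoch in `dilation_epochs`).
#'
#' @param total_epochs training epochs (default 300).
#' @param warmup_start,warmup_end warm-up window (defaults 80 and 150).
#' @param dilation_epochs epochs at which the batch dilates (50, 100, 150).
#' @param dilation_factor multiplicative dilation (default 1.5).
#' @param base_batch_size starting mini-batch size N (default 64).
#' @param seed master seed for initialization, shuffling and sampling.
#' @return an object of class `training_schedule`.
#' @export
training_schedule <- function(total_epochs = 300L, warmup_start = 80L,
                              warmup_end = 150L,
                              dilation_epochs = c(50L, 100L, 150L),
                              dilation_factor = 1.5, base_batch_size = 64L,
                              seed = 1L) {
  stopifnot(warmup_start < warmup_end, warmup_end <= total_epochs,
            dilation_factor > 1, base_batch_size >= 1, total_epochs >= 1)
  structure(list(total_epochs = as.integer(total_epochs),
                 warmup_start = as.integer(warmup_start),
                 warmup_end = as.integer(warmup_end),
                 dilation_epochs = as.integer(dilation_epochs),
                 dilation_factor = dilation_factor,
                 base_batch_size = as.integer(base_batch_size),
                 seed = as.integer(seed)),
            class = "training_schedule")
}

check_epoch <- function(epoch, schedule) {
  if (epoch < 0 || epoch >= schedule$total_epochs) {
    fail("epoch ", epoch, " outside [0, ", schedule$total_epochs, ")")
  }
}

#' KL weight at a given epoch
#'
#' 0 before `warmup_start`, the final beta at and after `warmup_end`, and
#' linearly interpolated in between.
#'
#' @param epoch 0-based epoch index.
#' @param schedule a [training_schedule()].
#' @param beta_final final KL weight (default taken from [vae_config()]).
#' @return the scalar beta applied at that epoch.
#' @export
beta_at_epoch <- function(epoch, schedule, beta_final = 0.001) {
  check_epoch(epoch, schedule)
  if (epoch < schedule$warmup_start) return(0)
  if (epoch >= schedule$warmup_end) return(beta_final)
  beta_final * (epoch - schedule$warmup_start) /
    (schedule$warmup_end - schedule$warmup_start)
}

#' Mini-batch size at a given epoch
#'
#' The base size, multiplied by `dilation_factor` at each dilation epoch the
#' given epoch has reached, rounded to the nearest integer (minimum 2) after
#' each dilation.
#'
#' @inheritParams beta_at_epoch
#' @return integer batch size.
#' @export
batch_size_at_epoch <- function(epoch, schedule) {
  check_epoch(epoch, schedule)
  size <- schedule$base_batch_size
  for (d in schedule$dilation_epochs) {
    if (epoch >= d) size <- max(2L, as.integer(round(size * schedule$dilation_factor)))
  }
  size
}

#' Kullback-Leibler divergence of the encoder posterior from the prior
#'
#' `KLD = -(1/2N) * sum_i sum_j (1 + ln(sigma^2) - mu^2 - sigma^2)`, summed
#' over the J latent dimensions of each of the N samples in the batch. It is
#' non-negative for any input and 0 exactly when mu = 0 and sigma^2 = 1.
#'
#' @param mu matrix (N x J) of posterior means.
#' @param logvar matrix (N x J) of posterior log-variances.
#' @param n batch size N; must equal `nrow(mu)`.
#' @return scalar KLD.
#' @export
kld_term <- function(mu, logvar, n = nrow(mu)) {
  mu <- as.matrix(mu); logvar <- as.matrix(logvar)
  if (!all(dim(mu) == dim(logvar))) fail("mu/logvar shape mismatch")
  if (!is.finite(n) || n <= 0) fail("batch size N must be positive")
  if (n != nrow(mu)) fail("N must equal the number of rows")
  if (!all(is.finite(mu)) || !all(is.finite(logvar))) fail("non-finite input")
  -(1 / (2 * n)) * sum(1 + logvar - mu^2 - exp(logvar))
}

## ---- column layout -------------------------------------------------------

## Splits the encoded columns into the continuous block and per-feature
## categorical softmax groups; cached on the model.
column_layout <- function(column_map) {
  cont <- which(column_map$type == "continuous")
  cat_feats <- unique(column_map$feature[column_map$type == "categorical"])
  groups <- lapply(cat_feats, function(f) {
    which(column_map$feature == f & column_map$type == "categorical")
  })
  names(groups) <- cat_feats
  list(cont = cont, groups = groups,
       n_con = length(cont), n_cat = length(groups))
}

#' Masked reconstruction losses for mixed data
#'
#' Computes the categorical (cross-entropy over per-feature softmax
#' probabilities) and continuous (squared error) reconstruction losses,
#' with missing entries contributing exactly zero. Each term is normalized
#' by (number of features of that family x batch size).
#'
#' @param batch input matrix (N x encoded columns).
#' @param reconstruction matrix of the same shape: probabilities for
#'   categorical columns (each observed group must lie in [0,1]), values for
#'   continuous columns.
#' @param mask logical matrix, `TRUE` where the entry is missing.
#' @param column_map the encoded-column map of a `preprocessed_matrix`.
#' @return list with `Ecat` and `Econ`.
#' @export
reconstruction_losses <- function(batch, reconstruction, mask, column_map) {
  lay <- column_layout(column_map)
  nb <- nrow(batch)
  if (!all(dim(batch) == dim(reconstruction)) || !all(dim(batch) == dim(mask))) {
    fail("batch / reconstruction / mask shapes differ")
  }
  econ <- 0
  if (lay$n_con > 0) {
    d <- (reconstruction[, lay$cont, drop = FALSE] -
            batch[, lay$cont, drop = FALSE])
    d[mask[, lay$cont, drop = FALSE]] <- 0
    econ <- sum(d^2) / (lay$n_con * nb)
  }
  ecat <- 0
  if (lay$n_cat > 0) {
    for (g in lay$groups) {
      p <- reconstruction[, g, drop = FALSE]
      obs <- !mask[, g[1]]
      if (any(p[obs, ] < -1e-9 | p[obs, ] > 1 + 1e-9)) {
        fail("categorical reconstruction probabilities outside [0, 1]")
      }
      tgt <- batch[, g, drop = FALSE]
      ll <- rowSums(tgt * log(pmax(p, 1e-12)))
      ecat <- ecat - sum(ll[obs])
    }
    ecat <- ecat / (lay$n_cat * nb)
  }
  list(Ecat = econ_clean(ecat), Econ = econ_clean(econ))
}

econ_clean <- function(x) if (abs(x) < 1e-300) 0 else x

## ---- layers --------------------------------------------------------------

new_linear <- function(n_in, n_out, scale = sqrt(2 / n_in)) {
  list(type = "linear",
       W = matrix(stats::rnorm(n_in * n_out, sd = scale), n_in, n_out),
       b = rep(0, n_out))
}

new_bn <- function(n) {
  list(type = "bn", gamma = rep(1, n), beta = rep(0, n),
       running_mean = rep(0, n), running_var = rep(1, n))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

## forward through one hidden block: linear -> bn -> leakyrelu -> dropout
## `env` carries training flag, dropout rate and leaky slope.
block_forward <- function(lin, bn, X, env) {
  Z <- X %*% lin$W + matrix(lin$b, nrow(X), length(lin$b), byrow = TRUE)
  if (env$training) {
    m <- colMeans(Z)
    v <- colMeans(Z^2) - m^2
    bn$running_mean <- (1 - BN_MOMENTUM) * bn$running_mean + BN_MOMENTUM * m
    bn$running_var <- (1 - BN_MOMENTUM) * bn$running_var + BN_MOMENTUM * v
  } else {
    m <- bn$running_mean
    v <- bn$running_var
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  Xhat <- sweep(sweep(Z, 2, m), 2, invstd, "*")
  A <- sweep(Xhat, 2, bn$gamma, "*")
  A <- sweep(A, 2, bn$beta, "+")
  neg <- A < 0
  H <- A
  H[neg] <- env$slope * H[neg]
  if (env$training && env$dropout > 0) {
    keep <- matrix(stats::runif(length(H)) >= env$dropout, nrow(H), ncol(H))
    H <- H * keep / (1 - env$dropout)
  } else {
    keep <- NULL
  }
  list(out = H, bn = bn,
       cache = list(X = X, Xhat = Xhat, invstd = invstd, neg = neg,
                    keep = keep))
}

block_backward <- function(lin, bn, cache, dH, env) {
  if (!is.null(cache$keep)) dH <- dH * cache$keep / (1 - env$dropout)
  dA <- dH
  dA[cache$neg] <- env$slope * dA[cache$neg]
  dgamma <- colSums(dA * cache$Xhat)
  dbeta <- colSums(dA)
  if (env$training) {
    B <- nrow(dA)
    dXhat <- sweep(dA, 2, bn$gamma, "*")
    s1 <- colSums(dXhat)
    s2 <- colSums(dXhat * cache$Xhat)
    dZ <- sweep(
      dXhat - sweep(matrix(1, B, 1) %*% t(s1), 2, rep(1, length(s1)), "*") / B -
        sweep(cache$Xhat, 2, s2, "*") / B,
      2, cache$invstd, "*")
  } else {
    dZ <- sweep(sweep(dA, 2, bn$gamma, "*"), 2, cache$invstd, "*")
  }
  list(dW = crossprod(cache$X, dZ), db = colSums(dZ),
       dgamma = dgamma, dbeta = dbeta, dX = dZ %*% t(lin$W))
}

## ---- model ---------------------------------------------------------------

#' Initialize an untrained VAE
#'
#' @param column_map encoded-column map from [fit_transform()].
#' @param config a [vae_config()].
#' @param seed initialization seed.
#' @return an object of class `vae_model`.
#' @export
init_vae <- function(column_map, config = vae_config(), seed = 1L) {
  lay <- column_layout(column_map)
  d_in <- nrow(column_map)
  J <- config$latent_dim
  with_seed(seed, {
    enc_lin <- list(); enc_bn <- list()
    w <- d_in
    for (h in config$hidden_layers) {
      enc_lin[[length(enc_lin) + 1L]] <- new_linear(w, h)
      enc_bn[[length(enc_bn) + 1L]] <- new_bn(h)
      w <- h
    }
    mu_head <- new_linear(w, J, scale = sqrt(1 / w))
    lv_head <- new_linear(w, J, scale = sqrt(1 / w))
    dec_lin <- list(); dec_bn <- list()
    w <- J
    for (h in rev(config$hidden_layers)) {
      dec_lin[[length(dec_lin) + 1L]] <- new_linear(w, h)
      dec_bn[[length(dec_bn) + 1L]] <- new_bn(h)
      w <- h
    }
    out_head <- new_linear(w, d_in, scale = sqrt(1 / w))
    structure(list(config = config, column_map = column_map,
                   column_hash = rlang::hash(column_map), layout = lay,
                   enc_lin = enc_lin, enc_bn = enc_bn,
                   mu_head = mu_head, lv_head = lv_head,
                   dec_lin = dec_lin, dec_bn = dec_bn,
                   out_head = out_head,
                   history = NULL, trained = FALSE),
              class = "vae_model")
  })
}

## full forward pass; eps = NULL draws fresh noise, eps = 0 sets z = mu.
vae_forward <- function(model, X, mask, training = FALSE, eps = NULL) {
  env <- list(training = training, dropout = model$config$dropout_rate,
              slope = model$config$leaky_slope)
  Xin <- X
  Xin[mask] <- 0  # masked entries enter the encoder as the zero placeholder
  caches <- list()
  H <- Xin
  for (i in seq_along(model$enc_lin)) {
    fw <- block_forward(model$enc_lin[[i]], model$enc_bn[[i]], H, env)
    model$enc_bn[[i]] <- fw$bn
    caches[[paste0("enc", i)]] <- fw$cache
    H <- fw$out
  }
  mu <- H %*% model$mu_head$W +
    matrix(model$mu_head$b, nrow(H), ncol(model$mu_head$W), byrow = TRUE)
  logvar <- H %*% model$lv_head$W +
    matrix(model$lv_head$b, nrow(H), ncol(model$lv_head$W), byrow = TRUE)
  logvar <- pmin(pmax(logvar, -10), 10)
  if (is.null(eps)) {
    epsm <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  } else {
    epsm <- matrix(eps, nrow(mu), ncol(mu))
  }
  sd <- exp(0.5 * logvar)
  Z <- mu + sd * epsm
  caches$enc_top <- H
  D <- Z
  for (i in seq_along(model$dec_lin)) {
    fw <- block_forward(model$dec_lin[[i]], model$dec_bn[[i]], D, env)
    model$dec_bn[[i]] <- fw$bn
    caches[[paste0("dec", i)]] <- fw$cache
    D <- fw$out
  }
  logits <- D %*% model$out_head$W +
    matrix(model$out_head$b, nrow(D), ncol(model$out_head$W), byrow = TRUE)
  recon <- logits
  for (g in model$layout$groups) {
    lg <- logits[, g, drop = FALSE]
    lg <- lg - apply(lg, 1, max)
    e <- exp(lg)
    recon[, g] <- e / rowSums(e)
  }
  list(model = model, mu = mu, logvar = logvar, z = Z, eps = epsm, sd = sd,
       recon = recon, logits = logits, dec_top = D, caches = caches, env = env)
}

#' Loss (and optionally gradients) of a VAE on one batch
#'
#' Runs a forward pass and evaluates the total loss
#' `L = Ecat + Econ + beta * KLD` with missing entries excluded. With
#' `deterministic = TRUE` the latent noise is suppressed (`z = mu`), making
#' the result a pure function of the inputs — used by masking-invariance
#' checks and evaluation. With `return_grads = TRUE` the full parameter
#' gradient list is attached.
#'
#' @param model a `vae_model`.
#' @param x batch matrix.
#' @param mask logical missingness matrix aligned to `x`.
#' @param beta KL weight applied.
#' @param deterministic suppress reparameterization noise and dropout.
#' @param return_grads also return parameter gradients.
#' @return list with `Ecat`, `Econ`, `KLD`, `L`, `mu`, and `grads` if
#'   requested.
#' @export
vae_batch_loss <- function(model, x, mask, beta = model$config$beta_final,
                           deterministic = TRUE, return_grads = FALSE) {
  fw <- vae_forward(model, x, mask, training = !deterministic,
                    eps = if (deterministic) 0 else NULL)
  losses <- reconstruction_losses(x, fw$recon, mask, model$column_map)
  kld <- kld_term(fw$mu, fw$logvar)
  out <- list(Ecat = losses$Ecat, Econ = losses$Econ, KLD = kld,
              L = losses$Ecat + losses$Econ + beta * kld, mu = fw$mu)
  if (return_grads) {
    out$grads <- vae_backward(model, fw, x, mask, beta)
  }
  out
}

## gradients of L wrt all parameters, given a forward pass
vae_backward <- function(model, fw, x, mask, beta) {
  lay <- model$layout
  nb <- nrow(x)
  dlogits <- matrix(0, nrow(x), ncol(x))
  if (lay$n_con > 0) {
    d <- 2 * (fw$recon[, lay$cont, drop = FALSE] -
                x[, lay$cont, drop = FALSE])
    d[mask[, lay$cont, drop = FALSE]] <- 0
    dlogits[, lay$cont] <- d / (lay$n_con * nb)
  }
  for (g in lay$groups) {
    obs <- !mask[, g[1]]
    dg <- fw$recon[, g, drop = FALSE] - x[, g, drop = FALSE]
    dg[!obs, ] <- 0
    dlogits[, g] <- dg / (lay$n_cat * nb)
  }
  grads <- list()
  grads$out_head <- list(dW = crossprod(fw$dec_top, dlogits),
                         db = colSums(dlogits))
  dD <- dlogits %*% t(model$out_head$W)
  for (i in rev(seq_along(model$dec_lin))) {
    bw <- block_backward(model$dec_lin[[i]], model$dec_bn[[i]],
                         fw$caches[[paste0("dec", i)]], dD, fw$env)
    grads[[paste0("dec", i)]] <- bw
    dD <- bw$dX
  }
  dZ <- dD
  # KLD gradients: d/dmu = beta*mu/N ; d/dlogvar = beta*(sigma^2 - 1)/(2N)
  dmu <- dZ + beta * fw$mu / nb
  dlogvar <- dZ * fw$sd * fw$eps * 0.5 + beta * (exp(fw$logvar) - 1) / (2 * nb)
  H <- fw$caches$enc_top
  grads$mu_head <- list(dW = crossprod(H, dmu), db = colSums(dmu))
  grads$lv_head <- list(dW = crossprod(H, dlogvar), db = colSums(dlogvar))
  dH <- dmu %*% t(model$mu_head$W) + dlogvar %*% t(model$lv_head$W)
  for (i in rev(seq_along(model$enc_lin))) {
    bw <- block_backward(model$enc_lin[[i]], model$enc_bn[[i]],
                         fw$caches[[paste0("enc", i)]], dH, fw$env)
    grads[[paste0("enc", i)]] <- bw
    dH <- bw$dX
  }
  grads
}

## ---- Adam ----------------------------------------------------------------

adam_init <- function(model) {
  zero_like <- function(l) list(W = l$W * 0, b = l$b * 0)
  zero_bn <- function(l) list(gamma = l$gamma * 0, beta = l$beta * 0)
  st <- list(t = 0)
  for (i in seq_along(model$enc_lin)) {
    st[[paste0("enc", i)]] <- list(m = c(zero_like(model$enc_lin[[i]]),
                                         zero_bn(model$enc_bn[[i]])),
                                   v = c(zero_like(model$enc_lin[[i]]),
                                         zero_bn(model$enc_bn[[i]])))
  }
  for (i in seq_along(model$dec_lin)) {
    st[[paste0("dec", i)]] <- list(m = c(zero_like(model$dec_lin[[i]]),
                                         zero_bn(model$dec_bn[[i]])),
                                   v = c(zero_like(model$dec_lin[[i]]),
                                         zero_bn(model$dec_bn[[i]])))
  }
  for (h in c("mu_head", "lv_head", "out_head")) {
    st[[h]] <- list(m = zero_like(model[[h]]), v = zero_like(model[[h]]))
  }
  st
}

adam_update_one <- function(param, grad, state, lr, t,
                            b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (nm in names(grad)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grad[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grad[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    param[[nm]] <- param[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(param = param, state = state)
}

## ---- training ------------------------------------------------------------

#' Train the beta-VAE
#'
#' Adam optimization under the KLD warm-up and batch-dilation schedules.
#' Missing entries enter the encoder as zeros and contribute nothing to the
#' loss or gradients. Deterministic given the schedule seed (single-threaded
#' numeric kernels assumed).
#'
#' @param pm a `preprocessed_matrix` from [fit_transform()].
#' @param config a [vae_config()].
#' @param schedule a [training_schedule()].
#' @param rows optional row subset to train on (default all).
#' @param verbose print a line every 10 epochs.
#' @return the trained `vae_model`, with `$history` holding one row per
#'   epoch: `epoch`, `beta`, `batch_size`, `Ecat`, `Econ`, `KLD`, `L`
#'   (epoch means over batches).
#' @export
train_vae <- function(pm, config = vae_config(), schedule = training_schedule(),
                      rows = NULL, verbose = FALSE) {
  stopifnot(inherits(pm, "preprocessed_matrix"))
  rows <- rows %||% seq_len(nrow(pm$x))
  X <- pm$x[rows, , drop = FALSE]
  M <- pm$mask[rows, , drop = FALSE]
  model <- init_vae(pm$column_map, config, seed = derive_seed(schedule$seed, 11L))
  adam <- adam_init(model)
  lr <- config$learning_rate
  hist <- vector("list", schedule$total_epochs)
  with_seed(derive_seed(schedule$seed, 12L), {
    for (epoch in seq_len(schedule$total_epochs) - 1L) {
      beta_t <- beta_at_epoch(epoch, schedule, config$beta_final)
      bs <- batch_size_at_epoch(epoch, schedule)
      ord <- sample.int(nrow(X))
      starts <- seq(1L, nrow(X), by = bs)
      acc <- c(Ecat = 0, Econ = 0, KLD = 0)
      nbatch <- 0L
      for (s in starts) {
        idx <- ord[s:min(s + bs - 1L, nrow(X))]
        if (length(idx) < 2L) next  # batch-norm needs >= 2 samples
        fw <- vae_forward(model, X[idx, , drop = FALSE],
                          M[idx, , drop = FALSE], training = TRUE)
        # propagate updated batch-norm running stats
        model$enc_bn <- fw$model$enc_bn
        model$dec_bn <- fw$model$dec_bn
        losses <- reconstruction_losses(X[idx, , drop = FALSE], fw$recon,
                                        M[idx, , drop = FALSE],
                                        model$column_map)
        kld <- kld_term(fw$mu, fw$logvar)
        L <- losses$Ecat + losses$Econ + beta_t * kld
        if (!is.finite(L)) {
          fail("non-finite loss at epoch ", epoch, " — aborting training")
        }
        grads <- vae_backward(model, fw, X[idx, , drop = FALSE],
                              M[idx, , drop = FALSE], beta_t)
        adam$t <- adam$t + 1
        for (i in seq_along(model$enc_lin)) {
          key <- paste0("enc", i)
          g <- grads[[key]]
          upd <- adam_update_one(
            c(model$enc_lin[[i]], model$enc_bn[[i]][c("gamma", "beta")]),
            list(W = g$dW, b = g$db, gamma = g$dgamma, beta = g$dbeta),
            adam[[key]], lr, adam$t)
          model$enc_lin[[i]]$W <- upd$param$W
          model$enc_lin[[i]]$b <- upd$param$b
          model$enc_bn[[i]]$gamma <- upd$param$gamma
          model$enc_bn[[i]]$beta <- upd$param$beta
          adam[[key]] <- upd$state
        }
        for (i in seq_along(model$dec_lin)) {
          key <- paste0("dec", i)
          g <- grads[[key]]
          upd <- adam_update_one(
            c(model$dec_lin[[i]], model$dec_bn[[i]][c("gamma", "beta")]),
            list(W = g$dW, b = g$db, gamma = g$dgamma, beta = g$dbeta),
            adam[[key]], lr, adam$t)
          model$dec_lin[[i]]$W <- upd$param$W
          model$dec_lin[[i]]$b <- upd$param$b
          model$dec_bn[[i]]$gamma <- upd$param$gamma
          model$dec_bn[[i]]$beta <- upd$param$beta
          adam[[key]] <- upd$state
        }
        for (h in c("mu_head", "lv_head", "out_head")) {
          upd <- adam_update_one(model[[h]],
                                 list(W = grads[[h]]$dW, b = grads[[h]]$db),
                                 adam[[h]], lr, adam$t)
          model[[h]] <- upd$param
          adam[[h]] <- upd$state
        }
        acc <- acc + c(losses$Ecat, losses$Econ, kld)
        nbatch <- nbatch + 1L
      }
      acc <- acc / max(nbatch, 1L)
      hist[[epoch + 1L]] <- data.frame(
        epoch = epoch, beta = beta_t, batch_size = bs,
        Ecat = acc[["Ecat"]], Econ = acc[["Econ"]], KLD = acc[["KLD"]],
        L = acc[["Ecat"]] + acc[["Econ"]] + beta_t * acc[["KLD"]])
      if (verbose && epoch %% 10L == 0L) {
        message(sprintf("epoch %3d  L=%.4f (Ecat %.4f Econ %.4f KLD %.3f) bs=%d beta=%g",
                        epoch, hist[[epoch + 1L]]$L, acc[["Ecat"]],
                        acc[["Econ"]], acc[["KLD"]], bs, beta_t))
      }
    }
  })
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model
}

#' Extract the latent representation (encoder means)
#'
#' Evaluation-mode encoding: dropout off, batch-normalization statistics
#' frozen at their running values, `z = mu`. Deterministic; row order matches
#' the input individuals.
#'
#' @param model a trained `vae_model`.
#' @param pm a `preprocessed_matrix` with the same column map the model was
#'   trained on.
#' @param rows optional row subset.
#' @param return_logvar also return the log-variance matrix.
#' @return matrix of encoder means (individuals x J), or a list
#'   `(mu, logvar)` when `return_logvar = TRUE`.
#' @export
encode <- function(model, pm, rows = NULL, return_logvar = FALSE) {
  stopifnot(inherits(model, "vae_model"))
  if (!identical(model$column_hash, rlang::hash(pm$column_map))) {
    fail("column map of the data does not match the one the model was trained on")
  }
  rows <- rows %||% seq_len(nrow(pm$x))
  fw <- vae_forward(model, pm$x[rows, , drop = FALSE],
                    pm$mask[rows, , drop = FALSE],
                    training = FALSE, eps = 0)
  if (return_logvar) list(mu = fw$mu, logvar = fw$logvar) else fw$mu
}
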