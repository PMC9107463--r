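#' Initialise the parameters of the two-latent variational autoencoder
#'
#' The architecture follows the semi-supervised clock analysis design:
#' encoder 10,000 -> 512 (rectifier) -> two heads of width 2 (posterior mean
#' and log-variance); decoder 2 -> 512 (rectifier) -> 10,000 with a logistic
#' squashing so reconstructions live in (0, 1). Weights use fan-in-scaled
#' uniform initialisation, `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`, seeded.
#'
#' @param input_dim Flattened image length; default 10000.
#' @param hidden_dim Intermediate width; default 512.
#' @param latent_dim Embedding width; default 2.
#' @param seed Integer seed for the initial weights.
#' @return An object of class `vae_params`.
#' @export
vae_params <- function(input_dim = 10000, hidden_dim = 512, latent_dim = 2,
                       seed = 1) {
  init <- function(fan_in, fan_out) {
    l <- 1 / sqrt(fan_in)
    matrix(stats::runif(fan_in * fan_out, -l, l), fan_in, fan_out)
  }
  with_seed(seed, {
    p <- list(
      W1 = init(input_dim, hidden_dim), b1 = numeric(hidden_dim),
      Wm = init(hidden_dim, latent_dim), bm = numeric(latent_dim),
      Ws = init(hidden_dim, latent_dim), bs = numeric(latent_dim),
      U1 = init(latent_dim, hidden_dim), c1 = numeric(hidden_dim),
      U2 = init(hidden_dim, input_dim), c2 = numeric(input_dim)
    )
    structure(c(p, list(input_dim = input_dim, hidden_dim = hidden_dim,
                        latent_dim = latent_dim)),
              class = "vae_params")
  })
}

#' @export
print.vae_params <- function(x, ...) {
  cat(sprintf("<vae_params %d -> %d -> %d (encoder) | %d -> %d -> %d (decoder)>\n",
              x$input_dim, x$hidden_dim, x$latent_dim,
              x$latent_dim, x$hidden_dim, x$input_dim))
  invisible(x)
}

as_row_matrix <- function(x, dim_needed, what = "input") {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != dim_needed) {
    stop(sprintf("%s has %d columns; expected %d", what, ncol(x), dim_needed),
         call. = FALSE)
  }
  x
}

# Encoder forward pass on a batch; returns intermediates for backprop.
enc_forward <- function(params, X) {
  H1 <- sweep(X %*% params$W1, 2, params$b1, `+`)
  Hr <- relu(H1)
  list(H1 = H1, Hr = Hr,
       mean = sweep(Hr %*% params$Wm, 2, params$bm, `+`),
       log_variance = sweep(Hr %*% params$Ws, 2, params$bs, `+`))
}

# Decoder forward pass on a batch of latent rows.
dec_forward <- function(params, Z) {
  D1 <- sweep(Z %*% params$U1, 2, params$c1, `+`)
  Dr <- relu(D1)
  logits <- sweep(Dr %*% params$U2, 2, params$c2, `+`)
  list(D1 = D1, Dr = Dr, logits = logits, xhat = sigmoid(logits))
}

#' Encode an image vector into its latent Gaussian posterior
#'
#' @param params A `vae_params` object.
#' @param x A flattened image vector of length `input_dim`, or a matrix with
#'   one image per row.
#' @return For a single vector, a `latent_posterior`: list with `mean` and
#'   `log_variance`, each length `latent_dim`. For a matrix input, a list of
#'   two matrices (`mean`, `log_variance`) with one row per image.
#' @export
encode <- function(params, x) {
  single <- is.null(dim(x))
  X <- as_row_matrix(x, params$input_dim)
  fw <- enc_forward(params, X)
  if (single) {
    structure(list(mean = drop(fw$mean), log_variance = drop(fw$log_variance)),
              class = "latent_posterior")
  } else {
    list(mean = fw$mean, log_variance = fw$log_variance)
  }
}

#' Sample a latent point from a posterior by reparameterization
#'
#' Draws `z = mean + exp(log_variance / 2) * eps` with standard-normal
#' `eps`, the reparameterization that lets gradients flow through the
#' sampling step during training.
#'
#' @param posterior A `latent_posterior` (or any list with `mean` and
#'   `log_variance`).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A numeric latent vector (`z`).
#' @export
reparameterize <- function(posterior, seed = 1) {
  mu <- posterior$mean
  lv <- posterior$log_variance
  stopifnot(length(mu) == length(lv), all(is.finite(mu)), all(is.finite(lv)))
  eps <- with_seed(seed, stats::rnorm(length(mu)))
  mu + exp(lv / 2) * eps
}

#' Decode a latent point into a reconstructed image vector
#'
#' @param params A `vae_params` object.
#' @param z A latent vector of length `latent_dim`, or a matrix with one
#'   point per row.
#' @return A numeric vector of length `input_dim` (or matrix), with every
#'   value strictly inside (0, 1).
#' @export
decode <- function(params, z) {
  single <- is.null(dim(z))
  Z <- as_row_matrix(z, params$latent_dim, "latent point")
  xhat <- dec_forward(params, Z)$xhat
  xhat <- pmin(pmax(xhat, 1e-12), 1 - 1e-12)
  if (single) drop(xhat) else xhat
}

#' Binary cross-entropy reconstruction loss
#'
#' Sum over pixels of `-(x * log(xhat) + (1 - x) * log(1 - xhat))`.
#' Predictions exactly at 0 or 1 are clamped to `[1e-7, 1 - 1e-7]` (with a
#' message) so the loss stays finite.
#'
#' @param x Target intensities in `[0, 1]`.
#' @param x_hat Predicted intensities; same length as `x`.
#' @return A nonnegative scalar.
#' @export
reconstruction_loss <- function(x, x_hat) {
  stopifnot(length(x) == length(x_hat))
  if (any(x_hat <= 0) || any(x_hat >= 1)) {
    message("reconstruction_loss: clamping predictions to [1e-7, 1 - 1e-7]")
    x_hat <- pmin(pmax(x_hat, 1e-7), 1 - 1e-7)
  }
  -sum(x * log(x_hat) + (1 - x) * log(1 - x_hat))
}

#' Kullback-Leibler term of the ELBO
#'
#' Closed-form KL divergence of the diagonal-Gaussian posterior from the
#' standard-normal prior:
#' `0.5 * sum(mean^2 + var - 1 - log(var))`. Zero iff the posterior equals
#' the prior.
#'
#' @param posterior A `latent_posterior`.
#' @return A nonnegative scalar.
#' @export
kl_term <- function(posterior) {
  mu <- posterior$mean
  lv <- posterior$log_variance
  0.5 * sum(mu^2 + exp(lv) - 1 - lv)
}

#' Training configuration for the VAE
#'
#' @param epochs Number of passes over the data; default 50.
#' @param batch_size Minibatch size; default 16.
#' @param seed Master seed controlling initialisation, per-epoch shuffling
#'   and reparameterization noise.
#' @param learning_rate Adam step size; default 1e-3.
#' @param kl_weight Weight on the KL term (1 = plain ELBO).
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabiliser.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 50, batch_size = 16, seed = 1,
                         learning_rate = 1e-3, kl_weight = 1,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  check_range(epochs, "epochs", 1, 1e6, integer = TRUE)
  check_range(batch_size, "batch_size", 1, 1e6, integer = TRUE)
  check_range(learning_rate, "learning_rate", 1e-12, 1)
  check_range(kl_weight, "kl_weight", 0, 1e3)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = seed, learning_rate = learning_rate,
                 kl_weight = kl_weight, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps),
            class = "train_config")
}

# Adam optimiser state. Parameters are deep-copied once up front so the
# C++ kernel can update weights, first and second moments in place without
# touching anything the caller still holds.
adam_state <- function(params, names) {
  st <- new.env(parent = emptyenv())
  st$t <- 0
  st$m <- lapply(stats::setNames(names, names),
                 function(nm) params[[nm]] * 0)
  st$v <- lapply(stats::setNames(names, names),
                 function(nm) params[[nm]] * 0)
  st
}

deep_copy_weights <- function(params, names) {
  for (nm in names) params[[nm]] <- params[[nm]] + 0
  params
}

adam_step <- function(params, grads, st, cfg) {
  st$t <- st$t + 1
  corr1 <- 1 - cfg$beta1^st$t
  corr2 <- 1 - cfg$beta2^st$t
  for (nm in names(grads)) {
    .adam_update(params[[nm]], grads[[nm]], st$m[[nm]], st$v[[nm]],
                 cfg$learning_rate, cfg$beta1, cfg$beta2, cfg$adam_eps,
                 corr1, corr2)
  }
  invisible(params)
}

# One VAE minibatch: forward, loss components, gradients of
# mean-over-batch (sum-over-pixel BCE + kl_weight * KL).
vae_batch <- function(params, X, EPS, kl_weight) {
  B <- nrow(X)
  ef <- enc_forward(params, X)
  MU <- ef$mean
  LV <- ef$log_variance
  SD <- exp(LV / 2)
  Z <- MU + SD * EPS
  df <- dec_forward(params, Z)
  XH <- pmin(pmax(df$xhat, 1e-7), 1 - 1e-7)

  recon <- -sum(X * log(XH) + (1 - X) * log(1 - XH)) / B
  kl <- 0.5 * sum(MU^2 + exp(LV) - 1 - LV) / B
  loss <- recon + kl_weight * kl

  dLOG <- (df$xhat - X) / B
  gU2 <- crossprod(df$Dr, dLOG)
  gc2 <- colSums(dLOG)
  dDr <- tcrossprod(dLOG, params$U2)
  dD1 <- dDr * (df$D1 > 0)
  gU1 <- crossprod(Z, dD1)
  gc1 <- colSums(dD1)
  dZ <- tcrossprod(dD1, params$U1)
  dMU <- dZ + kl_weight * MU / B
  dLV <- dZ * EPS * SD / 2 + kl_weight * (exp(LV) - 1) / (2 * B)
  gWm <- crossprod(ef$Hr, dMU)
  gbm <- colSums(dMU)
  gWs <- crossprod(ef$Hr, dLV)
  gbs <- colSums(dLV)
  dHr <- tcrossprod(dMU, params$Wm) + tcrossprod(dLV, params$Ws)
  dH1 <- dHr * (ef$H1 > 0)
  gW1 <- crossprod(X, dH1)
  gb1 <- colSums(dH1)

  list(loss = loss, recon = recon, kl = kl,
       grads = list(W1 = gW1, b1 = gb1, Wm = gWm, bm = gbm,
                    Ws = gWs, bs = gbs, U1 = gU1, c1 = gc1,
                    U2 = gU2, c2 = gc2))
}

#' Train the VAE on unlabelled image vectors
#'
#' Minimises the negative ELBO — mean over minibatches of the summed-pixel
#' binary cross-entropy plus `kl_weight` times the Gaussian KL term — with
#' Adam. Data are reshuffled every epoch with a per-epoch derived seed; the
#' last partial batch is kept. Fully deterministic given
#' `(x, config)`.
#'
#' @param x Matrix of flattened images, one per row, values in `[0, 1]`.
#' @param config A [train_config()]; `input_dim` is taken from `ncol(x)`.
#' @param hidden_dim,latent_dim Architecture widths; defaults 512 and 2.
#' @return A list with `params` (trained `vae_params`) and `history` (data
#'   frame with one row per epoch: `epoch`, `recon`, `kl`, `total`, each the
#'   mean over that epoch's batches).
#' @export
train_vae <- function(x, config = train_config(), hidden_dim = 512,
                      latent_dim = 2) {
  stopifnot(is.matrix(x))
  if (nrow(x) < config$batch_size) {
    stop("need at least `batch_size` training vectors", call. = FALSE)
  }
  seeds <- derive_seeds(config$seed, 2L + config$epochs)
  params <- vae_params(ncol(x), hidden_dim, latent_dim, seed = seeds[1])
  wt_names <- c("W1", "b1", "Wm", "bm", "Ws", "bs", "U1", "c1", "U2", "c2")
  params <- deep_copy_weights(params, wt_names)
  st <- adam_state(params, wt_names)
  hist <- data.frame(epoch = integer(0), recon = numeric(0),
                     kl = numeric(0), total = numeric(0))
  n <- nrow(x)
  for (ep in seq_len(config$epochs)) {
    ep_seed <- seeds[2L + ep]
    order_eps <- with_seed(ep_seed, {
      ord <- sample.int(n)
      eps <- matrix(stats::rnorm(n * latent_dim), n, latent_dim)
      list(ord = ord, eps = eps)
    })
    ord <- order_eps$ord
    starts <- seq(1L, n, by = config$batch_size)
    tot <- rec <- kld <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      bt <- vae_batch(params, x[idx, , drop = FALSE],
                      order_eps$eps[idx, , drop = FALSE], config$kl_weight)
      if (!is.finite(bt$loss)) {
        stop(sprintf(
          "non-finite loss at epoch %d, batch starting %d (recon %.4g, kl %.4g)",
          ep, s, bt$recon, bt$kl), call. = FALSE)
      }
      adam_step(params, bt$grads, st, config)
      tot <- tot + bt$loss
      rec <- rec + bt$recon
      kld <- kld + bt$kl
    }
    nb <- length(starts)
    hist <- rbind(hist, data.frame(epoch = ep, recon = rec / nb,
                                   kl = kld / nb, total = tot / nb))
  }
  list(params = params, history = hist)
}

#' Mean per-pixel absolute reconstruction error
#'
#' Encodes each row of `x` to its posterior mean, decodes, and averages the
#' absolute pixel error. Used to compare trained against untrained models.
#'
#' @param params A `vae_params`.
#' @param x Matrix of flattened images, one per row.
#' @return A scalar in `[0, 1]`.
#' @export
reconstruction_error <- function(params, x) {
  x <- as_row_matrix(x, params$input_dim)
  mu <- enc_forward(params, x)$mean
  xhat <- dec_forward(params, mu)$xhat
  mean(abs(xhat - x))
}
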