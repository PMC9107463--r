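#' Build a classifier from a pre-trained VAE encoder
#'
#' Copies the encoder weights (input -> hidden -> posterior-mean head) from a
#' trained VAE and attaches a freshly initialised feed-forward head
#' `latent_dim -> head_hidden -> 1` with a logistic output. The encoder part
#' is bit-identical to the source; only the head depends on `seed`.
#'
#' @param vae A trained `vae_params`.
#' @param head_hidden Hidden width of the head; default 512.
#' @param seed Integer seed for the head initialisation.
#' @return An object of class `classifier_params`.
#' @export
init_from_encoder <- function(vae, head_hidden = 512, seed = 1) {
  stopifnot(inherits(vae, "vae_params"))
  check_range(head_hidden, "head_hidden", 1, 1e5, integer = TRUE)
  init <- function(fan_in, fan_out) {
    l <- 1 / sqrt(fan_in)
    matrix(stats::runif(fan_in * fan_out, -l, l), fan_in, fan_out)
  }
  with_seed(seed, {
    structure(list(
      W1 = vae$W1, b1 = vae$b1, Wm = vae$Wm, bm = vae$bm,
      H1 = init(vae$latent_dim, head_hidden), hb1 = numeric(head_hidden),
      H2 = init(head_hidden, 1), hb2 = 0,
      input_dim = vae$input_dim, hidden_dim = vae$hidden_dim,
      latent_dim = vae$latent_dim, head_hidden = as.integer(head_hidden)
    ), class = "classifier_params")
  })
}

clf_forward <- function(params, X) {
  H1 <- sweep(X %*% params$W1, 2, params$b1, `+`)
  Hr <- relu(H1)
  MU <- sweep(Hr %*% params$Wm, 2, params$bm, `+`)
  G1 <- sweep(MU %*% params$H1, 2, params$hb1, `+`)
  Gr <- relu(G1)
  logit <- Gr %*% params$H2 + params$hb2
  list(H1 = H1, Hr = Hr, MU = MU, G1 = G1, Gr = Gr,
       logit = logit, p = sigmoid(logit))
}

#' Predicted dementia probability for image vectors
#'
#' Deterministic: the classifier consumes the encoder's posterior mean (no
#' latent sampling).
#'
#' @param params A `classifier_params`.
#' @param x A flattened image vector or matrix of rows.
#' @return Probability (or vector of probabilities) strictly in (0, 1);
#'   dementia is the positive class (label 1).
#' @export
predict_proba <- function(params, x) {
  single <- is.null(dim(x))
  X <- as_row_matrix(x, params$input_dim)
  p <- drop(clf_forward(params, X)$p)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  if (single) unname(p) else p
}

#' Fine-tune the encoder + head on a labelled cohort
#'
#' Minimises the binary cross-entropy of the predicted dementia probability
#' with Adam. By default the encoder weights are updated jointly with the
#' head at the same learning rate; set `freeze_encoder = TRUE` to train the
#' head only (ablation). Deterministic given the seed. `epochs = 0` returns
#' the parameters unchanged.
#'
#' @param params A `classifier_params` from [init_from_encoder()].
#' @param x Matrix of flattened images, one per row.
#' @param y Binary labels (dementia = 1, control = 0); both classes must be
#'   present.
#' @param epochs Fine-tuning epochs; default 10.
#' @param batch_size Minibatch size; default 16.
#' @param learning_rate Adam step size; default 1e-3.
#' @param seed Integer seed for shuffling.
#' @param freeze_encoder Train only the head?
#' @return A list with `params` (updated `classifier_params`) and `history`
#'   (data frame `epoch`, `loss` — mean over batches).
#' @export
fine_tune <- function(params, x, y, epochs = 10, batch_size = 16,
                      learning_rate = 1e-3, seed = 1,
                      freeze_encoder = FALSE) {
  stopifnot(inherits(params, "classifier_params"), is.matrix(x),
            nrow(x) == length(y))
  check_range(epochs, "epochs", 0, 1e6, integer = TRUE)
  if (length(unique(y)) < 2L) {
    stop("fine-tuning cohort must contain both classes", call. = FALSE)
  }
  hist <- data.frame(epoch = integer(0), loss = numeric(0))
  if (epochs == 0) return(list(params = params, history = hist))
  cfg <- train_config(epochs = epochs, batch_size = batch_size, seed = seed,
                      learning_rate = learning_rate)
  wt <- c("H1", "hb1", "H2", "hb2")
  if (!freeze_encoder) wt <- c("W1", "b1", "Wm", "bm", wt)
  params <- deep_copy_weights(params, wt)
  st <- adam_state(params, wt)
  n <- nrow(x)
  seeds <- derive_seeds(seed, epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(seeds[ep], sample.int(n))
    starts <- seq(1L, n, by = cfg$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      X <- x[idx, , drop = FALSE]
      yy <- y[idx]
      B <- length(idx)
      fw <- clf_forward(params, X)
      p <- pmin(pmax(fw$p, 1e-7), 1 - 1e-7)
      loss <- -mean(yy * log(p) + (1 - yy) * log(1 - p))
      if (!is.finite(loss)) {
        stop(sprintf("non-finite fine-tune loss at epoch %d", ep),
             call. = FALSE)
      }
      dlogit <- (fw$p - yy) / B
      dG1 <- (dlogit %*% t(params$H2)) * (fw$G1 > 0)
      grads <- list(H1 = crossprod(fw$MU, dG1), hb1 = colSums(dG1),
                    H2 = crossprod(fw$Gr, dlogit), hb2 = sum(dlogit))
      if (!freeze_encoder) {
        dMU <- dG1 %*% t(params$H1)
        dH1 <- (dMU %*% t(params$Wm)) * (fw$H1 > 0)
        grads <- c(list(W1 = crossprod(X, dH1), b1 = colSums(dH1),
                        Wm = crossprod(fw$Hr, dMU), bm = colSums(dMU)),
                   grads)
      }
      adam_step(params, grads, st, cfg)
      ep_loss <- ep_loss + loss
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / length(starts)))
  }
  list(params = params, history = hist)
}

# Stratified fold assignment: within each class, a seeded shuffle followed
# by round-robin allocation.
stratified_folds <- function(y, folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Randomised search over head widths in stratified cross-validation
#'
#' Samples candidate hidden widths (without replacement), scores each by the
#' mean validation AUROC of a fine-tuned classifier over stratified
#' `folds`-fold cross-validation, and returns the best; exact score ties go
#' to the smaller width.
#'
#' @param vae A trained `vae_params`.
#' @param x,y Labelled cohort (matrix of rows, binary labels).
#' @param widths Candidate hidden widths; default `c(8, 32, 128, 512)`.
#' @param folds Number of CV folds; default 3.
#' @param n_iter Number of widths to sample; default all.
#' @param epochs Fine-tuning epochs per fold; default 10.
#' @param seed Integer seed (fold assignment, sampling and training).
#' @return A list with `best_width` and `scores` (data frame `width`,
#'   `cv_auroc`).
#' @export
search_head <- function(vae, x, y, widths = c(8, 32, 128, 512), folds = 3,
                        n_iter = length(widths), epochs = 10, seed = 1) {
  tab <- table(y)
  if (length(tab) < 2L || any(tab < folds)) {
    stop("need at least `folds` samples per class", call. = FALSE)
  }
  seeds <- derive_seeds(seed, 3L)
  pick <- with_seed(seeds[1],
                    sample.int(length(widths), min(n_iter, length(widths))))
  cand <- sort(widths[pick])
  fold <- stratified_folds(y, folds, seeds[2])
  scores <- vapply(cand, function(w) {
    aucs <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      clf <- init_from_encoder(vae, head_hidden = w, seed = seeds[3])
      ft <- fine_tune(clf, x[tr, , drop = FALSE], y[tr], epochs = epochs,
                      seed = seeds[3])
      auroc(y[!tr], predict_proba(ft$params, x[!tr, , drop = FALSE]))
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  best <- cand[which.max(scores)]  # which.max takes the first (smallest) tie
  list(best_width = best,
       scores = data.frame(width = cand, cv_auroc = scores))
}

#' Fit a k-nearest-neighbour model on labelled latent points
#'
#' Majority vote over the `k` Euclidean-nearest training points in the
#' (Z0, Z1) plane. `k` must be odd (a binary vote cannot tie) and at most
#' the number of training points.
#'
#' @param points Numeric matrix of latent points (n x 2).
#' @param labels Binary labels, one per point.
#' @param k Neighbour count; default 13.
#' @return An object of class `knn_model`.
#' @export
fit_knn <- function(points, labels, k = 13) {
  points <- as.matrix(points)
  stopifnot(nrow(points) == length(labels))
  check_range(k, "k", 1, nrow(points), integer = TRUE)
  if (k %% 2 == 0) stop("`k` must be odd", call. = FALSE)
  structure(list(points = points, labels = as.integer(labels),
                 k = as.integer(k)),
            class = "knn_model")
}

#' Predict labels for query points with a fitted kNN model
#'
#' Points co-distant with the k-th neighbour are all included in the vote;
#' an exact vote tie (possible only through distance ties) resolves to
#' label 0.
#'
#' @param model A `knn_model` from [fit_knn()].
#' @param queries Numeric matrix of query points (m x 2) or a single point.
#' @return Integer vector of predicted labels.
#' @export
predict_knn <- function(model, queries) {
  if (is.null(dim(queries))) queries <- matrix(queries, nrow = 1)
  queries <- as.matrix(queries)
  tp <- model$points
  vapply(seq_len(nrow(queries)), function(i) {
    d2 <- (tp[, 1] - queries[i, 1])^2 + (tp[, 2] - queries[i, 2])^2
    dk <- sort(d2, partial = model$k)[model$k]
    votes <- model$labels[d2 <= dk]
    frac <- mean(votes)
    if (frac > 0.5) 1L else 0L  # exact tie resolves to control
  }, integer(1))
}

#' Choose k by stratified cross-validated accuracy
#'
#' @param points,labels Labelled latent points.
#' @param candidates Odd candidate values of k; default `seq(1, 25, 2)`.
#' @param folds Number of CV folds; default 3.
#' @param seed Integer seed for fold assignment.
#' @return The candidate with the highest mean validation accuracy; ties go
#'   to the smaller k. The score table is attached as attribute
#'   `"scores"`.
#' @export
select_k <- function(points, labels, candidates = seq(1, 25, 2), folds = 3,
                     seed = 1) {
  points <- as.matrix(points)
  if (any(candidates %% 2 == 0)) {
    stop("all candidate k must be odd", call. = FALSE)
  }
  fold <- stratified_folds(labels, folds, seed)
  min_train <- min(vapply(seq_len(folds), function(f) sum(fold != f),
                          numeric(1)))
  candidates <- candidates[candidates <= min_train]
  if (!length(candidates)) stop("no feasible candidate k", call. = FALSE)
  acc <- vapply(candidates, function(k) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold != f
      m <- fit_knn(points[tr, , drop = FALSE], labels[tr], k)
      mean(predict_knn(m, points[!tr, , drop = FALSE]) == labels[!tr])
    }, numeric(1)))
  }, numeric(1))
  best <- candidates[which.max(acc)]
  attr(best, "scores") <- data.frame(k = candidates, cv_accuracy = acc)
  best
}

#' Label a regular grid of the latent plane
#'
#' Evaluates the kNN model at every cell centre of a regular grid,
#' producing the two-region decision map that operationalizes the latent
#' space into "dementia" and "control" areas.
#'
#' @param model A `knn_model`.
#' @param bounds Numeric vector `c(z0_min, z0_max, z1_min, z1_max)`;
#'   default `c(-4, 4, -4, 4)`.
#' @param resolution Cells per axis (single integer or length-2); default
#'   50.
#' @return An object of class `decision_region_map`: list with `z0`, `z1`
#'   (cell-centre coordinates) and `labels` (matrix, rows = z0 index,
#'   columns = z1 index).
#' @export
region_map <- function(model, bounds = c(-4, 4, -4, 4), resolution = 50) {
  resolution <- rep_len(as.integer(resolution), 2L)
  z0 <- seq(bounds[1], bounds[2], length.out = resolution[1])
  z1 <- seq(bounds[3], bounds[4], length.out = resolution[2])
  grid <- as.matrix(expand.grid(Z0 = z0, Z1 = z1))
  lab <- matrix(predict_knn(model, grid), resolution[1], resolution[2])
  structure(list(z0 = z0, z1 = z1, labels = lab),
            class = "decision_region_map")
}
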