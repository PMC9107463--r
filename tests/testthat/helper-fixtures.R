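# Shared fixtures, memoised across test files (one R session per run).
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# The reference pre-training run: a 10,000-512-2 VAE trained for 10 epochs
# (batch 16) on 2,000 synthetic clocks drawn from the default mixed
# population (85% control-like, 15% dementia-like).
trained_vae_fixture <- function() {
  memo("trained_vae", function() {
    un <- preprocess_cohort(sample_cohort(cohort_spec(1700, 300, seed = 101)))
    fit <- train_vae(un$x, train_config(epochs = 10, batch_size = 16,
                                        seed = 11))
    list(fit = fit, n_train = nrow(un$x))
  })
}

# Default 500 + 500 cohort with its factor table, used by the class
# separation and factor-recovery checks. Rendered pages are dropped after
# preprocessing to keep the memoised fixture small.
balanced_cohort_fixture <- function() {
  memo("balanced_cohort", function() {
    items <- sample_cohort(cohort_spec(500, 500, seed = 303))
    pc <- preprocess_cohort(items)
    ft <- factor_table(items)
    list(factors_all = ft, pc = pc, factors = ft[pc$report$kept, ])
  })
}

# Fine-tune (60 control / 53 dementia) and held-out test (50/50) cohorts.
labeled_cohorts_fixture <- function() {
  memo("labeled_cohorts", function() {
    ft <- preprocess_cohort(sample_cohort(cohort_spec(60, 53, seed = 404)))
    tst <- preprocess_cohort(sample_cohort(cohort_spec(50, 50, seed = 505)))
    list(ft = ft, tst = tst)
  })
}

# A small VAE (64-pixel "images") for unit tests of the training machinery.
tiny_vae <- function(seed = 7) {
  vae_params(input_dim = 64, hidden_dim = 8, latent_dim = 2, seed = seed)
}

# Toy separable "image" cohort at 64 pixels: class 1 lights the first half,
# class 0 the second half, plus noise.
tiny_cohort <- function(n_per_class = 30, seed = 5) {
  withr::with_seed(seed, {
    y <- rep(c(0, 1), each = n_per_class)
    x <- t(vapply(y, function(lbl) {
      base <- c(rep(0.8 * lbl, 32), rep(0.8 * (1 - lbl), 32))
      pmin(pmax(base + stats::rnorm(64, sd = 0.1), 0), 1)
    }, numeric(64)))
    list(x = x, y = y)
  })
}

# --- independent oracles -------------------------------------------------

# Brute-force AUROC: enumerate all (positive, negative) pairs, half credit
# for ties.
auroc_bruteforce <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Brute-force kNN vote with the same tie conventions as the package.
knn_bruteforce <- function(train, labels, query, k) {
  d <- sqrt(rowSums(sweep(train, 2, query)^2))
  dk <- sort(d)[k]
  votes <- labels[d <= dk]
  if (mean(votes) > 0.5) 1L else 0L
}

# Pure-R flood-fill connected components, 8-connectivity.
cc_bruteforce <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      r <- (cur - 1L) %% nrow(mask) + 1L
      c <- (cur - 1L) %/% nrow(mask) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > nrow(mask) || cc < 1 || cc > ncol(mask)) next
        ii <- (cc - 1L) * nrow(mask) + rr
        if (mask[ii] && lab[ii] == 0L) {
          lab[ii] <- nxt
          queue <- c(queue, ii)
        }
      }
    }
  }
  lab
}
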