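test_that("encoder weights are copied bit-identically, heads are seeded", {
  vae <- tiny_vae(seed = 1)
  clf1 <- init_from_encoder(vae, head_hidden = 16, seed = 5)
  clf2 <- init_from_encoder(vae, head_hidden = 16, seed = 6)
  expect_identical(clf1$W1, vae$W1)
  expect_identical(clf1$Wm, vae$Wm)
  expect_identical(clf1$W1, clf2$W1)
  expect_false(identical(clf1$H1, clf2$H1))

  clf512 <- init_from_encoder(vae, head_hidden = 512, seed = 1)
  expect_equal(dim(clf512$H1), c(2, 512))
  expect_equal(dim(clf512$H2), c(512, 1))
})

test_that("predict_proba is a deterministic probability with monotone bias", {
  vae <- tiny_vae(seed = 2)
  clf <- init_from_encoder(vae, head_hidden = 8, seed = 3)
  x <- withr::with_seed(4, stats::runif(64))
  p1 <- predict_proba(clf, x)
  expect_gt(p1, 0); expect_lt(p1, 1)
  expect_identical(predict_proba(clf, x), p1)

  zero <- clf
  zero$H1[] <- 0; zero$hb1[] <- 0; zero$H2[] <- 0; zero$hb2 <- 0
  expect_equal(predict_proba(zero, x), 0.5)

  up <- clf
  up$hb2 <- clf$hb2 + 1
  expect_gt(predict_proba(up, x), p1)
})

test_that("fine-tuning is seeded, reduces loss, and respects edge cases", {
  co <- tiny_cohort(n_per_class = 20, seed = 6)
  vae <- tiny_vae(seed = 3)
  clf <- init_from_encoder(vae, head_hidden = 8, seed = 1)

  expect_identical(fine_tune(clf, co$x, co$y, epochs = 0)$params, clf)
  expect_error(fine_tune(clf, co$x, rep(1, length(co$y))), "both classes")

  a <- fine_tune(clf, co$x, co$y, epochs = 10, batch_size = 8, seed = 2)
  b <- fine_tune(clf, co$x, co$y, epochs = 10, batch_size = 8, seed = 2)
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)
  expect_lt(a$history$loss[10], a$history$loss[1])
})

test_that("classifier gradients agree with finite differences", {
  vae <- vae_params(input_dim = 12, hidden_dim = 5, latent_dim = 2, seed = 2)
  clf <- init_from_encoder(vae, head_hidden = 4, seed = 3)
  X <- withr::with_seed(5, matrix(stats::runif(6 * 12), 6, 12))
  y <- c(0, 1, 0, 1, 1, 0)
  loss_of <- function(p) {
    pr <- predict_proba(p, X)
    -mean(y * log(pr) + (1 - y) * log(1 - pr))
  }
  # analytic gradients via one zero-momentum plain step is awkward; use the
  # internals directly
  fw <- clockvae:::clf_forward(clf, X)
  B <- nrow(X)
  dlogit <- (fw$p - y) / B
  dG1 <- (dlogit %*% t(clf$H2)) * (fw$G1 > 0)
  dMU <- dG1 %*% t(clf$H1)
  dH1 <- (dMU %*% t(clf$Wm)) * (fw$H1 > 0)
  grads <- list(H1 = crossprod(fw$MU, dG1), hb1 = colSums(dG1),
                H2 = crossprod(fw$Gr, dlogit), hb2 = sum(dlogit),
                W1 = crossprod(X, dH1), b1 = colSums(dH1),
                Wm = crossprod(fw$Hr, dMU), bm = colSums(dMU))
  h <- 1e-6
  for (nm in names(grads)) {
    i <- withr::with_seed(7, sample(length(clf[[nm]]), 1))
    up <- clf; up[[nm]][i] <- up[[nm]][i] + h
    dn <- clf; dn[[nm]][i] <- dn[[nm]][i] - h
    expect_equal(grads[[nm]][i], (loss_of(up) - loss_of(dn)) / (2 * h),
                 tolerance = 1e-4, label = paste("grad", nm))
  }
})

test_that("frozen-encoder fine-tuning leaves the encoder untouched", {
  co <- tiny_cohort(n_per_class = 12, seed = 8)
  clf <- init_from_encoder(tiny_vae(seed = 4), head_hidden = 8, seed = 1)
  ft <- fine_tune(clf, co$x, co$y, epochs = 3, seed = 1,
                  freeze_encoder = TRUE)
  expect_identical(ft$params$W1, clf$W1)
  expect_identical(ft$params$Wm, clf$Wm)
  expect_false(identical(ft$params$H1, clf$H1))
})

test_that("head search scores widths by CV AUROC with smaller-width ties", {
  co <- tiny_cohort(n_per_class = 15, seed = 9)
  vae <- train_vae(co$x, train_config(epochs = 5, batch_size = 8, seed = 3),
                   hidden_dim = 8, latent_dim = 2)$params
  single <- search_head(vae, co$x, co$y, widths = c(16), seed = 1, epochs = 5)
  expect_equal(single$best_width, 16)

  res <- search_head(vae, co$x, co$y, widths = c(4, 64), seed = 1, epochs = 5)
  expect_identical(res$scores,
                   search_head(vae, co$x, co$y, widths = c(4, 64), seed = 1,
                               epochs = 5)$scores)
  # the toy cohort is linearly separable in pixel space: both arms learn it
  expect_true(all(res$scores$cv_auroc > 0.9))
  if (res$scores$cv_auroc[1] == res$scores$cv_auroc[2]) {
    expect_equal(res$best_width, 4)
  }
  expect_error(search_head(vae, co$x, rep(0:1, c(28, 2)), widths = 8),
               "per class")
})

test_that("kNN votes match a brute-force distance oracle", {
  train <- withr::with_seed(11, matrix(stats::rnorm(30 * 2), 30, 2))
  labels <- withr::with_seed(12, stats::rbinom(30, 1, 0.5))
  queries <- withr::with_seed(13, matrix(stats::rnorm(50 * 2), 50, 2))
  model <- fit_knn(train, labels, k = 13)
  got <- predict_knn(model, queries)
  want <- vapply(seq_len(50), function(i) {
    knn_bruteforce(train, labels, queries[i, ], 13)
  }, integer(1))
  expect_identical(got, want)
})

test_that("kNN respects its preconditions and simple geometry", {
  pts <- matrix(c(0, 0), 1, 2)
  m1 <- fit_knn(pts, 1L, k = 1)
  expect_equal(predict_knn(m1, matrix(c(5, 5), 1, 2)), 1L)

  two <- fit_knn(matrix(c(1, 0, 2, 0), 2, 2, byrow = TRUE), c(1L, 0L), k = 1)
  expect_equal(predict_knn(two, c(0, 0)), 1L)  # nearer point wins

  expect_error(fit_knn(matrix(0, 4, 2), rep(0:1, 2), k = 2), "odd")
  expect_error(fit_knn(matrix(0, 4, 2), rep(0:1, 2), k = 5), "k")
})

test_that("kNN is invariant to a joint rotation of the plane", {
  train <- withr::with_seed(14, matrix(stats::rnorm(40), 20, 2))
  labels <- rep(0:1, 10)
  queries <- withr::with_seed(15, matrix(stats::rnorm(30), 15, 2))
  theta <- 0.83
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  m <- fit_knn(train, labels, k = 5)
  mr <- fit_knn(train %*% R, labels, k = 5)
  expect_identical(predict_knn(m, queries), predict_knn(mr, queries %*% R))
})

test_that("training points classify to their own labels at k = 1", {
  pts <- withr::with_seed(16, matrix(stats::rnorm(60), 30, 2))
  labels <- rep(0:1, 15)
  m <- fit_knn(pts, labels, k = 1)
  expect_equal(predict_knn(m, pts), labels)
})

test_that("select_k maximises CV accuracy with smaller-k ties", {
  # two tight, well-separated clusters: every odd k <= cluster size works,
  # so the tie rule must pick the smallest candidate
  pts <- rbind(withr::with_seed(17, matrix(stats::rnorm(40, 0, 0.1), 20, 2)),
               withr::with_seed(18, matrix(stats::rnorm(40, 5, 0.1), 20, 2)))
  labels <- rep(0:1, each = 20)
  k <- select_k(pts, labels, candidates = c(1, 3, 5), seed = 2)
  expect_equal(as.numeric(k), 1)
  expect_named(attr(k, "scores"), c("k", "cv_accuracy"))
  expect_error(select_k(pts, labels, candidates = c(2, 4)), "odd")
})

test_that("region maps label every cell and separate clear clusters", {
  pts <- rbind(matrix(c(-2, -2), 10, 2, byrow = TRUE) +
                 withr::with_seed(19, matrix(stats::rnorm(20, 0, 0.2), 10, 2)),
               matrix(c(2, 2), 10, 2, byrow = TRUE) +
                 withr::with_seed(20, matrix(stats::rnorm(20, 0, 0.2), 10, 2)))
  labels <- rep(0:1, each = 10)
  m <- fit_knn(pts, labels, k = 3)

  rm2 <- region_map(m, resolution = 2)
  expect_equal(dim(rm2$labels), c(2, 2))
  expect_true(all(rm2$labels %in% 0:1))

  rm50 <- region_map(m, resolution = 50)
  expect_setequal(unique(as.vector(rm50$labels)), 0:1)
  # the two cluster centroids sit in their own regions
  expect_equal(predict_knn(m, c(-2, -2)), 0L)
  expect_equal(predict_knn(m, c(2, 2)), 1L)

  uni <- region_map(fit_knn(pts[1:10, ], rep(0L, 10), k = 3), resolution = 5)
  expect_true(all(uni$labels == 0))
})
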