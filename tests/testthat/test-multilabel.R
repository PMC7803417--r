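test_that("label-powerset transformation encodes restrictions canonically", {
  y <- rbind(c(1, 1, 0, 0), c(0, 0, 0, 1), c(1, 1, 0, 0))
  expect_equal(lp_transform(y, 1:3), c("1+2", "{}", "1+2"))
  # restriction outside the sample's labels is the legal empty class
  expect_equal(lp_transform(y, c(1, 2))[2], "{}")
  # identical restrictions share a class id
  expect_equal(lp_transform(y, 1:4)[1], lp_transform(y, 1:4)[3])
  expect_error(lp_transform(y, integer()), "non-empty")
  expect_error(lp_transform(y, 9L), "out of range")
})

test_that("labelset draws exhaust, repeat, and replay deterministically", {
  # only one m-subset exists
  d1 <- sample_labelsets(11, 11, 5, seed = 1)
  expect_true(all(vapply(d1$sets, identical, TRUE, 1:11)))
  # without-replacement exhaustion of the three singletons
  d2 <- sample_labelsets(3, 1, 3, seed = 2)
  expect_setequal(vapply(d2$sets, identity, 0L), 1:3)
  # more draws than distinct subsets: sampling with replacement
  d3 <- sample_labelsets(3, 2, 10, seed = 3)
  expect_equal(length(d3$sets), 10L)
  expect_true(all(vapply(d3$sets, length, 0L) == 2L))
  # determinism
  expect_identical(sample_labelsets(8, 3, 6, seed = 9)$sets,
                   sample_labelsets(8, 3, 6, seed = 9)$sets)
  expect_error(sample_labelsets(3, 4, 1), "1 <= k <= m")
})

test_that("vote averaging assigns a label only above the strict threshold", {
  # hand-built ensemble of constant members over labelset {1, 2}:
  # 3 of 5 vote label 1 positive (0.6 > 0.5), label 2 gets 2 of 5 (0.4)
  constant <- function(cls) structure(list(constant = cls),
                                      class = "base_constant")
  model <- structure(list(
    labelsets = rep(list(1:2), 5),
    fits = c(rep(list(constant("1")), 2), list(constant("1+2")),
             rep(list(constant("2")), 1), list(constant("{}"))),
    base = base_config("knn1"), threshold = 0.5, k = 2L, M = 5L, m = 3L,
    label_names = c("A", "B", "C"), seed = 1L), class = "rakel_model")
  pred <- rakel_predict(model, matrix(0, 4, 2))
  votes <- attr(pred, "votes")
  expect_equal(unname(votes[1, ]), c(0.6, 0.4, 0))
  expect_equal(unname(pred[1, ]), c(1, 0, 0))
  # average exactly at threshold is NOT assigned
  expect_equal(unname(rakel_predict(model, matrix(0, 1, 2),
                                    threshold = 0.6)[1, ]),
               c(0, 0, 0))
  # label 3 is covered by no labelset and never predicted
  expect_true(all(pred[, 3] == 0))
})

test_that("ensemble matches the brute-force labelset-vote enumeration", {
  for (seed in c(1L, 2L, 3L)) {
    n <- 12L
    m <- 3L
    ytr <- random_labels(n, m, seed)
    withr::with_seed(seed + 50L, {
      xtr <- matrix(runif(n * 2), n)
      xte <- matrix(runif(8 * 2), 8)
    })
    all_subsets <- list(
      list(1L, 2L, 3L),                              # k = 1 exhaustive
      list(c(1L, 2L), c(1L, 3L), c(2L, 3L)),         # k = 2 exhaustive
      list(1:3),                                     # k = 3
      list(c(1L, 2L), c(1L, 2L), c(2L, 3L)))         # repeated draw
    for (sets in all_subsets) {
      model <- rakel_fit(xtr, ytr, k = length(sets[[1L]]), M = length(sets),
                         base = base_config("knn1"), labelsets = sets)
      got <- rakel_predict(model, xte)
      want <- oracle_rakel(xtr, ytr, xte, sets)
      expect_equal(unname(got[, ] * 1L), unname(want), ignore_attr = TRUE)
    }
  }
})

test_that("k = m collapses every member to one LP classifier", {
  b <- easy_bench()
  tr <- seq_len(150)
  te <- 151:180
  m <- ncol(b$labels)
  model <- rakel_fit(b$X[tr, ], b$labels[tr, ], k = m, M = 5,
                     base = base_config("svm_poly", C = 2, E = 1), seed = 4)
  expect_true(all(vapply(model$labelsets, identical, TRUE, seq_len(m))))
  # deterministic base: the five members share one fit
  expect_true(all(vapply(model$fits, identical, TRUE, model$fits[[1L]])))
  # prediction equals the single LP classifier's expanded class
  single <- rakel_fit(b$X[tr, ], b$labels[tr, ], k = m, M = 1,
                      base = base_config("svm_poly", C = 2, E = 1), seed = 4)
  expect_equal(rakel_predict(model, b$X[te, ])[, ],
               rakel_predict(single, b$X[te, ])[, ])
})

test_that("refits and predictions are deterministic given seeds", {
  b <- easy_bench()
  tr <- seq_len(120)
  te <- 121:180
  for (bt in c("svm_poly", "rf")) {
    bc <- base_config(bt, C = 2, E = 1, ntree = 30)
    p1 <- rakel_predict(rakel_fit(b$X[tr, ], b$labels[tr, ], k = 2, M = 6,
                                  base = bc, seed = 21), b$X[te, ])
    p2 <- rakel_predict(rakel_fit(b$X[tr, ], b$labels[tr, ], k = 2, M = 6,
                                  base = bc, seed = 21), b$X[te, ])
    expect_identical(p1, p2)
  }
})

test_that("predictions are equivariant under label-column permutation", {
  n <- 30L
  ytr <- random_labels(n, 3L, seed = 8)
  withr::with_seed(60L, {
    xtr <- matrix(runif(n * 3), n)
    xte <- matrix(runif(10 * 3), 10)
  })
  perm <- c(3L, 1L, 2L)
  sets <- list(1L, 2L, 3L)
  base <- base_config("knn1")
  p <- rakel_predict(rakel_fit(xtr, ytr, 1, 3, base, labelsets = sets),
                     xte)
  # permuting label columns (and the singleton cover to match) permutes output
  yp <- ytr[, perm]
  colnames(yp) <- colnames(ytr)
  pp <- rakel_predict(rakel_fit(xtr, yp, 1, 3, base,
                                labelsets = as.list(order(perm))),
                      xte)
  expect_equal(unname(pp[, ] * 1L), unname(p[, perm] * 1L))
})

test_that("binary relevance decomposes labels independently", {
  n <- 40L
  y <- random_labels(n, 3L, seed = 13)
  withr::with_seed(70L, {
    xtr <- matrix(runif(n * 4), n)
    xte <- matrix(runif(12 * 4), 12)
  })
  base <- base_config("svm_poly", C = 1, E = 1)
  p0 <- br_fit_predict(xtr, y, base, seed = 5, newdata = xte)
  # flipping one label's training column never alters another's predictions
  y2 <- y
  y2[, 2] <- ifelse(rowSums(y[, -2, drop = FALSE]) > 0, 0L, 1L)
  y2[rowSums(y2) == 0, 2] <- 1L
  p2 <- br_fit_predict(xtr, y2, base, seed = 5, newdata = xte)
  expect_equal(p2[, c(1, 3)], p0[, c(1, 3)])
  # an all-positive label column predicts positive everywhere, with warning
  y3 <- y
  y3[, 1] <- 1L
  expect_warning(p3 <- br_fit_predict(xtr, y3, base, seed = 5, newdata = xte),
                 "single class")
  expect_true(all(p3[, 1] == 1))
})

test_that("uncovered labels are reported and never predicted", {
  n <- 20L
  y <- random_labels(n, 4L, seed = 17)
  x <- matrix(seq_len(n * 2) / n, n)
  expect_warning(
    model <- rakel_fit(x, y, k = 2, M = 1, base = base_config("knn1"),
                       labelsets = list(c(1L, 2L))),
    "never covered")
  pred <- rakel_predict(model, x)
  expect_true(all(pred[, 3:4] == 0))
})

test_that("models survive an archive round trip", {
  b <- easy_bench()
  model <- rakel_fit(b$X[1:80, ], b$labels[1:80, ], k = 2, M = 3,
                     base = base_config("svm_poly"), seed = 2)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(rakel_predict(back, b$X[81:100, ]),
               rakel_predict(model, b$X[81:100, ]))
})
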