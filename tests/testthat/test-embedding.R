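test_that("transition matrix is column-stochastic weighted-degree division", {
  # single edge: normalization is weight-independent
  net2 <- toy_network(cci = list("a", "b", 800), chems = c("a", "b"),
                      enzs = character())
  expect_equal(transition_matrix(net2),
               matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"),
                                                        c("a", "b"))))
  # triangle with equal weights
  tri <- toy_network(cci = list(c("a", "a", "b"), c("b", "c", "c"),
                                c(500, 500, 500)),
                     chems = c("a", "b", "c"), enzs = character())
  P <- transition_matrix(tri)
  expect_true(all(P[upper.tri(P) | lower.tri(P)] == 0.5))
  expect_true(all(diag(P) == 0))
  # path a-b-c with weights 0.2, 0.8: column b divides by degree of b
  path <- toy_network(cci = list(c("a", "b"), c("b", "c"), c(200, 800)),
                      chems = c("a", "b", "c"), enzs = character())
  expect_equal(transition_matrix(path)[, "b"],
               c(a = 0.2, b = 0, c = 0.8))
  # isolated node: directed to drop_isolated
  iso <- toy_network(cci = list("a", "b", 500),
                     chems = c("a", "b", "lonely"), enzs = character())
  expect_error(transition_matrix(iso), "drop_isolated")
})

test_that("RWR fixed point matches the closed form and conserves mass", {
  net2 <- toy_network(cci = list("a", "b", 700), chems = c("a", "b"),
                      enzs = character())
  P <- transition_matrix(net2)
  p <- rwr(P, 1L, rwr_config(restart_prob = 0.5, tol = 1e-12))
  expect_equal(as.numeric(p), c(2 / 3, 1 / 3), tolerance = 1e-9)
  # restart probability one pins the walk at the seed
  p1 <- rwr(P, 2L, rwr_config(restart_prob = 1))
  expect_equal(as.numeric(p1), c(0, 1))
  # conservation and nonnegativity on a random network
  P5 <- random_transition(9L, seed = 42L)
  for (s in c(1L, 5L)) {
    ps <- rwr(P5, s, rwr_config())
    expect_equal(sum(ps), 1, tolerance = 1e-9)
    expect_true(all(ps >= 0))
  }
  # the iteration cap raises a warning and flags non-convergence
  expect_warning(pu <- rwr(P5, 1L, rwr_config(tol = 1e-14, max_iter = 3L)),
                 "did not converge")
  expect_false(attr(pu, "converged"))
})

test_that("diffusion states stack per-seed walks and respect symmetry", {
  net2 <- toy_network(cci = list("a", "b", 700), chems = c("a", "b"),
                      enzs = character())
  V <- diffusion_states(net2, rwr_config(restart_prob = 0.5))
  expect_equal(unname(V), matrix(c(2 / 3, 1 / 3, 1 / 3, 2 / 3), 2),
               tolerance = 1e-8)
  # complete graph with equal weights: columns equal up to seed swap
  cmpl <- toy_network(cci = list(c("a", "a", "b"), c("b", "c", "c"),
                                 c(400, 400, 400)),
                      chems = c("a", "b", "c"), enzs = character())
  Vc <- diffusion_states(cmpl)
  expect_equal(diag(Vc), rep(Vc[1, 1], 3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(Vc[2, 1], Vc[1, 2], tolerance = 1e-8)
  # definition: column i equals an individual seeded walk
  P <- transition_matrix(cmpl)
  expect_equal(Vc[, 2], as.numeric(rwr(P, 2L)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("full-rank SVD factorization reconstructs strictly positive states", {
  cfg <- synth_config(n_chem = 3, n_enz = 2, m = 2, p_intra = 0.9,
                      p_inter = 0.5, seed = 3)
  lab <- generate_labels(cfg)
  V <- diffusion_states(generate_network(lab$labels, lab$kinds, cfg))
  expect_true(all(V > 0))
  model <- mashup_embed(V, d = nrow(V), method = "svd")
  expect_lt(max(abs(reconstruct_diffusion(model) - V)), 1e-6)
  expect_error(mashup_embed(V, d = nrow(V) + 1L), "1 <= d <= n")
})

test_that("SVD reconstruction error of log states is monotone in rank", {
  b <- easy_bench()
  V <- diffusion_states(b$bench$network)
  L <- log(V + any(V <= 0) / nrow(V))
  errs <- vapply(c(2L, 8L, 32L, 64L), function(d) {
    m <- mashup_embed(V, d = d, method = "svd")
    sqrt(sum((m$W %*% t(m$X) - L)^2))
  }, 0)
  expect_true(all(diff(errs) < 1e-8))
})

test_that("KL objective evaluates hand cases and stays nonnegative", {
  # model column (0.5, 0.5) against target (1, 0): KL = log 2 per column
  V <- matrix(c(1, 0, 0, 1), 2)
  X <- matrix(0, 2, 1)           # zero inner products: uniform model columns
  W <- matrix(0, 2, 1)
  expect_equal(kl_objective(X, W, V), log(2))
  # perfect model has zero divergence
  Vpos <- matrix(c(0.7, 0.3, 0.2, 0.8), 2)
  s <- svd(log(Vpos))
  Xf <- s$v %*% diag(sqrt(s$d))
  Wf <- s$u %*% diag(sqrt(s$d))
  expect_equal(kl_objective(Xf, Wf, Vpos), 0, tolerance = 1e-12)
  # random configurations are never negative
  for (seed in 1:5) {
    withr::with_seed(seed, {
      Xr <- matrix(rnorm(6), 3)
      Wr <- matrix(rnorm(6), 3)
      Vr <- abs(matrix(rnorm(9), 3))
      Vr <- sweep(Vr, 2, colSums(Vr), "/")
    })
    expect_gte(kl_objective(Xr, Wr, Vr), 0)
  }
})

test_that("gradient optimizer descends monotonically and is reproducible", {
  cfg <- synth_config(n_chem = 4, n_enz = 2, m = 2, p_intra = 0.8,
                      p_inter = 0.4, seed = 5)
  lab <- generate_labels(cfg)
  V <- diffusion_states(generate_network(lab$labels, lab$kinds, cfg))
  m1 <- mashup_embed(V, d = 3, method = "kl_gradient", seed = 11, iters = 120)
  expect_true(all(diff(m1$objective_trace) <= 1e-8))
  expect_lte(m1$objective_trace[length(m1$objective_trace)],
             m1$objective_trace[1])
  expect_true(all(m1$objective_trace >= 0))
  m2 <- mashup_embed(V, d = 3, method = "kl_gradient", seed = 11, iters = 120)
  expect_identical(m1$X, m2$X)
  expect_identical(m1$objective_trace, m2$objective_trace)
})

test_that("automorphic nodes receive embeddings of equal norm", {
  # star: the three leaves are exchangeable
  star <- toy_network(cci = list(c("hub", "hub", "hub"), c("x", "y", "z"),
                                 c(600, 600, 600)),
                      chems = c("hub", "x", "y", "z"), enzs = character())
  V <- diffusion_states(star)
  model <- mashup_embed(V, d = 4, method = "svd")
  norms <- sqrt(rowSums(model$X^2))
  leaf <- norms[c("x", "y", "z")]
  expect_equal(max(leaf) - min(leaf), 0, tolerance = 1e-8)
})

test_that("embedding TSV round trip preserves features to 8 decimals", {
  b <- easy_bench()
  V <- diffusion_states(b$bench$network)
  model <- mashup_embed(V, d = 5)
  path <- tempfile(fileext = ".tsv")
  write_embedding(model, b$kinds, path)
  back <- read_embedding(path)
  expect_equal(back$X, model$X, tolerance = 1e-7, ignore_attr = TRUE)
  expect_identical(back$kinds, b$kinds)
  expect_identical(rownames(back$X), rownames(model$X))
})
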