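# Shared fixtures, built in code and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

# easy synthetic benchmark with its diffusion embedding
easy_bench <- function(seed = 7L, dim = 32L) {
  key <- sprintf("bench_%d_%d", seed, dim)
  if (is.null(.fixture_cache[[key]])) {
    b <- make_benchmark("easy", seed = seed)
    V <- diffusion_states(b$network)
    emb <- mashup_embed(V, d = dim)
    .fixture_cache[[key]] <- list(
      bench = b,
      X = emb$X,
      labels = b$labels[b$network$nodes$id, , drop = FALSE],
      kinds = b$network$nodes$kind,
      ids = b$network$nodes$id)
  }
  .fixture_cache[[key]]
}

# write a links-dialect TSV, returning its path
write_links <- function(rows, header = c("node1", "node2", "combined_score"),
                        gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".tsv.gz" else ".tsv")
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  writeLines(c(paste(header, collapse = "\t"), rows), con)
  close(con)
  path
}

# small hand-specified network: edges as data.frame(source, target, raw_score)
toy_network <- function(cci = NULL, cpi = NULL, ppi = NULL, chems, enzs) {
  mk <- function(x) {
    if (is.null(x)) {
      data.frame(source = character(), target = character(),
                 raw_score = integer(), stringsAsFactors = FALSE)
    } else {
      data.frame(source = x[[1L]], target = x[[2L]],
                 raw_score = as.integer(x[[3L]]), stringsAsFactors = FALSE)
    }
  }
  build_hetero_network(mk(cci), mk(cpi), mk(ppi), chems, enzs)
}

# random connected weighted network for RWR oracle checks
random_transition <- function(n, seed) {
  withr::with_seed(seed, {
    A <- matrix(0, n, n)
    ut <- which(upper.tri(A))
    on <- runif(length(ut)) < 0.4
    A[ut[on]] <- runif(sum(on), 0.001, 0.999)
    for (i in seq_len(n - 1)) {            # spanning path keeps it connected
      if (A[i, i + 1] == 0) A[i, i + 1] <- runif(1, 0.001, 0.999)
    }
    A <- A + t(A)
    sweep(A, 2L, colSums(A), "/")
  })
}

# direct linear-solve RWR: p = r (I - (1 - r) P)^{-1} e
rwr_solve <- function(P, seed_index, r) {
  n <- nrow(P)
  e <- numeric(n)
  e[seed_index] <- 1
  as.numeric(solve(diag(n) - (1 - r) * P, r * e))
}

# independent brute-force RAKEL oracle: LP restriction + 1-NN + vote average
oracle_rakel <- function(xtr, ytr, xte, labelsets, threshold = 0.5) {
  m <- ncol(ytr)
  n <- nrow(xte)
  votes <- matrix(0, n, m)
  cover <- integer(m)
  for (ls in labelsets) {
    cover[ls] <- cover[ls] + 1L
    for (i in seq_len(n)) {
      d2 <- rowSums(sweep(xtr, 2L, xte[i, ])^2)
      nn <- which.min(d2)
      votes[i, ls] <- votes[i, ls] + ytr[nn, ls]
    }
  }
  avg <- sweep(votes, 2L, pmax(cover, 1L), "/")
  avg[, cover == 0L] <- 0
  (avg > threshold) * 1L
}

# random multilabel data with every row non-empty
random_labels <- function(n, m, seed) {
  withr::with_seed(seed, {
    L <- matrix(rbinom(n * m, 1L, 0.4), n, m)
    for (i in which(rowSums(L) == 0)) L[i, sample.int(m, 1L)] <- 1L
    colnames(L) <- paste0("L", seq_len(m))
    L
  })
}
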