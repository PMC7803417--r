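#' Random walk with restart configuration
#'
#' @param restart_prob Probability of returning to the seed at each step,
#'   in (0, 1]. Default 0.5, the convention of the reference Mashup
#'   implementation.
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter Iteration cap.
#' @return A list of class `rwr_config`.
#' @export
rwr_config <- function(restart_prob = 0.5, tol = 1e-8, max_iter = 1000L) {
  stopifnot(is.numeric(restart_prob), length(restart_prob) == 1L,
            restart_prob > 0, restart_prob <= 1,
            is.numeric(tol), tol > 0, max_iter >= 1)
  structure(list(restart_prob = restart_prob, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "rwr_config")
}

#' Column-stochastic transition matrix of a heterogeneous network
#'
#' Entry (i, j) is weight(i, j) divided by the weighted degree of j, so
#' every column sums to one.
#'
#' @param network A `hetero_network` with no isolated nodes.
#' @return n x n numeric matrix, columns summing to 1.
#' @export
transition_matrix <- function(network) {
  A <- adjacency_matrix(network)
  deg <- colSums(A)
  if (any(deg == 0)) {
    stop("network has isolated node(s); run drop_isolated() first")
  }
  sweep(A, 2L, deg, "/")
}

#' Random walk with restart from one seed node
#'
#' Iterates `p <- (1 - r) * P %*% p + r * e_seed` from `p = e_seed` until the
#' L1 change falls below `cfg$tol` or `cfg$max_iter` is reached. The fixed
#' point is the diffusion state of the seed: a proximity distribution over
#' all nodes.
#'
#' @param P Column-stochastic transition matrix.
#' @param seed_index Seed node index (1-based).
#' @param cfg An [rwr_config()].
#' @return Probability vector over nodes, with attributes `converged`
#'   (logical) and `iterations`. A warning is raised when the cap is hit.
#' @export
rwr <- function(P, seed_index, cfg = rwr_config()) {
  n <- nrow(P)
  stopifnot(ncol(P) == n, seed_index >= 1L, seed_index <= n)
  r <- cfg$restart_prob
  e <- numeric(n)
  e[seed_index] <- 1
  p <- e
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    p_new <- (1 - r) * as.vector(P %*% p) + r * e
    if (sum(abs(p_new - p)) < cfg$tol) {
      p <- p_new
      converged <- TRUE
      break
    }
    p <- p_new
  }
  if (!converged) {
    warning("RWR did not converge in ", cfg$max_iter,
            " iterations (seed ", seed_index, ")")
  }
  structure(p, converged = converged, iterations = iter)
}

#' Diffusion states of every node
#'
#' Runs [rwr()] seeded at each node in canonical order and stacks the
#' resulting distributions as columns.
#'
#' @param network A `hetero_network` with no isolated nodes.
#' @param cfg An [rwr_config()].
#' @return n x n matrix; column i is the diffusion state of node i. Columns
#'   sum to 1; dimnames are node ids.
#' @export
diffusion_states <- function(network, cfg = rwr_config()) {
  P <- transition_matrix(network)
  n <- nrow(P)
  V <- vapply(seq_len(n), function(i) as.numeric(rwr(P, i, cfg)), numeric(n))
  dimnames(V) <- dimnames(P)
  V
}

column_softmax <- function(Z) {
  Z <- sweep(Z, 2L, apply(Z, 2L, max), "-")
  E <- exp(Z)
  sweep(E, 2L, colSums(E), "/")
}

#' Average KL divergence between diffusion states and the softmax model
#'
#' Computes `mean_i KL(V_i || softmax(W %*% X[i, ]))`, the objective
#' minimized by the embedding: node i's diffusion state is approximated by a
#' softmax over the inner products of its feature vector with every node's
#' context vector. Terms with `V[k, i] == 0` contribute zero.
#'
#' @param X n x d node feature matrix (row i = features of node i).
#' @param W n x d context matrix (row k = context vector of node k).
#' @param V n x n diffusion-state matrix, columns summing to 1.
#' @return Nonnegative scalar (nats).
#' @export
kl_objective <- function(X, W, V) {
  stopifnot(nrow(X) == ncol(V), nrow(W) == nrow(V), ncol(X) == ncol(W))
  Vt <- column_softmax(W %*% t(X))
  pos <- V > 0
  sum(V[pos] * (log(V[pos]) - log(Vt[pos]))) / ncol(V)
}

#' Low-dimensional embedding of diffusion states
#'
#' Factorizes the log diffusion-state matrix so the softmax model over
#' `X %*% t(W)` reproduces the diffusion states. Two routes:
#'
#' * `method = "svd"` (default, deterministic): truncated rank-d SVD of
#'   `L = log(V + eps)`; with `L = U S V'`, `W = U sqrt(S)` and
#'   `X = V sqrt(S)` so `W %*% t(X)` is the best rank-d approximation of L,
#'   and per-column softmax normalization absorbs any column shift.
#' * `method = "kl_gradient"`: full-batch gradient descent on the average-KL
#'   objective from a seeded small uniform init, with step halving on any
#'   objective increase; records the per-iteration objective trace.
#'
#' @param V Diffusion-state matrix from [diffusion_states()].
#' @param d Embedding dimension, 1 <= d <= n. Default 250.
#' @param method `"svd"` or `"kl_gradient"`.
#' @param seed RNG seed for the gradient init.
#' @param iters Gradient iterations (ignored for svd).
#' @param lr Initial gradient step size.
#' @param eps Pseudo-count inside the log. Default: `1/n` when V contains
#'   nonpositive entries (guards `log(0)`), 0 for strictly positive V so the
#'   full-rank factorization is exact.
#' @return A `mashup_model`: list with `X` (node features, used downstream),
#'   `W` (context vectors), `d`, `method`, and `objective_trace`.
#' @export
mashup_embed <- function(V, d = 250L, method = c("svd", "kl_gradient"),
                         seed = 1L, iters = 500L, lr = 0.1, eps = NULL) {
  method <- match.arg(method)
  n <- nrow(V)
  stopifnot(ncol(V) == n)
  d <- as.integer(d)
  if (d < 1L || d > n) stop("embedding dimension d must satisfy 1 <= d <= n")
  if (is.null(eps)) eps <- if (any(V <= 0)) 1 / n else 0
  if (method == "svd") {
    L <- log(V + eps)
    s <- svd(L, nu = d, nv = d)
    sq <- sqrt(s$d[seq_len(d)])
    W <- s$u * rep(sq, each = n)
    X <- s$v * rep(sq, each = n)
    trace <- kl_objective(X, W, V)
  } else {
    X <- withr::with_seed(seed, matrix(stats::runif(n * d, -0.01, 0.01), n, d))
    W <- withr::with_seed(seed + 1L, matrix(stats::runif(n * d, -0.01, 0.01), n, d))
    obj <- kl_objective(X, W, V)
    trace <- numeric(iters + 1L)
    trace[1L] <- obj
    for (it in seq_len(iters)) {
      G <- (column_softmax(W %*% t(X)) - V) / n
      dW <- G %*% X
      dX <- t(G) %*% W
      repeat {
        Xc <- X - lr * dX
        Wc <- W - lr * dW
        cand <- kl_objective(Xc, Wc, V)
        if (!is.finite(cand)) {
          if (lr < 1e-14) stop("non-finite objective at iteration ", it)
          lr <- lr / 2
          next
        }
        if (cand <= obj || lr < 1e-14) break
        lr <- lr / 2
      }
      X <- Xc
      W <- Wc
      obj <- cand
      trace[it + 1L] <- obj
    }
  }
  rownames(X) <- colnames(V)
  rownames(W) <- rownames(V)
  structure(list(X = X, W = W, d = d, method = method,
                 objective_trace = trace),
            class = "mashup_model")
}

#' Softmax reconstruction of diffusion states from an embedding
#'
#' @param model A `mashup_model`.
#' @return n x n matrix `column_softmax(W %*% t(X))`; each column is the
#'   model's approximation of the corresponding diffusion state.
#' @export
reconstruct_diffusion <- function(model) {
  column_softmax(model$W %*% t(model$X))
}

#' @export
print.mashup_model <- function(x, ...) {
  cat("Mashup embedding:", nrow(x$X), "nodes, d =", x$d,
      ", method =", x$method, "\n")
  cat("  final KL objective:",
      format(x$objective_trace[length(x$objective_trace)], digits = 6), "\n")
  invisible(x)
}

#' Write node embeddings to TSV
#'
#' @param model A `mashup_model`.
#' @param kinds Character vector of node kinds aligned with `rownames(model$X)`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_embedding <- function(model, kinds, path) {
  X <- model$X
  df <- data.frame(id = rownames(X), kind = kinds, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(matrix(sprintf("%.8f", X), nrow(X), ncol(X)),
                                stringsAsFactors = FALSE))
  names(df) <- c("id", "kind", paste0("f", seq_len(ncol(X))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an embedding TSV written by [write_embedding()]
#'
#' @param path File path.
#' @return List with `X` (numeric matrix, node ids as rownames) and `kinds`.
#' @export
read_embedding <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  X <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- df$id
  list(X = X, kinds = df$kind)
}
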