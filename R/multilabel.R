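#' Validate a binary label matrix
#'
#' @param labels n x m matrix with entries in {0, 1}; column names are the
#'   label vocabulary.
#' @param require_nonempty Require every row to carry at least one label
#'   (true for training labels).
#' @return The matrix, invisibly, after checks.
#' @keywords internal
check_label_matrix <- function(labels, require_nonempty = FALSE) {
  if (!is.matrix(labels) || !all(labels %in% c(0, 1))) {
    stop("labels must be a binary 0/1 matrix")
  }
  if (require_nonempty && any(rowSums(labels) == 0)) {
    stop("every training sample must carry at least one label")
  }
  invisible(labels)
}

#' Label-powerset transformation restricted to a labelset
#'
#' Maps each sample's label set, restricted to the given subset of label
#' indices, to a single class identifier: the sorted indices joined by "+",
#' with "{}" encoding the empty restriction. Two samples with identical
#' restrictions receive identical class ids.
#'
#' @param labels Binary label matrix.
#' @param labelset Integer vector of label column indices (non-empty).
#' @return Character vector of class ids, one per row of `labels`.
#' @examples
#' y <- rbind(c(1, 1, 0), c(0, 0, 1))
#' lp_transform(y, c(1, 2, 3))  # "1+2", "3"
#' @export
lp_transform <- function(labels, labelset) {
  check_label_matrix(labels)
  labelset <- sort(unique(as.integer(labelset)))
  if (length(labelset) == 0L) stop("labelset must be non-empty")
  if (any(labelset < 1L) || any(labelset > ncol(labels))) {
    stop("labelset indices out of range")
  }
  sub <- labels[, labelset, drop = FALSE]
  apply(sub, 1L, function(r) {
    if (!any(r == 1)) "{}" else paste(labelset[r == 1], collapse = "+")
  })
}

parse_lp_class <- function(class_id) {
  if (identical(class_id, "{}")) return(integer())
  as.integer(strsplit(class_id, "+", fixed = TRUE)[[1L]])
}

#' Draw random k-labelsets
#'
#' Draws M subsets of size k from m labels: uniformly without replacement
#' among distinct k-subsets when `choose(m, k) >= M`, with replacement
#' otherwise. Deterministic given the seed.
#'
#' @param m Number of labels.
#' @param k Subset size, 1 <= k <= m.
#' @param M Number of subsets.
#' @param seed RNG seed.
#' @return Object of class `labelset_draw`: list with `sets` (list of sorted
#'   integer vectors), `m`, `k`, `M`, `seed`.
#' @export
sample_labelsets <- function(m, k, M, seed = 1L) {
  m <- as.integer(m); k <- as.integer(k); M <- as.integer(M)
  if (k < 1L || k > m) stop("k must satisfy 1 <= k <= m")
  if (M < 1L) stop("M must be >= 1")
  n_distinct <- choose(m, k)
  sets <- withr::with_seed(seed, {
    if (n_distinct >= M) {
      seen <- character()
      out <- vector("list", M)
      i <- 0L
      while (i < M) {
        cand <- sort(sample.int(m, k))
        key <- paste(cand, collapse = "+")
        if (!key %in% seen) {
          i <- i + 1L
          seen <- c(seen, key)
          out[[i]] <- cand
        }
      }
      out
    } else {
      lapply(seq_len(M), function(i) sort(sample.int(m, k)))
    }
  })
  structure(list(sets = sets, m = m, k = k, M = M, seed = seed),
            class = "labelset_draw")
}

#' Base-learner configuration for the label-powerset members
#'
#' @param type One of `"svm_poly"` (SMO-trained SVM, polynomial kernel
#'   `(u.v + 1)^E`), `"svm_rbf"` (RBF kernel), `"rf"` (random forest), or
#'   `"knn1"` (1-nearest-neighbour; deterministic, used mainly for
#'   small-scale oracle checks).
#' @param C SVM regularization parameter.
#' @param E Polynomial kernel exponent.
#' @param gamma RBF kernel width.
#' @param ntree Random forest tree count.
#' @param scale Standardize features before fitting (default FALSE; the
#'   embedding features already share a common scale).
#' @return A list of class `base_config`.
#' @export
base_config <- function(type = c("svm_poly", "svm_rbf", "rf", "knn1"),
                        C = 1, E = 1, gamma = 0.01, ntree = 100L,
                        scale = FALSE) {
  type <- match.arg(type)
  structure(list(type = type, C = C, E = E, gamma = gamma,
                 ntree = as.integer(ntree), scale = scale),
            class = "base_config")
}

base_is_deterministic <- function(config) config$type != "rf"

fit_base <- function(config, x, y, seed = 1L) {
  y <- factor(y)
  if (nlevels(y) < 2L) {
    return(structure(list(constant = levels(y)), class = "base_constant"))
  }
  switch(config$type,
    svm_poly = e1071::svm(x = x, y = y, type = "C-classification",
                          kernel = "polynomial", degree = config$E,
                          gamma = 1, coef0 = 1, cost = config$C,
                          scale = config$scale),
    svm_rbf = e1071::svm(x = x, y = y, type = "C-classification",
                         kernel = "radial", gamma = config$gamma,
                         cost = config$C, scale = config$scale),
    rf = withr::with_seed(seed,
           randomForest::randomForest(x = x, y = y, ntree = config$ntree)),
    knn1 = structure(list(x = x, y = y), class = "base_knn1")
  )
}

# seed guards the RNG that randomForest uses to break prediction-vote ties
predict_base <- function(fit, x, seed = NULL) {
  if (inherits(fit, "base_constant")) {
    return(rep(fit$constant, nrow(x)))
  }
  if (inherits(fit, "base_knn1")) {
    return(as.character(class::knn1(fit$x, x, fit$y)))
  }
  if (inherits(fit, "randomForest") && !is.null(seed)) {
    return(withr::with_seed(seed, as.character(predict(fit, x))))
  }
  as.character(predict(fit, x))
}

#' Fit a RAKEL random-k-labelsets ensemble
#'
#' Draws (or accepts) M labelsets of size k, applies the label-powerset
#' transformation to each, and fits one multiclass base classifier per
#' labelset. When the random draw fails to cover every label present in the
#' training data and coverage is feasible (`k * M >=` number of present
#' labels), the draw is retried with stepped seeds; if coverage is
#' infeasible the uncovered labels are reported with a warning (they can
#' never be predicted).
#'
#' Members with a single observed powerset class degenerate to constant
#' predictors (with a warning). For deterministic base learners, members
#' sharing a labelset share one fit.
#'
#' @param features n x d numeric matrix.
#' @param labels Binary label matrix; every row must have >= 1 label.
#' @param k Labelset size.
#' @param M Ensemble size.
#' @param base A [base_config()].
#' @param seed Seed governing the labelset draw and per-member randomness.
#' @param threshold Vote threshold used at prediction time.
#' @param labelsets Optional explicit list of integer labelsets overriding
#'   the random draw (each sorted, size k).
#' @return A `rakel_model`.
#' @export
rakel_fit <- function(features, labels, k, M, base = base_config(),
                      seed = 1L, threshold = 0.5, labelsets = NULL) {
  check_label_matrix(labels, require_nonempty = TRUE)
  stopifnot(nrow(features) == nrow(labels), nrow(features) >= 2L)
  m <- ncol(labels)
  present <- which(colSums(labels) > 0)
  if (is.null(labelsets)) {
    feasible <- k * M >= length(present)
    draw <- NULL
    for (attempt in 0:99) {
      draw <- sample_labelsets(m, k, M, seed = seed + attempt)
      covered <- sort(unique(unlist(draw$sets)))
      if (!feasible || all(present %in% covered)) break
    }
    labelsets <- draw$sets
  } else {
    stopifnot(all(vapply(labelsets, length, 0L) == k))
    labelsets <- lapply(labelsets, function(s) sort(as.integer(s)))
    M <- length(labelsets)
  }
  covered <- sort(unique(unlist(labelsets)))
  uncovered <- setdiff(present, covered)
  if (length(uncovered) > 0L) {
    warning("label(s) never covered by any labelset and never predictable: ",
            paste(colnames(labels)[uncovered], collapse = ", "))
  }
  cache <- new.env(parent = emptyenv())
  fits <- vector("list", M)
  for (j in seq_len(M)) {
    key <- paste(labelsets[[j]], collapse = "+")
    if (base_is_deterministic(base) && !is.null(cache[[key]])) {
      fits[[j]] <- cache[[key]]
      next
    }
    y <- lp_transform(labels, labelsets[[j]])
    if (length(unique(y)) < 2L) {
      warning("labelset member ", j,
              " has a single powerset class; constant predictor retained")
    }
    fits[[j]] <- fit_base(base, features, y, seed = seed + j)
    if (base_is_deterministic(base)) cache[[key]] <- fits[[j]]
  }
  structure(list(labelsets = labelsets, fits = fits, base = base,
                 threshold = threshold, k = as.integer(k), M = M, m = m,
                 label_names = colnames(labels), seed = seed),
            class = "rakel_model")
}

# expand each member's predicted powerset class into per-label votes and
# average over the members whose labelset covers each label
rakel_votes <- function(model, features) {
  n <- nrow(features)
  m <- model$m
  votes <- matrix(0, n, m)
  cover <- integer(m)
  for (j in seq_len(model$M)) {
    ls <- model$labelsets[[j]]
    cover[ls] <- cover[ls] + 1L
    cls <- predict_base(model$fits[[j]], features, seed = model$seed + j)
    memb <- vapply(cls, function(cl) {
      v <- numeric(length(ls))
      v[ls %in% parse_lp_class(cl)] <- 1
      v
    }, numeric(length(ls)))
    votes[, ls] <- votes[, ls] + t(memb)
  }
  avg <- sweep(votes, 2L, pmax(cover, 1L), "/")
  avg[, cover == 0L] <- 0
  colnames(avg) <- model$label_names
  avg
}

#' Predict label sets with a RAKEL model
#'
#' Each member predicts a powerset class over its labelset; the class is
#' expanded to binary votes on those labels; per label the votes are
#' averaged over the members covering it, and the label is assigned iff the
#' average exceeds the threshold strictly. Predicted sets may be empty.
#'
#' @param model A `rakel_model`.
#' @param features Matrix with the training feature dimension.
#' @param threshold Vote threshold in (0, 1); defaults to the model's.
#' @return Binary label matrix with attribute `"votes"` (the per-label
#'   average votes).
#' @export
rakel_predict <- function(model, features, threshold = model$threshold) {
  stopifnot(threshold > 0, threshold < 1)
  avg <- rakel_votes(model, features)
  pred <- (avg > threshold) * 1L
  dimnames(pred) <- dimnames(avg)
  attr(pred, "votes") <- avg
  pred
}

#' @export
print.rakel_model <- function(x, ...) {
  cat("RAKEL model: m =", x$m, ", k =", x$k, ", M =", x$M,
      ", base =", x$base$type, "\n")
  invisible(x)
}

#' Fit a binary-relevance (one-vs-all) multilabel model
#'
#' One independent binary classifier per label. Equivalent to RAKEL with
#' k = 1 and a full singleton cover in label order (per-label seeds are
#' `seed + label index`, matching RAKEL's per-member seeds).
#'
#' @inheritParams rakel_fit
#' @return A `br_model`.
#' @export
br_fit <- function(features, labels, base = base_config(), seed = 1L) {
  check_label_matrix(labels, require_nonempty = TRUE)
  m <- ncol(labels)
  fits <- vector("list", m)
  for (l in seq_len(m)) {
    y <- ifelse(labels[, l] == 1, as.character(l), "{}")
    if (length(unique(y)) < 2L) {
      warning("label ", colnames(labels)[l],
              " has a single class in training; constant predictor retained")
    }
    fits[[l]] <- fit_base(base, features, y, seed = seed + l)
  }
  structure(list(fits = fits, base = base, m = m,
                 label_names = colnames(labels), seed = seed),
            class = "br_model")
}

#' Predict label sets with a binary-relevance model
#'
#' @param model A `br_model`.
#' @param features Feature matrix.
#' @return Binary label matrix; label assigned iff its classifier votes
#'   positive.
#' @export
br_predict <- function(model, features) {
  pred <- vapply(seq_len(model$m), function(l) {
    (predict_base(model$fits[[l]], features, seed = model$seed + l) !=
       "{}") * 1L
  }, integer(nrow(features)))
  pred <- matrix(pred, nrow = nrow(features))
  colnames(pred) <- model$label_names
  pred
}

#' Fit-and-predict convenience wrapper for binary relevance
#'
#' @inheritParams br_fit
#' @param newdata Feature matrix to predict; defaults to `features`.
#' @return Binary label matrix of predictions on `newdata`.
#' @export
br_fit_predict <- function(features, labels, base = base_config(),
                           seed = 1L, newdata = features) {
  br_predict(br_fit(features, labels, base, seed), newdata)
}

#' Save / load a fitted multilabel model
#'
#' Persists the model (configuration, labelset draw and fitted base
#' learners) to a single archive file.
#'
#' @param model A `rakel_model` or `br_model`.
#' @param path Archive path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
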