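#' Multilabel evaluation measures
#'
#' Computes the four measures used to assess the pathway-type classifier:
#' accuracy (mean per-sample Jaccard index `|L n L'| / |L u L'|`), exact
#' match (fraction of samples whose predicted set equals the true set),
#' hamming loss (mean size of the symmetric difference divided by the number
#' of labels m), and the integrated score
#' `accuracy * exact_match * (1 - hamming_loss)`.
#'
#' @param true_labels Binary label matrix; every row must be non-empty.
#' @param pred_labels Binary label matrix of the same shape (rows may be
#'   empty).
#' @return A `metrics_report`: list with `accuracy`, `exact_match`,
#'   `hamming_loss`, `integrated_score`, `n`, `m`.
#' @examples
#' truth <- rbind(c(1, 1, 0), c(0, 0, 1))
#' pred <- rbind(c(1, 0, 0), c(0, 0, 1))
#' multilabel_metrics(truth, pred)
#' @export
multilabel_metrics <- function(true_labels, pred_labels) {
  check_label_matrix(true_labels, require_nonempty = TRUE)
  check_label_matrix(pred_labels)
  if (!all(dim(true_labels) == dim(pred_labels))) {
    stop("true and predicted label matrices must have the same shape")
  }
  n <- nrow(true_labels)
  m <- ncol(true_labels)
  inter <- rowSums(true_labels == 1 & pred_labels == 1)
  uni <- rowSums(true_labels == 1 | pred_labels == 1)
  accuracy <- mean(inter / uni)
  exact <- mean(rowSums(true_labels != pred_labels) == 0)
  hamming <- mean(rowSums(true_labels != pred_labels) / m)
  structure(list(accuracy = accuracy, exact_match = exact,
                 hamming_loss = hamming,
                 integrated_score = integrated_score(accuracy, exact, hamming),
                 n = n, m = m),
            class = "metrics_report")
}

#' Integrated score of the three multilabel measures
#'
#' The single selection criterion used throughout:
#' `accuracy * exact_match * (1 - hamming_loss)`.
#'
#' @param accuracy,exact_match,hamming_loss Numeric vectors in \[0, 1\].
#' @return `accuracy * exact_match * (1 - hamming_loss)`.
#' @examples
#' integrated_score(0.75, 0.5, 1 / 6)
#' @export
integrated_score <- function(accuracy, exact_match, hamming_loss) {
  accuracy * exact_match * (1 - hamming_loss)
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat(sprintf(paste0("Multilabel metrics (n = %d, m = %d):\n",
                     "  accuracy         %.*f\n  exact match      %.*f\n",
                     "  hamming loss     %.*f\n  integrated score %.*f\n"),
              x$n, x$m, digits, x$accuracy, digits, x$exact_match,
              digits, x$hamming_loss, digits, x$integrated_score))
  invisible(x)
}

metrics_as_row <- function(report) {
  data.frame(accuracy = report$accuracy, exact_match = report$exact_match,
             hamming_loss = report$hamming_loss,
             integrated_score = report$integrated_score)
}

#' Seeded ten-fold cross-validation plan
#'
#' Plain seeded uniform random partition into near-equal folds (no
#' stratification by default; see [cross_validate()]).
#'
#' @param n Sample count (must be >= `folds`).
#' @param folds Number of folds, default 10.
#' @param seed RNG seed.
#' @return A `cv_plan`: list with `folds` (fold id per sample), `n`,
#'   `n_folds`, `seed`.
#' @export
make_cv_plan <- function(n, folds = 10L, seed = 1L) {
  n <- as.integer(n); folds <- as.integer(folds)
  if (n < folds) stop("need at least as many samples as folds")
  sizes <- rep(n %/% folds, folds) + c(rep(1L, n %% folds),
                                       rep(0L, folds - n %% folds))
  assignment <- withr::with_seed(seed, sample(rep(seq_len(folds), sizes)))
  structure(list(folds = assignment, n = n, n_folds = folds, seed = seed),
            class = "cv_plan")
}

#' Multilabel model configuration
#'
#' Bundles the classification scheme and its parameters for use by the
#' cross-validation and pipeline drivers.
#'
#' @param method `"rakel"` or `"br"`.
#' @param k,M RAKEL labelset size and ensemble size (ignored for `"br"`).
#' @param base A [base_config()].
#' @param threshold RAKEL vote threshold.
#' @param seed Seed for the labelset draw / base-learner randomness.
#' @return A list of class `ml_config`.
#' @export
ml_config <- function(method = c("rakel", "br"), k = 11L, M = 5L,
                      base = base_config(), threshold = 0.5, seed = 1L) {
  method <- match.arg(method)
  structure(list(method = method, k = as.integer(k), M = as.integer(M),
                 base = base, threshold = threshold, seed = as.integer(seed)),
            class = "ml_config")
}

fit_multilabel <- function(config, features, labels) {
  if (config$method == "rakel") {
    rakel_fit(features, labels, k = config$k, M = config$M,
              base = config$base, seed = config$seed,
              threshold = config$threshold)
  } else {
    br_fit(features, labels, base = config$base, seed = config$seed)
  }
}

predict_multilabel <- function(model, features) {
  if (inherits(model, "rakel_model")) {
    rakel_predict(model, features)
  } else {
    br_predict(model, features)
  }
}

#' Cross-validate a multilabel model
#'
#' For each fold, fits on the complement and predicts the held-out fold.
#' The metrics are computed once over the pooled out-of-fold predictions
#' (every sample is tested exactly once), not averaged per fold.
#'
#' @param features n x d feature matrix.
#' @param labels Binary label matrix.
#' @param config An [ml_config()].
#' @param plan A [make_cv_plan()] for the same n.
#' @return A `metrics_report` with attribute `"predictions"` (the pooled
#'   out-of-fold binary predictions).
#' @export
cross_validate <- function(features, labels, config, plan) {
  stopifnot(nrow(features) == plan$n, nrow(labels) == plan$n)
  pred <- matrix(0L, plan$n, ncol(labels),
                 dimnames = list(rownames(features), colnames(labels)))
  for (f in seq_len(plan$n_folds)) {
    test <- plan$folds == f
    ytr <- labels[!test, , drop = FALSE]
    missing <- colnames(labels)[colSums(ytr) == 0]
    if (length(missing) > 0L) {
      warning("fold ", f, ": label(s) absent from training partition: ",
              paste(missing, collapse = ", "))
    }
    model <- fit_multilabel(config, features[!test, , drop = FALSE], ytr)
    p <- predict_multilabel(model, features[test, , drop = FALSE])
    pred[test, ] <- p
  }
  report <- multilabel_metrics(labels, pred)
  attr(report, "predictions") <- pred
  report
}

#' Repeated cross-validation
#'
#' Runs [cross_validate()] `repeats` times with plan seeds
#' `base_seed + 0, ..., base_seed + repeats - 1`.
#'
#' @inheritParams cross_validate
#' @param repeats Number of repetitions (default 100).
#' @param base_seed Seed of the first plan.
#' @param folds Folds per plan.
#' @return List with `reports` (one `metrics_report` per repeat), `table`
#'   (long-format data frame: repeat, metric, value) and `summary` (min,
#'   max, mean, sd per metric).
#' @export
repeated_cv <- function(features, labels, config, repeats = 100L,
                        base_seed = 1L, folds = 10L) {
  reports <- lapply(seq_len(repeats) - 1L, function(i) {
    plan <- make_cv_plan(nrow(features), folds = folds, seed = base_seed + i)
    cross_validate(features, labels, config, plan)
  })
  tab <- do.call(rbind, lapply(seq_along(reports), function(i) {
    row <- metrics_as_row(reports[[i]])
    data.frame(rep = i, metric = names(row), value = as.numeric(row))
  }))
  rownames(tab) <- NULL
  summ <- do.call(rbind, lapply(split(tab$value, tab$metric), function(v) {
    data.frame(min = min(v), max = max(v), mean = mean(v), sd = stats::sd(v))
  }))
  list(reports = reports, table = tab, summary = summ)
}

#' Permute feature vectors within node-kind blocks
#'
#' Shuffles which node receives which feature vector (labels stay fixed),
#' within the chemical block, the enzyme block, or both, destroying the
#' node-feature correspondence while preserving the multiset of rows. Used
#' to test that the network-derived features, not their marginal
#' distribution, carry the pathway signal.
#'
#' @param features n x d matrix.
#' @param node_kinds Character vector (`"chemical"` / `"enzyme"`) aligned
#'   with the rows.
#' @param mode `"all"`, `"chemicals_only"` or `"enzymes_only"`.
#' @param seed RNG seed.
#' @return The permuted feature matrix.
#' @export
permute_features <- function(features, node_kinds,
                             mode = c("all", "chemicals_only", "enzymes_only"),
                             seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(node_kinds) == nrow(features))
  out <- features
  blocks <- switch(mode,
    all = c("chemical", "enzyme"),
    chemicals_only = "chemical",
    enzymes_only = "enzyme")
  withr::with_seed(seed, {
    for (b in blocks) {
      idx <- which(node_kinds == b)
      out[idx, ] <- features[sample(idx), , drop = FALSE]
    }
  })
  out
}

#' Grid search over embedding dimension and classifier parameters
#'
#' Evaluates every grid point by cross-validation and ranks by integrated
#' score (descending), breaking ties by accuracy then by lexicographic
#' configuration order.
#'
#' @param features_by_dim Named list of feature matrices, one per embedding
#'   dimension (names are the dimensions as character).
#' @param labels Binary label matrix.
#' @param grid Data frame of configurations with columns `d`, `M`, `k`,
#'   `C`, `E`. Default: d over the supplied dimensions, M in {5, 10}, k in
#'   2..m, C in 1..3, E in 1..3 (polynomial-kernel SVM).
#' @param plan_seed Seed of the shared cross-validation plan.
#' @param folds Folds.
#' @return List with `best` (top row) and `table` (full ranked results).
#' @export
grid_search <- function(features_by_dim, labels, grid = NULL,
                        plan_seed = 1L, folds = 10L) {
  if (is.null(grid)) {
    grid <- expand.grid(d = as.integer(names(features_by_dim)),
                        M = c(5L, 10L), k = 2:ncol(labels),
                        C = 1:3, E = 1:3)
  }
  if (nrow(grid) == 0L) stop("parameter grid is empty")
  plan <- make_cv_plan(nrow(labels), folds = folds, seed = plan_seed)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cfg <- ml_config("rakel", k = g$k, M = g$M,
                     base = base_config("svm_poly", C = g$C, E = g$E),
                     seed = plan_seed)
    rep <- cross_validate(features_by_dim[[as.character(g$d)]], labels,
                          cfg, plan)
    cbind(g, metrics_as_row(rep), seed = plan_seed)
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$integrated_score, -tab$accuracy,
               tab$d, tab$M, tab$k, tab$C, tab$E)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  list(best = tab[1L, , drop = FALSE], table = tab)
}

#' Group-separated classification with pooled evaluation
#'
#' Trains and cross-validates chemicals and enzymes independently (shared
#' plan seed), then pools both groups' out-of-fold predictions before
#' computing one metrics report — the "separate classification, combined
#' evaluation" ablation.
#'
#' @param features_chem,features_enz Feature matrices of the two disjoint
#'   groups.
#' @param labels_chem,labels_enz Their label matrices (same label
#'   vocabulary).
#' @param config An [ml_config()].
#' @param seed Shared cross-validation plan seed.
#' @param folds Folds.
#' @return A `metrics_report` over the pooled `n_chem + n_enz` samples.
#' @export
ablation_separate <- function(features_chem, features_enz, labels_chem,
                              labels_enz, config, seed = 1L, folds = 10L) {
  if (nrow(features_chem) == 0L || nrow(features_enz) == 0L) {
    stop("both groups must be non-empty")
  }
  run <- function(x, y) {
    plan <- make_cv_plan(nrow(x), folds = folds, seed = seed)
    attr(cross_validate(x, y, config, plan), "predictions")
  }
  pred <- rbind(run(features_chem, labels_chem), run(features_enz, labels_enz))
  multilabel_metrics(rbind(labels_chem, labels_enz), pred)
}
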