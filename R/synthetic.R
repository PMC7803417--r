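#' Synthetic heterogeneous-network configuration
#'
#' Parameters of the label-conditioned planted-partition generator: node
#' pairs sharing at least one label connect with probability `p_intra`,
#' other pairs with `p_inter`, and shared-label edges draw heavier weights.
#' This emulates the premise that interaction neighbourhoods encode pathway
#' membership while staying fully seeded and download-free.
#'
#' @param n_chem,n_enz Chemical and enzyme node counts.
#' @param m Label count (>= 2).
#' @param max_labels_per_node Upper bound of per-node label multiplicity;
#'   the count is drawn uniformly in 1..max. Default 2, giving a mean
#'   multiplicity of 1.5, close to the 1.25-1.5 seen in curated
#'   pathway-membership data.
#' @param p_intra Edge probability for label-sharing pairs.
#' @param p_inter Edge probability otherwise (`p_inter <= p_intra`).
#' @param seed RNG seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_chem = 120L, n_enz = 60L, m = 5L,
                         max_labels_per_node = 2L, p_intra = 0.25,
                         p_inter = 0.02, seed = 1L) {
  stopifnot(m >= 2, max_labels_per_node >= 1,
            p_inter >= 0, p_intra <= 1, p_inter <= p_intra)
  structure(list(n_chem = as.integer(n_chem), n_enz = as.integer(n_enz),
                 m = as.integer(m),
                 max_labels_per_node = as.integer(max_labels_per_node),
                 p_intra = p_intra, p_inter = p_inter,
                 seed = as.integer(seed)),
            class = "synth_config")
}

synth_ids <- function(cfg) {
  c(sprintf("CHEM%04d", seq_len(cfg$n_chem)),
    sprintf("ENZ%04d", seq_len(cfg$n_enz)))
}

#' Generate multilabel pathway-type assignments
#'
#' Every node receives between 1 and `max_labels_per_node` labels: the
#' count uniform, the labels uniform without replacement. Deterministic
#' given the seed.
#'
#' @param cfg A [synth_config()].
#' @return List with `labels` (binary matrix, rownames = node ids, colnames
#'   `L01`...), `kinds` and `ids`.
#' @export
generate_labels <- function(cfg) {
  n <- cfg$n_chem + cfg$n_enz
  ids <- synth_ids(cfg)
  kinds <- c(rep("chemical", cfg$n_chem), rep("enzyme", cfg$n_enz))
  labels <- withr::with_seed(cfg$seed, {
    L <- matrix(0L, n, cfg$m,
                dimnames = list(ids, sprintf("L%02d", seq_len(cfg$m))))
    for (i in seq_len(n)) {
      cnt <- sample.int(cfg$max_labels_per_node, 1L)
      L[i, sample.int(cfg$m, cnt)] <- 1L
    }
    L
  })
  list(labels = labels, kinds = kinds, ids = ids)
}

# weight laws, quantized to 3 decimals so score = weight * 1000 round-trips;
# the two components stay disjoint after rounding (>= 0.500 vs <= 0.499)
draw_weights <- function(n, shared) {
  w <- ifelse(shared, stats::runif(n, 0.5, 0.999), stats::runif(n, 0.001, 0.5))
  w <- round(w, 3L)
  ifelse(shared, pmin(pmax(w, 0.5), 0.999), pmin(pmax(w, 0.001), 0.499))
}

#' Generate a heterogeneous network with planted label-correlated edges
#'
#' Independently for every node pair, an edge is included with probability
#' `p_intra` when the pair shares at least one label, `p_inter` otherwise;
#' shared-label edges draw weights from the heavier-weight component
#' (uniform(0.5, 0.999) vs uniform(0.001, 0.5), quantized to 3 decimals so
#' the 1-999 integer score format round-trips exactly). Any node left
#' isolated is re-wired to one random label-sharing partner, so
#' [drop_isolated()] removes nothing.
#'
#' @param labels Binary label matrix (rownames = node ids).
#' @param kinds Node kinds aligned with the rows.
#' @param cfg A [synth_config()].
#' @return A `hetero_network`.
#' @export
generate_network <- function(labels, kinds, cfg) {
  if (cfg$p_intra == 0 && cfg$p_inter == 0) {
    stop("p_intra and p_inter cannot both be zero: connectivity impossible")
  }
  ids <- rownames(labels)
  n <- nrow(labels)
  shared_mat <- tcrossprod(labels) > 0
  iu <- which(upper.tri(shared_mat), arr.ind = TRUE)
  shared <- shared_mat[iu]
  edges <- withr::with_seed(cfg$seed + 1L, {
    prob <- ifelse(shared, cfg$p_intra, cfg$p_inter)
    keep <- stats::runif(length(prob)) < prob
    ef <- data.frame(from = ids[iu[keep, 1L]], to = ids[iu[keep, 2L]],
                     weight = draw_weights(sum(keep), shared[keep]),
                     stringsAsFactors = FALSE)
    # re-wire isolated nodes to one shared-label partner
    deg <- table(factor(c(ef$from, ef$to), levels = ids))
    for (i in which(deg == 0L)) {
      cand <- setdiff(which(shared_mat[i, ]), i)
      if (length(cand) == 0L) cand <- setdiff(seq_len(n), i)
      j <- cand[sample.int(length(cand), 1L)]
      ef <- rbind(ef, data.frame(from = ids[min(i, j)], to = ids[max(i, j)],
                                 weight = draw_weights(1L, TRUE),
                                 stringsAsFactors = FALSE))
    }
    ef
  })
  kind_of <- stats::setNames(kinds, ids)
  pair_type <- function(a, b) {
    ka <- kind_of[a]; kb <- kind_of[b]
    ifelse(ka == "chemical" & kb == "chemical", "cc",
           ifelse(ka == "enzyme" & kb == "enzyme", "pp", "cp"))
  }
  edges$type <- pair_type(edges$from, edges$to)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  counts <- c(cci = sum(edges$type == "cc"), cpi = sum(edges$type == "cp"),
              ppi = sum(edges$type == "pp"))
  new_hetero_network(canonical_nodes(ids[kinds == "chemical"],
                                     ids[kinds == "enzyme"]),
                     edges, counts)
}

synth_presets <- list(
  easy = list(p_intra = 0.25, p_inter = 0.02),
  medium = list(p_intra = 0.15, p_inter = 0.04),
  hard = list(p_intra = 0.08, p_inter = 0.04)
)

#' Seeded benchmark fixtures
#'
#' Presets share node counts (120 chemicals, 60 enzymes) and m = 5 labels;
#' the planted signal `p_intra - p_inter` shrinks from easy (0.25 vs 0.02)
#' through medium (0.15 vs 0.04) to hard (0.08 vs 0.04).
#'
#' @param difficulty `"easy"`, `"medium"` or `"hard"`.
#' @param seed RNG seed.
#' @return List with `network`, `labels`, `kinds`, `ids`, `config`.
#' @export
make_benchmark <- function(difficulty = c("easy", "medium", "hard"),
                           seed = 1L) {
  difficulty <- match.arg(difficulty)
  p <- synth_presets[[difficulty]]
  cfg <- synth_config(p_intra = p$p_intra, p_inter = p$p_inter, seed = seed)
  lab <- generate_labels(cfg)
  net <- generate_network(lab$labels, lab$kinds, cfg)
  list(network = net, labels = lab$labels, kinds = lab$kinds,
       ids = lab$ids, config = cfg)
}

#' Export a benchmark in the STITCH/STRING input dialects
#'
#' Writes `cci.tsv`, `cpi.tsv`, `ppi.tsv` (tab-separated, header, integer
#' scores `round(weight * 1000)`), `chemicals.txt`, `enzymes.txt` (one id
#' per line) and `labels.tsv` (id, semicolon-separated label names) so the
#' parsing front end is exercised end-to-end.
#'
#' @param benchmark Output of [make_benchmark()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
export_benchmark <- function(benchmark, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ed <- benchmark$network$edges
  write_links <- function(sub, path, col1, col2) {
    df <- data.frame(a = sub$from, b = sub$to,
                     score = as.integer(round(sub$weight * 1000)))
    names(df) <- c(col1, col2, "combined_score")
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(
    cci = write_links(ed[ed$type == "cc", ], file.path(dir, "cci.tsv"),
                      "chemical1", "chemical2"),
    cpi = write_links(ed[ed$type == "cp", ], file.path(dir, "cpi.tsv"),
                      "chemical", "protein"),
    ppi = write_links(ed[ed$type == "pp", ], file.path(dir, "ppi.tsv"),
                      "protein1", "protein2"),
    chemicals = file.path(dir, "chemicals.txt"),
    enzymes = file.path(dir, "enzymes.txt"),
    labels = file.path(dir, "labels.tsv"))
  writeLines(benchmark$ids[benchmark$kinds == "chemical"], paths[["chemicals"]])
  writeLines(benchmark$ids[benchmark$kinds == "enzyme"], paths[["enzymes"]])
  lab <- benchmark$labels
  sets <- apply(lab, 1L, function(r) paste(colnames(lab)[r == 1],
                                           collapse = ";"))
  utils::write.table(data.frame(id = rownames(lab), labels = sets),
                     paths[["labels"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

#' Read a node-label table
#'
#' Parses a TSV of (node id, semicolon-separated label names) into a binary
#' label matrix over the union of observed label names (sorted), or over an
#' explicit vocabulary.
#'
#' @param path Label TSV (with header).
#' @param vocabulary Optional character vector fixing the label order.
#' @return Binary label matrix, rownames = node ids.
#' @export
read_label_table <- function(path, vocabulary = NULL) {
  df <- utils::read.delim(path, colClasses = "character")
  sets <- strsplit(df[[2L]], ";", fixed = TRUE)
  if (is.null(vocabulary)) vocabulary <- sort(unique(unlist(sets)))
  lab <- matrix(0L, nrow(df), length(vocabulary),
                dimnames = list(df[[1L]], vocabulary))
  for (i in seq_along(sets)) lab[i, sets[[i]]] <- 1L
  lab
}
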