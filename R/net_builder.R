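#' Read a STITCH/STRING-dialect links file
#'
#' Parses a tab-separated edge list in the links-file dialect used by the
#' STITCH and STRING databases: three columns (node1, node2, score), an
#' optional single header line, optionally gzip-compressed. The score is an
#' integer evidence-integration confidence in \[1, 999\].
#'
#' @param path Path to the file (plain or `.gz`).
#' @param dialect One of `"cci"`, `"cpi"`, `"ppi"`. For `"cpi"` the first
#'   column is taken as the chemical and the second as the protein; for the
#'   homogeneous dialects the column order carries no meaning.
#' @return A data frame of class `edge_records` with columns `source`,
#'   `target` (character) and `raw_score` (integer). Self-interaction rows
#'   are dropped with a warning; an empty file yields zero rows.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("chem1\tchem2\t800", "chem1\tchem3\t150"), tf)
#' read_edge_list(tf, "cci")
#' @export
read_edge_list <- function(path, dialect = c("cci", "cpi", "ppi")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("edge list file not found: ", path)
  }
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con)
  empty <- data.frame(source = character(), target = character(),
                      raw_score = integer(), stringsAsFactors = FALSE)
  if (length(lines) == 0L) {
    return(structure(empty, dialect = dialect, class = c("edge_records", "data.frame")))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  first <- fields[[1L]]
  # header detection: a first line whose third column is not an integer
  if (length(first) == 3L && is.na(suppressWarnings(as.integer(first[3L])))) {
    start <- 2L
  }
  if (start > length(lines)) {
    return(structure(empty, dialect = dialect, class = c("edge_records", "data.frame")))
  }
  idx <- start:length(lines)
  nf <- lengths(fields[idx])
  bad <- idx[nf != 3L]
  if (length(bad) > 0L) {
    stop("malformed row at line ", bad[1L], ": expected 3 tab-separated columns, got ",
         nf[match(bad[1L], idx)])
  }
  mat <- matrix(unlist(fields[idx], use.names = FALSE), ncol = 3L, byrow = TRUE)
  score <- suppressWarnings(as.integer(mat[, 3L]))
  nonint <- is.na(score) | mat[, 3L] != as.character(score)
  if (any(nonint)) {
    stop("malformed row at line ", idx[which(nonint)[1L]],
         ": score is not an integer: '", mat[which(nonint)[1L], 3L], "'")
  }
  oob <- score < 1L | score > 999L
  if (any(oob)) {
    stop("invalid score at line ", idx[which(oob)[1L]], ": ",
         score[which(oob)[1L]], " is outside [1, 999]")
  }
  self <- mat[, 1L] == mat[, 2L]
  if (any(self)) {
    warning(sum(self), " self-interaction row(s) dropped")
  }
  keep <- !self
  out <- data.frame(source = mat[keep, 1L], target = mat[keep, 2L],
                    raw_score = score[keep], stringsAsFactors = FALSE)
  structure(out, dialect = dialect, class = c("edge_records", "data.frame"))
}

#' Refine a raw confidence score to an edge weight
#'
#' Maps the integer confidence score of a STITCH/STRING interaction, which
#' ranges over \[1, 999\], to a weight in (0, 1) by dividing by 1000.
#'
#' @param raw_score Integer vector of scores in \[1, 999\].
#' @return Numeric vector `raw_score / 1000`.
#' @examples
#' refine_score(c(1L, 500L, 999L))
#' @export
refine_score <- function(raw_score) {
  if (length(raw_score) == 0L) return(numeric())
  if (any(!is.finite(raw_score)) || any(raw_score != as.integer(raw_score)) ||
      any(raw_score < 1) || any(raw_score > 999)) {
    stop("raw_score must be integer-valued in [1, 999]")
  }
  raw_score / 1000
}

new_hetero_network <- function(nodes, edges, subnetwork_counts) {
  structure(list(nodes = nodes, edges = edges,
                 subnetwork_counts = subnetwork_counts),
            class = "hetero_network")
}

# canonical node order: chemicals sorted lexicographically, then enzymes
canonical_nodes <- function(chemical_ids, enzyme_ids) {
  data.frame(id = c(sort(chemical_ids), sort(enzyme_ids)),
             kind = c(rep("chemical", length(chemical_ids)),
                      rep("enzyme", length(enzyme_ids))),
             stringsAsFactors = FALSE)
}

# resolve duplicate unordered pairs keeping the maximum weight
dedupe_edges <- function(from, to, weight) {
  if (length(from) == 0L) {
    return(data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  w <- tapply(weight, key, max)
  ks <- strsplit(names(w), "\r", fixed = TRUE)
  out <- data.frame(from = vapply(ks, `[`, "", 1L),
                    to = vapply(ks, `[`, "", 2L),
                    weight = as.numeric(w), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$from, out$to), , drop = FALSE]
}

#' Assemble the heterogeneous chemical-enzyme network
#'
#' Combines chemical-chemical, chemical-protein and protein-protein edge
#' records into one weighted undirected network over the supplied node
#' rosters. Raw scores are refined via [refine_score()]; duplicate rows for
#' the same unordered pair keep the maximum refined score; edges with an
#' endpoint outside the rosters are dropped (their count is reported via
#' `message()`).
#'
#' @param cci,cpi,ppi Edge records as returned by [read_edge_list()] (any
#'   data frame with columns `source`, `target`, `raw_score` works).
#' @param chemical_ids,enzyme_ids Character vectors naming the chemical and
#'   enzyme nodes. They must be disjoint; kind is assigned only from these
#'   rosters, never inferred from identifier syntax.
#' @return A `hetero_network`: list with `nodes` (data frame `id`, `kind` in
#'   canonical order: chemicals sorted lexicographically, then enzymes),
#'   `edges` (data frame `from`, `to`, `weight`, `type`), and
#'   `subnetwork_counts` (named integer vector `cci`, `cpi`, `ppi` of
#'   deduplicated edge counts).
#' @export
build_hetero_network <- function(cci, cpi, ppi, chemical_ids, enzyme_ids) {
  chemical_ids <- unique(as.character(chemical_ids))
  enzyme_ids <- unique(as.character(enzyme_ids))
  both <- intersect(chemical_ids, enzyme_ids)
  if (length(both) > 0L) {
    stop("identifier(s) present in both rosters: ",
         paste(utils::head(both, 5L), collapse = ", "))
  }
  filter_part <- function(rec, ok_source, ok_target, symmetric) {
    if (is.null(rec) || nrow(rec) == 0L) {
      return(list(rec = rec[0L, , drop = FALSE], dropped = 0L))
    }
    if (symmetric) {
      keep <- rec$source %in% ok_source & rec$target %in% ok_source
    } else {
      keep <- rec$source %in% ok_source & rec$target %in% ok_target
    }
    list(rec = rec[keep, , drop = FALSE], dropped = sum(!keep))
  }
  fc <- filter_part(cci, chemical_ids, NULL, TRUE)
  fx <- filter_part(cpi, chemical_ids, enzyme_ids, FALSE)
  fp <- filter_part(ppi, enzyme_ids, NULL, TRUE)
  dropped <- fc$dropped + fx$dropped + fp$dropped
  if (dropped > 0L) {
    message(dropped, " edge(s) dropped: endpoint outside the node rosters")
  }
  parts <- list(cci = fc$rec, cpi = fx$rec, ppi = fp$rec)
  deduped <- lapply(parts, function(rec) {
    if (nrow(rec) == 0L) {
      return(dedupe_edges(character(), character(), numeric()))
    }
    dedupe_edges(rec$source, rec$target, refine_score(rec$raw_score))
  })
  counts <- vapply(deduped, nrow, 0L)
  type_of <- c(cci = "cc", cpi = "cp", ppi = "pp")
  edges <- do.call(rbind, lapply(names(deduped), function(nm) {
    d <- deduped[[nm]]
    if (nrow(d) > 0L) d$type <- type_of[[nm]] else d$type <- character()
    d
  }))
  rownames(edges) <- NULL
  new_hetero_network(canonical_nodes(chemical_ids, enzyme_ids), edges, counts)
}

#' @export
print.hetero_network <- function(x, ...) {
  cat("Heterogeneous network:", sum(x$nodes$kind == "chemical"), "chemicals,",
      sum(x$nodes$kind == "enzyme"), "enzymes,", nrow(x$edges), "edges\n")
  cat("  subnetwork edges: cci =", x$subnetwork_counts[["cci"]],
      ", cpi =", x$subnetwork_counts[["cpi"]],
      ", ppi =", x$subnetwork_counts[["ppi"]], "\n")
  invisible(x)
}

node_degrees <- function(network) {
  deg <- stats::setNames(rep(0L, nrow(network$nodes)), network$nodes$id)
  if (nrow(network$edges) > 0L) {
    t1 <- table(network$edges$from)
    t2 <- table(network$edges$to)
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  deg
}

#' Remove isolated nodes from a heterogeneous network
#'
#' Nodes with no incident edge carry no diffusion signal and are discarded
#' before embedding.
#'
#' @param network A `hetero_network`.
#' @return List with `network` (pruned, canonical order preserved) and
#'   `removed` (ids of dropped nodes, sorted lexicographically).
#' @export
drop_isolated <- function(network) {
  deg <- node_degrees(network)
  removed <- sort(names(deg)[deg == 0L])
  keep <- network$nodes[!(network$nodes$id %in% removed), , drop = FALSE]
  rownames(keep) <- NULL
  list(network = new_hetero_network(keep, network$edges,
                                    network$subnetwork_counts),
       removed = removed)
}

#' Write a heterogeneous network to canonical TSV files
#'
#' Writes `<prefix>_edges.tsv` (columns source, target, kind_pair, weight
#' with 6 decimals), `<prefix>_chemicals.txt` and `<prefix>_enzymes.txt`
#' (one id per line).
#'
#' @param network A `hetero_network`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_hetero_network <- function(network, prefix) {
  ed <- network$edges
  out <- data.frame(source = ed$from, target = ed$to, kind_pair = ed$type,
                    weight = sprintf("%.6f", ed$weight),
                    stringsAsFactors = FALSE)
  paths <- c(edges = paste0(prefix, "_edges.tsv"),
             chemicals = paste0(prefix, "_chemicals.txt"),
             enzymes = paste0(prefix, "_enzymes.txt"))
  utils::write.table(out, paths[["edges"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(network$nodes$id[network$nodes$kind == "chemical"],
             paths[["chemicals"]])
  writeLines(network$nodes$id[network$nodes$kind == "enzyme"],
             paths[["enzymes"]])
  invisible(paths)
}

#' Read a heterogeneous network written by [write_hetero_network()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `hetero_network`.
#' @export
read_hetero_network <- function(prefix) {
  ed <- utils::read.delim(paste0(prefix, "_edges.tsv"),
                          colClasses = c("character", "character",
                                         "character", "numeric"))
  chems <- readLines(paste0(prefix, "_chemicals.txt"))
  enzs <- readLines(paste0(prefix, "_enzymes.txt"))
  edges <- data.frame(from = ed$source, to = ed$target, weight = ed$weight,
                      type = ed$kind_pair, stringsAsFactors = FALSE)
  counts <- c(cci = sum(edges$type == "cc"), cpi = sum(edges$type == "cp"),
              ppi = sum(edges$type == "pp"))
  new_hetero_network(canonical_nodes(chems, enzs), edges, counts)
}

#' Weighted adjacency matrix in canonical node order
#'
#' @param network A `hetero_network`.
#' @return Symmetric n x n numeric matrix with dimnames set to node ids.
#' @export
adjacency_matrix <- function(network) {
  ids <- network$nodes$id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(network$edges) > 0L) {
    i <- match(network$edges$from, ids)
    j <- match(network$edges$to, ids)
    if (anyNA(i) || anyNA(j)) stop("edge endpoint missing from node table")
    A[cbind(i, j)] <- network$edges$weight
    A[cbind(j, i)] <- network$edges$weight
  }
  A
}
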