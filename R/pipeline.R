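#' Default pipeline configuration
#'
#' @param inputs Named list of input paths: `cci`, `cpi`, `ppi`,
#'   `chemicals`, `enzymes`, `labels`.
#' @param embedding List: `dim`, `method`, `restart`, `tol`, `max_iter`.
#' @param model List: `method`, `k`, `M`, `base`, `C`, `E`, `gamma`,
#'   `ntree`, `threshold`.
#' @param evaluation List: `folds`, `repeats`.
#' @param seed Global seed; every seeded stage derives from it.
#' @param out_dir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(inputs, embedding = list(), model = list(),
                       evaluation = list(), seed = 1L, out_dir = tempfile()) {
  emb <- utils::modifyList(list(dim = 250L, method = "svd", restart = 0.5,
                                tol = 1e-8, max_iter = 1000L), embedding)
  mod <- utils::modifyList(list(method = "rakel", k = NULL, M = 5L,
                                base = "svm_poly", C = 2, E = 1,
                                gamma = 0.01, ntree = 100L,
                                threshold = 0.5), model)
  ev <- utils::modifyList(list(folds = 10L, repeats = 1L), evaluation)
  structure(list(inputs = inputs, embedding = emb, model = mod,
                 evaluation = ev, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()].
#'
#' @param path YAML file.
#' @param overrides Named list applied on top of the file's values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- utils::modifyList(yaml::read_yaml(path), overrides)
  run_config(inputs = raw$inputs,
             embedding = raw$embedding %||% list(),
             model = raw$model %||% list(),
             evaluation = raw$evaluation %||% list(),
             seed = raw$seed %||% 1L,
             out_dir = raw$out_dir %||% tempfile())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_run_config <- function(config) {
  need <- c("cci", "cpi", "ppi", "chemicals", "enzymes", "labels")
  miss <- setdiff(need, names(config$inputs))
  if (length(miss) > 0L) {
    stop("missing input path(s) in config: ", paste(miss, collapse = ", "))
  }
  for (nm in need) {
    if (!file.exists(config$inputs[[nm]])) {
      stop("input file for '", nm, "' not found: ", config$inputs[[nm]])
    }
  }
  invisible(config)
}

config_base <- function(mod) {
  base_config(mod$base, C = mod$C, E = mod$E, gamma = mod$gamma,
              ntree = mod$ntree)
}

#' Run the full network-to-metrics pipeline
#'
#' Orchestrates network assembly (parse edge lists, refine scores, drop
#' isolated nodes), diffusion + embedding, and cross-validated multilabel
#' classification; persists intermediate artifacts and a manifest (config
#' hash, seeds, stage durations, warning counts) in the output directory.
#' Any stage failure aborts with the failing stage named; artifacts of
#' completed stages are retained.
#'
#' @param config A [run_config()] or path to a YAML file.
#' @return Invisibly, a list with `out_dir`, `metrics` (a `metrics_report`)
#'   and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("hnetpath")),
                   seed = config$seed, stages = list(), warnings = 0L)
  warn_count <- 0L
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        warn_count <<- warn_count + 1L
        invokeRestart("muffleWarning")
      })
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  net <- stage("build-net", {
    cci <- read_edge_list(config$inputs$cci, "cci")
    cpi <- read_edge_list(config$inputs$cpi, "cpi")
    ppi <- read_edge_list(config$inputs$ppi, "ppi")
    chems <- readLines(config$inputs$chemicals)
    enzs <- readLines(config$inputs$enzymes)
    full <- build_hetero_network(cci, cpi, ppi, chems, enzs)
    pruned <- drop_isolated(full)
    write_hetero_network(pruned$network, file.path(config$out_dir, "network"))
    utils::write.table(data.frame(removed = pruned$removed),
                       file.path(config$out_dir, "removed_nodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pruned$network
  })

  emb <- stage("embed", {
    cfg <- rwr_config(config$embedding$restart, config$embedding$tol,
                      config$embedding$max_iter)
    V <- diffusion_states(net, cfg)
    model <- mashup_embed(V, d = min(config$embedding$dim, nrow(V)),
                          method = config$embedding$method,
                          seed = config$seed)
    write_embedding(model, net$nodes$kind,
                    file.path(config$out_dir, "embedding.tsv"))
    model
  })

  metrics <- stage("cv", {
    labels <- read_label_table(config$inputs$labels)
    labels <- labels[net$nodes$id, , drop = FALSE]
    mod <- config$model
    k <- mod$k %||% ncol(labels)
    cfg <- ml_config(mod$method, k = k, M = mod$M, base = config_base(mod),
                     threshold = mod$threshold, seed = config$seed)
    plan <- make_cv_plan(nrow(labels), folds = config$evaluation$folds,
                         seed = config$seed)
    report <- cross_validate(emb$X, labels, cfg, plan)
    df <- cbind(data.frame(seed = config$seed, n = report$n, m = report$m),
                round(metrics_as_row(report), 6))
    utils::write.table(df, file.path(config$out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report
  })

  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  manifest$warnings <- warn_count
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(out_dir = config$out_dir, metrics = metrics,
                 manifest = manifest))
}
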