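#' Assemble a full-run configuration
#'
#' Collects the stage configurations for [run_pipeline()]. Any component
#' can be omitted to use its defaults. Round-trips losslessly through
#' YAML via [read_run_config()].
#'
#' @param sim [sim_config()] arguments as a list, or `NULL` with `input` a
#'   dataset directory for [read_dataset()].
#' @param input Optional MTX directory read instead of simulating.
#' @param preprocess List of [preprocess()] arguments.
#' @param net List of [net_config()] arguments (minus `input_dim`,
#'   `n_domains`, which come from the data).
#' @param train List of [train_config()] arguments.
#' @param seed Global seed applied to every stage.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = list(), input = NULL, preprocess = list(),
                       net = list(), train = list(), seed = 1L,
                       out_dir = tempfile("sctwin_run")) {
  structure(list(sim = sim, input = input, preprocess = preprocess,
                 net = net, train = train, seed = as.integer(seed),
                 out_dir = out_dir), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys match [run_config()]
#'   arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Run the full pipeline
#'
#' Simulate (or read) counts, preprocess, train, embed, score data
#' integration against a PCA baseline, and run leave-one-batch-out label
#' transfer. Writes `report.csv`, `transfer.csv`, `transfer_overall.csv`,
#' `history.csv`, `embedding.csv` and `run_info.json` (stamped with the
#' config hash and seed) to `out_dir`.
#'
#' @param cfg A [run_config()].
#' @param verbose Report stage progress?
#' @return Invisibly, a list with the trained checkpoint, embedding and
#'   the three reports.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (verbose) message("[sctwin] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(unclass(cfg))

  sce <- if (!is.null(cfg$input)) {
    say("reading ", cfg$input)
    stage("read", read_dataset(cfg$input))
  } else {
    say("simulating counts")
    stage("simulate",
          simulate_counts(do.call(sim_config,
                                  c(cfg$sim, list(seed = cfg$seed)))))
  }
  say("preprocessing")
  prep <- stage("preprocess", do.call(preprocess,
                                      c(list(sce), cfg$preprocess)))
  D <- nlevels(factor(SummarizedExperiment::colData(prep)$batch))
  ncfg <- stage("net", do.call(net_config,
                               c(list(input_dim = nrow(prep),
                                      n_domains = D), cfg$net)))
  tcfg <- stage("train-config",
                do.call(train_config, c(cfg$train, list(seed = cfg$seed))))
  say("training (up to ", tcfg$epochs, " epochs)")
  ckpt <- stage("train", fit_sctwin(prep, ncfg, tcfg, verbose = verbose))
  say("embedding")
  Z <- stage("embed", embed_cells(prep, ckpt))

  cd <- SummarizedExperiment::colData(prep)
  reports <- NULL
  transfer <- NULL
  overall <- NULL
  if (!is.null(cd$cell_type)) {
    say("scoring data integration (vs PCA baseline)")
    Zp <- pca_embed(prep)
    reports <- stage("eval-integration", aggregate_integration(rbind(
      evaluate_integration(Z, cd$batch, cd$cell_type, run = "sctwin",
                           seed = cfg$seed),
      evaluate_integration(Zp, cd$batch, cd$cell_type, run = "pca",
                           seed = cfg$seed))))
    say("label transfer (leave one batch out)")
    transfer <- stage("label-transfer",
                      evaluate_transfer(Z, cd$cell_type, cd$batch,
                                        run = "sctwin", seed = cfg$seed))
    overall <- aggregate_transfer(transfer)$overall
    utils::write.csv(reports, file.path(cfg$out_dir, "report.csv"),
                     row.names = FALSE)
    utils::write.csv(transfer, file.path(cfg$out_dir, "transfer.csv"),
                     row.names = FALSE)
    utils::write.csv(overall,
                     file.path(cfg$out_dir, "transfer_overall.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(ckpt$history, file.path(cfg$out_dir, "history.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(cell_id = rownames(Z), Z),
                   file.path(cfg$out_dir, "embedding.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(config_hash = hash, seed = cfg$seed,
                            best_epoch = ckpt$best_epoch,
                            n_cells = ncol(prep), n_genes = nrow(prep)),
                       file.path(cfg$out_dir, "run_info.json"),
                       auto_unbox = TRUE)
  invisible(list(checkpoint = ckpt, embedding = Z, integration = reports,
                 transfer = transfer, transfer_overall = overall))
}
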