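# Config-driven orchestration of the full analysis loop: load or simulate
# -> validate -> train initial SOMs -> flag outliers -> apply policy ->
# retrain -> network input maps to the output map -> unit clusters ->
# conditional queries -> figures -> report. Every stage derives its own
# seed from the one global seed so runs are reproducible end to end and
# stages can be re-run in isolation.

PIPELINE_DEFAULTS <- list(
  som = list(epochs = 30L, grid = "auto", init = "pca"),
  outliers = list(threshold = 3.5, policy = "paper_preset"),
  network = list(radius = 1.0),
  query_defaults = list(sigma = 0.1, q = 0.8)
)

#' Deterministic per-stage seed derived from the global seed
#'
#' Hashes the stage name into the global seed so each pipeline stage has
#' its own reproducible RNG stream.
#'
#' @param global_seed integer global seed.
#' @param stage stage name.
#' @return Integer seed in [1, 2^31 - 2].
#' @export
stage_seed <- function(global_seed, stage) {
  h <- as.double(global_seed) %% 2147483647
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 2147483647
  as.integer(h + 1)
}

known_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "))
  }
}

#' Parse a pipeline run configuration from YAML
#'
#' Unknown keys are errors (strict mode); omitted settings receive the
#' package defaults (SOM epochs 30, outlier threshold 3.5 with the bundled
#' preset policy and 97.5th-percentile winsorization, association radius
#' 1, query sigma 0.1 and region quantile 0.8), which are echoed back in
#' the parsed object and in the run report.
#'
#' @param path YAML file. Top-level keys: `seed` (required), `out_dir`,
#'   one of `synthetic` (`paper_like: true` or generator settings) or
#'   `input` (`data`/`meta` paths), plus optional `som`, `outliers`,
#'   `network`, `queries`.
#' @return An object of class `run_config`.
#' @export
parse_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_keys(raw, c("seed", "out_dir", "synthetic", "input", "som",
                    "outliers", "network", "queries"), "config")
  if (is.null(raw$seed)) stop("config must set a seed")
  if (is.null(raw$synthetic) && is.null(raw$input)) {
    stop("config must set either 'synthetic' or 'input'")
  }
  if (!is.null(raw$synthetic)) {
    known_keys(raw$synthetic, c("paper_like", "seed", "areas_per_region",
                                "noise_sd"), "synthetic")
  }
  if (!is.null(raw$input)) {
    known_keys(raw$input, c("data", "meta"), "input")
    if (is.null(raw$input$data) || is.null(raw$input$meta)) {
      stop("input requires 'data' and 'meta' paths")
    }
  }
  som <- utils::modifyList(PIPELINE_DEFAULTS$som, raw$som %||% list())
  known_keys(som, c("epochs", "grid", "init"), "som")
  outliers <- utils::modifyList(PIPELINE_DEFAULTS$outliers,
                                raw$outliers %||% list())
  known_keys(outliers, c("threshold", "policy"), "outliers")
  if (is.list(outliers$policy)) {
    known_keys(outliers$policy, c("drop", "winsorize", "keep", "percentile"),
               "outliers$policy")
  }
  network <- utils::modifyList(PIPELINE_DEFAULTS$network,
                               raw$network %||% list())
  known_keys(network, "radius", "network")
  queries <- lapply(raw$queries %||% list(), function(q) {
    known_keys(q, c("direction", "constraints", "sigma", "q", "report"),
               "query")
    if (is.null(q$direction) || is.null(q$constraints)) {
      stop("each query needs 'direction' and 'constraints'")
    }
    utils::modifyList(PIPELINE_DEFAULTS$query_defaults, q)
  })
  structure(
    list(seed = as.integer(raw$seed), out_dir = raw$out_dir,
         synthetic = raw$synthetic, input = raw$input, som = som,
         outliers = outliers, network = network, queries = queries),
    class = "run_config")
}

resolve_policy <- function(policy_cfg) {
  if (identical(policy_cfg, "paper_preset")) return(paper_preset_policy())
  if (identical(policy_cfg, "none")) return(outlier_policy())
  winz <- lapply(policy_cfg$winsorize %||% list(), unlist)
  outlier_policy(
    drop = as.character(policy_cfg$drop %||% character(0)),
    winsorize = winz,
    keep = as.character(policy_cfg$keep %||% character(0)),
    percentile = policy_cfg$percentile %||% 97.5
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_som_params <- function(cfg_som, seed) {
  som_params(
    grid = if (identical(cfg_som$grid, "auto")) NULL else
      as.integer(unlist(cfg_som$grid)),
    epochs = cfg_som$epochs, init = cfg_som$init, seed = seed
  )
}

#' Run the full analysis pipeline
#'
#' Executes every stage of the analysis loop from one configuration and
#' persists all artifacts (MMS CSV and metadata, initial and retrained SOM
#' JSON, outlier report, query reports, SVG figures, run report and
#' manifest) under the output directory. Identical configuration and seed
#' reproduce identical artifacts. A stage failure aborts with the stage
#' name; artifacts from completed stages remain on disk.
#'
#' @param config a [parse_config()] result or a path to a YAML config.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @return The run report (invisibly): see [write_report()].
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- parse_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory set")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(name) message("[somnet] stage: ", name)
  stage <- function(name, expr) {
    log_stage(name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  truth <- NULL
  tables <- stage("load", {
    if (!is.null(config$synthetic)) {
      sc <- if (isTRUE(config$synthetic$paper_like)) {
        paper_like_config(seed = config$synthetic$seed %||%
                            stage_seed(config$seed, "simulate"))
      } else {
        synth_config(
          areas_per_region = unlist(config$synthetic$areas_per_region %||%
            c(Catalonia = 74L, Biscay = 19L, Gipuzkoa = 13L)),
          seed = config$synthetic$seed %||% stage_seed(config$seed, "simulate"),
          noise_sd = config$synthetic$noise_sd %||% 0.1
        )
      }
      sys <- generate_system(sc)
      truth <<- sys$truth
      write_mms(sys$tables, file.path(out_dir, "mms.csv"))
      write_mms_metadata(file.path(out_dir, "metadata.json"))
      sys$tables
    } else {
      if (!file.exists(config$input$data)) {
        stop("input data file not found: ", config$input$data)
      }
      load_mms(config$input$data, config$input$meta)
    }
  })

  validation <- stage("validate", validate_mms(tables))

  initial_soms <- stage("train-initial", {
    lapply(tables, function(tab) {
      params <- make_som_params(
        config$som, stage_seed(config$seed, paste0("initial-", tab$dataset)))
      som <- train_som(normalize_mms(tab), params)
      write_som(som, file.path(out_dir,
                               paste0("som_initial_", tab$dataset, ".json")))
      som
    })
  })

  outlier_reports <- stage("flag-outliers", {
    reps <- lapply(tables, flag_outliers,
                   threshold = config$outliers$threshold)
    jsonlite::write_json(
      lapply(reps, function(r) list(dataset = r$dataset,
                                    threshold = r$threshold,
                                    entries = r$entries,
                                    skipped = r$skipped)),
      file.path(out_dir, "outliers.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
    reps
  })

  policy <- resolve_policy(config$outliers$policy)
  processed <- stage("apply-policy", apply_policy(tables, policy))

  soms <- stage("retrain", {
    lapply(processed, function(tab) {
      params <- make_som_params(
        config$som, stage_seed(config$seed, paste0("retrain-", tab$dataset)))
      som <- train_som(normalize_mms(tab), params)
      write_som(som, file.path(out_dir, paste0("som_", tab$dataset, ".json")))
      som
    })
  })

  networks <- stage("network", {
    input_ds <- setdiff(names(soms), "USE")
    nets <- lapply(soms[input_ds], build_association,
                   output_som = soms$USE, radius = config$network$radius)
    names(nets) <- input_ds
    nets
  })

  clusters <- stage("unit-clusters", lapply(soms, unit_clusters))

  query_results <- stage("queries", {
    lapply(seq_along(config$queries), function(i) {
      q <- config$queries[[i]]
      qq <- conditional_query(
        direction = q$direction,
        constraints = unlist(q$constraints),
        sigma = q$sigma, q = q$q,
        report = if (!is.null(q$report)) unlist(q$report))
      res <- run_query(networks, soms, qq)
      for (ds in names(res$fields)) {
        plot_weight_field(res$fields[[ds]], soms[[ds]],
                          file.path(out_dir,
                                    sprintf("fig_query%d_%s_weights.svg",
                                            i, ds)))
      }
      list(query = q, estimates = res$estimates,
           fields = lapply(res$fields, function(f) {
             list(target = f$target_dataset, weights = f$weights,
                  mask = f$mask, quantile = f$quantile)
           }))
    })
  })

  figures <- stage("figures", {
    figs <- character(0)
    for (ds in names(soms)) {
      f1 <- sprintf("fig_%s_planes.svg", ds)
      f2 <- sprintf("fig_%s_labels.svg", ds)
      f3 <- sprintf("fig_%s_glyphs.svg", ds)
      plot_component_planes(soms[[ds]], path = file.path(out_dir, f1))
      plot_label_map(soms[[ds]], file.path(out_dir, f2))
      suppressWarnings(plot_star_glyphs(soms[[ds]], file.path(out_dir, f3)))
      figs <- c(figs, f1, f2, f3)
    }
    figs <- c(figs, vapply(seq_along(query_results), function(i) {
      sprintf("fig_query%d_%s_weights.svg", i,
              names(query_results[[i]]$fields))
    }, ""))
    figs
  })

  report <- stage("report", {
    write_report(
      list(config = config, validation = validation,
           initial_soms = initial_soms, outlier_reports = outlier_reports,
           policy = policy, soms = soms, networks = networks,
           clusters = clusters, query_results = query_results,
           figures = figures, truth = truth),
      out_dir)
  })
  invisible(report)
}

#' Write the run report (JSON + Markdown) and manifest
#'
#' The JSON report carries the effective parameters, per-SOM quality
#' metrics before and after outlier processing, the outlier table, unit
#' cluster listing, per-query estimates with their qualitative categories,
#' and figure file names. The Markdown file is a human-readable summary of
#' the same content. The manifest lists every artifact file.
#'
#' @param artifacts list of run artifacts assembled by
#'   [run_full_analysis()].
#' @param out_dir run directory.
#' @return The report list, invisibly.
#' @export
write_report <- function(artifacts, out_dir) {
  cfg <- artifacts$config
  som_quality <- function(soms) {
    lapply(soms, function(s) list(
      grid = c(s$grid$rows, s$grid$cols),
      n_areas = length(s$assignments),
      quantization_error = s$quality$quantization_error,
      topographic_error = s$quality$topographic_error))
  }
  report <- list(
    parameters = list(
      seed = cfg$seed, som = cfg$som, outliers = cfg$outliers[
        setdiff(names(cfg$outliers), "policy")],
      policy = list(drop = artifacts$policy$drop,
                    winsorize = artifacts$policy$winsorize,
                    percentile = artifacts$policy$percentile),
      network = cfg$network),
    validation = list(ok = artifacts$validation$ok,
                      n_indicators = artifacts$validation$n_indicators,
                      checks = artifacts$validation$checks),
    initial_soms = som_quality(artifacts$initial_soms),
    outliers = lapply(artifacts$outlier_reports, function(r) r$entries),
    soms = som_quality(artifacts$soms),
    networks = lapply(artifacts$networks, function(n) list(
      input = n$input_dataset, output = n$output_dataset,
      radius = n$radius, supported_rows = sum(n$support))),
    unit_clusters = artifacts$clusters,
    queries = lapply(artifacts$query_results, function(qr) list(
      query = qr$query,
      estimates = qr$estimates)),
    figures = artifacts$figures
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  if (!is.null(artifacts$truth)) {
    jsonlite::write_json(
      list(region = as.list(artifacts$truth$region),
           outliers = artifacts$truth$outliers,
           seed = artifacts$truth$seed),
      file.path(out_dir, "ground_truth.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  md <- c("# Analysis run report", "",
          sprintf("- seed: %d", cfg$seed),
          sprintf("- datasets: %s", paste(names(artifacts$soms),
                                          collapse = ", ")),
          sprintf("- areas after outlier policy: %d",
                  length(artifacts$soms[[1L]]$assignments)), "",
          "## SOM quality (retrained)", "")
  for (ds in names(artifacts$soms)) {
    s <- artifacts$soms[[ds]]
    md <- c(md, sprintf("- %s: %dx%d grid, QE %.4f, TE %.4f", ds,
                        s$grid$rows, s$grid$cols,
                        s$quality$quantization_error,
                        s$quality$topographic_error))
  }
  md <- c(md, "", "## Outlier flags", "")
  for (ds in names(artifacts$outlier_reports)) {
    e <- artifacts$outlier_reports[[ds]]$entries
    md <- c(md, sprintf("- %s: %d flag(s)%s", ds, nrow(e),
                        if (nrow(e)) paste0(" (",
                          paste(unique(e$label), collapse = ", "), ")")
                        else ""))
  }
  md <- c(md, "", "## Queries", "")
  for (qr in artifacts$query_results) {
    md <- c(md, sprintf("- %s on %s:", qr$query$direction,
                        paste(names(qr$query$constraints), "=",
                              unlist(qr$query$constraints),
                              collapse = ", ")))
    e <- qr$estimates
    md <- c(md, sprintf("    - %s = %.4g (%s)", e$code, e$value, e$category))
  }
  writeLines(md, file.path(out_dir, "report.md"), useBytes = TRUE)

  manifest <- sort(setdiff(list.files(out_dir), "manifest.json"))
  jsonlite::write_json(list(files = manifest),
                       file.path(out_dir, "manifest.json"), pretty = TRUE)
  invisible(report)
}
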