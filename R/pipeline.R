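# End-to-end pipeline: ingest -> dedupe -> exclusions -> sufficiency ->
# reconstitute -> evaluate -> report, with a run manifest for reproducibility.

#' Build a run configuration
#'
#' Every field has a CLI flag equivalent; on conflict the CLI wins. `input`
#' and `generator` are mutually exclusive ways to obtain the raw records.
#'
#' @param input Path to a product CSV (read with [read_products()]), or `NULL`
#'   to generate synthetically.
#' @param generator A [generator_config()] used when `input` is `NULL`.
#' @param models Subset of `c("SEARO", "CWO_phase3")`.
#' @param searo_path,cwo_path Threshold-table files (defaults: shipped).
#' @param out_dir Output directory (created if needed).
#' @param digits,policy Report rounding (see [round_pct()]).
#' @param nns_counts,gate_unknown Engine conventions (see [evaluate_model()]).
#' @param seed Seed recorded in the manifest (and used for generation).
#' @return List of class `run_config`.
#' @export
run_config <- function(input = NULL, generator = NULL,
                       models = c("SEARO", "CWO_phase3"),
                       searo_path = NULL, cwo_path = NULL,
                       out_dir = tempfile("fopwarn_run_"),
                       digits = 1, policy = "round",
                       nns_counts = "label", gate_unknown = "skip",
                       seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(input) && is.null(generator)) generator <- generator_config(seed = seed)
  if (!is.null(input) && !file.exists(input)) {
    stop(sprintf("input file does not exist: %s", input), call. = FALSE)
  }
  structure(list(input = input, generator = generator, models = models,
                 searo_path = searo_path, cwo_path = cwo_path,
                 out_dir = out_dir, digits = digits, policy = policy,
                 nns_counts = nns_counts, gate_unknown = gate_unknown,
                 seed = as.integer(seed)),
            class = "run_config")
}

load_tables <- function(config) {
  tabs <- list()
  if ("SEARO" %in% config$models) {
    tabs <- c(tabs, list(if (is.null(config$searo_path)) searo_thresholds()
                         else searo_thresholds(config$searo_path)))
  }
  if ("CWO_phase3" %in% config$models) {
    tabs <- c(tabs, list(if (is.null(config$cwo_path)) cwo_thresholds()
                         else cwo_thresholds(config$cwo_path)))
  }
  tabs
}

#' Run the full analysis pipeline
#'
#' Executes the exclusion cascade and both engines, writes the retained
#' products, per-product results, coverage report, label distributions,
#' exclusion ledger and a JSON manifest to `config$out_dir`, and returns the
#' in-memory objects. Any stage failure aborts the run and removes partial
#' outputs. Determinism: the same config and seed reproduce every artifact.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage logging.
#' @return `list(report, ledger, results, products, distributions, manifest)`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  taxonomy <- searo_taxonomy()
  tables <- load_tables(config)
  v <- validate_thresholds(tables, taxonomy)
  if (!attr(v, "valid")) {
    stop(paste(c("threshold validation failed:", v), collapse = "\n  "), call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(config$out_dir, recursive = TRUE), add = TRUE)

  say("stage ingest")
  raw <- if (!is.null(config$input)) {
    read_products(config$input)
  } else {
    generate_products(config$generator)
  }
  say("stage filter (%d raw records)", nrow(raw))
  flt <- filter_products(raw, tables, taxonomy)
  ledger_check(flt$ledger)
  say("stage evaluate (%d analyzable)", nrow(flt$products))
  results <- evaluate_batch(flt$products, tables, taxonomy,
                            nns_counts = config$nns_counts,
                            gate_unknown = config$gate_unknown)
  say("stage report")
  # n_total counts all category-assigned products, analyzable or not
  dd <- deduplicate(raw)
  assigned <- apply_exclusions(dd$records, taxonomy)$records
  report <- build_report(results, assigned, taxonomy,
                         digits = config$digits, policy = config$policy)
  dists <- lapply(stats::setNames(nm = unique(results$model)), function(m) {
    label_distribution(results[results$model == m, ], flt$products,
                       taxonomy = taxonomy, digits = config$digits,
                       policy = config$policy)
  })

  utils::write.csv(flt$products, file.path(config$out_dir, "products.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(results, file.path(config$out_dir, "results.csv"),
                   row.names = FALSE)
  write_report(report, file.path(config$out_dir, "report.csv"))
  for (m in names(dists)) {
    utils::write.csv(dists[[m]],
                     file.path(config$out_dir, sprintf("labels_%s.csv", m)),
                     row.names = FALSE)
  }
  write_ledger(flt$ledger, file.path(config$out_dir, "ledger.csv"))

  cfg_json <- file.path(config$out_dir, "config.json")
  cfg_ser <- config
  cfg_ser$out_dir <- NULL  # hash covers the reproducible inputs only
  cfg_ser$generator <- if (is.null(config$generator)) NULL else {
    g <- config$generator
    g$tables <- NULL; g$taxonomy <- NULL
    g
  }
  jsonlite::write_json(cfg_ser, cfg_json, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("fopwarn")),
    r_version = R.version.string,
    seed = config$seed,
    models = config$models,
    config_md5 = unname(tools::md5sum(cfg_json)),
    ledger = as.list(flt$ledger)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("ledger: %s", paste(sprintf("%s=%d", names(flt$ledger), flt$ledger),
                          collapse = " "))
  ok <- TRUE
  list(report = report, ledger = flt$ledger, results = results,
       products = flt$products, distributions = dists, manifest = manifest)
}

#' Command-line entry point
#'
#' Subcommands: `run` (pipeline on a CSV or generated data), `generate`
#' (write a synthetic database), `calibrate` (write a calibrated generator
#' shift table), `validate-thresholds`, `fixtures` (small canned datasets).
#' Invoke via `Rscript -e 'fopwarn::fopwarn_main()' <subcommand> [options]`.
#'
#' @param args Command-line arguments (default: those after `--args`).
#' @return Exit status, invisibly (0 on success).
#' @export
fopwarn_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: fopwarn <run|generate|calibrate|validate-thresholds|fixtures> [options]")
    return(invisible(1L))
  }
  cmd <- args[1]; rest <- args[-1]
  opts <- optparse::OptionParser(option_list = list(
    optparse::make_option("--input", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = "fopwarn_out"),
    optparse::make_option("--models", type = "character", default = "SEARO,CWO_phase3"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--n", type = "integer", default = 41255L),
    optparse::make_option("--digits", type = "integer", default = 1L),
    optparse::make_option("--policy", type = "character", default = "round"),
    optparse::make_option("--nns-counts", dest = "nns_counts",
                          type = "character", default = "label"),
    optparse::make_option("--gate-unknown", dest = "gate_unknown",
                          type = "character", default = "skip"),
    optparse::make_option("--calibrated", action = "store_true", default = FALSE)
  ))
  o <- optparse::parse_args(opts, args = rest)
  status <- 0L
  switch(cmd,
    "run" = {
      gen <- NULL
      if (is.null(o$input)) {
        gen <- generator_config(seed = o$seed, n_products = o$n)
        if (o$calibrated) gen <- calibrate_to_table1(config = gen)
      }
      cfg <- run_config(input = o$input, generator = gen,
                        models = strsplit(o$models, ",")[[1]],
                        out_dir = o$out, digits = o$digits, policy = o$policy,
                        nns_counts = o$nns_counts, gate_unknown = o$gate_unknown,
                        seed = o$seed)
      res <- run_pipeline(cfg)
      ledger_check(res$ledger)
    },
    "generate" = {
      gen <- generator_config(seed = o$seed, n_products = o$n)
      if (o$calibrated) gen <- calibrate_to_table1(config = gen)
      write_products(generate_products(gen), o$out)
    },
    "calibrate" = {
      gen <- calibrate_to_table1(config = generator_config(seed = o$seed))
      utils::write.csv(data.frame(category_code = names(gen$shifts),
                                  shift = unlist(gen$shifts),
                                  mode = unlist(gen$modes[names(gen$shifts)])),
                       o$out, row.names = FALSE)
    },
    "validate-thresholds" = {
      v <- validate_thresholds(list(searo_thresholds(), cwo_thresholds()))
      if (length(v)) { message(paste(v, collapse = "\n")); status <- 1L }
      else message("threshold tables valid")
    },
    "fixtures" = {
      gen <- generator_config(seed = o$seed, n_products = 500L)
      write_products(generate_products(gen), o$out)
    },
    {
      message(sprintf("unknown subcommand: %s", cmd)); status <- 2L
    }
  )
  invisible(status)
}
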