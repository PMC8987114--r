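# File-level pipeline orchestration: simulate a dataset to disk, run the
# full analysis into an output directory with a manifest, and the thin
# command-line wrapper installed under inst/scripts.

#' Default pipeline configuration
#'
#' All thresholds the pipeline uses, with their documented defaults:
#' soft-threshold power 5, scale-free target R^2 0.80, minimum module size
#' 30, lfdr cutoff 0.05, differential-expression and enrichment alpha 0.05.
#'
#' @param ... Named overrides of any default.
#' @return Named list of configuration values.
#' @export
dcc_config <- function(...) {
  cfg <- list(
    expression = NULL, traits = NULL, gmt = NULL, out_dir = "dccnet_out",
    power = 5L, auto_power = FALSE, candidate_powers = 1:20, target_r2 = 0.80,
    min_module_size = 30L, cut_fraction = 0.99, sample_cut_quantile = 0.99,
    lfdr_cut = 0.05, dge_alpha = 0.05, enrich_alpha = 0.05,
    welch = FALSE, allow_single = FALSE, seed = 1L,
    # simulate subcommand
    n_genes = 300L, module_sizes = rep(50L, 4L), rho = 0.7,
    n_samples = c(150L, 80L), trait_modules = c(1L, 2L),
    trait_effects = c(1, -1), n_switch_pairs = 0L, switch_module = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$lfdr_cut > 0, cfg$lfdr_cut < 1,
            cfg$dge_alpha > 0, cfg$dge_alpha < 1, cfg$power >= 1)
  cfg
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file whose keys match [dcc_config()] fields.
#' @return Configuration list with defaults filled in.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(dcc_config, yaml::read_yaml(path))
}

#' Simulate a dataset to disk
#'
#' Writes `expression.tsv`, `traits.tsv` and `truth.json` for the
#' configured synthetic design.
#'
#' @param config Configuration list ([dcc_config()]).
#' @return Invisibly, the paths written.
#' @export
dcc_simulate <- function(config = dcc_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_expression(
    n_genes = config$n_genes, module_sizes = config$module_sizes,
    rho = config$rho, n_samples = config$n_samples,
    trait_modules = config$trait_modules, trait_effects = config$trait_effects,
    n_switch_pairs = config$n_switch_pairs, switch_module = config$switch_module,
    seed = config$seed)
  paths <- file.path(config$out_dir, c("expression.tsv", "traits.tsv", "truth.json"))
  write_expression(sim$expr, paths[1L])
  utils::write.table(
    data.frame(sample = names(sim$traits), label = sim$traits),
    paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(module_of_gene = as.list(truth$module_of_gene),
         trait_modules = truth$trait_modules,
         trait_effects = truth$trait_effects,
         switch_pairs = truth$switch_pairs,
         params = truth$params),
    paths[3L], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("simulated dataset written to ", config$out_dir, " (seed ", config$seed, ")")
  invisible(paths)
}

#' Run the full analysis into an output directory
#'
#' Loads the configured expression and trait tables, fits [dccnet()], and
#' writes: module assignment TSV, module-trait TSV, one
#' differential-correlation TSV and one switched-pair edge TSV per key
#' module, hub ranking TSV, differential-expression TSV, optional
#' enrichment TSV (when a GMT is configured), and a `manifest.json` with
#' the configuration echo, per-file MD5 checksums and captured warnings.
#'
#' @param config Configuration list ([dcc_config()]); `expression` and
#'   `traits` must point at existing files.
#' @return Invisibly, the fitted `dccnet` object.
#' @export
dcc_run <- function(config = dcc_config()) {
  for (f in c("expression", "traits")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      stop("required input missing: ", f, " = ",
           if (is.null(config[[f]])) "<unset>" else config[[f]])
    }
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  warns <- character(0)
  fit <- withCallingHandlers({
    expr <- read_expression(config$expression)
    traits <- read_traits(config$traits, expr)
    set.seed(as.integer(config$seed))
    dccnet(expr, traits,
           power = if (isTRUE(config$auto_power)) NULL else config$power,
           candidate_powers = config$candidate_powers,
           target_r2 = config$target_r2,
           min_module_size = config$min_module_size,
           cut_fraction = config$cut_fraction,
           sample_cut_quantile = config$sample_cut_quantile,
           lfdr_cut = config$lfdr_cut, dge_alpha = config$dge_alpha,
           welch = config$welch, allow_single = config$allow_single)
  }, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  tsv <- function(df, name) {
    path <- file.path(out, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- c(
    tsv(data.frame(gene = names(fit$modules), module = fit$modules),
        "modules.tsv"),
    tsv(fit$module_trait, "module_trait.tsv"),
    tsv(fit$dge, "differential_expression.tsv"),
    tsv(fit$hubs, "hubs.tsv")
  )
  for (lab in names(fit$diffcorr)) {
    files <- c(files,
               tsv(fit$diffcorr[[lab]], sprintf("diffcorr_%s.tsv", lab)))
    if (nrow(fit$switched[[lab]])) {
      p <- file.path(out, sprintf("switched_%s.tsv", lab))
      write_network(fit$switched[[lab]], p, format = "edge_tsv")
      files <- c(files, p)
    }
  }
  if (!is.null(config$gmt) && file.exists(config$gmt)) {
    sets <- read_gmt(config$gmt)
    key_genes <- unique(names(fit$modules)[fit$modules %in% unlist(fit$key_modules)])
    et <- enrich(key_genes, names(fit$modules), sets, alpha = config$enrich_alpha)
    files <- c(files, tsv(et, "enrichment.tsv"))
  }
  manifest <- list(
    tool = paste0("dccnet ", as.character(utils::packageVersion("dccnet"))),
    config = config[!vapply(config, is.null, TRUE)],
    seed = config$seed,
    key_modules = fit$key_modules,
    checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files))),
    warnings = warns,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fit)
}

#' Command-line entry point
#'
#' Thin wrapper used by the installed `scripts/dccnet.R` launcher.
#' Subcommands: `simulate` and `run-all`; arguments are `--key value` pairs
#' matching [dcc_config()] fields (`--config file.yaml` loads a YAML first).
#' Exit status: 0 on success, 2 on validation errors, 1 on runtime errors.
#'
#' @param args Character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Integer exit status, invisibly.
#' @export
dccnet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: dccnet.R <simulate|run-all> [--config cfg.yaml] [--key value ...]"
  if (!length(args) || args[1L] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(0L))
  }
  cmd <- args[1L]
  if (!cmd %in% c("simulate", "run-all")) {
    message("unknown subcommand '", cmd, "'\n", usage)
    return(invisible(2L))
  }
  rest <- args[-1L]
  if (length(rest) %% 2L != 0L) {
    message("arguments must come as --key value pairs")
    return(invisible(2L))
  }
  keys <- sub("^--", "", rest[c(TRUE, FALSE)])
  vals <- rest[c(FALSE, TRUE)]
  over <- list()
  for (i in seq_along(keys)) {
    v <- vals[i]
    num <- suppressWarnings(as.numeric(strsplit(v, ",", fixed = TRUE)[[1L]]))
    over[[keys[i]]] <- if (!anyNA(num)) num else
      if (v %in% c("true", "TRUE")) TRUE else
        if (v %in% c("false", "FALSE")) FALSE else v
  }
  status <- tryCatch({
    cfg <- if (!is.null(over$config)) read_config(over$config) else dcc_config()
    over$config <- NULL
    if (length(over)) cfg <- do.call(dcc_config, utils::modifyList(cfg, over))
    if (cmd == "simulate") dcc_simulate(cfg) else dcc_run(cfg)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("not found|missing|must|unknown|outside|needs", conditionMessage(e))) 2L else 1L
  })
  invisible(status)
}
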