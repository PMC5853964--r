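## One-command orchestration: bin/read -> normalize -> lift -> call ->
## flag -> refine -> gene content -> homoeologue intersection, with
## optional genotyping/segregation/granule stages, TSV/JSON/PNG outputs
## and a machine-readable run report.

#' Assemble a pipeline configuration
#'
#' A configuration is a plain list; this helper validates it and fills
#' defaults. Inputs come either from files (`mutant`, `wildtype` paths:
#' bedGraph coverage) or from the built-in simulator
#' (`simulate = list(lines = c("A1", "D4"), seed = 1, ...)` using
#' [paragon_layout()] or a supplied `spec`).
#'
#' @param out_dir output directory (created if needed).
#' @param mutant named character vector of per-line bedGraph paths
#'   (file-driven runs).
#' @param wildtype wild-type bedGraph path (file-driven runs).
#' @param simulate list of simulator options (simulation-driven runs):
#'   `lines`, `seed`, optionally `spec`, `params`
#'   ([coverage_sim_params()] fields), `genes` (logical: also simulate
#'   gene models and refine/intersect).
#' @param parts_map path to a parts-map TSV, or a data frame; `NULL`
#'   skips the lift.
#' @param params [caller_params()] or a list of overrides.
#' @param plots write per-chromosome coverage PNGs (default `TRUE`).
#' @param seed RNG seed recorded and applied at run start.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, mutant = NULL, wildtype = NULL,
                            simulate = NULL, parts_map = NULL,
                            params = caller_params(), plots = TRUE, seed = 1L) {
  if (is.null(simulate) && (is.null(mutant) || is.null(wildtype)))
    stop("either `simulate` or both `mutant` and `wildtype` must be given",
         call. = FALSE)
  if (!inherits(params, "caller_params")) params <- do.call(caller_params, params)
  structure(list(out_dir = out_dir, mutant = mutant, wildtype = wildtype,
                 simulate = simulate, parts_map = parts_map, params = params,
                 plots = plots, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml/.yml or .json", call. = FALSE)
  if (!is.null(cfg$params)) cfg$params <- do.call(caller_params, cfg$params)
  do.call(pipeline_config, cfg)
}

#' Run the deletion-discovery pipeline
#'
#' Executes bin/read, normalize, lift (when a parts map is available),
#' call, flag-shared (when two or more lines), and, for
#' simulation-driven runs with gene models, refine/gene-content/
#' homoeologue-intersection. Writes per-line normalized-coverage TSVs,
#' a combined calls TSV, per-line coverage plots, and a JSON run report.
#' Identical configuration and seed give identical outputs.
#'
#' @param config a [pipeline_config()] or path to a YAML/JSON file.
#' @return list of class `run_report`: per-stage records (inputs,
#'   parameters, outputs, counts, warnings), plus `calls`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  report <- list(tool = paste("delscan", as.character(utils::packageVersion("delscan"))),
                 seed = config$seed, stages = list())
  stage <- function(name, ...) {
    report$stages[[name]] <<- list(...)
  }
  params <- config$params
  norms <- list()
  parts <- NULL
  sim_genes <- NULL
  spec <- NULL

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    spec <- sim$spec %||% paragon_layout()
    if (!inherits(spec, "genome_spec")) spec <- do.call(genome_spec, spec)
    lines <- sim$lines %||% unique(spec$deletions$line_id)
    sp <- do.call(coverage_sim_params, sim$params %||% list())
    parts <- parts_map(spec)
    for (i in seq_along(lines)) {
      pair <- simulate_coverage_pair(spec, sp, line = lines[i],
                                     seed = config$seed + i)
      norms[[lines[i]]] <- normalize_coverage(pair$mutant, pair$wildtype)
    }
    stage("simulate", lines = lines, mean_reads_per_bin = sp$mean_reads_per_bin,
          residual_in_deletion = sp$residual_in_deletion)
    if (isTRUE(sim$genes)) {
      sim_genes <- simulate_gene_models(spec, seed = config$seed)
      stage("simulate_genes", n_genes = nrow(sim_genes$genes),
            n_pairs = nrow(sim_genes$map))
    }
  } else {
    wt <- read_coverage(config$wildtype, "bedgraph", line_id = "wildtype")
    for (i in seq_along(config$mutant)) {
      id <- names(config$mutant)[i] %||% paste0("line", i)
      mut <- read_coverage(config$mutant[i], "bedgraph", line_id = id)
      norms[[id]] <- normalize_coverage(mut, wt)
    }
    stage("read", wildtype = config$wildtype, mutant = unname(config$mutant))
    if (!is.null(config$parts_map)) {
      parts <- if (is.data.frame(config$parts_map)) config$parts_map
               else read_parts_map(config$parts_map)
    }
  }
  stage("normalize", lines = names(norms),
        bins = vapply(norms, function(n) nrow(n$bins), 0L))

  if (!is.null(parts)) {
    norms <- lapply(norms, lift_parts_to_full, parts = parts)
    stage("lift", chromosomes = parts$full_id)
  }

  calls <- do.call(rbind, lapply(norms, call_deletions, params = params))
  if (is.null(calls)) calls <- empty_calls()
  class(calls) <- c("deletion_calls", "data.frame")
  stage("call", n_calls = nrow(calls),
        per_line = table(factor(calls$line_id, levels = names(norms))))

  if (length(norms) >= 2 && nrow(calls)) {
    calls <- flag_shared_calls(calls)
    stage("flag_shared", n_flagged = sum(calls$flags != ""))
  }

  for (id in names(norms)) {
    write_coverage(norms[[id]], file.path(config$out_dir,
                                          paste0("coverage_", id, ".tsv")))
  }
  write_calls(calls, file.path(config$out_dir, "calls.tsv"))

  if (!is.null(sim_genes) && nrow(calls)) {
    refined <- list(); contents <- list()
    for (i in seq_len(nrow(calls))) {
      ln <- calls$line_id[i]
      refined[[i]] <- refine_borders(calls[i, , drop = FALSE], sim_genes$genes,
                                     sim_genes$values[[ln]],
                                     low_fraction = params$low_fraction,
                                     chrom_lengths = spec$chromosomes)
      contents[[i]] <- gene_content(calls[i, , drop = FALSE], sim_genes$genes)
    }
    refined <- do.call(rbind, refined)
    class(refined) <- c("deletion_calls", "data.frame")
    write_calls(refined, file.path(config$out_dir, "calls_refined.tsv"))
    stage("refine", n_refined = sum(refined$method == "refined"))
    stage("gene_content", n_genes = vapply(contents, nrow, 0L))
  }

  if (isTRUE(config$plots)) {
    for (id in names(norms)) {
      png(file.path(config$out_dir, paste0("coverage_", id, ".png")),
          width = 1400, height = 900)
      plot(norms[[id]], calls = calls[calls$line_id == id, , drop = FALSE],
           low_fraction = params$low_fraction,
           window = params$smoothing_window)
      dev.off()
    }
    stage("plots", files = paste0("coverage_", names(norms), ".png"))
  }

  report$calls <- calls
  ser <- report
  ser$calls <- as.data.frame(ser$calls)
  ser$stages <- lapply(ser$stages, function(s) lapply(s, function(v) {
    if (is.table(v)) as.list(v) else v
  }))
  jsonlite::write_json(ser, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(x$tool, "run (seed", x$seed, ")\n")
  cat("  stages:", paste(names(x$stages), collapse = " -> "), "\n")
  cat("  calls:", nrow(x$calls), "\n")
  invisible(x)
}
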