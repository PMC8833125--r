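#' Assemble and validate a pipeline configuration
#'
#' One configuration object drives the full analysis. Either `input`
#' (path to an SUV table) or `synthetic` (a [synthetic_spec()]) must be
#' supplied. All randomness flows from `seed` through documented child
#' seeds, so a configuration fully determines the report.
#'
#' @param input path to a delimited SUV table, or `NULL`.
#' @param synthetic a [synthetic_spec()], or `NULL`.
#' @param output_dir report directory.
#' @param seed master integer seed; required.
#' @param grid sparsity grid.
#' @param n_perm permutations for all tests.
#' @param ensemble_size rewired-ensemble size for normalized metrics in
#'   the observed curves.
#' @param perm_ensemble_size reduced ensemble size inside permutation
#'   and attack loops.
#' @param global_metrics global metrics to report.
#' @param alpha_edge edge-wise uncorrected level (default 0.001).
#' @param alpha_global global-metric level (default 0.05).
#' @param fdr_q nodal FDR level (default 0.05).
#' @param attack_kind `"targeted"`, `"random"` or `"none"`.
#' @param attack_reps random-failure repetitions.
#' @param attack_steps removed-node counts for the robustness
#'   comparison (`NULL` = every step).
#' @param attack_metrics metrics tracked under attack.
#' @param attack_n_perm permutations for the robustness comparison.
#' @param normalize whether to globally normalize the input table.
#' @param rank_by edge ranking for thresholding.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL, output_dir,
                            seed,
                            grid = sparsity_grid(),
                            n_perm = 5000,
                            ensemble_size = 5000,
                            perm_ensemble_size = 100,
                            global_metrics = GLOBAL_METRICS,
                            nodal_metrics = NODAL_METRICS,
                            alpha_edge = 0.001,
                            alpha_global = 0.05,
                            fdr_q = 0.05,
                            attack_kind = c("targeted", "random", "none"),
                            attack_reps = 40,
                            attack_steps = NULL,
                            attack_metrics = c("Lp", "Cp", "Eglob", "Eloc"),
                            attack_n_perm = n_perm,
                            normalize = TRUE,
                            rank_by = "signed") {
  seed <- require_seed(seed)
  attack_kind <- match.arg(attack_kind)
  if (is.null(input) && is.null(synthetic))
    stop("supply `input` (an SUV table path) or `synthetic` (a synthetic_spec)")
  stopifnot(alpha_edge > 0, alpha_edge < 1, alpha_global > 0, alpha_global < 1,
            fdr_q > 0, fdr_q < 1, n_perm >= 1)
  structure(list(input = input, synthetic = synthetic,
                 output_dir = output_dir, seed = seed, grid = grid,
                 n_perm = n_perm, ensemble_size = ensemble_size,
                 perm_ensemble_size = perm_ensemble_size,
                 global_metrics = global_metrics,
                 nodal_metrics = nodal_metrics,
                 alpha_edge = alpha_edge, alpha_global = alpha_global,
                 fdr_q = fdr_q, attack_kind = attack_kind,
                 attack_reps = attack_reps, attack_steps = attack_steps,
                 attack_metrics = attack_metrics,
                 attack_n_perm = attack_n_perm,
                 normalize = normalize, rank_by = rank_by),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' File fields mirror the arguments of [pipeline_config()]; a
#' `synthetic` block is passed to [synthetic_spec()] (its
#' `planted_edges` entry, if present, as a data frame).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @param ... named overrides applied on top of the file's fields
#'   (e.g. `seed`, `output_dir`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  if (!is.null(cfg$synthetic)) {
    syn <- cfg$synthetic
    if (!is.null(syn$planted_edges))
      syn$planted_edges <- as.data.frame(syn$planted_edges)
    if (!is.null(syn$n_per_group)) syn$n_per_group <- unlist(syn$n_per_group)
    cfg$synthetic <- do.call(synthetic_spec, syn)
  }
  if (!is.null(cfg$grid)) cfg$grid <- as.numeric(cfg$grid)
  do.call(pipeline_config, cfg)
}

# Deterministic 32-bit FNV-1a content hash of an R object.
content_hash <- function(object) {
  bytes <- as.integer(serialize(object, connection = NULL, version = 2L))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.12g", x))

write_tsv_report <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages: ingest (read or simulate the SUV table, optional global
#' normalization); group correlation networks; per-group global metric
#' curves and AUCs; edge-level permutation test; global-AUC permutation
#' tests; nodal-AUC permutation tests with FDR; optional robustness
#' comparison. The report directory receives, as TSV/JSON: the group
#' correlation matrices, a global-metric table (per-group AUC and
#' permutation p), a significant-edge table, a nodal table (regions
#' passing FDR), robustness trajectories, and a `manifest.json` tying
#' every number to the master seed and configuration hash. Rerunning an
#' unchanged configuration over an existing up-to-date report directory
#' is a no-op.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return A `run_report` list (invisibly) with all stage results.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[metconn] ", ...)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- content_hash(config[setdiff(names(config), "output_dir")])
  manifest_path <- file.path(config$output_dir, "manifest.json")
  if (file.exists(manifest_path)) {
    old <- tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)
    if (!is.null(old$config_hash) && identical(old$config_hash, hash) &&
        all(file.exists(file.path(config$output_dir, unlist(old$files))))) {
      say("configuration unchanged; report is up to date (no-op)")
      return(invisible(NULL))
    }
  }
  seed <- config$seed
  ## ingest
  table <- if (!is.null(config$input)) {
    say("reading SUV table from ", config$input)
    read_suv_table(config$input)
  } else {
    say("simulating synthetic SUV table")
    simulate_suv_table(config$synthetic, seed = child_seed(seed, "simulate"))
  }
  if (config$normalize) table <- normalize_suv_table(table)
  groups <- table_groups(table)
  say("groups: ", paste(sprintf("%s (n=%d)", groups,
                                table(suv_groups(table))[groups]), collapse = ", "))
  files <- character(0)
  emit <- function(name) files <<- c(files, name)

  ## networks
  nets <- lapply(groups, function(g) group_correlation(table, g))
  names(nets) <- groups
  for (g in groups) {
    f <- paste0("correlation_", g, ".tsv")
    m <- as.data.frame(nets[[g]]$matrix)
    write_tsv_report(cbind(region = rownames(nets[[g]]$matrix), m),
                     file.path(config$output_dir, f))
    emit(f)
  }

  ## observed global curves + permutation p per metric
  say("global metric AUC tests (n_perm = ", config$n_perm, ")")
  glob <- lapply(config$global_metrics, function(mm)
    global_auc_permutation_test(table, mm, grid = config$grid,
                                n_perm = config$n_perm,
                                seed = child_seed(seed, "global_test"),
                                ensemble_size = config$perm_ensemble_size,
                                rank_by = config$rank_by))
  names(glob) <- config$global_metrics
  glob_df <- data.frame(metric = config$global_metrics,
                        auc_a = vapply(glob, function(x) x$auc_a, numeric(1)),
                        auc_b = vapply(glob, function(x) x$auc_b, numeric(1)),
                        observed_diff = vapply(glob, function(x) x$observed_diff, numeric(1)),
                        p_value = vapply(glob, function(x) x$p_value, numeric(1)))
  names(glob_df)[2:3] <- paste0("auc_", groups)
  write_tsv_report(glob_df, file.path(config$output_dir, "global_metrics.tsv"))
  emit("global_metrics.tsv")

  ## edge test
  say("edge permutation test")
  edge <- edge_permutation_test(table, n_perm = config$n_perm,
                                seed = child_seed(seed, "edge_test"),
                                alpha = config$alpha_edge)
  edge_df <- rbind(
    if (nrow(edge$significant_increased))
      cbind(edge$significant_increased, direction = "increased"),
    if (nrow(edge$significant_decreased))
      cbind(edge$significant_decreased, direction = "decreased"))
  if (is.null(edge_df))
    edge_df <- data.frame(region_i = character(0), region_j = character(0),
                          observed_diff = numeric(0), p_value = numeric(0),
                          direction = character(0))
  write_tsv_report(edge_df, file.path(config$output_dir, "edges_significant.tsv"))
  emit("edges_significant.tsv")

  ## nodal test
  say("nodal permutation tests with FDR")
  nodal <- nodal_auc_permutation_test(table, grid = config$grid,
                                      n_perm = config$n_perm,
                                      seed = child_seed(seed, "nodal_test"),
                                      metrics = config$nodal_metrics,
                                      q = config$fdr_q,
                                      rank_by = config$rank_by)
  nodal_rows <- do.call(rbind, lapply(config$nodal_metrics, function(mm) {
    hit <- which(nodal[[mm]]$fdr_mask)
    if (!length(hit)) return(NULL)
    data.frame(metric = mm, region = names(hit),
               observed_diff = nodal[[mm]]$observed_diff[hit],
               p_value = nodal[[mm]]$p_values[hit])
  }))
  if (is.null(nodal_rows))
    nodal_rows <- data.frame(metric = character(0), region = character(0),
                             observed_diff = numeric(0), p_value = numeric(0))
  write_tsv_report(nodal_rows, file.path(config$output_dir, "nodal_significant.tsv"))
  emit("nodal_significant.tsv")

  ## robustness
  robust <- NULL
  if (config$attack_kind != "none") {
    say("robustness comparison (", config$attack_kind, " attack, n_perm = ",
        config$attack_n_perm, ")")
    robust <- compare_robustness(table, kind = config$attack_kind,
                                 grid = config$grid,
                                 n_perm = config$attack_n_perm,
                                 seed = child_seed(seed, "robustness"),
                                 n_reps = config$attack_reps,
                                 steps = config$attack_steps,
                                 metrics = config$attack_metrics,
                                 alpha = config$alpha_global,
                                 ensemble_size = config$perm_ensemble_size,
                                 rank_by = config$rank_by)
    long <- do.call(rbind, lapply(seq_along(robust$steps), function(si) {
      do.call(rbind, lapply(colnames(robust$p_values), function(mm)
        data.frame(kind = robust$kind, step = robust$steps[si],
                   fraction = robust$fraction[si], metric = mm,
                   value_a = robust$attack_a$metrics[si, mm],
                   value_b = robust$attack_b$metrics[si, mm],
                   lcc_a = robust$attack_a$lcc[si],
                   lcc_b = robust$attack_b$lcc[si],
                   p_value = robust$p_values[si, mm])))
    }))
    names(long)[names(long) == "value_a"] <- paste0("value_", groups[1])
    names(long)[names(long) == "value_b"] <- paste0("value_", groups[2])
    names(long)[names(long) == "lcc_a"] <- paste0("lcc_", groups[1])
    names(long)[names(long) == "lcc_b"] <- paste0("lcc_", groups[2])
    write_tsv_report(long, file.path(config$output_dir, "robustness.tsv"))
    emit("robustness.tsv")
  }

  manifest <- list(package = "metconn",
                   config_hash = hash,
                   seed = seed,
                   groups = as.list(stats::setNames(
                     as.integer(table(suv_groups(table))[groups]), groups)),
                   n_perm = config$n_perm,
                   grid = range(config$grid),
                   n_grid = length(config$grid),
                   rank_by = config$rank_by,
                   attack_kind = config$attack_kind,
                   files = as.list(files))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  say("report written to ", config$output_dir)
  invisible(structure(list(table = table, networks = nets, global = glob,
                           global_table = glob_df, edge = edge, nodal = nodal,
                           robustness = robust, manifest = manifest,
                           config = config),
                      class = "run_report"))
}
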