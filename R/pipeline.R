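# End-to-end orchestration: a validated config drives every stage and each
# output table carries a provenance header (parameters + seed), so a rerun
# with the same config is bit-identical.

#' Default pipeline parameters
#' @noRd
default_params <- function() {
  list(pseudocount = 1, assume_log = FALSE, min_confidence = 0,
       mode = "activated", span = 0.75, eps = 1e-4,
       terminal_fraction = 0.05, n_perm = 200, alpha = 0.05,
       k = 100, k_final = 100, fdr_max = 0.05, deg_method = "moderated",
       min_size = 10, max_size = 500, redundancy_cutoff = 0.8,
       background = 20000, model = "svm", folds = 5, n_boot = 1000,
       expressed_threshold = 0, top_hubs = 10, max_drugs = 3, seed = 1)
}

#' Build and validate a pipeline configuration
#'
#' Input paths: `expr` (expression TSV), `groups` (TSV `sample`, `group`),
#' `network` (edge list); optional `gmt`, `ref_lists` (named list of
#' gene-list paths), `sc_matrix` + `sc_labels`, `drug_table`.  Parameters
#' default to the pipeline's standard values (`n_perm = 200`,
#' `alpha = 0.05`, `k = 100`, `background = 20000`, `folds = 5`,
#' `n_boot = 1000`).  Unknown keys are rejected.
#'
#' @param ... named inputs and parameter overrides.
#' @param config_file optional YAML file whose entries are merged first.
#' @return A validated `PipelineConfig` list.
#' @export
pipeline_config <- function(..., config_file = NULL) {
  cfg <- list()
  if (!is.null(config_file)) cfg <- yaml::read_yaml(config_file)
  dots <- list(...)
  cfg[names(dots)] <- dots
  known <- c("expr", "groups", "network", "gmt", "ref_lists", "sc_matrix",
             "sc_labels", "drug_table", names(default_params()))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  params <- default_params()
  params[intersect(names(cfg), names(params))] <-
    cfg[intersect(names(cfg), names(params))]
  cfg[names(params)] <- params
  for (k in c("expr", "groups", "network"))
    if (is.null(cfg[[k]])) stop("config is missing required input: ", k)
  structure(cfg, class = "PipelineConfig")
}

#' Write a TSV with a provenance header comment
#' @noRd
write_stage_table <- function(df, path, cfg, stage) {
  hdr <- sprintf("# netmediator %s | seed=%s n_perm=%s alpha=%s k=%s background=%s",
                 stage, cfg$seed, cfg$n_perm, cfg$alpha, cfg$k,
                 cfg$background)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run a stage, aborting with the stage name on failure
#' @noRd
run_stage <- function(stage, log_con, code) {
  msg <- sprintf("[%s] running", stage)
  writeLines(msg, log_con)
  message(msg)
  tryCatch(force(code), error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Stages: ingest, differential expression, per-sample node weights +
#' path significance + TopNets + central genes, enrichment (if a GMT is
#' configured), benchmark overlaps (if reference lists are configured),
#' single-cell overlay (if a cell matrix is configured), classifier
#' evaluation, and hub/drug selection (always on the central genes).
#' Every table is written under `out_dir` with a parameter header; the
#' config itself is echoed to `out_dir/config.yaml`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  log_con <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(log_con))
  res <- list()

  res$expr <- run_stage("ingest", log_con, {
    gr <- utils::read.delim(config$groups, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    group_map <- stats::setNames(gr$group, gr$sample)
    read_expression(config$expr, group_map,
                    pseudocount = config$pseudocount,
                    assume_log = config$assume_log)
  })
  res$network <- run_stage("ingest-network", log_con,
    read_network(config$network, min_confidence = config$min_confidence))

  res$deg_table <- run_stage("deg", log_con,
    differential_expression(res$expr, method = config$deg_method))
  res$top_degs <- suppressWarnings(
    select_top_degs(res$deg_table, k = config$k, fdr_max = config$fdr_max))
  write_stage_table(res$deg_table, file.path(out_dir, "degs.tsv"),
                    config, "deg")
  writeLines(res$top_degs, file.path(out_dir, "top_degs.txt"))

  res$central <- run_stage("pathext", log_con, suppressWarnings(
    central_genes(res$expr, res$network, mode = config$mode,
                  k = config$k, k_final = config$k_final,
                  terminal_fraction = config$terminal_fraction,
                  n_perm = config$n_perm, alpha = config$alpha,
                  span = config$span, eps = config$eps,
                  seed = config$seed)))
  write_stage_table(as.data.frame(res$central$central),
                    file.path(out_dir, "central_genes.tsv"),
                    config, "central")
  central_ids <- res$central$central$gene

  if (!is.null(config$gmt)) {
    res$enrichment <- run_stage("enrich", log_con, {
      coll <- read_gmt(config$gmt)
      bg <- rownames(res$expr$values)
      ora <- hypergeom_ora(intersect(central_ids, bg), coll, bg,
                           min_size = config$min_size,
                           max_size = config$max_size)
      reduce_redundancy(ora, coll, cutoff = config$redundancy_cutoff)
    })
    write_stage_table(res$enrichment,
                      file.path(out_dir, "enrichment.tsv"), config,
                      "enrich")
  }

  if (!is.null(config$ref_lists)) {
    res$overlaps <- run_stage("overlap", log_con, {
      rows <- lapply(names(config$ref_lists), function(nm) {
        ref <- read_gene_list(config$ref_lists[[nm]])
        cbind(list_name = nm,
              fisher_overlap(central_ids, ref,
                             background_size = config$background))
      })
      do.call(rbind, rows)
    })
    write_stage_table(res$overlaps, file.path(out_dir, "overlaps.tsv"),
                      config, "overlap")
  }

  if (!is.null(config$sc_matrix)) {
    res$overlay <- run_stage("sc-overlay", log_con, {
      mat <- as.matrix(utils::read.delim(config$sc_matrix, row.names = 1,
                                         check.names = FALSE))
      lab <- utils::read.delim(config$sc_labels, stringsAsFactors = FALSE)
      sc_overlay(mat, stats::setNames(lab$type, lab$cell),
                 intersect(central_ids, colnames(mat)),
                 expressed_threshold = config$expressed_threshold)
    })
    write_stage_table(res$overlay$overlay,
                      file.path(out_dir, "sc_overlay.tsv"), config,
                      "sc-overlay")
  }

  res$eval <- run_stage("classify", log_con, {
    feats <- intersect(central_ids, rownames(res$expr$values))
    X <- t(res$expr$values[feats, , drop = FALSE])
    y <- as.integer(res$expr$group_of == "case")
    cv <- cross_validate(X, y, model_kind = config$model,
                         folds = config$folds, seed = config$seed)
    ci <- bootstrap_ci(cv$scores, y, auroc, n_boot = config$n_boot,
                       seed = config$seed)
    list(cv = cv, auroc_ci = ci)
  })
  ev <- res$eval
  jsonlite::write_json(
    list(model = ev$cv$model, auroc = ev$cv$auroc, auprc = ev$cv$auprc,
         f1 = ev$cv$f1, auroc_ci = as.list(ev$auroc_ci)),
    file.path(out_dir, "eval.json"), auto_unbox = TRUE, digits = NA)

  res$hubs <- run_stage("hubs", log_con, {
    h <- degree_hubs(central_ids, res$network,
                     min_confidence = config$min_confidence,
                     top_n = config$top_hubs)
    if (!is.null(config$drug_table))
      h <- map_drug_targets(h, read_drug_table(config$drug_table),
                            max_per_gene = config$max_drugs)
    h
  })
  write_stage_table(res$hubs, file.path(out_dir, "hubs.tsv"), config,
                    "hubs")

  writeLines("[done]", log_con)
  invisible(res)
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Generates a cohort, a mediator-wired network and truth tables, and
#' writes them as the TSV inputs `run_all()` consumes.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory.
#' @param attach_m,wire_per_mediator network-generator parameters.
#' @return Invisibly, a named list of the written paths plus the in-memory
#'   objects.
#' @export
simulate_inputs <- function(spec, out_dir, attach_m = 2,
                            wire_per_mediator = 20) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(spec)
  truth <- cohort$truth
  net <- generate_network(truth$gene,
                          mediator_ids = truth$gene[truth$role == "mediator"],
                          deg_ids = truth$gene[truth$role == "deg"],
                          attach_m = attach_m,
                          wire_per_mediator = wire_per_mediator,
                          seed = spec$seed + 1)
  paths <- list(expr = file.path(out_dir, "expression.tsv"),
                groups = file.path(out_dir, "groups.tsv"),
                network = file.path(out_dir, "network.tsv"),
                truth = file.path(out_dir, "truth.tsv"))
  write_expression(cohort$expr, paths$expr)
  utils::write.table(data.frame(sample = names(cohort$expr$group_of),
                                group = cohort$expr$group_of,
                                row.names = NULL),
                     paths$groups, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_network(net, paths$network)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, list(cohort = cohort, network = net)))
}
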