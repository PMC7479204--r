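# One-shot reproducible run: generate/load -> bipartite -> giant component ->
# project both sides -> cluster -> validate -> machine-readable report.

#' Run configuration
#'
#' A flat key-value configuration; [read_run_config()] loads it from a flat
#' YAML file, and every field can be overridden programmatically. Either
#' `incidence` (a path, with optional annotation paths) or `synthetic = TRUE`
#' (with [synthetic_config()] fields) must be provided.
#'
#' @param synthetic generate input data with [generate_dataset()]?
#' @param incidence path to an incidence TSV (ignored when `synthetic`).
#' @param annotations named list: for kinds validated on the herb projection
#'   (`label_set`) and ingredient projection (`string`, `id_set`), entries
#'   `name = list(path =, kind =, side =)`. Ignored when `synthetic`.
#' @param sides projections to compute, subset of `c("herb", "ingredient")`.
#' @param algorithm community-detection algorithm name (see
#'   [register_partitioner()]).
#' @param weighted use projection weights in clustering and scoring.
#' @param similarity set-similarity method, `"overlap"` or `"jaccard"`.
#' @param n_replicates random-grouping null replicates per validation.
#' @param seed master seed for the run; all randomness derives from it.
#' @param outdir output directory.
#' @param ... [synthetic_config()] fields when `synthetic = TRUE`.
#' @return a list of class `tcmnet_run_config`.
#' @export
run_config <- function(synthetic = TRUE, incidence = NULL, annotations = NULL,
                       sides = c("herb", "ingredient"),
                       algorithm = "fast_greedy", weighted = TRUE,
                       similarity = c("overlap", "jaccard"),
                       n_replicates = 100, seed = 1L, outdir = tempfile("tcmnet_run_"),
                       ...) {
  similarity <- match.arg(similarity)
  sides <- match.arg(sides, several.ok = TRUE)
  extra <- list(...)
  syn_cfg <- NULL
  if (isTRUE(synthetic)) {
    syn_args <- extra[intersect(names(extra), names(formals(synthetic_config)))]
    syn_args$seed <- seed
    syn_cfg <- do.call(synthetic_config, syn_args)
  } else if (is.null(incidence)) {
    stop_tcmnet("either synthetic = TRUE or an incidence path is required",
                "tcmnet_config_error")
  }
  structure(
    list(synthetic = isTRUE(synthetic), incidence = incidence,
         annotations = annotations, sides = sides, algorithm = algorithm,
         weighted = isTRUE(weighted), similarity = similarity,
         n_replicates = check_count(n_replicates, "n_replicates"),
         seed = check_count(seed, "seed", min = 0L),
         outdir = outdir, synthetic_config = syn_cfg),
    class = "tcmnet_run_config"
  )
}

#' @rdname run_config
#' @param path flat YAML file of config keys.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop_tcmnet(sprintf("pipeline stage '%s' failed: %s", name,
                        conditionMessage(e)),
                "tcmnet_stage_error")
  })
  message(sprintf("[%s] done in %.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

# which annotation kinds validate against which projection
default_annotation_plan <- function() {
  tibble::tibble(
    name = c("meridian", "property", "smiles", "targets"),
    kind = c("label_set", "label_set", "string", "id_set"),
    side = c("herb", "herb", "ingredient", "ingredient")
  )
}

#' Run the full analysis pipeline
#'
#' Stages: load or generate the incidence table; build the bipartite graph;
#' extract its giant component; project onto each requested side; detect
#' communities; validate each annotation kind on its projection against the
#' random-grouping null. All artifacts are written under `config$outdir`
#' (`incidence.tsv`, `nsn.tsv`, `isn.tsv`, `*_partition.csv`,
#' `validation_*.json`, `report.json`). A rerun with the same config and
#' seed reproduces every artifact byte-identically apart from timestamps.
#'
#' @param config a [run_config()].
#' @return the run report (list of class `tcmnet_report`), invisibly the
#'   same as written to `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "tcmnet_run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    software = paste0("tcmnet ", as.character(utils::packageVersion("tcmnet"))),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass_config(config)
  )

  ground_truth <- NULL
  ann_tables <- list()
  plan <- default_annotation_plan()
  if (config$synthetic) {
    ds <- stage("generate", generate_dataset(config$synthetic_config))
    write_dataset(ds, config$outdir)
    incidence <- ds$incidence
    ann_tables <- ds$annotations
    ground_truth <- ds$ground_truth
  } else {
    incidence <- stage("load", load_incidence(config$incidence))
    utils::write.table(incidence, file.path(config$outdir, "incidence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(config$annotations)) {
      entry <- config$annotations[[nm]]
      ann_tables[[nm]] <- read_annotations(entry$path, kind = entry$kind)
    }
    plan <- plan[plan$name %in% names(ann_tables), ]
    extra <- setdiff(names(config$annotations), plan$name)
    for (nm in extra) {
      entry <- config$annotations[[nm]]
      plan <- dplyr::bind_rows(plan, tibble::tibble(
        name = nm, kind = entry$kind, side = entry$side))
    }
  }

  bg <- stage("build", build_bipartite(incidence))
  report$bipartite <- list(
    n_herbs = length(herb_ids(bg)), n_ingredients = length(ingredient_ids(bg)),
    n_edges = igraph::gsize(bg)
  )
  gc_graph <- stage("giant_component", giant_component(bg))
  report$giant_component <- list(
    n_nodes = igraph::vcount(gc_graph), n_edges = igraph::gsize(gc_graph),
    n_herbs = length(herb_ids(gc_graph)),
    n_ingredients = length(ingredient_ids(gc_graph))
  )

  projections <- list()
  partitions <- list()
  report$projections <- list()
  for (side in config$sides) {
    tag <- if (side == "herb") "nsn" else "isn"
    pg <- stage(paste0("project_", side), project(gc_graph, side))
    write_projection(pg, file.path(config$outdir, paste0(tag, ".tsv")))
    part <- stage(paste0("cluster_", side), {
      fun <- get_partitioner(config$algorithm)
      if (identical(config$algorithm, "fast_greedy")) {
        fun(pg, weighted = config$weighted)
      } else {
        fun(pg)
      }
    })
    write_partition(part, file.path(config$outdir, paste0(tag, "_partition.csv")))
    ds_stats <- degree_stats(pg)
    proj_report <- list(
      side = side, n_nodes = igraph::vcount(pg), n_edges = igraph::gsize(pg),
      mean_degree = ds_stats$mean_degree,
      heterogeneity = ds_stats$heterogeneity,
      n_communities = dplyr::n_distinct(part$assignment$community),
      modularity = part$modularity
    )
    if (!is.null(ground_truth)) {
      gt <- ground_truth[ground_truth$side == side, ]
      proj_report$ari_vs_ground_truth <- adjusted_rand(part, gt)
    }
    report$projections[[tag]] <- proj_report
    projections[[side]] <- pg
    partitions[[side]] <- part
  }

  report$validation <- list()
  plan <- plan[plan$side %in% config$sides & plan$name %in% names(ann_tables), ]
  for (k in seq_len(nrow(plan))) {
    nm <- plan$name[k]
    v <- stage(paste0("validate_", nm), validate_communities(
      partitions[[plan$side[k]]], ann_tables[[nm]],
      n_replicates = config$n_replicates,
      seed = config$seed + k,
      method = config$similarity
    ))
    write_validation(
      v, file.path(config$outdir, sprintf("validation_%s.json", nm)),
      file.path(config$outdir, sprintf("validation_%s_values.tsv", nm))
    )
    report$validation[[nm]] <- as.list(glance(v))
  }

  report$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  class(report) <- "tcmnet_report"
  jsonlite::write_json(unclass(report), file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$synthetic_config <- if (!is.null(out$synthetic_config)) {
    unclass(out$synthetic_config)
  }
  out[!vapply(out, is.null, logical(1))]
}

#' @export
print.tcmnet_report <- function(x, ...) {
  cat(sprintf("<tcmnet_report> seed %d\n", x$seed))
  for (tag in names(x$projections)) {
    p <- x$projections[[tag]]
    cat(sprintf("  %s: %d nodes, %d edges, %d communities, Q = %.4f\n",
                toupper(tag), p$n_nodes, p$n_edges, p$n_communities,
                p$modularity))
  }
  for (nm in names(x$validation)) {
    v <- x$validation[[nm]]
    cat(sprintf("  %s: observed median %.3f vs null %.3f, p = %.3g\n",
                nm, v$observed_median, v$null_median, v$p_value))
  }
  invisible(x)
}
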