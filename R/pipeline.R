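#' Run the MR selection and synergy pipeline in memory
#'
#' Executes the analysis chain on loaded objects: per-dataset DA inference
#' ([da_signature()]), common top-N selection over the discovery datasets
#' ([common_top()]), rank-sum validation in the validation datasets
#' ([validate_common()]), the DA-DE consistency filter
#' ([da_de_consistent()]), and the all-pairs synergy screen over the
#' consistent MRs ([synergy_screen()]) on every dataset.
#'
#' @param net a [regulatory_network].
#' @param sigs named list of [de_signature]s covering all discovery and
#'   validation datasets.
#' @param discovery_ids,validation_ids disjoint nonempty dataset id sets.
#' @param n top-N cutoff (default 100).
#' @param de_threshold DA-DE consistency cutoff (default 3).
#' @param min_common,min_frac synergy eligibility thresholds (defaults 10 and
#'   0.10).
#' @param min_targets minimum scoreable targets per regulator for the DA step
#'   (default 2).
#' @return list with `da_tables` (named by dataset), `selection`
#'   (activated/suppressed sets), `validation_p` (data.frame `dataset_id`,
#'   `direction`, `p`), `consistent`, `synergy` (a `synergy_result`) and
#'   `top_pair`.
#' @export
run_pipeline <- function(net, sigs, discovery_ids, validation_ids,
                         n = 100L, de_threshold = 3,
                         min_common = 10L, min_frac = 0.10,
                         min_targets = 2L) {
  ids <- vapply(sigs, function(s) s$dataset_id, character(1))
  names(sigs) <- ids
  if (length(discovery_ids) == 0L || length(validation_ids) == 0L) {
    stop("discovery and validation dataset id sets must be nonempty")
  }
  if (length(intersect(discovery_ids, validation_ids)) > 0L) {
    stop("discovery and validation dataset ids must be disjoint")
  }
  missing_ids <- setdiff(c(discovery_ids, validation_ids), ids)
  if (length(missing_ids) > 0L) {
    stop("no signature for dataset id: ", missing_ids[1L])
  }
  das <- lapply(sigs, function(s) da_signature(net, s, min_targets = min_targets))
  disc_das <- das[discovery_ids]
  val_das <- das[validation_ids]
  disc_sigs <- sigs[discovery_ids]
  selection <- common_top(disc_das, n)
  vp <- list()
  for (direction in c("activated", "suppressed")) {
    mrs <- selection[[direction]]
    for (id in validation_ids) {
      p <- if (length(mrs) > 0L) validate_common(das[[id]], mrs) else NA_real_
      vp[[length(vp) + 1L]] <- data.frame(dataset_id = id,
                                          direction = direction, p = p,
                                          stringsAsFactors = FALSE)
    }
  }
  validation_p <- do.call(rbind, vp)
  consistent <- suppressWarnings(
    da_de_consistent(c(selection$activated, selection$suppressed),
                     disc_das, disc_sigs, de_threshold = de_threshold))
  synergy <- synergy_screen(net, consistent, sigs, das,
                            min_common = min_common, min_frac = min_frac)
  list(da_tables = das, selection = selection, validation_p = validation_p,
       consistent = consistent, synergy = synergy,
       top_pair = top_synergistic_pair(synergy))
}

config_hash <- function(text) {
  # 31-bit polynomial rolling hash of the UTF-8 bytes, as 8 hex digits
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(text)) {
    h <- (h * 131 + b) %% m
  }
  sprintf("%08x", as.integer(h))
}

default_run_config <- function() {
  list(top_n = 100L, de_threshold = 3, min_common = 10L, min_frac = 0.10,
       min_targets = 2L, alpha_mutation = 0.1, survival_percentile = 80,
       seed = 1L)
}

#' Read a pipeline run configuration
#'
#' YAML (or flat `key: value`) file with keys `interactome` (path),
#' `signature_files` (list of paths), `discovery_ids`, `validation_ids`,
#' `out_dir`, and optional `top_n`, `de_threshold`, `min_common`, `min_frac`,
#' `min_targets`, `alpha_mutation`, `survival_percentile`, `seed` (all
#' defaulting to the pipeline's standard thresholds).
#'
#' @param path YAML file path.
#' @return config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- utils::modifyList(default_run_config(), cfg)
  out
}

#' Run the full analysis from files and write all stage outputs
#'
#' File-level orchestration of [run_pipeline()]: validates the
#' configuration, reads the interactome and signatures, runs the pipeline,
#' and writes per-dataset DA tables, the selection report, the synergy
#' report, a machine-readable `summary.json` (selected and consistent MRs,
#' validation p-values, eligible pairs with their worst-case p, top
#' synergistic pair) and a deterministic `run.log` (config hash, seed, stage
#' sequence). When the config names a `cohort_dir` (see [read_cohort()]),
#' the clinical [association_battery()] also runs over all cohort genes and
#' its tables are written as `association_*.tsv`. Inputs are never modified;
#' rerunning on the same inputs gives byte-identical outputs.
#'
#' @param config config list (see [read_run_config()]) or path to a YAML
#'   config file.
#' @return invisible pipeline result list (as [run_pipeline()]), with
#'   `out_dir` attached.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) {
    config <- read_run_config(config)
  }
  config <- utils::modifyList(default_run_config(), config)
  required <- c("interactome", "signature_files", "discovery_ids",
                "validation_ids", "out_dir")
  miss <- setdiff(required, names(config))
  if (length(miss) > 0L) {
    stop("config error: missing key '", miss[1L], "'")
  }
  if (length(config$discovery_ids) == 0L || length(config$validation_ids) == 0L) {
    stop("config error: discovery_ids and validation_ids must be nonempty")
  }
  if (length(intersect(config$discovery_ids, config$validation_ids)) > 0L) {
    stop("config error: discovery and validation ids overlap")
  }
  paths <- c(config$interactome, unlist(config$signature_files))
  if (!all(file.exists(paths))) {
    stop("config error: missing input file ", paths[!file.exists(paths)][1L])
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  run_stage <- function(name, expr) {
    stages <<- c(stages, name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  net <- run_stage("read_interactome", read_interactome(config$interactome))
  sigs <- run_stage("read_signatures",
                    lapply(unlist(config$signature_files), read_de_signature))
  res <- run_stage("pipeline", run_pipeline(
    net, sigs, config$discovery_ids, config$validation_ids,
    n = config$top_n, de_threshold = config$de_threshold,
    min_common = config$min_common, min_frac = config$min_frac,
    min_targets = config$min_targets))
  battery <- NULL
  if (!is.null(config$cohort_dir)) {
    cohort <- run_stage("read_cohort", read_cohort(config$cohort_dir))
    battery <- run_stage("associations", association_battery(
      cohort, rownames(cohort$expression),
      alpha = config$alpha_mutation,
      percentile = config$survival_percentile))
  }
  run_stage("write_outputs", {
    da_dir <- file.path(out_dir, "da")
    dir.create(da_dir, showWarnings = FALSE)
    for (da in res$da_tables) {
      write_da_table(da, file.path(da_dir,
                                   paste0(da_dataset_id(da), ".tsv")))
    }
    write_selection_report(file.path(out_dir, "selection_report.tsv"),
                           res$selection,
                           res$da_tables[config$discovery_ids],
                           res$da_tables[config$validation_ids],
                           res$consistent)
    write_synergy_report(res$synergy, file.path(out_dir, "synergy_report.tsv"))
    if (!is.null(battery)) {
      for (nm in names(battery)) {
        if (!is.null(battery[[nm]])) {
          utils::write.table(battery[[nm]],
                             file.path(out_dir,
                                       paste0("association_", nm, ".tsv")),
                             sep = "\t", quote = FALSE, row.names = FALSE,
                             na = "NA")
        }
      }
    }
    pair_summary <- if (nrow(res$synergy) > 0L) {
      key <- paste(res$synergy$mr1, res$synergy$mr2, sep = "\t")
      worst <- tapply(pmax(ifelse(is.na(res$synergy$p1), 1, res$synergy$p1),
                           ifelse(is.na(res$synergy$p2), 1, res$synergy$p2)),
                      key, max)
      lapply(sort(names(worst)), function(k) {
        mr <- strsplit(k, "\t", fixed = TRUE)[[1L]]
        list(mr1 = mr[1L], mr2 = mr[2L], worst_p = unname(worst[[k]]))
      })
    } else {
      list()
    }
    summary <- list(
      selected = res$selection,
      validation_p = res$validation_p,
      consistent = res$consistent,
      eligible_pairs = pair_summary,
      top_pair = if (is.null(res$top_pair)) NULL else
        list(mr1 = res$top_pair[1L], mr2 = res$top_pair[2L]))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  })
  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  log_lines <- c(
    sprintf("config_hash: %s", config_hash(yaml::as.yaml(cfg_for_hash))),
    sprintf("seed: %d", as.integer(config$seed)),
    paste0("stages: ", paste(stages, collapse = " -> ")))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  res$associations <- battery
  res$out_dir <- out_dir
  invisible(res)
}

#' Export node and edge tables for network visualization
#'
#' Builds the tables a network viewer (e.g. Cytoscape) maps to colours: a
#' node table of the given MRs plus all their regulon targets that carry a DE
#' score in at least one signature, with each gene's cross-dataset average DE
#' score, and an edge table of the corresponding regulator-target MORs.
#'
#' @param net a [regulatory_network].
#' @param mrs character vector of regulator ids (all in `net`).
#' @param sigs list of [de_signature]s used for the DE averages.
#' @return list with data.frames `nodes` (`gene`, `average_de`) and `edges`
#'   (`regulator`, `target`, `mor`).
#' @export
export_cytoscape_tables <- function(net, mrs, sigs) {
  mrs <- sort(unique(as.character(mrs)))
  if (length(mrs) == 0L) {
    return(list(nodes = data.frame(gene = character(0),
                                   average_de = numeric(0)),
                edges = data.frame(regulator = character(0),
                                   target = character(0), mor = numeric(0))))
  }
  regs <- regulators(net)
  if (!all(mrs %in% regs)) {
    stop("MR not in network: ", setdiff(mrs, regs)[1L])
  }
  scored <- unique(unlist(lapply(sigs, function(s) names(s$scores))))
  idx <- net$regulator %in% mrs & net$target %in% scored
  edges <- data.frame(regulator = net$regulator[idx],
                      target = net$target[idx], mor = net$mor[idx],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  genes <- sort(unique(c(mrs, edges$target)))
  avg <- average_de_table(sigs, genes = genes)
  nodes <- data.frame(gene = genes,
                      average_de = unname(avg[match(genes, names(avg))]),
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}

#' Write Cytoscape-style node and edge tables to TSV
#' @param tables list from [export_cytoscape_tables()].
#' @param dir output directory; writes `nodes.tsv` and `edges.tsv`.
#' @export
write_cytoscape_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(tables$nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(tables$edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
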