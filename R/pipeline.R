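# Staged analysis pipeline: contacts -> consensus/communities ->
# transition deltas -> correlation networks -> suboptimal paths ->
# B-factors, from a single validated run configuration, with a JSON
# manifest recording parameters, seed and output checksums.

#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or YAML file) with either a
#' \code{synthetic} section (arguments to \code{\link{planted_config}}) or
#' a \code{states} section (named list per state with \code{topology},
#' \code{frames}, optional \code{format}), plus optional thresholds:
#' \code{contact_cutoff} (4.5), \code{persistence} (0.75),
#' \code{consensus_threshold} (0.9), \code{modularity_tol} (0.001),
#' \code{k_paths} (5000), \code{hop_radius} (2), \code{paths_source},
#' \code{paths_target}, \code{paths_state}, \code{cycle}, and \code{seed}.
#'
#' @param config list or YAML path
#' @return normalized configuration list
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML file path")
  defaults <- list(contact_cutoff = 4.5, persistence = 0.75,
                   consensus_threshold = 0.90, modularity_tol = 0.001,
                   k_paths = 5000, hop_radius = 2, seed = 1)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  chk(config$contact_cutoff > 0, "contact_cutoff must be > 0")
  chk(config$persistence >= 0 && config$persistence <= 1,
      "persistence must be in [0, 1]")
  chk(config$consensus_threshold >= 0 && config$consensus_threshold <= 1,
      "consensus_threshold must be in [0, 1]")
  chk(config$k_paths >= 1, "k_paths must be >= 1")
  chk(config$hop_radius >= 0, "hop_radius must be >= 0")
  chk(is.numeric(config$seed), "seed must be numeric")
  if (is.null(config$synthetic) && is.null(config$states))
    stop("config needs a 'synthetic' or 'states' section")
  config
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: input ensembles (generated or loaded),
#' per-state contact maps, consensus network + Girvan-Newman partition,
#' per-transition community delta matrices, per-state correlation-weighted
#' networks with suboptimal paths (when endpoints are configured), and
#' per-state B-factors. All outputs are TSV/JSON under \code{out_dir};
#' a manifest (parameters, seed, md5 checksums) is written last. Rerunning
#' with the same config and seed reproduces the outputs byte for byte.
#'
#' @param config see \code{\link{validate_run_config}}
#' @param out_dir output directory (created if needed)
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  stage <- "setup"
  note <- function(path) outputs <<- c(outputs, path)
  result <- tryCatch({
    stage <- "inputs"
    set.seed(config$seed)
    if (!is.null(config$synthetic)) {
      syn_args <- config$synthetic
      if (isTRUE(syn_args) || length(syn_args) == 0) syn_args <- list()
      if (is.null(syn_args$seed)) syn_args$seed <- config$seed
      gen <- generate_planted_ensembles(do.call(planted_config, syn_args))
      ensembles <- gen$ensembles
    } else {
      ensembles <- list()
      for (st in names(config$states)) {
        sc <- config$states[[st]]
        top <- load_structure(sc$topology)
        ensembles[[st]] <- load_ensemble(top, sc$frames,
                                         format = sc$format %||% "auto",
                                         state = st)
      }
    }
    states <- names(ensembles)

    stage <- "contacts"
    maps <- list()
    for (st in states) {
      maps[[st]] <- compute_contact_map(ensembles[[st]],
                                        cutoff = config$contact_cutoff)
      f <- file.path(out_dir, paste0("contacts_", st, ".tsv"))
      write_contact_map(maps[[st]], f)
      note(f)
    }

    stage <- "communities"
    cons <- build_consensus_network(maps,
                                    threshold = config$consensus_threshold)
    part <- girvan_newman_partition(cons,
                                    modularity_tol = config$modularity_tol)
    f <- file.path(out_dir, "partition.tsv")
    write_partition(part, maps[[1]], f)
    note(f); note(paste0(f, ".json"))

    stage <- "transitions"
    cycle <- config$cycle %||% states
    deltas <- hydrolysis_cycle_deltas(maps, part, cycle = cycle)
    for (tr in names(deltas)) {
      f <- file.path(out_dir,
                     paste0("delta_", gsub("->", "_to_", tr, fixed = TRUE),
                            ".tsv"))
      write_delta(deltas[[tr]], f)
      note(f)
    }

    stage <- "paths"
    pathsets <- NULL
    src <- config$paths_source
    tgt <- config$paths_target
    if (!is.null(config$synthetic) && is.null(src)) {
      labs <- rownames(maps[[1]]$p)
      src <- labs[1]; tgt <- labs[length(labs)]
    }
    if (!is.null(src) && !is.null(tgt)) {
      pstate <- config$paths_state %||% states[min(2, length(states))]
      corr <- cross_correlation(ensembles[[pstate]])
      net <- build_dynamic_network(maps[[pstate]], corr,
                                   persistence = config$persistence)
      f <- file.path(out_dir, paste0("network_", pstate, ".tsv"))
      write_network(net, f)
      note(f)
      ps <- soan_suboptimal_paths(net, src, tgt, k = config$k_paths,
                                  hop_radius = config$hop_radius)
      f <- file.path(out_dir, paste0("paths_", pstate, ".tsv"))
      write_pathset(ps, f)
      note(f)
      pathsets <- ps
    }

    stage <- "bfactors"
    bf <- lapply(ensembles, computed_bfactors)
    f <- file.path(out_dir, "bfactors.tsv")
    bdf <- data.frame(residue = names(bf[[1]]),
                      do.call(cbind, lapply(bf, unname)))
    names(bdf)[-1] <- states
    utils::write.table(bdf, f, sep = "\t", quote = FALSE, row.names = FALSE)
    note(f)

    stage <- "manifest"
    manifest <- list(
      package = "mdcna",
      version = as.character(utils::packageVersion("mdcna")),
      seed = config$seed,
      parameters = config[c("contact_cutoff", "persistence",
                            "consensus_threshold", "modularity_tol",
                            "k_paths", "hop_radius")],
      states = states,
      partition = list(K = part$K, Q = part$modularity),
      outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                        basename(outputs))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
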