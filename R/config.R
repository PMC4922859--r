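#' Parse a screen configuration file
#'
#' Reads a JSON screen description (blocks `nodes`, `k`, `constraints`,
#' `regime`, `sampling`) into a validated `run_config`. Unknown keys are
#' rejected by name, so typos fail loudly. A run is reproducible from its
#' config plus a seed alone.
#'
#' @param path JSON file.
#' @return An object of class `run_config`: list with `name`, `nodes`
#'   ([rd_nodes]), `k`, `constraints` ([constraint_set()]), `regime`,
#'   `sampling` (list with `budget`, `seed`, `robustness_n`, `criterion`).
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  known <- c("name", "description", "nodes", "k", "constraints", "regime",
             "sampling")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  if (is.null(cfg$nodes) || is.null(cfg$k)) stop("config needs nodes and k")
  labs <- vapply(cfg$nodes, function(nd) as.character(nd$label),
                 character(1L))
  dif <- vapply(cfg$nodes, function(nd) isTRUE(nd$diffusible), logical(1L))
  nodes <- rd_nodes(dif, labs)
  k <- as.integer(cfg$k)
  if (k < 1 || k > nrow(nodes)^2)
    stop("k = ", k, " outside 1..N^2 = ", nrow(nodes)^2)
  cb <- cfg$constraints
  if (!is.null(cb)) {
    cknown <- c("forced_edges", "forbidden_edges", "sign_constraints",
                "value_constraints", "phase_constraints", "fixed_diffusion",
                "no_diffusible_to_diffusible", "diffusible_self_inhibition")
    cunknown <- setdiff(names(cb), cknown)
    if (length(cunknown))
      stop("unknown constraint key(s): ", paste(cunknown, collapse = ", "))
  }
  edge_mat <- function(lst) {
    if (is.null(lst) || !length(lst)) return(NULL)
    do.call(rbind, lapply(lst, function(e)
      c(node_id(e$target, nodes), node_id(e$source, nodes))))
  }
  edge_df <- function(lst, field) {
    if (is.null(lst) || !length(lst)) return(NULL)
    do.call(rbind, lapply(lst, function(e) {
      out <- data.frame(target = as.character(e$target),
                        source = as.character(e$source),
                        stringsAsFactors = FALSE)
      out[[field]] <- as.numeric(e[[field]])
      out
    }))
  }
  phase_df <- function(lst) {
    if (is.null(lst) || !length(lst)) return(NULL)
    do.call(rbind, lapply(lst, function(e)
      data.frame(a = as.character(e$a), b = as.character(e$b),
                 relation = as.character(e$relation),
                 stringsAsFactors = FALSE)))
  }
  constraints <- constraint_set(
    nodes,
    forced_edges = edge_mat(cb$forced_edges),
    forbidden_edges = edge_mat(cb$forbidden_edges),
    sign_constraints = edge_df(cb$sign_constraints, "sign"),
    value_constraints = edge_df(cb$value_constraints, "value"),
    phase_constraints = phase_df(cb$phase_constraints),
    fixed_diffusion = if (!is.null(cb$fixed_diffusion))
      unlist(cb$fixed_diffusion),
    no_diffusible_to_diffusible =
      isTRUE(cb$no_diffusible_to_diffusible),
    diffusible_self_inhibition =
      isTRUE(cb$diffusible_self_inhibition))
  sampling <- list(budget = 20000L, seed = 1L, robustness_n = 2000L,
                   criterion = "band")
  if (!is.null(cfg$sampling)) {
    sunknown <- setdiff(names(cfg$sampling), names(sampling))
    if (length(sunknown))
      stop("unknown sampling key(s): ", paste(sunknown, collapse = ", "))
    sampling[names(cfg$sampling)] <- cfg$sampling
  }
  regime <- cfg$regime %||% "free"
  stopifnot(regime %in% c("free", "equal", "fixed", "universal"))
  structure(list(name = cfg$name %||% basename(path),
                 description = cfg$description %||% "",
                 nodes = nodes, k = k, constraints = constraints,
                 regime = regime, sampling = sampling),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %s: %d nodes (%d diffusible), k = %d, regime %s\n",
              x$name, nrow(x$nodes), sum(x$nodes$diffusible), x$k, x$regime))
  invisible(x)
}

#' Run a screen from a configuration
#'
#' Thin wrapper over [run_pipeline()] taking a `run_config` (or the path
#' of one, or a fixture name).
#'
#' @param config a `run_config`, a config file path, or a [fixture()]
#'   name.
#' @param seed overrides the config's sampling seed.
#' @param budget overrides the config's sampling budget.
#' @param ... further arguments to [run_pipeline()].
#' @return an `rd_catalog`.
#' @export
run_screen <- function(config, seed = NULL, budget = NULL, ...) {
  if (is.character(config)) {
    config <- if (file.exists(config)) parse_config(config)
              else fixture(config)
  }
  stopifnot(inherits(config, "run_config"))
  run_pipeline(config$nodes, config$k, constraints = config$constraints,
               regime = config$regime,
               criterion = config$sampling$criterion,
               budget = as.integer(budget %||% config$sampling$budget),
               robustness_n = as.integer(config$sampling$robustness_n),
               seed = as.integer(seed %||% config$sampling$seed), ...)
}

catalog_to_list <- function(catalog) {
  list(
    seed = catalog$seed, regime = catalog$regime,
    criterion = catalog$criterion %||% "band", k = catalog$k,
    budget = catalog$budget,
    nodes = lapply(seq_len(nrow(catalog$nodes)), function(i)
      list(label = catalog$nodes$label[i],
           diffusible = catalog$nodes$diffusible[i])),
    steps = catalog$steps,
    entries = lapply(catalog$entries, function(e) {
      ts <- cell_from_index(e$network$cells, nrow(catalog$nodes))
      list(key = as.character(e$key), type = e$type,
           n_phase_patterns = e$n_phase_patterns,
           edges = lapply(seq_len(nrow(ts)), function(r)
             list(target = ts[r, "target"], source = ts[r, "source"])),
           topologies = lapply(e$topologies, function(tp)
             list(signs = tp$signs, values = tp$values,
                  phase = as.integer(tp$phase),
                  type = tp$type, certificate = isTRUE(tp$certificate),
                  robustness = tp$robustness,
                  robustness_se = tp$robustness_se,
                  witness = list(J = tp$witness$J, D = tp$witness$D,
                                 seed = tp$witness$seed))))
    }))
}

#' Write a catalog to disk
#'
#' `format = "json"` writes the full catalog — networks, surviving
#' topologies, phases, robustness, and replayable witnesses with their
#' seeds; [read_catalog()] reconstructs it. `format = "csv"` writes the
#' one-row-per-network summary of [summary.rd_catalog()].
#'
#' @param catalog an `rd_catalog`.
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(catalog, "rd_catalog"))
  if (format == "csv") {
    utils::write.csv(summary(catalog), path, row.names = FALSE)
  } else {
    jsonlite::write_json(catalog_to_list(catalog), path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a JSON catalog back into an `rd_catalog`
#'
#' @param path a file written by [write_catalog()] with `format = "json"`.
#' @return an `rd_catalog`.
#' @export
read_catalog <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  labs <- vapply(x$nodes, function(nd) as.character(nd$label), character(1L))
  dif <- vapply(x$nodes, function(nd) isTRUE(nd$diffusible), logical(1L))
  nodes <- rd_nodes(dif, labs)
  steps <- do.call(rbind, lapply(x$steps, function(r)
    data.frame(step = r$step, networks = r$networks,
               topologies = r$topologies, stringsAsFactors = FALSE)))
  entries <- lapply(x$entries, function(e) {
    edges <- do.call(rbind, lapply(e$edges, function(ed)
      c(ed$target, ed$source)))
    net <- rd_network(nodes, edges)
    tops <- lapply(e$topologies, function(tp) {
      J <- do.call(rbind, lapply(tp$witness$J, unlist))
      ph <- unlist(tp$phase)
      names(ph) <- labs
      list(signs = unlist(tp$signs),
           values = if (is.null(tp$values)) NULL else unlist(tp$values),
           witness = list(J = J,
                          D = if (is.null(tp$witness$D)) NULL
                              else unlist(tp$witness$D),
                          seed = tp$witness$seed),
           certificate = isTRUE(tp$certificate),
           phase = as.integer(ph) * 1L,
           type = tp$type, robustness = tp$robustness %||% NA_real_,
           robustness_se = tp$robustness_se %||% NA_real_)
    })
    for (tp_i in seq_along(tops))
      names(tops[[tp_i]]$phase) <- labs
    list(network = net, key = e$key, type = e$type,
         n_phase_patterns = e$n_phase_patterns, topologies = tops)
  })
  structure(list(entries = entries, steps = steps, seed = x$seed,
                 regime = x$regime, criterion = x$criterion, nodes = nodes,
                 k = x$k, budget = x$budget), class = "rd_catalog")
}

#' Built-in screen fixtures
#'
#' Canned configurations for the worked systems: the classical 2-node
#' control, the unconstrained 3- and 4-node catalogs, the extended
#' Nodal/Lefty screen, the BMP/Sox9/Wnt digit-patterning screens (3- and
#' 5-node), the synthetic yeast IP-signaling screen, and a ready-made
#' capacitor system (`type3_capacitor`, returned as an [rd_system()]).
#'
#' @param name one of `two_node`, `three_node_full`, `four_node_full`,
#'   `nodal_lefty`, `bsw_three_node`, `bsw_five_node`, `yeast_ip`,
#'   `type3_capacitor`.
#' @return a `run_config`, or an `rd_system` for `type3_capacitor`.
#' @examples
#' fixture("two_node")
#' @export
fixture <- function(name) {
  valid <- c("two_node", "three_node_full", "four_node_full", "nodal_lefty",
             "bsw_three_node", "bsw_five_node", "yeast_ip",
             "type3_capacitor")
  if (!name %in% valid)
    stop("unknown fixture '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  path <- system.file("extdata", "fixtures", paste0(name, ".json"),
                      package = "turingnets", mustWork = TRUE)
  if (name == "type3_capacitor") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(rd_system(J = x$J, D = x$D, labels = x$labels))
  }
  parse_config(path)
}
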