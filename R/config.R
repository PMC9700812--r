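# Configuration loading and output writers.

#' Load a run configuration
#'
#' Reads a YAML or JSON configuration. Recognized top-level keys:
#' `parameters` (any of the model parameter names; `mdt` may be given
#' instead of `mu`, in which case `mu = ln 2 / mdt` is computed), `rules`
#' (a mutant label, or a named list of Boolean expressions overriding
#' individual target functions), and `seed`. Omitted parameters keep their
#' defaults; unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file. An empty file
#'   yields the full default configuration.
#' @return List of class `bkmc_config` with elements `params`
#'   ([default_params()] object), `rules` ([ruleset()]), `seed` (or `NULL`)
#'   and `raw` (the parsed file contents).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c("parameters", "rules", "seed"))
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  pars <- raw$parameters
  if (is.null(pars)) pars <- list()
  pars <- as.list(pars)
  if (!is.null(pars$mdt)) {
    if (!is.null(pars$mu)) stop("give either mu or mdt, not both")
    if (!is.numeric(pars$mdt) || pars$mdt <= 0) stop("mdt must be positive")
    pars$mu <- log(2) / pars$mdt
    pars$mdt <- NULL
  }
  params <- do.call(default_params, pars)
  rules <- raw$rules
  rules <- if (is.null(rules)) {
    ruleset()
  } else if (is.character(rules) && length(rules) == 1L) {
    mutant_ruleset(rules)
  } else {
    ruleset(label = "custom", targets = as.list(rules))
  }
  structure(list(params = params, rules = rules, seed = raw$seed, raw = raw),
            class = "bkmc_config")
}

#' Write a population event log as CSV
#'
#' One row per event with the cell's identity and pedigree, suitable for
#' downstream analysis outside R. Output is deterministic for a fixed seed
#' and configuration.
#'
#' @param pop A [run_population()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(pop, path) {
  ev <- merge(pop$events,
              pop$cells[, c("cell_id", "parent_id", "pedigree")],
              by = "cell_id", sort = FALSE)
  ev <- ev[order(ev$cell_id, ev$time),
           c("cell_id", "parent_id", "pedigree", "time", "kind", "variable",
             "state", "size")]
  names(ev)[names(ev) == "time"] <- "time_min"
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' @param x A list (or data frame) of results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Structural report on a transition graph
#'
#' Node/edge counts, acyclicity, roots and sinks, the recurrent highway and
#' the expected return-step summary, collected into one list (the payload of
#' the command-line `graph` report).
#'
#' @param rules,params Model rule set and parameters.
#' @return List with the quantities above.
#' @export
graph_report <- function(rules = ruleset(), params = default_params()) {
  g <- build_graph(rules, params, include_start_edge = FALSE)
  gs <- build_graph(rules, params, include_start_edge = TRUE)
  ka <- is_acyclic(g)
  rs <- graph_roots_sinks(g)
  hw <- tryCatch(find_highway(gs), error = function(e) NULL)
  steps <- tryCatch(
    steps_to_highway(g, highway = if (is.null(hw))
      highway_reference()$state else hw$state),
    error = function(e) NULL)
  list(
    n_states = length(g$states),
    n_edges = nrow(g$edges),
    acyclic_without_start_edge = ka$acyclic,
    roots = rs$roots, sinks = rs$sinks,
    highway = if (!is.null(hw)) hw$state else NULL,
    mean_steps_off_highway = if (!is.null(steps)) steps$mean_off_highway
      else NULL,
    mean_steps_component = if (!is.null(steps)) steps$mean_component
      else NULL,
    n_off_highway = if (!is.null(steps)) steps$n_off_highway else NULL
  )
}
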