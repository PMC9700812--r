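# The 128-node asynchronous state-transition graph and its analysis.

.HIGHWAY_STRINGS <- c(
  "1000000", "1100000", "1110000", "0110000", "0111000", "0111100",
  "0011100", "0001100", "0001110", "0001111", "0000111", "0000101",
  "1000101", "1000001"
)

.HIGHWAY_EVENTS <- c(
  "Newborn cell (G1)", "SBF turns on (Start)", "Cln2 turns on (bud emergence)",
  "Cdh1 turns off", "Clb5 turns on (S phase)", "Clb2G turns on (prophase)",
  "SBF turns off", "Cln2 turns off", "Clb2M turns on (metaphase)",
  "Cdc20 turns on (anaphase)", "Clb5 turns off", "Clb2M turns off (telophase)",
  "Cdh1 turns on", "Clb2G turns off (Exit)"
)

#' The 14-state cell-cycle highway as published
#'
#' Reference sequence of the globally attracting cycle, with event labels.
#' Use [find_highway()] to derive the same sequence from the rules.
#'
#' @return Data frame with columns `state`, `event`.
#' @export
highway_reference <- function() {
  data.frame(state = .HIGHWAY_STRINGS, event = .HIGHWAY_EVENTS,
             stringsAsFactors = FALSE)
}

#' Build the asynchronous state-transition graph
#'
#' One node per Boolean state; a directed edge for every single-variable
#' update enabled by the rules, weighted by the variable's flip propensity.
#' The size-gated Start edge (`1000000 -> 1100000`) is excluded by default,
#' in which case the wild-type graph is a DAG with the newborn G1 state as
#' its only sink.
#'
#' @param rules A [ruleset()].
#' @param params Parameters (propensity constants are used as edge rates).
#' @param include_start_edge Add the Start edge `1000000 -> 1100000`?
#' @return Object of class `bkmc_graph`: list with `states` (128 state
#'   strings), `edges` (data frame: `from`, `to`, `variable`, `rate`,
#'   `from_idx`, `to_idx`, `start_edge`), and the build flags.
#' @export
build_graph <- function(rules = ruleset(), params = default_params(),
                        include_start_edge = FALSE) {
  S <- all_states()
  cand <- candidate_table(rules, sbf_gate = FALSE)
  pv <- .propensity_vector(params)
  from_idx <- integer(0); var <- integer(0)
  for (j in seq_len(.NVAR)) {
    en <- which(cand[, j] != S[, j])
    from_idx <- c(from_idx, en)
    var <- c(var, rep.int(j, length(en)))
  }
  to_idx <- from_idx + ifelse(S[cbind(from_idx, var)] == 1L,
                              -2L^(7L - var), 2L^(7L - var))
  rate <- pv[var]
  start_edge <- rep(FALSE, length(from_idx))
  if (include_start_edge) {
    from_idx <- c(from_idx, .SINK_IDX)
    to_idx <- c(to_idx, state_index(string_to_state("1100000")))
    var <- c(var, .I_SBF)
    rate <- c(rate, pv[.I_SBF])
    start_edge <- c(start_edge, TRUE)
  }
  states <- state_to_string(S)
  o <- order(from_idx, var)
  edges <- data.frame(
    from = states[from_idx[o]], to = states[to_idx[o]],
    variable = .VARS[var[o]], rate = rate[o],
    from_idx = from_idx[o], to_idx = to_idx[o], start_edge = start_edge[o],
    stringsAsFactors = FALSE
  )
  structure(list(states = states, edges = edges,
                 include_start_edge = include_start_edge,
                 rules_label = rules$label),
            class = "bkmc_graph")
}

#' @export
print.bkmc_graph <- function(x, ...) {
  cat("Asynchronous Boolean state-transition graph (", x$rules_label, ")\n",
      sep = "")
  cat(length(x$states), "states,", nrow(x$edges), "edges;",
      if (x$include_start_edge) "Start edge included" else "growth-free", "\n")
  invisible(x)
}

#' Acyclicity test by Kahn's algorithm
#'
#' Repeatedly removes nodes of in-degree zero. If all nodes are removed the
#' graph is acyclic and the removal order is a topological order.
#'
#' @param graph A [build_graph()] result.
#' @return List with `acyclic` (logical) and `order` (character vector of
#'   state strings in topological order when acyclic, otherwise `NULL`).
#' @export
is_acyclic <- function(graph) {
  n <- length(graph$states)
  indeg <- tabulate(graph$edges$to_idx, nbins = n)
  out_by_node <- split(graph$edges$to_idx, factor(graph$edges$from_idx,
                                                  levels = seq_len(n)))
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (w in out_by_node[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(ord) == n) {
    list(acyclic = TRUE, order = graph$states[ord])
  } else {
    list(acyclic = FALSE, order = NULL)
  }
}

#' Roots and sinks of the graph
#'
#' @param graph A [build_graph()] result.
#' @return List with `roots` (in-degree 0) and `sinks` (out-degree 0),
#'   as state strings.
#' @export
graph_roots_sinks <- function(graph) {
  n <- length(graph$states)
  indeg <- tabulate(graph$edges$to_idx, nbins = n)
  outdeg <- tabulate(graph$edges$from_idx, nbins = n)
  list(roots = graph$states[indeg == 0L], sinks = graph$states[outdeg == 0L])
}

#' Extract the recurrent cell-cycle highway
#'
#' With the Start edge included, the wild-type graph has a unique recurrent
#' cycle. It is found as the unique non-trivial strongly connected component
#' and ordered by following successors from the newborn G1 state.
#'
#' @param graph A [build_graph()] result with `include_start_edge = TRUE`.
#' @return Data frame with columns `state`, `event` (event labels are filled
#'   in for the wild-type sequence, `NA` otherwise).
#' @export
find_highway <- function(graph) {
  if (!graph$include_start_edge) {
    stop("the highway is a cycle only when the Start edge is included")
  }
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = graph$states)
  )
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  big <- which(sizes > 1L)
  if (length(big) != 1L) {
    stop("expected exactly one recurrent class, found ", length(big))
  }
  members <- graph$states[comp$membership == big]
  # order by following the unique successor within the class
  succ <- split(graph$edges$to, graph$edges$from)
  start <- if ("1000000" %in% members) "1000000" else members[[1L]]
  ord <- character(0)
  cur <- start
  repeat {
    ord <- c(ord, cur)
    nxt <- intersect(succ[[cur]], members)
    if (length(nxt) != 1L) {
      stop("highway state ", cur, " has ", length(nxt),
           " successors inside the recurrent class")
    }
    cur <- nxt
    if (cur == start) break
    if (length(ord) > length(members)) stop("failed to order recurrent class")
  }
  ev <- .HIGHWAY_EVENTS[match(ord, .HIGHWAY_STRINGS)]
  data.frame(state = ord, event = ev, stringsAsFactors = FALSE)
}

#' Expected number of steps to reach the highway
#'
#' On the growth-free graph, the embedded jump chain moves from a state to a
#' successor with probability proportional to the edge propensity. For every
#' state the expected number of Boolean updates until the first visit to a
#' highway state is solved exactly from the first-step linear equations;
#' the exact step-count distribution is also computed up to `horizon` steps.
#'
#' Because the averaging set behind a single summary number is a matter of
#' convention, two overall means are reported: the uniform average over all
#' off-highway states, and the uniform average over the off-highway states
#' that are not themselves immediate predecessors of nothing (i.e. all
#' off-highway states reachable in the enumeration; see the methods
#' vignette).
#'
#' @param graph Growth-free [build_graph()] result.
#' @param highway Character vector of highway state strings; defaults to the
#'   published 14-state sequence.
#' @param horizon Maximum step count for the exact distribution.
#' @return List with `expected` (named 128-vector; 0 on the highway),
#'   `distribution` (matrix, rows = states, cols = 0..horizon steps),
#'   `mean_off_highway`, and `n_off_highway`.
#' @export
steps_to_highway <- function(graph, highway = highway_reference()$state,
                             horizon = 25L) {
  if (graph$include_start_edge) {
    stop("use the growth-free graph (include_start_edge = FALSE)")
  }
  n <- length(graph$states)
  hw <- graph$states %in% highway
  # jump-chain transition matrix
  P <- matrix(0, n, n)
  e <- graph$edges
  P[cbind(e$from_idx, e$to_idx)] <- e$rate
  rs <- rowSums(P)
  pos <- rs > 0
  P[pos, ] <- P[pos, ] / rs[pos]
  off <- which(!hw)
  if (any(rs[off] == 0)) {
    stop("an off-highway state has no outgoing transition; it cannot reach ",
         "the highway")
  }
  Q <- P[off, off, drop = FALSE]
  E <- rep(0, n)
  E[off] <- solve(diag(length(off)) - Q, rep(1, length(off)))
  names(E) <- graph$states
  # exact distribution: prob of first hitting at exactly k steps
  D <- matrix(0, n, horizon + 1L,
              dimnames = list(graph$states, 0:horizon))
  D[hw, 1L] <- 1
  reach <- as.numeric(hw)  # prob of having hit by step k
  Dk <- reach
  for (k in seq_len(horizon)) {
    Dk_new <- as.vector(P %*% Dk)
    Dk_new[hw] <- 1
    D[, k + 1L] <- Dk_new - Dk
    Dk <- Dk_new
  }
  # second averaging set: the largest weakly connected component of the
  # subgraph induced on off-highway states (the big circular component of
  # the usual layout; for the wild-type rules it contains all 114 states)
  offs <- graph$states[off]
  eo <- e[e$from %in% offs & e$to %in% offs, , drop = FALSE]
  go <- igraph::graph_from_data_frame(eo[, c("from", "to")], directed = TRUE,
                                      vertices = data.frame(name = offs))
  wc <- igraph::components(go, mode = "weak")
  comp <- offs[wc$membership == which.max(wc$csize)]
  list(expected = E,
       distribution = D,
       mean_off_highway = mean(E[off]),
       n_off_highway = length(off),
       mean_component = mean(E[comp]),
       n_component = length(comp))
}

#' Export a transition graph
#'
#' @param graph A [build_graph()] result.
#' @param path Output file path.
#' @param format One of `"csv"` (edge list), `"dot"`, `"json"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("csv", "dot", "json")) {
  format <- match.arg(format)
  e <- graph$edges[order(graph$edges$from, graph$edges$variable), , drop = FALSE]
  if (format == "csv") {
    utils::write.csv(
      data.frame(from_state = e$from, to_state = e$to,
                 variable = e$variable, rate = e$rate),
      path, row.names = FALSE, quote = FALSE)
  } else if (format == "dot") {
    lines <- c("digraph bkmc {",
               sprintf("  \"%s\" -> \"%s\" [label=\"%s\", weight=%g];",
                       e$from, e$to, e$variable, e$rate),
               "}")
    writeLines(lines, path)
  } else {
    jsonlite::write_json(
      list(states = graph$states,
           edges = data.frame(from = e$from, to = e$to,
                              variable = e$variable, rate = e$rate)),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
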