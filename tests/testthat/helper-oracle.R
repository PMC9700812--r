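# Independent oracles used to cross-check the implementation.

# Literal, scalar evaluation of the published target functions, written as
# plain boolean logic over named variables (deliberately a different code
# path from the package's vectorized truth tables).
oracle_candidates <- function(state, gate = FALSE) {
  v <- as.list(state == 1L)
  names(v) <- c("Cdh1", "SBF", "Cln2", "Clb5", "Clb2G", "Clb2M", "Cdc20")
  g1 <- state[1] == 1L && sum(state) == 1L  # state is exactly 1000000
  with(v, c(
    Cdh1  = !(Cln2 | Clb5 | Clb2G | Clb2M) | (Cdc20 & !(Cln2 | Clb5 | Clb2M)),
    SBF   = (gate && g1) | (SBF & !(Clb2G | Clb2M)),
    Cln2  = SBF,
    Clb5  = (Clb5 | SBF) & !(Cdh1 | Cdc20),
    Clb2G = Clb2M | ((Clb5 | Clb2G) & !Cdh1),
    Clb2M = (Clb2G | Clb2M) & !Cdh1 & (!Cdc20 | Clb5) & !Cln2,
    Cdc20 = Clb2M | (Clb2G & Cdc20)
  )) * 1L
}

# Expected steps to the highway by direct memoized recursion on the jump
# chain (independent of the package's linear solve).
oracle_hitting_steps <- function(graph, highway) {
  succ <- split(seq_len(nrow(graph$edges)), graph$edges$from)
  memo <- new.env(parent = emptyenv())
  rec <- function(s) {
    if (s %in% highway) return(0)
    hit <- memo[[s]]
    if (!is.null(hit)) return(hit)
    rows <- succ[[s]]
    w <- graph$edges$rate[rows]
    w <- w / sum(w)
    val <- 1 + sum(w * vapply(graph$edges$to[rows], rec, numeric(1)))
    memo[[s]] <- val
    val
  }
  vapply(graph$states, rec, numeric(1))
}

# Monte-Carlo hitting steps for a single start state.
mc_hitting_steps <- function(graph, highway, start, n = 2000L) {
  succ <- split(seq_len(nrow(graph$edges)), graph$edges$from)
  vapply(seq_len(n), function(i) {
    s <- start; k <- 0L
    while (!(s %in% highway)) {
      rows <- succ[[s]]
      w <- graph$edges$rate[rows]
      s <- graph$edges$to[rows][sample.int(length(rows), 1L, prob = w)]
      k <- k + 1L
    }
    as.numeric(k)
  }, numeric(1))
}

# Published Table of aberrant single-flip perturbations: state, variable,
# percent resuming normal progression (5000 repeats each), and the footnote
# class of the abnormal outcomes.
published_aberrant_rows <- function() {
  data.frame(
    highway_state = c("1000000", "1000000", "1100000", "1100000", "0111000",
                      "0111100", "0111100", "0011100", "0011100", "0001100",
                      "0001100", "0001110"),
    variable = c("Clb2G", "Clb2M", "Clb2G", "Clb2M", "Cdc20", "Cdh1",
                 "Cdc20", "Cdh1", "Cdc20", "Cdh1", "Cdc20", "Cdh1"),
    pct_normal = c(50.40, 16.50, 50.16, 16.22, 73.52, 49.48, 23.04, 49.98,
                   46.48, 49.72, 50.82, 87.12),
    class = c("no_bud_exit", "no_bud_exit", "no_bud_exit", "no_bud_exit",
              "exit_without_Clb2M", "exit_without_Cdc20",
              "exit_without_Clb2M", "exit_without_Cdc20",
              "exit_without_Clb2M", "exit_without_Cdc20",
              "exit_without_Clb2M", "exit_without_Cdc20"),
    stringsAsFactors = FALSE
  )
}

# Shared moderate-size wild-type population run (computed once per suite).
wt_population <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(424242)
      cache <<- run_population(n_founders = 3L, horizon = 900)
    }
    cache
  }
})
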