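# Continuous-time Boolean kinetic Monte-Carlo engine: Gillespie-style
# asynchronous updating, exponential size growth, size-gated Start,
# lognormal mitotic delays and unequal division.

.KIND_FLIP <- 1L; .KIND_DIVISION <- 2L; .KIND_START <- 3L; .KIND_WAIT <- 4L
.KIND_LABELS <- c("flip", "division", "start", "g1_wait")

# Precomputed single-variable update structure of the jump chain.
# For each of the 128 states: enabled variables (in component order, which is
# also the selection order of the smallest-index rule), their flip direction,
# successor state index, rate, cumulative rate and total propensity P0.
.jump_struct <- function(rules = ruleset(), params = default_params()) {
  S <- all_states()
  cand <- candidate_table(rules, sbf_gate = FALSE)
  pv <- .propensity_vector(params)
  en <- cand != S
  deg <- as.integer(rowSums(en))
  maxd <- max(deg, 1L)
  succ <- matrix(0L, 128L, maxd); var <- matrix(0L, 128L, maxd)
  dir <- matrix(0L, 128L, maxd); cum <- matrix(0, 128L, maxd)
  for (s in 1:128) {
    js <- which(en[s, ])
    if (!length(js)) next
    var[s, seq_along(js)] <- js
    dir[s, seq_along(js)] <- cand[s, js]
    succ[s, seq_along(js)] <- s + ifelse(S[s, js] == 1L, -2L^(7L - js),
                                         2L^(7L - js))
    cum[s, seq_along(js)] <- cumsum(pv[js])
  }
  list(deg = deg, succ = succ, var = var, dir = dir, cum = cum,
       P0 = ifelse(deg > 0L, cum[cbind(1:128, pmax(deg, 1L))], 0),
       pv = pv)
}

#' Resolve the parameters a rule set runs with
#'
#' Applies a rule set's parameter overrides (e.g. a raised `S0_mean` for a
#' larger mutant) on top of a base parameter list.
#'
#' @param params Base parameters.
#' @param rules A [ruleset()].
#' @return Parameter list of class `bkmc_params`.
#' @export
resolve_params <- function(params = default_params(), rules = ruleset()) {
  ov <- rules$param_overrides
  if (length(ov)) params[names(ov)] <- ov
  validate_params(params)
  params
}

# Simulate one cell (one physical cell, possibly through several cycles)
# from its birth to the horizon. Returns the event log and the spawned
# daughters' birth records. Daughter S0 values are drawn at the division so
# results are reproducible under FIFO scheduling with a single RNG stream.
.simulate_lineage <- function(state_idx, size, s0, t0, horizon,
                              js, params, record_waits = FALSE,
                              max_divisions = Inf) {
  mu <- params$mu
  p_g1 <- params$p_G1
  ml <- log(params$t_M_mean); sl <- params$t_M_CV
  fml <- log(params$f_mean); fsl <- params$f_CV
  s0ml <- log(params$S0_mean); s0sl <- params$S0_CV
  p_sbf <- params$p_SBF

  cap <- 256L
  ev_t <- numeric(cap); ev_k <- integer(cap); ev_v <- integer(cap)
  ev_s <- integer(cap); ev_z <- numeric(cap)
  n_ev <- 0L
  d_t <- numeric(8L); d_z <- numeric(8L); d_s0 <- numeric(8L)
  n_d <- 0L

  s <- state_idx; t <- t0; z <- size
  n_div <- 0L

  push <- function(time, kind, v, st, sz) {
    if (n_ev == cap) {
      cap <<- cap * 2L
      length(ev_t) <<- cap; length(ev_k) <<- cap; length(ev_v) <<- cap
      length(ev_s) <<- cap; length(ev_z) <<- cap
    }
    n_ev <<- n_ev + 1L
    ev_t[n_ev] <<- time; ev_k[n_ev] <<- kind; ev_v[n_ev] <<- v
    ev_s[n_ev] <<- st; ev_z[n_ev] <<- sz
  }

  repeat {
    deg <- js$deg[s]
    gate_state <- s == .SINK_IDX
    if (gate_state) {
      open <- sbf_gate_open(z, s0, stats::runif(1L))
      if (open) {
        # SBF activation joins the race (for the wild-type rules it is the
        # only enabled transition in this state)
        p0 <- js$P0[s] + p_sbf
        r1 <- stats::runif(1L) * p0
        # selection in component order; SBF is component 2
        j <- 0L; acc <- 0
        sel_var <- .I_SBF; sel_dir <- 1L; sel_succ <- s + 32L
        k <- 1L
        while (k <= deg && js$var[s, k] < .I_SBF) {
          if (js$cum[s, k] > r1) { j <- k; break }
          k <- k + 1L
        }
        if (j == 0L) {
          base <- if (k > 1L) js$cum[s, k - 1L] else 0
          if (base + p_sbf > r1) {
            j <- -1L  # SBF selected
          } else {
            while (k <= deg) {
              if (js$cum[s, k] + p_sbf > r1) { j <- k; break }
              k <- k + 1L
            }
          }
        }
        if (j > 0L) {
          sel_var <- js$var[s, j]; sel_dir <- js$dir[s, j]
          sel_succ <- js$succ[s, j]
        }
      } else {
        p0 <- js$P0[s]
        if (p0 == 0) {
          dt <- stats::rexp(1L, p_g1)
          tn <- t + dt
          if (tn > horizon) { z <- z * exp(mu * (horizon - t)); t <- horizon; break }
          z <- z * exp(mu * dt); t <- tn
          if (record_waits) push(t, .KIND_WAIT, 0L, s, z)
          next
        }
        r1 <- stats::runif(1L) * p0
        j <- 1L
        while (js$cum[s, j] <= r1) j <- j + 1L
        sel_var <- js$var[s, j]; sel_dir <- js$dir[s, j]
        sel_succ <- js$succ[s, j]
      }
    } else {
      p0 <- js$P0[s]
      if (p0 == 0) {
        # absorbing non-G1 state (possible under mutant rules): size keeps
        # growing but no further Boolean events occur
        z <- z * exp(mu * (horizon - t)); t <- horizon
        break
      }
      r1 <- stats::runif(1L) * p0
      j <- 1L
      while (js$cum[s, j] <= r1) j <- j + 1L
      sel_var <- js$var[s, j]; sel_dir <- js$dir[s, j]
      sel_succ <- js$succ[s, j]
    }

    # waiting time: lognormal for the delayed activations of Clb2M and
    # Cdc20, exponential with rate P0 otherwise
    if (sel_dir == 1L && (sel_var == .I_CLB2M || sel_var == .I_CDC20)) {
      dt <- stats::rlnorm(1L, ml, sl)
    } else {
      dt <- stats::rexp(1L, p0)
    }
    tn <- t + dt
    if (tn > horizon) { z <- z * exp(mu * (horizon - t)); t <- horizon; break }
    z <- z * exp(mu * dt); t <- tn
    s <- sel_succ

    if (sel_var == .I_CLB2G && sel_dir == 0L) {
      # division at the Clb2G switch-off
      f <- stats::rlnorm(1L, fml, fsl)
      while (f <= 0 || f >= 1) f <- stats::rlnorm(1L, fml, fsl)
      zd <- (1 - f) * z
      z <- f * z
      s0 <- stats::rlnorm(1L, s0ml, s0sl)
      n_d <- n_d + 1L
      if (n_d > length(d_t)) {
        length(d_t) <- 2L * n_d; length(d_z) <- 2L * n_d
        length(d_s0) <- 2L * n_d
      }
      d_t[n_d] <- t; d_z[n_d] <- zd
      d_s0[n_d] <- stats::rlnorm(1L, s0ml, s0sl)
      push(t, .KIND_DIVISION, .I_CLB2G, s, z)
      n_div <- n_div + 1L
      if (n_div >= max_divisions) break
    } else if (gate_state && sel_var == .I_SBF && sel_dir == 1L) {
      push(t, .KIND_START, .I_SBF, s, z)
    } else {
      push(t, .KIND_FLIP, sel_var, s, z)
    }
  }

  list(
    events = list(time = ev_t[seq_len(n_ev)], kind = ev_k[seq_len(n_ev)],
                  variable = ev_v[seq_len(n_ev)], state = ev_s[seq_len(n_ev)],
                  size = ev_z[seq_len(n_ev)]),
    daughters = list(time = d_t[seq_len(n_d)], size = d_z[seq_len(n_d)],
                     s0 = d_s0[seq_len(n_d)]),
    final_state = s, final_size = z, final_s0 = s0, final_time = t
  )
}

#' Perform one stochastic update step
#'
#' Runs a single iteration of the kinetic Monte-Carlo scheme from a given
#' state: evaluates the size gate (with a fresh uniform draw) if the cell is
#' in the newborn G1 state, selects the variable to flip by the
#' smallest-index rule, draws the waiting time (exponential with rate P0, or
#' lognormal for Clb2M/Cdc20 activations, or an exponential G1 wait with
#' rate `p_G1` when no variable can change), and grows the cell.
#'
#' @param state 7-digit string or 0/1 vector; current Boolean state.
#' @param size,s0 Current size and the cell's critical size.
#' @param params,rules Model parameters and rule set (overrides applied).
#' @param time Current clock (min).
#' @return List with `state` (string), `size`, `time`, `dt`, `kind`
#'   (one of `"flip"`, `"division"`, `"start"`, `"g1_wait"`), and `variable`
#'   (flipped variable name or `NA`).
#' @export
step_cell <- function(state, size, s0, params = default_params(),
                      rules = ruleset(), time = 0) {
  params <- resolve_params(params, rules)
  if (is.character(state)) state <- string_to_state(state)
  is_g1 <- state_index(state) == .SINK_IDX
  gate <- if (is_g1) sbf_gate_open(size, s0, stats::runif(1L)) else FALSE
  cand <- candidate_state(state, rules, sbf_gate = gate)
  pr <- propensities(state, cand, params)
  if (pr$P0 == 0) {
    dt <- stats::rexp(1L, params$p_G1)
    return(list(state = state_to_string(state),
                size = size * exp(params$mu * dt), time = time + dt, dt = dt,
                kind = "g1_wait", variable = NA_character_))
  }
  r1 <- stats::runif(1L) * pr$P0
  j <- which(cumsum(pr$P) > r1)[1L]
  activation <- state[j] == 0L
  dt <- if (activation && j %in% c(.I_CLB2M, .I_CDC20)) {
    stats::rlnorm(1L, log(params$t_M_mean), params$t_M_CV)
  } else {
    stats::rexp(1L, pr$P0)
  }
  state[j] <- 1L - state[j]
  kind <- if (j == .I_CLB2G && !activation) "division"
          else if (is_g1 && j == .I_SBF && activation) "start"
          else "flip"
  list(state = state_to_string(state), size = size * exp(params$mu * dt),
       time = time + dt, dt = dt, kind = kind, variable = .VARS[j])
}

#' Divide a cell unequally
#'
#' The mother keeps a lognormal fraction `f` of the size (redrawn in the
#' rare case a draw falls outside (0,1)); the daughter receives the rest.
#' Both progeny receive freshly drawn critical sizes.
#'
#' @param size Cell size at the division instant.
#' @param params Model parameters.
#' @return List with `mother` and `daughter`, each containing `size` and `s0`.
#' @export
divide_cell <- function(size, params = default_params()) {
  f <- stats::rlnorm(1L, log(params$f_mean), params$f_CV)
  while (f <= 0 || f >= 1) f <- stats::rlnorm(1L, log(params$f_mean), params$f_CV)
  s0m <- stats::rlnorm(1L, log(params$S0_mean), params$S0_CV)
  s0d <- stats::rlnorm(1L, log(params$S0_mean), params$S0_CV)
  list(mother = list(size = f * size, s0 = s0m),
       daughter = list(size = (1 - f) * size, s0 = s0d))
}

#' Simulate a single cell lineage
#'
#' Follows one physical cell from a starting state to the horizon (daughters
#' are recorded at each division but not simulated; see [run_population()]
#' for full populations).
#'
#' @param state Initial Boolean state (7-digit string), typically `"1000000"`.
#' @param size Initial size; 0.65 is the average size of a mother cell after
#'   division.
#' @param s0 Critical size; drawn from the birth distribution if `NULL`.
#' @param params,rules Model parameters and rule set.
#' @param horizon Simulation end time (min); must be positive.
#' @param max_divisions Stop after this many divisions (default unlimited).
#' @param record_waits Log G1 waiting events?
#' @return List with `events` (data frame: `time`, `kind`, `variable`,
#'   `state`, `size`), `daughters` (data frame: `time`, `size`, `s0`), and
#'   the final `state`, `size` and `time`.
#' @export
simulate_cell <- function(state = "1000000", size = 0.65, s0 = NULL,
                          params = default_params(), rules = ruleset(),
                          horizon = 400, max_divisions = Inf,
                          record_waits = FALSE) {
  if (!is.infinite(horizon) && horizon <= 0) stop("horizon must be positive")
  params <- resolve_params(params, rules)
  if (is.null(s0)) s0 <- stats::rlnorm(1L, log(params$S0_mean), params$S0_CV)
  js <- .jump_struct(rules, params)
  res <- .simulate_lineage(state_index(string_to_state(state)), size, s0, 0,
                           horizon, js, params, record_waits = record_waits,
                           max_divisions = max_divisions)
  states <- state_to_string(all_states())
  ev <- data.frame(
    time = res$events$time,
    kind = .KIND_LABELS[res$events$kind],
    variable = ifelse(res$events$variable > 0L, .VARS[res$events$variable],
                      NA_character_),
    state = states[res$events$state],
    size = res$events$size,
    stringsAsFactors = FALSE
  )
  dg <- data.frame(time = res$daughters$time, size = res$daughters$size,
                   s0 = res$daughters$s0)
  list(events = ev, daughters = dg,
       state = states[res$final_state], size = res$final_size,
       time = res$final_time)
}
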