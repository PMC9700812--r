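# Single-flip perturbation robustness screen.
#
# Each of the 14 highway states has five perturbable components (all except
# the variable just updated and the one to be updated next). A perturbed
# trajectory is followed, growth-free, until the stable G1 sink and its
# sequence of events is classified as normal or as one of three lethal
# patterns: division without bud emergence, division without Clb2M
# activation (no metaphase alignment), division without Cdc20 activation
# (no chromosome segregation).
#
# Bookkeeping conventions (see the methods vignette for the rationale):
# milestone *activity* (bud emergence, prophase entry, Clb2M and Cdc20
# activity) counts however the variable became active, including the
# perturbation flip itself; DNA replication and Cdc20 activation are
# credited as *events* only (a spontaneous 0->1 update, or highway history).
# Every spontaneous Clb2G 1->0 update is a division: if the cycle had
# neither a replication event nor a Cdc20 activation event the division is
# benign (the cell re-enters G1 and the cycle bookkeeping restarts),
# otherwise it completes the cycle and is classified.

.PCLASS <- c("normal", "no_bud_exit", "exit_without_Clb2M",
             "exit_without_Cdc20")

# variable updated on entry into each highway state (state 1 is entered by
# the Cdc20 switch-off that closes the previous cycle)
.HW_ENTER_VAR <- c(.I_CDC20, .I_SBF, .I_CLN2, .I_CDH1, .I_CLB5, .I_CLB2G,
                   .I_SBF, .I_CLN2, .I_CLB2M, .I_CDC20, .I_CLB5, .I_CLB2M,
                   .I_CDH1, .I_CLB2G)

.fresh_flags <- function() {
  c(budded = FALSE, prophased = FALSE, bud_ok = TRUE, replicated = FALSE,
    clb2m_seen = FALSE, cdc20_event = FALSE, cdc20_seen = FALSE)
}

# flags derived from a (post-division) state's current activities
.flags_from_state <- function(bits) {
  c(budded = unname(bits[.I_CLN2] == 1L || bits[.I_CLB5] == 1L),
    prophased = FALSE, bud_ok = TRUE, replicated = FALSE,
    clb2m_seen = FALSE, cdc20_event = FALSE,
    cdc20_seen = unname(bits[.I_CDC20]) == 1L)
}

# apply one variable change to the milestone flags.
# v: variable index; on: activation?; is_event: spontaneous update (TRUE) or
# perturbation flip (FALSE); post_bits: state bits after the change.
# Returns list(flags, outcome) where outcome is NULL, "benign" or a class.
.flag_step <- function(flags, v, on, is_event, post_bits) {
  if (on) {
    if (v == .I_CLN2 || v == .I_CLB5) flags[["budded"]] <- TRUE
    if (v == .I_CLB5 && is_event) flags[["replicated"]] <- TRUE
    if (v == .I_CLB2G) {
      if (!flags[["prophased"]]) {
        flags[["prophased"]] <- TRUE
        flags[["bud_ok"]] <- flags[["budded"]]
      }
      if (is_event) flags[["replicated"]] <- TRUE
    }
    if (v == .I_CLB2M) flags[["clb2m_seen"]] <- TRUE
    if (v == .I_CDC20) {
      flags[["cdc20_seen"]] <- TRUE
      if (is_event) flags[["cdc20_event"]] <- TRUE
    }
    return(list(flags = flags, outcome = NULL))
  }
  if (v == .I_CLB2G && is_event) {
    # division
    if (!flags[["replicated"]] && !flags[["cdc20_event"]]) {
      # nothing consequential happened: the cell re-enters G1 and the
      # cycle bookkeeping restarts
      return(list(flags = .flags_from_state(post_bits), outcome = "benign"))
    }
    if (flags[["replicated"]] && !flags[["clb2m_seen"]]) {
      # division of a replicated cell that never aligned chromosomes:
      # immediately lethal
      cls <- if (flags[["cdc20_seen"]]) "exit_without_Clb2M" else
        "exit_without_Cdc20"
      return(list(flags = flags, outcome = cls))
    }
    if (flags[["replicated"]] && !flags[["cdc20_seen"]]) {
      # metaphase was reached but Cdc20 has not fired; final judgement is
      # deferred to the arrival in stable G1 (flags keep accumulating)
      return(list(flags = flags, outcome = NULL))
    }
    cls <- if (!flags[["bud_ok"]]) "no_bud_exit" else "normal"
    return(list(flags = flags, outcome = cls))
  }
  list(flags = flags, outcome = NULL)
}

# classification on arrival in the stable G1 sink for walks not already
# absorbed at a division
.sink_class <- function(flags) {
  if (flags[["replicated"]]) {
    if (!flags[["cdc20_seen"]]) return("exit_without_Cdc20")
    if (!flags[["clb2m_seen"]]) return("exit_without_Clb2M")
    if (!flags[["bud_ok"]]) return("no_bud_exit")
    return("normal")
  }
  if (flags[["cdc20_event"]] && !flags[["bud_ok"]]) return("no_bud_exit")
  "normal"
}

# milestone flags accumulated along the highway up to entry into state k
.highway_flags <- function(k) {
  S <- all_states()
  hw_idx <- vapply(.HIGHWAY_STRINGS, function(s)
    state_index(string_to_state(s)), integer(1))
  flags <- .fresh_flags()
  if (k >= 2L) {
    for (j in 2:k) {
      v <- .HW_ENTER_VAR[j]
      bits <- S[hw_idx[j], ]
      # the cycle's bookkeeping boundary is the return to stable G1
      # (state 1), so the highway division entering state 14 accumulates
      # flags like any other event and its outcome is ignored
      flags <- .flag_step(flags, v, on = bits[v] == 1L, is_event = TRUE,
                          post_bits = bits)$flags
    }
  }
  flags
}

#' Enumerate the 70 single-state highway perturbations
#'
#' For each highway state, the five components that are neither the one just
#' updated nor the one to be updated next are flipped, one at a time. When
#' Clb2M is flipped on, Clb2G is also set on (high mitotic cyclin activity
#' implies the residual activity).
#'
#' @return Data frame with one row per perturbation: `highway_index`,
#'   `highway_state`, `variable`, `direction` (`"on"`/`"off"`),
#'   `coupled_clb2g` and `start_state` (the perturbed 7-digit state).
#' @export
enumerate_perturbations <- function() {
  S <- all_states()
  hw_idx <- vapply(.HIGHWAY_STRINGS, function(s)
    state_index(string_to_state(s)), integer(1))
  out <- list()
  for (k in 1:14) {
    prev_v <- .HW_ENTER_VAR[k]
    next_v <- .HW_ENTER_VAR[if (k == 14L) 1L else k + 1L]
    for (v in setdiff(1:7, c(prev_v, next_v))) {
      bits <- S[hw_idx[k], ]
      on <- bits[v] == 0L
      bits[v] <- 1L - bits[v]
      coupled <- FALSE
      if (v == .I_CLB2M && on && bits[.I_CLB2G] == 0L) {
        bits[.I_CLB2G] <- 1L
        coupled <- TRUE
      }
      out[[length(out) + 1L]] <- data.frame(
        highway_index = k, highway_state = .HIGHWAY_STRINGS[k],
        variable = .VARS[v], direction = if (on) "on" else "off",
        coupled_clb2g = coupled, start_state = state_to_string(bits),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# initial flags after applying a perturbation flip (not an event)
.perturbed_flags <- function(pert) {
  flags <- .highway_flags(pert$highway_index)
  bits <- string_to_state(pert$start_state)
  v <- match(pert$variable, .VARS)
  if (pert$direction == "on") {
    if (pert$coupled_clb2g) {
      st <- .flag_step(flags, .I_CLB2G, on = TRUE, is_event = FALSE,
                       post_bits = bits)
      flags <- st$flags
    }
    flags <- .flag_step(flags, v, on = TRUE, is_event = FALSE,
                        post_bits = bits)$flags
  }
  flags
}

#' Classify one perturbed trajectory
#'
#' Reference (scalar) implementation of the ordered-event rules. The
#' trajectory is the list of spontaneous single-variable updates from the
#' perturbed state to the stable G1 sink; highway history before the
#' perturbation is credited automatically.
#'
#' @param pert One row of [enumerate_perturbations()] (as a list or
#'   single-row data frame).
#' @param variables Character vector of flipped variable names, in order.
#' @return One of `"normal"`, `"no_bud_exit"`, `"exit_without_Clb2M"`,
#'   `"exit_without_Cdc20"`.
#' @export
classify_trace <- function(pert, variables) {
  flags <- .perturbed_flags(pert)
  bits <- string_to_state(pert$start_state)
  for (nm in variables) {
    v <- match(nm, .VARS)
    if (is.na(v)) stop("unknown variable: ", nm)
    on <- bits[v] == 0L
    bits[v] <- 1L - bits[v]
    st <- .flag_step(flags, v, on, is_event = TRUE, post_bits = bits)
    flags <- st$flags
    if (!is.null(st$outcome) && st$outcome != "benign") return(st$outcome)
  }
  if (state_index(bits) != .SINK_IDX) {
    stop("trace does not end at the G1 sink 1000000")
  }
  .sink_class(flags)
}

# flags packed as integers 0..127 for the vectorized screen and the oracle
.pack_flags <- function(flags) {
  sum(as.integer(flags) * 2L^(0:6)) + 1L
}

#' Run the Monte-Carlo perturbation screen
#'
#' Simulates `n_reps` growth-free trajectories from each perturbed state to
#' the G1 sink, selecting each update with probability proportional to its
#' propensity, and classifies every trajectory.
#'
#' @param n_reps Trajectories per perturbation (the published screen uses
#'   5000).
#' @param params Model parameters (propensity constants set the branch
#'   weights).
#' @param rules Rule set (wild-type for the published screen).
#' @param perturbations Data frame from [enumerate_perturbations()].
#' @return Data frame with, per perturbation, the fraction of each outcome
#'   class, `pct_normal`, `pct_abnormal` and `dominant_abnormal`; the overall
#'   normal fraction (in %) is attached as attribute `overall_normal_pct`.
#' @export
run_screen <- function(n_reps = 5000L, params = default_params(),
                       rules = ruleset(),
                       perturbations = enumerate_perturbations()) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  js <- .jump_struct(rules, params)
  maxd <- ncol(js$cum)
  cumI <- js$cum
  for (s in 1:128) if (js$deg[s] < maxd) {
    cumI[s, (js$deg[s] + 1L):maxd] <- Inf
  }
  S <- all_states()
  res <- perturbations
  counts <- matrix(0L, nrow(perturbations), 4L,
                   dimnames = list(NULL, .PCLASS))
  for (i in seq_len(nrow(perturbations))) {
    pert <- perturbations[i, ]
    f0 <- .perturbed_flags(pert)
    s0 <- state_index(string_to_state(pert$start_state))
    n <- n_reps
    s <- rep.int(s0, n)
    budded <- rep(f0[["budded"]], n); proph <- rep(f0[["prophased"]], n)
    budok <- rep(f0[["bud_ok"]], n); repl <- rep(f0[["replicated"]], n)
    clb2m <- rep(f0[["clb2m_seen"]], n); c20ev <- rep(f0[["cdc20_event"]], n)
    c20seen <- rep(f0[["cdc20_seen"]], n)
    cls <- integer(n)  # 0 = active
    if (s0 == .SINK_IDX) cls[] <- 1L
    it <- 0L
    while (any(cls == 0L)) {
      it <- it + 1L
      if (it > 1000L) stop("perturbed trajectory failed to absorb")
      a <- which(cls == 0L)
      ss <- s[a]
      if (any(js$deg[ss] == 0L)) stop("stuck in a non-sink state")
      u <- stats::runif(length(a)) * js$P0[ss]
      j <- rowSums(cumI[ss, , drop = FALSE] <= u) + 1L
      v <- js$var[cbind(ss, j)]
      on <- js$dir[cbind(ss, j)] == 1L
      s2 <- js$succ[cbind(ss, j)]
      # activations
      budded[a] <- budded[a] | (on & (v == .I_CLN2 | v == .I_CLB5))
      newp <- on & v == .I_CLB2G & !proph[a]
      budok[a] <- ifelse(newp, budded[a], budok[a])
      proph[a] <- proph[a] | (on & v == .I_CLB2G)
      repl[a] <- repl[a] | (on & (v == .I_CLB5 | v == .I_CLB2G))
      clb2m[a] <- clb2m[a] | (on & v == .I_CLB2M)
      c20ev[a] <- c20ev[a] | (on & v == .I_CDC20)
      c20seen[a] <- c20seen[a] | (on & v == .I_CDC20)
      # divisions
      dv <- !on & v == .I_CLB2G
      if (any(dv)) {
        benign <- dv & !repl[a] & !c20ev[a]
        if (any(benign)) {
          ib <- a[benign]; sb <- s2[benign]
          bits <- S[sb, , drop = FALSE]
          budded[ib] <- bits[, .I_CLN2] == 1L | bits[, .I_CLB5] == 1L
          proph[ib] <- FALSE; budok[ib] <- TRUE; repl[ib] <- FALSE
          clb2m[ib] <- FALSE; c20ev[ib] <- FALSE
          c20seen[ib] <- bits[, .I_CDC20] == 1L
        }
        lethal_m <- dv & !benign & repl[a] & !clb2m[a]
        if (any(lethal_m)) {
          il <- a[lethal_m]
          cls[il] <- ifelse(c20seen[il], 3L, 4L)
        }
        # divisions after metaphase but before any Cdc20 firing are judged
        # at the sink; completed cycles are classified here
        complete <- dv & !benign & !lethal_m & !(repl[a] & !c20seen[a])
        if (any(complete)) {
          ic <- a[complete]
          cls[ic] <- ifelse(budok[ic], 1L, 2L)
        }
      }
      s[a] <- s2
      a2 <- a[cls[a] == 0L]
      at_sink <- a2[s[a2] == .SINK_IDX]
      if (length(at_sink)) {
        cls[at_sink] <- ifelse(repl[at_sink],
          ifelse(!c20seen[at_sink], 4L,
          ifelse(!clb2m[at_sink], 3L,
          ifelse(!budok[at_sink], 2L, 1L))),
          ifelse(c20ev[at_sink] & !budok[at_sink], 2L, 1L))
      }
    }
    counts[i, ] <- tabulate(cls, nbins = 4L)
  }
  frac <- counts / n_reps
  res$frac_normal <- frac[, 1L]
  res$frac_no_bud_exit <- frac[, 2L]
  res$frac_exit_without_Clb2M <- frac[, 3L]
  res$frac_exit_without_Cdc20 <- frac[, 4L]
  res$pct_normal <- 100 * frac[, 1L]
  res$pct_abnormal <- 100 * (1 - frac[, 1L])
  res$dominant_abnormal <- apply(frac[, 2:4, drop = FALSE], 1L, function(z) {
    if (all(z == 0)) NA_character_ else .PCLASS[-1L][which.max(z)]
  })
  res$n_reps <- n_reps
  attr(res, "overall_normal_pct") <- 100 * sum(counts[, 1L]) /
    (n_reps * nrow(perturbations))
  res
}

#' Exact outcome-class probabilities for a perturbation
#'
#' Independent oracle for the Monte-Carlo screen: the Boolean state is
#' augmented with the milestone flags and the outcome-class probabilities
#' are computed exactly by first-step analysis on the propensity-weighted
#' jump chain (the growth-free graph is acyclic, so the recursion
#' terminates).
#'
#' @param pert One row of [enumerate_perturbations()].
#' @param params Model parameters.
#' @param rules Rule set.
#' @return Named numeric vector of probabilities over the four classes
#'   (sums to 1).
#' @export
exact_class_probabilities <- function(pert, params = default_params(),
                                      rules = ruleset()) {
  js <- .jump_struct(rules, params)
  S <- all_states()
  memo <- new.env(parent = emptyenv())
  recurse <- function(s, flags) {
    if (s == .SINK_IDX) return(c(1, 0, 0, 0))
    key <- paste0(s, ":", .pack_flags(flags))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    deg <- js$deg[s]
    if (deg == 0L) stop("absorbing non-sink state ", state_to_string(S[s, ]),
                        ": augmented chain is not absorbing at the sink")
    p0 <- js$P0[s]
    out <- c(0, 0, 0, 0)
    for (j in seq_len(deg)) {
      w <- (js$cum[s, j] - if (j > 1L) js$cum[s, j - 1L] else 0) / p0
      v <- js$var[s, j]; on <- js$dir[s, j] == 1L; s2 <- js$succ[s, j]
      st <- .flag_step(flags, v, on, is_event = TRUE, post_bits = S[s2, ])
      if (!is.null(st$outcome) && st$outcome != "benign") {
        k <- match(st$outcome, .PCLASS)
        out[k] <- out[k] + w
      } else if (s2 == .SINK_IDX) {
        k <- match(.sink_class(st$flags), .PCLASS)
        out[k] <- out[k] + w
      } else {
        out <- out + w * recurse(s2, st$flags)
      }
    }
    memo[[key]] <- out
    out
  }
  f0 <- .perturbed_flags(pert)
  s0 <- state_index(string_to_state(pert$start_state))
  p <- recurse(s0, f0)
  names(p) <- .PCLASS
  p
}

#' Exact class probabilities for all perturbations
#'
#' @param params,rules See [exact_class_probabilities()].
#' @param perturbations Data frame from [enumerate_perturbations()].
#' @return The perturbation data frame with columns `p_normal`,
#'   `p_no_bud_exit`, `p_exit_without_Clb2M`, `p_exit_without_Cdc20`.
#' @export
exact_screen <- function(params = default_params(), rules = ruleset(),
                         perturbations = enumerate_perturbations()) {
  P <- t(vapply(seq_len(nrow(perturbations)), function(i)
    exact_class_probabilities(perturbations[i, ], params, rules),
    numeric(4)))
  perturbations$p_normal <- P[, 1L]
  perturbations$p_no_bud_exit <- P[, 2L]
  perturbations$p_exit_without_Clb2M <- P[, 3L]
  perturbations$p_exit_without_Cdc20 <- P[, 4L]
  perturbations
}
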