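# Boolean state space, logical updating rules and propensities for the
# seven-variable budding yeast cell-cycle network.

#' Variable names of the Boolean cell-cycle network
#'
#' The fixed component order used everywhere in the package, including in
#' 7-digit state strings: Cdh1, SBF, Cln2, Clb5, Clb2G, Clb2M, Cdc20.
#'
#' @return Character vector of length 7.
#' @export
bkmc_variables <- function() {
  c("Cdh1", "SBF", "Cln2", "Clb5", "Clb2G", "Clb2M", "Cdc20")
}

#' Convert a Boolean state to its 7-digit string
#'
#' @param state Integer vector of length 7 (0/1), or a matrix with 7 columns
#'   in the order `bkmc_variables()`.
#' @return Character string(s) such as `"1000000"`.
#' @export
state_to_string <- function(state) {
  if (is.matrix(state)) {
    apply(state, 1L, paste0, collapse = "")
  } else {
    paste0(state, collapse = "")
  }
}

#' Parse a 7-digit state string
#'
#' @param s Character string of seven 0/1 digits, e.g. `"1000000"`.
#' @return Named integer vector of length 7.
#' @export
string_to_state <- function(s) {
  if (!is.character(s) || length(s) != 1L || nchar(s) != 7L) {
    stop("state must be a string of seven 0/1 digits")
  }
  bits <- as.integer(strsplit(s, "")[[1L]])
  if (anyNA(bits) || any(bits > 1L | bits < 0L)) {
    stop("state string must consist of seven 0/1 digits: ", s)
  }
  names(bits) <- .VARS
  bits
}

#' 1-based index of a state in the enumeration of all 128 states
#'
#' Cdh1 is the most significant bit, so `"1000000"` has index 65.
#'
#' @param state Integer vector of length 7 or matrix with 7 columns.
#' @return Integer index in 1..128.
#' @export
state_index <- function(state) {
  w <- 2L^(6:0)
  if (is.matrix(state)) as.integer(state %*% w) + 1L else
    as.integer(sum(state * w)) + 1L
}

#' Enumerate all 128 Boolean states
#'
#' @return 128 x 7 integer matrix; row `i` is the state with index `i`
#'   (see [state_index()]); columns named as in [bkmc_variables()].
#' @export
all_states <- function() {
  idx <- 0:127
  m <- sapply(6:0, function(b) (idx %/% 2L^b) %% 2L)
  colnames(m) <- .VARS
  storage.mode(m) <- "integer"
  m
}

#' Default model parameters
#'
#' Flip propensities (per minute), growth rate and the distributional
#' parameters of the mitotic delay, the critical size at Start, and the
#' mother/daughter division fraction. All propensities are 1/min except
#' `p_Cln2` = 10/min (Cln1/2 are unstable and track SBF quickly); the
#' specific growth rate `mu` = 0.007/min corresponds to a mass-doubling
#' time of about 99 min (glucose).
#'
#' @param ... Named overrides of individual parameters, e.g. `mu = 0.00462`.
#' @return Named list of class `bkmc_params`.
#' @export
#' @examples
#' p <- default_params(mu = log(2) / 150)
default_params <- function(...) {
  p <- list(
    p_G1 = 1, p_Cdh1 = 1, p_SBF = 1, p_Cln2 = 10, p_Clb5 = 1,
    p_Clb2G = 1, p_Clb2M = 1, p_Cdc20 = 1,
    mu = 0.007,
    t_M_mean = 30, t_M_CV = 0.30,
    S0_mean = 0.4, S0_CV = 0.05,
    f_mean = 0.58, f_CV = 0.05
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  class(p) <- "bkmc_params"
  validate_params(p)
  p
}

#' Validate a parameter list
#'
#' Checks positivity of rates and means, non-negativity of CVs, and
#' `0 < f_mean < 1`.
#'
#' @param p Parameter list as returned by [default_params()].
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_params <- function(p) {
  rates <- c("p_G1", "p_Cdh1", "p_SBF", "p_Cln2", "p_Clb5", "p_Clb2G",
             "p_Clb2M", "p_Cdc20", "t_M_mean", "S0_mean", "f_mean")
  for (nm in rates) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop("parameter ", nm, " must be a single positive number")
    }
  }
  # zero growth is allowed (cells then never pass the Start size gate)
  for (nm in c("mu", "t_M_CV", "S0_CV", "f_CV")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("parameter ", nm, " must be a single non-negative number")
    }
  }
  if (p$f_mean >= 1) stop("f_mean must lie strictly between 0 and 1")
  invisible(p)
}

# per-variable flip propensity constants, in variable order
.propensity_vector <- function(p) {
  c(p$p_Cdh1, p$p_SBF, p$p_Cln2, p$p_Clb5, p$p_Clb2G, p$p_Clb2M, p$p_Cdc20)
}

# ---------------------------------------------------------------------------
# Target functions. Each takes the columns of a state matrix (vectors of 0/1)
# and returns the candidate bit vector B*_i. SBF additionally takes the size
# gate outcome; its first disjunct applies only in the newborn G1 state and is
# injected by candidate_state()/candidate_table().

.wt_targets <- list(
  Cdh1 = function(S) {
    as.integer(!(S[, 3L] | S[, 4L] | S[, 5L] | S[, 6L]) |
                 (S[, 7L] & !(S[, 3L] | S[, 4L] | S[, 6L])))
  },
  SBF = function(S, gate) {
    g1 <- S[, 1L] & !(S[, 2L] | S[, 3L] | S[, 4L] | S[, 5L] | S[, 6L] | S[, 7L])
    as.integer((gate & g1) | (S[, 2L] & !(S[, 5L] | S[, 6L])))
  },
  Cln2 = function(S) as.integer(S[, 2L]),
  Clb5 = function(S) as.integer((S[, 4L] | S[, 2L]) & !(S[, 1L] | S[, 7L])),
  Clb2G = function(S) as.integer(S[, 6L] | ((S[, 4L] | S[, 5L]) & !S[, 1L])),
  Clb2M = function(S) {
    as.integer((S[, 5L] | S[, 6L]) & !S[, 1L] & (!S[, 7L] | S[, 4L]) & !S[, 3L])
  },
  Cdc20 = function(S) as.integer(S[, 6L] | (S[, 5L] & S[, 7L]))
)

#' Construct a rule set
#'
#' A rule set bundles one target function per Boolean variable together with
#' optional parameter overrides. Unspecified targets inherit the wild-type
#' logic.
#'
#' @param label Character label for the rule set.
#' @param targets Named list of replacement target functions. Each function
#'   receives the 0/1 state matrix `S` (columns in [bkmc_variables()] order)
#'   and returns an integer 0/1 vector of candidate bits. A replacement for
#'   `SBF` must accept `(S, gate)`. Entries may also be character strings:
#'   Boolean expressions over the variable names using `&`, `|`, `!` and
#'   parentheses (or the literals `0`/`1`), which are compiled with
#'   [rule_function()].
#' @param param_overrides Named list of parameter overrides applied on top of
#'   whatever parameters a simulation is run with (e.g. `S0_mean = 0.8`).
#' @return Object of class `bkmc_ruleset`.
#' @export
ruleset <- function(label = "wild-type", targets = list(),
                    param_overrides = list()) {
  tg <- .wt_targets
  if (length(targets)) {
    bad <- setdiff(names(targets), .VARS)
    if (length(bad)) stop("unknown variable(s) in targets: ",
                          paste(bad, collapse = ", "))
    for (nm in names(targets)) {
      f <- targets[[nm]]
      if (is.character(f)) f <- rule_function(f, sbf = identical(nm, "SBF"))
      tg[[nm]] <- f
    }
  }
  structure(list(label = label, targets = tg,
                 param_overrides = param_overrides),
            class = "bkmc_ruleset")
}

#' Compile a Boolean expression string into a target function
#'
#' Supports the seven variable names, `&`, `|`, `!`, parentheses and the
#' constants `0`/`1`/`TRUE`/`FALSE`. Anything else is rejected, so rule
#' overrides can safely be loaded from a configuration file.
#'
#' @param expr_string Boolean expression, e.g.
#'   `"Clb2M | ((Clb5 | Clb2G) & !Cdh1) | SBF"`.
#' @param sbf If `TRUE` the compiled function takes `(S, gate)` (the gate is
#'   ignored by the expression itself).
#' @return A target function usable in [ruleset()].
#' @export
rule_function <- function(expr_string, sbf = FALSE) {
  ex <- str2lang(expr_string)
  allowed <- c(.VARS, "&", "|", "!", "(", "TRUE", "FALSE")
  check <- function(e) {
    if (is.call(e)) {
      op <- as.character(e[[1L]])
      if (!op %in% c("&", "|", "!", "(")) {
        stop("disallowed operator in rule expression: ", op)
      }
      for (i in seq_along(e)[-1L]) check(e[[i]])
    } else if (is.name(e)) {
      if (!as.character(e) %in% allowed) {
        stop("unknown symbol in rule expression: ", as.character(e))
      }
    } else if (is.numeric(e) || is.logical(e)) {
      if (!as.numeric(e) %in% c(0, 1)) stop("only 0/1 literals are allowed")
    } else stop("unsupported token in rule expression")
  }
  check(ex)
  if (sbf) {
    function(S, gate) {
      env <- list2env(setNames(lapply(1:7, function(j) S[, j] > 0L), .VARS))
      rep_len(as.integer(eval(ex, env)), nrow(S))
    }
  } else {
    function(S) {
      env <- list2env(setNames(lapply(1:7, function(j) S[, j] > 0L), .VARS))
      rep_len(as.integer(eval(ex, env)), nrow(S))
    }
  }
}

#' Published mutant rule sets
#'
#' * `"wild-type"`: the unmodified rules.
#' * `"clns-clb2"`: a strain with no S-phase cyclins whose single mitotic
#'   cyclin is also expressed from the CLB5 promoter: `Clb5* = 0` and
#'   `Clb2G* = Clb2M | ((Clb5 | Clb2G) & !Cdh1) | SBF`.
#' * `"met3pr-cln2-clb2"`: the same strain with repressible CLN2, simulated
#'   in methionine: additionally `Cln2* = 0` and `S0_mean = 0.8`.
#' * `"dcln3"`: wild-type logic with a raised critical size (cells ~70%
#'   larger); `S0_mean` defaults to 0.68 and is configurable via `s0_mean`.
#'
#' @param label One of the labels above.
#' @param s0_mean Critical-size mean for `"dcln3"`.
#' @return Object of class `bkmc_ruleset`.
#' @export
mutant_ruleset <- function(label = c("wild-type", "clns-clb2",
                                     "met3pr-cln2-clb2", "dcln3"),
                           s0_mean = 0.68) {
  label <- match.arg(label)
  clb2g_mod <- "Clb2M | ((Clb5 | Clb2G) & !Cdh1) | SBF"
  switch(label,
    "wild-type" = ruleset("wild-type"),
    "clns-clb2" = ruleset("clns-clb2",
      targets = list(Clb5 = "0", Clb2G = clb2g_mod)),
    "met3pr-cln2-clb2" = ruleset("met3pr-cln2-clb2",
      targets = list(Clb5 = "0", Clb2G = clb2g_mod, Cln2 = "0"),
      param_overrides = list(S0_mean = 0.8)),
    "dcln3" = ruleset("dcln3", param_overrides = list(S0_mean = s0_mean))
  )
}

#' Size gate for the Start transition
#'
#' SBF can only be activated in the newborn G1 state once Size exceeds the
#' cell's critical size S0, and then with probability `(Size - S0)^2`
#' (capped at 1).
#'
#' @param size Current cell size (> 0).
#' @param s0 The cell's birth-assigned critical size (> 0).
#' @param r0 A uniform(0,1) draw; a fresh draw is used at every engine
#'   iteration in which the gate is evaluated.
#' @return `TRUE` if the gate opens.
#' @export
#' @examples
#' sbf_gate_open(1.4, 0.4, 0.9)  # TRUE: (1.0)^2 > 0.9
sbf_gate_open <- function(size, s0, r0) {
  stopifnot(size > 0, s0 > 0)
  size > s0 && r0 < min(1, (size - s0)^2)
}

#' Candidate state under a rule set
#'
#' Evaluates all seven target functions on the current state, giving the
#' potential next activity of each variable.
#'
#' @param state Integer 0/1 vector of length 7 (or a 7-digit string).
#' @param rules A [ruleset()]; default wild-type.
#' @param sbf_gate Externally evaluated size-gate outcome; only consulted
#'   when `state` is the newborn G1 state `1000000`.
#' @return Named integer vector of candidate bits.
#' @export
candidate_state <- function(state, rules = ruleset(), sbf_gate = FALSE) {
  if (is.character(state)) state <- string_to_state(state)
  S <- matrix(as.integer(state), nrow = 1L)
  out <- vapply(.VARS, function(nm) {
    f <- rules$targets[[nm]]
    if (identical(nm, "SBF")) f(S, gate = sbf_gate)[1L] else f(S)[1L]
  }, integer(1L))
  names(out) <- .VARS
  out
}

#' Candidate table over all 128 states
#'
#' @param rules A [ruleset()].
#' @param sbf_gate Gate outcome used for the SBF rule (default closed, so
#'   the newborn G1 state is a fixed point).
#' @return 128 x 7 integer matrix of candidate bits, rows indexed as in
#'   [state_index()].
#' @export
candidate_table <- function(rules = ruleset(), sbf_gate = FALSE) {
  S <- all_states()
  out <- matrix(0L, 128L, .NVAR, dimnames = list(NULL, .VARS))
  for (nm in .VARS) {
    f <- rules$targets[[nm]]
    out[, nm] <- if (identical(nm, "SBF")) f(S, gate = sbf_gate) else f(S)
  }
  out
}

#' Flip propensities for a state
#'
#' `P_i = p_i * |B*_i - B_i|`, together with their sum P0.
#'
#' @param state Integer 0/1 vector of length 7 (or 7-digit string).
#' @param candidates Candidate vector from [candidate_state()].
#' @param params Parameters from [default_params()].
#' @return List with `P` (named 7-vector of rates, each 0 or `p_i`) and
#'   `P0` (their sum).
#' @export
propensities <- function(state, candidates, params = default_params()) {
  if (is.character(state)) state <- string_to_state(state)
  pv <- .propensity_vector(params)
  P <- pv * abs(as.integer(candidates) - as.integer(state))
  names(P) <- .VARS
  list(P = P, P0 = sum(P))
}
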