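# Population and lineage experiments: synchronized outgrowth, asynchronous
# steady-state sampling, cell-cycle interval statistics and size-control
# slopes.

#' Simulate a population of growing and dividing cells
#'
#' Starts `n_founders` independent cells and follows them and all of their
#' progeny to the horizon. Cells do not interact, so lineages are simulated
#' one cell at a time in birth (FIFO) order, which makes runs reproducible
#' with a single seeded RNG stream.
#'
#' @param params,rules Model parameters and rule set.
#' @param n_founders Number of founder cells (>= 1).
#' @param founder_size Initial size of each founder; 0.65 is the average
#'   size of a mother cell after division.
#' @param founder_state Initial Boolean state (7-digit string).
#' @param founder_pedigree `"mother"` (default; e.g. newly divided mother
#'   cells) or `"daughter"` (never-divided newborns, as in size-selection
#'   outgrowth experiments).
#' @param horizon Simulation end time (min).
#' @return Object of class `bkmc_population`: list with `cells` (data frame:
#'   `cell_id`, `parent_id`, `pedigree`, `birth_time`, `birth_size`, `s0`),
#'   `events` (data frame: `cell_id`, `time`, `kind`, `variable`, `state`,
#'   `size`), `params`, `horizon`.
#' @export
run_population <- function(params = default_params(), rules = ruleset(),
                           n_founders = 20L, founder_size = 0.65,
                           founder_state = "1000000",
                           founder_pedigree = c("mother", "daughter"),
                           horizon = 400) {
  stopifnot(n_founders >= 1L, horizon > 0)
  founder_pedigree <- match.arg(founder_pedigree)
  params <- resolve_params(params, rules)
  js <- .jump_struct(rules, params)
  s0ml <- log(params$S0_mean); s0sl <- params$S0_CV
  start_idx <- state_index(string_to_state(founder_state))

  # birth queue, processed FIFO
  q_state <- rep(start_idx, n_founders)
  q_size <- rep(founder_size, n_founders)
  q_s0 <- stats::rlnorm(n_founders, s0ml, s0sl)
  q_time <- rep(0, n_founders)
  q_parent <- rep(NA_integer_, n_founders)

  cells <- list(); ev <- list()
  next_id <- 1L; head <- 1L
  while (head <= length(q_state)) {
    id <- next_id; next_id <- next_id + 1L
    res <- .simulate_lineage(q_state[head], q_size[head], q_s0[head],
                             q_time[head], horizon, js, params)
    cells[[id]] <- data.frame(
      cell_id = id, parent_id = q_parent[head],
      pedigree = if (is.na(q_parent[head])) founder_pedigree else "daughter",
      birth_time = q_time[head], birth_size = q_size[head],
      s0 = q_s0[head]
    )
    nd <- length(res$daughters$time)
    if (nd) {
      q_state <- c(q_state, rep(res$events$state[match(res$daughters$time,
                                                       res$events$time)],
                                length.out = nd))
      q_size <- c(q_size, res$daughters$size)
      q_s0 <- c(q_s0, res$daughters$s0)
      q_time <- c(q_time, res$daughters$time)
      q_parent <- c(q_parent, rep(id, nd))
    }
    ne <- length(res$events$time)
    if (ne) {
      ev[[id]] <- data.frame(
        cell_id = rep(id, ne), time = res$events$time,
        kind = res$events$kind, variable = res$events$variable,
        state = res$events$state, size = res$events$size
      )
    }
    head <- head + 1L
  }
  cells <- do.call(rbind, cells)
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(cell_id = integer(), time = numeric(), kind = integer(),
               variable = integer(), state = integer(), size = numeric())
  states <- state_to_string(all_states())
  events$kind <- .KIND_LABELS[events$kind]
  events$variable <- ifelse(events$variable > 0L, .VARS[events$variable],
                            NA_character_)
  events$state <- states[events$state]
  structure(list(cells = cells, events = events, params = params,
                 horizon = horizon, rules_label = rules$label),
            class = "bkmc_population")
}

#' @export
print.bkmc_population <- function(x, ...) {
  cat("BKMC population (", x$rules_label, "): ", nrow(x$cells), " cells, ",
      sum(x$events$kind == "division"), " divisions, horizon ", x$horizon,
      " min\n", sep = "")
  invisible(x)
}

#' Extract completed cell cycles from a population run
#'
#' A cycle runs from a birth (the cell's own birth, or its previous
#' division) to the next division. `T_G1` is the time from mitotic exit to
#' SBF activation, `T_bud` from SBF activation to the division, so
#' `T_c = T_G1 + T_bud`. Cycles not completed by the horizon are dropped.
#' A cycle is labelled `daughter` if the cell has never divided before
#' (0 bud scars), `mother` otherwise.
#'
#' @param pop A [run_population()] result.
#' @return Data frame of cycle records: `cell_id`, `pedigree`, `scars`,
#'   `birth_time`, `size_at_birth`, `T_c`, `T_G1`, `T_bud`.
#' @export
extract_cycles <- function(pop) {
  ev <- pop$events
  cells <- pop$cells
  is_div <- ev$kind == "division"
  is_sbf <- ev$kind == "start" | (ev$kind == "flip" & ev$variable == "SBF" &
                                    substr(ev$state, 2L, 2L) == "1")
  fid <- factor(ev$cell_id, levels = cells$cell_id)
  div_t_by <- split(ev$time[is_div], fid[is_div])
  div_z_by <- split(ev$size[is_div], fid[is_div])
  sbf_by <- split(ev$time[is_sbf], fid[is_sbf])

  acc <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    div_t <- div_t_by[[i]]
    if (!length(div_t)) next
    div_z <- div_z_by[[i]]
    sbf_t <- sbf_by[[i]]
    starts_t <- c(cells$birth_time[i], div_t[-length(div_t)])
    starts_z <- c(cells$birth_size[i], div_z[-length(div_z)])
    base_scars <- if (cells$pedigree[i] == "daughter") 0L else 1L
    # first SBF activation within each cycle
    sb1 <- vapply(seq_along(div_t), function(k) {
      sb <- sbf_t[sbf_t > starts_t[k] & sbf_t <= div_t[k]]
      if (length(sb)) sb[1L] else NA_real_
    }, numeric(1))
    ok <- !is.na(sb1)
    if (!any(ok)) next
    scars <- base_scars + seq_along(div_t) - 1L
    acc[[i]] <- data.frame(
      cell_id = cells$cell_id[i],
      pedigree = ifelse(scars[ok] == 0L, "daughter", "mother"),
      scars = scars[ok],
      birth_time = starts_t[ok], size_at_birth = starts_z[ok],
      T_c = div_t[ok] - starts_t[ok],
      T_G1 = sb1[ok] - starts_t[ok],
      T_bud = div_t[ok] - sb1[ok])
  }
  res <- do.call(rbind, acc)
  if (is.null(res)) {
    res <- data.frame(cell_id = integer(), pedigree = character(),
                      scars = integer(), birth_time = numeric(),
                      size_at_birth = numeric(), T_c = numeric(),
                      T_G1 = numeric(), T_bud = numeric())
  }
  rownames(res) <- NULL
  res
}

#' Means and coefficients of variation of cycle statistics
#'
#' @param records Cycle records from [extract_cycles()].
#' @param burn_in Drop cycles beginning before this time (min), to remove
#'   the synchronized transient of the founders.
#' @return Data frame with one row per pedigree and per quantity
#'   (`T_c`, `T_G1`, `T_bud`, `size_at_birth`): `n`, `mean`, `cv`.
#' @export
summarize_cycles <- function(records, burn_in = 0) {
  records <- records[records$birth_time >= burn_in, , drop = FALSE]
  if (!nrow(records)) stop("no cycle records after burn-in")
  qty <- c("T_c", "T_G1", "T_bud", "size_at_birth")
  out <- list()
  for (ped in unique(records$pedigree)) {
    r <- records[records$pedigree == ped, , drop = FALSE]
    if (nrow(r) < 2L) stop("fewer than 2 records for pedigree ", ped)
    for (q in qty) {
      v <- r[[q]]
      out[[length(out) + 1L]] <- data.frame(
        pedigree = ped, quantity = q, n = length(v), mean = mean(v),
        cv = stats::sd(v) / mean(v))
    }
  }
  do.call(rbind, out)
}

#' Binned size-control slope
#'
#' Regresses the per-bin mean of `mu * T_G1` on the per-bin mean of
#' `ln(size-at-birth)`, after binning cells by size at birth in fixed-width
#' volume intervals (2 fL by default, with 61.4 fL per dimensionless size
#' unit). A slope of -1 indicates a perfect sizer, 0 no size control.
#' For daughters, two straight lines joined at a breakpoint chosen by
#' minimizing the total squared error are fitted in addition to the single
#' line (small daughters show stronger size control than large ones).
#'
#' @param records Cycle records from [extract_cycles()].
#' @param pedigree `"mother"` or `"daughter"`.
#' @param mu Specific growth rate used in the simulation (1/min).
#' @param conversion_fl Volume per dimensionless size unit (fL).
#' @param bin_width_fl Bin width (fL).
#' @param min_per_bin Bins with fewer records are dropped.
#' @param burn_in Drop cycles beginning before this time (min).
#' @param breakpoint_fl For daughters: the volume (fL) separating the small-
#'   and large-cell lines. The natural anchor is the average mother size at
#'   birth (the unit of the relative-size axis), e.g.
#'   `61.4 * mean(size_at_birth)` over mother records. If `NULL`, the
#'   breakpoint is chosen by minimizing the total squared error of the two
#'   fits, which tends to land near the daughter size mode and steepens the
#'   small-cell limb towards the perfect-sizer limit.
#' @return List with `slope` (single-line fit), `bins` (data frame of bin
#'   means and counts), and for daughters also `slope_small`, `slope_large`
#'   and `breakpoint_fl`.
#' @export
binned_slope <- function(records, pedigree = "mother", mu = 0.007,
                         conversion_fl = 61.4, bin_width_fl = 2,
                         min_per_bin = 5L, burn_in = 0,
                         breakpoint_fl = NULL) {
  r <- records[records$pedigree == pedigree & records$birth_time >= burn_in, ,
               drop = FALSE]
  x <- log(r$size_at_birth)
  y <- mu * r$T_G1
  bin <- floor(r$size_at_birth * conversion_fl / bin_width_fl)
  agg <- data.frame(bin = sort(unique(bin)))
  agg$n <- as.integer(table(bin)[as.character(agg$bin)])
  agg$x <- tapply(x, bin, mean)[as.character(agg$bin)]
  agg$y <- tapply(y, bin, mean)[as.character(agg$bin)]
  agg$fl <- (agg$bin + 0.5) * bin_width_fl
  agg <- agg[agg$n >= min_per_bin, , drop = FALSE]
  if (nrow(agg) < 2L) stop("fewer than 2 usable bins")
  fit <- stats::lm(y ~ x, data = agg)
  out <- list(slope = unname(stats::coef(fit)[2L]), bins = agg)
  if (pedigree == "daughter" && nrow(agg) >= 4L) {
    if (!is.null(breakpoint_fl)) {
      k <- sum(agg$fl <= breakpoint_fl)
      if (k < 2L || k > nrow(agg) - 2L) {
        stop("breakpoint leaves fewer than 2 bins on one side")
      }
      lo <- agg[1:k, ]; hi <- agg[(k + 1L):nrow(agg), ]
      out$slope_small <- unname(stats::coef(stats::lm(y ~ x, data = lo))[2L])
      out$slope_large <- unname(stats::coef(stats::lm(y ~ x, data = hi))[2L])
      out$breakpoint_fl <- breakpoint_fl
    } else {
      best <- NULL
      for (k in 2:(nrow(agg) - 2L)) {
        lo <- agg[1:k, ]; hi <- agg[(k + 1L):nrow(agg), ]
        f1 <- stats::lm(y ~ x, data = lo); f2 <- stats::lm(y ~ x, data = hi)
        sse <- sum(stats::resid(f1)^2) + sum(stats::resid(f2)^2)
        if (is.null(best) || sse < best$sse) {
          best <- list(sse = sse, k = k,
                       slope_small = unname(stats::coef(f1)[2L]),
                       slope_large = unname(stats::coef(f2)[2L]))
        }
      }
      out$slope_small <- best$slope_small
      out$slope_large <- best$slope_large
      out$breakpoint_fl <- agg$fl[best$k]
    }
  }
  out
}

#' Budded fraction over time for a scar-count cohort
#'
#' A cell is budded from SBF activation until its next division. The
#' fraction is computed among cells that, at each time point, are alive and
#' carry the requested number of bud scars (0 = never divided).
#'
#' @param pop A [run_population()] result.
#' @param times Numeric vector of time points (min).
#' @param scars Bud-scar count selecting the cohort.
#' @return Data frame with `time`, `n` (cohort size) and `budded_fraction`.
#' @export
budded_fraction <- function(pop, times, scars = 0L) {
  ev <- pop$events
  cells <- pop$cells
  base_scars <- ifelse(cells$pedigree == "daughter", 0L, 1L)
  out <- data.frame(time = times, n = 0L, budded_fraction = NA_real_)
  # per cell: birth, division times, SBF-activation times
  div_by <- split(ev$time[ev$kind == "division"],
                  ev$cell_id[ev$kind == "division"])
  sbf_on <- ev$kind == "start" | (ev$kind == "flip" & ev$variable == "SBF" &
                                    substr(ev$state, 2L, 2L) == "1")
  sbf_by <- split(ev$time[sbf_on], ev$cell_id[sbf_on])
  for (ti in seq_along(times)) {
    t <- times[ti]
    alive <- cells$birth_time <= t
    n <- 0L; nb <- 0L
    for (i in which(alive)) {
      id <- as.character(cells$cell_id[i])
      dv <- div_by[[id]]
      k <- base_scars[i] + sum(dv <= t)
      if (k != scars) next
      n <- n + 1L
      last_birth <- max(c(cells$birth_time[i], dv[dv <= t]))
      sb <- sbf_by[[id]]
      if (length(sb) && any(sb > last_birth & sb <= t)) nb <- nb + 1L
    }
    out$n[ti] <- n
    out$budded_fraction[ti] <- if (n > 0L) nb / n else NA_real_
  }
  out
}

#' Population-average trajectories of the Boolean variables and size
#'
#' Averages the value of each Boolean variable (and of size, under
#' exponential interpolation) over all cells extant at each time point,
#' emulating bulk measurements on a size-selected synchronized culture.
#'
#' @param pop A [run_population()] result.
#' @param times Numeric vector of time points (min).
#' @return Data frame with `time`, `n_cells`, one column per Boolean
#'   variable, and `size`.
#' @export
population_average <- function(pop, times) {
  ev <- pop$events
  cells <- pop$cells
  mu <- pop$params$mu
  out <- matrix(NA_real_, length(times), .NVAR + 2L)
  colnames(out) <- c("n_cells", .VARS, "size")
  ev_by <- split(seq_len(nrow(ev)), ev$cell_id)
  for (ti in seq_along(times)) {
    t <- times[ti]
    alive <- which(cells$birth_time <= t)
    acc <- numeric(.NVAR); sz <- 0
    for (i in alive) {
      id <- as.character(cells$cell_id[i])
      rows <- ev_by[[id]]
      past <- if (length(rows)) rows[ev$time[rows] <= t] else integer(0)
      if (length(past)) {
        last <- past[length(past)]
        st <- string_to_state(ev$state[last])
        sz <- sz + ev$size[last] * exp(mu * (t - ev$time[last]))
      } else {
        st <- string_to_state("1000000")
        sz <- sz + cells$birth_size[i] * exp(mu * (t - cells$birth_time[i]))
      }
      acc <- acc + st
    }
    out[ti, ] <- c(length(alive), acc / length(alive), sz / length(alive))
  }
  data.frame(time = times, out)
}

#' Cell count over time and fitted number-doubling time
#'
#' @param pop A [run_population()] result.
#' @param times Time grid (min); defaults to every 10 min.
#' @param fit_window Time range used for the log-linear fit; defaults to the
#'   second half of the run.
#' @return List with `counts` (data frame `time`, `n`) and `doubling_time`
#'   (min, from a log2-linear least-squares fit).
#' @export
population_growth <- function(pop, times = NULL, fit_window = NULL) {
  if (is.null(times)) times <- seq(0, pop$horizon, by = 10)
  n <- vapply(times, function(t) sum(pop$cells$birth_time <= t), numeric(1))
  counts <- data.frame(time = times, n = n)
  if (is.null(fit_window)) fit_window <- c(pop$horizon / 2, pop$horizon)
  w <- counts$time >= fit_window[1L] & counts$time <= fit_window[2L] & counts$n > 0
  fit <- stats::lm(log2(n) ~ time, data = counts[w, ])
  list(counts = counts, doubling_time = 1 / unname(stats::coef(fit)[2L]))
}
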