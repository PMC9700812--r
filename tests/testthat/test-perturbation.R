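test_that("exactly 70 perturbations are enumerated, five per highway state", {
  pe <- enumerate_perturbations()
  expect_identical(nrow(pe), 70L)
  expect_true(all(table(pe$highway_index) == 5L))
  # the flipped variable is neither the one just updated nor the next one
  enter_var <- c("Cdc20", "SBF", "Cln2", "Cdh1", "Clb5", "Clb2G", "SBF",
                 "Cln2", "Clb2M", "Cdc20", "Clb5", "Clb2M", "Cdh1", "Clb2G")
  for (k in 1:14) {
    vars <- pe$variable[pe$highway_index == k]
    excluded <- c(enter_var[k], enter_var[if (k == 14L) 1L else k + 1L])
    expect_length(intersect(vars, excluded), 0L)
    expect_setequal(vars, setdiff(bkmc_variables(), excluded))
  }
  # the S/prophase state carries a premature Cdc20 activation
  expect_true(any(pe$highway_state == "0111100" & pe$variable == "Cdc20" &
                    pe$direction == "on"))
  # flipping Clb2M on also sets Clb2G on
  cm <- pe[pe$variable == "Clb2M" & pe$direction == "on", ]
  expect_true(all(cm$coupled_clb2g | substr(cm$highway_state, 5L, 5L) == "1"))
  g1 <- pe[pe$highway_state == "1000000" & pe$variable == "Clb2M", ]
  expect_identical(g1$start_state, "1000110")
  # every perturbed state differs from its highway state as declared
  for (i in seq_len(nrow(pe))) {
    a <- string_to_state(pe$highway_state[i])
    b <- string_to_state(pe$start_state[i])
    expect_identical(sum(a != b), 1L + pe$coupled_clb2g[i], info = i)
  }
})

test_that("classify_trace applies the ordered-event rules to explicit traces", {
  pe <- enumerate_perturbations()
  pick <- function(state, var) pe[pe$highway_state == state &
                                    pe$variable == var, ][1L, ]
  # an immediately reverted flip resumes the normal sequence
  expect_identical(classify_trace(pick("1000000", "Clb2G"), "Clb2G"),
                   "normal")
  # premature Cdc20 in S phase, trace that never activates Clb2M
  p <- pick("0111000", "Cdc20")
  expect_identical(
    classify_trace(p, c("Clb2G", "Clb5", "SBF", "Cln2", "Cdh1", "Clb2G",
                        "Cdc20")),
    "exit_without_Clb2M")
  # premature Clb2M in newborn G1: mitotic exit without ever budding
  p <- pick("1000000", "Clb2M")
  expect_identical(
    classify_trace(p, c("Cdh1", "Cdc20", "Clb2M", "Cdh1", "Clb2G", "Cdc20")),
    "no_bud_exit")
  # premature Cdh1 in prophase: direct division without Cdc20
  p <- pick("0111100", "Cdh1")
  expect_identical(classify_trace(p, "Clb2G"), "exit_without_Cdc20")
  # a trace that does not reach the sink is rejected
  expect_error(classify_trace(pick("1000000", "Clb2G"), "Cdh1"), "sink")
})

test_that("the exact oracle solves simple races in closed form", {
  pe <- enumerate_perturbations()
  p <- pe[pe$highway_state == "1000000" & pe$variable == "Clb2G", ][1L, ]
  pr <- exact_class_probabilities(p)
  # two-way race between Cdh1 and Clb2G at equal propensities
  expect_equal(unname(pr["normal"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(pr["no_bud_exit"]), 0.5, tolerance = 1e-12)
  # class probabilities always sum to one
  expect_equal(sum(pr), 1, tolerance = 1e-12)
})

test_that("exactly the 12 published perturbations are aberrant, with matching classes", {
  ex <- exact_screen()
  expect_equal(rowSums(ex[, c("p_normal", "p_no_bud_exit",
                              "p_exit_without_Clb2M",
                              "p_exit_without_Cdc20")]),
               rep(1, 70), tolerance = 1e-9)
  nz <- ex[ex$p_normal < 1 - 1e-9, ]
  pub <- published_aberrant_rows()
  expect_identical(nrow(nz), 12L)
  key <- function(d) paste(d$highway_state, d$variable)
  expect_setequal(key(nz), key(pub))
  m <- match(key(pub), key(nz))
  # exact probabilities lie within the sampling error of the published
  # 5000-repeat percentages
  se <- sqrt(pub$pct_normal / 100 * (1 - pub$pct_normal / 100) / 5000) * 100
  expect_true(all(abs(100 * nz$p_normal[m] - pub$pct_normal) <= 3 * se))
  # the dominant aberrant class matches the published footnotes
  dom <- c("p_no_bud_exit", "p_exit_without_Clb2M", "p_exit_without_Cdc20")
  for (i in seq_len(nrow(pub))) {
    probs <- unlist(nz[m[i], dom])
    expect_identical(
      c("no_bud_exit", "exit_without_Clb2M",
        "exit_without_Cdc20")[which.max(probs)],
      pub$class[i], info = key(pub)[i])
  }
})

test_that("Monte-Carlo fractions match the exact oracle within binomial error", {
  set.seed(31)
  reps <- 800L
  sc <- run_screen(n_reps = reps)
  ex <- exact_screen()
  expect_equal(sc$frac_normal + sc$frac_no_bud_exit +
                 sc$frac_exit_without_Clb2M + sc$frac_exit_without_Cdc20,
               rep(1, 70), tolerance = 1e-12)
  tol <- 3 * sqrt(pmax(ex$p_normal * (1 - ex$p_normal), 1e-9) / reps)
  expect_true(all(abs(sc$frac_normal - ex$p_normal) <= tol + 1e-9))
  # classes agree too, on the aberrant rows
  nz <- which(ex$p_normal < 1 - 1e-9)
  for (cl in c("no_bud_exit", "exit_without_Clb2M", "exit_without_Cdc20")) {
    pcol <- paste0("p_", cl); fcol <- paste0("frac_", cl)
    tol <- 3 * sqrt(pmax(ex[[pcol]][nz] * (1 - ex[[pcol]][nz]), 1e-9) / reps)
    expect_true(all(abs(sc[[fcol]][nz] - ex[[pcol]][nz]) <= tol + 1e-9))
  }
  expect_error(run_screen(n_reps = 0L), "n_reps")
})

test_that("the scalar reference classifier agrees with the exact oracle", {
  # independent scalar walk: choose updates with candidate_state() and
  # propensity weights, feed the realized trace to classify_trace(), and
  # compare outcome frequencies against the first-step-analysis oracle
  set.seed(32)
  pe <- enumerate_perturbations()
  p <- default_params()
  pv <- c(p$p_Cdh1, p$p_SBF, p$p_Cln2, p$p_Clb5, p$p_Clb2G, p$p_Clb2M,
          p$p_Cdc20)
  walk_class <- function(pert) {
    bits <- string_to_state(pert$start_state)
    vars <- character(0)
    while (state_to_string(bits) != "1000000") {
      cand <- candidate_state(bits)
      en <- which(cand != bits)
      j <- if (length(en) == 1L) en else
        en[sample.int(length(en), 1L, prob = pv[en])]
      bits[j] <- 1L - bits[j]
      vars <- c(vars, bkmc_variables()[j])
      if (length(vars) > 500L) stop("walk failed to absorb")
    }
    classify_trace(pert, vars)
  }
  for (key in c("0111100 Cdc20", "0001110 Cdh1", "1000000 Clb2M")) {
    parts <- strsplit(key, " ")[[1L]]
    pert <- pe[pe$highway_state == parts[1L] & pe$variable == parts[2L], ][1L, ]
    n <- 300L
    cls <- replicate(n, walk_class(pert))
    ex <- exact_class_probabilities(pert)
    p_hat <- mean(cls == "normal")
    tol <- 3 * sqrt(ex[["normal"]] * (1 - ex[["normal"]]) / n)
    expect_lt(abs(p_hat - ex[["normal"]]), tol + 1e-9)
  }
})
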