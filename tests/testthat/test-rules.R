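test_that("state strings round-trip and enumerate 128 distinct states", {
  S <- all_states()
  str <- state_to_string(S)
  expect_length(unique(str), 128L)
  for (s in c("1000000", "0111100", "1101010")) {
    expect_identical(state_to_string(string_to_state(s)), s)
  }
  expect_identical(state_index(string_to_state("1000000")), 65L)
  expect_identical(S[65L, ], string_to_state("1000000"))
  expect_error(string_to_state("100000"), "seven")
  expect_error(string_to_state("1000002"), "0/1")
})

test_that("wild-type candidates match a literal truth-table oracle on all 128 states", {
  S <- all_states()
  rules <- ruleset()
  for (gate in c(FALSE, TRUE)) {
    tab <- candidate_table(rules, sbf_gate = gate)
    for (i in 1:128) {
      expect_identical(unname(tab[i, ]),
                       unname(oracle_candidates(S[i, ], gate = gate)),
                       info = paste("state", state_to_string(S[i, ]),
                                    "gate", gate))
    }
  }
})

test_that("candidate_state reproduces the published single-state examples", {
  # late G1: only Cln2 is enabled (bud emergence)
  st <- string_to_state("1100000")
  cand <- candidate_state(st)
  expect_identical(which(cand != st), c(Cln2 = 3L))
  # newborn G1 with the gate closed is a fixed point
  st <- string_to_state("1000000")
  expect_identical(candidate_state(st, sbf_gate = FALSE), st)
  # metaphase: only Cdc20 is enabled (anaphase onset)
  st <- string_to_state("0001110")
  cand <- candidate_state(st)
  expect_identical(which(cand != st), c(Cdc20 = 7L))
  # off-highway state with exactly two enabled variables
  st <- string_to_state("1000100")
  cand <- candidate_state(st)
  expect_identical(which(cand != st), c(Cdh1 = 1L, Clb2G = 5L))
})

test_that("size gate opens strictly above S0 with probability (Size-S0)^2 capped at 1", {
  expect_false(sbf_gate_open(0.3, 0.4, 0))
  expect_true(sbf_gate_open(1.4, 0.4, 0.9))   # (1.0)^2 = 1 > 0.9
  expect_false(sbf_gate_open(0.9, 0.4, 0.25)) # r0 equals (Size-S0)^2 exactly
  expect_true(sbf_gate_open(1.9, 0.4, 0.999)) # capped at 1
  expect_false(sbf_gate_open(0.4, 0.4, 0))    # strict inequality at S0
})

test_that("propensities are 0 or the per-variable constant and sum to P0", {
  p <- default_params()
  st <- string_to_state("1100000")
  pr <- propensities(st, candidate_state(st), p)
  expect_equal(unname(pr$P), c(0, 0, 10, 0, 0, 0, 0))
  expect_equal(pr$P0, 10)
  st <- string_to_state("1000000")
  pr <- propensities(st, candidate_state(st, sbf_gate = FALSE), p)
  expect_equal(pr$P0, 0)
  st <- string_to_state("1000100")
  pr <- propensities(st, candidate_state(st), p)
  expect_equal(unname(pr$P), c(1, 0, 0, 0, 1, 0, 0))
  expect_equal(pr$P0, 2)
  # every propensity is either 0 or its constant, over all states
  tab <- candidate_table()
  S <- all_states()
  pv <- c(p$p_Cdh1, p$p_SBF, p$p_Cln2, p$p_Clb5, p$p_Clb2G, p$p_Clb2M,
          p$p_Cdc20)
  for (i in seq(1, 128, by = 7)) {
    pr <- propensities(S[i, ], tab[i, ], p)
    expect_true(all(pr$P == 0 | pr$P == pv))
    expect_equal(pr$P0, sum(pr$P))
  }
})

test_that("each highway state enables exactly the published next event", {
  hw <- highway_reference()
  events_var <- c("SBF", "Cln2", "Cdh1", "Clb5", "Clb2G", "SBF", "Cln2",
                  "Clb2M", "Cdc20", "Clb5", "Clb2M", "Cdh1", "Clb2G", "Cdc20")
  for (k in 1:14) {
    st <- string_to_state(hw$state[k])
    gate <- k == 1L  # Start: the size gate is open for the newborn state
    cand <- candidate_state(st, sbf_gate = gate)
    enabled <- which(cand != st)
    expect_length(enabled, 1L)
    expect_identical(bkmc_variables()[enabled], events_var[k],
                     info = paste("state", hw$state[k]))
  }
})

test_that("default parameters equal the published table and are validated", {
  p <- default_params()
  expect_equal(p$p_Cln2, 10)
  expect_equal(p[c("p_G1", "p_Cdh1", "p_SBF", "p_Clb5", "p_Clb2G", "p_Clb2M",
                   "p_Cdc20")],
               list(p_G1 = 1, p_Cdh1 = 1, p_SBF = 1, p_Clb5 = 1, p_Clb2G = 1,
                    p_Clb2M = 1, p_Cdc20 = 1))
  expect_equal(p$mu, 0.007)
  expect_equal(p$t_M_mean, 30); expect_equal(p$t_M_CV, 0.30)
  expect_equal(p$S0_mean, 0.4); expect_equal(p$S0_CV, 0.05)
  expect_equal(p$f_mean, 0.58); expect_equal(p$f_CV, 0.05)
  expect_error(default_params(p_Cln2 = -1), "positive")
  expect_error(default_params(f_mean = 1.2), "f_mean")
  expect_error(default_params(nonsense = 1), "unknown")
})

test_that("mutant rule sets implement the published genotype changes", {
  # single-cyclin strain: Clb2G can be driven directly by SBF
  rs <- mutant_ruleset("clns-clb2")
  st <- string_to_state("0100000")
  cand <- candidate_state(st, rs)
  expect_equal(unname(cand["Clb2G"]), 1L)
  # and Clb5 is never a candidate
  tab <- candidate_table(rs)
  expect_true(all(tab[, "Clb5"] == 0L))
  # methionine-repressed Cln2: always off, and a doubled critical size
  rs2 <- mutant_ruleset("met3pr-cln2-clb2")
  tab2 <- candidate_table(rs2)
  expect_true(all(tab2[, "Cln2"] == 0L))
  expect_equal(rs2$param_overrides$S0_mean, 0.8)
  expect_equal(resolve_params(default_params(), rs2)$S0_mean, 0.8)
  # cln3 deletion: wild-type logic, larger critical size
  rs3 <- mutant_ruleset("dcln3")
  expect_identical(candidate_table(rs3), candidate_table(ruleset()))
  expect_equal(resolve_params(default_params(), rs3)$S0_mean, 0.68)
  expect_equal(resolve_params(default_params(),
                              mutant_ruleset("dcln3", s0_mean = 0.75))$S0_mean,
               0.75)
  # wild-type label is the identity
  expect_identical(candidate_table(mutant_ruleset("wild-type")),
                   candidate_table(ruleset()))
  expect_error(mutant_ruleset("nonsense"))
})

test_that("rule expressions are restricted to Boolean syntax over the variables", {
  f <- rule_function("Clb2M | ((Clb5 | Clb2G) & !Cdh1) | SBF")
  S <- all_states()
  expect_identical(f(S), as.integer(S[, 6] | ((S[, 4] | S[, 5]) & !S[, 1]) |
                                      S[, 2]))
  expect_error(rule_function("system('ls')"), "disallowed|unknown")
  expect_error(rule_function("Cdh1 + 1"), "disallowed")
  expect_error(rule_function("Foo & Cdh1"), "unknown symbol")
})
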