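test_that("cycle extraction reproduces exact durations from a synthetic log", {
  # one founder, two completed cycles with hand-written event times
  pop <- structure(list(
    cells = data.frame(cell_id = 1L, parent_id = NA_integer_,
                       pedigree = "mother", birth_time = 0,
                       birth_size = 0.65, s0 = 0.4),
    events = data.frame(
      cell_id = 1L,
      time = c(10, 20, 95, 120, 210),
      kind = c("start", "flip", "division", "start", "division"),
      variable = c("SBF", "Cln2", "Clb2G", "SBF", "Clb2G"),
      state = c("1100000", "1110000", "1000001", "1100000", "1000001"),
      size = c(0.7, 0.71, 0.6, 0.65, 0.62)),
    params = default_params(), horizon = 250, rules_label = "wild-type"),
    class = "bkmc_population")
  cy <- extract_cycles(pop)
  expect_identical(nrow(cy), 2L)
  expect_equal(cy$T_c, c(95, 115))
  expect_equal(cy$T_G1, c(10, 25))
  expect_equal(cy$T_bud, c(85, 90))
  expect_equal(cy$size_at_birth, c(0.65, 0.6))
  expect_identical(cy$pedigree, c("mother", "mother"))
  expect_identical(cy$scars, c(1L, 2L))
})

test_that("extracted cycles satisfy T_c = T_G1 + T_bud with positive parts", {
  cy <- extract_cycles(wt_population())
  expect_gt(nrow(cy), 500)
  expect_equal(cy$T_c, cy$T_G1 + cy$T_bud, tolerance = 1e-9)
  expect_true(all(cy$T_G1 > 0 & cy$T_bud > 0))
})

test_that("mothers are born larger and cycle faster than daughters", {
  cy <- extract_cycles(wt_population())
  s <- summarize_cycles(cy, burn_in = 400)
  get <- function(ped, q, col) s[s$pedigree == ped & s$quantity == q, col]
  expect_gt(get("mother", "size_at_birth", "mean"),
            get("daughter", "size_at_birth", "mean"))
  expect_gt(get("daughter", "T_c", "mean"), get("mother", "T_c", "mean"))
  expect_gt(get("daughter", "T_G1", "mean"), get("mother", "T_G1", "mean"))
  # identical records give a zero CV
  two <- extract_cycles(wt_population())[c(1L, 1L), ]
  z <- summarize_cycles(two)
  expect_true(all(z$cv == 0))
  expect_error(summarize_cycles(two[0L, ]), "no cycle")
})

test_that("the population count doubles at the mass-doubling time", {
  pop <- wt_population()
  g <- population_growth(pop, fit_window = c(300, 900))
  expect_lt(abs(g$doubling_time - log(2) / 0.007), 0.05 * log(2) / 0.007)
})

test_that("binned slope recovers the perfect-sizer and no-sizer limits exactly", {
  set.seed(20)
  n <- 2000
  mu <- 0.007
  size <- exp(stats::rnorm(n, log(0.45), 0.25))
  target <- 0.9
  sizer <- data.frame(cell_id = 1L, pedigree = "mother", scars = 1L,
                      birth_time = 0, size_at_birth = size,
                      T_c = 1, T_G1 = (log(target) - log(size)) / mu,
                      T_bud = 1)
  sizer <- sizer[sizer$T_G1 > 0, ]
  b <- binned_slope(sizer, "mother", mu = mu)
  expect_equal(b$slope, -1, tolerance = 1e-9)
  timer <- transform(sizer, T_G1 = 30)
  b0 <- binned_slope(timer, "mother", mu = mu)
  expect_equal(b0$slope, 0, tolerance = 1e-9)
  expect_error(binned_slope(sizer[1:3, ], "mother", mu = mu), "bins")
})

test_that("daughter two-line fit honours a fixed breakpoint and errors sensibly", {
  set.seed(21)
  n <- 3000
  mu <- 0.007
  size <- exp(stats::rnorm(n, log(0.45), 0.22))
  # piecewise size control: strong below 0.5, none above
  tg1 <- ifelse(size < 0.5, (log(0.5) - log(size)) / mu, 0) + 20
  rec <- data.frame(cell_id = 1L, pedigree = "daughter", scars = 0L,
                    birth_time = 0, size_at_birth = size, T_c = 1,
                    T_G1 = tg1, T_bud = 1)
  b <- binned_slope(rec, "daughter", mu = mu, breakpoint_fl = 0.5 * 61.4)
  expect_lt(b$slope_small, -0.85)
  expect_gt(b$slope_large, -0.1)
  expect_equal(b$breakpoint_fl, 30.7)
  expect_error(binned_slope(rec, "daughter", mu = mu, breakpoint_fl = 5),
               "breakpoint")
})

test_that("budded fractions start at zero for a synchronized G1 cohort and stay in [0,1]", {
  set.seed(22)
  pop <- run_population(n_founders = 30L, founder_size = 0.5,
                        founder_pedigree = "daughter", horizon = 250)
  bf <- budded_fraction(pop, times = seq(0, 250, by = 10), scars = 0L)
  expect_equal(bf$budded_fraction[1L], 0)
  ok <- !is.na(bf$budded_fraction)
  expect_true(all(bf$budded_fraction[ok] >= 0 & bf$budded_fraction[ok] <= 1))
  # a wave of budding passes through the synchronized newborns
  expect_gt(max(bf$budded_fraction[ok]), 0.5)
})

test_that("population averages damp towards intermediate activities", {
  set.seed(23)
  pop <- run_population(n_founders = 20L, founder_size = 0.65, horizon = 300)
  avg <- population_average(pop, times = c(0, 150, 300))
  expect_equal(avg$Cdh1[1L], 1)  # all founders start in stable G1
  expect_equal(avg$Clb2M[1L], 0)
  expect_true(all(avg$n_cells == cumsum(c(20, diff(avg$n_cells)))))
  late <- avg[nrow(avg), ]
  expect_true(late$Cdh1 > 0.1 && late$Cdh1 < 0.95)
})

test_that("founders too short-lived to divide pass through unchanged", {
  set.seed(24)
  pop <- run_population(n_founders = 5L, horizon = 0.001)
  expect_identical(nrow(pop$cells), 5L)
  expect_identical(sum(pop$events$kind == "division"), 0L)
})
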