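test_that("noiseless on-grid generators are recovered exactly", {
  rr <- bt2_series(delta_a = 200, n = 22)
  fit <- heat_fit(rr, ctl_small())
  expect_true(fit$feasible)
  expect_identical(fit$objective, 0)
  expect_equal(fit$params$delta_a, 200)
  ## perturbing one interval by +2 ms moves the objective to exactly 2
  rr2 <- rr
  rr2[7] <- rr2[7] + 2
  fit2 <- heat_fit(rr2, ctl_small())
  expect_equal(fit2$objective, 2)
  expect_equal(fit2$params$delta_a, 200)
  expect_same_solution(fit2, brute_force_solve(rr2, ctl_small()))
})

test_that("enumeration equals the brute-force oracle on random instances", {
  ctl <- heat_control(grid_step = 5)
  set.seed(501)
  cases <- gen_recovery_cases(1, n_rr = 12, seed = 501)
  ## noisy structured instances across all presets
  for (case in cases) {
    y <- pmax(1, case$rr + sample(-20:20, 12, replace = TRUE))
    expect_same_solution(heat_fit(y, ctl), brute_force_solve(y, ctl))
  }
  ## unstructured uniform draws (typically clipped everywhere)
  for (i in 1:4) {
    y <- round(runif(12, 300, 1400))
    expect_same_solution(heat_fit(y, ctl), brute_force_solve(y, ctl))
  }
})

test_that("pruning and the delta_a restriction never change the solution", {
  set.seed(502)
  case <- gen_recovery_cases(1, n_rr = 12, blocktype_ids = 3, seed = 502)[[1]]
  y <- pmax(1, case$rr + sample(-10:10, 12, replace = TRUE))
  base <- heat_fit(y, heat_control(grid_step = 5))
  for (ctl in list(heat_control(grid_step = 5, prune = FALSE),
                   heat_control(grid_step = 5, restrict_delta_a = FALSE))) {
    expect_same_solution(base, heat_fit(y, ctl))
    expect_same_solution(base, brute_force_solve(y, ctl))
  }
})

test_that("delta_a bounds follow the conducted fraction with 25% slack", {
  two_one <- mavb_blocktype(9L, "pure 2:1",
                            list(mavb_level("II", list(list(c(2, 1))))))
  passthrough <- mavb_blocktype(8L, "1:1",
                                list(mavb_level("II", list(list(c(1, 1))))))
  ## rho = 1/2, mean RR 400: range within [175, 250] and containing 200
  b <- delta_a_bounds(two_one, rep(400, 10))
  expect_true(b[1] >= 175 && b[2] <= 250)
  expect_true(b[1] <= 200 && 200 <= b[2])
  ## rho = 1, mean RR 240: contains 240
  b <- delta_a_bounds(passthrough, rep(240, 10))
  expect_true(b[1] <= 240 && 240 <= b[2])
  ## rho * mean RR = 900 exceeds the 400 ms cap: empty range
  expect_length(delta_a_bounds(passthrough, rep(900, 10)), 0)
})

test_that("an instance with no feasible candidate returns a sentinel", {
  ## wildly alternating intervals no MAVB pattern can track within 150 ms
  y <- rep(c(200, 1400), 6)
  fit <- heat_fit(y, ctl_small())
  expect_false(fit$feasible)
  expect_identical(fit$objective, Inf)
  expect_null(fit$params)
  ## empty blocktype set: sentinel as well
  fit <- heat_fit(bt2_series(n = 12),
                  heat_control(blocktype_ids = integer(0)))
  expect_false(fit$feasible)
})

test_that("the returned objective lower-bounds any user-supplied candidate", {
  set.seed(503)
  case <- gen_recovery_cases(1, n_rr = 14, blocktype_ids = 1, seed = 503)[[1]]
  y <- pmax(1, case$rr + sample(-25:25, 14, replace = TRUE))
  fit <- heat_fit(y)
  ref <- mavb_objective(case$params, y)
  expect_true(fit$objective <= ref$objective)
})

test_that("sensitivity scan: counts, identity offset, quadratic segments", {
  y <- bt2_series(delta_a = 240, n = 10)
  ctl <- ctl_small()
  sc <- sensitivity_scan(y, index = 5, lo = -30, hi = 30, step = 1,
                         control = ctl)
  expect_equal(nrow(sc), 61)
  expect_equal(sc$objective[sc$offset == 0], heat_fit(y, ctl)$objective)
  ## within each constant-argmin run the squared objective is one quadratic
  ## in the offset: second differences are exactly 2 * step^2
  seg <- rle(sc$argmin)
  ends <- cumsum(seg$lengths)
  starts <- ends - seg$lengths + 1
  checked <- 0
  for (i in seq_along(seg$lengths)) {
    if (seg$lengths[i] < 3 || is.na(seg$values[i])) next
    dd <- diff(sc$objective_sq[starts[i]:ends[i]], differences = 2)
    expect_true(all(abs(dd - 2) < 1e-9))
    checked <- checked + 1
  }
  expect_gt(checked, 0)
  ## a perturbation driving the interval non-positive is recorded infeasible
  sc2 <- sensitivity_scan(c(100, rep(480, 9)), index = 1, lo = -150, hi = 0,
                          step = 50, control = ctl)
  expect_false(sc2$feasible[sc2$offset == -150])
})

test_that("solutions serialize to JSON and back", {
  fit <- heat_fit(bt2_series(n = 12), ctl_small())
  path <- tempfile(fileext = ".json")
  write_solution(fit, path)
  s <- read_solution(path)
  expect_equal(s$objective, fit$objective)
  expect_equal(s$delta_a, fit$params$delta_a)
  expect_equal(s$schema_version, "1")
  expect_equal(unlist(s$residuals), fit$residuals)
})
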