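test_that("atrial train is arithmetic and validates its input", {
  expect_equal(atrial_train(250, 0, 4), c(0, 250, 500, 750))
  expect_equal(atrial_train(182, 0, 3), c(0, 182, 364))
  expect_equal(atrial_train(1, 5, 2), c(5, 6))
  expect_error(atrial_train(0, 0, 3), class = "heatrr_invalid")
  expect_error(atrial_train(250, 0, 0), class = "heatrr_invalid")
})

test_that("ratio cycles encode conduction slots and Wenckebach positions", {
  expect_equal(ratio_cycle(list(c(2, 1))), c(1L, 0L))
  expect_equal(ratio_cycle(list(c(4, 3))), c(1L, 2L, 3L, 0L))
  expect_equal(ratio_cycle(list(c(1, 1))), 1L)
  expect_equal(ratio_cycle(list(c(2, 1), c(3, 2))), c(1L, 0L, 1L, 2L, 0L))
  expect_error(ratio_cycle(list(c(4, 2))))
})

test_that("conduct_level blocks, delays and cycles as specified", {
  ## fixed 2:1 Mobitz
  r <- conduct_level(c(0, 200, 400, 600),
                     block_level("II", list(c(2, 1)), delay = 60))
  expect_equal(r$times, c(60, 460))
  expect_equal(r$conducted, c(TRUE, FALSE, TRUE, FALSE))
  ## 4:3 Wenckebach: delays 50, 70, 90, reset after the dropped beat
  r <- conduct_level(seq(0, 1750, by = 250),
                     block_level("I", list(c(4, 3)), delay = 50, increment = 20))
  expect_equal(r$times, c(50, 320, 590, 1050, 1320, 1590))
  expect_equal(sum(r$conducted), 6L)
  ## 1:1 passthrough is the identity
  x <- c(3, 17, 40, 140)
  r <- conduct_level(x, block_level("I", list(c(1, 1))))
  expect_equal(r$times, x)
  expect_true(all(r$conducted))
  ## phase offset starts mid-cycle
  r <- conduct_level(c(0, 200, 400, 600),
                     block_level("II", list(c(2, 1)), phase = 1))
  expect_equal(r$conducted, c(FALSE, TRUE, FALSE, TRUE))
  ## an increment too large for the incoming spacing is infeasible
  expect_error(
    conduct_level(seq(0, 900, by = 100),
                  block_level("I", list(c(3, 2)), increment = 250)),
    class = "heatrr_infeasible")
})

test_that("forward simulation reproduces closed forms", {
  ## 1:1, no blocking: constant delta_a
  p <- mavb_params(250, list(block_level("I", list(c(1, 1)))))
  expect_equal(forward_simulate(p, 5)$ventricular_rr, rep(250, 5))
  ## 2:1 Mobitz: halved rate
  p <- mavb_params(200, list(block_level("II", list(c(2, 1)), delay = 60)))
  expect_equal(forward_simulate(p, 2)$ventricular_rr, c(400, 400))
  ## 4:3 Wenckebach closed form: (da+inc, da+inc, 2 da - 2 inc) repeating
  expect_equal(forward_simulate(wenckebach_params(), 6)$ventricular_rr,
               c(270, 270, 460, 270, 270, 460))
  ## closed form for all single-level (n+1):n Type I cycles:
  ## (n-1) intervals of da+inc, then 2 da - (n-1) inc
  for (n in 2:5) {
    da <- 300; inc <- 15
    p <- mavb_params(da, list(block_level("I", list(c(n + 1, n)),
                                          increment = inc)))
    rr <- forward_simulate(p, 2 * n)$ventricular_rr
    expected <- rep(c(rep(da + inc, n - 1), 2 * da - (n - 1) * inc),
                    length.out = 2 * n)
    expect_equal(rr, expected, info = paste("ratio", n + 1, ":", n))
  }
})

test_that("simulation traces conserve signals and keep exact atrial spacing", {
  cases <- gen_recovery_cases(2, n_rr = 12, seed = 301)
  for (case in cases) {
    tr <- forward_simulate(case$params, 12)
    ## level-0 spacing is exactly delta_a
    expect_true(all(diff(tr$times_per_level[[1]]) == case$params$delta_a))
    ## conducted + blocked = incoming, per level
    for (l in seq_along(tr$conducted_flags)) {
      expect_equal(length(tr$conducted_flags[[l]]),
                   length(tr$times_per_level[[l]]))
      expect_equal(sum(tr$conducted_flags[[l]]),
                   length(tr$times_per_level[[l + 1]]))
    }
    expect_true(all(tr$ventricular_rr > 0))
  }
})

test_that("the atrial offset cancels from RR intervals and the objective", {
  cases <- gen_recovery_cases(1, n_rr = 10, seed = 302)
  for (case in cases) {
    p2 <- case$params
    p2$t_start <- 1234
    expect_equal(forward_simulate(p2, 10)$ventricular_rr, case$rr)
    expect_equal(mavb_objective(p2, case$rr)$objective, 0)
  }
})

test_that("the objective is the Euclidean norm with 150 ms clipping", {
  p <- wenckebach_params()
  ## self-match: zero residuals
  rr <- forward_simulate(p, 8)$ventricular_rr
  r <- mavb_objective(p, rr)
  expect_equal(r$objective, 0)
  expect_true(r$feasible)
  ## a single 10 ms deviation gives F = 10
  r <- mavb_objective(p, c(270, 280, 460))
  expect_equal(r$residuals, c(0, -10, 0))
  expect_equal(r$objective, 10)
  ## a 200 ms deviation exceeds the clip: infeasible, objective Inf
  r <- mavb_objective(p, c(270, 270, 660))
  expect_false(r$feasible)
  expect_identical(r$objective, Inf)
})

test_that("forward and inverse objective agree for all presets", {
  ## objective(params, forward_simulate(params)) = 0, randomized draws
  cases <- gen_recovery_cases(3, n_rr = 15, seed = 303)
  expect_length(cases, 15)
  for (case in cases) {
    r <- mavb_objective(case$params, case$rr)
    expect_equal(r$objective, 0)
    expect_true(r$feasible)
  }
})

test_that("degenerate and invalid model inputs signal errors", {
  expect_error(rr_series(c(200)), class = "heatrr_invalid")
  expect_error(rr_series(c(200, -5)), class = "heatrr_invalid")
  expect_warning(rr_series(c(200.7, 300.2, 400)), "rounded")
  expect_error(mavb_params(0, list(block_level("I", list(c(1, 1))))),
               class = "heatrr_invalid")
  expect_error(block_level("II", list(c(2, 1)), increment = 5),
               class = "heatrr_invalid")
  expect_error(block_level("I", list(c(2, 1)), phase = 2),
               class = "heatrr_invalid")
})
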