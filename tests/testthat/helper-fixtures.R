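## Shared fixtures: everything is built in code at test time.

## reduced search space for fast solver tests
ctl_small <- function(...) heat_control(blocktype_ids = 1:2, ...)

## noiseless 2:1 Mobitz simulation (constant RR = 2 * delta_a)
bt2_series <- function(delta_a = 200, n = 22, delay = 60) {
  p <- mavb_params(delta_a,
                   list(block_level("II", list(c(2, 1)), delay = delay)),
                   blocktype_id = 2L)
  forward_simulate(p, n)$ventricular_rr
}

## the 4:3 Wenckebach reference parameters
wenckebach_params <- function(delta_a = 250, increment = 20, delay = 50) {
  mavb_params(delta_a,
              list(block_level("I", list(c(4, 3)), delay = delay,
                               increment = increment)),
              blocktype_id = 1L)
}

## compare two heat_fit results for identical argmin (objective + params)
expect_same_solution <- function(a, b) {
  expect_identical(a$feasible, b$feasible)
  expect_identical(a$objective, b$objective)
  if (a$feasible) {
    expect_identical(a$params$delta_a, b$params$delta_a)
    expect_identical(a$params$blocktype_id, b$params$blocktype_id)
    expect_identical(unname(a$oc), unname(b$oc))
  }
}
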