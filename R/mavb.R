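## Forward model: a regular atrial impulse train cascaded through up to three
## blocking levels.  All times in milliseconds on an integer grid.

stop_invalid <- function(msg) {
  stop(structure(class = c("heatrr_invalid", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_infeasible <- function(msg) {
  stop(structure(class = c("heatrr_infeasible", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_degenerate <- function(msg) {
  stop(structure(class = c("heatrr_degenerate", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' RR-interval series
#'
#' Lightweight container for one sample: consecutive RR-interval durations in
#' milliseconds at 1 ms resolution, with optional class label and patient age.
#' Most functions in the package also accept a bare numeric vector.
#'
#' @param intervals numeric vector of RR durations (ms), length >= 2, all > 0.
#'   Off-grid values are rounded to the 1 ms grid with a warning.
#' @param label optional, \code{"AFib"} or \code{"AFlu"}.
#' @param age optional age in years.
#' @param sample_id,patient_id optional identifiers.
#' @return an object of class \code{rr_series}.
#' @export
rr_series <- function(intervals, label = NULL, age = NULL,
                      sample_id = NULL, patient_id = NULL) {
  if (length(intervals) < 2L) stop_invalid("an RR series needs at least 2 intervals")
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop_invalid("RR intervals must be positive and finite")
  r <- round(intervals)
  if (any(abs(intervals - r) > 1e-9))
    warning("off-grid RR intervals rounded to the 1 ms grid")
  if (!is.null(label)) label <- match.arg(label, c("AFib", "AFlu"))
  structure(list(intervals = as.integer(r), label = label, age = age,
                 sample_id = sample_id, patient_id = patient_id),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("RR series%s: %d intervals, mean %.0f ms%s\n",
              if (is.null(x$sample_id)) "" else paste0(" ", x$sample_id),
              length(x$intervals), mean(x$intervals),
              if (is.null(x$label)) "" else paste0(", label ", x$label)))
  print(x$intervals)
  invisible(x)
}

## coerce numeric vector / rr_series to integer intervals
rr_intervals <- function(x) {
  if (inherits(x, "rr_series")) return(x$intervals)
  rr_series(x)$intervals
}

#' Regular atrial impulse train
#'
#' @param delta_a atrial cycle length (ms), > 0.
#' @param t_start time of the first impulse (ms).
#' @param count number of impulses, >= 1.
#' @return strictly increasing numeric vector
#'   \code{t_start + (0:(count-1)) * delta_a}.
#' @export
atrial_train <- function(delta_a, t_start = 0, count) {
  if (length(delta_a) != 1L || !is.finite(delta_a) || delta_a <= 0)
    stop_invalid("delta_a must be a single positive number")
  if (length(count) != 1L || count < 1 || count != round(count))
    stop_invalid("count must be a positive integer")
  t_start + (seq_len(count) - 1) * delta_a
}

#' Concrete blocking level
#'
#' @param type \code{"I"} (Wenckebach: conduction delay grows linearly within
#'   a cycle and resets after the dropped beat) or \code{"II"} (Mobitz: fixed
#'   delay).
#' @param pattern list of block-ratio pairs cycled in order, see
#'   \code{\link{ratio_cycle}}.
#' @param phase integer phase offset into the conduction cycle,
#'   \code{0 <= phase < length(ratio_cycle(pattern))}.
#' @param delay base conduction delay c (ms), >= 0.
#' @param increment per-position delay increment (ms), >= 0; Type I only
#'   (forced to 0 for Type II).
#' @return an object of class \code{block_level}.
#' @export
block_level <- function(type = c("I", "II"), pattern, phase = 0L,
                        delay = 0L, increment = 0L) {
  type <- match.arg(type)
  slots <- ratio_cycle(pattern)
  phase <- as.integer(phase)
  if (phase < 0L || phase >= length(slots))
    stop_invalid("phase must lie in [0, cycle length)")
  if (delay < 0 || increment < 0) stop_invalid("delay and increment must be >= 0")
  if (type == "II" && increment != 0)
    stop_invalid("Type II levels have a fixed delay (increment must be 0)")
  structure(list(type = type, pattern = pattern, slots = slots, phase = phase,
                 delay = delay, increment = increment),
            class = "block_level")
}

#' Conduct an impulse train through one blocking level
#'
#' Walks the incoming signals through the level's conduction cycle starting at
#' its phase offset.  A signal at Wenckebach position \code{k} leaves at
#' \code{t + delay + (k - 1) * increment}; the dropped slot of each ratio pair
#' blocks its signal.
#'
#' @param incoming strictly increasing times (ms).
#' @param level a \code{\link{block_level}}.
#' @return list with \code{times} (outgoing, strictly increasing) and
#'   \code{conducted} (logical flag per incoming signal).  Signals an
#'   infeasible-parameters error if the outgoing times are not strictly
#'   increasing (increment too large for the incoming spacing).
#' @export
conduct_level <- function(incoming, level) {
  stopifnot(inherits(level, "block_level"))
  if (is.unsorted(incoming, strictly = TRUE))
    stop_invalid("incoming times must be strictly increasing")
  n <- length(incoming)
  slots <- level$slots
  idx <- ((level$phase + seq_len(n) - 1L) %% length(slots)) + 1L
  k <- slots[idx]
  conducted <- k > 0L
  out <- incoming[conducted] + level$delay + (k[conducted] - 1L) * level$increment
  if (is.unsorted(out, strictly = TRUE))
    stop_infeasible("level parameters yield non-increasing conducted times")
  list(times = out, conducted = conducted)
}

#' Parameter point of the MAVB model
#'
#' @param delta_a atrial cycle length (ms), integer grid.
#' @param levels list of \code{\link{block_level}} objects (1 to 3).
#' @param blocktype_id optional integer id of the preset the levels came from.
#' @param t_start atrial train offset (ms).  The offset shifts all activation
#'   times uniformly and cancels from every RR interval, so it is fixed to 0
#'   by convention.
#' @return an object of class \code{mavb_params}.
#' @export
mavb_params <- function(delta_a, levels, blocktype_id = NA_integer_, t_start = 0) {
  if (!is.list(levels) || !length(levels) ||
      !all(vapply(levels, inherits, logical(1), "block_level")))
    stop_invalid("levels must be a non-empty list of block_level objects")
  if (length(levels) > 3L) stop_invalid("at most 3 block levels")
  if (delta_a <= 0) stop_invalid("delta_a must be positive")
  structure(list(delta_a = delta_a, levels = levels,
                 blocktype_id = as.integer(blocktype_id), t_start = t_start),
            class = "mavb_params")
}

#' @export
print.mavb_params <- function(x, ...) {
  cat(sprintf("MAVB parameters: delta_a = %g ms, %d level(s)%s\n",
              x$delta_a, length(x$levels),
              if (is.na(x$blocktype_id)) "" else sprintf(" (blocktype %d)", x$blocktype_id)))
  for (i in seq_along(x$levels)) {
    lv <- x$levels[[i]]
    rat <- paste(vapply(lv$pattern, function(p) paste0(p[1], ":", p[2]), ""),
                 collapse = "/")
    cat(sprintf("  level %d: Type %-2s %s phase %d delay %g increment %g\n",
                i, lv$type, rat, lv$phase, lv$delay, lv$increment))
  }
  invisible(x)
}

## Phase-state period of the cascade: the joint phase vector evolves under an
## invertible map on a finite set, hence is purely periodic.  Returns atrial
## period P and conducted count Q per period.
cascade_period <- function(levels) {
  phases <- vapply(levels, `[[`, integer(1), "phase")
  slot_list <- lapply(levels, `[[`, "slots")
  lens <- lengths(slot_list)
  state <- phases
  p <- 0L; q <- 0L
  repeat {
    surv <- TRUE
    for (l in seq_along(levels)) {
      if (!surv) break
      k <- slot_list[[l]][state[l] + 1L]
      state[l] <- (state[l] + 1L) %% lens[l]
      if (k == 0L) surv <- FALSE
    }
    p <- p + 1L
    if (surv) q <- q + 1L
    if (identical(state, phases)) break
    if (p > 10000L) stop_degenerate("conduction cascade does not close")
  }
  if (q == 0L) stop_degenerate("blocktype conducts no signal at all")
  list(P = p, Q = q)
}

#' Forward simulation of the MAVB cascade
#'
#' Generates enough atrial impulses for the final level to conduct at least
#' \code{n_intervals + 1} signals, cascades them through all levels and
#' returns the activation times per level together with the ventricular RR
#' intervals.
#'
#' @param params an \code{\link{mavb_params}} object.
#' @param n_intervals number of ventricular RR intervals required.
#' @return an object of class \code{mavb_sim}: list with
#'   \code{times_per_level} (level 0 = atrium), \code{conducted_flags}
#'   (per level below the atrium) and \code{ventricular_rr}
#'   (exactly \code{n_intervals} intervals, ms).
#' @export
forward_simulate <- function(params, n_intervals) {
  stopifnot(inherits(params, "mavb_params"))
  if (n_intervals < 1 || n_intervals != round(n_intervals))
    stop_invalid("n_intervals must be a positive integer")
  per <- cascade_period(params$levels)
  count <- ceiling((n_intervals + 1) * per$P / per$Q) + per$P
  for (tries in 1:6) {
    t0 <- atrial_train(params$delta_a, params$t_start, count)
    times <- vector("list", length(params$levels) + 1L)
    flags <- vector("list", length(params$levels))
    times[[1L]] <- t0
    cur <- t0
    for (l in seq_along(params$levels)) {
      res <- conduct_level(cur, params$levels[[l]])
      cur <- res$times
      times[[l + 1L]] <- cur
      flags[[l]] <- res$conducted
    }
    if (length(cur) >= n_intervals + 1L) {
      rr <- diff(cur)[seq_len(n_intervals)]
      if (any(rr <= 0)) stop_infeasible("simulated RR intervals not positive")
      return(structure(list(times_per_level = times, conducted_flags = flags,
                            ventricular_rr = rr),
                       class = "mavb_sim"))
    }
    count <- count * 2L
  }
  stop_degenerate("cascade conducts too few signals")
}

#' @export
print.mavb_sim <- function(x, ...) {
  cat(sprintf("MAVB simulation: %d levels, %d ventricular intervals\n",
              length(x$conducted_flags), length(x$ventricular_rr)))
  print(x$ventricular_rr)
  invisible(x)
}

#' Deviation objective of a parameter point against observed RR data
#'
#' Forward-simulates \code{params} and measures the deviation from the
#' observed series in the Euclidean norm.  A candidate whose simulation
#' deviates by more than \code{clip} ms in any single interval is clipped:
#' it is reported infeasible with an infinite objective.
#'
#' @param params an \code{\link{mavb_params}}.
#' @param observed numeric vector or \code{\link{rr_series}}.
#' @param shift integer; compare the simulation's intervals
#'   \code{(1+shift)..(n+shift)} against the observed window.  Negative
#'   shifts are lifted by the exact period of the conduction cascade.  Used
#'   by the moving-horizon cross-window evaluation.
#' @param clip per-interval clipping threshold (ms).
#' @return list with \code{objective} (ms; \code{Inf} when clipped or the
#'   parameters are infeasible), \code{residuals} (simulated - observed) and
#'   \code{feasible}.
#' @export
mavb_objective <- function(params, observed, shift = 0L, clip = 150) {
  y <- rr_intervals(observed)
  n <- length(y)
  shift <- as.integer(shift)
  if (shift < 0L) {
    q <- cascade_period(params$levels)$Q
    shift <- shift + ceiling(-shift / q) * q
  }
  sim <- tryCatch(forward_simulate(params, n + shift)$ventricular_rr,
                  heatrr_infeasible = function(e) NULL,
                  heatrr_degenerate = function(e) NULL)
  if (is.null(sim))
    return(list(objective = Inf, residuals = rep(NA_real_, n), feasible = FALSE))
  r <- sim[(1L + shift):(n + shift)] - y
  feasible <- all(abs(r) <= clip)
  list(objective = if (feasible) sqrt(sum(r^2)) else Inf,
       residuals = r, feasible = feasible)
}
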