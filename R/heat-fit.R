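#' Solver configuration
#'
#' Collects everything that defines the feasible set of the inverse
#' simulation: the physiological atrial cycle bounds, the time grid, the
#' blocktype presets to search, the increment bounds and the clipping
#' threshold.
#'
#' @param delta_a_bounds atrial cycle length bounds (ms), default
#'   \code{c(175, 400)} from physiological observation.
#' @param grid_step time grid (ms) for \code{delta_a} and the conduction
#'   increments; default 1 ms.
#' @param blocktype_ids subset of preset ids to search (default all five).
#' @param blocktypes blocktype registry, see \code{\link{mavb_blocktypes}}.
#' @param increment_max upper bound (ms) of the Wenckebach delay increment
#'   grid \code{[0, increment_max]}.
#' @param clip per-interval clipping threshold (ms); any candidate whose
#'   simulation deviates by more than this in a single interval is discarded.
#' @param prune enable monotone prefix-sum pruning in the brute-force path.
#' @param restrict_delta_a intersect the \code{delta_a} grid with the
#'   data-consistency range \code{rho * mean(RR) * (1 +/- tau)} per searched
#'   structure (\code{rho} = conducted fraction); applied identically in both
#'   solver paths.
#' @param tau relative slack of the data-consistency range.
#' @param oc_encode length to which the free-parameter vector is padded (or
#'   truncated) in numeric feature encodings.
#' @return an object of class \code{heat_control}.
#' @export
heat_control <- function(delta_a_bounds = c(175, 400), grid_step = 1,
                         blocktype_ids = 1:5, blocktypes = mavb_blocktypes(),
                         increment_max = 100, clip = 150, prune = TRUE,
                         restrict_delta_a = TRUE, tau = 0.25, oc_encode = 4) {
  stopifnot(length(delta_a_bounds) == 2L, delta_a_bounds[1] >= 0,
            delta_a_bounds[1] < delta_a_bounds[2], grid_step >= 1)
  structure(list(
    delta_a_bounds = as.integer(round(delta_a_bounds)),
    grid_step = as.integer(grid_step),
    blocktype_ids = as.integer(blocktype_ids),
    blocktypes = blocktypes,
    increment_max = as.integer(increment_max),
    clip = as.integer(clip),
    prune = isTRUE(prune),
    restrict_delta_a = isTRUE(restrict_delta_a),
    tau = tau,
    oc_encode = as.integer(oc_encode),
    default_registry = identical(blocktypes, mavb_blocktypes())
  ), class = "heat_control")
}

#' Fit the MAVB model to an observed RR series by inverse simulation
#'
#' Globally minimizes the Euclidean deviation between the forward-simulated
#' and the observed RR intervals over the discrete feasible set (blocktype,
#' atrial cycle length and conduction parameters on the millisecond grid).
#' The search is exact: the default path eliminates the \code{delta_a}
#' dimension analytically per combinatorial structure, and
#' \code{method = "brute"} is the definitional exhaustive loop over the same
#' candidate set; both return the identical, deterministically tie-broken
#' minimizer.
#'
#' @param observed numeric vector or \code{\link{rr_series}} (ms, >= 2
#'   intervals).
#' @param control a \code{\link{heat_control}} configuration.
#' @param method \code{"enumerate"} (default) or \code{"brute"}.
#' @param window optional \code{c(start, end)} (1-based, inclusive) selecting
#'   a sub-series to fit.
#' @return an object of class \code{heat_fit} with components \code{params}
#'   (an \code{\link{mavb_params}}, \code{NULL} when no candidate is
#'   feasible), \code{objective} (ms; \code{Inf} when infeasible),
#'   \code{residuals}, \code{fitted}, \code{feasible},
#'   \code{n_candidates}, \code{window} and \code{control}.
#' @seealso \code{\link{brute_force_solve}}, \code{\link{sensitivity_scan}},
#'   \code{\link{delta_a_bounds}}
#' @examples
#' sim <- forward_simulate(mavb_params(250, list(
#'   block_level("I", list(c(4, 3)), increment = 20, delay = 50))), 8)
#' fit <- heat_fit(sim$ventricular_rr,
#'                 heat_control(blocktype_ids = 1:2))
#' coef(fit)
#' @export
heat_fit <- function(observed, control = heat_control(),
                     method = c("enumerate", "brute"), window = NULL) {
  method <- match.arg(method)
  y_all <- rr_intervals(observed)
  if (is.null(window)) window <- c(1L, length(y_all))
  stopifnot(length(window) == 2L, window[1] >= 1L, window[2] <= length(y_all),
            window[2] - window[1] >= 1L)
  y <- y_all[window[1]:window[2]]
  structures <- heat_structures(control, length(y))
  res <- .solve_grid(y, structures,
                     control$delta_a_bounds[1], control$delta_a_bounds[2],
                     control$grid_step, control$clip,
                     brute = (method == "brute"), prune = control$prune,
                     restrict_da = control$restrict_delta_a, tau = control$tau)
  if (!isTRUE(res$found)) {
    out <- list(params = NULL, objective = Inf, objective_sq = Inf,
                residuals = rep(NA_real_, length(y)), fitted = NULL,
                feasible = FALSE, oc = NULL,
                n_candidates = res$n_eval, observed = y,
                window = as.integer(window), control = control,
                method = method)
    return(structure(out, class = "heat_fit"))
  }
  str <- structures[[res$struct_idx]]
  params <- structure_params(control, str, res$delta_a, res$deltas)
  fitted <- forward_simulate(params, length(y))$ventricular_rr
  resid <- fitted - y
  if (abs(sum(as.numeric(resid)^2) - res$F2) > 1e-6)
    warning("internal inconsistency between solver and forward simulation")
  oc <- res$oc
  names(oc) <- names(str$oc)
  out <- list(params = params, objective = sqrt(res$F2), objective_sq = res$F2,
              residuals = resid, fitted = fitted, feasible = TRUE,
              oc = oc, n_candidates = res$n_eval, observed = y,
              window = as.integer(window), control = control,
              method = method)
  structure(out, class = "heat_fit")
}

#' Definitional exhaustive solver (testing oracle)
#'
#' Identical contract to \code{\link{heat_fit}}, but evaluates every grid
#' candidate by direct accumulation.  Used as the independent oracle for the
#' enumeration path; on any instance both must return the same objective and
#' the same tie-broken minimizer.
#'
#' @inheritParams heat_fit
#' @return a \code{heat_fit} object.
#' @export
brute_force_solve <- function(observed, control = heat_control(), window = NULL) {
  heat_fit(observed, control = control, method = "brute", window = window)
}

#' Data-consistent atrial cycle range for a blocktype
#'
#' The conducted fraction \code{rho} of a blocktype ties the atrial cycle to
#' the observed mean RR interval (\code{delta_a ~= rho * mean(RR)}, since the
#' increments cancel over full conduction cycles).  The returned range is the
#' intersection of the physiological bounds with
#' \code{[rho_min * mean(RR) * (1 - tau), rho_max * mean(RR) * (1 + tau)]},
#' where \code{rho} ranges over the blocktype's ratio options.
#'
#' @param blocktype a blocktype definition from the registry, or an integer
#'   preset id.
#' @param observed numeric vector or \code{\link{rr_series}}.
#' @param control a \code{\link{heat_control}}.
#' @return numeric \code{c(lo, hi)} in ms, or \code{numeric(0)} when the
#'   intersection is empty (blocktype implausible for this sample).
#' @export
delta_a_bounds <- function(blocktype, observed, control = heat_control()) {
  if (is.numeric(blocktype)) {
    bt <- NULL
    for (b in control$blocktypes) if (b$id == blocktype) bt <- b
    if (is.null(bt)) stop_invalid("unknown blocktype id")
  } else bt <- blocktype
  y <- rr_intervals(observed)
  rho_lo <- 1; rho_hi <- 1
  for (lv in bt$levels) {
    fr <- vapply(lv$options, function(opt) {
      s <- ratio_cycle(opt); sum(s > 0) / length(s)
    }, numeric(1))
    rho_lo <- rho_lo * min(fr)
    rho_hi <- rho_hi * max(fr)
  }
  m <- mean(y)
  lo <- max(control$delta_a_bounds[1], rho_lo * m * (1 - control$tau))
  hi <- min(control$delta_a_bounds[2], rho_hi * m * (1 + control$tau))
  if (lo > hi) return(numeric(0))
  c(lo, hi)
}

#' Objective landscape under perturbation of a single interval
#'
#' Replays the inverse simulation for copies of the input in which one
#' interval is shifted by every offset on a grid, tracing how the optimal
#' objective responds.  Within any maximal run of offsets sharing the same
#' minimizer the squared objective is exactly quadratic in the offset; the
#' jumps between runs are the clipping-induced switches to a different
#' feasible candidate.
#'
#' @param observed numeric vector or \code{\link{rr_series}}.
#' @param index position of the perturbed interval.
#' @param lo,hi offset range (ms), \code{lo <= 0 <= hi}.
#' @param step offset step (ms).
#' @param control a \code{\link{heat_control}}.
#' @return data frame with one row per offset: \code{offset},
#'   \code{objective}, \code{objective_sq}, \code{feasible}, \code{delta_a},
#'   \code{blocktype} and \code{argmin} (a label identifying the minimizer,
#'   constant within each quadratic segment).
#' @export
sensitivity_scan <- function(observed, index, lo = -400, hi = 400, step = 1,
                             control = heat_control()) {
  y <- rr_intervals(observed)
  stopifnot(index >= 1L, index <= length(y), lo <= 0, hi >= 0, step >= 1)
  offsets <- seq.int(lo, hi, by = step)
  structures <- heat_structures(control, length(y))
  out <- data.frame(offset = offsets, objective = NA_real_,
                    objective_sq = NA_real_, feasible = FALSE,
                    delta_a = NA_real_, blocktype = NA_integer_,
                    argmin = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(offsets)) {
    y2 <- y
    y2[index] <- y2[index] + offsets[i]
    if (y2[index] <= 0) next  # recorded as infeasible
    res <- .solve_grid(y2, structures,
                       control$delta_a_bounds[1], control$delta_a_bounds[2],
                       control$grid_step, control$clip,
                       brute = FALSE, prune = control$prune,
                       restrict_da = control$restrict_delta_a,
                       tau = control$tau)
    if (!isTRUE(res$found)) next
    out$objective[i] <- sqrt(res$F2)
    out$objective_sq[i] <- res$F2
    out$feasible[i] <- TRUE
    out$delta_a[i] <- res$delta_a
    out$blocktype[i] <- res$bt
    out$argmin[i] <- paste(res$bt, res$struct_idx, res$delta_a,
                           paste(res$oc, collapse = ","), sep = "|")
  }
  out$objective[!out$feasible] <- Inf
  out$objective_sq[!out$feasible] <- Inf
  out
}

## ---- S3 methods for heat_fit -------------------------------------------

#' @export
print.heat_fit <- function(x, ...) {
  if (!x$feasible) {
    cat("HEAT fit: no feasible MAVB candidate (all clipped)\n")
    return(invisible(x))
  }
  cat(sprintf("HEAT fit: objective %.3f ms over %d intervals\n",
              x$objective, length(x$observed)))
  cat(sprintf("  delta_a = %g ms, blocktype %d, oc = (%s)\n",
              x$params$delta_a, x$params$blocktype_id,
              paste(names(x$oc), x$oc, sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
summary.heat_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.heat_fit")
}

#' @export
print.summary.heat_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (f$feasible) {
    cat(sprintf("  RMS residual %.2f ms, max |residual| %.0f ms\n",
                sqrt(mean(f$residuals^2)), max(abs(f$residuals))))
    print(f$params)
  }
  cat(sprintf("  %d intervals (window %d..%d), %s path, %.0f candidates evaluated\n",
              length(f$observed), f$window[1], f$window[2], f$method,
              f$n_candidates))
  invisible(x)
}

#' @export
coef.heat_fit <- function(object, ...) {
  if (!object$feasible)
    return(c(delta_a = NA_real_, blocktype = NA_real_))
  c(delta_a = object$params$delta_a,
    blocktype = as.numeric(object$params$blocktype_id),
    stats::setNames(as.numeric(object$oc), names(object$oc)))
}

#' @export
fitted.heat_fit <- function(object, ...) object$fitted

#' @export
residuals.heat_fit <- function(object, ...) object$residuals

#' @export
predict.heat_fit <- function(object, n_intervals = length(object$observed), ...) {
  if (!object$feasible) stop_invalid("cannot predict from an infeasible fit")
  forward_simulate(object$params, n_intervals)$ventricular_rr
}

#' Simulate noisy RR series from a fitted MAVB model
#'
#' @param object a feasible \code{heat_fit}.
#' @param nsim number of series.
#' @param seed optional RNG seed.
#' @param jitter_sd measurement jitter standard deviation (ms).
#' @param ... unused.
#' @return matrix with \code{nsim} rows of simulated RR intervals (ms,
#'   integer grid).
#' @export
simulate.heat_fit <- function(object, nsim = 1, seed = NULL, jitter_sd = 5, ...) {
  if (!object$feasible) stop_invalid("cannot simulate from an infeasible fit")
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$observed)
  base <- forward_simulate(object$params, n)$ventricular_rr
  t(vapply(seq_len(nsim), function(i)
    pmax(1, round(base + stats::rnorm(n, 0, jitter_sd))), numeric(n)))
}

#' @export
plot.heat_fit <- function(x, ...) {
  n <- length(x$observed)
  plot(seq_len(n), x$observed, type = "b", pch = 16, xlab = "interval index",
       ylab = "RR (ms)", main = sprintf("HEAT fit (F = %.1f ms)", x$objective),
       ...)
  if (x$feasible) {
    graphics::lines(seq_len(n), x$fitted, type = "b", col = 2, pch = 1)
    graphics::legend("topright", legend = c("observed", "simulated"),
                     col = c(1, 2), pch = c(16, 1), bty = "n")
  }
  invisible(x)
}
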