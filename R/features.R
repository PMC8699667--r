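## Feature generation: basic RR statistics, HEAT-derived features, the
## moving-horizon HEAT series, N-gram subsequence statistics, and
## train-set standardization.

#' Basic RR statistics
#'
#' @param rr numeric vector or \code{\link{rr_series}} (>= 2 intervals).
#' @return named numeric: \code{RRmean} (ms) and \code{RRvar} (ms^2, sample
#'   variance).
#' @export
basic_features <- function(rr) {
  y <- rr_intervals(rr)
  c(RRmean = mean(y), RRvar = stats::var(y))
}

## saturation value reported for clipped/infeasible fits: the largest
## objective a feasible candidate could attain, sqrt(n) * clip
objective_saturation <- function(n, clip) sqrt(n) * clip

## numeric encoding of a solution: delta_a, blocktype id, free parameters
## padded (or truncated) to oc_encode values
encode_solution <- function(fit, control) {
  k <- control$oc_encode
  if (!fit$feasible) return(c(delta_a = 0, blocktype = 0,
                              stats::setNames(rep(0, k), paste0("oc", seq_len(k)))))
  oc <- as.numeric(fit$oc)
  oc <- if (length(oc) >= k) oc[seq_len(k)] else c(oc, rep(0, k - length(oc)))
  c(delta_a = fit$params$delta_a, blocktype = fit$params$blocktype_id,
    stats::setNames(oc, paste0("oc", seq_len(k))))
}

#' HEAT solution features of one RR series
#'
#' Runs the inverse simulation and returns the heatSolution feature layout:
#' the optimal objective, the numerically encoded optimal solution, and the
#' basic RR statistics.  With the default encoding length this is 9 features.
#' When no candidate is feasible the objective saturates at
#' \code{sqrt(n) * clip} and the solution fields are zero (flagged in the
#' \code{"clipped"} attribute).
#'
#' @param rr numeric vector or \code{\link{rr_series}}.
#' @param control a \code{\link{heat_control}}.
#' @return named numeric vector
#'   \code{(HEATobj, delta_a, blocktype, oc1..ocK, RRvar, RRmean)}.
#' @export
heat_features <- function(rr, control = heat_control()) {
  y <- rr_intervals(rr)
  fit <- heat_fit(y, control = control)
  obj <- if (fit$feasible) fit$objective
         else objective_saturation(length(y), control$clip)
  b <- basic_features(y)
  out <- c(HEATobj = obj, encode_solution(fit, control),
           RRvar = unname(b["RRvar"]), RRmean = unname(b["RRmean"]))
  attr(out, "clipped") <- !fit$feasible
  out
}

#' Moving-horizon windows
#'
#' Contiguous windows of length \code{n_sub} sliding with stride 1 over a
#' series of \code{n_rr} intervals; indices are 1-based and inclusive.
#'
#' @param rr an RR series, or a single integer total length \code{n_rr}.
#' @param n_sub window length, \code{10 <= n_sub <= n_rr}.
#' @return integer matrix with columns \code{start}, \code{end} and
#'   \code{n_rr - n_sub + 1} rows.
#' @export
moving_windows <- function(rr, n_sub) {
  n_rr <- if (length(rr) == 1L && is.numeric(rr)) as.integer(rr)
          else length(rr_intervals(rr))
  n_sub <- as.integer(n_sub)
  if (n_sub < 10L || n_sub > n_rr)
    stop_invalid("n_sub must lie in {10, ..., n_rr}")
  starts <- seq_len(n_rr - n_sub + 1L)
  cbind(start = starts, end = starts + n_sub - 1L)
}

#' Moving-horizon HEAT series
#'
#' Fits every window independently and records, per window k: the optimal
#' objective (HEATobj), the encoded optimal solution (HEATsol), and the
#' cross-window generalization HEATfit -- the objective of window k's
#' solution evaluated on window k+1 (the last window is evaluated on its
#' predecessor).  Cross-window evaluation aligns the simulation by shifting
#' it along the series, so on stationary data a perfect fit generalizes with
#' HEATfit = 0 exactly.  Clipped entries saturate at \code{sqrt(n_sub)*clip}.
#'
#' @param rr numeric vector or \code{\link{rr_series}}.
#' @param n_sub window length.
#' @param control a \code{\link{heat_control}}.
#' @return an object of class \code{heat_series}: list with \code{HEATobj}
#'   (numeric, one per window), \code{HEATsol} (matrix, one row per window),
#'   \code{HEATfit} (numeric), \code{windows} and \code{fits}.
#' @export
heat_series <- function(rr, n_sub, control = heat_control()) {
  y <- rr_intervals(rr)
  win <- moving_windows(length(y), n_sub)
  K <- nrow(win)
  sat <- objective_saturation(n_sub, control$clip)
  fits <- vector("list", K)
  obj <- numeric(K)
  sol <- NULL
  for (k in seq_len(K)) {
    fits[[k]] <- heat_fit(y, control = control, window = win[k, ])
    obj[k] <- if (fits[[k]]$feasible) fits[[k]]$objective else sat
    enc <- encode_solution(fits[[k]], control)
    if (is.null(sol)) sol <- matrix(0, K, length(enc),
                                    dimnames = list(NULL, names(enc)))
    sol[k, ] <- enc
  }
  fit_on <- function(k, j) {
    f <- fits[[k]]
    if (!f$feasible) return(sat)
    shift <- win[j, "start"] - win[k, "start"]
    r <- mavb_objective(f$params, y[win[j, "start"]:win[j, "end"]],
                        shift = shift, clip = control$clip)
    if (r$feasible) r$objective else sat
  }
  hfit <- vapply(seq_len(K), function(k) {
    j <- if (k < K) k + 1L else K - 1L
    if (K == 1L) obj[1L] else fit_on(k, j)
  }, numeric(1))
  structure(list(HEATobj = obj, HEATsol = sol, HEATfit = hfit,
                 windows = win, fits = fits, n_sub = n_sub),
            class = "heat_series")
}

#' @export
print.heat_series <- function(x, ...) {
  cat(sprintf("HEAT moving-horizon series: %d windows of length %d\n",
              nrow(x$windows), x$n_sub))
  print(rbind(HEATobj = round(x$HEATobj, 2), HEATfit = round(x$HEATfit, 2)))
  invisible(x)
}

#' Mean/sd summary of a moving-horizon HEAT series
#'
#' Mean and sample standard deviation of every component series (HEATobj,
#' each encoded solution column, HEATfit), concatenated; optionally the
#' patient age is appended.
#'
#' @param series a \code{\link{heat_series}}.
#' @param age optional age in years (appended as the final feature).
#' @return named numeric vector.  For a single-window series the standard
#'   deviations are undefined and reported as 0 with a warning.
#' @export
series_avg <- function(series, age = NULL) {
  stopifnot(inherits(series, "heat_series"))
  comp <- cbind(HEATobj = series$HEATobj, series$HEATsol,
                HEATfit = series$HEATfit)
  if (nrow(comp) < 2L) {
    warning("single-window series: standard deviations reported as 0")
    sds <- rep(0, ncol(comp))
  } else sds <- apply(comp, 2, stats::sd)
  out <- c(stats::setNames(colMeans(comp), paste0(colnames(comp), "_mean")),
           stats::setNames(sds, paste0(colnames(comp), "_sd")))
  if (!is.null(age)) out <- c(out, age = as.numeric(age))
  out
}

#' N-gram subsequence features
#'
#' Means of all \code{n(n+1)/2} contiguous subsequences (length >= 1) and
#' sample standard deviations of all \code{n(n-1)/2} subsequences of length
#' >= 2: exactly \code{n^2} features, ordered deterministically by start
#' index, then length (all means first, then all standard deviations).
#'
#' @param x numeric vector, length >= 2.
#' @return named numeric vector of length \code{length(x)^2}.
#' @export
ngram_features <- function(x) {
  n <- length(x)
  if (n < 2L) stop_invalid("N-gram features need at least 2 values")
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  means <- numeric(n * (n + 1) / 2); mn <- character(length(means))
  sds <- numeric(n * (n - 1) / 2);   sn <- character(length(sds))
  im <- 0L; is <- 0L
  for (s in seq_len(n)) {
    for (l in seq_len(n - s + 1L)) {
      sm <- cs[s + l] - cs[s]
      im <- im + 1L
      means[im] <- sm / l
      mn[im] <- sprintf("mean_s%d_l%d", s, l)
      if (l >= 2L) {
        ss <- cs2[s + l] - cs2[s]
        is <- is + 1L
        v <- (ss - sm^2 / l) / (l - 1)
        sds[is] <- sqrt(max(v, 0))
        sn[is] <- sprintf("sd_s%d_l%d", s, l)
      }
    }
  }
  stats::setNames(c(means, sds), c(mn, sn))
}

#' Train-set standardization
#'
#' Learns per-feature location (mean) and scale (standard deviation) from
#' training data only; the identical transformation is applied at evaluation
#' time, so no information leaks from held-out folds.
#'
#' @param x numeric matrix (samples in rows), >= 2 rows.
#' @return \code{fit_standardizer}: an object of class \code{standardizer}
#'   with \code{center} and \code{scale}; constant columns get scale 1 with a
#'   warning.
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_invalid("standardization needs >= 2 training samples")
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  if (any(scale == 0)) {
    warning(sprintf("%d constant feature(s): scale set to 1", sum(scale == 0)))
    scale[scale == 0] <- 1
  }
  structure(list(center = center, scale = scale), class = "standardizer")
}

#' @rdname fit_standardizer
#' @param params a \code{standardizer}.
#' @export
apply_standardizer <- function(params, x) {
  stopifnot(inherits(params, "standardizer"))
  x <- as.matrix(x)
  scale(x, center = params$center, scale = params$scale)[, , drop = FALSE]
}

#' Feature matrix of a dataset for one feature set
#'
#' Builds the per-sample feature matrix for one of the named feature sets:
#' \describe{
#'   \item{rawRR}{the raw RR intervals (first \code{n_sub} when given).}
#'   \item{rawRR_ngram}{N-gram statistics of the (truncated) raw series.}
#'   \item{heatObjective}{the optimal HEAT objective alone.}
#'   \item{heatSolution}{HEATobj, encoded solution, RRvar, RRmean.}
#'   \item{heatSerAvg / heatSerAvgAge}{mean/sd summary of the moving-horizon
#'     series (windows of \code{n_sub}), without / with age.}
#'   \item{heatSeries}{N-gram statistics of every moving-horizon component
#'     series, concatenated.}
#' }
#'
#' @param x a benchmark samples data frame (see \code{\link{make_benchmark}})
#'   or a list of RR vectors.
#' @param set feature set name.
#' @param n_sub window length for the moving-horizon sets and truncation
#'   length for the raw sets (default: full length for raw sets, 17 for
#'   moving-horizon sets).
#' @param control a \code{\link{heat_control}}.
#' @return numeric matrix, one row per sample, with feature names.
#' @export
heat_feature_set <- function(x, set = c("rawRR", "rawRR_ngram",
                                        "heatObjective", "heatSolution",
                                        "heatSerAvg", "heatSerAvgAge",
                                        "heatSeries"),
                             n_sub = NULL, control = heat_control()) {
  set <- match.arg(set)
  rrs <- as_rr_list(x)
  ages <- attr(rrs, "ages")
  one <- function(i) {
    y <- rrs[[i]]
    switch(set,
      rawRR = {
        if (!is.null(n_sub)) y <- y[seq_len(n_sub)]
        stats::setNames(as.numeric(y), sprintf("rr%02d", seq_along(y)))
      },
      rawRR_ngram = {
        if (!is.null(n_sub)) y <- y[seq_len(n_sub)]
        ngram_features(y)
      },
      heatObjective = heat_features(y, control)["HEATobj"],
      heatSolution = heat_features(y, control),
      heatSerAvg = series_avg(heat_series(y, n_sub %||% 17L, control)),
      heatSerAvgAge = series_avg(heat_series(y, n_sub %||% 17L, control),
                                 age = if (is.null(ages)) NA_real_ else ages[i]),
      heatSeries = {
        hs <- heat_series(y, n_sub %||% 17L, control)
        comp <- cbind(HEATobj = hs$HEATobj, hs$HEATsol, HEATfit = hs$HEATfit)
        unlist(lapply(colnames(comp), function(cn) {
          ng <- ngram_features(comp[, cn])
          stats::setNames(ng, paste0(cn, ".", names(ng)))
        }))
      })
  }
  rows <- lapply(seq_along(rrs), one)
  out <- do.call(rbind, rows)
  rownames(out) <- names(rrs)
  attr(out, "feature_set") <- set
  attr(out, "n_sub") <- n_sub
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## coerce benchmark samples / list of vectors / matrix to a list of integer
## RR vectors, with ages attached when available
as_rr_list <- function(x) {
  if (is.data.frame(x)) {
    rrcols <- grep("^rr_?[0-9]+$", names(x), value = TRUE)
    if (!length(rrcols)) stop_invalid("no rr_* columns found")
    rrs <- lapply(seq_len(nrow(x)), function(i) as.integer(unlist(x[i, rrcols])))
    names(rrs) <- if ("sample_id" %in% names(x)) as.character(x$sample_id)
                  else sprintf("s%04d", seq_len(nrow(x)))
    if ("age" %in% names(x)) attr(rrs, "ages") <- x$age
    return(rrs)
  }
  if (is.matrix(x)) x <- lapply(seq_len(nrow(x)), function(i) x[i, ])
  if (inherits(x, "rr_series")) x <- list(x)
  rrs <- lapply(x, rr_intervals)
  if (is.null(names(rrs))) names(rrs) <- sprintf("s%04d", seq_along(rrs))
  rrs
}
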