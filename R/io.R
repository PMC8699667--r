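## Readers and writers.  Samples travel as CSV (sample_id, label, age,
## rr_01..rr_NN), solutions and cross-validation results as JSON with a
## schema version, feature tables as CSV with a JSON sidecar.

.schema_version <- "1"

#' Read RR series from CSV
#'
#' Expects a header with \code{sample_id}, optional \code{label} and
#' \code{age}, and the interval columns \code{rr_01, rr_02, ...} (any
#' \code{rr*} numbering).  Values are validated; off-grid values are
#' rounded to the 1 ms grid with a warning.
#'
#' @param path CSV file.
#' @return list of \code{\link{rr_series}}.
#' @export
read_rr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rrcols <- grep("^rr_?[0-9]+$", names(df), value = TRUE)
  if (!("sample_id" %in% names(df)) || !length(rrcols))
    stop_invalid("CSV must have sample_id and rr_* columns")
  rrcols <- rrcols[order(as.integer(sub("^rr_?", "", rrcols)))]
  lapply(seq_len(nrow(df)), function(i) {
    vals <- as.numeric(df[i, rrcols])
    if (any(!is.finite(vals)) || any(vals <= 0))
      stop_invalid(sprintf("row %d (%s): non-positive or missing RR interval",
                           i, df$sample_id[i]))
    rr_series(vals,
              label = if ("label" %in% names(df)) df$label[i],
              age = if ("age" %in% names(df)) df$age[i],
              sample_id = as.character(df$sample_id[i]))
  })
}

#' Write RR series (or a benchmark) to CSV
#'
#' @param x list of \code{\link{rr_series}} or a \code{heat_benchmark}.
#' @param path CSV file.
#' @return the path, invisibly.
#' @export
write_rr_csv <- function(x, path) {
  if (inherits(x, "heat_benchmark")) {
    utils::write.csv(x$samples, path, row.names = FALSE)
    return(invisible(path))
  }
  n <- length(x[[1]]$intervals)
  rrmat <- t(vapply(x, `[[`, numeric(n), "intervals"))
  colnames(rrmat) <- sprintf("rr_%02d", seq_len(n))
  df <- data.frame(
    sample_id = vapply(seq_along(x), function(i)
      x[[i]]$sample_id %||% sprintf("s%04d", i), character(1)),
    label = vapply(x, function(s) s$label %||% NA_character_, character(1)),
    age = vapply(x, function(s) as.numeric(s$age %||% NA_real_), numeric(1)),
    rrmat, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a HEAT solution as JSON
#'
#' @param fit a \code{\link{heat_fit}}.
#' @param path JSON file.
#' @return the path, invisibly.
#' @export
write_solution <- function(fit, path) {
  stopifnot(inherits(fit, "heat_fit"))
  obj <- list(
    schema_version = .schema_version,
    feasible = fit$feasible,
    objective = if (is.finite(fit$objective)) fit$objective else "Inf",
    window = fit$window,
    n_candidates = fit$n_candidates,
    residuals = fit$residuals,
    observed = fit$observed)
  if (fit$feasible) {
    obj$delta_a <- fit$params$delta_a
    obj$blocktype <- fit$params$blocktype_id
    obj$oc <- as.list(fit$oc)
    obj$fitted <- fit$fitted
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_solution
#' @export
read_solution <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(s$objective, "Inf")) s$objective <- Inf
  s
}

#' Write a feature matrix as CSV with a JSON sidecar
#'
#' The sidecar (\code{<path>.json}) records the feature set, window length,
#' schema version and a checksum of the solver configuration so feature
#' tables are traceable to the run that produced them.
#'
#' @param x feature matrix from \code{\link{heat_feature_set}}.
#' @param path CSV file.
#' @param control the \code{\link{heat_control}} used (for the checksum).
#' @param labels optional label column to attach.
#' @return the path, invisibly.
#' @export
write_features <- function(x, path, control = NULL, labels = NULL) {
  df <- data.frame(sample_id = rownames(x) %||% sprintf("s%04d", seq_len(nrow(x))),
                   as.data.frame(x), check.names = FALSE)
  if (!is.null(labels)) df <- cbind(df[1], label = labels, df[-1])
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(schema_version = .schema_version,
               feature_set = attr(x, "feature_set"),
               n_sub = attr(x, "n_sub"),
               n_features = ncol(x),
               control_checksum = control_checksum(control))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

control_checksum <- function(control) {
  if (is.null(control)) return(NA_character_)
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(control[setdiff(names(control), "blocktypes")], tf)
  unname(tools::md5sum(tf))
}

#' Serialize a cross-validation result as JSON
#'
#' @param cv a \code{heat_cv} from \code{\link{cross_validate}}.
#' @param path JSON file.
#' @return the path, invisibly.
#' @export
write_cvresult <- function(cv, path) {
  stopifnot(inherits(cv, "heat_cv"))
  obj <- list(schema_version = .schema_version,
              model = cv$model, folds = cv$folds, repeats = cv$repeats,
              mean_accuracy = cv$mean_accuracy, sd_accuracy = cv$sd_accuracy,
              mean_roc = cv$mean_roc, sd_roc = cv$sd_roc,
              sensitivity = cv$sensitivity, specificity = cv$specificity,
              per_fold = cv$per_fold)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the ground-truth sidecar of a benchmark
#'
#' @param bench a \code{heat_benchmark}.
#' @param path JSON file.
#' @return the path, invisibly.
#' @export
write_truth <- function(bench, path) {
  stopifnot(inherits(bench, "heat_benchmark"))
  truth <- lapply(bench$truth, function(t) {
    t$params <- NULL  # concrete parameter object is not JSON material
    t
  })
  jsonlite::write_json(list(schema_version = .schema_version, seed = bench$seed,
                            truth = truth), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
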