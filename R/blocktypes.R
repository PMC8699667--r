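#' Conduction cycle template of a block-ratio pattern
#'
#' A block level conducts according to a cyclic pattern of block ratios.
#' Each ratio \code{(n+1):n} means \code{n+1} incoming signals, of which the
#' first \code{n} are conducted (at Wenckebach positions \code{k = 1..n}) and
#' the last is dropped; a \code{1:1} pair is a plain passthrough slot.
#' Alternating ratios (e.g. 2:1 / 3:2) are expressed as a list of pairs that
#' the level walks through in order, wrapping around.
#'
#' @param pairs list of integer pairs \code{c(incoming, conducted)}.
#' @return integer vector of slots, one per incoming signal of a full cycle:
#'   \code{k >= 1} for a conducted signal at Wenckebach position \code{k},
#'   \code{0} for a blocked signal.
#' @examples
#' ratio_cycle(list(c(2, 1)))           # 2:1 -> conduct, block
#' ratio_cycle(list(c(2, 1), c(3, 2)))  # alternating 2:1 / 3:2
#' @export
ratio_cycle <- function(pairs) {
  slots <- integer(0)
  for (p in pairs) {
    inc <- as.integer(p[[1]]); con <- as.integer(p[[2]])
    if (!(inc == con || inc == con + 1L) || con < 1L)
      stop("block ratio must be (n+1):n or 1:1 with n >= 1", call. = FALSE)
    slots <- c(slots, seq_len(con), if (inc == con + 1L) 0L)
  }
  slots
}

#' Level template and blocktype constructors
#'
#' Building blocks for custom blocktype registries.  A level template fixes
#' the block type (I or II) and the list of admissible ratio patterns; the
#' phase offset and (for Type I) the delay increment stay free and are
#' searched by the solver.
#'
#' @param type \code{"I"} or \code{"II"}.
#' @param options list of ratio patterns, each a list of
#'   \code{c(incoming, conducted)} pairs (see \code{\link{ratio_cycle}}).
#' @return \code{mavb_level}: a level template; \code{mavb_blocktype}: a
#'   blocktype definition usable in a registry.
#' @export
mavb_level <- function(type, options) {
  stopifnot(type %in% c("I", "II"))
  structure(list(type = type, options = options), class = "mavb_level_template")
}

#' @rdname mavb_level
#' @param id integer blocktype id.
#' @param name descriptive name.
#' @param levels list of level templates (1 to 3).
#' @export
mavb_blocktype <- function(id, name, levels) {
  stopifnot(length(levels) >= 1L, length(levels) <= 3L)
  list(id = as.integer(id), name = name, levels = levels)
}

new_level_template <- mavb_level

## single-pair options (n+1):n for n in ns
free_ratio_options <- function(ns) lapply(ns, function(n) list(c(n + 1L, n)))

#' Registry of multilevel AV block presets
#'
#' The model restricts itself to five clinically observed blocktype
#' combinations of at most three cascaded levels.  Each level is either
#' Mobitz Type II (fixed conduction delay) or Wenckebach Type I (conduction
#' delay growing linearly within a cycle, resetting after each dropped beat).
#' Free quantities per level are the block ratio (where several are allowed),
#' the phase offset into the conduction cycle and, for Type I levels, the
#' delay increment.
#'
#' The registry is an ordinary list and can be replaced wholesale (e.g. read
#' back from \code{\link{write_blocktypes}}) through the \code{blocktypes}
#' argument of \code{\link{heat_control}}.
#'
#' @return named list of five blocktype definitions, each with fields
#'   \code{id}, \code{name} and \code{levels}.
#' @export
mavb_blocktypes <- function() {
  bt <- list(
    list(id = 1L, name = "single Type I, free ratio",
         levels = list(new_level_template("I", free_ratio_options(1:5)))),
    list(id = 2L, name = "single Type II, free ratio",
         levels = list(new_level_template("II", free_ratio_options(1:5)))),
    list(id = 3L, name = "Type II 2:1 into Type I, free ratio",
         levels = list(new_level_template("II", list(list(c(2L, 1L)))),
                       new_level_template("I", free_ratio_options(1:5)))),
    list(id = 4L, name = "Type II 2:1/3:2 into two Type II 1:1/2:1",
         levels = list(new_level_template("II", list(list(c(2L, 1L), c(3L, 2L)))),
                       new_level_template("II", list(list(c(1L, 1L), c(2L, 1L)))),
                       new_level_template("II", list(list(c(1L, 1L), c(2L, 1L)))))),
    list(id = 5L, name = "two Type I levels, free ratios",
         levels = list(new_level_template("I", free_ratio_options(1:5)),
                       new_level_template("I", free_ratio_options(1:5))))
  )
  names(bt) <- paste0("BT", vapply(bt, `[[`, integer(1), "id"))
  bt
}

#' Serialize / restore a blocktype registry as YAML
#'
#' @param blocktypes registry as returned by \code{\link{mavb_blocktypes}}.
#' @param path file path.
#' @return \code{read_blocktypes} returns a registry list equal to the one
#'   written.
#' @export
write_blocktypes <- function(blocktypes, path) {
  ser <- lapply(blocktypes, function(b) {
    list(id = b$id, name = b$name,
         levels = lapply(b$levels, function(lv) {
           list(type = lv$type,
                options = lapply(lv$options, function(opt)
                  lapply(opt, function(p) as.integer(p))))
         }))
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_blocktypes
#' @export
read_blocktypes <- function(path) {
  raw <- yaml::read_yaml(path)
  bt <- lapply(raw, function(b) {
    list(id = as.integer(b$id), name = b$name,
         levels = lapply(b$levels, function(lv) {
           new_level_template(lv$type, lapply(lv$options, function(opt)
             lapply(opt, function(p) as.integer(unlist(p)))))
         }))
  })
  names(bt) <- paste0("BT", vapply(bt, `[[`, integer(1), "id"))
  bt
}
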