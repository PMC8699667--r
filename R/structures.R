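## Search-space structures.
##
## For a fixed blocktype, ratio assignment and phase offsets, which atrial
## impulse reaches the ventricles (and at which Wenckebach position of each
## level) is a purely combinatorial question: blocking depends on signal
## counts, never on times.  Every simulated quantity is then LINEAR in the
## remaining parameters with integer coefficients:
##
##   conducted time  t = t_s + j * delta_a + sum_l [ c_l + (k_l - 1) * inc_l ]
##   RR interval       = dj * delta_a + sum_l dk_l * inc_l
##
## The base delays c_l and t_s cancel from every difference, so they are not
## identifiable from RR data and the solver fixes them at 0.  A "structure"
## bundles the integer coefficient system for one combinatorial assignment:
## the objective rows (one per observed RR interval), monotonicity constraint
## rows for the intermediate levels, and the increment grids.

.heatrr_cache <- new.env(parent = emptyenv())

## simulate the cascade combinatorially until n_final survivors reach the
## ventricles; returns final survivors and per-level survivor bookkeeping
sim_structure <- function(slot_list, phases, n_final) {
  nlev <- length(slot_list)
  lens <- lengths(slot_list)
  per <- cascade_period_slots(slot_list, phases)
  if (per$Q == 0L) return(NULL)
  max_j <- ceiling(n_final * per$P / per$Q) + 2L * per$P
  state <- phases
  fin_j <- integer(n_final); fin_k <- matrix(0L, n_final, nlev); nf <- 0L
  surv <- vector("list", nlev)  # per level: list(j = ..., k = matrix)
  for (l in seq_len(nlev)) surv[[l]] <- list(j = integer(0), k = NULL)
  sj <- lapply(seq_len(nlev), function(l) integer(max_j))
  sk <- lapply(seq_len(nlev), function(l) matrix(0L, max_j, l))
  ns <- integer(nlev)
  j <- 0L
  while (nf < n_final && j < max_j) {
    alive <- TRUE
    kvec <- integer(nlev)
    for (l in seq_len(nlev)) {
      if (!alive) break
      k <- slot_list[[l]][state[l] + 1L]
      state[l] <- (state[l] + 1L) %% lens[l]
      if (k == 0L) { alive <- FALSE } else {
        kvec[l] <- k
        ns[l] <- ns[l] + 1L
        sj[[l]][ns[l]] <- j
        sk[[l]][ns[l], ] <- kvec[seq_len(l)]
      }
    }
    if (alive) {
      nf <- nf + 1L
      fin_j[nf] <- j
      fin_k[nf, ] <- kvec
    }
    j <- j + 1L
  }
  if (nf < n_final) return(NULL)
  last_j <- fin_j[nf]
  for (l in seq_len(nlev)) {
    keep <- seq_len(ns[l])
    keep <- keep[sj[[l]][keep] <= last_j]
    surv[[l]] <- list(j = sj[[l]][keep], k = sk[[l]][keep, , drop = FALSE])
  }
  list(fin_j = fin_j, fin_k = fin_k, surv = surv, P = per$P, Q = per$Q)
}

## period of the joint phase state (same dynamics as cascade_period(), but on
## raw slot vectors)
cascade_period_slots <- function(slot_list, phases) {
  lens <- lengths(slot_list)
  state <- phases
  p <- 0L; q <- 0L
  repeat {
    alive <- TRUE
    for (l in seq_along(slot_list)) {
      if (!alive) break
      k <- slot_list[[l]][state[l] + 1L]
      state[l] <- (state[l] + 1L) %% lens[l]
      if (k == 0L) alive <- FALSE
    }
    p <- p + 1L
    if (alive) q <- q + 1L
    if (identical(state, phases)) break
    if (p > 100000L) stop_degenerate("cascade state does not close")
  }
  list(P = p, Q = q)
}

## enumerate all (option, phase) combinations of a blocktype, in the
## lexicographic order of the free-parameter vector (n, o per level, outer
## levels first; increments are enumerated inside the solver)
enumerate_level_combos <- function(bt) {
  combos <- list(list(opts = integer(0), phases = integer(0)))
  for (lv in bt$levels) {
    nxt <- list()
    for (ci in seq_along(combos)) {
      for (oi in seq_along(lv$options)) {
        L <- length(ratio_cycle(lv$options[[oi]]))
        for (ph in 0:(L - 1L)) {
          base <- combos[[ci]]
          nxt[[length(nxt) + 1L]] <- list(opts = c(base$opts, oi),
                                          phases = c(base$phases, ph))
        }
      }
    }
    combos <- nxt
  }
  combos
}

## free-parameter code of a ratio option: conducted count for a single
## (n+1):n pair, option index otherwise
option_code <- function(option, index) {
  if (length(option) == 1L) as.integer(option[[1L]][2L]) else as.integer(index)
}

## Build the full structure list for n observed intervals.
heat_structures <- function(control, n) {
  registry <- control$blocktypes
  key <- paste(paste(control$blocktype_ids, collapse = ","), n,
               control$increment_max, control$grid_step, sep = "|")
  cacheable <- isTRUE(control$default_registry)
  if (cacheable && !is.null(.heatrr_cache[[key]])) return(.heatrr_cache[[key]])

  out <- list()
  for (bid in sort(control$blocktype_ids)) {
    bt <- NULL
    for (b in registry) if (b$id == bid) bt <- b
    if (is.null(bt)) stop_invalid(sprintf("blocktype id %d not in registry", bid))
    nlev <- length(bt$levels)
    types <- vapply(bt$levels, `[[`, character(1), "type")
    multi <- vapply(bt$levels, function(lv) length(lv$options) > 1L, logical(1))
    dims <- which(types == "I")  # increment dimensions, level order
    for (cmb in enumerate_level_combos(bt)) {
      slot_list <- lapply(seq_len(nlev), function(l)
        ratio_cycle(bt$levels[[l]]$options[[cmb$opts[l]]]))
      sim <- sim_structure(slot_list, cmb$phases, n + 1L)
      if (is.null(sim)) next
      a <- diff(sim$fin_j)
      B <- matrix(0L, n, length(dims))
      for (d in seq_along(dims)) B[, d] <- diff(sim$fin_k[, dims[d]])
      ## intermediate-level monotonicity constraints (final level is covered
      ## by the positivity of the data rows)
      cons_a <- integer(0)
      cons_B <- matrix(0L, 0L, length(dims))
      if (nlev > 1L) {
        for (l in seq_len(nlev - 1L)) {
          sv <- sim$surv[[l]]
          if (length(sv$j) < 2L) next
          ca <- diff(sv$j)
          cB <- matrix(0L, length(ca), length(dims))
          for (d in seq_along(dims)) {
            if (dims[d] <= l) cB[, d] <- diff(sv$k[, dims[d]])
          }
          cons_a <- c(cons_a, ca)
          cons_B <- rbind(cons_B, cB)
        }
      }
      ## increment grids; a dimension no time difference depends on is inert
      ## and its canonical grid is {0}
      grids <- vector("list", length(dims))
      for (d in seq_along(dims)) {
        grids[[d]] <- if (all(B[, d] == 0L) && all(cons_B[, d] == 0L)) 0L
                      else seq.int(0L, control$increment_max, by = control$grid_step)
      }
      ## canonical free-parameter vector: per level (ratio code if free,
      ## phase, increment slot if Type I)
      oc <- integer(0); dpos <- integer(0); dd <- 0L
      oc_names <- character(0)
      for (l in seq_len(nlev)) {
        if (multi[l]) {
          oc <- c(oc, option_code(bt$levels[[l]]$options[[cmb$opts[l]]], cmb$opts[l]))
          oc_names <- c(oc_names, sprintf("n%d", l))
        }
        oc <- c(oc, cmb$phases[l]); oc_names <- c(oc_names, sprintf("o%d", l))
        if (types[l] == "I") {
          dd <- dd + 1L
          oc <- c(oc, 0L); oc_names <- c(oc_names, sprintf("d%d", l))
          dpos <- c(dpos, length(oc))
        }
      }
      names(oc) <- oc_names
      out[[length(out) + 1L]] <- list(
        bt = bid, opts = cmb$opts, phases = cmb$phases,
        a = as.integer(a), B = B, cons_a = as.integer(cons_a), cons_B = cons_B,
        grids = grids, oc = oc, dpos = as.integer(dpos),
        rho = sim$Q / sim$P, P = sim$P, Q = sim$Q)
    }
  }
  if (cacheable) .heatrr_cache[[key]] <- out
  out
}

## rebuild concrete mavb_params from a structure and solved values
structure_params <- function(control, str, delta_a, deltas) {
  registry <- control$blocktypes
  bt <- NULL
  for (b in registry) if (b$id == str$bt) bt <- b
  types <- vapply(bt$levels, `[[`, character(1), "type")
  d_i <- 0L
  levels <- vector("list", length(bt$levels))
  for (l in seq_along(bt$levels)) {
    inc <- 0L
    if (types[l] == "I") { d_i <- d_i + 1L; inc <- deltas[d_i] }
    levels[[l]] <- block_level(types[l], bt$levels[[l]]$options[[str$opts[l]]],
                               phase = str$phases[l], delay = 0L, increment = inc)
  }
  mavb_params(delta_a, levels, blocktype_id = str$bt)
}
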