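#' GC state of the reference engine
#'
#' A `gc_state` holds one germinal centre at one instant: the live cell
#' population, its shape-space positions, bookkeeping counters and the founder
#' log. `state$cells` is a data frame with one row per live cell and columns
#' `cell_id`, `clone_id`, `lineage_id` (`NA` until lineages are defined),
#' `lineage_late` (lineage created by a founder arriving after the lineage
#' definition time), `color` (integer index into the staining scheme, 0 =
#' black/unstained), `zone` (0 = dark zone, 1 = light zone), `divisions_left`,
#' `birth_time`, `lz_time`, `help`, `stain_tried` and `stain_count`.
#' Shape-space positions are the rows of the integer matrix `state$pos`,
#' aligned with `state$cells`.
#'
#' @param config A [gc_config()].
#' @param seed Optional integer; when supplied the R random number generator
#'   is seeded, which makes the whole trajectory reproducible.
#' @return An empty `gc_state` at `time = 0`.
#' @export
init_gc <- function(config, seed = NULL) {
  stopifnot(inherits(config, "gc_config"))
  if (!is.null(seed)) set.seed(seed)
  empty <- data.frame(
    cell_id = integer(), clone_id = integer(), lineage_id = integer(),
    lineage_late = logical(), color = integer(), zone = integer(),
    divisions_left = integer(), birth_time = numeric(), lz_time = numeric(),
    help = numeric(), stain_tried = logical(), stain_count = integer()
  )
  structure(
    list(
      time = 0, cells = empty,
      pos = matrix(0L, nrow = 0, ncol = config$shape_dim),
      next_cell_id = 1L, next_clone_id = 1L, next_lineage_id = 1L,
      n_output = 0L, lineages_defined = FALSE,
      counts = c(influx = 0L, divisions = 0L, deaths = 0L, output = 0L),
      founder_log = data.frame(clone_id = integer(), entry_time = numeric(),
                               late = logical()),
      genealogy = NULL
    ),
    class = "gc_state"
  )
}

#' @export
print.gc_state <- function(x, ...) {
  cat("<gc_state> t =", x$time, "h, N =", nrow(x$cells),
      "cells,", nrow(x$founder_log), "founders,",
      x$n_output, "output cells\n")
  if (x$lineages_defined) cat("  lineages defined\n")
  invisible(x)
}

#' Founder-cell influx
#'
#' Adds `Poisson(founder_rate * dt)` new founder cells while
#' `state$time < influx_window`; no influx afterwards. Each founder receives a
#' fresh clone id, a shape-space position drawn from the configured founder
#' distance band, the initial division budget, dark-zone state and no colour.
#' If a founder-staining protocol is supplied, founders draw their colour from
#' the full scheme at entry. Under a decay protocol, founders arriving after
#' the injection arrive pre-stained with the cumulative recombination
#' probability already spent (tamoxifen exposure is systemic, so B cells are
#' exposed before they enter the GC). Founders arriving after lineages were
#' defined receive a fresh lineage id flagged as late.
#'
#' @param state A [gc_state][init_gc()].
#' @param config A [gc_config()].
#' @param dt Interval covered by this influx call (hours).
#' @param protocol Optional [staining_protocol()]; only `founder` mode has an
#'   effect here.
#' @return The updated state.
#' @export
influx_founders <- function(state, config, dt = config$dt, protocol = NULL) {
  stopifnot(inherits(state, "gc_state"), inherits(config, "gc_config"))
  if (dt <= 0 || state$time >= config$influx_window) return(state)
  k <- rpois(1L, config$founder_rate * dt)
  if (k == 0L) return(state)
  model <- config_affinity_model(config)
  pos <- sample_founder_position(model, k, config$founder_dist)
  ids <- state$next_cell_id + seq_len(k) - 1L
  clones <- state$next_clone_id + seq_len(k) - 1L
  color <- rep(0L, k)
  tried <- rep(FALSE, k)
  if (!is.null(protocol) && protocol$mode == "founder") {
    full <- sample.int(length(protocol$scheme$probabilities), k,
                       replace = TRUE, prob = protocol$scheme$probabilities)
    color <- full - 1L
    tried <- rep(TRUE, k)
  } else if (!is.null(protocol) && protocol$mode == "decay") {
    h <- spent_staining_hazard(protocol, state$time)
    if (h > 0) {
      hit <- runif(k) < h
      if (any(hit)) {
        color[hit] <- draw_visible_color(protocol$scheme, sum(hit))
        tried[hit] <- TRUE
      }
    }
  }
  lin <- rep(NA_integer_, k)
  late <- rep(FALSE, k)
  if (state$lineages_defined) {
    lin <- state$next_lineage_id + seq_len(k) - 1L
    late <- rep(TRUE, k)
    state$next_lineage_id <- state$next_lineage_id + k
  }
  new <- data.frame(
    cell_id = ids, clone_id = clones, lineage_id = lin, lineage_late = late,
    color = color, zone = 0L,
    divisions_left = rep(config$initial_divisions, k),
    birth_time = rep(state$time, k), lz_time = 0, help = 0,
    stain_tried = tried, stain_count = as.integer(color > 0L)
  )
  state$cells <- rbind(state$cells, new)
  state$pos <- rbind(state$pos, pos)
  state$next_cell_id <- state$next_cell_id + k
  state$next_clone_id <- state$next_clone_id + k
  state$counts["influx"] <- state$counts["influx"] + k
  state$founder_log <- rbind(
    state$founder_log,
    data.frame(clone_id = clones, entry_time = rep(state$time, k),
               late = rep(state$lineages_defined, k))
  )
  if (!is.null(state$genealogy)) {
    state$genealogy <- rbind(
      state$genealogy,
      data.frame(cell_id = ids, parent_id = NA_integer_,
                 birth_time = rep(state$time, k), clone_id = clones)
    )
  }
  state
}

#' Advance a GC state by one time step (reference engine)
#'
#' Applies, per cell, the rate-derived stochastic events of the
#' dark-zone/light-zone model: dark-zone cells with remaining budget divide
#' (both daughters inherit clone, lineage and colour; each mutates
#' independently with `mutation_prob`); dark-zone cells with exhausted budget
#' move to the light zone; light-zone cells are tested for selection with a
#' probability proportional to their affinity relative to the light-zone mean,
#' and on success either recycle to the dark zone with a fresh division budget
#' from the dynamic-number-of-divisions rule, or leave the GC as output cells;
#' unselected light-zone cells past the maximal dwell time die. Advances
#' `state$time` by `config$dt`.
#'
#' @param state A [gc_state][init_gc()].
#' @param config A [gc_config()].
#' @return The updated state.
#' @export
gc_step <- function(state, config) {
  stopifnot(inherits(state, "gc_state"), inherits(config, "gc_config"))
  dt <- config$dt
  cells <- state$cells
  pos <- state$pos
  n0 <- nrow(cells)
  if (n0 > 0L) {
    model <- config_affinity_model(config)
    aff <- affinity(model, pos)
    p_div <- 1 - exp(-config$dz_division_rate * dt)
    p_sel_base <- 1 - exp(-config$sel_rate * dt)
    p_death <- 1 - exp(-config$lz_death_rate * dt)

    dz <- cells$zone == 0L
    lz <- !dz
    abar <- if (any(lz)) mean(aff[lz]) else 0
    # limited Tfh help and decaying antigen availability
    # before antigen is presented on FDCs neither selection tests nor
    # death-by-neglect happen
    rise <- if (config$antigen_rise > 0) {
      1 - exp(-state$time / config$antigen_rise)
    } else {
      1
    }
    sel_scale <- rise / (1 + sum(lz) / config$tfh_capacity)
    if (is.finite(config$antigen_tau)) {
      sel_scale <- sel_scale * exp(-state$time / config$antigen_tau)
    }
    p_death <- p_death * rise

    # dark zone: exhausted budget -> light zone
    to_lz <- dz & cells$divisions_left <= 0L
    cells$zone[to_lz] <- 1L
    cells$lz_time[to_lz] <- 0

    # dark zone: division
    can_div <- dz & cells$divisions_left > 0L
    dividing <- which(can_div & runif(n0) < p_div)
    if (length(dividing)) {
      cells$divisions_left[dividing] <- cells$divisions_left[dividing] - 1L
      daughters <- cells[dividing, , drop = FALSE]
      daughters$cell_id <- state$next_cell_id + seq_along(dividing) - 1L
      daughters$birth_time <- state$time + dt
      dpos <- pos[dividing, , drop = FALSE]
      # each daughter (the updated parent row and the new row) mutates
      mut1 <- runif(length(dividing)) < config$mutation_prob
      if (any(mut1)) {
        pos[dividing[mut1], ] <- mutate_position(pos[dividing[mut1], ,
                                                     drop = FALSE])
      }
      mut2 <- runif(length(dividing)) < config$mutation_prob
      if (any(mut2)) {
        dpos[mut2, ] <- mutate_position(dpos[mut2, , drop = FALSE])
      }
      if (!is.null(state$genealogy)) {
        state$genealogy <- rbind(
          state$genealogy,
          data.frame(cell_id = daughters$cell_id,
                     parent_id = cells$cell_id[dividing],
                     birth_time = state$time + dt,
                     clone_id = daughters$clone_id)
        )
      }
      state$next_cell_id <- state$next_cell_id + length(dividing)
      state$counts["divisions"] <- state$counts["divisions"] +
        length(dividing)
      cells <- rbind(cells, daughters)
      pos <- rbind(pos, dpos)
    }

    # light zone: selection, recycling/output, death
    dead <- rep(FALSE, n0)
    lz_idx <- which(lz)
    if (length(lz_idx)) {
      a <- aff[lz_idx]
      ratio <- if (config$affinity_dependent && abar > 0) a / abar else 1
      p_sel <- pmin(1, p_sel_base * ratio * sel_scale)
      selected <- runif(length(lz_idx)) < p_sel
      sel_idx <- lz_idx[selected]
      if (length(sel_idx)) {
        s <- if (config$affinity_dependent) {
          a_s <- aff[sel_idx]
          ifelse(a_s + abar > 0, a_s / (a_s + abar), 0.5)
        } else {
          rep(0.5, length(sel_idx))
        }
        recyc <- runif(length(sel_idx)) < config$p_recycle
        ri <- sel_idx[recyc]
        cells$zone[ri] <- 0L
        cells$divisions_left[ri] <- as.integer(round(
          config$d_min + (config$d_max - config$d_min) * s[recyc]
        ))
        cells$help[ri] <- s[recyc]
        oi <- sel_idx[!recyc]
        dead[oi] <- TRUE
        state$n_output <- state$n_output + length(oi)
        state$counts["output"] <- state$counts["output"] + length(oi)
      }
      ns_idx <- lz_idx[!selected]
      if (length(ns_idx)) {
        cells$lz_time[ns_idx] <- cells$lz_time[ns_idx] + dt
        prone <- ns_idx[cells$lz_time[ns_idx] > config$lz_max_dwell]
        dying <- prone[runif(length(prone)) < p_death]
        dead[dying] <- TRUE
        state$counts["deaths"] <- state$counts["deaths"] + length(dying)
      }
    }
    if (any(dead)) {
      keep <- c(!dead, rep(TRUE, nrow(cells) - n0))
      cells <- cells[keep, , drop = FALSE]
      pos <- pos[keep, , drop = FALSE]
    }
    rownames(cells) <- NULL
    state$cells <- cells
    state$pos <- pos
  }
  state$time <- state$time + dt
  state
}
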