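#' Initial recombination probability for decaying tamoxifen activity
#'
#' After a tamoxifen injection the per-call recombination probability decays
#' exponentially with time constant `tau_tamoxifen` and is switched off at
#' `tau_stainstop`. The initial per-call probability is calibrated so that the
#' accumulated staining over the active window equals the target stained
#' fraction:
#' \deqn{p_0 \Delta t = \frac{f}{\tau (1 - e^{-\tau_{stop}/\tau})}}
#'
#' @param f_stained Target stained fraction, in (0, 1).
#' @param tau_tamoxifen Decay time constant of tamoxifen activity (hours).
#' @param tau_stainstop Time after which staining is switched off (hours).
#' @param dt_stain Interval between staining calls (hours).
#' @return `p_stain_0`, the initial per-unit-time staining probability, such
#'   that `p_stain_0 * dt_stain` is the probability at the first call.
#' @export
initial_staining_probability <- function(f_stained, tau_tamoxifen = 24,
                                         tau_stainstop = 48, dt_stain = 1) {
  if (!is.finite(f_stained) || f_stained <= 0 || f_stained >= 1) {
    stop("`f_stained` must lie in (0, 1)", call. = FALSE)
  }
  if (!is.finite(tau_tamoxifen) || tau_tamoxifen <= 0) {
    stop("`tau_tamoxifen` must be > 0", call. = FALSE)
  }
  if (!is.finite(tau_stainstop) || tau_stainstop <= 0) {
    stop("`tau_stainstop` must be > 0", call. = FALSE)
  }
  if (!is.finite(dt_stain) || dt_stain <= 0) {
    stop("`dt_stain` must be > 0", call. = FALSE)
  }
  f_stained / (tau_tamoxifen * (1 - exp(-tau_stainstop / tau_tamoxifen))) /
    dt_stain
}

#' Staining protocol
#'
#' Describes how and when colours are attributed to GC B cells:
#' \describe{
#'   \item{`founder`}{Each founder cell draws a colour (black possible) from
#'     the full scheme at GC entry, i.e. cells arrive pre-stained.}
#'   \item{`one_shot`}{A single staining pass at `t_start`; each cell is
#'     stained with probability `f_stained`.}
#'   \item{`decay`}{Staining passes every `dt_stain` hours from `t_start`
#'     until `t_start + tau_stainstop`, with per-call probability decaying as
#'     `exp(-(t - t_start)/tau_tamoxifen)` and initial value from
#'     [initial_staining_probability()].}
#'   \item{`none`}{No staining (control runs).}
#' }
#' Newly stained cells draw their colour from the scheme's non-black
#' distribution, renormalised; black in the scheme encodes failed
#' recombination, not a colour. Once stained, a cell keeps its colour and
#' passes it to its progeny, unless `allow_restain = TRUE`, in which case
#' already-stained cells may redraw a (possibly identical) visible colour
#' during the active window.
#'
#' Lineages are defined at `lineage_t0` (default: the injection time
#' `t_start`): every cell alive then founds its own lineage. Set
#' `lineage_t0 = NA` to disable lineage tracking.
#'
#' @param mode One of `"decay"`, `"one_shot"`, `"founder"`, `"none"`.
#' @param scheme A [color_scheme()].
#' @param t_start Staining start, hours post GC onset.
#' @param f_stained Target stained fraction in (0, 1) (decay and one-shot
#'   modes).
#' @param tau_tamoxifen,tau_stainstop,dt_stain Decay-mode timing constants
#'   (hours); see [initial_staining_probability()].
#' @param allow_restain Allow recombination of already recombined cells.
#' @param lineage_t0 Lineage definition time (hours), or `NA` for none.
#' @return An object of class `staining_protocol`.
#' @export
staining_protocol <- function(mode = c("decay", "one_shot", "founder", "none"),
                              scheme = builtin_schemes()$tamoxifen10,
                              t_start = 48, f_stained = 0.48,
                              tau_tamoxifen = 24, tau_stainstop = 48,
                              dt_stain = 1, allow_restain = FALSE,
                              lineage_t0 = t_start) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "color_scheme"))
  if (mode %in% c("decay", "one_shot")) {
    if (!is.finite(f_stained) || f_stained <= 0 || f_stained > 1) {
      stop("`f_stained` must lie in (0, 1]", call. = FALSE)
    }
  }
  if (!is.finite(t_start) || t_start < 0) {
    stop("`t_start` must be a non-negative time in hours", call. = FALSE)
  }
  p0 <- NA_real_
  if (mode == "decay") {
    p0 <- initial_staining_probability(f_stained, tau_tamoxifen,
                                       tau_stainstop, dt_stain)
    if (p0 * dt_stain > 1) {
      stop("initial per-call staining probability exceeds 1; ",
           "reduce `f_stained` or lengthen the staining window", call. = FALSE)
    }
  }
  structure(
    list(mode = mode, scheme = scheme, t_start = as.numeric(t_start),
         f_stained = as.numeric(f_stained),
         tau_tamoxifen = as.numeric(tau_tamoxifen),
         tau_stainstop = as.numeric(tau_stainstop),
         dt_stain = as.numeric(dt_stain),
         allow_restain = isTRUE(allow_restain),
         lineage_t0 = as.numeric(lineage_t0),
         p_stain_0 = p0),
    class = "staining_protocol"
  )
}

#' @export
print.staining_protocol <- function(x, ...) {
  cat("<staining_protocol> mode =", x$mode, " scheme =", x$scheme$name, "\n")
  if (x$mode %in% c("decay", "one_shot")) {
    cat("  t_start =", x$t_start, "h, f_stained =", x$f_stained, "\n")
  }
  if (x$mode == "decay") {
    cat("  tau_tamoxifen =", x$tau_tamoxifen, "h, tau_stainstop =",
        x$tau_stainstop, "h, dt_stain =", x$dt_stain,
        "h, restain =", x$allow_restain, "\n")
  }
  if (is.finite(x$lineage_t0)) cat("  lineage_t0 =", x$lineage_t0, "h\n")
  invisible(x)
}

#' Per-call staining probability under decaying tamoxifen activity
#'
#' @param protocol A decay-mode [staining_protocol()].
#' @param t Time (hours post GC onset); may be a vector.
#' @return Probability applied at a staining call at time `t`:
#'   `p_stain_0 * dt_stain * exp(-(t - t_start)/tau_tamoxifen)` inside the
#'   active window `[t_start, t_start + tau_stainstop)`, 0 outside.
#' @export
staining_probability_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "staining_protocol"))
  if (protocol$mode != "decay") {
    stop("staining_probability_at() is defined for decay mode only",
         call. = FALSE)
  }
  p <- protocol$p_stain_0 * protocol$dt_stain *
    exp(-(t - protocol$t_start) / protocol$tau_tamoxifen)
  p[t < protocol$t_start | t >= protocol$t_start + protocol$tau_stainstop] <- 0
  p
}

# Cumulative per-call staining probability spent strictly before time t.
# Tamoxifen exposure is systemic, so decay-mode founders arriving mid-window
# carry this as entry staining (see influx_founders()).
spent_staining_hazard <- function(protocol, t) {
  if (protocol$mode != "decay" || t <= protocol$t_start + 1e-9) return(0)
  horizon <- min(t, protocol$t_start + protocol$tau_stainstop)
  m <- ceiling((horizon - protocol$t_start) / protocol$dt_stain - 1e-9)
  q <- exp(-protocol$dt_stain / protocol$tau_tamoxifen)
  h <- protocol$p_stain_0 * protocol$dt_stain * (1 - q^m) / (1 - q)
  min(1, h)
}

# Times (hours) of the scheduled staining calls of a protocol.
staining_call_times <- function(protocol) {
  switch(protocol$mode,
    decay = {
      k <- seq(0, protocol$tau_stainstop - protocol$dt_stain,
               by = protocol$dt_stain)
      protocol$t_start + k
    },
    one_shot = protocol$t_start,
    numeric(0)
  )
}

# Draw n colours from the renormalised non-black distribution of a scheme.
draw_visible_color <- function(scheme, n) {
  p <- scheme$probabilities[-1]
  sample.int(length(p), n, replace = TRUE, prob = p)
}

#' Apply a staining pass to a GC state (reference engine)
#'
#' Implements one staining call on a [gc_state]:
#' \itemize{
#'   \item `founder` mode: every cell that has not yet had a staining
#'     attempt draws from the full scheme (black possible). In a simulation
#'     loop only newly arrived founders are in that state, so founders are
#'     effectively stained at GC entry.
#'   \item `one_shot` mode: every cell is stained with probability
#'     `f_stained`.
#'   \item `decay` mode: the call at time `t` recombines an expected fraction
#'     `p(t)` of the whole population (see [staining_probability_at()]).
#'     With `allow_restain = FALSE` attempts on stained cells are ignored, so
#'     the per-unstained-cell probability is `p(t) * N / N_unstained` (capped
#'     at 1), which keeps the accumulated stained fraction equal to the
#'     calibration target. With `allow_restain = TRUE`, stained cells
#'     additionally redraw a visible colour with probability `p(t)`.
#' }
#'
#' @param state A [gc_state] object.
#' @param protocol A [staining_protocol()].
#' @param t Time of the call; defaults to `state$time`.
#' @return The updated state.
#' @export
apply_staining <- function(state, protocol, t = state$time) {
  stopifnot(inherits(state, "gc_state"), inherits(protocol, "staining_protocol"))
  cells <- state$cells
  n <- nrow(cells)
  if (n == 0L) return(state)

  if (protocol$mode == "founder") {
    idx <- which(!cells$stain_tried)
    if (length(idx)) {
      full <- sample.int(length(protocol$scheme$probabilities), length(idx),
                         replace = TRUE, prob = protocol$scheme$probabilities)
      cells$color[idx] <- full - 1L       # 0 = black
      cells$stain_tried[idx] <- TRUE
      cells$stain_count[idx] <- cells$stain_count[idx] + as.integer(full > 1L)
    }
  } else if (protocol$mode == "one_shot") {
    hit <- runif(n) < protocol$f_stained
    idx <- which(hit & (protocol$allow_restain | cells$color == 0L))
    if (length(idx)) {
      cells$color[idx] <- draw_visible_color(protocol$scheme, length(idx))
      cells$stain_count[idx] <- cells$stain_count[idx] + 1L
      cells$stain_tried[idx] <- TRUE
    }
  } else if (protocol$mode == "decay") {
    p_call <- staining_probability_at(protocol, t)
    if (p_call > 0) {
      unstained <- which(cells$color == 0L)
      stained_before <- which(cells$color != 0L)
      n_un <- length(unstained)
      if (n_un > 0L) {
        p_eff <- min(1, p_call * n / n_un)
        idx <- unstained[runif(n_un) < p_eff]
        if (length(idx)) {
          cells$color[idx] <- draw_visible_color(protocol$scheme, length(idx))
          cells$stain_count[idx] <- cells$stain_count[idx] + 1L
          cells$stain_tried[idx] <- TRUE
        }
      }
      if (protocol$allow_restain && length(stained_before)) {
        re <- stained_before[runif(length(stained_before)) < p_call]
        if (length(re)) {
          cells$color[re] <- draw_visible_color(protocol$scheme, length(re))
          cells$stain_count[re] <- cells$stain_count[re] + 1L
        }
      }
    }
  }
  state$cells <- cells
  state
}
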