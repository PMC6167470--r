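# Dominance statistics on a GC snapshot.
#
# All metrics take a cell table: a data frame with one row per live GC B cell
# and (depending on the metric) columns `clone_id`, `lineage_id`,
# `lineage_late` and `color`. `color` is either an integer index (0 = black)
# or a character label ("black" = unstained). They are deliberately
# independent of the simulation engine so that they can also be applied to
# external tabular cell records.

# Largest count and smallest-id argmax over a vector of ids (ties -> lowest).
max_count_by <- function(ids) {
  u <- sort(unique(ids))
  cnt <- tabulate(match(ids, u), nbins = length(u))
  i <- which.max(cnt)                 # first max = lowest id
  list(count = cnt[i], id = u[i])
}

is_black <- function(color) {
  if (is.numeric(color)) color == 0 else tolower(as.character(color)) == "black"
}

#' Clonal dominance of a cell population
#'
#' The largest fraction of GC B cells that stems from a single clone
#' (founder). Ties are broken toward the lowest clone id.
#'
#' @param cells Cell table with a `clone_id` column.
#' @return List with `dominance` (in `[0, 1]`) and `id` (dominant clone).
#' @export
clonal_dominance <- function(cells) {
  n <- nrow(cells)
  if (n == 0L) stop("empty GC: clonal dominance is undefined", call. = FALSE)
  m <- max_count_by(cells$clone_id)
  list(dominance = m$count / n, id = m$id)
}

#' Lineage dominance of a cell population
#'
#' The largest fraction of GC B cells that stems from a single lineage.
#' Cells without a lineage (progeny of founders that entered after the
#' definition time, when late founders are excluded) count in the denominator
#' but belong to no lineage.
#'
#' @param cells Cell table with `lineage_id` (and, if late founders are to be
#'   distinguished, `lineage_late`) columns.
#' @param include_late_founders Count lineages founded by late-arriving
#'   founders.
#' @return List with `dominance` and `id` (`NA` if no lineage cell is alive).
#' @export
lineage_dominance <- function(cells, include_late_founders = FALSE) {
  n <- nrow(cells)
  if (n == 0L) stop("empty GC: lineage dominance is undefined", call. = FALSE)
  if (is.null(cells$lineage_id) || all(is.na(cells$lineage_id))) {
    stop("no lineages defined for this population", call. = FALSE)
  }
  keep <- !is.na(cells$lineage_id)
  if (!include_late_founders && !is.null(cells$lineage_late)) {
    keep <- keep & !cells$lineage_late
  }
  if (!any(keep)) return(list(dominance = 0, id = NA_integer_))
  m <- max_count_by(cells$lineage_id[keep])
  list(dominance = m$count / n, id = m$id)
}

#' Colour dominance of a cell population
#'
#' The largest fraction of GC B cells expressing a single non-black colour.
#' If no cell is stained the dominance is 0 and the dominant colour is `NA`.
#' Ties are broken toward the first colour in scheme order (integer colour
#' indices; for character labels, the order of `scheme$colors` when a scheme
#' is given, alphabetical otherwise).
#'
#' @param cells Cell table with a `color` column.
#' @param scheme Optional [color_scheme()] used to order labels and to name
#'   the dominant colour of integer-coded populations.
#' @return List with `dominance` and `color` (label or index, `NA` if none).
#' @export
color_dominance <- function(cells, scheme = NULL) {
  n <- nrow(cells)
  if (n == 0L) stop("empty GC: colour dominance is undefined", call. = FALSE)
  col <- cells$color
  stained <- !is_black(col)
  if (!any(stained)) return(list(dominance = 0, color = NA))
  col <- col[stained]
  if (is.numeric(col)) {
    m <- max_count_by(as.integer(col))
    label <- if (!is.null(scheme)) scheme$colors[m$id + 1L] else m$id
  } else {
    col <- as.character(col)
    lv <- if (!is.null(scheme)) {
      intersect(scheme$colors[-1], unique(col))
    } else {
      sort(unique(col))
    }
    cnt <- tabulate(match(col, lv), nbins = length(lv))
    i <- which.max(cnt)
    m <- list(count = cnt[i])
    label <- lv[i]
  }
  list(dominance = m$count / n, color = label)
}

#' Colour density of a cell population
#'
#' The fraction of GC B cells expressing any non-black colour.
#'
#' @param cells Cell table with a `color` column.
#' @return Numeric in `[0, 1]`.
#' @export
color_density <- function(cells) {
  n <- nrow(cells)
  if (n == 0L) stop("empty GC: colour density is undefined", call. = FALSE)
  mean(!is_black(cells$color))
}

#' Staining-threshold filter
#'
#' A GC passes the staining threshold `T` iff its colour density is strictly
#' above `T` at the analysis time.
#'
#' @param record A dominance record (any list/row with a `d` field) or a
#'   numeric colour density.
#' @param threshold Threshold in `[0, 1]`.
#' @return Logical.
#' @export
passes_threshold <- function(record, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  d <- if (is.numeric(record)) record else record$d
  d > threshold
}

#' Did the dominant colour switch between two snapshots of one GC?
#'
#' @param record_at_staining,record_at_analysis Dominance records of the same
#'   GC (rows of a cohort table or results of [dominance_record()]).
#' @return `TRUE`/`FALSE`, or `NA` when either snapshot has no dominant
#'   colour (such GCs are excluded from switch statistics).
#' @export
color_switched <- function(record_at_staining, record_at_analysis) {
  c1 <- record_at_staining$dominant_color
  c2 <- record_at_analysis$dominant_color
  if (is.na(c1) || is.na(c2)) return(NA)
  !identical(as.character(c1), as.character(c2))
}

#' Dominance record of one GC snapshot
#'
#' Computes all snapshot statistics at once: population size `n`, clonal
#' dominance `f`, lineage dominance `l` (late founders excluded) and `l_late`
#' (late founders included), colour dominance `c`, colour density `d`, their
#' product `pdd = c * d` (a proxy for the in-vivo normalised density score),
#' the dominant clone/lineage/colour, and the mean affinity when an
#' `affinity` column is present.
#'
#' @param cells Cell table (see [clonal_dominance()]).
#' @param gc_id,t Identifiers stored in the record.
#' @param scheme Optional [color_scheme()] for colour labels.
#' @return A one-row [tibble::tibble()].
#' @export
dominance_record <- function(cells, gc_id = NA_integer_, t = NA_real_,
                             scheme = NULL) {
  n <- nrow(cells)
  if (n == 0L) {
    return(tibble::tibble(
      gc_id = gc_id, t = t, n = 0L, f = NA_real_, dominant_clone = NA_integer_,
      l = NA_real_, dominant_lineage = NA_integer_, l_late = NA_real_,
      c = NA_real_, dominant_color = NA_character_, d = NA_real_,
      pdd = NA_real_, mean_affinity = NA_real_
    ))
  }
  fd <- clonal_dominance(cells)
  has_lin <- !is.null(cells$lineage_id) && any(!is.na(cells$lineage_id))
  if (has_lin) {
    ld <- lineage_dominance(cells, include_late_founders = FALSE)
    ll <- lineage_dominance(cells, include_late_founders = TRUE)
  } else {
    ld <- list(dominance = NA_real_, id = NA_integer_)
    ll <- list(dominance = NA_real_)
  }
  cd <- color_dominance(cells, scheme = scheme)
  d <- color_density(cells)
  tibble::tibble(
    gc_id = as.integer(gc_id), t = as.numeric(t), n = as.integer(n),
    f = fd$dominance, dominant_clone = as.integer(fd$id),
    l = ld$dominance, dominant_lineage = as.integer(ld$id),
    l_late = ll$dominance,
    c = cd$dominance,
    dominant_color = if (is.na(cd$color[1])) NA_character_
                     else as.character(cd$color),
    d = d, pdd = cd$dominance * d,
    mean_affinity = if (!is.null(cells$affinity)) mean(cells$affinity)
                    else NA_real_
  )
}
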