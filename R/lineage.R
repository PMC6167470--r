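#' Define GC B-cell lineages
#'
#' Every cell alive at the lineage definition time `t0` (typically the
#' tamoxifen injection time) founds its own lineage: each receives a distinct
#' lineage id, inherited unchanged by all its progeny. Two sibling cells alive
#' at `t0` found different lineages even though they share a clone. Founders
#' entering the GC after `t0` always receive fresh lineage ids flagged as
#' "late"; whether those late lineages are counted by the dominance metrics is
#' controlled at analysis time (see [lineage_dominance()]), with the state's
#' `include_late_founders` flag providing the default.
#'
#' @param state A [gc_state][init_gc()] at the definition time.
#' @param t0 Definition time; must equal `state$time`.
#' @param include_late_founders Default analysis behaviour for founders
#'   arriving after `t0` (stored on the state).
#' @return The updated state.
#' @export
define_lineages <- function(state, t0 = state$time,
                            include_late_founders = FALSE) {
  stopifnot(inherits(state, "gc_state"))
  if (state$lineages_defined) {
    stop("lineages have already been defined for this GC", call. = FALSE)
  }
  if (abs(t0 - state$time) > 1e-9) {
    stop("define_lineages() must be called at t0 (state time ", state$time,
         " != t0 ", t0, ")", call. = FALSE)
  }
  n <- nrow(state$cells)
  state$cells$lineage_id <- state$next_lineage_id + seq_len(n) - 1L
  state$cells$lineage_late <- rep(FALSE, n)
  state$next_lineage_id <- state$next_lineage_id + n
  state$lineages_defined <- TRUE
  state$lineage_t0 <- t0
  state$include_late_founders <- isTRUE(include_late_founders)
  state
}

#' Export a cell genealogy as a Newick tree
#'
#' Writes the division history of one simulated GC as a Newick forest (one
#' tree per founder). A dividing cell is encoded as an internal node whose
#' two children are the continuing parent branch and the newborn daughter;
#' branch lengths are hours. Leaves are labelled
#' `cellID|cloneID|lineageID|color` for cells with known final state (from
#' `cells`), `cellID|cloneID` otherwise. Intended as an inspection aid on
#' small runs with `genealogy = TRUE` in [run_gc()].
#'
#' @param genealogy Data frame with columns `cell_id`, `parent_id` (`NA` for
#'   founders), `birth_time`, `clone_id`, as returned in `run_gc()$genealogy`.
#' @param path Output file; one Newick string per founder tree.
#' @param cells Optional final cell table used for leaf annotations.
#' @param end_time Time assigned to the tips (defaults to the latest birth).
#' @return Invisibly, the character vector of Newick strings.
#' @export
write_genealogy_newick <- function(genealogy, path, cells = NULL,
                                   end_time = NULL) {
  stopifnot(is.data.frame(genealogy),
            all(c("cell_id", "parent_id", "birth_time", "clone_id") %in%
                  names(genealogy)))
  if (is.null(end_time)) end_time <- max(genealogy$birth_time, 0)
  lab <- function(id) {
    if (!is.null(cells) && id %in% cells$cell_id) {
      i <- match(id, cells$cell_id)
      paste(id, cells$clone_id[i],
            ifelse(is.na(cells$lineage_id[i]), "NA", cells$lineage_id[i]),
            cells$color[i], sep = "|")
    } else {
      i <- match(id, genealogy$cell_id)
      paste(id, genealogy$clone_id[i], sep = "|")
    }
  }
  kids <- split(seq_len(nrow(genealogy)),
                factor(genealogy$parent_id,
                       levels = unique(genealogy$cell_id)))
  # subtree of cell `id` from time `from` onwards
  build <- function(id, from) {
    rows <- kids[[as.character(id)]]
    rows <- rows[genealogy$birth_time[rows] > from + 1e-12]
    if (length(rows) == 0L) {
      return(paste0(lab(id), ":", format(max(end_time - from, 0),
                                         digits = 10)))
    }
    rows <- rows[order(genealogy$birth_time[rows])]
    r <- rows[1L]
    tsplit <- genealogy$birth_time[r]
    paste0("(", build(id, tsplit), ",",
           build(genealogy$cell_id[r], tsplit), "):",
           format(tsplit - from, digits = 10))
  }
  roots <- which(is.na(genealogy$parent_id))
  nwk <- vapply(roots, function(r) {
    s <- build(genealogy$cell_id[r], genealogy$birth_time[r])
    # a founder that never divided is a bare leaf; parenthesise for parsers
    if (!startsWith(s, "(")) s <- paste0("(", s, ")")
    paste0(s, ";")
  }, character(1))
  writeLines(nwk, path)
  invisible(nwk)
}
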