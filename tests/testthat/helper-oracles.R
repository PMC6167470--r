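# Brute-force oracles for the dominance statistics, written independently of
# the production tally (explicit loops over ids).

oracle_clonal <- function(cells) {
  best <- -1L
  bid <- NA_integer_
  for (id in sort(unique(cells$clone_id))) {
    cnt <- 0L
    for (x in cells$clone_id) if (x == id) cnt <- cnt + 1L
    if (cnt > best) {
      best <- cnt
      bid <- id
    }
  }
  list(dominance = best / nrow(cells), id = bid)
}

oracle_lineage <- function(cells, include_late = FALSE) {
  ok <- !is.na(cells$lineage_id)
  if (!include_late && !is.null(cells$lineage_late)) {
    ok <- ok & !cells$lineage_late
  }
  ids <- sort(unique(cells$lineage_id[ok]))
  if (length(ids) == 0L) return(list(dominance = 0, id = NA_integer_))
  best <- -1L
  bid <- NA_integer_
  for (id in ids) {
    cnt <- sum(ok & cells$lineage_id == id)
    if (cnt > best) {
      best <- cnt
      bid <- id
    }
  }
  list(dominance = best / nrow(cells), id = bid)
}

oracle_color <- function(cells) {
  cols <- sort(unique(cells$color[cells$color != 0L]))
  if (length(cols) == 0L) return(list(dominance = 0, color = NA))
  best <- -1L
  bcol <- NA_integer_
  for (cc in cols) {
    cnt <- sum(cells$color == cc)
    if (cnt > best) {
      best <- cnt
      bcol <- cc
    }
  }
  list(dominance = best / nrow(cells), color = bcol)
}

oracle_density <- function(cells) {
  cnt <- 0L
  for (x in cells$color) if (x != 0L) cnt <- cnt + 1L
  cnt / nrow(cells)
}

# Random toy population for fuzzing the metrics.
random_population <- function(n = NULL) {
  if (is.null(n)) n <- sample(1:40, 1)
  has_lineage <- runif(1) < 0.7
  lin <- if (has_lineage) {
    ifelse(runif(n) < 0.2, NA_integer_, sample(1:6, n, replace = TRUE))
  } else {
    rep(NA_integer_, n)
  }
  data.frame(
    clone_id = sample(1:5, n, replace = TRUE),
    lineage_id = lin,
    lineage_late = !is.na(lin) & runif(n) < 0.25,
    color = sample(0:4, n, replace = TRUE,
                   prob = c(0.45, 0.25, 0.15, 0.1, 0.05))
  )
}

make_cells <- function(clone = 1L, lineage = NA_integer_, late = FALSE,
                       color = 0L) {
  n <- max(lengths(list(clone, lineage, late, color)))
  data.frame(clone_id = rep_len(clone, n),
             lineage_id = rep_len(lineage, n),
             lineage_late = rep_len(late, n),
             color = rep_len(color, n))
}
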