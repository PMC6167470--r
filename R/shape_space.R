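#' Gaussian affinity model on an integer shape-space lattice
#'
#' B-cell receptors are represented by positions on a `dim`-dimensional integer
#' lattice ("shape space"). Affinity for the antigen is a Gaussian function of
#' the Euclidean distance to the optimal binder: `exp(-dist^2 / gamma^2)`, so
#' the optimum has affinity 1 and affinity decays smoothly with distance.
#'
#' @param dim Dimension of the shape space (positive integer).
#' @param gamma Width of the Gaussian affinity kernel, in lattice units
#'   (positive). At distance `gamma` the affinity is `exp(-1)`.
#' @param optimum Integer vector of length `dim`: the position that binds the
#'   antigen optimally.
#' @return An object of class `affinity_model`.
#' @examples
#' m <- affinity_model()
#' affinity(m, m$optimum)        # 1
#' affinity(m, c(2, 0, 0, 0))    # exp(-4 / 2.8^2)
#' @export
affinity_model <- function(dim = 4L, gamma = 2.8, optimum = rep(0L, dim)) {
  if (length(dim) != 1L || is.na(dim) || dim < 1 || dim != as.integer(dim)) {
    stop("`dim` must be a single positive integer", call. = FALSE)
  }
  if (length(gamma) != 1L || !is.finite(gamma) || gamma <= 0) {
    stop("`gamma` must be a single positive number", call. = FALSE)
  }
  if (length(optimum) != dim || any(optimum != round(optimum))) {
    stop("`optimum` must be an integer vector of length `dim`", call. = FALSE)
  }
  structure(
    list(dim = as.integer(dim), gamma = as.numeric(gamma),
         optimum = as.integer(round(optimum))),
    class = "affinity_model"
  )
}

#' @export
print.affinity_model <- function(x, ...) {
  cat("<affinity_model> dim =", x$dim, " gamma =", x$gamma,
      " optimum = (", paste(x$optimum, collapse = ", "), ")\n")
  invisible(x)
}

#' Affinity of one or more shape-space positions
#'
#' @param model An [affinity_model()].
#' @param pos Integer vector of length `model$dim`, or an integer matrix with
#'   one position per row.
#' @return Numeric affinity value(s) in `[0, 1]`.
#' @export
affinity <- function(model, pos) {
  stopifnot(inherits(model, "affinity_model"))
  if (is.matrix(pos)) {
    if (ncol(pos) != model$dim) {
      stop("position dimension (", ncol(pos), ") does not match model dim (",
           model$dim, ")", call. = FALSE)
    }
    d2 <- rowSums(sweep(pos, 2L, model$optimum)^2)
  } else {
    if (length(pos) != model$dim) {
      stop("position dimension (", length(pos), ") does not match model dim (",
           model$dim, ")", call. = FALSE)
    }
    d2 <- sum((pos - model$optimum)^2)
  }
  exp(-d2 / model$gamma^2)
}

#' Somatic hypermutation as a unit lattice step
#'
#' Displaces each position by +1 or -1 in exactly one uniformly chosen
#' dimension. The input is not modified.
#'
#' @param pos Integer vector, or matrix with one position per row (every row is
#'   mutated independently).
#' @return An object of the same shape as `pos`.
#' @export
mutate_position <- function(pos) {
  if (is.matrix(pos)) {
    n <- nrow(pos)
    if (n == 0L) return(pos)
    k <- sample.int(ncol(pos), n, replace = TRUE)
    s <- sample(c(-1L, 1L), n, replace = TRUE)
    pos[cbind(seq_len(n), k)] <- pos[cbind(seq_len(n), k)] + s
    pos
  } else {
    k <- sample.int(length(pos), 1L)
    pos[k] <- pos[k] + sample(c(-1L, 1L), 1L)
    pos
  }
}

#' Sample founder-cell positions at a fixed distance band from the optimum
#'
#' Founder positions are drawn uniformly from lattice points whose Euclidean
#' distance to the optimum lies in `dist_range`, so that founder affinity is
#' low but the optimum is reachable within a handful of mutations.
#'
#' @param model An [affinity_model()].
#' @param n Number of positions to draw.
#' @param dist_range Length-2 numeric: inclusive distance band (lattice units).
#' @return Integer matrix with `n` rows and `model$dim` columns.
#' @export
sample_founder_position <- function(model, n = 1L, dist_range = c(5, 7)) {
  stopifnot(inherits(model, "affinity_model"),
            length(dist_range) == 2L, dist_range[1] >= 0,
            dist_range[2] >= dist_range[1])
  r <- ceiling(dist_range[2])
  lo2 <- dist_range[1]^2
  hi2 <- dist_range[2]^2
  out <- matrix(0L, nrow = n, ncol = model$dim)
  for (i in seq_len(n)) {
    repeat {
      v <- sample.int(2L * r + 1L, model$dim, replace = TRUE) - r - 1L
      s2 <- sum(v^2)
      if (s2 >= lo2 && s2 <= hi2) break
    }
    out[i, ] <- model$optimum + v
  }
  out
}
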