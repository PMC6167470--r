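#' Brainbow colour schemes
#'
#' A colour scheme is an ordered palette together with the probability that a
#' recombination event attributes each colour to a cell. The first entry is
#' always `"black"`, the unstained state (no visible colour / failed
#' recombination). Single-allele Confetti staining yields 4 visible colours;
#' recombination of both alleles yields 10 colour combinations.
#'
#' Measured attribution probabilities are printed at limited precision and may
#' not sum exactly to one; with `normalize = TRUE` (default) the vector is
#' rescaled to sum to 1 exactly.
#'
#' @param name Scheme name.
#' @param colors Character vector of colour labels. `"black"` must be present
#'   and is moved to the front if necessary.
#' @param probabilities Numeric vector of attribution probabilities aligned
#'   with `colors`; non-negative, summing to 1 within 0.02 before
#'   normalisation.
#' @param normalize Rescale probabilities to sum exactly to 1.
#' @return An object of class `color_scheme` with fields `name`, `colors`
#'   (black first) and `probabilities`.
#' @seealso [builtin_schemes()], [read_scheme_csv()]
#' @export
color_scheme <- function(name, colors, probabilities, normalize = TRUE) {
  if (length(colors) != length(probabilities)) {
    stop("`colors` and `probabilities` must have the same length", call. = FALSE)
  }
  colors <- as.character(colors)
  if (anyDuplicated(colors)) stop("duplicated colour labels", call. = FALSE)
  ib <- match("black", tolower(colors))
  if (is.na(ib)) stop("a colour scheme must contain \"black\"", call. = FALSE)
  ord <- c(ib, setdiff(seq_along(colors), ib))
  colors <- colors[ord]
  colors[1] <- "black"
  probabilities <- as.numeric(probabilities)[ord]
  if (any(!is.finite(probabilities)) || any(probabilities < 0)) {
    stop("probabilities must be finite and non-negative", call. = FALSE)
  }
  s <- sum(probabilities)
  if (abs(s - 1) > 0.02) {
    stop("probabilities sum to ", format(s), ", not 1", call. = FALSE)
  }
  if (normalize) probabilities <- probabilities / s
  structure(
    list(name = as.character(name)[1], colors = colors,
         probabilities = probabilities),
    class = "color_scheme"
  )
}

#' @export
print.color_scheme <- function(x, ...) {
  cat("<color_scheme> ", x$name, ": ", length(x$colors) - 1L,
      " colours + black\n", sep = "")
  print(setNames(round(x$probabilities, 4), x$colors))
  invisible(x)
}

#' Number of visible (non-black) colours in a scheme
#' @param scheme A [color_scheme()].
#' @return Integer count of non-black colours.
#' @export
n_colors <- function(scheme) {
  stopifnot(inherits(scheme, "color_scheme"))
  length(scheme$colors) - 1L
}

#' Built-in colour schemes
#'
#' Returns the measured attribution probabilities for the standard staining
#' settings, plus an idealised equal-probability 10-colour scheme:
#' \describe{
#'   \item{`confetti4`}{Single-allele staining, 4 colours
#'     (black 0.40, YFP/RFP/CFP 0.18 each, GFP 0.06).}
#'   \item{`tamoxifen10`}{Tamoxifen-induced double-allele staining, 10 colour
#'     combinations (black 0.52; visible mass dominated by YFP/RFP/CFP).}
#'   \item{`founder10`}{Constitutive pre-GC staining of founder cells,
#'     10 colour combinations (black 0.11).}
#'   \item{`equal10`}{Hypothetical scheme: black as in `tamoxifen10`, the ten
#'     visible colours equiprobable among the stained mass.}
#' }
#' Probability vectors are renormalised to sum exactly to 1.
#'
#' @return Named list of [color_scheme()] objects.
#' @export
builtin_schemes <- function() {
  lbl10 <- c("black", "YFP", "RFP", "CFP", "GFP",
             "C/R", "C/Y", "Y/R", "G/R", "C/G", "G/Y")
  list(
    confetti4 = color_scheme(
      "confetti4",
      c("black", "YFP", "RFP", "CFP", "GFP"),
      c(0.40, 0.18, 0.18, 0.18, 0.06)
    ),
    tamoxifen10 = color_scheme(
      "tamoxifen10", lbl10,
      c(0.52, 0.13, 0.12, 0.10, 0.056,
        0.027, 0.016, 0.014, 0.0032, 0.0018, 0.001)
    ),
    founder10 = color_scheme(
      "founder10", lbl10,
      c(0.11, 0.17, 0.17, 0.17, 0.051,
        0.080, 0.080, 0.028, 0.080, 0.028, 0.028)
    ),
    equal10 = color_scheme(
      "equal10", lbl10,
      c(0.52, rep((1 - 0.52) / 10, 10))
    )
  )
}

#' Read or write a colour scheme as CSV
#'
#' The file has two columns, `color` and `probability`, one row per colour
#' (black included).
#'
#' @param path File path.
#' @param name Scheme name; defaults to the file name without extension.
#' @param normalize Passed to [color_scheme()].
#' @return [read_scheme_csv()] returns a [color_scheme()];
#'   [write_scheme_csv()] returns `path` invisibly.
#' @export
read_scheme_csv <- function(path, name = NULL, normalize = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("color", "probability") %in% names(df))) {
    stop("scheme CSV must have columns `color` and `probability`", call. = FALSE)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  color_scheme(name, df$color, df$probability, normalize = normalize)
}

#' @param scheme A [color_scheme()] to write.
#' @rdname read_scheme_csv
#' @export
write_scheme_csv <- function(scheme, path) {
  stopifnot(inherits(scheme, "color_scheme"))
  write.csv(
    data.frame(color = scheme$colors,
               probability = formatC(scheme$probabilities, digits = 17,
                                     format = "g")),
    path, row.names = FALSE, quote = TRUE
  )
  invisible(path)
}
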