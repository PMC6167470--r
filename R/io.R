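#' Load a simulation configuration and staining protocol from YAML
#'
#' The file has two top-level sections, `simulation` and `staining`, whose
#' keys mirror the arguments of [gc_config()] and [staining_protocol()].
#' Unknown keys are rejected with their names; omitted keys take the package
#' defaults. Inside `staining`, the colour scheme is given either as
#' `scheme: <builtin name>` or as `scheme_csv: <path>` (see
#' [read_scheme_csv()]; relative to the config file).
#'
#' @param path Path to the YAML file. The package ships a default at
#'   `system.file("extdata", "default_config.yaml", package = "gcbrainbow")`:
#'   tamoxifen-decay staining at day 2 post GC onset with the measured
#'   10-colour probabilities and a 48% target stained fraction.
#' @return List with elements `config` ([gc_config()]) and `protocol`
#'   ([staining_protocol()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), c("simulation", "staining"))
  if (length(bad)) {
    stop("unknown top-level config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sim <- raw$simulation
  if (is.null(sim)) sim <- list()
  allowed_sim <- names(formals(gc_config))
  bad <- setdiff(names(sim), allowed_sim)
  if (length(bad)) {
    stop("unknown simulation key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  config <- do.call(gc_config, sim)

  st <- raw$staining
  if (is.null(st)) st <- list()
  allowed_st <- c(setdiff(names(formals(staining_protocol)), "scheme"),
                  "scheme", "scheme_csv")
  bad <- setdiff(names(st), allowed_st)
  if (length(bad)) {
    stop("unknown staining key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(st$scheme_csv)) {
    scheme_path <- st$scheme_csv
    if (!file.exists(scheme_path)) {
      scheme_path <- file.path(dirname(path), st$scheme_csv)
    }
    st$scheme <- read_scheme_csv(scheme_path)
    st$scheme_csv <- NULL
  } else if (!is.null(st$scheme)) {
    schemes <- builtin_schemes()
    if (!st$scheme %in% names(schemes)) {
      stop("unknown scheme `", st$scheme, "`; builtin schemes: ",
           paste(names(schemes), collapse = ", "), call. = FALSE)
    }
    st$scheme <- schemes[[st$scheme]]
  }
  protocol <- do.call(staining_protocol, st)
  list(config = config, protocol = protocol)
}

cohort_columns <- c("gc_id", "t", "n", "f", "dominant_clone", "l",
                    "dominant_lineage", "l_late", "c", "dominant_color",
                    "d", "pdd", "mean_affinity")

#' Write / read a cohort table as CSV
#'
#' Tidy CSV with one row per `(gc_id, t)` and the [dominance_record()]
#' columns; unset fields (e.g. lineage statistics before lineage definition)
#' are written as empty cells and read back as `NA`. Numeric values are
#' written at full double precision so the round trip is lossless.
#'
#' @param cohort A [run_cohort()] table (or any tibble of dominance records).
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   returns a tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- as.data.frame(cohort)[, cohort_columns, drop = FALSE]
  for (cn in names(df)) {
    if (is.double(df[[cn]])) {
      df[[cn]] <- ifelse(is.na(df[[cn]]), NA,
                         trimws(formatC(df[[cn]], digits = 17, format = "g")))
    }
  }
  write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    suppressWarnings(read.csv(path, stringsAsFactors = FALSE,
             colClasses = c(
               gc_id = "integer", t = "numeric", n = "integer",
               f = "numeric", dominant_clone = "integer", l = "numeric",
               dominant_lineage = "integer", l_late = "numeric",
               c = "numeric", dominant_color = "character", d = "numeric",
               pdd = "numeric", mean_affinity = "numeric"))),
    error = function(e) stop("malformed cohort CSV: ", conditionMessage(e),
                             call. = FALSE)
  )
  missing <- setdiff(cohort_columns, names(df))
  if (length(missing)) {
    stop("cohort CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$dominant_color[!is.na(df$dominant_color) & df$dominant_color == ""] <-
    NA_character_
  tibble::as_tibble(df[, cohort_columns])
}
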