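#' Construct a cohort
#'
#' A cohort is the unit of data for all design-stage calculations: one row
#' per individual, a numeric matrix of predictor values, optional follow-up
#' (time in years plus a binary event indicator) and optional categorical
#' subgroup labels (e.g. menopausal status) that need not be in the model.
#'
#' Missing values are a hard error: silently imputing or dropping rows would
#' corrupt the information matrix downstream. Time and event must be both
#' present or both absent, and all times must be strictly positive.
#'
#' @param predictors Numeric matrix (or data frame of numerics), one column
#'   per predictor, with column names.
#' @param time Optional numeric vector of follow-up times in years (> 0).
#' @param event Optional binary (0/1) event indicator, required iff `time`
#'   is given.
#' @param subgroups Optional data frame of categorical label columns.
#' @param ids Optional row identifiers; defaults to `1:n`.
#' @param standardisation Optional named list of `c(mean, sd)` pairs recording
#'   the centring/scaling already applied to columns (set by [standardise()]).
#' @return An object of class `cohort`.
#' @seealso [read_cohort()], [standardise()], [summarise_followup()]
#' @export
#' @examples
#' ch <- cohort(cbind(age = c(50, 60, 70)), time = c(1, 2, 3),
#'              event = c(1, 0, 1))
#' ch
cohort <- function(predictors, time = NULL, event = NULL, subgroups = NULL,
                   ids = NULL, standardisation = list()) {
  predictors <- as.matrix(predictors)
  if (ncol(predictors) > 0 &&
      (is.null(colnames(predictors)) || anyDuplicated(colnames(predictors)))) {
    stop_stabsize("predictor columns must have unique names", "schema_error")
  }
  storage.mode(predictors) <- "double"
  n <- nrow(predictors)
  if (anyNA(predictors)) {
    bad <- which(rowSums(is.na(predictors)) > 0)[1L]
    stop_stabsize(sprintf("missing predictor value in row %d", bad),
                  "validation_error")
  }
  if (xor(is.null(time), is.null(event))) {
    stop_stabsize("time and event must be both present or both absent",
                  "validation_error")
  }
  if (!is.null(time)) {
    time <- as.double(time)
    event <- as.double(event)
    if (length(time) != n || length(event) != n) {
      stop_stabsize("time/event length does not match predictors",
                    "validation_error")
    }
    if (anyNA(time) || anyNA(event)) {
      bad <- which(is.na(time) | is.na(event))[1L]
      stop_stabsize(sprintf("missing follow-up value in row %d", bad),
                    "validation_error")
    }
    if (any(time <= 0)) {
      bad <- which(time <= 0)[1L]
      stop_stabsize(sprintf("non-positive follow-up time in row %d", bad),
                    "validation_error")
    }
    if (!all(event %in% c(0, 1))) {
      bad <- which(!event %in% c(0, 1))[1L]
      stop_stabsize(sprintf("event indicator not in {0,1} in row %d", bad),
                    "validation_error")
    }
  }
  if (!is.null(subgroups)) {
    subgroups <- as.data.frame(subgroups, stringsAsFactors = FALSE)
    if (nrow(subgroups) != n) {
      stop_stabsize("subgroup rows do not match predictors", "validation_error")
    }
    if (anyNA(subgroups)) {
      stop_stabsize("missing subgroup label", "validation_error")
    }
  }
  if (is.null(ids)) ids <- seq_len(n)
  structure(
    list(predictors = predictors, time = time, event = event,
         subgroups = subgroups, ids = ids,
         standardisation = standardisation),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d individuals, %d predictors (%s)\n",
              nrow(x$predictors), ncol(x$predictors),
              paste(colnames(x$predictors), collapse = ", ")))
  if (!is.null(x$time)) {
    cat(sprintf("  follow-up present: %d events / %d\n",
                sum(x$event), length(x$event)))
  } else {
    cat("  follow-up absent\n")
  }
  if (!is.null(x$subgroups)) {
    cat(sprintf("  subgroups: %s\n", paste(names(x$subgroups), collapse = ", ")))
  }
  if (length(x$standardisation)) {
    cat(sprintf("  standardised: %s\n",
                paste(names(x$standardisation), collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$predictors)

#' Subset a cohort by row
#'
#' @param x A `cohort`.
#' @param i Row index (logical or integer).
#' @param ... Ignored.
#' @return A `cohort` with the selected individuals.
#' @export
subset_cohort <- function(x, i, ...) {
  stopifnot(inherits(x, "cohort"))
  cohort(x$predictors[i, , drop = FALSE],
         time = if (!is.null(x$time)) x$time[i],
         event = if (!is.null(x$event)) x$event[i],
         subgroups = if (!is.null(x$subgroups)) x$subgroups[i, , drop = FALSE],
         ids = x$ids[i],
         standardisation = x$standardisation)
}

#' Declare column roles for reading a cohort file
#'
#' @param predictors Character vector of predictor column names.
#' @param time,event Optional column names for follow-up.
#' @param subgroups Optional character vector of subgroup label columns.
#' @param id Optional identifier column.
#' @param categorical Named list mapping categorical predictor columns to
#'   their reference level; these are expanded to 0/1 dummy columns named
#'   `<column><level>` (reference level omitted).
#' @param filter Optional single-argument function applied to the raw data
#'   frame returning a logical row mask (e.g. a target-population predicate).
#' @return A `cohort_schema` list.
#' @export
cohort_schema <- function(predictors, time = NULL, event = NULL,
                          subgroups = NULL, id = NULL,
                          categorical = list(), filter = NULL) {
  structure(list(predictors = predictors, time = time, event = event,
                 subgroups = subgroups, id = id, categorical = categorical,
                 filter = filter),
            class = "cohort_schema")
}

#' Read a cohort schema from a YAML file
#'
#' The file declares `predictors`, optional `time`, `event`, `subgroups`,
#' `id`, and a `categorical` mapping of column name to reference level.
#'
#' @param path Path to a YAML file.
#' @return A `cohort_schema`.
#' @export
read_schema <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_schema(predictors = as.character(y$predictors),
                time = y$time, event = y$event,
                subgroups = if (!is.null(y$subgroups)) as.character(y$subgroups),
                id = y$id,
                categorical = if (is.null(y$categorical)) list() else y$categorical)
}

#' Read a cohort from a delimited text file
#'
#' Files are comma-separated with a header row, UTF-8, `.` decimal mark.
#' Categorical predictors declared in the schema are dummy-coded against
#' their reference level.
#'
#' @param path Path to a CSV file.
#' @param schema A [cohort_schema()] mapping column roles.
#' @return A validated [cohort()].
#' @export
read_cohort <- function(path, schema) {
  if (!file.exists(path)) {
    stop_stabsize(sprintf("file not found: %s", path), "schema_error")
  }
  stopifnot(inherits(schema, "cohort_schema"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!is.null(schema$filter)) {
    df <- df[schema$filter(df), , drop = FALSE]
  }
  declared <- c(schema$predictors, schema$time, schema$event,
                schema$subgroups, schema$id)
  missing_cols <- setdiff(declared, names(df))
  if (length(missing_cols)) {
    stop_stabsize(sprintf("declared column(s) absent from file: %s",
                          paste(missing_cols, collapse = ", ")),
                  "schema_error")
  }
  cols <- list()
  for (p in schema$predictors) {
    if (p %in% names(schema$categorical)) {
      ref <- as.character(schema$categorical[[p]])
      lev <- unique(as.character(df[[p]]))
      if (!ref %in% lev) {
        stop_stabsize(sprintf("reference level '%s' not observed in '%s'",
                              ref, p), "schema_error")
      }
      for (l in setdiff(sort(lev), ref)) {
        cols[[paste0(p, l)]] <- as.double(df[[p]] == l)
      }
    } else {
      v <- df[[p]]
      if (!is.numeric(v)) {
        stop_stabsize(sprintf("predictor '%s' is not numeric; declare it categorical",
                              p), "schema_error")
      }
      cols[[p]] <- as.double(v)
    }
  }
  predictors <- do.call(cbind, cols)
  cohort(predictors,
         time = if (!is.null(schema$time)) df[[schema$time]],
         event = if (!is.null(schema$event)) df[[schema$event]],
         subgroups = if (!is.null(schema$subgroups)) df[schema$subgroups],
         ids = if (!is.null(schema$id)) df[[schema$id]])
}

#' Write a cohort to a CSV file
#'
#' Inverse of [read_cohort()] for already-numeric cohorts: numeric columns
#' are written at full precision so a read/write round trip is bit-exact.
#'
#' @param x A `cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  df <- data.frame(id = x$ids, x$predictors, check.names = FALSE)
  if (!is.null(x$time)) {
    df$time <- x$time
    df$event <- x$event
  }
  if (!is.null(x$subgroups)) df <- cbind(df, x$subgroups)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Standardise continuous predictor columns
#'
#' Replaces each named column by `(x - mean) / sd` using this cohort's sample
#' mean and sample SD (n - 1 denominator) and records the pair so the same
#' transformation can be applied to new individuals and inverted exactly.
#'
#' @param x A `cohort`.
#' @param columns Names of continuous columns to standardise.
#' @return The cohort with standardised columns and updated metadata.
#' @export
standardise <- function(x, columns) {
  stopifnot(inherits(x, "cohort"))
  missing_cols <- setdiff(columns, colnames(x$predictors))
  if (length(missing_cols)) {
    stop_stabsize(sprintf("unknown column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  "schema_error")
  }
  for (cl in columns) {
    v <- x$predictors[, cl]
    m <- mean(v)
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop_stabsize(sprintf("column '%s' has zero SD; cannot standardise", cl),
                    "degenerate_predictor_error")
    }
    x$predictors[, cl] <- (v - m) / s
    x$standardisation[[cl]] <- c(mean = m, sd = s)
  }
  x
}

#' Undo standardisation using the stored constants
#'
#' @param x A `cohort` with standardisation metadata.
#' @param columns Columns to restore; defaults to all standardised columns.
#' @return The cohort on the original predictor scale.
#' @export
destandardise <- function(x, columns = names(x$standardisation)) {
  stopifnot(inherits(x, "cohort"))
  for (cl in columns) {
    ms <- x$standardisation[[cl]]
    if (is.null(ms)) {
      stop_stabsize(sprintf("no standardisation stored for '%s'", cl),
                    "schema_error")
    }
    x$predictors[, cl] <- x$predictors[, cl] * ms["sd"] + ms["mean"]
    x$standardisation[[cl]] <- NULL
  }
  x
}

#' Summarise observed follow-up
#'
#' @param x A `cohort` with follow-up.
#' @return A `cohort_summary` with counts, person-years, mean and maximum
#'   follow-up, and the event rate per person-year (events / person-years).
#' @export
#' @examples
#' ch <- cohort(cbind(z = 0:2), time = c(1, 2, 3), event = c(1, 0, 1))
#' summarise_followup(ch)
summarise_followup <- function(x) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(x$time)) {
    stop_stabsize("cohort has no follow-up information", "state_error")
  }
  py <- sum(x$time)
  ev <- sum(x$event)
  structure(
    list(n = nrow(x$predictors), events = ev, person_years = py,
         mean_followup = mean(x$time), max_followup = max(x$time),
         event_rate = ev / py),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<cohort follow-up> n = %d, events = %d\n",
    "  person-years %.1f, mean follow-up %.2f y, max %.2f y\n",
    "  event rate %.4f per person-year\n"),
    x$n, x$events, x$person_years, x$mean_followup, x$max_followup,
    x$event_rate))
  invisible(x)
}

#' The GBSG ER-positive / tamoxifen pilot cohort
#'
#' Builds the breast-cancer pilot cohort used throughout the worked example:
#' the 220 node-positive, oestrogen-receptor-positive patients treated with
#' tamoxifen from the German Breast Cancer Study Group cohort shipped with
#' the survival package. Recurrence-free survival time is converted from
#' days to years. Continuous predictors (age, tumour size, nodes) are
#' standardised; tumour grade is dummy-coded against grade 1; menopausal
#' status enters both as a predictor and as a subgroup label for fairness
#' summaries.
#'
#' @param standardised Standardise the continuous predictors (default TRUE).
#' @return A [cohort()] with 220 individuals, 6 predictor columns and
#'   follow-up.
#' @export
#' @examples
#' summarise_followup(gbsg_pilot_cohort())
gbsg_pilot_cohort <- function(standardised = TRUE) {
  g <- survival::gbsg
  g <- g[g$er > 0 & g$hormon == 1, ]
  predictors <- cbind(
    age = as.double(g$age),
    size = as.double(g$size),
    nodes = as.double(g$nodes),
    postmeno = as.double(g$meno),
    grade2 = as.double(g$grade == 2),
    grade3 = as.double(g$grade == 3)
  )
  ch <- cohort(predictors,
               time = g$rfstime / 365.25,
               event = g$status,
               subgroups = data.frame(
                 menopause = ifelse(g$meno == 1, "post", "pre"),
                 stringsAsFactors = FALSE),
               ids = g$pid)
  if (standardised) ch <- standardise(ch, c("age", "size", "nodes"))
  ch
}
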