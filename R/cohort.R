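VALID_KINDS <- c("continuous", "discrete", "time_to_event")
VALID_PROVENANCE <- c("real", "virtual", "unspecified")

#' Variable specification for a cohort column
#'
#' Describes one analysis variable: its name, its statistical kind
#' (`continuous`, `discrete`, or `time_to_event`) and, for time-to-event
#' variables only, the name of the companion 0/1 event-indicator column
#' (1 = event observed, 0 = censored).
#'
#' @param name Non-empty variable name (column header).
#' @param kind One of `"continuous"`, `"discrete"`, `"time_to_event"`.
#' @param event_indicator For `kind = "time_to_event"`, the name of the
#'   companion event-indicator column; must be `NA` otherwise.
#' @return A `variable_spec` object (named list).
#' @export
variable_spec <- function(name, kind, event_indicator = NA_character_) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    stop("variable name must be a non-empty string", call. = FALSE)
  kind <- match.arg(kind, VALID_KINDS)
  if (kind == "time_to_event") {
    if (is.na(event_indicator) || !nzchar(event_indicator))
      stop(sprintf("time-to-event variable '%s' requires an event_indicator column name", name),
           call. = FALSE)
  } else if (!is.na(event_indicator)) {
    stop(sprintf("event_indicator is only meaningful for time_to_event variables (got one for '%s', kind '%s')",
                 name, kind), call. = FALSE)
  }
  structure(list(name = name, kind = kind,
                 event_indicator = as.character(event_indicator)),
            class = "variable_spec")
}

#' Construct a cohort from a data frame
#'
#' A cohort is a typed table of patient records: a data frame plus a variable
#' table assigning each analysis column a kind, and a provenance label saying
#' whether the records are real patients, virtual (synthetic) patients, or
#' unspecified. Event-indicator columns named by a time-to-event variable are
#' kept in the data but are not themselves listed as analysis variables.
#'
#' @param data A data frame; one row per patient record.
#' @param kinds Optional named character vector mapping column names to kinds
#'   (`continuous`, `discrete`, `time_to_event`). Unmapped columns default to
#'   `continuous` when fully numeric, otherwise `discrete`.
#' @param provenance `"real"`, `"virtual"` or `"unspecified"`.
#' @param event_indicators Named character vector mapping each time-to-event
#'   variable name to its companion event-indicator column name.
#' @return A `cohort` object with elements `data`, `variables`
#'   (data frame: `name`, `kind`, `event_indicator`), `provenance`, `n`.
#' @examples
#' ch <- cohort(data.frame(a = c(1, 2), b = c(3, 4)), provenance = "real")
#' ch$n
#' @export
cohort <- function(data, kinds = NULL, provenance = "unspecified",
                   event_indicators = NULL) {
  stopifnot(is.data.frame(data))
  provenance <- match.arg(provenance, VALID_PROVENANCE)
  cols <- names(data)
  if (anyDuplicated(cols))
    stop("duplicate column names: ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "), call. = FALSE)
  if (!is.null(kinds)) {
    unknown <- setdiff(names(kinds), cols)
    if (length(unknown))
      stop("kinds given for columns not in the data: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    bad <- setdiff(kinds, VALID_KINDS)
    if (length(bad))
      stop("unknown variable kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  event_indicators <- event_indicators %||% character(0)
  tte_names <- names(kinds)[kinds == "time_to_event"]
  missing_ind <- setdiff(tte_names, names(event_indicators))
  if (length(missing_ind))
    stop("time_to_event variable(s) without an event_indicators entry: ",
         paste(missing_ind, collapse = ", "), call. = FALSE)
  absent <- setdiff(unname(event_indicators[tte_names]), cols)
  if (length(absent))
    stop("event-indicator column(s) not found in the data: ",
         paste(absent, collapse = ", "), call. = FALSE)

  indicator_cols <- unname(event_indicators[tte_names])
  specs <- list()
  for (cn in cols) {
    if (cn %in% indicator_cols) next  # companion column, not its own variable
    kind <- if (cn %in% names(kinds)) unname(kinds[[cn]]) else {
      v <- data[[cn]]
      fully_numeric <- is.numeric(v) ||
        all(is.na(v)) ||
        !anyNA(suppressWarnings(as.numeric(v[!is.na(v)])))
      if (fully_numeric) "continuous" else "discrete"
    }
    ev <- if (kind == "time_to_event") unname(event_indicators[[cn]]) else NA_character_
    specs[[cn]] <- variable_spec(cn, kind, ev)
  }
  variables <- data.frame(
    name = vapply(specs, `[[`, "", "name"),
    kind = vapply(specs, `[[`, "", "kind"),
    event_indicator = vapply(specs, `[[`, "", "event_indicator"),
    stringsAsFactors = FALSE, row.names = NULL
  )

  # type coercion + value validation
  for (i in seq_len(nrow(variables))) {
    nm <- variables$name[i]; kind <- variables$kind[i]
    if (kind %in% c("continuous", "time_to_event")) {
      v <- data[[nm]]
      if (!is.numeric(v)) {
        suppressWarnings(num <- as.numeric(as.character(v)))
        bad <- !is.na(v) & is.na(num) & as.character(v) != ""
        if (any(bad))
          stop(sprintf("non-numeric value in %s column '%s': %s",
                       kind, nm, paste(utils::head(unique(v[bad]), 3), collapse = ", ")),
               call. = FALSE)
        v <- num
      }
      if (any(!is.na(v) & !is.finite(v)))
        stop(sprintf("non-finite value in column '%s'", nm), call. = FALSE)
      if (kind == "time_to_event" && any(!is.na(v) & v < 0))
        stop(sprintf("negative time in time-to-event column '%s'", nm), call. = FALSE)
      data[[nm]] <- as.numeric(v)
    } else {
      data[[nm]] <- as.character(data[[nm]])
    }
    if (kind == "time_to_event") {
      ev <- variables$event_indicator[i]
      e <- data[[ev]]
      suppressWarnings(e <- as.numeric(as.character(e)))
      if (any(!is.na(e) & !(e %in% c(0, 1))))
        stop(sprintf("event indicator '%s' has values outside {0, 1}", ev), call. = FALSE)
      data[[ev]] <- e
    }
  }
  rownames(data) <- NULL
  structure(list(data = data, variables = variables,
                 provenance = provenance, n = nrow(data)),
            class = "cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d records, %d variables, provenance: %s\n",
              x$n, nrow(x$variables), x$provenance))
  kinds <- table(x$variables$kind)
  cat("  ", paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", "), "\n")
  invisible(x)
}

#' Load a cohort from a CSV file
#'
#' Reads a comma-separated, UTF-8, header-row CSV (decimal point `.`;
#' empty cells and `NA` are treated as missing) into a [cohort()]. Columns
#' not named in `variable_kinds` default to `continuous` when fully numeric
#' and `discrete` otherwise.
#'
#' @param path Path to the CSV file.
#' @param variable_kinds Named character vector mapping column name to kind.
#' @param provenance `"real"`, `"virtual"` or `"unspecified"`.
#' @param event_indicators Named character vector: time-to-event variable name
#'   to event-indicator column name.
#' @return A [cohort()].
#' @export
load_cohort <- function(path, variable_kinds = NULL,
                        provenance = "unspecified", event_indicators = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- utils::read.csv(path, header = FALSE, nrows = 1,
                            colClasses = "character",
                            check.names = FALSE, encoding = "UTF-8")
  hdr <- as.character(unlist(header, use.names = FALSE))
  if (anyDuplicated(hdr))
    stop("duplicate header names in ", path, ": ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "), call. = FALSE)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        colClasses = "character",
                        na.strings = c("", "NA"), encoding = "UTF-8")
  names(df) <- hdr
  cohort(df, kinds = variable_kinds, provenance = provenance,
         event_indicators = event_indicators)
}

#' Check that a real/virtual cohort pair share one variable structure
#'
#' Validation analyses require the two cohorts to have the same variable
#' structure: the same variable names with the same kinds. Column-order
#' differences are reported but do not fail the check. Discrepancies are
#' returned as data, never raised as errors.
#'
#' @param real,virtual Two [cohort()] objects.
#' @return A `structure_match` list with `pass` (logical), `discrepancies`
#'   (data frame: `type`, `name`, `detail`), `order_mismatch` (logical).
#' @export
check_structure_match <- function(real, virtual) {
  stopifnot(inherits(real, "cohort"), inherits(virtual, "cohort"))
  rv <- real$variables; vv <- virtual$variables
  disc <- data.frame(type = character(0), name = character(0),
                     detail = character(0), stringsAsFactors = FALSE)
  add <- function(type, name, detail) {
    rbind(disc, data.frame(type = type, name = name, detail = detail,
                           stringsAsFactors = FALSE))
  }
  only_real <- setdiff(rv$name, vv$name)
  for (nm in only_real)
    disc <- add("missing_in_virtual", nm, "variable present only in the real cohort")
  only_virtual <- setdiff(vv$name, rv$name)
  for (nm in only_virtual)
    disc <- add("missing_in_real", nm, "variable present only in the virtual cohort")
  common <- intersect(rv$name, vv$name)
  for (nm in common) {
    kr <- rv$kind[rv$name == nm]; kv <- vv$kind[vv$name == nm]
    if (kr != kv)
      disc <- add("kind_mismatch", nm, sprintf("real: %s, virtual: %s", kr, kv))
  }
  order_mismatch <- !identical(rv$name[rv$name %in% common],
                               vv$name[vv$name %in% common])
  structure(list(pass = nrow(disc) == 0L, discrepancies = disc,
                 order_mismatch = order_mismatch),
            class = "structure_match")
}

#' @export
print.structure_match <- function(x, ...) {
  cat(sprintf("<structure_match> %s\n", if (x$pass) "PASS" else "FAIL"))
  if (nrow(x$discrepancies)) {
    for (i in seq_len(nrow(x$discrepancies)))
      cat(sprintf("  - [%s] %s: %s\n", x$discrepancies$type[i],
                  x$discrepancies$name[i], x$discrepancies$detail[i]))
  }
  if (x$order_mismatch) cat("  (column order differs; not a failure)\n")
  invisible(x)
}

#' Restrict a cohort to complete cases on selected variables
#'
#' Drops records with missing values in any of the named variables (and, for
#' time-to-event variables, their event-indicator columns). The number of
#' dropped records is attached as attribute `dropped`.
#'
#' @param ch A [cohort()].
#' @param variables Character vector of variable names; empty vector keeps
#'   every record.
#' @return A [cohort()] with `attr(, "dropped")` set.
#' @export
complete_cases <- function(ch, variables = character(0)) {
  stopifnot(inherits(ch, "cohort"))
  unknown <- setdiff(variables, ch$variables$name)
  if (length(unknown))
    stop("unknown variable name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  cols <- variables
  for (nm in variables) {
    ev <- ch$variables$event_indicator[ch$variables$name == nm]
    if (!is.na(ev)) cols <- c(cols, ev)
  }
  keep <- if (length(cols) == 0L) rep(TRUE, ch$n) else
    !Reduce(`|`, lapply(cols, function(cn) is.na(ch$data[[cn]])))
  out <- ch
  out$data <- ch$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  out$n <- nrow(out$data)
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Write a cohort to a CSV file
#'
#' Writes RFC-4180-style CSV with a header row; missing values become empty
#' fields; numeric columns are written with 17 significant digits so that
#' `load_cohort(write_cohort(ch))` reproduces every value exactly.
#'
#' @param ch A [cohort()].
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(ch, path) {
  stopifnot(inherits(ch, "cohort"))
  df <- ch$data
  out <- df
  for (cn in names(df)) {
    v <- df[[cn]]
    out[[cn]] <- if (is.numeric(v)) {
      ifelse(is.na(v), "", sprintf("%.17g", v))
    } else {
      s <- as.character(v)
      needs_quote <- !is.na(s) & grepl('[",\n]', s)
      s[needs_quote] <- paste0('"', gsub('"', '""', s[needs_quote]), '"')
      ifelse(is.na(s), "", s)
    }
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = ",")), con)
  invisible(path)
}

#' Context-of-Use / Question-of-Interest documentation
#'
#' Validation and application activities are carried out relative to a stated
#' Context of Use (how the computational model is used) and Question of
#' Interest (what the simulation is meant to answer). Both are free text and
#' are prerequisites for validation reports; pass `allow_empty = TRUE` to opt
#' out explicitly.
#'
#' @param cou,qoi Free-text strings.
#' @param allow_empty Permit empty strings (explicit opt-out).
#' @return A `context_doc` list.
#' @export
context_doc <- function(cou, qoi, allow_empty = FALSE) {
  stopifnot(is.character(cou), length(cou) == 1L,
            is.character(qoi), length(qoi) == 1L)
  if (!allow_empty && (!nzchar(cou) || !nzchar(qoi)))
    stop("CoU and QoI must be non-empty (or set allow_empty = TRUE to opt out)",
         call. = FALSE)
  structure(list(cou = cou, qoi = qoi), class = "context_doc")
}

# internal: fetch and check a variable of a required kind, complete cases
get_variable <- function(ch, name, kind = NULL) {
  idx <- match(name, ch$variables$name)
  if (is.na(idx)) stop("unknown variable: ", name, call. = FALSE)
  if (!is.null(kind) && ch$variables$kind[idx] != kind)
    stop(sprintf("variable '%s' is %s, expected %s",
                 name, ch$variables$kind[idx], kind), call. = FALSE)
  v <- ch$data[[name]]
  v[!is.na(v)]
}
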