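# Structured analysis reports: a CoU/QoI header plus the result blocks of any
# analysis, renderable losslessly to JSON and readably to Markdown or HTML.

#' Assemble an analysis report
#'
#' Bundles the Context-of-Use / Question-of-Interest documentation with one
#' or more analysis result blocks, input fingerprints and seeds, into a
#' structure renderable with [render_report()]. Two assemblies from the same
#' inputs and seeds differ only in the timestamp.
#'
#' @param context A [context_doc()].
#' @param results Named list of result blocks (any result object from this
#'   package, or plain lists/data frames).
#' @param inputs Optional named list of input fingerprints
#'   (see [input_fingerprint()]).
#' @param seeds Optional named list/vector of seeds used by stochastic blocks.
#' @param timestamp Report timestamp string; defaults to the current UTC time.
#' @return An `analysis_report` list.
#' @export
analysis_report <- function(context, results, inputs = NULL, seeds = NULL,
                            timestamp = format(Sys.time(), tz = "UTC",
                                               "%Y-%m-%dT%H:%M:%SZ")) {
  stopifnot(inherits(context, "context_doc"), is.list(results))
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("results must be a fully named list", call. = FALSE)
  structure(list(
    tool = "cohortval",
    tool_version = as.character(utils::packageVersion("cohortval")),
    timestamp = timestamp,
    context = unclass(context),
    inputs = inputs,
    seeds = seeds,
    results = results
  ), class = "analysis_report")
}

#' Fingerprint an input file for the report header
#'
#' Records the file name, row and column counts of a loaded cohort, and an
#' MD5 checksum of the file bytes.
#'
#' @param path The file the cohort was loaded from.
#' @param ch The loaded [cohort()].
#' @return A named list.
#' @export
input_fingerprint <- function(path, ch) {
  list(file = basename(path), rows = ch$n,
       columns = ncol(ch$data),
       md5 = unname(tools::md5sum(path)))
}

# strip S3 classes recursively so jsonlite serializes plainly
strip_classes <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

render_markdown_value <- function(x, depth = 2) {
  h <- strrep("#", min(depth, 6))
  if (is.data.frame(x)) {
    cols <- names(x)
    header <- paste0("| ", paste(cols, collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|")
    rows <- apply(x, 1, function(r)
      paste0("| ", paste(format(r, trim = TRUE), collapse = " | "), " |"))
    return(c(header, sep, rows, ""))
  }
  if (is.matrix(x)) return(render_markdown_value(as.data.frame(x), depth))
  if (is.list(x)) {
    out <- character(0)
    for (nm in names(x)) {
      val <- x[[nm]]
      if (is.list(val) || is.data.frame(val) || is.matrix(val) ||
          length(val) > 12) {
        out <- c(out, paste0(h, " ", nm), "",
                 render_markdown_value(val, depth + 1))
      } else {
        out <- c(out, paste0("- **", nm, "**: ",
                             paste(format(val), collapse = ", ")))
      }
    }
    return(c(out, ""))
  }
  if (length(x) > 12)
    return(c(paste0("`", length(x), " values: ",
                    paste(format(utils::head(x, 6)), collapse = ", "),
                    ", ...`"), ""))
  c(paste(format(x), collapse = ", "), "")
}

#' Render an analysis report
#'
#' JSON output is lossless for all numeric content (full double precision);
#' Markdown and HTML are readable summaries. Two renders of the same report
#' object produce identical bytes.
#'
#' @param report An [analysis_report()].
#' @param format `"json"`, `"markdown"` or `"html"`.
#' @param path Optional output file; when `NULL` the document is returned as
#'   a character string.
#' @return The rendered document (invisibly when written to `path`).
#' @export
render_report <- function(report, format = c("json", "markdown", "html"),
                          path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  format <- match.arg(format)
  doc <- switch(format,
    json = jsonlite::toJSON(strip_classes(unclass(report)),
                            auto_unbox = TRUE, digits = I(17), na = "null",
                            pretty = TRUE),
    markdown = {
      lines <- c(paste0("# Analysis report (", report$tool, " ",
                        report$tool_version, ")"), "",
                 paste0("_Generated: ", report$timestamp, "_"), "",
                 "## Context of Use", "", report$context$cou, "",
                 "## Question of Interest", "", report$context$qoi, "")
      if (!is.null(report$inputs))
        lines <- c(lines, "## Inputs", "",
                   render_markdown_value(report$inputs, 3))
      if (!is.null(report$seeds))
        lines <- c(lines, "## Seeds", "",
                   render_markdown_value(report$seeds, 3))
      lines <- c(lines, "## Results", "")
      for (nm in names(report$results))
        lines <- c(lines, paste0("### ", nm), "",
                   render_markdown_value(strip_classes(report$results[[nm]]), 4))
      paste(lines, collapse = "\n")
    },
    html = {
      md <- render_report(report, "markdown")
      body <- paste0("<pre>\n",
                     gsub(">", "&gt;", gsub("<", "&lt;",
                          gsub("&", "&amp;", md))),
                     "\n</pre>")
      paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">",
             "<title>Analysis report</title></head>\n<body>\n",
             body, "\n</body></html>\n")
    })
  doc <- as.character(doc)
  if (!is.null(path)) {
    writeLines(doc, path, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}
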