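#' Import a table of raw data
#'
#' Reads a rectangular table from an Excel workbook (first or named sheet)
#' or a CSV file, with the header row supplying variable names. Values are
#' imported as-is; coercion of numeric strings happens later, at validation
#' time, so a spreadsheet's stringified numbers are not a problem.
#'
#' @param path Path to an `.xlsx` or `.csv` file.
#' @param sheet Sheet name or index (xlsx only).
#'
#' @return A data frame.
#' @export
import_capl_data <- function(path, sheet = 1) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (is.character(sheet) && !sheet %in% readxl::excel_sheets(path)) {
      stop("sheet '", sheet, "' not found in ", path, call. = FALSE)
    }
    as.data.frame(readxl::read_excel(path, sheet = sheet, guess_max = 10000))
  } else if (ext == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    stop("unsupported input format: .", ext, " (use .xlsx or .csv)",
         call. = FALSE)
  }
}

#' Export a table of raw or scored data
#'
#' Writes to CSV, to a single-sheet Excel workbook, or (when the haven
#' package is installed) to SPSS `.sav`. Numbers, strings, and missing
#' values round-trip through csv and xlsx.
#'
#' @param data A data frame.
#' @param path Output path; the format is taken from the extension unless
#'   `format` is given.
#' @param format One of `"auto"`, `"csv"`, `"xlsx"`, `"sav"`.
#'
#' @return `path`, invisibly.
#' @export
export_capl_data <- function(data, path,
                             format = c("auto", "csv", "xlsx", "sav")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
  }
  switch(format,
    csv = utils::write.csv(data, path, row.names = FALSE, na = ""),
    xlsx = write_minimal_xlsx(data, path),
    sav = {
      if (!requireNamespace("haven", quietly = TRUE)) {
        stop("SPSS export requires the 'haven' package", call. = FALSE)
      }
      haven::write_sav(data, path)
    },
    stop("unsupported export format: ", format, call. = FALSE)
  )
  invisible(path)
}

# --- minimal single-sheet xlsx writer -------------------------------------
# No xlsx-writing package is assumed; an .xlsx file is a zip of XML parts,
# which is all we need for one sheet of numbers and (inline) strings.
# readxl reads the result, which the tests use as the independent check.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# spreadsheet column label: 1 -> A, 27 -> AA, ...
col_letter <- function(j) {
  out <- ""
  while (j > 0) {
    out <- paste0(LETTERS[(j - 1) %% 26 + 1], out)
    j <- (j - 1) %/% 26
  }
  out
}

write_minimal_xlsx <- function(data, path, sheet = "Sheet1") {
  stage <- tempfile("xlsx")
  dir.create(file.path(stage, "_rels"), recursive = TRUE)
  dir.create(file.path(stage, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(stage, "xl", "worksheets"), recursive = TRUE)

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    "</Types>"
  ), file.path(stage, "[Content_Types].xml"))

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>"
  ), file.path(stage, "_rels", ".rels"))

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    "<sheets>",
    sprintf('<sheet name="%s" sheetId="1" r:id="rId1"/>', xml_escape(sheet)),
    "</sheets>",
    "</workbook>"
  ), file.path(stage, "xl", "workbook.xml"))

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    "</Relationships>"
  ), file.path(stage, "xl", "_rels", "workbook.xml.rels"))

  cells <- character(0)
  rows <- character(nrow(data) + 1)
  header <- vapply(seq_along(data), function(j) {
    sprintf('<c r="%s1" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
            col_letter(j), xml_escape(names(data)[j]))
  }, character(1))
  rows[1] <- sprintf('<row r="1">%s</row>', paste(header, collapse = ""))
  is_num <- vapply(data, is.numeric, logical(1))
  cols <- lapply(data, function(x) if (is.numeric(x)) x else as.character(x))
  for (i in seq_len(nrow(data))) {
    line <- character(0)
    for (j in seq_along(cols)) {
      v <- cols[[j]][i]
      if (is.na(v)) next
      ref <- paste0(col_letter(j), i + 1)
      line <- c(line, if (is_num[j]) {
        sprintf('<c r="%s"><v>%s</v></c>', ref,
                format(v, digits = 17, scientific = FALSE, trim = TRUE))
      } else {
        sprintf('<c r="%s" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
                ref, xml_escape(v))
      })
    }
    rows[i + 1] <- sprintf('<row r="%d">%s</row>', i + 1,
                           paste(line, collapse = ""))
  }
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    "<sheetData>", rows, "</sheetData>", "</worksheet>"
  ), file.path(stage, "xl", "worksheets", "sheet1.xml"))

  zip::zip(
    zipfile = normalizePath(path, mustWork = FALSE),
    files = c("[Content_Types].xml", "_rels", "xl"),
    root = stage, include_directories = FALSE
  )
  unlink(stage, recursive = TRUE)
  invisible(path)
}

#' Bar plot of scores by interpretive category
#'
#' Draws one bar per interpretive category (in `beginning` to `excelling`
#' order) whose height is the mean score among rows assigned that category;
#' the mean appears above each bar. Rows with a missing interpretation are
#' excluded; if every interpretation is missing, an empty plot is returned
#' with a warning.
#'
#' @param score Numeric scores.
#' @param interpretation Categories aligned with `score` (see
#'   [capl_interpretation()]).
#' @param x_label,y_label Axis labels.
#' @param colors Optional character vector of exactly 4 fill colors, in
#'   category order.
#'
#' @return A ggplot object.
#'
#' @examples
#' d <- score_capl_data(capl_demo_data(50, seed = 2))
#' capl_bar_plot(d$pc_score, d$pc_interpretation,
#'               "Interpretation", "Physical competence (/30)")
#'
#' @export
capl_bar_plot <- function(score, interpretation, x_label = "Interpretation",
                          y_label = "Score", colors = NULL) {
  if (is.null(colors)) {
    colors <- c("#a6cee3", "#1f78b4", "#b2df8a", "#33a02c")
  }
  if (length(colors) != 4) {
    stop("`colors` must contain exactly 4 values", call. = FALSE)
  }
  keep <- !is.na(interpretation) & !is.na(score) &
    interpretation %in% capl_categories
  if (!any(keep)) {
    warning("no rows with both a score and an interpretation; empty plot")
    df <- data.frame(category = factor(character(0),
                                       levels = capl_categories),
                     mean_score = numeric(0))
  } else {
    means <- tapply(score[keep], interpretation[keep], mean)
    df <- data.frame(
      category = factor(names(means), levels = capl_categories),
      mean_score = as.numeric(means)
    )
    df <- df[order(df$category), , drop = FALSE]
  }
  category <- mean_score <- NULL # data-masked ggplot variables
  ggplot2::ggplot(df, ggplot2::aes(x = category, y = mean_score,
                                   fill = category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = round(mean_score, 1)),
                       vjust = -0.4) +
    ggplot2::scale_fill_manual(values = stats::setNames(colors,
                                                        capl_categories)) +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(x = x_label, y = y_label) +
    ggplot2::theme_minimal()
}
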