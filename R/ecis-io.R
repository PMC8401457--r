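#' Read an ECIS "selected wells/time" table
#'
#' Imports the tabular export of an ECIS instrument: first column time in
#' hours, remaining columns impedance (ohm), one per well. Both comma- and
#' semicolon-separated CSV (decimal point) and xlsx are accepted. Leading
#' lines starting with `#` of the form `# key: value` are read into the
#' dataset metadata; an xlsx workbook may carry the same pairs on a second
#' sheet named `meta`.
#'
#' @param path Path to the exported table.
#' @param format `"csv"`, `"xlsx"` or `"auto"` (by file extension, default).
#' @param impute `"error"` (default) refuses blank cells; `"linear"`
#'   interpolates runs of at most 3 consecutive missing points per well.
#' @return An [ecis_dataset]. `meta$source` records the file and
#'   `meta$dialect` the detected field separator.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines("Time,A1,A2\n0,100,101\n1,110,112\n2,150,149", f)
#' read_ecis_table(f)
read_ecis_table <- function(path, format = c("auto", "csv", "xlsx"),
                            impute = c("error", "linear")) {
  format <- match.arg(format)
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xlsx", "xls")) "xlsx" else "csv"
  }
  if (format == "xlsx") {
    tab <- as.data.frame(readxl::read_xlsx(path, sheet = 1L,
                                           col_types = "numeric"))
    meta <- list(source = path, dialect = "xlsx")
    sheets <- readxl::excel_sheets(path)
    if ("meta" %in% sheets) {
      ms <- as.data.frame(readxl::read_xlsx(path, sheet = "meta",
                                            col_names = c("key", "value"),
                                            col_types = "text"))
      for (i in seq_len(nrow(ms))) meta[[ms$key[i]]] <- .parse_meta(ms$value[i])
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    meta <- list(source = path)
    hdr <- grepl("^#", lines)
    for (ln in lines[hdr]) {
      kv <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
      if (length(kv) == 3L) meta[[trimws(kv[2])]] <- .parse_meta(kv[3])
    }
    lines <- lines[!hdr & nzchar(trimws(lines))]
    if (length(lines) < 2L) stop("no data rows in ", path, call. = FALSE)
    sep <- if (lengths(regmatches(lines[1], gregexpr(";", lines[1]))) >
               lengths(regmatches(lines[1], gregexpr(",", lines[1]))))
      ";" else ","
    meta$dialect <- sep
    # strsplit drops trailing empty fields; pad from the separator count
    fields <- lapply(lines, function(ln) {
      f <- strsplit(ln, sep, fixed = TRUE)[[1]]
      want <- lengths(regmatches(ln, gregexpr(sep, ln, fixed = TRUE))) + 1L
      c(f, rep("", want - length(f)))
    })
    nf <- lengths(fields)
    if (length(unique(nf)) != 1L)
      stop("ragged rows in ", path, ": rows ",
           paste(utils::head(which(nf != nf[1]), 5L), collapse = ", "),
           " have a different number of fields", call. = FALSE)
    header <- trimws(fields[[1]])
    body <- fields[-1L]
    tab <- as.data.frame(
      lapply(seq_along(header), function(j) {
        vapply(body, function(r) trimws(r[j]), character(1))
      }), stringsAsFactors = FALSE)
    names(tab) <- header
    for (j in seq_along(tab)) {
      raw <- tab[[j]]
      num <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(num) & nzchar(raw))
      if (length(bad))
        stop(sprintf("non-numeric cell '%s' at data row %d, column '%s'",
                     raw[bad[1]], bad[1], header[j]), call. = FALSE)
      tab[[j]] <- num
    }
  }
  if (ncol(tab) < 2L) stop("need a time column plus at least one well",
                           call. = FALSE)
  if (nrow(tab) < 3L) stop("need at least 3 rows of data", call. = FALSE)
  known_time <- c("time", "time (hrs)", "time(hrs)", "time [h]", "t")
  if (!tolower(trimws(names(tab)[1])) %in% known_time)
    warning("first column '", names(tab)[1],
            "' not a recognised time header; treating it as time in hours",
            call. = FALSE)
  wells <- names(tab)[-1L]
  if (anyDuplicated(wells))
    stop("duplicate well header(s): ",
         paste(unique(wells[duplicated(wells)]), collapse = ", "),
         call. = FALSE)
  time <- tab[[1L]]
  if (anyNA(time)) stop("missing value in time column at row ",
                        which(is.na(time))[1], call. = FALSE)
  imp <- as.matrix(tab[, -1L, drop = FALSE])
  if (anyNA(imp)) {
    if (impute == "error") {
      ij <- which(is.na(imp), arr.ind = TRUE)[1L, ]
      stop(sprintf(paste0("missing impedance at row %d, well '%s' ",
                          "(use impute = 'linear' to interpolate short gaps)"),
                   ij[1], wells[ij[2]]), call. = FALSE)
    }
    imp <- .impute_linear(time, imp, max_run = 3L)
  }
  ecis_dataset(time, imp, wells, meta)
}

.parse_meta <- function(v) {
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
  v
}

.impute_linear <- function(time, imp, max_run = 3L) {
  for (j in seq_len(ncol(imp))) {
    y <- imp[, j]
    if (!anyNA(y)) next
    r <- rle(is.na(y))
    if (any(r$values & r$lengths > max_run) || is.na(y[1]) ||
        is.na(y[length(y)]))
      stop("gap of more than ", max_run, " consecutive missing points in ",
           "well ", colnames(imp)[j], call. = FALSE)
    ok <- !is.na(y)
    imp[, j] <- stats::approx(time[ok], y[ok], xout = time)$y
  }
  imp
}

#' Write an ECIS dataset back to a "selected wells/time" table
#'
#' CSV output carries metadata as leading `# key: value` comment lines; xlsx
#' output places it on a second sheet named `meta`. A written table reads
#' back identically (values to better than 1e-9).
#'
#' @param ds An [ecis_dataset].
#' @param path Output path.
#' @param format `"csv"`, `"xlsx"` or `"auto"` (by extension).
#' @return Invisibly, `path`.
#' @export
write_ecis_table <- function(ds, path, format = c("auto", "csv", "xlsx")) {
  validate_ecis_dataset(ds)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xlsx", "xls")) "xlsx" else "csv"
  }
  meta <- ds$meta[setdiff(names(ds$meta), c("source", "dialect"))]
  tab <- as.data.frame(ds)
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in names(meta))
      writeLines(sprintf("# %s: %s", k, format(meta[[k]], digits = 17)), con)
    writeLines(paste(c("Time", ds$wells), collapse = ","), con)
    utils::write.table(format(tab, digits = 17, trim = TRUE,
                              scientific = FALSE),
                       con, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    sheets <- list(`selected wells_time` = tab)
    if (length(meta))
      sheets$meta <- data.frame(key = names(meta),
                                value = vapply(meta, function(v)
                                  format(v, digits = 17), character(1)))
    .write_xlsx_minimal(sheets, path)
  }
  invisible(path)
}

# Minimal Office Open XML writer: numeric cells as <v>, strings inline.
# Covers exactly what read_ecis_table needs back; not a general xlsx writer.
.write_xlsx_minimal <- function(sheets, path) {
  tmp <- tempfile("xlsx")
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)
  ns <- length(sheets)
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
            seq_len(ns)),
    '</Types>'), file.path(tmp, "[Content_Types].xml"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'), file.path(tmp, "_rels", ".rels"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets>',
    sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
            .xml_escape(names(sheets)), seq_len(ns), seq_len(ns)),
    '</sheets></workbook>'), file.path(tmp, "xl", "workbook.xml"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
            seq_len(ns), seq_len(ns)),
    '</Relationships>'), file.path(tmp, "xl", "_rels", "workbook.xml.rels"))
  for (i in seq_len(ns))
    writeLines(.sheet_xml(sheets[[i]]),
               file.path(tmp, "xl", "worksheets", sprintf("sheet%d.xml", i)))
  old <- setwd(tmp)
  on.exit(setwd(old), add = TRUE)
  if (file.exists(path)) unlink(path)
  zip::zip(zipfile = path,
           files = c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
                     "xl/_rels/workbook.xml.rels",
                     sprintf("xl/worksheets/sheet%d.xml", seq_len(ns))),
           mode = "mirror")
  invisible(path)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.col_letter <- function(j) {
  s <- ""
  while (j > 0) {
    s <- paste0(LETTERS[(j - 1L) %% 26L + 1L], s)
    j <- (j - 1L) %/% 26L
  }
  s
}

.sheet_xml <- function(df) {
  nr <- nrow(df); nc <- ncol(df)
  rows <- character(nr + 1L)
  hdr <- vapply(seq_len(nc), function(j)
    sprintf('<c r="%s1" t="inlineStr"><is><t>%s</t></is></c>',
            .col_letter(j), .xml_escape(names(df)[j])), character(1))
  rows[1L] <- sprintf('<row r="1">%s</row>', paste(hdr, collapse = ""))
  num <- vapply(df, is.numeric, logical(1))
  for (i in seq_len(nr)) {
    cells <- vapply(seq_len(nc), function(j) {
      ref <- paste0(.col_letter(j), i + 1L)
      if (num[j])
        sprintf('<c r="%s"><v>%s</v></c>', ref,
                format(df[i, j], digits = 17, scientific = FALSE))
      else
        sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>', ref,
                .xml_escape(as.character(df[i, j])))
    }, character(1))
    rows[i + 1L] <- sprintf('<row r="%d">%s</row>', i + 1L,
                            paste(cells, collapse = ""))
  }
  c('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetData>', rows, '</sheetData></worksheet>')
}
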