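# Plate-reader export parsing and annotated result I/O. Two generic export
# dialects are supported: a wide matrix (row letters x column numbers, 8x12
# or 16x24) and a long table with columns (well, value). Mixed files are
# rejected; the dialect is auto-detected from the header shape.

.detect_sep <- function(lines) {
  header <- lines[1]
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

#' Parse one plate-reader export into well observations
#'
#' Accepts either a wide matrix export (first column row letters, header row
#' column numbers; 8x12 or 16x24 inferred from shape) or a long export with
#' columns `well` and `value`. Empty cells become missing values, never
#' zero; any non-numeric, non-empty cell is a parse error naming the well.
#'
#' @param source Path to a CSV/TSV file (or a connection readable by
#'   `readLines`).
#' @param plate_id Plate identifier to stamp on every observation.
#' @param time Measurement time in hours (the screen uses 0 and 48).
#' @param batch Optional batch label.
#' @return A data.frame with columns `plate_id`, `batch`, `well`, `row`,
#'   `col`, `time`, `od600` — one row per well present in the export.
#' @export
read_plate_matrix <- function(source, plate_id, time, batch = "") {
  lines <- readLines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty plate export: ", plate_id)
  sep <- .detect_sep(lines)
  # appending one separator preserves a trailing empty field, which
  # strsplit would otherwise drop
  cells <- strsplit(paste0(lines, sep), sep, fixed = TRUE)
  header <- trimws(cells[[1]])

  if (any(tolower(header) == "well")) {
    return(.read_plate_long(cells, header, plate_id, time, batch))
  }
  .read_plate_wide(cells, header, plate_id, time, batch)
}

.parse_cell <- function(x, where) {
  x <- trimws(x)
  x[is.na(x)] <- ""  # trailing empty fields dropped by the splitter
  out <- suppressWarnings(as.numeric(x))
  bad <- nzchar(x) & is.na(out)
  if (any(bad)) {
    stop("non-numeric cell(s) in plate export at ",
         paste(where[bad], collapse = ", "))
  }
  out
}

.read_plate_wide <- function(cells, header, plate_id, time, batch) {
  body <- cells[-1]
  n_rows <- length(body)
  fmt <- if (n_rows == 8L) 96L else if (n_rows == 16L) 384L else
    stop("plate matrix must have 8 or 16 data rows, found ", n_rows)
  dims <- plate_dims(fmt)
  widths <- vapply(body, length, 1L)
  if (any(widths != dims[2] + 1L)) {
    stop("ragged plate matrix: expected ", dims[2] + 1L,
         " fields per row, found ", paste(unique(widths), collapse = "/"))
  }
  row_letters <- toupper(trimws(vapply(body, `[`, "", 1L)))
  if (!identical(row_letters, LETTERS[seq_len(dims[1])])) {
    stop("plate matrix row labels must be ",
         LETTERS[1], "..", LETTERS[dims[1]], " in order")
  }
  out <- do.call(rbind, lapply(seq_along(body), function(i) {
    labels <- well_label(rep(i - 1L, dims[2]), seq_len(dims[2]) - 1L, fmt)
    data.frame(
      plate_id = plate_id, batch = batch, well = labels,
      row = i - 1L, col = seq_len(dims[2]) - 1L, time = time,
      od600 = .parse_cell(body[[i]][-1], labels),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

.read_plate_long <- function(cells, header, plate_id, time, batch) {
  icol_well <- which(tolower(header) == "well")[1]
  icol_val <- which(tolower(header) == "value")[1]
  if (is.na(icol_val)) stop("long plate export needs a 'value' column")
  body <- cells[-1]
  wells <- toupper(trimws(vapply(body, `[`, "", icol_well)))
  if (anyDuplicated(wells)) {
    stop("duplicate well(s) in long plate export: ",
         paste(unique(wells[duplicated(wells)]), collapse = ", "))
  }
  # format from the largest coordinate present
  fmt <- tryCatch({ well_index(wells, 96); 96L }, error = function(e) 384L)
  idx <- well_index(wells, fmt)
  data.frame(
    plate_id = plate_id, batch = batch, well = wells,
    row = idx$row, col = idx$col, time = time,
    od600 = .parse_cell(vapply(body, `[`, "", icol_val), wells),
    stringsAsFactors = FALSE
  )
}

#' Annotate well observations with their experimental condition
#'
#' Joins parsed observations to a plate layout (`plate_id`, `well`,
#' `condition_id`) and a validated condition table. Blank wells are retained
#' and labeled. Observed wells absent from the layout are dropped with a
#' warning listing them; a layout referencing an unknown condition or an
#' unobserved well is an error.
#'
#' @param observations Output of [read_plate_matrix()] (rows from several
#'   plates/timepoints may be concatenated).
#' @param conditions Condition table (see [read_condition_table()]).
#' @param layout data.frame with columns `plate_id`, `well`, `condition_id`.
#' @return Tidy observation table: one row per (well, time) with condition
#'   annotations (`condition_id`, `kind`, `strain_1`, `strain_2`).
#' @export
join_layout <- function(observations, conditions, layout) {
  conditions <- .validate_conditions(conditions)
  unknown <- setdiff(layout$condition_id, conditions$condition_id)
  if (length(unknown)) {
    stop("layout references condition_id(s) absent from the condition table: ",
         paste(unique(unknown), collapse = ", "))
  }
  obs_key <- paste(observations$plate_id, observations$well)
  lay_key <- paste(layout$plate_id, layout$well)
  missing_wells <- setdiff(lay_key, obs_key)
  if (length(missing_wells)) {
    stop("layout well(s) not present among observations: ",
         paste(missing_wells, collapse = ", "))
  }
  unmapped <- !(obs_key %in% lay_key)
  if (any(unmapped)) {
    dropped <- unique(obs_key[unmapped])
    warning(length(dropped), " observed well(s) missing from layout, dropped: ",
            paste(dropped, collapse = ", "))
    observations <- observations[!unmapped, , drop = FALSE]
    obs_key <- obs_key[!unmapped]
  }
  m <- match(obs_key, lay_key)
  observations$condition_id <- layout$condition_id[m]
  cm <- match(observations$condition_id, conditions$condition_id)
  observations$kind <- conditions$kind[cm]
  observations$strain_1 <- conditions$strain_1[cm]
  observations$strain_2 <- conditions$strain_2[cm]
  rownames(observations) <- NULL
  observations
}

.config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a result table as annotated CSV
#'
#' Prepends `#`-comment header lines recording the package version and a
#' hash of the configuration that produced the table, so result files are
#' traceable. Values round-trip exactly through [read_results()] at the
#' printed precision (full double precision).
#'
#' @param table data.frame to write.
#' @param path Destination file.
#' @param config Optional `screen_config` recorded in the header hash.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, config = NULL) {
  if (!is.data.frame(table)) stop("table must be a data.frame")
  if (nrow(table) == 0L) warning("writing an empty result table (header only)")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("# syntroscreen ", as.character(utils::packageVersion("syntroscreen"))),
    paste0("# config_hash: ", if (is.null(config)) "none" else .config_hash(unclass(config))),
    paste0("# written: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), con)
  printable <- table
  for (j in seq_along(printable)) {
    if (is.numeric(printable[[j]]) && !is.integer(printable[[j]])) {
      printable[[j]] <- sprintf("%.17g", printable[[j]])
      printable[[j]][is.na(table[[j]])] <- NA
    }
  }
  utils::write.table(printable, con, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path CSV file path.
#' @return data.frame (comment header skipped).
#' @export
read_results <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
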