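#' @keywords internal
"_PACKAGE"

# Supported liquid-microplate formats, rows x columns.
.PLATE_DIMS <- list("96" = c(8L, 12L), "384" = c(16L, 24L))

#' Plate dimensions for a supported format
#'
#' @param format Plate format, `96` or `384`.
#' @return Integer vector `c(rows, cols)`.
#' @export
plate_dims <- function(format) {
  key <- as.character(format)
  if (length(key) != 1L || !key %in% names(.PLATE_DIMS)) {
    stop("unsupported plate format: ", paste(format, collapse = ", "),
         " (supported: 96, 384)")
  }
  .PLATE_DIMS[[key]]
}

#' Convert well labels to 0-based plate coordinates
#'
#' Wells are addressed internally by 0-based, row-major coordinates; the
#' canonical letter+number labels (`A1` ... `H12` for 96-well, `A1` ... `P24`
#' for 384-well) appear only at I/O boundaries. [well_label()] is the exact
#' inverse.
#'
#' @param label Character vector of well labels such as `"A1"`, `"P24"`.
#' @param format Plate format, `96` or `384`.
#' @return A data.frame with integer columns `row` and `col` (0-based).
#' @examples
#' well_index("A1", 96)    # row 0, col 0
#' well_index("P24", 384)  # row 15, col 23
#' @export
well_index <- function(label, format = 384) {
  dims <- plate_dims(format)
  label <- toupper(as.character(label))
  m <- regmatches(label, regexec("^([A-Z])([0-9]+)$", label))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed well label(s): ", paste(label[bad], collapse = ", "))
  }
  row <- match(vapply(m, `[`, "", 2L), LETTERS) - 1L
  col <- as.integer(vapply(m, `[`, "", 3L)) - 1L
  oob <- row < 0L | row >= dims[1] | col < 0L | col >= dims[2]
  if (any(oob)) {
    stop("well label(s) out of range for ", format, "-well format: ",
         paste(label[oob], collapse = ", "))
  }
  data.frame(row = row, col = col)
}

#' Convert 0-based plate coordinates to canonical well labels
#'
#' @param row,col Integer vectors of 0-based coordinates.
#' @param format Plate format, `96` or `384`.
#' @return Character vector of labels.
#' @export
well_label <- function(row, col, format = 384) {
  dims <- plate_dims(format)
  row <- as.integer(row)
  col <- as.integer(col)
  oob <- is.na(row) | is.na(col) | row < 0L | row >= dims[1] |
    col < 0L | col >= dims[2]
  if (any(oob)) {
    stop("coordinates out of range for ", format, "-well format")
  }
  paste0(LETTERS[row + 1L], col + 1L)
}

#' Is a well on the plate perimeter?
#'
#' Edge wells are the first/last row and first/last column; the perimeter of
#' an R x C plate has 2(R + C) - 4 wells (36 for 96-well, 44 for 384-well).
#'
#' @param row,col 0-based coordinates.
#' @param format Plate format, `96` or `384`.
#' @return Logical vector.
#' @export
is_edge <- function(row, col, format = 384) {
  dims <- plate_dims(format)
  row <- as.integer(row)
  col <- as.integer(col)
  if (any(is.na(row) | is.na(col) | row < 0L | row >= dims[1] |
          col < 0L | col >= dims[2])) {
    stop("coordinates out of range for ", format, "-well format")
  }
  row == 0L | row == dims[1] - 1L | col == 0L | col == dims[2] - 1L
}

#' Screen analysis configuration
#'
#' Collects every tunable threshold of the pipeline with its default.
#' Defaults follow the screen's published constants where stated
#' (auxotroph fraction 0.2, fold-difference gate 1.5, alpha 0.05, inoculum
#' OD600 0.1, pre-pinning normalization OD 2.5); the remaining values are
#' conventional robust-statistics choices documented in the methods
#' vignette.
#'
#' @param auxotroph_fraction_threshold Growth fraction of the prototrophic
#'   parent in minimal medium below which (strictly) a strain is called an
#'   auxotroph. Default 0.2.
#' @param fc_threshold Fold-difference gate, coculture vs fittest
#'   constituent monoculture. Default 1.5.
#' @param alpha Adjusted-p threshold for hit calls. Default 0.05.
#' @param z_threshold Z-factor below which an assay lacks an adequate
#'   activity window and is dropped. Default 0.5.
#' @param mad_k Multiplier on the scaled MAD for replicate-spread flags.
#'   Default 3.
#' @param mad_scale Consistency factor making MAD comparable to a normal
#'   standard deviation. Default 1.4826.
#' @param blank_margin Blank-corrected growth (OD units) above which a
#'   well expected not to grow is treated as contaminated. Default 0.05.
#' @param edge_bias_k Multiplier on the scaled MAD for positional-bias
#'   flags. Default 3.
#' @param fd_floor Floor on the fold-difference denominator. Default 1e-3.
#' @param inoculum_od Inoculation density per well, OD600 equivalents.
#'   Default 0.1.
#' @param normalization_od OD to which input plates are normalized before
#'   pinning. Default 2.5.
#' @param sc_growth_threshold Minimum growth fraction of the parent on
#'   complete medium for a strain to count as a viable auxotroph (rather
#'   than generally sick). Default 0.5.
#' @param stability_tolerance Maximum absolute difference in final
#'   blue-strain proportion between consecutive passages for a community to
#'   be classified as re-established. Default 0.15.
#' @param seed Integer seed recorded with results.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(auxotroph_fraction_threshold = 0.2,
                          fc_threshold = 1.5,
                          alpha = 0.05,
                          z_threshold = 0.5,
                          mad_k = 3,
                          mad_scale = 1.4826,
                          blank_margin = 0.05,
                          edge_bias_k = 3,
                          fd_floor = 1e-3,
                          inoculum_od = 0.1,
                          normalization_od = 2.5,
                          sc_growth_threshold = 0.5,
                          stability_tolerance = 0.15,
                          seed = 1L) {
  cfg <- list(
    auxotroph_fraction_threshold = auxotroph_fraction_threshold,
    fc_threshold = fc_threshold,
    alpha = alpha,
    z_threshold = z_threshold,
    mad_k = mad_k,
    mad_scale = mad_scale,
    blank_margin = blank_margin,
    edge_bias_k = edge_bias_k,
    fd_floor = fd_floor,
    inoculum_od = inoculum_od,
    normalization_od = normalization_od,
    sc_growth_threshold = sc_growth_threshold,
    stability_tolerance = stability_tolerance,
    seed = as.integer(seed)
  )
  thresholds <- cfg[setdiff(names(cfg), "seed")]
  if (any(!vapply(thresholds, function(x) is.numeric(x) && length(x) == 1L && x > 0, TRUE))) {
    stop("all screen_config thresholds must be positive scalars")
  }
  if (cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  class(cfg) <- "screen_config"
  cfg
}

#' @export
print.screen_config <- function(x, ...) {
  cat("screen_config:\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

.validate_strains <- function(strains) {
  req <- c("strain_id", "deleted_gene", "is_reference", "fluorophore")
  miss <- setdiff(req, names(strains))
  if (length(miss)) stop("strain table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(strains$strain_id)) stop("strain_id values must be unique")
  strains$is_reference <- as.logical(strains$is_reference)
  bad_ref <- strains$is_reference & nzchar(trimws(strains$deleted_gene))
  if (any(bad_ref, na.rm = TRUE)) {
    stop("reference (prototrophic) strains must have an empty deleted_gene: ",
         paste(strains$strain_id[bad_ref], collapse = ", "))
  }
  ok_fluor <- strains$fluorophore %in% c("none", "blue", "red")
  if (!all(ok_fluor)) {
    stop("fluorophore must be one of none/blue/red; offending strain(s): ",
         paste(strains$strain_id[!ok_fluor], collapse = ", "))
  }
  strains
}

.validate_conditions <- function(conditions) {
  req <- c("condition_id", "kind", "strain_1", "strain_2",
           "ratio_1", "ratio_2", "media")
  miss <- setdiff(req, names(conditions))
  if (length(miss)) stop("condition table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(conditions$condition_id)) stop("condition_id values must be unique")
  if (!all(conditions$kind %in% c("blank", "monoculture", "coculture"))) {
    stop("condition kind must be blank/monoculture/coculture")
  }
  n_strains <- nzchar(trimws(ifelse(is.na(conditions$strain_1), "", conditions$strain_1))) +
    nzchar(trimws(ifelse(is.na(conditions$strain_2), "", conditions$strain_2)))
  want <- c(blank = 0L, monoculture = 1L, coculture = 2L)[conditions$kind]
  if (any(n_strains != want)) {
    stop("strain count does not match condition kind for: ",
         paste(conditions$condition_id[n_strains != want], collapse = ", "))
  }
  co <- conditions$kind == "coculture"
  r1 <- suppressWarnings(as.numeric(conditions$ratio_1))
  r2 <- suppressWarnings(as.numeric(conditions$ratio_2))
  if (any(co & (is.na(r1) | is.na(r2) | r1 <= 0 | r2 <= 0))) {
    stop("cocultures require positive inoculation_ratio components: ",
         paste(conditions$condition_id[co & (is.na(r1) | is.na(r2) | r1 <= 0 | r2 <= 0)],
               collapse = ", "))
  }
  if (any(!co & (!is.na(r1) | !is.na(r2)))) {
    stop("inoculation ratios are only meaningful for cocultures")
  }
  conditions
}

#' Read and validate a strain annotation table
#'
#' Expects CSV columns `strain_id`, `deleted_gene`, `is_reference`,
#' `fluorophore` (none/blue/red). Reference (prototrophic) strains must have
#' an empty `deleted_gene`.
#'
#' @param path CSV file path.
#' @return Validated data.frame.
#' @export
read_strain_table <- function(path) {
  .validate_strains(utils::read.csv(path, stringsAsFactors = FALSE,
                                    na.strings = character()))
}

#' Read and validate a condition table
#'
#' Expects CSV columns `condition_id`, `kind` (blank/monoculture/coculture),
#' `strain_1`, `strain_2`, `ratio_1`, `ratio_2`, `media`. Blanks carry no
#' strains, monocultures one, cocultures two plus a positive inoculation
#' ratio.
#'
#' @param path CSV file path.
#' @return Validated data.frame.
#' @export
read_condition_table <- function(path) {
  .validate_conditions(utils::read.csv(path, stringsAsFactors = FALSE,
                                       na.strings = c("NA", "")))
}
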