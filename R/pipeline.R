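# End-to-end orchestration: QC cascade then hit calling, with per-stage
# accounting of how many wells and assays each filter removed. These are
# the entry points the analysis scripts drive.

#' Run the QC cascade on a tidy observation table
#'
#' Blank correction, per-condition replicate-spread flags, contamination
#' detection and positional-bias detection. Flags gate downstream
#' inclusion; they do not alter values.
#'
#' @param tidy Annotated observation table ([join_layout()] or
#'   [simulate_screen()]`$tidy`).
#' @param conditions Condition table.
#' @param config A [screen_config()].
#' @param strict_strains Optional strain ids known to be strict auxotrophs
#'   (passed to [detect_contamination()]).
#' @return list: `growth` (blank-corrected per-well table), `flags`
#'   (combined QC flag table), `counts` (wells flagged per filter).
#' @export
screen_qc <- function(tidy, conditions, config = screen_config(),
                      strict_strains = NULL) {
  growth <- blank_correct(tidy)

  spread <- lapply(split(growth, growth$condition_id), function(g) {
    if (g$kind[1] == "blank" || nrow(g) < 3L) return(NULL)
    f <- mad_spread_flags(g$growth, k = config$mad_k, scale = config$mad_scale,
                          blank_margin = config$blank_margin)
    if (!any(f)) return(NULL)
    .qc_flag(g$plate_id[f], g$well[f], g$condition_id[f],
             "replicate_spread", "flag",
             sprintf("replicate %.3f deviates from condition median", g$growth[f]))
  })
  spread <- do.call(rbind, spread[!vapply(spread, is.null, TRUE)])
  if (is.null(spread)) spread <- .empty_flags()

  contam <- detect_contamination(growth, blank_margin = config$blank_margin,
                                 strict_strains = strict_strains)
  bias <- positional_bias_flags(growth, edge_bias_k = config$edge_bias_k,
                                mad_scale = config$mad_scale)
  flags <- rbind(spread, contam, bias)
  rownames(flags) <- NULL
  hard <- flags[flags$severity == "flag", ]
  counts <- table(factor(hard$flag_kind,
                         levels = c("replicate_spread", "contamination",
                                    "positional_bias")))
  list(growth = growth, flags = flags, counts = as.list(counts))
}

#' Call hits on a QC'd growth table
#'
#' Removes hard-flagged wells, assembles pair assays (with the Z-factor
#' activity-range gate), applies Benjamini-Hochberg across the surviving
#' family and calls hits at the configured thresholds.
#'
#' @param growth Blank-corrected table from [screen_qc()].
#' @param conditions Condition table.
#' @param config A [screen_config()].
#' @param flags Optional QC flag table; wells with `severity == "flag"` are
#'   excluded before assay assembly.
#' @param strains Optional strain table for the unique-gene summary.
#' @param apply_activity_filter Apply the Z-factor gate. Default `TRUE`.
#' @return list: `assays` (hit table), `volcano`, `summary`.
#' @export
screen_hits <- function(growth, conditions, config = screen_config(),
                        flags = NULL, strains = NULL,
                        apply_activity_filter = TRUE) {
  if (!is.null(flags) && nrow(flags)) {
    hard <- flags[flags$severity == "flag", ]
    drop <- paste(growth$plate_id, growth$well) %in%
      paste(hard$plate_id, hard$well)
    growth <- growth[!drop, , drop = FALSE]
  }
  assays <- pair_assays(growth, conditions, config,
                        apply_activity_filter = apply_activity_filter)
  assays <- call_hits(assays, config)
  list(assays = assays, volcano = volcano_table(assays),
       summary = hit_summary(assays, strains))
}

#' Full screen pipeline: QC then hit calling
#'
#' @inheritParams screen_qc
#' @param strains Optional strain table for the unique-gene summary.
#' @param apply_activity_filter Apply the Z-factor gate. Default `TRUE`.
#' @return list: `growth`, `flags`, `qc_counts`, `assays`, `volcano`,
#'   `summary`.
#' @export
run_screen <- function(tidy, conditions, config = screen_config(),
                       strains = NULL, strict_strains = NULL,
                       apply_activity_filter = TRUE) {
  qc <- screen_qc(tidy, conditions, config, strict_strains = strict_strains)
  hits <- screen_hits(qc$growth, conditions, config, flags = qc$flags,
                      strains = strains,
                      apply_activity_filter = apply_activity_filter)
  c(list(growth = qc$growth, flags = qc$flags, qc_counts = qc$counts), hits)
}
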