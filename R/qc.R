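# Quality-control cascade for the growth-complementation screen:
# blank correction, auxotroph classification, robust replicate-spread and
# contamination flags, positional-bias detection, and the Z-factor
# activity-range gate. Flags gate which assays enter hit calling; they never
# adjust the measured values themselves (the only value-altering step is
# blank correction).

.qc_flag <- function(plate_id, well, condition_id, flag_kind, severity, detail) {
  data.frame(plate_id = plate_id, well = well, condition_id = condition_id,
             flag_kind = flag_kind, severity = severity, detail = detail,
             stringsAsFactors = FALSE)
}

.empty_flags <- function() {
  .qc_flag(character(), character(), character(), character(),
           character(), character())
}

#' Blank-correct a tidy observation table into per-well growth values
#'
#' Growth per well is the OD gain between the first and last timepoint,
#' minus the median OD gain of the blank wells on the same plate, floored at
#' zero. The subtraction removes shared drift (condensation, medium
#' absorbance); the earlier-timepoint subtraction removes the inoculum.
#' Plates without blanks fall back to the raw OD gain with a warning. Raw
#' values are retained alongside the corrected ones.
#'
#' @param tidy Annotated observation table from [join_layout()] (or the
#'   simulator) holding at least two timepoints per well.
#' @return data.frame with one row per well: identity columns plus `od_t0`,
#'   `od_t48`, `delta` (raw gain), `growth` (blank-corrected, floored at 0)
#'   and `blank_corrected` (logical).
#' @export
blank_correct <- function(tidy) {
  times <- sort(unique(tidy$time))
  if (length(times) < 2L) stop("blank correction needs at least two timepoints")
  t0 <- tidy[tidy$time == times[1], ]
  t1 <- tidy[tidy$time == times[length(times)], ]
  key0 <- paste(t0$plate_id, t0$well)
  key1 <- paste(t1$plate_id, t1$well)
  m <- match(key0, key1)
  if (anyNA(m)) stop("wells present at the first timepoint are missing at the last")
  out <- t0[, setdiff(names(t0), c("time", "od600"))]
  out$od_t0 <- t0$od600
  out$od_t48 <- t1$od600[m]
  out$delta <- out$od_t48 - out$od_t0

  out$blank_corrected <- FALSE
  out$growth <- NA_real_
  for (pl in unique(out$plate_id)) {
    sel <- out$plate_id == pl
    blanks <- sel & out$kind == "blank"
    if (any(blanks, na.rm = TRUE)) {
      bmed <- stats::median(out$delta[blanks], na.rm = TRUE)
      out$growth[sel] <- pmax(out$delta[sel] - bmed, 0)
      out$blank_corrected[sel] <- TRUE
    } else {
      warning("plate ", pl, " has no blank wells; raw OD gain used")
      out$growth[sel] <- pmax(out$delta[sel], 0)
    }
  }
  rownames(out) <- NULL
  out
}

#' Classify a strain as auxotroph or leaky/prototroph
#'
#' A strain is an auxotroph when its minimal-medium (SM) growth falls
#' strictly below `threshold` (default 20%) of the prototrophic parent's,
#' while it still grows adequately on complete medium (SC; at least
#' `sc_threshold` of the parent) — the SC criterion separates auxotrophy
#' from general sickness.
#'
#' @param od_sm,od_parent_sm Strain and parent OD in minimal medium.
#' @param od_sc,od_parent_sc Strain and parent OD in complete medium.
#' @param threshold SM growth fraction boundary (strict `<`). Default 0.2.
#' @param sc_threshold Minimum SC growth fraction. Default 0.5.
#' @return Character vector, `"auxotroph"` or `"leaky_or_prototroph"`.
#' @export
classify_auxotroph <- function(od_sm, od_parent_sm, od_sc, od_parent_sc,
                               threshold = 0.2, sc_threshold = 0.5) {
  if (any(od_parent_sm <= 0) || any(od_parent_sc <= 0)) {
    stop("parent OD values must be positive")
  }
  aux <- (od_sm < threshold * od_parent_sm) & (od_sc >= sc_threshold * od_parent_sc)
  ifelse(aux, "auxotroph", "leaky_or_prototroph")
}

#' Flag outlying replicates by the median-absolute-deviation rule
#'
#' A replicate is flagged when it deviates from the replicate median by more
#' than `k * scale * MAD`, with `MAD` the raw median absolute deviation and
#' `scale` the normal-consistency factor 1.4826. When the MAD is exactly
#' zero (robotic replicates identical to instrument precision) the rule
#' degenerates, and any value more than `blank_margin` from the median is
#' flagged instead.
#'
#' @param x Numeric replicate values (at least 3; fewer returns all
#'   unflagged with a warning).
#' @param k MAD multiplier. Default 3.
#' @param scale MAD consistency factor. Default 1.4826.
#' @param blank_margin Fallback absolute margin when MAD = 0. Default 0.05.
#' @return Logical vector parallel to `x`.
#' @export
mad_spread_flags <- function(x, k = 3, scale = 1.4826, blank_margin = 0.05) {
  if (length(x) < 3L) {
    warning("fewer than 3 replicates; spread flags not assessed")
    return(rep(FALSE, length(x)))
  }
  med <- stats::median(x)
  dev <- abs(x - med)
  mad_raw <- stats::median(dev)
  if (mad_raw == 0) dev > blank_margin else dev > k * scale * mad_raw
}

.neighbour_wells <- function(row, col, format) {
  dims <- plate_dims(format)
  dr <- rep(-1:1, times = 3)
  dc <- rep(-1:1, each = 3)
  keep <- !(dr == 0 & dc == 0)
  r <- row + dr[keep]
  cl <- col + dc[keep]
  ok <- r >= 0 & r < dims[1] & cl >= 0 & cl < dims[2]
  well_label(r[ok], cl[ok], format)
}

#' Detect contamination in wells expected not to grow
#'
#' Flags (a) blank wells whose blank-corrected growth exceeds
#' `blank_margin`, and (b) monoculture wells of strict auxotrophs that grow
#' past the margin while their condition median does not (a single
#' contaminated replicate, not a leaky strain). Wells in the 8-connected
#' neighborhood of a flagged well inherit a soft `warning`-severity flag,
#' since cross-well contamination spreads locally under seal handling.
#'
#' @param growth Blank-corrected table from [blank_correct()].
#' @param blank_margin Growth margin in OD units. Default 0.05.
#' @param strict_strains Optional character vector of strain ids known (from
#'   independent classification, e.g. the library preselection) to be strict
#'   auxotrophs; any of their monoculture wells growing past the margin is
#'   flagged directly. When `NULL`, strictness is inferred: only monoculture
#'   conditions whose median growth is within the margin are treated as
#'   non-growing, which protects leaky strains from false flags but can miss
#'   contamination that hits several replicates of one condition.
#' @return QC flag table (`plate_id`, `well`, `condition_id`, `flag_kind`,
#'   `severity`, `detail`); possibly empty.
#' @export
detect_contamination <- function(growth, blank_margin = 0.05,
                                 strict_strains = NULL) {
  flags <- list()
  blank_hit <- growth$kind == "blank" & growth$growth > blank_margin
  if (any(blank_hit, na.rm = TRUE)) {
    b <- growth[which(blank_hit), ]
    flags[[length(flags) + 1L]] <- .qc_flag(
      b$plate_id, b$well, b$condition_id, "contamination", "flag",
      sprintf("blank well growth %.3f exceeds margin %.3f", b$growth, blank_margin))
  }
  mono <- growth$kind == "monoculture"
  if (!is.null(strict_strains)) {
    # strictness known independently: growth in these wells IS contamination
    mono_hit <- mono & growth$strain_1 %in% strict_strains &
      growth$growth > blank_margin
  } else if (any(mono, na.rm = TRUE)) {
    med <- tapply(growth$growth[mono], growth$condition_id[mono],
                  stats::median, na.rm = TRUE)
    cond_ok <- names(med)[med <= blank_margin]
    mono_hit <- mono & growth$condition_id %in% cond_ok &
      growth$growth > blank_margin
  } else mono_hit <- FALSE
  if (any(mono_hit, na.rm = TRUE)) {
    m <- growth[which(mono_hit), ]
    flags[[length(flags) + 1L]] <- .qc_flag(
      m$plate_id, m$well, m$condition_id, "contamination", "flag",
      sprintf("non-growing monoculture replicate at growth %.3f", m$growth))
  }
  hard <- if (length(flags)) do.call(rbind, flags) else .empty_flags()
  if (nrow(hard)) {
    fmt <- if (max(growth$row, growth$col) >= 12L) 384L else 96L
    neigh <- lapply(seq_len(nrow(hard)), function(i) {
      src <- growth[growth$plate_id == hard$plate_id[i] &
                      growth$well == hard$well[i], ][1, ]
      nb <- .neighbour_wells(src$row, src$col, fmt)
      tgt <- growth[growth$plate_id == hard$plate_id[i] &
                      growth$well %in% nb, ]
      if (!nrow(tgt)) return(NULL)
      .qc_flag(tgt$plate_id, tgt$well, tgt$condition_id, "contamination",
               "warning", paste0("adjacent to contaminated well ", hard$well[i]))
    })
    neigh <- do.call(rbind, neigh[!vapply(neigh, is.null, TRUE)])
    if (!is.null(neigh) && nrow(neigh)) {
      key <- paste(neigh$plate_id, neigh$well)
      neigh <- neigh[!duplicated(key) &
                       !(key %in% paste(hard$plate_id, hard$well)), ]
      hard <- rbind(hard, neigh)
    }
  }
  rownames(hard) <- NULL
  hard
}

# Alternating row/column median sweep; mirrors stats::medpolish output shape.
.median_polish <- function(mat, maxiter = 100L, eps = 1e-8) {
  fit <- stats::medpolish(mat, eps = eps, maxiter = maxiter,
                          na.rm = TRUE, trace.iter = FALSE)
  fit
}

#' Flag plate positional bias (edge effects and row/column trends)
#'
#' Two per-plate tests on blank-corrected growth of non-blank wells, either
#' of which flags. (a) Edge effect: if the median growth of perimeter wells
#' differs from the interior median by more than `edge_bias_k` scaled MADs
#' of the interior, every assay well on that plate's edge is flagged (the
#' screen attributed such bias to sealing-film handling). (b) Row/column
#' trend: additive row+column effects are fit by median polish; wells whose
#' fitted positional effect exceeds `edge_bias_k` scaled MADs of the
#' residuals are flagged. Plates offering no contrast (fewer than two
#' conditions among assay wells) are skipped with a warning.
#'
#' @param growth Blank-corrected table from [blank_correct()].
#' @param edge_bias_k Threshold multiplier. Default 3.
#' @param mad_scale MAD consistency factor. Default 1.4826.
#' @return QC flag table with `flag_kind = "positional_bias"`.
#' @export
positional_bias_flags <- function(growth, edge_bias_k = 3, mad_scale = 1.4826) {
  flags <- list()
  fmt <- if (max(growth$row, growth$col) >= 12L) 384L else 96L
  for (pl in unique(growth$plate_id)) {
    p <- growth[growth$plate_id == pl & growth$kind != "blank", ]
    if (nrow(p) == 0L) next
    if (length(unique(p$condition_id)) < 2L) {
      warning("plate ", pl, " offers no condition contrast; positional bias not assessed")
      next
    }
    edge <- is_edge(p$row, p$col, fmt)
    if (any(edge) && any(!edge)) {
      interior <- p$growth[!edge]
      spread <- mad_scale * stats::median(abs(interior - stats::median(interior, na.rm = TRUE)),
                                          na.rm = TRUE)
      gap <- abs(stats::median(p$growth[edge], na.rm = TRUE) -
                   stats::median(interior, na.rm = TRUE))
      if (is.finite(gap) && gap > edge_bias_k * spread) {
        e <- p[edge, ]
        flags[[length(flags) + 1L]] <- .qc_flag(
          e$plate_id, e$well, e$condition_id, "positional_bias", "flag",
          sprintf("edge-vs-interior median gap %.3f exceeds %.3f", gap,
                  edge_bias_k * spread))
      }
    }
    dims <- plate_dims(fmt)
    mat <- matrix(NA_real_, dims[1], dims[2])
    mat[cbind(p$row + 1L, p$col + 1L)] <- p$growth
    fit <- .median_polish(mat)
    eff <- outer(fit$row, fit$col, `+`)
    res_spread <- mad_scale * stats::median(abs(fit$residuals), na.rm = TRUE)
    thr <- edge_bias_k * res_spread
    hit <- which(abs(eff[cbind(p$row + 1L, p$col + 1L)]) > thr)
    if (length(hit)) {
      h <- p[hit, ]
      flags[[length(flags) + 1L]] <- .qc_flag(
        h$plate_id, h$well, h$condition_id, "positional_bias", "flag",
        sprintf("row+column effect %.3f exceeds %.3f",
                eff[cbind(h$row + 1L, h$col + 1L)], thr))
    }
  }
  out <- if (length(flags)) do.call(rbind, flags) else .empty_flags()
  key <- paste(out$plate_id, out$well)
  out <- out[!duplicated(key), ]
  rownames(out) <- NULL
  out
}

#' Z-factor screening-window statistic
#'
#' `Z = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|` with sample
#' standard deviations; at most 1, and symmetric in the two groups. Equal
#' means return `-Inf` with a `degenerate` attribute (no assay window at
#' all).
#'
#' @param pos,neg Numeric vectors (each at least 2 values); by convention
#'   the positive group is the coculture and the negative group the fittest
#'   constituent monoculture.
#' @return Numeric Z; `attr(., "degenerate")` is `TRUE` when means coincide.
#' @export
z_factor <- function(pos, neg) {
  if (length(pos) < 2L || length(neg) < 2L) {
    stop("z_factor needs at least 2 values per group")
  }
  mu_p <- mean(pos); mu_n <- mean(neg)
  if (mu_p == mu_n) {
    z <- -Inf
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  z <- 1 - 3 * (stats::sd(pos) + stats::sd(neg)) / abs(mu_p - mu_n)
  attr(z, "degenerate") <- FALSE
  z
}

#' Activity-range gate for one pair assay
#'
#' Drops an assay when the Z-factor between the coculture replicates and the
#' fittest-monoculture replicates falls below `z_threshold`: a high-growing
#' (leaky) monoculture erases the window within which synergy could be
#' detected. Missing monoculture data or fewer than two replicates also
#' drop, with distinct reasons.
#'
#' @param co Coculture replicate growth values.
#' @param mono Fittest-monoculture replicate growth values (or `NULL`).
#' @param z_threshold Minimum acceptable Z-factor. Default 0.5.
#' @return list with `keep` (logical), `z` (numeric or NA), `reason`.
#' @export
activity_range_filter <- function(co, mono, z_threshold = 0.5) {
  if (is.null(mono) || !length(mono)) {
    return(list(keep = FALSE, z = NA_real_, reason = "missing monoculture data"))
  }
  if (length(co) < 2L || length(mono) < 2L) {
    return(list(keep = FALSE, z = NA_real_, reason = "insufficient replicates"))
  }
  z <- z_factor(co, mono)
  if (z < z_threshold) {
    return(list(keep = FALSE, z = as.numeric(z), reason = "activity_range"))
  }
  list(keep = TRUE, z = as.numeric(z), reason = "")
}

#' Per-condition replicate summaries
#'
#' @param growth Blank-corrected table from [blank_correct()].
#' @param mad_scale MAD consistency factor applied to the reported MAD.
#' @return data.frame: `condition_id`, `kind`, `strain_1`, `strain_2`, `n`,
#'   `mean_od`, `sd_od`, `median_od`, `mad_od` (scaled).
#' @export
summarize_conditions <- function(growth, mad_scale = 1.4826) {
  sp <- split(growth, growth$condition_id)
  out <- do.call(rbind, lapply(sp, function(g) {
    x <- g$growth[!is.na(g$growth)]
    data.frame(
      condition_id = g$condition_id[1], kind = g$kind[1],
      strain_1 = g$strain_1[1], strain_2 = g$strain_2[1],
      n = length(x),
      mean_od = mean(x),
      sd_od = if (length(x) > 1L) stats::sd(x) else NA_real_,
      median_od = stats::median(x),
      mad_od = mad_scale * stats::median(abs(x - stats::median(x))),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
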