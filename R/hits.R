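# Hit calling: fold difference of the coculture against its fittest
# constituent monoculture, two-sided Welch's t-test, Benjamini-Hochberg
# correction across all QC-passed cocultures, and the threshold rule
# (adjusted p < alpha AND fold difference >= fc_threshold).

#' Pick the fittest constituent monoculture
#'
#' The monoculture with the larger mean blank-corrected growth; an exact tie
#' is broken deterministically toward the lexicographically smaller
#' condition id.
#'
#' @param mono_a,mono_b Lists/rows with fields `condition_id` and `mean_od`.
#' @return `condition_id` of the fitter monoculture.
#' @export
fittest_monoculture <- function(mono_a, mono_b) {
  if (is.null(mono_a) || is.null(mono_b) ||
      is.na(mono_a$mean_od) || is.na(mono_b$mean_od)) {
    stop("both monoculture summaries are required")
  }
  if (mono_a$mean_od > mono_b$mean_od) return(mono_a$condition_id)
  if (mono_b$mean_od > mono_a$mean_od) return(mono_b$condition_id)
  min(mono_a$condition_id, mono_b$condition_id)
}

#' Fold difference of coculture growth over the fittest monoculture
#'
#' `mean_co / max(mean_fittest, fd_floor)`. The floor keeps the ratio
#' finite when the fittest monoculture does not grow (the interesting
#' case); floored denominators and nonpositive coculture means are flagged.
#'
#' @param mean_co Coculture mean blank-corrected growth.
#' @param mean_fittest Fittest-monoculture mean growth.
#' @param fd_floor Denominator floor. Default 1e-3.
#' @return list with `fc` (> 0), `floored`, `nonpositive_co`.
#' @export
fold_difference <- function(mean_co, mean_fittest, fd_floor = 1e-3) {
  denom <- max(mean_fittest, fd_floor)
  if (is.na(mean_co) || mean_co <= 0) {
    return(list(fc = fd_floor / denom, floored = TRUE, nonpositive_co = TRUE))
  }
  list(fc = mean_co / denom, floored = mean_fittest < fd_floor,
       nonpositive_co = FALSE)
}

#' Two-sided Welch's t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom. When both groups have zero variance the test degenerates:
#' differing means give `t = +/-Inf`, `p = 0`; equal means give `t = 0`,
#' `p = 1` (robotic replicates can be identical to instrument precision).
#'
#' @param group1,group2 Numeric vectors, each with at least 2 finite values.
#' @return list with `t`, `df`, `p` and logical `degenerate`.
#' @export
welch_test <- function(group1, group2) {
  if (length(group1) < 2L || length(group2) < 2L ||
      !all(is.finite(group1)) || !all(is.finite(group2))) {
    stop("welch_test needs two groups of at least 2 finite values")
  }
  v1 <- stats::var(group1); v2 <- stats::var(group2)
  if (v1 == 0 && v2 == 0) {
    d <- mean(group1) - mean(group2)
    if (d == 0) return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    return(list(t = sign(d) * Inf, df = NA_real_, p = 0, degenerate = TRUE))
  }
  fit <- stats::t.test(group1, group2, var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment across the family, returned in input order,
#' capped at 1; the family for the screen is all QC-passed cocultures in
#' one run.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Assemble pair assays from a blank-corrected growth table
#'
#' For every coculture condition, collects its replicate growth values and
#' those of its two constituent monocultures, identifies the fittest
#' monoculture, computes the Z-factor window, the fold difference and the
#' Welch statistics (coculture vs fittest monoculture). Assays failing the
#' activity-range gate (or lacking monoculture data / replicates) are
#' marked dropped with a reason; they keep their statistics where
#' computable.
#'
#' @param growth Blank-corrected table from [blank_correct()], optionally
#'   pre-filtered of flagged wells.
#' @param conditions Condition table.
#' @param config A [screen_config()].
#' @param apply_activity_filter Apply the Z-factor activity-range gate.
#'   Default `TRUE`.
#' @return data.frame with one row per coculture condition.
#' @export
pair_assays <- function(growth, conditions, config = screen_config(),
                        apply_activity_filter = TRUE) {
  conditions <- .validate_conditions(conditions)
  reps <- split(growth$growth, growth$condition_id)
  mono <- conditions[conditions$kind == "monoculture", ]
  mono_by_strain <- stats::setNames(mono$condition_id, mono$strain_1)
  cocs <- conditions[conditions$kind == "coculture", ]
  cocs <- cocs[cocs$condition_id %in% names(reps), ]
  if (nrow(cocs) == 0L) stop("no coculture conditions with observations")

  rows <- lapply(seq_len(nrow(cocs)), function(i) {
    cc <- cocs[i, ]
    co_x <- reps[[cc$condition_id]]
    co_x <- co_x[!is.na(co_x)]
    get_mono <- function(s) {
      id <- mono_by_strain[[s]]
      if (is.null(id) || !id %in% names(reps)) return(NULL)
      x <- reps[[id]]
      list(condition_id = id, x = x[!is.na(x)], mean_od = mean(x, na.rm = TRUE))
    }
    ma <- get_mono(cc$strain_1)
    mb <- get_mono(cc$strain_2)

    out <- data.frame(
      coculture_id = cc$condition_id, strain_1 = cc$strain_1,
      strain_2 = cc$strain_2,
      mono_1_id = if (is.null(ma)) NA_character_ else ma$condition_id,
      mono_2_id = if (is.null(mb)) NA_character_ else mb$condition_id,
      fittest_mono_id = NA_character_,
      n_co = length(co_x), mean_co = mean(co_x), sd_co = stats::sd(co_x),
      n_fittest = NA_integer_, mean_fittest = NA_real_, sd_fittest = NA_real_,
      z = NA_real_, fold_difference = NA_real_, fd_floored = FALSE,
      t_stat = NA_real_, df = NA_real_, p_raw = NA_real_, degenerate = FALSE,
      dropped = FALSE, drop_reason = "", stringsAsFactors = FALSE
    )
    if (is.null(ma) || is.null(mb) || !length(ma$x) || !length(mb$x)) {
      out$dropped <- TRUE
      out$drop_reason <- "missing monoculture data"
      return(out)
    }
    fid <- fittest_monoculture(ma, mb)
    fit <- if (identical(fid, ma$condition_id)) ma else mb
    out$fittest_mono_id <- fid
    out$n_fittest <- length(fit$x)
    out$mean_fittest <- mean(fit$x)
    out$sd_fittest <- stats::sd(fit$x)

    fd <- fold_difference(out$mean_co, out$mean_fittest, config$fd_floor)
    out$fold_difference <- fd$fc
    out$fd_floored <- fd$floored || fd$nonpositive_co

    gate <- activity_range_filter(co_x, fit$x, config$z_threshold)
    out$z <- gate$z
    if (apply_activity_filter && !gate$keep) {
      out$dropped <- TRUE
      out$drop_reason <- gate$reason
    }
    if (length(co_x) >= 2L && length(fit$x) >= 2L) {
      w <- welch_test(co_x, fit$x)
      out$t_stat <- w$t; out$df <- w$df; out$p_raw <- w$p
      out$degenerate <- w$degenerate
    } else if (!out$dropped) {
      out$dropped <- TRUE
      out$drop_reason <- "insufficient replicates"
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call hits among pair assays
#'
#' Applies Benjamini-Hochberg correction jointly across all non-dropped
#' assays and calls: `hit` when `p_adj < alpha` and
#' `fold_difference >= fc_threshold`; `near_hit` (a reporting tier, never
#' counted as a hit) when the fold gate passes but
#' `alpha <= p_adj < 2 alpha`; otherwise `no_growth_advantage`. Dropped
#' assays keep the call `dropped`.
#'
#' @param assays Output of [pair_assays()].
#' @param config A [screen_config()].
#' @return `assays` with columns `p_adj` and `call` added.
#' @export
call_hits <- function(assays, config = screen_config()) {
  if (!nrow(assays)) stop("empty assay list")
  fam <- !assays$dropped & !is.na(assays$p_raw)
  assays$p_adj <- NA_real_
  if (any(fam)) assays$p_adj[fam] <- bh_adjust(assays$p_raw[fam])
  call <- rep("no_growth_advantage", nrow(assays))
  call[assays$dropped] <- "dropped"
  fc_ok <- !is.na(assays$fold_difference) &
    assays$fold_difference >= config$fc_threshold
  hit <- fam & fc_ok & assays$p_adj < config$alpha
  near <- fam & fc_ok & !hit & assays$p_adj < 2 * config$alpha
  call[near] <- "near_hit"
  call[hit] <- "hit"
  assays$call <- call
  assays
}

#' Summarize a hit table
#'
#' @param hit_table Output of [call_hits()].
#' @param strains Optional strain table mapping `strain_id` to
#'   `deleted_gene`; without it, unique strains stand in for unique genes.
#' @return list: `n_cocultures` (non-dropped), `n_dropped`, `n_hits`,
#'   `n_not_called`, `n_unique_genes` (distinct deleted genes among hit
#'   constituents).
#' @export
hit_summary <- function(hit_table, strains = NULL) {
  hits <- hit_table[hit_table$call == "hit", ]
  members <- unique(c(hits$strain_1, hits$strain_2))
  genes <- if (!is.null(strains)) {
    unique(strains$deleted_gene[match(members, strains$strain_id)])
  } else members
  tested <- sum(!hit_table$dropped)
  list(
    n_cocultures = tested,
    n_dropped = sum(hit_table$dropped),
    n_hits = nrow(hits),
    n_not_called = tested - nrow(hits),
    n_unique_genes = length(genes[!is.na(genes) & nzchar(genes)])
  )
}

#' Volcano-plot-ready export
#'
#' `log2` fold difference against the natural log of the adjusted p-value
#' (raw p is exported too, since either may be plotted); adjusted p below
#' 1e-300 is clamped before the log with a flag.
#'
#' @param assays Output of [call_hits()].
#' @return data.frame: `coculture_id`, `log2_fc`, `ln_p_adj`, `ln_p_raw`,
#'   `clamped`, `call`.
#' @export
volcano_table <- function(assays) {
  clamp <- function(p) pmax(p, 1e-300)
  data.frame(
    coculture_id = assays$coculture_id,
    log2_fc = log2(assays$fold_difference),
    ln_p_adj = log(clamp(assays$p_adj)),
    ln_p_raw = log(clamp(assays$p_raw)),
    clamped = !is.na(assays$p_adj) & assays$p_adj < 1e-300,
    call = assays$call,
    stringsAsFactors = FALSE
  )
}
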