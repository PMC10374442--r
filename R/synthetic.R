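# Synthetic screen and coculture-dynamics generators with planted ground
# truth, so every pipeline stage is testable without external data. The
# screen generator emulates the robotic workflow's endpoints: OD600 at 0 h
# and 48 h for blanks, monocultures (strict or leaky auxotrophs) and
# pairwise cocultures inoculated at 0.1 OD600 equivalents.

# Run code under a fixed RNG state without disturbing the caller's stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Parameters for the synthetic growth-complementation screen
#'
#' The defaults are the study conditions the generator emulates: 4
#' replicates per condition at a 0.1 OD600 inoculum in 384-well plates,
#' multiplicative lognormal measurement noise (sdlog 0.05) plus a small
#' additive read noise, about 27% leaky auxotrophs in the library,
#' sporadic contamination, and no positional bias unless planted.
#'
#' @param n_strains Number of auxotroph strains; all pairwise cocultures
#'   are generated.
#' @param replicates Replicates per condition. Default 4.
#' @param leaky_fraction Fraction of strains that grow detectably by 48 h
#'   despite failing the 18-h auxotrophy cut. Default 0.27.
#' @param leak_range Uniform range of leakiness (fraction of carrying OD
#'   reached by a leaky monoculture). Default `c(0.1, 0.6)`.
#' @param leakiness Optional explicit per-strain leakiness vector in
#'   `[0, 1]`, overriding the two parameters above.
#' @param planted_pairs Optional data.frame (`strain_a`, `strain_b`,
#'   `effect` in `(0, 1]`) of planted syntrophic pairs; the coculture grows
#'   to `inoculum + effect * K` regardless of leakiness.
#' @param K Carrying OD. Default 1.
#' @param noise_sd sdlog of the multiplicative lognormal reading noise.
#'   Default 0.05.
#' @param additive_sd sd of the additive OD read noise (lets blanks show
#'   noise). Default 0.002.
#' @param contamination_prob Per-well contamination probability. Default
#'   0.005.
#' @param contamination_range Uniform range of the OD boost a contaminated
#'   well receives at 48 h. Default `c(0.2, 0.8)`.
#' @param contamination_targets `"all"` wells, or `"nongrowing"` (blanks
#'   and strict-auxotroph monocultures only, where contamination is
#'   detectable as unexpected growth).
#' @param bias_plates Integer indices of plates that receive a positional
#'   bias field.
#' @param edge_offset,row_slope,col_slope Bias field added to the 48-h
#'   reading of biased plates: `edge_offset` on perimeter wells plus
#'   `row_slope`/`col_slope` times the centered row/column index.
#' @param plate_format 96 or 384. Default 384.
#' @param blanks_per_plate Blank wells per plate. Default 8.
#' @param inoculum_od Inoculum per non-blank well. Default 0.1.
#' @param seed Integer seed; a fixed seed reproduces the dataset exactly.
#' @return list of class `screen_sim_params`.
#' @export
screen_sim_params <- function(n_strains = 24L, replicates = 4L,
                              leaky_fraction = 0.27, leak_range = c(0.1, 0.6),
                              leakiness = NULL, planted_pairs = NULL,
                              K = 1, noise_sd = 0.05, additive_sd = 0.002,
                              contamination_prob = 0.005,
                              contamination_range = c(0.2, 0.8),
                              contamination_targets = c("all", "nongrowing"),
                              bias_plates = integer(0), edge_offset = 0,
                              row_slope = 0, col_slope = 0,
                              plate_format = 384L, blanks_per_plate = 8L,
                              inoculum_od = 0.1, seed = 1L) {
  contamination_targets <- match.arg(contamination_targets)
  if (K <= 0) stop("carrying OD K must be positive")
  if (contamination_prob < 0 || contamination_prob > 1) {
    stop("contamination_prob must lie in [0, 1]")
  }
  if (!is.null(leakiness)) {
    if (length(leakiness) != n_strains || any(leakiness < 0 | leakiness > 1)) {
      stop("leakiness must have one value in [0, 1] per strain")
    }
  }
  structure(as.list(environment()), class = "screen_sim_params")
}

#' Simulate a growth-complementation screen with known ground truth
#'
#' Generates 0-h and 48-h OD600 readings for blanks, all monocultures and
#' all pairwise cocultures under the null model "coculture growth equals
#' that of the leakier constituent" (a leaky partner alone explains
#' coculture growth), with planted syntrophic pairs overriding the null.
#' Readings carry multiplicative lognormal noise and additive read noise;
#' biased plates receive an additive positional field at 48 h, and
#' contaminated wells a uniform OD boost. Output flows through the real
#' pipeline unchanged.
#'
#' @param params A [screen_sim_params()].
#' @return list: `tidy` (long observation table at both timepoints),
#'   `conditions`, `strains`, and `truth` (`planted_pairs` with coculture
#'   ids, `contaminated` wells, `biased_plates`, `leakiness` map).
#' @export
simulate_screen <- function(params = screen_sim_params()) {
  stopifnot(inherits(params, "screen_sim_params"))
  .with_seed(params$seed, {
    p <- params
    dims <- plate_dims(p$plate_format)
    wells_per_plate <- dims[1] * dims[2]
    strain_ids <- sprintf("S%03d", seq_len(p$n_strains))
    leak <- p$leakiness
    if (is.null(leak)) {
      leaky <- stats::runif(p$n_strains) < p$leaky_fraction
      leak <- ifelse(leaky,
                     stats::runif(p$n_strains, p$leak_range[1], p$leak_range[2]),
                     0)
    }
    names(leak) <- strain_ids

    strains <- data.frame(
      strain_id = strain_ids,
      deleted_gene = sprintf("GENE%03d", seq_len(p$n_strains)),
      is_reference = FALSE, fluorophore = "none",
      stringsAsFactors = FALSE
    )
    pairs <- t(utils::combn(strain_ids, 2L))
    coc_ids <- paste0("co_", pairs[, 1], "_", pairs[, 2])
    conditions <- rbind(
      data.frame(condition_id = "blank", kind = "blank",
                 strain_1 = "", strain_2 = "", ratio_1 = NA_real_,
                 ratio_2 = NA_real_, media = "SM", stringsAsFactors = FALSE),
      data.frame(condition_id = paste0("mono_", strain_ids),
                 kind = "monoculture", strain_1 = strain_ids, strain_2 = "",
                 ratio_1 = NA_real_, ratio_2 = NA_real_, media = "SM",
                 stringsAsFactors = FALSE),
      data.frame(condition_id = coc_ids, kind = "coculture",
                 strain_1 = pairs[, 1], strain_2 = pairs[, 2],
                 ratio_1 = 1, ratio_2 = 1, media = "SM",
                 stringsAsFactors = FALSE)
    )

    # planted syntrophy overrides the max-leak null
    co_true48 <- p$inoculum_od + pmax(leak[pairs[, 1]], leak[pairs[, 2]]) * p$K
    planted <- p$planted_pairs
    if (!is.null(planted) && nrow(planted)) {
      unknown <- setdiff(c(planted$strain_a, planted$strain_b), strain_ids)
      if (length(unknown)) {
        stop("planted pair references unknown strain(s): ",
             paste(unknown, collapse = ", "))
      }
      key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
      pkey <- paste(pmin(planted$strain_a, planted$strain_b),
                    pmax(planted$strain_a, planted$strain_b))
      idx <- match(pkey, key)
      co_true48[idx] <- p$inoculum_od + planted$effect * p$K
      planted$coculture_id <- coc_ids[idx]
    }

    assay_conditions <- c(paste0("mono_", strain_ids), coc_ids)
    true48 <- c(p$inoculum_od + leak * p$K, co_true48)
    names(true48) <- assay_conditions

    # condition-to-well assignment: replicates scattered at random across
    # plates; a fixed count of blanks per plate at random positions
    assignment <- sample(rep(assay_conditions, each = p$replicates))
    assays_per_plate <- wells_per_plate - p$blanks_per_plate
    n_plates <- ceiling(length(assignment) / assays_per_plate)

    rows_list <- vector("list", n_plates)
    taken <- 0L
    for (pl in seq_len(n_plates)) {
      n_here <- min(assays_per_plate, length(assignment) - taken)
      conds_here <- assignment[taken + seq_len(n_here)]
      taken <- taken + n_here
      blank_pos <- sample(wells_per_plate, p$blanks_per_plate)
      assay_pos <- setdiff(seq_len(wells_per_plate), blank_pos)[seq_len(n_here)]
      pos <- c(blank_pos, assay_pos)
      cond <- c(rep("blank", p$blanks_per_plate), conds_here)
      row <- (pos - 1L) %/% dims[2]
      col <- (pos - 1L) %% dims[2]
      rows_list[[pl]] <- data.frame(
        plate_id = sprintf("plate%02d", pl), batch = "sim",
        well = well_label(row, col, p$plate_format), row = row, col = col,
        condition_id = cond, stringsAsFactors = FALSE
      )
    }
    layout <- do.call(rbind, rows_list)
    cm <- match(layout$condition_id, conditions$condition_id)
    layout$kind <- conditions$kind[cm]
    layout$strain_1 <- conditions$strain_1[cm]
    layout$strain_2 <- conditions$strain_2[cm]

    n_wells <- nrow(layout)
    truth_true48 <- ifelse(layout$kind == "blank", 0,
                           true48[layout$condition_id])
    true0 <- ifelse(layout$kind == "blank", 0, p$inoculum_od)

    noisy <- function(true_vals) {
      pmax(true_vals * stats::rlnorm(n_wells, 0, p$noise_sd) +
             stats::rnorm(n_wells, 0, p$additive_sd), 0)
    }
    od0 <- noisy(true0)
    od48 <- noisy(truth_true48)

    plate_index <- as.integer(factor(layout$plate_id,
                                     levels = sprintf("plate%02d", seq_len(n_plates))))
    biased <- plate_index %in% p$bias_plates
    if (any(biased)) {
      edge <- is_edge(layout$row, layout$col, p$plate_format)
      field <- p$edge_offset * edge +
        p$row_slope * (layout$row - (dims[1] - 1) / 2) +
        p$col_slope * (layout$col - (dims[2] - 1) / 2)
      od48[biased] <- pmax(od48[biased] + field[biased], 0)
    }

    eligible <- if (p$contamination_targets == "all") rep(TRUE, n_wells) else {
      layout$kind == "blank" |
        (layout$kind == "monoculture" & leak[layout$strain_1] == 0)
    }
    contam <- eligible & stats::runif(n_wells) < p$contamination_prob
    if (any(contam)) {
      od48[contam] <- od48[contam] +
        stats::runif(sum(contam), p$contamination_range[1],
                     p$contamination_range[2])
    }

    tidy <- rbind(
      cbind(layout, time = 0, od600 = od0),
      cbind(layout, time = 48, od600 = od48)
    )
    rownames(tidy) <- NULL
    truth <- list(
      planted_pairs = planted,
      contaminated = layout[contam, c("plate_id", "well", "condition_id", "kind")],
      biased_plates = sprintf("plate%02d", p$bias_plates),
      leakiness = data.frame(strain_id = strain_ids, leakiness = unname(leak),
                             stringsAsFactors = FALSE)
    )
    list(tidy = tidy, conditions = conditions, strains = strains, truth = truth)
  })
}

#' Simulate two-species cross-feeding coculture dynamics
#'
#' Phenomenological obligate cross-feeding model integrated with
#' fixed-step fourth-order Runge-Kutta: each strain grows logistically at a
#' rate limited (Monod form) by the metabolite its partner exports,
#'
#' \deqn{dN_i/dt = r_i N_i \frac{E_j}{K_m + E_j} (1 - (N_1+N_2)/K)}
#' \deqn{dE_i/dt = \rho_i N_i - y \, dN_j/dt}
#'
#' Fluorescence channels are generated from the abundances via the given
#' calibration slopes with multiplicative noise. With both export rates at
#' zero neither strain grows (obligate dependence); fully symmetric
#' parameters at a 1:1 inoculum hold the blue proportion at 0.5.
#'
#' @param r1,r2 Maximum specific growth rates (per hour).
#' @param rho1,rho2 Metabolite export rates (metabolite OD-equivalents per
#'   biomass OD per hour).
#' @param K Carrying OD. Default 1.
#' @param Km Monod half-saturation of the cross-fed metabolite. Default
#'   0.01.
#' @param yield Metabolite consumed per unit partner biomass formed.
#'   Default 1.
#' @param n0 Length-2 inoculum ODs (blue-tagged strain first); the
#'   characterization series used total OD 0.10.
#' @param slopes 2x2 calibration slope matrix (channels x strains) used to
#'   synthesize fluorescence; diagonal 1000/800 by default.
#' @param backgrounds Per-channel background intensities. Default `c(0, 0)`.
#' @param channel_noise_sd sdlog of multiplicative channel noise. Default 0.
#' @param duration Hours simulated. Default 72.
#' @param step RK4 step in hours. Default 0.2.
#' @param seed Seed for the channel noise.
#' @return list: `times`, `N1`, `N2`, `E1`, `E2`, `proportion_true`,
#'   `F_blue`, `F_red`, and the calibration curves implied by
#'   `slopes`/`backgrounds` (as `curves`, ready for [unmix()]).
#' @export
simulate_coculture_dynamics <- function(r1 = 0.4, r2 = 0.4,
                                        rho1 = 0.05, rho2 = 0.05,
                                        K = 1, Km = 0.01, yield = 1,
                                        n0 = c(0.05, 0.05),
                                        slopes = matrix(c(1000, 0, 0, 800), 2, 2),
                                        backgrounds = c(0, 0),
                                        channel_noise_sd = 0,
                                        duration = 72, step = 0.2, seed = 1L) {
  if (step <= 0 || duration <= 0) stop("step and duration must be positive")
  if (any(c(r1, r2, rho1, rho2) < 0)) stop("rates must be nonnegative")
  times <- seq(0, duration, by = step)
  derivs <- function(t, y, parms) {
    N1 <- y[1]; N2 <- y[2]; E1 <- max(y[3], 0); E2 <- max(y[4], 0)
    cap <- 1 - (N1 + N2) / K
    g1 <- r1 * N1 * E2 / (Km + E2) * cap
    g2 <- r2 * N2 * E1 / (Km + E1) * cap
    list(c(g1, g2, rho1 * N1 - yield * g2, rho2 * N2 - yield * g1))
  }
  sol <- deSolve::ode(y = c(N1 = n0[1], N2 = n0[2], E1 = 0, E2 = 0),
                      times = times, func = derivs, parms = NULL,
                      method = "rk4")
  N1 <- sol[, "N1"]; N2 <- sol[, "N2"]
  Fclean <- slopes %*% rbind(N1, N2) + backgrounds
  noise <- .with_seed(seed, {
    matrix(stats::rlnorm(2L * length(times), 0, channel_noise_sd),
           2L, length(times))
  })
  if (channel_noise_sd == 0) noise[] <- 1
  Fnoisy <- Fclean * noise
  curves <- list(
    structure(list(strain_id = "blue_strain", channel = "blue",
                   slope = slopes[1, 1], background = backgrounds[1],
                   fit_r2 = 1, n_points = 9L), class = "calibration_curve"),
    structure(list(strain_id = "red_strain", channel = "red",
                   slope = slopes[2, 2], background = backgrounds[2],
                   fit_r2 = 1, n_points = 9L), class = "calibration_curve"),
    structure(list(strain_id = "red_strain", channel = "blue",
                   slope = slopes[1, 2], background = 0,
                   fit_r2 = 1, n_points = 9L), class = "calibration_curve"),
    structure(list(strain_id = "blue_strain", channel = "red",
                   slope = slopes[2, 1], background = 0,
                   fit_r2 = 1, n_points = 9L), class = "calibration_curve")
  )
  list(times = times, N1 = N1, N2 = N2,
       E1 = sol[, "E1"], E2 = sol[, "E2"],
       proportion_true = N1 / (N1 + N2),
       F_blue = Fnoisy[1, ], F_red = Fnoisy[2, ],
       curves = curves)
}

#' Serial passaging of the coculture dynamics model
#'
#' Runs [simulate_coculture_dynamics()] repeatedly; between passages the
#' community is diluted to a total OD of `passage_od` (preserving
#' composition, as a wash-and-dilute does) and the metabolite pools are
#' reset to zero (fresh medium).
#'
#' @param n_passages Number of passages. Default 2.
#' @param passage_od Total OD after dilution. Default 0.1.
#' @param duration Hours per passage. Default 48.
#' @param ... Passed to [simulate_coculture_dynamics()].
#' @return list of per-passage results.
#' @export
simulate_serial_passages <- function(n_passages = 2L, passage_od = 0.1,
                                     duration = 48, ...) {
  args <- list(...)
  base_seed <- if (is.null(args$seed)) 1L else args$seed
  args$seed <- NULL
  out <- vector("list", n_passages)
  for (i in seq_len(n_passages)) {
    res <- do.call(simulate_coculture_dynamics,
                   c(args, list(duration = duration, seed = base_seed + i)))
    out[[i]] <- res
    last <- length(res$times)
    total <- res$N1[last] + res$N2[last]
    args$n0 <- passage_od * c(res$N1[last], res$N2[last]) / total
  }
  out
}

#' Score hit calls against planted ground truth
#'
#' @param hit_table Output of [call_hits()] on a simulated screen.
#' @param truth `truth` element of [simulate_screen()].
#' @return list: `n_planted`, `n_hits`, `tp`, `precision` (NA with no
#'   calls), `recall` (over all planted pairs present in the table) and
#'   `recall_tested` (over planted pairs that passed QC).
#' @export
evaluate_calls <- function(hit_table, truth) {
  planted <- truth$planted_pairs
  planted_ids <- if (is.null(planted)) character() else planted$coculture_id
  if (length(planted_ids) &&
      !all(planted_ids %in% hit_table$coculture_id)) {
    stop("truth references cocultures absent from the hit table")
  }
  hits <- hit_table$coculture_id[hit_table$call == "hit"]
  tp <- sum(hits %in% planted_ids)
  tested_planted <- hit_table$coculture_id %in% planted_ids & !hit_table$dropped
  list(
    n_planted = length(planted_ids),
    n_hits = length(hits),
    tp = tp,
    precision = if (length(hits)) tp / length(hits) else NA_real_,
    recall = if (length(planted_ids)) tp / length(planted_ids) else NA_real_,
    recall_tested = if (any(tested_planted)) {
      sum(hits %in% hit_table$coculture_id[tested_planted]) / sum(tested_planted)
    } else NA_real_
  )
}

#' Score QC flags against planted artifacts
#'
#' @param flags QC flag table (hard flags, `severity == "flag"`, are
#'   scored; soft warnings are ignored).
#' @param truth `truth` element of [simulate_screen()].
#' @param growth Blank-corrected growth table of the same dataset (for the
#'   well universe when computing false-flag rates).
#' @return list with per-filter detection and false-flag rates:
#'   `contamination_missed`, `contamination_false_rate`, `bias_missed`
#'   (biased plates with no positional flag), `bias_false_plates`.
#' @export
evaluate_flags <- function(flags, truth, growth) {
  hard <- flags[flags$severity == "flag", ]
  ckey <- function(d) paste(d$plate_id, d$well)
  contam_flagged <- ckey(hard[hard$flag_kind == "contamination", ])
  contam_true <- if (nrow(truth$contaminated)) ckey(truth$contaminated) else character()
  bias_plates_flagged <- unique(hard$plate_id[hard$flag_kind == "positional_bias"])
  n_wells <- nrow(growth)
  list(
    contamination_missed = sum(!(contam_true %in% contam_flagged)),
    contamination_false_rate =
      sum(!(contam_flagged %in% contam_true)) / max(n_wells, 1L),
    bias_missed = sum(!(truth$biased_plates %in% bias_plates_flagged)),
    bias_false_plates = setdiff(bias_plates_flagged, truth$biased_plates)
  )
}
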