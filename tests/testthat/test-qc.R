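tidy_two_times <- function(wells, plate_id = "p1") {
  base <- data.frame(plate_id = plate_id, batch = "t",
                     well = well_label(wells$row, wells$col, 96),
                     row = wells$row, col = wells$col,
                     condition_id = wells$condition_id, kind = wells$kind,
                     strain_1 = "", strain_2 = "", stringsAsFactors = FALSE)
  rbind(cbind(base, time = 0, od600 = wells$od0),
        cbind(base, time = 48, od600 = wells$od48))
}

test_that("blank correction subtracts the plate blank median and floors at zero", {
  wells <- data.frame(row = 0L, col = 0:4,
                      condition_id = c("blank", "blank", "c1", "c1", "c2"),
                      kind = c("blank", "blank", rep("coculture", 3)),
                      od0 = c(0, 0, 0.1, 0.1, 0.1),
                      od48 = c(0.02, 0.02, 0.60, 0.15, 0.10))
  g <- blank_correct(tidy_two_times(wells))
  expect_equal(g$growth[g$well == "A3"], 0.60 - 0.1 - 0.02)
  expect_equal(g$growth[g$well == "A4"], 0.15 - 0.1 - 0.02)  # above blank
  expect_equal(g$growth[g$well == "A5"], 0)                  # floored (delta below blank)
  expect_true(all(g$blank_corrected))
  expect_equal(g$delta[g$well == "A3"], 0.5)  # raw retained

  no_blanks <- wells[wells$kind != "blank", ]
  expect_warning(g2 <- blank_correct(tidy_two_times(no_blanks)), "no blank")
  expect_equal(g2$growth[g2$well == "A3"], 0.5)
  expect_false(any(g2$blank_corrected))
})

test_that("auxotroph classification uses the strict 20% rule plus SC growth", {
  expect_equal(classify_auxotroph(0.19, 1, 1, 1), "auxotroph")
  expect_equal(classify_auxotroph(0.20, 1, 1, 1), "leaky_or_prototroph")  # boundary strict
  expect_equal(classify_auxotroph(0.05, 1, 0.3, 1), "leaky_or_prototroph")  # sick on SC too
  expect_error(classify_auxotroph(0.1, 0, 1, 1), "positive")
})

test_that("MAD spread rule flags the hand-computed outlier and handles degeneracy", {
  expect_equal(mad_spread_flags(c(1, 1, 1, 1)), rep(FALSE, 4))
  # median 1.05, raw MAD 0.10, threshold 3 * 1.4826 * 0.10 = 0.445
  expect_equal(mad_spread_flags(c(0.9, 1.0, 1.1, 5.0)),
               c(FALSE, FALSE, FALSE, TRUE))
  # MAD = 0 falls back to the absolute margin
  expect_equal(mad_spread_flags(c(1, 1, 1, 2), blank_margin = 0.05),
               c(FALSE, FALSE, FALSE, TRUE))
  expect_warning(f <- mad_spread_flags(c(1, 2)), "fewer than 3")
  expect_equal(f, c(FALSE, FALSE))
})

test_that("MAD spread flags are invariant under permutation and positive affine maps", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(6)
    f <- mad_spread_flags(x)
    perm <- sample(6)
    expect_equal(mad_spread_flags(x[perm]), f[perm])
    a <- runif(1, 0.5, 3); b <- rnorm(1)
    expect_equal(mad_spread_flags(a * x + b), f)
  }
})

test_that("contamination detection flags growing blanks and odd monoculture replicates", {
  wells <- data.frame(
    row = c(0, 0, 2, 2, 2, 2, 3),
    col = c(0, 5, 0, 2, 4, 6, 4),
    condition_id = c("blank", "blank", rep("m_a", 4), "blank"),
    kind = c("blank", "blank", rep("monoculture", 4), "blank"),
    growth = c(0.03, 0.40, 0.01, 0.02, 0.30, 0.00, 0.02))
  wells$strain_1 <- ifelse(wells$kind == "monoculture", "a", "")
  g <- make_growth(wells, format = 96)
  flags <- detect_contamination(g, blank_margin = 0.05)
  hard <- flags[flags$severity == "flag", ]
  expect_setequal(hard$well, c("A6", "C5"))  # the 0.40 blank, the 0.30 mono rep
  # the D5 blank sits in C5's 8-connected neighborhood -> soft warning
  warn <- flags[flags$severity == "warning", ]
  expect_true("D5" %in% warn$well)

  clean <- g; clean$growth <- pmin(clean$growth, 0.03)
  expect_equal(nrow(detect_contamination(clean)[
    detect_contamination(clean)$severity == "flag", ]), 0L)
})

test_that("growing-strain monocultures are not mistaken for contamination", {
  wells <- data.frame(row = 1L, col = 0:3, condition_id = "m_leaky",
                      kind = "monoculture",
                      growth = c(0.42, 0.45, 0.40, 0.43))
  wells$strain_1 <- "leaky"
  flags <- detect_contamination(make_growth(wells, format = 96))
  expect_equal(nrow(flags), 0L)
})

test_that("known-strict strains are flagged directly, bypassing the median guard", {
  # contamination in 2 of 4 replicates drags the condition median above the
  # margin, which the inference path cannot see through
  wells <- data.frame(row = 1L, col = c(0L, 2L, 4L, 6L), condition_id = "m_s",
                      kind = "monoculture",
                      growth = c(0.00, 0.55, 0.01, 0.60))
  wells$strain_1 <- "s"
  g <- make_growth(wells, format = 96)
  inferred <- detect_contamination(g)
  expect_equal(nrow(inferred[inferred$severity == "flag", ]), 0L)
  known <- detect_contamination(g, strict_strains = "s")
  expect_setequal(known$well[known$severity == "flag"], c("B3", "B7"))
})

test_that("z_factor matches direct arithmetic and its degenerate rule", {
  pos <- c(1.0, 1.1, 0.9); neg <- c(0.1, 0.2, 0.3)
  z <- z_factor(pos, neg)
  expect_equal(as.numeric(z),
               1 - 3 * (sd(pos) + sd(neg)) / abs(mean(pos) - mean(neg)))
  # ideal separation
  expect_equal(as.numeric(z_factor(c(1, 1), c(0.2, 0.2))), 1)
  zd <- z_factor(c(0.5, 0.7), c(0.7, 0.5))
  expect_identical(as.numeric(zd), -Inf)
  expect_true(attr(zd, "degenerate"))
  expect_error(z_factor(1, c(1, 2)), "at least 2")
})

test_that("z_factor is symmetric and invariant under shared positive affine maps", {
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(4, mean = 1); b <- rnorm(4)
    expect_equal(as.numeric(z_factor(a, b)), as.numeric(z_factor(b, a)))
    s <- runif(1, 0.1, 5); t <- rnorm(1)
    expect_equal(as.numeric(z_factor(s * a + t, s * b + t)),
                 as.numeric(z_factor(a, b)))
    expect_lte(as.numeric(z_factor(a, b)), 1)
  }
})

test_that("activity-range gate keeps wide windows and drops degenerate ones", {
  co <- c(0.75, 0.80, 0.85); mono <- c(0.05, 0.10, 0.15)
  # Z = 1 - 3(0.05 + 0.05)/0.7 = 0.571...
  res <- activity_range_filter(co, mono, z_threshold = 0.5)
  expect_true(res$keep)
  expect_equal(res$z, 1 - 3 * (sd(co) + sd(mono)) / 0.7)

  leaky <- activity_range_filter(co, co)  # equal means -> Z = -Inf
  expect_false(leaky$keep)
  expect_equal(leaky$reason, "activity_range")
  expect_equal(activity_range_filter(0.8, mono)$reason, "insufficient replicates")
  expect_equal(activity_range_filter(co, NULL)$reason, "missing monoculture data")
})

test_that("edge bias is flagged and spatially uniform plates rarely are", {
  dims <- plate_dims(384)
  rows <- rep(seq_len(dims[1]) - 1L, each = dims[2])
  cols <- rep(seq_len(dims[2]) - 1L, times = dims[1])
  conds <- rep(c("c1", "c2"), length.out = length(rows))

  # planted +0.5 on every edge well
  set.seed(99)
  growth_vals <- rnorm(length(rows), 0.3, 0.02) +
    0.5 * is_edge(rows, cols, 384)
  g <- make_growth(data.frame(row = rows, col = cols, condition_id = conds,
                              kind = "coculture", growth = growth_vals))
  flags <- positional_bias_flags(g, edge_bias_k = 3)
  edge_wells <- well_label(rows, cols, 384)[is_edge(rows, cols, 384)]
  expect_true(all(edge_wells %in% flags$well))

  # noise-only plates: zero flags in >= 95% of seeded replicates
  n_zero <- 0L
  for (s in 1:200) {
    set.seed(s)
    g0 <- make_growth(data.frame(row = rows, col = cols, condition_id = conds,
                                 kind = "coculture",
                                 growth = rnorm(length(rows), 0.3, 0.02)))
    n_zero <- n_zero + (nrow(positional_bias_flags(g0)) == 0L)
  }
  expect_gte(n_zero / 200, 0.95)
})

test_that("row/column gradients match the brute-force median-polish oracle", {
  dims <- plate_dims(96)
  rows <- rep(seq_len(dims[1]) - 1L, each = dims[2])
  cols <- rep(seq_len(dims[2]) - 1L, times = dims[1])
  set.seed(5)
  slope <- 0.04
  vals <- 0.3 + slope * (cols - (dims[2] - 1) / 2) + rnorm(length(rows), 0, 0.005)
  g <- make_growth(data.frame(row = rows, col = cols,
                              condition_id = rep(c("c1", "c2"), length.out = length(rows)),
                              kind = "coculture", growth = vals),
                   format = 96)
  flags <- positional_bias_flags(g, edge_bias_k = 3)

  mat <- matrix(NA_real_, dims[1], dims[2])
  mat[cbind(rows + 1L, cols + 1L)] <- vals
  fit <- oracle_medpolish(mat)
  eff <- outer(fit$row, fit$col, `+`)
  thr <- 3 * 1.4826 * median(abs(fit$residuals), na.rm = TRUE)
  expected <- well_label(rows, cols, 96)[abs(eff[cbind(rows + 1L, cols + 1L)]) > thr]
  # oracle agreement within one borderline well either way
  expect_lte(length(setdiff(expected, flags$well)), 1L)
  expect_lte(length(setdiff(flags$well, expected)), 1L)
  expect_gt(nrow(flags), 0L)
})

test_that("plates without condition contrast are skipped with a warning", {
  wells <- data.frame(row = rep(0:3, each = 4), col = rep(0:3, 4),
                      condition_id = "only", kind = "coculture",
                      growth = rnorm(16, 0.3, 0.01))
  expect_warning(flags <- positional_bias_flags(make_growth(wells, format = 96)),
                 "no condition contrast")
  expect_equal(nrow(flags), 0L)
})

test_that("condition summaries report robust and classical moments", {
  wells <- data.frame(row = 0L, col = 0:3, condition_id = "c1",
                      kind = "coculture", growth = c(0.2, 0.4, 0.3, 0.5))
  s <- summarize_conditions(make_growth(wells, format = 96))
  expect_equal(s$n, 4L)
  expect_equal(s$mean_od, 0.35)
  expect_equal(s$median_od, 0.35)
  expect_equal(s$mad_od, 1.4826 * 0.1)
  expect_equal(s$sd_od, sd(c(0.2, 0.4, 0.3, 0.5)))
})
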