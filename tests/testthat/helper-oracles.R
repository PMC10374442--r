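# Independent oracles used to cross-check the pipeline's statistics.
# These re-derive each quantity from its defining formula, deliberately
# avoiding the code paths (and library calls) used by the implementation.

# Welch's t, Welch-Satterthwaite df and two-sided p from first principles.
oracle_welch <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  m1 <- sum(g1) / n1; m2 <- sum(g2) / n2
  v1 <- sum((g1 - m1)^2) / (n1 - 1)
  v2 <- sum((g2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Benjamini-Hochberg step-up by direct evaluation of
# adj_(i) = min_{j >= i} p_(j) * m / j, returned in input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# All permutations of 1..n as rows of a matrix (n <= 6).
combinat_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- combinat_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Additive row+column decomposition by alternating median sweeps
# (brute-force median polish).
oracle_medpolish <- function(mat, iter = 200L) {
  overall <- 0
  row_eff <- rep(0, nrow(mat))
  col_eff <- rep(0, ncol(mat))
  res <- mat
  for (i in seq_len(iter)) {
    rmed <- apply(res, 1, stats::median, na.rm = TRUE)
    row_eff <- row_eff + rmed
    res <- sweep(res, 1, rmed)
    overall <- overall + stats::median(row_eff)
    row_eff <- row_eff - stats::median(row_eff)
    cmed <- apply(res, 2, stats::median, na.rm = TRUE)
    col_eff <- col_eff + cmed
    res <- sweep(res, 2, cmed)
    overall <- overall + stats::median(col_eff)
    col_eff <- col_eff - stats::median(col_eff)
    if (max(abs(rmed), abs(cmed)) < 1e-10) break
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = res)
}

# Build a blank-corrected growth table directly from per-well values:
# `wells` is a data.frame with row, col, condition_id, kind, growth
# (strain_1/strain_2 optional). One synthetic plate in 384 format unless
# stated otherwise.
make_growth <- function(wells, plate_id = "plateA", format = 384) {
  wells$plate_id <- plate_id
  wells$batch <- "test"
  wells$well <- well_label(wells$row, wells$col, format)
  if (is.null(wells$strain_1)) wells$strain_1 <- ""
  if (is.null(wells$strain_2)) wells$strain_2 <- ""
  wells$od_t0 <- 0.1
  wells$od_t48 <- 0.1 + wells$growth
  wells$delta <- wells$growth
  wells$blank_corrected <- TRUE
  wells
}
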