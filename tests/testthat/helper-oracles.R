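# Brute-force oracles, written independently of the package internals:
# plain loops and textbook formulas only.

# weighted mean density: sum(d*y)/sum(y) with an explicit loop
oracle_wad <- function(density, copies) {
  num <- 0
  den <- 0
  for (i in seq_along(density)) {
    num <- num + density[i] * copies[i]
    den <- den + copies[i]
  }
  num / den
}

# two-step absolute abundance: per fraction, read share times ddPCR copies;
# then summed over the gradient
oracle_absolute_abundance <- function(reads_by_taxon_fraction, total_copies) {
  out <- numeric(nrow(reads_by_taxon_fraction))
  for (f in seq_along(total_copies)) {
    tot <- sum(reads_by_taxon_fraction[, f])
    if (tot > 0) {
      out <- out + reads_by_taxon_fraction[, f] / tot * total_copies[f]
    }
  }
  out
}

# Welch statistic, Welch-Satterthwaite df, two-sided p
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}

# balanced two-way ANOVA with interaction from raw sums of squares
oracle_anova_two_way <- function(values, fa, fb) {
  fa <- as.character(fa); fb <- as.character(fb)
  gm <- mean(values)
  ss_total <- sum((values - gm)^2)
  mean_a <- tapply(values, fa, mean)
  mean_b <- tapply(values, fb, mean)
  n_a <- table(fa); n_b <- table(fb)
  ss_a <- sum(n_a * (mean_a - gm)^2)
  ss_b <- sum(n_b * (mean_b - gm)^2)
  cell <- paste(fa, fb)
  mean_ab <- tapply(values, cell, mean)
  n_ab <- table(cell)
  ss_cells <- sum(n_ab * (mean_ab - gm)^2)
  ss_axb <- ss_cells - ss_a - ss_b
  ss_res <- ss_total - ss_cells
  df_a <- length(mean_a) - 1
  df_b <- length(mean_b) - 1
  df_axb <- df_a * df_b
  df_res <- length(values) - length(mean_ab)
  f <- c(ss_a / df_a, ss_b / df_b, ss_axb / df_axb) / (ss_res / df_res)
  p <- pf(f, c(df_a, df_b, df_axb), df_res, lower.tail = FALSE)
  list(ss = c(ss_a, ss_b, ss_axb, ss_res), f = f, p = p)
}

# BH step-up by direct definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (i in m:1) {
    val <- p[ord[i]] * m / i
    running_min <- min(running_min, val)
    adj[ord[i]] <- min(running_min, 1)
  }
  adj
}
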