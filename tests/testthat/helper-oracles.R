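# Independent oracles used across the suite.  These deliberately re-derive
# quantities by the most elementary route available (scalar loops, textbook
# formulas) and stay independent of the package's vectorised code paths.

# Scalar even-odd point-in-polygon with boundary-inside convention.
oracle_point_in_polygon <- function(x, y, vertices) {
  n <- nrow(vertices)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    if (abs(cross) < 1e-12 &&
        x >= min(xi, xj) - 1e-12 && x <= max(xi, xj) + 1e-12 &&
        y >= min(yi, yj) - 1e-12 && y <= max(yi, yj) + 1e-12) return(TRUE)
    if ((yi > y) != (yj > y) &&
        x < (xj - xi) * (y - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# Textbook paired t: t = mean(d) / (sd(d)/sqrt(n)), two-sided p from t_{n-1}.
oracle_paired_t <- function(treated, control) {
  d <- treated - control
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df = n - 1))
}

# Direct Z'-factor arithmetic.
oracle_z_prime <- function(m_neg, s_neg, m_pos, s_pos) {
  1 - 3 * (s_neg + s_pos) / abs(m_neg - m_pos)
}

# A small event table with known channel values for gate tests.
toy_events <- function(n = 100, seed = 42) {
  set.seed(seed)
  df <- as.data.frame(setNames(
    lapply(es_channels(), function(ch) runif(n, 0, 8)), es_channels()))
  cbind(event_id = seq_len(n), df, truth_label = "")
}
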