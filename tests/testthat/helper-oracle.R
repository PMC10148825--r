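# Independent oracles, kept deliberately naive: plain double loops over
# ordered pairs, no shared code with the package's vectorized pipeline.

# Full-precision PROMETHEE-II with the threshold-free linear preference
# function, recomputed pair by pair.
oracle_promethee <- function(scores, weights, directions = NULL) {
  m <- nrow(scores)
  k <- ncol(scores)
  directions <- directions %||% rep("beneficial", k)
  weights <- weights / sum(weights)
  norm <- scores
  for (j in seq_len(k)) {
    lo <- min(scores[, j]); hi <- max(scores[, j])
    if (hi == lo) {
      norm[, j] <- 0
    } else if (directions[j] == "beneficial") {
      norm[, j] <- (scores[, j] - lo) / (hi - lo)
    } else {
      norm[, j] <- (hi - scores[, j]) / (hi - lo)
    }
  }
  pi_mat <- matrix(0, m, m)
  for (z in seq_len(m)) {
    for (y in seq_len(m)) {
      if (z == y) next
      acc <- 0
      for (j in seq_len(k)) {
        w <- norm[z, j] - norm[y, j]
        acc <- acc + weights[j] * (if (w > 0) w else 0)
      }
      pi_mat[z, y] <- acc
    }
  }
  phi_plus <- numeric(m); phi_minus <- numeric(m)
  for (z in seq_len(m)) {
    for (y in seq_len(m)) {
      if (z == y) next
      phi_plus[z] <- phi_plus[z] + pi_mat[z, y]
      phi_minus[z] <- phi_minus[z] + pi_mat[y, z]
    }
  }
  phi_plus <- phi_plus / (m - 1)
  phi_minus <- phi_minus / (m - 1)
  phi <- phi_plus - phi_minus
  list(norm = norm, pi = pi_mat, phi_plus = phi_plus,
       phi_minus = phi_minus, phi = phi,
       rank = rank(-phi, ties.method = "min"))
}

# Kendall tau-b by direct enumeration of all pairs with tie correction.
oracle_tau_b <- function(ra, rb) {
  n <- length(ra)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- sign(ra[i] - ra[j]); b <- sign(rb[i] - rb[j])
      if (a == 0 && b == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (a == 0) tx <- tx + 1
      else if (b == 0) ty <- ty + 1
      else if (a == b) C <- C + 1
      else D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# Random decision matrix with equal-weight beneficial criteria.
random_dm <- function(m, k, scale_values = NULL) {
  vals <- if (is.null(scale_values)) stats::runif(m * k) else
    sample(scale_values, m * k, replace = TRUE)
  scores <- matrix(vals, m, k,
                   dimnames = list(paste0("A", seq_len(m)),
                                   paste0("C", seq_len(k))))
  decision_matrix(scores)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
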