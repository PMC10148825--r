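#' Min-max normalization of a decision matrix
#'
#' Beneficial columns map to `(C - min) / (max - min)` and cost columns to
#' `(max - C) / (max - min)`, so that for every non-degenerate criterion the
#' best alternative scores 1 and the worst 0. Degenerate columns (max = min)
#' would divide by zero; they are set to all zeros and flagged — a constant
#' criterion prefers no alternative over another.
#'
#' @param dm a [decision_matrix()].
#' @param rounding number of decimal places for half-up rounding of the
#'   normalized values, or `NULL` (default) for full precision. Rounding to 3
#'   decimals reproduces hand-worked tables.
#' @return An object of class `normalized_matrix`: list with `values`
#'   (m x k matrix in \[0,1\]) and `degenerate` (names of flagged criteria).
#' @export
normalize_matrix <- function(dm, rounding = NULL) {
  v <- validate_matrix(dm)
  if (!v$ok)
    pr_stop(paste0("invalid decision matrix: ",
                   paste(v$errors, collapse = "; ")), "validation_error")
  s <- dm$scores
  dir <- dm_directions(dm)
  out <- s
  degenerate <- character(0)
  for (j in seq_len(ncol(s))) {
    lo <- min(s[, j]); hi <- max(s[, j])
    if (hi == lo) {
      out[, j] <- 0
      degenerate <- c(degenerate, colnames(s)[j])
    } else if (dir[j] == "beneficial") {
      out[, j] <- (s[, j] - lo) / (hi - lo)
    } else {
      out[, j] <- (hi - s[, j]) / (hi - lo)
    }
  }
  if (!is.null(rounding)) out <- round_half_up(out, rounding)
  structure(list(values = out, degenerate = degenerate,
                 alternatives = rownames(out)),
            class = "normalized_matrix")
}

#' Pairwise evaluation difference on one criterion
#'
#' The deviation `w_j(z, y)` is the difference between the normalized scores
#' of alternatives `z` and `y` on criterion `j`; it is antisymmetric in
#' `(z, y)` by construction.
#'
#' @param norm a [normalize_matrix()] result.
#' @param j criterion name or column index.
#' @param z,y alternative names or row indices.
#' @return a single numeric deviation.
#' @export
deviation <- function(norm, j, z, y) {
  v <- norm$values
  resolve <- function(idx, names, what) {
    if (is.character(idx)) {
      pos <- match(idx, names)
      if (is.na(pos))
        pr_stop(sprintf("unknown %s: '%s'", what, idx), "lookup_error")
      return(pos)
    }
    if (idx < 1 || idx > length(names))
      pr_stop(sprintf("%s index %s out of range", what, idx), "lookup_error")
    idx
  }
  zi <- resolve(z, rownames(v), "alternative")
  yi <- resolve(y, rownames(v), "alternative")
  ji <- resolve(j, colnames(v), "criterion")
  v[zi, ji] - v[yi, ji]
}

#' Preference degree of a deviation
#'
#' Maps a pairwise deviation `w` to a preference degree in \[0, 1\] under the
#' chosen preference function. All kinds return 0 for `w <= 0`. The
#' `paper-linear` kind returns the deviation itself for `w > 0` (deviations on
#' normalized scores already lie in \[0, 1\]); the remaining kinds are the six
#' classical shapes (usual, U-shape, V-shape, level, V-shape with
#' indifference, Gaussian).
#'
#' @param w numeric vector of deviations.
#' @param spec a [pf_spec()].
#' @return numeric vector of preference degrees in \[0, 1\].
#' @export
preference_value <- function(w, spec = pf_spec("paper-linear")) {
  if (!inherits(spec, "pf_spec")) pr_stop("spec must be a pf_spec", "config_error")
  pos <- w > 0
  out <- numeric(length(w))
  q <- spec$q; p <- spec$p; s <- spec$s
  out[pos] <- switch(spec$kind,
    "paper-linear" = w[pos],
    "usual" = 1,
    "u-shape" = as.numeric(w[pos] > q),
    "v-shape" = pmin(w[pos] / p, 1),
    "level" = ifelse(w[pos] > p, 1, ifelse(w[pos] > q, 0.5, 0)),
    "v-shape-indifference" =
      ifelse(w[pos] > p, 1,
             ifelse(w[pos] > q, (w[pos] - q) / (p - q), 0)),
    "gaussian" = 1 - exp(-w[pos]^2 / (2 * s^2))
  )
  out
}

# internal: m x m x k array of per-criterion pairwise preferences P_j(z, y),
# diagonal NA (an alternative is never compared with itself)
pairwise_preferences <- function(norm, criteria) {
  v <- norm$values
  m <- nrow(v); k <- ncol(v)
  pref <- array(NA_real_, c(m, m, k),
                dimnames = list(rownames(v), rownames(v), colnames(v)))
  for (j in seq_len(k)) {
    w <- outer(v[, j], v[, j], "-")
    pj <- matrix(preference_value(as.numeric(w), criteria[[j]]$pf), m, m)
    diag(pj) <- NA_real_
    pref[, , j] <- pj
  }
  pref
}

#' Aggregate per-criterion preferences into the weighted preference index
#'
#' Computes `pi(z, y) = sum_j d_j * P_j(z, y)` over the ordered pairs
#' `z != y`, where the weights `d_j` sum to one.
#'
#' @param pref m x m x k array of per-criterion preferences (diagonal `NA`),
#'   as built inside [run_promethee2()].
#' @param weights numeric weight vector of length k; renormalized to sum to 1
#'   if needed.
#' @param rounding decimal places for half-up rounding of each aggregated
#'   value, or `NULL` for full precision.
#' @return m x m matrix of aggregated preference indices, diagonal `NA`.
#' @export
aggregate_preferences <- function(pref, weights, rounding = NULL) {
  if (length(dim(pref)) != 3L)
    pr_stop("pref must be an m x m x k array", "config_error")
  if (dim(pref)[3] != length(weights))
    pr_stop(sprintf("got %d weights for %d criterion tables",
                    length(weights), dim(pref)[3]), "config_error")
  weights <- normalize_weights(weights, quiet = TRUE)
  m <- dim(pref)[1]
  pi_mat <- matrix(0, m, m, dimnames = dimnames(pref)[1:2])
  for (j in seq_along(weights)) pi_mat <- pi_mat + weights[j] * pref[, , j]
  if (!is.null(rounding)) pi_mat <- round_half_up(pi_mat, rounding)
  diag(pi_mat) <- NA_real_
  pi_mat
}

#' Positive (leaving) outranking flow
#'
#' `phi+(z)` averages the aggregated preference of `z` over every other
#' alternative: the row sum of the preference index over `y != z` divided by
#' `n - 1`. It measures how strongly `z` outranks the field.
#'
#' @param pi_mat m x m aggregated preference matrix (diagonal `NA`).
#' @return named numeric vector of positive flows in \[0, 1\].
#' @export
positive_flow <- function(pi_mat) {
  if (nrow(pi_mat) < 2L)
    pr_stop("outranking flows need at least 2 alternatives", "domain_error")
  rowSums(pi_mat, na.rm = TRUE) / (nrow(pi_mat) - 1)
}

#' Negative (entering) outranking flow
#'
#' `phi-(z)` averages the aggregated preference of every other alternative
#' over `z`: the column sum over `y != z` divided by `n - 1`. It measures how
#' strongly `z` is outranked.
#'
#' @inheritParams positive_flow
#' @return named numeric vector of negative flows in \[0, 1\].
#' @export
negative_flow <- function(pi_mat) {
  if (nrow(pi_mat) < 2L)
    pr_stop("outranking flows need at least 2 alternatives", "domain_error")
  colSums(pi_mat, na.rm = TRUE) / (nrow(pi_mat) - 1)
}

#' Net outranking flow
#'
#' @param phi_plus,phi_minus equal-length numeric vectors of positive and
#'   negative flows.
#' @return `phi_plus - phi_minus`, elementwise.
#' @export
net_flow <- function(phi_plus, phi_minus) {
  if (length(phi_plus) != length(phi_minus))
    pr_stop("flow vectors must have equal length", "domain_error")
  phi_plus - phi_minus
}

#' Rank alternatives by net flow
#'
#' Produces the complete ranking: descending net flow with competition
#' ranking for ties (tied alternatives share the smallest applicable rank and
#' the following rank is skipped). Display order of tied alternatives follows
#' input order.
#'
#' @param phi_plus,phi_minus,phi_net named flow vectors (from
#'   [positive_flow()], [negative_flow()], [net_flow()]).
#' @return A `data.frame` of class `flow_table` with columns `alternative`,
#'   `phi_plus`, `phi_minus`, `phi_net`, `rank`.
#' @export
rank_alternatives <- function(phi_plus, phi_minus, phi_net = net_flow(phi_plus, phi_minus)) {
  stopifnot(length(phi_plus) == length(phi_net))
  ranks <- rank(-phi_net, ties.method = "min")
  out <- data.frame(
    alternative = names(phi_net) %||% paste0("A", seq_along(phi_net)),
    phi_plus = unname(phi_plus),
    phi_minus = unname(phi_minus),
    phi_net = unname(phi_net),
    rank = as.integer(ranks),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  class(out) <- c("flow_table", "data.frame")
  out
}

#' Run the complete PROMETHEE-II pipeline
#'
#' Composes the seven phases: validation, min-max normalization, pairwise
#' deviations, preference evaluation, weighted aggregation, positive/negative
#' outranking flows, and the net-flow ranking.
#'
#' Two arithmetic modes are offered. `"full-precision"` (the default for new
#' analyses) carries full double precision through every stage.
#' `"paper"` rounds the normalized matrix and the aggregated preference
#' indices half-up to 3 decimals, the convention of hand-worked published
#' tables, so printed intermediates can be reproduced exactly.
#'
#' @param dm a [decision_matrix()].
#' @param mode `"full-precision"` or `"paper"`.
#' @return An object of class `promethee_result`: list with elements
#'   `normalized` ([normalize_matrix()] output), `preferences` (list with the
#'   per-criterion `per_criterion` array and the `aggregated` index matrix),
#'   `flows` (the ranked [rank_alternatives()] table), `weights`, and `mode`.
#' @examples
#' res <- run_promethee2(rtki_case_study(), mode = "paper")
#' subset(res$flows, rank == 1)
#' @export
run_promethee2 <- function(dm, mode = c("full-precision", "paper")) {
  mode <- match.arg(mode)
  rounding <- if (mode == "paper") 3L else NULL
  v <- validate_matrix(dm)
  if (!v$ok)
    pr_stop(paste0("invalid decision matrix: ",
                   paste(v$errors, collapse = "; ")), "validation_error")
  criteria <- normalize_weights(dm$criteria, quiet = TRUE)
  weights <- vapply(criteria, `[[`, numeric(1), "weight")
  norm <- normalize_matrix(dm, rounding = rounding)
  pref <- pairwise_preferences(norm, criteria)
  pi_mat <- aggregate_preferences(pref, weights, rounding = rounding)
  phi_plus <- positive_flow(pi_mat)
  phi_minus <- negative_flow(pi_mat)
  flows <- rank_alternatives(phi_plus, phi_minus)
  structure(
    list(normalized = norm,
         preferences = list(per_criterion = pref, aggregated = pi_mat),
         flows = flows, weights = weights, mode = mode),
    class = "promethee_result"
  )
}

#' @export
print.promethee_result <- function(x, digits = 6, ...) {
  cat(sprintf("PROMETHEE-II result (%s mode), %d alternatives x %d criteria\n",
              x$mode, nrow(x$flows), length(x$weights)))
  if (length(x$normalized$degenerate))
    cat("  degenerate criteria:",
        paste(x$normalized$degenerate, collapse = ", "), "\n")
  fl <- x$flows
  fl[c("phi_plus", "phi_minus", "phi_net")] <-
    lapply(fl[c("phi_plus", "phi_minus", "phi_net")], round, digits)
  print.data.frame(fl[order(fl$rank), ], row.names = FALSE)
  invisible(x)
}

#' Export the valued outranking graph
#'
#' The aggregated preference index defines a complete valued digraph with two
#' arcs between every pair of alternatives. This returns the arcs whose
#' weight reaches a threshold.
#'
#' @param pi_mat aggregated preference matrix (from a `promethee_result`'s
#'   `preferences$aggregated`).
#' @param threshold minimum preference index for an arc to be kept
#'   (default 0: all `m * (m - 1)` arcs).
#' @return `data.frame` with columns `from`, `to`, `weight`, ordered by
#'   source then target.
#' @seealso [write_graph_dot()]
#' @export
export_outranking_graph <- function(pi_mat, threshold = 0) {
  if (threshold < 0)
    pr_stop("threshold must be non-negative", "domain_error")
  nm <- rownames(pi_mat)
  keep <- which(!is.na(pi_mat) & pi_mat >= threshold, arr.ind = TRUE)
  edges <- data.frame(
    from = nm[keep[, 1]],
    to = nm[keep[, 2]],
    weight = pi_mat[keep],
    stringsAsFactors = FALSE
  )
  edges[order(match(edges$from, nm), match(edges$to, nm)), , drop = FALSE] |>
    `rownames<-`(NULL)
}
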