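#' Kendall tau-b agreement between two rankings
#'
#' Standard Kendall rank correlation with the tau-b tie correction. Inputs can
#' be character vectors listing the alternatives best-first, or (possibly
#' tied) named rank vectors; both must cover the same alternative set.
#'
#' @param order_a,order_b character orderings (best first) or named numeric
#'   rank vectors.
#' @return tau-b in \[-1, 1\].
#' @export
rank_agreement <- function(order_a, order_b) {
  as_ranks <- function(x) {
    if (is.character(x)) {
      r <- seq_along(x); names(r) <- x; return(r)
    }
    if (is.numeric(x) && !is.null(names(x))) return(x)
    pr_stop("orderings must be character vectors or named rank vectors",
            "domain_error")
  }
  ra <- as_ranks(order_a)
  rb <- as_ranks(order_b)
  if (length(ra) != length(rb) || !setequal(names(ra), names(rb)))
    pr_stop("orderings must cover the same alternative set", "domain_error")
  rb <- rb[names(ra)]
  stats::cor(ra, rb, method = "kendall")
}

# internal: full-precision pipeline run returning ranks + order for a
# reweighted copy of dm
run_scenario <- function(dm, weights) {
  dm$criteria <- Map(function(cr, w) { cr$weight <- w; cr },
                     dm$criteria, weights)
  res <- run_promethee2(dm, mode = "full-precision")
  fl <- res$flows
  list(
    weights = vapply(normalize_weights(dm$criteria, quiet = TRUE),
                     `[[`, numeric(1), "weight"),
    ranks = stats::setNames(fl$rank, fl$alternative),
    order = fl$alternative[order(fl$phi_net, decreasing = TRUE)]
  )
}

# internal: assemble a sensitivity_report from a base scenario and a list of
# named scenarios
build_report <- function(base, scenarios, labels) {
  alts <- names(base$ranks)
  rank_mat <- do.call(rbind, lapply(scenarios, function(s) s$ranks[alts]))
  rownames(rank_mat) <- labels
  taus <- vapply(scenarios, function(s)
    rank_agreement(base$ranks, s$ranks), numeric(1))
  ws <- lapply(scenarios, `[[`, "weights")
  # knockout scenarios have one weight fewer than the base: no common matrix
  weight_mat <- if (length(unique(lengths(ws))) == 1L) {
    wm <- do.call(rbind, ws); rownames(wm) <- labels; wm
  }
  weight_strs <- vapply(scenarios, function(s)
    paste(sprintf("%.4f", s$weights), collapse = "/"), character(1))
  order_strs <- vapply(scenarios, function(s)
    paste(s$order, collapse = " > "), character(1))
  stability <- data.frame(
    alternative = alts,
    base_rank = unname(base$ranks[alts]),
    min_rank = apply(rank_mat, 2, min),
    max_rank = apply(rank_mat, 2, max),
    row.names = NULL, stringsAsFactors = FALSE
  )
  reversals <- list()
  for (a in seq_along(alts)) {
    for (b in seq_len(a - 1L)) {
      d <- rank_mat[, alts[a]] - rank_mat[, alts[b]]
      if (any(d > 0) && any(d < 0))
        reversals[[length(reversals) + 1L]] <-
          data.frame(alt_1 = alts[b], alt_2 = alts[a],
                     stringsAsFactors = FALSE)
    }
  }
  reversals <- if (length(reversals)) do.call(rbind, reversals) else
    data.frame(alt_1 = character(0), alt_2 = character(0))
  structure(
    list(
      scenarios = data.frame(scenario = labels, weights = weight_strs,
                             order = order_strs, tau_vs_base = taus,
                             row.names = NULL, stringsAsFactors = FALSE),
      ranks = rank_mat,
      weight_matrix = weight_mat,
      stability = stability,
      reversals = reversals,
      base = base
    ),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity report: %d scenarios, %d alternatives\n",
              nrow(x$scenarios), nrow(x$stability)))
  print.data.frame(x$scenarios, row.names = FALSE)
  if (nrow(x$reversals)) {
    cat("rank reversals observed for pairs:\n")
    print.data.frame(x$reversals, row.names = FALSE)
  } else cat("no rank reversals across scenarios\n")
  invisible(x)
}

#' Weight sensitivity sweep
#'
#' Recomputes the full-precision PROMETHEE-II ranking over a grid of
#' criterion-weight perturbations. Each scenario adds one delta per criterion
#' to the base weights (all combinations of the per-criterion delta grids),
#' renormalizes, and reruns the pipeline; the report collects the resulting
#' orders, per-alternative rank ranges, and every pair whose relative order
#' reverses in some scenario.
#'
#' @param dm a [decision_matrix()].
#' @param base_weights base weight vector; defaults to the matrix's own
#'   criterion weights.
#' @param grid list of numeric delta vectors, one per criterion (recycled if a
#'   single vector is given). Deltas producing a negative weight are rejected.
#' @return A `sensitivity_report`; the base (zero-delta) scenario is always
#'   included first.
#' @export
weight_sweep <- function(dm, base_weights = NULL, grid = list(c(-0.1, 0, 0.1))) {
  v <- validate_matrix(dm)
  if (!v$ok)
    pr_stop(paste0("invalid decision matrix: ",
                   paste(v$errors, collapse = "; ")), "validation_error")
  k <- length(dm$criteria)
  base_weights <- base_weights %||% dm_weights(dm)
  if (length(base_weights) != k)
    pr_stop("base_weights length must equal the criterion count", "config_error")
  if (is.numeric(grid)) grid <- list(grid)
  if (!is.list(grid) || !length(grid) || !all(lengths(grid) > 0))
    pr_stop("grid must be a non-empty list of delta vectors", "config_error")
  if (length(grid) == 1L) grid <- rep(grid, k)
  if (length(grid) != k)
    pr_stop("grid must supply one delta vector per criterion", "config_error")
  combos <- as.matrix(expand.grid(grid, KEEP.OUT.ATTRS = FALSE))
  base <- run_scenario(dm, base_weights)
  scen_w <- lapply(seq_len(nrow(combos)), function(i) base_weights + combos[i, ])
  # keep the base case first; drop duplicates of it arising from zero deltas
  is_base <- vapply(scen_w, function(w) all(abs(w - base_weights) < 1e-12), TRUE)
  scen_w <- scen_w[!is_base]
  for (w in scen_w) {
    if (any(w < 0))
      pr_stop("a perturbed weight is negative; shrink the grid", "config_error")
    if (sum(w) <= 0)
      pr_stop("a perturbed weight vector is all zero", "config_error")
  }
  scenarios <- c(list(base), lapply(scen_w, function(w) run_scenario(dm, w)))
  labels <- c("base", if (length(scen_w)) paste0("sweep_", seq_along(scen_w)))
  build_report(base, scenarios, labels)
}

#' Criterion knockout analysis
#'
#' Removes each criterion in turn, renormalizes the remaining weights
#' proportionally (preserving their relative priorities), and reruns the
#' full-precision pipeline.
#'
#' @param dm a [decision_matrix()] with at least two criteria.
#' @return A `sensitivity_report` with one scenario per removed criterion
#'   (plus the base case).
#' @export
criterion_knockout <- function(dm) {
  k <- length(dm$criteria)
  if (k < 2L)
    pr_stop("knockout needs at least 2 criteria", "domain_error")
  base <- run_scenario(dm, dm_weights(dm))
  scenarios <- vector("list", k)
  for (j in seq_len(k)) {
    sub <- dm
    sub$criteria <- dm$criteria[-j]
    sub$scores <- dm$scores[, -j, drop = FALSE]
    scenarios[[j]] <- run_scenario(sub, dm_weights(sub))
  }
  labels <- c("base", paste0("drop_", vapply(dm$criteria, `[[`, character(1), "name")))
  build_report(base, c(list(base), scenarios), labels)
}
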