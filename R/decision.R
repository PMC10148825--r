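#' Preference-function specification
#'
#' The six standard preference-function shapes plus `paper-linear`, the
#' threshold-free linear function used by the bundled case study: the
#' preference degree equals the (already normalized) positive deviation
#' itself, and 0 for deviations at or below zero.
#'
#' @param kind one of `"paper-linear"`, `"usual"`, `"u-shape"`, `"v-shape"`,
#'   `"level"`, `"v-shape-indifference"`, `"gaussian"`.
#' @param q indifference threshold (>= 0); required by `u-shape`, `level` and
#'   `v-shape-indifference`.
#' @param p preference threshold (>= q); required by `v-shape`, `level` and
#'   `v-shape-indifference`.
#' @param s Gaussian inflection point (> 0); required by `gaussian`.
#' @return An object of class `pf_spec`.
#' @export
pf_spec <- function(kind = c("paper-linear", "usual", "u-shape", "v-shape",
                             "level", "v-shape-indifference", "gaussian"),
                    q = NULL, p = NULL, s = NULL) {
  kind <- match.arg(kind)
  need <- switch(kind,
    "u-shape" = "q",
    "v-shape" = "p",
    "level" = c("q", "p"),
    "v-shape-indifference" = c("q", "p"),
    "gaussian" = "s",
    character(0)
  )
  given <- c(q = !is.null(q), p = !is.null(p), s = !is.null(s))
  missing <- setdiff(need, names(given)[given])
  if (length(missing))
    pr_stop(sprintf("preference function '%s' requires threshold(s): %s",
                    kind, paste(missing, collapse = ", ")),
            "config_error")
  if (!is.null(q) && q < 0) pr_stop("q must be >= 0", "config_error")
  if (!is.null(p) && !is.null(q) && p < q)
    pr_stop("p must be >= q", "config_error")
  if (!is.null(p) && p <= 0 && kind %in% c("v-shape"))
    pr_stop("p must be > 0 for v-shape", "config_error")
  if (!is.null(s) && s <= 0) pr_stop("s must be > 0", "config_error")
  structure(list(kind = kind, q = q, p = p, s = s), class = "pf_spec")
}

#' Define a criterion
#'
#' @param name unique criterion identifier.
#' @param direction `"beneficial"` (higher raw score is better) or `"cost"`.
#' @param weight non-negative relative importance; weights are renormalized to
#'   sum to 1 before aggregation.
#' @param pf a [pf_spec()]; defaults to the threshold-free linear function.
#' @return An object of class `criterion`.
#' @export
criterion <- function(name, direction = c("beneficial", "cost"), weight = 1,
                      pf = pf_spec("paper-linear")) {
  direction <- match.arg(direction)
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) || weight < 0)
    pr_stop(sprintf("criterion '%s': weight must be a non-negative number", name),
            "config_error")
  if (!inherits(pf, "pf_spec")) pr_stop("pf must be a pf_spec", "config_error")
  structure(list(name = as.character(name), direction = direction,
                 weight = weight, pf = pf),
            class = "criterion")
}

#' Construct a crisp decision matrix
#'
#' The core container: an m x k table of crisp performance scores `C[i, j]`
#' for m alternatives (rows) against k criteria (columns), with per-criterion
#' metadata (direction, weight, preference function). Row and column order is
#' preserved through every downstream output.
#'
#' @param scores numeric matrix (or data.frame) of scores; rownames are the
#'   alternative identifiers.
#' @param criteria list of [criterion()] objects, one per column, or a
#'   character vector of names (beneficial, equal weights).
#' @return An object of class `decision_matrix`.
#' @seealso [validate_matrix()], [run_promethee2()], [rtki_case_study()]
#' @export
decision_matrix <- function(scores, criteria = colnames(scores)) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (is.character(criteria))
    criteria <- lapply(criteria, function(nm)
      criterion(nm, weight = 1 / ncol(scores)))
  if (!is.list(criteria) || !all(vapply(criteria, inherits, TRUE, "criterion")))
    pr_stop("criteria must be a list of criterion objects", "config_error")
  if (length(criteria) != ncol(scores))
    pr_stop(sprintf("got %d criteria for %d score columns",
                    length(criteria), ncol(scores)), "config_error")
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("A", seq_len(nrow(scores)))
  colnames(scores) <- vapply(criteria, `[[`, character(1), "name")
  structure(
    list(scores = scores, criteria = criteria,
         alternatives = rownames(scores)),
    class = "decision_matrix"
  )
}

#' @export
print.decision_matrix <- function(x, ...) {
  cat(sprintf("Decision matrix: %d alternatives x %d criteria\n",
              nrow(x$scores), ncol(x$scores)))
  info <- vapply(x$criteria, function(cr)
    sprintf("%s (%s, w=%.4g, pf=%s)", cr$name, cr$direction, cr$weight,
            cr$pf$kind), character(1))
  cat("  criteria:", paste(info, collapse = "; "), "\n")
  print(x$scores, ...)
  invisible(x)
}

# internal accessors
dm_weights <- function(dm) vapply(dm$criteria, `[[`, numeric(1), "weight")
dm_directions <- function(dm) vapply(dm$criteria, `[[`, character(1), "direction")

#' Validate a decision matrix
#'
#' Checks dimensions (at least two alternatives, one criterion), missing or
#' non-finite cells, duplicate alternative or criterion names, and negative
#' weights; degenerate criteria (constant columns, which carry no
#' discriminating information) are flagged as warnings rather than failures.
#'
#' @param dm a [decision_matrix()].
#' @return A list of class `dm_validation` with elements `ok` (logical),
#'   `errors` and `warnings` (character vectors of messages).
#' @export
validate_matrix <- function(dm) {
  errors <- character(0)
  warnings <- character(0)
  if (!inherits(dm, "decision_matrix")) {
    return(structure(list(ok = FALSE, errors = "not a decision_matrix",
                          warnings = character(0)), class = "dm_validation"))
  }
  s <- dm$scores
  if (nrow(s) < 2L)
    errors <- c(errors, sprintf("need at least 2 alternatives, got %d", nrow(s)))
  if (ncol(s) < 1L)
    errors <- c(errors, "need at least 1 criterion")
  bad <- which(!is.finite(s), arr.ind = TRUE)
  if (nrow(bad)) {
    errors <- c(errors, sprintf(
      "missing or non-finite score in cell (%s, %s)",
      rownames(s)[bad[, 1]], colnames(s)[bad[, 2]]))
  }
  if (anyDuplicated(rownames(s)))
    errors <- c(errors, sprintf("duplicate alternative id: %s",
                                paste(unique(rownames(s)[duplicated(rownames(s))]),
                                      collapse = ", ")))
  if (anyDuplicated(colnames(s)))
    errors <- c(errors, sprintf("duplicate criterion name: %s",
                                paste(unique(colnames(s)[duplicated(colnames(s))]),
                                      collapse = ", ")))
  w <- dm_weights(dm)
  if (any(w < 0)) errors <- c(errors, "negative criterion weight")
  if (all(w == 0)) errors <- c(errors, "all criterion weights are zero")
  if (ncol(s) >= 1L && nrow(s) >= 2L && !nrow(bad)) {
    const <- colnames(s)[apply(s, 2, function(col) max(col) == min(col))]
    if (length(const))
      warnings <- c(warnings, sprintf(
        "degenerate criterion (constant column): %s",
        paste(const, collapse = ", ")))
  }
  structure(list(ok = length(errors) == 0L, errors = errors,
                 warnings = warnings),
            class = "dm_validation")
}

#' @export
print.dm_validation <- function(x, ...) {
  cat("Decision-matrix validation:", if (x$ok) "PASS" else "FAIL", "\n")
  if (length(x$errors)) cat(paste0("  error: ", x$errors), sep = "\n")
  if (length(x$warnings)) cat(paste0("  warning: ", x$warnings), sep = "\n")
  invisible(x)
}

#' Renormalize criterion weights to sum to one
#'
#' Weights already summing to 1 (within 1e-9) are returned unchanged;
#' otherwise each weight is divided by the total and a notice is emitted.
#'
#' @param criteria list of [criterion()] objects or a numeric weight vector.
#' @param quiet suppress the renormalization notice.
#' @return Same type as the input, with weights summing to 1.
#' @export
normalize_weights <- function(criteria, quiet = FALSE) {
  numeric_in <- is.numeric(criteria)
  w <- if (numeric_in) criteria else vapply(criteria, `[[`, numeric(1), "weight")
  if (any(w < 0))
    pr_stop("criterion weights must be non-negative", "config_error")
  total <- sum(w)
  if (total <= 0)
    pr_stop("at least one criterion weight must be positive", "config_error")
  if (abs(total - 1) <= 1e-9) return(criteria)
  if (!quiet)
    message(sprintf("renormalizing criterion weights (sum was %.6g)", total))
  w <- w / total
  if (numeric_in) return(w)
  Map(function(cr, wi) { cr$weight <- wi; cr }, criteria, w)
}

#' The bundled anti-angiogenic inhibitor case study
#'
#' Nine receptor-tyrosine-kinase inhibitors — ponatinib (In1), SU 5402 (In2),
#' regorafenib (In3), nintedanib (In4), linifanib (In5), dovitinib (In6),
#' sorafenib (In7), pazopanib (In8) and lenvatinib (In9) — scored against
#' three angiogenic growth-factor criteria (GF1 = VEGF, GF2 = FGF,
#' GF3 = PDGF) on the five-level verbal scale by a 72-expert panel, with
#' criterion weights 0.45 / 0.35 / 0.20. All three criteria are beneficial
#' and use the threshold-free linear preference function.
#'
#' @return A [decision_matrix()] (9 alternatives x 3 criteria).
#' @examples
#' res <- run_promethee2(rtki_case_study(), mode = "paper")
#' res$flows
#' @export
rtki_case_study <- function() {
  scores <- matrix(c(
    0.333, 0.250, 0.333,
    0.333, 0.250, 0.333,
    1.000, 0.000, 0.333,
    1.000, 0.666, 0.666,
    0.333, 0.000, 0.333,
    1.000, 0.333, 0.666,
    0.666, 0.000, 0.333,
    1.000, 0.250, 0.333,
    1.000, 1.000, 0.333
  ), nrow = 9, byrow = TRUE,
  dimnames = list(paste0("In", 1:9), c("GF1", "GF2", "GF3")))
  weights <- c(GF1 = 0.45, GF2 = 0.35, GF3 = 0.20)
  decision_matrix(scores, criteria = lapply(colnames(scores), function(nm)
    criterion(nm, direction = "beneficial", weight = weights[[nm]])))
}
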