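#' Ordered linguistic scale for expert elicitation
#'
#' A linguistic scale maps ordered verbal judgements (best to worst) to crisp
#' scores in \[0, 1\]. The default five-level scale used throughout the package
#' is High (1.000), Average (0.666), Low (0.333), Very Low (0.250),
#' Null (0.000).
#'
#' @param labels character vector of labels, ordered best to worst.
#' @param values numeric vector of crisp scores in \[0, 1\], strictly
#'   decreasing along `labels`.
#' @return An object of class `linguistic_scale`.
#' @examples
#' sc <- default_scale()
#' to_crisp("High", sc)
#' from_crisp(0.30, sc)
#' @export
linguistic_scale <- function(labels, values) {
  labels <- as.character(labels)
  values <- as.numeric(values)
  if (length(labels) != length(values) || length(labels) < 2L)
    pr_stop("labels and values must have equal length >= 2", "scale_error")
  if (anyNA(values) || any(values < 0 | values > 1))
    pr_stop("scale values must lie in [0, 1]", "scale_error")
  if (any(diff(values) >= 0))
    pr_stop("scale values must be strictly decreasing from best to worst label",
            "scale_error")
  if (anyDuplicated(tolower(trimws(labels))))
    pr_stop("scale labels must be unique (case-insensitive)", "scale_error")
  structure(list(labels = labels, values = values), class = "linguistic_scale")
}

#' @rdname linguistic_scale
#' @export
default_scale <- function() {
  linguistic_scale(
    labels = c("High", "Average", "Low", "Very Low", "Null"),
    values = c(1.000, 0.666, 0.333, 0.250, 0.000)
  )
}

#' @export
print.linguistic_scale <- function(x, ...) {
  cat("Linguistic scale (", length(x$labels), " levels)\n", sep = "")
  cat(paste0("  ", format(x$labels), " -> ", sprintf("%.3f", x$values)),
      sep = "\n")
  invisible(x)
}

# internal: case-insensitive, whitespace-trimmed label lookup -> index
match_label <- function(label, scale) {
  idx <- match(tolower(trimws(label)), tolower(trimws(scale$labels)))
  if (anyNA(idx)) {
    bad <- unique(label[is.na(idx)])
    pr_stop(sprintf(
      "unknown label(s) %s; allowed labels: %s",
      paste(sQuote(bad), collapse = ", "),
      paste(sQuote(scale$labels), collapse = ", ")
    ), "elicitation_error")
  }
  idx
}

#' Convert linguistic labels to crisp scores
#'
#' Matching is case-insensitive and whitespace-trimmed.
#'
#' @param label character vector of scale labels.
#' @param scale a [linguistic_scale()]; defaults to the five-level scale.
#' @return numeric vector of crisp scores.
#' @export
to_crisp <- function(label, scale = default_scale()) {
  scale$values[match_label(label, scale)]
}

#' Map crisp scores back to the nearest scale label
#'
#' Returns the label whose crisp value is nearest to `value`; exact ties are
#' broken toward the better (higher-valued) label so the mapping is
#' deterministic.
#'
#' @param value numeric vector in \[0, 1\].
#' @param scale a [linguistic_scale()].
#' @return character vector of labels.
#' @export
from_crisp <- function(value, scale = default_scale()) {
  if (anyNA(value) || any(value < 0 | value > 1))
    pr_stop("value must lie in [0, 1]", "domain_error")
  vapply(value, function(v) {
    d <- abs(scale$values - v)
    # labels are ordered best (highest value) first, so the earliest minimum is
    # the tie-break toward the better label; the epsilon keeps decimal ties
    # (e.g. 0.2915 between 0.250 and 0.333) ties under binary arithmetic
    scale$labels[which(d <= min(d) + 1e-12)[1]]
  }, character(1))
}

#' Construct an expert panel of linguistic judgements
#'
#' @param responses 3-dimensional character array with dimensions
#'   expert x alternative x criterion, each cell a scale label.
#' @param alternatives,criteria optional identifier vectors; default to the
#'   dimnames of `responses` or generated identifiers.
#' @param scale the [linguistic_scale()] the labels must belong to.
#' @return An object of class `expert_panel`.
#' @export
expert_panel <- function(responses, alternatives = NULL, criteria = NULL,
                         scale = default_scale()) {
  if (!is.array(responses) || length(dim(responses)) != 3L)
    pr_stop("responses must be a 3-d array (expert x alternative x criterion)",
            "elicitation_error")
  d <- dim(responses)
  if (any(d < 1L)) pr_stop("empty panel", "elicitation_error")
  alternatives <- alternatives %||% dimnames(responses)[[2]] %||%
    paste0("A", seq_len(d[2]))
  criteria <- criteria %||% dimnames(responses)[[3]] %||%
    paste0("C", seq_len(d[3]))
  if (length(alternatives) != d[2] || length(criteria) != d[3])
    pr_stop("alternative/criterion names do not match response dimensions",
            "elicitation_error")
  match_label(as.character(responses), scale) # validates every cell
  dimnames(responses) <- list(NULL, alternatives, criteria)
  structure(
    list(responses = responses, n_experts = d[1],
         alternatives = alternatives, criteria = criteria, scale = scale),
    class = "expert_panel"
  )
}

#' @export
print.expert_panel <- function(x, ...) {
  cat(sprintf("Expert panel: %d experts x %d alternatives x %d criteria\n",
              x$n_experts, length(x$alternatives), length(x$criteria)))
  invisible(x)
}

#' Aggregate an expert panel into one crisp decision matrix
#'
#' Collapses the expert dimension of a panel into a single crisp score per
#' (alternative, criterion) cell. `mode` takes the crisp value of the most
#' frequent label (ties broken toward the higher-valued label), so every
#' output cell remains a scale value; `mean` and `median` apply the statistic
#' to the crisp-converted responses.
#'
#' @param panel an [expert_panel()].
#' @param scale the [linguistic_scale()] used for conversion; defaults to the
#'   panel's own scale.
#' @param method aggregation rule: `"mode"` (default), `"mean"` or `"median"`.
#' @param criteria optional list of [criterion()] objects (one per panel
#'   criterion); defaults to beneficial criteria with equal weights.
#' @return A [decision_matrix()] whose `"aggregation"` attribute records the
#'   method used.
#' @export
aggregate_panel <- function(panel, scale = NULL, method = c("mode", "mean", "median"),
                            criteria = NULL) {
  if (!inherits(panel, "expert_panel"))
    pr_stop("panel must be an expert_panel", "elicitation_error")
  method <- match.arg(method)
  scale <- scale %||% panel$scale
  m <- length(panel$alternatives)
  k <- length(panel$criteria)
  scores <- matrix(NA_real_, m, k,
                   dimnames = list(panel$alternatives, panel$criteria))
  for (i in seq_len(m)) {
    for (j in seq_len(k)) {
      idx <- match_label(panel$responses[, i, j], scale)
      scores[i, j] <- switch(method,
        mode = {
          tab <- tabulate(idx, nbins = length(scale$values))
          # scale is ordered best-first: which.max's first maximum is the
          # higher-valued label among tied modes
          scale$values[which.max(tab)]
        },
        mean = mean(scale$values[idx]),
        median = stats::median(scale$values[idx])
      )
    }
  }
  if (is.null(criteria)) {
    criteria <- lapply(panel$criteria, function(nm)
      criterion(nm, weight = 1 / k))
  }
  dm <- decision_matrix(scores, criteria)
  attr(dm, "aggregation") <- list(method = method, n_experts = panel$n_experts)
  dm
}
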