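# File formats: delimited text (tab or comma, autodetected on read), '.'
# decimal point. Flows are written with 6-decimal fixed formatting,
# intermediates with 3 decimals in paper mode and 6 otherwise.

# internal: sniff the delimiter of a text file from its header line
sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a decision matrix from delimited text
#'
#' Expected layout: header row of criterion names, first column the
#' alternative identifier, remaining columns one per criterion. Comma- or
#' tab-delimited (autodetected). Row order is preserved.
#'
#' @param path file path.
#' @param criteria optional list of [criterion()] objects; their names must
#'   match the file header (same order). When omitted, criteria default to
#'   beneficial with equal weights.
#' @return A validated [decision_matrix()].
#' @export
read_decision_matrix <- function(path, criteria = NULL) {
  if (!file.exists(path))
    pr_stop(sprintf("file not found: %s", path), "io_error")
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    pr_stop(sprintf("%s: need an id column plus at least one criterion", path),
            "parse_error")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    pr_stop(sprintf("%s: duplicate alternative id: %s", path,
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
            "parse_error")
  if (!is.null(criteria)) {
    want <- vapply(criteria, `[[`, character(1), "name")
    have <- colnames(df)[-1L]
    if (!identical(want, have))
      pr_stop(sprintf("%s: header criteria (%s) do not match config (%s)",
                      path, paste(have, collapse = ", "),
                      paste(want, collapse = ", ")),
              "parse_error")
  }
  num <- suppressWarnings(
    vapply(df[-1L], function(col) as.numeric(col), numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(ids, colnames(df)[-1L]))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad))
    pr_stop(sprintf("%s: non-numeric cell at row '%s', column '%s'", path,
                    ids[bad[1, 1]], colnames(num)[bad[1, 2]]),
            "parse_error")
  dm <- decision_matrix(num, criteria = criteria %||% colnames(num))
  v <- validate_matrix(dm)
  if (!v$ok)
    pr_stop(sprintf("%s: %s", path, paste(v$errors, collapse = "; ")),
            "parse_error")
  dm
}

#' Write a decision matrix as delimited text
#'
#' @param dm a [decision_matrix()].
#' @param path output path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_decision_matrix <- function(dm, path, sep = "\t") {
  df <- data.frame(alternative = dm$alternatives, dm$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expert panel from long-format delimited text
#'
#' Expected columns: `expert_id`, `alternative`, `criterion`, `label`
#' (header required; comma- or tab-delimited). Every expert must rate every
#' (alternative, criterion) cell exactly once.
#'
#' @param path file path.
#' @param scale the [linguistic_scale()] the labels must belong to.
#' @return An [expert_panel()].
#' @export
read_panel <- function(path, scale = default_scale()) {
  if (!file.exists(path))
    pr_stop(sprintf("file not found: %s", path), "io_error")
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("expert_id", "alternative", "criterion", "label")
  if (!all(need %in% colnames(df)))
    pr_stop(sprintf("%s: required columns missing: %s", path,
                    paste(setdiff(need, colnames(df)), collapse = ", ")),
            "parse_error")
  experts <- unique(df$expert_id)
  alts <- unique(df$alternative)
  crits <- unique(df$criterion)
  key <- interaction(df$expert_id, df$alternative, df$criterion, drop = FALSE)
  if (anyDuplicated(key))
    pr_stop(sprintf("%s: duplicate (expert, alternative, criterion) rows", path),
            "parse_error")
  if (nrow(df) != length(experts) * length(alts) * length(crits))
    pr_stop(sprintf(
      "%s: incomplete panel: %d rows but %d experts x %d alternatives x %d criteria",
      path, nrow(df), length(experts), length(alts), length(crits)),
      "parse_error")
  responses <- array(NA_character_,
                     dim = c(length(experts), length(alts), length(crits)))
  ei <- match(df$expert_id, experts)
  ai <- match(df$alternative, alts)
  ci <- match(df$criterion, crits)
  responses[cbind(ei, ai, ci)] <- df$label
  expert_panel(responses, alternatives = alts, criteria = crits, scale = scale)
}

#' Write an expert panel as long-format delimited text
#'
#' @param panel an [expert_panel()].
#' @param path output path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, sep = ",") {
  d <- dim(panel$responses)
  grid <- expand.grid(expert = seq_len(d[1]),
                      alternative = panel$alternatives,
                      criterion = panel$criteria,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- data.frame(expert_id = paste0("E", grid$expert),
                   alternative = grid$alternative,
                   criterion = grid$criterion,
                   label = as.character(panel$responses),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a criteria configuration (JSON or YAML)
#'
#' The config holds a `criteria` list (or is itself that list); each entry
#' has `name`, and optionally `direction`, `weight` and a `pf` block
#' (`kind`, `q`, `p`, `s`).
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return list of [criterion()] objects.
#' @export
read_criteria_config <- function(path) {
  if (!file.exists(path))
    pr_stop(sprintf("file not found: %s", path), "io_error")
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  entries <- cfg$criteria %||% cfg
  if (!length(entries))
    pr_stop(sprintf("%s: no criteria defined", path), "config_error")
  lapply(entries, function(e) {
    if (is.null(e$name)) pr_stop("criterion entry without a name", "config_error")
    pf <- if (is.null(e$pf)) pf_spec("paper-linear") else
      pf_spec(kind = e$pf$kind %||% "paper-linear",
              q = e$pf$q, p = e$pf$p, s = e$pf$s)
    criterion(e$name, direction = e$direction %||% "beneficial",
              weight = e$weight %||% 1, pf = pf)
  })
}

#' Write the outranking graph in DOT format
#'
#' @param edges edge list from [export_outranking_graph()].
#' @param path output `.dot` path.
#' @return `path`, invisibly.
#' @export
write_graph_dot <- function(edges, path) {
  lines <- c(
    "digraph outranking {",
    "  rankdir=LR;",
    sprintf('  "%s" -> "%s" [label="%.3f", weight=%.6f];',
            edges$from, edges$to, edges$weight, edges$weight),
    "}"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write the full result bundle of a pipeline run
#'
#' Writes `normalized.tsv`, `preferences.tsv` (long form: one row per ordered
#' pair with the per-criterion preference degrees and the aggregated index),
#' `flows.tsv` (6-decimal fixed formatting plus ranks), `graph.dot`, and
#' `run_manifest.json` recording mode, rounding, seed, package version and
#' timestamp so the run can be reproduced from the manifest alone.
#'
#' @param result a `promethee_result` from [run_promethee2()].
#' @param out_dir output directory (created if needed).
#' @param seed optional seed to record in the manifest.
#' @param config optional config echo (named list) for the manifest.
#' @param threshold minimum aggregated preference for graph arcs.
#' @return character vector of the files written, invisibly.
#' @export
write_results <- function(result, out_dir, seed = NULL, config = NULL,
                          threshold = 0) {
  if (!inherits(result, "promethee_result"))
    pr_stop("result must be a promethee_result", "io_error")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0)
    pr_stop(sprintf("cannot write to directory: %s", out_dir), "io_error")
  dec <- if (result$mode == "paper") 3L else 6L
  fmt <- function(x, d) formatC(x, digits = d, format = "f")

  norm_path <- file.path(out_dir, "normalized.tsv")
  nv <- result$normalized$values
  utils::write.table(
    data.frame(alternative = rownames(nv),
               apply(nv, 2, fmt, d = dec),
               check.names = FALSE, stringsAsFactors = FALSE),
    norm_path, sep = "\t", quote = FALSE, row.names = FALSE)

  pref_path <- file.path(out_dir, "preferences.tsv")
  pref <- result$preferences$per_criterion
  pi_mat <- result$preferences$aggregated
  alts <- rownames(pi_mat)
  pairs <- expand.grid(y = alts, z = alts, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)[, 2:1]
  pairs <- pairs[pairs$z != pairs$y, ]
  pdf_ <- data.frame(z = pairs$z, y = pairs$y, stringsAsFactors = FALSE)
  for (j in dimnames(pref)[[3]])
    pdf_[[paste0("P_", j)]] <- fmt(pref[cbind(pairs$z, pairs$y, j)], dec)
  pdf_$pi <- fmt(pi_mat[cbind(pairs$z, pairs$y)], dec)
  utils::write.table(pdf_, pref_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  flow_path <- file.path(out_dir, "flows.tsv")
  fl <- result$flows
  utils::write.table(
    data.frame(alternative = fl$alternative,
               phi_plus = fmt(fl$phi_plus, 6),
               phi_minus = fmt(fl$phi_minus, 6),
               phi_net = fmt(fl$phi_net, 6),
               rank = fl$rank, stringsAsFactors = FALSE),
    flow_path, sep = "\t", quote = FALSE, row.names = FALSE)

  graph_path <- file.path(out_dir, "graph.dot")
  write_graph_dot(export_outranking_graph(pi_mat, threshold), graph_path)

  manifest_path <- file.path(out_dir, "run_manifest.json")
  manifest <- list(
    package = "promethee2",
    version = as.character(utils::packageVersion("promethee2")),
    mode = result$mode,
    rounding = if (result$mode == "paper") 3L else NULL,
    weights = as.numeric(result$weights),
    alternatives = alts,
    degenerate_criteria = result$normalized$degenerate,
    graph_threshold = threshold,
    seed = seed,
    config = config,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       null = "null", digits = NA, pretty = TRUE)
  invisible(c(norm_path, pref_path, flow_path, graph_path, manifest_path))
}

#' Read a flow table written by [write_results()]
#'
#' @param path `flows.tsv` path.
#' @return A `flow_table` data.frame.
#' @export
read_flows <- function(path) {
  if (!file.exists(path))
    pr_stop(sprintf("file not found: %s", path), "io_error")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  class(df) <- c("flow_table", "data.frame")
  df
}

#' Write a sensitivity report (text table + JSON twin)
#'
#' @param report a `sensitivity_report`.
#' @param out_dir output directory.
#' @return files written, invisibly.
#' @export
write_sensitivity <- function(report, out_dir) {
  if (!inherits(report, "sensitivity_report"))
    pr_stop("report must be a sensitivity_report", "io_error")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) pr_stop(sprintf("cannot create directory: %s", out_dir), "io_error")
  tsv <- file.path(out_dir, "sensitivity.tsv")
  utils::write.table(report$scenarios, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- file.path(out_dir, "sensitivity.json")
  jsonlite::write_json(
    list(scenarios = report$scenarios, stability = report$stability,
         reversals = report$reversals),
    js, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(tsv, js))
}
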