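#' End-to-end security evaluation
#'
#' Runs the full chain on in-memory inputs: validate -> normalize -> IAHP
#' weights -> entropy weights (computed from the panel, or supplied
#' pre-computed) -> combined weights -> composite index and grades ->
#' obstacle diagnosis. Warnings raised by any stage are collected into
#' `$log`.
#'
#' @param panel an [indicator_panel()].
#' @param comparisons named list of comparison matrices (see
#'   [iahp_weights()]).
#' @param entropy_weights optional named vector of pre-computed entropy
#'   weights; when `NULL` they are computed from the normalized panel.
#' @param k top-k size for the obstacle ranking.
#' @param scale a [grade_scale()].
#' @param grade_on_rounded grade rounded composites? see [security_index()].
#' @param constant_rows,constant_value constant-row policy, see
#'   [normalize_panel()].
#' @return object of class `landsec_eval`: list with `panel`, `normalized`,
#'   `iahp`, `entropy` (`NULL` when weights were supplied), `weights` (data
#'   frame `code`, `layer`, `M`, `W`, `A`, unrounded), `series`
#'   ([security_index()] result), `obstacles` ([obstacle_diagnosis()]
#'   result), `log` (character vector of collected warnings).
#' @export
evaluate_security <- function(panel, comparisons, entropy_weights = NULL,
                              k = 5, scale = grade_scale(),
                              grade_on_rounded = FALSE,
                              constant_rows = c("error", "fill"),
                              constant_value = 0.5) {
  log <- character(0)
  collect <- function(expr, stage) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop_("stage '%s': %s", stage, conditionMessage(e))),
      warning = function(w) {
        log <<- c(log, sprintf("[%s] %s", stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  collect(validate_panel(panel), "validate")
  np <- collect(normalize_panel(panel, constant_rows, constant_value), "normalize")
  iahp <- collect(iahp_weights(comparisons), "iahp")
  ent <- NULL
  if (is.null(entropy_weights)) {
    ent <- collect(panel_entropy_weights(np), "entropy")
    W <- ent$W
  } else {
    W <- entropy_weights
  }
  codes <- panel$metadata$code
  if (!setequal(names(W), codes))
    stop_("stage 'combine': entropy weight codes do not match panel codes")
  W <- W[codes]
  M <- iahp$total
  if (!setequal(names(M), codes))
    stop_("stage 'combine': IAHP codes do not match panel codes")
  M <- M[codes]
  A <- collect(combine_weights(M, W), "combine")
  series <- collect(security_index(np, A, scale, grade_on_rounded), "index")
  obstacles <- collect(obstacle_diagnosis(np, A, k = k), "obstacles")
  weights <- data.frame(code = codes, layer = panel$metadata$layer,
                        M = unname(M), W = unname(W), A = unname(A))
  structure(list(panel = panel, normalized = np, iahp = iahp, entropy = ent,
                 weights = weights, series = series, obstacles = obstacles,
                 log = log),
            class = "landsec_eval")
}

#' @export
print.landsec_eval <- function(x, ...) {
  cat(sprintf("<landsec_eval> %d indicators, %d years\n",
              nrow(x$weights), length(x$series$years)))
  print(x$series$table, row.names = FALSE)
  if (length(x$log)) cat("warnings:\n", paste(" -", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Structural validation of input files
#'
#' Runs every structural validator without computing results, and reports
#' all errors and warnings found instead of stopping at the first.
#'
#' @inheritParams run_pipeline
#' @return data frame with columns `level` (`"error"`/`"warning"`) and
#'   `message`; zero rows means fully valid inputs.
#' @export
validate_inputs <- function(metadata_file, panel_file, matrices_manifest,
                            entropy_weights_file = NULL) {
  findings <- data.frame(level = character(0), message = character(0))
  note <- function(level, msg)
    findings <<- rbind(findings, data.frame(level = level, message = msg))
  try_stage <- function(expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) { note("error", conditionMessage(e)); NULL }),
      warning = function(w) { note("warning", conditionMessage(w)); invokeRestart("muffleWarning") })
  }
  md <- try_stage(read_indicator_metadata(metadata_file))
  if (!is.null(md)) try_stage(read_panel(panel_file, md))
  mats <- try_stage(read_matrix_manifest(matrices_manifest))
  if (!is.null(mats)) for (G in mats) try_stage(validate_comparison(G))
  if (!is.null(entropy_weights_file))
    try_stage(read_entropy_weights(entropy_weights_file))
  findings
}

#' Read a comparison-matrix manifest
#'
#' JSON object mapping `"criterion"` and each layer letter to a comparison
#' matrix CSV (paths relative to the manifest's directory).
#'
#' @param path manifest JSON path.
#' @return named list of [comparison_matrix()] objects.
#' @export
read_matrix_manifest <- function(path) {
  if (!file.exists(path)) stop_("matrices manifest not found: %s", path)
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  lapply(manifest, function(f) {
    fp <- if (file.exists(f)) f else file.path(base, f)
    read_comparison_matrix(fp)
  })
}

#' Run the pipeline from files and write all result artifacts
#'
#' File-level front end to [evaluate_security()]. Writes `weights.csv`
#' (`code,layer,M,W,A`, rounded to `weight_digits`), `series.csv`
#' (`year,T,D,P,S,I,R,grade`), `obstacles.csv` (`year,rank,code,obstacle_pct`),
#' `obstacle_frequency.csv` (`code,count,pct`) and a markdown `report.md`
#' into `output_dir`. Outputs are byte-identical across runs on identical
#' inputs.
#'
#' @param metadata_file indicator metadata CSV.
#' @param panel_file raw panel CSV.
#' @param matrices_manifest JSON manifest of comparison-matrix CSVs.
#' @param output_dir directory for results (created if absent).
#' @param entropy_weights_file optional pre-computed entropy weight CSV.
#' @param k top-k obstacle count.
#' @param weight_digits,index_digits,obstacle_digits reporting precision.
#' @param grade_on_rounded grade the rounded composite values?
#' @param constant_rows,constant_value constant-row policy.
#' @return the [evaluate_security()] result, invisibly.
#' @export
run_pipeline <- function(metadata_file, panel_file, matrices_manifest,
                         output_dir, entropy_weights_file = NULL, k = 5,
                         weight_digits = 4, index_digits = 2,
                         obstacle_digits = 2, grade_on_rounded = FALSE,
                         constant_rows = c("error", "fill"),
                         constant_value = 0.5) {
  md <- read_indicator_metadata(metadata_file)
  panel <- read_panel(panel_file, md)
  comparisons <- read_matrix_manifest(matrices_manifest)
  W <- if (!is.null(entropy_weights_file)) read_entropy_weights(entropy_weights_file)
  res <- evaluate_security(panel, comparisons, entropy_weights = W, k = k,
                           grade_on_rounded = grade_on_rounded,
                           constant_rows = constant_rows,
                           constant_value = constant_value)
  write_results(res, output_dir, weight_digits = weight_digits,
                index_digits = index_digits, obstacle_digits = obstacle_digits)
  invisible(res)
}

#' Write the result CSVs and markdown report
#'
#' @param res a `landsec_eval` from [evaluate_security()].
#' @param output_dir target directory.
#' @inheritParams run_pipeline
#' @return `output_dir`, invisibly.
#' @export
write_results <- function(res, output_dir, weight_digits = 4,
                          index_digits = 2, obstacle_digits = 2) {
  stopifnot(inherits(res, "landsec_eval"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  wt <- res$weights
  for (col in c("M", "W", "A")) wt[[col]] <- round_half_up(wt[[col]], weight_digits)
  utils::write.csv(wt, p("weights.csv"), row.names = FALSE, quote = FALSE)
  ser <- res$series$table
  utils::write.csv(ser, p("series.csv"), row.names = FALSE, quote = FALSE)
  top <- res$obstacles$top[c("year", "rank", "code", "obstacle_pct")]
  utils::write.csv(top, p("obstacles.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(res$obstacles$frequency, p("obstacle_frequency.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(render_report(res, weight_digits, index_digits, obstacle_digits),
             p("report.md"))
  invisible(output_dir)
}

md_table <- function(df) {
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) format(col, trim = TRUE, scientific = FALSE)
    else as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  fmt <- matrix(fmt, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

# report mirrors the CSV values after configured rounding; no recomputation
render_report <- function(res, weight_digits = 4, index_digits = 2,
                          obstacle_digits = 2) {
  wt <- res$weights
  for (col in c("M", "W", "A")) wt[[col]] <- round_half_up(wt[[col]], weight_digits)
  crit <- data.frame(layer = names(res$iahp$criterion),
                     BL = round_half_up(unname(res$iahp$criterion), weight_digits))
  c("# Land ecological security evaluation",
    "",
    "## Criterion-layer weights (IAHP)",
    "", md_table(crit), "",
    "## Indicator weights",
    "",
    "M: improved-AHP total; W: entropy; A: combined = (M + W) / 2.",
    "", md_table(wt), "",
    "## Composite security series",
    "", md_table(res$series$table), "",
    "## Top obstacle factors per year",
    "", md_table(res$obstacles$top[c("year", "rank", "code", "obstacle_pct")]), "",
    "## Obstacle factor frequency",
    "", md_table(res$obstacles$frequency), "",
    "## Appendix: warnings",
    "",
    if (length(res$log)) paste0("- ", res$log) else "none")
}
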