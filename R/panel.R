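#' Indicator system metadata
#'
#' An indicator system lists the evaluation indicators with their DPSIR layer
#' assignment and polarity ("safety tendency"). Positive polarity means larger
#' raw values indicate a more secure land ecological state; negative polarity
#' the opposite (e.g. pesticide usage).
#'
#' @param df data frame with columns `code`, `name`, `layer`, `polarity` and
#'   optionally `units`. `layer` must be one of D, P, S, I, R; `polarity` is
#'   `"positive"`/`"negative"` (the shorthand `"+"`/`"-"` is also accepted).
#' @return the validated data frame with class `indicator_system`, polarity
#'   normalized to `"positive"`/`"negative"`.
#' @export
#' @examples
#' indicator_system(data.frame(
#'   code = c("D_1", "P_1"), name = c("per capita GDP", "economic density"),
#'   layer = c("D", "P"), polarity = c("+", "+"), units = ""
#' ))
indicator_system <- function(df) {
  df <- as.data.frame(df)
  need <- c("code", "name", "layer", "polarity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_("metadata is missing column(s): %s", toString(miss))
  if (!"units" %in% names(df)) df$units <- ""
  df$code <- as.character(df$code)
  dup <- unique(df$code[duplicated(df$code)])
  if (length(dup)) stop_("duplicate indicator code(s): %s", toString(dup))
  bad <- setdiff(unique(df$layer), .layers)
  if (length(bad)) stop_("unknown layer(s): %s (expected D, P, S, I, R)", toString(bad))
  pol <- c("positive" = "positive", "negative" = "negative",
           "+" = "positive", "-" = "negative")
  if (any(is.na(df$polarity)) || !all(df$polarity %in% names(pol)))
    stop_("polarity must be 'positive'/'negative' (or '+'/'-') for every indicator")
  df$polarity <- unname(pol[as.character(df$polarity)])
  rownames(df) <- NULL
  structure(df[, c("code", "name", "layer", "polarity", "units")],
            class = c("indicator_system", "data.frame"))
}

#' Read indicator metadata from CSV
#'
#' Expects a header `code,name,layer,polarity,units` (UTF-8, comma-separated).
#'
#' @param path CSV file path.
#' @return an [indicator_system()] data frame.
#' @export
read_indicator_metadata <- function(path) {
  if (!file.exists(path)) stop_("metadata file not found: %s", path)
  indicator_system(utils::read.csv(path, check.names = FALSE))
}

#' Raw indicator panel
#'
#' Couples an n x m matrix of raw indicator values (rows: indicators, columns:
#' years) with its metadata. Validation is deferred to [validate_panel()],
#' which the constructor calls.
#'
#' @param X numeric matrix, one row per indicator and one column per year.
#' @param metadata an [indicator_system()] covering the rows of `X`, in order.
#' @param years integer year labels, strictly increasing (gaps allowed).
#' @return a list with elements `metadata`, `years`, `X`, of class
#'   `indicator_panel`.
#' @export
indicator_panel <- function(X, metadata, years) {
  metadata <- indicator_system(metadata)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  years <- as.integer(years)
  dimnames(X) <- list(metadata$code, years)
  validate_panel(structure(list(metadata = metadata, years = years, X = X),
                           class = "indicator_panel"))
}

#' Validate an indicator panel
#'
#' Checks completeness (no missing cells), shape agreement between matrix and
#' metadata, year ordering, and layer/polarity validity. Constant-valued rows
#' are legal raw data but break min-max normalization, so they are reported as
#' a warning here and handled explicitly by [normalize_panel()].
#'
#' @param panel an [indicator_panel()].
#' @return the panel, invisibly unchanged, if valid.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "indicator_panel"))
  X <- panel$X
  md <- panel$metadata
  if (nrow(X) != nrow(md))
    stop_("panel has %d rows but metadata describes %d indicators", nrow(X), nrow(md))
  if (ncol(X) != length(panel$years))
    stop_("panel has %d columns but %d year labels", ncol(X), length(panel$years))
  if (length(panel$years) < 2) stop_("a panel needs at least 2 years")
  if (any(diff(panel$years) <= 0)) stop_("years must be strictly increasing")
  if (anyNA(X) || any(!is.finite(X))) {
    bad <- which(is.na(X) | !is.finite(X), arr.ind = TRUE)
    stop_("missing/non-finite cell(s): %s",
          toString(sprintf("%s@%s", md$code[bad[, 1]], panel$years[bad[, 2]])))
  }
  const <- md$code[apply(X, 1, function(r) max(r) == min(r))]
  if (length(const))
    warn_("constant-valued indicator row(s): %s", toString(const))
  invisible(panel)
}

#' Read a raw indicator panel from CSV
#'
#' First column `code`, remaining columns the year labels; rows are matched to
#' `metadata` by code (every metadata code must be present exactly once).
#'
#' @param path CSV file path.
#' @param metadata an [indicator_system()] (or data frame coercible to one).
#' @return an [indicator_panel()].
#' @export
read_panel <- function(path, metadata) {
  if (!file.exists(path)) stop_("panel file not found: %s", path)
  metadata <- indicator_system(metadata)
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "code") stop_("panel CSV must have 'code' as its first column")
  miss <- setdiff(metadata$code, df$code)
  if (length(miss)) stop_("panel is missing indicator(s): %s", toString(miss))
  df <- df[match(metadata$code, df$code), , drop = FALSE]
  years <- as.integer(names(df)[-1])
  if (anyNA(years)) stop_("panel CSV column names after 'code' must be integer years")
  indicator_panel(as.matrix(df[, -1, drop = FALSE]), metadata, years)
}

#' Write a raw indicator panel to CSV
#'
#' Inverse of [read_panel()]; [write_metadata()] emits the matching metadata.
#'
#' @param panel an [indicator_panel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(code = panel$metadata$code, panel$X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @param metadata an [indicator_system()].
#' @export
write_metadata <- function(metadata, path) {
  utils::write.csv(as.data.frame(metadata), path, row.names = FALSE)
  invisible(path)
}

#' Polarity-aware min-max normalization
#'
#' Range-transforms each indicator over the supplied years onto \[0, 1\]:
#' positive indicators by (x - min) / (max - min), negative indicators by
#' (max - x) / (max - min), so that for every indicator 1 is the most secure
#' observed state and 0 the least secure. Each row therefore attains both 0
#' and 1 in some year.
#'
#' A constant row has max = min and no defined normalization; by default it is
#' an error. With `constant_rows = "fill"` the row is replaced by
#' `constant_value` (a neutral 0.5 by default) and a warning names the
#' indicator.
#'
#' @param panel an [indicator_panel()].
#' @param constant_rows `"error"` (default) or `"fill"`.
#' @param constant_value fill value used when `constant_rows = "fill"`.
#' @return a `normalized_panel`: list with `metadata`, `years`, `Y`.
#' @export
#' @examples
#' md <- indicator_system(data.frame(code = c("D_1", "D_2"), name = "x",
#'                                   layer = "D", polarity = c("+", "-")))
#' p <- indicator_panel(rbind(c(2, 4, 6), c(2, 4, 6)), md, 2006:2008)
#' normalize_panel(p)$Y
normalize_panel <- function(panel, constant_rows = c("error", "fill"),
                            constant_value = 0.5) {
  constant_rows <- match.arg(constant_rows)
  validate_panel_quiet(panel)
  X <- panel$X
  lo <- apply(X, 1, min)
  hi <- apply(X, 1, max)
  const <- hi == lo
  if (any(const) && constant_rows == "error")
    stop_("constant indicator row(s) cannot be range-normalized: %s (use constant_rows = 'fill')",
          toString(panel$metadata$code[const]))
  rng <- ifelse(const, 1, hi - lo)
  Y <- (X - lo) / rng
  neg <- panel$metadata$polarity == "negative"
  Y[neg, ] <- 1 - Y[neg, , drop = FALSE]
  if (any(const)) {
    Y[const, ] <- constant_value
    warn_("constant row(s) filled with %g: %s", constant_value,
          toString(panel$metadata$code[const]))
  }
  structure(list(metadata = panel$metadata, years = panel$years, Y = Y),
            class = "normalized_panel")
}

# validation without the constant-row warning (normalize handles those itself)
validate_panel_quiet <- function(panel) {
  withCallingHandlers(validate_panel(panel),
                      warning = function(w) invokeRestart("muffleWarning"))
}

# accept a normalized_panel or a bare matrix already in [0, 1]
as_Y <- function(Y) {
  if (inherits(Y, "normalized_panel")) Y <- Y$Y
  Y <- as.matrix(Y)
  if (any(Y < -1e-12 | Y > 1 + 1e-12))
    stop_("normalized values must lie in [0, 1]")
  pmin(pmax(Y, 0), 1)
}

#' @export
print.indicator_panel <- function(x, ...) {
  cat(sprintf("<indicator_panel> %d indicators x %d years (%d-%d)\n",
              nrow(x$X), length(x$years), min(x$years), max(x$years)))
  invisible(x)
}

#' @export
print.normalized_panel <- function(x, ...) {
  cat(sprintf("<normalized_panel> %d indicators x %d years, range [%.3f, %.3f]\n",
              nrow(x$Y), length(x$years), min(x$Y), max(x$Y)))
  invisible(x)
}
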