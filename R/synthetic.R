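#' Specification for a synthetic indicator panel
#'
#' Describes a DPSIR panel with linear per-indicator trends plus Gaussian
#' noise, mirroring the structure of the Xingtai case (24 indicators in
#' layers D:3, P:8, S:7, I:3, R:3 observed 2006-2017, with the case's mix of
#' positive and negative safety tendencies). Raw values follow
#' `X[i, j] = baseline_i + slope_i * (j - 1) + rnorm(sd = noise_i)`.
#'
#' Per-indicator parameters may be scalars (recycled) or length-n vectors.
#' When they are left `NULL` they are drawn once, deterministically from
#' `seed`: baselines uniform on \[50, 150\], slopes uniform on \[-8, 8\] per
#' year (so the trend spans roughly a quarter of the baseline over a decade),
#' noise standard deviation 5 (visible year-to-year jitter that does not
#' drown the trend). Polarities default to the Xingtai signs when the layer
#' sizes are the default, else alternate +/- within each layer.
#'
#' @param layer_sizes named integer vector of indicators per layer.
#' @param years integer year labels.
#' @param baseline,slope,noise scalar or per-indicator numeric; see above.
#' @param polarity optional per-indicator `"positive"`/`"negative"`.
#' @param seed integer seed controlling both parameter draws and noise.
#' @return a `panel_spec` list.
#' @export
panel_spec <- function(layer_sizes = c(D = 3, P = 8, S = 7, I = 3, R = 3),
                       years = 2006:2017, baseline = NULL, slope = NULL,
                       noise = NULL, polarity = NULL, seed = 42) {
  if (is.null(names(layer_sizes)) || !all(names(layer_sizes) %in% .layers))
    stop_("layer_sizes must be named with DPSIR letters")
  if (any(layer_sizes < 1)) stop_("layer sizes must be positive")
  if (length(years) < 2) stop_("need at least 2 years")
  if (!is.null(noise) && any(noise < 0)) stop_("noise scale must be >= 0")
  structure(list(layer_sizes = layer_sizes, years = as.integer(years),
                 baseline = baseline, slope = slope, noise = noise,
                 polarity = polarity, seed = as.integer(seed)),
            class = "panel_spec")
}

# the Xingtai safety-tendency signs, by code
.xingtai_polarity <- c(
  D_1 = "positive", D_2 = "negative", D_3 = "negative",
  P_1 = "positive", P_2 = "negative", P_3 = "negative", P_4 = "negative",
  P_5 = "negative", P_6 = "negative", P_7 = "positive", P_8 = "positive",
  S_1 = "positive", S_2 = "positive", S_3 = "positive", S_4 = "positive",
  S_5 = "positive", S_6 = "negative", S_7 = "positive",
  I_1 = "positive", I_2 = "positive", I_3 = "positive",
  R_1 = "positive", R_2 = "positive", R_3 = "positive"
)

#' Generate a synthetic indicator panel
#'
#' Deterministic for a given spec (same seed, same panel, bit for bit); uses
#' R's default Mersenne-Twister generator, restoring the caller's RNG state
#' on exit.
#'
#' @param spec a [panel_spec()].
#' @return an [indicator_panel()] that passes [validate_panel()] (constant
#'   rows, possible with zero slope and noise, surface as the usual warning).
#' @export
#' @examples
#' p <- simulate_panel(panel_spec(seed = 1))
#' dim(p$X)
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  n <- sum(spec$layer_sizes)
  m <- length(spec$years)
  codes <- unlist(lapply(names(spec$layer_sizes), function(l)
    paste0(l, "_", seq_len(spec$layer_sizes[[l]]))), use.names = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  expand <- function(x, default) {
    x <- if (is.null(x)) default else x
    if (length(x) == 1) rep(x, n) else if (length(x) == n) x else
      stop_("per-indicator parameters must have length 1 or %d", n)
  }
  baseline <- expand(spec$baseline, stats::runif(n, 50, 150))
  slope <- expand(spec$slope, stats::runif(n, -8, 8))
  noise <- expand(spec$noise, 5)
  polarity <- spec$polarity
  if (is.null(polarity)) {
    polarity <- if (identical(codes, names(.xingtai_polarity)))
      unname(.xingtai_polarity)
    else rep_len(c("positive", "negative"), n)
  }
  polarity <- if (length(polarity) == 1) rep(polarity, n) else polarity
  X <- baseline + outer(slope, seq_len(m) - 1) +
    matrix(stats::rnorm(n * m, sd = rep(noise, m)), n, m)
  md <- indicator_system(data.frame(
    code = codes, name = paste("synthetic", codes),
    layer = code_layer(codes), polarity = polarity, units = "a.u."
  ))
  indicator_panel(X, md, spec$years)
}

#' Comparison matrix from an importance ranking
#'
#' Inverts the 3-scale semantics: given ordered groups of codes (earlier
#' groups strictly more important, within-group equally important), builds
#' the G with `G[i, j] = 2` when i's group precedes j's, 1 within a group,
#' 0 otherwise. The resulting IAHP weights recover the specified order
#' exactly.
#'
#' @param groups list of character vectors, most important first; a plain
#'   character vector is treated as singleton groups.
#' @return a [comparison_matrix()].
#' @export
#' @examples
#' ranking_comparison(list("A", c("B", "C")))
ranking_comparison <- function(groups) {
  if (is.character(groups)) groups <- as.list(groups)
  codes <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(codes)) stop_("each code may appear in exactly one group")
  if (length(codes) < 2) stop_("need at least 2 codes")
  grp <- rep(seq_along(groups), lengths(groups))
  G <- outer(grp, grp, function(a, b) ifelse(a < b, 2, ifelse(a == b, 1, 0)))
  diag(G) <- 1
  comparison_matrix(G, codes)
}

#' Write a comparison matrix to CSV
#'
#' Inverse of [read_comparison_matrix()].
#'
#' @param G a [comparison_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_matrix <- function(G, path) {
  df <- data.frame(code = rownames(G), as.matrix(G), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Emit a complete synthetic input set to a directory
#'
#' Writes everything [run_pipeline()] needs: `metadata.csv`, `panel.csv`,
#' one comparison-matrix CSV per layer plus the criterion layer, and
#' `matrices.json` tying them together. The comparison matrices encode a
#' deterministic importance ranking drawn from the spec's seed, so the
#' implied IAHP weight ordering is known by construction.
#'
#' @param spec a [panel_spec()].
#' @param dir output directory (created if absent).
#' @return named list of the file paths written, invisibly.
#' @export
simulate_inputs <- function(spec, dir) {
  stopifnot(inherits(spec, "panel_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_panel(spec)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed + 1L)
  ranked_cmp <- function(codes) ranking_comparison(as.list(sample(codes)))
  layers <- names(spec$layer_sizes)
  comparisons <- c(list(criterion = ranked_cmp(layers)),
                   stats::setNames(lapply(layers, function(l)
                     ranked_cmp(panel$metadata$code[panel$metadata$layer == l])),
                     layers))
  paths <- list(metadata = file.path(dir, "metadata.csv"),
                panel = file.path(dir, "panel.csv"),
                manifest = file.path(dir, "matrices.json"))
  write_metadata(panel$metadata, paths$metadata)
  write_panel(panel, paths$panel)
  manifest <- stats::setNames(
    sprintf("cmp_%s.csv", names(comparisons)), names(comparisons))
  for (nm in names(comparisons))
    write_comparison_matrix(comparisons[[nm]], file.path(dir, manifest[[nm]]))
  jsonlite::write_json(as.list(manifest), paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
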