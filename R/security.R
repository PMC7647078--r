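#' Combine subjective and objective weights
#'
#' Arithmetic mean of the improved-AHP weights M and the entropy weights W:
#' `A_i = (M_i + W_i) / 2`. Averaging two unit-sum vectors keeps the unit sum
#' while damping both the subjectivity of expert scoring and the
#' data-artefact sensitivity of entropy weighting.
#'
#' @param M named weight vector (subjective, hierarchy-composed).
#' @param W named weight vector (objective, entropy); same codes, same order.
#' @param tol tolerance for the sum-to-one check on the result. Published
#'   4-decimal inputs do not sum to exactly 1; the default accommodates them.
#' @return named combined weight vector `A`.
#' @export
#' @examples
#' combine_weights(c(a = 0.6, b = 0.4), c(a = 0.2, b = 0.8))
combine_weights <- function(M, W, tol = 0.005) {
  if (is.null(names(M)) || is.null(names(W)))
    stop_("both weight vectors must be named by indicator code")
  if (!identical(names(M), names(W)))
    stop_("weight code mismatch: %s",
          toString(union(setdiff(names(M), names(W)), setdiff(names(W), names(M)))))
  A <- (M + W) / 2
  if (abs(sum(A) - 1) > tol)
    stop_("combined weights sum to %.6f; inputs are not unit-sum", sum(A))
  A
}

#' Grade scale for the composite security value
#'
#' Five ordered grades partitioning the composite value: bins are lower-open
#' and upper-closed, so a value sitting exactly on a boundary takes the lower
#' (less secure) grade. The default reproduces the standard scale:
#' V: T <= 0.35, IV: (0.35, 0.55], III: (0.55, 0.65], II: (0.65, 0.85],
#' I: T > 0.85 (grade I is best).
#'
#' @param breaks increasing internal cut points (length = number of grades - 1).
#' @param labels grade labels from worst to best.
#' @return a `grade_scale` object.
#' @export
grade_scale <- function(breaks = c(0.35, 0.55, 0.65, 0.85),
                        labels = c("V", "IV", "III", "II", "I")) {
  if (length(labels) != length(breaks) + 1) stop_("need one more label than breaks")
  if (is.unsorted(breaks, strictly = TRUE)) stop_("breaks must be strictly increasing")
  structure(list(breaks = breaks, labels = labels), class = "grade_scale")
}

#' Classify composite security values into grades
#'
#' Total, order-preserving step function of T; boundary values fall into the
#' lower grade's bin (e.g. 0.35 is grade V, 0.55 is IV under the default
#' scale).
#'
#' @param T numeric composite values.
#' @param scale a [grade_scale()].
#' @return character vector of grade labels, same length and names as `T`.
#' @export
#' @examples
#' classify_security(c(0.28, 0.35, 0.52, 0.66))
classify_security <- function(T, scale = grade_scale()) {
  stopifnot(inherits(scale, "grade_scale"))
  g <- cut(T, breaks = c(-Inf, scale$breaks, Inf), labels = scale$labels,
           right = TRUE)
  stats::setNames(as.character(g), names(T))
}

#' Composite land ecological security series
#'
#' Single-indicator security values `H[i, j] = Y[i, j] * A_i`, composite
#' `T_j = sum_i H[i, j]`, per-layer subscores (sums over each DPSIR layer's
#' indicators) and the per-year grade.
#'
#' @param Y a `normalized_panel` (metadata supplies the layer of each code).
#' @param A named combined weight vector aligned with the panel codes.
#' @param scale a [grade_scale()].
#' @param grade_on_rounded grade the rounded (reported) composite rather than
#'   the full-precision one? Published series are typically graded on their
#'   printed 2-decimal values; default FALSE grades full precision.
#' @param digits decimals for the reported composite and subscores.
#' @return object of class `security_series`: list with `years`, `total`,
#'   `layer_scores` (layers x years), `H`, `grades`, and a rounded `table`
#'   (`year`, `T`, one column per layer, `grade`).
#' @export
security_index <- function(Y, A, scale = grade_scale(),
                           grade_on_rounded = FALSE, digits = 2) {
  stopifnot(inherits(Y, "normalized_panel"))
  codes <- Y$metadata$code
  if (is.null(names(A)) || !identical(names(A), codes))
    stop_("weight codes do not match panel codes")
  H <- Y$Y * A
  total <- colSums(H)
  layer <- factor(Y$metadata$layer, levels = .layers)
  layer_scores <- rowsum(H, layer)
  layer_scores <- layer_scores[intersect(.layers, rownames(layer_scores)), ,
                               drop = FALSE]
  graded_on <- if (grade_on_rounded) round_half_up(total, digits) else total
  grades <- classify_security(graded_on, scale)
  tab <- data.frame(year = Y$years, T = round_half_up(total, digits),
                    round_half_up(t(layer_scores), digits),
                    grade = unname(grades), check.names = FALSE)
  rownames(tab) <- NULL
  structure(list(years = Y$years, total = total, layer_scores = layer_scores,
                 H = H, grades = grades, table = tab),
            class = "security_series")
}

#' @export
print.security_series <- function(x, ...) {
  cat("<security_series>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
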