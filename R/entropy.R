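#' Year-share proportions of a normalized panel
#'
#' For each indicator, the share of each year in the indicator's total:
#' `P[i, j] = Y[i, j] / sum_j Y[i, j]`. Rows of Y that are all zero (possible
#' only for constant-filled indicators) have no defined shares and are mapped
#' to an all-zero row with a warning; [indicator_entropy()] treats such rows
#' as maximally entropic (no information).
#'
#' @param Y a `normalized_panel` or matrix with values in \[0, 1\].
#' @return matrix `P` of the same shape; non-degenerate rows sum to 1.
#' @export
year_proportions <- function(Y) {
  Y <- as_Y(Y)
  tot <- rowSums(Y)
  zero <- tot == 0
  if (any(zero))
    warn_("all-zero normalized row(s) carry no information: %s",
          toString(rownames(Y)[zero] %||% which(zero)))
  P <- Y / ifelse(tot == 0, 1, tot)
  P
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Information entropy of each indicator
#'
#' `E_i = -(1 / ln m) * sum_j P[i, j] * ln P[i, j]` with the convention
#' `0 * ln 0 = 0`, where m is the number of years. E is 1 for an indicator
#' spread uniformly over the years (no information) and 0 for one
#' concentrated in a single year. All-zero rows are assigned E = 1.
#'
#' @param P proportion matrix from [year_proportions()].
#' @param m number of years; defaults to `ncol(P)`.
#' @return named vector of entropies in \[0, 1\].
#' @export
#' @examples
#' indicator_entropy(rbind(rep(0.25, 4), c(1, 0, 0, 0)))
indicator_entropy <- function(P, m = ncol(P)) {
  P <- as.matrix(P)
  if (m < 2) stop_("entropy needs at least 2 years (K = 1/ln(m) undefined)")
  plogp <- ifelse(P > 0, P * log(P), 0)
  E <- -rowSums(plogp) / log(m)
  E[rowSums(P) == 0] <- 1
  E <- pmin(pmax(E, 0), 1)
  stats::setNames(E, rownames(P))
}

#' Entropy weights from indicator entropies
#'
#' `W_i = (1 - E_i) / (n - sum(E))`: the lower an indicator's entropy (the
#' more its values vary across years), the larger its objective weight.
#'
#' @param E entropy vector from [indicator_entropy()].
#' @return named weight vector summing to 1; `W_i = 0` iff `E_i = 1`.
#' @export
entropy_weights <- function(E) {
  n <- length(E)
  if (n < 1) stop_("need at least one indicator")
  if (any(E < -1e-12 | E > 1 + 1e-12)) stop_("entropies must lie in [0, 1]")
  denom <- n - sum(E)
  if (denom <= 1e-12)
    stop_("all indicators have maximum entropy: no information to weight")
  W <- (1 - E) / denom
  check_weights(W, what = "entropy weights")
  W
}

#' Entropy weights straight from a normalized panel
#'
#' Convenience wrapper: [year_proportions()] then [indicator_entropy()] then
#' [entropy_weights()].
#'
#' @param Y a `normalized_panel` or matrix in \[0, 1\].
#' @return list with `P`, `E`, `K` (= 1/ln m) and `W`.
#' @export
panel_entropy_weights <- function(Y) {
  Ym <- as_Y(Y)
  P <- year_proportions(Ym)
  E <- indicator_entropy(P, ncol(Ym))
  list(P = P, E = E, K = 1 / log(ncol(Ym)), W = entropy_weights(E))
}

#' Read pre-computed entropy weights from CSV
#'
#' Alternative input path for reproducing combined weights when the raw panel
#' is unavailable: a two-column CSV `code,weight`.
#'
#' @param path CSV file path.
#' @param tol tolerance on the sum-to-one check.
#' @return named weight vector.
#' @export
read_entropy_weights <- function(path, tol = 0.005) {
  if (!file.exists(path)) stop_("entropy weight file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("code", "weight") %in% names(df)))
    stop_("entropy weight CSV needs columns 'code' and 'weight'")
  W <- stats::setNames(as.numeric(df$weight), as.character(df$code))
  if (abs(sum(W) - 1) > tol)
    warn_("entropy weights sum to %.4f, not 1 (rounded published values?)", sum(W))
  W
}
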