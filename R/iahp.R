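#' Three-scale pairwise comparison matrix
#'
#' The improved AHP scores relative importance on three levels: `G[i, j]` is
#' 0 if element i is less important than j, 1 if equally important, 2 if more
#' important. Reciprocity requires `G[i, j] + G[j, i] == 2` and a unit
#' diagonal. Unlike Saaty's 1-9 scale, no consistency ratio is needed: the
#' optimal-transfer construction below yields a perfectly consistent judgment
#' matrix for any valid G.
#'
#' @param G square numeric matrix with entries in \{0, 1, 2\}.
#' @param codes element identifiers; defaults to `rownames(G)`.
#' @return `G` with class `comparison_matrix` and codes as dimnames.
#' @export
comparison_matrix <- function(G, codes = rownames(G)) {
  G <- as.matrix(G)
  if (is.null(codes)) codes <- paste0("e", seq_len(nrow(G)))
  dimnames(G) <- list(codes, codes)
  validate_comparison(structure(G, class = c("comparison_matrix", "matrix")))
}

#' Validate a comparison matrix
#'
#' Structural rules only: square, size >= 2, entries in \{0, 1, 2\}, unit
#' diagonal, reciprocity `G[i, j] + G[j, i] == 2`. Ordinal intransitivity
#' (i beats j beats k beats i) is self-repairing under the transfer-matrix
#' construction, so it triggers at most a warning.
#'
#' @param G a [comparison_matrix()] (or plain matrix).
#' @param warn_intransitive warn on preference cycles among triples?
#' @return `G`, invisibly, if valid.
#' @export
validate_comparison <- function(G, warn_intransitive = TRUE) {
  G <- as.matrix(G)
  n <- nrow(G)
  if (n != ncol(G) || n < 2) stop_("comparison matrix must be square with size >= 2")
  if (!all(G %in% c(0, 1, 2))) stop_("comparison entries must be 0, 1 or 2")
  if (any(diag(G) != 1)) stop_("comparison diagonal must be all 1")
  bad <- which(G + t(G) != 2, arr.ind = TRUE)
  bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
  if (nrow(bad)) {
    cd <- if (!is.null(rownames(G))) rownames(G) else as.character(seq_len(n))
    stop_("reciprocity violated (G[i,j] + G[j,i] != 2) at: %s",
          toString(sprintf("(%s,%s)", cd[bad[, 1]], cd[bad[, 2]])))
  }
  if (warn_intransitive && n >= 3) {
    pref <- G == 2
    # cycle i>j, j>k, k>i among any triple
    cyc <- pref & t(pref %*% pref > 0)
    if (any(cyc & upper.tri(cyc)))
      warn_("ordinal intransitivity detected (preference cycle); weights remain well-defined")
  }
  invisible(G)
}

#' Read a comparison matrix from CSV
#'
#' Header row and first column both carry the element codes; cells are 0/1/2.
#'
#' @param path CSV file path.
#' @return a [comparison_matrix()].
#' @export
read_comparison_matrix <- function(path) {
  if (!file.exists(path)) stop_("comparison matrix file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  codes <- as.character(df[[1]])
  G <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(G), codes))
    stop_("comparison CSV row and column codes differ in %s", path)
  comparison_matrix(G, codes)
}

#' Optimal transfer matrix
#'
#' Maps the ordinal 0/1/2 comparisons onto a consistent additive scale. With
#' `T = G - 1` (so entries -1/0/+1, antisymmetric under reciprocity) and row
#' sums `r_i = sum_k T[i, k]`, the optimal transfer matrix is
#' `B[i, j] = (r_i - r_j) / n`, the least-squares consistent approximation of
#' T; equivalently `B[i, j] = mean_k(T[i, k] + T[k, j])`.
#'
#' @param G a [comparison_matrix()].
#' @return antisymmetric matrix `B` with attribute `r` (the row sums of T).
#' @export
optimal_transfer <- function(G) {
  validate_comparison(G, warn_intransitive = FALSE)
  Tm <- as.matrix(G) - 1
  r <- rowSums(Tm)
  n <- nrow(Tm)
  B <- outer(r, r, "-") / n
  dimnames(B) <- dimnames(G)
  structure(B, r = r)
}

#' Consistent judgment matrix
#'
#' Exponentiates the transfer matrix: `Q[i, j] = exp(B[i, j])`. Because B is
#' additively consistent (`B[i, j] + B[j, k] = B[i, k]`), Q is a perfectly
#' consistent positive reciprocal matrix, whose principal eigenvalue equals
#' its order.
#'
#' @param B antisymmetric transfer matrix from [optimal_transfer()].
#' @return positive matrix `Q`.
#' @export
judgment_matrix <- function(B) {
  B <- as.matrix(B)
  if (max(abs(B + t(B))) > 1e-9) stop_("transfer matrix must be antisymmetric")
  exp(B)
}

#' Layer weights by the product square (geometric mean) method
#'
#' The normalized geometric means of the rows of Q approximate the principal
#' eigenvector; for the perfectly consistent Q produced by
#' [judgment_matrix()] they equal it exactly.
#'
#' @param Q positive judgment matrix with codes as dimnames.
#' @return named weight vector summing to 1.
#' @export
#' @examples
#' G <- comparison_matrix(rbind(c(1, 2), c(0, 1)), c("A", "B"))
#' layer_weights(judgment_matrix(optimal_transfer(G)))
layer_weights <- function(Q) {
  Q <- as.matrix(Q)
  if (any(Q <= 0)) stop_("judgment matrix must be strictly positive")
  g <- exp(rowMeans(log(Q)))
  w <- g / sum(g)
  names(w) <- rownames(Q)
  check_weights(w, what = "layer weights")
  w
}

#' Compose hierarchical weights
#'
#' Total weight of an indicator is its criterion-layer weight times its
#' within-layer weight. With exact (unrounded) inputs the result sums to 1;
#' no renormalization is applied, so rounded inputs reproduce a rounded
#' composition.
#'
#' @param criterion named weight vector over layers.
#' @param per_layer named list of within-layer weight vectors (names are
#'   layer letters; elements named by indicator code).
#' @param layer_of optional named character vector mapping indicator code to
#'   layer; defaults to the prefix before `_` in each code.
#' @return named total weight vector over all indicators, in per-layer order.
#' @export
compose_hierarchy <- function(criterion, per_layer, layer_of = NULL) {
  if (is.null(names(criterion))) stop_("criterion weights must be named by layer")
  out <- numeric(0)
  for (layer in names(per_layer)) {
    w <- per_layer[[layer]]
    lay <- if (is.null(layer_of)) rep(layer, length(w)) else layer_of[names(w)]
    if (any(lay != layer))
      stop_("indicator(s) %s mapped to layer %s but listed under %s",
            toString(names(w)[lay != layer]), toString(unique(lay)), layer)
    if (!layer %in% names(criterion))
      stop_("layer %s has no criterion weight", layer)
    out <- c(out, criterion[[layer]] * w)
  }
  out
}

#' Full improved-AHP weighting of an indicator hierarchy
#'
#' Runs comparison -> transfer -> judgment -> geometric-mean weights for the
#' criterion layer and every indicator layer, then composes total weights.
#'
#' Reported (rounded) columns follow the display convention that the printed
#' total is the product of the printed factors: `M` in `$report` is
#' round(round(BL, digits) * round(BP, digits), digits), keeping all displayed
#' columns mutually consistent. `$total` keeps full precision and is what the
#' rest of the pipeline consumes.
#'
#' @param comparisons named list of [comparison_matrix()] objects: one
#'   element `criterion` (codes = layer letters) plus one per layer letter.
#' @param digits decimals for the `$report` table (default 4).
#' @return object of class `iahp_weights`: list with `criterion`, `within`,
#'   `total` (named, unrounded) and `report` (data frame `code`, `layer`,
#'   `BL`, `BP`, `M`).
#' @export
iahp_weights <- function(comparisons, digits = 4) {
  if (!"criterion" %in% names(comparisons))
    stop_("comparisons must contain a 'criterion' matrix")
  crit_G <- comparisons$criterion
  crit <- layer_weights(judgment_matrix(optimal_transfer(crit_G)))
  layers <- setdiff(names(comparisons), "criterion")
  miss <- setdiff(layers, names(crit))
  if (length(miss)) stop_("layer(s) %s missing from the criterion matrix", toString(miss))
  layers <- layers[order(match(layers, names(crit)))]
  per_layer <- lapply(comparisons[layers], function(G)
    layer_weights(judgment_matrix(optimal_transfer(G))))
  total <- compose_hierarchy(crit, per_layer)
  check_weights(total, tol = 1e-9, what = "total IAHP weights")
  BL <- unlist(lapply(layers, function(l) rep(crit[[l]], length(per_layer[[l]]))))
  BP <- unlist(per_layer[layers], use.names = TRUE)
  codes <- unlist(lapply(per_layer[layers], names), use.names = FALSE)
  report <- data.frame(
    code = codes,
    layer = rep(layers, vapply(per_layer[layers], length, 1L)),
    BL = round_half_up(BL, digits),
    BP = round_half_up(unname(BP), digits),
    row.names = NULL
  )
  report$M <- round_half_up(report$BL * report$BP, digits)
  structure(list(criterion = crit, within = per_layer,
                 total = stats::setNames(unname(total), codes), report = report),
            class = "iahp_weights")
}

#' @export
print.iahp_weights <- function(x, ...) {
  cat("<iahp_weights> criterion layer:\n")
  print(round_half_up(x$criterion, 4))
  cat("indicator totals (rounded report):\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
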