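# Independent oracles and small generators shared across tests.

# principal eigenvector by brute-force power iteration (oracle for the
# geometric-mean "product square" path; deliberately independent of it)
power_iteration <- function(Q, iter = 500, tol = 1e-14) {
  v <- rep(1 / nrow(Q), nrow(Q))
  for (i in seq_len(iter)) {
    v2 <- as.vector(Q %*% v)
    v2 <- v2 / sum(v2)
    if (max(abs(v2 - v)) < tol) break
    v <- v2
  }
  stats::setNames(v2, rownames(Q))
}

# closed form for the end-to-end IAHP weights: exp(r_i/n) / sum exp(r_k/n)
# with r the row sums of G - 1
closed_form_weights <- function(G) {
  r <- rowSums(as.matrix(G) - 1)
  e <- exp(r / nrow(G))
  stats::setNames(e / sum(e), rownames(G))
}

# random structurally valid 0/1/2 comparison matrix (often intransitive,
# which is legal and only warns -- silenced here)
random_comparison <- function(n) {
  G <- matrix(1, n, n)
  G[upper.tri(G)] <- sample(0:2, sum(upper.tri(G)), replace = TRUE)
  tG <- t(G)
  G[lower.tri(G)] <- 2 - tG[lower.tri(G)]
  suppressWarnings(comparison_matrix(G, paste0("e", seq_len(n))))
}

# normalized panel straight from a [0,1] matrix, with minimal metadata
make_np <- function(Y, layers = NULL) {
  codes <- rownames(Y)
  if (is.null(codes)) codes <- paste0("D_", seq_len(nrow(Y)))
  if (is.null(layers)) layers <- sub("_.*", "", codes)
  md <- indicator_system(data.frame(code = codes, name = codes, layer = layers,
                                    polarity = "positive", units = ""))
  years <- as.integer(colnames(Y) %||% (2000 + seq_len(ncol(Y))))
  structure(list(metadata = md, years = years,
                 Y = matrix(as.numeric(Y), nrow(Y), dimnames = list(codes, years))),
            class = "normalized_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# raw panel from a matrix + polarities
make_panel <- function(X, polarity = "positive", years = NULL) {
  codes <- rownames(X) %||% paste0("D_", seq_len(nrow(X)))
  md <- data.frame(code = codes, name = codes, layer = sub("_.*", "", codes),
                   polarity = polarity, units = "")
  indicator_panel(X, md, years %||% (2000 + seq_len(ncol(X))))
}

# printed reference values for the Xingtai case (criterion, within-layer and
# total weight columns), used by several suites
xingtai_within <- c(
  D_1 = 0.4484, D_2 = 0.3213, D_3 = 0.2302,
  P_1 = 0.0520, P_2 = 0.1102, P_3 = 0.0668, P_4 = 0.2332, P_5 = 0.2332,
  P_6 = 0.1102, P_7 = 0.0972, P_8 = 0.0972,
  S_1 = 0.0556, S_2 = 0.1310, S_3 = 0.0984, S_4 = 0.2319, S_5 = 0.2010,
  S_6 = 0.1511, S_7 = 0.1310,
  I_1 = 0.1483, I_2 = 0.2889, I_3 = 0.5627,
  R_1 = 0.1554, R_2 = 0.4223, R_3 = 0.4223
)
xingtai_criterion <- c(D = 0.0774, P = 0.3834, S = 0.1411, I = 0.2570, R = 0.1411)
xingtai_M <- c(
  D_1 = 0.0347, D_2 = 0.0249, D_3 = 0.0178,
  P_1 = 0.0199, P_2 = 0.0423, P_3 = 0.0256, P_4 = 0.0894, P_5 = 0.0894,
  P_6 = 0.0423, P_7 = 0.0373, P_8 = 0.0373,
  S_1 = 0.0078, S_2 = 0.0185, S_3 = 0.0139, S_4 = 0.0327, S_5 = 0.0284,
  S_6 = 0.0213, S_7 = 0.0185,
  I_1 = 0.0381, I_2 = 0.0742, I_3 = 0.1446,
  R_1 = 0.0219, R_2 = 0.0596, R_3 = 0.0596
)
xingtai_A <- c(
  D_1 = 0.0392, D_2 = 0.0318, D_3 = 0.0207,
  P_1 = 0.0275, P_2 = 0.0377, P_3 = 0.0379, P_4 = 0.0633, P_5 = 0.0777,
  P_6 = 0.0334, P_7 = 0.0355, P_8 = 0.0272,
  S_1 = 0.0335, S_2 = 0.0273, S_3 = 0.0277, S_4 = 0.0422, S_5 = 0.0394,
  S_6 = 0.0418, S_7 = 0.0275,
  I_1 = 0.0432, I_2 = 0.0647, I_3 = 0.0996,
  R_1 = 0.0246, R_2 = 0.0479, R_3 = 0.0488
)
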