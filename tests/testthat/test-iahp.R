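test_that("comparison-matrix validation enforces the 0/1/2 reciprocal structure", {
  xt <- xingtai_case()
  expect_invisible(validate_comparison(xt$comparisons$criterion))

  G <- rbind(c(1, 0), c(0, 1))
  expect_error(comparison_matrix(G, c("A", "B")), "reciprocity.*\\(A,B\\)")
  expect_error(comparison_matrix(rbind(c(1, 3), c(-1, 1))), "0, 1 or 2")
  expect_error(comparison_matrix(rbind(c(2, 2), c(0, 1))), "diagonal")

  # all-indifferent matrix: valid, and no intransitivity warning
  expect_silent(validate_comparison(comparison_matrix(matrix(1, 3, 3))))

  # a preference cycle warns but does not fail
  cyc <- rbind(c(1, 2, 0), c(0, 1, 2), c(2, 0, 1))
  expect_warning(comparison_matrix(cyc), "intransitivity")
})

test_that("optimal transfer matrix follows the row-sum closed form", {
  xt <- xingtai_case()
  B <- optimal_transfer(xt$comparisons$criterion)
  # row sums of T = G - 1 for the criterion matrix, computed by hand
  expect_equal(unname(attr(B, "r")), c(-4, 4, -1, 2, -1))
  expect_equal(B["D", "P"], -8 / 5)
  expect_equal(max(abs(B + t(B))), 0)                        # antisymmetry
  expect_equal(optimal_transfer(comparison_matrix(matrix(1, 4, 4))),
               matrix(0, 4, 4), ignore_attr = TRUE)          # indifference

  Q <- judgment_matrix(B)
  expect_equal(Q["P", "D"], exp(8 / 5))
  expect_equal(Q * t(Q), matrix(1, 5, 5), ignore_attr = TRUE) # reciprocal
  # multiplicative consistency Q_ij * Q_jk = Q_ik
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_equal(Q[i, j] * Q[j, k], Q[i, k], tolerance = 1e-9)
  expect_equal(judgment_matrix(matrix(0, 3, 3)), matrix(1, 3, 3))
  expect_error(judgment_matrix(rbind(c(0, 1), c(1, 0))), "antisymmetric")
})

test_that("geometric-mean weights reproduce the Xingtai within-layer blocks", {
  xt <- xingtai_case()
  w_of <- function(G) layer_weights(judgment_matrix(optimal_transfer(G)))
  expect_equal(round_half_up(unname(w_of(xt$comparisons$criterion)), 4),
               unname(xingtai_criterion))
  expect_equal(round_half_up(unname(w_of(xt$comparisons$D)), 4),
               c(0.4484, 0.3213, 0.2302))
  expect_equal(round_half_up(unname(w_of(xt$comparisons$I)), 4),
               c(0.1483, 0.2889, 0.5627))
  expect_equal(unname(w_of(comparison_matrix(matrix(1, 3, 3)))), rep(1 / 3, 3))
})

test_that("hierarchical composition multiplies layer by within-layer weight", {
  # printed-value compositions
  expect_equal(round_half_up(0.2570 * 0.5627, 4), 0.1446)  # I_3
  expect_equal(round_half_up(0.0774 * 0.4484, 4), 0.0347)  # D_1
  crit <- c(D = 0.3, P = 0.7)
  per <- list(D = c(D_1 = 0.5, D_2 = 0.5), P = c(P_1 = 1))
  tot <- compose_hierarchy(crit, per)
  expect_equal(tot, c(D_1 = 0.15, D_2 = 0.15, P_1 = 0.7))
  # single layer with weight 1: within-layer weights unchanged
  expect_equal(compose_hierarchy(c(D = 1), list(D = c(D_1 = 0.25, D_2 = 0.75))),
               c(D_1 = 0.25, D_2 = 0.75))
  # indicator mapped to a layer absent from the criterion
  expect_error(compose_hierarchy(c(D = 1), list(S = c(S_1 = 1))), "criterion")
  expect_error(iahp_weights(list(D = comparison_matrix(matrix(1, 2, 2)))),
               "criterion")
})

test_that("pipeline weights agree with closed form, eigenvector oracle and permutation", {
  set.seed(101)
  for (rep in 1:30) {
    n <- sample(3:9, 1)
    G <- random_comparison(n)
    Q <- judgment_matrix(optimal_transfer(G))
    w <- layer_weights(Q)
    expect_equal(unname(w), unname(closed_form_weights(G)), tolerance = 1e-12)
    expect_equal(unname(w), unname(power_iteration(Q)), tolerance = 1e-10)
    # permuting element order permutes weights identically
    perm <- sample(n)
    Gp <- suppressWarnings(comparison_matrix(as.matrix(G)[perm, perm],
                                             rownames(G)[perm]))
    wp <- layer_weights(judgment_matrix(optimal_transfer(Gp)))
    expect_equal(wp, w[perm], tolerance = 1e-12)
  }
})
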