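test_that("deviations complement the normalized values", {
  Y <- rbind(D_1 = c(1, 0, 0.25))
  expect_equal(unname(deviation_matrix(Y)[1, ]), c(0, 1, 0.75))
})

test_that("obstacle degrees weight deviations and normalize per year", {
  codes <- c("D_1", "P_1", "S_1")
  A <- stats::setNames(c(0.5, 0.3, 0.2), codes)
  # uniform deviations cancel: F reduces to the weights
  N_unif <- matrix(0.4, 3, 4, dimnames = list(codes, 2006:2009))
  Fm <- obstacle_degrees(N_unif, A)
  expect_equal(Fm, matrix(A, 3, 4, dimnames = dimnames(N_unif)),
               tolerance = 1e-12)
  # a single deviating factor takes the whole obstacle share
  N_one <- matrix(0, 3, 2, dimnames = list(codes, 2006:2007))
  N_one[2, ] <- 0.1
  expect_equal(unname(obstacle_degrees(N_one, A)[2, ]), c(1, 1))
  # columns always sum to 1
  set.seed(31)
  N <- matrix(runif(15), 3, 5, dimnames = list(codes, 2006:2010))
  expect_equal(unname(colSums(obstacle_degrees(N, A))), rep(1, 5))
  # perfect-security year: all-zero with a warning
  N0 <- matrix(0, 3, 1, dimnames = list(codes, 2006))
  expect_warning(F0 <- obstacle_degrees(N0, A), "perfect security")
  expect_equal(unname(F0[, 1]), c(0, 0, 0))
  expect_error(obstacle_degrees(N, A[1:2]), "length")
})

test_that("obstacle degrees are scale-invariant and antitone in Y", {
  codes <- paste0("P_", 1:6)
  A <- stats::setNames(prop.table(1:6), codes)
  set.seed(32)
  N <- matrix(runif(6 * 4, 0.1, 0.9), 6, 4, dimnames = list(codes, 2006:2009))
  F1 <- obstacle_degrees(N, A)
  # uniformly rescaling one year's deviation column changes nothing
  N2 <- N
  N2[, 2] <- N[, 2] * 0.37
  expect_equal(obstacle_degrees(N2, A), F1, tolerance = 1e-12)
  # increasing Y (decreasing N) never increases that factor's obstacle degree
  N3 <- N
  N3[4, 3] <- N[4, 3] * 0.5
  expect_lte(obstacle_degrees(N3, A)[4, 3], F1[4, 3])
})

test_that("top-k ranking orders by degree with the documented tie rule", {
  codes <- c("D_1", "P_2", "P_10", "S_1")
  F <- matrix(c(0.1, 0.4, 0.4, 0.1), 4, 1, dimnames = list(codes, 2006))
  top <- top_obstacles(F, k = 4)
  # ties broken by layer order D,P,S,I,R then numeric index; all ties flagged
  expect_equal(top$code, c("P_2", "P_10", "D_1", "S_1"))
  expect_true(all(top$tie))
  expect_equal(top$rank, 1:4)
  # k = n gives the full ranking; percentages are 2-dp percents
  expect_equal(sum(top$obstacle_pct), 100)
  expect_error(top_obstacles(F, k = 9), "between")

  set.seed(33)
  F2 <- matrix(prop.table(runif(5)), 5, 1,
               dimnames = list(paste0("P_", 1:5), 2006))
  t2 <- top_obstacles(F2, k = 3)
  expect_true(all(diff(t2$obstacle_pct) <= 0))
  expect_false(any(t2$tie))
})

test_that("frequency summary reproduces the reference Xingtai bookkeeping", {
  xt <- xingtai_case()
  freq <- obstacle_frequency(xt$obstacle_top5)
  ref_counts <- c(P_3 = 1L, P_4 = 6L, P_5 = 11L, P_7 = 2L, S_3 = 1L,
                  S_6 = 9L, I_1 = 3L, I_2 = 10L, I_3 = 11L, R_2 = 2L, R_3 = 4L)
  ref_pct <- c(8.33, 50.00, 91.67, 16.67, 8.33, 75.00, 25.00, 83.33,
               91.67, 16.67, 33.33)
  expect_equal(stats::setNames(freq$count, freq$code), ref_counts)
  expect_equal(freq$pct, ref_pct)
  # total appearances = k x years
  expect_equal(sum(freq$count), 5L * 12L)
  # degenerate single-year ranking
  one <- data.frame(year = 2006, rank = 1, code = "P_5")
  f1 <- obstacle_frequency(one)
  expect_equal(f1$count, 1L)
  expect_equal(f1$pct, 100)
  expect_error(obstacle_frequency(one[0, ]), "empty")
})

test_that("obstacle diagnosis bundles consistent pieces", {
  np <- normalize_panel(simulate_panel(panel_spec(seed = 12)))
  A <- stats::setNames(rep(1 / 24, 24), np$metadata$code)
  d <- obstacle_diagnosis(np, A, k = 5)
  expect_equal(unname(colSums(d$F)), rep(1, 12), tolerance = 1e-10)
  expect_equal(unname(colSums(d$layer_obstacles)), rep(1, 12), tolerance = 1e-10)
  expect_equal(nrow(d$top), 5 * 12)
  expect_equal(sum(d$frequency$count), 60L)
  # F is zero wherever Y is ideal
  expect_true(all(d$F[np$Y == 1] == 0))
})
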