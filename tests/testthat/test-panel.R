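test_that("panel validation catches structural defects and names offenders", {
  md <- data.frame(code = c("D_1", "P_1"), name = c("a", "b"),
                   layer = c("D", "P"), polarity = c("+", "-"), units = "")
  p <- indicator_panel(rbind(c(1, 2, 3), c(4, 5, 6)), md, 2006:2008)
  expect_s3_class(p, "indicator_panel")
  expect_invisible(validate_panel(p))

  # missing cell: error names indicator and year
  p_bad <- p
  p_bad$X[2, 2] <- NA
  expect_error(validate_panel(p_bad), "P_1@2007")

  # duplicate codes
  md_dup <- md
  md_dup$code <- c("D_1", "D_1")
  expect_error(indicator_system(md_dup), "duplicate")

  # unknown layer / polarity
  expect_error(indicator_system(transform(md, layer = c("D", "X"))), "unknown layer")
  expect_error(indicator_system(transform(md, polarity = c("+", "up"))), "polarity")

  # shape and year checks
  expect_error(indicator_panel(rbind(c(1, 2), c(3, 4)), md, 2008:2007),
               "strictly increasing")
  expect_error(indicator_panel(matrix(1:2, 2, 1), md, 2006), "at least 2 years")

  # constant row warns with the indicator's name
  expect_warning(
    p_const <- indicator_panel(rbind(c(5, 5, 5), c(4, 5, 6)), md, 2006:2008),
    "D_1")
  expect_warning(validate_panel(p_const), "D_1")
})

test_that("min-max normalization maps polarities onto [0, 1] with exact endpoints", {
  md <- data.frame(code = c("D_1", "D_2"), name = "x", layer = "D",
                   polarity = c("positive", "negative"), units = "")
  p <- indicator_panel(rbind(c(2, 4, 6), c(2, 4, 6)), md, 2006:2008)
  np <- normalize_panel(p)
  expect_equal(unname(np$Y[1, ]), c(0, 0.5, 1))   # positive: forced linear map
  expect_equal(unname(np$Y[2, ]), c(1, 0.5, 0))   # negative: reversed
  # the year attaining a positive indicator's max gets exactly 1
  expect_identical(np$Y[1, which.max(p$X[1, ])], 1)

  # constant rows: error by default, fill-with-warning when enabled
  pc <- suppressWarnings(make_panel(rbind(D_1 = c(3, 3, 3), D_2 = c(1, 2, 3))))
  expect_error(normalize_panel(pc), "D_1")
  expect_warning(npc <- normalize_panel(pc, constant_rows = "fill"), "D_1")
  expect_equal(unname(npc$Y[1, ]), rep(0.5, 3))
})

test_that("normalization is affine-invariant, polarity-symmetric and bounded", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(6 * 8, 100, 20), 6, 8)
    rownames(X) <- paste0("D_", 1:6)
    p_pos <- make_panel(X, "positive")
    np <- normalize_panel(p_pos)
    expect_true(all(np$Y >= 0 & np$Y <= 1))
    # each row attains both endpoints
    expect_equal(unname(apply(np$Y, 1, min)), rep(0, 6))
    expect_equal(unname(apply(np$Y, 1, max)), rep(1, 6))
    # positive affine rescaling of the raw rows leaves Y unchanged
    a <- runif(6, 0.5, 3)
    b <- rnorm(6, 0, 50)
    np2 <- normalize_panel(make_panel(X * a + b, "positive"))
    expect_equal(np2$Y, np$Y, tolerance = 1e-12)
    # flipping polarity maps Y to 1 - Y
    np_neg <- normalize_panel(make_panel(X, "negative"))
    expect_equal(np_neg$Y, 1 - np$Y, tolerance = 1e-12)
  }
})

test_that("metadata and panel CSVs round-trip exactly", {
  p <- simulate_panel(panel_spec(seed = 3))
  dir <- withr::local_tempdir()
  write_metadata(p$metadata, file.path(dir, "md.csv"))
  write_panel(p, file.path(dir, "panel.csv"))
  md2 <- read_indicator_metadata(file.path(dir, "md.csv"))
  p2 <- read_panel(file.path(dir, "panel.csv"), md2)
  expect_equal(as.data.frame(md2), as.data.frame(p$metadata))
  expect_equal(p2$X, p$X, tolerance = 1e-12)
  expect_identical(p2$years, p$years)
})
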