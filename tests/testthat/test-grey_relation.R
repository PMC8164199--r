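test_that("absolute differences and extremes reproduce the reference table to 6 decimals", {
  diffs <- gra_differences(ref_panel())
  for (col in colnames(published_differences)) {
    expect_equal(diffs[[col]], unname(published_differences[, col]),
      tolerance = 5e-7, ignore_attr = TRUE
    )
  }
  expect_equal(attr(diffs, "column_min")[names(published_extremes$min)],
    published_extremes$min,
    tolerance = 5e-7
  )
  expect_equal(attr(diffs, "column_max")[names(published_extremes$max)],
    published_extremes$max,
    tolerance = 5e-7
  )
  expect_equal(attr(diffs, "global_min"), 0.398000, tolerance = 5e-7)
  expect_equal(attr(diffs, "global_max"), 0.999999, tolerance = 5e-7)
})

test_that("per-sequence coefficients and degrees reproduce the reference tables", {
  res <- run_gra(ref_panel())
  for (col in colnames(published_coefficients)) {
    expect_equal(res$coefficients[[col]], unname(published_coefficients[, col]),
      tolerance = 1e-3, ignore_attr = TRUE
    )
  }
  expect_equal(res$degrees$degree, unname(published_degrees), tolerance = 1e-3)
  # spot cells: DEHP/daphnid coefficient, the all-minimum BCHP row
  expect_equal(res$coefficients$daphnid[1], 0.6027, tolerance = 1e-3)
  bchp <- as.numeric(res$coefficients[res$coefficients$compound == "BCHP", -1])
  expect_equal(bchp, rep(1, 4))
})

test_that("global normalization follows the double-extremum formula and diverges from per-sequence", {
  panel <- ref_panel()
  per_seq <- run_gra(panel, gra_config(normalization = "per_sequence"))
  glob <- run_gra(panel, gra_config(normalization = "global"))
  # hand evaluation of both conventions for the DEHP/fish cell
  delta <- 0.990000
  expect_equal(per_seq$coefficients$fish[1],
    (0.583 + 0.5 * 0.999817) / (delta + 0.5 * 0.999817),
    tolerance = 1e-6
  )
  expect_equal(glob$coefficients$fish[1],
    (0.398 + 0.5 * 0.999999) / (delta + 0.5 * 0.999999),
    tolerance = 1e-6
  )
  expect_equal(glob$coefficients$fish[1], 0.6027, tolerance = 1e-3)
  expect_gt(abs(glob$coefficients$fish[1] - 0.7268), 0.1)
  # full-matrix agreement with the literal oracle under both conventions
  vals <- as.matrix(as.data.frame(panel[receptor_ids(panel)]))
  for (norm in c("per_sequence", "global")) {
    oracle <- literal_gra(vals, normalization = norm)
    ours <- run_gra(panel, gra_config(normalization = norm))
    expect_equal(as.matrix(as.data.frame(ours$coefficients[-1])), oracle$xi,
      tolerance = 1e-12, ignore_attr = TRUE
    )
  }
})

test_that("degrees are weighted horizontal means and weights are validated", {
  panel <- ref_panel()
  res <- run_gra(panel)
  # equal weights = arithmetic mean of the compound's coefficients
  expect_equal(
    res$degrees$degree,
    rowMeans(as.matrix(as.data.frame(res$coefficients[-1])))
  )
  # degenerate weight on the fish sequence alone returns that coefficient
  w <- c(0, 0, 0, 1) # panel column order: green_algae, daphnid, mysid, fish
  res_w <- run_gra(panel, gra_config(weights = w))
  expect_equal(res_w$degrees$degree[1], 0.7268, tolerance = 1e-3)
  expect_error(
    gra_degrees(res$coefficients, gra_config(weights = c(0.5, 0.5))),
    class = "greytox_error_config"
  )
  expect_error(gra_config(weights = c(0.6, 0.6)), class = "greytox_error_config")
  expect_error(gra_config(rho = 1), class = "greytox_error_config")
  expect_error(gra_config(reference = -1), class = "greytox_error_config")
})

test_that("an all-reference panel is rejected as degenerate", {
  panel <- tox_panel(tibble::tibble(compound = c("a", "b"), r1 = c(1, 1), r2 = c(1, 1)))
  expect_error(run_gra(panel), class = "greytox_error_degenerate")
})

test_that("a single-compound panel yields coefficients of exactly 1", {
  panel <- tox_panel(tibble::tibble(compound = "only", r1 = 0.2, r2 = 0.004))
  res <- run_gra(panel)
  expect_equal(as.numeric(res$coefficients[1, -1]), c(1, 1))
  expect_equal(res$degrees$degree, 1)
})

test_that("coefficients are bounded, maximal exactly at the column minimum, and scale invariant", {
  for (seed in 1:5) {
    panel <- random_panel(n = 8, m = 4, seed = seed)
    res <- run_gra(panel)
    xi <- as.matrix(as.data.frame(res$coefficients[-1]))
    expect_true(all(xi > 0 & xi <= 1 + 1e-12))
    diffs <- as.matrix(as.data.frame(res$differences[-1]))
    at_min <- sweep(diffs, 2, apply(diffs, 2, min), "==")
    expect_equal(xi == 1, at_min, ignore_attr = TRUE)
    # lower bound (min + rho max)/(max + rho max) per column
    lb <- (apply(diffs, 2, min) + 0.5 * apply(diffs, 2, max)) /
      (apply(diffs, 2, max) + 0.5 * apply(diffs, 2, max))
    expect_true(all(sweep(xi, 2, lb, ">=")))

    # scaling every difference by c > 0: value' = 1 - c * (1 - value)
    for (c_scale in c(0.3, 2.5)) {
      vals <- as.matrix(as.data.frame(panel[receptor_ids(panel)]))
      scaled <- 1 - c_scale * (1 - vals)
      if (any(scaled <= 0)) next
      panel2 <- tox_panel(dplyr::bind_cols(
        tibble::tibble(compound = panel$compound),
        tibble::as_tibble(as.data.frame(scaled))
      ))
      res2 <- run_gra(panel2)
      expect_equal(
        as.matrix(as.data.frame(res2$coefficients[-1])), xi,
        tolerance = 1e-9, ignore_attr = TRUE
      )
    }
  }
})

test_that("permuting panel rows permutes degrees identically", {
  panel <- ref_panel()
  set.seed(99)
  perm <- sample(nrow(panel))
  shuffled <- tox_panel(tibble::as_tibble(panel)[perm, ])
  d1 <- run_gra(panel)$degrees
  d2 <- run_gra(shuffled)$degrees
  expect_equal(d2$degree, d1$degree[perm])
  expect_equal(d2$compound, d1$compound[perm])
})

test_that("uniformly moving one compound toward the reference never lowers its degree", {
  # anchor compounds pin the column extremes; the probe moves in between
  for (seed in 1:4) {
    set.seed(seed)
    m <- 3
    anchor_hi <- 10^runif(m, -0.3, -0.05) # closest to 1.0 -> column minima
    anchor_lo <- 10^runif(m, -5, -4.5) # farthest -> column maxima
    probe <- 10^runif(m, -4, -1)
    build <- function(p) {
      tox_panel(tibble::tibble(
        compound = c("hi", "lo", "probe"),
        !!!setNames(
          purrr::map(seq_len(m), ~ c(anchor_hi[.x], anchor_lo[.x], p[.x])),
          paste0("r", seq_len(m))
        )
      ))
    }
    degrees <- purrr::map_dbl(c(1, 1.5, 2, 4), function(f) {
      d <- run_gra(build(pmin(probe * f, anchor_hi)))$degrees
      d$degree[d$compound == "probe"]
    })
    expect_true(all(diff(degrees) >= -1e-12))
  }
})

test_that("run_gra agrees with the literal recomputation on random panels", {
  for (seed in 1:6) {
    panel <- random_panel(n = 5, m = 3, seed = seed + 100)
    vals <- as.matrix(as.data.frame(panel[receptor_ids(panel)]))
    oracle <- literal_gra(vals)
    res <- run_gra(panel)
    expect_equal(res$degrees$degree, oracle$degree, tolerance = 1e-12)
  }
})

test_that("result accessors summarise and plot without error", {
  res <- run_gra(ref_panel())
  long <- tidy(res)
  expect_equal(nrow(long), 14 * 4)
  expect_true(all(c("coefficient", "degree") %in% names(long)))
  g <- glance(res)
  expect_equal(g$n_compounds, 14)
  expect_equal(g$max_degree, 1.0, tolerance = 1e-9)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  tmp <- withr::local_tempdir()
  paths <- write_gra(res, tmp)
  expect_true(all(file.exists(paths)))
  written <- readr::read_csv(paths["degrees"], show_col_types = FALSE)
  expect_equal(written$degree[written$compound == "DEHP"], 0.7920)
})
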