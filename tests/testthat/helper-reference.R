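# Fixture loaders and independently transcribed reference values for the
# bundled 14-phthalate / 4-receptor screening panel, plus a literal
# (loop-based, spreadsheet-style) grey-relational recomputation used as the
# independent oracle against run_gra().

fx <- function(name) {
  readr::read_csv(greytox_example(name), show_col_types = FALSE, na = c("", "NA"))
}

ref_panel <- function() {
  read_tox_panel(
    greytox_example("pae_acute_toxicity.csv"),
    schema = greytox_example("pae_panel_schema.yml")
  )
}

# p-value table split into parent and derivative rows, reported_* dropped
ref_ptox <- function(name = "pae_derivative_ptox.csv") {
  ptox <- fx(name)
  ptox <- ptox[setdiff(names(ptox), grep("^reported_", names(ptox), value = TRUE))]
  list(
    parents = dplyr::filter(ptox, is.na(parent)),
    derivatives = dplyr::filter(ptox, !is.na(parent))
  )
}

compounds_in_order <- c(
  "DEHP", "DIDP", "DNOP", "DPP", "DCHP", "DUP", "BCHP",
  "BDP", "BMPP", "BOP", "DINP", "DIPP", "DNDP", "HEHP"
)

# published absolute differences |1.0 - value|, 6 decimals
# (columns as published: fish, green algae, daphnid, mysid)
published_differences <- matrix(
  c(
    0.990000, 0.998430, 0.990000, 0.999581,
    0.999213, 0.999924, 0.999331, 0.999989,
    0.992000, 0.998760, 0.992000, 0.999683,
    0.673000, 0.889000, 0.537000, 0.933000,
    0.845000, 0.955000, 0.794000, 0.977000,
    0.999817, 0.999987, 0.999862, 0.999999,
    0.583000, 0.851000, 0.398000, 0.905000,
    0.972000, 0.994000, 0.968000, 0.998100,
    0.884000, 0.968000, 0.850000, 0.985000,
    0.905000, 0.975000, 0.879000, 0.989000,
    0.998000, 0.999728, 0.998000, 0.999947,
    0.602000, 0.859000, 0.427000, 0.912000,
    0.999354, 0.999940, 0.999460, 0.999991,
    0.970000, 0.994000, 0.965000, 0.998000
  ),
  ncol = 4, byrow = TRUE,
  dimnames = list(compounds_in_order, c("fish", "green_algae", "daphnid", "mysid"))
)

published_extremes <- list(
  min = c(fish = 0.583000, green_algae = 0.851000, daphnid = 0.398000, mysid = 0.905000),
  max = c(fish = 0.999817, green_algae = 0.999987, daphnid = 0.999862, mysid = 0.999999)
)

# published grey interconnect coefficients, 4 decimals (same column order)
published_coefficients <- matrix(
  c(
    0.7268, 0.9016, 0.6027, 0.9369,
    0.7224, 0.9007, 0.5989, 0.9367,
    0.7259, 0.9014, 0.6019, 0.9369,
    0.9233, 0.9726, 0.8660, 0.9805,
    0.8052, 0.9285, 0.6940, 0.9513,
    0.7221, 0.9007, 0.5987, 0.9367,
    1.0000, 1.0000, 1.0000, 1.0000,
    0.7357, 0.9043, 0.6117, 0.9379,
    0.7825, 0.9203, 0.6652, 0.9461,
    0.7708, 0.9159, 0.6512, 0.9436,
    0.7229, 0.9008, 0.5994, 0.9367,
    0.9828, 0.9941, 0.9687, 0.9950,
    0.7223, 0.9007, 0.5989, 0.9367,
    0.7367, 0.9043, 0.6130, 0.9379
  ),
  ncol = 4, byrow = TRUE,
  dimnames = list(compounds_in_order, c("fish", "green_algae", "daphnid", "mysid"))
)

published_degrees <- c(
  DEHP = 0.7920, DIDP = 0.7897, DNOP = 0.7915, DPP = 0.9356, DCHP = 0.8447,
  DUP = 0.7895, BCHP = 1.0000, BDP = 0.7974, BMPP = 0.8285, BOP = 0.8204,
  DINP = 0.7900, DIPP = 0.9852, DNDP = 0.7896, HEHP = 0.7980
)

# Literal spreadsheet-style grey relational computation: explicit loops,
# independent of the package's vectorized path. `normalization` mirrors the
# two conventions for the extremes in the coefficient formula.
literal_gra <- function(values, reference = 1, rho = 0.5,
                        normalization = "per_sequence") {
  n <- nrow(values)
  m <- ncol(values)
  delta <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      delta[i, j] <- abs(reference - values[i, j])
    }
  }
  gmin <- delta[1, 1]
  gmax <- delta[1, 1]
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (delta[i, j] < gmin) gmin <- delta[i, j]
      if (delta[i, j] > gmax) gmax <- delta[i, j]
    }
  }
  xi <- matrix(0, n, m)
  for (j in seq_len(m)) {
    lo <- delta[1, j]
    hi <- delta[1, j]
    for (i in seq_len(n)) {
      if (delta[i, j] < lo) lo <- delta[i, j]
      if (delta[i, j] > hi) hi <- delta[i, j]
    }
    if (normalization == "global") {
      lo <- gmin
      hi <- gmax
    }
    for (i in seq_len(n)) {
      xi[i, j] <- (lo + rho * hi) / (delta[i, j] + rho * hi)
    }
  }
  degree <- numeric(n)
  for (i in seq_len(n)) {
    degree[i] <- sum(xi[i, ]) / m
  }
  list(delta = delta, xi = xi, degree = degree)
}

# random strictly-sub-boundary panel for property tests
random_panel <- function(n = 5, m = 3, seed = 1) {
  set.seed(seed)
  vals <- matrix(10^runif(n * m, -5, -0.05), n, m)
  data <- tibble::as_tibble(as.data.frame(vals))
  names(data) <- paste0("r", seq_len(m))
  tox_panel(dplyr::bind_cols(
    tibble::tibble(compound = paste0("c", seq_len(n))), data
  ))
}

# Reported rate cells are printed at 1 or 2 decimals, computed by the source
# from unrounded inputs; agreement is therefore limited by the printed
# precision of the cell plus up to 0.01 pp of input display rounding.
expect_rates_close <- function(computed, reported) {
  keep <- !is.na(reported)
  computed <- computed[keep]
  reported <- reported[keep]
  digits <- ifelse(abs(reported - round_half_up(reported, 1)) < 1e-9, 1, 2)
  tol <- pmax(0.01, 0.5 * 10^(-digits)) + 1e-9
  expect_true(all(abs(computed - reported) <= tol))
}
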