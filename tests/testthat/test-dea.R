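# helpers ------------------------------------------------------------------

random_problem <- function(n, p, q) {
  list(X = matrix(runif(n * p, 0.5, 10), n),
       Y = matrix(runif(n * q, 0.5, 10), n))
}

all_theta <- function(pr) {
  vapply(seq_len(nrow(pr$X)),
         function(i) farrell_output_distance(pr, i)$theta, numeric(1))
}

# unit cases ----------------------------------------------------------------

test_that("a lone DMU envelops itself", {
  pr <- dea_problem(matrix(3), matrix(5))
  sc <- farrell_output_distance(pr, 1)
  expect_equal(sc$theta, 1)
  expect_equal(sc$efficiency, 1)
})

test_that("a dominated DMU's outputs can be expanded to the dominating frontier", {
  # A = (x=1, y=2), B = (x=1, y=1): B's output can be doubled at A's inputs
  pr <- dea_problem(matrix(c(1, 1)), matrix(c(2, 1)))
  sc <- farrell_output_distance(pr, 2)
  expect_equal(sc$theta, 2, tolerance = 1e-9)
  expect_equal(sc$efficiency, 0.5, tolerance = 1e-9)
  expect_equal(sum(sc$lambda), 1, tolerance = 1e-8)
  expect_equal(farrell_output_distance(pr, 1)$theta, 1, tolerance = 1e-9)
})

test_that("intensity weights satisfy the envelopment constraints", {
  set.seed(2)
  d <- random_problem(15, 2, 2)
  pr <- dea_problem(d$X, d$Y)
  for (i in c(1, 7, 15)) {
    sc <- farrell_output_distance(pr, i)
    expect_true(all(sc$lambda >= -1e-8))
    expect_equal(sum(sc$lambda), 1, tolerance = 1e-7)
    expect_true(all(t(d$X) %*% sc$lambda <= d$X[i, ] + 1e-6))
    expect_true(all(t(d$Y) %*% sc$lambda >= sc$theta * d$Y[i, ] - 1e-6))
  }
})

# oracle cross-validation ---------------------------------------------------

test_that("hull oracle handles duplicated, collinear and trivial layouts", {
  expect_equal(hull_oracle_1in_1out(c(1, 1), c(2, 1)), c(1, 2))
  expect_equal(hull_oracle_1in_1out(1:3, 1:3), rep(1, 3))
  # toy year: frontier through (2,3)-(4,4) interpolates 3.5 at x = 3
  th <- hull_oracle_1in_1out(c(1, 2, 4, 3), c(1, 3, 4, 2))
  expect_equal(th[4], 1.75, tolerance = 1e-12)
})

test_that("LP distances match the concave-hull oracle on random single-input data", {
  set.seed(3)
  x <- runif(30, 1, 10); y <- runif(30, 1, 10)
  pr <- dea_problem(matrix(x), matrix(y))
  expect_equal(all_theta(pr), hull_oracle_1in_1out(x, y), tolerance = 1e-6)
})

test_that("LP distances match exact vertex enumeration on small instances", {
  set.seed(7)
  for (rep in 1:6) {
    n <- sample(3:12, 1); p <- sample(1:2, 1); q <- sample(1:2, 1)
    d <- random_problem(n, p, q)
    pr <- dea_problem(d$X, d$Y)
    th <- all_theta(pr)
    oracle <- vapply(seq_len(n),
                     function(i) vertex_enum_oracle(d$X, d$Y, i), numeric(1))
    expect_equal(th, oracle, tolerance = 1e-6)
  }
  # CRS route against the oracle without the convexity constraint
  d <- random_problem(6, 2, 1)
  prc <- dea_problem(d$X, d$Y, rts = "crs")
  expect_equal(all_theta(prc),
               vapply(1:6, function(i)
                 vertex_enum_oracle(d$X, d$Y, i, vrs = FALSE), numeric(1)),
               tolerance = 1e-6)
})

# year scoring --------------------------------------------------------------

test_that("score_year handles identical DMUs, zero columns and bad input", {
  slice <- data.frame(jurisdiction_id = sprintf("J%02d", 1:5), year = 2010,
                      in1 = 2, in2 = 0, out1 = 7)
  expect_message(sc <- score_year(slice, c("in1", "in2"), "out1"),
                 "all-zero input column")
  expect_equal(sc$efficiency, rep(1, 5))

  expect_error(score_year(slice[1, ], "in1", "out1"), "at least 2")
  slice$in1[2] <- NA
  expect_error(score_year(slice, "in1", "out1"), "rows: 2")
  expect_error(score_year(slice, c("in1", "nope"), "out1"), "missing columns")
})

test_that("per-year DEA scores recover the true efficiency ordering", {
  g <- generate_panel(synthetic_config(n_jurisdictions = 100L, years = 2009L,
                                       noise_scale = 0, seed = 11L))
  pan <- add_input_aggregates(g$panel)
  sc <- score_year(pan, c("infra_total", "hr_total"),
                   c("treated", "controlled"))
  expect_gte(max(sc$efficiency), 1 - 1e-9)     # frontier nonempty
  m <- merge(sc, g$truth, by = "jurisdiction_id")
  expect_gte(cor(m$true_efficiency, m$efficiency, method = "spearman"), 0.8)
})

# properties ----------------------------------------------------------------

test_that("efficiency is invariant to the units of any input or output", {
  set.seed(12)
  d <- random_problem(20, 3, 2)
  pr <- dea_problem(d$X, d$Y)
  base <- all_theta(pr)
  for (cs in list(c(1000, 1, 1), c(1, 0.001, 1), c(1, 1, 7))) {
    pr2 <- dea_problem(sweep(d$X, 2, cs, "*"), d$Y)
    expect_equal(all_theta(pr2), base, tolerance = 1e-8)
  }
  pr3 <- dea_problem(d$X, sweep(d$Y, 2, c(250, 0.004), "*"))
  expect_equal(all_theta(pr3), base, tolerance = 1e-8)
})

test_that("raising a DMU's output never lowers its efficiency", {
  set.seed(13)
  d <- random_problem(15, 2, 2)
  pr <- dea_problem(d$X, d$Y)
  for (i in c(2, 9)) {
    before <- farrell_output_distance(pr, i)$efficiency
    Y2 <- d$Y; Y2[i, 1] <- Y2[i, 1] * 1.3
    after <- farrell_output_distance(dea_problem(d$X, Y2), i)$efficiency
    expect_gte(after, before - 1e-8)
  }
})

test_that("VRS efficiency dominates CRS efficiency and both stay in (0, 1]", {
  set.seed(14)
  d <- random_problem(25, 2, 2)
  ev <- 1 / all_theta(dea_problem(d$X, d$Y, rts = "vrs"))
  ec <- 1 / all_theta(dea_problem(d$X, d$Y, rts = "crs"))
  expect_true(all(ev >= ec - 1e-8))
  expect_true(all(ev > 0 & ev <= 1 + 1e-9))
  expect_true(all(ec > 0 & ec <= 1 + 1e-9))
})

test_that("malformed problems are rejected", {
  expect_error(dea_problem(matrix(c(1, 2)), matrix(c(0, 0))), "all-zero outputs")
  expect_error(dea_problem(matrix(c(0, 0)), matrix(c(1, 2))), "no positive entry")
  expect_error(dea_problem(matrix(c(-1, 2)), matrix(c(1, 2))), "non-negative")
  expect_error(dea_problem(matrix(c(NA, 2)), matrix(c(1, 2))), "missing")
})
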