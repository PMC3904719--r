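tr <- function(...) species_preset("trifolium_repens", ...)

test_that("common-ratio calibration solves 100 R^b = terminal AL", {
  # independent cross-check: bisection on the defining equation
  bisect <- uniroot(function(R) 100 * R^21 - 0.5, c(0.5, 0.99),
                    tol = 1e-12)$root
  expect_equal(calibrate_common_ratio(21, 0.5), bisect, tolerance = 1e-9)
  expect_equal(round(calibrate_common_ratio(21, 0.5), 2), 0.78)
  expect_equal(calibrate_common_ratio(21, 0.5), 0.7770109, tolerance = 1e-7)
  expect_equal(calibrate_common_ratio(1, 0.5), 0.005)

  # roundtrip property over a grid of plant sizes and terminal ALs
  for (b in c(1, 5, 21, 40)) {
    for (ta in c(0.1, 0.5, 2, 50)) {
      R <- calibrate_common_ratio(b, ta)
      expect_lt(abs(100 * R^b - ta), 1e-9)
    }
  }

  expect_error(calibrate_common_ratio(0, 0.5), "positive")
  expect_error(calibrate_common_ratio(21, 0), "0, 100")
  expect_error(calibrate_common_ratio(21, 100), "0, 100")
})

test_that("nodal-distance exponent matches step-by-step traversal oracle", {
  p <- tr()
  expect_identical(nrs_exponent(1L, p), 1L)
  expect_identical(nrs_exponent(c(1L, 1L), p), 4L)   # 1 + 1 + L
  expect_identical(nrs_exponent(c(1L, 1L, 1L), p), 7L)  # 3 + 2L

  # closed form == per-edge accumulation on all positions to order 5
  params_cases <- list(tr(), shoot_params(0.78, 0, 21, 6, 1.3),
                       shoot_params(0.78, 3, 21, 6, 1.3, decay_origin = 5))
  for (prm in params_cases) {
    for (ord in 1:5) {
      paths <- as.matrix(do.call(expand.grid, rep(list(1:6), ord)))
      closed <- apply(paths, 1L, nrs_exponent, params = prm)
      stepped <- apply(paths, 1L, oracle_exponent, L = prm$delay,
                       decay_origin = prm$decay_origin)
      expect_equal(closed, stepped)
    }
  }
})

test_that("NRS availability is R to the power of the effective distance", {
  p <- tr()
  expect_equal(nrs(1L, p), 0.78)
  expect_equal(nrs(c(1L, 1L), p), 0.78^4, tolerance = 1e-4)
  # all-zero effective exponent: order 1 proximal to the decay origin
  p5 <- shoot_params(0.78, 2, 21, 6, 1.3, decay_origin = 5)
  expect_equal(nrs(3L, p5), 1.0)
  expect_equal(nrs(5L, p5), 0.78)  # the named node is the first to decay
})

test_that("outgrowth potential is the parent founding bud's emergence NRS", {
  p <- tr()
  for (path in list(1L, 7L, 21L))
    expect_equal(outgrowth_potential(path, p), 100)
  expect_equal(outgrowth_potential(c(1L, 1L), p), 78)
  expect_equal(outgrowth_potential(c(1L, 1L, 1L), p),
               100 * oracle_power(0.78, 4), tolerance = 1e-9)
  expect_equal(outgrowth_potential(c(1L, 1L, 1L), p), 37.01506,
               tolerance = 1e-4)

  # both op_modes agree for buds up to path length 2
  p_al <- tr(); p_al$op_mode <- "parent_al"
  for (path in list(1L, 5L, c(1L, 1L), c(3L, 4L))) {
    expect_equal(outgrowth_potential(path, p_al),
                 outgrowth_potential(path, p))
    expect_equal(activation_level(path, p_al), activation_level(path, p))
  }
  # beyond that, parent_al compounds and is strictly smaller
  expect_lt(outgrowth_potential(c(1L, 1L, 1L), p_al),
            outgrowth_potential(c(1L, 1L, 1L), p))
})

test_that("activation level is NRS x OP (+OP) or scaled NRS (-OP)", {
  p <- tr()
  m <- tr(variant = "minus_op")
  expect_equal(activation_level(1L, p), 78)
  # independent product oracle at path (1,1,1)
  expect_equal(activation_level(c(1L, 1L, 1L), p),
               oracle_power(0.78, 7) * 100 * oracle_power(0.78, 4),
               tolerance = 1e-12)
  expect_equal(activation_level(c(1L, 1L, 1L), p), 6.501905,
               tolerance = 1e-6)
  expect_equal(activation_level(c(1L, 1L, 1L), m), 100 * 0.78^7,
               tolerance = 1e-12)
  expect_equal(activation_level(c(1L, 1L, 1L), m), 17.56557,
               tolerance = 1e-5)
})

test_that("AL under -OP dominates +OP and declines with position", {
  p <- tr()
  m <- tr(variant = "minus_op")
  set.seed(42)
  for (i in 1:50) {
    ord <- sample(1:4, 1)
    path <- sample(1:6, ord, replace = TRUE)
    al_p <- activation_level(path, p)
    al_m <- activation_level(path, m)
    expect_gte(al_m, al_p)
    # appending any coordinate strictly decreases AL, both variants
    child <- c(path, sample(1:6, 1))
    expect_lt(activation_level(child, p), al_p)
    expect_lt(activation_level(child, m), al_m)
    # incrementing any single coordinate strictly decreases AL
    k <- sample(ord, 1)
    bumped <- path; bumped[k] <- bumped[k] + 1L
    expect_lt(activation_level(bumped, p), al_p)
    expect_lt(activation_level(bumped, m), al_m)
  }
})

test_that("invalid paths and parameters are rejected", {
  p <- tr()
  expect_error(nrs_exponent(c(1, 0), p), "positive integer")
  expect_error(nrs_exponent(integer(0), p), "positive integer")
  expect_error(shoot_params(1.2, 2, 21, 6, 1.3), "common_ratio")
  expect_error(shoot_params(0.78, 2, 21, 1.3, 6), "threshold")
  expect_error(shoot_params(0.78, -1, 21, 6, 1.3), "delay")
})
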