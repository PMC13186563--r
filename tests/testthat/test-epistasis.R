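# Variance decomposition by interaction order and global epistasis.

test_that("variance fractions are non-negative and sum to one", {
  ls <- planted_test_landscape(m = 6, noise_sd = 0.1, seed = 4)
  vd <- variance_by_order(ls)
  expect_true(all(vd$fraction >= 0))
  expect_equal(sum(vd$fraction), 1, tolerance = 1e-9)
  expect_equal(vd$cumulative[6], 1, tolerance = 1e-9)
})

test_that("a purely additive landscape is all order-1 variance", {
  ls <- generate_landscape(5, data.frame(members = as.character(1:5),
                                         value = c(1, -2, 3, 0.5, 2)))
  vd <- variance_by_order(ls)
  expect_equal(vd$fraction[1], 1, tolerance = 1e-12)
  expect_equal(sum(vd$fraction[-1]), 0, tolerance = 1e-12)
})

test_that("singles-plus-pairs landscapes close at order 2", {
  co <- data.frame(members = c("1", "2", "3", "4", "1,2", "2,4", "3,4"),
                   value = c(0.5, 0.2, -0.4, 0.3, -0.3, 0.25, 0.1))
  vd <- variance_by_order(generate_landscape(4, co))
  expect_equal(vd$cumulative[2], 1, tolerance = 1e-12)
  expect_gt(vd$fraction[2], 0)
})

test_that("fractions match a dense-basis oracle, including mixed orders", {
  # random-ish landscape with planted structure plus noise
  ls <- planted_test_landscape(m = 6, noise_sd = 0.2, seed = 14)
  vd <- variance_by_order(ls)
  expect_equal(vd$fraction,
               oracle_variance_fractions(ls$mean_by_code, 6),
               tolerance = 1e-10)
  # equal-magnitude coefficients at orders 1..3: fractions proportional to
  # (count x squared basis coefficient) per order, checked through the oracle
  co <- data.frame(members = c("1", "2", "1,2", "2,3", "1,2,3"),
                   value = rep(0.4, 5))
  ls2 <- generate_landscape(3, co)
  expect_equal(variance_by_order(ls2)$fraction,
               oracle_variance_fractions(ls2$mean_by_code, 3),
               tolerance = 1e-12)
})

test_that("walsh coefficients reconstruct the landscape exactly", {
  ls <- planted_test_landscape(m = 6, noise_sd = 0.5, seed = 8)
  co <- walsh_coefficients(ls)
  expect_equal(max(abs(walsh_reconstruct(co) - ls$mean_by_code)), 0,
               tolerance = 1e-9)
  expect_equal(co$order, hamming_weight(0:63, 6))
})

test_that("incomplete landscapes are rejected with the missing codes listed", {
  df <- data.frame(consortium = code_to_binary(0:13, 4), value = rnorm(14))
  ls <- function_landscape(df)
  err <- tryCatch(variance_by_order(ls), error = function(e) e)
  expect_s3_class(err, "consortia_incomplete_error")
  expect_match(conditionMessage(err), "1110")
})

test_that("measurement noise shifts variance toward higher orders on average", {
  singles <- data.frame(members = as.character(1:5), value = c(1, 2, 1.5, 0.5, 1))
  frac1 <- function(sd, seed) {
    variance_by_order(generate_landscape(5, singles, noise_sd = sd,
                                         seed = seed))$fraction[1]
  }
  seeds <- 1:25
  low <- mean(vapply(seeds, function(s) frac1(0.05, s), numeric(1)))
  high <- mean(vapply(seeds, function(s) frac1(0.5, s), numeric(1)))
  expect_gt(low, high)
})

test_that("global epistasis fit matches a normal-equations oracle", {
  ls <- planted_test_landscape(m = 6, noise_sd = 0.2, seed = 31)
  for (k in c(1, 4, 6)) {
    fit <- global_epistasis_fit(ls, k)
    eff <- functional_effects(ls, k)
    oracle <- oracle_ols(eff$background_function, eff$effect)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
    expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
    expect_equal(fit$n_backgrounds, 32L)
  }
})

test_that("an exactly linear effect-function relation gives R^2 = 1", {
  ls <- generate_epistatic_landscape(5, slopes = c(-0.3, -0.15, 0.1, 0.25, 0.4))
  fits <- global_epistasis_fits(ls)
  expect_equal(fits$r_squared, rep(1, 5), tolerance = 1e-9)
  # slope of dF_k on F(b) equals s_k by construction
  expect_equal(fits$slope, c(-0.3, -0.15, 0.1, 0.25, 0.4), tolerance = 1e-9)
})

test_that("constant effects (additive landscape) give R^2 = 0 by convention", {
  ls <- generate_landscape(4, data.frame(members = as.character(1:4),
                                         value = c(1, 2, 3, 4)))
  expect_equal(global_epistasis_fits(ls)$r_squared, rep(0, 4))
})

test_that("permutation null is seeded, reproducible, and contains its own permutations", {
  ls <- planted_test_landscape(m = 5, noise_sd = 0.4, seed = 2)
  n1 <- epistasis_null(ls, B = 30, seed = 99)
  n2 <- epistasis_null(ls, B = 30, seed = 99)
  expect_equal(n1$null_mean_r2, n2$null_mean_r2)
  # a landscape that IS a permutation of its values scores inside the null
  set.seed(1)
  perm <- suppressWarnings(function_landscape(data.frame(
    consortium = 0:31, value = sample(ls$mean_by_code)), m = 5))
  np <- epistasis_null(perm, B = 100, seed = 5)
  expect_lte(np$observed_mean_r2, max(np$null_mean_r2) + 0.05)
  expect_error(epistasis_null(ls, B = 0, seed = 1), "B")
  expect_error(epistasis_null(ls, B = 10), "seed")
})

test_that("planted global epistasis exceeds the null's 95th percentile", {
  ls <- generate_epistatic_landscape(5)
  nl <- epistasis_null(ls, B = 200, seed = 17)
  expect_gt(nl$observed_mean_r2,
            unname(quantile(nl$null_mean_r2, 0.95)))
  expect_lt(nl$p_value, 0.05)
})
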