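# Functional effects, pairwise and third-order interactions, diversity and
# ranking on the composition hypercube.

test_that("functional effect is the with-minus-without difference", {
  ls <- function_landscape(data.frame(
    consortium = c("00", "01", "10", "11"), value = c(1.0, 1.3, 0.9, 1.1)))
  eff <- functional_effect(ls, 1, "00")
  expect_equal(eff$effect, 0.3)
  expect_equal(eff$background_function, 1.0)
  expect_equal(functional_effect(ls, 2, "01")$effect, 1.1 - 1.3)
  expect_error(functional_effect(ls, 1, "01"), "focal")
})

test_that("on an additive landscape each strain's effect is constant", {
  ls <- generate_landscape(5, data.frame(members = as.character(1:5),
                                         value = c(0.5, -0.2, 0.3, 0.1, 0.4)))
  for (k in 1:5) {
    eff <- functional_effects(ls, k)
    expect_equal(nrow(eff), 16L)
    expect_equal(eff$effect, rep(c(0.5, -0.2, 0.3, 0.1, 0.4)[k], 16))
  }
})

test_that("pairwise interaction follows the four-corner formula", {
  # F(b)=1.0, F(b+i)=1.5, F(b+j)=1.4, F(b+ij)=1.6 -> epsilon = -0.3
  ls <- function_landscape(data.frame(
    consortium = c("00", "01", "10", "11"), value = c(1.0, 1.5, 1.4, 1.6)))
  expect_equal(pairwise_interaction(ls, 1, 2, "00")$epsilon, -0.3)
})

test_that("planted pairwise coefficients are recovered in every background", {
  ls <- planted_test_landscape(m = 6)
  eps12 <- pairwise_interactions(ls, 1, 2)
  expect_equal(nrow(eps12), 2^4)
  expect_equal(eps12$epsilon, rep(-0.3, 16))
  # pair (4,5) interacts only through the planted (4,5,6) term
  eps45 <- pairwise_interactions(ls, 4, 5)
  has6 <- grepl("^1", eps45$background_binary) # bit 6 is the leftmost digit
  expect_equal(eps45$epsilon[has6], rep(0.2, sum(has6)))
  expect_equal(eps45$epsilon[!has6], rep(0, sum(!has6)))
  # and a pure additive landscape has no interactions anywhere
  add <- generate_landscape(4, data.frame(members = as.character(1:4),
                                          value = 1:4 / 10))
  for (b in c("0000", "1000", "0100")) {
    expect_equal(pairwise_interaction(add, 1, 2, b)$epsilon, 0)
  }
})

test_that("third-order interaction recovers the planted coefficient and vanishes otherwise", {
  ls <- planted_test_landscape(m = 6)
  expect_equal(third_order_interaction(ls, 4, 5, 6), 0.2)
  expect_equal(third_order_interaction(ls, 4, 5, 6,
                                       background = encode_consortium(3, 6)), 0.2)
  expect_equal(third_order_interaction(ls, 1, 2, 3), 0)  # additive + pairwise only
  expect_error(third_order_interaction(ls, 1, 1, 2), "distinct")
})

test_that("interaction consistency: epsilon_ij(b) = dF_i(b+j) - dF_i(b), exhaustively", {
  ls <- planted_test_landscape(m = 5, noise_sd = 0.3, seed = 9)
  for (i in 1:4) for (j in (i + 1):5) {
    for (b in all_backgrounds_for_test(5, c(i, j))) {
      eps <- pairwise_interaction(ls, i, j, b)$epsilon
      bj <- bitwOr(b, bitwShiftL(1L, j - 1L))
      diff <- functional_effect(ls, i, bj)$effect - functional_effect(ls, i, b)$effect
      expect_equal(eps, diff)
    }
  }
})

test_that("missing consortia raise an incompleteness error naming the code", {
  df <- data.frame(consortium = code_to_binary(1:14, 4), value = rnorm(14))
  ls <- suppressWarnings(function_landscape(df))
  err <- tryCatch(functional_effect(ls, 4, "0111"), error = function(e) e)
  expect_s3_class(err, "consortia_incomplete_error")
  expect_match(conditionMessage(err), "1111")
})

test_that("an unmeasured empty consortium defaults to zero with a warning", {
  df <- data.frame(consortium = code_to_binary(1:3, 2), value = c(1, 2, 4))
  expect_warning(ls <- function_landscape(df), "empty consortium")
  expect_equal(functional_effect(ls, 1, "00")$effect, 1)
  expect_equal(pairwise_interaction(ls, 1, 2, "00")$epsilon, 4 - 2 - 1 + 0)
})

test_that("replicate order does not affect summaries or effects", {
  set.seed(21)
  df <- data.frame(
    consortium = rep(code_to_binary(0:7, 3), each = 3),
    replicate = rep(1:3, 8), value = rnorm(24))
  ls1 <- function_landscape(df)
  ls2 <- function_landscape(df[sample(nrow(df)), ])
  expect_equal(ls1$summary, ls2$summary)
  expect_equal(functional_effects(ls1, 2), functional_effects(ls2, 2))
})

test_that("diversity curve groups by richness with binomial group sizes", {
  ls <- planted_test_landscape(m = 6)
  dv <- diversity_function_curve(ls)
  expect_equal(dv$richness, 0:6)
  expect_equal(dv$n, choose(6, 0:6))
  expect_equal(dv$n[7], 1L)  # single full consortium
  # additive landscape: mean function grows linearly with richness
  add <- generate_landscape(4, data.frame(members = as.character(1:4),
                                          value = rep(0.5, 4)))
  expect_equal(diversity_function_curve(add)$mean, 0.5 * (0:4))
})

test_that("ranking is by descending mean with deterministic integer tie-break", {
  ls <- function_landscape(data.frame(
    consortium = c("00", "01", "10", "11"), value = c(0.5, 1.0, 1.0, 0.2)))
  rk <- rank_consortia(ls)
  expect_equal(rk$consortium_binary, c("01", "10", "00", "11"))
  const <- function_landscape(data.frame(
    consortium = code_to_binary(0:7, 3), value = rep(1, 8)))
  expect_equal(rank_consortia(const)$consortium_binary, code_to_binary(0:7, 3))
  top <- rank_consortia(ls, top_n = 2)
  expect_equal(nrow(top), 2L)
  expect_equal(top$rank, 1:2)
})

test_that("hypercube adjacency has m * 2^(m-1) single-strain edges", {
  expect_equal(nrow(adjacency_graph(1)), 1L)
  expect_equal(nrow(adjacency_graph(3)), 12L)
  expect_equal(nrow(adjacency_graph(8)), 1024L)
  g <- adjacency_graph(3)
  d <- abs(binary_to_code(g$from_binary) - binary_to_code(g$to_binary))
  expect_true(all(d %in% c(1, 2, 4)))  # single-bit differences
  expect_false(anyDuplicated(paste(g$from_binary, g$to_binary)) > 0)
})
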