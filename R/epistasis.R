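# Variance decomposition by interaction order, and global epistasis.
#
# A complete landscape F on {0,1}^m decomposes uniquely in the orthogonal
# Walsh-Hadamard basis phi_S(c) = (-1)^{|S intersect c|}. The squared
# coefficients of the weight-r basis functions give the fraction of
# functional variance attributable to interactions of order r (order 1 =
# additive strain effects); the constant term is excluded. Global epistasis
# is the emergent linear relationship between a strain's functional effect
# dF_k(b) and the background function F(b), fit by ordinary least squares
# over all 2^(m-1) backgrounds and compared against a permutation null.

# in-place fast Walsh-Hadamard transform; self-inverse up to a factor 2^m
fwht <- function(v) {
  n <- length(v)
  h <- 1L
  while (h < n) {
    for (s in seq(1L, n, by = 2L * h)) {
      i <- s:(s + h - 1L)
      a <- v[i]; bb <- v[i + h]
      v[i] <- a + bb
      v[i + h] <- a - bb
    }
    h <- 2L * h
  }
  v
}

require_complete <- function(landscape) {
  if (!inherits(landscape, "function_landscape")) {
    stop_validation("`landscape` must be a function_landscape")
  }
  if (!landscape$complete) {
    miss <- setdiff(0:(2^landscape$m - 1), landscape$summary$code)
    miss <- setdiff(miss, 0L) # empty code defaults to 0
    stop_incomplete(
      "landscape is incomplete; missing %d consortia (e.g. %s)",
      length(miss),
      paste(code_to_binary(utils::head(miss, 5L), landscape$m), collapse = ", "))
  }
  invisible(landscape)
}

#' Walsh coefficients of a complete landscape
#'
#' Coefficients `a_S = 2^-m * sum_c F(c) * (-1)^{|S intersect c|}` of the
#' replicate-mean landscape in the orthogonal Walsh-Hadamard basis. The
#' subset `S` is read from the index's bitmask; `|S|` is the interaction
#' order.
#'
#' @param landscape A complete [function_landscape()].
#' @return Data frame: `subset_binary`, `order`, `coefficient`.
#' @export
walsh_coefficients <- function(landscape) {
  require_complete(landscape)
  m <- landscape$m
  f <- landscape$mean_by_code
  a <- fwht(f) / 2^m
  masks <- 0:(2^m - 1)
  data.frame(
    subset_binary = code_to_binary(masks, m),
    order = hamming_weight(masks, m),
    coefficient = a, stringsAsFactors = FALSE
  )
}

#' Reconstruct landscape values from Walsh coefficients
#'
#' Round-trip companion of [walsh_coefficients()]; reconstruction is exact up
#' to numerical tolerance, which certifies the decomposition is complete.
#'
#' @param coefficients Output of [walsh_coefficients()].
#' @return Numeric vector of `2^m` function values indexed by `code + 1`.
#' @export
walsh_reconstruct <- function(coefficients) {
  fwht(coefficients$coefficient)
}

#' Fraction of functional variance by interaction order
#'
#' Partitions the variance of a complete replicate-mean landscape across
#' interaction orders `1..m`: fraction at order `r` is the sum of squared
#' Walsh coefficients of weight-`r` subsets divided by the total over all
#' orders `>= 1` (the constant term carries no variance). Fractions are
#' non-negative and sum to 1.
#'
#' @param landscape A complete [function_landscape()].
#' @return Data frame of class `order_decomposition`: `order`, `fraction`,
#'   `cumulative`.
#' @export
variance_by_order <- function(landscape) {
  co <- walsh_coefficients(landscape)
  sq <- co$coefficient^2
  sq[1] <- 0 # constant term
  total <- sum(sq)
  if (total < 1e-24) {
    warning("landscape has (numerically) zero variance; fractions are NA")
    frac <- rep(NA_real_, landscape$m)
  } else {
    frac <- vapply(seq_len(landscape$m), function(r) {
      sum(sq[co$order == r]) / total
    }, numeric(1))
  }
  structure(
    data.frame(order = seq_len(landscape$m), fraction = frac,
               cumulative = cumsum(frac)),
    class = c("order_decomposition", "data.frame")
  )
}

#' Global epistasis regression for one strain
#'
#' Ordinary least squares of the strain's functional effect `dF_k(b)` on the
#' background function `F(b)` over all `2^(m-1)` backgrounds that do not
#' contain `k`. A constant response (e.g. on a purely additive landscape) has
#' `r_squared = 0` by convention.
#'
#' @param landscape A complete [function_landscape()].
#' @param k Focal strain index.
#' @return Data frame row: `strain`, `slope`, `intercept`, `r_squared`,
#'   `n_backgrounds`.
#' @export
global_epistasis_fit <- function(landscape, k) {
  require_complete(landscape)
  eff <- functional_effects(landscape, k)
  x <- eff$background_function
  y <- eff$effect
  if (length(x) < 3L) stop_validation("need at least 3 backgrounds to fit")
  if (stats::var(y) < 1e-24) {
    return(data.frame(strain = k, slope = 0, intercept = mean(y),
                      r_squared = 0, n_backgrounds = length(x)))
  }
  if (stats::var(x) < 1e-24) {
    return(data.frame(strain = k, slope = NA_real_, intercept = mean(y),
                      r_squared = 0, n_backgrounds = length(x)))
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact fits, which are legitimate here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  data.frame(
    strain = k,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    n_backgrounds = length(x)
  )
}

#' Global epistasis regressions for every strain
#'
#' @param landscape A complete [function_landscape()].
#' @return Data frame with one [global_epistasis_fit()] row per strain.
#' @export
global_epistasis_fits <- function(landscape) {
  do.call(rbind, lapply(seq_len(landscape$m), function(k) {
    global_epistasis_fit(landscape, k)
  }))
}

# mean R^2 across strains for a vector of 2^m landscape values
mean_r2_of_values <- function(values, m) {
  ls <- function_landscape(
    data.frame(consortium = 0:(2^m - 1), value = values), m = m)
  mean(global_epistasis_fits(ls)$r_squared)
}

#' Permutation null for global epistasis
#'
#' Compares the observed mean `R^2` of the per-strain global-epistasis fits
#' against a null in which the replicate-mean function values are randomly
#' permuted across consortia (`B` times). Permutation preserves the value
#' distribution while destroying any composition-function structure.
#'
#' @param landscape A complete [function_landscape()].
#' @param B Number of permutation replicates (default 1000).
#' @param seed Integer RNG seed (required, for reproducibility).
#' @return Object of class `epistasis_null`: list with `observed_mean_r2`,
#'   `null_mean_r2` (length `B`), `p_value` (upper-tail, with the +1
#'   correction), `B`, `seed`.
#' @export
epistasis_null <- function(landscape, B = 1000, seed) {
  require_complete(landscape)
  if (B < 1) stop_validation("`B` must be >= 1")
  if (missing(seed)) stop_validation("`seed` is required for a reproducible null")
  m <- landscape$m
  vals <- landscape$mean_by_code
  observed <- mean_r2_of_values(vals, m)
  set.seed(seed)
  null <- vapply(seq_len(B), function(i) {
    suppressWarnings(mean_r2_of_values(sample(vals), m))
  }, numeric(1))
  structure(list(
    observed_mean_r2 = observed,
    null_mean_r2 = null,
    p_value = (1 + sum(null >= observed)) / (B + 1),
    B = as.integer(B), seed = as.integer(seed),
    randomization = "value permutation across consortia"
  ), class = "epistasis_null")
}

#' @export
print.epistasis_null <- function(x, ...) {
  cat(sprintf(
    "Global epistasis permutation null (B = %d, seed = %d)\n", x$B, x$seed))
  cat(sprintf("  observed mean R^2: %.4f\n", x$observed_mean_r2))
  cat(sprintf("  null mean R^2: median %.4f, 95th percentile %.4f\n",
              stats::median(x$null_mean_r2),
              stats::quantile(x$null_mean_r2, 0.95)))
  cat(sprintf("  upper-tail p = %.4g\n", x$p_value))
  invisible(x)
}
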