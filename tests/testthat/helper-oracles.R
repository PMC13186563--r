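# Independent oracles used to cross-check the implementation. They share no
# code path with the package internals they verify: placement is derived from
# block-alternation arithmetic, variance fractions from a dense basis matrix,
# regressions from the normal equations, and expected spectral deviations
# from plain Monte-Carlo simulation.

# Is species k present in well (i, j_global)? Alternating-block arithmetic:
# species k <= r occupies alternating blocks of 2^(k-1) rows (absent in the
# first block), species k > r alternating blocks of 2^(k-r-1) global columns.
oracle_species_in_well <- function(k, i, j, format = 96) {
  r <- if (format == 96) 3L else 4L
  if (k <= r) {
    floor((i - 1) / 2^(k - 1)) %% 2 == 1
  } else {
    floor((j - 1) / 2^(k - r - 1)) %% 2 == 1
  }
}

# Variance fractions by order from an explicitly constructed orthogonal basis
# (columns phi_S(c) = (-1)^{|S intersect c|}); practical for m <= 8.
oracle_variance_fractions <- function(values, m) {
  n <- 2^m
  codes <- 0:(n - 1)
  popcount <- function(x) vapply(x, function(z) sum(bitwAnd(z, 2^(0:30)) > 0), numeric(1))
  phi <- outer(codes, codes, function(c0, s) (-1)^popcount(bitwAnd(c0, s)))
  a <- drop(crossprod(phi, values)) / n   # coefficients, index = subset mask
  sq <- a^2
  sq[1] <- 0
  ord <- popcount(codes)
  vapply(1:m, function(r) sum(sq[ord == r]) / sum(sq), numeric(1))
}

# Simple linear regression via the normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  fitted <- drop(X %*% beta)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r_squared = r2)
}

# Monte-Carlo expectation of the pooled mean relative deviation for additive
# mixtures under multiplicative aliquot noise of the given cv, using the same
# monoculture spectra, mixtures and masking threshold as the pipeline.
oracle_mc_mean_delta <- function(mono_mat, codes, m, cv, threshold = 0.1,
                                 n_rep = 40, min_members = 2) {
  membership <- t(vapply(codes, function(c0) bitwAnd(c0, 2^(0:(m - 1))) > 0,
                         logical(m)))
  keep <- rowSums(membership) >= min_members
  membership <- membership[keep, , drop = FALSE]
  add <- mono_mat %*% t(membership)   # wavelengths x mixtures
  means <- vapply(seq_len(n_rep), function(r) {
    fac <- membership * (1 + matrix(rnorm(length(membership), 0, cv),
                                    nrow = nrow(membership)))
    emp <- mono_mat %*% t(fac)
    rel <- abs(emp - add) / emp
    mean(rel[emp > threshold])
  }, numeric(1))
  mean(means)
}

# Planted-coefficient landscape value by direct subset enumeration.
oracle_subset_sum <- function(code, coef_masks, coef_values) {
  sum(coef_values[bitwAnd(code, coef_masks) == coef_masks])
}

# Replicate-mean function value of one code, via the public summary table.
landscape_mean_for_test <- function(landscape, code) {
  s <- landscape$summary
  s$mean[s$code == code]
}

# Enumerate all background codes excluding the given strains.
all_backgrounds_for_test <- function(m, strains) {
  codes <- 0:(2^m - 1)
  codes[bitwAnd(codes, sum(2^(strains - 1))) == 0]
}

# A small standard planted landscape used across tests: additive singles,
# one pairwise term on (1,2), one third-order term on the last three strains
# (so (4,5,6) at the default m = 6).
planted_test_landscape <- function(m = 6, noise_sd = 0, replicates = 1, seed = NULL) {
  co <- data.frame(
    members = c("", as.character(1:m), "1,2", paste(m - 2, m - 1, m, sep = ",")),
    value = c(0.4, seq(0.1, by = 0.08, length.out = m), -0.3, 0.2)
  )
  generate_landscape(m, co, noise_sd = noise_sd, replicates = replicates,
                     seed = seed)
}
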