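# Community-function landscapes and the interaction calculus.
#
# A landscape maps each consortium code to replicate measurements of a scalar
# function F (e.g. Abs600 as a biomass proxy). All effect and interaction
# formulas operate on replicate means:
#   functional effect   dF_k(b)   = F(b + k)  - F(b)
#   pairwise epsilon    e_ij(b)   = F(b+i+j) - F(b+i) - F(b+j) + F(b)
#   third order         u_ijk(b)  = alternating sum over the 2^3 sub-lattice
# where b is a background consortium containing none of the focal strains.

#' Construct a community-function landscape
#'
#' @param data Data frame with columns `consortium` (binary string or integer
#'   code), `replicate` (optional; defaults to 1) and `value`.
#' @param m Library size; inferred from binary strings if omitted.
#' @return Object of class `function_landscape`: list with `m`, `data` (long,
#'   replicate-level), `summary` (per code: `consortium_binary`, `code`,
#'   `richness`, `mean`, `sd`, `n`), `mean_by_code` (numeric vector indexed by
#'   `code + 1`, NA where unmeasured), and `complete` (TRUE when all `2^m`
#'   codes are present). If the empty consortium is unmeasured its function is
#'   taken as 0, with a warning, so that background-referenced formulas remain
#'   defined.
#' @export
function_landscape <- function(data, m = NULL) {
  if (!all(c("consortium", "value") %in% names(data))) {
    stop_validation("`data` must have columns consortium and value")
  }
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  cons <- data$consortium
  if (is.character(cons) || is.factor(cons)) {
    cons <- as.character(cons)
    if (is.null(m)) {
      m <- unique(nchar(cons))
      if (length(m) != 1L) stop_validation("consortium codes have inconsistent widths")
    }
    codes <- binary_to_code(cons, m)
  } else {
    if (is.null(m)) stop_validation("`m` is required when codes are integers")
    codes <- assert_mask(cons, m)
  }
  if (any(!is.finite(data$value))) stop_validation("`value` contains non-finite entries")
  df <- data.frame(code = codes, replicate = data$replicate, value = data$value)
  if (anyDuplicated(df[, c("code", "replicate")])) {
    stop_validation("duplicate (consortium, replicate) rows")
  }
  agg_mean <- tapply(df$value, df$code, mean)
  agg_sd <- tapply(df$value, df$code, stats::sd)
  agg_n <- tapply(df$value, df$code, length)
  u <- as.integer(names(agg_mean))
  summary <- data.frame(
    consortium_binary = code_to_binary(u, m), code = u,
    richness = hamming_weight(u, m),
    mean = as.numeric(agg_mean), sd = as.numeric(agg_sd),
    n = as.integer(agg_n), stringsAsFactors = FALSE
  )
  summary <- summary[order(summary$code), ]
  rownames(summary) <- NULL
  mean_by_code <- rep(NA_real_, 2^m)
  mean_by_code[summary$code + 1L] <- summary$mean
  if (is.na(mean_by_code[1])) {
    warning("empty consortium not measured; its function is taken as 0")
    mean_by_code[1] <- 0
  }
  structure(list(
    m = as.integer(m), data = df, summary = summary,
    mean_by_code = mean_by_code,
    complete = nrow(summary) == 2^m ||
      (nrow(summary) == 2^m - 1L && !(0L %in% summary$code))
  ), class = "function_landscape")
}

#' @export
print.function_landscape <- function(x, ...) {
  cat(sprintf("Community-function landscape: m = %d, %d/%d consortia measured%s\n",
              x$m, nrow(x$summary), 2^x$m,
              if (x$complete) " (complete)" else ""))
  cat(sprintf("  function range of means: [%.4g, %.4g]\n",
              min(x$summary$mean), max(x$summary$mean)))
  invisible(x)
}

# replicate-mean F of a code, erroring (with the code's name) when unmeasured
landscape_value <- function(landscape, code) {
  v <- landscape$mean_by_code[code + 1L]
  if (any(is.na(v))) {
    miss <- code[is.na(v)]
    stop_incomplete("landscape is missing consortium %s",
                    paste(code_to_binary(miss, landscape$m), collapse = ", "))
  }
  v
}

check_focal <- function(k, background, m) {
  if (any(k < 1L) || any(k > m)) stop_validation("focal strain outside 1..m")
  if (any(bitwAnd(background, bitwShiftL(1L, k - 1L)) != 0L)) {
    stop_validation("background must not contain the focal strain(s)")
  }
}

#' Functional effect of a strain in one background
#'
#' The difference in function between the consortia with and without the
#' focal strain: `dF_k(b) = F(b + k) - F(b)`.
#'
#' @param landscape A [function_landscape()].
#' @param k Focal strain index.
#' @param background Background consortium (bitmask or binary string) not
#'   containing `k`.
#' @return Data frame row: `strain`, `background_binary`,
#'   `background_function`, `effect`.
#' @export
functional_effect <- function(landscape, k, background) {
  m <- landscape$m
  if (is.character(background)) background <- binary_to_code(background, m)
  background <- assert_mask(background, m)
  check_focal(k, background, m)
  fb <- landscape_value(landscape, background)
  fk <- landscape_value(landscape, bitwOr(background, bitwShiftL(1L, k - 1L)))
  data.frame(
    strain = k, background_binary = code_to_binary(background, m),
    background_function = fb, effect = fk - fb, stringsAsFactors = FALSE
  )
}

#' Functional effects of a strain across all backgrounds
#'
#' @param landscape A complete [function_landscape()].
#' @param k Focal strain index.
#' @return Data frame with `2^(m-1)` rows as in [functional_effect()].
#' @export
functional_effects <- function(landscape, k) {
  m <- landscape$m
  backgrounds <- all_backgrounds(m, k)
  do.call(rbind, lapply(backgrounds, function(b) functional_effect(landscape, k, b)))
}

# all codes not containing the given strains
all_backgrounds <- function(m, strains) {
  mask <- sum(bitwShiftL(1L, as.integer(strains) - 1L))
  codes <- 0:(2^m - 1)
  codes[bitwAnd(codes, mask) == 0L]
}

#' Pairwise functional interaction in one background
#'
#' Deviation of the joint effect of strains `i` and `j` from the additive
#' expectation of their individual effects in the same background:
#' `e_ij(b) = F(b+i+j) - F(b+i) - F(b+j) + F(b)`.
#'
#' @param landscape A [function_landscape()].
#' @param i,j Focal strain indices.
#' @param background Background code (bitmask or binary string) containing
#'   neither strain.
#' @return Data frame row: `strain_i`, `strain_j`, `background_binary`,
#'   `epsilon`.
#' @export
pairwise_interaction <- function(landscape, i, j, background) {
  m <- landscape$m
  if (i == j) stop_validation("`i` and `j` must differ")
  if (is.character(background)) background <- binary_to_code(background, m)
  background <- assert_mask(background, m)
  check_focal(c(i, j), background, m)
  bi <- bitwOr(background, bitwShiftL(1L, i - 1L))
  bj <- bitwOr(background, bitwShiftL(1L, j - 1L))
  bij <- bitwOr(bi, bitwShiftL(1L, j - 1L))
  eps <- landscape_value(landscape, bij) - landscape_value(landscape, bi) -
    landscape_value(landscape, bj) + landscape_value(landscape, background)
  data.frame(
    strain_i = i, strain_j = j,
    background_binary = code_to_binary(background, m),
    epsilon = eps, stringsAsFactors = FALSE
  )
}

#' Pairwise interactions of a strain pair across all backgrounds
#'
#' @param landscape A complete [function_landscape()].
#' @param i,j Focal strain indices.
#' @return Data frame with `2^(m-2)` rows as in [pairwise_interaction()].
#' @export
pairwise_interactions <- function(landscape, i, j) {
  backgrounds <- all_backgrounds(landscape$m, c(i, j))
  do.call(rbind, lapply(backgrounds, function(b) pairwise_interaction(landscape, i, j, b)))
}

#' Third-order functional interaction
#'
#' Deviation of the trio's empirical function from the null expectation built
#' from additive effects and pairwise interactions: the alternating
#' inclusion-exclusion sum over the `2^3` sub-lattice spanned by strains
#' `i`, `j`, `k` above the background,
#' `sum over S of (-1)^(3 - |S|) F(b + S)`.
#'
#' @param landscape A [function_landscape()].
#' @param i,j,k Distinct focal strain indices.
#' @param background Background code containing none of the three (default:
#'   the empty consortium).
#' @return Scalar interaction value.
#' @export
third_order_interaction <- function(landscape, i, j, k, background = 0L) {
  m <- landscape$m
  trio <- c(i, j, k)
  if (length(unique(trio)) != 3L) stop_validation("strains must be distinct")
  if (is.character(background)) background <- binary_to_code(background, m)
  background <- assert_mask(background, m)
  check_focal(trio, background, m)
  total <- 0
  for (s in 0:7) {
    members <- trio[bitwAnd(s, bitwShiftL(1L, 0:2)) > 0L]
    code <- bitwOr(background, encode_consortium(members, m))
    total <- total + (-1)^(3 - length(members)) * landscape_value(landscape, code)
  }
  total
}

#' Diversity-function relationship
#'
#' Groups consortia by richness (Hamming weight) and summarizes their
#' replicate-mean functions; there are `choose(m, r)` consortia at richness
#' `r`.
#'
#' @param landscape A [function_landscape()].
#' @return Data frame: `richness`, `mean` (of per-consortium means), `sd`
#'   (across consortia), `n` (consortia in the group).
#' @export
diversity_function_curve <- function(landscape) {
  s <- landscape$summary
  out <- data.frame(
    richness = sort(unique(s$richness)),
    mean = as.numeric(tapply(s$mean, s$richness, mean)),
    sd = as.numeric(tapply(s$mean, s$richness, stats::sd)),
    n = as.integer(tapply(s$mean, s$richness, length))
  )
  rownames(out) <- NULL
  out
}

#' Rank consortia by function
#'
#' Descending order of replicate-mean function; ties are broken by the code's
#' integer value, ascending, so the ranking is deterministic.
#'
#' @param landscape A [function_landscape()].
#' @param top_n Optionally keep only the best `top_n` consortia.
#' @return Data frame: `rank`, `consortium_binary`, `richness`, `mean`, `sd`,
#'   `n`.
#' @export
rank_consortia <- function(landscape, top_n = NULL) {
  s <- landscape$summary
  s <- s[order(-s$mean, s$code), ]
  s$rank <- seq_len(nrow(s))
  if (!is.null(top_n)) s <- s[seq_len(min(top_n, nrow(s))), ]
  rownames(s) <- NULL
  s[, c("rank", "consortium_binary", "richness", "mean", "sd", "n")]
}

#' Hypercube adjacency graph of a landscape
#'
#' Edges connect consortia differing in exactly one strain; a complete
#' landscape on `m` strains has `m * 2^(m-1)` edges.
#'
#' @param landscape A [function_landscape()], or an integer `m`.
#' @return Data frame: `from_binary`, `to_binary`, `strain` (the strain whose
#'   presence differs; `to` contains it).
#' @export
adjacency_graph <- function(landscape) {
  m <- if (inherits(landscape, "function_landscape")) landscape$m else as.integer(landscape)
  codes <- 0:(2^m - 1)
  rows <- lapply(seq_len(m), function(k) {
    bit <- bitwShiftL(1L, k - 1L)
    from <- codes[bitwAnd(codes, bit) == 0L]
    data.frame(
      from_binary = code_to_binary(from, m),
      to_binary = code_to_binary(bitwOr(from, bit), m),
      strain = k, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
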