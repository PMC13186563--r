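# Synthetic data: additive mixture spectra with pipetting noise, and
# interacting function landscapes with planted coefficients.
#
# The spectra generator emulates a colorant-style validation experiment: each
# "colorant" has a smooth absorbance spectrum (sum of Gaussian peaks on a
# 380-780 nm grid) and each mixture is the sum of its constituents' spectra,
# each scaled by an independent multiplicative aliquot factor (1 + eta),
# eta ~ Normal(0, cv). The default cv of 0.0075 sits mid-range of typical
# micropipette error (0.5-1%). The landscape generator plants subset
# coefficients in the {0,1} (presence) basis -- F(c) = sum of coef(S) over
# subsets S of c plus replicate noise -- so that background-referenced
# effects and interactions recover the planted values exactly at zero noise.

#' Default colorant spectral shapes
#'
#' Deterministic single-Gaussian absorbance peaks with centers spread across
#' the wavelength range, widths 30-60 nm and unit-scale heights, loosely
#' shaped like diluted food colorants.
#'
#' @param m Number of colorants.
#' @param wavelengths Wavelength grid (nm).
#' @return List of `m` data frames with columns `center`, `width`, `height`.
#' @export
default_colorant_peaks <- function(m, wavelengths = 380:780) {
  lo <- min(wavelengths); hi <- max(wavelengths)
  centers <- lo + (hi - lo) * (seq_len(m) - 0.5) / m
  widths <- 30 + 30 * (seq_len(m) %% 3) / 2
  heights <- 0.8 + 0.1 * (seq_len(m) %% 4)
  lapply(seq_len(m), function(k) {
    data.frame(center = centers[k], width = widths[k], height = heights[k])
  })
}

gaussian_spectrum <- function(peaks, wavelengths) {
  acc <- numeric(length(wavelengths))
  for (p in seq_len(nrow(peaks))) {
    acc <- acc + peaks$height[p] *
      exp(-0.5 * ((wavelengths - peaks$center[p]) / peaks$width[p])^2)
  }
  acc
}

#' Generate additive mixture spectra with pipetting noise
#'
#' Emulates a full factorial colorant experiment: monoculture spectra for
#' each of `m` colorants, and for every requested mixture the sum of its
#' constituents' spectra scaled by independent per-constituent aliquot
#' factors `1 + eta`, `eta ~ Normal(0, cv)`. With `cv = 0` every mixture is
#' exactly additive.
#'
#' @param m Number of colorants (default 8).
#' @param wavelengths Wavelength grid in nm (default 380:780).
#' @param peaks Per-colorant peak tables as in [default_colorant_peaks()].
#' @param cv Coefficient of variation of the multiplicative pipetting noise
#'   (default 0.0075, mid-range of typical 0.5-1% micropipette error).
#' @param codes Integer codes of the mixtures to generate (default: all
#'   `2^m`).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `monocultures` (`species`, `wavelength`, `absorbance`),
#'   `mixtures` (`sample`, `replicate`, `wavelength`, `absorbance`) and
#'   `aliquot_factors` (`sample`, `species`, `factor`; the ground truth).
#' @export
generate_spectra <- function(m = 8, wavelengths = 380:780, peaks = NULL,
                             cv = 0.0075, codes = NULL, seed = NULL) {
  if (cv < 0) stop_validation("`cv` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(peaks)) peaks <- default_colorant_peaks(m, wavelengths)
  if (length(peaks) != m) stop_validation("`peaks` must have one entry per colorant")
  if (is.null(codes)) codes <- 0:(2^m - 1)
  codes <- assert_mask(codes, m)
  mono_mat <- vapply(peaks, gaussian_spectrum, numeric(length(wavelengths)),
                     wavelengths = wavelengths)
  monocultures <- data.frame(
    species = rep(seq_len(m), each = length(wavelengths)),
    wavelength = rep(wavelengths, m),
    absorbance = as.vector(mono_mat)
  )
  mix_rows <- vector("list", length(codes))
  fac_rows <- vector("list", length(codes))
  for (idx in seq_along(codes)) {
    c0 <- codes[idx]
    members <- decode_consortium(c0, m)
    bin <- code_to_binary(c0, m)
    eta <- if (length(members)) stats::rnorm(length(members), 0, cv) else numeric(0)
    spec <- numeric(length(wavelengths))
    for (t in seq_along(members)) {
      spec <- spec + (1 + eta[t]) * mono_mat[, members[t]]
    }
    mix_rows[[idx]] <- data.frame(
      sample = bin, replicate = 1L, wavelength = wavelengths,
      absorbance = spec, stringsAsFactors = FALSE
    )
    if (length(members)) {
      fac_rows[[idx]] <- data.frame(
        sample = bin, species = members, factor = 1 + eta,
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    monocultures = monocultures,
    mixtures = do.call(rbind, mix_rows),
    aliquot_factors = do.call(rbind, fac_rows)
  )
}

# parse a coefficient table: `members` is "" (intercept) or comma-separated
# strain indices, e.g. "1,3"; returns masks and values
parse_coefficients <- function(coefficients, m) {
  if (is.null(coefficients) || nrow(coefficients) == 0L) {
    return(data.frame(mask = integer(), value = numeric()))
  }
  if (!all(c("members", "value") %in% names(coefficients))) {
    stop_validation("`coefficients` must have columns members and value")
  }
  mask <- vapply(as.character(coefficients$members), function(s) {
    s <- trimws(s)
    if (s == "" || s == "0") return(0L)
    encode_consortium(as.integer(strsplit(s, ",")[[1]]), m)
  }, integer(1))
  if (anyDuplicated(mask)) stop_validation("duplicate coefficient subsets")
  data.frame(mask = mask, value = coefficients$value)
}

#' Generate a function landscape with planted coefficients
#'
#' Builds `F(c) = sum of coef(S) over subsets S of c`, plus independent
#' `Normal(0, noise_sd)` noise per replicate. Coefficients are specified in
#' the presence basis, so a planted pair coefficient is exactly the pairwise
#' interaction `epsilon` recovered downstream in every background (at zero
#' noise), and singleton coefficients are the additive strain contributions.
#'
#' @param m Library size.
#' @param coefficients Data frame with columns `members` (comma-separated
#'   strain indices, `""` for the intercept, e.g. `"2"` or `"1,3"`) and
#'   `value`.
#' @param noise_sd Replicate noise standard deviation (default 0).
#' @param replicates Replicates per consortium (default 1).
#' @param seed Optional integer seed.
#' @return A [function_landscape()] with attribute `ground_truth` (the parsed
#'   coefficient table: `mask`, `members_binary`, `value`).
#' @export
generate_landscape <- function(m, coefficients, noise_sd = 0, replicates = 1,
                               seed = NULL) {
  if (replicates < 1) stop_validation("`replicates` must be >= 1")
  if (noise_sd < 0) stop_validation("`noise_sd` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  co <- parse_coefficients(coefficients, m)
  codes <- 0:(2^m - 1)
  f <- numeric(length(codes))
  for (r in seq_len(nrow(co))) {
    sub <- bitwAnd(codes, co$mask[r]) == co$mask[r]
    f[sub] <- f[sub] + co$value[r]
  }
  df <- data.frame(
    consortium = rep(codes, each = replicates),
    replicate = rep(seq_len(replicates), length(codes)),
    value = rep(f, each = replicates) +
      stats::rnorm(length(codes) * replicates, 0, noise_sd)
  )
  ls <- function_landscape(df, m = m)
  attr(ls, "ground_truth") <- data.frame(
    mask = co$mask, members_binary = code_to_binary(co$mask, m),
    value = co$value, stringsAsFactors = FALSE
  )
  ls
}

#' Generate a landscape with exact global epistasis
#'
#' Constructs a landscape on which every strain's functional effect is an
#' exactly linear function of the background function: adding strain `k`
#' maps `F` to `a_k + (1 + s_k) F` with `a_k = alpha * s_k`, which commutes
#' across strains and yields `F(c) = (f0 + alpha) * prod(1 + s_k) - alpha`
#' over the members of `c`. Per-strain global-epistasis fits on this
#' landscape have `R^2 = 1` (for `s_k != 0`), making it a positive control
#' for [epistasis_null()].
#'
#' @param m Library size.
#' @param slopes Numeric vector of `m` per-strain slopes `s_k` (default: a
#'   fixed spread of nonzero diminishing/amplifying factors).
#' @param alpha,f0 Scalars of the construction (defaults 1 and 1).
#' @return A [function_landscape()].
#' @export
generate_epistatic_landscape <- function(m, slopes = NULL, alpha = 1, f0 = 1) {
  if (is.null(slopes)) slopes <- seq(-0.35, 0.35, length.out = m) + 0.05
  if (length(slopes) != m) stop_validation("`slopes` must have length m")
  codes <- 0:(2^m - 1)
  f <- vapply(codes, function(c0) {
    members <- decode_consortium(c0, m)
    (f0 + alpha) * prod(1 + slopes[members]) - alpha
  }, numeric(1))
  function_landscape(data.frame(consortium = codes, value = f), m = m)
}
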