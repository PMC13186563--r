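# Additive spectral expectations and deviation statistics.
#
# For non-interacting constituents (e.g. colorants), the absorbance spectrum
# of a mixture should equal the sum of its constituents' spectra. The relative
# deviation between an empirical spectrum and this additive expectation,
#   delta(c, lambda) = |Abs(c) - Abs_add(c)| / Abs(c),
# bounds the cumulative pipetting error of the assembly; for organisms that do
# interact, the same deviation quantifies interaction signal instead.
# Relative deviations are only computed where the empirical absorbance
# exceeds a threshold (0.1 A.U. by default), since the ratio is unstable near
# zero.

check_spectrum_table <- function(x, what = "spectrum table") {
  need <- c("sample", "wavelength", "absorbance")
  if (!all(need %in% names(x))) {
    stop_validation("%s must have columns %s", what, paste(need, collapse = ", "))
  }
  if (any(!is.finite(x$absorbance))) stop_validation("%s has non-finite absorbances", what)
  invisible(x)
}

#' Additive spectral expectation of a mixture
#'
#' Pointwise sum of the monoculture spectra of a consortium's constituents;
#' the empty consortium has an all-zero expectation.
#'
#' @param code Consortium code (integer bitmask or binary string).
#' @param monocultures Data frame with columns `species` (index 1..m),
#'   `wavelength`, `absorbance`, one value per (species, wavelength). All
#'   species must share the same wavelength grid.
#' @param m Library size (inferred from a binary-string `code` if omitted).
#' @return Data frame with columns `wavelength` and `absorbance`.
#' @export
additive_expectation <- function(code, monocultures, m = NULL) {
  if (is.character(code)) {
    if (is.null(m)) m <- nchar(code)
    code <- binary_to_code(code, m)
  }
  if (is.null(m)) stop_validation("`m` is required for integer codes")
  if (!all(c("species", "wavelength", "absorbance") %in% names(monocultures))) {
    stop_validation("`monocultures` must have columns species, wavelength, absorbance")
  }
  grid <- sort(unique(monocultures$wavelength))
  members <- decode_consortium(code, m)
  acc <- numeric(length(grid))
  for (k in members) {
    sk <- monocultures[monocultures$species == k, ]
    if (nrow(sk) == 0L) {
      stop_validation("no monoculture spectrum for species %d", k)
    }
    sk <- sk[order(sk$wavelength), ]
    if (!identical(as.numeric(sk$wavelength), as.numeric(grid))) {
      stop_validation("species %d is not on the shared wavelength grid", k)
    }
    acc <- acc + sk$absorbance
  }
  data.frame(wavelength = grid, absorbance = acc)
}

#' Deviations between empirical spectra and additive expectations
#'
#' Computes, per mixture and wavelength, the absolute deviation
#' `|Abs - Abs_add|` everywhere and the relative deviation
#' `|Abs - Abs_add| / Abs` wherever the empirical absorbance exceeds
#' `threshold` (masked to `NA` elsewhere). Replicates, if present, are
#' averaged per (sample, wavelength) before the comparison.
#'
#' @param mixtures Spectrum table: columns `sample` (binary code string),
#'   optional `replicate`, `wavelength`, `absorbance`.
#' @param monocultures Monoculture spectra as in [additive_expectation()].
#' @param m Library size; inferred from the sample codes if omitted.
#' @param threshold Minimum empirical absorbance (A.U.) for a relative
#'   deviation to be reported; default 0.1.
#' @return Data frame with columns `sample`, `richness`, `wavelength`,
#'   `empirical`, `additive_expectation`, `absolute_deviation`,
#'   `relative_deviation` (NA where masked).
#' @export
spectral_deviations <- function(mixtures, monocultures, m = NULL, threshold = 0.1) {
  check_spectrum_table(mixtures, "`mixtures`")
  samples <- unique(as.character(mixtures$sample))
  if (is.null(m)) m <- unique(nchar(samples))
  if (length(m) != 1L) stop_validation("sample codes have inconsistent widths")
  # replicate means per (sample, wavelength)
  emp <- stats::aggregate(absorbance ~ sample + wavelength, data = mixtures, FUN = mean)
  out <- lapply(samples, function(s) {
    e <- emp[emp$sample == s, ]
    e <- e[order(e$wavelength), ]
    add <- additive_expectation(s, monocultures, m)
    if (!identical(as.numeric(e$wavelength), as.numeric(add$wavelength))) {
      stop_validation("sample %s is not on the monoculture wavelength grid", s)
    }
    absdev <- abs(e$absorbance - add$absorbance)
    rel <- ifelse(e$absorbance > threshold, absdev / e$absorbance, NA_real_)
    data.frame(
      sample = s, richness = hamming_weight(s),
      wavelength = e$wavelength, empirical = e$absorbance,
      additive_expectation = add$absorbance,
      absolute_deviation = absdev, relative_deviation = rel,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Summarize spectral deviations
#'
#' Headline statistics pool all unmasked wavelengths of all mixtures with at
#' least `min_richness` constituents (2 by default, so monocultures -- which
#' match their own expectation trivially -- are excluded).
#'
#' @param deviations Output of [spectral_deviations()].
#' @param group_by `"overall"` (default), `"sample"`, `"cardinality"` (groups
#'   by the number of constituents) or `"wavelength"`.
#' @param min_richness Minimum number of constituents for a mixture to enter
#'   the summary.
#' @return Data frame with, per group: `n` (unmasked points),
#'   `mean_relative`, `median_relative`, `mean_absolute`, `median_absolute`.
#' @export
deviation_summary <- function(deviations,
                              group_by = c("overall", "sample", "cardinality", "wavelength"),
                              min_richness = 2) {
  group_by <- match.arg(group_by)
  d <- deviations[deviations$richness >= min_richness, ]
  if (nrow(d) == 0L || all(is.na(d$relative_deviation))) {
    warning("no unmasked deviations to summarize")
    return(data.frame(group = character(), n = integer(),
                      mean_relative = numeric(), median_relative = numeric(),
                      mean_absolute = numeric(), median_absolute = numeric()))
  }
  key <- switch(group_by,
    overall = rep("overall", nrow(d)),
    sample = d$sample,
    cardinality = d$richness,
    wavelength = d$wavelength
  )
  groups <- split(d, key)
  out <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    rel <- x$relative_deviation[!is.na(x$relative_deviation)]
    data.frame(
      group = g, n = length(rel),
      mean_relative = mean(rel), median_relative = stats::median(rel),
      mean_absolute = mean(x$absolute_deviation),
      median_absolute = stats::median(x$absolute_deviation),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (group_by %in% c("cardinality", "wavelength")) {
    out$group <- as.numeric(out$group)
    out <- out[order(out$group), ]
  }
  rownames(out) <- NULL
  out
}
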