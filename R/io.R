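# CSV readers/writers for the interchange schemas. Long/tidy CSV is the
# canonical format; every writer's output is accepted unchanged by its
# paired reader.

#' Write a function landscape to CSV
#'
#' Schema: `consortium_binary,replicate,value`, one row per replicate
#' measurement.
#'
#' @param landscape A [function_landscape()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_function_csv <- function(landscape, path) {
  df <- data.frame(
    consortium_binary = code_to_binary(landscape$data$code, landscape$m),
    replicate = landscape$data$replicate,
    value = landscape$data$value
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a function landscape from CSV
#'
#' @param path CSV with columns `consortium_binary`, `replicate` (optional)
#'   and `value`.
#' @param m Optional expected library size.
#' @return A [function_landscape()].
#' @export
read_function_csv <- function(path, m = NULL) {
  df <- utils::read.csv(path, colClasses = c(consortium_binary = "character"))
  if (nrow(df) == 0L) stop_validation("%s: empty function table", path)
  if (!all(c("consortium_binary", "value") %in% names(df))) {
    stop_validation("%s: need columns consortium_binary and value", path)
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$value))))
  if (length(bad)) {
    stop_validation("%s: non-numeric value at data row(s) %s", path,
                    paste(utils::head(bad, 5), collapse = ", "))
  }
  names(df)[names(df) == "consortium_binary"] <- "consortium"
  function_landscape(df, m = m)
}

#' Write a spectrum table to CSV
#'
#' Schema: `sample,replicate,wavelength,absorbance`.
#'
#' @param spectra Data frame with those columns (`replicate` optional).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  check_spectrum_table(spectra)
  if (!"replicate" %in% names(spectra)) spectra$replicate <- 1L
  utils::write.csv(spectra[, c("sample", "replicate", "wavelength", "absorbance")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read plate-reader measurements from CSV
#'
#' Accepts long tables with either an explicit `consortium_binary` column or
#' `(plate, well)` columns resolved against a [plate_layout()]. Column names
#' can be remapped via `mapping` (names are canonical: `sample`, `plate`,
#' `well`, `replicate`, `wavelength`, `absorbance`) to accommodate
#' instrument-export headers such as `wavelength_nm`.
#'
#' @param path CSV file path.
#' @param layout Optional [plate_layout()] used to translate `(plate, well)`
#'   into consortium codes when the file lacks a code column.
#' @param mapping Optional named character vector, canonical name -> file
#'   column name.
#' @return Spectrum table: `sample`, `replicate`, `wavelength`, `absorbance`.
#' @export
read_measurements_csv <- function(path, layout = NULL, mapping = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L) stop_validation("%s: empty measurement table", path)
  canon <- c(sample = "consortium_binary", plate = "plate", well = "well",
             replicate = "replicate", wavelength = "wavelength",
             absorbance = "absorbance")
  if (!is.null(mapping)) canon[names(mapping)] <- mapping
  # the writer's own header spells the code column "sample"
  if (!canon[["sample"]] %in% names(df) && "sample" %in% names(df)) {
    canon[["sample"]] <- "sample"
  }
  pick <- function(key) if (canon[[key]] %in% names(df)) df[[canon[[key]]]] else NULL
  absorb <- pick("absorbance")
  wl <- pick("wavelength")
  if (is.null(absorb) || is.null(wl)) {
    stop_validation("%s: need wavelength and absorbance columns (see `mapping`)", path)
  }
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad)) {
      stop_validation("%s: non-numeric %s at data row(s) %s", path, what,
                      paste(utils::head(bad, 5), collapse = ", "))
    }
    v
  }
  sample <- pick("sample")
  if (is.null(sample)) {
    if (is.null(layout)) {
      stop_validation("%s: no consortium column and no layout to resolve wells", path)
    }
    plate <- num(pick("plate"), "plate")
    well <- pick("well")
    if (is.null(plate) || is.null(well)) {
      stop_validation("%s: need plate and well columns to join against the layout", path)
    }
    key <- paste(plate, toupper(well))
    lay_key <- paste(layout$plate, layout$well_name)
    hit <- match(key, lay_key)
    if (anyNA(hit)) {
      bad <- which(is.na(hit))
      stop_validation("%s: unknown well(s) at data row(s) %s (e.g. %s)", path,
                      paste(utils::head(bad, 5), collapse = ", "),
                      key[bad[1]])
    }
    sample <- layout$consortium_binary[hit]
  }
  rep_col <- pick("replicate")
  out <- data.frame(
    sample = as.character(sample),
    replicate = if (is.null(rep_col)) 1L else as.integer(rep_col),
    wavelength = num(wl, "wavelength"),
    absorbance = num(absorb, "absorbance"),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(out[, c("sample", "replicate", "wavelength")])
  if (any(dup)) {
    stop_validation("%s: duplicate (sample, replicate, wavelength) at data row(s) %s",
                    path, paste(utils::head(which(dup), 5), collapse = ", "))
  }
  out
}

#' Write run metadata as JSON
#'
#' Records package version, timestamp, seed, parameters, and input file
#' hashes alongside any pipeline output, for reproducibility.
#'
#' @param path Output file path.
#' @param params Named list of run parameters.
#' @param seed Integer seed used (or `NA`).
#' @param inputs Character vector of input file paths to fingerprint.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(path, params = list(), seed = NA, inputs = character()) {
  meta <- list(
    package = "consortia",
    version = as.character(utils::packageVersion("consortia")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    params = params,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
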