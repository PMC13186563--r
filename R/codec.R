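# Binary consortium codec and plate layout.
#
# Every consortium drawn from an m-species library is identified by the binary
# number c = x_m x_{m-1} ... x_1, where x_k = 1 iff species k is present.
# Internally a code is a non-negative integer bitmask (bit k-1 <-> species k);
# the binary string is a rendering. The same integer doubles as the rank of
# the consortium in the canonical plate layout: the low row bits give the row,
# the remaining bits the (global) column.

#' Define a species library
#'
#' @param m Number of species (1 to 30).
#' @param names Optional character vector of `m` unique species labels.
#'   Defaults to `"S1" ... "Sm"`. Species `k` corresponds to bit `k - 1` of a
#'   consortium code.
#' @return An object of class `species_library` with fields `m` and `names`.
#' @examples
#' lib <- species_library(8)
#' lib$names
#' @export
species_library <- function(m, names = NULL) {
  if (length(m) != 1L || is.na(m) || m < 1 || m != round(m)) {
    stop_validation("`m` must be a single integer >= 1")
  }
  if (m > 30) stop_validation("`m` must be <= 30 (codes are 32-bit integers)")
  m <- as.integer(m)
  if (is.null(names)) names <- paste0("S", seq_len(m))
  if (length(names) != m) stop_validation("`names` must have length m")
  if (anyDuplicated(names)) stop_validation("species names must be unique")
  structure(list(m = m, names = as.character(names)), class = "species_library")
}

#' @export
print.species_library <- function(x, ...) {
  cat("Species library: m =", x$m, "\n ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

# number of 1-bits of each element of a non-negative integer vector
bit_count <- function(x) {
  x <- as.integer(x)
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

assert_mask <- function(mask, m, what = "code") {
  if (any(is.na(mask)) || any(mask < 0) || any(mask != round(mask))) {
    stop_validation(sprintf("%s must be non-negative integers", what))
  }
  if (any(mask >= 2^m)) {
    stop_validation(sprintf("%s out of range for m = %d (must be < 2^m)", what, m))
  }
  invisible(as.integer(mask))
}

#' Encode a set of species as a consortium code
#'
#' Builds the integer bitmask of the consortium containing exactly the given
#' species, i.e. the binary number `x_m ... x_1` with `x_k = 1` iff `k` is a
#' member. For instance with `m = 6`, members `c(1, 2, 3)` encode to
#' `"000111"`.
#'
#' @param members Integer vector of species indices (subset of `1:m`); may be
#'   empty for the blank consortium.
#' @param m Library size.
#' @return Integer bitmask in `0:(2^m - 1)`.
#' @seealso [decode_consortium()], [code_to_binary()]
#' @export
encode_consortium <- function(members, m) {
  members <- as.integer(members)
  if (anyDuplicated(members)) members <- unique(members)
  if (length(members) && (any(members < 1L) || any(members > m))) {
    stop_validation(sprintf("species indices must lie in 1..%d", m))
  }
  as.integer(sum(bitwShiftL(1L, members - 1L)))
}

#' Decode a consortium code into its member species
#'
#' @param code Integer bitmask.
#' @param m Library size.
#' @return Increasing integer vector of species indices present in the code.
#' @export
decode_consortium <- function(code, m) {
  code <- assert_mask(code, m)
  which(bitwAnd(code, bitwShiftL(1L, 0:(m - 1L))) > 0L)
}

#' Render consortium codes as binary strings
#'
#' The leftmost character is `x_m` (species m), the rightmost `x_1`.
#'
#' @param code Integer vector of bitmasks.
#' @param m Library size (string width).
#' @return Character vector of `m`-character binary strings.
#' @export
code_to_binary <- function(code, m) {
  code <- assert_mask(code, m)
  vapply(code, function(z) {
    bits <- bitwAnd(bitwShiftR(z, (m - 1L):0L), 1L)
    paste(bits, collapse = "")
  }, character(1))
}

#' Parse binary strings into consortium codes
#'
#' @param x Character vector of binary strings (`x_m ... x_1`).
#' @param m Optional expected width; inferred from the strings if omitted.
#' @return Integer vector of bitmasks.
#' @export
binary_to_code <- function(x, m = NULL) {
  x <- as.character(x)
  w <- unique(nchar(x))
  if (length(w) != 1L) stop_validation("binary strings must share one width")
  if (!is.null(m) && w != m) {
    stop_validation(sprintf("binary strings have width %d, expected m = %d", w, m))
  }
  if (any(grepl("[^01]", x))) stop_validation("binary strings may only contain 0/1")
  vapply(strsplit(x, ""), function(b) {
    as.integer(sum(as.integer(b) * 2^((w - 1L):0L)))
  }, integer(1))
}

#' Hamming weight (richness) of consortium codes
#'
#' The number of 1-bits of a code equals the number of species present, e.g.
#' `H(0000) = 0`, `H(0010) = 1`, `H(1111) = 4`.
#'
#' @param code Integer vector of bitmasks (or binary strings).
#' @param m Library size; required only for range checking of integer input.
#' @return Integer vector of richness values.
#' @export
hamming_weight <- function(code, m = NULL) {
  if (is.character(code)) code <- binary_to_code(code, m)
  if (!is.null(m)) assert_mask(code, m)
  bit_count(code)
}

#' Merge two disjoint consortia
#'
#' Merging disjoint consortia is binary addition of their codes
#' (`110000 + 000011 = 110011`). The operation is only defined when the two
#' consortia share no species; merging overlapping consortia is an error, as
#' binary addition would then carry into a spurious species
#' (`100001 + 000001` would yield `100010`).
#'
#' @param c1,c2 Codes (integer bitmasks, or binary strings of equal width).
#' @param m Library size; required for integer input.
#' @return Merged code, in the representation of the input (string in, string
#'   out).
#' @export
merge_disjoint <- function(c1, c2, m = NULL) {
  as_string <- is.character(c1) || is.character(c2)
  if (is.character(c1) != is.character(c2)) {
    stop_validation("`c1` and `c2` must share a representation")
  }
  if (as_string) {
    if (!length(unique(nchar(c(c1, c2)))) == 1L) {
      stop_validation("codes have mismatched widths")
    }
    m <- nchar(c1[1])
    c1 <- binary_to_code(c1, m)
    c2 <- binary_to_code(c2, m)
  }
  if (is.null(m)) stop_validation("`m` is required for integer codes")
  c1 <- assert_mask(c1, m)
  c2 <- assert_mask(c2, m)
  if (any(bitwAnd(c1, c2) != 0L)) {
    stop_validation("consortia share species: merge is only defined for disjoint consortia")
  }
  out <- c1 + c2
  if (as_string) code_to_binary(out, m) else out
}

# plate geometry: rows, columns, and how many low bits of a code are row bits
plate_dims <- function(format) {
  format <- as.integer(format)
  if (identical(format, 96L))  return(list(rows = 8L,  cols = 12L, row_bits = 3L))
  if (identical(format, 384L)) return(list(rows = 16L, cols = 24L, row_bits = 4L))
  stop_validation("`format` must be 96 or 384")
}

#' Number of plates needed for a full factorial layout
#'
#' All `2^m` consortia occupy `max(1, 2^(m - r))` global columns, where `r` is
#' the number of row bits (3 for 96-well, 4 for 384-well); columns beyond the
#' plate width continue on the next plate.
#'
#' @param m Library size.
#' @param format Plate format, 96 (default) or 384.
#' @return Integer number of plates.
#' @export
plates_required <- function(m, format = 96) {
  d <- plate_dims(format)
  n_cols <- max(1, 2^(max(0L, m - d$row_bits)))
  as.integer(ceiling(n_cols / d$cols))
}

#' Map a consortium code to its well
#'
#' In the canonical layout the low row bits of a code give the row
#' (`i = low bits + 1`, row 1 = row A at the top) and the remaining high bits
#' give the global column (`j_global = high bits + 1`); global columns beyond
#' the plate width wrap onto subsequent plates. Consortia therefore appear in
#' increasing integer order top-to-bottom, then left-to-right across plates.
#'
#' @param code Integer vector of bitmasks.
#' @param m Library size.
#' @param format Plate format, 96 or 384.
#' @return Data frame with columns `code`, `plate`, `i` (row index), `j_global`,
#'   `j_local`, `row_letter`, `well_name`.
#' @export
code_to_well <- function(code, m, format = 96) {
  d <- plate_dims(format)
  code <- assert_mask(code, m)
  base <- 2L^d$row_bits
  i <- code %% base + 1L
  j_global <- code %/% base + 1L
  plate <- (j_global - 1L) %/% d$cols + 1L
  j_local <- (j_global - 1L) %% d$cols + 1L
  data.frame(
    code = code, plate = plate, i = i, j_global = j_global, j_local = j_local,
    row_letter = LETTERS[i],
    well_name = paste0(LETTERS[i], sprintf("%02d", j_local)),
    stringsAsFactors = FALSE
  )
}

#' Map a well back to its consortium code
#'
#' Inverse of [code_to_well()]: the three (96-well) or four (384-well) low
#' bits of the code are `B(i - 1)`, the remaining bits are `B(j_global - 1)`.
#'
#' @param i Row index (1 = row A).
#' @param j_global Global column index (column 13 of a 96-well layout = column
#'   1 of plate 2, and so on).
#' @param m Library size.
#' @param format Plate format, 96 or 384.
#' @return Integer vector of bitmasks.
#' @export
well_to_code <- function(i, j_global, m, format = 96) {
  d <- plate_dims(format)
  if (any(i < 1L) || any(i > d$rows)) stop_validation("row index out of range")
  if (any(j_global < 1L)) stop_validation("column index out of range")
  code <- (as.integer(j_global) - 1L) * as.integer(2^d$row_bits) +
    (as.integer(i) - 1L)
  assert_mask(code, m, what = "well")
  as.integer(code)
}

#' Hamming-weight split of a well address
#'
#' Because the row determines the low bits of a code and the column the high
#' bits, the richness of the consortium in well `(i, j)` decomposes as
#' `H(c) = H(B(i - 1)) + H(B(j - 1))`. This function returns that sum from the
#' positional indices alone.
#'
#' @param i Row index (1-based).
#' @param j Global column index (1-based).
#' @return Integer vector `H(B(i - 1)) + H(B(j - 1))`.
#' @export
hamming_split <- function(i, j) {
  if (any(i < 1L) || any(j < 1L)) stop_validation("indices are 1-based")
  bit_count(as.integer(i) - 1L) + bit_count(as.integer(j) - 1L)
}

#' Placement rule for one species
#'
#' Species occupy alternating blocks of rows or columns: on a 96-well layout
#' species `k <= 3` is present in alternating sets of `2^(k-1)` rows, and
#' species `k >= 4` in alternating sets of `2^(k-4)` global columns (e.g.
#' species 4 in columns 2, 4, 6, 8, ..., species 5 in columns 3, 4, 7, 8, ...).
#' On a 384-well layout the split is after species 4 (16 rows = 4 row bits).
#'
#' @param k Species index.
#' @param m Library size.
#' @param format Plate format, 96 or 384.
#' @return List with `axis` (`"rows"` or `"columns"`), `block` (the alternation
#'   block size) and `indices` (rows, or global columns, where species `k` is
#'   present).
#' @export
species_positions <- function(k, m, format = 96) {
  d <- plate_dims(format)
  if (length(k) != 1L || k < 1L || k > m) stop_validation("`k` must lie in 1..m")
  k <- as.integer(k)
  n_cols <- max(1L, 2L^(max(0L, m - d$row_bits)))
  if (k <= d$row_bits) {
    idx <- seq_len(min(d$rows, 2L^m))
    keep <- bitwAnd(idx - 1L, bitwShiftL(1L, k - 1L)) > 0L
    list(axis = "rows", block = 2L^(k - 1L), indices = idx[keep])
  } else {
    idx <- seq_len(n_cols)
    keep <- bitwAnd(idx - 1L, bitwShiftL(1L, k - 1L - d$row_bits)) > 0L
    list(axis = "columns", block = 2L^(k - 1L - d$row_bits), indices = idx[keep])
  }
}

#' Full factorial plate layout
#'
#' Enumerates all `2^m` consortia in canonical order and assigns each to its
#' well, one row per consortium.
#'
#' @param library A [species_library()], or an integer `m`.
#' @param format Plate format, 96 (default) or 384.
#' @return A data frame of class `plate_layout` with columns `plate`,
#'   `row_letter`, `col_local`, `well_name`, `col_global`, `consortium_binary`,
#'   `consortium_int`, `richness`, plus attributes `m` and `format`.
#' @examples
#' head(plate_layout(4))
#' @export
plate_layout <- function(library, format = 96) {
  if (!inherits(library, "species_library")) library <- species_library(library)
  m <- library$m
  codes <- 0:(2^m - 1)
  w <- code_to_well(codes, m, format)
  out <- data.frame(
    plate = w$plate,
    row_letter = w$row_letter,
    col_local = w$j_local,
    well_name = w$well_name,
    col_global = w$j_global,
    consortium_binary = code_to_binary(codes, m),
    consortium_int = as.integer(codes),
    richness = hamming_weight(codes, m),
    stringsAsFactors = FALSE
  )
  structure(out,
    m = m, format = as.integer(format), library = library,
    class = c("plate_layout", "data.frame")
  )
}

#' Write a plate layout to CSV
#'
#' @param layout A [plate_layout()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_layout_csv <- function(layout, path) {
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
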