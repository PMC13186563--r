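# Pipetting-plan generation and verification.
#
# A plan realizes the full factorial layout with multichannel pipettes. Two
# strategies are provided:
#
#  * direct_dispense (default): the 2^r starting mixes of the row species
#    (r = 3 on 96-well plates) are prepared in tubes -- with buffer added per
#    tube when densities are homogenized, which makes row-wise buffer
#    pipetting unnecessary -- then dispensed into every global column; the
#    remaining species are added column-wise per their placement rule, and
#    column-wise buffer tops every well up to m * v0.
#  * block_duplication: the literal column-doubling scheme -- assemble the
#    row-species combinations in column 1 at 2^(m-r)-fold scale, then
#    repeatedly transfer half of each existing column into a fresh column and
#    add the next species to the copies (re-buffering the originals), until
#    all 2^m consortia exist. Faithful to the doubling narrative but the
#    first-column volumes scale as 2^(m-r) * v0, so large m exceeds well
#    capacity and the planner reports the failing step.
#
# Both are verified by a deterministic liquid-transfer simulator whose
# endpoint must equal the layout composition, with per-species
# monoculture-equivalent volume v0 and (under full homogenization) total
# volume m * v0 in every well.

#' Configure an assembly plan
#'
#' @param library A [species_library()] or an integer `m`.
#' @param v0 Per-species aliquot volume in each final well (uL of monoculture
#'   equivalent).
#' @param format Plate format, 96 (default) or 384.
#' @param strategy `"direct_dispense"` (default) or `"block_duplication"`.
#' @param homogenize `"full"` (default; buffer brings every well to `m * v0`
#'   so each species sits at `1/m` of monoculture density), `"column_only"`
#'   (column-term buffer only) or `"off"` (no buffer; well volume is
#'   `richness * v0`).
#' @param buffer_name Label of the volume-adjustment liquid (water, PBS,
#'   medium); chemistry is not modeled.
#' @param well_capacity Maximum working volume per well (uL). Intermediate
#'   volumes above this abort planning with a capacity error naming the step.
#' @param inoculum_volume,culture_volume Volumes (uL) used by
#'   [inoculation_summary()]; defaults 0.5 uL into 200 uL (a 1:400 dilution).
#' @return An object of class `plan_config`.
#' @export
plan_config <- function(library, v0 = 25, format = 96,
                        strategy = c("direct_dispense", "block_duplication"),
                        homogenize = c("full", "column_only", "off"),
                        buffer_name = "buffer", well_capacity = 300,
                        inoculum_volume = 0.5, culture_volume = 200) {
  if (!inherits(library, "species_library")) library <- species_library(library)
  strategy <- match.arg(strategy)
  homogenize <- match.arg(homogenize)
  if (!is.numeric(v0) || length(v0) != 1L || v0 <= 0) {
    stop_validation("`v0` must be a single positive volume")
  }
  if (!is.numeric(well_capacity) || well_capacity <= 0) {
    stop_validation("`well_capacity` must be positive")
  }
  if (strategy == "block_duplication" && homogenize == "column_only") {
    stop_validation(paste(
      "homogenize = 'column_only' is not defined for block_duplication:",
      "per-row totals diverge and the halving schedule is ambiguous;",
      "use 'full' or 'off'"
    ))
  }
  plate_dims(format)
  structure(list(
    library = library, m = library$m, v0 = v0, format = as.integer(format),
    strategy = strategy, homogenize = homogenize, buffer_name = buffer_name,
    well_capacity = well_capacity,
    inoculum_volume = inoculum_volume, culture_volume = culture_volume
  ), class = "plan_config")
}

#' Naive liquid-handling event count
#'
#' Assembling all `2^m` consortia one aliquot at a time takes `m * 2^(m-1)`
#' pipetting events (each species enters half of all consortia). Plans
#' produced here need far fewer events; the ratio is the method's efficiency
#' gain.
#'
#' @param m Library size.
#' @return `m * 2^(m-1)`.
#' @export
naive_event_count <- function(m) {
  if (any(m < 1)) stop_validation("`m` must be >= 1")
  m * 2^(m - 1)
}

#' Buffer volume for a consortium
#'
#' Under full density homogenization every well is brought to the volume of
#' the richest consortium, `m * v0`, so consortium `c` needs
#' `v_B(c) = v0 * (m - H(c))` of buffer.
#'
#' @param code Integer bitmask(s) (or binary strings).
#' @param m Library size.
#' @param v0 Per-species aliquot volume (uL).
#' @return Numeric buffer volume(s) in uL.
#' @export
buffer_volume_code <- function(code, m, v0) {
  v0 * (m - hamming_weight(code, m))
}

#' Positional split of the buffer volume
#'
#' The buffer volume of the consortium in well `(i, j)` splits into a row term
#' `v0 * (r - H(B(i-1)))` and a column term `v0 * (m - r - H(B(j-1)))`, with
#' `r` the number of row bits (3 on 96-well plates, capped at `m`). The two
#' terms always sum to [buffer_volume_code()] of the well's consortium, which
#' is what lets buffer be pipetted column-wise then row-wise with multichannel
#' pipettes instead of well by well.
#'
#' @param i Row index (1-based).
#' @param j Global column index (1-based).
#' @param m Library size.
#' @param v0 Per-species aliquot volume (uL).
#' @param format Plate format, 96 or 384.
#' @return Data frame with columns `row_term` and `column_term` (uL).
#' @export
buffer_volume_positional <- function(i, j, m, v0, format = 96) {
  d <- plate_dims(format)
  r <- min(m, d$row_bits)
  data.frame(
    row_term = v0 * (r - bit_count(as.integer(i) - 1L)),
    column_term = v0 * (m - r - bit_count(as.integer(j) - 1L))
  )
}

#' Per-strain inoculation arithmetic
#'
#' With densities homogenized, inoculating a consortium into fresh medium
#' delivers an equal share of every member's monoculture: e.g. 0.5 uL of an
#' 8-species mix into 200 uL of medium is a 1:400 dilution carrying
#' `0.5 / 8 = 0.0625` uL of each strain's monoculture.
#'
#' @param config A [plan_config()].
#' @return List with `dilution_factor`, `dilution_label`, and
#'   `per_strain_volume_uL`.
#' @export
inoculation_summary <- function(config) {
  if (!inherits(config, "plan_config")) stop_validation("`config` must be a plan_config")
  if (config$homogenize != "full") {
    stop_validation("inoculation_summary assumes homogenize = 'full' (uniform densities)")
  }
  dil <- config$culture_volume / config$inoculum_volume
  list(
    dilution_factor = dil,
    dilution_label = sprintf("1:%g", dil),
    per_strain_volume_uL = config$inoculum_volume / config$m
  )
}

# --- internal plan builder -------------------------------------------------

# wells are addressed by slot = (j_global - 1) * 2^row_bits + i
well_slot <- function(i, j, row_bits) (as.integer(j) - 1L) * 2L^row_bits + as.integer(i)

slot_ij <- function(slot, row_bits) {
  slot <- as.integer(slot)
  list(i = (slot - 1L) %% 2L^row_bits + 1L, j = (slot - 1L) %/% 2L^row_bits + 1L)
}

new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$step <- 0L
  env
}

# one physical pipetting event (possibly multichannel: several elementary
# transfers sharing a step id)
add_step <- function(b, phase, reagent, channel, source_kind, source_ref,
                     dest_kind, dest_ref, volume) {
  n <- max(length(source_ref), length(dest_ref), length(volume))
  source_ref <- rep_len(as.integer(source_ref), n)
  dest_ref <- rep_len(as.integer(dest_ref), n)
  volume <- rep_len(volume, n)
  keep <- volume > 0
  if (!any(keep)) return(invisible(NULL))
  b$step <- b$step + 1L
  b$rows[[length(b$rows) + 1L]] <- data.frame(
    step = b$step, phase = phase, reagent = reagent, channel = channel,
    source_kind = source_kind, source_ref = source_ref[keep],
    dest_kind = dest_kind, dest_ref = dest_ref[keep],
    volume = volume[keep],
    stringsAsFactors = FALSE
  )
  invisible(NULL)
}

#' Build a full factorial assembly plan
#'
#' Produces the ordered pipetting plan for the configuration, verifies it with
#' [simulate_transfers()] (any intermediate volume above `well_capacity`
#' aborts with a capacity error naming the step), and tallies resources.
#'
#' @param config A [plan_config()].
#' @return An object of class `protocol_plan`: a list with `config`, `layout`,
#'   `transfers` (elementary, one row per destination), `worklist` (one row
#'   per pipetting event), `resources` (plates, tubes, steps, tip estimate,
#'   naive event count), and `final_state` (the simulated endpoint).
#' @examples
#' plan <- plan_assembly(plan_config(5, v0 = 10))
#' plan$resources$steps
#' @export
plan_assembly <- function(config) {
  if (!inherits(config, "plan_config")) stop_validation("`config` must be a plan_config")
  m <- config$m
  d <- plate_dims(config$format)
  rb <- d$row_bits
  r_eff <- min(m, rb)
  n_rows_used <- 2L^r_eff
  n_cols <- max(1L, 2L^(max(0L, m - rb)))
  v0 <- config$v0
  b <- new_builder()
  sp <- config$library$names
  buf <- config$buffer_name
  rows_of_col <- function(j) well_slot(seq_len(n_rows_used), j, rb)
  col_channel <- if (n_rows_used > 1L) paste0(n_rows_used, "-channel") else "single"

  if (config$strategy == "direct_dispense") {
    n_tubes <- n_rows_used
    # starting mixes: per-tube species aliquots sized for all n_cols columns;
    # homogenize != off adds the row-term buffer to the tube itself
    for (t in 0:(n_tubes - 1L)) {
      for (k in decode_consortium(t, r_eff)) {
        add_step(b, "starting_mixes", sp[k], "single", "species", k,
                 "tube", t + 1L, n_cols * v0)
      }
      if (config$homogenize == "full") {
        add_step(b, "starting_mixes", buf, "single", "buffer", NA_integer_,
                 "tube", t + 1L, n_cols * v0 * (r_eff - bit_count(t)))
      }
    }
    # dispense the mixes: one multichannel event per global column when the
    # per-row volume is uniform (full homogenization), else per tube
    disp <- if (config$homogenize == "full") rep(r_eff * v0, n_tubes)
            else bit_count(0:(n_tubes - 1L)) * v0
    for (j in seq_len(n_cols)) {
      if (config$homogenize == "full") {
        add_step(b, "starting_mixes", "starting mixes", col_channel,
                 "tube", 1:n_tubes, "well", rows_of_col(j), disp)
      } else {
        for (t in which(disp > 0)) {
          add_step(b, "starting_mixes", sprintf("mix T%d", t), "single",
                   "tube", t, "well", well_slot(t, j, rb), disp[t])
        }
      }
    }
    # column species: species k > r_eff goes into alternating column blocks
    if (m > rb) {
      for (k in (rb + 1L):m) {
        for (j in species_positions(k, m, config$format)$indices) {
          add_step(b, "species_addition", sp[k], col_channel, "species", k,
                   "well", rows_of_col(j), rep(v0, n_rows_used))
        }
      }
    }
    # column-term buffer
    if (config$homogenize %in% c("full", "column_only")) {
      for (j in seq_len(n_cols)) {
        ct <- v0 * (m - r_eff - bit_count(j - 1L))
        add_step(b, "buffer_column", buf, col_channel, "buffer", NA_integer_,
                 "well", rows_of_col(j), rep(ct, n_rows_used))
      }
    }
    tubes <- n_tubes
  } else {
    # block duplication: column 1 assembled at 2^(m - rb) scale, then doubled
    scale0 <- n_cols
    for (t in 0:(n_rows_used - 1L)) {
      for (k in decode_consortium(t, r_eff)) {
        add_step(b, "starting_mixes", sp[k], "single", "species", k,
                 "well", well_slot(t + 1L, 1L, rb), scale0 * v0)
      }
      if (config$homogenize == "full") {
        add_step(b, "starting_mixes", buf, "single", "buffer", NA_integer_,
                 "well", well_slot(t + 1L, 1L, rb),
                 scale0 * v0 * (r_eff - bit_count(t)))
      }
    }
    if (m > rb) {
      for (k in (rb + 1L):m) {
        n_old <- 2L^(k - 1L - rb)
        half <- 2^(m - k)
        for (j in seq_len(n_old)) {
          src <- rows_of_col(j); dst <- rows_of_col(j + n_old)
          if (config$homogenize == "full") {
            # uniform totals: transfer half of every well of the column
            add_step(b, "duplication", sprintf("column %d contents", j),
                     col_channel, "well", src, "well", dst,
                     rep(half * (k - 1) * v0, n_rows_used))
          } else {
            vols <- half * v0 * bit_count(well_to_code(seq_len(n_rows_used), j, m,
                                                       config$format))
            for (t in which(vols > 0)) {
              add_step(b, "duplication", sprintf("well contents col %d", j),
                       "single", "well", src[t], "well", dst[t], vols[t])
            }
          }
        }
        for (j in seq_len(n_old)) {
          add_step(b, "species_addition", sp[k], col_channel, "species", k,
                   "well", rows_of_col(j + n_old), rep(half * v0, n_rows_used))
        }
        if (config$homogenize == "full") {
          # the originals, lacking species k, get the same volume as buffer
          for (j in seq_len(n_old)) {
            add_step(b, "buffer_column", buf, col_channel, "buffer", NA_integer_,
                     "well", rows_of_col(j), rep(half * v0, n_rows_used))
          }
        }
      }
    }
    tubes <- 0L
  }

  transfers <- do.call(rbind, b$rows)
  layout <- plate_layout(config$library, config$format)
  plan <- structure(list(
    config = config, layout = layout, transfers = transfers,
    worklist = NULL, resources = NULL, final_state = NULL
  ), class = "protocol_plan")
  # verify: the simulator enforces capacity and source sufficiency
  plan$final_state <- simulate_transfers(plan)
  groups <- !duplicated(transfers$step)
  plan$worklist <- build_worklist(plan)
  plan$resources <- list(
    plates = plates_required(m, config$format),
    tubes = as.integer(tubes),
    steps = sum(groups),
    elementary_transfers = nrow(transfers),
    tip_sets = sum(groups),
    naive_events = naive_event_count(m)
  )
  plan
}

#' @export
print.protocol_plan <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Full factorial assembly plan: m = %d, v0 = %g uL, %d-well, %s, homogenize = %s\n",
    cfg$m, cfg$v0, cfg$format, cfg$strategy, cfg$homogenize))
  r <- x$resources
  cat(sprintf("  %d consortia on %d plate(s), %d tube(s)\n",
              2^cfg$m, r$plates, r$tubes))
  cat(sprintf("  %d pipetting events (naive one-by-one assembly: %d)\n",
              r$steps, r$naive_events))
  invisible(x)
}

# group elementary transfers into the human/robot worklist
build_worklist <- function(plan) {
  tr <- plan$transfers
  d <- plate_dims(plan$config$format)
  src_label <- function(kind, ref) {
    out <- character(length(kind))
    out[kind == "species"] <- plan$config$library$names[ref[kind == "species"]]
    out[kind == "buffer"] <- plan$config$buffer_name
    out[kind == "tube"] <- paste0("T", ref[kind == "tube"])
    w <- kind == "well"
    if (any(w)) {
      ij <- slot_ij(ref[w], d$row_bits)
      pl <- (ij$j - 1L) %/% d$cols + 1L
      jl <- (ij$j - 1L) %% d$cols + 1L
      out[w] <- paste0("P", pl, ":", LETTERS[ij$i], sprintf("%02d", jl))
    }
    out
  }
  dest_label <- function(kind, ref) {
    out <- character(length(kind))
    out[kind == "tube"] <- paste0("T", ref[kind == "tube"])
    w <- kind == "well"
    if (any(w)) {
      ij <- slot_ij(ref[w], d$row_bits)
      pl <- (ij$j - 1L) %/% d$cols + 1L
      jl <- (ij$j - 1L) %% d$cols + 1L
      out[w] <- paste0("P", pl, ":", LETTERS[ij$i], sprintf("%02d", jl))
    }
    out
  }
  sp <- split(seq_len(nrow(tr)), tr$step)
  rows <- lapply(sp, function(idx) {
    g <- tr[idx, ]
    srcs <- unique(src_label(g$source_kind, g$source_ref))
    dests <- dest_label(g$dest_kind, g$dest_ref)
    data.frame(
      step = g$step[1], phase = g$phase[1], reagent = g$reagent[1],
      source = if (length(srcs) > 3) paste0(srcs[1], "-", srcs[length(srcs)])
               else paste(srcs, collapse = ";"),
      destinations = paste(dests, collapse = ";"),
      volume_uL = g$volume[1],
      channel_mode = g$channel[1],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$step), , drop = FALSE]
}

#' Simulate a plan's liquid transfers
#'
#' Executes the elementary transfers of a plan in order, tracking each well's
#' per-species monoculture-equivalent volume and buffer volume. Transfers from
#' tubes or wells move composition proportionally. Drawing more than a source
#' holds raises a simulation error; exceeding `well_capacity` raises a
#' capacity error naming the step. This is the oracle that every plan must
#' pass: the endpoint must reproduce the layout composition exactly.
#'
#' @param plan A `protocol_plan` from [plan_assembly()].
#' @return Data frame with one row per laid-out well: `plate`, `well_name`,
#'   `i`, `j_global`, `consortium_binary`, per-species volume columns
#'   (`vol_<name>`), `buffer_volume`, `total_volume`, `observed_binary` (from
#'   volumes > 0) and `matches_layout`.
#' @export
simulate_transfers <- function(plan) {
  if (!inherits(plan, "protocol_plan")) stop_validation("`plan` must be a protocol_plan")
  cfg <- plan$config
  m <- cfg$m
  d <- plate_dims(cfg$format)
  rb <- d$row_bits
  n_cols <- max(1L, 2L^(max(0L, m - rb)))
  n_slots <- n_cols * 2L^rb
  tr <- plan$transfers
  n_tubes <- max(1L, suppressWarnings(max(c(
    tr$source_ref[tr$source_kind == "tube"],
    tr$dest_ref[tr$dest_kind == "tube"]), na.rm = TRUE)))

  well_sp <- matrix(0, nrow = m, ncol = n_slots)   # monoculture equivalents
  well_bf <- numeric(n_slots)
  tube_sp <- matrix(0, nrow = m, ncol = n_tubes)
  tube_bf <- numeric(n_tubes)
  tol <- 1e-9

  for (r in seq_len(nrow(tr))) {
    kind <- tr$source_kind[r]; ref <- tr$source_ref[r]
    vol <- tr$volume[r]
    if (kind == "species") {
      mv_sp <- numeric(m); mv_sp[ref] <- vol; mv_bf <- 0
    } else if (kind == "buffer") {
      mv_sp <- numeric(m); mv_bf <- vol
    } else if (kind == "tube") {
      tot <- sum(tube_sp[, ref]) + tube_bf[ref]
      if (tot < vol - tol) {
        stop_simulation("step %d: tube T%d holds %.3f uL, cannot draw %.3f uL",
                        tr$step[r], ref, tot, vol)
      }
      f <- vol / tot
      mv_sp <- tube_sp[, ref] * f; mv_bf <- tube_bf[ref] * f
      tube_sp[, ref] <- tube_sp[, ref] - mv_sp
      tube_bf[ref] <- tube_bf[ref] - mv_bf
    } else { # well
      tot <- sum(well_sp[, ref]) + well_bf[ref]
      if (tot < vol - tol) {
        stop_simulation("step %d: source well slot %d holds %.3f uL, cannot draw %.3f uL",
                        tr$step[r], ref, tot, vol)
      }
      f <- vol / tot
      mv_sp <- well_sp[, ref] * f; mv_bf <- well_bf[ref] * f
      well_sp[, ref] <- well_sp[, ref] - mv_sp
      well_bf[ref] <- well_bf[ref] - mv_bf
    }
    dk <- tr$dest_kind[r]; dr <- tr$dest_ref[r]
    if (dk == "tube") {
      tube_sp[, dr] <- tube_sp[, dr] + mv_sp
      tube_bf[dr] <- tube_bf[dr] + mv_bf
    } else if (dk == "well") {
      well_sp[, dr] <- well_sp[, dr] + mv_sp
      well_bf[dr] <- well_bf[dr] + mv_bf
      if (sum(well_sp[, dr]) + well_bf[dr] > cfg$well_capacity + tol) {
        ij <- slot_ij(dr, rb)
        stop_capacity(
          "step %d: well (row %d, global column %d) reaches %.1f uL, above capacity %.1f uL",
          tr$step[r], ij$i, ij$j,
          sum(well_sp[, dr]) + well_bf[dr], cfg$well_capacity,
          step = tr$step[r])
      }
    } # dest_kind "culture" is a sink
  }

  codes <- 0:(2^m - 1)
  slots <- codes + 1L
  w <- code_to_well(codes, m, cfg$format)
  comp <- t(well_sp[, slots, drop = FALSE])
  colnames(comp) <- paste0("vol_", cfg$library$names)
  observed <- vapply(slots, function(s) {
    sum(bitwShiftL(1L, which(well_sp[, s] > tol) - 1L))
  }, numeric(1))
  out <- data.frame(
    plate = w$plate, well_name = w$well_name, i = w$i, j_global = w$j_global,
    consortium_binary = code_to_binary(codes, m),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(comp))
  out$buffer_volume <- well_bf[slots]
  out$total_volume <- rowSums(comp) + out$buffer_volume
  out$observed_binary <- code_to_binary(as.integer(observed), m)
  out$matches_layout <- out$observed_binary == out$consortium_binary
  out
}

#' Verify a plan against its layout endpoint
#'
#' Checks that the simulated endpoint of a plan places exactly the right
#' species in every well at `v0` monoculture equivalents each, and (under full
#' homogenization) that every well totals `m * v0`.
#'
#' @param plan A `protocol_plan`.
#' @param tol Numeric tolerance on volumes (uL).
#' @return List with `ok` (logical) and `checks` (named logical vector).
#' @export
verify_assembly <- function(plan, tol = 1e-6) {
  st <- plan$final_state
  cfg <- plan$config
  m <- cfg$m
  volcols <- paste0("vol_", cfg$library$names)
  comp <- as.matrix(st[, volcols, drop = FALSE])
  codes <- binary_to_code(st$consortium_binary, m)
  member <- t(vapply(codes, function(z)
    bitwAnd(z, bitwShiftL(1L, 0:(m - 1L))) > 0L, logical(m)))
  checks <- c(
    composition = all(st$matches_layout),
    per_species_v0 = all(abs(comp[member] - cfg$v0) < tol),
    absent_zero = all(abs(comp[!member]) < tol),
    totals = if (cfg$homogenize == "full") {
      all(abs(st$total_volume - m * cfg$v0) < tol)
    } else if (cfg$homogenize == "off") {
      all(abs(st$total_volume - hamming_weight(codes, m) * cfg$v0) < tol)
    } else TRUE
  )
  list(ok = all(checks), checks = checks)
}

#' Write a plan's worklist to CSV
#'
#' @param plan A `protocol_plan`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_worklist_csv <- function(plan, path) {
  utils::write.csv(plan$worklist, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a plan as a numbered plain-text protocol
#'
#' @param plan A `protocol_plan`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protocol_text <- function(plan, path) {
  wl <- plan$worklist
  cfg <- plan$config
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "Full factorial assembly protocol (m = %d, v0 = %g uL, %d-well, %s, homogenize = %s)",
    cfg$m, cfg$v0, cfg$format, cfg$strategy, cfg$homogenize), con)
  writeLines(sprintf("Plates: %d; tubes: %d; pipetting events: %d (naive: %d)",
                     plan$resources$plates, plan$resources$tubes,
                     plan$resources$steps, plan$resources$naive_events), con)
  for (ph in unique(wl$phase)) {
    writeLines(c("", paste0("== ", gsub("_", " ", ph), " ==")), con)
    g <- wl[wl$phase == ph, ]
    writeLines(sprintf("%4d. [%s] %s: %s -> %s, %.1f uL per destination",
                       g$step, g$channel_mode, g$reagent, g$source,
                       g$destinations, g$volume_uL), con)
  }
  invisible(path)
}
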