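# Buffer arithmetic, plan generation, and the transfer-simulator oracle.

test_that("buffer volume is v0 * (m - richness)", {
  expect_equal(buffer_volume_code(2^8 - 1, 8, 25), 0)       # full consortium
  expect_equal(buffer_volume_code(0, 8, 25), 200)           # empty
  singletons <- 2^(0:7)
  expect_equal(buffer_volume_code(singletons, 8, 25), rep(175, 8))
})

test_that("positional buffer split matches the per-consortium volume everywhere", {
  expect_equal(buffer_volume_positional(1, 4, 8, 25)$column_term, 75)
  expect_equal(buffer_volume_positional(1, 1, 8, 25)$row_term, 75)  # 3 * v0
  w <- code_to_well(0:255, 8)
  split <- buffer_volume_positional(w$i, w$j_global, 8, 25)
  expect_equal(split$row_term + split$column_term,
               buffer_volume_code(0:255, 8, 25))
})

test_that("direct-dispense plan for m = 8, v0 = 25 reaches the homogenized endpoint", {
  plan <- plan_assembly(plan_config(8, v0 = 25))
  st <- plan$final_state
  expect_equal(nrow(st), 256L)
  expect_true(all(st$matches_layout))
  expect_equal(st$total_volume, rep(200, 256))  # m * v0 in every well
  comp <- as.matrix(st[, paste0("vol_", plan$config$library$names)])
  member <- t(vapply(binary_to_code(st$consortium_binary, 8),
                     function(z) bitwAnd(z, 2^(0:7)) > 0, logical(8)))
  expect_true(all(abs(comp[member] - 25) < 1e-9))
  expect_true(all(comp[!member] == 0))
  expect_identical(plan$resources$plates, 3L)
  expect_identical(plan$resources$tubes, 8L)
})

test_that("both strategies reproduce the layout composition exactly (m = 3..6)", {
  for (m in 3:6) {
    for (strat in c("direct_dispense", "block_duplication")) {
      plan <- plan_assembly(plan_config(m, v0 = 10, strategy = strat,
                                        well_capacity = 1000))
      v <- verify_assembly(plan)
      expect_true(v$ok, label = sprintf("m=%d %s: %s", m, strat,
                                        paste(names(which(!v$checks)), collapse = ",")))
      expect_equal(plan$final_state$total_volume, rep(m * 10, 2^m))
    }
  }
})

test_that("homogenize = off leaves richness * v0 per well; column_only only tops columns", {
  for (strat in c("direct_dispense", "block_duplication")) {
    plan <- plan_assembly(plan_config(5, v0 = 10, strategy = strat,
                                      homogenize = "off", well_capacity = 1000))
    st <- plan$final_state
    expect_true(all(st$matches_layout))
    expect_equal(st$total_volume,
                 10 * hamming_weight(st$consortium_binary))
    expect_true(all(st$buffer_volume == 0))
  }
  plan <- plan_assembly(plan_config(5, v0 = 10, homogenize = "column_only"))
  st <- plan$final_state
  codes <- binary_to_code(st$consortium_binary, 5)
  row_h <- hamming_weight(bitwAnd(codes, 7L), 5)
  col_h <- hamming_weight(codes, 5) - row_h
  expect_equal(st$total_volume, 10 * (row_h + 2))  # species + column buffer to m-3
  expect_error(plan_config(5, strategy = "block_duplication",
                           homogenize = "column_only"), "column_only")
})

test_that("with full homogenization every present species sits at 1/m density", {
  plan <- plan_assembly(plan_config(6, v0 = 20))
  st <- plan$final_state
  comp <- as.matrix(st[, paste0("vol_", plan$config$library$names)])
  frac <- comp / st$total_volume
  member <- comp > 1e-9
  expect_true(all(abs(frac[member] - 1 / 6) < 1e-12))
})

test_that("naive event count is m * 2^(m-1) and plans beat it for m >= 4", {
  expect_equal(naive_event_count(1), 1)
  expect_equal(naive_event_count(8), 1024)
  expect_equal(naive_event_count(10), 5120)
  for (m in 4:8) {
    plan <- plan_assembly(plan_config(m, v0 = 10))
    expect_lt(plan$resources$steps, naive_event_count(m))
  }
})

test_that("m = 3 plans have no column-species additions", {
  plan <- plan_assembly(plan_config(3, v0 = 25))
  expect_false("species_addition" %in% plan$transfers$phase)
  expect_equal(plan$final_state$total_volume, rep(75, 8))
})

test_that("no step draws from a well that is only filled later", {
  for (strat in c("direct_dispense", "block_duplication")) {
    tr <- plan_assembly(plan_config(6, v0 = 10, strategy = strat,
                                    well_capacity = 1000))$transfers
    first_write <- tapply(seq_len(nrow(tr))[tr$dest_kind == "well"],
                          tr$dest_ref[tr$dest_kind == "well"], min)
    reads <- which(tr$source_kind == "well")
    for (r in reads) {
      expect_lt(first_write[[as.character(tr$source_ref[r])]], r)
    }
  }
})

test_that("block duplication at large m reports a capacity error with the step", {
  err <- tryCatch(
    plan_assembly(plan_config(8, v0 = 25, strategy = "block_duplication")),
    consortia_capacity_error = function(e) e)
  expect_s3_class(err, "consortia_capacity_error")
  expect_false(is.na(err$step))
  expect_match(conditionMessage(err), "capacity")
})

test_that("inoculation arithmetic: 0.5 uL into 200 uL is 1:400, 0.0625 uL per strain", {
  cfg <- plan_config(8, v0 = 25)
  s <- inoculation_summary(cfg)
  expect_equal(s$dilution_factor, 400)
  expect_equal(s$dilution_label, "1:400")
  expect_equal(s$per_strain_volume_uL, 0.0625)
  expect_equal(inoculation_summary(plan_config(1, v0 = 25))$per_strain_volume_uL, 0.5)
  cfg4 <- plan_config(4, v0 = 25, inoculum_volume = 1.0)
  expect_equal(inoculation_summary(cfg4)$per_strain_volume_uL, 0.25)
})

test_that("worklist and protocol exports are written and internally consistent", {
  plan <- plan_assembly(plan_config(5, v0 = 10))
  expect_equal(nrow(plan$worklist), plan$resources$steps)
  expect_true(all(plan$worklist$volume_uL > 0))
  csv <- withr::local_tempfile(fileext = ".csv")
  txt <- withr::local_tempfile(fileext = ".txt")
  write_worklist_csv(plan, csv)
  write_protocol_text(plan, txt)
  wl <- read.csv(csv)
  expect_equal(nrow(wl), plan$resources$steps)
  expect_true(any(grepl("starting mixes", readLines(txt))))
})
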