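test_that("molecular weights match hand sums of standard atomic weights", {
  expect_equal(molecular_weight("H2O"), 18.02, tolerance = 0.01 / 18.02)
  expect_equal(molecular_weight("CH4N2O"), 60.06, tolerance = 0.01 / 60.06)
  expect_equal(molecular_weight("C5H14ClNO"), 139.62,
               tolerance = 0.01 / 139.62)
  # named-vector input agrees with string input
  expect_identical(molecular_weight(c(C = 5, H = 14, Cl = 1, N = 1, O = 1)),
                   molecular_weight("C5H14ClNO"))
})

test_that("unknown element symbols are rejected by name", {
  expect_error(molecular_weight("C2Xx3"), "Xx")
  expect_error(molecular_weight(c(C = 1, Zz = 2)), "Zz")
})

test_that("mole fractions are proportional to ratio parts and sum to 1", {
  expect_equal(mole_fractions(c(1, 2)), c(1, 2) / 3)
  expect_equal(mole_fractions(c(2, 1, 6)), c(2, 1, 6) / 9)
  expect_equal(mole_fractions(c(1, 1)), c(0.5, 0.5))
  expect_error(mole_fractions(numeric(0)), "at least one")
  expect_error(mole_fractions(c(1, -1)), "positive")
  for (parts in list(c(3, 7), c(1, 1, 1), c(5, 2, 9, 1))) {
    expect_equal(sum(mole_fractions(parts)), 1, tolerance = 1e-12)
  }
})

test_that("DES lookup returns full definitions with dataset tags", {
  d21 <- lookup_des("DES21")
  expect_equal(d21$component, c("choline chloride", "urea"))
  expect_equal(d21$ratio_part, c(1, 2))
  expect_true(all(d21$dataset == "training"))

  d20 <- lookup_des("DES20")
  expect_equal(d20$component, c("betaine", "citric acid", "water"))
  expect_equal(d20$ratio_part, c(2, 1, 6))
  expect_true(all(d20$dataset == "test"))
  expect_equal(d20$mole_fraction, c(2, 1, 6) / 9)

  expect_error(lookup_des("DES40"), "DES1\\.\\.DES39")
})

test_that("registry holds 39 DESs split 28 training / 11 test", {
  reg <- des_registry()
  expect_equal(nrow(reg), 39L)
  expect_equal(sum(reg$dataset == "training"), 28L)
  expect_equal(sum(reg$dataset == "test"), 11L)
  # record counts of the mirrored literature compilation
  expect_equal(sum(reg$n_data), 420)
  expect_equal(sum(reg$n_data[reg$dataset == "training"]), 292)
  expect_equal(sum(reg$n_data[reg$dataset == "test"]), 128)
})

test_that("every registry compound has a consistent stored record", {
  reg <- compound_registry()
  # mw recomputes from the formula
  expect_equal(reg$mw_g_mol,
               vapply(reg$formula, molecular_weight, numeric(1),
                      USE.NAMES = FALSE))
  # group decompositions exist except for direct-property compounds
  n_groups <- vapply(reg$groups, length, integer(1))
  expect_true(all(n_groups > 0 | reg$direct))
  expect_true(all(vapply(reg$groups, function(g) all(g >= 1), logical(1))))
})

test_that("compound and DES definitions round-trip through files", {
  reg <- compound_registry()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_compounds(reg[reg$compound %in% c("urea", "glycerol"), ], tmp)
  back <- read_compounds(tmp)
  expect_setequal(back$compound, c("urea", "glycerol"))
  expect_equal(back$groups, reg$groups[match(back$compound, reg$compound)],
               ignore_attr = TRUE)

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_des_definitions(des_components("DES21"), tmp2)
  back2 <- read_des_definitions(tmp2)
  expect_equal(back2$component, c("choline chloride", "urea"))
  expect_error(read_des_definitions(write_des_definitions(
    data.frame(a = 1), withr::local_tempfile(fileext = ".csv")
  )), "lacks columns")
})
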