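test_that("AARD and RD match their definitions on hand-checked cases", {
  expect_equal(aard(100, 90), 10)
  expect_equal(aard(c(100, 200), c(100, 200)), 0)
  expect_equal(aard(c(100, 200), c(110, 180)), 10)
  expect_equal(rd(100, 90), 10)
  expect_equal(rd(100, 110), -10)
  expect_error(aard(c(1, 2), 1), "length")
  expect_error(aard(c(0, 2), c(1, 2)), "nonzero")
})

test_that("mean absolute RD equals AARD and both are order/scale invariant", {
  withr::with_seed(5, {
    for (i in 1:5) {
      u_exp <- runif(50, 1200, 2000)
      u_cal <- u_exp * (1 + rnorm(50, sd = 0.05))
      expect_equal(mean(abs(rd(u_exp, u_cal))), aard(u_exp, u_cal))
      ord <- sample.int(50)
      expect_equal(aard(u_exp[ord], u_cal[ord]), aard(u_exp, u_cal))
      expect_equal(aard(3.7 * u_exp, 3.7 * u_cal), aard(u_exp, u_cal))
    }
  })
})

test_that("objective equals an independently coded AARD of proposed predictions", {
  d <- generate_synthetic(c("DES16", "DES21", "DES31"), noise = 0.02,
                          seed = 9)
  k <- proposed_coefficients(7.1, -2.0, -2.8, 2500)
  props <- des_properties(unique(d$des_id))
  # independent oracle: explicit loop over records
  u_cal <- vapply(seq_len(nrow(d)), function(i) {
    p <- props[props$des_id == d$des_id[i], ]
    p$omega * (k[["omega_mw"]] * p$mw_g_mol + k[["omega_t"]] * d$T_K[i]) +
      k[["vc"]] * p$vc_cm3_mol + k[["intercept"]]
  }, numeric(1))
  oracle <- 100 * mean(abs(d$u_exp_ms - u_cal) / d$u_exp_ms)
  expect_equal(objective(d, k, properties = props), oracle)
  expect_gte(objective(d, k), 0)
})

test_that("objective is zero on noise-free synthetic data at the published coefficients", {
  d <- generate_synthetic(c("DES1", "DES21"), noise = 0)
  expect_equal(objective(d), 0, tolerance = 1e-12)
})

test_that("model evaluation reports per-DES, per-split and overall AARD", {
  d <- generate_synthetic(c("DES21", "DES22", "DES31"), noise = 0.01,
                          seed = 3)
  ev <- evaluate_models(d)
  expect_s3_class(ev, "des_eval")
  expect_equal(nrow(ev$by_des), 3)
  # overall AARD equals the count-weighted mean of per-DES AARDs
  overall <- ev$by_split$aard_pct[ev$by_split$split == "overall"]
  expect_equal(overall,
               sum(ev$by_des$aard_pct * ev$by_des$n) / sum(ev$by_des$n))
  # split tags come from the registry (DES22 is a test-set DES)
  expect_setequal(ev$by_split$split, c("training", "test", "overall"))
  # perfect predictions give zero AARD everywhere
  ev0 <- evaluate_models(generate_synthetic("DES21", noise = 0))
  expect_true(all(ev0$by_des$aard_pct == 0))
  expect_true(all(ev0$by_split$aard_pct == 0))
})

test_that("tidy, glance and the wide report table expose the evaluation", {
  d <- generate_synthetic(c("DES21", "DES31"), noise = 0.01, seed = 21)
  ev <- evaluate_models(d)
  expect_equal(tidy(ev), ev$by_des)
  g <- glance(ev)
  expect_true(all(c("aard_pct_overall", "n_overall") %in% names(g)))
  wide <- eval_table(ev)
  expect_equal(names(wide), c("des_id", "proposed"))
  expect_equal(nrow(wide), 2)
})

test_that("dataset validation rejects malformed records", {
  d <- generate_synthetic("DES21", noise = 0)
  bad <- d
  bad$u_exp_ms[1] <- -1
  expect_error(evaluate_models(bad), "positive")
  expect_error(evaluate_models(dplyr::bind_rows(d, d[1, ])), "duplicate")
  expect_error(objective(d[0, ]), "empty")
})

test_that("datasets round-trip through CSV with validation", {
  d <- generate_synthetic("DES21", noise = 0)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_speed_dataset(d, tmp)
  back <- read_speed_dataset(tmp)
  expect_equal(back$u_exp_ms, d$u_exp_ms)
  expect_equal(back$T_K, d$T_K)
})
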