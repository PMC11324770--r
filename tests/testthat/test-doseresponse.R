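make_well_table <- function(conc, jpc, counts, veh_jpc = 1, veh_count = 100) {
  data.frame(
    plate = "P1",
    well = sprintf("W%02d", seq_len(length(conc) + length(veh_jpc))),
    compound = "X",
    concentration_um = c(conc, rep(NA, length(veh_jpc))),
    role = c(rep("treated", length(conc)), rep("vehicle", length(veh_jpc))),
    n_fields = 16,
    mean_nuclei_count = c(counts, rep(veh_count, length(veh_jpc))),
    membrane_area_per_cell_um2 = 1,
    junction_area_per_cell_um2 = c(jpc, veh_jpc),
    stringsAsFactors = FALSE)
}

test_that("vehicle normalization produces fold changes with replicate averaging", {
  wt <- make_well_table(conc = c(1, 1, 10), jpc = c(0.4, 0.6, 0.2),
                        counts = c(100, 100, 50),
                        veh_jpc = c(0.9, 1.1), veh_count = 100)
  r <- normalize_to_vehicle(wt)
  expect_equal(r$concentration_um, c(1, 10))
  expect_equal(r$response[1], 0.5)          # mean(0.4, 0.6) / mean(0.9, 1.1)
  expect_equal(r$response[2], 0.2)
  expect_equal(r$viability_response, c(1, 0.5))

  # identity: treated equal to vehicle -> response 1
  wt2 <- make_well_table(conc = 1, jpc = 1, counts = 100)
  expect_equal(normalize_to_vehicle(wt2)$response, 1)

  # degenerate vehicle
  wt3 <- make_well_table(conc = 1, jpc = 1, counts = 100, veh_jpc = 0)
  expect_error(normalize_to_vehicle(wt3), "vehicle")
  expect_error(normalize_to_vehicle(wt2[wt2$role == "treated", ]), "vehicle")
})

test_that("loglinear and 4PL fits recover an exact Hill curve", {
  conc <- 100 / 3^(0:8)
  for (h in c(1, 2)) {
    resp <- hill_fraction(conc, 10, h)
    fl <- fit_ic50(conc, resp, method = "loglinear")
    expect_true(fl$established)
    expect_lt(abs(fl$ic50_um - 10) / 10, 0.10)
    f4 <- fit_ic50(conc, resp, method = "fourpl")
    expect_true(f4$established)
    expect_lt(abs(f4$ic50_um - 10) / 10, 0.02)
    expect_equal(unname(coef(f4)["h"]), h, tolerance = 0.05)
  }
})

test_that("IC50 is invariant to a consistent concentration-unit rescaling", {
  conc <- 100 / 3^(0:8)
  resp <- hill_fraction(conc, 7, 1.5)
  f_um <- fit_ic50(conc, resp)
  f_nm <- fit_ic50(conc * 1000, resp)
  expect_equal(f_nm$ic50_um / 1000, f_um$ic50_um, tolerance = 1e-8)
})

test_that("flat responses give NOT_ESTABLISHED and a NEGATIVE call", {
  conc <- 100 / 3^(0:8)
  set.seed(1)
  resp <- 1 + rnorm(9, 0, 0.03)
  fit <- fit_ic50(conc, resp)
  expect_false(fit$established)
  expect_true(is.na(fit$ic50_um))
  expect_equal(classify_compound(fit), "NEGATIVE")

  # minor effect only at the top concentration, never reaching 0.5
  resp2 <- c(rep(1, 8), 0.8)
  expect_false(fit_ic50(conc, resp2)$established)
})

test_that("a crossing exactly at the highest concentration is still POSITIVE", {
  conc <- sort(100 / 3^(0:8))                  # ascending
  resp <- c(rep(1, 6), 0.9, 0.7, 0.5)          # reaches 0.5 only at 100 uM
  fit <- fit_ic50(conc, resp)
  expect_true(fit$established)
  expect_lte(fit$ic50_um, 100)
  expect_equal(classify_compound(fit), "POSITIVE")
})

test_that("established IC50 lies within the tested range and predicts the curve", {
  conc <- 100 / 3^(0:8)
  resp <- hill_fraction(conc, 27.9, 1)
  fit <- fit_ic50(conc, resp, method = "fourpl")
  expect_gte(fit$ic50_um, min(conc))
  expect_lte(fit$ic50_um, max(conc))
  # midpoint of a 4PL with top 1, bottom 0 responds 0.5 at the IC50
  expect_equal(predict(fit, fit$ic50_um), 0.5, tolerance = 1e-3)
})

test_that("Cooper statistics on the bundled validation set match its annotation", {
  tab <- validation_compounds()
  expect_equal(nrow(tab), 19L)
  expect_equal(sum(tab$risk), 10L)
  preds <- calls_from_ic50_table(tab)
  cs <- cooper_statistics(preds, tab)
  expect_equal(cs$tp, 9L)
  expect_equal(cs$fn, 1L)
  expect_equal(cs$tn, 9L)
  expect_equal(cs$fp, 0L)
  expect_equal(cs$sensitivity, 0.9)
  expect_equal(cs$specificity, 1.0)
  expect_equal(cs$accuracy, 18 / 19)
})

test_that("Cooper statistics flag degenerate truth tables and perfect calls", {
  preds <- data.frame(compound = c("a", "b"), call = c("POSITIVE", "NEGATIVE"))
  truth <- data.frame(compound = c("a", "b"), risk = c(TRUE, FALSE))
  cs <- cooper_statistics(preds, truth)
  expect_equal(cs$sensitivity, 1)
  expect_equal(cs$specificity, 1)
  expect_equal(cs$accuracy, 1)

  truth_all_pos <- data.frame(compound = c("a", "b"), risk = c(TRUE, TRUE))
  cs2 <- cooper_statistics(preds, truth_all_pos)
  expect_true(is.na(cs2$specificity))
  expect_true("no_negatives_in_truth" %in% cs2$flags)

  expect_error(cooper_statistics(preds, data.frame(compound = "a", risk = TRUE)),
               "same compounds")
})

test_that("pooled t statistic matches the textbook case and stats::t.test", {
  df <- data.frame(concentration_um = 1,
                   group = rep(c("g1", "g2"), each = 3),
                   response = c(1, 2, 3, 2, 3, 4))
  out <- per_concentration_test(df)
  expect_equal(out$t, -1.224745, tolerance = 1e-6)
  expect_equal(out$df, 4)
  expect_equal(out$p, 0.2878641, tolerance = 1e-6)

  # identical groups: t = 0, p = 1
  df2 <- data.frame(concentration_um = 1, group = rep(c("a", "b"), each = 3),
                    response = rep(c(1, 2, 3), 2))
  out2 <- per_concentration_test(df2)
  expect_equal(out2$t, 0)
  expect_equal(out2$p, 1)

  # full separation with epsilon variance
  df3 <- data.frame(concentration_um = 1, group = rep(c("a", "b"), each = 3),
                    response = c(0, 1e-6, 0, 1, 1, 1 + 1e-6))
  expect_lt(per_concentration_test(df3)$p, 0.001)

  # property: agrees with the independent stats::t.test implementation
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1))
    d <- data.frame(concentration_um = 1,
                    group = c(rep("x", length(x)), rep("y", length(y))),
                    response = c(x, y))
    mine <- per_concentration_test(d)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }

  # zero pooled variance with distinct means: infinite t, p -> 0, flagged
  df4 <- data.frame(concentration_um = 1, group = rep(c("a", "b"), each = 2),
                    response = c(0, 0, 1, 1))
  out4 <- per_concentration_test(df4)
  expect_true(out4$degenerate)
  expect_equal(out4$p, 0)
  expect_false(attr(out4, "p_adjusted"))
})
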