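test_that("IS normalisation rescales by the water-to-sample IS ratio", {
  tab <- make_table(list(
    list("s1", 1, "IS", 80), list("s1", 1, "ELAAVPSR", 800),
    list("s2", 1, "IS", 100), list("s2", 1, "ELAAVPSR", 640)))
  norm <- is_normalize(tab, is_reference_area = 100)
  expect_equal(norm$peak_area[norm$sample_id == "s1" &
                                norm$analyte_id == "ELAAVPSR"], 1000)
  # IS equal to reference: analyte areas unchanged
  expect_equal(norm$peak_area[norm$sample_id == "s2" &
                                norm$analyte_id == "ELAAVPSR"], 640)
  expect_equal(unique(norm$peak_area[norm$analyte_id == "IS"]), 100)
})

test_that("IS normalisation errors name the offending cell", {
  missing_is <- make_table(list(list("s1", 1, "ELAAVPSR", 800)))
  expect_error(is_normalize(missing_is, 100), "s1.*replicate 1")
  zero_is <- make_table(list(list("s1", 1, "IS", 0),
                             list("s1", 1, "ELAAVPSR", 5)))
  expect_error(is_normalize(zero_is, 100), "zero")
  expect_error(is_normalize(make_table(list(list("s1", 1, "IS", 10))), -1),
               "positive")
})

test_that("normalisation is invariant to a common ionization-stage factor", {
  set.seed(55)
  for (i in 1:10) {
    base <- make_table(list(
      list("s1", 1, "IS", 100), list("s1", 1, "ELAAVPSR", runif(1, 10, 1e4)),
      list("s1", 1, "TYMVR", runif(1, 10, 1e4))))
    scaled <- base
    c_factor <- runif(1, 0.1, 10)
    scaled$peak_area <- scaled$peak_area * c_factor
    expect_equal(is_normalize(scaled, 100)$peak_area,
                 is_normalize(base, 100)$peak_area)
  }
})

test_that("matrix recovery and loss are complementary percentages", {
  r <- matrix_recovery(90, 1000)
  expect_equal(r$recovery_pct, 9)
  expect_equal(r$loss_pct, 91)
  expect_equal(matrix_recovery(630, 1000)$loss_pct, 37)
  expect_equal(matrix_recovery(1000, 1000)$loss_pct, 0)
  expect_error(matrix_recovery(5, 0), "positive")
})

test_that("relative content divides quantifier areas by the effective flour mass", {
  tab <- make_table(list(
    list("s1", 1, "IS", 100),
    list("s1", 1, "ELAAVPSR", 60000), list("s1", 1, "TYMVR", 40000)),
    flour_mass_mg = 1, extraction_volume_mL = 1, digest_aliquot_mL = 1,
    final_volume_mL = 1, injected_volume_uL = 1000)
  expect_equal(effective_flour_mg(tab), 1)
  qr <- relative_ati_content(tab, c(A = "ELAAVPSR", B = "TYMVR"))
  expect_equal(qr$summary$total_pa_per_mg_mean, 100000)
  expect_equal(qr$summary$pct_A_mean, 60)
  expect_equal(qr$summary$pct_B_mean, 40)
})

test_that("composition percentages reproduce a dominant-protein split", {
  tab <- make_table(list(
    list("s1", 1, "IS", 100),
    list("s1", 1, "ELAAVPSR", 91.8), list("s1", 1, "TYMVR", 8.2)))
  qr <- relative_ati_content(tab, c(A = "ELAAVPSR", B = "TYMVR"))
  expect_equal(qr$summary$pct_A_mean, 91.8)
  expect_equal(qr$summary$pct_B_mean, 8.2)
})

test_that("degenerate all-zero samples report missing composition", {
  tab <- make_table(list(
    list("s1", 1, "IS", 100),
    list("s1", 1, "ELAAVPSR", 0), list("s1", 1, "TYMVR", 0)))
  qr <- relative_ati_content(tab, c(A = "ELAAVPSR", B = "TYMVR"))
  expect_equal(qr$summary$total_pa_per_mg_mean, 0)
  expect_true(is.na(qr$summary$pct_A_mean))
  expect_error(
    relative_ati_content(tab, c(A = "ELAAVPSR", B = "ABSENT")), "ABSENT")
})

test_that("quantification is scale-invariant and compositions sum to 100", {
  set.seed(66)
  for (i in 1:25) {
    pa <- runif(2, 1, 1e5)
    rows <- list(list("s", 1, "IS", runif(1, 10, 1000)),
                 list("s", 1, "P1pep", pa[1]), list("s", 1, "P2pep", pa[2]))
    tab <- make_table(rows)
    qr <- relative_ati_content(is_normalize(tab, 500),
                               c(A = "P1pep", B = "P2pep"))
    expect_equal(qr$summary$pct_A_mean + qr$summary$pct_B_mean, 100,
                 tolerance = 1e-9)
    scaled <- tab
    scaled$peak_area <- scaled$peak_area * runif(1, 0.01, 100)
    qr2 <- relative_ati_content(is_normalize(scaled, 500),
                                c(A = "P1pep", B = "P2pep"))
    expect_equal(qr2$summary$total_pa_per_mg_mean,
                 qr$summary$total_pa_per_mg_mean, tolerance = 1e-9)
    expect_equal(qr2$summary$pct_A_mean, qr$summary$pct_A_mean,
                 tolerance = 1e-9)
  }
})

test_that("replicates aggregate as mean and sample SD of per-replicate results", {
  rows <- list()
  for (r in 1:3) {
    rows <- c(rows, list(list("s1", r, "IS", 100),
                         list("s1", r, "ELAAVPSR", c(9, 10, 11)[r] * 1000),
                         list("s1", r, "TYMVR", 1000)))
  }
  tab <- make_table(rows, flour_mass_mg = 1, extraction_volume_mL = 1,
                    digest_aliquot_mL = 1, final_volume_mL = 1,
                    injected_volume_uL = 1000)
  qr <- relative_ati_content(tab, c(A = "ELAAVPSR", B = "TYMVR"))
  expect_equal(qr$summary$total_pa_per_mg_mean, 11000)
  expect_equal(qr$summary$total_pa_per_mg_sd, sd(c(10000, 11000, 12000)))
})

test_that("group summaries report per-condition mean and SD", {
  t1 <- make_table(list(list("a", 1, "X", 9), list("a", 2, "X", 10),
                        list("a", 3, "X", 11)))
  t2 <- make_table(list(list("b", 1, "X", 5)))
  g <- group_summary(list(ctrl = t1, treated = t2))
  ctrl <- g[g$condition == "ctrl", ]
  expect_equal(ctrl$mean_pa, 10)
  expect_equal(ctrl$sd_pa, 1)
  expect_true(is.na(g$sd_pa[g$condition == "treated"]))
  # three identical replicates: zero SD
  t3 <- make_table(list(list("a", 1, "X", 7), list("a", 2, "X", 7),
                        list("a", 3, "X", 7)))
  expect_equal(group_summary(list(z = t3))$sd_pa, 0)
})

test_that("measurement tables validate schema and round-trip through CSV", {
  expect_error(measurement_table(data.frame(sample_id = "a")), "missing")
  expect_error(make_table(list(list("a", 1, "X", -5))), "non-negative")
  expect_error(make_table(list(list("a", 1, "X", 5)), flour_mass_mg = 0),
               "positive")
  tab <- make_table(list(list("a", 1, "IS", 10), list("a", 1, "X", 3.25)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurement_table(tab, path)
  back <- read_measurement_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})
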