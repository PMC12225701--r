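test_that("flat and background-only profiles fit to zero amplitude", {
  n <- rep(5000L, 15)
  # no mismatches at all
  fit0 <- fit_damage(rep(0L, 15), n)
  expect_lt(fit0$a, 0.005)
  expect_lt(fit0$z, 2)

  # constant 1% frequency: absorbed by the background term
  fitc <- fit_damage(rep(50L, 15), n)
  expect_lt(fitc$a, 0.01)
  expect_equal(fitc$c, 0.01, tolerance = 0.005)

  expect_error(fit_damage(c(1L, 0L), c(10L, 10L)), "at least 4")
})

test_that("damage parameters are recovered from simulated counts", {
  x <- 1:15
  p <- 0.25 * (1 - 0.35)^(x - 1) + 0.01
  withr::with_seed(5, {
    k <- stats::rbinom(15, 5000, p)
  })
  fit <- fit_damage(k, rep(5000L, 15))
  expect_lt(abs(fit$a - 0.25), 0.03)
  expect_lt(abs(fit$q - 0.35), 0.15)
  expect_lt(abs(fit$c - 0.01), 0.01)
  expect_gt(fit$z, 2)
  expect_identical(fit$n_reads, 5000L)
  expect_equal(fit$z, fit$a / fit$se_a)
})

test_that("tidy and glance expose the fit in broom shape", {
  withr::with_seed(6, {
    k <- stats::rbinom(15, 2000, 0.2 * 0.7^(0:14) + 0.01)
  })
  fit <- fit_damage(k, rep(2000L, 15))
  td <- tidy(fit)
  expect_identical(td$term, c("amplitude", "decay", "background"))
  expect_identical(td$estimate[1], fit$a)
  gl <- glance(fit)
  expect_identical(names(gl),
                   c("amplitude", "z", "n_reads", "logLik", "converged"))
  expect_true(gl$converged)
})

make_fits <- function(...) {
  # rows: genus_taxid, sample_id, age, a, z, n_reads
  tibble::tibble(...)
}

test_that("envelope calibration enforces the read and z thresholds", {
  tax <- example_taxonomy()
  fits <- make_fits(
    genus_taxid = c(300L, 310L, 320L, 330L, 340L, 100L),
    sample_id = paste0("s", 1:6),
    age = c(2000, 6000, 3000, 4000, 5000, 7000),
    a = c(0.10, 0.20, 0.15, 0.12, 0.05, 0.30),
    q = 0.3, c = 0.01, se_a = 0.01,
    z = c(10, 10, 1.9, 10, 10, 10),
    n_reads = c(1000L, 1000L, 1000L, 499L, 1000L, 1000L)
  )
  env <- build_envelope(fits, tax, plant_clade = 11L, exclusions = 340L)
  # 320 fails z (1.9 < 2), 330 fails reads (499 < 500), 340 is the excluded
  # eelgrass, 100 is not a plant: only 300 and 310 calibrate
  expect_identical(env$points$age, c(2000, 6000))
  expect_identical(env$points$envelope, c(0.10, 0.10))
  # running minimum, linearly interpolated: value at 4 kyr is 0.10
  expect_equal(envelope_at(env, 4000), 0.10)
  # constant beyond the oldest point
  expect_equal(envelope_at(env, 8000), 0.10)
  # unassessable before the youngest calibration age
  expect_true(is.na(envelope_at(env, 1000)))
})

test_that("fewer than two calibration points yields no envelope", {
  tax <- example_taxonomy()
  fits <- make_fits(
    genus_taxid = 300L, sample_id = "s1", age = 2000,
    a = 0.1, q = 0.3, c = 0.01, se_a = 0.01, z = 10, n_reads = 1000L
  )
  expect_warning(env <- build_envelope(fits, tax, 11L, 340L),
                 "fewer than 2")
  expect_null(env)
  cls <- classify_ancient(dplyr::mutate(fits, age = 5000), env)
  expect_identical(cls$damage_status, "unassessable")
})

test_that("authentication compares amplitude against the envelope at age", {
  tax <- example_taxonomy()
  cal <- make_fits(
    genus_taxid = c(300L, 310L), sample_id = c("s1", "s2"),
    age = c(2000, 6000), a = c(0.10, 0.20), q = 0.3, c = 0.01,
    se_a = 0.01, z = c(10, 10), n_reads = c(1000L, 1000L)
  )
  env <- build_envelope(cal, tax, 11L, 340L)
  obs <- make_fits(
    genus_taxid = 100L, sample_id = paste0("x", 1:4),
    age = c(3000, 3000, 3000, 1000),
    a = c(0.15, 0.0, 0.15, 0.3), q = 0.3, c = 0.01, se_a = 0.01,
    z = c(3, 0, 1.5, 10), n_reads = 1000L
  )
  cls <- classify_ancient(obs, env)
  expect_identical(cls$damage_status,
                   c("ancient",       # above envelope, significant
                     "not_damaged",   # flat profile
                     "not_damaged",   # amplitude fine but z below 2
                     "unassessable")) # younger than first calibration point
  # boundary: amplitude exactly at the envelope authenticates (inclusive)
  at <- classify_ancient(make_fits(
    genus_taxid = 100L, sample_id = "x", age = 2000, a = 0.10,
    q = 0.3, c = 0.01, se_a = 0.01, z = 2, n_reads = 1000L
  ), env)
  expect_identical(at$damage_status, "ancient")
})

test_that("raising amplitude never demotes an authenticated observation", {
  tax <- example_taxonomy()
  cal <- make_fits(
    genus_taxid = c(300L, 310L), sample_id = c("s1", "s2"),
    age = c(1000, 7000), a = c(0.08, 0.18), q = 0.3, c = 0.01,
    se_a = 0.01, z = c(10, 10), n_reads = c(1000L, 1000L)
  )
  env <- build_envelope(cal, tax, 11L, 340L)
  withr::with_seed(12, {
    for (i in 1:30) {
      age <- stats::runif(1, 1000, 8000)
      a <- stats::runif(1, 0, 0.4)
      base <- classify_ancient(make_fits(
        genus_taxid = 100L, sample_id = "x", age = age, a = a,
        q = 0.3, c = 0.01, se_a = 0.01, z = 5, n_reads = 1000L
      ), env)
      up <- classify_ancient(make_fits(
        genus_taxid = 100L, sample_id = "x", age = age, a = a + 0.1,
        q = 0.3, c = 0.01, se_a = 0.01, z = 5, n_reads = 1000L
      ), env)
      if (base$damage_status == "ancient") {
        expect_identical(up$damage_status, "ancient")
      }
    }
  })
})

test_that("binned envelope variant takes per-bin minima", {
  tax <- example_taxonomy()
  fits <- make_fits(
    genus_taxid = c(300L, 310L, 320L),
    sample_id = paste0("s", 1:3),
    age = c(2000, 2400, 6000), a = c(0.12, 0.08, 0.20),
    q = 0.3, c = 0.01, se_a = 0.01, z = 10, n_reads = 1000L
  )
  env <- build_envelope(fits, tax, 11L, 340L, method = "binned",
                        bin_width = 1000)
  # the 2000-2400 bin collapses to its minimum 0.08
  expect_equal(env$points$envelope[1], 0.08)
  expect_identical(nrow(env$points), 2L)
})
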