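test_that("phenotype tables round-trip through CSV", {
  recs <- generate_phenotypes(synth_config("ale", n = 8, seed = 4, cv = 0.02))
  f <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(recs, f)
  back <- read_phenotypes(f)
  expect_identical(nrow(back), 8L)
  expect_identical(names(back), names(recs))
  expect_equal(as.data.frame(back), as.data.frame(recs), tolerance = 1e-12)
  # header-only file reads as an empty dataset
  f0 <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(recs[0, ], f0)
  expect_identical(nrow(read_phenotypes(f0)), 0L)
})

test_that("malformed tables are rejected with located problems", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("strain_id,dataset,mu,mu_sd,q_glc,q_glc_sd,q_ac,q_ac_sd",
               "a,ale,0.95,0.01,9.1,0.1,4.4,0.1",
               "b,ale,oops,0.01,9.9,0.1,5.6,0.1"), f)
  expect_error(read_phenotypes(f), "non-numeric 'mu' at line\\(s\\) 3")
  writeLines(c("strain_id,mu,q_glc", "a,0.9,8"), f)
  expect_error(read_phenotypes(f), "missing required columns")
  # invariant violations carry row numbers
  bad <- tibble::tibble(strain_id = "x", dataset = "ale", mu = 1,
                        mu_sd = 0, q_glc = -2, q_glc_sd = 0,
                        q_ac = 1, q_ac_sd = 0)
  expect_error(validate_phenotypes(bad), "q_glc not positive.*row\\(s\\) 1")
})

test_that("yields follow Y = mu / (M_glc q_glc) with the documented units", {
  expect_equal(compute_yield(1.0, 10), 1 / (0.180156 * 10), tolerance = 1e-12)
  expect_equal(compute_yield(1.0, 10), 0.5551, tolerance = 1e-4)
  expect_identical(compute_yield(0, 5), 0)
  expect_error(compute_yield(0.9, 0), "undefined")
  # independent unit-tracked oracle: g glucose consumed per gDW per h is
  # q_glc * M_glc, and yield is growth over that mass flux
  mu <- 0.9; q <- 5
  grams_glucose_per_gdw_h <- q * 0.180156
  expect_equal(compute_yield(mu, q), mu / grams_glucose_per_gdw_h)
  # linear in mu, inverse in q_glc (property over random positive inputs)
  withr::with_seed(5, {
    mu <- runif(50, 0.1, 1.2); q <- runif(50, 1, 15); k <- runif(50, 0.5, 2)
    expect_equal(compute_yield(k * mu, q), k * compute_yield(mu, q))
    expect_equal(compute_yield(mu, k * q), compute_yield(mu, q) / k)
  })
})

test_that("growth binning uses closed intervals and rejects overlap", {
  df <- tibble::tibble(mu = c(1.02, 0.96, 1.09, 0.99, 1.00, 1.04))
  out <- bin_by_growth(df)
  expect_identical(as.character(out$growth_bin),
                   c("[1,1.04]", "[0.95,0.97]", "[1.08,1.1]", NA,
                     "[1,1.04]", "[1,1.04]"))
  # boundary record on touching bins goes to the lower bin
  touching <- tibble::tibble(lo = c(0.9, 1.0), hi = c(1.0, 1.1))
  expect_identical(as.character(bin_by_growth(tibble::tibble(mu = 1.0),
                                              touching)$growth_bin),
                   "[0.9,1]")
  expect_error(bin_by_growth(df, tibble::tibble(lo = c(0.9, 0.95),
                                                hi = c(1.0, 1.1))),
               "overlapping")
  # an empty bin is not an error
  empty <- fit_d2_lines(bin_by_growth(tibble::tibble(
    mu = 0.5, q_glc = 5, q_ac = 1)))
  expect_identical(nrow(empty), 0L)
})

test_that("d2 regression matches its definition and degeneracies are flagged", {
  # collinear points: perfect fit
  d <- tibble::tibble(q_glc = c(9, 11, 13), q_ac = 1.5 * c(9, 11, 13) - 9)
  fit <- fit_d2_line(d)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 1.5, tolerance = 1e-12)
  # r^2 is symmetric in the axes
  swapped <- fit_d2_line(tibble::tibble(q_glc = d$q_ac, q_ac = d$q_glc))
  expect_equal(fit$r_squared, swapped$r_squared, tolerance = 1e-12)
  # two points: exact but df = 0, p undefined
  f2 <- fit_d2_line(d[1:2, ])
  expect_true(f2$degenerate)
  expect_true(is.na(f2$p_value))
  expect_equal(f2$r_squared, 1)
  # zero uptake variance
  fz <- fit_d2_line(tibble::tibble(q_glc = c(9, 9, 9), q_ac = 1:3))
  expect_true(fz$degenerate)
  # known slope recovered within 2 SE on noisy synthetic strains
  withr::with_seed(31, {
    recs <- generate_phenotypes(synth_config("ale", n = 30, seed = 31,
                                             cv = 0.02))
    fr <- fit_d2_line(recs)
    se <- sqrt(sum(lm(q_ac ~ q_glc, recs)$residuals^2 / (30 - 2)) /
                 sum((recs$q_glc - mean(recs$q_glc))^2))
    expect_lt(abs(fr$slope - 1.5), 2 * se)
    expect_lt(fr$p_value, 1e-6)
  })
})

test_that("tradeoff reports combine records, fits and optional curves", {
  recs <- generate_phenotypes(synth_config("ale", n = 8, seed = 77, cv = 0.01))
  rep1 <- tradeoff_report(recs)
  expect_null(rep1$curves)
  expect_true("Y" %in% names(rep1$records))
  # within each bin, yield falls strictly as uptake rises at fixed mu
  by_bin <- split(rep1$records, rep1$records$growth_bin, drop = TRUE)
  for (b in by_bin) {
    if (nrow(b) < 2) next
    o <- order(b$q_glc)
    expect_true(all(diff(b$Y[o] * b$mu[o][1] / b$mu[o]) < 0))
  }
  m <- default_model()
  rep2 <- tradeoff_report(recs, model_curves = phenotype_curve(m, c(0.5, 0.9)))
  expect_identical(nrow(rep2$curves), 2L)
})
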