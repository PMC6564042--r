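test_that("zero leak is the identity and positive leak shifts phenotypes", {
  m <- default_model()
  expect_identical(add_proton_leak(m, 0), m)
  mu <- 0.6 * max_growth(m)
  s0 <- phenotype_at(m, mu, "max_yield")
  s50 <- phenotype_at(add_proton_leak(m, 50), mu, "max_yield")
  expect_gt(s50$q_glc, s0$q_glc)
  expect_gt(s50$q_ac, s0$q_ac)
  expect_lt(s50$Y, s0$Y)
})

test_that("the critical leak level renders a growth rate infeasible", {
  m <- default_model()
  cp <- coarse_params(m)
  mu <- 0.6 * analytic_acetate_line(cp)$mu_max
  # energy-balance arithmetic: max ATP supply at mu is F * (phi_max0 -
  # b*mu); leak ATP beyond the slack over demand is unsatisfiable
  F_ <- cp$a_fer * cp$eps_fer
  slack <- F_ * (cp$phi_max0 - cp$b * mu) - (cp$sigma * mu + cp$ngam)
  crit <- slack / m$globals$atp_per_leak
  expect_identical(phenotype_at(add_proton_leak(m, crit * 0.99), mu,
                                "max_yield")$status, "optimal")
  expect_identical(phenotype_at(add_proton_leak(m, crit * 1.01), mu,
                                "max_yield")$status, "infeasible")
})

test_that("leak monotonicity holds over levels and growth rates", {
  m <- default_model()
  mu_max <- max_growth(m)
  mus <- seq(0.3, 0.9, length.out = 10) * mu_max
  levels <- c(0, 50, 100)
  qglc <- sapply(levels, function(L) vapply(mus, function(mu)
    phenotype_at(add_proton_leak(m, L), mu, "max_yield")$q_glc, numeric(1)))
  Y <- sapply(seq_along(levels), function(j) mus / (m$globals$M_glc * qglc[, j]))
  for (j in 2:3) {
    expect_true(all(qglc[, j] > qglc[, j - 1] |
                      is.na(qglc[, j]) | is.na(qglc[, j - 1])))
    expect_true(all(Y[, j] < Y[, j - 1] | is.na(Y[, j]) | is.na(Y[, j - 1])))
  }
})

test_that("extensions widen the space but never touch the optimal curve", {
  m <- default_model()
  mu_max <- max_growth(m)
  m13 <- m |> add_extension(1) |> add_extension(3)
  m24 <- m |> add_extension(2) |> add_extension(4)
  mu_probe <- c(0.3, 0.6, 0.85, 0.97) * mu_max
  for (mu in mu_probe) {
    base_lo <- phenotype_at(m, mu, "min_qac")$q_ac
    base_hi <- phenotype_at(m, mu, "max_qac")$q_ac
    # (1)+(3): low-q_ac gain at high growth (where overflow was forced)
    lo13 <- phenotype_at(m13, mu, "min_qac")$q_ac
    expect_lte(lo13, base_lo + 1e-9)
    if (base_lo > 1e-6) expect_lt(lo13, base_lo - 1e-6)
    # (2)+(4): high-q_ac gain across all growth rates
    hi24 <- phenotype_at(m24, mu, "max_qac")$q_ac
    expect_gt(hi24, base_hi + 1e-6)
    # the yield-maximized curve is untouched
    for (mx in list(m13, m24))
      expect_equal(phenotype_at(mx, mu, "max_yield")$q_glc,
                   phenotype_at(m, mu, "max_yield")$q_glc,
                   tolerance = 1e-9)
  }
  # parameters that would put the extension on the optimal frontier are
  # rejected with a diagnostic
  expect_error(add_extension(m, 3, a = 14, k_eff = 16), "yield-maximized")
  expect_error(add_extension(m, 5), "kind")
})

test_that("solution spaces nest under reaction addition and removal", {
  m <- default_model()
  mu_max <- max_growth(m)
  big <- m |> add_extension(2) |> add_extension(3)
  cut <- knockout(m, "FER")
  for (mu in c(0.4, 0.8) * mu_max) {
    r_base <- c(phenotype_at(m, mu, "min_qac")$q_ac,
                phenotype_at(m, mu, "max_qac")$q_ac)
    r_big <- c(phenotype_at(big, mu, "min_qac")$q_ac,
               phenotype_at(big, mu, "max_qac")$q_ac)
    expect_lte(r_big[1], r_base[1] + 1e-9)
    expect_gte(r_big[2], r_base[2] - 1e-9)
    s_cut <- phenotype_at(cut, mu, "max_qac")
    if (s_cut$status == "optimal") {
      expect_gte(s_cut$q_ac, r_base[1] - 1e-9)
      expect_lte(s_cut$q_ac, r_base[2] + 1e-9)
    }
  }
})

test_that("knockouts reshape phenotypes as the oracle predicts", {
  m <- default_model()
  line <- analytic_acetate_line(coarse_params(m))
  # no fermentation: acetate gone, growth capped at the base threshold
  # (where pure respiration exhausts the budget)
  kf <- knockout(m, "FER")
  expect_equal(max_growth(kf), line$mu_threshold, tolerance = 1e-5)
  s <- phenotype_at(kf, line$mu_threshold * 0.9, "max_qac")
  expect_equal(s$q_ac, 0, tolerance = 1e-10)
  # no respiration: the fermentation line, lower yield everywhere
  kr <- knockout(m, "RES")
  for (mu in c(0.3, 0.7, 1.0)) {
    sr <- phenotype_at(kr, mu, "max_yield")
    sb <- phenotype_at(m, mu, "max_yield")
    cp <- coarse_params(m)
    expect_equal(sr$q_glc,
                 (cp$sigma * mu + cp$ngam) / cp$a_fer + cp$c_bms * mu,
                 tolerance = 1e-8)
    expect_lt(sr$Y, sb$Y)
  }
  # knocking out an inactive extension changes nothing
  me <- add_extension(m, 4)
  mek <- knockout(me, "EXT4")
  for (mu in c(0.5, 1.0))
    expect_equal(phenotype_at(mek, mu, "max_yield")$q_glc,
                 phenotype_at(me, mu, "max_yield")$q_glc, tolerance = 1e-12)
  expect_error(knockout(m, "NOPE"), "unknown reaction")
})
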