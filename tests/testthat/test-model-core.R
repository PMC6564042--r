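test_that("default model is structurally consistent and carbon-balanced", {
  m <- default_model()
  v <- validate_model(m)
  expect_true(v$pass)
  cb <- dplyr::filter(v$checks, check == "carbon_balance")
  expect_gt(nrow(cb), 0)
  expect_true(all(abs(cb$value) < 1e-12))
  # exactly three catalyzed pathways, plus exchange/pseudo reactions
  expect_identical(sum(!is.na(m$reactions$k_eff)), 3L)
  expect_gte(sum(is.na(m$reactions$k_eff)), 3L)
})

test_that("validation flags forced carbon imbalance and bad enzyme refs", {
  m <- default_model()
  i <- match("RES", m$reactions$id)
  st <- m$reactions$stoich[[i]]
  st["glc"] <- st["glc"] - 1  # one extra glucose consumed: 6 atoms lost
  m$reactions$stoich[[i]] <- st
  v <- validate_model(m)
  expect_false(v$pass)
  bad <- dplyr::filter(v$checks, check == "carbon_balance", subject == "RES")
  expect_equal(abs(bad$value), 6)
  expect_false(bad$ok)

  m2 <- default_model()
  m2$reactions$enzyme[match("FER", m2$reactions$id)] <- "glc"
  v2 <- validate_model(m2)
  expect_false(v2$pass)
  expect_true(any(v2$checks$check == "enzyme_reference" & !v2$checks$ok))
})

test_that("LP at mu = 0 reduces to the maintenance-only respiration solution", {
  # hand-solved: with only NGAM to satisfy, min q_glc uses respiration
  # alone (best ATP per glucose), so q_glc = NGAM / a_res
  m <- default_model(NGAM = 1.3)
  sol <- phenotype_at(m, 0, "max_yield")
  expect_equal(sol$q_glc, 1.3 / 26, tolerance = 1e-10)
  expect_equal(unname(sol$fluxes["FER"]), 0, tolerance = 1e-10)

  m0 <- default_model(NGAM = 0)
  sol0 <- phenotype_at(m0, 0, "max_yield")
  expect_equal(sol0$q_glc, 0, tolerance = 1e-12)
  expect_true(all(abs(sol0$fluxes) < 1e-10))
})

test_that("LP beyond the exhaustion growth rate is reported infeasible", {
  m <- default_model()
  mu_max <- analytic_acetate_line(coarse_params(m))$mu_max
  sol <- phenotype_at(m, mu_max + 0.05, "max_yield")
  expect_identical(sol$status, "infeasible")
  expect_true(is.na(sol$q_glc))
  expect_error(build_lp(m, -0.1), "nonnegative")
  expect_error(build_lp(m, 0.5, objective = "min_biomass"), "unknown objective")
})

test_that("LP assembly is deterministic", {
  m <- default_model()
  lp1 <- build_lp(m, 0.8, "min_qglc")
  lp2 <- build_lp(m, 0.8, "min_qglc")
  expect_identical(lp1$A1, lp2$A1)
  expect_identical(lp1$A3, lp2$A3)
  expect_identical(lp1$b1, lp2$b1)
  expect_identical(lp1$b3, lp2$b3)
  expect_identical(lp1$obj, lp2$obj)
})

test_that("optimal solutions satisfy every constraint post hoc", {
  m <- default_model()
  for (mu in c(0.2, 0.8, 1.05)) {
    for (objective in c("min_qglc", "max_qglc", "min_qac", "max_qac")) {
      lp <- build_lp(m, mu, objective)
      res <- solve_lp(lp)
      expect_identical(res$status, "optimal")
      x <- c(res$fluxes, res$enzymes)[lp$vars]
      expect_true(all(abs(lp$A3 %*% x - lp$b3) <= 1e-9))
      expect_true(all(lp$A1 %*% x - lp$b1 <= 1e-9))
    }
  }
})

test_that("scaling k_eff with demand rescales the enzyme-binding optima", {
  # the constraint polytope is homogeneous: scaling all k_eff, mu and
  # NGAM by c scales every optimal flux objective by c
  withr::with_seed(11, {
    for (rep in 1:3) {
      m <- random_model()
      p <- ssme_params(m)
      cc <- 2.5
      m2 <- ssme_set_params(m, k_eff_res = p$k_eff_res * cc,
                            k_eff_fer = p$k_eff_fer * cc,
                            k_eff_bms = p$k_eff_bms * cc,
                            NGAM = p$NGAM * cc)
      mu <- 0.6 * analytic_acetate_line(coarse_params(m))$mu_max
      for (objective in c("max_yield", "max_qac")) {
        s1 <- phenotype_at(m, mu, objective)
        s2 <- phenotype_at(m2, cc * mu, objective)
        expect_equal(s2$q_glc, cc * s1$q_glc, tolerance = 1e-8)
        expect_equal(s2$q_ac, cc * s1$q_ac, tolerance = 1e-8)
      }
    }
  })
})

test_that("model YAML round trip is lossless", {
  m <- default_model()
  f <- withr::local_tempfile(fileext = ".yaml")
  ssme_write_model(m, f)
  m2 <- ssme_read_model(f)
  expect_identical(m$globals, m2$globals)
  expect_equal(m$reactions$stoich, m2$reactions$stoich)
  expect_equal(as.data.frame(m$species), as.data.frame(m2$species))
  expect_equal(m$reactions$k_eff, m2$reactions$k_eff)
  expect_equal(m$reactions$ub, m2$reactions$ub)  # including Inf
  # round trip preserves phenotypes exactly
  s1 <- phenotype_at(m, 0.9, "max_yield")
  s2 <- phenotype_at(m2, 0.9, "max_yield")
  expect_identical(s1$q_glc, s2$q_glc)
})

test_that("ssme_set_params keeps dependent stoichiometry in step", {
  m <- ssme_set_params(default_model(), GAM = 50, NGAM = 2.5, n_ac = 3)
  i <- match(c("BMS", "FER", "NGAM"), m$reactions$id)
  expect_equal(unname(m$reactions$stoich[[i[1]]]["atp"]), -50)
  expect_equal(unname(m$reactions$stoich[[i[2]]]["ac"]), 3)
  expect_equal(m$reactions$lb[i[3]], 2.5)
  expect_true(validate_model(m)$pass)
  expect_error(ssme_set_params(m, bogus = 1), "unknown SSME parameter")
})
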