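test_that("NN summation reproduces hand-computed duplex values", {
  ps <- ref_params()
  th <- predict_duplex("GGCUGUUC", ps)
  expect_equal(th$dG37, -8.98, tolerance = 1e-9)
  expect_equal(th$dH, -79.7, tolerance = 1e-9)
  expect_equal(th$dS * 1000, -228.0, tolerance = 1e-9)

  th2 <- predict_duplex("GAUUACGCCUG", ps)
  expect_equal(th2$dG37, -13.02, tolerance = 1e-9)
  expect_equal(th2$dH, -112.0, tolerance = 1e-9)

  # self-complementary strands get the +0.43 symmetry term
  th3 <- predict_duplex("GGAUCGAUCC", ps)
  expect_equal(unname(th3$breakdown["symmetry"]), 0.43)
  expect_false("symmetry" %in% names(th$breakdown))
})

test_that("the breakdown sums exactly to the totals", {
  ps <- ref_params()
  set.seed(7)
  for (i in 1:10) {
    th <- predict_duplex(random_duplex(), ps)
    expect_identical(sum(th$breakdown), th$dG37)
  }
})

test_that("identical NN multisets give identical predictions", {
  ps <- ref_params()
  # a sequence pair sharing the same stack multiset (different order)
  a <- predict_duplex("GGCUGUUC", ps)
  b <- predict_duplex("GGUUCUGC", ps)
  expect_equal(sort(nn_steps(duplex_spec("GGCUGUUC"))),
               sort(nn_steps(duplex_spec("GGUUCUGC"))))
  expect_equal(a$dG37, b$dG37)
  expect_equal(a$dH, b$dH)
})

test_that("free energy at temperature follows dH - T dS with dCp = 0", {
  th <- list(dH = -13.8, dS = -0.0346)
  expect_equal(free_energy_at(th, 310.15), -3.07, tolerance = 0.015)
  th2 <- list(dH = -112.0, dS = -0.3191)
  expect_equal(free_energy_at(th2, 310.15), -13.03, tolerance = 0.005)
  # melting point of the unimolecular limit (far from 37 C, hence warned)
  expect_equal(suppressWarnings(free_energy_at(th, T = th$dH / th$dS)), 0)
  expect_warning(free_energy_at(th, 273.15), "extrapolating")
})

test_that("melting temperature inverts the concentration relation", {
  ps <- ref_params()
  th <- predict_duplex("GGCUGUUC", ps)
  expect_equal(melting_temperature(th, Ct = 1e-4, s = 4), 320.0,
               tolerance = 0.05)
  # ln term vanishes at Ct = s: Tm = dH/dS
  expect_equal(melting_temperature(th, Ct = 4, s = 4), th$dH / th$dS)
  # monotonic in concentration for dH < 0
  tms <- vapply(c(1e-6, 1e-5, 1e-4), melting_temperature, numeric(1),
                thermo = th, s = 4)
  expect_true(all(diff(tms) > 0))
  expect_error(melting_temperature(list(dH = 10, dS = 0.01,
                                        self_complementary = FALSE), 1e-4, 4),
               "dH >= 0")
})

test_that("van't Hoff fit round-trips noiseless melting data exactly", {
  ps <- ref_params()
  th <- predict_duplex("GGCUGUUC", ps)
  Ct <- exp(seq(log(2e-6), log(2e-4), length.out = 10))
  pts <- data.frame(Ct = Ct,
                    Tm = vapply(Ct, melting_temperature, numeric(1),
                                thermo = th, s = 4))
  vf <- vant_hoff_fit(pts, s = 4)
  expect_equal(vf$dH, th$dH, tolerance = 1e-6)
  expect_equal(vf$dS, th$dS, tolerance = 1e-6)
  expect_equal(vf$dG37, th$dH - 310.15 * th$dS, tolerance = 1e-6)
  expect_error(vant_hoff_fit(data.frame(Ct = rep(1e-4, 3), Tm = rep(320, 3))),
               "distinct")
})

test_that("van't Hoff and melting temperature are mutual inverses", {
  set.seed(11)
  for (i in 1:20) {
    dH <- runif(1, -120, -40)
    Tm_target <- runif(1, 290, 350)
    # pick dS so that Tm(1e-4, s = 4) hits the target
    dS <- dH / Tm_target - 1.9872e-3 * log(1e-4 / 4)
    th <- list(dH = dH, dS = dS, self_complementary = FALSE)
    Ct <- exp(seq(log(1e-5), log(1e-3), length.out = 8))
    pts <- data.frame(Ct = Ct,
                      Tm = vapply(Ct, melting_temperature, numeric(1),
                                  thermo = th, s = 4))
    vf <- vant_hoff_fit(pts, s = 4)
    expect_equal(vf$dH, dH, tolerance = 1e-6)
    expect_equal(vf$dS, dS, tolerance = 1e-6)
  }
})

test_that("van't Hoff error stays small under realistic Tm noise", {
  # regime of a typical 8-mer: dH ~ -79.8 kcal/mol, dG37 ~ -8.7
  dH0 <- -79.8; dS0 <- (dH0 + 8.7) / 310.15
  set.seed(1203)
  Ct <- exp(seq(log(2e-6), log(2e-4), length.out = 12))
  Tm <- vapply(Ct, function(ct)
    melting_temperature(list(dH = dH0, dS = dS0), ct, 4), numeric(1)) +
    rnorm(12, 0, 0.3)
  vf <- vant_hoff_fit(data.frame(Ct = Ct, Tm = Tm), s = 4)
  expect_lt(abs(vf$dG37 - (dH0 - 310.15 * dS0)), 0.3)
})
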