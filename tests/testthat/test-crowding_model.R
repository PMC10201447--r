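test_that("osmolality converts to water activity", {
  expect_equal(water_activity_from_osmolality(0), 1.0)
  # 1 osmol/kg at 25 C; cross-check against the ideal-solution relation
  expect_equal(water_activity_from_osmolality(1000, 298.15), 0.9822,
               tolerance = 5e-4)
  expect_equal(water_activity_from_osmolality(1000), exp(-0.018),
               tolerance = 5e-4)
  aw <- water_activity_from_osmolality(seq(0, 3000, by = 500))
  expect_true(all(diff(aw) < 0))
  expect_error(water_activity_from_osmolality(-1), "non-negative")
})

test_that("molality uses the grams-per-100-g-water convention", {
  eg62 <- cosolute("EG62", molar_mass = 62, n_monomers = 1,
                   cls = "diol_class")
  expect_equal(molality(10, eg62), 1.613, tolerance = 1e-3)
  expect_equal(molality(40, "PEG200"), 2.0)
  expect_equal(molality(0, "glycerol"), 0)
})

test_that("generic excluded volume follows the cylinder model", {
  expect_equal(excluded_volume_generic(1, 1, 1), 6.022e-4)
  expect_equal(excluded_volume_generic(2, 3, 4),
               2 * excluded_volume_generic(2, 3, 2))   # linear in k
  expect_equal(excluded_volume_change(2 * 0.5, 0.5), 0) # V_dup = 2 V_ss
})

test_that("duplex excluded-volume term matches the printed calibration", {
  # 11-mer in 10 wt% ethylene glycol: the printed worked example
  C <- molality(10, "ethylene_glycol")
  expect_equal(excluded_volume_duplex(11, C, 1), -0.45, tolerance = 0.005)
  # 10-mer in 20 wt% EG (the composed-prediction pipeline input)
  expect_equal(excluded_volume_duplex(10, molality(20, "ethylene_glycol"), 1),
               -0.84, tolerance = 0.005)
  expect_equal(excluded_volume_duplex(8, 0, 1), 0)
  expect_warning(excluded_volume_duplex(20, 1, 1), "6-12")
  # monotone non-increasing in n, C and N
  expect_true(excluded_volume_duplex(12, 1, 1) < excluded_volume_duplex(6, 1, 1))
  expect_true(excluded_volume_duplex(8, 2, 1) < excluded_volume_duplex(8, 1, 1))
  expect_true(excluded_volume_duplex(8, 1, 4) < excluded_volume_duplex(8, 1, 1))
})

test_that("per-parameter excluded volume shares the duplex term evenly", {
  expect_equal(excluded_volume_per_nn(-0.45, 11), -0.0409, tolerance = 1e-3)
  expect_equal(excluded_volume_per_nn(0, 9), 0)
  # at the reference condition (C*N = 8) the sequence-average is ~-0.22
  pernn <- vapply(6:12, function(n)
    excluded_volume_per_nn(excluded_volume_duplex(n, 2.0, 4), n), numeric(1))
  expect_lt(abs(mean(pernn) - (-0.22)), 0.005)
})

test_that("water-activity contributions are linear with class ordering", {
  dec <- ref_decomp()
  m_peg <- m_cs_for("PEG200", dec)
  m_diol <- m_cs_for("ethylene_glycol", dec)
  expect_equal(wa_contribution(m_peg["initiation"], 0.0489),
               c(initiation = 1.63), tolerance = 0.005)
  expect_equal(wa_contribution(m_diol["initiation"], 0.047),
               c(initiation = 0.644), tolerance = 0.001)
  expect_equal(wa_contribution(m_peg, 0), m_peg * 0)
  # linearity in delta_aw
  expect_equal(wa_contribution(m_peg, 0.08), 2 * wa_contribution(m_peg, 0.04))
  # vicinal-diol class destabilizes less than the PEG class at equal delta_aw
  pos <- m_peg > 0
  expect_true(all(wa_contribution(m_diol, 0.05)[pos] <
                  wa_contribution(m_peg, 0.05)[pos]))
})

test_that("prefactors select or scale by cosolute class", {
  dec <- ref_decomp()
  expect_equal(m_cs_for("PEG400", dec), m_cs_for("PEG200", dec))
  expect_equal(m_cs_for("ethylene_glycol", dec),
               m_cs_for("PEG200", dec) * dec$slope_ratio, tolerance = 0.01)
  half <- cosolute("X", 100, 1, "custom", slope_ratio = 0.5)
  expect_equal(m_cs_for(half, dec), 0.5 * m_cs_for("PEG200", dec))
  expect_error(cosolute("X", 100, 1, "custom"), "slope_ratio")
})

test_that("delta_aw back-inferred from the decomposition agrees across rows", {
  dec <- ref_decomp()
  daw <- dec$table$dG_wa / dec$table$m_peg
  expect_true(all(abs(daw - mean(daw)) < 0.001))
})

test_that("solution conditions resolve delta_aw or fail loudly", {
  # bundled lookup for the calibration conditions
  expect_equal(solution_condition("PEG200", 40)$delta_aw, 0.0489)
  expect_equal(solution_condition("ethylene_glycol", 20)$delta_aw, 0.047)
  # no cosolute: zero depression
  expect_equal(solution_condition(NULL)$delta_aw, 0)
  # osmometry route
  sol <- solution_condition("glycerol", 10, osmolality_mmol_kg = 1000)
  expect_equal(sol$delta_aw, 1 - water_activity_from_osmolality(1000, 310.15))
  # unknown condition: error, never silently zero
  expect_error(solution_condition("glycerol", 15), "delta_aw unknown")
})

test_that("composition at the reference condition reproduces the table", {
  dec <- ref_decomp()
  ps <- ref_params()
  sol <- solution_condition("PEG200", 40)   # 122 mM Na+, delta_aw 0.0489
  cmp <- compose_condition_parameters(dec, sol, n_bp = 8)
  labels <- rownames(dec$table)
  expect_true(all(abs(cmp$table[labels, "dG37"] -
                      ps$table[labels, "dG37"]) <= 0.03))
  # the audit columns sum to the composed value
  sums <- rowSums(cmp$table[labels, c("bulk", "cation", "ev", "wa")])
  expect_equal(unname(sums), cmp$table[labels, "dG37"], tolerance = 1e-12)
  # composed sets carry no enthalpy and refuse Tm
  th <- predict_duplex("GGCUGUUC", cmp)
  expect_true(is.na(th$dH))
  expect_error(melting_temperature(th, 1e-4), "refused")
})

test_that("no-cosolute composition is bulk plus cation only", {
  dec <- ref_decomp()
  sol <- solution_condition(NULL, na_mM = 122)
  cmp <- compose_condition_parameters(dec, sol, n_bp = 8)
  labels <- rownames(dec$table)
  expect_equal(cmp$table[labels, "dG37"],
               dec$table$dG_bulk + dec$table$dG_cat_122, tolerance = 1e-12)
})

test_that("the composed-prediction pipeline reproduces the worked 10-mer", {
  dec <- ref_decomp()
  sol <- solution_condition("ethylene_glycol", 20, delta_aw = 0.047)
  th <- predict_in_condition("GGAUCGAUCC", sol, dec)
  # independent hand assembly from the decomposition table
  steps <- nn_steps(duplex_spec("GGAUCGAUCC"))
  tab <- dec$table
  expected <- sum(tab[steps, "dG_bulk"] + tab[steps, "dG_cat_122"]) +
    tab["initiation", "dG_bulk"] + tab["initiation", "dG_cat_122"] +
    excluded_volume_duplex(10, molality(20, "ethylene_glycol"), 1) +
    (sum(tab[steps, "m_diol"]) + tab["initiation", "m_diol"]) * 0.047 +
    0.43
  expect_equal(th$dG37, expected, tolerance = 1e-12)
  expect_equal(th$dG37, -13.07, tolerance = 0.005)
  expect_true("symmetry" %in% names(th$breakdown))
})
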