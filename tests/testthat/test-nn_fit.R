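test_that("design rows count canonical stacks, initiation and terminal AU", {
  ps <- ref_params()
  base <- simulate_duplex_set(ps, n_duplexes = 20, seed = 3)$duplexes
  d <- build_design(c(base, list(duplex_spec("GAUUACGCCUG"),
                                 duplex_spec("AGCGCU"),
                                 duplex_spec("GGCUGUUC"),
                                 duplex_spec("GGUUCUGC"))))
  row <- d$X["GAUUACGCCUG", ]
  expect_true(all(row[nn_step_labels()] == 1))
  expect_equal(unname(row["initiation"]), 1)
  expect_equal(unname(row["terminal_AU"]), 0)
  expect_equal(unname(d$X["AGCGCU", "terminal_AU"]), 2)
  # sequences with identical stack multisets share a design row
  expect_equal(unname(d$X["GGCUGUUC", ]), unname(d$X["GGUUCUGC", ]))
  expect_equal(d$rank, 12)
})

test_that("under-determined designs fail with a diagnosis", {
  ps <- ref_params()
  sim <- simulate_duplex_set(ps, n_duplexes = 45, seed = 5)
  expect_error(build_design(sim$duplexes[1:11]), "rank-deficient")
})

test_that("noiseless synthetic data is recovered exactly", {
  ps <- ref_params()
  sim <- simulate_duplex_set(ps, seed = 17, sd_dG37 = 0, sd_dH = 0)
  # zero noise: responses equal the NN predictions exactly
  expect_equal(sim$dG37, sim$truth$dG37)
  fit <- fit_parameters(sim$design, sim$dG37, sim$dH)
  free <- c(nn_step_labels(), "initiation", "terminal_AU")
  expect_equal(fit$params$table[free, "dG37"], ps$table[free, "dG37"],
               tolerance = 1e-9)
  expect_equal(fit$params$table[free, "dH"], ps$table[free, "dH"],
               tolerance = 1e-9)
  # derived entropies close the free-energy relation by construction
  t <- fit$params$table[free, ]
  expect_equal(t$dG37, t$dH - 310.15 * t$dS, tolerance = 1e-9)
})

test_that("the generator covers all stacks and reproduces under its seed", {
  ps <- ref_params()
  sim1 <- simulate_duplex_set(ps, seed = 23)
  sim2 <- simulate_duplex_set(ps, seed = 23)
  expect_identical(sim1$truth$sequence, sim2$truth$sequence)
  expect_identical(sim1$dG37, sim2$dG37)
  # every stack appears in at least 5 duplexes
  counts <- colSums(sim1$design$X[, nn_step_labels()] > 0)
  expect_true(all(counts >= 5))
  # lengths span the study design and stability floor is respected
  lens <- nchar(sim1$truth$sequence)
  expect_true(all(lens >= 6 & lens <= 12))
  expect_true(all(sim1$truth$dG37 <= -4))
  expect_equal(sum(vapply(sim1$duplexes, `[[`, logical(1),
                          "self_complementary")), 20)
})

test_that("simulated melting datasets invert back to the generator truth", {
  ps <- ref_params()
  sim <- simulate_duplex_set(ps, n_duplexes = 14, n_selfcomp = 4, seed = 31,
                             melting = TRUE, sd_Tm = 0)
  i <- 3
  s <- if (sim$duplexes[[i]]$self_complementary) 1 else 4
  vf <- vant_hoff_fit(sim$melting[[i]], s = s)
  expect_equal(vf$dH, sim$truth$dH[i], tolerance = 1e-6)
  # concentrations span a ~100-fold range, as in a melting series
  Ct <- sim$melting[[i]]$Ct
  expect_equal(max(Ct) / min(Ct), 100, tolerance = 0.01)
  expect_equal(nrow(sim$melting[[i]]), 12)
})

test_that("the estimator is unbiased with bounded error under noise", {
  ps <- ref_params()
  free <- c(nn_step_labels(), "initiation", "terminal_AU")
  truth <- ps$table[free, "dG37"]
  reps <- 200
  err <- matrix(NA_real_, reps, length(free))
  for (r in seq_len(reps)) {
    sim <- simulate_duplex_set(ps, seed = 1000 + r)
    fit <- fit_parameters(sim$design, sim$dG37, sim$dH)
    err[r, ] <- fit$params$table[free, "dG37"] - truth
  }
  rmse <- sqrt(colMeans(err^2))
  names(rmse) <- free
  # stacks and the terminal penalty are well determined ...
  expect_true(all(rmse[c(nn_step_labels(), "terminal_AU")] < 0.15))
  # ... initiation is the least identifiable parameter of random designs
  expect_lt(rmse["initiation"], 0.30)
  # zero-mean noise propagates to (Monte-Carlo) zero-mean parameter error
  bias <- colMeans(err)
  mc_se <- rmse / sqrt(reps)
  expect_true(all(abs(bias) < 4 * mc_se))
})
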