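test_that("response additivity matches hand arithmetic and its limits", {
  expect_equal(additivity_total(0.3, 0.2), 0.44)
  expect_equal(additivity_total(0, 0.7), 0.7)
  expect_equal(additivity_total(0.7, 0), 0.7)
  expect_equal(additivity_total(1, 0.3), 1)
  expect_error(additivity_total(1.2, 0), "\\[0, 1\\]")
  set.seed(6)
  a <- runif(50); b <- runif(50)
  tot <- additivity_total(a, b)
  expect_equal(tot, additivity_total(b, a))          # symmetric
  expect_true(all(tot >= pmax(a, b)))                # never below either agent
  expect_true(all(tot >= 0 & tot <= 1))
})

test_that("effect inversion undoes additivity on the interior and clips noise", {
  expect_equal(invert_particle_effect(0.44, 0.2), 0.3)
  expect_equal(invert_particle_effect(0.2, 0.2), 0)
  expect_warning(out <- invert_particle_effect(0.1, 0.2), "clipped")
  expect_equal(out, 0)
  expect_error(invert_particle_effect(0.5, 1), "unidentifiable")
  set.seed(8)
  e_p <- runif(50, 0, 0.99); e_i <- runif(50, 0, 0.99)
  expect_equal(invert_particle_effect(additivity_total(e_p, e_i), e_i), e_p)
})

test_that("toxic units and relative contributions follow their definitions", {
  expect_equal(toxic_units(5, 10), 0.5)
  expect_equal(toxic_units(0, 10), 0)
  expect_equal(toxic_units(10, 10), 1)
  expect_error(toxic_units(5, 0), "positive")
  expect_equal(unname(relative_contributions(0.5, 0.5)), c(0.5, 0.5))
  expect_equal(unname(relative_contributions(0.6, 0.2)), c(0.75, 0.25))
  expect_equal(unname(relative_contributions(0.3, 0)), c(1, 0))
  expect_error(relative_contributions(0, 0), "undefined")
})

test_that("with a negligible ion component the particle fit reduces to a plain fit", {
  f <- 1e-4
  # an AgNO3 series spanning the (very weak) ion curve keeps its fit regular
  # while the ion doses in the suspension wells stay vanishingly small
  tr <- synthetic_truth(dissolved_fraction = f, ion_ec50 = 1e5,
                        agno3_concentrations = c(5e4, 1e5, 2e5, 4e5),
                        particle_ec50 = 20, icpms_cv = 0, timepoints = 48,
                        n_per_well = 20L, seed = 12)
  ex <- generate_experiment(tr)
  ion <- fit_ll4(ex$immobility, condition = "agno3", timepoint = 48)
  tab <- build_speciation_table(ex$speciation)
  np <- ex$immobility[ex$immobility$series == "np", ]
  part <- fit_particle_curve(np, ion, tab)
  plain_rec <- np
  plain_rec$conc_ug_per_l <- (1 - f) * np$conc_ug_per_l
  plain <- fit_ll4(plain_rec)
  expect_equal(part$ec50, plain$ec50, tolerance = 1e-3)
  expect_equal(part$slope, plain$slope, tolerance = 1e-3)
})

test_that("the additivity particle fit recovers its generating curve", {
  # single replicates of this design leave the particle slope noisy even at
  # large n (ions dominate the low doses), so recovery is asserted on the
  # median estimate over replicates
  est <- sapply(11:40, function(s) {
    tr <- synthetic_truth(dissolved_fraction = 0.3, ion_slope = 3, ion_ec50 = 3,
                          particle_slope = 3, particle_ec50 = 25, icpms_cv = 0,
                          timepoints = 48, n_per_well = 250L, seed = s)
    ex <- generate_experiment(tr)
    ion <- fit_ll4(ex$immobility, condition = "agno3", timepoint = 48)
    tab <- build_speciation_table(ex$speciation)
    np <- ex$immobility[ex$immobility$series == "np", ]
    part <- suppressWarnings(fit_particle_curve(np, ion, tab))
    c(part$ec50, part$slope)
  })
  expect_lt(abs(stats::median(est[1, ]) - 25) / 25, 0.05)
  expect_lt(abs(stats::median(est[2, ]) - 3) / 3, 0.25)
})

test_that("the particle-fit optimum matches exhaustive grid search", {
  tr <- synthetic_truth(dissolved_fraction = 0.3, ion_slope = 3, ion_ec50 = 3,
                        particle_slope = 3, particle_ec50 = 25, icpms_cv = 0,
                        timepoints = 48, n_per_well = 50L, seed = 23)
  ex <- generate_experiment(tr)
  ion <- fit_ll4(ex$immobility, condition = "agno3", timepoint = 48)
  tab <- build_speciation_table(ex$speciation)
  np <- ex$immobility[ex$immobility$series == "np", ]
  part <- fit_particle_curve(np, ion, tab)
  best <- grid_search_particle(np, ion, tab)
  expect_lte(-part$loglik, best$val + 1e-8)
  expect_lt(abs(part$slope - best$h), best$dh)
  expect_lt(abs(part$ec50 - best$e), best$de)
})

test_that("an unidentifiable particle component is reported, not fitted", {
  # ion effect alone explains all observed immobility
  tr <- synthetic_truth(dissolved_fraction = 0.6, ion_ec50 = 2,
                        particle_ec50 = 20, icpms_cv = 0, timepoints = 48,
                        n_per_well = 20L, seed = 31)
  ex <- generate_experiment(tr)
  tab <- build_speciation_table(ex$speciation)
  np <- ex$immobility[ex$immobility$series == "np", ]
  # an ion curve steep and potent enough to sit above every observation
  strong_ion <- fit_ll4(make_noisefree_records(0.5, 6, concs = c(0.2, 0.5, 1, 2, 5)))
  expect_error(fit_particle_curve(np, strong_ion, tab), "unidentifiable")
})

test_that("a symmetric truth partitions into equal halves", {
  tr <- synthetic_truth(dissolved_fraction = 0.5, ion_slope = 3,
                        particle_slope = 3, ion_ec50 = 10, particle_ec50 = 10,
                        icpms_cv = 0.05, timepoints = 48, n_per_well = 50L)
  vals <- sapply(1:12, function(i) {
    tr$seed <- 600 + i
    ex <- generate_experiment(tr)
    ion <- fit_ll4(ex$immobility, condition = "agno3", timepoint = 48)
    tab <- build_speciation_table(ex$speciation)
    np <- ex$immobility[ex$immobility$series == "np", ]
    suppressWarnings(partition_condition(np, ion, tab))$ion_fraction
  })
  expect_lt(abs(mean(vals) - 0.5), 0.05)
})

test_that("partition output is internally consistent and deterministic", {
  tr <- synthetic_truth(seed = 44, timepoints = 48, n_per_well = 20L,
                        dissolved_fraction = 0.3, ion_ec50 = 4)
  ex <- generate_experiment(tr)
  ion <- fit_ll4(ex$immobility, condition = "agno3", timepoint = 48)
  tab <- build_speciation_table(ex$speciation)
  np <- ex$immobility[ex$immobility$series == "np", ]
  pr1 <- partition_condition(np, ion, tab)
  pr2 <- partition_condition(np, ion, tab)
  expect_equal(pr1$ion_fraction, pr2$ion_fraction)
  expect_equal(pr1$ion_fraction + pr1$particle_fraction, 1)
  expect_gte(pr1$tu_ion, 0); expect_gte(pr1$tu_particle, 0)
  expect_equal(pr1$tu_ion, pr1$c_ion / ion$ec50)
  expect_equal(pr1$tu_particle, pr1$c_particle / pr1$particle_curve$ec50)
  # the suspension EC50 sits on the fitted suspension curve's midpoint
  expect_equal(ll4_effect(pr1$suspension_ec50, pr1$suspension_curve$slope,
                          pr1$suspension_curve$ec50), 0.5)
})

test_that("recovered contributions track the truth across a grid of conditions", {
  grid <- expand.grid(f = c(0.2, 0.35, 0.5), e_i = c(4, 8, 16))
  for (k in seq_len(nrow(grid))) {
    tr <- synthetic_truth(dissolved_fraction = grid$f[k], ion_ec50 = grid$e_i[k],
                          particle_ec50 = 20, ion_slope = 3, particle_slope = 3,
                          icpms_cv = 0.05, timepoints = 48, n_per_well = 50L)
    truth_frac <- true_contributions(tr)[["ion"]]
    vals <- sapply(1:15, function(i) {
      tr$seed <- 7000 + 97L * k + i
      ex <- generate_experiment(tr)
      tab <- build_speciation_table(ex$speciation)
      np <- ex$immobility[ex$immobility$series == "np", ]
      tryCatch({
        ion <- fit_ll4(ex$immobility, condition = "agno3", timepoint = 48)
        suppressWarnings(partition_condition(np, ion, tab))$ion_fraction
      }, error = function(e) NA_real_)
    })
    expect_gte(sum(!is.na(vals)), 12)
    expect_lt(abs(mean(vals, na.rm = TRUE) - truth_frac), 0.05,
              label = sprintf("f=%.2f e_i=%g: |%.3f - %.3f|", grid$f[k],
                              grid$e_i[k], mean(vals, na.rm = TRUE), truth_frac))
  }
})

test_that("raising the dissolved fraction never lowers the recovered ion share", {
  fs <- c(0.2, 0.4, 0.6, 0.8)
  means <- sapply(fs, function(f) {
    tr <- synthetic_truth(dissolved_fraction = f, ion_ec50 = 6,
                          particle_ec50 = 20, icpms_cv = 0.05,
                          timepoints = 48, n_per_well = 50L)
    mean(sapply(1:10, function(i) {
      tr$seed <- 9000 + round(1000 * f) + i
      ex <- generate_experiment(tr)
      tab <- build_speciation_table(ex$speciation)
      np <- ex$immobility[ex$immobility$series == "np", ]
      tryCatch({
        ion <- fit_ll4(ex$immobility, condition = "agno3", timepoint = 48)
        suppressWarnings(partition_condition(np, ion, tab))$ion_fraction
      }, error = function(e) NA_real_)
    }), na.rm = TRUE)
  })
  expect_true(all(diff(means) > -0.02))   # monotone within Monte-Carlo slack
})
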