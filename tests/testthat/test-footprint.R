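test_that("oxidation level is the oxidized fraction and scale-invariant", {
  expect_equal(oxidation_level(100, 300), 0.25)
  expect_equal(oxidation_level(0, 42), 0)
  expect_error(oxidation_level(0, 0), "undefined")
  expect_error(oxidation_level(-1, 5), "non-negative")
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 0, 100); b <- runif(1, 1e-3, 100); c <- runif(1, 1e-3, 50)
    expect_equal(oxidation_level(c * a, c * b), oxidation_level(a, b))
  }
})

test_that("relative oxidation ratios against the summed controls", {
  expect_equal(relative_oxidation(0.3, 0.1, 0.2), 1.0)
  expect_equal(relative_oxidation(0, 0.1, 0.2), 0)
  expect_error(relative_oxidation(0.3, 0, 0), "control")
})

test_that("fold change is the 4/30 degC ratio with reciprocal symmetry", {
  expect_equal(fold_change(0.5, 0.4), 1.25)
  expect_equal(fold_change(0.7, 0.7), 1.0)
  expect_error(fold_change(0.5, 0), "30 degC")
  set.seed(12)
  for (i in 1:20) {
    a <- runif(1, 0.01, 5); b <- runif(1, 0.01, 5)
    expect_equal(fold_change(a, b) * fold_change(b, a), 1)
  }
})

test_that("exposure calls use strict thresholds with boundaries unchanged", {
  expect_equal(call_exposure_change(1.25), "more_exposed")
  expect_equal(call_exposure_change(1.00), "unchanged")
  expect_equal(call_exposure_change(0.80), "more_buried")
  ## the 0.87 boundary case: above the 0.83 cutoff, so not called buried
  expect_equal(call_exposure_change(0.87), "unchanged")
  expect_equal(call_exposure_change(c(1.20, 0.83)), c("unchanged", "unchanged"))
  expect_error(call_exposure_change(1.1, upper = 0.8, lower = 1.2), "thresholds")
  expect_error(call_exposure_change(-1), "positive")
})

test_that("single-oxidation filter drops multiply-oxidized records only", {
  sim <- simulate_footprint(footprint_sim_config(n_residues = 12,
                                                 sites_exposed = 3,
                                                 sites_buried = 8,
                                                 n_double_oxidized = 5,
                                                 noise_cv = 0, seed = 21))
  tab <- sim$table
  filtered <- filter_single_oxidation(tab)
  expect_equal(nrow(filtered), sum(tab$n_oxidations_on_peptide <= 1))
  expect_true(all(filtered$n_oxidations_on_peptide <= 1))
  ## unmodified partners of the removed peptides survive
  removed_peps <- unique(tab$peptide_sequence[tab$n_oxidations_on_peptide > 1])
  expect_true(any(filtered$peptide_sequence %in% removed_peps &
                    filtered$n_oxidations_on_peptide == 0))
  ## all singly oxidized: identity
  clean <- tab[tab$n_oxidations_on_peptide <= 1, ]
  expect_identical(filter_single_oxidation(clean), clean)
})

test_that("noiseless chain returns planted fold changes exactly", {
  cfg <- footprint_sim_config(n_residues = 20, sites_exposed = c(4, 9),
                              sites_buried = 15, fc_exposed = 1.25,
                              fc_buried = 0.87, noise_cv = 0, seed = 5)
  sim <- simulate_footprint(cfg)
  rep <- residue_fc_table(sim$table)
  expect_equal(nrow(rep), 20)
  expect_equal(rep$fc_mean[rep$residue == 4], 1.25)
  expect_equal(rep$fc_mean[rep$residue == 9], 1.25)
  expect_equal(rep$fc_mean[rep$residue == 15], 0.87)
  expect_equal(rep$call[rep$residue == 4], "more_exposed")
  ## planted 0.87 sits above the 0.83 cutoff: surfaced as unchanged
  expect_equal(rep$call[rep$residue == 15], "unchanged")
  expect_true(all(rep$fc_mean[!rep$residue %in% c(4, 9, 15)] == 1))
  expect_true(all(rep$call[!rep$residue %in% c(4, 9, 15)] == "unchanged"))
  expect_equal(rep$n_detections, rep(3L, 20))
  expect_true(all(rep$fc_sem == 0))
})

test_that("fc report is invariant to row order and intensity rescaling", {
  sim <- simulate_footprint(footprint_sim_config(n_residues = 10,
                                                 sites_exposed = 2,
                                                 sites_buried = 7,
                                                 noise_cv = 0.05, seed = 31))
  base <- residue_fc_table(sim$table)
  set.seed(32)
  shuffled <- sim$table[sample(nrow(sim$table)), ]
  expect_equal(residue_fc_table(shuffled), base)
  rescaled <- sim$table
  rescaled$intensity <- rescaled$intensity * 1e3
  expect_equal(residue_fc_table(rescaled), base)
})

test_that("single detection reports no s.e.m.", {
  sim <- simulate_footprint(footprint_sim_config(n_residues = 6,
                                                 sites_exposed = 2,
                                                 sites_buried = 5,
                                                 noise_cv = 0, seed = 41))
  one_rep <- sim$table[sim$table$replicate == 1, ]
  rep <- residue_fc_table(one_rep)
  expect_equal(rep$n_detections, rep(1L, 6))
  expect_true(all(is.na(rep$fc_sem)))
})

test_that("pooled aggregation gives one fold change from summed intensities", {
  sim <- simulate_footprint(footprint_sim_config(n_residues = 6,
                                                 sites_exposed = 2,
                                                 sites_buried = 5,
                                                 noise_cv = 0, seed = 43))
  pooled <- residue_fc_table(sim$table, method = "pooled")
  expect_equal(pooled$n_detections, rep(1L, 6))
  expect_true(all(is.na(pooled$fc_sem)))
  ## noiseless: pooling and per-replicate averaging agree
  expect_equal(pooled$fc_mean, residue_fc_table(sim$table)$fc_mean)
})

test_that("across seeds the mean recovered FC is calibrated under noise", {
  ## replicate-noise study: cv = 0.10, 3 replicates; the across-seed
  ## average FC at each planted site stays within 0.05 of the plant
  fcs <- vapply(1:60, function(s) {
    sim <- simulate_footprint(footprint_sim_config(
      n_residues = 8, sites_exposed = 3, sites_buried = 6,
      fc_exposed = 1.25, fc_buried = 0.80, noise_cv = 0.10, seed = s))
    rep <- residue_fc_table(sim$table)
    c(rep$fc_mean[rep$residue == 3], rep$fc_mean[rep$residue == 6])
  }, numeric(2))
  expect_lt(abs(mean(fcs[1, ]) - 1.25), 0.05)
  expect_lt(abs(mean(fcs[2, ]) - 0.80), 0.05)
})

test_that("peptide tables survive a TSV round trip", {
  sim <- simulate_footprint(footprint_sim_config(n_residues = 5,
                                                 sites_exposed = 2,
                                                 sites_buried = 4,
                                                 noise_cv = 0.1, seed = 51))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_table(sim$table, path)
  back <- read_peptide_table(path)
  expect_equal(back$intensity, sim$table$intensity)
  expect_equal(residue_fc_table(back), residue_fc_table(sim$table))
})
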