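test_that("Kabsch superposition recovers known rigid transforms", {
  set.seed(91)
  x <- matrix(rnorm(30, sd = 5), ncol = 3)
  ## identity
  tr <- kabsch_transform(x, x)
  expect_equal(apply_rigid_transform(x, tr), x, tolerance = 1e-10)
  ## known rotation + translation inverted to 1e-8
  for (i in 1:10) {
    rot <- random_rotation()
    shift <- rnorm(3, sd = 10)
    moved <- x %*% rot + matrix(shift, nrow(x), 3, byrow = TRUE)
    tr <- kabsch_transform(moved, x)
    expect_lt(max(abs(apply_rigid_transform(moved, tr) - x)), 1e-8)
    expect_equal(det(tr$rotation), 1, tolerance = 1e-10)
  }
  expect_error(kabsch_transform(cbind(1:5, 0, 0), cbind(1:5, 0, 0)),
               "collinear")
})

test_that("mirror images are fit with a proper rotation, never a reflection", {
  set.seed(92)
  x <- matrix(rnorm(30, sd = 5), ncol = 3)
  mirrored <- x %*% diag(c(-1, 1, 1))
  tr <- kabsch_transform(mirrored, x)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-10)
  resid <- sqrt(mean(rowSums((apply_rigid_transform(mirrored, tr) - x)^2)))
  expect_gt(resid, 0.1)   # documented residual: chirality is preserved
})

test_that("superposition agrees with the bio3d reference fit", {
  set.seed(93)
  ens <- simulate_ensemble(ensemble_sim_config(n_residues = 8, n_subunits = 2,
                                               n_snapshots = 5, sigma = 0.5,
                                               seed = 93))
  ## knock every snapshot out of frame with a random rigid move
  for (i in 1:5) {
    rot <- random_rotation()
    ens$coords[i, , ] <- ens$coords[i, , ] %*% rot +
      matrix(rnorm(3, sd = 8), dim(ens$coords)[2], 3, byrow = TRUE)
  }
  aligned <- superimpose(ens)
  for (i in 1:5) {
    ref_fit <- suppressWarnings(
      bio3d::fit.xyz(fixed = as.vector(t(ens$reference)),
                     mobile = as.vector(t(ens$coords[i, , ]))))
    expect_equal(aligned$coords[i, , ],
                 matrix(ref_fit, ncol = 3, byrow = TRUE),
                 tolerance = 1e-6)
  }
})

test_that("RMSF matches the brute-force formula and its closed-form limits", {
  ## M = 1: identically zero
  ens1 <- simulate_ensemble(ensemble_sim_config(n_residues = 4,
                                                n_snapshots = 1,
                                                sigma = 1, seed = 94))
  expect_true(all(rmsf(ens1)$rmsf == 0))
  ## zero fluctuation: identically zero
  ens0 <- simulate_ensemble(ensemble_sim_config(n_residues = 4,
                                                n_snapshots = 10,
                                                sigma = 0, seed = 94))
  expect_true(all(rmsf(ens0)$rmsf == 0))
  ## two snapshots offset +/- d on one axis at one residue: RMSF = d
  co <- array(0, c(2, 4, 3))
  co[, , 1] <- matrix(c(1, 2, 3, 4), 2, 4, byrow = TRUE)
  co[1, 2, 3] <- 1.5; co[2, 2, 3] <- -1.5
  ens <- coord_ensemble(co, residue = 1:4, subunit = rep(1, 4))
  expect_equal(rmsf(ens)$rmsf, c(0, 1.5, 0, 0))
  ## random ensembles against the double-loop oracle
  set.seed(95)
  for (i in 1:5) {
    e <- simulate_ensemble(ensemble_sim_config(
      n_residues = sample(3:6, 1), n_subunits = sample(1:4, 1),
      n_snapshots = sample(2:20, 1), sigma = runif(1, 0.1, 2),
      seed = 95 + i))
    expect_equal(rmsf(e)$rmsf, brute_force_rmsf(e), tolerance = 1e-12)
  }
})

test_that("isotropic Gaussian fluctuations converge to sigma * sqrt(3)", {
  ens <- simulate_ensemble(ensemble_sim_config(n_residues = 3, n_subunits = 4,
                                               n_snapshots = 10000,
                                               sigma = 0.8, seed = 96))
  expect_equal(rmsf(ens)$rmsf, rep(0.8 * sqrt(3), 3), tolerance = 0.02)
})

test_that("profiles are invariant to global rigid moves and subunit labels", {
  ens <- simulate_ensemble(ensemble_sim_config(n_residues = 5, n_subunits = 4,
                                               n_snapshots = 30, sigma = 0.5,
                                               seed = 97))
  base_rmsf <- rmsf(superimpose(ens))$rmsf
  ## one global rigid transform of every snapshot + reference
  set.seed(98)
  rot <- random_rotation(); shift <- rnorm(3, sd = 5)
  moved <- ens
  for (i in seq_len(dim(ens$coords)[1]))
    moved$coords[i, , ] <- ens$coords[i, , ] %*% rot +
      matrix(shift, dim(ens$coords)[2], 3, byrow = TRUE)
  moved$reference <- ens$reference %*% rot +
    matrix(shift, nrow(ens$reference), 3, byrow = TRUE)
  aligned <- superimpose(moved)
  expect_equal(rmsf(aligned)$rmsf, base_rmsf, tolerance = 1e-8)
  ## permuting subunit labels leaves the averaged profile unchanged
  perm <- ens
  perm$subunit <- c(3, 1, 4, 2)[ens$subunit]
  expect_equal(rmsf(perm)$rmsf, rmsf(ens)$rmsf)
  expect_equal(radial_rg(perm)$radial_rg, radial_rg(ens)$radial_rg)
})

test_that("fractional RMSF change flags residues beyond the 20% band", {
  prof <- rmsf(simulate_ensemble(ensemble_sim_config(
    n_residues = 6, n_snapshots = 20, sigma = 0.5, seed = 99)))
  same <- fractional_rmsf_change(prof, prof)
  expect_true(all(same$frac_change == 0))
  expect_false(any(same$significant))
  ## warm fluctuating 1.5x more than cold: fraction -0.5, significant
  warm <- prof; warm$rmsf <- prof$rmsf * 1.5
  fr <- fractional_rmsf_change(prof, warm)
  expect_equal(fr$frac_change, rep(-0.5, 6))
  expect_true(all(fr$significant))
  ## planted mixed profile against direct thresholding
  warm2 <- prof
  warm2$rmsf <- prof$rmsf * c(1.1, 1.5, 0.7, 1.0, 1.25, 0.79)
  fr2 <- fractional_rmsf_change(prof, warm2)
  expect_equal(fr2$significant,
               abs((prof$rmsf - warm2$rmsf) / prof$rmsf) > 0.2)
  ## zero cold RMSF is undefined, not significant
  z <- prof; z$rmsf[2] <- 0
  fz <- fractional_rmsf_change(z, warm)
  expect_true(fz$undefined[2] && is.na(fz$frac_change[2]) && !fz$significant[2])
})

test_that("radial Rg measures distance to the channel axis", {
  ## all atoms on the axis
  co <- array(0, c(3, 4, 3)); co[, , 3] <- 5
  on_axis <- coord_ensemble(co, residue = 1:4, subunit = rep(1, 4))
  expect_true(all(radial_rg(on_axis)$radial_rg == 0))
  ## rigid rings of radius r
  ens <- simulate_ensemble(ensemble_sim_config(n_residues = 4, sigma = 0,
                                               ring_radii = c(8, 10, 12, 14),
                                               n_snapshots = 5, seed = 101))
  expect_equal(radial_rg(ens)$radial_rg, c(8, 10, 12, 14))
  ## cold contraction: negative delta
  cold <- simulate_ensemble(ensemble_sim_config(n_residues = 4, sigma = 0.2,
                                                ring_radii = 18,
                                                n_snapshots = 50, seed = 102))
  warm <- simulate_ensemble(ensemble_sim_config(n_residues = 4, sigma = 0.2,
                                                ring_radii = 20,
                                                n_snapshots = 50, seed = 103))
  expect_true(all(delta_radial_rg(cold, warm)$delta_rg < 0))
  expect_error(coord_ensemble(co, 1:4, rep(1, 4), axis = c(0, 0, 0)),
               "axis")
})

test_that("water contacts count strictly within the cutoff", {
  ## no waters: zero with a warning
  dry <- simulate_ensemble(ensemble_sim_config(n_residues = 3,
                                               n_snapshots = 2, seed = 104))
  expect_warning(wc <- count_water_contacts(dry), "no water")
  expect_true(all(wc$n_waters == 0))
  ## planted counts recovered exactly
  wet <- simulate_ensemble(ensemble_sim_config(
    n_residues = 5, n_snapshots = 10, sigma = 0,
    water_counts = c(0, 8, 0, 3, 0), seed = 105))
  expect_equal(count_water_contacts(wet)$n_waters, c(0, 8, 0, 3, 0))
  ## a water exactly at the cutoff is excluded
  co <- array(0, c(1, 1, 3))
  at_cut <- coord_ensemble(co, residue = 1, subunit = 1,
                           waters = list(matrix(c(3.5, 0, 0, 3.4999, 0, 0),
                                                ncol = 3, byrow = TRUE)))
  expect_equal(count_water_contacts(at_cut, cutoff = 3.5)$n_waters, 1)
  ## cold gain of 8 waters shows up in the delta
  dry5 <- simulate_ensemble(ensemble_sim_config(
    n_residues = 5, n_snapshots = 10, sigma = 0,
    water_counts = rep(0L, 5), seed = 106))
  dlt <- suppressWarnings(delta_water_contacts(wet, dry5))
  expect_equal(dlt$delta_waters, c(0, 8, 0, 3, 0))
})

test_that("ensembles survive a multi-model PDB round trip", {
  ens <- simulate_ensemble(ensemble_sim_config(
    n_residues = 4, n_subunits = 2, n_snapshots = 3, sigma = 0.4,
    water_counts = c(0, 5, 0, 0), seed = 107))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, path)
  back <- read_ensemble_pdb(path)
  expect_equal(dim(back$coords), dim(ens$coords))
  expect_lt(max(abs(back$coords - ens$coords)), 1e-3)  # %.3f precision
  expect_equal(back$residue, ens$residue)
  expect_equal(back$subunit, ens$subunit)
  expect_equal(count_water_contacts(back)$n_waters,
               count_water_contacts(ens)$n_waters)
})

test_that("the combined ensemble report assembles every descriptor", {
  cold <- simulate_ensemble(ensemble_sim_config(
    n_residues = 6, n_snapshots = 30, sigma = 0.3, ring_radii = 18,
    water_counts = c(0, 0, 8, 0, 0, 0), seed = 108))
  warm <- simulate_ensemble(ensemble_sim_config(
    n_residues = 6, n_snapshots = 30, sigma = 0.6, ring_radii = 20,
    seed = 109))
  rep <- suppressWarnings(ensemble_report(cold, warm))
  expect_named(rep, c("residue", "rmsf_cold", "rmsf_warm", "frac_change",
                      "significant", "radial_rg_delta", "delta_waters"))
  expect_true(all(rep$radial_rg_delta < 0))
  expect_equal(rep$delta_waters[3], 8)
  expect_true(all(rep$frac_change < 0))   # cold quieter than warm
})
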