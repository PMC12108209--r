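test_that("generators are deterministic under a fixed seed", {
  sc <- biosensor_scene(oxd = 0.4, seed = 9)
  a <- generate_biosensor_stack(sc)
  b <- generate_biosensor_stack(sc)
  expect_identical(a$sample$channels, b$sample$channels)
  spec <- phenotype_preset_gpxl(n_per_group = 5, seed = 9)
  expect_identical(generate_phenotype_table(spec),
                   generate_phenotype_table(spec))
  # different seed changes the draw
  sc2 <- biosensor_scene(oxd = 0.4, seed = 10)
  expect_false(identical(generate_biosensor_stack(sc2)$sample$channels,
                         a$sample$channels))
})

test_that("zero-noise scenes are inverted exactly by the pipeline", {
  sc <- biosensor_scene(oxd = 0.5, photon_scale = 0, read_noise_sd = 0,
                        calib = rogfp_calibration(0.25, 2.0, 0.5, 0.5),
                        seed = 1)
  res <- measure_stack_set(generate_biosensor_stack(sc))
  expect_equal(res$oxd, 0.5, tolerance = 1e-12)
  expect_equal(res$egsh, -272, tolerance = 1e-9)
  # asymmetric calibration, arbitrary OxD
  for (oxd in c(0.0866, 0.37, 0.9)) {
    sc <- biosensor_scene(oxd = oxd, photon_scale = 0, read_noise_sd = 0,
                          seed = 1)
    res <- measure_stack_set(generate_biosensor_stack(sc))
    expect_equal(res$oxd, oxd, tolerance = 1e-10)
  }
})

test_that("zero-noise round trip survives TIFF files", {
  dir <- tempfile()
  sc <- biosensor_scene(oxd = 0.0866, photon_scale = 0, read_noise_sd = 0,
                        seed = 2)
  generate_biosensor_stack(sc, dir = dir)
  stacks <- list(sample = read_stack_tiff(file.path(dir, "sample.tif")),
                 calib_red = read_stack_tiff(file.path(dir, "calib_red.tif")),
                 calib_ox = read_stack_tiff(file.path(dir, "calib_ox.tif")))
  res <- measure_stack_set(stacks)
  expect_equal(res$oxd, 0.0866, tolerance = 1e-5)
  expect_equal(res$egsh, -302.27, tolerance = 0.01 / 302)
  truth <- read_table_csv(file.path(dir, "truth.csv"))
  expect_equal(unique(truth$oxd), 0.0866)
})

test_that("recovered OxD is nearly unbiased at the default noise level", {
  # reduced-size Monte Carlo; the acceptance suite runs the full 200 scenes
  errs <- vapply(1:25, function(s) {
    sc <- biosensor_scene(oxd = 0.37, dim = c(48L, 48L), seed = 1000 + s)
    measure_stack_set(generate_biosensor_stack(sc))$oxd - 0.37
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.02)
})

test_that("gradient and two-region OxD fields render as specified", {
  sc <- biosensor_scene(oxd = list(type = "gradient", from = 0.1, to = 0.9),
                        dim = c(10L, 20L), photon_scale = 0,
                        read_noise_sd = 0, seed = 1)
  expect_equal(dim(sc$oxd_map), c(10L, 20L))
  expect_equal(sc$oxd_map[1, 1], 0.1)
  expect_equal(sc$oxd_map[10, 20], 0.9)
  expect_true(all(diff(sc$oxd_map[5, ]) > 0))
  sc2 <- biosensor_scene(oxd = list(type = "two_region", left = 0.2,
                                    right = 0.8), dim = c(10L, 10L))
  expect_equal(unique(as.vector(sc2$oxd_map[, 1:5])), 0.2)
  expect_equal(unique(as.vector(sc2$oxd_map[, 6:10])), 0.8)
  expect_error(biosensor_scene(oxd = 1.2), "\\[0, 1\\]")
})

test_that("phenotype tables honor means, floors and the copula floor", {
  spec <- phenotype_preset_gpxl(n_per_group = 45, seed = 21)
  tab <- generate_phenotype_table(spec)
  expect_equal(nrow(tab), 9 * 5 * 45)
  expect_true(all(tab$lateral_root_count >= 0))
  expect_true(all(tab$lateral_root_count == round(tab$lateral_root_count)))
  expect_true(all(tab$primary_root_length > 0))
  # empirical group means within 3 SE of the specified means
  for (g in c("Col-0", "gpxl5")) {
    for (tr in c("control", "NaCl100")) {
      sub <- tab[tab$genotype == g & tab$treatment == tr, ]
      mu <- spec$means[[g]][[tr]]
      for (v in c("root_ros", "shoot_vitality", "primary_root_length")) {
        se <- spec$sds[[v]] / sqrt(45)
        expect_lt(abs(mean(sub[[v]]) - mu[[v]]), 3 * se)
      }
    }
  }
})

test_that("null correlation spec yields near-zero sample correlations", {
  traits <- phenotype_traits()
  means <- list(wt = list(control = stats::setNames(
    c(100, 100, 100, 100, 100, 60, 12), traits)))
  spec <- phenotype_sim_spec("wt", "control", means,
                             sds = stats::setNames(c(15, 15, 15, 15, 15,
                                                     6, 3), traits),
                             correlations = diag(7) |>
                               `dimnames<-`(list(traits, traits)),
                             n_per_group = 45, seed = 31)
  tab <- generate_phenotype_table(spec)
  r <- pearson_matrix(tab, traits = traits)
  off <- r[upper.tri(r)]
  # null sampling bounds at n = 45: each |r| below the Bonferroni-corrected
  # alpha = 0.01 critical value over the 21 pairs, and small on average
  tcrit <- qt(1 - 0.01 / (2 * 21), df = 43)
  rcrit <- tcrit / sqrt(tcrit^2 + 43)
  expect_true(all(abs(off) < rcrit))
  expect_lt(mean(abs(off)), 0.15)
})

test_that("strong specified correlations are recovered at n = 45", {
  spec <- phenotype_preset_gpxl(n_per_group = 45, seed = 8)
  tab <- generate_phenotype_table(spec)
  sub <- tab[tab$genotype == "Col-0" & tab$treatment == "control", ]
  r <- pearson_matrix(sub, traits = phenotype_traits())
  # within-group target for shoot~root vitality is 0.8125 (factor model)
  expect_gt(r["shoot_vitality", "root_vitality"], 0.7)
})

test_that("empirical correlations converge to the spec at large n", {
  spec <- phenotype_preset_gpxl(n_per_group = 1000, seed = 12)
  spec$genotypes <- "Col-0"
  spec$treatments <- "control"
  tab <- generate_phenotype_table(spec)
  r <- pearson_matrix(tab, traits = phenotype_traits())
  target <- spec$correlations[["Col-0"]]
  # count rounding perturbs the copula correlation slightly
  expect_lt(max(abs(r - target)), 0.06)
})

test_that("a non-positive-semidefinite correlation is rejected outright", {
  traits <- phenotype_traits()
  bad <- diag(7); dimnames(bad) <- list(traits, traits)
  bad[1, 2] <- bad[2, 1] <- 0.9
  bad[1, 3] <- bad[3, 1] <- 0.9
  bad[2, 3] <- bad[3, 2] <- -0.9
  means <- list(wt = list(control = stats::setNames(rep(100, 7), traits)))
  expect_error(
    phenotype_sim_spec("wt", "control", means,
                       sds = stats::setNames(rep(10, 7), traits),
                       correlations = bad, seed = 1),
    "positive semidefinite")
})
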