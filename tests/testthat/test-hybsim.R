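test_that("chip designs honour the cross-hybridization fraction and seed", {
  set.seed(301)
  chip <- make_chip(1000, xhyb_fraction = 0.1)
  expect_equal(length(unique(chip$xhyb$probe)), 100L)
  per_probe <- table(chip$xhyb$probe)
  expect_true(all(per_probe >= 1 & per_probe <= 12))

  chip0 <- make_chip(50, xhyb_fraction = 0)
  expect_equal(nrow(chip0$xhyb), 0L)

  c1 <- withr::with_seed(5, make_chip(200))
  c2 <- withr::with_seed(5, make_chip(200))
  expect_identical(c1, c2)
})

test_that("duplex thermodynamics are exergonic with weaker non-targets", {
  set.seed(302)
  chip <- make_chip(500)
  for (t_c in c(47, 52, 57)) {
    t_k <- t_c + 273.15
    dg_t <- duplex_dG(chip$genes$dH, chip$genes$dS, t_k)
    expect_true(all(dg_t < 0))
  }
  # in the binding regime (at or below the probe's melting midpoint)
  # non-target binding is strictly weaker than the probe's target binding
  p_idx <- match(chip$xhyb$probe, chip$genes$gene_id)
  for (t_k in list(rep(47 + 273.15, nrow(chip$xhyb)),
                   chip$genes$tm_k[p_idx])) {
    dg_t <- duplex_dG(chip$genes$dH[p_idx], chip$genes$dS[p_idx], t_k)
    dg_nt <- duplex_dG(chip$xhyb$dH, chip$xhyb$dS, t_k)
    expect_true(all(dg_nt > dg_t))
  }
  # binding constant decreasing in temperature (dH < 0)
  grid <- seq(315, 335, by = 0.5)
  for (i in c(1, 250, 500)) {
    k <- duplex_K(chip$genes$dH[i], chip$genes$dS[i], grid)
    expect_true(all(diff(k) < 0))
  }
})

test_that("Langmuir occupancy has the isotherm limits and monotone
           temperature response", {
  th <- list(dH = -300, dS = -0.86)
  expect_equal(duplex_occupancy(th, 0, 325), 0)
  # c K(T) = 1 at the midpoint concentration
  c_mid <- 1 / duplex_K(th$dH, th$dS, 325)
  expect_equal(duplex_occupancy(th, c_mid, 325), 0.5)
  # bounded and monotone non-increasing in T
  grid <- seq(315, 335, by = 0.25)
  theta <- duplex_occupancy(th, 1e-4, grid)
  expect_true(all(theta >= 0 & theta <= 1))
  expect_true(all(diff(theta) <= 0))
})

test_that("simulated arrays are valid, noise-free symmetric, and lose mean
           signal with temperature", {
  set.seed(303)
  chip <- make_chip(300)
  sc0 <- sample_scenario(fractions = c(Z = 1, L = 0, M = 0, H = 0),
                         noise_sd_log2 = 0, noise_int_frac = 0)
  es0 <- simulate_arrays(chip, sc0, 51)
  expect_s3_class(validate_expression_set(es0), "hyb_eset")
  # no DE, no noise: the two channels of every slide agree exactly
  m <- dye_swap_log_ratios(es0)
  expect_true(all(abs(m) < 1e-12))

  # intensities stay at or above background without noise
  expect_true(all(2^es0$values >= 50 - 1e-9))

  # mean target signal monotone non-increasing across the grid
  truth <- withr::with_seed(1, draw_chip_sample(chip, sc0))
  means <- sapply(c(47, 49, 51, 53, 55, 57), function(t_c) {
    es <- simulate_arrays(chip, sc0, t_c, sample_truth = truth)
    mean(2^es$values)
  })
  expect_true(all(diff(means) < 0))

  expect_error(sample_scenario(fractions = c(Z = 0.5, L = 0.5, M = 0.2,
                                             H = -0.2)), "fractions")
})

test_that("cross-hybridization contributes more signal at lower
           temperature", {
  set.seed(304)
  chip <- make_chip(400, xhyb_fraction = 0.25)
  chip_free <- chip; chip_free$xhyb <- chip$xhyb[0, ]
  sc <- sample_scenario(noise_sd_log2 = 0, noise_int_frac = 0)
  truth <- draw_chip_sample(chip, sc)
  contaminated <- function(t_c) {
    a <- simulate_arrays(chip, sc, t_c, sample_truth = truth)
    b <- simulate_arrays(chip_free, sc, t_c, sample_truth = truth)
    mean(2^a$values - 2^b$values)
  }
  expect_gt(contaminated(47), contaminated(57))
  expect_gt(contaminated(47), 0)
})

test_that("Gaussian group datasets plant recoverable strata", {
  set.seed(305)
  d <- gaussian_group_dataset()
  expect_equal(nrow(d$es$values), 400L)
  expect_equal(ncol(d$es$values), 12L)
  validate_expression_set(d$es)

  models <- fit_gene_models(d$es)
  dstat <- abs(models$mu1 - models$mu0) / models$sigma
  expect_gt(min(dstat[d$truth$stratum == "H"]),
            max(dstat[d$truth$stratum == "Z"]) * 0.9)
  # effect-0 genes: empirical mean difference shrinks with n_obs
  big <- gaussian_group_dataset(n_per_group = 50,
                                effect_sizes = c(Z = 0, L = 0, M = 0,
                                                 H = 0),
                                n_obs = 48)
  mb <- fit_gene_models(big$es)
  expect_lt(mean(abs(mb$mu1 - mb$mu0)), 0.2)
})

test_that("contamination offsets shift the likelihood with the documented
           signs", {
  set.seed(306)
  d <- gaussian_group_dataset()
  ll0 <- loglik_nb(d$es, fit_gene_models(d$es))

  # offset 0 is the identity
  expect_identical(apply_crosshyb_offset(d$es, d$truth, "Z", 0)$values,
                   d$es$values)

  es_z <- apply_crosshyb_offset(d$es, d$truth, "Z")
  expect_gt(loglik_nb(es_z, fit_gene_models(es_z)), ll0)

  es_all <- apply_crosshyb_offset(d$es, d$truth, c("Z", "L", "M", "H"))
  expect_lt(loglik_nb(es_all, fit_gene_models(es_all)), ll0)

  tab <- withr::with_seed(1, run_crosshyb_study())
  expect_equal(tab$loglik_rel[tab$condition == "no_xhyb"], 0)
  expect_lt(tab$loglik_rel[tab$condition == "xhyb Z+M"], 0)
  expect_equal(nrow(tab), 9L)
})

test_that("temperature study output is a per-row permutation of the grid
           and cross-hybridization penalizes low temperatures", {
  set.seed(307)
  chip <- make_chip(400)
  tab <- run_temperature_study(chip,
                               scenarios = calibration_scenarios()[c(1, 3)],
                               t_grid_c = c(47, 51, 55))
  labels <- c("47C", "51C", "55C")
  for (i in 1:2)
    expect_setequal(unlist(tab[i, paste0("rank", 1:3)]), labels)

  # removing cross-hybridization helps low temperatures the most
  set.seed(401)
  chip2 <- make_chip(1000, xhyb_fraction = 0.25)
  chip_free <- chip2; chip_free$xhyb <- chip2$xhyb[0, ]
  sc <- calibration_scenarios()[[1]]
  truth <- draw_chip_sample(chip2, sc)
  gain <- function(t_c) {
    nz <- list(mult = matrix(rnorm(1000 * 12), 1000, 12),
               add = matrix(rnorm(1000 * 12), 1000, 12))
    a <- simulate_arrays(chip2, sc, t_c, sample_truth = truth,
                         noise_z = nz)
    b <- simulate_arrays(chip_free, sc, t_c, sample_truth = truth,
                         noise_z = nz)
    loglik_nb(b, fit_gene_models(b)) - loglik_nb(a, fit_gene_models(a))
  }
  expect_gt(gain(47), gain(57))
})
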