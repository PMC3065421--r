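test_that("pooled-ML gene model fits match hand computation", {
  # group0 {1,3}, group1 {2,4}: mu0=2, mu1=3, pooled ML sigma=1
  es <- toy_es(matrix(c(1, 2, 3, 4), 1, 4))  # y = 0,1,0,1
  m <- fit_gene_models(es)
  expect_equal(m$mu0, 2); expect_equal(m$mu1, 3); expect_equal(m$sigma, 1)
  expect_equal(m$prior1, 0.5)
  expect_equal(m$w, 1)
  expect_equal(m$b, (4 - 9) / 2)  # equal priors: log-odds term drops

  # identical groups: w = 0, b = logit(prior1)
  es2 <- toy_es(matrix(c(5, 5, 7, 7), 1, 4))
  m2 <- fit_gene_models(es2)
  expect_equal(m2$w, 0)
  expect_equal(m2$b, log(m2$prior1 / (1 - m2$prior1)))

  # constant gene hits the sigma floor without error
  m3 <- fit_gene_models(toy_es(matrix(3, 2, 4)))
  expect_equal(m3$sigma, c(1e-6, 1e-6))

  expect_error(fit_gene_models(toy_es(matrix(1:4, 1, 4)),
                               subset = character(0)), "empty")
})

test_that("linear log-likelihood has the closed form and is maximal at ML", {
  # single gene, residuals all zero, sigma floored to 1 by hand model
  es <- toy_es(matrix(c(0, 1, 0, 1), 1, 4))
  models <- data.frame(gene_id = "g1", mu0 = 0, mu1 = 1, sigma = 1,
                       prior1 = 0.5, w = 1, b = -0.5)
  expect_equal(loglik_linear(es, models), 4 * log(1 / sqrt(2 * pi)))

  # additivity: appending a duplicate slide adds its own terms
  set.seed(11)
  es1 <- random_es(g = 4, n_slides = 2)
  es2 <- random_es(g = 4, n_slides = 4)
  es2$values[, 1:4] <- es1$values; es2$values[, 5:8] <- es1$values
  es2$obs$y <- rep(es1$obs$y, 2); es2$obs$dye <- rep(es1$obs$dye, 2)
  m <- fit_gene_models(es1)
  expect_equal(loglik_linear(es2, m), 2 * loglik_linear(es1, m))

  # ML property: no random perturbation of the fit scores higher
  set.seed(12)
  es <- random_es(g = 6, n_slides = 3)
  ml <- fit_gene_models(es)
  ll_ml <- loglik_linear(es, ml)
  for (i in 1:25) {
    pert <- ml
    pert$mu0 <- pert$mu0 + rnorm(6, 0, 0.3)
    pert$mu1 <- pert$mu1 + rnorm(6, 0, 0.3)
    pert$sigma <- pert$sigma * exp(rnorm(6, 0, 0.2))
    expect_lt(loglik_linear(es, pert), ll_ml)
  }
})

test_that("naive-Bayes posterior is the logistic dual of Bayes' rule", {
  # midpoint with equal priors -> exactly 1/2
  m <- data.frame(gene_id = "g", mu0 = 1, mu1 = 3, sigma = 0.7,
                  prior1 = 0.5)
  m$w <- (m$mu1 - m$mu0) / m$sigma^2
  m$b <- (m$mu0^2 - m$mu1^2) / (2 * m$sigma^2)
  expect_equal(nb_posterior(2, m), 0.5)

  # mu0=0, mu1=2, sigma=1, equal priors, x=2 -> logistic(2)
  m2 <- data.frame(gene_id = "g", mu0 = 0, mu1 = 2, sigma = 1,
                   prior1 = 0.5, w = 2, b = -2)
  expect_equal(nb_posterior(2, m2), 0.880797, tolerance = 1e-6)
  expect_equal(nb_posterior(2, m2, eps = 0),
               bayes_posterior_oracle(2, 0, 2, 1, 0.5))

  # w = 0 -> posterior equals the prior for every x
  m3 <- data.frame(gene_id = "g", mu0 = 1, mu1 = 1, sigma = 1,
                   prior1 = 0.3, w = 0, b = log(0.3 / 0.7))
  expect_equal(nb_posterior(c(-10, 0, 10), m3), rep(0.3, 3))

  # clipping bounds
  m4 <- data.frame(w = 50, b = 0)
  expect_equal(nb_posterior(10, m4), 1 - 1e-6)
  expect_equal(nb_posterior(-10, m4), 1e-6)
})

test_that("naive-Bayes log-likelihood matches its direct oracle and bounds", {
  set.seed(21)
  es <- random_es(g = 8, n_slides = 3)
  models <- fit_gene_models(es)
  ll <- loglik_nb(es, models)
  expect_lte(ll, 0)

  # direct oracle: sum of log nb_posterior over all genes and observations
  direct <- 0
  for (g in seq_len(8)) {
    p1 <- nb_posterior(es$values[g, ], models[g, ])
    py <- ifelse(es$obs$y == 1L, p1, 1 - p1)
    direct <- direct + sum(log(py))
  }
  expect_equal(ll, direct)

  # perfectly separated genes approach 0; uninformative approach N*G*ln(1/2)
  sep <- toy_es(matrix(c(0, 10, 0, 10), 2, 4, byrow = TRUE))
  expect_gt(loglik_nb(sep, fit_gene_models(sep)), 2 * 4 * log(1 - 1e-5))
  flat <- toy_es(matrix(c(5, 5, 5, 5), 2, 4, byrow = TRUE))
  expect_equal(loglik_nb(flat, fit_gene_models(flat)), 2 * 4 * log(0.5))
})

test_that("protocol scoring is deterministic and ranks noise levels", {
  set.seed(31)
  d1 <- gaussian_group_dataset(n_per_group = 15, noise_sd = 0.3)
  d2 <- gaussian_group_dataset(noise_sd = 0.6, truth = d1$truth)
  sc <- score_protocol(list(lo = d1$es, hi = d2$es), fdr_cutoff = 0.05)
  # every measure prefers the low-noise protocol
  expect_gt(sc$loglik_linear[1], sc$loglik_linear[2])
  expect_gt(sc$loglik_nb[1], sc$loglik_nb[2])
  expect_gt(sc$accuracy_pct[1], sc$accuracy_pct[2])
  expect_gt(sc$mean_auc[1], sc$mean_auc[2])
  expect_gt(sc$bitrate[1], sc$bitrate[2])
  expect_gte(sc$n_sig[1], sc$n_sig[2])

  # identical inputs give identical scores; gene-id mismatch errors
  sc2 <- score_protocol(list(a = d1$es, b = d1$es))
  expect_equal(sc2$loglik_nb[1], sc2$loglik_nb[2])
  expect_equal(sc2$bitrate[1], sc2$bitrate[2])
  es_bad <- d1$es; es_bad$gene_ids[1] <- "other"
  rownames(es_bad$values)[1] <- "other"
  expect_error(score_protocol(list(a = d1$es, b = es_bad)), "gene ids")

  # subset bookkeeping
  sub <- d1$truth$gene_id[1:20]
  sc3 <- score_protocol(list(a = d1$es), subset = sub)
  expect_match(sc3$subset, "subset_20")
})

test_that("adding pure-noise genes degrades the mean bitrate", {
  set.seed(41)
  drops <- replicate(5, {
    inf <- gaussian_group_dataset(n_per_group = 10,
                                  effect_sizes = c(Z = 1, L = 1.5, M = 2,
                                                   H = 2.5))
    noise <- gaussian_group_dataset(n_per_group = 10,
                                    effect_sizes = c(Z = 0, L = 0, M = 0,
                                                     H = 0))
    noise$es$gene_ids <- paste0("n", noise$es$gene_ids)
    rownames(noise$es$values) <- noise$es$gene_ids
    both <- inf$es
    both$gene_ids <- c(inf$es$gene_ids, noise$es$gene_ids)
    both$values <- rbind(inf$es$values, noise$es$values)
    mutual_information(cross_test(inf$es)) -
      mutual_information(cross_test(both))
  })
  expect_true(all(drops > 0))
})
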