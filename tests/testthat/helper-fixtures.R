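# Fixtures are built in code; oracles here are kept independent of the
# implementation paths they check.

# small dye-swap expression set with explicit values (genes x 4 obs,
# slides s1/s2)
toy_es <- function(values, transform = "log2") {
  expression_set(as.matrix(values),
                 slide = c("s1", "s1", "s2", "s2"),
                 dye = c("Cy3", "Cy5", "Cy5", "Cy3"),
                 y = c(0L, 1L, 0L, 1L), protocol = "51C",
                 transform = transform)
}

# four-slide variant (8 observations) for cross-testing small fixtures
toy8_es <- function(values) {
  expression_set(as.matrix(values),
                 slide = rep(c("s1", "s2", "s3", "s4"), each = 2),
                 dye = rep(c("Cy3", "Cy5", "Cy5", "Cy3"), 2),
                 y = rep(c(0L, 1L), 4), protocol = "51C")
}

# random valid dye-swap expression set
random_es <- function(g = 5, n_slides = 3) {
  design <- list(slide = rep(sprintf("s%d", seq_len(n_slides)), each = 2),
                 dye = c(rep(c("Cy3", "Cy5"), ceiling(n_slides / 2)),
                         rep(c("Cy5", "Cy3"),
                             n_slides - ceiling(n_slides / 2)))[
                               seq_len(2 * n_slides)],
                 y = rep(c(0L, 1L), n_slides))
  expression_set(matrix(rnorm(g * 2 * n_slides, 8, 2), g, 2 * n_slides),
                 slide = design$slide, dye = design$dye, y = design$y)
}

# Bayes-rule posterior from the two class-conditional Gaussians,
# computed in log space for numerical stability
bayes_posterior_oracle <- function(x, mu0, mu1, sigma, prior1) {
  l1 <- dnorm(x, mu1, sigma, log = TRUE) + log(prior1)
  l0 <- dnorm(x, mu0, sigma, log = TRUE) + log(1 - prior1)
  1 / (1 + exp(l0 - l1))
}

# literal Benjamini-Hochberg step-up: q_i = min_{j: p_(j) >= p_(i)} p_(j)*n/j
bh_stepup_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    js <- which(p[ord] >= p[i] - 1e-15)
    q[i] <- min(pmin(p[ord][js] * n / js, 1))
  }
  q
}

# two-sided Fisher p by exhaustive enumeration over tables with the
# observed margins (minimum-likelihood method)
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# hand-rolled leave-one-slide-out cross-test using the exported primitives
loo_oracle <- function(es, eps = 1e-6) {
  post <- matrix(NA_real_, nrow(es$values), ncol(es$values))
  for (s in unique(es$obs$slide)) {
    test <- which(es$obs$slide == s)
    train <- which(es$obs$slide != s)
    es_train <- es
    es_train$values <- es$values[, train, drop = FALSE]
    es_train$obs <- es$obs[train, , drop = FALSE]
    models <- fit_gene_models(es_train)
    for (g in seq_len(nrow(es$values)))
      post[g, test] <- nb_posterior(es$values[g, test], models[g, ],
                                    eps = eps)
  }
  post
}

# flip the label orientation of randomly chosen slides (the sign-flip
# label shuffle that preserves the dye-swap design)
shuffle_labels <- function(es) {
  for (s in unique(es$obs$slide))
    if (runif(1) < 0.5) {
      idx <- which(es$obs$slide == s)
      es$obs$y[idx] <- 1L - es$obs$y[idx]
    }
  es
}
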