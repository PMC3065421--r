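## Gas constant in kJ / (mol K); free energies are in kJ/mol.
R_GAS <- 0.0083144626

#' Duplex thermodynamics helpers
#'
#' A duplex is parameterized by its binding enthalpy `dH` (kJ/mol, < 0)
#' and entropy `dS` (kJ/mol/K, < 0), giving the free energy
#' `dG(T) = dH - T dS` and the equilibrium binding constant
#' `K(T) = exp(-dG / (R T))` (Boltzmann factor in molar units).  With
#' `dH < 0` the binding constant decreases monotonically in temperature.
#'
#' @param dH binding enthalpy, kJ/mol.
#' @param dS binding entropy, kJ/mol/K.
#' @param temp_k absolute temperature, kelvin.
#' @return `duplex_dG`: free energy (kJ/mol); `duplex_K`: binding constant
#'   (inverse concentration units of the simulator's dimensionless scale).
#' @export
duplex_dG <- function(dH, dS, temp_k) dH - temp_k * dS

#' @rdname duplex_dG
#' @export
duplex_K <- function(dH, dS, temp_k)
  exp(-duplex_dG(dH, dS, temp_k) / (R_GAS * temp_k))

#' Langmuir occupancy of a probe duplex
#'
#' Fraction of probe molecules bound at equilibrium for a duplex with the
#' given thermodynamics, target concentration `conc` and hybridization
#' temperature: `theta = c K(T) / (1 + c K(T))`, always in `[0, 1]`.
#'
#' @param thermo list or data frame with elements `dH` and `dS` (kJ/mol,
#'   kJ/mol/K).
#' @param conc target concentration (dimensionless simulator units), >= 0.
#' @param temp_k absolute temperature, kelvin.
#' @return Bound fraction(s) in `[0, 1]`.
#' @export
duplex_occupancy <- function(thermo, conc, temp_k) {
  stopifnot(all(conc >= 0), all(temp_k > 0))
  ck <- conc * duplex_K(thermo$dH, thermo$dS, temp_k)
  ck / (1 + ck)
}

#' Generate a random chip design
#'
#' Draws per-probe target duplex thermodynamics and a cross-hybridization
#' map.  Target enthalpies are uniform in `dH_range`; entropies are set so
#' that each probe's melting midpoint (occupancy 1/2 at the reference
#' concentration `c_ref`) falls uniformly in `tm_range_c`.  A fraction
#' `xhyb_fraction` of the probes receives 1-12 non-targets, each binding
#' more weakly than the probe's own target: enthalpy scaled towards zero
#' by `nt_dh_scale`, melting midpoint `nt_tm_offset` kelvin lower, and an
#' amplitude scale `alpha` well below 1.  Reproducible under `set.seed()`.
#'
#' @param n_genes number of probes/genes.
#' @param xhyb_fraction fraction of probes with cross-hybridization
#'   (default 0.1).
#' @param dH_range target enthalpy range, kJ/mol (default -350 to -250).
#' @param tm_range_c target melting-midpoint range, Celsius.
#' @param c_ref reference concentration defining the melting midpoint.
#' @param alpha_range cross-hybridization amplitude scale range.
#' @param nt_dh_scale multiplicative range shrinking non-target enthalpies
#'   (less negative than the target's).
#' @param nt_tm_offset range of melting-midpoint reduction for non-targets,
#'   kelvin.
#' @param nt_max maximum number of non-targets per cross-hybridizing probe.
#' @return Object of class `hyb_chip`: list with `genes` (data frame
#'   `gene_id`, `dH`, `dS`, `tm_k`), `xhyb` (data frame `probe`,
#'   `nontarget`, `dH`, `dS`, `alpha`) and `params`.
#' @export
make_chip <- function(n_genes, xhyb_fraction = 0.1,
                      dH_range = c(-350, -250), tm_range_c = c(52, 60),
                      c_ref = 1e-3, alpha_range = c(0.02, 0.2),
                      nt_dh_scale = c(0.5, 0.8), nt_tm_offset = c(3, 12),
                      nt_max = 12L) {
  stopifnot(n_genes >= 1, xhyb_fraction >= 0, xhyb_fraction <= 1)
  gene_id <- sprintf("g%05d", seq_len(n_genes))
  dH <- stats::runif(n_genes, dH_range[1L], dH_range[2L])
  tm_k <- stats::runif(n_genes, tm_range_c[1L], tm_range_c[2L]) + 273.15
  ## entropy such that c_ref * K(tm) = 1 (melting midpoint at c_ref)
  dS <- dH / tm_k - R_GAS * log(c_ref)
  genes <- data.frame(gene_id = gene_id, dH = dH, dS = dS, tm_k = tm_k,
                      stringsAsFactors = FALSE)
  n_x <- round(xhyb_fraction * n_genes)
  xhyb <- data.frame(probe = character(0), nontarget = character(0),
                     dH = numeric(0), dS = numeric(0), alpha = numeric(0),
                     stringsAsFactors = FALSE)
  if (n_x > 0L) {
    probes <- sample(gene_id, n_x)
    k <- sample.int(nt_max, n_x, replace = TRUE)
    rows <- lapply(seq_len(n_x), function(i) {
      p <- probes[i]
      nt <- sample(setdiff(gene_id, p), k[i])
      pi <- match(p, gene_id)
      dh_nt <- dH[pi] * stats::runif(k[i], nt_dh_scale[1L], nt_dh_scale[2L])
      tm_nt <- tm_k[pi] - stats::runif(k[i], nt_tm_offset[1L],
                                       nt_tm_offset[2L])
      data.frame(probe = p, nontarget = nt, dH = dh_nt,
                 dS = dh_nt / tm_nt - R_GAS * log(c_ref),
                 alpha = stats::runif(k[i], alpha_range[1L],
                                      alpha_range[2L]),
                 stringsAsFactors = FALSE)
    })
    xhyb <- do.call(rbind, rows)
  }
  structure(list(genes = genes, xhyb = xhyb,
                 params = list(xhyb_fraction = xhyb_fraction,
                               c_ref = c_ref, dH_range = dH_range,
                               tm_range_c = tm_range_c,
                               alpha_range = alpha_range)),
            class = "hyb_chip")
}

#' @export
print.hyb_chip <- function(x, ...) {
  cat(sprintf("hyb_chip: %d probes, %d cross-hybridizing (%d duplex pairs)\n",
              nrow(x$genes), length(unique(x$xhyb$probe)), nrow(x$xhyb)))
  invisible(x)
}

#' Describe a calibration sample scenario
#'
#' Bundles the composition of a simulated two-sample comparison: the
#' fractions of genes with zero/low/medium/high differential expression,
#' the direction bias among differentially expressed genes, the base
#' concentration distribution (log-normal), per-stratum fold changes, the
#' replicate count and the measurement noise.
#'
#' @param fractions named fractions for Z, L, M, H; must sum to 1.
#' @param down_fraction fraction of differentially expressed genes that are
#'   down-regulated in sample 1 (0.5 = balanced directions).
#' @param conc_meanlog,conc_sdlog log-normal parameters of the base target
#'   concentration (dimensionless units shared with [make_chip()]'s
#'   `c_ref`).
#' @param fold_changes per-stratum concentration fold changes; Z must be 1.
#' @param n_slides number of dye-swap slides simulated (even).
#' @param noise_sd_log2 multiplicative measurement noise, sd on the log2
#'   intensity scale.
#' @param noise_int_frac additive intensity noise, sd as a fraction of the
#'   background level.
#' @return Object of class `hyb_scenario`.
#' @export
sample_scenario <- function(fractions = c(Z = 0.25, L = 0.25, M = 0.25,
                                          H = 0.25),
                            down_fraction = 0.5,
                            conc_meanlog = log(3e-5), conc_sdlog = 1.5,
                            fold_changes = c(Z = 1, L = 1.5, M = 2, H = 4),
                            n_slides = 6L, noise_sd_log2 = 0.15,
                            noise_int_frac = 0.2) {
  fractions <- fractions[c("Z", "L", "M", "H")]
  if (anyNA(fractions) || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-6)
    stop("invalid scenario: fractions Z/L/M/H must be non-negative and ",
         "sum to 1", call. = FALSE)
  if (fold_changes[["Z"]] != 1)
    stop("invalid scenario: fold change of Z genes must be 1",
         call. = FALSE)
  stopifnot(down_fraction >= 0, down_fraction <= 1, n_slides %% 2 == 0)
  structure(list(fractions = fractions, down_fraction = down_fraction,
                 conc_meanlog = conc_meanlog, conc_sdlog = conc_sdlog,
                 fold_changes = fold_changes, n_slides = as.integer(n_slides),
                 noise_sd_log2 = noise_sd_log2,
                 noise_int_frac = noise_int_frac),
            class = "hyb_scenario")
}

## internal: largest-remainder rounding of proportions * n
integer_split <- function(proportions, n) {
  counts <- floor(proportions * n)
  short <- n - sum(counts)
  if (short > 0L) {
    add <- order(proportions * n - counts, decreasing = TRUE)[seq_len(short)]
    counts[add] <- counts[add] + 1L
  }
  counts
}

## internal: dye-swap observation metadata for n_slides slides
dye_swap_design <- function(n_slides, protocol) {
  h <- n_slides %/% 2L
  slide <- rep(sprintf("sl%02d", seq_len(n_slides)), each = 2L)
  y <- rep(c(0L, 1L), n_slides)
  dye <- c(rep(c("Cy3", "Cy5"), h), rep(c("Cy5", "Cy3"), n_slides - h))
  list(slide = slide, y = y, dye = dye, protocol = protocol)
}

#' Simulate a dye-swap calibration experiment on a chip
#'
#' Generates a two-sample dye-swap experiment from the Langmuir model: the
#' noise-free intensity of a probe in a channel is
#' `A theta(target, c_channel) + A sum_j alpha_j theta(nontarget_j,
#' c_j,channel) + background`, where occupancies follow
#' [duplex_occupancy()] at the requested hybridization temperature.
#' Per-gene base concentrations are drawn log-normally; differentially
#' expressed genes have one channel's concentration multiplied or divided
#' by the stratum fold change according to the scenario's direction bias.
#' Measurement noise is multiplicative (log-normal on the intensity) plus
#' a small additive component.  The result is log2-transformed into a
#' validated dye-swap [expression_set()].
#'
#' Hybridizing aliquots of the same sample at several temperatures is a
#' paired comparison, so the biological sample (stratum assignment,
#' regulation direction, concentrations) can be drawn once with
#' [draw_chip_sample()] and passed via `sample_truth`; only the
#' measurement noise then differs between temperatures.
#'
#' @param chip a [make_chip()] design.
#' @param scenario a [sample_scenario()].
#' @param t_celsius hybridization temperature, Celsius.
#' @param n_slides number of slides (default from the scenario).
#' @param amplitude full-scale intensity of a saturated probe (default
#'   1e4).
#' @param background additive background intensity (default 50).
#' @param sample_truth optional [draw_chip_sample()] result to measure; by
#'   default a fresh sample is drawn.
#' @param noise_z optional list of two genes-by-observations matrices of
#'   standard normal draws (`mult`, `add`) reused as common random numbers
#'   when the same sample is measured at several temperatures; by default
#'   fresh draws are taken.
#' @return An [expression_set()] (transform `"log2"`, protocol label
#'   `"<T>C"`) with a `truth` attribute: data frame `gene_id`, `stratum`,
#'   `direction`, `fold`, `conc0`, `conc1`.
#' @export
simulate_arrays <- function(chip, scenario, t_celsius,
                            n_slides = scenario$n_slides,
                            amplitude = 1e4, background = 50,
                            sample_truth = NULL, noise_z = NULL) {
  stopifnot(inherits(chip, "hyb_chip"), inherits(scenario, "hyb_scenario"),
            n_slides %% 2 == 0, n_slides >= 2)
  temp_k <- t_celsius + 273.15
  genes <- chip$genes
  g <- nrow(genes)
  if (is.null(sample_truth)) sample_truth <- draw_chip_sample(chip, scenario)
  stopifnot(identical(sample_truth$gene_id, genes$gene_id))
  conc0 <- sample_truth$conc0
  conc1 <- sample_truth$conc1
  theta0 <- duplex_occupancy(genes, conc0, temp_k)
  theta1 <- duplex_occupancy(genes, conc1, temp_k)
  signal0 <- amplitude * theta0
  signal1 <- amplitude * theta1
  if (nrow(chip$xhyb) > 0L) {
    x <- chip$xhyb
    nt_idx <- match(x$nontarget, genes$gene_id)
    p_idx <- match(x$probe, genes$gene_id)
    add0 <- amplitude * x$alpha * duplex_occupancy(x, conc0[nt_idx], temp_k)
    add1 <- amplitude * x$alpha * duplex_occupancy(x, conc1[nt_idx], temp_k)
    signal0 <- signal0 + unname(rowsum_into(add0, p_idx, g))
    signal1 <- signal1 + unname(rowsum_into(add1, p_idx, g))
  }
  design <- dye_swap_design(n_slides, sprintf("%gC", t_celsius))
  n_obs <- 2L * n_slides
  clean <- matrix(0, g, n_obs)
  clean[, design$y == 0L] <- signal0 + background
  clean[, design$y == 1L] <- signal1 + background
  if (is.null(noise_z))
    noise_z <- list(mult = matrix(stats::rnorm(g * n_obs), g, n_obs),
                    add = matrix(stats::rnorm(g * n_obs), g, n_obs))
  noisy <- clean * 2^(scenario$noise_sd_log2 * noise_z$mult) +
    scenario$noise_int_frac * background * noise_z$add
  noisy <- pmax(noisy, background / 100)
  es <- expression_set(log2(noisy), slide = design$slide, dye = design$dye,
                       y = design$y, protocol = design$protocol,
                       gene_ids = genes$gene_id, transform = "log2")
  attr(es, "truth") <- sample_truth
  es
}

#' Draw a biological calibration sample for a chip
#'
#' Draws the biological side of a simulated calibration experiment: each
#' gene's Z/L/M/H stratum (exact counts by largest-remainder rounding of
#' the scenario fractions), regulation direction under the scenario's
#' direction bias, log-normal base concentration, and the two channel
#' concentrations.  The same sample can then be "measured" at several
#' temperatures with [simulate_arrays()], mirroring a calibration run that
#' hybridizes aliquots of one RNA pool under every protocol.
#'
#' @param chip a [make_chip()] design.
#' @param scenario a [sample_scenario()].
#' @return Data frame `gene_id`, `stratum`, `direction`, `fold`, `conc0`,
#'   `conc1`.
#' @export
draw_chip_sample <- function(chip, scenario) {
  stopifnot(inherits(chip, "hyb_chip"), inherits(scenario, "hyb_scenario"))
  g <- nrow(chip$genes)
  counts <- integer_split(scenario$fractions, g)
  stratum <- character(g)
  stratum[sample.int(g)] <- rep(c("Z", "L", "M", "H"), counts)
  fold <- unname(scenario$fold_changes[stratum])
  direction <- integer(g)
  de <- stratum != "Z"
  direction[de] <- ifelse(stats::runif(sum(de)) < scenario$down_fraction,
                          -1L, 1L)
  conc0 <- stats::rlnorm(g, scenario$conc_meanlog, scenario$conc_sdlog)
  data.frame(gene_id = chip$genes$gene_id, stratum = stratum,
             direction = direction, fold = fold, conc0 = conc0,
             conc1 = conc0 * fold^direction, stringsAsFactors = FALSE)
}

## internal: sum values into g bins given an index vector
rowsum_into <- function(values, idx, g) {
  out <- numeric(g)
  agg <- rowsum(values, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Simulate a Gaussian Z/L/M/H group dataset
#'
#' The simple generator for contamination studies: four equally sized gene
#' groups with zero, low, medium and high differential expression.  Each
#' gene gets a random baseline log2 expression and, if differentially
#' expressed, its group's effect added to the sample-1 channel with a
#' random sign; observations carry independent Gaussian noise.  The design
#' is a balanced dye swap.
#'
#' @param n_per_group genes per stratum (default 100).
#' @param effect_sizes named effects in log2 units for Z, L, M, H (default
#'   0, 0.5, 1, 2).
#' @param noise_sd observation noise sd in log2 units (default 0.3).
#' @param n_obs number of channel-observations (default 12, i.e. 6 slides).
#' @param baseline_mean,baseline_sd distribution of per-gene baseline log2
#'   expression.
#' @param truth optionally reuse the planted truth (data frame from a
#'   previous call) so several protocols share genes, baselines, signs and
#'   strata; only the noise differs.
#' @return List with `es` (an [expression_set()]) and `truth` (data frame
#'   `gene_id`, `stratum`, `baseline`, `sign`, `effect`).
#' @export
gaussian_group_dataset <- function(n_per_group = 100L,
                                   effect_sizes = c(Z = 0, L = 0.5, M = 1,
                                                    H = 2),
                                   noise_sd = 0.3, n_obs = 12L,
                                   baseline_mean = 8, baseline_sd = 1.5,
                                   truth = NULL) {
  stopifnot(n_obs %% 2 == 0, n_obs >= 4)
  if (is.null(truth)) {
    g <- 4L * n_per_group
    stratum <- rep(c("Z", "L", "M", "H"), each = n_per_group)
    truth <- data.frame(gene_id = sprintf("g%04d", seq_len(g)),
                        stratum = stratum,
                        baseline = stats::rnorm(g, baseline_mean,
                                                baseline_sd),
                        sign = sample(c(-1, 1), g, replace = TRUE),
                        effect = unname(effect_sizes[stratum]),
                        stringsAsFactors = FALSE)
  }
  g <- nrow(truth)
  design <- dye_swap_design(n_obs %/% 2L, "sim")
  shift <- outer(truth$sign * truth$effect, as.numeric(design$y == 1L))
  values <- truth$baseline + shift + stats::rnorm(g * n_obs, 0, noise_sd)
  es <- expression_set(values, slide = design$slide, dye = design$dye,
                       y = design$y, protocol = design$protocol,
                       gene_ids = truth$gene_id, transform = "log2")
  list(es = es, truth = truth)
}

#' Add a cross-hybridization contamination offset
#'
#' Emulates cross-hybridization artefacts by adding a small constant
#' offset, for selected strata, to the lower-expressed channel of a random
#' half of the weakly expressed genes (bottom half of the stratum by
#' planted baseline).  The lower channel is determined per gene from the
#' empirical channel means, so contaminating non-differential genes
#' fabricates differential signal while contaminating differential genes
#' erodes their true signal.
#'
#' The contaminated channel is the gene's truly lower-expressed channel
#' (from the planted sign); for non-differential genes, where both
#' channels are equal in truth, a random but fixed channel is hit.  The
#' offset is constant across slides, as physical cross-hybridization from
#' a given non-target is, so it does not depend on the measurement noise.
#'
#' @param es an [expression_set()] from [gaussian_group_dataset()].
#' @param truth the matching planted-truth data frame.
#' @param groups strata to contaminate, subset of `c("Z","L","M","H")`.
#' @param offset log2 offset added (default 0.3).
#' @return The contaminated [expression_set()].
#' @export
apply_crosshyb_offset <- function(es, truth, groups, offset = 0.3) {
  stopifnot(all(groups %in% c("Z", "L", "M", "H")))
  if (offset == 0) return(es)
  y1 <- es$obs$y == 1L
  for (grp in groups) {
    idx <- which(truth$stratum == grp)
    if (length(idx) == 0L) next
    weak <- idx[order(truth$baseline[idx])][seq_len(length(idx) %/% 2L)]
    hit <- sample(weak, round(length(weak) / 2))
    planted <- truth$sign[hit] * truth$effect[hit]
    ## planted > 0 means sample 1 is truly higher, so its lower channel is
    ## y = 0; lower1 marks genes whose y = 1 channel receives the offset
    lower1 <- ifelse(planted == 0, stats::runif(length(hit)) < 0.5,
                     planted < 0)
    es$values[hit[lower1], y1] <- es$values[hit[lower1], y1] + offset
    es$values[hit[!lower1], !y1] <- es$values[hit[!lower1], !y1] + offset
  }
  es
}

#' Cross-hybridization contamination study
#'
#' Generates one Gaussian Z/L/M/H dataset and scores the naive-Bayes
#' log-likelihood under nine contamination conditions: none, each stratum
#' alone, the pairs Z+L, Z+M, Z+H, and all four strata together
#' ("unbiased" contamination).  Likelihoods are reported relative to the
#' uncontaminated baseline, whose row is 0 by construction.
#'
#' @param n_per_group,effect_sizes,noise_sd,n_obs passed to
#'   [gaussian_group_dataset()].
#' @param offset contamination offset, log2 units.
#' @return Data frame `condition`, `loglik_rel`.
#' @export
run_crosshyb_study <- function(n_per_group = 100L,
                               effect_sizes = c(Z = 0, L = 0.5, M = 1,
                                                H = 2),
                               noise_sd = 0.3, n_obs = 12L, offset = 0.3) {
  dat <- gaussian_group_dataset(n_per_group, effect_sizes, noise_sd, n_obs)
  ll0 <- loglik_nb(dat$es, fit_gene_models(dat$es))
  conditions <- list(no_xhyb = character(0), `xhyb Z` = "Z", `xhyb L` = "L",
                     `xhyb M` = "M", `xhyb H` = "H",
                     `xhyb Z+L` = c("Z", "L"), `xhyb Z+M` = c("Z", "M"),
                     `xhyb Z+H` = c("Z", "H"),
                     `xhyb unbiased` = c("Z", "L", "M", "H"))
  rel <- vapply(conditions, function(grps) {
    if (length(grps) == 0L) return(0)
    es_c <- apply_crosshyb_offset(dat$es, dat$truth, grps, offset)
    loglik_nb(es_c, fit_gene_models(es_c)) - ll0
  }, numeric(1))
  data.frame(condition = names(conditions), loglik_rel = unname(rel),
             stringsAsFactors = FALSE)
}

#' The five Z/L/M/H scenario compositions of the temperature study
#'
#' Returns the five sample compositions used in the temperature-ranking
#' study (Z/L/M/H fractions 30/20/20/30, 40/15/25/20, 45/10/30/15,
#' 50/10/30/10 and 55/10/30/5 percent), each with a 2:1 down- vs
#' up-regulation bias among differentially expressed genes (20% down, 10%
#' up in the most biased composition).
#'
#' @param ... further arguments passed to every [sample_scenario()].
#' @return List of five `hyb_scenario` objects.
#' @export
calibration_scenarios <- function(...) {
  rows <- list(c(30, 20, 20, 30), c(40, 15, 25, 20), c(45, 10, 30, 15),
               c(50, 10, 30, 10), c(55, 10, 30, 5))
  lapply(rows, function(r)
    sample_scenario(fractions = c(Z = r[1], L = r[2], M = r[3],
                                  H = r[4]) / 100,
                    down_fraction = 2 / 3, ...))
}

#' Temperature-ranking study on a simulated chip
#'
#' For each calibration-sample scenario, simulates the chip at every
#' temperature of the grid, scores each temperature by the naive-Bayes
#' log-likelihood of its experiment, and ranks the temperatures (rank 1 =
#' largest likelihood).  A consistent rank-1 temperature across scenario
#' rows demonstrates that the calibration optimum does not depend on the
#' sample composition.
#'
#' @param chip a [make_chip()] design shared by all scenarios.
#' @param scenarios list of [sample_scenario()]s (default
#'   [calibration_scenarios()]).
#' @param t_grid_c temperature grid, Celsius (>= 2 values).
#' @param ... passed to [simulate_arrays()].
#' @return Data frame with the scenario fractions and one column per rank
#'   holding the temperature label; the per-cell log-likelihoods are in
#'   attribute `loglik`.
#' @export
run_temperature_study <- function(chip, scenarios = calibration_scenarios(),
                                  t_grid_c = c(47, 49, 51, 53, 55, 57),
                                  ...) {
  stopifnot(length(t_grid_c) >= 2L)
  labels <- sprintf("%gC", t_grid_c)
  ll <- matrix(NA_real_, length(scenarios), length(t_grid_c),
               dimnames = list(NULL, labels))
  for (i in seq_along(scenarios)) {
    ## one RNA sample per scenario row, measured at every temperature
    ## with common random numbers for the measurement noise, so the
    ## within-row temperature comparison is fully paired
    sc <- scenarios[[i]]
    truth <- draw_chip_sample(chip, sc)
    n_obs <- 2L * sc$n_slides
    g <- nrow(chip$genes)
    nz <- list(mult = matrix(stats::rnorm(g * n_obs), g, n_obs),
               add = matrix(stats::rnorm(g * n_obs), g, n_obs))
    for (j in seq_along(t_grid_c)) {
      es <- simulate_arrays(chip, sc, t_grid_c[j], sample_truth = truth,
                            noise_z = nz, ...)
      ll[i, j] <- loglik_nb(es, fit_gene_models(es))
    }
  }
  ranking <- t(apply(ll, 1L, function(r) labels[order(-r)]))
  colnames(ranking) <- paste0("rank", seq_along(t_grid_c))
  fractions <- t(vapply(scenarios, function(s) s$fractions, numeric(4)))
  out <- data.frame(fractions, ranking, stringsAsFactors = FALSE,
                    check.names = FALSE)
  attr(out, "loglik") <- ll
  out
}
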