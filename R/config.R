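#' Default configuration for calibration runs
#'
#' Returns the defaults shared by the command front ends: seed,
#' normalization method, FDR cutoff, subsampling counts and simulator
#' parameters.  A YAML file read with [read_config()] overrides individual
#' entries.
#'
#' @return Named list of settings.
#' @export
hybcal_config <- function() {
  list(seed = 1L,
       normalization = "location",
       fdr_q = 0.01,
       folds = "loo",
       subsamples = 100L,
       subsample_size = NULL,
       top_share_threshold = 0.5,
       entropy_threshold = 1.5,
       sigma_floor = 1e-6,
       eps = 1e-6,
       log_floor = 1,
       simulator = list(n_genes = 2000L, xhyb_fraction = 0.1,
                        t_grid_c = c(47, 49, 51, 53, 55, 57),
                        n_slides = 6L))
}

#' Read and validate a YAML configuration
#'
#' Merges a YAML file over [hybcal_config()] defaults and validates the
#' result (FDR cutoff in (0, 1), positive counts).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Named list of settings.
#' @export
read_config <- function(path = NULL) {
  cfg <- hybcal_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  if (!is.numeric(cfg$fdr_q) || cfg$fdr_q <= 0 || cfg$fdr_q >= 1)
    stop("config error: fdr_q must lie in (0, 1)", call. = FALSE)
  counts <- c(subsamples = cfg$subsamples,
              n_genes = cfg$simulator$n_genes,
              n_slides = cfg$simulator$n_slides)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("config error: counts must be positive integers", call. = FALSE)
  cfg
}
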