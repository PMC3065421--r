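#' Stratify genes by differential-expression strength
#'
#' Assigns every gene to one of the strata Z (zero), L (low), M (medium),
#' H (high) differential expression by quartiles of the standardized mean
#' difference `d_g = |mu1 - mu0| / sigma` computed on the pooled data, so
#' one assignment serves all protocols.  Ties in `d_g` are broken by gene
#' id order, which makes the assignment deterministic.
#'
#' @param es_pooled an [expression_set()], typically the pooled data across
#'   all protocols (see [pool_protocols()]) or a reference protocol.
#' @param sigma_floor passed to [fit_gene_models()].
#' @return A data frame of class `hyb_strata`: `gene_id`, `d` (the
#'   stratification statistic) and `stratum` (ordered factor Z < L < M < H).
#' @export
stratify_genes <- function(es_pooled, sigma_floor = 1e-6) {
  validate_expression_set(es_pooled)
  if (nrow(es_pooled$values) < 4L)
    stop("at least 4 genes are required for Z/L/M/H stratification",
         call. = FALSE)
  models <- fit_gene_models(es_pooled, sigma_floor = sigma_floor)
  d <- abs(models$mu1 - models$mu0) / models$sigma
  ord <- order(d, models$gene_id)
  g <- length(d)
  stratum <- character(g)
  stratum[ord] <- c("Z", "L", "M", "H")[ceiling(seq_len(g) * 4 / g)]
  out <- data.frame(gene_id = models$gene_id, d = d,
                    stratum = factor(stratum, levels = c("Z", "L", "M", "H"),
                                     ordered = TRUE),
                    stringsAsFactors = FALSE)
  class(out) <- c("hyb_strata", "data.frame")
  out
}

#' Draw a stratified random gene subsample
#'
#' Samples genes without replacement within each Z/L/M/H stratum, with
#' per-stratum counts obtained from the requested proportions by
#' largest-remainder rounding.  Counts exceeding a stratum's size are
#' truncated to the genes available.  Reproducible given the session RNG
#' state (use `set.seed()`).
#'
#' @param strata a [stratify_genes()] result.
#' @param proportions numeric vector of length 4 (Z, L, M, H), non-negative,
#'   summing to approximately 1.
#' @param size total number of genes requested (at least 4).
#' @return Character vector of sampled gene ids.
#' @export
draw_subsample <- function(strata, proportions, size) {
  stopifnot(inherits(strata, "hyb_strata"))
  if (size < 4L) stop("subsample size must be at least 4", call. = FALSE)
  if (length(proportions) != 4L || any(proportions < 0) ||
      abs(sum(proportions) - 1) > 1e-6)
    stop("'proportions' must be 4 non-negative numbers summing to 1",
         call. = FALSE)
  counts <- floor(proportions * size)
  rem <- proportions * size - counts
  short <- size - sum(counts)
  if (short > 0L) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[add] <- counts[add] + 1L
  }
  levels4 <- c("Z", "L", "M", "H")
  out <- character(0)
  for (i in seq_len(4L)) {
    pool <- strata$gene_id[strata$stratum == levels4[i]]
    k <- min(counts[i], length(pool))
    if (k > 0L) out <- c(out, sample(pool, k))
  }
  out
}

#' Pool protocol experiments into one expression set
#'
#' Column-binds the observations of several protocol experiments sharing
#' the same gene ids; slide ids are prefixed with the protocol name so the
#' pooled design stays a valid collection of dye-swap slides.
#'
#' @param es_list named list of [expression_set()] objects with identical
#'   gene ids.
#' @return A pooled [expression_set()].
#' @export
pool_protocols <- function(es_list) {
  stopifnot(is.list(es_list), length(es_list) >= 1L)
  if (is.null(names(es_list)))
    names(es_list) <- vapply(es_list, function(e) e$obs$protocol[1L], "")
  ids <- es_list[[1L]]$gene_ids
  vals <- list(); slide <- dye <- proto <- character(0); y <- integer(0)
  for (k in names(es_list)) {
    e <- es_list[[k]]
    if (!identical(e$gene_ids, ids))
      stop("protocols do not share the same gene ids", call. = FALSE)
    vals[[k]] <- e$values
    slide <- c(slide, paste(k, e$obs$slide, sep = "."))
    dye <- c(dye, e$obs$dye)
    y <- c(y, e$obs$y)
    proto <- c(proto, e$obs$protocol)
  }
  expression_set(do.call(cbind, vals), slide = slide, dye = dye, y = y,
                 protocol = proto, gene_ids = ids,
                 transform = es_list[[1L]]$transform)
}

#' Rank protocols over stratified random gene subsamples
#'
#' The sample-independence check: for each of `S` subsamples a random
#' Z/L/M/H composition is drawn (flat Dirichlet by default), one gene
#' subset is drawn by [draw_subsample()], every protocol is scored by its
#' naive-Bayes log-likelihood on that same subset (paired comparison), and
#' the protocols are ranked (rank 1 = best, i.e. largest log-likelihood).
#' Exact score ties are broken at random.  The aggregated frequencies form
#' a doubly stochastic protocol-by-rank matrix.
#'
#' @param es_list named list of protocol [expression_set()]s with shared
#'   gene ids.
#' @param strata a [stratify_genes()] result for those genes.
#' @param S number of subsamples (default 100).
#' @param size subset size (default: a quarter of the genes).
#' @param proportion_sampler function returning a 4-vector of Z/L/M/H
#'   proportions; default draws from Dirichlet(1,1,1,1).
#' @param sigma_floor,eps numerical guards, see [fit_gene_models()].
#' @return Object of class `hyb_rankdist`: list with `freq` (protocol x
#'   rank frequency matrix), `counts`, `S`, `size`.
#' @export
rank_protocols <- function(es_list, strata, S = 100L, size = NULL,
                           proportion_sampler = NULL, sigma_floor = 1e-6,
                           eps = 1e-6) {
  stopifnot(is.list(es_list), length(es_list) >= 2L)
  if (is.null(names(es_list)))
    names(es_list) <- vapply(es_list, function(e) e$obs$protocol[1L], "")
  if (is.null(size)) size <- max(4L, nrow(strata) %/% 4L)
  if (is.null(proportion_sampler))
    proportion_sampler <- function() {
      gam <- stats::rgamma(4L, shape = 1)
      gam / sum(gam)
    }
  p <- length(es_list)
  counts <- matrix(0L, p, p, dimnames = list(names(es_list),
                                             paste0("rank", seq_len(p))))
  for (s in seq_len(S)) {
    subset <- draw_subsample(strata, proportion_sampler(), size)
    ll <- vapply(es_list, function(es) {
      es_sub <- subset_genes(es, subset)
      loglik_nb(es_sub, fit_gene_models(es_sub, sigma_floor = sigma_floor),
                eps = eps)
    }, numeric(1))
    rk <- rank(-ll, ties.method = "random")
    counts[cbind(seq_len(p), rk)] <- counts[cbind(seq_len(p), rk)] + 1L
  }
  structure(list(freq = counts / S, counts = counts, S = S, size = size),
            class = "hyb_rankdist")
}

#' @export
print.hyb_rankdist <- function(x, ...) {
  cat(sprintf("hyb_rankdist: %d protocols, %d subsamples of size %d\n",
              nrow(x$freq), x$S, x$size))
  print(round(x$freq, 3))
  invisible(x)
}

#' Recommend a protocol from a rank distribution
#'
#' Protocols whose rank-1 frequency reaches at least `top_share_threshold`
#' times the best rank-1 frequency are considered joint winners.  Among
#' them the highest hybridization temperature is recommended, to minimize
#' cross-hybridization potential.  The recommendation is flagged stable
#' when the joint winners are adjacent on the temperature-sorted protocol
#' grid given by `temperature_of`.
#'
#' @param rd a [rank_protocols()] result.
#' @param temperature_of named numeric vector mapping protocol labels to
#'   temperatures (degrees Celsius); must cover all protocols in `rd` and
#'   defines the protocol grid used for the adjacency check.
#' @param top_share_threshold fraction of the maximum rank-1 share that
#'   qualifies a protocol as joint winner (default 0.5).
#' @return List with `winner`, `stable` (logical), `winners` and
#'   `rank1_shares`.
#' @export
recommend_protocol <- function(rd, temperature_of,
                               top_share_threshold = 0.5) {
  stopifnot(inherits(rd, "hyb_rankdist"))
  r1 <- rd$freq[, 1L]
  if (all(r1 == 0)) stop("empty rank distribution", call. = FALSE)
  protos <- rownames(rd$freq)
  if (!all(protos %in% names(temperature_of)))
    stop("temperatures missing for protocol(s): ",
         paste(setdiff(protos, names(temperature_of)), collapse = ", "),
         call. = FALSE)
  winners <- protos[r1 >= top_share_threshold * max(r1)]
  winner <- winners[which.max(temperature_of[winners])]
  grid <- names(sort(temperature_of))
  pos <- sort(match(winners, grid))
  stable <- length(pos) == 1L || all(diff(pos) == 1L)
  list(winner = winner, stable = stable, winners = winners,
       rank1_shares = r1)
}

#' Diagnose an unstable protocol ranking
#'
#' Computes the Shannon entropy (bits) of the rank-1 distribution across
#' protocols.  High entropy means no protocol wins consistently, which
#' indicates that the calibration samples may be biased (e.g. strongly
#' unidirectional differential expression) and that a reliable calibration
#' cannot be based on them.
#'
#' @param rd a [rank_protocols()] result.
#' @param entropy_threshold flag threshold in bits (default 1.5).
#' @return List with `entropy_bits`, `flagged` and `message`.
#' @export
diagnose_instability <- function(rd, entropy_threshold = 1.5) {
  stopifnot(inherits(rd, "hyb_rankdist"))
  p <- rd$freq[, 1L]
  p <- p[p > 0]
  h <- max(0, -sum(p * log2(p)))
  flagged <- h > entropy_threshold
  msg <- if (flagged)
    paste0("rank-1 entropy ", sprintf("%.2f", h), " bits exceeds ",
           entropy_threshold, ": no protocol wins consistently; the ",
           "calibration samples may be biased (e.g. strongly ",
           "unidirectional differential expression)")
  else
    paste0("rank-1 entropy ", sprintf("%.2f", h),
           " bits: ranking is consistent")
  list(entropy_bits = h, flagged = flagged, message = msg)
}

#' Write a rank distribution as TSV
#'
#' @param rd a [rank_protocols()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rank_distribution <- function(rd, path) {
  tab <- data.frame(protocol = rownames(rd$freq), rd$freq,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
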