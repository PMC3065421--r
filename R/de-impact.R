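#' Orientation-corrected dye-swap log ratios
#'
#' For every slide, the difference between its two channel-observations on
#' the log scale, oriented so that positive values mean higher expression
#' in sample 1 regardless of which dye carried which sample:
#' `m_{g,slide} = x(y = 1 channel) - x(y = 0 channel)`.
#'
#' @param es a valid dye-swap [expression_set()] on the log2 scale.
#' @return Matrix, genes by slides, of corrected log ratios.
#' @export
dye_swap_log_ratios <- function(es) {
  validate_expression_set(es)
  slides <- unique(es$obs$slide)
  m <- vapply(slides, function(s) {
    idx <- which(es$obs$slide == s)
    i1 <- idx[es$obs$y[idx] == 1L]
    i0 <- idx[es$obs$y[idx] == 0L]
    if (length(i1) != 1L || length(i0) != 1L)
      stop("slide ", s, " is missing a channel", call. = FALSE)
    es$values[, i1] - es$values[, i0]
  }, numeric(nrow(es$values)))
  m <- matrix(m, nrow = nrow(es$values),
              dimnames = list(es$gene_ids, slides))
  m
}

#' Per-gene differential-expression test on dye-swap ratios
#'
#' One-sample two-sided t test of the mean corrected log ratio against
#' zero, per gene, with `slides - 1` degrees of freedom -- the exact
#' reduction of a balanced two-channel dye-swap ANOVA with slide as block.
#' Raw p-values are converted to Benjamini-Hochberg false discovery rates.
#' Zero-variance genes use the degenerate rule: p = 0 when the mean ratio
#' is non-zero (infinite t), p = 1 when all ratios are exactly zero.
#'
#' @param ratios a [dye_swap_log_ratios()] matrix with at least 2 columns.
#' @return Data frame of class `hyb_de`: `gene_id`, `logFC` (mean log2
#'   ratio), `t`, `p`, `q`.
#' @export
de_test <- function(ratios) {
  ratios <- as.matrix(ratios)
  n <- ncol(ratios)
  if (n < 2L) stop("at least 2 slides are required", call. = FALSE)
  m <- rowMeans(ratios)
  s <- sqrt(rowSums((ratios - m)^2) / (n - 1))
  t_stat <- ifelse(s > 0, m / (s / sqrt(n)),
                   ifelse(m != 0, Inf * sign(m), 0))
  p <- ifelse(s > 0, 2 * stats::pt(-abs(t_stat), df = n - 1),
              ifelse(m != 0, 0, 1))
  out <- data.frame(gene_id = rownames(ratios), logFC = m, t = t_stat,
                    p = p, q = bh_fdr(p), stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("hyb_de", "data.frame")
  out
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjusted p-values `q_i = min_{j: p_(j) >= p_(i)} p_(j) n / j`,
#' capped at 1 and mapped back to the input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in the input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE) || anyNA(pvals))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Count significant genes at an FDR cutoff
#'
#' Number of genes with BH q-value strictly below the cutoff (`q < cutoff`).
#'
#' @param de a [de_test()] result.
#' @param cutoff FDR cutoff (default 0.01).
#' @return Integer count.
#' @export
count_significant <- function(de, cutoff = 0.01) {
  stopifnot(inherits(de, "hyb_de"))
  sum(de$q < cutoff)
}

#' Compare detection between an optimal and a suboptimal protocol
#'
#' Splits the genes significant under the optimal protocol into those
#' retained (also significant under the suboptimal protocol) and those
#' lost, separates the lost genes by the sign of their fold change, and
#' summarizes the absolute log2 fold changes of the retained and lost sets
#' (five-number summaries, the box-plot data of a sensitivity-loss
#' analysis).
#'
#' @param de_opt,de_sub [de_test()] results on the same gene universe.
#' @param cutoff FDR cutoff defining significance (default 0.01).
#' @return List with `lost`, `retained`, `lost_up`, `lost_down` (gene id
#'   vectors) and `summary` (data frame of five-number summaries of
#'   `|logFC|`, fold changes taken from the optimal protocol).
#' @export
compare_protocol_de <- function(de_opt, de_sub, cutoff = 0.01) {
  stopifnot(inherits(de_opt, "hyb_de"), inherits(de_sub, "hyb_de"))
  if (!identical(de_opt$gene_id, de_sub$gene_id))
    stop("gene universes differ between the two results", call. = FALSE)
  sig_opt <- de_opt$gene_id[de_opt$q < cutoff]
  sig_sub <- de_sub$gene_id[de_sub$q < cutoff]
  lost <- setdiff(sig_opt, sig_sub)
  retained <- intersect(sig_opt, sig_sub)
  fc <- stats::setNames(de_opt$logFC, de_opt$gene_id)
  lost_up <- lost[fc[lost] > 0]
  lost_down <- lost[fc[lost] < 0]
  five <- function(ids) {
    if (length(ids) == 0L) return(rep(NA_real_, 5L))
    stats::fivenum(abs(fc[ids]))
  }
  summary <- data.frame(set = c("retained", "lost"),
                        n = c(length(retained), length(lost)),
                        rbind(five(retained), five(lost)))
  names(summary)[3:7] <- c("min", "q1", "median", "q3", "max")
  list(lost = lost, retained = retained, lost_up = lost_up,
       lost_down = lost_down, summary = summary)
}

#' Fisher's exact test for category enrichment
#'
#' Two-sided exact test of association in a 2x2 contingency table
#' (category membership by detection status), using the conventional
#' minimum-likelihood definition of the two-sided p-value (sum of
#' hypergeometric probabilities of all tables no more likely than the
#' observed one).  The reported odds ratio is the sample odds ratio
#' `(a d) / (b c)` (infinite when `b c = 0` with `a d > 0`).
#'
#' @param tab 2x2 matrix (or object coercible to one) of non-negative
#'   counts.
#' @return List with `p_value` and `odds_ratio`.
#' @export
fisher_enrichment <- function(tab) {
  tab <- matrix(as.numeric(tab), 2L, 2L)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(tab) == 0) stop("all-zero contingency table", call. = FALSE)
  p <- stats::fisher.test(tab)$p.value
  num <- tab[1, 1] * tab[2, 2]
  den <- tab[1, 2] * tab[2, 1]
  or <- if (den == 0) {
    if (num == 0) NaN else Inf
  } else num / den
  list(p_value = p, odds_ratio = or)
}

#' Write differential-expression results as TSV
#'
#' @param de a [de_test()] result.
#' @param path output path.
#' @param cutoff FDR cutoff for the `significant` column.
#' @return `path`, invisibly.
#' @export
write_de_results <- function(de, path, cutoff = 0.01) {
  out <- de
  out$significant <- de$q < cutoff
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
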