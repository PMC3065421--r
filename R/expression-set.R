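#' Two-colour calibration expression set
#'
#' Container for a two-channel microarray calibration experiment: a
#' genes-by-observations matrix of intensities together with per-observation
#' metadata (slide, dye, biological sample label, protocol label).  Every
#' slide carries exactly two channel-observations with opposite dyes and
#' opposite sample labels (dye-swap design), so the design is balanced by
#' construction.
#'
#' @param values numeric matrix, genes in rows, channel-observations in
#'   columns.  Row names (if present) are used as gene ids.
#' @param slide character vector of slide ids, one per column of `values`.
#' @param dye character vector, `"Cy3"` or `"Cy5"`, one per column.
#' @param y integer vector of biological sample labels (0 or 1), one per
#'   column.
#' @param protocol protocol label (e.g. `"51C"`); scalar or one per column.
#' @param gene_ids character vector of gene identifiers; defaults to the
#'   row names of `values`.
#' @param transform one of `"raw"`, `"log2"`, `"normalized"`; records the
#'   scale the values are on.
#' @return An object of class `hyb_eset`: a list with elements `gene_ids`,
#'   `values`, `obs` (data frame with columns `slide`, `dye`, `y`,
#'   `protocol`) and `transform`.
#' @examples
#' x <- matrix(rnorm(8), 2, 4,
#'             dimnames = list(c("g1", "g2"), NULL))
#' es <- expression_set(x, slide = c("s1", "s1", "s2", "s2"),
#'                      dye = c("Cy3", "Cy5", "Cy5", "Cy3"),
#'                      y = c(0, 1, 0, 1), protocol = "51C")
#' es
#' @export
expression_set <- function(values, slide, dye, y, protocol = "P1",
                           gene_ids = rownames(values),
                           transform = c("log2", "raw", "normalized")) {
  transform <- match.arg(transform)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids))
    gene_ids <- paste0("g", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids)
  n <- ncol(values)
  if (length(protocol) == 1L) protocol <- rep(protocol, n)
  obs <- data.frame(slide = as.character(slide),
                    dye = as.character(dye),
                    y = as.integer(y),
                    protocol = as.character(protocol),
                    stringsAsFactors = FALSE)
  rownames(values) <- gene_ids
  colnames(values) <- paste(obs$slide, obs$dye, sep = ".")
  es <- structure(list(gene_ids = gene_ids, values = values, obs = obs,
                       transform = transform),
                  class = "hyb_eset")
  validate_expression_set(es)
}

#' Validate a two-colour expression set
#'
#' Checks the dye-swap design invariants: no missing values, at least four
#' observations, every slide present with exactly two observations carrying
#' opposite dyes and opposite sample labels, and a balanced label design.
#'
#' @param es a [expression_set()] object.
#' @return `es`, invisibly unchanged, if valid; otherwise an error listing
#'   the offending slides.
#' @export
validate_expression_set <- function(es) {
  if (!inherits(es, "hyb_eset"))
    stop("not a 'hyb_eset' object", call. = FALSE)
  v <- es$values
  if (!is.matrix(v) || !is.numeric(v))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (anyNA(v) || any(!is.finite(v)))
    stop("'values' contains missing or non-finite entries", call. = FALSE)
  if (nrow(v) < 1L)
    stop("at least one gene is required", call. = FALSE)
  if (ncol(v) < 4L)
    stop("at least 4 channel-observations (2 slides) are required",
         call. = FALSE)
  if (length(es$gene_ids) != nrow(v))
    stop("gene_ids length does not match the number of rows", call. = FALSE)
  if (anyDuplicated(es$gene_ids))
    stop("gene ids must be unique", call. = FALSE)
  obs <- es$obs
  if (nrow(obs) != ncol(v))
    stop("observation metadata does not match the number of columns",
         call. = FALSE)
  if (!all(obs$dye %in% c("Cy3", "Cy5")))
    stop("dye must be 'Cy3' or 'Cy5'", call. = FALSE)
  if (!all(obs$y %in% c(0L, 1L)))
    stop("sample label y must be 0 or 1", call. = FALSE)
  bad <- vapply(split(seq_len(nrow(obs)), obs$slide), function(idx) {
    length(idx) != 2L ||
      !setequal(obs$dye[idx], c("Cy3", "Cy5")) ||
      !setequal(obs$y[idx], c(0L, 1L))
  }, logical(1))
  if (any(bad))
    stop("invalid dye-swap design for slide(s): ",
         paste(names(bad)[bad], collapse = ", "),
         " (each slide needs exactly two observations with opposite dyes ",
         "and opposite sample labels)", call. = FALSE)
  if (sum(obs$y == 0L) != sum(obs$y == 1L))
    stop("design is not balanced in the sample labels", call. = FALSE)
  invisible(es)
}

#' @export
print.hyb_eset <- function(x, ...) {
  cat(sprintf("hyb_eset: %d genes x %d channel-observations (%d slides)\n",
              nrow(x$values), ncol(x$values), length(unique(x$obs$slide))))
  cat(sprintf("  transform: %s; protocol(s): %s\n", x$transform,
              paste(unique(x$obs$protocol), collapse = ", ")))
  invisible(x)
}

#' @export
dim.hyb_eset <- function(x) dim(x$values)

## internal: subset genes, keeping metadata
subset_genes <- function(es, ids) {
  idx <- match(ids, es$gene_ids)
  if (anyNA(idx))
    stop("unknown gene id(s): ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  es$gene_ids <- es$gene_ids[idx]
  es$values <- es$values[idx, , drop = FALSE]
  es
}

## internal: subset observations (whole slides only keeps the design valid)
subset_obs <- function(es, idx) {
  es$values <- es$values[, idx, drop = FALSE]
  es$obs <- es$obs[idx, , drop = FALSE]
  rownames(es$obs) <- NULL
  es
}

#' Read a calibration expression table
#'
#' Reads the package's tab-separated expression format: comment-prefixed
#' metadata lines (`#transform`, `#slide`, `#dye`, `#sample`, optionally
#' `#protocol`) describing each observation column, followed by a header
#' line and one row per gene with the gene id in the first column.
#'
#' @param path path to a TSV file written by [write_expression_table()] (or
#'   assembled by hand in the same dialect).
#' @return A validated [expression_set()].
#' @export
read_expression_table <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta_lines <- lines[is_meta]
  keys <- sub("^#([^\t]+)\t?.*$", "\\1", meta_lines)
  meta <- lapply(strsplit(meta_lines, "\t", fixed = TRUE), `[`, -1L)
  names(meta) <- keys
  need <- c("slide", "dye", "sample")
  missing <- setdiff(need, keys)
  if (length(missing) > 0L)
    stop("expression table format error: missing metadata line(s): ",
         paste0("#", missing, collapse = ", "), call. = FALSE)
  body <- lines[!is_meta]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1L]])
  values <- as.matrix(tab[, -1L, drop = FALSE])
  transform <- if ("transform" %in% keys) meta$transform[1L] else "log2"
  protocol <- if ("protocol" %in% keys) meta$protocol else "P1"
  expression_set(values, slide = meta$slide, dye = meta$dye,
                 y = as.integer(meta$sample), protocol = protocol,
                 gene_ids = gene_ids, transform = transform)
}

#' Write a calibration expression table
#'
#' Inverse of [read_expression_table()].  Columns are emitted in a
#' deterministic order (slide, then dye), so repeated writes of the same
#' data are byte-identical and write/read round trips preserve values and
#' metadata exactly.
#'
#' @param es a valid [expression_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(es, path) {
  validate_expression_set(es)
  ord <- order(es$obs$slide, es$obs$dye)
  es <- subset_obs(es, ord)
  con <- file(path, open = "wt")
  on.exit(close(con))
  meta <- c(paste(c("#transform", es$transform), collapse = "\t"),
            paste(c("#slide", es$obs$slide), collapse = "\t"),
            paste(c("#dye", es$obs$dye), collapse = "\t"),
            paste(c("#sample", es$obs$y), collapse = "\t"),
            paste(c("#protocol", es$obs$protocol), collapse = "\t"))
  writeLines(meta, con)
  header <- paste(c("gene_id", colnames(es$values)), collapse = "\t")
  writeLines(header, con)
  rows <- apply(es$values, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(es$gene_ids, rows, sep = "\t"), con)
  invisible(path)
}

#' Normalize per-observation expression columns
#'
#' The normalization variants considered for calibration data: none,
#' location removal (subtract each observation column's mean of the log
#' signal), or location and scale removal (additionally divide by the
#' column standard deviation, population form with denominator n).  Raw
#' intensities are first clipped below at `log_floor` and log2-transformed.
#'
#' @param es an [expression_set()].
#' @param method `"none"`, `"location"` or `"location_scale"`.
#' @param log_floor floor applied to raw intensities before log2 (default 1).
#' @return A new `hyb_eset` on the log2 scale; for the location methods the
#'   transform flag is set to `"normalized"`.
#' @export
normalize_expression <- function(es,
                                 method = c("none", "location",
                                            "location_scale"),
                                 log_floor = 1) {
  method <- match.arg(method)
  validate_expression_set(es)
  v <- es$values
  if (es$transform == "raw") {
    v <- log2(pmax(v, log_floor))
    es$transform <- "log2"
  }
  if (method != "none") {
    v <- sweep(v, 2L, colMeans(v), "-")
    if (method == "location_scale") {
      sds <- sqrt(colMeans(v^2))  # population sd, mean already removed
      if (any(sds == 0))
        stop("zero variance in column(s): ",
             paste(colnames(es$values)[sds == 0], collapse = ", "),
             call. = FALSE)
      v <- sweep(v, 2L, sds, "/")
    }
    es$transform <- "normalized"
  }
  dimnames(v) <- dimnames(es$values)
  es$values <- v
  es
}

#' Read a gene annotation table
#'
#' Reads a tab-separated table whose first column holds gene ids and whose
#' remaining column(s) hold binary category flags (e.g. a
#' transcription-factor indicator).  Duplicate rows with identical flags are
#' deduplicated; duplicate gene ids with conflicting flags are an error.
#' The annotation may cover genes absent from an expression set (superset
#' annotations are allowed).
#'
#' @param path path to the TSV file (with a header line).
#' @return A data frame with a `gene_id` column and logical flag columns.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(tab) < 2L)
    stop("annotation table needs a gene id column and at least one flag",
         call. = FALSE)
  names(tab)[1L] <- "gene_id"
  tab$gene_id <- as.character(tab$gene_id)
  for (j in seq(2L, ncol(tab)))
    tab[[j]] <- as.logical(as.integer(tab[[j]]))
  tab <- unique(tab)
  dup <- duplicated(tab$gene_id)
  if (any(dup))
    stop("conflicting annotation for gene id(s): ",
         paste(unique(tab$gene_id[dup]), collapse = ", "), call. = FALSE)
  rownames(tab) <- NULL
  tab
}
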