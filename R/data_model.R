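#' Labeled expression dataset
#'
#' Container for a genes-by-samples expression matrix with per-sample class
#' labels. Gene order is a contract throughout the package: downstream
#' objects (rankings, mutual-information matrices) identify rows by position
#' in `gene_ids` and readers never reorder genes.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of unique gene identifiers (row order).
#' @param sample_ids character vector of unique sample identifiers (column
#'   order).
#' @param labels per-sample class labels, one per sample, aligned with
#'   `sample_ids`.
#' @return An object of class `LabeledExpressionDataset`: a list with
#'   elements `values`, `gene_ids`, `sample_ids` and `labels` (a factor
#'   named by sample).
#' @export
labeled_expression_dataset <- function(values, gene_ids, sample_ids, labels) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids))
    stop("row count (", nrow(values), ") does not match number of gene ids (",
         length(gene_ids), ")")
  if (ncol(values) != length(sample_ids))
    stop("column count (", ncol(values), ") does not match number of sample ids (",
         length(sample_ids), ")")
  if (length(labels) != length(sample_ids))
    stop("need one label per sample: got ", length(labels), " labels for ",
         length(sample_ids), " samples")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicated gene id(s): ", paste(dup, collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicated sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyNA(values))
    stop("expression matrix contains missing values; impute or filter before loading")
  dimnames(values) <- list(gene_ids, sample_ids)
  labels <- stats::setNames(factor(as.character(labels)), sample_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, labels = labels),
            class = "LabeledExpressionDataset")
}

#' @export
print.LabeledExpressionDataset <- function(x, ...) {
  cat("LabeledExpressionDataset: ", length(x$gene_ids), " genes x ",
      length(x$sample_ids), " samples\n", sep = "")
  cat("classes:", paste(sprintf("%s(%d)", levels(x$labels),
                                tabulate(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression matrix and its sample labels
#'
#' The expression file is delimited text with sample ids in the first row and
#' gene ids in the first column. The labels file has two columns
#' (sample id, class) and no header. Labels are aligned to samples by id, not
#' by file order; every sample in the expression header must have a label.
#'
#' @param expr_path path to the expression table.
#' @param labels_path path to the two-column label table.
#' @param sep field separator; default guesses `","` for `.csv`, tab
#'   otherwise.
#' @return A [labeled_expression_dataset()].
#' @export
read_dataset <- function(expr_path, labels_path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", expr_path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(expr_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "\"")
  if (ncol(tab) < 2) stop("expression file needs a gene-id column plus >=1 sample")
  gene_ids <- as.character(tab[[1]])
  sample_ids <- colnames(tab)[-1]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicated gene id(s) in ", expr_path, ": ", paste(dup, collapse = ", "))
  vals <- matrix(NA_real_, length(gene_ids), length(sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- tab[[j + 1L]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop("non-numeric value at gene '", gene_ids[bad[1]],
             "', sample '", sample_ids[j], "'")
      col <- num
    }
    vals[, j] <- col
  }
  lab <- utils::read.table(labels_path, header = FALSE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "\"",
                           col.names = c("sample_id", "class"))
  lab_map <- stats::setNames(as.character(lab$class), as.character(lab$sample_id))
  missing <- setdiff(sample_ids, names(lab_map))
  if (length(missing))
    stop("no label for sample(s): ", paste(missing, collapse = ", "))
  labeled_expression_dataset(vals, gene_ids, sample_ids, lab_map[sample_ids])
}

#' Restrict a dataset to a subset of genes and/or samples
#'
#' Order follows the `genes`/`samples` arguments, so callers control row and
#' column order explicitly.
#'
#' @param data a `LabeledExpressionDataset`.
#' @param genes,samples identifiers to keep (`NULL` keeps all, in current
#'   order).
#' @return A `LabeledExpressionDataset` view.
#' @export
restrict_dataset <- function(data, genes = NULL, samples = NULL) {
  genes <- genes %||% data$gene_ids
  samples <- samples %||% data$sample_ids
  missg <- setdiff(genes, data$gene_ids)
  if (length(missg)) stop("unknown gene(s): ", paste(missg, collapse = ", "))
  misss <- setdiff(samples, data$sample_ids)
  if (length(misss)) stop("unknown sample(s): ", paste(misss, collapse = ", "))
  labeled_expression_dataset(data$values[genes, samples, drop = FALSE],
                             genes, samples,
                             as.character(data$labels[samples]))
}

#' Ordered gene list
#'
#' @param gene_ids character vector, unique, order meaningful.
#' @param provenance free-text note on which step produced the list.
#' @return An object of class `GeneList`.
#' @export
gene_list <- function(gene_ids, provenance = "") {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids))
    stop("gene list contains duplicates: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  structure(list(gene_ids = gene_ids, provenance = provenance),
            class = "GeneList")
}

#' @export
print.GeneList <- function(x, ...) {
  cat("GeneList (", length(x$gene_ids), " genes)",
      if (nzchar(x$provenance)) paste0(" [", x$provenance, "]"), "\n", sep = "")
  utils::head(x$gene_ids, 10) |> paste(collapse = ", ") |> cat("\n")
  invisible(x)
}

#' @rdname gene_list
#' @param path file with one gene id per line.
#' @export
read_gene_list <- function(path, provenance = path) {
  ids <- readLines(path)
  gene_list(ids[nzchar(ids)], provenance)
}

#' @rdname gene_list
#' @param x a `GeneList`.
#' @export
write_gene_list <- function(x, path) {
  writeLines(x$gene_ids, path)
  invisible(path)
}

#' Union of gene lists with duplicates removed
#'
#' Used by the hierarchical driver to merge per-step selections; order of
#' first appearance is preserved and the number of duplicates removed is
#' recorded.
#'
#' @param lists a list of `GeneList` objects or character vectors.
#' @param provenance note for the merged list.
#' @return A `GeneList` with attribute `n_duplicates` (entries removed) and
#'   `raw_sum` (sum of input lengths).
#' @export
union_gene_lists <- function(lists, provenance = "union") {
  ids <- unlist(lapply(lists, function(l)
    if (inherits(l, "GeneList")) l$gene_ids else as.character(l)),
    use.names = FALSE)
  uni <- unique(ids)
  out <- gene_list(uni, provenance)
  attr(out, "raw_sum") <- length(ids)
  attr(out, "n_duplicates") <- length(ids) - length(uni)
  out
}

#' Write a selection report
#'
#' Writes the selected genes one id per line to `path` and a machine-readable
#' JSON sidecar (`<path>.json`) holding the chosen subset-index `p*`, the
#' averaged validation-accuracy curve, the baseline and test accuracies, the
#' master seed and a fingerprint of the configuration.
#'
#' @param result a `SelectionResult` from [run_amfes()].
#' @param path output path for the gene-list file.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(result, path) {
  stopifnot(inherits(result, "SelectionResult"))
  write_gene_list(result$selected_genes, path)
  sidecar <- list(
    p_star = result$p_star,
    k_star = result$k_star,
    fallback = result$fallback,
    n_selected = length(result$selected_genes$gene_ids),
    v_baseline = result$v_baseline,
    test_accuracy = result$test_accuracy,
    av_curve = result$av_curve,
    seed = result$seed,
    config_hash = config_hash(result$config)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Mutual-information matrix container
#'
#' @param values square numeric matrix of pairwise mutual-information
#'   estimates (nats), symmetric within `1e-10`.
#' @param gene_ids identifiers for rows/columns, in matrix order.
#' @param bandwidth_h positive kernel bandwidth used for the estimates.
#' @param condition_label free-text condition (e.g. the class the samples
#'   were restricted to).
#' @return An object of class `MIMatrix`.
#' @export
mi_matrix_new <- function(values, gene_ids, bandwidth_h, condition_label = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != ncol(values))
    stop("MI matrix must be square, got ", nrow(values), "x", ncol(values))
  if (nrow(values) != length(gene_ids))
    stop("matrix dimension (", nrow(values), ") != number of gene ids (",
         length(gene_ids), ")")
  if (max(abs(values - t(values))) > 1e-10)
    stop("MI matrix is not symmetric within 1e-10")
  if (!is.numeric(bandwidth_h) || bandwidth_h <= 0)
    stop("bandwidth_h must be a positive number")
  dimnames(values) <- list(gene_ids, gene_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 bandwidth_h = as.numeric(bandwidth_h),
                 condition_label = as.character(condition_label)),
            class = "MIMatrix")
}

#' @export
print.MIMatrix <- function(x, ...) {
  cat("MIMatrix: ", length(x$gene_ids), "x", length(x$gene_ids),
      " genes, h = ", format(x$bandwidth_h), sep = "")
  if (nzchar(x$condition_label)) cat(", condition:", x$condition_label)
  cat("\n")
  invisible(x)
}

#' Write / read an MI matrix as labeled CSV
#'
#' The file carries the bandwidth and condition label as `#`-prefixed header
#' comments, then a square CSV with gene ids as header and first column.
#' A write/read round trip preserves gene order and values to at least 12
#' significant digits.
#'
#' @param m an `MIMatrix`.
#' @param path output/input path.
#' @return `write_mi_matrix`: `path` invisibly; `read_mi_matrix`: an
#'   `MIMatrix`.
#' @export
write_mi_matrix <- function(m, path) {
  stopifnot(inherits(m, "MIMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# bandwidth_h ", sprintf("%.17g", m$bandwidth_h)),
               paste0("# condition_label ", m$condition_label)), con)
  writeLines(paste(c("gene_id", m$gene_ids), collapse = ","), con)
  for (i in seq_along(m$gene_ids)) {
    writeLines(paste(c(m$gene_ids[i], sprintf("%.17g", m$values[i, ])),
                     collapse = ","), con)
  }
  invisible(path)
}

#' @rdname write_mi_matrix
#' @export
read_mi_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  h <- NA_real_
  cond <- ""
  bh <- grep("^# bandwidth_h ", hdr, value = TRUE)
  if (length(bh)) h <- as.numeric(sub("^# bandwidth_h ", "", bh[1]))
  cl <- grep("^# condition_label", hdr, value = TRUE)
  if (length(cl)) cond <- sub("^# condition_label ?", "", cl[1])
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.csv(text = body, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (nrow(vals) != ncol(vals))
    stop("MI matrix file is not square: ", nrow(vals), " rows x ",
         ncol(vals), " value columns")
  if (!identical(gene_ids, colnames(vals)))
    stop("row labels do not match column header in ", path)
  if (is.na(h)) h <- 1  # legacy file without bandwidth header
  mi_matrix_new(vals, gene_ids, h, cond)
}

#' Write MI summary statistics as TSV
#'
#' Columns follow the condition-contrast table layout: mean, std,
#' n_positive, n_negative, n_sign_diff, min, max.
#'
#' @param stats a single `MIStatsRow` or a named list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mi_stats <- function(stats, path) {
  if (inherits(stats, "MIStatsRow")) stats <- list(stats)
  rows <- lapply(stats, function(s) {
    data.frame(mean = s$mean, std = s$std, n_positive = s$n_positive,
               n_negative = s$n_negative,
               n_sign_diff = if (is.na(s$n_sign_diff)) NA_integer_ else s$n_sign_diff,
               min = s$min, max = s$max)
  })
  df <- do.call(rbind, rows)
  if (!is.null(names(stats))) df <- cbind(condition = names(stats), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
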