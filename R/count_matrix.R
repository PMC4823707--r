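#' Count matrix with sample group labels
#'
#' The universal input container: a genes-by-samples matrix of non-negative
#' values (integer read counts or reads-per-million) together with a group
#' label for every sample. All downstream operations — noise diagnostics,
#' goodness-of-fit scans, differential-expression tests — read the design
#' from the object itself, so the whole analysis agrees on one grouping.
#'
#' @param values numeric matrix, genes in rows and samples in columns, with
#'   unique rownames (gene IDs) and colnames (sample IDs). All values must
#'   be non-negative and finite.
#' @param groups group assignment for the samples: either a character/factor
#'   vector of length `ncol(values)` (optionally named by sample ID), or
#'   `NULL` to place every sample in a single group `"all"`. At most two
#'   distinct groups are supported by the testing operations.
#'
#' @return An object of class `count_matrix`: a list with elements `values`
#'   (the numeric matrix) and `groups` (a factor named by sample ID).
#' @examples
#' m <- count_matrix(matrix(c(0, 5, 2, 7, 1, 6), 2,
#'                          dimnames = list(c("miR-a", "miR-b"), c("s1", "s2", "s3"))),
#'                   groups = c("A", "A", "B"))
#' m
#' @export
count_matrix <- function(values, groups = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values))) {
    if (nrow(values) > 0L)
      stop("'values' must have rownames (gene IDs)")
    rownames(values) <- character()
  }
  if (is.null(colnames(values)))
    stop("'values' must have colnames (sample IDs)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ID: ", rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ID: ", colnames(values)[duplicated(colnames(values))][1L])
  if (any(!is.finite(values)))
    stop("non-finite value in count matrix")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop("negative value for gene '", rownames(values)[bad[1L]],
         "', sample '", colnames(values)[bad[2L]], "'")
  }
  if (is.null(groups)) groups <- rep("all", ncol(values))
  if (!is.null(names(groups))) {
    missing <- setdiff(names(groups), colnames(values))
    if (length(missing))
      stop("sample in group map missing from matrix: ", missing[1L])
    groups <- groups[colnames(values)]
    if (anyNA(groups))
      stop("no group assigned for sample: ",
           colnames(values)[which(is.na(groups))[1L]])
  }
  if (length(groups) != ncol(values))
    stop("'groups' must assign one group per sample")
  groups <- factor(as.character(groups))
  names(groups) <- colnames(values)
  structure(list(values = values, groups = groups), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  tab <- table(x$groups)
  cat("groups: ", paste0(names(tab), " (n=", tab, ")", collapse = ", "), "\n",
      sep = "")
  k <- min(5L, nrow(x$values))
  print(x$values[seq_len(k), , drop = FALSE])
  if (nrow(x$values) > k) cat("... (", nrow(x$values) - k, " more genes)\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Extract genes/samples from a count matrix
#'
#' @param x a [count_matrix()].
#' @param i,j gene and sample indices.
#' @param ... ignored.
#' @return A `count_matrix` restricted to the selected genes and samples.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  count_matrix(v, groups = as.character(x$groups[colnames(v)]))
}

#' @rdname count_matrix
#' @param m a `count_matrix`.
#' @export
counts <- function(m) m$values

#' @rdname count_matrix
#' @export
sample_groups <- function(m) m$groups

group_cols <- function(m, group) {
  which(as.character(m$groups) == group)
}

#' Read a count table from TSV/CSV
#'
#' Expects genes in rows, the first column holding gene IDs and the header
#' row holding sample IDs. Group labels are attached from `group_map`, which
#' may be a named vector (`sample -> group`) or the path of a two-column
#' headerless TSV sidecar file with sample IDs in column 1 and group names
#' in column 2.
#'
#' @param path path of the table to read.
#' @param format `"tsv"` or `"csv"`.
#' @param group_map named character vector, sidecar file path, or `NULL`
#'   (single group `"all"`).
#' @return A [count_matrix()].
#' @export
read_count_table <- function(path, format = c("tsv", "csv"), group_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("counts file not found: ", path)
  reader <- if (format == "tsv") read.delim else read.csv
  df <- reader(path, check.names = FALSE, stringsAsFactors = FALSE,
               comment.char = "#")
  if (ncol(df) < 2L) stop("count table needs a gene-ID column and >= 1 sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate gene ID: ", ids[duplicated(ids)][1L])
  vals <- df[, -1L, drop = FALSE]
  for (cn in colnames(vals)) {
    col <- suppressWarnings(as.numeric(vals[[cn]]))
    bad <- which(is.na(col) & !is.na(vals[[cn]]))
    if (length(bad))
      stop("non-numeric value '", vals[[cn]][bad[1L]], "' for gene '",
           ids[bad[1L]], "', sample '", cn, "'")
    neg <- which(col < 0)
    if (length(neg))
      stop("negative value for gene '", ids[neg[1L]], "', sample '", cn, "'")
    vals[[cn]] <- col
  }
  v <- as.matrix(vals)
  rownames(v) <- ids
  if (is.character(group_map) && length(group_map) == 1L &&
      is.null(names(group_map))) {
    group_map <- read_group_map(group_map)
  }
  count_matrix(v, groups = group_map)
}

read_group_map <- function(path) {
  if (!file.exists(path)) stop("group map file not found: ", path)
  g <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#")
  if (ncol(g) < 2L) stop("group map needs two columns: sample_id, group")
  setNames(as.character(g[[2L]]), as.character(g[[1L]]))
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_count_table()]: gene IDs in the first column
#' (`gene_id`), one column per sample; values, IDs and order round-trip
#' exactly. Group labels are not stored in the table; keep the sidecar.
#'
#' @param m a [count_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(m, path) {
  df <- data.frame(gene_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write any result table to TSV
#'
#' Deterministic column order (as given), header row, missing values as
#' `"NA"`.
#'
#' @param rows a data.frame of homogeneous result records (may have 0 rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  if (!is.data.frame(rows)) rows <- as.data.frame(rows)
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Scale each sample to counts per million
#'
#' Every column is rescaled so that it sums to 1e6, making samples of
#' different sequencing depth comparable (reads-per-million scale).
#'
#' @param m a [count_matrix()].
#' @return A [count_matrix()] on the CPM scale.
#' @export
normalize_cpm <- function(m) {
  cs <- colSums(m$values)
  if (any(cs == 0))
    stop("sample has all-zero counts: ", colnames(m$values)[which(cs == 0)[1L]])
  v <- sweep(m$values, 2L, 1e6 / cs, `*`)
  count_matrix(v, groups = as.character(m$groups))
}

#' Filter genes by mean-read regime
#'
#' Retains genes whose mean read count exceeds `mean_threshold` (strict
#' inequality). The threshold defaults to 10, the conventional boundary
#' between the low-read (Poisson-like) and high-read (gamma-like) noise
#' regimes. With `per_group = TRUE` the threshold must be exceeded in every
#' group separately; otherwise the pooled mean over all samples is used.
#'
#' @param m a [count_matrix()].
#' @param mean_threshold non-negative mean-read cutoff (default 10).
#' @param per_group require the threshold in every group rather than pooled.
#' @return The filtered [count_matrix()] (possibly with zero genes, with a
#'   warning). Retained/dropped totals are reported via [message()].
#' @export
filter_by_mean <- function(m, mean_threshold = 10, per_group = FALSE) {
  stopifnot(is.numeric(mean_threshold), length(mean_threshold) == 1L,
            mean_threshold >= 0)
  if (per_group) {
    keep <- rep(TRUE, nrow(m$values))
    for (g in levels(m$groups)) {
      cols <- group_cols(m, g)
      keep <- keep & rowMeans(m$values[, cols, drop = FALSE]) > mean_threshold
    }
  } else {
    keep <- rowMeans(m$values) > mean_threshold
  }
  message("filter_by_mean: retained ", sum(keep), " of ", length(keep),
          " genes (mean > ", mean_threshold,
          if (per_group) ", per group" else ", pooled", ")")
  if (!any(keep)) warning("no genes pass the mean filter")
  out <- m
  out$values <- m$values[keep, , drop = FALSE]
  out
}
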