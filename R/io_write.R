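#' Write binding clusters as a BED6-style file
#'
#' One line per cluster: chromosome, cluster start, cluster end (0-based
#' half-open, so end is the last member summit + 1), name (comma-joined
#' sorted distinct TF labels), score (number of distinct TFs), strand `"."`.
#' Lines are sorted by (chromosome, start). A header comment documents the
#' columns.
#'
#' @param x a `cluster_set` from [build_clusters()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters_bed <- function(x, path) {
  stopifnot(inherits(x, "cluster_set"))
  cl <- x$clusters
  cl <- cl[order(cl$chrom, cl$start), , drop = FALSE]
  lines <- "# chrom\tstart\tend\ttf_labels\tn_tfs\tstrand"
  if (nrow(cl)) {
    lines <- c(lines, sprintf("%s\t%s\t%s\t%s\t%d\t.",
                              cl$chrom,
                              format(cl$start, scientific = FALSE, trim = TRUE),
                              format(cl$end + 1, scientific = FALSE, trim = TRUE),
                              cl$tf_labels, cl$n_tfs))
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write clusters to ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a clusters BED file written by [write_clusters_bed()]
#'
#' @param path path to the BED file.
#' @return Data frame `chrom`, `start`, `end` (0-based half-open),
#'   `tf_labels`, `n_tfs`.
#' @export
read_clusters_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      tf_labels = character(), n_tfs = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 0L) < 5L)) {
    stop("malformed clusters BED line in ", path, call. = FALSE)
  }
  data.frame(chrom = vapply(parts, `[[`, "", 1L),
             start = as.numeric(vapply(parts, `[[`, "", 2L)),
             end = as.numeric(vapply(parts, `[[`, "", 3L)),
             tf_labels = vapply(parts, `[[`, "", 4L),
             n_tfs = as.integer(vapply(parts, `[[`, "", 5L)),
             stringsAsFactors = FALSE)
}

#' Write a labelled square matrix as TSV
#'
#' Header row and first column carry the labels. Integer matrices round-trip
#' exactly; floating-point values are written with six decimals.
#'
#' @param m square numeric matrix; dimnames, when present, must agree with
#'   `labels`.
#' @param path output path.
#' @param labels row/column labels; default: `rownames(m)`.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, labels = rownames(m)) {
  stopifnot(is.matrix(m))
  if (is.null(labels)) stop("matrix labels are required", call. = FALSE)
  if (nrow(m) != ncol(m) || length(labels) != nrow(m)) {
    stop("matrix must be square with one label per row", call. = FALSE)
  }
  x <- unclass(m)
  as_int <- is.integer(x) || all(is.na(x) | x == floor(x))
  fmt <- function(v) {
    if (as_int) {
      ifelse(is.na(v), "NA", format(v, scientific = FALSE, trim = TRUE))
    } else {
      ifelse(is.na(v), "NA", sprintf("%.6f", v))
    }
  }
  lines <- c(paste(c("", labels), collapse = "\t"),
             vapply(seq_len(nrow(x)), function(i) {
               paste(c(labels[i], fmt(x[i, ])), collapse = "\t")
             }, ""))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write matrix to ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a labelled square matrix written by [write_matrix_tsv()]
#'
#' @param path path to the TSV.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(tab)
}

#' Write a size histogram, occurrence table or null distribution as TSV
#'
#' Plain tab-separated tables with a header row; numeric columns are written
#' in full precision so reruns can be compared byte for byte.
#'
#' @param x a data frame (e.g. [size_histogram()], [tf_occurrence()],
#'   [simulate_null()] output).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
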