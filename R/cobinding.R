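#' Pairwise co-occurrence matrix of TF binding sites
#'
#' Counts, for every pair of TFs, the site pairs that fall within a genomic
#' window of each other: cell (i, j), i != j, is the number of pairs
#' (a in sites_i, b in sites_j) on the same chromosome with
#' `|pos_a - pos_b| <= window`. All within-window cross pairs are counted,
#' which makes the matrix exactly symmetric. The diagonal holds each TF's
#' site count. Computed with a sorted sweep (binary search per site), not a
#' quadratic double loop.
#'
#' @param sitesets list of two or more [site_set()] objects with distinct
#'   labels.
#' @param window window half-width in nucleotides (> 0).
#' @return A `cooccurrence_matrix`: symmetric integer matrix with TF labels
#'   as dimnames and attribute `window`.
#' @export
pairwise_cooccurrence <- function(sitesets, window = 200) {
  if (!is.list(sitesets) || length(sitesets) < 2L ||
      !all(vapply(sitesets, inherits, logical(1), "site_set"))) {
    stop("`sitesets` must be a list of >= 2 site_set objects", call. = FALSE)
  }
  if (!is.numeric(window) || length(window) != 1L || window <= 0) {
    stop("`window` must be a single positive number", call. = FALSE)
  }
  labels <- vapply(sitesets, tf_label, "")
  if (anyDuplicated(labels)) {
    stop("duplicate TF labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  m <- length(labels)
  # per TF: positions split by chromosome, sorted
  by_chrom <- lapply(sitesets, function(s) {
    lapply(split(s$position, s$chrom), sort)
  })
  cells <- matrix(0, m, m, dimnames = list(labels, labels))
  diag(cells) <- vapply(sitesets, nrow, 0L)
  for (i in seq_len(m - 1L)) {
    for (j in seq(i + 1L, m)) {
      tot <- 0
      common <- intersect(names(by_chrom[[i]]), names(by_chrom[[j]]))
      for (ch in common) {
        a <- by_chrom[[i]][[ch]]
        b <- by_chrom[[j]][[ch]]
        # number of b in [a - window, a + window] for each a, via sorted search
        tot <- tot + sum(findInterval(a + window, b) -
                           findInterval(a - window - 1, b))
      }
      cells[i, j] <- cells[j, i] <- tot
    }
  }
  storage.mode(cells) <- "integer"
  attr(cells, "window") <- window
  class(cells) <- c("cooccurrence_matrix", class(cells))
  cells
}

#' Pearson correlation of co-occurrence matrix rows
#'
#' Turns the integer co-occurrence matrix into a measure of association: the
#' correlation of two TFs' co-occurrence profiles across all other TFs. With
#' `drop_self_indices` (the default) the entries at positions i and j are
#' removed from both row vectors before correlating, so the self-count
#' diagonal cannot dominate. Rank (Spearman) correlation is available as an
#' alternative to the linear coefficient. A zero-variance vector yields `NA`
#' cells rather than an error.
#'
#' @param coocc a [pairwise_cooccurrence()] matrix.
#' @param drop_self_indices remove entries i and j from both rows first.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A `correlation_matrix`: symmetric numeric matrix, defined cells in
#'   `[-1, 1]`, diagonal 1 where defined, `NA` marking undefined cells.
#' @export
correlation_matrix <- function(coocc, drop_self_indices = TRUE,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!inherits(coocc, "cooccurrence_matrix")) {
    stopifnot(is.matrix(coocc), nrow(coocc) == ncol(coocc))
  }
  m <- nrow(coocc)
  if (drop_self_indices && m < 3L) {
    stop("need >= 3 labels to correlate rows with self indices dropped",
         call. = FALSE)
  }
  labels <- rownames(coocc)
  out <- matrix(NA_real_, m, m, dimnames = list(labels, labels))
  x <- unclass(coocc)
  for (i in seq_len(m)) {
    for (j in i:m) {
      keep <- if (drop_self_indices) setdiff(seq_len(m), c(i, j)) else seq_len(m)
      vi <- x[i, keep]
      vj <- x[j, keep]
      if (stats::sd(vi) == 0 || stats::sd(vj) == 0) next  # undefined
      out[i, j] <- out[j, i] <- stats::cor(vi, vj, method = method)
    }
  }
  class(out) <- c("correlation_matrix", class(out))
  out
}

#' Hierarchically order TFs by co-binding similarity
#'
#' Agglomerative clustering of the TFs on the distance `d = 1 - correlation`,
#' giving the leaf order used to arrange heatmap rows so that groups of
#' co-occurring factors appear as contiguous blocks. Undefined correlations
#' are treated as 0 (distance 1) with a warning. Labels are pre-sorted
#' lexicographically so tied merges resolve deterministically.
#'
#' @param corr a [correlation_matrix()].
#' @param linkage agglomeration rule: `"average"`, `"complete"` or
#'   `"single"`.
#' @return A `tf_ordering`: list with `order` (labels in leaf order) and
#'   `tree` (the `hclust` merge tree).
#' @export
hierarchical_order <- function(corr, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  labels <- rownames(corr)
  if (is.null(labels)) labels <- paste0("TF", seq_len(nrow(corr)))
  if (length(labels) == 1L) {
    return(structure(list(order = labels, tree = NULL), class = "tf_ordering"))
  }
  x <- unclass(corr)
  dimnames(x) <- list(labels, labels)
  ord <- order(labels)
  x <- x[ord, ord, drop = FALSE]
  off <- x[upper.tri(x)]
  if (anyNA(off)) {
    warning("undefined correlations treated as 0 for ordering")
    x[is.na(x)] <- 0
  }
  d <- stats::as.dist(1 - x)
  tree <- stats::hclust(d, method = linkage)
  # orient every merge so the subtree holding the alphabetically first label
  # comes first: deterministic leaf order under tied distances
  dend <- stats::reorder(stats::as.dendrogram(tree), seq_len(nrow(x)),
                         agglo.FUN = min)
  structure(list(order = labels(dend), tree = tree),
            class = "tf_ordering")
}

#' @export
print.tf_ordering <- function(x, ...) {
  cat("TF leaf order:", paste(x$order, collapse = " "), "\n")
  invisible(x)
}

# Map a correlation value in [-1, 1] to a fill color: white -> red for
# positive association, white -> blue for negative, grey for undefined.
heat_color <- function(v) {
  if (is.na(v)) return("#bbbbbb")
  v <- max(-1, min(1, v))
  ch <- sprintf("%02x", round(255 * (1 - abs(v))))
  if (v >= 0) paste0("#ff", ch, ch) else paste0("#", ch, ch, "ff")
}

#' Render a co-binding heatmap as an SVG file
#'
#' Writes the correlation (or count) matrix as a red-intensity heatmap with
#' rows and columns in a given order. The SVG is generated directly so the
#' output is byte-identical across runs for identical input — reruns of a
#' pipeline can be diffed. Optional block outlines highlight groups of
#' factors that tend to occur together.
#'
#' @param corr square numeric matrix with dimnames (correlations in
#'   `[-1, 1]`; `NA` rendered grey).
#' @param ordering optional [hierarchical_order()] result or character vector
#'   of labels; default: matrix order.
#' @param path output path (`.svg`).
#' @param blocks optional list of character vectors; each block contiguous in
#'   `ordering` is outlined.
#' @param cell cell size in pixels.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(corr, ordering = NULL, path, blocks = NULL,
                           cell = 18) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  labels <- rownames(corr)
  if (is.null(labels)) labels <- paste0("TF", seq_len(nrow(corr)))
  ord <- if (is.null(ordering)) {
    labels
  } else if (inherits(ordering, "tf_ordering")) {
    ordering$order
  } else {
    as.character(ordering)
  }
  if (!setequal(ord, labels) || length(ord) != length(labels)) {
    stop("`ordering` must be a permutation of the matrix labels", call. = FALSE)
  }
  x <- unclass(corr)
  dimnames(x) <- list(labels, labels)
  x <- x[ord, ord, drop = FALSE]
  m <- length(ord)
  margin <- 10 + 7 * max(nchar(ord))
  w <- margin + m * cell + 10
  h <- margin + m * cell + 10
  svg <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    w, h, w, h),
    '<style>text{font-family:monospace;font-size:10px;}</style>',
    sprintf('<rect width="%d" height="%d" fill="white"/>', w, h))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      svg <- c(svg, sprintf(
        '<rect x="%g" y="%g" width="%g" height="%g" fill="%s"/>',
        margin + (j - 1) * cell, margin + (i - 1) * cell, cell, cell,
        heat_color(x[i, j])))
    }
    svg <- c(svg, sprintf(
      '<text x="%g" y="%g" text-anchor="end">%s</text>',
      margin - 4, margin + (i - 0.35) * cell, ord[i]))
    svg <- c(svg, sprintf(
      '<text x="%g" y="%g" text-anchor="end" transform="rotate(-90 %g %g)">%s</text>',
      margin + (i - 0.3) * cell, margin - 4,
      margin + (i - 0.3) * cell, margin - 4, ord[i]))
  }
  if (!is.null(blocks)) {
    for (b in blocks) {
      idx <- match(b, ord)
      if (anyNA(idx)) next
      lo <- min(idx) - 1L
      n <- max(idx) - lo
      svg <- c(svg, sprintf(
        '<rect x="%g" y="%g" width="%g" height="%g" fill="none" stroke="black" stroke-width="2"/>',
        margin + lo * cell, margin + lo * cell, n * cell, n * cell))
    }
  }
  svg <- c(svg, "</svg>")
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write heatmap to ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  writeLines(svg, con)
  invisible(path)
}
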