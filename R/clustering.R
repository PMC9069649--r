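#' Clustering parameters
#'
#' Parameters of the summit-chaining rule. Two consecutive sites (sorted by
#' position within a chromosome) join the same cluster when the distance
#' between them is strictly less than `gap`; additionally, with a span cap
#' enabled, a site only extends the current cluster while its distance to the
#' cluster's first site does not exceed `span_cap`. The defaults reflect
#' inter-peak distances observed in genome-scale ChIP-seq profiles (200 nt)
#' and the width of a typical promoter (500 nt), the range over which
#' DNA-bound proteins can physically interact.
#'
#' @param gap maximum chaining distance, nucleotides (> 0); sites at distance
#'   >= `gap` split.
#' @param span_cap maximum cluster width, nucleotides (>= `gap`), or `NULL`
#'   to disable the cap.
#' @param size_metric which cluster-size definition is the headline one:
#'   number of distinct TFs (`"distinct_tfs"`) or total member sites
#'   (`"total_sites"`).
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(gap = 200, span_cap = 500,
                           size_metric = c("distinct_tfs", "total_sites")) {
  size_metric <- match.arg(size_metric)
  if (!is.numeric(gap) || length(gap) != 1L || is.na(gap) || gap <= 0) {
    stop("`gap` must be a single positive number", call. = FALSE)
  }
  if (!is.null(span_cap)) {
    if (!is.numeric(span_cap) || length(span_cap) != 1L || is.na(span_cap) ||
        span_cap < gap) {
      stop("`span_cap` must be >= `gap` (or NULL to disable)", call. = FALSE)
    }
  }
  structure(list(gap = gap, span_cap = span_cap, size_metric = size_metric),
            class = "cluster_params")
}

# Greedy left-to-right cluster ids for sorted positions on one chromosome.
chain_ids <- function(pos, gap, span_cap) {
  n <- length(pos)
  id <- integer(n)
  if (n == 0L) return(id)
  cur <- 1L
  id[1] <- 1L
  first <- pos[1]
  for (i in seq_len(n - 1L) + 1L) {
    ok <- (pos[i] - pos[i - 1L]) < gap
    if (ok && !is.null(span_cap)) ok <- (pos[i] - first) <= span_cap
    if (ok) {
      id[i] <- cur
    } else {
      cur <- cur + 1L
      id[i] <- cur
      first <- pos[i]
    }
  }
  id
}

#' Build binding clusters from the site sets of several TFs
#'
#' Pools the summit positions of all TFs, sorts them by (chromosome,
#' position, TF label) and chains them left to right: the current cluster
#' extends while the next site is closer than `gap` to the previous one and,
#' when the span cap is enabled, no farther than `span_cap` from the
#' cluster's first site; any violation closes the cluster and the next site
#' opens a new one. Every site belongs to exactly one cluster; single
#' isolated sites come out as singleton clusters. Equal positions always
#' co-cluster and are ordered by TF label for determinism.
#'
#' @param sitesets a list of [site_set()] objects (>= 1), or a single one.
#' @param params a [cluster_params()].
#' @return A `cluster_set`: list with elements
#'   * `clusters` — data frame `cluster_id`, `chrom`, `start`, `end`
#'     (positions of the first and last member summit), `n_sites`, `n_tfs`,
#'     `tf_labels` (comma-joined sorted distinct labels);
#'   * `members` — data frame `cluster_id`, `chrom`, `position`, `tf`;
#'   * `params` — the parameters used.
#' @export
build_clusters <- function(sitesets, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  if (inherits(sitesets, "site_set")) sitesets <- list(sitesets)
  if (!is.list(sitesets) || length(sitesets) < 1L ||
      !all(vapply(sitesets, inherits, logical(1), "site_set"))) {
    stop("`sitesets` must be a list of site_set objects", call. = FALSE)
  }

  pool <- do.call(rbind, lapply(sitesets, function(s) {
    data.frame(chrom = s$chrom, position = s$position,
               tf = rep(tf_label(s), nrow(s)), stringsAsFactors = FALSE)
  }))
  if (nrow(pool) == 0L) {
    return(new_cluster_set(
      clusters = data.frame(cluster_id = integer(), chrom = character(),
                            start = numeric(), end = numeric(),
                            n_sites = integer(), n_tfs = integer(),
                            tf_labels = character(), stringsAsFactors = FALSE),
      members = data.frame(cluster_id = integer(), chrom = character(),
                           position = numeric(), tf = character(),
                           stringsAsFactors = FALSE),
      params = params))
  }

  pool <- pool[order(pool$chrom, pool$position, pool$tf), , drop = FALSE]
  rownames(pool) <- NULL

  ids <- integer(nrow(pool))
  offset <- 0L
  for (ch in unique(pool$chrom)) {
    sel <- pool$chrom == ch
    local <- chain_ids(pool$position[sel], params$gap, params$span_cap)
    ids[sel] <- local + offset
    offset <- offset + max(local)
  }
  pool$cluster_id <- ids

  firsts <- !duplicated(ids)
  lasts <- !duplicated(ids, fromLast = TRUE)
  tf_by_cluster <- split(pool$tf, ids)
  clusters <- data.frame(
    cluster_id = ids[firsts],
    chrom = pool$chrom[firsts],
    start = pool$position[firsts],
    end = pool$position[lasts],
    n_sites = as.integer(tabulate(ids)),
    n_tfs = vapply(tf_by_cluster, function(t) length(unique(t)), 0L),
    tf_labels = vapply(tf_by_cluster,
                       function(t) paste(sort(unique(t)), collapse = ","), ""),
    stringsAsFactors = FALSE)
  rownames(clusters) <- NULL

  new_cluster_set(clusters = clusters,
                  members = pool[, c("cluster_id", "chrom", "position", "tf")],
                  params = params)
}

new_cluster_set <- function(clusters, members, params) {
  structure(list(clusters = clusters, members = members, params = params),
            class = "cluster_set")
}

#' Cluster sizes under a given metric
#'
#' The size of a binding cluster can be counted as the number of distinct
#' TFs with at least one member site (the headline metric: how many different
#' factors co-occupy the locus) or as the total number of member sites.
#'
#' @param x a `cluster_set` from [build_clusters()].
#' @param metric `"distinct_tfs"` or `"total_sites"`; defaults to the metric
#'   recorded in the cluster set's parameters.
#' @return Integer vector of sizes, one per cluster, in `x$clusters` order.
#' @export
cluster_sizes <- function(x, metric = NULL) {
  stopifnot(inherits(x, "cluster_set"))
  if (is.null(metric)) metric <- x$params$size_metric
  metric <- match.arg(metric, c("distinct_tfs", "total_sites"))
  if (metric == "distinct_tfs") x$clusters$n_tfs else x$clusters$n_sites
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf(
    "Cluster set: %d cluster(s) from %d site(s) (gap %g nt, span cap %s)\n",
    nrow(x$clusters), nrow(x$members), x$params$gap,
    if (is.null(x$params$span_cap)) "off" else paste0(x$params$span_cap, " nt")))
  if (nrow(x$clusters)) {
    cat(sprintf("  sizes (distinct TFs): max %d; singletons: %d\n",
                max(x$clusters$n_tfs), sum(x$clusters$n_sites == 1L)))
  }
  invisible(x)
}
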