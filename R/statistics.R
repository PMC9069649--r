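#' Cluster-size histogram
#'
#' Counts clusters by size, singletons included at size 1.
#'
#' @param x a `cluster_set` from [build_clusters()].
#' @param metric size metric, see [cluster_sizes()].
#' @return A `size_histogram`: data frame with columns `size` and `count`
#'   (all sizes with at least one cluster, ascending), attribute `metric`.
#' @export
size_histogram <- function(x, metric = NULL) {
  stopifnot(inherits(x, "cluster_set"))
  if (is.null(metric)) metric <- x$params$size_metric
  metric <- match.arg(metric, c("distinct_tfs", "total_sites"))
  sizes <- cluster_sizes(x, metric)
  new_size_histogram(sizes, metric)
}

new_size_histogram <- function(sizes, metric) {
  if (length(sizes) == 0L) {
    out <- data.frame(size = integer(), count = integer())
  } else {
    tb <- table(sizes)
    out <- data.frame(size = as.integer(names(tb)), count = as.integer(tb))
  }
  attr(out, "metric") <- metric
  class(out) <- c("size_histogram", "data.frame")
  out
}

#' Per-TF occurrence in binding clusters
#'
#' The occurrence of a TF is the fraction of clusters that contain at least
#' one of its sites. By default only co-binding clusters (two or more member
#' sites) enter numerator and denominator, so occurrence measures
#' participation in co-binding; singletons can be included with
#' `include_singletons = TRUE`.
#'
#' @param x a `cluster_set`.
#' @param tf_labels labels to report; defaults to all labels present, sorted.
#' @param include_singletons count single-site clusters too.
#' @return An `occurrence_table`: data frame `tf`, `occurrence` (in `[0, 1]`,
#'   `NA` when no cluster qualifies), attribute `denominator`.
#' @export
tf_occurrence <- function(x, tf_labels = NULL, include_singletons = FALSE) {
  stopifnot(inherits(x, "cluster_set"))
  present <- sort(unique(x$members$tf))
  if (is.null(tf_labels)) {
    tf_labels <- present
  } else if (!all(present %in% tf_labels)) {
    stop("`tf_labels` must cover every label present in the clusters",
         call. = FALSE)
  }
  keep_ids <- if (include_singletons) {
    x$clusters$cluster_id
  } else {
    x$clusters$cluster_id[x$clusters$n_sites >= 2L]
  }
  denom <- length(keep_ids)
  if (denom == 0L) {
    warning("no cluster qualifies for the occurrence denominator; ",
            "occurrences are undefined")
    occ <- rep(NA_real_, length(tf_labels))
  } else {
    mem <- x$members[x$members$cluster_id %in% keep_ids, , drop = FALSE]
    hits <- table(unique(mem[, c("cluster_id", "tf")])$tf)
    occ <- as.numeric(hits[tf_labels]) / denom
    occ[is.na(occ)] <- 0
  }
  out <- data.frame(tf = tf_labels, occurrence = occ, stringsAsFactors = FALSE)
  attr(out, "denominator") <- denom
  attr(out, "include_singletons") <- include_singletons
  class(out) <- c("occurrence_table", "data.frame")
  out
}

#' Fit the tail of a cluster-size histogram
#'
#' Least-squares regression on log counts, the log-scale reading of a size
#' histogram: a power law `count ~ k^slope` is a line in log(count) versus
#' log(k), an exponential `count ~ exp(slope * k)` a line in log(count)
#' versus k. Only sizes `>= k_min` with nonzero counts are used.
#'
#' @param hist a [size_histogram()].
#' @param model `"power_law"` or `"exponential"`.
#' @param k_min smallest size entering the fit.
#' @return A `tail_fit` list: `model`, `slope`, `intercept`, `r_squared`,
#'   `k_min`, `n_points`.
#' @export
fit_tail <- function(hist, model = c("power_law", "exponential"), k_min = 1L) {
  stopifnot(inherits(hist, "size_histogram"))
  model <- match.arg(model)
  use <- hist$size >= k_min & hist$count > 0
  k <- hist$size[use]
  cnt <- hist$count[use]
  if (length(k) < 3L) {
    stop("tail fit needs at least 3 sizes with nonzero counts at k >= ",
         k_min, call. = FALSE)
  }
  xx <- if (model == "power_law") log(k) else k
  fit <- stats::lm(log(cnt) ~ xx)
  structure(list(model = model,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = summary(fit)$r.squared,
                 k_min = k_min,
                 n_points = length(k)),
            class = "tail_fit")
}

#' @export
print.tail_fit <- function(x, ...) {
  cat(sprintf("%s tail fit (k >= %d, %d points): slope %.4f, r^2 %.4f\n",
              x$model, x$k_min, x$n_points, x$slope, x$r_squared))
  invisible(x)
}

# One uniform random placement of `counts[tf]` sites per TF on `layout`,
# chromosomes weighted by length. Positions are 0-based integers; collisions
# are allowed (independent placement).
random_sitesets <- function(layout, counts) {
  labels <- names(counts)
  prob <- layout$length / sum(layout$length)
  lapply(labels, function(tf) {
    n <- counts[[tf]]
    ci <- sample.int(nrow(layout), n, replace = TRUE, prob = prob)
    pos <- floor(stats::runif(n) * layout$length[ci])
    site_set(tf, layout$name[ci], pos)
  })
}

#' Monte-Carlo null model of cluster sizes under random placement
#'
#' Formalizes the question of whether observed cluster sizes can arise by
#' chance: in each replicate every TF's sites are repositioned uniformly at
#' random (integer positions, chromosomes weighted by length, per-TF site
#' counts preserved, collisions allowed), clusters are rebuilt with the same
#' parameters, and the size histogram is recorded. When an observed histogram
#' is supplied the empirical exceedance probability of each observed count is
#' reported with the (r + 1) / (reps + 1) correction, both per size and for
#' the upper tail (clusters of size >= k), so a statement like "clusters of
#' four or more TFs exceed chance" can be read off directly.
#'
#' @param layout a [genome_layout()].
#' @param site_counts named integer vector or list, sites per TF (> 0).
#' @param params a [cluster_params()]; the same parameters used for the
#'   observed clusters.
#' @param reps number of Monte-Carlo replicates (>= 1).
#' @param seed integer seed; identical seed and parameters give an identical
#'   result.
#' @param observed optional [size_histogram()] of the observed clusters
#'   (same metric as `params$size_metric`).
#' @return A `null_distribution`: data frame with one row per size `k` up to
#'   the largest seen (null or observed) — `size`, `mean_count`, `sd_count`,
#'   `obs_count`, `p_ge` (P(null count >= observed)), `mean_count_tail`,
#'   `obs_count_tail`, `p_ge_tail` (same for counts of clusters of size
#'   >= k); `obs_*`/`p_*` are `NA` without `observed`. Attributes `reps`,
#'   `seed`, `metric`.
#' @export
simulate_null <- function(layout, site_counts, params = cluster_params(),
                          reps = 1000L, seed = 1L, observed = NULL) {
  stopifnot(inherits(layout, "genome_layout"), inherits(params, "cluster_params"))
  counts <- unlist(site_counts)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("`site_counts` must be named by TF label", call. = FALSE)
  }
  if (any(counts <= 0) || any(counts != floor(counts))) {
    stop("all site counts must be positive integers", call. = FALSE)
  }
  if (reps < 1L) stop("`reps` must be >= 1", call. = FALSE)
  if (!is.null(observed)) stopifnot(inherits(observed, "size_histogram"))

  metric <- params$size_metric
  total <- sum(counts)
  set.seed(seed)

  tally <- matrix(0L, nrow = reps, ncol = total)  # counts per size, per rep
  kmax <- 0L
  for (r in seq_len(reps)) {
    cs <- build_clusters(random_sitesets(layout, counts), params)
    sz <- cluster_sizes(cs, metric)
    tb <- tabulate(sz, nbins = total)
    tally[r, ] <- tb
    kmax <- max(kmax, max(sz))
  }
  if (!is.null(observed) && nrow(observed)) {
    kmax <- max(kmax, max(observed$size))
  }
  tally <- tally[, seq_len(kmax), drop = FALSE]
  tail_tally <- t(apply(tally, 1L, function(v) rev(cumsum(rev(v)))))
  if (reps == 1L) tail_tally <- matrix(tail_tally, nrow = 1L)

  obs <- rep(NA_real_, kmax)
  if (!is.null(observed)) {
    obs <- rep(0, kmax)
    obs[observed$size] <- observed$count
  }
  obs_tail <- if (anyNA(obs)) rep(NA_real_, kmax) else rev(cumsum(rev(obs)))

  p_ge <- p_ge_tail <- rep(NA_real_, kmax)
  if (!is.null(observed)) {
    for (k in seq_len(kmax)) {
      p_ge[k] <- (sum(tally[, k] >= obs[k]) + 1) / (reps + 1)
      p_ge_tail[k] <- (sum(tail_tally[, k] >= obs_tail[k]) + 1) / (reps + 1)
    }
  }

  out <- data.frame(
    size = seq_len(kmax),
    mean_count = colMeans(tally),
    sd_count = apply(tally, 2L, stats::sd),
    obs_count = obs,
    p_ge = p_ge,
    mean_count_tail = colMeans(tail_tally),
    obs_count_tail = obs_tail,
    p_ge_tail = p_ge_tail)
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  attr(out, "metric") <- metric
  class(out) <- c("null_distribution", "data.frame")
  out
}
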