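#' Specification of a synthetic multi-TF binding landscape
#'
#' Describes a genome in which uniform background binding sites are mixed
#' with planted co-binding hubs: loci where a chosen subset of TFs each place
#' one site within a small jitter of a common center. This emulates the
#' structure seen in real multi-TF ChIP-seq compendia — a power-law-decaying
#' mass of small clusters plus complex loci bound by many factors — while
#' giving tests an exact ground truth.
#'
#' @param layout a [genome_layout()].
#' @param tf_labels character vector of TF names.
#' @param background_counts named integer vector: uniform background sites
#'   per TF (0 allowed); names must be a subset of `tf_labels`.
#' @param hubs data frame with columns `chrom`, `center` (0-based position),
#'   `tfs` (comma-joined member labels) and `jitter` (>= 0, nucleotides);
#'   or `NULL` for background only.
#' @param seed integer seed; generation is fully reproducible.
#' @param hub_guard background sites are kept at least this many nucleotides
#'   away from every hub center (resampled otherwise), so planted hubs sit in
#'   otherwise-unoccupied loci and their recovery is a property of the
#'   chaining rule, not of luck. Set 0 to disable.
#' @return A `synthesis_spec` list.
#' @export
synthesis_spec <- function(layout, tf_labels, background_counts, hubs = NULL,
                           seed = 1L, hub_guard = 500) {
  stopifnot(inherits(layout, "genome_layout"))
  tf_labels <- as.character(tf_labels)
  if (anyDuplicated(tf_labels)) stop("duplicate TF labels", call. = FALSE)
  bg <- unlist(background_counts)
  if (length(bg) && (is.null(names(bg)) || !all(names(bg) %in% tf_labels))) {
    stop("`background_counts` names must be TF labels", call. = FALSE)
  }
  if (any(bg < 0) || any(bg != floor(bg))) {
    stop("background counts must be non-negative integers", call. = FALSE)
  }
  if (!is.null(hubs)) {
    stopifnot(is.data.frame(hubs),
              all(c("chrom", "center", "tfs", "jitter") %in% names(hubs)))
    ci <- match(hubs$chrom, layout$name)
    if (anyNA(ci)) stop("hub chromosome not in layout", call. = FALSE)
    if (any(hubs$center < 0) || any(hubs$center >= layout$length[ci])) {
      stop("hub centers must lie within chromosome bounds", call. = FALSE)
    }
    if (any(hubs$jitter < 0)) stop("hub jitter must be >= 0", call. = FALSE)
    members <- strsplit(hubs$tfs, ",", fixed = TRUE)
    if (!all(unlist(members) %in% tf_labels)) {
      stop("hub member not in `tf_labels`", call. = FALSE)
    }
  }
  structure(list(layout = layout, tf_labels = tf_labels,
                 background_counts = bg, hubs = hubs, seed = seed,
                 hub_guard = hub_guard),
            class = "synthesis_spec")
}

#' Generate site sets with planted co-binding hubs
#'
#' For each hub, every member TF receives one site at
#' `center + U[-jitter, +jitter]` (integer offsets), clamped to the
#' chromosome bounds so per-TF counts stay exact. Background sites are placed
#' uniformly per TF (chromosomes weighted by length), resampling any draw
#' that lands within `hub_guard` of a hub center. The same spec and seed
#' always give byte-identical output.
#'
#' @param spec a [synthesis_spec()].
#' @return List with elements
#'   * `sitesets` — list of [site_set()], one per TF in `tf_labels` order
#'     (TFs with no sites are dropped);
#'   * `truth` — data frame `hub_id`, `chrom`, `center`, `tfs`, `start`,
#'     `end`: the planted ground truth (realized site span per hub).
#' @export
generate_sitesets <- function(spec) {
  stopifnot(inherits(spec, "synthesis_spec"))
  set.seed(spec$seed)
  layout <- spec$layout
  hubs <- spec$hubs

  sites <- list()  # per TF: data.frame(chrom, position)
  for (tf in spec$tf_labels) {
    sites[[tf]] <- data.frame(chrom = character(), position = numeric(),
                              stringsAsFactors = FALSE)
  }

  truth <- data.frame(hub_id = integer(), chrom = character(),
                      center = numeric(), tfs = character(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
  if (!is.null(hubs) && nrow(hubs)) {
    for (h in seq_len(nrow(hubs))) {
      members <- strsplit(hubs$tfs[h], ",", fixed = TRUE)[[1]]
      len <- layout$length[match(hubs$chrom[h], layout$name)]
      off <- if (hubs$jitter[h] > 0) {
        sample.int(2L * hubs$jitter[h] + 1L, length(members),
                   replace = TRUE) - hubs$jitter[h] - 1L
      } else {
        rep(0L, length(members))
      }
      pos <- pmin(pmax(hubs$center[h] + off, 0), len - 1)
      if (any(pos != hubs$center[h] + off)) {
        message("hub ", h, ": site(s) clamped to chromosome bounds")
      }
      for (k in seq_along(members)) {
        sites[[members[k]]] <- rbind(
          sites[[members[k]]],
          data.frame(chrom = hubs$chrom[h], position = pos[k],
                     stringsAsFactors = FALSE))
      }
      truth <- rbind(truth, data.frame(
        hub_id = h, chrom = hubs$chrom[h], center = hubs$center[h],
        tfs = paste(sort(members), collapse = ","),
        start = min(pos), end = max(pos), stringsAsFactors = FALSE))
    }
  }

  guarded <- function(chrom, pos) {
    if (is.null(hubs) || nrow(hubs) == 0L || spec$hub_guard <= 0) {
      return(rep(FALSE, length(pos)))
    }
    bad <- rep(FALSE, length(pos))
    for (h in seq_len(nrow(hubs))) {
      bad <- bad | (chrom == hubs$chrom[h] &
                      abs(pos - hubs$center[h]) <= spec$hub_guard)
    }
    bad
  }
  prob <- layout$length / sum(layout$length)
  for (tf in names(spec$background_counts)) {
    n <- spec$background_counts[[tf]]
    if (n == 0L) next
    ci <- sample.int(nrow(layout), n, replace = TRUE, prob = prob)
    chrom <- layout$name[ci]
    pos <- floor(stats::runif(n) * layout$length[ci])
    redo <- which(guarded(chrom, pos))
    while (length(redo)) {
      ci2 <- sample.int(nrow(layout), length(redo), replace = TRUE, prob = prob)
      chrom[redo] <- layout$name[ci2]
      pos[redo] <- floor(stats::runif(length(redo)) * layout$length[ci2])
      redo <- redo[guarded(chrom[redo], pos[redo])]
    }
    sites[[tf]] <- rbind(sites[[tf]],
                         data.frame(chrom = chrom, position = pos,
                                    stringsAsFactors = FALSE))
  }

  sitesets <- list()
  for (tf in spec$tf_labels) {
    if (nrow(sites[[tf]]) == 0L) next
    sitesets[[tf]] <- site_set(tf, sites[[tf]]$chrom, sites[[tf]]$position)
  }
  list(sitesets = unname(sitesets), truth = truth)
}

#' Draw cluster sizes from a truncated discrete power law
#'
#' Samples `n` sizes from `P(k) proportional to k^(-alpha)` on
#' `k = 1..k_max`, the size decay reported for binding-cluster histograms.
#' The normalization constant is computed by direct summation.
#'
#' @param alpha exponent (> 1).
#' @param k_max largest size (>= 2; with `k_max = 1` all draws are 1).
#' @param n number of draws.
#' @param seed integer seed.
#' @return Integer vector of `n` sizes.
#' @export
generate_powerlaw_sizes <- function(alpha, k_max, n, seed = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 1) {
    stop("`alpha` must be a single number > 1", call. = FALSE)
  }
  if (k_max < 1L) stop("`k_max` must be >= 1", call. = FALSE)
  set.seed(seed)
  if (k_max == 1L) return(rep(1L, n))
  p <- (seq_len(k_max))^(-alpha)
  p <- p / sum(p)
  sample.int(k_max, n, replace = TRUE, prob = p)
}

#' A ready-made synthetic fixture: co-binding hubs on a three-chromosome genome
#'
#' Builds the study conditions used throughout the package's tests and
#' examples: a 3 x 10 Mb genome and twelve TFs with 100 uniform background
#' sites each. Ten of the TFs (`T01`..`T10`) form a co-binding pool from
#' which each hub draws a random subset of 5-10 members (one site per member,
#' 50 nt jitter, centers >= 1 Mb apart); `T11` and `T12` bind background
#' only, so a correlation heatmap should separate hub participants from
#' loners. With the default chaining parameters (gap 200 nt, span cap
#' 500 nt) every hub is recoverable as one cluster.
#'
#' @param seed integer seed.
#' @param n_hubs number of hubs.
#' @param background_per_tf background sites per TF.
#' @param jitter hub half-width in nucleotides.
#' @return A [synthesis_spec()].
#' @export
hub_fixture_spec <- function(seed = 1L, n_hubs = 10L, background_per_tf = 100L,
                             jitter = 50L) {
  layout <- genome_layout(c("chr1", "chr2", "chr3"), rep(1e7, 3))
  tfs <- sprintf("T%02d", 1:12)
  pool <- tfs[1:10]
  set.seed(seed)
  if (n_hubs == 0L) {
    bg <- stats::setNames(rep(as.integer(background_per_tf), length(tfs)), tfs)
    return(synthesis_spec(layout, tfs, bg, NULL, seed = seed))
  }
  chrom <- layout$name[(seq_len(n_hubs) - 1L) %% 3L + 1L]
  # centers on a coarse deterministic grid, >= 1 Mb apart within a chromosome
  center <- 5e5 + 1e6 * ((seq_len(n_hubs) - 1L) %/% 3L)
  n_members <- sample(5:10, n_hubs, replace = TRUE)
  tf_sets <- vapply(seq_len(n_hubs), function(h) {
    paste(sort(sample(pool, n_members[h])), collapse = ",")
  }, "")
  hubs <- data.frame(chrom = chrom, center = center, tfs = tf_sets,
                     jitter = jitter, stringsAsFactors = FALSE)
  bg <- stats::setNames(rep(as.integer(background_per_tf), length(tfs)), tfs)
  synthesis_spec(layout, tfs, bg, hubs, seed = seed)
}
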