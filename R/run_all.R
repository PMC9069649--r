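#' Read a pipeline configuration
#'
#' The configuration is a flat YAML file. Recognized keys:
#' \describe{
#'   \item{beds}{map of TF label to BED path (required).}
#'   \item{layout}{path to a GFF3 or chromosome-size TSV (required).}
#'   \item{gap, span_cap, window}{chaining and co-occurrence parameters;
#'     defaults 200, 500, 200 nt. `span_cap: null` disables the cap.}
#'   \item{size_metric}{`distinct_tfs` (default) or `total_sites`.}
#'   \item{summit_col}{BED fourth column is a summit offset (default false).}
#'   \item{include_singletons}{occurrence denominator includes singletons
#'     (default false).}
#'   \item{fit_k_min}{smallest size entering the tail fits (default 1).}
#'   \item{null_reps, seed}{Monte-Carlo replicates (default 200) and seed
#'     (default 1).}
#'   \item{linkage}{hierarchical linkage (default `average`).}
#'   \item{outdir}{output directory (required).}
#' }
#'
#' @param path YAML file.
#' @param overrides named list applied on top of the file values.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) {
    stop("config error: file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a plain list of configuration values.
#' @export
as_run_config <- function(cfg) {
  defaults <- list(gap = 200, span_cap = 500, window = 200,
                   size_metric = "distinct_tfs", summit_col = FALSE,
                   include_singletons = FALSE, fit_k_min = 1L,
                   null_reps = 200L, seed = 1L, linkage = "average")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("beds", "layout", "outdir")) {
    if (is.null(cfg[[k]])) stop("config error: missing `", k, "`", call. = FALSE)
  }
  if (length(cfg$beds) < 1L || is.null(names(cfg$beds)) ||
      any(!nzchar(names(cfg$beds)))) {
    stop("config error: `beds` must map TF labels to paths", call. = FALSE)
  }
  if (cfg$gap <= 0 || cfg$window <= 0) {
    stop("config error: `gap` and `window` must be > 0", call. = FALSE)
  }
  missing <- !vapply(unlist(cfg$beds), file.exists, logical(1))
  if (any(missing)) {
    stop("config error: BED file not found: ",
         paste(unlist(cfg$beds)[missing], collapse = ", "), call. = FALSE)
  }
  if (!file.exists(cfg$layout)) {
    stop("config error: layout file not found: ", cfg$layout, call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' One-shot driver mirroring the standard data flow: load chromosome sizes
#' and per-TF peak files, chain summits into binding clusters, write the
#' clusters and their size histograms, per-TF occurrence, power-law and
#' exponential tail fits, the Monte-Carlo null of the size distribution,
#' the windowed co-occurrence and correlation matrices, the hierarchical TF
#' ordering and a correlation heatmap, plus a run log recording every
#' parameter. Identical config and seed give numerically identical outputs.
#'
#' Outputs are first written with a `.partial` suffix and renamed on success,
#' so an interrupted run leaves only `.partial` files behind.
#'
#' @param config a `run_config` from [read_run_config()]/[as_run_config()].
#' @return Named character vector of output paths, invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  final <- c(clusters = "clusters.bed",
             size_histogram = "size_histogram.tsv",
             occurrence = "occurrence.tsv",
             tail_fits = "tail_fits.tsv",
             null_model = "null_model.tsv",
             cooccurrence = "cooccurrence.tsv",
             correlation = "correlation.tsv",
             heatmap = "heatmap.svg",
             log = "run_log.txt")
  final <- vapply(final, function(f) file.path(config$outdir, f), "")
  tmp <- paste0(final, ".partial")
  names(tmp) <- names(final)

  layout <- stage("load_layout", read_chromosome_lengths(config$layout))
  sitesets <- stage("load_beds", lapply(names(config$beds), function(tf) {
    read_simplified_bed(config$beds[[tf]], tf, layout = layout,
                        summit_col = config$summit_col)
  }))

  params <- cluster_params(gap = config$gap, span_cap = config$span_cap,
                           size_metric = config$size_metric)
  clusters <- stage("cluster", build_clusters(sitesets, params))
  stage("write_clusters", write_clusters_bed(clusters, tmp[["clusters"]]))

  hist_tfs <- size_histogram(clusters, "distinct_tfs")
  hist_sites <- size_histogram(clusters, "total_sites")
  stage("write_histogram", {
    h <- rbind(cbind(metric = "distinct_tfs", as.data.frame(hist_tfs)),
               cbind(metric = "total_sites", as.data.frame(hist_sites)))
    write_table_tsv(h, tmp[["size_histogram"]])
  })

  occ <- stage("occurrence",
               tf_occurrence(clusters,
                             include_singletons = config$include_singletons))
  stage("write_occurrence", write_table_tsv(as.data.frame(occ),
                                            tmp[["occurrence"]]))

  headline <- if (config$size_metric == "distinct_tfs") hist_tfs else hist_sites
  fits <- stage("tail_fits", {
    lapply(c("power_law", "exponential"), function(mod) {
      f <- tryCatch(fit_tail(headline, mod, k_min = config$fit_k_min),
                    error = function(e) NULL)
      if (is.null(f)) {
        data.frame(model = mod, slope = NA_real_, intercept = NA_real_,
                   r_squared = NA_real_, k_min = config$fit_k_min,
                   n_points = NA_integer_)
      } else {
        data.frame(model = f$model, slope = f$slope, intercept = f$intercept,
                   r_squared = f$r_squared, k_min = f$k_min,
                   n_points = f$n_points)
      }
    })
  })
  stage("write_tail_fits",
        write_table_tsv(do.call(rbind, fits), tmp[["tail_fits"]]))

  null <- stage("null_model", {
    counts <- stats::setNames(vapply(sitesets, nrow, 0L),
                              vapply(sitesets, tf_label, ""))
    simulate_null(layout, counts, params, reps = config$null_reps,
                  seed = config$seed, observed = headline)
  })
  stage("write_null", write_table_tsv(as.data.frame(null), tmp[["null_model"]]))

  coocc <- stage("cooccurrence", pairwise_cooccurrence(sitesets,
                                                       window = config$window))
  stage("write_cooccurrence", write_matrix_tsv(coocc, tmp[["cooccurrence"]]))

  corr <- stage("correlation", correlation_matrix(coocc))
  stage("write_correlation", write_matrix_tsv(corr, tmp[["correlation"]]))

  ordering <- stage("ordering", hierarchical_order(corr,
                                                   linkage = config$linkage))
  stage("heatmap", render_heatmap(corr, ordering, tmp[["heatmap"]]))

  stage("write_log", {
    lines <- c(
      paste0("tfclust ", as.character(utils::packageVersion("tfclust"))),
      paste0("gap\t", config$gap),
      paste0("span_cap\t", if (is.null(config$span_cap)) "off" else config$span_cap),
      paste0("window\t", config$window),
      paste0("size_metric\t", config$size_metric),
      paste0("include_singletons\t", config$include_singletons),
      paste0("fit_k_min\t", config$fit_k_min),
      paste0("null_reps\t", config$null_reps),
      paste0("seed\t", config$seed),
      paste0("linkage\t", config$linkage),
      paste0("layout\t", config$layout),
      vapply(names(config$beds), function(tf) {
        paste0("bed\t", tf, "\t", config$beds[[tf]])
      }, ""),
      paste0("n_clusters\t", nrow(clusters$clusters)),
      paste0("n_sites\t", nrow(clusters$members)),
      paste0("leaf_order\t", paste(ordering$order, collapse = ",")))
    writeLines(lines, tmp[["log"]])
  })

  ok <- file.rename(tmp, final)
  if (!all(ok)) stop("stage 'finalize' failed: could not rename outputs",
                     call. = FALSE)
  invisible(final)
}
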