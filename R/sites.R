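#' Construct a site set
#'
#' A site set holds all binding sites of one transcription factor as point
#' positions (peak summits) together with their source peak intervals. Sites
#' are kept sorted by (chromosome, position).
#'
#' @param tf_label non-empty TF name.
#' @param chrom chromosome of each site.
#' @param position 0-based summit position of each site.
#' @param start,end 0-based half-open source interval; default a 1-nt interval
#'   at the summit.
#' @return A `site_set`: a data frame with columns `chrom`, `position`,
#'   `start`, `end` and attribute `tf_label`.
#' @export
site_set <- function(tf_label, chrom = character(), position = integer(),
                     start = position, end = position + 1) {
  if (!is.character(tf_label) || length(tf_label) != 1L || !nzchar(tf_label)) {
    stop("`tf_label` must be a non-empty string", call. = FALSE)
  }
  chrom <- as.character(chrom)
  position <- as.numeric(position)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(position)) {
    if (any(start < 0) || any(start >= end)) {
      stop("need 0 <= start < end for every source interval", call. = FALSE)
    }
    if (any(position < start) || any(position >= end)) {
      stop("every summit position must lie inside its source interval",
           call. = FALSE)
    }
  }
  out <- data.frame(chrom = chrom, position = position, start = start,
                    end = end, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tf_label") <- tf_label
  class(out) <- c("site_set", "data.frame")
  out
}

#' TF label of a site set
#' @param x a [site_set()].
#' @return The TF label string.
#' @export
tf_label <- function(x) attr(x, "tf_label")

#' Read a simplified BED file of ChIP-seq peaks
#'
#' The simplified BED carries one peak per line: `chrom`, `start`, `end`
#' (0-based half-open), optionally a fourth numeric column. Each peak is
#' reduced to a single site position, the peak summit. When no summit column
#' is available the summit falls back to the interval midpoint,
#' `floor((start + end) / 2)`; with `summit_col = TRUE` a numeric fourth
#' column is taken as the summit offset from `start`.
#'
#' Lines beginning with `track`, `browser` or `#` are skipped. Strand, if
#' present, is ignored. Duplicate records are retained (with a message)
#' unless `dedup = TRUE`.
#'
#' @param path path to the BED file.
#' @param tf_label TF name to attach to the sites.
#' @param layout optional [genome_layout()]; when given, records on unknown
#'   chromosomes or extending past the chromosome end are an error.
#' @param summit_col interpret a numeric fourth column as summit offset.
#' @param dedup drop exact duplicate records.
#' @return A [site_set()], sorted by (chromosome, position).
#' @export
read_simplified_bed <- function(path, tf_label, layout = NULL,
                                summit_col = FALSE, dedup = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_data <- nzchar(trimws(lines)) &
    !grepl("^(track|browser|#)", lines)
  idx <- which(is_data)
  if (length(idx) == 0L) return(site_set(tf_label))

  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- vapply(parts, length, 0L)
  if (any(nf < 3L)) {
    stop("line ", idx[which(nf < 3L)[1]],
         ": expected at least 3 tab-separated fields", call. = FALSE)
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad)) {
    stop("line ", idx[which(bad)[1]], ": non-integer coordinates",
         call. = FALSE)
  }
  bad <- start < 0 | start >= end
  if (any(bad)) {
    stop("line ", idx[which(bad)[1]],
         ": need 0 <= start < end", call. = FALSE)
  }

  position <- floor((start + end) / 2)
  if (summit_col) {
    off <- rep(NA_real_, length(parts))
    has4 <- nf >= 4L
    off[has4] <- suppressWarnings(as.numeric(
      vapply(parts[has4], `[[`, "", 4L)))
    use <- !is.na(off)
    if (any(use)) {
      bad <- use & (off < 0 | off != floor(off) | off >= end - start)
      if (any(bad)) {
        stop("line ", idx[which(bad)[1]],
             ": summit offset outside [0, end - start)", call. = FALSE)
      }
      position[use] <- start[use] + off[use]
    }
  }

  if (!is.null(layout)) {
    stopifnot(inherits(layout, "genome_layout"))
    known <- match(chrom, layout$name)
    if (anyNA(known)) {
      stop("line ", idx[which(is.na(known))[1]], ": chromosome '",
           chrom[which(is.na(known))[1]], "' not in genome layout",
           call. = FALSE)
    }
    over <- end > layout$length[known]
    if (any(over)) {
      stop("line ", idx[which(over)[1]],
           ": interval extends past chromosome end", call. = FALSE)
    }
  }

  rec <- data.frame(chrom = chrom, position = position, start = start,
                    end = end, stringsAsFactors = FALSE)
  ndup <- sum(duplicated(rec))
  if (ndup > 0L) {
    if (dedup) {
      rec <- rec[!duplicated(rec), , drop = FALSE]
      message(ndup, " duplicate record(s) dropped from ", basename(path))
    } else {
      message(ndup, " duplicate record(s) retained in ", basename(path))
    }
  }
  site_set(tf_label, rec$chrom, rec$position, rec$start, rec$end)
}

#' @export
print.site_set <- function(x, ...) {
  cat(sprintf("Site set '%s': %d site(s) on %d chromosome(s)\n",
              tf_label(x), nrow(x), length(unique(x$chrom))))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
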