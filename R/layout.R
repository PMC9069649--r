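#' Construct a genome layout
#'
#' A genome layout is the coordinate universe of an analysis: an ordered set
#' of chromosome names with their lengths in nucleotides. It is used to
#' validate peak coordinates on input and to place sites uniformly at random
#' in the Monte-Carlo null model.
#'
#' @param name character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths (nucleotides, > 0).
#' @return A `genome_layout`: a data frame with columns `name` and `length`,
#'   in the order given.
#' @examples
#' genome_layout(c("Chr1", "Chr2"), c(30427671, 19698289))
#' @export
genome_layout <- function(name, length) {
  name <- as.character(name)
  length <- as.numeric(length)
  if (length(name) != length(length)) {
    stop("`name` and `length` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(name)) {
    stop("duplicate chromosome name: ",
         paste(unique(name[duplicated(name)]), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(length)) || any(length <= 0) || any(length != floor(length))) {
    stop("all chromosome lengths must be positive integers", call. = FALSE)
  }
  out <- data.frame(name = name, length = length, stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Total genome length of a layout
#'
#' @param layout a [genome_layout()].
#' @return Sum of chromosome lengths (numeric, nucleotides).
#' @export
genome_length <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(layout$length)
}

#' Read chromosome names and lengths
#'
#' Reads the chromosome metadata that defines the coordinate universe, from
#' either a GFF3 file (the `##sequence-region <name> <start> <end>` pragma
#' lines; 1-based inclusive ranges are converted to lengths) or a two-column
#' tab-separated file of `name<TAB>length`.
#'
#' @param path path to the GFF3 or TSV file.
#' @param format `"auto"` (GFF3 when the file carries sequence-region pragmas
#'   or a `##gff-version` header, TSV otherwise), `"gff3"`, or `"tsv"`.
#' @return A [genome_layout()], chromosome order as first appearance in the
#'   file.
#' @export
read_chromosome_lengths <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(grepl("^##(gff-version|sequence-region)", lines))) "gff3" else "tsv"
  }
  if (format == "gff3") {
    prag <- grep("^##sequence-region\\s", lines, value = TRUE)
    if (length(prag) == 0L) {
      stop("no ##sequence-region pragma lines found in GFF3 file: ", path,
           call. = FALSE)
    }
    parts <- strsplit(trimws(prag), "\\s+")
    bad <- vapply(parts, function(p) length(p) < 4L, logical(1))
    if (any(bad)) {
      stop("malformed ##sequence-region pragma in ", path, call. = FALSE)
    }
    nm <- vapply(parts, `[[`, "", 2L)
    start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4L)))
    if (any(is.na(start)) || any(is.na(end)) || any(end < start)) {
      stop("malformed ##sequence-region coordinates in ", path, call. = FALSE)
    }
    genome_layout(nm, end - start + 1)
  } else {
    keep <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
    if (length(keep) == 0L) stop("no data lines in ", path, call. = FALSE)
    parts <- strsplit(keep, "\t", fixed = TRUE)
    if (any(vapply(parts, length, 0L) < 2L)) {
      stop("chromosome-size TSV needs two tab-separated columns: ", path,
           call. = FALSE)
    }
    nm <- vapply(parts, `[[`, "", 1L)
    len <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    if (any(is.na(len))) stop("non-numeric chromosome length in ", path, call. = FALSE)
    genome_layout(nm, len)
  }
}

#' Write a genome layout as a two-column TSV
#'
#' @param layout a [genome_layout()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chromosome_lengths <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  writeLines(paste(layout$name, format(layout$length, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("Genome layout: %d chromosome(s), %s nt total\n",
              nrow(x), format(sum(x$length), big.mark = ",", scientific = FALSE)))
  print.data.frame(x, ...)
  invisible(x)
}
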