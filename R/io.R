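#' Read mapped tags from a BED or tag-list file
#'
#' A "tag" is a uniquely mapped single-end read reduced to the genomic
#' position of its fragment-proximal 5' end. For a BED record this is
#' `chromStart` on the forward strand and `chromEnd - 1` (the right-most
#' aligned base) on the reverse strand. The plain tag-list format carries the
#' reduction already: three tab-separated columns `chrom`, `pos`, `strand`.
#' All coordinates are 0-based; intervals are half-open.
#'
#' @param path Path to the input file.
#' @param format `"bed"` (>= 6 columns, strand in column 6) or `"taglist"`
#'   (3 columns: chrom, 0-based position, strand).
#' @return A tibble with columns `chrom` (character), `pos` (integer, 0-based
#'   5'-end position) and `strand` (`"+"` or `"-"`), sorted by
#'   `(chrom, pos)`.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t125\tr1\t0\t+", "chr1\t100\t125\tr2\t0\t-"), tf)
#' read_tags(tf)
#' @export
read_tags <- function(path, format = c("bed", "taglist")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("no tags in '", path, "'")
    return(tibble::tibble(chrom = character(), pos = integer(),
                          strand = character()))
  }
  fields <- strsplit(lines, "[\t ]+")
  ncols <- lengths(fields)
  need <- if (format == "bed") 6L else 3L
  bad <- which(ncols < need)
  if (length(bad)) {
    stop("malformed ", format, " record at line ", bad[1L], " of '", path,
         "': expected >= ", need, " fields, found ", ncols[bad[1L]])
  }
  mat <- vapply(fields, function(f) f[seq_len(need)], character(need))
  if (format == "bed") {
    chrom <- mat[1L, ]
    start <- suppressWarnings(as.integer(mat[2L, ]))
    end <- suppressWarnings(as.integer(mat[3L, ]))
    strand <- mat[6L, ]
    bad <- which(is.na(start) | is.na(end))
    if (length(bad)) stop("non-numeric coordinate at line ", bad[1L],
                          " of '", path, "'")
    pos <- ifelse(strand == "+", start, end - 1L)
  } else {
    chrom <- mat[1L, ]
    pos <- suppressWarnings(as.integer(mat[2L, ]))
    bad <- which(is.na(pos))
    if (length(bad)) stop("non-numeric position at line ", bad[1L],
                          " of '", path, "'")
    strand <- mat[3L, ]
  }
  strand <- normalize_strand(strand, path)
  tags <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                         strand = strand)
  if (any(tags$pos < 0L)) stop("negative tag position in '", path, "'")
  dplyr::arrange(tags, .data$chrom, .data$pos)
}

normalize_strand <- function(strand, path = "<input>") {
  out <- dplyr::case_match(strand,
                           c("+", "F", "f", "forward") ~ "+",
                           c("-", "R", "r", "reverse") ~ "-",
                           .default = NA_character_)
  bad <- which(is.na(out))
  if (length(bad)) {
    stop("unknown strand symbol '", strand[bad[1L]], "' in '", path, "'")
  }
  out
}

#' Write tags as a three-column tag list
#'
#' Inverse of [read_tags()] with `format = "taglist"`; round-trips every
#' `(chrom, pos, strand)` triple.
#'
#' @param tags Tag tibble (`chrom`, `pos`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tags <- function(tags, path) {
  df <- dplyr::arrange(tags, .data$chrom, .data$pos)
  write.table(df[, c("chrom", "pos", "strand")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write detected binding regions as BED6+
#'
#' One half-open interval per region with name, tag count as score placeholder
#' and extra columns `count`, `density`, `pvalue`, `qvalue`. Regions are
#' written in coordinate order (lexicographic chromosome, then start).
#'
#' @param regions Region tibble from [detect_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  if (nrow(regions) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  df <- dplyr::arrange(regions, .data$chrom, .data$start)
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = sprintf("region_%d", seq_len(nrow(df))),
                    score = df$count, strand = ".",
                    count = df$count,
                    density = signif(df$density, 6),
                    pvalue = signif(df$pvalue, 6),
                    qvalue = signif(df$qvalue, 6))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write detected binding sites as single-base BED
#'
#' Each site becomes a 1-bp interval `[pos, pos + 1)`. The name encodes the
#' source region and the strand evidence (`F`, `R` or `FR`); the score column
#' carries the relative binding affinity (regression slope).
#'
#' @param sites Site tibble from [detect_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  if (nrow(sites) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  df <- dplyr::arrange(sites, .data$chrom, .data$pos)
  region_id <- if ("region_id" %in% names(df)) df$region_id else
    rep(NA_integer_, nrow(df))
  out <- data.frame(chrom = df$chrom, start = df$pos, end = df$pos + 1L,
                    name = sprintf("site_r%s_%s",
                                   ifelse(is.na(region_id), "NA", region_id),
                                   df$evidence),
                    score = signif(df$affinity, 6), strand = ".")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read reference centers (or truth sites) from a BED file
#'
#' Used by the evaluation step: each interval contributes its midpoint,
#' `floor((start + end) / 2)`.
#'
#' @param path BED file path (>= 3 columns).
#' @return Tibble with `chrom` and `pos` (integer centers), sorted.
#' @export
read_centers <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer()))
  }
  fields <- strsplit(lines, "[\t ]+")
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stop("malformed BED record at line ", bad[1L],
                        " of '", path, "'")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.integer(vapply(fields, `[[`, "", 2L))
  end <- as.integer(vapply(fields, `[[`, "", 3L))
  dplyr::arrange(
    tibble::tibble(chrom = chrom, pos = as.integer((start + end) %/% 2L)),
    .data$chrom, .data$pos)
}
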