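#' Standardised binding regions around detected sites
#'
#' A standardised binding region (SBR) is a fixed-width window (default
#' 200 bp) centred at each detected site, used to compare detections across
#' methods on a common footing. The left edge is clipped at position 0
#' (shortening the window near a chromosome start).
#'
#' @param sites Site tibble (`chrom`, `pos`).
#' @param width Window width in bp (even).
#' @return Tibble (`chrom`, `start`, `end`) of half-open SBR intervals.
#' @examples
#' make_sbrs(tibble::tibble(chrom = "chr1", pos = 1000L))
#' @export
make_sbrs <- function(sites, width = 200) {
  stopifnot(width %% 2 == 0)
  half <- width %/% 2L
  tibble::tibble(chrom = sites$chrom,
                 start = pmax(0L, as.integer(sites$pos - half)),
                 end = as.integer(sites$pos + half))
}

#' Resolution of detections against reference centers
#'
#' For each detected site, the distance to the nearest reference center
#' (simulation truth, or motif centers supplied as BED) on the same
#' chromosome; reported as the full distance list plus the fraction of
#' sites within each threshold. Matching is unconstrained — one reference
#' may be nearest to several sites.
#'
#' @param sites Site tibble (`chrom`, `pos`).
#' @param reference Reference tibble (`chrom`, `pos`), non-empty.
#' @param thresholds Distances (bp) at which to report fractions.
#' @return A list of class `"resolution_report"`: `distances` tibble
#'   (per-site nearest distance), `fractions` tibble (`threshold`,
#'   `fraction`), `n_sites`, `n_reference`.
#' @export
resolution_metrics <- function(sites, reference, thresholds = c(5, 10, 20)) {
  if (nrow(reference) == 0L) stop("empty reference center list")
  dist <- purrr::map_dbl(seq_len(nrow(sites)), function(i) {
    refs <- reference$pos[reference$chrom == sites$chrom[i]]
    if (length(refs) == 0L) return(Inf)
    min(abs(refs - sites$pos[i]))
  })
  fractions <- tibble::tibble(
    threshold = sort(thresholds),
    fraction = purrr::map_dbl(sort(thresholds), function(th) {
      if (length(dist) == 0L) return(NA_real_)
      mean(dist <= th)
    }))
  structure(
    list(distances = tibble::tibble(chrom = sites$chrom, pos = sites$pos,
                                    distance = dist),
         fractions = fractions,
         n_sites = nrow(sites), n_reference = nrow(reference)),
    class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  cat("<resolution_report> ", x$n_sites, " site(s) vs ", x$n_reference,
      " reference center(s)\n", sep = "")
  if (x$n_sites > 0L) {
    cat(sprintf("  median distance: %.1f bp\n",
                stats::median(x$distances$distance)))
    for (i in seq_len(nrow(x$fractions))) {
      cat(sprintf("  within %3d bp: %5.1f%%\n", x$fractions$threshold[i],
                  100 * x$fractions$fraction[i]))
    }
  }
  invisible(x)
}

#' @rdname resolution_metrics
#' @param x A `resolution_report`.
#' @param ... Unused.
#' @export
tidy.resolution_report <- function(x, ...) {
  x$fractions
}

#' @rdname resolution_metrics
#' @export
glance.resolution_report <- function(x, ...) {
  tibble::tibble(n_sites = x$n_sites, n_reference = x$n_reference,
                 median_distance = if (x$n_sites) {
                   stats::median(x$distances$distance)
                 } else NA_real_)
}
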