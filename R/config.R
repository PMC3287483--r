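#' Pipeline configuration
#'
#' Collects every tunable parameter of the two-step pipeline in one list, with
#' the defaults used throughout: tags closer than `gap` bp are clustered;
#' clusters with fewer than `min_tags` tags or spanning less than `min_len` bp
#' are dropped before testing; regions are kept at Benjamini-Hochberg
#' `fdr`; the densest `top_fraction` of regions feed fragment-length
#' estimation; the fragment-length gamma has shape `alpha` and maximum
#' `max_frag` bp; per-base counts are smoothed over `smooth_b` bp; the fitting
#' window is `round(window_frac * L)` bp; near-duplicate site calls from
#' opposite strands are merged below `merge_dist` bp; candidate peaks need a
#' slope of at least `slope_frac` times the strand maximum.
#'
#' @param gap Maximum distance (bp) between successive tags in one cluster.
#' @param min_tags Minimum tag count for a cluster to be tested.
#' @param min_len Minimum cluster span (bp) for a cluster to be tested.
#' @param fdr False discovery rate for region calls (q-value cutoff).
#' @param top_fraction Fraction of densest regions used for fragment-length
#'   estimation.
#' @param alpha Gamma shape of the fragment-length distribution.
#' @param smooth_b Smoothing window (bp) for per-base tag-start counts.
#' @param window_frac Fitting-window width as a fraction of the mean fragment
#'   length; must lie in (0, 1).
#' @param max_frag Maximum fragment length D (bp), set by size selection.
#' @param effective_genome Effective (mappable) genome size in bp; the default
#'   2.4e9 is 80% of the human genome, appropriate for ~30-nt reads.
#' @param merge_dist Two strand calls closer than this (bp) become one site.
#' @param slope_frac Minimum slope relative to the per-strand maximum for a
#'   peak to be reported.
#' @param fragment_length Mean fragment length L in bp, or `"estimate"` to
#'   estimate it from the densest regions.
#' @param seed Optional integer seed forwarded to the simulator.
#'
#' @return A named list of class `"chipsite_config"`.
#' @examples
#' cfg <- site_config(fdr = 0.05)
#' cfg$gap
#' @export
site_config <- function(gap = 30, min_tags = 10, min_len = 100, fdr = 0.10,
                        top_fraction = 0.05, alpha = 10, smooth_b = 20,
                        window_frac = 0.8, max_frag = 300,
                        effective_genome = 2.4e9, merge_dist = 20,
                        slope_frac = 0.5, fragment_length = "estimate",
                        seed = NULL) {
  stopifnot(gap >= 0, min_tags >= 0, min_len >= 0,
            fdr > 0, fdr < 1,
            top_fraction > 0, top_fraction <= 1,
            alpha > 0, smooth_b >= 1,
            window_frac > 0, window_frac < 1,
            max_frag > 0, effective_genome > 0,
            merge_dist >= 0, slope_frac >= 0)
  if (!identical(fragment_length, "estimate")) {
    stopifnot(is.numeric(fragment_length), fragment_length > 0)
  }
  structure(
    list(gap = gap, min_tags = min_tags, min_len = min_len, fdr = fdr,
         top_fraction = top_fraction, alpha = alpha, smooth_b = smooth_b,
         window_frac = window_frac, max_frag = max_frag,
         effective_genome = effective_genome, merge_dist = merge_dist,
         slope_frac = slope_frac, fragment_length = fragment_length,
         seed = seed),
    class = "chipsite_config"
  )
}

#' @export
print.chipsite_config <- function(x, ...) {
  cat("<chipsite_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-17s %s\n", nm, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}
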