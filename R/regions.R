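#' Cluster nearby tags into candidate enriched regions
#'
#' Groups tags into maximal runs in which successive 5'-end positions on the
#' same chromosome differ by at most `gap` bp (default 30). Region detection
#' pools both strands; single-strand clustering is used by the fragment-size
#' estimator and the strand-geometry diagnostics.
#'
#' @param tags Tag tibble (`chrom`, `pos`, `strand`), sorted by
#'   `(chrom, pos)`; unsorted input is an error.
#' @param gap Maximum within-cluster distance between successive tags (bp).
#' @param strand `"both"` (pool strands), `"forward"` or `"reverse"`.
#' @return Tibble with one row per cluster: `chrom`, `start`, `end`
#'   (half-open, spanning member tag positions), `count`.
#' @examples
#' tags <- tibble::tibble(chrom = "chr1", pos = c(100L, 125L, 200L),
#'                        strand = "+")
#' cluster_tags(tags, gap = 30)
#' @export
cluster_tags <- function(tags, gap = 30,
                         strand = c("both", "forward", "reverse")) {
  strand <- match.arg(strand)
  stopifnot(gap >= 0)
  if (strand != "both") {
    want <- if (strand == "forward") "+" else "-"
    tags <- dplyr::filter(tags, .data$strand == want)
  }
  if (nrow(tags) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), count = integer()))
  }
  if (is.unsorted(order(tags$chrom, tags$pos), strictly = FALSE) ||
      any(diff(order(tags$chrom, tags$pos)) != 1L)) {
    stop("tags must be sorted by (chrom, pos); see read_tags()")
  }
  new_chrom <- c(TRUE, tags$chrom[-1L] != tags$chrom[-nrow(tags)])
  jump <- c(TRUE, diff(tags$pos) > gap)
  grp <- cumsum(new_chrom | jump)
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(chrom = tags$chrom, pos = tags$pos,
                                   grp = grp), .data$grp),
    chrom = .data$chrom[1L],
    start = min(.data$pos),
    end = max(.data$pos) + 1L,
    count = dplyr::n(),
    .groups = "drop"
  )[, c("chrom", "start", "end", "count")]
}

#' Drop clusters too small or too short to test
#'
#' Clusters with fewer than `min_tags` tags or spanning less than `min_len`
#' bp are removed before enrichment testing; sparse or jagged short stacks
#' are dominated by noise and poison site fitting. Both bounds are inclusive
#' on the keep side.
#'
#' @param clusters Cluster tibble from [cluster_tags()].
#' @param min_tags Minimum member tag count (default 10).
#' @param min_len Minimum span in bp (default 100).
#' @return The filtered cluster tibble.
#' @export
filter_clusters <- function(clusters, min_tags = 10, min_len = 100) {
  dplyr::filter(clusters, .data$count >= min_tags,
                .data$end - .data$start >= min_len)
}

count_in_window <- function(sorted_pos, lo, hi) {
  # number of positions in [lo, hi); sorted_pos ascending integers
  findInterval(hi - 0.5, sorted_pos) - findInterval(lo - 0.5, sorted_pos)
}

#' Dynamic local Poisson rate for each cluster
#'
#' The null tag rate for a cluster is the most conservative of several
#' per-base rates. Without a control library:
#' \deqn{\lambda_{local} = \max(\lambda_{BG}, \lambda_{5k}, \lambda_{10k})}
#' where \eqn{\lambda_{BG}} is the genome-wide rate (total tags divided by
#' the effective genome size) and \eqn{\lambda_{5k}}, \eqn{\lambda_{10k}}
#' are measured in 5-kb and 10-kb windows centred at the cluster midpoint in
#' the ChIP data itself. With a control library:
#' \deqn{\lambda_{local} = \max(\lambda_{BG}, R\,\lambda_{control},
#'   R\,\lambda_{control,1k})}
#' with \eqn{\lambda_{control}} measured on the cluster's own interval in
#' the control, \eqn{\lambda_{control,1k}} in the 1-kb window at its
#' midpoint, and \eqn{R} the ChIP/control depth ratio. Windows are truncated
#' at position 0 and rates use the truncated width.
#'
#' @param clusters Cluster tibble (`chrom`, `start`, `end`).
#' @param chip_tags Full ChIP tag tibble.
#' @param control_tags Optional control tag tibble.
#' @param effective_genome Effective genome size (bp).
#' @return `clusters` with rate columns added (all in tags/bp):
#'   `lambda_bg`, then either `lambda_5k`/`lambda_10k` or
#'   `lambda_control`/`lambda_control_1k`/`r_control2chip`, and
#'   `lambda_local`.
#' @export
local_lambda <- function(clusters, chip_tags, control_tags = NULL,
                         effective_genome = 2.4e9) {
  stopifnot(effective_genome > 0)
  lambda_bg <- nrow(chip_tags) / effective_genome
  mid <- (clusters$start + clusters$end) %/% 2L

  window_rate <- function(tag_tbl, center, chrom, width) {
    lo <- pmax(0, center - width %/% 2L)
    hi <- center + width %/% 2L
    by_chrom <- split(sort(tag_tbl$pos), tag_tbl$chrom)[
      as.character(chrom)]
    n <- vapply(seq_along(center), function(i) {
      p <- by_chrom[[i]]
      if (is.null(p)) 0L else count_in_window(p, lo[i], hi[i])
    }, integer(1))
    n / (hi - lo)
  }

  if (is.null(control_tags)) {
    lambda_5k <- window_rate(chip_tags, mid, clusters$chrom, 5000L)
    lambda_10k <- window_rate(chip_tags, mid, clusters$chrom, 10000L)
    out <- dplyr::mutate(clusters,
                         lambda_bg = lambda_bg,
                         lambda_5k = lambda_5k,
                         lambda_10k = lambda_10k,
                         lambda_local = pmax(lambda_bg, lambda_5k,
                                             lambda_10k))
  } else {
    if (nrow(control_tags) == 0L) {
      stop("control tag set is empty; omit `control_tags` to use the ",
           "ChIP data itself as local background")
    }
    r <- nrow(chip_tags) / nrow(control_tags)
    by_chrom <- split(sort(control_tags$pos), control_tags$chrom)[
      as.character(clusters$chrom)]
    n_own <- vapply(seq_len(nrow(clusters)), function(i) {
      p <- by_chrom[[i]]
      if (is.null(p)) 0L else
        count_in_window(p, clusters$start[i], clusters$end[i])
    }, integer(1))
    lambda_control <- n_own / (clusters$end - clusters$start)
    lambda_control_1k <- window_rate(control_tags, mid, clusters$chrom,
                                     1000L)
    out <- dplyr::mutate(clusters,
                         lambda_bg = lambda_bg,
                         lambda_control = lambda_control,
                         lambda_control_1k = lambda_control_1k,
                         r_control2chip = r,
                         lambda_local = pmax(lambda_bg, r * lambda_control,
                                             r * lambda_control_1k))
  }
  out
}

#' Upper-tail Poisson p-value for a cluster's tag count
#'
#' Under the null the cluster's tag count is Poisson with mean
#' `lambda_local * region_len`; the p-value is the inclusive upper tail
#' `P(X >= count)`.
#'
#' @param count Observed tag count(s).
#' @param lambda_local Per-base null rate(s), tags/bp.
#' @param region_len Cluster span(s), bp.
#' @return p-value(s), vectorised over the inputs.
#' @examples
#' poisson_pvalue(3, 0.01, 100) # mean 1
#' @export
poisson_pvalue <- function(count, lambda_local, region_len) {
  if (any(count < 0) || any(lambda_local < 0) || any(region_len < 0)) {
    stop("count, lambda_local and region_len must be nonnegative")
  }
  ppois(count - 1, lambda_local * region_len, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment: with p-values ranked from most to least significant,
#' the raw ratio `p * Count / Rank` is monotonised by a cumulative minimum
#' from the least significant end and capped at 1, then mapped back to input
#' order. Regions are kept when `q <= fdr`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_qvalues <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  p.adjust(pvalues, method = "BH")
}

# Per-base tag-start counts of `positions` over [start, end), as a vector of
# length end - start (index 1 = position `start`).
position_counts <- function(positions, start, end) {
  tabulate(positions - start + 1L, nbins = end - start)
}

#' Refine region boundaries by the local noise level
#'
#' Within each cluster the pooled-strand per-base tag-start counts are
#' smoothed ([smooth_counts()], window `smooth_b`); the refined region is the
#' interval between the outermost bases whose smoothed density exceeds the
#' cluster's `lambda_local`. If no base exceeds the noise level the original
#' bounds are kept, with a warning.
#'
#' @param clusters Cluster tibble with a `lambda_local` column (see
#'   [local_lambda()]).
#' @param tags Tag tibble covering the clusters.
#' @param smooth_b Smoothing window (bp).
#' @return `clusters` with `refined_start` and `refined_end` columns.
#' @export
refine_boundaries <- function(clusters, tags, smooth_b = 20) {
  stopifnot("lambda_local" %in% names(clusters))
  if (nrow(clusters) == 0L) {
    return(dplyr::mutate(clusters, refined_start = integer(),
                         refined_end = integer()))
  }
  by_chrom <- split(sort(tags$pos), tags$chrom)
  res <- purrr::map(seq_len(nrow(clusters)), function(i) {
    start <- clusters$start[i]; end <- clusters$end[i]
    p <- by_chrom[[as.character(clusters$chrom[i])]]
    p <- p[p >= start & p < end]
    if (length(p) == 0L) {
      stop("cluster ", i, " has no member tags")
    }
    s <- smooth_counts(position_counts(p, start, end), b = smooth_b)
    above <- which(s > clusters$lambda_local[i])
    if (length(above) == 0L) {
      warning("no base above the noise level in cluster ", i,
              "; keeping original bounds")
      c(start, end)
    } else {
      c(start + min(above) - 1L, start + max(above))
    }
  })
  dplyr::mutate(clusters,
                refined_start = as.integer(vapply(res, `[`, 0, 1L)),
                refined_end = as.integer(vapply(res, `[`, 0, 2L)))
}

#' Detect tag-enriched binding regions
#'
#' Step one of the pipeline: cluster pooled-strand tags ([cluster_tags()]),
#' drop untestably small clusters ([filter_clusters()]), compute the dynamic
#' local background ([local_lambda()]), test each cluster with the
#' upper-tail Poisson model ([poisson_pvalue()]), adjust across all tested
#' clusters ([bh_qvalues()]), keep clusters with `q <= fdr`, and refine
#' boundaries against the noise level ([refine_boundaries()]).
#'
#' @param tags ChIP tag tibble (`chrom`, `pos`, `strand`).
#' @param control Optional control tag tibble.
#' @param config A [site_config()].
#' @return Tibble of binding regions sorted by coordinate: cluster columns,
#'   rate columns, `pvalue`, `qvalue`, `density` (tags/bp over the original
#'   span), `refined_start`, `refined_end` and `region_id`.
#' @export
detect_regions <- function(tags, control = NULL, config = site_config()) {
  cl <- cluster_tags(tags, gap = config$gap, strand = "both")
  cl <- filter_clusters(cl, min_tags = config$min_tags,
                        min_len = config$min_len)
  if (nrow(cl) == 0L) {
    return(dplyr::mutate(cl, lambda_local = double(), pvalue = double(),
                         qvalue = double(), density = double(),
                         refined_start = integer(), refined_end = integer(),
                         region_id = integer()))
  }
  cl <- local_lambda(cl, tags, control_tags = control,
                     effective_genome = config$effective_genome)
  cl$pvalue <- poisson_pvalue(cl$count, cl$lambda_local,
                              cl$end - cl$start)
  cl$qvalue <- bh_qvalues(cl$pvalue)
  cl <- dplyr::filter(cl, .data$qvalue <= config$fdr)
  if (nrow(cl) == 0L) {
    return(dplyr::mutate(cl, density = double(),
                         refined_start = integer(), refined_end = integer(),
                         region_id = integer()))
  }
  cl <- refine_boundaries(cl, tags, smooth_b = config$smooth_b)
  cl <- dplyr::mutate(cl, density = .data$count / (.data$end - .data$start))
  cl <- dplyr::arrange(cl, .data$chrom, .data$start)
  dplyr::mutate(cl, region_id = dplyr::row_number())
}

#' Densest regions
#'
#' A region's density is its total tag count divided by its span. The
#' densest `top_fraction` of regions (default the top 5%) anchor the
#' fragment-size estimate, because their strand-specific stacks are the
#' cleanest.
#'
#' @param regions Region tibble with `density` (and `count`) columns.
#' @param top_fraction Fraction in (0, 1] of regions to keep.
#' @return The `ceiling(top_fraction * nrow)` densest regions, sorted by
#'   density descending (ties: higher count, then coordinate).
#' @export
rank_by_density <- function(regions, top_fraction = 0.05) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  if (nrow(regions) == 0L) return(regions)
  df <- dplyr::arrange(regions, dplyr::desc(.data$density),
                       dplyr::desc(.data$count), .data$chrom, .data$start)
  head(df, ceiling(top_fraction * nrow(df)))
}
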