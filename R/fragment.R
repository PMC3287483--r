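#' Density center of a single-strand tag stack
#'
#' The tag-count-weighted arithmetic mean position of a stack's member tags.
#'
#' @param x Numeric vector of tag positions, or a tibble with a `pos` column.
#' @return The mean position (real-valued bp).
#' @examples
#' density_center(c(100, 100, 130))
#' @export
density_center <- function(x) {
  pos <- if (is.data.frame(x)) x$pos else x
  if (length(pos) == 0L) stop("empty tag stack has no density center")
  mean(pos)
}

#' Estimate the mean ChIP fragment length from the densest regions
#'
#' In a region driven by one site, forward-strand 5' ends pile up one arm
#' length upstream of the site and reverse-strand 5' ends one arm length
#' downstream, so the distance between the two strand stack centers
#' estimates the full fragment length. Within each of the densest regions
#' (see [rank_by_density()]) tags are clustered per strand; the centers of
#' the largest forward and largest reverse cluster give one distance
#' `d1 = reverse center - forward center`, and the estimate `L` is the mean
#' of the positive `d1` values. Regions missing a strand, or with `d1 <= 0`
#' (overlapping or inverted stacks, typical of multi-site regions), are
#' skipped and counted in a message.
#'
#' @param regions Region tibble (needs `chrom`, `start`, `end`, `density`,
#'   `count`).
#' @param tags Tag tibble covering the regions.
#' @param top_fraction Fraction of densest regions to use (default 0.05).
#' @param gap Clustering gap for the per-strand sub-clustering (bp).
#' @return The estimated mean fragment length in bp.
#' @export
estimate_fragment_length <- function(regions, tags, top_fraction = 0.05,
                                     gap = 30) {
  top <- rank_by_density(regions, top_fraction)
  if (nrow(top) == 0L) {
    stop("no regions available for fragment length estimation; ",
         "set `fragment_length` explicitly")
  }
  d1 <- purrr::map_dbl(seq_len(nrow(top)), function(i) {
    reg <- top[i, ]
    in_reg <- dplyr::filter(tags, .data$chrom == reg$chrom,
                            .data$pos >= reg$start, .data$pos < reg$end)
    centers <- purrr::map_dbl(c("forward", "reverse"), function(str) {
      cl <- cluster_tags(dplyr::arrange(in_reg, .data$chrom, .data$pos),
                         gap = gap, strand = str)
      if (nrow(cl) == 0L) return(NA_real_)
      big <- cl[which.max(cl$count), ]
      want <- if (str == "forward") "+" else "-"
      density_center(in_reg$pos[in_reg$strand == want &
                                  in_reg$pos >= big$start &
                                  in_reg$pos < big$end])
    })
    centers[2L] - centers[1L]
  })
  usable <- !is.na(d1) & d1 > 0
  if (!any(usable)) {
    stop("no region with usable forward/reverse stacks; ",
         "set `fragment_length` explicitly")
  }
  if (any(!usable)) {
    message(sum(!usable), " of ", length(d1),
            " top-density regions skipped in fragment length estimation")
  }
  mean(d1[usable])
}

#' Build the single-site tag-density template
#'
#' The fragment length `l` is modelled as Gamma(shape `alpha`, mean `L`).
#' A fragment straddles its binding site with two arms whose lengths sum to
#' `l`; since gamma shapes add at a common scale, one arm length is
#' Gamma(shape `alpha/2`, scale `L/alpha`), with mean `L/2`. A tag's 5' end
#' sits one arm length from the site, so the probability that a tag starts
#' `d` bp from the site is the arm-length mass on `(d-1, d]`, attenuated for
#' `d` near the maximum fragment length `D` by the chance
#' `Q(D - d)` that the opposite arm fits inside the size selection
#' (approximately 1 for `d < L < D`). The discrete weights are renormalised
#' to sum to one over `d = 0..D`.
#'
#' For the defaults `L = 120`, `alpha = 10`, `D = 300` the template peaks
#' 49 bp from the site.
#'
#' @param L Mean fragment length (bp), > 0.
#' @param alpha Gamma shape of the fragment length (default 10; `alpha >= 2`
#'   so the arm shape is at least 1).
#' @param D Maximum fragment length from size selection (bp), > `L`.
#' @return An object of class `"tag_profile"`: a list with `alpha`, `L`,
#'   `scale`, `D`, `f_tag` (numeric weights for offsets `0..D`) and `mode`
#'   (the argmax offset).
#' @examples
#' prof <- build_profile(L = 120)
#' prof$mode
#' @export
build_profile <- function(L, alpha = 10, D = 300) {
  stopifnot(L > 0, alpha >= 2, D > L)
  scale <- L / alpha
  d <- 0:D
  arm_mass <- pgamma(d, shape = alpha / 2, scale = scale) -
    pgamma(d - 1, shape = alpha / 2, scale = scale)
  trunc <- pgamma(D - d, shape = alpha / 2, scale = scale)
  f <- arm_mass * trunc
  f <- f / sum(f)
  structure(
    list(alpha = alpha, L = L, scale = scale, D = D, f_tag = f,
         mode = d[which.max(f)]),
    class = "tag_profile"
  )
}

#' @export
print.tag_profile <- function(x, ...) {
  cat("<tag_profile> gamma arm-length tag density template\n")
  cat(sprintf("  fragment length L = %.1f bp (shape %.1f, scale %.2f)\n",
              x$L, x$alpha, x$scale))
  cat(sprintf("  max fragment D = %d bp; peak offset %d bp\n",
              as.integer(x$D), as.integer(x$mode)))
  invisible(x)
}

#' @rdname build_profile
#' @param x A `tag_profile`.
#' @param ... Unused.
#' @export
tidy.tag_profile <- function(x, ...) {
  tibble::tibble(offset = 0:x$D, density = x$f_tag)
}

#' @rdname build_profile
#' @export
glance.tag_profile <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, L = x$L, scale = x$scale, D = x$D,
                 mode = x$mode)
}

#' Strand-geometry diagnostics of a binding region
#'
#' Three distances summarise the strand structure of a region:
#' `d1`, the distance from the forward-strand stack center to the
#' reverse-strand stack center; `d2`, the lag from the forward center to the
#' end of the forward stack (last base whose smoothed forward density
#' exceeds `lambda_local`); and `d3`, the lag from the start of the reverse
#' stack to the reverse center. For a single site `d1` approximates the
#' fragment length and `d2 + d3 < d1`; overlapping stacks with
#' `d2 + d3 > d1` flag multiple closely spaced sites.
#'
#' @param region One-row region tibble (`chrom`, `start`, `end`).
#' @param tags Tag tibble covering the region.
#' @param lambda_local Per-base noise level used as the stack boundary
#'   threshold.
#' @param smooth_b Smoothing window (bp).
#' @return A one-row tibble: `fwd_center`, `rev_center`, `d1`, `d2`, `d3`.
#' @export
stack_geometry <- function(region, tags, lambda_local, smooth_b = 20) {
  stopifnot(nrow(region) == 1L)
  in_reg <- dplyr::filter(tags, .data$chrom == region$chrom,
                          .data$pos >= region$start, .data$pos < region$end)
  fwd <- in_reg$pos[in_reg$strand == "+"]
  rev_ <- in_reg$pos[in_reg$strand == "-"]
  if (length(fwd) == 0L || length(rev_) == 0L) {
    stop("stack geometry requires tags on both strands")
  }
  fwd_center <- mean(fwd)
  rev_center <- mean(rev_)
  s_fwd <- smooth_counts(position_counts(fwd, region$start, region$end),
                         b = smooth_b)
  s_rev <- smooth_counts(position_counts(rev_, region$start, region$end),
                         b = smooth_b)
  above_f <- which(s_fwd > lambda_local)
  above_r <- which(s_rev > lambda_local)
  fwd_stack_end <- if (length(above_f)) region$start + max(above_f) - 1L else
    max(fwd)
  rev_stack_start <- if (length(above_r)) region$start + min(above_r) - 1L else
    min(rev_)
  tibble::tibble(fwd_center = fwd_center, rev_center = rev_center,
                 d1 = rev_center - fwd_center,
                 d2 = fwd_stack_end - fwd_center,
                 d3 = rev_center - rev_stack_start)
}
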