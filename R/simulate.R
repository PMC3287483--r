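with_opt_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Draw tag positions for one binding site on one strand
#'
#' Tags are placed independently with the template probabilities: a tag's
#' offset `d` from the site is drawn from `f_tag`, and the 5' end lands at
#' `p_bs - d` on the forward strand (upstream of the site) or `p_bs + d` on
#' the reverse strand (downstream). Positions are clipped at 0.
#'
#' @param p_bs True binding-site position (bp).
#' @param w Number of tags to draw.
#' @param profile A [build_profile()] template.
#' @param strand `"forward"` or `"reverse"`.
#' @return Integer vector of `w` tag positions.
#' @export
sample_site_tags <- function(p_bs, w, profile,
                             strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  stopifnot(inherits(profile, "tag_profile"), w >= 0)
  if (w == 0L) return(integer(0))
  d <- sample(0:profile$D, w, replace = TRUE, prob = profile$f_tag)
  pos <- if (strand == "forward") p_bs - d else p_bs + d
  as.integer(pmax(pos, 0L))
}

#' Simulate one tag-enriched region
#'
#' Draws `w` tags per strand for each binding site from the tag-density
#' template and pools them; tag counts at every position accumulate across
#' sites. This reproduces the benchmark conditions of the method's
#' simulation study (single sites and pairs of adjacent sites, no
#' background noise at the region level).
#'
#' @param sites Integer vector of true site positions (strictly
#'   increasing).
#' @param w Tag budget per strand: per site (default) or per region,
#'   depending on `budget`.
#' @param profile A [build_profile()] template.
#' @param chrom Chromosome name for the emitted tags.
#' @param seed Optional integer seed; fixing it makes the draw
#'   reproducible.
#' @param budget `"per_site"` draws `w` tags per strand for every site;
#'   `"per_region"` splits `w` equally across the sites (rounded down),
#'   fixing the region's per-strand depth instead.
#' @return A list with `tags` (tag tibble sorted by position) and `truth`
#'   (tibble `chrom`, `pos`, `site_id`, `w`).
#' @examples
#' prof <- build_profile(L = 120)
#' sim <- simulate_region(c(500, 560), w = 100, profile = prof, seed = 1)
#' nrow(sim$tags)
#' @export
simulate_region <- function(sites, w, profile, chrom = "sim", seed = NULL,
                            budget = c("per_site", "per_region")) {
  budget <- match.arg(budget)
  stopifnot(all(diff(sites) > 0) || length(sites) <= 1L, w >= 1 ||
              length(sites) == 0L)
  w_site <- if (budget == "per_region" && length(sites) > 0L) {
    max(1L, w %/% length(sites))
  } else {
    w
  }
  with_opt_seed(seed, {
    draws <- purrr::map(sites, function(p) {
      tibble::tibble(
        chrom = chrom,
        pos = c(sample_site_tags(p, w_site, profile, "forward"),
                sample_site_tags(p, w_site, profile, "reverse")),
        strand = rep(c("+", "-"), each = w_site))
    })
    tags <- dplyr::arrange(
      dplyr::bind_rows(c(list(tibble::tibble(chrom = character(),
                                             pos = integer(),
                                             strand = character())), draws)),
      .data$chrom, .data$pos)
    truth <- tibble::tibble(chrom = chrom, pos = as.integer(sites),
                            site_id = seq_along(sites), w = w_site)
    list(tags = tags, truth = truth)
  })
}

#' Single region spanning a tag set
#'
#' Convenience for benchmarking the site-detection step on simulated
#' region-level data, where the enriched region is simply the span of the
#' drawn tags and region detection is not involved.
#'
#' @param tags Tag tibble (one chromosome).
#' @return One-row region tibble (`chrom`, `start`, `end`) covering all
#'   tag positions, half-open.
#' @export
tag_span_region <- function(tags) {
  stopifnot(nrow(tags) > 0L, length(unique(tags$chrom)) == 1L)
  tibble::tibble(chrom = tags$chrom[1L], start = min(tags$pos),
                 end = max(tags$pos) + 1L)
}

#' Simulate a toy genome-wide ChIP experiment
#'
#' Plants single-site regions at random, well-separated loci on one toy
#' chromosome and overlays uniform Poisson background tags on both strands.
#' Unlike the region-level simulations this exercises the full pipeline
#' including region detection.
#'
#' @param n_regions Number of planted binding sites.
#' @param w Tags per site per strand.
#' @param profile A [build_profile()] template.
#' @param genome_len Toy chromosome length (bp).
#' @param background_rate Uniform background tag rate per strand
#'   (tags/bp).
#' @param min_sep Minimum separation between planted sites (bp).
#' @param chrom Chromosome name.
#' @param seed Optional integer seed.
#' @param max_tries Redraws allowed before giving up on a non-overlapping
#'   placement.
#' @return A list with `tags` and `truth` as in [simulate_region()].
#' @export
simulate_experiment <- function(n_regions = 20, w = 100,
                                profile = build_profile(L = 120),
                                genome_len = 2e6, background_rate = 1e-4,
                                min_sep = 5000, chrom = "sim", seed = NULL,
                                max_tries = 100) {
  stopifnot(genome_len > 0, n_regions >= 0, background_rate >= 0)
  with_opt_seed(seed, {
    sites <- integer(0)
    if (n_regions > 0L) {
      lo <- profile$D; hi <- genome_len - profile$D
      stopifnot(hi > lo)
      for (k in seq_len(max_tries)) {
        sites <- sort(as.integer(runif(n_regions, lo, hi)))
        if (n_regions < 2L || min(diff(sites)) >= min_sep) break
        if (k == max_tries) {
          stop("could not place ", n_regions, " sites >= ", min_sep,
               " bp apart in ", genome_len, " bp")
        }
      }
    }
    sim <- if (n_regions > 0L) {
      simulate_region(sites, w, profile, chrom = chrom)
    } else {
      list(tags = tibble::tibble(chrom = character(), pos = integer(),
                                 strand = character()),
           truth = tibble::tibble(chrom = character(), pos = integer(),
                                  site_id = integer(), w = integer()))
    }
    bg <- purrr::map(c("+", "-"), function(str) {
      n_bg <- rpois(1L, genome_len * background_rate)
      tibble::tibble(chrom = chrom,
                     pos = as.integer(runif(n_bg, 0, genome_len)),
                     strand = str)
    })
    tags <- dplyr::arrange(dplyr::bind_rows(c(list(sim$tags), bg)),
                           .data$chrom, .data$pos)
    list(tags = tags, truth = sim$truth)
  })
}
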