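# Small in-code fixtures and independent oracles shared across tests.

make_tags <- function(pos, strand = "+", chrom = "chr1") {
  df <- tibble::tibble(chrom = chrom, pos = as.integer(pos), strand = strand)
  dplyr::arrange(df, chrom, pos)
}

# Quadratic transitive-closure clustering oracle: two tags are linked when
# their positions differ by <= gap; clusters are the connected components.
oracle_cluster <- function(pos, gap) {
  pos <- sort(pos)
  n <- length(pos)
  if (n == 0L) return(integer(0))
  linked <- outer(pos, pos, function(a, b) abs(a - b) <= gap)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (linked[i, j] && grp[j] != grp[i]) {
          grp[grp == grp[j]] <- grp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(grp, unique(grp))
}

# Direct quadratic moving average with edge truncation.
oracle_smooth <- function(t, b) {
  C <- length(t)
  left <- (b - 1) %/% 2
  right <- b - 1 - left
  sapply(seq_len(C), function(n) {
    w <- max(1, n - left):min(C, n + right)
    mean(t[w])
  })
}

# Step-up BH oracle straight from the rank formula.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_raw <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q_raw)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

default_profile <- function() build_profile(L = 120, alpha = 10, D = 300)

# Pooled per-site benchmark: for each rep, distances from every detected
# site to its nearest true site, concatenated across reps.
sim_site_dists <- function(sites, w, profile, config = site_config(),
                           n_rep = 100) {
  unlist(lapply(seq_len(n_rep), function(i) {
    sim <- simulate_region(sites, w = w, profile = profile)
    st <- suppressWarnings(
      detect_sites(sim$tags, tag_span_region(sim$tags), profile, config))
    vapply(st$pos, function(p) min(abs(sim$truth$pos - p)), 0)
  }))
}

# Region-level simulation benchmark: distance from each truth-nearest
# detected site, Inf when nothing is detected.
sim_site_errors <- function(sites, w, profile, config = site_config(),
                            n_rep = 20, budget = "per_site") {
  replicate(n_rep, {
    sim <- simulate_region(sites, w = w, profile = profile, budget = budget)
    st <- suppressWarnings(
      detect_sites(sim$tags, tag_span_region(sim$tags), profile, config))
    if (nrow(st) == 0L) Inf else
      min(vapply(st$pos, function(p) min(abs(sim$truth$pos - p)), 0))
  })
}
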