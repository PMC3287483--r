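test_that("count smoothing is a truncated centred box filter", {
  expect_equal(smooth_counts(rep(3, 50), b = 20), rep(3, 50))
  imp <- rep(0, 101)
  imp[51] <- 1
  s <- smooth_counts(imp, b = 20)
  expect_equal(sum(s > 0), 20L)
  expect_equal(unique(s[s > 0]), 1 / 20)
  withr::local_seed(3)
  t <- rpois(200, 2)
  expect_equal(smooth_counts(t, b = 20), oracle_smooth(t, 20))
  expect_equal(smooth_counts(t, b = 7), oracle_smooth(t, 7))
})

test_that("window fits match the no-intercept normal equations", {
  prof <- default_profile()
  x <- prof$f_tag[1:96]
  fit <- window_fit(c(2 * x, rep(0, 10)), 1, x)
  expect_equal(fit$beta, 2, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(window_fit(rep(0, 200), 5, x), list(beta = 0, r2 = 0))
  withr::local_seed(8)
  for (rep in 1:5) {
    s <- runif(150)
    j <- sample(1:(150 - 96 + 1), 1)
    fit <- window_fit(s, j, x)
    y <- s[j:(j + 95)]
    ref <- lm(y ~ x + 0)
    expect_equal(fit$beta, unname(coef(ref)), tolerance = 1e-10)
    expect_equal(fit$r2, 1 - sum(resid(ref)^2) / sum(y^2),
                 tolerance = 1e-10)
    expect_gte(fit$r2, 0)
    expect_lte(fit$r2, 1)
  }
})

test_that("the sliding scan agrees with per-window fits", {
  prof <- default_profile()
  sim <- simulate_region(1000L, w = 50, profile = prof, seed = 2)
  reg <- tag_span_region(sim$tags)
  sp <- strand_profile(sim$tags, reg, "reverse", b = 20)
  W <- 96
  curve <- scan_region(sp, prof, W)
  x <- prof$f_tag[1:W]
  for (j in c(1, 57, nrow(curve))) {
    fit <- window_fit(sp$s, j, x)
    expect_equal(curve$beta[j], fit$beta, tolerance = 1e-12)
    expect_equal(curve$r2[j], fit$r2, tolerance = 1e-12)
  }
  expect_equal(nrow(curve), sp$C - W + 1)
})

test_that("each strand's best fit localises a deep simulated site", {
  prof <- default_profile()
  cfg <- site_config()
  sim <- simulate_region(1000L, w = 200, profile = prof, seed = 5)
  reg <- tag_span_region(sim$tags)
  for (str in c("forward", "reverse")) {
    sp <- strand_profile(sim$tags, reg, str, b = 20)
    curve <- scan_region(sp, prof, 96)
    expect_lte(abs(curve$pos[which.max(curve$r2)] - 1000), 5)
    expect_true(all(curve$r2 >= 0 & curve$r2 <= 1))
  }
})

test_that("pure noise fits worse than a true site at equal depth", {
  prof <- default_profile()
  withr::local_seed(6)
  noise_max <- replicate(10, {
    tags <- make_tags(sort(sample(1000:1600, 100, replace = TRUE)),
                      strand = "-", chrom = "sim")
    sp <- strand_profile(tags, tag_span_region(tags), "reverse", b = 20)
    max(scan_region(sp, prof, 96)$r2)
  })
  site_max <- replicate(10, {
    sim <- simulate_region(1300L, w = 100, profile = prof)
    sp <- strand_profile(sim$tags, tag_span_region(sim$tags), "reverse",
                         b = 20)
    max(scan_region(sp, prof, 96)$r2)
  })
  expect_gt(min(site_max), max(noise_max))
})

test_that("peak extraction enforces slope and separation rules", {
  bump <- function(center, pos, height, width = 12)
    height * exp(-(pos - center)^2 / (2 * width^2))
  pos <- 1:200
  two_far <- tibble::tibble(pos = pos,
                            r2 = bump(60, pos, 0.9) + bump(110, pos, 0.8),
                            beta = 5)
  expect_equal(nrow(extract_peaks(two_far)), 2L)
  two_near <- tibble::tibble(pos = pos,
                             r2 = bump(60, pos, 0.9) + bump(75, pos, 0.85),
                             beta = 5)
  got <- extract_peaks(two_near)
  expect_equal(nrow(got), 1L)
  expect_lt(abs(got$pos - 60), 8) # the higher-R2 summit wins
  weak <- tibble::tibble(pos = pos,
                         r2 = bump(60, pos, 0.9) + bump(140, pos, 0.8),
                         beta = ifelse(abs(pos - 60) < 25, 10, 1))
  expect_equal(extract_peaks(weak)$pos, 60)
  expect_equal(nrow(extract_peaks(two_far[0, ])), 0L)
})

test_that("strand merging pairs nearby calls and keeps singletons", {
  f <- tibble::tibble(pos = 500L, beta = 4, r2 = 0.9)
  r <- tibble::tibble(pos = 510L, beta = 2, r2 = 0.8)
  m <- merge_strands(f, r)
  expect_equal(m$pos, 505L)
  expect_equal(m$evidence, "FR")
  expect_equal(m$affinity, 3)
  r2 <- tibble::tibble(pos = 530L, beta = 2, r2 = 0.8)
  m2 <- merge_strands(f, r2)
  expect_equal(m2$pos, c(500L, 530L))
  expect_equal(m2$evidence, c("F", "R"))
  m3 <- merge_strands(tibble::tibble(pos = 400L, beta = 1, r2 = 0.5),
                      tibble::tibble(pos = integer(), beta = double(),
                                     r2 = double()))
  expect_equal(m3$evidence, "F")
  # exactly at the merge distance stays separate
  m4 <- merge_strands(f, tibble::tibble(pos = 520L, beta = 1, r2 = 0.5))
  expect_equal(nrow(m4), 2L)
})

test_that("site detection is shift-equivariant and mirror-symmetric", {
  prof <- default_profile()
  cfg <- site_config()
  sim <- simulate_region(c(1000L, 1080L), w = 60, profile = prof, seed = 13)
  reg <- tag_span_region(sim$tags)
  base <- detect_sites(sim$tags, reg, prof, cfg)
  expect_gt(nrow(base), 0L)
  # translation by +k moves every site by exactly +k
  k <- 3170L
  shifted <- dplyr::mutate(sim$tags, pos = pos + k)
  s2 <- detect_sites(shifted, tag_span_region(shifted), prof, cfg)
  expect_equal(s2$pos, base$pos + k)
  expect_equal(s2$affinity, base$affinity)
  # mirroring (reflect coordinates, swap strands) reflects the calls
  M <- 5000L
  mirrored <- dplyr::arrange(
    dplyr::mutate(sim$tags, pos = M - pos,
                  strand = ifelse(strand == "+", "-", "+")),
    chrom, pos)
  s3 <- detect_sites(mirrored, tag_span_region(mirrored), prof, cfg)
  expect_equal(nrow(s3), nrow(base))
  # the even smoothing window and floored merge midpoints each allow a
  # 1-bp skew under reflection
  expect_true(all(abs(sort(M - s3$pos) - sort(base$pos)) <= 2))
})

test_that("reported sites respect separation, slope floor and bounds", {
  prof <- default_profile()
  cfg <- site_config()
  sim <- simulate_region(c(2000L, 2060L, 2300L), w = 80, profile = prof,
                         seed = 21)
  reg <- tag_span_region(sim$tags)
  sites <- detect_sites(sim$tags, reg, prof, cfg)
  if (nrow(sites) > 1L) {
    expect_true(all(diff(sort(sites$pos)) >= cfg$merge_dist))
  }
  expect_true(all(sites$affinity > 0))
  expect_true(all(sites$pos >= reg$start & sites$pos < reg$end))
  # a region carrying only forward tags yields forward-only evidence
  fwd <- dplyr::filter(sim$tags, strand == "+")
  sf <- detect_sites(fwd, tag_span_region(fwd), prof, cfg)
  expect_true(all(sf$evidence == "F"))
  # no tags at all: empty result
  empty <- detect_sites(sim$tags[0, ], reg[0, ], prof, cfg)
  expect_equal(nrow(empty), 0L)
})

test_that("low-depth single-site regions stay essentially unsplit", {
  # at 10 tags/strand the two strand estimates scatter by ~10 bp each, so
  # they occasionally land >= 20 bp apart and survive as an F + R pair;
  # a clear majority of runs still yields a single merged call and no run
  # splinters into more than two
  prof <- default_profile()
  withr::local_seed(30)
  n_calls <- replicate(40, {
    sim <- simulate_region(1000L, w = 10, profile = prof)
    st <- suppressWarnings(
      detect_sites(sim$tags, tag_span_region(sim$tags), prof,
                   site_config()))
    nrow(st)
  })
  expect_gte(mean(n_calls == 1L), 0.65)
  expect_true(all(n_calls <= 2L))
})

test_that("fit_region exposes broom-style summaries", {
  prof <- default_profile()
  sim <- simulate_region(700L, w = 100, profile = prof, seed = 9)
  fit <- fit_region(sim$tags, tag_span_region(sim$tags), prof)
  expect_s3_class(fit, "site_fit")
  expect_equal(tidy(fit), fit$sites)
  g <- glance(fit)
  expect_equal(g$n_sites, nrow(fit$sites))
  expect_equal(g$W, 96)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(prof), "ggplot")
})
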