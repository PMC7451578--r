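test_that("Welch test matches the reference implementation and behaves antisymmetrically", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5, 6)
  w <- welch_t_test(a, b)
  ref <- stats::t.test(a, b)
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)
  expect_identical(sign(w$t), sign(w$mean_diff))

  sw <- welch_t_test(b, a)
  expect_equal(sw$t, -w$t, tolerance = 1e-14)
  expect_equal(sw$p, w$p, tolerance = 1e-14)

  same <- welch_t_test(a, a)
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)

  expect_error(welch_t_test(1, a), "at least 2")
  expect_error(welch_t_test(c(1, 1, 1), c(2, 2)), "degenerate")
})

test_that("Welch implementation equals the oracle on random sample pairs", {
  set.seed(301)
  for (rep in 1:200) {
    a <- stats::rnorm(sample(3:30, 1), sd = stats::runif(1, .5, 3))
    b <- stats::rnorm(sample(3:30, 1), mean = stats::runif(1, -1, 1))
    w <- welch_t_test(a, b)
    ref <- stats::t.test(a, b)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("null-model angle sets are seeded, reproducible and pipeline-consistent", {
  n1 <- random_model_null(n = 10, R = 20, n_sets = 2, seed = 5)
  n2 <- random_model_null(n = 10, R = 20, n_sets = 2, seed = 5)
  expect_identical(n1[[1]], n2[[1]])
  expect_identical(n1[[2]], n2[[2]])
  expect_gt(max(abs(n1[[1]] - n1[[2]])), 0)   # sets are independent
  expect_true(all(n1[[1]] >= 0 & n1[[1]] <= pi))
  expect_identical(attr(n1, "R"), 20)
  expect_error(random_model_null(n = 10, R = 1, seed = 1), "at least 2")
})

test_that("eligibility is all-pairs at alpha 1, empty at alpha 0, and catches planted signal", {
  n <- 10
  nulls <- random_model_null(n = n, R = 50, n_sets = 3, seed = 11)
  set.seed(401)
  mk_stack <- function() {
    array(stats::runif(n * n * 8, 0, pi), dim = c(n, n, 8))
  }
  s1 <- mk_stack(); s2 <- mk_stack()

  m_all <- eligible_pairs(s1, s2, nulls, alpha = 1)
  expect_true(all(m_all[upper.tri(m_all)]))
  expect_false(any(diag(m_all)))
  m_none <- eligible_pairs(s1, s2, nulls, alpha = 0)
  expect_false(any(m_none))

  # an ultra-tight pair in group 1 must survive every set's screen
  hits <- 0L
  for (rep in 1:20) {
    set.seed(500 + rep)
    s1p <- mk_stack(); s2p <- mk_stack()
    s1p[1, 2, ] <- s1p[2, 1, ] <- stats::runif(8, 0, .01)
    m <- eligible_pairs(s1p, s2p, nulls, alpha = .05)
    if (m[1, 2]) hits <- hits + 1L
  }
  expect_identical(hits, 20L)
})

test_that("alignment comparison contracts hold: null case, counts, direction, monotonicity", {
  spec <- cohort_spec(n_roi = 12, n_subjects = 6,
                      homotopic_pairs = cbind(1:6, 7:12),
                      blocks = list(1:6, 7:12), seed = 42)
  a1 <- analyze_group(generate_cohort(spec, "g1"))
  expect_identical(
    sum(compare_alignment(a1$angles, a1$angles)$significant), 0L)

  spec2 <- cohort_spec(n_roi = 12, n_subjects = 6,
                       homotopic_pairs = cbind(1:6, 7:12),
                       blocks = list(1:6, 7:12), delta = .7,
                       seed = 43)
  a2 <- analyze_group(generate_cohort(spec2, "g2"))
  cmp <- compare_alignment(a2$angles, a1$angles,
                           labels = c("g2", "g1"))
  expect_identical(sum(cmp$roi_counts),
                   2L * sum(cmp$significant[upper.tri(cmp$significant)]))
  sig_up <- which(cmp$significant & upper.tri(cmp$significant))
  expect_true(all((cmp$direction[sig_up] == "increase") ==
                    (cmp$delta[sig_up] < 0)))

  strict <- compare_alignment(a2$angles, a1$angles, alpha = .01)
  loose <- compare_alignment(a2$angles, a1$angles, alpha = .1)
  expect_true(all(loose$significant[strict$significant]))

  expect_error(compare_alignment(a1$angles[, , 1, drop = FALSE],
                                 a1$angles), "at least 2")
})

test_that("significance never escapes the eligibility mask", {
  spec <- cohort_spec(n_roi = 10, n_subjects = 5,
                      homotopic_pairs = cbind(1:5, 6:10),
                      blocks = list(1:5, 6:10), seed = 52)
  a1 <- analyze_group(generate_cohort(spec, "a"))
  spec2 <- cohort_spec(n_roi = 10, n_subjects = 5,
                       homotopic_pairs = cbind(1:5, 6:10),
                       blocks = list(1:5, 6:10), delta = .8, seed = 53)
  a2 <- analyze_group(generate_cohort(spec2, "b"))
  nulls <- random_model_null(n = 10, R = 60, n_sets = 3, seed = 7)
  mask <- eligible_pairs(a1$angles, a2$angles, nulls)
  cmp <- compare_alignment(a1$angles, a2$angles, mask = mask)
  expect_true(all(mask[cmp$significant]))
  expect_true(all(is.na(cmp$p[!mask])))
})

test_that("centrality comparison flags a planted hub and flips with group order", {
  mk_ec <- function(boost) {
    sapply(1:8, function(s) {
      W <- random_uniform_matrix(12)
      W <- unclass(W)[, ]
      if (boost) { W[3, ] <- W[, 3] <- pmin(.99, W[3, ] + .6) }
      diag(W) <- 0
      fit <- eigenalign(fc_matrix(W))
      fit$ec
    })
  }
  hits <- 0L
  for (rep in 1:20) {
    set.seed(600 + rep)
    ec1 <- mk_ec(FALSE); ec2 <- mk_ec(TRUE)
    cmp <- compare_centrality(ec1, ec2)
    if (cmp$significant[3] && cmp$direction[3] == "decrease")
      hits <- hits + 1L
    flip <- compare_centrality(ec2, ec1)
    expect_equal(flip$t, -cmp$t, tolerance = 1e-12)
  }
  expect_gte(hits, 16L)

  set.seed(700)
  ec <- mk_ec(FALSE)
  expect_identical(sum(compare_centrality(ec, ec)$significant), 0L)
})

test_that("connectivity comparison pinpoints a planted edge shift", {
  template <- function(shift, seed) {
    set.seed(seed)
    mats <- lapply(1:8, function(s) {
      W <- matrix(.4, 10, 10)
      E <- matrix(stats::rnorm(100, sd = .03), 10, 10)
      W <- W + (E + t(E)) / 2
      W[2, 7] <- W[7, 2] <- W[2, 7] + shift
      diag(W) <- 0
      fc_matrix((W + t(W)) / 2)
    })
    subject_group(if (shift > 0) "shifted" else "base", mats)
  }
  g0 <- template(0, 801)
  g1 <- template(.35, 802)
  cmp <- compare_connectivity(g1, g0, alpha = 1e-4)
  sig <- which(cmp$significant & upper.tri(cmp$significant),
               arr.ind = TRUE)
  expect_identical(nrow(sig), 1L)
  expect_identical(as.integer(sig), c(2L, 7L))
  expect_identical(cmp$direction[2, 7], "increase")
  expect_identical(sum(compare_connectivity(g0, g0)$roi_counts), 0L)
})

test_that("widespread connectivity change without stable geometry separates FC from EA counts", {
  # ROI 5's couplings all shift upward but with large per-subject
  # scatter: the FC test sees a clean mean shift per edge, while the
  # angles ROI 5 makes are too erratic for the EA test.
  mk <- function(wobble, seed) {
    set.seed(seed)
    mats <- lapply(1:10, function(s) {
      W <- matrix(.35, 16, 16)
      W[1:8, 1:8] <- .55
      E <- matrix(stats::rnorm(256, sd = .04), 16, 16)
      W <- W + (E + t(E)) / 2
      if (wobble) {
        row <- W[5, ] + .3 + stats::rnorm(16, sd = .2)
        W[5, ] <- W[, 5] <- pmin(.99, pmax(-.99, row))
      }
      diag(W) <- 0
      fc_matrix((W + t(W)) / 2)
    })
    subject_group(if (wobble) "wobble" else "base", mats)
  }
  g0 <- mk(FALSE, 901); g1 <- mk(TRUE, 902)
  fc <- compare_connectivity(g1, g0)
  a0 <- analyze_group(g0); a1 <- analyze_group(g1)
  ea <- compare_alignment(a1$angles, a0$angles)
  expect_gt(fc$roi_counts[5], 2 * ea$roi_counts[5])
  expect_gte(fc$roi_counts[5], 8)
})

test_that("community-size comparison reports all four statistics and detects planted structure", {
  spec_even <- cohort_spec(n_roi = 18, n_subjects = 8,
                           homotopic_pairs = cbind(1:3, 10:12),
                           blocks = list(1:6, 7:12, 13:18),
                           mu_in = .6, mu_out = .1, noise_sd = .05,
                           seed = 61)
  spec_skew <- cohort_spec(n_roi = 18, n_subjects = 8,
                           homotopic_pairs = cbind(1:3, 10:12),
                           blocks = list(1:12, 13:18),
                           mu_in = .6, mu_out = .1, noise_sd = .05,
                           seed = 62)
  a_even <- analyze_group(generate_cohort(spec_even, "even"))
  a_skew <- analyze_group(generate_cohort(spec_skew, "skew"))
  res <- compare_community_sizes(a_even$profiles, a_skew$profiles)
  expect_identical(res$statistic,
                   c("most", "least", "mean_two_most",
                     "mean_two_least"))
  expect_true(all(res$p >= 0 & res$p <= 1))

  same <- compare_community_sizes(a_even$profiles, a_even$profiles)
  expect_true(all(same$t == 0) && all(same$p == 1))
})

test_that("ROI substitution is local, exact and identity-safe", {
  spec <- cohort_spec(n_roi = 10, n_subjects = 6,
                      homotopic_pairs = cbind(1:5, 6:10),
                      blocks = list(1:5, 6:10), seed = 71)
  host <- generate_cohort(spec, "host")
  spec2 <- cohort_spec(n_roi = 10, n_subjects = 6,
                       homotopic_pairs = cbind(1:5, 6:10),
                       blocks = list(1:5, 6:10), delta = .9, seed = 72)
  donor <- generate_cohort(spec2, "donor")

  ident <- substitute_roi(host, host, roi = 4)
  for (m in seq_len(length(ident)))
    expect_equal(unclass(ident$matrices[[m]])[, ],
                 unclass(host$matrices[[m]])[, ], tolerance = 0)

  alt <- substitute_roi(host, donor, roi = 4)
  expect_length(alt, 6L)
  h1 <- unclass(host$matrices[[1]])[, ]
  d1 <- unclass(donor$matrices[[1]])[, ]
  a1 <- unclass(alt$matrices[[1]])[, ]
  expect_identical(a1[4, -4], d1[4, -4])
  expect_identical(a1[-4, 4], d1[-4, 4])
  expect_identical(a1[-4, -4], h1[-4, -4])
  expect_identical(a1[4, 4], 0)
  expect_identical(a1, t(a1))

  expect_error(substitute_roi(host, donor, roi = 11), "1..10")
})

test_that("substituting an alien coupling pattern moves the target ROI's angles most", {
  # donor ROI 2 couples to the opposite block, orthogonal to the host's
  # pattern; distant ROI pairs (not involving 2) stay within noise
  spec_h <- cohort_spec(n_roi = 12, n_subjects = 8,
                        homotopic_pairs = cbind(1:6, 7:12),
                        blocks = list(1:6, 7:12), noise_sd = .05,
                        seed = 81)
  host <- generate_cohort(spec_h, "host")
  set.seed(82)
  donor_mats <- lapply(seq_len(8), function(s) {
    W <- unclass(host$matrices[[s]])[, ]
    W[2, ] <- W[, 2] <- c(rep(.1, 6), rep(.7, 6)) *
      (1 + stats::rnorm(12, sd = .02))
    W[2, 2] <- 0
    fc_matrix((W + t(W)) / 2)
  })
  donor <- subject_group("donor", donor_mats)
  alt <- substitute_roi(host, donor, roi = 2)
  a_host <- analyze_group(host)
  a_alt <- analyze_group(alt)
  dmean <- abs(a_alt$summary$mean_angles - a_host$summary$mean_angles)
  target_shift <- mean(dmean[2, -2])
  distant <- dmean[-2, -2]
  distant_shift <- mean(distant[upper.tri(distant)])
  expect_gt(target_shift, 2 * distant_shift)
})

test_that("flag rates among eligible pairs of identical generators sit at the nominal level", {
  # one 3 x 200-model filter for the generator conditions, reused across
  # the 200 same-generator comparisons (the cohorts are exchangeable
  # draws, so eligibility is a property of the conditions, not of one
  # draw)
  spec_fun <- function(seed)
    cohort_spec(n_roi = 12, n_subjects = 6,
                homotopic_pairs = cbind(1:6, 7:12),
                blocks = list(1:6, 7:12), seed = seed)
  aA <- analyze_group(generate_cohort(spec_fun(9001), "a"))
  aB <- analyze_group(generate_cohort(spec_fun(9002), "b"))
  nulls <- random_model_null(n = 12, R = 200, n_sets = 3, seed = 12)
  mask <- eligible_pairs(aA$angles, aB$angles, nulls)
  expect_gt(sum(mask[upper.tri(mask)]), 0)

  flagged <- 0L; tested <- 0L
  for (rep in 1:200) {
    g1 <- analyze_group(generate_cohort(spec_fun(10000 + rep), "x"))
    g2 <- analyze_group(generate_cohort(spec_fun(20000 + rep), "y"))
    cmp <- compare_alignment(g1$angles, g2$angles, mask = mask)
    flagged <- flagged + sum(cmp$significant[upper.tri(mask)])
    tested <- tested + sum(mask[upper.tri(mask)])
  }
  rate <- flagged / tested
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})
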