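test_that("chain sampling has the exact Gaussian moments and is seeded", {
  # two-bead chain with k = 4: <r^2> = 3/k
  ch <- gaussian_chain(2, 1000, s_ref = 1000)
  ch$k <- 4
  cfg <- sample_chain(ch, 1e5, seed = 6)
  r2 <- (cfg$x[2, ] - cfg$x[1, ])^2 + (cfg$y[2, ] - cfg$y[1, ])^2 +
    (cfg$z[2, ] - cfg$z[1, ])^2
  expect_equal(mean(r2), 3 / 4, tolerance = 0.02)

  # determinism contract
  a <- sample_chain(gaussian_chain(10, 1e4), 5, seed = 3)
  b <- sample_chain(gaussian_chain(10, 1e4), 5, seed = 3)
  expect_identical(a$x, b$x)

  # empty draw
  z <- sample_chain(gaussian_chain(5, 1e4), 0)
  expect_equal(ncol(z$x), 0L)
})

test_that("end-to-end variance grows linearly with bead count", {
  msd <- sapply(c(100, 400), function(n) {
    ch <- gaussian_chain(n, 1e4, -1.5)
    cfg <- sample_chain(ch, 4000, seed = n)
    mean((cfg$x[n, ] - cfg$x[1, ])^2 + (cfg$y[n, ] - cfg$y[1, ])^2 +
           (cfg$z[n, ] - cfg$z[1, ])^2)
  })
  expect_equal(msd[2] / msd[1], 399 / 99, tolerance = 0.1)
})

test_that("contact probabilities behave at the limits and decay with s", {
  ch <- gaussian_chain(50, 1e4, -1.5)
  cfg <- sample_chain(ch, 400, seed = 5)
  P_huge <- contact_probabilities(cfg, radius = 1e3)
  expect_true(all(P_huge == 1))                       # radius -> very large
  P <- unname(contact_probabilities(cfg, radius = contact_radius(ch)))
  expect_equal(P, t(P))
  expect_true(mean(P[cbind(1:49, 2:50)]) > mean(P[cbind(1:40, 11:50)]))
  expect_error(contact_probabilities(cfg, radius = 0), "positive")
})

test_that("the closed-form profile matches Monte Carlo on the ideal chain", {
  ch <- gaussian_chain(200, 1e4, -1.5)
  r <- contact_radius(ch)
  cfg <- sample_chain(ch, 6000, seed = 13)
  P_mc <- contact_probabilities(cfg, r, beads = 100)[1, ]
  P_th <- theoretical_contact_profile(ch, 100, r)
  near <- abs(seq_len(200) - 100) %in% 1:40
  expect_lt(max(abs(P_mc[near] - P_th[near])), 0.025)
  # adjacent-bead contact frequency ~ p_adjacent by the radius definition
  expect_equal(mean(P_mc[c(99, 101)]), 0.5, tolerance = 0.05)
  # pairwise generalized form reproduces its exponent
  ch2 <- gaussian_chain(2000, 1e4, -1.1)
  pr <- theoretical_contact_profile(ch2, 1000, contact_radius(ch2))
  s <- abs(ch2$pos - ch2$pos[1000])
  use <- s >= 1e5 & s <= 5e6
  slope <- coef(lm(log(pr[use]) ~ log(s[use])))[2]
  expect_equal(unname(slope), -1.1, tolerance = 0.05)
})

test_that("deletions splice the chain with correct bookkeeping", {
  ch <- gaussian_chain(100, 1e4, -1.5)
  expect_identical(apply_deletion(ch, NULL), ch)
  d <- apply_deletion(ch, c(40, 60))
  expect_equal(d$n, 100 - 21)
  # genomic length shrinks by the removed material: 22 severed segments
  # replaced by one of summed half-lengths
  expect_equal(d$pos[d$n], ch$pos[100] - (22 * 1e4 - 1e4))
  expect_equal(length(d$seg), d$n - 1)
  expect_true(all(d$k > 0))
  # reference coordinates of retained beads are unchanged
  expect_equal(d$ref_pos, ch$pos[c(1:39, 61:100)])
  expect_error(apply_deletion(ch, c(1, 5)), "inside")
  expect_error(apply_deletion(ch, c(90, 100)), "inside")
})

test_that("deleting beads increases flanking-bead contact probability", {
  ch <- gaussian_chain(300, 1e4, -1.5)
  del <- apply_deletion(ch, c(120, 180))
  r <- contact_radius(ch)
  p_before <- contact_probabilities(sample_chain(ch, 3000, seed = 91), r,
                                    beads = 119)[1, 181]
  flank2 <- which(del$ref_pos == ch$pos[181])
  p_after <- contact_probabilities(sample_chain(del, 3000, seed = 92), r,
                                   beads = 119)[1, flank2]
  expect_gt(p_after, p_before)
})

test_that("FISH distance draws have the Maxwell moments and are seeded", {
  r <- sample_fish_distances(3, 1e5, seed = 8)
  expect_equal(mean(r^2), 1, tolerance = 0.02)        # 3/k
  expect_identical(r, sample_fish_distances(3, 1e5, seed = 8))
  big <- sample_fish_distances(400, 1e4, seed = 9)
  expect_lt(stats::median(big), 0.1)                  # concentrates near 0
})

test_that("capture counts are Poisson at the bias-scaled expectation", {
  ch <- gaussian_chain(40, 1e4, -1.5)
  frags <- as_fragment_map(ch)
  vps <- viewpoint_set("v1", frags$start[20], frags$end[20],
                       chrom = attr(frags, "chrom"))
  P <- matrix(theoretical_contact_profile(ch, 20, contact_radius(ch)),
              nrow = 1)
  depth <- 5e4
  lam_expected <- depth * P[1, ] * frags$length / sum(P[1, ] * frags$length)

  set.seed(55)
  tot <- numeric(40)
  nrep <- 500
  for (i in seq_len(nrep)) {
    ct <- generate_capture_counts(P, frags, vps, depth = depth)
    tot <- tot + ct$count
  }
  emp <- tot / nrep
  se <- sqrt(lam_expected / nrep)
  z <- (emp - lam_expected) / se
  expect_gt(mean(abs(z) < 3), 0.95)
  expect_lt(max(abs(z)), 4.5)

  # depth 0: all counts zero
  ct0 <- generate_capture_counts(P, frags, vps, depth = 0)
  expect_true(all(ct0$count == 0))

  # doubling K doubles every expectation (checked on large-count totals)
  set.seed(1)
  c1 <- generate_capture_counts(P, frags, vps, K = 1, depth = 1e6)
  set.seed(1)
  c2 <- generate_capture_counts(P, frags, vps, K = 2, depth = 1e6)
  expect_equal(sum(c2$count) / sum(c1$count), 2, tolerance = 0.01)

  expect_error(inject_spike(P, frags, vps, c(0, 1e4), c(2e4, 3e4), fold = -2),
               "positive")
})

test_that("the synthetic study is reproducible and shaped as declared", {
  s1 <- simulate_study(seed = 5, n_beads = 600, n_viewpoints = 6,
                       deletion_beads = c(250, 380), depth = 1e5)
  s2 <- simulate_study(seed = 5, n_beads = 600, n_viewpoints = 6,
                       deletion_beads = c(250, 380), depth = 1e5)
  expect_identical(s1$counts, s2$counts)
  expect_setequal(unique(s1$counts$condition), c("del", "WT"))
  expect_setequal(unique(s1$counts$replicate), c("1", "2"))
  # deletion-condition experiments exist only for outside viewpoints
  del_vps <- unique(s1$counts$viewpoint[s1$counts$condition == "del"])
  expect_setequal(del_vps, s1$viewpoints$id[s1$outside])
  expect_equal(s1$deletion[2] - s1$deletion[1],
               sum(s1$frags$length[250:380]))
})
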