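pair3 <- matrix(c(0, 1, 2,
                  1, 0, 3,
                  2, 3, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))

test_that("mean pairwise disparity averages unordered pairs", {
  expect_equal(mean_pairwise_disparity(c("A", "B"), pair3), 1)
  expect_equal(mean_pairwise_disparity(c("A", "B", "C"), pair3), 2)
  expect_error(mean_pairwise_disparity("A", pair3), "fewer than two")
  expect_error(mean_pairwise_disparity(c("A", "Z"), pair3), "Z")
})

test_that("null distribution matches exhaustive enumeration on tiny pools", {
  ns <- null_disparity(2, pair3, n_iter = 4000, seed = 1)
  se <- ns$sd / sqrt(ns$n_iter)
  expect_lt(abs(ns$grand_mean - 2), 3 * se)  # exhaustive mean of pairs 1,2,3

  set.seed(99)
  d8 <- random_disparity(8)
  for (k in c(3, 4)) {
    exact <- exhaustive_null_mean(d8, k)
    ns <- null_disparity(k, d8, n_iter = 5000, seed = k)
    expect_lt(abs(ns$grand_mean - exact), 3 * ns$sd / sqrt(ns$n_iter))
  }
})

test_that("null distribution is seeded, bounded and degenerate at full pool", {
  d <- random_disparity(10)
  a <- null_disparity(4, d, n_iter = 500, seed = 42, observed = 3)
  b <- null_disparity(4, d, n_iter = 500, seed = 42, observed = 3)
  expect_identical(a$null_means, b$null_means)
  expect_identical(a$z, b$z)
  expect_true(a$grand_mean >= min(a$null_means) &&
              a$grand_mean <= max(a$null_means))
  expect_lte(a$ci95[1], a$ci95[2])
  expect_gte(a$ci95[1], min(a$null_means))
  expect_lte(a$ci95[2], max(a$null_means))

  expect_warning(deg <- null_disparity(10, d, n_iter = 50,
                                       observed = sum(d) / 90),
                 "degenerate")
  expect_equal(deg$sd, 0)
  expect_equal(deg$z, 0)
  expect_equal(deg$grand_mean, sum(d) / 90)

  expect_error(null_disparity(11, d), "exceeds pool")
  expect_error(null_disparity(1, d), "at least 2")
})

test_that("Monte-Carlo error of the grand mean shrinks as 1/sqrt(n_iter)", {
  set.seed(5)
  d <- random_disparity(10)
  gm <- function(n_iter) vapply(1:40, function(i)
    null_disparity(3, d, n_iter = n_iter)$grand_mean, numeric(1))
  r <- sd(gm(100)) / sd(gm(2500))
  expect_gt(r, 2.5)   # theoretical ratio 5
  expect_lt(r, 10)
})

test_that("guild restriction intersects membership and drops small communities", {
  comm <- data.frame(
    seep_id = c("s1", "s1", "s1", "s2", "s2", "s2", "s2", "s3", "s3", "s3"),
    species = c("A", "B", "C", "A", "B", "C", "D", "E", "F", "G"))
  vis <- data.frame(species = c("A", "B", "C", "D", "E"),
                    bee_visited = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                    fly_visited = c(TRUE, FALSE, TRUE, TRUE, FALSE))
  # bee guild: s1 and s2 keep {A,B,C}; s3 has no bee-visited species
  expect_message(r <- guild_restrict(comm, vis, "bee"), "s3")
  expect_setequal(r$species[r$seep_id == "s1"], c("A", "B", "C"))
  expect_false("s3" %in% r$seep_id)
  # fly guild: s1 keeps {A,C} (dropped at min 3), s2 keeps {A,C,D}
  expect_message(rf <- guild_restrict(comm, vis, "fly"), "s1")
  expect_setequal(unique(rf$seep_id), "s2")
  expect_setequal(rf$species, c("A", "C", "D"))
  # relaxed threshold retains the two-species community
  suppressMessages(r2 <- guild_restrict(comm, vis, "fly", min_members = 2))
  expect_setequal(unique(r2$seep_id), c("s1", "s2"))
})

test_that("deliberately extreme communities get signed z-scores", {
  set.seed(77)
  d <- random_disparity(20)
  k <- 5
  # greedy max-min selection: most disparate community in the pool
  pick <- function(best) {
    sel <- rownames(d)[which(d == max(d), arr.ind = TRUE)[1, ]]
    while (length(sel) < k) {
      cand <- setdiff(rownames(d), sel)
      score <- vapply(cand, function(s)
        if (best) min(d[s, sel]) else -mean(d[s, sel]), numeric(1))
      sel <- c(sel, cand[which.max(score)])
    }
    sel
  }
  hi <- pick(TRUE)
  zhi <- null_disparity(k, d, n_iter = 2000, seed = 1,
                        observed = mean_pairwise_disparity(hi, d))$z
  expect_gt(zhi, 1)
  lo <- pick(FALSE)
  zlo <- null_disparity(k, d, n_iter = 2000, seed = 2,
                        observed = mean_pairwise_disparity(lo, d))$z
  expect_lt(zlo, 0)
})

test_that("community_dispersion is order-independent and deterministic", {
  set.seed(13)
  d <- random_disparity(15)
  comm <- data.frame(seep_id = rep(c("sA", "sB", "sC"), each = 4),
                     species = c(rownames(d)[1:4], rownames(d)[5:8],
                                 rownames(d)[9:12]))
  r1 <- community_dispersion(comm, d, n_iter = 300, seed = 10)
  r2 <- community_dispersion(comm[sample(nrow(comm)), ], d,
                             n_iter = 300, seed = 10)
  expect_equal(r1, r2)
  expect_equal(r1$richness, rep(4L, 3))
  expect_equal(r1$z, (r1$observed_mean - r1$null_grand_mean) / r1$null_sd)
})
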