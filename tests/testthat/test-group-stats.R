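test_that("circular median handles clusters, wrap-around, and NA", {
  expect_equal(circular_median(c(170, 180, 190)), 180)
  expect_equal(circular_median(c(350, 0, 10)), 0)
  expect_equal(circular_median(c(350, NA, 0, 10)), 0)
  expect_error(circular_median(c(NA_real_, NA_real_)), "no phases")
  # simulation consistency around the twilight median
  set.seed(77)
  ph <- rvonmises_deg(100, 177.6, kappa = 8)
  expect_lt(abs(circ_signed_diff(circular_median(ph), 177.6)), 3)
})

test_that("circular median is rotation-equivariant", {
  set.seed(11)
  for (i in 1:20) {
    ph <- runif(15, 0, 360)
    delta <- runif(1, 0, 360)
    expect_lt(abs(circ_signed_diff(circular_median((ph + delta) %% 360),
                                   (circular_median(ph) + delta) %% 360)),
              1e-9)
  }
})

test_that("signed-rank exact p matches brute-force sign enumeration", {
  # uniformly signed n = 8: the exact two-sided floor 2 / 2^8
  x <- c(0.42, 1.21, 0.57, 1.20, 0.39, 1.22, 0.44, 1.25)
  y <- x - c(0.11, 0.23, 0.05, 0.17, 0.29, 0.41, 0.08, 0.33)
  res <- paired_signed_rank(x, y)
  expect_true(res$exact)
  expect_equal(res$statistic, 36)
  expect_equal(res$p.value, 2 / 2^8)
  expect_equal(res$p.value, enum_signed_rank_p(x - y))
  # random tie-free pairs, n <= 10: exact path == enumeration oracle
  set.seed(123)
  for (i in 1:5) {
    n <- sample(5:10, 1)
    a <- rnorm(n)
    b <- a + rnorm(n, sd = 2)
    res <- paired_signed_rank(a, b)
    expect_true(res$exact)
    expect_equal(res$p.value, enum_signed_rank_p(a - b), tolerance = 1e-12)
  }
})

test_that("signed-rank degenerate and approximate paths behave", {
  x <- c(1, 2, 3)
  expect_error(paired_signed_rank(x, x), "degenerate")
  expect_error(paired_signed_rank(1:3, 1:4), "paired")
  # tie-ridden data fall back to the corrected normal approximation and
  # agree with the reference implementation
  a <- c(1, 2, 2, 3, 3, 3, 5, 6, 7, 9, 9, 4)
  b <- c(2, 1, 4, 3.5, 2, 5, 5.5, 5, 9, 8, 11, 6)
  res <- paired_signed_rank(a, b)
  expect_false(res$exact)
  ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                             correct = TRUE))
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("rank-sum exact p matches arrangement enumeration", {
  res <- rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_true(res$exact)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 0.1)  # 2 / choose(6, 3)
  set.seed(321)
  for (i in 1:5) {
    x <- rnorm(sample(4:7, 1))
    y <- rnorm(sample(4:7, 1), mean = 1)
    expect_equal(rank_sum(x, y)$p.value, enum_rank_sum_p(x, y),
                 tolerance = 1e-12)
  }
  # identical multisets sit at the null center
  res0 <- rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_gte(res0$p.value, 0.9)
  expect_error(rank_sum(numeric(0), 1:3), "nonempty")
})

test_that("rank-sum decisions track the reference test on simulated shifts", {
  set.seed(99)
  mine <- logical(200); ref <- logical(200)
  for (i in 1:200) {
    x <- rnorm(12); y <- rnorm(12, mean = 1)
    mine[i] <- rank_sum(x, y)$p.value < 0.05
    ref[i] <- stats::wilcox.test(x, y, exact = TRUE)$p.value < 0.05
  }
  expect_identical(mine, ref)  # same exact distribution, case by case
  expect_gt(mean(mine), 0.4)   # non-trivial power at this effect size
})

test_that("Kruskal-Wallis H matches direct rank arithmetic", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  res <- kruskal_nemenyi(g)
  # mean ranks 2, 5, 8 -> H = 12/(9*10) * 3*((2-5)^2 + 0 + (8-5)^2) = 7.2
  expect_equal(res$H, 7.2)
  expect_equal(unname(res$mean_ranks), c(2, 5, 8))
  expect_equal(res$p.value, stats::pchisq(7.2, 2, lower.tail = FALSE))
  # identical groups: H ~ 0, all pairwise p ~ 1
  same <- list(c(1, 5, 9), c(5, 1, 9), c(9, 5, 1))
  res0 <- kruskal_nemenyi(same)
  expect_lt(res0$H, 1e-10)
  expect_true(all(res0$pairwise >= 0.999))
  expect_error(kruskal_nemenyi(list(1:3)), ">= 2 groups")
  expect_error(kruskal_nemenyi(list(1:3, numeric(0))), "nonempty")
})

test_that("Kruskal-Wallis agrees with the reference under ties", {
  set.seed(55)
  for (i in 1:10) {
    g <- list(sample(1:5, 8, TRUE), sample(1:5, 9, TRUE),
              sample(1:5, 7, TRUE))
    res <- kruskal_nemenyi(g)
    ref <- stats::kruskal.test(g)
    expect_equal(res$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("tests are invariant to group relabeling", {
  set.seed(14)
  x <- rnorm(9); y <- rnorm(10); z <- rnorm(8)
  a <- kruskal_nemenyi(list(x = x, y = y, z = z))
  b <- kruskal_nemenyi(list(z = z, x = x, y = y))
  expect_equal(a$H, b$H)
  expect_equal(a$pairwise["x", "y"], b$pairwise["x", "y"])
  expect_equal(rank_sum(x, y)$p.value, rank_sum(y, x)$p.value)
})

test_that("two-group Kruskal-Wallis is the squared rank-sum z", {
  set.seed(26)
  x <- rnorm(9); y <- rnorm(11)
  H <- kruskal_nemenyi(list(x, y))$H
  # rank-sum z without continuity correction
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  U <- sum(rank(c(x, y))[1:n1]) - n1 * (n1 + 1) / 2
  z <- (U - n1 * n2 / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(H, z^2, tolerance = 1e-10)
})

test_that("Nemenyi pairwise p is conservative relative to the normal p", {
  set.seed(31)
  for (i in 1:10) {
    g <- list(rnorm(8), rnorm(9, 0.5), rnorm(10, 1))
    res <- kruskal_nemenyi(g)
    sizes <- lengths(g); N <- sum(sizes)
    for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
      se <- sqrt(N * (N + 1) / 12 * (1 / sizes[pr[1]] + 1 / sizes[pr[2]]))
      q <- abs(res$mean_ranks[pr[1]] - res$mean_ranks[pr[2]]) / se
      expect_gte(res$pairwise[pr[1], pr[2]], 2 * pnorm(-q) - 1e-12)
    }
  }
})

test_that("flight metrics follow the duration and rounding rules", {
  b <- flight_bout(0, 10, collisions = 4)
  m <- flight_metrics(b)
  expect_equal(m$duration, 10)
  expect_equal(m$collision_rate, 0.4)
  # skid subtraction happens before rounding: 2.4 - 0.9 = 1.5 -> 2 s
  b2 <- flight_bout(0, 2.4, skids = list(c(1.0, 1.9)), collisions = 1)
  m2 <- flight_metrics(b2)
  expect_equal(m2$duration, 2)
  expect_equal(m2$collision_rate, 0.5)
  expect_equal(flight_metrics(flight_bout(0, 30))$collision_rate, 0)
  # invalid bouts
  expect_error(flight_bout(5, 5), "landing")
  expect_error(flight_bout(0, 10, skids = list(c(-1, 2))), "within")
  expect_error(flight_bout(0, 10, skids = list(c(1, 3), c(2, 4))), "overlap")
  expect_error(flight_metrics(flight_bout(0, 0.4)), "<= 0")
})
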