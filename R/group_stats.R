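#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test for within-animal comparisons (e.g. the
#' same animals under twilight and dark). Zero differences are dropped. With
#' tie-free differences and n <= `exact_max` the p value comes from the exact
#' null distribution of the positive-rank sum (all 2^n sign assignments);
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. With n = 8 uniformly signed tie-free pairs the exact
#' two-sided p is its floor 2 / 2^8 = 0.0078125.
#'
#' @param x,y Paired samples of equal length.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact distribution;
#'   default `NULL` decides by sample size and ties.
#' @param exact_max Largest n for which the exact distribution is used by
#'   default.
#' @return List with `statistic` (V, the positive-rank sum), `p.value`, `n`
#'   (non-zero pairs), `exact`, and `method`.
#' @export
paired_signed_rank <- function(x, y, exact = NULL, exact_max = 25L) {
  if (length(x) != length(y))
    stop("`x` and `y` must be paired (equal length)", call. = FALSE)
  d <- x - y
  d <- d[!is.na(d)]
  nzero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("all paired differences are zero: test is degenerate", call. = FALSE)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (is.null(exact)) exact <- (n <= exact_max) && !ties && nzero == 0L
  if (exact && ties)
    stop("exact p value is not defined with tied |differences|", call. = FALSE)
  if (exact) {
    p <- 2 * min(stats::psignrank(V, n),
                 stats::psignrank(V - 1, n, lower.tail = FALSE))
    p <- min(1, p)
    method <- "exact signed-rank distribution"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- sign(V - mu) * 0.5
    z <- (V - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (tie/zero corrected)"
  }
  list(statistic = V, p.value = p, n = n, exact = exact, method = method)
}

#' Wilcoxon rank-sum test for two independent groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum comparison. With tie-free data
#' and both groups below `exact_max` the exact null distribution of U is
#' used; otherwise a tie-corrected normal approximation with continuity
#' correction.
#'
#' @param x,y The two independent samples.
#' @param exact Force or forbid the exact distribution (`NULL` = decide).
#' @param exact_max Largest group size for the exact default.
#' @return List with `statistic` (U for `x`), `p.value`, `n` (c(nx, ny)),
#'   `exact`, and `method`.
#' @export
rank_sum <- function(x, y, exact = NULL, exact_max = 50L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be nonempty", call. = FALSE)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (is.null(exact)) exact <- !ties && n1 < exact_max && n2 < exact_max
  if (exact && ties)
    stop("exact p value is not defined with ties", call. = FALSE)
  if (exact) {
    p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                        stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)))
    method <- "exact rank-sum distribution"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sigma2 <- (n1 * n2 / 12) *
      (N + 1 - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    cc <- sign(U - mu) * 0.5
    z <- (U - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "tie-corrected normal approximation"
  }
  list(statistic = U, p.value = p, n = c(n1, n2), exact = exact,
       method = method)
}

#' Kruskal-Wallis test with Nemenyi post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H across k independent groups with a
#' chi-square(k - 1) p value, followed by all-pairs Nemenyi comparisons on
#' the mean ranks using the Studentized-range distribution
#' (`q = |Rbar_i - Rbar_j| / sqrt(N (N + 1) / 12 (1/n_i + 1/n_j))`,
#' `p = P(Q_k > q sqrt(2))`), the conventional post hoc for this omnibus
#' test. For two groups the Nemenyi p reduces to the two-sided normal p on
#' the same statistic.
#'
#' @param groups List of numeric vectors, one per group (named or not).
#' @return List with `H`, `df`, `p.value`, `mean_ranks`, and `pairwise` (a
#'   k x k matrix of Nemenyi p values).
#' @export
kruskal_nemenyi <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("`groups` must be a list of >= 2 groups", call. = FALSE)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("all groups must be nonempty", call. = FALSE)
  k <- length(groups)
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_len(k))
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  grp <- rep(seq_len(k), sizes)
  rbar <- tapply(r, grp, mean)
  H <- 12 / (N * (N + 1)) * sum(sizes * (rbar - (N + 1) / 2)^2)
  tie_tab <- table(r)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  if (corr > 0) H <- H / corr
  p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  pw <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    se <- sqrt(N * (N + 1) / 12 * (1 / sizes[i] + 1 / sizes[j]))
    q <- abs(rbar[i] - rbar[j]) / se
    pw[i, j] <- pw[j, i] <-
      stats::ptukey(q * sqrt(2), nmeans = k, df = Inf, lower.tail = FALSE)
  }
  diag(pw) <- 1
  list(H = H, df = k - 1, p.value = p,
       mean_ranks = stats::setNames(as.numeric(rbar), labels), pairwise = pw)
}

#' Free-flight bout record
#'
#' One flight bout: take-off to landing, any intermediate skid/crawl
#' intervals (moth touching the ground or walls while flapping; not counted
#' as flight), and the number of side-wall collisions.
#'
#' @param takeoff,landing Bout start and end times in seconds
#'   (`landing > takeoff`).
#' @param skids List of `c(start, end)` intervals within the bout,
#'   non-overlapping.
#' @param collisions Non-negative integer collision count.
#' @return Object of class `"flight_bout"`.
#' @export
flight_bout <- function(takeoff, landing, skids = list(), collisions = 0L) {
  if (landing <= takeoff) stop("`landing` must exceed `takeoff`", call. = FALSE)
  if (collisions < 0 || collisions != round(collisions))
    stop("`collisions` must be a non-negative integer", call. = FALSE)
  if (length(skids)) {
    m <- do.call(rbind, lapply(skids, function(s) {
      if (length(s) != 2L || s[2] <= s[1])
        stop("each skid interval must be c(start, end) with end > start",
             call. = FALSE)
      s
    }))
    if (any(m[, 1] < takeoff) || any(m[, 2] > landing))
      stop("skid intervals must lie within [takeoff, landing]", call. = FALSE)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (nrow(m) > 1L && any(m[-1L, 1] < m[-nrow(m), 2]))
      stop("skid intervals must not overlap", call. = FALSE)
  }
  structure(list(takeoff = takeoff, landing = landing, skids = skids,
                 collisions = as.integer(collisions)),
            class = "flight_bout")
}

#' Flight-bout duration and collision rate
#'
#' Duration is the time from take-off to landing minus all skid/crawl time,
#' rounded to the nearest second (timing resolution of the free-flight
#' videos); the collision rate divides the collision count by that rounded
#' duration, so the rate inherits the discretization.
#'
#' @param bout A [flight_bout()].
#' @return List with `duration` (s, integer-valued) and `collision_rate`
#'   (collisions per second).
#' @export
flight_metrics <- function(bout) {
  stopifnot(inherits(bout, "flight_bout"))
  skid_total <- if (length(bout$skids))
    sum(vapply(bout$skids, function(s) s[2] - s[1], numeric(1))) else 0
  duration <- round(bout$landing - bout$takeoff - skid_total)
  if (duration <= 0)
    stop("flight duration is <= 0 s after skid subtraction and rounding",
         call. = FALSE)
  list(duration = duration, collision_rate = bout$collisions / duration)
}
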