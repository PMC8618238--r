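test_that("log-space hypergeometric tail matches exact enumeration", {
  # P(all 5 marked drawn) = 1 / C(20, 5)
  expect_equal(log_hypergeom_sf(5, 5, 5, 20), log10(1 / choose(20, 5)),
               tolerance = 1e-12)
  # brute-force pmf sum: P(X >= 3) = 66/252 for N=10, m=4, n=5
  expect_equal(log_hypergeom_sf(3, 4, 5, 10), log10(66 / 252),
               tolerance = 1e-12)
  expect_equal(hyper_sf_oracle(3, 4, 5, 10), 66 / 252)
  # k = 0 tail includes everything
  expect_identical(log_hypergeom_sf(0, 7, 3, 12), 0)
})

test_that("hypergeometric tail matches the base-R survival function on random configs", {
  set.seed(5)
  for (i in 1:300) {
    N <- sample(1:60, 1)
    m <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(m, n), 1)
    ours <- log_hypergeom_sf(k, m, n, N)
    ref <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE,
                         log.p = TRUE) / log(10)
    expect_lt(abs(ours - ref), 1e-9)  # absolute in log10
  }
})

test_that("tail probability is finite and monotone non-increasing far below underflow", {
  ks <- c(18000, 18500, 19000, 19500, 20000)
  lp <- log_hypergeom_sf(ks, 20000, 20000, 40000)
  expect_true(all(is.finite(lp)))
  expect_true(all(diff(lp) < 0))
  expect_lt(lp[3], -2500)  # far beyond double underflow (~1e-308)
})

test_that("vectorised tail equals scalar evaluation", {
  k <- c(0, 2, 5, 1); m <- c(4, 6, 5, 9); n <- c(4, 3, 5, 2)
  N <- c(10, 12, 20, 15)
  k <- pmin(k, pmin(m, n))
  vec <- log_hypergeom_sf(k, m, n, N)
  sca <- mapply(log_hypergeom_sf, k, m, n, N)
  expect_equal(vec, unname(sca), tolerance = 1e-12)
  expect_error(log_hypergeom_sf(5, 4, 4, 10), "min")
  expect_error(log_hypergeom_sf(1, 11, 4, 10), "<= N")
})

test_that("representation factor is observed over expected overlap", {
  expect_equal(representation_factor(1, 10, 10, 100), 1)
  expect_equal(representation_factor(30, 50, 60, 1000), 10)
  expect_equal(representation_factor(0, 5, 5, 100), 0)
  expect_error(representation_factor(1, 0, 5, 10), "positive")
  # rf * expected overlap recovers k to machine precision
  set.seed(7)
  for (i in 1:50) {
    N <- sample(50:5000, 1); m <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(m, n), 1)
    rf <- representation_factor(k, m, n, N)
    expect_equal(rf * (m * n / N), k, tolerance = 1e-12)
  }
})

test_that("common/exclusive splits behave like set algebra", {
  a <- sprintf("g%d", 1:5); b <- sprintf("g%d", 3:6)
  cg <- common_genes(a, b)
  expect_equal(sort(cg$common), sprintf("g%d", 3:5))
  expect_equal(lengths(cg), c(common = 3, exclusive_a = 2, exclusive_b = 1))
  expect_equal(common_genes(a, a)$common, a)
  expect_length(common_genes(a, a)$exclusive_a, 0)
  expect_length(common_genes(a, sprintf("x%d", 1:3))$common, 0)
})

test_that("detection rules gate on reads per replicate or mean RPKM", {
  m <- matrix(c(0, 5,
                3, 7,
                99, 99), 3, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), NULL))
  x <- make_cm(m, c("A", "A"), lengths_bp = c(g1 = 1000, g2 = 1000,
                                              g3 = 1000))
  det <- detected_genes(x, "A")
  expect_false("g1" %in% det)  # a zero replicate fails the default rule
  expect_true(all(c("g2", "g3") %in% det))
  expect_error(detected_genes(x, "Z"), "unknown")
  # mean-RPKM floor: with 1 Mb genes and 1e6 libraries RPKM = count/1000,
  # so 9900 reads give RPKM 9.9, just missing a floor of 10
  m2 <- matrix(c(9900, 9900, 10000, 10000, 1e6 - 19900, 1e6 - 19900),
               3, 2, byrow = TRUE,
               dimnames = list(c("lo", "hi", "filler"), NULL))
  x2 <- make_cm(m2, c("A", "A"),
                lengths_bp = c(lo = 1e6, hi = 1e6, filler = 98e6))
  det2 <- detected_genes(x2, "A", rule = "rpkm_floor", rpkm_floor = 10)
  expect_false("lo" %in% det2)
  expect_true("hi" %in% det2)
})

test_that("venn partitions are disjoint, exhaustive and correctly sized", {
  s <- list(A = sprintf("g%d", 1:7), B = sprintf("g%d", 1:7),
            C = sprintf("g%d", 1:7))
  vp <- venn_partition(s)
  expect_equal(lengths(vp$regions), c(`A&B&C` = 7L))
  s2 <- list(A = c("a1", "a2"), B = c("b1", "b2", "b3"),
             C = c("c1", "c2", "c3", "c4"))
  vp2 <- venn_partition(s2)
  expect_equal(sum(lengths(vp2$regions)), 9)
  expect_equal(lengths(vp2$regions)[c("A", "B", "C")],
               c(A = 2L, B = 3L, C = 4L))
  # randomized sets: regions disjoint and union-complete
  set.seed(9)
  for (i in 1:20) {
    sets <- lapply(1:3, function(j) sample(sprintf("g%d", 1:40),
                                           sample(0:30, 1)))
    names(sets) <- c("X", "Y", "Z")
    vp3 <- venn_partition(sets)
    genes <- unlist(vp3$regions)
    expect_equal(length(genes), length(unique(genes)))
    expect_setequal(genes, unique(unlist(sets)))
    expect_equal(sum(lengths(vp3$regions)), vp3$union_size)
  }
  expect_error(venn_partition(list(1:3)), "2 or 3")
})

test_that("venn summary reproduces the published partition arithmetic", {
  # region sizes matching the printed genome-wide TF partition:
  # 4344 single-TF, 4031 in exactly two, 659 in all three, union 9034
  mk <- function(n, prefix) if (n > 0) paste0(prefix, seq_len(n)) else character(0)
  singles <- c(1448, 1448, 1448)   # sums to 4344
  pairs <- c(1344, 1344, 1343)     # sums to 4031
  sets <- list(
    daf16 = c(mk(singles[1], "s1_"), mk(pairs[1], "p12_"),
              mk(pairs[2], "p13_"), mk(659, "t_")),
    skn1 = c(mk(singles[2], "s2_"), mk(pairs[1], "p12_"),
             mk(pairs[3], "p23_"), mk(659, "t_")),
    hsf1 = c(mk(singles[3], "s3_"), mk(pairs[2], "p13_"),
             mk(pairs[3], "p23_"), mk(659, "t_"))
  )
  vp <- venn_partition(sets)
  expect_equal(vp$union_size, 9034)
  vs <- venn_summary(vp)
  expect_equal(vs$count, c(4344L, 4031L, 659L))
  expect_equal(vs$pct_of_union, c(48.1, 44.6, 7.3))
  # reported to the paper's integer precision: 48%
  expect_equal(round_half_up(vs$pct_of_union[1], 0), 48)
})

test_that("overlap_test assembles k, rf and log10 p consistently", {
  a <- sprintf("g%d", 1:50); b <- sprintf("g%d", 26:85)
  ov <- overlap_test(a, b, universe_size = 1000)
  expect_equal(ov$k, 25)
  expect_equal(ov$rf, 25 * 1000 / (50 * 60))
  expect_equal(ov$log10_p, log_hypergeom_sf(25, 50, 60, 1000))
  expect_error(overlap_test(a, b, universe_size = 55), "universe")
})
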