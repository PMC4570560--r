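test_that("direct and chained ratios follow the design", {
  sites <- make_sites(
    list(gene = "G1", residue = "S1", int_set1_light = 1000,
         int_set1_medium = 250,
         int_set2_light = 100, int_set2_medium = 50, int_set2_heavy = 400),
    list(gene = "G2", residue = "S2", int_set1_light = 100,
         int_set1_medium = 400,
         int_set2_light = 100, int_set2_medium = 800, int_set2_heavy = 100),
    list(gene = "G3", residue = "S3", int_set1_light = 10,
         int_set2_light = 10, int_set2_medium = 10, int_set2_heavy = 10)
  )
  d <- default_design()

  # direct: log2(1000/250) = 2 before centering
  r <- compute_ratios(sites, d, "smarcb1_high", center = FALSE)
  expect_equal(r$log2_ratio[r$gene == "G1"], 2)
  expect_equal(r$summed_intensity[r$gene == "G1"], 1250)
  # G3 lacks set1 medium -> excluded from this comparison
  expect_false("G3" %in% r$gene)

  # chained deficient-cell serum comparison with equal anchor values
  # reduces to log2(def_high / def_low): G2 -> log2(400/100) = 2
  rc <- compute_ratios(sites, d, "serum_deficient", center = FALSE)
  expect_true(attr(rc, "chained"))
  expect_equal(rc$log2_ratio[rc$gene == "G2"], 2)
  # chained summed intensity is the minimum of the two legs
  expect_equal(rc$summed_intensity[rc$gene == "G2"], min(100 + 400, 100 + 100))

  # centering: median log2 ratio is 0 afterwards, offset retained
  r2 <- compute_ratios(sites, d, "smarcb1_high", center = TRUE)
  expect_equal(stats::median(r2$log2_ratio), 0)
  expect_equal(r2$log2_ratio + attr(r2, "centering_offset"),
               compute_ratios(sites, d, "smarcb1_high", center = FALSE)$log2_ratio)

  expect_error(compute_ratios(sites, d, "nope"),
               class = "silac_config_error")
})

test_that("noise-free generated data recovers planted ratios after un-centering", {
  cfg <- quick_config(31, noise_floor = 1e-9, noise_amplitude = 0,
                      missing_rate = 0)
  study <- generate_phosphoproteome(cfg)
  d <- default_design()
  for (cmp in c("smarcb1_high", "smarcb1_low", "serum_proficient",
                "serum_deficient")) {
    r <- compute_ratios(study$sites, d, cmp)
    raw <- r$log2_ratio + attr(r, "centering_offset")
    truth_col <- c(smarcb1_high = "d_high", smarcb1_low = "d_low",
                   serum_proficient = "x", serum_deficient = "y")[[cmp]]
    want <- study$truth[[truth_col]][match(r$site_id, study$truth$site_id)]
    expect_equal(raw, want, tolerance = 1e-6)
  }
})

test_that("significance_A matches its closed forms at the center and one scale out", {
  x <- c(-3, -1, 0, 1, 3)
  p <- significance_A(x)
  expect_equal(p[x == 0], 0.5)  # median -> z = 0 -> p = 1/2

  # a value sitting at the 84.13th percentile has z = 1, p ~ 0.1587
  g <- seq(0, 1, length.out = 10001)
  pg <- significance_A(g)
  at <- which.min(abs(g - unname(stats::quantile(g, stats::pnorm(1)))))
  expect_equal(pg[at], stats::pnorm(1, lower.tail = FALSE), tolerance = 1e-3)

  expect_error(significance_A(c(1, 2)), class = "silac_statistic_error")
  expect_error(significance_A(rep(1, 10)), "degenerate",
               class = "silac_statistic_error")
  expect_error(significance_A(c(1, 2, NA, 4)), class = "silac_statistic_error")
})

test_that("significance_A is shift-invariant, scale-equivariant and monotone in |z|", {
  set.seed(21)
  x <- rnorm(500, sd = 1.4)
  p <- significance_A(x)
  expect_equal(significance_A(x + 3.7), p)
  expect_equal(significance_A(x * 2.5), p)
  # monotone non-increasing in distance from the median, per side
  r0 <- stats::median(x)
  up <- order(x[x > r0])
  expect_true(all(diff(p[x > r0][up]) <= 1e-12))
  dn <- order(-x[x < r0])
  expect_true(all(diff(p[x < r0][dn]) <= 1e-12))
})

test_that("the doubled tail probability is calibrated on a Gaussian null", {
  set.seed(42)
  x <- rnorm(10000)
  frac <- mean(significance_A(x, two_sided = TRUE) < 0.05)
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.06)
  # the one-sided score exceeds alpha at twice the rate, by construction
  frac1 <- mean(significance_A(x) < 0.05)
  expect_gt(frac1, 0.08)
  expect_lt(frac1, 0.12)
})

test_that("significance_B with a single bin reduces to significance_A exactly", {
  set.seed(5)
  x <- rnorm(100)
  int <- rlnorm(100, 10, 1)
  expect_warning(pb <- significance_B(x, int, min_bin = 300),
                 "reduces to Significance A")
  expect_identical(pb, significance_A(x))
  # n == min_bin: one bin, no warning path needed
  expect_identical(significance_B(x, int, min_bin = 100), significance_A(x))
})

test_that("intensity binning rescues precise high-intensity outliers", {
  set.seed(8)
  n_half <- 500
  lr <- c(rnorm(n_half, 0, 2.0),   # low intensity, noisy regime
          rnorm(n_half, 0, 0.5),   # high intensity, tight regime
          1.5)                     # the site under test, high intensity
  int <- c(runif(n_half, 1e4, 2e4), runif(n_half, 1e6, 2e6), 1.5e6)
  ids <- sprintf("s%04d", seq_along(lr))
  pA <- significance_A(lr)
  pB <- significance_B(lr, int, min_bin = 500, ids = ids)
  i <- length(lr)
  expect_lt(pB[i], 0.01)
  expect_gt(pA[i], 0.05)

  # erfc oracle: the binned p equals the one-sided normal tail of the
  # asymmetric z computed from the site's own bin
  bin <- order(int)[(n_half + 1):length(lr)]
  xb <- lr[bin]
  r0 <- stats::median(xb)
  s_plus <- unname(stats::quantile(xb, stats::pnorm(1), type = 7)) - r0
  expect_equal(pB[i], stats::pnorm((1.5 - r0) / s_plus, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("binned and global p-values agree under homoscedastic noise", {
  set.seed(13)
  n <- 3000
  lr <- rnorm(n, 0, 0.6)
  int <- rlnorm(n, 14, 2)  # intensity carries no information about spread
  pA <- significance_A(lr, two_sided = TRUE)
  pB <- significance_B(lr, int, min_bin = 300, two_sided = TRUE)
  expect_lt(stats::median(abs(pB - pA)), 0.05)
  fr <- mean(pB < 0.05)
  expect_gt(fr, 0.04)
  expect_lt(fr, 0.06)
})

test_that("BH adjustment matches the hand step-up oracle", {
  expect_identical(bh_adjust(numeric()), numeric())
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  # monotone non-decreasing in p-rank and never above 1
  set.seed(2)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 0)), class = "silac_value_error")
})

test_that("significant sets, venn counts and volcano rows are consistent", {
  set.seed(77)
  ra <- make_ratios(rnorm(400), genes = sprintf("GA%03d", 1:400))
  ra <- add_significance(ra, method = "A", alpha = 0.05)
  sa <- significant_sites(ra, alpha = 0.05)
  vt <- volcano_table(ra)
  expect_identical(nrow(vt), nrow(ra))
  expect_equal(vt$neg_log10_p, -log10(ra$p_value))
  expect_setequal(site_key(vt$gene[vt$significant],
                           vt$residue[vt$significant]), sa$key)

  # venn algebra: disjoint, identical, and the conservation identity
  sb <- sa
  sb$key <- paste0("OTHER_", sb$key)
  v <- venn_counts(sa, sb)
  expect_identical(v$both, 0L)
  v2 <- venn_counts(sa, sa)
  expect_identical(v2$only_a + v2$only_b, 0L)
  expect_identical(v2$both, v2$n_a)
  half <- sa[seq_len(nrow(sa) %/% 2), ]
  v3 <- venn_counts(sa, half)
  expect_identical(v3$n_a + v3$n_b, v3$only_a + v3$only_b + 2L * v3$both)
  expect_identical(v3$a_up + v3$a_down, nrow(sa))
})
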