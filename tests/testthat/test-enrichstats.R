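# Gene lists, term enrichment, chromosome statistics, depth correlation
# and assembly statistics.

test_that("rate-class gene lists apply their thresholds", {
  rates <- data.frame(gene_id = sprintf("g%02d", 1:10),
                      omega = c(rep(0.1, 9), 2.0))
  cl <- select_rate_classes(rates)
  expect_identical(cl$lists$omega_gt_1, "g10")
  expect_identical(cl$lists$omega_gt_0.8, "g10")
  expect_gte(length(cl$lists$top_decile), 1L)
  expect_equal(cl$n_undefined, 0L)

  rates2 <- data.frame(gene_id = sprintf("g%03d", 1:100),
                       omega = seq(0.01, 1, length.out = 100))
  cl2 <- select_rate_classes(rates2)
  expect_gte(length(cl2$lists$top_decile), 10L)
  expect_equal(cl2$thresholds[["top_decile"]],
               unname(quantile(rates2$omega, 0.9)))

  expect_error(select_rate_classes(rates[0, ]), "empty")
  expect_error(select_rate_classes(data.frame(gene_id = "a", omega = NA)),
               "no usable estimates")
  # undefined omegas are excluded and counted
  rates$omega[1:3] <- NA
  expect_equal(select_rate_classes(rates)$n_undefined, 3L)
})

test_that("enrichment p-values match hypergeometric worked examples", {
  universe <- sprintf("u%02d", 1:10)
  tmap <- data.frame(gene_id = universe[1:5], term_id = "T1",
                     term_desc = "term one")
  # both of a 2-gene list inside a 5-gene term: p = C(5,2)/C(10,2)
  r <- term_enrichment(universe[1:2], universe, tmap)
  expect_equal(r$p_hyper, choose(5, 2) / choose(10, 2), tolerance = 1e-9)
  expect_identical(r$direction, "over")
  expect_equal(r$expected, 5 * 2 / 10)
  expect_equal(r$observed, 2L)

  # 5-gene list entirely outside a 5-gene term: under-representation
  r2 <- term_enrichment(universe[6:10], universe, tmap)
  expect_equal(r2$p_hyper, 1 / choose(10, 5), tolerance = 1e-9)
  expect_identical(r2$direction, "under")

  # symmetric 2x2 table: two-sided Fisher p = 1
  expect_equal(omegascan:::.fisher2x2_p(1, 2, 2, 4), 1, tolerance = 1e-9)

  # empty list: observed 0, p = 1 for a full-universe term, no error
  r3 <- term_enrichment(character(0), universe,
                        data.frame(gene_id = universe, term_id = "T2",
                                   term_desc = "all"))
  expect_equal(r3$observed, 0L)
  expect_equal(r3$p, 1)
})

test_that("two-sided Fisher enumeration agrees with fisher.test", {
  set.seed(50)
  for (rep in 1:40) {
    N <- sample(6:25, 1)
    l <- sample(1:(N - 1), 1)
    t <- sample(1:(N - 1), 1)
    obs <- sample(max(0, l + t - N):min(l, t), 1)
    mine <- omegascan:::.fisher2x2_p(obs, l, t, N)
    m <- matrix(c(obs, l - obs, t - obs, N - l - t + obs), 2)
    expect_equal(mine, fisher.test(m)$p.value, tolerance = 1e-9,
                 info = paste(N, l, t, obs))
  }
})

test_that("BH-adjusted p-values are monotone in rank and bounded", {
  set.seed(51)
  p <- runif(200)
  tab <- term_enrichment(sprintf("g%d", 1:5), sprintf("g%d", 1:50),
                         data.frame(gene_id = sample(sprintf("g%d", 1:50),
                                                     200, TRUE),
                                    term_id = rep(sprintf("T%d", 1:20), 10),
                                    term_desc = "x"))
  expect_true(all(diff(tab$p_adjusted[order(tab$p)]) >= -1e-12))
  expect_true(all(tab$p_adjusted <= 1 & tab$p_adjusted >= tab$p - 1e-12))
})

test_that("random gene lists rarely reach adjusted significance", {
  set.seed(52)
  universe <- sprintf("g%03d", 1:80)
  tmap <- do.call(rbind, lapply(1:15, function(k)
    data.frame(gene_id = sample(universe, sample(5:25, 1)),
               term_id = sprintf("T%02d", k), term_desc = "x")))
  frac <- replicate(30, {
    tab <- term_enrichment(sample(universe, 10), universe, tmap)
    mean(tab$p_adjusted < 0.05)
  })
  expect_lte(mean(frac), 0.05)
})

test_that("chromosome ANOVA and contrasts handle degenerate and shifted data", {
  rates <- data.frame(omega = c(1, 2, 3, 1, 2, 3),
                      chrom = rep(c("1", "2"), each = 3))
  st <- omega_chromosome_stats(rates,
                               list(c("1", ">", "2"), c("2", "<", "1")))
  expect_equal(st$anova$F, 0)
  expect_equal(st$anova$p, 1)
  expect_equal(st$contrasts$t, c(0, 0))
  expect_equal(st$contrasts$p, c(0.5, 0.5))
  expect_error(omega_chromosome_stats(rates, list(c("9", ">", "1"))),
               "absent: 9")
  expect_error(omega_chromosome_stats(data.frame(omega = 1, chrom = "1")),
               ">= 2 chromosomes")

  # a genuinely shifted chromosome is detected
  set.seed(53)
  r2 <- data.frame(
    omega = c(rgamma(300, 2, 2 / 0.13), rgamma(300, 2, 2 / 0.195)),
    chrom = rep(c("4", "Z"), each = 300))
  st2 <- omega_chromosome_stats(r2, list(c("Z", ">", "4")))
  expect_lt(st2$anova$p, 0.05)
  expect_lt(st2$contrasts$p, 0.05)
  # matches a direct Welch t-test
  direct <- t.test(r2$omega[r2$chrom == "Z"], r2$omega[r2$chrom == "4"],
                   alternative = "greater")
  expect_equal(st2$contrasts$p, direct$p.value)
})

test_that("depth correlation recovers exact and sampled correlations", {
  d1 <- data.frame(gene_id = sprintf("g%d", 1:20), omega = seq(0.1, 2, 0.1))
  d2 <- d1; d2$omega <- 2 * d1$omega
  expect_equal(depth_correlation(d1, d2)$r, 1, tolerance = 1e-12)
  d3 <- d1; d3$omega <- -d1$omega
  expect_equal(depth_correlation(d1, d3)$r, -1, tolerance = 1e-12)
  expect_error(depth_correlation(d1[1:2, ], d2[1:2, ]), "fewer than 3")

  set.seed(54)
  n <- 2000
  x <- rnorm(n); y <- 0.35 * x + sqrt(1 - 0.35^2) * rnorm(n)
  da <- data.frame(gene_id = seq_len(n), omega = x)
  db <- data.frame(gene_id = seq_len(n), omega = y)
  r <- depth_correlation(da, db)
  expect_gt(r$r, 0.30); expect_lt(r$r, 0.40)
  expect_lt(r$p, 0.001)
  # undefined omegas dropped with count
  db$omega[1:10] <- NA
  expect_equal(depth_correlation(da, db)$n_dropped, 10L)
})

test_that("assembly statistics and N50 follow the cumulative-sum definition", {
  s <- assembly_stats(c(8, 4, 3, 3, 2, 2, 2))
  expect_equal(s$n50, 4)
  expect_equal(s$total_bp, 24)
  expect_equal(s$mean_length, 24 / 7)
  expect_equal(assembly_stats(1234)$n50, 1234)
  expect_equal(assembly_stats(rep(77, 9))$n50, 77)
  expect_error(assembly_stats(numeric(0)), "no sequence lengths")
  # N50 >= median and within the observed range
  set.seed(55)
  lens <- rpois(200, 800) + 1
  s2 <- assembly_stats(lens)
  expect_gte(s2$n50, median(lens))
  expect_true(s2$n50 %in% lens)
})
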