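test_that("one-tailed Fisher equals hypergeometric enumeration", {
  ex <- fisher_one_tailed(10, 5, 5, 80)
  expect_equal(ex$p, oracle_fisher_p(10, 5, 5, 80))
  expect_equal(ex$odds_ratio, (10 * 80) / (5 * 5))

  set.seed(81)
  for (i in 1:100) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c <- sample(0:15, 1); d <- sample(0:15, 1)
    if (a + b + c + d == 0) next
    got <- fisher_one_tailed(a, b, c, d)
    expect_equal(got$p, oracle_fisher_p(a, b, c, d), tolerance = 1e-12)
    # base R agreement on the same table
    expect_equal(got$p,
                 stats::fisher.test(matrix(c(a, c, b, d), 2),
                                    alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
  # complete enrichment attains the minimal p for those margins
  full <- fisher_one_tailed(5, 0, 3, 10)
  expect_equal(full$p, oracle_fisher_p(5, 0, 3, 10))
  expect_equal(full$odds_ratio, Inf)
  expect_error(fisher_one_tailed(0, 0, 0, 0), "all-zero")
  # independence construction is not spuriously significant on average
  set.seed(82)
  ps <- replicate(50, {
    m <- matrix(stats::rmultinom(1, 80, rep(0.25, 4)), 2)
    fisher_one_tailed(m)$p
  })
  expect_gt(mean(ps), 0.3)
})

test_that("matrix input maps to the same cells", {
  expect_equal(fisher_one_tailed(matrix(c(10, 5, 5, 80), 2, byrow = TRUE)),
               fisher_one_tailed(10, 5, 5, 80))
})

test_that("paired Wilcoxon: degenerate, exact small-n, enumeration oracle", {
  x <- c(1, 2, 3); y <- x
  d0 <- wilcoxon_one_tailed(x, y, paired = TRUE)
  expect_true(d0$degenerate)
  expect_equal(d0$p, 1)

  # n = 6, all differences positive: exact p = 1/64
  set.seed(83)
  xx <- runif(6) + 2; yy <- runif(6)
  expect_equal(wilcoxon_one_tailed(xx, yy, paired = TRUE)$p, 1 / 64)

  for (i in 1:40) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n, 0.3, 1), 3)
    d <- d[d != 0]
    if (length(d) < 2 || any(duplicated(abs(d)))) next
    got <- wilcoxon_one_tailed(d, rep(0, length(d)), paired = TRUE)
    expect_equal(got$p, oracle_signed_rank_p(d))
  }
  expect_error(wilcoxon_one_tailed(1:3, 1:4, paired = TRUE),
               "equal lengths")
})

test_that("unpaired Wilcoxon matches rank-sum enumeration; approx branch sane", {
  set.seed(84)
  for (i in 1:30) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    x <- round(rnorm(nx, 1), 3); y <- round(rnorm(ny), 3)
    if (any(duplicated(c(x, y)))) next
    got <- wilcoxon_one_tailed(x, y, paired = FALSE)
    expect_equal(got$p, oracle_rank_sum_p(x, y))
  }
  # large/tied samples use the normal approximation, one-tailed direction
  x <- rep(c(5, 6), 20); y <- rep(c(1, 2), 20)
  big <- wilcoxon_one_tailed(x, y, paired = FALSE)
  expect_lt(big$p, 1e-6)
  expect_match(big$method, "normal approx")
  rev <- wilcoxon_one_tailed(y, x, paired = FALSE)
  expect_gt(rev$p, 0.99)
})

test_that("Pratt variant keeps zeros in the ranking", {
  d <- c(0, 0, 1, 2, 3, -1.5)
  pr <- wilcoxon_one_tailed(d, rep(0, 6), paired = TRUE, pratt = TRUE)
  expect_match(pr$method, "Pratt")
  expect_true(pr$p > 0 && pr$p < 1)
})

test_that("Spearman is the Pearson correlation of mid-ranks", {
  expect_equal(spearman_rho(1:10, 1:10), 1)
  expect_equal(spearman_rho(1:10, 10:1), -1)
  set.seed(85)
  for (i in 1:30) {
    n <- sample(4:20, 1)
    x <- sample(1:5, n, replace = TRUE)  # heavy ties
    y <- sample(1:5, n, replace = TRUE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y))
  }
  expect_warning(r <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
})

test_that("interval Jaccard equals per-base enumeration", {
  a <- tibble(chrom = "c1", start = c(0L, 100L), end = c(50L, 150L))
  expect_equal(jaccard_index(a, a), 1)
  b <- tibble(chrom = "c1", start = 200L, end = 300L)
  expect_equal(jaccard_index(a, b), 0)
  expect_warning(
    expect_equal(jaccard_index(a[0, ], b[0, ]), 0), "empty union")
  set.seed(86)
  for (i in 1:25) {
    mk <- function() {
      n <- sample(1:5, 1)
      s <- sample(0:300, n)
      tibble(chrom = sample(c("c1", "c2"), n, replace = TRUE),
             start = s, end = s + sample(5:60, n, replace = TRUE))
    }
    x <- mk(); y <- mk()
    expect_equal(jaccard_index(x, y), oracle_jaccard(x, y))
  }
})

test_that("link validation uses flanks, gene matching, and LD proxies", {
  links <- tibble(region = c("R1", "R1", "R2"),
                  element_id = c("e1", "e2", "e3"),
                  gene_id = c("gA", "gB", "gC"), rank = c(1L, 2L, 1L),
                  chrom = "chr1",
                  start = c(1000L, 5000L, 9000L),
                  end = c(1500L, 5500L, 9500L))
  # variant 300 bp outside e1 with matching gene: validated via flank
  reference <- tibble(variant_id = c("v1", "v2"), chrom = "chr1",
                      pos = c(1801L, 5201L), gene_id = c("gA", "gX"))
  out <- validate_links(links, reference)
  p1 <- out$proportions
  r1 <- p1[p1$region == "R1" & p1$promoter_type == "five_prime", ]
  expect_equal(r1$n_intersected, 1L)
  expect_equal(r1$n_validated, 1L)
  # e2 intersects v2 but the target gene differs: denominator only
  r1n <- p1[p1$region == "R1" & p1$promoter_type == "non_five_prime", ]
  expect_equal(r1n$n_intersected, 1L)
  expect_equal(r1n$n_validated, 0L)
  # e3 intersects nothing
  r2 <- p1[p1$region == "R2", ]
  expect_equal(r2$n_intersected, 0L)
  expect_true(is.na(r2$proportion))

  # an LD proxy with r2 > 0.8 inherits the lead's gene and validates e3
  proxies <- tibble(lead_id = "v1", proxy_id = "v1p", chrom = "chr1",
                    pos = 9201L, r2 = 0.9)
  links3 <- links; links3$gene_id[3] <- "gA"
  out2 <- validate_links(links3, reference, proxies)
  r2b <- out2$proportions[out2$proportions$region == "R2", ]
  expect_equal(r2b$n_validated, 1L)
  # below the r2 threshold the proxy is ignored
  out3 <- validate_links(links3, reference,
                         proxies %>% dplyr::mutate(r2 = 0.5))
  expect_equal(out3$proportions$n_validated[
    out3$proportions$region == "R2"], 0L)
  expect_error(validate_links(links, reference[0, ]), "empty reference")
})

test_that("enlarging the flank weakly grows numerator and denominator", {
  set.seed(87)
  links <- tibble(region = "R1", element_id = sprintf("e%d", 1:20),
                  gene_id = sprintf("g%d", 1:20), rank = 1L, chrom = "chr1",
                  start = sample.int(50000L, 20))
  links$end <- links$start + 400L
  reference <- tibble(variant_id = sprintf("v%d", 1:30), chrom = "chr1",
                      pos = sample.int(50000L, 30),
                      gene_id = sample(sprintf("g%d", 1:20), 30,
                                       replace = TRUE))
  small <- validate_links(links, reference, flank_bp = 100L)$proportions
  large <- validate_links(links, reference, flank_bp = 2000L)$proportions
  expect_gte(large$n_intersected, small$n_intersected)
  expect_gte(large$n_validated, small$n_validated)
  expect_true(all(stats::na.omit(c(small$proportion, large$proportion)) >= 0))
})

test_that("links from planted loops validate better than decoys", {
  b <- simulate_bundle(sim_config(seed = 9))
  res <- suppressWarnings(suppressMessages(run_pipeline(b)))
  # reference built from the generator's true loops
  el <- res$links %>%
    dplyr::distinct(element_id, chrom, start, end)
  reference <- b$truth$loops %>%
    dplyr::inner_join(el, by = "element_id") %>%
    dplyr::transmute(variant_id = paste0("v_", element_id), chrom,
                     pos = as.integer((start + end) / 2) + 1L, gene_id)
  links <- res$links %>%
    dplyr::filter(kind == "distal", region == "R1") %>%
    dplyr::mutate(is_true = paste(element_id, promoter_id) %in%
                    paste(b$truth$loops$element_id, b$truth$loops$promoter_id),
                  region = ifelse(is_true, "true", "decoy"))
  out <- validate_links(links, reference)
  pr <- out$proportions %>%
    dplyr::group_by(region) %>%
    dplyr::summarise(prop = sum(n_validated) / sum(n_intersected))
  expect_gt(pr$prop[pr$region == "true"], pr$prop[pr$region == "decoy"])
})
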