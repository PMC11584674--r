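fake_expr <- function(cpm_matrix, kind = "promoter_isoform") {
  structure(list(
    cpm = wide_counts(cpm_matrix),
    counts = wide_counts(cpm_matrix),
    factors = tibble(sample_id = colnames(cpm_matrix),
                     lib_size = 1e6, norm_factor = 1),
    feature_kind = kind), class = "promiso_expr")
}

region_meta <- function(n = 10, region = "R1") {
  tibble(sample_id = sprintf("%s_S%02d", region, seq_len(n)),
         donor = sprintf("D%d", seq_len(n)), region = region)
}

test_that("active promoters require expression and adjacent accessibility", {
  meta <- region_meta(10)
  cpm <- rbind(p_active = c(rep(5, 3), rep(0.2, 7)),   # >1 CPM in 30%
               p_silent = rep(0.5, 10),
               p_no_ocr = rep(50, 10))
  colnames(cpm) <- meta$sample_id
  e <- fake_expr(cpm)
  oa <- tibble(promoter_id = c("p_active", "p_silent", "p_no_ocr"),
               ocr_id = c("o1", "o2", NA), distance_bp = c(400L, 0L, NA))
  act <- call_active_promoters(e, oa, meta, "R1")
  expect_true(act$active[act$promoter_id == "p_active"])
  expect_false(act$active[act$promoter_id == "p_silent"])    # not expressed
  expect_false(act$active[act$promoter_id == "p_no_ocr"])    # 1.5 kb+ away
  expect_error(call_active_promoters(e, oa, meta, "nowhere"), "no samples")

  # conjunction oracle on random inputs
  set.seed(61)
  for (rep in 1:20) {
    cpm <- matrix(runif(50, 0, 3), 5, 10,
                  dimnames = list(sprintf("p%d", 1:5), meta$sample_id))
    oa <- tibble(promoter_id = sprintf("p%d", 1:5),
                 ocr_id = ifelse(runif(5) < 0.5, "o", NA),
                 distance_bp = 0L)
    act <- call_active_promoters(fake_expr(cpm), oa, meta, "R1")
    want <- rowMeans(cpm > 1) >= 0.2 & !is.na(oa$ocr_id)
    expect_equal(act$active, unname(want))
  }
})

test_that("element activity is the regional mean CPM with proximal flagging", {
  meta <- region_meta(4)
  peaks <- tibble(ocr_id = c("near", "far"), chrom = "chr1",
                  start = c(9500L, 50000L), end = c(9900L, 50400L))
  cpm <- rbind(near = rep(8, 4), far = c(2, 4, 6, 8))
  colnames(cpm) <- meta$sample_id
  pm <- tibble(promoter_id = "P1", gene_id = "G", chrom = "chr1",
               strand = "+", tss = 10000L, rank = 1L)
  el <- element_activity(peaks, fake_expr(cpm, "ocr"), meta, "R1", pm)
  expect_equal(el$activity[el$element_id == "near"], 8)
  expect_equal(el$activity[el$element_id == "far"], 5)
  expect_equal(el$kind[el$element_id == "near"], "promoter_proximal")
  expect_equal(el$kind[el$element_id == "far"], "distal")
})

test_that("contact fallback follows the power law; diagonal dominates", {
  empty <- contact_map(tibble(bin_a = integer(), bin_b = integer(),
                              count = numeric()), resolution = 5000)
  d <- 40000
  ratio <- contact_at(empty, 0, 2 * d) / contact_at(empty, 0, d)
  expect_equal(ratio, (d + 5000) / (2 * d + 5000))
  # gamma = 2 closed form
  r2 <- contact_at(empty, 0, 2 * d, gamma = 2) /
    contact_at(empty, 0, d, gamma = 2)
  expect_equal(r2, ((d + 5000) / (2 * d + 5000))^2)
  # same-bin self-contact >= any other contact at that anchor
  m <- contact_map(tibble(bin_a = c(0, 0, 5000), bin_b = c(5000, 100000, 100000),
                          count = c(40, 7, 6)), resolution = 5000)
  self <- contact_at(m, 1000, 2000)
  others <- contact_at(m, rep(1000, 4), c(6000, 52000, 101000, 500000))
  expect_true(all(self >= others))
})

test_that("observed contacts equal direct lookup; zeros fall back", {
  set.seed(62)
  res <- 5000
  bins <- expand.grid(bin_a = seq(0, 45000, res), bin_b = seq(0, 45000, res))
  bins <- bins[bins$bin_a <= bins$bin_b & bins$bin_a < bins$bin_b, ]
  bins$count <- rpois(nrow(bins), 30) + 1
  m <- contact_map(tibble::as_tibble(bins), resolution = res)
  for (i in sample(nrow(bins), 25)) {
    pa <- bins$bin_a[i] + sample(0:(res - 1), 1)
    pb <- bins$bin_b[i] + sample(0:(res - 1), 1)
    expect_equal(contact_at(m, pa, pb), bins$count[i])
    expect_equal(contact_at(m, pb, pa), bins$count[i])  # symmetric accessor
  }
  expect_warning(
    expect_equal(contact_at(m, 0, 10000, chrom_a = "chr1", chrom_b = "chr2"),
                 0),
    "cross-chromosome")
})

toy_abc <- function(activities, contacts, tss = 10e6, threshold = 0,
                    window_bp = 5e6) {
  n <- length(activities)
  res <- 5000
  mids <- tss + (seq_len(n)) * 50000   # distinct bins
  elements <- tibble(element_id = sprintf("e%02d", seq_len(n)),
                     chrom = "chr1", start = mids - 250L, end = mids + 250L,
                     kind = "distal", activity = activities)
  bins <- tibble(bin_a = pmin(floor(mids / res), floor(tss / res)) * res,
                 bin_b = pmax(floor(mids / res), floor(tss / res)) * res,
                 count = contacts)
  m <- contact_map(bins, resolution = res)
  pm <- tibble(promoter_id = "P1", gene_id = "G", chrom = "chr1",
               strand = "+", tss = tss, rank = 1L)
  active <- tibble(promoter_id = "P1", active = TRUE)
  abc_scores(active, elements, m, pm, region = "R1",
             threshold = threshold, window_bp = window_bp)
}

test_that("ABC scores normalize to 1 and match hand examples", {
  one <- toy_abc(5, 100)
  expect_equal(one$abc, 1.0)
  two <- toy_abc(c(3, 1), c(100, 100))
  expect_equal(sort(two$abc), c(0.25, 0.75))
  # at threshold 0.02 both are emitted
  two_thr <- toy_abc(c(3, 1), c(100, 100), threshold = 0.02)
  expect_equal(nrow(two_thr), 2L)
  # un-thresholded scores sum to 1
  set.seed(63)
  many <- toy_abc(runif(30, 0.1, 10), runif(30, 1, 50))
  expect_equal(sum(many$abc), 1, tolerance = 1e-9)
})

test_that("elements beyond the screening window are never candidates", {
  tss <- 10e6
  res <- 5000
  elements <- tibble(element_id = c("inside", "outside"), chrom = "chr1",
                     start = c(tss + 1e6, tss + 6e6),
                     end = c(tss + 1e6 + 500, tss + 6e6 + 500),
                     kind = "distal", activity = 5)
  m <- contact_map(tibble(bin_a = integer(), bin_b = integer(),
                          count = numeric()), resolution = res)
  pm <- tibble(promoter_id = "P1", gene_id = "G", chrom = "chr1",
               strand = "+", tss = tss, rank = 1L)
  lk <- abc_scores(tibble(promoter_id = "P1", active = TRUE),
                   elements, m, pm, region = "R1", threshold = 0)
  expect_equal(lk$element_id, "inside")
  expect_equal(lk$abc, 1.0)
})

test_that("raising one element's activity is monotone in ABC scores", {
  set.seed(64)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    act <- runif(n, 0.5, 8); cc <- runif(n, 1, 60)
    base <- toy_abc(act, cc)
    k <- sample(n, 1)
    act2 <- act; act2[k] <- act2[k] * 1.5
    bump <- toy_abc(act2, cc)
    eid <- sprintf("e%02d", k)
    expect_gte(bump$abc[bump$element_id == eid],
               base$abc[base$element_id == eid])
    expect_true(all(bump$abc[bump$element_id != eid] <=
                      base$abc[base$element_id != eid] + 1e-12))
  }
})

test_that("link sharing: identity, disjoint, and brute-force random cases", {
  mk <- function(region, ids, abc) {
    tibble(region = region, element_id = ids, promoter_id = "P1", abc = abc)
  }
  same <- bind_rows(mk("A", sprintf("e%d", 1:5), (1:5) / 10),
                    mk("B", sprintf("e%d", 1:5), (1:5) / 10))
  sh <- link_sharing(same)
  expect_equal(sh$unique$unique_frac, c(0, 0))
  expect_equal(sh$rho["A", "B"], 1)
  expect_equal(sh$shared$n_shared, 5L)

  disj <- bind_rows(mk("A", sprintf("a%d", 1:4), (1:4) / 10),
                    mk("B", sprintf("b%d", 1:4), (1:4) / 10))
  sd_ <- link_sharing(disj)
  expect_equal(sd_$unique$unique_frac, c(1, 1))
  expect_equal(sd_$shared$n_shared, 0L)
  expect_true(is.na(sd_$rho["A", "B"]))

  set.seed(65)
  for (rep in 1:10) {
    lk <- purrr::map_dfr(c("A", "B", "C"), function(r) {
      ids <- sample(sprintf("e%d", 1:12), sample(4:10, 1))
      mk(r, ids, runif(length(ids)))
    })
    sh <- link_sharing(lk)
    keys <- split(lk$element_id, lk$region)
    for (i in seq_len(nrow(sh$shared))) {
      a <- sh$shared$region_a[i]; b <- sh$shared$region_b[i]
      expect_equal(sh$shared$n_shared[i],
                   length(intersect(keys[[a]], keys[[b]])))
    }
    for (r in c("A", "B", "C")) {
      others <- unlist(keys[setdiff(c("A", "B", "C"), r)])
      expect_equal(sh$unique$unique_frac[sh$unique$region == r],
                   mean(!keys[[r]] %in% others))
    }
    # rank correlation oracle over shared links
    common <- intersect(keys$A, keys$B)
    if (length(common) >= 3) {
      sa <- lk$abc[lk$region == "A"][match(sort(common),
                                           sort(keys$A)[sort(keys$A) %in% common])]
      va <- lk[lk$region == "A" & lk$element_id %in% common, ]
      vb <- lk[lk$region == "B" & lk$element_id %in% common, ]
      va <- va[order(va$element_id), ]; vb <- vb[order(vb$element_id), ]
      expect_equal(sh$rho["A", "B"], oracle_spearman(va$abc, vb$abc))
    }
  }
})

test_that("gene-level collapse keeps the maximum-ABC promoter link", {
  lk <- tibble(region = "A", element_id = "e1",
               promoter_id = c("P1", "P2"), gene_id = "G",
               rank = c(1L, 2L), abc = c(0.1, 0.4))
  gl <- collapse_gene_links(lk)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$promoter_id, "P2")
})
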