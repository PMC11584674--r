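sim_expr <- function(n_feat, meta, mu = 100, lfc_features = integer(),
                     lfc = 0, lfc_group = NULL, group_col = "region",
                     donor_shift = NULL, seed = 1, dispersion = 0.05) {
  set.seed(seed)
  m <- matrix(rnbinom(n_feat * nrow(meta), mu = mu, size = 1 / dispersion),
              n_feat, nrow(meta),
              dimnames = list(sprintf("f%04d", seq_len(n_feat)),
                              meta$sample_id))
  if (length(lfc_features)) {
    sel <- meta[[group_col]] == lfc_group
    m[lfc_features, sel] <- rnbinom(length(lfc_features) * sum(sel),
                                    mu = mu * 2^lfc, size = 1 / dispersion)
  }
  if (!is.null(donor_shift)) {
    for (d in names(donor_shift)) {
      sel <- meta$donor == d
      m[, sel] <- matrix(
        rnbinom(n_feat * sum(sel), mu = mu * donor_shift[[d]],
                size = 1 / dispersion), n_feat, sum(sel))
    }
  }
  tmm_normalize(wide_counts(m))
}

two_group_meta <- function(n_per = 6, regions = c("A", "B")) {
  tibble(sample_id = sprintf("%s%d", rep(regions, each = n_per),
                             rep(seq_len(n_per), length(regions))),
         donor = sprintf("D%d", rep(seq_len(n_per %/% 2),
                                    length.out = n_per * length(regions))),
         region = rep(regions, each = n_per))
}

test_that("null data gives approximately uniform p-values", {
  meta <- two_group_meta(8)
  e <- sim_expr(1000, meta, seed = 101)
  de <- fit_pairwise_de(e, meta, "A", "B")
  expect_lt(abs(mean(de$p < 0.05) - 0.05), 0.02)
  expect_gt(stats::ks.test(de$p, "punif")$p.value, 1e-4)
})

test_that("planted log2 fold changes are recovered; power matches a t-test oracle", {
  meta <- two_group_meta(6)
  # keep the planted fraction small so TMM's trimmed majority stays null
  planted <- 1:40
  e <- sim_expr(400, meta, lfc_features = planted, lfc = 2, lfc_group = "A",
                seed = 102)
  de <- fit_pairwise_de(e, meta, "A", "B")
  est <- de$log2fc[planted]
  expect_lt(abs(mean(est) - 2), 0.2)  # Monte-Carlo error

  # oracle: plain two-sample t-test on the same log2-CPM rows
  y <- log2(as.matrix(e$cpm[, -1]) + 0.5)
  sel_a <- meta$sample_id[meta$region == "A"]
  sel_b <- meta$sample_id[meta$region == "B"]
  p_t <- vapply(planted, function(g) {
    stats::t.test(y[g, sel_a], y[g, sel_b])$p.value
  }, numeric(1))
  power_impl <- mean(de$p[planted] < 0.05)
  power_oracle <- mean(p_t < 0.05)
  expect_equal(power_impl, power_oracle, tolerance = 0.05)
})

test_that("donor-confounded shifts stay null-calibrated with donor in the model", {
  meta <- two_group_meta(6)
  e <- sim_expr(600, meta, donor_shift = list(D1 = 2.5, D2 = 0.6),
                seed = 103)
  de <- fit_pairwise_de(e, meta, "A", "B")
  expect_lt(mean(de$p < 0.05), 0.09)
})

test_that("degenerate designs and inputs are handled", {
  meta <- two_group_meta(4)
  e <- sim_expr(20, meta, seed = 104)
  expect_error(fit_pairwise_de(e, meta, "A", "A"), "must differ")
  expect_error(fit_pairwise_de(e, meta, "A", "B", covariates = "nope"),
               "absent from meta")
  # zero-variance feature (constant CPM): p = 1, log2fc = 0
  e2 <- e
  e2$cpm[1, -1] <- as.list(rep(25, nrow(meta)))
  de <- fit_pairwise_de(e2, meta, "A", "B")
  expect_equal(unname(de$p[1]), 1)
  expect_equal(unname(de$log2fc[1]), 0)
  # covariate collinear with group is dropped with a warning
  meta$batch <- ifelse(meta$region == "A", "x", "y")
  expect_warning(fit_pairwise_de(e, meta, "A", "B", covariates = "batch"),
                 "collinear")
})

test_that("BH adjustment matches the step-up oracle and its invariants", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.037), 0.037)
  set.seed(105)
  for (i in 1:30) {
    p <- runif(sample(3:40, 1))
    if (i %% 5 == 0) p[sample(length(p), 1)] <- NaN
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(ifelse(is.nan(p), NA, p)))
    # monotone in p, never below the raw p, capped at 1
    ok <- !is.na(adj)
    expect_true(all(diff(adj[ok][order(p[ok])]) >= -1e-12))
    expect_true(all(adj[ok] >= p[ok] & adj[ok] <= 1))
  }
  expect_error(bh_fdr(c(0.5, 1.4)), "\\[0, 1\\]")
})

test_that("pi1 behaves at the null, saturated, and mixture limits", {
  set.seed(106)
  expect_lte(storey_pi1(runif(5000)), 0.08)
  expect_gte(storey_pi1(runif(5000, 0, 1e-6)), 0.99)
  p_mix <- c(runif(3500), rbeta(1500, 0.1, 10))
  expect_lt(abs(storey_pi1(p_mix) - 0.30), 0.06)
  expect_error(storey_pi1(numeric(0)), "no p-values")
  expect_warning(storey_pi1(runif(50)), "fewer than 100")
  # clamped to [0, 1] on adversarial input
  expect_gte(storey_pi1(rep(0.999, 200)), 0)
})

test_that("region specificity requires winning every pairwise comparison", {
  de <- tibble(
    feature_id = "f1",
    contrast = c("R1_vs_R2", "R1_vs_R3", "R2_vs_R3"),
    group_a = c("R1", "R1", "R2"), group_b = c("R2", "R3", "R3"),
    log2fc = c(2, 2, 0), p = c(1e-5, 1e-5, 0.9))
  lab <- broad_region_specific(de, fdr_cut = 0.05)
  expect_equal(lab, tibble(feature_id = "f1", region = "R1"))

  # up in only one of two comparisons: unlabeled
  de2 <- de
  de2$p[2] <- 0.9
  expect_equal(nrow(broad_region_specific(de2)), 0L)

  expect_error(broad_region_specific(de[-3, ]), "missing contrast.*R2 vs R3")
})

test_that("region specificity matches a brute-force all-pairs checker", {
  set.seed(107)
  regions <- c("R1", "R2", "R3")
  pairs <- combn(regions, 2)
  for (rep in 1:20) {
    de <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      tibble(feature_id = sprintf("f%02d", 1:15),
             contrast = paste0(pairs[1, i], "_vs_", pairs[2, i]),
             group_a = pairs[1, i], group_b = pairs[2, i],
             log2fc = rnorm(15), p = runif(15)^3)
    })
    lab <- broad_region_specific(de, fdr_cut = 0.2)
    fdr_g <- p.adjust(de$p, "BH")
    for (f in unique(de$feature_id)) {
      for (R in regions) {
        wins <- vapply(setdiff(regions, R), function(Q) {
          row <- which(de$feature_id == f &
                         ((de$group_a == R & de$group_b == Q) |
                            (de$group_a == Q & de$group_b == R)))
          lfc <- ifelse(de$group_a[row] == R, de$log2fc[row], -de$log2fc[row])
          fdr_g[row] < 0.2 && lfc > 0
        }, logical(1))
        expect_equal(all(wins),
                     any(lab$feature_id == f & lab$region == R))
      }
    }
  }
})

test_that("isoform-specific DEG rule: gene-null and opposite-sign branches", {
  pm <- tibble(promoter_id = c("P1", "P2", "P3"), gene_id = c("g1", "g2", "g3"))
  iso <- tibble(feature_id = c("P1", "P2", "P3"), contrast = "A_vs_B",
                log2fc = c(1.5, 2, 1), p = c(1e-4, 1e-4, 1e-4),
                fdr = c(0.01, 0.01, 0.01))
  gene <- tibble(feature_id = c("g1", "g2", "g3"), contrast = "A_vs_B",
                 log2fc = c(0.2, -1, 1.2), p = c(0.5, 0.001, 0.001),
                 fdr = c(0.6, 0.01, 0.01))
  out <- isoform_specific_degs(iso, gene, pm)
  expect_equal(out$reason[out$promoter_id == "P1"], "gene_null")
  expect_equal(out$reason[out$promoter_id == "P2"], "opposite_sign")
  expect_false("P3" %in% out$promoter_id)  # concordant
  # output is a pure filter of significant isoforms
  expect_true(all(out$iso_fdr < 0.05))
  # zero gene log2fc counts as neither sign
  gene0 <- gene; gene0$log2fc[2] <- 0; gene0$p[2] <- 0.01
  out0 <- isoform_specific_degs(iso, gene0, pm)
  expect_false("P2" %in% out0$promoter_id)
  # removing the gene row skips the promoter rather than calling it
  out_skip <- isoform_specific_degs(iso, gene[-2, ], pm)
  expect_false("P2" %in% out_skip$promoter_id)
  expect_equal(attr(out_skip, "n_skipped"), 1L)
})

test_that("pairwise pi1 matrix separates shifted from identical regions", {
  set.seed(108)
  meta <- tibble(sample_id = sprintf("s%02d", 1:18),
                 donor = rep(sprintf("D%d", 1:3), 6),
                 region = rep(c("R1", "R2", "R3"), each = 6))
  m <- matrix(rnbinom(400 * 18, mu = 80, size = 20), 400, 18,
              dimnames = list(sprintf("f%03d", 1:400), meta$sample_id))
  sel <- meta$region == "R3"
  m[1:200, sel] <- rnbinom(200 * sum(sel), mu = 80 * 4, size = 20)
  e <- tmm_normalize(wide_counts(m))
  pi1 <- pairwise_dissimilarity(e, meta)
  expect_s3_class(pi1, "promiso_pi1")
  expect_equal(diag(pi1$pi1), c(R1 = 0, R2 = 0, R3 = 0))
  expect_equal(pi1$pi1, t(pi1$pi1))
  expect_lt(pi1$pi1["R1", "R2"], 0.15)
  expect_gt(pi1$pi1["R1", "R3"], 0.35)
  expect_gt(pi1$pi1["R2", "R3"], 0.35)
  # regions with < 2 samples are excluded with a warning
  meta2 <- meta
  meta2$region[meta2$sample_id == "s01"] <- "tiny"
  expect_warning(pairwise_dissimilarity(e, meta2), "tiny")
})
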