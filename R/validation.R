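# Generic statistical validation operators: one-tailed Fisher
# enrichment, one-tailed Wilcoxon comparisons, Spearman correlation,
# basepair Jaccard, and external-link validation with flanked elements
# and LD proxies.

#' One-tailed Fisher's exact test for enrichment
#'
#' Exact hypergeometric upper-tail p-value for enrichment of the `a`
#' cell, with the sample odds ratio `(a d)/(b c)` (infinite when
#' `b c = 0` and the numerator is positive).
#'
#' @param a,b,c,d Nonnegative integer cells: in-set & in-annotation,
#'   in-set & not, not & in, not & not. A 2x2 matrix may be passed as
#'   `a`.
#' @return Tibble `odds_ratio`, `p`.
#' @export
fisher_one_tailed <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("contingency cells must be nonnegative integers")
  }
  if (sum(cells) == 0) abort("all-zero contingency table")
  p <- phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
  num <- a * d; den <- b * c
  odds <- if (den > 0) num / den else if (num > 0) Inf else NaN
  tibble(odds_ratio = odds, p = p)
}

#' One-tailed Wilcoxon test (x greater)
#'
#' Paired mode is the signed-rank test: zero differences are dropped
#' (Pratt's zero-inclusive variant via `pratt = TRUE`), the exact null is
#' used up to n = 25 without ties, and the normal approximation with
#' continuity and tie corrections otherwise. Unpaired mode is the
#' rank-sum test under the same exact/approximate policy. The
#' alternative is fixed as "x greater".
#'
#' @param x,y Numeric score vectors (equal lengths in paired mode).
#' @param paired Paired signed-rank (`TRUE`) or rank-sum (`FALSE`);
#'   always pass this explicitly when comparing gene sets.
#' @param pratt In paired mode, keep zero differences in the ranking
#'   (Pratt) instead of dropping them.
#' @param exact_max_n Largest n for the exact null (default 25).
#' @return Tibble `statistic`, `p`, `method`, `degenerate`.
#' @export
wilcoxon_one_tailed <- function(x, y, paired = FALSE, pratt = FALSE,
                                exact_max_n = 25L) {
  if (paired && length(x) != length(y)) {
    abort("paired mode requires equal lengths")
  }
  if (paired) {
    d <- x - y
    if (all(d == 0)) {
      return(tibble(statistic = 0, p = 1, method = "signed-rank",
                    degenerate = TRUE))
    }
    if (pratt) {
      # zero-inclusive signed-rank: zeros keep their ranks but drop from W
      r <- rank(abs(d))
      W <- sum(r[d > 0])
      n <- length(d); n0 <- sum(d == 0)
      e <- n * (n + 1) / 4 - n0 * (n0 + 1) / 4
      tie_tab <- table(r)
      v <- n * (n + 1) * (2 * n + 1) / 24 -
        n0 * (n0 + 1) * (2 * n0 + 1) / 24 -
        sum(tie_tab^3 - tie_tab) / 48
      z <- (W - e - 0.5) / sqrt(v)
      return(tibble(statistic = W, p = stats::pnorm(z, lower.tail = FALSE),
                    method = "signed-rank (Pratt, normal approx)",
                    degenerate = FALSE))
    }
    dd <- d[d != 0]
    exact <- length(dd) <= exact_max_n && !any(duplicated(abs(dd)))
    ht <- suppressWarnings(
      wilcox.test(dd, alternative = "greater", mu = 0,
                  exact = exact, correct = TRUE))
    return(tibble(statistic = unname(ht$statistic), p = ht$p.value,
                  method = paste0("signed-rank (",
                                  if (exact) "exact" else "normal approx", ")"),
                  degenerate = FALSE))
  }
  exact <- length(x) <= exact_max_n && length(y) <= exact_max_n &&
    !any(duplicated(c(x, y)))
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "greater", exact = exact,
                correct = TRUE))
  tibble(statistic = unname(ht$statistic), p = ht$p.value,
         method = paste0("rank-sum (",
                         if (exact) "exact" else "normal approx", ")"),
         degenerate = FALSE)
}

#' Spearman rank correlation (tie-aware)
#'
#' Pearson correlation of mid-ranks after pairwise-complete filtering.
#' Returns `NA` with a warning when either vector is constant.
#'
#' @param x,y Numeric vectors of equal length.
#' @return The correlation (single number, or `NA`).
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(rank(x), rank(y), method = "pearson")
}

#' Basepair Jaccard index of two interval sets
#'
#' Overlap basepairs divided by union basepairs, computed on the merged
#' interval sets. An empty union returns 0 with a warning.
#'
#' @param intervals_a,intervals_b Tibbles with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return The Jaccard index in \[0, 1\].
#' @export
jaccard_index <- function(intervals_a, intervals_b) {
  chroms <- union(intervals_a$chrom, intervals_b$chrom)
  to_gr <- function(x) {
    if (!nrow(x)) {
      return(GenomicRanges::GRanges(seqlengths = setNames(
        rep(NA_integer_, length(chroms)), chroms)))
    }
    GenomicRanges::reduce(GenomicRanges::GRanges(
      factor(x$chrom, levels = chroms),
      IRanges::IRanges(x$start + 1L, x$end)))
  }
  ga <- to_gr(intervals_a); gb <- to_gr(intervals_b)
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(ga, gb)))
  if (uni == 0) {
    warn("empty union: Jaccard index defined as 0")
    return(0)
  }
  inter / uni
}

# expand a reference set with LD proxies above r2_min; proxies inherit
# the lead variant's target gene
expand_reference <- function(reference, proxies, r2_min) {
  assert_columns(reference, c("variant_id", "chrom", "pos", "gene_id"),
                 "reference")
  ref <- reference %>%
    mutate(pos0 = .data$pos - 1L) %>%
    select("variant_id", "chrom", "pos0", "gene_id")
  if (is.null(proxies) || !nrow(proxies)) return(ref)
  assert_columns(proxies, c("lead_id", "proxy_id", "chrom", "pos", "r2"),
                 "proxies")
  if (any(proxies$r2 < 0 | proxies$r2 > 1)) abort("r2 must lie in [0, 1]")
  px <- proxies %>%
    filter(.data$r2 > r2_min) %>%
    inner_join(reference %>% select(lead_id = "variant_id", "gene_id"),
               by = "lead_id", relationship = "many-to-many") %>%
    mutate(pos0 = .data$pos - 1L) %>%
    select(variant_id = "proxy_id", "chrom", "pos0", "gene_id")
  bind_rows(ref, px) %>% distinct()
}

#' Validate links against an external reference set
#'
#' A link's element, flanked by `flank_bp` on both sides, is intersected
#' with reference variant positions (leads plus LD proxies with
#' `r2 > r2_min`, which inherit the lead's target gene). A link is
#' *validated* when an intersecting variant's target gene matches the
#' link's gene; the validated proportion divides validated links by
#' links whose flanked element intersects any reference position.
#' Proportions are reported per region, split by promoter type (5' vs
#' non-5'), and each region is compared against the pooled others with
#' the one-tailed Fisher test (alternative: that region's proportion is
#' higher).
#'
#' @param links Link tibble (needs `region`, `element_id`, `gene_id`,
#'   `rank`, `chrom`, `start`, `end`).
#' @param reference Tibble `variant_id`, `chrom`, `pos` (1-based),
#'   `gene_id`, optional `source`.
#' @param proxies Optional LD proxy tibble `lead_id`, `proxy_id`,
#'   `chrom`, `pos`, `r2`.
#' @param flank_bp Element flank (default 500).
#' @param r2_min LD threshold for proxies (default 0.8).
#' @return List with `$proportions` (per region x promoter type:
#'   `n_intersected`, `n_validated`, `proportion`) and `$fisher`
#'   (region-vs-rest tests).
#' @export
validate_links <- function(links, reference, proxies = NULL,
                           flank_bp = 500L, r2_min = 0.8) {
  if (!nrow(reference)) abort("empty reference set")
  ref <- expand_reference(reference, proxies, r2_min)
  flk <- links %>%
    distinct(.data$region, .data$element_id, .data$gene_id, .data$rank,
             .data$chrom, .data$start, .data$end) %>%
    mutate(fstart = .data$start - flank_bp, fend = .data$end + flank_bp,
           promoter_type = if_else(.data$rank == 1L, "five_prime",
                                   "non_five_prime"))
  hits <- flk %>%
    inner_join(ref, by = "chrom", suffix = c("", ".ref"),
               relationship = "many-to-many") %>%
    filter(.data$pos0 >= .data$fstart, .data$pos0 < .data$fend) %>%
    group_by(.data$region, .data$element_id, .data$gene_id,
             .data$promoter_type) %>%
    summarise(validated = any(.data$gene_id == .data$gene_id.ref),
              .groups = "drop")
  props <- flk %>%
    left_join(hits, by = c("region", "element_id", "gene_id",
                           "promoter_type")) %>%
    mutate(intersected = !is.na(.data$validated),
           validated = !is.na(.data$validated) & .data$validated) %>%
    group_by(.data$region, .data$promoter_type) %>%
    summarise(n_links = n(),
              n_intersected = sum(.data$intersected),
              n_validated = sum(.data$validated),
              proportion = if (sum(.data$intersected) > 0)
                sum(.data$validated) / sum(.data$intersected) else NA_real_,
              .groups = "drop")

  fisher <- props %>%
    group_by(.data$promoter_type) %>%
    dplyr::group_modify(function(gdf, key) {
      purrr::map_dfr(seq_len(nrow(gdf)), function(i) {
        a <- gdf$n_validated[i]
        b <- gdf$n_intersected[i] - a
        cc <- sum(gdf$n_validated[-i])
        dd <- sum(gdf$n_intersected[-i]) - cc
        if (a + b == 0 || cc + dd == 0) {
          return(tibble(region = gdf$region[i], odds_ratio = NA_real_,
                        p = NA_real_))
        }
        ft <- fisher_one_tailed(a, b, cc, dd)
        tibble(region = gdf$region[i], odds_ratio = ft$odds_ratio, p = ft$p)
      })
    }) %>%
    ungroup()

  list(proportions = props, fisher = fisher)
}
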