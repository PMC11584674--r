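# ABC-Max assignment of fine-mapped GWAS variants to
# promoter-isoforms/genes, closest-gene context, lead-SNP windows, and
# cross-region target summaries.

#' Overlap fine-mapped SNPs with linked elements
#'
#' Pairs SNPs passing the posterior-inclusion-probability filter with
#' every link whose element interval contains the SNP. SNP positions are
#' 1-based on input and converted to 0-based internally; element
#' intervals are 0-based half-open. Promoter-proximal elements are
#' excluded by default (enhancer fine-mapping).
#'
#' @param snps Tibble `rsid`, `chrom`, `pos` (1-based), `pip`.
#' @param links Link tibble from [abc_scores()] (element coordinates
#'   included).
#' @param pip_min PIP threshold; SNPs must exceed it (default 0.01).
#' @param include_proximal Also overlap promoter-proximal elements.
#' @return Tibble of (snp, link) pairs. SNPs overlapping no element are
#'   counted in the `n_unpaired` attribute; malformed positions are
#'   dropped and reported.
#' @export
overlap_snps <- function(snps, links, pip_min = 0.01,
                         include_proximal = FALSE) {
  assert_columns(snps, c("rsid", "chrom", "pos", "pip"), "snps")
  bad <- !is.finite(snps$pos) | snps$pos < 1
  if (any(bad)) {
    warn(sprintf("dropping %d SNP row(s) with malformed positions", sum(bad)))
    snps <- snps[!bad, ]
  }
  snps <- snps %>%
    filter(.data$pip > pip_min) %>%
    mutate(pos0 = .data$pos - 1L)
  lk <- if (include_proximal) links else links %>% filter(.data$kind == "distal")
  pairs <- snps %>%
    inner_join(lk, by = "chrom", suffix = c("", ".link"),
               relationship = "many-to-many") %>%
    filter(.data$pos0 >= .data$start, .data$pos0 < .data$end)
  attr(pairs, "n_unpaired") <- sum(!snps$rsid %in% pairs$rsid)
  pairs
}

#' ABC-Max target assignment
#'
#' Per SNP (and per region unless `per_region = FALSE`), retains the
#' link with the maximum ABC score; ties break toward the smaller TSS
#' distance, then lexicographic `promoter_id`. The assignment is
#' deterministic and invariant to input order. Per-gene aggregation over
#' a gene's assignments sets `gene_promoter_class` to `5'`, `non-5'`, or
#' `both`.
#'
#' @param pairs Output of [overlap_snps()].
#' @param per_region Keep one assignment per (snp, region) (default);
#'   otherwise one global maximum per snp.
#' @return Tibble of target assignments with `promoter_type`
#'   (`five_prime` iff promoter rank is 1) and `gene_promoter_class`.
#' @export
abc_max <- function(pairs, per_region = TRUE) {
  if (!nrow(pairs)) {
    return(tibble(rsid = character(), region = character(),
                  element_id = character(), promoter_id = character(),
                  gene_id = character(), abc = numeric(),
                  promoter_type = character(),
                  gene_promoter_class = character()))
  }
  grouped <- if (per_region) {
    pairs %>% group_by(.data$rsid, .data$region)
  } else {
    pairs %>% group_by(.data$rsid)
  }
  out <- grouped %>%
    arrange(dplyr::desc(.data$abc), .data$distance_bp, .data$promoter_id,
            .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    mutate(promoter_type = if_else(.data$rank == 1L,
                                   "five_prime", "non_five_prime")) %>%
    arrange(.data$rsid, .data$region)
  cls <- out %>%
    group_by(.data$gene_id) %>%
    summarise(gene_promoter_class = dplyr::case_when(
      all(.data$promoter_type == "five_prime") ~ "5'",
      all(.data$promoter_type == "non_five_prime") ~ "non-5'",
      TRUE ~ "both"), .groups = "drop")
  out %>%
    left_join(cls, by = "gene_id") %>%
    select("rsid", "region", "element_id", "promoter_id", "gene_id",
           "rank", "promoter_type", "gene_promoter_class", "abc",
           "activity", "contact", "distance_bp", "pip",
           "start", "end", "chrom", "pos")
}

#' Closest gene to each SNP
#'
#' The closest gene is the gene whose nearest promoter TSS minimizes the
#' absolute distance to the SNP. Exact ties report all tied genes,
#' sorted by `gene_id`.
#'
#' @param snps SNP tibble (`rsid`, `chrom`, `pos` 1-based).
#' @param promoters Promoter tibble carrying TSSs.
#' @return Tibble `rsid`, `gene_id`, `distance_bp` (possibly several
#'   rows per rsid on ties).
#' @export
closest_gene <- function(snps, promoters) {
  if (!nrow(promoters)) abort("empty promoter annotation")
  per_gene <- snps %>%
    mutate(pos0 = .data$pos - 1L) %>%
    inner_join(promoters %>% select("gene_id", "chrom", "tss"),
               by = "chrom", relationship = "many-to-many") %>%
    mutate(distance_bp = abs(.data$pos0 - .data$tss)) %>%
    group_by(.data$rsid, .data$gene_id) %>%
    summarise(distance_bp = min(.data$distance_bp), .groups = "drop")
  per_gene %>%
    group_by(.data$rsid) %>%
    filter(.data$distance_bp == min(.data$distance_bp)) %>%
    ungroup() %>%
    arrange(.data$rsid, .data$gene_id)
}

#' Lead SNPs per merged window
#'
#' Flanks each significant variant by `flank_bp` on both sides, merges
#' overlapping windows per chromosome, and reports the variant with the
#' lowest p-value in each merged window (ties break toward the smaller
#' position).
#'
#' @param gwas_hits Tibble `chrom`, `pos`, `p` (any extra columns are
#'   carried through for the lead row).
#' @param flank_bp Flank width (default 10000).
#' @return One row per merged window: lead variant columns plus
#'   `window_start`, `window_end`, `n_in_window`.
#' @export
lead_snp_windows <- function(gwas_hits, flank_bp = 1e4) {
  assert_columns(gwas_hits, c("chrom", "pos", "p"), "gwas_hits")
  if (any(!is.finite(gwas_hits$p) | gwas_hits$p < 0 | gwas_hits$p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  purrr::map_dfr(split(gwas_hits, gwas_hits$chrom), function(h) {
    ir <- IRanges::IRanges(pmax(0L, h$pos - flank_bp), h$pos + flank_bp)
    merged <- IRanges::reduce(ir)
    idx <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, merged))
    h %>%
      mutate(window = idx,
             window_start = IRanges::start(merged)[idx],
             window_end = IRanges::end(merged)[idx]) %>%
      group_by(.data$window) %>%
      arrange(.data$p, .data$pos, .by_group = TRUE) %>%
      mutate(n_in_window = n()) %>%
      slice(1L) %>%
      ungroup() %>%
      select(-"window")
  }) %>%
    arrange(.data$chrom, .data$pos)
}

#' Assign fine-mapped SNPs to target genes end-to-end
#'
#' Composes [overlap_snps()], [abc_max()], [closest_gene()], and
#' optional priority scores (rank percentile over all scored genes)
#' into the full target-assignment table.
#'
#' @inheritParams overlap_snps
#' @param promoters Promoter tibble.
#' @param scores Optional tibble `gene_id`, `score` of per-gene priority
#'   scores.
#' @param per_region See [abc_max()].
#' @return Assignment tibble with `is_closest_gene`, `closest_gene_id`
#'   and, when scores are given, `priority_score` and
#'   `priority_rank_pct`.
#' @export
assign_targets <- function(snps, links, promoters, scores = NULL,
                           pip_min = 0.01, include_proximal = FALSE,
                           per_region = TRUE) {
  pairs <- overlap_snps(snps, links, pip_min = pip_min,
                        include_proximal = include_proximal)
  tgt <- abc_max(pairs, per_region = per_region)
  if (!nrow(tgt)) return(tgt)
  cg <- closest_gene(snps %>% semi_join(tgt, by = "rsid"), promoters) %>%
    group_by(.data$rsid) %>%
    summarise(closest_gene_id = paste(.data$gene_id, collapse = ","),
              .groups = "drop")
  tgt <- tgt %>%
    left_join(cg, by = "rsid") %>%
    mutate(is_closest_gene = purrr::map2_lgl(
      .data$gene_id, .data$closest_gene_id,
      ~ .x %in% strsplit(.y, ",", fixed = TRUE)[[1]]))
  if (!is.null(scores)) {
    assert_columns(scores, c("gene_id", "score"), "scores")
    sc <- scores %>%
      mutate(priority_rank_pct = rank(.data$score) / n()) %>%
      rename(priority_score = "score")
    tgt <- tgt %>% left_join(sc, by = "gene_id")
  }
  tgt
}

#' Summarize target assignments across regions
#'
#' Reports, per region and pooled, the fraction of target genes reached
#' only via non-5' links, the fraction that are not the closest gene to
#' their SNP, and the fraction of genes unique to one region. When
#' priority scores are present, compares score distributions of non-5'
#' targets against 5' targets and against closest genes with the
#' one-tailed rank-sum test (alternative: non-5' greater; unpaired mode,
#' as the gene sets have unequal sizes).
#'
#' @param assignments Output of [assign_targets()].
#' @param scores Optional `gene_id`/`score` tibble used for the closest
#'   genes' scores (defaults to the scores already joined on
#'   assignments).
#' @return List with `$per_region`, `$pooled` and (when scores are
#'   available) `$score_tests`.
#' @export
summarize_targets <- function(assignments, scores = NULL) {
  if (!nrow(assignments)) abort("no assignments to summarise")
  gene_flags <- assignments %>%
    group_by(.data$gene_id) %>%
    summarise(
      non5_only = all(.data$promoter_type == "non_five_prime"),
      not_closest = all(!.data$is_closest_gene),
      n_regions = n_distinct(.data$region), .groups = "drop")
  pooled <- gene_flags %>%
    summarise(n_genes = n(),
              frac_non5_only = mean(.data$non5_only),
              frac_not_closest = mean(.data$not_closest),
              frac_single_region = mean(.data$n_regions == 1L))
  per_region <- assignments %>%
    group_by(.data$region, .data$gene_id) %>%
    summarise(non5_only = all(.data$promoter_type == "non_five_prime"),
              not_closest = all(!.data$is_closest_gene),
              .groups = "drop_last") %>%
    summarise(n_genes = n(),
              frac_non5_only = mean(.data$non5_only),
              frac_not_closest = mean(.data$not_closest),
              .groups = "drop")

  out <- list(per_region = per_region, pooled = pooled)

  have_scores <- "priority_score" %in% names(assignments) || !is.null(scores)
  if (have_scores) {
    if (is.null(scores)) {
      scores <- assignments %>%
        distinct(.data$gene_id, score = .data$priority_score)
    }
    g5 <- assignments %>%
      filter(.data$promoter_type == "five_prime") %>%
      distinct(.data$gene_id) %>%
      left_join(scores, by = "gene_id") %>% pull("score")
    gn5 <- assignments %>%
      filter(.data$promoter_type == "non_five_prime") %>%
      distinct(.data$gene_id) %>%
      left_join(scores, by = "gene_id") %>% pull("score")
    gcl <- assignments %>%
      tidyr::separate_longer_delim("closest_gene_id", ",") %>%
      distinct(gene_id = .data$closest_gene_id) %>%
      left_join(scores, by = "gene_id") %>% pull("score")
    tests <- list()
    if (length(gn5) && length(g5)) {
      tests$non5_vs_5 <- wilcoxon_one_tailed(gn5, g5, paired = FALSE)
    }
    if (length(gn5) && length(gcl)) {
      tests$non5_vs_closest <- wilcoxon_one_tailed(gn5, gcl[!is.na(gcl)],
                                                   paired = FALSE)
    }
    if (length(tests)) {
      out$score_tests <- dplyr::bind_rows(tests, .id = "comparison")
    }
  }
  out
}
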