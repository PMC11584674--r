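# Promoter-isoform quantification from junction reads, TMM/CPM
# normalization, detection filters, and major-promoter calls.

#' Quantify promoter-isoforms from junction read counts
#'
#' Sums, per promoter and sample, the reads over the promoter's
#' first-intron junctions. By default only uniquely identifiable
#' promoters are quantified; `internal` promoters may be included (used
#' when calling active promoters for enhancer linking), while
#' `single_exon_only` promoters have no junctions and are always dropped.
#' Junctions matching more than one retained promoter are counted for
#' none of them and reported in the `ambiguous_junctions` attribute;
#' junction rows matching no promoter are tallied in `unassigned`.
#'
#' @param junctions Wide tibble of junction counts with key columns
#'   `chrom`, `donor`, `acceptor`, `strand` followed by one column per
#'   sample.
#' @param promoters Classified promoter tibble ([promoter_models()]).
#' @param exclude_nonunique Drop `internal` promoters (default `TRUE`).
#' @return Wide count tibble (`feature_id` = promoter_id, one column per
#'   sample), with attributes `feature_kind = "promoter_isoform"`,
#'   `ambiguous_junctions` and `unassigned`.
#' @export
quantify_promoters <- function(junctions, promoters, exclude_nonunique = TRUE) {
  assert_columns(junctions, c("chrom", "donor", "acceptor", "strand"),
                 "junctions")
  keep_class <- if (exclude_nonunique) "unique" else c("unique", "internal")
  kept <- promoters %>% filter(.data$class %in% keep_class)

  jmap <- kept %>%
    select("promoter_id", "chrom", "strand", "junctions") %>%
    tidyr::unnest("junctions")

  key <- function(df) paste(df$chrom, df$strand, df$donor, df$acceptor)
  jmap$key <- key(jmap)
  amb_keys <- jmap %>% count(.data$key) %>% filter(.data$n > 1L) %>% pull("key")
  ambiguous <- jmap %>% filter(.data$key %in% amb_keys)
  if (nrow(ambiguous)) {
    inform(sprintf(
      "%d junction(s) shared between promoters excluded from quantification",
      length(amb_keys)))
  }
  jmap <- jmap %>% filter(!.data$key %in% amb_keys)

  jx <- junctions
  jx$key <- key(jx)
  unassigned <- sum(!jx$key %in% jmap$key)
  if (unassigned > 0L) {
    inform(sprintf("%d junction row(s) match no quantifiable promoter", unassigned))
  }

  samples <- setdiff(names(junctions), c("chrom", "donor", "acceptor", "strand"))
  counts <- jmap %>%
    select("promoter_id", "key") %>%
    left_join(jx %>% select("key", all_of(samples)), by = "key") %>%
    group_by(feature_id = .data$promoter_id) %>%
    summarise(across(all_of(samples), ~ sum(.x, na.rm = TRUE)), .groups = "drop")

  # promoters keep a zero row when their junctions never appear in the
  # table or were all ambiguous
  quantifiable_ids <- kept$promoter_id[
    vapply(kept$junctions, nrow, integer(1)) > 0L]
  out <- tibble(feature_id = sort(quantifiable_ids)) %>%
    left_join(counts, by = "feature_id") %>%
    mutate(across(all_of(samples), ~ tidyr::replace_na(.x, 0)))

  attr(out, "feature_kind") <- "promoter_isoform"
  attr(out, "ambiguous_junctions") <- ambiguous %>% select(-"key")
  attr(out, "unassigned") <- unassigned
  out
}

#' TMM normalization and CPM
#'
#' Computes trimmed-mean-of-M-values scaling factors (reference sample =
#' the one whose upper-quartile count fraction is closest to the mean,
#' trims M = 0.30 / A = 0.05, inverse-binomial precision weights) and
#' counts-per-million against the factor-adjusted library sizes. Factors
#' are rescaled to geometric mean 1.
#'
#' @param counts Wide count tibble (`feature_id` + sample columns).
#' @param feature_kind Optional label (`gene`, `promoter_isoform`, `ocr`);
#'   defaults to the table's `feature_kind` attribute.
#' @return A `promiso_expr` object: list with `cpm` and `counts` wide
#'   tibbles, a `factors` tibble (`sample_id`, `lib_size`, `norm_factor`)
#'   and `feature_kind`.
#' @export
tmm_normalize <- function(counts, feature_kind = NULL) {
  m <- as_count_matrix(counts)
  if (ncol(m) < 2L) abort("TMM normalization requires at least 2 samples")
  lib <- colSums(m)
  if (any(lib <= 0)) {
    abort(paste0("sample(s) with zero library size: ",
                 paste(colnames(m)[lib <= 0], collapse = ", ")))
  }
  nf <- edgeR::calcNormFactors(m, method = "TMM",
                               logratioTrim = 0.30, sumTrim = 0.05)
  nf <- nf / exp(mean(log(nf)))
  cpm <- t(t(m) / (lib * nf)) * 1e6
  structure(
    list(
      cpm = matrix_to_tibble(cpm),
      counts = matrix_to_tibble(m),
      factors = tibble(sample_id = colnames(m), lib_size = unname(lib),
                       norm_factor = unname(nf)),
      feature_kind = feature_kind %||% attr(counts, "feature_kind") %||% "feature"
    ),
    class = "promiso_expr"
  )
}

#' @export
print.promiso_expr <- function(x, ...) {
  cat(sprintf("<promiso_expr> %s: %d features x %d samples (TMM-normalized CPM)\n",
              x$feature_kind, nrow(x$cpm), nrow(x$factors)))
  invisible(x)
}

#' @export
tidy.promiso_expr <- function(x, ...) {
  tidyr::pivot_longer(x$cpm, -"feature_id",
                      names_to = "sample_id", values_to = "cpm")
}

#' @export
glance.promiso_expr <- function(x, ...) {
  tibble(feature_kind = x$feature_kind, n_features = nrow(x$cpm),
         n_samples = nrow(x$factors),
         median_lib_size = median(x$factors$lib_size),
         factor_range = diff(range(x$factors$norm_factor)))
}

# CPM matrix accessor (pseudo-count only for log transforms, never filtering)
expr_cpm <- function(expr) as_count_matrix(expr$cpm)

log2_cpm <- function(expr, pseudo = 0.5) log2(expr_cpm(expr) + pseudo)

#' Detection filter on normalized expression
#'
#' Keeps features with CPM at least `min_cpm` in at least (or, with
#' `strict_gt_fraction`, strictly more than) `min_fraction` of samples.
#' Defaults match the gene/OCR rule (1 CPM, 20%, non-strict); the
#' promoter-isoform rule is 2 CPM in more than 40% of samples
#' (`min_cpm = 2, min_fraction = 0.4, strict_gt_fraction = TRUE`).
#'
#' @param expr A `promiso_expr` object.
#' @param min_cpm CPM detection threshold.
#' @param min_fraction Required fraction of samples, in (0, 1].
#' @param strict_gt_fraction Require strictly more than `min_fraction`.
#' @return The filtered `promiso_expr`.
#' @export
filter_detected <- function(expr, min_cpm = 1, min_fraction = 0.20,
                            strict_gt_fraction = FALSE) {
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    abort("min_fraction must lie in (0, 1]")
  }
  cpm <- expr_cpm(expr)
  frac <- rowMeans(cpm >= min_cpm)
  keep <- if (strict_gt_fraction) frac > min_fraction else frac >= min_fraction
  expr$cpm <- expr$cpm[keep, , drop = FALSE]
  expr$counts <- expr$counts[keep, , drop = FALSE]
  expr
}

#' Call the major promoter of each gene
#'
#' The major promoter is the promoter-isoform with the highest mean CPM
#' across the selected samples; ties break toward the smaller (more 5')
#' rank. Genes with no surviving promoter are omitted and counted in the
#' `n_omitted` attribute.
#'
#' @param expr `promiso_expr` over promoter-isoforms.
#' @param promoters Promoter tibble (for gene and rank lookup).
#' @param samples Optional character vector restricting the sample set
#'   (e.g. one region's samples); default all samples.
#' @return Tibble `gene_id`, `major_promoter_id`, `rank`, `mean_cpm`,
#'   `is_5prime`.
#' @export
call_major_promoters <- function(expr, promoters, samples = NULL) {
  cpm <- expr_cpm(expr)
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(cpm))
    if (length(missing)) abort("unknown sample(s) in `samples`")
    cpm <- cpm[, samples, drop = FALSE]
  }
  means <- tibble(promoter_id = rownames(cpm), mean_cpm = rowMeans(cpm))
  scored <- promoters %>%
    select("promoter_id", "gene_id", "rank") %>%
    inner_join(means, by = "promoter_id")
  n_omitted <- n_distinct(promoters$gene_id) - n_distinct(scored$gene_id)
  out <- scored %>%
    group_by(.data$gene_id) %>%
    arrange(dplyr::desc(.data$mean_cpm), .data$rank, .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    mutate(is_5prime = .data$rank == 1L) %>%
    select("gene_id", major_promoter_id = "promoter_id", "rank",
           "mean_cpm", "is_5prime")
  attr(out, "n_omitted") <- n_omitted
  out
}
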