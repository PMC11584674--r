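# Pairwise differential statistics across regions: weighted
# least-squares per-feature models, BH FDR, Storey pi1 dissimilarity,
# region-specificity calls, and the promoter-isoform-specific DEG rule.

# precision weights from a LOWESS trend of residual sqrt-SD against mean
# log2-CPM, evaluated at each observation's fitted value
mean_variance_weights <- function(y, X) {
  fit <- stats::lm.fit(X, t(y))
  res <- t(as.matrix(fit$residuals))
  df <- ncol(y) - fit$rank
  s <- sqrt(rowSums(res^2) / max(df, 1L))
  mu <- rowMeans(y)
  ok <- s > 0
  if (sum(ok) < 10L || df < 1L) {
    return(matrix(1, nrow(y), ncol(y), dimnames = dimnames(y)))
  }
  tr <- lowess(mu[ok], sqrt(s[ok]), f = 0.5)
  fitted <- t(as.matrix(fit$fitted.values))
  sd_hat <- approx(tr$x, tr$y, xout = pmin(pmax(fitted, min(tr$x)), max(tr$x)),
                   rule = 2, ties = mean)$y
  w <- matrix(pmax(sd_hat, 1e-4)^-4, nrow(y), ncol(y))
  dimnames(w) <- dimnames(y)
  w
}

#' Pairwise differential expression / accessibility
#'
#' Fits, per feature, `log2(CPM + 0.5) ~ group + donor + covariates` by
#' weighted least squares, where the weights follow an inverse
#' mean-variance trend (LOWESS of residual sqrt-SD versus mean log2-CPM).
#' The donor is always included as a fixed blocking covariate when more
#' than one donor is present; covariates collinear with the design are
#' dropped with a warning. Reports the group-coefficient log2 fold change
#' (`group_a` minus `group_b`), a two-sided t-test p-value, and the
#' BH-adjusted FDR within the contrast.
#'
#' @param expr A `promiso_expr` object.
#' @param meta Sample metadata tibble with `sample_id`, the grouping
#'   column, and a `donor` column.
#' @param group_a,group_b Group labels to contrast (log2fc = a minus b).
#' @param group_col Metadata column holding the group labels
#'   (default `"region"`).
#' @param covariates Additional metadata columns to adjust for.
#' @return Tibble of per-feature results: `feature_id`, `contrast`,
#'   `group_a`, `group_b`, `log2fc`, `t`, `df`, `p`, `fdr`.
#' @export
fit_pairwise_de <- function(expr, meta, group_a, group_b,
                            group_col = "region", covariates = character()) {
  assert_columns(meta, c("sample_id", group_col), "meta")
  if (identical(group_a, group_b)) abort("group_a and group_b must differ")
  sub <- meta %>%
    filter(.data[[group_col]] %in% c(group_a, group_b),
           .data$sample_id %in% sample_cols(expr$cpm))
  if (min(table(factor(sub[[group_col]], levels = c(group_a, group_b)))) < 2L) {
    abort("each group needs at least 2 samples")
  }
  y <- log2_cpm(expr)[, sub$sample_id, drop = FALSE]

  grp <- factor(sub[[group_col]], levels = c(group_b, group_a))
  df_design <- tibble(.grp = grp)
  if ("donor" %in% names(meta) && n_distinct(sub$donor) > 1L) {
    df_design$.donor <- factor(sub$donor)
  }
  missing_cov <- setdiff(covariates, names(meta))
  if (length(missing_cov)) {
    abort(paste0("covariate(s) absent from meta: ",
                 paste(missing_cov, collapse = ", ")))
  }
  for (cv in covariates) df_design[[cv]] <- sub[[cv]]

  X <- model.matrix(~ ., data = df_design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[-(qrX$pivot[seq_len(qrX$rank)])]
    if (any(startsWith(drop_cols, ".grp"))) {
      abort("group term is collinear with the remaining design")
    }
    warn(paste0("dropping collinear design column(s): ",
                paste(drop_cols, collapse = ", ")))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  grp_col <- grep("^\\.grp", colnames(X))
  stopifnot(length(grp_col) == 1L)
  df_resid <- nrow(X) - ncol(X)
  if (df_resid < 1L) abort("no residual degrees of freedom")

  W <- mean_variance_weights(y, X)

  res <- purrr::map_dfr(seq_len(nrow(y)), function(g) {
    yg <- y[g, ]
    if (sd(yg) == 0) {
      return(tibble(log2fc = 0, t = 0, p = 1))
    }
    wg <- W[g, ]
    fit <- stats::lm.wfit(X, yg, wg)
    rss <- sum(wg * fit$residuals^2)
    sigma2 <- rss / df_resid
    R <- qr.R(fit$qr)
    XtWXi <- chol2inv(R)
    beta <- unname(fit$coefficients[grp_col])
    se <- sqrt(sigma2 * XtWXi[grp_col, grp_col])
    tt <- if (se > 0) beta / se else 0
    tibble(log2fc = unname(beta), t = unname(tt),
           p = 2 * pt(-abs(tt), df_resid))
  })

  tibble(feature_id = rownames(y),
         contrast = paste0(group_a, "_vs_", group_b),
         group_a = group_a, group_b = group_b) %>%
    dplyr::bind_cols(res) %>%
    mutate(df = df_resid, fdr = bh_fdr(.data$p)) %>%
    select("feature_id", "contrast", "group_a", "group_b",
           "log2fc", "t", "df", "p", "fdr")
}

#' All-pairs differential analysis
#'
#' Runs [fit_pairwise_de()] for every unordered pair of group labels and
#' binds the results.
#'
#' @inheritParams fit_pairwise_de
#' @return Bound tibble of [fit_pairwise_de()] results.
#' @export
fit_all_pairs_de <- function(expr, meta, group_col = "region",
                             covariates = character()) {
  groups <- sort(unique(meta[[group_col]][meta$sample_id %in%
                                            sample_cols(expr$cpm)]))
  if (length(groups) < 2L) abort("need at least two groups")
  pairs <- combn(groups, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    fit_pairwise_de(expr, meta, pairs[1L, i], pairs[2L, i],
                    group_col = group_col, covariates = covariates)
  })
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment, monotone and capped at 1. `NaN` inputs
#' propagate as `NA` at their positions and are excluded from ranking.
#'
#' @param pvalues Numeric vector in \[0, 1\] (NA/NaN allowed).
#' @return Adjusted p-values, same length.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(ifelse(is.nan(pvalues), NA, pvalues), method = "BH")
}

#' Storey's estimate of the proportion of non-null tests
#'
#' Estimates pi0 as `#\{p > lambda\} / ((1 - lambda) n)` over a lambda
#' grid, smooths the estimates with a cubic smoothing spline (df = 3),
#' evaluates at the largest lambda, and clamps to \[0, 1\]; pi1 = 1 - pi0.
#' When fewer than 5 usable grid points remain the fixed lambda = 0.5
#' estimate is used instead.
#'
#' @param pvalues Numeric p-values.
#' @param lambda_grid Evaluation grid (default `seq(0.05, 0.95, 0.05)`).
#' @return The pi1 estimate (single number in \[0, 1\]).
#' @export
storey_pi1 <- function(pvalues, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  p <- pvalues[!is.na(pvalues)]
  if (!length(p)) abort("no p-values supplied")
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  if (length(p) < 100L) {
    warn("fewer than 100 p-values; pi1 estimate may be unstable")
  }
  lambda_grid <- sort(lambda_grid)
  pi0_l <- vapply(lambda_grid,
                  function(l) mean(p > l) / (1 - l), numeric(1))
  usable <- is.finite(pi0_l)
  pi0 <- if (sum(usable) < 5L) {
    mean(p > 0.5) / 0.5
  } else {
    sp <- tryCatch(
      smooth.spline(lambda_grid[usable], pi0_l[usable], df = 3),
      error = function(e) NULL)
    if (is.null(sp)) mean(p > 0.5) / 0.5
    else predict(sp, x = max(lambda_grid[usable]))$y
  }
  1 - min(max(pi0, 0), 1)
}

#' Broad-region specificity calls
#'
#' A feature is specific to region R iff, at a global FDR recomputed by
#' pooling p-values over all supplied contrasts, every pairwise contrast
#' of R against another region is significant with the fold change
#' favoring R.
#'
#' @param de Bound DE tibble covering all pairwise contrasts among the
#'   regions present (from [fit_all_pairs_de()]).
#' @param fdr_cut Global FDR threshold (default 0.05).
#' @return Tibble `feature_id`, `region` for labeled features (possibly
#'   zero rows).
#' @export
broad_region_specific <- function(de, fdr_cut = 0.05) {
  regions <- sort(unique(c(de$group_a, de$group_b)))
  have <- unique(paste(pmin(de$group_a, de$group_b),
                       pmax(de$group_a, de$group_b)))
  need <- combn(regions, 2L)
  miss <- !paste(need[1L, ], need[2L, ]) %in% have
  if (any(miss)) {
    abort(paste0("missing contrast(s): ",
                 paste(need[1L, miss], need[2L, miss], sep = " vs ",
                       collapse = ", ")))
  }
  de <- de %>% mutate(fdr_global = bh_fdr(.data$p))
  purrr::map_dfr(regions, function(R) {
    hits <- de %>%
      filter((.data$group_a == R & .data$log2fc > 0) |
               (.data$group_b == R & .data$log2fc < 0),
             .data$fdr_global < fdr_cut) %>%
      mutate(other = if_else(.data$group_a == R, .data$group_b, .data$group_a)) %>%
      group_by(.data$feature_id) %>%
      summarise(n_other = n_distinct(.data$other), .groups = "drop") %>%
      filter(.data$n_other == length(regions) - 1L)
    tibble(feature_id = hits$feature_id, region = R)
  })
}

#' Promoter-isoform-specific differential calls
#'
#' A promoter-isoform is a specific DEG for a contrast iff its FDR is
#' below `fdr_cut` while the parent gene is either not nominally
#' significant (`p > gene_null_p`) or changes in the opposite direction
#' (strict sign inequality; a zero fold change counts as neither sign).
#'
#' @param iso_de DE tibble over promoter-isoforms.
#' @param gene_de DE tibble over genes (same contrasts, same engine).
#' @param promoters Promoter tibble providing the promoter-to-gene map.
#' @param fdr_cut Isoform FDR threshold (default 0.05).
#' @param gene_null_p Gene nominal-p threshold (default 0.1).
#' @return Tibble `promoter_id`, `gene_id`, `contrast`, `iso_log2fc`,
#'   `iso_fdr`, `gene_log2fc`, `gene_p`, `reason`
#'   (`gene_null` / `opposite_sign`). Promoters lacking a parent-gene DE
#'   row are skipped and counted in the `n_skipped` attribute.
#' @export
isoform_specific_degs <- function(iso_de, gene_de, promoters,
                                  fdr_cut = 0.05, gene_null_p = 0.1) {
  sig <- iso_de %>%
    filter(.data$fdr < fdr_cut) %>%
    inner_join(promoters %>% select(feature_id = "promoter_id", "gene_id"),
               by = "feature_id")
  joined <- sig %>%
    left_join(gene_de %>%
                select(gene_id = "feature_id", "contrast",
                       gene_log2fc = "log2fc", gene_p = "p"),
              by = c("gene_id", "contrast"))
  n_skipped <- sum(is.na(joined$gene_p))
  out <- joined %>%
    filter(!is.na(.data$gene_p)) %>%
    mutate(
      gene_null = .data$gene_p > gene_null_p,
      opposite = sign(.data$log2fc) * sign(.data$gene_log2fc) == -1,
      reason = dplyr::case_when(.data$gene_null ~ "gene_null",
                                .data$opposite ~ "opposite_sign",
                                TRUE ~ NA_character_)
    ) %>%
    filter(!is.na(.data$reason)) %>%
    select(promoter_id = "feature_id", "gene_id", "contrast",
           iso_log2fc = "log2fc", iso_fdr = "fdr",
           "gene_log2fc", "gene_p", "reason")
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Pairwise pi1 dissimilarity matrix
#'
#' For every unordered pair of regions, fits the pairwise differential
#' model and summarises its p-values by Storey's pi1, giving a
#' statistical dissimilarity between regions. Regions with fewer than
#' two samples are excluded with a warning.
#'
#' @inheritParams fit_all_pairs_de
#' @return A `promiso_pi1` object wrapping the symmetric pi1 matrix
#'   (diagonal 0).
#' @export
pairwise_dissimilarity <- function(expr, meta, group_col = "region",
                                   covariates = character()) {
  meta <- meta %>% filter(.data$sample_id %in% sample_cols(expr$cpm))
  sizes <- table(meta[[group_col]])
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warn(paste0("excluding region(s) with < 2 samples: ",
                paste(small, collapse = ", ")))
    meta <- meta %>% filter(!.data[[group_col]] %in% small)
  }
  regions <- sort(unique(meta[[group_col]]))
  m <- matrix(0, length(regions), length(regions),
              dimnames = list(regions, regions))
  pairs <- combn(regions, 2L)
  for (i in seq_len(ncol(pairs))) {
    de <- fit_pairwise_de(expr, meta, pairs[1L, i], pairs[2L, i],
                          group_col = group_col, covariates = covariates)
    v <- storey_pi1(de$p)
    m[pairs[1L, i], pairs[2L, i]] <- v
    m[pairs[2L, i], pairs[1L, i]] <- v
  }
  structure(list(pi1 = m, n_features = nrow(expr$cpm)),
            class = "promiso_pi1")
}

#' @export
print.promiso_pi1 <- function(x, ...) {
  cat(sprintf("<promiso_pi1> %d regions, %d features\n",
              nrow(x$pi1), x$n_features))
  print(round(x$pi1, 3))
  invisible(x)
}

#' @export
tidy.promiso_pi1 <- function(x, ...) {
  as_tibble(as.data.frame.table(x$pi1, responseName = "pi1",
                                stringsAsFactors = FALSE)) %>%
    rename(region_a = "Var1", region_b = "Var2")
}

#' @export
glance.promiso_pi1 <- function(x, ...) {
  off <- x$pi1[row(x$pi1) != col(x$pi1)]
  tibble(n_regions = nrow(x$pi1), n_features = x$n_features,
         mean_pi1 = mean(off), max_pi1 = max(off))
}
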