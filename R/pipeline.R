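# End-to-end orchestration of the analysis stages on an input bundle.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
}

#' Run the full promoter-isoform analysis pipeline
#'
#' Executes quantify -> differential analysis -> enhancer linking (per
#' region) -> fine-mapping -> target summary on an input bundle (a
#' [simulate_bundle()] result or a [read_bundle()] directory image), and
#' returns every stage's table together with a checksum manifest.
#' Deterministic stages reproduce identical checksums on re-runs with
#' the same inputs.
#'
#' @param bundle Input bundle list.
#' @param fdr_cut FDR threshold for differential calls (default 0.05).
#' @param abc_threshold Minimum reported ABC score (default 0.02).
#' @param window_bp ABC screening window half-width (default 5e6).
#' @param pip_min Fine-mapped SNP PIP threshold (default 0.01).
#' @param gamma Contact fallback exponent (default: bundle config value,
#'   else 1).
#' @param compute_pi1 Also compute the pairwise pi1 dissimilarity matrix
#'   (default FALSE; it refits every pairwise model).
#' @return Named list of stage outputs (`promoters`, `expr_prom`,
#'   `expr_gene`, `expr_ocr`, `de_iso`, `de_gene`, `iso_specific`,
#'   `region_specific`, `major_calls`, `ocr_assignments`, `links`,
#'   `sharing`, `assignments`, `target_summary`, optionally `pi1`) plus
#'   a `manifest` tibble of per-artifact hashes.
#' @export
run_pipeline <- function(bundle, fdr_cut = 0.05, abc_threshold = 0.02,
                         window_bp = 5e6, pip_min = 0.01, gamma = NULL,
                         compute_pi1 = FALSE) {
  gamma <- gamma %||% bundle$config$gamma %||% 1
  meta <- bundle$meta
  regions <- sort(unique(meta$region))

  promoters <- run_stage("annotation", promoter_models(bundle$transcripts))

  prom_counts <- run_stage("quantify",
    suppressMessages(quantify_promoters(bundle$junctions, promoters)))
  prom_counts_all <- run_stage("quantify",
    suppressMessages(quantify_promoters(bundle$junctions, promoters,
                                        exclude_nonunique = FALSE)))

  expr_prom <- run_stage("normalize",
    filter_detected(tmm_normalize(prom_counts, "promoter_isoform"),
                    min_cpm = 2, min_fraction = 0.40,
                    strict_gt_fraction = TRUE))
  expr_gene <- run_stage("normalize",
    filter_detected(tmm_normalize(bundle$gene_counts, "gene"),
                    min_cpm = 1, min_fraction = 0.20))
  expr_ocr <- run_stage("normalize",
    filter_detected(tmm_normalize(bundle$peak_counts, "ocr"),
                    min_cpm = 1, min_fraction = 0.20))
  expr_prom_abc <- run_stage("normalize",
    tmm_normalize(prom_counts_all, "promoter_isoform"))

  de_iso <- run_stage("de", fit_all_pairs_de(expr_prom, meta))
  de_gene <- run_stage("de", fit_all_pairs_de(expr_gene, meta))
  iso_specific <- run_stage("de",
    isoform_specific_degs(de_iso, de_gene, promoters, fdr_cut = fdr_cut))
  region_specific <- run_stage("de",
    broad_region_specific(de_gene, fdr_cut = fdr_cut))
  pi1 <- if (compute_pi1) {
    run_stage("pi1", pairwise_dissimilarity(expr_gene, meta))
  } else NULL

  major_calls <- run_stage("major",
    call_major_promoters(expr_prom, promoters))

  ocr_assignments <- run_stage("abc",
    assign_promoter_ocrs(promoters, bundle$peaks))
  if (is.null(bundle$contacts)) {
    run_stage("abc", abort("no contact maps in bundle"))
  }
  links <- run_stage("abc", purrr::map_dfr(regions, function(r) {
    cm <- bundle$contacts[[r]]
    if (is.null(cm)) abort(sprintf("no contact map for region '%s'", r))
    active <- call_active_promoters(expr_prom_abc, ocr_assignments, meta, r)
    elements <- element_activity(bundle$peaks, expr_ocr, meta, r, promoters)
    abc_scores(active, elements, cm, promoters, region = r,
               window_bp = window_bp, threshold = abc_threshold,
               gamma = gamma)
  }))
  sharing <- if (length(regions) >= 2L && nrow(links)) {
    run_stage("abc", link_sharing(links))
  } else NULL

  assignments <- run_stage("finemap",
    assign_targets(bundle$snps, links, promoters, scores = bundle$scores,
                   pip_min = pip_min))
  target_summary <- if (nrow(assignments)) {
    run_stage("finemap", summarize_targets(assignments))
  } else NULL

  out <- list(promoters = promoters, expr_prom = expr_prom,
              expr_gene = expr_gene, expr_ocr = expr_ocr,
              de_iso = de_iso, de_gene = de_gene,
              iso_specific = iso_specific,
              region_specific = region_specific, pi1 = pi1,
              major_calls = major_calls,
              ocr_assignments = ocr_assignments, links = links,
              sharing = sharing, assignments = assignments,
              target_summary = target_summary)
  hashable <- out[!vapply(out, is.null, logical(1))]
  out$manifest <- tibble(
    artifact = names(hashable),
    hash = vapply(hashable, rlang::hash, character(1)))
  out
}
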