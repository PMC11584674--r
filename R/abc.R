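# Activity-by-contact enhancer-promoter links at promoter-isoform
# resolution: active promoters, element activity, Hi-C contact with a
# power-law fallback, normalized ABC scores, and cross-region link
# statistics.

#' Call active promoters in a region
#'
#' A promoter is active in a region iff its expression exceeds
#' `min_cpm` CPM (strict) in at least `min_fraction` of the region's
#' samples AND it has an assigned promoter-proximal open-chromatin peak.
#' Internal promoters participate; quantify them with
#' `quantify_promoters(..., exclude_nonunique = FALSE)`.
#'
#' @param expr `promiso_expr` over promoter-isoforms.
#' @param ocr_assignments Output of [assign_promoter_ocrs()].
#' @param meta Sample metadata with `sample_id` and the grouping column.
#' @param region Region label to evaluate.
#' @param group_col Metadata column holding region labels.
#' @param min_cpm,min_fraction Activity rule parameters (defaults 1, 0.20).
#' @return Tibble `promoter_id`, `expressed`, `accessible`, `active`.
#' @export
call_active_promoters <- function(expr, ocr_assignments, meta, region,
                                  group_col = "region",
                                  min_cpm = 1, min_fraction = 0.20) {
  samples <- meta$sample_id[meta[[group_col]] == region]
  samples <- intersect(samples, sample_cols(expr$cpm))
  if (!length(samples)) abort(sprintf("region '%s' has no samples", region))
  cpm <- expr_cpm(expr)[, samples, drop = FALSE]
  frac <- unname(rowMeans(cpm > min_cpm))
  tibble(promoter_id = rownames(cpm), expressed = frac >= min_fraction) %>%
    left_join(ocr_assignments, by = "promoter_id") %>%
    mutate(accessible = !is.na(.data$ocr_id),
           active = .data$expressed & .data$accessible) %>%
    select("promoter_id", "expressed", "accessible", "active")
}

#' Candidate element activity in a region
#'
#' Element activity is the mean depth-normalized accessibility (CPM) of
#' the peak across the region's samples. Elements overlapping any
#' annotated promoter window (`tss +/- promoter_window_bp`) are flagged
#' `promoter_proximal`, the rest `distal`.
#'
#' @param peaks Peak tibble (`ocr_id`, `chrom`, `start`, `end`).
#' @param peak_expr `promiso_expr` over peaks (feature_id = ocr_id).
#' @param meta Sample metadata.
#' @param region Region label.
#' @param promoters Promoter tibble (for the proximal flag).
#' @param group_col Metadata column holding region labels.
#' @param promoter_window_bp Promoter window half-width (default 1000).
#' @return Tibble `element_id`, `chrom`, `start`, `end`, `kind`,
#'   `activity`.
#' @export
element_activity <- function(peaks, peak_expr, meta, region, promoters,
                             group_col = "region", promoter_window_bp = 1000L) {
  samples <- intersect(meta$sample_id[meta[[group_col]] == region],
                       sample_cols(peak_expr$cpm))
  if (!length(samples)) abort(sprintf("region '%s' has no samples", region))
  cpm <- expr_cpm(peak_expr)[, samples, drop = FALSE]
  act <- tibble(ocr_id = rownames(cpm), activity = unname(rowMeans(cpm)))

  pg <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end))
  wg <- GenomicRanges::GRanges(
    promoters$chrom,
    IRanges::IRanges(pmax(0L, promoters$tss - promoter_window_bp) + 1L,
                     promoters$tss + promoter_window_bp))
  prox <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(pg, wg)))

  peaks %>%
    mutate(kind = if_else(row_number() %in% prox,
                          "promoter_proximal", "distal")) %>%
    inner_join(act, by = "ocr_id") %>%
    select(element_id = "ocr_id", "chrom", "start", "end", "kind", "activity")
}

#' Build a contact map
#'
#' Stores a sparse symmetric intra-chromosomal contact map from binned
#' triplets. Bin pairs are canonicalized (`bin_a <= bin_b`, bins snapped
#' to the resolution grid) and duplicate pairs summed.
#'
#' @param contacts Tibble with `bin_a`, `bin_b` (bin start coordinates)
#'   and `count`.
#' @param resolution Bin size in bp.
#' @param chrom Optional chromosome label.
#' @return A `promiso_contacts` object.
#' @export
contact_map <- function(contacts, resolution, chrom = NA_character_) {
  assert_columns(contacts, c("bin_a", "bin_b", "count"), "contacts")
  if (any(contacts$count < 0)) abort("contact counts must be nonnegative")
  snap <- function(x) floor(x / resolution) * resolution
  bins <- contacts %>%
    mutate(a = snap(pmin(.data$bin_a, .data$bin_b)),
           b = snap(pmax(.data$bin_a, .data$bin_b))) %>%
    group_by(.data$a, .data$b) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    rename(bin_a = "a", bin_b = "b")
  structure(list(bins = bins, resolution = resolution, chrom = chrom),
            class = "promiso_contacts")
}

#' @export
print.promiso_contacts <- function(x, ...) {
  cat(sprintf("<promiso_contacts> %s: %d bin pairs at %d bp resolution\n",
              x$chrom %||% "?", nrow(x$bins), x$resolution))
  invisible(x)
}

# mean observed contact near the 100 kb reference distance (for scaling
# the power-law fallback); 1 when the map is empty there
contact_reference <- function(map, ref_distance = 1e5) {
  d <- map$bins$bin_b - map$bins$bin_a
  near <- d >= 0.8 * ref_distance & d <= 1.2 * ref_distance
  if (any(near)) mean(map$bins$count[near]) else 1
}

#' Contact frequency between two positions
#'
#' Returns the observed normalized contact at the bin pair. Absent or
#' zero pairs fall back to a power law
#' `C100 * ((|delta| + resolution) / (1e5 + resolution))^(-gamma)`,
#' scaled so the fallback equals the map's mean contact at the 100 kb
#' reference distance (`C100`; 1 on an empty map). Same-bin queries
#' return the self-contact convention value, the maximum of the map's
#' largest count and the fallback at distance zero, so that the diagonal
#' dominates. Cross-chromosome queries return 0 with a warning.
#'
#' @param map A `promiso_contacts` object.
#' @param pos_a,pos_b Positions (bp), vectorized.
#' @param gamma Power-law decay exponent (default 1).
#' @param chrom_a,chrom_b Optional chromosome labels for the two
#'   positions; must match the map's chromosome when given.
#' @return Nonnegative contact values.
#' @export
contact_at <- function(map, pos_a, pos_b, gamma = 1,
                       chrom_a = NULL, chrom_b = NULL) {
  stopifnot(inherits(map, "promiso_contacts"))
  n <- max(length(pos_a), length(pos_b))
  pos_a <- rep_len(pos_a, n); pos_b <- rep_len(pos_b, n)
  cross <- rep_len(FALSE, n)
  if (!is.null(chrom_a) && !is.null(chrom_b)) {
    cross <- rep_len(chrom_a, n) != rep_len(chrom_b, n)
    if (any(cross)) warn("cross-chromosome contact query returns 0")
  }
  res <- map$resolution
  ba <- pmin(floor(pos_a / res), floor(pos_b / res)) * res
  bb <- pmax(floor(pos_a / res), floor(pos_b / res)) * res
  c100 <- contact_reference(map)
  fallback <- function(delta) c100 * ((delta + res) / (1e5 + res))^(-gamma)
  key <- paste(ba, bb)
  lut <- setNames(map$bins$count, paste(map$bins$bin_a, map$bins$bin_b))
  obs <- unname(lut[key])
  obs[is.na(obs)] <- 0
  out <- ifelse(obs > 0, obs, fallback(bb - ba))
  self_value <- max(c(map$bins$count, fallback(0)))
  out[bb == ba] <- self_value
  out[cross] <- 0
  out
}

#' ABC scores for one region
#'
#' For each active promoter, candidate elements are all elements on the
#' same chromosome whose midpoint lies within `tss +/- window_bp`. The
#' raw score of an element is `activity x contact(element, tss)`; ABC
#' scores normalize raw scores over all candidates (including the
#' promoter's own proximal elements) so they sum to 1, and links at or
#' above `threshold` are emitted (distal and promoter-proximal alike,
#' flagged by `kind`). Promoters with zero total raw score yield no links
#' and are counted in the `n_zero_total` attribute.
#'
#' @param active Output of [call_active_promoters()] (or any tibble with
#'   `promoter_id` and logical `active`).
#' @param elements Output of [element_activity()].
#' @param map `promiso_contacts` for the region's chromosome set (a named
#'   list of maps keyed by chromosome is also accepted).
#' @param promoters Promoter tibble (TSS and gene lookup).
#' @param region Region label stamped on the links.
#' @param window_bp Screening window half-width (default 5e6).
#' @param threshold Minimum reported ABC score (default 0.02).
#' @param gamma Power-law fallback exponent (default 1).
#' @return Tibble of links: `region`, `element_id`, `promoter_id`,
#'   `gene_id`, `rank`, `kind`, `activity`, `contact`, `abc`,
#'   `distance_bp`.
#' @export
abc_scores <- function(active, elements, map, promoters, region,
                       window_bp = 5e6, threshold = 0.02, gamma = 1) {
  act_ids <- active$promoter_id[active$active]
  proms <- promoters %>%
    filter(.data$promoter_id %in% act_ids) %>%
    select("promoter_id", "gene_id", "rank", "chrom", "tss")
  maps <- if (inherits(map, "promiso_contacts")) {
    chroms <- unique(proms$chrom)
    setNames(rep(list(map), length(chroms)), chroms)
  } else map

  n_zero <- 0L
  links <- purrr::map_dfr(seq_len(nrow(proms)), function(i) {
    p <- proms[i, ]
    cand <- elements %>%
      filter(.data$chrom == p$chrom,
             abs((.data$start + .data$end) / 2 - p$tss) <= window_bp)
    if (!nrow(cand)) return(NULL)
    mid <- (cand$start + cand$end) / 2
    cc <- contact_at(maps[[p$chrom]], mid, rep(p$tss, nrow(cand)),
                     gamma = gamma)
    raw <- cand$activity * cc
    tot <- sum(raw)
    if (tot <= 0) { n_zero <<- n_zero + 1L; return(NULL) }
    out <- cand %>%
      mutate(region = region, promoter_id = p$promoter_id,
             gene_id = p$gene_id, rank = p$rank,
             contact = cc, abc = raw / tot,
             distance_bp = abs(round(mid) - p$tss)) %>%
      filter(.data$abc >= threshold)
    out
  })
  if (is.null(links) || !nrow(links)) {
    links <- tibble(region = character(), element_id = character(),
                    promoter_id = character(), gene_id = character(),
                    rank = integer(), kind = character(),
                    activity = numeric(), contact = numeric(),
                    abc = numeric(), distance_bp = numeric(),
                    chrom = character(), start = integer(), end = integer())
  }
  links <- links %>%
    select("region", "element_id", "promoter_id", "gene_id", "rank",
           "kind", "activity", "contact", "abc", "distance_bp",
           "chrom", "start", "end")
  attr(links, "n_zero_total") <- n_zero
  links
}

#' Cross-region link sharing statistics
#'
#' Link identity is `(element_id, promoter_id)` on a shared element
#' universe. Reports pairwise shared link counts, the per-region unique
#' fraction (links present in no other region), and the Spearman
#' correlation of ABC scores over links present in both regions of a
#' pair (`NA` when fewer than 3 are shared or a score vector is
#' constant).
#'
#' @param links Link tibble covering two or more regions (a `region`
#'   column is required).
#' @return A `promiso_sharing` object with `$shared`, `$unique` and the
#'   correlation matrix `$rho`.
#' @export
link_sharing <- function(links) {
  assert_columns(links, c("region", "element_id", "promoter_id", "abc"),
                 "links")
  links <- links %>%
    mutate(link_key = paste(.data$element_id, .data$promoter_id, sep = "|"))
  regions <- sort(unique(links$region))
  if (length(regions) < 2L) abort("link sharing requires at least 2 regions")

  keysets <- lapply(setNames(regions, regions),
                    function(r) unique(links$link_key[links$region == r]))
  occ <- table(unlist(keysets))

  uniq <- purrr::map_dfr(regions, function(r) {
    ks <- keysets[[r]]
    tibble(region = r, n_links = length(ks),
           unique_frac = if (length(ks)) mean(occ[ks] == 1L) else NA_real_)
  })

  pairs <- combn(regions, 2L)
  rho <- matrix(NA_real_, length(regions), length(regions),
                dimnames = list(regions, regions))
  diag(rho) <- 1
  shared <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    common <- intersect(keysets[[a]], keysets[[b]])
    if (length(common) >= 3L) {
      sa <- links %>% filter(.data$region == a, .data$link_key %in% common) %>%
        distinct(.data$link_key, .keep_all = TRUE) %>% arrange(.data$link_key)
      sb <- links %>% filter(.data$region == b, .data$link_key %in% common) %>%
        distinct(.data$link_key, .keep_all = TRUE) %>% arrange(.data$link_key)
      r <- spearman_rho(sa$abc, sb$abc)
      rho[a, b] <<- r; rho[b, a] <<- r
    }
    tibble(region_a = a, region_b = b, n_shared = length(common))
  })
  structure(list(shared = shared, unique = uniq, rho = rho),
            class = "promiso_sharing")
}

#' @export
print.promiso_sharing <- function(x, ...) {
  cat(sprintf("<promiso_sharing> %d regions\n", nrow(x$unique)))
  print(x$unique)
  invisible(x)
}

#' @export
tidy.promiso_sharing <- function(x, ...) {
  x$shared %>%
    left_join(
      as_tibble(as.data.frame.table(x$rho, responseName = "rho",
                                    stringsAsFactors = FALSE)) %>%
        rename(region_a = "Var1", region_b = "Var2"),
      by = c("region_a", "region_b"))
}

#' @export
glance.promiso_sharing <- function(x, ...) {
  tibble(n_regions = nrow(x$unique),
         mean_unique_frac = mean(x$unique$unique_frac, na.rm = TRUE),
         mean_rho = mean(x$rho[upper.tri(x$rho)], na.rm = TRUE))
}

#' Collapse promoter-isoform links to gene-level links
#'
#' Per (element, gene, region), keeps the maximum ABC score across the
#' gene's promoter-isoforms.
#'
#' @param links Promoter-isoform link tibble.
#' @return Gene-level link tibble.
#' @export
collapse_gene_links <- function(links) {
  links %>%
    group_by(.data$region, .data$element_id, .data$gene_id) %>%
    arrange(dplyr::desc(.data$abc), .data$rank, .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup()
}
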