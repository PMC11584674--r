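# Promoter-isoform models from transcript annotation.
#
# Transcripts of a gene that share a strand-aware TSS form one
# promoter-isoform; each is quantified downstream by the set of splice
# junctions spanning the first intron of its member transcripts.
# Coordinates are 0-based half-open throughout the package; GTF input is
# converted at the reader boundary (see read_gtf()).

# per-transcript summaries: TSS, exon count, first-intron junction,
# all introns with their transcription-order index
transcript_summaries <- function(transcripts) {
  assert_columns(transcripts,
                 c("transcript_id", "gene_id", "chrom", "strand", "start", "end"),
                 "transcripts")
  bad <- transcripts %>%
    group_by(.data$transcript_id) %>%
    summarise(n_chrom = n_distinct(.data$chrom),
              n_strand = n_distinct(.data$strand), .groups = "drop") %>%
    filter(.data$n_chrom > 1L | .data$n_strand > 1L)
  if (nrow(bad)) {
    abort(paste0("transcript(s) with exons on multiple chroms/strands: ",
                 paste(bad$transcript_id, collapse = ", ")))
  }
  if (any(transcripts$end <= transcripts$start)) {
    abort("exon with end <= start (coordinates must be 0-based half-open)")
  }

  exons <- transcripts %>% arrange(.data$transcript_id, .data$start)
  ov <- exons %>%
    group_by(.data$transcript_id) %>%
    filter(n() > 1L, any(.data$start[-1L] < .data$end[-n()])) %>%
    ungroup()
  if (nrow(ov)) {
    abort(paste0("overlapping exons within transcript(s): ",
                 paste(unique(ov$transcript_id), collapse = ", ")))
  }

  per_tx <- exons %>%
    group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) %>%
    summarise(
      n_exons = n(),
      tss = if (first(.data$strand) == "+") min(.data$start) else max(.data$end),
      exon_starts = list(.data$start),
      exon_ends = list(.data$end),
      .groups = "drop"
    )

  # introns in genomic order: (end of exon j, start of exon j+1);
  # donor = left boundary, acceptor = right boundary (genomic convention).
  # transcription-order index: genomic order on "+", reversed on "-".
  multi <- per_tx %>% filter(.data$n_exons > 1L)
  introns <- if (!nrow(multi)) {
    tibble(transcript_id = character(), gene_id = character(),
           chrom = character(), strand = character(), donor = integer(),
           acceptor = integer(), intron_index = integer())
  } else {
    multi %>%
      mutate(intron = purrr::pmap(
        list(.data$exon_starts, .data$exon_ends, .data$strand),
        function(s, e, str) {
          k <- length(s) - 1L
          idx <- if (str == "+") seq_len(k) else rev(seq_len(k))
          tibble(donor = e[seq_len(k)], acceptor = s[-1L], intron_index = idx)
        })) %>%
      select("transcript_id", "gene_id", "chrom", "strand", "intron") %>%
      tidyr::unnest("intron")
  }

  list(per_tx = per_tx, introns = introns)
}

#' Group transcripts into promoter-isoforms
#'
#' Transcripts of a gene sharing a strand-aware transcription start site
#' (interval start on `+`, interval end on `-`) are grouped into one
#' promoter-isoform. Promoters are ranked 1..k in transcription direction
#' (rank 1 = 5'-most), and each promoter carries the union of its member
#' transcripts' first-intron junctions, the handle used for junction-read
#' quantification.
#'
#' @param transcripts Tibble of exons with columns `transcript_id`,
#'   `gene_id`, `chrom`, `strand` (`+`/`-`), `start`, `end`
#'   (0-based half-open), one row per exon.
#' @return A tibble with one row per promoter: `promoter_id`, `gene_id`,
#'   `chrom`, `strand`, `tss`, `rank`, `class` (`single_exon_only` or
#'   `unclassified`; see [classify_identifiability()]), `label_transcript`
#'   (lexicographically smallest member, the deterministic display label),
#'   `members` (list of transcript ids) and `junctions` (list of
#'   `donor`/`acceptor` tibbles; donor = genomic left intron boundary).
#'   Genes with transcripts on both strands are dropped with a warning and
#'   recorded in the `rejected_genes` attribute.
#' @seealso [classify_identifiability()], [quantify_promoters()]
#' @export
build_promoters <- function(transcripts) {
  ts <- transcript_summaries(transcripts)
  per_tx <- ts$per_tx

  mixed <- per_tx %>%
    group_by(.data$gene_id) %>%
    summarise(n_strand = n_distinct(.data$strand), .groups = "drop") %>%
    filter(.data$n_strand > 1L)
  if (nrow(mixed)) {
    warn(paste0("rejecting gene(s) with transcripts on both strands: ",
                paste(mixed$gene_id, collapse = ", ")))
    per_tx <- per_tx %>% filter(!.data$gene_id %in% mixed$gene_id)
  }

  first_introns <- ts$introns %>%
    filter(.data$intron_index == 1L) %>%
    select("transcript_id", "donor", "acceptor")

  promoters <- per_tx %>%
    left_join(first_introns, by = "transcript_id") %>%
    group_by(.data$gene_id, .data$chrom, .data$strand, .data$tss) %>%
    summarise(
      members = list(sort(unique(.data$transcript_id))),
      label_transcript = min(.data$transcript_id),
      junctions = list({
        keep <- !is.na(.data$donor)
        d <- .data$donor[keep]
        a <- .data$acceptor[keep]
        o <- order(d, a)
        distinct(tibble(donor = d[o], acceptor = a[o]))
      }),
      single_exon_only = all(.data$n_exons == 1L),
      .groups = "drop"
    ) %>%
    mutate(.ord = if_else(.data$strand == "+", .data$tss, -.data$tss)) %>%
    group_by(.data$gene_id) %>%
    arrange(.data$.ord, .by_group = TRUE) %>%
    mutate(rank = row_number()) %>%
    ungroup() %>%
    select(-".ord") %>%
    mutate(
      promoter_id = sprintf("%s_P%02d", .data$gene_id, .data$rank),
      class = if_else(.data$single_exon_only, "single_exon_only", "unclassified")
    ) %>%
    select("promoter_id", "gene_id", "chrom", "strand", "tss", "rank",
           "class", "label_transcript", "members", "junctions") %>%
    arrange(.data$gene_id, .data$rank)

  attr(promoters, "rejected_genes") <- mixed$gene_id
  promoters
}

#' Classify promoter-isoform identifiability
#'
#' A promoter is `internal` when any edge (donor or acceptor) of any of its
#' member transcripts' first-intron junctions coincides with a non-first
#' intron edge of another transcript of the same gene, making its junction
#' reads ambiguous. Remaining multi-exon promoters are `unique`;
#' `single_exon_only` promoters are unchanged. Only `unique` promoters are
#' flagged quantifiable.
#'
#' @param promoters Output of [build_promoters()].
#' @param transcripts The exon tibble the promoters were built from.
#' @return `promoters` with `class` set to `unique`/`internal`/
#'   `single_exon_only` and a logical `quantifiable` column.
#' @export
classify_identifiability <- function(promoters, transcripts) {
  ts <- transcript_summaries(transcripts)
  introns <- ts$introns

  first_edges <- introns %>%
    filter(.data$intron_index == 1L) %>%
    tidyr::pivot_longer(c("donor", "acceptor"), values_to = "edge") %>%
    select("transcript_id", "gene_id", "edge")
  other_edges <- introns %>%
    filter(.data$intron_index > 1L) %>%
    tidyr::pivot_longer(c("donor", "acceptor"), values_to = "edge") %>%
    select(other_transcript = "transcript_id", "gene_id", "edge")

  internal_tx <- first_edges %>%
    inner_join(other_edges, by = c("gene_id", "edge"),
               relationship = "many-to-many") %>%
    filter(.data$transcript_id != .data$other_transcript) %>%
    distinct(.data$transcript_id) %>%
    pull("transcript_id")

  promoters %>%
    mutate(
      class = dplyr::case_when(
        .data$class == "single_exon_only" ~ "single_exon_only",
        purrr::map_lgl(.data$members, ~ any(.x %in% internal_tx)) ~ "internal",
        TRUE ~ "unique"
      ),
      quantifiable = .data$class == "unique"
    )
}

#' Build and classify promoter-isoform models in one step
#'
#' @inheritParams build_promoters
#' @return Classified promoter tibble; see [classify_identifiability()].
#' @export
promoter_models <- function(transcripts) {
  classify_identifiability(build_promoters(transcripts), transcripts)
}

#' Attach promoter-proximal open-chromatin peaks
#'
#' Assigns to each promoter the open-chromatin peak overlapping the window
#' `tss +/- window_bp`, keeping the peak whose nearest edge is closest to
#' the TSS (distance 0 when the TSS lies inside the peak). Ties break
#' toward the smaller peak start, then lexicographic `ocr_id`.
#'
#' @param promoters Promoter tibble (needs `promoter_id`, `chrom`, `tss`).
#' @param peaks Tibble with `ocr_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param window_bp Window half-width around the TSS (default 1000).
#' @return One row per promoter: `promoter_id`, `ocr_id` (`NA` when no
#'   peak qualifies) and `distance_bp`.
#' @export
assign_promoter_ocrs <- function(promoters, peaks, window_bp = 1000L) {
  assert_columns(peaks, c("ocr_id", "chrom", "start", "end"), "peaks")
  unknown <- setdiff(unique(peaks$chrom), unique(promoters$chrom))
  if (length(unknown)) {
    warn(paste0("ignoring peak(s) on chrom(s) absent from annotation: ",
                paste(unknown, collapse = ", ")))
  }
  hits <- promoters %>%
    select("promoter_id", "chrom", "tss") %>%
    inner_join(peaks, by = "chrom", relationship = "many-to-many") %>%
    filter(.data$start < .data$tss + window_bp,
           .data$end > .data$tss - window_bp) %>%
    mutate(distance_bp = point_interval_distance(.data$tss, .data$start, .data$end)) %>%
    group_by(.data$promoter_id) %>%
    arrange(.data$distance_bp, .data$start, .data$ocr_id, .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    select("promoter_id", "ocr_id", "distance_bp")

  promoters %>%
    select("promoter_id") %>%
    left_join(hits, by = "promoter_id")
}

#' Export promoter windows as BED6
#'
#' Writes `tss +/- window_bp` windows, named by `promoter_id`, score 0,
#' with strand, in BED (0-based half-open) convention.
#'
#' @inheritParams assign_promoter_ocrs
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_promoter_bed <- function(promoters, path, window_bp = 1000L) {
  bed <- promoters %>%
    mutate(start = pmax(0L, .data$tss - window_bp), end = .data$tss + window_bp,
           score = 0L) %>%
    select("chrom", "start", "end", name = "promoter_id", "score", "strand")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write a promoter table as TSV
#'
#' List columns are serialized: members comma-delimited, junctions as
#' semicolon-delimited `donor-acceptor` pairs.
#'
#' @param promoters Promoter tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_promoter_table <- function(promoters, path) {
  flat <- promoters %>%
    mutate(
      members = purrr::map_chr(.data$members, paste, collapse = ","),
      junctions = purrr::map_chr(
        .data$junctions,
        ~ paste(sprintf("%d-%d", .x$donor, .x$acceptor), collapse = ";"))
    )
  readr::write_tsv(flat, path)
  invisible(path)
}
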