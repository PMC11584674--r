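# Readers and writers for the standard text formats, with coordinate
# conversion performed exactly once at the boundary: GTF is 1-based
# closed on disk and 0-based half-open in memory; BED-side tables are
# already 0-based half-open; SNP positions are 1-based on disk.

#' Read transcript models from a GTF file
#'
#' Imports exon features, requires `gene_id` and `transcript_id`
#' attributes, and converts 1-based closed GTF coordinates to the
#' package's 0-based half-open convention. Exon rows missing a
#' transcript id are reported; the file is rejected when more than
#' `max_error_rate` of exon rows are unusable.
#'
#' @param path GTF file path.
#' @param max_error_rate Tolerated fraction of bad exon rows
#'   (default 0.01).
#' @return Exon tibble (`transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end`), sorted.
#' @export
read_gtf <- function(path, max_error_rate = 0.01) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) abort("no exon features in GTF")
  tid <- gr$transcript_id %||% rep(NA_character_, length(gr))
  gid <- gr$gene_id %||% rep(NA_character_, length(gr))
  bad <- is.na(tid) | is.na(gid)
  if (any(bad)) {
    warn(sprintf("%d exon row(s) missing gene_id/transcript_id", sum(bad)))
    if (mean(bad) > max_error_rate) {
      abort("too many malformed exon rows in GTF")
    }
  }
  tibble(
    transcript_id = tid[!bad], gene_id = gid[!bad],
    chrom = as.character(GenomicRanges::seqnames(gr))[!bad],
    strand = as.character(GenomicRanges::strand(gr))[!bad],
    start = GenomicRanges::start(gr)[!bad] - 1L,
    end = GenomicRanges::end(gr)[!bad]
  ) %>%
    arrange(.data$transcript_id, .data$start)
}

#' Write transcript models to a GTF file
#'
#' Emits one exon feature per row, converting back to 1-based closed
#' coordinates. Round-trips with [read_gtf()].
#'
#' @param transcripts Exon tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  gr <- GenomicRanges::GRanges(
    transcripts$chrom,
    IRanges::IRanges(transcripts$start + 1L, transcripts$end),
    strand = transcripts$strand)
  gr$type <- "exon"
  gr$source <- "promiso"
  gr$gene_id <- transcripts$gene_id
  gr$transcript_id <- transcripts$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a junction count table
#'
#' TSV with key columns `chrom`, `donor`, `acceptor`, `strand` followed
#' by one numeric column per sample.
#'
#' @param path TSV path.
#' @return Wide junction count tibble.
#' @export
read_junction_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(x, c("chrom", "donor", "acceptor", "strand"), "junctions")
  x
}

#' Read a contact-map triplet file
#'
#' TSV with columns `bin_a`, `bin_b`, `count`; the resolution is either
#' passed explicitly or parsed from a `# resolution=<bp>` header line.
#'
#' @param path TSV path.
#' @param resolution Bin size in bp (optional if in the header).
#' @param chrom Optional chromosome label.
#' @return A `promiso_contacts` object.
#' @export
read_contacts <- function(path, resolution = NULL, chrom = NA_character_) {
  header <- readLines(path, n = 1L)
  if (is.null(resolution)) {
    m <- regmatches(header, regexec("resolution=([0-9]+)", header))[[1]]
    if (length(m) < 2L) abort("resolution neither given nor in header")
    resolution <- as.integer(m[2])
  }
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  contact_map(x, resolution = resolution, chrom = chrom)
}

#' Write a synthetic bundle to a directory of standard-format files
#'
#' Writes the annotation as GTF, counts and metadata as TSV, peaks as
#' BED4, contact maps as headered triplet TSVs, SNPs and scores as TSV,
#' and the truth tables under `truth/`.
#'
#' @param bundle Output of [simulate_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gtf(bundle$transcripts, file.path(dir, "annotation.gtf"))
  readr::write_tsv(bundle$junctions, file.path(dir, "junctions.tsv"))
  readr::write_tsv(bundle$gene_counts, file.path(dir, "gene_counts.tsv"))
  readr::write_tsv(bundle$meta, file.path(dir, "meta.tsv"))
  readr::write_tsv(bundle$peaks %>%
                     select("chrom", "start", "end", "ocr_id"),
                   file.path(dir, "peaks.bed"), col_names = FALSE)
  readr::write_tsv(bundle$peak_counts, file.path(dir, "peak_counts.tsv"))
  for (r in names(bundle$contacts)) {
    cm <- bundle$contacts[[r]]
    f <- file.path(dir, sprintf("contacts_%s.tsv", r))
    writeLines(sprintf("# resolution=%d", cm$resolution), f)
    readr::write_tsv(cm$bins, f, append = TRUE, col_names = TRUE)
  }
  readr::write_tsv(bundle$snps, file.path(dir, "snps.tsv"))
  readr::write_tsv(bundle$scores, file.path(dir, "scores.tsv"))
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  for (nm in names(bundle$truth)) {
    readr::write_tsv(bundle$truth[[nm]], file.path(tdir, paste0(nm, ".tsv")))
  }
  invisible(dir)
}

#' Read a bundle directory written by [write_bundle()]
#'
#' @param dir Bundle directory.
#' @return A bundle list (without the original `config`).
#' @export
read_bundle <- function(dir) {
  rd <- function(f) readr::read_tsv(file.path(dir, f), show_col_types = FALSE)
  contact_files <- list.files(dir, pattern = "^contacts_.*\\.tsv$")
  regions <- sub("^contacts_(.*)\\.tsv$", "\\1", contact_files)
  contacts <- setNames(lapply(contact_files, function(f) {
    read_contacts(file.path(dir, f), chrom = "chr1")
  }), regions)
  peaks <- readr::read_tsv(file.path(dir, "peaks.bed"),
                           col_names = c("chrom", "start", "end", "ocr_id"),
                           show_col_types = FALSE) %>%
    select("ocr_id", "chrom", "start", "end")
  truth_files <- list.files(file.path(dir, "truth"), pattern = "\\.tsv$")
  truth <- setNames(
    lapply(truth_files, function(f) rd(file.path("truth", f))),
    sub("\\.tsv$", "", truth_files))
  list(transcripts = read_gtf(file.path(dir, "annotation.gtf")),
       junctions = rd("junctions.tsv"), gene_counts = rd("gene_counts.tsv"),
       meta = rd("meta.tsv"), peaks = peaks,
       peak_counts = rd("peak_counts.tsv"), contacts = contacts,
       snps = rd("snps.tsv"), scores = rd("scores.tsv"), truth = truth)
}

#' Write an enhancer-promoter link table as BEDPE-like TSV
#'
#' @param links Link tibble from [abc_scores()].
#' @param promoters Promoter tibble (for the promoter-side interval).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_links_bedpe <- function(links, promoters, path) {
  out <- links %>%
    left_join(promoters %>% select("promoter_id", p_tss = "tss"),
              by = "promoter_id") %>%
    mutate(chrom2 = .data$chrom, p_start = .data$p_tss,
           p_end = .data$p_tss + 1L) %>%
    select("chrom", e_start = "start", e_end = "end", "chrom2",
           "p_start", "p_end", "element_id", "promoter_id", "gene_id",
           "region", "activity", "contact", abc_score = "abc", "kind")
  readr::write_tsv(out, path)
  invisible(path)
}
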