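# Independent brute-force oracles and small random-input constructors
# used across the suite. Oracles are written directly from definitions,
# never by calling the implementation under test.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
  library(purrr)
})

# --- random annotation generator (plain loops, no package code) -----------

rand_transcripts <- function(n_genes, seed) {
  set.seed(seed)
  out <- list()
  for (g in seq_len(n_genes)) {
    gid <- sprintf("g%03d", g)
    strand <- sample(c("+", "-"), 1)
    anchor <- g * 50000L
    n_tx <- sample(1:4, 1)
    tss_pool <- anchor + sort(sample(seq(0L, 9000L, by = 1000L),
                                     sample(1:3, 1)))
    for (t in seq_len(n_tx)) {
      tid <- sprintf("%s.t%d", gid, t)
      tss <- sample(tss_pool, 1)
      n_ex <- sample(1:3, 1)
      # exons laid out left-to-right from tss; for "-" we mirror below
      starts <- tss + c(0L, 12000L, 20000L)[seq_len(n_ex)]
      ends <- starts + sample(c(200L, 300L, 500L), n_ex, replace = TRUE)
      if (strand == "-") {
        L <- 30000L
        s2 <- anchor + L - (ends - anchor)
        e2 <- anchor + L - (starts - anchor)
        starts <- rev(s2); ends <- rev(e2)
      }
      out[[length(out) + 1L]] <- tibble(
        transcript_id = tid, gene_id = gid, chrom = "chrT",
        strand = strand, start = starts, end = ends)
    }
  }
  bind_rows(out)
}

# strand-aware TSS per transcript, directly from exons
oracle_tx_tss <- function(tx_rows) {
  if (tx_rows$strand[1] == "+") min(tx_rows$start) else max(tx_rows$end)
}

# brute-force promoter grouping: partition transcripts by
# (gene, strand-aware TSS), rank in transcription direction
oracle_group_promoters <- function(transcripts) {
  res <- list()
  for (gid in unique(transcripts$gene_id)) {
    gtx <- transcripts[transcripts$gene_id == gid, ]
    tss <- vapply(split(gtx, gtx$transcript_id), oracle_tx_tss, numeric(1))
    u <- sort(unique(tss), decreasing = gtx$strand[1] == "-")
    for (r in seq_along(u)) {
      mem <- sort(names(tss)[tss == u[r]])
      res[[length(res) + 1L]] <- tibble(
        gene_id = gid, tss = u[r], rank = r, members = list(mem))
    }
  }
  bind_rows(res)
}

# exhaustive internal-promoter oracle: first-intron edges of transcript t
# vs non-first intron edges of every other transcript of the same gene
oracle_internal_transcripts <- function(transcripts) {
  introns_of <- function(tx_rows) {
    tx_rows <- tx_rows[order(tx_rows$start), ]
    k <- nrow(tx_rows) - 1L
    if (k < 1L) return(NULL)
    idx <- seq_len(k)
    ti <- if (tx_rows$strand[1] == "+") idx else rev(idx)
    data.frame(left = tx_rows$end[idx], right = tx_rows$start[idx + 1L],
               order = ti)
  }
  internal <- character(0)
  for (gid in unique(transcripts$gene_id)) {
    gtx <- transcripts[transcripts$gene_id == gid, ]
    by_tx <- split(gtx, gtx$transcript_id)
    intr <- lapply(by_tx, introns_of)
    for (t in names(by_tx)) {
      it <- intr[[t]]
      if (is.null(it)) next
      fi <- it[it$order == 1L, ]
      edges_t <- c(fi$left, fi$right)
      for (o in setdiff(names(by_tx), t)) {
        io <- intr[[o]]
        if (is.null(io)) next
        nf <- io[io$order > 1L, ]
        if (!nrow(nf)) next
        if (any(edges_t %in% c(nf$left, nf$right))) {
          internal <- c(internal, t)
        }
      }
    }
  }
  unique(internal)
}

# --- TMM oracle coded from the M/A trimming definition --------------------

oracle_tmm_factors <- function(m, logratioTrim = 0.3, sumTrim = 0.05) {
  lib <- colSums(m)
  f75 <- apply(m, 2, function(u) quantile(u, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  one <- function(obs, refv, nO, nR) {
    logR <- log2((obs / nO) / (refv / nR))
    absE <- (log2(obs / nO) + log2(refv / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refv) / nR / refv
    fin <- is.finite(logR) & is.finite(absE) & absE > -1e10
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratioTrim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sumTrim) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    f <- sum(logR[keep] / v[keep]) / sum(1 / v[keep])
    f <- 2^f
    if (!is.finite(f)) f <- 1
    f
  }
  f <- vapply(seq_len(ncol(m)), function(i) {
    one(m[, i], m[, ref], lib[i], lib[ref])
  }, numeric(1))
  f / exp(mean(log(f)))
}

# --- scalar-statistics oracles -------------------------------------------

oracle_bh <- function(p) {
  n <- sum(!is.na(p))
  adj <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  o <- ok[order(p[ok])]
  for (i in seq_along(o)) {
    vals <- vapply(i:length(o), function(j) p[o[j]] * n / j, numeric(1))
    adj[o[i]] <- min(1, min(vals))
  }
  adj
}

oracle_fisher_p <- function(a, b, c, d) {
  # upper tail: tables at least as enriched, margins fixed
  kmax <- min(a + b, a + c)
  ks <- a:kmax
  num <- vapply(ks, function(k) {
    choose(a + b, k) * choose(c + d, a + c - k)
  }, numeric(1))
  sum(num) / choose(a + b + c + d, a + c)
}

oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  # enumerate all 2^n sign patterns
  total <- 0L
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(mask))[1:n]
    w <- sum(r[signs == 1L])
    total <- total + 1L
    if (w >= W) hits <- hits + 1L
  }
  hits / total
}

oracle_rank_sum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- combn(nx + ny, nx)
  ws <- apply(idx, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
  mean(ws >= W)
}

oracle_midrank <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x); ry <- oracle_midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

oracle_jaccard <- function(a, b, max_pos = 2000L) {
  cover <- function(df) {
    keys <- character(0)
    for (i in seq_len(nrow(df))) {
      pos <- seq(df$start[i], df$end[i] - 1L)
      keys <- union(keys, paste(df$chrom[i], pos))
    }
    keys
  }
  ca <- cover(a); cb <- cover(b)
  u <- union(ca, cb)
  if (!length(u)) return(0)
  length(intersect(ca, cb)) / length(u)
}

oracle_lead_windows <- function(hits, flank = 1e4) {
  out <- list()
  for (ch in unique(hits$chrom)) {
    h <- hits[hits$chrom == ch, ]
    h <- h[order(h$pos), ]
    s <- pmax(0, h$pos - flank); e <- h$pos + flank
    grp <- integer(nrow(h)); g <- 1L; grp[1] <- 1L
    cur_end <- e[1]
    for (i in seq_len(nrow(h))[-1]) {
      if (s[i] <= cur_end + 1) {
        grp[i] <- g; cur_end <- max(cur_end, e[i])
      } else {
        g <- g + 1L; grp[i] <- g; cur_end <- e[i]
      }
    }
    for (gg in unique(grp)) {
      hh <- h[grp == gg, ]
      lead <- hh[order(hh$p, hh$pos), ][1, ]
      out[[length(out) + 1L]] <- lead
    }
  }
  bind_rows(out) %>% arrange(chrom, pos)
}

# quick wide count tibble from a matrix
wide_counts <- function(m, prefix = "f") {
  rownames(m) <- rownames(m) %||% sprintf("%s%03d", prefix, seq_len(nrow(m)))
  bind_cols(tibble(feature_id = rownames(m)), as_tibble(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
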