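#' Load a genome assembly from FASTA
#'
#' Reads an assembly into a [Biostrings::DNAStringSet]. Sequences are
#' uppercased; soft-masked (lowercase) runs are retained separately as a
#' tibble of 0-based half-open intervals in `metadata(x)$softmask`.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`. `S4Vectors::metadata(x)$softmask` holds a
#'   tibble with columns `chrom`, `start`, `end` describing lowercase runs.
#' @details Duplicate sequence names and characters outside the IUPAC DNA
#'   alphabet are hard errors; the offending record and offset are named.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  raw <- Biostrings::readBStringSet(path)
  names(raw) <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(names(raw))) {
    dup <- unique(names(raw)[duplicated(names(raw))])
    abort(sprintf("duplicate sequence name(s) in %s: %s",
                  path, paste(dup, collapse = ", ")))
  }
  iupac <- c(strsplit("ACGTRYSWKMBDHVN", "")[[1]])
  ok_chars <- c(iupac, tolower(iupac))
  masks <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    s <- as.character(raw[[i]])
    chars <- strsplit(s, "")[[1]]
    bad <- which(!chars %in% ok_chars)
    if (length(bad)) {
      abort(sprintf("non-IUPAC character '%s' in sequence %s at offset %d",
                    chars[bad[1]], names(raw)[i], bad[1] - 1L))
    }
    lc <- chars %in% letters
    if (any(lc)) {
      r <- rle(lc)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values
      masks[[i]] <- tibble(chrom = names(raw)[i],
                           start = starts[keep] - 1L, end = ends[keep])
    }
  }
  genome <- Biostrings::DNAStringSet(toupper(as.character(raw)))
  names(genome) <- names(raw)
  softmask <- if (length(masks)) bind_rows(masks) else
    tibble(chrom = character(), start = integer(), end = integer())
  S4Vectors::metadata(genome)$softmask <- softmask
  genome
}

#' Load gene models from GFF3
#'
#' Parses gene/mRNA/CDS features linked by `Parent` attributes into a tidy
#' table of CDS intervals, one row per CDS segment per transcript.
#' Coordinates are converted from GFF3 1-based inclusive to the package's
#' 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open), sorted by position.
#' @details CDS features whose `Parent` chain cannot be resolved to a gene
#'   are skipped with a warning. Non-positive or inverted coordinates are a
#'   hard error.
#' @export
load_gene_models <- function(path) {
  if (!file.exists(path)) abort(sprintf("GFF3 file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(tibble(gene_id = character(), transcript_id = character(),
                  chrom = character(), strand = character(),
                  start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    abort(sprintf("malformed GFF3 line %d: expected 9 columns, got %d",
                  which(nf != 9L)[1], nf[nf != 9L][1]))
  }
  m <- do.call(rbind, fields)
  attr_get <- function(attrs, key) {
    val <- stringr::str_match(attrs, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    val
  }
  feat <- tibble(
    chrom = m[, 1], type = m[, 3],
    start1 = as.integer(m[, 4]), end1 = as.integer(m[, 5]),
    strand = m[, 7], attrs = m[, 9]
  )
  if (any(is.na(feat$start1)) || any(is.na(feat$end1)) ||
      any(feat$start1 < 1L) || any(feat$end1 < feat$start1)) {
    abort("out-of-bounds coordinates in GFF3 (start < 1 or end < start)")
  }
  feat$id <- attr_get(feat$attrs, "ID")
  feat$parent <- attr_get(feat$attrs, "Parent")

  genes <- feat$id[feat$type == "gene"]
  mrna <- feat[feat$type %in% c("mRNA", "transcript"), ]
  mrna_gene <- setNames(mrna$parent, mrna$id)
  cds <- feat[feat$type == "CDS", ]
  if (!nrow(cds)) {
    return(tibble(gene_id = character(), transcript_id = character(),
                  chrom = character(), strand = character(),
                  start = integer(), end = integer()))
  }
  tx <- cds$parent
  gid <- ifelse(tx %in% names(mrna_gene), unname(mrna_gene[tx]),
                ifelse(tx %in% genes, tx, NA_character_))
  # a CDS whose Parent is itself an annotated gene id is acceptable
  orphan <- is.na(tx) | is.na(gid) | !gid %in% c(genes, unname(mrna_gene))
  if (any(orphan)) {
    warn(sprintf("skipping %d CDS feature(s) without a resolvable gene ancestor",
                 sum(orphan)))
    cds <- cds[!orphan, , drop = FALSE]
    tx <- tx[!orphan]
    gid <- gid[!orphan]
  }
  out <- tibble(
    gene_id = gid, transcript_id = tx, chrom = cds$chrom,
    strand = cds$strand, start = cds$start1 - 1L, end = cds$end1
  )
  arrange(out, .data$chrom, .data$start, .data$gene_id, .data$transcript_id)
}

#' Read alignments from a PAF file
#'
#' @param path Path to a PAF file (12 or more tab-separated columns).
#' @return A tibble of alignment records with columns `qname`, `qlen`,
#'   `qstart`, `qend`, `strand`, `tname`, `tlen`, `tstart`, `tend`,
#'   `matches`, `block_len`, `mapq`, `is_primary`, `cigar` (NA when absent).
#' @details When `tp:A:P`/`tp:A:S` tags are present they define primacy;
#'   otherwise the record with the highest `matches` per query is primary,
#'   ties broken by lowest target coordinate. A malformed column count is a
#'   hard error naming the line.
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) abort(sprintf("PAF file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble(qname = character(), qlen = integer(), qstart = integer(),
                  qend = integer(), strand = character(), tname = character(),
                  tlen = integer(), tstart = integer(), tend = integer(),
                  matches = integer(), block_len = integer(), mapq = integer(),
                  is_primary = logical(), cigar = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    abort(sprintf("malformed PAF line %d: expected >= 12 columns, got %d",
                  which(nf < 12L)[1], min(nf)))
  }
  tag_val <- function(f, prefix) {
    hit <- f[startsWith(f, prefix)]
    if (length(hit)) sub(prefix, "", hit[1], fixed = TRUE) else NA_character_
  }
  rec <- purrr::map(fields, function(f) {
    tibble(
      qname = f[1], qlen = as.integer(f[2]), qstart = as.integer(f[3]),
      qend = as.integer(f[4]), strand = f[5], tname = f[6],
      tlen = as.integer(f[7]), tstart = as.integer(f[8]),
      tend = as.integer(f[9]), matches = as.integer(f[10]),
      block_len = as.integer(f[11]), mapq = as.integer(f[12]),
      tp = tag_val(f[-(1:12)], "tp:A:"),
      cigar = tag_val(f[-(1:12)], "cg:Z:")
    )
  })
  out <- bind_rows(rec)
  if (all(is.na(out$tp))) {
    out <- out |>
      group_by(.data$qname) |>
      mutate(is_primary = row_number(order(-.data$matches, .data$tstart)) == 1L) |>
      ungroup()
  } else {
    out$is_primary <- !is.na(out$tp) & out$tp == "P"
  }
  select(out, -"tp")
}

#' Write intervals to a BED file
#'
#' Writes 0-based half-open intervals as sorted 3+ column BED preceded by a
#' `#` header line; round-trips losslessly with [read_bed()].
#'
#' @param items A tibble with columns `chrom`, `start`, `end` (extra columns
#'   are appended as BED columns 4+).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(items, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(items)))
  items <- arrange(items, .data$chrom, .data$start, .data$end)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(items), collapse = "\t")), con)
  if (nrow(items)) {
    body <- do.call(paste, c(lapply(items, as.character), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a BED file written by [write_bed()]
#'
#' @param path Path to a BED file; `#` lines are treated as the header.
#' @return A tibble with at least `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  cols <- if (length(header)) {
    strsplit(sub("^#", "", header[1]), "\t", fixed = TRUE)[[1]]
  } else c("chrom", "start", "end")
  if (!length(body)) {
    out <- tibble(chrom = character(), start = integer(), end = integer())
    return(out)
  }
  m <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  out <- as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
  names(out) <- cols[seq_len(ncol(out))]
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  for (col in setdiff(names(out), c("chrom", "start", "end"))) {
    conv <- suppressWarnings(as.numeric(out[[col]]))
    if (!any(is.na(conv))) out[[col]] <- conv
  }
  arrange(out, .data$chrom, .data$start, .data$end)
}

#' Write gene models to GFF3
#'
#' Inverse of [load_gene_models()]: converts the package's 0-based half-open
#' CDS intervals back to 1-based inclusive GFF3 with gene/mRNA/CDS rows.
#'
#' @param cds A tibble of CDS intervals as returned by [load_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(cds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(cds)) {
    cds <- arrange(cds, .data$chrom, .data$start)
    by_gene <- split(cds, cds$gene_id)[unique(cds$gene_id)]
    for (g in by_gene) {
      gid <- g$gene_id[1]
      writeLines(sprintf("%s\tpavscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                         g$chrom[1], min(g$start) + 1L, max(g$end),
                         g$strand[1], gid), con)
      for (tid in unique(g$transcript_id)) {
        t <- g[g$transcript_id == tid, ]
        writeLines(sprintf("%s\tpavscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                           t$chrom[1], min(t$start) + 1L, max(t$end),
                           t$strand[1], tid, gid), con)
        writeLines(sprintf("%s\tpavscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
                           t$chrom, t$start + 1L, t$end, t$strand, tid, tid), con)
      }
    }
  }
  invisible(path)
}

#' Write reads to FASTQ
#'
#' @param reads A named `DNAStringSet` (or named character vector) of reads.
#' @param path Output path.
#' @param quality Single quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality = "I") {
  seqs <- as.character(reads)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(seqs)) {
    qual <- vapply(nchar(seqs), function(n) strrep(quality, n), character(1))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
  }
  invisible(path)
}
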