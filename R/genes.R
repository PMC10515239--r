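# Gene-level PAV classification: transcript-merged CDS, segment-overlap
# candidacy, read-support validation, and cross-taxon presence tracing.

#' Merge the CDS of a gene's transcripts
#'
#' Represents each gene by the interval union of its transcripts' CDS, the
#' unit on which PAV coverage fractions are computed.
#'
#' @param cds CDS tibble (`gene_id`, `transcript_id`, `chrom`, `strand`,
#'   `start`, `end`) as from [load_gene_models()].
#' @return A tibble of merged, non-overlapping, sorted CDS intervals:
#'   `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @details Transcripts of one gene on different chromosomes are a hard
#'   error.
#' @export
merge_transcript_cds <- function(cds) {
  if (!nrow(cds)) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer()))
  }
  chroms <- cds |> distinct(.data$gene_id, .data$chrom)
  bad <- chroms$gene_id[duplicated(chroms$gene_id)]
  if (length(bad)) {
    abort(sprintf("gene(s) with transcripts on conflicting chromosomes: %s",
                  paste(unique(bad), collapse = ", ")))
  }
  out <- purrr::map(split(cds, cds$gene_id), function(g) {
    ir <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    tibble(gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
           start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
  arrange(bind_rows(out), .data$chrom, .data$start, .data$gene_id)
}

cds_lengths <- function(merged) {
  merged |>
    group_by(.data$gene_id) |>
    summarise(cds_length = sum(.data$end - .data$start), .groups = "drop")
}

# bp of overlap between each gene's merged CDS and an interval set
gene_overlap_bp <- function(merged, intervals) {
  if (!nrow(intervals)) {
    return(tibble(gene_id = unique(merged$gene_id), overlap_bp = 0L))
  }
  res <- purrr::map(split(merged, merged$chrom), function(m) {
    iv <- intervals[intervals$chrom == m$chrom[1], ]
    if (!nrow(iv)) return(tibble(gene_id = unique(m$gene_id), overlap_bp = 0L))
    gr <- IRanges::IRanges(m$start + 1L, m$end)
    sr <- IRanges::reduce(IRanges::IRanges(iv$start + 1L, iv$end))
    ov <- IRanges::findOverlaps(gr, sr)
    w <- IRanges::width(IRanges::pintersect(
      gr[S4Vectors::queryHits(ov)], sr[S4Vectors::subjectHits(ov)]))
    tibble(gene_id = m$gene_id[S4Vectors::queryHits(ov)], bp = w) |>
      group_by(.data$gene_id) |>
      summarise(overlap_bp = sum(.data$bp), .groups = "drop") |>
      (\(x) bind_rows(x, tibble(gene_id = setdiff(unique(m$gene_id), x$gene_id),
                                overlap_bp = 0L)))()
  })
  bind_rows(res)
}

#' Call candidate PAV genes from segment overlap
#'
#' A gene is a PAV-gene candidate when strictly more than `threshold` of
#' its transcript-merged CDS is covered by PAV segments of the same genome.
#'
#' @param merged Merged CDS tibble from [merge_transcript_cds()].
#' @param segments PAV segment tibble (`chrom`, `start`, `end`).
#' @param threshold Strict CDS-coverage fraction (default 0.75).
#' @return A tibble per gene: `gene_id`, `cds_length`, `pav_bp`,
#'   `pav_fraction`, `candidate`. Genes with zero CDS length are skipped
#'   with a warning.
#' @export
call_pav_genes <- function(merged, segments, threshold = 0.75) {
  lens <- cds_lengths(merged)
  zero <- lens$gene_id[lens$cds_length == 0]
  if (length(zero)) {
    warn(sprintf("skipping gene(s) with zero CDS length: %s",
                 paste(zero, collapse = ", ")))
    lens <- lens[lens$cds_length > 0, ]
    merged <- merged[!merged$gene_id %in% zero, ]
  }
  ov <- gene_overlap_bp(merged, segments)
  lens |>
    left_join(ov, by = "gene_id") |>
    mutate(overlap_bp = dplyr::coalesce(.data$overlap_bp, 0L),
           pav_fraction = .data$overlap_bp / .data$cds_length,
           candidate = .data$pav_fraction > threshold) |>
    rename(pav_bp = "overlap_bp") |>
    arrange(.data$gene_id)
}

#' Validate candidate PAV genes against counterpart read coverage
#'
#' Reads of the counterpart genome mapped onto this genome evidence that a
#' candidate's sequence is in fact present there: candidates with strictly
#' more than `threshold` of their CDS covered by such reads are rejected;
#' the rest are the final PAV genes.
#'
#' @param candidates Output of [call_pav_genes()].
#' @param read_cov A tibble `gene_id`, `read_fraction` (CDS fraction
#'   covered at depth >= 1 by counterpart reads), e.g. from
#'   [cds_read_coverage()] or a user-supplied table.
#' @param threshold Strict rejection fraction (default 0.50).
#' @return The candidate tibble with `read_fraction` and
#'   `status` in `candidate` (non-candidates), `final_pav`, `rejected`.
#'   Candidates missing from `read_cov` are a hard error naming the genes.
#' @export
read_support_filter <- function(candidates, read_cov, threshold = 0.50) {
  cand_ids <- candidates$gene_id[candidates$candidate]
  missing <- setdiff(cand_ids, read_cov$gene_id)
  if (length(missing)) {
    abort(sprintf("missing read coverage for candidate gene(s): %s",
                  paste(missing, collapse = ", ")))
  }
  check_fraction(read_cov$read_fraction, "read_fraction")
  candidates |>
    left_join(select(read_cov, "gene_id", "read_fraction"), by = "gene_id") |>
    mutate(status = case_when(
      !.data$candidate ~ "not_candidate",
      .data$read_fraction > threshold ~ "rejected",
      TRUE ~ "final_pav"
    ))
}

#' CDS read-coverage fractions from mapped reads
#'
#' Maps reads onto a genome with the internal seed mapper, keeps primary
#' alignments whose seed coverage is at least `min_identity` (simulated or
#' resequencing reads are near-exact), accumulates per-base depth from the
#' primary spans, and reports for each gene the fraction of merged-CDS
#' bases covered at depth >= 1.
#'
#' @param merged Merged CDS tibble from [merge_transcript_cds()].
#' @param reads A `DNAStringSet` (or character vector) of reads.
#' @param genome The `DNAStringSet` the genes are annotated on.
#' @param min_identity Minimum read identity for a read to count (default
#'   0.95). Each mismatch can erase up to `k` exact-seed-covered bases, so
#'   the identity floor is applied as a seed-coverage floor of
#'   `1 - (1 - min_identity) * k`.
#' @param k Seed length.
#' @return A tibble `gene_id`, `read_fraction`.
#' @export
cds_read_coverage <- function(merged, reads, genome, min_identity = 0.95,
                              k = 15L) {
  hits <- map_windows(reads, genome, k = k)
  min_cov <- max(0, 1 - (1 - min_identity) * k)
  hits <- filter(hits, .data$coverage >= min_cov)
  cov_by_chrom <- lapply(setNames(nm = names(genome)), function(ch) {
    h <- hits[hits$tchrom == ch, ]
    len <- Biostrings::width(genome[ch])
    if (!nrow(h)) return(IRanges::coverage(IRanges::IRanges(), width = len))
    IRanges::coverage(IRanges::IRanges(h$tstart + 1L, h$tend), width = len)
  })
  res <- merged
  res$covered <- purrr::map_dbl(seq_len(nrow(merged)), function(i) {
    v <- cov_by_chrom[[merged$chrom[i]]][(merged$start[i] + 1):merged$end[i]]
    sum(S4Vectors::runLength(v)[S4Vectors::runValue(v) > 0])
  })
  res |>
    group_by(.data$gene_id) |>
    summarise(cds_length = sum(.data$end - .data$start),
              covered = sum(.data$covered), .groups = "drop") |>
    mutate(read_fraction = .data$covered / .data$cds_length) |>
    select("gene_id", "read_fraction")
}

#' Cross-taxon presence matrix for final PAV genes
#'
#' For each final PAV gene and each taxon, the gene is called present when
#' the taxon's reads cover strictly more than `threshold` of the CDS. The
#' summary reports the fraction of PAV genes with a homolog in at least one
#' taxon.
#'
#' @param calls Output of [read_support_filter()] (only `final_pav` genes
#'   are used).
#' @param taxa_cov Long tibble `gene_id`, `taxon`, `coverage`.
#' @param threshold Strict presence threshold (default 0.50).
#' @return An object of class `taxon_presence`: list with `cells` (long
#'   tibble `gene_id`, `taxon`, `coverage`, `present`) and `summary`
#'   (`n_genes`, `n_taxa`, `frac_present_any`).
#' @export
taxon_presence_matrix <- function(calls, taxa_cov, threshold = 0.50) {
  pav_ids <- calls$gene_id[calls$status == "final_pav"]
  taxa <- unique(taxa_cov$taxon)
  grid <- tidyr::expand_grid(gene_id = pav_ids, taxon = taxa)
  cells <- grid |>
    left_join(taxa_cov, by = c("gene_id", "taxon")) |>
    mutate(coverage = dplyr::coalesce(.data$coverage, 0),
           present = .data$coverage > threshold)
  check_fraction(cells$coverage, "taxon coverage")
  summary <- cells |>
    group_by(.data$gene_id) |>
    summarise(any_taxon = any(.data$present), .groups = "drop")
  structure(
    list(cells = cells,
         summary = tibble(n_genes = length(pav_ids), n_taxa = length(taxa),
                          frac_present_any = if (length(pav_ids))
                            mean(summary$any_taxon) else NA_real_)),
    class = "taxon_presence"
  )
}

#' @export
print.taxon_presence <- function(x, ...) {
  cat("Cross-taxon PAV gene presence\n")
  print(x$summary)
  invisible(x)
}
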