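# One-to-one syntenic block selection, SNP/small-indel calling within
# blocks, per-kb densities, and SNP genotype-matrix filtering/thinning.

#' Select one-to-one syntenic blocks from alignment records
#'
#' Greedy selection by descending match count (ties by query coordinate): a
#' record is kept only if it overlaps no already-kept record on either the
#' query or the target. Kept records are then grouped into co-linear
#' blocks (same chromosome pair and strand, consistent order).
#'
#' @param aln Alignment tibble with columns `qchrom`, `qstart`, `qend`,
#'   `tchrom`, `tstart`, `tend`, `strand`, `matches` (PAF tables from
#'   [read_paf()] are accepted; `qname`/`tname` are used as chromosomes).
#' @param max_gap Maximum query/target gap between records merged into one
#'   block (default `1e6`).
#' @return The kept records, sorted by query position, with a `block_id`
#'   column; no query or target base occurs in two kept records.
#' @export
chain_one_to_one <- function(aln, max_gap = 1e6) {
  if ("qname" %in% names(aln) && !"qchrom" %in% names(aln)) {
    aln <- rename(aln, qchrom = "qname", tchrom = "tname")
  }
  if (!nrow(aln)) return(mutate(aln, block_id = integer()))
  aln <- arrange(aln, desc(.data$matches), .data$qchrom, .data$qstart,
                 .data$tchrom, .data$tstart)
  kept <- logical(nrow(aln))
  occ_q <- list(); occ_t <- list()
  overlaps <- function(occ, key, s, e) {
    iv <- occ[[key]]
    if (is.null(iv)) return(FALSE)
    any(iv$s < e & s < iv$e)
  }
  add <- function(occ, key, s, e) {
    iv <- occ[[key]]
    if (is.null(iv)) iv <- list(s = numeric(), e = numeric())
    iv$s <- c(iv$s, s); iv$e <- c(iv$e, e)
    occ[[key]] <- iv
    occ
  }
  for (i in seq_len(nrow(aln))) {
    if (overlaps(occ_q, aln$qchrom[i], aln$qstart[i], aln$qend[i])) next
    if (overlaps(occ_t, aln$tchrom[i], aln$tstart[i], aln$tend[i])) next
    kept[i] <- TRUE
    occ_q <- add(occ_q, aln$qchrom[i], aln$qstart[i], aln$qend[i])
    occ_t <- add(occ_t, aln$tchrom[i], aln$tstart[i], aln$tend[i])
  }
  out <- arrange(aln[kept, , drop = FALSE], .data$qchrom, .data$qstart)
  # co-linear grouping
  bid <- integer(nrow(out))
  cur <- 0L
  for (i in seq_len(nrow(out))) {
    new_block <- i == 1 ||
      out$qchrom[i] != out$qchrom[i - 1] ||
      out$tchrom[i] != out$tchrom[i - 1] ||
      out$strand[i] != out$strand[i - 1] ||
      out$qstart[i] - out$qend[i - 1] > max_gap ||
      (out$strand[i] == "+" &&
         (out$tstart[i] < out$tend[i - 1] ||
            out$tstart[i] - out$tend[i - 1] > max_gap)) ||
      (out$strand[i] == "-" && out$tend[i] > out$tstart[i - 1])
    if (new_block) cur <- cur + 1L
    bid[i] <- cur
  }
  mutate(out, block_id = bid)
}

parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  if (m[1] == -1) abort("unparsable CIGAR string")
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", toks)),
       op = sub("^\\d+", "", toks))
}

#' Call SNPs and indels within syntenic blocks
#'
#' Walks each block's column-level alignment: mismatch columns become
#' SNPs (adjacent mismatches stay separate events), each maximal gap run
#' becomes one indel event of its length. Indels of 100 bp or more are
#' excluded from the retained list but logged. Aligned bp is the number of
#' match/mismatch columns.
#'
#' @param blocks Block tibble with `qchrom`, `qstart`, `qend`, `tchrom`,
#'   `tstart`, `tend`, `strand`, `cigar` (e.g. from [truth_alignment()] or
#'   a PAF with `cg:Z` tags chained by [chain_one_to_one()]).
#' @param query_genome,target_genome `DNAStringSet`s providing the block
#'   sequences.
#' @param max_indel Indels strictly shorter than this are retained
#'   (default 100 bp).
#' @return An object of class `variant_calls`: list with `variants`
#'   (tibble `kind`, `qchrom`, `qpos`, `tchrom`, `tpos`, `ref`, `alt`,
#'   `length`, `retained`; positions 0-based), `aligned_bp`, and the
#'   retained/excluded counts. A missing CIGAR is a hard error.
#' @export
call_block_variants <- function(blocks, query_genome, target_genome,
                                max_indel = 100L) {
  if (is.null(blocks$cigar) || any(is.na(blocks$cigar))) {
    abort("blocks must carry a column-level alignment (CIGAR)")
  }
  if (any(blocks$strand != "+")) {
    abort("only forward-strand blocks are supported")
  }
  aligned_bp <- 0
  rows <- list()
  for (b in seq_len(nrow(blocks))) {
    cg <- parse_cigar(blocks$cigar[b])
    qs <- as.character(Biostrings::subseq(
      query_genome[[blocks$qchrom[b]]], blocks$qstart[b] + 1L, blocks$qend[b]))
    ts <- as.character(Biostrings::subseq(
      target_genome[[blocks$tchrom[b]]], blocks$tstart[b] + 1L, blocks$tend[b]))
    qp <- 0L; tp <- 0L
    for (i in seq_along(cg$op)) {
      len <- cg$len[i]; op <- cg$op[i]
      if (op %in% c("M", "=", "X")) {
        qv <- charToRaw(substr(qs, qp + 1L, qp + len))
        tv <- charToRaw(substr(ts, tp + 1L, tp + len))
        mm <- which(qv != tv)
        if (length(mm)) {
          rows[[length(rows) + 1]] <- tibble(
            kind = "SNP", qchrom = blocks$qchrom[b],
            qpos = blocks$qstart[b] + qp + mm - 1L,
            tchrom = blocks$tchrom[b],
            tpos = blocks$tstart[b] + tp + mm - 1L,
            ref = rawToChar(tv[mm], multiple = TRUE),
            alt = rawToChar(qv[mm], multiple = TRUE),
            length = 1L)
        }
        aligned_bp <- aligned_bp + len
        qp <- qp + len; tp <- tp + len
      } else if (op == "I") {
        rows[[length(rows) + 1]] <- tibble(
          kind = "indel", qchrom = blocks$qchrom[b],
          qpos = blocks$qstart[b] + qp, tchrom = blocks$tchrom[b],
          tpos = blocks$tstart[b] + tp,
          ref = "-", alt = substr(qs, qp + 1L, qp + min(len, 20L)),
          length = len)
        qp <- qp + len
      } else if (op %in% c("D", "N")) {
        rows[[length(rows) + 1]] <- tibble(
          kind = "indel", qchrom = blocks$qchrom[b],
          qpos = blocks$qstart[b] + qp, tchrom = blocks$tchrom[b],
          tpos = blocks$tstart[b] + tp,
          ref = substr(ts, tp + 1L, tp + min(len, 20L)), alt = "-",
          length = len)
        tp <- tp + len
      } else {
        abort(sprintf("unsupported CIGAR op '%s'", op))
      }
    }
  }
  variants <- if (length(rows)) bind_rows(rows) else
    tibble(kind = character(), qchrom = character(), qpos = integer(),
           tchrom = character(), tpos = integer(), ref = character(),
           alt = character(), length = integer())
  variants <- mutate(variants,
                     retained = .data$kind == "SNP" | .data$length < max_indel)
  structure(
    list(variants = variants, aligned_bp = aligned_bp,
         n_snps = sum(variants$kind == "SNP"),
         n_indels = sum(variants$kind == "indel" & variants$retained),
         n_excluded = sum(!variants$retained)),
    class = "variant_calls"
  )
}

#' @export
print.variant_calls <- function(x, ...) {
  cat(sprintf("%d SNPs, %d indels (< max) over %d aligned bp (%d excluded)\n",
              x$n_snps, x$n_indels, as.integer(x$aligned_bp), x$n_excluded))
  invisible(x)
}

#' Per-kilobase variant densities
#'
#' @param calls A `variant_calls` object (or a tibble with `kind` and
#'   `retained` columns plus `aligned_bp` passed explicitly).
#' @param aligned_bp Aligned match/mismatch columns; taken from `calls`
#'   when it is a `variant_calls` object.
#' @return A one-row tibble: `snps_per_kb`, `indels_per_kb`, `aligned_bp`.
#' @export
variant_density <- function(calls, aligned_bp = NULL) {
  if (inherits(calls, "variant_calls")) {
    aligned_bp <- calls$aligned_bp
    v <- calls$variants
  } else {
    v <- calls
  }
  if (is.null(aligned_bp) || aligned_bp <= 0) {
    abort("aligned_bp must be positive")
  }
  ret <- if (is.null(v$retained)) rep(TRUE, nrow(v)) else v$retained
  n_snp <- sum(v$kind == "SNP" & ret)
  n_ind <- sum(v$kind == "indel" & ret)
  tibble(snps_per_kb = n_snp * 1000 / aligned_bp,
         indels_per_kb = n_ind * 1000 / aligned_bp,
         aligned_bp = aligned_bp)
}

#' Filter a SNP genotype matrix by MAF and missingness
#'
#' Keeps biallelic sites with minor allele frequency strictly above `maf`
#' (computed over non-missing alleles) and missing-data fraction strictly
#' below `max_missing` (over all samples).
#'
#' @param m A tibble with site columns `chrom`, `pos` and one column per
#'   sample holding diploid genotype dosages in `{0, 1, 2, NA}`.
#' @param maf Strict minor-allele-frequency lower bound (default 0.05).
#' @param max_missing Strict missing-fraction upper bound (default 0.20).
#' @return The filtered tibble, same columns, original site order. Sites
#'   with all calls missing are removed with a warning.
#' @export
filter_snp_matrix <- function(m, maf = 0.05, max_missing = 0.20) {
  samp_cols <- setdiff(names(m), c("chrom", "pos"))
  if (!length(samp_cols)) abort("no sample columns in matrix")
  g <- as.matrix(m[samp_cols])
  if (!all(g %in% c(0, 1, 2, NA))) {
    abort("genotypes must be dosages in {0, 1, 2} or NA")
  }
  n_samp <- length(samp_cols)
  n_miss <- rowSums(is.na(g))
  all_missing <- n_miss == n_samp
  if (any(all_missing)) {
    warn(sprintf("removing %d site(s) with all calls missing",
                 sum(all_missing)))
  }
  alt_count <- rowSums(g, na.rm = TRUE)
  n_alleles <- 2 * (n_samp - n_miss)
  p <- ifelse(n_alleles > 0, alt_count / n_alleles, NA_real_)
  site_maf <- pmin(p, 1 - p)
  keep <- !all_missing & site_maf > maf & (n_miss / n_samp) < max_missing
  m[keep, , drop = FALSE]
}

#' Thin SNP sites at a fixed stride
#'
#' Keeps every `stride`-th site in genome order, starting from the site at
#' `offset` (0-based index of the first retained site).
#'
#' @param m A site tibble with `chrom` and `pos` columns.
#' @param stride Keep one site in `stride` (default 37).
#' @param offset 0-based index of the first kept site (default 0).
#' @return The thinned tibble.
#' @export
thin_sites <- function(m, stride = 37L, offset = 0L) {
  if (stride < 1) abort("stride must be at least 1")
  m <- arrange(m, .data$chrom, .data$pos)
  if (!nrow(m)) return(m)
  idx <- seq.int(offset + 1L, nrow(m), by = stride)
  m[idx, , drop = FALSE]
}
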