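# Sliding-window presence/absence variation detection: windowing, window
# mapping, coverage classification, merging, and segment reporting.

#' Parameters for sliding-window PAV detection
#'
#' @param window Window width in bp (default 500).
#' @param step Step between window starts in bp (default 100; must not
#'   exceed `window`, or bases would go unclassified).
#' @param min_other_cov Windows whose primary alignment coverage on the
#'   counterpart genome is below this fraction (strictly) are candidate
#'   genome-specific windows (default 0.25).
#' @param min_self_cov A window must align back to its own genome with at
#'   least this coverage to be called specific (default 0.90); this
#'   suppresses assembly-artifact windows.
#' @param min_segment Merged segments must be strictly longer than this to
#'   be reported (default 500 bp).
#' @param large_segment Strict threshold for the large-segment class
#'   (default 5000 bp).
#' @param max_n_frac Windows with at least this fraction of N bases are
#'   masked and never called specific (default 0.5).
#' @return A list of class `pav_params`.
#' @export
pav_params <- function(window = 500L, step = 100L, min_other_cov = 0.25,
                       min_self_cov = 0.90, min_segment = 500L,
                       large_segment = 5000L, max_n_frac = 0.5) {
  if (step > window) abort("step > window would leave unclassified gaps")
  if (step < 1 || window < 1) abort("window and step must be positive")
  check_fraction(c(min_other_cov, min_self_cov, max_n_frac),
                 "coverage thresholds")
  structure(list(window = as.integer(window), step = as.integer(step),
                 min_other_cov = min_other_cov, min_self_cov = min_self_cov,
                 min_segment = as.integer(min_segment),
                 large_segment = as.integer(large_segment),
                 max_n_frac = max_n_frac),
            class = "pav_params")
}

#' Tile a genome into fixed-width overlapping windows
#'
#' Windows start at 0, `step`, `2*step`, ... on each chromosome while
#' `start + window <= length`; there is no trailing partial window, so up
#' to `window - 1` bases at each chromosome end are unclassifiable.
#'
#' @param genome A `DNAStringSet`.
#' @param params A [pav_params()].
#' @return A tibble `chrom`, `start`, `end`, `n_frac` (fraction of N bases).
#' @export
make_windows <- function(genome, params = pav_params()) {
  lens <- Biostrings::width(genome)
  if (all(lens < params$window)) {
    abort("window exceeds every chromosome length")
  }
  out <- purrr::map(seq_along(genome), function(i) {
    L <- lens[i]
    if (L < params$window) return(NULL)
    starts <- seq.int(0L, L - params$window, by = params$step)
    w <- tibble(chrom = names(genome)[i], start = starts,
                end = starts + params$window)
    v <- Biostrings::Views(genome[[i]], start = starts + 1L, width = params$window)
    nf <- Biostrings::letterFrequency(v, "N") / params$window
    w$n_frac <- as.numeric(nf)
    w
  })
  bind_rows(out)
}

#' Map query windows (or reads) to a target genome
#'
#' A deterministic internal mapper: exact 15-mer seeds against an index of
#' the target, clustered by target locality on both strands; the best
#' cluster per query is its primary alignment, and coverage is the fraction
#' of query bases spanned by that cluster's seed matches. An external
#' aligner's PAF ([read_paf()]) can be used instead wherever a coverage
#' table is accepted.
#'
#' @param queries A tibble with `chrom`, `start`, `end` (windows to extract
#'   from `query_genome`), or a `DNAStringSet`/character vector of
#'   sequences (then `query_genome` is ignored).
#' @param target A `DNAStringSet` to map against.
#' @param query_genome The `DNAStringSet` windows are extracted from.
#' @param k Seed length (default 15).
#' @param max_occ Seeds occurring more often than this in the target are
#'   skipped as repetitive (default 64).
#' @return A tibble of primary alignment records: `query` (index into
#'   `queries`), `tchrom`, `tstart`, `tend`, `strand`, `matches`, `qlen`,
#'   `coverage`. Queries with no seed hit are absent.
#' @export
map_windows <- function(queries, target, query_genome = NULL, k = 15L,
                        max_occ = 64L) {
  if (is.data.frame(queries)) {
    stopifnot(!is.null(query_genome))
    seqs <- extract_window_seqs(queries, query_genome)
  } else {
    seqs <- as.character(queries)
  }
  hits <- cpp_map_queries(unname(seqs), unname(as.character(target)),
                          names(target), as.integer(k), as.integer(max_occ))
  hits <- as_tibble(hits)
  hits$coverage <- hits$matches / hits$qlen
  hits
}

extract_window_seqs <- function(windows, genome) {
  out <- character(nrow(windows))
  for (ch in unique(windows$chrom)) {
    sel <- windows$chrom == ch
    s <- as.character(genome[[ch]])
    out[sel] <- substring(s, windows$start[sel] + 1L, windows$end[sel])
  }
  out
}

#' Per-window self and counterpart coverage
#'
#' Convenience wrapper running the internal mapper twice: each window
#' against its own genome and against the counterpart.
#'
#' @param windows Window tibble from [make_windows()].
#' @param self_genome,other_genome `DNAStringSet`s.
#' @inheritParams map_windows
#' @return The window tibble with `self_cov`, `other_cov`, `other_aligned`.
#' @export
window_coverage <- function(windows, self_genome, other_genome, k = 15L,
                            max_occ = 64L) {
  seqs <- extract_window_seqs(windows, self_genome)
  self_hits <- map_windows(seqs, self_genome, k = k, max_occ = max_occ)
  other_hits <- map_windows(seqs, other_genome, k = k, max_occ = max_occ)
  windows$self_cov <- 0
  windows$self_cov[self_hits$query] <- self_hits$coverage
  windows$other_cov <- 0
  windows$other_cov[other_hits$query] <- other_hits$coverage
  windows$other_aligned <- FALSE
  windows$other_aligned[other_hits$query] <- TRUE
  windows
}

#' Classify windows as genome-specific or shared
#'
#' A window is `specific` when it is unaligned on the counterpart genome or
#' its primary alignment coverage there is strictly below `min_other_cov`,
#' AND it aligns properly to its own genome (`self_cov >= min_self_cov`).
#' Masked windows (N fraction at or above the mask threshold) are never
#' specific.
#'
#' @param calls A tibble with `chrom`, `start`, `end`, `self_cov`,
#'   `other_cov`, and optionally `other_aligned` and `n_frac`.
#' @param params A [pav_params()].
#' @return The input with a `status` column: `specific`, `shared`, `masked`.
#' @export
classify_windows <- function(calls, params = pav_params()) {
  check_fraction(calls$self_cov, "self_cov")
  check_fraction(calls$other_cov, "other_cov")
  if (is.null(calls$other_aligned)) calls$other_aligned <- calls$other_cov > 0
  if (is.null(calls$n_frac)) calls$n_frac <- 0
  calls |>
    mutate(status = case_when(
      .data$n_frac >= params$max_n_frac ~ "masked",
      (!.data$other_aligned | .data$other_cov < params$min_other_cov) &
        .data$self_cov >= params$min_self_cov ~ "specific",
      TRUE ~ "shared"
    ))
}

#' Merge overlapping specific windows into PAV segments
#'
#' Maximal unions of specific windows: a window extends the current segment
#' when its start does not exceed the running union end.
#'
#' @param calls Classified window tibble (from [classify_windows()]),
#'   sorted by chromosome and start.
#' @return A tibble of segments: `chrom`, `start`, `end`, `length`,
#'   `n_windows`.
#' @export
merge_specific_windows <- function(calls) {
  spec <- calls |>
    filter(.data$status == "specific") |>
    arrange(.data$chrom, .data$start)
  if (!nrow(spec)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  length = integer(), n_windows = integer()))
  }
  out <- purrr::map(split(spec, spec$chrom), function(s) {
    ir <- IRanges::IRanges(start = s$start + 1L, end = s$end)
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    tibble(chrom = s$chrom[1],
           start = IRanges::start(red) - 1L,
           end = IRanges::end(red),
           length = IRanges::width(red),
           n_windows = lengths(S4Vectors::mcols(red)$revmap))
  })
  arrange(bind_rows(out), .data$chrom, .data$start)
}

#' Filter segments by the reporting length threshold
#'
#' @param segments Segment tibble from [merge_specific_windows()].
#' @param params A [pav_params()].
#' @return Segments strictly longer than `min_segment`.
#' @export
filter_segments <- function(segments, params = pav_params()) {
  filter(segments, .data$length > params$min_segment)
}

#' Summarise PAV segments
#'
#' Retains segments strictly longer than `min_segment` and reports their
#' count and total length, plus the count and total length of the large
#' class (strictly longer than `large_segment`).
#'
#' @param segments Segment tibble from [merge_specific_windows()].
#' @param params A [pav_params()].
#' @return A one-row tibble: `n_segments`, `total_bp`, `n_large`,
#'   `large_bp`.
#' @export
summarize_segments <- function(segments, params = pav_params()) {
  kept <- filter_segments(segments, params)
  large <- filter(kept, .data$length > params$large_segment)
  tibble(n_segments = nrow(kept), total_bp = sum(kept$length),
         n_large = nrow(large), large_bp = sum(large$length))
}

#' Run the full sliding-window PAV scan between two genomes
#'
#' Tiles each genome into overlapping windows, maps every window against
#' both assemblies with the internal seed mapper, classifies windows,
#' merges specific windows into segments, and reports both directions.
#'
#' @param genome_a,genome_b `DNAStringSet` assemblies (labels `A` and `B`).
#' @param params A [pav_params()].
#' @param k,max_occ Seed mapper settings, see [map_windows()].
#' @return An object of class `pav_result`: list with `windows` (classified
#'   calls, both genomes), `segments` (retained segments with a `genome`
#'   label), `report` (per-genome summary). Supports [tidy()], [glance()]
#'   and [autoplot()].
#' @export
pav_scan <- function(genome_a, genome_b, params = pav_params(), k = 15L,
                     max_occ = 64L) {
  one_direction <- function(self, other, label) {
    w <- make_windows(self, params)
    w <- window_coverage(w, self, other, k = k, max_occ = max_occ)
    w <- classify_windows(w, params)
    segs <- merge_specific_windows(w)
    list(windows = mutate(w, genome = label),
         segments = mutate(filter_segments(segs, params), genome = label),
         report = mutate(summarize_segments(segs, params), genome = label))
  }
  a <- one_direction(genome_a, genome_b, "A")
  b <- one_direction(genome_b, genome_a, "B")
  structure(
    list(windows = bind_rows(a$windows, b$windows),
         segments = bind_rows(a$segments, b$segments),
         report = bind_rows(a$report, b$report),
         params = params),
    class = "pav_result"
  )
}

#' @export
print.pav_result <- function(x, ...) {
  cat("Sliding-window PAV scan\n")
  print(x$report)
  invisible(x)
}
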