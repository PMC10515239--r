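# k-mer survey statistics: canonical k-mer histogram, genome-size estimate,
# heterozygous k-mer-species percentage.

#' Canonical k-mer depth histogram
#'
#' Counts canonical k-mers (lexicographic minimum of a k-mer and its
#' reverse complement) across a read set and tabulates the number of
#' distinct k-mer species at each depth. k-mers containing non-ACGT bases
#' are skipped.
#'
#' @param reads A `DNAStringSet`/character vector of reads, or a path to a
#'   FASTQ/FASTA file.
#' @param k Odd k-mer size (default 17; even k would make canonicalisation
#'   ambiguous for palindromes).
#' @return An object of class `kmer_histogram`: tibble `depth`, `species`
#'   sorted by depth, with attributes `k` and `total_kmers`.
#' @export
kmer_histogram <- function(reads, k = 17L) {
  if (k %% 2 == 0) abort("k must be odd (canonical ambiguity for even k)")
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  }
  res <- cpp_kmer_census(unname(as.character(reads)), as.integer(k))
  hist <- tibble(depth = as.integer(res$depth), species = res$species) |>
    arrange(.data$depth)
  structure(hist, class = c("kmer_histogram", class(tibble())),
            k = as.integer(k),
            total_kmers = sum(hist$depth * hist$species))
}

# error threshold: depth of the first local minimum of the species counts,
# i.e. where the error-tail decline from depth 1 first bottoms out
error_threshold <- function(hist) {
  depth_max <- max(hist$depth)
  full <- rep(0, depth_max)
  full[hist$depth] <- hist$species
  if (depth_max < 3) {
    abort("no local minimum in the k-mer histogram; sequencing too shallow")
  }
  i <- 2
  while (i < depth_max && full[i] < full[i - 1]) i <- i + 1
  if (i == depth_max && full[i] < full[i - 1]) {
    abort("no local minimum in the k-mer histogram; sequencing too shallow")
  }
  i - 1
}

# homozygous peak depth above the error threshold, with a check that the
# detected maximum is not the heterozygous peak at half depth: when another
# local concentration of species sits near twice the detected depth with
# comparable mass, the doubled depth is taken instead.
homozygous_peak <- function(hist, threshold) {
  above <- hist[hist$depth > threshold, ]
  if (!nrow(above)) abort("no k-mer species above the error threshold")
  peak <- above$depth[which.max(above$species)]
  dbl <- above[above$depth >= round(1.8 * peak) &
                 above$depth <= round(2.2 * peak), ]
  if (nrow(dbl)) {
    sp_dbl <- max(dbl$species)
    if (sp_dbl >= 0.5 * max(above$species)) {
      peak <- dbl$depth[which.max(dbl$species)]
    }
  }
  peak
}

#' Genome size from a k-mer histogram
#'
#' Classic peak method: k-mers at depths at or below the error threshold
#' (the first local minimum of species counts) are discarded as sequencing
#' errors; the genome size is the retained k-mer volume divided by the
#' homozygous peak depth.
#'
#' @param hist A [kmer_histogram()].
#' @return A one-row tibble: `genome_size_bp`, `peak_depth`,
#'   `error_threshold`, `total_kmers` (retained volume).
#' @export
estimate_genome_size <- function(hist) {
  thr <- error_threshold(hist)
  peak <- homozygous_peak(hist, thr)
  retained <- hist[hist$depth > thr, ]
  total <- sum(retained$depth * retained$species)
  tibble(genome_size_bp = total / peak, peak_depth = peak,
         error_threshold = thr, total_kmers = total)
}

#' Heterozygosity as the percentage of heterozygous k-mer species
#'
#' In a diploid read set, heterozygous k-mers form a peak near half the
#' homozygous depth. The statistic is the percentage of retained k-mer
#' species falling in the heterozygous-peak window (depths within
#' `window` times the homozygous peak depth).
#'
#' @param hist A [kmer_histogram()].
#' @param window Depth window as fractions of the homozygous peak
#'   (default `c(0.3, 0.7)`).
#' @return A one-row tibble: `het_pct` (percentage of retained species in
#'   the window), `het_species`, `retained_species`, `peak_depth`. When no
#'   heterozygous peak is resolvable the percentage is 0 with a warning.
#' @export
estimate_heterozygosity <- function(hist, window = c(0.3, 0.7)) {
  thr <- error_threshold(hist)
  peak <- homozygous_peak(hist, thr)
  retained <- hist[hist$depth > thr, ]
  lo <- window[1] * peak; hi <- window[2] * peak
  het <- retained[retained$depth >= lo & retained$depth <= hi, ]
  if (!nrow(het) || lo <= thr) {
    warn("no resolvable heterozygous peak; returning 0")
    return(tibble(het_pct = 0, het_species = 0,
                  retained_species = sum(retained$species),
                  peak_depth = peak))
  }
  tibble(het_pct = 100 * sum(het$species) / sum(retained$species),
         het_species = sum(het$species),
         retained_species = sum(retained$species),
         peak_depth = peak)
}
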