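# Nei-Gojobori (1986) synonymous/nonsynonymous divergence, Ks-based WGD
# binning and dating, Ks-mixture peak finding, and LTR pair dating.

the_codon_tables <- new.env(parent = emptyenv())

# Degeneracy tables for the standard genetic code.
# Site counting: at each codon position the synonymous fraction is the
# number of the 3 possible single-base changes that preserve the amino acid
# (changes creating a stop codon are never synonymous), divided by 3; so
# S + N = 3 per codon by construction.
# Difference counting: all minimal substitution pathways between two codons
# are enumerated with equal weight; pathways passing through a stop codon
# are excluded (if every pathway is blocked, all are used with stop steps
# counted as nonsynonymous).
codon_tables <- function() {
  if (!is.null(the_codon_tables$tabs)) return(the_codon_tables$tabs)
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- sort(codons)
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  names(aa) <- codons
  is_stop <- aa == "*"

  syn_sites <- setNames(rep(NA_real_, 64), codons)
  syn_alts <- setNames(vector("list", 64), codons)
  for (cdn in codons[!is_stop]) {
    s <- 0
    alts <- vector("list", 3)
    for (pos in 1:3) {
      ref <- substr(cdn, pos, pos)
      alt_ok <- character()
      for (b in setdiff(bases, ref)) {
        mut <- cdn
        substr(mut, pos, pos) <- b
        if (!is_stop[[mut]] && aa[[mut]] == aa[[cdn]]) {
          s <- s + 1 / 3
          alt_ok <- c(alt_ok, b)
        }
      }
      alts[[pos]] <- alt_ok
    }
    syn_sites[[cdn]] <- s
    syn_alts[[cdn]] <- alts
  }

  path_counts <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    d <- length(pos)
    if (d == 0) return(c(sd = 0, nd = 0))
    perms <- list(seq_len(d))
    if (d > 1) {
      perms <- lapply(asplit(permutations_of(d), 1), function(p) pos[p])
    } else {
      perms <- list(pos)
    }
    step_counts <- function(order_pos, allow_stop) {
      cur <- c1
      sd <- 0; nd <- 0
      for (p in order_pos) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (is_stop[[nxt]] && nxt != c2 && !allow_stop) return(NULL)
        if (!is_stop[[cur]] && !is_stop[[nxt]] && aa[[cur]] == aa[[nxt]]) {
          sd <- sd + 1
        } else {
          nd <- nd + 1
        }
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    }
    res <- purrr::compact(lapply(perms, step_counts, allow_stop = FALSE))
    if (!length(res)) res <- lapply(perms, step_counts, allow_stop = TRUE)
    mat <- do.call(rbind, res)
    colMeans(mat)
  }

  sense <- codons[!is_stop]
  sd_tab <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  nd_tab <- sd_tab
  for (c1 in sense) {
    for (c2 in sense) {
      pc <- path_counts(c1, c2)
      sd_tab[c1, c2] <- pc[["sd"]]
      nd_tab[c1, c2] <- pc[["nd"]]
    }
  }
  the_codon_tables$tabs <- list(
    codons = codons, aa = aa, is_stop = is_stop,
    syn_sites = syn_sites, syn_alts = syn_alts,
    sd = sd_tab, nd = nd_tab
  )
  the_codon_tables$tabs
}

# all permutations of 1..n as a matrix (n <= 3 needed here)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

jc_correct <- function(p) -3 / 4 * log(1 - 4 / 3 * p)

#' Nei-Gojobori (1986) synonymous and nonsynonymous divergence
#'
#' Computes Ks and Ka for codon-aligned coding sequence pairs using the
#' classical counting method: synonymous site fractions per codon averaged
#' over the two sequences, pathway-averaged difference counting with
#' stop-codon pathways excluded, and Jukes-Cantor multiple-hit correction.
#'
#' @param seq1,seq2 Character vectors of equal-length, codon-aligned
#'   nucleotide sequences (lengths divisible by 3). Codons containing gaps
#'   (`-`) or ambiguous bases in either sequence are skipped pairwise. A
#'   shared terminal stop codon is dropped; an internal stop is a hard error
#'   naming the codon index.
#' @param pair_id Optional identifiers, recycled to the number of pairs.
#' @return A tibble with one row per pair: `pair_id`, `codons` (compared),
#'   `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`, `saturated`. `Ks` (or
#'   `Ka`) is `NA` with `saturated = TRUE` when the observed proportion
#'   reaches the Jukes-Cantor limit of 3/4.
#' @examples
#' a <- paste(rep("TTT", 10), collapse = "")
#' b <- sub("TTT$", "TTC", a)
#' ng86_ks(a, b)
#' @export
ng86_ks <- function(seq1, seq2, pair_id = NULL) {
  stopifnot(length(seq1) == length(seq2))
  if (is.null(pair_id)) pair_id <- paste0("pair", seq_along(seq1))
  pair_id <- rep_len(as.character(pair_id), length(seq1))
  tabs <- codon_tables()
  rows <- purrr::pmap(list(seq1, seq2, pair_id), function(s1, s2, id) {
    s1 <- toupper(s1); s2 <- toupper(s2)
    if (nchar(s1) != nchar(s2)) {
      abort(sprintf("pair %s: sequences differ in length", id))
    }
    if (nchar(s1) %% 3 != 0) {
      abort(sprintf("pair %s: length not divisible by 3", id))
    }
    n_cod <- nchar(s1) %/% 3
    starts <- 3L * (seq_len(n_cod) - 1L) + 1L
    c1 <- substring(s1, starts, starts + 2L)
    c2 <- substring(s2, starts, starts + 2L)
    ok <- c1 %in% tabs$codons & c2 %in% tabs$codons
    c1 <- c1[ok]; c2 <- c2[ok]
    idx <- which(ok)
    # shared terminal stop codons are not compared
    if (length(c1) && idx[length(idx)] == n_cod &&
        tabs$is_stop[[c1[length(c1)]]] && tabs$is_stop[[c2[length(c2)]]]) {
      c1 <- c1[-length(c1)]; c2 <- c2[-length(c2)]; idx <- idx[-length(idx)]
    }
    stop1 <- tabs$is_stop[c1]; stop2 <- tabs$is_stop[c2]
    if (any(stop1) || any(stop2)) {
      bad <- idx[which(stop1 | stop2)[1]]
      abort(sprintf("pair %s: internal stop codon at codon %d", id, bad))
    }
    L <- length(c1)
    if (L == 0) {
      return(tibble(pair_id = id, codons = 0L, S = NA_real_, N = NA_real_,
                    Sd = NA_real_, Nd = NA_real_, pS = NA_real_,
                    pN = NA_real_, Ks = NA_real_, Ka = NA_real_,
                    saturated = NA))
    }
    S <- (sum(tabs$syn_sites[c1]) + sum(tabs$syn_sites[c2])) / 2
    N <- 3 * L - S
    ij <- cbind(match(c1, tabs$codons), match(c2, tabs$codons))
    Sd <- sum(tabs$sd[ij])
    Nd <- sum(tabs$nd[ij])
    pS <- Sd / S
    pN <- Nd / N
    sat_s <- pS >= 3 / 4
    sat_n <- pN >= 3 / 4
    tibble(pair_id = id, codons = L, S = S, N = N, Sd = Sd, Nd = Nd,
           pS = pS, pN = pN,
           Ks = if (sat_s) NA_real_ else jc_correct(pS),
           Ka = if (sat_n) NA_real_ else jc_correct(pN),
           saturated = sat_s || sat_n)
  })
  bind_rows(rows)
}

#' Assign Ks values to whole-genome-duplication bins
#'
#' Splits synonymous divergences of paralog pairs into the two
#' kiwifruit-lineage duplication events by the conventional Ks breakpoints:
#' the younger Ad-alpha event at Ks in (0, 0.335] and the older Ad-beta
#' event at Ks in (0.335, 1]. Ks of exactly 0 (likely allelic or tandem
#' artifacts) and Ks above the upper bound are left unassigned.
#'
#' @param ks Numeric vector of Ks values (must be non-negative).
#' @param bounds Increasing breakpoints, default `c(0.335, 1)`.
#' @return A character vector of bins: `"Ad-alpha"`, `"Ad-beta"`,
#'   `"unassigned"`. `NA` Ks yields `NA`.
#' @export
classify_wgd <- function(ks, bounds = c(0.335, 1)) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  if (any(ks < 0, na.rm = TRUE)) abort("negative Ks is not allowed")
  case_when(
    is.na(ks) ~ NA_character_,
    ks == 0 ~ "unassigned",
    ks <= bounds[1] ~ "Ad-alpha",
    ks <= bounds[2] ~ "Ad-beta",
    TRUE ~ "unassigned"
  )
}

#' Convert synonymous divergence to an age
#'
#' Applies the molecular clock `age = Ks / (2 * rate)`, with the asterid
#' synonymous substitution rate as default.
#'
#' @param ks Non-negative Ks value(s).
#' @param rate Synonymous substitutions per site per year (default
#'   `8.25e-9`).
#' @return Age(s) in Mya (millions of years).
#' @examples
#' ks_to_age(0.165) # 10 Mya
#' @export
ks_to_age <- function(ks, rate = 8.25e-9) {
  if (any(rate <= 0)) abort("rate must be positive")
  if (any(ks < 0, na.rm = TRUE)) abort("negative Ks is not allowed")
  ks / (2 * rate) / 1e6
}

#' Find modes of a Ks distribution
#'
#' Gaussian kernel density over the interval `[from, to]` evaluated on a
#' fixed grid; modes are the local maxima of the density, reported tallest
#' first. Used to locate whole-genome-duplication peaks in paralog Ks
#' distributions.
#'
#' @param ks Numeric vector of at least 30 Ks values.
#' @param bandwidth Gaussian kernel standard deviation in Ks units
#'   (default 0.03).
#' @param from,to Evaluation interval (default `[0, 3]`).
#' @param grid_step Grid resolution in Ks units (default 0.001).
#' @param min_height Modes below this fraction of the tallest density value
#'   are discarded as numerical ripple in flat tails (default 0.01).
#' @return An object of class `ks_peaks`: a list with `peaks` (tibble of
#'   `mode`, `density`, sorted by height), `density` (the full grid), and
#'   the call parameters. Supports [tidy()], [glance()], and [autoplot()].
#' @export
ks_distribution_peaks <- function(ks, bandwidth = 0.03, from = 0, to = 3,
                                  grid_step = 0.001, min_height = 0.01) {
  ks <- ks[!is.na(ks)]
  if (length(ks) < 30) abort("at least 30 Ks values are required")
  n_grid <- round((to - from) / grid_step) + 1
  d <- stats::density(ks, bw = bandwidth, from = from, to = to, n = n_grid)
  y <- d$y
  i <- 2:(length(y) - 1)
  is_peak <- y[i] > y[i - 1] & y[i] >= y[i + 1] & y[i] > min_height * max(y)
  modes <- tibble(mode = d$x[i][is_peak], density = y[i][is_peak]) |>
    arrange(desc(.data$density))
  structure(
    list(peaks = modes,
         density = tibble(ks = d$x, density = y),
         n = length(ks), bandwidth = bandwidth),
    class = "ks_peaks"
  )
}

#' @export
print.ks_peaks <- function(x, ...) {
  cat(sprintf("Ks density (n = %d, bw = %g): %d mode(s)\n",
              x$n, x$bandwidth, nrow(x$peaks)))
  print(x$peaks)
  invisible(x)
}

#' Divergence between the two LTRs of a retroelement
#'
#' Globally aligns the 5' and 3' long terminal repeats (free end gaps),
#' drops gapped columns, and computes a per-site substitution distance.
#' The default is the Kimura two-parameter distance; Jukes-Cantor and the
#' raw proportion of differences are available since the choice of
#' correction is conventional.
#'
#' @param ltr5,ltr3 Character vectors of LTR sequences (recycled pairwise).
#' @param method `"k2p"` (default), `"jc"`, or `"raw"`.
#' @param element_id Optional identifiers.
#' @return A tibble with one row per element: `element_id`, `sites`
#'   (ungapped columns), `transitions`, `transversions`, `P`, `Q`, `K`,
#'   `saturated`. `K` is `NA` with `saturated = TRUE` when the distance
#'   formula's logarithm argument is non-positive.
#' @export
ltr_divergence <- function(ltr5, ltr3, method = c("k2p", "jc", "raw"),
                           element_id = NULL) {
  method <- match.arg(method)
  stopifnot(length(ltr5) == length(ltr3))
  if (is.null(element_id)) element_id <- paste0("ltr", seq_along(ltr5))
  rows <- purrr::pmap(list(ltr5, ltr3, as.character(element_id)),
                      function(a, b, id) {
    a <- toupper(a); b <- toupper(b)
    if (nchar(a) == nchar(b) && a == b) {
      return(tibble(element_id = id, sites = nchar(a), transitions = 0L,
                    transversions = 0L, P = 0, Q = 0, K = 0,
                    saturated = FALSE))
    }
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = FALSE),
      gapOpening = 5, gapExtension = 2)
    x <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    y <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    keep <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
    x <- x[keep]; y <- y[keep]
    n <- length(x)
    if (n == 0) {
      # too diverged to align at all: report as saturated
      warn(sprintf("element %s: no aligned ungapped columns", id))
      return(tibble(element_id = id, sites = 0L, transitions = NA_integer_,
                    transversions = NA_integer_, P = NA_real_, Q = NA_real_,
                    K = NA_real_, saturated = TRUE))
    }
    diff <- x != y
    purine <- c("A", "G")
    ts <- sum(diff & (x %in% purine) == (y %in% purine))
    tv <- sum(diff) - ts
    P <- ts / n; Q <- tv / n
    K <- NA_real_; sat <- FALSE
    if (method == "raw") {
      K <- P + Q
    } else if (method == "jc") {
      p <- P + Q
      if (p >= 3 / 4) sat <- TRUE else K <- jc_correct(p)
    } else {
      w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
      if (w1 <= 0 || w2 <= 0) sat <- TRUE
      else K <- -0.5 * log(w1) - 0.25 * log(w2)
    }
    tibble(element_id = id, sites = n, transitions = as.integer(ts),
           transversions = as.integer(tv), P = P, Q = Q, K = K,
           saturated = sat)
  })
  bind_rows(rows)
}

#' LTR insertion time from LTR-pair divergence
#'
#' The two LTRs of a retroelement are identical at insertion; their
#' divergence `K` converts to an insertion age via `t = K / (2 r)`.
#'
#' @param K Per-site substitution divergence between the LTR pair.
#' @param r Nucleotide substitution rate per site per year (default `1e-8`).
#' @return Insertion time(s) in years.
#' @examples
#' ltr_insertion_time(0.02) # 1 My
#' @export
ltr_insertion_time <- function(K, r = 1e-8) {
  if (any(r <= 0)) abort("substitution rate r must be positive")
  if (any(K < 0, na.rm = TRUE)) abort("negative K is not allowed")
  K / (2 * r)
}

#' Summarise gene-pair Ks per syntenic block
#'
#' @param ks_tbl A tibble with a `Ks` column and a block identifier column.
#' @param by Name of the block identifier column.
#' @param stat `"median"` (default) or `"mean"`.
#' @return A tibble of one Ks summary per block.
#' @export
block_ks <- function(ks_tbl, by = "block_id", stat = c("median", "mean")) {
  stat <- match.arg(stat)
  fun <- if (stat == "median") stats::median else mean
  ks_tbl |>
    group_by(.data[[by]]) |>
    summarise(n_pairs = dplyr::n(), Ks = fun(.data$Ks, na.rm = TRUE),
              .groups = "drop")
}
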