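test_that("window tiling follows the no-partial-window rule", {
  g <- Biostrings::DNAStringSet(c(c1 = paste(rep("A", 1200), collapse = "")))
  w <- make_windows(g)
  expect_equal(nrow(w), 8)
  expect_equal(w$start, seq(0L, 700L, by = 100L))
  expect_true(all(w$end - w$start == 500L))

  g1 <- Biostrings::DNAStringSet(c(c1 = paste(rep("A", 500), collapse = "")))
  expect_equal(nrow(make_windows(g1)), 1)

  # 560 bp: one window, tail bases unclassified
  g2 <- Biostrings::DNAStringSet(c(c1 = paste(rep("A", 560), collapse = "")))
  w2 <- make_windows(g2)
  expect_equal(nrow(w2), 1)
  expect_equal(w2$end, 500L)

  expect_error(pav_params(window = 100, step = 200), "step")
})

test_that("window classification applies strict thresholds on both branches", {
  base <- tibble::tibble(chrom = "c1", start = 0L, end = 500L, n_frac = 0)
  cl <- function(self, other, aligned = TRUE) {
    classify_windows(dplyr::mutate(base, self_cov = self, other_cov = other,
                                   other_aligned = aligned))$status
  }
  expect_equal(cl(0.95, 0.24), "specific")
  expect_equal(cl(0.95, 0.25), "shared")        # strict <
  expect_equal(cl(0.40, 0, aligned = FALSE), "shared")  # fails self check
  expect_equal(cl(0.90, 0, aligned = FALSE), "specific")
  expect_equal(cl(0.89, 0.1), "shared")

  masked <- classify_windows(dplyr::mutate(base, self_cov = 1, other_cov = 0,
                                           other_aligned = FALSE, n_frac = 0.6))
  expect_equal(masked$status, "masked")

  expect_error(classify_windows(dplyr::mutate(base, self_cov = 1.2,
                                              other_cov = 0)), "\\[0, 1\\]")
})

test_that("classification is monotone in the counterpart-coverage threshold", {
  set.seed(4)
  w <- tibble::tibble(chrom = "c1", start = 100L * (0:199), end = 500L + 100L * (0:199),
                      n_frac = 0, self_cov = runif(200, 0.8, 1),
                      other_cov = runif(200), other_aligned = runif(200) > 0.1)
  spec_at <- function(th) {
    p <- pav_params(min_other_cov = th)
    sum(classify_windows(w, p)$status == "specific")
  }
  counts <- vapply(c(0.1, 0.25, 0.5, 0.9), spec_at, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("merging specific windows equals the boolean-mask union oracle", {
  mk <- function(starts) {
    tibble::tibble(chrom = "c1", start = starts, end = starts + 500L,
                   n_frac = 0, self_cov = 1, other_cov = 0,
                   other_aligned = FALSE, status = "specific")
  }
  m1 <- merge_specific_windows(mk(c(0L, 100L)))
  expect_equal(m1$start, 0L)
  expect_equal(m1$end, 600L)
  m2 <- merge_specific_windows(mk(c(0L, 800L)))
  expect_equal(nrow(m2), 2)

  set.seed(8)
  for (i in 1:25) {
    starts <- sort(sample(0:195, sample(3:60, 1)) * 100L)
    got <- merge_specific_windows(mk(starts))
    want <- oracle_merge_mask(starts, starts + 500L, 20500L)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(sum(got$n_windows), length(starts))
  }
})

test_that("segment summary applies strict length thresholds", {
  seg <- tibble::tibble(chrom = "c1", start = c(0L, 1000L, 10000L),
                        end = c(500L, 1600L, 15200L),
                        length = c(500L, 600L, 5200L),
                        n_windows = c(1L, 2L, 48L))
  rep <- summarize_segments(seg)
  expect_equal(rep$n_segments, 2)       # 500 excluded (strict >)
  expect_equal(rep$total_bp, 5800)
  expect_equal(rep$n_large, 1)

  expect_equal(summarize_segments(seg[0, ])$n_segments, 0)

  seg5k <- dplyr::mutate(seg[3, ], length = 5000L, end = start + 5000L)
  expect_equal(summarize_segments(seg5k)$n_large, 0)  # strict >
})

test_that("the seed mapper recovers planted, absent, and half-present windows", {
  set.seed(21)
  tseq <- paste(sample(c("A", "C", "G", "T"), 60000, TRUE), collapse = "")
  target <- Biostrings::DNAStringSet(c(t1 = tseq))

  # verbatim copy -> coverage 1 at the right locus
  win <- substr(tseq, 10001, 10500)
  h <- map_windows(win, target)
  expect_equal(h$coverage, 1)
  expect_equal(h$tstart, 10000)
  expect_equal(h$tend, 10500)

  # random 500-mer absent from an unrelated target -> no record
  alien <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  expect_equal(nrow(map_windows(alien, target)), 0)

  # half-present window -> coverage about 0.5 (within one seed length)
  half <- paste0(substr(tseq, 20001, 20250),
                 paste(sample(c("A", "C", "G", "T"), 250, TRUE), collapse = ""))
  hh <- map_windows(half, target)
  expect_gt(hh$coverage, 0.5 - 15 / 500 - 0.02)
  expect_lt(hh$coverage, 0.5 + 15 / 500 + 0.02)

  # reverse-complemented window still maps, flagged '-'
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
  hr <- map_windows(rc, target)
  expect_equal(hr$coverage, 1)
  expect_equal(hr$strand, "-")
})

test_that("the PAV machinery is label-equivariant", {
  sim <- tiny_sim(seed = 14, length = 1.5e5, n_genes = 4,
                  pav = tibble::tibble(count = 2, min_size = 600,
                                       max_size = 2000))
  fwd <- pav_scan(sim$genome_a, sim$genome_b)
  rev <- pav_scan(sim$genome_b, sim$genome_a)
  a_fwd <- dplyr::select(dplyr::filter(fwd$segments, genome == "A"), -genome)
  a_rev <- dplyr::select(dplyr::filter(rev$segments, genome == "B"), -genome)
  expect_equal(a_fwd, a_rev)
  b_fwd <- dplyr::select(dplyr::filter(fwd$segments, genome == "B"), -genome)
  b_rev <- dplyr::select(dplyr::filter(rev$segments, genome == "A"), -genome)
  expect_equal(b_fwd, b_rev)
})

test_that("pav_scan recovers planted segments on a small pair", {
  sim <- tiny_sim(seed = 17, length = 2e5, n_genes = 6,
                  pav = tibble::tibble(count = 4, min_size = 800,
                                       max_size = 4000))
  res <- pav_scan(sim$genome_a, sim$genome_b)
  for (g in c("A", "B")) {
    called <- dplyr::filter(res$segments, genome == g)
    truth <- dplyr::filter(sim$truth$pav_segments, genome == g)
    ci <- IRanges::reduce(IRanges::IRanges(called$start + 1L, called$end))
    ti <- IRanges::reduce(IRanges::IRanges(truth$start + 1L, truth$end))
    ov <- sum(IRanges::width(IRanges::intersect(ci, ti)))
    expect_gte(ov / sum(IRanges::width(ti)), 0.9)
    # boundary windows overhang each planted segment by up to
    # window - step bp per side, which dominates at this small scale
    expect_gte(ov / sum(IRanges::width(ci)), 0.85)
  }
  # tidy/glance surface
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(nrow(glance(res)), 2)
})
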