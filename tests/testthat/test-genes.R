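mk_cds <- function(...) {
  rows <- list(...)
  tibble::tibble(
    gene_id = vapply(rows, `[[`, "", 1),
    transcript_id = vapply(rows, `[[`, "", 2),
    chrom = "c1", strand = "+",
    start = as.integer(vapply(rows, `[[`, 0, 3)),
    end = as.integer(vapply(rows, `[[`, 0, 4)))
}

test_that("transcript CDS merging takes the interval union", {
  cds <- mk_cds(list("g1", "t1", 100, 200), list("g1", "t1", 300, 400),
                list("g1", "t2", 150, 250))
  m <- merge_transcript_cds(cds)
  expect_equal(m$start, c(100L, 300L))
  expect_equal(m$end, c(250L, 400L))
  expect_equal(sum(m$end - m$start), 250)

  single <- mk_cds(list("g2", "t1", 10, 40))
  expect_equal(merge_transcript_cds(single)$end, 40L)

  confl <- mk_cds(list("g3", "t1", 0, 10), list("g3", "t2", 0, 10))
  confl$chrom <- c("c1", "c2")
  expect_error(merge_transcript_cds(confl), "conflicting")
})

test_that("CDS merging agrees with the base-set union oracle", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    starts <- sample(0:500, n)
    ends <- starts + sample(10:120, n, replace = TRUE)
    cds <- tibble::tibble(gene_id = "g", transcript_id = paste0("t", seq_len(n)),
                          chrom = "c1", strand = "+",
                          start = as.integer(starts), end = as.integer(ends))
    got <- merge_transcript_cds(cds)
    want <- oracle_base_union(starts, ends)
    expect_equal(got$start, as.integer(want$start))
    expect_equal(got$end, as.integer(want$end))
  }
})

test_that("PAV gene candidacy uses a strict 75% CDS-coverage rule", {
  merged <- tibble::tibble(gene_id = "g1", chrom = "c1", strand = "+",
                           start = 0L, end = 1000L)
  seg <- function(bp) tibble::tibble(chrom = "c1", start = 0L, end = as.integer(bp))
  expect_true(call_pav_genes(merged, seg(760))$candidate)   # 0.76
  expect_false(call_pav_genes(merged, seg(750))$candidate)  # exactly 0.75
  expect_false(call_pav_genes(merged, seg(0)[0, ])$candidate)

  zero <- tibble::tibble(gene_id = "gz", chrom = "c1", strand = "+",
                         start = 5L, end = 5L)
  expect_warning(res <- call_pav_genes(dplyr::bind_rows(merged, zero), seg(760)),
                 "zero CDS")
  expect_equal(res$gene_id, "g1")
})

test_that("read-support filtering rejects strictly above 50% coverage", {
  cand <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
                         cds_length = 1000L, pav_bp = 800L,
                         pav_fraction = 0.8,
                         candidate = c(TRUE, TRUE, TRUE, FALSE))
  cov <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        read_fraction = c(0.51, 0.50, 0.0))
  out <- read_support_filter(cand, cov)
  expect_equal(out$status, c("rejected", "final_pav", "final_pav",
                             "not_candidate"))

  expect_error(read_support_filter(cand, cov[1:2, ]), "g3")
})

test_that("final PAV genes are a subset of candidates, monotone in thresholds", {
  set.seed(9)
  n <- 50
  merged <- tibble::tibble(gene_id = sprintf("g%02d", 1:n), chrom = "c1",
                           strand = "+", start = 1000L * (0:(n - 1)),
                           end = 1000L * (0:(n - 1)) + 500L)
  segs <- tibble::tibble(chrom = "c1",
                         start = merged$start,
                         end = merged$start + as.integer(runif(n, 0, 500)))
  cand_tbl <- function(pav_th) call_pav_genes(merged, segs, threshold = pav_th)
  cov <- tibble::tibble(gene_id = sprintf("g%02d", 1:n),
                        read_fraction = runif(n))
  final_set <- function(pav_th, read_th) {
    calls <- read_support_filter(cand_tbl(pav_th), cov, threshold = read_th)
    calls$gene_id[calls$status == "final_pav"]
  }
  base <- final_set(0.75, 0.5)
  cand <- cand_tbl(0.75)
  expect_true(all(base %in% cand$gene_id[cand$candidate]))
  # raising the PAV threshold or lowering the read threshold never enlarges
  expect_true(all(final_set(0.9, 0.5) %in% base))
  expect_true(all(final_set(0.75, 0.3) %in% base))
})

test_that("taxon presence matrix has one cell per gene-taxon pair", {
  calls <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                          status = c("final_pav", "final_pav", "final_pav"))
  cov <- tibble::tibble(gene_id = c("g1", "g1", "g2"),
                        taxon = c("t1", "t2", "t1"),
                        coverage = c(0.9, 0.1, 0.0))
  pm <- taxon_presence_matrix(calls, cov)
  expect_equal(nrow(pm$cells), 6)  # 3 genes x 2 taxa
  g1 <- dplyr::filter(pm$cells, gene_id == "g1")
  expect_equal(g1$present[g1$taxon == "t1"], TRUE)
  expect_equal(g1$present[g1$taxon == "t2"], FALSE)
  # g2, g3 absent everywhere -> taxon orphans
  expect_equal(pm$summary$frac_present_any, 1 / 3)
  expect_equal(glance(pm)$n_taxa, 2)
})

test_that("genes planted in specific segments are recovered as final PAV", {
  sim <- tiny_sim(seed = 23, length = 3e5, n_genes = 12,
                  pav = tibble::tibble(count = 4, min_size = 2000,
                                       max_size = 6000),
                  pav_gene_fraction = 1)
  res <- pav_scan(sim$genome_a, sim$genome_b)
  segs <- dplyr::filter(res$segments, genome == "A")
  merged <- merge_transcript_cds(sim$genes_a)
  cand <- call_pav_genes(merged, segs)
  reads_b <- simulate_reads(sim$genome_b, 20, 150, 0, seed = 24)
  cov <- cds_read_coverage(merged, reads_b, sim$genome_a)
  calls <- read_support_filter(cand, cov)
  planted <- stats::na.omit(
    sim$truth$pav_segments$gene_id[sim$truth$pav_segments$genome == "A"])
  called <- calls$gene_id[calls$status == "final_pav"]
  expect_true(all(planted %in% called))
  expect_true(all(called %in% planted))  # no shared gene called PAV
})
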