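test_that("simulation is deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 31, ancestor_length = 5e4, n_genes = 3,
                           pav_spec = tibble::tibble(count = 2, min_size = 600,
                                                     max_size = 1500))
  a1 <- simulate_ancestor(cfg)
  a2 <- simulate_ancestor(cfg)
  expect_identical(as.character(a1$genome), as.character(a2$genome))
  expect_identical(a1$genes, a2$genes)

  s1 <- evolve_pair(a1, cfg)
  s2 <- evolve_pair(a2, cfg)
  expect_identical(as.character(s1$genome_a), as.character(s2$genome_a))
  expect_identical(s1$truth$pav_segments, s2$truth$pav_segments)

  r1 <- simulate_reads(s1$genome_a, 5, 100, 0.01, seed = 3)
  r2 <- simulate_reads(s2$genome_a, 5, 100, 0.01, seed = 3)
  expect_identical(as.character(r1), as.character(r2))
})

test_that("ancestor genomes honour GC content and gene validity", {
  cfg <- simulation_config(seed = 32, ancestor_length = 1e6, n_genes = 0,
                           pav_spec = tibble::tibble(count = 0, min_size = 600,
                                                     max_size = 1500))
  anc <- simulate_ancestor(cfg)
  gc <- Biostrings::letterFrequency(anc$genome[[1]], "GC") / 1e6
  expect_lt(abs(gc - 0.37), 0.01)
  expect_equal(nrow(anc$genes), 0)

  cfg2 <- simulation_config(seed = 33, ancestor_length = 1e5, n_genes = 5)
  anc2 <- simulate_ancestor(cfg2)
  cds <- cds_sequence(anc2$genome, anc2$genes)
  expect_length(cds, 5)
  for (s in cds) {
    expect_equal(nchar(s) %% 3, 0)
    expect_equal(substr(s, 1, 3), "ATG")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*.", aa))  # no internal stop
  }
})

test_that("zero rates and empty segment spec reproduce the ancestor", {
  cfg <- simulation_config(seed = 34, ancestor_length = 3e4, n_genes = 2,
                           snp_rate = 0, indel_rate = 0,
                           pav_spec = tibble::tibble(count = 0, min_size = 600,
                                                     max_size = 1500))
  anc <- simulate_ancestor(cfg)
  sim <- evolve_pair(anc, cfg)
  expect_identical(as.character(sim$genome_a), as.character(anc$genome))
  expect_identical(as.character(sim$genome_b), as.character(anc$genome))
  expect_equal(nrow(sim$truth$pav_segments), 0)
  expect_equal(nrow(sim$truth$snps), 0)
})

test_that("planted segment counts and sizes match the spec exactly", {
  sim <- tiny_sim(seed = 35, length = 1e5, n_genes = 0,
                  pav = tibble::tibble(count = 5, min_size = 600,
                                       max_size = 5000))
  tr <- sim$truth$pav_segments
  expect_equal(sum(tr$genome == "A"), 5)
  expect_equal(sum(tr$genome == "B"), 5)
  expect_true(all(tr$length >= 600 & tr$length <= 5000))
  # segment coordinates index real sequence of the right genome
  for (i in seq_len(nrow(tr))) {
    g <- if (tr$genome[i] == "A") sim$genome_a else sim$genome_b
    expect_lte(tr$end[i], Biostrings::width(g)[1])
  }
})

test_that("SNP counts follow the configured binomial rate", {
  sim <- tiny_sim(seed = 36, length = 1e6, n_genes = 0,
                  pav = tibble::tibble(count = 0, min_size = 600,
                                       max_size = 1500))
  n <- nrow(sim$truth$snps)
  expected <- 0.024 * 1e6
  sigma <- sqrt(1e6 * 0.024)  # binomial sd at small rate
  expect_lt(abs(n - expected), 4 * sigma)
})

test_that("genome length is conserved up to signed event sizes", {
  sim <- tiny_sim(seed = 37, length = 2e5, n_genes = 5)
  ev <- sim$truth$events
  for (lab in c("A", "B")) {
    ins <- sum(ev$size[ev$lineage == lab & ev$kind %in% c("ins", "pav")])
    del <- sum(ev$size[ev$lineage == lab & ev$kind == "del"])
    g <- if (lab == "A") sim$genome_a else sim$genome_b
    expect_equal(Biostrings::width(g)[1], 2e5 + ins - del)
  }
})

test_that("planted segment cores are absent from the counterpart genome", {
  sim <- tiny_sim(seed = 38, length = 1e5, n_genes = 0,
                  pav = tibble::tibble(count = 3, min_size = 700,
                                       max_size = 2000))
  tr <- sim$truth$pav_segments
  for (i in seq_len(nrow(tr))) {
    own <- if (tr$genome[i] == "A") sim$genome_a else sim$genome_b
    other <- if (tr$genome[i] == "A") sim$genome_b else sim$genome_a
    mid <- tr$start[i] + floor(tr$length[i] / 2)
    core <- Biostrings::subseq(own[[tr$chrom[i]]], mid - 49L, mid + 50L)
    expect_equal(Biostrings::countPattern(core, own[[tr$chrom[i]]]), 1)
    expect_equal(Biostrings::countPattern(core, other[[tr$chrom[i]]]), 0)
  }
})

test_that("read simulation meets its count, content and coverage contracts", {
  cfg <- simulation_config(seed = 39, ancestor_length = 15e4, n_genes = 0,
                           pav_spec = tibble::tibble(count = 0, min_size = 600,
                                                     max_size = 1500))
  anc <- simulate_ancestor(cfg)
  reads <- simulate_reads(anc$genome, 30, 150, 0, seed = 40)
  expect_equal(length(reads), round(30 * 15e4 / 150))

  # error-free reads are exact substrings
  for (s in as.character(reads[1:20])) {
    expect_equal(Biostrings::countPattern(s, anc$genome[[1]],
                                          max.mismatch = 0) > 0 ||
                 Biostrings::countPattern(Biostrings::reverseComplement(
                   Biostrings::DNAString(s)), anc$genome[[1]]) > 0, TRUE)
  }

  # Poisson(30) zero-class: uncovered fraction below 1e-4
  hits <- map_windows(reads, anc$genome)
  hits <- hits[hits$coverage == 1, ]
  covered <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(hits$tstart + 1L, hits$tend))))
  expect_lt(1 - covered / 15e4, 1e-4)

  expect_error(simulate_reads(anc$genome, 0), "positive")
})

test_that("WGD planting errors on saturated targets and hits requested Ks", {
  cfg <- simulation_config(seed = 41, ancestor_length = 2e5, n_genes = 30,
                           pav_spec = tibble::tibble(count = 0, min_size = 600,
                                                     max_size = 1500))
  anc <- simulate_ancestor(cfg)
  expect_error(plant_wgd(anc$genome, anc$genes,
                         tibble::tibble(n = 1, target_ks = 3.5)), "saturated")

  w0 <- plant_wgd(anc$genome, anc$genes,
                  tibble::tibble(n = 3, target_ks = 0), seed = 42)
  seqs <- cds_sequence(w0$genome, w0$genes)
  expect_identical(unname(seqs[w0$pairs$gene_id]),
                   unname(seqs[w0$pairs$dup_gene_id]))

  w <- plant_wgd(anc$genome, anc$genes,
                 tibble::tibble(n = 20, target_ks = 0.2), seed = 43)
  seqs <- cds_sequence(w$genome, w$genes)
  est <- ng86_ks(seqs[w$pairs$gene_id], seqs[w$pairs$dup_gene_id])
  expect_gt(mean(est$Ks), 0.17)
  expect_lt(mean(est$Ks), 0.23)
})

test_that("LTR planting records exact truth and recoverable divergence", {
  cfg <- simulation_config(seed = 44, ancestor_length = 2e5, n_genes = 0,
                           pav_spec = tibble::tibble(count = 0, min_size = 600,
                                                     max_size = 1500))
  anc <- simulate_ancestor(cfg)
  expect_error(plant_ltrs(anc$genome,
                          tibble::tibble(n = 1, ltr_length = 500,
                                         internal_length = 1000,
                                         target_K = 0.8)), "0.75")

  p0 <- plant_ltrs(anc$genome,
                   tibble::tibble(n = 2, ltr_length = 800,
                                  internal_length = 1500, target_K = 0),
                   seed = 45)
  s <- as.character(p0$genome[[1]])
  el <- p0$elements
  expect_identical(substring(s, el$ltr5_start + 1, el$ltr5_end),
                   substring(s, el$ltr3_start + 1, el$ltr3_end))
  expect_equal(el$true_age_years, c(0, 0))

  expect_equal(plant_ltrs(anc$genome,
                          tibble::tibble(n = 1, ltr_length = 500,
                                         internal_length = 500,
                                         target_K = 0.02),
                          seed = 46)$elements$true_age_years, 1e6)

  p <- plant_ltrs(anc$genome,
                  tibble::tibble(n = 20, ltr_length = 1000,
                                 internal_length = 1000, target_K = 0.01),
                  seed = 47)
  s <- as.character(p$genome[[1]])
  el <- p$elements
  div <- ltr_divergence(substring(s, el$ltr5_start + 1, el$ltr5_end),
                        substring(s, el$ltr3_start + 1, el$ltr3_end))
  expect_gt(mean(div$K), 0.008)
  expect_lt(mean(div$K), 0.012)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(snp_rate = 1.2), "rates")
  expect_error(simulation_config(ancestor_length = 5e3, n_genes = 2), "10 kb")
  expect_error(simulation_config(indel_size_range = c(10, 200)), "100")
  expect_error(
    simulation_config(pav_spec = tibble::tibble(count = 1, min_size = 0,
                                                max_size = 10)), "pav_spec")
})
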