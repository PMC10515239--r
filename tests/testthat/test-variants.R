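test_that("one-to-one chaining keeps best records and forbids reuse", {
  # self-alignment style: one full-length record is kept untouched
  self <- tibble::tibble(qchrom = "c1", qstart = 0L, qend = 1000L,
                         tchrom = "c1", tstart = 0L, tend = 1000L,
                         strand = "+", matches = 1000L)
  expect_equal(nrow(chain_one_to_one(self)), 1)

  # two records compete for the same target span: higher matches wins
  comp <- tibble::tibble(
    qchrom = c("c1", "c2"), qstart = c(0L, 0L), qend = c(900L, 400L),
    tchrom = "t1", tstart = c(100L, 200L), tend = c(1000L, 600L),
    strand = "+", matches = c(900L, 400L))
  kept <- chain_one_to_one(comp)
  expect_equal(kept$matches, 900L)

  # property: no query or target base in two kept records
  set.seed(12)
  for (i in 1:15) {
    n <- sample(5:20, 1)
    s <- sample(0:5000, n)
    rec <- tibble::tibble(
      qchrom = sample(c("q1", "q2"), n, TRUE), qstart = s,
      qend = s + sample(100:800, n, TRUE),
      tchrom = sample(c("t1", "t2"), n, TRUE),
      tstart = sample(0:5000, n),
      strand = "+", matches = sample(50:800, n, TRUE))
    rec$tend <- rec$tstart + (rec$qend - rec$qstart)
    kept <- chain_one_to_one(rec)
    for (side in list(c("qchrom", "qstart", "qend"),
                      c("tchrom", "tstart", "tend"))) {
      by_chrom <- split(kept, kept[[side[1]]])
      for (k in by_chrom) {
        ir <- IRanges::IRanges(k[[side[2]]] + 1L, k[[side[3]]])
        expect_equal(sum(IRanges::width(IRanges::reduce(ir))),
                     sum(IRanges::width(ir)))
      }
    }
  }
})

test_that("block variant calling separates SNPs, small and large indels", {
  # construct query/target with 2 SNPs, a 3-bp insertion, a 120-bp deletion
  set.seed(13)
  left <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  mid <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  big <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  tv <- strsplit(paste0(left, mid), "")[[1]]
  qv <- tv
  qv[50] <- setdiff(c("A", "C", "G", "T"), qv[50])[1]
  qv[200] <- setdiff(c("A", "C", "G", "T"), qv[200])[1]
  q <- paste0(paste(qv[1:300], collapse = ""), "TTT",
              paste(qv[301:600], collapse = ""))
  t <- paste0(left, mid, big)
  qg <- Biostrings::DNAStringSet(c(q1 = q))
  tg <- Biostrings::DNAStringSet(c(t1 = t))
  blocks <- tibble::tibble(qchrom = "q1", qstart = 0L, qend = nchar(q),
                           tchrom = "t1", tstart = 0L, tend = nchar(t),
                           strand = "+", cigar = "300M3I300M120D")
  calls <- call_block_variants(blocks, qg, tg)
  expect_equal(calls$n_snps, 2)
  expect_equal(calls$n_indels, 1)     # the 3-bp insertion
  expect_equal(calls$n_excluded, 1)   # the 120-bp deletion
  expect_equal(calls$aligned_bp, 600)
  snps <- dplyr::filter(calls$variants, kind == "SNP")
  expect_equal(snps$qpos, c(49L, 199L))

  # identical sequences: nothing called
  id_blocks <- tibble::tibble(qchrom = "t1", qstart = 0L, qend = nchar(t),
                              tchrom = "t1", tstart = 0L, tend = nchar(t),
                              strand = "+", cigar = paste0(nchar(t), "M"))
  none <- call_block_variants(id_blocks, tg, tg)
  expect_equal(none$n_snps + none$n_indels, 0)

  expect_error(call_block_variants(dplyr::mutate(blocks, cigar = NA), qg, tg),
               "CIGAR")
})

test_that("synthetic truth is recovered exactly on planted blocks", {
  sim <- tiny_sim(seed = 51, length = 1.5e5, n_genes = 5)
  calls <- call_block_variants(truth_alignment(sim), sim$genome_a,
                               sim$genome_b)
  expect_equal(calls$n_snps, nrow(sim$truth$snps))
  expect_equal(calls$n_indels, nrow(sim$truth$indels))
})

test_that("variant densities are counts per aligned kilobase", {
  v <- tibble::tibble(kind = c(rep("SNP", 24), rep("indel", 6)),
                      retained = TRUE)
  d <- variant_density(v, aligned_bp = 1000)
  expect_equal(d$snps_per_kb, 24)
  expect_equal(d$indels_per_kb, 6)
  expect_equal(variant_density(v[0, ], aligned_bp = 500)$snps_per_kb, 0)
  expect_error(variant_density(v, aligned_bp = 0), "positive")
})

test_that("SNP matrix filtering applies strict MAF and missingness rules", {
  # 10 samples; construct dosage rows with known MAF / missingness
  row_of <- function(x) setNames(as.list(x), paste0("s", 1:10))
  m <- tibble::tibble(chrom = "c1", pos = 1:5 * 100L) |>
    dplyr::bind_cols(dplyr::bind_rows(
      row_of(c(1, rep(0, 9))),              # MAF 0.05 exactly -> removed
      row_of(c(1, 1, rep(0, 8))),           # MAF 0.10 -> kept
      row_of(c(2, 1, rep(0, 7), NA)),       # missing 0.1, MAF 0.15/0.167 kept
      row_of(c(1, 0, NA, NA, 0, 0, 0, 0, 0, 0)),  # missing 0.2 -> removed
      row_of(c(rep(NA, 10)))                # all missing -> removed + warning
    ))
  expect_warning(f <- filter_snp_matrix(m), "all calls missing")
  expect_equal(f$pos, c(200L, 300L))

  # MAF 0.02 removed (below the 5% bound)
  m25 <- tibble::tibble(chrom = "c1", pos = 1L) |>
    dplyr::bind_cols(tibble::as_tibble(setNames(as.list(c(1, rep(0, 24))),
                                                paste0("s", 1:25))))
  expect_equal(nrow(filter_snp_matrix(m25)), 0)  # MAF 0.02 < 0.05

  # idempotence
  expect_warning(f1 <- filter_snp_matrix(m))
  expect_identical(filter_snp_matrix(f1), f1)
})

test_that("site thinning keeps every stride-th site from the offset", {
  m <- tibble::tibble(chrom = "c1", pos = 1:74 * 10L)
  t1 <- thin_sites(m, 37)
  expect_equal(nrow(t1), 2)
  expect_equal(t1$pos, c(10L, 380L))  # indices 0 and 37

  expect_identical(thin_sites(m, 1), m)
  expect_error(thin_sites(m, 0), "stride")

  # thinning commutes with per-chromosome splitting under global indexing
  m2 <- tibble::tibble(chrom = rep(c("c1", "c2"), each = 40),
                       pos = rep(1:40 * 5L, 2))
  th <- thin_sites(m2, 7)
  expect_equal(nrow(th), ceiling(80 / 7))
})
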