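# Seeded synthetic-genome generator: diverged genome pairs with planted
# species-specific segments, SNPs, small indels, duplicated gene blocks at a
# target Ks, LTR elements at a target divergence, and uniform short reads.
# Every planted event is recorded in a truth set for recovery testing.

BASES <- c("A", "C", "G", "T")

# run expr under a temporary RNG state
with_seed_ <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

# deterministic stage-local substream below 2^31
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  (as.numeric(seed) * 7919 + h * 104729) %% 2147483647
}

random_dna <- function(n, gc = 0.37) {
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(BASES, n, replace = TRUE, prob = prob)
}

sense_codons <- function() {
  tabs <- codon_tables()
  tabs$codons[!tabs$is_stop]
}

# random ORF: ATG + sense codons + stop, length 3*n_codons
random_orf <- function(n_codons) {
  stopifnot(n_codons >= 3)
  body <- sample(setdiff(sense_codons(), "ATG"), n_codons - 2, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

#' Configuration for the synthetic genome pair generator
#'
#' Defaults emulate the divergence observed between the two kiwifruit
#' assemblies the pipeline targets: about 24 SNPs and 6 small indels per
#' aligned kilobase (split evenly over the two lineages), planted
#' lineage-specific insertions of 0.6-10 kb, multi-exon protein-coding
#' genes at genomic GC 0.37, and 30x 150-bp single-end reads.
#'
#' @param seed Integer seed; a fixed seed makes all downstream simulation
#'   output byte-identical.
#' @param ancestor_length Ancestral genome length in bp.
#' @param n_genes Number of multi-exon genes placed in the ancestor.
#' @param gc GC content of intergenic sequence.
#' @param snp_rate Expected pairwise substitutions per bp between the two
#'   descendant genomes (each lineage receives half).
#' @param indel_rate Expected pairwise small-indel events per bp.
#' @param indel_size_range Inclusive bp range of small indel sizes
#'   (must stay below 100).
#' @param pav_spec Tibble with columns `count`, `min_size`, `max_size`:
#'   lineage-specific insertions planted per genome.
#' @param pav_gene_fraction Fraction of planted segments (of sufficient
#'   size) that carry a complete embedded gene.
#' @param read_depth,read_length,read_error Short-read simulation: fold
#'   coverage, read length (bp), per-base substitution error rate.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              ancestor_length = 5e6,
                              n_genes = 200L,
                              gc = 0.37,
                              snp_rate = 0.024,
                              indel_rate = 0.006,
                              indel_size_range = c(1L, 10L),
                              pav_spec = tibble(count = 30L, min_size = 600L,
                                                max_size = 10000L),
                              pav_gene_fraction = 0.5,
                              read_depth = 30,
                              read_length = 150L,
                              read_error = 0.001) {
  rates <- c(snp_rate, indel_rate, read_error)
  if (any(rates < 0) || any(rates >= 1)) abort("rates must lie in [0, 1)")
  if (ancestor_length < 1e4 && n_genes > 0) {
    abort("ancestor_length must be >= 10 kb when genes are requested")
  }
  if (any(indel_size_range < 1) || indel_size_range[2] >= 100) {
    abort("indel sizes must be positive and below 100 bp")
  }
  if (any(pav_spec$min_size <= 0) || any(pav_spec$max_size < pav_spec$min_size)) {
    abort("pav_spec sizes must be positive with min_size <= max_size")
  }
  structure(
    list(seed = as.integer(seed), ancestor_length = as.integer(ancestor_length),
         n_genes = as.integer(n_genes), gc = gc, snp_rate = snp_rate,
         indel_rate = indel_rate,
         indel_size_range = as.integer(indel_size_range),
         pav_spec = as_tibble(pav_spec),
         pav_gene_fraction = pav_gene_fraction,
         read_depth = read_depth, read_length = as.integer(read_length),
         read_error = read_error),
    class = "sim_config"
  )
}

# generate a gene layout (exon/intron structure) as relative 0-based CDS
# intervals within a span, plus the sequence of the span
random_gene_layout <- function(n_codons = NULL, n_exons = NULL) {
  if (is.null(n_codons)) n_codons <- sample(100:400, 1)
  if (is.null(n_exons)) n_exons <- sample(2:6, 1)
  orf <- random_orf(n_codons)
  cds_len <- nchar(orf)
  # composition of cds_len into n_exons parts, each >= 3 bp
  repeat {
    cuts <- sort(sample(3:(cds_len - 3), n_exons - 1))
    if (n_exons == 1 || all(diff(c(0, cuts, cds_len)) >= 3)) break
  }
  exon_lens <- diff(c(0, cuts, cds_len))
  intron_lens <- if (n_exons > 1) sample(80:400, n_exons - 1, replace = TRUE)
                 else integer()
  span <- cds_len + sum(intron_lens)
  seq_v <- random_dna(span)
  cds_rel <- integer(0)
  pos <- 0L
  starts <- integer(n_exons); ends <- integer(n_exons)
  orf_v <- strsplit(orf, "")[[1]]
  orf_off <- 0L
  for (e in seq_len(n_exons)) {
    starts[e] <- pos
    ends[e] <- pos + exon_lens[e]
    seq_v[(pos + 1):(pos + exon_lens[e])] <-
      orf_v[(orf_off + 1):(orf_off + exon_lens[e])]
    orf_off <- orf_off + exon_lens[e]
    pos <- ends[e] + if (e < n_exons) intron_lens[e] else 0L
  }
  list(seq = seq_v, span = span, exon_starts = starts, exon_ends = ends,
       cds_len = cds_len)
}

#' Simulate an ancestral genome with multi-exon genes
#'
#' Draws an i.i.d. background sequence at the configured GC content and
#' places non-overlapping protein-coding genes, each with 2-6 exons and a
#' valid CDS (ATG start, in-frame sense codons, terminal stop).
#'
#' @param config A [simulation_config()].
#' @return A list with `genome` (single-chromosome `DNAStringSet`) and
#'   `genes` (CDS tibble as from [load_gene_models()]).
#' @export
simulate_ancestor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_(stage_seed(config$seed, "ancestor"), {
    L <- config$ancestor_length
    v <- random_dna(L, config$gc)
    genes <- tibble(gene_id = character(), transcript_id = character(),
                    chrom = character(), strand = character(),
                    start = integer(), end = integer())
    if (config$n_genes > 0) {
      placed_start <- integer(0); placed_end <- integer(0)
      rows <- list()
      attempts <- 0L
      i <- 1L
      while (i <= config$n_genes) {
        attempts <- attempts + 1L
        if (attempts > config$n_genes * 60L) {
          abort("could not place genes without overlap; lower n_genes")
        }
        lay <- random_gene_layout()
        if (lay$span + 2 >= L) next
        start0 <- sample.int(L - lay$span - 1L, 1)  # 0-based
        end0 <- start0 + lay$span
        if (any(start0 < placed_end + 200L & end0 + 200L > placed_start)) next
        v[(start0 + 1):end0] <- lay$seq
        gid <- sprintf("g%04d", i)
        rows[[i]] <- tibble(
          gene_id = gid, transcript_id = paste0(gid, ".t1"), chrom = "chr1",
          strand = "+", start = start0 + lay$exon_starts,
          end = start0 + lay$exon_ends
        )
        placed_start <- c(placed_start, start0)
        placed_end <- c(placed_end, end0)
        i <- i + 1L
      }
      genes <- arrange(bind_rows(rows), .data$start)
    }
    genome <- Biostrings::DNAStringSet(setNames(paste(v, collapse = ""), "chr1"))
    list(genome = genome, genes = genes)
  })
}

# uniform integer draw in [lo, hi]
runif_int <- function(n, lo, hi) lo + floor(runif(n) * (hi - lo + 1))

#' Evolve an ancestor into a diverged genome pair with recorded truth
#'
#' Each lineage independently receives substitutions (half the pairwise
#' rate), small indels, and planted lineage-specific insertions per
#' `pav_spec`. Mutational events avoid annotated CDS (so gene models stay
#' translatable) and avoid each other, keeping truth classes disjoint; a
#' configurable fraction of planted segments carries a complete embedded
#' gene. The returned truth set records every event in final coordinates.
#'
#' @param ancestor Output of [simulate_ancestor()].
#' @param config The same [simulation_config()].
#' @return A list of class `sim_pair`: `genome_a`, `genome_b`
#'   (`DNAStringSet`), `genes_a`, `genes_b` (CDS tibbles), and `truth`, a
#'   list of tibbles `pav_segments`, `snps`, `indels`, and the internal
#'   `events` table used to reconstruct the true pairwise alignment.
#' @export
evolve_pair <- function(ancestor, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_(stage_seed(config$seed, "evolve"), {
    v <- strsplit(as.character(ancestor$genome[[1]]), "")[[1]]
    G <- length(v)
    chrom <- names(ancestor$genome)[1]
    genes <- ancestor$genes

    cds_mask <- rep(FALSE, G)
    if (nrow(genes)) {
      for (r in seq_len(nrow(genes))) {
        cds_mask[(genes$start[r] + 1):genes$end[r]] <- TRUE
      }
    }

    # insertion before 1-based position p splits a CDS interval [s0,e0)
    # when s0 + 2 <= p <= e0; build the forbidden-anchor mask
    no_ins <- rep(FALSE, G)
    if (nrow(genes)) {
      for (r in seq_len(nrow(genes))) {
        if (genes$end[r] - genes$start[r] >= 2) {
          no_ins[(genes$start[r] + 2):genes$end[r]] <- TRUE
        }
      }
    }

    # ---- planted lineage-specific segments (exact requested counts) ----
    ps <- config$pav_spec
    pav <- list()
    free_anchor <- which(!no_ins)
    for (lineage in c("A", "B")) {
      for (r in seq_len(nrow(ps))) {
        n_pav <- ps$count[r]
        if (n_pav > 0) {
          sizes <- runif_int(n_pav, ps$min_size[r], ps$max_size[r])
          if (any(sizes >= G)) abort("planted segment larger than genome")
          pav[[length(pav) + 1]] <- tibble(
            lineage = lineage, kind = "pav", anchor = 0L, size = sizes)
        }
      }
    }
    pav <- if (length(pav)) bind_rows(pav) else
      tibble(lineage = character(), kind = character(),
             anchor = integer(), size = integer())
    if (nrow(pav)) {
      pav$anchor <- sort(sample(free_anchor, nrow(pav)))[sample.int(nrow(pav))]
    }
    pav_anchors <- sort(pav$anchor)

    # ---- small-indel background, rejected around CDS and planted sites ----
    cand <- list()
    for (lineage in c("A", "B")) {
      n_ind <- rbinom(1, G, config$indel_rate / 2)
      if (n_ind > 0) {
        cand[[length(cand) + 1]] <- tibble(
          lineage = lineage,
          kind = sample(c("ins", "del"), n_ind, replace = TRUE),
          anchor = sample.int(G, n_ind),
          size = runif_int(n_ind, config$indel_size_range[1],
                           config$indel_size_range[2]))
      }
    }
    indels <- if (length(cand)) bind_rows(cand) else pav[0, ]
    if (nrow(indels)) {
      indels <- arrange(indels, .data$anchor)
      keep <- rep(TRUE, nrow(indels))
      last_end <- 0L
      for (r in seq_len(nrow(indels))) {
        a <- indels$anchor[r]
        is_del <- indels$kind[r] == "del"
        e <- if (is_del) a + indels$size[r] - 1L else a
        # a one-base spacer keeps gap runs of neighbouring events separate
        bad <- a <= last_end + 1L || e > G ||
          (is_del && any(cds_mask[a:e])) ||
          (!is_del && no_ins[a])
        if (!bad && length(pav_anchors)) {
          # forbid containing or abutting a planted anchor
          j <- findInterval(e + 1L, pav_anchors)
          bad <- j >= 1 && pav_anchors[j] >= a
        }
        if (bad) keep[r] <- FALSE else last_end <- e
      }
      indels <- indels[keep, , drop = FALSE]
    }
    events <- arrange(bind_rows(pav, indels), .data$anchor)

    # ---- planted segment content (random DNA, optionally with a gene) ----
    events$seq <- NA_character_
    events$pav_gene <- NA_character_
    events$gene_cds_start <- NA
    pav_rows <- which(events$kind == "pav")
    pav_gene_layouts <- list()
    gidx <- 0L
    for (r in pav_rows) {
      size <- events$size[r]
      content <- random_dna(size)
      if (runif(1) < config$pav_gene_fraction && size >= 1200) {
        # embed a complete gene occupying at most 80% of the segment
        max_span <- floor(size * 0.8)
        lay <- NULL
        for (try in 1:20) {
          n_cod <- sample(100:min(300, floor((max_span - 500) / 3)), 1)
          cand_lay <- random_gene_layout(n_codons = max(100, n_cod))
          if (cand_lay$span <= max_span) { lay <- cand_lay; break }
        }
        if (!is.null(lay)) {
          gidx <- gidx + 1L
          off <- sample.int(size - lay$span, 1)  # 0-based offset in segment
          content[(off + 1):(off + lay$span)] <- lay$seq
          gid <- sprintf("pav%s%03d", events$lineage[r], gidx)
          events$pav_gene[r] <- gid
          events$gene_cds_start[r] <- off
          pav_gene_layouts[[gid]] <- lay
        }
      }
      events$seq[r] <- paste(content, collapse = "")
    }
    ins_rows <- which(events$kind == "ins")
    for (r in ins_rows) {
      events$seq[r] <- paste(random_dna(events$size[r]), collapse = "")
    }

    # ---- SNPs ----
    del_mask <- rep(FALSE, G)
    del_rows <- which(events$kind == "del")
    for (r in del_rows) {
      del_mask[events$anchor[r]:(events$anchor[r] + events$size[r] - 1L)] <- TRUE
    }
    snp_pos_a <- which(runif(G) < config$snp_rate / 2 & !del_mask)
    snp_pos_b <- which(runif(G) < config$snp_rate / 2 & !del_mask)
    snp_pos_b <- setdiff(snp_pos_b, snp_pos_a)
    # vectorised draw of a uniform non-reference base
    alt_mat <- t(vapply(BASES, function(b) setdiff(BASES, b), character(3)))
    alt_of <- function(ref) {
      if (!length(ref)) return(character(0))
      alt_mat[cbind(match(ref, BASES), sample.int(3, length(ref), TRUE))]
    }
    snps <- bind_rows(
      tibble(lineage = "A", anchor = snp_pos_a, ref = v[snp_pos_a],
             alt = alt_of(v[snp_pos_a])),
      tibble(lineage = "B", anchor = snp_pos_b, ref = v[snp_pos_b],
             alt = alt_of(v[snp_pos_b]))
    )

    # ---- build each lineage's final sequence and coordinate lift ----
    build_lineage <- function(lineage) {
      ev <- events[events$lineage == lineage, , drop = FALSE]
      ev <- arrange(ev, .data$anchor)
      sv <- v
      sn <- snps[snps$lineage == lineage, ]
      sv[sn$anchor] <- sn$alt
      big <- paste(sv, collapse = "")
      # assemble pieces around structural events
      piece_start <- 1L
      pieces <- character(0)
      for (r in seq_len(nrow(ev))) {
        a <- ev$anchor[r]
        if (ev$kind[r] == "del") {
          if (a > piece_start) {
            pieces <- c(pieces, substr(big, piece_start, a - 1L))
          }
          piece_start <- a + ev$size[r]
        } else {
          if (a > piece_start) {
            pieces <- c(pieces, substr(big, piece_start, a - 1L))
          }
          pieces <- c(pieces, ev$seq[r])
          piece_start <- a
        }
      }
      pieces <- c(pieces, substr(big, piece_start, G))
      final_seq <- paste(pieces, collapse = "")
      # lift: ancestor 1-based position -> final 1-based position
      delta_at <- ev$anchor
      delta <- ifelse(ev$kind == "del", -ev$size, ev$size)
      lift <- function(pos) {
        if (!nrow(ev)) return(pos)
        i <- findInterval(pos, delta_at)
        shift <- cumsum(delta)
        base <- ifelse(i == 0, 0, shift[pmax(i, 1)])
        # positions inside a deletion have no image; callers avoid them
        pos + base
      }
      list(seq = final_seq, events = ev, lift = lift)
    }
    la <- build_lineage("A")
    lb <- build_lineage("B")

    # lifted gene models (+ genes embedded in planted segments)
    lift_genes <- function(genes, lin) {
      out <- genes
      if (nrow(out)) {
        out$start <- lin$lift(out$start + 1L) - 1L
        out$end <- lin$lift(out$end)
      }
      ev <- lin$events
      extra <- list()
      for (r in which(!is.na(ev$pav_gene))) {
        gid <- ev$pav_gene[r]
        lay <- pav_gene_layouts[[gid]]
        # lift(anchor - 1) is the final 1-based position of the last base
        # before the insertion, i.e. the 0-based start of the segment
        seg_start0 <- lin$lift(ev$anchor[r] - 1L)
        gs <- seg_start0 + ev$gene_cds_start[r]    # 0-based gene start
        extra[[gid]] <- tibble(
          gene_id = gid, transcript_id = paste0(gid, ".t1"),
          chrom = chrom, strand = "+",
          start = gs + lay$exon_starts, end = gs + lay$exon_ends)
      }
      bind_rows(out, bind_rows(extra)) |> arrange(.data$start)
    }
    genes_a <- lift_genes(genes, la)
    genes_b <- lift_genes(genes, lb)

    # truth tables in final coordinates
    truth_pav <- function(lin, label) {
      ev <- lin$events
      rows <- ev[ev$kind == "pav", , drop = FALSE]
      if (!nrow(rows)) {
        return(tibble(genome = character(), chrom = character(),
                      start = integer(), end = integer(), length = integer(),
                      gene_id = character()))
      }
      # lift(a-1) is the final 1-based position of the last base before the
      # insertion, which equals the 0-based start of the inserted segment
      start0 <- lin$lift(rows$anchor - 1L)
      tibble(genome = label, chrom = chrom, start = as.integer(start0),
             end = as.integer(start0 + rows$size),
             length = as.integer(rows$size), gene_id = rows$pav_gene)
    }
    truth_snps <- bind_rows(
      mutate(snps[snps$lineage == "A", ],
             pos = as.integer(la$lift(.data$anchor) - 1L)),
      mutate(snps[snps$lineage == "B", ],
             pos = as.integer(lb$lift(.data$anchor) - 1L))
    ) |>
      mutate(chrom = chrom, anc_pos = .data$anchor - 1L) |>
      select("lineage", "chrom", "anc_pos", "pos", "ref", "alt")
    truth_indels <- events |>
      filter(.data$kind %in% c("ins", "del")) |>
      mutate(chrom = chrom, anc_pos = .data$anchor - 1L) |>
      select("lineage", "kind", "chrom", "anc_pos", "size")

    truth <- list(
      pav_segments = bind_rows(truth_pav(la, "A"), truth_pav(lb, "B")),
      snps = truth_snps,
      indels = truth_indels,
      events = mutate(events, chrom = chrom),
      snp_events = mutate(snps, chrom = chrom)
    )
    structure(
      list(genome_a = Biostrings::DNAStringSet(setNames(la$seq, chrom)),
           genome_b = Biostrings::DNAStringSet(setNames(lb$seq, chrom)),
           genes_a = genes_a, genes_b = genes_b,
           truth = truth, config = config),
      class = "sim_pair"
    )
  })
}

#' True pairwise alignment of a simulated genome pair
#'
#' Reconstructs the exact column-level alignment between the two simulated
#' genomes from the recorded event list, as syntenic blocks split at the
#' planted lineage-specific segments (so every returned block is free of
#' planted presence/absence sequence). Genome A is the query, genome B the
#' target; substitutions fall inside `M` runs, lineage indels become
#' `I`/`D` runs.
#'
#' @param sim A `sim_pair` from [evolve_pair()].
#' @return A tibble of blocks: `qchrom`, `qstart`, `qend`, `tchrom`,
#'   `tstart`, `tend`, `strand`, `matches` (aligned columns), `block_len`,
#'   `cigar`.
#' @export
truth_alignment <- function(sim) {
  stopifnot(inherits(sim, "sim_pair"))
  ev <- sim$truth$events
  chrom <- names(sim$genome_a)[1]
  G <- sim$config$ancestor_length
  ev <- arrange(ev, .data$anchor)
  blocks <- list()
  ops <- character(0); lens <- integer(0)
  qpos <- 0L; tpos <- 0L          # final 0-based positions consumed
  q0 <- 0L; t0 <- 0L              # current block start
  cur <- 1L                       # next ancestor position to emit
  push <- function(op, len) {
    if (len <= 0) return()
    n <- length(ops)
    if (n && ops[n] == op) lens[n] <<- lens[n] + len
    else { ops[n + 1] <<- op; lens[n + 1] <<- len }
  }
  close_block <- function() {
    if (length(ops)) {
      m <- sum(lens[ops == "M"])
      blocks[[length(blocks) + 1]] <<- tibble(
        qchrom = chrom, qstart = q0, qend = qpos,
        tchrom = chrom, tstart = t0, tend = tpos, strand = "+",
        matches = m, block_len = sum(lens),
        cigar = paste0(lens, ops, collapse = ""))
    }
    ops <<- character(0); lens <<- integer(0)
  }
  for (r in seq_len(nrow(ev))) {
    a <- ev$anchor[r]; k <- ev$kind[r]; sz <- ev$size[r]; lin <- ev$lineage[r]
    mlen <- a - cur
    push("M", mlen); qpos <- qpos + mlen; tpos <- tpos + mlen
    if (k == "del") {
      if (lin == "A") { push("D", sz); tpos <- tpos + sz }
      else { push("I", sz); qpos <- qpos + sz }
      cur <- a + sz
    } else if (k == "ins") {
      if (lin == "A") { push("I", sz); qpos <- qpos + sz }
      else { push("D", sz); tpos <- tpos + sz }
      cur <- a
    } else {  # planted segment: split blocks here
      close_block()
      if (lin == "A") qpos <- qpos + sz else tpos <- tpos + sz
      q0 <- qpos; t0 <- tpos
      cur <- a
    }
  }
  push("M", G - cur + 1L)
  qpos <- qpos + (G - cur + 1L); tpos <- tpos + (G - cur + 1L)
  close_block()
  bind_rows(blocks)
}

#' Duplicate gene blocks at a target synonymous divergence
#'
#' Copies blocks containing complete genes to new locations and mutates
#' synonymous sites of each duplicated CDS so that the expected pairwise Ks
#' equals the target: the expected proportion of synonymous differences is
#' set analytically by inverting the Jukes-Cantor correction, then realised
#' as independent synonymous substitutions within per-position codon
#' degeneracy classes.
#'
#' @param genome A `DNAStringSet`.
#' @param genes CDS tibble (as from [load_gene_models()]).
#' @param wgd_spec Tibble with columns `n` (pairs to plant) and `target_ks`;
#'   optional `flank` (bp copied around each gene, default 100).
#' @param seed Integer seed.
#' @return A list: `genome` (with appended duplicate blocks as new
#'   sequences), `genes` (augmented with `*_dup` copies), `pairs` (tibble
#'   `pair_id`, `gene_id`, `dup_gene_id`, `true_ks`).
#' @export
plant_wgd <- function(genome, genes, wgd_spec, seed = 1L) {
  if (any(wgd_spec$target_ks > 3)) {
    abort("target_ks > 3 is saturated and cannot be planted")
  }
  if (!"flank" %in% names(wgd_spec)) wgd_spec$flank <- 100L
  tabs <- codon_tables()
  with_seed_(stage_seed(seed, "wgd"), {
    gene_ids <- unique(genes$gene_id)
    pairs <- list()
    new_seqs <- list()
    new_genes <- list()
    pick_pool <- sample(gene_ids)
    pool_i <- 1L
    bi <- 0L
    for (r in seq_len(nrow(wgd_spec))) {
      for (j in seq_len(wgd_spec$n[r])) {
        if (pool_i > length(pick_pool)) {
          abort("not enough genes to plant the requested duplicate pairs")
        }
        gid <- pick_pool[pool_i]; pool_i <- pool_i + 1L
        g <- genes[genes$gene_id == gid, ]
        g <- g[g$transcript_id == g$transcript_id[1], ]
        chrom_len <- Biostrings::width(genome[g$chrom[1]])
        flank <- wgd_spec$flank[r]
        b_start <- max(0L, min(g$start) - flank)
        b_end <- min(chrom_len, max(g$end) + flank)
        block <- strsplit(as.character(
          Biostrings::subseq(genome[[g$chrom[1]]], b_start + 1L, b_end)),
          "")[[1]]
        rel_start <- g$start - b_start
        rel_end <- g$end - b_start
        cds_pos <- unlist(purrr::map2(rel_start + 1L, rel_end, seq))
        cds <- block[cds_pos]
        mutated <- mutate_synonymous(cds, wgd_spec$target_ks[r], tabs)
        block[cds_pos] <- mutated
        bi <- bi + 1L
        new_chrom <- sprintf("wgd_block%03d", bi)
        new_seqs[[new_chrom]] <- paste(block, collapse = "")
        dup_id <- paste0(gid, "_dup")
        new_genes[[new_chrom]] <- tibble(
          gene_id = dup_id, transcript_id = paste0(dup_id, ".t1"),
          chrom = new_chrom, strand = "+",
          start = rel_start, end = rel_end)
        pairs[[bi]] <- tibble(pair_id = sprintf("wgdpair%03d", bi),
                              gene_id = gid, dup_gene_id = dup_id,
                              true_ks = wgd_spec$target_ks[r])
      }
    }
    genome_out <- c(genome, Biostrings::DNAStringSet(unlist(new_seqs)))
    list(genome = genome_out,
         genes = bind_rows(genes, bind_rows(new_genes)),
         pairs = bind_rows(pairs))
  })
}

# Apply synonymous-only substitutions to a CDS (character vector of bases)
# so that the expected NG86 synonymous-difference proportion matches the
# Jukes-Cantor inverse of target_ks. Positions are marked independently;
# each marked position takes a uniform draw from its synonymous class.
mutate_synonymous <- function(cds, target_ks, tabs = codon_tables()) {
  n_cod <- length(cds) %/% 3
  if (n_cod < 1) return(cds)
  codons <- vapply(seq_len(n_cod),
                   function(i) paste(cds[(3 * i - 2):(3 * i)], collapse = ""),
                   character(1))
  ok <- codons %in% tabs$codons & !tabs$is_stop[codons]
  # degenerate positions: (codon index, position, alternatives)
  deg <- list()
  S <- 0
  for (i in which(ok)) {
    alts <- tabs$syn_alts[[codons[i]]]
    S <- S + tabs$syn_sites[[codons[i]]]
    for (p in 1:3) {
      if (length(alts[[p]])) {
        deg[[length(deg) + 1]] <- list(i = i, p = p, alts = alts[[p]])
      }
    }
  }
  P <- length(deg)
  if (P == 0 || target_ks == 0) return(cds)
  pS <- 3 / 4 * (1 - exp(-4 / 3 * target_ks))
  pi_mark <- min(1, pS * S / P)
  marked <- which(runif(P) < pi_mark)
  for (m in marked) {
    d <- deg[[m]]
    pos <- 3 * (d$i - 1) + d$p
    cds[pos] <- if (length(d$alts) == 1) d$alts else sample(d$alts, 1)
  }
  cds
}

#' Insert LTR retroelements at a target LTR-pair divergence
#'
#' Each element is a long terminal repeat, an internal region, and an
#' identical copy of the repeat; the two repeat copies are then diverged to
#' an expected pairwise per-site substitution distance `target_K`
#' (positions differ independently with the Jukes-Cantor inverse
#' probability). The true insertion age `target_K / (2e-8)` years is
#' recorded.
#'
#' @param genome A `DNAStringSet`.
#' @param ltr_spec Tibble with columns `n`, `ltr_length`, `internal_length`,
#'   `target_K`.
#' @param seed Integer seed.
#' @param r Substitution rate used for the recorded true ages.
#' @return A list: `genome` (with insertions applied) and `elements`, a
#'   tibble of `element_id`, `chrom`, `start`, `end`, `ltr5_start`,
#'   `ltr5_end`, `ltr3_start`, `ltr3_end` (0-based half-open in the updated
#'   genome), `true_K`, `true_age_years`.
#' @export
plant_ltrs <- function(genome, ltr_spec, seed = 1L, r = 1e-8) {
  if (any(ltr_spec$target_K >= 0.75)) {
    abort("target_K >= 0.75 cannot be recovered under Jukes-Cantor")
  }
  with_seed_(stage_seed(seed, "ltr"), {
    chrom <- names(genome)[1]
    seq0 <- as.character(genome[[chrom]])
    G <- nchar(seq0)
    specs <- tidyr::uncount(ltr_spec, .data$n)
    n_el <- nrow(specs)
    el_len <- 2L * specs$ltr_length + specs$internal_length
    if (any(el_len >= G)) abort("element does not fit in genome")
    anchors <- sort(sample.int(G - 1L, n_el) + 1L)  # insert before anchor
    make_el <- function(i) {
      lt <- specs$ltr_length[i]
      base <- random_dna(lt)
      K <- specs$target_K[i]
      # plant the Jukes-Cantor inverse of the target divergence as an exact
      # count of differing sites so the realised K is the recorded truth
      p_diff <- 3 / 4 * (1 - exp(-4 / 3 * K))
      l5 <- base; l3 <- base
      marked <- sample.int(lt, round(p_diff * lt))
      for (m in marked) {
        newb <- sample(setdiff(BASES, base[m]), 1)
        if (runif(1) < 0.5) l5[m] <- newb else l3[m] <- newb
      }
      internal <- random_dna(specs$internal_length[i])
      list(l5 = paste(l5, collapse = ""), l3 = paste(l3, collapse = ""),
           internal = paste(internal, collapse = ""))
    }
    els <- lapply(seq_len(n_el), make_el)
    pieces <- character(0)
    prev <- 1L
    for (i in seq_len(n_el)) {
      pieces <- c(pieces, substr(seq0, prev, anchors[i] - 1L),
                  els[[i]]$l5, els[[i]]$internal, els[[i]]$l3)
      prev <- anchors[i]
    }
    pieces <- c(pieces, substr(seq0, prev, G))
    final <- paste(pieces, collapse = "")
    offset <- cumsum(c(0, el_len))[seq_len(n_el)]
    start0 <- anchors - 1L + offset
    lt <- specs$ltr_length
    elements <- tibble(
      element_id = sprintf("ltr%03d", seq_len(n_el)),
      chrom = chrom,
      start = as.integer(start0), end = as.integer(start0 + el_len),
      ltr5_start = as.integer(start0), ltr5_end = as.integer(start0 + lt),
      ltr3_start = as.integer(start0 + el_len - lt),
      ltr3_end = as.integer(start0 + el_len),
      true_K = specs$target_K,
      true_age_years = specs$target_K / (2 * r)
    )
    seqs <- as.character(genome)
    seqs[chrom] <- final
    list(genome = Biostrings::DNAStringSet(seqs), elements = elements)
  })
}

#' Simulate uniform single-end short reads
#'
#' Fixed-length reads with uniform start positions and independent per-base
#' substitution errors. The read count is
#' `round(depth * genome_length / read_length)`.
#'
#' @param genome A `DNAStringSet`.
#' @param depth Fold coverage (> 0).
#' @param read_length Read length in bp (shorter than every sequence).
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @return A named `DNAStringSet` of reads.
#' @export
simulate_reads <- function(genome, depth = 30, read_length = 150L,
                           error_rate = 0, seed = 1L) {
  if (depth <= 0) abort("depth must be positive")
  lens <- Biostrings::width(genome)
  if (read_length >= sum(lens)) abort("read_length must be below genome length")
  with_seed_(stage_seed(seed, "reads"), {
    total <- sum(lens)
    n_reads <- round(depth * total / read_length)
    w <- pmax(lens - read_length + 1L, 0L)
    chrom_i <- sample.int(length(genome), n_reads, replace = TRUE,
                          prob = w / sum(w))
    starts <- 1L + floor(runif(n_reads) * w[chrom_i])
    seqs <- character(n_reads)
    for (ci in unique(chrom_i)) {
      sel <- chrom_i == ci
      s <- as.character(genome[[ci]])
      seqs[sel] <- substring(s, starts[sel], starts[sel] + read_length - 1L)
    }
    if (error_rate > 0) {
      n_err <- rbinom(n_reads, read_length, error_rate)
      for (i in which(n_err > 0)) {
        pos <- sample.int(read_length, n_err[i])
        v <- strsplit(seqs[i], "")[[1]]
        v[pos] <- vapply(v[pos], function(b) sample(setdiff(BASES, b), 1),
                         character(1))
        seqs[i] <- paste(v, collapse = "")
      }
    }
    names(seqs) <- sprintf("read%07d", seq_len(n_reads))
    Biostrings::DNAStringSet(seqs)
  })
}

#' Extract spliced CDS sequences for genes
#'
#' @param genome A `DNAStringSet`.
#' @param cds CDS tibble (`gene_id`, `chrom`, `start`, `end`; one transcript
#'   per gene assumed, extra transcripts merged by exon order).
#' @return A named character vector of CDS sequences, one per gene.
#' @export
cds_sequence <- function(genome, cds) {
  by_gene <- split(cds, cds$gene_id)
  out <- vapply(by_gene, function(g) {
    g <- arrange(g[g$transcript_id == g$transcript_id[1], ], .data$start)
    paste(vapply(seq_len(nrow(g)), function(i) {
      as.character(Biostrings::subseq(genome[[g$chrom[i]]],
                                      g$start[i] + 1L, g$end[i]))
    }, character(1)), collapse = "")
  }, character(1))
  out
}
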