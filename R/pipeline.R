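# End-to-end orchestration: simulate -> pav -> genes -> variants -> profile
# from a single YAML config, with a manifest of resolved parameters and
# output checksums and checksum-based stage skipping.

known_stage_keys <- list(
  simulate = c("ancestor_length", "n_genes", "gc", "snp_rate", "indel_rate",
               "indel_size_range", "pav_count", "pav_min_size", "pav_max_size",
               "pav_gene_fraction", "read_depth", "read_length", "read_error",
               "write_reads"),
  pav = c("window", "step", "min_other_cov", "min_self_cov", "min_segment",
          "large_segment", "max_n_frac"),
  genes = c("pav_threshold", "read_threshold"),
  variants = c("max_indel"),
  profile = c("k", "depth")
)

#' Run the full synthetic PAV pipeline from a config
#'
#' Stages are executed in dependency order
#' (`simulate -> pav -> genes -> variants -> profile`); a stage whose
#' outputs already exist with a matching parameter fingerprint in the run
#' manifest is skipped. All randomness derives from the single `seed` via
#' stage-named substreams, so stage order cannot change results.
#'
#' @param config Path to a YAML file, or an equivalent named list. Top
#'   level: `seed`, plus one section per stage to run (see the package
#'   vignette). Unknown keys are rejected by name.
#' @param out Output directory (created if needed).
#' @return Invisibly, the manifest list (resolved parameters and md5
#'   checksums of every output).
#' @export
run_pipeline <- function(config, out) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  allowed_top <- c("seed", names(known_stage_keys))
  unknown <- setdiff(names(config), allowed_top)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (stage in intersect(names(config), names(known_stage_keys))) {
    bad <- setdiff(names(config[[stage]]), known_stage_keys[[stage]])
    if (length(bad)) {
      abort(sprintf("unknown key(s) in stage '%s': %s", stage,
                    paste(bad, collapse = ", ")))
    }
  }
  seed <- config$seed %||% 1L
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out, "manifest.json")
  old_manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else list()
  manifest <- list(seed = seed, stages = list())

  fingerprint <- function(stage, params) {
    paste(stage, seed, paste(deparse(params), collapse = ""), collapse = "|")
  }
  up_to_date <- function(stage, params, outputs) {
    rec <- old_manifest$stages[[stage]]
    !is.null(rec) && identical(rec$fingerprint, fingerprint(stage, params)) &&
      all(file.exists(file.path(out, outputs)))
  }
  record <- function(stage, params, outputs) {
    sums <- tools::md5sum(file.path(out, outputs))
    manifest$stages[[stage]] <<- list(
      fingerprint = fingerprint(stage, params),
      params = params,
      outputs = as.list(setNames(unname(sums), outputs)))
  }

  sim <- NULL
  get_sim <- function(p) {
    if (!is.null(sim)) return(sim)
    cfg <- simulation_config(
      seed = seed,
      ancestor_length = p$ancestor_length %||% 1e6,
      n_genes = p$n_genes %||% 50L,
      gc = p$gc %||% 0.37,
      snp_rate = p$snp_rate %||% 0.024,
      indel_rate = p$indel_rate %||% 0.006,
      pav_spec = tibble(count = p$pav_count %||% 10L,
                        min_size = p$pav_min_size %||% 600L,
                        max_size = p$pav_max_size %||% 10000L),
      pav_gene_fraction = p$pav_gene_fraction %||% 0.5,
      read_depth = p$read_depth %||% 30,
      read_length = p$read_length %||% 150L,
      read_error = p$read_error %||% 0.001)
    anc <- simulate_ancestor(cfg)
    sim <<- evolve_pair(anc, cfg)
    sim
  }

  if ("simulate" %in% names(config)) {
    p <- config$simulate %||% list()
    outputs <- c("genome_a.fa", "genome_b.fa", "genes_a.gff3", "genes_b.gff3",
                 "truth_segments.bed", "truth_snps.tsv", "truth_indels.tsv")
    if (up_to_date("simulate", p, outputs)) {
      manifest$stages[["simulate"]] <- old_manifest$stages[["simulate"]]
    } else {
      s <- get_sim(p)
      Biostrings::writeXStringSet(s$genome_a, file.path(out, "genome_a.fa"))
      Biostrings::writeXStringSet(s$genome_b, file.path(out, "genome_b.fa"))
      write_gff3(s$genes_a, file.path(out, "genes_a.gff3"))
      write_gff3(s$genes_b, file.path(out, "genes_b.gff3"))
      write_bed(s$truth$pav_segments, file.path(out, "truth_segments.bed"))
      readr::write_tsv(s$truth$snps, file.path(out, "truth_snps.tsv"))
      readr::write_tsv(s$truth$indels, file.path(out, "truth_indels.tsv"))
      if (isTRUE(p$write_reads)) {
        ra <- simulate_reads(s$genome_a, s$config$read_depth,
                             s$config$read_length, s$config$read_error,
                             seed = stage_seed(seed, "reads_a"))
        write_fastq(ra, file.path(out, "reads_a.fq"))
        outputs <- c(outputs, "reads_a.fq")
      }
      record("simulate", p, outputs)
    }
  }

  pav_res <- NULL
  load_genomes <- function() {
    fa <- file.path(out, c("genome_a.fa", "genome_b.fa"))
    missing <- fa[!file.exists(fa)]
    if (length(missing)) {
      abort(sprintf("missing input file: %s", paste(missing, collapse = ", ")))
    }
    list(a = load_genome(fa[1]), b = load_genome(fa[2]))
  }

  if ("pav" %in% names(config)) {
    p <- config$pav %||% list()
    outputs <- c("windows.tsv", "segments_A.bed", "segments_B.bed",
                 "pav_report.tsv")
    if (up_to_date("pav", p, outputs)) {
      manifest$stages[["pav"]] <- old_manifest$stages[["pav"]]
    } else {
      g <- if (!is.null(sim)) list(a = sim$genome_a, b = sim$genome_b)
           else load_genomes()
      params <- pav_params(
        window = p$window %||% 500L, step = p$step %||% 100L,
        min_other_cov = p$min_other_cov %||% 0.25,
        min_self_cov = p$min_self_cov %||% 0.90,
        min_segment = p$min_segment %||% 500L,
        large_segment = p$large_segment %||% 5000L,
        max_n_frac = p$max_n_frac %||% 0.5)
      pav_res <- pav_scan(g$a, g$b, params)
      readr::write_tsv(pav_res$windows, file.path(out, "windows.tsv"))
      write_bed(filter(pav_res$segments, .data$genome == "A"),
                file.path(out, "segments_A.bed"))
      write_bed(filter(pav_res$segments, .data$genome == "B"),
                file.path(out, "segments_B.bed"))
      readr::write_tsv(pav_res$report, file.path(out, "pav_report.tsv"))
      record("pav", p, outputs)
    }
  }

  if ("genes" %in% names(config)) {
    p <- config$genes %||% list()
    outputs <- c("pav_genes_A.tsv", "pav_genes_B.tsv")
    if (up_to_date("genes", p, outputs)) {
      manifest$stages[["genes"]] <- old_manifest$stages[["genes"]]
    } else {
      if (is.null(sim)) abort("the 'genes' stage requires the simulate stage")
      seg_a <- read_bed(file.path(out, "segments_A.bed"))
      seg_b <- read_bed(file.path(out, "segments_B.bed"))
      for (side in c("A", "B")) {
        genes <- if (side == "A") sim$genes_a else sim$genes_b
        self <- if (side == "A") sim$genome_a else sim$genome_b
        other <- if (side == "A") sim$genome_b else sim$genome_a
        segs <- if (side == "A") seg_a else seg_b
        merged <- merge_transcript_cds(genes)
        cand <- call_pav_genes(merged, segs, p$pav_threshold %||% 0.75)
        reads <- simulate_reads(other, sim$config$read_depth,
                                sim$config$read_length, sim$config$read_error,
                                seed = stage_seed(seed, paste0("reads_", side)))
        cov <- cds_read_coverage(merged, reads, self)
        calls <- read_support_filter(cand, cov, p$read_threshold %||% 0.50)
        readr::write_tsv(calls, file.path(out, sprintf("pav_genes_%s.tsv", side)))
      }
      record("genes", p, outputs)
    }
  }

  if ("variants" %in% names(config)) {
    p <- config$variants %||% list()
    outputs <- c("variants.tsv", "variant_density.tsv")
    if (up_to_date("variants", p, outputs)) {
      manifest$stages[["variants"]] <- old_manifest$stages[["variants"]]
    } else {
      if (is.null(sim)) abort("the 'variants' stage requires the simulate stage")
      blocks <- chain_one_to_one(truth_alignment(sim))
      calls <- call_block_variants(blocks, sim$genome_a, sim$genome_b,
                                   max_indel = p$max_indel %||% 100L)
      readr::write_tsv(calls$variants, file.path(out, "variants.tsv"))
      readr::write_tsv(variant_density(calls),
                       file.path(out, "variant_density.tsv"))
      record("variants", p, outputs)
    }
  }

  if ("profile" %in% names(config)) {
    p <- config$profile %||% list()
    outputs <- c("kmer_hist.tsv", "genome_profile.tsv")
    if (up_to_date("profile", p, outputs)) {
      manifest$stages[["profile"]] <- old_manifest$stages[["profile"]]
    } else {
      g <- if (!is.null(sim)) sim$genome_a else load_genomes()$a
      reads <- simulate_reads(g, p$depth %||% 30, 150L, 0,
                              seed = stage_seed(seed, "profile_reads"))
      hist <- kmer_histogram(reads, k = p$k %||% 17L)
      readr::write_tsv(as_tibble(hist), file.path(out, "kmer_hist.tsv"))
      readr::write_tsv(estimate_genome_size(hist),
                       file.path(out, "genome_profile.tsv"))
      record("profile", p, outputs)
    }
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
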