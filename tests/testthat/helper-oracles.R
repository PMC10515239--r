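# Independent brute-force oracles used to validate the implementation.

# ---- brute-force Nei-Gojobori: explicit string mutation and recursive
# pathway enumeration, no shared tables with the package ----
oracle_ng86 <- function(s1, s2) {
  code <- Biostrings::GENETIC_CODE
  nb <- c("A", "C", "G", "T")
  split_codons <- function(s) {
    n <- nchar(s) / 3
    substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
  }
  syn_sites_codon <- function(codon) {
    s <- 0
    for (pos in 1:3) {
      for (b in nb) {
        if (b == substr(codon, pos, pos)) next
        mut <- codon
        substr(mut, pos, pos) <- b
        if (code[[mut]] != "*" && code[[mut]] == code[[codon]]) s <- s + 1 / 3
      }
    }
    s
  }
  pair_diffs <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    paths <- list()
    rec <- function(cur, remaining, steps) {
      if (!length(remaining)) {
        paths[[length(paths) + 1]] <<- steps
        return(invisible())
      }
      for (p in remaining) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        rec(nxt, setdiff(remaining, p),
            rbind(steps, c(code[[cur]], code[[nxt]], nxt)))
      }
    }
    rec(c1, pos, NULL)
    score <- function(steps, allow_stop) {
      inter <- steps[-nrow(steps), 3]
      if (!allow_stop && any(code[inter] == "*")) return(NULL)
      syn <- sum(steps[, 1] == steps[, 2] & steps[, 1] != "*" &
                   steps[, 2] != "*")
      c(syn, nrow(steps) - syn)
    }
    ok <- Filter(Negate(is.null), lapply(paths, score, allow_stop = FALSE))
    if (!length(ok)) ok <- lapply(paths, score, allow_stop = TRUE)
    colMeans(do.call(rbind, ok))
  }
  c1 <- split_codons(toupper(s1))
  c2 <- split_codons(toupper(s2))
  keep <- !grepl("[^ACGT]", c1) & !grepl("[^ACGT]", c2)
  c1 <- c1[keep]; c2 <- c2[keep]
  n <- length(c1)
  if (n && code[[c1[n]]] == "*" && code[[c2[n]]] == "*") {
    c1 <- c1[-n]; c2 <- c2[-n]
  }
  S <- (sum(vapply(c1, syn_sites_codon, numeric(1))) +
          sum(vapply(c2, syn_sites_codon, numeric(1)))) / 2
  N <- 3 * length(c1) - S
  d <- colSums(do.call(rbind, Map(function(a, b) pair_diffs(a, b), c1, c2)))
  pS <- d[1] / S
  pN <- d[2] / N
  list(S = S, N = N, Sd = d[1], Nd = d[2], pS = pS, pN = pN,
       Ks = if (pS < 3 / 4) -3 / 4 * log(1 - 4 / 3 * pS) else NA_real_,
       Ka = if (pN < 3 / 4) -3 / 4 * log(1 - 4 / 3 * pN) else NA_real_)
}

# random coding sequence of n sense codons (no internal stops)
random_coding <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# mutate a fraction of codons to fresh random sense codons
perturb_coding <- function(s, frac) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  n <- nchar(s) / 3
  hit <- which(runif(n) < frac)
  for (i in hit) {
    substr(s, 3 * i - 2, 3 * i) <- sample(sense, 1)
  }
  s
}

# ---- boolean-mask union oracle for window merging ----
oracle_merge_mask <- function(starts, ends, len) {
  mask <- rep(FALSE, len)
  for (i in seq_along(starts)) mask[(starts[i] + 1):ends[i]] <- TRUE
  r <- rle(mask)
  e <- cumsum(r$lengths)
  s <- e - r$lengths
  tibble::tibble(start = s[r$values], end = e[r$values])
}

# ---- base-set union oracle for CDS merging ----
oracle_base_union <- function(starts, ends) {
  bases <- sort(unique(unlist(Map(function(s, e) (s + 1):e, starts, ends))))
  brk <- which(diff(bases) > 1)
  run_start <- bases[c(1, brk + 1)] - 1L
  run_end <- bases[c(brk, length(bases))]
  tibble::tibble(start = run_start, end = run_end)
}

# small fixture: write a FASTA file from a named character vector
write_tmp_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

tiny_sim <- function(seed = 1, length = 2e5, n_genes = 8,
                     pav = tibble::tibble(count = 3, min_size = 600,
                                          max_size = 3000), ...) {
  cfg <- simulation_config(seed = seed, ancestor_length = length,
                           n_genes = n_genes, pav_spec = pav, ...)
  evolve_pair(simulate_ancestor(cfg), cfg)
}
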