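# Shared fixtures, built in code.

toy_build <- function() genome_build(c("chrA", "chrB"), c(100, 200))

# a small build with per-base-countable chromosomes for FGA oracles
oracle_build <- function(n_chrom = 8, len = 10000)
  genome_build(paste0("c", seq_len(n_chrom)), rep(len, n_chrom))

# one fully passing exome-paired variant row
passing_variant <- function(...) {
  v <- data.frame(
    chrom = "toy1", pos = 50L, ref = "C", alt = "T", qual = 45,
    depth = 60L, alt_depth = 9L, vaf_tumor = 0.15, vaf_normal = 0,
    callers = "VarDict,Platypus", passes_caller_filters = TRUE,
    consequence = "coding", effect = "missense", gene = "TP53",
    pop_af = NA_real_, clinvar_pathogenic = FALSE, is_hotspot = FALSE,
    stringsAsFactors = FALSE)
  over <- list(...)
  v[names(over)] <- over
  v
}

# random called segment profile on a build; non-overlapping by construction
random_profile <- function(build, max_seg_per_chrom = 4) {
  rows <- list()
  for (i in seq_len(nrow(build))) {
    n <- sample(0:max_seg_per_chrom, 1)
    if (n == 0) next
    len <- build$length[i]
    cuts <- sort(sample(0:len, 2 * n))
    for (j in seq_len(n)) {
      s <- cuts[2 * j - 1]; e <- cuts[2 * j]
      if (s >= e) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = build$chrom[i], start = s, end = e,
        log2 = runif(1, -1.5, 1.5), loh = FALSE)
    }
  }
  if (!length(rows))
    return(cn_segments(data.frame(chrom = character(), start = numeric(),
                                  end = numeric(), log2 = numeric(),
                                  loh = logical())))
  call_segments(do.call(rbind, rows))
}

# independent per-base FGA oracle: mark altered bases explicitly
fga_brute_force <- function(seg, build) {
  fracs <- numeric(nrow(build))
  for (i in seq_len(nrow(build))) {
    len <- build$length[i]
    mask <- logical(len)
    s <- seg[seg$chrom == build$chrom[i] & seg$call != "neutral", ,
             drop = FALSE]
    if (nrow(s)) for (j in seq_len(nrow(s)))
      mask[(s$start[j] + 1):s$end[j]] <- TRUE
    fracs[i] <- sum(mask) / len
  }
  mean(fracs)
}

# independent two-sided Fisher p by full enumeration over fixed margins
fisher_brute_force <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)), 0)
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# minimal synthetic case with given tables
quick_case <- function(id, classification = "G1", mode = "exome_paired",
                       variants = NULL, segments = NULL, svs = NULL,
                       time = NA_real_, event = "censored") {
  case_record(id, classification, mode, time = time, event = event,
              variants = variants, segments = segments, svs = svs)
}
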