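#' Discrete copy-number calls from log2 ratios
#'
#' Thresholds: homozygous deletion below -1, loss from -1 to -0.2,
#' neutral strictly inside (-0.2, 0.2), gain from 0.2 to 0.6, and
#' high-level amplification above 0.6. Boundary values (exactly
#' \eqn{\pm 0.2}, exactly 0.6 or -1) are assigned to gain/loss, matching
#' the inclusive phrasing "\eqn{\pm 0.2} for gains and losses" with
#' strict cutoffs for amplification and homozygous deletion.
#'
#' @param seg segment table (see [segment-io]).
#' @param cfg a [moc_thresholds()].
#' @return `seg` with a `call` column.
#' @export
call_segments <- function(seg, cfg = moc_thresholds()) {
  seg <- cn_segments(seg)
  l <- seg$log2
  seg$call <- ifelse(l < cfg$log2_homdel, "homdel",
              ifelse(l <= cfg$log2_loss, "loss",
              ifelse(l < cfg$log2_gain, "neutral",
              ifelse(l <= cfg$log2_amp, "gain", "amp"))))
  seg
}

# merge touching same-call segments so event counts are invariant to
# how an equal-call run happens to be split
coalesce_segments <- function(seg) {
  if (!nrow(seg)) return(seg)
  stopifnot("call" %in% names(seg))
  out <- list()
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    i <- 1L
    while (i <= nrow(s)) {
      j <- i
      while (j < nrow(s) && s$start[j + 1] <= s$end[j] &&
             s$call[j + 1] == s$call[j]) j <- j + 1L
      row <- s[i, , drop = FALSE]
      row$end <- max(s$end[i:j])
      out[[length(out) + 1L]] <- row
      i <- j + 1L
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of the genome altered (FGA)
#'
#' For each chromosome of the build, the number of bases covered by a
#' non-neutral copy-number call divided by the chromosome length; FGA is
#' the mean of these fractions over all chromosomes of the build
#' (chromosomes without segments contribute 0). Copy-neutral LOH does
#' not count: only bases affected by copy-number change enter the
#' numerator. The default build holds autosomes plus X (23
#' denominators).
#'
#' @param seg called segment table for one case.
#' @param build a [genome_build()].
#' @return FGA in \[0, 1\].
#' @export
fraction_genome_altered <- function(seg, build) {
  stopifnot(inherits(build, "moc_build"))
  if (!nrow(seg)) return(0)
  if (!"call" %in% names(seg)) stop("segments must be called first")
  len <- chrom_length(build, seg$chrom)
  if (any(seg$end > len)) stop("segment extends beyond chromosome end")
  alt <- seg[seg$call != "neutral", , drop = FALSE]
  per_chrom <- stats::setNames(numeric(nrow(build)), build$chrom)
  if (nrow(alt)) {
    bases <- tapply(alt$end - alt$start, alt$chrom, sum)
    per_chrom[names(bases)] <- as.numeric(bases) /
      chrom_length(build, names(bases))
  }
  mean(per_chrom)
}

#' Copy-number profile type
#'
#' Classifies one tumor's called profile into `simple`,
#' `simple_one_amp`, `complex`, `complex_whole_chr` or
#' `complex_multi_amp`. The rules (all cutoffs in `cfg`): adjacent
#' equal-call segments are first coalesced into events; amplifications
#' on two or more chromosomes give `complex_multi_amp` (this takes
#' precedence over the whole-chromosome pattern); otherwise fewer than
#' `profile_complex_min_events` (10) altered autosomal events is the
#' simple family, split into `simple_one_amp` when exactly one
#' chromosome bears an amplification; with 10 or more events the profile
#' is complex, called `complex_whole_chr` when at least
#' `profile_whole_chr_bases` (80%) of altered bases come from
#' whole-chromosome events (covering `profile_whole_chr_frac` (95%) of
#' their chromosome).
#'
#' @param seg called segment table for one case.
#' @param build a [genome_build()].
#' @param cfg a [moc_thresholds()].
#' @return One of the five profile labels.
#' @export
classify_profile <- function(seg, build, cfg = moc_thresholds()) {
  stopifnot(inherits(build, "moc_build"))
  if (!nrow(seg)) return("simple")
  if (!"call" %in% names(seg)) stop("segments must be called first")
  seg <- coalesce_segments(seg[order(seg$chrom, seg$start), , drop = FALSE])
  alt <- seg[seg$call != "neutral", , drop = FALSE]
  if (!nrow(alt)) return("simple")
  amp_chroms <- unique(alt$chrom[alt$call == "amp"])
  if (length(amp_chroms) >= 2) return("complex_multi_amp")
  autos <- !grepl("X$|Y$", alt$chrom)
  n_events <- sum(autos)
  if (n_events < cfg$profile_complex_min_events)
    return(if (length(amp_chroms) == 1) "simple_one_amp" else "simple")
  width <- alt$end - alt$start
  whole <- width >= cfg$profile_whole_chr_frac * chrom_length(build, alt$chrom)
  if (sum(width[whole]) >= cfg$profile_whole_chr_bases * sum(width))
    return("complex_whole_chr")
  "complex"
}

# ---- interval set helpers (half-open [start, end)) ----

merge_intervals <- function(start, end) {
  if (!length(start)) return(data.frame(start = numeric(), end = numeric()))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me)
           ms <- start[i]; me <- end[i] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

intersect_interval_sets <- function(a, b) {
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    s <- max(a$start[i], b$start[j]); e <- min(a$end[i], b$end[j])
    if (s < e) { out_s <- c(out_s, s); out_e <- c(out_e, e) }
  }
  merge_intervals(out_s, out_e)
}

overlap_width <- function(start, end, set) {
  if (!nrow(set)) return(0)
  sum(pmax(0, pmin(end, set$end) - pmax(start, set$start)))
}

#' Compare aberration frequencies between two groups of cases
#'
#' The genome is partitioned into minimal consistent intervals (the
#' union of every segment breakpoint in either group). For each interval
#' and each aberration direction (gain family: gain or amplification;
#' loss family: loss or homozygous deletion), cases are counted as
#' aberrant when any overlapping segment carries a call of that family,
#' and the two groups are compared with a two-sided Fisher exact test. A
#' region is flagged significant when p is below the per-region bound
#' (0.002, i.e. 0.05 split over the 23 chromosomes), the absolute
#' frequency difference is at least 15%, the interval does not fall in a
#' platform-artifact region, and no more than 90% of it is covered by a
#' known copy-number polymorphism.
#'
#' @param cases_a,cases_b lists of `moc_case` objects with called
#'   segments (at least 2 cases each).
#' @param build a [genome_build()].
#' @param cfg a [moc_thresholds()].
#' @param cnp_track optional data.frame (`chrom`, `start`, `end`) of
#'   copy-number polymorphisms.
#' @param artifact_regions optional data.frame (`chrom`, `start`, `end`)
#'   of platform-artifact regions.
#' @param drop_empty drop intervals aberrant in neither group.
#' @return data.frame with one row per interval x direction: frequencies
#'   in each group, Fisher p-value, absolute difference, exclusion flags
#'   and the `significant` verdict.
#' @export
compare_group_frequencies <- function(cases_a, cases_b, build,
                                      cfg = moc_thresholds(),
                                      cnp_track = NULL,
                                      artifact_regions = NULL,
                                      drop_empty = TRUE) {
  if (length(cases_a) < 2 || length(cases_b) < 2)
    stop("each group needs at least 2 cases")
  seg_of <- function(cs) {
    s <- cs$segments
    if (is.null(s) || !nrow(s)) return(NULL)
    if (!"call" %in% names(s)) stop("segments must be called first")
    s
  }
  segs_a <- lapply(cases_a, seg_of)
  segs_b <- lapply(cases_b, seg_of)
  fam <- list(gain = c("gain", "amp"), loss = c("loss", "homdel"))
  res <- list()
  for (ch in build$chrom) {
    bp <- sort(unique(c(0, chrom_length(build, ch),
                        unlist(lapply(c(segs_a, segs_b), function(s)
                          if (is.null(s)) NULL
                          else { x <- s[s$chrom == ch, ]
                                 c(x$start, x$end) })))))
    if (length(bp) < 3) next   # no breakpoints inside the chromosome
    iv_s <- bp[-length(bp)]; iv_e <- bp[-1]
    aberrant <- function(segs, dir) vapply(segs, function(s) {
      if (is.null(s)) return(rep(FALSE, length(iv_s)))
      s <- s[s$chrom == ch & s$call %in% fam[[dir]], , drop = FALSE]
      if (!nrow(s)) return(rep(FALSE, length(iv_s)))
      vapply(seq_along(iv_s), function(i)
        any(s$start < iv_e[i] & s$end > iv_s[i]), TRUE)
    }, logical(length(iv_s)))
    for (dir in names(fam)) {
      A <- matrix(aberrant(segs_a, dir), nrow = length(iv_s))
      B <- matrix(aberrant(segs_b, dir), nrow = length(iv_s))
      ka <- rowSums(A); kb <- rowSums(B)
      for (i in seq_along(iv_s)) {
        if (drop_empty && ka[i] + kb[i] == 0) next
        tab <- matrix(c(ka[i], length(cases_a) - ka[i],
                        kb[i], length(cases_b) - kb[i]), 2)
        p <- stats::fisher.test(tab)$p.value
        fa <- ka[i] / length(cases_a); fb <- kb[i] / length(cases_b)
        w <- iv_e[i] - iv_s[i]
        cnp_frac <- if (is.null(cnp_track)) 0 else
          overlap_width(iv_s[i], iv_e[i],
                        cnp_track[cnp_track$chrom == ch, ]) / w
        artif <- if (is.null(artifact_regions)) FALSE else
          overlap_width(iv_s[i], iv_e[i],
                        artifact_regions[artifact_regions$chrom == ch, ]) > 0
        res[[length(res) + 1L]] <- data.frame(
          chrom = ch, start = iv_s[i], end = iv_e[i], direction = dir,
          freq_group1 = fa, freq_group2 = fb, p_value = p,
          diff = abs(fa - fb), cnp_frac = cnp_frac,
          platform_artifact = artif,
          significant = p < cfg$cmp_p & abs(fa - fb) >= cfg$cmp_diff &
            !artif & cnp_frac <= cfg$cnp_overlap,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), direction = character(),
                      freq_group1 = numeric(), freq_group2 = numeric(),
                      p_value = numeric(), diff = numeric(),
                      cnp_frac = numeric(), platform_artifact = logical(),
                      significant = logical()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Minimal region of overlap of amplified cases
#'
#' Within a target region (typically a chromosome arm), each case
#' contributes the union of its amplified segments; the minimal region
#' of overlap is the intersection of those unions across all cases. An
#' empty intersection is reported explicitly as a 0-row table.
#'
#' @param cases list of `moc_case` objects with called segments.
#' @param chrom target chromosome.
#' @param region_start,region_end bounds of the target arm (defaults:
#'   whole chromosome).
#' @return data.frame of intervals (`chrom`, `start`, `end`).
#' @export
minimal_overlap_region <- function(cases, chrom, region_start = 0,
                                   region_end = Inf) {
  per_case <- lapply(cases, function(cs) {
    s <- cs$segments
    if (is.null(s) || !"call" %in% names(s)) s <- NULL
    if (!is.null(s))
      s <- s[s$chrom == chrom & s$call == "amp" &
               s$end > region_start & s$start < region_end, , drop = FALSE]
    if (is.null(s) || !nrow(s))
      stop("case ", cs$case_id, " has no amplification in the target region")
    merge_intervals(pmax(s$start, region_start), pmin(s$end, region_end))
  })
  mro <- Reduce(intersect_interval_sets, per_case)
  if (!nrow(mro))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  data.frame(chrom = chrom, start = mro$start, end = mro$end,
             stringsAsFactors = FALSE)
}
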