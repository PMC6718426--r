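#' Structural variant classification
#'
#' Breakend pairs on different chromosomes are inter-chromosomal
#' translocations. Intra-chromosomal deletions and duplications are
#' small when their breakend distance is below 1 Mb, large otherwise.
#' Inversions follow the same 1 Mb small/large boundary but are called
#' fold-back inversions when below 30 kb — the size regime produced by
#' breakage-fusion-bridge amplification. Boundaries are strict (`<`),
#' and the size is the absolute breakend distance, so classification is
#' invariant to swapping the breakend order.
#'
#' @param svs an [sv_pairs()] table.
#' @param cfg a [moc_thresholds()] (size cutoffs `sv_small_bp`,
#'   `foldback_bp`).
#' @return Character vector of classes: `small_deletion`,
#'   `large_deletion`, `small_duplication`, `large_duplication`,
#'   `foldback_inversion`, `small_inversion`, `large_inversion`,
#'   `interchromosomal_translocation` — exactly one per pair.
#' @examples
#' svs <- sv_pairs(data.frame(chrom_a = "chr9", pos_a = 1e6,
#'                            chrom_b = "chr9", pos_b = 1e6 + 12e3,
#'                            sv_type = "inversion"))
#' classify_sv(svs) # foldback_inversion
#' @export
classify_sv <- function(svs, cfg = moc_thresholds()) {
  svs <- sv_pairs(svs)
  if (any(!is.na(svs$size) & svs$size < 0)) stop("negative SV size")
  size_word <- ifelse(svs$size < cfg$sv_small_bp, "small", "large")
  out <- character(nrow(svs))
  out[svs$sv_type == "translocation"] <- "interchromosomal_translocation"
  for (ty in c("deletion", "duplication")) {
    i <- svs$sv_type == ty
    out[i] <- paste0(size_word[i], "_", ty)
  }
  inv <- svs$sv_type == "inversion"
  out[inv] <- ifelse(svs$size[inv] < cfg$foldback_bp, "foldback_inversion",
                     paste0(size_word[inv], "_inversion"))
  out
}

.sv_classes <- c("small_deletion", "large_deletion", "small_duplication",
                 "large_duplication", "foldback_inversion",
                 "small_inversion", "large_inversion",
                 "interchromosomal_translocation")

#' Per-case breakpoint summary
#'
#' Counts and proportions of SV classes plus the groupings used to
#' describe rearrangement burden: small intra-chromosomal events
#' (including fold-back inversions), large intra-chromosomal events and
#' inter-chromosomal translocations. The fold-back share is reported
#' both as a fraction of all breakpoint pairs and as a fraction of
#' inversions.
#'
#' @param svs an [sv_pairs()] table for one case.
#' @param cfg a [moc_thresholds()].
#' @return List with `n`, `counts`, `proportions` (all 8 classes),
#'   `groups` (small_intra / large_intra / inter proportions),
#'   `foldback_of_all` and `foldback_of_inversions`. For an empty input
#'   all proportions are `NA` (reported as absent, not 0).
#' @export
breakpoint_summary <- function(svs, cfg = moc_thresholds()) {
  cls <- classify_sv(svs, cfg)
  n <- length(cls)
  counts <- stats::setNames(integer(length(.sv_classes)), .sv_classes)
  tab <- table(cls)
  counts[names(tab)] <- as.integer(tab)
  if (n == 0) {
    na3 <- stats::setNames(rep(NA_real_, 3),
                           c("small_intra", "large_intra", "inter"))
    return(list(n = 0L, counts = counts,
                proportions = stats::setNames(rep(NA_real_, length(counts)),
                                              names(counts)),
                groups = na3, foldback_of_all = NA_real_,
                foldback_of_inversions = NA_real_))
  }
  props <- counts / n
  small_intra <- sum(counts[c("small_deletion", "small_duplication",
                              "foldback_inversion", "small_inversion")])
  large_intra <- sum(counts[c("large_deletion", "large_duplication",
                              "large_inversion")])
  inter <- counts[["interchromosomal_translocation"]]
  n_inv <- sum(counts[c("foldback_inversion", "small_inversion",
                        "large_inversion")])
  list(
    n = n, counts = counts, proportions = props,
    groups = c(small_intra = small_intra / n, large_intra = large_intra / n,
               inter = inter / n),
    foldback_of_all = counts[["foldback_inversion"]] / n,
    foldback_of_inversions = if (n_inv > 0)
      counts[["foldback_inversion"]] / n_inv else NA_real_
  )
}
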