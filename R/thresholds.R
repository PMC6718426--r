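#' Analysis thresholds
#'
#' All numeric cutoffs used across the pipeline, bundled in a single
#' configuration object. Defaults are the values used throughout the
#' package: population allele-frequency cutoff 1e-4 (with a
#' ClinVar-pathogenic rescue), caller QUAL >= 30, read depth >= 10
#' (targeted panel: 20), variant-supporting reads >= 2 (panel: 10),
#' tumor VAF > 0.05, matched-normal VAF <= 0.05, cohort recurrence <= 20%
#' (hotspots exempt), at most 1 panel-of-normals hit, a 2.07 Mb panel
#' target size for burden, copy-number log2 cutoffs of +/-0.2 for
#' gain/loss, > 0.6 for high-level amplification and < -1 for homozygous
#' deletion, SV size classes at 1 Mb (30 kb for fold-back inversions),
#' region comparison at p < 0.002 with >= 15% frequency difference and a
#' 90% copy-number-polymorphism overlap exclusion, a 0.06 signature
#' sparsity cutoff and k = 3 de novo signatures.
#'
#' @param ... named overrides for any default listed above.
#'
#' @return An object of class `moc_thresholds` (a named list).
#' @examples
#' cfg <- moc_thresholds()
#' cfg$log2_amp
#' moc_thresholds(cohort_recurrence_max = 0.1)$cohort_recurrence_max
#' @export
moc_thresholds <- function(...) {
  cfg <- list(
    pop_af_max            = 1e-4,
    qual_min              = 30,
    depth_min             = 10,
    depth_min_panel       = 20,
    alt_depth_min         = 2,
    alt_depth_min_panel   = 10,
    vaf_min               = 0.05,
    normal_vaf_max        = 0.05,
    cohort_recurrence_max = 0.20,
    pon_max_hits          = 1,
    panel_target_mb       = 2.07,
    log2_gain             = 0.2,
    log2_loss             = -0.2,
    log2_amp              = 0.6,
    log2_homdel           = -1.0,
    sv_small_bp           = 1e6,
    foldback_bp           = 3e4,
    cmp_alpha             = 0.05,
    cmp_p                 = 0.002,
    cmp_diff              = 0.15,
    cnp_overlap           = 0.90,
    sig_sparsity          = 0.06,
    nmf_k                 = 3,
    # profile classification rule parameters
    profile_complex_min_events = 10,
    profile_whole_chr_frac     = 0.95,
    profile_whole_chr_bases    = 0.80
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  num <- unlist(cfg)
  if (any(!is.finite(num))) stop("all thresholds must be finite")
  structure(cfg, class = "moc_thresholds")
}

#' Per-region significance level for copy-number group comparisons
#'
#' The family-wise error rate is split over chromosomes rather than over
#' regions, because segments within a chromosome are not independent. The
#' quotient `alpha / n_chrom` is reported rounded to three decimals, the
#' precision at which the bound is used by [compare_group_frequencies()].
#'
#' @param alpha family-wise significance level (default 0.05).
#' @param n_chrom number of chromosomes in the analysis build (default 23:
#'   autosomes plus X).
#' @param digits rounding precision of the returned bound.
#' @return The per-region p-value bound.
#' @examples
#' region_significance_level() # 0.002
#' @export
region_significance_level <- function(alpha = 0.05, n_chrom = 23, digits = 3) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_chrom < 1) stop("n_chrom must be >= 1")
  round(alpha / n_chrom, digits)
}

#' @export
print.moc_thresholds <- function(x, ...) {
  cat("mocprog thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
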