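#' High-confidence somatic variant filtering cascade
#'
#' Multi-caller variant lists are reduced to high-confidence somatic
#' calls by a conjunctive rule cascade. In order, a variant is rejected
#' when:
#' \enumerate{
#'   \item `population_af` — its maximum population allele frequency
#'     exceeds `pop_af_max` (1e-4) and it is not ClinVar pathogenic;
#'   \item `qual` — QUAL below 30 (absent QUAL fails);
#'   \item `depth` — read depth below 10 (panel: 20);
#'   \item `alt_depth` — variant-supporting reads below 2 (panel: 10);
#'   \item `vaf_tumor` — tumor allele fraction not above 0.05;
#'   \item `normal_vaf` — (paired platforms) matched-normal allele
#'     fraction above 0.05 (germline leakage);
#'   \item `blacklist` — the gene is blacklisted;
#'   \item `panel_of_normals` — seen in more than one in-house germline
#'     exome;
#'   \item `cohort_recurrence` — present in more than 20% of the cohort,
#'     unless a known hotspot (e.g. KRAS codon 12);
#'   \item `caller_concordance` — called only by VarScan; on platforms
#'     without a matched normal (unpaired exome, panel) also when called
#'     only by UnifiedGenotyper;
#'   \item `caller_filters` — failed the callers' own default filters;
#'   \item `batch_normal` — (panel) present in the three normal samples
#'     sequenced in the same batch.
#' }
#' The rules are conjunctive, so their order affects only the order of
#' reported reasons, never the keep/reject outcome. WGS calls go through
#' the paired-exome rule set.
#'
#' @name variant-filter
NULL

.filter_rules <- c("population_af", "qual", "depth", "alt_depth",
                   "vaf_tumor", "normal_vaf", "blacklist",
                   "panel_of_normals", "cohort_recurrence",
                   "caller_concordance", "caller_filters", "batch_normal")

.paired_modes <- c("exome_paired", "wgs")

#' Cohort context for the filtering cascade
#'
#' @param cohort_fraction named numeric: for each [variant_key()], the
#'   fraction of cohort cases carrying the variant.
#' @param pon_hits named integer: panel-of-normals hit counts by key.
#' @param blacklist character vector of blacklisted genes.
#' @param batch_normals character vector of keys seen in the panel batch
#'   normals.
#' @return A list used as the `ctx` argument of [classify_variant()].
#' @export
filter_context <- function(cohort_fraction = numeric(),
                           pon_hits = integer(),
                           blacklist = character(),
                           batch_normals = character()) {
  list(cohort_fraction = cohort_fraction, pon_hits = pon_hits,
       blacklist = blacklist, batch_normals = batch_normals)
}

#' Classify variants through the somatic filtering cascade
#'
#' @param v a [variant_calls()] table.
#' @param mode platform mode (see [variant-io]).
#' @param ctx a [filter_context()].
#' @param cfg a [moc_thresholds()] configuration.
#' @return data.frame with logical `keep` and character `reasons`
#'   (semicolon-joined failed-rule identifiers in cascade order; empty
#'   iff kept), one row per variant.
#' @seealso [variant-filter] for the rule definitions.
#' @export
classify_variant <- function(v, mode, ctx = filter_context(),
                             cfg = moc_thresholds()) {
  v <- variant_calls(v)
  mode <- match.arg(mode, .platform_modes)
  n <- nrow(v)
  paired <- mode %in% .paired_modes
  if (paired && n && anyNA(v$vaf_normal))
    stop("paired-mode variant without a normal VAF (contract violation)")

  depth_min <- if (mode == "panel") cfg$depth_min_panel else cfg$depth_min
  alt_min <- if (mode == "panel") cfg$alt_depth_min_panel else cfg$alt_depth_min
  key <- variant_key(v)
  lookup <- function(map, default) {
    if (!length(map)) return(rep(default, n))
    x <- map[key]
    x[is.na(x)] <- default
    unname(x)
  }
  frac <- lookup(ctx$cohort_fraction, 0)
  pon <- lookup(ctx$pon_hits, 0L)

  fail <- list(
    population_af = !is.na(v$pop_af) & v$pop_af > cfg$pop_af_max &
      !(v$clinvar_pathogenic %in% TRUE),
    qual = is.na(v$qual) | v$qual < cfg$qual_min,
    depth = is.na(v$depth) | v$depth < depth_min,
    alt_depth = is.na(v$alt_depth) | v$alt_depth < alt_min,
    vaf_tumor = is.na(v$vaf_tumor) | v$vaf_tumor <= cfg$vaf_min,
    normal_vaf = if (paired) v$vaf_normal > cfg$normal_vaf_max
                 else rep(FALSE, n),
    blacklist = !is.na(v$gene) & v$gene %in% ctx$blacklist,
    panel_of_normals = pon > cfg$pon_max_hits,
    cohort_recurrence = frac > cfg$cohort_recurrence_max &
      !(v$is_hotspot %in% TRUE),
    caller_concordance = {
      sets <- strsplit(v$callers, ",", fixed = TRUE)
      only <- function(who) vapply(sets, function(s)
        length(s) == 1L && trimws(s) == who, TRUE)
      if (paired) only("VarScan") else only("VarScan") | only("UnifiedGenotyper")
    },
    caller_filters = !(v$passes_caller_filters %in% TRUE),
    batch_normal = if (mode == "panel") key %in% ctx$batch_normals
                   else rep(FALSE, n)
  )
  fail_mat <- do.call(cbind, fail)
  reasons <- apply(fail_mat, 1L, function(row)
    paste(.filter_rules[row], collapse = ";"))
  if (n == 0) reasons <- character()
  data.frame(keep = !as.logical(rowSums(fail_mat) > 0), reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Filter a whole cohort (two-pass)
#'
#' Pass one computes cohort recurrence over rule-independent variant
#' identity (chrom, pos, ref, alt) across all cases; pass two applies
#' [classify_variant()] per case with that context. Filtering is
#' idempotent: re-filtering the kept sets changes nothing, because
#' removing variants can only lower recurrence fractions.
#'
#' @param cohort a [moc_cohort()] whose cases carry variants.
#' @param cfg a [moc_thresholds()].
#' @return A list with `cohort` (cases reduced to kept variants),
#'   `decisions` (per-case classification tables keyed by case id) and
#'   `ledger` (data.frame of per-rule rejection counts).
#' @export
filter_cohort <- function(cohort, cfg = moc_thresholds()) {
  stopifnot(inherits(cohort, "moc_cohort"))
  cases <- cohort$cases
  if (!length(cases)) stop("empty cohort")
  n_cases <- length(cases)

  keys_per_case <- lapply(cases, function(cs)
    if (is.null(cs$variants) || !nrow(cs$variants)) character()
    else unique(variant_key(cs$variants)))
  tab <- table(unlist(keys_per_case))
  cohort_fraction <- as.numeric(tab) / n_cases
  names(cohort_fraction) <- names(tab)

  pon_hits <- integer()
  if (!is.null(cohort$pon) && nrow(cohort$pon)) {
    pon_hits <- as.integer(cohort$pon$hits)
    names(pon_hits) <- cohort$pon$key
  }
  ctx <- filter_context(cohort_fraction = cohort_fraction,
                        pon_hits = pon_hits,
                        blacklist = cohort$blacklist,
                        batch_normals = cohort$batch_normals)

  decisions <- list()
  rule_counts <- stats::setNames(integer(length(.filter_rules)), .filter_rules)
  kept_total <- 0L; seen_total <- 0L
  for (id in names(cases)) {
    cs <- cases[[id]]
    if (is.null(cs$variants) || !nrow(cs$variants)) next
    dec <- classify_variant(cs$variants, cs$platform_mode, ctx, cfg)
    decisions[[id]] <- dec
    seen_total <- seen_total + nrow(dec)
    kept_total <- kept_total + sum(dec$keep)
    failed <- unlist(strsplit(dec$reasons[!dec$keep], ";", fixed = TRUE))
    if (length(failed)) {
      tf <- table(failed)
      rule_counts[names(tf)] <- rule_counts[names(tf)] + as.integer(tf)
    }
    cases[[id]]$variants <- cs$variants[dec$keep, , drop = FALSE]
    rownames(cases[[id]]$variants) <- NULL
  }
  out <- cohort
  out$cases <- cases
  list(cohort = out,
       decisions = decisions,
       ledger = data.frame(rule = .filter_rules,
                           rejected = as.integer(rule_counts),
                           stringsAsFactors = FALSE),
       n_input = seen_total, n_kept = kept_total)
}

#' Mutation burden in variants per megabase
#'
#' Counts kept coding and splice-site variants restricted to the
#' validation-panel genes (so exome, genome and panel platforms are
#' compared over the same footprint) and divides by the panel target
#' size in Mb (2.07 by default).
#'
#' @param v kept variant table for one case.
#' @param panel_genes character vector of panel gene symbols.
#' @param target_mb capture target size in megabases.
#' @return Variants per Mb (numeric scalar).
#' @examples
#' # 207 qualifying variants over 2.07 Mb = 100 per Mb
#' @export
variants_per_mb <- function(v, panel_genes, target_mb = 2.07) {
  if (!is.numeric(target_mb) || target_mb <= 0)
    stop("target_mb must be positive")
  v <- variant_calls(v)
  qual <- v$consequence %in% c("coding", "splice") &
    !is.na(v$gene) & v$gene %in% panel_genes
  sum(qual) / target_mb
}
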