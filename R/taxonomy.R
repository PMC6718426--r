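#' Binary gene x case event matrix under per-gene counting rules
#'
#' A gene scores 1 in a case when it carries a qualifying mutation or a
#' qualifying copy-number event. Mutation qualification follows the
#' per-gene rule: `all` counts any non-synonymous coding or splice
#' variant, `missense_only` counts missense variants (the oncogenic mode
#' of KRAS/BRAF), `inactivating_only` counts truncating (nonsense,
#' frameshift) and splice variants, `none` ignores mutations. Only
#' high-level amplifications and homozygous deletions are considered for
#' copy number, per the gene's `cn_rule`, using gene footprints from
#' `gene_coords`.
#'
#' @param cases list of `moc_case` objects with filtered variants and
#'   called segments.
#' @param rules rule table as from [default_event_rules()].
#' @param gene_coords gene footprint table as from
#'   [driver_gene_coords()].
#' @return Integer matrix (genes x cases) of 0/1 indicators.
#' @export
build_event_matrix <- function(cases, rules = default_event_rules(),
                               gene_coords = driver_gene_coords()) {
  stopifnot(is.list(cases), length(cases) > 0)
  genes <- rules$gene
  ids <- vapply(cases, `[[`, "", "case_id")
  M <- matrix(0L, nrow = length(genes), ncol = length(cases),
              dimnames = list(genes, ids))
  qualifies_var <- function(v, rule) {
    if (is.null(v) || !nrow(v)) return(logical(0))
    eff <- ifelse(is.na(v$effect), "other", v$effect)
    coding <- v$consequence %in% c("coding", "splice")
    switch(rule,
      all = coding & eff != "synonymous",
      missense_only = coding & eff == "missense",
      inactivating_only = coding &
        eff %in% c("nonsense", "frameshift", "splice"),
      none = rep(FALSE, nrow(v)),
      stop("gene without a recognised variant rule: ", rule))
  }
  for (j in seq_along(cases)) {
    cs <- cases[[j]]
    v <- cs$variants
    seg <- cs$segments
    for (i in seq_along(genes)) {
      g <- genes[i]
      hit <- FALSE
      if (!is.null(v) && nrow(v)) {
        vg <- v[!is.na(v$gene) & v$gene == g, , drop = FALSE]
        if (nrow(vg) && any(qualifies_var(vg, rules$variant_rule[i])))
          hit <- TRUE
      }
      cn_rule <- rules$cn_rule[i]
      if (!hit && cn_rule != "none" && !is.null(seg) && nrow(seg) &&
          "call" %in% names(seg)) {
        gc <- gene_coords[gene_coords$gene == g, , drop = FALSE]
        if (nrow(gc)) {
          wanted <- switch(cn_rule, amp = "amp", homdel = "homdel",
                           amp_or_homdel = c("amp", "homdel"),
                           stop("unknown cn_rule: ", cn_rule))
          sg <- seg[seg$chrom == gc$chrom & seg$call %in% wanted &
                      seg$start < gc$end & seg$end > gc$start, , drop = FALSE]
          if (nrow(sg)) hit <- TRUE
        }
      }
      M[i, j] <- as.integer(hit)
    }
  }
  M
}

#' Gene x tumor-type frequency matrix
#'
#' @param event_matrix gene x case 0/1 matrix from
#'   [build_event_matrix()].
#' @param types character vector assigning a tumor type to each case
#'   (column).
#' @return List with `freq` (gene x type frequencies, events / cases
#'   exactly) and `n_cases` (per-type counts).
#' @export
event_frequencies <- function(event_matrix, types) {
  stopifnot(ncol(event_matrix) == length(types))
  levels <- unique(types)
  freq <- sapply(levels, function(t)
    rowMeans(event_matrix[, types == t, drop = FALSE]))
  freq <- matrix(freq, nrow = nrow(event_matrix),
                 dimnames = list(rownames(event_matrix), levels))
  list(freq = freq, n_cases = stats::setNames(
    as.integer(table(factor(types, levels = levels))), levels))
}

#' Hierarchically cluster tumor types by event frequencies
#'
#' Euclidean distance between frequency columns with complete linkage;
#' the dendrogram is reordered by mean frequency (the default reordering
#' of standard R heatmap routines), making the leaf order deterministic
#' and reproducible by other implementations.
#'
#' @param freq gene x type frequency matrix (values in \[0, 1\]).
#' @return List with `hclust`, `dendrogram`, `leaf_order` (type names in
#'   display order), `cophenetic` (distance matrix) and `distance` (the
#'   input distances). A constant matrix yields all-zero distances and a
#'   degenerate tree, with a warning.
#' @export
cluster_tumor_types <- function(freq) {
  freq <- as.matrix(freq)
  if (ncol(freq) < 2) stop("need at least 2 tumor types")
  if (nrow(freq) < 1) stop("need at least 1 gene")
  d <- stats::dist(t(freq), method = "euclidean")
  if (all(d == 0)) warning("constant frequency matrix: degenerate tree")
  hc <- stats::hclust(d, method = "complete")
  dend <- stats::reorder(stats::as.dendrogram(hc), colMeans(freq))
  list(hclust = hc, dendrogram = dend,
       leaf_order = labels(dend),
       cophenetic = stats::cophenetic(hc),
       distance = d)
}

#' Export a tumor-type dendrogram as Newick
#'
#' @param clustering result of [cluster_tumor_types()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
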