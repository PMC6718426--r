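# Reference tables for the driver genes the pipeline reasons about.
# Coordinates are hg19 gene footprints (1-based, inclusive), used only to
# intersect copy-number segments with genes; they are deliberately coarse.

.driver_gene_coords <- data.frame(
  gene  = c("ARID1A", "PIK3CA", "APC", "BRAF", "CDKN2A", "KRAS", "RNF43",
            "TP53", "ERBB2", "SMAD4", "MYC"),
  chrom = c("chr1", "chr3", "chr5", "chr7", "chr9", "chr12", "chr17",
            "chr17", "chr17", "chr18", "chr8"),
  start = c(27022522, 178866311, 112043195, 140419127, 21967751, 25358180,
            56429861, 7571720, 37844393, 48556583, 128748315),
  end   = c(27108601, 178952497, 112181936, 140624564, 21995300, 25403854,
            56494956, 7590868, 37884915, 48611412, 128753680),
  stringsAsFactors = FALSE
)

#' Driver gene coordinates (hg19)
#'
#' Gene footprints used to intersect copy-number calls with genes when
#' building the event matrix. Users may supply their own table with the
#' same columns (`gene`, `chrom`, `start`, `end`).
#'
#' @return data.frame with columns gene, chrom, start, end.
#' @export
driver_gene_coords <- function() .driver_gene_coords

#' Somatic hotspot table
#'
#' Recurrent activating codons exempt from the cohort-recurrence filter:
#' KRAS codons 12/13/61, BRAF 600, PIK3CA 542/545/1047, and the common
#' TP53 DNA-binding-domain hotspot codons. Editable: pass a modified copy
#' to the filtering functions.
#'
#' @return data.frame with columns gene and codon.
#' @examples
#' head(hotspot_table())
#' @export
hotspot_table <- function() {
  data.frame(
    gene  = c("KRAS", "KRAS", "KRAS", "BRAF", "PIK3CA", "PIK3CA", "PIK3CA",
              "TP53", "TP53", "TP53", "TP53", "TP53", "TP53"),
    codon = c(12, 13, 61, 600, 542, 545, 1047,
              175, 245, 248, 249, 273, 282),
    stringsAsFactors = FALSE
  )
}

#' Default per-gene event-counting rules for the cross-tumor-type taxonomy
#'
#' Most genes count any non-synonymous mutation; KRAS and BRAF count
#' missense only (their oncogenic mode), CDKN2A counts inactivating
#' mutations only. Copy-number events are restricted to high-level
#' amplifications and homozygous deletions: ERBB2 and MYC are counted
#' when amplified, CDKN2A and SMAD4 when homozygously deleted.
#'
#' @return data.frame with columns `gene`, `variant_rule`
#'   (`"all"`, `"missense_only"`, `"inactivating_only"`, `"none"`) and
#'   `cn_rule` (`"none"`, `"amp"`, `"homdel"`, `"amp_or_homdel"`).
#' @export
default_event_rules <- function() {
  data.frame(
    gene = c("CDKN2A", "KRAS", "TP53", "ERBB2", "RNF43", "BRAF", "PIK3CA",
             "ARID1A", "APC", "SMAD4", "MYC"),
    variant_rule = c("inactivating_only", "missense_only", "all", "all",
                     "all", "missense_only", "all", "all", "all", "all",
                     "none"),
    cn_rule = c("homdel", "none", "none", "amp", "none", "none", "none",
                "none", "none", "homdel", "amp"),
    stringsAsFactors = FALSE
  )
}
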