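#' @name variant-io
#' @title Variant call tables
#'
#' @description
#' A variant call set is a data.frame with one row per called variant and
#' columns:
#' \describe{
#'   \item{chrom, pos}{1-based position (VCF convention).}
#'   \item{ref, alt}{alleles.}
#'   \item{qual}{caller quality score; `NA` means absent (an absent score
#'     fails the QUAL filter rather than passing silently).}
#'   \item{depth, alt_depth}{total and variant-supporting read counts.}
#'   \item{vaf_tumor, vaf_normal}{allele fractions in \[0, 1\];
#'     `vaf_normal` is `NA` for unpaired and panel platforms.}
#'   \item{callers}{comma-separated subset of UnifiedGenotyper, Platypus,
#'     VarScan, VarDict, MuTect2.}
#'   \item{passes_caller_filters}{did the variant pass the callers' own
#'     default filters.}
#'   \item{consequence}{`coding`, `splice` or `other`.}
#'   \item{effect}{finer mutation type (missense, nonsense, frameshift,
#'     splice, synonymous, other); optional, used by the event taxonomy.}
#'   \item{gene}{symbol or `NA`.}
#'   \item{pop_af}{maximum population allele frequency across the
#'     reference resources, `NA` when unobserved (exclusion triggers when
#'     any resource exceeds the cutoff, hence the maximum).}
#'   \item{clinvar_pathogenic, is_hotspot}{logical annotations.}
#' }
NULL

.caller_levels <- c("UnifiedGenotyper", "Platypus", "VarScan", "VarDict",
                    "MuTect2")
.platform_modes <- c("exome_paired", "exome_unpaired", "wgs", "panel")

.variant_cols <- c("chrom", "pos", "ref", "alt", "qual", "depth",
                   "alt_depth", "vaf_tumor", "vaf_normal", "callers",
                   "passes_caller_filters", "consequence", "effect",
                   "gene", "pop_af", "clinvar_pathogenic", "is_hotspot")

#' Construct / validate a variant call table
#'
#' @param df data.frame carrying the columns described in [variant-io];
#'   missing optional columns (`effect`, `vaf_normal`, `pop_af`, `gene`)
#'   are added as `NA`.
#' @return The validated data.frame with columns in canonical order.
#'   Extra columns (e.g. simulation truth labels) are preserved.
#' @export
variant_calls <- function(df) {
  stopifnot(is.data.frame(df))
  for (opt in c("effect", "vaf_normal", "pop_af", "gene"))
    if (!opt %in% names(df)) df[[opt]] <- NA
  if (!"qual" %in% names(df)) df$qual <- NA_real_
  missing <- setdiff(.variant_cols, names(df))
  if (length(missing))
    stop("variant table lacks column(s): ", paste(missing, collapse = ", "))
  df$pos <- as.integer(df$pos)
  df$depth <- as.integer(df$depth)
  df$alt_depth <- as.integer(df$alt_depth)
  if (nrow(df)) {
    bad <- which(df$alt_depth > df$depth)
    if (length(bad))
      stop("alt_depth exceeds depth at row(s) ", paste(bad, collapse = ", "))
    vv <- c(df$vaf_tumor, df$vaf_normal)
    vv <- vv[!is.na(vv)]
    if (length(vv) && (any(vv < 0) || any(vv > 1)))
      stop("VAF values must lie in [0, 1]")
    if (any(is.na(df$callers) | !nzchar(df$callers)))
      stop("every variant must name at least one caller")
    tokens <- unique(unlist(strsplit(df$callers, ",", fixed = TRUE)))
    unknown <- setdiff(trimws(tokens), .caller_levels)
    if (length(unknown))
      stop("unknown caller(s): ", paste(unknown, collapse = ", "))
  }
  extra <- setdiff(names(df), .variant_cols)
  df[, c(.variant_cols, extra), drop = FALSE]
}

#' Variant identity key
#'
#' Rule-independent identity (chrom, pos, ref, alt) used for cohort
#' recurrence, panel-of-normals lookups and batch-normal matching.
#'
#' @param v variant table (or any data.frame with those columns).
#' @return character vector of keys.
#' @export
variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Read variant calls from VCF or the tab-delimited dialect
#'
#' VCF v4.2 files (detected by the `##fileformat` header) are read with
#' vcfR. Caller and annotation evidence travel in INFO keys `CALLERS`
#' (comma list), `CQ` (consequence), `EFF` (effect), `GENE`, `POPAF`,
#' `CLNPATH` (flag) and `HOTSPOT` (flag); depths in the genotype `DP` and
#' `AD` (ref,alt) fields of the first (tumor) sample, with an optional
#' second (normal) sample supplying `vaf_normal`. Any other file is read
#' as the tab-delimited dialect written by [write_variants_tsv()], with
#' `.` for absent values. Absent annotations become `NA`, never 0.
#'
#' @param path input file.
#' @param mode platform mode: one of `exome_paired`, `exome_unpaired`,
#'   `wgs`, `panel`. Panel input must not carry normal VAFs.
#' @return A [variant_calls()] table with a `mode` attribute; rows in
#'   file order.
#' @export
parse_variants <- function(path, mode = c("exome_paired", "exome_unpaired",
                                          "wgs", "panel")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  df <- if (startsWith(first, "##fileformat=VCF")) .read_variants_vcf(path)
        else .read_variants_tsv(path)
  df <- variant_calls(df)
  if (mode == "panel" && any(!is.na(df$vaf_normal)))
    stop("panel-mode variants must not carry a normal VAF")
  attr(df, "mode") <- mode
  df
}

.read_variants_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          na.strings = ".", stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  for (col in c("passes_caller_filters", "clinvar_pathogenic", "is_hotspot"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  n <- nrow(df)
  if (n) {
    num <- suppressWarnings(as.numeric(df$pos))
    if (anyNA(num)) stop("malformed record at data line ",
                         which(is.na(num))[1], " of ", path)
  }
  df
}

.read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  n <- nrow(fix)
  info1 <- function(key) {
    x <- vcfR::extract.info(vcf, element = key)
    if (is.null(x)) rep(NA_character_, n) else as.character(x)
  }
  flag <- function(key) {
    info <- vcf@fix[, "INFO"]
    grepl(paste0("(^|;)", key, "(;|$)"), info)
  }
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(dp) || is.null(ad)) stop("VCF lacks DP/AD genotype fields")
  ad_alt <- function(col) as.integer(vapply(strsplit(ad[, col], ",", fixed = TRUE),
                                            function(x) x[2], ""))
  alt_depth <- ad_alt(1)
  depth <- as.integer(dp[, 1])
  vaf_tumor <- ifelse(depth > 0, alt_depth / depth, NA_real_)
  if (ncol(dp) >= 2) {
    n_alt <- ad_alt(2)
    n_dp <- as.integer(dp[, 2])
    vaf_normal <- ifelse(is.na(n_dp) | n_dp == 0, NA_real_, n_alt / n_dp)
  } else vaf_normal <- rep(NA_real_, n)
  data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    depth = depth, alt_depth = alt_depth,
    vaf_tumor = vaf_tumor, vaf_normal = vaf_normal,
    callers = info1("CALLERS"),
    passes_caller_filters = is.na(fix$FILTER) | fix$FILTER %in% c("PASS", "."),
    consequence = info1("CQ"), effect = info1("EFF"), gene = info1("GENE"),
    pop_af = suppressWarnings(as.numeric(info1("POPAF"))),
    clinvar_pathogenic = flag("CLNPATH"), is_hotspot = flag("HOTSPOT"),
    stringsAsFactors = FALSE
  )
}

#' Write variant calls in the tab-delimited dialect
#'
#' Columns mirror [variant_calls()]; absent values are written as `.`.
#' A write/parse round trip reproduces all fields.
#'
#' @param v variant table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(v, path) {
  v <- variant_calls(v)
  utils::write.table(v, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE)
  invisible(path)
}

#' Write variant calls as VCF v4.2
#'
#' Emits the package's documented INFO dialect (`CALLERS`, `CQ`, `EFF`,
#' `GENE`, `POPAF`, `CLNPATH`, `HOTSPOT`) with `DP`/`AD` genotype fields
#' for a TUMOR sample and, when any normal VAF is present, a NORMAL
#' sample whose depth is fixed at 100 reads for the allele-fraction
#' round trip.
#'
#' @inheritParams write_variants_tsv
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(v, path) {
  v <- variant_calls(v)
  paired <- any(!is.na(v$vaf_normal))
  meta <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CALLERS,Number=1,Type=String,Description=\"Callers reporting the variant\">",
    "##INFO=<ID=CQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Mutation effect\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=POPAF,Number=1,Type=Float,Description=\"Max population allele frequency\">",
    "##INFO=<ID=CLNPATH,Number=0,Type=Flag,Description=\"ClinVar pathogenic\">",
    "##INFO=<ID=HOTSPOT,Number=0,Type=Flag,Description=\"Known hotspot\">",
    "##FILTER=<ID=caller_filter,Description=\"Failed default caller filters\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR",
           if (paired) "\tNORMAL" else "")
  )
  info <- vapply(seq_len(nrow(v)), function(i) {
    kv <- c(paste0("CALLERS=", v$callers[i]),
            paste0("CQ=", v$consequence[i]),
            if (!is.na(v$effect[i])) paste0("EFF=", v$effect[i]),
            if (!is.na(v$gene[i])) paste0("GENE=", v$gene[i]),
            if (!is.na(v$pop_af[i]))
              paste0("POPAF=", format(v$pop_af[i], digits = 15)),
            if (isTRUE(v$clinvar_pathogenic[i])) "CLNPATH",
            if (isTRUE(v$is_hotspot[i])) "HOTSPOT")
    paste(kv, collapse = ";")
  }, "")
  tumor <- paste0(v$depth, ":", v$depth - v$alt_depth, ",", v$alt_depth)
  rows <- paste(v$chrom, v$pos, ".", v$ref, v$alt,
                ifelse(is.na(v$qual), ".", format(v$qual)),
                ifelse(v$passes_caller_filters, "PASS", "caller_filter"),
                info, "DP:AD", tumor, sep = "\t")
  if (paired) {
    ndp <- 100L
    nad <- ifelse(is.na(v$vaf_normal), NA_integer_,
                  as.integer(round(v$vaf_normal * ndp)))
    normal <- ifelse(is.na(nad), ".:.",
                     paste0(ndp, ":", ndp - nad, ",", nad))
    rows <- paste(rows, normal, sep = "\t")
  }
  writeLines(c(meta, rows), path)
  invisible(path)
}
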