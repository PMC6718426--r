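#' Copy-number segments and structural variants
#'
#' Segments are data.frames with columns `sample` (optional), `chrom`,
#' `start`, `end` (half-open, 0-based — BED convention; conversions
#' happen only at the I/O boundary), `log2` and logical `loh`; a `call`
#' column (`homdel`, `loss`, `neutral`, `gain`, `amp`) is added by
#' [call_segments()]. Structural variants are breakend pairs with
#' columns `chrom_a`, `pos_a`, `chrom_b`, `pos_b` and `sv_type`
#' (`deletion`, `duplication`, `inversion`, `translocation`).
#'
#' @name segment-io
NULL

.cn_calls <- c("homdel", "loss", "neutral", "gain", "amp")
.sv_types <- c("deletion", "duplication", "inversion", "translocation")

#' Validate a copy-number segment table
#'
#' @param df segment data.frame (see [segment-io]).
#' @param build optional [genome_build()]; when given, segments must lie
#'   within their chromosome.
#' @return The validated data.frame.
#' @export
cn_segments <- function(df, build = NULL) {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end", "log2")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("segment table lacks column(s): ", paste(missing, collapse = ", "))
  if (!"loh" %in% names(df)) df$loh <- FALSE
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  if (nrow(df)) {
    if (any(df$start < 0)) stop("segment start < 0")
    bad <- which(df$start >= df$end)
    if (length(bad)) stop("segment start >= end at row(s) ",
                          paste(bad, collapse = ", "))
    if (any(!is.finite(df$log2))) stop("log2 ratios must be finite")
    if (!is.null(build)) {
      len <- chrom_length(build, df$chrom)
      if (any(df$end > len)) stop("segment extends beyond chromosome end")
    }
    key <- if ("sample" %in% names(df)) paste(df$sample, df$chrom) else df$chrom
    for (k in unique(key)) {
      s <- df[key == k, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
        stop("overlapping segments on ", k)
    }
    if ("call" %in% names(df) && !all(df$call %in% .cn_calls))
      stop("invalid copy-number call label")
  }
  df
}

#' Read a SEG-like segment table
#'
#' Tab-delimited with header columns `sample`, `chrom`, `start`, `end`,
#' `log2` and optional `loh`; intervals are half-open 0-based.
#'
#' @param path input file.
#' @param build optional [genome_build()] for coordinate validation.
#' @return A [cn_segments()] data.frame (possibly 0 rows).
#' @export
parse_segments <- function(path, build = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines) || all(!nzchar(lines)))
    return(cn_segments(data.frame(chrom = character(), start = numeric(),
                                  end = numeric(), log2 = numeric(),
                                  loh = logical())))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if ("loh" %in% names(df)) df$loh <- as.logical(df$loh)
  cn_segments(df, build)
}

#' Write a segment table in the SEG-like dialect
#' @param seg segment data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_segments <- function(seg, path) {
  seg <- cn_segments(seg)
  utils::write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a structural-variant breakend-pair table
#'
#' @param df data.frame with columns `chrom_a`, `pos_a`, `chrom_b`,
#'   `pos_b`, `sv_type`.
#' @return The validated data.frame with a `size` column (absolute
#'   breakend distance for intra-chromosomal pairs, `NA` for
#'   translocations).
#' @export
sv_pairs <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("chrom_a", "pos_a", "chrom_b", "pos_b", "sv_type")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("SV table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(df)) {
    if (!all(df$sv_type %in% .sv_types))
      stop("invalid sv_type; allowed: ", paste(.sv_types, collapse = ", "))
    inter <- df$chrom_a != df$chrom_b
    if (any(inter != (df$sv_type == "translocation")))
      stop("sv_type must be translocation iff breakends lie on different chromosomes")
  }
  df$size <- ifelse(df$chrom_a == df$chrom_b, abs(df$pos_b - df$pos_a),
                    NA_real_)
  df
}

#' Read a structural-variant table (tab-delimited)
#' @param path input file with header chrom_a, pos_a, chrom_b, pos_b, sv_type.
#' @return A [sv_pairs()] data.frame.
#' @export
parse_svs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sv_pairs(df)
}
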