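#' Case records and cohorts
#'
#' A case record bundles one tumor's classification, sequencing platform,
#' stage, survival and genomic data. A cohort is a list of cases plus the
#' cohort-level resources the filtering cascade needs: the panel of
#' normals, the panel batch-normal variant list, and the gene blacklist.
#'
#' @param case_id identifier.
#' @param classification one of BEN, MBT, G1, G2, G3, EOM.
#' @param platform_mode one of exome_paired, exome_unpaired, wgs, panel.
#' @param stage FIGO stage `"I"`--`"IV"` or `NA`.
#' @param time survival time in months (`NA` if unknown).
#' @param event `"death-of-disease"` or `"censored"`.
#' @param variants,segments,svs genomic tables (see [variant-io],
#'   [segment-io]); may be `NULL`.
#' @return An object of class `moc_case`.
#' @export
case_record <- function(case_id, classification, platform_mode,
                        stage = NA_character_, time = NA_real_,
                        event = "censored", variants = NULL,
                        segments = NULL, svs = NULL) {
  classification <- match.arg(classification,
                              c("BEN", "MBT", "G1", "G2", "G3", "EOM"))
  platform_mode <- match.arg(platform_mode, .platform_modes)
  if (!is.na(stage)) stage <- match.arg(stage, c("I", "II", "III", "IV"))
  event <- match.arg(event, c("death-of-disease", "censored"))
  if (!is.na(time) && time < 0) stop("survival time must be >= 0")
  if (!is.null(variants)) {
    variants <- variant_calls(variants)
    if (platform_mode == "panel" && any(!is.na(variants$vaf_normal)))
      stop("panel-mode case must not carry normal VAFs")
  }
  if (!is.null(segments)) segments <- cn_segments(segments)
  if (!is.null(svs)) svs <- sv_pairs(svs)
  structure(list(case_id = case_id, classification = classification,
                 platform_mode = platform_mode, stage = stage,
                 time = time, event = event, variants = variants,
                 segments = segments, svs = svs),
            class = "moc_case")
}

#' @rdname case_record
#' @param cases list of `moc_case` objects.
#' @param build the [genome_build()] the segments refer to.
#' @param pon panel of normals: data.frame with columns `key`
#'   (see [variant_key()]) and `hits`.
#' @param batch_normals character vector of variant keys observed in the
#'   panel batch normal samples.
#' @param blacklist character vector of blacklisted gene symbols.
#' @param reference optional `DNAStringSet` reference for trinucleotide
#'   context lookup.
#' @param truth optional ground-truth annotations from the simulator.
#' @export
moc_cohort <- function(cases, build = NULL, pon = NULL,
                       batch_normals = character(), blacklist = character(),
                       reference = NULL, truth = NULL) {
  stopifnot(is.list(cases), length(cases) > 0,
            all(vapply(cases, inherits, TRUE, "moc_case")))
  ids <- vapply(cases, `[[`, "", "case_id")
  if (anyDuplicated(ids)) stop("duplicate case ids")
  names(cases) <- ids
  structure(list(cases = cases, build = build, pon = pon,
                 batch_normals = batch_normals, blacklist = blacklist,
                 reference = reference, truth = truth),
            class = "moc_cohort")
}

#' Clinical metadata table of a cohort
#' @param cohort a [moc_cohort()].
#' @return data.frame with one row per case.
#' @export
cohort_metadata <- function(cohort) {
  stopifnot(inherits(cohort, "moc_cohort"))
  do.call(rbind, lapply(cohort$cases, function(cs)
    data.frame(case_id = cs$case_id, classification = cs$classification,
               platform_mode = cs$platform_mode, stage = cs$stage,
               time = cs$time, event = cs$event,
               stringsAsFactors = FALSE, row.names = NULL)))
}

#' @export
print.moc_case <- function(x, ...) {
  cat(sprintf("<moc_case %s> %s, %s, %d variants, %d segments, %d SVs\n",
              x$case_id, x$classification, x$platform_mode,
              if (is.null(x$variants)) 0L else nrow(x$variants),
              if (is.null(x$segments)) 0L else nrow(x$segments),
              if (is.null(x$svs)) 0L else nrow(x$svs)))
  invisible(x)
}

#' @export
print.moc_cohort <- function(x, ...) {
  md <- cohort_metadata(x)
  cat(sprintf("<moc_cohort> %d cases: %s\n", nrow(md),
              paste(sprintf("%s=%d", names(table(md$classification)),
                            table(md$classification)), collapse = ", ")))
  invisible(x)
}
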