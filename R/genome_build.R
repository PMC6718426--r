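#' Genome builds
#'
#' A genome build is an ordered set of chromosome names and lengths. It
#' supplies the denominators for the fraction of the genome altered and
#' the chromosome count used to derive the per-region significance level
#' (0.05 divided by the number of chromosomes). The bundled `"hg19"`
#' build holds the 22 autosomes plus X (23 chromosomes); Y is excluded
#' by default because copy-number denominators in a female-cancer cohort
#' do not include it.
#'
#' @param chrom character vector of unique chromosome names, in order.
#' @param length positive integer chromosome lengths in base pairs.
#' @return An object of class `moc_build`: a data.frame with columns
#'   `chrom` and `length`, with an `n_chrom` attribute.
#' @examples
#' genome_build(c("chrA", "chrB"), c(100, 200))
#' @export
genome_build <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (base::length(chrom) != base::length(length) || base::length(chrom) == 0)
    stop("chrom and length must be non-empty vectors of equal length")
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be positive")
  out <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  structure(out, class = c("moc_build", "data.frame"),
            n_chrom = base::length(chrom))
}

# hg19 (GRCh37) chromosome lengths, autosomes + X
.hg19_lengths <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
  chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
  chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
  chr21 = 48129895, chr22 = 51304566, chrX = 155270560
)

#' Load a genome build by name or from a chromosome-length table
#'
#' @param name_or_path `"hg19"` for the bundled autosome+X build, or the
#'   path of a two-column (chrom, length) tab- or whitespace-delimited
#'   file with or without a header.
#' @return A [genome_build()] object.
#' @examples
#' b <- load_genome_build("hg19")
#' attr(b, "n_chrom") # 23
#' @export
load_genome_build <- function(name_or_path) {
  if (identical(name_or_path, "hg19"))
    return(genome_build(names(.hg19_lengths), unname(.hg19_lengths)))
  if (!file.exists(name_or_path))
    stop("unknown build name or missing file: ", name_or_path)
  tab <- utils::read.table(name_or_path, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("build table needs two columns: chrom, length")
  if (is.na(suppressWarnings(as.numeric(tab[1, 2])))) tab <- tab[-1, , drop = FALSE]
  genome_build(tab[[1]], as.numeric(tab[[2]]))
}

#' Number of chromosomes in a build
#' @param build a [genome_build()] object.
#' @return Integer chromosome count.
#' @export
n_chromosomes <- function(build) {
  stopifnot(inherits(build, "moc_build"))
  attr(build, "n_chrom")
}

chrom_length <- function(build, chrom) {
  i <- match(chrom, build$chrom)
  if (anyNA(i)) stop("chromosome(s) not in build: ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  build$length[i]
}
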