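#' Built-in hg19 centromere table
#'
#' Approximate centromere midpoints for hg19 chromosomes 1-22 and X, derived
#' from the UCSC cytoband annotation (midpoint of the acen bands). Positions
#' are 1-based. Sites at or below the centromere position are assigned to the
#' p arm, sites above it to the q arm. Supply a UCSC `cytoBand.txt` via
#' [read_cytoband()] to override.
#'
#' @return data.frame with columns `chrom` and `centromere`.
#' @export
hg19_centromeres <- function() {
  data.frame(
    chrom = c(as.character(1:22), "X"),
    centromere = c(
      125000000L,  93300000L,  91000000L,  50400000L,  48400000L,
       61000000L,  59900000L,  45600000L,  49000000L,  40200000L,
       53700000L,  35800000L,  17900000L,  17600000L,  19000000L,
       36600000L,  24000000L,  17200000L,  26500000L,  27500000L,
       13200000L,  14700000L,  60600000L),
    stringsAsFactors = FALSE
  )
}

#' Build a chromosome-arm table
#'
#' @param centromeres data.frame with columns `chrom`, `centromere`
#'   (defaults to the built-in hg19 table). Chromosome names are normalized by
#'   stripping a leading `"chr"`.
#' @return An `arm_table` object (named integer vector of centromere positions
#'   keyed by chromosome).
#' @export
arm_table <- function(centromeres = hg19_centromeres()) {
  stopifnot(all(c("chrom", "centromere") %in% names(centromeres)))
  chrom <- sub("^chr", "", as.character(centromeres$chrom))
  pos <- as.integer(centromeres$centromere)
  if (any(pos < 1L)) stop("centromere positions must be >= 1")
  if (anyDuplicated(chrom)) stop("duplicate chromosome in centromere table")
  structure(stats::setNames(pos, chrom), class = "arm_table")
}

#' Read arm definitions from a UCSC cytoBand file
#'
#' Parses `cytoBand.txt` (tab-separated: chrom, start, end, band, stain) and
#' places the centromere at the boundary between p and q bands (end of the
#' last p band).
#'
#' @param path path to an uncompressed cytoBand.txt.
#' @return an `arm_table`.
#' @export
read_cytoband <- function(path) {
  cb <- utils::read.delim(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "band", "stain"),
                          stringsAsFactors = FALSE)
  pb <- cb[grepl("^p", cb$band), ]
  if (nrow(pb) == 0L) stop("no p-arm bands found in ", path)
  cen <- stats::aggregate(end ~ chrom, data = pb, FUN = max)
  arm_table(data.frame(chrom = cen$chrom, centromere = cen$end))
}

#' Assign chromosome arms
#'
#' Positions at or below the centromere map to the p arm, positions above it
#' to the q arm (closed boundary on the p side, by convention).
#'
#' @param chrom chromosome name(s); `"chr"` prefixes are ignored.
#' @param pos 1-based position(s), recycled against `chrom`.
#' @param arms an [arm_table()].
#' @return character vector of arm labels, e.g. `"7q"`.
#' @export
assign_arm <- function(chrom, pos, arms = arm_table()) {
  stopifnot(inherits(arms, "arm_table"))
  chrom <- sub("^chr", "", as.character(chrom))
  cen <- unclass(arms)[chrom]
  if (anyNA(cen))
    stop("chromosome(s) missing from arm table: ",
         paste(unique(chrom[is.na(cen)]), collapse = ", "))
  paste0(chrom, ifelse(pos <= cen, "p", "q"))
}

#' Arm label per variant of a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param arms an [arm_table()].
#' @return character vector of arm labels parallel to `x$variants`.
#' @export
variant_arms <- function(x, arms = arm_table()) {
  assign_arm(x$variants$chrom, x$variants$pos, arms)
}
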