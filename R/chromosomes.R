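#' Human chromosome metadata
#'
#' Reference lengths (GRCh37, megabases) for chromosomes 1--22, X and Y,
#' together with size ranks. The thirteen largest autosomes (1--13), which
#' carry roughly three quarters of the genome, are the set used for
#' autosome-ploidy calls and the cohesion analysis: chromosome 13 is the
#' largest autosome compatible with viable constitutional trisomy, so gains
#' of these chromosomes are assumed to carry only a small fitness cost.
#'
#' @return A `data.frame` with columns `chrom` (character: `"1"`..`"22"`,
#'   `"X"`, `"Y"`), `length_mb` (numeric), `is_autosome` (logical) and
#'   `size_rank` (integer rank by decreasing length over all 24 chromosomes).
#' @export
#' @examples
#' chromosome_table()
chromosome_table <- function() {
  chrom <- c(as.character(1:22), "X", "Y")
  length_mb <- c(
    249.25, 243.20, 198.02, 191.15, 180.92, 171.12, 159.14, 146.36,
    141.21, 135.53, 135.01, 133.85, 115.17, 107.35, 102.53, 90.35,
    81.20, 78.08, 59.13, 63.03, 48.13, 51.30, 155.27, 59.37
  )
  data.frame(
    chrom = chrom,
    length_mb = length_mb,
    is_autosome = c(rep(TRUE, 22), FALSE, FALSE),
    size_rank = as.integer(rank(-length_mb, ties.method = "first")),
    stringsAsFactors = FALSE
  )
}

#' Names of the largest autosomes
#'
#' @param n How many autosomes to return (by decreasing length).
#' @return Character vector of chromosome names.
#' @export
largest_autosomes <- function(n = 13) {
  tab <- chromosome_table()
  tab <- tab[tab$is_autosome, ]
  tab$chrom[order(-tab$length_mb)][seq_len(n)]
}
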