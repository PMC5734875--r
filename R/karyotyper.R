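#' Classify XIST expression status
#'
#' XIST is the long non-coding RNA expressed from, and silencing, the
#' inactive X; its expression marks the presence of an Xi. A gene is called
#' expressed when its log2 array intensity is at least 5 (signal >= 32).
#'
#' @param xist_intensity Log2 intensity of XIST (length-1 finite numeric,
#'   or `NA` if the XIST probe is missing).
#' @param threshold Inclusive log2 cutoff.
#' @return `"expressed"`, `"silent"` or `"unusable"` (missing/non-finite).
#' @export
#' @examples
#' classify_xist(9)    # expressed
#' classify_xist(5.0)  # expressed: boundary is inclusive
#' classify_xist(2)    # silent
classify_xist <- function(xist_intensity, threshold = 5) {
  if (length(xist_intensity) != 1L || !is.finite(xist_intensity)) return("unusable")
  if (xist_intensity >= threshold) "expressed" else "silent"
}

#' Infer the sex-chromosome genotype of one line
#'
#' Active X's can only be counted in lines where every X present can be
#' assumed active, i.e. where XIST is silent. Male lines qualify whenever
#' XIST is silent (Xa\[Y\] with one X, XaXa\[Y\] with two; Y presence is
#' annotated separately). Female lines qualify only after whole-X LOH
#' (the surviving homolog, possibly re-duplicated as isodisomy): XaO with
#' one X, XaXa with two. Females without X LOH retain a heterozygous XaXb
#' pair whose XIST-expressing Xi makes the active-X count undeterminable.
#' XIST never turns on in lines that do not already express it, so a line
#' with silent XIST and k X copies has k active X's.
#'
#' @param sex `"female"` or `"male"`.
#' @param xist `"expressed"`, `"silent"` or `"unusable"` (see
#'   [classify_xist()]).
#' @param x_loh Logical: whole-X LOH (`NA` = not assessable).
#' @param x_copy Integer X copy number (`NA` = undetermined).
#' @param y_lost Logical Y-loss call (`NA` allowed for females).
#' @return A list with `sex_genotype` (one of `"XaO"`, `"XaXa"`, `"XaXb"`,
#'   `"Xa[Y]"`, `"XaXa[Y]"`, `"other"`, `"unusable"`) and `xa_count`
#'   (integer or `NA`). `"other"` covers countable lines outside the five
#'   canonical genotypes (e.g. three active X's); their `xa_count` is still
#'   usable.
#' @export
infer_sex_genotype <- function(sex, xist, x_loh, x_copy, y_lost = NA) {
  unusable <- list(sex_genotype = "unusable", xa_count = NA_integer_)
  if (sex == "female") {
    if (isFALSE(y_lost)) {
      stopf("inconsistent input: female line with a Y chromosome present")
    }
    if (is.na(x_loh)) return(unusable)
    if (!x_loh) return(list(sex_genotype = "XaXb", xa_count = NA_integer_))
    # whole-X LOH: survivors kept the active X; require silent XIST so all
    # remaining X's can be assumed active
    if (!identical(xist, "silent")) return(unusable)
    if (is.na(x_copy) || x_copy < 1) return(unusable)
    g <- if (x_copy == 1) "XaO" else if (x_copy == 2) "XaXa" else "other"
    return(list(sex_genotype = g, xa_count = as.integer(x_copy)))
  }
  if (sex == "male") {
    if (!identical(xist, "silent")) return(unusable)
    if (is.na(x_copy) || x_copy < 1) return(unusable)
    g <- if (x_copy == 1) "Xa[Y]" else if (x_copy == 2) "XaXa[Y]" else "other"
    return(list(sex_genotype = g, xa_count = as.integer(x_copy)))
  }
  stopf("unknown sex '%s'", sex)
}

#' Autosome ploidy from the 13 largest autosomes
#'
#' The autosome set's ploidy n_A (in multiples of 22) is the copy number
#' shared by a supermajority of the 13 largest autosomes — the set that
#' evolves cohesively. Smaller autosomes are more erratic and are ignored.
#'
#' @param copies Integer copy numbers named by chromosome; only the 13
#'   largest autosomes are used.
#' @param majority_fraction Fraction of determined chromosomes that must
#'   share the modal copy number.
#' @param min_determined Minimum number of the 13 with determined copies.
#' @return Integer ploidy or `NA` (undetermined).
#' @export
#' @examples
#' autosome_ploidy(setNames(rep(3L, 13), largest_autosomes()))  # 3
autosome_ploidy <- function(copies, majority_fraction = 0.7, min_determined = 10L) {
  big <- largest_autosomes(13)
  if (is.null(names(copies))) stopf("autosome_ploidy: copies must be named by chromosome")
  cn <- copies[names(copies) %in% big]
  cn <- cn[!is.na(cn)]
  if (length(cn) < min_determined) return(NA_integer_)
  tab <- table(cn)
  frac <- max(tab) / length(cn)
  if (frac >= majority_fraction) as.integer(names(tab)[which.max(tab)]) else NA_integer_
}

#' Karyotype every line of a panel
#'
#' Combines chromosome-state calls, XIST expression and line sex into a
#' C(Xa:A) karyotype call per line.
#'
#' @param states Output of [call_states()].
#' @param expression Gene-by-line log2 matrix containing an `"XIST"` row
#'   (or `NULL` for genotype-only panels: XIST status is then inferred from
#'   the sex/LOH configuration and flagged).
#' @param sex Named sex vector or `data.frame(line, sex)`.
#' @param xist_threshold Passed to [classify_xist()].
#' @param majority_fraction,min_determined Passed to [autosome_ploidy()].
#' @return A `data.frame` with one row per line: `line`, `sex`, `xist`,
#'   `sex_genotype`, `xa_count`, `n_A`, `label` (`NA` when either count is
#'   undetermined).
#' @export
karyotype_panel <- function(states, expression, sex, xist_threshold = 5,
                            majority_fraction = 0.7, min_determined = 10L) {
  if (is.data.frame(sex)) sex <- stats::setNames(sex$sex, sex$line)
  lines <- unique(states$line)
  big <- largest_autosomes(13)
  out <- lapply(lines, function(l) {
    st <- states[states$line == l, ]
    xist <- if (is.null(expression) || !"XIST" %in% rownames(expression) ||
                !l %in% colnames(expression)) {
      "unusable"
    } else {
      classify_xist(expression["XIST", l], xist_threshold)
    }
    xrow <- st[st$chrom == "X", ]
    yrow <- st[st$chrom == "Y", ]
    y_lost <- if (nrow(yrow)) yrow$y_lost[1L] else NA
    sg <- infer_sex_genotype(
      sex = sex[[l]], xist = xist,
      x_loh = if (nrow(xrow)) xrow$loh[1L] else NA,
      x_copy = if (nrow(xrow)) xrow$copy_number[1L] else NA_integer_,
      y_lost = y_lost
    )
    cn <- stats::setNames(st$copy_number, st$chrom)
    n_A <- autosome_ploidy(cn[names(cn) %in% big], majority_fraction, min_determined)
    data.frame(
      line = l, sex = sex[[l]], xist = xist,
      sex_genotype = sg$sex_genotype, xa_count = sg$xa_count, n_A = n_A,
      label = cxa_label(sg$xa_count, n_A),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Default karyotype-cluster mapping
#'
#' Genotypes are grouped into four clusters centred on the dominant
#' karyotypes. C(1:3), adjacent to both C(1:2) and C(2:3), is split
#' half-and-half between clusters x1 and x3. Labels outside the mapping
#' count toward the residual.
#'
#' @return A named list (`x1`..`x4`) of named weight vectors.
#' @export
default_cluster_map <- function() {
  list(
    x1 = c("C(1:2)" = 1, "C(1:1)" = 1, "C(1:3)" = 0.5),
    x2 = c("C(2:2)" = 1, "C(3:2)" = 1),
    x3 = c("C(2:3)" = 1, "C(3:3)" = 1, "C(1:3)" = 0.5),
    x4 = c("C(2:4)" = 1)
  )
}

#' Tally karyotype-cluster frequencies
#'
#' @param labels Character vector of C(Xa:A) labels (one per classified
#'   line; `NA`s are dropped), or a `data.frame` with a `label` column such
#'   as [karyotype_panel()] output.
#' @param mapping Cluster mapping as in [default_cluster_map()], or a path
#'   to a YAML file with the same structure.
#' @return An object of class `cluster_tally`: list with `x1`..`x4`,
#'   `residual`, `n_classified` and `unmapped` (frequency table of labels
#'   that fell into the residual). Frequencies (including the residual) sum
#'   to 1.
#' @export
#' @examples
#' tally_clusters(rep(c("C(1:2)", "C(1:3)", "C(2:3)"), each = 10))
tally_clusters <- function(labels, mapping = default_cluster_map()) {
  if (is.data.frame(labels)) labels <- labels$label
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- lapply(yaml::read_yaml(mapping), unlist)
  }
  labels <- labels[!is.na(labels)]
  n <- length(labels)
  if (n == 0L) stopf("tally_clusters: no classified lines")
  freqs <- vapply(mapping, function(w) {
    sum(w[labels], na.rm = TRUE) / n
  }, numeric(1))
  mapped_labels <- unique(unlist(lapply(mapping, names)))
  unmapped <- labels[!labels %in% mapped_labels]
  residual <- length(unmapped) / n
  total <- sum(freqs) + residual
  if (abs(total - 1) > 1e-9) {
    stopf("cluster mapping weights are inconsistent: frequencies sum to %.12f", total)
  }
  structure(
    c(as.list(freqs),
      list(residual = residual, n_classified = n,
           unmapped = table(unmapped))),
    class = "cluster_tally"
  )
}

#' @export
print.cluster_tally <- function(x, ...) {
  cat(sprintf(
    "<cluster_tally> n = %d\n  [x1, x2, x3, x4] = [%.3f, %.3f, %.3f, %.3f], residual %.3f\n",
    x$n_classified, x$x1, x$x2, x$x3, x$x4, x$residual))
  invisible(x)
}

#' Convert a cluster tally to a numeric vector
#'
#' @param x A `cluster_tally` (or any list with `x1`..`x4`).
#' @param residual Include the residual component?
#' @return Named numeric vector of cluster frequencies.
#' @export
tally_vector <- function(x, residual = FALSE) {
  out <- c(x1 = x$x1, x2 = x$x2, x3 = x$x3, x4 = x$x4)
  if (residual) out <- c(out, residual = x$residual)
  out
}
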