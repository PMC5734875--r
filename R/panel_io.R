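# Plain-text persistence for synthetic panels.
#
# Layout of a panel directory:
#   probes_<line>.tsv  probe_id, chrom, pos, genotype {AA,AB,BB,NC},
#                      total_cn, minor_cn
#   expression.tsv     gene_id, chrom, then one log2-intensity column per line
#   truth.tsv          line, sex, label, xa_count, n_A, x_loh, y_lost, xist,
#                      then loh_<chrom> and cn_<chrom> for every chromosome
#   config.yaml        panel_config fields

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

# strict TSV reader: every row must have the header's field count
read_tsv_strict <- function(path, n_max = Inf) {
  lines <- readLines(path)
  if (!length(lines)) stopf("parse error in %s: file is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != nf[1L])
  if (length(bad)) {
    stopf("parse error in %s at line %d: expected %d fields, found %d",
          path, bad[1L], nf[1L], nf[bad[1L]])
  }
  header <- fields[[1L]]
  body <- fields[-1L]
  out <- as.data.frame(
    stats::setNames(lapply(seq_along(header), function(j) {
      vapply(body, `[[`, "", j)
    }), header),
    stringsAsFactors = FALSE
  )
  out
}

retype <- function(df, types) {
  for (nm in names(types)) {
    if (!nm %in% names(df)) stopf("parse error: missing column '%s'", nm)
    df[[nm]] <- switch(types[[nm]],
      int = as.integer(df[[nm]]),
      num = as.numeric(df[[nm]]),
      lgl = as.logical(df[[nm]]),
      chr = df[[nm]]
    )
  }
  df
}

#' Write a synthetic panel to a directory of TSV files
#'
#' @param panel A `synthetic_panel` from [generate_panel()].
#' @param directory Output directory (created if missing).
#' @return The directory path, invisibly.
#' @seealso [read_panel()] for the inverse; the round trip is lossless up to
#'   15 significant digits on the expression matrix.
#' @export
write_panel <- function(panel, directory) {
  stopifnot(inherits(panel, "synthetic_panel"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (l in names(panel$probes)) {
    write_tsv(panel$probes[[l]], file.path(directory, sprintf("probes_%s.tsv", l)))
  }
  expr <- cbind(panel$genes, as.data.frame(panel$expression))
  write_tsv(expr, file.path(directory, "expression.tsv"))

  tl <- panel$truth$lines
  st <- panel$truth$states
  chroms <- chromosome_table()$chrom
  wide <- tl
  for (ch in chroms) {
    sc <- st[st$chrom == ch, ]
    sc <- sc[match(tl$line, sc$line), ]
    wide[[paste0("loh_", ch)]] <- sc$loh
    wide[[paste0("cn_", ch)]] <- sc$copy
  }
  write_tsv(wide, file.path(directory, "truth.tsv"))

  cfg <- unclass(panel$config)
  cfg$genotype_freqs <- as.list(cfg$genotype_freqs)
  yaml::write_yaml(cfg, file.path(directory, "config.yaml"), precision = 15)
  invisible(directory)
}

#' Read a synthetic panel back from a directory
#'
#' @param directory A directory produced by [write_panel()].
#' @return A `synthetic_panel`; `read_panel(write_panel(p, d))` reproduces
#'   `p` (expression values to 15 significant digits). Malformed TSV input
#'   raises a parse error naming the offending file and line.
#' @export
read_panel <- function(directory) {
  if (!dir.exists(directory)) stopf("panel directory not found: %s", directory)
  cfg <- yaml::read_yaml(file.path(directory, "config.yaml"))
  cfg$genotype_freqs <- unlist(cfg$genotype_freqs)
  cfg <- do.call(panel_config, cfg)

  truth_path <- file.path(directory, "truth.tsv")
  wide <- read_tsv_strict(truth_path)
  chroms <- chromosome_table()$chrom
  base_cols <- c("line", "sex", "label", "xa_count", "n_A", "x_loh", "y_lost", "xist")
  wide <- retype(wide, c(line = "chr", sex = "chr", label = "chr",
                         xa_count = "int", n_A = "int", x_loh = "lgl",
                         y_lost = "lgl", xist = "chr"))
  truth_lines <- wide[base_cols]
  empty_states <- data.frame(line = character(0), chrom = character(0),
                             loh = logical(0), copy = integer(0),
                             stringsAsFactors = FALSE)
  states <- do.call(rbind, c(list(empty_states),
                             lapply(seq_len(nrow(wide)), function(i) {
    data.frame(
      line = wide$line[i], chrom = chroms,
      loh = as.logical(unlist(wide[i, paste0("loh_", chroms)])),
      copy = as.integer(unlist(wide[i, paste0("cn_", chroms)])),
      stringsAsFactors = FALSE
    )
  })))

  probes <- stats::setNames(lapply(truth_lines$line, function(l) {
    path <- file.path(directory, sprintf("probes_%s.tsv", l))
    if (!file.exists(path)) stopf("missing probe table for line %s: %s", l, path)
    retype(read_tsv_strict(path),
           c(probe_id = "chr", chrom = "chr", pos = "int", genotype = "chr",
             total_cn = "int", minor_cn = "int"))
  }), truth_lines$line)

  expr_df <- read_tsv_strict(file.path(directory, "expression.tsv"))
  genes <- retype(expr_df[c("gene_id", "chrom")], c(gene_id = "chr", chrom = "chr"))
  line_cols <- setdiff(names(expr_df), c("gene_id", "chrom"))
  if (length(line_cols)) {
    mat <- as.matrix(as.data.frame(lapply(expr_df[line_cols], as.numeric)))
  } else {
    mat <- matrix(numeric(0), nrow = nrow(genes), ncol = 0)
  }
  dimnames(mat) <- list(genes$gene_id, line_cols)

  structure(
    list(probes = probes, expression = mat, genes = genes,
         truth = list(lines = truth_lines, states = states), config = cfg),
    class = "synthetic_panel"
  )
}
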