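# Readers and writers for the package's delimited-text formats. All writers
# emit a header line; all readers refuse headerless files.

#' Write / read a trio table
#'
#' Tab-delimited, one row per trio. Columns: `trio_id`; per-SNP offspring,
#' mother and father genotypes `g<k>_o`, `g<k>_m`, `g<k>_f` (0/1/2 effect
#' allele counts); per-SNP mother/father nontransmitted haplotype counts
#' `nt<k>_m`, `nt<k>_f` (0/1), when available; phenotypes `x`, `y`; optional
#' parental phenotypes `x_m`, `x_f`, `y_m`, `y_f`; and the split label.
#' Missing values are coded `NA`.
#'
#' @param trios A `trio_dataset`.
#' @param path File path.
#' @return `read_trio_table` returns a `trio_dataset` (without a SNP panel;
#'   instrument columns must then be chosen by the caller).
#' @export
write_trio_table <- function(trios, path) {
  stopifnot(inherits(trios, "trio_dataset"))
  m <- ncol(trios$g_o)
  cols <- list(trio_id = seq_len(trios$n))
  add_mat <- function(cols, mat, stem) {
    if (is.null(mat)) return(cols)
    colnames(mat) <- sprintf(stem, seq_len(ncol(mat)))
    c(cols, as.data.frame(mat))
  }
  cols <- add_mat(cols, trios$g_o, "g%d_o")
  cols <- add_mat(cols, trios$g_m, "g%d_m")
  cols <- add_mat(cols, trios$g_f, "g%d_f")
  cols <- add_mat(cols, trios$nt_m, "nt%d_m")
  cols <- add_mat(cols, trios$nt_f, "nt%d_f")
  cols$x <- trios$x
  cols$y <- trios$y
  for (v in c("x_m", "x_f", "y_m", "y_f"))
    if (!is.null(trios[[v]])) cols[[v]] <- trios[[v]]
  cols$split <- as.character(trios$split)
  df <- as.data.frame(cols, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trio_table
#' @export
read_trio_table <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  if (!("trio_id" %in% header) || !all(c("x", "y") %in% header))
    stop_invalid("not a trio table: header must contain trio_id, x, y ",
                 "(headerless files are not accepted)")
  df <- read.delim(path, check.names = FALSE)
  mat_of <- function(suffix, stem = "g") {
    nm <- grep(sprintf("^%s[0-9]+_%s$", stem, suffix), names(df), value = TRUE)
    if (!length(nm)) return(NULL)
    k <- as.integer(sub(sprintf("^%s([0-9]+)_%s$", stem, suffix), "\\1", nm))
    as.matrix(df[nm[order(k)]])
  }
  split <- if ("split" %in% names(df)) factor(df$split, levels = c("A", "B"))
           else factor(rep(c("A", "B"), length.out = nrow(df)),
                       levels = c("A", "B"))
  new_trio_dataset(
    g_o = mat_of("o"), g_m = mat_of("m"), g_f = mat_of("f"),
    nt_m = mat_of("m", "nt"), nt_f = mat_of("f", "nt"),
    x = df$x, y = df$y,
    x_m = df$x_m, x_f = df$x_f, y_m = df$y_m, y_f = df$y_f,
    split = split, panel = NULL)
}

#' Write / read allele-score weights
#'
#' Two-column tab-delimited text: `snp_id`, `weight`.
#'
#' @param weights An `allele_weights` object.
#' @param path File path.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "allele_weights"))
  write.table(data.frame(snp_id = weights$snps, weight = weights$weights),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  df <- read.delim(path)
  if (!all(c("snp_id", "weight") %in% names(df)))
    stop_invalid("weights file must have header columns snp_id, weight")
  structure(list(snps = as.integer(df$snp_id), weights = as.numeric(df$weight),
                 half = "external"),
            class = "allele_weights")
}

#' Write / read per-SNP summary statistics
#'
#' Tab-delimited with the de-facto two-sample-MR layout: `snp_id`, `beta_x`,
#' `se_x`, `beta_y`, `se_y`, `n_x`, `n_y`.
#'
#' @param stats An `mr_sumstats` data frame.
#' @param path File path.
#' @export
write_sumstats <- function(stats, path) {
  write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  df <- read.delim(path)
  need <- c("snp_id", "beta_x", "se_x", "beta_y", "se_y")
  if (!all(need %in% names(df)))
    stop_invalid("summary-statistics file must have header columns ",
                 paste(need, collapse = ", "))
  structure(df, class = c("mr_sumstats", "data.frame"))
}

# Run manifest: enough to reproduce a run exactly. Written before the run
# starts and finalized (with the output inventory) when it ends.
write_manifest <- function(path, cfg = NULL, seed = NULL, outputs = NULL,
                           status = "running", extra = NULL) {
  man <- list(package = "triomr",
              version = as.character(packageVersion("triomr")),
              timestamp = format(Sys.time(), tz = "UTC",
                                 "%Y-%m-%dT%H:%M:%SZ"),
              seed = seed, status = status, outputs = outputs)
  if (!is.null(cfg)) {
    man$config <- unclass(cfg)
    man$config$assortment <- unclass(man$config$assortment)
    man$config$phenotype_defs <- lapply(man$config$phenotype_defs, unclass)
  }
  man <- c(man, extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}
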