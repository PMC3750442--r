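#' Read a delimited genotype matrix
#'
#' Expects a header row of marker ids and one row per individual; an
#' optional leading `id` column (any non-numeric first column) carries
#' individual labels.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param coding dosage coding of the file contents.
#' @param chrom,pos_cM optional map vectors.
#' @return A list with `panel` ([genotype_panel()]) and `ids`.
#' @export
read_genotypes <- function(path, sep = "\t", coding = "raw", chrom = NULL,
                           pos_cM = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- NULL
  if (ncol(df) > 1L && !is.numeric(df[[1L]])) {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric dosage column(s): ", paste(names(df)[bad],
                                                 collapse = ", "))
  panel <- genotype_panel(as.matrix(df), marker_ids = names(df),
                          chrom = chrom, pos_cM = pos_cM, coding = coding)
  list(panel = panel, ids = ids)
}

#' Write a genotype panel as delimited text
#'
#' @param panel a [genotype_panel()].
#' @param path output path.
#' @param ids optional individual labels written as a leading `id` column.
#' @param sep field separator.
#' @return `path`, invisibly. Values are serialized at full precision so a
#'   read-back reproduces the panel exactly.
#' @export
write_genotypes <- function(panel, path, ids = NULL, sep = "\t") {
  stopifnot(inherits(panel, "genotype_panel"))
  X <- panel$dosage
  txt <- apply(X, 2L, function(v) sprintf("%.17g", v))
  df <- as.data.frame(txt, stringsAsFactors = FALSE)
  names(df) <- panel$marker_ids
  if (!is.null(ids)) df <- cbind(data.frame(id = ids), df)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PLINK RAW additive-dosage file
#'
#' Whitespace-delimited dialect with header
#' `FID IID PAT MAT SEX PHENOTYPE snp1_A ...`; SNP columns hold additive
#' dosages 0/1/2 (real-valued imputed dosages allowed). The trailing
#' `_allele` suffix is stripped from marker names.
#'
#' @param path file path.
#' @return A list with `panel` (raw coding), `ids` (IID) and `phenotype`
#'   (numeric, `NA` where coded -9).
#' @export
read_plink_raw <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(need %in% names(df)[seq_len(6L)]))
    stop("not a PLINK RAW header: expected leading columns ",
         paste(need, collapse = " "))
  snps <- df[, -(1:6), drop = FALSE]
  if (ncol(snps) == 0L) stop("no SNP columns found in ", path)
  marker_ids <- sub("_[ACGT0-9]+$", "", names(snps))
  phen <- as.numeric(df$PHENOTYPE)
  phen[phen == -9] <- NA_real_
  list(panel = genotype_panel(as.matrix(snps), marker_ids = marker_ids,
                              coding = "raw"),
       ids = as.character(df$IID), phenotype = phen)
}

#' Read a phenotype table
#'
#' Two-column delimited text: `id` and trait `value`.
#'
#' @param path file path.
#' @param sep field separator.
#' @return List with `phen` ([phenotype_set()]) and `ids`.
#' @export
read_phenotypes <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("phenotype file needs columns id, value")
  list(phen = phenotype_set(as.numeric(df[[2L]])),
       ids = as.character(df[[1L]]))
}

#' Read a family table
#'
#' Two-column delimited text: `id` and `family`.
#'
#' @param path file path.
#' @param sep field separator.
#' @return List with `fam` ([family_map()]) and `ids`.
#' @export
read_families <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("family file needs columns id, family")
  list(fam = family_map(df[[2L]]), ids = as.character(df[[1L]]))
}

#' Read a list of MU prior specifications from a config file
#'
#' YAML-like key-value text: one spec per line as `p0 b l` (whitespace
#' separated), comment lines starting with `#` ignored. Intended for
#' sensitivity sweeps and model averaging.
#'
#' @param path file path.
#' @return List of [mu_prior_spec()].
#' @export
read_prior_specs <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    v <- as.numeric(strsplit(ln, "[[:space:],]+")[[1L]])
    if (length(v) != 3L || anyNA(v))
      stop("malformed prior spec line: '", ln, "' (expected: p0 b l)")
    mu_prior_spec(v[1L], v[2L], v[3L])
  })
}
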