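#' Genotype panel
#'
#' Container for an N x M matrix of genotype dosages together with the marker
#' map and the coding convention in use. Three codings are supported:
#' `"raw"` (allele counts 0/1/2, real-valued imputed dosages allowed),
#' `"centered"` (raw minus 1, i.e. -1/0/1 for integer genotypes) and
#' `"standardized"` (each column scaled to mean 0, variance 1; the scaling
#' constants are kept on the object so predictions can be mapped back).
#'
#' @param dosage numeric matrix, individuals in rows, markers in columns.
#' @param marker_ids character vector of marker labels (defaults to column
#'   names or `snp1..snpM`).
#' @param chrom integer vector of chromosome indices per marker.
#' @param pos_cM numeric vector of map positions in centiMorgans.
#' @param coding one of `"raw"`, `"centered"`, `"standardized"`.
#' @param col_means,col_sds per-marker statistics; required when
#'   `coding = "standardized"`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, marker_ids = NULL, chrom = NULL,
                           pos_cM = NULL, coding = c("raw", "centered",
                                                     "standardized"),
                           col_means = NULL, col_sds = NULL) {
  coding <- match.arg(coding)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(marker_ids) && !is.null(colnames(dosage)))
    marker_ids <- colnames(dosage)
  dimnames(dosage) <- NULL
  if (nrow(dosage) < 1L || ncol(dosage) < 1L)
    stop("genotype panel needs at least one individual and one marker")
  if (anyNA(dosage) || !all(is.finite(dosage)))
    stop("genotype dosages must be finite; impute missing values upstream")
  M <- ncol(dosage)
  if (is.null(marker_ids)) marker_ids <- paste0("snp", seq_len(M))
  if (length(marker_ids) != M) stop("marker_ids length must match columns")
  if (is.null(chrom)) chrom <- rep(1L, M)
  if (is.null(pos_cM)) pos_cM <- as.numeric(seq_len(M))
  if (length(chrom) != M || length(pos_cM) != M)
    stop("chrom and pos_cM must have one entry per marker")
  if (coding == "raw" && (min(dosage) < 0 || max(dosage) > 2))
    stop("raw coding requires dosages in [0, 2]")
  if (coding == "standardized" && (is.null(col_means) || is.null(col_sds)))
    stop("standardized coding requires col_means and col_sds")
  structure(list(dosage = dosage, marker_ids = as.character(marker_ids),
                 chrom = as.integer(chrom), pos_cM = as.numeric(pos_cM),
                 coding = coding, col_means = col_means, col_sds = col_sds),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d markers (%s coding, %d chromosome%s)\n",
              nrow(x$dosage), ncol(x$dosage), x$coding,
              length(unique(x$chrom)),
              if (length(unique(x$chrom)) == 1L) "" else "s"))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Phenotype set
#'
#' @param y numeric vector of trait values, one per individual.
#' @param standardized logical; has `y` been scaled to mean 0, variance 1?
#' @param y_mean,y_sd scaling constants recorded when standardizing.
#' @return An object of class `phenotype_set`.
#' @export
phenotype_set <- function(y, standardized = FALSE, y_mean = NA_real_,
                          y_sd = NA_real_) {
  y <- as.numeric(y)
  if (length(y) < 1L || anyNA(y) || !all(is.finite(y)))
    stop("phenotypes must be finite and non-missing")
  structure(list(y = y, standardized = standardized,
                 y_mean = y_mean, y_sd = y_sd),
            class = "phenotype_set")
}

#' @export
print.phenotype_set <- function(x, ...) {
  cat(sprintf("phenotype_set: %d individuals%s\n", length(x$y),
              if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

#' Full-sib family map
#'
#' Assigns every individual to exactly one full-sib family; used for the
#' polygenic family effect and for family-aware cross-validation folds.
#'
#' @param family_of vector of family labels or indices, one per individual.
#' @return An object of class `family_map` with components `family_of`
#'   (integer indices in `1..K`), `sizes` (per-family counts) and `labels`.
#' @export
family_map <- function(family_of) {
  if (anyNA(family_of)) stop("every individual must belong to a family")
  f <- factor(family_of, levels = unique(family_of))
  idx <- as.integer(f)
  sizes <- as.integer(table(f))
  stopifnot(sum(sizes) == length(idx))
  structure(list(family_of = idx, sizes = sizes, labels = levels(f)),
            class = "family_map")
}

#' @export
print.family_map <- function(x, ...) {
  cat(sprintf("family_map: %d individuals in %d families (sizes %d-%d)\n",
              length(x$family_of), length(x$sizes),
              min(x$sizes), max(x$sizes)))
  invisible(x)
}

#' Recode a genotype panel between dosage conventions
#'
#' Raw allele counts 0/1/2 map to the centered codes -1/0/1 by subtracting 1;
#' the inverse adds 1. A standardized panel can be recoded back only if the
#' column means and standard deviations recorded at standardization time are
#' available on the object.
#'
#' @param panel a [genotype_panel()].
#' @param target target coding, `"raw"` or `"centered"`.
#' @return A recoded `genotype_panel`.
#' @export
recode <- function(panel, target = c("centered", "raw")) {
  target <- match.arg(target)
  stopifnot(inherits(panel, "genotype_panel"))
  if (panel$coding == target) return(panel)
  d <- panel$dosage
  if (panel$coding == "standardized") {
    if (is.null(panel$col_means) || is.null(panel$col_sds))
      stop("cannot leave standardized coding: column means/sds not recorded")
    d <- sweep(sweep(d, 2L, panel$col_sds, "*"), 2L, panel$col_means, "+")
    # col_means/col_sds were taken on the coding active at standardization
    # time, assumed raw or centered as recorded in attr
    from <- attr(panel$col_means, "source_coding")
    if (is.null(from)) from <- "raw"
    if (from == "raw" && target == "centered") d <- d - 1
    if (from == "centered" && target == "raw") d <- d + 1
  } else if (panel$coding == "raw" && target == "centered") {
    d <- d - 1
  } else if (panel$coding == "centered" && target == "raw") {
    d <- d + 1
  }
  genotype_panel(d, panel$marker_ids, panel$chrom, panel$pos_cM,
                 coding = target)
}

#' Standardize genotypes and phenotype on a training set
#'
#' Scales every marker column and the phenotype to a sample mean of 0 and a
#' variance of 1 (population convention, divisor N, so the unit variance is
#' exact on the training data). Returns the scaling record so that held-out
#' individuals can be standardized with the *training* statistics and
#' predictions translated back to the original scale.
#'
#' @param panel training [genotype_panel()] (raw or centered coding).
#' @param phen training [phenotype_set()].
#' @return A list with components `panel`, `phen` (both standardized) and
#'   `scaling` (class `scaling_record`: `x_means`, `x_sds`, `y_mean`, `y_sd`).
#' @export
standardize_fit <- function(panel, phen) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(phen, "phenotype_set"))
  if (panel$coding == "standardized") stop("panel is already standardized")
  X <- panel$dosage
  n <- nrow(X)
  mns <- colMeans(X)
  sds <- sqrt(colMeans(sweep(X, 2L, mns)^2))
  if (any(sds <= 0))
    stop("monomorphic marker (zero sd): run maf_filter() before standardizing")
  attr(mns, "source_coding") <- panel$coding
  Xs <- sweep(sweep(X, 2L, mns), 2L, sds, "/")
  ym <- mean(phen$y)
  ys <- sqrt(mean((phen$y - ym)^2))
  if (ys <= 0) stop("phenotype has zero variance")
  scaling <- structure(list(x_means = mns, x_sds = sds,
                            y_mean = ym, y_sd = ys),
                       class = "scaling_record")
  list(panel = genotype_panel(Xs, panel$marker_ids, panel$chrom, panel$pos_cM,
                              coding = "standardized", col_means = mns,
                              col_sds = sds),
       phen = phenotype_set((phen$y - ym) / ys, standardized = TRUE,
                            y_mean = ym, y_sd = ys),
       scaling = scaling)
}

#' Apply a training scaling record to a held-out panel
#'
#' @param scaling a `scaling_record` from [standardize_fit()].
#' @param panel held-out [genotype_panel()] in the same coding the training
#'   panel had when standardized.
#' @return The panel standardized with training means/sds.
#' @export
apply_scaling <- function(scaling, panel) {
  stopifnot(inherits(scaling, "scaling_record"),
            inherits(panel, "genotype_panel"))
  Xs <- sweep(sweep(panel$dosage, 2L, scaling$x_means), 2L, scaling$x_sds, "/")
  genotype_panel(Xs, panel$marker_ids, panel$chrom, panel$pos_cM,
                 coding = "standardized", col_means = scaling$x_means,
                 col_sds = scaling$x_sds)
}

#' Back-transform standardized phenotype predictions
#'
#' @param scaling a `scaling_record`.
#' @param y_std predictions on the standardized scale.
#' @return Predictions on the original phenotype scale.
#' @export
unscale_phenotype <- function(scaling, y_std) {
  scaling$y_mean + scaling$y_sd * y_std
}

#' Minor allele frequencies of a panel
#'
#' MAF is computed from the mean dosage (allele count of the rarer allele
#' over 2N); non-integer imputed dosages contribute fractionally.
#'
#' @param panel a [genotype_panel()] in raw or centered coding.
#' @return Numeric vector of per-marker minor allele frequencies.
#' @export
panel_maf <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (panel$coding == "standardized")
    stop("MAF is undefined on a standardized panel; recode first")
  p <- colMeans(panel$dosage) / 2
  if (panel$coding == "centered") p <- (colMeans(panel$dosage) + 1) / 2
  pmin(p, 1 - p)
}

#' Remove markers with low minor allele frequency
#'
#' @param panel a [genotype_panel()] in raw or centered coding.
#' @param min_maf markers with MAF strictly below this fraction are removed.
#' @return A list with `panel` (filtered) and `removed_ids`.
#' @export
maf_filter <- function(panel, min_maf = 0.01) {
  maf <- panel_maf(panel)
  drop <- maf < min_maf
  keep <- which(!drop)
  if (length(keep) == 0L) stop("maf_filter would remove every marker")
  list(panel = genotype_panel(panel$dosage[, keep, drop = FALSE],
                              panel$marker_ids[keep], panel$chrom[keep],
                              panel$pos_cM[keep], coding = panel$coding),
       removed_ids = panel$marker_ids[drop])
}

#' Subset a panel by individuals
#'
#' @param panel a [genotype_panel()].
#' @param idx row indices (individuals) to keep.
#' @return The subsetted panel.
#' @export
subset_individuals <- function(panel, idx) {
  genotype_panel(panel$dosage[idx, , drop = FALSE], panel$marker_ids,
                 panel$chrom, panel$pos_cM, coding = panel$coding,
                 col_means = panel$col_means, col_sds = panel$col_sds)
}
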