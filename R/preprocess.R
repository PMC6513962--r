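#' Quantile-normalize a gene-by-sample matrix
#'
#' Forces every sample onto the common reference distribution (the
#' across-sample mean of sorted values); ties within a sample receive the
#' mean of the reference values they span, and within-sample rank order is
#' preserved. Idempotent.
#'
#' @param values Numeric gene-by-sample matrix, no missing values.
#' @return Matrix of the same shape and dimnames.
#' @export
#' @examples
#' m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
#' quantile_normalize(m) # both samples become (2.5, 3.5, 4.5)
quantile_normalize <- function(values) {
  values <- check_matrix(values, min_samples = 2)
  if (anyNA(values)) {
    stop("missing values present; impute or drop genes with NAs first",
         call. = FALSE)
  }
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Remove covariate effects by per-gene linear regression
#'
#' Fits ordinary least squares of each gene on an intercept plus the named
#' covariates (categoricals one-hot encoded dropping one level) and replaces
#' the values with residuals plus the gene's grand mean, so per-gene means
#' are untouched. The intended workflow adjusts each condition separately;
#' call once per condition matrix for that behaviour, or once on the
#' combined matrix for a joint fit.
#'
#' @param values Numeric gene-by-sample matrix.
#' @param covariates Data frame of per-sample covariates, rows aligned with
#'   (or named by) the matrix columns.
#' @param vars Character vector of covariate column names to adjust for.
#' @return Adjusted matrix of the same shape.
#' @export
adjust_covariates <- function(values, covariates, vars) {
  values <- check_matrix(values, min_samples = 3)
  covariates <- as.data.frame(covariates)
  if (!is.null(rownames(covariates)) &&
      all(colnames(values) %in% rownames(covariates))) {
    covariates <- covariates[colnames(values), , drop = FALSE]
  }
  if (nrow(covariates) != ncol(values)) {
    stop("covariates must have one row per sample", call. = FALSE)
  }
  missing <- setdiff(vars, colnames(covariates))
  if (length(missing)) {
    stop("covariate(s) not found: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- character(0)
  for (v in vars) {
    col <- covariates[[v]]
    if (length(unique(col[!is.na(col)])) < 2) {
      warning("covariate '", v, "' has a single level; skipped", call. = FALSE)
    } else {
      keep <- c(keep, v)
    }
  }
  if (!length(keep)) return(values)
  design <- stats::model.matrix(
    stats::reformulate(keep),
    data = covariates[, keep, drop = FALSE]
  )
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(design, t(values))
  out <- t(fit$residuals) + rowMeans(values)
  dimnames(out) <- dimnames(values)
  out
}

#' Center and scale batches to the pooled gene distribution
#'
#' Per gene and batch, standardizes values to the pooled (all-sample) gene
#' mean and sd: a direct location/scale batch adjustment. Recovers planted
#' additive batch offsets up to per-batch sampling noise.
#'
#' @param values Numeric gene-by-sample matrix.
#' @param batch Character/factor vector of batch labels, one per sample (or
#'   named by sample ID).
#' @return Adjusted matrix.
#' @export
center_batches <- function(values, batch) {
  values <- check_matrix(values, min_samples = 2)
  if (!is.null(names(batch)) && all(colnames(values) %in% names(batch))) {
    batch <- batch[colnames(values)]
  }
  if (length(batch) != ncol(values)) {
    stop("batch must have one label per sample", call. = FALSE)
  }
  batch <- as.character(batch)
  tab <- table(batch)
  if (any(tab < 2)) {
    stop("singleton batch(es): ", paste(names(tab)[tab < 2], collapse = ", "),
         call. = FALSE)
  }
  if (length(tab) == 1) return(values)
  pool_m <- rowMeans(values)
  pool_s <- apply(values, 1, stats::sd)
  out <- values
  warned <- FALSE
  for (b in names(tab)) {
    idx <- which(batch == b)
    sub <- values[, idx, drop = FALSE]
    m <- rowMeans(sub)
    s <- apply(sub, 1, stats::sd)
    zero <- s == 0
    if (any(zero) && !warned) {
      warning("zero within-batch variance for some genes; location-only adjustment",
              call. = FALSE)
      warned <- TRUE
    }
    ratio <- pool_s / s
    ratio[zero] <- 1
    out[, idx] <- (sub - m) * ratio + pool_m
  }
  out
}

#' Flag outlier samples by average correlation to the rest
#'
#' Computes each sample's mean Spearman correlation to all other samples and
#' flags those lying more than `z` sd below the mean of these statistics: an
#' automatic stand-in for visual PCA/clustering inspection.
#'
#' @param values Numeric gene-by-sample matrix with at least 4 samples.
#' @param z Flagging threshold in sd units (default 3); `Inf` flags nothing.
#' @return Character vector of flagged sample IDs (possibly empty).
#' @export
flag_outlier_samples <- function(values, z = 3) {
  values <- check_matrix(values, min_samples = 4)
  cc <- stats::cor(values, method = "spearman")
  diag(cc) <- NA
  avg <- rowMeans(cc, na.rm = TRUE)
  cut <- mean(avg) - z * stats::sd(avg)
  names(avg)[avg < cut]
}

#' Drop genes unusable for rank correlation
#'
#' Removes genes with any missing value (rank statistics here use a fixed n
#' per condition) and genes with zero variance in either condition
#' (undefined ranks), reporting counts.
#'
#' @param expr_a,expr_b Gene-by-sample matrices sharing a gene universe.
#' @return List with filtered `expr_a`, `expr_b`, and `dropped` (gene IDs).
#' @export
filter_genes <- function(expr_a, expr_b) {
  expr_a <- check_matrix(expr_a)
  expr_b <- check_matrix(expr_b)
  shared <- intersect(rownames(expr_a), rownames(expr_b))
  expr_a <- expr_a[shared, , drop = FALSE]
  expr_b <- expr_b[shared, , drop = FALSE]
  has_na <- rowSums(is.na(expr_a)) + rowSums(is.na(expr_b)) > 0
  const <- apply(expr_a, 1, stats::sd, na.rm = TRUE) == 0 |
    apply(expr_b, 1, stats::sd, na.rm = TRUE) == 0
  drop <- has_na | const
  if (any(drop)) {
    message("filter_genes: dropping ", sum(has_na), " gene(s) with missing values and ",
            sum(const & !has_na), " constant gene(s)")
  }
  list(expr_a = expr_a[!drop, , drop = FALSE],
       expr_b = expr_b[!drop, , drop = FALSE],
       dropped = shared[drop])
}
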