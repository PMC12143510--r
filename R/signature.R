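# The fixed 17-gene CEDG prognostic risk signature: z-score normalization,
# linear scoring with the published coefficients, and median-split risk
# stratification.

#' The packaged 17-gene CEDG risk model
#'
#' Returns the fixed linear risk model: 17 gene symbols with signed
#' coefficients (11 positive, 6 negative) applied to per-gene z-scored
#' expression. Gene tokens are stored as published; `MTL5` and `SAPS3`
#' are older aliases of `TESMIN` and `PPP6R3` respectively (see the
#' `alias` column), without asserting which annotation vintage applies.
#'
#' @return A data.frame with columns `gene`, `coefficient`, `alias`
#'   (current symbol where it differs, else `NA`).
#' @export
cedg17_model <- function() {
  data.frame(
    gene = c("C11orf24", "MYEOV", "ALDH3B1", "UNC93B1", "MRGPRD", "PPFIA1",
             "FGF19", "GAL", "ANKRD13D", "FGF3", "MRPL21", "MTL5", "CHKA",
             "TCIRG1", "CCND1", "IGHMBP2", "SAPS3"),
    coefficient = c(0.2768, 0.0661, 0.0843, 0.1076, 0.1479, 0.2884,
                    0.0353, 0.0235, 0.0861, 0.0272, 0.0658, -0.1364, -0.1131,
                    -0.0844, -0.1363, -0.1111, -0.1099),
    alias = c(NA, NA, NA, NA, NA, NA,
              NA, NA, NA, NA, NA, "TESMIN", NA,
              NA, NA, NA, "PPP6R3"),
    stringsAsFactors = FALSE)
}

#' Read a signature model from a two-column TSV
#'
#' @param path TSV with columns `gene`, `coefficient` (header required).
#' @return A data.frame with columns `gene`, `coefficient`.
#' @export
read_signature_model <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "coefficient") %in% names(df)))
  if (anyDuplicated(df$gene))
    stop("duplicate gene in signature model", call. = FALSE)
  df$coefficient <- as.numeric(df$coefficient)
  df[, c("gene", "coefficient")]
}

#' Zero-mean z-score normalization per gene
#'
#' Standardizes each gene (row) across samples to zero mean and unit
#' variance using the population standard deviation
#' (`sqrt(mean((x - mean(x))^2))`). Genes with zero variance map to
#' all-zero rows with a warning. With `center_only = TRUE` only the mean
#' is subtracted.
#'
#' @param expr_matrix Numeric genes-by-samples matrix with at least two
#'   samples.
#' @param center_only If `TRUE`, mean-center without scaling.
#' @return A matrix of the same shape.
#' @export
zscore_rows <- function(expr_matrix, center_only = FALSE) {
  if (!is.matrix(expr_matrix) || !is.numeric(expr_matrix))
    stop("expression must be a numeric matrix", call. = FALSE)
  if (ncol(expr_matrix) < 2L)
    stop("z-score normalization needs at least 2 samples", call. = FALSE)
  mu <- rowMeans(expr_matrix)
  centered <- expr_matrix - mu
  if (center_only) return(centered)
  sdev <- sqrt(rowMeans(centered^2))  # population sd
  zero <- sdev == 0
  if (any(zero)) {
    warning(sum(zero), " constant gene row(s) set to all-zero z-scores",
            call. = FALSE)
    sdev[zero] <- 1
  }
  centered / sdev
}

#' Apply a linear signature model to normalized expression
#'
#' Per sample, the score is the coefficient-weighted sum of the model
#' genes' normalized expression values.
#'
#' @param model Data.frame with columns `gene`, `coefficient` (e.g.
#'   [cedg17_model()]).
#' @param normalized_expr Genes-by-samples matrix of normalized (z-scored)
#'   expression.
#' @param strict If `TRUE` (default) all model genes must be present as
#'   rows; missing genes are an error listing the absentees. If `FALSE`,
#'   missing genes contribute 0 with a warning.
#' @return A named numeric vector of per-sample scores.
#' @export
apply_signature <- function(model, normalized_expr, strict = TRUE) {
  stopifnot(all(c("gene", "coefficient") %in% names(model)))
  missing <- setdiff(model$gene, rownames(normalized_expr))
  if (length(missing) > 0L) {
    if (strict)
      stop("signature genes missing from the expression matrix: ",
           paste(missing, collapse = ", "), call. = FALSE)
    warning(length(missing), " missing signature gene(s) imputed as 0",
            call. = FALSE)
  }
  present <- model[model$gene %in% rownames(normalized_expr), , drop = FALSE]
  sub <- normalized_expr[present$gene, , drop = FALSE]
  scores <- drop(crossprod(sub, present$coefficient))
  names(scores) <- colnames(normalized_expr)
  scores
}

#' Median-split risk stratification
#'
#' The median score is the cutoff: samples with a score strictly above it
#' form the high-risk group; samples at or below it (including ties at
#' the median) form the low-risk group.
#'
#' @param scores Named numeric vector of per-sample risk scores (>= 2
#'   samples).
#' @return A data.frame with columns `sample_id`, `cedg_score`,
#'   `risk_group` (`"high"`/`"low"`), plus attribute `cutoff`.
#' @export
risk_stratify <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 samples", call. = FALSE)
  cutoff <- median(scores)
  out <- data.frame(
    sample_id = if (is.null(names(scores))) paste0("S", seq_along(scores))
                else names(scores),
    cedg_score = as.numeric(scores),
    risk_group = ifelse(scores > cutoff, "high", "low"),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "cutoff") <- cutoff
  out
}

#' Score samples with a signature and stratify by the median
#'
#' Convenience wrapper: per-gene normalization of the raw expression
#' matrix, linear scoring, and median-split risk groups.
#'
#' @param expr_matrix Raw genes-by-samples numeric matrix.
#' @param model Signature model (default [cedg17_model()]).
#' @param normalization `"zscore"` (default) or `"center"` (mean only).
#' @inheritParams apply_signature
#' @return The [risk_stratify()] table.
#' @export
score_signature <- function(expr_matrix, model = cedg17_model(),
                            normalization = c("zscore", "center"),
                            strict = TRUE) {
  normalization <- match.arg(normalization)
  z <- zscore_rows(expr_matrix, center_only = normalization == "center")
  risk_stratify(apply_signature(model, z, strict = strict))
}
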