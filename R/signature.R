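#' Construct a gene-pair signature model
#'
#' A signature is an ordered list of oriented gene pairs with one weight per
#' pair (multivariate Cox log hazard ratios), an optional classification
#' cutoff on the weighted index, and the ROC horizon the cutoff refers to.
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b` (and optionally
#'   `pair_id`, filled in if absent).
#' @param coefficients Numeric weights, one per pair.
#' @param cutoff Classification cutoff on the index scale (`NA` if unset).
#' @param horizon_months ROC horizon in months.
#' @param provenance Free-text description of where the model came from.
#' @return Object of class `brgpi_signature`.
#' @export
new_brgpi_signature <- function(pairs, coefficients, cutoff = NA_real_,
                                horizon_months = 12, provenance = "") {
  stopifnot(is.data.frame(pairs), all(c("gene_a", "gene_b") %in% names(pairs)))
  if (is.null(pairs$pair_id))
    pairs$pair_id <- paste(pairs$gene_a, pairs$gene_b, sep = "|")
  if (nrow(pairs) < 1 || length(coefficients) != nrow(pairs))
    stop("pairs and coefficients must have the same positive length",
         call. = FALSE)
  if (any(pairs$gene_a == pairs$gene_b))
    stop("pair genes must be distinct", call. = FALSE)
  if (!all(is.finite(coefficients)))
    stop("coefficients must be finite", call. = FALSE)
  if (!is.na(cutoff) && !is.finite(cutoff))
    stop("cutoff must be finite (or NA when unset)", call. = FALSE)
  coefficients <- stats::setNames(as.numeric(coefficients), pairs$pair_id)
  structure(list(pairs = pairs[, c("gene_a", "gene_b", "pair_id")],
                 coefficients = coefficients,
                 cutoff = cutoff,
                 horizon_months = horizon_months,
                 provenance = provenance),
            class = "brgpi_signature")
}

#' The frozen published four-pair signature
#'
#' Returns the published benefit-related gene-pair index for NSCLC patients
#' treated with anti-PD-1 immunotherapy, exactly as reported from its
#' training cohort: index = 1.521 x \[CCL2|VEGFA\] + 1.257 x \[CDK1|CXCL9\]
#' - 1.495 x \[HLA-DOB|LCK\] + 1.812 x \[IL12A|TBX21\], with classification
#' cutoff 0.317 on a one-year (12-month) time-dependent ROC. Samples scoring
#' strictly above the cutoff are classified high-risk.
#'
#' @return A `brgpi_signature` with the printed pairs, coefficients, cutoff
#'   and horizon.
#' @export
#' @examples
#' sig <- published_signature()
#' coef(sig)
#' sum(coef(sig))  # index of a sample with all four indicators = 1
published_signature <- function() {
  new_brgpi_signature(
    pairs = data.frame(gene_a = c("CCL2", "CDK1", "HLA-DOB", "IL12A"),
                       gene_b = c("VEGFA", "CXCL9", "LCK", "TBX21"),
                       stringsAsFactors = FALSE),
    coefficients = c(1.521, 1.257, -1.495, 1.812),
    cutoff = 0.317,
    horizon_months = 12,
    provenance = paste("frozen published four-gene-pair anti-PD-1 NSCLC",
                       "signature (training-cohort values)"))
}

#' @export
print.brgpi_signature <- function(x, ...) {
  terms <- sprintf("%+.4g x [%s]", unname(x$coefficients), x$pairs$pair_id)
  cat("Gene-pair index:\n  score =", paste(terms, collapse = " "), "\n")
  cat(sprintf("  cutoff: %s (high iff score > cutoff), horizon: %g months\n",
              if (is.na(x$cutoff)) "unset" else format(x$cutoff),
              x$horizon_months))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
coef.brgpi_signature <- function(object, ...) object$coefficients

#' @export
summary.brgpi_signature <- function(object, ...) {
  print(object)
  if (!is.null(object$screen)) {
    cat(sprintf("\nScreening: %d candidate pair(s) at alpha = %g\n",
                nrow(object$screen), attr(object$screen, "alpha")))
  }
  if (!is.null(object$roc)) {
    cat(sprintf("Training AUC at %g months: %.3f\n",
                object$roc$horizon_months, object$roc$auc))
  }
  invisible(object)
}

#' Score and classify new samples with a signature
#'
#' @param object A `brgpi_signature`.
#' @param newdata A `brgpi_cohort`, a gene-by-sample expression matrix, or a
#'   `brgpi_pairs` indicator object containing the model's pairs.
#' @param type `"score"` for the weighted index, `"class"` for the
#'   low/high classification at the model cutoff.
#' @param ... Unused.
#' @return Named numeric vector of scores, or a factor with levels
#'   `c("low", "high")`.
#' @export
predict.brgpi_signature <- function(object, newdata,
                                    type = c("score", "class"), ...) {
  type <- match.arg(type)
  ind <- if (inherits(newdata, "brgpi_pairs")) newdata
         else encode_pairs(newdata, object$pairs)
  sc <- score_brgpi(ind, object)
  if (type == "score") return(sc)
  classify(sc, object$cutoff)
}

#' Serialize a signature to / from a JSON text file
#'
#' The round trip is lossless: coefficients and cutoff are written at full
#' double precision.
#'
#' @param signature A `brgpi_signature`.
#' @param path File path.
#' @return `write_signature` invisibly returns `path`; `read_signature`
#'   returns the reconstructed `brgpi_signature`.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "brgpi_signature"))
  obj <- list(pairs = signature$pairs,
              coefficients = unname(signature$coefficients),
              cutoff = signature$cutoff,
              horizon_months = signature$horizon_months,
              provenance = signature$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cutoff <- obj$cutoff
  if (is.null(cutoff)) cutoff <- NA_real_
  new_brgpi_signature(pairs = as.data.frame(obj$pairs,
                                            stringsAsFactors = FALSE),
                      coefficients = as.numeric(obj$coefficients),
                      cutoff = as.numeric(cutoff),
                      horizon_months = as.numeric(obj$horizon_months),
                      provenance = obj$provenance %||% "")
}
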