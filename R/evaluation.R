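# Accuracy evaluation.
#
# The reference ("supervised classification") cover fraction is the share
# of vegetation pixels among all classified pixels. A model's extraction
# error EC is its relative deviation from that reference, in percent.
# Agreement between two label maps is summarised by the confusion matrix,
# overall accuracy and Cohen's kappa.

#' Tally land-cover classes
#'
#' Counts valid pixels per class of a label map. Every class in the map's
#' `class_names` gets a row, including classes with zero pixels.
#'
#' @param labels An `rgbfvc_labels` map.
#' @return A tibble with `code`, `class`, `n` and `is_vegetation`.
#' @export
count_classes <- function(labels) {
  codes <- as.integer(names(labels$class_names))
  lab <- labels$labels[labels$mask]
  tibble(
    code = codes,
    class = unname(labels$class_names),
    n = vapply(codes, function(k) sum(lab == k), integer(1)),
    is_vegetation = unname(labels$class_names) == labels$vegetation
  )
}

#' Reference FVC from class pixel counts
#'
#' The supervised-classification cover fraction: vegetation pixels divided
#' by the total over all classes (vegetation, bare ground, road,
#' sedimentation pond, building, or any other class set with one
#' designated vegetation class).
#'
#' @param counts Either the tibble returned by [count_classes()], or a
#'   named numeric vector of per-class pixel counts.
#' @param vegetation Name of the vegetation class (used for the vector
#'   form, or when the tibble lacks an `is_vegetation` column).
#' @return The vegetation cover fraction in \[0, 1\].
#' @examples
#' fvc_from_counts(c(vegetation = 13143311, bare_ground = 1267092,
#'                   road = 1838215, pond = 320001, building = 1257173))
#' @export
fvc_from_counts <- function(counts, vegetation = "vegetation") {
  if (is.data.frame(counts)) {
    n <- counts$n
    veg <- if ("is_vegetation" %in% names(counts)) {
      counts$is_vegetation
    } else {
      counts$class == vegetation
    }
  } else {
    n <- as.numeric(counts)
    veg <- names(counts) == vegetation
  }
  if (any(n < 0)) abort("class counts must be non-negative")
  if (!any(veg)) abort(sprintf("no '%s' class in counts", vegetation))
  total <- sum(n)
  if (total <= 0) abort("total pixel count is zero")
  sum(n[veg]) / total
}

#' Extraction error of a model FVC against the reference
#'
#' EC = |FI - FV| / FI x 100, where FI is the reference (supervised
#' classification) cover and FV the model (dimidiate pixel) cover. The
#' absolute difference is reported so the error is a magnitude regardless
#' of the direction of the deviation.
#'
#' @param fi Reference cover fraction (> 0).
#' @param fv Model cover fraction.
#' @return A one-row tibble: `fv`, `fi`, `difference` (= |fi - fv|) and
#'   `ec` (percent), at full precision.
#' @examples
#' extraction_error(0.737320, 0.750179)
#' @export
extraction_error <- function(fi, fv) {
  if (fi <= 0) abort("reference FVC must be positive")
  d <- abs(fi - fv)
  tibble(fv = fv, fi = fi, difference = d, ec = d / fi * 100)
}

#' Rank dimidiate-pixel models against the reference FVC
#'
#' One row per model with its extraction error, sorted by EC ascending.
#' Ties are broken by the canonical index order (EXG, GRVI, EXGR, NGBDI,
#' CIVE, RGBVI, VDVI), then by input order.
#'
#' @param reference_fvc Reference cover fraction (> 0).
#' @param model_fvcs Named numeric vector of per-model cover fractions, or
#'   a data frame with columns `model` and `fv`.
#' @return A tibble: `model`, `fv`, `fi`, `difference`, `ec`, `rank`.
#' @export
compare_models <- function(reference_fvc, model_fvcs) {
  if (is.data.frame(model_fvcs)) {
    models <- model_fvcs$model
    fvs <- model_fvcs$fv
  } else {
    models <- names(model_fvcs)
    fvs <- as.numeric(model_fvcs)
  }
  if (length(fvs) == 0) abort("no model FVC values supplied")
  if (is.null(models)) abort("model FVC values must be named")
  tab <- dplyr::bind_rows(lapply(fvs, function(fv) extraction_error(reference_fvc, fv)))
  tab <- dplyr::mutate(tab, model = models, .before = 1)
  tie <- match(toupper(models), INDEX_ORDER, nomatch = length(INDEX_ORDER) + 1L)
  ord <- order(tab$ec, tie, seq_along(fvs))
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  tab
}

kappa_stats <- function(confusion) {
  total <- sum(confusion)
  p_o <- sum(diag(confusion)) / total
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  kappa <- if (1 - p_e == 0) NA_real_ else (p_o - p_e) / (1 - p_e)
  tibble(n = total, overall_accuracy = p_o, expected_accuracy = p_e, kappa = kappa)
}

#' Agreement statistics for a confusion matrix
#'
#' Overall accuracy (trace over total) and Cohen's kappa
#' ((p_o - p_e) / (1 - p_e), with chance agreement p_e from the marginal
#' products). When p_e = 1 (both maps constant and equal) kappa is
#' undefined and reported as `NA`.
#'
#' @param confusion A square count matrix, reference classes in rows and
#'   predicted classes in columns.
#' @return A one-row tibble: `n`, `overall_accuracy`, `expected_accuracy`,
#'   `kappa`.
#' @examples
#' agreement_stats(matrix(c(40, 20, 10, 30), 2, 2))
#' @export
agreement_stats <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) abort("confusion matrix must be square")
  if (sum(confusion) == 0) abort("confusion matrix is empty")
  kappa_stats(confusion)
}

#' Agreement between two land-cover maps
#'
#' Cross-tabulates two label maps over their jointly valid pixels. A
#' sparse validation sample (e.g. surveyed sample points) is represented
#' naturally by a reference map that is invalid everywhere except the
#' sample pixels.
#'
#' @param reference,predicted `rgbfvc_labels` maps of identical dimensions
#'   sharing a class vocabulary.
#' @return An object of class `rgbfvc_agreement` holding the confusion
#'   matrix (reference in rows) and the summary statistics; use [tidy()]
#'   for the long confusion table and [glance()] for the one-row summary.
#' @export
agreement <- function(reference, predicted) {
  if (!identical(dim(reference), dim(predicted))) {
    abort("label maps have different dimensions")
  }
  joint <- reference$mask & predicted$mask
  if (!any(joint)) abort("no jointly valid pixels")
  classes <- union(unname(reference$class_names), unname(predicted$class_names))
  ref <- unname(reference$class_names[as.character(reference$labels[joint])])
  prd <- unname(predicted$class_names[as.character(predicted$labels[joint])])
  confusion <- table(factor(ref, levels = classes), factor(prd, levels = classes))
  confusion <- unclass(as.matrix(confusion))
  names(dimnames(confusion)) <- c("reference", "predicted")
  structure(
    list(confusion = confusion, stats = kappa_stats(confusion)),
    class = "rgbfvc_agreement"
  )
}

#' @export
print.rgbfvc_agreement <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<rgbfvc_agreement> n = %d, overall accuracy %.4f, kappa %s\n",
              s$n, s$overall_accuracy,
              if (is.na(s$kappa)) "undefined" else sprintf("%.4f", s$kappa)))
  print(x$confusion)
  invisible(x)
}

#' @rdname agreement
#' @param x An `rgbfvc_agreement` object.
#' @param ... Unused.
#' @export
tidy.rgbfvc_agreement <- function(x, ...) {
  df <- as.data.frame(as.table(x$confusion), stringsAsFactors = FALSE)
  names(df) <- c("reference", "predicted", "n")
  as_tibble(df)
}

#' @rdname agreement
#' @export
glance.rgbfvc_agreement <- function(x, ...) x$stats
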