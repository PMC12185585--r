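# Evaluation suite: mask IoU, keypoint mean error (mm), multiclass
# accuracy / precision / F1, Cohen's kappa with asymptotic CI, and
# region-by-grade distribution tables.

#' Intersection over union of two binary masks
#'
#' @param a,b `ldh_mask` objects (or logical matrices) on congruent grids.
#' @return fraction in `[0, 1]`; two empty masks compare as 1 with a warning.
#' @export
iou <- function(a, b) {
  ma <- if (inherits(a, "ldh_mask")) a$mask else a > 0
  mb <- if (inherits(b, "ldh_mask")) b$mask else b > 0
  if (!identical(dim(ma), dim(mb)))
    stop("mask shape mismatch: ", paste(dim(ma), collapse = "x"), " vs ",
         paste(dim(mb), collapse = "x"))
  uni <- sum(ma | mb)
  if (uni == 0) {
    warning("both masks empty; IoU defined as 1")
    return(1)
  }
  sum(ma & mb) / uni
}

#' Mean keypoint localization error in millimetres
#'
#' Mean Euclidean mm distance over the nine role-matched points.
#'
#' @param pred,ref `ldh_keypoints` in px on the same grid.
#' @param spacing `c(row_mm, col_mm)`.
#' @return list with `me` (mm) and `per_role` (named mm vector).
#' @export
keypoint_me <- function(pred, ref, spacing) {
  mp <- px_to_mm(keypoint_matrix(pred), spacing)
  mr <- px_to_mm(keypoint_matrix(ref), spacing)
  d <- sqrt(rowSums((mp - mr)^2))
  names(d) <- rownames(keypoint_matrix(ref))
  list(me = mean(d), per_role = d)
}

#' Multiclass agreement metrics: accuracy, precision, F1
#'
#' Accuracy is the exact-match fraction. Precision and F1 are one-vs-rest
#' per-class values averaged over the classes present in `ref`, weighted by
#' their reference support (`average = "weighted"`, the default) or equally
#' (`average = "macro"`). A class with no predicted positives contributes
#' precision 0.
#'
#' @param pred,ref equal-length label vectors.
#' @param average `"weighted"` or `"macro"`.
#' @return list: `n`, `accuracy`, `precision`, `f1` (percentages), and
#'   `per_class` data.frame (support, precision, recall, f1 as fractions).
#' @export
classification_metrics <- function(pred, ref, average = c("weighted", "macro")) {
  average <- match.arg(average)
  if (length(pred) != length(ref)) stop("pred and ref length mismatch")
  if (length(ref) == 0) stop("empty label vectors")
  pred <- as.character(pred); ref <- as.character(ref)
  lev <- sort(unique(c(pred, ref)))
  cm <- table(factor(ref, lev), factor(pred, lev))
  tp <- diag(cm)
  support <- rowSums(cm)
  predn <- colSums(cm)
  classes <- lev[support > 0]
  prec <- ifelse(predn[classes] > 0, tp[classes] / predn[classes], 0)
  rec <- tp[classes] / support[classes]
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- if (average == "weighted") support[classes] / sum(support[classes])
       else rep(1 / length(classes), length(classes))
  list(n = length(ref),
       accuracy = 100 * mean(pred == ref),
       precision = 100 * sum(w * prec),
       f1 = 100 * sum(w * f1),
       per_class = data.frame(class = classes, support = as.integer(support[classes]),
                              precision = as.numeric(prec), recall = as.numeric(rec),
                              f1 = as.numeric(f1), stringsAsFactors = FALSE))
}

#' Cohen's kappa with asymptotic standard error, 95% CI and agreement band
#'
#' Unweighted kappa `(p_o - p_e) / (1 - p_e)` with chance agreement from the
#' marginal products. The standard error is the large-sample
#' Fleiss-Cohen-Everitt formula; the 95% CI is `kappa +/- 1.96 SE`, truncated
#' to `[-1, 1]`. The p-value tests kappa = 0 with the null-variance z
#' statistic; significance is declared at p < 0.01. Agreement bands:
#' kappa <= 0.4 poor, (0.4, 0.6] moderate, (0.6, 0.8] high, > 0.8 excellent.
#'
#' @param pred,ref equal-length label vectors (length >= 2).
#' @return object of class `ldh_kappa`: `n`, `kappa`, `se`, `ci95`,
#'   `z`, `p_value`, `p_display`, `significant`, `band`, `p_o`, `p_e`.
#' @export
cohens_kappa <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("pred and ref length mismatch")
  n <- length(ref)
  if (n < 2) stop("need at least 2 paired labels")
  lev <- sort(unique(c(as.character(pred), as.character(ref))))
  p <- table(factor(ref, lev), factor(pred, lev)) / n
  po <- sum(diag(p))
  rowm <- rowSums(p); colm <- colSums(p)
  pe <- sum(rowm * colm)
  if (pe >= 1 - 1e-12)
    stop("chance agreement p_e = 1 (both raters constant); kappa undefined")
  k <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt large-sample variance
  m <- length(lev)
  a <- sum(diag(p) * (1 - (rowm + colm) * (1 - k))^2)
  b <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) if (i != j)
    b <- b + p[i, j] * (colm[i] + rowm[j])^2
  b <- (1 - k)^2 * b
  cc <- (k - pe * (1 - k))^2
  se <- sqrt(max(a + b - cc, 0)) / ((1 - pe) * sqrt(n))
  se0 <- sqrt(max(pe + pe^2 - sum(rowm * colm * (rowm + colm)), 0)) /
    ((1 - pe) * sqrt(n))
  z <- if (se0 > 0) k / se0 else Inf
  pval <- 2 * stats::pnorm(-abs(z))
  ci <- pmin(1, pmax(-1, k + c(-1, 1) * 1.96 * se))
  band <- if (k <= 0.4) "poor" else if (k <= 0.6) "moderate"
          else if (k <= 0.8) "high" else "excellent"
  structure(list(n = n, kappa = unname(k), se = unname(se),
                 ci95 = unname(ci), z = unname(z), p_value = unname(pval),
                 p_display = if (pval < 0.01) "<0.01" else sprintf("%.2f", pval),
                 significant = pval < 0.01, band = band,
                 p_o = unname(po), p_e = unname(pe)),
            class = "ldh_kappa")
}

#' @export
print.ldh_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (%s; 95%% CI %.3f, %.3f; p %s; n = %d)\n",
              x$kappa, x$band, x$ci95[1], x$ci95[2], x$p_display, x$n))
  invisible(x)
}

#' Full agreement report between two raters
#'
#' Combines [classification_metrics()] and [cohens_kappa()] for one of the
#' three label schemes.
#'
#' @param pred,ref category code vectors (0-17).
#' @param scheme `"cat18"`, `"grade4"` or `"region8"`.
#' @param average averaging for precision/F1.
#' @return list of class `ldh_agreement` with `scheme`, `n`, `accuracy`,
#'   `precision`, `f1` (percentages), `kappa` (an `ldh_kappa`), `per_class`.
#' @export
agreement_report <- function(pred, ref, scheme = c("cat18", "grade4", "region8"),
                             average = "weighted") {
  scheme <- match.arg(scheme)
  lab <- function(code) switch(scheme,
    cat18 = category_label(code),
    grade4 = as.character(project_category(code, "grade4")),
    region8 = project_category(code, "region8"))
  pl <- lab(pred); rl <- lab(ref)
  cm <- classification_metrics(pl, rl, average)
  kap <- cohens_kappa(pl, rl)
  structure(list(scheme = scheme, n = cm$n, accuracy = cm$accuracy,
                 precision = cm$precision, f1 = cm$f1, kappa = kap,
                 per_class = cm$per_class),
            class = "ldh_agreement")
}

#' @export
print.ldh_agreement <- function(x, ...) {
  cat(sprintf("[%s] n = %d  accuracy %.2f%%  P %.2f%%  F1 %.2f%%\n",
              x$scheme, x$n, x$accuracy, x$precision, x$f1))
  print(x$kappa)
  invisible(x)
}

.table_valid_cells <- function() {
  lat <- enumerate_categories()
  regions <- attr(lat, "regions")
  valid <- matrix(FALSE, 8, 4, dimnames = list(regions, paste0("grade", 0:3)))
  valid[cbind(lat$region, paste0("grade", lat$grade))] <- TRUE
  valid
}

#' Region-by-grade distribution table with percentages
#'
#' One row per region label (NONE first, then LEFZ..REFZ in code order), one
#' column per grade 0-3; each valid cell carries the count and the percentage
#' of the total n (2 decimals). Cells outside the 18-member lattice are
#' structural dashes.
#'
#' @param codes category code vector (0-17) for one rater; or `NULL` when
#'   `counts` is supplied directly.
#' @param counts optional 8 x 4 count matrix (rows NONE..REFZ, cols grade
#'   0-3) taken instead of tabulating `codes`.
#' @param n total used for percentages (defaults to the sum of counts).
#' @param rater label attached to the table.
#' @return object of class `ldh_disttable`: `counts`, `pct` (numeric, NA on
#'   structural dashes), `cells` (formatted "count(pct)" strings), `n`,
#'   `rater`.
#' @export
distribution_table <- function(codes = NULL, counts = NULL, n = NULL,
                               rater = "rater") {
  valid <- .table_valid_cells()
  if (is.null(counts)) {
    if (is.null(codes)) stop("supply codes or counts")
    lat <- enumerate_categories()
    i <- match(codes, lat$code)
    if (anyNA(i)) stop("invalid category code(s) in input")
    counts <- matrix(0L, 8, 4, dimnames = dimnames(valid))
    if (length(i)) {
      tab <- table(factor(lat$region[i], rownames(valid)),
                   factor(paste0("grade", lat$grade[i]), colnames(valid)))
      counts[] <- as.integer(tab)
    }
  } else {
    counts <- as.matrix(counts)
    dimnames(counts) <- dimnames(valid)
    if (any(counts[!valid] != 0))
      stop("count in a structural-dash cell (no such classification exists)")
  }
  if (is.null(n)) n <- sum(counts)
  pct <- matrix(NA_real_, 8, 4, dimnames = dimnames(valid))
  pct[valid] <- round(100 * counts[valid] / n, 2)
  cells <- matrix("-", 8, 4, dimnames = dimnames(valid))
  cells[valid] <- sprintf("%d(%.2f)", counts[valid], pct[valid])
  structure(list(counts = counts, pct = pct, cells = cells, n = n,
                 rater = rater),
            class = "ldh_disttable")
}

#' @export
print.ldh_disttable <- function(x, ...) {
  cat(sprintf("Distribution of %d discs (%s):\n", x$n, x$rater))
  print(as.data.frame(x$cells), right = TRUE)
  invisible(x)
}

#' Published two-rater reader-study counts shipped with the package
#'
#' Region-by-grade classification counts from a two-rater reader study of
#' axial lumbar MRI (an orthopedist and an automated model), on an internal
#' set of 400 slices and an external multi-center set of 1500 slices,
#' together with the percentages as originally printed. Used to exercise the
#' distribution-table arithmetic against an independent published layout.
#'
#' @return data.frame with columns `dataset` (internal/external), `rater`
#'   (orthopedist/model), `region`, `grade`, `count`, `pct_printed`, `total`.
#' @export
reader_study_counts <- function() {
  path <- system.file("extdata", "reader_study_counts.csv", package = "ldhquant")
  if (path == "") stop("reader_study_counts.csv not found in the installed package")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
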