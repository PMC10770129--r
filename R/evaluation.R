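#' Object-level matching under the 50% overlap rule
#'
#' A ground-truth object is a true positive iff at least `min_coverage`
#' (default 50%) of its area is covered by a single prediction; otherwise it
#' is a false negative. A prediction that validates no ground truth under
#' that rule is a false positive. One prediction may validate several ground
#' truths; a ground truth needs only one validating prediction. Overlap is
#' measured against each single prediction by default; `union_mode = TRUE`
#' measures coverage by the union of all predictions instead (sensitivity
#' analysis).
#'
#' All areas are pixel counts on the 0.5 um/px grid (ground-truth polygons
#' are rasterized with the package's pixel-center rule; detection objects
#' are already pixel regions, so grid coverage is exact for them).
#'
#' @param ground_truth an [annotation_set()] (with slide dimensions) or a
#'   list of polygon coordinate matrices.
#' @param predictions a list of detection objects from [extract_objects()],
#'   or an [annotation_set()] (e.g. comparing two annotation sessions).
#' @param category category to evaluate ("TLS" or "GC").
#' @param dims `c(H, W)` of the common grid; inferred from the inputs when
#'   possible.
#' @param min_coverage matching threshold on the covered GT-area fraction.
#' @param union_mode measure GT coverage against the union of predictions.
#' @return a `MatchResult`: list with counts `tp`, `fp`, `fn`, the
#'   `assignments` table (gt, prediction, coverage), per-GT maximum
#'   `gt_coverage`, and the per-prediction `pred_validates` flags.
#' @export
match_objects <- function(ground_truth, predictions, category = "TLS",
                          dims = NULL, min_coverage = 0.5,
                          union_mode = FALSE) {
  if (inherits(ground_truth, "AnnotationSet")) {
    if (is.null(dims)) dims <- c(ground_truth$height, ground_truth$width)
    gt_polys <- category_polygons(ground_truth, category)
  } else gt_polys <- ground_truth
  if (inherits(predictions, "AnnotationSet")) {
    pred_pix <- lapply(category_polygons(predictions, category),
                       function(p) polygon_pixels(p, dims[1], dims[2]))
  } else {
    if (length(predictions)) {
      bad <- vapply(predictions, function(o) o$category != category, TRUE)
      if (any(bad)) stop("predictions contain mixed categories")
      if (is.null(dims)) dims <- predictions[[1]]$dims
    }
    pred_pix <- lapply(predictions, `[[`, "pixels")
  }
  if (is.null(dims) || any(is.na(dims)))
    stop("grid dimensions could not be inferred; supply dims")
  gt_pix <- lapply(gt_polys, function(p) polygon_pixels(p, dims[1], dims[2]))

  n_gt <- length(gt_pix); n_pred <- length(pred_pix)
  pred_validates <- rep(FALSE, n_pred)
  gt_cov <- numeric(n_gt)
  assignments <- list()
  # prediction membership as one label raster would lose overlapping
  # predictions; use per-prediction membership vectors instead
  npix <- prod(dims)
  pred_member <- lapply(pred_pix, function(p) p)
  for (g in seq_len(n_gt)) {
    gset <- logical(npix); gset[gt_pix[[g]]] <- TRUE
    ga <- length(gt_pix[[g]])
    if (ga == 0) next
    for (p in seq_len(n_pred)) {
      inter <- sum(gset[pred_member[[p]]])
      cov <- inter / ga
      if (cov >= min_coverage) {
        pred_validates[p] <- TRUE
        assignments[[length(assignments) + 1]] <-
          data.frame(gt = g, pred = p, coverage = cov)
      }
      gt_cov[g] <- max(gt_cov[g], cov)
    }
    if (union_mode) {
      un <- logical(npix)
      for (p in pred_pix) un[p] <- TRUE
      gt_cov[g] <- sum(un[gt_pix[[g]]]) / ga
    }
  }
  tp <- sum(gt_cov >= min_coverage)
  structure(list(category = category,
                 tp = tp, fp = sum(!pred_validates), fn = n_gt - tp,
                 assignments = if (length(assignments))
                   do.call(rbind, assignments)
                 else data.frame(gt = integer(0), pred = integer(0),
                                 coverage = numeric(0)),
                 gt_coverage = gt_cov,
                 pred_validates = pred_validates),
            class = "MatchResult")
}

#' F1 score and its components
#'
#' `f1()` is the harmonic mean of precision and recall; `f1_from_counts()`
#' derives precision = TP/(TP+FP) and recall = TP/(TP+FN) first. Any 0/0
#' component is defined as 0.
#'
#' @param precision,recall values in 0..1.
#' @return `f1`: numeric scalar. `f1_from_counts`: list with `precision`,
#'   `recall`, `f1`.
#' @export
f1 <- function(precision, recall) {
  if (precision < 0 || recall < 0) stop("precision/recall must be >= 0")
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' @rdname f1
#' @param tp,fp,fn non-negative object counts.
#' @export
f1_from_counts <- function(tp, fp, fn) {
  if (tp < 0 || fp < 0 || fn < 0) stop("counts must be non-negative")
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  list(precision = precision, recall = recall, f1 = f1(precision, recall))
}

#' Per-slide and pooled F1 tables
#'
#' `per_slide_f1()` scores every slide from its own counts, with the
#' empty-slide convention: no ground truth and no predictions scores 1;
#' no ground truth but spurious predictions scores 0. `overall_f1()` pools
#' the raw counts across slides first (it is not the mean of per-slide F1s
#' and ignores the empty-slide convention).
#'
#' @param matches list of `MatchResult`s (one per slide), optionally named.
#' @return `per_slide_f1`: data frame with one row per slide;
#'   `overall_f1`: list with pooled `precision`, `recall`, `f1` and counts.
#' @export
per_slide_f1 <- function(matches) {
  if (length(matches) == 0) stop("empty slide list")
  rows <- lapply(seq_along(matches), function(i) {
    m <- matches[[i]]
    sc <- f1_from_counts(m$tp, m$fp, m$fn)
    if (m$tp + m$fn == 0)  # no ground truth on this slide
      sc$f1 <- if (m$fp == 0) 1 else 0
    data.frame(slide = if (!is.null(names(matches))) names(matches)[i]
               else as.character(i),
               category = m$category, tp = m$tp, fp = m$fp, fn = m$fn,
               precision = sc$precision, recall = sc$recall, f1 = sc$f1)
  })
  do.call(rbind, rows)
}

#' @rdname per_slide_f1
#' @export
overall_f1 <- function(matches) {
  if (length(matches) == 0) stop("empty slide list")
  tp <- sum(vapply(matches, `[[`, 0, "tp"))
  fp <- sum(vapply(matches, `[[`, 0, "fp"))
  fn <- sum(vapply(matches, `[[`, 0, "fn"))
  c(f1_from_counts(tp, fp, fn), list(tp = tp, fp = fp, fn = fn))
}

#' Quantify lymphoid structures on a slide
#'
#' Per-category object count, density (objects per cm^2 of tissue) and mean
#' object size (mm^2). Works identically for manual annotations and for
#' predicted detections, so the two sources are directly comparable.
#'
#' @param objects an [annotation_set()] or a list of detection objects.
#' @param tissue_mask a [compute_tissue_mask()] result with positive area.
#' @param slide_id,source metadata recorded in the output row.
#' @return a one-row-per-category data frame (`DensityRecord`).
#' @export
quantify <- function(objects, tissue_mask, slide_id = NULL,
                     source = c("predicted", "manual")) {
  source <- match.arg(source)
  if (tissue_mask$area_cm2 <= 0) stop("tissue area must be positive")
  px_mm2 <- (0.5e-3)^2
  per_cat <- lapply(c("TLS", "GC"), function(cat) {
    if (inherits(objects, "AnnotationSet")) {
      if (is.null(slide_id)) slide_id <<- objects$slide_id
      areas <- vapply(category_polygons(objects, cat), polygon_area, 0) *
        px_mm2
    } else {
      objs <- Filter(function(o) o$category == cat, objects)
      areas <- vapply(objs, `[[`, 0, "area_mm2")
    }
    data.frame(slide = if (is.null(slide_id)) "slide" else slide_id,
               source = source, category = cat, count = length(areas),
               density_per_cm2 = length(areas) / tissue_mask$area_cm2,
               mean_area_mm2 = if (length(areas)) mean(areas) else NA_real_,
               tissue_cm2 = tissue_mask$area_cm2)
  })
  do.call(rbind, per_cat)
}

#' Median split of patients by TLS density
#'
#' The per-patient density is the maximum over that patient's slides; the
#' cohort threshold is the median over all patients of the cohort; a patient
#' is TLS-high iff strictly above the median (so an all-tied cohort is
#' entirely TLS-low).
#'
#' @param records data frame with columns `cohort`, `patient`,
#'   `density_per_cm2` (one row per slide).
#' @return data frame with one row per patient: `cohort`, `patient`,
#'   `density`, `cohort_median`, `group` ("TLS-high"/"TLS-low").
#' @export
median_split <- function(records) {
  stopifnot(all(c("cohort", "patient", "density_per_cm2") %in%
                  names(records)))
  out <- list()
  for (co in unique(records$cohort)) {
    rc <- records[records$cohort == co, ]
    pat <- unique(rc$patient)
    dens <- vapply(pat, function(p)
      max(rc$density_per_cm2[rc$patient == p]), 0)
    med <- median(dens)
    out[[length(out) + 1]] <- data.frame(
      cohort = co, patient = pat, density = dens, cohort_median = med,
      group = ifelse(dens > med, "TLS-high", "TLS-low"))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
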