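#' Construct a class sample
#'
#' @param label cover class: `"bare_soil"`, `"crop"`, `"weed"` or
#'   `"vegetation"` (weeds and crop pooled).
#' @param indexName the vegetation index the values were computed with (or
#'   `"raw"`).
#' @param values per-pixel values.
#' @param nRois number of sampling areas pooled into the sample.
#' @return A [ClassSample-class].
#' @export
ClassSample <- function(label, indexName, values, nRois = 1L) {
  new("ClassSample", label = label, indexName = indexName,
      values = as.numeric(values), nRois = as.integer(nRois))
}

setMethod("show", "ClassSample", function(object) {
  v <- object@values[!is.na(object@values)]
  cat(sprintf("ClassSample: %s / %s, n = %d px from %d ROI(s); mean %.3f, sd %.3f\n",
              object@label, object@indexName, length(v), object@nRois,
              mean(v), stats::sd(v)))
  invisible(NULL)
})

#' @rdname accessors
#' @export
setMethod("sampleValues", "ClassSample", function(x) x@values)

#' Pool index pixels over regions of interest
#'
#' Collects the valid (non-`NA`) pixels of an index image falling inside a
#' set of sampling areas. Regions are either a logical mask matching the
#' image, or a list of polygons (each a 2-column matrix / data.frame of
#' `x`, `y` vertex coordinates in pixels); a pixel belongs to a polygon when
#' its centre does, under a 0-based, top-left-origin, half-open raster
#' convention (the centre of the pixel in row r, column c is
#' `(c - 0.5, r - 0.5)`).
#'
#' @param indexImage H x W numeric matrix (e.g. from [computeIndex()]).
#' @param rois logical mask or list of polygons.
#' @param label cover class of the sample.
#' @param indexName index name recorded in the sample.
#' @return A [ClassSample-class].
#' @export
sampleClassPixels <- function(indexImage, rois, label,
                              indexName = "raw") {
  if (is.logical(rois) && is.matrix(rois)) {
    if (!identical(dim(rois), dim(indexImage)))
      stop("mask dimensions must match the index image")
    vals <- indexImage[rois]
    nRois <- 1L
  } else if (is.list(rois) && length(rois) > 0L) {
    H <- nrow(indexImage); W <- ncol(indexImage)
    inside <- matrix(FALSE, H, W)
    for (poly in rois) {
      poly <- as.matrix(poly)
      if (ncol(poly) < 2L) stop("each polygon needs x and y columns")
      cols <- max(1L, floor(min(poly[, 1L]))):min(W, ceiling(max(poly[, 1L])))
      rows <- max(1L, floor(min(poly[, 2L]))):min(H, ceiling(max(poly[, 2L])))
      if (!length(cols) || !length(rows)) next
      cx <- rep(cols - 0.5, each = length(rows))
      cy <- rep(rows - 0.5, times = length(cols))
      hit <- pracma::inpolygon(cx, cy, poly[, 1L], poly[, 2L],
                               boundary = TRUE)
      inside[cbind(rep(rows, length(cols))[hit],
                   rep(cols, each = length(rows))[hit])] <- TRUE
    }
    vals <- indexImage[inside]
    nRois <- length(rois)
  } else stop("rois must be a logical mask or a non-empty list of polygons")
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L)
    stop("no valid pixels fall inside the regions of interest")
  ClassSample(label, indexName, vals, nRois)
}

#' Pool crop and weed samples into a vegetation sample
#'
#' Vegetation is weeds and crop studied together.
#'
#' @param crop,weed [ClassSample-class] objects of the same index.
#' @return A [ClassSample-class] labelled `"vegetation"`.
#' @export
vegetationSample <- function(crop, weed) {
  stopifnot(crop@indexName == weed@indexName)
  ClassSample("vegetation", crop@indexName, c(crop@values, weed@values),
              crop@nRois + weed@nRois)
}

#' M-statistic histogram separability
#'
#' `M = (mean1 - mean2) / (sd1 + sd2)`: the difference in class means
#' normalised by the sum of the class standard deviations. The same mean
#' difference separates narrow histograms better than wide ones; two classes
#' show moderate separability when `|M|` exceeds 1, with larger values
#' giving easier discrimination. Antisymmetric under swapping the classes.
#'
#' @param s1,s2 [ClassSample-class] objects, or plain numeric vectors.
#' @return the M value.
#' @examples
#' a <- ClassSample("vegetation", "NDVI", rnorm(500, 0.58, 0.07))
#' b <- ClassSample("bare_soil", "NDVI", rnorm(500, -0.16, 0.01))
#' mStatistic(a, b)
#' @export
mStatistic <- function(s1, s2) {
  v1 <- if (is(s1, "ClassSample")) s1@values else as.numeric(s1)
  v2 <- if (is(s2, "ClassSample")) s2@values else as.numeric(s2)
  v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
  if (!length(v1) || !length(v2)) stop("both samples must be non-empty")
  s <- stats::sd(v1) + stats::sd(v2)
  if (!is.finite(s) || s == 0)
    stop("degenerate distributions: sd1 + sd2 must be > 0")
  (mean(v1) - mean(v2)) / s
}

#' One-way ANOVA with pairwise LSD comparisons
#'
#' Fits a one-way analysis of variance across the groups (via
#' [stats::aov()]), then compares every pair of group means with the
#' classical least-significant-difference criterion: the pooled
#' within-group mean square gives the standard error
#' `sqrt(MSE * (1/ni + 1/nj))` (equivalently the harmonic-mean-n form for
#' unequal group sizes) and a t test with the residual degrees of freedom.
#' No multiplicity correction is applied, as is conventional for the
#' protected LSD. Groups are summarised with a compact letter display at
#' `alpha`: groups sharing a letter are not significantly different.
#'
#' @param samples named list of numeric vectors, or of
#'   [ClassSample-class] objects (names default to their labels).
#' @param alpha significance level (default 0.01).
#' @return list with elements `anova` (data.frame: `F`, `p`, `df1`, `df2`),
#'   `pairs` (data.frame: `group1`, `group2`, `diff`, `t`, `p`,
#'   `distinct`), `letters` (named character vector) and `alpha`; class
#'   `"anovaLSD"`.
#' @export
anovaLsd <- function(samples, alpha = 0.01) {
  if (length(samples) < 2L) stop("at least two groups are required")
  vals <- lapply(samples, function(s) {
    v <- if (is(s, "ClassSample")) s@values else as.numeric(s)
    v[!is.na(v)]
  })
  if (is.null(names(vals)) || any(names(vals) == ""))
    names(vals) <- vapply(seq_along(samples), function(i) {
      s <- samples[[i]]
      if (is(s, "ClassSample")) s@label else paste0("group", i)
    }, character(1L))
  ns <- lengths(vals)
  if (any(ns < 2L)) stop("every group needs at least two values")
  df <- data.frame(y = unlist(vals, use.names = FALSE),
                   g = factor(rep(names(vals), ns), levels = names(vals)))
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1L]]
  mse <- an["Residuals", "Mean Sq"]
  dfe <- an["Residuals", "Df"]
  Fv <- an["g", "F value"]; pv <- an["g", "Pr(>F)"]
  means <- vapply(vals, mean, numeric(1L))
  cmb <- utils::combn(names(vals), 2L)
  pairs <- do.call(rbind, apply(cmb, 2L, function(p) {
    se <- sqrt(mse * (1 / ns[[p[1L]]] + 1 / ns[[p[2L]]]))
    dm <- means[[p[1L]]] - means[[p[2L]]]
    tv <- if (se > 0) dm / se else Inf * sign(dm)
    pp <- 2 * stats::pt(-abs(tv), dfe)
    data.frame(group1 = p[1L], group2 = p[2L], diff = dm, t = tv, p = pp,
               distinct = pp <= alpha)
  }))
  rownames(pairs) <- NULL
  out <- list(anova = data.frame(F = Fv, p = pv, df1 = an["g", "Df"],
                                 df2 = dfe),
              pairs = pairs,
              letters = .letterDisplay(names(vals), means, pairs),
              alpha = alpha)
  class(out) <- "anovaLSD"
  out
}

#' @export
print.anovaLSD <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.3g; LSD at alpha = %g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p, x$alpha))
  print(x$pairs, digits = 4)
  cat("letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = "  "), "\n")
  invisible(x)
}

# insert-and-absorb compact letter display from a pairwise `distinct` table
.letterDisplay <- function(groups, means, pairs) {
  groups <- groups[order(-means[groups])]
  cols <- list(groups)  # each column: set of groups sharing a letter
  for (k in seq_len(nrow(pairs))) {
    if (!pairs$distinct[k]) next
    a <- pairs$group1[k]; b <- pairs$group2[k]
    newCols <- list()
    for (cl in cols) {
      if (all(c(a, b) %in% cl)) {
        newCols <- c(newCols, list(setdiff(cl, a)), list(setdiff(cl, b)))
      } else newCols <- c(newCols, list(cl))
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(newCols))
    for (i in seq_along(newCols)) for (j in seq_along(newCols))
      if (i != j && keep[i] && keep[j] &&
          all(newCols[[i]] %in% newCols[[j]]) &&
          length(newCols[[i]]) < length(newCols[[j]]))
        keep[i] <- FALSE
    dup <- duplicated(lapply(newCols, sort))
    cols <- newCols[keep & !dup]
  }
  # order columns by the best (highest-mean) group they contain
  first <- vapply(cols, function(cl)
    min(match(cl, groups, nomatch = length(groups) + 1L)), numeric(1L))
  cols <- cols[order(first)]
  lets <- vapply(groups, function(g) {
    paste(letters[which(vapply(cols, function(cl) g %in% cl, logical(1L)))],
          collapse = "")
  }, character(1L))
  names(lets) <- groups
  lets
}

#' Class-separability table over cameras, altitudes and indices
#'
#' For every scene (one camera x altitude combination) and every requested
#' vegetation index, samples the three cover classes from their regions of
#' interest, pools crop and weeds into a vegetation class, and emits one row
#' per class pair — vegetation vs bare soil and crop vs weed — carrying the
#' class max/min/mean/SD, the two-group ANOVA/LSD outcome at `alpha` and the
#' M-statistic. NDVI rows are produced only for stacks with a NIR band; a
#' missing class yields an absent row rather than a failure.
#'
#' @param scenes list of entries, each a list with elements `camera`
#'   (label), `altitude` (m), `stack` (a [MultibandStack-class]) and `rois`
#'   (named list with `crop`, `weed`, `bare_soil` masks or polygon lists,
#'   as accepted by [sampleClassPixels()]).
#' @param indices character vector of indices to evaluate.
#' @param alpha LSD significance level.
#' @return data.frame with columns `camera`, `altitude`, `index`, `pair`,
#'   `max1`, `min1`, `mean1`, `sd1`, `max2`, `min2`, `mean2`, `sd2`,
#'   `anova_p`, `lsd_distinct`, `M`.
#' @export
separabilityTable <- function(scenes, indices = c("NDVI", "NGRDI", "ExG"),
                              alpha = 0.01) {
  indices <- match.arg(indices, .indexNames, several.ok = TRUE)
  rows <- list()
  for (sc in scenes) {
    stopifnot(all(c("camera", "altitude", "stack", "rois") %in% names(sc)))
    for (ix in indices) {
      if (ix == "NDVI" && is.na(bandIndex(sc$stack, "NIR"))) next
      img <- computeIndex(sc$stack, ix)
      samp <- lapply(c(crop = "crop", weed = "weed",
                       bare_soil = "bare_soil"), function(cl) {
        if (is.null(sc$rois[[cl]])) return(NULL)
        tryCatch(sampleClassPixels(img, sc$rois[[cl]], cl, ix),
                 error = function(e) NULL)
      })
      veg <- if (!is.null(samp$crop) && !is.null(samp$weed))
        vegetationSample(samp$crop, samp$weed) else NULL
      rows[[length(rows) + 1L]] <-
        .sepRow(sc$camera, sc$altitude, ix, "vegetation_vs_bare_soil",
                veg, samp$bare_soil, alpha)
      rows[[length(rows) + 1L]] <-
        .sepRow(sc$camera, sc$altitude, ix, "crop_vs_weed",
                samp$crop, samp$weed, alpha)
    }
  }
  do.call(rbind, rows)
}

.sepRow <- function(camera, altitude, index, pair, s1, s2, alpha) {
  base <- data.frame(camera = camera, altitude = altitude, index = index,
                     pair = pair)
  if (is.null(s1) || is.null(s2)) {
    base[c("max1", "min1", "mean1", "sd1", "max2", "min2", "mean2", "sd2",
           "anova_p", "M")] <- NA_real_
    base$lsd_distinct <- NA
    return(base)
  }
  v1 <- s1@values; v2 <- s2@values
  lsd <- anovaLsd(stats::setNames(list(v1, v2), c(s1@label, s2@label)),
                  alpha = alpha)
  cbind(base,
        data.frame(max1 = max(v1), min1 = min(v1), mean1 = mean(v1),
                   sd1 = stats::sd(v1),
                   max2 = max(v2), min2 = min(v2), mean2 = mean(v2),
                   sd2 = stats::sd(v2),
                   anova_p = lsd$anova$p,
                   lsd_distinct = lsd$pairs$distinct[1L],
                   M = mStatistic(s1, s2)))
}
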