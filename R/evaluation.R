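#' Per-class Euclidean landmark errors
#'
#' @param pred,truth complete [LandmarkSet-class] objects.
#' @return named numeric(5), Euclidean distance in mm per class.
#' @export
landmarkErrors <- function(pred, truth) {
    a <- landmarkPoints(pred)
    b <- landmarkPoints(truth)
    sqrt(rowSums((a - b)^2))
}

#' Build a distance table
#'
#' @param caseId,class,error equal-length vectors (error in mm, >= 0).
#' @return data.frame with columns case, class, error.
#' @export
distanceTable <- function(caseId, class, error) {
    stopifnot(length(caseId) == length(class),
              length(class) == length(error), all(error >= 0))
    data.frame(case = caseId, class = class, error = error)
}

.summary_row <- function(x, label) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    sw <- if (length(x) >= 3 && stats::sd(x) > 0)
        tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
    else NA_real_
    data.frame(class = label, n = length(x), median = q[2], lq = q[1],
               uq = q[3], shapiro_p = sw)
}

#' Median (LQ-UQ) error summaries
#'
#' Summarises a distance table per landmark class plus a pooled row
#' ("All"), as median with lower/upper quartiles by inclusive linear
#' interpolation, and a Shapiro-Wilk normality p-value per group.
#'
#' @param table data.frame from [distanceTable()] (columns class, error).
#' @return data.frame: class, n, median, lq, uq, shapiro_p.
#' @export
summarizeDistances <- function(table) {
    if (nrow(table) == 0L) stop("empty distance table")
    groups <- split(table$error, table$class)
    out <- do.call(rbind, lapply(names(groups), function(g)
        .summary_row(groups[[g]], g)))
    # keep anatomical ordering where applicable
    known <- intersect(.LANDMARK_CLASSES, out$class)
    out <- out[order(match(out$class, .LANDMARK_CLASSES)), ]
    rbind(out, .summary_row(table$error, "All"))
}

#' Paired difference of two matched error lists
#'
#' Mean +/- sd of the paired differences d1 - d2 together with a two-sided
#' Wilcoxon signed-rank p-value. Zero differences are dropped before the
#' test; the exact null distribution is used for n <= 25 without ties,
#' otherwise a normal approximation with continuity correction. When all
#' differences are zero the test is degenerate and p = 1 by convention.
#'
#' @param d1,d2 equal-length numeric vectors (n >= 5).
#' @return list: mean, sd, p, nNonzero, method.
#' @export
pairedDifferenceTest <- function(d1, d2) {
    if (length(d1) != length(d2)) stop("d1 and d2 must have equal length")
    if (length(d1) < 5L) stop("need at least 5 pairs")
    d <- d1 - d2
    dn <- d[d != 0]
    if (length(dn) == 0L)
        return(list(mean = 0, sd = stats::sd(d), p = 1, nNonzero = 0L,
                    method = "degenerate (all differences zero)"))
    wt <- suppressWarnings(
        stats::wilcox.test(dn, exact = length(dn) <= 25, correct = TRUE))
    list(mean = mean(d), sd = stats::sd(d), p = wt$p.value,
         nNonzero = length(dn), method = wt$method)
}

#' Bland-Altman agreement
#'
#' Bias (mean difference a - b) and 95\% limits of agreement
#' bias +/- 1.96 sd (sample sd, n - 1).
#'
#' @param a,b equal-length numeric vectors (n >= 2).
#' @return list: bias, sd, loaLower, loaUpper, n.
#' @export
blandAltman <- function(a, b) {
    if (length(a) != length(b)) stop("a and b must have equal length")
    if (length(a) < 2L) stop("need at least 2 pairs")
    d <- a - b
    bias <- mean(d)
    s <- stats::sd(d)
    list(bias = bias, sd = s, loaLower = bias - 1.96 * s,
         loaUpper = bias + 1.96 * s, n = length(d))
}

#' Squared Pearson correlation
#'
#' @param a,b equal-length numeric vectors (n >= 3) with nonzero variance.
#' @return r^2 in [0, 1].
#' @export
correlationR2 <- function(a, b) {
    if (length(a) != length(b)) stop("a and b must have equal length")
    if (length(a) < 3L) stop("need at least 3 pairs")
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
        stop("zero variance in one of the inputs")
    stats::cor(a, b)^2
}
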