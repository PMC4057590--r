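#' Result of a nonparametric hypothesis test
#'
#' @slot statistic the test statistic (U, W+, H or rho).
#' @slot pValue two-sided p-value in \code{[0, 1]}.
#' @slot method short label of the test and mode.
#' @slot tieCorrected whether a tie correction entered the null
#'   distribution or variance.
#' @export
setClass("TestResult",
    representation(statistic = "numeric", pValue = "numeric",
        method = "character", tieCorrected = "logical"))

setValidity("TestResult", function(object) {
    if (length(object@pValue) == 1L && !is.na(object@pValue) &&
        object@pValue >= 0 && object@pValue <= 1) TRUE
    else "pValue must be a single probability"
})

setMethod("show", "TestResult", function(object) {
    cat(sprintf("%s: statistic = %.4g, two-sided p = %.4g%s\n",
        object@method, object@statistic, object@pValue,
        if (object@tieCorrected) " (tie-corrected)" else ""))
})

testResult <- function(statistic, pValue, method, tieCorrected = FALSE) {
    new("TestResult", statistic = as.numeric(statistic),
        pValue = min(1, max(0, as.numeric(pValue))), method = method,
        tieCorrected = tieCorrected)
}

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
setMethod("pValue", "TestResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))
#' @rdname accessors
setMethod("statistic", "TestResult", function(x) x@statistic)

#' Tumour volume from three orthogonal diameters
#'
#' The ellipsoid-type approximation customary for xenografts measured by
#' ultrasound: height x width x thickness / 2, symmetric in its three
#' arguments.
#'
#' @param height,width,thickness diameters in mm, all > 0 (vectorized).
#' @return Volume in mm^3.
#' @examples
#' tumorVolume(10, 10, 10)  # 500
#' @export
tumorVolume <- function(height, width, thickness) {
    if (any(c(height, width, thickness) <= 0, na.rm = TRUE) ||
        anyNA(c(height, width, thickness)))
        stopf("all diameters must be positive")
    height * width * thickness / 2
}

#' Percentage change between two measurements
#'
#' \code{100 * (final - start) / start}; signed, negative values allowed
#' (regression under treatment).
#'
#' @param start,final measurements in the same units; \code{start > 0}
#'   (vectorized).
#' @return Signed percentage.
#' @examples
#' percentDelta(100, 200)  # +100
#' percentDelta(200, 172)  # -14
#' @export
percentDelta <- function(start, final) {
    if (any(start <= 0, na.rm = TRUE) || anyNA(start))
        stopf("start values must be positive")
    100 * (final - start) / start
}

#' Fold change implied by a percentage delta
#'
#' \code{1 + delta/100}, reported to one decimal as customary in growth
#' summaries (a +79% delta is a 1.8-fold increase).
#'
#' @param deltaPercent percentage delta, > -100 (vectorized).
#' @param digits decimals in the report (default 1).
#' @return Fold change, rounded half away from zero.
#' @examples
#' foldChange(c(79, 37, 81))  # 1.8 1.4 1.8
#' @export
foldChange <- function(deltaPercent, digits = 1) {
    if (any(deltaPercent <= -100, na.rm = TRUE) || anyNA(deltaPercent))
        stopf("deltaPercent must exceed -100")
    roundHalfUp((1 + deltaPercent / 100) * 10^digits) / 10^digits
}

#' Median (range) summary of a group
#'
#' The summary convention of small-cohort animal studies: sample median
#' (mean of the middle two for even n) with the min-max range.
#'
#' @param values numeric vector, n >= 1.
#' @return One-row data.frame with columns \code{n, median, range_low,
#'   range_high}.
#' @examples
#' groupSummary(c(20, 0, 30, 10))  # median 15
#' @export
groupSummary <- function(values) {
    if (!length(values) || anyNA(values))
        stopf("values must be non-empty and free of NA")
    data.frame(n = length(values), median = stats::median(values),
        range_low = min(values), range_high = max(values))
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic (the raw rank statistic divided by
#' \eqn{1 - \sum(t^3 - t)/(N^3 - N)}) referred to a chi-square distribution
#' with k-1 degrees of freedom; the computation is delegated to
#' \code{stats::kruskal.test}. All-identical data return H = 0, p = 1 by
#' convention.
#'
#' @param groups list of >= 2 numeric vectors, each non-empty, total
#'   N >= 3.
#' @return A [TestResult-class].
#' @examples
#' kruskalWallis(list(c(20, 20, 50, 40), c(0, 30, 10, 20, 40, 0),
#'     c(10, 0, 10, 0)))
#' @export
kruskalWallis <- function(groups) {
    if (!is.list(groups) || length(groups) < 2L)
        stopf("at least two groups are required")
    if (any(!vapply(groups, length, integer(1))))
        stopf("every group must be non-empty")
    pooled <- unlist(groups)
    if (length(pooled) < 3L)
        stopf("at least 3 observations in total are required")
    if (length(unique(pooled)) == 1L)
        return(testResult(0, 1, "Kruskal-Wallis", tieCorrected = TRUE))
    kt <- stats::kruskal.test(groups)
    testResult(unname(kt$statistic), kt$p.value, "Kruskal-Wallis",
        tieCorrected = TRUE)
}

# exact two-sided p by doubling the smaller tail, capped at 1
twoSidedFromTails <- function(pLow, pHigh) min(1, 2 * min(pLow, pHigh))

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' The U statistic counts pairs \eqn{a_i > b_j} plus half the ties. Exact
#' mode uses the closed-form null distribution when the pooled sample has
#' no ties, and otherwise enumerates every assignment of the observed
#' multiset to the two groups (feasible for groups of up to 10); with
#' larger tied samples it refuses and instructs the asymptotic mode.
#' Asymptotic mode is the normal approximation with tie-corrected variance
#' and no continuity correction (so that with two groups it squares to the
#' tie-corrected Kruskal-Wallis chi-square). Two-sided throughout.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param mode \code{"auto"} (exact when both groups have <= 10
#'   observations), \code{"exact"} or \code{"asymptotic"}.
#' @return A [TestResult-class] with the U statistic of \code{a} over
#'   \code{b}.
#' @examples
#' mannWhitney(c(20, 20, 50, 40), c(10, 0, 10, 0), mode = "exact")
#' @export
mannWhitney <- function(a, b, mode = c("auto", "exact", "asymptotic")) {
    mode <- match.arg(mode)
    if (!length(a) || !length(b))
        stopf("both samples must be non-empty")
    if (anyNA(a) || anyNA(b)) stopf("samples must be free of NA")
    m <- length(a); n <- length(b); N <- m + n
    pooled <- c(a, b)
    hasTies <- anyDuplicated(pooled) > 0L
    U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    if (mode == "auto")
        mode <- if (m <= 10L && n <= 10L) "exact" else "asymptotic"
    if (mode == "exact") {
        if (!hasTies) {
            # closed-form exact null (Mann-Whitney counts), any group size
            pLow <- stats::pwilcox(U, m, n)
            pHigh <- 1 - stats::pwilcox(U - 1, m, n)
            return(testResult(U, twoSidedFromTails(pLow, pHigh),
                "Mann-Whitney exact"))
        }
        nComb <- choose(N, m)
        if (nComb > 5e5)
            stopf(paste("exact mode with ties requires enumerating %g",
                "assignments; use mode = 'asymptotic'"), nComb)
        r <- rank(pooled)
        idx <- utils::combn(N, m)
        Uall <- colSums(matrix(r[idx], nrow = m)) - m * (m + 1) / 2
        eps <- 1e-9
        pLow <- mean(Uall <= U + eps)
        pHigh <- mean(Uall >= U - eps)
        return(testResult(U, twoSidedFromTails(pLow, pHigh),
            "Mann-Whitney exact (tie permutation)", tieCorrected = TRUE))
    }
    # asymptotic: tie-corrected variance, no continuity correction
    tieTab <- table(pooled)
    sigma2 <- m * n / 12 * ((N + 1) - sum(tieTab^3 - tieTab) / (N * (N - 1)))
    if (sigma2 <= 0)
        return(testResult(U, 1, "Mann-Whitney asymptotic",
            tieCorrected = TRUE))
    z <- (U - m * n / 2) / sqrt(sigma2)
    testResult(U, 2 * stats::pnorm(-abs(z)), "Mann-Whitney asymptotic",
        tieCorrected = TRUE)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences \code{x - y} are ranked by absolute value with midranks;
#' zero differences are dropped first (all-zero pairs return p = 1 by
#' convention). Exact mode (n <= 15 after dropping zeros) enumerates all
#' 2^n sign assignments of the observed absolute ranks, so tied ranks are
#' handled exactly; larger samples use the normal approximation with
#' tie-corrected variance. Two-sided.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return A [TestResult-class] with the positive-rank sum W+.
#' @examples
#' wilcoxonSignedRank(1:6, 1:6 + 5)  # exact p = 2/64
#' @export
wilcoxonSignedRank <- function(x, y) {
    if (length(x) != length(y))
        stopf("paired samples must have equal length")
    if (anyNA(x) || anyNA(y)) stopf("samples must be free of NA")
    d <- x - y
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L)
        return(testResult(0, 1, "Wilcoxon signed-rank"))
    if (n < 3L)
        stopf("at least 3 non-zero differences are required, got %d", n)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    eps <- 1e-9
    if (n <= 15L) {
        signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
        Wall <- as.vector(signs %*% r)
        pLow <- mean(Wall <= W + eps)
        pHigh <- mean(Wall >= W - eps)
        return(testResult(W, twoSidedFromTails(pLow, pHigh),
            "Wilcoxon signed-rank exact", tieCorrected = TRUE))
    }
    tieTab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tieTab^3 - tieTab) / 48
    if (sigma2 <= 0)
        return(testResult(W, 1, "Wilcoxon signed-rank asymptotic",
            tieCorrected = TRUE))
    z <- (W - n * (n + 1) / 4) / sqrt(sigma2)
    testResult(W, 2 * stats::pnorm(-abs(z)),
        "Wilcoxon signed-rank asymptotic", tieCorrected = TRUE)
}

# all permutations of 1..n as an (n! x n) matrix
permMatrix <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    p <- permMatrix(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
        q <- p
        q[q >= i] <- q[q >= i] + 1L
        cbind(rep.int(i, nrow(q)), q)
    }))
}

#' Spearman rank correlation test
#'
#' Rank correlation with midrank ties. For n <= 8 the two-sided p-value is
#' the exact permutation probability of an absolute correlation at least
#' as large; for larger n the t-approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n-2 degrees of freedom is
#' used.
#'
#' @param x,y numeric vectors of equal length >= 3; either having
#'   zero rank variance (all values tied) is an error.
#' @return A [TestResult-class] with statistic rho.
#' @examples
#' spearmanRank(1:5, c(2, 1, 4, 3, 5))
#' @export
spearmanRank <- function(x, y) {
    n <- length(x)
    if (length(y) != n || n < 3L)
        stopf("x and y must have equal length >= 3")
    if (anyNA(x) || anyNA(y)) stopf("samples must be free of NA")
    rx <- rank(x); ry <- rank(y)
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
        stopf("zero variance in ranks; correlation undefined")
    rho <- stats::cor(rx, ry)
    tied <- anyDuplicated(rx) > 0L || anyDuplicated(ry) > 0L
    if (n <= 8L) {
        perms <- permMatrix(n)
        rhoPerm <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
        p <- mean(abs(rhoPerm) >= abs(rho) - 1e-9)
        return(testResult(rho, p, "Spearman exact permutation",
            tieCorrected = tied))
    }
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    testResult(rho, 2 * stats::pt(-abs(tstat), n - 2),
        "Spearman t-approximation", tieCorrected = tied)
}
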