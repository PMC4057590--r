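test_that("tumour volume is half the diameter product and symmetric", {
    expect_equal(tumorVolume(10, 10, 10), 500)
    expect_equal(tumorVolume(5, 8, 10), 200)
    perms <- rbind(c(5, 8, 10), c(5, 10, 8), c(8, 5, 10), c(8, 10, 5),
        c(10, 5, 8), c(10, 8, 5))
    expect_equal(apply(perms, 1, function(p)
        tumorVolume(p[1], p[2], p[3])), rep(200, 6))
    expect_error(tumorVolume(0, 5, 5), "positive")
})

test_that("percentage deltas are signed and need a positive start", {
    expect_equal(percentDelta(100, 200), 100)
    expect_equal(percentDelta(200, 172), -14)
    expect_equal(percentDelta(143, 706), 393.7, tolerance = 1e-3)
    expect_error(percentDelta(0, 5), "positive")
})

test_that("fold changes match the printed one-decimal convention", {
    expect_equal(foldChange(79), 1.8)
    expect_equal(foldChange(37), 1.4)
    expect_equal(foldChange(81), 1.8)
    expect_equal(foldChange(0), 1.0)
    expect_error(foldChange(-100), "-100")
})

test_that("group summaries use the median (range) convention", {
    t1 <- table1()
    expect_equal(groupSummary(t1$exam1$g1)$median, 15)
    expect_equal(groupSummary(t1$exam1$g2)$median, 10)
    expect_equal(groupSummary(t1$exam2$g3)$median, 5)
    s <- groupSummary(c(3, 1, 4, 1, 5))
    expect_equal(s$range_low, 1)
    expect_equal(s$range_high, 5)
    expect_equal(s$n, 5)
    expect_error(groupSummary(numeric()), "non-empty")
})

test_that("tie-corrected Kruskal-Wallis matches the hand rank computation", {
    t1 <- table1()
    groups <- t1$exam2
    res <- kruskalWallis(groups)
    # independent oracle: rank sums with midranks and the tie factor
    pooled <- unlist(groups)
    r <- bruteMidranks(pooled)
    N <- length(pooled)
    sizes <- lengths(groups)
    Rsum <- split(r, rep(seq_along(groups), sizes))
    Hraw <- 12 / (N * (N + 1)) *
        sum(vapply(seq_along(Rsum), function(i)
            sum(Rsum[[i]])^2 / sizes[i], numeric(1))) - 3 * (N + 1)
    tieTab <- table(pooled)
    H <- Hraw / (1 - sum(tieTab^3 - tieTab) / (N^3 - N))
    expect_equal(statistic(res), H, tolerance = 1e-10)
    expect_equal(pValue(res), stats::pchisq(H, 2, lower.tail = FALSE))
    # degenerate: identical data
    expect_equal(pValue(kruskalWallis(list(c(1, 1), c(1, 1, 1)))), 1)
    expect_error(kruskalWallis(list(1:3)), "two groups")
})

test_that("exact Mann-Whitney enumerates the observed multiset", {
    res <- mannWhitney(c(20, 20, 50, 40), c(10, 0, 10, 0), mode = "exact")
    expect_equal(pValue(res), 2 / 70)
    expect_equal(statistic(res), 16)    # complete separation: U = mn
    same <- mannWhitney(c(1, 2, 3), c(1, 2, 3), mode = "exact")
    expect_equal(pValue(same), 1)
    # without ties the enumeration equals the closed-form null
    a <- c(1.1, 2.3, 3.7, 5.2); b <- c(0.4, 2.9, 4.1, 6.6)
    expect_equal(pValue(mannWhitney(a, b, mode = "exact")),
        stats::wilcox.test(a, b, exact = TRUE)$p.value)
})

test_that("asymptotic Mann-Whitney squares to two-group Kruskal-Wallis", {
    a <- c(3, 5, 5, 8, 12, 12, 12, 15)
    b <- c(2, 5, 7, 9, 12, 18)
    pa <- pValue(mannWhitney(a, b, mode = "asymptotic"))
    pk <- pValue(kruskalWallis(list(a, b)))
    expect_equal(pa, pk, tolerance = 1e-10)
})

test_that("exact and asymptotic Mann-Whitney agree for larger samples", {
    a <- (1:15) + 3.5; b <- as.numeric(1:15)   # shifted, no ties
    pe <- pValue(mannWhitney(a, b, mode = "exact"))
    pa <- pValue(mannWhitney(a, b, mode = "asymptotic"))
    expect_lt(abs(pe - pa), 0.01)
})

test_that("Mann-Whitney detects a constructed shift with high power", {
    hits <- vapply(1:100, function(s) {
        set.seed(s)
        a <- stats::rnorm(20, 10, 5)
        b <- stats::rnorm(20, 0, 5)
        pValue(mannWhitney(a, b, mode = "exact")) < 0.05
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("exact signed-rank handles tied ranks and the zero convention", {
    res <- wilcoxonSignedRank(1:6, 1:6 + 5)
    expect_equal(pValue(res), 2 / 64)
    expect_equal(statistic(res), 0)
    expect_equal(pValue(wilcoxonSignedRank(c(4, 4, 4), c(4, 4, 4))), 1)
    expect_error(wilcoxonSignedRank(1:4, c(1, 2, 3, 9)), "3 non-zero")
    # antisymmetric differences sit at the null centre W+ = n(n+1)/4
    x <- c(10, 20, 30, 40, 50, 60); y <- x + c(5, 5, 5, -5, -5, -5)
    expect_equal(statistic(wilcoxonSignedRank(x, y)), 6 * 7 / 4)
    # no ties: agrees with the classical exact distribution
    x2 <- c(1, 4, 9, 16, 25, 36, 49); y2 <- x2 + c(2, -1, 5, 3, -7, 11, 6)
    expect_equal(pValue(wilcoxonSignedRank(y2, x2)),
        stats::wilcox.test(y2, x2, paired = TRUE,
            exact = TRUE)$p.value)
})

test_that("Spearman matches brute-force midranks and the monotone limits", {
    expect_equal(statistic(spearmanRank(1:6, c(2, 4, 6, 8, 10, 12))), 1)
    expect_equal(statistic(spearmanRank(1:6, 6:1)), -1)
    x <- c(1, 2, 2, 3, 4); y <- c(2, 1, 3, 5, 4)
    res <- spearmanRank(x, y)
    expect_equal(statistic(res),
        brutePearson(bruteMidranks(x), bruteMidranks(y)))
    expect_error(spearmanRank(c(1, 1, 1), 1:3), "zero variance")
    # t-approximation branch agrees with cor.test for n > 8
    set.seed(1)
    a <- stats::rnorm(20); b <- a + stats::rnorm(20)
    expect_equal(pValue(spearmanRank(a, b)),
        stats::cor.test(a, b, method = "spearman",
            exact = FALSE)$p.value, tolerance = 1e-6)
})

test_that("rank-based tests are invariant under monotone transforms", {
    a <- c(3, 7, 8, 12, 20); b <- c(1, 6, 9, 15, 27, 31)
    f <- function(v) exp(v / 10)
    expect_equal(pValue(mannWhitney(a, b)),
        pValue(mannWhitney(f(a), f(b))))
    expect_equal(pValue(kruskalWallis(list(a, b))),
        pValue(kruskalWallis(list(f(a), f(b)))))
    expect_equal(statistic(spearmanRank(a, b[1:5])),
        statistic(spearmanRank(f(a), f(b[1:5]))))
})
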