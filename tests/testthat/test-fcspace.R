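test_that("projection onto basis loadings reads off coordinates", {
    S <- diag(3)[, 1:2]
    rownames(S) <- paste0("g", 1:3)
    colnames(S) <- c("FC1", "FC2")
    Q <- ExpressionMatrix(matrix(c(5, -2, 7), ncol = 1,
                                 dimnames = list(paste0("g", 1:3), "q1")))
    pr <- projectToFC(Q, S)
    expect_equal(unname(fcScores(pr)[, 1]), c(5, -2))
    # zero sample vector projects to zero scores
    Q0 <- ExpressionMatrix(matrix(0, 3, 1,
                                  dimnames = list(paste0("g", 1:3), "q")))
    expect_equal(unname(fcScores(projectToFC(Q0, S))[, 1]), c(0, 0))
})

test_that("projection recovers known coefficients for orthonormal loadings", {
    withr::with_seed(16, {
        S <- qr.Q(qr(matrix(rnorm(400 * 4), 400, 4)))
        w <- matrix(rnorm(4 * 6), 4, 6)
    })
    rownames(S) <- paste0("g", 1:400)
    Q <- ExpressionMatrix(S %*% w,
                          geneIds = rownames(S),
                          sampleIds = paste0("q", 1:6))
    pr <- projectToFC(Q, S)
    expect_equal(unname(fcScores(pr)), w, tolerance = 1e-10)
    expect_equal(pr@coverage, 1)
})

test_that("projection is linear in the query", {
    withr::with_seed(17, {
        S <- matrix(rnorm(200 * 3), 200, 3,
                    dimnames = list(paste0("g", 1:200), NULL))
        Q1 <- matrix(rnorm(200 * 2), 200, 2,
                     dimnames = list(paste0("g", 1:200), c("a", "b")))
        Q2 <- matrix(rnorm(200 * 2), 200, 2,
                     dimnames = list(paste0("g", 1:200), c("a", "b")))
    })
    combo <- fcScores(projectToFC(2 * Q1 + 5 * Q2, S))
    expect_equal(combo,
                 2 * fcScores(projectToFC(Q1, S)) +
                 5 * fcScores(projectToFC(Q2, S)),
                 tolerance = 1e-10)
})

test_that("unit-norm loadings rescale scores per component", {
    withr::with_seed(18, S <- matrix(rnorm(100 * 2), 100, 2,
                                     dimnames = list(paste0("g", 1:100),
                                                     NULL)))
    Q <- matrix(rnorm(100), 100, 1,
                dimnames = list(paste0("g", 1:100), "q"))
    raw <- fcScores(projectToFC(Q, S))
    un <- fcScores(projectToFC(Q, S, unitNorm = TRUE))
    expect_equal(un, raw / sqrt(colSums(S^2)), tolerance = 1e-12)
})

test_that("low gene coverage is refused with a clear error", {
    S <- matrix(rnorm(100), 100, 1, dimnames = list(paste0("g", 1:100), NULL))
    Q <- matrix(rnorm(50), 50, 1,
                dimnames = list(paste0("g", 1:50), "q"))
    expect_error(projectToFC(Q, S), "coverage")
    pr <- projectToFC(Q, S, minCoverage = 0.4)
    expect_equal(pr@coverage, 0.5)
    Qnone <- matrix(rnorm(5), 5, 1, dimnames = list(paste0("x", 1:5), "q"))
    expect_error(projectToFC(Qnone, S), "no genes shared")
})

test_that("neighbor retention follows the frequency rule", {
    # group of 2; reference correlations crafted per the worked case:
    # ref1 (0.99, 0.99), ref2 (0.96, 0.20), ref3 (0.10, 0.10)
    base <- withr::with_seed(19, matrix(rnorm(40 * 5), 40, 5))
    mk <- function(target, anchor) {
        z <- residuals(lm(withr::with_seed(anchor * 91 + round(target * 100),
                                           rnorm(length(anchor_vec))) ~
                          anchor_vec))
        anchor_vec * target + z * sqrt(1 - target^2) * sd(anchor_vec) / sd(z)
    }
    anchor_vec <- base[, 1]
    g1 <- anchor_vec
    g2 <- mk(0.2, 2)   # weakly related second member
    ref1 <- mk(0.995, 3)
    ref3 <- mk(0.10, 5)
    group <- as_projection(cbind(m1 = g1, m2 = g2))
    # ref2 correlates highly with m1 only
    ref2 <- mk(0.97, 7)
    reference <- as_projection(cbind(r1 = ref1, r2 = ref2, r3 = ref3))
    # compute the actual correlation pattern and check the rule directly
    nb <- findNeighbors(group, reference, minCor = 0.95, minFrac = 0.5)
    cc <- cor(fcScores(group), fcScores(reference))
    freq <- colSums(cc > 0.95)
    expected <- names(freq)[freq >= 1]       # ceiling(0.5 * 2) = 1
    expect_setequal(nb$sample, expected)
    expect_true(all(nb$freq >= 1))
    # an exact copy of a member is always retained with minCor 1
    reference2 <- as_projection(cbind(copy = g1, r3 = ref3))
    nb2 <- findNeighbors(group, reference2, minCor = 0.95)
    expect_true("copy" %in% nb2$sample)
    expect_equal(nb2$minCor[nb2$sample == "copy"], 1, tolerance = 1e-12)
    expect_error(findNeighbors(as_projection(base[, 0, drop = FALSE]),
                               reference), "empty")
})

test_that("lowering the correlation threshold never drops a neighbor", {
    withr::with_seed(23, {
        g <- matrix(rnorm(30 * 4), 30, 4)
        r <- matrix(rnorm(30 * 15), 30, 15)
    })
    group <- as_projection(g)
    reference <- as_projection(r)
    prev <- character(0)
    for (mc in c(0.8, 0.5, 0.2, -1)) {
        nb <- findNeighbors(group, reference, minCor = mc, minFrac = 0.25)
        expect_true(all(prev %in% nb$sample))
        prev <- nb$sample
    }
    # threshold 1: only a bit-identical profile survives
    refId <- as_projection(cbind(r[, 1:5], dup = g[, 1]))
    nbId <- findNeighbors(group, refId, minCor = 1 - 1e-12, minFrac = 0.25)
    expect_equal(nbId$sample, "dup")
})

test_that("tissue fingerprints annotate samples with their own tissue", {
    # three tissues with distinct planted FC signatures
    withr::with_seed(25, {
        centers <- matrix(rnorm(6 * 3, sd = 6), 6, 3)
        sc <- centers[, rep(1:3, each = 5)] +
            matrix(rnorm(6 * 15, sd = 0.4), 6)
    })
    colnames(sc) <- sprintf("r%02d", 1:15)
    labels <- setNames(rep(c("liver", "brain", "lung"), each = 5),
                       colnames(sc))
    proj <- as_projection(sc)
    fp <- buildFingerprint(proj, labels)
    expect_setequal(names(fp$medoids), c("liver", "brain", "lung"))
    expect_true(all(labels[fp$medoids] == names(fp$medoids)))
    # annotating the reference samples themselves returns their own label
    ann <- queryFingerprint(fp, proj)
    expect_equal(ann$label, unname(labels[ann$sample]))
    # a query identical to one reference sample: that tissue, correlation 1
    q <- as_projection(sc[, 3, drop = FALSE])
    one <- queryFingerprint(fp, q)
    expect_equal(one$label, "liver")
    expect_equal(one$bestCor, 1, tolerance = 1e-12)
    # cross-tissue correlation summary: diagonal beats off-diagonal
    summ <- tissueCorrelationSummary(proj, labels)
    for (lab in rownames(summ$median)) {
        others <- setdiff(colnames(summ$median), lab)
        expect_gt(summ$median[lab, lab], max(summ$median[lab, others]))
    }
})
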