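test_that("null two-class studies produce no differential FCs", {
    st <- genTwoClassStudy(400, 10, 6, shiftedFcs = integer(0),
                           effectSize = 0, seed = 31)
    de <- deFCTest(projectToFC(st$expr, st$S), st$labels)
    expect_equal(sum(de$de), 0)
    expect_equal(nrow(de), 6)
})

test_that("strongly shifted FCs are detected and others controlled", {
    hits <- misses <- 0
    for (seed in 1:10) {
        st <- genTwoClassStudy(400, 10, 6, shiftedFcs = c(2, 5),
                               effectSize = 5, seed = seed)
        de <- deFCTest(projectToFC(st$expr, st$S), st$labels)
        hits <- hits + sum(de$de[c(2, 5)])
        misses <- misses + sum(de$de[-c(2, 5)])
    }
    expect_equal(hits, 20)            # full power on the planted components
    expect_lte(misses, 4)             # false positives controlled
})

test_that("signature union bookkeeping matches the set algebra", {
    # two DE sets of sizes 72 and 89 sharing 61 members combine to 100
    setA <- paste0("FC", 1:72)
    setB <- paste0("FC", c(12:72, 73:100))
    expect_length(setB, 89)
    expect_length(intersect(setA, setB), 61)
    expect_length(union(setA, setB), 100)
})

test_that("t-test flavor and family size are honored", {
    st <- genTwoClassStudy(300, 8, 4, shiftedFcs = 1, effectSize = 3,
                           seed = 77)
    pr <- projectToFC(st$expr, st$S)
    welch <- deFCTest(pr, st$labels)
    student <- deFCTest(pr, st$labels, equalVar = TRUE)
    expect_false(identical(welch$p, student$p))
    wide <- deFCTest(pr, st$labels, familySize = 139)
    expect_true(all(wide$pAdj >= welch$pAdj - 1e-12))
    expect_error(deFCTest(pr, rep("A", ncol(fcScores(pr)))), "two groups")
})

test_that("purity and Gini follow the printed formulas", {
    # clusters (9A + 1B) and (2A + 8B): purity 17/20, Gini 0.18 / 0.32
    assignments <- rep(c(1, 2), c(10, 10))
    labels <- c(rep("A", 9), "B", rep("A", 2), rep("B", 8))
    ev <- clusterEval(assignments, labels)
    expect_equal(ev$purity, 0.85)
    expect_equal(unname(ev$gini), c(0.18, 0.32))
    expect_equal(unname(ev$clusterClass), c("A", "B"))

    # perfect split
    perfect <- clusterEval(rep(1:2, each = 5), rep(c("A", "B"), each = 5))
    expect_equal(perfect$purity, 1)
    expect_equal(unname(perfect$gini), c(0, 0))

    # one balanced cluster: purity 0.5, Gini 0.5, majority tie flagged
    expect_warning(even <- clusterEval(rep(1, 20),
                                       rep(c("A", "B"), each = 10)),
                   "tie")
    expect_equal(even$purity, 0.5)
    expect_equal(unname(even$gini), 0.5)
    # relabeling clusters leaves purity unchanged
    ev2 <- clusterEval(3 - assignments, labels)
    expect_equal(ev2$purity, ev$purity)
})

test_that("cophenetic correlation is exact on toy trees", {
    D <- as.matrix(dist(c(0, 1, 5, 6)))
    rownames(D) <- colnames(D) <- letters[1:4]
    t1 <- averageLinkageTree(D)
    expect_equal(copheneticCorrelation(t1, t1), 1)
    # same distances, same linkage: identical trees
    expect_equal(copheneticCorrelation(t1, averageLinkageTree(D)), 1)
    # perturbed tree: compare against brute-force pairwise cophenetics
    D2 <- D; D2["a", "b"] <- D2["b", "a"] <- 4
    t2 <- averageLinkageTree(D2)
    c1 <- as.matrix(cophenetic(t1)); c2 <- as.matrix(cophenetic(t2))
    ord <- rownames(c1)
    pairs <- t(combn(ord, 2))
    v1 <- c1[pairs]; v2 <- c2[ord, ord][pairs]
    expect_equal(copheneticCorrelation(t1, t2), cor(v1, v2),
                 tolerance = 1e-12)
    t3 <- averageLinkageTree(D[1:3, 1:3])
    expect_error(copheneticCorrelation(t1, t3), "same leaves")
})

test_that("binary metrics implement the five ratios with undefined flags", {
    # all correct
    perfect <- binaryMetrics(rep(c("p", "n"), c(5, 10)),
                             rep(c("p", "n"), c(5, 10)), "p")
    expect_equal(perfect$PPV, 1)
    expect_equal(perfect$NPV, 1)
    expect_equal(perfect$sensitivity, 1)
    expect_equal(perfect$specificity, 1)
    expect_equal(perfect$accuracy, 1)

    # mixed toy: TP=3 FP=1 FN=2 TN=4
    truth <- c(rep("p", 5), rep("n", 5))
    pred <- c("p", "p", "p", "n", "n", "p", "n", "n", "n", "n")
    bm <- binaryMetrics(pred, truth, "p")
    expect_equal(bm$PPV, 0.75)
    expect_equal(bm$NPV, 2 / 3)
    expect_equal(bm$sensitivity, 0.6)
    expect_equal(bm$specificity, 0.8)
    expect_equal(bm$accuracy, 0.7)
    expect_equal(bm$TP + bm$FN, bm$P)
    expect_equal(bm$TN + bm$FP, bm$N)

    # all-negative predictor: PPV undefined, specificity 1
    allneg <- binaryMetrics(rep("n", 10), truth, "p")
    expect_true(is.na(allneg$PPV))
    expect_equal(allneg$undefined, "PPV")
    expect_equal(allneg$specificity, 1)
    expect_equal(allneg$sensitivity, 0)
})

test_that("accuracy is the prevalence-weighted mix of sensitivity/specificity", {
    withr::with_seed(41, {
        truth <- sample(c("p", "n"), 60, replace = TRUE, prob = c(.3, .7))
        pred <- ifelse(runif(60) < 0.8, truth,
                       ifelse(truth == "p", "n", "p"))
    })
    bm <- binaryMetrics(pred, truth, "p")
    expect_equal(bm$accuracy,
                 (bm$sensitivity * bm$P + bm$specificity * bm$N) /
                     (bm$P + bm$N))
})

test_that("McNemar comparison uses the continuity-corrected statistic", {
    # b = 10, c = 2: statistic 49/12, significant
    truth <- rep("x", 20)
    predA <- c(rep("x", 10), rep("y", 2), rep("x", 8))
    predB <- c(rep("y", 10), rep("x", 2), rep("x", 8))
    mc <- mcnemarCompare(predA, predB, truth)
    expect_equal(mc$statistic, 49 / 12)
    expect_equal(mc$verdict, "different")
    # agreement with the standard implementation
    ref <- mcnemar.test(table(factor(predA == truth, c(FALSE, TRUE)),
                              factor(predB == truth, c(FALSE, TRUE))),
                        correct = TRUE)
    expect_equal(mc$statistic, unname(ref$statistic))
    expect_equal(mc$p, ref$p.value)

    # b = c = 5: statistic 0.1, not different
    pa <- c(rep("x", 5), rep("y", 5), rep("x", 10))
    pb <- c(rep("y", 5), rep("x", 5), rep("x", 10))
    mc2 <- mcnemarCompare(pa, pb, truth)
    expect_equal(mc2$statistic, 0.1)
    expect_equal(mc2$verdict, "not_different")
    # symmetry in (b, c)
    expect_equal(mcnemarCompare(pb, pa, truth)$statistic, mc2$statistic)
    # identical predictions
    mc3 <- mcnemarCompare(predA, predA, truth)
    expect_equal(mc3$verdict, "identical")
    expect_true(is.na(mc3$statistic))
})

test_that("majority-vote SVM classification is exact on separable classes", {
    withr::with_seed(51, {
        sc <- matrix(rnorm(4 * 60, sd = 0.3), 4, 60)
        sc[1, 1:20] <- sc[1, 1:20] + 6
        sc[2, 21:40] <- sc[2, 21:40] + 6
    })
    colnames(sc) <- sprintf("t%02d", 1:60)
    labels <- setNames(rep(c("a", "b", "c"), each = 20), colnames(sc))
    res <- maxvoteClassify(sc, labels, folds = 5, runs = 2, seed = 1)
    expect_equal(unname(res$sensitivity), rep(1, 3))
    expect_equal(unname(res$callRate), rep(1, 3))
    expect_equal(sum(res$confusion), 60)
    # per-class row sums + IDC = class totals
    expect_equal(rowSums(res$confusion) + res$idc, res$total)

    # two classes: a single voter cannot tie, so CR is 1 by construction
    two <- maxvoteClassify(sc[, 1:40], labels[1:40], folds = 4, runs = 1,
                           seed = 2)
    expect_equal(unname(two$callRate), c(1, 1))

    # sensitivity arithmetic: 68 correct of 70 called is about 0.971
    expect_equal(68 / 70, 0.9714286, tolerance = 1e-6)
})

test_that("the subsampling harness compares FC and gene spaces", {
    # small planted two-class study; FC space uses the true loadings
    st <- genTwoClassStudy(300, 30, 5, shiftedFcs = 2, effectSize = 2.5,
                           noiseSd = 2, seed = 61)
    pos <- ExpressionMatrix(exprValues(st$expr)[, st$labels == "B"])
    neg <- ExpressionMatrix(exprValues(st$expr)[, st$labels == "A"])
    res <- subsampleExperiment(pos, neg, st$S, testSizes = c(8, 8),
                               fractions = c(0.3, 1.0), repeats = 4,
                               runs = 2, seed = 5)
    s <- res$summary
    expect_setequal(unique(s$fraction), c(0.3, 1.0))
    expect_setequal(unique(s$space), c("fc", "gene"))
    expect_true(all(s$mean[!is.na(s$mean)] >= 0 &
                    s$mean[!is.na(s$mean)] <= 1))
    # fraction-1.0 rows come from a single evaluation per run: sd over runs
    expect_true(all(c("meanPctDifferent", "sdPctDifferent") %in%
                    names(res$agreement)))
    # determinism: the same seed reproduces the experiment bit-exactly
    res2 <- subsampleExperiment(pos, neg, st$S, testSizes = c(8, 8),
                                fractions = c(0.3, 1.0), repeats = 4,
                                runs = 2, seed = 5)
    expect_identical(res$summary, res2$summary)
    expect_error(subsampleExperiment(pos, neg, st$S, testSizes = c(8, 8),
                                     fractions = 0.001, repeats = 1,
                                     runs = 1, seed = 1), "empty class")
})
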