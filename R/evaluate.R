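#' @include fcspace.R
NULL

#' Differential FC testing between two groups
#'
#' Runs a two-sided unpaired t-test per FC (Welch by default) between the
#' two groups, adjusts with Benjamini-Hochberg over \code{familySize}
#' tests, and flags components with adjusted p below \code{alpha}.
#'
#' @param scores [FCProjection-class] or FCs x samples matrix.
#' @param groups named vector/factor assigning each sample to one of two
#'   groups (>= 2 samples per group).
#' @param alpha significance threshold on the adjusted p-value.
#' @param familySize BH family size; defaults to the number of FCs.
#' @param equalVar use Student's pooled-variance t-test instead of Welch.
#' @return data.frame with \code{fc}, \code{t}, \code{p}, \code{pAdj},
#'   \code{de}.
#' @export
deFCTest <- function(scores, groups, alpha = 0.05, familySize = NULL,
                     equalVar = FALSE) {
    sc <- if (is(scores, "FCProjection")) fcScores(scores) else as.matrix(scores)
    if (!is.null(names(groups))) groups <- groups[colnames(sc)]
    groups <- factor(groups)
    if (nlevels(groups) != 2) stop("exactly two groups are required")
    if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
    if (is.null(familySize)) familySize <- nrow(sc)
    g1 <- groups == levels(groups)[1]
    res <- t(apply(sc, 1, function(x) {
        tt <- stats::t.test(x[g1], x[!g1], var.equal = equalVar)
        c(tt$statistic, tt$p.value)
    }))
    fcIds <- rownames(sc)
    if (is.null(fcIds)) fcIds <- paste0("FC", seq_len(nrow(sc)))
    out <- data.frame(fc = fcIds, t = res[, 1], p = res[, 2],
                      row.names = NULL)
    out$pAdj <- bhAdjust(out$p, familySize)
    out$de <- out$pAdj < alpha
    out
}

#' Purity and Gini impurity of a clustering against mega-class labels
#'
#' Each cluster is assigned the majority mega-class of its members (ties
#' go to the lower-indexed class and are flagged).  Purity is the overall
#' fraction of samples whose cluster's class matches their own; the Gini
#' impurity of a cluster is 1 - sum of squared class fractions.
#'
#' @param assignments cluster ids per sample.
#' @param megaLabels class labels per sample (same order/names).
#' @return A list with \code{purity}, \code{gini} (named per cluster),
#'   \code{clusterClass}, and \code{ties} (logical per cluster).
#' @export
clusterEval <- function(assignments, megaLabels) {
    if (!is.null(names(assignments)) && !is.null(names(megaLabels)))
        megaLabels <- megaLabels[names(assignments)]
    if (length(assignments) != length(megaLabels))
        stop("assignments and labels must align")
    cl <- factor(assignments)
    lab <- factor(megaLabels)
    tab <- table(cl, lab)
    clusterClass <- apply(tab, 1, function(r) colnames(tab)[which.max(r)])
    ties <- apply(tab, 1, function(r) sum(r == max(r)) > 1)
    if (any(ties))
        warning("majority tie in cluster(s) ",
                paste(rownames(tab)[ties], collapse = ", "),
                "; assigned the lower-indexed class")
    correct <- sum(vapply(seq_len(nrow(tab)), function(i)
        tab[i, clusterClass[i]], numeric(1)))
    gini <- apply(tab, 1, function(r) {
        f <- r / sum(r)
        1 - sum(f^2)
    })
    list(purity = correct / length(assignments),
         gini = gini, clusterClass = clusterClass, ties = ties)
}

#' Cophenetic correlation between two clustering trees
#'
#' Pearson correlation of the cophenetic-distance vectors over all leaf
#' pairs; 1 for identical trees.
#'
#' @param tree1,tree2 \code{hclust} trees over the same leaf set.
#' @return Correlation in [-1, 1].
#' @export
copheneticCorrelation <- function(tree1, tree2) {
    d1 <- as.matrix(stats::cophenetic(tree1))
    d2 <- as.matrix(stats::cophenetic(tree2))
    if (!setequal(rownames(d1), rownames(d2)))
        stop("trees must share the same leaves")
    ord <- rownames(d1)
    d2 <- d2[ord, ord]
    stats::cor(d1[lower.tri(d1)], d2[lower.tri(d2)])
}

# train one-vs-one linear SVMs on the given feature columns; returns a
# vote-based predictor.  Pairs whose classes are missing from the
# training data are skipped with a warning.
.ovo_predict <- function(trainX, trainY, testX, cost = 1) {
    classes <- levels(trainY)
    pairs <- utils::combn(classes, 2, simplify = FALSE)
    votes <- matrix(0, nrow = ncol(testX), ncol = length(classes),
                    dimnames = list(NULL, classes))
    for (pr in pairs) {
        idx <- trainY %in% pr
        ytr <- droplevels(trainY[idx])
        if (nlevels(ytr) < 2) {
            warning("class absent from training data; skipping pair ",
                    paste(pr, collapse = " vs "))
            next
        }
        fit <- e1071::svm(x = t(trainX[, idx, drop = FALSE]), y = ytr,
                          kernel = "linear", cost = cost, scale = FALSE)
        pred <- as.character(stats::predict(fit, t(testX)))
        for (k in seq_along(pred))
            votes[k, pred[k]] <- votes[k, pred[k]] + 1
    }
    calls <- character(nrow(votes))
    for (k in seq_len(nrow(votes))) {
        top <- which(votes[k, ] == max(votes[k, ]))
        calls[k] <- if (length(top) > 1) NA_character_ else classes[top]
    }
    calls
}

#' Cross-validated one-vs-one SVM classification with majority voting
#'
#' Splits the labelled samples into \code{folds} folds (stratified by
#' class when sizes permit), trains pairwise linear SVMs on each training
#' split, and calls each held-out sample by majority vote over the
#' pairwise classifiers.  Vote ties are indeterminable calls (IDC).  The
#' procedure is repeated in \code{runs} independent runs and confusion
#' counts are averaged.  Per-class sensitivity is computed among called
#' specimens of that class; the call rate (CR) is the fraction of a
#' class's specimens receiving a determinable call.
#'
#' @param scores [FCProjection-class] or features x samples matrix.
#' @param labels named class labels per sample (>= 2 classes).
#' @param folds cross-validation folds (default 30).
#' @param runs independent repetitions (default 3).
#' @param seed base seed; run i uses seed + i.
#' @param cost SVM regularization constant (default 1).
#' @return A list with \code{confusion} (classes x classes mean counts),
#'   \code{idc}, \code{total}, \code{callRate}, \code{sensitivity} (all
#'   per class, averaged over runs).
#' @export
maxvoteClassify <- function(scores, labels, folds = 30, runs = 3,
                            seed = 1, cost = 1) {
    X <- if (is(scores, "FCProjection")) fcScores(scores) else as.matrix(scores)
    if (!is.null(names(labels))) labels <- labels[colnames(X)]
    y <- factor(labels)
    if (nlevels(y) < 2) stop("need at least two classes")
    m <- ncol(X)
    classes <- levels(y)
    conf <- matrix(0, length(classes), length(classes),
                   dimnames = list(classes, classes))
    idc <- stats::setNames(numeric(length(classes)), classes)
    for (r in seq_len(runs)) {
        foldId <- withr::with_seed(seed + r, {
            f <- integer(m)
            for (cl in classes) {       # stratified assignment per class
                idx <- sample(which(y == cl))
                f[idx] <- rep_len(sample(folds), length(idx))
            }
            f
        })
        calls <- character(m)
        for (k in sort(unique(foldId))) {
            test <- foldId == k
            calls[test] <- .ovo_predict(X[, !test, drop = FALSE],
                                        droplevels(y[!test]),
                                        X[, test, drop = FALSE], cost)
        }
        for (i in seq_len(m)) {
            if (is.na(calls[i])) idc[as.character(y[i])] <-
                    idc[as.character(y[i])] + 1
            else conf[as.character(y[i]), calls[i]] <-
                    conf[as.character(y[i]), calls[i]] + 1
        }
    }
    conf <- conf / runs
    idc <- idc / runs
    total <- as.numeric(table(y))
    names(total) <- classes
    called <- rowSums(conf)
    callRate <- called / total
    sens <- ifelse(called > 0, diag(conf) / called, NA_real_)
    list(confusion = conf, idc = idc, total = total,
         callRate = callRate, sensitivity = sens)
}

#' Binary classification metrics
#'
#' The five standard ratios with explicit flagging of undefined values:
#' PPV is undefined when no positive predictions were made, NPV when no
#' negative predictions were made (returned as NA and listed in
#' \code{undefined}, never silently 0).
#'
#' @param predictions,truth vectors of class labels over the same
#'   samples.
#' @param positiveClass the label treated as positive.
#' @return A list with counts TP/TN/FP/FN, totals P/N/PredP/PredN, the
#'   metrics \code{PPV}, \code{NPV}, \code{sensitivity},
#'   \code{specificity}, \code{accuracy}, and \code{undefined} (names of
#'   undefined metrics).
#' @export
binaryMetrics <- function(predictions, truth, positiveClass) {
    if (length(predictions) != length(truth)) stop("length mismatch")
    posT <- truth == positiveClass
    posP <- predictions == positiveClass
    TP <- sum(posT & posP); FN <- sum(posT & !posP)
    FP <- sum(!posT & posP); TN <- sum(!posT & !posP)
    P <- TP + FN; N <- TN + FP
    PredP <- TP + FP; PredN <- TN + FN
    undef <- character(0)
    PPV <- if (PredP > 0) TP / PredP else { undef <- c(undef, "PPV"); NA_real_ }
    NPV <- if (PredN > 0) TN / PredN else { undef <- c(undef, "NPV"); NA_real_ }
    list(TP = TP, TN = TN, FP = FP, FN = FN, P = P, N = N,
         PredP = PredP, PredN = PredN,
         PPV = PPV, NPV = NPV,
         sensitivity = TP / P, specificity = TN / N,
         accuracy = (TP + TN) / (P + N), undefined = undef)
}

#' McNemar comparison of two classifiers with continuity correction
#'
#' b counts samples classifier A got right and B wrong, c the reverse;
#' the statistic is (|b - c| - 1)^2 / (b + c) against chi-square with one
#' degree of freedom.  Identical predictions make the statistic undefined
#' and the verdict "identical".
#'
#' @param predA,predB,truth label vectors over the same test samples.
#' @return A list with \code{statistic}, \code{p}, \code{b}, \code{c},
#'   and \code{verdict} in \{"different", "not_different", "identical"\}.
#' @export
mcnemarCompare <- function(predA, predB, truth) {
    if (length(predA) != length(truth) || length(predB) != length(truth))
        stop("length mismatch")
    if (all(predA == predB))
        return(list(statistic = NA_real_, p = NA_real_, b = 0L, c = 0L,
                    verdict = "identical"))
    aOK <- predA == truth; bOK <- predB == truth
    b <- sum(aOK & !bOK); cc <- sum(!aOK & bOK)
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    list(statistic = stat, p = p, b = b, c = cc,
         verdict = if (p < 0.05) "different" else "not_different")
}

.train_predict_binary <- function(trainX, trainY, testX, cost = 1) {
    fit <- e1071::svm(x = t(trainX), y = factor(trainY), kernel = "linear",
                      cost = cost, scale = FALSE)
    as.character(stats::predict(fit, t(testX)))
}

#' Training-set subsampling experiment: FC space vs gene space
#'
#' Emulates the low-sample-setting evaluation: per run a held-out test
#' set of \code{testSizes} positive/negative samples is drawn; the
#' remaining pools are subsampled at each fraction (\code{repeats} times,
#' except fraction 1.0 which is evaluated once per run), a linear SVM is
#' trained per feature space, binary metrics are computed on the test
#' set, and the two spaces' predictions are compared by McNemar's test.
#' Undefined metric values (e.g. PPV of an all-negative predictor) are
#' excluded from averages and counted.
#'
#' @param pos,neg [ExpressionMatrix-class] gene-space samples of the
#'   positive and negative class.
#' @param loadings FC loading matrix (genes x FCs) defining the FC
#'   feature space.
#' @param testSizes held-out test-set sizes (positive, negative).
#' @param fractions training-pool subsampling fractions.
#' @param repeats samplings per fraction within a run (default 200).
#' @param runs number of independent runs, each with its own test set
#'   (default 10).
#' @param seed base seed; run i uses seed + i, repeat j within it uses
#'   (seed + i) * 1000 + j.
#' @param cost SVM regularization constant.
#' @param unitNorm use unit-norm loadings for the FC projection.
#' @return A list with \code{summary} (data.frame: fraction, space,
#'   metric, mean, sd, nUndefined across runs), \code{agreement}
#'   (data.frame: fraction, meanPctDifferent, sdPctDifferent), and
#'   \code{perRun} (the per-run averages).
#' @export
subsampleExperiment <- function(pos, neg, loadings,
                                testSizes = c(22, 37),
                                fractions = c(0.05, 0.1, 0.2, 0.4, 0.6,
                                              0.8, 1.0),
                                repeats = 200, runs = 10, seed = 1,
                                cost = 1, unitNorm = FALSE) {
    pos <- .as_em(pos); neg <- .as_em(neg)
    if (nSamples(pos) <= testSizes[1] || nSamples(neg) <= testSizes[2])
        stop("class pools too small for the requested test sizes")
    geneX <- cbind(exprValues(pos), exprValues(neg))
    fcX <- fcScores(projectToFC(ExpressionMatrix(geneX), loadings,
                                unitNorm = unitNorm))
    truthAll <- c(rep("pos", nSamples(pos)), rep("neg", nSamples(neg)))
    names(truthAll) <- colnames(geneX)
    posIds <- sampleIds(pos); negIds <- sampleIds(neg)
    metrics <- c("PPV", "NPV", "sensitivity", "specificity", "accuracy")
    perRun <- list(); agree <- list()
    for (r in seq_len(runs)) {
        runSeed <- seed + r
        split <- withr::with_seed(runSeed, list(
            testPos = sample(posIds, testSizes[1]),
            testNeg = sample(negIds, testSizes[2])))
        testIds <- c(split$testPos, split$testNeg)
        poolPos <- setdiff(posIds, split$testPos)
        poolNeg <- setdiff(negIds, split$testNeg)
        truth <- truthAll[testIds]
        for (f in fractions) {
            nP <- round(f * length(poolPos)); nN <- round(f * length(poolNeg))
            if (nP < 1 || nN < 1)
                stop(sprintf("fraction %.2f yields an empty class", f))
            reps <- if (f == 1) 1L else repeats
            acc <- list(fc = vector("list", reps),
                        gene = vector("list", reps))
            nDiff <- 0L; nIdent <- 0L
            for (j in seq_len(reps)) {
                ids <- withr::with_seed(runSeed * 1000 + j, c(
                    if (f == 1) poolPos else sample(poolPos, nP),
                    if (f == 1) poolNeg else sample(poolNeg, nN)))
                trY <- truthAll[ids]
                predFC <- .train_predict_binary(
                    fcX[, ids, drop = FALSE], trY,
                    fcX[, testIds, drop = FALSE], cost)
                predGene <- .train_predict_binary(
                    geneX[, ids, drop = FALSE], trY,
                    geneX[, testIds, drop = FALSE], cost)
                acc$fc[[j]] <- binaryMetrics(predFC, truth, "pos")
                acc$gene[[j]] <- binaryMetrics(predGene, truth, "pos")
                mc <- mcnemarCompare(predFC, predGene, truth)
                if (identical(mc$verdict, "different")) nDiff <- nDiff + 1L
                if (identical(mc$verdict, "identical")) nIdent <- nIdent + 1L
            }
            for (space in c("fc", "gene")) {
                vals <- acc[[space]]
                for (metric in metrics) {
                    v <- vapply(vals, function(x) x[[metric]], numeric(1))
                    nU <- sum(is.na(v))
                    perRun[[length(perRun) + 1L]] <- data.frame(
                        run = r, fraction = f, space = space,
                        metric = metric,
                        value = if (all(is.na(v))) NA_real_
                                else mean(v, na.rm = TRUE),
                        nUndefined = nU)
                }
            }
            agree[[length(agree) + 1L]] <- data.frame(
                run = r, fraction = f,
                pctDifferent = 100 * nDiff / reps,
                pctIdentical = 100 * nIdent / reps)
        }
    }
    perRun <- do.call(rbind, perRun)
    agree <- do.call(rbind, agree)
    summary <- do.call(rbind, lapply(
        split(perRun, list(perRun$fraction, perRun$space, perRun$metric),
              drop = TRUE),
        function(d) data.frame(
            fraction = d$fraction[1], space = d$space[1],
            metric = d$metric[1],
            mean = mean(d$value, na.rm = TRUE),
            sd = if (sum(!is.na(d$value)) > 1) stats::sd(d$value, na.rm = TRUE)
                 else 0,
            nUndefined = sum(d$nUndefined))))
    rownames(summary) <- NULL
    agreement <- do.call(rbind, lapply(split(agree, agree$fraction),
        function(d) data.frame(
            fraction = d$fraction[1],
            meanPctDifferent = mean(d$pctDifferent),
            sdPctDifferent = if (nrow(d) > 1) stats::sd(d$pctDifferent) else 0)))
    rownames(agreement) <- NULL
    list(summary = summary, agreement = agreement, perRun = perRun)
}
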