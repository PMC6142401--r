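test_that("the Hungarian solver matches brute force on random costs", {
    for (n in 2:6) {
        for (rep in 1:5) {
            withr::with_seed(n * 100 + rep,
                             cost <- matrix(runif(n * n), n, n))
            a <- solveAssignment(cost)
            bf <- brute_force_assignment(cost)
            expect_equal(attr(a, "totalCost"), bf$cost, tolerance = 1e-12)
        }
    }
    expect_equal(unclass(solveAssignment(matrix(c(4, 2, 1, 3), 2))),
                 c(2L, 1L), ignore_attr = TRUE)
    expect_error(solveAssignment(matrix(1, 2, 3)), "square")
})

test_that("correlation costs hit the sign-invariant extremes", {
    withr::with_seed(2, x <- rnorm(200))
    S0 <- cbind(a = x, b = rnorm(200))
    ccId <- correlationCost(S0, S0)
    expect_equal(diag(ccId$cost), c(0, 0), tolerance = 1e-12,
                 ignore_attr = TRUE)
    ccNeg <- correlationCost(S0, -S0)
    expect_equal(diag(ccNeg$cost), c(0, 0), tolerance = 1e-12,
                 ignore_attr = TRUE)       # anticorrelation also costs 0
    expect_equal(ccNeg$rPlus + ccNeg$rMinus,
                 matrix(1, 2, 2), tolerance = 1e-12, ignore_attr = TRUE)
    # orthogonal columns cost the maximum 0.5
    y <- rep(c(1, -1), 100)
    S1 <- cbind(x - mean(x), y)
    ccOrtho <- correlationCost(S1, S1[, 2:1])
    expect_equal(ccOrtho$cost[1, 1], 0.5, tolerance = 0.1)
    expect_error(correlationCost(cbind(x, rep(1, 200)), S0), "constant")
})

test_that("matching recovers planted signed permutations exactly", {
    withr::with_seed(31, S0 <- scale(matrix(rnorm(400 * 5), 400, 5)))
    # identity case
    id <- matchComponents(S0, S0)
    expect_equal(id@B, diag(5), ignore_attr = TRUE)
    expect_equal(id@P, diag(5), ignore_attr = TRUE)
    expect_equal(alignedCor(id), rep(1, 5), tolerance = 1e-12)

    for (n in 2:6) {
        withr::with_seed(n, Sn <- scale(matrix(rnorm(300 * n), 300, n)))
        for (rep in 1:10) {
            sp <- random_signed_permutation(n, seed = n * 50 + rep)
            Sk <- Sn[, sp$perm] * rep(sp$signs, each = nrow(Sn))
            mr <- matchComponents(Sn, Sk)
            # recovered assignment equals the planted permutation:
            # run column j carries reference component perm[j]
            expectedB <- matrix(0, n, n)
            expectedB[cbind(sp$perm, seq_len(n))] <- 1
            expect_equal(mr@B, expectedB, ignore_attr = TRUE)
            # signs recovered exactly where columns were negated
            expect_equal(alignedCor(mr), rep(1, n), tolerance = 1e-10)
            expect_equal(sum(mr@P == -1), sum(sp$signs == -1))
            # optimal cost no worse than identity assignment, and matches
            # the brute-force optimum
            cc <- correlationCost(Sn, Sk)
            bf <- brute_force_assignment(cc$cost)
            expect_equal(sum(cc$cost[mr@B == 1]), bf$cost, tolerance = 1e-12)
            expect_lte(sum(cc$cost[mr@B == 1]), sum(diag(cc$cost)) + 1e-12)
        }
    }
})

test_that("aligned correlations are sign-oriented and scale-invariant", {
    withr::with_seed(12, S0 <- scale(matrix(rnorm(500 * 4), 500, 4)))
    withr::with_seed(13, Sk <- S0 + matrix(rnorm(500 * 4, sd = 0.4), 500))
    mr <- matchComponents(S0, Sk)
    expect_true(all(alignedCor(mr) >= 0))
    # rescaling run columns by positive constants changes nothing
    mr2 <- matchComponents(S0, sweep(Sk, 2, c(2, 10, 0.5, 7), "*"))
    expect_equal(alignedCor(mr2), alignedCor(mr), tolerance = 1e-10)
})

test_that("unrelated solutions align near zero", {
    cs <- vapply(1:20, function(seed) {
        withr::with_seed(seed, {
            S0 <- scale(matrix(rnorm(1000 * 5), 1000, 5))
            Sk <- scale(matrix(rnorm(1000 * 5), 1000, 5))
        })
        mean(alignedCor(matchComponents(S0, Sk)))
    }, numeric(1))
    expect_lt(abs(mean(cs)), 0.2)
})

test_that("stability summaries aggregate aligned correlations per component", {
    mix <- genMixture(900, 3, noiseSd = 0.02, seed = 21)
    wd <- svdWhiten(mix$X, nComponents = 3)
    batch <- runICABatch(wd, runs = 3, baseSeed = 40)
    # comparing the best solution with itself: mean = max = 1, sem = 0
    self <- stabilitySummary(batch$best, list(batch$best))
    expect_equal(self$mean, rep(1, 3), tolerance = 1e-10)
    expect_equal(self$max, rep(1, 3), tolerance = 1e-10)
    expect_equal(self$sem, rep(0, 3), tolerance = 1e-10)

    others <- Filter(function(s) s@seed != batch$best@seed, batch$solutions)
    stab <- stabilitySummary(batch$best, others)
    expect_true(all(stab$max >= stab$mean - 1e-12))
    # strong planted sources: every run recovers every component
    expect_true(all(stab$mean > 0.95))
    expect_error(stabilitySummary(batch$best, list()), "no comparison")
})

test_that("two-run aggregation arithmetic is exact", {
    # synthetic aligned-correlation vectors (1.0, 0.8) and (1.0, 0.6):
    # FC2 mean 0.7, max 0.8 -- realized through scaled noisy copies
    withr::with_seed(5, S0 <- scale(matrix(rnorm(2000 * 2), 2000, 2)))
    mk <- function(target) {
        # mix in orthogonal noise to hit an exact correlation target
        withr::with_seed(target * 1000, z <- rnorm(2000))
        z <- residuals(lm(z ~ S0[, 2]))
        w <- S0[, 2] * target + z * sqrt(1 - target^2) / sd(z) * sd(S0[, 2])
        cbind(S0[, 1], w)
    }
    stab <- stabilitySummary(as_solution <- new("ICASolution",
        S = S0, A = diag(2), negentropy = c(1, 1), totalNegentropy = 2,
        iterations = 1L, converged = TRUE, seed = 1L, backend = "logcosh",
        params = list()),
        list(new("ICASolution", S = mk(0.8), A = diag(2),
                 negentropy = c(1, 1), totalNegentropy = 2, iterations = 1L,
                 converged = TRUE, seed = 2L, backend = "logcosh",
                 params = list()),
             new("ICASolution", S = mk(0.6), A = diag(2),
                 negentropy = c(1, 1), totalNegentropy = 2, iterations = 1L,
                 converged = TRUE, seed = 3L, backend = "logcosh",
                 params = list())))
    expect_equal(stab$mean[2], 0.7, tolerance = 1e-6)
    expect_equal(stab$max[2], 0.8, tolerance = 1e-6)
    expect_equal(stab$mean[1], 1, tolerance = 1e-6)
})

test_that("subsampled pseudo-compendia reproduce strong planted components", {
    # 5 strong sources over 40 samples; resample 80% of columns
    mix <- genMixture(800, 5, noiseSd = 0.02, seed = 33)
    W <- withr::with_seed(34, matrix(rnorm(5 * 40, sd = 1.5), 5, 40))
    X <- mix$S %*% W
    colnames(X) <- sprintf("s%02d", 1:40)
    full <- ExpressionMatrix(X)
    wd <- svdWhiten(full, nComponents = 5)
    ref <- runICABatch(wd, runs = 3, baseSeed = 7)$best
    stab <- subsampleStability(full, ref, size = 32, nResamples = 5,
                               runsEach = 3, seed = 11)
    expect_true(all(stab$mean > 0.8))
    expect_true(all(stab$max >= stab$mean))
    expect_error(subsampleStability(full, ref, size = 100), "exceeds")
})
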