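# shared fixtures and independent oracles, built in code

# all permutations of 1..n (n small), for brute-force assignment checks
all_perms <- function(n) {
    if (n == 1) return(list(1L))
    out <- list()
    for (p in all_perms(n - 1L)) {
        for (pos in seq_len(n)) {
            out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
        }
    }
    out
}

# brute-force minimum-cost perfect matching: returns assignment (row i ->
# column a[i]) and its total cost, scanning all n! permutations
brute_force_assignment <- function(cost) {
    n <- nrow(cost)
    best <- NULL
    bestCost <- Inf
    for (p in all_perms(n)) {
        tc <- sum(cost[cbind(seq_len(n), p)])
        if (tc < bestCost - 1e-12) {
            bestCost <- tc
            best <- p
        }
    }
    list(assignment = unlist(best), cost = bestCost)
}

# exact hypergeometric upper tail by direct enumeration of draw outcomes
brute_force_hypergeom <- function(overlap, nActive, nSignature, nUniverse) {
    ks <- overlap:min(nActive, nSignature)
    sum(choose(nSignature, ks) * choose(nUniverse - nSignature, nActive - ks)) /
        choose(nUniverse, nActive)
}

# matrix of noise plus planted rank-1 signals with known singular values
planted_signal_matrix <- function(g, s, strengths, seed) {
    withr::with_seed(seed, {
        Z <- matrix(rnorm(g * s), g, s)
        k <- length(strengths)
        U <- qr.Q(qr(matrix(rnorm(g * k), g, k)))
        V <- qr.Q(qr(matrix(rnorm(s * k), s, k)))
        Z + U %*% diag(strengths, k) %*% t(V)
    })
}

# FCProjection from a raw score matrix (FCs x samples)
as_projection <- function(scores) {
    if (is.null(colnames(scores)) && ncol(scores))
        colnames(scores) <- paste0("q", seq_len(ncol(scores)))
    if (is.null(rownames(scores)) && nrow(scores))
        rownames(scores) <- paste0("FC", seq_len(nrow(scores)))
    new("FCProjection", scores = scores,
        fcIds = rownames(scores) %||% character(0),
        sampleIds = colnames(scores) %||% character(0),
        unitNorm = FALSE, coverage = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random signed permutation matrix of size n (acts by Sk = S0[, perm] with
# signs flipped on `neg`)
random_signed_permutation <- function(n, seed) {
    withr::with_seed(seed, {
        perm <- sample(n)
        signs <- sample(c(-1, 1), n, replace = TRUE)
        list(perm = perm, signs = signs)
    })
}
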