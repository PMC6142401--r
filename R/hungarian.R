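#' Exact minimum-cost perfect matching (Hungarian algorithm)
#'
#' Solves the square linear assignment problem exactly in O(n^3) by the
#' shortest-augmenting-path formulation with row/column potentials.
#' Degenerate multiple optima are resolved by the algorithm's
#' deterministic scan order (lowest index first).
#'
#' @param cost numeric n x n cost matrix.
#' @return Integer vector \code{a} of length n with \code{a[i]} the
#'   column assigned to row i; attribute \code{totalCost} carries the
#'   optimal total cost.
#' @examples
#' solveAssignment(matrix(c(4, 2, 1, 3), 2))  # rows -> columns 2, 1
#' @export
solveAssignment <- function(cost) {
    cost <- as.matrix(cost)
    n <- nrow(cost)
    if (n != ncol(cost)) stop("cost matrix must be square")
    if (anyNA(cost)) stop("cost matrix must not contain NA")
    u <- numeric(n + 1)            # potentials; index i+1 for row i (0 = dummy)
    v <- numeric(n + 1)
    p <- integer(n + 1)            # p[j+1] = row matched to column j
    way <- integer(n + 1)
    for (i in seq_len(n)) {
        p[1] <- i
        j0 <- 0
        minv <- rep(Inf, n + 1)
        used <- rep(FALSE, n + 1)
        repeat {
            used[j0 + 1] <- TRUE
            i0 <- p[j0 + 1]
            delta <- Inf; j1 <- -1
            for (j in seq_len(n)) {
                if (!used[j + 1]) {
                    cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
                    if (cur < minv[j + 1]) {
                        minv[j + 1] <- cur
                        way[j + 1] <- j0
                    }
                    if (minv[j + 1] < delta) {
                        delta <- minv[j + 1]
                        j1 <- j
                    }
                }
            }
            for (j in 0:n) {
                if (used[j + 1]) {
                    u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
                    v[j + 1] <- v[j + 1] - delta
                } else {
                    minv[j + 1] <- minv[j + 1] - delta
                }
            }
            j0 <- j1
            if (p[j0 + 1] == 0) break
        }
        repeat {
            j1 <- way[j0 + 1]
            p[j0 + 1] <- p[j1 + 1]
            j0 <- j1
            if (j0 == 0) break
        }
    }
    assign <- integer(n)
    for (j in seq_len(n)) assign[p[j + 1]] <- j
    structure(assign, totalCost = sum(cost[cbind(seq_len(n), assign)]))
}
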