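#' @include consensus.R annotate.R evaluate.R compendium.R
NULL

.write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Run the discovery pipeline end to end
#'
#' Executes the staged pipeline compendium -> whiten -> ica -> consensus
#' -> annotate (any prefix of it) on a gene-expression matrix, writing
#' each stage's artifacts plus a JSON manifest recording parameters,
#' seeds, and md5 checksums of every output.  All outputs are staged in a
#' temporary directory and copied to \code{outDir} only on success, so a
#' failing stage leaves no partial outputs behind.
#'
#' @param matrixPath tab-separated genes x samples expression matrix (see
#'   [readExpressionMatrix()]).
#' @param outDir output directory (created if needed).
#' @param stages prefix of c("compendium", "whiten", "ica", "consensus",
#'   "annotate") to execute.
#' @param metric,k,height,minSize compendium parameters (see
#'   [buildCompendium()]).
#' @param nSim,paQuantile parallel-analysis parameters.
#' @param runs,backend,tol,maxIter,gridPoints ICA batch parameters.
#' @param gmtPath GMT gene-set collection (required for the annotate
#'   stage).
#' @param z,alpha annotation parameters.
#' @param seed base seed recorded in the manifest and used for every
#'   stochastic stage.
#' @param preprocess run [preprocessExpression()] on the input first.
#' @return The manifest, invisibly (also written as manifest.json).
#' @export
runPipeline <- function(matrixPath, outDir,
                        stages = c("compendium", "whiten", "ica",
                                   "consensus", "annotate"),
                        metric = "spearman", k = 4, height = NULL,
                        minSize = 5, nSim = 5000, paQuantile = 0.5,
                        runs = 100, backend = "logcosh", tol = 1e-6,
                        maxIter = 8000, gridPoints = 2000,
                        gmtPath = NULL, z = 3, alpha = 0.01,
                        seed = 1, preprocess = TRUE) {
    allStages <- c("compendium", "whiten", "ica", "consensus", "annotate")
    if (!all(stages == allStages[seq_along(stages)]))
        stop("stages must be a prefix of: ", paste(allStages, collapse = " -> "))
    if (!file.exists(matrixPath))
        stop("input matrix not found: ", matrixPath)
    if ("annotate" %in% stages &&
        (is.null(gmtPath) || !file.exists(gmtPath)))
        stop("annotate stage requires an existing gmtPath")
    staging <- tempfile("fcm-stage-")
    dir.create(staging)
    on.exit(unlink(staging, recursive = TRUE), add = TRUE)
    runStage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    params <- list(metric = metric, k = k, height = height,
                   minSize = minSize, nSim = nSim, paQuantile = paQuantile,
                   runs = runs, backend = backend, tol = tol,
                   maxIter = maxIter, gridPoints = gridPoints,
                   z = z, alpha = alpha, seed = seed,
                   preprocess = preprocess)
    M <- runStage("read", {
        m <- readExpressionMatrix(matrixPath)
        if (preprocess) preprocessExpression(m) else m
    })
    comp <- NULL; wd <- NULL; batch <- NULL
    results <- list()
    if ("compendium" %in% stages) runStage("compendium", {
        comp <- buildCompendium(M, metric = metric, k = k,
                                 height = height, minSize = minSize)
        writeExpressionMatrix(comp$compendium,
                              file.path(staging, "compendium.tsv"))
        results$compendium <- list(height = comp$height,
                                    nRetained = length(comp$retained),
                                    medoids = unname(comp$medoids))
    })
    if ("whiten" %in% stages) runStage("whiten", {
        Xc <- comp$compendium
        n <- parallelAnalysis(Xc, nSim = nSim, quantile = paQuantile,
                              seed = seed)
        if (n < 1) n <- 1L   # keep at least one component for downstream
        wd <- svdWhiten(Xc, nComponents = n)
        .write_tsv(attr(parallelAnalysis(Xc, nSim = nSim,
                                         quantile = paQuantile, seed = seed),
                        "table"),
                   file.path(staging, "scree.tsv"))
        results$whiten <- list(nComponents = wd@nComponents,
                                varianceExplained =
                                    varianceExplained(covEigenvalues(wd),
                                                      wd@nComponents))
    })
    if ("ica" %in% stages) runStage("ica", {
        batch <- runICABatch(wd, runs = runs, backend = backend,
                              tol = tol, maxIter = maxIter,
                              gridPoints = gridPoints, baseSeed = seed)
        S <- sources(batch$best)
        .write_tsv(data.frame(gene_id = rownames(S), S,
                              check.names = FALSE),
                   file.path(staging, "best_S.tsv"))
        results$ica <- list(bestSeed = batch$best@seed,
                             totalNegentropy = totalNegentropy(batch$best),
                             converged = batch$best@converged)
    })
    if ("consensus" %in% stages) runStage("consensus", {
        others <- Filter(function(s) s@seed != batch$best@seed,
                         batch$solutions)
        stab <- stabilitySummary(batch$best, others)
        .write_tsv(stab, file.path(staging, "stability.tsv"))
        results$consensus <- list(meanAlignedCor = mean(stab$mean),
                                   minMax = min(stab$max))
    })
    if ("annotate" %in% stages) runStage("annotate", {
        sets <- readGmt(gmtPath)
        enr <- enrichModules(batch$best, sets, z = z, alpha = alpha)
        .write_tsv(enr, file.path(staging, "enrichment.tsv"))
        results$annotate <- list(nSignificant = sum(enr$significant))
    })
    outputs <- list.files(staging, full.names = TRUE)
    manifest <- list(
        package = "fcmodules",
        version = as.character(utils::packageVersion("fcmodules")),
        input = matrixPath, stages = stages, params = params,
        results = results,
        checksums = as.list(tools::md5sum(outputs)) |>
            stats::setNames(basename(outputs)))
    jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (f in list.files(staging, full.names = TRUE))
        file.copy(f, file.path(outDir, basename(f)), overwrite = TRUE)
    invisible(manifest)
}

.parse_args <- function(args) {
    out <- list(positional = character(0))
    i <- 1
    while (i <= length(args)) {
        a <- args[i]
        if (startsWith(a, "--")) {
            key <- sub("^--", "", a)
            if (i < length(args) && !startsWith(args[i + 1], "--")) {
                out[[key]] <- args[i + 1]; i <- i + 2
            } else {
                out[[key]] <- TRUE; i <- i + 1
            }
        } else {
            out$positional <- c(out$positional, a); i <- i + 1
        }
    }
    out
}

.opt <- function(opts, key, default = NULL, as = identity) {
    if (is.null(opts[[key]])) default else as(opts[[key]])
}

#' Command-line entry point
#'
#' Thin dispatcher behind the \code{exec/fcm} script.  Every subcommand
#' wraps a library function; no computation lives only here.  Supported
#' subcommands: \code{simulate}, \code{compendium}, \code{whiten},
#' \code{ica}, \code{pipeline}, \code{project}, \code{de},
#' \code{annotate}.  Run \code{fcm help} for usage.
#'
#' @param argv character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
fcmMain <- function(argv = commandArgs(trailingOnly = TRUE)) {
    usage <- paste(
        "usage: fcm <subcommand> [--options]",
        "  simulate   --type mixture|study --g --n --noise-sd --seed --out prefix",
        "  compendium --matrix X.tsv --metric spearman --k 4 --min-size 5 [--height H] --out dir",
        "  whiten     --matrix X.tsv --nsim 5000 --quantile 0.5 --seed 1 --out scree.tsv",
        "  ica        --matrix Y.tsv --runs 10 --backend logcosh --seed 1 --out S.tsv",
        "  pipeline   --matrix X.tsv --out dir [--stages compendium,whiten,ica,consensus]",
        "             [--runs N --nsim N --seed N --gmt sets.gmt]",
        "  project    --matrix Q.tsv --loadings S.tsv [--unit-norm] --out scores.tsv",
        "  de         --scores scores.tsv --labels labels.tsv --alpha 0.05 --out de.tsv",
        "  annotate   --loadings S.tsv --gmt sets.gmt --z 3 --alpha 0.01 --out enrich.tsv",
        sep = "\n")
    if (!length(argv) || argv[1] %in% c("help", "--help", "-h")) {
        cat(usage, "\n")
        return(invisible(0L))
    }
    cmd <- argv[1]
    opts <- .parse_args(argv[-1])
    status <- tryCatch({
        switch(cmd,
            simulate = {
                type <- .opt(opts, "type", "mixture")
                seed <- .opt(opts, "seed", 1, as.integer)
                out <- .opt(opts, "out", "synthetic")
                if (type == "mixture") {
                    mix <- genMixture(.opt(opts, "g", 2000, as.integer),
                                      .opt(opts, "n", 5, as.integer),
                                      noiseSd = .opt(opts, "noise-sd", 0,
                                                     as.numeric),
                                      seed = seed)
                    writeExpressionMatrix(mix$X, paste0(out, "_X.tsv"))
                    .write_tsv(data.frame(gene_id = rownames(mix$S), mix$S),
                               paste0(out, "_S_true.tsv"))
                    .write_tsv(as.data.frame(mix$A), paste0(out, "_A_true.tsv"))
                    jsonlite::write_json(
                        mix[c("sourceFamily", "mixing", "noiseSd", "seed",
                              "conditionNumber")],
                        paste0(out, "_manifest.json"), auto_unbox = TRUE)
                } else {
                    st <- genTwoClassStudy(
                        .opt(opts, "g", 2000, as.integer),
                        .opt(opts, "n-per-group", 10, as.integer),
                        .opt(opts, "n-fcs", 5, as.integer),
                        shiftedFcs = seq_len(.opt(opts, "n-shifted", 1,
                                                  as.integer)),
                        effectSize = .opt(opts, "effect-size", 2, as.numeric),
                        seed = seed)
                    writeExpressionMatrix(st$expr, paste0(out, "_X.tsv"))
                    .write_tsv(data.frame(sample_id = names(st$labels),
                                          label = st$labels),
                               paste0(out, "_labels.tsv"))
                }
                0L
            },
            compendium = {
                M <- readExpressionMatrix(.opt(opts, "matrix"))
                rep <- buildCompendium(
                    M, metric = .opt(opts, "metric", "spearman"),
                    k = .opt(opts, "k", 4, as.integer),
                    height = .opt(opts, "height", NULL, as.numeric),
                    minSize = .opt(opts, "min-size", 5, as.integer))
                out <- .opt(opts, "out", "compendium")
                dir.create(out, showWarnings = FALSE, recursive = TRUE)
                writeExpressionMatrix(rep$compendium,
                                      file.path(out, "compendium.tsv"))
                jsonlite::write_json(
                    list(height = rep$height, retained = rep$retained,
                         medoids = unname(rep$medoids)),
                    file.path(out, "report.json"), auto_unbox = TRUE)
                0L
            },
            whiten = {
                M <- readExpressionMatrix(.opt(opts, "matrix"))
                n <- parallelAnalysis(
                    M, nSim = .opt(opts, "nsim", 5000, as.integer),
                    quantile = .opt(opts, "quantile", 0.5, as.numeric),
                    seed = .opt(opts, "seed", 1, as.integer))
                tab <- attr(n, "table")
                .write_tsv(tab, .opt(opts, "out", "scree.tsv"))
                cat("retained components:", n, "\n")
                0L
            },
            ica = {
                M <- readExpressionMatrix(.opt(opts, "matrix"))
                batch <- runICABatch(
                    exprValues(M),
                    runs = .opt(opts, "runs", 10, as.integer),
                    backend = .opt(opts, "backend", "logcosh"),
                    tol = .opt(opts, "tol", 1e-6, as.numeric),
                    maxIter = .opt(opts, "max-iter", 8000, as.integer),
                    baseSeed = .opt(opts, "seed", 1, as.integer))
                S <- sources(batch$best)
                .write_tsv(data.frame(gene_id = rownames(S), S,
                                      check.names = FALSE),
                           .opt(opts, "out", "S.tsv"))
                0L
            },
            pipeline = {
                stages <- strsplit(.opt(
                    opts, "stages",
                    "compendium,whiten,ica,consensus"), ",")[[1]]
                runPipeline(.opt(opts, "matrix"), .opt(opts, "out", "fcm-out"),
                            stages = stages,
                            nSim = .opt(opts, "nsim", 5000, as.integer),
                            runs = .opt(opts, "runs", 100, as.integer),
                            gmtPath = .opt(opts, "gmt", NULL),
                            seed = .opt(opts, "seed", 1, as.integer))
                0L
            },
            project = {
                Q <- readExpressionMatrix(.opt(opts, "matrix"))
                S <- readExpressionMatrix(.opt(opts, "loadings"))
                pr <- projectToFC(Q, exprValues(S),
                                  unitNorm = isTRUE(opts[["unit-norm"]]))
                sc <- fcScores(pr)
                .write_tsv(data.frame(fc = rownames(sc), sc,
                                      check.names = FALSE),
                           .opt(opts, "out", "scores.tsv"))
                0L
            },
            de = {
                sc <- readExpressionMatrix(.opt(opts, "scores"))
                lab <- utils::read.delim(.opt(opts, "labels"),
                                         stringsAsFactors = FALSE)
                groups <- stats::setNames(lab[[2]], lab[[1]])
                res <- deFCTest(exprValues(sc), groups,
                                alpha = .opt(opts, "alpha", 0.05, as.numeric))
                .write_tsv(res, .opt(opts, "out", "de.tsv"))
                0L
            },
            annotate = {
                S <- readExpressionMatrix(.opt(opts, "loadings"))
                enr <- enrichModules(
                    exprValues(S), readGmt(.opt(opts, "gmt")),
                    z = .opt(opts, "z", 3, as.numeric),
                    alpha = .opt(opts, "alpha", 0.01, as.numeric))
                .write_tsv(enr, .opt(opts, "out", "enrich.tsv"))
                0L
            },
            {
                message("unknown subcommand: ", cmd)
                message(usage)
                1L
            })
    }, error = function(e) {
        message("fcm ", cmd, ": ", conditionMessage(e))
        1L
    })
    invisible(status)
}
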