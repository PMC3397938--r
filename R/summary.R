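#' Highest posterior density interval
#'
#' The shortest contiguous order-statistic window containing
#' \code{ceiling(level * n)} of the samples.
#'
#' @param x numeric vector of >= 20 samples.
#' @param level probability mass of the interval (default 0.95).
#' @return named numeric \code{c(lower, upper)}.
#' @export
hpdInterval <- function(x, level = 0.95) {
    if (length(x) < 20L) stop("need at least 20 samples for an HPD")
    if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
    s <- sort(x)
    n <- length(s)
    m <- ceiling(level * n)
    if (m >= n) return(c(lower = s[1L], upper = s[n]))
    starts <- seq_len(n - m + 1L)
    widths <- s[starts + m - 1L] - s[starts]
    i <- which.min(widths)
    c(lower = s[i], upper = s[i + m - 1L])
}

#' Ratio of posterior-average rates q01 / q10
#'
#' The ratio of the mean of the sampled q01 values to the mean of the
#' sampled q10 values -- a ratio of averages, not an average of ratios.
#' Samples in which a rate is fixed to zero by the current model
#' contribute their zeros to the averages: they are legitimate posterior
#' mass under the model-averaged posterior.
#'
#' @param chain an [AsrChain-class] over a binary character.
#' @return positive real; \code{Inf} with a warning when the average q10
#'   is zero.
#' @export
rateRatio <- function(chain) {
    s <- chain@samples
    if (!all(c("q01", "q10") %in% names(s)))
        stop("rateRatio is defined for binary-character chains")
    m10 <- mean(s$q10)
    if (m10 == 0) {
        warning("average q10 is zero; ratio reported as Inf")
        return(Inf)
    }
    mean(s$q01) / m10
}

#' Effective sample size by initial positive sequence truncation
#'
#' \eqn{ESS = n / (1 + 2 \sum_k \rho_k)} with the autocorrelation sum
#' truncated at the first non-positive pair of consecutive lags
#' (Geyer's initial positive sequence rule).
#'
#' @param x numeric vector of >= 50 samples.
#' @return the effective sample size (capped at n).
#' @export
essCalc <- function(x) {
    n <- length(x)
    if (n < 50L) stop("need at least 50 samples for an ESS estimate")
    if (stats::var(x) == 0) return(1)
    rho <- stats::acf(x, lag.max = min(n - 1L, 2000L),
                      plot = FALSE)$acf[-1L]
    ssum <- 0
    i <- 1L
    while (i <= length(rho)) {
        pair <- rho[i] + if (i + 1L <= length(rho)) rho[i + 1L] else 0
        if (pair <= 0) break
        ssum <- ssum + rho[i] +
            (if (i + 1L <= length(rho)) rho[i + 1L] else 0)
        i <- i + 2L
    }
    min(n, n / (1 + 2 * ssum))
}

#' Posterior marginal state probabilities at queried nodes
#'
#' For every saved chain sample, resolves each query's MRCA on that
#' sample's tree, computes the marginal state probabilities under that
#' sample's model, rates and kappa, and averages the vectors across
#' samples with equal weight (the samples are already posterior-weighted
#' by the chain).
#'
#' @param chain an [AsrChain-class].
#' @param treeSample the [TreeSample-class] the chain integrated over.
#' @param column the [CharacterColumn-class] analysed.
#' @param queries named list of taxon sets (>= 2 taxa each).
#' @param every thin the saved samples further by this factor (default 1:
#'   use every saved sample).
#' @return matrix (queries x states) of averaged probabilities; every row
#'   sums to 1.
#' @export
nodeProbabilities <- function(chain, treeSample, column, queries,
                              every = 1L) {
    stopifnot(is(treeSample, "TreeSample"), is(column, "CharacterColumn"))
    if (is.null(names(queries)) || any(!nzchar(names(queries))))
        stop("queries must be a named list of taxon sets")
    allTaxa <- taxa(treeSample)
    for (qn in names(queries)) {
        bad <- setdiff(queries[[qn]], allTaxa)
        if (length(bad))
            stop(sprintf("query '%s' names taxa absent from the sample: %s",
                         qn, paste(bad, collapse = ", ")))
        if (length(queries[[qn]]) < 2L)
            stop(sprintf("query '%s' needs at least two taxa", qn))
    }
    k <- chain@k
    rateNames <- if (k == 2L) c("q01", "q10")
                 else c("q01", "q02", "q10", "q12", "q20", "q21")
    part <- toPartials(column, allTaxa)
    trs <- trees(treeSample)
    # MRCA node ids resolved once per (tree, query)
    usedTrees <- sort(unique(chain@samples$treeIndex))
    mrcaTab <- lapply(usedTrees, function(ti) {
        vapply(queries, function(q) mrcaNode(trs[[ti]], q), integer(1))
    })
    names(mrcaTab) <- as.character(usedTrees)
    rows <- seq(1L, nrow(chain@samples), by = every)
    acc <- matrix(0, length(queries), k,
                  dimnames = list(names(queries),
                                  as.character(column@stateSpace)))
    for (i in rows) {
        s <- chain@samples[i, ]
        ti <- s$treeIndex
        rates <- as.numeric(s[rateNames])
        marg <- allNodeMarginals(trs[[ti]], rates, s$kappa, part,
                                 rootPrior = chain@config@rootPrior)
        nodes <- mrcaTab[[as.character(ti)]]
        acc <- acc + marg[nodes, , drop = FALSE]
    }
    acc / length(rows)
}

#' Summarise a chain into the standard reporting quantities
#'
#' Produces an [AsrSummary-class]: the ratio of average rates q01/q10
#' (binary characters), posterior mean and 95% HPD of kappa, marginal
#' state probabilities at each query node, posterior model frequencies,
#' and effective sample sizes of the scalar parameters.
#'
#' @inheritParams nodeProbabilities
#' @param level credible level for the kappa HPD (default 0.95).
#' @return an [AsrSummary-class].
#' @export
summarizeChain <- function(chain, treeSample, column, queries = list(),
                           level = 0.95, every = 1L) {
    s <- chain@samples
    k <- chain@k
    qRatio <- if (k == 2L) suppressWarnings(rateRatio(chain)) else
        NA_real_
    kh <- hpdInterval(s$kappa, level)
    np <- if (length(queries))
        nodeProbabilities(chain, treeSample, column, queries,
                          every = every)
    else matrix(numeric(0), 0L, k)
    scalars <- intersect(c("q01", "q10", "kappa", "m", "loglik"),
                         names(s))
    ess <- vapply(scalars, function(v) {
        if (stats::var(s[[v]]) == 0) return(NA_real_)
        essCalc(s[[v]])
    }, numeric(1))
    new("AsrSummary", character = column@name,
        states = paste(column@stateSpace, collapse = "/"),
        qRatio = qRatio, kappaMean = mean(s$kappa),
        kappaHPD = unname(kh), nodeProbs = np,
        modelPosterior = modelPosterior(chain), ess = ess,
        rootPrior = chain@config@rootPrior)
}

#' Pool several replicate chains into one
#'
#' Concatenates the post-burn-in samples of replicate runs (the pooled
#' posterior the reported summaries are computed on), keeping the first
#' chain's metadata.
#'
#' @param chains list of [AsrChain-class] objects over the same inputs.
#' @return an [AsrChain-class].
#' @export
poolChains <- function(chains) {
    stopifnot(length(chains) >= 1L)
    out <- chains[[1L]]
    out@samples <- do.call(rbind, lapply(chains, samples))
    out
}

#' Write a summary in the tabular report layout
#'
#' TSV with one row per quantity: the coded states, q01/q10, kappa with
#' its 95% HPD in parentheses, and the state-0 probability (binary) or
#' the full simplex (3-state) per query node.
#'
#' @param x an [AsrSummary-class].
#' @param path output path.
#' @export
writeSummaryTable <- function(x, path) {
    rows <- list(
        c("character", x@character),
        c("coded_states", x@states),
        c("root_prior", x@rootPrior))
    if (!is.na(x@qRatio))
        rows <- c(rows, list(c("q01/q10", sprintf("%.3f", x@qRatio))))
    rows <- c(rows, list(c("kappa",
        sprintf("%.3f (%.3f-%.3f)", x@kappaMean, x@kappaHPD[1],
                x@kappaHPD[2]))))
    if (nrow(x@nodeProbs)) {
        for (nm in rownames(x@nodeProbs)) {
            p <- x@nodeProbs[nm, ]
            val <- if (length(p) == 2L) sprintf("%.3f", p[1L])
                   else paste(sprintf("%.3f", p), collapse = ", ")
            rows <- c(rows, list(c(paste0("node_", nm), val)))
        }
    }
    for (mn in names(x@modelPosterior))
        rows <- c(rows, list(c(paste0("P(", mn, ")"),
                               sprintf("%.3f", x@modelPosterior[mn]))))
    mat <- do.call(rbind, rows)
    utils::write.table(mat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
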