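#' Build the Mk generator matrix from off-diagonal rates
#'
#' Rates are given row-wise over the off-diagonal entries: for k = 2,
#' \code{c(q01, q10)}; for k = 3, \code{c(q01, q02, q10, q12, q20, q21)}.
#' The diagonal is set so that every row sums to zero.
#'
#' @param rates non-negative numeric vector of length k(k-1).
#' @return k x k generator matrix.
#' @export
makeGenerator <- function(rates) {
    nr <- length(rates)
    k <- round((1 + sqrt(1 + 4 * nr)) / 2)
    if (k * (k - 1) != nr)
        stop("rates must have length k(k-1) for some integer k >= 2")
    if (any(rates < 0)) stop("rates must be >= 0")
    Q <- matrix(0, k, k)
    Q[row(Q) != col(Q)] <- 0  # fill row-wise below
    idx <- 1L
    for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
        Q[i, j] <- rates[idx]
        idx <- idx + 1L
    }
    diag(Q) <- -rowSums(Q)
    Q
}

#' Transition probability matrix of the Mk process
#'
#' For two states the closed form
#' \deqn{P_{00}(t) = (q_{10} + q_{01} e^{-(q_{01}+q_{10})t}) / (q_{01}+q_{10})}
#' is used; for three or more states a numerically robust matrix
#' exponential (\code{\link[Matrix]{expm}}).  At t = 0 the matrix is the
#' identity regardless of rates, so zero-length branches are legal.
#'
#' @param rates off-diagonal rates as in [makeGenerator()].
#' @param t elapsed (transformed) branch length, finite and >= 0.
#' @return k x k row-stochastic matrix.
#' @export
transitionMatrix <- function(rates, t) {
    if (!is.finite(t) || t < 0) stop("t must be finite and >= 0")
    Q <- makeGenerator(rates)
    k <- nrow(Q)
    if (t == 0) return(diag(k))
    if (all(rates == 0)) {
        warning("all-zero generator: transition matrix is the identity")
        return(diag(k))
    }
    if (k == 2L) {
        q01 <- rates[1L]; q10 <- rates[2L]
        s <- q01 + q10
        e <- exp(-s * t)
        P <- matrix(c(q10 / s + q01 / s * e, q01 / s - q01 / s * e,
                      q10 / s - q10 / s * e, q01 / s + q10 / s * e),
                    2L, 2L, byrow = TRUE)
    } else {
        P <- as.matrix(Matrix::expm(Q * t))
    }
    P[P < 0] <- 0
    P / rowSums(P)
}

# uniform or stationary root distribution for a given generator
rootPriorVector <- function(rates, k, choice = c("uniform", "stationary")) {
    choice <- match.arg(choice)
    if (choice == "uniform") return(rep(1 / k, k))
    Q <- makeGenerator(rates)
    A <- rbind(t(Q), rep(1, k))
    pi <- tryCatch(qr.solve(A, c(rep(0, k), 1)),
                   error = function(e) rep(1 / k, k))
    pi[pi < 0] <- 0
    if (sum(pi) == 0) pi <- rep(1, k)
    pi / sum(pi)
}

# per-call preprocessing shared by mkLoglik and the marginal pass
prepTree <- function(tree, partials) {
    po <- ape::reorder.phylo(tree, "postorder")
    miss <- setdiff(po$tip.label, rownames(partials))
    if (length(miss))
        stop(sprintf("partials missing for taxa: %s",
                     paste(miss, collapse = ", ")))
    list(edge = po$edge, len = po$edge.length,
         ntip = length(po$tip.label),
         tipPart = partials[po$tip.label, , drop = FALSE])
}

#' Log-likelihood of a discrete character on a tree
#'
#' Felsenstein pruning (post-order conditional likelihoods) on the
#' kappa-transformed tree, with per-node rescaling accumulated in log
#' space to guard against underflow on large trees.  Polytomies are
#' supported.  With every tip missing the likelihood is exactly 1
#' (log-likelihood 0) for any rates and kappa.
#'
#' @param tree a \code{"phylo"} object.
#' @param rates off-diagonal rates as in [makeGenerator()].
#' @param kappa branch-length transform exponent (>= 0).
#' @param partials tip likelihood matrix from [toPartials()], rows named
#'   by taxon and covering every tip of \code{tree}.
#' @param rootPrior probability vector over states (default uniform), or
#'   \code{"uniform"} / \code{"stationary"}.
#' @return the log-likelihood.
#' @export
mkLoglik <- function(tree, rates, kappa = 1, partials,
                     rootPrior = "uniform") {
    stopifnot(inherits(tree, "phylo"))
    if (!is.finite(kappa) || kappa < 0)
        stop("kappa must be finite and >= 0")
    k <- ncol(partials)
    if (is.character(rootPrior))
        rootPrior <- rootPriorVector(rates, k, rootPrior)
    stopifnot(length(rootPrior) == k, abs(sum(rootPrior) - 1) < 1e-8)
    pp <- prepTree(tree, partials)
    Q <- makeGenerator(rates)
    ll <- mk_loglik_cpp(pp$edge, pp$len, pp$ntip, Q, pp$tipPart,
                        rootPrior, kappa)
    if (is.nan(ll)) stop("non-finite log-likelihood")
    ll
}

# Marginal state probabilities at every node: down (post-order) pass plus
# up (pre-order) pass; returns an (ntip + nnode) x k matrix of normalised
# marginals in ape node numbering.  Pure R: used per saved MCMC sample,
# not in the chain's inner loop.
allNodeMarginals <- function(tree, rates, kappa, partials,
                             rootPrior = "uniform") {
    k <- ncol(partials)
    if (is.character(rootPrior))
        rootPrior <- rootPriorVector(rates, k, rootPrior)
    pp <- prepTree(tree, partials)
    edge <- pp$edge
    len <- if (kappa == 0) ifelse(pp$len == 0, 1, pp$len^kappa)
           else pp$len^kappa
    ntip <- pp$ntip
    nedge <- nrow(edge)
    nnodeTot <- ntip + tree$Nnode
    down <- matrix(1, nnodeTot, k)
    down[seq_len(ntip), ] <- pp$tipPart
    Plist <- vector("list", nedge)
    contrib <- matrix(NA_real_, nedge, k)
    for (e in seq_len(nedge)) {
        par <- edge[e, 1L]; chi <- edge[e, 2L]
        P <- transitionMatrix(rates, len[e])
        Plist[[e]] <- P
        cv <- as.numeric(P %*% down[chi, ])
        contrib[e, ] <- cv
        down[par, ] <- down[par, ] * cv
        mx <- max(down[par, ])
        if (mx > 0 && mx < 1e-100) down[par, ] <- down[par, ] / mx
    }
    root <- edge[nedge, 1L]
    up <- matrix(NA_real_, nnodeTot, k)
    up[root, ] <- rootPrior
    childEdges <- split(seq_len(nedge), edge[, 1L])
    for (e in rev(seq_len(nedge))) {     # pre-order traversal
        par <- edge[e, 1L]; chi <- edge[e, 2L]
        sibs <- setdiff(childEdges[[as.character(par)]], e)
        prodExcl <- up[par, ]
        for (se in sibs) prodExcl <- prodExcl * contrib[se, ]
        upv <- as.numeric(prodExcl %*% Plist[[e]])
        mx <- max(upv)
        if (mx > 0) upv <- upv / mx
        up[chi, ] <- upv
    }
    marg <- down * up
    rs <- rowSums(marg)
    bad <- rs <= 0 | !is.finite(rs)
    if (any(bad)) marg[bad, ] <- 1 / k
    marg / rowSums(marg)
}

#' Marginal state probabilities at a node
#'
#' Standard marginal ancestral-state reconstruction: the conditional
#' likelihood of the data below the node is combined with the likelihood
#' of the rest of the tree given each node state (an up-down pass,
#' equivalent to virtual re-rooting), and normalised.  A tip node with an
#' observed state returns the degenerate unit vector.
#'
#' @inheritParams mkLoglik
#' @param node ape node id (e.g. from [mrcaNode()]).
#' @return probability vector over the state space (sums to 1).
#' @export
marginalNodeProbs <- function(tree, rates, kappa = 1, partials,
                              rootPrior = "uniform", node) {
    stopifnot(inherits(tree, "phylo"))
    nnodeTot <- length(tree$tip.label) + tree$Nnode
    if (!(node %in% seq_len(nnodeTot)))
        stop(sprintf("node %s not in tree", node))
    m <- allNodeMarginals(tree, rates, kappa, partials, rootPrior)
    as.numeric(m[node, ])
}
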