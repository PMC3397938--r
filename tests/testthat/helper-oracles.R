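# Independent oracles used across the suite.  All deliberately brute
# force: they share no code with the implementation they check.

# random rooted tree with uniform branch lengths
randomTree <- function(ntip, minLen = 0.05, maxLen = 1.5) {
    tr <- ape::rtree(ntip)
    tr$edge.length <- stats::runif(nrow(tr$edge), minLen, maxLen)
    tr
}

# exhaustive-enumeration likelihood: sum over every assignment of states
# to every node, weighting tips by their partial entries
enumLoglik <- function(tree, rates, kappa, partials, rootPrior) {
    k <- ncol(partials)
    tr <- tree
    tr$edge.length <- ifelse(tr$edge.length == 0 & kappa == 0, 1,
                             tr$edge.length^kappa)
    ntip <- length(tr$tip.label)
    nnode <- ntip + tr$Nnode
    root <- ntip + 1L
    Pedge <- lapply(seq_len(nrow(tr$edge)), function(e)
        transitionMatrix(rates, tr$edge.length[e]))
    states <- rep(1L, nnode)
    total <- 0
    repeat {
        w <- rootPrior[states[root]]
        for (e in seq_len(nrow(tr$edge))) {
            w <- w * Pedge[[e]][states[tr$edge[e, 1L]],
                                states[tr$edge[e, 2L]]]
        }
        for (i in seq_len(ntip))
            w <- w * partials[tr$tip.label[i], states[i]]
        total <- total + w
        # odometer increment over k^nnode assignments
        j <- 1L
        while (j <= nnode && states[j] == k) {
            states[j] <- 1L
            j <- j + 1L
        }
        if (j > nnode) break
        states[j] <- states[j] + 1L
    }
    log(total)
}

# brute-force Bayes marginal at one node by the same enumeration
enumMarginal <- function(tree, rates, kappa, partials, rootPrior, node) {
    k <- ncol(partials)
    tr <- tree
    tr$edge.length <- ifelse(tr$edge.length == 0 & kappa == 0, 1,
                             tr$edge.length^kappa)
    ntip <- length(tr$tip.label)
    nnode <- ntip + tr$Nnode
    root <- ntip + 1L
    Pedge <- lapply(seq_len(nrow(tr$edge)), function(e)
        transitionMatrix(rates, tr$edge.length[e]))
    states <- rep(1L, nnode)
    acc <- numeric(k)
    repeat {
        w <- rootPrior[states[root]]
        for (e in seq_len(nrow(tr$edge)))
            w <- w * Pedge[[e]][states[tr$edge[e, 1L]],
                                states[tr$edge[e, 2L]]]
        for (i in seq_len(ntip))
            w <- w * partials[tr$tip.label[i], states[i]]
        acc[states[node]] <- acc[states[node]] + w
        j <- 1L
        while (j <= nnode && states[j] == k) {
            states[j] <- 1L
            j <- j + 1L
        }
        if (j > nnode) break
        states[j] <- states[j] + 1L
    }
    acc / sum(acc)
}

# MRCA by intersecting root paths (O(n^2))
mrcaOracle <- function(tree, taxonSet) {
    parentOf <- integer(length(tree$tip.label) + tree$Nnode)
    parentOf[tree$edge[, 2L]] <- tree$edge[, 1L]
    pathToRoot <- function(node) {
        p <- node
        while (parentOf[node] != 0L) {
            node <- parentOf[node]
            p <- c(p, node)
        }
        p
    }
    tipIds <- match(taxonSet, tree$tip.label)
    common <- Reduce(intersect, lapply(tipIds, pathToRoot))
    # deepest common node = the one whose root path is longest
    common[which.max(lengths(lapply(common, pathToRoot)))]
}

# shortest interval by exhaustive scan over all sample-pair windows
hpdOracle <- function(x, level) {
    s <- sort(x)
    n <- length(s)
    need <- ceiling(level * n)
    best <- c(-Inf, Inf)
    for (i in seq_len(n)) {
        j <- i + need - 1L
        if (j > n) break
        if (s[j] - s[i] < best[2] - best[1]) best <- c(s[i], s[j])
    }
    best
}

# model posterior by quadrature over each model's rate space, under an
# Exponential(mean m) rate prior, via the u = 1 - exp(-q/m) transform
quadModelPosterior <- function(tree, column, kappa, m, nQuad = 120) {
    part <- toPartials(column, tree$tip.label)
    lik <- function(q01, q10)
        exp(mkLoglik(tree, c(q01, q10), kappa, part))
    gl <- pracma::gaussLegendre(nQuad, 0, 1)
    qs <- -m * log(1 - gl$x)
    Zfree <- 0
    for (i in seq_along(qs)) {
        li <- vapply(qs, function(q) lik(qs[i], q), numeric(1))
        Zfree <- Zfree + gl$w[i] * sum(gl$w * li)
    }
    Zeq <- sum(gl$w * vapply(qs, function(q) lik(q, q), numeric(1)))
    Z01 <- sum(gl$w * vapply(qs, function(q) lik(q, 0), numeric(1)))
    Z10 <- sum(gl$w * vapply(qs, function(q) lik(0, q), numeric(1)))
    z <- c(free = Zfree, equal = Zeq, q01_only = Z01, q10_only = Z10)
    z / sum(z)
}

# random binary/k-state column over a tree's tips, with optional missing
randomColumn <- function(tree, k = 2, pMissing = 0.1) {
    codes <- sample.int(k, length(tree$tip.label), replace = TRUE) - 1L
    codes[stats::runif(length(codes)) < pMissing] <- NA_integer_
    CharacterColumn("rnd", stats::setNames(codes, tree$tip.label),
                    stateSpace = 0:(k - 1L))
}
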