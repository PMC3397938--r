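test_that("transitionMatrix matches the binary closed form and its limits", {
    expect_equal(transitionMatrix(c(1.3, 0.4), 0), diag(2))
    expect_equal(transitionMatrix(c(1, 1, 1, 1, 1, 1), 0), diag(3))
    # symmetric rates, long time -> uniform stationary rows
    P <- transitionMatrix(c(1, 1), 50)
    expect_equal(unname(P), matrix(0.5, 2, 2), tolerance = 1e-12)
    # q01 = q10 = 1, t = 1: P00 = (1 + e^-2)/2
    expect_equal(transitionMatrix(c(1, 1), 1)[1, 1], (1 + exp(-2)) / 2,
                 tolerance = 1e-12)
    expect_warning(Pz <- transitionMatrix(c(0, 0), 1), "identity")
    expect_equal(Pz, diag(2))
    # rows are stochastic over a parameter grid, k = 2 and k = 3
    set.seed(5)
    for (rep in 1:20) {
        k <- sample(2:3, 1)
        rates <- stats::rexp(k * (k - 1), 1)
        P <- transitionMatrix(rates, stats::runif(1, 0, 3))
        expect_equal(rowSums(P), rep(1, k), tolerance = 1e-12)
        expect_true(all(P >= 0))
    }
})

test_that("binary transition probabilities agree with forward-equation integration", {
    grid <- expand.grid(q01 = c(0.3, 1.7), q10 = c(0.6, 2.2),
                        t = c(0.25, 1.5))
    for (i in seq_len(nrow(grid))) {
        g <- grid[i, ]
        Q <- makeGenerator(c(g$q01, g$q10))
        ode <- deSolve::ode(y = c(1, 0), times = c(0, g$t),
            func = function(t, y, parms) list(as.numeric(y %*% Q)),
            rtol = 1e-12, atol = 1e-12)
        expect_equal(transitionMatrix(c(g$q01, g$q10), g$t)[1, ],
                     unname(ode[2, 2:3]), tolerance = 1e-9)
    }
})

test_that("mkLoglik reproduces hand computations and boundary cases", {
    # all tips missing -> likelihood exactly 1
    tr <- parseNewick("((A:0.3,B:0.8):0.2,C:1.1);")
    colMiss <- CharacterColumn("m",
        c(A = NA_integer_, B = NA_integer_, C = NA_integer_), 0:1)
    pm <- toPartials(colMiss, tr$tip.label)
    expect_equal(mkLoglik(tr, c(1.2, 0.3), 0.7, pm), 0)
    expect_equal(mkLoglik(tr, c(0.1, 5), 2, pm), 0)

    # two-tip closed form: both tips state 0, uniform root prior
    tr2 <- parseNewick("(A:0.4,B:0.9);")
    col2 <- CharacterColumn("c", c(A = 0L, B = 0L), 0:1)
    p2 <- toPartials(col2, tr2$tip.label)
    q01 <- 0.8; q10 <- 0.5
    P1 <- transitionMatrix(c(q01, q10), 0.4)
    P2 <- transitionMatrix(c(q01, q10), 0.9)
    byHand <- log(0.5 * (P1[1, 1] * P2[1, 1] + P1[2, 1] * P2[2, 1]))
    expect_equal(mkLoglik(tr2, c(q01, q10), 1, p2), byHand,
                 tolerance = 1e-12)
})

test_that("mkLoglik equals exhaustive enumeration on random trees", {
    set.seed(31)
    for (rep in 1:25) {
        k <- sample(2:3, 1)
        tr <- randomTree(sample(3:5, 1))
        cc <- randomColumn(tr, k, pMissing = 0.2)
        part <- toPartials(cc, tr$tip.label)
        rates <- stats::rexp(k * (k - 1), 1)
        kap <- stats::runif(1, 0.2, 2)
        rp <- rep(1 / k, k)
        expect_equal(mkLoglik(tr, rates, kap, part, rp),
                     enumLoglik(tr, rates, kap, part, rp),
                     tolerance = 1e-8)
    }
})

test_that("likelihood is invariant to state relabelling, tip order and root polytomy form", {
    set.seed(13)
    for (rep in 1:10) {
        tr <- randomTree(6)
        cc <- randomColumn(tr, 2, pMissing = 0.2)
        part <- toPartials(cc, tr$tip.label)
        rates <- stats::rexp(2, 1)
        ll <- mkLoglik(tr, rates, 1, part)
        # swap states 0 <-> 1 in data and rates
        partSwap <- part[, c(2, 1)]
        colnames(partSwap) <- colnames(part)
        expect_equal(mkLoglik(tr, rev(rates), 1, partSwap), ll,
                     tolerance = 1e-10)
        # permute partial rows (tip order must not matter)
        expect_equal(mkLoglik(tr, rates, 1,
                              part[sample(rownames(part)), ]), ll,
                     tolerance = 1e-12)
    }
    # zero-length internal branch equals the explicit trichotomy
    bi <- parseNewick("((A:1,B:1):0,C:1);")
    tri <- parseNewick("(A:1,B:1,C:1);")
    cc <- CharacterColumn("c", c(A = 0L, B = 1L, C = 0L), 0:1)
    pb <- toPartials(cc, bi$tip.label)
    expect_equal(mkLoglik(bi, c(0.7, 0.2), 1, pb),
                 mkLoglik(tri, c(0.7, 0.2), 1, pb), tolerance = 1e-12)
})

test_that("with kappa = 0 the likelihood depends only on topology", {
    set.seed(17)
    tr <- randomTree(8)
    cc <- randomColumn(tr, 2, pMissing = 0)
    part <- toPartials(cc, tr$tip.label)
    tr2 <- tr
    tr2$edge.length <- stats::runif(nrow(tr$edge), 0.01, 5)
    rates <- c(0.6, 1.1)
    expect_equal(mkLoglik(tr, rates, 0, part),
                 mkLoglik(tr2, rates, 0, part), tolerance = 1e-12)
})

test_that("marginalNodeProbs matches enumeration and handles degenerate nodes", {
    # observed tip -> unit vector
    tr <- parseNewick("((A:0.3,B:0.8):0.2,C:1.1);")
    cc <- CharacterColumn("c", c(A = 0L, B = 1L, C = 1L), 0:1)
    part <- toPartials(cc, tr$tip.label)
    expect_equal(marginalNodeProbs(tr, c(1, 1), 1, part,
                                   node = which(tr$tip.label == "B")),
                 c(0, 1))
    # fully symmetric case -> (0.5, 0.5) at the root
    trs <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
    ccs <- CharacterColumn("c", c(A = 0L, B = 1L, C = 1L, D = 0L), 0:1)
    ps <- toPartials(ccs, trs$tip.label)
    expect_equal(marginalNodeProbs(trs, c(1, 1), 1, ps, node = 5L),
                 c(0.5, 0.5), tolerance = 1e-12)
    # enumeration oracle on random 4-tip trees, every node
    set.seed(23)
    for (rep in 1:20) {
        k <- sample(2:3, 1)
        tr <- randomTree(4)
        cc <- randomColumn(tr, k, pMissing = 0.2)
        part <- toPartials(cc, tr$tip.label)
        rates <- stats::rexp(k * (k - 1), 1)
        kap <- stats::runif(1, 0.3, 1.8)
        rp <- rep(1 / k, k)
        for (node in seq_len(4 + tr$Nnode)) {
            got <- marginalNodeProbs(tr, rates, kap, part, rp, node)
            expect_equal(sum(got), 1, tolerance = 1e-10)
            expect_equal(got,
                         enumMarginal(tr, rates, kap, part, rp, node),
                         tolerance = 1e-10)
        }
    }
})

test_that("relabelling states swaps marginal probabilities", {
    set.seed(29)
    tr <- randomTree(6)
    cc <- randomColumn(tr, 2, pMissing = 0.2)
    part <- toPartials(cc, tr$tip.label)
    partSwap <- part[, c(2, 1)]
    colnames(partSwap) <- colnames(part)
    rates <- c(1.4, 0.3)
    root <- 7L
    expect_equal(marginalNodeProbs(tr, rev(rates), 1, partSwap,
                                   node = root),
                 rev(marginalNodeProbs(tr, rates, 1, part, node = root)),
                 tolerance = 1e-10)
})

test_that("the stationary root prior option is a left null vector of Q", {
    rates <- c(2.5, 0.5)
    tr <- parseNewick("(A:0.4,B:0.9);")
    cc <- CharacterColumn("c", c(A = 0L, B = 0L), 0:1)
    p <- toPartials(cc, tr$tip.label)
    llu <- mkLoglik(tr, rates, 1, p, "uniform")
    lls <- mkLoglik(tr, rates, 1, p, "stationary")
    # stationary pi = (q10, q01)/(q01+q10) = (1/6, 5/6)
    P1 <- transitionMatrix(rates, 0.4); P2 <- transitionMatrix(rates, 0.9)
    expect_equal(lls, log(1 / 6 * P1[1, 1] * P2[1, 1] +
                          5 / 6 * P1[2, 1] * P2[2, 1]),
                 tolerance = 1e-12)
    expect_false(isTRUE(all.equal(llu, lls)))
})
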