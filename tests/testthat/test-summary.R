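# minimal chain object for summary-level tests
dummyChain <- function(df, k = 2L) {
    new("AsrChain", samples = df, tuning = data.frame(),
        acceptance = c(withinModel = NA_real_),
        modelSpace = enumerateModels(k), config = new("RunConfig"),
        priors = new("PriorSpec"), k = k)
}

test_that("hpdInterval is the shortest window and beats equal tails on skew", {
    expect_equal(unname(hpdInterval(rep(5, 30), 0.95)), c(5, 5))
    x <- as.numeric(1:1000)
    expect_equal(unname(hpdInterval(x, 0.95)), hpdOracle(x, 0.95))
    set.seed(3)
    for (rep in 1:20) {
        y <- stats::rexp(sample(50:400, 1), rate = stats::runif(1, .5, 3))
        lv <- sample(c(0.5, 0.8, 0.95), 1)
        expect_equal(unname(hpdInterval(y, lv)), hpdOracle(y, lv))
    }
    # right-skewed sample: HPD upper end below the equal-tail upper end
    set.seed(4)
    y <- stats::rexp(5000)
    expect_lt(hpdInterval(y, 0.95)[["upper"]],
              stats::quantile(y, 0.975))
    expect_error(hpdInterval(1:10, 0.95), "at least 20")
    expect_error(hpdInterval(1:100, 1.2), "level")
})

test_that("rateRatio is the ratio of averages with zero-rate samples included", {
    df <- data.frame(q01 = rep(2, 100), q10 = rep(1, 100),
                     kappa = 1, m = 5, model = "free", treeIndex = 1L)
    expect_equal(rateRatio(dummyChain(df)), 2)
    # zero-rate model samples enter the averages
    df2 <- data.frame(q01 = c(rep(2, 50), rep(0, 50)),
                      q10 = rep(1, 100), kappa = 1, m = 5,
                      model = c(rep("free", 50), rep("q10_only", 50)),
                      treeIndex = 1L)
    expect_equal(rateRatio(dummyChain(df2)), 1)
    # relabelled chain gives the reciprocal
    df3 <- df; names(df3)[1:2] <- c("q10", "q01")
    expect_equal(rateRatio(dummyChain(df3)), 1 / 2)
    dfInf <- data.frame(q01 = rep(1, 30), q10 = rep(0, 30))
    expect_warning(r <- rateRatio(dummyChain(dfInf)), "Inf")
    expect_equal(r, Inf)
})

test_that("essCalc tracks the AR(1) closed form and flags degenerate series", {
    set.seed(9)
    x <- stats::rnorm(20000)
    expect_gt(essCalc(x), 20000 * 0.8)
    rho <- 0.5
    ar <- as.numeric(stats::arima.sim(list(ar = rho), 50000))
    want <- 50000 * (1 - rho) / (1 + rho)
    expect_equal(essCalc(ar), want, tolerance = 0.2)
    expect_equal(essCalc(rep(3, 100)), 1)  # constant series flagged tiny
    expect_error(essCalc(1:10), "at least 50")
})

test_that("nodeProbabilities reduces to marginalNodeProbs for a one-sample chain", {
    tr <- parseNewick("((A:0.3,B:0.8):0.2,(C:0.5,D:0.6):0.4);")
    cc <- CharacterColumn("c", c(A = 0L, B = 0L, C = 1L, D = 1L), 0:1)
    ts <- TreeSample(tr)
    df <- data.frame(q01 = 0.9, q10 = 0.4, kappa = 1.2, m = 5,
                     model = "free", treeIndex = 1L)
    ch <- dummyChain(df)
    queries <- list(AB = c("A", "B"), all = c("A", "B", "C", "D"))
    np <- nodeProbabilities(ch, ts, cc, queries)
    part <- toPartials(cc, tr$tip.label)
    expect_equal(unname(np["AB", ]),
                 marginalNodeProbs(tr, c(0.9, 0.4), 1.2, part,
                                   node = mrcaNode(tr, c("A", "B"))),
                 tolerance = 1e-12)
    expect_equal(unname(np["all", ]),
                 marginalNodeProbs(tr, c(0.9, 0.4), 1.2, part,
                                   node = 5L), tolerance = 1e-12)
    expect_equal(unname(rowSums(np)), c(1, 1), tolerance = 1e-8)
    expect_error(nodeProbabilities(ch, ts, cc, list(bad = c("A", "Z"))),
                 "Z")
    expect_error(nodeProbabilities(ch, ts, cc, list(one = "A")),
                 "two taxa")
})

test_that("limiting behaviours of node probabilities hold", {
    # cherry of two state-0 tips on very short branches -> P(state 0) ~ 1
    tr <- parseNewick("((A:0.001,B:0.001):0.5,(C:0.4,D:0.6):0.3);")
    cc <- CharacterColumn("c", c(A = 0L, B = 0L, C = 1L, D = 1L), 0:1)
    part <- toPartials(cc, tr$tip.label)
    p <- marginalNodeProbs(tr, c(1, 1), 1, part,
                           node = mrcaNode(tr, c("A", "B")))
    expect_gt(p[1L], 0.98)
    # all-missing data, symmetric rates -> uniform at every node; under
    # asymmetric rates the uniform root prior drifts toward the
    # stationary distribution away from the root, so the chain-averaged
    # (prior-symmetric) quantity is checked at the pipeline level instead
    ccm <- CharacterColumn("m", c(A = NA, B = NA, C = NA, D = NA), 0:1)
    pm <- toPartials(ccm, tr$tip.label)
    for (node in 5:7)
        expect_equal(marginalNodeProbs(tr, c(0.7, 0.7), 1, pm,
                                       node = node),
                     c(0.5, 0.5), tolerance = 1e-10)
    expect_equal(marginalNodeProbs(tr, c(1.7, 0.2), 1, pm, node = 5L),
                 c(0.5, 0.5), tolerance = 1e-10)  # at the root itself
})

test_that("summaries are stable under further thinning", {
    fx <- makeFixture("symmetric", seed = 8)
    cfg <- runConfigProfile("test", generations = 6e4, burnin = 1e4,
                            thin = 10, seed = 21)
    ch <- runChain(fx$treeSample, fx$characters[[1L]], cfg)
    full <- summarizeChain(ch, fx$treeSample, fx$characters[[1L]],
                           queries = list(root = taxa(fx$treeSample)))
    chThin <- ch
    chThin@samples <- ch@samples[seq(1, nrow(ch@samples), by = 3), ]
    thin <- summarizeChain(chThin, fx$treeSample, fx$characters[[1L]],
                           queries = list(root = taxa(fx$treeSample)))
    expect_equal(thin@kappaMean, full@kappaMean, tolerance = 0.1)
    expect_equal(unname(thin@nodeProbs["root", 1L]),
                 unname(full@nodeProbs["root", 1L]), tolerance = 0.05)
    # reporting contract: binary state-0 probability determines state 1
    expect_equal(unname(rowSums(full@nodeProbs)), 1, tolerance = 1e-8)
    expect_true(all(full@nodeProbs >= 0 & full@nodeProbs <= 1))
})
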