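test_that("the binary model space holds exactly the four rate configurations", {
    ms <- enumerateModels(2)
    expect_equal(length(ms@models), 4L)
    expect_setequal(ms@models, c("free", "equal", "q01_only", "q10_only"))
    expect_equal(ms@nFree[match("free", ms@models)], 2L)
    expect_equal(ms@nFree[match("equal", ms@models)], 1L)
    ms3 <- enumerateModels(3)
    expect_equal(length(ms3@models), 1L)
    expect_equal(ms3@nFree, 6L)
    expect_error(enumerateModels(4), "unsupported")
})

test_that("tuneRateDeviation applies the multiplicative rule with clamping", {
    expect_equal(tuneRateDeviation(0.30, 0.5), 0.5)    # inside the band
    expect_equal(tuneRateDeviation(0.05, 0.5), 0.4)    # shrink x 0.8
    expect_equal(tuneRateDeviation(0.80, 0.5), 0.625)  # grow x 1.25
    expect_equal(tuneRateDeviation(0.0, 1e-6), 1e-6)  # clamped below
    expect_gte(tuneRateDeviation(0, 1e-7), 1e-6)
    expect_lte(tuneRateDeviation(1, 1e3), 1e3)
    expect_error(tuneRateDeviation(1.2, 0.5))
})

test_that("proposals preserve model constraints and report the prior-ratio correction", {
    ms <- enumerateModels(2)
    priors <- new("PriorSpec")
    st <- list(model = "equal", rates = c(0.7, 0.7), kappa = 1, m = 2,
               treeIndex = 1L)
    set.seed(1)
    for (i in 1:20) {
        pr <- proposeMove(st, 0.3, ms, 5L, priors, moveType = "rates")
        expect_equal(pr$state$rates[1L], pr$state$rates[2L])
        expect_gte(pr$state$rates[1L], 0)
        expect_equal(pr$logCorrection, 0)
    }
    # one-way model keeps its fixed zero under rate moves
    st0 <- list(model = "q01_only", rates = c(0.9, 0), kappa = 1, m = 2,
                treeIndex = 1L)
    pr0 <- proposeMove(st0, 0.3, ms, 5L, priors, moveType = "rates")
    expect_equal(pr0$state$rates[2L], 0)

    # kappa and m stay inside their prior support under huge kernels
    set.seed(2)
    for (i in 1:50) {
        pk <- proposeMove(st, 500, ms, 5L, priors, moveType = "kappa")
        expect_true(pk$state$kappa >= 0 && pk$state$kappa <= 5)
        pm <- proposeMove(st, 500, ms, 5L, priors, moveType = "m")
        expect_true(pm$state$m >= 0 && pm$state$m <= 10)
    }

    # model jump: correction is the prior log-density ratio of the
    # replaced free parameters
    set.seed(3)
    pj <- proposeMove(st, 0.3, ms, 5L, priors, moveType = "model")
    expect_true(pj$state$model != "equal")
    newVals <- switch(pj$state$model,
        free = pj$state$rates,
        q01_only = pj$state$rates[1L],
        q10_only = pj$state$rates[2L])
    expect_equal(pj$logCorrection,
                 dexp(0.7, 1 / 2, log = TRUE) -
                 sum(dexp(newVals, 1 / 2, log = TRUE)),
                 tolerance = 1e-12)
})

test_that("identical seeds give bit-identical chains", {
    fx <- makeFixture("symmetric", seed = 4)
    cfg <- runConfigProfile("test", generations = 4000, burnin = 1000,
                            thin = 5, seed = 99)
    ch1 <- runChain(fx$treeSample, fx$characters[[1L]], cfg)
    ch2 <- runChain(fx$treeSample, fx$characters[[1L]], cfg)
    expect_identical(samples(ch1), samples(ch2))
    d <- withr::local_tempdir()
    writeTrace(ch1, file.path(d, "a.tsv"))
    writeTrace(ch2, file.path(d, "b.tsv"))
    expect_identical(readLines(file.path(d, "a.tsv")),
                     readLines(file.path(d, "b.tsv")))
})

test_that("with the likelihood switched off the sampler recovers its priors", {
    # short-chain version: the full-length check lives in the acceptance
    # suite; here we assert loose Monte Carlo agreement
    fx <- makeFixture("prior-only", seed = 2)
    cfg <- runConfigProfile("test", generations = 1.2e5, burnin = 2e4,
                            thin = 5, seed = 5)
    ch <- runChain(fx$treeSample, fx$characters[[1L]], cfg)
    s <- samples(ch)
    expect_equal(mean(s$kappa), 2.5, tolerance = 0.04)
    expect_equal(mean(s$m), 5, tolerance = 0.04)      # relative
    mp <- modelPosterior(ch)
    expect_true(all(abs(mp - 0.25) < 0.03))
    # kappa marginal is Uniform(0,5): quartiles near 1.25 / 3.75
    expect_equal(unname(stats::quantile(s$kappa, c(.25, .75))),
                 c(1.25, 3.75), tolerance = 0.05)
})

test_that("fixed-kappa and fixed-m modes hold their values constant", {
    fx <- makeFixture("symmetric", seed = 6)
    cfg <- runConfigProfile("test", generations = 3000, burnin = 500,
                            thin = 5, seed = 11, fixKappa = 1.3,
                            fixM = 4)
    ch <- runChain(fx$treeSample, fx$characters[[1L]], cfg)
    expect_true(all(samples(ch)$kappa == 1.3))
    expect_true(all(samples(ch)$m == 4))
})

test_that("a three-state character runs under the single free model", {
    fx <- makeFixture("morindeae-like", seed = 3)
    cfg <- runConfigProfile("test", generations = 5000, burnin = 1000,
                            thin = 10, seed = 8)
    ch <- runChain(fx$treeSample, fx$characters$growth_form, cfg)
    s <- samples(ch)
    expect_true(all(s$model == "free"))
    expect_true(all(c("q01", "q02", "q10", "q12", "q20", "q21")
                    %in% names(s)))
    expect_true(all(is.finite(s$loglik)))
})
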