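#' Enumerate the rate-model space for a k-state character
#'
#' For a binary character there are exactly four models: both rates free
#' (\code{"free"}), the single-rate model with q01 = q10 (\code{"equal"}),
#' and the two one-way models \code{"q01_only"} (q10 fixed to 0) and
#' \code{"q10_only"} (q01 fixed to 0).  The model prior is uniform.  For a
#' three-state character a single all-rates-free model (6 rates) is used
#' and no reversible jump takes place.
#'
#' @param k number of states (2 or 3).
#' @return a [ModelSpace-class] object.
#' @export
enumerateModels <- function(k) {
    k <- as.integer(k)
    if (k == 2L)
        new("ModelSpace", k = 2L,
            models = c("free", "equal", "q01_only", "q10_only"),
            nFree = c(2L, 1L, 1L, 1L))
    else if (k == 3L)
        new("ModelSpace", k = 3L, models = "free", nFree = 6L)
    else stop("unsupported number of states: ", k)
}

# free-parameter values of a state's rate vector under its model
freeRateValues <- function(model, rates, k) {
    if (k != 2L) return(rates)
    switch(model,
        free = rates,
        equal = rates[1L],
        q01_only = rates[1L],
        q10_only = rates[2L],
        stop("unknown model ", model))
}

# expand free-parameter values into the full off-diagonal rate vector
expandRates <- function(model, vals, k) {
    if (k != 2L) return(vals)
    switch(model,
        free = vals,
        equal = c(vals, vals),
        q01_only = c(vals, 0),
        q10_only = c(0, vals),
        stop("unknown model ", model))
}

# fold x back into [lo, hi] by reflection (hi may be Inf)
reflect <- function(x, lo, hi) {
    if (is.infinite(hi)) return(lo + abs(x - lo))
    period <- 2 * (hi - lo)
    y <- (x - lo) %% period
    y <- ifelse(y > hi - lo, period - y, y)
    lo + y
}

#' Adjust the proposal deviation toward the target acceptance band
#'
#' Multiplicative tuning used during burn-in: an acceptance rate below the
#' lower target shrinks the normal kernel's standard deviation (x 0.8), a
#' rate above the upper target grows it (x 1.25); inside the band it is
#' left unchanged.  The deviation is clamped to [1e-6, 1e3].  Tuning is
#' frozen after burn-in to preserve detailed balance.
#'
#' @param acceptanceRate realised acceptance fraction in the last window.
#' @param currentDeviation current kernel standard deviation.
#' @param targetLow,targetHigh the target band (default 0.20--0.40).
#' @return the new deviation.
#' @export
tuneRateDeviation <- function(acceptanceRate, currentDeviation,
                              targetLow = 0.20, targetHigh = 0.40) {
    stopifnot(acceptanceRate >= 0, acceptanceRate <= 1)
    d <- currentDeviation
    if (acceptanceRate < targetLow) d <- d * 0.8
    else if (acceptanceRate > targetHigh) d <- d * 1.25
    min(max(d, 1e-6), 1e3)
}

#' Propose a Metropolis--Hastings move
#'
#' One move is drawn at random from the mixture: (i) within-model rate
#' perturbation (each free rate gets Normal(0, dev) noise, reflected at
#' 0); (ii) kappa perturbation with the same kernel, reflected into
#' (0, kappaMax); (iii) hyperprior-mean perturbation reflected into
#' (0, hyperMax); (iv) reversible model jump: a different model chosen
#' uniformly, with all free rates of the proposed model drawn fresh from
#' the current Exponential(m) rate prior (an independence birth proposal,
#' whose dimension-matching correction is the prior density ratio of the
#' replaced parameters); (v) tree move proposing an index uniformly from
#' the sample.  The returned \code{logCorrection} is
#' log q(current | candidate) - log q(candidate | current); adding it to
#' the posterior log-ratio gives the Metropolis--Hastings log acceptance
#' probability.
#'
#' @param state list with elements \code{model}, \code{rates} (full
#'   off-diagonal vector), \code{kappa}, \code{m}, \code{treeIndex}.
#' @param dev current kernel standard deviation.
#' @param modelSpace a [ModelSpace-class].
#' @param nTreesAvail number of trees in the sample.
#' @param priors a [PriorSpec-class].
#' @param moveType move to perform; drawn from \code{weights} when NULL.
#' @param weights named move-mixture weights (rates, kappa, m, model, tree).
#' @return list(state = candidate, logCorrection, type).
#' @export
proposeMove <- function(state, dev, modelSpace, nTreesAvail, priors,
                        moveType = NULL,
                        weights = c(rates = .4, kappa = .2, m = .1,
                                    model = .15, tree = .15)) {
    k <- modelSpace@k
    if (is.null(moveType))
        moveType <- sample(names(weights), 1L, prob = weights)
    cand <- state
    corr <- 0
    switch(moveType,
        rates = {
            vals <- freeRateValues(state$model, state$rates, k)
            vals <- reflect(vals + stats::rnorm(length(vals), 0, dev),
                            0, Inf)
            cand$rates <- expandRates(state$model, vals, k)
        },
        kappa = {
            cand$kappa <- reflect(state$kappa + stats::rnorm(1, 0, dev),
                                  0, priors@kappaMax)
        },
        m = {
            cand$m <- reflect(state$m + stats::rnorm(1, 0, dev),
                              0, priors@hyperMax)
        },
        model = {
            others <- setdiff(modelSpace@models, state$model)
            if (length(others)) {
                cand$model <- if (length(others) == 1L) others
                              else sample(others, 1L)
                nNew <- modelSpace@nFree[match(cand$model,
                                               modelSpace@models)]
                newVals <- stats::rexp(nNew, rate = 1 / state$m)
                cand$rates <- expandRates(cand$model, newVals, k)
                oldVals <- freeRateValues(state$model, state$rates, k)
                corr <- sum(stats::dexp(oldVals, 1 / state$m, log = TRUE)) -
                        sum(stats::dexp(newVals, 1 / state$m, log = TRUE))
            }
        },
        tree = {
            cand$treeIndex <- sample.int(nTreesAvail, 1L)
        },
        stop("unknown move type ", moveType))
    list(state = cand, logCorrection = corr, type = moveType)
}

# log prior density of a state (model and tree terms are constant under a
# uniform model prior and uniform tree weights, and are omitted)
logPriorState <- function(state, modelSpace, priors, config) {
    vals <- freeRateValues(state$model, state$rates, modelSpace@k)
    lp <- sum(stats::dexp(vals, rate = 1 / state$m, log = TRUE))
    if (is.na(config@fixKappa))
        lp <- lp + stats::dunif(state$kappa, 0, priors@kappaMax,
                                log = TRUE)
    if (is.na(config@fixM))
        lp <- lp + stats::dunif(state$m, 0, priors@hyperMax, log = TRUE)
    lp
}

#' Run one reversible-jump MCMC chain
#'
#' Samples the joint posterior of rate model, rates, kappa, the
#' hierarchical rate-prior mean m, and the tree index, for one character
#' over a posterior tree sample.  During burn-in the shared proposal
#' deviation is tuned every \code{tuneInterval} generations toward the
#' configured acceptance band; tuning is frozen afterwards.  Samples are
#' saved every \code{thin} generations after burn-in.  The run is fully
#' determined by \code{config@seed}.
#'
#' @param treeSample a [TreeSample-class].
#' @param column a [CharacterColumn-class] over the sample's taxa.
#' @param config a [RunConfig-class].
#' @param priors a [PriorSpec-class].
#' @param modelSpace optional [ModelSpace-class]; defaults to
#'   [enumerateModels()] on the column's state count.
#' @return an [AsrChain-class] object.
#' @export
runChain <- function(treeSample, column, config = new("RunConfig"),
                     priors = new("PriorSpec"), modelSpace = NULL) {
    stopifnot(is(treeSample, "TreeSample"), is(column, "CharacterColumn"))
    k <- length(column@stateSpace)
    if (is.null(modelSpace)) modelSpace <- enumerateModels(k)
    validObject(config); validObject(priors)

    part <- toPartials(column, taxa(treeSample))
    prepped <- lapply(trees(treeSample), prepTree, partials = part)
    nT <- length(prepped)
    uniformRoot <- rep(1 / k, k)
    useStationary <- config@rootPrior == "stationary"

    llFun <- function(st) {
        pp <- prepped[[st$treeIndex]]
        Q <- makeGenerator(st$rates)
        rp <- if (useStationary)
            rootPriorVector(st$rates, k, "stationary") else uniformRoot
        mk_loglik_cpp(pp$edge, pp$len, pp$ntip, Q, pp$tipPart, rp,
                      st$kappa)
    }

    set.seed(config@seed)
    weights <- config@moveWeights[c("rates", "kappa", "m", "model",
                                    "tree")]
    if (!is.na(config@fixKappa)) weights["kappa"] <- 0
    if (!is.na(config@fixM)) weights["m"] <- 0
    if (length(modelSpace@models) == 1L) weights["model"] <- 0
    if (nT == 1L) weights["tree"] <- 0
    if (sum(weights) <= 0) stop("no free parameter to sample")
    weights <- weights / sum(weights)

    m0 <- if (!is.na(config@fixM)) config@fixM else
        stats::runif(1, 0, priors@hyperMax)
    kap0 <- if (!is.na(config@fixKappa)) config@fixKappa else
        stats::runif(1, 0, priors@kappaMax)
    model0 <- modelSpace@models[1L]
    nFree0 <- modelSpace@nFree[1L]
    state <- list(model = model0,
                  rates = expandRates(model0,
                                      stats::rexp(nFree0, 1 / m0), k),
                  kappa = kap0, m = m0,
                  treeIndex = sample.int(nT, 1L))
    curLL <- llFun(state)
    curLP <- logPriorState(state, modelSpace, priors, config)
    if (!is.finite(curLL))
        stop("non-finite initial log-likelihood; check inputs")

    gens <- config@generations
    burnin <- config@burnin
    thin <- config@thin
    nSave <- floor((gens - burnin) / thin)
    rateNames <- if (k == 2L) c("q01", "q10")
                 else c("q01", "q02", "q10", "q12", "q20", "q21")
    smp <- matrix(NA_real_, nSave, 4L + length(rateNames),
                  dimnames = list(NULL, c("generation", rateNames,
                                          "kappa", "m", "treeIndex")))
    smpModel <- character(nSave)
    smpLL <- numeric(nSave); smpLP <- numeric(nSave)
    dev <- config@rateDev
    tuneGen <- numeric(0); tuneDev <- numeric(0); tuneAcc <- numeric(0)
    winAtt <- 0L; winAcc <- 0L
    moveTypes <- c("rates", "kappa", "m", "model", "tree")
    attempts <- stats::setNames(numeric(5), moveTypes)
    accepts <- stats::setNames(numeric(5), moveTypes)
    paramMoves <- c("rates", "kappa", "m")
    isave <- 0L

    for (gen in seq_len(gens)) {
        prop <- proposeMove(state, dev, modelSpace, nT, priors,
                            weights = weights)
        type <- prop$type
        cand <- prop$state
        candLL <- if (type == "m") curLL else llFun(cand)
        candLP <- logPriorState(cand, modelSpace, priors, config)
        if (!is.finite(candLP)) {
            logAlpha <- -Inf
        } else {
            if (is.nan(candLL))
                stop(sprintf(
                    "non-finite posterior at generation %d (move %s)",
                    gen, type))
            logAlpha <- (candLL - curLL) + (candLP - curLP) +
                prop$logCorrection
        }
        acc <- is.finite(logAlpha) &&
            (logAlpha >= 0 || log(stats::runif(1)) < logAlpha)
        if (acc) {
            state <- cand; curLL <- candLL; curLP <- candLP
        }
        if (gen > burnin) {
            attempts[type] <- attempts[type] + 1
            if (acc) accepts[type] <- accepts[type] + 1
        }
        if (gen <= burnin && type %in% paramMoves) {
            winAtt <- winAtt + 1L
            if (acc) winAcc <- winAcc + 1L
        }
        if (gen <= burnin && gen %% config@tuneInterval == 0 &&
            winAtt > 0L) {
            accRate <- winAcc / winAtt
            dev <- tuneRateDeviation(accRate, dev, config@targetLow,
                                     config@targetHigh)
            tuneGen <- c(tuneGen, gen); tuneDev <- c(tuneDev, dev)
            tuneAcc <- c(tuneAcc, accRate)
            winAtt <- 0L; winAcc <- 0L
        }
        if (gen > burnin && (gen - burnin) %% thin == 0) {
            isave <- isave + 1L
            smp[isave, ] <- c(gen, state$rates, state$kappa, state$m,
                              state$treeIndex)
            smpModel[isave] <- state$model
            smpLL[isave] <- curLL
            smpLP[isave] <- curLP
        }
    }

    samples <- as.data.frame(smp[seq_len(isave), , drop = FALSE])
    samples$model <- smpModel[seq_len(isave)]
    samples$loglik <- smpLL[seq_len(isave)]
    samples$logprior <- smpLP[seq_len(isave)]
    samples <- samples[, c("generation", "model", rateNames, "kappa",
                           "m", "treeIndex", "loglik", "logprior")]
    accRate <- ifelse(attempts > 0, accepts / attempts, NA_real_)
    pAtt <- sum(attempts[paramMoves])
    accRate <- c(accRate, withinModel = if (pAtt > 0)
        sum(accepts[paramMoves]) / pAtt else NA_real_)
    new("AsrChain", samples = samples,
        tuning = data.frame(generation = tuneGen, rateDev = tuneDev,
                            acceptance = tuneAcc),
        acceptance = accRate, modelSpace = modelSpace, config = config,
        priors = priors, k = as.integer(k))
}

#' Realised within-model parameter acceptance rate of a chain
#'
#' The fraction of post-burn-in rate/kappa/m perturbations that were
#' accepted -- the quantity the 20--40% tuning band refers to.
#'
#' @param chain an [AsrChain-class].
#' @return acceptance fraction.
#' @export
withinModelAcceptance <- function(chain) {
    unname(chain@acceptance["withinModel"])
}

#' Serialise a chain trace as TSV
#'
#' One row per saved sample (generation, model, rates, kappa, m, tree
#' index, log-likelihood, log-prior), loadable by standard MCMC
#' diagnostic tools.
#'
#' @param chain an [AsrChain-class].
#' @param path output path.
#' @export
writeTrace <- function(chain, path) {
    utils::write.table(chain@samples, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a serialised trace back as a minimal chain
#'
#' Reconstructs an [AsrChain-class] carrying the samples (for
#' re-summarising existing traces); tuning and acceptance metadata are
#' not stored in the trace and come back empty.
#'
#' @param path a TSV written by [writeTrace()].
#' @return an [AsrChain-class].
#' @export
readTrace <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    k <- if ("q02" %in% names(df)) 3L else 2L
    new("AsrChain", samples = df, tuning = data.frame(),
        acceptance = stats::setNames(numeric(0), character(0)),
        modelSpace = enumerateModels(k), config = new("RunConfig"),
        priors = new("PriorSpec"), k = k)
}
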