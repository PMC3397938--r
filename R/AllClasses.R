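#' @useDynLib mkasr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

setOldClass("phylo")

#' TreeSample: a posterior sample of rooted trees over one taxon set
#'
#' Container for an ordered collection of rooted trees (class
#' \code{"phylo"} from \pkg{ape}) that share a single tip-label set, as
#' produced by Bayesian phylogenetic samplers.  Ancestral-state inference
#' integrates over the members of a \code{TreeSample} by treating the tree
#' index as a sampled quantity.
#'
#' @slot trees list of \code{"phylo"} objects in file/sample order.
#' @slot taxa character vector, the shared tip-label set (sorted).
#' @slot provenance free-text note on where the sample came from.
#'
#' @seealso [readTreeSample()], [simulateTreeSample()]
#' @export
setClass("TreeSample",
    representation(trees = "list", taxa = "character",
                   provenance = "character"),
    prototype(provenance = NA_character_))

setValidity("TreeSample", function(object) {
    if (length(object@trees) == 0L)
        return("TreeSample must contain at least one tree")
    if (!all(vapply(object@trees, inherits, logical(1), "phylo")))
        return("all trees must be 'phylo' objects")
    ref <- sort(object@trees[[1L]]$tip.label)
    for (i in seq_along(object@trees)) {
        lab <- sort(object@trees[[i]]$tip.label)
        if (!identical(lab, ref)) {
            d <- c(setdiff(lab, ref), setdiff(ref, lab))
            return(sprintf(
                "tree %d has a different taxon set (difference: %s)",
                i, paste(d, collapse = ", ")))
        }
    }
    if (!identical(sort(object@taxa), ref))
        return("taxa slot does not match the trees' tip labels")
    TRUE
})

#' CharacterColumn: one discrete character over a taxon set
#'
#' A single discrete character: its ordered state space (integer codes,
#' state 0 first) and a taxon-to-state assignment in which \code{NA}
#' denotes missing ("?").  At least two distinct observed states are
#' required before rate inference is meaningful; the validity check only
#' enforces structural invariants so that degenerate columns can still be
#' constructed (e.g. the all-missing prior-recovery fixture).
#'
#' @slot name character scalar, e.g. \code{"growth_form"}.
#' @slot stateSpace integer vector of codes, length 2 or 3, state 0 first.
#' @slot assignments named integer vector (taxon -> code), \code{NA} missing.
#'
#' @seealso [readCharacterMatrix()], [toPartials()]
#' @export
setClass("CharacterColumn",
    representation(name = "character", stateSpace = "integer",
                   assignments = "integer"))

setValidity("CharacterColumn", function(object) {
    k <- length(object@stateSpace)
    if (k < 2L) return("state space must have at least two states")
    if (anyDuplicated(object@stateSpace))
        return("state space codes must be unique")
    if (is.null(names(object@assignments)) ||
        anyDuplicated(names(object@assignments)))
        return("assignments must be uniquely named by taxon")
    obs <- object@assignments[!is.na(object@assignments)]
    if (length(obs) && !all(obs %in% object@stateSpace))
        return(sprintf("assigned code(s) outside state space: %s",
                       paste(unique(obs[!obs %in% object@stateSpace]),
                             collapse = ", ")))
    TRUE
})

#' ModelSpace: the rate-model configurations visited by reversible jump
#'
#' For a binary character the model space holds exactly four models: both
#' rates free, the two rates constrained equal, and the two one-way models
#' in which the opposite rate is fixed to zero.  For a three-state
#' character a single all-rates-free model is used (no reversible jump).
#'
#' @slot k integer, number of states.
#' @slot models character vector of model labels.
#' @slot nFree integer vector, free-parameter count per model.
#'
#' @seealso [enumerateModels()]
#' @export
setClass("ModelSpace",
    representation(k = "integer", models = "character", nFree = "integer"))

setValidity("ModelSpace", function(object) {
    if (length(object@models) != length(object@nFree))
        return("models and nFree must have equal length")
    if (object@k == 2L && length(object@models) != 4L)
        return("binary model space must contain exactly 4 models")
    TRUE
})

#' PriorSpec: priors of the ancestral-state model
#'
#' Rates carry an exponential prior whose mean m is itself given a uniform
#' hyperprior on (0, hyperMax); the branch-length transform kappa has a
#' uniform prior on (0, kappaMax); the model prior is uniform over the
#' model space.
#'
#' @slot hyperMax upper bound of the uniform hyperprior on the exponential
#'   rate-prior mean (default 10).
#' @slot kappaMax upper bound of the uniform prior on kappa (default 5).
#'
#' @export
setClass("PriorSpec",
    representation(hyperMax = "numeric", kappaMax = "numeric"),
    prototype(hyperMax = 10, kappaMax = 5))

setValidity("PriorSpec", function(object) {
    if (object@hyperMax <= 0 || object@kappaMax <= 0)
        return("prior bounds must be positive")
    TRUE
})

#' RunConfig: MCMC run-length, tuning and reproducibility settings
#'
#' Desk-scale defaults (2e6 generations, 2e5 burn-in, thinning 1000) are
#' sized for interactive reanalysis; the "paper" profile
#' ([runConfigProfile()]) carries the full-scale protocol (220e6
#' generations, 20e6 burn-in).
#'
#' @slot generations total MCMC generations.
#' @slot burnin generations discarded before sampling starts.
#' @slot thin save a sample every \code{thin} generations.
#' @slot targetLow,targetHigh acceptance band targeted by proposal tuning
#'   (default 0.20--0.40).
#' @slot rateDev initial standard deviation of the normal perturbation
#'   kernel shared by the rate, kappa and hyperprior-mean moves.
#' @slot tuneInterval generations between tuning adjustments (burn-in only).
#' @slot moveWeights named numeric weights for the move mixture
#'   (rates, kappa, m, model, tree).
#' @slot rootPrior \code{"uniform"} or \code{"stationary"}.
#' @slot fixKappa \code{NA} to sample kappa, or a fixed value.
#' @slot fixM \code{NA} to sample the rate-prior mean hierarchically, or a
#'   fixed value.
#' @slot seed RNG seed for the run.
#' @slot nRuns replicate runs launched by [reconstruct()] (default 3).
#'
#' @export
setClass("RunConfig",
    representation(generations = "numeric", burnin = "numeric",
                   thin = "numeric", targetLow = "numeric",
                   targetHigh = "numeric", rateDev = "numeric",
                   tuneInterval = "numeric", moveWeights = "numeric",
                   rootPrior = "character", fixKappa = "numeric",
                   fixM = "numeric", seed = "numeric", nRuns = "numeric"),
    prototype(generations = 2e6, burnin = 2e5, thin = 1000,
              targetLow = 0.20, targetHigh = 0.40, rateDev = 0.5,
              tuneInterval = 1000,
              moveWeights = c(rates = 0.40, kappa = 0.20, m = 0.10,
                              model = 0.15, tree = 0.15),
              rootPrior = "uniform", fixKappa = NA_real_, fixM = NA_real_,
              seed = 1, nRuns = 3))

setValidity("RunConfig", function(object) {
    if (object@burnin >= object@generations)
        return("burnin must be smaller than generations")
    if (object@thin < 1) return("thin must be >= 1")
    if (!(object@targetLow > 0 && object@targetHigh < 1 &&
          object@targetLow < object@targetHigh))
        return("acceptance band must satisfy 0 < low < high < 1")
    if (!all(c("rates", "kappa", "m", "model", "tree") %in%
             names(object@moveWeights)))
        return("moveWeights must name rates, kappa, m, model, tree")
    if (!object@rootPrior %in% c("uniform", "stationary"))
        return("rootPrior must be 'uniform' or 'stationary'")
    TRUE
})

#' AsrChain: a thinned post-burn-in posterior sample
#'
#' One MCMC run: the saved samples (model indicator, rates, kappa,
#' hyperprior mean, tree index, log-likelihood, log-prior), the tuning
#' trace recorded during burn-in, per-move acceptance counts, and the
#' configuration that produced it.
#'
#' @slot samples data.frame, one row per saved sample.
#' @slot tuning data.frame of (generation, rateDev, acceptance) rows.
#' @slot acceptance named numeric, realised post-burn-in acceptance rate
#'   per move type.
#' @slot modelSpace the [ModelSpace-class] sampled over.
#' @slot config the [RunConfig-class] used.
#' @slot priors the [PriorSpec-class] used.
#' @slot k number of character states.
#'
#' @export
setClass("AsrChain",
    representation(samples = "data.frame", tuning = "data.frame",
                   acceptance = "numeric", modelSpace = "ModelSpace",
                   config = "RunConfig", priors = "PriorSpec",
                   k = "integer"))

#' AsrSummary: reporting quantities of an ancestral-state analysis
#'
#' Mirrors the standard reporting layout for this analysis: the ratio of
#' posterior-average rates q01/q10, the posterior mean of kappa with its
#' 95% highest-posterior-density interval, marginal state probabilities at
#' each queried node, the posterior model frequencies, and effective
#' sample sizes of the scalar parameters.
#'
#' @slot character name of the character summarised.
#' @slot states human-readable state coding note.
#' @slot qRatio ratio of average q01 to average q10 (NA for 3-state runs).
#' @slot kappaMean posterior mean of kappa.
#' @slot kappaHPD length-2 numeric, 95% HPD of kappa.
#' @slot nodeProbs matrix (queries x states) of marginal state
#'   probabilities averaged over the posterior sample.
#' @slot modelPosterior named numeric, posterior model frequencies.
#' @slot ess named numeric, effective sample sizes.
#' @slot rootPrior root-prior choice the results are conditional on.
#'
#' @export
setClass("AsrSummary",
    representation(character = "character", states = "character",
                   qRatio = "numeric", kappaMean = "numeric",
                   kappaHPD = "numeric", nodeProbs = "matrix",
                   modelPosterior = "numeric", ess = "numeric",
                   rootPrior = "character"))

#' SimScenario: parameters of the synthetic tree-and-character generator
#'
#' Describes the generative model the test fixtures use: a Yule (pure
#' birth) focal topology rescaled to a given root-to-tip depth, per-tree
#' lognormal branch-length jitter and optional NNI topology perturbation
#' (emulating a Bayesian posterior sample), and character evolution under
#' known rates and kappa.
#'
#' @slot nTaxa number of tips (>= 3).
#' @slot nTrees number of trees in the emulated posterior sample.
#' @slot birthRate Yule birth rate.
#' @slot treeDepth root-to-tip depth the focal tree is rescaled to
#'   (expected substitutions per site).
#' @slot jitterSd sdlog of the lognormal branch-length jitter (mean 1).
#' @slot nniProb probability that a sampled tree receives one NNI move.
#' @slot rates true off-diagonal rates (length 2 for binary: q01, q10).
#' @slot kappa true branch-length transform exponent.
#' @slot rootDist root state distribution used when simulating characters.
#' @slot seed RNG seed.
#'
#' @seealso [simulateTreeSample()], [simulateCharacter()], [makeFixture()]
#' @export
setClass("SimScenario",
    representation(nTaxa = "numeric", nTrees = "numeric",
                   birthRate = "numeric", treeDepth = "numeric",
                   jitterSd = "numeric", nniProb = "numeric",
                   rates = "numeric", kappa = "numeric",
                   rootDist = "numeric", seed = "numeric"),
    prototype(nTaxa = 61, nTrees = 100, birthRate = 1, treeDepth = 1,
              jitterSd = 0.1, nniProb = 0, rates = c(q01 = 1, q10 = 1),
              kappa = 1, rootDist = c(0.5, 0.5), seed = 1))

setValidity("SimScenario", function(object) {
    if (object@nTaxa < 3) return("nTaxa must be >= 3")
    if (object@jitterSd < 0) return("jitterSd must be >= 0")
    if (any(object@rates < 0)) return("rates must be >= 0")
    if (abs(sum(object@rootDist) - 1) > 1e-8)
        return("rootDist must sum to 1")
    TRUE
})
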