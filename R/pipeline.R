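#' End-to-end ancestral-state reconstruction
#'
#' Ties the stages together for one or more characters: optionally prunes
#' outgroup taxa from every tree, runs the configured number of replicate
#' MCMC chains (distinct seeds derived from \code{config@seed}), checks
#' replicate agreement, pools the chains, and summarises rates, kappa,
#' model posterior and per-node marginal state probabilities.
#'
#' @param treeSample a [TreeSample-class].
#' @param characters a [CharacterColumn-class] or named list of them.
#' @param queries named list of taxon sets for node queries (taxa that are
#'   pruned away are dropped from each query automatically).
#' @param outgroup taxa to prune before analysis (default none).
#' @param config a [RunConfig-class]; \code{config@nRuns} replicate chains
#'   are run with seeds \code{seed, seed + 1, ...}.
#' @param priors a [PriorSpec-class].
#' @param outputDir if non-NULL, traces, summary tables, the resolved
#'   configuration and a log are written here.
#' @param every forward to [nodeProbabilities()] (thin node-probability
#'   averaging).
#' @return named list, one element per character, each with elements
#'   \code{summary} ([AsrSummary-class]), \code{chains} (list of
#'   [AsrChain-class]), \code{pooled} ([AsrChain-class]) and
#'   \code{agreement} (per-run kappa means, MC standard errors and the
#'   largest pairwise z score).
#' @export
reconstruct <- function(treeSample, characters, queries = list(),
                        outgroup = character(0),
                        config = new("RunConfig"),
                        priors = new("PriorSpec"), outputDir = NULL,
                        every = 1L) {
    if (is(characters, "CharacterColumn"))
        characters <- stats::setNames(list(characters), characters@name)
    if (length(outgroup))
        treeSample <- pruneTreeSample(treeSample, outgroup)
    keep <- taxa(treeSample)
    queries <- lapply(queries, intersect, y = keep)
    queries <- queries[lengths(queries) >= 2L]
    if (!is.null(outputDir))
        dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    logLines <- character(0)
    say <- function(fmt, ...) {
        msg <- sprintf(fmt, ...)
        logLines <<- c(logLines, msg)
        message(msg)
    }
    say("reconstruct: %d trees, %d taxa, %d character(s), %d quer%s",
        nTrees(treeSample), length(keep), length(characters),
        length(queries), if (length(queries) == 1L) "y" else "ies")
    out <- vector("list", length(characters))
    names(out) <- names(characters)
    for (nm in names(characters)) {
        col <- restrictColumn(characters[[nm]], keep)
        if (nObservedStates(col) < 2L)
            say("character %s: fewer than two observed states; %s",
                nm, "the posterior will follow the priors")
        chains <- vector("list", config@nRuns)
        for (r in seq_len(config@nRuns)) {
            cfg <- config
            cfg@seed <- config@seed + (r - 1L)
            chains[[r]] <- runChain(treeSample, col, cfg, priors)
            finalDev <- if (nrow(chains[[r]]@tuning))
                utils::tail(chains[[r]]@tuning$rateDev, 1L) else
                cfg@rateDev
            say("character %s run %d/%d: %d samples, %s %.2f, %s %.3g",
                nm, r, config@nRuns, nrow(samples(chains[[r]])),
                "within-model acceptance",
                withinModelAcceptance(chains[[r]]), "proposal deviation",
                finalDev)
        }
        agreement <- replicateAgreement(chains)
        say("character %s: replicate kappa means %s (max |z| = %.2f)",
            nm, paste(sprintf("%.3f", agreement$kappaMeans),
                      collapse = ", "), agreement$maxZ)
        pooled <- poolChains(chains)
        summ <- summarizeChain(pooled, treeSample, col, queries,
                               every = every)
        if (!is.null(outputDir)) {
            for (r in seq_along(chains))
                writeTrace(chains[[r]],
                           file.path(outputDir,
                                     sprintf("%s_run%d.trace.tsv", nm, r)))
            writeSummaryTable(summ,
                              file.path(outputDir,
                                        sprintf("%s_summary.tsv", nm)))
        }
        out[[nm]] <- list(summary = summ, chains = chains,
                          pooled = pooled, agreement = agreement)
    }
    if (!is.null(outputDir)) {
        writeLines(logLines, file.path(outputDir, "run.log"))
        writeLines(configEcho(config, priors, outgroup),
                   file.path(outputDir, "config_echo.txt"))
    }
    out
}

# keep only assignments for the retained taxa
restrictColumn <- function(column, keep) {
    a <- column@assignments[intersect(names(column@assignments), keep)]
    missing <- setdiff(keep, names(a))
    if (length(missing))
        a <- c(a, stats::setNames(rep(NA_integer_, length(missing)),
                                  missing))
    new("CharacterColumn", name = column@name,
        stateSpace = column@stateSpace, assignments = a[keep])
}

# replicate-run agreement on the kappa posterior mean, in MC-standard-
# error units (ESS-corrected)
replicateAgreement <- function(chains) {
    mns <- vapply(chains, function(ch) mean(ch@samples$kappa), numeric(1))
    ses <- vapply(chains, function(ch) {
        x <- ch@samples$kappa
        if (stats::var(x) == 0) return(0)
        stats::sd(x) / sqrt(essCalc(x))
    }, numeric(1))
    maxZ <- 0
    if (length(chains) > 1L) {
        for (i in seq_along(chains)[-1L]) for (j in seq_len(i - 1L)) {
            den <- sqrt(ses[i]^2 + ses[j]^2)
            if (den > 0)
                maxZ <- max(maxZ, abs(mns[i] - mns[j]) / den)
        }
    }
    list(kappaMeans = mns, kappaSEs = ses, maxZ = maxZ)
}

# fully resolved configuration echo for reproducibility
configEcho <- function(config, priors, outgroup) {
    c(sprintf("generations=%g", config@generations),
      sprintf("burnin=%g", config@burnin),
      sprintf("thin=%g", config@thin),
      sprintf("acceptance_band=%g-%g", config@targetLow,
              config@targetHigh),
      sprintf("initial_rate_deviation=%g", config@rateDev),
      sprintf("tune_interval=%g", config@tuneInterval),
      sprintf("move_weights=%s",
              paste(sprintf("%s:%g", names(config@moveWeights),
                            config@moveWeights), collapse = ",")),
      sprintf("root_prior=%s", config@rootPrior),
      sprintf("fix_kappa=%s", format(config@fixKappa)),
      sprintf("fix_m=%s", format(config@fixM)),
      sprintf("seed=%g", config@seed),
      sprintf("n_runs=%g", config@nRuns),
      sprintf("rate_prior=Exponential(mean m), m~Uniform(0,%g)",
              priors@hyperMax),
      sprintf("kappa_prior=Uniform(0,%g)", priors@kappaMax),
      sprintf("outgroup=%s", paste(outgroup, collapse = ",")))
}

#' Named run-length profiles
#'
#' \code{"desk"} is the package default (2e6 generations, 2e5 burn-in,
#' thinning 1000); \code{"paper"} carries the full-scale protocol of the
#' original analyses (220e6 generations, 20e6 burn-in, thinning 1000,
#' three replicate runs); \code{"test"} is a fast profile for examples
#' and unit tests.
#'
#' @param profile one of \code{"desk"}, \code{"paper"}, \code{"test"}.
#' @param ... slot overrides passed to the [RunConfig-class] constructor.
#' @return a [RunConfig-class].
#' @export
runConfigProfile <- function(profile = c("desk", "paper", "test"), ...) {
    profile <- match.arg(profile)
    base <- switch(profile,
        desk = list(generations = 2e6, burnin = 2e5, thin = 1000),
        paper = list(generations = 220e6, burnin = 20e6, thin = 1000),
        test = list(generations = 5e4, burnin = 1e4, thin = 20,
                    tuneInterval = 500))
    args <- utils::modifyList(base, list(...))
    do.call(new, c(list("RunConfig"), args))
}

#' File-driven reconstruction (command-line back end)
#'
#' Reads the engine's input formats (Newick list or NEXUS trees, a
#' delimited or NEXUS character matrix, a key=value query file), applies
#' optional outgroup pruning, and calls [reconstruct()].
#'
#' @param treesPath,charactersPath paths to tree sample and character
#'   matrix.
#' @param queriesPath optional query file ([readQueries()] format).
#' @param outgroup taxa to prune (character vector).
#' @param outputDir output directory (required).
#' @param config,priors as in [reconstruct()].
#' @param characterNames optional subset of characters to analyse.
#' @return the [reconstruct()] result, invisibly.
#' @export
cmdReconstruct <- function(treesPath, charactersPath, queriesPath = NULL,
                           outgroup = character(0), outputDir,
                           config = new("RunConfig"),
                           priors = new("PriorSpec"),
                           characterNames = NULL) {
    ts <- readTreeSample(treesPath)
    chars <- readCharacterMatrix(charactersPath)
    if (!is.null(characterNames)) chars <- chars[characterNames]
    queries <- if (!is.null(queriesPath)) readQueries(queriesPath)
               else list()
    invisible(reconstruct(ts, chars, queries, outgroup = outgroup,
                          config = config, priors = priors,
                          outputDir = outputDir))
}

#' Simulate a fixture bundle to disk (command-line back end)
#'
#' @param name fixture name, see [makeFixture()].
#' @param dir output directory.
#' @param seed RNG seed.
#' @return paths written, invisibly.
#' @export
cmdSimulate <- function(name, dir, seed = 1) {
    writeFixture(makeFixture(name, seed = seed), dir)
}
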