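#' Construct a simulation scenario
#'
#' @param nTaxa,nTrees,birthRate,treeDepth,jitterSd,nniProb,rates,kappa,rootDist,seed
#'   see [SimScenario-class].
#' @return a [SimScenario-class] object.
#' @export
simScenario <- function(nTaxa = 61, nTrees = 100, birthRate = 1,
                        treeDepth = 1, jitterSd = 0.1, nniProb = 0,
                        rates = c(q01 = 1, q10 = 1), kappa = 1,
                        rootDist = NULL, seed = 1) {
    if (is.null(rootDist)) {
        nr <- length(rates)
        k <- round((1 + sqrt(1 + 4 * nr)) / 2)
        rootDist <- rep(1 / k, k)
    }
    new("SimScenario", nTaxa = nTaxa, nTrees = nTrees,
        birthRate = birthRate, treeDepth = treeDepth, jitterSd = jitterSd,
        nniProb = nniProb, rates = rates, kappa = kappa,
        rootDist = rootDist, seed = seed)
}

# one focal Yule topology rescaled to the scenario's root-to-tip depth
yuleFocalTree <- function(scenario) {
    tr <- ape::rphylo(scenario@nTaxa, birth = scenario@birthRate,
                      death = 0)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * scenario@treeDepth / depth
    tr
}

#' Simulate an emulated posterior tree sample
#'
#' One focal Yule (pure-birth) tree is drawn and rescaled to the
#' scenario's root-to-tip depth; each sample member is the focal topology
#' with every branch length multiplied by independent lognormal jitter
#' (mean 1, sdlog \code{jitterSd}), and, with probability \code{nniProb},
#' one random NNI rearrangement -- mimicking the branch-length and
#' topological variation of a Bayesian posterior sample.
#'
#' @param scenario a [SimScenario-class].
#' @param focal optional \code{"phylo"} focal tree overriding the Yule
#'   draw (tip count may then differ from \code{scenario@nTaxa}).
#' @return a [TreeSample-class].
#' @export
simulateTreeSample <- function(scenario, focal = NULL) {
    validObject(scenario)
    set.seed(scenario@seed)
    if (is.null(focal)) focal <- yuleFocalTree(scenario)
    trs <- lapply(seq_len(scenario@nTrees), function(i) {
        tr <- focal
        if (scenario@nniProb > 0 &&
            stats::runif(1) < scenario@nniProb)
            tr <- phangorn::rNNI(tr, moves = 1)
        if (scenario@jitterSd > 0) {
            sd <- scenario@jitterSd
            tr$edge.length <- tr$edge.length *
                stats::rlnorm(length(tr$edge.length), -sd^2 / 2, sd)
        }
        tr
    })
    TreeSample(trs, provenance = sprintf(
        "simulated: %d-taxon Yule focal tree, jitter sdlog %g, NNI prob %g, seed %g",
        length(focal$tip.label), scenario@jitterSd, scenario@nniProb,
        scenario@seed))
}

#' Simulate a discrete character along a tree
#'
#' Draws the root state from \code{rootDist} and evolves it along every
#' branch of the kappa-transformed tree by sampling from the transition
#' matrix over the transformed branch length -- the generative twin of the
#' likelihood model.
#'
#' @param tree a \code{"phylo"} object.
#' @param rates off-diagonal rates as in [makeGenerator()].
#' @param kappa branch-length transform exponent.
#' @param rootDist probability vector over states.
#' @param name name for the resulting column.
#' @return a [CharacterColumn-class] with every tip observed.
#' @export
simulateCharacter <- function(tree, rates, kappa = 1,
                              rootDist = NULL, name = "sim") {
    stopifnot(inherits(tree, "phylo"))
    nr <- length(rates)
    k <- round((1 + sqrt(1 + 4 * nr)) / 2)
    if (is.null(rootDist)) rootDist <- rep(1 / k, k)
    stopifnot(length(rootDist) == k)
    tr <- kappaTransform(tree, kappa)
    po <- ape::reorder.phylo(tr, "postorder")
    ntip <- length(po$tip.label)
    nnodeTot <- ntip + po$Nnode
    stateOf <- integer(nnodeTot)
    root <- po$edge[nrow(po$edge), 1L]
    stateOf[root] <- sample.int(k, 1L, prob = rootDist)
    # walk edges root-to-tips (reverse postorder)
    uniqueLens <- unique(po$edge.length)
    Pcache <- lapply(uniqueLens, function(b) transitionMatrix(rates, b))
    lenIdx <- match(po$edge.length, uniqueLens)
    for (e in rev(seq_len(nrow(po$edge)))) {
        par <- po$edge[e, 1L]; chi <- po$edge[e, 2L]
        P <- Pcache[[lenIdx[e]]]
        stateOf[chi] <- sample.int(k, 1L, prob = P[stateOf[par], ])
    }
    codes <- stateOf[seq_len(ntip)] - 1L   # states coded 0 .. k-1
    CharacterColumn(name,
                    stats::setNames(codes, po$tip.label),
                    stateSpace = 0:(k - 1L))
}

# assemble a clade-structured focal tree from per-clade Yule subtrees
cladeFocalTree <- function(cladeSizes, prefixes, depth = 1,
                           outgroup = NULL) {
    subNewick <- function(n, prefix) {
        tr <- ape::rphylo(n, birth = 1, death = 0)
        tr$tip.label <- sprintf("%s_%02d", prefix, seq_len(n))
        d <- max(ape::node.depth.edgelength(tr))
        tr$edge.length <- tr$edge.length * (0.4 * depth) / d
        sub(";$", "", ape::write.tree(tr))
    }
    subs <- mapply(subNewick, cladeSizes, prefixes)
    # ((Morinda,(Coelospermum,Gynochthodes)), Appunia) backbone
    ingroup <- sprintf("((%s:0.15,(%s:0.1,%s:0.1):0.1):0.15,%s:0.3)",
                       subs[2L], subs[3L], subs[4L], subs[1L])
    txt <- if (is.null(outgroup))
        paste0(ingroup, ";")
    else sprintf("(%s:0.2,(%s:0.3,%s:0.3):0.2);", ingroup,
                 outgroup[1L], outgroup[2L])
    parseNewick(txt)
}

#' Build a named, reproducible test fixture
#'
#' Bundles a tree sample, character column(s), node queries, and a truth
#' record, under a fixed seed:
#' \describe{
#'   \item{"prior-only"}{all characters missing; the likelihood is
#'     identically 1, so the sampler must recover its priors.}
#'   \item{"symmetric"}{a binary character simulated with q01 = q10 = 1,
#'     kappa = 1.}
#'   \item{"asymmetric-ratio5"}{20 replicate binary characters simulated
#'     on a 60-tip jittered tree sample with q01/q10 = 5 (q01 = 2.5,
#'     q10 = 0.5) and kappa = 1, for parameter-recovery checks.}
#'   \item{"morindeae-like"}{a synthetic bundle shaped like the study
#'     system: 61 ingroup tips in four genus-like clades plus two
#'     outgroup taxa, four clade-biased characters (growth form,
#'     inflorescence architecture, flower size, fruit type), and seven
#'     MRCA queries named A-G plus the ingroup-outgroup root.}
#' }
#'
#' @param name one of \code{"symmetric"}, \code{"asymmetric-ratio5"},
#'   \code{"morindeae-like"}, \code{"prior-only"}.
#' @param seed RNG seed (default 1).
#' @return list with elements \code{treeSample}, \code{characters} (named
#'   list of [CharacterColumn-class]), \code{queries} (named list of
#'   taxon sets), \code{outgroup} (character vector, possibly empty) and
#'   \code{truth} (list of generating parameters).
#' @export
makeFixture <- function(name, seed = 1) {
    choices <- c("symmetric", "asymmetric-ratio5", "morindeae-like",
                 "prior-only")
    if (!name %in% choices)
        stop("unknown fixture '", name, "'; choices: ",
             paste(choices, collapse = ", "))
    if (name == "prior-only") {
        sc <- simScenario(nTaxa = 12, nTrees = 5, jitterSd = 0.1,
                          seed = seed)
        ts <- simulateTreeSample(sc)
        tips <- taxa(ts)
        col <- CharacterColumn("all_missing",
            stats::setNames(rep(NA_integer_, length(tips)), tips),
            stateSpace = 0:1)
        return(list(treeSample = ts, characters = list(all_missing = col),
                    queries = list(root = tips), outgroup = character(0),
                    truth = list()))
    }
    if (name == "symmetric") {
        sc <- simScenario(nTaxa = 32, nTrees = 20, jitterSd = 0.1,
                          rates = c(q01 = 1, q10 = 1), kappa = 1,
                          seed = seed)
        ts <- simulateTreeSample(sc)
        set.seed(seed + 1000L)
        col <- simulateCharacter(trees(ts)[[1L]], sc@rates, sc@kappa,
                                 name = "symmetric")
        return(list(treeSample = ts, characters = list(symmetric = col),
                    queries = list(root = taxa(ts)),
                    outgroup = character(0),
                    truth = list(rates = sc@rates, kappa = sc@kappa,
                                 ratio = 1)))
    }
    if (name == "asymmetric-ratio5") {
        sc <- simScenario(nTaxa = 60, nTrees = 30, jitterSd = 0.1,
                          rates = c(q01 = 2.5, q10 = 0.5), kappa = 1,
                          rootDist = c(q10 = 0.5 / 3, q01 = 2.5 / 3),
                          seed = seed)
        ts <- simulateTreeSample(sc)
        set.seed(seed + 1000L)
        cols <- lapply(seq_len(20L), function(i)
            simulateCharacter(trees(ts)[[1L]], sc@rates, sc@kappa,
                              rootDist = sc@rootDist,
                              name = sprintf("rep%02d", i)))
        names(cols) <- vapply(cols, function(x) x@name, character(1))
        return(list(treeSample = ts, characters = cols,
                    queries = list(root = taxa(ts)),
                    outgroup = character(0),
                    truth = list(rates = sc@rates, kappa = sc@kappa,
                                 ratio = 5)))
    }
    # morindeae-like: 61 ingroup tips in four clades + 2 outgroup taxa
    set.seed(seed)
    cladeSizes <- c(Appunia = 8L, Morinda = 12L, Coelospermum = 9L,
                    Gynochthodes = 32L)
    focal <- cladeFocalTree(cladeSizes, names(cladeSizes), depth = 1,
                            outgroup = c("Damnacanthus_sp:0.3",
                                         "Mitchella_sp:0.3"))
    # jittered sample around the focal topology
    sc <- simScenario(nTaxa = 63, nTrees = 50, jitterSd = 0.1,
                      seed = seed + 1L)
    ts <- simulateTreeSample(sc, focal = focal)
    tips <- taxa(ts)
    cladeOf <- function(genus) grep(paste0("^", genus, "_"), tips,
                                    value = TRUE)
    app <- cladeOf("Appunia"); mor <- cladeOf("Morinda")
    coe <- cladeOf("Coelospermum"); gyn <- cladeOf("Gynochthodes")
    og <- c("Damnacanthus_sp", "Mitchella_sp")
    assign0 <- function(vals) stats::setNames(as.integer(vals), tips)
    # clade-biased codings shaped like the study's character table:
    # growth: lianescent 0 / arborescent 1 / herbaceous 2 (outgroup only)
    growth <- assign0(rep(0L, length(tips)))
    growth[app] <- 1L
    growth[mor] <- c(rep(1L, 9L), rep(0L, 3L))
    growth[coe[1L]] <- 1L
    growth["Damnacanthus_sp"] <- 1L
    growth["Mitchella_sp"] <- 2L
    # inflorescence: headed 0 / non-headed 1
    infl <- assign0(rep(0L, length(tips)))
    infl[coe] <- c(rep(1L, 7L), 0L, 0L)
    infl[gyn[1:6]] <- 1L
    # flower size: large 0 / small 1
    flower <- assign0(rep(1L, length(tips)))
    flower[c(app, mor)] <- 0L
    flower["Damnacanthus_sp"] <- 0L
    # fruit: simple 0 / fused (multiple) 1
    fruit <- assign0(rep(1L, length(tips)))
    fruit[app] <- 0L
    fruit[coe] <- c(rep(0L, 7L), 1L, 1L)
    fruit[gyn[1:6]] <- 0L
    fruit[og] <- 0L
    chars <- list(
        growth_form = CharacterColumn("growth_form", growth,
                                      stateSpace = 0:2),
        inflorescence = CharacterColumn("inflorescence", infl, 0:1),
        flower_size = CharacterColumn("flower_size", flower, 0:1),
        fruit_type = CharacterColumn("fruit_type", fruit, 0:1))
    ingroup <- setdiff(tips, og)
    queries <- list(A = ingroup, B = c(mor, coe, gyn), C = c(coe, gyn),
                    D = app, E = mor, F = coe, G = gyn, root = tips)
    list(treeSample = ts, characters = chars, queries = queries,
         outgroup = og,
         truth = list(cladeSizes = cladeSizes,
                      note = "clade-biased synthetic codings"))
}

#' Write a fixture bundle to disk in the engine's input formats
#'
#' Newick list for the trees, a tab-separated character matrix, a plain
#' key=value query file (query name -> comma-separated taxa), and a
#' key=value truth record.
#'
#' @param fixture a bundle from [makeFixture()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeFixture <- function(fixture, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pTrees <- file.path(dir, "trees.nwk")
    pChars <- file.path(dir, "characters.tsv")
    pQueries <- file.path(dir, "queries.txt")
    pTruth <- file.path(dir, "truth.txt")
    writeTreeSample(fixture$treeSample, pTrees)
    writeCharacterMatrix(fixture$characters, pChars)
    writeLines(vapply(names(fixture$queries), function(qn)
        paste0(qn, "=", paste(fixture$queries[[qn]], collapse = ",")),
        character(1)), pQueries)
    tr <- fixture$truth
    writeLines(vapply(names(tr), function(nm)
        paste0(nm, "=", paste(format(tr[[nm]]), collapse = ",")),
        character(1)), pTruth)
    invisible(c(trees = pTrees, characters = pChars, queries = pQueries,
                truth = pTruth))
}

#' Read a query file written by [writeFixture()]
#'
#' @param path key=value file, one query per line.
#' @return named list of taxon sets.
#' @export
readQueries <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    out <- list()
    for (ln in lines) {
        kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
        out[[trimws(kv[1L])]] <- trimws(strsplit(kv[2L], ",")[[1L]])
    }
    out
}
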