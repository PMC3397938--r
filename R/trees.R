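#' Parse a single rooted tree from a Newick string
#'
#' Thin validating wrapper around \code{\link[ape]{read.tree}}.  The tree
#' is used as read (no re-rooting): downstream MRCA queries require the
#' root the sampler produced.  Polytomies, including a basal trichotomy,
#' are legal.  Branch lengths are mandatory and must be non-negative;
#' zero-length branches are allowed (the transition matrix at t = 0 is the
#' identity).
#'
#' @param text a Newick string, terminated by ";".
#' @return an object of class \code{"phylo"}.
#' @examples
#' tr <- parseNewick("((A:0.1,B:0.2):0.05,C:0.3);")
#' @export
parseNewick <- function(text) {
    stopifnot(is.character(text), length(text) == 1L)
    if (!grepl(";", text))
        stop("Newick string must end with ';'")
    n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
    n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
    if (n_open != n_close)
        stop(sprintf("unbalanced parentheses: %d '(' vs %d ')'",
                     n_open, n_close))
    tr <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tr)) {
        # single-tip degenerate tree, e.g. "(A:0.1);" -- ape refuses it
        m <- regmatches(text,
            regexec("^\\(\\s*([^():,;]+)\\s*:\\s*([-0-9.eE+]+)\\s*\\)\\s*;",
                    text))[[1L]]
        if (length(m) == 3L) {
            bl <- as.numeric(m[3L])
            if (is.na(bl) || bl < 0)
                stop(sprintf("negative or malformed branch length '%s'",
                             m[3L]))
            warning("degenerate single-tip tree")
            tr <- structure(list(
                edge = matrix(c(2L, 1L), 1L, 2L),
                edge.length = bl, tip.label = trimws(m[2L]),
                Nnode = 1L), class = "phylo")
            attr(tr, "order") <- "cladewise"
            return(tr)
        }
        stop("malformed Newick string")
    }
    validateTree(tr)
    if (length(tr$tip.label) < 2L)
        warning("degenerate single-tip tree")
    tr
}

# shared invariant checks for any tree entering the engine
validateTree <- function(tr) {
    if (anyDuplicated(tr$tip.label)) {
        dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
        stop(sprintf("duplicate tip label(s): %s",
                     paste(dup, collapse = ", ")))
    }
    if (is.null(tr$edge.length))
        stop("tree has no branch lengths")
    if (anyNA(tr$edge.length))
        stop("tree has missing branch lengths")
    if (any(tr$edge.length < 0)) {
        bad <- which(tr$edge.length < 0)[1L]
        stop(sprintf("negative branch length %g on edge to node %d",
                     tr$edge.length[bad], tr$edge[bad, 2L]))
    }
    invisible(tr)
}

#' Construct a TreeSample from a list of trees
#'
#' @param trees list of \code{"phylo"} objects over one taxon set.
#' @param provenance optional free-text provenance note.
#' @return a [TreeSample-class] object.
#' @export
TreeSample <- function(trees, provenance = NA_character_) {
    if (inherits(trees, "phylo")) trees <- list(trees)
    for (tr in trees) validateTree(tr)
    new("TreeSample", trees = trees,
        taxa = sort(trees[[1L]]$tip.label),
        provenance = as.character(provenance))
}

#' Read a posterior sample of trees
#'
#' Reads either a Newick list (one tree per line) or a NEXUS trees block
#' (case-insensitive keywords, optional translate table, square-bracket
#' comments stripped), preserving file order.  All trees must share one
#' taxon set; a mismatch is reported as the symmetric difference of the
#' offending tree's labels against the first tree's.
#'
#' @param path path to the tree file.
#' @param format \code{"newick-list"} or \code{"nexus"}; \code{"auto"}
#'   sniffs for a \code{#NEXUS} header.
#' @return a [TreeSample-class] object.
#' @seealso [writeTreeSample()]
#' @export
readTreeSample <- function(path, format = c("auto", "newick-list", "nexus")) {
    format <- match.arg(format)
    if (format == "auto") {
        first <- readLines(path, n = 1L, warn = FALSE)
        format <- if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE))
            "nexus" else "newick-list"
    }
    if (format == "nexus") {
        trs <- ape::read.nexus(path)
        if (inherits(trs, "phylo")) trs <- list(trs)
        else trs <- lapply(seq_along(trs), function(i) trs[[i]])
    } else {
        lines <- readLines(path, warn = FALSE)
        lines <- lines[nzchar(trimws(lines))]
        if (!length(lines)) stop("no trees found in ", path)
        trs <- lapply(lines, parseNewick)
    }
    for (tr in trs) validateTree(tr)
    TreeSample(trs, provenance = path)
}

#' Write a tree sample to disk
#'
#' @param x a [TreeSample-class] object.
#' @param path output path.
#' @param format \code{"newick-list"} (one tree per line) or
#'   \code{"nexus"} (trees block with translate table).
#' @export
writeTreeSample <- function(x, path, format = c("newick-list", "nexus")) {
    format <- match.arg(format)
    stopifnot(is(x, "TreeSample"))
    if (format == "nexus") {
        cls <- x@trees
        class(cls) <- "multiPhylo"
        ape::write.nexus(cls, file = path, translate = TRUE)
    } else {
        writeLines(vapply(x@trees, ape::write.tree, character(1)), path)
    }
    invisible(path)
}

#' Prune taxa from a rooted tree
#'
#' Removes the named tips and collapses the resulting degree-2 internal
#' nodes, summing the two incident branch lengths, so that path lengths
#' between every retained pair of tips are preserved.  Used to drop
#' outgroup taxa before the without-outgroup analyses.
#'
#' @param tree a \code{"phylo"} object.
#' @param drop character vector of tip labels to remove; must be a proper
#'   subset of the tree's tips.
#' @return the pruned \code{"phylo"} tree.
#' @export
pruneTaxa <- function(tree, drop) {
    stopifnot(inherits(tree, "phylo"))
    unknown <- setdiff(drop, tree$tip.label)
    if (length(unknown))
        stop(sprintf("unknown taxa: %s", paste(unknown, collapse = ", ")))
    if (length(drop) >= length(tree$tip.label))
        stop("cannot prune every taxon from the tree")
    ape::drop.tip(tree, drop, trim.internal = TRUE, collapse.singles = TRUE)
}

#' Prune taxa from every tree of a sample
#'
#' @param x a [TreeSample-class] object.
#' @param drop tip labels to remove from every member tree.
#' @return a new [TreeSample-class].
#' @export
pruneTreeSample <- function(x, drop) {
    stopifnot(is(x, "TreeSample"))
    TreeSample(lapply(x@trees, pruneTaxa, drop = drop),
               provenance = x@provenance)
}

#' Most recent common ancestor of a taxon set
#'
#' Returns the ape node id of the deepest node whose subtree contains all
#' taxa of \code{taxonSet}.  On a rooted tree the MRCA is always defined,
#' which is what lets a "node" be addressed consistently across a sample
#' of differing topologies.
#'
#' @param tree a \code{"phylo"} object.
#' @param taxonSet character vector of >= 2 tip labels.
#' @return integer node id (ape numbering).
#' @export
mrcaNode <- function(tree, taxonSet) {
    stopifnot(inherits(tree, "phylo"))
    if (length(taxonSet) < 2L)
        stop("taxonSet must contain at least two taxa")
    unknown <- setdiff(taxonSet, tree$tip.label)
    if (length(unknown))
        stop(sprintf("unknown taxa: %s", paste(unknown, collapse = ", ")))
    ape::getMRCA(tree, taxonSet)
}

#' Apply the kappa branch-length power transform
#'
#' Raises every branch length to the power kappa, leaving the topology
#' unchanged.  kappa = 1 leaves the tree as is (change proportional to
#' branch length); kappa = 0 makes all branches length 1 (change
#' independent of branch length, punctuational); 0^0 is defined as 1.
#'
#' @param tree a \code{"phylo"} object.
#' @param kappa non-negative finite exponent (prior support is (0, 5)).
#' @return the transformed \code{"phylo"} tree.
#' @export
kappaTransform <- function(tree, kappa) {
    stopifnot(inherits(tree, "phylo"))
    if (!is.finite(kappa) || kappa < 0)
        stop("kappa must be finite and >= 0")
    tree$edge.length <- ifelse(tree$edge.length == 0 & kappa == 0, 1,
                               tree$edge.length^kappa)
    tree
}
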