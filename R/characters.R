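#' Construct a CharacterColumn
#'
#' @param name character name.
#' @param assignments named integer vector (taxon -> code), \code{NA} for
#'   missing.
#' @param stateSpace ordered integer codes (state 0 first); inferred from
#'   the observed codes when \code{NULL}.
#' @return a [CharacterColumn-class] object.
#' @export
CharacterColumn <- function(name, assignments, stateSpace = NULL) {
    assignments <- vapply(assignments, function(x) {
        if (is.na(x)) NA_integer_ else as.integer(x)
    }, integer(1))
    if (is.null(stateSpace))
        stateSpace <- sort(unique(assignments[!is.na(assignments)]))
    new("CharacterColumn", name = as.character(name),
        stateSpace = as.integer(stateSpace), assignments = assignments)
}

#' Read a discrete character matrix
#'
#' Accepts a delimited table (first column taxon, remaining columns
#' characters, "?" or empty for missing) or a NEXUS characters/data block
#' (standard datatype, symbols "012...", missing "?").  Each character
#' becomes one [CharacterColumn-class].
#'
#' @param path path to the file.
#' @param stateSpaces optional list (by character name) of declared state
#'   spaces; codes outside a declared space are an error.  Characters not
#'   listed get their space inferred from the observed codes.  The state
#'   space is a per-run configuration: the same growth-form column is
#'   binary when outgroup taxa are pruned and three-state when the
#'   herbaceous outgroup taxon is retained.
#' @param sep field separator for delimited input; \code{NULL} sniffs
#'   tab-vs-comma.
#' @return named list of [CharacterColumn-class] objects.
#' @seealso [writeCharacterMatrix()]
#' @export
readCharacterMatrix <- function(path, stateSpaces = NULL, sep = NULL) {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE)) {
        dat <- ape::read.nexus.data(path)
        tab <- do.call(rbind, lapply(dat, function(x) unlist(x)))
        taxa <- rownames(tab)
        cols <- lapply(seq_len(ncol(tab)), function(j) {
            v <- tab[, j]
            v[v == "?"] <- NA
            stats::setNames(suppressWarnings(as.integer(v)), taxa)
        })
        names(cols) <- paste0("char", seq_along(cols))
    } else {
        if (is.null(sep))
            sep <- if (grepl("\t", first)) "\t" else ","
        df <- utils::read.table(path, header = TRUE, sep = sep,
                                stringsAsFactors = FALSE,
                                na.strings = c("?", "NA", ""),
                                check.names = FALSE,
                                colClasses = "character")
        if (ncol(df) < 2L)
            stop("character matrix needs a taxon column plus >= 1 character")
        taxa <- df[[1L]]
        dupRow <- which(duplicated(taxa))
        if (length(dupRow))
            stop(sprintf("taxon '%s' duplicated at row %d",
                         taxa[dupRow[1L]], dupRow[1L] + 1L))
        cols <- lapply(df[-1L], function(v) {
            out <- suppressWarnings(as.integer(v))
            bad <- which(!is.na(v) & is.na(out))
            if (length(bad))
                stop(sprintf("non-integer state code '%s' at row %d",
                             v[bad[1L]], bad[1L] + 1L))
            stats::setNames(out, taxa)
        })
    }
    out <- vector("list", length(cols))
    names(out) <- names(cols)
    for (nm in names(cols)) {
        ss <- stateSpaces[[nm]]
        if (!is.null(ss)) {
            obs <- cols[[nm]][!is.na(cols[[nm]])]
            bad <- setdiff(unique(obs), ss)
            if (length(bad))
                stop(sprintf(
                    "character '%s': code(s) %s outside declared state space {%s}",
                    nm, paste(bad, collapse = ","),
                    paste(ss, collapse = ",")))
        }
        out[[nm]] <- CharacterColumn(nm, cols[[nm]], stateSpace = ss)
    }
    out
}

#' Write character columns as a delimited matrix
#'
#' Round-trips losslessly through [readCharacterMatrix()], including
#' missing cells (written as "?").
#'
#' @param columns named list of [CharacterColumn-class] objects over one
#'   taxon set.
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
writeCharacterMatrix <- function(columns, path, sep = "\t") {
    taxa <- names(columns[[1L]]@assignments)
    df <- data.frame(taxon = taxa, check.names = FALSE,
                     stringsAsFactors = FALSE)
    for (cc in columns) {
        v <- as.character(cc@assignments[taxa])
        v[is.na(v)] <- "?"
        df[[cc@name]] <- v
    }
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Code flower size from corolla tube and lobe lengths
#'
#' Flowers are coded large (0) when corolla tube length / corolla lobe
#' length exceeds 1 and small (1) when the ratio is below 1.  A ratio of
#' exactly 1 is not covered by the rule and is returned as missing
#' (\code{NA}) with a warning.
#'
#' @param tubeLength corolla tube length in mm (> 0).
#' @param lobeLength corolla lobe length in mm (> 0).
#' @return integer code 0 (large), 1 (small), or \code{NA}.
#' @examples
#' codeRatioCharacter(23.5, 16)  # 0, large
#' codeRatioCharacter(3, 5)      # 1, small
#' @export
codeRatioCharacter <- function(tubeLength, lobeLength) {
    if (!is.finite(tubeLength) || !is.finite(lobeLength) ||
        tubeLength <= 0 || lobeLength <= 0)
        stop("tube and lobe lengths must be positive")
    r <- tubeLength / lobeLength
    if (r > 1) return(0L)
    if (r < 1) return(1L)
    warning("tube/lobe ratio exactly 1 is undefined; coded as missing")
    NA_integer_
}

#' Tip likelihood vectors for a character
#'
#' Converts a character column into the per-tip conditional-likelihood
#' boundary vectors of the pruning algorithm: an observed code c maps to
#' the unit vector at c, a missing code to the all-ones vector.  Taxa in
#' \code{taxaSet} that the column does not mention at all are treated as
#' missing, with a warning.
#'
#' @param column a [CharacterColumn-class].
#' @param taxaSet taxa (rows of the result), usually a tree's tip labels.
#' @return numeric matrix (length(taxaSet) x k) of 0/1 entries, rows named
#'   by taxon; every row has at least one 1.
#' @export
toPartials <- function(column, taxaSet) {
    stopifnot(is(column, "CharacterColumn"))
    k <- length(column@stateSpace)
    out <- matrix(1, nrow = length(taxaSet), ncol = k,
                  dimnames = list(taxaSet, as.character(column@stateSpace)))
    absent <- setdiff(taxaSet, names(column@assignments))
    if (length(absent))
        warning(sprintf("taxa absent from character '%s', treated as missing: %s",
                        column@name, paste(absent, collapse = ", ")))
    for (tx in intersect(taxaSet, names(column@assignments))) {
        code <- column@assignments[[tx]]
        if (!is.na(code)) {
            row <- numeric(k)
            row[match(code, column@stateSpace)] <- 1
            out[tx, ] <- row
        }
    }
    out
}

# count of distinct observed states; inference needs >= 2
nObservedStates <- function(column) {
    length(unique(column@assignments[!is.na(column@assignments)]))
}
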