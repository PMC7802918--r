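#' @include AllClasses.R
NULL

#' Parse gene-tree tip labels into species / gene / transcript identities
#'
#' Tip labels are expected to pack the three identity fields into one string
#' with a fixed separator, by default \code{"species@gene@transcript"}. The
#' field order is configurable because different pipelines order the fields
#' differently; no label format is standard in the field.
#'
#' @param labels character vector of tip labels.
#' @param sep single-character field separator (default \code{"@"}).
#' @param fields character vector naming the field order; a permutation of
#'   \code{c("species", "gene", "transcript")}.
#' @return data.frame with columns label, species, gene, transcript.
#' @examples
#' parseTipLabels(c("Hydra@g1@t1", "Nanomia@g2@t9"))
#' @export
parseTipLabels <- function(labels, sep = "@",
                           fields = c("species", "gene", "transcript")) {
    if (!setequal(fields, c("species", "gene", "transcript")))
        stop("'fields' must be a permutation of species, gene, transcript")
    parts <- strsplit(labels, sep, fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 3L))
        stop(sprintf("tip label not parseable as %s: '%s'",
                     paste(fields, collapse = sep), labels[which(nf != 3L)[1L]]))
    m <- do.call(rbind, parts)
    colnames(m) <- fields
    data.frame(label = labels, species = m[, "species"], gene = m[, "gene"],
               transcript = m[, "transcript"], stringsAsFactors = FALSE)
}

#' Construct a GeneTree from an ape phylo
#'
#' @param tree a rooted \code{ape::phylo} with branch lengths.
#' @param id family identifier.
#' @param sep,fields tip-label convention, see [parseTipLabels()].
#' @param midpointRoot if TRUE, unrooted input is midpoint-rooted (via
#'   \pkg{phangorn}) instead of rejected.
#' @return a [GeneTree-class].
#' @export
GeneTree <- function(tree, id = "G1", sep = "@",
                     fields = c("species", "gene", "transcript"),
                     midpointRoot = FALSE) {
    if (!inherits(tree, "phylo")) stop("'tree' must be an ape 'phylo'")
    if (is.null(tree$edge.length))
        stop(sprintf("tree '%s' has no branch lengths", id))
    if (!ape::is.rooted(tree)) {
        if (!midpointRoot)
            stop(sprintf(
                "tree '%s' is unrooted; re-root it or pass midpointRoot = TRUE", id))
        if (!requireNamespace("phangorn", quietly = TRUE))
            stop("midpoint rooting requires the 'phangorn' package")
        tree <- phangorn::midpoint(tree)
    }
    methods::new("GeneTree", id = id, tree = tree,
                 tipInfo = parseTipLabels(tree$tip.label, sep, fields))
}

#' Read Newick gene trees with identity-parsed tips
#'
#' Reads one or more Newick trees (one per line or concatenated) and parses
#' every tip label into a (species, gene, transcript) identity. Branch
#' lengths must be present: the subtree-length statistic that drives
#' flagging is meaningless without them. Unrooted trees are rejected unless
#' \code{midpointRoot = TRUE}.
#'
#' @param path file containing >= 1 Newick tree.
#' @param sep,fields tip-label convention, see [parseTipLabels()].
#' @param midpointRoot midpoint-root unrooted input instead of erroring.
#' @param ids optional character vector of family identifiers; defaults to
#'   names stored in the file, else \code{"G1"}, \code{"G2"}, ...
#' @return list of [GeneTree-class] (empty, with a warning, for an empty file).
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((Hydra@g1@t1:0.1,Hydra@g2@t2:0.2):0.3,Nanomia@g1@t9:0.4);", tf)
#' readGeneTrees(tf)
#' @export
readGeneTrees <- function(path, sep = "@",
                          fields = c("species", "gene", "transcript"),
                          midpointRoot = FALSE, ids = NULL) {
    txt <- readLines(path, warn = FALSE)
    if (!any(nzchar(trimws(txt)))) {
        warning(sprintf("no trees in '%s'; returning an empty list", path))
        return(list())
    }
    trees <- tryCatch(ape::read.tree(path),
                      error = function(e) stop(sprintf(
                          "malformed Newick in '%s': %s", path, conditionMessage(e))))
    if (inherits(trees, "phylo")) trees <- list(trees)
    if (is.null(ids)) {
        ids <- names(trees)
        if (is.null(ids) || !all(nzchar(ids)))
            ids <- sprintf("G%d", seq_along(trees))
    }
    if (length(ids) != length(trees))
        stop("'ids' must have one identifier per tree")
    out <- vector("list", length(trees))
    for (k in seq_along(trees)) {
        out[[k]] <- tryCatch(
            GeneTree(trees[[k]], id = ids[k], sep = sep, fields = fields,
                     midpointRoot = midpointRoot),
            error = function(e) stop(sprintf(
                "tree %d ('%s'): %s", k, ids[k], conditionMessage(e))))
    }
    out
}

#' Write gene trees to a Newick file
#'
#' One tree per line, branch lengths at full precision (so that a
#' read/write/read cycle preserves topology and lengths).
#'
#' @param trees list of [GeneTree-class].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeGeneTrees <- function(trees, path) {
    txt <- vapply(trees, function(g) ape::write.tree(phyloTree(g), digits = 15),
                  character(1))
    writeLines(txt, path)
    invisible(path)
}

#' Construct a TranscriptCatalog
#'
#' @param transcript,gene,species character vectors, one entry per transcript.
#' @param length optional numeric transcript lengths (nt); NA when unknown.
#' @return a [TranscriptCatalog-class].
#' @export
TranscriptCatalog <- function(transcript, gene, species,
                              length = rep(NA_real_, base::length(transcript))) {
    methods::new("TranscriptCatalog", table = data.frame(
        transcript = as.character(transcript), gene = as.character(gene),
        species = as.character(species), length = as.numeric(length),
        stringsAsFactors = FALSE))
}

#' Read a transcript catalog from a TSV file
#'
#' Expects a header with columns \code{transcript}, \code{gene},
#' \code{species} and optionally \code{length}. Duplicate transcript ids or
#' a gene mapped to two species are rejected (catalog invariants).
#'
#' @param path TSV file path.
#' @return a [TranscriptCatalog-class].
#' @export
readCatalog <- function(path) {
    tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("transcript", "gene", "species")
    if (!all(need %in% names(tb)))
        stop(sprintf("catalog '%s' must have header columns %s", path,
                     paste(need, collapse = ", ")))
    len <- if ("length" %in% names(tb)) as.numeric(tb$length) else
        rep(NA_real_, nrow(tb))
    TranscriptCatalog(tb$transcript, tb$gene, tb$species, len)
}

#' Write a transcript catalog to a TSV file
#'
#' Rows are sorted by (species, gene, transcript) so output is deterministic
#' and independent of input row order. The length column is written only if
#' any length is known.
#'
#' @param catalog a [TranscriptCatalog-class].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeCatalog <- function(catalog, path) {
    stopifnot(methods::is(catalog, "TranscriptCatalog"))
    tb <- catalogTable(catalog)
    tb <- tb[order(tb$species, tb$gene, tb$transcript), , drop = FALSE]
    if (all(is.na(tb$length))) tb$length <- NULL
    utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Fill catalog transcript lengths from a FASTA file
#'
#' Sequence names must match transcript ids; lengths (in nt) are taken from
#' the sequences. Transcripts absent from the FASTA keep their current value.
#'
#' @param catalog a [TranscriptCatalog-class].
#' @param fasta path to a FASTA of transcript sequences.
#' @return the catalog with updated lengths.
#' @export
addLengthsFromFasta <- function(catalog, fasta) {
    seqs <- ape::read.FASTA(fasta)
    nm <- sub("\\s.*$", "", names(seqs))
    tb <- catalogTable(catalog)
    hit <- match(tb$transcript, nm)
    tb$length[!is.na(hit)] <- lengths(seqs)[hit[!is.na(hit)]]
    TranscriptCatalog(tb$transcript, tb$gene, tb$species, tb$length)
}
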