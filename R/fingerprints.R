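# Electrotopological-state (E-state) atom-type fingerprints, path-based
# fingerprints, Tanimoto similarity and hierarchical clustering.
#
# The E-state scheme assigns every atom to one of 79 published
# electrotopological atom types. Each type name encodes the atom's
# environment exactly -- bond pattern (s single, d double, t triple,
# a aromatic), element, and attached hydrogen count (e.g. "aaCH" is an
# aromatic CH, "ddssS" a sulfone-type sulfur) -- so the matching SMARTS is
# generated mechanically from the name: element + total-H + heavy-atom
# degree + one bond branch per letter. Atoms fitting no type (bare metals,
# charged atoms outside the table such as a sulfonate O-) contribute to no
# feature, as in the published scheme.

.esTypeNames <- c(
  "sLi", "ssBe", "ssssBe", "ssBH", "sssB", "ssssB", "sCH3", "dCH2",
  "ssCH2", "tCH", "dsCH", "aaCH", "sssCH", "ddC", "tsC", "dssC", "aasC",
  "aaaC", "ssssC", "sNH3", "sNH2", "ssNH2", "dNH", "ssNH", "aaNH", "tN",
  "sssNH", "dsN", "aaN", "sssN", "ddsN", "aasN", "ssssN", "sOH", "dO",
  "ssO", "aaO", "sF", "sSiH3", "ssSiH2", "sssSiH", "ssssSi", "sPH2",
  "ssPH", "sssP", "dsssP", "sssssP", "sSH", "dS", "ssS", "aaS", "dssS",
  "ddssS", "sCl", "sGeH3", "ssGeH2", "sssGeH", "ssssGe", "sAsH2",
  "ssAsH", "sssAs", "sssdAs", "sssssAs", "sSeH", "dSe", "ssSe", "aaSe",
  "dssSe", "ddssSe", "sBr", "sSnH3", "ssSnH2", "sssSnH", "ssssSn", "sI",
  "sPbH3", "ssPbH2", "sssPbH", "ssssPb")

.esAtomicNumber <- c(Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9,
                     Si = 14, P = 15, S = 16, Cl = 17, Ge = 32, As = 33,
                     Se = 34, Br = 35, Sn = 50, I = 53, Pb = 82)

.esBondSymbol <- c(s = "-", d = "=", t = "#", a = ":")

# Decompose a type name into (bond letters, element, H count) and emit the
# SMARTS that matches exactly that atom environment.
.esTypeSmarts <- function(typeName) {
  m <- regmatches(typeName,
                  regexec("^([sdta]+)([A-Z][a-z]?)(H([0-9]?))?$",
                          typeName))[[1]]
  if (length(m) == 0) stop("malformed E-state type name: ", typeName)
  bonds <- strsplit(m[2], "")[[1]]
  elem <- m[3]
  nH <- if (!nzchar(m[4])) 0L else if (nzchar(m[5])) as.integer(m[5]) else 1L
  z <- .esAtomicNumber[[elem]]
  atom <- sprintf("[#%d;H%d;D%d]", z, nH, length(bonds))
  sym <- .esBondSymbol[bonds]
  branches <- if (length(sym) > 1)
    paste0("(", sym[-length(sym)], "*)", collapse = "") else ""
  paste0(atom, branches, sym[length(sym)], "*")
}

.esSmartsTable <- function() {
  vapply(.esTypeNames, .esTypeSmarts, character(1))
}

#' E-state atom-type fingerprints
#'
#' Counts, for every compound, the atoms falling into each of the 79
#' electrotopological-state atom types, giving a fixed-length 79-feature
#' fingerprint. By default the counts are binarized at > 0, the form used
#' for Tanimoto similarity and clustering; set \code{binary = FALSE} to
#' keep raw counts.
#'
#' @param library a \linkS4class{CompoundLibrary} or character vector of
#'   SMILES.
#' @param binary binarize counts at > 0.
#' @param stripSalts strip each structure to its largest covalent
#'   component first. Defaults to \code{FALSE}: similarity and clustering
#'   profile the compound as a whole (counter-ion features included), which
#'   is also how marketed salt-form drugs are listed in a library.
#' @return a \linkS4class{FingerprintSet} (scheme \code{"estate"}).
#' @examples
#' fp <- eStateFingerprint(compoundLibrary("tra", "NCCCS(=O)(=O)O"))
#' sum(fingerprintValues(fp))
#' @export
eStateFingerprint <- function(library, binary = TRUE, stripSalts = FALSE) {
  if (is.character(library))
    library <- compoundLibrary(sprintf("mol%d", seq_along(library)),
                               library)
  stopifnot(is(library, "CompoundLibrary"))
  smi <- if (stripSalts) stripSalts(library@smiles) else library@smiles
  counts <- .smartsCountMatrix(smi, .esSmartsTable())
  vals <- matrix(as.numeric(counts), nrow = nrow(counts),
                 dimnames = list(library@id, .esTypeNames))
  if (binary) vals <- (vals > 0) + 0
  new("FingerprintSet", scheme = "estate", values = vals, binary = binary)
}

#' Path-based fingerprints
#'
#' Linear-fragment (path) hashed fingerprints of length 1024 from
#' OpenBabel, as a binary alternative to the E-state scheme.
#'
#' @inheritParams eStateFingerprint
#' @return a \linkS4class{FingerprintSet} (scheme \code{"path"}).
#' @export
pathFingerprint <- function(library, stripSalts = FALSE) {
  if (is.character(library))
    library <- compoundLibrary(sprintf("mol%d", seq_along(library)),
                               library)
  stopifnot(is(library, "CompoundLibrary"))
  smi <- if (stripSalts) stripSalts(library@smiles) else library@smiles
  vals <- .obPathFingerprint(smi)
  rownames(vals) <- library@id
  new("FingerprintSet", scheme = "path", values = vals + 0, binary = TRUE)
}

#' @rdname FingerprintSet-class
#' @export
setMethod("fingerprintScheme", "FingerprintSet",
          function(object) object@scheme)

#' @rdname FingerprintSet-class
#' @export
setMethod("fingerprintValues", "FingerprintSet",
          function(object) object@values)

#' @rdname FingerprintSet-class
#' @export
setMethod("length", "FingerprintSet", function(x) nrow(x@values))

setMethod("show", "FingerprintSet", function(object) {
  cat(sprintf("FingerprintSet: %d compound(s), scheme '%s' (%d features%s)\n",
              nrow(object@values), object@scheme, ncol(object@values),
              if (object@binary) ", binary" else ", counts"))
})

#' Tanimoto similarity of two fingerprints
#'
#' For binary fingerprints the classic set form intersection / union; for
#' count fingerprints the min/max generalization. Two all-zero
#' fingerprints have no defined overlap; their similarity is returned as 0
#' with a warning.
#'
#' @param a,b numeric fingerprint vectors of equal length, or two
#'   \linkS4class{FingerprintSet}s of length 1 (schemes must agree).
#' @return similarity in [0, 1].
#' @examples
#' tanimoto(c(1, 1, 0), c(1, 0, 1))
#' @export
tanimoto <- function(a, b) {
  if (is(a, "FingerprintSet") || is(b, "FingerprintSet")) {
    stopifnot(is(a, "FingerprintSet"), is(b, "FingerprintSet"))
    if (a@scheme != b@scheme)
      stop("fingerprint scheme mismatch: '", a@scheme, "' vs '", b@scheme,
           "'", call. = FALSE)
    stopifnot(nrow(a@values) == 1, nrow(b@values) == 1)
    return(tanimoto(as.vector(a@values), as.vector(b@values)))
  }
  if (length(a) != length(b))
    stop("fingerprint length mismatch", call. = FALSE)
  if (any(a < 0) || any(b < 0))
    stop("fingerprint values must be non-negative", call. = FALSE)
  denom <- sum(pmax(a, b))
  if (denom == 0) {
    warning("both fingerprints are all-zero; similarity defined as 0")
    return(0)
  }
  sum(pmin(a, b)) / denom
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param fps a \linkS4class{FingerprintSet}.
#' @return a \linkS4class{SimilarityMatrix} over the fingerprinted
#'   compounds.
#' @export
tanimotoMatrix <- function(fps) {
  stopifnot(is(fps, "FingerprintSet"))
  v <- fps@values
  n <- nrow(v)
  out <- matrix(1, n, n, dimnames = list(rownames(v), rownames(v)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        out[i, j] <- out[j, i] <-
          suppressWarnings(tanimoto(v[i, ], v[j, ]))
      }
    }
  }
  new("SimilarityMatrix", ids = rownames(v), values = out)
}

#' @rdname SimilarityMatrix-class
#' @export
setMethod("similarityValues", "SimilarityMatrix",
          function(object) object@values)

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix over %d compound(s)\n",
              length(object@ids)))
  if (length(object@ids) > 1) {
    off <- object@values[upper.tri(object@values)]
    cat(sprintf("  off-diagonal Tanimoto: min %.3f, median %.3f, max %.3f\n",
                min(off), stats::median(off), max(off)))
  }
})

#' Tanimoto similarity of each library compound to a reference
#'
#' Fingerprints the library and the reference under one scheme and returns
#' the per-compound Tanimoto index, e.g. similarity of every hit to the
#' bare scaffold. The reference against itself scores 1.
#'
#' @param library a \linkS4class{CompoundLibrary}.
#' @param reference a single reference SMILES (default: the
#'   propane-1-sulfonic acid scaffold of tramiprosate).
#' @param scheme fingerprint scheme.
#' @param stripSalts passed to the fingerprint computation.
#' @return data.frame with columns \code{id, tanimoto}.
#' @export
similarityToReference <- function(library, reference = "CCCS(=O)(=O)O",
                                  scheme = c("estate", "path"),
                                  stripSalts = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(is(library, "CompoundLibrary"))
  if (length(library) == 0)
    return(data.frame(id = character(), tanimoto = numeric()))
  fpFun <- if (scheme == "estate") eStateFingerprint else pathFingerprint
  refLib <- compoundLibrary("__reference__", reference)
  fps <- fpFun(library, stripSalts = stripSalts)
  refFp <- as.vector(fingerprintValues(fpFun(refLib,
                                             stripSalts = stripSalts)))
  tv <- apply(fps@values, 1, function(row)
    suppressWarnings(tanimoto(row, refFp)))
  data.frame(id = library@id, tanimoto = as.numeric(tv),
             stringsAsFactors = FALSE)
}

#' Agglomerative clustering of a similarity matrix
#'
#' Hierarchical (agglomerative) clustering on Tanimoto distance
#' \code{1 - T}, cut into \code{k} groups. Average linkage is the default
#' for chemical similarity trees; the merge order of
#' \code{\link[stats]{hclust}} is deterministic, ties resolved by lowest
#' pair index.
#'
#' @param similarity a \linkS4class{SimilarityMatrix}.
#' @param k number of groups to cut into (1 <= k <= n).
#' @param linkage agglomeration method.
#' @return a \linkS4class{ClusterTree}.
#' @examples
#' fp <- eStateFingerprint(compoundLibrary(
#'   c("a", "b", "c"), c("CCO", "CCCO", "c1ccccc1")))
#' hierarchicalCluster(tanimotoMatrix(fp), k = 2)
#' @export
hierarchicalCluster <- function(similarity, k,
                                linkage = c("average", "complete",
                                            "single")) {
  linkage <- match.arg(linkage)
  stopifnot(is(similarity, "SimilarityMatrix"))
  n <- length(similarity@ids)
  k <- as.integer(k)
  if (k < 1 || k > n)
    stop("k must lie between 1 and the number of compounds (", n, ")",
         call. = FALSE)
  d <- stats::as.dist(1 - similarity@values)
  hc <- stats::hclust(d, method = linkage)
  assign <- stats::cutree(hc, k = k)
  new("ClusterTree", hclust = hc, k = k,
      assignments = stats::setNames(as.integer(assign), similarity@ids),
      linkage = linkage)
}

#' @rdname ClusterTree-class
#' @export
setMethod("clusterAssignments", "ClusterTree",
          function(object) object@assignments)

setMethod("show", "ClusterTree", function(object) {
  cat(sprintf("ClusterTree: %d leaves, %s linkage, cut into %d group(s)\n",
              length(object@assignments), object@linkage, object@k))
  print(table(group = object@assignments))
})

#' Export a cluster tree as a Newick string
#'
#' @param tree a \linkS4class{ClusterTree}.
#' @return a Newick string with the compound ids as leaf labels.
#' @export
treeNewick <- function(tree) {
  stopifnot(is(tree, "ClusterTree"))
  phy <- ape::as.phylo(tree@hclust)
  ape::write.tree(phy)
}

#' Write a similarity matrix as long-format CSV
#'
#' @param similarity a \linkS4class{SimilarityMatrix}.
#' @param path output CSV path (columns \code{id_a,id_b,tanimoto}).
#' @return the long table, invisibly.
#' @export
writeSimilarity <- function(similarity, path) {
  stopifnot(is(similarity, "SimilarityMatrix"))
  ids <- similarity@ids
  idx <- which(upper.tri(similarity@values, diag = TRUE), arr.ind = TRUE)
  out <- data.frame(id_a = ids[idx[, 1]], id_b = ids[idx[, 2]],
                    tanimoto = similarity@values[idx],
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
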