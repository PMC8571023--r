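#' Construct a compound library
#'
#' Builds a validated \linkS4class{CompoundLibrary} from parallel vectors.
#' Every SMILES must parse to a molecular graph with at least one heavy
#' atom; duplicate ids are an error.
#'
#' @param id character vector of unique compound identifiers.
#' @param smiles character vector of SMILES strings.
#' @param name optional display names; defaults to \code{id}.
#' @param source provenance tag.
#' @param metadata optional list of annotations.
#' @param check validate that every SMILES parses (set \code{FALSE} only
#'   for inputs already validated upstream).
#' @return a \code{CompoundLibrary}.
#' @examples
#' lib <- compoundLibrary(c("a", "b"), c("CCO", "c1ccccc1"))
#' length(lib)
#' @export
compoundLibrary <- function(id, smiles, name = id, source = NA_character_,
                            metadata = list(), check = TRUE) {
  id <- as.character(id)
  smiles <- as.character(smiles)
  name <- as.character(name)
  if (check) {
    ok <- .isParseableSmiles(smiles)
    if (!all(ok))
      stop("unparseable SMILES for id(s): ",
           paste(id[!ok], collapse = ", "), call. = FALSE)
  }
  new("CompoundLibrary", id = id, name = name, smiles = smiles,
      source = source, metadata = metadata)
}

#' @rdname CompoundLibrary-class
#' @export
setMethod("compoundIds", "CompoundLibrary", function(object) object@id)

#' @rdname CompoundLibrary-class
#' @export
setMethod("compoundNames", "CompoundLibrary", function(object) object@name)

#' @rdname CompoundLibrary-class
#' @export
setMethod("compoundSmiles", "CompoundLibrary",
          function(object) stats::setNames(object@smiles, object@id))

#' @rdname CompoundLibrary-class
#' @export
setMethod("librarySource", "CompoundLibrary", function(object) object@source)

#' @rdname CompoundLibrary-class
#' @export
setMethod("length", "CompoundLibrary", function(x) length(x@id))

#' @rdname CompoundLibrary-class
#' @param i index vector (integer, logical, or compound ids).
#' @param j,drop,... ignored.
#' @export
setMethod("[", "CompoundLibrary", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(i, x@id)
    if (anyNA(idx))
      stop("unknown compound id(s): ", paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  initialize(x, id = x@id[i], name = x@name[i], smiles = x@smiles[i])
})

setMethod("show", "CompoundLibrary", function(object) {
  cat(sprintf("CompoundLibrary with %d compound(s)\n", length(object)))
  if (!is.na(object@source)) cat("  source:", object@source, "\n")
  n <- min(length(object), 5L)
  if (n > 0) {
    for (k in seq_len(n))
      cat(sprintf("  %s  %s  %s\n", object@id[k], object@name[k],
                  object@smiles[k]))
    if (length(object) > n) cat("  ...\n")
  }
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' @rdname CompoundLibrary-class
#' @param row.names,optional passed through to the data.frame method.
#' @export
setMethod("as.data.frame", "CompoundLibrary",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(id = x@id, name = x@name, smiles = x@smiles,
               row.names = row.names, stringsAsFactors = FALSE)
  })

#' Read a compound library from disk
#'
#' Reads a drug library in one of three dialects: \code{.smi} (one
#' \code{SMILES<whitespace>name} per line; the name is optional), SDF
#' (V2000; the molecule title line provides the id), or CSV (mandatory
#' header with required columns \code{id,smiles} and optional \code{name}).
#' Unparseable entries are skipped and counted (reported via a message and
#' in \code{metadata(library)$skipped}); a file that yields zero parseable
#' records is an error.
#'
#' @param path input file.
#' @param format one of \code{"smi"}, \code{"sdf"}, \code{"csv"}; guessed
#'   from the file extension when omitted.
#' @return a \linkS4class{CompoundLibrary}.
#' @examples
#' smi <- tempfile(fileext = ".smi")
#' writeLines(c("CCO ethanol", "c1ccccc1 benzene"), smi)
#' lib <- readLibrary(smi)
#' compoundIds(lib)
#' @export
readLibrary <- function(path, format = c("auto", "smi", "sdf", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, smi = "smi", sdf = "sdf", csv = "csv",
      stop("cannot guess library format from extension '", ext,
           "'; pass format=", call. = FALSE))
  }
  raw <- switch(format,
    smi = .readSmiEntries(path),
    sdf = .readSdfEntries(path),
    csv = .readCsvEntries(path))
  if (nrow(raw) == 0)
    stop("zero parseable records in ", path, call. = FALSE)
  ok <- .isParseableSmiles(raw$smiles)
  skipped <- sum(!ok) + attr(raw, "preSkipped", exact = TRUE) %||% 0L
  raw <- raw[ok, , drop = FALSE]
  if (nrow(raw) == 0)
    stop("zero parseable records in ", path, call. = FALSE)
  if (skipped > 0)
    message(sprintf("readLibrary: skipped %d unparseable record(s)", skipped))
  compoundLibrary(raw$id, raw$smiles, raw$name, source = path,
                  metadata = list(skipped = as.integer(skipped)),
                  check = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.readSmiEntries <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(id = character(), name = character(),
                      smiles = character()))
  smiles <- sub("[ \t].*$", "", lines)
  name <- trimws(sub("^[^ \t]+", "", lines))
  fallback <- sprintf("mol%d", seq_along(lines))
  name <- ifelse(nzchar(name), name, fallback)
  id <- if (anyDuplicated(name)) fallback else name
  data.frame(id = id, name = name, smiles = smiles,
             stringsAsFactors = FALSE)
}

.readSdfEntries <- function(path) {
  sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                     error = function(e) NULL)
  if (is.null(sdfset) || length(sdfset) == 0)
    return(data.frame(id = character(), name = character(),
                      smiles = character()))
  valid <- ChemmineR::validSDF(sdfset)
  pre <- sum(!valid)
  sdfset <- sdfset[valid]
  smiles <- vapply(seq_along(sdfset), function(k) {
    tryCatch(as.character(ChemmineR::sdf2smiles(sdfset[k])),
             error = function(e) NA_character_)
  }, character(1))
  title <- vapply(seq_along(sdfset), function(k)
    trimws(ChemmineR::header(sdfset[[k]])[["Molecule_Name"]]), character(1))
  fallback <- sprintf("mol%d", seq_along(smiles))
  title <- ifelse(nzchar(title), title, fallback)
  id <- if (anyDuplicated(title)) fallback else title
  out <- data.frame(id = id, name = title, smiles = smiles,
                    stringsAsFactors = FALSE)
  drop <- is.na(out$smiles)
  structure(out[!drop, , drop = FALSE],
            preSkipped = pre + sum(drop))
}

.readCsvEntries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  need <- c("id", "smiles")
  if (!all(need %in% names(df)))
    stop("CSV library requires columns 'id' and 'smiles'", call. = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicate compound ids in ", path, call. = FALSE)
  name <- if ("name" %in% names(df)) df$name else df$id
  data.frame(id = as.character(df$id), name = as.character(name),
             smiles = as.character(df$smiles), stringsAsFactors = FALSE)
}

#' Strip salts and counter-ions from SMILES
#'
#' Keeps the largest covalently connected component of each structure,
#' measured in heavy atoms (ties keep the first component as written).
#' Monatomic counter-ions such as \code{[Na+]} are thereby removed. The
#' operation is idempotent and returns single-component input unchanged.
#'
#' @param smiles character vector of SMILES (dot-separated components).
#' @return character vector of the retained components.
#' @examples
#' stripSalts("CCCS(=O)(=O)[O-].[Na+]")
#' @export
stripSalts <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !grepl(".", s, fixed = TRUE)) return(s)
    parts <- strsplit(s, ".", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) <= 1) return(parts[1] %||% s)
    counts <- .heavyAtomCount(parts)
    counts[is.na(counts)] <- -1L
    parts[which.max(counts)]
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname stripSalts
#' @param library a \linkS4class{CompoundLibrary}.
#' @return \code{stripSaltsLibrary}: the library with each structure
#'   replaced by its largest component.
#' @export
stripSaltsLibrary <- function(library) {
  stopifnot(is(library, "CompoundLibrary"))
  initialize(library, smiles = stripSalts(library@smiles))
}

#' Scaffold substructure queries
#'
#' \code{scaffoldQuery} builds a validated \linkS4class{ScaffoldQuery}: the
#' SMARTS pattern must compile and match its own reference structure,
#' otherwise a configuration error is raised. \code{defaultScaffoldQuery}
#' returns the propane-1-sulfonic acid core of tramiprosate
#' (3-aminopropanesulfonic acid), written to match both the protonated and
#' the anionic sulfonate form, which is the query that defines the
#' repurposing hit set.
#'
#' @param name query label.
#' @param pattern SMARTS substructure pattern.
#' @param reference SMILES the pattern must match (self-match check).
#' @return a \code{ScaffoldQuery}.
#' @examples
#' q <- defaultScaffoldQuery()
#' q
#' @export
scaffoldQuery <- function(name, pattern,
                          reference = "NCCCS(=O)(=O)O") {
  q <- new("ScaffoldQuery", name = name, pattern = pattern,
           reference = reference)
  if (!.isParseableSmiles(reference))
    stop("reference SMILES does not parse: ", reference, call. = FALSE)
  hits <- .smartsCountSmiles(reference, "ref", c(q = pattern))
  if (hits < 1)
    stop("configuration error: pattern '", pattern,
         "' does not match its reference structure '", reference, "'",
         call. = FALSE)
  q
}

#' @rdname scaffoldQuery
#' @export
defaultScaffoldQuery <- function() {
  scaffoldQuery("propanesulfonic", "CCCS(=O)(=O)[OX1,OX2]",
                reference = "NCCCS(=O)(=O)O")
}

setMethod("show", "ScaffoldQuery", function(object) {
  cat("ScaffoldQuery:", object@name, "\n")
  cat("  pattern:  ", object@pattern, "\n")
  cat("  reference:", object@reference, "\n")
})

#' Count scaffold matches per compound
#'
#' Number of embeddings of the query pattern in each (salt-stripped)
#' library structure; unique atom sets are counted once.
#'
#' @param library a \linkS4class{CompoundLibrary}.
#' @param query a \linkS4class{ScaffoldQuery}.
#' @return named integer vector of match counts.
#' @export
scaffoldMatchCount <- function(library, query = defaultScaffoldQuery()) {
  stopifnot(is(library, "CompoundLibrary"), is(query, "ScaffoldQuery"))
  if (length(library) == 0)
    return(stats::setNames(integer(0), character(0)))
  stripped <- stripSalts(library@smiles)
  .smartsCountSmiles(stripped, library@id, c(query = query@pattern))
}

#' Filter a library for a scaffold
#'
#' Returns exactly the records whose molecular graph (after salt stripping)
#' contains at least one embedding of the query pattern. Input order is
#' preserved and the result is a subset of the input; the original (salted)
#' structures are retained in the output.
#'
#' @inheritParams scaffoldMatchCount
#' @return a \linkS4class{CompoundLibrary} of hits, with the per-hit match
#'   counts in \code{metadata(...)$nMatches}.
#' @examples
#' lib <- compoundLibrary(c("tra", "benzene"),
#'                        c("NCCCS(=O)(=O)O", "c1ccccc1"))
#' compoundIds(scaffoldFilter(lib))
#' @export
scaffoldFilter <- function(library, query = defaultScaffoldQuery()) {
  counts <- scaffoldMatchCount(library, query)
  hits <- library[which(counts > 0)]
  hits@metadata$nMatches <- counts[counts > 0]
  hits@metadata$query <- query@pattern
  hits
}

#' Write scaffold hits to CSV
#'
#' @param library a \linkS4class{CompoundLibrary} (typically the full
#'   library; it is filtered with \code{query} before writing).
#' @param path output CSV path (columns \code{id,name,smiles,n_matches}).
#' @inheritParams scaffoldMatchCount
#' @return the hit table, invisibly.
#' @export
writeHits <- function(library, path, query = defaultScaffoldQuery()) {
  hits <- scaffoldFilter(library, query)
  out <- data.frame(id = hits@id, name = hits@name, smiles = hits@smiles,
                    n_matches = as.integer(hits@metadata$nMatches),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
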