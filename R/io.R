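## Flat-file readers and writers. Formats:
##  - proteins: FASTA, or 2-column TSV  id <TAB> sequence
##  - ligands:  2-column TSV            id <TAB> smiles
##  - affinities: 3-column TSV  protein_id <TAB> ligand_id <TAB> value,
##    or a dense CSV matrix (rows = proteins, columns = ligands by default,
##    empty/NaN cells = unmeasured pairs)
## '#'-prefixed lines are comments. Everything is UTF-8.

.readTsv2 <- function(path, what) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(stats::setNames(character(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed ", what, " row at line ", bad[1], " of ", path)
  stats::setNames(vapply(parts, `[[`, "", 2L), vapply(parts, `[[`, "", 1L))
}

.readProteins <- function(path) {
  first <- readLines(path, n = 50L)
  first <- first[!grepl("^#", first) & nzchar(first)]
  if (length(first) && startsWith(first[1], ">")) {
    aa <- Biostrings::readAAStringSet(path)
    names(aa) <- sub("\\s.*", "", names(aa))  # id = first word of header
    aa
  } else {
    v <- .readTsv2(path, "protein")
    aa <- Biostrings::AAStringSet(unname(v))
    names(aa) <- names(v)
    aa
  }
}

.readAffinityTriples <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]
  lineNo <- which(keep)
  if (!length(lines))
    return(data.frame(protein_id = character(0), ligand_id = character(0),
                      value = numeric(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed affinity row at line ", lineNo[bad[1]], " of ", path)
  val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(val))
    stop("non-numeric affinity value at line ",
         lineNo[which(is.na(val))[1]], " of ", path)
  data.frame(protein_id = vapply(parts, `[[`, "", 1L),
             ligand_id = vapply(parts, `[[`, "", 2L),
             value = val)
}

.readAffinityDense <- function(path, proteinsAsRows = TRUE) {
  m <- utils::read.csv(path, row.names = 1L, check.names = FALSE,
                       comment.char = "#")
  m <- as.matrix(m)
  if (!proteinsAsRows) m <- t(m)
  idx <- which(is.finite(m), arr.ind = TRUE)
  data.frame(protein_id = rownames(m)[idx[, 1]],
             ligand_id = colnames(m)[idx[, 2]],
             value = m[idx])
}

#' Load an affinity dataset from flat files
#'
#' Reads proteins (FASTA or id/sequence TSV), ligands (id/SMILES TSV) and
#' affinities, either as triples (`protein_id`, `ligand_id`, `value` TSV)
#' or as a dense CSV matrix whose missing cells (empty/NaN) are dropped.
#' Ligand ids listed more than once must agree on their SMILES; conflicting
#' entries keep the first string and are logged in the dataset metadata.
#'
#' @param proteinPath,ligandPath,affinityPath input files.
#' @param format `"triples_tsv"` or `"dense_matrix"`.
#' @param measure affinity measure tag stored per record.
#' @param proteinsAsRows for the dense format, whether matrix rows are
#'   proteins (the usual layout); set `FALSE` for the transposed layout.
#' @return an [AffinityDataset-class] with referential integrity checked.
#' @export
loadAffinityDataset <- function(proteinPath, ligandPath, affinityPath,
                                format = c("triples_tsv", "dense_matrix"),
                                measure = "pre-transformed",
                                proteinsAsRows = TRUE) {
  format <- match.arg(format)
  for (p in c(proteinPath, ligandPath, affinityPath))
    if (!file.exists(p)) stop("no such file: ", p)
  proteins <- .readProteins(proteinPath)
  ligRaw <- .readTsv2(ligandPath, "ligand")
  meta <- list()
  if (anyDuplicated(names(ligRaw))) {
    first <- !duplicated(names(ligRaw))
    conflict <- tapply(ligRaw, names(ligRaw),
                       function(s) length(unique(s)) > 1L)
    if (any(conflict)) {
      meta$droppedSmiles <- names(conflict)[conflict]
      warning("ligand id(s) with multiple SMILES, keeping first: ",
              paste(meta$droppedSmiles, collapse = ", "))
    }
    ligRaw <- ligRaw[first]
  }
  rec <- switch(format,
                triples_tsv = .readAffinityTriples(affinityPath),
                dense_matrix = .readAffinityDense(affinityPath,
                                                  proteinsAsRows))
  unkP <- setdiff(rec$protein_id, names(proteins))
  if (length(unkP))
    stop("affinity file references unknown protein id(s): ",
         paste(utils::head(unkP, 5), collapse = ", "))
  unkL <- setdiff(rec$ligand_id, names(ligRaw))
  if (length(unkL))
    stop("affinity file references unknown ligand id(s): ",
         paste(utils::head(unkL, 5), collapse = ", "))
  if (nrow(rec)) rec$measure <- measure
  AffinityDataset(proteins, ligRaw, rec, meta)
}

#' Write / read a similarity matrix as CSV with a JSON sidecar
#'
#' The CSV has an id header row and id first column; full double precision
#' is preserved (round-trip exact at 1e-12, in practice bit-exact). The
#' sidecar `<path>.json` records the kind and the scheme/compressor
#' parameters so a matrix file is self-describing.
#'
#' @param x a [SimilarityMatrix-class].
#' @param path CSV output path (sidecar written next to it).
#' @return `writeSimilarityMatrix` returns `path` invisibly;
#'   `readSimilarityMatrix` returns the reconstructed
#'   [SimilarityMatrix-class].
#' @export
writeSimilarityMatrix <- function(x, path) {
  stopifnot(methods::is(x, "SimilarityMatrix"))
  v <- x@values
  dimnames(v) <- list(x@ids, x@ids)
  df <- data.frame(id = rownames(v),
                   format(v, digits = 17, scientific = TRUE, trim = TRUE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(list(kind = x@kind, ids = x@ids), x@metadata),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSimilarityMatrix
#' @export
readSimilarityMatrix <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  ids <- df[[1]]
  v <- apply(as.matrix(df[, -1, drop = FALSE]), c(1, 2), as.numeric)
  dimnames(v) <- NULL
  meta <- side[setdiff(names(side), c("kind", "ids"))]
  methods::new("SimilarityMatrix", ids = ids, values = v,
               kind = side$kind, metadata = meta)
}

#' Write a split manifest as JSON
#'
#' Serializes folds from [makeSplits()] as
#' `{mode, seed, folds: [{train: [...], test: [...]}]}` with 1-based record
#' indices.
#'
#' @param folds list of `list(train=, test=)` integer index vectors.
#' @param spec the [SplitSpec-class] that produced them.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeSplitManifest <- function(folds, spec, path) {
  jsonlite::write_json(
    list(mode = spec@mode, seed = spec@seed,
         folds = lapply(folds, function(f)
           list(train = as.integer(f$train), test = as.integer(f$test)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
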