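#' Read an aligned FASTA into a character matrix
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @return character matrix (sequences x positions), uppercase, rows named
#'   by sequence id.
#' @export
read_fasta_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequences have unequal lengths")
  m <- toupper(as.character(as.matrix(dna)))
  m
}

## aligned character matrix -> FASTA file (deterministic bytes)
write_fasta <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  lines <- character(2L * nrow(m))
  lines[seq(1, by = 2, length.out = nrow(m))] <- paste0(">", rownames(m))
  lines[seq(2, by = 2, length.out = nrow(m))] <- apply(m, 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a taxon-by-sample count table from TSV
#'
#' Rows are taxa (first column `taxon_id`), remaining columns samples.
#'
#' @param path TSV path.
#' @return integer matrix with taxon row names and sample column names.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

write_counts_tsv <- function(counts, path) {
  df <- data.frame(taxon_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Expects columns `sample_id`, `habitat` (values `marine`/`freshwater`),
#' and optionally `site` and `depth_class`.
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "habitat") %in% names(df)))
    stop("metadata must contain sample_id and habitat columns")
  df
}

#' Read per-taxon lineage strings from TSV
#'
#' Expects columns `taxon_id` and `lineage` (semicolon-delimited
#' phylum;class;order;family;genus).
#'
#' @param path TSV path.
#' @return data frame with `taxon_id`, `lineage`, and one column per rank.
#' @export
read_lineage_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon_id", "lineage") %in% names(df)))
    stop("lineage table must contain taxon_id and lineage columns")
  ranks <- c("phylum", "class", "order", "family", "genus")
  parts <- strsplit(df$lineage, ";", fixed = TRUE)
  if (any(lengths(parts) != length(ranks)))
    stop("each lineage string must have exactly 5 semicolon-delimited ranks")
  for (i in seq_along(ranks)) df[[ranks[i]]] <- vapply(parts, `[[`, character(1), i)
  df
}

## pull the grouping vector for a rank, erroring on unknown ranks
lineage_at_rank <- function(lineage, rank) {
  ranks <- c("phylum", "class", "order", "family", "genus")
  if (!rank %in% ranks)
    stop(sprintf("unknown rank '%s' (expected one of %s)", rank, paste(ranks, collapse = ", ")))
  if (!rank %in% names(lineage)) {
    parts <- strsplit(lineage$lineage, ";", fixed = TRUE)
    stats::setNames(vapply(parts, `[[`, character(1), match(rank, ranks)), lineage$taxon_id)
  } else {
    stats::setNames(lineage[[rank]], lineage$taxon_id)
  }
}
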