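# Alignments are stored as a character matrix (rows = sequences, columns =
# alignment columns) with unique rownames; '-' is the gap symbol. This keeps
# column extraction cheap for the all-pairs covariation loops.

GAP <- "-"

#' Construct an alignment from named sequence strings
#'
#' @param seqs Named character vector of equal-length residue strings.
#' @return A character matrix of class `"coevar_aln"` with sequence
#'   identifiers as rownames.
#' @export
alignment <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop_invalid("sequences must have unique names")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop_invalid("all sequences must have equal length (got lengths %s)",
                 paste(unique(lens), collapse = ", "))
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- names(seqs)
  class(m) <- c("coevar_aln", class(m))
  m
}

#' Read a FASTA alignment
#'
#' @param path Path to a FASTA file; all records must have equal length.
#' @return A `"coevar_aln"` character matrix.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))   # keep identifier token only
  alignment(seqs)
}

#' Write an alignment to FASTA
#'
#' @param aln A `"coevar_aln"` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  seqs <- apply(unclass(aln), 1, paste0, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- rownames(aln)
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' @export
print.coevar_aln <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d columns (alphabet: %s)\n",
              nrow(x), ncol(x),
              paste(sort(setdiff(unique(as.vector(x)), GAP)), collapse = "")))
  invisible(x)
}

#' Remove invariant alignment columns
#'
#' Drops columns with at most one distinct non-gap symbol (including
#' all-gap columns), as invariant sites carry no covariation signal. The
#' returned index map preserves the original 1-based column numbers so that
#' downstream pair reports refer to the input coordinate system.
#'
#' @param aln A `"coevar_aln"` matrix.
#' @return List with `alignment` (filtered) and `kept` (integer vector of
#'   original column indices). Warns (does not error) if nothing is left.
#' @export
filter_invariant_columns <- function(aln) {
  if (ncol(aln) == 0L) stop_invalid("alignment has no columns")
  variable <- vapply(seq_len(ncol(aln)), function(j) {
    s <- unique(aln[, j])
    length(setdiff(s, GAP)) > 1L
  }, logical(1))
  if (!any(variable))
    warning("all columns invariant; returning empty alignment", call. = FALSE)
  out <- aln[, variable, drop = FALSE]
  class(out) <- c("coevar_aln", class(unclass(out)))
  list(alignment = out, kept = which(variable))
}
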