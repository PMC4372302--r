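#' Sequence set container
#'
#' A light container for an ordered set of named sequences, either protein
#' or DNA. Identifiers must be unique and sequences non-empty; characters
#' are validated against the alphabet (IUPAC ambiguity codes are accepted
#' for DNA, and `X` for protein).
#'
#' @param ids character vector of unique identifiers.
#' @param seqs character vector of sequences (same length as `ids`).
#' @param alphabet `"protein"` or `"dna"`.
#' @param desc optional character vector of descriptions (header remainder).
#' @return An object of class `seq_set`: a list with elements `id`, `seq`,
#'   `desc` and `alphabet`.
#' @export
seq_set <- function(ids, seqs, alphabet = c("protein", "dna"), desc = NULL) {
  alphabet <- match.arg(alphabet)
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("ids and seqs must have the same length")
  if (anyDuplicated(ids))
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(seqs) && any(!nzchar(seqs)))
    stop("empty sequence for record: ", ids[!nzchar(seqs)][1L])
  if (is.null(desc)) desc <- rep("", length(ids))
  ok <- .alphabet_ok(seqs, alphabet)
  if (!all(ok))
    stop("illegal ", alphabet, " characters in record: ", ids[!ok][1L])
  structure(list(id = ids, seq = stats::setNames(seqs, ids),
                 desc = as.character(desc), alphabet = alphabet),
            class = "seq_set")
}

.alphabet_chars <- function(alphabet) {
  if (alphabet == "dna") "ACGTUNRYSWKMBDHV-" else "ACDEFGHIKLMNPQRSTVWYX-"
}

.alphabet_ok <- function(seqs, alphabet) {
  pat <- sprintf("^[%s]*$", .alphabet_chars(alphabet))
  grepl(pat, seqs)
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set of %d %s sequence(s)\n", length(x$id), x$alphabet))
  n <- min(6L, length(x$id))
  for (i in seq_len(n))
    cat(sprintf("  %s (%d)\n", x$id[i], nchar(x$seq[i])))
  if (length(x$id) > n) cat("  ...\n")
  invisible(x)
}

#' @export
length.seq_set <- function(x) length(x$id)

#' Read a FASTA file
#'
#' The identifier is everything after `>` up to the first whitespace; the
#' remainder of the header line is kept as the description. Sequence case
#' is normalized to upper and whitespace stripped.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"protein"` or `"dna"`.
#' @return A [seq_set].
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L)
    return(seq_set(character(), character(), alphabet))
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) && !startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop("malformed FASTA: line ", nonblank[1L], " is not a header")
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- gsub("[[:space:]]", "", toupper(as.character(set)))
  if (any(!nzchar(seqs))) {
    bad <- ids[!nzchar(seqs)][1L]
    ln <- grep(paste0("^>", bad), lines)[1L]
    stop("empty FASTA record '", bad, "' at line ", ln)
  }
  ok <- .alphabet_ok(seqs, alphabet)
  if (!all(ok)) {
    i <- which(!ok)[1L]
    pat <- sprintf("[^>%s[:space:]%s]", .alphabet_chars(alphabet),
                   tolower(.alphabet_chars(alphabet)))
    ln <- grep(pat, lines)[1L]
    stop("illegal ", alphabet, " character in record '", ids[i],
         "' near line ", if (is.na(ln)) "?" else ln)
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    ln <- grep(paste0("^>", dup, "(\\s|$)"), lines)
    stop("duplicate FASTA identifier '", dup, "' at line ",
         paste(ln, collapse = " and "))
  }
  seq_set(ids, seqs, alphabet, desc)
}

#' Write a FASTA file
#'
#' Sequences are written in record order, wrapped at 60 columns.
#'
#' @param seqs a [seq_set].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(inherits(seqs, "seq_set"))
  headers <- ifelse(nzchar(seqs$desc),
                    paste(seqs$id, seqs$desc), seqs$id)
  x <- Biostrings::BStringSet(seqs$seq)
  names(x) <- headers
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Parse a Newick tree string
#'
#' Wraps [ape::read.tree] with stricter validation: unbalanced parentheses,
#' quoted labels and duplicate leaf labels are errors. Missing branch
#' lengths are kept absent (`NULL` `edge.length`), not coerced to zero.
#'
#' @param text a single Newick string.
#' @return An [ape::phylo] tree.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (grepl("['\"]", text))
    stop("quoted Newick labels are not supported")
  opens <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  closes <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (opens != closes)
    stop("unbalanced parentheses in Newick string (", opens, " '(' vs ",
         closes, " ')')")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("failed to parse Newick string")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' Serialize a tree to Newick
#'
#' @param tree an [ape::phylo] tree.
#' @param digits number of significant digits for branch lengths.
#' @return A Newick string terminated by `;`.
#' @export
write_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}

#' Read a tab-separated table with schema validation
#'
#' The file must be TSV with a header row; `#`-prefixed lines are skipped.
#' `schema` is a named character vector mapping required column names to
#' types (`"character"`, `"numeric"` or `"integer"`); extra columns are
#' kept as-is.
#'
#' @param path path to a TSV file.
#' @param schema named character vector of required column types, or `NULL`.
#' @return A `data.frame`, row order as in the file.
#' @export
read_table_tsv <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!is.null(schema)) {
    missing_cols <- setdiff(names(schema), names(df))
    if (length(missing_cols))
      stop("missing required column(s): ",
           paste(missing_cols, collapse = ", "))
    for (col in names(schema)) {
      type <- schema[[col]]
      if (type %in% c("numeric", "integer")) {
        v <- suppressWarnings(as.numeric(df[[col]]))
        bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
        if (length(bad))
          stop("non-numeric value '", df[[col]][bad[1L]], "' in column '",
               col, "' at data row ", bad[1L])
        df[[col]] <- if (type == "integer") as.integer(round(v)) else v
      } else {
        df[[col]] <- as.character(df[[col]])
      }
    }
  }
  df
}

#' Write a tab-separated table
#'
#' @param df a `data.frame`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
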