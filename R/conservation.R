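#' Construct a protein alignment
#'
#' @param seqs Named character vector (or list) of gapped sequences of
#'   equal length; gap character `-`. At least two rows; no all-gap
#'   column.
#' @return A `protein_alignment`: list with `ids` and `seqs`.
#' @export
protein_alignment <- function(seqs) {
  seqs <- toupper(unlist(seqs))
  if (length(seqs) < 2L) stop("alignment needs >= 2 rows", call. = FALSE)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("alignment rows must be named", call. = FALSE)
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  m <- aln_matrix(seqs)
  if (any(colSums(m != "-") == 0L)) {
    stop("alignment contains an all-gap column", call. = FALSE)
  }
  structure(list(ids = names(seqs), seqs = unname(seqs)),
            class = "protein_alignment")
}

aln_matrix <- function(seqs) {
  do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("<protein_alignment> %d rows x %d columns\n", length(x$ids),
              nchar(x$seqs[1L])))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned (gapped) protein FASTA file.
#' @return A [protein_alignment()].
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  protein_alignment(setNames(as.character(set), ids))
}

#' Write an alignment to FASTA
#'
#' @param aln A [protein_alignment()].
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(setNames(aln$seqs, aln$ids)), path, width = 60L)
  invisible(path)
}

#' Percent identity between two protein sequences
#'
#' Sequences of equal length are compared position by position. Unequal
#' lengths are first aligned globally (BLOSUM62, affine gaps); identity is
#' then computed over aligned columns excluding terminal gaps, with
#' internal gaps counted as mismatches. Reported to one decimal, matching
#' the conventional precision of printed identity values.
#'
#' @param a,b Protein strings (or [seq_record]s).
#' @return Percent identity in `[0, 100]`, rounded to one decimal.
#' @examples
#' pairwise_identity("MKVA", "MKTA")  # 75.0
#' @export
pairwise_identity <- function(a, b) {
  if (is(a, "seq_record")) a <- a$sequence
  if (is(b, "seq_record")) b <- b$sequence
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  if (nchar(a) == nchar(b)) {
    ca <- strsplit(a, "", fixed = TRUE)[[1L]]
    cb <- strsplit(b, "", fixed = TRUE)[[1L]]
    pid <- 100 * sum(ca == cb) / length(ca)
  } else {
    al <- align_global(a, b)
    pid <- aligned_identity(al$a, al$b)
  }
  round(pid, 1L)
}

#' Per-column conservation profile of an alignment
#'
#' For each column: the modal non-gap residue (consensus; ties broken
#' alphabetically and flagged), percent conservation (modal count over the
#' non-gap count), and whether gaps form the column majority.
#'
#' @param aln A [protein_alignment()].
#' @return Data frame with columns `column`, `consensus`, `conservation`,
#'   `tie`, `gap_majority`.
#' @export
column_profile <- function(aln) {
  stopifnot(is(aln, "protein_alignment"))
  m <- aln_matrix(aln$seqs)
  nrows <- nrow(m)
  out <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    res <- col[col != "-"]
    tab <- sort(table(res), decreasing = TRUE)
    top <- tab[tab == tab[1L]]
    consensus <- sort(names(top))[1L]
    data.frame(column = j, consensus = consensus,
               conservation = 100 * as.integer(tab[1L]) / length(res),
               tie = length(top) > 1L,
               gap_majority = (nrows - length(res)) > length(res),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Consensus sequence of an alignment
#'
#' Modal non-gap residue per column (alphabetical tie-break); columns in
#' which gaps form the majority are omitted, so the consensus is an
#' ungapped protein string.
#'
#' @param aln A [protein_alignment()].
#' @return The consensus protein string.
#' @export
consensus <- function(aln) {
  prof <- column_profile(aln)
  paste(prof$consensus[!prof$gap_majority], collapse = "")
}

#' Positions differing between two consensus sequences
#'
#' @param consensus_a,consensus_b Protein strings of equal length (unequal
#'   lengths are first aligned globally and compared column-wise, with a
#'   gap counting as a difference; positions then refer to alignment
#'   columns).
#' @return Sorted integer vector of 1-based differing positions.
#' @examples
#' group_differences("MSKATA", "MRAKST")  # 2 3 4 5 6
#' @export
group_differences <- function(consensus_a, consensus_b) {
  a <- toupper(consensus_a); b <- toupper(consensus_b)
  if (nchar(a) != nchar(b)) {
    al <- align_global(a, b)
    a <- al$a; b <- al$b
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  which(ca != cb)
}

#' Export a conservation profile as TSV
#'
#' @param aln A [protein_alignment()].
#' @param path Output path.
#' @export
write_column_profile <- function(aln, path) {
  prof <- column_profile(aln)
  prof$conservation <- sprintf("%.4f", prof$conservation)
  utils::write.table(prof, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
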