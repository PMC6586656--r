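#' @importFrom methods is
#' @importFrom stats sd rnorm runif setNames
#' @importFrom utils combn head write.csv
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
PROTEIN_ALPHABET <- c(AA_LETTERS, "X")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Construct a sequence record
#'
#' A `seq_record` is the elementary unit consumed by every scanner in the
#' package: an identified DNA or protein sequence. Sequences are stored
#' upper-case and validated against the declared alphabet (DNA: ACGTN;
#' protein: the 20 amino acids plus X).
#'
#' @param id Character identifier (non-empty).
#' @param sequence Residue string.
#' @param moltype `"dna"` or `"protein"`.
#' @param description Optional free-text description.
#' @return An object of class `seq_record` with fields `id`, `sequence`,
#'   `moltype`, `description`.
#' @examples
#' seq_record("orf1", "ATGAAATAA", "dna")
#' @export
seq_record <- function(id, sequence, moltype = c("dna", "protein"),
                       description = "") {
  moltype <- match.arg(moltype)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) {
    stop("record '", id, "': sequence is empty", call. = FALSE)
  }
  alphabet <- if (moltype == "dna") DNA_ALPHABET else PROTEIN_ALPHABET
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% alphabet)
  if (length(bad)) {
    stop(sprintf("record '%s': illegal %s character '%s' at position %d",
                 id, moltype, chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, moltype = moltype,
                 description = description),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  seq_show <- if (nchar(x$sequence) > 60L) {
    paste0(substr(x$sequence, 1L, 57L), "...")
  } else {
    x$sequence
  }
  cat(sprintf("<seq_record %s> %s (%d %s)\n  %s\n", x$moltype, x$id,
              nchar(x$sequence), if (x$moltype == "dna") "nt" else "aa",
              seq_show))
  invisible(x)
}

#' Read a FASTA file into sequence records
#'
#' Parsing is delegated to [Biostrings::readBStringSet()]; each record is
#' then validated against the declared alphabet, so malformed residues are
#' reported with the offending record id and 1-based position. The id of a
#' record is the first whitespace-delimited token of its header; the
#' remainder becomes the description. Multi-line (wrapped) sequences are
#' concatenated; records are returned in file order.
#'
#' @param path Path to a FASTA file.
#' @param moltype `"dna"` or `"protein"`.
#' @return A list of [seq_record] objects.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, moltype = c("dna", "protein")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate record id in ", path, ": ",
         ids[duplicated(ids)][1L], call. = FALSE)
  }
  mapply(function(id, s, d) seq_record(id, s, moltype, d),
         ids, as.character(set), descs,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequence records to FASTA
#'
#' Sequences are wrapped at 60 columns. Round-trips exactly with
#' [read_fasta()] for any valid record set.
#'
#' @param records A list of [seq_record] objects (or a single record).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  if (is(records, "seq_record")) records <- list(records)
  seqs <- vapply(records, `[[`, character(1L), "sequence")
  ids <- vapply(records, `[[`, character(1L), "id")
  descs <- vapply(records, `[[`, character(1L), "description")
  names(seqs) <- ifelse(nzchar(descs), paste(ids, descs), ids)
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 60L)
  invisible(path)
}

codon_split <- function(nt) {
  n <- nchar(nt)
  substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
}

translate_codons <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"  # any codon containing N
  aa
}

#' Translate a coding sequence
#'
#' Standard genetic code; the terminal stop codon is required and excluded
#' from the output. Codons containing the ambiguity base N translate to X;
#' an internal stop codon is an error reporting the codon index.
#'
#' @param nt A DNA string beginning with ATG and ending with a stop codon,
#'   length divisible by 3.
#' @return The protein string, of length `nchar(nt)/3 - 1`.
#' @examples
#' translate_cds("ATGAAATAA")  # "MK"
#' @export
translate_cds <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n %% 3L != 0L) {
    stop("coding sequence length ", n, " is not divisible by 3",
         call. = FALSE)
  }
  codons <- codon_split(nt)
  k <- length(codons)
  if (codons[1L] != "ATG") stop("sequence does not begin with ATG",
                                call. = FALSE)
  if (!codons[k] %in% STOP_CODONS) stop("sequence does not end with a stop codon",
                                        call. = FALSE)
  internal <- which(codons[-k] %in% STOP_CODONS)
  if (length(internal)) {
    stop("internal stop codon at codon index ", internal[1L], call. = FALSE)
  }
  paste(translate_codons(codons[-k]), collapse = "")
}

#' @rdname translate_cds
#' @param orf An `orf` object as returned by [find_orfs()].
#' @export
translate_orf <- function(orf) {
  stopifnot(is(orf, "orf"))
  translate_cds(orf$nt_sequence)
}

new_orf <- function(parent_id, start, end, strand, nt_sequence) {
  structure(list(parent_id = parent_id, start = start, end = end,
                 strand = strand, nt_sequence = nt_sequence,
                 aa_sequence = translate_cds(nt_sequence)),
            class = "orf")
}

revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

# Frame scan on one strand: ATG -> nearest in-frame stop, no internal stop.
# Returns codon-index pairs (start codon, stop codon) per frame offset.
frame_orf_spans <- function(codons) {
  starts <- which(codons == "ATG")
  stops <- which(codons %in% STOP_CODONS)
  if (!length(starts) || !length(stops)) return(NULL)
  stop_after <- findInterval(starts, stops) + 1L  # first stop strictly after
  ok <- stop_after <= length(stops)
  if (!any(ok)) return(NULL)
  cbind(start = starts[ok], stop = stops[stop_after[ok]])
}

#' Find open reading frames in all six frames
#'
#' An ORF is a complete coding unit: an ATG start codon through the nearest
#' in-frame stop codon (TAA/TAG/TGA), with no internal stop. Every
#' qualifying ATG yields an ORF, so nested ORFs sharing a stop are all
#' reported. Start and stop codons containing N are not accepted.
#' Coordinates are 1-based inclusive on the forward strand; reverse-strand
#' ORFs report the forward-strand interval they span, with `strand = "-"`.
#'
#' @param record A DNA [seq_record].
#' @param min_aa Minimum protein length (excluding the stop), >= 1.
#' @return A list of `orf` objects sorted by decreasing protein length
#'   (ties by strand then start), possibly empty. Each has fields
#'   `parent_id`, `start`, `end`, `strand`, `nt_sequence`, `aa_sequence`.
#' @examples
#' find_orfs(seq_record("x", "ATGAAATAA", "dna"), min_aa = 1)
#' @export
find_orfs <- function(record, min_aa = 1L) {
  stopifnot(is(record, "seq_record"), record$moltype == "dna", min_aa >= 1L)
  seq_fwd <- record$sequence
  L <- nchar(seq_fwd)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_fwd else revcomp(seq_fwd)
    for (off in 0:2) {
      usable <- L - off
      ncod <- usable %/% 3L
      if (ncod < 2L) next
      sub <- substr(s, off + 1L, off + 3L * ncod)
      spans <- frame_orf_spans(codon_split(sub))
      if (is.null(spans)) next
      for (r in seq_len(nrow(spans))) {
        a <- unname(spans[r, "start"]); z <- unname(spans[r, "stop"])
        if (z - a < min_aa) next  # aa length = z - a (codons before the stop)
        nt <- substr(sub, 3L * (a - 1L) + 1L, 3L * z)
        p1 <- off + 3L * (a - 1L) + 1L  # on strand s
        p2 <- off + 3L * z
        if (strand == "+") {
          start <- p1; end <- p2
        } else {
          start <- L - p2 + 1L; end <- L - p1 + 1L
        }
        out[[length(out) + 1L]] <-
          new_orf(record$id, start, end, strand, nt)
      }
    }
  }
  if (!length(out)) return(out)
  aa_len <- vapply(out, function(o) nchar(o$aa_sequence), integer(1L))
  strand <- vapply(out, `[[`, character(1L), "strand")
  start <- vapply(out, `[[`, integer(1L), "start")
  out[order(-aa_len, strand, start)]
}

#' @export
print.orf <- function(x, ...) {
  cat(sprintf("<orf> %s:%d-%d(%s) %d nt -> %d aa\n", x$parent_id, x$start,
              x$end, x$strand, nchar(x$nt_sequence), nchar(x$aa_sequence)))
  invisible(x)
}

#' Tabulate ORFs
#'
#' @param orfs List of `orf` objects from [find_orfs()].
#' @return A data frame with columns `parent_id`, `start`, `end`, `strand`,
#'   `aa_len`.
#' @export
orfs_to_table <- function(orfs) {
  data.frame(
    parent_id = vapply(orfs, `[[`, character(1L), "parent_id"),
    start = vapply(orfs, `[[`, integer(1L), "start"),
    end = vapply(orfs, `[[`, integer(1L), "end"),
    strand = vapply(orfs, `[[`, character(1L), "strand"),
    aa_len = vapply(orfs, function(o) nchar(o$aa_sequence), integer(1L)),
    stringsAsFactors = FALSE
  )
}
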