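#' Parse a degenerate protein motif notation
#'
#' The notation is a run of amino-acid letters in which `X` is a wildcard
#' (matches any residue, never counted as a mismatch) and a single
#' parenthesized letter is an alternative to the immediately preceding
#' position, e.g. `"S(A)EAYLGK(G)E(A)"` is an 8-position pattern with
#' alternatives at positions 1, 7 and 8. This grammar reproduces the
#' conventional way variable ATP-site residues are printed for Hsp70.
#'
#' @param notation Pattern string (amino-acid letters, `X`, balanced
#'   single-letter parentheses).
#' @param max_mismatches Non-negative mismatch budget for scanning.
#' @param anchor `"anywhere"`, `"n_terminus"` (match must start at residue
#'   1) or `"c_terminus"` (match must end at the last residue).
#' @param name Pattern name; defaults to the notation itself.
#' @return A `motif_pattern`: list with `name`, `positions` (list of
#'   residue sets; `"X"` marks a wildcard), `max_mismatches`, `anchor`.
#' @examples
#' parse_motif("S(A)EAYLGK(G)E(A)")
#' parse_motif("KKXXXXXXXXXRRLRT")
#' @export
parse_motif <- function(notation, max_mismatches = 0L,
                        anchor = c("anywhere", "n_terminus", "c_terminus"),
                        name = notation) {
  anchor <- match.arg(anchor)
  stopifnot(is.character(notation), length(notation) == 1L, nzchar(notation),
            max_mismatches >= 0L)
  chars <- strsplit(toupper(notation), "", fixed = TRUE)[[1L]]
  positions <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      if (i + 2L > length(chars) || chars[i + 2L] != ")") {
        stop("motif '", notation,
             "': parenthesis must enclose exactly one letter", call. = FALSE)
      }
      alt <- chars[i + 1L]
      if (!alt %in% AA_LETTERS) {
        stop("motif '", notation, "': illegal alternative '", alt, "'",
             call. = FALSE)
      }
      if (!length(positions)) {
        stop("motif '", notation, "': leading parenthesized alternative",
             call. = FALSE)
      }
      last <- positions[[length(positions)]]
      if (identical(last, "X")) {
        stop("motif '", notation, "': alternative after wildcard",
             call. = FALSE)
      }
      positions[[length(positions)]] <- sort(unique(c(last, alt)))
      i <- i + 3L
    } else if (ch == "X") {
      positions[[length(positions) + 1L]] <- "X"
      i <- i + 1L
    } else if (ch %in% AA_LETTERS) {
      positions[[length(positions) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("motif '", notation, "': illegal character '", ch, "'",
           call. = FALSE)
    }
  }
  if (!length(positions)) stop("motif '", notation, "': no positions",
                               call. = FALSE)
  structure(list(name = name, positions = positions,
                 max_mismatches = as.integer(max_mismatches),
                 anchor = anchor),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  shown <- vapply(x$positions, function(p) {
    if (identical(p, "X")) "X"
    else if (length(p) == 1L) p
    else paste0("[", paste(p, collapse = ""), "]")
  }, character(1L))
  cat(sprintf("<motif_pattern> %s: %s (%d positions, <=%d mismatches, %s)\n",
              x$name, paste(shown, collapse = ""), length(x$positions),
              x$max_mismatches, x$anchor))
  invisible(x)
}

#' Scan a protein for a degenerate motif
#'
#' Every window of pattern length is tested; a window is a hit when at most
#' `max_mismatches` positions fall outside their residue set. Wildcard
#' positions never count as mismatches. Anchored patterns are tested only
#' at the first (N-terminal) or last (C-terminal) window.
#'
#' @param protein A protein [seq_record].
#' @param pattern A `motif_pattern` from [parse_motif()].
#' @return A data frame of hits (possibly zero rows), sorted by `start`:
#'   columns `pattern_name`, `start`, `end`, `matched`, `mismatches`.
#' @export
scan_motif <- function(protein, pattern) {
  stopifnot(is(protein, "seq_record"), protein$moltype == "protein",
            is(pattern, "motif_pattern"))
  s <- protein$sequence
  L <- nchar(s)
  plen <- length(pattern$positions)
  empty <- data.frame(pattern_name = character(), start = integer(),
                      end = integer(), matched = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  if (plen > L) return(empty)
  starts <- switch(pattern$anchor,
                   anywhere = seq_len(L - plen + 1L),
                   n_terminus = 1L,
                   c_terminus = L - plen + 1L)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  mism <- integer(length(starts))
  for (j in seq_len(plen)) {
    set <- pattern$positions[[j]]
    if (identical(set, "X")) next
    mism <- mism + as.integer(!chars[starts + j - 1L] %in% set)
  }
  keep <- mism <= pattern$max_mismatches
  if (!any(keep)) return(empty)
  st <- starts[keep]
  data.frame(pattern_name = pattern$name, start = st, end = st + plen - 1L,
             matched = substring(s, st, st + plen - 1L),
             mismatches = mism[keep], stringsAsFactors = FALSE)
}

#' The built-in Hsp/Hsc70 signature set
#'
#' The diagnostic and family-wide signatures used for typing: the three
#' family signatures IDLGTTYS, TVPAYFND and NEPTAA; the phosphate-binding
#' site IFDLGGGTFDVSIL; the putative nuclear localization signal
#' KK-X9-RRLRT; the cytosolic-localization evidence RARFEEL/RARFEEM and
#' C-terminal GPTIEEVD with the EEVD tail; the ATP/GTP-binding site in its
#' heat-inducible (S(A)EAYLGK(G)E(A)) and cognate (ADAYLGTN) forms; and the
#' N-terminal hexamers MRAKST (heat-inducible) and MSKATA (cognate).
#'
#' @param mismatch_budgets Optional named integer vector overriding the
#'   default per-signature mismatch budget of 0 (e.g.
#'   `c(IDLGTTYS = 1)`), supporting relaxed "signature-like" searches.
#' @return Named list of `motif_pattern` objects.
#' @export
hsp70_signatures <- function(mismatch_budgets = NULL) {
  defs <- list(
    IDLGTTYS = list("IDLGTTYS", "anywhere"),
    TVPAYFND = list("TVPAYFND", "anywhere"),
    NEPTAA = list("NEPTAA", "anywhere"),
    phosphate_binding = list("IFDLGGGTFDVSIL", "anywhere"),
    NLS = list("KKXXXXXXXXXRRLRT", "anywhere"),
    RARFEEL = list("RARFEEL", "anywhere"),
    RARFEEM = list("RARFEEM", "anywhere"),
    GPTIEEVD = list("GPTIEEVD", "c_terminus"),
    EEVD_tail = list("EEVD", "c_terminus"),
    ATP_inducible = list("S(A)EAYLGK(G)E(A)", "anywhere"),
    ATP_cognate = list("ADAYLGTN", "anywhere"),
    Nterm_inducible = list("MRAKST", "n_terminus"),
    Nterm_cognate = list("MSKATA", "n_terminus")
  )
  out <- lapply(names(defs), function(nm) {
    budget <- 0L
    if (!is.null(mismatch_budgets) && nm %in% names(mismatch_budgets)) {
      budget <- as.integer(mismatch_budgets[[nm]])
    }
    parse_motif(defs[[nm]][[1L]], max_mismatches = budget,
                anchor = defs[[nm]][[2L]], name = nm)
  })
  names(out) <- names(defs)
  out
}

#' Profile a protein against the built-in signature set
#'
#' Applies [scan_motif()] for every built-in signature; the result always
#' carries one entry per signature (possibly an empty hit table), so
#' downstream classification can distinguish "absent" from "not scanned".
#'
#' @inheritParams hsp70_signatures
#' @param protein A protein [seq_record].
#' @return A `signature_profile`: list with `sequence_id` and `hits`, a
#'   named list of hit data frames over the full signature set.
#' @export
profile_signatures <- function(protein, mismatch_budgets = NULL) {
  sigs <- hsp70_signatures(mismatch_budgets)
  hits <- lapply(sigs, function(p) scan_motif(protein, p))
  structure(list(sequence_id = protein$id, hits = hits),
            class = "signature_profile")
}

#' @export
print.signature_profile <- function(x, ...) {
  present <- names(x$hits)[vapply(x$hits, nrow, integer(1L)) > 0L]
  cat(sprintf("<signature_profile> %s: %d/%d signatures present\n  %s\n",
              x$sequence_id, length(present), length(x$hits),
              if (length(present)) paste(present, collapse = ", ")
              else "(none)"))
  invisible(x)
}

sig_present <- function(profile, name) nrow(profile$hits[[name]]) > 0L

#' Classify an Hsp/Hsc70 signature profile
#'
#' Ordered, conflict-aware decision rules:
#' \enumerate{
#'   \item Family membership: at least two of IDLGTTYS, TVPAYFND, NEPTAA
#'     and the phosphate-binding site present.
#'   \item Localization: cytosolic when the C-terminal EEVD tail is
#'     present (GPTIEEVD and RARFEEL/RARFEEM are recorded as supporting
#'     evidence); non-cytosolic when a family member lacks the EEVD tail;
#'     undetermined otherwise.
#'   \item Inducibility (family members only): heat-inducible when the
#'     inducible ATP site, the MRAKST N-terminus or RARFEEM is present and
#'     the cognate ATP site is absent; cognate-like when the cognate ATP
#'     site, MSKATA or RARFEEL is present and the inducible ATP site is
#'     absent; undetermined on conflicting evidence or no diagnostic hit.
#' }
#' The score counts diagnostic signatures concordant with the verdict
#' (ATP site, N-terminal hexamer, RARFEEL/RARFEEM; maximum 3).
#'
#' @param profile A `signature_profile` from [profile_signatures()].
#' @return An `hsp70_classification`: `sequence_id`, `is_family_member`,
#'   `localization`, `inducibility`, `score`, `evidence` (data frame of
#'   signature, present, positions), `conflicts` (character vector of
#'   contradictions observed).
#' @export
classify_hsp70 <- function(profile) {
  stopifnot(is(profile, "signature_profile"))
  p <- function(nm) sig_present(profile, nm)
  family_sigs <- c("IDLGTTYS", "TVPAYFND", "NEPTAA", "phosphate_binding")
  is_family <- sum(vapply(family_sigs, p, logical(1L))) >= 2L

  localization <- if (p("EEVD_tail")) {
    "cytosolic"
  } else if (is_family) {
    "non_cytosolic"
  } else {
    "undetermined"
  }

  conflicts <- character()
  inducibility <- "undetermined"
  score <- 0L
  if (is_family) {
    heat <- (p("ATP_inducible") || p("Nterm_inducible") || p("RARFEEM")) &&
      !p("ATP_cognate")
    cognate <- (p("ATP_cognate") || p("Nterm_cognate") || p("RARFEEL")) &&
      !p("ATP_inducible")
    if (p("ATP_inducible") && p("ATP_cognate")) {
      conflicts <- c(conflicts, "both ATP-site variants present")
    }
    if (heat && cognate) {
      conflicts <- c(conflicts, "heat-inducible and cognate evidence both satisfied")
    }
    if (heat && !cognate) {
      inducibility <- "heat_inducible"
      score <- sum(p("ATP_inducible"), p("Nterm_inducible"), p("RARFEEM"))
    } else if (cognate && !heat) {
      inducibility <- "cognate_like"
      score <- sum(p("ATP_cognate"), p("Nterm_cognate"), p("RARFEEL"))
    }
  }

  evidence <- data.frame(
    signature = names(profile$hits),
    present = vapply(profile$hits, function(h) nrow(h) > 0L, logical(1L)),
    positions = vapply(profile$hits, function(h) {
      paste(h$start, collapse = ",")
    }, character(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  )

  structure(list(sequence_id = profile$sequence_id,
                 is_family_member = is_family,
                 localization = localization,
                 inducibility = inducibility,
                 score = as.integer(score),
                 evidence = evidence,
                 conflicts = conflicts),
            class = "hsp70_classification")
}

#' @export
print.hsp70_classification <- function(x, ...) {
  cat(sprintf("<hsp70_classification> %s\n", x$sequence_id))
  cat(sprintf("  family member: %s | localization: %s | inducibility: %s (score %d/3)\n",
              x$is_family_member, x$localization, x$inducibility, x$score))
  pres <- x$evidence[x$evidence$present, , drop = FALSE]
  cat("  evidence:",
      if (nrow(pres)) paste0(pres$signature, "@", pres$positions,
                             collapse = "; ") else "(none)", "\n")
  if (length(x$conflicts)) cat("  conflicts:", paste(x$conflicts, collapse = "; "), "\n")
  invisible(x)
}

#' Construct a reference domain model
#'
#' A full-length Hsp70 reference with its domain boundaries: nucleotide
#' binding domain (NBD), substrate binding domain (SBD) and C-terminal
#' domain (CTD), 1-based inclusive. The defaults are the canonical
#' amphipod 641-residue layout (NBD 1-390, SBD 397-560, CTD 561-641, with
#' the 391-396 linker belonging to no domain).
#'
#' @param aa_sequence Protein string (or a protein [seq_record]).
#' @param accession Label for the reference.
#' @param nbd,sbd,ctd Length-2 integer vectors of domain start/end.
#' @return A `reference_model`.
#' @export
reference_model <- function(aa_sequence, accession = "reference",
                            nbd = c(1L, 390L), sbd = c(397L, 560L),
                            ctd = c(561L, 641L)) {
  if (is(aa_sequence, "seq_record")) {
    if (missing(accession)) accession <- aa_sequence$id
    aa_sequence <- aa_sequence$sequence
  }
  aa_sequence <- toupper(aa_sequence)
  L <- nchar(aa_sequence)
  doms <- rbind(nbd = nbd, sbd = sbd, ctd = ctd)
  if (any(doms[, 1L] > doms[, 2L]) || any(doms < 1L) || any(doms > L)) {
    stop("domain boundaries must be ordered and within the sequence (length ",
         L, ")", call. = FALSE)
  }
  if (nbd[2L] >= sbd[1L] || sbd[2L] >= ctd[1L]) {
    stop("domains must not overlap", call. = FALSE)
  }
  structure(list(accession = accession, aa_sequence = aa_sequence,
                 domains = data.frame(domain = c("NBD", "SBD", "CTD"),
                                      start = doms[, 1L], end = doms[, 2L],
                                      row.names = NULL,
                                      stringsAsFactors = FALSE)),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("<reference_model> %s (%d aa)\n", x$accession,
              nchar(x$aa_sequence)))
  for (i in seq_len(nrow(x$domains))) {
    cat(sprintf("  %s %d-%d\n", x$domains$domain[i], x$domains$start[i],
                x$domains$end[i]))
  }
  invisible(x)
}

# Global alignment of two proteins; returns the two gapped rows.
align_global <- function(a, b, gap_opening = 10, gap_extension = 0.5) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)))
}

# Identity over aligned rows: terminal-gap columns excluded from the
# denominator, internal gaps counted as mismatches.
aligned_identity <- function(row_a, row_b) {
  ca <- strsplit(row_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(row_b, "", fixed = TRUE)[[1L]]
  if (!any(ca != "-" & cb != "-")) return(0)
  # terminal-gap columns lie before the later-starting row begins or after
  # the earlier-ending row ends; exclude them from the denominator
  first <- max(min(which(ca != "-")), min(which(cb != "-")))
  last <- min(max(which(ca != "-")), max(which(cb != "-")))
  core <- first:last
  100 * sum(ca[core] == cb[core]) / length(core)
}

# Map reference positions to query positions via a global alignment.
# Returns an integer vector over reference positions; NA where the query
# has a gap.
ref_to_query_map <- function(query_seq, ref_seq) {
  al <- align_global(query_seq, ref_seq)
  cq <- strsplit(al$a, "", fixed = TRUE)[[1L]]
  cr <- strsplit(al$b, "", fixed = TRUE)[[1L]]
  qpos <- cumsum(cq != "-")
  rpos <- cumsum(cr != "-")
  map <- rep(NA_integer_, nchar(ref_seq))
  ref_cols <- which(cr != "-")
  q_at <- ifelse(cq[ref_cols] != "-", qpos[ref_cols], NA_integer_)
  map[rpos[ref_cols]] <- q_at
  attr(map, "identity") <- aligned_identity(al$a, al$b)
  map
}

#' Transfer reference domain boundaries onto a query protein
#'
#' Globally aligns the query to the reference (BLOSUM62, affine gaps) and
#' transfers each domain boundary to the nearest aligned query position.
#' Coverage is the fraction of reference domain positions aligned to a
#' query residue.
#'
#' @param query A protein [seq_record].
#' @param reference A [reference_model()].
#' @param min_identity Warning floor (percent) for alignment identity.
#' @return A `domain_annotation`: `query_id`, `domains` (data frame with
#'   `domain`, `ref_start`, `ref_end`, `q_start`, `q_end`, `coverage`),
#'   `identity`, `low_identity` flag.
#' @export
map_domains <- function(query, reference, min_identity = 30) {
  stopifnot(is(query, "seq_record"), query$moltype == "protein",
            is(reference, "reference_model"))
  map <- ref_to_query_map(query$sequence, reference$aa_sequence)
  identity <- attr(map, "identity")
  doms <- reference$domains
  out <- lapply(seq_len(nrow(doms)), function(i) {
    span <- doms$start[i]:doms$end[i]
    q <- map[span]
    covered <- !is.na(q)
    if (!any(covered)) {
      data.frame(domain = doms$domain[i], ref_start = doms$start[i],
                 ref_end = doms$end[i], q_start = NA_integer_,
                 q_end = NA_integer_, coverage = 0,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(domain = doms$domain[i], ref_start = doms$start[i],
                 ref_end = doms$end[i],
                 q_start = min(q[covered]), q_end = max(q[covered]),
                 coverage = mean(covered), stringsAsFactors = FALSE)
    }
  })
  structure(list(query_id = query$id, domains = do.call(rbind, out),
                 identity = identity,
                 low_identity = identity < min_identity),
            class = "domain_annotation")
}

#' @export
print.domain_annotation <- function(x, ...) {
  cat(sprintf("<domain_annotation> %s (identity %.1f%%%s)\n", x$query_id,
              x$identity, if (x$low_identity) ", LOW" else ""))
  print(x$domains, row.names = FALSE)
  invisible(x)
}

#' Extract the query region aligned to a reference interval
#'
#' Returns the query residues aligned to reference positions
#' `ref_start..ref_end`. When the query equals the reference this is the
#' literal slice of length `ref_end - ref_start + 1`.
#'
#' @param protein A protein [seq_record].
#' @param ref_start,ref_end 1-based inclusive reference coordinates.
#' @param reference A [reference_model()].
#' @return List with `sequence` (the extracted residues) and `length`.
#' @export
extract_region <- function(protein, ref_start, ref_end, reference) {
  stopifnot(is(protein, "seq_record"), is(reference, "reference_model"))
  L <- nchar(reference$aa_sequence)
  if (ref_start < 1L || ref_start > ref_end) {
    stop("invalid region: need 1 <= ref_start <= ref_end", call. = FALSE)
  }
  if (ref_end > L) {
    stop("ref_end ", ref_end, " exceeds reference length ", L, call. = FALSE)
  }
  if (identical(protein$sequence, reference$aa_sequence)) {
    sub <- substr(protein$sequence, ref_start, ref_end)
  } else {
    map <- ref_to_query_map(protein$sequence, reference$aa_sequence)
    q <- map[ref_start:ref_end]
    q <- q[!is.na(q)]
    sub <- if (length(q)) substr(protein$sequence, min(q), max(q)) else ""
  }
  list(sequence = sub, length = nchar(sub))
}
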