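TTC_CORE <- c("T", "T", "C")
GAA_CORE <- c("G", "A", "A")

core_dist <- function(pent_chars, core) {
  sum(pent_chars[2:4] != core)
}

#' Classify a single pentamer as an HSE unit
#'
#' A heat shock element is built from the pentamer units NTTCN and NGAAN;
#' only the central trinucleotide (positions 2-4) is informative, the
#' flanking N positions are free by definition. With `allow_mismatch`, one
#' mismatch in the core is tolerated and recorded. A core one mismatch
#' away from both TTC and GAA cannot occur (the two cores differ at all
#' three positions).
#'
#' @param pentamer A 5-base ACGT string.
#' @param allow_mismatch Tolerate one core mismatch?
#' @return List with `unit_class` (`"NTTCN"`, `"NGAAN"` or `"none"`) and
#'   `mismatches` (0 or 1).
#' @examples
#' classify_pentamer("AGAAA")        # NGAAN, 0 mismatches
#' classify_pentamer("ATCCA", TRUE)  # NTTCN, 1 mismatch
#' @export
classify_pentamer <- function(pentamer, allow_mismatch = FALSE) {
  pentamer <- toupper(pentamer)
  chars <- strsplit(pentamer, "", fixed = TRUE)[[1L]]
  if (length(chars) != 5L || any(!chars %in% c("A", "C", "G", "T"))) {
    stop("pentamer must be exactly 5 bases of ACGT: '", pentamer, "'",
         call. = FALSE)
  }
  d_ttc <- core_dist(chars, TTC_CORE)
  d_gaa <- core_dist(chars, GAA_CORE)
  budget <- if (allow_mismatch) 1L else 0L
  if (d_ttc <= budget) {
    list(unit_class = "NTTCN", mismatches = d_ttc)
  } else if (d_gaa <= budget) {
    list(unit_class = "NGAAN", mismatches = d_gaa)
  } else {
    list(unit_class = "none", mismatches = NA_integer_)
  }
}

# Per-phase unit costs against both cores for one strand sequence.
phase_unit_costs <- function(chars, phase) {
  L <- length(chars)
  K <- (L - phase) %/% 5L
  if (K < 1L) return(NULL)
  starts <- phase + 1L + 5L * (0:(K - 1L))
  d_ttc <- integer(K)
  d_gaa <- integer(K)
  for (k in seq_len(K)) {
    core <- chars[(starts[k] + 1L):(starts[k] + 3L)]
    d_ttc[k] <- sum(core != TTC_CORE)
    d_gaa[k] <- sum(core != GAA_CORE)
  }
  list(starts = starts, d_ttc = d_ttc, d_gaa = d_gaa)
}

# Maximal windows with all costs <= 1 and total cost <= 1 in a cost vector.
maximal_budget_windows <- function(cost) {
  n <- length(cost)
  out <- list()
  finite <- cost <= 1L
  r <- rle(finite)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (seg in which(r$values)) {
    a <- starts[seg]; b <- ends[seg]
    ones <- which(cost[a:b] == 1L) + a - 1L
    if (length(ones) <= 1L) {
      out[[length(out) + 1L]] <- c(a, b)
    } else {
      bounds_lo <- c(a, ones[-length(ones)] + 1L)
      bounds_hi <- c(ones[-1L] - 1L, b)
      for (i in seq_along(bounds_lo)) {
        out[[length(out) + 1L]] <- c(bounds_lo[i], bounds_hi[i])
      }
    }
  }
  out
}

find_hse_one_strand <- function(s, min_units) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  hits <- list()
  for (phase in 0:4) {
    pc <- phase_unit_costs(chars, phase)
    if (is.null(pc)) next
    K <- length(pc$starts)
    phase_windows <- list()
    for (parity in 1:2) {
      # parity 1: odd stream indices are NTTCN; parity 2: odd are NGAAN
      odd <- seq_len(K) %% 2L == 1L
      cost <- ifelse(xor(odd, parity == 2L), pc$d_ttc, pc$d_gaa)
      cls <- ifelse(xor(odd, parity == 2L), "NTTCN", "NGAAN")
      for (w in maximal_budget_windows(cost)) {
        a <- w[1L]; b <- w[2L]
        n_units <- b - a + 1L
        total <- sum(cost[a:b])
        hse_class <-
          if (n_units >= 3L && total == 0L) "canonical"
          else if (n_units >= 3L && total == 1L) "hse_like"
          else if (n_units == 2L && total == 0L) "hse_like"
          else NA_character_
        if (is.na(hse_class) || n_units < min_units) next
        phase_windows[[length(phase_windows) + 1L]] <- list(
          start = pc$starts[a], end = pc$starts[b] + 4L,
          units = cls[a:b], n_units = n_units, total = total,
          hse_class = hse_class)
      }
    }
    # within one phase, suppress windows contained in another window
    if (length(phase_windows) > 1L) {
      st <- vapply(phase_windows, `[[`, integer(1L), "start")
      en <- vapply(phase_windows, `[[`, integer(1L), "end")
      contained <- vapply(seq_along(phase_windows), function(i) {
        any(st <= st[i] & en >= en[i] & (st < st[i] | en > en[i]))
      }, logical(1L))
      phase_windows <- phase_windows[!contained]
    }
    hits <- c(hits, phase_windows)
  }
  hits
}

#' Find heat shock elements in a DNA sequence
#'
#' A heat shock element (HSE) is a run of contiguous, strictly alternating
#' NTTCN/NGAAN pentamer units; heat shock factor trimers require at least
#' three units, so `min_units = 3` is the canonical default. All five
#' pentamer phases are scanned and maximal, non-extendable runs are
#' reported per phase (overlapping runs in different phases are all
#' reported). A run is `canonical` when it has >= 3 units and no core
#' mismatch, and `hse_like` when one unit carries a single core mismatch
#' (>= 3 units total); a bare two-unit perfect run is reported as
#' `hse_like` only when `min_units <= 2`. HSE runs are reverse-complement
#' symmetric (the reverse complement of NGAAN is NTTCN), so reverse-strand
#' scanning finds the same forward-coordinate intervals; each interval is
#' reported once, on the forward strand, and minus-strand scanning is
#' retained as a consistency check.
#'
#' @param record A DNA [seq_record].
#' @param min_units Minimum number of pentamer units (default 3).
#' @param scan_both_strands Also scan the reverse complement (deduplicated
#'   against forward hits by coordinates).
#' @return A data frame of class `hse_hits`: `sequence_id`, `start`,
#'   `end`, `strand`, `n_units`, `units` (classes joined with `|`),
#'   `total_mismatches`, `hse_class`; sorted by `start`.
#' @examples
#' find_hse(seq_record("p", "AGAAAGTTCTAGAAC", "dna"))
#' @export
find_hse <- function(record, min_units = 3L, scan_both_strands = TRUE) {
  stopifnot(is(record, "seq_record"), record$moltype == "dna",
            min_units >= 2L)
  L <- nchar(record$sequence)
  fwd <- find_hse_one_strand(record$sequence, min_units)
  rows <- lapply(fwd, function(h) {
    data.frame(sequence_id = record$id, start = h$start, end = h$end,
               strand = "+", n_units = h$n_units,
               units = paste(h$units, collapse = "|"),
               total_mismatches = h$total, hse_class = h$hse_class,
               stringsAsFactors = FALSE)
  })
  if (scan_both_strands) {
    rev_hits <- find_hse_one_strand(revcomp(record$sequence), min_units)
    for (h in rev_hits) {
      start_f <- L - h$end + 1L
      end_f <- L - h$start + 1L
      dup <- any(vapply(rows, function(r) {
        r$start == start_f && r$end == end_f
      }, logical(1L)))
      if (!dup) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = record$id, start = start_f, end = end_f,
          strand = "-", n_units = h$n_units,
          units = paste(h$units, collapse = "|"),
          total_mismatches = h$total, hse_class = h$hse_class,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(sequence_id = character(), start = integer(),
               end = integer(), strand = character(), n_units = integer(),
               units = character(), total_mismatches = integer(),
               hse_class = character(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hse_hits", "data.frame")
  out
}

#' Distance between an HSE and the ORF start
#'
#' The distance is the number of bases strictly between the element's last
#' base and the A of the ATG start codon: `orf_start - end - 1`. An
#' element overlapping or downstream of the start codon is an error.
#'
#' @param hit One HSE hit: a single-row data frame (or list) with at least
#'   `start` and `end`.
#' @param orf_start 1-based coordinate of the A of ATG on the same
#'   sequence.
#' @return Integer distance in bp (0 when the element abuts the start).
#' @export
upstream_distance <- function(hit, orf_start) {
  if (is.data.frame(hit)) {
    stopifnot(nrow(hit) == 1L)
    hit <- as.list(hit)
  }
  if (hit$end >= orf_start) {
    stop("HSE at ", hit$start, "-", hit$end,
         " overlaps or lies downstream of the ORF start at ", orf_start,
         call. = FALSE)
  }
  as.integer(orf_start - hit$end - 1L)
}

#' Annotate HSE hits with upstream distances
#'
#' Vectorized companion to [upstream_distance()]: adds an
#' `upstream_distance` column, `NA` for hits not entirely 5' of the start.
#'
#' @param hits An `hse_hits` data frame from [find_hse()].
#' @param orf_start 1-based ORF start coordinate.
#' @return `hits` with an `upstream_distance` column.
#' @export
add_upstream_distance <- function(hits, orf_start) {
  hits$upstream_distance <- ifelse(hits$end < orf_start,
                                   as.integer(orf_start - hits$end - 1L),
                                   NA_integer_)
  hits
}
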