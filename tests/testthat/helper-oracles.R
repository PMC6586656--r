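# Independent brute-force oracles used by the property tests. These are
# deliberately naive re-derivations, kept separate from the package's own
# algorithms.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein_str <- function(n) paste(sample(AA20, n, TRUE), collapse = "")
random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                    collapse = "")

# --- six-frame ORF oracle: plain double loop over start/stop codons -------
oracle_orfs <- function(seq_fwd, min_aa) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_fwd)))
  L <- nchar(seq_fwd)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_fwd else rc
    for (i in seq_len(max(0L, L - 5L))) {
      if (substr(s, i, i + 2L) != "ATG") next
      j <- i + 3L
      while (j + 2L <= L) {
        cod <- substr(s, j, j + 2L)
        if (cod %in% stops) break
        j <- j + 3L
      }
      if (j + 2L > L) next
      if (!substr(s, j, j + 2L) %in% stops) next
      aa_len <- (j + 2L - i + 1L) / 3L - 1L
      if (aa_len < min_aa) next
      if (strand == "+") {
        out[[length(out) + 1L]] <- c(i, j + 2L, 1L)
      } else {
        out[[length(out) + 1L]] <- c(L - (j + 2L) + 1L, L - i + 1L, 2L)
      }
    }
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer(),
                                      strand = character()))
  m <- do.call(rbind, out)
  df <- data.frame(start = m[, 1L], end = m[, 2L],
                   strand = c("+", "-")[m[, 3L]])
  df[order(df$start, df$end, df$strand), ]
}

# --- per-position set-membership motif oracle -----------------------------
oracle_scan <- function(seq_str, pattern) {
  chars <- strsplit(seq_str, "")[[1L]]
  plen <- length(pattern$positions)
  L <- length(chars)
  if (plen > L) return(integer(0))
  starts <- switch(pattern$anchor,
                   anywhere = seq_len(L - plen + 1L),
                   n_terminus = 1L,
                   c_terminus = L - plen + 1L)
  hits <- integer(0)
  for (st in starts) {
    mm <- 0L
    for (j in seq_len(plen)) {
      set <- pattern$positions[[j]]
      if (identical(set, "X")) next
      if (!chars[st + j - 1L] %in% set) mm <- mm + 1L
    }
    if (mm <= pattern$max_mismatches) hits <- c(hits, st)
  }
  hits
}

random_pattern <- function() {
  plen <- sample(3:10, 1L)
  notation <- character(0)
  for (j in seq_len(plen)) {
    kind <- sample(c("fixed", "wild", "alt"), 1L,
                   prob = c(0.6, 0.2, 0.2))
    notation <- c(notation, switch(kind,
      fixed = sample(AA20, 1L),
      wild = "X",
      alt = {
        res <- sample(AA20, 2L)
        paste0(res[1L], "(", res[2L], ")")
      }))
  }
  parse_motif(paste(notation, collapse = ""),
              max_mismatches = sample(0:2, 1L))
}

# --- brute-force HSE run enumerator ---------------------------------------
# Enumerates every alternating pentamer run (any start, any length, either
# starting class), with at most one core mismatch in total, then keeps runs
# that are not contained in a longer valid run of the same phase.
oracle_hse <- function(seq_str, min_units = 3L) {
  chars <- strsplit(seq_str, "")[[1L]]
  L <- length(chars)
  dist_to <- function(at, core) sum(chars[(at + 1L):(at + 3L)] != core)
  cores <- list(NTTCN = c("T", "T", "C"), NGAAN = c("G", "A", "A"))
  runs <- list()
  for (i in seq_len(max(0L, L - 4L))) {
    for (first in c("NTTCN", "NGAAN")) {
      u <- 0L; total <- 0L
      repeat {
        at <- i + 5L * u
        if (at + 4L > L) break
        cls <- if (u %% 2L == 0L) first else setdiff(names(cores), first)
        d <- dist_to(at, cores[[cls]])
        if (d > 1L || total + d > 1L) break
        total <- total + d
        u <- u + 1L
      }
      n_units <- u
      if (n_units < 2L) next
      # recompute total for the full run
      tt <- 0L
      for (k in seq_len(n_units)) {
        cls <- if (k %% 2L == 1L) first else setdiff(names(cores), first)
        tt <- tt + dist_to(i + 5L * (k - 1L), cores[[cls]])
      }
      cls_ok <- (n_units >= 3L && tt <= 1L) ||
        (n_units == 2L && tt == 0L && min_units <= 2L)
      if (!cls_ok || n_units < min_units) next
      runs[[length(runs) + 1L]] <-
        list(start = i, end = i + 5L * n_units - 1L, n = n_units,
             mism = tt)
    }
  }
  if (!length(runs)) return(data.frame(start = integer(), end = integer(),
                                       n_units = integer(),
                                       mism = integer(),
                                       class = character()))
  df <- unique(data.frame(start = vapply(runs, `[[`, integer(1L), "start"),
                          end = vapply(runs, `[[`, numeric(1L), "end"),
                          n_units = vapply(runs, `[[`, integer(1L), "n"),
                          mism = vapply(runs, `[[`, integer(1L), "mism")))
  # drop runs contained in another run of the same phase
  keep <- vapply(seq_len(nrow(df)), function(r) {
    same_phase <- (df$start - df$start[r]) %% 5L == 0L
    !any(same_phase & df$start <= df$start[r] & df$end >= df$end[r] &
           (df$start < df$start[r] | df$end > df$end[r]))
  }, logical(1L))
  df <- df[keep, , drop = FALSE]
  df$class <- ifelse(df$n_units >= 3L & df$mism == 0L, "canonical",
                     "hse_like")
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# --- exact Mann-Whitney oracle by pair counting over all labelings --------
oracle_mw_p <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  u_of <- function(x, y) {
    u <- 0
    for (xi in x) for (yj in y) {
      u <- u + (xi > yj) + 0.5 * (xi == yj)
    }
    u
  }
  u_obs <- u_of(a, b)
  labelings <- combn(n + m, n)
  dev_obs <- abs(u_obs - n * m / 2)
  count <- 0L
  for (col in seq_len(ncol(labelings))) {
    ia <- labelings[, col]
    u <- u_of(pooled[ia], pooled[-ia])
    if (abs(u - n * m / 2) >= dev_obs - 1e-9) count <- count + 1L
  }
  count / ncol(labelings)
}

make_protein_record <- function(s, id = "p") seq_record(id, s, "protein")
make_dna_record <- function(s, id = "d") seq_record(id, s, "dna")

# random complete CDS: ATG + k non-stop codons + stop
random_cds <- function(n_codons_inner) {
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1L, paste,
                      collapse = "")
  sense <- setdiff(all_codons, stops)
  paste0("ATG", paste(sample(sense, n_codons_inner, TRUE), collapse = ""),
         sample(stops, 1L))
}
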