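# Run code under a temporary RNG state so generators are deterministic in
# their seed and leave the caller's RNG untouched.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

random_aa <- function(n) paste(sample(AA_LETTERS, n, replace = TRUE),
                               collapse = "")
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

plant <- function(s, at, motif) {
  paste0(substr(s, 1L, at - 1L), motif,
         substr(s, at + nchar(motif), nchar(s)))
}

ATP_INDUCIBLE_VARIANTS <- as.vector(outer(
  as.vector(outer(c("S", "A"), "EAYLG", paste0)),
  as.vector(outer(c("K", "G"), c("E", "A"), paste0)), paste0))

#' Generate a synthetic Hsp/Hsc70-like protein
#'
#' Builds a random-backbone protein with type-appropriate signatures
#' planted at domain-consistent positions mirroring the canonical layout:
#' the N-terminal hexamer at 1-6, the family signatures and the
#' ATP/phosphate/NLS sites inside the nucleotide binding domain, the
#' RARFEEL/RARFEEM signature past the NBD, and GPTIEEVD ending in the EEVD
#' tail at the C-terminus (omitted for the non-cytosolic kind). The
#' backbone is resampled if it accidentally contains a diagnostic motif
#' of the opposite type, so a zero-mutation fixture is guaranteed to
#' classify as its planted type. Optionally, `mutations` point mutations
#' are placed inside planted motifs to degrade them.
#'
#' @param seed Integer seed; identical arguments give identical output.
#' @param type `"inducible"`, `"cognate"` or `"noncytosolic"` (an
#'   inducible-type sequence lacking the EEVD tail).
#' @param length Protein length (>= 320; default 641).
#' @param mutations Number of point mutations planted inside motifs.
#' @param id Record id.
#' @return A protein [seq_record] with attribute `truth`: list with
#'   `type`, `motifs` (data frame of name, start, end) and `mutated`
#'   (positions).
#' @export
gen_protein <- function(seed, type = c("inducible", "cognate",
                                       "noncytosolic"),
                        length = 641L, mutations = 0L, id = NULL) {
  type <- match.arg(type)
  stopifnot(length >= 320L)
  if (is.null(id)) id <- paste0("syn_", type, "_", seed)
  with_seed(seed, {
    hexamer <- if (type == "cognate") "MSKATA" else "MRAKST"
    atp <- if (type == "cognate") "ADAYLGTN" else "SEAYLGKE"
    rarfee <- if (type == "cognate") "RARFEEL" else "RARFEEM"
    plants <- data.frame(
      name = c("Nterm", "IDLGTTYS", "TVPAYFND", "NEPTAA", "ATP",
               "phosphate_binding", "NLS_KK", "NLS_RRLRT", "RARFEE"),
      motif = c(hexamer, "IDLGTTYS", "TVPAYFND", "NEPTAA", atp,
                "IFDLGGGTFDVSIL", "KK", "RRLRT", rarfee),
      start = c(1L, 10L, 40L, 70L, 131L, 195L, 246L, 257L, 300L),
      stringsAsFactors = FALSE)
    if (type != "noncytosolic") {
      plants <- rbind(plants, data.frame(name = "GPTIEEVD",
                                         motif = "GPTIEEVD",
                                         start = length - 7L,
                                         stringsAsFactors = FALSE))
    }
    plants$end <- plants$start + nchar(plants$motif) - 1L
    if (any(plants$end > length)) stop("protein too short for the planted layout",
                                       call. = FALSE)
    if (any(utils::head(order(plants$start), -1) != seq_len(nrow(plants) - 1L)) ||
        any(plants$start[-1L] <= plants$end[-nrow(plants)])) {
      stop("planted motifs overlap", call. = FALSE)
    }
    opposing <- if (type == "cognate") {
      ATP_INDUCIBLE_VARIANTS
    } else {
      c("ADAYLGTN", "RARFEEL")
    }
    s <- NULL
    for (try in 1:100) {
      cand <- random_aa(length)
      for (i in seq_len(nrow(plants))) {
        cand <- plant(cand, plants$start[i], plants$motif[i])
      }
      clean <- !any(vapply(opposing, grepl, logical(1L), cand,
                           fixed = TRUE))
      if (type == "noncytosolic") {
        clean <- clean && substr(cand, length - 3L, length) != "EEVD"
      }
      if (clean) { s <- cand; break }
    }
    if (is.null(s)) stop("could not generate a conflict-free backbone",
                         call. = FALSE)
    mutated <- integer(0)
    if (mutations > 0L) {
      footprint <- unlist(mapply(seq, plants$start, plants$end,
                                 SIMPLIFY = FALSE))
      mutated <- sample(footprint, min(mutations, base::length(footprint)))
      for (pos in mutated) {
        cur <- substr(s, pos, pos)
        repl <- sample(setdiff(AA_LETTERS, cur), 1L)
        s <- paste0(substr(s, 1L, pos - 1L), repl,
                    substr(s, pos + 1L, nchar(s)))
      }
    }
    rec <- seq_record(id, s, "protein",
                      description = paste0("synthetic ", type, " fixture"))
    attr(rec, "truth") <- list(type = type,
                               motifs = plants[, c("name", "start", "end")],
                               mutated = sort(mutated))
    rec
  })
}

make_hse_element <- function(n_units = 3L, hse_class = c("canonical",
                                                         "hse_like")) {
  hse_class <- match.arg(hse_class)
  first_ttc <- sample(c(TRUE, FALSE), 1L)
  units <- character(n_units)
  for (k in seq_len(n_units)) {
    core <- if (xor(k %% 2L == 1L, !first_ttc)) "TTC" else "GAA"
    units[k] <- paste0(sample(c("A", "C", "G", "T"), 1L), core,
                       sample(c("A", "C", "G", "T"), 1L))
  }
  if (hse_class == "hse_like") {
    # one core mismatch in the first (flanking) unit
    u <- strsplit(units[1L], "", fixed = TRUE)[[1L]]
    pos <- sample(2:4, 1L)
    u[pos] <- sample(setdiff(c("A", "C", "G", "T"), u[pos]), 1L)
    units[1L] <- paste(u, collapse = "")
  }
  paste(units, collapse = "")
}

#' Generate a synthetic promoter with planted heat shock elements
#'
#' Plants HSEs of known class at exact distances upstream of an ORF start
#' (an ATG at the 3' end of the sequence) on a random background that is
#' rejection-sampled until a scan of the full sequence recovers exactly
#' the planted elements — no accidental runs, no extensions of planted
#' runs. Retries are capped and failure is an error rather than a silent
#' degradation of the guarantee.
#'
#' @param seed Integer seed.
#' @param distances Integer vector of upstream distances in bp (bases
#'   strictly between the element end and the ATG); may be empty.
#' @param classes `"canonical"` or `"hse_like"`, recycled over
#'   `distances`.
#' @param strands `"+"`/`"-"`, recycled; minus-strand elements are planted
#'   as the reverse complement (HSE runs are reverse-complement
#'   symmetric, so the planted interval and class are recovered either
#'   way).
#' @param length Total sequence length; default fits the largest distance.
#' @param id Record id.
#' @return A DNA [seq_record] with attribute `truth`: list with
#'   `elements` (data frame start, end, class, strand, distance) and
#'   `orf_start`.
#' @export
gen_promoter <- function(seed, distances = 1187L, classes = "canonical",
                         strands = "+", length = NULL, id = NULL) {
  n_el <- base::length(distances)
  if (n_el) {
    classes <- rep_len(classes, n_el)
    strands <- rep_len(strands, n_el)
  }
  if (is.null(length)) {
    length <- if (n_el) max(distances) + 15L + 120L else 1000L
  }
  if (is.null(id)) id <- paste0("syn_promoter_", seed)
  orf_start <- length - 2L
  el_len <- 15L  # three pentamer units
  ends <- if (n_el) orf_start - distances - 1L else integer(0)
  starts <- ends - el_len + 1L
  if (n_el && (any(starts < 1L) ||
               any(ends + 1L > orf_start))) {
    stop("requested distances do not fit in the sequence", call. = FALSE)
  }
  if (n_el > 1L) {
    o <- order(starts)
    if (any(starts[o][-1L] <= ends[o][-n_el] + 5L)) {
      stop("planted elements overlap or abut in phase", call. = FALSE)
    }
  }
  with_seed(seed, {
    for (try in 1:100) {
      s <- random_dna(length)
      s <- plant(s, orf_start, "ATG")
      if (n_el) {
        for (i in seq_len(n_el)) {
          el <- make_hse_element(3L, classes[i])
          if (strands[i] == "-") el <- revcomp(el)
          s <- plant(s, starts[i], el)
        }
      }
      rec <- seq_record(id, s, "dna",
                        description = "synthetic promoter fixture")
      hits <- find_hse(rec, min_units = 3L)
      ok <- nrow(hits) == n_el &&
        (!n_el || (all(sort(hits$start) == sort(starts)) &&
                     all(sort(hits$end) == sort(ends)) &&
                     all(hits$hse_class[order(hits$start)] ==
                           classes[order(starts)])))
      if (ok) {
        attr(rec, "truth") <- list(
          elements = data.frame(start = starts, end = ends,
                                class = if (n_el) classes else character(0),
                                strand = if (n_el) strands else character(0),
                                distance = distances,
                                stringsAsFactors = FALSE),
          orf_start = orf_start)
        return(rec)
      }
    }
    stop("could not generate an accident-free promoter background in 100 tries",
         call. = FALSE)
  })
}

#' Generate a synthetic differential-expression table
#'
#' Exactly `n_pass` rows jointly satisfy the candidate filter
#' ([filter_config()] defaults); the remaining rows each fail at least
#' one criterion, cycling over the single-failure modes (fold change too
#' small, adjusted p too large, abundance too low, missing adjusted p).
#'
#' @param seed Integer seed.
#' @param n_total Total rows.
#' @param n_pass Rows that pass the filter jointly (`<= n_total`).
#' @param conditions Condition names for the TPM columns.
#' @return Data frame `transcript_id`, `annotation`, `tpm_<condition>`
#'   columns, `log2fc`, `pvalue`, `padj`; attribute `truth` holds the
#'   logical `planted_pass` vector.
#' @export
gen_de_table <- function(seed, n_total = 155L, n_pass = 23L,
                         conditions = c("control", "heat_shock")) {
  stopifnot(n_total >= n_pass, n_pass >= 0L)
  with_seed(seed, {
    n_fail <- n_total - n_pass
    pass <- c(rep(TRUE, n_pass), rep(FALSE, n_fail))
    modes <- if (n_fail) rep_len(c("lfc", "padj", "tpm", "padj_missing"),
                                 n_fail) else character(0)
    lfc <- numeric(n_total); padj <- numeric(n_total)
    tpm <- matrix(0, n_total, base::length(conditions))
    lfc[pass] <- sample(c(-1, 1), n_pass, TRUE) * runif(n_pass, 1.5, 11)
    padj[pass] <- 10^runif(n_pass, -20, -4)
    tpm[pass, ] <- runif(n_pass * ncol(tpm), 250, 5000)
    fail_idx <- which(!pass)
    for (j in seq_along(fail_idx)) {
      i <- fail_idx[j]
      lfc[i] <- sample(c(-1, 1), 1L) * runif(1, 1.5, 11)
      padj[i] <- 10^runif(1, -20, -4)
      tpm[i, ] <- runif(ncol(tpm), 250, 5000)
      switch(modes[j],
             lfc = { lfc[i] <- runif(1, -1, 1) },
             padj = { padj[i] <- runif(1, 0.002, 0.5) },
             tpm = { tpm[i, ] <- runif(ncol(tpm), 0.1, 150) },
             padj_missing = { padj[i] <- NA_real_ })
    }
    pvalue <- padj * runif(n_total, 0.1, 1)
    ord <- sample.int(n_total)
    out <- data.frame(
      transcript_id = sprintf("TR_%04d", seq_len(n_total)),
      annotation = sample(c("heat shock protein 70", "heat shock cognate 71",
                            "hsp70-like protein"), n_total, TRUE),
      stringsAsFactors = FALSE)
    for (k in seq_along(conditions)) {
      out[[paste0("tpm_", conditions[k])]] <- tpm[, k]
    }
    out$log2fc <- lfc
    out$pvalue <- pvalue
    out$padj <- padj
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "truth") <- list(planted_pass = pass[ord])
    out
  })
}

#' Generate a synthetic qPCR Cq table
#'
#' Two groups (control and heat shock) with a fixed-mean reference-gene
#' Cq and target-gene Cq shifted by `effect_size` delta-Cq units in the
#' heat-shock group (negative effect = induction). Optional planted QC
#' failures: reference gene above the detection cutoff, or a minus-RT
#' control below it.
#'
#' @param seed Integer seed.
#' @param n_per_group Biological replicates per group (>= 4).
#' @param effect_size Heat-shock shift of the target delta-Cq, in cycles.
#' @param target_genes Character vector of target gene names.
#' @param ref_mean Mean reference-gene Cq.
#' @param baseline_delta Control-group target minus reference Cq.
#' @param sd Within-group Cq standard deviation.
#' @param n_below_detection,n_contaminated Control samples planted to fail
#'   QC with reference Cq 31 / minus-RT Cq 28.
#' @return Data frame `sample_id`, `group`, `gene`, `cq`, `minus_rt_cq`;
#'   attribute `truth` lists the planted bad samples and effect size.
#' @export
gen_cq_table <- function(seed, n_per_group = 6L, effect_size = -6,
                         target_genes = "hsp70", ref_mean = 20,
                         baseline_delta = 5, sd = 0.3,
                         n_below_detection = 0L, n_contaminated = 0L) {
  stopifnot(n_per_group >= 4L,
            n_below_detection + n_contaminated <= n_per_group)
  with_seed(seed, {
    samples <- data.frame(
      sample_id = c(sprintf("C%d", seq_len(n_per_group)),
                    sprintf("H%d", seq_len(n_per_group))),
      group = rep(c("control", "heat_shock"), each = n_per_group),
      stringsAsFactors = FALSE)
    rows <- list()
    bad <- character(0)
    for (i in seq_len(nrow(samples))) {
      sid <- samples$sample_id[i]; grp <- samples$group[i]
      ref_cq <- rnorm(1, ref_mean, sd)
      minus_rt <- NA_real_
      if (grp == "control") {
        idx <- as.integer(sub("C", "", sid))
        if (idx <= n_below_detection) {
          ref_cq <- 31; bad <- c(bad, sid)
        } else if (idx <= n_below_detection + n_contaminated) {
          minus_rt <- 28; bad <- c(bad, sid)
        }
      }
      rows[[base::length(rows) + 1L]] <- data.frame(
        sample_id = sid, group = grp, gene = "gapdh", cq = ref_cq,
        minus_rt_cq = minus_rt, stringsAsFactors = FALSE)
      for (g in target_genes) {
        shift <- if (grp == "heat_shock") effect_size else 0
        rows[[base::length(rows) + 1L]] <- data.frame(
          sample_id = sid, group = grp, gene = g,
          cq = ref_cq + baseline_delta + shift + rnorm(1, 0, sd),
          minus_rt_cq = NA_real_, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(planted_bad = bad,
                               effect_size = effect_size)
    out
  })
}
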