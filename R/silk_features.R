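# Silk protein characterization: isoelectric point, hydropathy profiles,
# poly-alanine / spacer decomposition, GGGX-grammar motif inventory.

#' Default side-chain and terminal pKa values
#'
#' An electrophoresis-calibrated set: side chains C 8.5, D 3.9, E 4.1,
#' H 6.5, K 10.8, R 12.5, Y 10.1; N-terminus 8.6, C-terminus 3.6.
#'
#' @return Named numeric vector with entries `C D E H K R Y Nterm Cterm`.
#' @export
default_pka <- function() {
  c(C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1,
    Nterm = 8.6, Cterm = 3.6)
}

#' Isoelectric point of a protein sequence
#'
#' Finds the pH at which the Henderson-Hasselbalch net charge (sum over
#' ionizable side chains plus the two termini) crosses zero, by bisection
#' on [0, 14] to a pH tolerance of 1e-4. `X` residues are ignored for
#' charge.
#'
#' @param seq protein string (standard residues plus `X`).
#' @param pka named pKa vector as in [default_pka()].
#' @return The pI in pH units.
#' @export
compute_pI <- function(seq, pka = default_pka()) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty sequence")
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", seq))
    stop("non-standard residue in sequence")
  res <- strsplit(seq, "")[[1L]]
  counts <- table(res)
  nof <- function(r) if (r %in% names(counts)) as.numeric(counts[[r]]) else 0
  basic <- c(Nterm = 1, K = nof("K"), R = nof("R"), H = nof("H"))
  acidic <- c(Cterm = 1, D = nof("D"), E = nof("E"),
              C = nof("C"), Y = nof("Y"))
  net_charge <- function(ph) {
    pos <- sum(basic * 1 / (1 + 10^(ph - pka[names(basic)])))
    neg <- sum(acidic * 1 / (1 + 10^(pka[names(acidic)] - ph)))
    pos - neg
  }
  lo <- 0; hi <- 14
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (net_charge(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Sliding-window hydropathy profile
#'
#' Arithmetic mean of the residue scale over a sliding window of odd width.
#' With `hydrophilicity = TRUE` the profile is sign-flipped (hydrophilicity
#' as negated Kyte-Doolittle).
#'
#' @param seq protein string.
#' @param window odd window width, at most the sequence length.
#' @param scale named residue scale; default [kyte_doolittle()].
#' @param hydrophilicity flip sign of the reported scores.
#' @return List with `positions` (1-based window centers), `scores`,
#'   `window`.
#' @export
hydropathy_profile <- function(seq, window = 9, scale = kyte_doolittle(),
                               hydrophilicity = FALSE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (window %% 2 == 0) stop("window must be odd")
  if (window > n) stop("window larger than sequence")
  res <- strsplit(seq, "")[[1L]]
  vals <- unname(scale[res])
  if (anyNA(vals)) stop("residue missing from scale: ",
                        res[is.na(vals)][1L])
  cs <- c(0, cumsum(vals))
  k <- n - window + 1L
  scores <- (cs[(window + 1):(n + 1)] - cs[1:k]) / window
  if (hydrophilicity) scores <- -scores
  half <- (window - 1L) / 2L
  list(positions = seq_len(k) + half, scores = scores, window = window)
}

#' Global pairwise alignment against a reference
#'
#' Needleman-Wunsch global alignment (end gaps penalized) with BLOSUM62 and
#' affine gaps, via [Biostrings::pairwiseAlignment]. Returns the aligned
#' columns in which neither sequence is gapped, so that downstream
#' composition and hydropathy comparisons are restricted to shared regions.
#'
#' @param ref,query protein strings.
#' @param substitution_matrix scoring matrix name (default `"BLOSUM62"`).
#' @param gap_opening,gap_extension positive gap costs.
#' @return List with `score`, `identity` (over aligned columns), and
#'   `columns`: data.frame `ref_pos`, `query_pos`, `ref_char`, `query_char`
#'   (1-based positions in the ungapped inputs).
#' @export
align_to_reference <- function(ref, query,
                               substitution_matrix = "BLOSUM62",
                               gap_opening = 10, gap_extension = 1) {
  stopifnot(nzchar(ref), nzchar(query))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(query)), Biostrings::AAString(toupper(ref)),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension)
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  rpos <- cumsum(ra != "-")
  qpos <- cumsum(qa != "-")
  both <- ra != "-" & qa != "-"
  cols <- data.frame(ref_pos = rpos[both], query_pos = qpos[both],
                     ref_char = ra[both], query_char = qa[both],
                     stringsAsFactors = FALSE)
  list(score = Biostrings::score(aln),
       identity = if (nrow(cols)) mean(cols$ref_char == cols$query_char) else 0,
       columns = cols)
}

#' Construct a silk protein record
#'
#' A protein sequence with annotated N-terminus and repeat-region spans
#' (0-based, half-open). The N-terminus span must precede the repeat span
#' and both must lie within the sequence.
#'
#' @param id,species identifiers.
#' @param sequence protein string.
#' @param nterm_span,repeat_span integer vectors `c(start, end)`.
#' @return An object of class `silk_protein_record`.
#' @export
silk_protein_record <- function(id, species, sequence,
                                nterm_span = NULL, repeat_span = NULL) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  chk <- function(sp, nm) {
    if (is.null(sp)) return(NULL)
    sp <- as.integer(sp)
    if (length(sp) != 2L || sp[1L] < 0L || sp[2L] > n || sp[1L] >= sp[2L])
      stop("invalid ", nm, " for ", id)
    sp
  }
  nterm_span <- chk(nterm_span, "nterm_span")
  repeat_span <- chk(repeat_span, "repeat_span")
  if (!is.null(nterm_span) && !is.null(repeat_span) &&
      nterm_span[2L] > repeat_span[1L])
    stop("nterm_span must precede repeat_span")
  structure(list(id = id, species = species, sequence = sequence,
                 nterm_span = nterm_span, repeat_span = repeat_span),
            class = "silk_protein_record")
}

#' @export
print.silk_protein_record <- function(x, ...) {
  cat(sprintf("silk_protein_record %s (%s), %d aa\n", x$id, x$species,
              nchar(x$sequence)))
  if (!is.null(x$nterm_span))
    cat(sprintf("  nterm  [%d, %d)\n", x$nterm_span[1], x$nterm_span[2]))
  if (!is.null(x$repeat_span))
    cat(sprintf("  repeat [%d, %d)\n", x$repeat_span[1], x$repeat_span[2]))
  invisible(x)
}

#' Decompose a repeat region into poly-alanine and spacer blocks
#'
#' Maximal runs of `A` of length at least `min_run` become `polyA` blocks;
#' everything between them becomes `spacer` blocks. Blocks tile the repeat
#' span exactly.
#'
#' @param record a [silk_protein_record] with `repeat_span` set.
#' @param min_run minimum alanine run length (default 3).
#' @return data.frame with columns `kind` (`"polyA"`/`"spacer"`), `start`,
#'   `end` (0-based half-open, in sequence coordinates), `subseq`.
#' @export
decompose_repeats <- function(record, min_run = 3) {
  stopifnot(inherits(record, "silk_protein_record"))
  if (is.null(record$repeat_span))
    stop("repeat_span not set on record ", record$id)
  s <- record$repeat_span[1L]; e <- record$repeat_span[2L]
  region <- substr(record$sequence, s + 1L, e)
  res <- strsplit(region, "")[[1L]]
  r <- rle(res == "A")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_polyA <- r$values & r$lengths >= min_run
  kind <- ifelse(is_polyA, "polyA", "spacer")
  # merge adjacent non-polyA stretches (short A runs count as spacer)
  df <- data.frame(kind = kind, start = starts, end = ends,
                   stringsAsFactors = FALSE)
  merged <- list()
  for (i in seq_len(nrow(df))) {
    m <- length(merged)
    if (m > 0 && df$kind[i] == "spacer" && merged[[m]]$kind == "spacer") {
      merged[[m]]$end <- df$end[i]
    } else {
      merged[[m + 1L]] <- as.list(df[i, ])
    }
  }
  out <- do.call(rbind, lapply(merged, as.data.frame))
  out$subseq <- substring(region, out$start, out$end)
  # convert to 0-based half-open sequence coordinates
  out$start <- s + out$start - 1L
  out$end <- s + out$end
  rownames(out) <- NULL
  out[, c("kind", "start", "end", "subseq")]
}

#' Inventory of GGGX / GGX / GX motifs in spacer sequences
#'
#' Greedy, non-overlapping, left-to-right scan of each spacer: at each
#' position GGGX is tried first, then GGX, then GX, where X is any residue
#' other than G. On a match the motif is consumed and its X recorded;
#' otherwise the position is counted as unparsed and the scan advances one
#' residue. Motifs never span spacer boundaries.
#'
#' @param spacer_seqs character vector of spacer subsequences.
#' @return List with `counts` (named: GGGX, GGX, GX), `x_composition`
#'   (per-class residue fraction tables), `unparsed` (residue count) and
#'   `unparsed_fraction`.
#' @export
motif_inventory <- function(spacer_seqs) {
  xs <- list(GGGX = character(0), GGX = character(0), GX = character(0))
  unparsed <- 0L; total <- 0L
  for (sp in spacer_seqs) {
    res <- strsplit(toupper(sp), "")[[1L]]
    n <- length(res); total <- total + n
    i <- 1L
    while (i <= n) {
      matched <- FALSE
      for (g in c(3L, 2L, 1L)) {
        if (i + g <= n && all(res[i:(i + g - 1L)] == "G") &&
            res[i + g] != "G") {
          cls <- c("GX", "GGX", "GGGX")[g]
          xs[[cls]] <- c(xs[[cls]], res[i + g])
          i <- i + g + 1L
          matched <- TRUE
          break
        }
      }
      if (!matched) { unparsed <- unparsed + 1L; i <- i + 1L }
    }
  }
  comp <- lapply(xs, function(v)
    if (length(v)) prop.table(table(v)) else table(character(0)))
  list(counts = vapply(xs, length, integer(1)),
       x_composition = comp,
       unparsed = unparsed,
       unparsed_fraction = if (total > 0) unparsed / total else 0)
}

#' Amino-acid composition
#'
#' Residue fractions over the 20 standard amino acids; `X` is excluded from
#' the denominator.
#'
#' @param seq protein string (possibly restricted to aligned columns).
#' @return Named numeric vector of 20 fractions summing to 1.
#' @export
aa_composition <- function(seq) {
  res <- strsplit(toupper(seq), "")[[1L]]
  res <- res[res != "X" & res != "-"]
  if (length(res) == 0L) stop("empty sequence after exclusions")
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  if (any(!res %in% aas)) stop("non-standard residue: ",
                               res[!res %in% aas][1L])
  tab <- table(factor(res, levels = aas))
  stats::setNames(as.numeric(tab) / length(res), aas)
}

#' Detect N-terminus / repeat-region boundary in a fibroin-like protein
#'
#' The boundary is the start of the first poly-alanine run of length at
#' least `min_run` found at or after `head_length`, capped at `nterm_max`.
#' The N-terminus span is `[0, b)` and the repeat span `[b, length)`.
#'
#' @param seq protein string.
#' @param id,species identifiers for the returned record.
#' @param head_length conserved head length (default 14).
#' @param nterm_max maximum N-terminus length (default 120).
#' @param min_run minimum alanine run (default 3).
#' @return A [silk_protein_record] with both spans set.
#' @export
detect_regions <- function(seq, id = "protein", species = NA_character_,
                           head_length = 14, nterm_max = 120, min_run = 3) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n <= nterm_max)
    stop("sequence shorter than nterm_max; no repeat region to detect")
  res <- strsplit(seq, "")[[1L]]
  runs <- rle(res == "A")
  ends <- cumsum(runs$lengths)
  starts0 <- ends - runs$lengths            # 0-based run starts
  cand <- which(runs$values & runs$lengths >= min_run &
                  starts0 >= head_length)
  if (length(cand) == 0L)
    stop("no poly-alanine run of length >= ", min_run, " found after the ",
         head_length, "-residue head; supply spans manually")
  b <- min(starts0[cand[1L]], nterm_max)
  silk_protein_record(id, species, seq,
                      nterm_span = c(0L, b), repeat_span = c(b, n))
}
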