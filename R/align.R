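# Pairwise alignment, significance filtering, the FAO/WHO linear-window
# rule, and the anchored three-sequence mapping used by the epitope stage.
#
# BLASTP/MAFFT of the original pipeline are replaced by in-process
# Needleman-Wunsch / Smith-Waterman (BLOSUM62, affine gaps open 11 extend 1)
# with Karlin-Altschul statistics, so results are bit-reproducible and need
# no external tools.

# Karlin-Altschul gapped constants for BLOSUM62 with gap open 11 / extend 1
KA_LAMBDA <- 0.267
KA_K <- 0.041

blosum62 <- function() {
  m <- .allerscreen_env$BLOSUM62
  if (is.null(m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    .allerscreen_env$BLOSUM62 <- m
  }
  m
}

# J/O/U have no BLOSUM62 row; treat them as X for alignment purposes
sanitize_for_align <- function(s) chartr("JOU", "XXX", toupper(s))

#' Global pairwise alignment
#'
#' Needleman-Wunsch with BLOSUM62 scoring and affine gap penalties
#' (open 11, extend 1), including end-gap penalties. Identity is the number
#' of identical columns divided by the total alignment length (gap columns
#' included).
#'
#' @param a,b Non-empty amino-acid strings.
#' @return List with `aligned_a`, `aligned_b` (equal-length gapped strings,
#'   `-` for gaps), `score`, `length` (alignment columns), `matches`
#'   (identical columns) and `identity`.
#' @export
#' @examples
#' global_align("MKVLAT", "MKVAT")$identity
global_align <- function(a, b) {
  assert_string(a); assert_string(b)
  if (!nchar(a) || !nchar(b)) stop("sequences must be non-empty", call. = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sanitize_for_align(a)),
    Biostrings::AAString(sanitize_for_align(b)),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1)
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  ca <- seq_chars(al_a); cb <- seq_chars(al_b)
  matches <- sum(ca == cb & ca != "-")
  list(aligned_a = al_a, aligned_b = al_b,
       score = Biostrings::score(pa), length = length(ca),
       matches = matches, identity = matches / length(ca))
}

# global identities of one sequence against many (vectorized over `targets`);
# denominator is the full alignment length including end-gap columns
alignment_identity <- function(query, targets) {
  if (!length(targets)) return(numeric())
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(sanitize_for_align(targets)),
    Biostrings::AAString(sanitize_for_align(query)),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1)
  Biostrings::nmatch(pa) / padded_length(pa, nchar(targets), nchar(query))
}

# alignment length including end gaps: P + S - aligned pairs
padded_length <- function(pa, P, S) {
  P + S - (Biostrings::nmatch(pa) + Biostrings::nmismatch(pa))
}

#' Local similarity search against a sequence database
#'
#' Smith-Waterman local alignment of the query against every database
#' record, with significance estimated by the Karlin-Altschul formula
#' `E = K * m * n * exp(-lambda * S)` using the published gapped BLOSUM62
#' constants (lambda = 0.267, K = 0.041; `m`, `n` are the query and target
#' lengths). Unlike BLASTP no database-size correction is applied, so
#' E-values near the cutoff may differ from BLASTP's.
#'
#' @param query Amino-acid string.
#' @param db A [sequence_database()].
#' @param e_max E-value cutoff (default 0.001); only hits with `E < e_max`
#'   are returned.
#' @param query_id Query id used in the result table.
#' @return Object of class `AlignmentHits`: data frame with columns
#'   `query_id`, `target_id`, `score`, `bitscore`, `evalue`, `qstart`,
#'   `qend`, `tstart`, `tend` (1-based inclusive local-alignment intervals),
#'   ranked by increasing E then decreasing score then target id; zero rows
#'   when nothing passes the cutoff. The first row is the best hit.
#' @export
search_db <- function(query, db, e_max = 0.001, query_id = "query") {
  stopifnot(inherits(db, "SequenceDatabase"))
  assert_number(e_max, lower = 1e-300)
  empty <- data.frame(query_id = character(), target_id = character(),
                      score = numeric(), bitscore = numeric(),
                      evalue = numeric(), qstart = integer(), qend = integer(),
                      tstart = integer(), tend = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("AlignmentHits", "data.frame")
  if (!nrow(db) || !nchar(query)) return(empty)
  qs <- Biostrings::AAString(sanitize_for_align(query))
  ts <- Biostrings::AAStringSet(sanitize_for_align(db$sequence))
  # scores first (cheap); full alignments only for records passing e_max
  S <- Biostrings::pairwiseAlignment(
    ts, qs, type = "local", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
  m <- nchar(query)
  n <- nchar(db$sequence)
  E <- KA_K * m * n * exp(-KA_LAMBDA * S)
  bits <- (KA_LAMBDA * S - log(KA_K)) / log(2)
  pass <- which(E < e_max)
  if (!length(pass)) return(empty)
  pa <- Biostrings::pairwiseAlignment(
    ts[pass], qs, type = "local", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1)
  tr <- Biostrings::pattern(pa)
  qr <- Biostrings::subject(pa)
  hits <- data.frame(query_id = query_id, target_id = db$id[pass],
                     score = S[pass], bitscore = bits[pass],
                     evalue = E[pass],
                     qstart = Biostrings::start(qr),
                     qend = Biostrings::end(qr),
                     tstart = Biostrings::start(tr),
                     tend = Biostrings::end(tr),
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$evalue, -hits$score, hits$target_id), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("AlignmentHits", "data.frame")
  hits
}

# best window identity over the columns of one fixed alignment
window_scan_alignment <- function(aligned_a, aligned_b, window) {
  ca <- seq_chars(aligned_a); cb <- seq_chars(aligned_b)
  L <- length(ca)
  w <- min(window, L)
  idc <- as.integer(ca == cb & ca != "-")
  cs <- cumsum(c(0L, idc))
  sums <- cs[(w + 1L):(L + 1L)] - cs[1:(L - w + 1L)]
  best <- which.max(sums)  # leftmost maximum
  list(identity = sums[best] / w, matches = sums[best],
       window_start = as.integer(best), window_cols = as.integer(w))
}

#' FAO/WHO linear-window rule
#'
#' Globally aligns query and allergen, slides a window of `window` alignment
#' columns across the alignment and reports the best per-window identity
#' (identical columns / window; gap columns count as mismatches). If the
#' alignment is shorter than `window` columns, the whole alignment is used
#' as one window, which lets short known allergens self-match. A hit is
#' declared when the best window identity is at least `min_identity`
#' (inclusive: "at least 35%").
#'
#' @param query,allergen Amino-acid strings.
#' @param window Window length in alignment columns (default 80).
#' @param min_identity Identity threshold in (0, 1] (default 0.35).
#' @return List with `hit` (logical), `identity` (best window identity),
#'   `matches`, `window_start` (leftmost maximizing alignment column on
#'   ties), `window_cols` (effective window length).
#' @export
linear_window_hit <- function(query, allergen, window = 80L,
                              min_identity = 0.35) {
  window <- as.integer(assert_number(window, lower = 1))
  assert_number(min_identity, lower = 1e-9, upper = 1)
  al <- global_align(query, allergen)
  ws <- window_scan_alignment(al$aligned_a, al$aligned_b, window)
  c(list(hit = ws$identity >= min_identity), ws)
}

# vectorized linear-window scan of one query against a whole database.
# Avoids per-alignment aligned-string extraction (which dominates runtime at
# database scale) by reconstructing the alignment-column positions of the
# identical residue pairs from the compact alignment representation:
# aligned ranges, interior indel ranges (each in its own sequence's
# ungapped coordinates) and the mismatch table. The best window always
# starts at a match column, so the sliding maximum over match positions
# equals the full column scan; equivalence with window_scan_alignment() is
# asserted in the test suite.
linear_window_scan <- function(query, db, window = 80L) {
  if (!nrow(db)) return(numeric())
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(sanitize_for_align(db$sequence)),
    Biostrings::AAString(sanitize_for_align(query)),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1)
  L_pad <- padded_length(pa, nchar(db$sequence), nchar(query))
  pat <- Biostrings::pattern(pa)
  sub <- Biostrings::subject(pa)
  gp <- Biostrings::indel(pat)   # gaps in target, target coordinates
  gs <- Biostrings::indel(sub)   # gaps in query, query coordinates
  ps <- Biostrings::start(pat); pe <- Biostrings::end(pat)
  ss <- Biostrings::start(sub)
  mt <- Biostrings::mismatchTable(pa)
  mism <- split(mt$PatternStart, factor(mt$PatternId, levels = seq_len(length(pa))))
  # indel starts are relative to the aligned core (range-clipped
  # coordinates); mismatchTable positions are in the original sequences
  vapply(seq_len(length(pa)), function(i) {
    w_eff <- min(window, L_pad[i])
    if (pe[i] < ps[i]) return(0)           # no aligned core at all
    kk <- seq_len(pe[i] - ps[i] + 1L)      # core-relative target positions
    gpi <- gp[[i]]
    cumP <- c(0, cumsum(Biostrings::width(gpi)))
    colP <- kk + cumP[findInterval(kk, Biostrings::start(gpi)) + 1L]
    gsi <- gs[[i]]
    if (length(gsi)) {
      # columns occupied by each query gap (= unmatched target residues)
      wg <- Biostrings::width(gsi)
      hi <- Biostrings::start(gsi) + cumsum(wg) - 1L
      lo <- hi - wg + 1L
      slot <- findInterval(colP, lo)
      in_gap <- slot >= 1L & colP <= hi[pmax(slot, 1L)]
    } else {
      in_gap <- rep(FALSE, length(kk))
    }
    is_match <- !in_gap & !((kk + ps[i] - 1L) %in% mism[[i]])
    mc <- colP[is_match]
    if (!length(mc)) return(0)
    j <- findInterval(mc + w_eff - 1L, mc)
    max(j - seq_along(mc) + 1L) / w_eff
  }, numeric(1L))
}

#' Anchored three-sequence mapping
#'
#' Merges two global alignments (query vs. structure representative,
#' allergen vs. representative) using the representative sequence as the
#' coordinate anchor: every representative residue maps to at most one query
#' residue and at most one allergen residue (or a gap). This stands in for
#' the multiple alignment of query, best structure hit and best allergen
#' hit: epitope definitions live in representative coordinates, so only
#' rep-anchored columns matter.
#'
#' @param query,allergen Amino-acid strings.
#' @param rep Representative (structure) sequence.
#' @return Data frame with one row per representative residue: `rep_pos`
#'   (1-based), `rep_res`, `query_res`, `allergen_res` (`NA` for a gap).
#' @export
anchored_triple_map <- function(query, rep, allergen) {
  map_to_rep <- function(other) {
    al <- global_align(other, rep)
    co <- seq_chars(al$aligned_a); cr <- seq_chars(al$aligned_b)
    keep <- cr != "-"
    out <- co[keep]
    out[out == "-"] <- NA_character_
    out
  }
  rep_res <- seq_chars(toupper(rep))
  data.frame(rep_pos = seq_along(rep_res), rep_res = rep_res,
             query_res = map_to_rep(query),
             allergen_res = map_to_rep(allergen),
             stringsAsFactors = FALSE)
}

#' Best epitope identity between query and allergen over a structure
#'
#' For every epitope patch of the table, counts the member residues whose
#' mapped query residue equals the mapped allergen residue (a gap on either
#' side counts as non-identical) and divides by the full epitope size, so
#' unaligned surface regions dilute identity. Returns the epitope with the
#' highest identity; ties are broken by larger epitope, then smaller center
#' index.
#'
#' @param mapping An [anchored_triple_map()]; `rep_pos` must be in the same
#'   coordinate system as the epitope member indices (see
#'   [reference_bundle()] for the renumbering of structure residues).
#' @param table An [build_epitope_table()] result.
#' @return `NULL` when the table has no epitopes (caller falls back), else a
#'   list with `structure_id`, `center`, `size`, `identical`, `identity`.
#' @export
best_epitope_identity <- function(mapping, table) {
  stopifnot(inherits(table, "EpitopeTable"))
  if (!length(table$epitopes)) return(NULL)
  same <- !is.na(mapping$query_res) & !is.na(mapping$allergen_res) &
    mapping$query_res == mapping$allergen_res
  pos_ok <- mapping$rep_pos[same]
  centers <- as.integer(names(table$epitopes))
  stats <- lapply(seq_along(centers), function(i) {
    members <- table$epitopes[[i]]
    ident <- sum(members %in% pos_ok)
    c(identity = ident / length(members), size = length(members),
      identical = ident)
  })
  identity <- vapply(stats, `[[`, numeric(1L), "identity")
  size <- vapply(stats, `[[`, numeric(1L), "size")
  best <- order(-identity, -size, centers)[1L]
  list(structure_id = table$structure_id, center = centers[best],
       size = as.integer(size[best]),
       identical = as.integer(stats[[best]][["identical"]]),
       identity = identity[best])
}

#' Export alignment hits as TSV
#'
#' @param hits An [search_db()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  stopifnot(inherits(hits, "AlignmentHits"))
  utils::write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
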