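# The decision cascade from query sequence to strong/weak/no evidence,
# batch execution with CSV reporting, and the self-screen sensitivity check.

#' Workflow configuration
#'
#' Houses every numeric parameter of the assessment cascade. All thresholds
#' must be positive; fractions lie in (0, 1].
#'
#' @param entropy_min Hexamer entropy threshold in bits (default 0.34).
#' @param kmer_k Hexamer length (default 6).
#' @param kmer_min_hits Distinct shared hexamers required for a k-mer hit
#'   (default 3).
#' @param qrepeat_window Q-repeat window length (default 9).
#' @param qrepeat_sd_multiplier SD multiplier of the Q-repeat threshold
#'   (default 1).
#' @param surface_cutoff Surface distance cutoff in Angstrom (default 2.55).
#' @param probe Solvent probe radius in Angstrom (default 1.4).
#' @param epitope_radius Epitope patch radius in Angstrom (default 12).
#' @param epitope_min_size Minimum epitope size in residues (default 13).
#' @param e_max E-value cutoff for similarity searches (default 0.001).
#' @param epitope_strong_identity Epitope identity for strong evidence
#'   (default 0.93).
#' @param window_len Linear window length in alignment columns (default 80).
#' @param window_min_identity Linear-window identity threshold (default
#'   0.35).
#' @param cluster_identity Reference clustering identity (default 0.70).
#' @param max_batch Maximum queries per batch (default 50).
#' @param min_query_len Minimum evaluable query length in residues (default
#'   8, the span of three consecutive hexamer hits); shorter queries are
#'   reported as no evidence with a "too short" note.
#' @return Object of class `WorkflowConfig` (named list).
#' @export
workflow_config <- function(entropy_min = 0.34, kmer_k = 6L,
                            kmer_min_hits = 3L, qrepeat_window = 9L,
                            qrepeat_sd_multiplier = 1,
                            surface_cutoff = 2.55, probe = 1.4,
                            epitope_radius = 12, epitope_min_size = 13L,
                            e_max = 0.001, epitope_strong_identity = 0.93,
                            window_len = 80L, window_min_identity = 0.35,
                            cluster_identity = 0.70, max_batch = 50L,
                            min_query_len = 8L) {
  cfg <- list(entropy_min = entropy_min, kmer_k = as.integer(kmer_k),
              kmer_min_hits = as.integer(kmer_min_hits),
              qrepeat_window = as.integer(qrepeat_window),
              qrepeat_sd_multiplier = qrepeat_sd_multiplier,
              surface_cutoff = surface_cutoff, probe = probe,
              epitope_radius = epitope_radius,
              epitope_min_size = as.integer(epitope_min_size),
              e_max = e_max,
              epitope_strong_identity = epitope_strong_identity,
              window_len = as.integer(window_len),
              window_min_identity = window_min_identity,
              cluster_identity = cluster_identity,
              max_batch = as.integer(max_batch),
              min_query_len = as.integer(min_query_len))
  pos <- c("kmer_k", "kmer_min_hits", "qrepeat_window", "surface_cutoff",
           "probe", "epitope_radius", "epitope_min_size", "e_max",
           "window_len", "max_batch", "min_query_len")
  for (nm in pos) assert_number(cfg[[nm]], nm, lower = 1e-12)
  assert_number(cfg$entropy_min, "entropy_min", lower = 0)
  assert_number(cfg$qrepeat_sd_multiplier, "qrepeat_sd_multiplier", lower = 0)
  for (nm in c("epitope_strong_identity", "window_min_identity",
               "cluster_identity")) {
    assert_number(cfg[[nm]], nm, lower = 1e-12, upper = 1)
  }
  structure(cfg, class = "WorkflowConfig")
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value` (or `key: value`; `#` comments allowed)
#' override [workflow_config()] defaults; unknown keys are an error.
#'
#' @param path Configuration file path.
#' @return A `WorkflowConfig`.
#' @export
read_workflow_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("[=:]", lines)])
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(workflow_config())
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*[=:]\\s*(.+)$", lines))
  keys <- vapply(kv, `[`, character(1L), 2L)
  vals <- as.numeric(vapply(kv, `[`, character(1L), 3L))
  known <- names(formals(workflow_config))
  bad <- setdiff(keys, known)
  if (length(bad)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  do.call(workflow_config, as.list(setNames(vals, keys)))
}

#' Bundle the reference material for assessment
#'
#' @param allergens [sequence_database()] of known allergens.
#' @param structures Named list of [structure_object()]s for cluster
#'   representatives (may be empty). Residues are renumbered 1..L in chain
#'   order so that epitope indices live in sequence coordinates.
#' @param qrepeat_model A [train_fingerprint()] model.
#' @param epitope_tables Optional named list of precomputed
#'   [build_epitope_table()] results (names = structure ids); computed from
#'   the structures when omitted.
#' @param cfg A [workflow_config()] supplying surface/epitope parameters.
#' @return Object of class `ReferenceBundle`: list with `allergens`,
#'   `structures`, `epitope_tables`, `rep_sequences` (named character,
#'   structure id -> representative sequence), `qrepeat_model`, and
#'   `rep_db` (the representative sequences as a SequenceDatabase used by
#'   the structure search).
#' @export
reference_bundle <- function(allergens, structures = list(),
                             qrepeat_model, epitope_tables = NULL,
                             cfg = workflow_config()) {
  stopifnot(inherits(allergens, "SequenceDatabase"),
            inherits(qrepeat_model, "QRepeatModel"),
            inherits(cfg, "WorkflowConfig"))
  if (length(structures)) {
    stopifnot(all(vapply(structures, inherits, logical(1L), "Structure")))
    structures <- lapply(structures, renumber_structure)
    if (is.null(names(structures)) || any(!nzchar(names(structures)))) {
      names(structures) <- vapply(structures, `[[`, character(1L), "id")
    }
  }
  if (is.null(epitope_tables)) {
    epitope_tables <- lapply(structures, function(st) {
      surf <- surface_residues(st, probe = cfg$probe,
                               cutoff = cfg$surface_cutoff)
      build_epitope_table(st, surf, radius = cfg$epitope_radius,
                          min_size = cfg$epitope_min_size)
    })
  } else {
    miss <- setdiff(names(epitope_tables), names(structures))
    if (length(miss)) {
      stop(sprintf("epitope table(s) for unknown structure(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  rep_sequences <- vapply(structures, `[[`, character(1L), "sequence")
  if (length(rep_sequences) && any(!nzchar(rep_sequences))) {
    stop("every structure must yield a non-empty representative sequence",
         call. = FALSE)
  }
  rep_db <- if (length(structures)) {
    sequence_database(names(structures), unname(rep_sequences),
                      sources = "structure", name = "structure_reps")
  } else {
    sequence_database(character(), character(), name = "structure_reps")
  }
  structure(list(allergens = allergens, structures = structures,
                 epitope_tables = epitope_tables,
                 rep_sequences = rep_sequences, rep_db = rep_db,
                 qrepeat_model = qrepeat_model),
            class = "ReferenceBundle")
}

# renumber residues 1..L in chain order (sequence coordinates)
renumber_structure <- function(st) {
  new_idx <- match(st$atoms$residue_index, st$residue_index)
  atoms <- st$atoms
  atoms$residue_index <- new_idx
  structure_object(st$id, atoms)
}

#' @export
print.ReferenceBundle <- function(x, ...) {
  cat(sprintf("ReferenceBundle: %d allergen(s), %d structure(s)\n",
              nrow(x$allergens), length(x$structures)))
  invisible(x)
}

evidence_call <- function(query_id, level = "none", basis = "none",
                          best_allergen = "", best_structure = "",
                          epitope_identity = NA_real_,
                          window_identity = NA_real_,
                          hexamer_hits = NA_integer_, notes = "") {
  data.frame(query_id = query_id, evidence = level, basis = basis,
             best_allergen = best_allergen, best_structure = best_structure,
             epitope_identity = epitope_identity,
             window_identity = window_identity,
             hexamer_hits = hexamer_hits, notes = notes,
             stringsAsFactors = FALSE)
}

#' Assess one query protein
#'
#' Runs the evidence cascade in fixed order; earlier stages shadow later
#' ones:
#' 1. Gluten-like Q-repeat hit -> strong evidence (independent of all other
#'    features, evaluated first).
#' 2. Significant similarity to a structure representative (`E < e_max`):
#'    the query and its best allergen hit are mapped onto the
#'    representative and compared over all epitope patches; identity at or
#'    above `epitope_strong_identity` gives strong evidence, below gives
#'    weak evidence (same fold). If no allergen hit passes `e_max`, or the
#'    structure has no epitopes, the cascade falls through.
#' 3. Linear-window rule against the full allergen database -> strong
#'    evidence on hit.
#' 4. Entropy-filtered triple-hexamer rule -> weak evidence on hit.
#' 5. Otherwise: no evidence.
#'
#' Queries shorter than `cfg$min_query_len` residues are reported as no
#' evidence with a "too short" note.
#'
#' @param query A single-row [sequence_database()] slice, or a list with
#'   `id` and `sequence`.
#' @param refs A [reference_bundle()].
#' @param cfg A [workflow_config()].
#' @param kmer_idx Optional precomputed [kmer_index()] of
#'   `refs$allergens` (rebuilt per call otherwise).
#' @return One-row data frame (an `EvidenceCall`): `query_id`, `evidence`
#'   (strong/weak/none), `basis` (qrepeat/epitope3d/linear_window/kmer/
#'   none), `best_allergen`, `best_structure`, `epitope_identity`,
#'   `window_identity`, `hexamer_hits`, `notes`.
#' @export
assess <- function(query, refs, cfg = workflow_config(), kmer_idx = NULL) {
  stopifnot(inherits(refs, "ReferenceBundle"), inherits(cfg, "WorkflowConfig"))
  if (inherits(query, "SequenceDatabase")) {
    stopifnot(nrow(query) == 1L)
    query <- list(id = query$id, sequence = query$sequence)
  }
  qid <- query$id
  qseq <- toupper(query$sequence)
  if (nchar(qseq) < 1L) stop("query sequence must have length >= 1", call. = FALSE)
  if (nchar(qseq) < cfg$min_query_len) {
    return(evidence_call(qid, notes = sprintf(
      "too short to be evaluated (length %d)", nchar(qseq))))
  }

  # stage 1: Gluten-like Q-repeat
  qr <- qrepeat_hit(refs$qrepeat_model, qseq,
                    sd_multiplier = cfg$qrepeat_sd_multiplier)
  if (isTRUE(qr$hit)) {
    return(evidence_call(qid, "strong", "qrepeat",
                         notes = sprintf("Q-repeat window %s at %d (%.2f bits)",
                                         qr$best_window, qr$best_pos,
                                         qr$best_score)))
  }

  # allergen-database search is shared by stages 2 and (implicitly) 3
  allergen_hits <- search_db(qseq, refs$allergens, e_max = cfg$e_max,
                             query_id = qid)

  # stage 2: 3D surface-epitope similarity
  if (nrow(refs$rep_db)) {
    struct_hits <- search_db(qseq, refs$rep_db, e_max = cfg$e_max,
                             query_id = qid)
    if (nrow(struct_hits) && nrow(allergen_hits)) {
      sid <- struct_hits$target_id[1L]
      aid <- allergen_hits$target_id[1L]
      tab <- refs$epitope_tables[[sid]]
      if (!is.null(tab) && length(tab$epitopes)) {
        aseq <- refs$allergens$sequence[refs$allergens$id == aid]
        mapping <- anchored_triple_map(qseq, refs$rep_sequences[[sid]], aseq)
        res <- best_epitope_identity(mapping, tab)
        if (!is.null(res)) {
          level <- if (res$identity >= cfg$epitope_strong_identity) "strong" else "weak"
          return(evidence_call(
            qid, level, "epitope3d", best_allergen = aid,
            best_structure = sid, epitope_identity = res$identity,
            notes = sprintf("epitope center %d size %d (%d identical)",
                            res$center, res$size, res$identical)))
        }
      }
    }
  }

  # stage 3: classical linear-window rule over the full allergen database
  if (nrow(refs$allergens)) {
    wid <- linear_window_scan(qseq, refs$allergens, window = cfg$window_len)
    best <- order(-wid, refs$allergens$id)[1L]
    if (length(wid) && wid[best] >= cfg$window_min_identity) {
      return(evidence_call(qid, "strong", "linear_window",
                           best_allergen = refs$allergens$id[best],
                           window_identity = wid[best]))
    }
  }

  # stage 4: entropy-filtered triple-hexamer rule
  if (is.null(kmer_idx)) {
    kmer_idx <- kmer_index(refs$allergens, entropy_min = cfg$entropy_min,
                           k = cfg$kmer_k)
  }
  qh <- valid_hexamers(qseq, entropy_min = cfg$entropy_min, k = cfg$kmer_k)
  th <- triple_hit(qh, kmer_idx, min_hits = cfg$kmer_min_hits)
  if (length(th)) {
    return(evidence_call(qid, "weak", "kmer",
                         best_allergen = names(th)[1L],
                         hexamer_hits = as.integer(th[1L])))
  }

  evidence_call(qid)
}

#' Assess a batch of queries and write a CSV report
#'
#' One row per query in input order; identical inputs produce byte-identical
#' output. Exceeding `cfg$max_batch` is an error raised before any output
#' is written.
#'
#' @param queries A [sequence_database()] of queries.
#' @param refs A [reference_bundle()].
#' @param cfg A [workflow_config()].
#' @param out Optional CSV path; `NULL` skips writing.
#' @return Data frame of evidence calls (invisibly when `out` is given).
#' @export
run_batch <- function(queries, refs, cfg = workflow_config(), out = NULL) {
  stopifnot(inherits(queries, "SequenceDatabase"))
  if (nrow(queries) < 1L) stop("batch must contain at least one query", call. = FALSE)
  if (nrow(queries) > cfg$max_batch) {
    stop(sprintf("batch of %d queries exceeds the limit of %d",
                 nrow(queries), cfg$max_batch), call. = FALSE)
  }
  idx <- kmer_index(refs$allergens, entropy_min = cfg$entropy_min,
                    k = cfg$kmer_k)
  calls <- do.call(rbind, lapply(seq_len(nrow(queries)), function(i) {
    assess(list(id = queries$id[i], sequence = queries$sequence[i]),
           refs, cfg, kmer_idx = idx)
  }))
  rownames(calls) <- NULL
  if (!is.null(out)) {
    fmt <- calls
    fmt$epitope_identity <- ifelse(is.na(calls$epitope_identity), "",
                                   sprintf("%.4f", calls$epitope_identity))
    fmt$window_identity <- ifelse(is.na(calls$window_identity), "",
                                  sprintf("%.4f", calls$window_identity))
    fmt$hexamer_hits <- ifelse(is.na(calls$hexamer_hits), "",
                               as.character(calls$hexamer_hits))
    utils::write.csv(fmt, out, row.names = FALSE, quote = TRUE, eol = "\n")
    return(invisible(calls))
  }
  calls
}

#' Self-screen sensitivity of a reference bundle
#'
#' Assesses every allergen of the bundle as a query against the bundle
#' itself. In jack-knife mode, records with a sequence identical to the
#' query, and structures whose representative sequence equals the query,
#' are removed from the reference before assessing, emulating
#' leave-one-out cross-validation.
#'
#' @param refs A [reference_bundle()].
#' @param cfg A [workflow_config()].
#' @param jackknife Exclude self-identical reference material (default
#'   `FALSE`).
#' @return List with `calls` (data frame of evidence calls), `counts`
#'   (named table over strong/weak/none) and `missed` (data frame of
#'   level-none queries with their notes).
#' @export
self_screen <- function(refs, cfg = workflow_config(), jackknife = FALSE) {
  stopifnot(inherits(refs, "ReferenceBundle"))
  db <- refs$allergens
  idx <- if (!jackknife) {
    kmer_index(db, entropy_min = cfg$entropy_min, k = cfg$kmer_k)
  } else NULL
  calls <- do.call(rbind, lapply(seq_len(nrow(db)), function(i) {
    r <- refs
    this_idx <- idx
    if (jackknife) {
      keep <- db$sequence != db$sequence[i]
      r$allergens <- db[keep, , drop = FALSE]
      attr(r$allergens, "name") <- attr(db, "name")
      class(r$allergens) <- class(db)
      drop_st <- names(r$rep_sequences)[r$rep_sequences == db$sequence[i]]
      if (length(drop_st)) {
        r$structures <- r$structures[setdiff(names(r$structures), drop_st)]
        r$epitope_tables <- r$epitope_tables[setdiff(names(r$epitope_tables), drop_st)]
        r$rep_sequences <- r$rep_sequences[setdiff(names(r$rep_sequences), drop_st)]
        r$rep_db <- r$rep_db[r$rep_db$id %in% names(r$structures), , drop = FALSE]
        class(r$rep_db) <- class(refs$rep_db)
      }
    }
    assess(list(id = db$id[i], sequence = db$sequence[i]), r, cfg,
           kmer_idx = this_idx)
  }))
  rownames(calls) <- NULL
  counts <- table(factor(calls$evidence, levels = c("strong", "weak", "none")))
  missed <- calls[calls$evidence == "none", c("query_id", "notes"), drop = FALSE]
  list(calls = calls, counts = counts, missed = missed)
}
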