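# Deterministic synthetic-data generators: every stage of the workflow is
# testable offline, with no reference downloads. All generators are
# seed-deterministic and emit the standard formats (FASTA, PDB, plain
# peptide lists) consumed unchanged by the rest of the package.

#' Specification for synthetic sequence generation
#'
#' @param seed Integer RNG seed; the same spec always yields byte-identical
#'   output.
#' @param n Number of sequences (>= 1).
#' @param length_range Integer vector `c(min, max)` of sequence lengths, or
#'   a single fixed length.
#' @param mutation_rate Per-position substitution rate used when deriving
#'   homologs (default 0.1, i.e. 90% identity — the most stringent
#'   cross-validation tier of the reference workflow).
#' @param composition Named residue-frequency vector over the 20 standard
#'   residues (default [uniprot_background()]).
#' @param prefix Record id prefix.
#' @return Object of class `FixtureSpec`.
#' @export
fixture_spec <- function(seed = 1L, n = 10L, length_range = c(100L, 300L),
                         mutation_rate = 0.1,
                         composition = uniprot_background(),
                         prefix = "syn") {
  n <- as.integer(assert_number(n, lower = 1))
  if (length(length_range) == 1L) length_range <- rep(length_range, 2L)
  comp <- composition[AA_STANDARD]
  if (anyNA(comp) || any(comp < 0) || sum(comp) <= 0) {
    stop("'composition' must be a non-negative table over the 20 standard residues",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n = n,
                 length_range = as.integer(length_range),
                 mutation_rate = assert_number(mutation_rate, lower = 0, upper = 1),
                 composition = comp / sum(comp),
                 prefix = assert_string(prefix)),
            class = "FixtureSpec")
}

#' Generate a synthetic sequence database
#'
#' Seeded i.i.d. sequences drawn from the spec's residue composition, with
#' reproducible ids `<prefix>001`, `<prefix>002`, ...
#'
#' @param spec A [fixture_spec()].
#' @return A [sequence_database()].
#' @export
make_synthetic_db <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  with_seed(spec$seed, {
    lens <- sample(spec$length_range[1L]:spec$length_range[2L], spec$n,
                   replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_STANDARD, L, replace = TRUE, prob = spec$composition),
            collapse = "")
    }, character(1L))
    ids <- sprintf("%s%03d", spec$prefix, seq_len(spec$n))
    sequence_database(ids, seqs, sources = "synthetic",
                      name = sprintf("%s_seed%d", spec$prefix, spec$seed))
  })
}

#' Derive a homolog at a target identity
#'
#' Substitutes a seeded random subset of positions so that the realized
#' ungapped same-length identity equals `round(target_identity * length)`
#' positions (within one position). Substituted residues always differ from
#' the original residue.
#'
#' @param seq Amino-acid string.
#' @param target_identity Identity fraction in (0, 1].
#' @param seed Integer seed.
#' @return The mutated sequence string.
#' @export
mutate_homolog <- function(seq, target_identity, seed = 1L) {
  assert_string(seq)
  assert_number(target_identity, lower = 1e-9, upper = 1)
  L <- nchar(seq)
  n_sub <- L - round(target_identity * L)
  if (n_sub == 0L) return(toupper(seq))
  with_seed(seed, {
    ch <- seq_chars(toupper(seq))
    pos <- sample.int(L, n_sub)
    for (p in pos) {
      ch[p] <- sample(setdiff(AA_STANDARD, ch[p]), 1L)
    }
    paste(ch, collapse = "")
  })
}

#' Reverse every sequence of a database
#'
#' The classic negative-control construction: a reversed sequence is a
#' non-sensical copy that preserves the number, lengths and residue
#' compositions of the true set, making it a cheap stand-in for a
#' non-allergen proteome when estimating false-positive rates.
#'
#' @param db A [sequence_database()].
#' @return A database of the reversed sequences (same ids, name suffixed
#'   `_rev`).
#' @export
reverse_db <- function(db) {
  stopifnot(inherits(db, "SequenceDatabase"))
  rev_seq <- vapply(db$sequence, function(s) {
    paste(rev(seq_chars(s)), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
  sequence_database(db$id, rev_seq, db$description, sources = db$sources,
                    name = paste0(attr(db, "name"), "_rev"))
}

#' Build an idealized alpha-helix structure for a sequence
#'
#' Backbone (N, CA, C, O) plus one pseudo-side-chain atom (CB) per residue
#' on an ideal helix: rise 1.5 Angstrom and 100 degrees of twist per
#' residue, CA radius 2.3 Angstrom. Coordinates are deterministic. The
#' resulting helix is thin, so every residue is solvent accessible — a
#' convenient property for surface and epitope tests.
#'
#' @param sequence Amino-acid string (standard residues; others become UNK).
#' @param id Structure id.
#' @return A [structure_object()] with residues numbered 1..n.
#' @export
make_helix_structure <- function(sequence, id = "helix") {
  assert_string(sequence)
  res <- seq_chars(toupper(sequence))
  n <- length(res)
  if (!n) stop("sequence must be non-empty", call. = FALSE)
  resname <- AA1TO3[res]
  resname[is.na(resname)] <- "UNK"
  i <- seq_len(n)
  theta <- (i - 1L) * 100 * pi / 180
  z <- (i - 1L) * 1.5
  place <- function(r, dth, dz, name, element) {
    data.frame(residue_index = i, resname = resname, atom_name = name,
               element = element,
               x = r * cos(theta + dth), y = r * sin(theta + dth),
               z = z + dz, stringsAsFactors = FALSE)
  }
  atoms <- rbind(place(1.6, -0.50, -0.90, "N", "N"),
                 place(2.3, 0.00, 0.00, "CA", "C"),
                 place(1.7, 0.40, 0.60, "C", "C"),
                 place(2.6, 0.55, 0.70, "O", "O"),
                 place(3.8, 0.00, 0.00, "CB", "C"))
  atoms <- atoms[order(atoms$residue_index), , drop = FALSE]
  rownames(atoms) <- NULL
  structure_object(id, atoms)
}

#' Generate Q/P-enriched training peptides
#'
#' Seeded peptides drawn from a composition shifted toward glutamine and
#' proline, standing in for the Celiac-disease peptide training set of the
#' Q-repeat fingerprint. With `enrichment = 1` every residue is glutamine.
#'
#' @param n Number of peptides.
#' @param length_range Peptide length range (minimum 9).
#' @param enrichment Fraction of the composition mass moved to Q (2/3) and
#'   P (1/3); the remainder stays on the background composition. Default
#'   0.8.
#' @param seed Integer seed.
#' @return Character vector of peptides.
#' @export
make_qrich_peptides <- function(n = 50L, length_range = c(9L, 30L),
                                enrichment = 0.8, seed = 1L) {
  n <- as.integer(assert_number(n, lower = 1))
  assert_number(enrichment, lower = 0, upper = 1)
  if (length(length_range) == 1L) length_range <- rep(length_range, 2L)
  if (length_range[1L] < 9L) stop("peptides must be at least 9 residues", call. = FALSE)
  comp <- uniprot_background() * (1 - enrichment)
  comp["Q"] <- comp["Q"] + enrichment * 2 / 3
  comp["P"] <- comp["P"] + enrichment * 1 / 3
  with_seed(seed, {
    lens <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
    vapply(lens, function(L) {
      paste(sample(AA_STANDARD, L, replace = TRUE, prob = comp), collapse = "")
    }, character(1L))
  })
}

#' Write a complete demo fixture bundle
#'
#' Generates, under `dir`: `allergens.fasta` (synthetic known-allergen set),
#' `structures/<id>.pdb` (helix structures for a subset of allergens),
#' `epitopes.json` (their epitope tables), `qrepeat_peptides.txt`
#' (Q/P-enriched training peptides, one per line), `qrepeat_model.json`
#' (the trained fingerprint) and `queries.fasta` (a homolog of the first
#' allergen, a Q-repeat carrier, and an unrelated random sequence).
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_allergens Number of synthetic allergens (default 20).
#' @param n_structures Number of allergens that receive a helix structure
#'   (default 5).
#' @param cfg A [workflow_config()] for the epitope parameters.
#' @return Invisibly, a list of the written paths.
#' @export
make_fixture_bundle <- function(dir, seed = 1L, n_allergens = 20L,
                                n_structures = 5L, cfg = workflow_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sdir <- file.path(dir, "structures")
  dir.create(sdir, showWarnings = FALSE)
  db <- make_synthetic_db(fixture_spec(seed = seed, n = n_allergens,
                                       length_range = c(60L, 160L),
                                       prefix = "alg"))
  paths <- list(allergens = file.path(dir, "allergens.fasta"))
  write_fasta(db, paths$allergens)
  n_structures <- min(n_structures, nrow(db))
  structs <- lapply(seq_len(n_structures), function(i) {
    make_helix_structure(db$sequence[i], id = paste0("str_", db$id[i]))
  })
  names(structs) <- vapply(structs, `[[`, character(1L), "id")
  paths$structures <- vapply(structs, function(st) {
    p <- file.path(sdir, paste0(st$id, ".pdb"))
    write_pdb(st, p)
    p
  }, character(1L))
  tables <- lapply(structs, function(st) {
    surf <- surface_residues(st, probe = cfg$probe, cutoff = cfg$surface_cutoff)
    build_epitope_table(st, surf, radius = cfg$epitope_radius,
                        min_size = cfg$epitope_min_size)
  })
  paths$epitopes <- file.path(dir, "epitopes.json")
  write_epitope_tables(tables, paths$epitopes)
  peps <- make_qrich_peptides(n = 60L, seed = seed + 1L)
  paths$peptides <- file.path(dir, "qrepeat_peptides.txt")
  writeLines(peps, paths$peptides)
  model <- train_fingerprint(peps)
  paths$model <- file.path(dir, "qrepeat_model.json")
  write_qrepeat_model(model, paths$model)
  queries <- with_seed(seed + 2L, {
    carrier <- paste(sample(AA_STANDARD, 60L, replace = TRUE), collapse = "")
    qpep <- paste(sample(c("Q", "P"), 12L, replace = TRUE, prob = c(0.75, 0.25)),
                  collapse = "")
    random <- paste(sample(AA_STANDARD, 80L, replace = TRUE), collapse = "")
    sequence_database(
      c("homolog_q", "qrepeat_q", "random_q"),
      c(mutate_homolog(db$sequence[1L], 0.95, seed = seed + 3L),
        paste0(substr(carrier, 1L, 30L), qpep, substr(carrier, 31L, 60L)),
        random),
      description = c("95% homolog of first allergen",
                      "Q-repeat carrier", "unrelated random sequence"),
      sources = "query", name = "queries")
  })
  paths$queries <- file.path(dir, "queries.fasta")
  write_fasta(queries, paths$queries)
  invisible(paths)
}

#' Load a fixture bundle directory into a ReferenceBundle
#'
#' Reads the files written by [make_fixture_bundle()] (or equivalents laid
#' out the same way) into a ready-to-use [reference_bundle()].
#'
#' @param dir Bundle directory.
#' @param cfg A [workflow_config()].
#' @return A `ReferenceBundle`.
#' @export
load_fixture_bundle <- function(dir, cfg = workflow_config()) {
  db <- read_fasta(file.path(dir, "allergens.fasta"), name = "allergens")
  pdbs <- list.files(file.path(dir, "structures"), pattern = "\\.pdb$",
                     full.names = TRUE)
  structs <- lapply(pdbs, read_structure)
  names(structs) <- vapply(structs, `[[`, character(1L), "id")
  tabs_path <- file.path(dir, "epitopes.json")
  tables <- if (file.exists(tabs_path)) read_epitope_tables(tabs_path) else NULL
  model <- read_qrepeat_model(file.path(dir, "qrepeat_model.json"))
  reference_bundle(db, structs, model, epitope_tables = tables, cfg = cfg)
}
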