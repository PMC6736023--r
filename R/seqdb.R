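# Sequence database management: FASTA IO, merge/dedup, greedy clustering.

#' Construct a sequence database
#'
#' A `SequenceDatabase` is an ordered collection of named amino-acid
#' sequences with per-record provenance tags. It backs both query sets and
#' the reference database of known allergens.
#'
#' @param id Character vector of unique record ids.
#' @param sequence Character vector of amino-acid sequences (stored
#'   uppercase; the 20 standard letters plus B, J, O, U, X, Z are accepted on
#'   input — ambiguity handling happens downstream, at the hexamer stage).
#' @param description Character vector of free-text descriptions.
#' @param sources List of character vectors of provenance tags (one vector
#'   per record), or a single character scalar recycled to all records.
#' @param name Database name.
#' @return An object of class `SequenceDatabase`: a data frame with columns
#'   `id`, `description`, `sequence` and list-column `sources`.
#' @export
#' @examples
#' db <- sequence_database(c("p1", "p2"), c("MKVLAT", "qqqpqq"), name = "demo")
#' db$sequence[2]  # stored uppercase
sequence_database <- function(id, sequence, description = "",
                              sources = "user", name = "db") {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence)) {
    stop("'id' and 'sequence' must have equal length", call. = FALSE)
  }
  if (anyDuplicated(id)) {
    stop("record ids must be unique within a database", call. = FALSE)
  }
  if (length(sequence) && any(nchar(sequence) < 1L)) {
    stop("every sequence must have length >= 1", call. = FALSE)
  }
  bad <- grepl(sprintf("[^%s]", paste(c(AA_STANDARD, AA_AMBIGUOUS),
                                      collapse = "")), sequence)
  if (any(bad)) {
    stop(sprintf("record '%s' contains characters outside the amino-acid alphabet",
                 id[which(bad)[1L]]), call. = FALSE)
  }
  description <- rep_len(as.character(description), length(id))
  if (is.character(sources)) {
    sources <- rep(list(sources), length(id))
  }
  stopifnot(is.list(sources), length(sources) == length(id) || !length(id))
  db <- data.frame(id = id, description = description, sequence = sequence,
                   stringsAsFactors = FALSE)
  db$sources <- sources
  attr(db, "name") <- assert_string(name)
  class(db) <- c("SequenceDatabase", "data.frame")
  db
}

#' @export
`[.SequenceDatabase` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("id", "sequence") %in% names(out))) {
    attr(out, "name") <- attr(x, "name")
    class(out) <- class(x)
  }
  out
}

#' @export
print.SequenceDatabase <- function(x, ...) {
  cat(sprintf("SequenceDatabase '%s': %d record(s)\n",
              attr(x, "name"), nrow(x)))
  if (nrow(x)) {
    shown <- utils::head(x, 6L)
    for (i in seq_len(nrow(shown))) {
      s <- shown$sequence[i]
      if (nchar(s) > 40L) s <- paste0(substr(s, 1L, 40L), "...")
      cat(sprintf("  %-12s %5d aa  %s\n", shown$id[i],
                  nchar(shown$sequence[i]), s))
    }
    if (nrow(x) > 6L) cat(sprintf("  ... and %d more\n", nrow(x) - 6L))
  }
  invisible(x)
}

#' Read a FASTA file into a SequenceDatabase
#'
#' Sequences are uppercased and input order is preserved. Record ids are the
#' first whitespace-delimited token of each header; duplicated ids are
#' disambiguated deterministically by appending `.2`, `.3`, ... in order of
#' appearance. An empty file yields an empty database; sequence data before
#' the first header is a parse error naming the offending line.
#'
#' @param path Path to a FASTA file (wrapped or single-line records).
#' @param name Database name; defaults to the file name without extension.
#' @param source Provenance tag attached to every record; defaults to `name`.
#' @return A [sequence_database()].
#' @export
read_fasta <- function(path, name = NULL, source = NULL) {
  assert_string(path)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(source)) source <- name
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines)
  idx <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(sequence_database(character(), character(), name = name))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) {
    stop(sprintf("malformed FASTA: sequence data before first header at line %d of %s",
                 idx[1L], path), call. = FALSE)
  }
  grp <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]),
                 paste, collapse = "", FUN.VALUE = character(1L))
  out <- character(length(headers))
  out[as.integer(names(seqs))] <- seqs
  if (any(out == "")) {
    stop(sprintf("malformed FASTA: header '%s' has no sequence",
                 headers[which(out == "")[1L]]), call. = FALSE)
  }
  out <- toupper(gsub("[\\s*]", "", out, perl = TRUE))
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  # deterministic disambiguation of duplicate headers
  if (anyDuplicated(ids)) {
    counts <- stats::ave(seq_along(ids), ids, FUN = seq_along)
    ids <- ifelse(counts > 1L, paste0(ids, ".", counts), ids)
  }
  sequence_database(ids, out, desc, sources = source, name = name)
}

#' Write a SequenceDatabase to FASTA
#'
#' @param db A [sequence_database()].
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path, width = 60L) {
  stopifnot(inherits(db, "SequenceDatabase"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(db))) {
    hdr <- if (nzchar(db$description[i])) {
      paste(db$id[i], db$description[i])
    } else db$id[i]
    writeLines(paste0(">", hdr), con)
    s <- db$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Merge sequence databases with 100%-identity deduplication
#'
#' Records whose sequence strings are byte-identical (after case
#' normalization) are collapsed into a single record keeping the first-seen
#' id and description; the `sources` of the merged record is the union of
#' all contributing tags. Ids never participate in deduplication; a later
#' record whose id collides with a retained record of a *different* sequence
#' is renamed deterministically (`id.2`, `id.3`, ...).
#'
#' @param dbs A list of [sequence_database()] objects (at least one).
#' @param name Name for the merged database.
#' @return A deduplicated [sequence_database()].
#' @export
merge_databases <- function(dbs, name = "merged") {
  if (inherits(dbs, "SequenceDatabase")) dbs <- list(dbs)
  if (!length(dbs)) stop("need at least one input database", call. = FALSE)
  stopifnot(all(vapply(dbs, inherits, logical(1L), "SequenceDatabase")))
  ids <- character(); desc <- character(); seqs <- character()
  src <- list()
  pos <- new.env(parent = emptyenv())  # sequence -> index in output
  used_ids <- new.env(parent = emptyenv())
  for (db in dbs) {
    for (i in seq_len(nrow(db))) {
      s <- db$sequence[i]
      j <- pos[[s]]
      if (is.null(j)) {
        id <- db$id[i]
        k <- 1L
        while (!is.null(used_ids[[id]])) {
          k <- k + 1L
          id <- paste0(db$id[i], ".", k)
        }
        seqs <- c(seqs, s); ids <- c(ids, id); desc <- c(desc, db$description[i])
        src <- c(src, list(sort(unique(db$sources[[i]]))))
        pos[[s]] <- length(seqs)
        used_ids[[id]] <- TRUE
      } else {
        src[[j]] <- sort(unique(c(src[[j]], db$sources[[i]])))
      }
    }
  }
  sequence_database(ids, seqs, desc, sources = src, name = name)
}

#' Greedy incremental identity clustering
#'
#' cd-hit style clustering by exact global alignment: records are visited in
#' order of decreasing sequence length (ties keep database order) and each
#' record joins the first-founded existing cluster whose representative it
#' matches at `>= threshold` global identity, computed as identical columns
#' divided by total alignment length (gap columns included). Otherwise the
#' record founds a new cluster. Word-size heuristics of cd-hit are replaced
#' by exact alignment, which is exact and fast at reference-set scale.
#'
#' @param db A [sequence_database()].
#' @param threshold Identity fraction in (0, 1]; default 0.70.
#' @return An object of class `ClusterSet`: list with `clusters` (named list
#'   representative id -> member ids, members include the representative),
#'   `identity` (named list of member identities to the representative) and
#'   `identity_threshold`.
#' @export
greedy_cluster <- function(db, threshold = 0.70) {
  stopifnot(inherits(db, "SequenceDatabase"))
  assert_number(threshold, lower = 1e-9, upper = 1)
  ord <- order(-nchar(db$sequence), seq_len(nrow(db)))
  rep_id <- character(); rep_seq <- character()
  members <- list(); idents <- list()
  for (i in ord) {
    s <- db$sequence[i]
    joined <- FALSE
    if (length(rep_seq)) {
      idv <- alignment_identity(s, rep_seq)
      hit <- which(idv >= threshold)
      if (length(hit)) {
        j <- hit[1L]  # first-founded cluster wins
        members[[j]] <- c(members[[j]], db$id[i])
        idents[[j]] <- c(idents[[j]], idv[j])
        joined <- TRUE
      }
    }
    if (!joined) {
      rep_id <- c(rep_id, db$id[i]); rep_seq <- c(rep_seq, s)
      members <- c(members, list(db$id[i])); idents <- c(idents, list(1.0))
    }
  }
  names(members) <- rep_id
  names(idents) <- rep_id
  structure(list(clusters = members, identity = idents,
                 identity_threshold = threshold),
            class = "ClusterSet")
}

#' @export
print.ClusterSet <- function(x, ...) {
  cat(sprintf("ClusterSet: %d cluster(s) at >= %.0f%% identity\n",
              length(x$clusters), 100 * x$identity_threshold))
  invisible(x)
}

#' Write a ClusterSet as TSV
#'
#' One row per member: `representative_id`, `member_id`, `identity`.
#'
#' @param cs A [greedy_cluster()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(cs, path) {
  stopifnot(inherits(cs, "ClusterSet"))
  rep <- rep(names(cs$clusters), lengths(cs$clusters))
  tab <- data.frame(representative_id = rep,
                    member_id = unlist(cs$clusters, use.names = FALSE),
                    identity = sprintf("%.4f", unlist(cs$identity, use.names = FALSE)),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
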