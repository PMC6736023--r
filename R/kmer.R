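# Hexamer extraction, entropy filtering, indexing, and the triple-hit rule.

#' Shannon entropy of k-mer residue composition
#'
#' Entropy in bits of the within-k-mer residue frequency distribution:
#' `H = -sum_a f_a * log2(f_a)` over the residues `a` occurring in the k-mer.
#' A homopolymer scores 0; a hexamer of two residues at 3/6 each scores
#' exactly 1 bit. Vectorized over k-mers.
#'
#' @param kmer Character vector of amino-acid strings (length >= 1 each).
#' @return Numeric vector of entropies in bits.
#' @export
#' @examples
#' kmer_entropy(c("AAAAAA", "QAQAQA", "MKVLAT"))
kmer_entropy <- function(kmer) {
  if (!is.character(kmer)) stop("'kmer' must be character", call. = FALSE)
  if (!length(kmer)) return(numeric())
  if (any(is.na(kmer) | nchar(kmer) < 1L)) {
    stop("k-mers must be non-empty strings", call. = FALSE)
  }
  vapply(strsplit(kmer, "", fixed = TRUE), function(ch) {
    f <- tabulate(factor(ch)) / length(ch)
    -sum(f * log2(f))
  }, numeric(1L))
}

#' Extract valid hexamers from a sequence
#'
#' All distinct overlapping k-mers of `sequence`, minus those containing an
#' ambiguous residue (B, J, O, U, X, Z) and minus those with
#' [kmer_entropy()] below `entropy_min`. With the default threshold of 0.34
#' bits the entropy filter removes exactly the homopolymeric k-mers (entropy
#' 0): the next-lowest achievable hexamer entropy, 5+1 of two residues, is
#' already about 0.65 bits. Sequences shorter than `k` yield an empty set.
#'
#' @param sequence Amino-acid string.
#' @param entropy_min Minimum entropy in bits (default 0.34); 0 disables the
#'   filter.
#' @param k k-mer length (default 6).
#' @return Character vector of distinct valid k-mers (class `HexamerSet`
#'   attributes `k` and `entropy_min`).
#' @export
valid_hexamers <- function(sequence, entropy_min = 0.34, k = 6L) {
  assert_string(sequence)
  assert_number(entropy_min, lower = 0)
  k <- as.integer(assert_number(k, lower = 1))
  s <- toupper(sequence)
  n <- nchar(s)
  km <- if (n < k) character() else {
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  if (length(km)) {
    km <- km[!grepl(sprintf("[%s]", paste(AA_AMBIGUOUS, collapse = "")), km)]
  }
  if (length(km) && entropy_min > 0) {
    km <- km[kmer_entropy(km) >= entropy_min]
  }
  structure(km, k = k, entropy_min = entropy_min, class = "HexamerSet")
}

#' Build a hexamer index over an allergen database
#'
#' Maps every valid hexamer (same ambiguity and entropy filter as
#' [valid_hexamers()], applied symmetrically to the database side) to the
#' set of allergen record ids containing it.
#'
#' @param db A [sequence_database()].
#' @inheritParams valid_hexamers
#' @return An object of class `KmerIndex`: a data frame with columns
#'   `hexamer`, `id` (one row per hexamer-record pair) plus attributes `k`
#'   and `entropy_min`.
#' @export
kmer_index <- function(db, entropy_min = 0.34, k = 6L) {
  stopifnot(inherits(db, "SequenceDatabase"))
  sets <- lapply(db$sequence, valid_hexamers, entropy_min = entropy_min, k = k)
  idx <- data.frame(
    hexamer = unlist(sets, use.names = FALSE),
    id = rep(db$id, lengths(sets)),
    stringsAsFactors = FALSE)
  attr(idx, "k") <- as.integer(k)
  attr(idx, "entropy_min") <- entropy_min
  class(idx) <- c("KmerIndex", "data.frame")
  idx
}

#' Write / read a KmerIndex as TSV
#'
#' Flat inspection format: `hexamer` and comma-joined record ids.
#'
#' @param index A [kmer_index()].
#' @param path Output path.
#' @return `path` invisibly (write); a `KmerIndex` (read).
#' @export
write_kmer_index <- function(index, path) {
  stopifnot(inherits(index, "KmerIndex"))
  ids <- vapply(split(index$id, index$hexamer), paste, collapse = ",",
                FUN.VALUE = character(1L))
  tab <- data.frame(hexamer = names(ids), ids = unname(ids),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$hexamer), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kmer_index
#' @export
read_kmer_index <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  ids <- strsplit(tab$ids, ",", fixed = TRUE)
  idx <- data.frame(hexamer = rep(tab$hexamer, lengths(ids)),
                    id = unlist(ids, use.names = FALSE),
                    stringsAsFactors = FALSE)
  k <- if (nrow(idx)) nchar(idx$hexamer[1L]) else 6L
  attr(idx, "k") <- as.integer(k)
  attr(idx, "entropy_min") <- NA_real_
  class(idx) <- c("KmerIndex", "data.frame")
  idx
}

#' Triple-hexamer hit rule
#'
#' Counts, for every allergen in the index, how many distinct valid query
#' hexamers it shares with the query, and keeps the allergens reaching
#' `min_hits` (default 3, the triple-hit criterion: three consecutive shared
#' hexamers fit exactly into a shared 8-residue stretch). Counts distinct
#' hexamer strings, not occurrence positions.
#'
#' @param query_hexamers A [valid_hexamers()] set (or character vector).
#' @param index A [kmer_index()].
#' @param min_hits Minimum shared-hexamer count (default 3).
#' @return Named integer vector of shared-hexamer counts (names = allergen
#'   ids), sorted by decreasing count then id, so the first element is the
#'   best hit; empty when nothing reaches `min_hits`.
#' @export
triple_hit <- function(query_hexamers, index, min_hits = 3L) {
  stopifnot(inherits(index, "KmerIndex"))
  min_hits <- as.integer(assert_number(min_hits, lower = 1))
  qh <- unique(as.character(query_hexamers))
  if (!length(qh) || !nrow(index)) return(setNames(integer(), character()))
  sub <- index[index$hexamer %in% qh, , drop = FALSE]
  if (!nrow(sub)) return(setNames(integer(), character()))
  counts <- vapply(split(sub$hexamer, sub$id),
                   function(h) length(unique(h)), integer(1L))
  counts <- counts[counts >= min_hits]
  counts[order(-counts, names(counts))]
}
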