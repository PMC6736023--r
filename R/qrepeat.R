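# Gluten-like Q-repeat compositional fingerprint: training and scanning.
#
# The score is a pure composition fingerprint: a per-residue log-odds table
# (log2 of the pooled training-window frequency over a background frequency)
# summed over a 9-residue window. Repeats of the same residues in any order
# score identically, which is exactly what makes the score suitable for
# Gluten-like Q/P repeats that the hexamer entropy filter would discard.

#' Train the Q-repeat fingerprint model
#'
#' Pools residue frequencies over every overlapping `window`-mer of the
#' training peptides, adds a pseudocount, and derives per-residue log-odds
#' against a background composition:
#' `logodds_a = log2((f_a + eps) / bg_a)`. The training mean and standard
#' deviation are computed by re-scoring every training window with
#' [score_window()].
#'
#' @param peptides Character vector of training peptides; peptides shorter
#'   than `window` are skipped with a warning.
#' @param background Named residue-frequency vector over the 20 standard
#'   residues, strictly positive, summing to 1 (+/- 1e-6). Default
#'   [uniprot_background()].
#' @param window Window length (default 9, the minimal training-peptide and
#'   MHC-core size).
#' @param pseudocount Frequency added to every residue before taking logs;
#'   `NULL` (default) uses `0.5 / N` where `N` is the total pooled residue
#'   count. Zero is allowed when every residue is observed.
#' @return An object of class `QRepeatModel`: list with `window`, `logodds`
#'   (named over the 20 standard residues), `floor_logodds` (score assigned
#'   to non-standard residues), `train_mean`, `train_sd`, `pseudocount`,
#'   `n_windows`.
#' @export
train_fingerprint <- function(peptides, background = uniprot_background(),
                              window = 9L, pseudocount = NULL) {
  window <- as.integer(assert_number(window, lower = 1))
  if (!is.character(peptides) || !length(peptides)) {
    stop("'peptides' must be a non-empty character vector", call. = FALSE)
  }
  peptides <- toupper(peptides)
  bg <- background[AA_STANDARD]
  if (anyNA(bg) || any(bg <= 0) || abs(sum(bg) - 1) > 1e-6) {
    stop("'background' must cover the 20 standard residues, be positive and sum to 1",
         call. = FALSE)
  }
  short <- nchar(peptides) < window
  if (any(short)) {
    warning(sprintf("skipping %d peptide(s) shorter than %d residues",
                    sum(short), window))
    peptides <- peptides[!short]
  }
  wins <- unlist(lapply(peptides, function(p) {
    n <- nchar(p)
    substring(p, 1:(n - window + 1L), window:n)
  }), use.names = FALSE)
  if (!length(wins)) stop("no usable training window", call. = FALSE)
  ch <- unlist(strsplit(wins, "", fixed = TRUE), use.names = FALSE)
  counts <- table(factor(ch, levels = AA_STANDARD))
  n_total <- length(ch)
  eps <- if (is.null(pseudocount)) 0.5 / n_total else {
    assert_number(pseudocount, lower = 0)
  }
  f <- as.numeric(counts) / n_total
  lo <- log2((f + eps) / bg)
  names(lo) <- AA_STANDARD
  # a residue never seen in training (frequency == pseudocount alone) against
  # a uniform background slot defines the floor for non-standard residues
  floor_lo <- log2(max(eps, .Machine$double.xmin) * 20)
  model <- structure(list(window = window, logodds = lo,
                          floor_logodds = floor_lo,
                          train_mean = NA_real_, train_sd = NA_real_,
                          pseudocount = eps, n_windows = length(wins)),
                     class = "QRepeatModel")
  scores <- vapply(wins, score_window, numeric(1L), model = model,
                   USE.NAMES = FALSE)
  model$train_mean <- mean(scores)
  model$train_sd <- if (length(scores) > 1L) stats::sd(scores) else 0
  model
}

#' @export
print.QRepeatModel <- function(x, ...) {
  cat(sprintf("QRepeatModel: window %d, %d training window(s), mean %.2f, sd %.2f bits\n",
              x$window, x$n_windows, x$train_mean, x$train_sd))
  top <- sort(x$logodds, decreasing = TRUE)[1:3]
  cat("  top log-odds:", paste(sprintf("%s=%.2f", names(top), top),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Score one window under a Q-repeat model
#'
#' Sum of per-residue log-odds over the window; non-standard residues score
#' the pseudocount-derived floor. The score depends only on composition, so
#' any permutation of the window scores identically.
#'
#' @param model A [train_fingerprint()] model.
#' @param window String of exactly `model$window` residues.
#' @return Score in bits.
#' @export
score_window <- function(model, window) {
  stopifnot(inherits(model, "QRepeatModel"))
  assert_string(window)
  if (nchar(window) != model$window) {
    stop(sprintf("window must have length %d", model$window), call. = FALSE)
  }
  lo <- model$logodds[seq_chars(toupper(window))]
  lo[is.na(lo)] <- model$floor_logodds
  sum(lo)
}

# per-position window scores for a whole sequence (running sum)
scan_windows <- function(model, sequence) {
  s <- toupper(sequence)
  n <- nchar(s)
  w <- model$window
  if (n < w) return(numeric())
  lo <- model$logodds[seq_chars(s)]
  lo[is.na(lo)] <- model$floor_logodds
  cs <- cumsum(c(0, lo))
  cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]
}

#' Scan a sequence for a Gluten-like Q-repeat hit
#'
#' A hit is triggered when any `window`-mer of the sequence scores at least
#' `train_mean - sd_multiplier * train_sd` ("within one standard deviation
#' of the training average", applied one-sidedly so that windows scoring
#' *above* the training average always hit). Sequences shorter than the
#' window cannot hit.
#'
#' @param model A [train_fingerprint()] model.
#' @param sequence Amino-acid string.
#' @param sd_multiplier Standard-deviation multiplier (default 1).
#' @return List with `hit` (logical), `threshold`, `best_score`,
#'   `best_window` and `best_pos` (1-based start of the maximal-scoring
#'   window, leftmost on ties; `NA` when no window exists).
#' @export
qrepeat_hit <- function(model, sequence, sd_multiplier = 1) {
  stopifnot(inherits(model, "QRepeatModel"))
  assert_number(sd_multiplier, lower = 0)
  thr <- model$train_mean - sd_multiplier * model$train_sd
  sc <- scan_windows(model, sequence)
  if (!length(sc)) {
    return(list(hit = FALSE, threshold = thr, best_score = NA_real_,
                best_window = NA_character_, best_pos = NA_integer_))
  }
  # leftmost maximum; tolerance absorbs running-sum rounding noise
  best <- which(sc >= max(sc) - 1e-9)[1L]
  list(hit = max(sc) >= thr, threshold = thr, best_score = sc[best],
       best_window = substr(toupper(sequence), best, best + model$window - 1L),
       best_pos = as.integer(best))
}

#' Serialize / restore a QRepeatModel as JSON
#'
#' @param model A [train_fingerprint()] model.
#' @param path JSON path.
#' @return `path` invisibly (write); a `QRepeatModel` (read).
#' @export
write_qrepeat_model <- function(model, path) {
  stopifnot(inherits(model, "QRepeatModel"))
  out <- unclass(model)
  out$logodds <- as.list(out$logodds)  # keep residue names in JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_qrepeat_model
#' @export
read_qrepeat_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$window <- as.integer(x$window)
  x$logodds <- unlist(x$logodds)[AA_STANDARD]
  structure(x[c("window", "logodds", "floor_logodds", "train_mean",
                "train_sd", "pseudocount", "n_windows")],
            class = "QRepeatModel")
}
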