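# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation under test.

# residue-composition entropy via counts and natural logs
oracle_entropy <- function(kmer) {
  counts <- table(strsplit(kmer, NULL)[[1L]])
  p <- as.numeric(counts) / sum(counts)
  -sum(p * log(p)) / log(2)
}

# brute-force shared-hexamer counting by double loop over substrings
oracle_shared_hexamers <- function(query, target, k = 6L, entropy_min = 0.34) {
  subs <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    out <- character()
    for (i in seq_len(n - k + 1L)) out <- c(out, substr(s, i, i + k - 1L))
    out <- unique(out)
    out <- out[!grepl("[BJOUXZ]", out)]
    if (entropy_min > 0) {
      out <- out[vapply(out, oracle_entropy, numeric(1L)) >= entropy_min]
    }
    out
  }
  length(intersect(subs(query), subs(target)))
}

# Gotoh affine-gap dynamic programming; gap of length L costs open+extend*L.
# type "global" includes end-gap penalties, "local" is Smith-Waterman.
oracle_align_score <- function(a, b, type = c("global", "local"),
                               open = 11, extend = 1) {
  type <- match.arg(type)
  sm <- get_blosum62()
  ca <- strsplit(a, NULL)[[1L]]; cb <- strsplit(b, NULL)[[1L]]
  n <- length(ca); m <- length(cb)
  neg <- -1e9
  M <- matrix(neg, n + 1L, m + 1L)
  Ix <- matrix(neg, n + 1L, m + 1L)  # gap in b (a residue vs gap)
  Iy <- matrix(neg, n + 1L, m + 1L)  # gap in a
  M[1L, 1L] <- 0
  if (type == "global") {
    for (i in seq_len(n)) Ix[i + 1L, 1L] <- -(open + extend * i)
    for (j in seq_len(m)) Iy[1L, j + 1L] <- -(open + extend * j)
  } else {
    M[, 1L] <- 0; M[1L, ] <- 0
  }
  best_local <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sm[ca[i], cb[j]]
      d <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      if (type == "local") d <- max(d, s, 0)
      M[i + 1L, j + 1L] <- d
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - extend,
                                Iy[i, j + 1L] - open - extend,
                                Ix[i, j + 1L] - extend)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - extend,
                                Ix[i + 1L, j] - open - extend,
                                Iy[i + 1L, j] - extend)
      if (type == "local" && d > best_local) best_local <- d
    }
  }
  if (type == "local") best_local else max(M[n + 1L, m + 1L],
                                           Ix[n + 1L, m + 1L],
                                           Iy[n + 1L, m + 1L])
}

get_blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# random ambiguity-free sequence from the uniform composition
random_seq <- function(len, seed = NULL) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", NULL)[[1L]]
  gen <- function() paste(sample(aa, len, replace = TRUE), collapse = "")
  if (is.null(seed)) gen() else withr_seed(seed, gen())
}

# evaluate `code` under a temporary seed, restoring the caller's RNG stream
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# a "buried core" fixture: one central GLY residue inside three dense
# concentric shells of carbon atoms so that no 1.4 A probe reaches it
make_buried_core <- function(shell_radii = c(4.5, 6.5, 8.5), n_shell = 250L) {
  pts <- function(n) {
    i <- seq_len(n) - 0.5
    phi <- acos(1 - 2 * i / n)
    th <- pi * (1 + sqrt(5)) * i
    cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
  }
  shells <- do.call(rbind, lapply(shell_radii, function(r) pts(n_shell) * r))
  atoms <- data.frame(
    residue_index = c(1L, rep(2L, nrow(shells))),
    resname = c("GLY", rep("ALA", nrow(shells))),
    atom_name = c("CA", sprintf("C%d", seq_len(nrow(shells)))),
    element = "C",
    x = c(0, shells[, 1L]), y = c(0, shells[, 2L]), z = c(0, shells[, 3L]),
    stringsAsFactors = FALSE)
  structure_object("buried_core", atoms)
}

# rigid-body rotation + translation of a Structure
transform_structure <- function(st, angle = 0.7, axis = c(1, 2, 3),
                                shift = c(5, -3, 11)) {
  u <- axis / sqrt(sum(axis^2))
  c1 <- cos(angle); s1 <- sin(angle)
  R <- c1 * diag(3) + s1 * rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]),
                                 c(-u[2], u[1], 0)) +
    (1 - c1) * (u %o% u)
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% t(R)
  a <- st$atoms
  a$x <- xyz[, 1L] + shift[1L]
  a$y <- xyz[, 2L] + shift[2L]
  a$z <- xyz[, 3L] + shift[3L]
  structure_object(st$id, a)
}
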