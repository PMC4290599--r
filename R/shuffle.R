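#' Count overlapping k-mers of a sequence
#'
#' @param seq A DNA string.
#' @param k k-mer size (default 3).
#' @return A table of overlapping k-mer counts.
#' @export
count_kmers <- function(seq, k = 3L) {
  n <- nchar(seq)
  if (n < k) return(table(character(0)))
  table(substring(seq, 1:(n - k + 1L), k:n))
}

#' Trinucleotide shuffle of a sequence
#'
#' Draws a uniform sample from the set of sequences having exactly the same
#' multiset of overlapping trinucleotides as `seq` (and hence the same length,
#' dinucleotide and base composition, and the same first and last
#' dinucleotide). This generalizes the Altschul-Erickson doublet-shuffle to
#' order 2: vertices are overlapping dinucleotides, each trinucleotide is an
#' edge, and a random Eulerian path from the first to the last dinucleotide
#' is drawn by sampling a uniformly random valid last-edge assignment (an
#' arborescence toward the final vertex, obtained by rejection) and uniformly
#' permuting the remaining edges at each vertex.
#'
#' Trinucleotide (rather than mono- or dinucleotide) shuffling is the natural
#' negative control for G4 sequences because G-runs of three or more
#' consecutive Gs are what stabilize the structure: the shuffle preserves
#' GGG content while destroying the four-run architecture.
#'
#' @param seq A DNA string of length >= 3; shorter sequences are returned
#'   unchanged with `degenerate = TRUE` and a warning.
#' @param seed Optional integer seed (`set.seed` is called when supplied).
#' @param max_tries Cap on arborescence rejection sampling.
#' @return An object of class `shuffle_result`: list with `original`,
#'   `shuffled`, `degenerate`, and the overlapping trinucleotide count tables
#'   `k3_before` and `k3_after` (always identical).
#' @export
trinucleotide_shuffle <- function(seq, seed = NULL, max_tries = 10000L) {
  if (!is.null(seed)) set.seed(seed)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 3L) {
    warning("sequence shorter than 3: returned unchanged")
    return(structure(list(original = seq, shuffled = seq, degenerate = TRUE,
                          k3_before = count_kmers(seq), k3_after = count_kmers(seq)),
                     class = "shuffle_result"))
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  verts <- paste0(chars[-n], chars[-1])            # n-1 overlapping dinucleotides
  from <- verts[-(n - 1L)]
  to <- verts[-1L]                                 # n-2 edges (trinucleotides)
  s <- verts[1L]
  t <- verts[n - 1L]
  adj <- split(to, factor(from, levels = unique(verts)))
  adj <- adj[vapply(adj, length, integer(1)) > 0L]
  vs <- setdiff(names(adj), t)                     # vertices needing a last edge

  ord <- NULL
  if (length(vs) == 0L) {
    ord <- lapply(adj, function(e) sample.int(length(e)))
  } else {
    for (try in seq_len(max_tries)) {
      last <- vapply(vs, function(v) {
        e <- adj[[v]]
        e[[sample.int(length(e), 1L)]]
      }, character(1))
      # valid iff following last-edge pointers from every vertex reaches t
      ok <- TRUE
      for (v in vs) {
        cur <- v
        steps <- 0L
        while (cur != t) {
          cur <- last[[cur]]
          steps <- steps + 1L
          if (is.null(cur) || !(cur %in% c(vs, t)) || steps > length(vs)) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      if (ok) {
        ord <- lapply(names(adj), function(v) {
          e <- adj[[v]]
          if (!v %in% vs) return(sample.int(length(e)))
          li <- which(e == last[[v]])[1L]
          rest <- setdiff(seq_along(e), li)
          c(if (length(rest)) rest[sample.int(length(rest))], li)
        })
        names(ord) <- names(adj)
        break
      }
    }
    if (is.null(ord)) stop("failed to sample a valid last-edge arborescence")
  }

  ptr <- setNames(rep(1L, length(adj)), names(adj))
  out <- c(chars[1L], chars[2L])
  cur <- s
  for (step in seq_len(n - 2L)) {
    e <- adj[[cur]]
    nxt <- e[[ord[[cur]][ptr[[cur]]]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out <- c(out, substr(nxt, 2L, 2L))
    cur <- nxt
  }
  shuffled <- paste(out, collapse = "")
  k3b <- count_kmers(seq)
  k3a <- count_kmers(shuffled)
  stopifnot(identical(sort(names(k3b)), sort(names(k3a))),
            all(k3a[names(k3b)] == k3b))
  structure(list(original = seq, shuffled = shuffled, degenerate = FALSE,
                 k3_before = k3b, k3_after = k3a),
            class = "shuffle_result")
}

#' @export
print.shuffle_result <- function(x, ...) {
  cat(sprintf("<shuffle_result>%s\n  original: %s\n  shuffled: %s\n",
              if (x$degenerate) " (degenerate)" else "",
              x$original, x$shuffled))
  invisible(x)
}

#' Build a trinucleotide-shuffled negative set
#'
#' One shuffled negative per positive sequence, reproducible under `seed`.
#' Ids (if present) gain a `_shuf` suffix.
#'
#' @param positives Named character vector of positive sequences.
#' @param seed Integer seed for the whole set.
#' @return Named character vector of shuffled sequences, same length.
#' @export
make_negative_set <- function(positives, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- vapply(positives, function(s) trinucleotide_shuffle(s)$shuffled,
                character(1), USE.NAMES = FALSE)
  names(out) <- if (!is.null(names(positives))) paste0(names(positives), "_shuf")
  out
}

#' Naive codon-style shuffle (non-default comparison variant)
#'
#' Permutes the non-overlapping trinucleotide codons of a sequence (trailing
#' 1-2 bases kept in place). Unlike [trinucleotide_shuffle()] this does *not*
#' preserve the overlapping 3-mer multiset; it is provided only for
#' comparison and is clearly non-default.
#'
#' @inheritParams trinucleotide_shuffle
#' @return A shuffled DNA string.
#' @export
codon_shuffle <- function(seq, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seq <- toupper(seq)
  n <- nchar(seq)
  ncod <- n %/% 3L
  if (ncod < 2L) return(seq)
  codons <- substring(seq, 3L * (seq_len(ncod) - 1L) + 1L, 3L * seq_len(ncod))
  tail <- if (n %% 3L) substr(seq, 3L * ncod + 1L, n) else ""
  paste0(paste(codons[sample.int(ncod)], collapse = ""), tail)
}
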