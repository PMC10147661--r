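# Genotype space of three-node CRISPRi circuits.
#
# A genotype is an 8-slot vector: six edge slots in the fixed order
# A->B, A->C, B->A, B->C, C->A, C->B (A = orange/input node, B = blue,
# C = green), each holding an sgRNA identity or ABSENT, plus two promoter
# slots for nodes B and C. The genotype space contains every assignment with
# 3 to 6 present edges; topologies with 1-2 repressions are excluded.

# slot -> (source, target) wiring, nodes coded 1 = A, 2 = B, 3 = C
EDGE_SRC <- c(1L, 1L, 2L, 2L, 3L, 3L)
EDGE_TGT <- c(2L, 3L, 1L, 3L, 1L, 2L)
EDGE_NAMES <- c("A->B", "A->C", "B->A", "B->C", "C->A", "C->B")

#' Construct a circuit genotype
#'
#' @param edges Integer vector of length 6 over `0..s`: for each edge slot
#'   (order `A->B, A->C, B->A, B->C, C->A, C->B`), the 1-based index of the
#'   sgRNA in the parts library occupying it, or `0` for an absent edge.
#' @param promoter_B,promoter_C Promoter token (name in `parts$promoters`,
#'   `"0"` accepted for `ZERO`) or 1-based index of the promoter level driving
#'   the blue / green node.
#' @param parts A [parts_library()].
#' @return An object of class `grn_genotype` with fields `edges` (integer 6),
#'   `prom` (integer 2, indices into `parts$promoters`).
#' @examples
#' g <- genotype(c(1, 2, 0, 4, 0, 0), "PH", "PL")
#' n_edges(g)
#' @export
genotype <- function(edges, promoter_B, promoter_C, parts = parts_library()) {
  edges <- as.integer(edges)
  if (length(edges) != 6) stop("edges must have length 6")
  if (any(edges < 0L | edges > parts$s)) {
    bad <- which(edges < 0L | edges > parts$s)[1]
    stop(sprintf("edge slot %d (%s): sgRNA index %d outside 0..%d",
                 bad, EDGE_NAMES[bad], edges[bad], parts$s))
  }
  prom <- vapply(list(promoter_B, promoter_C), resolve_promoter, integer(1), parts = parts)
  g <- structure(list(edges = edges, prom = prom), class = "grn_genotype")
  e <- n_edges(g)
  if (e < 3L || e > 6L) {
    stop(sprintf("genotype has %d edges; the space requires 3 to 6", e))
  }
  g
}

resolve_promoter <- function(x, parts) {
  toks <- names(parts$promoters)
  if (is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 1 && x <= parts$p && x == round(x)) {
    return(as.integer(x))
  }
  x <- as.character(x)
  if (identical(x, "0")) x <- "ZERO"
  i <- match(x, toks)
  if (is.na(i)) stop(sprintf("unknown promoter token '%s' (expected one of %s)",
                             x, paste(toks, collapse = ", ")))
  i
}

#' Number of present edges (repressions) of a genotype
#' @param g A `grn_genotype` or encoding string.
#' @param parts Parts library used to decode strings.
#' @return Integer in 3..6 for any valid genotype.
#' @export
n_edges <- function(g, parts = parts_library()) {
  g <- as_genotype(g, parts)
  sum(g$edges > 0L)
}

#' Coerce to a genotype object
#' @inheritParams n_edges
#' @return A `grn_genotype`.
#' @export
as_genotype <- function(g, parts = parts_library()) {
  if (inherits(g, "grn_genotype")) return(g)
  if (is.character(g) && length(g) == 1) return(decode_genotype(g, parts))
  stop("cannot interpret object of class ", paste(class(g), collapse = "/"), " as a genotype")
}

#' @export
print.grn_genotype <- function(x, ...) {
  cat("<grn_genotype> ", encode_genotype(x), " (", n_edges(x), " edges)\n", sep = "")
  invisible(x)
}

#' @export
format.grn_genotype <- function(x, ...) encode_genotype(x)

#' Encode / decode the canonical genotype string
#'
#' The canonical grammar is `"e1-e2-e3-e4-e5-e6|pB-pC"`: six edge tokens
#' (1-based sgRNA index, `0` for absent) followed by the two promoter tokens
#' (`PH`/`PM`/`PL`/..., `0` for the knockout level). Decoding accepts sgRNA
#' identifiers (e.g. `sg1t4`) in place of indices; encoding always emits
#' indices, so `encode(decode(x))` is canonical and round-trips losslessly on
#' canonical strings.
#'
#' @param g A `grn_genotype`.
#' @param text A genotype string.
#' @param parts A [parts_library()].
#' @return `encode_genotype()`: a character scalar. `decode_genotype()`: a
#'   `grn_genotype`; malformed tokens raise an error naming the offending field.
#' @examples
#' g <- decode_genotype("1-0-0-2-4-0|PH-PL")
#' encode_genotype(g)
#' @export
encode_genotype <- function(g, parts = parts_library()) {
  g <- as_genotype(g, parts)
  ptok <- names(parts$promoters)[g$prom]
  ptok[ptok == "ZERO"] <- "0"
  paste0(paste(g$edges, collapse = "-"), "|", paste(ptok, collapse = "-"))
}

#' @rdname encode_genotype
#' @export
decode_genotype <- function(text, parts = parts_library()) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    stop("genotype text must be a single string")
  }
  halves <- strsplit(text, "|", fixed = TRUE)[[1]]
  if (length(halves) != 2) stop("malformed genotype '", text, "': expected one '|' separator")
  etok <- strsplit(halves[1], "-", fixed = TRUE)[[1]]
  ptok <- strsplit(halves[2], "-", fixed = TRUE)[[1]]
  if (length(etok) != 6) stop("malformed genotype '", text, "': expected 6 edge tokens")
  if (length(ptok) != 2) stop("malformed genotype '", text, "': expected 2 promoter tokens")
  edges <- integer(6)
  for (i in seq_len(6)) {
    tk <- etok[i]
    if (grepl("^[0-9]+$", tk)) {
      v <- as.integer(tk)
      if (v > parts$s) stop(sprintf("edge slot %d (%s): index %d exceeds library size %d",
                                    i, EDGE_NAMES[i], v, parts$s))
      edges[i] <- v
    } else {
      v <- match(tk, parts$sgrna_ids)
      if (is.na(v)) stop(sprintf("edge slot %d (%s): unknown sgRNA token '%s'",
                                 i, EDGE_NAMES[i], tk))
      edges[i] <- v
    }
  }
  genotype(edges, ptok[1], ptok[2], parts)
}

# ---- topologies --------------------------------------------------------------

#' Enumerate circuit topologies
#'
#' A topology is the presence mask over the six directed repression slots; the
#' space admits every mask with 3 to 6 present edges, giving the 42 topologies
#' of the three-node space without self-repression. Masks are encoded as
#' 6-character bitstrings in the canonical edge order.
#'
#' @return A tibble with columns `topology` (bitstring), `n_edges`, ordered by
#'   edge count then by bitstring.
#' @examples
#' nrow(enumerate_topologies()) # 42
#' @export
enumerate_topologies <- function() {
  masks <- lapply(0:63, function(m) as.integer(intToBits(m)[1:6]))
  keep <- vapply(masks, function(b) sum(b) >= 3 && sum(b) <= 6, logical(1))
  masks <- masks[keep]
  tb <- tibble::tibble(
    topology = vapply(masks, function(b) paste(b, collapse = ""), character(1)),
    n_edges = vapply(masks, sum, integer(1))
  )
  dplyr::arrange(tb, .data$n_edges, .data$topology)
}

#' Topology (edge presence mask) of a genotype
#' @inheritParams n_edges
#' @return A 6-character bitstring in canonical edge order.
#' @export
topology_of <- function(g, parts = parts_library()) {
  g <- as_genotype(g, parts)
  paste(as.integer(g$edges > 0L), collapse = "")
}

#' Are two topologies reachable by a single mutation?
#' @param t1,t2 Topology bitstrings.
#' @return `TRUE` iff the masks differ in exactly one slot.
#' @export
topology_adjacent <- function(t1, t2) {
  b1 <- as.integer(strsplit(t1, "")[[1]])
  b2 <- as.integer(strsplit(t2, "")[[1]])
  if (length(b1) != 6 || length(b2) != 6) stop("topologies must be 6-bit strings")
  sum(b1 != b2) == 1L
}

#' Number of genotypes realising a topology
#'
#' With `p` promoter levels for the two constitutive nodes and `s` sgRNAs per
#' present edge, a topology with `E` edges is realised by `p^2 * s^E`
#' genotypes.
#'
#' @param topology A 6-character bitstring (or a row of [enumerate_topologies()]).
#' @param parts A [parts_library()].
#' @return Integer count.
#' @examples
#' genotype_count("111000") # 3456 with the default parts
#' @export
genotype_count <- function(topology, parts = parts_library()) {
  e <- sum(as.integer(strsplit(topology, "")[[1]]))
  if (e < 3 || e > 6) stop("topology must have 3 to 6 edges")
  parts$p^2 * parts$s^e
}

#' Total size of the genotype space
#'
#' Sum of [genotype_count()] over all topologies: 1,873,152 for the default
#' parts (6 sgRNAs, 4 promoter levels).
#'
#' @param parts A [parts_library()].
#' @return Integer (as double for large libraries).
#' @export
total_space_size <- function(parts = parts_library()) {
  tp <- enumerate_topologies()
  sum(vapply(tp$topology, genotype_count, numeric(1), parts = parts))
}

# ---- neighborhood ------------------------------------------------------------

#' 1-Hamming mutational neighborhood of a genotype
#'
#' All genotypes differing from `g` in exactly one of the 8 slots (an sgRNA
#' substitution, an edge gain or loss, or a promoter level change) that remain
#' inside the 3-6-edge space. Edge removal is forbidden for 3-edge genotypes,
#' so they have 39 neighbors while 4-6-edge genotypes have 42 (default parts).
#'
#' @inheritParams n_edges
#' @return Character vector of canonical genotype encodings, deterministic
#'   order (slot-major, then substituted value), excluding `g` itself.
#' @examples
#' length(genotype_neighbors("1-2-0-4-0-0|PH-PL")) # 39
#' @export
genotype_neighbors <- function(g, parts = parts_library()) {
  g <- as_genotype(g, parts)
  e <- n_edges(g)
  out <- character(0)
  for (slot in 1:6) {
    cur <- g$edges[slot]
    for (v in 0:parts$s) {
      if (v == cur) next
      if (v == 0L && e == 3L) next # removal would leave the space
      h <- g
      h$edges[slot] <- as.integer(v)
      out <- c(out, encode_genotype(h, parts))
    }
  }
  for (pslot in 1:2) {
    cur <- g$prom[pslot]
    for (v in seq_len(parts$p)) {
      if (v == cur) next
      h <- g
      h$prom[pslot] <- v
      out <- c(out, encode_genotype(h, parts))
    }
  }
  out
}

#' Hamming distance between two genotypes over the 8 slots
#' @param g1,g2 Genotypes (objects or encodings).
#' @param parts A [parts_library()].
#' @return Integer in 0..8.
#' @export
genotype_hamming <- function(g1, g2, parts = parts_library()) {
  g1 <- as_genotype(g1, parts)
  g2 <- as_genotype(g2, parts)
  sum(g1$edges != g2$edges) + sum(g1$prom != g2$prom)
}

#' Draw genotypes uniformly at random from the space
#'
#' Sampling is uniform over genotypes (not over topologies): a topology is
#' selected with probability proportional to its genotype count, then sgRNAs
#' and promoters are drawn uniformly.
#'
#' @param n Number of genotypes.
#' @param parts A [parts_library()].
#' @return Character vector of `n` canonical encodings (duplicates possible,
#'   as in uniform sampling with replacement).
#' @export
sample_genotypes <- function(n, parts = parts_library()) {
  tp <- enumerate_topologies()
  w <- vapply(tp$topology, genotype_count, numeric(1), parts = parts)
  rows <- sample.int(nrow(tp), n, replace = TRUE, prob = w)
  vapply(rows, function(r) {
    mask <- as.integer(strsplit(tp$topology[r], "")[[1]])
    edges <- integer(6)
    edges[mask == 1L] <- sample.int(parts$s, sum(mask), replace = TRUE)
    encode_genotype(genotype(edges,
                             sample.int(parts$p, 1),
                             sample.int(parts$p, 1),
                             parts), parts)
  }, character(1))
}
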