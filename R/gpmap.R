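# Genotype-phenotype map and genotype-network statistics. A phenotype map
# is a lazily evaluated, cached labeling of genotypes; every statistic
# (components, robustness, evolvability, transition frequencies, random
# walks, epistasis) queries labels through the map so that each genotype is
# classified at most once per provenance.

fnv1a <- function(obj) {
  raw <- as.integer(serialize(obj, NULL, version = 2))
  h <- 2166136261
  for (b in raw) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    # 32-bit modular multiply by the FNV prime, split to stay in double range
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Create a phenotype map
#'
#' Binds a labeling function (mechanistic classification under a fixed
#' parameter set, or an arbitrary deterministic rule for toy maps) to a
#' cache. Labels are computed on first query and cached; the provenance hash
#' covers the parameter set and classifier settings so caches from different
#' provenances are never mixed.
#'
#' @param theta Parameter set used for classification (ignored when `rule`
#'   is given).
#' @param parts Parts library.
#' @param mode `"steady"` (GREEN/BLUE/NF) or `"dynamic"` (OSC/NF).
#' @param criterion Stripe criterion (steady mode).
#' @param rule Optional labeling function `function(genotype_string) label`;
#'   when supplied it replaces the mechanistic classifier (toy maps).
#' @param labels Optional named character vector of precomputed labels; a
#'   map built from labels alone is closed: querying an unlabeled genotype
#'   is an error.
#' @return An object of class `phenotype_map`.
#' @export
phenotype_map <- function(theta = default_parameters(parts),
                          parts = parts_library(),
                          mode = c("steady", "dynamic"),
                          criterion = stripe_criterion(),
                          rule = NULL, labels = NULL) {
  mode <- match.arg(mode)
  cache <- new.env(parent = emptyenv())
  if (!is.null(labels)) {
    stopifnot(!is.null(names(labels)))
    for (g in names(labels)) assign(g, labels[[g]], envir = cache)
  }
  label_fun <- if (!is.null(rule)) {
    function(gstr) rule(gstr)
  } else if (!is.null(labels)) {
    NULL # closed map
  } else if (mode == "steady") {
    function(gstr) classify_steady(gstr, theta, parts, criterion)
  } else {
    function(gstr) classify_dynamic(gstr, theta, parts)
  }
  prov <- fnv1a(list(
    mode = mode, criterion = unclass(criterion),
    theta = if (is.null(rule) && is.null(labels)) unclass(theta) else NULL,
    rule = if (!is.null(rule)) deparse(body(rule)) else NULL,
    closed = is.null(rule) && !is.null(labels)
  ))
  structure(
    list(cache = cache, label_fun = label_fun, parts = parts,
         mode = mode, criterion = criterion, provenance = prov,
         phenotypes = if (mode == "steady") c("GREEN", "BLUE", "NF") else c("OSC", "NF")),
    class = "phenotype_map"
  )
}

#' @export
print.phenotype_map <- function(x, ...) {
  cat("<phenotype_map> mode ", x$mode, ", ", length(ls(x$cache)),
      " cached labels, provenance ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Query (and cache) phenotype labels
#'
#' @param map A [phenotype_map()].
#' @param genotypes Character vector of genotype encodings.
#' @return Character vector of labels, same length and order.
#' @export
map_label <- function(map, genotypes) {
  vapply(genotypes, function(g) {
    if (!exists(g, envir = map$cache, inherits = FALSE)) {
      if (is.null(map$label_fun)) {
        stop("genotype ", g, " is not labeled in this closed phenotype map")
      }
      assign(g, map$label_fun(g), envir = map$cache)
    }
    get(g, envir = map$cache, inherits = FALSE)
  }, character(1), USE.NAMES = FALSE)
}

#' Cached labels as a tibble
#' @param map A `phenotype_map`.
#' @return Tibble with columns `genotype`, `label`.
#' @export
map_labels_tbl <- function(map) {
  gs <- sort(ls(map$cache))
  tibble::tibble(genotype = gs,
                 label = vapply(gs, get, character(1), envir = map$cache))
}

# single-slot changes of g, annotated by slot; edge removals that would
# leave the space are excluded (mirrors genotype_neighbors)
genotype_mutations <- function(g, parts = parts_library()) {
  g <- as_genotype(g, parts)
  e <- n_edges(g)
  slots <- integer(0); encs <- character(0)
  for (slot in 1:6) {
    cur <- g$edges[slot]
    for (v in 0:parts$s) {
      if (v == cur || (v == 0L && e == 3L)) next
      h <- g; h$edges[slot] <- as.integer(v)
      slots <- c(slots, slot); encs <- c(encs, encode_genotype(h, parts))
    }
  }
  for (pslot in 1:2) {
    cur <- g$prom[pslot]
    for (v in seq_len(parts$p)) {
      if (v == cur) next
      h <- g; h$prom[pslot] <- v
      slots <- c(slots, 6L + pslot); encs <- c(encs, encode_genotype(h, parts))
    }
  }
  tibble::tibble(slot = slots, genotype = encs)
}

#' Connected components of genotype networks
#'
#' Builds the induced subgraph on the given genotypes (vertices) with edges
#' between 1-Hamming neighbors, restricted per phenotype, and returns the
#' maximal connected sets (breadth-first search via igraph).
#'
#' @param map A `phenotype_map`.
#' @param genotypes Character vector of genotypes to consider.
#' @param phenotype Optional single phenotype to restrict to; default all.
#' @return Tibble with columns `genotype`, `label`, `component` (component
#'   ids numbered within each phenotype, decreasing size).
#' @export
map_components <- function(map, genotypes, phenotype = NULL) {
  genotypes <- unique(genotypes)
  lab <- map_label(map, genotypes)
  keep <- if (is.null(phenotype)) rep(TRUE, length(genotypes)) else lab == phenotype
  out <- list()
  for (ph in unique(lab[keep])) {
    vs <- genotypes[lab == ph & keep]
    idx <- stats::setNames(seq_along(vs), vs)
    edges <- integer(0)
    for (v in vs) {
      nb <- intersect(genotype_neighbors(v, map$parts), vs)
      nb <- nb[idx[nb] > idx[v]]
      if (length(nb)) edges <- c(edges, rbind(idx[v], idx[nb]))
    }
    gr <- igraph::make_empty_graph(n = length(vs), directed = FALSE)
    if (length(edges)) gr <- igraph::add_edges(gr, edges)
    comp <- igraph::components(gr)
    ord <- rank(-comp$csize, ties.method = "first")[comp$membership]
    out[[ph]] <- tibble::tibble(genotype = vs, label = ph, component = as.integer(ord))
  }
  dplyr::bind_rows(out)
}

#' Genotypic evolvability
#'
#' Number of distinct phenotypes among a genotype's 1-mutation neighbors.
#'
#' @param g Genotype encoding.
#' @param map A `phenotype_map`.
#' @return Integer `>= 1`.
#' @export
genotype_evolvability <- function(g, map) {
  length(unique(map_label(map, genotype_neighbors(g, map$parts))))
}

#' Genotypic robustness
#'
#' Fraction of a genotype's 1-mutation neighbors sharing its phenotype.
#'
#' @inheritParams genotype_evolvability
#' @return Numeric in `[0, 1]`.
#' @export
genotype_robustness <- function(g, map) {
  nb <- genotype_neighbors(g, map$parts)
  mean(map_label(map, nb) == map_label(map, g))
}

#' Robustness per perturbation slot
#'
#' For each genotype of the given phenotype, the fraction of neighbors
#' differing at one specific slot (1-6: edge sgRNA identity, 7-8: promoter
#' of node B / C) that keep the phenotype.
#'
#' @param map A `phenotype_map`.
#' @param genotypes Genotypes to evaluate (e.g. a phenotype-stratified
#'   sample).
#' @param slots Slots to evaluate (default all 8).
#' @return Tibble with columns `genotype`, `label`, `slot`, `robustness`
#'   (`NA` when a slot admits no in-space change).
#' @export
robustness_per_perturbation <- function(map, genotypes, slots = 1:8) {
  rows <- lapply(genotypes, function(g) {
    mu <- genotype_mutations(g, map$parts)
    lab <- map_label(map, g)
    vapply(slots, function(s) {
      nb <- mu$genotype[mu$slot == s]
      if (!length(nb)) return(NA_real_)
      mean(map_label(map, nb) == lab)
    }, numeric(1))
  })
  tibble::tibble(
    genotype = rep(genotypes, each = length(slots)),
    label = rep(map_label(map, genotypes), each = length(slots)),
    slot = rep(slots, length(genotypes)),
    robustness = unlist(rows)
  )
}

#' Phenotype transition frequencies between neighboring genotypes
#'
#' For each evaluated genotype, the fraction of its 1-neighbors carrying
#' each phenotype; summarised per source phenotype by the median and
#' interquartile range over genotypes. The diagonal is the per-genotype
#' robustness distribution.
#'
#' @param map A `phenotype_map`.
#' @param genotypes Genotypes to evaluate.
#' @return A tibble of class `grn_transitions` with columns `source`,
#'   `target`, `median`, `q25`, `q75`, `n`.
#' @export
transition_frequencies <- function(map, genotypes) {
  phenos <- map$phenotypes
  src <- map_label(map, genotypes)
  fr <- t(vapply(genotypes, function(g) {
    lab <- map_label(map, genotype_neighbors(g, map$parts))
    vapply(phenos, function(p) mean(lab == p), numeric(1))
  }, numeric(length(phenos))))
  out <- tidyr::expand_grid(source = phenos, target = phenos)
  stats_row <- function(s, t) {
    v <- fr[src == s, match(t, phenos)]
    if (!length(v)) return(c(NA_real_, NA_real_, NA_real_, 0))
    c(stats::median(v), stats::quantile(v, c(0.25, 0.75), names = FALSE), length(v))
  }
  m <- unname(mapply(stats_row, out$source, out$target))
  out$median <- unname(m[1, ]); out$q25 <- unname(m[2, ])
  out$q75 <- unname(m[3, ]); out$n <- as.integer(m[4, ])
  class(out) <- c("grn_transitions", class(out))
  out
}

#' Per-topology evolvability / robustness summary with motif clustering
#'
#' For each sampled genotype, evolvability and robustness are computed twice:
#' over the entire 1-neighborhood (`E`, `R`) and over only the neighbors
#' sharing the genotype's topology, i.e. identical edge mask (`E_F`, `R_F`).
#' Topology means are clustered by k-means (default k = 5, best of 10
#' restarts) on the `(E, E_F)` plane.
#'
#' @param map A `phenotype_map`.
#' @param genotypes Genotypes to evaluate (grouped by their topology).
#' @param k Number of k-means clusters.
#' @param nstart k-means restarts.
#' @return A tibble of class `grn_topology_summary`: one row per topology
#'   with columns `topology`, `n_edges`, `n`, `E`, `E_F`, `R`, `R_F`,
#'   `cluster`.
#' @export
topology_summary <- function(map, genotypes, k = 5, nstart = 10) {
  per_g <- lapply(genotypes, function(g) {
    topo <- topology_of(g, map$parts)
    nb <- genotype_neighbors(g, map$parts)
    nb_lab <- map_label(map, nb)
    own <- map_label(map, g)
    fixed <- vapply(nb, function(h) topology_of(h, map$parts) == topo, logical(1))
    tibble::tibble(
      topology = topo,
      E = length(unique(nb_lab)),
      E_F = length(unique(nb_lab[fixed])),
      R = mean(nb_lab == own),
      R_F = mean(nb_lab[fixed] == own)
    )
  })
  tb <- dplyr::bind_rows(per_g)
  sm <- dplyr::summarise(tb,
    n = dplyr::n(), E = mean(.data$E), E_F = mean(.data$E_F),
    R = mean(.data$R), R_F = mean(.data$R_F),
    .by = "topology"
  )
  sm$n_edges <- vapply(sm$topology,
                       function(t) sum(as.integer(strsplit(t, "")[[1]])), integer(1))
  keff <- min(k, nrow(unique(sm[, c("E", "E_F")])))
  sm$cluster <- if (keff >= 2) {
    as.integer(stats::kmeans(as.matrix(sm[, c("E", "E_F")]), centers = keff,
                             nstart = nstart)$cluster)
  } else {
    1L
  }
  sm <- sm[, c("topology", "n_edges", "n", "E", "E_F", "R", "R_F", "cluster")]
  class(sm) <- c("grn_topology_summary", class(sm))
  sm
}

#' Random mutational walks until phenotype change
#'
#' From each start, repeatedly move to a uniformly chosen 1-neighbor; the
#' walk length is the step index at which the phenotype first differs from
#' the start's phenotype, censored at `max_steps` (censored walks count
#' `max_steps` in the median, and are flagged).
#'
#' @param map A `phenotype_map`.
#' @param starts Character vector of start genotypes (typically all of one
#'   phenotype).
#' @param max_steps Step cap (50 for functional phenotypes, 300 for NF).
#' @return A tibble of class `grn_walks` with columns `start`, `length`,
#'   `censored`; attributes `median` (censoring-at-cap convention) and
#'   `censoring_rate`.
#' @export
random_walk_lengths <- function(map, starts, max_steps = 50) {
  res <- lapply(starts, function(g0) {
    ph0 <- map_label(map, g0)
    g <- g0
    for (step in seq_len(max_steps)) {
      nb <- genotype_neighbors(g, map$parts)
      g <- nb[sample.int(length(nb), 1)]
      if (map_label(map, g) != ph0) {
        return(c(step, 0))
      }
    }
    c(max_steps, 1)
  })
  m <- do.call(rbind, res)
  out <- tibble::tibble(start = starts, length = m[, 1], censored = m[, 2] == 1)
  attr(out, "median") <- stats::median(out$length)
  attr(out, "censoring_rate") <- mean(out$censored)
  class(out) <- c("grn_walks", class(out))
  out
}

#' Prevalence of order-dependent epistasis
#'
#' For each genotype `g` with phenotype `phi`, enumerate unordered pairs of
#' single changes `{A, B}` at distinct slots such that `g+A`, `g+B` and
#' `g+A+B` are all inside the genotype space. A pair is an epistatic
#' instance when the double mutant keeps `phi` but exactly one of the two
#' intermediates loses it: the two orders of applying the same changes then
#' differ in whether the path stays on the genotype network. The per-genotype
#' prevalence is instances / evaluated pairs.
#'
#' @param map A `phenotype_map`.
#' @param genotypes Genotypes to evaluate.
#' @param max_pairs Optional cap on evaluated pairs per genotype (uniform
#'   subsample; `Inf` evaluates all).
#' @return A tibble of class `grn_epistasis` with columns `genotype`,
#'   `label`, `pairs`, `instances`, `prevalence`; attributes `median`,
#'   `q25`, `q75` and `pooled` (total instances / total pairs).
#' @export
epistasis_prevalence <- function(map, genotypes, max_pairs = Inf) {
  rows <- lapply(genotypes, function(g0) {
    g <- as_genotype(g0, map$parts)
    phi <- map_label(map, encode_genotype(g, map$parts))
    mu <- genotype_mutations(g, map$parts)
    # split changes by slot; pair changes at distinct slots
    pair_idx <- which(outer(mu$slot, mu$slot, `<`), arr.ind = TRUE)
    if (is.finite(max_pairs) && nrow(pair_idx) > max_pairs) {
      pair_idx <- pair_idx[sample.int(nrow(pair_idx), max_pairs), , drop = FALSE]
    }
    n_pairs <- 0L; n_inst <- 0L
    for (r in seq_len(nrow(pair_idx))) {
      i <- pair_idx[r, 1]; j <- pair_idx[r, 2]
      dbl <- apply_two_changes(g, mu$genotype[i], mu$slot[i],
                               mu$genotype[j], mu$slot[j], map$parts)
      if (is.null(dbl)) next # double mutant outside the space
      n_pairs <- n_pairs + 1L
      if (map_label(map, dbl) == phi) {
        ok <- map_label(map, c(mu$genotype[i], mu$genotype[j])) == phi
        if (sum(ok) == 1L) n_inst <- n_inst + 1L
      }
    }
    tibble::tibble(genotype = encode_genotype(g, map$parts), label = phi,
                   pairs = n_pairs, instances = n_inst,
                   prevalence = if (n_pairs > 0) n_inst / n_pairs else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "median") <- stats::median(out$prevalence, na.rm = TRUE)
  attr(out, "q25") <- stats::quantile(out$prevalence, 0.25, na.rm = TRUE, names = FALSE)
  attr(out, "q75") <- stats::quantile(out$prevalence, 0.75, na.rm = TRUE, names = FALSE)
  attr(out, "pooled") <- sum(out$instances) / max(sum(out$pairs), 1L)
  class(out) <- c("grn_epistasis", class(out))
  out
}

# compose two single-slot changes on g; NULL when the double mutant leaves
# the 3-6-edge space
apply_two_changes <- function(g, enc_i, slot_i, enc_j, slot_j, parts) {
  gi <- as_genotype(enc_i, parts)
  h <- g
  if (slot_i <= 6) h$edges[slot_i] <- gi$edges[slot_i] else h$prom[slot_i - 6] <- gi$prom[slot_i - 6]
  gj <- as_genotype(enc_j, parts)
  if (slot_j <= 6) h$edges[slot_j] <- gj$edges[slot_j] else h$prom[slot_j - 6] <- gj$prom[slot_j - 6]
  e <- sum(h$edges > 0L)
  if (e < 3L || e > 6L) return(NULL)
  encode_genotype(h, parts)
}

#' Stratified phenotype sample from the genotype space
#'
#' Draws uniform genotypes, labels them through the map, and keeps up to
#' `n_per` genotypes per requested phenotype (the sampling scheme behind the
#' per-phenotype statistics: a fixed number of functional and non-functional
#' genotypes rather than a fixed fraction).
#'
#' @param map A `phenotype_map`.
#' @param n_per Named integer vector: phenotype -> sample size.
#' @param max_draws Cap on uniform draws while filling the strata.
#' @return Tibble with columns `genotype`, `label` (the full labeled draw
#'   is in the map's cache).
#' @export
sample_phenotype_strata <- function(map, n_per, max_draws = 100 * sum(n_per)) {
  got <- lapply(names(n_per), function(p) character(0))
  names(got) <- names(n_per)
  drawn <- 0
  while (drawn < max_draws && any(vapply(got, length, integer(1)) < n_per)) {
    batch <- unique(sample_genotypes(min(200, max_draws - drawn), map$parts))
    drawn <- drawn + length(batch)
    lab <- map_label(map, batch)
    for (p in names(n_per)) {
      need <- n_per[[p]] - length(got[[p]])
      if (need > 0) {
        new <- setdiff(batch[lab == p], got[[p]])
        got[[p]] <- c(got[[p]], utils::head(new, need))
      }
    }
  }
  tibble::tibble(
    genotype = unlist(got, use.names = FALSE),
    label = rep(names(n_per), vapply(got, length, integer(1)))
  )
}
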