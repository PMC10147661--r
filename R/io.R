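# Readers and writers for the package's artifacts: parameter sets and
# growth models as YAML, phenotype-map caches and calibration datasets as
# CSV, genotype networks as edge lists / GraphML. Every artifact carries
# enough provenance to regenerate it (seeds, provenance hashes); numbers
# round-trip at full precision.

#' Write / read a parameter set as YAML
#'
#' The schema mirrors the parameter table layout: blocks `sgrna` (one entry
#' per sgRNA), `shared`, `d_rna` and `dcas_total` (keyed by total
#' repressions), `nodes`, `ara_translation`, `scaling`, `od_cells`.
#'
#' @param theta A `grn_parameters`.
#' @param path File path.
#' @return `read_parameters` returns a `grn_parameters` identical (to full
#'   double precision) to the one written.
#' @export
write_parameters <- function(theta, path) {
  obj <- list(
    sgrna = lapply(seq_len(nrow(theta$sgrna)), function(i) as.list(theta$sgrna[i, ])),
    shared = theta$shared,
    d_rna = as.list(theta$d_rna),
    dcas_total = as.list(theta$dcas_total),
    nodes = lapply(seq_len(nrow(theta$nodes)), function(i) as.list(theta$nodes[i, ])),
    ara_translation = theta$ara_translation,
    scaling = as.list(theta$scaling),
    od_cells = theta$od_cells
  )
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  obj <- yaml::read_yaml(path)
  parameter_set(
    sgrna = dplyr::bind_rows(lapply(obj$sgrna, tibble::as_tibble)),
    shared = obj$shared,
    d_rna = unlist(obj$d_rna),
    dcas_total = unlist(obj$dcas_total),
    nodes = dplyr::bind_rows(lapply(obj$nodes, function(x) {
      x[vapply(x, is.null, logical(1))] <- NA_real_
      tibble::as_tibble(x)
    })),
    ara_translation = obj$ara_translation,
    scaling = unlist(obj$scaling),
    od_cells = obj$od_cells
  )
}

#' Write / read a growth model as YAML
#' @param gm A `grn_growth`.
#' @param path File path.
#' @export
write_growth_model <- function(gm, path) {
  yaml::write_yaml(unclass(gm), path, precision = 17)
  invisible(path)
}

#' @rdname write_growth_model
#' @export
read_growth_model <- function(path) {
  obj <- yaml::read_yaml(path)
  growth_model(p1 = obj$p1, p2 = unlist(obj$p2), p3 = unlist(obj$p3),
               p4 = unlist(obj$p4), p5 = unlist(obj$p5),
               mode = obj$mode, m_const = obj$m_const)
}

#' Persist / restore a phenotype-map cache
#'
#' The cache file is a CSV of (genotype, label, mode, provenance). Reading
#' into a map whose provenance differs is refused: labels computed under
#' different parameters or classifier settings must never be mixed.
#'
#' @param map A `phenotype_map`.
#' @param path File path.
#' @return `read_phenotype_cache` returns the map, with the stored labels
#'   inserted into its cache.
#' @export
write_phenotype_cache <- function(map, path) {
  tb <- map_labels_tbl(map)
  tb$mode <- map$mode
  tb$provenance <- map$provenance
  utils::write.csv(tb, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_cache
#' @export
read_phenotype_cache <- function(map, path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "label", "mode", "provenance")
  if (!all(need %in% names(tb))) {
    stop("phenotype cache ", path, " lacks columns: ",
         paste(setdiff(need, names(tb)), collapse = ", "))
  }
  if (nrow(tb) && any(tb$provenance != map$provenance)) {
    stop("cache provenance ", tb$provenance[1],
         " does not match this map's provenance ", map$provenance,
         "; refusing to mix")
  }
  for (i in seq_len(nrow(tb))) {
    assign(tb$genotype[i], tb$label[i], envir = map$cache)
  }
  map
}

#' Export a genotype network
#'
#' Writes the induced 1-Hamming graph on the given genotypes as an edge
#' list CSV, or GraphML via igraph (vertices annotated with phenotype
#' labels).
#'
#' @param map A `phenotype_map`.
#' @param genotypes Vertices.
#' @param path Output path.
#' @param format `"edgelist"` (CSV `from`,`to`) or `"graphml"`.
#' @export
write_genotype_network <- function(map, genotypes, path,
                                   format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  genotypes <- unique(genotypes)
  idx <- stats::setNames(seq_along(genotypes), genotypes)
  from <- character(0); to <- character(0)
  for (g in genotypes) {
    nb <- intersect(genotype_neighbors(g, map$parts), genotypes)
    nb <- nb[idx[nb] > idx[g]]
    from <- c(from, rep(g, length(nb))); to <- c(to, nb)
  }
  if (format == "edgelist") {
    utils::write.csv(data.frame(from = from, to = to), path, row.names = FALSE)
  } else {
    gr <- igraph::graph_from_data_frame(
      data.frame(from = from, to = to), directed = FALSE,
      vertices = data.frame(name = genotypes, label = map_label(map, genotypes))
    )
    igraph::write_graph(gr, path, format = "graphml")
  }
  invisible(path)
}

#' Read / write calibration datasets and dose responses as CSV
#'
#' Plain UTF-8 CSV with a header row and '.' decimal separator; malformed
#' rows are reported with their row number.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @param required Column names that must be present on read.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path, required = NULL) {
  tb <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!is.null(required)) {
    miss <- setdiff(required, names(tb))
    if (length(miss)) {
      stop("file ", path, " lacks required columns: ", paste(miss, collapse = ", "))
    }
    for (col in intersect(required, c("ara", "time", "value", "sd"))) {
      bad <- which(!is.finite(tb[[col]]))
      if (length(bad)) {
        stop("file ", path, ", column ", col, ": non-numeric value at row ", bad[1])
      }
    }
  }
  tb
}

#' Run manifest
#'
#' A JSON-able provenance record for a pipeline run: configuration hash,
#' seeds, package version and timestamp.
#'
#' @param config List of settings that determined the run.
#' @param seed Seed(s) used.
#' @return A list with elements `config_hash`, `seed`, `package_version`,
#'   `created`.
#' @export
run_manifest <- function(config, seed) {
  list(
    config_hash = fnv1a(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("grnmap")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}
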