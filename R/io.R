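#' Read a karyotype table from delimited text
#'
#' Reads a TSV (default) or CSV file with one row per sample and one
#' column per chromosome. Chromosome columns are located by
#' normalizing header names (Roman numerals in any case, Arabic
#' numbers, optional `chr` prefix); all 16 must be present. An
#' optional `role` column marks the population row for network
#' construction; an optional `sample_id` column provides row names.
#' Malformed cells are reported with their row and column.
#'
#' @param path Path to the file.
#' @param sep Field separator; by default inferred from the extension
#'   (`","` for `.csv`, tab otherwise).
#' @return Integer matrix of samples x 16 chromosomes (canonical
#'   column order), with attribute `role` (character vector or `NULL`)
#'   and row names from `sample_id` when present.
#' @export
read_karyotype_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  nm <- names(df)
  norm <- vapply(nm, function(x) {
    tryCatch(normalize_chromosome(x), error = function(e) NA_character_)
  }, "")
  chrom_cols <- which(!is.na(norm))
  present <- norm[chrom_cols]
  missing <- setdiff(chromosome_ids(), present)
  if (length(missing) > 0) {
    stop("missing chromosome column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(present)) {
    stop("duplicated chromosome column(s): ",
         paste(unique(present[duplicated(present)]), collapse = ", "))
  }
  sub <- df[, chrom_cols[match(chromosome_ids(), present)], drop = FALSE]
  for (j in seq_along(sub)) {
    v <- suppressWarnings(as.numeric(sub[[j]]))
    bad <- which(is.na(v) | v != round(v) | v < 0)
    if (length(bad) > 0) {
      stop(sprintf(
        "non-integer copy number in column '%s', row %d: '%s'",
        chromosome_ids()[j], bad[1], as.character(sub[[j]][bad[1]])))
    }
  }
  m <- as.matrix(sub)
  storage.mode(m) <- "integer"
  colnames(m) <- chromosome_ids()
  if ("sample_id" %in% nm) rownames(m) <- as.character(df$sample_id)
  attr(m, "role") <- if ("role" %in% nm) as.character(df$role) else NULL
  m
}

#' Write a karyotype table as delimited text
#'
#' Inverse of [read_karyotype_table()]: one row per sample, columns
#' `sample_id` (if the matrix has row names), optional `role`, then
#' the 16 chromosomes.
#'
#' @param karyotypes Integer matrix of samples x 16 chromosomes.
#' @param path Output path (`.csv` switches to comma separation).
#' @param role Optional character vector marking sample roles
#'   (e.g. `"population"` / `"colony"`); defaults to the matrix's
#'   `role` attribute.
#' @return `path`, invisibly.
#' @export
write_karyotype_table <- function(karyotypes, path,
                                  role = attr(karyotypes, "role")) {
  m <- as.matrix(karyotypes)
  if (ncol(m) != 16L) stop("karyotype matrix must have 16 columns")
  df <- as.data.frame(m)
  names(df) <- chromosome_ids()
  if (!is.null(role)) df <- cbind(role = role, df)
  if (!is.null(rownames(m))) df <- cbind(sample_id = rownames(m), df)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert a karyotype network to an igraph object
#'
#' Nodes carry the karyotype string, observation frequency and a root
#' marker; edges carry the chromosome-change label (e.g. `"+VII,-X"`)
#' and the number of changed chromosomes.
#'
#' @param network A `karyotype_network`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "karyotype_network"))
  n <- nrow(network$karyotypes)
  nodes <- data.frame(
    name = paste0("k", seq_len(n)),
    karyotype = apply(network$karyotypes, 1, paste, collapse = ","),
    frequency = network$frequency,
    is_root = seq_len(n) == network$root,
    stringsAsFactors = FALSE
  )
  edges <- if (nrow(network$edges) == 0L) {
    data.frame(from = character(0), to = character(0),
               label = character(0), n_changes = integer(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      from = paste0("k", network$edges$from),
      to = paste0("k", network$edges$to),
      label = network$edges$label,
      n_changes = network$edges$n_changes,
      stringsAsFactors = FALSE
    )
  }
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = nodes)
}

#' Export a karyotype network to GraphML
#'
#' Writes the network in GraphML, a standard text graph exchange
#' format readable by igraph, Cytoscape, Gephi and similar tools.
#'
#' @param network A `karyotype_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [import_network()]
#' @export
export_network <- function(network, path) {
  g <- as_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Import a karyotype network from GraphML
#'
#' Reads a file written by [export_network()] and rebuilds the
#' `karyotype_network` (topology, karyotypes, frequencies, root, edge
#' labels; the total cost is recomputed from the edge labels).
#'
#' @param path Path to a GraphML file.
#' @return A `karyotype_network`.
#' @export
import_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  karyo <- do.call(rbind, lapply(
    strsplit(igraph::vertex_attr(g, "karyotype"), ","), as.integer))
  freq <- as.integer(igraph::vertex_attr(g, "frequency"))
  root <- which(as.logical(igraph::vertex_attr(g, "is_root")))
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  cost <- if (nrow(el) > 0) {
    sum(as.integer(igraph::edge_attr(g, "n_changes")))
  } else {
    0L
  }
  new_karyotype_network(karyo, freq, root, el, cost, exact = NA)
}
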